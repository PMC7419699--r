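#' Read a tomographic volume
#'
#' Supported containers: a single multi-page TIFF, a directory of numbered
#' single-slice TIFFs (sorted by filename, ascending z), or a MetaImage
#' header (`.mhd`) with its raw data file.  A JSON sidecar written by
#' [write_volume()] (same path plus `.json`) restores the voxel size, the
#' intensity scaling used to fit TIFF's float range, and masked voxels.
#'
#' @param path file or directory to read.
#' @param voxel_size_um voxel size (um); overrides the sidecar/header value
#'   if given, required when neither exists.
#' @return a [bone_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) .stopf("no such file or directory: %s", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) .stopf("no TIFF slices in directory %s", path)
    slices <- lapply(files, tiff::readTIFF)
    vol <- .stack_slices(slices)
    side <- file.path(path, "volume.json")
  } else if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    return(.read_mhd(path, voxel_size_um))
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    vol <- .stack_slices(slices)
    side <- paste0(path, ".json")
  }
  vs <- voxel_size_um
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(vs)) vs <- sc$voxel_size_um
    if (!is.null(sc$scale)) {
      nan <- vol < sc$nan_below
      vol <- (vol - sc$gray_lo) / (sc$gray_hi - sc$gray_lo) *
        sc$scale + sc$offset
      vol[nan] <- NaN
    }
  }
  if (is.null(vs))
    .stopf("voxel size unknown: give 'voxel_size_um' or provide a sidecar")
  bone_volume(vol, voxel_size_um = vs)
}

.stack_slices <- function(slices) {
  shp <- lapply(slices, dim)
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
    .stopf("slices have mixed shapes")
  d <- c(length(slices), shp[[1]][1], shp[[1]][2])
  vol <- array(0, d)
  for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]
  vol
}

#' Write a tomographic volume
#'
#' TIFF output is 32-bit float; because that container carries values in
#' `[0, 1]` and no NaN, intensities are affinely mapped into a gray band
#' and masked voxels stored as a sentinel below it, with the inverse map
#' recorded in a JSON sidecar so that [read_volume()] restores the volume
#' to float32 precision.  MetaImage (`.mhd` + `.raw`, MET_DOUBLE) stores
#' doubles verbatim: the round trip is bit-exact, NaN included.
#'
#' @param vol a [bone_volume()].
#' @param path destination: `*.tif` (multi-page), `*.mhd`, or an existing
#'   directory (one numbered TIFF per slice plus `volume.json`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE))
    return(invisible(.write_mhd(vol, path)))
  a <- .as_array(vol)
  fin <- is.finite(a)
  lo <- if (any(fin)) min(a[fin]) else 0
  hi <- if (any(fin)) max(a[fin]) else 1
  if (hi <= lo) hi <- lo + 1
  gray_lo <- 0.125
  g <- array(0, dim(a))  # NaN sentinel: 0, data band [0.125, 1]
  g[fin] <- gray_lo + (1 - gray_lo) * (a[fin] - lo) / (hi - lo)
  sidecar <- list(voxel_size_um = voxel_size(vol),
                  scale = hi - lo, offset = lo,
                  gray_lo = gray_lo, gray_hi = 1, nan_below = gray_lo / 2,
                  dims_zyx = dim(a))
  if (dir.exists(path)) {
    nz <- dim(a)[1]
    for (z in seq_len(nz))
      tiff::writeTIFF(g[z, , ],
                      file.path(path, sprintf("slice_%04d.tif", z)),
                      bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(sidecar, file.path(path, "volume.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    pages <- lapply(seq_len(dim(a)[1]), function(z) g[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# -- MetaImage (MHD + raw): x varies fastest on disk, per the format -------

.write_mhd <- function(vol, path) {
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  a <- .as_array(vol)
  d <- dim(a)  # (nz, ny, nx)
  sp <- voxel_size(vol) / 1000  # mm
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
           sprintf("ElementSpacing = %.9g %.9g %.9g", sp, sp, sp),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(a, c(3, 2, 1))), con, size = 8,
           endian = "little")
  invisible(path)
}

.read_mhd <- function(path, voxel_size_um = NULL) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  getv <- function(k) vals[match(k, keys)]
  dims_xyz <- as.integer(strsplit(trimws(getv("dimsize")), "\\s+")[[1]])
  etype <- trimws(getv("elementtype"))
  sizes <- c(MET_DOUBLE = 8, MET_FLOAT = 4, MET_USHORT = 2, MET_SHORT = 2,
             MET_UCHAR = 1)
  if (!etype %in% names(sizes)) .stopf("unsupported ElementType: %s", etype)
  raw_path <- file.path(dirname(path), trimws(getv("elementdatafile")))
  if (!file.exists(raw_path)) .stopf("raw data file missing: %s", raw_path)
  n <- prod(dims_xyz)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  what <- if (etype %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  a <- readBin(con, what, n = n, size = sizes[[etype]], endian = "little",
               signed = !etype %in% c("MET_UCHAR"))
  if (length(a) != n) .stopf("raw file truncated: %s", raw_path)
  vol <- aperm(array(as.double(a), dims_xyz), c(3, 2, 1))
  vs <- voxel_size_um
  if (is.null(vs)) {
    sp <- suppressWarnings(
      as.numeric(strsplit(trimws(getv("elementspacing")), "\\s+")[[1]][1]))
    if (is.finite(sp)) vs <- sp * 1000
  }
  if (is.null(vs) || !is.finite(vs)) .stopf("voxel size unknown for %s", path)
  bone_volume(vol, voxel_size_um = vs)
}

# -- field export: CSV table + legacy VTK structured grid ------------------

#' Write a displacement or strain field to CSV and VTK
#'
#' Writes (a) `table.csv`, one row per node/element with 0-based voxel and
#' micrometre coordinates, every field component, correlation score and
#' status, and (b) `field.vtk`, a legacy ASCII VTK structured grid with one
#' point-data array per component, readable by standard VTK viewers.
#'
#' @param field a `dvc_field` or `strain_field`.
#' @param path output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_field <- function(field, path) {
  df <- as.data.frame(field)
  if (!nrow(df)) .stopf("empty field")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(path, "table.csv")
  write.csv(format(df, digits = 12, trim = TRUE), csv, row.names = FALSE,
            quote = FALSE)
  vtk <- file.path(path, "field.vtk")
  gd <- field$grid_dims  # (nz, ny, nx) of the node/element grid
  vs <- field$voxel_size_um
  coords <- field[[if (inherits(field, "dvc_field")) "nodes" else "centers"]]
  arr_names <- setdiff(names(df), c("z_vox", "y_vox", "x_vox",
                                    "z_um", "y_um", "x_um", "status"))
  # VTK wants x varying fastest; our tables run z fastest
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  con <- file(vtk, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "boneDVC field", "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d %d", gd[3], gd[2], gd[1]),
               sprintf("POINTS %d float", nrow(df))), con)
  pts_um <- coords[ord, c(3, 2, 1), drop = FALSE] * vs
  writeLines(paste(pts_um[, 1], pts_um[, 2], pts_um[, 3]), con)
  writeLines(sprintf("POINT_DATA %d", nrow(df)), con)
  for (nm in arr_names) {
    v <- df[[nm]][ord]
    v <- ifelse(is.finite(v), format(v, digits = 9, trim = TRUE,
                                     scientific = TRUE), "nan")
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default", v), con)
  }
  invisible(c(csv = csv, vtk = vtk))
}
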