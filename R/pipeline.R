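# default run configuration: the analysis settings of the targeted
# experiments (node spacing 4, subset 17, median radii 4 and 1, cylindrical
# ROI 500 um x 2200 um on 25 um voxels)
.default_config <- function() {
  list(
    phantom = list(dims = c(96, 96, 96), voxel_size_um = 25,
                   target_bvtv = 0.32, screw_radius_um = 600,
                   thread_pitch_um = 400, thread_depth_um = 200,
                   bone_texture_scale_um = 100, seed = 1),
    warp = list(kind = "none", translation_vox = c(0, 0, 0),
                magnitude_vox = 4, plateau_um = 400, decay_um = 400),
    noise = list(sigma = 0, seed_ref = 1, seed_def = 2),
    input = list(ref = "", def = "", voxel_size_um = 25),
    dvc = list(node_spacing_vox = 4, subset_side_vox = 17,
               search_radius_vox = 3, min_valid_fraction = 0.5,
               subpixel = TRUE, cc_min = 0.5),
    preprocess = list(median_radius_pre = 4, smooth_radius_nodes = 1,
                      t_background = NA, t_screw = NA),
    roi = list(radial_extent_um = 500, axial_span_um = 2200),
    run = list(out_dir = "", seed = 1, cache = TRUE)
  )
}

# minimal TOML-subset reader: [section] headers, key = value lines with
# numbers, booleans, quoted strings, and flat [a, b, c] arrays; # comments
.read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (tok %in% c("true", "false")) return(tok == "true")
    num <- suppressWarnings(as.numeric(tok))
    if (is.na(num)) .stopf("cannot parse config value: %s", tok)
    num
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) .stopf("config key outside any [section]: %s", ln)
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(kv[2])
      if (grepl("^\\[.*\\]$", val)) {
        toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
        val <- unlist(lapply(toks, parse_scalar))
      } else {
        val <- parse_scalar(val)
      }
      out[[section]][[key]] <- val
    } else {
      .stopf("cannot parse config line: %s", ln)
    }
  }
  out
}

#' Parse a pipeline run configuration
#'
#' Reads a plain-text config (TOML dialect: `[section]` headers and
#' `key = value` lines) and fills unset keys with the package defaults,
#' which equal the targeted experiments' printed settings (DVC spacing 4,
#' subset 17, median radii 4 and 1, ROI 500/2200 um, voxel 25 um).
#' Unknown sections or keys are an error, never silently ignored, and
#' out-of-range values are reported with their key name.
#'
#' @param path config file; an empty file yields pure defaults.
#' @return a `run_config` nested list.
#' @export
parse_config <- function(path) {
  defaults <- .default_config()
  user <- if (is.null(path)) list() else .read_toml(path)
  for (sec in names(user)) {
    if (!sec %in% names(defaults))
      .stopf("unknown config section [%s]", sec)
    for (key in names(user[[sec]])) {
      if (!key %in% names(defaults[[sec]]))
        .stopf("unknown config key '%s' in [%s]", key, sec)
      defaults[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg <- defaults
  # validate by constructing the typed specs (errors carry the key names)
  do.call(phantom_spec, cfg$phantom)
  do.call(dvc_config, cfg$dvc)
  if (!cfg$warp$kind %in% c("none", "rigid_translation", "pullout_envelope"))
    .stopf("config [warp] kind '%s' not supported (none, rigid_translation, pullout_envelope)",
           cfg$warp$kind)
  .check_scalar(cfg$noise$sigma, "noise.sigma", lower = 0)
  .check_scalar(cfg$preprocess$median_radius_pre,
                "preprocess.median_radius_pre", lower = 0, integer = TRUE)
  .check_scalar(cfg$preprocess$smooth_radius_nodes,
                "preprocess.smooth_radius_nodes", lower = 0, integer = TRUE)
  .check_scalar(cfg$roi$radial_extent_um, "roi.radial_extent_um",
                lower = 1e-9)
  .check_scalar(cfg$roi$axial_span_um, "roi.axial_span_um", lower = 1e-9)
  structure(cfg, class = "run_config")
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full phantom-to-report pipeline
#'
#' Chains the stages end to end: phantom generation (or volume input),
#' screw/background masking, DVC, strain, repeated-scan error report
#' (when no warp is imposed), and peri-implant BV/TV morphometry; writes
#' the displacement and strain fields (CSV + VTK), a JSON manifest with
#' the configuration and its hash, and returns every stage result.
#' Bit-reproducible for identical config; when `run$cache` is true and an
#' earlier run with the same config hash exists in `out_dir`, the DVC
#' stage (the slow one) is reloaded instead of recomputed.
#'
#' @param cfg a `run_config` from [parse_config()], or `NULL` for
#'   defaults.
#' @param out_dir output directory; overrides `cfg$run$out_dir`.
#' @return list with `field`, `strain`, `errors`, `morphometry`,
#'   `manifest`, `out_dir`.
#' @export
run_full <- function(cfg = NULL, out_dir = NULL) {
  if (is.null(cfg)) cfg <- parse_config(NULL)
  if (!inherits(cfg, "run_config")) .stopf("'cfg' must be a run_config")
  out_dir <- out_dir %||%
    (if (nzchar(cfg$run$out_dir)) cfg$run$out_dir else tempfile("dvc_run_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  hash <- .config_hash(cfg)

  # -- inputs ---------------------------------------------------------------
  ph <- do.call(phantom_spec, cfg$phantom)
  have_files <- nzchar(cfg$input$ref) && nzchar(cfg$input$def)
  vols <- stage("input", {
    if (have_files) {
      list(ref = read_volume(cfg$input$ref, cfg$input$voxel_size_um),
           def = read_volume(cfg$input$def, cfg$input$voxel_size_um))
    } else {
      ref <- insert_screw(make_trabecular_volume(ph), ph)
      def <- switch(cfg$warp$kind,
        none = ref,
        rigid_translation = apply_warp(ref,
          warp_spec("rigid_translation",
                    translation_vox = cfg$warp$translation_vox)),
        pullout_envelope = apply_warp(ref,
          warp_spec("pullout_envelope",
                    envelope = list(magnitude_vox = cfg$warp$magnitude_vox,
                                    surface_radius_um = ph$screw_radius_um,
                                    plateau_um = cfg$warp$plateau_um,
                                    decay_um = cfg$warp$decay_um))))
      if (cfg$noise$sigma > 0) {
        ref <- add_noise(ref, cfg$noise$sigma, cfg$noise$seed_ref)
        def <- add_noise(def, cfg$noise$sigma, cfg$noise$seed_def)
      }
      list(ref = ref, def = def)
    }
  })

  # -- masking for DVC ------------------------------------------------------
  masked <- stage("mask", {
    ints <- ph$intensities
    t_bg <- cfg$preprocess$t_background
    t_sc <- cfg$preprocess$t_screw
    if (is.na(t_sc)) t_sc <- mean(ints[c("bone", "screw")])
    if (is.na(t_bg)) t_bg <- min(min(vols$ref, na.rm = TRUE),
                                 min(vols$def, na.rm = TRUE)) - 1
    list(ref = mask_phases(vols$ref, t_bg, t_sc)$volume,
         def = mask_phases(vols$def, t_bg, t_sc)$volume)
  })

  # -- DVC (cached) + strain ------------------------------------------------
  dvc_cfg <- do.call(dvc_config, cfg$dvc)
  cache_file <- file.path(out_dir, "dvc_field.rds")
  manifest_file <- file.path(out_dir, "manifest.json")
  field <- NULL
  if (isTRUE(cfg$run$cache) && file.exists(cache_file) &&
      file.exists(manifest_file)) {
    old <- jsonlite::read_json(manifest_file)
    if (identical(old$config_hash, hash)) field <- readRDS(cache_file)
  }
  if (is.null(field)) {
    field <- stage("dvc", run_dvc(masked$ref, masked$def, dvc_cfg))
    if (isTRUE(cfg$run$cache)) saveRDS(field, cache_file)
  }
  strain <- stage("strain",
                  run_strain(field, cfg$preprocess$smooth_radius_nodes))

  # -- quantification -------------------------------------------------------
  errors <- if (cfg$warp$kind == "none" && !have_files)
    stage("errors", dvc_error_report(field, strain)) else NULL
  morpho <- stage("morphometry", {
    filt <- median_filter3d(vols$ref, cfg$preprocess$median_radius_pre)
    a <- .as_array(filt)
    mask <- attr(vols$ref, "screw_mask")
    if (!is.null(mask)) a[mask] <- NaN  # implant must not bias IsoData
    thr <- isodata_threshold(a)
    solid <- !is.nan(a) & a >= thr
    tryCatch(bvtv_cylinder(solid, ph$screw_radius_um,
                           cfg$roi$radial_extent_um, cfg$roi$axial_span_um,
                           voxel_size_um = voxel_size(vols$ref)),
             error = function(e) conditionMessage(e))
  })

  # -- outputs --------------------------------------------------------------
  stage("write", {
    write_field(field, file.path(out_dir, "displacement"))
    write_field(strain, file.path(out_dir, "strain"))
  })
  manifest <- list(
    package = "boneDVC",
    version = as.character(utils::packageVersion("boneDVC")),
    config = unclass(cfg), config_hash = hash,
    n_nodes = nrow(field$nodes),
    node_status = as.list(table(field$status)),
    n_valid_elements = sum(strain$status == "ok"),
    map_spacing_um = map_resolution(field),
    bvtv = if (inherits(morpho, "morphometry")) morpho$bvtv else NA,
    errors = if (!is.null(errors))
      list(displacement = errors$displacement, strain = errors$strain)
    else NULL)
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  list(field = field, strain = strain, errors = errors,
       morphometry = morpho, manifest = manifest, out_dir = out_dir)
}
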