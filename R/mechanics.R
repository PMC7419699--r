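#' Read a pullout force-displacement record
#'
#' CSV with headers `time_s`, `disp_mm`, `force_N` (extra columns kept).
#' Time must be strictly increasing and all channels equal length.
#'
#' @param path CSV file path.
#' @return a `load_curve` data frame.
#' @export
read_load_curve <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "disp_mm", "force_N")
  if (!all(need %in% names(df)))
    .stopf("load curve must have columns %s", paste(need, collapse = ", "))
  load_curve(df$time_s, df$disp_mm, df$force_N)
}

#' Construct a load curve
#'
#' @param time_s,disp_mm,force_N equal-length channels; time strictly
#'   increasing.
#' @return a `load_curve` data frame.
#' @export
load_curve <- function(time_s, disp_mm, force_N) {
  if (length(unique(c(length(time_s), length(disp_mm),
                      length(force_N)))) != 1L)
    .stopf("channels must have equal length")
  if (any(diff(time_s) <= 0))
    .stopf("'time_s' must be strictly increasing")
  structure(data.frame(time_s = time_s, disp_mm = disp_mm,
                       force_N = force_N),
            class = c("load_curve", "data.frame"))
}

#' Summarise a pullout curve
#'
#' Extracts the macro-mechanical metrics of a stepwise in situ pullout
#' test.  Relaxation holds (the pauses for tomographic acquisition, where
#' the crosshead is stationary) are excluded by thresholding the crosshead
#' velocity; the loading envelope is the sequence of samples reaching a
#' new displacement maximum.  Stiffness is the least-squares slope of
#' force versus displacement over the samples whose preload-corrected
#' force lies in the `fit_window` fraction range of the corrected
#' maximum force, on the loading envelope; defining the window on the
#' corrected range makes the slope invariant to a constant force offset.
#' Failure is the first sample whose force drops below `drop_fraction`
#' of the running maximum.
#'
#' @param curve a `load_curve` (or data frame with the same columns).
#' @param fit_window force-fraction range for the stiffness fit (default
#'   20--80 percent of max force).
#' @param drop_fraction failure-detection threshold on the running force
#'   maximum (default 0.9).
#' @param velocity_tol fraction of the peak |crosshead velocity| below
#'   which a sample counts as a hold (default 0.05).
#' @return a `mech_summary` list: `stiffness_N_mm`, `max_force_N`,
#'   `displacement_at_max_force_mm`, `failure_index` (`NA` if no drop),
#'   `preload_N`, `n_fit`.
#' @export
summarize_curve <- function(curve, fit_window = c(0.2, 0.8),
                            drop_fraction = 0.9, velocity_tol = 0.05) {
  if (nrow(curve) < 10) .stopf("need at least 10 samples")
  f <- curve$force_N
  dmm <- curve$disp_mm
  if (diff(range(f)) == 0) .stopf("force range is zero")
  fmax_i <- which.max(f)
  max_force <- f[fmax_i]
  # loading envelope: new displacement maxima, outside stationary holds
  v <- c(0, diff(dmm) / diff(curve$time_s))
  moving <- abs(v) > velocity_tol * max(abs(v))
  envelope <- dmm >= cummax(dmm) - 1e-12 & moving
  if (any(dmm < cummax(dmm) - 1e-9 & moving))
    warning("non-monotone displacement during loading; using the loading envelope")
  # window on the preload-corrected force range, so a constant force
  # offset moves the preload estimate but not the stiffness
  fc <- f - f[1]
  fit_lo <- fit_window[1] * fc[fmax_i]
  fit_hi <- fit_window[2] * fc[fmax_i]
  sel <- envelope & fc >= fit_lo & fc <= fit_hi & seq_along(f) <= fmax_i
  if (sum(sel) < 2)
    .stopf("fewer than 2 samples in the stiffness fit window")
  stiffness <- unname(coef(lm(f[sel] ~ dmm[sel]))[2])
  run_max <- cummax(f)
  dropped <- which(f < drop_fraction * run_max & run_max > 0)
  failure <- if (length(dropped)) dropped[1] else NA_integer_
  structure(list(stiffness_N_mm = stiffness, max_force_N = max_force,
                 displacement_at_max_force_mm = dmm[fmax_i],
                 failure_index = failure, preload_N = f[1],
                 n_fit = sum(sel)),
            class = "mech_summary")
}

#' @export
print.mech_summary <- function(x, ...) {
  cat(sprintf("pullout summary: stiffness %.1f N/mm (%d pts), max force %.1f N at %.3f mm\n",
              x$stiffness_N_mm, x$n_fit, x$max_force_N,
              x$displacement_at_max_force_mm))
  cat(sprintf("  preload %.2f N, failure at sample %s\n", x$preload_N,
              ifelse(is.na(x$failure_index), "none",
                     as.character(x$failure_index))))
  invisible(x)
}

#' @param x a `load_curve`.
#' @param ... passed to [plot()].
#' @rdname load_curve
#' @export
plot.load_curve <- function(x, ...) {
  graphics::plot(x$disp_mm, x$force_N, type = "l",
                 xlab = "displacement (mm)", ylab = "force (N)", ...)
  invisible(x)
}
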