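#' Spatially resolved flow-cytometry pulse profile
#'
#' One particle's in-flow signal profile: forward scatter (FSC), sideward
#' scatter (SSC), green (FLG) and red (FLR) fluorescence in mV sampled at
#' strictly increasing positions in um along the flow axis. The recording
#' instrument clips FSC at `saturation_mv`; `trigger_mv` is the acquisition
#' threshold used to delimit the particle extent.
#'
#' @param position_um Strictly increasing sample positions (um).
#' @param fsc_mv,ssc_mv,flg_mv,flr_mv Channel values (mV), all `>= 0`, same
#'   length as `position_um` (at least 4 samples).
#' @param particle_id Identifier.
#' @param saturation_mv FSC clipping level (mV).
#' @param trigger_mv Acquisition threshold (mV), default 200.
#' @param stained Whether the run was FDA/PI stained (`FALSE` for
#'   autofluorescence runs).
#' @return Object of class `pulse_profile`.
#' @export
pulse_profile <- function(position_um, fsc_mv, ssc_mv, flg_mv, flr_mv,
                          particle_id = "p1", saturation_mv = Inf,
                          trigger_mv = 200, stained = TRUE) {
  n <- length(position_um)
  if (n < 4L) stop("a pulse profile needs at least 4 samples")
  if (any(diff(position_um) <= 0)) stop("positions must be strictly increasing")
  for (ch in list(fsc_mv, ssc_mv, flg_mv, flr_mv)) {
    if (length(ch) != n) stop("all channels must match the position vector length")
    if (any(ch < 0)) stop("channel values must be non-negative")
  }
  structure(list(position_um = as.numeric(position_um),
                 fsc_mv = as.numeric(fsc_mv), ssc_mv = as.numeric(ssc_mv),
                 flg_mv = as.numeric(flg_mv), flr_mv = as.numeric(flr_mv),
                 particle_id = particle_id, saturation_mv = saturation_mv,
                 trigger_mv = trigger_mv, stained = isTRUE(stained)),
            class = "pulse_profile")
}

#' @export
print.pulse_profile <- function(x, ...) {
  cat(sprintf("<pulse_profile> %s: %d samples over [%.1f, %.1f] um, FSC max %.0f mV%s\n",
              x$particle_id, length(x$position_um), min(x$position_um),
              max(x$position_um), max(x$fsc_mv),
              if (x$stained) " (stained)" else " (unstained)"))
  invisible(x)
}

# Per-channel baseline: median of the first and last 3 samples.
pulse_baseline <- function(values) {
  n <- length(values)
  stats::median(values[c(1:3, (n - 2):n)])
}

#' Particle extent from the FSC trigger crossing
#'
#' Start and end are the first and last sample positions where FSC exceeds
#' the trigger level; their difference is the signal length, the particle
#' diameter proxy used throughout the pulse metrics.
#'
#' @param profile A [pulse_profile()].
#' @return List with `start_um`, `end_um`, `signal_length_um`.
#' @export
detect_extent <- function(profile) {
  above <- which(profile$fsc_mv > profile$trigger_mv)
  if (!length(above))
    stop("no particle: FSC never exceeds the trigger level")
  start <- profile$position_um[above[1L]]
  end <- profile$position_um[above[length(above)]]
  list(start_um = start, end_um = end, signal_length_um = end - start)
}

#' Classify a particle from FSC saturation and signal length
#'
#' A particle is a `"pellet"` when its FSC trace shows a saturated core (at
#' least `min_sat_run` consecutive samples at >= 99% of the saturation
#' level) *and* its signal length exceeds 80 um; otherwise `"large"` above
#' 80 um and `"small"` below.
#'
#' @param profile A [pulse_profile()].
#' @param length_threshold_um Pellet length cut-off (um), default 80.
#' @param min_sat_run Minimum saturated run length in samples, default 3.
#' @return `"pellet"`, `"large"` or `"small"`.
#' @export
classify_particle <- function(profile, length_threshold_um = 80,
                              min_sat_run = 3L) {
  ext <- detect_extent(profile)
  sat <- is.finite(profile$saturation_mv) &
    profile$fsc_mv >= 0.99 * profile$saturation_mv
  r <- rle(sat)
  has_core <- any(r$values & r$lengths >= min_sat_run)
  if (has_core && ext$signal_length_um > length_threshold_um) "pellet"
  else if (ext$signal_length_um > length_threshold_um) "large"
  else "small"
}

# Positions where a curve crosses `level` (linear interpolation); returns
# the sorted crossing positions. `y` and `x` are the curve samples.
crossings <- function(x, y, level) {
  s <- y - level
  out <- numeric(0)
  for (i in seq_len(length(x) - 1L)) {
    if ((s[i] <= 0 && s[i + 1L] > 0) || (s[i] > 0 && s[i + 1L] <= 0)) {
      out <- c(out, x[i] + (0 - s[i]) / (s[i + 1L] - s[i]) * (x[i + 1L] - x[i]))
    }
  }
  sort(out)
}

# Total length (um) where curve > level, as a union of sub-intervals with
# interpolated endpoints.
length_above <- function(x, y, level) {
  s <- y > level
  if (!any(s)) return(0)
  cr <- crossings(x, y, level)
  bounds <- c(if (s[1L]) x[1L], cr, if (s[length(s)]) x[length(x)])
  sum(bounds[seq(2, length(bounds), by = 2)] -
        bounds[seq(1, length(bounds) - 1, by = 2)])
}

#' Pellet compactness from the SSC pulse width
#'
#' Full width at half maximum of the baseline-subtracted SSC curve (linear
#' interpolation between samples, first to last half-maximum crossing)
#' divided by the overall signal length. For a homogeneous projected sphere
#' the ratio is sqrt(3)/2; denser cores push it higher, loose hyphal
#' coronas lower.
#'
#' @param profile A [pulse_profile()].
#' @return Dimensionless compactness in (0, 1\].
#' @export
compactness <- function(profile) {
  ext <- detect_extent(profile)
  base <- pulse_baseline(profile$ssc_mv)
  y <- profile$ssc_mv - base
  m <- max(y)
  if (m <= 0) stop("flat SSC signal: maximum equals baseline")
  cr <- crossings(profile$position_um, y, m / 2)
  if (length(cr) < 2L) stop("SSC half-maximum level is never crossed twice")
  (max(cr) - min(cr)) / ext$signal_length_um
}

# Trapezoidal area of a baseline-subtracted channel over the particle extent.
channel_area <- function(profile, channel) {
  ext <- detect_extent(profile)
  x <- profile$position_um
  y <- profile[[channel]] - pulse_baseline(profile[[channel]])
  keep <- x >= ext$start_um & x <= ext$end_um
  pracma::trapz(x[keep], y[keep])
}

#' Viable layer from FDA (green fluorescence) signal
#'
#' Ratio of the trapezoidal area under the baseline-subtracted FLG curve to
#' the area under the FSC curve (clipped as recorded), both over the
#' particle extent, times the signal length, times 0.5 to express the
#' viable layer as a simplified radius of the spherical pellet.
#'
#' @param profile A [pulse_profile()].
#' @return Viable layer thickness in um.
#' @export
viable_layer_fda <- function(profile) {
  ext <- detect_extent(profile)
  a_fsc <- channel_area(profile, "fsc_mv")
  if (a_fsc <= 0) stop("zero FSC area under the pulse")
  a_flg <- channel_area(profile, "flg_mv")
  0.5 * (a_flg / a_fsc) * ext$signal_length_um
}

#' Viable layer from PI (red fluorescence) signal
#'
#' The dead core is delimited by where the baseline-subtracted FLR signal
#' exceeds `threshold_frac` (default 0.3) of its own maximum; the summed
#' length of those sub-intervals (interpolated crossings) approximates the
#' dead-core diameter, and half of what remains of the signal length is the
#' viable shell radius: `0.5 * (signal_length - length_above_threshold)`,
#' floored at 0.
#'
#' @param profile A [pulse_profile()].
#' @param threshold_frac Fraction of the FLR maximum, default 0.3.
#' @return Viable layer thickness in um.
#' @export
viable_layer_pi <- function(profile, threshold_frac = 0.3) {
  ext <- detect_extent(profile)
  y <- profile$flr_mv - pulse_baseline(profile$flr_mv)
  m <- max(y)
  ell <- if (m <= 0) 0 else
    length_above(profile$position_um, y, threshold_frac * m)
  max(0, 0.5 * (ext$signal_length_um - ell))
}

#' Viability factor of a pellet
#'
#' Twice the viable layer over the pellet size (signal length): 1 for a
#' fully viable pellet, 0 for a fully dead one.
#'
#' @param vl_um Viable layer (um), in \[0, signal_length/2\].
#' @param signal_length_um Pellet size proxy (um), positive.
#' @return Dimensionless factor in \[0, 1\].
#' @export
viability_factor <- function(vl_um, signal_length_um) {
  if (any(signal_length_um <= 0)) stop("signal length must be positive")
  2 * vl_um / signal_length_um
}

#' Autofluorescence factor of an unstained particle
#'
#' Area under the baseline-subtracted FLG curve over the area under the FSC
#' curve (both over the particle extent). On unstained biomass the green
#' autofluorescence scales with intracellular pigment content, making the
#' factor a candidate productivity indicator.
#'
#' @param profile A [pulse_profile()] from an unstained run.
#' @return Dimensionless factor.
#' @export
autofluorescence_factor <- function(profile) {
  a_fsc <- channel_area(profile, "fsc_mv")
  if (a_fsc <= 0) stop("zero FSC area under the pulse")
  channel_area(profile, "flg_mv") / a_fsc
}

#' Per-particle metric record
#'
#' Computes every pulse metric for one profile. Metrics that fail (e.g.
#' compactness on a flat SSC trace) are returned as `NA`.
#'
#' @param profile A [pulse_profile()].
#' @param pi_threshold_frac Passed to [viable_layer_pi()].
#' @return One-row data frame: `particle_id`, `particle_class`,
#'   `signal_length_um`, `ssc_fwhm_um`, `compactness`, `vl_fda_um`,
#'   `vl_pi_um`, `viability_factor_fda`, `viability_factor_pi`,
#'   `autofluorescence_factor`, `flr_flg_area_ratio`.
#' @export
pulse_metrics <- function(profile, pi_threshold_frac = 0.3) {
  ext <- detect_extent(profile)
  cls <- classify_particle(profile)
  comp <- tryCatch(compactness(profile), error = function(e) NA_real_)
  vfda <- tryCatch(viable_layer_fda(profile), error = function(e) NA_real_)
  vpi <- tryCatch(viable_layer_pi(profile, pi_threshold_frac),
                  error = function(e) NA_real_)
  auto <- tryCatch(autofluorescence_factor(profile), error = function(e) NA_real_)
  a_flg <- tryCatch(channel_area(profile, "flg_mv"), error = function(e) NA_real_)
  a_flr <- tryCatch(channel_area(profile, "flr_mv"), error = function(e) NA_real_)
  data.frame(particle_id = profile$particle_id, particle_class = cls,
             signal_length_um = ext$signal_length_um,
             ssc_fwhm_um = if (is.na(comp)) NA_real_ else comp * ext$signal_length_um,
             compactness = comp, vl_fda_um = vfda, vl_pi_um = vpi,
             viability_factor_fda = if (is.na(vfda)) NA_real_ else
               viability_factor(vfda, ext$signal_length_um),
             viability_factor_pi = if (is.na(vpi)) NA_real_ else
               viability_factor(vpi, ext$signal_length_um),
             autofluorescence_factor = auto,
             flr_flg_area_ratio = if (!is.na(a_flg) && !is.na(a_flr) && a_flg > 0)
               a_flr / a_flg else NA_real_)
}

#' Population summary of pulse-shape metrics
#'
#' Computes per-particle metrics for a batch of profiles, restricts the
#' summary to particles classified as pellets, and reports n plus mean and
#' sd of signal length, compactness, viability factor and (for unstained
#' runs) the autofluorescence factor. Samples with fewer than `min_pellets`
#' pellets are flagged, as are particles whose red-to-green fluorescence
#' area ratio deviates more than `mad_k` scaled MADs from the run median
#' (spectral-overlap quality control).
#'
#' @param profiles List of [pulse_profile()]s, non-empty.
#' @param stained Whether the run was stained; viability metrics are
#'   summarized only for stained runs, the autofluorescence factor only for
#'   unstained ones.
#' @param min_pellets Minimum pellets per sample before flagging (default 50).
#' @param layer `"fda"` or `"pi"`: which viable layer feeds the summarized
#'   viability factor.
#' @param mad_k Outlier cut-off in scaled MADs for the FLR/FLG ratio QC.
#' @param max_diameter_um Optional instrument size-exclusion filter; profiles
#'   with larger signal length are dropped before summarizing (`Inf` = off).
#' @return List with `particles` (per-particle data frame, QC column
#'   `flagged_spectral`), `summary` (one-row data frame) and `warnings`
#'   (character vector).
#' @export
summarize_population <- function(profiles, stained = TRUE, min_pellets = 50L,
                                 layer = c("fda", "pi"), mad_k = 3.5,
                                 max_diameter_um = Inf) {
  layer <- match.arg(layer)
  if (!length(profiles)) stop("no profiles supplied")
  per <- do.call(rbind, lapply(profiles, pulse_metrics))
  warnings <- character(0)
  if (is.finite(max_diameter_um)) {
    drop <- per$signal_length_um > max_diameter_um
    if (any(drop)) {
      warnings <- c(warnings, sprintf("%d particles above the %g um size exclusion removed",
                                      sum(drop), max_diameter_um))
      per <- per[!drop, , drop = FALSE]
    }
  }
  ratio <- per$flr_flg_area_ratio
  med <- stats::median(ratio, na.rm = TRUE)
  md <- stats::mad(ratio, na.rm = TRUE)
  per$flagged_spectral <- !is.na(ratio) & md > 0 & abs(ratio - med) > mad_k * md
  if (any(per$flagged_spectral))
    warnings <- c(warnings, sprintf("%d particles flagged for red/green ratio deviation (spectral overlap QC)",
                                    sum(per$flagged_spectral)))
  pel <- per[per$particle_class == "pellet", , drop = FALSE]
  n <- nrow(pel)
  if (n < min_pellets)
    warnings <- c(warnings, sprintf("only %d pellets in sample (minimum %d): summary statistically weak",
                                    n, min_pellets))
  vf <- if (layer == "fda") pel$viability_factor_fda else pel$viability_factor_pi
  msd <- function(v) if (length(v)) c(mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)) else c(NA_real_, NA_real_)
  sl <- msd(pel$signal_length_um); cp <- msd(pel$compactness); vv <- msd(vf)
  af <- if (!stained) msd(pel$autofluorescence_factor) else c(NA_real_, NA_real_)
  summary <- data.frame(n_particles = nrow(per), n_pellets = n,
                        signal_length_mean_um = sl[1L], signal_length_sd_um = sl[2L],
                        compactness_mean = cp[1L], compactness_sd = cp[2L],
                        viability_factor_mean = vv[1L], viability_factor_sd = vv[2L],
                        autofluorescence_factor_mean = af[1L],
                        autofluorescence_factor_sd = af[2L],
                        viability_layer = layer, stained = stained,
                        below_min_pellets = n < min_pellets)
  for (w in warnings) message("summarize_population: ", w)
  list(particles = per, summary = summary, warnings = warnings)
}

#' Write / read pulse profiles in the package's interchange dialect
#'
#' One CSV per particle (columns `position_um`, `fsc_mv`, `ssc_mv`,
#' `flg_mv`, `flr_mv`) plus a JSON header `<path>.json` holding
#' `particle_id`, `trigger_mv`, `saturation_mv` and the `stained` flag.
#'
#' @param profile A [pulse_profile()].
#' @param path CSV path to write.
#' @return `path` invisibly (write); a [pulse_profile()] (read).
#' @export
write_pulse_profile <- function(profile, path) {
  utils::write.csv(data.frame(position_um = profile$position_um,
                              fsc_mv = profile$fsc_mv, ssc_mv = profile$ssc_mv,
                              flg_mv = profile$flg_mv, flr_mv = profile$flr_mv),
                   path, row.names = FALSE)
  jsonlite::write_json(list(particle_id = profile$particle_id,
                            trigger_mv = profile$trigger_mv,
                            saturation_mv = if (is.finite(profile$saturation_mv))
                              profile$saturation_mv else NULL,
                            stained = profile$stained),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pulse_profile
#' @export
read_pulse_profile <- function(path) {
  d <- utils::read.csv(path)
  hd <- jsonlite::read_json(paste0(path, ".json"))
  pulse_profile(d$position_um, d$fsc_mv, d$ssc_mv, d$flg_mv, d$flr_mv,
                particle_id = hd$particle_id %||% basename(path),
                saturation_mv = hd$saturation_mv %||% Inf,
                trigger_mv = hd$trigger_mv %||% 200,
                stained = isTRUE(hd$stained))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
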