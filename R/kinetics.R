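#' Decision thresholds for signature classification
#'
#' All decision boundaries used by [classify_signature()] and the kinetic
#' descriptor functions, exposed in one place. The reported exemplar values
#' behind the defaults: a complete bilayer stabilises near −26 Hz (band
#' 24–30 Hz in magnitude) with dissipation below 1e-6 (the rigid-film
#' criterion under which the Sauerbrey relation applies); two-step rupture
#' recovers tens of Hz from a ~−72 Hz minimum (prominence and rupture-rise
#' defaults 10 Hz); a rinse-induced dissipation rise of ~0.2e-6 accompanies
#' lipid removal from a patchy film (threshold 0.1e-6).
#'
#' @param reference_harmonic Harmonic from which scalar descriptors are
#'   extracted (default 3rd).
#' @param smooth_window Centred moving-average width (samples) applied before
#'   extremum and phase analysis.
#' @param prominence Minimum post-minimum recovery (Hz) for a frequency
#'   minimum to count as prominent.
#' @param rupture_rise Minimum recovery (Hz) from the minimum to the pre-rinse
#'   plateau required to call two-step bilayer formation.
#' @param bilayer_band Magnitude band (Hz) of final frequency shifts
#'   consistent with a complete bilayer.
#' @param rinse_f_rise,rinse_D_rise Minimum rinse-induced frequency rise (Hz)
#'   and dissipation rise (1e-6) to call an incomplete bilayer.
#' @param plateau_window Width (minutes) of the averaging windows used for
#'   pre-rinse and final plateaus.
#' @param rigid_limit Dissipation (1e-6) below which the film counts as rigid.
#' @param flat_tol Final frequency change (Hz) below which a trace is treated
#'   as showing no adsorption.
#' @param dead_band Length-2 `c(f, D)` increments (Hz, 1e-6) below which a
#'   phase-plot step is labelled stationary.
#' @return A named list of class `signature_thresholds`.
#' @export
signature_thresholds <- function(reference_harmonic = 3L,
                                 smooth_window = 5L,
                                 prominence = 10,
                                 rupture_rise = 10,
                                 bilayer_band = c(24, 30),
                                 rinse_f_rise = 1,
                                 rinse_D_rise = 0.1,
                                 plateau_window = 1,
                                 rigid_limit = 1,
                                 flat_tol = 1,
                                 dead_band = c(f = 0.1, D = 0.02)) {
  structure(list(reference_harmonic = as.integer(reference_harmonic),
                 smooth_window = as.integer(smooth_window),
                 prominence = prominence, rupture_rise = rupture_rise,
                 bilayer_band = bilayer_band,
                 rinse_f_rise = rinse_f_rise, rinse_D_rise = rinse_D_rise,
                 plateau_window = plateau_window, rigid_limit = rigid_limit,
                 flat_tol = flat_tol, dead_band = dead_band),
            class = "signature_thresholds")
}

# single-harmonic series, time-ordered
harmonic_series <- function(trace, harmonic) {
  if (!harmonic %in% trace$harmonic) {
    abort(paste0("harmonic ", harmonic, " not present in trace"))
  }
  trace |>
    filter(.data$harmonic == !!harmonic) |>
    arrange(.data$time_min)
}

window_mean <- function(series, col, t0, t1) {
  v <- series[[col]][series$time_min >= t0 & series$time_min <= t1]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Detect a prominent frequency minimum
#'
#' During two-step bilayer formation the frequency descends while vesicles
#' accumulate, then rises as they rupture and release entrapped water. The
#' minimum is located on the smoothed series and reported only when the
#' subsequent recovery exceeds `prominence`; a monotone approach or a
#' noise-only trace yields no minimum, which is a valid (absent) result.
#'
#' @param trace A [qcmd_trace()].
#' @param harmonic Harmonic to analyse.
#' @param prominence Required recovery, Hz.
#' @param smooth_window Moving-average width, samples.
#' @param window Optional `c(t0, t1)` restricting the search, minutes.
#' @return A tibble with columns `t_min`, `f_min`: one row if a prominent
#'   minimum exists, zero rows otherwise.
#' @export
detect_frequency_minimum <- function(trace, harmonic = 3L, prominence = 10,
                                     smooth_window = 5L, window = NULL) {
  s <- harmonic_series(trace, harmonic)
  if (!is.null(window)) {
    s <- filter(s, .data$time_min >= window[1], .data$time_min <= window[2])
  }
  absent <- tibble(t_min = numeric(0), f_min = numeric(0))
  if (nrow(s) < 3) return(absent)
  sm <- moving_average(s$delta_f, smooth_window)
  i <- which.min(sm)
  recovery <- max(sm[i:length(sm)]) - sm[i]
  if (recovery < prominence) return(absent)
  tibble(t_min = s$time_min[i], f_min = sm[i])
}

#' Initial adsorption slope of the frequency shift
#'
#' The slope of \eqn{\Delta f} versus time from the start of vesicle flow to
#' the frequency minimum, by least squares; a steeper negative slope means
#' faster vesicle attachment. When the trace has no prominent minimum (intact
#' vesicle layers and one-step bilayers descend monotonically) the window
#' instead ends where the frequency first reaches 90% of its final plateau
#' change — a surrogate endpoint, since a slope is still reported for such
#' films.
#'
#' Slopes are invariant under a vertical offset of the trace (changes are
#' measured relative to the level at `t_start`) and under joint time
#' translation of trace and markers.
#'
#' @param trace A [qcmd_trace()].
#' @param markers [flow_markers()]; defaults to markers stored in the trace.
#' @param harmonic Harmonic to analyse.
#' @param thresholds A [signature_thresholds()] (smoothing, prominence and
#'   flat-trace tolerance are taken from it).
#' @return Slope in Hz/min. A flat trace returns 0 with a "no adsorption"
#'   warning.
#' @export
initial_slope <- function(trace, markers = trace_markers(trace),
                          harmonic = 3L,
                          thresholds = signature_thresholds()) {
  if (is.null(markers)) abort("markers are required (none stored in trace)")
  s <- harmonic_series(trace, harmonic)
  if (markers$t_start < min(s$time_min) || markers$t_start > max(s$time_min)) {
    abort("t_start lies outside the trace")
  }
  t_hi <- min(markers$t_rinse, max(s$time_min))
  sm <- moving_average(s$delta_f, thresholds$smooth_window)
  i0 <- which(s$time_min >= markers$t_start)[1]
  f0 <- sm[i0]

  mn <- detect_frequency_minimum(trace, harmonic,
                                 prominence = thresholds$prominence,
                                 smooth_window = thresholds$smooth_window,
                                 window = c(markers$t_start, t_hi))
  if (nrow(mn) == 1) {
    t_end_win <- mn$t_min
  } else {
    f_final <- window_mean(s, "delta_f", t_hi - thresholds$plateau_window, t_hi)
    change <- f_final - f0
    if (!is.finite(change) || abs(change) < thresholds$flat_tol) {
      warn("no adsorption: frequency change below tolerance; slope set to 0")
      return(0)
    }
    in_win <- s$time_min >= markers$t_start & s$time_min <= t_hi
    reached <- in_win & (sm - f0) <= 0.9 * change
    if (!any(reached)) {
      t_end_win <- t_hi
    } else {
      t_end_win <- s$time_min[which(reached)[1]]
    }
  }
  rows <- filter(s, .data$time_min >= markers$t_start,
                 .data$time_min <= t_end_win)
  if (nrow(rows) < 3) abort("slope window shorter than 3 samples")
  unname(stats::coef(stats::lm(delta_f ~ time_min, data = rows))[2])
}

#' Overtone spread of the frequency shift
#'
#' Maximum minus minimum of the window-averaged frequency shift across
#' harmonics. Rigid uniform films show near-coincident overtones; hydrated
#' films that are not uniform through their thickness (e.g. vesicle layers)
#' show the overtones separating during mass attachment.
#'
#' @param trace A [qcmd_trace()] with at least two harmonics.
#' @param window `c(t0, t1)` averaging window, minutes.
#' @return Spread in Hz.
#' @export
overtone_spread <- function(trace, window) {
  harmonics <- trace_harmonics(trace)
  if (length(harmonics) < 2) abort("overtone spread requires >= 2 harmonics")
  means <- trace |>
    filter(.data$time_min >= window[1], .data$time_min <= window[2]) |>
    group_by(.data$harmonic) |>
    summarise(f = mean(.data$delta_f), .groups = "drop")
  if (nrow(means) == 0) abort("empty window")
  max(means$f) - min(means$f)
}

#' Compass-direction phase trajectory in the (-delta f, delta D) plane
#'
#' Dissipation-versus-frequency plots read surface processes off the
#' direction of travel: with the frequency axis reversed, movement east means
#' mass gain, north means increasing viscoelasticity. Vesicle adsorption
#' (mass plus trapped water) runs north-east; vesicle rupture (water loss,
#' rigidification) runs south-west; direct bilayer deposition runs mainly
#' east. Steps whose smoothed increments fall inside the dead-band on both
#' axes are labelled stationary.
#'
#' @param trace A [qcmd_trace()].
#' @param harmonic Harmonic to analyse.
#' @param smooth_window Moving-average width, samples.
#' @param dead_band Length-2 `c(f, D)`: increments below these magnitudes
#'   count as zero on that axis.
#' @return A tibble with columns `t` (minutes, at the end of each step) and
#'   `direction` (factor with levels N, NE, E, SE, S, SW, W, NW, stationary).
#' @export
phase_trajectory <- function(trace, harmonic = 3L, smooth_window = 5L,
                             dead_band = c(f = 0.1, D = 0.02)) {
  s <- harmonic_series(trace, harmonic)
  if (nrow(s) < max(smooth_window, 2L)) {
    abort("fewer samples than smooth_window")
  }
  x <- moving_average(-s$delta_f, smooth_window)
  y <- moving_average(s$delta_D, smooth_window)
  dx <- diff(x)
  dy <- diff(y)
  dx[abs(dx) < dead_band[[1]]] <- 0
  dy[abs(dy) < dead_band[[2]]] <- 0
  key <- paste(sign(dx), sign(dy))
  dirs <- c("0 0" = "stationary",
            "1 0" = "E", "1 1" = "NE", "0 1" = "N", "-1 1" = "NW",
            "-1 0" = "W", "-1 -1" = "SW", "0 -1" = "S", "1 -1" = "SE")
  levels <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW", "stationary")
  tibble(t = s$time_min[-1],
         direction = factor(unname(dirs[key]), levels = levels))
}

#' Classify a deposition trace into its outcome signature
#'
#' Applies decision rules to the reference harmonic (3rd by default) of a
#' baselined trace:
#'
#' 1. final dissipation above the rigid limit with no prominent frequency
#'    minimum: `vesicle_layer` (intact vesicles, viscoelastic film);
#' 2. prominent minimum whose recovery to the pre-rinse plateau is at least
#'    `rupture_rise`, with rigid final film: `two_step_slb`;
#' 3. no minimum, rigid film, final |frequency| inside the bilayer band:
#'    `one_step_slb`;
#' 4. rigid film below the bilayer band whose rinse raises both frequency and
#'    dissipation (lipid removal from a patchy film): `incomplete_bilayer`;
#' 5. otherwise `indeterminate`.
#'
#' When both the vesicle-layer and incomplete-bilayer patterns could apply,
#' the final dissipation decides (above the rigid limit means vesicle layer).
#' All descriptor fields are populated regardless of the label.
#'
#' @param trace A [qcmd_trace()] covering `t_start` and `t_rinse`.
#' @param markers [flow_markers()]; defaults to markers stored in the trace.
#' @param thresholds A [signature_thresholds()].
#' @return An object of class `slb_signature`: a list with elements `label`,
#'   `f_final`, `D_final`, `f_min`, `t_min`, `initial_slope`,
#'   `overtone_spread_final`, `rinse_delta_f`, `rinse_delta_D`, `rigid`,
#'   `harmonic`, `thresholds`. Use [glance()] for a one-row tibble.
#' @export
classify_signature <- function(trace, markers = trace_markers(trace),
                               thresholds = signature_thresholds()) {
  if (is.null(markers)) abort("markers are required (none stored in trace)")
  h <- thresholds$reference_harmonic
  s <- harmonic_series(trace, h)
  t_lo <- min(s$time_min)
  t_hi <- max(s$time_min)
  if (markers$t_start < t_lo || markers$t_rinse > t_hi) {
    abort("markers lie outside the trace")
  }
  w <- thresholds$plateau_window

  f_pre <- window_mean(s, "delta_f", markers$t_rinse - w, markers$t_rinse)
  D_pre <- window_mean(s, "delta_D", markers$t_rinse - w, markers$t_rinse)
  f_final <- window_mean(s, "delta_f", t_hi - w, t_hi)
  D_final <- window_mean(s, "delta_D", t_hi - w, t_hi)

  mn <- detect_frequency_minimum(trace, h,
                                 prominence = thresholds$prominence,
                                 smooth_window = thresholds$smooth_window,
                                 window = c(markers$t_start, markers$t_rinse))
  prominent <- nrow(mn) == 1
  recovery <- if (prominent) f_pre - mn$f_min else NA_real_

  slope <- initial_slope(trace, markers, h, thresholds)
  spread <- if (length(trace_harmonics(trace)) >= 2) {
    overtone_spread(trace, c(t_hi - w, t_hi))
  } else {
    NA_real_
  }
  rinse_df <- f_final - f_pre
  rinse_dD <- D_final - D_pre
  rigid <- D_final < thresholds$rigid_limit
  band <- thresholds$bilayer_band

  label <- if (!prominent && !rigid) {
    "vesicle_layer"
  } else if (prominent && rigid && recovery >= thresholds$rupture_rise) {
    "two_step_slb"
  } else if (!prominent && rigid &&
             abs(f_final) >= band[1] && abs(f_final) <= band[2]) {
    "one_step_slb"
  } else if (!prominent && rigid && abs(f_final) < band[1] &&
             rinse_df >= thresholds$rinse_f_rise &&
             rinse_dD >= thresholds$rinse_D_rise) {
    "incomplete_bilayer"
  } else {
    "indeterminate"
  }

  structure(list(label = label,
                 f_final = f_final, D_final = D_final,
                 f_min = if (prominent) mn$f_min else NA_real_,
                 t_min = if (prominent) mn$t_min else NA_real_,
                 initial_slope = slope,
                 overtone_spread_final = spread,
                 rinse_delta_f = rinse_df, rinse_delta_D = rinse_dD,
                 rigid = rigid,
                 f_prerinse = f_pre, D_prerinse = D_pre,
                 harmonic = h, thresholds = thresholds),
            class = "slb_signature")
}

#' @export
print.slb_signature <- function(x, ...) {
  cat("<slb_signature> ", x$label,
      sprintf(" (harmonic %d)\n", x$harmonic), sep = "")
  cat(sprintf("  f_final %.2f Hz, D_final %.2f x 1e-6 (%s film)\n",
              x$f_final, x$D_final, if (x$rigid) "rigid" else "viscoelastic"))
  if (is.finite(x$f_min)) {
    cat(sprintf("  minimum %.1f Hz at %.2f min\n", x$f_min, x$t_min))
  }
  cat(sprintf("  initial slope %.2f Hz/min, rinse df %+0.2f Hz, dD %+0.2f\n",
              x$initial_slope, x$rinse_delta_f, x$rinse_delta_D))
  invisible(x)
}

#' Tidy and summarise signature reports
#'
#' `glance()` returns the full one-row summary of a classified trace;
#' `tidy()` returns the numeric descriptors in long metric/value form.
#'
#' @param x An `slb_signature` from [classify_signature()].
#' @param ... Unused.
#' @return A tibble.
#' @method glance slb_signature
#' @export
glance.slb_signature <- function(x, ...) {
  tibble(label = x$label, f_final = x$f_final, D_final = x$D_final,
         f_min = x$f_min, t_min = x$t_min,
         initial_slope = x$initial_slope,
         overtone_spread_final = x$overtone_spread_final,
         rinse_delta_f = x$rinse_delta_f, rinse_delta_D = x$rinse_delta_D,
         rigid = x$rigid)
}

#' @rdname glance.slb_signature
#' @method tidy slb_signature
#' @export
tidy.slb_signature <- function(x, ...) {
  g <- glance(x)
  num <- g[vapply(g, is.numeric, logical(1))]
  tibble(metric = names(num), value = as.numeric(unlist(num[1, ])))
}
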