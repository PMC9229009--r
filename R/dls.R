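#' Particle size distribution on a stated basis
#'
#' Dynamic light scattering reports particle size distributions on one of
#' three bases. With \eqn{N_i} spherical particles of diameter \eqn{d_i},
#' \deqn{\%I = 100 N_i d_i^6 / \sum N_i d_i^6, \quad
#'       \%V = 100 N_i d_i^3 / \sum N_i d_i^3, \quad
#'       \%N = 100 N_i / \sum N_i,}
#' i.e. the intensity basis weights each particle by \eqn{d^6} (Rayleigh
#' scattering), the volume basis by \eqn{d^3}, the number basis counts
#' particles. Distributions are discrete binned weights; no bin-width
#' correction is applied.
#'
#' @param d Strictly increasing diameter bins, nm.
#' @param values Per-bin abundances, >= 0.
#' @param basis One of `"number"`, `"volume"`, `"intensity"`.
#' @param normalized If `TRUE`, `values` must sum to 100 (within 1e-9).
#' @param timestamp Optional days since preparation.
#' @return A tibble of class `size_distribution` with columns `d_nm`,
#'   `value`; basis, normalization flag and timestamp stored as attributes.
#' @export
size_distribution <- function(d, values,
                              basis = c("number", "volume", "intensity"),
                              normalized = FALSE, timestamp = NA_real_) {
  basis <- match.arg(basis)
  d <- as.numeric(d)
  values <- as.numeric(values)
  if (length(d) != length(values)) abort("d and values must match in length")
  if (length(d) == 0) abort("empty distribution")
  if (any(d <= 0)) abort("diameters must be > 0")
  if (any(diff(d) <= 0)) abort("diameters must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("values must be finite and >= 0")
  }
  if (normalized && abs(sum(values) - 100) > 1e-9) {
    abort("normalized distributions must sum to 100")
  }
  structure(tibble(d_nm = d, value = values),
            basis = basis, normalized = normalized, timestamp = timestamp,
            class = c("size_distribution", class(tibble())))
}

#' @rdname size_distribution
#' @param dist A `size_distribution`.
#' @export
dist_basis <- function(dist) attr(dist, "basis")

#' @rdname size_distribution
#' @export
dist_timestamp <- function(dist) attr(dist, "timestamp")

basis_exponent <- c(number = 0, volume = 3, intensity = 6)

#' Convert a size distribution between bases
#'
#' Reweights bins by the diameter-power ratio between bases (number to
#' volume multiplies by \eqn{d^3}, number to intensity by \eqn{d^6}; inverse
#' conversions divide) and renormalises to 100. Converting a distribution to
#' its own basis returns it unchanged. On positive distributions conversion
#' is an exact bijection: round trips recover the input to 1e-9.
#'
#' @param dist A [size_distribution()].
#' @param to_basis Target basis.
#' @return A normalised [size_distribution()] on `to_basis`.
#' @export
#' @examples
#' nd <- size_distribution(c(1, 2), c(50, 50), "number", normalized = TRUE)
#' convert_distribution(nd, "intensity")
convert_distribution <- function(dist,
                                 to_basis = c("number", "volume", "intensity")) {
  to_basis <- match.arg(to_basis)
  from <- dist_basis(dist)
  if (to_basis == from) return(dist)
  expo <- basis_exponent[[to_basis]] - basis_exponent[[from]]
  w <- dist$value * dist$d_nm^expo
  total <- sum(w)
  if (total <= 0) abort("zero total weight: cannot convert")
  size_distribution(dist$d_nm, 100 * w / total, basis = to_basis,
                    normalized = TRUE, timestamp = dist_timestamp(dist))
}

#' Normalise a distribution to percentages
#'
#' @param dist A [size_distribution()].
#' @return The distribution rescaled to sum to 100.
#' @export
normalize_distribution <- function(dist) {
  total <- sum(dist$value)
  if (total <= 0) abort("zero total weight: cannot normalize")
  size_distribution(dist$d_nm, 100 * dist$value / total,
                    basis = dist_basis(dist), normalized = TRUE,
                    timestamp = dist_timestamp(dist))
}

#' Detect modes of a size distribution
#'
#' Finds local maxima of the (optionally smoothed) distribution, assigns each
#' bin to the nearest peak region (regions split at the minima between
#' adjacent peaks) and keeps peaks whose region carries at least
#' `min_fraction` percent of the mass.
#'
#' @param dist A [size_distribution()]; normalised internally if needed.
#' @param min_fraction Minimum percent mass for a mode to be reported.
#' @param smooth_window Optional moving-average width (bins); default no
#'   smoothing.
#' @return A tibble with columns `d_mode` (nm) and `fraction` (%), largest
#'   fraction first. Zero rows for an all-zero distribution.
#' @export
detect_modes <- function(dist, min_fraction = 5, smooth_window = 1L) {
  empty <- tibble(d_mode = numeric(0), fraction = numeric(0))
  if (sum(dist$value) <= 0) return(empty)
  dist <- normalize_distribution(dist)
  v <- moving_average(dist$value, smooth_window)
  n <- length(v)
  if (n == 1) return(tibble(d_mode = dist$d_nm[1], fraction = 100))

  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  peaks <- which(v > left & v >= right & v > 0)
  if (length(peaks) == 0) return(empty)

  # region boundaries at the minima between adjacent peaks
  bounds <- c(0, vapply(seq_len(length(peaks) - 1), function(i) {
    seg <- peaks[i]:peaks[i + 1]
    seg[which.min(v[seg])]
  }, numeric(1)), n)
  fractions <- vapply(seq_along(peaks), function(i) {
    sum(dist$value[(bounds[i] + 1):bounds[i + 1]])
  }, numeric(1))
  out <- tibble(d_mode = dist$d_nm[peaks], fraction = fractions) |>
    filter(.data$fraction >= min_fraction) |>
    arrange(dplyr::desc(.data$fraction))
  out
}

#' Assess vesicle stability from a size-distribution time course
#'
#' Vesicle preparations aggregate over time; on the intensity basis this
#' shows as the primary peak shifting towards larger diameters and as new
#' peaks appearing. Each time point is compared against the first (day 0):
#' a primary-mode shift beyond `shift_tol` percent of the day-0 diameter, or
#' a mode absent at day 0 carrying at least `new_peak_fraction` percent of
#' the mass, flags the time point as aggregating.
#'
#' @param series A list of [size_distribution()] objects, ordered by
#'   timestamp, all on the same basis.
#' @param shift_tol Allowed primary-mode diameter shift, percent.
#' @param new_peak_fraction Mass threshold for a new mode, percent.
#' @param min_fraction Passed to [detect_modes()].
#' @return A tibble of class `dls_stability` with one row per time point
#'   (`timestamp`, `primary_mode_nm`, `shift_pct`, `mode_shift`, `new_peak`,
#'   `aggregating`) and the overall verdict (`"stable"` or `"aggregating"`)
#'   in attribute `"verdict"`.
#' @export
stability_assessment <- function(series, shift_tol = 25,
                                 new_peak_fraction = 5, min_fraction = 5) {
  if (length(series) < 2) abort("need at least two time points")
  bases <- vapply(series, dist_basis, character(1))
  if (length(unique(bases)) != 1) abort("mismatched bases across time points")

  modes <- lapply(series, detect_modes, min_fraction = min_fraction)
  ref <- modes[[1]]
  if (nrow(ref) == 0) abort("no modes detected at the reference time point")
  ref_primary <- ref$d_mode[1]

  rows <- purrr::map_dfr(seq_along(series), function(i) {
    m <- modes[[i]]
    primary <- if (nrow(m) > 0) m$d_mode[1] else NA_real_
    shift_pct <- 100 * abs(primary - ref_primary) / ref_primary
    mode_shift <- is.finite(shift_pct) && shift_pct > shift_tol
    new_modes <- m |>
      filter(.data$fraction >= new_peak_fraction) |>
      filter(vapply(.data$d_mode, function(d) {
        all(100 * abs(d - ref$d_mode) / ref$d_mode > shift_tol)
      }, logical(1)))
    new_peak <- i > 1 && nrow(new_modes) > 0
    tibble(timestamp = dist_timestamp(series[[i]]) %||% NA_real_,
           primary_mode_nm = primary, shift_pct = shift_pct,
           mode_shift = i > 1 && mode_shift, new_peak = new_peak,
           aggregating = (i > 1 && mode_shift) || new_peak)
  })
  verdict <- if (any(rows$aggregating)) "aggregating" else "stable"
  structure(rows, verdict = verdict,
            class = c("dls_stability", class(tibble())))
}

#' @rdname stability_assessment
#' @param x A `dls_stability` object.
#' @export
stability_verdict <- function(x) attr(x, "verdict")

#' Read and write size-distribution CSV files
#'
#' The dialect is a two-column CSV `d_nm, value` preceded by a comment line
#' `# basis=..., day=...`.
#'
#' @param path File path.
#' @return `read_dls()` returns a [size_distribution()]; `write_dls()`
#'   returns `path` invisibly.
#' @export
read_dls <- function(path) {
  lines <- readLines(path)
  comment <- grepl("^\\s*#", lines)
  basis <- "number"
  day <- NA_real_
  for (ln in sub("^\\s*#\\s*", "", lines[comment])) {
    kv <- strsplit(ln, ",")[[1]]
    for (item in kv) {
      parts <- strsplit(trimws(item), "=")[[1]]
      if (length(parts) == 2) {
        if (parts[1] == "basis") basis <- trimws(parts[2])
        if (parts[1] == "day") day <- as.numeric(parts[2])
      }
    }
  }
  df <- utils::read.csv(text = paste(lines[!comment], collapse = "\n"))
  vals <- df$value
  normalized <- abs(sum(vals) - 100) <= 1e-9
  size_distribution(df$d_nm, vals, basis = basis, normalized = normalized,
                    timestamp = day)
}

#' @rdname read_dls
#' @param dist A [size_distribution()].
#' @export
write_dls <- function(dist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# basis=", dist_basis(dist), ", day=",
                    dist_timestamp(dist)), con)
  writeLines("d_nm,value", con)
  writeLines(paste(format(dist$d_nm, digits = 17),
                   format(dist$value, digits = 17), sep = ","), con)
  invisible(path)
}
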