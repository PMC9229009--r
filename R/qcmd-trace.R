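#' Construct a multi-harmonic QCM-D trace
#'
#' A QCM-D trace records, for each measured odd harmonic of the quartz
#' crystal's resonance, the frequency shift \eqn{\Delta f} (Hz,
#' overtone-normalised, i.e. \eqn{\Delta f_n / n}) and the dissipation shift
#' \eqn{\Delta D} (in units of \eqn{1 \times 10^{-6}}) on a common time grid.
#' Traces are stored long: one row per (time, harmonic) pair, so they pipe
#' directly into dplyr verbs and ggplot2.
#'
#' @param data A data frame with columns `time_min`, `harmonic`, `delta_f`,
#'   `delta_D`. Time is in minutes and must be strictly increasing within each
#'   harmonic; all harmonics must share the same time grid.
#' @param meta Named list of free-form metadata (sample name, lipid
#'   composition, flow markers...). Stored as an attribute and serialised as
#'   comment header lines by [write_qcmd()].
#'
#' @return A tibble of class `qcmd_trace` with attributes `meta` and
#'   `harmonics`.
#' @export
#' @examples
#' tr <- qcmd_trace(tibble::tibble(
#'   time_min = rep(0:4, 2), harmonic = rep(c(3L, 5L), each = 5),
#'   delta_f = 0, delta_D = 0
#' ))
#' trace_harmonics(tr)
qcmd_trace <- function(data, meta = list()) {
  data <- as_tibble(data)
  required <- c("time_min", "harmonic", "delta_f", "delta_D")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data$harmonic <- as.integer(data$harmonic)
  harmonics <- sort(unique(data$harmonic))
  if (length(harmonics) == 0) abort("trace must contain at least one harmonic")
  if (!all(harmonics %in% c(3L, 5L, 7L, 9L, 11L))) {
    abort("harmonics must be odd integers among 3, 5, 7, 9, 11")
  }
  grids <- split(data$time_min, data$harmonic)
  ref_grid <- grids[[1]]
  if (any(diff(ref_grid) <= 0)) abort("time must be strictly increasing")
  same <- vapply(grids, function(g) {
    length(g) == length(ref_grid) && all(g == ref_grid)
  }, logical(1))
  if (!all(same)) abort("all harmonics must share the same time grid")
  if (any(!is.finite(data$delta_D))) abort("delta_D values must be finite")

  data <- arrange(data, .data$harmonic, .data$time_min)
  structure(data,
            meta = meta,
            harmonics = harmonics,
            class = c("qcmd_trace", class(tibble())))
}

#' Trace accessors
#'
#' @param trace A [qcmd_trace()].
#' @return `trace_harmonics()` returns the sorted integer vector of harmonics
#'   present; `trace_meta()` the metadata list; `trace_markers()` a
#'   [flow_markers()] object recovered from metadata (or `NULL` if the trace
#'   carries none).
#' @export
trace_harmonics <- function(trace) {
  sort(unique(as.integer(trace$harmonic)))
}

#' @rdname trace_harmonics
#' @export
trace_meta <- function(trace) attr(trace, "meta") %||% list()

#' @rdname trace_harmonics
#' @export
trace_markers <- function(trace) {
  meta <- trace_meta(trace)
  if (is.null(meta$t_start) || is.null(meta$t_rinse)) return(NULL)
  flow_markers(as.numeric(meta$t_start), as.numeric(meta$t_rinse),
               if (!is.null(meta$t_end)) as.numeric(meta$t_end) else NA_real_)
}

#' Flow markers for a vesicle-deposition experiment
#'
#' The two time points that segment a deposition experiment: the start of
#' vesicle flow over the sensor and the start of the final buffer rinse that
#' removes weakly attached material. Everything before `t_start` is baseline
#' buffer flow.
#'
#' @param t_start Minutes at which vesicle flow begins.
#' @param t_rinse Minutes at which the final buffer rinse begins.
#' @param t_end Optional end of record, minutes.
#' @return A named list of class `flow_markers`.
#' @export
flow_markers <- function(t_start, t_rinse, t_end = NA_real_) {
  if (!is_number(t_start) || !is_number(t_rinse)) {
    abort("t_start and t_rinse must be finite numbers")
  }
  if (t_start >= t_rinse) abort("t_start must precede t_rinse")
  if (is.finite(t_end) && t_rinse > t_end) abort("t_rinse must not exceed t_end")
  structure(list(t_start = t_start, t_rinse = t_rinse, t_end = t_end),
            class = "flow_markers")
}

#' Read flow markers from a YAML file
#'
#' Expects a top-level `flow:` mapping with `t_start`, `t_rinse` and optional
#' `t_end`, all in minutes.
#'
#' @param path Path to a YAML file.
#' @return A [flow_markers()] object.
#' @export
read_flow_markers <- function(path) {
  cfg <- yaml::read_yaml(path)
  flow <- cfg$flow %||% cfg
  flow_markers(flow$t_start, flow$t_rinse, flow$t_end %||% NA_real_)
}

#' Read a QCM-D trace from a wide CSV file
#'
#' The on-disk dialect is a wide CSV with a `time_min` column and per-harmonic
#' column pairs `f3, D3, f5, D5, ...`. Lines starting with `#` are metadata
#' comments of the form `# key: value` and are restored into the trace's
#' `meta`. Missing harmonics are tolerated; rows containing non-finite values
#' are dropped with a warning that reports their indices.
#'
#' @param path File to read.
#' @param normalized Are the frequency columns already overtone-normalised
#'   (\eqn{\Delta f_n/n}, the convention in which a complete bilayer sits near
#'   \eqn{-26} Hz on every harmonic)? If `FALSE`, each `f<n>` column is divided
#'   by `n` at read time.
#' @return A [qcmd_trace()].
#' @export
read_qcmd <- function(path, normalized = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  comment <- grepl("^\\s*#", lines)
  meta <- parse_meta_lines(lines[comment])
  body <- lines[!comment & nzchar(trimws(lines))]
  if (length(body) < 2) abort("unparseable file: no data rows")
  wide <- utils::read.csv(text = paste(body, collapse = "\n"),
                          check.names = FALSE)
  if (!"time_min" %in% names(wide)) abort("no time column")

  f_cols <- grep("^f([0-9]+)$", names(wide), value = TRUE)
  if (length(f_cols) == 0) abort("no harmonic columns (expected f3, D3, ...)")
  harmonics <- sort(as.integer(sub("^f", "", f_cols)))

  long <- purrr::map_dfr(harmonics, function(h) {
    fc <- paste0("f", h)
    dc <- paste0("D", h)
    if (!dc %in% names(wide)) {
      abort(paste0("harmonic ", h, " has a frequency column but no ", dc))
    }
    f <- wide[[fc]]
    if (!normalized) f <- f / h
    tibble(time_min = wide$time_min, harmonic = h,
           delta_f = f, delta_D = wide[[dc]])
  })

  bad_rows <- sort(unique(which(
    !is.finite(wide$time_min) |
      rowSums(!is.finite(as.matrix(wide[, c(paste0("f", harmonics),
                                            paste0("D", harmonics))]))) > 0
  )))
  if (length(bad_rows) > 0) {
    warn(paste0("dropping ", length(bad_rows), " row(s) with non-finite values: ",
                paste(bad_rows, collapse = ", ")))
    keep_t <- wide$time_min[-bad_rows]
    long <- filter(long, .data$time_min %in% keep_t)
  }
  qcmd_trace(long, meta = meta)
}

parse_meta_lines <- function(lines) {
  lines <- sub("^\\s*#\\s*", "", lines)
  lines <- lines[grepl(":", lines)]
  meta <- list()
  for (ln in lines) {
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

#' Write a QCM-D trace to a wide CSV file
#'
#' Inverse of [read_qcmd()]: metadata becomes `# key: value` comment lines,
#' data becomes wide columns `time_min, f3, D3, ...`. Values are written at
#' full precision so a read/write round trip is exact.
#'
#' @param trace A [qcmd_trace()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_qcmd <- function(trace, path) {
  trace <- qcmd_trace(trace, meta = trace_meta(trace))  # revalidate
  meta <- trace_meta(trace)
  wide <- tidyr::pivot_wider(trace,
                             id_cols = "time_min",
                             names_from = "harmonic",
                             values_from = c("delta_f", "delta_D"))
  harmonics <- trace_harmonics(trace)
  names(wide) <- c("time_min",
                   paste0("f", harmonics), paste0("D", harmonics))
  wide <- wide[, c("time_min",
                   as.vector(rbind(paste0("f", harmonics),
                                   paste0("D", harmonics))))]
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(paste0("# ", key, ": ", format(meta[[key]], digits = 17)), con)
  }
  writeLines(paste(names(wide), collapse = ","), con)
  body <- apply(wide, 1, function(r) {
    paste(vapply(r, function(x) format(x, digits = 17), character(1)),
          collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Re-zero a trace against a baseline buffer window
#'
#' Deposition experiments start by flowing pure buffer to establish a
#' baseline; all reported shifts are relative to it. `rebaseline()` subtracts,
#' per harmonic, the mean frequency and dissipation over a baseline window so
#' the baseline averages zero. The operation is a pure per-harmonic shift
#' (all pairwise differences within a series are preserved) and is idempotent
#' on an already-zeroed baseline.
#'
#' @param trace A [qcmd_trace()].
#' @param window Numeric length-2 `c(t0, t1)` in minutes; should lie before
#'   the start of vesicle flow.
#' @return A rebaselined [qcmd_trace()].
#' @export
rebaseline <- function(trace, window) {
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2]) {
    abort("window must be c(t0, t1) with t0 < t1")
  }
  in_win <- trace$time_min >= window[1] & trace$time_min <= window[2]
  if (!any(in_win)) abort("empty baseline window")
  base <- trace |>
    filter(in_win) |>
    group_by(.data$harmonic) |>
    summarise(f0 = mean(.data$delta_f), D0 = mean(.data$delta_D),
              .groups = "drop")
  out <- trace |>
    left_join(base, by = "harmonic") |>
    mutate(delta_f = .data$delta_f - .data$f0,
           delta_D = .data$delta_D - .data$D0) |>
    dplyr::select(-"f0", -"D0")
  qcmd_trace(out, meta = trace_meta(trace))
}

#' @export
print.qcmd_trace <- function(x, ...) {
  h <- trace_harmonics(x)
  cat("<qcmd_trace> ", length(unique(x$time_min)), " time points, harmonics ",
      paste(h, collapse = ", "), "\n", sep = "")
  meta <- trace_meta(x)
  if (length(meta) > 0) {
    cat("meta: ", paste(names(meta), unlist(lapply(meta, format)),
                        sep = "=", collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}
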