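#' End-to-end analysis of a deposition trace
#'
#' Composes the full pipeline: classify the trace into its outcome signature,
#' then — when the label indicates a bilayer-type film (one-step, two-step or
#' incomplete) and a lipid mixture is supplied — run the packing-geometry
#' chain on the final frequency shift. An intact vesicle layer gets no
#' packing block: its Sauerbrey mass would be dominated by entrapped water.
#'
#' Warnings attached to the report: Sauerbrey inapplicability when the final
#' dissipation is at or above the rigid limit; a non-continuous-film caveat
#' for incomplete bilayers (the area per lipid is then a surface average over
#' patches and gaps); corrected mass within 20% of zero.
#'
#' @param trace A [qcmd_trace()] or path to a trace CSV ([read_qcmd()]).
#' @param markers [flow_markers()]; defaults to markers stored in the trace.
#' @param mixture Optional [lipid_mixture()] for the packing chain.
#' @param thresholds A [signature_thresholds()].
#' @param config A [packing_config()].
#' @return An object of class `slb_report`: list with elements `signature`,
#'   `packing` (or `NULL`), `warnings`, `config`, `version`.
#' @export
#' @examples
#' tr <- simulate_trace(slb_preset("PC"))
#' rep <- analyze_slb(tr, mixture = lipid_mixture(c(PC = 1)))
#' rep$signature$label
analyze_slb <- function(trace, markers = NULL, mixture = NULL,
                        thresholds = signature_thresholds(),
                        config = packing_config()) {
  if (is.character(trace)) trace <- read_qcmd(trace)
  if (is.null(markers)) markers <- trace_markers(trace)
  sig <- classify_signature(trace, markers, thresholds)

  warnings <- character(0)
  packing <- NULL
  bilayer_labels <- c("one_step_slb", "two_step_slb", "incomplete_bilayer")
  if (sig$label %in% bilayer_labels && !is.null(mixture)) {
    packing <- packing_from_frequency(sig$f_final, mixture, config,
                                      D_final = sig$D_final)
    warnings <- c(warnings, attr(packing, "warnings"))
    if (sig$label == "incomplete_bilayer") {
      warnings <- c(warnings, paste0(
        "non-continuous film: bilayer patches with gaps; ",
        "a_L is a surface average"))
    }
    if (packing$corrected_mass < 0.2 * config$water_correction) {
      warnings <- c(warnings, "corrected mass near zero")
    }
  } else if (sig$label %in% bilayer_labels && is.null(mixture)) {
    warnings <- c(warnings, "no lipid mixture supplied; packing skipped")
  }
  if (!is.null(packing) && !sig$rigid) {
    # invariant: packing present implies rigid film or an explicit warning
    stopifnot(any(grepl("Sauerbrey", warnings)))
  }

  structure(list(signature = sig, packing = packing, warnings = warnings,
                 config = list(thresholds = unclass(thresholds),
                               packing = unclass(config)),
                 version = as.character(utils::packageVersion("qslb"))),
            class = "slb_report")
}

#' Serialise an analysis report to canonical JSON
#'
#' Keys are sorted and floats written with fixed precision so identical
#' inputs produce byte-identical JSON.
#'
#' @param report An [analyze_slb()] report.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  sig <- glance(report$signature)
  payload <- list(
    signature = as.list(sig),
    packing = if (!is.null(report$packing)) {
      as.list(as_tibble(report$packing)[1, ])
    } else {
      NULL
    },
    warnings = as.list(report$warnings),
    config = report$config,
    version = report$version
  )
  payload <- sort_named_lists(payload)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10, null = "null",
                   na = "null")
}

sort_named_lists <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x))]
    lapply(x, sort_named_lists)
  } else if (is.list(x)) {
    lapply(x, sort_named_lists)
  } else {
    x
  }
}

#' @rdname report_json
#' @param path File to write.
#' @export
write_report <- function(report, path) {
  writeLines(report_json(report), path)
  invisible(path)
}

#' Validate a report against the shipped schema
#'
#' Checks the structural contract published in
#' `system.file("schema", "slb-report-schema.json", package = "qslb")`:
#' required top-level and signature fields present, label among the allowed
#' values, numeric fields numeric.
#'
#' @param report An [analyze_slb()] report (or a parsed JSON list).
#' @return `TRUE` invisibly; aborts with the first violation otherwise.
#' @export
validate_report <- function(report) {
  if (inherits(report, "slb_report")) {
    report <- jsonlite::fromJSON(report_json(report), simplifyVector = FALSE)
  }
  schema_path <- system.file("schema", "slb-report-schema.json",
                             package = "qslb")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)

  for (field in names(schema$required)) {
    if (!field %in% names(report)) {
      abort(paste0("report missing required field: ", field))
    }
  }
  sig <- report$signature
  for (field in unlist(schema$signature_required)) {
    if (!field %in% names(sig)) {
      abort(paste0("signature missing required field: ", field))
    }
  }
  allowed <- unlist(schema$labels)
  if (!sig$label %in% allowed) {
    abort(paste0("invalid label: ", sig$label))
  }
  for (field in unlist(schema$signature_numeric)) {
    v <- sig[[field]]
    if (!is.null(v) && !is.na(v) && !is.numeric(v)) {
      abort(paste0("signature field not numeric: ", field))
    }
  }
  invisible(TRUE)
}

#' @export
print.slb_report <- function(x, ...) {
  cat("<slb_report> version", x$version, "\n")
  print(x$signature)
  if (!is.null(x$packing)) {
    cat(sprintf("packing: N_L %.2f /nm^2, a_L %.2f nm^2, h_L %.2f nm\n",
                x$packing$N_L, x$packing$a_L, x$packing$h_L))
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @rdname glance.slb_signature
#' @method glance slb_report
#' @export
glance.slb_report <- function(x, ...) {
  out <- glance(x$signature)
  if (!is.null(x$packing)) {
    out <- dplyr::bind_cols(out, as_tibble(x$packing)[, c(
      "areal_mass", "corrected_mass", "M_L", "N_L", "a_L", "h_L")])
  }
  out$n_warnings <- length(x$warnings)
  out
}

#' @rdname glance.slb_signature
#' @method tidy slb_report
#' @export
tidy.slb_report <- function(x, ...) {
  g <- glance(x)
  num <- g[vapply(g, is.numeric, logical(1))]
  tibble(metric = names(num), value = as.numeric(unlist(num[1, ])))
}
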