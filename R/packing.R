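#' Built-in lipid species constants
#'
#' Molecular weight and hydrophobic-tail volume for the three lipids used
#' throughout: egg phosphatidylglycerol (PG, anionic, two acyl chains),
#' lysophosphatidylglycerol (LPG, anionic, single chain) and egg
#' phosphatidylcholine (PC, zwitterionic). Tail volumes are per-molecule
#' averages over the constituent C16/C18 acyl chains.
#'
#' @return A tibble with columns `name`, `mw` (g/mol), `v_tail`
#'   (nm^3/molecule).
#' @export
#' @examples
#' slb_lipids()
slb_lipids <- function() {
  tibble(name = c("PG", "LPG", "PC"),
         mw = c(782, 506, 770),
         v_tail = c(0.96, 0.46, 0.96))
}

#' Define a lipid species
#'
#' @param name Label.
#' @param mw Molecular weight, g/mol (> 0).
#' @param v_tail Hydrophobic tail volume, nm^3/molecule (> 0).
#' @return A one-row tibble.
#' @export
lipid_species <- function(name, mw, v_tail) {
  if (!is_number(mw) || mw <= 0) abort("mw must be > 0")
  if (!is_number(v_tail) || v_tail <= 0) abort("v_tail must be > 0")
  tibble(name = as.character(name), mw = mw, v_tail = v_tail)
}

#' Define a lipid mixture by mole fractions
#'
#' @param fractions Named numeric vector of mole fractions in (0, 1], summing
#'   to 1 (within 1e-9); names are looked up in `species`.
#' @param species A data frame of species constants with columns `name`,
#'   `mw`, `v_tail`; defaults to [slb_lipids()].
#' @return A tibble of class `lipid_mixture` with columns `name`, `mw`,
#'   `v_tail`, `fraction`.
#' @export
#' @examples
#' lipid_mixture(c(PG = 0.9, LPG = 0.1))
lipid_mixture <- function(fractions, species = slb_lipids()) {
  if (length(fractions) == 0) abort("empty mixture")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    abort("fractions must be a named vector")
  }
  if (any(fractions <= 0 | fractions > 1)) {
    abort("mole fractions must lie in (0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("mole fractions must sum to 1")
  species <- as_tibble(species)
  missing <- setdiff(names(fractions), species$name)
  if (length(missing) > 0) {
    abort(paste0("unknown species: ", paste(missing, collapse = ", ")))
  }
  mix <- tibble(name = names(fractions), fraction = unname(fractions)) |>
    left_join(species, by = "name") |>
    dplyr::select("name", "mw", "v_tail", "fraction")
  structure(mix, class = c("lipid_mixture", class(tibble())))
}

#' Read a lipid mixture from YAML
#'
#' Expects optional `species:` entries (`name`, `mw`, `v_tail`) and a
#' `mixture:` list of `{name, fraction}`; species not defined in the file are
#' looked up in [slb_lipids()].
#'
#' @param path Path to a YAML file.
#' @return A [lipid_mixture()].
#' @export
read_mixture <- function(path) {
  cfg <- yaml::read_yaml(path)
  species <- slb_lipids()
  if (!is.null(cfg$species)) {
    extra <- bind_rows(lapply(cfg$species, function(sp) {
      lipid_species(sp$name, sp$mw, sp$v_tail)
    }))
    species <- bind_rows(extra, species) |> distinct(.data$name, .keep_all = TRUE)
  }
  if (is.null(cfg$mixture)) abort("YAML file has no 'mixture' entry")
  fr <- vapply(cfg$mixture, function(x) as.numeric(x$fraction), numeric(1))
  names(fr) <- vapply(cfg$mixture, function(x) as.character(x$name), character(1))
  lipid_mixture(fr, species = species)
}

#' Mole-fraction-weighted mixture averages
#'
#' Average molecular weight and hydrophobic tail volume of a lipid mixture,
#' e.g. 0.9 PG (782 g/mol, 0.96 nm^3) + 0.1 LPG (506, 0.46) gives 754.4 g/mol
#' and 0.91 nm^3/molecule.
#'
#' @param mixture A [lipid_mixture()].
#' @return A one-row tibble with `mw_avg` (g/mol) and `v_tail_avg`
#'   (nm^3/molecule).
#' @export
mixture_average <- function(mixture) {
  if (!inherits(mixture, "lipid_mixture")) {
    mixture <- lipid_mixture_from_df(mixture)
  }
  tibble(mw_avg = sum(mixture$fraction * mixture$mw),
         v_tail_avg = sum(mixture$fraction * mixture$v_tail))
}

lipid_mixture_from_df <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("name", "mw", "v_tail", "fraction") %in% names(df)))
  fr <- stats::setNames(df$fraction, df$name)
  lipid_mixture(fr, species = df[, c("name", "mw", "v_tail")])
}

#' Sauerbrey areal mass from a frequency shift
#'
#' For a thin rigid film the areal mass follows \eqn{\Delta m = -C \Delta f}
#' with \eqn{C = 17.8} ng/cm^2/Hz for a crystal with a 5 MHz natural
#' frequency; a negative frequency shift (mass addition) gives a positive
#' mass.
#'
#' @param delta_f Frequency shift, Hz (vectorised).
#' @param C Mass-sensitivity constant, ng/cm^2/Hz.
#' @return Areal mass, ng/cm^2.
#' @export
#' @examples
#' sauerbrey_mass(-25) # 445 ng/cm^2
sauerbrey_mass <- function(delta_f, C = 17.8) {
  if (C <= 0) abort("C must be > 0")
  -C * delta_f
}

#' Is the Sauerbrey relation applicable?
#'
#' The relation assumes a rigid film; it applies when the dissipation change
#' is small, strictly below 1e-6. At or above that the film is viscoelastic
#' and a Sauerbrey mass underestimates the coupled mass.
#'
#' @param D_final Final dissipation shift, units of 1e-6 (vectorised).
#' @param limit Rigidity threshold, default 1.
#' @return Logical.
#' @export
sauerbrey_applicable <- function(D_final, limit = 1) {
  D_final < limit
}

#' Configuration constants for the packing chain
#'
#' @param C Sauerbrey constant, ng/cm^2/Hz (default 17.8, 5 MHz crystal).
#' @param water_correction Areal mass of the water layer trapped between
#'   bilayer and sensor, ng/cm^2 (default 102, estimated for PC bilayers on
#'   silica and assumed transferable to anionic bilayers).
#' @param avogadro Avogadro constant, 1/mol.
#' @return A named list of class `packing_config`.
#' @export
packing_config <- function(C = 17.8, water_correction = 102,
                           avogadro = 6.02214e23) {
  if (C <= 0) abort("C must be > 0")
  if (water_correction < 0) abort("water_correction must be >= 0")
  structure(list(C = C, water_correction = water_correction,
                 avogadro = avogadro),
            class = "packing_config")
}

#' Molecular packing geometry of a bilayer from its frequency shift
#'
#' The full chain from a stabilised bilayer's final frequency shift to its
#' packing geometry:
#' \enumerate{
#'   \item areal mass \eqn{\Delta m = -C\,\Delta f};
#'   \item corrected mass = areal mass − trapped-water layer;
#'   \item per-molecule mass \eqn{M_L = \bar{m}w / N_A} (ng/lipid);
#'   \item total surface density = corrected mass / \eqn{M_L}, converted to
#'     lipids/nm^2 (1 cm^2 = 1e14 nm^2);
#'   \item per-leaflet density \eqn{N_L} = total / 2;
#'   \item area per lipid \eqn{a_L = 1/N_L};
#'   \item hydrophobic thickness \eqn{h_L = 2\bar{v}_L / a_L}.
#' }
#' All steps are computed at full precision; round only at report time.
#'
#' @param delta_f Final frequency shift, Hz (negative).
#' @param mixture A [lipid_mixture()].
#' @param config A [packing_config()].
#' @param D_final Optional final dissipation (1e-6). When supplied and at or
#'   above the rigid limit, a Sauerbrey-inapplicability warning is attached
#'   (the chain still computes).
#' @return A one-row tibble of class `packing_result` with columns `delta_f`,
#'   `areal_mass`, `corrected_mass`, `mw_avg`, `M_L`, `density_total`, `N_L`,
#'   `a_L`, `v_L_avg`, `h_L`. Warnings, if any, in attribute `"warnings"`.
#' @export
#' @examples
#' packing_from_frequency(-25, lipid_mixture(c(PG = 0.9, LPG = 0.1)))
packing_from_frequency <- function(delta_f, mixture,
                                   config = packing_config(),
                                   D_final = NULL) {
  if (!is_number(delta_f)) abort("delta_f must be a finite number")
  avg <- mixture_average(mixture)
  areal <- sauerbrey_mass(delta_f, config$C)
  corrected <- areal - config$water_correction
  if (corrected <= 0) {
    abort("corrected mass <= 0: film lighter than the assumed water layer")
  }
  M_L <- avg$mw_avg / config$avogadro * 1e9       # g -> ng per molecule
  density_total <- corrected / M_L / 1e14          # lipids/cm^2 -> lipids/nm^2
  N_L <- density_total / 2
  a_L <- 1 / N_L
  h_L <- 2 * avg$v_tail_avg / a_L

  warnings <- character(0)
  if (!is.null(D_final) && !sauerbrey_applicable(D_final)) {
    warnings <- c(warnings, paste0(
      "Sauerbrey relation inapplicable: final dissipation ", D_final,
      "e-6 indicates a viscoelastic film; mass is an underestimate"))
  }
  out <- tibble(delta_f = delta_f, areal_mass = areal,
                corrected_mass = corrected,
                mw_avg = avg$mw_avg, M_L = M_L,
                density_total = density_total, N_L = N_L, a_L = a_L,
                v_L_avg = avg$v_tail_avg, h_L = h_L)
  structure(out, warnings = warnings,
            class = c("packing_result", class(tibble())))
}

#' Packing geometry for a batch of compositions
#'
#' Runs [packing_from_frequency()] on each row; a row whose chain fails (e.g.
#' corrected mass at or below zero) is flagged in the `note` column with its
#' numeric results set to `NA`, without aborting the batch.
#'
#' @param rows A data frame with columns `label`, `delta_f` and a list-column
#'   `mixture` of [lipid_mixture()] objects.
#' @param config A [packing_config()].
#' @return A tibble with one result row per input row plus `label` and `note`
#'   columns.
#' @export
packing_table <- function(rows, config = packing_config()) {
  rows <- as_tibble(rows)
  stopifnot(all(c("label", "delta_f", "mixture") %in% names(rows)))
  if (nrow(rows) == 0) {
    return(tibble(label = character(0), delta_f = numeric(0),
                  areal_mass = numeric(0), corrected_mass = numeric(0),
                  mw_avg = numeric(0), M_L = numeric(0),
                  density_total = numeric(0), N_L = numeric(0),
                  a_L = numeric(0), v_L_avg = numeric(0), h_L = numeric(0),
                  note = character(0)))
  }
  res <- purrr::pmap(rows, function(label, delta_f, mixture, ...) {
    out <- tryCatch(
      packing_from_frequency(delta_f, mixture, config),
      error = function(e) {
        tibble(delta_f = delta_f, areal_mass = NA_real_,
               corrected_mass = NA_real_, mw_avg = NA_real_, M_L = NA_real_,
               density_total = NA_real_, N_L = NA_real_, a_L = NA_real_,
               v_L_avg = NA_real_, h_L = NA_real_) |>
          structure(note = conditionMessage(e))
      })
    note <- attr(out, "note") %||% NA_character_
    mutate(as_tibble(out), label = label, note = note)
  })
  bind_rows(res) |>
    dplyr::relocate("label")
}

#' Render a packing table at report precision
#'
#' Rounds a [packing_table()] to the precision conventionally printed:
#' per-molecule mass `M_L` to 3 significant figures, all other quantities to
#' 2 decimal places.
#'
#' @param table Output of [packing_table()].
#' @return A tibble.
#' @export
format_packing_table <- function(table) {
  table |>
    mutate(M_L = signif(.data$M_L, 3),
           across(c("areal_mass", "corrected_mass", "mw_avg",
                    "density_total", "N_L", "a_L", "v_L_avg", "h_L"),
                  ~ round(.x, 2)))
}
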