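#' Reference table of biomarker compounds
#'
#' Per-compound chemistry needed to turn measured derivative delta-13C values
#' and concentrations into analyte-carbon quantities: number of analyte
#' carbons, carbons added during derivatization, and the analyte molar mass
#' (free compound) from which the carbon mass fraction is computed. PLFAs are
#' measured as fatty acid methyl esters (one methanol carbon added); amino
#' sugars as aldononitrile acetates (eight acetyl/nitrile-path carbons for
#' hexosamines, six for muramic acid); amino acids as acetylated isopropyl
#' esters (five added carbons). These counts are package defaults — the
#' original chromatography workflow does not publish them per compound — and
#' any user table with the same columns can be passed wherever a `reference`
#' argument appears.
#'
#' The amino sugar panel is fixed to GlcN, GalN, MurN, ManN; the amino acid
#' panel to the 11 entries alanine, Asx, Glx, glycine, isoleucine, lysine,
#' phenylalanine, Pro/Thr, serine, tyrosine, valine.
#'
#' @return A tibble with columns `compound`, `biomarker_class`,
#'   `n_carbon_analyte`, `n_carbon_added`, `molar_mass`, `c_fraction`.
#' @examples
#' biomarker_reference()
#' @export
biomarker_reference <- function() {
  fa <- function(compound, n_c, mm) {
    tibble::tibble(compound = compound, biomarker_class = "PLFA",
                   n_carbon_analyte = n_c, n_carbon_added = 1,
                   molar_mass = mm)
  }
  plfa <- dplyr::bind_rows(
    fa("i15:0", 15, 242.40), fa("a15:0", 15, 242.40), fa("15:0", 15, 242.40),
    fa("16:0", 16, 256.42), fa("16:1w7", 16, 254.41), fa("i16:0", 16, 256.42),
    fa("17:0", 17, 270.45), fa("cy17:0", 17, 268.43),
    fa("18:0", 18, 284.48), fa("18:1w9", 18, 282.46), fa("18:2w6", 18, 280.45),
    fa("cy19:0", 19, 296.49))
  as_tbl <- tibble::tibble(
    compound = c("GlcN", "GalN", "ManN", "MurN"),
    biomarker_class = "AS",
    n_carbon_analyte = c(6, 6, 6, 9),
    n_carbon_added = c(8, 8, 8, 6),
    molar_mass = c(179.17, 179.17, 179.17, 251.23))
  aa_tbl <- tibble::tibble(
    compound = c("alanine", "Asx", "Glx", "glycine", "isoleucine", "lysine",
                 "phenylalanine", "Pro/Thr", "serine", "tyrosine", "valine"),
    biomarker_class = "AA",
    n_carbon_analyte = c(3, 4, 5, 2, 6, 6, 9, 5, 3, 9, 5),
    n_carbon_added = 5,
    molar_mass = c(89.09, 133.10, 147.13, 75.07, 131.17, 146.19,
                   165.19, 115.13, 105.09, 181.19, 117.15))
  dplyr::bind_rows(plfa, as_tbl, aa_tbl) |>
    dplyr::mutate(c_fraction = 12.011 * .data$n_carbon_analyte /
                    .data$molar_mass)
}

#' Correct a derivative delta-13C for derivatization carbon dilution
#'
#' Carbon atoms added during derivatization dilute the analyte's isotopic
#' signal. The correction inverts a two-pool mixing balance. On the default
#' delta scale (the linear approximation standard in compound-specific
#' work):
#' \deqn{\delta_{analyte} = \frac{(n_a + n_d)\,\delta_{measured} -
#'   n_d\,\delta_{reagent}}{n_a}.}
#' With `scale = "atom_fraction"` the same balance is solved exactly on the
#' atom-fraction scale; at natural-abundance reagent values the two agree to
#' well under 0.01 per-mil.
#'
#' @param delta_measured Measured delta-13C of the derivative (per-mil).
#' @param n_analyte Number of analyte carbons (>= 1).
#' @param n_added Number of derivatization carbons (>= 0).
#' @param delta_reagent Delta-13C of the added-carbon source (per-mil).
#' @param scale `"delta"` (default) or `"atom_fraction"`.
#' @param standard Reference standard, used only on the atom-fraction scale.
#' @return Corrected analyte delta-13C (per-mil).
#' @examples
#' correct_derivatization_dilution(-30, 16, 1, -40)  # -29.375
#' @export
correct_derivatization_dilution <- function(delta_measured, n_analyte,
                                            n_added, delta_reagent = NULL,
                                            scale = c("delta", "atom_fraction"),
                                            standard = std_vpdb()) {
  scale <- match.arg(scale)
  if (any(n_analyte < 1, na.rm = TRUE)) {
    stop("`n_analyte` must be at least 1", call. = FALSE)
  }
  if (any(n_added < 0, na.rm = TRUE)) {
    stop("`n_added` must be non-negative", call. = FALSE)
  }
  if (any(n_added > 0, na.rm = TRUE) && is.null(delta_reagent)) {
    stop("`delta_reagent` is required when derivatization adds carbon",
         call. = FALSE)
  }
  if (is.null(delta_reagent)) delta_reagent <- 0
  if (scale == "delta") {
    ((n_analyte + n_added) * delta_measured - n_added * delta_reagent) /
      n_analyte
  } else {
    f_m <- delta_to_atom_percent(delta_measured, standard) / 100
    f_r <- delta_to_atom_percent(delta_reagent, standard) / 100
    f_a <- ((n_analyte + n_added) * f_m - n_added * f_r) / n_analyte
    atom_percent_to_delta(100 * f_a, standard)
  }
}

#' Fit an instrument correction model for compound-specific delta-13C
#'
#' Least-squares fit of the systematic measurement error of a CSIA run
#' (measured minus true delta of co-analyzed standards) against an intercept
#' (offset), run index (drift) and log peak amount (amount dependence).
#' Applying the fitted model to a measured delta subtracts the predicted
#' error.
#'
#' @param calibration Data frame of standard runs with columns `true_d13c`,
#'   `measured_d13c`, and — for the respective terms — `run_index` and
#'   `amount`.
#' @param terms Character subset of `c("offset", "drift", "amount")`.
#' @return An object of class `csia_correction` with elements `offset`,
#'   `drift_slope`, `amount_slope`, and the fit.
#' @examples
#' cal <- data.frame(true_d13c = c(-30, -25, -20, -30, -25, -20),
#'                   measured_d13c = c(-29.5, -24.5, -19.5, -29.5, -24.5, -19.5),
#'                   run_index = 1:6, amount = c(10, 20, 40, 10, 20, 40))
#' fit_instrument_correction(cal)$offset  # 0.5
#' @export
fit_instrument_correction <- function(calibration,
                                      terms = c("offset", "drift", "amount")) {
  terms <- match.arg(terms, several.ok = TRUE)
  stopifnot(is.data.frame(calibration))
  need <- c("true_d13c", "measured_d13c",
            if ("drift" %in% terms) "run_index",
            if ("amount" %in% terms) "amount")
  missing_cols <- setdiff(need, names(calibration))
  if (length(missing_cols)) {
    stop("calibration table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(calibration) < 2L) {
    stop("at least 2 calibration points are required", call. = FALSE)
  }
  if ("amount" %in% terms &&
      length(unique(calibration$amount)) < 2L) {
    stop("amount term requested but all calibration amounts are equal",
         call. = FALSE)
  }
  if ("drift" %in% terms &&
      length(unique(calibration$run_index)) < 2L) {
    stop("drift term requested but all calibration run indices are equal",
         call. = FALSE)
  }
  err <- calibration$measured_d13c - calibration$true_d13c
  rhs <- c("1", if ("drift" %in% terms) "run_index",
           if ("amount" %in% terms) "log(amount)")
  fit <- stats::lm(stats::reformulate(rhs, response = "err"),
                   data = cbind(calibration, err = err))
  cf <- stats::coef(fit)
  structure(list(
    offset = unname(cf["(Intercept)"]),
    drift_slope = unname(cf["run_index"] %|NA|% 0),
    amount_slope = unname(cf["log(amount)"] %|NA|% 0),
    terms = terms, fit = fit, n = nrow(calibration)),
    class = "csia_correction")
}

`%|NA|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

#' @rdname fit_instrument_correction
#' @export
identity_correction <- function() {
  structure(list(offset = 0, drift_slope = 0, amount_slope = 0,
                 terms = character(), fit = NULL, n = 0L),
            class = "csia_correction")
}

#' @export
print.csia_correction <- function(x, ...) {
  cat(sprintf(
    "<csia_correction> offset %.4f permil, drift %.5f permil/run, amount %.5f permil/log-amount (n = %d)\n",
    x$offset, x$drift_slope, x$amount_slope, x$n))
  invisible(x)
}

#' @rdname fit_instrument_correction
#' @param model A `csia_correction`.
#' @param delta_measured Measured delta-13C values (per-mil).
#' @param run_index Run index of each measurement (needed for a drift term).
#' @param amount Peak amount of each measurement (needed for an amount term).
#' @export
apply_instrument_correction <- function(model, delta_measured,
                                        run_index = 0, amount = 1) {
  stopifnot(inherits(model, "csia_correction"))
  delta_measured - model$offset - model$drift_slope * run_index -
    model$amount_slope * log(amount)
}

#' 13C incorporation into a single biomarker
#'
#' The atom-percent 13C excess of the (fully corrected) biomarker over its
#' unlabeled counterpart, times the analyte carbon content of the compound in
#' the sample.
#'
#' @param delta_corrected Corrected analyte delta-13C (per-mil).
#' @param delta_background Corrected analyte delta-13C of the same compound
#'   in an unlabeled sample.
#' @param concentration_ug_per_g Compound concentration (ug per g dry matrix).
#' @param c_fraction Carbon mass fraction of the analyte.
#' @param standard Reference standard.
#' @return 13C excess in ug 13C per g dry matrix.
#' @export
biomarker_13c_incorporation <- function(delta_corrected, delta_background,
                                        concentration_ug_per_g, c_fraction,
                                        standard = std_vpdb()) {
  ape <- atom_percent_excess(delta_corrected, delta_background, standard)
  tracer_mass(concentration_ug_per_g * c_fraction, ape)
}

#' Correct and quantify a biomarker table
#'
#' Applies the fixed correction order — instrument model first, then
#' derivatization dilution — to every record, joins the compound reference
#' chemistry, validates class membership, and computes per-compound carbon
#' content, atom-percent 13C excess, and 13C incorporation.
#'
#' @param records Data frame with one row per compound x sample: `sample_id`,
#'   `compound`, `biomarker_class` (PLFA/AS/AA), `matrix`,
#'   `concentration_ug_per_g`, `d13c_measured`, `d13c_background` (analyte
#'   scale, unlabeled counterpart), `d13c_reagent`, and optional `run_index`
#'   and `peak_amount`. Extra identifier columns (plot, depth, ...) pass
#'   through.
#' @param correction A `csia_correction`; defaults to the identity.
#' @param reference Compound reference table; see [biomarker_reference()].
#' @param dilution_scale Passed to [correct_derivatization_dilution()].
#' @param standard Reference standard.
#' @return The input tibble plus `d13c_instrument`, `d13c_corrected`,
#'   `c_content_ug_per_g`, `ape_13c`, `incorporation_ug_13c_per_g`.
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 1, noise_cv = 0))
#' head(correct_biomarkers(sim$biomarkers))
#' @export
correct_biomarkers <- function(records, correction = identity_correction(),
                               reference = biomarker_reference(),
                               dilution_scale = c("delta", "atom_fraction"),
                               standard = std_vpdb()) {
  dilution_scale <- match.arg(dilution_scale)
  stopifnot(is.data.frame(records))
  req <- c("sample_id", "compound", "biomarker_class",
           "concentration_ug_per_g", "d13c_measured", "d13c_background")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("biomarker table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_panels(records, reference)
  if (!"run_index" %in% names(records)) records$run_index <- 0
  if (!"peak_amount" %in% names(records)) records$peak_amount <- 1
  out <- records |>
    dplyr::left_join(
      reference |>
        dplyr::select("compound", "biomarker_class", "n_carbon_analyte",
                      "n_carbon_added", "c_fraction"),
      by = c("compound", "biomarker_class"))
  if (anyNA(out$n_carbon_analyte)) {
    unk <- unique(out$compound[is.na(out$n_carbon_analyte)])
    stop("compound(s) absent from the reference table: ",
         paste(unk, collapse = ", "), call. = FALSE)
  }
  if (any(out$n_carbon_added > 0) && !"d13c_reagent" %in% names(out)) {
    stop("`d13c_reagent` column required: derivatization adds carbon and the ",
         "reagent delta-13C has no default", call. = FALSE)
  }
  if (!"d13c_reagent" %in% names(out)) out$d13c_reagent <- NA_real_
  if (anyNA(out$d13c_background)) {
    bad <- out[is.na(out$d13c_background), ]
    stop("missing unlabeled background delta-13C for ",
         paste(unique(paste0(bad$compound, " (", bad$sample_id, ")")),
               collapse = ", "), call. = FALSE)
  }
  out |>
    dplyr::mutate(
      d13c_instrument = apply_instrument_correction(
        correction, .data$d13c_measured, .data$run_index,
        .data$peak_amount),
      d13c_corrected = correct_derivatization_dilution(
        .data$d13c_instrument, .data$n_carbon_analyte,
        .data$n_carbon_added, .data$d13c_reagent, scale = dilution_scale,
        standard = standard),
      c_content_ug_per_g = .data$concentration_ug_per_g * .data$c_fraction,
      ape_13c = atom_percent_excess(.data$d13c_corrected,
                                    .data$d13c_background, standard),
      incorporation_ug_13c_per_g = tracer_mass(.data$c_content_ug_per_g,
                                               .data$ape_13c)) |>
    tibble::as_tibble()
}

validate_panels <- function(records, reference) {
  allowed <- split(reference$compound, reference$biomarker_class)
  for (cls in c("AS", "AA")) {
    rows <- records$biomarker_class == cls
    bad <- setdiff(unique(records$compound[rows]), allowed[[cls]])
    if (length(bad)) {
      stop("compound(s) not in the ", cls, " panel: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Aggregate corrected biomarkers into pool summaries
#'
#' Sums each biomarker class within each sample into pool totals and the
#' pool's weighted atom-percent 13C excess — the total 13C incorporation
#' divided by the total analyte carbon of the pool. Classes with no records
#' in a sample are simply absent from the output (an absent pool, not a zero
#' one); downstream indices treat them as undefined.
#'
#' @param corrected Output of [correct_biomarkers()].
#' @param by Extra grouping columns carried through (auto-detected from
#'   `plot_id`, `species`, `n_rate`, `depth_top_cm`, `depth_bottom_cm`,
#'   `matrix` when present).
#' @return Tibble with one row per sample x class: `total_concentration`,
#'   `total_c_ug_per_g`, `total_13c_excess_ug_per_g`, `weighted_ape`,
#'   `n_compounds`.
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 1, noise_cv = 0))
#' summarize_pools(correct_biomarkers(sim$biomarkers))
#' @export
summarize_pools <- function(corrected, by = NULL) {
  if (is.null(by)) {
    by <- intersect(c("plot_id", "species", "n_rate", "depth_top_cm",
                      "depth_bottom_cm", "matrix"), names(corrected))
  }
  if (nrow(corrected) == 0L) {
    stop("no biomarker records to summarize: absent pool", call. = FALSE)
  }
  corrected |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sample_id", by, "biomarker_class")))) |>
    dplyr::summarise(
      total_concentration = sum(.data$concentration_ug_per_g),
      total_c_ug_per_g = sum(.data$c_content_ug_per_g),
      total_13c_excess_ug_per_g = sum(.data$incorporation_ug_13c_per_g),
      weighted_ape = ifelse(
        .data$total_c_ug_per_g > 0,
        100 * .data$total_13c_excess_ug_per_g / .data$total_c_ug_per_g,
        NA_real_),
      n_compounds = dplyr::n(),
      .groups = "drop")
}
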