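#' Configure a synthetic pulse-labeling experiment
#'
#' Builds the parameter set for [simulate_tracer_experiment()]. Defaults
#' emulate the field design the pipeline targets: three replicate field
#' plots, lucerne plus kernza at two fertilizer rates (100 and 200 kg N
#' ha-1), four depth intervals (0-25, 25-50, 50-100, 100-150 cm), repeated
#' 13C/14C-CO2 pulses whose volume follows the 5-mL-per-20-cm-of-height
#' rule, and a trace 15N addition. Tracer reaching belowground pools at each
#' depth is split root : rhizodeposit as (1 - f) : f where f is the true
#' ClvR fraction, rhizodeposits split bulk : rhizosphere 3:1, and a share of
#' the root tracer sits in unrecovered root fragments. Biomarker 13C in the
#' rhizosphere splits between the amino sugar (necromass) and PLFA (living
#' biomass) pools by `necromass_fraction`, which fixes the true RMS.
#'
#' Measurement noise is multiplicative lognormal (mean 1, coefficient of
#' variation `noise_cv`) on masses, concentrations and activities, and
#' additive Gaussian (`delta_noise_sd`, per-mil) on delta values, mirroring
#' how scintillation-counting and IRMS errors differ.
#'
#' @param seed Integer seed; the same seed and config give byte-identical
#'   tables.
#' @param n_plots Number of replicate field plots.
#' @param species Data frame with columns `species` and `n_rate`.
#' @param depths Data frame with `depth_top_cm`, `depth_bottom_cm`.
#' @param true_clvr_fraction Per-depth true fraction of belowground tracer
#'   lost via rhizodeposition, in `[0, 1)`.
#' @param root_c_mg_per_kg Per-depth true root C concentration.
#' @param depth_dose_weight Per-depth share of the belowground tracer dose.
#' @param shoot_allocation Fraction of the assimilated tracer retained
#'   aboveground.
#' @param frag_fraction Share of root tracer residing in unrecovered
#'   fragments.
#' @param bulk_rhizosphere_split Bulk : rhizosphere ratio of rhizodeposit
#'   tracer (default 3, i.e. 3:1).
#' @param pulse_heights_cm Plant height at each labeling pulse (cm,
#'   non-decreasing); sets the total labeling solution volume via
#'   [dose_schedule()].
#' @param c14_bq_per_ml,c13_mg_per_ml Tracer content of the labeling
#'   solution.
#' @param n15_dose_mg Belowground-available 15N excess per plot (mg).
#' @param background_d13c,background_d15n,background_activity Natural
#'   abundance backgrounds (per-mil, per-mil, Bq per g).
#' @param noise_cv Fractional CV of the multiplicative measurement noise.
#' @param delta_noise_sd Standard deviation of additive delta noise
#'   (per-mil).
#' @param necromass_fraction Per-depth share of biomarker 13C in the amino
#'   sugar pool (vs PLFA), in `[0, 1]`.
#' @param soil_c_mg_per_g,soil_n_mg_per_g Per-depth soil C and N
#'   concentrations.
#' @param soil_mass_kg Per-depth quantity of soil sampled.
#' @param subsample_mass_kg Mass of the washed bulk-soil subsample.
#' @param root_c_conc,root_n_conc Root tissue C and N (mg per g).
#' @param plfa_total,as_total,aa_total Topsoil biomarker pool sizes (ug per g
#'   rhizosphere soil).
#' @param biomarker_depth_factor Per-depth scaling of all biomarker pools.
#' @param microbial_13c_fraction Biomarker-bound 13C as a fraction of the
#'   combined AS + PLFA carbon (sets pool APEs to realistic sub-percent
#'   levels).
#' @param delta_reagent Delta-13C of the derivatization carbon source.
#' @param instrument_offset,instrument_drift,instrument_amount_slope
#'   Injected instrument artifacts (per-mil, per-mil per run, per-mil per
#'   log amount); zero by default.
#' @return A `scenario_config` list, validated.
#' @examples
#' cfg <- scenario_config(seed = 42, noise_cv = 0)
#' @export
scenario_config <- function(
    seed = 1L,
    n_plots = 3L,
    species = tibble::tibble(species = c("lucerne", "kernza", "kernza"),
                             n_rate = c(0, 100, 200)),
    depths = tibble::tibble(depth_top_cm = c(0, 25, 50, 100),
                            depth_bottom_cm = c(25, 50, 100, 150)),
    true_clvr_fraction = c(0.10, 0.12, 0.14, 0.16),
    root_c_mg_per_kg = c(600, 250, 120, 60),
    depth_dose_weight = c(0.50, 0.25, 0.15, 0.10),
    shoot_allocation = 0.6,
    frag_fraction = 0.05,
    bulk_rhizosphere_split = 3,
    pulse_heights_cm = round(seq(10, 110, length.out = 26)),
    c14_bq_per_ml = 11000,
    c13_mg_per_ml = 15.3,
    n15_dose_mg = 73.5,
    background_d13c = -27,
    background_d15n = 5,
    background_activity = 0.1,
    noise_cv = 0.05,
    delta_noise_sd = 0.15,
    necromass_fraction = c(0.35, 0.50, 0.60, 0.70),
    soil_c_mg_per_g = c(15, 8, 4, 2),
    soil_n_mg_per_g = c(1.5, 0.9, 0.5, 0.25),
    soil_mass_kg = c(3, 3, 6, 6),
    subsample_mass_kg = 0.15,
    root_c_conc = 420,
    root_n_conc = 15,
    plfa_total = 40,
    as_total = 600,
    aa_total = 250,
    biomarker_depth_factor = c(1, 0.6, 0.35, 0.2),
    microbial_13c_fraction = 0.004,
    delta_reagent = -40,
    instrument_offset = 0,
    instrument_drift = 0,
    instrument_amount_slope = 0) {
  cfg <- as.list(environment())
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  nd <- nrow(cfg$depths)
  per_depth <- c("true_clvr_fraction", "root_c_mg_per_kg",
                 "depth_dose_weight", "necromass_fraction",
                 "soil_c_mg_per_g", "soil_n_mg_per_g", "soil_mass_kg",
                 "biomarker_depth_factor")
  bad_len <- per_depth[vapply(per_depth,
                              function(f) length(cfg[[f]]) != nd, logical(1))]
  if (length(bad_len)) {
    stop("per-depth field(s) not matching the ", nd, " depth intervals: ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  fracs <- c("shoot_allocation", "frag_fraction")
  for (f in c(fracs, "true_clvr_fraction", "necromass_fraction")) {
    v <- cfg[[f]]
    if (any(v < 0 | v > 1)) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(cfg$true_clvr_fraction >= 1)) {
    stop("`true_clvr_fraction` must be < 1", call. = FALSE)
  }
  with(cfg$depths, {
    if (any(depth_top_cm >= depth_bottom_cm) ||
        is.unsorted(depth_top_cm, strictly = TRUE) ||
        any(depth_top_cm[-1] < depth_bottom_cm[-length(depth_bottom_cm)])) {
      stop("depth intervals must be sorted and non-overlapping", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Labeling-solution dose schedule
#'
#' Volume of labeling solution added at each pulse, following the
#' 5-mL-per-20-cm-of-plant-height rule: each started 20-cm increment of
#' height adds 5 mL, so the per-pulse volume is piecewise constant in
#' height.
#'
#' @param heights_cm Plant height at each pulse (cm); non-decreasing, within
#'   `[0, 150]`.
#' @return A tibble with `pulse`, `height_cm`, `volume_ml`; the experiment
#'   total is `sum(.$volume_ml)`.
#' @examples
#' sum(dose_schedule(rep(20, 4))$volume_ml)  # 20 mL
#' @export
dose_schedule <- function(heights_cm) {
  if (length(heights_cm) == 0L) {
    return(tibble::tibble(pulse = integer(), height_cm = numeric(),
                          volume_ml = numeric()))
  }
  if (any(heights_cm < 0 | heights_cm > 150)) {
    stop("plant heights must lie within [0, 150] cm", call. = FALSE)
  }
  if (is.unsorted(heights_cm)) {
    stop("plant heights must be non-decreasing across pulses", call. = FALSE)
  }
  tibble::tibble(pulse = seq_along(heights_cm), height_cm = heights_cm,
                 volume_ml = 5 * ceiling(heights_cm / 20))
}

plot_stream_seed <- function(seed, plot_index) {
  as.integer((as.numeric(seed) * 1009 + plot_index * 7919) %% 2147483563)
}

ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# compounds used by the generator, with within-class concentration weights
sim_compound_weights <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      compound = c("i15:0", "a15:0", "16:0", "16:1w7", "cy17:0",
                   "18:1w9", "18:2w6", "18:0"),
      biomarker_class = "PLFA",
      weight = c(0.10, 0.08, 0.25, 0.12, 0.08, 0.17, 0.10, 0.10)),
    tibble::tibble(
      compound = c("GlcN", "GalN", "MurN", "ManN"),
      biomarker_class = "AS",
      weight = c(0.55, 0.25, 0.12, 0.08)),
    tibble::tibble(
      compound = c("alanine", "Asx", "Glx", "glycine", "isoleucine",
                   "lysine", "phenylalanine", "Pro/Thr", "serine",
                   "tyrosine", "valine"),
      biomarker_class = "AA",
      weight = c(0.12, 0.11, 0.13, 0.10, 0.07, 0.08, 0.07, 0.12, 0.08,
                 0.05, 0.07)))
}

#' Forward-simulate the labeled field experiment
#'
#' Generates the two input tables the pipeline consumes — a compartment
#' sample table and a biomarker table — together with the ground truth they
#' encode. Pre-noise tracer pools are exact: running
#' [partition_rhizodeposition()] and [rms_profile()] on a `noise_cv = 0`,
#' `delta_noise_sd = 0` simulation recovers the configured true %ClvR, net
#' rhizodeposition and RMS to floating-point accuracy.
#'
#' Randomness is drawn from per-plot substreams derived deterministically
#' from the seed, so adding plots does not reshuffle existing ones, and the
#' user's RNG state is left untouched.
#'
#' @param config A [scenario_config()].
#' @param biomarkers Generate the biomarker table (default TRUE); skipping
#'   it speeds up replication studies that only exercise the mass balance.
#' @return An object of class `rhizo_simulation`: a list with `samples`
#'   (compartment rows incl. unlabeled backgrounds), `biomarkers`
#'   (compound x sample rows incl. analyte-scale backgrounds), `truth`
#'   (per plot x species x depth: `true_clvr_percent`,
#'   `true_net_rhizo_c_mg_per_kg`, `true_rms`), and `config`.
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 7))
#' names(sim)
#' @export
simulate_tracer_experiment <- function(config = scenario_config(),
                                       biomarkers = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  make_biomarkers <- isTRUE(biomarkers)
  cfg <- config
  nd <- nrow(cfg$depths)

  volume_ml <- sum(dose_schedule(cfg$pulse_heights_cm)$volume_ml)
  dose14 <- volume_ml * cfg$c14_bq_per_ml * (1 - cfg$shoot_allocation)
  dose13 <- volume_ml * cfg$c13_mg_per_ml * (1 - cfg$shoot_allocation)
  dose15 <- cfg$n15_dose_mg

  depth_tbl <- cfg$depths |>
    dplyr::mutate(
      f = cfg$true_clvr_fraction,
      root_c = cfg$root_c_mg_per_kg,
      w = cfg$depth_dose_weight / sum(cfg$depth_dose_weight),
      soil_c = cfg$soil_c_mg_per_g, soil_n = cfg$soil_n_mg_per_g,
      soil_kg = cfg$soil_mass_kg, nf = cfg$necromass_fraction,
      bfac = cfg$biomarker_depth_factor)

  split_b <- cfg$bulk_rhizosphere_split / (1 + cfg$bulk_rhizosphere_split)

  # expected (pre-noise) per-compartment quantities for one plot of one
  # species; identical across plots and species by construction
  pools <- depth_tbl |>
    dplyr::mutate(
      d14 = dose14 * .data$w, d13 = dose13 * .data$w, d15 = dose15 * .data$w,
      root14_tot = (1 - .data$f) * .data$d14,
      frag14 = cfg$frag_fraction * .data$root14_tot,
      root14 = .data$root14_tot - .data$frag14,
      bulk14 = .data$f * .data$d14 * split_b,
      rhiz14 = .data$f * .data$d14 * (1 - split_b),
      root13_tot = (1 - .data$f) * .data$d13,
      frag13 = cfg$frag_fraction * .data$root13_tot,
      root13 = .data$root13_tot - .data$frag13,
      bulk13 = .data$f * .data$d13 * split_b,
      rhiz13 = .data$f * .data$d13 * (1 - split_b),
      root15_tot = (1 - .data$f) * .data$d15,
      frag15 = cfg$frag_fraction * .data$root15_tot,
      root15 = .data$root15_tot - .data$frag15,
      bulk15 = .data$f * .data$d15 * split_b,
      rhiz15 = .data$f * .data$d15 * (1 - split_b),
      # compartment masses
      soil_g = .data$soil_kg * 1000,
      rhiz_g = 0.02 * .data$soil_g,
      root_c_mg = .data$root_c * .data$soil_kg,
      root_g = .data$root_c_mg / cfg$root_c_conc,
      frag_g_total = 0.08 * .data$root_g,
      sub_frac = cfg$subsample_mass_kg / .data$soil_kg)

  ap13 <- function(excess_mg, c_mg) {
    delta_to_atom_percent(cfg$background_d13c) + 100 * excess_mg / c_mg
  }
  ap15 <- function(excess_mg, n_mg) {
    delta_to_atom_percent(cfg$background_d15n, std_air_n2()) +
      100 * excess_mg / n_mg
  }

  comp_rows <- function(p) {
    with(p, dplyr::bind_rows(
      tibble::tibble(  # bulk soil: includes unrecovered fragments
        compartment = "bulk_soil", dry_mass_g = soil_g,
        soil_mass_kg = soil_kg, c_mg_per_g = soil_c, n_mg_per_g = soil_n,
        c14_bq_per_g = (bulk14 + frag14) / soil_g + cfg$background_activity,
        d13c_permil = atom_percent_to_delta(
          ap13(bulk13 + frag13, soil_c * soil_g)),
        d15n_permil = atom_percent_to_delta(
          ap15(bulk15 + frag15, soil_n * soil_g), std_air_n2())),
      tibble::tibble(
        compartment = "rhizosphere_soil", dry_mass_g = rhiz_g,
        soil_mass_kg = soil_kg, c_mg_per_g = soil_c * 1.2,
        n_mg_per_g = soil_n * 1.2,
        c14_bq_per_g = rhiz14 / rhiz_g + cfg$background_activity,
        d13c_permil = atom_percent_to_delta(
          ap13(rhiz13, soil_c * 1.2 * rhiz_g)),
        d15n_permil = atom_percent_to_delta(
          ap15(rhiz15, soil_n * 1.2 * rhiz_g), std_air_n2())),
      tibble::tibble(
        compartment = "root", dry_mass_g = root_g, soil_mass_kg = soil_kg,
        c_mg_per_g = cfg$root_c_conc, n_mg_per_g = cfg$root_n_conc,
        c14_bq_per_g = root14 / root_g + cfg$background_activity,
        d13c_permil = atom_percent_to_delta(
          ap13(root13, cfg$root_c_conc * root_g)),
        d15n_permil = atom_percent_to_delta(
          ap15(root15, cfg$root_n_conc * root_g), std_air_n2())),
      tibble::tibble(  # fragments washed from the subsample
        compartment = "root_fragment",
        dry_mass_g = frag_g_total * sub_frac,
        soil_mass_kg = cfg$subsample_mass_kg,
        c_mg_per_g = cfg$root_c_conc, n_mg_per_g = cfg$root_n_conc,
        c14_bq_per_g = frag14 * sub_frac / (frag_g_total * sub_frac) +
          cfg$background_activity,
        d13c_permil = atom_percent_to_delta(
          ap13(frag13 * sub_frac,
               cfg$root_c_conc * frag_g_total * sub_frac)),
        d15n_permil = atom_percent_to_delta(
          ap15(frag15 * sub_frac,
               cfg$root_n_conc * frag_g_total * sub_frac), std_air_n2()))
    ) |>
      dplyr::mutate(depth_top_cm = p$depth_top_cm,
                    depth_bottom_cm = p$depth_bottom_cm))
  }

  clean_depth_rows <- purrr::map(seq_len(nd),
                                 ~ comp_rows(pools[.x, ])) |>
    purrr::list_rbind()

  grid <- tidyr::expand_grid(plot_id = paste0("P", seq_len(cfg$n_plots)),
                             cfg$species)
  labeled <- dplyr::cross_join(grid, clean_depth_rows) |>
    dplyr::mutate(is_labeled = TRUE)

  backgrounds <- clean_depth_rows |>
    dplyr::mutate(
      plot_id = "background", species = "background", n_rate = NA_real_,
      is_labeled = FALSE,
      c14_bq_per_g = cfg$background_activity,
      d13c_permil = cfg$background_d13c,
      d15n_permil = cfg$background_d15n)

  # ---- biomarkers (rhizosphere soil) -----------------------------------
  ref <- biomarker_reference()
  wts <- sim_compound_weights() |>
    dplyr::left_join(ref, by = c("compound", "biomarker_class"))
  class_totals <- c(PLFA = cfg$plfa_total, AS = cfg$as_total,
                    AA = cfg$aa_total)
  class_bg_delta <- c(PLFA = -30, AS = -22, AA = -25)

  bio_depth <- function(p) {
    b <- wts |>
      dplyr::mutate(
        concentration_ug_per_g =
          unname(class_totals[.data$biomarker_class]) * p$bfac * .data$weight,
        c_content = .data$concentration_ug_per_g * .data$c_fraction)
    cls_c <- tapply(b$c_content, b$biomarker_class, sum)
    t_mic <- cfg$microbial_13c_fraction * (cls_c[["AS"]] + cls_c[["PLFA"]])
    ape_cls <- c(
      PLFA = 100 * (1 - p$nf) * t_mic / cls_c[["PLFA"]],
      AS = 100 * p$nf * t_mic / cls_c[["AS"]],
      AA = 50 * (1 - p$nf) * t_mic / cls_c[["AA"]])
    b |>
      dplyr::mutate(
        ape = unname(ape_cls[.data$biomarker_class]),
        bg_delta = unname(class_bg_delta[.data$biomarker_class]),
        d13c_analyte = atom_percent_to_delta(
          delta_to_atom_percent(.data$bg_delta) + .data$ape),
        depth_top_cm = p$depth_top_cm, depth_bottom_cm = p$depth_bottom_cm,
        true_ape_plfa = ape_cls[["PLFA"]], true_ape_as = ape_cls[["AS"]])
  }
  bio_clean <- purrr::map(seq_len(nd), ~ bio_depth(pools[.x, ])) |>
    purrr::list_rbind()

  # ---- noise, applied per plot substream --------------------------------
  noisy_plot_samples <- function(df, stream) {
    withr::with_seed(plot_stream_seed(cfg$seed, stream), {
      n <- nrow(df)
      df |>
        dplyr::mutate(
          dry_mass_g = .data$dry_mass_g * ln_noise(n, cfg$noise_cv),
          c_mg_per_g = .data$c_mg_per_g * ln_noise(n, cfg$noise_cv),
          n_mg_per_g = .data$n_mg_per_g * ln_noise(n, cfg$noise_cv),
          c14_bq_per_g = .data$c14_bq_per_g * ln_noise(n, cfg$noise_cv),
          d13c_permil = .data$d13c_permil +
            stats::rnorm(n, 0, cfg$delta_noise_sd),
          d15n_permil = .data$d15n_permil +
            stats::rnorm(n, 0, cfg$delta_noise_sd))
    })
  }
  noisy_plot_bio <- function(df, stream) {
    withr::with_seed(plot_stream_seed(cfg$seed, 10000 + stream), {
      n <- nrow(df)
      df |>
        dplyr::mutate(
          concentration_ug_per_g =
            .data$concentration_ug_per_g * ln_noise(n, cfg$noise_cv),
          d13c_measured = .data$d13c_measured +
            stats::rnorm(n, 0, cfg$delta_noise_sd),
          d13c_background = .data$d13c_background +
            stats::rnorm(n, 0, cfg$delta_noise_sd))
    })
  }

  plot_number <- function(df) as.integer(sub("^P", "", df$plot_id[1]))
  samples <- labeled |>
    dplyr::group_split(.data$plot_id) |>
    purrr::map(~ noisy_plot_samples(.x, plot_number(.x))) |>
    purrr::list_rbind() |>
    dplyr::bind_rows(noisy_plot_samples(backgrounds, 0L)) |>
    dplyr::select("plot_id", "species", "n_rate", "depth_top_cm",
                  "depth_bottom_cm", "compartment", "dry_mass_g",
                  "soil_mass_kg", "c_mg_per_g", "n_mg_per_g", "d13c_permil",
                  "d15n_permil", "c14_bq_per_g", "is_labeled")

  bio_tbl <- NULL
  if (make_biomarkers) {
  bio_tbl <- dplyr::cross_join(grid, bio_clean) |>
    dplyr::mutate(
      sample_id = paste(.data$plot_id, .data$species, .data$n_rate,
                        .data$depth_top_cm, sep = "_"),
      matrix = "rhizosphere_soil",
      d13c_reagent = cfg$delta_reagent,
      # forward derivatization dilution, then instrument artifacts
      d13c_deriv = (.data$n_carbon_analyte * .data$d13c_analyte +
                      .data$n_carbon_added * .data$d13c_reagent) /
        (.data$n_carbon_analyte + .data$n_carbon_added),
      peak_amount = pmax(.data$concentration_ug_per_g * 0.1, 1e-3)) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::mutate(run_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      d13c_measured = .data$d13c_deriv + cfg$instrument_offset +
        cfg$instrument_drift * .data$run_index +
        cfg$instrument_amount_slope * log(.data$peak_amount),
      d13c_background = .data$bg_delta)

  bio_tbl <- bio_tbl |>
    dplyr::group_split(.data$plot_id) |>
    purrr::map(~ noisy_plot_bio(.x, plot_number(.x))) |>
    purrr::list_rbind() |>
    dplyr::select("sample_id", "plot_id", "species", "n_rate",
                  "depth_top_cm", "depth_bottom_cm", "matrix", "compound",
                  "biomarker_class", "concentration_ug_per_g",
                  "d13c_measured", "d13c_background", "d13c_reagent",
                  "run_index", "peak_amount")
  }

  truth <- grid |>
    tidyr::expand_grid(
      depth_tbl |>
        dplyr::transmute(
          .data$depth_top_cm, .data$depth_bottom_cm,
          true_clvr_percent = 100 * .data$f,
          true_net_rhizo_c_mg_per_kg =
            .data$f / (1 - .data$f) * .data$root_c,
          true_root_c_mg_per_kg = .data$root_c)) |>
    dplyr::left_join(
      bio_clean |>
        dplyr::distinct(.data$depth_top_cm, .data$true_ape_plfa,
                        .data$true_ape_as) |>
        dplyr::mutate(true_rms = log10(.data$true_ape_as /
                                         .data$true_ape_plfa)) |>
        dplyr::select("depth_top_cm", "true_rms"),
      by = "depth_top_cm")

  structure(list(samples = samples, biomarkers = bio_tbl, truth = truth,
                 config = cfg),
            class = "rhizo_simulation")
}

#' @export
print.rhizo_simulation <- function(x, ...) {
  cat(sprintf(
    "<rhizo_simulation> %d sample rows, %d biomarker rows, seed %d, noise_cv %.3f\n",
    nrow(x$samples), nrow(x$biomarkers), x$config$seed, x$config$noise_cv))
  invisible(x)
}
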