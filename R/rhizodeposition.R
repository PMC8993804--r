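#' Root carbon concentration in sampled soil
#'
#' Root C per kg of sampled soil: root dry matter times its C concentration,
#' divided by the quantity of soil the roots were recovered from.
#'
#' @param root_dry_matter_g Root dry matter recovered from the sample (g).
#' @param c_mg_per_g Root C concentration (mg C per g dry root).
#' @param soil_mass_kg Quantity of soil sampled (kg); must be positive.
#' @param sample_id Optional identifiers for error messages.
#' @return Root C in mg C per kg soil.
#' @examples
#' root_c_concentration(2, 400, 4)  # 200 mg C kg-1 soil
#' @export
root_c_concentration <- function(root_dry_matter_g, c_mg_per_g, soil_mass_kg,
                                 sample_id = NULL) {
  bad <- !is.na(soil_mass_kg) & soil_mass_kg <= 0
  if (any(bad)) {
    stop(oob_message("soil_mass_kg", soil_mass_kg, bad, sample_id,
                     "must be positive"), call. = FALSE)
  }
  root_dry_matter_g * c_mg_per_g / soil_mass_kg
}

#' Tracer content of unrecovered root fragments, scaled to the full sample
#'
#' Root fragments are washed out of a subsample of the bulk soil; their
#' tracer content is scaled up to the entire soil volume sampled by the
#' soil-mass ratio. Works for 14C (enrichment in Bq per g fragment) and for
#' any per-gram excess currency.
#'
#' @param fragment_enrichment Tracer excess per g dry fragment (e.g. Bq/g).
#' @param fragment_dry_mass_g Dry mass of fragments recovered from the
#'   subsample (g).
#' @param subsample_mass_kg Mass of the washed soil subsample (kg).
#' @param full_sample_mass_kg Mass of the entire soil sample (kg); must be at
#'   least `subsample_mass_kg`.
#' @return Tracer content attributable to fragments in the whole sample (in
#'   the enrichment unit times grams, e.g. Bq).
#' @examples
#' # fragments from a 0.15 kg subsample of a 1.5 kg sample: scaled 10x
#' fragment_tracer_content(2, 25, 0.15, 1.5)
#' @export
fragment_tracer_content <- function(fragment_enrichment, fragment_dry_mass_g,
                                    subsample_mass_kg, full_sample_mass_kg) {
  if (any(subsample_mass_kg <= 0, na.rm = TRUE)) {
    stop("`subsample_mass_kg` must be positive", call. = FALSE)
  }
  if (any(subsample_mass_kg > full_sample_mass_kg, na.rm = TRUE)) {
    stop("washed subsample mass exceeds the full sample mass", call. = FALSE)
  }
  fragment_enrichment * fragment_dry_mass_g *
    (full_sample_mass_kg / subsample_mass_kg)
}

#' Adjusted bulk-soil tracer content
#'
#' The bulk-soil tracer pool minus the pool attributable to unrecovered root
#' fragments washed from it. A negative difference (fragment content larger
#' than bulk content, a sign of measurement noise) is clamped to zero with a
#' warning reporting the deficit, unless `clamp = FALSE`.
#'
#' @param bulk Bulk-soil tracer content (e.g. Bq).
#' @param fragments Fragment tracer content scaled to the same soil volume.
#' @param clamp Clamp negative differences to zero (default) or preserve them.
#' @return Adjusted bulk tracer content.
#' @examples
#' adjusted_bulk_tracer(100, 30)
#' @export
adjusted_bulk_tracer <- function(bulk, fragments, clamp = TRUE) {
  out <- bulk - fragments
  neg <- !is.na(out) & out < 0
  if (any(neg) && clamp) {
    warning(sprintf(
      "adjusted bulk tracer negative in %d case(s); clamped to 0 (max deficit %.4g)",
      sum(neg), max(-out[neg])), call. = FALSE)
    out[neg] <- 0
  }
  out
}

#' Percent carbon lost via rhizodeposition (%ClvR)
#'
#' The share of recovered belowground tracer found in soil rather than roots:
#' \deqn{\%ClvR = 100 \times \frac{^{14}C_{rhizosphere} + {}^{14}C_{bulk,adj}}
#'   {^{14}C_{bulk} + {}^{14}C_{rhizosphere} + {}^{14}C_{root}}.}
#' By default the denominator uses the *adjusted* bulk pool and counts the
#' fragment tracer as part of the root pool, so that the soil share plus the
#' root share sum exactly to the denominator (mass conservation). With
#' `strict_literal = TRUE` the denominator is the *raw* bulk pool plus
#' rhizosphere plus the root pool (root plus washed fragments), the literal
#' printed form; because the raw bulk pool still contains the fragment
#' tracer, that denominator counts fragments twice and gives a slightly
#' smaller %ClvR.
#'
#' @param rhizosphere Rhizosphere-soil tracer content (e.g. Bq).
#' @param bulk Raw bulk-soil tracer content.
#' @param root Root tracer content (recovered roots, excluding fragments).
#' @param fragments Fragment tracer content scaled to the full sample
#'   (default 0).
#' @param strict_literal Use the literal published denominator (see Details).
#' @param clamp Passed to [adjusted_bulk_tracer()].
#' @param sample_id Optional identifiers for error messages.
#' @return Percent ClvR in `[0, 100)`.
#' @examples
#' percent_clvr(rhizosphere = 5, bulk = 15, root = 80)  # 20 %
#' @export
percent_clvr <- function(rhizosphere, bulk, root, fragments = 0,
                         strict_literal = FALSE, clamp = TRUE,
                         sample_id = NULL) {
  adj <- adjusted_bulk_tracer(bulk, fragments, clamp = clamp)
  soil <- rhizosphere + adj
  denom <- if (strict_literal) {
    bulk + rhizosphere + root + fragments
  } else {
    adj + rhizosphere + root + fragments
  }
  bad <- !is.na(denom) & denom <= 0
  if (any(bad)) {
    stop(oob_message("tracer denominator", denom, bad, sample_id,
                     "must be positive (no tracer recovered)"), call. = FALSE)
  }
  100 * soil / denom
}

#' Net rhizodeposition from %ClvR and root carbon
#'
#' \deqn{Net = \frac{\%ClvR \times root\ C}{100 - \%ClvR}.}
#' The identity `net / (net + root_c) == clvr / 100` holds exactly.
#'
#' @param clvr Percent C lost via rhizodeposition, in `[0, 100)`.
#' @param root_c Root C content (mg C per kg soil).
#' @param sample_id Optional identifiers for error messages.
#' @return Net rhizodeposited C, mg C per kg soil.
#' @examples
#' net_rhizodeposition(20, 800)  # 200
#' @export
net_rhizodeposition <- function(clvr, root_c, sample_id = NULL) {
  bad <- !is.na(clvr) & (clvr < 0 | clvr >= 100)
  if (any(bad)) {
    stop(oob_message("clvr", clvr, bad, sample_id,
                     "must lie in [0, 100)"), call. = FALSE)
  }
  clvr * root_c / (100 - clvr)
}

#' Convert a soil concentration to an area-based stock
#'
#' `conc` (mg per kg soil) times bulk density (g cm-3) times layer thickness
#' (cm) gives, after unit expansion over one hectare (1 ha = 1e8 cm2), a
#' stock in Mg per ha: `conc * bd * thickness * 1e-4`.
#'
#' @param conc Concentration in mg per kg soil.
#' @param bulk_density_g_cm3 Soil bulk density (g cm-3); must be positive.
#' @param depth_top_cm,depth_bottom_cm Layer bounds in cm.
#' @return Stock in Mg per ha.
#' @examples
#' concentration_to_area_stock(1000, 1.5, 0, 25)  # 3.75 Mg ha-1
#' @export
concentration_to_area_stock <- function(conc, bulk_density_g_cm3,
                                        depth_top_cm, depth_bottom_cm) {
  if (anyNA(bulk_density_g_cm3)) {
    stop("missing bulk density for depth(s): ",
         paste(unique(paste0(depth_top_cm[is.na(bulk_density_g_cm3)], "-",
                             depth_bottom_cm[is.na(bulk_density_g_cm3)])),
               collapse = ", "), call. = FALSE)
  }
  if (any(bulk_density_g_cm3 <= 0)) {
    stop("bulk density must be positive", call. = FALSE)
  }
  thickness <- depth_bottom_cm - depth_top_cm
  if (any(thickness <= 0)) stop("depth interval must have positive thickness",
                                call. = FALSE)
  conc * bulk_density_g_cm3 * thickness * 1e-4
}

# Compartment tracer pools, one row per plot x species x depth group:
# 14C (Bq) and 15N (mg 15N excess) of each compartment plus root C and N
# concentrations. Vectorized over all groups at once.
compute_tracer_pools <- function(lab, keys) {
  dup <- lab |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "compartment")))) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate compartment rows: ",
         paste(utils::head(paste0(dup$compartment, " for plot ", dup$plot_id,
                                  " depth ", dup$depth_top_cm, "-",
                                  dup$depth_bottom_cm), 5), collapse = "; "),
         call. = FALSE)
  }
  wide <- lab |>
    dplyr::select(dplyr::all_of(c(
      keys, "compartment", "dry_mass_g", "soil_mass_kg", "c_mg_per_g",
      "n_mg_per_g", "d15n_permil", "bg_d15n_permil", "c14_bq_per_g",
      "bg_c14_bq_per_g"))) |>
    tidyr::pivot_wider(
      names_from = "compartment",
      values_from = !dplyr::all_of(c(keys, "compartment")))
  for (comp in c("bulk_soil", "rhizosphere_soil", "root")) {
    col <- paste0("dry_mass_g_", comp)
    if (!col %in% names(wide) || anyNA(wide[[col]])) {
      bad <- if (!col %in% names(wide)) wide else wide[is.na(wide[[col]]), ]
      stop("missing ", comp, " compartment for plot ",
           paste(utils::head(paste0(bad$plot_id, " depth ", bad$depth_top_cm,
                                    "-", bad$depth_bottom_cm), 5),
                 collapse = "; "), call. = FALSE)
    }
  }
  has_frag <- "dry_mass_g_root_fragment" %in% names(wide)
  if (!has_frag) {
    for (col in c("dry_mass_g_root_fragment", "soil_mass_kg_root_fragment",
                  "n_mg_per_g_root_fragment", "d15n_permil_root_fragment",
                  "bg_d15n_permil_root_fragment",
                  "c14_bq_per_g_root_fragment",
                  "bg_c14_bq_per_g_root_fragment")) {
      wide[[col]] <- NA_real_
    }
  }
  frag_ok <- !is.na(wide$dry_mass_g_root_fragment)

  id <- paste0(wide$plot_id, "/", wide$depth_top_cm, "-",
               wide$depth_bottom_cm)
  exc14 <- function(comp) {
    c14_excess(wide[[paste0("c14_bq_per_g_", comp)]],
               wide[[paste0("bg_c14_bq_per_g_", comp)]])
  }
  # 15N atom% excess per compartment; NA-tolerant (N channel is optional)
  ape15 <- function(comp) {
    d <- wide[[paste0("d15n_permil_", comp)]]
    b <- wide[[paste0("bg_d15n_permil_", comp)]]
    ok <- !is.na(d) & !is.na(b)
    out <- rep(NA_real_, length(d))
    if (any(ok)) {
      out[ok] <- atom_percent_excess(d[ok], b[ok], std_air_n2())
    }
    out
  }
  frag14 <- rep(0, nrow(wide))
  frag15 <- rep(0, nrow(wide))
  if (any(frag_ok)) {
    frag14[frag_ok] <- fragment_tracer_content(
      exc14("root_fragment")[frag_ok],
      wide$dry_mass_g_root_fragment[frag_ok],
      wide$soil_mass_kg_root_fragment[frag_ok],
      wide$soil_mass_kg_bulk_soil[frag_ok])
    f15 <- ape15("root_fragment") / 100 *
      wide$n_mg_per_g_root_fragment * wide$dry_mass_g_root_fragment *
      (wide$soil_mass_kg_bulk_soil / wide$soil_mass_kg_root_fragment)
    frag15[frag_ok] <- f15[frag_ok]
  }
  tibble::tibble(
    wide[keys],
    sample_ref = id,
    c14_bulk_bq = exc14("bulk_soil") * wide$soil_mass_kg_bulk_soil * 1000,
    c14_rhizosphere_bq = exc14("rhizosphere_soil") *
      wide$dry_mass_g_rhizosphere_soil,
    c14_root_bq = exc14("root") * wide$dry_mass_g_root,
    c14_fragments_bq = frag14,
    n15_bulk_mg = ape15("bulk_soil") / 100 * wide$n_mg_per_g_bulk_soil *
      wide$soil_mass_kg_bulk_soil * 1000,
    n15_rhizosphere_mg = ape15("rhizosphere_soil") / 100 *
      wide$n_mg_per_g_rhizosphere_soil * wide$dry_mass_g_rhizosphere_soil,
    n15_root_mg = ape15("root") / 100 * wide$n_mg_per_g_root *
      wide$dry_mass_g_root,
    n15_fragments_mg = frag15,
    root_c_mg_per_kg = root_c_concentration(
      wide$dry_mass_g_root, wide$c_mg_per_g_root, wide$soil_mass_kg_root,
      id),
    root_n_mg_per_kg = wide$dry_mass_g_root * wide$n_mg_per_g_root /
      wide$soil_mass_kg_root)
}

#' Partition belowground tracer into root carbon and net rhizodeposition
#'
#' The core mass-balance stage. For every plot x species x depth group it
#' forms the compartment tracer pools (bulk soil referenced to the full soil
#' quantity sampled; root fragments washed from a subsample scaled up by the
#' soil-mass ratio), adjusts the bulk pool for fragments, and computes %ClvR,
#' root C, and net rhizodeposited C. When delta-15N readings are present the
#' same algebra is run on mg-15N-excess pools to give the N analog.
#'
#' @param samples A data frame of compartment samples, one row per plot x
#'   species x depth x compartment, with columns `plot_id`, `species`,
#'   `n_rate`, `depth_top_cm`, `depth_bottom_cm`, `compartment` (one of
#'   `bulk_soil`, `rhizosphere_soil`, `root`, `root_fragment`), `dry_mass_g`,
#'   `soil_mass_kg`, `c_mg_per_g`, `n_mg_per_g`, `d13c_permil`,
#'   `d15n_permil`, `c14_bq_per_g`, `is_labeled`. Unlabeled rows
#'   (`is_labeled = FALSE`) are the natural-abundance backgrounds, matched to
#'   labeled rows by depth interval and compartment.
#' @param strict_literal Use the literal published %ClvR denominator; see
#'   [percent_clvr()].
#' @param clamp Clamp negative adjusted bulk pools to zero (default TRUE).
#' @param bulk_density Optional data frame with `depth_top_cm`,
#'   `depth_bottom_cm`, `bulk_density_g_cm3`; when supplied, Mg ha-1 stocks
#'   are appended.
#' @return A tibble with one row per plot x species x n_rate x depth:
#'   `clvr_percent`, `root_c_mg_per_kg`, `net_rhizo_c_mg_per_kg`,
#'   `clvr_n_percent`, `net_rhizo_n_mg_per_kg`, and (with `bulk_density`)
#'   `root_c_mg_ha`, `net_rhizo_c_mg_ha`.
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 1, noise_cv = 0))
#' partition_rhizodeposition(sim$samples)
#' @export
partition_rhizodeposition <- function(samples, strict_literal = FALSE,
                                      clamp = TRUE, bulk_density = NULL) {
  lab <- match_backgrounds(samples)
  keys <- c("plot_id", "species", "n_rate", "depth_top_cm", "depth_bottom_cm")
  pools <- compute_tracer_pools(lab, keys)

  out <- pools |>
    dplyr::mutate(
      clvr_percent = percent_clvr(
        .data$c14_rhizosphere_bq, .data$c14_bulk_bq, .data$c14_root_bq,
        .data$c14_fragments_bq, strict_literal = strict_literal,
        clamp = clamp, sample_id = .data$sample_ref),
      net_rhizo_c_mg_per_kg = net_rhizodeposition(
        .data$clvr_percent, .data$root_c_mg_per_kg, .data$sample_ref),
      clvr_n_percent = ifelse(
        is.na(.data$n15_bulk_mg) | is.na(.data$n15_rhizosphere_mg) |
          is.na(.data$n15_root_mg),
        NA_real_,
        percent_clvr(.data$n15_rhizosphere_mg, .data$n15_bulk_mg,
                     .data$n15_root_mg, .data$n15_fragments_mg,
                     strict_literal = strict_literal, clamp = clamp,
                     sample_id = .data$sample_ref)),
      net_rhizo_n_mg_per_kg = ifelse(
        is.na(.data$clvr_n_percent), NA_real_,
        net_rhizodeposition(dplyr::coalesce(.data$clvr_n_percent, 0),
                            .data$root_n_mg_per_kg))
    ) |>
    dplyr::select(-"sample_ref") |>
    dplyr::arrange(.data$species, .data$n_rate, .data$plot_id,
                   .data$depth_top_cm)

  if (!is.null(bulk_density)) {
    out <- out |>
      dplyr::left_join(bulk_density,
                       by = c("depth_top_cm", "depth_bottom_cm")) |>
      dplyr::mutate(
        root_c_mg_ha = concentration_to_area_stock(
          .data$root_c_mg_per_kg, .data$bulk_density_g_cm3,
          .data$depth_top_cm, .data$depth_bottom_cm),
        net_rhizo_c_mg_ha = concentration_to_area_stock(
          .data$net_rhizo_c_mg_per_kg, .data$bulk_density_g_cm3,
          .data$depth_top_cm, .data$depth_bottom_cm))
  }
  out
}

# Attach background readings (bg_* columns) to labeled rows, matching
# unlabeled rows by depth interval and compartment (averaged if replicated).
match_backgrounds <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!is.logical(samples$is_labeled)) {
    samples$is_labeled <- as.logical(samples$is_labeled)
  }
  bg <- samples |>
    dplyr::filter(!.data$is_labeled) |>
    dplyr::group_by(.data$depth_top_cm, .data$depth_bottom_cm,
                    .data$compartment) |>
    dplyr::summarise(
      bg_d13c_permil = mean(.data$d13c_permil, na.rm = TRUE),
      bg_d15n_permil = mean(.data$d15n_permil, na.rm = TRUE),
      bg_c14_bq_per_g = mean(.data$c14_bq_per_g, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("bg_"),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
  lab <- samples |>
    dplyr::filter(.data$is_labeled) |>
    dplyr::left_join(bg, by = c("depth_top_cm", "depth_bottom_cm",
                                "compartment"))
  unmatched <- lab |>
    dplyr::filter(is.na(.data$bg_c14_bq_per_g) & is.na(.data$bg_d13c_permil))
  if (nrow(unmatched) > 0L) {
    stop("no background reading for ",
         paste(unique(paste0(unmatched$compartment, " at ",
                             unmatched$depth_top_cm, "-",
                             unmatched$depth_bottom_cm, " cm")),
               collapse = "; "), call. = FALSE)
  }
  lab
}
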