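# Builders for tiny hand-checkable inputs used across tests.

# One plot x one depth sample set with known pools:
# bulk excess 15 Bq (raw bulk pool includes 3 Bq of fragments -> 18 raw),
# rhizosphere 5 Bq, root 80 Bq, fragments 3 Bq; root C = 200 mg/kg.
tiny_samples <- function() {
  bg_act <- 0.2
  soil_kg <- 2
  frag_sub_kg <- 0.2
  row <- function(compartment, dry_g, soil_kg_row, c_mg, n_mg, act, d13c,
                  d15n, labeled) {
    tibble::tibble(
      plot_id = if (labeled) "P1" else "BG", species = "lucerne", n_rate = 0,
      depth_top_cm = 0, depth_bottom_cm = 25, compartment = compartment,
      dry_mass_g = dry_g, soil_mass_kg = soil_kg_row, c_mg_per_g = c_mg,
      n_mg_per_g = n_mg, d13c_permil = d13c, d15n_permil = d15n,
      c14_bq_per_g = act, is_labeled = labeled)
  }
  dplyr::bind_rows(
    # bulk: pool (15 + 3 fragments) Bq over 2 kg => excess 0.009 Bq/g
    row("bulk_soil", 2000, soil_kg, 12, 1.2, 18 / 2000 + bg_act, -26, 6, TRUE),
    # rhizosphere: 5 Bq over 50 g => excess 0.1 Bq/g
    row("rhizosphere_soil", 50, soil_kg, 14, 1.4, 5 / 50 + bg_act, -25, 6.5,
        TRUE),
    # root: 80 Bq over 1 g root; 1 g x 400 mg/g / 2 kg = 200 mg C/kg
    row("root", 1, soil_kg, 400, 12, 80 / 1 + bg_act, -20, 8, TRUE),
    # fragments: washed from 0.2 of 2 kg; subsample pool 0.3 Bq over 0.05 g
    row("root_fragment", 0.05, frag_sub_kg, 400, 12, 0.3 / 0.05 + bg_act,
        -20, 8, TRUE),
    row("bulk_soil", 2000, soil_kg, 12, 1.2, bg_act, -27, 5, FALSE),
    row("rhizosphere_soil", 50, soil_kg, 14, 1.4, bg_act, -27, 5, FALSE),
    row("root", 1, soil_kg, 400, 12, bg_act, -27, 5, FALSE),
    row("root_fragment", 0.05, frag_sub_kg, 400, 12, bg_act, -27, 5, FALSE))
}

# Expected results for tiny_samples(): soil = 5 + (18 - 3) = 20 Bq,
# denominator = 15 + 5 + 80 + 3 = 103 Bq.
tiny_expected_clvr <- 100 * 20 / 103

# Minimal biomarker input: compounds with chosen analyte APEs and carbon
# contents; measured deltas are forward-diluted with the reference
# derivatization carbons so correct_biomarkers() must invert them.
tiny_biomarkers <- function(ape = c(2, 0.4), conc_c = c(10, 30),
                            compounds = c("16:0", "18:0"),
                            class = "PLFA", reagent = -40) {
  ref <- biomarker_reference()
  i <- match(compounds, ref$compound)
  cf <- ref$c_fraction[i]
  na <- ref$n_carbon_analyte[i]
  nd <- ref$n_carbon_added[i]
  bg <- -28
  d_analyte <- atom_percent_to_delta(delta_to_atom_percent(bg) + ape)
  tibble::tibble(
    sample_id = "S1", compound = compounds, biomarker_class = class,
    matrix = "rhizosphere_soil",
    concentration_ug_per_g = conc_c / cf,
    d13c_measured = (na * d_analyte + nd * reagent) / (na + nd),
    d13c_background = bg, d13c_reagent = reagent)
}

noise_free_config <- function(seed = 1, ...) {
  scenario_config(seed = seed, noise_cv = 0, delta_noise_sd = 0, ...)
}
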