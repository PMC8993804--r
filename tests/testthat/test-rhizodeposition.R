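test_that("root C concentration follows the dry-matter x concentration rule", {
  expect_equal(root_c_concentration(0, 350, 5), 0)
  expect_equal(root_c_concentration(2, 400, 4), 200)
  # doubling the soil quantity halves the concentration
  expect_equal(root_c_concentration(2, 400, 8),
               root_c_concentration(2, 400, 4) / 2)
  expect_error(root_c_concentration(2, 400, 0, sample_id = "P1/0-25"),
               "P1/0-25")
})

test_that("fragment tracer scales from subsample to full sample by mass", {
  expect_equal(fragment_tracer_content(2, 25, 1.5, 1.5), 2 * 25)
  expect_equal(fragment_tracer_content(2, 25, 0.15, 1.5),
               10 * fragment_tracer_content(2, 25, 1.5, 1.5))
  expect_error(fragment_tracer_content(2, 25, 2, 1.5), "exceeds")
})

test_that("adjusted bulk subtracts fragments and clamps with a warning", {
  expect_equal(adjusted_bulk_tracer(100, 0), 100)
  expect_equal(adjusted_bulk_tracer(100, 30), 70)
  expect_warning(out <- adjusted_bulk_tracer(100, 120), "clamped")
  expect_equal(out, 0)
  expect_equal(suppressWarnings(adjusted_bulk_tracer(100, 120,
                                                     clamp = FALSE)), -20)
})

test_that("%ClvR matches the hand-computed mass balance", {
  expect_equal(percent_clvr(0, 0, 80), 0)
  # soil total equals root total -> 50 %
  expect_equal(percent_clvr(10, 40, 50), 50)
  # rhizosphere 5, adjusted bulk 15, root 80 -> 100 x 20/100
  expect_equal(percent_clvr(5, 15, 80), 20)
  expect_error(percent_clvr(0, 0, 0, sample_id = "x"), "x")
})

test_that("%ClvR is scale invariant and monotone in rhizosphere tracer", {
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- stats::runif(4, 0.1, 100)  # rhizo, bulk, root, frag (frag < bulk)
      p[4] <- p[4] * 0.01
      base <- percent_clvr(p[1], p[2], p[3], p[4])
      k <- stats::runif(1, 0.01, 50)
      expect_equal(percent_clvr(k * p[1], k * p[2], k * p[3], k * p[4]),
                   base, tolerance = 1e-12)
      expect_gt(percent_clvr(p[1] * 1.1, p[2], p[3], p[4]), base)
    }
  })
})

test_that("strict-literal mode reproduces the printed denominator", {
  # conserving: (5 + 15)/(15 + 5 + 80 + 3); literal keeps the raw bulk pool
  # in the denominator and so counts the 3 Bq of fragments twice
  expect_equal(percent_clvr(5, 18, 80, fragments = 3), 100 * 20 / 103)
  expect_equal(percent_clvr(5, 18, 80, fragments = 3, strict_literal = TRUE),
               100 * 20 / 106)
  expect_lt(percent_clvr(5, 18, 80, fragments = 3, strict_literal = TRUE),
            percent_clvr(5, 18, 80, fragments = 3))
  # without fragments the two modes coincide
  expect_equal(percent_clvr(5, 15, 80, strict_literal = TRUE),
               percent_clvr(5, 15, 80))
})

test_that("net rhizodeposition identity net/(net + root) = clvr/100 holds", {
  expect_equal(net_rhizodeposition(0, 500), 0)
  expect_equal(net_rhizodeposition(50, 100), 100)
  expect_equal(net_rhizodeposition(20, 800), 200)
  withr::with_seed(41, {
    clvr <- stats::runif(100, 0, 99.9)
    root <- stats::runif(100, 0, 2000)
    net <- net_rhizodeposition(clvr, root)
    expect_equal(net / (net + root), clvr / 100, tolerance = 1e-12)
  })
  expect_error(net_rhizodeposition(100, 10), "\\[0, 100\\)")
})

test_that("area stocks agree with an explicit dimensional expansion", {
  # 1000 mg/kg x BD 1.5 g/cm3 x 25 cm over 1 ha = 1e8 cm2:
  # soil mass per ha = 1.5 * 25 * 1e8 g = 3.75e9 g = 3.75e6 kg
  # stock = 1000 mg/kg * 3.75e6 kg = 3.75e9 mg = 3.75 Mg
  expect_equal(concentration_to_area_stock(1000, 1.5, 0, 25), 3.75)
  expect_equal(concentration_to_area_stock(0, 1.5, 0, 25), 0)
  expect_equal(concentration_to_area_stock(1000, 1.5, 0, 50),
               2 * concentration_to_area_stock(1000, 1.5, 0, 25))
  expect_error(concentration_to_area_stock(1, NA, 25, 50), "25-50")
})

test_that("the partition stage reproduces hand-computed pools end to end", {
  part <- partition_rhizodeposition(tiny_samples())
  expect_equal(nrow(part), 1L)
  expect_equal(part$clvr_percent, tiny_expected_clvr, tolerance = 1e-9)
  expect_equal(part$root_c_mg_per_kg, 200, tolerance = 1e-12)
  expect_equal(part$net_rhizo_c_mg_per_kg,
               tiny_expected_clvr * 200 / (100 - tiny_expected_clvr),
               tolerance = 1e-9)
})

test_that("partition errors name missing compartments and duplicates", {
  s <- tiny_samples()
  expect_error(partition_rhizodeposition(
    s[!(s$compartment == "root" & s$is_labeled), ]), "missing root")
  expect_error(partition_rhizodeposition(
    dplyr::bind_rows(s, s[s$compartment == "bulk_soil" & s$is_labeled, ])),
    "duplicate")
  expect_error(partition_rhizodeposition(
    s[!(s$compartment == "bulk_soil" & !s$is_labeled), ]), "background")
})

test_that("bulk-density tables append Mg/ha stocks", {
  bd <- tibble::tibble(depth_top_cm = 0, depth_bottom_cm = 25,
                       bulk_density_g_cm3 = 1.4)
  part <- partition_rhizodeposition(tiny_samples(), bulk_density = bd)
  expect_equal(part$root_c_mg_ha,
               concentration_to_area_stock(part$root_c_mg_per_kg, 1.4, 0, 25))
})

test_that("the 15N path reuses the mass-balance algebra", {
  part <- partition_rhizodeposition(tiny_samples())
  # N pools are hand-recomputable: ape15 x N mass per compartment
  ape15 <- function(d) atom_percent_excess(d, 5, std_air_n2())
  n_bulk <- ape15(6) / 100 * 1.2 * 2000
  n_rhiz <- ape15(6.5) / 100 * 1.4 * 50
  n_root <- ape15(8) / 100 * 12 * 1
  n_frag <- ape15(8) / 100 * 12 * 0.05 * (2 / 0.2)
  expect_equal(part$clvr_n_percent,
               100 * (n_rhiz + n_bulk - n_frag) / (n_bulk + n_rhiz + n_root),
               tolerance = 1e-9)
  # when the N channel is absent the N columns are NA, the C path unaffected
  s <- tiny_samples()
  s$d15n_permil <- NA_real_
  part2 <- partition_rhizodeposition(s)
  expect_true(is.na(part2$clvr_n_percent))
  expect_equal(part2$clvr_percent, part$clvr_percent)
})
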