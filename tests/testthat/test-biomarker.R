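test_that("derivatization dilution correction inverts the mixing balance", {
  expect_equal(correct_derivatization_dilution(-30, 16, 0), -30)
  expect_equal(correct_derivatization_dilution(-30, 16, 1, -30), -30)
  # (17 x (-30) - 1 x (-40)) / 16
  expect_equal(correct_derivatization_dilution(-30, 16, 1, -40), -29.375)
  expect_error(correct_derivatization_dilution(-30, 0, 1, -40), "n_analyte")
  expect_error(correct_derivatization_dilution(-30, 16, 2), "delta_reagent")
})

test_that("forward dilution then correction round-trips to 1e-9 permil", {
  withr::with_seed(52, {
    n <- 200
    na <- sample(1:30, n, replace = TRUE)
    nd <- sample(0:12, n, replace = TRUE)
    d_analyte <- stats::runif(n, -60, 800)
    d_reagent <- stats::runif(n, -55, -20)
    d_mix <- (na * d_analyte + nd * d_reagent) / (na + nd)
    expect_equal(correct_derivatization_dilution(d_mix, na, nd, d_reagent),
                 d_analyte, tolerance = 1e-9)
  })
})

test_that("delta-scale and exact atom-fraction dilution agree closely at
           natural abundance", {
  d <- correct_derivatization_dilution(-30, 16, 1, -40)
  d2 <- correct_derivatization_dilution(-30, 16, 1, -40,
                                        scale = "atom_fraction")
  expect_lt(abs(d - d2), 0.01)
})

test_that("instrument correction recovers injected offset, drift and
           amount dependence", {
  cal0 <- tibble::tibble(true_d13c = rep(c(-30, -25, -20), 3),
                         measured_d13c = rep(c(-30, -25, -20), 3),
                         run_index = 1:9,
                         amount = rep(c(5, 20, 60), each = 3))
  m0 <- fit_instrument_correction(cal0)
  expect_equal(m0$offset, 0, tolerance = 1e-12)
  expect_equal(m0$drift_slope, 0, tolerance = 1e-12)
  expect_equal(m0$amount_slope, 0, tolerance = 1e-12)

  # constant bias only
  cal1 <- dplyr::mutate(cal0, measured_d13c = true_d13c + 0.5)
  m1 <- fit_instrument_correction(cal1)
  expect_equal(m1$offset, 0.5, tolerance = 1e-10)
  expect_equal(m1$drift_slope, 0, tolerance = 1e-10)

  # injected drift and amount effects, recovered by the least-squares fit
  withr::with_seed(61, {
    cal2 <- tibble::tibble(
      true_d13c = rep(-25, 40), run_index = 1:40,
      amount = stats::runif(40, 2, 80))
    cal2$measured_d13c <- cal2$true_d13c + 0.3 + 0.02 * cal2$run_index -
      0.05 * log(cal2$amount) + stats::rnorm(40, 0, 0.01)
    m2 <- fit_instrument_correction(cal2)
    expect_lt(abs(m2$offset - 0.3), 0.05)
    expect_lt(abs(m2$drift_slope - 0.02), 0.002)
    expect_lt(abs(m2$amount_slope - (-0.05)), 0.02)
    # correction reduces the residual spread of its own calibration
    g <- glance(m2)
    expect_lt(g$sd_corrected, g$sd_uncorrected)
  })

  expect_error(fit_instrument_correction(
    dplyr::mutate(cal0, amount = 10)), "amount")
})

test_that("corrections compose in the fixed order: instrument first,
           then dilution", {
  m <- fit_instrument_correction(
    tibble::tibble(true_d13c = c(-30, -20, -25, -28),
                   measured_d13c = c(-29.5, -19.5, -24.5, -27.5),
                   run_index = 1:4, amount = c(5, 10, 20, 40)))
  rec <- tibble::tibble(
    sample_id = "s", compound = "16:0", biomarker_class = "PLFA",
    matrix = "rhizosphere_soil", concentration_ug_per_g = 10,
    d13c_measured = -30, d13c_background = -28.5, d13c_reagent = -40,
    run_index = 3, peak_amount = 12)
  out <- correct_biomarkers(rec, correction = m)
  # golden sequence: subtract instrument error, then unmix the methyl carbon
  step1 <- -30 - m$offset - m$drift_slope * 3 - m$amount_slope * log(12)
  step2 <- (17 * step1 - 1 * (-40)) / 16
  expect_equal(out$d13c_instrument, step1, tolerance = 1e-12)
  expect_equal(out$d13c_corrected, step2, tolerance = 1e-12)
  # identity model leaves the measured value for the dilution step
  out0 <- correct_biomarkers(rec)
  expect_equal(out0$d13c_instrument, -30)
})

test_that("13C incorporation is APE times compound carbon", {
  expect_equal(biomarker_13c_incorporation(-28, -28, 100, 0.5), 0)
  expect_equal(biomarker_13c_incorporation(-10, -28, 0, 0.5), 0)
  # APE 0.5 atom% on 10 ug C/g -> 0.05 ug 13C/g
  d <- atom_percent_to_delta(delta_to_atom_percent(-28) + 0.5)
  expect_equal(biomarker_13c_incorporation(d, -28, 20, 0.5), 0.05,
               tolerance = 1e-12)
})

test_that("pool summaries compute carbon-weighted atom percent excess", {
  # two compounds, C 10 and 30 ug/g, APE 2 and 0.4 -> weighted 0.8
  out <- summarize_pools(correct_biomarkers(tiny_biomarkers()))
  expect_equal(nrow(out), 1L)
  expect_equal(out$total_c_ug_per_g, 40, tolerance = 1e-9)
  expect_equal(out$weighted_ape, 0.8, tolerance = 1e-6)

  # single compound: weighted APE equals the compound APE
  one <- summarize_pools(correct_biomarkers(
    tiny_biomarkers(ape = 1.3, conc_c = 5, compounds = "16:0")))
  expect_equal(one$weighted_ape, 1.3, tolerance = 1e-6)

  # equal carbon, APE 1 and 3 -> 2
  eq <- summarize_pools(correct_biomarkers(
    tiny_biomarkers(ape = c(1, 3), conc_c = c(10, 10))))
  expect_equal(eq$weighted_ape, 2, tolerance = 1e-6)
})

test_that("pool totals are additive, permutation invariant, and weighted APE
           is convex", {
  withr::with_seed(71, {
    for (i in 1:10) {
      ape <- stats::runif(4, 0.05, 3)
      cc <- stats::runif(4, 1, 50)
      recs <- tiny_biomarkers(ape = ape, conc_c = cc,
                              compounds = c("16:0", "18:0", "16:1w7",
                                            "18:2w6"))
      pool <- summarize_pools(correct_biomarkers(recs))
      shuffled <- summarize_pools(correct_biomarkers(
        recs[sample(nrow(recs)), ]))
      expect_equal(pool$weighted_ape, shuffled$weighted_ape)
      expect_gte(pool$weighted_ape, min(ape) - 1e-9)
      expect_lte(pool$weighted_ape, max(ape) + 1e-9)
      # additivity under concatenation of two record sets
      a <- correct_biomarkers(recs[1:2, ])
      b <- correct_biomarkers(recs[3:4, ])
      both <- summarize_pools(dplyr::bind_rows(a, b))
      expect_equal(both$total_c_ug_per_g,
                   summarize_pools(a)$total_c_ug_per_g +
                     summarize_pools(b)$total_c_ug_per_g)
    }
  })
})

test_that("panel membership is enforced and backgrounds are required", {
  bad <- tiny_biomarkers(compounds = c("16:0", "18:0"))
  bad$biomarker_class <- "AS"
  expect_error(correct_biomarkers(bad), "AS panel")
  miss <- tiny_biomarkers()
  miss$d13c_background[1] <- NA
  expect_error(correct_biomarkers(miss), "background")
  unk <- tiny_biomarkers()
  unk$compound[1] <- "C99:9"
  expect_error(correct_biomarkers(unk), "reference table")
  expect_error(summarize_pools(correct_biomarkers(tiny_biomarkers())[0, ]),
               "absent pool")
})

test_that("the bundled reference covers the fixed AS and AA panels", {
  ref <- biomarker_reference()
  expect_setequal(ref$compound[ref$biomarker_class == "AS"],
                  c("GlcN", "GalN", "MurN", "ManN"))
  expect_length(ref$compound[ref$biomarker_class == "AA"], 11L)
  expect_true(all(ref$c_fraction > 0 & ref$c_fraction < 1))
  expect_true(all(ref$n_carbon_analyte >= 1))
})
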