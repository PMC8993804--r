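test_that("assumption checks pass clean data and trigger the log transform
           under heteroscedasticity", {
  withr::with_seed(91, {
    clean <- data.frame(g = rep(c("a", "b", "c"), each = 10),
                        y = stats::rnorm(30, 10, 1))
    res <- check_assumptions(clean, "y", "g")
    expect_gt(res$fligner_p, 0.05)
    expect_equal(res$transform, "none")
    # one group scaled x100: variance heterogeneity forces the transform
    het <- clean
    het$y[het$g == "c"] <- het$y[het$g == "c"] * 100
    res2 <- check_assumptions(het, "y", "g")
    expect_equal(res2$transform, "log")
    # non-positive values block the required transform with advice
    het$y[1] <- 0
    expect_error(check_assumptions(het, "y", "g"), "offset")
  })
  expect_error(check_assumptions(
    data.frame(g = "a", y = 1), "y", "g"), "2 groups")
})

test_that("identical groups give F near 0 and p near 1; separated groups are
           detected by Tukey", {
  d <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(c(1, 2, 3, 4), 2))
  fit <- compare_groups(d, "y", "g", transform = "none")
  expect_lt(tidy(fit)$statistic[1], 1e-20)
  expect_gt(tidy(fit)$p_value[1], 0.999)
  expect_equal(unique(tidy(fit, "letters")$letters), "a")

  withr::with_seed(101, {
    sep <- data.frame(g = rep(c("lo", "hi"), each = 3),
                      y = c(stats::rnorm(3, 1, 0.1), stats::rnorm(3, 20, 0.1)))
    fit2 <- compare_groups(sep, "y", "g", transform = "none")
    expect_lt(tidy(fit2, "tukey")$adj_p_value, 0.05)
    expect_equal(sort(tidy(fit2, "letters")$letters), c("a", "b"))
  })
  expect_error(compare_groups(data.frame(g = "a", y = 1:3), "y", "g"),
               "single level")
})

# Raw (unadjusted) pairwise p from the same model fit: pooled MSE, residual
# df — the quantity the Tukey studentized-range adjustment acts on.
raw_pairwise_p <- function(fit, pairs, data, group_col, response_col) {
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  dfres <- stats::df.residual(fit)
  vapply(seq_len(nrow(pairs)), function(k) {
    na <- sum(data[[group_col]] == pairs$group_a[k])
    nb <- sum(data[[group_col]] == pairs$group_b[k])
    se <- sqrt(mse * (1 / na + 1 / nb))
    2 * stats::pt(-abs(pairs$estimate[k]) / se, dfres)
  }, numeric(1))
}

test_that("Tukey-adjusted p-values are never smaller than the raw pairwise p", {
  withr::with_seed(111, {
    for (i in 1:5) {
      d <- data.frame(g = rep(letters[1:4], each = 5),
                      y = stats::rnorm(20, 10, 2))
      fit <- compare_groups(d, "y", "g", transform = "none")
      pairs <- tidy(fit, "tukey")
      raw <- raw_pairwise_p(fit$fit, pairs, d, "g", "y")
      expect_true(all(pairs$adj_p_value >= raw - 1e-10))
    }
  })
})

test_that("compact letters agree with the multcomp reference implementation", {
  withr::with_seed(121, {
    for (i in 1:4) {
      d <- data.frame(g = factor(rep(letters[1:4], each = 5)),
                      y = stats::rnorm(20, rep(c(0, 0.5, 3, 10), each = 5)))
      fit <- compare_groups(d, "y", "g", transform = "none")
      ours <- tidy(fit, "letters")
      glht <- multcomp::glht(stats::aov(y ~ g, d),
                             linfct = multcomp::mcp(g = "Tukey"))
      theirs <- multcomp::cld(glht)$mcletters$Letters
      # same partition: groups share a letter with us iff they do in multcomp
      share <- function(lets, a, b) {
        any(strsplit(lets[a], "")[[1]] %in% strsplit(lets[b], "")[[1]])
      }
      ours_named <- stats::setNames(ours$letters, ours$group)
      for (a in levels(d$g)) for (b in levels(d$g)) {
        if (a < b) {
          expect_equal(share(ours_named, a, b),
                       share(theirs, a, b),
                       info = paste("pair", a, b, "iter", i))
        }
      }
    }
  })
})

test_that("two-factor ANOVA reports species, depth, and interaction terms", {
  sim <- simulate_tracer_experiment(scenario_config(seed = 8))
  part <- partition_rhizodeposition(sim$samples) |>
    dplyr::mutate(depth = paste0(depth_top_cm, "-", depth_bottom_cm))
  fit <- compare_groups(part, "net_rhizo_c_mg_per_kg", c("species", "depth"),
                        tukey_factor = "depth")
  terms <- tidy(fit)$term
  expect_true(all(c("species", "depth", "species:depth") %in% terms))
  expect_equal(nrow(tidy(fit, "tukey")), choose(4, 2))
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("the merge rule averages indistinguishable kernza subplots and
           refuses separated ones", {
  sim <- simulate_tracer_experiment(scenario_config(seed = 12))
  part <- partition_rhizodeposition(sim$samples)
  merged <- merge_kernza(part, c("clvr_percent", "net_rhizo_c_mg_per_kg"))
  expect_true(attr(merged, "merged"))
  # exactly one kernza row per plot x depth after merging
  kz <- merged[merged$species == "kernza", ]
  expect_equal(nrow(kz), 3 * 4)
  expect_true(all(is.na(kz$n_rate)))
  # merged values are the subplot means
  k100 <- part[part$species == "kernza" & part$n_rate == 100, ]
  k200 <- part[part$species == "kernza" & part$n_rate == 200, ]
  key <- function(d) paste(d$plot_id, d$depth_top_cm)
  expect_equal(kz$clvr_percent[order(key(kz))],
               ((k100$clvr_percent[order(key(k100))] +
                   k200$clvr_percent[order(key(k200))]) / 2))

  # idempotent: merging again changes nothing
  again <- merge_kernza(merged, c("clvr_percent", "net_rhizo_c_mg_per_kg"))
  expect_false(attr(again, "merged"))
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(merged),
               ignore_attr = TRUE)

  # a strongly separated variable blocks the merge
  sep <- part
  sep$clvr_percent[sep$species == "kernza" & sep$n_rate == 200] <-
    sep$clvr_percent[sep$species == "kernza" & sep$n_rate == 200] + 50
  not_merged <- merge_kernza(sep, "clvr_percent")
  expect_false(attr(not_merged, "merged"))
  expect_true(any(attr(not_merged, "merge_report")$differs))
  expect_equal(nrow(not_merged), nrow(sep))

  # unpaired subplots are an error naming the plot
  unpaired <- part[!(part$plot_id == "P2" & part$n_rate == 200 &
                       part$depth_top_cm == 0), ]
  expect_error(merge_kernza(unpaired, "clvr_percent"), "P2")
})
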