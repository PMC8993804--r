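#' Check ANOVA assumptions and decide on a log transform
#'
#' Runs the Fligner-Killeen test of homogeneity of variances across the
#' factor-level groups and the Shapiro-Wilk test of normality on the
#' residuals from the group means. When either test rejects at `alpha` the
#' response is log-transformed, provided all values are strictly positive;
#' otherwise an error points the user at offset handling.
#'
#' @param data A data frame.
#' @param response Name of the response column (string).
#' @param factors Character vector of grouping factor columns.
#' @param alpha Significance level for the assumption tests (default 0.05).
#' @param enforce_positive Error when the checks demand a log transform that
#'   non-positive values make impossible (default TRUE); [compare_groups()]
#'   disables this when the caller overrides the transform decision.
#' @return A list with `fligner_p`, `shapiro_p`, `transform` (`"none"` or
#'   `"log"`), and `alpha`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 5),
#'                 y = c(rnorm(5, 10), rnorm(5, 12)))
#' check_assumptions(d, "y", "g")
#' @export
check_assumptions <- function(data, response, factors, alpha = 0.05,
                              enforce_positive = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)))
  y <- data[[response]]
  grp <- interaction(data[factors], drop = TRUE)
  if (nlevels(grp) < 2L) {
    stop("assumption checks need at least 2 groups", call. = FALSE)
  }
  if (min(table(grp)) < 2L) {
    stop("assumption checks need at least 2 observations per group",
         call. = FALSE)
  }
  fligner_p <- stats::fligner.test(y, grp)$p.value
  if (is.na(fligner_p)) fligner_p <- 1  # degenerate: no within-group spread
  resid <- y - stats::ave(y, grp)
  shapiro_p <- if (stats::sd(resid) == 0) 1 else stats::shapiro.test(resid)$p.value
  transform <- if (fligner_p < alpha || shapiro_p < alpha) "log" else "none"
  if (enforce_positive && transform == "log" && any(y <= 0)) {
    stop("log transform required by the assumption checks but the response ",
         "has non-positive values; add an offset or rescale before calling",
         call. = FALSE)
  }
  list(fligner_p = fligner_p, shapiro_p = shapiro_p, transform = transform,
       alpha = alpha)
}

#' ANOVA with Tukey HSD pairwise comparisons
#'
#' The treatment-comparison stage: checks assumptions (optionally
#' log-transforming the response), fits a fixed-effects ANOVA of the
#' response on the crossed factors, and runs the Tukey HSD post-hoc test on
#' one factor, attaching compact-letter-display group letters at `alpha`.
#'
#' @inheritParams check_assumptions
#' @param tukey_factor Factor for the pairwise comparisons; defaults to the
#'   first of `factors`.
#' @param transform `"auto"` (decide from the assumption checks), `"none"`,
#'   or `"log"`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `rhizo_comparison`; see [tidy.rhizo_comparison()]
#'   and [glance.rhizo_comparison()].
#' @examples
#' d <- expand.grid(species = c("lucerne", "kernza"), plot = 1:3)
#' d$y <- rnorm(nrow(d), mean = ifelse(d$species == "lucerne", 10, 14), sd = 1)
#' fit <- compare_groups(d, "y", "species")
#' tidy(fit)
#' @export
compare_groups <- function(data, response, factors,
                           tukey_factor = factors[1],
                           transform = c("auto", "none", "log"),
                           alpha = 0.05) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)), tukey_factor %in% factors)
  data <- as.data.frame(data)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L) {
      stop("factor `", f, "` has a single level", call. = FALSE)
    }
  }
  assumptions <- check_assumptions(data, response, factors, alpha,
                                   enforce_positive = transform == "auto")
  applied <- switch(transform, auto = assumptions$transform, transform)
  if (applied == "log" && any(data[[response]] <= 0)) {
    stop("log transform requested but the response has non-positive values",
         call. = FALSE)
  }
  data$.y <- if (applied == "log") log(data[[response]]) else data[[response]]
  rhs <- paste(factors, collapse = " * ")
  fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = data)
  an <- as.data.frame(summary(fit)[[1]])
  an_tbl <- tibble::tibble(
    term = trimws(rownames(an)),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`)
  tk <- stats::TukeyHSD(fit, which = tukey_factor)[[tukey_factor]]
  pairs <- tibble::tibble(
    contrast = rownames(tk),
    group_a = sub("-.*$", "", rownames(tk)),
    group_b = sub("^[^-]*-", "", rownames(tk)),
    estimate = tk[, "diff"], conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"], adj_p_value = tk[, "p adj"])
  means <- tapply(data$.y, data[[tukey_factor]], mean)
  letters_tbl <- cld_letters(names(means), means, pairs, alpha)
  structure(list(
    response = response, factors = factors, tukey_factor = tukey_factor,
    transform_applied = applied, assumptions = assumptions, alpha = alpha,
    anova = an_tbl, tukey = pairs, letters = letters_tbl, fit = fit),
    class = "rhizo_comparison")
}

# Compact letter display by insert-and-absorb over the significant pairs.
cld_letters <- function(groups, means, pairs, alpha) {
  ord <- groups[order(-means)]
  sets <- list(ord)  # start: one letter containing every group
  sig <- pairs[!is.na(pairs$adj_p_value) & pairs$adj_p_value < alpha, ,
               drop = FALSE]
  if (nrow(sig) > 0) {
    for (k in seq_len(nrow(sig))) {
      a <- sig$group_a[k]; b <- sig$group_b[k]
      new_sets <- list()
      for (s in sets) {
        if (all(c(a, b) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another
      keep <- vapply(seq_along(new_sets), function(i) {
        !any(vapply(seq_along(new_sets), function(j) {
          i != j && all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[j]]) > length(new_sets[[i]]) || j < i)
        }, logical(1)))
      }, logical(1))
      sets <- unique(new_sets[keep])
    }
  }
  # order letters by the best (highest-mean) group they contain
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first_pos)]
  lab <- vapply(ord, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = ord, mean = unname(means[ord]),
                 letters = unname(lab))
}

#' @export
print.rhizo_comparison <- function(x, ...) {
  cat(sprintf("<rhizo_comparison> %s ~ %s (transform: %s)\n",
              x$response, paste(x$factors, collapse = " * "),
              x$transform_applied))
  print(x$anova)
  cat("Tukey HSD on", x$tukey_factor, "\n")
  print(x$letters)
  invisible(x)
}

#' Merge kernza fertilizer subplots when they do not differ
#'
#' The two kernza fertilizer rates (100 and 200 kg N ha-1) are subplots
#' within each field plot. When none of the requested variables differs
#' significantly between the two rates (paired by plot and depth), the
#' subplot values are averaged within each field plot and the merged rows
#' carry the plain `"kernza"` label with `n_rate = NA`. When any variable
#' separates, the table is returned unchanged and flagged. The operation is
#' idempotent: merging a merged table is a no-op.
#'
#' @param data A data frame with `species`, `n_rate`, `plot_id` and the
#'   variables; extra id columns (depths) are respected as pairing keys.
#' @param variables Character vector of measurement columns to test and
#'   merge.
#' @param alpha Significance level for the per-variable paired tests.
#' @return The (possibly merged) tibble, with attributes `merged` (logical)
#'   and `merge_report` (per-variable tibble of p-values and decisions).
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 2))
#' part <- partition_rhizodeposition(sim$samples)
#' merged <- merge_kernza(part, c("clvr_percent", "net_rhizo_c_mg_per_kg"))
#' attr(merged, "merge_report")
#' @export
merge_kernza <- function(data, variables, alpha = 0.05) {
  stopifnot(is.data.frame(data), all(variables %in% names(data)),
            all(c("species", "n_rate", "plot_id") %in% names(data)))
  k <- data[data$species == "kernza" & data$n_rate %in% c(100, 200), ,
            drop = FALSE]
  if (nrow(k) == 0L) {  # already merged (or no kernza subplots): no-op
    out <- tibble::as_tibble(data)
    attr(out, "merged") <- FALSE
    attr(out, "merge_report") <- tibble::tibble(
      variable = variables, p_value = NA_real_, differs = NA)
    return(out)
  }
  keys <- intersect(c("plot_id", "depth_top_cm", "depth_bottom_cm"),
                    names(data))
  wide_check <- k |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$n_rate) |>
    tidyr::pivot_wider(names_from = "n_rate", values_from = "n")
  if (anyNA(wide_check) || any(wide_check$`100` != wide_check$`200`)) {
    bad <- wide_check[!stats::complete.cases(wide_check), , drop = FALSE]
    stop("unpaired kernza subplots for plot(s): ",
         paste(utils::head(unique(c(bad$plot_id, wide_check$plot_id[
           wide_check$`100` != wide_check$`200`])), 5), collapse = ", "),
         call. = FALSE)
  }
  report <- purrr::map(variables, function(v) {
    wide <- k |>
      dplyr::select(dplyr::all_of(c(keys, "n_rate", v))) |>
      tidyr::pivot_wider(names_from = "n_rate", values_from = dplyr::all_of(v))
    d <- wide$`100` - wide$`200`
    p <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
    tibble::tibble(variable = v, p_value = p, differs = p < alpha)
  }) |> purrr::list_rbind()
  if (any(report$differs)) {
    out <- tibble::as_tibble(data)
    attr(out, "merged") <- FALSE
    attr(out, "merge_report") <- report
    return(out)
  }
  merged_rows <- k |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("species", keys)))) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                     !dplyr::any_of("n_rate"), mean),
                     .groups = "drop") |>
    dplyr::mutate(n_rate = NA_real_)
  out <- data |>
    dplyr::filter(!(.data$species == "kernza" &
                      .data$n_rate %in% c(100, 200))) |>
    dplyr::bind_rows(merged_rows) |>
    dplyr::arrange(.data$species, dplyr::across(dplyr::all_of(keys))) |>
    tibble::as_tibble()
  attr(out, "merged") <- TRUE
  attr(out, "merge_report") <- report
  out
}
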