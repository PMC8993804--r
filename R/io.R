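compartment_aliases <- c(
  "bulk_soil" = "bulk_soil", "bulk soil" = "bulk_soil", "bulk" = "bulk_soil",
  "rhizosphere_soil" = "rhizosphere_soil",
  "rhizosphere soil" = "rhizosphere_soil",
  "rhizosphere" = "rhizosphere_soil",
  "root" = "root", "roots" = "root",
  "root_fragment" = "root_fragment", "root fragment" = "root_fragment",
  "root fragments" = "root_fragment", "washed_root" = "root_fragment",
  "washed root" = "root_fragment")

normalize_compartment <- function(x) {
  key <- gsub("[ -]+", " ", trimws(tolower(x)))
  key <- ifelse(key %in% names(compartment_aliases), key,
                gsub(" ", "_", key))
  out <- unname(compartment_aliases[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown compartment value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (row ", paste(utils::head(which(bad), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

sample_schema <- c("plot_id", "species", "n_rate", "depth_top_cm",
                   "depth_bottom_cm", "compartment", "dry_mass_g",
                   "soil_mass_kg", "c_mg_per_g", "n_mg_per_g",
                   "d13c_permil", "d15n_permil", "c14_bq_per_g",
                   "is_labeled")

#' Read and validate a compartment sample table
#'
#' Reads the samples CSV (units are encoded in the column names; `#` lines
#' are provenance comments), normalizes compartment spelling variants,
#' validates signs and domains with row-level diagnostics, and reports
#' labeled rows that have no unlabeled background at their depth and
#' compartment as an `unmatched` attribute.
#'
#' @param path Path to a CSV file with the columns listed in
#'   [partition_rhizodeposition()].
#' @return A validated tibble of samples; attribute `unmatched` lists
#'   labeled rows without a background.
#' @export
read_samples <- function(path) {
  # base parser: correctly-rounded doubles, so written files re-read losslessly
  df <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(sample_schema, names(df))
  if (length(missing_cols)) {
    stop("samples file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("samples file has a header but no data rows", call. = FALSE)
    return(tibble::as_tibble(df))
  }
  df$compartment <- normalize_compartment(df$compartment)
  df$is_labeled <- as.logical(df$is_labeled)
  check_nonneg <- function(col) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      stop("negative ", col, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("dry_mass_g", "soil_mass_kg", "c_mg_per_g", "n_mg_per_g",
                "c14_bq_per_g")) check_nonneg(col)
  bad_delta <- which(!is.na(df$d13c_permil) & df$d13c_permil <= -1000)
  if (length(bad_delta)) {
    stop("d13c_permil out of domain (<= -1000) at data row(s) ",
         paste(utils::head(bad_delta, 5), collapse = ", "), call. = FALSE)
  }
  lab <- df[df$is_labeled, , drop = FALSE]
  bgk <- unique(df[!df$is_labeled,
                   c("depth_top_cm", "depth_bottom_cm", "compartment")])
  unmatched <- dplyr::anti_join(
    lab, bgk, by = c("depth_top_cm", "depth_bottom_cm", "compartment"))
  if (nrow(unmatched)) {
    warning(nrow(unmatched),
            " labeled row(s) have no background at their depth/compartment",
            call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "unmatched") <- tibble::as_tibble(unmatched)
  out
}

#' Read and validate a biomarker table
#'
#' @param path Path to a CSV with the columns listed in
#'   [correct_biomarkers()].
#' @return A validated tibble of biomarker records.
#' @export
read_biomarkers <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  req <- c("sample_id", "compound", "biomarker_class",
           "concentration_ug_per_g", "d13c_measured")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("biomarker file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$concentration_ug_per_g) &
                 df$concentration_ug_per_g < 0)
  if (length(bad)) {
    stop("negative concentration at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a result table with a provenance header
#'
#' Plain CSV preceded by `#`-commented provenance lines (package version,
#' seed, configuration hash) so every output is self-describing and
#' re-reads cleanly through [read_samples()] / [readr::read_csv()] with
#' `comment = "#"`. Numeric columns are written at full precision, so a
#' write-read round trip is lossless.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @param config Optional configuration object; hashed into the header.
#' @return `path`, invisibly.
#' @export
write_provenance_csv <- function(x, path, seed = NULL, config = NULL) {
  header <- c(
    sprintf("# rhizotrace %s", as.character(utils::packageVersion("rhizotrace"))),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    if (!is.null(config)) sprintf("# config_hash: %s", rlang::hash(config)))
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full belowground carbon-accounting pipeline
#'
#' Composes the stages in order — tracer partition, biomarker correction,
#' pool summaries, RMS profile, and the treatment comparison — on a sample
#' table and a biomarker table. With identical inputs and options the
#' result is identical; no stage draws randomness.
#'
#' @param samples Compartment sample table (see
#'   [partition_rhizodeposition()]).
#' @param biomarkers Biomarker record table (see [correct_biomarkers()]),
#'   or `NULL` to skip the biomarker stages.
#' @param correction A `csia_correction` for the instrument stage.
#' @param strict_literal,clamp,bulk_density Passed to
#'   [partition_rhizodeposition()].
#' @param log_base Passed to [rms_profile()].
#' @param compare_variables Variables for [merge_kernza()] and
#'   [compare_groups()]; defaults to the main partition outputs.
#' @param alpha Significance level for the statistical stage.
#' @return A list of class `rhizo_run`: `partition`, `biomarkers_corrected`,
#'   `pools`, `rms`, `merged`, `comparisons`.
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 3))
#' run <- run_rhizo_pipeline(sim$samples, sim$biomarkers)
#' run$rms
#' @export
run_rhizo_pipeline <- function(samples, biomarkers = NULL,
                               correction = identity_correction(),
                               strict_literal = FALSE, clamp = TRUE,
                               bulk_density = NULL, log_base = 10,
                               compare_variables =
                                 c("clvr_percent", "net_rhizo_c_mg_per_kg"),
                               alpha = 0.05) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  partition <- stage("partition", partition_rhizodeposition(
    samples, strict_literal = strict_literal, clamp = clamp,
    bulk_density = bulk_density))
  corrected <- pools <- rms <- NULL
  if (!is.null(biomarkers)) {
    corrected <- stage("csia", correct_biomarkers(biomarkers, correction))
    pools <- stage("pools", summarize_pools(corrected))
    rms <- stage("rms", rms_profile(pools, log_base = log_base))
  }
  merged <- stage("merge", merge_kernza(partition, compare_variables,
                                        alpha = alpha))
  comparisons <- purrr::map(compare_variables, function(v) {
    stage(paste0("compare:", v),
          compare_groups(merged |> dplyr::mutate(
            depth = paste0(.data$depth_top_cm, "-", .data$depth_bottom_cm)),
            v, c("species", "depth"), alpha = alpha))
  })
  names(comparisons) <- compare_variables
  structure(list(partition = partition, biomarkers_corrected = corrected,
                 pools = pools, rms = rms, merged = merged,
                 comparisons = comparisons),
            class = "rhizo_run")
}

#' @export
print.rhizo_run <- function(x, ...) {
  cat("<rhizo_run>\n")
  cat(" partition:", nrow(x$partition), "plot x species x depth rows\n")
  if (!is.null(x$rms)) cat(" rms:", nrow(x$rms), "values\n")
  cat(" merged kernza subplots:", isTRUE(attr(x$merged, "merged")), "\n")
  invisible(x)
}
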