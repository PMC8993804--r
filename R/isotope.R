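#' Reference isotope standards
#'
#' An isotope reference standard is described by its heavy/light isotope
#' abundance ratio. `iso_standard()` builds one; `std_vpdb()` and
#' `std_air_n2()` return the two standards used throughout: Vienna PeeDee
#' Belemnite for carbon and atmospheric N2 for nitrogen. The ratios are the
#' conventional values \eqn{R_{VPDB} = 0.0111802} and
#' \eqn{R_{air} = 0.0036765}; both can be overridden by constructing a custom
#' standard.
#'
#' @param name Identifier of the standard.
#' @param isotope_ratio Heavy/light isotope abundance ratio; must be positive.
#' @return An object of class `iso_standard`.
#' @examples
#' std_vpdb()
#' delta_to_atom_percent(0, std_vpdb())
#' @export
iso_standard <- function(name, isotope_ratio) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(isotope_ratio) || length(isotope_ratio) != 1L ||
      !is.finite(isotope_ratio) || isotope_ratio <= 0) {
    stop("`isotope_ratio` must be a single positive number", call. = FALSE)
  }
  structure(list(name = name, isotope_ratio = isotope_ratio),
            class = "iso_standard")
}

#' @rdname iso_standard
#' @export
std_vpdb <- function() iso_standard("VPDB", 0.0111802)

#' @rdname iso_standard
#' @export
std_air_n2 <- function() iso_standard("air-N2", 0.0036765)

#' @export
print.iso_standard <- function(x, ...) {
  cat(sprintf("<iso_standard> %s (R = %.7f)\n", x$name, x$isotope_ratio))
  invisible(x)
}

ratio_of <- function(standard) {
  if (inherits(standard, "iso_standard")) return(standard$isotope_ratio)
  if (is.numeric(standard) && length(standard) == 1L && standard > 0) {
    return(standard)
  }
  stop("`standard` must be an iso_standard or a positive ratio", call. = FALSE)
}

#' Convert between delta notation and atom percent
#'
#' `delta_to_atom_percent()` maps a per-mil delta value against a reference
#' standard onto the atom-percent scale (0-100),
#' \deqn{AP = 100 \, \frac{R(\delta/1000 + 1)}{1 + R(\delta/1000 + 1)},}
#' where \eqn{R} is the standard's heavy/light ratio.
#' `atom_percent_to_delta()` is the exact inverse. Both are vectorized and
#' strictly monotone on their domains.
#'
#' @param delta Delta values in per-mil; must exceed -1000 (the atom fraction
#'   is zero at exactly -1000).
#' @param ap Atom percent values, strictly inside (0, 100).
#' @param standard An [iso_standard] (or a bare positive ratio). Defaults to
#'   VPDB.
#' @param sample_id Optional identifiers used in error messages when a value
#'   is out of domain.
#' @return Numeric vector: atom percent, or per-mil delta.
#' @examples
#' delta_to_atom_percent(-27)              # typical C3 background, ~1.076
#' atom_percent_to_delta(delta_to_atom_percent(500))
#' @export
delta_to_atom_percent <- function(delta, standard = std_vpdb(),
                                  sample_id = NULL) {
  r <- ratio_of(standard)
  bad <- !is.na(delta) & delta <= -1000
  if (any(bad)) {
    stop(oob_message("delta", delta, bad, sample_id,
                     "must be > -1000 per-mil"), call. = FALSE)
  }
  rp <- r * (delta / 1000 + 1)
  100 * rp / (1 + rp)
}

#' @rdname delta_to_atom_percent
#' @export
atom_percent_to_delta <- function(ap, standard = std_vpdb(),
                                  sample_id = NULL) {
  r <- ratio_of(standard)
  bad <- !is.na(ap) & (ap <= 0 | ap >= 100)
  if (any(bad)) {
    stop(oob_message("ap", ap, bad, sample_id,
                     "must lie strictly inside (0, 100)"), call. = FALSE)
  }
  rp <- ap / (100 - ap)
  1000 * (rp / r - 1)
}

oob_message <- function(what, values, bad, sample_id, rule) {
  idx <- which(bad)
  lab <- if (!is.null(sample_id)) sample_id[idx] else idx
  sprintf("%s %s: %s (got %s)", what, rule,
          paste0("sample ", paste(utils::head(lab, 5L), collapse = ", ")),
          paste(signif(values[idx][seq_len(min(5L, length(idx)))], 6),
                collapse = ", "))
}

#' Isotopic enrichment against an unlabeled background
#'
#' `atom_percent_excess()` returns the atom-percent difference between a
#' labeled and an unlabeled delta reading against the same standard.
#' `c14_excess()` is the radiocarbon analog on the activity scale: the
#' difference in 14C activity (Bq per g dry sample) between labeled and
#' background material. Negative excess (labeled below background) is
#' preserved, never clamped; use [flag_below_background()] to flag it.
#'
#' @param delta_labeled,delta_background Per-mil delta of the labeled sample
#'   and of its unlabeled background.
#' @inheritParams delta_to_atom_percent
#' @param activity_labeled,activity_background 14C activities in Bq per g dry
#'   sample; both must be non-negative.
#' @return Numeric vector of excess: atom percent for
#'   `atom_percent_excess()`, Bq per g for `c14_excess()`.
#' @examples
#' atom_percent_excess(0, -27)   # positive excess of a labeled sample
#' c14_excess(30, 10)
#' @export
atom_percent_excess <- function(delta_labeled, delta_background,
                                standard = std_vpdb(), sample_id = NULL) {
  if (anyNA(delta_labeled) || anyNA(delta_background)) {
    stop("missing delta reading: both labeled and background values are required",
         call. = FALSE)
  }
  delta_to_atom_percent(delta_labeled, standard, sample_id) -
    delta_to_atom_percent(delta_background, standard, sample_id)
}

#' @rdname atom_percent_excess
#' @export
c14_excess <- function(activity_labeled, activity_background) {
  if (anyNA(activity_labeled) || anyNA(activity_background)) {
    stop("missing 14C activity: both labeled and background values are required",
         call. = FALSE)
  }
  if (any(activity_labeled < 0) || any(activity_background < 0)) {
    stop("14C activities must be non-negative", call. = FALSE)
  }
  activity_labeled - activity_background
}

#' @rdname atom_percent_excess
#' @param excess Numeric vector of excess values.
#' @export
flag_below_background <- function(excess) {
  !is.na(excess) & excess < 0
}

#' Tracer mass carried by a carbon pool
#'
#' The mass of excess 13C in a pool is its carbon content multiplied by its
#' atom-percent 13C excess over 100. Applied alike to bulk pools and to
#' individual biomarkers.
#'
#' @param c_content Carbon content of the pool (any mass unit, e.g. mg C).
#' @param ape Atom percent excess (0-100 scale).
#' @return Excess 13C mass in the same unit as `c_content`.
#' @examples
#' tracer_mass(100, 1)  # 1 mg 13C excess
#' @export
tracer_mass <- function(c_content, ape) {
  if (any(!is.na(c_content) & c_content < 0)) {
    stop("`c_content` must be non-negative", call. = FALSE)
  }
  c_content * ape / 100
}
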