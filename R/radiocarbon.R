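# Radiocarbon conversions and two-endmember source apportionment.
# Delta14C (permil, decay-corrected reporting convention) -> fraction modern
# -> conventional 14C age, plus a linear mixing model in Fm space between a
# contemporary endmember and an old (basal-peat) endmember.

C14_LAMBDA <- 1 / 8267   # yr-1, reporting-convention decay constant
LIBBY_MEAN_LIFE <- 8033  # yr, conventional-age constant

#' Fraction modern from Delta14C
#'
#' Fm = (Delta14C/1000 + 1) / exp(lambda * (1950 - year)), lambda = 1/8267
#' yr-1. The denominator undoes the decay correction built into the
#' Delta14C reporting convention for a sample measured in `year_measured`.
#' Strictly increasing in Delta14C; Fm > 1 indicates post-bomb carbon.
#'
#' @param delta14c Permil; must be > -1000 (-1000 is radiocarbon-dead).
#' @param year_measured Calendar year of measurement (default 2011).
#' @return Fraction modern.
#' @examples
#' delta14c_to_fm(0, 1950)     # exactly 1
#' delta14c_to_fm(114.9, 2011)
#' @export
delta14c_to_fm <- function(delta14c, year_measured = 2011) {
  if (any(delta14c <= -1000)) {
    stop("delta14c must be > -1000 permil", call. = FALSE)
  }
  (delta14c / 1000 + 1) / exp(C14_LAMBDA * (1950 - year_measured))
}

#' Delta14C from fraction modern (inverse of [delta14c_to_fm()])
#'
#' @param fm Fraction modern; > 0.
#' @param year_measured Calendar year of measurement.
#' @return Delta14C, permil.
#' @export
fm_to_delta14c <- function(fm, year_measured = 2011) {
  if (any(fm <= 0)) stop("fm must be > 0", call. = FALSE)
  (fm * exp(C14_LAMBDA * (1950 - year_measured)) - 1) * 1000
}

#' Conventional radiocarbon age
#'
#' age = -8033 * ln(Fm), in 14C years BP. Samples with Fm >= 1 contain bomb
#' carbon and have no positive conventional age; they are flagged modern and
#' their `age_bp` is reported as the (non-positive) formal value.
#'
#' @param fm Fraction modern; must be > 0.
#' @return data.frame with `age_bp` and logical `modern` (Fm >= 1).
#' @export
conventional_age <- function(fm) {
  if (any(fm <= 0)) stop("fm must be > 0", call. = FALSE)
  data.frame(age_bp = -LIBBY_MEAN_LIFE * log(fm), modern = fm >= 1)
}

#' Classify a sample as modern or old carbon
#'
#' Modern means post-bomb (Fm >= 1) or a conventional age within
#' `modern_window_yr` (default 60 yr) of present; otherwise old.
#'
#' @inheritParams delta14c_to_fm
#' @param modern_window_yr Age window still counted as modern, yr.
#' @return Character vector, `"modern"` or `"old"`.
#' @export
classify_age <- function(delta14c, year_measured = 2011,
                         modern_window_yr = 60) {
  fm <- delta14c_to_fm(delta14c, year_measured)
  age <- conventional_age(fm)
  ifelse(age$modern | age$age_bp <= modern_window_yr, "modern", "old")
}

#' Endmember pair for old-carbon apportionment
#'
#' Defaults: modern endmember Fm = 1.05 (carbon recently fixed from the
#' post-bomb atmosphere) and old endmember Fm = exp(-3670/8033), the
#' fraction modern of basal peat aged 3670 14C yr BP — the oldest organic
#' carbon plausibly eroding into the ponds.
#'
#' @param modern_fm,old_fm Fractions modern; `modern_fm > old_fm >= 0`.
#' @return list with `modern_fm`, `old_fm`.
#' @export
endmember_pair <- function(modern_fm = 1.05,
                           old_fm = exp(-3670 / LIBBY_MEAN_LIFE)) {
  if (!(modern_fm > old_fm) || old_fm < 0) {
    stop("need modern_fm > old_fm >= 0", call. = FALSE)
  }
  list(modern_fm = modern_fm, old_fm = old_fm)
}

#' Old-carbon fraction from two-endmember mixing
#'
#' Linear mixing in fraction-modern space:
#' f_old = (modern_fm - fm_sample) / (modern_fm - old_fm). Samples outside
#' the endmember interval are clamped to [0, 1] and flagged (`clamped`),
#' with a warning, rather than silently dropped.
#'
#' @param fm_sample Sample fraction modern.
#' @param endmembers From [endmember_pair()].
#' @return data.frame with `f_old` and logical `clamped`.
#' @export
old_carbon_fraction <- function(fm_sample, endmembers = endmember_pair()) {
  span <- endmembers$modern_fm - endmembers$old_fm
  if (span == 0) stop("degenerate endmembers: modern_fm == old_fm", call. = FALSE)
  f <- (endmembers$modern_fm - fm_sample) / span
  clamped <- f < 0 | f > 1
  if (any(clamped)) {
    warning(sum(clamped), " sample(s) outside the endmember interval; ",
            "f_old clamped to [0, 1]", call. = FALSE)
    f <- pmin(pmax(f, 0), 1)
  }
  data.frame(f_old = f, clamped = clamped)
}

#' Derive radiocarbon quantities for a sample table
#'
#' Adds fraction modern, conventional age (or modern flag), the modern/old
#' class, and the two-endmember old-carbon fraction to a table in the
#' [read_radiocarbon_csv()] schema.
#'
#' @param c14 data.frame with `delta14c_permil` and `year` columns.
#' @param endmembers From [endmember_pair()].
#' @param modern_window_yr Passed to [classify_age()].
#' @return Input with `fm`, `age_bp`, `modern`, `age_class`, `f_old`,
#'   `f_old_clamped` columns appended.
#' @export
radiocarbon_table <- function(c14, endmembers = endmember_pair(),
                              modern_window_yr = 60) {
  fm <- delta14c_to_fm(c14$delta14c_permil, c14$year)
  age <- conventional_age(fm)
  fo <- suppressWarnings(old_carbon_fraction(fm, endmembers))
  c14$fm <- fm
  c14$age_bp <- age$age_bp
  c14$modern <- age$modern
  c14$age_class <- classify_age(c14$delta14c_permil, c14$year,
                                modern_window_yr)
  c14$f_old <- fo$f_old
  c14$f_old_clamped <- fo$clamped
  c14
}
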