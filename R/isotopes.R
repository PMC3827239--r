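# Stable-isotope attribution of the methanogenic pathway. Two complementary
# classifiers: the carbon-deuterium (CD) diagram on (d13C-CH4, dD-CH4), and
# the apparent carbon fractionation factor alphaC between co-occurring CO2
# and CH4. Low alphaC additionally flags partial methanotrophic oxidation,
# which enriches the residual CH4 in 13C.

#' Apparent carbon fractionation factor between CO2 and CH4
#'
#' alphaC = (d13C-CO2 + 1000) / (d13C-CH4 + 1000). Values near 1.04-1.055
#' are typical of acetoclastic methanogenesis, 1.055-1.09 of
#' hydrogenotrophic methanogenesis; values below the production range point
#' to partial CH4 oxidation.
#'
#' @param d13c_co2,d13c_ch4 Delta values, permil vs VPDB; both > -1000.
#' @return alphaC, dimensionless.
#' @examples
#' apparent_fractionation(-15, -60)  # ~1.0479
#' @export
apparent_fractionation <- function(d13c_co2, d13c_ch4) {
  if (any(d13c_co2 <= -1000) || any(d13c_ch4 <= -1000)) {
    stop("delta values must be > -1000 permil", call. = FALSE)
  }
  (d13c_co2 + 1000) / (d13c_ch4 + 1000)
}

#' Default CD-diagram region boundaries
#'
#' Rectangular regions in (d13C-CH4, dD-CH4) space following the standard
#' CD-diagram convention for freshwater methanogenesis: acetoclastic
#' d13C in [-65, -50] and dD in [-400, -250]; hydrogenotrophic d13C in
#' [-110, -60] and dD in [-250, -150]. Boundaries are configuration, not
#' constants: pass an edited copy to [classify_pathway_cd()] to use other
#' conventions, and every classification records the boundary set id.
#'
#' @return Named list of regions, each with `d13c` and `dd` ranges, plus an
#'   `id` attribute.
#' @export
cd_boundaries <- function() {
  b <- list(
    acetoclastic = list(d13c = c(-65, -50), dd = c(-400, -250)),
    hydrogenotrophic = list(d13c = c(-110, -60), dd = c(-250, -150))
  )
  attr(b, "id") <- "freshwater-default-v1"
  b
}

in_box <- function(x, y, region) {
  x >= region$d13c[1] & x <= region$d13c[2] &
    y >= region$dd[1] & y <= region$dd[2]
}

#' Classify the methanogenic pathway on the CD diagram
#'
#' Deterministic rectangular-region membership call. A sample inside exactly
#' one region gets that region's label; inside both, `mixed`; inside
#' neither, `indeterminate`. Classification without dD-CH4 is refused:
#' d13C-CH4 alone cannot separate the pathways (the hydrogenotrophic and
#' acetoclastic d13C ranges overlap), which is why the deuterium signature
#' is required.
#'
#' @param d13c_ch4 Permil vs VPDB.
#' @param dd_ch4 Permil vs VSMOW; required.
#' @param boundaries Region set from [cd_boundaries()].
#' @return data.frame with `label`, `basis` (`cd_diagram`) and
#'   `boundary_set`.
#' @export
classify_pathway_cd <- function(d13c_ch4, dd_ch4, boundaries = cd_boundaries()) {
  if (missing(dd_ch4) || any(is.na(dd_ch4))) {
    stop("dD-CH4 is required: without it the hydrogenotrophic pathway ",
         "cannot be ruled out", call. = FALSE)
  }
  if (any(d13c_ch4 <= -130) || any(d13c_ch4 >= 20)) {
    stop("d13c_ch4 outside plausible range (-130, 20) permil", call. = FALSE)
  }
  if (any(dd_ch4 <= -500) || any(dd_ch4 >= 0)) {
    stop("dd_ch4 outside plausible range (-500, 0) permil", call. = FALSE)
  }
  am <- in_box(d13c_ch4, dd_ch4, boundaries$acetoclastic)
  hm <- in_box(d13c_ch4, dd_ch4, boundaries$hydrogenotrophic)
  label <- ifelse(am & hm, "mixed",
           ifelse(am, "acetoclastic",
           ifelse(hm, "hydrogenotrophic", "indeterminate")))
  data.frame(label = label, basis = "cd_diagram",
             boundary_set = attr(boundaries, "id"))
}

#' Default alphaC classification windows
#'
#' @return Named list with `acetoclastic`, `hydrogenotrophic` intervals and
#'   the `oxidation_below` threshold.
#' @export
alpha_windows <- function() {
  list(acetoclastic = c(1.040, 1.055),
       hydrogenotrophic = c(1.055, 1.090),
       oxidation_below = 1.040)
}

#' Classify the methanogenic pathway from alphaC
#'
#' Interval membership: acetoclastic for alphaC in [1.040, 1.055],
#' hydrogenotrophic in (1.055, 1.090], `oxidation_affected` below 1.040
#' (oxidation drives the apparent fractionation down), `indeterminate`
#' above 1.090. Bounds are configurable.
#'
#' @param alpha_c Apparent fractionation factor; must be > 0.
#' @param windows Interval set from [alpha_windows()].
#' @return data.frame with `label`, `alpha_c`, `basis` (`alpha_c`).
#' @export
classify_pathway_alpha <- function(alpha_c, windows = alpha_windows()) {
  if (any(alpha_c <= 0)) stop("alpha_c must be > 0", call. = FALSE)
  ac <- windows$acetoclastic
  hm <- windows$hydrogenotrophic
  label <- ifelse(alpha_c < windows$oxidation_below, "oxidation_affected",
           ifelse(alpha_c >= ac[1] & alpha_c <= ac[2], "acetoclastic",
           ifelse(alpha_c > hm[1] & alpha_c <= hm[2], "hydrogenotrophic",
                  "indeterminate")))
  data.frame(label = label, alpha_c = alpha_c, basis = "alpha_c")
}

#' Classify a whole isotope sample table
#'
#' Adds the CD-diagram call (where dD-CH4 is present), alphaC and its call
#' (where d13C-CO2 is present), and a combined label: the CD call when
#' available, otherwise the alphaC call.
#'
#' @param iso data.frame in the [read_isotope_csv()] schema.
#' @param boundaries CD regions; @param windows alphaC intervals.
#' @return Input with `cd_label`, `alpha_c`, `alpha_label`, `label`, `basis`,
#'   `boundary_set` columns appended.
#' @export
classify_isotopes <- function(iso, boundaries = cd_boundaries(),
                              windows = alpha_windows()) {
  n <- nrow(iso)
  cd_label <- rep(NA_character_, n)
  has_dd <- "dd_ch4" %in% names(iso) & if ("dd_ch4" %in% names(iso))
    !is.na(iso$dd_ch4) else rep(FALSE, n)
  if (any(has_dd)) {
    cd_label[has_dd] <- classify_pathway_cd(iso$d13c_ch4[has_dd],
                                            iso$dd_ch4[has_dd],
                                            boundaries)$label
  }
  alpha_c <- rep(NA_real_, n)
  alpha_label <- rep(NA_character_, n)
  has_co2 <- "d13c_co2" %in% names(iso) & if ("d13c_co2" %in% names(iso))
    !is.na(iso$d13c_co2) else rep(FALSE, n)
  if (any(has_co2)) {
    alpha_c[has_co2] <- apparent_fractionation(iso$d13c_co2[has_co2],
                                               iso$d13c_ch4[has_co2])
    alpha_label[has_co2] <- classify_pathway_alpha(alpha_c[has_co2],
                                                   windows)$label
  }
  iso$cd_label <- cd_label
  iso$alpha_c <- alpha_c
  iso$alpha_label <- alpha_label
  iso$label <- ifelse(!is.na(cd_label), cd_label, alpha_label)
  iso$basis <- ifelse(!is.na(cd_label) & !is.na(alpha_label), "both",
               ifelse(!is.na(cd_label), "cd_diagram",
               ifelse(!is.na(alpha_label), "alpha_c", NA_character_)))
  iso$boundary_set <- attr(boundaries, "id")
  iso
}

#' Regression of d13C-CH4 on surface oxygen
#'
#' Ordinary least squares of the methane carbon-isotope signature on surface
#' dissolved oxygen. A positive slope (13C enrichment with oxygen) is the
#' signature of partial methanotrophic oxidation of diffusing CH4.
#'
#' @param o2 Surface O2, mg L-1; not all equal, n >= 3.
#' @param d13c_ch4 Permil vs VPDB.
#' @return data.frame with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
oxidation_regression <- function(o2, d13c_ch4) {
  n <- length(o2)
  if (n < 3 || length(d13c_ch4) != n) {
    stop("need >= 3 paired observations", call. = FALSE)
  }
  if (stats::var(o2) == 0) {
    stop("O2 values are all equal: singular fit", call. = FALSE)
  }
  fit <- stats::lm(d13c_ch4 ~ o2)
  s <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r2 = s$r.squared,
             p = unname(s$coefficients[2, 4]),
             n = n)
}
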