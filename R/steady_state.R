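#' Steady-state distribution from a kinetic rate set
#'
#' Converts first-order shuttling and chromatin-binding rates into the
#' steady-state partition of the protein over three pools: cytoplasmic,
#' nuclear mobile and nuclear chromatin-bound. At steady state the
#' concentrations obey `N_M0 = (km2 / k2) * C0` (import/export balance) and
#' `N_I0 = (k1 / km1) * N_M0` (binding balance); fractions are computed from
#' amounts, i.e. concentration times effective compartment volume.
#'
#' @param k1 Association rate onto chromatin partners, 1/s.
#' @param km1 Dissociation rate from the bound state, 1/s.
#' @param k2 Nuclear export rate, 1/s.
#' @param km2 Nuclear import rate, 1/s.
#' @param volume_ratio Nuclear over cytoplasmic effective volume (default 1).
#' @return A `Distribution`: list with `frac_cytoplasmic`,
#'   `frac_nuclear_mobile`, `frac_nuclear_bound`, `frac_nuclear` (their sum
#'   minus the cytoplasmic part) and `volume_ratio`.
#' @examples
#' distribution_from_rates(k1 = 0.25, km1 = 0.56, k2 = 0.046, km2 = 0.021)
#' @export
distribution_from_rates <- function(k1, km1, k2, km2, volume_ratio = 1) {
  if (k2 <= 0) stop("export rate k2 must be positive")
  if (km1 <= 0) stop("dissociation rate km1 must be positive")
  if (k1 < 0 || km2 < 0) stop("rates must be non-negative")
  C0 <- 1
  NM0 <- km2 * C0 / k2
  NI0 <- k1 * NM0 / km1
  amounts <- c(cyt = C0 * 1, mob = NM0 * volume_ratio, bound = NI0 * volume_ratio)
  f <- amounts / sum(amounts)
  structure(
    list(frac_cytoplasmic = unname(f["cyt"]),
         frac_nuclear_mobile = unname(f["mob"]),
         frac_nuclear_bound = unname(f["bound"]),
         frac_nuclear = unname(f["mob"] + f["bound"]),
         volume_ratio = volume_ratio),
    class = "Distribution")
}

#' @export
print.Distribution <- function(x, ...) {
  cat(sprintf(
    "Distribution: cytoplasmic %.1f%%, nuclear mobile %.1f%%, nuclear bound %.1f%% (nuclear total %.1f%%) [%s]\n",
    100 * x$frac_cytoplasmic, 100 * x$frac_nuclear_mobile,
    100 * x$frac_nuclear_bound, 100 * x$frac_nuclear,
    classify_distribution(x)))
  invisible(x)
}

#' Classify a distribution as NF-like or CAF-like
#'
#' Activated fibroblasts hold a clearly nuclear-enriched steady state
#' (roughly 60 percent nuclear) while normal fibroblasts sit around 40
#' percent. The classifier labels a distribution CAF-like above the upper
#' threshold, NF-like below the lower one, and intermediate otherwise.
#'
#' @param dist A `Distribution`.
#' @param caf_threshold,nf_threshold Nuclear-fraction thresholds.
#' @return `"CAF-like"`, `"NF-like"` or `"intermediate"`.
#' @export
classify_distribution <- function(dist, caf_threshold = 0.55, nf_threshold = 0.45) {
  if (dist$frac_nuclear > caf_threshold) "CAF-like"
  else if (dist$frac_nuclear < nf_threshold) "NF-like"
  else "intermediate"
}

#' Rate-substitution experiment
#'
#' Replaces a named subset of the rates of a base rate set with the donor's
#' values and returns the resulting steady-state distribution, emulating the
#' in-silico parameter swaps used to identify which rate difference drives
#' the localization difference between cell states.
#'
#' @param base,donor Named lists or vectors containing `k1`, `km1`, `k2`,
#'   `km2` (a `RateSet` as returned by [yap_rates()] rows works).
#' @param which Character subset of `c("k1", "km1", "k2", "km2")` to take
#'   from the donor; empty means no swap.
#' @param volume_ratio Passed to [distribution_from_rates()].
#' @return A `Distribution`.
#' @export
substitute_rates <- function(base, donor, which = character(),
                             volume_ratio = 1) {
  rate_names <- c("k1", "km1", "k2", "km2")
  if (!all(which %in% rate_names))
    stop("unknown rate name(s): ", paste(setdiff(which, rate_names), collapse = ", "))
  rates <- lapply(stats::setNames(rate_names, rate_names), function(nm) {
    v <- if (nm %in% which) donor[[nm]] else base[[nm]]
    if (is.null(v) || is.na(v)) stop("rate set is missing ", nm)
    v
  })
  distribution_from_rates(rates$k1, rates$km1, rates$k2, rates$km2,
                          volume_ratio = volume_ratio)
}

#' Published median kinetic rates for EYFP-YAP1
#'
#' Median rate estimates per cell type and construct: chromatin dissociation
#' from nuclear and cytoplasmic FRAP, import/export from FLIP, plus the fixed
#' dissociation values used when fitting FLIP. Association medians are not
#' reported numerically (only the 0.15-0.5 1/s range); the values here are
#' back-calculated so the reported steady-state fractions (about 40 percent
#' nuclear / 12 percent bound in NF1 and 60 / 22 in CAF1) are reproduced, and
#' they lie inside the reported range.
#'
#' @return A data frame keyed by `condition` with columns `km1_nuc`,
#'   `km1_cyt`, `km2` (import), `k2` (export), `k1` (association) and
#'   `km1_flip_fixed`, all in 1/s.
#' @export
yap_rates <- function() {
  data.frame(
    condition = c("NF1_WT", "CAF1_WT", "NF1_5SA", "CAF1_5SA"),
    km1_nuc = c(0.56, 0.39, NA, NA),
    km1_cyt = c(0.67, 0.65, NA, NA),
    km2 = c(0.021, 0.017, 0.018, NA),
    k2 = c(0.046, 0.018, 0.012, 0.013),
    k1 = c(0.25, 0.235, NA, NA),
    km1_flip_fixed = c(0.55, 0.40, 0.55, 0.40),
    row.names = c("NF1_WT", "CAF1_WT", "NF1_5SA", "CAF1_5SA"),
    stringsAsFactors = FALSE)
}

#' Rate set for one condition
#'
#' Convenience accessor over [yap_rates()] returning a named list usable by
#' [substitute_rates()] and [distribution_from_rates()].
#'
#' @param condition One of `"NF1_WT"`, `"CAF1_WT"`, `"NF1_5SA"`, `"CAF1_5SA"`.
#' @return Named list with `k1`, `km1`, `k2`, `km2` (dissociation taken from
#'   the nuclear FRAP median).
#' @export
rate_set <- function(condition = c("NF1_WT", "CAF1_WT", "NF1_5SA", "CAF1_5SA")) {
  condition <- match.arg(condition)
  r <- yap_rates()[condition, ]
  list(k1 = r$k1, km1 = r$km1_nuc, k2 = r$k2, km2 = r$km2,
       condition = condition)
}
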