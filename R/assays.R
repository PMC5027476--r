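#' Pfaffl efficiency-corrected qPCR fold change
#'
#' Relative expression of a target gene against a reference gene, corrected
#' for the amplification efficiency of each assay:
#'
#' \deqn{\mathrm{ratio} = E_t^{\Delta Ct_t} / E_{ref}^{\Delta Ct_{ref}}}
#'
#' where efficiencies are expressed as the per-cycle amplification factor
#' (2 = perfect doubling) and each \eqn{\Delta Ct} is `control - sample` in
#' cycles (technical-replicate Cts should be averaged before computing
#' \eqn{\Delta Ct}). With both efficiencies equal to 2 this reduces exactly
#' to the classic \eqn{2^{-\Delta\Delta Ct}} formula.
#'
#' @param e_target,e_ref Amplification efficiencies in \[1, 2.2\].
#'   Efficiencies given as percent (e.g. 95) are rejected, not rescaled.
#' @param delta_ct_target,delta_ct_ref Ct differences (control - sample),
#'   in cycles.
#' @return Numeric vector of fold changes.
#' @examples
#' pfaffl_fold_change(2, 3, 2, 0)       # 8
#' pfaffl_fold_change(1.9, 2, 2.0, 1)   # 1.805
#' @export
pfaffl_fold_change <- function(e_target, delta_ct_target, e_ref,
                               delta_ct_ref) {
  check_efficiency(e_target, "e_target")
  check_efficiency(e_ref, "e_ref")
  if (!all(is.finite(delta_ct_target) & is.finite(delta_ct_ref))) {
    abort("delta Ct values must be finite")
  }
  e_target^delta_ct_target / e_ref^delta_ct_ref
}

check_efficiency <- function(e, what) {
  if (any(e <= 0)) abort(paste0(what, " must be positive"))
  if (any(e < 1 | e > 2.2)) {
    abort(paste0(what, " must lie in [1, 2.2] (per-cycle amplification ",
                 "factor; percent efficiencies are not accepted)"))
  }
  invisible(e)
}

#' Pfaffl fold changes for a measurement table
#'
#' Data-frame front end to [pfaffl_fold_change()]: takes one row per
#' measurement and appends a `fold_change` column.
#'
#' @param df Tibble with columns `e_target`, `delta_ct_target`, `e_ref`,
#'   `delta_ct_ref` (extra columns pass through).
#' @return `df` with a `fold_change` column.
#' @export
pfaffl_table <- function(df) {
  need <- c("e_target", "delta_ct_target", "e_ref", "delta_ct_ref")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  mutate(as_tibble(df),
         fold_change = pfaffl_fold_change(.data$e_target,
                                          .data$delta_ct_target,
                                          .data$e_ref,
                                          .data$delta_ct_ref))
}

#' Percent 5-methylcytosine from HPLC peak areas
#'
#' Converts the chromatogram peak areas of dCMP and 5-methyl-dCMP (detected
#' at 276 nm and 282 nm respectively) into molar amounts via their molar
#' extinction coefficients, and reports 5mC as a percentage of the cytosine
#' pool:
#'
#' \deqn{\%5mC = 100 \cdot \frac{A_{5mC}/\varepsilon_{5mC}}
#'   {A_C/\varepsilon_C + A_{5mC}/\varepsilon_{5mC}}}
#'
#' The result is invariant to rescaling both areas by a common factor.
#'
#' @param area_c,area_5mc Non-negative peak areas of dCMP and 5mdCMP.
#' @param eps_c Extinction coefficient of dCMP (default 8.86e3).
#' @param eps_5mc Extinction coefficient of 5mdCMP (default 9.0e3).
#' @return Percent of the cytosine pool that is 5mC.
#' @examples
#' hplc_5mc_percent(1, 1)  # 49.61...
#' hplc_5mc_percent(1, 0)  # 0
#' @export
hplc_5mc_percent <- function(area_c, area_5mc, eps_c = 8.86e3,
                             eps_5mc = 9.0e3) {
  if (any(area_c < 0 | area_5mc < 0)) abort("peak areas must be non-negative")
  if (any(eps_c <= 0 | eps_5mc <= 0)) {
    abort("extinction coefficients must be positive")
  }
  if (any(area_c + area_5mc == 0)) {
    abort("both peak areas are zero; nothing to quantify")
  }
  n_c <- area_c / eps_c
  n_5mc <- area_5mc / eps_5mc
  100 * n_5mc / (n_c + n_5mc)
}

#' Percent 5mC for a table of HPLC measurements
#'
#' @param df Tibble with columns `area_c` and `area_5mc` (optionally
#'   `eps_c`, `eps_5mc`; defaults used otherwise).
#' @return `df` with a `percent_5mc` column.
#' @export
hplc_table <- function(df) {
  if (!all(c("area_c", "area_5mc") %in% names(df))) {
    abort("missing column(s): area_c, area_5mc")
  }
  df <- as_tibble(df)
  eps_c <- if ("eps_c" %in% names(df)) df$eps_c else 8.86e3
  eps_5mc <- if ("eps_5mc" %in% names(df)) df$eps_5mc else 9.0e3
  mutate(df, percent_5mc = hplc_5mc_percent(.data$area_c, .data$area_5mc,
                                            eps_c, eps_5mc))
}
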