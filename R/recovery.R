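#' Per-region methylation recovery
#'
#' The core statistic of the pipeline. For a region with normalized log2
#' MeDIP abundance `w` in the wild-type reference, `m0` in the null baseline
#' and `s` in a rescue sample, the methylation deficit is `D = w - m0`, the
#' residual deficit is `S = w - s`, and the recovery is
#'
#' \deqn{MR = 100 (D - S) / D = 100 (s - m0) / D}
#'
#' i.e. the percent of the lost log2 signal regained: 100 when the rescue
#' sample matches the reference, 0 when it matches the baseline. Regions
#' whose deficit is below `d_min` carry too little methylation loss for MR
#' to be meaningful; they are flagged as excluded, never silently dropped.
#' MR is not clamped by default — sampling noise legitimately produces
#' values outside \[0, 100\].
#'
#' @param w,m0,s Numeric vectors of normalized log2 values for the
#'   reference, baseline and test sample (recycled to a common length).
#' @param d_min Minimum deficit, in log2 units, for a region to be scored.
#'   Default 1 (a two-fold loss in the null). Must be > 0 unless you accept
#'   division by zero at `D = 0`.
#' @param clamp If `TRUE`, clamp MR into \[0, 100\].
#' @return A tibble with columns `D`, `S`, `MR`, `excluded`,
#'   `excluded_reason` (`MR` is `NA` for excluded regions).
#' @examples
#' methylation_recovery(w = 6, m0 = 4, s = c(6, 4, 5))
#' @export
methylation_recovery <- function(w, m0, s, d_min = 1, clamp = FALSE) {
  n <- max(length(w), length(m0), length(s))
  w <- rep_len(w, n); m0 <- rep_len(m0, n); s <- rep_len(s, n)
  if (!all(is.finite(w) & is.finite(m0) & is.finite(s))) {
    abort("methylation_recovery requires finite log2 values")
  }
  if (d_min < 0) abort("d_min must be >= 0")
  D <- w - m0
  S <- w - s
  if (d_min == 0 && any(D == 0)) {
    abort("D = 0 with d_min = 0: methylation recovery is undefined (division by zero)")
  }
  excluded <- D < d_min
  MR <- ifelse(excluded, NA_real_, 100 * (D - S) / D)
  if (clamp) MR <- pmin(pmax(MR, 0), 100)
  tibble(D = D, S = S, MR = MR,
         excluded = excluded,
         excluded_reason = if_else(excluded, "low_deficit", NA_character_))
}

#' Recovery records for every test sample of a normalized dataset
#'
#' Applies [methylation_recovery()] region-by-region for each `test` sample
#' in the manifest, using the manifest's `reference` and `baseline` columns
#' of the normalized table.
#'
#' @param norm A `medip_norm` object (or any tibble with `region_id` plus
#'   sample columns on the log2 scale).
#' @param manifest A sample manifest.
#' @param regions Optional regions tibble contributing `region_class` (and
#'   dropping nothing); when `NULL` the class is taken from a
#'   `region_class` column of `norm` if present, else `NA`.
#' @param d_min Minimum log2 deficit for a region to be scored (default 1).
#' @param clamp Clamp MR into \[0, 100\]? Default `FALSE`.
#' @return A tibble of class `mr_records`: one row per (region, test
#'   sample) with columns `sample_id`, `region_id`, `region_class`, `D`,
#'   `S`, `MR`, `excluded`, `excluded_reason`. Invariant control regions are
#'   excluded with reason `"invariant"` when `regions` flags them.
#' @export
recovery_table <- function(norm, manifest, regions = NULL, d_min = 1,
                           clamp = FALSE) {
  manifest <- validate_manifest(manifest)
  samples <- setdiff(names(norm), "region_id")
  reference <- manifest_role(manifest, "reference")
  baseline <- manifest_role(manifest, "baseline")
  tests <- manifest_role(manifest, "test")
  missing <- setdiff(c(reference, baseline, tests), samples)
  if (length(missing) > 0L) {
    abort(paste0("normalized table lacks sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(tests) == 0L) abort("manifest declares no test samples")
  class_of <- rep(NA_character_, nrow(norm))
  invariant <- rep(FALSE, nrow(norm))
  if (!is.null(regions)) {
    regions <- validate_regions(regions)
    i <- match(norm$region_id, regions$region_id)
    class_of <- regions$region_class[i]
    invariant <- regions$invariant[i] %in% TRUE
  } else if ("region_class" %in% names(norm)) {
    class_of <- norm$region_class
  }
  w <- norm[[reference]]
  m0 <- norm[[baseline]]
  out <- bind_rows(lapply(tests, function(s) {
    rec <- methylation_recovery(w, m0, norm[[s]], d_min = d_min, clamp = clamp)
    bind_cols(tibble(sample_id = s,
                     region_id = norm$region_id,
                     region_class = class_of),
              rec)
  }))
  # invariant regions are normalization anchors, not recovery candidates
  is_inv <- rep(invariant, length(tests))
  out$MR[is_inv] <- NA_real_
  out$excluded[is_inv] <- TRUE
  out$excluded_reason[is_inv] <- "invariant"
  structure(out, d_min = d_min,
            class = c("mr_records", class(as_tibble(out))))
}

#' Five-number boxplot summary of recovery by region class
#'
#' Summarizes scored (non-excluded) MR values per region class the way the
#' recovery boxplots are drawn: quartiles by linear interpolation of order
#' statistics (R quantile type 7) and whiskers at the most extreme
#' observations within 1.5 interquartile ranges of the quartiles.
#'
#' @param records An `mr_records` tibble from [recovery_table()].
#' @param by Grouping column(s); default `c("sample_id", "region_class")`.
#' @return A tibble with columns `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high` per group. Groups with no scored regions are omitted
#'   with a warning.
#' @export
summarize_recovery <- function(records, by = c("sample_id", "region_class")) {
  by <- intersect(by, names(records))
  scored <- filter(records, !.data$excluded & is.finite(.data$MR))
  all_groups <- distinct(records[, by, drop = FALSE])
  if (nrow(scored) == 0L) abort("no scored regions to summarize")
  out <- scored |>
    group_by(across(all_of(by))) |>
    summarise(n = n(),
              median = median(.data$MR),
              q1 = quantile(.data$MR, 0.25, type = 7, names = FALSE),
              q3 = quantile(.data$MR, 0.75, type = 7, names = FALSE),
              whisker_low = whisker(.data$MR, lower = TRUE),
              whisker_high = whisker(.data$MR, lower = FALSE),
              .groups = "drop")
  dropped <- nrow(all_groups) - nrow(out)
  if (dropped > 0L) {
    warn(sprintf("%d group(s) had no scored regions and were omitted", dropped))
  }
  out
}

whisker <- function(x, lower) {
  q1 <- quantile(x, 0.25, type = 7, names = FALSE)
  q3 <- quantile(x, 0.75, type = 7, names = FALSE)
  iqr <- q3 - q1
  inside <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
  if (lower) min(inside) else max(inside)
}

#' Fraction of regions with substantial recovery
#'
#' Percent of scored regions whose MR meets the threshold, with the counts
#' reported alongside — the quantity behind statements like "X% of
#' hypomethylated promoters substantially recovered methylation".
#'
#' @param records An `mr_records` tibble (pre-filter to one class, e.g.
#'   promoters, as needed).
#' @param mr_threshold MR cutoff in percent defining "substantially
#'   recovered"; default 50.
#' @param by Grouping column(s); default `"sample_id"`.
#' @return A tibble per group: `n_pass`, `n_total` (scored regions) and
#'   `percent = 100 * n_pass / n_total`.
#' @export
fraction_recovered <- function(records, mr_threshold = 50, by = "sample_id") {
  by <- intersect(by, names(records))
  scored <- filter(records, !.data$excluded & is.finite(.data$MR))
  if (nrow(scored) == 0L) abort("no scored regions")
  scored |>
    group_by(across(all_of(by))) |>
    summarise(n_pass = sum(.data$MR >= mr_threshold),
              n_total = n(),
              percent = 100 * .data$n_pass / .data$n_total,
              .groups = "drop") |>
    mutate(mr_threshold = mr_threshold)
}

#' Pairwise Spearman correlation of methylome profiles
#'
#' Spearman's rank correlation between every pair of samples over the
#' normalized log2 values (rho computed as Pearson correlation of
#' average-ranked values, so ties get average ranks). Pairs involving a
#' constant column are undefined and reported as `NA`, never coerced to 0.
#'
#' @param norm A `medip_norm` object or tibble with `region_id` plus sample
#'   columns.
#' @param region_subset Optional character vector of `region_id`s to
#'   restrict the comparison to.
#' @return A symmetric matrix of class `cor_matrix` with unit diagonal;
#'   `tidy()` converts it to a long tibble and `autoplot()` draws a heat
#'   map.
#' @export
spearman_matrix <- function(norm, region_subset = NULL) {
  df <- as_tibble(unclass(norm))
  if (!is.null(region_subset)) {
    df <- filter(df, .data$region_id %in% region_subset)
  }
  samples <- setdiff(names(df), c("region_id", "region_class"))
  if (length(samples) < 2L) abort("need at least 2 samples")
  if (nrow(df) < 3L) abort("need at least 3 regions")
  m <- as.matrix(df[, samples])
  constant <- apply(m, 2L, function(col) var(col) == 0)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  # undefined (constant-column) pairs stay NA; self-correlation is 1 by convention
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  structure(rho, n_regions = nrow(df),
            undefined_samples = samples[constant],
            class = c("cor_matrix", "matrix", "array"))
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<cor_matrix> Spearman rho over %d regions\n",
              attr(x, "n_regions")))
  print(round(unclass(x)[, , drop = FALSE], digits), ...)
  invisible(x)
}

#' Tidy a correlation matrix into a long tibble
#'
#' @param x A `cor_matrix` from [spearman_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_a`, `sample_b`, `rho`.
#' @export
tidy.cor_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(sample_a = rep(rownames(m), times = ncol(m)),
         sample_b = rep(colnames(m), each = nrow(m)),
         rho = as.vector(m))
}

#' Write recovery records to TSV
#'
#' @param records An `mr_records` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recovery_table <- function(records, path) {
  df <- as_tibble(unclass(records)) |>
    mutate(across(c("D", "S", "MR"), ~ round(.x, 6)))
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Write a correlation matrix to TSV
#'
#' @param x A `cor_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cor_matrix <- function(x, path) {
  m <- round(unclass(x), 6)
  df <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}
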