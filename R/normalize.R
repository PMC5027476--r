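#' Reads per kilobase of feature
#'
#' First normalization step for region-level MeDIP-seq counts: divide the raw
#' count by the region length in kilobases, removing the trivial dependence
#' of coverage on feature size.
#'
#' @param count Non-negative numeric vector of read counts.
#' @param length_bp Positive region lengths in base pairs (recycled).
#' @return `count / (length_bp / 1000)`.
#' @examples
#' rpk(100, 1000)  # 100
#' rpk(30, 250)    # 120
#' @export
rpk <- function(count, length_bp) {
  if (any(length_bp <= 0)) abort("length_bp must be positive")
  if (any(count < 0)) abort("counts must be non-negative")
  count / (length_bp / 1000)
}

#' Normalization configuration
#'
#' @param pseudocount Positive value added to RPK before taking log2, so
#'   zero-count regions stay finite. Default 0.5, the conventional
#'   half-count.
#' @param reference_sample Optional sample id the invariant regression is
#'   fitted against; defaults to the manifest's `reference` sample.
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(pseudocount = 0.5, reference_sample = NULL) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    abort("pseudocount must be a single positive number")
  }
  structure(list(pseudocount = pseudocount,
                 reference_sample = reference_sample),
            class = "norm_config")
}

#' Log2 reads-per-kilobase table
#'
#' Converts a raw count table into the log2 abundance scale every downstream
#' statistic works on: `log2(rpk + pseudocount)` per cell.
#'
#' @param table A count table tibble (`region_id` plus one column per
#'   sample).
#' @param regions A regions tibble supplying lengths; every `region_id` in
#'   `table` must be present.
#' @param pseudocount Value added to RPK before log2 (may be 0 if all counts
#'   are positive); default 0.5.
#' @return A tibble of the same shape with log2-RPK values.
#' @export
log2_rpk_table <- function(table, regions, pseudocount = 0.5) {
  regions <- validate_regions(regions)
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  len <- region_lengths(regions)
  missing <- setdiff(table$region_id, names(len))
  if (length(missing) > 0L) {
    abort(paste0("regions missing for region_id(s): ",
                 paste(head(missing, 3L), collapse = ", ")))
  }
  l <- unname(len[table$region_id])
  samples <- setdiff(names(table), "region_id")
  out <- tibble(region_id = table$region_id)
  for (s in samples) {
    out[[s]] <- log2(rpk(table[[s]], l) + pseudocount)
  }
  out
}

#' Fit the invariant-region normalization model
#'
#' Ordinary least-squares regression of one sample's log2 values on the
#' reference sample's, restricted to the invariant control regions — regions
#' whose methylation is known not to differ between the compared cell
#' states. The fitted line captures the sample's residual depth/efficiency
#' distortion; [apply_model()] removes it.
#'
#' @param sample_values Numeric vector of the sample's log2 values
#'   (dependent variable).
#' @param reference_values Numeric vector of the reference's log2 values
#'   (independent variable), same length.
#' @param invariant Logical vector (or integer index) selecting the
#'   invariant regions used for the fit.
#' @param sample_id Optional sample label stored in the model.
#' @return A one-row tibble of class `invariant_model` with columns
#'   `sample_id`, `slope`, `intercept`, `r_squared`, `n_invariant`.
#' @examples
#' ref <- c(1, 2, 3, 4)
#' fit_invariant_model(0.5 * ref + 2, ref, rep(TRUE, 4))
#' @export
fit_invariant_model <- function(sample_values, reference_values, invariant,
                                sample_id = "sample") {
  y <- sample_values[invariant]
  x <- reference_values[invariant]
  if (length(y) != length(x)) abort("sample and reference lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    abort("need at least 3 finite invariant regions to fit the normalization")
  }
  if (var(x) == 0) {
    abort("reference values are constant over the invariant regions; cannot fit")
  }
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2L])
  b <- unname(coef(fit)[1L])
  if (m < 0) {
    abort(paste0("invariant regression slope is negative for sample '",
                 sample_id, "'; the invariant set looks corrupt"))
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    tibble(sample_id = sample_id, slope = m, intercept = b,
           r_squared = r2, n_invariant = length(x)),
    class = c("invariant_model", "tbl_df", "tbl", "data.frame"))
}

#' Apply an invariant-region normalization model
#'
#' Affine transform `(value - intercept) / slope` chosen so that refitting
#' the invariant regression on the transformed values yields an intercept of
#' 0 and a gradient of 1.
#'
#' @param values Numeric vector of log2 values for one sample.
#' @param model An `invariant_model` (one row) from [fit_invariant_model()].
#' @return The transformed values.
#' @export
apply_model <- function(values, model) {
  if (!all(c("slope", "intercept") %in% names(model))) {
    abort("model must have slope and intercept")
  }
  if (model$slope[1L] == 0) {
    abort("model slope is 0; inspect the invariant region set")
  }
  (values - model$intercept[1L]) / model$slope[1L]
}

#' Normalize a MeDIP-seq count table against its reference sample
#'
#' The complete two-step normalization: counts are scaled to reads per
#' kilobase and log2-transformed ([log2_rpk_table()]); then each
#' non-reference sample is affine-transformed so that its invariant-region
#' regression against the reference has intercept 0 and gradient 1
#' ([fit_invariant_model()], [apply_model()]). The reference column is left
#' as its own log2 RPK (identity model).
#'
#' @param table A raw count table tibble.
#' @param regions A regions tibble with an `invariant` column flagging the
#'   control regions.
#' @param manifest A sample manifest ([manifest()]); all its samples must be
#'   columns of `table`.
#' @param config A [norm_config()].
#' @return A tibble of class `medip_norm` (shape of `table`, log2 scale) with
#'   the fitted models attached; retrieve them with [tidy()][tidy.medip_norm].
#' @examples
#' sim <- simulate_annotation(sim_params(n_regions = 40), seed = 1)
#' truth <- simulate_methylomes(sim, sim_params(n_regions = 40), seed = 1)
#' counts <- simulate_medip_counts(truth, sim, sim_params(n_regions = 40), seed = 1)
#' norm <- normalize_dataset(counts, sim, default_manifest())
#' generics::tidy(norm)
#' @export
normalize_dataset <- function(table, regions, manifest,
                              config = norm_config()) {
  regions <- validate_regions(regions)
  manifest <- validate_manifest(manifest)
  if (!inherits(config, "norm_config")) abort("config must be a norm_config()")
  samples <- setdiff(names(table), "region_id")
  missing <- setdiff(manifest$sample_id, samples)
  if (length(missing) > 0L) {
    abort(paste0("manifest sample(s) absent from count table: ",
                 paste(missing, collapse = ", ")))
  }
  reference <- config$reference_sample %||% manifest_role(manifest, "reference")
  if (!reference %in% samples) {
    abort(paste0("reference sample '", reference, "' not in count table"))
  }
  logtab <- log2_rpk_table(table, regions, config$pseudocount)
  inv <- regions$invariant[match(logtab$region_id, regions$region_id)]
  if (sum(inv) < 3L) {
    abort("need at least 3 invariant regions flagged in `regions`")
  }
  ref_values <- logtab[[reference]]
  models <- list()
  out <- logtab
  for (s in setdiff(samples, reference)) {
    mod <- fit_invariant_model(logtab[[s]], ref_values, inv, sample_id = s)
    out[[s]] <- apply_model(logtab[[s]], mod)
    models[[s]] <- mod
  }
  new_medip_norm(out,
                 models = bind_rows(models),
                 reference = reference,
                 invariant_ids = logtab$region_id[inv],
                 pseudocount = config$pseudocount)
}

new_medip_norm <- function(values, models, reference, invariant_ids,
                           pseudocount) {
  structure(values,
            models = models,
            reference = reference,
            invariant_ids = invariant_ids,
            pseudocount = pseudocount,
            class = c("medip_norm", class(as_tibble(values))))
}

#' @export
print.medip_norm <- function(x, ...) {
  samples <- setdiff(names(x), "region_id")
  cat(sprintf("<medip_norm> %d regions x %d samples (reference: %s)\n",
              nrow(x), length(samples), attr(x, "reference")))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Tidy the fitted invariant-region models of a normalized table
#'
#' @param x A `medip_norm` object from [normalize_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per non-reference sample: `sample_id`,
#'   `slope`, `intercept`, `r_squared`, `n_invariant`.
#' @export
tidy.medip_norm <- function(x, ...) {
  as_tibble(attr(x, "models"))
}

#' One-row summary of a normalized MeDIP-seq dataset
#'
#' @param x A `medip_norm` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_regions`, `n_samples`, `n_invariant`,
#'   `reference`, `pseudocount`.
#' @export
glance.medip_norm <- function(x, ...) {
  tibble(n_regions = nrow(x),
         n_samples = length(setdiff(names(x), "region_id")),
         n_invariant = length(attr(x, "invariant_ids")),
         reference = attr(x, "reference"),
         pseudocount = attr(x, "pseudocount"))
}

#' Write a normalized table and its model side-car
#'
#' Writes the log2 normalized values as TSV and, when `models_path` is
#' given, the fitted invariant models as JSON
#' (`{sample, slope, intercept, r2, n_invariant}`).
#'
#' @param norm A `medip_norm` object.
#' @param path Output TSV path.
#' @param models_path Optional JSON path for the fitted models.
#' @return `path`, invisibly.
#' @export
write_normalized_table <- function(norm, path, models_path = NULL) {
  df <- as_tibble(unclass(norm))
  samples <- setdiff(names(df), "region_id")
  df <- mutate(df, across(all_of(samples), ~ round(.x, 6)))
  readr::write_tsv(df, path)
  if (!is.null(models_path)) {
    m <- as_tibble(attr(norm, "models"))
    jsonlite::write_json(
      list(reference = attr(norm, "reference"),
           pseudocount = attr(norm, "pseudocount"),
           models = m),
      models_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
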