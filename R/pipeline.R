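#' Run the full methylation-recovery pipeline
#'
#' Chains every stage — simulate (annotation, methylomes, counts), normalize,
#' recover, correlate, report — writing each stage's artifact plus a JSON run
#' report into `out_dir`. All randomness derives from `seed`, so a fixed
#' `(params, seed)` reproduces every output byte-for-byte.
#'
#' Files written: `regions.bed`, `manifest.yaml`, `counts.tsv`,
#' `truth.json`, `normalized.tsv`, `models.json`, `recovery.tsv`,
#' `class_summary.tsv`, `fraction_recovered.tsv`, `correlation.tsv`,
#' `report.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param params A [sim_params()] describing the simulated experiment.
#' @param seed Integer seed.
#' @param d_min Minimum log2 deficit for a region to be scored (default 1).
#' @param mr_threshold MR cutoff defining substantial recovery (default 50).
#' @param pseudocount Pseudocount for the log2 transform (default 0.5).
#' @param cor_classes Optional character vector of region classes the
#'   correlation matrix is restricted to (default: all regions).
#' @return Invisibly, a list with the in-memory stage results (`regions`,
#'   `truth`, `counts`, `norm`, `records`, `summary`, `fraction`,
#'   `correlation`, `report`) and `paths` to the written files.
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("run"), sim_params(n_regions = 50), seed = 1)
#' res$summary
#' }
#' @export
run_pipeline <- function(out_dir, params = sim_params(), seed = 1L,
                         d_min = 1, mr_threshold = 50, pseudocount = 0.5,
                         cor_classes = NULL) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  regions <- simulate_annotation(params, seed)
  truth <- simulate_methylomes(regions, params, seed + 1L)
  counts <- simulate_medip_counts(truth, regions, params, seed + 2L)
  write_regions(regions, p("regions.bed"))
  write_manifest(params$samples, p("manifest.yaml"))
  write_count_table(counts, p("counts.tsv"))
  jsonlite::write_json(
    list(seed = seed,
         rho = as.list(params$rho),
         methylomes = mutate(truth, across(
           all_of(params$samples$sample_id), ~ round(.x, 6)))),
    p("truth.json"), auto_unbox = TRUE, digits = NA)

  norm <- normalize_dataset(counts, regions, params$samples,
                            norm_config(pseudocount = pseudocount))
  write_normalized_table(norm, p("normalized.tsv"), p("models.json"))

  records <- recovery_table(norm, params$samples, regions, d_min = d_min)
  write_recovery_table(records, p("recovery.tsv"))
  summary <- summarize_recovery(records)
  readr::write_tsv(mutate(summary, across(c("median", "q1", "q3",
                                            "whisker_low", "whisker_high"),
                                          ~ round(.x, 6))),
                   p("class_summary.tsv"))
  promoters <- filter(records, .data$region_class == "promoter")
  fraction <- if (nrow(filter(promoters, !.data$excluded)) > 0L) {
    fraction_recovered(promoters, mr_threshold = mr_threshold)
  } else {
    fraction_recovered(records, mr_threshold = mr_threshold)
  }
  readr::write_tsv(mutate(fraction, percent = round(.data$percent, 6)),
                   p("fraction_recovered.tsv"))

  subset_ids <- if (is.null(cor_classes)) NULL else {
    regions$region_id[regions$region_class %in% cor_classes]
  }
  correlation <- spearman_matrix(norm, region_subset = subset_ids)
  write_cor_matrix(correlation, p("correlation.tsv"))

  report <- list(
    package_version = as.character(utils::packageVersion("methrecover")),
    seed = seed,
    parameters = list(d_min = d_min, mr_threshold = mr_threshold,
                      pseudocount = pseudocount,
                      n_regions_per_class = params$n_regions,
                      depth = params$depth,
                      dispersion = params$dispersion,
                      rho = as.list(params$rho)),
    n_regions = nrow(regions),
    n_invariant = sum(regions$invariant),
    n_scored = sum(!records$excluded) / length(manifest_role(params$samples,
                                                             "test")),
    models = as_tibble(attr(norm, "models")),
    class_summary = summary,
    fraction_recovered = fraction,
    spearman = tidy(correlation),
    file_checksums = as.list(tools::md5sum(
      vapply(c("regions.bed", "counts.tsv", "normalized.tsv",
               "recovery.tsv", "class_summary.tsv", "correlation.tsv"),
             p, character(1))))
  )
  names(report$file_checksums) <- basename(names(report$file_checksums))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(regions = regions, truth = truth, counts = counts,
                 norm = norm, records = records, summary = summary,
                 fraction = fraction, correlation = correlation,
                 report = report,
                 paths = setNames(
                   file.path(out_dir,
                             c("regions.bed", "manifest.yaml", "counts.tsv",
                               "truth.json", "normalized.tsv", "models.json",
                               "recovery.tsv", "class_summary.tsv",
                               "fraction_recovered.tsv", "correlation.tsv",
                               "report.json")),
                   c("regions", "manifest", "counts", "truth", "normalized",
                     "models", "recovery", "class_summary",
                     "fraction_recovered", "correlation", "report"))))
}
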