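test_that("MR hits its endpoints and interpolates linearly", {
  full <- methylation_recovery(w = 6, m0 = 4, s = 6)
  expect_equal(full$D, 2); expect_equal(full$S, 0); expect_equal(full$MR, 100)
  none <- methylation_recovery(w = 6, m0 = 4, s = 4)
  expect_equal(none$S, 2); expect_equal(none$MR, 0)
  half <- methylation_recovery(w = 6, m0 = 4, s = 5)
  expect_equal(half$MR, 50)
})

test_that("MR depends only on differences and is reported unclamped", {
  withr::with_seed(3, {
    w <- rnorm(50, 6); m0 <- w - runif(50, 1.2, 3); s <- m0 + rnorm(50)
    base <- methylation_recovery(w, m0, s)
    for (k in c(-3.7, 0.01, 12)) {
      shifted <- methylation_recovery(w + k, m0 + k, s + k)
      expect_equal(shifted$MR, base$MR, tolerance = 1e-9)
    }
  })
  # overshoot and negative recovery are reported as-is...
  expect_gt(methylation_recovery(6, 4, 7)$MR, 100)
  expect_lt(methylation_recovery(6, 4, 3)$MR, 0)
  # ...unless clamping is requested
  expect_equal(methylation_recovery(6, 4, 7, clamp = TRUE)$MR, 100)
})

test_that("regions below the deficit floor are flagged, not dropped", {
  rec <- methylation_recovery(w = c(6, 6), m0 = c(4, 5.5), s = c(5, 5.6),
                              d_min = 1)
  expect_equal(rec$excluded, c(FALSE, TRUE))
  expect_equal(rec$excluded_reason, c(NA, "low_deficit"))
  expect_true(is.na(rec$MR[2]))
  expect_equal(nrow(rec), 2L)
  expect_error(methylation_recovery(6, 6, 6, d_min = 0), "division by zero")
})

test_that("recovery_table reproduces the endpoint identities per test sample", {
  # test column copied from the reference: MR exactly 100 everywhere scored
  run <- simulate_small_run(17)
  norm <- run$norm
  norm$LSH1 <- norm$WT
  norm$K237Q3 <- norm$MSCV
  rec <- recovery_table(norm, small_params()$samples, run$ann, d_min = 1)
  lsh <- dplyr::filter(rec, sample_id == "LSH1", !excluded)
  k <- dplyr::filter(rec, sample_id == "K237Q3", !excluded)
  expect_gt(nrow(lsh), 0)
  expect_equal(lsh$MR, rep(100, nrow(lsh)))
  expect_equal(k$MR, rep(0, nrow(k)))
  # invariant anchors are never scored
  inv_ids <- run$ann$region_id[run$ann$invariant]
  expect_true(all(rec$excluded_reason[rec$region_id %in% inv_ids] == "invariant"))
})

test_that("per-region MR estimates the simulated recovery fraction", {
  params <- small_params(n_regions = 300, n_invariant = 200,
                         rho = c(LSH1 = 0.6, K237Q3 = 0.1),
                         class_bias = NULL)
  run <- simulate_small_run(23, params)
  med <- summarize_recovery(run$records)
  lsh <- dplyr::filter(med, sample_id == "LSH1")
  expect_true(all(abs(lsh$median - 60) < 10))
  k <- dplyr::filter(med, sample_id == "K237Q3")
  expect_true(all(abs(k$median - 10) < 10))
})

test_that("boxplot summaries match a sort-based quantile oracle", {
  vals <- c(40, 50, 60)
  rec <- tibble::tibble(sample_id = "S", region_id = paste0("R", 1:3),
                        region_class = "promoter", D = 2, S = 1, MR = vals,
                        excluded = FALSE, excluded_reason = NA_character_)
  s <- summarize_recovery(rec)
  expect_equal(s$median, 50)
  # degenerate distribution: everything collapses to the common value
  rec$MR <- 7
  s7 <- summarize_recovery(rec)
  expect_equal(unlist(s7[, c("median", "q1", "q3", "whisker_low",
                             "whisker_high")], use.names = FALSE),
               rep(7, 5))
  # 1000 seeded values vs an explicit sort-and-interpolate oracle
  withr::with_seed(101, {
    x <- runif(1000, -40, 140)
    recx <- tibble::tibble(sample_id = "S", region_id = paste0("R", 1:1000),
                           region_class = "gene_body", D = 2, S = 1, MR = x,
                           excluded = FALSE, excluded_reason = NA_character_)
    sx <- summarize_recovery(recx)
    qs <- function(p) { # linear interpolation of order statistics
      xs <- sort(x); h <- (length(xs) - 1) * p + 1
      lo <- floor(h); xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
    }
    expect_equal(sx$median, qs(0.5), tolerance = 1e-12)
    expect_equal(sx$q1, qs(0.25), tolerance = 1e-12)
    expect_equal(sx$q3, qs(0.75), tolerance = 1e-12)
    iqr <- qs(0.75) - qs(0.25)
    expect_equal(sx$whisker_low, min(x[x >= qs(0.25) - 1.5 * iqr]))
    expect_equal(sx$whisker_high, max(x[x <= qs(0.75) + 1.5 * iqr]))
  })
})

test_that("empty classes are omitted with a warning", {
  rec <- tibble::tibble(sample_id = "S", region_id = c("R1", "R2"),
                        region_class = c("promoter", "intergenic"),
                        D = c(2, 0.2), S = 1, MR = c(80, NA),
                        excluded = c(FALSE, TRUE),
                        excluded_reason = c(NA, "low_deficit"))
  expect_warning(s <- summarize_recovery(rec), "omitted")
  expect_equal(s$region_class, "promoter")
})

test_that("fraction_recovered reports percent plus counts", {
  rec <- tibble::tibble(sample_id = "S", region_id = paste0("R", 1:3),
                        region_class = "promoter", D = 2, S = 1,
                        MR = c(100, 80, 10),
                        excluded = FALSE, excluded_reason = NA_character_)
  fr <- fraction_recovered(rec, mr_threshold = 50)
  expect_equal(fr$percent, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(fr$n_pass, 2L); expect_equal(fr$n_total, 3L)
  expect_equal(fraction_recovered(rec, mr_threshold = 5)$percent, 100)
  expect_equal(fraction_recovered(rec, mr_threshold = 101)$percent, 0)
  expect_error(fraction_recovered(rec[0, ]), "no scored")
})

test_that("Spearman matrix is rank-invariant, symmetric, and flags constants", {
  x <- c(0.3, 1.8, 0.9, 2.4, 1.1, 0.2, 3.3, 2.0)
  tab <- tibble::tibble(region_id = paste0("R", seq_along(x)),
                        A = x, B = exp(x), C = -x^3)
  m <- spearman_matrix(tab)
  expect_equal(m["A", "B"], 1)
  expect_equal(m["A", "C"], -1)
  expect_identical(unclass(m), t(unclass(m)))
  expect_equal(diag(unclass(m)), c(A = 1, B = 1, C = 1))
  tab$D <- 5
  md <- spearman_matrix(tab)
  expect_true(is.na(md["A", "D"]))
  expect_equal(md["D", "D"], 1)
  expect_equal(attr(md, "undefined_samples"), "D")
})

test_that("Spearman with ties matches an explicit average-rank oracle", {
  withr::with_seed(202, {
    for (rep in 1:100) {
      n <- sample(5:40, 1)
      # coarse rounding forces ties
      a <- round(rnorm(n), sample(0:1, 1))
      b <- round(a + rnorm(n, 0, runif(1, 0.1, 2)), sample(0:1, 1))
      if (sd(a) == 0 || sd(b) == 0) next
      tab <- tibble::tibble(region_id = paste0("R", 1:n), A = a, B = b)
      expect_equal(spearman_matrix(tab)["A", "B"], spearman_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("samples with identical methylomes correlate above 0.95 at full depth", {
  params <- sim_params(n_regions = 500,
                       classes = c("promoter", "gene_body", "intergenic",
                                   "repeat:IAP"),
                       rho = c(LSH1 = 1, K237Q3 = 1), class_bias = NULL,
                       loss_fraction = 0)
  ann <- simulate_annotation(params, 41)
  truth <- simulate_methylomes(ann, params, 42)
  counts <- simulate_medip_counts(truth, ann, params, 43)
  m <- spearman_matrix(normalize_dataset(counts, ann, params$samples))
  expect_gte(min(m[upper.tri(m)]), 0.95)
})

test_that("recovery tables round-trip through their TSV export", {
  run <- simulate_small_run(61)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recovery_table(run$records, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(run$records))
  expect_equal(back$MR, run$records$MR, tolerance = 1e-5)
  g <- withr::local_tempfile(fileext = ".tsv")
  cm <- spearman_matrix(run$norm)
  write_cor_matrix(cm, g)
  back_cm <- readr::read_tsv(g, show_col_types = FALSE)
  expect_equal(back_cm$WT, unname(unclass(cm)[, "WT"]), tolerance = 1e-5)
})
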