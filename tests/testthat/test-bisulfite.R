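test_that("global alignment scores identity and the worked gap case", {
  ident <- align_global("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(ident$score, 10)
  expect_false(grepl("-", ident$aligned_query, fixed = TRUE))
  gap <- align_global("ACTAC", "ACGTAC")
  expect_equal(gap$score, 3) # 5 matches - one 1 bp gap
  expect_equal(nchar(gap$aligned_ref), 6L)
  expect_equal(sum(strsplit(gap$aligned_query, "")[[1]] == "-"), 1L)
  expect_error(align_global("", "ACGT"), "non-empty")
  expect_error(align_global("ACGT", "ACXT"), "alphabet")
})

test_that("alignment scores equal brute-force enumeration over all paths", {
  # every pair over {A,C,G,T} up to length 2, plus seeded longer pairs
  short <- c("A", "C", "G", "T",
             apply(expand.grid(c("A", "C", "G", "T"),
                               c("A", "C", "G", "T")), 1, paste0,
                   collapse = ""))
  for (a in short) for (b in short) {
    expect_equal(align_global(a, b)$score, alignment_score_oracle(a, b))
  }
  withr::with_seed(303, {
    for (rep in 1:100) {
      a <- random_seq(sample(3:6, 1))
      b <- random_seq(sample(3:6, 1))
      expect_equal(align_global(a, b)$score, alignment_score_oracle(a, b))
    }
  })
})

test_that("alignment scores agree with an independent aligner", {
  withr::with_seed(304, {
    for (rep in 1:25) {
      ref <- random_seq(40)
      # clone: reference with a few substitutions
      cl <- strsplit(ref, "")[[1]]
      idx <- sample(40, 4)
      cl[idx] <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
      clone <- paste(cl, collapse = "")
      got <- align_global(clone, ref)$score
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
      want <- Biostrings::pairwiseAlignment(
        clone, ref, type = "global", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
      expect_equal(got, want)
    }
  })
})

test_that("alignment and traceback are deterministic across runs", {
  a1 <- align_global("ACGTAGGAT", "ACGTTAGAT")
  a2 <- align_global("ACGTAGGAT", "ACGTTAGAT")
  expect_identical(a1, a2)
})

test_that("methylation calls read off CpG cytosines of the unconverted reference", {
  amp <- amplicon("toy", "ACCGT") # CpG C at index 2, non-CpG C at index 1
  meth <- call_methylation(align_global("ATCGT", "ACCGT"), amp, "c1")
  expect_equal(meth$states[[1]], "methylated")
  expect_equal(meth$conversion_rate, 1)
  unmeth <- call_methylation(align_global("ATTGT", "ACCGT"), amp, "c2")
  expect_equal(unmeth$states[[1]], "unmethylated")
  expect_equal(unmeth$conversion_rate, 1)
  # wrong reference in the alignment is refused
  expect_error(call_methylation(align_global("ATCGT", "AACGT"), amp), "match")
})

test_that("conversion rate counts converted non-CpG cytosines", {
  # reference has 3 non-CpG Cs; clone converts 2 of them
  amp <- amplicon("toy3", "ACACACGTAC")
  expect_equal(amp$cpg_positions, 5L)
  clone <- "ATACATGTAC" # C1 -> T, CpG C -> T (unmethylated), C9 kept, C3 kept
  got <- call_methylation(align_global(clone, amp$reference_sequence), amp)
  expect_equal(got$states[[1]], "unmethylated")
  expect_equal(got$conversion_rate, 1 / 3, tolerance = 1e-12)
  # 2 of 3 converted
  clone2 <- "ATATACGTAC"
  got2 <- call_methylation(align_global(clone2, amp$reference_sequence), amp)
  expect_equal(got2$conversion_rate, 2 / 3, tolerance = 1e-12)
  expect_equal(got2$states[[1]], "methylated")
})

test_that("gaps and foreign bases at CpG positions yield missing calls", {
  amp <- amplicon("toy", "AACGTTACGT")
  clone <- "AACGTTAGT" # deletion removes the second CpG C
  got <- call_methylation(align_global(clone, amp$reference_sequence), amp)
  expect_equal(got$states[[1]], c("methylated", "missing"))
})

test_that("build_pattern tabulates the hand-counted example and applies QC", {
  amp <- amplicon("two", "TTCGATTCGA")
  mk_call <- function(id, states, conv = 1, idn = 1) {
    tibble::tibble(clone_id = id, amplicon = "two", aligned = TRUE,
                   conversion_rate = conv, identity = idn,
                   n_methylated = sum(states == "methylated"),
                   n_unmethylated = sum(states == "unmethylated"),
                   n_missing = sum(states == "missing"),
                   states = list(states))
  }
  m <- "methylated"; u <- "unmethylated"
  calls <- dplyr::bind_rows(mk_call("a", c(m, m)), mk_call("b", c(m, u)),
                            mk_call("c", c(u, m)))
  pat <- build_pattern(calls, amp)
  expect_equal(pat$overall_percent, 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(pat$per_cpg$percent, c(100 * 2 / 3, 100 * 2 / 3),
               tolerance = 1e-12)
  # a clone failing conversion QC is excluded with the right reason
  calls2 <- dplyr::bind_rows(calls, mk_call("bad", c(m, m), conv = 0.5))
  pat2 <- build_pattern(calls2, amp)
  expect_equal(nrow(pat2$states), 3L)
  expect_equal(pat2$calls$exclude_reason[pat2$calls$clone_id == "bad"],
               "conversion")
  expect_equal(pat2$overall_percent, pat$overall_percent)
  # all excluded: error names the dominant reason
  expect_error(build_pattern(mk_call("x", c(m, m), conv = 0.2), amp),
               "conversion")
})

test_that("overall percent is the call-count weighted mean of per-CpG percents", {
  amp <- simulate_amplicon(seed = 9)
  sim <- simulate_bisulfite_clones(amp, p_meth = runif(12), n_clones = 30,
                                   conversion_failure = 0.01,
                                   seq_error = 0.01, seed = 10)
  pat <- analyze_clones(amp, sim$clones)
  per <- pat$per_cpg
  wmean <- sum(per$percent * (per$n_methylated + per$n_unmethylated)) /
    sum(per$n_methylated + per$n_unmethylated)
  expect_equal(pat$overall_percent, wmean, tolerance = 1e-12)
})

test_that("pattern comparison reports differences with a bootstrap interval", {
  amp <- simulate_amplicon(seed = 21)
  lo <- analyze_clones(amp, simulate_bisulfite_clones(
    amp, p_meth = 0, n_clones = 12, conversion_failure = 0,
    seq_error = 0, seed = 22)$clones)
  hi <- analyze_clones(amp, simulate_bisulfite_clones(
    amp, p_meth = 1, n_clones = 12, conversion_failure = 0,
    seq_error = 0, seed = 23)$clones)
  expect_equal(compare_patterns(lo, lo, n_boot = 50, seed = 1)$difference, 0)
  ext <- compare_patterns(lo, hi, n_boot = 50, seed = 1)
  expect_equal(ext$difference, 100)
  mid <- analyze_clones(amp, simulate_bisulfite_clones(
    amp, p_meth = 0.5, n_clones = 40, conversion_failure = 0,
    seq_error = 0, seed = 24)$clones)
  cmp <- compare_patterns(lo, mid, n_boot = 400, seed = 2)
  expect_lt(cmp$conf_low, cmp$difference)
  expect_gt(cmp$conf_high, cmp$difference)
  amp2 <- simulate_amplicon(name = "other", seed = 31)
  other <- analyze_clones(amp2, simulate_bisulfite_clones(
    amp2, 0.5, n_clones = 5, seed = 32)$clones)
  expect_error(compare_patterns(lo, other), "different amplicons")
})

test_that("bootstrap interval covers the simulated truth in most replications", {
  amp <- simulate_amplicon(length_bp = 120, n_cpg = 6, seed = 51)
  true_diff <- 100 * (0.8 - 0.3)
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    a <- analyze_clones(amp, simulate_bisulfite_clones(
      amp, 0.3, n_clones = 20, conversion_failure = 0, seq_error = 0,
      seed = 1000 + r)$clones)
    b <- analyze_clones(amp, simulate_bisulfite_clones(
      amp, 0.8, n_clones = 20, conversion_failure = 0, seq_error = 0,
      seed = 2000 + r)$clones)
    ci <- compare_patterns(a, b, n_boot = 200, seed = r)
    if (ci$conf_low <= true_diff && true_diff <= ci$conf_high) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("lollipop text rendering is a stable direct mapping", {
  amp <- amplicon("two", "TTCGATTCGA")
  m <- "methylated"; u <- "unmethylated"
  call <- tibble::tibble(clone_id = "c1", amplicon = "two", aligned = TRUE,
                         conversion_rate = 1, identity = 1,
                         n_methylated = 1L, n_unmethylated = 1L,
                         n_missing = 0L, states = list(c(m, u)))
  pat <- build_pattern(call, amp)
  expect_identical(render_lollipop_text(pat),
                   c(c1 = "●○"))
  expect_identical(render_lollipop_text(pat), render_lollipop_text(pat))
  expect_equal(length(render_lollipop_text(pat)), nrow(pat$states))
})

test_that("clone FASTA files round-trip and feed the full analysis", {
  amp <- simulate_amplicon(seed = 71)
  sim <- simulate_bisulfite_clones(amp, 0.6, n_clones = 8, seed = 72)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$clones, f)
  expect_identical(read_fasta(f), sim$clones)
  ref_f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(stats::setNames(amp$reference_sequence, amp$name), ref_f)
  pat <- analyze_clones(ref_f, f)
  expect_equal(nrow(pat$calls), 8L)
})
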