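# Small fixtures shared across test files; everything is built in code.

toy_regions <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(0L, 1000L, 3000L, 6000L, 10000L),
    end = c(500L, 2000L, 5000L, 9000L, 12000L),
    region_id = paste0("R", 1:5),
    region_class = c("promoter", "gene_body", "intergenic",
                     "repeat:IAP", "intergenic"),
    strand = NA_character_,
    invariant = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

toy_counts <- function() {
  out <- tibble::tibble(region_id = paste0("R", 1:5),
                        WT = c(10L, 40L, 25L, 80L, 60L),
                        MSCV = c(3L, 12L, 30L, 20L, 55L))
  attr(out, "library_size") <- c(WT = 1000, MSCV = 900)
  out
}

# normalized table where the recovery answer is known by construction
toy_norm <- function(test_values, w = c(6, 7, 5, 8),
                     m0 = c(4, 5, 4.5, 5)) {
  tibble::tibble(region_id = paste0("R", seq_along(w)),
                 WT = w, MSCV = m0, T1 = test_values)
}

toy_manifest <- function() {
  manifest(c("WT", "MSCV", "T1"), c("reference", "baseline", "test"))
}

# small simulation preset used wherever a full dataset is needed quickly
small_params <- function(...) {
  args <- list(n_regions = 60,
               classes = c("promoter", "gene_body", "intergenic",
                           "repeat:IAP"),
               n_invariant = 40)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

simulate_small_run <- function(seed, params = small_params(), d_min = 1) {
  ann <- simulate_annotation(params, seed)
  truth <- simulate_methylomes(ann, params, seed + 1L)
  counts <- simulate_medip_counts(truth, ann, params, seed + 2L)
  norm <- normalize_dataset(counts, ann, params$samples)
  list(ann = ann, truth = truth, counts = counts, norm = norm,
       records = recovery_table(norm, params$samples, ann, d_min = d_min))
}

# brute-force per-base overlap oracle for interval counting
brute_force_counts <- function(reads, regions, min_overlap_bp = 1L) {
  vapply(seq_len(nrow(regions)), function(i) {
    same <- reads[reads$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(0L)
    ov <- pmin(same$end, regions$end[i]) - pmax(same$start, regions$start[i])
    sum(ov >= min_overlap_bp)
  }, integer(1))
}

# explicit average-rank Spearman oracle
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    s <- sort(v)
    vapply(v, function(vi) mean(which(s == vi)), numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive global-alignment score oracle (enumerates every alignment path)
alignment_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
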