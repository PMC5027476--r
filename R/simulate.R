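#' Simulation parameters for a methylation-rescue experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the study design the pipeline targets: a wild-type reference methylome, a
#' null baseline that has lost most methylation at the factor-dependent
#' regions, and rescue samples that regain a class-dependent fraction of the
#' lost signal. Counts are overdispersed (negative binomial) around a mean
#' proportional to region length, sequencing depth and methylation, with a
#' per-sample library factor the normalization has to remove.
#'
#' The true recovery fraction `rho` of a test sample is defined on the scale
#' the MR statistic measures: the test sample's expected MeDIP signal
#' interpolates geometrically between baseline and wild-type,
#' `q_test = q_baseline^(1-rho) * q_wt^rho`, so `rho` is exactly the
#' fraction of the log2 deficit regained and MR estimates `100 * rho`.
#'
#' @param n_regions Regions simulated per class (default 500).
#' @param classes Region classes; defaults to promoters, gene bodies,
#'   intergenic blocks and four repeat families.
#' @param length_range Named list of `c(min, max)` region lengths in bp per
#'   class; the entry `default` covers classes without their own entry.
#'   Lengths are floored at 200 bp (sonication-fragment scale).
#' @param fraction_lsh_dependent Fraction of regions per class whose
#'   methylation depends on the rescued factor (scalar, or named vector with
#'   a `default` entry).
#' @param wt_meth_shape Beta shape parameters for wild-type methylation
#'   levels (default `c(8, 2)`, mean 0.8).
#' @param loss_fraction Fraction of wild-type methylation lost in the
#'   baseline at dependent regions (default 0.9: dependent regions are
#'   essentially unmethylated in the null).
#' @param samples Sample manifest tibble (default [default_manifest()]).
#' @param rho Named vector mapping each test sample to its true recovery
#'   fraction in \[0, 1\].
#' @param class_bias Named list (per test sample) of named multipliers on
#'   `rho` per region class; effective recovery is clamped to \[0, 1\].
#'   Defaults emulate a wild-type rescue favoring gene bodies and a mutant
#'   rescue favoring intergenic regions.
#' @param depth Expected reads per kb-region at methylation 1 and library
#'   factor 1 (default 200).
#' @param dispersion Negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson. Default 0.2.
#' @param background Unmethylated pulldown rate: expected signal is
#'   `background + (1 - background) * methylation`. Default 0.05.
#' @param region_effect_range Range, in log2 units, of a per-region
#'   enrichment factor drawn uniformly and shared by all samples: CpG
#'   density, mappability and repeat copy number make region-level MeDIP
#'   coverage span orders of magnitude (default `c(-3, 8)`, a mappability
#'   floor of 1/8 up to ~250-fold copy-number amplification). Being shared,
#'   it cancels out of every between-sample difference, but it gives the
#'   invariant-region regression and the rank correlations the dynamic
#'   range real count tables have.
#' @param library_factor_range Per-sample depth multipliers are drawn
#'   log-uniformly from this range (default `c(0.5, 2)`).
#' @param n_invariant Number of non-dependent regions flagged as invariant
#'   normalization anchors (default 500; control sets derived from
#'   genome-wide comparisons are of this scale, and the affine fit must be
#'   anchored tightly enough to extrapolate below the anchor mean).
#' @param n_clones Clones per simulated bisulfite amplicon (default 20).
#' @param conversion_failure Probability an unmethylated C escapes
#'   bisulfite conversion (default 0.01).
#' @param seq_error Per-base sequencing error rate in clones
#'   (default 0.001).
#' @param ct_noise_sd Gaussian noise on simulated Ct values, in cycles
#'   (default 0.1).
#' @param hplc_noise_cv Lognormal coefficient of variation of simulated HPLC
#'   peak areas (default 0.02).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_regions = 500,
                       classes = c("promoter", "gene_body", "intergenic",
                                   "repeat:IAP", "repeat:LINE",
                                   "repeat:minor_satellite",
                                   "repeat:major_satellite"),
                       length_range = list(promoter = c(500, 2000),
                                           gene_body = c(2000, 10000),
                                           intergenic = c(1000, 5000),
                                           default = c(1000, 6000)),
                       fraction_lsh_dependent = 0.7,
                       wt_meth_shape = c(8, 2),
                       loss_fraction = 0.9,
                       samples = default_manifest(),
                       rho = c(LSH1 = 0.6, K237Q3 = 0.1),
                       class_bias = list(
                         LSH1 = c(gene_body = 1.15, intergenic = 0.85),
                         K237Q3 = c(gene_body = 0.7, intergenic = 1.3)),
                       depth = 200,
                       dispersion = 0.2,
                       background = 0.05,
                       region_effect_range = c(-3, 8),
                       library_factor_range = c(0.5, 2),
                       n_invariant = 500,
                       n_clones = 20,
                       conversion_failure = 0.01,
                       seq_error = 0.001,
                       ct_noise_sd = 0.1,
                       hplc_noise_cv = 0.02) {
  samples <- validate_manifest(samples)
  tests <- manifest_role(samples, "test")
  missing_rho <- setdiff(tests, names(rho))
  if (length(missing_rho) > 0L) {
    abort(paste0("rho missing for test sample(s): ",
                 paste(missing_rho, collapse = ", ")))
  }
  stopifnot(
    n_regions >= 1, length(classes) >= 1,
    all(rho >= 0 & rho <= 1),
    loss_fraction >= 0, loss_fraction <= 1,
    depth > 0, dispersion >= 0,
    background >= 0, background < 1,
    length(region_effect_range) == 2L,
    region_effect_range[1L] <= region_effect_range[2L],
    length(library_factor_range) == 2L,
    all(library_factor_range > 0),
    n_invariant >= 3,
    conversion_failure >= 0, conversion_failure <= 1,
    seq_error >= 0, seq_error <= 1,
    ct_noise_sd >= 0, hplc_noise_cv >= 0
  )
  frac <- fraction_lsh_dependent
  if (is.null(names(frac))) {
    frac <- c(default = unname(frac[1L]))
  }
  if (any(frac < 0 | frac > 1)) {
    abort("fraction_lsh_dependent must lie in [0, 1]")
  }
  structure(list(
    n_regions = as.integer(n_regions), classes = classes,
    length_range = length_range,
    fraction_lsh_dependent = frac,
    wt_meth_shape = wt_meth_shape, loss_fraction = loss_fraction,
    samples = samples, rho = rho, class_bias = class_bias,
    depth = depth, dispersion = dispersion, background = background,
    region_effect_range = region_effect_range,
    library_factor_range = library_factor_range,
    n_invariant = as.integer(n_invariant),
    n_clones = as.integer(n_clones),
    conversion_failure = conversion_failure, seq_error = seq_error,
    ct_noise_sd = ct_noise_sd, hplc_noise_cv = hplc_noise_cv
  ), class = "sim_params")
}

#' Default four-sample manifest of a rescue experiment
#'
#' Wild-type reference, empty-vector baseline and two rescue test lines
#' (an active-factor rescue and a catalytically dead point-mutant rescue).
#'
#' @return A manifest tibble.
#' @export
default_manifest <- function() {
  manifest(sample_id = c("WT", "MSCV", "LSH1", "K237Q3"),
           role = c("reference", "baseline", "test", "test"),
           label = c("wild-type", "null + empty vector",
                     "null + active rescue", "null + K237Q mutant"))
}

class_lookup <- function(map, class, what) {
  if (class %in% names(map)) map[[class]]
  else if ("default" %in% names(map)) map[["default"]]
  else abort(paste0("no ", what, " entry for class '", class,
                    "' and no default"))
}

#' Simulate a region annotation
#'
#' Lays out `n_regions` regions per class end-to-end (with random gaps) on
#' one synthetic chromosome per class, draws region lengths from the
#' class-specific ranges, marks the factor-dependent regions and flags
#' `n_invariant` of the non-dependent regions as invariant normalization
#' anchors. Deterministic for a fixed `(params, seed)`.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A regions tibble with the extra logical column `lsh_dependent`
#'   (the truth-table skeleton); invariant regions are never
#'   factor-dependent.
#' @export
simulate_annotation <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    per_class <- lapply(seq_along(params$classes), function(ci) {
      cls <- params$classes[ci]
      rng <- class_lookup(params$length_range, cls, "length_range")
      len <- pmax(200L, as.integer(round(runif(params$n_regions,
                                               rng[1L], rng[2L]))))
      gaps <- as.integer(round(runif(params$n_regions, 100, 1000)))
      start <- cumsum(c(0L, head(len + gaps, -1L)))
      frac <- class_lookup(params$fraction_lsh_dependent, cls,
                           "fraction_lsh_dependent")
      tibble(chrom = sprintf("chrS%d", ci),
             start = start,
             end = start + len,
             region_id = sprintf("%s_%04d",
                                 gsub("[^A-Za-z0-9]+", "_", cls),
                                 seq_len(params$n_regions)),
             region_class = cls,
             strand = NA_character_,
             invariant = FALSE,
             lsh_dependent = runif(params$n_regions) < frac)
    })
    regions <- bind_rows(per_class)
    pool <- which(!regions$lsh_dependent)
    if (length(pool) < params$n_invariant) {
      abort(sprintf(
        "only %d non-dependent regions available for %d invariant anchors; lower fraction_lsh_dependent or n_invariant",
        length(pool), params$n_invariant))
    }
    regions$invariant[sample(pool, params$n_invariant)] <- TRUE
    regions
  })
}

#' Simulate true methylomes for every sample
#'
#' Wild-type methylation is drawn per region from `Beta(wt_meth_shape)`,
#' except at invariant anchor regions, whose common level is uniform on
#' \[0, 1\]: a useful control set spans the whole methylation range, from
#' constitutively unmethylated CpG islands to fully methylated repeats, so
#' the normalization regression is anchored across its entire dynamic
#' range. The baseline keeps wild-type methylation at non-dependent regions
#' and loses `loss_fraction` of it at dependent regions. Each test sample's expected MeDIP signal interpolates
#' geometrically between baseline and wild-type with its effective recovery
#' `rho * class_bias` (clamped to \[0, 1\]), and the methylation level is
#' back-computed from that signal. Invariant regions are identical across
#' all samples by construction.
#'
#' @param annotation Regions tibble from [simulate_annotation()].
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A truth tibble: `region_id`, `region_class`, `lsh_dependent`,
#'   `invariant`, plus one methylation column (in \[0, 1\]) per sample.
#' @export
simulate_methylomes <- function(annotation, params, seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!"lsh_dependent" %in% names(annotation)) {
    abort("annotation must carry the lsh_dependent column from simulate_annotation()")
  }
  m <- params$samples
  reference <- manifest_role(m, "reference")
  baseline <- manifest_role(m, "baseline")
  tests <- manifest_role(m, "test")
  bg <- params$background
  q_of <- function(meth) bg + (1 - bg) * meth
  meth_of <- function(q) (q - bg) / (1 - bg)
  withr::with_seed(seed, {
    n <- nrow(annotation)
    wt <- rbeta(n, params$wt_meth_shape[1L], params$wt_meth_shape[2L])
    wt[annotation$invariant] <- runif(sum(annotation$invariant))
    m0 <- ifelse(annotation$lsh_dependent & !annotation$invariant,
                 wt * (1 - params$loss_fraction), wt)
    out <- tibble(region_id = annotation$region_id,
                  region_class = annotation$region_class,
                  lsh_dependent = annotation$lsh_dependent &
                    !annotation$invariant,
                  invariant = annotation$invariant)
    out[[reference]] <- wt
    out[[baseline]] <- m0
    for (s in tests) {
      bias <- params$class_bias[[s]]
      mult <- if (is.null(bias)) rep(1, n) else {
        ifelse(out$region_class %in% names(bias),
               unname(bias[out$region_class]), 1)
      }
      rho_eff <- pmin(pmax(params$rho[[s]] * mult, 0), 1)
      q_test <- q_of(m0)^(1 - rho_eff) * q_of(wt)^rho_eff
      out[[s]] <- meth_of(q_test)
    }
    out
  })
}

#' Simulate a MeDIP-seq count table from true methylomes
#'
#' Counts are negative-binomial with mean
#' `library_factor * enrichment * (length / 1000) * depth * (background +
#' (1 - background) * methylation)` and variance `mu + dispersion * mu^2`
#' (Poisson when `dispersion = 0`). One library factor per sample is drawn
#' log-uniformly from `library_factor_range`, forcing the invariant-region
#' normalization to do real work; one enrichment factor per region
#' (log2-uniform over `region_effect_range`) is shared by all samples,
#' giving the count table the region-to-region dynamic range of real MeDIP
#' data while cancelling out of every recovery statistic.
#'
#' @param truth Truth tibble from [simulate_methylomes()].
#' @param annotation Regions tibble supplying lengths.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A count table tibble (`region_id` plus one column per sample)
#'   with `library_size` and `library_factor` attributes.
#' @export
simulate_medip_counts <- function(truth, annotation, params, seed) {
  stopifnot(inherits(params, "sim_params"))
  len <- region_lengths(annotation)[truth$region_id]
  samples <- params$samples$sample_id
  withr::with_seed(seed, {
    lf <- exp(runif(length(samples),
                    log(params$library_factor_range[1L]),
                    log(params$library_factor_range[2L])))
    names(lf) <- samples
    enrichment <- 2^runif(nrow(truth), params$region_effect_range[1L],
                          params$region_effect_range[2L])
    out <- tibble(region_id = truth$region_id)
    for (s in samples) {
      mu <- lf[[s]] * enrichment * (len / 1000) * params$depth *
        (params$background + (1 - params$background) * truth[[s]])
      out[[s]] <- if (params$dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
      }
    }
    attr(out, "library_size") <-
      setNames(vapply(samples, function(s) sum(out[[s]]), numeric(1)),
               samples)
    attr(out, "library_factor") <- lf
    out
  })
}

#' Emit read intervals realizing a target per-region count
#'
#' Companion generator for exercising [count_reads_in_regions()]: for each
#' region, draws the requested number of fixed-length reads uniformly placed
#' so that each read lies entirely inside its region.
#'
#' @param regions A regions tibble.
#' @param counts Named integer vector (by `region_id`) of reads to emit per
#'   region; regions longer than `read_length` only.
#' @param read_length Read length in bp (default 50).
#' @param seed Integer seed.
#' @return A tibble of read intervals (`chrom`, `start`, `end`), shuffled.
#' @export
simulate_reads <- function(regions, counts, read_length = 50L, seed = 1L) {
  regions <- validate_regions(regions)
  counts <- counts[regions$region_id]
  counts[is.na(counts)] <- 0L
  if (any(counts > 0 & (regions$end - regions$start) < read_length)) {
    abort("some regions are shorter than read_length")
  }
  withr::with_seed(seed, {
    reads <- bind_rows(lapply(which(counts > 0), function(i) {
      k <- counts[[i]]
      start <- as.integer(floor(runif(
        k, regions$start[i], regions$end[i] - read_length + 1)))
      tibble(chrom = regions$chrom[i], start = start,
             end = start + as.integer(read_length))
    }))
    if (nrow(reads) > 0L) reads <- reads[sample.int(nrow(reads)), ]
    reads
  })
}

#' Simulate a random bisulfite amplicon
#'
#' Random A/C/G/T sequence with `n_cpg` CpG dinucleotides planted at spaced
#' positions (any additional CpGs arising by chance are detected and used
#' too).
#'
#' @param length_bp Amplicon length (default 250).
#' @param n_cpg Number of planted CpGs (default 12).
#' @param name Amplicon name.
#' @param seed Integer seed.
#' @return An [amplicon()].
#' @export
simulate_amplicon <- function(length_bp = 250L, n_cpg = 12L,
                              name = "sim_amplicon", seed = 1L) {
  if (length_bp < 4L * n_cpg + 4L) abort("amplicon too short for n_cpg CpGs")
  withr::with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
    # spaced CpG sites, with a non-G base after each to keep them distinct
    slots <- floor(seq(2L, length_bp - 2L, length.out = n_cpg))
    bases[slots] <- "C"
    bases[slots + 1L] <- "G"
    bases[slots - 1L][bases[slots - 1L] == "C"] <- "A"
    bases[slots + 2L][bases[slots + 2L] == "G"] <- "T"
    amplicon(name, paste(bases, collapse = ""))
  })
}

#' Simulate bisulfite clone sequences
#'
#' Each clone is derived from the amplicon's unconverted reference: the C of
#' CpG number *k* is methylated (kept as C) with probability `p_meth[k]`,
#' unmethylated Cs (CpG or not) convert to T except with probability
#' `conversion_failure`, and every base is finally substituted uniformly at
#' random with probability `seq_error`.
#'
#' @param amp An [amplicon()].
#' @param p_meth Per-CpG methylation probabilities (recycled to the number
#'   of CpGs).
#' @param n_clones Number of clones.
#' @param conversion_failure Probability an unmethylated C stays C.
#' @param seq_error Per-base substitution error rate.
#' @param seed Integer seed.
#' @return A list: `clones` (named character vector of clone sequences) and
#'   `truth` (clones-by-CpG logical matrix of simulated methylation).
#' @export
simulate_bisulfite_clones <- function(amp, p_meth, n_clones = 20L,
                                      conversion_failure = 0.01,
                                      seq_error = 0.001, seed = 1L) {
  stopifnot(inherits(amp, "amplicon"))
  p_meth <- rep_len(p_meth, length(amp$cpg_positions))
  if (any(p_meth < 0 | p_meth > 1)) abort("p_meth must lie in [0, 1]")
  ref <- strsplit(amp$reference_sequence, "", fixed = TRUE)[[1L]]
  cpg_idx <- amp$cpg_positions + 1L
  other_c <- setdiff(which(ref == "C"), cpg_idx)
  withr::with_seed(seed, {
    truth <- matrix(FALSE, n_clones, length(cpg_idx),
                    dimnames = list(sprintf("clone_%02d", seq_len(n_clones)),
                                    paste0("CpG", seq_along(cpg_idx))))
    clones <- vapply(seq_len(n_clones), function(i) {
      s <- ref
      meth <- runif(length(cpg_idx)) < p_meth
      truth[i, ] <<- meth
      # unmethylated CpG cytosines convert unless the chemistry fails
      unmeth <- cpg_idx[!meth]
      escaped <- runif(length(unmeth)) < conversion_failure
      s[unmeth[!escaped]] <- "T"
      conv <- runif(length(other_c)) >= conversion_failure
      s[other_c[conv]] <- "T"
      if (seq_error > 0) {
        hit <- which(runif(length(s)) < seq_error)
        for (j in hit) {
          s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1L)
        }
      }
      paste(s, collapse = "")
    }, character(1))
    names(clones) <- rownames(truth)
    list(clones = clones, truth = truth)
  })
}

#' Simulate qPCR and HPLC assay measurements
#'
#' Generates the inputs of the two closed-form calculators together with
#' their truth. qPCR: for each entry of `fold_changes` a measurement with
#' the given efficiencies whose noiseless Pfaffl ratio equals the true fold
#' change; Gaussian cycle noise of sd `ct_noise_sd` is added to each delta
#' Ct. HPLC: for each entry of `percent_5mc`, peak areas proportional to
#' molar amount times extinction coefficient with lognormal noise of
#' coefficient of variation `hplc_noise_cv`.
#'
#' @param params A [sim_params()] (supplies the noise levels).
#' @param seed Integer seed.
#' @param fold_changes Named vector of true expression fold changes.
#' @param percent_5mc Named vector of true percent-5mC values (defaults:
#'   wild-type 3.3 percent of cytosines, null at about half of that, rescue
#'   at about three quarters of wild-type).
#' @param e_target,e_ref Amplification efficiencies used for the simulated
#'   qPCR assays.
#' @return A list with tibbles `qpcr` (one row per target:
#'   `target`, `e_target`, `delta_ct_target`, `e_ref`, `delta_ct_ref`) and
#'   `hplc` (`sample_id`, `area_c`, `area_5mc`, `eps_c`, `eps_5mc`), plus
#'   `truth`.
#' @export
simulate_assays <- function(params, seed,
                            fold_changes = c(IAP = 0.1, Rhox2a = 0.05,
                                             Rhox6 = 0.08, Gm9 = 0.2),
                            percent_5mc = c(WT = 3.3, MSCV = 1.7,
                                            LSH1 = 2.5, K237Q3 = 1.8),
                            e_target = 1.95, e_ref = 2.0) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    n_q <- length(fold_changes)
    dct_ref <- rnorm(n_q, 0, params$ct_noise_sd)
    dct_t <- log(fold_changes * e_ref^0) / log(e_target) +
      rnorm(n_q, 0, params$ct_noise_sd)
    qpcr <- tibble(target = names(fold_changes),
                   e_target = e_target,
                   delta_ct_target = unname(dct_t),
                   e_ref = e_ref,
                   delta_ct_ref = unname(dct_ref))
    sdlog <- sqrt(log(1 + params$hplc_noise_cv^2))
    n_h <- length(percent_5mc)
    total_nmol <- 100 # arbitrary cytosine pool; percent is scale-invariant
    n_5mc <- total_nmol * percent_5mc / 100
    n_c <- total_nmol - n_5mc
    hplc <- tibble(sample_id = names(percent_5mc),
                   area_c = unname(n_c * 8.86e3 * rlnorm(n_h, 0, sdlog)),
                   area_5mc = unname(n_5mc * 9.0e3 * rlnorm(n_h, 0, sdlog)),
                   eps_c = 8.86e3,
                   eps_5mc = 9.0e3)
    list(qpcr = qpcr, hplc = hplc,
         truth = list(fold_changes = fold_changes,
                      percent_5mc = percent_5mc))
  })
}
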