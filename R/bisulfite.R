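#' Define a bisulfite amplicon
#'
#' An amplicon couples the unconverted genomic reference sequence with the
#' 0-based positions of the C of every CpG dinucleotide. Clone reads are
#' compared against this unconverted reference: bisulfite chemistry converts
#' unmethylated C to T, so a retained C at a CpG position reads out
#' methylation directly.
#'
#' @param name Amplicon name.
#' @param reference_sequence Uppercase A/C/G/T genomic sequence.
#' @param cpg_positions Optional integer vector of 0-based positions of CpG
#'   cytosines; found automatically from the sequence when `NULL`.
#' @return A list of class `amplicon` with elements `name`,
#'   `reference_sequence`, `cpg_positions`.
#' @examples
#' amplicon("toy", "ACGTACGT")$cpg_positions  # 1 5
#' @export
amplicon <- function(name, reference_sequence, cpg_positions = NULL) {
  reference_sequence <- toupper(reference_sequence)
  if (!grepl("^[ACGT]+$", reference_sequence)) {
    abort("reference_sequence must contain only A/C/G/T")
  }
  found <- as.integer(gregexpr("CG", reference_sequence, fixed = TRUE)[[1L]])
  found <- if (found[1L] == -1L) integer(0) else found - 1L
  if (is.null(cpg_positions)) {
    cpg_positions <- found
  } else {
    cpg_positions <- as.integer(sort(cpg_positions))
    if (!all(cpg_positions %in% found)) {
      abort("every cpg_position must point at a C followed by G in the reference")
    }
  }
  if (length(cpg_positions) == 0L) {
    abort("amplicon contains no CpG dinucleotide")
  }
  structure(list(name = name,
                 reference_sequence = reference_sequence,
                 cpg_positions = cpg_positions),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s: %d bp, %d CpGs\n", x$name,
              nchar(x$reference_sequence), length(x$cpg_positions)))
  invisible(x)
}

#' Global alignment of a clone read to a reference
#'
#' Needleman–Wunsch global alignment with unit match/mismatch scores and a
#' linear gap penalty. Traceback ties are broken deterministically
#' (diagonal, then up, then left) so repeated runs give identical
#' alignments.
#'
#' @param clone Clone sequence (A/C/G/T/N).
#' @param reference Reference sequence (A/C/G/T/N).
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1). `N` scores as a mismatch
#'   against any other base.
#' @param gap Per-base gap penalty (default -2).
#' @return A list of class `pairwise_alignment`: `score`, `aligned_query`,
#'   `aligned_ref`.
#' @examples
#' align_global("ACTAC", "ACGTAC")$score  # 3
#' @export
align_global <- function(clone, reference, match = 1, mismatch = -1,
                         gap = -2) {
  clone <- toupper(clone); reference <- toupper(reference)
  if (nchar(clone) == 0L || nchar(reference) == 0L) {
    abort("sequences must be non-empty")
  }
  if (!grepl("^[ACGTN]+$", clone) || !grepl("^[ACGTN]+$", reference)) {
    abort("sequences must be over the alphabet A/C/G/T/N")
  }
  res <- nw_align_cpp(clone, reference, match, mismatch, gap)
  structure(list(score = res$score,
                 aligned_query = res$aligned_query,
                 aligned_ref = res$aligned_ref),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("clone: ", x$aligned_query, "\n  ref: ", x$aligned_ref,
      "\nscore: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Call CpG methylation states from a clone alignment
#'
#' Reads off the clone base aligned to each CpG cytosine of the unconverted
#' reference: `C` means the cytosine was protected (methylated), `T` means
#' it was converted (unmethylated), anything else (gap, N, other base) is a
#' missing call. Two per-clone QC statistics are computed: the bisulfite
#' conversion rate — the fraction of non-CpG reference cytosines read as T —
#' and the sequence identity over aligned non-cytosine reference positions
#' (bisulfite-expected C-to-T changes therefore never count as mismatches).
#'
#' @param alignment A `pairwise_alignment` of the clone against the
#'   amplicon's unconverted reference.
#' @param amp An [amplicon()].
#' @param clone_id Identifier stored in the call.
#' @return A one-row tibble: `clone_id`, `amplicon`, `aligned`,
#'   `conversion_rate`, `identity`, `n_methylated`, `n_unmethylated`,
#'   `n_missing` and a list-column `states` holding the per-CpG state vector
#'   (`"methylated"`, `"unmethylated"`, `"missing"`).
#' @export
call_methylation <- function(alignment, amp, clone_id = "clone") {
  if (!inherits(amp, "amplicon")) abort("amp must be an amplicon()")
  ar <- strsplit(alignment$aligned_ref, "", fixed = TRUE)[[1L]]
  aq <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1L]]
  if (paste(ar[ar != "-"], collapse = "") != amp$reference_sequence) {
    abort("alignment reference does not match the amplicon reference")
  }
  ref_pos <- cumsum(ar != "-") - 1L # 0-based reference coordinate per column
  ref_cols <- which(ar != "-")
  # clone base aligned to each reference position
  base_at <- setNames(aq[ref_cols], ref_pos[ref_cols])
  cpg <- as.character(amp$cpg_positions)
  cpg_base <- base_at[cpg]
  states <- dplyr::case_when(
    cpg_base == "C" ~ "methylated",
    cpg_base == "T" ~ "unmethylated",
    TRUE ~ "missing")
  ref_chars <- strsplit(amp$reference_sequence, "", fixed = TRUE)[[1L]]
  is_c <- ref_chars == "C"
  non_cpg_c <- which(is_c) - 1L
  non_cpg_c <- setdiff(non_cpg_c, amp$cpg_positions)
  conv_base <- base_at[as.character(non_cpg_c)]
  informative <- conv_base %in% c("C", "T")
  conversion_rate <- if (sum(informative) == 0L) NA_real_ else {
    sum(conv_base[informative] == "T") / sum(informative)
  }
  non_c_pos <- which(!is_c) - 1L
  idn_base <- base_at[as.character(non_c_pos)]
  aligned_non_c <- !is.na(idn_base) & idn_base != "-"
  identity <- if (sum(aligned_non_c) == 0L) NA_real_ else {
    mean(idn_base[aligned_non_c] == ref_chars[non_c_pos + 1L][aligned_non_c])
  }
  tibble(clone_id = clone_id,
         amplicon = amp$name,
         aligned = TRUE,
         conversion_rate = conversion_rate,
         identity = identity,
         n_methylated = sum(states == "methylated"),
         n_unmethylated = sum(states == "unmethylated"),
         n_missing = sum(states == "missing"),
         states = list(states))
}

#' Build a QC-filtered methylation pattern from clone calls
#'
#' Applies the two per-clone quality filters (bisulfite conversion rate and
#' alignment identity), then tabulates methylation per CpG position and
#' overall. Percentages are computed over non-missing calls only.
#'
#' @param calls A tibble of clone calls ([call_methylation()] rows bound
#'   together).
#' @param amp The [amplicon()] the calls refer to.
#' @param min_conversion Minimum conversion rate to keep a clone
#'   (default 0.95).
#' @param min_identity Minimum non-cytosine identity to keep a clone
#'   (default 0.80).
#' @return An object of class `meth_pattern`: list with `amplicon`, `calls`
#'   (all clones with `passed` and `exclude_reason` columns), `states`
#'   (passing-clone by CpG character matrix), `per_cpg` tibble
#'   (`cpg_index`, `position`, `n_methylated`, `n_unmethylated`,
#'   `n_missing`, `percent`) and `overall_percent`.
#' @export
build_pattern <- function(calls, amp, min_conversion = 0.95,
                          min_identity = 0.80) {
  if (nrow(calls) == 0L) abort("no clone calls supplied")
  fail_conv <- is.na(calls$conversion_rate) | calls$conversion_rate < min_conversion
  fail_idn <- is.na(calls$identity) | calls$identity < min_identity
  calls <- mutate(calls,
                  passed = !fail_conv & !fail_idn,
                  exclude_reason = dplyr::case_when(
                    fail_conv ~ "conversion",
                    fail_idn ~ "identity",
                    TRUE ~ NA_character_))
  kept <- filter(calls, .data$passed)
  if (nrow(kept) == 0L) {
    dominant <- names(sort(table(calls$exclude_reason), decreasing = TRUE))[1L]
    abort(paste0("all clones failed QC (dominant reason: ", dominant, ")"))
  }
  states <- do.call(rbind, kept$states)
  rownames(states) <- kept$clone_id
  colnames(states) <- paste0("CpG", seq_along(amp$cpg_positions))
  n_meth <- colSums(states == "methylated")
  n_unmeth <- colSums(states == "unmethylated")
  per_cpg <- tibble(
    cpg_index = seq_along(amp$cpg_positions),
    position = amp$cpg_positions,
    n_methylated = as.integer(n_meth),
    n_unmethylated = as.integer(n_unmeth),
    n_missing = as.integer(colSums(states == "missing")),
    percent = unname(ifelse(n_meth + n_unmeth == 0, NA_real_,
                            100 * n_meth / (n_meth + n_unmeth))))
  overall <- 100 * sum(n_meth) / (sum(n_meth) + sum(n_unmeth))
  structure(list(amplicon = amp,
                 calls = calls,
                 states = states,
                 per_cpg = per_cpg,
                 overall_percent = overall,
                 min_conversion = min_conversion,
                 min_identity = min_identity),
            class = "meth_pattern")
}

#' @export
print.meth_pattern <- function(x, ...) {
  cat(sprintf("<meth_pattern> %s: %d/%d clones pass QC, overall %.1f%% methylated\n",
              x$amplicon$name, nrow(x$states), nrow(x$calls),
              x$overall_percent))
  writeLines(render_lollipop_text(x))
  invisible(x)
}

#' Tidy per-CpG methylation of a pattern
#'
#' @param x A `meth_pattern`.
#' @param ... Unused.
#' @return The `per_cpg` tibble.
#' @export
tidy.meth_pattern <- function(x, ...) x$per_cpg

#' One-row summary of a methylation pattern
#'
#' @param x A `meth_pattern`.
#' @param ... Unused.
#' @return Tibble with `amplicon`, `n_clones`, `n_passed`, `n_cpg`,
#'   `overall_percent`, `mean_conversion_rate`.
#' @export
glance.meth_pattern <- function(x, ...) {
  tibble(amplicon = x$amplicon$name,
         n_clones = nrow(x$calls),
         n_passed = nrow(x$states),
         n_cpg = length(x$amplicon$cpg_positions),
         overall_percent = x$overall_percent,
         mean_conversion_rate = mean(x$calls$conversion_rate[x$calls$passed]))
}

#' Compare overall methylation of two clone patterns
#'
#' Difference in overall percent methylation (`b - a`, percentage points)
#' with a seeded bootstrap confidence interval obtained by resampling clones
#' with replacement within each pattern.
#'
#' @param a,b `meth_pattern` objects for the same amplicon.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return A one-row tibble: `amplicon`, `percent_a`, `percent_b`,
#'   `difference`, `conf_low`, `conf_high`, `n_boot`.
#' @export
compare_patterns <- function(a, b, n_boot = 1000, conf_level = 0.95,
                             seed = NULL) {
  if (!identical(a$amplicon$name, b$amplicon$name)) {
    abort("patterns come from different amplicons")
  }
  overall_of <- function(states, idx) {
    s <- states[idx, , drop = FALSE]
    nm <- sum(s == "methylated"); nu <- sum(s == "unmethylated")
    if (nm + nu == 0L) NA_real_ else 100 * nm / (nm + nu)
  }
  boot_once <- function() {
    ia <- sample.int(nrow(a$states), replace = TRUE)
    ib <- sample.int(nrow(b$states), replace = TRUE)
    overall_of(b$states, ib) - overall_of(a$states, ia)
  }
  run <- function() vapply(seq_len(n_boot), function(i) boot_once(), numeric(1))
  boots <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  alpha <- (1 - conf_level) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble(amplicon = a$amplicon$name,
         percent_a = a$overall_percent,
         percent_b = b$overall_percent,
         difference = b$overall_percent - a$overall_percent,
         conf_low = ci[1L], conf_high = ci[2L],
         n_boot = n_boot)
}

#' Render a methylation pattern as a text lollipop grid
#'
#' One row per passing clone, one column per CpG: `●` methylated,
#' `○` unmethylated, `·` missing. Output is deterministic.
#'
#' @param pattern A `meth_pattern`.
#' @return Character vector, one line per clone.
#' @export
render_lollipop_text <- function(pattern) {
  glyph <- c(methylated = "●", unmethylated = "○",
             missing = "·")
  apply(pattern$states, 1L, function(row) paste(glyph[row], collapse = ""))
}

#' Analyze a set of clone sequences against a reference amplicon
#'
#' Convenience wrapper chaining [align_global()], [call_methylation()] and
#' [build_pattern()] over a FASTA (or named character vector) of clone
#' reads.
#'
#' @param amp An [amplicon()], or a path to a single-record reference FASTA.
#' @param clones Named character vector of clone sequences, or a path to a
#'   clone FASTA.
#' @param min_conversion,min_identity QC thresholds, see [build_pattern()].
#' @param ... Passed to [align_global()].
#' @return A `meth_pattern`.
#' @export
analyze_clones <- function(amp, clones, min_conversion = 0.95,
                           min_identity = 0.80, ...) {
  if (is.character(amp) && length(amp) == 1L && file.exists(amp)) {
    seqs <- read_fasta(amp)
    amp <- amplicon(names(seqs)[1L], seqs[[1L]])
  }
  if (is.character(clones) && length(clones) == 1L && file.exists(clones)) {
    clones <- read_fasta(clones)
  }
  if (is.null(names(clones))) {
    names(clones) <- sprintf("clone_%02d", seq_along(clones))
  }
  calls <- bind_rows(imap(clones, function(seq, id) {
    aln <- align_global(seq, amp$reference_sequence, ...)
    call_methylation(aln, amp, clone_id = id)
  }))
  build_pattern(calls, amp, min_conversion = min_conversion,
                min_identity = min_identity)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write per-clone calls and per-CpG summary of a pattern to TSV
#'
#' @param pattern A `meth_pattern`.
#' @param calls_path Output TSV for per-clone calls.
#' @param per_cpg_path Optional output TSV for the per-CpG summary.
#' @return `calls_path`, invisibly.
#' @export
write_pattern <- function(pattern, calls_path, per_cpg_path = NULL) {
  calls <- pattern$calls |>
    mutate(pattern = map_chr(.data$states, function(s) {
      paste(substr(s, 1L, 1L), collapse = "")
    })) |>
    select(-"states") |>
    mutate(across(c("conversion_rate", "identity"), ~ round(.x, 4)))
  readr::write_tsv(calls, calls_path, na = "NA")
  if (!is.null(per_cpg_path)) {
    readr::write_tsv(mutate(pattern$per_cpg,
                            percent = round(.data$percent, 4)),
                     per_cpg_path, na = "NA")
  }
  invisible(calls_path)
}
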