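#' Build a sample manifest
#'
#' The manifest declares the role each MeDIP-seq sample plays in the recovery
#' analysis: exactly one `reference` (the wild-type methylome every other
#' sample is compared to), exactly one `baseline` (the null cells carrying an
#' empty vector, defining the methylation deficit) and any number of `test`
#' samples (rescue lines whose recovery is quantified).
#'
#' @param sample_id Character vector of unique sample ids.
#' @param role Character vector of roles, one of `"reference"`, `"baseline"`,
#'   `"test"`.
#' @param label Optional display labels (defaults to `sample_id`).
#' @return A validated manifest tibble with columns `sample_id`, `role`,
#'   `label`.
#' @examples
#' manifest(c("WT", "MSCV", "LSH1", "K237Q3"),
#'          c("reference", "baseline", "test", "test"))
#' @export
manifest <- function(sample_id, role, label = sample_id) {
  validate_manifest(tibble(sample_id = as.character(sample_id),
                           role = as.character(role),
                           label = as.character(label)))
}

#' Validate a sample manifest
#'
#' @param m A data frame with columns `sample_id` and `role` (and optionally
#'   `label`).
#' @return The manifest as a tibble, or an error describing the violated
#'   contract.
#' @export
validate_manifest <- function(m) {
  if (!all(c("sample_id", "role") %in% names(m))) {
    abort("manifest must have columns sample_id and role")
  }
  m <- as_tibble(m)
  if (!"label" %in% names(m)) m$label <- m$sample_id
  bad <- setdiff(unique(m$role), c("reference", "baseline", "test"))
  if (length(bad) > 0L) {
    abort(paste0("unknown role(s): ", paste(bad, collapse = ", "),
                 " (expected reference, baseline or test)"))
  }
  if (anyDuplicated(m$sample_id)) {
    abort("duplicate sample_id in manifest")
  }
  if (sum(m$role == "reference") != 1L) {
    abort("manifest must declare exactly one reference sample")
  }
  if (sum(m$role == "baseline") != 1L) {
    abort("manifest must declare exactly one baseline sample")
  }
  m[, c("sample_id", "role", "label")]
}

#' Read a sample manifest from a YAML file
#'
#' The file declares one mapping per sample, e.g.
#' ```yaml
#' samples:
#'   - {sample_id: WT,   role: reference}
#'   - {sample_id: MSCV, role: baseline}
#'   - {sample_id: LSH1, role: test, label: "Lsh-/- LSH line 1"}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A validated manifest tibble.
#' @seealso [manifest()], [write_manifest()]
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  y <- yaml::read_yaml(path)
  entries <- y$samples %||% y
  if (!is.list(entries) || length(entries) == 0L) {
    abort("manifest must declare a non-empty 'samples' list")
  }
  m <- bind_rows(lapply(entries, function(e) {
    if (is.null(e$sample_id) || is.null(e$role)) {
      abort("each manifest entry needs sample_id and role")
    }
    tibble(sample_id = as.character(e$sample_id),
           role = as.character(e$role),
           label = as.character(e$label %||% e$sample_id))
  }))
  validate_manifest(m)
}

#' Write a sample manifest to a YAML file
#'
#' @param m A manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  m <- validate_manifest(m)
  entries <- pmap(m, function(sample_id, role, label) {
    list(sample_id = sample_id, role = role, label = label)
  })
  yaml::write_yaml(list(samples = entries), path)
  invisible(path)
}

# role lookup helpers used across stages
manifest_role <- function(m, role) {
  m$sample_id[m$role == role]
}
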