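# Clonotype frequency computation, hyperexpansion calling, cross-sample
# sharing/persistence, and CDR3 matching against a specificity reference.

#' Build clone keys from clonotype fields
#'
#' The default key combines the allele-stripped V gene with the CDR3
#' amino-acid sequence, so clones are reported the way repertoire figures
#' list them (CDR3 with V context). Platforms that resolve nucleotide-level
#' identity can key on the CDR3 nucleotide sequence instead.
#'
#' @param v_call V gene call (may be empty).
#' @param cdr3_aa CDR3 amino-acid sequence.
#' @param cdr3_nt CDR3 nucleotide sequence (required for `key = "nt"`).
#' @param key Key convention: `"v+aa"` (default), `"aa"`, or `"nt"`.
#' @return Character vector of clone keys.
#' @export
make_clone_key <- function(v_call, cdr3_aa, cdr3_nt = NULL, key = c("v+aa", "aa", "nt")) {
  key <- match.arg(key)
  switch(key,
    "v+aa" = paste(strip_allele(ifelse(is.na(v_call), "", v_call)), cdr3_aa, sep = "|"),
    "aa" = cdr3_aa,
    "nt" = {
      if (is.null(cdr3_nt)) stopf("key = \"nt\" requires cdr3_nt sequences")
      cdr3_nt
    }
  )
}

validate_clonotypes <- function(clonotypes) {
  req <- c("sample_id", "junction_aa", "duplicate_count")
  miss <- setdiff(req, names(clonotypes))
  if (length(miss)) stopf("clonotype table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(clonotypes) < 1L) stopf("clonotype table is empty")
  if (length(unique(clonotypes$sample_id)) > 1L) {
    stopf("mixed sample ids in one summary: %s",
          paste(unique(clonotypes$sample_id), collapse = ", "))
  }
  aa <- clonotypes$junction_aa
  bad <- !nzchar(aa) | grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), aa)
  if (any(bad)) {
    stopf("invalid CDR3 amino-acid sequence(s) at row(s): %s",
          paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  cnt <- clonotypes$duplicate_count
  if (any(!is.finite(cnt) | cnt < 1 | cnt != round(cnt))) {
    stopf("duplicate_count must be a positive integer for every row")
  }
  invisible(clonotypes)
}

#' Clone frequencies and ranks for one sample
#'
#' Aggregates clonotype records by clone key (duplicate rows summed, as
#' export formats often split clones across rows), then computes each
#' clone's frequency of the total read count and a deterministic 1-based
#' rank (descending frequency, ties broken by clone key).
#'
#' @param clonotypes Data frame of clonotype records for a single sample
#'   with columns `sample_id`, `junction_aa`, `duplicate_count` and
#'   optionally `v_call`, `j_call`, `junction`.
#' @param key Clone key convention, see [make_clone_key()].
#' @return A `repertoire_summary` data frame with columns `clone_key`,
#'   `v_call`, `j_call`, `cdr3_aa`, `cdr3_nt`, `count`, `frequency`,
#'   `rank`, ordered by rank, with attributes `sample_id`, `total_count`
#'   and `key_type`.
#' @examples
#' tab <- data.frame(sample_id = "s", junction_aa = c("CASSLF", "CASRGF", "CAWSVF"),
#'                   duplicate_count = c(6L, 3L, 1L))
#' compute_frequencies(tab, key = "aa")$frequency
#' @export
compute_frequencies <- function(clonotypes, key = c("v+aa", "aa", "nt")) {
  key <- match.arg(key)
  validate_clonotypes(clonotypes)
  v <- if ("v_call" %in% names(clonotypes)) clonotypes$v_call else rep("", nrow(clonotypes))
  j <- if ("j_call" %in% names(clonotypes)) clonotypes$j_call else rep("", nrow(clonotypes))
  nt <- if ("junction" %in% names(clonotypes)) clonotypes$junction else NULL
  ck <- make_clone_key(v, clonotypes$junction_aa, nt, key)

  first <- !duplicated(ck)
  counts <- tapply(as.numeric(clonotypes$duplicate_count), ck, sum)
  total <- sum(counts)
  if (total <= 0) stopf("zero total read count")

  out <- data.frame(
    clone_key = ck[first],
    v_call = v[first],
    j_call = j[first],
    cdr3_aa = clonotypes$junction_aa[first],
    cdr3_nt = if (is.null(nt)) NA_character_ else nt[first],
    stringsAsFactors = FALSE
  )
  out$count <- as.numeric(counts[out$clone_key])
  out$frequency <- out$count / total
  ord <- order(-out$frequency, out$clone_key)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out,
            sample_id = clonotypes$sample_id[1L],
            total_count = total,
            key_type = key,
            class = c("repertoire_summary", "data.frame"))
}

#' Flag hyperexpanded clones
#'
#' A clone is hyperexpanded when its frequency is strictly greater than the
#' threshold (default 1% of all reads) — a clone at exactly the threshold is
#' not flagged.
#'
#' @param summary A [compute_frequencies()] result.
#' @param threshold Frequency threshold in (0,1); default 0.01.
#' @return The summary with a logical `hyperexpanded` column and a
#'   `hyper_threshold` attribute.
#' @export
call_hyperexpanded <- function(summary, threshold = 0.01) {
  stopifnot(inherits(summary, "repertoire_summary"))
  if (!is_scalar_num(threshold) || threshold <= 0 || threshold >= 1) {
    stopf("threshold must lie strictly inside (0,1)")
  }
  summary$hyperexpanded <- summary$frequency > threshold
  attr(summary, "hyper_threshold") <- threshold
  summary
}

#' Clone sharing and persistence between two samples
#'
#' Intersects two repertoire summaries by exact clone key and classifies
#' each shared clone by where it is hyperexpanded. Both summaries must
#' carry hyperexpansion flags (see [call_hyperexpanded()]).
#'
#' @param summary_a,summary_b Flagged repertoire summaries.
#' @return A `sharing_report` list: `n_shared`, `n_unique_a`, `n_unique_b`,
#'   sorted `shared_keys`, per-shared-clone `persistence` data frame
#'   (`clone_key`, `class` in `hyper_in_both`, `hyper_in_a_only`,
#'   `hyper_in_b_only`, `hyper_in_neither`, plus both frequencies), and the
#'   two sample ids.
#' @export
compare_samples <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "repertoire_summary"),
            inherits(summary_b, "repertoire_summary"))
  if (is.null(summary_a$hyperexpanded) || is.null(summary_b$hyperexpanded)) {
    stopf("summaries must carry hyperexpansion flags; run call_hyperexpanded() first")
  }
  if (nrow(summary_a) == 0L || nrow(summary_b) == 0L) stopf("summaries must be non-empty")
  shared <- sort(intersect(summary_a$clone_key, summary_b$clone_key))
  ia <- match(shared, summary_a$clone_key)
  ib <- match(shared, summary_b$clone_key)
  ha <- summary_a$hyperexpanded[ia]
  hb <- summary_b$hyperexpanded[ib]
  cls <- ifelse(ha & hb, "hyper_in_both",
         ifelse(ha & !hb, "hyper_in_a_only",
         ifelse(!ha & hb, "hyper_in_b_only", "hyper_in_neither")))
  persistence <- data.frame(
    clone_key = shared,
    class = cls,
    frequency_a = summary_a$frequency[ia],
    frequency_b = summary_b$frequency[ib],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      n_shared = length(shared),
      n_unique_a = nrow(summary_a) - length(shared),
      n_unique_b = nrow(summary_b) - length(shared),
      shared_keys = shared,
      persistence = persistence,
      sample_a = attr(summary_a, "sample_id"),
      sample_b = attr(summary_b, "sample_id")
    ),
    class = "sharing_report"
  )
}

#' @method print sharing_report
#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf("Clone sharing: %s vs %s\n", x$sample_a, x$sample_b))
  cat(sprintf("  shared %d | unique %d / %d\n", x$n_shared, x$n_unique_a, x$n_unique_b))
  print(table(factor(x$persistence$class,
                     levels = c("hyper_in_both", "hyper_in_a_only",
                                "hyper_in_b_only", "hyper_in_neither"))))
  invisible(x)
}

#' Match CDR3 sequences against a specificity reference
#'
#' Computes the Levenshtein edit distance between each query clone's CDR3
#' amino-acid sequence and every reference CDR3, returning all reference
#' rows within `max_edit_distance` per query, sorted by distance then
#' reference id. V-gene consistency (gene level, allele stripped) is
#' evaluated whenever both records carry a V call.
#'
#' @param summary A repertoire summary (or any data frame with `clone_key`,
#'   `cdr3_aa` and optionally `v_call`).
#' @param reference Data frame with column `cdr3_aa` and optionally
#'   `v_call`, `epitope`, `antigen`, `source_id`.
#' @param max_edit_distance Maximum Levenshtein distance (default 1;
#'   0 gives exact matching).
#' @param require_v_match Drop matches whose V genes are present in both
#'   records but disagree.
#' @return Data frame of matches: `clone_key`, `cdr3_aa`, `ref_cdr3_aa`,
#'   `edit_distance`, `v_gene_consistent`, `epitope`, `antigen`,
#'   `source_id`.
#' @export
match_cdr3 <- function(summary, reference, max_edit_distance = 1L,
                       require_v_match = FALSE) {
  if (is.null(reference) || nrow(reference) == 0L) stopf("reference table is empty")
  if (!"cdr3_aa" %in% names(reference)) stopf("reference lacks a cdr3_aa column")
  if (!is.numeric(max_edit_distance) || max_edit_distance < 0) {
    stopf("max_edit_distance must be a non-negative integer")
  }
  if (!"source_id" %in% names(reference)) {
    reference$source_id <- sprintf("ref%04d", seq_len(nrow(reference)))
  }
  d <- utils::adist(summary$cdr3_aa, reference$cdr3_aa)
  hits <- which(d <= max_edit_distance, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(clone_key = character(), cdr3_aa = character(),
                      ref_cdr3_aa = character(), edit_distance = integer(),
                      v_gene_consistent = logical(), epitope = character(),
                      antigen = character(), source_id = character(),
                      stringsAsFactors = FALSE))
  }
  qi <- hits[, 1L]
  ri <- hits[, 2L]
  qv <- if (!is.null(summary$v_call)) summary$v_call[qi] else rep(NA_character_, length(qi))
  rv <- if (!is.null(reference$v_call)) reference$v_call[ri] else rep(NA_character_, length(ri))
  both_v <- !is.na(qv) & nzchar(qv) & !is.na(rv) & nzchar(rv)
  v_ok <- rep(NA, length(qi))
  v_ok[both_v] <- strip_allele(qv[both_v]) == strip_allele(rv[both_v])
  out <- data.frame(
    clone_key = summary$clone_key[qi],
    cdr3_aa = summary$cdr3_aa[qi],
    ref_cdr3_aa = reference$cdr3_aa[ri],
    edit_distance = as.integer(d[hits]),
    v_gene_consistent = v_ok,
    epitope = if (!is.null(reference$epitope)) reference$epitope[ri] else NA_character_,
    antigen = if (!is.null(reference$antigen)) reference$antigen[ri] else NA_character_,
    source_id = reference$source_id[ri],
    stringsAsFactors = FALSE
  )
  if (require_v_match) out <- out[is.na(out$v_gene_consistent) | out$v_gene_consistent, , drop = FALSE]
  ord <- order(match(out$clone_key, summary$clone_key), out$edit_distance, out$source_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bundled synthetic spike-specificity CDR3 reference
#'
#' A small synthetic stand-in for a curated TCR specificity database,
#' listing CDR3 beta sequences annotated to the SARS-CoV-2 spike epitope
#' YLQPRTFLL. The sequences are constructed for simulation and matching
#' tests; they are not measured sequences.
#'
#' @return Data frame with columns `cdr3_aa`, `v_call`, `j_call`,
#'   `epitope`, `antigen`, `source_id`.
#' @export
spike_reference <- function() {
  path <- system.file("extdata", "spike_cdr3_reference_synthetic.csv",
                      package = "clonescape", mustWork = TRUE)
  read_cdr3_reference(path)
}
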