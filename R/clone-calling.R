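# Transcript-to-cell rollup, TCR-clone-positive cell calling, bleed-through
# quantification, expression summaries and differential expression.

#' Configuration for TCR clone calling
#'
#' @param clone_probe_names Names of the clone probe features.
#' @param eligible_cell_type Cell type eligible for clone assignment
#'   (default `"CD8_T"`).
#' @param min_transcripts Minimum summed clone-probe transcripts for a cell
#'   to be called clone-positive (default 1).
#' @param min_qv Minimum transcript quality used during aggregation
#'   (default 20, a common in situ platform cutoff).
#' @return A `clone_call_config` list.
#' @export
clone_call_config <- function(clone_probe_names,
                              eligible_cell_type = "CD8_T",
                              min_transcripts = 1L,
                              min_qv = 20) {
  if (!length(clone_probe_names)) stopf("at least one clone probe is required")
  if (!is_count(min_transcripts)) stopf("min_transcripts must be a positive integer")
  stopifnot(is_scalar_num(min_qv), min_qv >= 0)
  structure(
    list(clone_probe_names = as.character(clone_probe_names),
         eligible_cell_type = eligible_cell_type,
         min_transcripts = as.integer(min_transcripts),
         min_qv = min_qv),
    class = "clone_call_config"
  )
}

#' Aggregate transcripts into per-cell feature counts
#'
#' Counts assigned transcripts per (cell, feature) after filtering on
#' quality; unassigned transcripts (no cell id) are tallied separately so
#' transcript conservation is auditable.
#'
#' @param transcripts Transcript data frame (`feature_name`, `cell_id`,
#'   `qv`, positions).
#' @param cells Cell data frame (`cell_id`, `cell_type`, ...); transcript
#'   cell ids must be a subset of the cell table (or `NA`).
#' @param min_qv Quality threshold; transcripts below it are dropped (and
#'   counted).
#' @return A `cell_counts` object: sparse `counts` matrix (cells x
#'   features, rownames = cell ids), `unassigned` per-feature tally,
#'   `n_input`, `n_assigned`, `n_unassigned`, `n_below_qv`, `min_qv`.
#' @export
aggregate_transcripts <- function(transcripts, cells, min_qv = 20) {
  stopifnot(is_scalar_num(min_qv), min_qv >= 0)
  tx_cells <- transcripts$cell_id
  known <- is.na(tx_cells) | tx_cells %in% cells$cell_id
  if (any(!known)) {
    stopf("transcripts reference unknown cell id(s): %s",
          paste(utils::head(unique(tx_cells[!known]), 5L), collapse = ", "))
  }
  pass <- transcripts$qv >= min_qv
  assigned <- pass & !is.na(tx_cells)
  features <- sort(unique(transcripts$feature_name))
  counts <- Matrix::sparseMatrix(
    i = match(tx_cells[assigned], cells$cell_id),
    j = match(transcripts$feature_name[assigned], features),
    x = rep(1, sum(assigned)),
    dims = c(nrow(cells), length(features)),
    dimnames = list(cells$cell_id, features)
  )
  # The unassigned tally is a property of segmentation, not of transcript
  # quality, so it ignores the qv filter.
  un <- table(factor(transcripts$feature_name[is.na(tx_cells)], levels = features))
  structure(
    list(counts = counts,
         unassigned = stats::setNames(as.integer(un), features),
         n_input = nrow(transcripts),
         n_assigned = sum(assigned),
         n_unassigned = sum(is.na(tx_cells)),
         n_below_qv = sum(!pass & !is.na(tx_cells)),
         min_qv = min_qv),
    class = "cell_counts"
  )
}

clone_count_matrix <- function(cell_counts, probes) {
  counts <- cell_counts$counts
  present <- intersect(probes, colnames(counts))
  m <- matrix(0, nrow(counts), length(probes), dimnames = list(rownames(counts), probes))
  if (length(present)) m[, present] <- as.matrix(counts[, present, drop = FALSE])
  m
}

#' Call TCR-clone-positive cells
#'
#' A cell is clone-positive (TCR+) when it has the eligible cell type and
#' at least `min_transcripts` clone-probe transcripts in total. The
#' assigned clone is the probe with the highest count; cells with tied
#' maxima are called `"ambiguous"` — they count as TCR+ but are excluded
#' from per-clone frequencies. Per-clone frequency is the number of cells
#' of that clone over all eligible cells.
#'
#' @param cells Cell data frame with `cell_id` and `cell_type`.
#' @param cell_counts An [aggregate_transcripts()] result aligned to
#'   `cells`.
#' @param config A [clone_call_config()].
#' @return A list: `cells` (with `tcr_status` in `"TCR+"`/`"TCR-"` and
#'   `clone` columns) and `summary` (`n_eligible`, `n_tcr_pos`,
#'   `tcr_pos_fraction`, `n_ambiguous`, named `clone_frequencies` and
#'   `clone_cells`).
#' @export
call_tcr_positive <- function(cells, cell_counts, config) {
  stopifnot(inherits(cell_counts, "cell_counts"), inherits(config, "clone_call_config"))
  eligible <- cells$cell_type == config$eligible_cell_type
  if (!any(eligible)) stopf("no cells of eligible type '%s'", config$eligible_cell_type)
  cm <- clone_count_matrix(cell_counts, config$clone_probe_names)
  cm <- cm[match(cells$cell_id, rownames(cm)), , drop = FALSE]
  cm[is.na(cm)] <- 0
  total <- rowSums(cm)
  tcr_pos <- eligible & total >= config$min_transcripts

  clone <- rep(NA_character_, nrow(cells))
  if (any(tcr_pos)) {
    sub <- cm[tcr_pos, , drop = FALSE]
    top <- apply(sub, 1L, max)
    n_at_top <- rowSums(sub == top)
    pick <- config$clone_probe_names[max.col(sub, ties.method = "first")]
    pick[n_at_top > 1L] <- "ambiguous"
    clone[tcr_pos] <- pick
  }
  cells$tcr_status <- ifelse(tcr_pos, "TCR+", "TCR-")
  cells$clone <- clone

  n_eligible <- sum(eligible)
  clone_cells <- vapply(config$clone_probe_names,
                        function(p) sum(clone == p, na.rm = TRUE), numeric(1))
  summary <- list(
    n_eligible = n_eligible,
    n_tcr_pos = sum(tcr_pos),
    tcr_pos_fraction = sum(tcr_pos) / n_eligible,
    n_ambiguous = sum(clone == "ambiguous", na.rm = TRUE),
    clone_cells = clone_cells,
    clone_frequencies = clone_cells / n_eligible
  )
  list(cells = cells, summary = summary)
}

#' Quantify clone-probe signal bleed-through
#'
#' Tallies clone-probe transcripts by recipient cell type, reporting each
#' type's share of assigned transcripts, the unassigned share, and the
#' fraction outside the eligible type. A model-based estimate of the
#' bleed-through rate divides the outside-eligible fraction by the fraction
#' of eligible cells whose nearest neighbouring cell is not eligible — the
#' transfer probability under nearest-neighbour bleed-through of signal
#' that originates in eligible cells.
#'
#' @param transcripts Transcript data frame.
#' @param cells Cell data frame (`cell_id`, `cell_type`, positions).
#' @param clone_probe_names Clone probe feature names.
#' @param eligible_cell_type The type clone signal originates from.
#' @param estimate_rate Compute the nearest-neighbour rate estimate
#'   (involves a neighbour search over the cell table).
#' @return A `bleedthrough_report` list: `by_type` data frame (recipient
#'   type, n, share of assigned), `per_probe` counts, `eligible_fraction`,
#'   `outside_eligible_fraction`, `unassigned_fraction`, `n_clone_transcripts`
#'   and `bleed_rate_estimate` (`NA` unless `estimate_rate`).
#' @export
bleedthrough_fraction <- function(transcripts, cells, clone_probe_names,
                                  eligible_cell_type = "CD8_T",
                                  estimate_rate = FALSE) {
  sel <- transcripts$feature_name %in% clone_probe_names
  tx <- transcripts[sel, , drop = FALSE]
  if (nrow(tx) == 0L) stopf("no clone-probe transcripts found")
  type_of <- stats::setNames(cells$cell_type, cells$cell_id)
  recipient <- rep(NA_character_, nrow(tx))
  has_cell <- !is.na(tx$cell_id)
  recipient[has_cell] <- type_of[tx$cell_id[has_cell]]
  n_assigned <- sum(has_cell)
  tab <- sort(table(recipient[has_cell]), decreasing = TRUE)
  by_type <- data.frame(
    recipient_type = names(tab),
    n = as.integer(tab),
    share = as.integer(tab) / n_assigned,
    stringsAsFactors = FALSE
  )
  eligible_fraction <- if (n_assigned > 0)
    sum(recipient[has_cell] == eligible_cell_type) / n_assigned else NA_real_
  per_probe <- table(
    factor(tx$feature_name, levels = clone_probe_names),
    factor(ifelse(is.na(recipient), "unassigned", recipient))
  )
  est <- NA_real_
  if (estimate_rate) {
    elig_idx <- which(cells$cell_type == eligible_cell_type)
    if (length(elig_idx) >= 2L && nrow(cells) >= 2L) {
      nn <- nearest_other_point(cells$x_um, cells$y_um, query = elig_idx)
      w <- mean(cells$cell_type[nn] != eligible_cell_type)
      if (w > 0) est <- min(1, (1 - eligible_fraction) / w)
    }
  }
  structure(
    list(by_type = by_type,
         per_probe = per_probe,
         eligible_fraction = eligible_fraction,
         outside_eligible_fraction = 1 - eligible_fraction,
         unassigned_fraction = sum(!has_cell) / nrow(tx),
         n_clone_transcripts = nrow(tx),
         eligible_cell_type = eligible_cell_type,
         bleed_rate_estimate = est),
    class = "bleedthrough_report"
  )
}

#' @method print bleedthrough_report
#' @export
print.bleedthrough_report <- function(x, ...) {
  cat(sprintf("bleed-through: %d clone transcripts, %.1f%% in %s, %.1f%% outside, %.1f%% unassigned\n",
              x$n_clone_transcripts, 100 * x$eligible_fraction, x$eligible_cell_type,
              100 * x$outside_eligible_fraction, 100 * x$unassigned_fraction))
  if (!is.na(x$bleed_rate_estimate)) {
    cat(sprintf("  estimated bleed-through rate: %.3f\n", x$bleed_rate_estimate))
  }
  invisible(x)
}

# Median-total normalisation: counts scaled so every cell has the median
# total count, the usual library-size normalisation for in situ panels.
# Custom probes (e.g. clone CDR3 probes) can be excluded from the totals so
# they do not distort the library size of probe-positive cells.
normalise_counts <- function(counts, exclude_from_norm = character()) {
  keep <- setdiff(colnames(counts), exclude_from_norm)
  tot <- Matrix::rowSums(counts[, keep, drop = FALSE])
  med <- stats::median(tot)
  scale <- ifelse(tot > 0, med / tot, 0)
  counts * scale
}

#' Per-group percent-expressing and scaled mean expression
#'
#' Dot-plot style summary: for each gene and cell group, the fraction of
#' cells with at least one transcript and the mean of log1p
#' median-normalised counts, z-scaled across groups per gene (a gene
#' identical in all groups scales to 0 everywhere).
#'
#' @param cell_counts An [aggregate_transcripts()] result.
#' @param groups Character/factor vector (length = number of cells) of
#'   group labels; `NA` cells are excluded.
#' @param genes Genes to summarise (must be in the panel).
#' @param exclude_from_norm Features excluded from the library-size totals
#'   (typically the clone probes).
#' @return Data frame: `gene`, `group`, `pct_expressing`, `mean_log1p`,
#'   `scaled_mean`.
#' @export
expression_summary <- function(cell_counts, groups, genes,
                               exclude_from_norm = character()) {
  stopifnot(inherits(cell_counts, "cell_counts"))
  counts <- cell_counts$counts
  if (length(groups) != nrow(counts)) stopf("groups length does not match cell count matrix")
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) stopf("gene(s) not in panel: %s", paste(missing, collapse = ", "))
  norm <- normalise_counts(counts, exclude_from_norm)
  keep <- !is.na(groups)
  gf <- factor(groups[keep])
  out <- list()
  for (g in genes) {
    raw <- counts[keep, g]
    lg <- log1p(norm[keep, g])
    pct <- tapply(raw >= 1, gf, mean)
    mu <- tapply(lg, gf, mean)
    sdv <- stats::sd(mu)
    scaled <- if (is.na(sdv) || sdv == 0) rep(0, length(mu)) else (mu - mean(mu)) / sdv
    out[[g]] <- data.frame(gene = g, group = levels(gf),
                           pct_expressing = as.vector(pct),
                           mean_log1p = as.vector(mu),
                           scaled_mean = as.vector(scaled),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Vectorised two-sided Wilcoxon rank-sum p-values (normal approximation
# with tie correction and continuity correction, the same large-sample path
# as stats::wilcox.test) across the columns of a matrix.
rank_sum_p <- function(X, in_group1) {
  n1 <- sum(in_group1)
  n2 <- sum(!in_group1)
  n <- n1 + n2
  vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j])
    W <- sum(r[in_group1]) - n1 * (n1 + 1) / 2
    z <- W - n1 * n2 / 2
    nties <- table(r)
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
    if (sigma == 0) return(1)
    z <- z - sign(z) * 0.5
    min(1, 2 * stats::pnorm(-abs(z) / sigma))
  }, numeric(1))
}

#' Differential expression between clone-positive and clone-negative cells
#'
#' For each gene, the log2 fold change of mean median-normalised counts
#' (with a 1e-9 pseudocount), a two-sided Wilcoxon rank-sum p-value on
#' log1p normalised values, Benjamini-Hochberg adjustment across tested
#' genes, percent-expressing per group, and a significance flag
#' (`log2_fold_change > fc_threshold` and `p_adj < alpha`).
#'
#' @param cell_counts An [aggregate_transcripts()] result.
#' @param group1,group2 Logical vectors (length = number of cells) marking
#'   the two disjoint groups (e.g. TCR+ and TCR- CD8 T cells); each must
#'   contain at least 3 cells.
#' @param fc_threshold,alpha Significance thresholds (defaults 0.25 and
#'   0.05).
#' @param genes Genes to test (default: every panel feature not excluded
#'   from normalisation).
#' @param exclude_from_norm Features excluded from the library-size totals
#'   (typically the clone probes).
#' @return A `DEGResult` data frame: `gene`, `avg_1`, `avg_2`,
#'   `log2_fold_change`, `p_value`, `p_adj`, `pct_1`, `pct_2`,
#'   `significant`, sorted by decreasing fold change.
#' @export
differential_expression <- function(cell_counts, group1, group2,
                                    fc_threshold = 0.25, alpha = 0.05,
                                    genes = NULL,
                                    exclude_from_norm = character()) {
  stopifnot(inherits(cell_counts, "cell_counts"))
  counts <- cell_counts$counts
  if (length(group1) != nrow(counts) || length(group2) != nrow(counts)) {
    stopf("group vectors must match the cell count matrix")
  }
  group1[is.na(group1)] <- FALSE
  group2[is.na(group2)] <- FALSE
  if (any(group1 & group2)) stopf("groups must be disjoint")
  if (sum(group1) < 3L || sum(group2) < 3L) {
    stopf("each group needs at least 3 cells (got %d and %d)", sum(group1), sum(group2))
  }
  if (is.null(genes)) genes <- setdiff(colnames(counts), exclude_from_norm)
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) stopf("gene(s) not in panel: %s", paste(missing, collapse = ", "))

  keep <- group1 | group2
  norm <- normalise_counts(counts, exclude_from_norm)[keep, genes, drop = FALSE]
  raw <- counts[keep, genes, drop = FALSE]
  g1 <- group1[keep]
  eps <- 1e-9
  avg1 <- Matrix::colMeans(norm[g1, , drop = FALSE])
  avg2 <- Matrix::colMeans(norm[!g1, , drop = FALSE])
  log2fc <- log2((avg1 + eps) / (avg2 + eps))
  p <- rank_sum_p(as.matrix(log1p(norm)), g1)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene = genes,
    avg_1 = unname(avg1), avg_2 = unname(avg2),
    log2_fold_change = unname(log2fc),
    p_value = p, p_adj = p_adj,
    pct_1 = unname(Matrix::colMeans(raw[g1, , drop = FALSE] >= 1)),
    pct_2 = unname(Matrix::colMeans(raw[!g1, , drop = FALSE] >= 1)),
    stringsAsFactors = FALSE
  )
  out$significant <- out$log2_fold_change > fc_threshold & out$p_adj < alpha
  out <- out[order(-out$log2_fold_change), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DEGResult", "data.frame")
  out
}

#' MAIT marker co-expression check
#'
#' Fraction of the selected cells co-expressing both MAIT markers (at
#' least one transcript each of, by default, KLRB1 and TRAV1-2), with the
#' per-gene expressing fractions. Hyperexpanded KLRB1-high clones that lack
#' TRAV1-2 co-expression are CD161+ non-MAIT cells.
#'
#' @param cell_counts An [aggregate_transcripts()] result.
#' @param select Logical vector of cells to assess (default: all).
#' @param genes The two marker genes (default `c("KLRB1", "TRAV1-2")`).
#' @return A list: `frac_coexpressing`, per-gene expressing fractions,
#'   `n_cells`.
#' @export
mait_coexpression <- function(cell_counts, select = NULL,
                              genes = c("KLRB1", "TRAV1-2")) {
  stopifnot(inherits(cell_counts, "cell_counts"), length(genes) == 2L)
  counts <- cell_counts$counts
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) stopf("gene(s) not in panel: %s", paste(missing, collapse = ", "))
  if (is.null(select)) select <- rep(TRUE, nrow(counts))
  select[is.na(select)] <- FALSE
  if (!any(select)) stopf("no cells selected")
  a <- counts[select, genes[1L]] >= 1
  b <- counts[select, genes[2L]] >= 1
  out <- list(
    frac_coexpressing = mean(a & b),
    n_cells = sum(select)
  )
  out[[paste0("frac_", genes[1L])]] <- mean(a)
  out[[paste0("frac_", genes[2L])]] <- mean(b)
  out
}
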