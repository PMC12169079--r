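# Per-cell Poisson transcript tables with positional jitter and
# nearest-neighbour signal bleed-through.

#' Parameters for synthetic transcript generation
#'
#' Per-cell, per-feature counts are Poisson with rates given by
#' `mean_counts` (features x cell types). Clone probes (features named
#' after clone labels) are only expressed in cells whose true clone matches
#' the probe. A `bleedthrough_rate` fraction of all transcripts is
#' reassigned to the source cell's nearest neighbouring cell while keeping
#' the jittered position, emulating segmentation signal bleed-through.
#'
#' @param panel Character vector of feature names, including clone probes.
#' @param mean_counts Numeric matrix: rows = features (all of `panel`),
#'   columns = cell types; Poisson mean per cell.
#' @param clone_probes Features that are clone probes (default: none).
#' @param bleedthrough_rate Fraction in \[0,1) of transcripts reassigned to
#'   the nearest other cell.
#' @param position_jitter_sigma_um Gaussian jitter of transcript positions
#'   around the cell centroid.
#' @param labelled_overrides Optional named numeric vector of per-feature
#'   Poisson rates applied to clone-labelled cells in place of their cell
#'   type's rate, so activation/residency genes can differ between
#'   clone-labelled and unlabelled cells of the same type.
#' @param qv_mean,qv_sd Transcript quality scores are drawn from a normal
#'   distribution (clipped at 0).
#' @param seed Integer seed.
#' @return A validated `transcript_sim_params` list.
#' @export
transcript_sim_params <- function(panel, mean_counts,
                                  clone_probes = character(),
                                  bleedthrough_rate = 0,
                                  position_jitter_sigma_um = 3,
                                  labelled_overrides = NULL,
                                  qv_mean = 30, qv_sd = 6,
                                  seed = 1L) {
  mean_counts <- as.matrix(mean_counts)
  if (!is.null(labelled_overrides)) {
    if (is.null(names(labelled_overrides)) ||
        !all(names(labelled_overrides) %in% panel) || any(labelled_overrides < 0)) {
      stopf("labelled_overrides must be non-negative rates named by panel features")
    }
  }
  missing <- setdiff(panel, rownames(mean_counts))
  if (length(missing)) {
    stopf("feature(s) missing from the rate table: %s", paste(missing, collapse = ", "))
  }
  if (any(mean_counts < 0)) stopf("Poisson rates must be non-negative")
  if (!is_fraction(bleedthrough_rate) || bleedthrough_rate >= 1) {
    stopf("bleedthrough_rate must lie in [0,1)")
  }
  if (!all(clone_probes %in% panel)) stopf("every clone probe must be in the panel")
  stopifnot(position_jitter_sigma_um >= 0, qv_sd >= 0)
  structure(
    list(panel = panel, mean_counts = mean_counts[panel, , drop = FALSE],
         clone_probes = clone_probes,
         bleedthrough_rate = bleedthrough_rate,
         position_jitter_sigma_um = position_jitter_sigma_um,
         labelled_overrides = labelled_overrides,
         qv_mean = qv_mean, qv_sd = qv_sd, seed = as.integer(seed)),
    class = "transcript_sim_params"
  )
}

#' Generate a synthetic transcript table for a cell table
#'
#' @param cells Cell data frame (from [generate_cells()] or compatible)
#'   with `cell_id`, `x_um`, `y_um`, `cell_type` and, when clone probes are
#'   simulated, `true_clone`.
#' @param params A [transcript_sim_params()] object.
#' @return A list with `transcripts` (data frame: `transcript_id`,
#'   `feature_name`, `x_um`, `y_um`, `cell_id`, `qv`) and `manifest`
#'   recording the pre-bleed source counts (sparse cells x features
#'   matrix), the number of reassigned transcripts, the realised
#'   bleed-through fraction and the seed.
#' @export
generate_transcripts <- function(cells, params) {
  stopifnot(inherits(params, "transcript_sim_params"))
  if (nrow(cells) == 0L) stopf("cell table is empty")
  withr::local_seed(child_seed(params$seed, "transcripts"))
  n_cells <- nrow(cells)
  features <- params$panel
  F <- length(features)
  types <- colnames(params$mean_counts)
  # Cell types absent from the rate table express nothing.
  rates_of <- function(t) if (t %in% types) params$mean_counts[, t] else rep(0, F)

  src <- integer(0)
  feat <- integer(0)
  for (t in unique(cells$cell_type)) {
    rows <- which(cells$cell_type == t)
    lam <- rates_of(t)
    M <- matrix(rpois(length(rows) * F, rep(lam, each = length(rows))),
                nrow = length(rows))
    if (!is.null(params$labelled_overrides) && !is.null(cells$true_clone)) {
      lab <- which(!is.na(cells$true_clone[rows]))
      if (length(lab)) {
        for (f in names(params$labelled_overrides)) {
          j <- match(f, features)
          M[lab, j] <- rpois(length(lab), params$labelled_overrides[[f]])
        }
      }
    }
    if (length(params$clone_probes) && !is.null(cells$true_clone)) {
      for (p in intersect(params$clone_probes, features)) {
        j <- match(p, features)
        M[cells$true_clone[rows] != p | is.na(cells$true_clone[rows]), j] <- 0L
      }
    }
    cnt <- as.vector(M)
    src <- c(src, rep(rep(rows, times = F), cnt))
    feat <- c(feat, rep(rep(seq_len(F), each = length(rows)), cnt))
  }
  n_tx <- length(src)
  if (n_tx == 0L) {
    transcripts <- data.frame(transcript_id = character(0), feature_name = character(0),
                              x_um = numeric(0), y_um = numeric(0),
                              cell_id = character(0), qv = numeric(0))
    manifest <- list(transcripts = list(
      source_counts = Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                           dims = c(n_cells, F),
                                           dimnames = list(cells$cell_id, features)),
      n_transcripts = 0L, n_reassigned = 0L,
      bleedthrough_rate = params$bleedthrough_rate,
      realised_bleed_fraction = NA_real_, seed = params$seed
    ))
    return(list(transcripts = transcripts, manifest = manifest))
  }

  ord <- order(src, feat)
  src <- src[ord]; feat <- feat[ord]

  x <- cells$x_um[src] + rnorm(n_tx, 0, params$position_jitter_sigma_um)
  y <- cells$y_um[src] + rnorm(n_tx, 0, params$position_jitter_sigma_um)
  qv <- pmax(0, rnorm(n_tx, params$qv_mean, params$qv_sd))

  recipient <- src
  bleed <- logical(n_tx)
  if (params$bleedthrough_rate > 0 && n_cells > 1L) {
    bleed <- runif(n_tx) < params$bleedthrough_rate
    if (any(bleed)) {
      bleed_src <- unique(src[bleed])
      nn <- nearest_other_point(cells$x_um, cells$y_um, query = bleed_src)
      nn_of <- stats::setNames(nn, bleed_src)
      recipient[bleed] <- nn_of[as.character(src[bleed])]
    }
  }

  transcripts <- data.frame(
    transcript_id = sprintf("tx_%08d", seq_len(n_tx)),
    feature_name = features[feat],
    x_um = x, y_um = y,
    cell_id = cells$cell_id[recipient],
    qv = round(qv, 1),
    stringsAsFactors = FALSE
  )
  source_counts <- Matrix::sparseMatrix(
    i = src, j = feat, x = rep(1, n_tx), dims = c(n_cells, F),
    dimnames = list(cells$cell_id, features), use.last.ij = FALSE
  )
  manifest <- list(transcripts = list(
    source_counts = source_counts,
    n_transcripts = n_tx,
    n_reassigned = sum(bleed),
    bleedthrough_rate = params$bleedthrough_rate,
    realised_bleed_fraction = sum(bleed) / n_tx,
    seed = params$seed
  ))
  list(transcripts = transcripts, manifest = manifest)
}
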