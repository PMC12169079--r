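# Small programmatic fixtures shared across tests.

# A mask bundle with a single portal disk, a duct inside it, and a sinusoid
# stripe in the lobule.
disk_masks <- function(nr = 120, nc = 120, ps = 2, centre = c(120, 120),
                       radius_um = 60, duct_radius_um = 0,
                       sinusoid_rows = integer()) {
  px <- (seq_len(nc) - 0.5) * ps
  py <- (seq_len(nr) - 0.5) * ps
  d2 <- outer((py - centre[2])^2, (px - centre[1])^2, "+")
  portal <- d2 <= radius_um^2
  duct <- if (duct_radius_um > 0) d2 <= duct_radius_um^2 else matrix(FALSE, nr, nc)
  sinusoid <- matrix(FALSE, nr, nc)
  if (length(sinusoid_rows)) sinusoid[sinusoid_rows, ] <- TRUE
  sinusoid <- sinusoid & !portal
  hepatocyte <- !portal & !sinusoid
  mask_bundle(hepatocyte, portal, sinusoid, duct, pixel_size_um = ps)
}

# A tiny clonotype table builder; default CDR3s are distinct by encoding
# the clone index in the amino-acid alphabet.
clonotype_table <- function(counts, sample_id = "s1",
                            cdr3 = NULL, v = NULL) {
  n <- length(counts)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(cdr3)) {
    cdr3 <- vapply(seq_len(n), function(i) {
      paste0("CASS", aa[(i - 1L) %/% 400 + 1L], aa[((i - 1L) %/% 20) %% 20 + 1L],
             aa[(i - 1L) %% 20 + 1L], "F")
    }, character(1))
  }
  if (is.null(v)) v <- sprintf("TRBV%d*01", seq_len(n))
  data.frame(sample_id = rep(sample_id, n), v_call = v,
             j_call = rep("TRBJ2-1*01", n),
             junction_aa = cdr3, duplicate_count = as.integer(counts),
             stringsAsFactors = FALSE)
}

# Random CDR3-like strings for distance tests.
random_aa_string <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# A minimal cell_counts object from a dense matrix (rows = cells).
counts_fixture <- function(M, cell_ids = sprintf("c%03d", seq_len(nrow(M)))) {
  rownames(M) <- cell_ids
  structure(
    list(counts = methods::as(Matrix::Matrix(M, sparse = TRUE), "CsparseMatrix"),
         unassigned = stats::setNames(integer(ncol(M)), colnames(M)),
         n_input = sum(M), n_assigned = sum(M), n_unassigned = 0L,
         n_below_qv = 0L, min_qv = 0),
    class = "cell_counts"
  )
}
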