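simple_cells <- function(n_cd8 = 4, n_other = 2) {
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n_cd8 + n_other)),
    x_um = seq_len(n_cd8 + n_other) * 10, y_um = 5,
    cell_type = rep(c("CD8_T", "Hepatocyte"), c(n_cd8, n_other)),
    stringsAsFactors = FALSE
  )
}

test_that("transcript aggregation counts, filters and conserves", {
  cells <- simple_cells()
  tx <- data.frame(
    transcript_id = sprintf("t%d", 1:6),
    feature_name = c("clone1", "clone1", "GZMK", "clone2", "GZMK", "clone1"),
    x_um = 0, y_um = 0,
    cell_id = c("c001", "c001", "c002", NA, "c005", "c003"),
    qv = c(30, 10, 30, 30, 30, 30),
    stringsAsFactors = FALSE
  )
  cc <- aggregate_transcripts(tx, cells, min_qv = 20)
  expect_equal(as.numeric(cc$counts["c001", "clone1"]), 1)  # one filtered by qv
  expect_equal(as.numeric(cc$counts["c003", "clone1"]), 1)
  expect_equal(cc$unassigned[["clone2"]], 1L)
  expect_equal(cc$n_assigned + cc$n_unassigned + cc$n_below_qv, cc$n_input)

  # qv above everything: counts empty, unassigned tally unchanged
  hi <- aggregate_transcripts(tx, cells, min_qv = 1000)
  expect_equal(sum(hi$counts), 0)
  expect_equal(hi$unassigned[["clone2"]], 1L)

  none <- aggregate_transcripts(tx[0, ], cells, min_qv = 20)
  expect_equal(sum(none$counts), 0)

  orphan <- tx
  orphan$cell_id[1] <- "ghost"
  expect_error(aggregate_transcripts(orphan, cells), "ghost")
})

test_that("clone calling applies eligibility, thresholds and the tie rule", {
  cells <- simple_cells()
  M <- matrix(0, 6, 3, dimnames = list(cells$cell_id, c("clone1", "clone2", "clone3")))
  M["c001", "clone1"] <- 2                      # CD8, clone1
  M["c002", c("clone1", "clone2")] <- c(1, 1)   # CD8, tie -> ambiguous
  M["c005", "clone1"] <- 5                      # hepatocyte: not eligible
  cc <- counts_fixture(M, cells$cell_id)
  cfg <- clone_call_config(c("clone1", "clone2", "clone3"))
  out <- call_tcr_positive(cells, cc, cfg)
  expect_equal(out$cells$tcr_status[1], "TCR+")
  expect_equal(out$cells$clone[1], "clone1")
  expect_equal(out$cells$clone[2], "ambiguous")
  expect_equal(out$cells$tcr_status[5], "TCR-")
  expect_equal(out$summary$n_tcr_pos, 2L)
  expect_equal(out$summary$n_ambiguous, 1L)
  # ambiguous cells are excluded from per-clone frequencies
  expect_equal(unname(out$summary$clone_frequencies["clone1"]), 1 / 4)

  # raising min_transcripts never enlarges the TCR+ set (monotonicity)
  prev <- out$cells$tcr_status == "TCR+"
  for (k in 2:4) {
    cfg_k <- clone_call_config(c("clone1", "clone2", "clone3"), min_transcripts = k)
    cur <- call_tcr_positive(cells, cc, cfg_k)$cells$tcr_status == "TCR+"
    expect_true(all(!cur | prev))
    prev <- cur
  }
  expect_error(call_tcr_positive(simple_cells(0, 3), cc, cfg), "eligible")
})

test_that("bleed-through shares follow the constructed table", {
  cells <- simple_cells(4, 2)
  # 45 of 100 clone transcripts inside CD8 cells
  tx <- data.frame(
    transcript_id = sprintf("t%d", 1:100),
    feature_name = "clone1", x_um = 0, y_um = 0,
    cell_id = c(rep("c001", 45), rep("c005", 55)),
    qv = 30, stringsAsFactors = FALSE
  )
  bt <- bleedthrough_fraction(tx, cells, "clone1")
  expect_equal(bt$eligible_fraction, 0.45)
  expect_equal(bt$outside_eligible_fraction, 0.55)
  expect_equal(bt$unassigned_fraction, 0)
})

test_that("with no bleed and CD8-restricted expression all clone signal is eligible", {
  masks <- disk_masks(nr = 100, nc = 100, ps = 4, centre = c(200, 200), radius_um = 60)
  zm <- build_zone_map(masks, 50)
  gc1 <- suppressWarnings(generate_cells(zm, cell_sim_params(
    base_density_per_mm2 = c(CD8_T = 1500, Hepatocyte = 2000),
    clone_labels = "clone1", clone_freq_in_cd8 = 0.3, seed = 2
  )))  # the fixture has no sinusoid zone, which warns by design
  pars <- transcript_sim_params(
    panel = c("clone1", "GZMK"),
    mean_counts = cbind(CD8_T = c(clone1 = 3, GZMK = 1),
                        Hepatocyte = c(clone1 = 0, GZMK = 0.2)),
    clone_probes = "clone1", bleedthrough_rate = 0, seed = 3
  )
  gtx <- generate_transcripts(gc1$cells, pars)
  expect_true(all(gtx$transcripts$cell_id[gtx$transcripts$feature_name == "clone1"] %in%
                  gc1$cells$cell_id[gc1$cells$cell_type == "CD8_T"]))
  bt <- bleedthrough_fraction(gtx$transcripts, gc1$cells, "clone1")
  expect_equal(bt$outside_eligible_fraction, 0)

  # aggregation reproduces the generator's source counts when bleed = 0
  cc <- aggregate_transcripts(gtx$transcripts, gc1$cells, min_qv = 0)
  src <- gtx$manifest$transcripts$source_counts
  expect_equal(as.matrix(cc$counts[, colnames(src)]), as.matrix(src),
               ignore_attr = TRUE)
})

test_that("transcript generation conserves counts and reassigns at the requested rate", {
  cells <- simple_cells(30, 30)
  cells$x_um <- runif(60, 0, 500); cells$y_um <- runif(60, 0, 500)
  pars <- transcript_sim_params(
    panel = c("A", "B"), mean_counts = cbind(CD8_T = c(A = 5, B = 5),
                                             Hepatocyte = c(A = 5, B = 5)),
    bleedthrough_rate = 0.3, seed = 6
  )
  gtx <- generate_transcripts(cells, pars)
  man <- gtx$manifest$transcripts
  expect_equal(nrow(gtx$transcripts), man$n_transcripts)   # conservation
  expect_equal(sum(man$source_counts), man$n_transcripts)
  p <- man$realised_bleed_fraction
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / man$n_transcripts) + 0.02)

  zero <- generate_transcripts(cells, transcript_sim_params(
    panel = c("A", "B"), mean_counts = cbind(CD8_T = c(A = 5, B = 5),
                                             Hepatocyte = c(A = 5, B = 5)),
    bleedthrough_rate = 0, seed = 6
  ))
  # with bleed 0 every transcript stays in its source cell
  src_cells <- rownames(zero$manifest$transcripts$source_counts)
  expect_equal(zero$manifest$transcripts$n_reassigned, 0L)
  expect_true(all(zero$transcripts$cell_id %in% src_cells))
})

test_that("expression summary reports percent expressing and symmetric scaling", {
  M <- rbind(
    matrix(c(rep(1, 10), rep(0, 10)), 10, 2),   # group 1: gene A always, B never
    matrix(c(rep(1, 10), rep(0, 10)), 10, 2)    # group 2 identical
  )
  colnames(M) <- c("A", "B")
  cc <- counts_fixture(M)
  es <- expression_summary(cc, rep(c("g1", "g2"), each = 10), c("A", "B"))
  expect_equal(es$pct_expressing[es$gene == "A"], c(1, 1))
  expect_equal(es$pct_expressing[es$gene == "B"], c(0, 0))
  expect_equal(es$scaled_mean, rep(0, 4))  # identical groups scale to zero
  expect_error(expression_summary(cc, rep("g", 20), "Z"), "not in panel")
})

test_that("identical groups produce null differential expression", {
  withr::with_seed(13, {
    M <- matrix(rpois(40 * 6, 2), 40, 6)
    colnames(M) <- paste0("g", 1:6)
    cc <- counts_fixture(rbind(M, M))
    deg <- differential_expression(cc, rep(c(TRUE, FALSE), each = 40),
                                   rep(c(FALSE, TRUE), each = 40))
    expect_true(all(abs(deg$log2_fold_change) < 1e-9))
    expect_true(all(!deg$significant))
    expect_true(all(deg$p_adj >= deg$p_value))
  })
})

test_that("rank-sum p-values equal stats::wilcox.test", {
  withr::with_seed(99, {
    for (i in 1:10) {
      x <- matrix(c(rpois(60, 2), rpois(140, 2.6)), ncol = 1)
      g <- rep(c(TRUE, FALSE), c(60, 140))
      ours <- clonescape:::rank_sum_p(x, g)
      ref <- stats::wilcox.test(x[g, 1], x[!g, 1], exact = FALSE,
                                correct = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("differential expression input contracts are enforced", {
  M <- matrix(1, 10, 2, dimnames = list(NULL, c("A", "B")))
  cc <- counts_fixture(M)
  expect_error(differential_expression(cc, rep(c(TRUE, FALSE), each = 5),
                                       rep(TRUE, 10)), "disjoint")
  expect_error(differential_expression(cc, c(TRUE, TRUE, rep(FALSE, 8)),
                                       c(FALSE, FALSE, rep(TRUE, 8))),
               "at least 3")
})

test_that("MAIT co-expression covers the degenerate cases", {
  M <- cbind(KLRB1 = c(1, 1, 0, 2), `TRAV1-2` = c(0, 0, 0, 0))
  cc <- counts_fixture(M)
  res <- mait_coexpression(cc)
  expect_equal(res$frac_coexpressing, 0)
  both <- counts_fixture(cbind(KLRB1 = rep(2, 4), `TRAV1-2` = rep(1, 4)))
  expect_equal(mait_coexpression(both)$frac_coexpressing, 1)
  expect_error(mait_coexpression(cc, genes = c("KLRB1", "CCR6")), "not in panel")
})

test_that("independent marker rates multiply in co-expression (oracle product)", {
  withr::with_seed(31, {
    n <- 20000
    M <- cbind(KLRB1 = rbinom(n, 1, 0.47), `TRAV1-2` = rbinom(n, 1, 0.05))
    cc <- counts_fixture(M)
    res <- mait_coexpression(cc)
    expected <- 0.47 * 0.05
    expect_lt(abs(res$frac_coexpressing - expected),
              3 * sqrt(expected * (1 - expected) / n))
  })
})
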