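test_that("frequencies, ranks and aggregation follow hand-computed values", {
  tab <- clonotype_table(c(6, 3, 1), cdr3 = c("CAAAF", "CDDDF", "CEEEF"))
  s <- compute_frequencies(tab)
  expect_equal(s$frequency, c(0.6, 0.3, 0.1))
  expect_equal(s$rank, 1:3)
  expect_equal(sum(s$frequency), 1, tolerance = 1e-12)

  # duplicate rows of the same clone are summed before frequencies
  tab2 <- rbind(tab, tab[1, ])
  s2 <- compute_frequencies(tab2)
  expect_equal(nrow(s2), 3L)
  expect_equal(s2$count[s2$cdr3_aa == "CAAAF"], 12)

  one <- compute_frequencies(clonotype_table(5))
  expect_equal(one$frequency, 1)
  expect_equal(one$rank, 1L)
})

test_that("frequency computation rejects bad input", {
  tab <- clonotype_table(c(2, 3))
  tab$sample_id <- c("s1", "s2")
  expect_error(compute_frequencies(tab), "mixed sample ids")
  bad <- clonotype_table(3)
  bad$junction_aa <- "CASS1F"
  expect_error(compute_frequencies(bad), "invalid CDR3")
  expect_error(compute_frequencies(clonotype_table(integer(0))), "empty")
})

test_that("frequencies always sum to one (property)", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(2:40, 1)
      tab <- clonotype_table(sample(1:1000, n, replace = TRUE),
                             cdr3 = replicate(n, paste0("C", random_aa_string(8), "F")))
      expect_equal(sum(compute_frequencies(tab)$frequency), 1, tolerance = 1e-9)
    }
  })
})

test_that("hyperexpansion uses a strict threshold", {
  # 200 clones at exactly 0.5% each: none hyperexpanded
  s <- call_hyperexpanded(compute_frequencies(clonotype_table(rep(5, 200))))
  expect_equal(sum(s$hyperexpanded), 0L)
  # a clone at exactly the threshold is NOT hyperexpanded ("more than 1%")
  s2 <- call_hyperexpanded(compute_frequencies(clonotype_table(c(1, 99),
                           cdr3 = c("CAAAF", "CDDDF"))))
  expect_equal(s2$frequency[s2$cdr3_aa == "CAAAF"], 0.01)
  expect_false(s2$hyperexpanded[s2$cdr3_aa == "CAAAF"])
  expect_true(s2$hyperexpanded[s2$cdr3_aa == "CDDDF"])
  expect_error(call_hyperexpanded(s2, threshold = 0), "threshold")
  expect_error(call_hyperexpanded(s2, threshold = 1), "threshold")
})

test_that("sample comparison handles identity, disjoint sets and symmetry", {
  a <- call_hyperexpanded(compute_frequencies(clonotype_table(c(50, 30, 20),
        cdr3 = c("CAAAF", "CDDDF", "CEEEF"), v = rep("TRBV9*01", 3))))
  b <- call_hyperexpanded(compute_frequencies(clonotype_table(c(10, 10),
        cdr3 = c("CGGGF", "CHHHF"), v = rep("TRBV9*01", 2), sample_id = "s2")))
  expect_equal(compare_samples(a, b)$n_shared, 0L)

  self <- compare_samples(a, a)
  expect_equal(self$n_shared, 3L)
  expect_true(all(self$persistence$class %in% c("hyper_in_both", "hyper_in_neither")))

  ab <- compare_samples(a, b)
  ba <- compare_samples(b, a)
  expect_equal(ab$n_shared, ba$n_shared)
  expect_equal(ab$n_unique_a, ba$n_unique_b)
  expect_equal(ab$n_unique_b, ba$n_unique_a)
  expect_equal(ab$n_shared + ab$n_unique_a, nrow(a))
})

test_that("CDR3 matching respects the distance cutoff and V consistency", {
  s <- compute_frequencies(clonotype_table(c(5, 5), cdr3 = c("CASSL", "CWWWW"),
                                           v = c("TRBV9*01", "TRBV2*01")))
  ref <- data.frame(cdr3_aa = "CASSV", v_call = "TRBV9*02",
                    epitope = "YLQPRTFLL", antigen = "spike",
                    source_id = "r1", stringsAsFactors = FALSE)
  m1 <- match_cdr3(s, ref, max_edit_distance = 1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$edit_distance, 1L)
  expect_true(m1$v_gene_consistent)  # allele stripped: TRBV9 == TRBV9
  m0 <- match_cdr3(s, ref, max_edit_distance = 0)
  expect_equal(nrow(m0), 0L)
  expect_error(match_cdr3(s, ref[0, ]), "empty")
})

test_that("match distances agree with a dynamic-programming oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      a <- random_aa_string(sample(5:15, 1))
      b <- random_aa_string(sample(5:15, 1))
      s <- data.frame(clone_key = "q", cdr3_aa = a, stringsAsFactors = FALSE)
      ref <- data.frame(cdr3_aa = b, stringsAsFactors = FALSE)
      m <- match_cdr3(s, ref, max_edit_distance = 100)
      expect_equal(m$edit_distance, dp_edit_distance(a, b))
    }
  })
})

test_that("injected reference sequences are recovered by exact matching", {
  ref <- spike_reference()
  pars <- repertoire_sim_params(
    n_clones_a = 40, n_clones_b = 60, shared_clones = 12,
    top_freqs_a = c(0.12, 0.05, 0.04), top_freqs_b = c(0.10, 0.06, 0.05),
    total_reads_per_sample = 20000,
    spike_cdr3_aa = ref$cdr3_aa[1:3], spike_v_call = ref$v_call[1:3],
    seed = 5
  )
  pr <- generate_repertoire_pair(pars)
  s_b <- compute_frequencies(pr$sample_b)
  m <- match_cdr3(s_b, ref, max_edit_distance = 0)
  expect_setequal(m$clone_key, pr$manifest$repertoire$spike_keys)
  expect_true(all(m$edit_distance == 0L))
})
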