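test_that("parameter validation catches infeasible repertoires", {
  expect_error(repertoire_sim_params(10, 10, 11), "shared_clones")
  expect_error(repertoire_sim_params(10, 10, 2, top_freqs_a = c(0.6, 0.5)),
               "sum to less than 1")
  expect_error(repertoire_sim_params(10, 10, 2, top_freqs_b = 1.2), "top_freqs_b")
})

test_that("disjoint construction yields no shared clones", {
  pr <- generate_repertoire_pair(repertoire_sim_params(
    n_clones_a = 25, n_clones_b = 30, shared_clones = 0,
    total_reads_per_sample = 5000, seed = 2
  ))
  ka <- make_clone_key(pr$sample_a$v_call, pr$sample_a$junction_aa)
  kb <- make_clone_key(pr$sample_b$v_call, pr$sample_b$junction_aa)
  expect_length(intersect(ka, kb), 0)
})

test_that("clone counts are exact and forced frequencies are recovered", {
  pars <- repertoire_sim_params(
    n_clones_a = 189, n_clones_b = 508, shared_clones = 59,
    top_freqs_a = 0.16, top_freqs_b = 0.145,
    total_reads_per_sample = 1e5, seed = 3
  )
  pr <- generate_repertoire_pair(pars)
  expect_equal(nrow(pr$sample_a), 189L)
  expect_equal(nrow(pr$sample_b), 508L)
  ka <- make_clone_key(pr$sample_a$v_call, pr$sample_a$junction_aa)
  kb <- make_clone_key(pr$sample_b$v_call, pr$sample_b$junction_aa)
  expect_equal(length(intersect(ka, kb)), 59L)

  # forced top-clone frequency within 3 binomial SD at 100k reads
  s_b <- compute_frequencies(pr$sample_b)
  sd3 <- 3 * sqrt(0.145 * 0.855 / 1e5)
  expect_lt(abs(s_b$frequency[1] - 0.145), sd3)
})

test_that("generated CDR3 sequences are valid and identical across shared clones", {
  pr <- generate_repertoire_pair(repertoire_sim_params(
    n_clones_a = 30, n_clones_b = 30, shared_clones = 10,
    total_reads_per_sample = 3000, seed = 9
  ))
  for (tab in list(pr$sample_a, pr$sample_b)) {
    expect_true(all(grepl("^C[ACDEFGHIKLMNPQRSTVWY]{6,18}F$", tab$junction_aa)))
    expect_true(all(nchar(tab$junction_aa) >= 8 & nchar(tab$junction_aa) <= 20))
    # nucleotide junction back-translates to the amino-acid junction
    expect_true(all(nchar(tab$junction) == 3 * nchar(tab$junction_aa)))
  }
  shared <- pr$manifest$repertoire$shared_keys
  ka <- make_clone_key(pr$sample_a$v_call, pr$sample_a$junction_aa)
  kb <- make_clone_key(pr$sample_b$v_call, pr$sample_b$junction_aa)
  expect_true(all(shared %in% ka) && all(shared %in% kb))
})

test_that("identical parameters and seed give byte-identical tables", {
  pars <- repertoire_sim_params(20, 25, 5, top_freqs_a = 0.2,
                                total_reads_per_sample = 2000, seed = 11)
  p1 <- generate_repertoire_pair(pars)
  p2 <- generate_repertoire_pair(pars)
  expect_identical(p1$sample_a, p2$sample_a)
  expect_identical(p1$sample_b, p2$sample_b)
})
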