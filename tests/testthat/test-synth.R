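# Synthetic cohort generator: Markov sequence simulation, count sampling,
# tree simulation, and the end-to-end cohort contract.

test_that("state sequences follow degenerate chains exactly", {
  s <- simulate_state_sequences(diag(2), c(1, 0), n_steps = 5, n_series = 3,
                                seed = 1)
  expect_true(all(vapply(s, function(x) all(x == 1), logical(1))))

  P <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  s <- simulate_state_sequences(P, c(1, 0), n_steps = 4, n_series = 5,
                                seed = 2)
  expect_true(all(vapply(s, identical, logical(1), y = c(1L, 2L, 1L, 2L))))
})

test_that("empirical transition frequencies converge to the chain", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  seqs <- simulate_state_sequences(P, c(1, 0), n_steps = 50, n_series = 200,
                                   seed = 1)
  C <- matrix(0, 2, 2)
  for (s in seqs) {
    for (i in seq_len(length(s) - 1)) C[s[i], s[i + 1]] <- C[s[i], s[i + 1]] + 1
  }
  Phat <- C / rowSums(C)
  expect_lt(max(abs(Phat - P)), 0.05)
})

test_that("non-stochastic matrices are rejected with the row index", {
  P <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(simulate_state_sequences(P, c(1, 0), 3, 1, seed = 1), "row 1")
})

test_that("sample_counts respects the profile and library size", {
  # degenerate point mass
  out <- sample_counts(list(mean = c(1, 0, 0), concentration = Inf),
                       library_size = 600, seed = 1)
  expect_identical(unname(out), c(600L, 0L, 0L))
  expect_error(sample_counts(list(mean = numeric(), concentration = 1), 10, 1),
               "empty")

  # SC-like profile: dominant mean 0.61 recovered across draws
  prof <- default_state_profiles(50)$SC
  doms <- vapply(1:1000, function(i) {
    sample_counts(prof, 600, seed = i)[["ASV_3"]] / 600
  }, double(1))
  expect_gt(mean(doms), 0.58)
  expect_lt(mean(doms), 0.64)

  # uniform profile: each taxon's mean fraction near 1/4
  unif <- list(mean = rep(0.25, 4), concentration = Inf)
  fr <- vapply(1:1000, function(i) sample_counts(unif, 600, seed = 5000 + i),
               integer(4)) / 600
  expect_true(all(abs(rowMeans(fr) - 0.25) < 0.02))
})

test_that("simulated trees are valid, named, and reproducible", {
  tr <- simulate_tree(2, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("ASV_1", "ASV_2"))
  rt <- ape::read.tree(text = ape::write.tree(tr))
  expect_equal(sort(rt$tip.label), sort(tr$tip.label))

  t1 <- simulate_tree(300, seed = 9)
  t2 <- simulate_tree(300, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length > 0))
  expect_error(simulate_tree(1, seed = 1), ">= 2")
})

test_that("generate_cohort produces the configured design with truth", {
  co <- small_cohort(1)
  expect_equal(nrow(co$metadata), 15 * 3 * 4)
  expect_equal(nrow(as_tibble(co$counts)), 180)
  expect_setequal(unique(co$truth$state$state), c("SC", "EC", "LC", "IC"))
  # truth stationary solves pi P = pi
  for (site in names(co$truth$transition_matrices)) {
    P <- co$truth$transition_matrices[[site]]
    pi_ <- co$truth$stationary[[site]]
    expect_lt(max(abs(pi_ %*% P - pi_)), 1e-10)
  }
  # metadata completeness and key uniqueness
  expect_true(all(co$truth$state$sample_id %in% co$metadata$sample_id))
  expect_silent(validate_metadata(co$metadata))
})

test_that("single-sample edge case produces no transitions", {
  cfg <- synth_config(n_patients = 1, body_sites = "gut", time_days = 1,
                      seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$metadata), 1)
  expect_error(estimate_transitions(co$truth$state, co$metadata, "gut"),
               "length >= 2")
})

test_that("the master seed fixes outputs bit-for-bit", {
  a <- generate_cohort(synth_config(seed = 5))
  b <- generate_cohort(synth_config(seed = 5))
  c <- generate_cohort(synth_config(seed = 6))
  expect_identical(count_matrix(a$counts), count_matrix(b$counts))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$tree_newick, b$truth$tree_newick)
  expect_false(identical(count_matrix(a$counts), count_matrix(c$counts)))
})

test_that("long-run simulated state frequencies match the true stationary", {
  P <- default_transition_matrices()$gut
  s <- simulate_state_sequences(P, rep(0.25, 4), n_steps = 1e5, seed = 8)[[1]]
  emp <- table(factor(s, colnames(P))) / 1e5
  pi_ <- stationary_distribution(P)[1, ]
  expect_lt(sum(abs(emp - pi_)) / 2, 0.01)
})

test_that("planted ASV pairs are strongly monotonically coupled", {
  co <- small_cohort(1)
  m <- count_matrix(co$counts)
  for (pair in co$truth$planted_edges) {
    rho <- cor(m[, pair[1]], m[, pair[2]], method = "spearman")
    expect_gte(rho, 0.8)
  }
})

test_that("invalid configurations fail validation", {
  expect_error(synth_config(transition_matrices = list(
    gut = matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2),
    oral = diag(2), skin = diag(2)),
    state_profiles = list(
      A = list(mean = c(0.5, 0.5), concentration = 1),
      B = list(mean = c(0.5, 0.5), concentration = 1)),
    n_asvs = 2, contamination = NULL, planted_edges = NULL), "sums to")
})
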