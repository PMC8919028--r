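# Markov transition models, stationary distributions, recurrence
# classification, conditional detection.

hand_series_fixture <- function() {
  # two patients at one site: series A,A,B and A,B,B
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    patient_id = rep(c("p1", "p2"), each = 3),
    body_site = "gut",
    time_index = rep(1:3, 2))
  asn <- tibble::tibble(sample_id = meta$sample_id,
                        state = c("A", "A", "B", "A", "B", "B"))
  list(meta = meta, asn = asn)
}

test_that("transition counts and probabilities match hand tallies", {
  fx <- hand_series_fixture()
  m <- estimate_transitions(fx$asn, fx$meta, "gut")
  expect_equal(m$C, matrix(c(1, 2, 0, 1), 2, 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(m$P["A", ], c(A = 1 / 3, B = 2 / 3))
  expect_equal(m$P["B", ], c(A = 0, B = 1))
  # edge list and stability from the same fixture
  edges <- transition_graph_summary(m)
  expect_equal(nrow(edges), 3)
  expect_equal(attr(edges, "mean_self_transition"), (1 / 3 + 1) / 2)
})

test_that("constant series flag unobserved origin rows as uniform", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         patient_id = rep("p1", 4), body_site = "gut",
                         time_index = 1:4)
  asn <- tibble::tibble(sample_id = meta$sample_id, state = "A")
  expect_warning(
    m <- estimate_transitions(asn, meta, "gut", states = c("A", "B")),
    "uniform")
  expect_equal(m$P["A", "A"], 1)
  expect_equal(unname(m$P["B", ]), c(0.5, 0.5))
  expect_equal(m$uniform_rows, "B")
})

test_that("transition estimates recover the generating chain", {
  P <- default_transition_matrices()$oral
  seqs <- simulate_state_sequences(P, rep(0.25, 4), n_steps = 50,
                                   n_series = 200, seed = 12)
  n <- 200 * 50
  meta <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                         patient_id = rep(seq_len(200), each = 50),
                         body_site = "oral",
                         time_index = rep(seq_len(50), 200))
  asn <- tibble::tibble(sample_id = meta$sample_id, state = unlist(seqs))
  m <- estimate_transitions(asn, meta, "oral")
  expect_lt(max(abs(m$P[rownames(P), colnames(P)] - P)), 0.05)
})

test_that("stationary distributions solve pi P = pi, including reducible chains", {
  P <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(unname(stationary_distribution(P)[1, ]), c(0.5, 0.5))

  # reducible: identity has one extremal solution per absorbing state
  s_id <- stationary_distribution(diag(2))
  expect_equal(nrow(s_id), 2)
  expect_equal(sort(s_id[, 1]), c(0, 1))

  P2 <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  pi2 <- stationary_distribution(P2)[1, ]
  expect_equal(unname(pi2), c(5 / 6, 1 / 6), tolerance = 1e-12)
  # matrix-power oracle
  Pk <- P2
  for (i in 1:10) Pk <- Pk %*% Pk
  expect_lt(max(abs(sweep(Pk, 2, pi2))), 1e-8)

  expect_error(stationary_distribution(matrix(c(1, 1, 0, 1), 2, 2)), "row")
})

test_that("recurrence classification matches structure and an oracle", {
  P <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  cls <- classify_states(P)
  expect_equal(unname(c(cls)), c("recurrent", "transient"))

  P_irr <- matrix(1 / 3, 3, 3)
  expect_true(all(classify_states(P_irr) == "recurrent"))

  set.seed(31)
  for (i in 1:100) {
    P <- random_stochastic(4, sparse = TRUE)
    got <- classify_states(P) == "recurrent"
    expect_identical(unname(got), oracle_recurrent(P))
  }
})

test_that("smoothing drives transition rows toward uniform", {
  fx <- hand_series_fixture()
  m <- estimate_transitions(fx$asn, fx$meta, "gut", smoothing = 1e6)
  expect_true(all(abs(m$P - 0.5) < 1e-4))
})

test_that("conditional detection counts and Bayes identity are exact", {
  # 4 matched occasions; ASV x at s1 in 4, both sites in 2
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    patient_id = rep("p1", 8),
    body_site = rep(c("gut", "oral"), 4),
    time_index = rep(1:4, each = 2))
  m <- matrix(0L, 8, 2, dimnames = list(meta$sample_id, c("x", "y")))
  m[meta$body_site == "gut", "x"] <- 1L           # x always in gut
  m[meta$sample_id %in% c("s2", "s4"), "x"] <- 1L # x in oral at t1, t2
  m[, "y"] <- 1L                                  # y everywhere
  cd <- conditional_detection(count_tbl(m), meta)
  x_go <- dplyr::filter(cd$per_asv, asv_id == "x", site_from == "gut",
                        site_to == "oral")
  expect_equal(x_go$p_cond, 0.5)
  y_row <- dplyr::filter(cd$per_asv, asv_id == "y", site_from == "gut",
                         site_to == "oral")
  expect_equal(y_row$p_cond, 1)
  # Bayes identity on every defined entry
  flip <- dplyr::select(cd$per_asv, asv_id, site_from = site_to,
                        site_to = site_from, p_flip = p_cond)
  both <- dplyr::inner_join(cd$per_asv, flip,
                            by = c("asv_id", "site_from", "site_to"))
  both <- dplyr::filter(both, !is.na(p_cond), !is.na(p_flip))
  expect_lt(max(abs(both$p_cond * both$p_s1 - both$p_flip * both$p_s2)),
            1e-15)
})

test_that("ASVs undetected at the conditioning site are missing, not zero", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         patient_id = "p1",
                         body_site = rep(c("gut", "oral"), 2),
                         time_index = rep(1:2, each = 2))
  m <- matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 1L, 1L), 4, 2,
              dimnames = list(meta$sample_id, c("x", "y")))
  cd <- conditional_detection(count_tbl(m), meta)
  x_from_gut <- dplyr::filter(cd$per_asv, asv_id == "x", site_from == "gut")
  expect_true(is.na(x_from_gut$p_cond))
})

test_that("degenerate chains summarize correctly", {
  asn <- tibble::tibble(sample_id = paste0("s", 1:4),
                        state = c("A", "A", "B", "B"))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4), patient_id = "p1",
                         body_site = "gut", time_index = 1:4)
  m <- estimate_transitions(asn, meta, "gut")
  edges <- transition_graph_summary(m)
  expect_true(all(edges$prob > 0))
  # uniform 4-state chain: 16 edges at 0.25, stability 0.25
  mu <- structure(list(body_site = "gut", states = letters[1:4],
                       C = matrix(1, 4, 4, dimnames = list(letters[1:4],
                                                           letters[1:4])),
                       P = matrix(0.25, 4, 4, dimnames = list(letters[1:4],
                                                              letters[1:4])),
                       stationary = matrix(0.25, 1, 4),
                       classification = rep("recurrent", 4),
                       mean_self_transition = 0.25,
                       observed_origin = rep(TRUE, 4), uniform_rows = character(),
                       per_patient = list(), smoothing = 0, n_steps = 16),
                  class = "transition_model")
  eu <- transition_graph_summary(mu)
  expect_equal(nrow(eu), 16)
  expect_true(all(eu$prob == 0.25))
})
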