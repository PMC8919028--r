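# betaMNTD/betaNTI, Raup-Crick, process partitioning, chi-square contrasts,
# and odds-ratio attribution.

test_that("betaMNTD equals the exhaustive double-loop oracle exactly", {
  set.seed(41)
  for (rep in 1:50) {
    nt <- sample(3:10, 1)
    tr <- ape::rtree(nt, tip.label = paste0("ASV_", seq_len(nt)))
    m <- matrix(rpois(2 * nt, 2), 2, nt,
                dimnames = list(c("a", "b"), paste0("ASV_", seq_len(nt))))
    m[1, sample(nt, 1)] <- m[1, sample(nt, 1)] + 1L
    m[2, sample(nt, 1)] <- m[2, sample(nt, 1)] + 1L
    tab <- count_tbl(m)
    got <- beta_mntd(tab, tr,
                     tibble::tibble(sample_i = "a", sample_j = "b"))$bmntd
    D <- ape::cophenetic.phylo(tr)[colnames(m), colnames(m)]
    expect_lt(abs(got - oracle_bmntd(m[1, ], m[2, ], D)), 1e-12)
  }
})

test_that("betaMNTD trivial geometries behave as expected", {
  tr <- ape::rtree(4, tip.label = paste0("ASV_", 1:4))
  m <- rbind(a = c(2, 1, 0, 3), b = c(2, 1, 0, 3), c = c(5, 0, 0, 0),
             d = c(0, 0, 4, 0))
  colnames(m) <- paste0("ASV_", 1:4)
  tab <- count_tbl(m)
  res <- beta_mntd(tab, tr, tibble::tibble(
    sample_i = c("a", "c"), sample_j = c("b", "d")))
  expect_equal(res$bmntd[1], 0)  # identical communities
  D <- ape::cophenetic.phylo(tr)
  expect_equal(res$bmntd[2], D["ASV_1", "ASV_3"])  # singletons: patristic d
  # missing tip is an error
  tr2 <- ape::drop.tip(tr, "ASV_4")
  expect_error(beta_mntd(tab, tr2), "missing from tree")
})

test_that("betaMNTD agrees with an independent package implementation", {
  set.seed(42)
  nt <- 15
  tr <- ape::rtree(nt, tip.label = paste0("ASV_", seq_len(nt)))
  m <- matrix(rpois(6 * nt, 2), 6, nt,
              dimnames = list(paste0("s", 1:6), paste0("ASV_", seq_len(nt))))
  m[cbind(1:6, sample(nt, 6))] <- 5L
  ours <- beta_mntd(count_tbl(m), tr)
  ref <- as.matrix(picante::comdistnt(m, ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  expect_lt(max(abs(ours$bmntd - ref[cbind(ours$sample_i, ours$sample_j)])),
            1e-12)
})

test_that("betaNTI is zero on a star phylogeny and scale-invariant", {
  # star tree: tip shuffling cannot change any distance
  star <- ape::stree(6, type = "star")
  star$tip.label <- paste0("ASV_", 1:6)
  star$edge.length <- rep(1, nrow(star$edge))
  m <- rbind(a = c(3, 2, 1, 0, 0, 0), b = c(0, 0, 1, 2, 3, 0))
  colnames(m) <- paste0("ASV_", 1:6)
  bn <- beta_nti(count_tbl(m), star, n_null = 99, seed = 1)
  expect_equal(bn$bnti, 0)

  set.seed(43)
  tr <- ape::rtree(10, tip.label = paste0("ASV_", 1:10))
  m2 <- matrix(rpois(4 * 10, 2) + 1L, 4, 10,
               dimnames = list(paste0("s", 1:4), paste0("ASV_", 1:10)))
  tab <- count_tbl(m2)
  b1 <- beta_nti(tab, tr, n_null = 199, seed = 7)
  tr_scaled <- tr
  tr_scaled$edge.length <- tr$edge.length * 7.3
  b2 <- beta_nti(tab, tr_scaled, n_null = 199, seed = 7)
  # betaMNTD scales linearly; the standardized score does not change
  expect_equal(b2$bmntd, b1$bmntd * 7.3, tolerance = 1e-12)
  expect_equal(b2$bnti, b1$bnti, tolerance = 1e-9)
  # and the score ignores the tip order of the Newick encoding
  tr_rot <- ape::read.tree(text = ape::write.tree(ape::rotate(tr, 12)))
  b3 <- beta_nti(tab, tr_rot, n_null = 199, seed = 7)
  expect_equal(b3$bmntd, b1$bmntd, tolerance = 1e-12)
})

test_that("Raup-Crick stays in bounds and is centered under its own null", {
  # communities generated by the null reassembly process itself (fixed-point
  # metacommunity stats): RC should be near-uniform on [-1, 1]
  rcs <- unlist(lapply(1:4, function(b) {
    fx <- neutral_null_cohort(seed = b)
    pr <- t(combn(fx$test_ids, 2))[1:60, ]
    raup_crick_bray(fx$table,
                    tibble::tibble(sample_i = pr[, 1], sample_j = pr[, 2]),
                    n_null = 499, seed = b)$rc
  }))
  expect_gte(length(rcs), 200)
  expect_true(all(rcs >= -1 & rcs <= 1))
  expect_gte(mean(abs(rcs) <= 0.95), 0.9)
  expect_lt(abs(mean(rcs)), 0.1)
})

test_that("Raup-Crick hits its boundaries for extreme observations", {
  # two communities on private species within a shared-species metacommunity:
  # observed BC (=1) exceeds nearly every null reassembly
  m <- rbind(a = c(50, 0, rep(2, 8)), b = c(0, 50, rep(2, 8)))
  m2 <- matrix(rep(c(10, 10, rep(2, 8)), 10), 10, 10, byrow = TRUE)
  m_all <- rbind(m, m2)
  dimnames(m_all) <- list(c("a", "b", paste0("s", 1:10)), paste0("x", 1:10))
  storage.mode(m_all) <- "integer"
  tab <- count_tbl(m_all)
  rc <- raup_crick_bray(tab, tibble::tibble(sample_i = "a", sample_j = "b"),
                        n_null = 199, seed = 5)$rc
  expect_gt(rc, 0.9)
  # identical communities: observed BC (=0) below every null
  rc0 <- raup_crick_bray(tab, tibble::tibble(sample_i = "s1",
                                             sample_j = "s2"),
                         n_null = 199, seed = 6)$rc
  expect_lt(rc0, 0)
})

test_that("process partitioning applies the thresholds exactly", {
  t1 <- tibble::tibble(bnti = c(3, -3, 0), rc = c(0, 0, 0.2))
  p1 <- partition_processes(t1)
  expect_equal(p1$summary$fraction,
               c(1 / 3, 1 / 3, 0, 0, 1 / 3))
  t2 <- tibble::tibble(bnti = c(0.5, -1.9, 1.2), rc = c(0.3, -0.9, 0))
  expect_equal(partition_processes(t2)$summary$fraction[5], 1)
  # 2.5 is variable selection; boundary 2 is not
  t3 <- tibble::tibble(bnti = c(2.5, 2), rc = c(0, 0))
  p3 <- partition_processes(t3)
  expect_equal(p3$summary$n[p3$summary$process == "variable_selection"], 1L)
  expect_equal(p3$summary$n[p3$summary$process == "drift"], 1L)
})

test_that("partition fractions match a brute-force recount on random inputs", {
  set.seed(45)
  n <- 10000
  tt <- tibble::tibble(bnti = runif(n, -4, 4), rc = runif(n, -1, 1))
  p <- partition_processes(tt)
  recount <- c(
    variable_selection = sum(tt$bnti > 2),
    homogeneous_selection = sum(tt$bnti < -2),
    dispersal_limitation = sum(abs(tt$bnti) <= 2 & tt$rc > 0.95),
    homogenizing_dispersal = sum(abs(tt$bnti) <= 2 & tt$rc < -0.95),
    drift = sum(abs(tt$bnti) <= 2 & abs(tt$rc) <= 0.95))
  expect_identical(setNames(p$summary$n, as.character(p$summary$process)),
                   recount)
  expect_equal(sum(p$summary$fraction), 1)
  # missing values excluded and counted
  tt$bnti[1:5] <- NA
  pm <- partition_processes(tt)
  expect_equal(pm$n_missing$n_missing, 5L)
  expect_equal(sum(pm$summary$n), n - 5L)
})

test_that("chi-square contrasts match hand formulas", {
  part <- structure(list(summary = tibble::tibble(
    group = rep(c("g1", "g2"), each = 2),
    process = factor(rep(c("drift", "variable_selection"), 2),
                     levels = c("drift", "variable_selection")),
    n = c(30L, 70L, 70L, 30L),
    fraction = c(0.3, 0.7, 0.7, 0.3)),
    n_missing = tibble::tibble(group = c("g1", "g2"), n_missing = c(0L, 0L)),
    bnti_threshold = 2, rc_threshold = 0.95, grouped_by = "group"),
    class = "process_partition")
  res <- process_chisq(part)
  expect_equal(res$statistic[res$contrast == "overall"], 32)
  expect_equal(res$statistic[res$contrast == "drift"], 32)

  # identical distributions: statistic 0, p = 1
  part$summary$n <- c(30L, 70L, 30L, 70L)
  res0 <- process_chisq(part)
  expect_equal(res0$statistic[1], 0)
  expect_equal(res0$p_value[1], 1)
})

test_that("odds ratios, CIs and the zero-cell correction are exact", {
  mk_pairs <- function(a, b, c_, d) {
    tibble::tibble(
      body_site = "gut",
      bnti = c(rep(3, a), rep(0, b), rep(3, c_), rep(0, d)),
      state_i = c(rep("X", a + b), rep("Y", c_ + d)),
      state_j = c(rep("Z", a + b), rep("Y", c_ + d)))
  }
  tt <- mk_pairs(20, 30, 10, 50)
  or <- deterministic_odds_ratio(tt, "gut")
  x <- or[or$state == "X", ]
  expect_equal(x$odds_ratio, (20 * 50) / (30 * 10))
  se <- sqrt(1 / 20 + 1 / 30 + 1 / 10 + 1 / 50)
  expect_equal(x$ci_lower, exp(log(x$odds_ratio) - 1.96 * se))
  expect_true(x$significant)

  tz <- mk_pairs(5, 0, 10, 50)
  orz <- deterministic_odds_ratio(tz, "gut")
  xz <- orz[orz$state == "X", ]
  expect_true(xz$corrected)
  expect_true(is.finite(xz$odds_ratio))
})

test_that("odds-ratio CIs cover 1 when state and determinism are independent", {
  set.seed(46)
  cover <- vapply(1:200, function(i) {
    tt <- tibble::tibble(
      body_site = "gut",
      bnti = sample(c(3, 0), 120, replace = TRUE, prob = c(0.3, 0.7)),
      state_i = sample(c("X", "Y"), 120, replace = TRUE),
      state_j = sample(c("X", "Y"), 120, replace = TRUE))
    or <- deterministic_odds_ratio(tt, "gut")
    x <- or[or$state == "X", ]
    x$ci_lower <= 1 && x$ci_upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
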