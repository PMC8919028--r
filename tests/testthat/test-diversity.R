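# Alpha/beta diversity, ordination, association statistics, contrasts.

test_that("alpha diversity matches closed forms", {
  m <- rbind(u = c(5, 5, 5, 5), s = c(10, 0, 0, 0), p = c(10, 5, 5, 0))
  colnames(m) <- paste0("a", 1:4)
  suppressWarnings(alpha <- alpha_diversity(count_tbl(m)))
  expect_equal(alpha$richness, c(4L, 1L, 3L))
  expect_equal(alpha$shannon[1], log(4))
  expect_equal(alpha$evenness[1], 1)
  expect_equal(alpha$shannon[2], 0)
  expect_true(is.na(alpha$evenness[2]))
  # p = (0.5, 0.25, 0.25)
  expect_equal(alpha$shannon[3], -sum(c(.5, .25, .25) * log(c(.5, .25, .25))),
               tolerance = 1e-10)
  # invariant to ASV order
  suppressWarnings(alpha2 <- alpha_diversity(count_tbl(m[, c(3, 1, 4, 2)])))
  expect_equal(alpha2$shannon, alpha$shannon)
})

test_that("Bray-Curtis matches its closed form and bounds", {
  m <- rbind(x = c(6, 2), y = c(2, 2), z = c(6, 2))
  colnames(m) <- c("a", "b")
  d <- as.matrix(bray_curtis(count_tbl(m)))
  expect_equal(d["x", "y"], 1 / 3)
  expect_equal(d["x", "z"], 0)
  disj <- rbind(x = c(5, 0), y = c(0, 7))
  colnames(disj) <- c("a", "b")
  expect_equal(as.matrix(bray_curtis(count_tbl(disj)))["x", "y"], 1)
  expect_error(bray_curtis(count_tbl(rbind(x = c(a = 0, b = 0),
                                           y = c(a = 1, b = 1)))),
               "all-zero")
})

test_that("PCoA recovers geometry from distances", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(1, 3, 3) - diag(3))
  attr(d3, "Labels") <- paste0("s", 1:3)
  ord <- pcoa_ord(d3)
  pos <- ord$eigenvalues[seq_len(ord$n_positive)]
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # collinear points: one dominating positive axis
  x <- c(0, 1, 2, 5)
  dl <- stats::dist(x)
  attr(dl, "Labels") <- paste0("s", 1:4)
  ordl <- pcoa_ord(dl)
  expect_equal(ordl$prop_explained[1], 1, tolerance = 1e-10)

  # Euclidean-embeddable distances are reproduced on the positive axes
  set.seed(3)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  de <- stats::dist(pts)
  attr(de, "Labels") <- paste0("s", 1:20)
  orde <- pcoa_ord(de)
  coords <- as.matrix(orde$scores[, -1])
  expect_lt(max(abs(stats::dist(coords) - de)), 1e-6)

  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA agrees with an independent implementation", {
  set.seed(7)
  m <- matrix(rpois(24 * 15, 4) + 1, 24, 15,
              dimnames = list(paste0("s", 1:24), paste0("a", 1:15)))
  grp <- rep(c("g1", "g2", "g3"), each = 8)
  d <- bray_curtis(count_tbl(m))
  ours <- permanova(d, grp, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(d ~ grp, permutations = 199)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA detects complete separation at the minimum p", {
  m <- rbind(matrix(c(10L, 0L), 10, 2, byrow = TRUE),
             matrix(c(0L, 10L), 10, 2, byrow = TRUE))
  m <- m + matrix(rep(0:9, 4), 20, 2)   # distinct samples, still disjoint
  dimnames(m) <- list(paste0("s", 1:20), c("a", "b"))
  m[1:10, 2] <- 0L
  m[11:20, 1] <- 0L
  d <- bray_curtis(count_tbl(m))
  res <- permanova(d, rep(c("x", "y"), each = 10), n_perm = 999, seed = 4)
  expect_equal(res$p_value, 1 / 1000)
  r1 <- permanova(d, rep(c("x", "y"), each = 10), n_perm = 99, seed = 1)
  r2 <- permanova(d, rep(c("x", "y"), each = 10), n_perm = 99, seed = 1)
  expect_identical(r1$pseudo_f, r2$pseudo_f)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("block-restricted permutations never move labels across blocks", {
  # groups nested in blocks: within-block shuffles cannot change the
  # statistic, so every permutation equals the observed F and p = 1
  set.seed(9)
  m <- matrix(rpois(12 * 8, 4) + 1, 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("a", 1:8)))
  d <- bray_curtis(count_tbl(m))
  blocks <- rep(1:4, each = 3)
  groups <- c("x", "x", "x", "x", "x", "x", "y", "y", "y", "y", "y", "y")
  res <- permanova(d, groups, blocks = blocks, n_perm = 200, seed = 2)
  expect_equal(res$p_value, 1)
})

test_that("envfit r-squared matches vegan for vectors and factors", {
  set.seed(11)
  m <- matrix(rpois(30 * 12, 5) + 1, 30, 12,
              dimnames = list(paste0("s", 1:30), paste0("a", 1:12)))
  d <- bray_curtis(count_tbl(m))
  ord <- pcoa_ord(d)
  X <- as.matrix(ord$scores[, 2:3])
  v <- rnorm(30)
  expect_equal(envfit_ord(ord, v, n_perm = 99, seed = 1)$r_squared,
               vegan::envfit(X, data.frame(v = v),
                             permutations = 99)$vectors$r[[1]],
               tolerance = 1e-10)
  f <- factor(rep(c("p", "q", "r"), 10))
  expect_equal(envfit_ord(ord, f, n_perm = 99, seed = 1)$r_squared,
               vegan::envfit(X, data.frame(f = f),
                             permutations = 99)$factors$r[[1]],
               tolerance = 1e-10)
  # a variable identical to axis 1 has r-squared 1
  ax1 <- ord$scores$Axis1
  expect_equal(envfit_ord(ord, ax1, n_perm = 99, seed = 2)$r_squared, 1,
               tolerance = 1e-10)
  expect_error(envfit_ord(ord, rep(1, 30), n_perm = 99, seed = 1), "constant")
})

test_that("envfit separates planted clusters with minimum p", {
  co <- preprocessed_cohort(1)
  d <- bray_curtis(co$table)
  ord <- pcoa_ord(d)
  truth <- co$cohort$truth$state
  states <- truth$state[match(ord$scores$sample_id, truth$sample_id)]
  res <- envfit_ord(ord, factor(states), n_perm = 999, seed = 3)
  expect_gt(res$r_squared, 0.8)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("Cohen's d matches hand computations", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x + sd(x), x), 1)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("dissimilarity contrasts partition within-patient pairs", {
  co <- preprocessed_cohort(1)
  d <- bray_curtis(co$table)
  res <- dissimilarity_contrasts(d, co$meta)
  one <- dplyr::filter(res$contrasts, patient_id == "P01")
  n_samples <- sum(co$meta$patient_id == "P01" &
                     co$meta$sample_id %in% labels(d))
  if (n_samples == 12) {
    expect_equal(nrow(one), choose(12, 2))
    expect_equal(sum(one$class == "within_site"), 3 * choose(4, 2))
    expect_equal(sum(one$class == "between_site"), choose(12, 2) - 18)
  }
  # the founder's distance to itself is zero
  firsts <- dplyr::filter(res$founder, time_index == 1)
  expect_true(all(firsts$founder_distance == 0))
})
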