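# Shared fixtures, built in code. Expensive objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# small count table with explicit taxonomy
toy_table <- function() {
  m <- matrix(c(6, 2, 0, 5,
                2, 2, 0, 3,
                0, 0, 7, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("ASV_1", "ASV_2", "ASV_3", "ASV_4")))
  tax <- tibble::tibble(
    asv_id = colnames(m),
    taxonomy = paste0("d__Bacteria;p__;c__;o__;f__;g__",
                      c("Escherichia/Shigella", "Lactobacillus",
                        "Staphylococcus", "Enterococcus"), ";s__"))
  count_tbl(m, tax)
}

# default synthetic cohort, preprocessed once for reuse across tests
small_cohort <- function(seed = 1) {
  cached(paste0("cohort_", seed), generate_cohort(synth_config(seed = seed)))
}

preprocessed_cohort <- function(seed = 1) {
  cached(paste0("prep_", seed), {
    co <- small_cohort(seed)
    filt <- filter_contaminants(co$counts,
                                neg_controls = co$truth$negative_controls)
    rare <- rarefy(filt$table, 600, seed = seed + 500)
    list(cohort = co, table = rare, meta = co$metadata,
         report = filt$report)
  })
}

# independent pure-R betaMNTD oracle: exhaustive double loop
oracle_bmntd <- function(x, y, D) {
  fx <- x / sum(x)
  fy <- y / sum(y)
  ix <- which(x > 0)
  iy <- which(y > 0)
  s1 <- sum(vapply(ix, function(i) fx[i] * min(D[i, iy]), double(1)))
  s2 <- sum(vapply(iy, function(j) fy[j] * min(D[ix, j]), double(1)))
  (s1 + s2) / 2
}

# brute-force recurrence oracle: state i is recurrent iff every state
# reachable from i can reach i back
oracle_recurrent <- function(P) {
  k <- nrow(P)
  reach <- (P > 0) | diag(k) > 0
  for (m in seq_len(k)) reach <- reach | (reach %*% reach) > 0
  vapply(seq_len(k), function(i) {
    js <- which(reach[i, ])
    all(reach[js, i])
  }, logical(1))
}

random_stochastic <- function(k, sparse = FALSE) {
  P <- matrix(rgamma(k * k, 1), k, k)
  if (sparse) P[matrix(runif(k * k) < 0.5, k, k)] <- 0
  bad <- rowSums(P) == 0
  P[bad, ] <- 1
  P / rowSums(P)
}

# one symmetric-ish Dirichlet draw for building neutral metacommunities
rdirichlet_test <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# Neutral fixture for Raup-Crick self-consistency: iterate the null's own
# reassembly process on a base table until its occupancy/abundance stats are
# (approximately) a fixed point, then draw fresh test communities from those
# stats. RC on test-sample pairs is then computed against nulls drawn from
# near-identical stats.
neutral_null_cohort <- function(seed, n_species = 300, n_base = 150,
                                n_test = 25, n_iter = 8) {
  set.seed(seed)
  g <- rgamma(n_species, 0.15)
  p <- g / sum(g)
  m <- t(vapply(seq_len(n_base), function(i) rmultinom(1, 600, p)[, 1],
                integer(n_species)))
  reassemble_from <- function(occ, ab) {
    function(rich, total) {
      sp <- sample(n_species, rich, prob = occ)
      w <- ab[sp] / sum(ab[sp])
      v <- integer(n_species)
      v[sp] <- 1L + rmultinom(1, total - rich, w)[, 1]
      v
    }
  }
  for (it in seq_len(n_iter)) {
    f <- reassemble_from(colSums(m > 0), colSums(m))
    m <- t(vapply(seq_len(n_base), function(i) f(sum(m[i, ] > 0), 600),
                  integer(n_species)))
  }
  f <- reassemble_from(colSums(m > 0), colSums(m))
  test <- t(vapply(seq_len(n_test), function(i) f(sample(60:120, 1), 600),
                   integer(n_species)))
  mm <- rbind(m, test)
  dimnames(mm) <- list(paste0("s", seq_len(n_base + n_test)),
                       paste0("a", seq_len(n_species)))
  list(table = count_tbl(mm),
       test_ids = paste0("s", n_base + seq_len(n_test)))
}
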