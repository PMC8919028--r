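# Alpha/beta diversity, ordination, and permutation association statistics.

#' Alpha diversity per sample
#'
#' Richness S (observed ASVs), Shannon H (natural log by default) and Pielou
#' evenness J = H / log(S); J is reported as `NA` when S = 1.
#'
#' @param table a [count_tbl()]; rarefy first for comparability (a warning is
#'   emitted when sample depths are unequal).
#' @param base logarithm base for H (default `exp(1)`, i.e. nats).
#' @return Tibble with `sample_id`, `richness`, `shannon`, `evenness`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- count_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) abort(paste0("empty sample: ",
                                     rownames(m)[totals == 0][1]))
  if (length(unique(totals)) > 1) {
    warn("unequal sample depths; consider rarefying before alpha diversity")
  }
  S <- unname(rowSums(m > 0))
  H <- as.numeric(vegan::diversity(m, index = "shannon", base = base))
  tibble(sample_id = rownames(m), richness = as.integer(S),
         shannon = H,
         evenness = ifelse(S > 1, H / (log(S) / log(base)), NA_real_))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum(x) + sum(y))`.
#'
#' @param table a [count_tbl()] with at least two samples.
#' @return A `dist` object labeled by sample ids.
#' @export
bray_curtis <- function(table) {
  m <- count_matrix(table)
  if (nrow(m) < 2) abort("need at least two samples")
  if (any(rowSums(m) == 0)) {
    abort(paste0("all-zero sample: ", rownames(m)[rowSums(m) == 0][1]))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition of a dissimilarity matrix;
#' coordinates are returned for positive-eigenvalue axes only, ordered by
#' decreasing eigenvalue, with proportions of (positive) eigenvalue sum
#' explained.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @return A `pcoa_ord` object: `scores` tibble (`sample_id`, `Axis1`, ...),
#'   `eigenvalues` (all, decreasing), `prop_explained` (positive axes).
#' @export
pcoa_ord <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # negative eigenvalues are expected for non-Euclidean dissimilarities
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-9)
  coords <- fit$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(
    scores = as_tibble(coords, rownames = "sample_id"),
    eigenvalues = eig,
    prop_explained = eig[pos] / sum(eig[pos]),
    n_positive = length(pos)
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("PCoA: ", nrow(x$scores), " samples, ", x$n_positive,
      " positive axes\n", sep = "")
  cat("  first axes explain: ",
      paste(sprintf("%.1f%%", 100 * head(x$prop_explained, 3)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Gower-centered inner-product matrix from squared dissimilarities
gower_center <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D2 %*% J
}

# permutation indices restricted to blocks (labels never cross blocks)
restricted_perm <- function(n, blocks = NULL) {
  if (is.null(blocks)) return(sample.int(n))
  idx <- seq_len(n)
  for (b in unique(blocks)) {
    members <- which(blocks == b)
    idx[members] <- members[sample.int(length(members))]
  }
  idx
}

#' Single-factor PERMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squares of a dissimilarity matrix between and
#' within groups (Gower-centered), reporting pseudo-F, r-squared =
#' SS_between / SS_total, and a permutation p-value with the +1 rule
#' `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`. When `blocks` is given,
#' group labels are shuffled within blocks only (e.g. permutations
#' constrained to each patient's samples).
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param groups factor of group labels (aligned to samples of `d`).
#' @param blocks optional blocking factor restricting permutations.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return A `comm_assoc` object with `statistic` ("PERMANOVA"), `r_squared`,
#'   `pseudo_f`, `p_value`, `n_perm`, `df`.
#' @export
permanova <- function(d, groups, blocks = NULL, n_perm = 1000, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) abort("`groups` length must match samples")
  if (nlevels(droplevels(groups)) < 2) abort("need at least two groups")
  if (any(table(groups) < 2)) abort("each group needs >= 2 samples")
  if (!is.null(blocks) && length(blocks) != n) {
    abort("`blocks` length must match samples")
  }
  W <- dm^2
  a <- nlevels(droplevels(groups))
  ss_total <- sum(W) / (2 * n)
  ss_within_f <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      if (length(i)) s <- s + sum(W[i, i]) / (2 * length(i))
    }
    s
  }
  f_stat <- function(g) {
    ssw <- ss_within_f(g)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  r2 <- (ss_total - ss_within_f(groups)) / ss_total
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_stat(groups[restricted_perm(n, blocks)])
    }, double(1)) >= f_obs)
  })
  new_comm_assoc("PERMANOVA", r2, (1 + exceed) / (n_perm + 1), n_perm,
                 pseudo_f = f_obs, df = c(a - 1, n - a),
                 blocks = !is.null(blocks))
}

#' Fit a variable onto ordination axes (envfit-style)
#'
#' Continuous variables: r-squared is the squared multiple correlation of the
#' variable with the retained ordination axes. Factors: r-squared is
#' `1 - SS_within / SS_total` of the coordinates by level. Significance by
#' (optionally block-restricted) permutation of the variable with the +1
#' rule.
#'
#' @param ord a [pcoa_ord()] (or matrix of coordinates).
#' @param variable continuous vector or factor, aligned to samples.
#' @param blocks optional blocking factor restricting permutations.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param axes how many leading axes to use (default 2).
#' @return A `comm_assoc` object with `statistic` ("envfit").
#' @export
envfit_ord <- function(ord, variable, blocks = NULL, n_perm = 1000,
                       seed = 1L, axes = 2) {
  X <- if (inherits(ord, "pcoa_ord")) {
    as.matrix(ord$scores[, -1, drop = FALSE])
  } else {
    as.matrix(ord)
  }
  X <- X[, seq_len(min(axes, ncol(X))), drop = FALSE]
  n <- nrow(X)
  if (length(variable) != n) abort("`variable` length must match samples")
  if (is.character(variable)) variable <- factor(variable)
  r2_of <- if (is.factor(variable)) {
    if (nlevels(droplevels(variable)) < 2) abort("constant variable")
    function(v) {
      tot <- sum(scale(X, scale = FALSE)^2)
      within <- 0
      for (lev in levels(v)) {
        i <- which(v == lev)
        if (length(i)) within <- within + sum(scale(X[i, , drop = FALSE],
                                                    scale = FALSE)^2)
      }
      1 - within / tot
    }
  } else {
    if (var(variable) == 0) abort("constant variable")
    # squared multiple correlation via an orthonormal basis of the centered
    # axes (equivalent to lm(v ~ X)$r.squared, cheap inside the loop)
    Qc <- qr.Q(qr(scale(X, scale = FALSE)))
    function(v) {
      vc <- v - mean(v)
      sum(crossprod(Qc, vc)^2) / sum(vc^2)
    }
  }
  r2_obs <- r2_of(variable)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      r2_of(variable[restricted_perm(n, blocks)])
    }, double(1)) >= r2_obs)
  })
  new_comm_assoc("envfit", r2_obs, (1 + exceed) / (n_perm + 1), n_perm,
                 blocks = !is.null(blocks))
}

new_comm_assoc <- function(statistic, r2, p, n_perm, pseudo_f = NA_real_,
                           df = NULL, blocks = FALSE) {
  structure(list(statistic = statistic, r_squared = r2, pseudo_f = pseudo_f,
                 p_value = p, n_perm = n_perm, df = df, blocked = blocks),
            class = "comm_assoc")
}

#' @export
print.comm_assoc <- function(x, ...) {
  cat(x$statistic, ": r2 = ", signif(x$r_squared, 3), sep = "")
  if (is.finite(x$pseudo_f)) cat(", pseudo-F = ", signif(x$pseudo_f, 4), sep = "")
  cat(", p = ", signif(x$p_value, 3), " (", x$n_perm, " ",
      if (x$blocked) "block-restricted " else "", "permutations)\n", sep = "")
  invisible(x)
}

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y)) / s_pooled`, with the pooled standard deviation
#' weighted by n - 1.
#'
#' @param x,y numeric vectors with >= 2 values each.
#' @return A single number.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 values per group")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) abort("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Within- vs between-site dissimilarity contrasts and founder distances
#'
#' For every patient, each unordered within-patient sample pair is assigned
#' to exactly one contrast class (`within_site` or `between_site`). The
#' founder series tracks, per patient and site, the dissimilarity of every
#' sample to that patient-site's first occasion.
#'
#' @param d a `dist` of sample dissimilarities.
#' @param meta sample metadata.
#' @return List of two tibbles: `contrasts` (`patient_id`, `class`,
#'   `sample_i`, `sample_j`, `value`) and `founder` (`patient_id`,
#'   `body_site`, `time_index`, `day_of_life`, `founder_distance`). Patients
#'   with a single sample are excluded with a message.
#' @export
dissimilarity_contrasts <- function(d, meta) {
  dm <- as.matrix(d)
  meta <- filter(meta, .data$sample_id %in% rownames(dm))
  singles <- meta %>% count(.data$patient_id) %>% filter(n < 2)
  if (nrow(singles)) {
    inform(paste0("excluding patient(s) with a single sample: ",
                  paste(singles$patient_id, collapse = ", ")))
    meta <- filter(meta, !.data$patient_id %in% singles$patient_id)
  }
  contrasts <- meta %>%
    split(.$patient_id) %>%
    map(function(md) {
      if (nrow(md) < 2) return(NULL)
      pr <- combn(seq_len(nrow(md)), 2)
      tibble(
        patient_id = md$patient_id[1],
        sample_i = md$sample_id[pr[1, ]],
        sample_j = md$sample_id[pr[2, ]],
        class = ifelse(md$body_site[pr[1, ]] == md$body_site[pr[2, ]],
                       "within_site", "between_site"),
        value = dm[cbind(md$sample_id[pr[1, ]], md$sample_id[pr[2, ]])]
      )
    }) %>%
    bind_rows()

  founder <- meta %>%
    group_by(.data$patient_id, .data$body_site) %>%
    filter(dplyr::n() >= 1) %>%
    group_modify(function(md, key) {
      ref <- md$sample_id[which.min(md$time_index)]
      tibble(time_index = md$time_index,
             day_of_life = if ("day_of_life" %in% names(md)) md$day_of_life
                           else md$time_index,
             founder_distance = dm[ref, md$sample_id])
    }) %>%
    ungroup()

  list(contrasts = contrasts, founder = founder)
}
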