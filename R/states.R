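# Discrete community-state discovery: cluster-number selection, clustering on
# Bray-Curtis profiles, dominant-ASV naming, and body-site representation.

# k-means cannot consume a dissimilarity matrix directly, so clustering runs
# in full PCoA space (all positive-eigenvalue axes); PAM on the dissimilarity
# matrix itself is offered as an alternative. Silhouettes are always computed
# on the original dissimilarities; Calinski-Harabasz needs coordinates and is
# computed on the embedding.

# PCoA coordinates as a matrix with sample-id rownames
ord_coords <- function(d) {
  ord <- pcoa_ord(d)
  X <- as.matrix(ord$scores[, -1, drop = FALSE])
  rownames(X) <- ord$scores$sample_id
  X
}

cluster_labels <- function(d, k, seed, n_init, method) {
  if (method == "pam") {
    fit <- with_seed(seed, cluster::pam(d, k = k, diss = TRUE))
    return(fit$clustering)
  }
  X <- ord_coords(d)
  fit <- with_seed(seed, kmeans(X, centers = k, nstart = n_init,
                                iter.max = 100))
  setNames(fit$cluster, rownames(X))
}

calinski_harabasz <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  overall <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (lev in unique(labels)) {
    i <- which(labels == lev)
    cent <- colMeans(X[i, , drop = FALSE])
    ssb <- ssb + length(i) * sum((cent - overall)^2)
    ssw <- ssw + sum(sweep(X[i, , drop = FALSE], 2, cent)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Choose the number of community states
#'
#' Runs clustering for each candidate `k`, scoring mean silhouette on the
#' dissimilarity matrix and Calinski-Harabasz on the PCoA embedding. The
#' chosen `k` maximizes mean silhouette, with CH breaking ties.
#'
#' @param d a `dist` of Bray-Curtis dissimilarities.
#' @param k_range candidate cluster counts (default 2:8), within `[2, n-1]`.
#' @param seed integer seed.
#' @param n_init k-means restarts per k (default 100).
#' @param method `"kmeans"` (on PCoA coordinates) or `"pam"` (on `d`).
#' @return List with `k` (chosen) and `scores` (tibble per candidate k).
#' @export
select_k <- function(d, k_range = 2:8, seed = 1L, n_init = 100,
                     method = c("kmeans", "pam")) {
  method <- match.arg(method)
  n <- attr(stats::as.dist(d), "Size")
  if (n < 3) abort("need at least 3 samples to select k")
  if (max(as.matrix(d)) == 0) abort("all dissimilarities are zero; clustering degenerate")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) abort("`k_range` must intersect [2, n - 1]")
  X <- ord_coords(d)
  dm <- as.matrix(d)
  scores <- map(k_range, function(k) {
    labels <- cluster_labels(d, k, seed, n_init, method)
    sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = dm)
    tibble(k = k,
           mean_silhouette = mean(sil[, "sil_width"]),
           calinski_harabasz = calinski_harabasz(X, labels))
  }) %>% bind_rows()
  best <- scores %>%
    arrange(dplyr::desc(.data$mean_silhouette),
            dplyr::desc(.data$calinski_harabasz)) %>%
    slice(1)
  list(k = best$k, scores = scores)
}

#' Assign samples to community states
#'
#' Clusters samples (k-means on PCoA coordinates, best of `n_init` restarts,
#' or PAM on the dissimilarities), computes per-sample silhouettes on the
#' original dissimilarity matrix, and names each cluster after its most
#' abundant ASV: clusters whose top ASV has an in-cluster mean relative
#' abundance of at least `dominance` are named `<initial of genus>C`
#' (e.g. SC for a *Staphylococcus*-dominated cluster); less dominated
#' clusters get the mixed-community label `IC` (suffixed with a counter on
#' collision).
#'
#' @param d a `dist` of Bray-Curtis dissimilarities.
#' @param table the [count_tbl()] behind `d` (for naming by composition).
#' @param k number of states.
#' @param seed integer seed.
#' @param n_init k-means restarts (default 100).
#' @param method `"kmeans"` or `"pam"`.
#' @param dominance dominance threshold for mono-dominated naming
#'   (default 0.4).
#' @return A `state_assignment`: `assignments` tibble (`sample_id`,
#'   `cluster`, `state`, `silhouette`), `k`, `mean_silhouette`,
#'   `calinski_harabasz`, `state_info` (per-state dominant ASV, genus, mean
#'   relative abundance, size).
#' @export
assign_states <- function(d, table, k, seed = 1L, n_init = 100,
                          method = c("kmeans", "pam"), dominance = 0.4) {
  method <- match.arg(method)
  if (k < 2) abort("`k` must be >= 2")
  labels <- cluster_labels(d, k, seed, n_init, method)
  dm <- as.matrix(d)
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = dm)
  X <- ord_coords(d)

  m <- count_matrix(table)[names(labels), , drop = FALSE]
  rel <- m / pmax(rowSums(m), 1)
  tax <- taxonomy_tbl(table)
  genus_of <- setNames(tax$genus, tax$asv_id)

  info <- map(sort(unique(labels)), function(cl) {
    i <- which(labels == cl)
    mean_rel <- colMeans(rel[i, , drop = FALSE])
    top <- names(which.max(mean_rel))
    tibble(cluster = cl, n = length(i), dominant_asv = top,
           dominant_genus = unname(genus_of[top]),
           dominant_mean = unname(mean_rel[top]))
  }) %>% bind_rows()

  # deterministic naming: dominance >= threshold -> genus initial + "C",
  # otherwise the mixed label "IC"; collisions numbered in cluster order
  raw_names <- ifelse(
    info$dominant_mean >= dominance & info$dominant_genus != "g__unclassified",
    paste0(toupper(substr(info$dominant_genus, 1, 1)), "C"), "IC")
  info$state <- make.unique(raw_names, sep = "")

  state_of <- setNames(info$state, info$cluster)
  assignments <- tibble(
    sample_id = names(labels),
    cluster = as.integer(labels),
    state = unname(state_of[as.character(labels)]),
    silhouette = sil[, "sil_width"]
  )
  structure(list(
    assignments = assignments, k = k,
    mean_silhouette = mean(assignments$silhouette),
    calinski_harabasz = calinski_harabasz(X, labels),
    state_info = select(info, "state", "cluster", "n", "dominant_asv",
                        "dominant_genus", "dominant_mean"),
    method = method, dominance = dominance
  ), class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("Community-state assignment: k = ", x$k, " (", x$method, ")\n", sep = "")
  cat(sprintf("  mean silhouette = %.3f, Calinski-Harabasz = %.1f\n",
              x$mean_silhouette, x$calinski_harabasz))
  print(x$state_info)
  invisible(x)
}

#' Body-site representation of each community state
#'
#' For every state, the percentage of its samples observed at each body
#' site (rows sum to 100), and the deviation from a uniform distribution
#' across sites (100 / number of sites).
#'
#' @param assignment a [state_assignment][assign_states()] or tibble with
#'   `sample_id`, `state`.
#' @param meta sample metadata with `body_site`.
#' @return Tibble with `state`, `body_site`, `n`, `percent`, `deviation`.
#' @export
site_representation <- function(assignment, meta) {
  labels <- assignment_tbl(assignment)
  dat <- inner_join(labels, meta, by = "sample_id")
  sites <- sort(unique(dat$body_site))
  uniform <- 100 / length(sites)
  out <- dat %>%
    count(.data$state, .data$body_site) %>%
    tidyr::complete(state = unique(dat$state), body_site = sites,
                    fill = list(n = 0L)) %>%
    group_by(.data$state) %>%
    mutate(percent = 100 * .data$n / sum(.data$n),
           deviation = .data$percent - uniform) %>%
    ungroup()
  stopifnot(all(abs(tapply(out$percent, out$state, sum) - 100) < 1e-9))
  out
}

#' Best-match label agreement between two partitions
#'
#' Fraction of samples on which two labelings agree after optimally
#' relabeling one of them (maximum over label bijections, exact for up to 8
#' labels, greedy beyond).
#'
#' @param labels,truth equal-length label vectors.
#' @return Agreement in \[0, 1\].
#' @export
label_agreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  tab <- table(labels, truth)
  k1 <- nrow(tab)
  k2 <- ncol(tab)
  if (k1 <= 8 && k1 <= k2) {
    perms <- all_permutations(k2, k1)
    best <- 0
    for (p in perms) {
      s <- sum(tab[cbind(seq_len(k1), p)])
      if (s > best) best <- s
    }
    return(best / length(labels))
  }
  # greedy fallback for many labels
  total <- 0
  tab_w <- tab
  for (i in seq_len(min(k1, k2))) {
    j <- which(tab_w == max(tab_w), arr.ind = TRUE)[1, ]
    total <- total + tab_w[j[1], j[2]]
    tab_w[j[1], ] <- -1
    tab_w[, j[2]] <- -1
  }
  total / length(labels)
}

# all injective maps 1..k1 -> 1..k2 as a list of index vectors
all_permutations <- function(k2, k1) {
  if (k1 == 0) return(list(integer()))
  out <- list()
  rec <- function(chosen) {
    if (length(chosen) == k1) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    for (j in setdiff(seq_len(k2), chosen)) rec(c(chosen, j))
  }
  rec(integer())
  out
}
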