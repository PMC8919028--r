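# Permutation-null Spearman co-occurrence networks per community state.

#' Build a permutation-null co-occurrence network
#'
#' Spearman correlations (average ranks on ties) between all pairs of ASVs
#' present in at least `min_prevalence` of the group's samples. The null
#' distribution shuffles every ASV's abundance vector across samples
#' independently (breaking all pairwise dependence, preserving marginals)
#' and recomputes all correlations `n_perm` times; per-pair
#' `p = (1 + #(|rho_null| >= |rho_obs|)) / (n_perm + 1)`, then
#' Benjamini-Hochberg correction over all tested pairs. Edges are kept where
#' the chosen filter (`q` by default, `p` optionally) is below `alpha`.
#' Constant ASVs have undefined correlations; their pairs are skipped and
#' counted.
#'
#' @param table a [count_tbl()].
#' @param samples optional character vector restricting to a sample group
#'   (e.g. all samples of one community state).
#' @param min_prevalence minimum samples an ASV must appear in (default 2).
#' @param n_perm null shuffles (default 1000).
#' @param alpha retention threshold (default 0.01).
#' @param seed integer seed.
#' @param filter_on `"q"` (BH-adjusted, default) or `"p"` (raw).
#' @param group label stored with the network (e.g. the community state).
#' @return A `cooccurrence_network`: `nodes` tibble (`asv_id`,
#'   `mean_abundance`, `prevalence`), `edges` tibble (`asv_a`, `asv_b`,
#'   `rho`, `p_value`, `q_value`, `sign`, `kept`), counts of skipped pairs,
#'   and the parameters used.
#' @export
build_network <- function(table, samples = NULL, min_prevalence = 2,
                          n_perm = 1000, alpha = 0.01, seed = 1L,
                          filter_on = c("q", "p"), group = NA_character_) {
  filter_on <- match.arg(filter_on)
  m <- count_matrix(table)
  if (!is.null(samples)) m <- m[intersect(rownames(m), samples), , drop = FALSE]
  n <- nrow(m)
  if (n < 4) abort("fewer than 4 samples; rank correlation is meaningless")
  prevalence <- colSums(m > 0)
  keep <- prevalence >= min_prevalence
  m <- m[, keep, drop = FALSE]
  n_asv <- ncol(m)
  if (n_asv < 2) abort("fewer than 2 ASVs pass the prevalence filter")

  nodes <- tibble(asv_id = colnames(m),
                  mean_abundance = colMeans(m / pmax(rowSums(m), 1)),
                  prevalence = as.integer(prevalence[keep]))

  # centered/scaled column ranks make rho a crossprod; constant columns -> NA
  R <- apply(m, 2, rank)
  R <- scale(R)
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  rho_of <- function(M) crossprod(M) / (n - 1)
  rho_obs <- rho_of(R)

  ut <- upper.tri(rho_obs)
  exceed <- matrix(0, n_asv, n_asv)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      Rp <- R
      for (j in seq_len(n_asv)) Rp[, j] <- R[sample.int(n), j]
      exceed <- exceed + (abs(rho_of(Rp)) >= abs(rho_obs) - 1e-12)
    }
  })
  p_mat <- (1 + exceed) / (n_perm + 1)

  pair_idx <- which(ut, arr.ind = TRUE)
  edges <- tibble(
    asv_a = colnames(m)[pair_idx[, 1]],
    asv_b = colnames(m)[pair_idx[, 2]],
    rho = rho_obs[ut],
    defined = !(constant[pair_idx[, 1]] | constant[pair_idx[, 2]]),
    p_value = p_mat[ut]
  )
  n_skipped <- sum(!edges$defined)
  if (n_skipped) {
    inform(paste0("skipping ", n_skipped,
                  " pair(s) with undefined correlation (constant ASV)"))
  }
  edges <- edges %>%
    filter(.data$defined) %>%
    select(-"defined") %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           sign = ifelse(.data$rho >= 0, "positive", "negative"),
           kept = if (filter_on == "q") .data$q_value < alpha
                  else .data$p_value < alpha)

  structure(list(nodes = nodes,
                 edges = edges,
                 group = group,
                 n_samples = n,
                 n_skipped_pairs = n_skipped,
                 params = list(min_prevalence = min_prevalence,
                               n_perm = n_perm, alpha = alpha,
                               filter_on = filter_on, seed = seed)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network", if (!is.na(x$group)) paste0(" [", x$group, "]"),
      ": ", nrow(x$nodes), " nodes, ",
      sum(x$edges$kept), " retained edges of ", nrow(x$edges),
      " tested pairs (", x$params$filter_on, " < ", x$params$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param network a [build_network()] result.
#' @param kept_only keep only retained edges (default `TRUE`).
#' @return An `igraph` graph with node/edge attributes.
#' @export
as_igraph <- function(network, kept_only = TRUE) {
  stopifnot(inherits(network, "cooccurrence_network"))
  e <- network$edges
  if (kept_only) e <- filter(e, .data$kept)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = network$nodes)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param network a [build_network()] result.
#' @param path_tsv edge-list TSV path (`NULL` to skip).
#' @param path_graphml GraphML path (`NULL` to skip).
#' @return The network, invisibly.
#' @export
write_network <- function(network, path_tsv = NULL, path_graphml = NULL) {
  if (!is.null(path_tsv)) {
    readr::write_tsv(network$edges, path_tsv, progress = FALSE)
  }
  if (!is.null(path_graphml)) {
    igraph::write_graph(as_igraph(network), path_graphml, format = "graphml")
  }
  invisible(network)
}
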