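# broom-style tidiers for the package's fitted objects.

#' @describeIn estimate_transitions Tidy edge list: one row per transition
#'   with `from`, `to`, `n_obs`, `prob`.
#' @param x a `transition_model`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.transition_model <- function(x, ...) {
  tibble(
    body_site = x$body_site,
    from = rep(x$states, times = length(x$states)),
    to = rep(x$states, each = length(x$states)),
    n_obs = as.vector(t(x$C)),
    prob = as.vector(t(x$P))
  )
}

#' @describeIn estimate_transitions One-row model summary: observed steps,
#'   mean self-transition, number of recurrent states, and the stationary
#'   frequency of each state (columns `pi_<state>`; `NA` when the chain has
#'   several closed classes and no unique stationary distribution).
#' @exportS3Method generics::glance
glance.transition_model <- function(x, ...) {
  out <- tibble(
    body_site = x$body_site,
    n_steps = x$n_steps,
    n_states = length(x$states),
    n_recurrent = sum(x$classification == "recurrent"),
    mean_self_transition = x$mean_self_transition
  )
  pi_ <- if (nrow(x$stationary) == 1) x$stationary[1, ] else
    rep(NA_real_, length(x$states))
  out[paste0("pi_", x$states)] <- as.list(pi_)
  out
}

#' @describeIn permanova Tidy one-row summary of a permutation association
#'   test (`statistic`, `r_squared`, `pseudo_f`, `p_value`, `n_perm`,
#'   `blocked`).
#' @param x a `comm_assoc`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.comm_assoc <- function(x, ...) {
  tibble(statistic = x$statistic, r_squared = x$r_squared,
         pseudo_f = x$pseudo_f, p_value = x$p_value, n_perm = x$n_perm,
         blocked = x$blocked)
}

#' @describeIn permanova Alias of `tidy()` for `comm_assoc` (the test is its
#'   own one-row summary).
#' @exportS3Method generics::glance
glance.comm_assoc <- function(x, ...) tidy(x, ...)

#' @describeIn assign_states Per-sample tibble: `sample_id`, `cluster`,
#'   `state`, `silhouette`.
#' @param x a `state_assignment`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.state_assignment <- function(x, ...) x$assignments

#' @describeIn assign_states One-row summary: `k`, `mean_silhouette`,
#'   `calinski_harabasz`, `method`.
#' @exportS3Method generics::glance
glance.state_assignment <- function(x, ...) {
  tibble(k = x$k, mean_silhouette = x$mean_silhouette,
         calinski_harabasz = x$calinski_harabasz, method = x$method)
}

#' @describeIn pcoa_ord Sample scores tibble (`sample_id`, `Axis1`, ...).
#' @param x a `pcoa_ord`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.pcoa_ord <- function(x, ...) x$scores

#' @describeIn pcoa_ord One row per axis: `axis`, `eigenvalue`,
#'   `prop_explained`.
#' @exportS3Method generics::glance
glance.pcoa_ord <- function(x, ...) {
  tibble(axis = seq_len(x$n_positive),
         eigenvalue = x$eigenvalues[seq_len(x$n_positive)],
         prop_explained = x$prop_explained)
}

#' @describeIn build_network Edge tibble with correlation, p/q values and
#'   retention flag.
#' @param x a `cooccurrence_network`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @describeIn build_network One-row summary: group, node/edge counts,
#'   retained edges.
#' @exportS3Method generics::glance
glance.cooccurrence_network <- function(x, ...) {
  tibble(group = x$group, n_samples = x$n_samples, n_nodes = nrow(x$nodes),
         n_pairs_tested = nrow(x$edges), n_edges_kept = sum(x$edges$kept),
         n_skipped = x$n_skipped_pairs)
}

#' @describeIn partition_processes Per-group process fractions, long format.
#' @param x a `process_partition`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.process_partition <- function(x, ...) x$summary

#' @describeIn partition_processes One row per group: total classified pairs
#'   and missing count.
#' @exportS3Method generics::glance
glance.process_partition <- function(x, ...) {
  x$summary %>%
    group_by(.data$group) %>%
    summarise(n_pairs = sum(.data$n), .groups = "drop") %>%
    left_join(x$n_missing, by = "group")
}

#' @describeIn conditional_detection Per-ASV ordered-site-pair tibble of
#'   conditional detection probabilities.
#' @param x a `conditional_detection`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.conditional_detection <- function(x, ...) x$per_asv

#' @describeIn conditional_detection Aggregate mean conditional probability
#'   per ordered site pair.
#' @exportS3Method generics::glance
glance.conditional_detection <- function(x, ...) x$aggregate
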