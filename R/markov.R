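# Community-state Markov models: per-site transition estimation, stationary
# frequencies, recurrent/transient classification, and cross-site conditional
# ASV detection probabilities.

#' Estimate a per-site community-state transition model
#'
#' Each patient's series at `site`, ordered by `time_index`, contributes one
#' observed step per consecutive pair of occasions; steps are pooled across
#' patients (the maximum-likelihood estimate of a shared site-level chain).
#' Rows of the count matrix with no observed departures are set to uniform
#' with a warning so stationary frequencies stay computable.
#'
#' @param assignment a [state_assignment][assign_states()] object or a tibble
#'   with `sample_id` and `state`.
#' @param meta sample metadata (`sample_id`, `patient_id`, `body_site`,
#'   `time_index`).
#' @param site body-site label to model.
#' @param smoothing pseudo-count added to every transition cell before row
#'   normalization (default 0).
#' @param states optional state-label universe (defaults to levels present in
#'   the assignment), so all sites share one state set.
#' @return A `transition_model`: transition counts `C`, row-stochastic `P`,
#'   stationary distribution(s) `stationary`, per-state
#'   `classification` (recurrent/transient), `mean_self_transition` (mean of
#'   `diag(P)` over observed-origin states), per-patient count matrices, and
#'   flags for zero-count rows.
#' @export
estimate_transitions <- function(assignment, meta, site, smoothing = 0,
                                 states = NULL) {
  labels <- assignment_tbl(assignment)
  states <- states %||% sort(unique(labels$state))
  k <- length(states)
  dat <- labels %>%
    inner_join(meta, by = "sample_id") %>%
    filter(.data$body_site == site) %>%
    arrange(.data$patient_id, .data$time_index)
  series <- split(dat, dat$patient_id)
  series <- lapply(series, function(d) d$state[order(d$time_index)])
  if (!any(lengths(series) >= 2)) {
    abort(paste0("site '", site, "' has no patient series of length >= 2"))
  }
  C <- matrix(0, k, k, dimnames = list(states, states))
  per_patient <- list()
  for (pid in names(series)) {
    s <- series[[pid]]
    Cp <- matrix(0, k, k, dimnames = list(states, states))
    if (length(s) >= 2) {
      from <- s[-length(s)]
      to <- s[-1]
      for (i in seq_along(from)) Cp[from[i], to[i]] <- Cp[from[i], to[i]] + 1
    }
    per_patient[[pid]] <- Cp
    C <- C + Cp
  }
  Cs <- C + smoothing
  totals <- rowSums(Cs)
  uniform_rows <- rownames(C)[totals == 0]
  if (length(uniform_rows)) {
    warn(paste0("site '", site, "': no observed departures from state(s) ",
                paste(uniform_rows, collapse = ", "),
                "; row(s) set to uniform"))
    Cs[totals == 0, ] <- 1
  }
  P <- Cs / rowSums(Cs)
  observed_origin <- rowSums(C) > 0
  model <- structure(list(
    body_site = site, states = states, C = C, P = P,
    stationary = stationary_distribution(P),
    classification = classify_states(P),
    mean_self_transition = mean(diag(P)[observed_origin]),
    observed_origin = observed_origin,
    uniform_rows = uniform_rows,
    per_patient = per_patient,
    smoothing = smoothing,
    n_steps = sum(C)
  ), class = "transition_model")
  model
}

# accept either a state_assignment object or a bare tibble
assignment_tbl <- function(assignment) {
  if (inherits(assignment, "state_assignment")) {
    tibble(sample_id = assignment$assignments$sample_id,
           state = assignment$assignments$state)
  } else {
    tbl <- as_tibble(assignment)
    stopifnot(all(c("sample_id", "state") %in% names(tbl)))
    mutate(tbl, state = as.character(.data$state))
  }
}

#' Stationary distributions of a finite Markov chain
#'
#' Returns the extremal stationary distributions, one per closed
#' communicating class: each solves `pi %*% P = pi`, sums to one, and is
#' supported on its class. An irreducible chain yields a single distribution.
#'
#' @param P row-stochastic matrix.
#' @return A matrix with one stationary distribution per row (named by the
#'   chain's states when `P` has dimnames).
#' @export
stationary_distribution <- function(P) {
  check_row_stochastic(P, tol = 1e-8)
  k <- nrow(P)
  cls <- classify_states(P)
  closed <- attr(cls, "closed_classes")
  out <- matrix(0, length(closed), k)
  colnames(out) <- rownames(P) %||% as.character(seq_len(k))
  for (i in seq_along(closed)) {
    idx <- closed[[i]]
    Psub <- P[idx, idx, drop = FALSE]
    # solve pi (P - I) = 0 with sum(pi) = 1 via least squares on the
    # augmented system t(A) x = b
    A <- rbind(t(Psub) - diag(length(idx)), rep(1, length(idx)))
    b <- c(rep(0, length(idx)), 1)
    pi_sub <- qr.solve(A, b)
    pi_sub[pi_sub < 0 & pi_sub > -1e-12] <- 0
    pi_sub <- pi_sub / sum(pi_sub)
    out[i, idx] <- pi_sub
  }
  resid <- out %*% P - out
  stopifnot(max(abs(resid)) < 1e-10)
  out
}

#' Classify chain states as recurrent or transient
#'
#' Builds the digraph of positive-probability transitions, finds strongly
#' connected components, and labels states in closed components (no edge
#' leaving the component) recurrent; all others transient.
#'
#' @param P row-stochastic matrix.
#' @return Named character vector (`"recurrent"`/`"transient"`) with the
#'   closed communicating classes attached as attribute `"closed_classes"`
#'   (list of state index vectors).
#' @export
classify_states <- function(P) {
  check_row_stochastic(P, tol = 1e-8)
  k <- nrow(P)
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  closed <- list()
  cls <- rep("transient", k)
  for (c_i in seq_len(comp$no)) {
    members <- which(comp$membership == c_i)
    leaves <- any(P[members, -members, drop = FALSE] > 0)
    if (length(members) == k) leaves <- FALSE
    if (!leaves) {
      cls[members] <- "recurrent"
      closed[[length(closed) + 1]] <- members
    }
  }
  names(cls) <- rownames(P) %||% as.character(seq_len(k))
  attr(cls, "closed_classes") <- closed
  cls
}

#' Cross-site conditional ASV detection probabilities
#'
#' For each ASV and ordered pair of body sites, estimates the probability of
#' detecting the ASV (count > 0) at site `s2` given its detection at site
#' `s1`, over sampling occasions matched on `(patient, time_index)`. Both the
#' direct estimate and the Bayes-formula route
#' `P(s1|s2) = P(s2|s1) P(s1) / P(s2)` are computed and asserted equal.
#' ASVs never detected at the conditioning site get `NA` (undefined), not 0.
#'
#' @param table a rarefied [count_tbl()].
#' @param meta sample metadata.
#' @return A `conditional_detection` object: `per_asv` tibble (`asv_id`,
#'   `site_from` = conditioning site s1, `site_to` = s2, `n_matched`, `n_s1`,
#'   `n_both`, `p_cond`, `p_s1`, `p_s2`), and `aggregate` (unweighted mean of
#'   defined `p_cond` per ordered site pair; abundance weighting available
#'   via `weights`).
#' @param weights `"equal"` (default; unweighted mean over ASVs detected at
#'   the conditioning site) or `"abundance"` (weighted by mean relative
#'   abundance).
#' @export
conditional_detection <- function(table, meta, weights = c("equal", "abundance")) {
  weights <- match.arg(weights)
  m <- count_matrix(table)
  det <- m > 0
  meta <- filter(meta, .data$sample_id %in% rownames(m))
  sites <- sort(unique(meta$body_site))
  key <- paste(meta$patient_id, meta$time_index)
  rel_mean <- colMeans(m / pmax(rowSums(m), 1))

  res <- list()
  for (s1 in sites) for (s2 in setdiff(sites, s1)) {
    m1 <- meta[meta$body_site == s1, ]
    m2 <- meta[meta$body_site == s2, ]
    k1 <- paste(m1$patient_id, m1$time_index)
    k2 <- paste(m2$patient_id, m2$time_index)
    shared <- intersect(k1, k2)
    if (!length(shared)) next
    id1 <- m1$sample_id[match(shared, k1)]
    id2 <- m2$sample_id[match(shared, k2)]
    d1 <- det[id1, , drop = FALSE]
    d2 <- det[id2, , drop = FALSE]
    n1 <- unname(colSums(d1))
    n2 <- unname(colSums(d2))
    nboth <- unname(colSums(d1 & d2))
    res[[paste(s1, s2)]] <- tibble(
      asv_id = colnames(m), site_from = s1, site_to = s2,
      n_matched = length(shared),
      n_s1 = as.integer(n1), n_both = as.integer(nboth),
      p_cond = ifelse(n1 > 0, nboth / n1, NA_real_),
      p_s1 = n1 / length(shared), p_s2 = n2 / length(shared)
    )
  }
  per_asv <- bind_rows(res)

  # Bayes identity check: P(s2|s1) P(s1) must equal P(s1|s2) P(s2)
  flip <- per_asv %>%
    select(asv_id = "asv_id", site_from = "site_to", site_to = "site_from",
           p_flip = "p_cond")
  both <- inner_join(per_asv, flip, by = c("asv_id", "site_from", "site_to")) %>%
    filter(!is.na(.data$p_cond) & !is.na(.data$p_flip))
  stopifnot(max(abs(both$p_cond * both$p_s1 - both$p_flip * both$p_s2), 0) < 1e-12)

  aggregate <- per_asv %>%
    filter(!is.na(.data$p_cond)) %>%
    mutate(w = if (weights == "equal") 1 else rel_mean[.data$asv_id]) %>%
    group_by(.data$site_from, .data$site_to) %>%
    summarise(n_asvs = dplyr::n(),
              mean_p_cond = sum(.data$p_cond * .data$w) / sum(.data$w),
              .groups = "drop")

  structure(list(per_asv = per_asv, aggregate = aggregate, weights = weights),
            class = "conditional_detection")
}

#' Edge-list summary of a transition model
#'
#' @param model a [transition_model][estimate_transitions()].
#' @return Tibble of positive-probability edges (`from`, `to`, `prob`,
#'   `n_obs`, `self`), with the model's mean self-transition (over
#'   observed-origin states) as attribute `"mean_self_transition"`.
#' @export
transition_graph_summary <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  P <- model$P
  edges <- as_tibble(as.table(P), .name_repair = "minimal")
  names(edges) <- c("from", "to", "prob")
  edges <- edges %>%
    mutate(n_obs = as.vector(model$C), self = .data$from == .data$to) %>%
    filter(.data$prob > 0) %>%
    arrange(.data$from, dplyr::desc(.data$prob))
  attr(edges, "mean_self_transition") <- model$mean_self_transition
  edges
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Community-state transition model -- site:", x$body_site, "\n")
  cat("  observed steps:", x$n_steps, "\n")
  cat("  transition probabilities:\n")
  print(round(x$P, 3))
  cat("  stationary frequencies:\n")
  print(round(x$stationary, 3))
  cat("  classification:", paste(x$states, "=",
                                 x$classification, collapse = ", "), "\n")
  cat(sprintf("  mean self-transition (observed origins): %.3f\n",
              x$mean_self_transition))
  invisible(x)
}

#' @export
print.conditional_detection <- function(x, ...) {
  cat("Conditional ASV detection probabilities (", x$weights,
      " aggregation)\n", sep = "")
  print(x$aggregate)
  invisible(x)
}
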