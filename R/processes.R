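# Null-model inference of community assembly processes: betaMNTD/betaNTI
# against a tip-shuffling phylogenetic null, Raup-Crick with Bray-Curtis
# under a probabilistic reassembly null, the five-way process partition,
# chi-square contrasts across body sites, and odds-ratio attribution of
# community states to deterministic turnover.

#' Enumerate sample pairs, optionally within body sites
#'
#' @param table a [count_tbl()] (defines the sample universe).
#' @param meta sample metadata; required when `within_site = TRUE`.
#' @param within_site if `TRUE` (default) only pairs from the same body site
#'   are returned, annotated with their site.
#' @return Tibble with `sample_i`, `sample_j` (and `body_site`,
#'   `same_site`).
#' @export
turnover_pairs <- function(table, meta = NULL, within_site = TRUE) {
  ids <- as_tibble(table)$sample_id
  pr <- combn(ids, 2)
  pairs <- tibble(sample_i = pr[1, ], sample_j = pr[2, ])
  if (is.null(meta)) return(pairs)
  site_of <- setNames(meta$body_site, meta$sample_id)
  pairs <- pairs %>%
    mutate(site_i = unname(site_of[.data$sample_i]),
           site_j = unname(site_of[.data$sample_j]),
           same_site = .data$site_i == .data$site_j,
           body_site = ifelse(.data$same_site, .data$site_i, NA_character_)) %>%
    select(-"site_i", -"site_j")
  if (within_site) pairs <- filter(pairs, .data$same_site)
  pairs
}

# build the inputs the compiled betaMNTD core needs
prepare_phylo_inputs <- function(table, tree, pairs, weighted) {
  m <- count_matrix(table)
  involved <- union(pairs$sample_i, pairs$sample_j)
  missing_s <- setdiff(involved, rownames(m))
  if (length(missing_s)) {
    abort(paste0("pair sample(s) not in table: ",
                 paste(head(missing_s, 5), collapse = ", ")))
  }
  m <- m[involved, , drop = FALSE]
  present_any <- colnames(m)[colSums(m) > 0]
  missing_t <- setdiff(present_any, tree$tip.label)
  if (length(missing_t)) {
    abort(paste0("ASV(s) missing from tree: ",
                 paste(head(missing_t, 5), collapse = ", ")))
  }
  D <- ape::cophenetic.phylo(tree)[present_any, present_any, drop = FALSE]
  m <- m[, present_any, drop = FALSE]
  comm_idx <- comm_w <- vector("list", nrow(m))
  for (s in seq_len(nrow(m))) {
    i <- which(m[s, ] > 0)
    if (!length(i)) abort(paste0("empty sample in pairs: ", rownames(m)[s]))
    comm_idx[[s]] <- as.integer(i - 1L)
    comm_w[[s]] <- if (weighted) {
      as.numeric(m[s, i] / sum(m[s, i]))
    } else {
      rep(1 / length(i), length(i))
    }
  }
  pair_idx <- cbind(match(pairs$sample_i, rownames(m)),
                    match(pairs$sample_j, rownames(m))) - 1L
  list(D = D, comm_idx = comm_idx, comm_w = comm_w, pair_idx = pair_idx)
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair (k, m): the abundance-weighted mean, over taxa in
#' each community, of the patristic distance to the nearest taxon in the
#' other community, averaged over the two directions. Unweighted uses equal
#' weights 1/S.
#'
#' @param table a [count_tbl()]; every ASV present in paired samples must be
#'   a tip of `tree`.
#' @param tree rooted `phylo` (or path to a Newick file).
#' @param pairs tibble with `sample_i`, `sample_j` (default: all pairs).
#' @param weighted use relative-abundance weights (default `TRUE`).
#' @return `pairs` with a `bmntd` column appended.
#' @export
beta_mntd <- function(table, tree, pairs = NULL, weighted = TRUE) {
  tree <- as_phylo(tree)
  pairs <- pairs %||% turnover_pairs(table)
  inp <- prepare_phylo_inputs(table, tree, pairs, weighted)
  mutate(pairs, bmntd = as.numeric(
    cpp_beta_mntd(inp$D, inp$comm_idx, inp$comm_w, inp$pair_idx)))
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    return(if (file.exists(tree)) ape::read.tree(tree)
           else ape::read.tree(text = tree))
  }
  abort("`tree` must be a phylo object, Newick string, or file path")
}

#' beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a null that shuffles the
#' ASV-to-tip mapping across the whole tree (one shared permutation per
#' replicate): `bNTI = (obs - mean_null) / sd_null`. |bNTI| > 2 flags
#' deterministic (selection-driven) turnover. Pairs with zero null standard
#' deviation are reported `NA`.
#'
#' @inheritParams beta_mntd
#' @param n_null null replicates (>= 99; default 999).
#' @param seed integer seed.
#' @return `pairs` with `bmntd`, `null_mean`, `null_sd`, `bnti` appended.
#' @export
beta_nti <- function(table, tree, pairs = NULL, n_null = 999, seed = 1L,
                     weighted = TRUE) {
  if (n_null < 99) abort("`n_null` must be >= 99")
  tree <- as_phylo(tree)
  pairs <- pairs %||% turnover_pairs(table)
  inp <- prepare_phylo_inputs(table, tree, pairs, weighted)
  res <- with_seed(seed, cpp_beta_nti(inp$D, inp$comm_idx, inp$comm_w,
                                      inp$pair_idx, as.integer(n_null)))
  out <- mutate(pairs, bmntd = as.numeric(res$obs),
                null_mean = as.numeric(res$null_mean),
                null_sd = as.numeric(res$null_sd),
                bnti = as.numeric(res$bnti))
  n_undef <- sum(is.na(out$bnti))
  if (n_undef) {
    inform(paste0("betaNTI undefined (zero null SD) for ", n_undef, " pair(s)"))
  }
  attr(out, "n_null") <- n_null
  out
}

#' Raup-Crick index on Bray-Curtis dissimilarities
#'
#' Null model: per replicate, every community is probabilistically
#' reassembled preserving its observed richness and total reads — species
#' drawn weighted by metacommunity occupancy (each seeded with one read),
#' remaining reads assigned by draws weighted by metacommunity relative
#' abundance. `RC = 2 * ((#null < obs) + 0.5 * #ties) / n_null - 1`, in
#' \[-1, 1\]; RC > 0.95 indicates fewer shared species than expected by
#' chance (dispersal limitation), RC < -0.95 more (homogenizing dispersal).
#' The metacommunity is all samples of `table`.
#'
#' @inheritParams beta_mntd
#' @param n_null null replicates (default 999).
#' @param seed integer seed.
#' @return `pairs` with an `rc` column appended.
#' @export
raup_crick_bray <- function(table, pairs = NULL, n_null = 999, seed = 1L) {
  m <- count_matrix(table)
  pairs <- pairs %||% turnover_pairs(table)
  pair_idx <- cbind(match(pairs$sample_i, rownames(m)),
                    match(pairs$sample_j, rownames(m))) - 1L
  if (anyNA(pair_idx)) abort("pair sample(s) not found in table")
  rc <- with_seed(seed, cpp_rc_bray(m, pair_idx, as.integer(n_null)))
  out <- mutate(pairs, rc = as.numeric(rc))
  attr(out, "n_null") <- n_null
  out
}

#' Annotate turnover pairs with community states
#'
#' @param pairs a turnover tibble with `sample_i`, `sample_j`.
#' @param assignment a [state_assignment][assign_states()] or tibble.
#' @return `pairs` with `state_i`, `state_j` columns.
#' @export
annotate_states <- function(pairs, assignment) {
  labels <- assignment_tbl(assignment)
  state_of <- setNames(labels$state, labels$sample_id)
  mutate(pairs, state_i = unname(state_of[.data$sample_i]),
         state_j = unname(state_of[.data$sample_j]))
}

process_levels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

classify_processes <- function(bnti, rc, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  out <- rep(NA_character_, length(bnti))
  sel_var <- !is.na(bnti) & bnti > bnti_threshold
  sel_hom <- !is.na(bnti) & bnti < -bnti_threshold
  stoch <- !is.na(bnti) & abs(bnti) <= bnti_threshold
  out[sel_var] <- "variable_selection"
  out[sel_hom] <- "homogeneous_selection"
  out[stoch & !is.na(rc) & rc > rc_threshold] <- "dispersal_limitation"
  out[stoch & !is.na(rc) & rc < -rc_threshold] <- "homogenizing_dispersal"
  out[stoch & !is.na(rc) & abs(rc) <= rc_threshold] <- "drift"
  out
}

#' Partition community turnover into assembly processes
#'
#' Applies the standard thresholds to per-pair (betaNTI, RC) values:
#' betaNTI > +2 variable selection; betaNTI < -2 homogeneous selection;
#' otherwise RC > 0.95 dispersal limitation; RC < -0.95 homogenizing
#' dispersal; |RC| <= 0.95 ecological drift. Pairs with undefined values are
#' excluded and counted.
#'
#' @param turnover tibble with `bnti` and `rc` columns (and optionally a
#'   grouping column).
#' @param by optional column name to partition within (e.g. `"body_site"`).
#' @param bnti_threshold selection threshold (default 2).
#' @param rc_threshold dispersal threshold (default 0.95).
#' @return A `process_partition`: `pairs` (input plus `process`), `summary`
#'   tibble of counts and fractions per group and process (five fractions
#'   summing to 1), `n_missing` per group, and the thresholds.
#' @export
partition_processes <- function(turnover, by = NULL, bnti_threshold = 2,
                                rc_threshold = 0.95) {
  stopifnot(all(c("bnti", "rc") %in% names(turnover)))
  turnover <- mutate(turnover, process = classify_processes(
    .data$bnti, .data$rc, bnti_threshold, rc_threshold))
  grp <- if (is.null(by)) "..all.." else by
  dat <- if (is.null(by)) mutate(turnover, `..all..` = "all") else turnover
  summary <- dat %>%
    filter(!is.na(.data$process)) %>%
    mutate(process = factor(.data$process, levels = process_levels)) %>%
    count(group = .data[[grp]], .data$process, .drop = FALSE) %>%
    group_by(.data$group) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  n_missing <- dat %>%
    group_by(group = .data[[grp]]) %>%
    summarise(n_missing = sum(is.na(.data$process)), .groups = "drop")
  frac_check <- tapply(summary$fraction, summary$group, sum)
  stopifnot(all(abs(frac_check - 1) < 1e-12))
  structure(list(pairs = turnover, summary = summary, n_missing = n_missing,
                 bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold, grouped_by = by),
            class = "process_partition")
}

#' @export
print.process_partition <- function(x, ...) {
  cat("Assembly-process partition (|bNTI| > ", x$bnti_threshold,
      ", |RC| > ", x$rc_threshold, ")\n", sep = "")
  print(tidyr::pivot_wider(x$summary, names_from = "process",
                           values_from = c("n", "fraction")))
  invisible(x)
}

#' Chi-square contrasts of process counts across groups
#'
#' Tests homogeneity of the process composition across groups (body sites)
#' on pair counts: one overall group x process test, and one 2 x groups test
#' per process (that process vs all others). No continuity correction.
#' Expected cells below 5 trigger a warning.
#'
#' @param partition a [partition_processes()] result with a grouping.
#' @return Tibble with `contrast`, `statistic`, `df`, `p_value`.
#' @export
process_chisq <- function(partition) {
  stopifnot(inherits(partition, "process_partition"))
  tab <- tidyr::pivot_wider(partition$summary[c("group", "process", "n")],
                            names_from = "process", values_from = "n")
  counts <- as.matrix(tab[, -1])
  rownames(counts) <- tab$group
  if (nrow(counts) < 2) abort("need >= 2 groups for a chi-square contrast")
  run_chisq <- function(m, label) {
    exp_cells <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(exp_cells < 5)) {
      warn(paste0("chi-square '", label, "': expected cell count below 5"))
    }
    fit <- suppressWarnings(chisq.test(m, correct = FALSE))
    tibble(contrast = label, statistic = unname(fit$statistic),
           df = unname(fit$parameter), p_value = fit$p.value)
  }
  overall <- run_chisq(counts[, colSums(counts) > 0, drop = FALSE], "overall")
  per_process <- map(colnames(counts), function(pr) {
    m <- cbind(counts[, pr], rowSums(counts) - counts[, pr])
    if (sum(m[, 1]) == 0) return(NULL)
    run_chisq(m, pr)
  }) %>% bind_rows()
  bind_rows(overall, per_process)
}

#' Odds ratios for state contributions to deterministic turnover
#'
#' For each community state X at a body site, cross-tabulates same-site
#' pairs by (involves X at either end) x (deterministic, |betaNTI| > 2) and
#' reports the odds ratio with a log-normal 95% CI. Any zero cell triggers
#' the Haldane-Anscombe 0.5 correction (flagged). Significant means the CI
#' lower bound exceeds 1.
#'
#' @param turnover state-annotated turnover tibble (see [annotate_states()])
#'   with `bnti`, `state_i`, `state_j` and `body_site` columns.
#' @param site body site to evaluate (filters `body_site`).
#' @param bnti_threshold deterministic threshold (default 2).
#' @param within_state_only if `TRUE`, "involves X" requires both endpoints
#'   in state X (default: either endpoint).
#' @return Tibble with `body_site`, `state`, cell counts `a`-`d`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `significant`, `corrected`.
#' @export
deterministic_odds_ratio <- function(turnover, site, bnti_threshold = 2,
                                     within_state_only = FALSE) {
  stopifnot(all(c("bnti", "state_i", "state_j") %in% names(turnover)))
  dat <- turnover %>%
    filter(.data$body_site == site, !is.na(.data$bnti),
           !is.na(.data$state_i), !is.na(.data$state_j)) %>%
    mutate(deterministic = abs(.data$bnti) > bnti_threshold)
  if (!nrow(dat)) abort(paste0("no usable pairs at site '", site, "'"))
  states <- sort(unique(c(dat$state_i, dat$state_j)))
  map(states, function(st) {
    involves <- if (within_state_only) {
      dat$state_i == st & dat$state_j == st
    } else {
      dat$state_i == st | dat$state_j == st
    }
    if (!any(involves)) {
      inform(paste0("state '", st, "' absent at site '", site, "'; skipped"))
      return(NULL)
    }
    a <- sum(involves & dat$deterministic)
    b <- sum(involves & !dat$deterministic)
    c_ <- sum(!involves & dat$deterministic)
    d <- sum(!involves & !dat$deterministic)
    corrected <- any(c(a, b, c_, d) == 0)
    h <- if (corrected) 0.5 else 0
    or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
    se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (c_ + h) + 1 / (d + h))
    tibble(body_site = site, state = st,
           a = a, b = b, c = c_, d = d,
           odds_ratio = or,
           ci_lower = exp(log(or) - 1.96 * se),
           ci_upper = exp(log(or) + 1.96 * se),
           significant = exp(log(or) - 1.96 * se) > 1,
           corrected = corrected)
  }) %>% bind_rows()
}
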