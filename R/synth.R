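# Synthetic longitudinal multi-site cohort generator. Emulates a neonatal
# intensive-care cohort: 15 patients x 3 body sites x 4 sampling occasions,
# low-diversity communities driven by 4 latent community states (three
# mono-dominated by Staphylococcus / Escherichia-Shigella / Lactobacillus
# ASVs, one even "intermediate" state), per-site latent Markov transition
# matrices, a birth-death phylogeny with tunable habitat signal, planted
# monotone ASV couplings and reagent-style contamination observable in
# negative controls. All randomness flows from one master seed through
# documented sub-streams (see substream_seed()).

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 15 patients,
#' three body sites, four occasions at nominal days 1/3/7/14, 300 ASVs, four
#' latent states whose dominant-ASV mean relative abundances are 0.61 (SC,
#' ASV_3 *Staphylococcus*), 0.60 (EC, ASV_1 *Escherichia/Shigella*) and 0.91
#' (LC, ASV_2 *Lactobacillus*) plus a high-evenness IC state, and per-site
#' transition matrices calibrated so the gut is the most stable site (mean
#' self-transition ~0.62), the skin the least (~0.21, with a strong pull
#' toward SC and ~70% SC at steady state) and oral LC transitions only to EC
#' or IC.
#'
#' @param n_patients number of patients (default 15).
#' @param body_sites site labels (default gut, oral, skin).
#' @param time_days nominal day of life per occasion (default 1, 3, 7, 14);
#'   occasions are modeled as equally spaced Markov steps, the nominal day is
#'   metadata only.
#' @param n_asvs number of ASVs including contaminants (default 300).
#' @param state_profiles named list per state: `mean` (simplex over ASVs) and
#'   `concentration` (Dirichlet precision). Default built by
#'   [default_state_profiles()].
#' @param transition_matrices named list (per site) of k x k row-stochastic
#'   matrices over the states.
#' @param initial_distribution named list (per site) of length-k simplexes.
#' @param library_size list with `mean`, `size` (negative-binomial mean and
#'   dispersion) and `min` (truncation; the default 650 keeps every sample
#'   above the default 600-read rarefaction depth even after contaminant
#'   removal; set `min = 0` to allow shallow, droppable samples).
#' @param tree_params list with `birth`, `death` rates and `habitat_signal`
#'   in \[0, 1\] (0 = ASV-to-tip assignment fully exchangeable).
#' @param contamination tibble with `genus`, `rate` (expected pooled
#'   negative-control reads; also scales the shared relative abundance
#'   injected into real samples) — or `NULL` for none.
#' @param planted_edges list of length-2 character vectors of ASV ids coupled
#'   through a shared per-sample lognormal factor (monotone association).
#' @param seed master integer seed; fixes all randomness end-to-end.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 15,
                         body_sites = c("gut", "oral", "skin"),
                         time_days = c(1, 3, 7, 14),
                         n_asvs = 300,
                         state_profiles = NULL,
                         transition_matrices = NULL,
                         initial_distribution = NULL,
                         library_size = list(mean = 2000, size = 4, min = 650),
                         tree_params = list(birth = 1, death = 0.3,
                                            habitat_signal = 0.5),
                         contamination = default_contamination(),
                         planted_edges = list(c("ASV_4", "ASV_5"),
                                              c("ASV_6", "ASV_7")),
                         seed = 1L) {
  if (is.null(state_profiles)) state_profiles <- default_state_profiles(n_asvs)
  states <- names(state_profiles)
  k <- length(states)
  if (is.null(transition_matrices)) {
    transition_matrices <- default_transition_matrices()[body_sites]
  }
  if (is.null(initial_distribution)) {
    initial_distribution <- default_initial_distribution()[body_sites]
  }
  cfg <- structure(list(
    n_patients = n_patients, body_sites = body_sites, time_days = time_days,
    n_asvs = n_asvs, state_profiles = state_profiles,
    transition_matrices = transition_matrices,
    initial_distribution = initial_distribution,
    library_size = library_size, tree_params = tree_params,
    contamination = contamination, planted_edges = planted_edges,
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  states <- names(cfg$state_profiles)
  k <- length(states)
  for (st in states) {
    pr <- cfg$state_profiles[[st]]
    check_simplex(pr$mean, tol = 1e-9, arg = paste0("state_profiles$", st, "$mean"))
    if (length(pr$mean) != cfg$n_asvs) {
      abort(paste0("state profile '", st, "' has length ", length(pr$mean),
                   ", expected n_asvs = ", cfg$n_asvs))
    }
    if (pr$concentration <= 0) abort("Dirichlet concentration must be > 0")
  }
  for (site in cfg$body_sites) {
    P <- cfg$transition_matrices[[site]]
    if (is.null(P)) abort(paste0("no transition matrix for site '", site, "'"))
    check_row_stochastic(P, tol = 1e-12,
                         arg = paste0("transition_matrices$", site))
    if (nrow(P) != k) abort("transition matrix dimension != number of states")
    check_simplex(cfg$initial_distribution[[site]], tol = 1e-9,
                  arg = paste0("initial_distribution$", site))
  }
  if (cfg$n_asvs < k) abort("need at least as many ASVs as states")
  invisible(cfg)
}

#' Default latent-state Dirichlet mean profiles
#'
#' Three mono-dominated states with dominant-ASV means 0.61 (SC), 0.60 (EC)
#' and 0.91 (LC), and an even IC state; residual mass decays geometrically
#' over the remaining "satellite" ASVs, with the first four satellites given
#' elevated means so planted correlations act on taxa with workable counts
#' at a 600-read depth.
#'
#' @param n_asvs number of ASVs.
#' @return Named list of `list(mean, concentration)` per state.
#' @export
default_state_profiles <- function(n_asvs) {
  stopifnot(n_asvs >= 10)
  dominants <- c(SC = "ASV_3", EC = "ASV_1", LC = "ASV_2")
  top <- list(
    # named shares of the three dominant ASVs in each state
    SC = c(ASV_3 = 0.61, ASV_1 = 0.08, ASV_2 = 0.05),
    EC = c(ASV_1 = 0.60, ASV_3 = 0.08, ASV_2 = 0.06),
    LC = c(ASV_2 = 0.91, ASV_1 = 0.03, ASV_3 = 0.02),
    IC = c(ASV_1 = 0.18, ASV_3 = 0.17, ASV_2 = 0.15)
  )
  conc <- c(SC = 100, EC = 100, LC = 200, IC = 120)
  asv_ids <- paste0("ASV_", seq_len(n_asvs))
  tail_ids <- asv_ids[-(1:3)]
  w <- 0.97^seq_along(tail_ids)
  # satellites carrying planted correlations get boosted weight
  w[1:4] <- c(12, 8, 10, 7) * w[1:4]
  w <- w / sum(w)
  lapply(setNames(names(top), names(top)), function(st) {
    mean <- setNames(numeric(n_asvs), asv_ids)
    mean[names(top[[st]])] <- top[[st]]
    mean[tail_ids] <- (1 - sum(top[[st]])) * w
    list(mean = mean / sum(mean), concentration = conc[[st]])
  })
}

#' Default per-site latent transition matrices
#'
#' Calibrated to the site dynamics the generator emulates: stable gut
#' (mean self-transition 0.62; EC/LC/IC sticky, SC near-uniform), oral with
#' a stable SC, elevated IC-to-SC flow and LC leaving only to EC or IC, and
#' a volatile skin (mean self-transition ~0.22) funneling toward SC
#' (stationary SC frequency ~0.70).
#'
#' @return Named list of 4x4 row-stochastic matrices (states SC, EC, LC, IC).
#' @export
default_transition_matrices <- function() {
  states <- c("SC", "EC", "LC", "IC")
  mk <- function(x) matrix(x, 4, 4, byrow = TRUE,
                           dimnames = list(states, states))
  list(
    gut = mk(c(0.28, 0.24, 0.24, 0.24,
               0.10, 0.72, 0.08, 0.10,
               0.06, 0.08, 0.76, 0.10,
               0.08, 0.10, 0.10, 0.72)),
    oral = mk(c(0.62, 0.14, 0.04, 0.20,
                0.16, 0.54, 0.04, 0.26,
                0.00, 0.50, 0.00, 0.50,
                0.35, 0.15, 0.05, 0.45)),
    skin = mk(c(0.68, 0.10, 0.04, 0.18,
                0.74, 0.05, 0.04, 0.17,
                0.72, 0.08, 0.04, 0.16,
                0.72, 0.10, 0.04, 0.14))
  )
}

#' @rdname default_transition_matrices
#' @export
default_initial_distribution <- function() {
  states <- c("SC", "EC", "LC", "IC")
  list(gut  = setNames(c(0.15, 0.30, 0.25, 0.30), states),
       oral = setNames(c(0.30, 0.25, 0.05, 0.40), states),
       skin = setNames(c(0.45, 0.15, 0.10, 0.30), states))
}

#' Default reagent-style contamination profile
#'
#' Genus-level rates shared between negative controls (expected pooled reads)
#' and real samples (injected relative abundance = `rate` x 1e-4, modulated
#' by a per-sample lognormal reagent-load factor common to all contaminant
#' genera, which is what makes the correlation-removal rule exercisable).
#' Rates straddle the 10-read control threshold on purpose.
#'
#' @return Tibble with `genus` and `rate`.
#' @export
default_contamination <- function() {
  tibble(genus = c("Ralstonia", "Sphingomonas", "Bradyrhizobium",
                   "Cutibacterium", "Methylobacterium"),
         rate = c(45, 28, 16, 7, 4))
}

#' Simulate discrete state sequences from a Markov chain
#'
#' @param P k x k row-stochastic transition matrix; `P[i, j]` is the
#'   probability of state `j` at the next occasion given state `i` now.
#' @param pi0 length-k initial distribution.
#' @param n_steps sequence length (including the initial draw).
#' @param n_series number of independent sequences.
#' @param seed integer seed.
#' @return List of length `n_series`; each element a length-`n_steps` vector
#'   of state labels (rownames of `P`, or integers when unnamed).
#' @export
simulate_state_sequences <- function(P, pi0, n_steps, n_series = 1, seed) {
  check_row_stochastic(P, tol = 1e-8)
  check_simplex(pi0, arg = "pi0")
  if (n_steps < 1) abort("`n_steps` must be >= 1")
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  cum0 <- cumsum(pi0)
  idx <- with_seed(seed, {
    out <- matrix(0L, n_series, n_steps)
    out[, 1] <- 1L + rowSums(outer(runif(n_series), cum0, ">"))
    for (t in seq_len(n_steps - 1)) {
      cur <- out[, t]
      u <- runif(n_series)
      out[, t + 1] <- 1L + as.integer(rowSums(u > cum[cur, , drop = FALSE]))
    }
    out
  })
  labels <- rownames(P) %||% seq_len(k)
  lapply(seq_len(n_series), function(i) labels[idx[i, ]])
}

#' Draw one ASV count vector from a Dirichlet-multinomial state profile
#'
#' @param profile list with `mean` (simplex) and `concentration` (Dirichlet
#'   precision; `Inf` collapses to the mean).
#' @param library_size total reads to draw.
#' @param seed integer seed.
#' @return Integer count vector summing to `library_size`.
#' @export
sample_counts <- function(profile, library_size, seed) {
  if (!length(profile$mean)) abort("empty state profile")
  if (library_size <= 0) abort("`library_size` must be positive")
  if (is.null(profile$concentration) || profile$concentration <= 0) {
    abort("Dirichlet concentration must be > 0")
  }
  check_simplex(profile$mean, tol = 1e-9, arg = "profile$mean")
  with_seed(seed, {
    p <- rdirichlet1(profile$mean, profile$concentration)
    counts <- as.integer(rmultinom(1, library_size, p))
  })
  setNames(counts, names(profile$mean))
}

# one Dirichlet draw; infinite concentration degenerates to the mean
rdirichlet1 <- function(mean, concentration) {
  if (!is.finite(concentration)) return(mean)
  alpha <- mean * concentration
  g <- ifelse(alpha > 0, rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) return(mean)
  g / sum(g)
}

#' Simulate a rooted phylogeny over ASVs
#'
#' Birth-death tree ([ape::rphylo()]) with tips labeled by ASV ids. When
#' `groups` (per-ASV habitat/state affinity) is supplied, ids are laid onto
#' the tree's cladewise tip order grouped by affinity and then each id is
#' independently relocated with probability `1 - habitat_signal`: signal 1
#' clusters affiliated taxa into clades, signal 0 yields a fully exchangeable
#' (uniformly random) ASV-to-tip assignment.
#'
#' @param n_taxa number of tips (>= 2).
#' @param tree_params list with `birth`, `death`, `habitat_signal`.
#' @param seed integer seed.
#' @param tip_labels ASV ids (default `ASV_1..ASV_n`).
#' @param groups optional factor of length `n_taxa` with the habitat affinity
#'   of each `tip_labels` entry.
#' @return A rooted `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, tree_params = list(birth = 1, death = 0.3,
                                                     habitat_signal = 0),
                          seed, tip_labels = NULL, groups = NULL) {
  if (n_taxa < 2) abort("`n_taxa` must be >= 2")
  tip_labels <- tip_labels %||% paste0("ASV_", seq_len(n_taxa))
  stopifnot(length(tip_labels) == n_taxa, !anyDuplicated(tip_labels))
  signal <- tree_params$habitat_signal %||% 0
  with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = tree_params$birth %||% 1,
                        death = tree_params$death %||% 0, T0 = 50)
    # order ids by affinity group, place on cladewise tip order, then blend
    ord <- if (is.null(groups)) seq_len(n_taxa) else order(as.integer(factor(groups)))
    placed <- tip_labels[ord]
    move <- which(runif(n_taxa) > signal)
    placed[sort(move)] <- placed[sample(sort(move))]
    tip_order <- tree$edge[tree$edge[, 2] <= n_taxa, 2]
    tree$tip.label[tip_order] <- placed
    tree$edge.length <- pmax(tree$edge.length, 1e-8)
    tree
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Runs the full generative model: per-patient, per-site latent state
#' sequences from the configured Markov chains; Dirichlet-multinomial counts
#' from the state profiles with planted pairwise couplings and shared-load
#' contamination; negative-binomial library sizes; a phylogeny with habitat
#' signal; clinical-style metadata; and pooled negative-control read counts.
#'
#' @param config a [synth_config()].
#' @return A `synth_cohort` list: `counts` ([count_tbl()]), `metadata`
#'   (tibble), `truth` (latent states per sample, transition matrices,
#'   stationary distributions, tree, planted edges, negative-control table).
#' @export
generate_cohort <- function(config = synth_config()) {
  validate_synth_config(config)
  cfg <- config
  states <- names(cfg$state_profiles)
  k <- length(states)
  n_t <- length(cfg$time_days)
  n_asvs <- cfg$n_asvs
  asv_ids <- names(cfg$state_profiles[[1]]$mean)

  # --- latent state sequences -------------------------------------------
  seq_seed <- substream_seed(cfg$seed, "states_seq")
  state_seq <- lapply(setNames(cfg$body_sites, cfg$body_sites), function(site) {
    simulate_state_sequences(cfg$transition_matrices[[site]],
                             cfg$initial_distribution[[site]],
                             n_steps = n_t, n_series = cfg$n_patients,
                             seed = seq_seed + match(site, cfg$body_sites))
  })

  # --- contamination setup ----------------------------------------------
  contam <- cfg$contamination
  has_contam <- !is.null(contam) && nrow(contam) > 0
  contam_ids <- character()
  if (has_contam) {
    contam_ids <- paste0("ASV_C", seq_len(nrow(contam)))
  }

  # --- phylogeny with habitat signal ------------------------------------
  # the tree spans every ASV in the emitted table, contaminants included,
  # as an inferred phylogeny over the observed sequences would
  affinity <- apply(sapply(cfg$state_profiles, function(p) {
    p$mean / sum(p$mean)
  }), 1, which.max)
  tree <- simulate_tree(n_asvs + length(contam_ids), cfg$tree_params,
                        seed = substream_seed(cfg$seed, "tree"),
                        tip_labels = c(asv_ids, contam_ids),
                        groups = c(affinity,
                                   rep(length(cfg$state_profiles) + 1,
                                       length(contam_ids))))

  # --- per-sample counts -------------------------------------------------
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  grid <- tidyr::expand_grid(patient_id = patients,
                             body_site = cfg$body_sites,
                             time_index = seq_len(n_t)) %>%
    mutate(sample_id = paste(.data$patient_id, .data$body_site,
                             sprintf("t%d", .data$time_index), sep = "_"),
           day_of_life = cfg$time_days[.data$time_index])

  lib_seed <- substream_seed(cfg$seed, "library")
  libs <- with_seed(lib_seed, {
    draw <- function(n) rnbinom(n, mu = cfg$library_size$mean,
                                size = cfg$library_size$size)
    L <- draw(nrow(grid))
    lmin <- cfg$library_size$min %||% 0
    for (iter in 1:50) {
      low <- L < lmin
      if (!any(low)) break
      L[low] <- draw(sum(low))
    }
    pmax(L, max(1, lmin))
  })

  counts_seed <- substream_seed(cfg$seed, "counts")
  n_total_asvs <- n_asvs + length(contam_ids)
  mat <- matrix(0L, nrow(grid), n_total_asvs,
                dimnames = list(grid$sample_id, c(asv_ids, contam_ids)))
  truth_state <- character(nrow(grid))
  with_seed(counts_seed, {
    for (r in seq_len(nrow(grid))) {
      site <- grid$body_site[r]
      pi_ <- match(grid$patient_id[r], patients)
      st <- state_seq[[site]][[pi_]][grid$time_index[r]]
      truth_state[r] <- st
      prof <- cfg$state_profiles[[st]]
      p <- rdirichlet1(prof$mean, prof$concentration)
      names(p) <- asv_ids
      # planted monotone couplings: shared lognormal factor per pair
      for (pair in cfg$planted_edges %||% list()) {
        lam <- rlnorm(1, -0.5, 1)  # mean-one factor: coupling without bias
        p[pair] <- prof$mean[pair] * lam
      }
      p_full <- c(p, setNames(numeric(length(contam_ids)), contam_ids))
      if (has_contam) {
        reagent_load <- rlnorm(1, 0, 0.5)
        p_full[contam_ids] <- contam$rate * 1e-4 * reagent_load
      }
      p_full <- p_full / sum(p_full)
      mat[r, ] <- as.integer(rmultinom(1, libs[r], p_full))
    }
  })

  # --- negative controls -------------------------------------------------
  neg_controls <- NULL
  if (has_contam) {
    neg_controls <- with_seed(substream_seed(cfg$seed, "contamination"), {
      per_ctrl <- sapply(1:3, function(i) rpois(nrow(contam), contam$rate / 3))
      tibble(genus = contam$genus,
             control_1 = per_ctrl[, 1], control_2 = per_ctrl[, 2],
             control_3 = per_ctrl[, 3],
             reads = as.integer(rowSums(per_ctrl)))
    })
  }

  # --- taxonomy ----------------------------------------------------------
  taxonomy <- synth_taxonomy(asv_ids, contam_ids,
                             if (has_contam) contam$genus else character())

  # --- metadata ----------------------------------------------------------
  metadata <- with_seed(substream_seed(cfg$seed, "metadata"), {
    pat <- tibble(
      patient_id = patients,
      ga_weeks = round(rnorm(cfg$n_patients, 24.67, 1.12), 1),
      delivery_mode = sample(c("cesarean", "vaginal"), cfg$n_patients,
                             replace = TRUE, prob = c(11, 4) / 15),
      rop = rbinom(cfg$n_patients, 1, 11 / 15),
      ivh = rbinom(cfg$n_patients, 1, 5 / 15),
      bpd = rbinom(cfg$n_patients, 1, 5 / 15),
      vent_propensity = runif(cfg$n_patients)
    )
    grid %>%
      left_join(pat, by = "patient_id") %>%
      mutate(
        dmv_days = round(.data$day_of_life * .data$vent_propensity),
        dos_days = pmin(.data$day_of_life,
                        .data$dmv_days + rpois(dplyr::n(), 1)),
        antibiotics_index = .data$day_of_life +
          rpois(dplyr::n(), .data$day_of_life / 4),
        elevated_il6 = rbinom(dplyr::n(), 1, 0.2)
      ) %>%
      select(-"vent_propensity") %>%
      select("sample_id", "patient_id", "body_site", "time_index",
             "day_of_life", dplyr::everything())
  })

  stationary <- lapply(cfg$transition_matrices,
                       function(P) stationary_distribution(P))

  truth <- list(
    state = tibble(sample_id = grid$sample_id, state = truth_state),
    transition_matrices = cfg$transition_matrices,
    stationary = stationary,
    tree = tree,
    tree_newick = ape::write.tree(tree),
    planted_edges = cfg$planted_edges,
    negative_controls = neg_controls,
    contaminant_asvs = contam_ids
  )

  structure(list(counts = count_tbl(mat, taxonomy), metadata = metadata,
                 truth = truth, config = cfg),
            class = "synth_cohort")
}

# Seven-rank semicolon taxonomy strings. The three dominants get the genera
# they emulate; satellites draw from a fixed pool of NICU-plausible genera;
# contaminant ASVs get their configured reagent genus.
synth_taxonomy <- function(asv_ids, contam_ids, contam_genera) {
  pool <- c("Enterococcus", "Streptococcus", "Klebsiella", "Enterobacter",
            "Corynebacterium", "Veillonella", "Haemophilus", "Acinetobacter",
            "Serratia", "Bacteroides", "Rothia", "Gemella", "Neisseria",
            "Prevotella", "Clostridium", "Finegoldia", "Micrococcus", "")
  genus <- character(length(asv_ids))
  genus[1] <- "Escherichia/Shigella"
  genus[2] <- "Lactobacillus"
  genus[3] <- "Staphylococcus"
  if (length(asv_ids) > 3) {
    genus[4:length(asv_ids)] <- pool[((seq_len(length(asv_ids) - 3) - 1) %%
                                        length(pool)) + 1]
  }
  mk_tax <- function(g) {
    paste0("d__Bacteria;p__;c__;o__;f__;g__", g, ";s__")
  }
  tibble(asv_id = c(asv_ids, contam_ids),
         taxonomy = c(mk_tax(genus), mk_tax(contam_genera)))
}

#' Write a synthetic cohort to disk
#'
#' Emits the count table TSV (+ taxonomy sidecar), metadata TSV, Newick tree,
#' negative-control TSV and a JSON truth bundle into `dir`.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  writeLines(cohort$truth$tree_newick, file.path(dir, "tree.nwk"))
  if (!is.null(cohort$truth$negative_controls)) {
    readr::write_tsv(cohort$truth$negative_controls,
                     file.path(dir, "negative_controls.tsv"), progress = FALSE)
  }
  truth <- cohort$truth
  truth_json <- list(
    state = truth$state,
    transition_matrices = lapply(truth$transition_matrices, function(P) {
      list(states = rownames(P), P = unname(P))
    }),
    stationary = lapply(truth$stationary, function(s) unname(as.matrix(s))),
    tree_newick = truth$tree_newick,
    planted_edges = truth$planted_edges,
    contaminant_asvs = truth$contaminant_asvs
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$metadata), " samples (",
      x$config$n_patients, " patients x ", length(x$config$body_sites),
      " sites x ", length(x$config$time_days), " occasions), ",
      ncol(x$counts) - 1L, " ASVs\n", sep = "")
  cat("  latent states: ", paste(names(x$config$state_profiles),
                                 collapse = ", "), "\n", sep = "")
  invisible(x)
}
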