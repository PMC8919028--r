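# End-to-end orchestration: synthetic or user data through preprocessing,
# diversity, community states, Markov models, assembly processes and
# co-occurrence networks, with a machine-readable run report.

#' Pipeline configuration
#'
#' Validates all stage parameters up front (fail-fast: no stage runs on an
#' invalid configuration). Either `synthetic = TRUE` (inputs generated by
#' [generate_cohort()] from `synth`) or paths to a count table, metadata,
#' tree and (optionally) negative controls.
#'
#' @param synthetic generate inputs from `synth` (default `TRUE`).
#' @param synth a [synth_config()]; its seed is overridden by `seed`.
#' @param counts,metadata,tree,neg_controls input file paths when
#'   `synthetic = FALSE` (`tree`/`neg_controls` optional unless their stages
#'   are enabled).
#' @param stages character vector of stages to run, from
#'   `c("preprocess", "diversity", "states", "markov", "processes",
#'   "networks")`.
#' @param depth rarefaction depth (default 600).
#' @param n_perm permutations for PERMANOVA/envfit/networks (default 1000).
#' @param n_null null replicates for betaNTI / RC (default 999).
#' @param k_range candidate state counts (default 2:8).
#' @param n_init k-means restarts (default 100).
#' @param bnti_threshold,rc_threshold process-partition thresholds
#'   (defaults 2 and 0.95).
#' @param alpha network edge threshold (default 0.01).
#' @param read_threshold,r_threshold contaminant-filter thresholds
#'   (defaults 10 and 0.9).
#' @param seed global seed; every stage derives its own sub-stream
#'   ([substream_seed()]).
#' @param outdir output directory (`NULL` for no file output).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = TRUE, synth = synth_config(),
                            counts = NULL, metadata = NULL, tree = NULL,
                            neg_controls = NULL,
                            stages = c("preprocess", "diversity", "states",
                                       "markov", "processes", "networks"),
                            depth = 600, n_perm = 1000, n_null = 999,
                            k_range = 2:8, n_init = 100,
                            bnti_threshold = 2, rc_threshold = 0.95,
                            alpha = 0.01, read_threshold = 10,
                            r_threshold = 0.9, seed = 1L, outdir = NULL) {
  known <- c("preprocess", "diversity", "states", "markov", "processes",
             "networks")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if (depth <= 0) abort("`depth` must be positive")
  if (n_perm < 1 || n_null < 99) abort("`n_perm` >= 1 and `n_null` >= 99 required")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1]")
  if (bnti_threshold <= 0 || rc_threshold <= 0 || rc_threshold > 1) {
    abort("thresholds must be positive (rc_threshold <= 1)")
  }
  if (!synthetic) {
    for (f in c("counts", "metadata")) {
      p <- get(f)
      if (is.null(p) || !file.exists(p)) {
        abort(paste0("`", f, "` path missing or nonexistent"))
      }
    }
    if ("processes" %in% stages &&
        (is.null(tree) || !file.exists(tree))) {
      abort("`tree` path required (and must exist) for the processes stage")
    }
    if (!is.null(neg_controls) && !file.exists(neg_controls)) {
      abort("`neg_controls` path does not exist")
    }
  } else {
    synth$seed <- as.integer(seed)
  }
  structure(list(synthetic = synthetic, synth = synth, counts = counts,
                 metadata = metadata, tree = tree,
                 neg_controls = neg_controls, stages = stages, depth = depth,
                 n_perm = n_perm, n_null = n_null, k_range = k_range,
                 n_init = n_init, bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold, alpha = alpha,
                 read_threshold = read_threshold, r_threshold = r_threshold,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (input/preprocess ->
#' diversity -> states -> markov / processes / networks). A stage failure
#' halts its dependents but lets independent stages continue; the report is
#' written regardless, naming the failed stage. Reruns with the same
#' configuration and seed reproduce byte-identical TSV outputs.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_run`: `results` (per-stage result objects), `report`
#'   (statuses, parameters, seeds, warnings, timings, output checksums), and
#'   `ok` (all enabled stages succeeded).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  report <- list(
    parameters = config[c("depth", "n_perm", "n_null", "k_range", "n_init",
                          "bnti_threshold", "rc_threshold", "alpha",
                          "read_threshold", "r_threshold", "seed")],
    seeds = lapply(setNames(commstate_stages(), commstate_stages()),
                   function(s) substream_seed(config$seed, s)),
    stages = list()
  )
  failed <- character()

  run_stage <- function(name, deps, fn) {
    if (!name %in% c("input", config$stages)) return(invisible())
    if (length(intersect(deps, failed))) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste0("dependency failed: ",
                                                     paste(intersect(deps, failed),
                                                           collapse = ", ")))
      failed <<- c(failed, name)
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    warnings_seen <- character()
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) structure(list(msg = conditionMessage(e)),
                                                   class = "stage_error")),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "stage_error")) {
      failed <<- c(failed, name)
      report$stages[[name]] <<- list(status = "error", error = res$msg,
                                     seconds = round(secs, 2))
    } else {
      results[[name]] <<- res
      report$stages[[name]] <<- list(status = "ok", seconds = round(secs, 2),
                                     warnings = warnings_seen)
    }
    invisible()
  }

  # ---- input ------------------------------------------------------------
  run_stage("input", character(), function() {
    if (config$synthetic) {
      cohort <- generate_cohort(config$synth)
      if (!is.null(outdir)) write_cohort(cohort, file.path(outdir, "input"))
      list(counts = cohort$counts, metadata = cohort$metadata,
           truth = cohort$truth,
           neg_controls = cohort$truth$negative_controls,
           tree = cohort$truth$tree)
    } else {
      list(counts = read_count_table(config$counts),
           metadata = read_metadata(config$metadata),
           truth = NULL,
           neg_controls = if (!is.null(config$neg_controls)) {
             readr::read_tsv(config$neg_controls, show_col_types = FALSE,
                             progress = FALSE)
           },
           tree = if (!is.null(config$tree)) ape::read.tree(config$tree))
    }
  })

  # ---- preprocess -------------------------------------------------------
  run_stage("preprocess", "input", function() {
    inp <- results$input
    filtered <- filter_contaminants(inp$counts,
                                    neg_controls = inp$neg_controls,
                                    read_threshold = config$read_threshold,
                                    r_threshold = config$r_threshold)
    rare <- rarefy(filtered$table, depth = config$depth,
                   seed = substream_seed(config$seed, "rarefy"))
    coverage <- goods_coverage(rare)
    meta <- filter(inp$metadata,
                   .data$sample_id %in% as_tibble(rare)$sample_id)
    if (!is.null(outdir)) {
      d <- file.path(outdir, "preprocess")
      dir.create(d, showWarnings = FALSE)
      write_count_table(rare, file.path(d, "rarefied_counts.tsv"))
      readr::write_tsv(coverage, file.path(d, "goods_coverage.tsv"),
                       progress = FALSE)
      jsonlite::write_json(
        filtered$report[c("removed_genera", "removed_asvs", "reads_removed",
                          "fraction_removed", "total_reads_before",
                          "total_reads_after")],
        file.path(d, "contaminant_report.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    }
    list(table = rare, meta = meta, report = filtered$report,
         coverage = coverage)
  })

  # ---- diversity --------------------------------------------------------
  run_stage("diversity", "preprocess", function() {
    pp <- results$preprocess
    alpha <- alpha_diversity(pp$table)
    d <- bray_curtis(pp$table)
    ord <- pcoa_ord(d)
    assoc <- permanova(d, groups = pp$meta$body_site,
                       blocks = pp$meta$patient_id, n_perm = config$n_perm,
                       seed = substream_seed(config$seed, "permanova"))
    contrasts <- dissimilarity_contrasts(d, pp$meta)
    if (!is.null(outdir)) {
      dd <- file.path(outdir, "diversity")
      dir.create(dd, showWarnings = FALSE)
      readr::write_tsv(alpha, file.path(dd, "alpha_diversity.tsv"),
                       progress = FALSE)
      readr::write_tsv(as_tibble(as.matrix(d), rownames = "sample_id"),
                       file.path(dd, "bray_curtis.tsv"), progress = FALSE)
      readr::write_tsv(tidy(assoc), file.path(dd, "permanova_site.tsv"),
                       progress = FALSE)
      readr::write_tsv(contrasts$contrasts,
                       file.path(dd, "dissimilarity_contrasts.tsv"),
                       progress = FALSE)
      readr::write_tsv(contrasts$founder,
                       file.path(dd, "founder_distances.tsv"),
                       progress = FALSE)
    }
    list(alpha = alpha, dist = d, ord = ord, permanova_site = assoc,
         contrasts = contrasts)
  })

  # ---- states -----------------------------------------------------------
  run_stage("states", "diversity", function() {
    div <- results$diversity
    pp <- results$preprocess
    seed <- substream_seed(config$seed, "clustering")
    sel <- select_k(div$dist, k_range = config$k_range, seed = seed,
                    n_init = config$n_init)
    assignment <- assign_states(div$dist, pp$table, k = sel$k, seed = seed,
                                n_init = config$n_init)
    repr <- site_representation(assignment, pp$meta)
    recovery <- NA_real_
    if (!is.null(results$input$truth)) {
      truth <- results$input$truth$state
      joined <- inner_join(assignment$assignments, truth, by = "sample_id",
                           suffix = c("_est", "_true"))
      recovery <- label_agreement(joined$state_est, joined$state_true)
    }
    if (!is.null(outdir)) {
      d <- file.path(outdir, "states")
      dir.create(d, showWarnings = FALSE)
      readr::write_tsv(assignment$assignments,
                       file.path(d, "state_assignments.tsv"), progress = FALSE)
      readr::write_tsv(sel$scores, file.path(d, "k_selection_scores.tsv"),
                       progress = FALSE)
      readr::write_tsv(repr, file.path(d, "site_representation.tsv"),
                       progress = FALSE)
    }
    list(selection = sel, assignment = assignment, representation = repr,
         state_recovery = recovery)
  })

  # ---- markov -----------------------------------------------------------
  run_stage("markov", "states", function() {
    pp <- results$preprocess
    st <- results$states
    sites <- sort(unique(pp$meta$body_site))
    states_all <- sort(unique(st$assignment$assignments$state))
    models <- lapply(setNames(sites, sites), function(s) {
      estimate_transitions(st$assignment, pp$meta, site = s,
                           states = states_all)
    })
    cond <- conditional_detection(pp$table, pp$meta)
    if (!is.null(outdir)) {
      d <- file.path(outdir, "markov")
      dir.create(d, showWarnings = FALSE)
      for (s in sites) {
        readr::write_tsv(tidy(models[[s]]),
                         file.path(d, paste0("transitions_", s, ".tsv")),
                         progress = FALSE)
      }
      readr::write_tsv(bind_rows(lapply(models, glance)),
                       file.path(d, "transition_models.tsv"),
                       progress = FALSE)
      readr::write_tsv(cond$aggregate,
                       file.path(d, "conditional_detection.tsv"),
                       progress = FALSE)
    }
    list(models = models, conditional = cond)
  })

  # ---- processes --------------------------------------------------------
  run_stage("processes", "states", function() {
    pp <- results$preprocess
    st <- results$states
    tree <- results$input$tree
    if (is.null(tree)) abort("processes stage requires a tree")
    pairs <- turnover_pairs(pp$table, pp$meta, within_site = TRUE)
    turn <- beta_nti(pp$table, tree, pairs, n_null = config$n_null,
                     seed = substream_seed(config$seed, "bnti"))
    turn <- raup_crick_bray(pp$table, turn, n_null = config$n_null,
                            seed = substream_seed(config$seed, "rcbray"))
    turn <- annotate_states(turn, st$assignment)
    part <- partition_processes(turn, by = "body_site",
                                bnti_threshold = config$bnti_threshold,
                                rc_threshold = config$rc_threshold)
    chisq <- process_chisq(part)
    ors <- bind_rows(lapply(sort(unique(pp$meta$body_site)), function(s) {
      deterministic_odds_ratio(turn, site = s,
                               bnti_threshold = config$bnti_threshold)
    }))
    if (!is.null(outdir)) {
      d <- file.path(outdir, "processes")
      dir.create(d, showWarnings = FALSE)
      readr::write_tsv(part$pairs, file.path(d, "turnover_pairs.tsv"),
                       progress = FALSE)
      readr::write_tsv(part$summary, file.path(d, "process_partition.tsv"),
                       progress = FALSE)
      readr::write_tsv(chisq, file.path(d, "process_chisq.tsv"),
                       progress = FALSE)
      readr::write_tsv(ors, file.path(d, "state_odds_ratios.tsv"),
                       progress = FALSE)
    }
    list(turnover = turn, partition = part, chisq = chisq, odds_ratios = ors)
  })

  # ---- networks ---------------------------------------------------------
  run_stage("networks", "states", function() {
    pp <- results$preprocess
    st <- results$states
    states_all <- sort(unique(st$assignment$assignments$state))
    seed0 <- substream_seed(config$seed, "network")
    nets <- lapply(setNames(states_all, states_all), function(state) {
      ids <- st$assignment$assignments$sample_id[
        st$assignment$assignments$state == state]
      if (length(ids) < 4) return(NULL)
      build_network(pp$table, samples = ids, n_perm = config$n_perm,
                    alpha = config$alpha,
                    seed = seed0 + match(state, states_all), group = state)
    })
    nets <- Filter(Negate(is.null), nets)
    if (!is.null(outdir)) {
      d <- file.path(outdir, "networks")
      dir.create(d, showWarnings = FALSE)
      for (nm in names(nets)) {
        write_network(nets[[nm]],
                      path_tsv = file.path(d, paste0("edges_", nm, ".tsv")),
                      path_graphml = file.path(d, paste0("network_", nm,
                                                         ".graphml")))
      }
    }
    nets
  })

  # ---- report -----------------------------------------------------------
  if (!is.null(outdir)) {
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("run_report\\.json$", files)]
    report$output_checksums <- as.list(tools::md5sum(files))
    names(report$output_checksums) <-
      sub(paste0("^", outdir, "/?"), "", names(report$output_checksums))
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(results = results, report = report,
                 ok = !length(failed)), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", if (x$ok) "all stages ok" else "FAILURES", "\n")
  for (nm in names(x$report$stages)) {
    st <- x$report$stages[[nm]]
    secs <- if (is.null(st$seconds)) "" else sprintf(" (%.1fs)", st$seconds)
    cat(sprintf("  %-10s %s%s\n", nm, st$status, secs))
  }
  if (!is.null(x$results$states)) {
    cat(sprintf("  state recovery vs truth: %.3f\n",
                x$results$states$state_recovery))
  }
  invisible(x)
}
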