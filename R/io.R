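# Reading/writing tables and the pre-processing steps applied before any
# ecological analysis: contaminant removal, rarefaction, coverage.

#' Read / write ASV count tables
#'
#' Count tables are TSV files with a `sample_id` column and one column per
#' ASV; taxonomy lives in a sidecar TSV (`asv_id`, `taxonomy`) written next to
#' the table as `<path>.taxonomy.tsv` (or given explicitly).
#'
#' @param path TSV path.
#' @param taxonomy_path optional sidecar path; defaults to
#'   `<path>.taxonomy.tsv` if that file exists.
#' @return A [count_tbl()].
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tbl)) {
    abort(paste0("'", path, "' has no `sample_id` column"))
  }
  if (is.null(taxonomy_path)) {
    default <- paste0(path, ".taxonomy.tsv")
    if (file.exists(default)) taxonomy_path <- default
  }
  tax <- if (!is.null(taxonomy_path)) {
    readr::read_tsv(taxonomy_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  count_tbl(tbl, tax)
}

#' @rdname read_count_table
#' @param table a [count_tbl()].
#' @export
write_count_table <- function(table, path, taxonomy_path = NULL) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  taxonomy_path <- taxonomy_path %||% paste0(path, ".taxonomy.tsv")
  readr::write_tsv(attr(table, "taxonomy"), taxonomy_path, progress = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Metadata rows describe one sample each: `sample_id`, `patient_id`,
#' `body_site`, `time_index`, `day_of_life`, plus clinical covariates.
#' `(patient_id, body_site, time_index)` must be unique.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta)
  meta
}

#' @rdname read_metadata
#' @param meta metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "patient_id", "body_site", "time_index")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("metadata missing columns: ", paste(miss, collapse = ", ")))
  }
  key <- paste(meta$patient_id, meta$body_site, meta$time_index)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (patient, site, time) key: ",
                 key[duplicated(key)][1]))
  }
  invisible(TRUE)
}

#' Remove contaminant taxa using negative controls
#'
#' Applies three removal rules in order: (a) genera exceeding
#' `read_threshold` reads in the pooled negative controls; (b) genera whose
#' across-sample relative-abundance profile has Pearson r strictly above
#' `r_threshold` with any rule-(a) genus; (c) genera on an explicit reagent
#' contaminant list. An optional `asv_exclude` list removes individual ASVs
#' (e.g. run-level cross-contamination identified externally). Unassigned
#' genera (`g__unclassified`) are exempt from the correlation rule so the
#' aggregate of all unknowns is never co-removed.
#'
#' @param table a [count_tbl()] with taxonomy.
#' @param neg_controls tibble with `genus` and `reads` columns (pooled
#'   negative-control read counts per genus).
#' @param reagent_list character vector of genus names (rule c).
#' @param asv_exclude character vector of ASV ids to drop outright.
#' @param read_threshold rule-(a) cutoff; genera with reads strictly greater
#'   are contaminants (default 10).
#' @param r_threshold rule-(b) Pearson correlation cutoff (default 0.9),
#'   computed on genus-aggregated relative abundances across all samples.
#' @return List with `table` (filtered [count_tbl()]) and `report`
#'   (`contaminant_report`: genera removed per rule, correlation values, and
#'   read fractions that reconcile exactly with the input total).
#' @export
filter_contaminants <- function(table, neg_controls = NULL,
                                reagent_list = character(),
                                asv_exclude = character(),
                                read_threshold = 10, r_threshold = 0.9) {
  m <- count_matrix(table)
  tax <- taxonomy_tbl(table)
  total_reads <- sum(m)

  genus_of <- setNames(tax$genus, tax$asv_id)
  genera <- genus_of[colnames(m)]

  # genus-aggregated relative abundances across samples
  rel <- m / pmax(rowSums(m), 1)
  genus_levels <- unique(genera)
  genus_rel <- sapply(genus_levels, function(g) {
    rowSums(rel[, genera == g, drop = FALSE])
  })
  if (is.null(dim(genus_rel))) genus_rel <- matrix(genus_rel, nrow = nrow(m),
                                                   dimnames = list(rownames(m), genus_levels))

  rule_a <- character()
  if (!is.null(neg_controls) && nrow(neg_controls)) {
    ctrl <- neg_controls %>%
      group_by(.data$genus) %>%
      summarise(reads = sum(.data$reads), .groups = "drop")
    rule_a <- ctrl$genus[ctrl$reads > read_threshold]
    rule_a <- intersect(rule_a, genus_levels)
  }

  rule_b <- tibble(genus = character(), partner = character(), r = double())
  if (length(rule_a)) {
    candidates <- setdiff(genus_levels, c(rule_a, "g__unclassified"))
    for (g in candidates) {
      rs <- suppressWarnings(
        cor(genus_rel[, g], genus_rel[, rule_a, drop = FALSE])
      )
      rs[is.na(rs)] <- -Inf
      if (max(rs) > r_threshold) {
        j <- which.max(rs)
        rule_b <- bind_rows(rule_b, tibble(genus = g, partner = rule_a[j],
                                           r = max(rs)))
      }
    }
  }

  rule_c <- setdiff(intersect(reagent_list, genus_levels),
                    c(rule_a, rule_b$genus))

  removed_genera <- list(control = rule_a,
                         correlated = setdiff(rule_b$genus, rule_a),
                         reagent = rule_c)
  all_removed <- unique(unlist(removed_genera))

  drop_asv <- names(genera)[genera %in% all_removed]
  drop_asv <- union(drop_asv, intersect(asv_exclude, colnames(m)))

  reads_by_rule <- vapply(removed_genera, function(gs) {
    sum(m[, genera %in% gs, drop = FALSE])
  }, double(1))
  reads_excluded <- sum(m[, setdiff(intersect(asv_exclude, colnames(m)),
                                    names(genera)[genera %in% all_removed]),
                          drop = FALSE])

  keep <- setdiff(colnames(m), drop_asv)
  if (!length(keep)) abort("contaminant filtering removed every ASV")
  out <- m[, keep, drop = FALSE]

  report <- structure(list(
    removed_genera = removed_genera,
    correlation_detail = rule_b,
    removed_asvs = drop_asv,
    reads_removed = c(reads_by_rule, excluded_asvs = reads_excluded),
    fraction_removed = c(reads_by_rule, excluded_asvs = reads_excluded) /
      max(total_reads, 1),
    total_reads_before = total_reads,
    total_reads_after = sum(out),
    read_threshold = read_threshold,
    r_threshold = r_threshold
  ), class = "contaminant_report")
  stopifnot(report$total_reads_before ==
              report$total_reads_after + sum(report$reads_removed))

  list(table = rebuild_count_tbl(out, tax), report = report)
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat("Contaminant filtering report\n")
  cat("  control-threshold genera: ",
      paste(x$removed_genera$control, collapse = ", "), "\n", sep = "")
  cat("  correlated genera:        ",
      paste(x$removed_genera$correlated, collapse = ", "), "\n", sep = "")
  cat("  reagent-list genera:      ",
      paste(x$removed_genera$reagent, collapse = ", "), "\n", sep = "")
  cat(sprintf("  reads removed: %d of %d (%.3f%%)\n",
              sum(x$reads_removed), x$total_reads_before,
              100 * sum(x$reads_removed) / max(x$total_reads_before, 1)))
  invisible(x)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth` reads. Samples
#' with fewer than `depth` total reads are dropped with a message.
#'
#' @param table a [count_tbl()].
#' @param depth target reads per sample (default 600).
#' @param seed integer seed (mandatory; logged by the pipeline).
#' @return A rarefied [count_tbl()] with attribute `"dropped_samples"`.
#' @export
rarefy <- function(table, depth = 600, seed) {
  if (depth <= 0) abort("`depth` must be positive")
  if (missing(seed)) abort("`seed` is required for rarefaction")
  m <- count_matrix(table)
  totals <- rowSums(m)
  dropped <- rownames(m)[totals < depth]
  if (length(dropped)) {
    inform(paste0("rarefy: dropping ", length(dropped),
                  " sample(s) below depth ", depth, ": ",
                  paste(head(dropped, 5), collapse = ", ")))
  }
  m <- m[totals >= depth, , drop = FALSE]
  if (!nrow(m)) abort("no samples at or above rarefaction depth")
  rare <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    # vegan cautions whenever depth exceeds some cell count; retained
    # samples all have totals >= depth, so the subsampling is well-defined
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  stopifnot(all(rowSums(rare) == depth))
  out <- rebuild_count_tbl(rare, taxonomy_tbl(table))
  attr(out, "dropped_samples") <- dropped
  out
}

#' Good's coverage per sample
#'
#' Coverage = 1 - singletons / total reads; an estimate of how completely a
#' sample's community was observed at its sequencing depth.
#'
#' @param table a [count_tbl()].
#' @return Tibble with `sample_id`, `singletons`, `reads`, `coverage`.
#' @export
goods_coverage <- function(table) {
  m <- count_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort(paste0("empty sample: ", rownames(m)[totals == 0][1]))
  }
  singletons <- unname(rowSums(m == 1))
  totals <- unname(totals)
  tibble(sample_id = rownames(m), singletons = as.integer(singletons),
         reads = as.integer(totals), coverage = 1 - singletons / totals)
}
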