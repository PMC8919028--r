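#' ASV count tables
#'
#' The pipeline currency is a samples-by-ASVs count table stored as a tibble:
#' a `sample_id` character column followed by one non-negative integer column
#' per ASV, with a per-ASV taxonomy table (semicolon-delimited seven-rank
#' strings, domain through genus/species) attached as the `"taxonomy"`
#' attribute.
#'
#' @param counts integer matrix (samples x ASVs) with dimnames, or a data
#'   frame with a `sample_id` column.
#' @param taxonomy tibble with columns `asv_id` and `taxonomy`, one row per
#'   ASV column. Missing ranks may be empty strings.
#' @return A `count_tbl` tibble.
#' @export
count_tbl <- function(counts, taxonomy = NULL) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts)) || is.null(colnames(counts))) {
      abort("count matrix must have sample rownames and ASV colnames")
    }
    tbl <- as_tibble(counts, rownames = "sample_id")
  } else {
    tbl <- as_tibble(counts)
    if (!"sample_id" %in% names(tbl)) {
      abort("count table needs a `sample_id` column")
    }
    tbl <- select(tbl, "sample_id", dplyr::everything())
  }
  validate_counts(tbl)
  if (is.null(taxonomy)) {
    taxonomy <- tibble(asv_id = setdiff(names(tbl), "sample_id"), taxonomy = "")
  }
  taxonomy <- as_tibble(taxonomy)
  if (!all(c("asv_id", "taxonomy") %in% names(taxonomy))) {
    abort("taxonomy needs `asv_id` and `taxonomy` columns")
  }
  missing_tax <- setdiff(setdiff(names(tbl), "sample_id"), taxonomy$asv_id)
  if (length(missing_tax)) {
    abort(paste0("taxonomy missing for ASVs: ",
                 paste(head(missing_tax, 5), collapse = ", ")))
  }
  new_count_tbl(tbl, taxonomy)
}

new_count_tbl <- function(tbl, taxonomy) {
  attr(tbl, "taxonomy") <- taxonomy
  class(tbl) <- unique(c("count_tbl", class(tbl)))
  tbl
}

validate_counts <- function(tbl) {
  if (anyDuplicated(tbl$sample_id)) {
    dup <- tbl$sample_id[duplicated(tbl$sample_id)][1]
    abort(paste0("duplicate sample id: '", dup, "'"))
  }
  asv_cols <- setdiff(names(tbl), "sample_id")
  if (anyDuplicated(asv_cols)) {
    abort(paste0("duplicate ASV id: '", asv_cols[duplicated(asv_cols)][1], "'"))
  }
  m <- as.matrix(tbl[asv_cols])
  if (!is.numeric(m)) abort("counts must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(m != round(m))) abort("counts must be integers")
  invisible(TRUE)
}

#' Extract the counts as an integer matrix (samples x ASVs)
#' @param table a `count_tbl` or compatible data frame.
#' @return Integer matrix with sample rownames and ASV colnames.
#' @export
count_matrix <- function(table) {
  tbl <- as_tibble(table)
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$sample_id
  m
}

#' Taxonomy table attached to a count table
#' @param table a `count_tbl`.
#' @return Tibble with `asv_id`, `taxonomy` (and a derived `genus` column).
#' @export
taxonomy_tbl <- function(table) {
  tax <- attr(table, "taxonomy")
  if (is.null(tax)) {
    tax <- tibble(asv_id = setdiff(names(as_tibble(table)), "sample_id"),
                  taxonomy = "")
  }
  mutate(tax, genus = genus_from_taxonomy(.data$taxonomy))
}

# Genus = 6th semicolon-delimited rank; blank or absent -> "g__unclassified".
genus_from_taxonomy <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  vapply(parts, function(p) {
    g <- if (length(p) >= 6) trimws(p[6]) else ""
    g <- sub("^g__", "", g)
    if (!nzchar(g)) "g__unclassified" else g
  }, character(1))
}

# rebuild a count_tbl from a matrix, carrying taxonomy for surviving ASVs
rebuild_count_tbl <- function(m, taxonomy) {
  keep <- taxonomy$asv_id %in% colnames(m)
  count_tbl(m, taxonomy[keep, c("asv_id", "taxonomy")])
}

#' @export
print.count_tbl <- function(x, ...) {
  n_asv <- ncol(x) - 1L
  cat("# ASV count table: ", nrow(x), " samples x ", n_asv, " ASVs\n", sep = "")
  NextMethod()
}
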