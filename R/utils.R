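# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic stage draws its own integer seed from the master seed so
#' that stages are independently reproducible: stage `i` (1-based position of
#' `stage` in the registered stage names) gets
#' `(seed * 48271 + 1000003 * i) mod (2^31 - 1)`. 48271 is the classic
#' Lehmer/MINSTD multiplier; the modulus keeps seeds within R's integer range.
#'
#' @param seed master integer seed.
#' @param stage character stage name (see `commstate_stages()`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stages <- commstate_stages()
  i <- match(stage, stages)
  if (is.na(i)) {
    abort(paste0("unknown stage '", stage, "'; known stages: ",
                 paste(stages, collapse = ", ")))
  }
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + 1000003 * i
  as.integer(s %% m)
}

#' Registered pipeline stage names for seed sub-streams
#' @return Character vector of stage names.
#' @export
commstate_stages <- function() {
  c("states_seq", "tree", "counts", "library", "contamination", "metadata",
    "rarefy", "clustering", "permanova", "envfit", "bnti", "rcbray",
    "network", "misc")
}

# stop unless all rows of P sum to 1 within tol; report offending row
check_row_stochastic <- function(P, tol = 1e-8, arg = "P") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    abort(paste0("`", arg, "` must be a square matrix"))
  }
  if (any(P < -tol)) abort(paste0("`", arg, "` has negative entries"))
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    abort(paste0("`", arg, "` row ", bad[1], " sums to ",
                 format(rs[bad[1]]), ", not 1"))
  }
  invisible(TRUE)
}

check_simplex <- function(p, tol = 1e-8, arg = "p") {
  if (any(p < -tol)) abort(paste0("`", arg, "` has negative entries"))
  if (abs(sum(p) - 1) > tol) {
    abort(paste0("`", arg, "` sums to ", format(sum(p)), ", not 1"))
  }
  invisible(TRUE)
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
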