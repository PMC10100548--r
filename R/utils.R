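# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this,
# so there is no hidden global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically maps a (global seed, stage name) pair to an integer seed
#' below 2^31, so that pipeline stages can be re-run in isolation while a
#' single global seed controls the whole run.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 2147483L) * 1000L + h) %% 2147483629L + 1L
}

abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a numeric data.frame as CSV at full double precision (%.17g round
# trips IEEE doubles exactly, unlike the default 15 significant digits)
write_csv_full_precision <- function(df, path) {
  cols <- lapply(df, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), lines), path)
}
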