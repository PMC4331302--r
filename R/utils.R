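# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Integer rounding with ties going up (0.5 -> 1), as used for the
#' conservation percentages in rendered specificity tables. Base R's
#' `round()` rounds half to even, which would print 50.5% as 50.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Write `lines` to `path` atomically: temp file in the same directory,
# then rename. Avoids truncated outputs on interrupt.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("nemapcr_user_error", "error")))
}

# Deterministic RNG scope: evaluates `expr` under `seed` and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
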