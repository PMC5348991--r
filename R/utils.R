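# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
.sn_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' @keywords internal
#' @noRd
.sn_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# single user-supplied seed makes a whole analysis reproducible without
# clobbering the session RNG.
#' @keywords internal
#' @noRd
.sn_with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from a master seed, each below 2^31, so
# independent stages (null sets, fixture parts) do not share RNG streams.
#' @keywords internal
#' @noRd
.sn_child_seeds <- function(seed, n) {
  .sn_with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @keywords internal
#' @noRd
.sn_assert_scalar_count <- function(x, name, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < minimum ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, minimum),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
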