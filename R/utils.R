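#' @keywords internal
#' @importFrom stats predict setNames runif rlnorm rgamma rmultinom sd
#' @importFrom utils read.csv write.csv
#' @importFrom graphics matplot legend
"_PACKAGE"

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points funnel their randomness through this helper so
# no global state leaks between calls.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_slrmig <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_slrmig(what, " is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Banker's rounding to whole persons, exposed where integer outputs are
# explicitly requested; populations are otherwise carried as nonnegative reals.
round_persons <- function(x) {
  round(x, 0)
}
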