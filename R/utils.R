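#' @keywords internal
"_PACKAGE"

# Stop with a consistent input-error class so callers (and the CLI) can
# distinguish bad input from internal failure.
input_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("combobench_input_error", "error")))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) input_error(msg)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a root seed
#'
#' All randomness in the package flows from one root seed; each pipeline
#' stage draws from its own substream so that adding a stage never perturbs
#' another stage's stream. The substream seed is a deterministic 31-bit hash
#' of the root seed and the stage name.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return an integer in [0, 2^31 - 1), usable with [set.seed()].
#' @export
substream_seed <- function(seed, stage) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  codes <- utf8ToInt(as.character(stage))
  h <- as.double(seed %% 2147483647)
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation of the BH step-up procedure (kept independent of
#' [stats::p.adjust()], which serves as the oracle in the test suite).
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && all(is.na(p) | (p >= 0 & p <= 1)),
              "p must be p-values in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  ord <- order(p, na.last = TRUE)
  ranked <- p[ord]
  q <- ranked * n / seq_len(n)
  # enforce monotonicity from the largest p downwards
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out[is.na(p)] <- NA_real_
  out
}
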