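#' @keywords internal
"_PACKAGE"

#' @useDynLib ccorganotrait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif dnorm var sd quantile t.test cor
#'   complete.cases setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed and a stage label
#'
#' All stochastic stages draw their seed from the run's single global seed
#' through this mixing function, keyed by a stage label, so that adding or
#' reordering stages does not reshuffle the randomness of unrelated stages.
#' The result is always a valid 32-bit seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label (or an integer index).
#' @return an integer in `[0, 2^31 - 1]` usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, "simulate") != child_seed(42, "classify")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.character(stage)) {
    h <- 0
    for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  } else {
    h <- as.numeric(stage) %% 2147483647
  }
  s <- (abs(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h * 69621 + 1) %% 2147483647)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate expr under a local RNG seed, restoring the caller's RNG state
# afterwards, so seeded package functions have no side effect on user code
# (e.g. permutation loops around run_classification_cv).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

#' Significance stars for a p-value
#'
#' Maps p-values to the conventional figure annotation: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, empty string otherwise (including
#' `NA`, which arises for degenerate contrasts).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}
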