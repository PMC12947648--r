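#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile qnorm pnorm qlnorm rexp runif rnorm rbinom
#'   plogis qlogis cor coef vcov pchisq setNames median sd complete.cases
#'   as.formula model.matrix cor.test quantile rlnorm optimize
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage draws from its own substream so that toggling one
#' stage cannot perturb the random numbers seen by another.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # cheap deterministic string hash (polynomial rolling, 31-bit)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1987654321
  as.integer(((abs(seed) %% 1000003) * 2038 + h) %% 2147483646) + 1L
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0
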