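#' @keywords internal
"_PACKAGE"

#' @importFrom stats ecdf ks.test median p.adjust pnorm ppois prcomp quantile
#'   rbinom rgamma rlnorm rmultinom rnorm runif var aov kruskal.test
#'   pairwise.wilcox.test wilcox.test phyper pt sd dist lowess approx fivenum
#'   rnbinom setNames complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

ss_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spikeshift_error")))
}

assert_that <- function(ok, msg, class = "spikeshift_parameter_error") {
  if (!isTRUE(ok)) ss_abort(msg, class)
  invisible(TRUE)
}

#' Package logging
#'
#' Every pipeline stage logs its input dimensions, applied scale factors and
#' random seed at INFO level.  Logging goes to `message()` and can be silenced
#' with `options(spikeshift.log_level = "WARN")` or `"NONE"`.
#'
#' @param ... passed to [sprintf()].
#' @param level one of `"INFO"`, `"WARN"`.
#' @return invisibly, the formatted message.
#' @keywords internal
ss_log <- function(..., level = "INFO") {
  threshold <- getOption("spikeshift.log_level", "INFO")
  ranks <- c(NONE = 3L, WARN = 2L, INFO = 1L)
  if (ranks[[threshold]] <= ranks[[level]]) {
    msg <- sprintf("[%s] %s", level, sprintf(...))
    message(msg)
    return(invisible(msg))
  }
  invisible(NULL)
}

# One master seed per experiment; per-sample child streams are derived by a
# fixed offset so samples are independent yet jointly reproducible.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647L)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

geometric_mean <- function(x) exp(mean(log(x)))
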