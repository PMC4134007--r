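#' @importFrom rlang abort warn inform .data
#' @importFrom stats qnorm plogis qlogis pnorm rnorm runif rbinom coef lm vcov
#'   cor ks.test p.adjust setNames complete.cases model.matrix
#' @importFrom utils head
NULL

# exact 97.5% normal quantile used for every Wald interval
z975 <- function() stats::qnorm(0.975)

# Run code with a temporary RNG state so package internals never disturb the
# caller's random stream. `seed` may be NULL (use current stream).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Named substreams derived from one master seed, kept below 2^31 so they are
# valid R integer seeds.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

stop_input <- function(msg, class) {
  rlang::abort(msg, class = c(class, "phewascan_error"))
}
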