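# Internal helpers shared across the package.

#' Avogadro constant (molecules per mole)
#'
#' Exact SI value, used to convert between protein mass and molecule counts.
#' @export
AVOGADRO <- 6.02214076e23

# Signal a classed error so callers/tests can discriminate failure modes.
ncp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ncp_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ncp_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "ncp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that they are
# pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Multiplicative log-normal noise with unit mean and coefficient of
# variation `cv`; cv = 0 returns exactly 1.
lognorm_noise <- function(n, cv) {
  if (cv < 0) ncp_stop("cv must be >= 0", "ncp_argument_error")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
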