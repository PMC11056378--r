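# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream, restoring the caller's RNG state.
# Used wherever an operation takes its own `seed` argument so that calling
# it does not perturb an enclosing simulation.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncated normal by inversion; exact, vectorised.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be non-negative")
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lower), upper))
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single probability in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_field(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

# Weighted mean / variance (frequency-style weights).
wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / (sum(w) - 1)
}
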