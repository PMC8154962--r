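#' Logit and inverse logit
#'
#' Convenience wrappers around [stats::qlogis()] and [stats::plogis()] used
#' throughout the package for moving between probabilities and log-odds.
#'
#' @param p Probability in (0, 1).
#' @param x Real value on the log-odds scale.
#' @return `logit()` returns log-odds; `inv_logit()` returns a probability.
#' @export
#' @examples
#' logit(0.024)
#' inv_logit(logit(0.024) + log(2.57))
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

# Round to nearest integer with ties away from zero (base round() halves to
# even, which would not reproduce conventional score weights).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate a function under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. All generator determinism
# contracts flow through this helper.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(code)
}

# Marginalize a linear predictor over a normal random intercept:
#   E_u[ inv_logit(eta + u) ],  u ~ N(0, sd^2)
# by Gauss-Hermite quadrature. Exact (degenerate) when sd == 0.
# `eta` may be a vector; returns a vector of the same length.
marginal_inv_logit <- function(eta, sd, nodes = 40) {
  stopifnot(sd >= 0, nodes >= 2)
  if (sd == 0) {
    return(inv_logit(eta))
  }
  gh <- pracma::gaussHermite(nodes)
  # change of variable u = sqrt(2) * sd * x
  vapply(eta, function(e) {
    sum(gh$w * inv_logit(e + sqrt(2) * sd * gh$x)) / sqrt(pi)
  }, numeric(1))
}

# Shared input check helpers -------------------------------------------------

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 ||
      (!allow_zero && x == 0) || (!allow_one && x == 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1] (got %s)",
                 name, format(x)), call. = FALSE)
  }
  invisible(x)
}

check_binary_outcome <- function(y, what = "outcomes") {
  if (!all(y %in% c(0, 1))) {
    stop(sprintf("%s must be coded 0/1", what), call. = FALSE)
  }
  if (all(y == 1)) stop(sprintf("all %s are events", what), call. = FALSE)
  if (all(y == 0)) stop(sprintf("no events among %s", what), call. = FALSE)
  invisible(y)
}
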