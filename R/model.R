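#' Rate parameters of the gap-aware two-parameter model
#'
#' Bundles the per-site per-unit-time rates of the continuous-time model in
#' which, besides transitions (rate `alpha`) and transversions (total rate
#' `2 * beta`), a nucleotide can be deleted (replaced by a gap, rate
#' `epsilon`) and a gap can be replaced by any of the four nucleotides
#' (total insertion rate `epsilon`, i.e. `epsilon / 4` per base).
#'
#' Only the products rate x time are identifiable from data, so `t` in the
#' downstream functions is dimensionless scaled time; "per year" is nominal.
#'
#' @param alpha transition rate (A<->G, C<->T), per site per unit time.
#' @param beta per-direction transversion rate; the total transversion rate
#'   is `2 * beta`.
#' @param epsilon total deletion rate, equal to the total insertion rate.
#' @param w probability that a site carries a nucleotide (rather than a gap)
#'   in the ancestral sequence; must lie in (0, 1].
#' @return An object of class `"rate_parameters"`: a named list with fields
#'   `alpha`, `beta`, `epsilon`, `w`.
#' @examples
#' rate_parameters(alpha = 0.1, beta = 0.05, epsilon = 0.02, w = 0.9)
#' @export
rate_parameters <- function(alpha, beta, epsilon, w = 1) {
  for (nm in c("alpha", "beta", "epsilon", "w")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  if (w <= 0 || w > 1) stop("'w' must lie in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon, w = w),
            class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat(sprintf(
    "Rate parameters: alpha = %g, beta = %g (total transversion %g), epsilon = %g, w = %g\n",
    x$alpha, x$beta, 2 * x$beta, x$epsilon, x$w))
  invisible(x)
}

as_rate_parameters <- function(params) {
  if (inherits(params, "rate_parameters")) return(params)
  if (is.list(params) || (is.numeric(params) && !is.null(names(params)))) {
    p <- as.list(params)
    return(rate_parameters(p$alpha, p$beta, p$epsilon,
                           if (is.null(p$w)) 1 else p$w))
  }
  stop("'params' must be created by rate_parameters()", call. = FALSE)
}

#' Total rate of nucleotide changes per site
#'
#' The model mixes nucleotide-carrying sites (which change by substitution or
#' deletion at rate `alpha + 2 beta + epsilon`) and gap sites (which change by
#' insertion at total rate `epsilon`), weighted by the nucleotide-existence
#' probability `w`:
#' \deqn{k = w(\alpha + 2\beta + \epsilon) + (1 - w)\epsilon.}
#'
#' @param params a [rate_parameters()] object.
#' @return The total change rate `k`, per site per unit time.
#' @examples
#' total_change_rate(rate_parameters(0.1, 0.05, 0.02, w = 0.9)) # 0.2
#' @export
total_change_rate <- function(params) {
  p <- as_rate_parameters(params)
  p$w * (p$alpha + 2 * p$beta + p$epsilon) + (1 - p$w) * p$epsilon
}

#' Expected number of changes separating two sequences
#'
#' Two lineages diverging for time `t` each accumulate `t * k` expected
#' changes per site, so the expected total is `K = 2 t k`.
#'
#' @inheritParams total_change_rate
#' @param t divergence time (time since the common ancestor); dimensionless
#'   scaled time.
#' @return Expected changes per site.
#' @export
expected_total_changes <- function(params, t) {
  if (!is.numeric(t) || any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  2 * t * total_change_rate(params)
}

new_pair_probabilities <- function(S, P, Q, G, N, t) {
  structure(list(S = S, P = P, Q = Q, G = G, N = N, t = t),
            class = "pair_probabilities")
}

#' @export
print.pair_probabilities <- function(x, ...) {
  cat(sprintf("Site-pair category probabilities at t = %g:\n", x$t))
  cat(sprintf("  S (identical)    %.6f\n  P (transition)   %.6f\n  Q (transversion) %.6f\n  G (nuc-gap)      %.6f\n  N (gap-gap)      %.6f\n",
              x$S, x$P, x$Q, x$G, x$N))
  invisible(x)
}

#' Closed-form site-pair category probabilities
#'
#' Probability that a homologous site pair in two sequences, `t` time units
#' after divergence from a common ancestor, shows identical nucleotides (S),
#' a transition-type pair (P), a transversion-type pair (Q), a
#' nucleotide--gap pair (G), or a gap--gap pair (N). These are the solutions
#' of the model's coupled linear differential equations with initial state
#' `S = w`, `N = 1 - w`, `P = Q = G = 0`; G is carried as the complement
#' `1 - S - P - Q - N` (the system determines it, no separate equation is
#' needed).
#'
#' @inheritParams expected_total_changes
#' @return A `"pair_probabilities"` object with fields `S`, `P`, `Q`, `G`,
#'   `N` (summing to 1) and `t`.
#' @seealso [ode_pair_probabilities()] for the numerical cross-check,
#'   [invert_rates()] for the inverse map.
#' @examples
#' pair_probabilities(rate_parameters(0.1, 0.05, 0.02, w = 0.9), t = 1)
#' @export
pair_probabilities <- function(params, t) {
  p <- as_rate_parameters(params)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("'t' must be a single finite number >= 0", call. = FALSE)
  e_eps  <- exp(-2 * p$epsilon * t)
  e_eps2 <- exp(-4 * p$epsilon * t)
  e_a    <- exp(-2 * (2 * p$alpha + 2 * p$beta + p$epsilon) * t)
  e_b    <- exp(-2 * (4 * p$beta + p$epsilon) * t)
  gap_core <- 1 + e_eps2 - 2 * e_eps          # shared indel-only bracket
  S <- gap_core / 16 + p$w / 4 * (e_eps + 2 * e_a + e_b)
  P <- gap_core / 16 + p$w / 4 * (e_eps - 2 * e_a + e_b)
  Q <- gap_core / 8  + p$w / 2 * (e_eps - e_b)
  N <- (1 + e_eps2 + 2 * e_eps) / 4 - p$w * e_eps
  G <- 1 - S - P - Q - N
  new_pair_probabilities(S, P, Q, G, N, t)
}

#' Site-pair category probabilities by numerical integration
#'
#' Integrates the model's four coupled linear difference/differential
#' equations for (S, P, Q, N) from the initial state `(w, 0, 0, 1 - w)` with
#' fixed-step classical Runge-Kutta (`deSolve::rk4`), tracking G as the
#' complement. The derivative function is written directly from the rate
#' diagram, independently of the closed forms, so this routine serves as a
#' numerical oracle for [pair_probabilities()].
#'
#' @inheritParams expected_total_changes
#' @param step integration step; defaults to
#'   `1e-3 / (alpha + 2 beta + epsilon + 1)` so that the O(step^4) truncation
#'   error is far below 1e-8.
#' @return A `"pair_probabilities"` object.
#' @export
ode_pair_probabilities <- function(params, t, step = NULL) {
  p <- as_rate_parameters(params)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("'t' must be a single finite number >= 0", call. = FALSE)
  if (is.null(step)) step <- 1e-3 / (p$alpha + 2 * p$beta + p$epsilon + 1)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a single number > 0", call. = FALSE)
  rate_scale <- p$alpha + 2 * p$beta + p$epsilon
  if (rate_scale > 0 && step > 0.5 / rate_scale)
    stop("integration step too large for stability: step must be << 1/(alpha + 2 beta + epsilon)",
         call. = FALSE)
  y0 <- c(S = p$w, P = 0, Q = 0, N = 1 - p$w)
  if (t == 0)
    return(new_pair_probabilities(p$w, 0, 0, 0, 1 - p$w, 0))
  deriv <- function(time, y, parms) {
    G <- 1 - y[["S"]] - y[["P"]] - y[["Q"]] - y[["N"]]
    a <- parms$alpha; b <- parms$beta; e <- parms$epsilon
    dS <- -2 * (a + 2 * b + e) * y[["S"]] + 2 * a * y[["P"]] +
      2 * b * y[["Q"]] + e / 4 * G
    dP <- -2 * (a + 2 * b + e) * y[["P"]] + 2 * a * y[["S"]] +
      2 * b * y[["Q"]] + e / 4 * G
    dQ <- -2 * (2 * b + e) * y[["Q"]] + 4 * b * y[["P"]] +
      4 * b * y[["S"]] + e / 2 * G
    dN <- -2 * e * y[["N"]] + e * G
    list(c(dS, dP, dQ, dN))
  }
  n_steps <- max(1L, ceiling(t / step))
  times <- seq(0, t, length.out = n_steps + 1L)
  out <- deSolve::rk4(y0, times, deriv, parms = p)
  last <- out[nrow(out), ]
  S <- last[["S"]]; P <- last[["P"]]; Q <- last[["Q"]]; N <- last[["N"]]
  new_pair_probabilities(S, P, Q, N = N, G = 1 - S - P - Q - N, t = t)
}

#' Recover rate-time products from site-pair proportions
#'
#' Inverts the closed-form category probabilities: given observed (or exact)
#' proportions of identical (S), transition (P), transversion (Q) and
#' gap--gap (N) site pairs, together with the ancestral nucleotide-existence
#' probability `w`, returns the products `alpha * t`, `beta * t` and
#' `epsilon * t` (natural logarithms throughout):
#' \deqn{\alpha t = \tfrac18 \log\frac{w(P - Q + S)(P + Q + S - N)}
#'   {(2w - 1)(S - P)^2}, \quad
#'   \beta t = \tfrac18 \log\frac{w(P + Q + S - N)}{(2w - 1)(P - Q + S)},
#'   \quad
#'   \epsilon t = \tfrac12 \log\frac{2w - 1}{P + Q + S - N}.}
#'
#' The map is only defined for `w > 1/2` and while every logarithm argument
#' is positive; beyond that boundary the proportions are saturated and the
#' divergence is not recoverable.
#'
#' @param obs a `"pair_probabilities"` object, or a named list/vector with
#'   components `S`, `P`, `Q`, `N`.
#' @param w ancestral nucleotide-existence probability, in (1/2, 1].
#' @return Named numeric vector `c(alpha_t, beta_t, epsilon_t)`.
#' @examples
#' pr <- pair_probabilities(rate_parameters(0.1, 0.05, 0.02, w = 0.9), t = 2)
#' invert_rates(pr, w = 0.9) # ~ c(0.2, 0.1, 0.04)
#' @export
invert_rates <- function(obs, w) {
  if (!is.numeric(w) || length(w) != 1L || w <= 0.5 || w > 1)
    stop("'w' must lie in (1/2, 1]", call. = FALSE)
  o <- as.list(obs)
  for (nm in c("S", "P", "Q", "N"))
    if (is.null(o[[nm]]) || !is.finite(o[[nm]]))
      stop("'obs' must supply finite components S, P, Q, N", call. = FALSE)
  S <- o$S; P <- o$P; Q <- o$Q; N <- o$N
  d1 <- S - P            # e^{-2(2a+2b+e)t} * w
  d2 <- P - Q + S        # related to e^{-2(4b+e)t}
  d3 <- P + Q + S - N    # (2w-1) e^{-2 e t}
  if (d1 <= 0 || d2 <= 0 || d3 <= 0)
    stop("saturation: observed proportions are outside the invertible domain ",
         "(need S - P > 0, P - Q + S > 0, P + Q + S - N > 0)", call. = FALSE)
  alpha_t   <- log(w * d2 * d3 / ((2 * w - 1) * d1^2)) / 8
  beta_t    <- log(w * d3 / ((2 * w - 1) * d2)) / 8
  epsilon_t <- log((2 * w - 1) / d3) / 2
  c(alpha_t = alpha_t, beta_t = beta_t, epsilon_t = epsilon_t)
}
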