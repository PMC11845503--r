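#' Initialise a Beta belief from a mean and variance
#'
#' The belief over expected success on a task is a Beta(a, b) distribution.
#' Rather than fitting \code{a0} and \code{b0} directly, the model
#' parameterises the initial belief by its mean \code{mu0} and variance
#' \code{v0}, which maps to shape parameters via
#' \deqn{a_0 = (\mu_0 / v_0)(\mu_0 - \mu_0^2 - v_0), \quad
#'       b_0 = ((1 - \mu_0) / v_0)(\mu_0 - \mu_0^2 - v_0).}
#' The variance of a Beta distribution with mean \eqn{\mu} is bounded above
#' by \eqn{\mu(1 - \mu)}; values at or beyond the bound are rejected.
#'
#' @param mu0 Initial belief mean, in (0, 1).
#' @param v0 Initial belief variance, in (0, mu0 * (1 - mu0)).
#' @return A \code{belief_state}: list with positive fields \code{a}, \code{b}.
#' @examples
#' init_belief(0.5, 0.05)  # Beta(2, 2)
#' @export
init_belief <- function(mu0, v0) {
  if (!is.finite(mu0) || mu0 <= 0 || mu0 >= 1)
    stop("'mu0' must lie strictly inside (0, 1)")
  if (!is.finite(v0) || v0 <= 0 || v0 >= mu0 * (1 - mu0))
    stop("'v0' must lie in (0, mu0*(1-mu0)); got v0 = ", v0,
         " with bound ", mu0 * (1 - mu0))
  k <- mu0 - mu0^2 - v0
  belief_state(a = mu0 / v0 * k, b = (1 - mu0) / v0 * k)
}

#' Construct a Beta belief state
#'
#' @param a,b Positive Beta shape parameters.
#' @return An object of class \code{belief_state}.
#' @export
belief_state <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("belief shape parameters must be finite and > 0")
  structure(list(a = a, b = b), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state> Beta(a = %.4g, b = %.4g), mean = %.4g\n",
              x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' Update a belief from a feedback event
#'
#' On feedback trials the belief is updated like a Beta-Bernoulli posterior,
#' but with a valence asymmetry \code{dlr_f}: correct feedback increments
#' \code{a} by \code{1 + dlr_f}, incorrect feedback increments \code{b} by
#' \code{1 - dlr_f}. With \code{dlr_f = 0} this is the symmetric baseline
#' update (a unit pseudo-count on the observed outcome).
#'
#' @param state A \code{belief_state}.
#' @param correct Logical; was the trial signalled as correct?
#' @param dlr_f Feedback learning-rate asymmetry, in (-1, 1).
#' @return The updated \code{belief_state}.
#' @export
update_feedback <- function(state, correct, dlr_f = 0) {
  stopifnot(inherits(state, "belief_state"), is.logical(correct) || correct %in% c(0, 1))
  if (!is.finite(dlr_f) || dlr_f <= -1 || dlr_f >= 1)
    stop("'dlr_f' must lie strictly inside (-1, 1)")
  if (isTRUE(as.logical(correct)))
    belief_state(state$a + (1 + dlr_f), state$b)
  else
    belief_state(state$a, state$b + (1 - dlr_f))
}

#' Update a belief from a local confidence report
#'
#' On no-feedback trials the confidence report (a subjective probability
#' correct in [0, 1]) stands in for the unobserved outcome: \code{a} gains
#' \code{conf * (1 + dlr_c)} and \code{b} gains
#' \code{(1 - conf) * (1 - dlr_c)}. With \code{dlr_c = 0} the two increments
#' sum to exactly 1 per trial; a positive \code{dlr_c} overweights
#' high-confidence evidence and a negative value overweights low-confidence
#' evidence.
#'
#' @param state A \code{belief_state}.
#' @param conf Local confidence in [0, 1].
#' @param dlr_c Confidence learning-rate asymmetry, in (-1, 1).
#' @return The updated \code{belief_state}.
#' @export
update_confidence <- function(state, conf, dlr_c = 0) {
  stopifnot(inherits(state, "belief_state"))
  if (!is.finite(conf) || conf < 0 || conf > 1)
    stop("'conf' must lie in [0, 1]")
  if (!is.finite(dlr_c) || dlr_c <= -1 || dlr_c >= 1)
    stop("'dlr_c' must lie strictly inside (-1, 1)")
  belief_state(state$a + conf * (1 + dlr_c),
               state$b + (1 - conf) * (1 - dlr_c))
}

#' Mean of a Beta belief
#'
#' @param state A \code{belief_state}.
#' @return \code{a / (a + b)}, the model's point prediction for the global
#'   self-performance estimate.
#' @export
belief_mean <- function(state) {
  stopifnot(inherits(state, "belief_state"))
  state$a / (state$a + state$b)
}

#' Apply a report bias to a belief and return the predicted SPE
#'
#' Under the response-bias distortion the reported global SPE is shifted
#' from the belief mean by \code{beta_a * mh}. The shifted prediction is
#' clipped to (0.001, 0.999) so it remains a valid proportion.
#'
#' @param state A \code{belief_state}.
#' @param params A \code{model_params} object (see [model_params()]).
#' @param spec A \code{distortion_spec}; variants without a free
#'   response-bias slope force \code{beta_a = 0}.
#' @param mh Mental-health (symptom) score of the participant.
#' @return Predicted SPE in (0, 1).
#' @export
predicted_spe <- function(state, params, spec = distortion_spec("D0"), mh = 0) {
  beta_a <- if (spec$free["beta_a"]) params$beta_a else 0
  clip01(belief_mean(state) + beta_a * mh, 0.001, 0.999)
}

# shift the Beta mean while preserving total concentration a + b; used to
# evaluate the report-bias likelihood without leaving the Beta family
bias_shift_belief <- function(state, beta_a, mh) {
  if (beta_a == 0 || mh == 0) return(state)
  n <- state$a + state$b
  m <- clip01(state$a / n + beta_a * mh, 0.001, 0.999)
  belief_state(m * n, (1 - m) * n)
}

#' Beta log-likelihood of an observed global SPE
#'
#' The observed end-of-block SPE is scored against the block-final belief
#' \code{Beta(a, b)}, after the report-bias shift (if the active distortion
#' variant frees \code{beta_a}). Observations exactly at 0 or 1 have no
#' density under a Beta law and must be mapped into the open interval first
#' (see [spe_boundary_transform()]).
#'
#' @param spe Observed SPE, strictly inside (0, 1).
#' @param state Block-final \code{belief_state}.
#' @inheritParams predicted_spe
#' @return Finite Beta log-density.
#' @export
spe_loglik <- function(spe, state, params = NULL, spec = distortion_spec("D0"), mh = 0) {
  if (any(spe <= 0 | spe >= 1))
    stop("observed SPE must be strictly inside (0, 1); apply ",
         "spe_boundary_transform() first")
  beta_a <- if (!is.null(params) && spec$free["beta_a"]) params$beta_a else 0
  st <- bias_shift_belief(state, beta_a, mh)
  stats::dbeta(spe, st$a, st$b, log = TRUE)
}

#' Map bounded proportions off the {0, 1} boundary
#'
#' Standard compression for bounded responses:
#' \code{(x * (n - 1) + 0.5) / n}, with \code{n} the number of observations.
#' Keeps interior values almost unchanged while giving boundary reports a
#' finite Beta density.
#'
#' @param x Numeric vector of proportions in [0, 1].
#' @param n Number of observations; defaults to \code{length(x)}.
#' @return Values strictly inside (0, 1).
#' @export
spe_boundary_transform <- function(x, n = length(x)) {
  stopifnot(n >= 1, all(x >= 0 & x <= 1))
  (x * (n - 1) + 0.5) / n
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
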