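#' Pairwise interaction probability
#'
#' The probability that two paired individuals actually interact is the
#' product of the interaction tendencies of both partners: for a mixed
#' pair `X_ir = x_ir * x_ri`, for same-type pairs `X_ii = x_ii^2` and
#' `X_rr = x_rr^2`. The result is symmetric in the two type arguments.
#'
#' @param type_a,type_b Cultural types, `"R"` or `"I"`.
#' @param params A [model_params()] object.
#' @return A probability in \[0, 1\].
#' @examples
#' p <- model_params(100, 0.01,
#'                   resident  = orientation(0.5, x_other = 0.2),
#'                   immigrant = orientation(0.5, x_other = 0.5))
#' interaction_probability("I", "R", p)  # 0.5 * 0.2 = 0.1
#' @export
interaction_probability <- function(type_a, type_b, params) {
  .check_type(type_a)
  .check_type(type_b)
  if (type_a == type_b) {
    o <- if (type_a == "R") params$resident else params$immigrant
    o$x_same^2
  } else {
    params$immigrant$x_other * params$resident$x_other
  }
}

#' Perceived frequency of a cultural type
#'
#' Individuals do not know the true population constitution; they
#' perceive the frequency of each trait as the frequency with which they
#' encounter it in realised interactions. For an observer of type y and
#' an observed type x != y this is the conditional probability
#'
#' \deqn{p_{x|y} = \frac{p_x X_{xy}}{p_x X_{xy} + (1 - p_x) X_{yy}}}
#'
#' that the observer's realised partner is of type x. The same-type
#' perception is by default the complement of the cross-type one
#' (`p_{r|r} = 1 - p_{i|r}`), which keeps the two perceptions a
#' conditional probability distribution over partner types. Setting
#' `literal_perception = TRUE` in [model_params()] instead applies the
#' cross-type formula literally with x = y, which collapses to the true
#' frequency.
#'
#' When all relevant interaction probabilities are equal, perception
#' equals truth.
#'
#' @param observed Type whose frequency is perceived (`"R"` or `"I"`).
#' @param observer Type of the perceiving individual.
#' @param p_i True frequency of type I, in \[0, 1\].
#' @param params A [model_params()] object.
#' @return A frequency in \[0, 1\]. Signals an error if the observer's
#'   total encounter rate is exactly zero (perception undefined).
#' @export
perceived_frequency <- function(observed, observer, p_i, params) {
  .check_type(observed)
  .check_type(observer)
  .check_prob(p_i, "p_i")
  if (observed == observer) {
    if (params$literal_perception) {
      # literal reading: both denominator terms carry X_yy, so the
      # encounter-rate weighting cancels and perception equals truth
      p_x <- if (observed == "I") p_i else 1 - p_i
      X_yy <- interaction_probability(observer, observer, params)
      X_xy <- X_yy
      denom <- p_x * X_xy + (1 - p_x) * X_yy
      if (denom == 0) {
        stop("perceived frequency undefined: observer of type ", observer,
             " has zero total encounter rate", call. = FALSE)
      }
      return(p_x * X_xy / denom)
    }
    other <- if (observed == "R") "I" else "R"
    return(1 - perceived_frequency(other, observer, p_i, params))
  }
  p_x <- if (observed == "I") p_i else 1 - p_i
  X_xy <- interaction_probability(observed, observer, params)
  X_yy <- interaction_probability(observer, observer, params)
  denom <- p_x * X_xy + (1 - p_x) * X_yy
  if (denom == 0) {
    stop("perceived frequency undefined: observer of type ", observer,
         " has zero total encounter rate", call. = FALSE)
  }
  p_x * X_xy / denom
}

#' Success-bias factor of the changing probability
#'
#' The changing bias is an increasing S-shaped (logistic) function of the
#' payoff difference between the partner's trait and the own trait, seen
#' from the focal individual's perspective:
#' \deqn{\mathrm{bias}(\Delta) = \frac{2}{1 + e^{-\Delta}}}
#' It ranges over (0, 2), equals 1 when payoffs are equal (so the
#' changing probability reduces to `1 - c`), and is strictly increasing.
#'
#' @param delta_W Payoff advantage of the other type over the focal's own
#'   type (finite numeric, vectorised).
#' @return Values in (0, 2).
#' @export
changing_bias <- function(delta_W) {
  stopifnot(is.numeric(delta_W), all(is.finite(delta_W)))
  2 / (1 + exp(-delta_W))
}

#' Trait payoffs at a given population state
#'
#' Returns the payoffs `(W_r, W_i)` of the two traits under the payoff
#' scenario in `params`. Under `"baseline"` both are 0; under the
#' constant-advantage scenarios the superior trait earns `W0` and the
#' other 0. Under `"coordination"` each trait earns `W0` times its own
#' perceived frequency (`W_r = W0 * p_{r|r}`, `W_i = W0 * p_{i|i}`);
#' under `"complementation"` each earns `W0` times the perceived
#' frequency of the opposite trait (`W_r = W0 * p_{i|r}`,
#' `W_i = W0 * p_{r|i}`).
#'
#' @param p_i Frequency of type I, in \[0, 1\].
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(W_r = , W_i = )`.
#' @export
trait_payoffs <- function(p_i, params) {
  .check_prob(p_i, "p_i")
  W0 <- params$payoff$W0
  switch(params$payoff$scenario,
    baseline = c(W_r = 0, W_i = 0),
    resident_advantage = c(W_r = W0, W_i = 0),
    immigrant_advantage = c(W_r = 0, W_i = W0),
    coordination = c(
      W_r = W0 * perceived_frequency("R", "R", p_i, params),
      W_i = W0 * perceived_frequency("I", "I", p_i, params)
    ),
    complementation = c(
      W_r = W0 * perceived_frequency("I", "R", p_i, params),
      W_i = W0 * perceived_frequency("R", "I", p_i, params)
    )
  )
}

#' Probability of changing cultural trait in a cross-type interaction
#'
#' The changing probability is the product of the focal individual's
#' willingness to change (`1 - c`) and its success bias
#' ([changing_bias()]) evaluated at the payoff advantage of the partner's
#' trait: with `dW = W_r - W_i`,
#' \deqn{S_i = (1 - c_i)\,\frac{2}{1 + e^{-\Delta W}}, \qquad
#'       S_r = (1 - c_r)\,\frac{2}{1 + e^{\Delta W}}.}
#'
#' The raw value is returned; since the bias ranges up to 2 it can exceed
#' 1 (e.g. `c = 0`, `dW = 1` gives 1.462...). The mean-field engine uses
#' the raw value, which keeps the closed-form equilibria exact; the
#' stochastic simulator clamps the per-event probability to `min(S, 1)`
#' and counts clamping events.
#'
#' @param focal Type of the focal individual (`"R"` or `"I"`).
#' @param p_i Frequency of type I, in \[0, 1\].
#' @param params A [model_params()] object.
#' @return Non-negative numeric (possibly above 1).
#' @export
changing_probability <- function(focal, p_i, params) {
  .check_type(focal)
  W <- trait_payoffs(p_i, params)
  dW <- W[["W_r"]] - W[["W_i"]]
  if (focal == "I") {
    (1 - params$immigrant$conservatism) * changing_bias(dW)
  } else {
    (1 - params$resident$conservatism) * changing_bias(-dW)
  }
}

#' Difference between the changing probabilities of the two types
#'
#' `delta_S(p) = S_r - S_i`, the net per-interaction rate at which
#' cross-type interactions move the type-I frequency upward. Under the
#' baseline scenario it is constant in `p_i` and equals `c_i - c_r`
#' (i.e. minus the conservatism difference).
#'
#' @inheritParams changing_probability
#' @return Numeric in (-2, 2).
#' @export
delta_S <- function(p_i, params) {
  changing_probability("R", p_i, params) -
    changing_probability("I", p_i, params)
}
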