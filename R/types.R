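#' Cultural type labels
#'
#' The model distinguishes exactly two cultural traits: `"R"`, the trait
#' initially carried by every resident, and `"I"`, the trait carried by
#' every arriving immigrant. Every individual carries exactly one of the
#' two at any time.
#'
#' @format Character vector of length 2.
#' @export
cultural_types <- c("R", "I")

.check_type <- function(type, arg = deparse(substitute(type))) {
  if (!(is.character(type) && length(type) == 1L && type %in% cultural_types)) {
    stop(sprintf("`%s` must be one of \"R\", \"I\"", arg), call. = FALSE)
  }
  type
}

.check_prob <- function(x, arg, open_left = FALSE, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    lo <- if (open_left) "(0" else "[0"
    hi <- if (open_right) "1)" else "1]"
    stop(sprintf("`%s` must be a single number in %s, %s", arg, lo, hi),
         call. = FALSE)
  }
  x
}

#' Acculturation orientation of a cultural type
#'
#' Bundles the three per-type behavioural parameters: the degree of
#' cultural conservatism `c` (probability of retaining the own trait in a
#' cross-type interaction), the interaction tendency toward individuals of
#' the same type, and the interaction tendency toward the other type. The
#' realised probability that a pair actually interacts is the product of
#' both partners' tendencies, see [interaction_probability()].
#'
#' @param conservatism Cultural conservatism, a probability in \[0, 1\].
#'   Fully conservative individuals (`conservatism = 1`) never change
#'   their trait.
#' @param x_same Interaction tendency toward individuals of the own type,
#'   in \[0, 1\].
#' @param x_other Interaction tendency toward individuals of the other
#'   type, in \[0, 1\].
#' @return An object of class `"orientation"`.
#' @examples
#' # an "integration" orientation: conservative but open to contact
#' orientation(conservatism = 0.9, x_same = 1, x_other = 1)
#' @export
orientation <- function(conservatism, x_same = 1, x_other = 1) {
  structure(
    list(
      conservatism = .check_prob(conservatism, "conservatism"),
      x_same = .check_prob(x_same, "x_same"),
      x_other = .check_prob(x_other, "x_other")
    ),
    class = "orientation"
  )
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf("<orientation> c = %g, x_same = %g, x_other = %g\n",
              x$conservatism, x$x_same, x$x_other))
  invisible(x)
}

#' Payoff scenarios
#'
#' Names of the five payoff regimes: `"baseline"` (traits are payoff
#' neutral), `"resident_advantage"` / `"immigrant_advantage"` (one trait
#' has a constant payoff advantage of `W0`), and `"coordination"` /
#' `"complementation"` (a trait's payoff is `W0` times its perceived
#' frequency, respectively `W0` times the perceived frequency of the
#' other trait).
#'
#' @format Character vector of length 5.
#' @export
payoff_scenarios <- c("baseline", "resident_advantage", "immigrant_advantage",
                      "coordination", "complementation")

#' Payoff specification
#'
#' @param scenario One of [payoff_scenarios].
#' @param W0 Superior (or base) payoff magnitude; must be positive for all
#'   non-baseline scenarios and is ignored under `"baseline"` (the
#'   inferior payoff is always 0).
#' @return An object of class `"payoff_spec"`.
#' @export
payoff_spec <- function(scenario = payoff_scenarios, W0 = 1) {
  scenario <- match.arg(scenario)
  if (scenario != "baseline") {
    if (!(is.numeric(W0) && length(W0) == 1L && is.finite(W0) && W0 > 0)) {
      stop("`W0` must be a single positive number for scenario \"",
           scenario, "\"", call. = FALSE)
    }
  }
  structure(list(scenario = scenario, W0 = W0), class = "payoff_spec")
}

#' Complete model parameterisation
#'
#' @param N Population size (integer, at least 2: a focal individual must
#'   be able to find a partner).
#' @param m Migration rate: the probability that a time step is an
#'   immigration event rather than an interaction event. Must lie strictly
#'   between 0 and 1 (at `m = 1` no interactions ever occur; the model
#'   only considers positive migration).
#' @param resident [orientation()] linked to the resident trait R.
#' @param immigrant [orientation()] linked to the immigrant trait I.
#' @param payoff A [payoff_spec()].
#' @param literal_perception If `TRUE`, the same-type perceived frequency is
#'   computed by applying the cross-type conditional-probability formula
#'   literally with both types equal (which collapses to the true
#'   frequency); the default `FALSE` uses the complement of the cross-type
#'   perception, preserving the conditional-probability interpretation.
#'   See [perceived_frequency()].
#' @return An object of class `"model_params"`.
#' @examples
#' model_params(N = 1000, m = 0.01,
#'              resident  = orientation(0.6, x_other = sqrt(0.5)),
#'              immigrant = orientation(0.1, x_other = sqrt(0.5)))
#' @export
model_params <- function(N, m, resident, immigrant,
                         payoff = payoff_spec("baseline"),
                         literal_perception = FALSE) {
  if (!(is.numeric(N) && length(N) == 1L && is.finite(N) && N >= 2 &&
        N == round(N))) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  .check_prob(m, "m", open_left = TRUE, open_right = TRUE)
  if (!inherits(resident, "orientation")) {
    stop("`resident` must be an orientation()", call. = FALSE)
  }
  if (!inherits(immigrant, "orientation")) {
    stop("`immigrant` must be an orientation()", call. = FALSE)
  }
  if (!inherits(payoff, "payoff_spec")) {
    stop("`payoff` must be a payoff_spec()", call. = FALSE)
  }
  structure(
    list(N = as.integer(N), m = m, resident = resident,
         immigrant = immigrant, payoff = payoff,
         literal_perception = isTRUE(literal_perception)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> N = %d, m = %g, scenario = %s",
              x$N, x$m, x$payoff$scenario))
  if (x$payoff$scenario != "baseline") cat(sprintf(", W0 = %g", x$payoff$W0))
  cat("\n  resident : ")
  cat(sprintf("c = %g, x_same = %g, x_other = %g\n",
              x$resident$conservatism, x$resident$x_same, x$resident$x_other))
  cat("  immigrant: ")
  cat(sprintf("c = %g, x_same = %g, x_other = %g\n",
              x$immigrant$conservatism, x$immigrant$x_same,
              x$immigrant$x_other))
  invisible(x)
}

#' Build model parameters from pairwise interaction probabilities
#'
#' Convenience constructor used throughout the sweep drivers: instead of
#' per-individual interaction tendencies it takes the realised pairwise
#' interaction probabilities `X_ir`, `X_ii`, `X_rr` directly and assigns
#' each type the symmetric tendency `sqrt(X)`. The mean-field dynamics
#' depend on the tendencies only through these products, so this loses no
#' generality at the level of the frequency dynamics.
#'
#' @param N,m Population size and migration rate, as in [model_params()].
#' @param c_r,c_i Cultural conservatism of the resident and immigrant
#'   types.
#' @param X_ir Interaction probability between a type-I and a type-R
#'   individual.
#' @param X_ii,X_rr Same-type interaction probabilities (default 1).
#' @param scenario,W0 Payoff regime, see [payoff_spec()].
#' @param literal_perception See [model_params()].
#' @return A [model_params()] object.
#' @export
params_from_X <- function(N, m, c_r, c_i, X_ir, X_ii = 1, X_rr = 1,
                          scenario = "baseline", W0 = 1,
                          literal_perception = FALSE) {
  .check_prob(X_ir, "X_ir")
  .check_prob(X_ii, "X_ii")
  .check_prob(X_rr, "X_rr")
  model_params(
    N = N, m = m,
    resident  = orientation(c_r, x_same = sqrt(X_rr), x_other = sqrt(X_ir)),
    immigrant = orientation(c_i, x_same = sqrt(X_ii), x_other = sqrt(X_ir)),
    payoff = payoff_spec(scenario, W0),
    literal_perception = literal_perception
  )
}

# Flat scalar view of a parameter set; precomputed once per hot path.
.param_scalars <- function(params) {
  list(
    N = params$N,
    m = params$m,
    c_r = params$resident$conservatism,
    c_i = params$immigrant$conservatism,
    X_rr = params$resident$x_same^2,
    X_ii = params$immigrant$x_same^2,
    X_ir = params$immigrant$x_other * params$resident$x_other,
    scenario = params$payoff$scenario,
    W0 = params$payoff$W0,
    literal_perception = params$literal_perception
  )
}
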