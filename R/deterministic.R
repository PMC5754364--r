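#' Mean-field drift of the immigrant-trait frequency
#'
#' The deterministic model tracks the frequency `p_i` of the immigrant
#' trait through the differential equation
#' \deqn{\frac{dp_i}{dt} = \frac{1}{N}\Big[m (1 - p_i) +
#'   (1 - m)(1 - p_i)\, p_i\, X_{ir}\, \Delta S(p_i)\Big],}
#' whose first term is the inflow of type-I individuals through
#' immigration and whose second term is the net effect of cross-type
#' interactions. Algebraically this equals
#' `(1/N) (1 - m)(1 - p_i) (M - psi(p_i))` with `M = m/(1-m)`, which is
#' the form used by the equilibrium condition.
#'
#' The raw (unclamped) changing probabilities are used, so the
#' closed-form equilibria hold exactly.
#'
#' @param p_i Frequency of type I; vectorised over \[0, 1\].
#' @param params A [model_params()] object.
#' @return `dp_i/dt`, same length as `p_i`.
#' @export
drift <- function(p_i, params) {
  stopifnot(is.numeric(p_i), all(p_i >= 0 & p_i <= 1))
  sc <- .param_scalars(params)
  vapply(p_i, function(p) {
    ds <- delta_S(p, params)
    (sc$m * (1 - p) + (1 - sc$m) * (1 - p) * p * sc$X_ir * ds) / sc$N
  }, numeric(1))
}

#' Migration-to-interaction odds
#'
#' `M = m / (1 - m)`: the ratio of the probability of a migration event
#' to the probability of an interaction event. Internal equilibria of the
#' mean-field model satisfy `M = psi(p_i)`.
#'
#' @param m Migration rate in \[0, 1); `m = 1` is rejected (no
#'   interaction events would remain).
#' @return Non-negative numeric; strictly increasing in `m`.
#' @export
migration_odds <- function(m) {
  stopifnot(is.numeric(m), all(m >= 0), all(m < 1))
  m / (1 - m)
}

#' Interaction side of the equilibrium condition
#'
#' \deqn{\Psi(p_i) = -\, p_i\, X_{ir}\, \Delta S(p_i).}
#' An internal equilibrium exists wherever `psi(p_i)` equals the
#' migration odds `M = m/(1-m)`. Under the baseline scenario `psi`
#' is the straight line `p_i * X_ir * (c_r - c_i)`.
#'
#' @param p_i Frequency of type I; vectorised over \[0, 1\].
#' @param params A [model_params()] object.
#' @return Numeric, same length as `p_i`.
#' @export
psi <- function(p_i, params) {
  stopifnot(is.numeric(p_i), all(p_i >= 0 & p_i <= 1))
  sc <- .param_scalars(params)
  vapply(p_i, function(p) -p * sc$X_ir * delta_S(p, params), numeric(1))
}

.equilibrium_set <- function(p_star, kind, stability, method) {
  ord <- order(p_star)
  structure(
    data.frame(p_star = p_star[ord], kind = kind[ord],
               stability = stability[ord], stringsAsFactors = FALSE),
    method = method,
    class = c("equilibrium_set", "data.frame")
  )
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("<equilibrium_set> method = %s\n", attr(x, "method")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Closed-form equilibria of the baseline model
#'
#' Without payoff differences the model has the fixation equilibrium
#' `p_i* = 1` and, when the existence condition
#' \deqn{\frac{m}{1-m} < \Delta c \cdot X_{ir}}
#' holds (which requires the residents to be the more conservative type,
#' `delta_c = c_r - c_i > 0`), an internal coexistence equilibrium at
#' \deqn{p_i^* = \frac{m}{1-m}\cdot\frac{1}{\Delta c}\cdot\frac{1}{X_{ir}}.}
#' The internal equilibrium, when it exists, is stable and fixation is
#' unstable; otherwise fixation is the only (stable) equilibrium. The
#' boundary `p_i = 0` is never an equilibrium since immigration keeps
#' `drift(0) = m/N > 0`.
#'
#' @param params A [model_params()] with a `"baseline"` payoff scenario.
#' @return An `equilibrium_set` data frame (columns `p_star`, `kind`,
#'   `stability`), ascending in `p_star`, with attribute
#'   `method = "closed_form"`.
#' @export
baseline_equilibria <- function(params) {
  if (params$payoff$scenario != "baseline") {
    stop("baseline_equilibria() requires the \"baseline\" scenario; got \"",
         params$payoff$scenario, "\"", call. = FALSE)
  }
  sc <- .param_scalars(params)
  delta_c <- sc$c_r - sc$c_i
  M <- migration_odds(sc$m)
  if (delta_c > 0 && sc$X_ir > 0 && M < delta_c * sc$X_ir) {
    p_int <- M / (delta_c * sc$X_ir)
    .equilibrium_set(c(p_int, 1),
                     c("internal", "fixation"),
                     c("stable", "unstable"),
                     "closed_form")
  } else {
    .equilibrium_set(1, "fixation", "stable", "closed_form")
  }
}

#' Closed-form equilibria under a constant payoff advantage
#'
#' When one trait has a fixed payoff advantage `W0`, the payoff
#' difference `dW = W_r - W_i` equals `+W0` (resident advantage) or
#' `-W0` (immigrant advantage), making `delta_S` constant in `p_i`.
#' The internal equilibrium
#' \deqn{p_i^* = -\frac{m}{1-m}\cdot\frac{1}{\Delta S}\cdot
#'   \frac{1}{X_{ir}}}
#' exists and is stable iff `m/(1-m) < -delta_S * X_ir`; otherwise the
#' immigrant trait fixes. In the limit `W0 -> 0` this reduces to
#' [baseline_equilibria()].
#'
#' @param params A [model_params()] with scenario `"resident_advantage"`
#'   or `"immigrant_advantage"`.
#' @return An `equilibrium_set`, as [baseline_equilibria()].
#' @export
constant_payoff_equilibria <- function(params) {
  scen <- params$payoff$scenario
  if (!scen %in% c("resident_advantage", "immigrant_advantage")) {
    stop("constant_payoff_equilibria() requires a constant-advantage ",
         "scenario; got \"", scen, "\"", call. = FALSE)
  }
  sc <- .param_scalars(params)
  dW <- if (scen == "resident_advantage") sc$W0 else -sc$W0
  ds <- (1 - sc$c_r) * 2 / (1 + exp(dW)) -
        (1 - sc$c_i) * 2 / (1 + exp(-dW))
  M <- migration_odds(sc$m)
  if (sc$X_ir > 0 && M < -ds * sc$X_ir) {
    p_int <- -M / (ds * sc$X_ir)
    .equilibrium_set(c(p_int, 1),
                     c("internal", "fixation"),
                     c("stable", "unstable"),
                     "closed_form")
  } else {
    .equilibrium_set(1, "fixation", "stable", "closed_form")
  }
}

#' Numerical location of all equilibria
#'
#' Scans `psi(p_i) - M` on a uniform grid over (0, 1), brackets every
#' sign change, refines each root by bisection to a width below `tol`,
#' and classifies stability from the sign of [drift()] on either side of
#' the root (positive below and negative above means stable). The
#' fixation equilibrium `p_i* = 1` is always appended, classified by the
#' drift sign just below 1 (positive drift approaching 1 means fixation
#' is stable). Roots closer together than the grid spacing may merge; the
#' default grid is fine enough for the at most two interior crossings
#' that arise in the payoff scenarios covered here.
#'
#' @param params A [model_params()] object (any scenario).
#' @param grid_points Number of grid points over \[0, 1\] (at least 3).
#' @param tol Bisection half-width tolerance for root location.
#' @return An `equilibrium_set` with attribute `method = "numeric"`.
#' @export
find_equilibria <- function(params, grid_points = 2001, tol = 1e-10) {
  stopifnot(length(grid_points) == 1L, grid_points >= 3,
            length(tol) == 1L, tol > 0)
  M <- migration_odds(params$m)
  grid <- seq(0, 1, length.out = grid_points)
  f <- psi(grid, params) - M
  spacing <- grid[2] - grid[1]

  roots <- numeric(0)
  for (i in seq_len(grid_points - 1L)) {
    lo <- grid[i]; hi <- grid[i + 1L]
    flo <- f[i]; fhi <- f[i + 1L]
    root <- NA_real_
    if (flo == 0 && lo > 0) {
      root <- lo
    } else if (flo * fhi < 0) {
      # bisection
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        fm <- psi(mid, params) - M
        if (fm == 0) { lo <- mid; hi <- mid; break }
        if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
      }
      root <- (lo + hi) / 2
    }
    if (!is.na(root) && root > 0 && root < 1 - spacing / 2) {
      roots <- c(roots, root)
    }
  }

  eps <- max(10 * tol, spacing / 10)
  stab <- vapply(roots, function(r) {
    below <- drift(max(r - eps, 0), params)
    above <- drift(min(r + eps, 1), params)
    if (below > 0 && above < 0) "stable" else "unstable"
  }, character(1))

  fix_stab <- if (drift(1 - eps, params) > 0) "stable" else "unstable"

  .equilibrium_set(c(roots, 1),
                   c(rep("internal", length(roots)), "fixation"),
                   c(stab, fix_stab),
                   "numeric")
}

#' Forward integration of the mean-field dynamics
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of [drift()].
#' The `1/N` prefactor is retained, so one time unit corresponds to about
#' `N` events of the event-based simulator. The state is clipped to
#' \[0, 1\] against round-off at the boundaries.
#'
#' @param params A [model_params()] object.
#' @param p0 Initial frequency of type I, in \[0, 1\].
#' @param t_end End time (> 0).
#' @param dt Step size (> 0).
#' @return A data frame with columns `time` and `p_i`.
#' @export
integrate_drift <- function(params, p0, t_end, dt) {
  .check_prob(p0, "p0")
  stopifnot(length(t_end) == 1L, t_end > 0, length(dt) == 1L, dt > 0)
  n_steps <- ceiling(t_end / dt)
  times <- c(0, seq_len(n_steps) * dt)
  p <- numeric(n_steps + 1L)
  p[1] <- p0
  clip01 <- function(x) min(max(x, 0), 1)
  for (k in seq_len(n_steps)) {
    x <- p[k]
    k1 <- drift(x, params)
    k2 <- drift(clip01(x + dt / 2 * k1), params)
    k3 <- drift(clip01(x + dt / 2 * k2), params)
    k4 <- drift(clip01(x + dt * k3), params)
    p[k + 1L] <- clip01(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  data.frame(time = times, p_i = p)
}
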