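#' Default parameter grids for the baseline sweep
#'
#' The full baseline sweep varies the migration rate `m` from 0.001 in
#' steps of 0.005 (20 values up to 0.096), the conservatism parameters
#' `c_i` and `c_r` from 0.001 in steps of 0.05 (20 values up to 0.951),
#' and the cross-type interaction probability over `{0.1, 0.5}`, with a
#' population of 1000 and 10 replicates of 10^6 events per grid point for
#' the stochastic engine. The reduced grids are strict subsets (about 5x
#' coarser, 3 replicates of 2e5 events) so the full pipeline runs in
#' minutes at the desk.
#'
#' @param reduced Use the reduced grids?
#' @return Named list of grid vectors and simulation settings.
#' @export
baseline_sweep_grid <- function(reduced = FALSE) {
  full <- list(
    m = seq(0.001, 0.096, by = 0.005),
    c_r = seq(0.001, 0.951, by = 0.05),
    c_i = seq(0.001, 0.951, by = 0.05),
    X_ir = c(0.1, 0.5),
    N = 1000L, replicates = 10L, n_events = 1e6
  )
  if (!reduced) return(full)
  list(
    m = full$m[seq(1, 20, by = 5)],
    c_r = full$c_r[seq(1, 20, by = 5)],
    c_i = full$c_i[seq(1, 20, by = 5)],
    X_ir = full$X_ir,
    N = 1000L, replicates = 3L, n_events = 2e5
  )
}

.check_grid <- function(x, name, lo = 0, hi = 1) {
  if (!(is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
        all(x >= lo & x <= hi))) {
    stop(sprintf("invalid sweep values for `%s`: must be numeric in [%g, %g]",
                 name, lo, hi), call. = FALSE)
  }
  x
}

#' Baseline parameter sweep
#'
#' Evaluates the baseline model over a grid of migration rates,
#' conservatism values and cross-type interaction probabilities, with the
#' analytic engine (closed-form equilibrium), the stochastic engine
#' (replicated event-based simulations), or both. Grid defaults mirror
#' the full study design (see [baseline_sweep_grid()]); pass explicit
#' vectors or `reduced = TRUE` for desk-scale runs.
#'
#' The returned long-format table has one row per parameter combination
#' and engine. The analytic outcome column `p_star` holds the stable
#' equilibrium frequency of the immigrant trait (the internal coexistence
#' value where it exists, otherwise 1: fixation). The simulation columns
#' hold the mean and standard deviation over replicates of the final
#' frequency, plus the total number of clamped changing probabilities
#' (always 0 under baseline, where S <= 1).
#'
#' @param m,c_r,c_i,X_ir Grid vectors (defaults from
#'   [baseline_sweep_grid()]).
#' @param engine `"analytic"`, `"simulation"` or `"both"`.
#' @param N,replicates,n_events Stochastic-engine settings.
#' @param seed Master seed for the whole sweep (per-combination seeds are
#'   derived deterministically).
#' @param reduced Use the reduced default grids.
#' @return A data frame, one row per grid point x engine; `delta_c` is
#'   reported as a derived column (baseline outcomes depend on the
#'   conservatism values only through it).
#' @export
sweep_baseline <- function(m = NULL, c_r = NULL, c_i = NULL, X_ir = NULL,
                           engine = c("analytic", "simulation", "both"),
                           N = NULL, replicates = NULL, n_events = NULL,
                           seed = 1L, reduced = FALSE) {
  engine <- match.arg(engine)
  g <- baseline_sweep_grid(reduced)
  m <- .check_grid(if (is.null(m)) g$m else m, "m", lo = 1e-12, hi = 1 - 1e-12)
  c_r <- .check_grid(if (is.null(c_r)) g$c_r else c_r, "c_r")
  c_i <- .check_grid(if (is.null(c_i)) g$c_i else c_i, "c_i")
  X_ir <- .check_grid(if (is.null(X_ir)) g$X_ir else X_ir, "X_ir")
  if (is.null(N)) N <- g$N
  if (is.null(replicates)) replicates <- g$replicates
  if (is.null(n_events)) n_events <- g$n_events

  grid <- expand.grid(m = m, c_r = c_r, c_i = c_i, X_ir = X_ir,
                      KEEP.OUT.ATTRS = FALSE)
  engines <- switch(engine, analytic = "analytic",
                    simulation = "simulation",
                    both = c("analytic", "simulation"))
  set.seed(seed)
  combo_seeds <- sample.int(.Machine$integer.max, nrow(grid))

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gi <- grid[i, ]
    params <- params_from_X(N = N, m = gi$m, c_r = gi$c_r, c_i = gi$c_i,
                            X_ir = gi$X_ir)
    out <- lapply(engines, function(eng) {
      row <- data.frame(scenario = "baseline", m = gi$m, c_r = gi$c_r,
                        c_i = gi$c_i, delta_c = gi$c_r - gi$c_i,
                        X_ir = gi$X_ir, engine = eng,
                        p_star = NA_real_, stability = NA_character_,
                        mean_final = NA_real_, sd_final = NA_real_,
                        replicates = NA_integer_, clamp_total = NA_integer_,
                        stringsAsFactors = FALSE)
      if (eng == "analytic") {
        eq <- baseline_equilibria(params)
        stable <- eq[eq$stability == "stable", ]
        row$p_star <- stable$p_star[1]
        row$stability <- "stable"
      } else {
        reps <- run_replicates(params, n_events = n_events,
                               n_rep = replicates, seed = combo_seeds[i])
        row$mean_final <- attr(reps, "mean")
        row$sd_final <- attr(reps, "sd")
        row$replicates <- replicates
        row$clamp_total <- sum(reps$clamp_count)
      }
      row
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Constant-payoff parameter sweep
#'
#' Sweeps the constant-advantage scenarios over immigrant conservatism
#' and cross-type interaction probability, with the resident conservatism,
#' payoff magnitude and migration rate held fixed (defaults `c_r = 0.95`,
#' `W0 = 1`, `m = 0.01`). Outcomes come from the closed-form equilibrium:
#' `p_star` is the stable equilibrium frequency of the immigrant trait
#' and `fixation` flags grid points where the internal coexistence
#' equilibrium does not exist.
#'
#' @param scenario `"resident_advantage"` or `"immigrant_advantage"`.
#' @param c_i Vector of immigrant conservatism values.
#' @param X_ir Vector of cross-type interaction probabilities.
#' @param c_r,W0,m Fixed parameters.
#' @param N Population size recorded in the parameter set (the analytic
#'   outcome does not depend on it).
#' @return A data frame, one row per grid point.
#' @export
sweep_constant_payoff <- function(scenario = c("resident_advantage",
                                               "immigrant_advantage"),
                                  c_i = seq(0.001, 0.951, by = 0.05),
                                  X_ir = seq(0.05, 1, by = 0.05),
                                  c_r = 0.95, W0 = 1, m = 0.01, N = 1000L) {
  scenario <- match.arg(scenario)
  c_i <- .check_grid(c_i, "c_i")
  X_ir <- .check_grid(X_ir, "X_ir")
  grid <- expand.grid(c_i = c_i, X_ir = X_ir, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gi <- grid[i, ]
    params <- params_from_X(N = N, m = m, c_r = c_r, c_i = gi$c_i,
                            X_ir = gi$X_ir, scenario = scenario, W0 = W0)
    eq <- constant_payoff_equilibria(params)
    stable <- eq[eq$stability == "stable", ]
    data.frame(scenario = scenario, m = m, c_r = c_r, c_i = gi$c_i,
               X_ir = gi$X_ir, W0 = W0,
               p_star = stable$p_star[1],
               fixation = !any(eq$kind == "internal"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Equilibrium-condition structure
#'
#' Tabulates both sides of the internal-equilibrium condition
#' `M = psi(p_i)` on a uniform frequency grid and appends the
#' numerically located equilibria, reproducing the phase-line view used
#' to analyse the frequency-dependent payoff scenarios (equilibria sit
#' where the horizontal migration-odds line crosses the psi curve;
#' stability follows from the drift sign on either side).
#'
#' @param params A [model_params()] object (any scenario).
#' @param p_grid Number of grid points over \[0, 1\] (at least 2).
#' @param ... Passed to [find_equilibria()].
#' @return A list with `curve` (data frame `p_i`, `M`, `psi`) and
#'   `equilibria` (an `equilibrium_set`).
#' @export
equilibrium_structure <- function(params, p_grid = 201, ...) {
  stopifnot(length(p_grid) == 1L, p_grid >= 2)
  p <- seq(0, 1, length.out = p_grid)
  curve <- data.frame(p_i = p,
                      M = rep(migration_odds(params$m), length(p)),
                      psi = psi(p, params))
  list(curve = curve, equilibria = find_equilibria(params, ...))
}
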