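#' @useDynLib accultdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd
NULL

.scenario_code <- function(scenario) {
  match(scenario, payoff_scenarios) - 1L
}

#' Initial population
#'
#' The population initially consists entirely of residents: all `N`
#' individuals carry trait R, so `p_i = 0`.
#'
#' @param params A [model_params()] object.
#' @return An object of class `"population"`: a list with `types` (length
#'   `N` character vector of `"R"`/`"I"`) and `counts` (named integer
#'   vector `c(R = , I = )`).
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "model_params"))
  new_population(rep("R", params$N))
}

#' Construct a population from a type vector
#'
#' @param types Character vector of `"R"`/`"I"` labels, one per
#'   individual (length at least 2).
#' @return A `"population"` object; `counts` always equals the tally of
#'   `types`.
#' @export
new_population <- function(types) {
  stopifnot(is.character(types), length(types) >= 2,
            all(types %in% cultural_types))
  structure(
    list(types = types,
         counts = c(R = sum(types == "R"), I = sum(types == "I"))),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  n <- length(x$types)
  cat(sprintf("<population> N = %d, N_r = %d, N_i = %d (p_i = %.4f)\n",
              n, x$counts[["R"]], x$counts[["I"]], x$counts[["I"]] / n))
  invisible(x)
}

#' Frequency of the immigrant trait in a population
#' @param pop A `"population"` object.
#' @return `N_i / N`.
#' @export
immigrant_frequency <- function(pop) {
  pop$counts[["I"]] / length(pop$types)
}

.sim_call <- function(types_int, params, n_events, record_every) {
  sc <- .param_scalars(params)
  sim_events_cpp(types_int, sc$m, sc$c_r, sc$c_i,
                 sc$X_ii, sc$X_rr, sc$X_ir,
                 .scenario_code(sc$scenario), sc$W0, sc$literal_perception,
                 as.integer(n_events), as.integer(record_every))
}

#' Advance the population by one event
#'
#' One time step of the event-based model: a focal individual is drawn
#' uniformly; with probability `m` it is replaced by a fresh type-I
#' immigrant (adopting the immigrant orientation along with the trait);
#' otherwise it is paired with one of the other `N - 1` individuals
#' drawn uniformly. A mixed pair actually interacts with probability
#' `X_ir`, in which case the focal switches type with probability
#' `min(S_focal, 1)`, where the changing probability is evaluated at the
#' pre-event frequency `p_i` from the global counts. Same-type pairings
#' never change the state. Uses the current R random number generator
#' state.
#'
#' @param pop A `"population"` object.
#' @param params A [model_params()] object.
#' @return The updated `"population"`; attribute `"clamp_count"` records
#'   whether the per-event changing probability had to be clamped to 1.
#' @export
sim_step <- function(pop, params) {
  stopifnot(inherits(pop, "population"), inherits(params, "model_params"),
            length(pop$types) == params$N)
  res <- .sim_call(as.integer(pop$types == "I"), params, 1L, 1L)
  out <- new_population(c("R", "I")[res$types + 1L])
  attr(out, "clamp_count") <- res$clamp_count
  out
}

#' Exact expected one-event change in the immigrant-trait frequency
#'
#' Exhaustively enumerates every (focal type, event type, partner type,
#' outcome) combination of a single event from the given state and sums
#' probability times frequency change. This is the finite-population
#' analogue of the mean-field [drift()] and serves as an exact oracle for
#' the stochastic engine; it accounts for partner sampling without
#' replacement (a factor `N/(N-1)` relative to the mean-field term) and
#' for the clamping of changing probabilities at 1.
#'
#' @param pop A `"population"` object.
#' @param params A [model_params()] object.
#' @return Expected change in `p_i` over one event.
#' @export
expected_step_change <- function(pop, params) {
  stopifnot(inherits(pop, "population"), length(pop$types) == params$N)
  N <- params$N
  n_i <- pop$counts[["I"]]
  p_i <- n_i / N
  sc <- .param_scalars(params)
  S_cl <- function(focal) min(changing_probability(focal, p_i, params), 1)

  expected <- 0
  for (focal in cultural_types) {
    pr_focal <- if (focal == "I") p_i else 1 - p_i
    if (pr_focal == 0) next
    # immigration event: R -> I gains one immigrant, I -> I changes nothing
    if (focal == "R") {
      expected <- expected + pr_focal * sc$m * (1 / N)
    }
    # interaction event: enumerate the partner's type
    n_other <- if (focal == "I") N - n_i else n_i
    pr_partner_other <- n_other / (N - 1)
    if (pr_partner_other > 0) {
      d <- if (focal == "R") 1 / N else -1 / N
      expected <- expected +
        pr_focal * (1 - sc$m) * pr_partner_other * sc$X_ir * S_cl(focal) * d
    }
  }
  expected
}

#' Run the event-based simulation
#'
#' Starts from an all-resident population (unless `pop` is supplied) and
#' iterates [sim_step()] dynamics for `n_events` events in compiled code,
#' recording the immigrant-trait frequency every `record_every` events.
#' Runs are bit-for-bit reproducible for a given `(params, n_events,
#' record_every, seed)`.
#'
#' @param params A [model_params()] object.
#' @param n_events Number of events to simulate.
#' @param record_every Events between recorded samples (default records
#'   about 1000 points).
#' @param seed Integer seed passed to [set.seed()]; `NULL` uses the
#'   current RNG state.
#' @param pop Optional starting `"population"` (default
#'   [init_population()]).
#' @return A `"sim_trajectory"`: a data frame with columns `event` and
#'   `p_i` (the initial state as row `event = 0`), with attributes
#'   `clamp_count`, `final_population`, `params` and `seed`.
#' @export
run_simulation <- function(params, n_events = 1e6,
                           record_every = max(1, floor(n_events / 1000)),
                           seed = NULL, pop = init_population(params)) {
  stopifnot(inherits(params, "model_params"),
            n_events >= 1, record_every >= 1, record_every <= n_events)
  if (!is.null(seed)) set.seed(seed)
  p0 <- immigrant_frequency(pop)
  res <- .sim_call(as.integer(pop$types == "I"), params,
                   n_events, record_every)
  traj <- data.frame(event = c(0L, res$event), p_i = c(p0, res$p_i))
  structure(traj,
            clamp_count = res$clamp_count,
            final_population = new_population(c("R", "I")[res$types + 1L]),
            params = params, seed = seed,
            class = c("sim_trajectory", "data.frame"))
}

#' Final immigrant-trait frequency of a trajectory
#' @param traj A `"sim_trajectory"`.
#' @return The last recorded `p_i`.
#' @export
final_frequency <- function(traj) {
  traj$p_i[nrow(traj)]
}

#' Replicate simulations from a master seed
#'
#' Runs `n_rep` independent replicates of [run_simulation()]. Replicate
#' seeds are derived deterministically from the master seed by seeding
#' the generator with it and drawing `n_rep` integers via
#' `sample.int(.Machine$integer.max, n_rep)`, so the whole set is
#' reproducible from one integer.
#'
#' @param params A [model_params()] object.
#' @param n_events Events per replicate.
#' @param n_rep Number of replicates (>= 1).
#' @param seed Master seed (integer).
#' @param record_every Passed to [run_simulation()]; default records only
#'   the final state.
#' @return A `"replicate_summary"`: data frame with one row per replicate
#'   (columns `replicate`, `seed`, `final_p_i`, `clamp_count`) and
#'   attributes `mean`, `sd` and `params`.
#' @export
run_replicates <- function(params, n_events = 1e6, n_rep = 10, seed = 1L,
                           record_every = n_events) {
  stopifnot(n_rep >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_rep)
  finals <- numeric(n_rep)
  clamps <- integer(n_rep)
  for (k in seq_len(n_rep)) {
    traj <- run_simulation(params, n_events = n_events,
                           record_every = record_every, seed = seeds[k])
    finals[k] <- final_frequency(traj)
    clamps[k] <- attr(traj, "clamp_count")
  }
  structure(
    data.frame(replicate = seq_len(n_rep), seed = seeds,
               final_p_i = finals, clamp_count = clamps),
    mean = mean(finals),
    sd = if (n_rep > 1) sd(finals) else 0,
    params = params,
    class = c("replicate_summary", "data.frame")
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> n_rep = %d, mean final p_i = %.5f, sd = %.5f\n",
              nrow(x), attr(x, "mean"), attr(x, "sd")))
  print.data.frame(x, ...)
  invisible(x)
}
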