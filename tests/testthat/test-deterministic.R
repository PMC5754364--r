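baseline_params <- function(m = 0.01, c_r = 0.6, c_i = 0.1, X_ir = 0.5,
                            N = 1000, ...) {
  params_from_X(N = N, m = m, c_r = c_r, c_i = c_i, X_ir = X_ir, ...)
}

random_scenario_params <- function() {
  scen <- sample(payoff_scenarios, 1)
  params_from_X(N = sample(2:2000, 1), m = runif(1, 0.001, 0.5),
                c_r = runif(1), c_i = runif(1),
                X_ir = runif(1, 0.05, 1), X_ii = runif(1, 0.05, 1),
                X_rr = runif(1, 0.05, 1),
                scenario = scen, W0 = runif(1, 0.1, 3))
}

test_that("drift vanishes at fixation and is positive at p_i = 0", {
  set.seed(21)
  for (k in 1:20) {
    pk <- random_scenario_params()
    expect_identical(drift(1, pk), 0)
    expect_equal(drift(0, pk), pk$m / pk$N)
  }
  # the closed-form internal equilibrium is a root of the drift
  p0 <- baseline_params()
  expect_equal(drift(0.0404040404040404, p0), 0, tolerance = 1e-15)
})

test_that("drift factorises as (1/N)(1-m)(1-p)(M - psi(p))", {
  set.seed(22)
  for (k in 1:20) {
    pk <- random_scenario_params()
    p <- runif(5, 0.01, 0.99)
    lhs <- pk$N * drift(p, pk)
    rhs <- (1 - pk$m) * (1 - p) * (migration_odds(pk$m) - psi(p, pk))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("migration odds m/(1-m) are computed and guarded", {
  expect_equal(migration_odds(0), 0)
  expect_equal(migration_odds(0.5), 1)
  expect_equal(migration_odds(0.01), 0.0101010101010101, tolerance = 1e-12)
  expect_true(all(diff(migration_odds(seq(0, 0.9, by = 0.1))) > 0))
  expect_error(migration_odds(1))
})

test_that("psi matches its defining formula", {
  expect_equal(psi(0, baseline_params()), 0)
  # baseline: straight line p * X_ir * delta_c
  expect_equal(psi(0.5, baseline_params()), 0.5 * 0.5 * 0.5)
  # coordination at fixation: common-trait advantage makes psi negative
  p_co <- params_from_X(1000, 0.001, c_r = 0.5, c_i = 0, X_ir = 1,
                        scenario = "coordination", W0 = 1)
  expect_equal(psi(1, p_co), -0.193175735890015, tolerance = 1e-12)
})

test_that("baseline closed-form equilibria obey the existence condition", {
  eq <- baseline_equilibria(baseline_params())
  expect_s3_class(eq, "equilibrium_set")
  expect_equal(nrow(eq), 2)
  expect_equal(eq$p_star, c(0.0404040404040404, 1), tolerance = 1e-12)
  expect_equal(eq$kind, c("internal", "fixation"))
  expect_equal(eq$stability, c("stable", "unstable"))

  # residents less conservative than immigrants: no coexistence
  eq_neg <- baseline_equilibria(baseline_params(c_r = 0.1, c_i = 0.6))
  expect_equal(eq_neg$p_star, 1)
  expect_equal(eq_neg$stability, "stable")

  # migration odds exceed delta_c * X_ir: fixation only
  eq_fix <- baseline_equilibria(baseline_params(m = 0.4))
  expect_equal(eq_fix$p_star, 1)
  expect_equal(eq_fix$stability, "stable")

  expect_error(baseline_equilibria(
    params_from_X(100, 0.01, 0.6, 0.1, 0.5, scenario = "coordination")),
    "baseline")
})

test_that("constant-payoff closed form matches hand evaluation and limits", {
  p_ra <- params_from_X(1000, 0.01, c_r = 0.95, c_i = 0.5, X_ir = 1,
                        scenario = "resident_advantage", W0 = 1)
  eq <- constant_payoff_equilibria(p_ra)
  expect_equal(eq$p_star[1], 0.0143446751604168, tolerance = 1e-12)
  expect_equal(eq$kind, c("internal", "fixation"))
  expect_equal(eq$stability, c("stable", "unstable"))

  # W0 -> 0 limit agrees with the baseline closed form
  p_tiny <- params_from_X(1000, 0.01, c_r = 0.6, c_i = 0.1, X_ir = 0.5,
                          scenario = "resident_advantage", W0 = 1e-10)
  expect_equal(constant_payoff_equilibria(p_tiny)$p_star,
               baseline_equilibria(baseline_params())$p_star,
               tolerance = 1e-8)

  # delta_S >= 0 leaves fixation as the only equilibrium
  p_pos <- params_from_X(1000, 0.01, c_r = 0.1, c_i = 0.9, X_ir = 1,
                         scenario = "immigrant_advantage", W0 = 1)
  expect_gte(delta_S(0.5, p_pos), 0)
  eq_pos <- constant_payoff_equilibria(p_pos)
  expect_equal(eq_pos$p_star, 1)

  expect_error(constant_payoff_equilibria(baseline_params()), "scenario")
})

test_that("numeric equilibrium scan reproduces the closed forms", {
  set.seed(23)
  n_checked <- 0
  while (n_checked < 40) {
    m <- runif(1, 0.001, 0.1)
    c_r <- runif(1); c_i <- runif(1); X_ir <- runif(1, 0.05, 1)
    if (migration_odds(m) >= (c_r - c_i) * X_ir) next
    pk <- baseline_params(m = m, c_r = c_r, c_i = c_i, X_ir = X_ir)
    closed <- baseline_equilibria(pk)
    numeric <- find_equilibria(pk)
    expect_equal(numeric$p_star, closed$p_star, tolerance = 1e-8)
    expect_equal(numeric$stability, closed$stability)
    n_checked <- n_checked + 1
  }
})

test_that("numeric scan recovers the frequency-dependent equilibrium structure", {
  # coordination, low migration: bistability (confirmed against an
  # independent fine-grid sign scan of psi - M)
  p_co <- params_from_X(1000, 0.001, c_r = 0.5, c_i = 0, X_ir = 1,
                        scenario = "coordination", W0 = 1)
  brackets <- oracle_root_brackets(0.001, c_r = 0.5, c_i = 0, X_ir = 1,
                                   scenario = "coordination")
  expect_equal(nrow(brackets), 2)
  eq <- find_equilibria(p_co)
  internal <- eq[eq$kind == "internal", ]
  expect_equal(nrow(internal), 2)
  for (i in 1:2) {
    expect_gte(internal$p_star[i], brackets$lo[i])
    expect_lte(internal$p_star[i], brackets$hi[i])
  }
  expect_equal(internal$stability, c("stable", "unstable"))
  expect_equal(eq$stability[eq$kind == "fixation"], "stable")

  # complementation: a single, always stable coexistence equilibrium
  p_cm <- params_from_X(1000, 0.01, c_r = 0.5, c_i = 0.5, X_ir = 1,
                        scenario = "complementation", W0 = 1)
  br_cm <- oracle_root_brackets(0.01, c_r = 0.5, c_i = 0.5, X_ir = 1,
                                scenario = "complementation")
  expect_equal(nrow(br_cm), 1)
  eq_cm <- find_equilibria(p_cm)
  internal_cm <- eq_cm[eq_cm$kind == "internal", ]
  expect_equal(nrow(internal_cm), 1)
  expect_equal(internal_cm$stability, "stable")
  expect_gte(internal_cm$p_star, br_cm$lo)
  expect_lte(internal_cm$p_star, br_cm$hi)

  expect_error(find_equilibria(p_cm, grid_points = 2))
})

test_that("every equilibrium set contains the fixation equilibrium", {
  set.seed(24)
  for (k in 1:20) {
    pk <- random_scenario_params()
    expect_true(any(find_equilibria(pk, grid_points = 501)$p_star == 1))
  }
  expect_true(any(baseline_equilibria(baseline_params())$p_star == 1))
})

test_that("trajectories converge to stable equilibria", {
  # fixation is invariant
  pk <- baseline_params(N = 2)
  traj1 <- integrate_drift(pk, p0 = 1, t_end = 100, dt = 1)
  expect_true(all(traj1$p_i == 1))

  # stable coexistence regime: converge to the closed-form value from 0
  traj <- integrate_drift(pk, p0 = 0, t_end = 4000, dt = 1)
  expect_equal(traj$p_i[nrow(traj)], 0.0404040404040404, tolerance = 1e-6)
  expect_true(all(traj$p_i >= 0 & traj$p_i <= 1))

  # without the conservatism advantage the immigrant trait fixes
  pk_fix <- baseline_params(N = 2, c_r = 0.1, c_i = 0.6)
  traj_fix <- integrate_drift(pk_fix, p0 = 0, t_end = 4000, dt = 1)
  expect_equal(traj_fix$p_i[nrow(traj_fix)], 1, tolerance = 1e-6)

  expect_error(integrate_drift(pk, p0 = 0, t_end = 10, dt = -1))
})

test_that("stability labels agree with the local flow", {
  p_co <- params_from_X(50, 0.001, c_r = 0.5, c_i = 0, X_ir = 1,
                        scenario = "coordination", W0 = 1)
  eq <- find_equilibria(p_co)
  internal <- eq[eq$kind == "internal", ]
  p_lo <- internal$p_star[1]   # stable
  p_hi <- internal$p_star[2]   # unstable
  off <- 0.02
  # nudged off the stable point, the flow returns
  back <- integrate_drift(p_co, p0 = p_lo + off, t_end = 3000, dt = 1)
  expect_equal(back$p_i[nrow(back)], p_lo, tolerance = 1e-4)
  # nudged off the unstable point, the flow departs to the neighbours
  down <- integrate_drift(p_co, p0 = p_hi - off, t_end = 8000, dt = 1)
  expect_equal(down$p_i[nrow(down)], p_lo, tolerance = 1e-4)
  up <- integrate_drift(p_co, p0 = p_hi + off, t_end = 8000, dt = 1)
  expect_equal(up$p_i[nrow(up)], 1, tolerance = 1e-4)
})

test_that("baseline coexistence frequency moves monotonically with m, delta_c, X_ir", {
  m_grid <- seq(0.001, 0.0055, length.out = 10)
  dc_grid <- seq(0.5, 0.95, length.out = 10)
  X_grid <- c(0.3, 0.5)
  p_star <- function(m, dc, Xir) {
    eq <- baseline_equilibria(baseline_params(m = m, c_r = dc, c_i = 0,
                                              X_ir = Xir))
    eq$p_star[eq$kind == "internal"]
  }
  for (Xir in X_grid) {
    for (dc in dc_grid) {
      vals <- vapply(m_grid, function(m) p_star(m, dc, Xir), numeric(1))
      expect_true(all(diff(vals) > 0))
    }
    for (m in m_grid) {
      vals <- vapply(dc_grid, function(dc) p_star(m, dc, Xir), numeric(1))
      expect_true(all(diff(vals) < 0))
    }
  }
  for (m in m_grid) for (dc in dc_grid) {
    expect_lt(p_star(m, dc, 0.5), p_star(m, dc, 0.3))
  }
})
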