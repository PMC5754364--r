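# Independent oracles: direct formula evaluations written separately from
# the package code paths they are used to check.

# psi(p) - M evaluated from the primitive formulas, vectorised over p.
oracle_psi_minus_M <- function(p, m, c_r, c_i, X_ir, X_ii = 1, X_rr = 1,
                               scenario = "baseline", W0 = 1) {
  perceive <- function(p_x, Xxy, Xyy) p_x * Xxy / (p_x * Xxy + (1 - p_x) * Xyy)
  if (scenario == "baseline") {
    W_r <- 0; W_i <- 0
  } else if (scenario == "resident_advantage") {
    W_r <- W0; W_i <- 0
  } else if (scenario == "immigrant_advantage") {
    W_r <- 0; W_i <- W0
  } else {
    p_i_given_r <- perceive(p, X_ir, X_rr)
    p_r_given_i <- perceive(1 - p, X_ir, X_ii)
    if (scenario == "coordination") {
      W_r <- W0 * (1 - p_i_given_r)
      W_i <- W0 * (1 - p_r_given_i)
    } else {
      W_r <- W0 * p_i_given_r
      W_i <- W0 * p_r_given_i
    }
  }
  dW <- W_r - W_i
  S_r <- (1 - c_r) * 2 / (1 + exp(dW))
  S_i <- (1 - c_i) * 2 / (1 + exp(-dW))
  -p * X_ir * (S_r - S_i) - m / (1 - m)
}

# Brute-force root bracketing of psi - M by sign changes on a fine grid;
# returns a data frame of brackets strictly inside (0, 1).
oracle_root_brackets <- function(m, c_r, c_i, X_ir, X_ii = 1, X_rr = 1,
                                 scenario = "baseline", W0 = 1,
                                 n_points = 2e5) {
  p <- seq(0, 1, length.out = n_points)
  f <- oracle_psi_minus_M(p, m, c_r, c_i, X_ir, X_ii, X_rr, scenario, W0)
  idx <- which(f[-length(f)] * f[-1] < 0)
  idx <- idx[p[idx + 1] < 1]
  data.frame(lo = p[idx], hi = p[idx + 1])
}

# Population with given counts.
make_pop <- function(n_r, n_i) {
  new_population(c(rep("R", n_r), rep("I", n_i)))
}

# Random valid orientation draws for property tests.
random_orientation <- function() {
  orientation(conservatism = runif(1), x_same = runif(1), x_other = runif(1))
}
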