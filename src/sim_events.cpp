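#include <Rcpp.h>
using namespace Rcpp;

// Scenario codes shared with the R wrapper (see .scenario_code()):
// 0 baseline, 1 resident_advantage, 2 immigrant_advantage,
// 3 coordination, 4 complementation.

// Conditional probability that an observer with same-type interaction
// probability Xyy meets the other type (frequency p_x, pair probability
// Xxy). Callers guarantee a positive denominator: a mixed interaction
// only occurs when X_ir > 0 and both types are present.
static inline double perceived_cross(double p_x, double Xxy, double Xyy) {
    return p_x * Xxy / (p_x * Xxy + (1.0 - p_x) * Xyy);
}

// One event of the event-based model, iterated n_events times.
// types: 0 = R, 1 = I. Uses R's RNG (unif_rand), so set.seed() on the R
// side makes runs bit-for-bit reproducible.
// [[Rcpp::export]]
List sim_events_cpp(IntegerVector types0, double m,
                    double c_r, double c_i,
                    double X_ii, double X_rr, double X_ir,
                    int scenario, double W0, bool literal_perception,
                    int n_events, int record_every) {
    int N = types0.size();
    IntegerVector types = clone(types0);
    int n_i = 0;
    for (int k = 0; k < N; ++k) n_i += types[k];

    int n_rec = n_events / record_every;
    IntegerVector rec_event(n_rec);
    NumericVector rec_p(n_rec);
    int rec_idx = 0;
    int clamp_count = 0;

    for (int ev = 1; ev <= n_events; ++ev) {
        int focal = (int)(unif_rand() * N);
        if (focal == N) focal = N - 1;  // guard against unif_rand() == 1

        if (unif_rand() < m) {
            // immigration event: focal replaced by a fresh type-I
            // individual (carrying the immigrant orientation)
            if (types[focal] == 0) { types[focal] = 1; ++n_i; }
        } else {
            // interaction event: partner drawn uniformly from the other
            // N - 1 individuals (the focal cannot meet itself)
            int j = (int)(unif_rand() * (N - 1));
            if (j == N - 1) j = N - 2;
            if (j >= focal) ++j;
            if (types[focal] != types[j]) {
                if (unif_rand() < X_ir) {
                    // realised cross-type interaction: focal may switch,
                    // with probability evaluated at the pre-event state
                    double p_i = (double)n_i / N;
                    double W_r = 0.0, W_i = 0.0;
                    if (scenario == 1) {
                        W_r = W0;
                    } else if (scenario == 2) {
                        W_i = W0;
                    } else if (scenario >= 3) {
                        double p_i_given_r = perceived_cross(p_i, X_ir, X_rr);
                        double p_r_given_i =
                            perceived_cross(1.0 - p_i, X_ir, X_ii);
                        double p_r_given_r =
                            literal_perception ? (1.0 - p_i) : 1.0 - p_i_given_r;
                        double p_i_given_i =
                            literal_perception ? p_i : 1.0 - p_r_given_i;
                        if (scenario == 3) {        // coordination
                            W_r = W0 * p_r_given_r;
                            W_i = W0 * p_i_given_i;
                        } else {                    // complementation
                            W_r = W0 * p_i_given_r;
                            W_i = W0 * p_r_given_i;
                        }
                    }
                    double dW = W_r - W_i;
                    double S;
                    if (types[focal] == 1) {
                        S = (1.0 - c_i) * 2.0 / (1.0 + std::exp(-dW));
                    } else {
                        S = (1.0 - c_r) * 2.0 / (1.0 + std::exp(dW));
                    }
                    if (S > 1.0) { S = 1.0; ++clamp_count; }
                    if (unif_rand() < S) {
                        if (types[focal] == 0) { types[focal] = 1; ++n_i; }
                        else                   { types[focal] = 0; --n_i; }
                    }
                }
            }
            // same-type pairings never change state; no draws consumed
        }

        if (ev % record_every == 0 && rec_idx < n_rec) {
            rec_event[rec_idx] = ev;
            rec_p[rec_idx] = (double)n_i / N;
            ++rec_idx;
        }
    }

    return List::create(
        _["types"] = types,
        _["n_i"] = n_i,
        _["event"] = rec_event,
        _["p_i"] = rec_p,
        _["clamp_count"] = clamp_count);
}
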