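#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent simulator with piecewise-exponential deme sizes.
//
// Demography: every deme follows the same size trajectory N(t), defined by
// anchor times (0 = present, increasing into the past) and anchor sizes,
// interpolated exponentially within each epoch and constant beyond the last
// anchor.  Backward-in-time events:
//   * coalescence within deme d at rate k_d (k_d - 1) / (4 N(t)),
//   * migration per lineage at `mig_rate` per generation:
//       - sink model: lineages outside deme 1 move to deme 1,
//       - island model: lineages move to a uniformly chosen other deme,
//   * at `fusion_time` (and again at `time_cap`) all lineages are relocated
//     to deme 1, which guarantees eventual coalescence.
//
// Time-inhomogeneous rates are handled by thinning: within an epoch the
// coalescence rate is bounded using the epoch's minimum deme size (N(t) is
// monotone within an epoch), candidate event times are drawn from the
// bounding rate and accepted with probability actual/bound.

static double size_at(double t, const NumericVector& at, const NumericVector& an) {
    int k = at.size();
    if (t >= at[k - 1]) return an[k - 1];
    int e = 0;
    while (t >= at[e + 1]) ++e;
    double ta = at[e], tb = at[e + 1];
    double frac = (t - ta) / (tb - ta);
    return an[e] * std::pow(an[e + 1] / an[e], frac);
}

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector tip_demes, int n_demes,
                       NumericVector anchor_times, NumericVector anchor_sizes,
                       double mig_rate, int mig_model, // 0 none, 1 sink, 2 island
                       double fusion_time, double time_cap) {
    int n = tip_demes.size();
    int n_nodes = 2 * n - 1;
    IntegerVector parent(n_nodes, 0);
    NumericVector node_time(n_nodes, 0.0);
    int n_mig = 0;

    std::vector<int> deme(n), node_id(n);
    for (int i = 0; i < n; ++i) { deme[i] = tip_demes[i]; node_id[i] = i + 1; }
    int n_live = n, next_node = n + 1;
    double t = 0.0;

    // epoch boundaries: anchor times, fusion time, cap
    std::vector<double> bounds;
    for (int i = 1; i < anchor_times.size(); ++i) bounds.push_back(anchor_times[i]);
    bounds.push_back(fusion_time);
    bounds.push_back(time_cap);
    std::sort(bounds.begin(), bounds.end());

    std::vector<int> k(n_demes + 1, 0); // lineages per deme, 1-based
    for (int i = 0; i < n_live; ++i) k[deme[i]]++;

    bool fused = false, capped = false;
    const double INF = std::numeric_limits<double>::infinity();

    while (n_live > 1) {
        // end of current epoch (next boundary strictly after t; INF beyond all)
        double t_end = INF;
        for (size_t b = 0; b < bounds.size(); ++b)
            if (bounds[b] > t) { t_end = bounds[b]; break; }

        // bounding coalescence rate over (t, t_end): N monotone in epoch
        double n_now = size_at(t, anchor_times, anchor_sizes);
        double n_end = R_FINITE(t_end) ? size_at(t_end, anchor_times, anchor_sizes)
                                       : anchor_sizes[anchor_sizes.size() - 1];
        double n_min = std::min(n_now, n_end);
        double pairs = 0.0;
        for (int d = 1; d <= n_demes; ++d) pairs += 0.5 * k[d] * (k[d] - 1.0);
        double coal_bound = pairs / (2.0 * n_min);

        double mig_total = 0.0;
        if (mig_model == 1) mig_total = mig_rate * (n_live - k[1]);
        else if (mig_model == 2) mig_total = mig_rate * n_live;

        double rate_bound = coal_bound + mig_total;
        if (rate_bound <= 0.0) {
            // isolated lineages that can never meet before a fusion event
            if (!R_FINITE(t_end)) stop("lineages can never reach a common deme");
            t = t_end;
        } else {
            double dt = R::exp_rand() / rate_bound;
            if (t + dt >= t_end) {
                t = t_end;
            } else {
                t += dt;
                // actual coalescence rate at time t
                double n_t = size_at(t, anchor_times, anchor_sizes);
                double coal_act = pairs / (2.0 * n_t);
                double u = R::unif_rand() * rate_bound;
                if (u < coal_act) {
                    // pick deme proportional to k_d (k_d - 1)
                    double v = R::unif_rand() * pairs;
                    int d_sel = n_demes; double acc = 0.0;
                    for (int d = 1; d <= n_demes; ++d) {
                        acc += 0.5 * k[d] * (k[d] - 1.0);
                        if (v < acc) { d_sel = d; break; }
                    }
                    // pick two distinct lineages in d_sel
                    int i1 = (int)(R::unif_rand() * k[d_sel]);
                    int i2 = (int)(R::unif_rand() * (k[d_sel] - 1));
                    if (i2 >= i1) ++i2;
                    int a = -1, b = -1, cnt = 0;
                    for (int i = 0; i < n_live; ++i) {
                        if (deme[i] == d_sel) {
                            if (cnt == i1) a = i;
                            if (cnt == i2) b = i;
                            ++cnt;
                        }
                    }
                    int anc = next_node++;
                    parent[node_id[a] - 1] = anc;
                    parent[node_id[b] - 1] = anc;
                    node_time[anc - 1] = t;
                    node_id[a] = anc;
                    if (b != n_live - 1) { deme[b] = deme[n_live - 1]; node_id[b] = node_id[n_live - 1]; }
                    --n_live;
                    k[d_sel]--;
                } else if (u < coal_act + mig_total) {
                    // migration: pick a migrating lineage
                    if (mig_model == 1) {
                        int m = (int)(R::unif_rand() * (n_live - k[1]));
                        int cnt = 0;
                        for (int i = 0; i < n_live; ++i) {
                            if (deme[i] != 1) {
                                if (cnt == m) { k[deme[i]]--; deme[i] = 1; k[1]++; ++n_mig; break; }
                                ++cnt;
                            }
                        }
                    } else {
                        int i = (int)(R::unif_rand() * n_live);
                        int d_new = 1 + (int)(R::unif_rand() * (n_demes - 1));
                        if (d_new >= deme[i]) ++d_new;
                        k[deme[i]]--; deme[i] = d_new; k[d_new]++; ++n_mig;
                    }
                } // else: thinning rejection
                continue;
            }
        }

        // arrived at an epoch boundary: apply fusion events
        if (!fused && t >= fusion_time) {
            for (int i = 0; i < n_live; ++i) { k[deme[i]]--; deme[i] = 1; k[1]++; }
            fused = true;
        }
        if (!capped && t >= time_cap) {
            for (int i = 0; i < n_live; ++i) { k[deme[i]]--; deme[i] = 1; k[1]++; }
            capped = true;
        }
        if (!R_FINITE(t)) stop("simulation failed to coalesce"); // unreachable guard
    }

    return List::create(_["parent"] = parent, _["time"] = node_time,
                        _["n_tips"] = n, _["n_migrations"] = n_mig,
                        _["tmrca"] = t);
}
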