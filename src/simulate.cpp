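#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Clock-driven integration of a conductance-based leaky integrate-and-fire
// network with alpha-function synapses and (optionally) nearest-spike
// pair-based STDP with hard bounds.
//
// Membrane equation, per neuron i:
//   tau_m dV_i/dt = (V_rest - V_i) + g * sum_j a_ji W_ji s_j(t) * (E_ex - V_i) + I_i(t)
// advanced with an exponential-Euler step (exact while conductance and
// current are held constant over the step).
//
// The alpha conductance s_j is maintained by two linear state variables
// (x, s) with exact per-step exponential updates:
//   dx/dt = -x/tau_a                (x += 1 at each spike of j)
//   ds/dt = (e * x - s)/tau_a
// so that a single spike at time 0 yields s(t) = (t/tau_a) exp(1 - t/tau_a),
// peaking at 1 one time constant after the spike.  Overlapping spikes
// superpose.
//
// Spikes are detected at step end (V >= V_th), the potential is reset to
// V_rest, and all spikes within one step count as simultaneous (dt_pair = 0)
// for plasticity.  On each postsynaptic-side spike the nearest-spike rule is
// applied: only the most recent spike of the partner contributes, weights are
// clipped into [w_min, w_max] after every update, and synchronous reciprocal
// pairs each receive a single potentiation of amplitude a_plus.

static const double NEVER = -1.0e30;

// [[Rcpp::export]]
List lif_simulate_cpp(int n,
                      IntegerVector edge_pre,
                      IntegerVector edge_post,
                      NumericVector w,
                      IntegerVector in_ptr,
                      IntegerVector in_idx,
                      IntegerVector out_ptr,
                      IntegerVector out_idx,
                      NumericVector v,
                      NumericVector x,
                      NumericVector s,
                      NumericVector last_spike,
                      double t0,
                      double duration,
                      double dt,
                      double tau_m,
                      double v_rest,
                      double v_th,
                      double e_ex,
                      double g,
                      double tau_alpha,
                      List stim_neurons,
                      NumericVector stim_start,
                      NumericVector stim_end,
                      NumericVector stim_amp,
                      bool plastic,
                      double a_plus,
                      double a_minus,
                      double tau_plus,
                      double tau_minus,
                      double w_min,
                      double w_max)
{
    if (dt <= 0.0) stop("dt must be positive");
    if (duration <= 0.0) stop("duration must be positive");

    // work on copies: the caller's network and state must stay untouched
    w = clone(w);
    v = clone(v);
    x = clone(x);
    s = clone(s);
    last_spike = clone(last_spike);

    const int nsteps = (int) std::lround(duration / dt);
    const double decay_a = std::exp(-dt / tau_alpha);
    const double decay_m = std::exp(-dt / tau_m);
    const double E1 = std::exp(1.0);
    // negligibility thresholds: alpha-kernel states below SEPS are dropped
    // and synaptic conductances below GEPS are treated as zero drive; the
    // induced membrane error is < 1e-4 mV, orders of magnitude below any
    // observable effect on spike times at dt = 0.1 ms
    const double SEPS = 1e-6;
    const double GEPS = 1e-8;

    const int nseg = stim_start.size();
    std::vector<std::vector<int> > seg(nseg);
    for (int q = 0; q < nseg; ++q) {
        IntegerVector nv = stim_neurons[q];
        seg[q].assign(nv.begin(), nv.end()); // 0-based indices
    }

    // scatter buffers, reset via touched lists only
    std::vector<double> G(n, 0.0), I(n, 0.0);
    std::vector<int> gtouch, itouch;
    gtouch.reserve(256); itouch.reserve(256);

    // active presynaptic units: x or s non-negligible
    std::vector<char> in_active(n, 0);
    std::vector<int> active;
    active.reserve(256);
    for (int j = 0; j < n; ++j)
        if (x[j] > SEPS || s[j] > SEPS) { in_active[j] = 1; active.push_back(j); }

    std::vector<int> fired;
    fired.reserve(64);
    std::vector<char> fired_flag(n, 0);

    // membrane hot list: only neurons with synaptic drive, injected current
    // or an off-rest potential need a step; everything else sits at V_rest
    std::vector<char> in_hot(n, 0);
    std::vector<int> hot;
    hot.reserve(256);
    for (int i = 0; i < n; ++i)
        if (v[i] != v_rest) { in_hot[i] = 1; hot.push_back(i); }

    std::vector<int> r_neuron;
    std::vector<double> r_time;

    for (int k = 0; k < nsteps; ++k) {
        const double t = t0 + k * dt;
        const double t_end = t0 + (k + 1) * dt;

        // piecewise-constant currents active on [start, end)
        for (size_t a = 0; a < itouch.size(); ++a) I[itouch[a]] = 0.0;
        itouch.clear();
        for (int q = 0; q < nseg; ++q) {
            if (t >= stim_start[q] - 1e-9 && t < stim_end[q] - 1e-9) {
                const double amp = stim_amp[q];
                for (size_t a = 0; a < seg[q].size(); ++a) {
                    const int i = seg[q][a];
                    if (I[i] == 0.0) itouch.push_back(i);
                    I[i] += amp;
                }
            }
        }

        // synaptic drive from currently active presynaptic neurons (s at step start)
        for (size_t a = 0; a < gtouch.size(); ++a) G[gtouch[a]] = 0.0;
        gtouch.clear();
        for (size_t a = 0; a < active.size(); ++a) {
            const int j = active[a];
            const double sj = s[j];
            if (sj > 1e-6) {
                for (int p = out_ptr[j]; p < out_ptr[j + 1]; ++p) {
                    const int e = out_idx[p];
                    const int i = edge_post[e];
                    if (G[i] == 0.0) gtouch.push_back(i);
                    G[i] += w[e] * sj;
                }
            }
        }

        // membrane update (exponential Euler) + threshold detection,
        // restricted to driven or off-rest neurons
        for (size_t a = 0; a < gtouch.size(); ++a) {
            const int i = gtouch[a];
            if (!in_hot[i]) { in_hot[i] = 1; hot.push_back(i); }
        }
        for (size_t a = 0; a < itouch.size(); ++a) {
            const int i = itouch[a];
            if (!in_hot[i]) { in_hot[i] = 1; hot.push_back(i); }
        }
        fired.clear();
        {
            size_t keep = 0;
            for (size_t a = 0; a < hot.size(); ++a) {
                const int i = hot[a];
                double vi = v[i];
                const double gi = g * G[i];
                bool driven = (gi > GEPS || I[i] != 0.0);
                if (!driven) {
                    vi = v_rest + (vi - v_rest) * decay_m;
                    if (std::fabs(vi - v_rest) < 1e-12) vi = v_rest;
                } else {
                    const double denom = 1.0 + gi;
                    const double vinf = (v_rest + gi * e_ex + I[i]) / denom;
                    vi = vinf + (vi - vinf) * std::exp(-dt * denom / tau_m);
                }
                if (!std::isfinite(vi))
                    stop("non-finite membrane potential at t = %f (neuron %d)",
                         t_end, i + 1);
                v[i] = vi;
                if (vi >= v_th) { fired.push_back(i); fired_flag[i] = 1; }
                if (driven || vi != v_rest) hot[keep++] = i;
                else in_hot[i] = 0;
            }
            hot.resize(keep);
        }

        // advance alpha-kernel states to t_end (before adding this step's spikes)
        {
            size_t keep = 0;
            for (size_t a = 0; a < active.size(); ++a) {
                const int j = active[a];
                s[j] = (s[j] + E1 * x[j] * dt / tau_alpha) * decay_a;
                x[j] *= decay_a;
                if (x[j] > SEPS || s[j] > SEPS) active[keep++] = j;
                else { in_active[j] = 0; x[j] = 0.0; s[j] = 0.0; }
            }
            active.resize(keep);
        }

        if (fired.size() > 1) std::sort(fired.begin(), fired.end());

        // plasticity: nearest-spike pairings at the moment of each spike
        if (plastic && !fired.empty()) {
            for (size_t a = 0; a < fired.size(); ++a) {
                const int i = fired[a];
                // incoming j -> i : potentiation path (and dt = 0 convention)
                for (int p = in_ptr[i]; p < in_ptr[i + 1]; ++p) {
                    const int e = in_idx[p];
                    const int j = edge_pre[e];
                    double dw;
                    if (fired_flag[j]) dw = a_plus;            // synchronous pair
                    else if (last_spike[j] > NEVER)
                        dw = a_plus * std::exp(-(t_end - last_spike[j]) / tau_plus);
                    else continue;
                    double wn = w[e] + dw;
                    w[e] = (wn > w_max) ? w_max : (wn < w_min ? w_min : wn);
                }
                // outgoing i -> j : depression path (synchronous handled above)
                for (int p = out_ptr[i]; p < out_ptr[i + 1]; ++p) {
                    const int e = out_idx[p];
                    const int j = edge_post[e];
                    if (fired_flag[j]) continue;
                    if (last_spike[j] > NEVER) {
                        const double dw = -a_minus *
                            std::exp(-(t_end - last_spike[j]) / tau_minus);
                        double wn = w[e] + dw;
                        w[e] = (wn > w_max) ? w_max : (wn < w_min ? w_min : wn);
                    }
                }
            }
        }

        // reset, record, and start the alpha kernels of this step's spikes
        for (size_t a = 0; a < fired.size(); ++a) {
            const int i = fired[a];
            v[i] = v_rest;
            last_spike[i] = t_end;
            x[i] += 1.0;
            fired_flag[i] = 0;
            if (!in_active[i]) { in_active[i] = 1; active.push_back(i); }
            r_neuron.push_back(i + 1);
            r_time.push_back(t_end);
        }
    }

    return List::create(_["spike_neuron"] = wrap(r_neuron),
                        _["spike_time"] = wrap(r_time),
                        _["v"] = v,
                        _["x"] = x,
                        _["s"] = s,
                        _["last_spike"] = last_spike,
                        _["w"] = w,
                        _["t"] = t0 + nsteps * dt);
}
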