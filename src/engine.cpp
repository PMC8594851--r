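// Full simulation loop for the force vector model.
//
// Per iteration: pairwise forces from the pre-step state (dot-product sign,
// inverse-power distance, AIB gating, force-mode post-processing), trial
// displacements at DT = 1, adaptive DT from the peak displacement
// (DT^2 = CR / peak), simultaneous position update, then a transitive merge
// pass over pairs closer than CR. Mirrors the pure-R step path exactly
// (same tie-breaks, same component ordering) so the two can be compared.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

namespace {

struct State {
  int n, d;
  std::vector<double> pos;      // row-major n x d
  std::vector<double> active, passive;
  std::vector<int> ids;
  std::vector<std::vector<int>> members;
};

int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// connected components of pairs closer than CR; the merged agent sits at
// the member with the greatest active mass (ties: lowest id)
void merge_pass(State& s, const std::vector<double>& w, double cr) {
  const int n = s.n, d = s.d;
  if (n < 2) return;
  std::vector<int> parent(n);
  std::iota(parent.begin(), parent.end(), 0);
  bool any = false;
  const double cr2 = cr * cr;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double wsq = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = s.pos[i * d + k] - s.pos[j * d + k];
        wsq += w[k] * diff * diff;
      }
      if (wsq < cr2) {
        int ri = find_root(parent, i), rj = find_root(parent, j);
        if (ri != rj) {
          parent[std::max(ri, rj)] = std::min(ri, rj);
          any = true;
        }
      }
    }
  }
  if (!any) return;
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) root[i] = find_root(parent, i);

  State out;
  out.d = d;
  std::vector<int> seen;  // roots in ascending first-occurrence order
  for (int i = 0; i < n; ++i)
    if (root[i] == i) seen.push_back(i);
  out.n = static_cast<int>(seen.size());
  out.pos.resize(out.n * d);
  out.active.resize(out.n);
  out.passive.resize(out.n);
  out.ids.resize(out.n);
  out.members.resize(out.n);
  for (int c = 0; c < out.n; ++c) {
    int r = seen[c];
    int best = -1;
    double suma = 0.0, sump = 0.0;
    for (int i = 0; i < n; ++i) {
      if (root[i] != r) continue;
      suma += s.active[i];
      sump += s.passive[i];
      if (best < 0 || s.active[i] > s.active[best] ||
          (s.active[i] == s.active[best] && s.ids[i] < s.ids[best]))
        best = i;
      out.members[c].insert(out.members[c].end(), s.members[i].begin(),
                            s.members[i].end());
    }
    std::sort(out.members[c].begin(), out.members[c].end());
    for (int k = 0; k < d; ++k) out.pos[c * d + k] = s.pos[best * d + k];
    out.active[c] = suma;
    out.passive[c] = sump;
    out.ids[c] = s.ids[best];
  }
  s = std::move(out);
}

}  // namespace

// [[Rcpp::export]]
List engine_run(NumericMatrix positions, NumericVector active_mass,
                NumericVector passive_mass, IntegerVector ids, List members,
                double g, NumericVector metric_weights,
                double distance_exponent, double aib, double cr,
                int force_mode, bool adaptive, int tickstop, int agent_stop,
                double dt_stop, double eq_tol, bool record_trajectory,
                int max_iterations) {
  State s;
  s.n = positions.nrow();
  s.d = positions.ncol();
  s.pos.resize(s.n * s.d);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < s.d; ++k) s.pos[i * s.d + k] = positions(i, k);
  s.active.assign(active_mass.begin(), active_mass.end());
  s.passive.assign(passive_mass.begin(), passive_mass.end());
  s.ids.assign(ids.begin(), ids.end());
  s.members.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    IntegerVector m = members[i];
    s.members[i].assign(m.begin(), m.end());
  }
  std::vector<double> w(metric_weights.begin(), metric_weights.end());

  std::vector<double> rec_iter, rec_dt, rec_et, rec_peak, rec_att, rec_rep,
      rec_pct, rec_n, rec_ngrp, rec_maxf;
  List trajectory = List::create();
  std::vector<List> traj;

  const bool sq = distance_exponent == 2.0;
  bool unit_w = true;
  for (double wk : w) unit_w = unit_w && wk == 1.0;
  const double aib2 = aib * aib;
  double et = 0.0;
  int iteration = 0;
  std::string stop_reason;
  std::vector<double> force, trial;

  for (;;) {
    const int n = s.n, d = s.d;
    force.assign(n * d, 0.0);
    double sum_att = 0.0, sum_rep = 0.0, min_wsq = R_PosInf;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double wsq = 0.0, dot = 0.0, dsq = 0.0;
        if (unit_w) {
          for (int k = 0; k < d; ++k) {
            double diff = s.pos[i * d + k] - s.pos[j * d + k];
            wsq += diff * diff;
            dot += s.pos[i * d + k] * s.pos[j * d + k];
          }
          dsq = wsq;
        } else {
          for (int k = 0; k < d; ++k) {
            double diff = s.pos[i * d + k] - s.pos[j * d + k];
            wsq += w[k] * diff * diff;
            dsq += diff * diff;
            dot += s.pos[i * d + k] * s.pos[j * d + k];
          }
        }
        if (wsq < min_wsq) min_wsq = wsq;
        if (wsq > aib2 || wsq == 0.0) continue;
        double r = std::sqrt(wsq);
        double rp = sq ? wsq : std::pow(r, distance_exponent);
        // scalar prefactors: force of i on j and of j on i
        double sc_i = g * s.active[i] * dot / rp;
        double sc_j = g * s.active[j] * dot / rp;
        switch (force_mode) {
          case 1: sc_i = std::fabs(sc_i); sc_j = std::fabs(sc_j); break;
          case 2: sc_i = -std::fabs(sc_i); sc_j = -std::fabs(sc_j); break;
          case 3: if (dot < 0) { sc_i = 0.0; sc_j = 0.0; } break;
          case 4: if (dot > 0) { sc_i = 0.0; sc_j = 0.0; } break;
          case 5: sc_i = -sc_i; sc_j = -sc_j; break;
          default: break;
        }
        double dnorm_over_r = std::sqrt(dsq) / r;
        for (int k = 0; k < d; ++k) {
          double u = (s.pos[i * d + k] - s.pos[j * d + k]) / r;
          force[j * d + k] += sc_i * u;   // i pulls/pushes j along (i - j)
          force[i * d + k] -= sc_j * u;   // j acts on i along (j - i)
        }
        double mag_i = std::fabs(sc_i) * dnorm_over_r;
        double mag_j = std::fabs(sc_j) * dnorm_over_r;
        if (sc_i > 0) sum_att += mag_i; else if (sc_i < 0) sum_rep += mag_i;
        if (sc_j > 0) sum_att += mag_j; else if (sc_j < 0) sum_rep += mag_j;
      }
    }
    if (n >= 2 && min_wsq > aib2) { stop_reason = "all_beyond_aib"; break; }

    trial.assign(n * d, 0.0);
    double peak = 0.0, max_force = 0.0;
    for (int i = 0; i < n; ++i) {
      double tn = 0.0, fn = 0.0;
      for (int k = 0; k < d; ++k) {
        double t = force[i * d + k] / s.passive[i];
        trial[i * d + k] = t;
        tn += t * t;
        fn += force[i * d + k] * force[i * d + k];
      }
      tn = std::sqrt(tn);
      fn = std::sqrt(fn);
      if (tn > peak) peak = tn;
      if (fn > max_force) max_force = fn;
    }
    if (peak < eq_tol) { stop_reason = "equilibrium"; break; }

    double dt = adaptive ? std::sqrt(cr / peak) : 1.0;
    double dt2 = dt * dt;
    for (int i = 0; i < n * d; ++i) s.pos[i] += trial[i] * dt2;
    merge_pass(s, w, cr);

    ++iteration;
    et += dt;
    int n_groups = 0;
    for (int i = 0; i < s.n; ++i)
      if (s.members[i].size() > 1) ++n_groups;
    double total = sum_att + sum_rep;
    rec_iter.push_back(iteration);
    rec_dt.push_back(dt);
    rec_et.push_back(et);
    rec_peak.push_back(peak);
    rec_att.push_back(sum_att);
    rec_rep.push_back(sum_rep);
    rec_pct.push_back(total > 0 ? 100.0 * sum_rep / total : 0.0);
    rec_n.push_back(s.n);
    rec_ngrp.push_back(n_groups);
    rec_maxf.push_back(max_force);

    if (record_trajectory) {
      NumericMatrix p(s.n, s.d);
      for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < s.d; ++k) p(i, k) = s.pos[i * s.d + k];
      List mem(s.n);
      for (int i = 0; i < s.n; ++i) mem[i] = wrap(s.members[i]);
      traj.push_back(List::create(
          _["ids"] = wrap(s.ids), _["positions"] = p,
          _["active_mass"] = wrap(s.active),
          _["passive_mass"] = wrap(s.passive), _["members"] = mem));
    }

    if (tickstop > 0 && iteration >= tickstop) { stop_reason = "tickstop"; break; }
    if (agent_stop > 0 && s.n <= agent_stop) { stop_reason = "agent_stop"; break; }
    if (dt_stop > 0 && dt > dt_stop) { stop_reason = "dt_stop"; break; }
    if (iteration >= max_iterations) { stop_reason = "max_iterations"; break; }
    if (iteration % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_pos(s.n, s.d);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < s.d; ++k) final_pos(i, k) = s.pos[i * s.d + k];
  List final_members(s.n);
  for (int i = 0; i < s.n; ++i) final_members[i] = wrap(s.members[i]);

  List records = List::create(
      _["iteration"] = wrap(rec_iter), _["dt"] = wrap(rec_dt),
      _["elapsed_time"] = wrap(rec_et), _["peak_distance"] = wrap(rec_peak),
      _["sum_attractive"] = wrap(rec_att), _["sum_repulsive"] = wrap(rec_rep),
      _["repulsive_pct"] = wrap(rec_pct), _["n_agents"] = wrap(rec_n),
      _["n_groups"] = wrap(rec_ngrp), _["max_force"] = wrap(rec_maxf));

  if (record_trajectory) trajectory = wrap(traj);

  return List::create(
      _["positions"] = final_pos, _["active_mass"] = wrap(s.active),
      _["passive_mass"] = wrap(s.passive), _["ids"] = wrap(s.ids),
      _["members"] = final_members, _["stop_reason"] = stop_reason,
      _["records"] = records, _["iterations"] = iteration,
      _["elapsed_time"] = et,
      _["trajectory"] = record_trajectory ? SEXP(trajectory) : R_NilValue);
}
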