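#include <Rcpp.h>
using namespace Rcpp;

// Cell state codes shared with the R side
static const int EMPTY = 0, VIABLE = 1, APOPTOTIC = 2, NECROTIC = 3;

static inline double hill(double x, double k, double h) {
  if (x <= 0.0) return 0.0;
  double xh = std::pow(x, h), kh = std::pow(k, h);
  return xh / (kh + xh);
}

static inline double birth_rate_cpp(double pO2, double R, double bP,
                                    double pP, double pN, double hn,
                                    bool linear_ramp, double eta) {
  if (pO2 <= pN) return 0.0;
  double inhib = 1.0 - eta * R;
  if (pO2 > pP) return bP * inhib;
  double s = (pO2 - pN) / (pP - pN);
  double g = linear_ramp ? s : std::pow(s, hn) / (1.0 + std::pow(s, hn));
  return bP * g * inhib;
}

// One synchronous update of the tumor lattice.  Decisions are made against a
// snapshot of the state at step entry; daughters placed this step never act
// this step.  Site exclusivity is enforced against the *current* grid when a
// daughter is placed.  All randomness flows through R's RNG so that
// set.seed() on the R side makes runs bit-reproducible.
// [[Rcpp::export]]
List ca_step_cpp(IntegerMatrix state, NumericMatrix exposure, IntegerMatrix clone_id,
                 NumericMatrix oxygen, NumericMatrix drug, List par, double t,
                 bool log_events) {
  const int nr = state.nrow(), nc = state.ncol();
  const double bP   = as<double>(par["birth_rate"]);
  const double pP   = as<double>(par["pO2_P"]);
  const double pN   = as<double>(par["pO2_N"]);
  const double hn   = as<double>(par["oxygen_hill_n"]);
  const bool linear_ramp = as<std::string>(par["oxygen_ramp"]) == "linear";
  const double eta  = as<double>(par["eta"]);
  const double alpha = as<double>(par["alpha"]);
  const double hh   = as<double>(par["drug_hill_h"]);
  const double dAs  = as<double>(par["d_A_star"]);
  const double dAm  = as<double>(par["d_A_max"]);
  const double dNs  = as<double>(par["d_N_star"]);
  const double TDA  = as<double>(par["T_D_apoptotic"]);
  const double TDN  = as<double>(par["T_D_necrotic"]);
  const double peri = as<double>(par["perinecrotic_prob"]);
  const bool peri_hazard = as<std::string>(par["perinecrotic_mode"]) == "hazard";
  const double dt   = as<double>(par["dt"]);
  const double mut  = as<double>(par["mutation_prob"]);
  const bool moore  = as<std::string>(par["neighborhood"]) == "moore";
  int next_clone    = as<int>(par["next_clone_id"]);

  IntegerMatrix s0 = clone(state); // snapshot for decisions

  const int ndir = moore ? 8 : 4;
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  const double p_lys_A = 1.0 - std::exp(-dt / TDA);
  const double p_lys_N = 1.0 - std::exp(-dt / TDN);
  const double p_necr  = 1.0 - std::exp(-dNs * dt);
  const double p_peri  = peri_hazard ? 1.0 - std::exp(-peri * dt) : peri;

  std::vector<int> ev_type, ev_i, ev_j, ev_clone;

  int nbi[8], nbj[8];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int st = s0(i, j);
      if (st == EMPTY) continue;

      if (st == APOPTOTIC || st == NECROTIC) {
        double pl = (st == APOPTOTIC) ? p_lys_A : p_lys_N;
        if (unif_rand() < pl) {
          state(i, j) = EMPTY;
          exposure(i, j) = 0.0;
          clone_id(i, j) = NA_INTEGER;
          if (log_events) { ev_type.push_back(4); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_clone.push_back(NA_INTEGER); }
        }
        continue;
      }

      // viable cell: accumulate drug exposure (rectangle rule, minutes)
      exposure(i, j) += drug(i, j) * dt * 60.0;
      const double E = exposure(i, j);
      const double R = hill(E, alpha, hh);
      const double pO2 = oxygen(i, j);

      // hypoxic necrosis first
      if (pO2 <= pN && unif_rand() < p_necr) {
        state(i, j) = NECROTIC;
        if (log_events) { ev_type.push_back(3); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_clone.push_back(clone_id(i, j)); }
        continue;
      }

      // perinecrotic contact necrosis
      bool near_necr = false;
      for (int d = 0; d < ndir; ++d) {
        int ii = i + dx8[d], jj = j + dy8[d];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && s0(ii, jj) == NECROTIC) { near_necr = true; break; }
      }
      if (near_necr && unif_rand() < p_peri) {
        state(i, j) = NECROTIC;
        if (log_events) { ev_type.push_back(3); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_clone.push_back(clone_id(i, j)); }
        continue;
      }

      // apoptosis
      const double dA = dAs + (dAm - dAs) * R;
      if (unif_rand() < 1.0 - std::exp(-dA * dt)) {
        state(i, j) = APOPTOTIC;
        if (log_events) { ev_type.push_back(2); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_clone.push_back(clone_id(i, j)); }
        continue;
      }

      // division into a uniformly chosen empty Moore/von-Neumann neighbour
      const double b = birth_rate_cpp(pO2, R, bP, pP, pN, hn, linear_ramp, eta);
      if (b > 0.0 && unif_rand() < 1.0 - std::exp(-b * dt)) {
        int nfree = 0;
        for (int d = 0; d < ndir; ++d) {
          int ii = i + dx8[d], jj = j + dy8[d];
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && state(ii, jj) == EMPTY) {
            nbi[nfree] = ii; nbj[nfree] = jj; ++nfree;
          }
        }
        if (nfree > 0) {
          int pick = (int)std::floor(unif_rand() * nfree);
          if (pick >= nfree) pick = nfree - 1;
          int ci = clone_id(i, j);
          if (mut > 0.0 && unif_rand() < mut) ci = ++next_clone;
          state(nbi[pick], nbj[pick]) = VIABLE;
          exposure(nbi[pick], nbj[pick]) = 0.0;
          clone_id(nbi[pick], nbj[pick]) = ci;
          if (log_events) { ev_type.push_back(1); ev_i.push_back(nbi[pick] + 1); ev_j.push_back(nbj[pick] + 1); ev_clone.push_back(ci); }
        }
      }
    }
  }

  List events;
  if (log_events) {
    events = List::create(_["type"] = wrap(ev_type), _["i"] = wrap(ev_i),
                          _["j"] = wrap(ev_j), _["clone_id"] = wrap(ev_clone),
                          _["t"] = t);
  }
  return List::create(_["next_clone_id"] = next_clone, _["events"] = events);
}

// Count of sites per state (empty, viable, apoptotic, necrotic)
// [[Rcpp::export]]
IntegerVector ca_counts_cpp(IntegerMatrix state) {
  IntegerVector out(4);
  for (int j = 0; j < state.ncol(); ++j)
    for (int i = 0; i < state.nrow(); ++i) out[state(i, j)]++;
  return out;
}
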