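// Individual-based lattice engine.
//
// State layout: nine per-box pools (substrate, enzyme, product x C, N, P),
// an integer genotype raster (0 = empty, 1..8 = genotype code with bits
// C*4 + N*2 + P), and per-microbe internal pools stored in parallel
// vectors. All randomness comes from one dedicated xoshiro256++ stream
// seeded from R's RNG at each exported entry point, so set.seed() on the
// R side makes whole runs reproducible.
//
// Per-minute process order (process-major):
//   substrate input, substrate decay, product decay, product diffusion,
//   enzyme decay, enzyme diffusion, product formation, uptake + enzyme
//   production, metabolism, death, reproduction.
// Processes whose per-box updates are independent (input, decay,
// formation, metabolism, mortality) sweep boxes in a fixed order; sweeps
// where order matters (diffusion exchanges, uptake from shared product
// pools, reproduction contests) use a fresh random permutation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

namespace {

// xoshiro256++ — a fast dedicated stream for the engine, seeded from
// R's RNG at every exported entry point so runs stay reproducible from
// set.seed() while the hot loop avoids per-draw calls into R.
struct FastRng {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  void seed_from_r() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next();  // warm up
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double uniform() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

static FastRng g_rng;

// Repeated small-fraction transfers drive far-field pools into the
// denormal range (~1e-320 fg, far below one atom), where x86 arithmetic
// is 10-100x slower. Flush denormals to zero inside the engine; the
// discarded mass is below any physical or ledger resolution.
struct DenormalGuard {
#ifdef __SSE2__
  unsigned int saved;
  DenormalGuard() : saved(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~DenormalGuard() { _mm_setcsr(saved); }
#endif
};

struct Cfg {
  int width, height;
  double dt;
  double input[3];
  double decay;
  double d_prod, d_enz;
  double vmax_form, km_form;
  double enz_per_area, area_to_mass, vmax_up, km_up;
  double e_constit, fac_frac;
  double cton_mic, ctop_mic, cton_enz, ctop_enz, resp_enz;
  double bmr, loss_factor;
  double division_mass, min_mass;
  double mortality, mutation_rate;
  bool mutation_enabled, well_mixed, torus;
};

Cfg parse_cfg(const List& cl) {
  Cfg c;
  c.width = as<int>(cl["width"]);
  c.height = as<int>(cl["height"]);
  c.dt = as<double>(cl["dt"]);
  NumericVector ir = cl["input_rate"];
  for (int i = 0; i < 3; ++i) c.input[i] = ir[i];
  c.decay = as<double>(cl["decay_rate"]);
  c.d_prod = as<double>(cl["product_diffusion"]);
  c.d_enz = as<double>(cl["enzyme_diffusion"]);
  c.vmax_form = as<double>(cl["Vmax_formation"]);
  c.km_form = as<double>(cl["Km_formation"]);
  c.enz_per_area = as<double>(cl["EnzPerArea"]);
  c.area_to_mass = as<double>(cl["AreaToMass"]);
  c.vmax_up = as<double>(cl["Vmax_uptake"]);
  c.km_up = as<double>(cl["Km_uptake"]);
  c.e_constit = as<double>(cl["EConstit"]);
  c.fac_frac = as<double>(cl["facultative_fraction"]);
  c.cton_mic = as<double>(cl["CtoN_mic"]);
  c.ctop_mic = as<double>(cl["CtoP_mic"]);
  c.cton_enz = as<double>(cl["CtoN_enz"]);
  c.ctop_enz = as<double>(cl["CtoP_enz"]);
  c.resp_enz = as<double>(cl["Resp_enz"]);
  c.bmr = as<double>(cl["BMR"]);
  c.loss_factor = as<double>(cl["loss_factor"]);
  c.division_mass = as<double>(cl["division_mass"]);
  c.min_mass = as<double>(cl["min_mass"]);
  c.mortality = as<double>(cl["mortality_rate"]);
  c.mutation_rate = as<double>(cl["mutation_rate"]);
  c.mutation_enabled = as<bool>(cl["mutation_enabled"]);
  c.well_mixed = as<bool>(cl["well_mixed"]);
  c.torus = as<bool>(cl["torus"]);
  return c;
}

// Ledger slots (cumulative fg since state creation).
enum LedgerSlot {
  L_INPUT_C, L_INPUT_N, L_INPUT_P,
  L_DECAY_C, L_DECAY_N, L_DECAY_P,
  L_RESP_C,             // BMR + enzyme-production respiration
  L_SEQ_N, L_SEQ_P,     // N / P incorporated into secreted enzymes
  L_DEPOLY_C, L_DEPOLY_N, L_DEPOLY_P,
  L_NSLOTS
};

struct State {
  int w, h, n;
  std::vector<double> sub[3], enz[3], prod[3];
  std::vector<int> geno;          // 0 empty, 1..8
  std::vector<double> poolC, poolN, poolP;
  std::vector<double> ledger;

  // neighbor table (torus or bounded), 8-neighborhood
  std::vector<int> nb;            // n x 8, -1 padding when bounded
  std::vector<int> nb_cnt;

  void build_neighbors(bool torus) {
    nb.assign((size_t)n * 8, -1);
    nb_cnt.assign(n, 0);
    for (int col = 0; col < w; ++col) {
      for (int row = 0; row < h; ++row) {
        int k = row + col * h, cnt = 0;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = row + dr, c2 = col + dc;
            if (torus) {
              r2 = (r2 + h) % h;
              c2 = (c2 + w) % w;
            } else if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) {
              continue;
            }
            nb[(size_t)k * 8 + cnt++] = r2 + c2 * h;
          }
        }
        nb_cnt[k] = cnt;
      }
    }
  }
};

State unpack_state(const List& sl, const Cfg& cfg) {
  State s;
  s.w = cfg.width;
  s.h = cfg.height;
  s.n = s.w * s.h;
  const char* keys[9] = {"substrate_C", "substrate_N", "substrate_P",
                         "enzyme_C", "enzyme_N", "enzyme_P",
                         "product_C", "product_N", "product_P"};
  for (int i = 0; i < 3; ++i) {
    s.sub[i] = as<std::vector<double> >(sl[keys[i]]);
    s.enz[i] = as<std::vector<double> >(sl[keys[3 + i]]);
    s.prod[i] = as<std::vector<double> >(sl[keys[6 + i]]);
  }
  s.geno = as<std::vector<int> >(sl["genotype"]);
  s.poolC = as<std::vector<double> >(sl["pool_C"]);
  s.poolN = as<std::vector<double> >(sl["pool_N"]);
  s.poolP = as<std::vector<double> >(sl["pool_P"]);
  s.ledger = as<std::vector<double> >(sl["ledger"]);
  if ((int)s.geno.size() != s.n)
    stop("state dimensions do not match config lattice size");
  if ((int)s.ledger.size() != L_NSLOTS) stop("malformed ledger");
  s.build_neighbors(cfg.torus);
  return s;
}

List pack_state(const State& s) {
  CharacterVector lnames = CharacterVector::create(
      "input_C", "input_N", "input_P", "decay_C", "decay_N", "decay_P",
      "respiration_C", "enzyme_N_sequestered", "enzyme_P_sequestered",
      "depoly_C", "depoly_N", "depoly_P");
  NumericVector led = wrap(s.ledger);
  led.attr("names") = lnames;
  return List::create(
      _["substrate_C"] = wrap(s.sub[0]), _["substrate_N"] = wrap(s.sub[1]),
      _["substrate_P"] = wrap(s.sub[2]),
      _["enzyme_C"] = wrap(s.enz[0]), _["enzyme_N"] = wrap(s.enz[1]),
      _["enzyme_P"] = wrap(s.enz[2]),
      _["product_C"] = wrap(s.prod[0]), _["product_N"] = wrap(s.prod[1]),
      _["product_P"] = wrap(s.prod[2]),
      _["genotype"] = wrap(s.geno),
      _["pool_C"] = wrap(s.poolC), _["pool_N"] = wrap(s.poolN),
      _["pool_P"] = wrap(s.poolP),
      _["ledger"] = led);
}

inline int rand_int(int k) {  // uniform on 0..k-1
  int r = (int)(g_rng.uniform() * k);
  return r >= k ? k - 1 : r;
}

void shuffle(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rand_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// ---- abiotic processes -----------------------------------------------

void proc_input(State& s, const Cfg& c) {
  for (int nu = 0; nu < 3; ++nu) {
    double add = c.input[nu] * c.dt;  // box area is 1 um^2
    if (add == 0) continue;
    for (int k = 0; k < s.n; ++k) s.sub[nu][k] += add;
    s.ledger[L_INPUT_C + nu] += add * s.n;
  }
}

void decay_vec(std::vector<double>& v, double frac, double& sink) {
  double lost = 0;
  for (size_t k = 0; k < v.size(); ++k) {
    double d = v[k] * frac;
    v[k] -= d;
    lost += d;
  }
  sink += lost;
}

void proc_substrate_decay(State& s, const Cfg& c) {
  for (int nu = 0; nu < 3; ++nu)
    decay_vec(s.sub[nu], c.decay * c.dt, s.ledger[L_DECAY_C + nu]);
}

void proc_product_decay(State& s, const Cfg& c) {
  for (int nu = 0; nu < 3; ++nu)
    decay_vec(s.prod[nu], c.decay * c.dt, s.ledger[L_DECAY_C + nu]);
}

void proc_enzyme_decay(State& s, const Cfg& c) {
  // all three enzyme pools are carbon mass
  for (int nu = 0; nu < 3; ++nu)
    decay_vec(s.enz[nu], c.decay * c.dt, s.ledger[L_DECAY_C]);
}

// One sweep: each box (random order) initiates one exchange per nutrient
// pool with a random partner; the transfer, frac * |difference|, moves
// from the higher to the lower concentration and is applied immediately.
void diffuse_pools(State& s, const Cfg& c, std::vector<double>* pools,
                   double rate, std::vector<int>& order) {
  double frac = rate * c.dt;
  if (frac <= 0) return;
  order.resize(s.n);
  for (int i = 0; i < s.n; ++i) order[i] = i;
  shuffle(order);
  for (int i = 0; i < s.n; ++i) {
    int k = order[i];
    // one random partner per initiating box, shared by the three
    // nutrient pools of the diffusing pool type
    int j;
    if (c.well_mixed) {
      if (s.n < 2) continue;
      j = rand_int(s.n - 1);
      if (j >= k) ++j;
    } else {
      int cnt = s.nb_cnt[k];
      if (cnt == 0) continue;
      j = s.nb[(size_t)k * 8 + rand_int(cnt)];
    }
    for (int nu = 0; nu < 3; ++nu) {
      std::vector<double>& p = pools[nu];
      double d = frac * (p[k] - p[j]);
      p[k] -= d;
      p[j] += d;
    }
  }
}

void proc_product_formation(State& s, const Cfg& c) {
  for (int k = 0; k < s.n; ++k) {
    for (int nu = 0; nu < 3; ++nu) {
      double S = s.sub[nu][k];
      if (S <= 0) continue;
      double d = s.enz[nu][k] * c.vmax_form * S / (c.km_form + S) * c.dt;
      if (d > S) d = S;
      s.sub[nu][k] -= d;
      s.prod[nu][k] += d;
      s.ledger[L_DEPOLY_C + nu] += d;
    }
  }
}

// ---- microbial processes ---------------------------------------------

inline void demand_flags(const Cfg& c, double C, double N, double P,
                         bool& dC, bool& dN, bool& dP) {
  // Equality counts as demand on both sides of the pair, so a perfectly
  // balanced microbe still feeds. Cross-multiplied to tolerate zero pools.
  dN = (C >= c.cton_mic * N);
  dP = (C >= c.ctop_mic * P);
  dC = (C <= c.cton_mic * N) || (C <= c.ctop_mic * P);
}

// Secrete enzyme of locus `loc`, scaling down so no pool goes negative.
// Uniform protein composition: every enzyme costs (1+Resp)*E carbon,
// E/CtoN_enz nitrogen, and E/CtoP_enz phosphorus.
void emit_enzyme(State& s, const Cfg& c, int k, int loc, double E) {
  if (E <= 0) return;
  double cC = (1.0 + c.resp_enz), cN = 1.0 / c.cton_enz,
         cP = 1.0 / c.ctop_enz;
  double scale = 1.0;
  if (cC * E > s.poolC[k]) scale = std::min(scale, s.poolC[k] / (cC * E));
  if (cN * E > s.poolN[k]) scale = std::min(scale, s.poolN[k] / (cN * E));
  if (cP * E > s.poolP[k]) scale = std::min(scale, s.poolP[k] / (cP * E));
  E *= scale;
  if (E <= 0) return;
  s.poolC[k] = std::max(0.0, s.poolC[k] - cC * E);
  s.poolN[k] = std::max(0.0, s.poolN[k] - cN * E);
  s.poolP[k] = std::max(0.0, s.poolP[k] - cP * E);
  s.enz[loc][k] += E;
  s.ledger[L_RESP_C] += c.resp_enz * E;
  s.ledger[L_SEQ_N] += cN * E;
  s.ledger[L_SEQ_P] += cP * E;
}

// Largest secretion that keeps a not-in-demand nutrient from crossing into
// demand, for the pair (C, X) with target T and enzyme C:X ratio ctox_enz.
// Returns +inf when the ratio moves away from the threshold.
double pair_cap(const Cfg& c, double C, double X, double T,
                double ctox_enz, bool x_in_demand, bool c_in_demand) {
  double costC = 1.0 + c.resp_enz, costX = 1.0 / ctox_enz;
  double inf = std::numeric_limits<double>::infinity();
  bool rising = (C * costX > X * costC);  // d(C/X)/dE > 0
  if (rising && !x_in_demand) {
    // C/X climbs toward T from below: stop exactly at T.
    double denom = T / ctox_enz - costC;
    if (denom <= 0) return 0.0;  // cannot cross without overshoot logic
    return std::max(0.0, (T * X - C) / denom);
  }
  if (!rising && !c_in_demand) {
    // C/X falls toward T from above: stop exactly at T.
    double denom = costC - T / ctox_enz;
    if (denom <= 0) return inf;
    return std::max(0.0, (C - T * X) / denom);
  }
  return inf;
}

void facultative_caps(const Cfg& c, double C, double N, double P,
                      double& capN_pair, double& capP_pair) {
  bool dC, dN, dP;
  demand_flags(c, C, N, P, dC, dN, dP);
  capN_pair = pair_cap(c, C, N, c.cton_mic, c.cton_enz, dN, dC);
  capP_pair = pair_cap(c, C, P, c.ctop_mic, c.ctop_enz, dP, dC);
}

void proc_uptake_production(State& s, const Cfg& c,
                            std::vector<int>& order) {
  order.clear();
  for (int k = 0; k < s.n; ++k)
    if (s.geno[k] > 0) order.push_back(k);
  shuffle(order);
  for (size_t i = 0; i < order.size(); ++i) {
    int k = order[i];
    int code = s.geno[k] - 1;  // bits: C*4 + N*2 + P
    bool has[3] = {(code & 4) != 0, (code & 2) != 0, (code & 1) != 0};
    double* pool[3] = {&s.poolC[k], &s.poolN[k], &s.poolP[k]};

    // demand evaluated once, before this step's uptake
    bool dC, dN, dP;
    demand_flags(c, s.poolC[k], s.poolN[k], s.poolP[k], dC, dN, dP);
    bool dem[3] = {dC, dN, dP};

    int perm[3] = {0, 1, 2};
    for (int a = 2; a > 0; --a) std::swap(perm[a], perm[rand_int(a + 1)]);

    double uptake[3] = {0, 0, 0};
    for (int a = 0; a < 3; ++a) {
      int nu = perm[a];
      if (!dem[nu]) continue;
      double prod = s.prod[nu][k];
      if (prod <= 0) continue;
      double cb = std::cbrt(s.poolC[k]);
      double u = c.enz_per_area * c.area_to_mass * cb * cb *
                 c.vmax_up * prod / (c.km_up + prod) * c.dt;
      if (u > prod) u = prod;
      s.prod[nu][k] -= u;
      *pool[nu] += u;
      uptake[nu] = u;
    }

    // constitutive: mandatory for every carried locus, scaled only by
    // what the internal pools can pay
    for (int a = 0; a < 3; ++a) {
      int loc = perm[a];
      if (!has[loc]) continue;
      emit_enzyme(s, c, k, loc, c.e_constit * s.poolC[k] * c.dt);
    }

    // facultative: only loci whose nutrient is still in demand, funded by
    // up to fac_frac of this step's uptake of that nutrient, capped so no
    // currently balanced nutrient is pushed into demand
    if (uptake[0] <= 0 && uptake[1] <= 0 && uptake[2] <= 0) continue;
    for (int a = 0; a < 3; ++a) {
      int loc = perm[a];
      if (!has[loc]) continue;
      if (uptake[loc] <= 0) continue;
      bool eC, eN, eP;
      demand_flags(c, s.poolC[k], s.poolN[k], s.poolP[k], eC, eN, eP);
      bool edem[3] = {eC, eN, eP};
      if (!edem[loc]) continue;
      double budget;
      if (loc == 0) budget = c.fac_frac * uptake[0];
      else if (loc == 1) budget = c.fac_frac * uptake[1] * c.cton_enz;
      else budget = c.fac_frac * uptake[2] * c.ctop_enz;
      if (budget <= 0) continue;
      double capN, capP;
      facultative_caps(c, s.poolC[k], s.poolN[k], s.poolP[k], capN, capP);
      double E = std::min(budget, std::min(capN, capP));
      emit_enzyme(s, c, k, loc, E);
    }
  }
}

void return_to_box(State& s, int k, double mC, double mN, double mP) {
  // half as substrate, half as product, per nutrient
  s.sub[0][k] += mC / 2; s.prod[0][k] += mC / 2;
  s.sub[1][k] += mN / 2; s.prod[1][k] += mN / 2;
  s.sub[2][k] += mP / 2; s.prod[2][k] += mP / 2;
}

void proc_metabolism(State& s, const Cfg& c) {
  for (int k = 0; k < s.n; ++k) {
    if (s.geno[k] == 0) continue;
    double dC = c.bmr * s.poolC[k] * c.dt;
    s.poolC[k] -= dC;
    s.ledger[L_RESP_C] += dC;
    double lN = std::min(s.poolN[k], c.loss_factor * dC / c.cton_mic);
    double lP = std::min(s.poolP[k], c.loss_factor * dC / c.ctop_mic);
    s.poolN[k] -= lN;
    s.poolP[k] -= lP;
    s.sub[1][k] += lN / 2; s.prod[1][k] += lN / 2;
    s.sub[2][k] += lP / 2; s.prod[2][k] += lP / 2;
  }
}

void kill_microbe(State& s, int k) {
  return_to_box(s, k, s.poolC[k], s.poolN[k], s.poolP[k]);
  s.geno[k] = 0;
  s.poolC[k] = s.poolN[k] = s.poolP[k] = 0;
}

void proc_death(State& s, const Cfg& c) {
  for (int k = 0; k < s.n; ++k) {
    if (s.geno[k] == 0) continue;
    bool dead = s.poolC[k] < c.min_mass;
    if (!dead) dead = (g_rng.uniform() < c.mortality * c.dt);
    if (dead) kill_microbe(s, k);
  }
}

void proc_reproduction(State& s, const Cfg& c, std::vector<int>& order,
                       std::vector<char>& placed) {
  order.clear();
  for (int k = 0; k < s.n; ++k)
    if (s.geno[k] > 0) order.push_back(k);
  shuffle(order);
  placed.assign(s.n, 0);
  for (size_t i = 0; i < order.size(); ++i) {
    int k = order[i];
    if (s.geno[k] == 0 || placed[k]) continue;
    if (s.poolC[k] < c.division_mass) continue;
    // split every pool in half; one daughter stays, one disperses
    double hC = s.poolC[k] / 2, hN = s.poolN[k] / 2, hP = s.poolP[k] / 2;
    s.poolC[k] = hC; s.poolN[k] = hN; s.poolP[k] = hP;
    int code = s.geno[k] - 1;
    if (c.mutation_enabled && c.mutation_rate > 0) {
      for (int b = 0; b < 3; ++b)
        if (g_rng.uniform() < c.mutation_rate) code ^= (4 >> b);
    }
    int cnt = s.nb_cnt[k];
    if (cnt == 0) continue;  // 1x1 bounded lattice: nowhere to go
    int j = s.nb[(size_t)k * 8 + rand_int(cnt)];
    if (s.geno[j] == 0) {
      s.geno[j] = code + 1;
      s.poolC[j] = hC; s.poolN[j] = hN; s.poolP[j] = hP;
      placed[j] = 1;
    } else if (g_rng.uniform() < 0.5) {
      // incumbent dies; its mass returns to the contested box
      kill_microbe(s, j);
      s.geno[j] = code + 1;
      s.poolC[j] = hC; s.poolN[j] = hN; s.poolP[j] = hP;
      placed[j] = 1;
    } else {
      // dispersing daughter dies in place
      return_to_box(s, j, hC, hN, hP);
    }
  }
}

int population(const State& s) {
  int tot = 0;
  for (int k = 0; k < s.n; ++k)
    if (s.geno[k] > 0) ++tot;
  return tot;
}

void one_step(State& s, const Cfg& c, std::vector<int>& ord,
              std::vector<char>& scratch) {
  proc_input(s, c);
  proc_substrate_decay(s, c);
  proc_product_decay(s, c);
  diffuse_pools(s, c, s.prod, c.d_prod, ord);
  proc_enzyme_decay(s, c);
  diffuse_pools(s, c, s.enz, c.d_enz, ord);
  proc_product_formation(s, c);
  proc_uptake_production(s, c, ord);
  proc_metabolism(s, c);
  proc_death(s, c);
  proc_reproduction(s, c, ord, scratch);
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List state, List config, int n_steps,
                  int metrics_every = 0, int snapshot_every = 0,
                  bool stop_when_extinct = false) {
  Cfg cfg = parse_cfg(config);
  State s = unpack_state(state, cfg);
  DenormalGuard ftz;
  g_rng.seed_from_r();
  std::vector<int> ord;
  ord.reserve(s.n);
  std::vector<char> scratch;

  int n_rows = (metrics_every > 0) ? n_steps / metrics_every : 0;
  NumericMatrix metrics(n_rows, 14);  // step, counts(8), total, div, depoly3
  std::vector<double> depoly_prev(3);
  for (int nu = 0; nu < 3; ++nu)
    depoly_prev[nu] = s.ledger[L_DEPOLY_C + nu];
  List snapshots;
  IntegerVector snap_steps;
  int row = 0;
  bool extinct_stop = false;

  for (int step = 1; step <= n_steps; ++step) {
    if (!extinct_stop) {
      one_step(s, cfg, ord, scratch);
      if (stop_when_extinct && population(s) == 0) extinct_stop = true;
    } else {
      // community extinct: only abiotic dynamics would continue; with
      // early stopping requested we freeze the state and pad metrics
    }
    if (metrics_every > 0 && step % metrics_every == 0) {
      double counts[8] = {0};
      for (int k = 0; k < s.n; ++k)
        if (s.geno[k] > 0) counts[s.geno[k] - 1] += 1;
      double tot = 0, ss = 0;
      for (int g = 0; g < 8; ++g) tot += counts[g];
      if (tot > 0)
        for (int g = 0; g < 8; ++g) ss += (counts[g] / tot) * (counts[g] / tot);
      metrics(row, 0) = step;
      for (int g = 0; g < 8; ++g) metrics(row, 1 + g) = counts[g];
      metrics(row, 9) = tot;
      metrics(row, 10) = tot > 0 ? 1.0 - ss : 0.0;
      for (int nu = 0; nu < 3; ++nu) {
        metrics(row, 11 + nu) = s.ledger[L_DEPOLY_C + nu] - depoly_prev[nu];
        depoly_prev[nu] = s.ledger[L_DEPOLY_C + nu];
      }
      ++row;
    }
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      IntegerMatrix snap(s.h, s.w);
      for (int k = 0; k < s.n; ++k) snap[k] = s.geno[k];
      snapshots.push_back(snap);
      snap_steps.push_back(step);
    }
    if (step % 4096 == 0) checkUserInterrupt();
  }
  if (row < n_rows) {
    metrics = (row == 0) ? NumericMatrix(0, 14)
                         : NumericMatrix(metrics(Range(0, row - 1), _));
  }
  return List::create(_["state"] = pack_state(s),
                      _["metrics"] = metrics,
                      _["snapshots"] = snapshots,
                      _["snapshot_steps"] = snap_steps,
                      _["extinct_early"] = extinct_stop);
}

// Run a single named process once (test access to the engine internals).
// [[Rcpp::export]]
List cpp_process(List state, List config, std::string process) {
  Cfg cfg = parse_cfg(config);
  State s = unpack_state(state, cfg);
  DenormalGuard ftz;
  g_rng.seed_from_r();
  std::vector<int> ord;
  std::vector<char> scratch;
  if (process == "input") proc_input(s, cfg);
  else if (process == "substrate_decay") proc_substrate_decay(s, cfg);
  else if (process == "product_decay") proc_product_decay(s, cfg);
  else if (process == "product_diffusion")
    diffuse_pools(s, cfg, s.prod, cfg.d_prod, ord);
  else if (process == "enzyme_decay") proc_enzyme_decay(s, cfg);
  else if (process == "enzyme_diffusion")
    diffuse_pools(s, cfg, s.enz, cfg.d_enz, ord);
  else if (process == "product_formation") proc_product_formation(s, cfg);
  else if (process == "uptake_production")
    proc_uptake_production(s, cfg, ord);
  else if (process == "metabolism") proc_metabolism(s, cfg);
  else if (process == "death") proc_death(s, cfg);
  else if (process == "reproduction")
    proc_reproduction(s, cfg, ord, scratch);
  else stop("unknown process: " + process);
  return pack_state(s);
}

// Diffuse one named pool for one sweep at the given rate.
// [[Rcpp::export]]
List cpp_diffuse_pool(List state, List config, std::string pool,
                      double rate) {
  Cfg cfg = parse_cfg(config);
  State s = unpack_state(state, cfg);
  DenormalGuard ftz;
  g_rng.seed_from_r();
  std::vector<int> ord;
  std::vector<double>* pools = NULL;
  if (pool == "product") pools = s.prod;
  else if (pool == "enzyme") pools = s.enz;
  else stop("only product and enzyme pools diffuse");
  diffuse_pools(s, cfg, pools, rate, ord);
  return pack_state(s);
}
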