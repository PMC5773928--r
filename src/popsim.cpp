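#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Stage codes: 0 egg, 1 larva, 2 pupa, 3 immature adult, 4 mature adult.
// Sex codes: -1 unassigned (juvenile), 0 female, 1 male.
// Mated codes: 0 unmated, 1 fertile_mated, 2 sterile_mated.

struct Params {
  double dd[4];    // per-stage thermal requirement, DDc
  double base[4];  // per-stage base temperature, degC
  double mu[5];    // per-stage daily baseline mortality
  double control;  // daily control-effort mortality, all stages
  double p_sit;    // daily probability an unmated female is sterilised
  double fecundity;      // eggs/female/day at the 25 degC reference
  double cold_lethal, p_cold;
  double heat_lethal, p_heat;
};

struct Pop {
  std::vector<int> stage, sex, mated;
  std::vector<double> dev;
  std::vector<int> alive;
  size_t size() const { return stage.size(); }
  int n_alive() const {
    int k = 0;
    for (size_t i = 0; i < alive.size(); ++i) k += alive[i];
    return k;
  }
};

static Params parse_params(const NumericVector& p) {
  Params pr;
  const char* dd_names[4] = {"dd_egg", "dd_larva", "dd_pupa", "dd_immature_adult"};
  const char* base_names[4] = {"base_egg", "base_larva", "base_pupa", "base_immature_adult"};
  const char* mu_names[5] = {"mu_egg", "mu_larva", "mu_pupa", "mu_immature_adult", "mu_mature_adult"};
  for (int s = 0; s < 4; ++s) {
    pr.dd[s] = p[dd_names[s]];
    pr.base[s] = p[base_names[s]];
  }
  for (int s = 0; s < 5; ++s) pr.mu[s] = p[mu_names[s]];
  pr.control = p["control_mortality_daily"];
  pr.p_sit = p["p_sit_daily"];
  pr.fecundity = p["fecundity"];
  pr.cold_lethal = p["cold_lethal_c"];
  pr.p_cold = p["p_cold_hourly"];
  pr.heat_lethal = p["heat_lethal_c"];
  pr.p_heat = p["p_heat_hourly"];
  return pr;
}

// Per-day summaries shared by every agent in a simulation: hourly prefix
// sums of degree-day increments per stage (all agents share the stage base
// temperatures within one parameter vector), lethal-hour counts, and the
// daily mean temperature.
struct DaySummary {
  double csum[4][25];  // csum[s][h] = development gained in hours [0, h)
  int n_cold, n_heat;
  double tbar;
};

static DaySummary summarise_day(const double* T, const Params& pr) {
  DaySummary ds;
  ds.n_cold = ds.n_heat = 0;
  ds.tbar = 0.0;
  for (int s = 0; s < 4; ++s) ds.csum[s][0] = 0.0;
  for (int h = 0; h < 24; ++h) {
    ds.tbar += T[h];
    if (T[h] < pr.cold_lethal) ++ds.n_cold;
    if (T[h] > pr.heat_lethal) ++ds.n_heat;
    for (int s = 0; s < 4; ++s) {
      double inc = T[h] - pr.base[s];
      ds.csum[s][h + 1] = ds.csum[s][h] + (inc > 0 ? inc / 24.0 : 0.0);
    }
  }
  ds.tbar /= 24.0;
  return ds;
}

// One simulated day. Event order is fixed: development, acute (hourly)
// temperature mortality, daily baseline + control mortality, mating,
// oviposition. Reordering these changes trajectories.
static void step_day_core(Pop& pop, const DaySummary& ds, const Params& pr) {
  const size_t n0 = pop.size();

  // (1) hourly degree-day development for pre-mature stages; surplus
  // degree-days carry into the next stage; sex assigned at adult emergence.
  // Equivalent to accumulating hour by hour: the prefix sums locate the
  // first hour at which the stage requirement is met.
  for (size_t i = 0; i < n0; ++i) {
    if (!pop.alive[i] || pop.stage[i] >= 4) continue;
    int h0 = 0;
    while (h0 < 24 && pop.stage[i] < 4) {
      int s = pop.stage[i];
      double gain = ds.csum[s][24] - ds.csum[s][h0];
      double need = pr.dd[s] - pop.dev[i];
      if (gain < need) {  // no advancement today in this stage
        pop.dev[i] += gain;
        break;
      }
      // first hour h (h0 < h <= 24) whose cumulative gain reaches the need
      int h = h0 + 1;
      while (ds.csum[s][h] - ds.csum[s][h0] < need) ++h;
      pop.dev[i] += ds.csum[s][h] - ds.csum[s][h0];
      pop.dev[i] -= pr.dd[s];
      pop.stage[i] += 1;
      if (pop.stage[i] == 3 && pop.sex[i] < 0) {
        pop.sex[i] = (unif_rand() < 0.5) ? 0 : 1;
      }
      h0 = h;
    }
  }

  // (2) acute hourly temperature mortality (development above completes
  // before any acute death, so per-hour Bernoulli deaths combine exactly
  // into one survival probability per agent)
  if (ds.n_cold > 0 || ds.n_heat > 0) {
    double surv = std::pow(1.0 - pr.p_cold, ds.n_cold) * std::pow(1.0 - pr.p_heat, ds.n_heat);
    if (surv < 1.0) {
      for (size_t i = 0; i < n0; ++i) {
        if (pop.alive[i] && unif_rand() >= surv) pop.alive[i] = 0;
      }
    }
  }

  // (3) daily baseline + control mortality as independent hazards
  for (size_t i = 0; i < n0; ++i) {
    if (!pop.alive[i]) continue;
    double pd = 1.0 - (1.0 - pr.mu[pop.stage[i]]) * (1.0 - pr.control);
    if (pd > 0 && unif_rand() < pd) pop.alive[i] = 0;
  }

  // (4) mating: one lifetime mating; daily sterilisation draw first
  int n_males = 0;
  for (size_t i = 0; i < n0; ++i) {
    if (pop.alive[i] && pop.stage[i] == 4 && pop.sex[i] == 1) ++n_males;
  }
  for (size_t i = 0; i < n0; ++i) {
    if (!pop.alive[i] || pop.stage[i] != 4 || pop.sex[i] != 0 || pop.mated[i] != 0) continue;
    if (unif_rand() < pr.p_sit) {
      pop.mated[i] = 2;
    } else if (n_males > 0) {
      pop.mated[i] = 1;
    }
  }

  // (5) oviposition by fertile females, scaled by mean-temperature
  // development rate relative to the 25 degC reference
  double scale = (ds.tbar - pr.base[0]) / (25.0 - pr.base[0]);
  if (scale < 0) scale = 0;
  double lambda = pr.fecundity * scale;
  if (lambda > 0) {
    int births = 0;
    for (size_t i = 0; i < n0; ++i) {
      if (pop.alive[i] && pop.stage[i] == 4 && pop.sex[i] == 0 && pop.mated[i] == 1) {
        births += (int) R::rpois(lambda);
      }
    }
    for (int b = 0; b < births; ++b) {
      pop.stage.push_back(0);
      pop.sex.push_back(-1);
      pop.mated.push_back(0);
      pop.dev.push_back(0.0);
      pop.alive.push_back(1);
    }
  }
}

static Pop pop_from_r(const IntegerVector& stage, const IntegerVector& sex,
                      const NumericVector& dev, const IntegerVector& mated,
                      const LogicalVector& alive) {
  Pop pop;
  size_t n = stage.size();
  pop.stage.assign(stage.begin(), stage.end());
  pop.sex.assign(sex.begin(), sex.end());
  pop.mated.assign(mated.begin(), mated.end());
  pop.dev.assign(dev.begin(), dev.end());
  pop.alive.resize(n);
  for (size_t i = 0; i < n; ++i) pop.alive[i] = alive[i] ? 1 : 0;
  return pop;
}

// [[Rcpp::export]]
List sim_step_day_cpp(IntegerVector stage, IntegerVector sex, NumericVector dev,
                      IntegerVector mated, LogicalVector alive,
                      NumericVector day_hours, NumericVector params) {
  if (day_hours.size() != 24) stop("day_hours must have exactly 24 values");
  Params pr = parse_params(params);
  Pop pop = pop_from_r(stage, sex, dev, mated, alive);
  DaySummary ds = summarise_day(day_hours.begin(), pr);
  step_day_core(pop, ds, pr);
  size_t n = pop.size();
  LogicalVector alive_out(n);
  for (size_t i = 0; i < n; ++i) alive_out[i] = pop.alive[i] != 0;
  return List::create(
    _["stage"] = IntegerVector(pop.stage.begin(), pop.stage.end()),
    _["sex"] = IntegerVector(pop.sex.begin(), pop.sex.end()),
    _["dev_accum"] = NumericVector(pop.dev.begin(), pop.dev.end()),
    _["mated"] = IntegerVector(pop.mated.begin(), pop.mated.end()),
    _["alive"] = alive_out);
}

// [[Rcpp::export]]
List sim_run_cpp(NumericVector temps, int start_hour, int max_days,
                 IntegerVector stage, IntegerVector sex, NumericVector dev,
                 IntegerVector mated, LogicalVector alive, NumericVector params,
                 int max_population) {
  Params pr = parse_params(params);
  Pop pop = pop_from_r(stage, sex, dev, mated, alive);

  int n_hours = temps.size() - start_hour;
  int n_days = n_hours / 24;
  if (n_days > max_days) n_days = max_days;

  int peak = pop.n_alive();
  if (peak == 0) {
    return List::create(_["elimination_day"] = 0, _["censored"] = false,
                        _["peak_population"] = 0);
  }

  for (int d = 1; d <= n_days; ++d) {
    const double* T = temps.begin() + start_hour + (d - 1) * 24;
    DaySummary ds = summarise_day(T, pr);
    step_day_core(pop, ds, pr);

    // compact the dead to keep the agent vectors small
    size_t w = 0;
    for (size_t i = 0; i < pop.size(); ++i) {
      if (pop.alive[i]) {
        pop.stage[w] = pop.stage[i];
        pop.sex[w] = pop.sex[i];
        pop.mated[w] = pop.mated[i];
        pop.dev[w] = pop.dev[i];
        pop.alive[w] = 1;
        ++w;
      }
    }
    pop.stage.resize(w); pop.sex.resize(w); pop.mated.resize(w);
    pop.dev.resize(w); pop.alive.resize(w);

    int n_now = (int) w;
    if (n_now > peak) peak = n_now;
    if (n_now == 0) {
      return List::create(_["elimination_day"] = d, _["censored"] = false,
                          _["peak_population"] = peak);
    }
    // a population far beyond outbreak scale is not being eliminated:
    // censor rather than simulate unbounded growth
    if (n_now > max_population) break;
  }
  return List::create(_["elimination_day"] = NA_INTEGER, _["censored"] = true,
                      _["peak_population"] = peak);
}

// Rolling median of neighbours within +/- window_sec of each record's own
// time, excluding the record itself; NA where no neighbour exists.
// [[Rcpp::export]]
NumericVector rolling_time_median_cpp(NumericVector t, NumericVector x,
                                      double window_sec) {
  int n = t.size();
  NumericVector out(n);
  std::vector<double> buf;
  int lo = 0, hi = 0;
  for (int i = 0; i < n; ++i) {
    while (lo < n && t[lo] < t[i] - window_sec) ++lo;
    if (hi < i) hi = i;
    while (hi + 1 < n && t[hi + 1] <= t[i] + window_sec) ++hi;
    buf.clear();
    for (int j = lo; j <= hi; ++j) {
      if (j != i) buf.push_back(x[j]);
    }
    if (buf.empty()) {
      out[i] = NA_REAL;
      continue;
    }
    size_t m = buf.size() / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double med = buf[m];
    if (buf.size() % 2 == 0) {
      double lo_m = *std::max_element(buf.begin(), buf.begin() + m);
      med = (med + lo_m) / 2.0;
    }
    out[i] = med;
  }
  return out;
}
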