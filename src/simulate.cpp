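// Compiled natural-history population simulator.
//
// Each agent owns a counter-based RNG stream (splitmix64 seeded from the
// population seed and the agent index), so simulated outcomes are invariant
// to agent ordering and to how a population is partitioned across batches.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1); never exactly 0 or 1
  double unif() {
    double u = (next() >> 11) * (1.0 / 9007199254740992.0);
    if (u <= 0.0) u = 5e-324;
    if (u >= 1.0) u = 1.0 - 1e-16;
    return u;
  }
  double norm() { return R::qnorm(unif(), 0.0, 1.0, 1, 0); }
};

struct NhParams {
  double A, sigma_alpha, alpha1, alpha20, alpha50, alpha60, alpha70;
  double beta1_colon, beta2_colon, beta1_rectum, beta2_rectum;
  double p_growth, gamma0, gamma1, gamma2, gamma3, gamma4, gamma5, sigma_gamma;
  double lambda1, lambda2, lambda3, d0, d_infinity;
};

NhParams unpack(const NumericVector& p) {
  NhParams q;
  q.A = p["A"]; q.sigma_alpha = p["sigma_alpha"]; q.alpha1 = p["alpha1"];
  q.alpha20 = p["alpha20"]; q.alpha50 = p["alpha50"];
  q.alpha60 = p["alpha60"]; q.alpha70 = p["alpha70"];
  q.beta1_colon = p["beta1_colon"]; q.beta2_colon = p["beta2_colon"];
  q.beta1_rectum = p["beta1_rectum"]; q.beta2_rectum = p["beta2_rectum"];
  q.p_growth = p["p_growth"];
  q.gamma0 = p["gamma0"]; q.gamma1 = p["gamma1"]; q.gamma2 = p["gamma2"];
  q.gamma3 = p["gamma3"]; q.gamma4 = p["gamma4"]; q.gamma5 = p["gamma5"];
  q.sigma_gamma = p["sigma_gamma"];
  q.lambda1 = p["lambda1"]; q.lambda2 = p["lambda2"]; q.lambda3 = p["lambda3"];
  q.d0 = p["d0"]; q.d_infinity = p["d_infinity"];
  return q;
}

double log_risk(double age, int female, double alpha0, const NhParams& p) {
  if (age < 20.0) return R_NegInf;
  double lr = alpha0 + p.alpha1 * female;
  lr += std::min(age - 20.0, 30.0) * p.alpha20;
  if (age > 50.0) lr += std::min(age - 50.0, 10.0) * p.alpha50;
  if (age > 60.0) lr += std::min(age - 60.0, 10.0) * p.alpha60;
  if (age > 70.0) lr += (age - 70.0) * p.alpha70;
  return lr;
}

double richards(double t, double lam, const NhParams& p) {
  double b = std::pow(p.d0 / p.d_infinity, 1.0 / p.p_growth) - 1.0;
  return p.d_infinity * std::pow(1.0 + b * std::exp(-lam * t), p.p_growth);
}

double growth_rate(double t10, const NhParams& p) {
  double num = std::pow(10.0 / p.d_infinity, 1.0 / p.p_growth) - 1.0;
  double den = std::pow(p.d0 / p.d_infinity, 1.0 / p.p_growth) - 1.0;
  return -std::log(num / den) / t10;
}

// time for diameter to reach d; +Inf if d >= d_infinity
double time_to_size(double d, double lam, const NhParams& p) {
  if (d >= p.d_infinity) return R_PosInf;
  if (d <= p.d0) return 0.0;
  double num = std::pow(d / p.d_infinity, 1.0 / p.p_growth) - 1.0;
  double den = std::pow(p.d0 / p.d_infinity, 1.0 / p.p_growth) - 1.0;
  double t = -std::log(num / den) / lam;
  return t > 0.0 ? t : 0.0;
}

double sample_death(SplitMix64& rng, const NumericVector& edges,
                    const NumericVector& haz, double max_age) {
  // piecewise-exponential inversion over [edges, max_age]
  double target = -std::log1p(-rng.unif());
  int k = haz.size();
  double cum = 0.0;
  for (int i = 0; i < k; ++i) {
    double hi = (i + 1 < k) ? edges[i + 1] : max_age;
    double seg = (hi - edges[i]) * haz[i];
    if (cum + seg >= target)
      return std::min(edges[i] + (target - cum) / haz[i], max_age);
    cum += seg;
  }
  return max_age;
}

double sens_interp(double size, const NumericVector& sx,
                   const NumericVector& sy) {
  int k = sx.size();
  if (size <= sx[0]) return sy[0];
  if (size >= sx[k - 1]) return sy[k - 1];
  int i = 0;
  while (i + 1 < k && sx[i + 1] < size) ++i;
  double w = (size - sx[i]) / (sx[i + 1] - sx[i]);
  return sy[i] + w * (sy[i + 1] - sy[i]);
}

}  // namespace

// [[Rcpp::export(name = ".simulate_population_cpp")]]
List simulate_population_cpp(NumericVector params,
                             IntegerVector female,
                             NumericVector index_age,
                             double p_rectum,
                             NumericVector lt_edges,
                             NumericVector lt_hazards,
                             double lt_max_age,
                             int screen_test,  // 0 none, 1 colonoscopy, 2 sigmoidoscopy
                             NumericVector sens_x,
                             NumericVector sens_y,
                             double preclin_floor,
                             double sigmoid_colon_reach,
                             double horizon,
                             double seed,
                             int agent_offset = 0) {
  NhParams p = unpack(params);
  int n = female.size();
  uint64_t base_seed = (uint64_t)seed;

  NumericVector death_age(n), clinical_age(n);
  IntegerVector eligible(n), n_det_aden(n), n_det_preclin(n);
  std::vector<int> les_agent;
  std::vector<double> les_size;
  std::vector<int> les_preclin;
  std::vector<int> les_rectum;

  double knots[4] = {20.0, 50.0, 60.0, 70.0};

  for (int i = 0; i < n; ++i) {
    SplitMix64 rng(base_seed ^ ((uint64_t)(i + 1 + agent_offset) * 0xD1B54A32D192ED03ULL));
    double alpha0 = p.A + p.sigma_alpha * rng.norm();
    double dage = sample_death(rng, lt_edges, lt_hazards, lt_max_age);
    death_age[i] = dage;
    double hor = std::min(horizon, dage);

    // adenoma initiations: NHPP by thinning with per-segment constant majorant
    std::vector<double> init_age;
    std::vector<int> rectum;
    for (int s = 0; s < 4; ++s) {
      double a0 = knots[s];
      double a1 = (s < 3) ? std::min(knots[s + 1], hor) : hor;
      if (a1 <= a0) break;
      double lmax = std::max(log_risk(a0, female[i], alpha0, p),
                             log_risk(a1, female[i], alpha0, p));
      if (!R_finite(lmax)) {
        if (lmax == R_NegInf) continue;
        stop("non-finite adenoma intensity");
      }
      double m = std::exp(lmax);
      double t = a0;
      while (true) {
        t += -std::log1p(-rng.unif()) / m;
        if (t > a1) break;
        if (rng.unif() < std::exp(log_risk(t, female[i], alpha0, p) - lmax)) {
          init_age.push_back(t);
          rectum.push_back(rng.unif() < p_rectum ? 1 : 0);
        }
      }
    }

    // per-adenoma growth, transition, sojourn
    double cl = R_PosInf;
    int m = (int)init_age.size();
    std::vector<double> lam(m), t_trans(m), t_clin(m);
    for (int j = 0; j < m; ++j) {
      double shape = rectum[j] ? p.beta1_rectum : p.beta1_colon;
      double scale = rectum[j] ? p.beta2_rectum : p.beta2_colon;
      double t10 = scale * std::pow(-std::log(rng.unif()), -1.0 / shape);
      lam[j] = growth_rate(t10, p);
      double ag = (init_age[j] - 50.0) / 10.0;
      double mu = p.gamma0 + p.gamma1 * female[i] + p.gamma2 * rectum[j] +
                  p.gamma3 * female[i] * rectum[j] + p.gamma4 * ag +
                  p.gamma5 * ag * ag;
      double tsize = std::exp(mu + p.sigma_gamma * rng.norm());
      double tt = time_to_size(tsize, lam[j], p);
      double ta = init_age[j] + tt;
      if (ta <= horizon) {
        double soj_scale = p.lambda1 * (rectum[j] ? std::exp(p.lambda3) : 1.0);
        double soj = soj_scale *
            std::pow(-std::log1p(-rng.unif()), 1.0 / p.lambda2);
        t_trans[j] = ta;
        t_clin[j] = ta + soj;
        if (t_clin[j] < cl) cl = t_clin[j];
      } else {
        t_trans[j] = R_PosInf;
        t_clin[j] = R_PosInf;
      }
    }
    if (cl >= std::min(dage, horizon)) cl = R_PosInf;
    clinical_age[i] = cl;

    double s_age = index_age[i];
    bool elig = (dage > s_age) && (cl > s_age);
    eligible[i] = elig ? 1 : 0;

    // one-time screening of eligible agents
    if (screen_test > 0 && elig) {
      for (int j = 0; j < m; ++j) {
        if (init_age[j] > s_age) continue;
        bool is_pre = (t_trans[j] <= s_age);
        if (is_pre && t_clin[j] <= s_age) continue;  // clinical: excluded upstream
        double size = richards(s_age - init_age[j], lam[j], p);
        double sens = sens_interp(size, sens_x, sens_y);
        if (is_pre && sens < preclin_floor) sens = preclin_floor;
        double reach = 1.0;
        if (screen_test == 2 && !rectum[j]) reach = sigmoid_colon_reach;
        if (rng.unif() < sens * reach) {
          if (is_pre) n_det_preclin[i]++; else n_det_aden[i]++;
          les_agent.push_back(i + 1);
          les_size.push_back(size);
          les_preclin.push_back(is_pre ? 1 : 0);
          les_rectum.push_back(rectum[j]);
        }
      }
    }
  }

  return List::create(
      _["death_age"] = death_age,
      _["clinical_age"] = clinical_age,
      _["eligible"] = eligible,
      _["n_det_adenoma"] = n_det_aden,
      _["n_det_preclin"] = n_det_preclin,
      _["lesion_agent"] = wrap(les_agent),
      _["lesion_size"] = wrap(les_size),
      _["lesion_preclin"] = wrap(les_preclin),
      _["lesion_rectum"] = wrap(les_rectum));
}
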