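// Monte-Carlo / KDE response log-likelihood, the inner loop of model
// fitting. Mirrors the R reference implementation (estimate_heading()
// plus kde_loglik()); the test suite asserts the two paths agree.

#include <Rcpp.h>
using namespace Rcpp;

// model codes (kept in sync with .model_code() on the R side)
enum ModelCode {
  CCI = 1, INTEGRATION = 2, SEGREGATION = 3, COVARIANCE = 4,
  FIXED = 5, HEURISTIC = 6, WTA = 7, MCI = 8, VARIABLE_WEIGHT = 9
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// posterior weight of the first alternative from two log-likelihoods and
// a prior probability, numerically safe at the prior's endpoints
static inline double post_w1(double ll1, double ll2, double p) {
  if (p >= 1.0) return 1.0;
  if (p <= 0.0) return 0.0;
  return 1.0 / (1.0 + std::exp(ll2 + std::log1p(-p) - ll1 - std::log(p)));
}

// [[Rcpp::export(name = ".mc_kde_loglik_cpp")]]
double mc_kde_loglik_cpp(int model,
                         List par,
                         NumericVector s_self,
                         NumericVector s_env,
                         NumericVector s_env0,
                         LogicalVector const_flag,
                         NumericMatrix z_vest,
                         NumericMatrix z_vis,
                         NumericMatrix z_vis0,
                         NumericVector resp,
                         IntegerVector resp_cond,  // 1-based condition index
                         double ref_speed,
                         double density_floor,
                         double bw_floor) {
  const int nc = s_self.size();
  const int n_mc = z_vest.ncol();
  const int nr = resp.size();

  auto getp = [&par](const char* nm) {
    return par.containsElementNamed(nm) ? as<double>(par[nm]) : NA_REAL;
  };
  const double sigma_self = getp("sigma_self");
  const double sigma_env = getp("sigma_env");
  const double sigma_vest = getp("sigma_vest");
  const double w_vis = getp("w_vis");
  const double p_constant = getp("p_constant");
  const double rho = getp("rho");
  const double a_vest = getp("alpha_vest");
  const double a_mom = getp("alpha_mom");
  const double a_cont = getp("alpha_cont");
  const double p_common = getp("p_common");
  const double alpha_1 = getp("alpha_1");
  const double alpha_2 = getp("alpha_2");
  const double eps = as<double>(par["noise_floor"]);

  const double s_self2 = sigma_self * sigma_self;
  const double s_env2 = sigma_env * sigma_env;
  const double v_vest2 = sigma_vest * sigma_vest;
  const double w_vest = 1.0 / v_vest2;
  const double w_prior = 1.0 / s_self2;
  const double LOG2PI = std::log(2.0 * M_PI);

  // group responses by condition once
  std::vector<std::vector<int>> by_cond(nc);
  for (int j = 0; j < nr; ++j) {
    int c = resp_cond[j] - 1;
    if (c < 0 || c >= nc) stop("response condition index out of range");
    by_cond[c].push_back(j);
  }

  std::vector<double> sims(n_mc);
  double total = 0.0;

  for (int i = 0; i < nc; ++i) {
    const double mu_vest = s_self[i];
    const double mu_vis = s_self[i] - s_env[i];
    const double mu_vis0 = -s_env0[i];
    const double sd_vis = std::max(eps, w_vis * std::fabs(mu_vis));
    const double sd_vis0 = std::max(eps, w_vis * std::fabs(s_env0[i]));
    const double v_vis2 = sd_vis * sd_vis;
    const double v_vis0_2 = sd_vis0 * sd_vis0;

    // per-condition constants of the cue summaries
    const double shrink = s_env2 / (s_env2 + v_vis0_2);
    const double s2K1 = v_vis2 + s_env2 * v_vis0_2 / (s_env2 + v_vis0_2);
    const double s2K2 = v_vis2 + s_env2;
    const double wK1 = 1.0 / s2K1;
    const double wK2 = 1.0 / s2K2;
    const double denom1 = w_vest + wK1 + w_prior;
    const double denom2 = w_vest + wK2 + w_prior;
    // marginal-likelihood constants of the two structures
    const double D1 = v_vest2 * s2K1 + v_vest2 * s_self2 + s2K1 * s_self2;
    const double D2 = v_vest2 * s2K2 + v_vest2 * s_self2 + s2K2 * s_self2;
    const double halflogD1 = 0.5 * std::log(D1);
    const double halflogD2 = 0.5 * std::log(D2);
    // covariance-model constants
    double s2Kc = 0.0, wKc = 0.0, denomc = 0.0;
    if (model == COVARIANCE) {
      s2Kc = v_vis2 + s_env2 * (1.0 - rho * rho * shrink);
      wKc = 1.0 / s2Kc;
      denomc = w_vest + wKc + w_prior;
    }
    // mci constants (its own assumed visual noise)
    double sd_vis_m = 0.0, v_vis_m2 = 0.0, w_vis_m = 0.0, Dm1 = 0.0;
    double halflogDm1 = 0.0, halflogDm2 = 0.0;
    if (model == MCI) {
      sd_vis_m = std::max(eps, w_vis * std::fabs(s_env[i]));
      v_vis_m2 = sd_vis_m * sd_vis_m;
      w_vis_m = 1.0 / v_vis_m2;
      Dm1 = v_vest2 * v_vis_m2 + v_vest2 * s_self2 + v_vis_m2 * s_self2;
      halflogDm1 = 0.5 * std::log(Dm1);
      halflogDm2 = 0.5 * std::log((v_vest2 + s_self2) * (v_vis_m2 + s_self2));
    }
    const double aw = const_flag[i] ? alpha_1 : alpha_2;

    double sum = 0.0, sumsq = 0.0;
    for (int k = 0; k < n_mc; ++k) {
      const double xv = mu_vest + sigma_vest * z_vest(i, k);
      const double x1 = mu_vis + sd_vis * z_vis(i, k);
      const double x0 = mu_vis0 + sd_vis0 * z_vis0(i, k);
      double est = 0.0;

      if (model == FIXED) {
        est = a_vest * xv + a_mom * x1 + a_cont * (x1 - x0);
      } else if (model == MCI) {
        const double Q1 = (xv - x1) * (xv - x1) * s_self2 +
          xv * xv * v_vis_m2 + x1 * x1 * v_vest2;
        const double ll1 = -LOG2PI - halflogDm1 - 0.5 * Q1 / Dm1;
        const double ll2 = -LOG2PI - halflogDm2 -
          0.5 * (xv * xv / (v_vest2 + s_self2) + x1 * x1 / (v_vis_m2 + s_self2));
        const double p1 = post_w1(ll1, ll2, p_common);
        const double e1 = (xv * w_vest + x1 * w_vis_m) /
          (w_vest + w_vis_m + w_prior);
        const double e2 = (xv * w_vest) / (w_vest + w_prior);
        est = p1 * e1 + (1.0 - p1) * e2;
      } else if (model == COVARIANCE) {
        const double muKc = x1 - rho * shrink * x0;
        est = (xv * w_vest + muKc * wKc) / denomc;
      } else {
        const double mu1 = x1 - shrink * x0;
        const double mu2 = x1;
        const double e1 = (xv * w_vest + mu1 * wK1) / denom1;
        const double e2 = (xv * w_vest + mu2 * wK2) / denom2;
        switch (model) {
          case INTEGRATION: est = e1; break;
          case SEGREGATION: est = e2; break;
          case HEURISTIC:
            est = (std::fabs(xv - mu1) >= std::fabs(xv - mu2)) ? e1 : e2;
            break;
          case VARIABLE_WEIGHT:
            est = aw * e1 + (1.0 - aw) * e2;
            break;
          case CCI:
          case WTA: {
            const double Q1 = (xv - mu1) * (xv - mu1) * s_self2 +
              xv * xv * s2K1 + mu1 * mu1 * v_vest2;
            const double Q2 = (xv - mu2) * (xv - mu2) * s_self2 +
              xv * xv * s2K2 + mu2 * mu2 * v_vest2;
            const double ll1 = -LOG2PI - halflogD1 - 0.5 * Q1 / D1;
            const double ll2 = -LOG2PI - halflogD2 - 0.5 * Q2 / D2;
            const double p1 = post_w1(ll1, ll2, p_constant);
            est = (model == CCI) ? p1 * e1 + (1.0 - p1) * e2
                                 : (p1 >= 0.5 ? e1 : e2);
            break;
          }
          default: stop("unknown model code");
        }
      }

      est = clampd(est, -ref_speed, ref_speed);
      sims[k] = est;
      sum += est;
      sumsq += est * est;
    }

    if (by_cond[i].empty()) continue;
    const double mean = sum / n_mc;
    double var = (sumsq / n_mc - mean * mean) * n_mc / (n_mc - 1.0);
    if (var < 0.0) var = 0.0;
    const double bw = std::max(0.9 * std::sqrt(var) *
                               std::pow((double)n_mc, -0.2), bw_floor);
    const double norm = 1.0 / (bw * std::sqrt(2.0 * M_PI) * n_mc);
    for (int j : by_cond[i]) {
      const double r = resp[j];
      double dens = 0.0;
      for (int k = 0; k < n_mc; ++k) {
        const double t = (r - sims[k]) / bw;
        if (t > 9.0 || t < -9.0) continue;  // exp(-40.5) is negligible
        dens += std::exp(-0.5 * t * t);
      }
      dens *= norm;
      total += std::log(std::max(dens, density_floor));
    }
  }
  return total;
}
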