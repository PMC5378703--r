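// M-step updates for marginal maximum likelihood EM calibration.
//
// Each item's update maximizes the expected complete-data log-likelihood
// (from the E-step's expected category counts at the quadrature nodes) plus
// the log prior, by damped Newton iterations with analytic gradients and
// Hessians and step-halving, so the penalized objective never decreases.
// The 1PL/PC model set shares one discrimination across all items; it is
// updated by a one-dimensional Newton step on the summed objective.
//
// Free parameterizations (unconstrained, so Newton needs no boxes):
//   1PL: (b)                       2PL: (log a, b)
//   3PL: (log a, b, logit c)       PC:  (b, d_1..d_{m-1})
//   GPC: (log a, b, d_1..d_{m-1})  with d_m = -(d_1 + ... + d_{m-1}).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double EXP_CLIP = 35.0;

static inline double clip_exp(double z) {
  if (z > EXP_CLIP) return EXP_CLIP;
  if (z < -EXP_CLIP) return -EXP_CLIP;
  return z;
}

struct Prior {
  bool on;
  double c_a, c_b;        // Beta(c_a, c_b) on the 3PL lower asymptote
  double loga_mean, loga_sd;
  double b_sd;
  double d_sd;
};

struct ItemCtx {
  int model, m;            // 1..5; m = number of positive categories
  arma::mat r;             // (m+1) x Q expected counts
  arma::vec nq;            // per-node totals sum_k r(k, q)
  arma::vec theta;
  double D;
  double shared_a;         // slope used by 1PL / PC items
  Prior prior;
  bool penalize_loga;      // false under a shared slope (penalized once)

  int npar() const {
    switch (model) {
      case 1: return 1;
      case 2: return 2;
      case 3: return 3;
      case 4: return m;      // b + (m-1) free d
      default: return m + 1; // log a + b + (m-1) free d
    }
  }

  void unpack(const arma::vec& phi, double& a, double& b, double& c,
              arma::vec& d) const {
    c = 0.0;
    d.set_size(std::max(m, 1));
    d.zeros();
    switch (model) {
      case 1: a = shared_a; b = phi[0]; break;
      case 2: a = std::exp(clip_exp(phi[0])); b = phi[1]; break;
      case 3: a = std::exp(clip_exp(phi[0])); b = phi[1];
              c = 1.0 / (1.0 + std::exp(-clip_exp(phi[2]))); break;
      case 4: {
        a = shared_a; b = phi[0];
        double s = 0.0;
        for (int k = 0; k < m - 1; ++k) { d[k] = phi[1 + k]; s += d[k]; }
        d[m - 1] = -s;
        break;
      }
      default: {
        a = std::exp(clip_exp(phi[0])); b = phi[1];
        double s = 0.0;
        for (int k = 0; k < m - 1; ++k) { d[k] = phi[2 + k]; s += d[k]; }
        d[m - 1] = -s;
      }
    }
  }

  // Penalized objective; when g/H are non-null, also accumulate the
  // analytic gradient and Hessian in the free parameterization.
  double eval(const arma::vec& phi, arma::vec* g, arma::mat* H) const {
    double a, b, c;
    arma::vec d;
    unpack(phi, a, b, c, d);
    const int p = npar();
    const int Q = theta.n_elem;
    double f = 0.0;
    if (g) { g->zeros(p); }
    if (H) { H->zeros(p, p); }

    if (model <= 3) {
      // component order: [la (2PL/3PL)], b, [lc (3PL)]
      int i_la = (model >= 2) ? 0 : -1;
      int i_b  = (model >= 2) ? 1 : 0;
      int i_lc = (model == 3) ? 2 : -1;
      for (int q = 0; q < Q; ++q) {
        double u = D * a * (theta[q] - b);
        double L = 1.0 / (1.0 + std::exp(-clip_exp(u)));
        double P = c + (1.0 - c) * L;
        if (P < 1e-12) P = 1e-12;
        if (P > 1.0 - 1e-12) P = 1.0 - 1e-12;
        double r0 = r(0, q), r1 = r(1, q);
        f += r0 * std::log(1.0 - P) + r1 * std::log(P);
        if (!g) continue;
        double w  = r1 / P - r0 / (1.0 - P);
        double w2 = -r1 / (P * P) - r0 / ((1.0 - P) * (1.0 - P));
        double Lp  = L * (1.0 - L);
        double Lpp = Lp * (1.0 - 2.0 * L);
        double dp[3] = {0, 0, 0};   // dP/d(la, b, lc) packed by index
        double Da = D * a;
        if (i_la >= 0) dp[i_la] = (1.0 - c) * Lp * u;
        dp[i_b] = -(1.0 - c) * Lp * Da;
        double ccp = c * (1.0 - c);
        if (i_lc >= 0) dp[i_lc] = (1.0 - L) * ccp;
        for (int i = 0; i < p; ++i) (*g)[i] += w * dp[i];
        if (!H) continue;
        // second derivatives of P
        double d2[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
        if (i_la >= 0) {
          d2[i_la][i_la] = (1.0 - c) * (Lpp * u * u + Lp * u);
          d2[i_la][i_b] = d2[i_b][i_la] =
            (1.0 - c) * (-Da) * (Lpp * u + Lp);
        }
        d2[i_b][i_b] = (1.0 - c) * Lpp * Da * Da;
        if (i_lc >= 0) {
          d2[i_lc][i_lc] = (1.0 - L) * ccp * (1.0 - 2.0 * c);
          if (i_la >= 0)
            d2[i_lc][i_la] = d2[i_la][i_lc] = -Lp * u * ccp;
          d2[i_lc][i_b] = d2[i_b][i_lc] = Lp * Da * ccp;
        }
        for (int i = 0; i < p; ++i)
          for (int j = 0; j < p; ++j)
            (*H)(i, j) += w2 * dp[i] * dp[j] + w * d2[i][j];
      }
    } else {
      // PC / GPC; component order: [la (GPC)], b, d_1..d_{m-1}
      int i_la = (model == 5) ? 0 : -1;
      int i_b  = (model == 5) ? 1 : 0;
      int off_d = i_b + 1;
      arma::vec z(m + 1), Pk(m + 1);
      arma::mat T(m + 1, p);     // T(k, i) = dz_k / dphi_i
      for (int q = 0; q < Q; ++q) {
        z[0] = 0.0;
        for (int k = 1; k <= m; ++k)
          z[k] = z[k - 1] + D * a * (theta[q] - b + d[k - 1]);
        double zmax = z.max();
        double denom = 0.0;
        for (int k = 0; k <= m; ++k) {
          Pk[k] = std::exp(clip_exp(z[k] - zmax));
          denom += Pk[k];
        }
        double logdenom = std::log(denom) + zmax;
        Pk /= denom;
        double n_q = nq[q];
        for (int k = 0; k <= m; ++k) f += r(k, q) * (z[k] - logdenom);
        if (!g) continue;
        double Da = D * a;
        T.zeros();
        for (int k = 1; k <= m; ++k) {
          if (i_la >= 0) T(k, i_la) = z[k];
          T(k, i_b) = -k * Da;
          if (k < m)
            for (int j = 0; j < m - 1 && j < k; ++j) T(k, off_d + j) = Da;
        }
        arma::vec resid(m + 1), tbar(p, arma::fill::zeros);
        for (int k = 0; k <= m; ++k) resid[k] = r(k, q) - n_q * Pk[k];
        for (int k = 0; k <= m; ++k)
          for (int i = 0; i < p; ++i) tbar[i] += Pk[k] * T(k, i);
        for (int i = 0; i < p; ++i)
          for (int k = 0; k <= m; ++k) (*g)[i] += resid[k] * T(k, i);
        if (!H) continue;
        // -n_q * Cov_P(t) from the log-normalizer, plus the curvature of
        // z in log a (z is linear in b and d but proportional to a)
        for (int i = 0; i < p; ++i)
          for (int j = i; j < p; ++j) {
            double cov = 0.0;
            for (int k = 0; k <= m; ++k) cov += Pk[k] * T(k, i) * T(k, j);
            cov -= tbar[i] * tbar[j];
            double h = -n_q * cov;
            (*H)(i, j) += h;
            if (j != i) (*H)(j, i) += h;
          }
        if (i_la >= 0) {
          // d2z_k/dla dphi_j = dz_k/dphi_j (incl. j = la where it is z_k)
          for (int k = 0; k <= m; ++k) {
            for (int j = 0; j < p; ++j) {
              double term = resid[k] * T(k, j);
              if (j == i_la) { (*H)(i_la, i_la) += term; }
              else {
                (*H)(i_la, j) += term;
                (*H)(j, i_la) += term;
              }
            }
          }
        }
      }
    }

    // log-prior contributions in the free parameterization
    if (prior.on) {
      bool has_a = (model == 2 || model == 3 || model == 5);
      if (has_a && penalize_loga) {
        double la = std::log(a);
        double s2 = prior.loga_sd * prior.loga_sd;
        f += -0.5 * (la - prior.loga_mean) * (la - prior.loga_mean) / s2;
        if (g) (*g)[0] += -(la - prior.loga_mean) / s2;
        if (H) (*H)(0, 0) += -1.0 / s2;
      }
      int i_b = (model == 2 || model == 3 || model == 5) ? 1 : 0;
      double sb2 = prior.b_sd * prior.b_sd;
      f += -0.5 * b * b / sb2;
      if (g) (*g)[i_b] += -b / sb2;
      if (H) (*H)(i_b, i_b) += -1.0 / sb2;
      if (model == 3) {
        double cc = std::min(std::max(c, 1e-10), 1.0 - 1e-10);
        f += (prior.c_a - 1.0) * std::log(cc) +
             (prior.c_b - 1.0) * std::log(1.0 - cc);
        double ccp = cc * (1.0 - cc);
        if (g) (*g)[2] += (prior.c_a - 1.0) * (1.0 - cc) -
                          (prior.c_b - 1.0) * cc;
        if (H) (*H)(2, 2) += -((prior.c_a - 1.0) + (prior.c_b - 1.0)) * ccp;
      }
      if (model >= 4 && m >= 2) {
        // every d_v (including the constrained d_m) is penalized
        double sd2 = prior.d_sd * prior.d_sd;
        int off_d = (model == 5) ? 2 : 1;
        double S = 0.0;
        for (int v = 0; v < m - 1; ++v) S += d[v];
        for (int v = 0; v < m; ++v) f += -0.5 * d[v] * d[v] / sd2;
        if (g)
          for (int j = 0; j < m - 1; ++j)
            (*g)[off_d + j] += -(d[j] + S) / sd2;  // d_m = -S
        if (H)
          for (int i = 0; i < m - 1; ++i)
            for (int j = 0; j < m - 1; ++j)
              (*H)(off_d + i, off_d + j) += -((i == j ? 1.0 : 0.0) + 1.0) / sd2;
      }
    }
    return f;
  }

  double obj(const arma::vec& phi) const { return eval(phi, nullptr, nullptr); }
};

// Damped Newton ascent with step halving; never returns a worse point.
static arma::vec newton_ascend(const ItemCtx& ctx, arma::vec phi,
                               int inner_max, double inner_tol,
                               double& fout) {
  const int p = phi.n_elem;
  arma::vec g(p);
  arma::mat H(p, p);
  double f = ctx.eval(phi, &g, &H);
  for (int it = 0; it < inner_max; ++it) {
    if (arma::norm(g, "inf") < 1e-9) break;
    arma::vec step;
    bool ok = arma::solve(step, -H, g, arma::solve_opts::no_approx);
    if (!ok || !step.is_finite() || arma::dot(step, g) <= 0.0)
      step = g / std::max(1.0, arma::norm(g, "inf"));  // ascent fallback
    double sn = arma::norm(step, "inf");
    if (sn > 2.0) step *= 2.0 / sn;                    // trust region
    double lambda = 1.0;
    bool accepted = false;
    for (int hcount = 0; hcount < 25; ++hcount) {
      arma::vec cand = phi + lambda * step;
      double fc = ctx.obj(cand);
      if (std::isfinite(fc) && fc >= f - 1e-12 && (fc > f || hcount == 0)) {
        double moved = lambda * sn;
        phi = cand;
        f = ctx.eval(phi, &g, &H);
        accepted = true;
        if (moved < inner_tol) { fout = f; return phi; }
        break;
      }
      lambda *= 0.5;
    }
    if (!accepted) break;
  }
  fout = f;
  return phi;
}

static arma::vec pack_row(const ItemCtx& ctx, const NumericMatrix& par, int j) {
  arma::vec phi(ctx.npar());
  double a = par(j, 0), b = par(j, 1), c = par(j, 2);
  switch (ctx.model) {
    case 1: phi[0] = b; break;
    case 2: phi[0] = std::log(a); phi[1] = b; break;
    case 3: phi[0] = std::log(a); phi[1] = b;
            phi[2] = std::log(std::max(c, 1e-6) / std::max(1.0 - c, 1e-6));
            break;
    case 4: phi[0] = b;
            for (int k = 0; k < ctx.m - 1; ++k) phi[1 + k] = par(j, 3 + k);
            break;
    default: phi[0] = std::log(a); phi[1] = b;
             for (int k = 0; k < ctx.m - 1; ++k) phi[2 + k] = par(j, 3 + k);
  }
  return phi;
}

static ItemCtx make_ctx(const arma::mat& R, const IntegerVector& offset,
                        const IntegerVector& ncat,
                        const IntegerVector& model_code, int j,
                        const arma::vec& theta, double D,
                        const Prior& prior, double shared_a,
                        bool shared_slope) {
  ItemCtx ctx;
  ctx.model = model_code[j];
  ctx.m = ncat[j] - 1;
  ctx.r = R.rows(offset[j], offset[j] + ncat[j] - 1);
  ctx.nq = arma::sum(ctx.r, 0).t();
  ctx.theta = theta;
  ctx.D = D;
  ctx.prior = prior;
  ctx.shared_a = shared_a;
  ctx.penalize_loga = !(shared_slope && (ctx.model == 1 || ctx.model == 4));
  return ctx;
}

// [[Rcpp::export]]
List cpp_mstep(const arma::mat& R, const IntegerVector& offset,
               const IntegerVector& ncat, const IntegerVector& model_code,
               NumericMatrix par, const LogicalVector& fixed,
               const arma::vec& theta, double D, const List& prior_list,
               bool shared_slope, double shared_a_init,
               int inner_max, double inner_tol) {
  const int J = model_code.size();
  Prior prior;
  prior.on = as<bool>(prior_list["on"]);
  prior.c_a = as<double>(prior_list["c_shape1"]);
  prior.c_b = as<double>(prior_list["c_shape2"]);
  prior.loga_mean = as<double>(prior_list["loga_mean"]);
  prior.loga_sd = as<double>(prior_list["loga_sd"]);
  prior.b_sd = as<double>(prior_list["b_sd"]);
  prior.d_sd = as<double>(prior_list["d_sd"]);

  NumericMatrix out(clone(par));
  double shared_a = shared_a_init;

  // Shared discrimination (1PL/PC set): 1-D Newton on the summed objective,
  // using the analytic la-gradient/Hessian of each item's GPC-form eval
  // (a 1PL item is a PC item with m = 1 up to a reparameterization; here we
  // just evaluate the summed objective directly).
  if (shared_slope) {
    std::vector<int> idx;
    for (int j = 0; j < J; ++j)
      if (!fixed[j] && (model_code[j] == 1 || model_code[j] == 4))
        idx.push_back(j);
    if (!idx.empty()) {
      auto total = [&](double la) {
        double a = std::exp(clip_exp(la)), tot = 0.0;
        for (size_t t = 0; t < idx.size(); ++t) {
          int j = idx[t];
          ItemCtx ctx = make_ctx(R, offset, ncat, model_code, j, theta, D,
                                 prior, a, true);
          arma::vec phi = pack_row(ctx, out, j);
          tot += ctx.obj(phi);
        }
        if (prior.on)
          tot += -0.5 * std::pow((la - prior.loga_mean) / prior.loga_sd, 2.0);
        return tot;
      };
      double la = std::log(shared_a);
      double f = total(la);
      for (int it = 0; it < inner_max; ++it) {
        double h = 1e-5;
        double fp = total(la + h), fm = total(la - h);
        double gg = (fp - fm) / (2 * h);
        double hh = (fp - 2 * f + fm) / (h * h);
        if (std::fabs(gg) < 1e-9) break;
        double step = (hh < -1e-12) ? -gg / hh : ((gg > 0) ? 0.2 : -0.2);
        if (std::fabs(step) > 0.5) step = (step > 0 ? 0.5 : -0.5);
        double lambda = 1.0;
        bool acc = false;
        for (int hcount = 0; hcount < 20; ++hcount) {
          double cand = la + lambda * step;
          double fc = total(cand);
          if (std::isfinite(fc) && fc >= f) {
            bool tiny = std::fabs(lambda * step) < inner_tol;
            la = cand; f = fc; acc = true;
            if (tiny) it = inner_max;
            break;
          }
          lambda *= 0.5;
        }
        if (!acc) break;
      }
      shared_a = std::exp(clip_exp(la));
      for (int j = 0; j < J; ++j)
        if (model_code[j] == 1 || model_code[j] == 4) out(j, 0) = shared_a;
    }
  }

  double total_obj = 0.0;
  for (int j = 0; j < J; ++j) {
    ItemCtx ctx = make_ctx(R, offset, ncat, model_code, j, theta, D, prior,
                           shared_a, shared_slope);
    if (fixed[j]) {
      // report the objective at the fixed values (their own slope, no prior)
      ctx.prior.on = false;
      ctx.shared_a = out(j, 0);
      arma::vec phi = pack_row(ctx, out, j);
      total_obj += ctx.obj(phi);
      continue;
    }
    arma::vec phi = pack_row(ctx, out, j);
    double f0 = ctx.obj(phi), f1 = f0;
    arma::vec phi1 = newton_ascend(ctx, phi, inner_max, inner_tol, f1);
    if (ctx.model == 3) {
      // second start from a neutral point: the 3PL penalized surface can
      // hold multiple modes along the c-ridge
      arma::vec phi_n = {0.0, 0.0, std::log(0.2 / 0.8)};
      double f2 = 0.0;
      arma::vec phi2 = newton_ascend(ctx, phi_n, inner_max, inner_tol, f2);
      if (f2 > f1) { phi1 = phi2; f1 = f2; }
    }
    if (f1 < f0 - 1e-10) { phi1 = phi; f1 = f0; }  // never accept descent
    double a, b, c;
    arma::vec d;
    ctx.unpack(phi1, a, b, c, d);
    out(j, 0) = a; out(j, 1) = b; out(j, 2) = c;
    for (int k = 0; k < ctx.m && ctx.model >= 4; ++k) out(j, 3 + k) = d[k];
    total_obj += f1;
  }
  return List::create(_["par"] = out, _["objective"] = total_obj,
                      _["shared_a"] = shared_a);
}
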