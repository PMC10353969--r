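// Compiled log-posterior and gradient cores for the migration hurdle model
// and the residence multi-logit model.  These mirror the R reference
// implementations exactly (same unconstrained parameterization); the R-side
// tests assert agreement between the two backends.
//
// Parameterization: regression coefficient blocks are centred (the data
// inform them strongly), with their scale/correlation hyperparameters
// unconstrained (log scales, tanh canonical partial correlations); varying
// intercepts are non-centred standard-normal deviates.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- canonical-partial-correlation Cholesky helpers ---------------------

static void cpc_chol_build(const double* y, int K, std::vector<double>& L,
                           std::vector<double>& z) {
  std::fill(L.begin(), L.end(), 0.0);
  int pos = 0;
  for (int i = 0; i < K; ++i) {
    double prod_c = 1.0;
    for (int j = 0; j < i; ++j) {
      double zz = std::tanh(y[pos]);
      z[pos] = zz;
      L[i + K * j] = zz * prod_c;
      prod_c *= std::sqrt(1.0 - zz * zz);
      ++pos;
    }
    L[i + K * i] = prod_c;
  }
}

// gradient backprop: GL (K x K, lower incl diag) -> ADDED into gy
static void cpc_chol_grad_acc(const double* z, int K, const double* L,
                              const double* GL, double* gy) {
  int pos0 = 0;
  for (int i = 1; i < K; ++i) {
    int m = i;
    std::vector<double> suf(m + 1, 0.0);
    suf[m] = GL[i + K * i] * L[i + K * i];
    for (int j = m - 1; j >= 1; --j) {
      suf[j] = suf[j + 1] + GL[i + K * j] * L[i + K * j];
    }
    double P = 1.0;
    for (int k = 0; k < m; ++k) {
      double zz = z[pos0 + k];
      double c2 = 1.0 - zz * zz;
      double g = GL[i + K * k] * P + (-zz / c2) * suf[k + 1];
      gy[pos0 + k] += g * c2;
      P *= std::sqrt(c2);
    }
    pos0 += m;
  }
}

static double lkj_cpc_lp(const double* y, int K, double eta, double* gy) {
  double lp = 0.0;
  int pos = 0;
  for (int i = 1; i < K; ++i) {
    for (int j = 0; j < i; ++j) {
      double a = eta + (K - 2 - j) / 2.0;
      double zz = std::tanh(y[pos]);
      lp += a * std::log1p(-zz * zz);
      if (gy) gy[pos] += -2.0 * a * zz;
      ++pos;
    }
  }
  return lp;
}

static double halfcauchy_lp(const double* ls, int n, double* g) {
  double lp = 0.0;
  for (int i = 0; i < n; ++i) {
    double s2 = std::exp(2.0 * ls[i]);
    lp += std::log(2.0 / M_PI) - std::log1p(s2) + ls[i];
    if (g) g[i] += 1.0 - 2.0 * s2 / (1.0 + s2);
  }
  return lp;
}

static double lognormdiff(double a, double b) {
  if (a > 0) {
    double l1 = R::pnorm(a, 0.0, 1.0, 0, 1);
    double l2 = R::pnorm(b, 0.0, 1.0, 0, 1);
    return l1 + std::log1p(-std::exp(l2 - l1));
  }
  double l1 = R::pnorm(b, 0.0, 1.0, 1, 1);
  double l2 = R::pnorm(a, 0.0, 1.0, 1, 1);
  return l1 + std::log1p(-std::exp(l2 - l1));
}

// centred MVN coefficient block: x ~ N(mean, diag(tau) L L' diag(tau)).
// Accumulates the prior log-density (incl. the -sum(lt) and -sum(log diag L)
// normalization pieces) and the gradients wrt x, lt and L.  Returns lp; the
// gradient wrt x is ADDED into gx, wrt lt ADDED into glt; GL gets a z'
// outer-product contribution plus the -1/L_ii diagonal term.
static double mvn_centred(const double* x, const double* mean,
                          const double* lt, const double* L, int K,
                          double* gx, double* glt, double* GL) {
  std::vector<double> w(K), z(K), a(K);
  double lp = 0.0;
  for (int k = 0; k < K; ++k) {
    double tau = std::exp(lt[k]);
    w[k] = (x[k] - (mean ? mean[k] : 0.0)) / tau;
    lp -= lt[k];
  }
  for (int k = 0; k < K; ++k) {               // z = L^{-1} w
    double s = w[k];
    for (int j = 0; j < k; ++j) s -= L[k + K * j] * z[j];
    z[k] = s / L[k + K * k];
    lp += -0.5 * z[k] * z[k] - std::log(L[k + K * k]);
  }
  for (int k = K - 1; k >= 0; --k) {          // a = L^{-T} z
    double s = z[k];
    for (int j = k + 1; j < K; ++j) s -= L[j + K * k] * a[j];
    a[k] = s / L[k + K * k];
  }
  for (int k = 0; k < K; ++k) {
    double tau = std::exp(lt[k]);
    gx[k] += -a[k] / tau;
    glt[k] += a[k] * w[k] - 1.0;
    for (int j = 0; j <= k; ++j) GL[k + K * j] += a[k] * z[j];
    GL[k + K * k] += -1.0 / L[k + K * k];
  }
  return lp - 0.5 * K * std::log(2.0 * M_PI);
}

// ---- migration hurdle model ---------------------------------------------

// theta layout: yb(Kc) ltb(K) beta(K) yg(Kc) ltg(K) gamma(K)
//               zS(L) zT(B) zU(L) zV(B) ls(5)
// [[Rcpp::export(name = ".mig_eval_cpp")]]
List mig_eval_cpp(NumericVector theta, NumericMatrix Xt,  // K x n (transposed)
                  IntegerVector li, IntegerVector bi,
                  IntegerVector st,       // 0 d==0, 1 d>0, 2 interval, 3 unknown
                  NumericVector val1,     // log d | log d_min | log d_max
                  NumericVector val2,     // log d_max (interval case)
                  int L, int B, double eta_lkj, NumericVector gamma_mean,
                  int centre_T, int centre_V) {
  const int n = Xt.ncol(), K = Xt.nrow();
  const int Kc = K * (K - 1) / 2;
  const double* th = theta.begin();
  const double* yb = th;            const double* ltb = yb + Kc;
  const double* beta = ltb + K;     const double* yg = beta + K;
  const double* ltg = yg + Kc;      const double* gamma = ltg + K;
  const double* zS = gamma + K;     const double* zT = zS + L;
  const double* zU = zT + B;        const double* zV = zU + L;
  const double* ls = zV + B;
  const int npar = 2 * (Kc + 2 * K) + 2 * L + 2 * B + 5;

  std::vector<double> Lb(K * K), Lg(K * K), zcb(Kc), zcg(Kc);
  cpc_chol_build(yb, K, Lb, zcb);
  cpc_chol_build(yg, K, Lg, zcg);
  double sS = std::exp(ls[0]), sT = std::exp(ls[1]), sU = std::exp(ls[2]),
         sV = std::exp(ls[3]), sE = std::exp(ls[4]);
  // birthplace intercept values (their blocks may be centred: the block
  // then stores the intercept itself rather than a standardized deviate)
  std::vector<double> Tv(B), Vv(B);
  for (int b = 0; b < B; ++b) {
    Tv[b] = centre_T ? zT[b] : sT * zT[b];
    Vv[b] = centre_V ? zV[b] : sV * zV[b];
  }

  NumericVector ll(n);
  NumericVector grad(npar);
  double* g = grad.begin();
  double* g_yb = g;          double* g_ltb = g_yb + Kc;
  double* g_beta = g_ltb + K; double* g_yg = g_beta + K;
  double* g_ltg = g_yg + Kc; double* g_gamma = g_ltg + K;
  double* g_zS = g_gamma + K; double* g_zT = g_zS + L;
  double* g_zU = g_zT + B;   double* g_zV = g_zU + L;
  double* g_ls = g_zV + B;

  std::vector<double> gS(L, 0.0), gT(B, 0.0), gU(L, 0.0), gV(B, 0.0);
  double glsE = 0.0, loglik = 0.0;
  const double LOG2PI = std::log(2.0 * M_PI);
  const double* xp = Xt.begin();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + (size_t)K * i;
    double eta = sS * zS[li[i] - 1] + Tv[bi[i] - 1];
    double mu = sU * zU[li[i] - 1] + Vv[bi[i] - 1];
    for (int k = 0; k < K; ++k) {
      eta += xi[k] * beta[k];
      mu += xi[k] * gamma[k];
    }
    // log pi, log(1-pi) with a single exp
    double lpi, lqi, pii;
    if (eta > 0) {
      double e = std::exp(-eta);
      lqi = -eta - std::log1p(e);
      lpi = lqi + eta;
      pii = 1.0 / (1.0 + e);
    } else {
      double e = std::exp(eta);
      lpi = eta - std::log1p(e);
      lqi = lpi - eta;
      pii = e / (1.0 + e);
    }
    double l, gei = 0.0, gmi = 0.0;
    switch (st[i]) {
    case 0:
      l = lqi; gei = -pii; break;
    case 1: {
      double r = (val1[i] - mu) / sE;
      l = lpi - val1[i] - ls[4] - 0.5 * LOG2PI - 0.5 * r * r;
      gei = 1.0 - pii; gmi = r / sE; glsE += r * r - 1.0;
      break;
    }
    case 2: {
      double a = (val1[i] - mu) / sE, b = (val2[i] - mu) / sE;
      double logD = lognormdiff(a, b);
      l = lpi + logD;
      // density/mass ratios on the log scale: stable even when both the
      // interval mass and the endpoint densities underflow
      double ra = std::exp(R::dnorm(a, 0.0, 1.0, 1) - logD);
      double rb = std::exp(R::dnorm(b, 0.0, 1.0, 1) - logD);
      gei = 1.0 - pii;
      gmi = (ra - rb) / sE;
      glsE += a * ra - b * rb;
      break;
    }
    default: {
      double b = (val1[i] - mu) / sE;
      double lPhi = R::pnorm(b, 0.0, 1.0, 1, 1);
      double l1 = lqi, l2 = lpi + lPhi;
      double mx = std::max(l1, l2);
      l = mx + std::log(std::exp(l1 - mx) + std::exp(l2 - mx));
      double q1 = std::exp(l1 - l), q2 = std::exp(l2 - l);
      gei = (1.0 - pii) * q2 - pii * q1;
      if (q2 > 0) {
        double im = std::exp(R::dnorm(b, 0.0, 1.0, 1) - lPhi);
        gmi = -q2 * im / sE;
        glsE += -q2 * im * b;
      }
    }
    }
    ll[i] = l; loglik += l;
    for (int k = 0; k < K; ++k) {
      g_beta[k] += xi[k] * gei;
      g_gamma[k] += xi[k] * gmi;
    }
    gS[li[i] - 1] += gei; gT[bi[i] - 1] += gei;
    gU[li[i] - 1] += gmi; gV[bi[i] - 1] += gmi;
  }

  double lp = loglik;
  // coefficient blocks: centred MVN priors with decomposed covariances
  std::vector<double> GLb(K * K, 0.0), GLg(K * K, 0.0);
  lp += mvn_centred(beta, nullptr, ltb, Lb.data(), K, g_beta, g_ltb,
                    GLb.data());
  lp += mvn_centred(gamma, gamma_mean.begin(), ltg, Lg.data(), K, g_gamma,
                    g_ltg, GLg.data());
  cpc_chol_grad_acc(zcb.data(), K, Lb.data(), GLb.data(), g_yb);
  cpc_chol_grad_acc(zcg.data(), K, Lg.data(), GLg.data(), g_yg);
  lp += lkj_cpc_lp(yb, K, eta_lkj, g_yb);
  lp += lkj_cpc_lp(yg, K, eta_lkj, g_yg);
  lp += halfcauchy_lp(ltb, K, g_ltb);
  lp += halfcauchy_lp(ltg, K, g_ltg);
  // varying intercepts (non-centred)
  double dS = 0.0, dT = 0.0, dU = 0.0, dV = 0.0;
  for (int l = 0; l < L; ++l) {
    lp += -0.5 * (zS[l] * zS[l] + zU[l] * zU[l]);
    g_zS[l] = sS * gS[l] - zS[l];
    g_zU[l] = sU * gU[l] - zU[l];
    dS += zS[l] * gS[l]; dU += zU[l] * gU[l];
  }
  for (int b = 0; b < B; ++b) {
    if (centre_T) {
      lp += -0.5 * Tv[b] * Tv[b] / (sT * sT) - ls[1];
      g_zT[b] = gT[b] - Tv[b] / (sT * sT);
      dT += Tv[b] * Tv[b];
    } else {
      lp += -0.5 * zT[b] * zT[b];
      g_zT[b] = sT * gT[b] - zT[b];
      dT += zT[b] * gT[b];
    }
    if (centre_V) {
      lp += -0.5 * Vv[b] * Vv[b] / (sV * sV) - ls[3];
      g_zV[b] = gV[b] - Vv[b] / (sV * sV);
      dV += Vv[b] * Vv[b];
    } else {
      lp += -0.5 * zV[b] * zV[b];
      g_zV[b] = sV * gV[b] - zV[b];
      dV += zV[b] * gV[b];
    }
  }
  g_ls[0] = sS * dS;
  g_ls[1] = centre_T ? (dT / (sT * sT) - B) : sT * dT;
  g_ls[2] = sU * dU;
  g_ls[3] = centre_V ? (dV / (sV * sV) - B) : sV * dV;
  g_ls[4] = glsE;
  lp += halfcauchy_lp(ls, 5, g_ls);
  return List::create(_["lp"] = lp, _["grad"] = grad, _["ll"] = ll);
}

// ---- residence multi-logit model ----------------------------------------

// theta layout: yd(Kdc) ltd(Kd) delta(Kd)
//               yW(3) ltW(3) zW(3L) yY(3) ltY(3) zY(3Bm) yZ(3) ltZ(3) zZ(3Bf)
// [[Rcpp::export(name = ".res_eval_cpp")]]
List res_eval_cpp(NumericVector theta, NumericMatrix Xt,  // K x n
                  IntegerVector li, IntegerVector mi, IntegerVector fi,
                  IntegerVector y, int L, int Bm, int Bf, double eta_lkj) {
  const int n = Xt.ncol(), K = Xt.nrow();
  const int Kd = 3 * K, Kdc = Kd * (Kd - 1) / 2;
  const double* th = theta.begin();
  const double* yd = th;            const double* ltd = yd + Kdc;
  const double* delta = ltd + Kd;
  const double* yW = delta + Kd;    const double* ltW = yW + 3;
  const double* zW = ltW + 3;       const double* yY = zW + 3 * L;
  const double* ltY = yY + 3;       const double* zY = ltY + 3;
  const double* yZ = zY + 3 * Bm;   const double* ltZ = yZ + 3;
  const double* zZ = ltZ + 3;
  const int npar = Kdc + 2 * Kd + 3 * (3 + 3) + 3 * (L + Bm + Bf);

  std::vector<double> Ld(Kd * Kd), zcd(Kdc);
  cpc_chol_build(yd, Kd, Ld, zcd);
  std::vector<double> LW(9), zcW(3), LY(9), zcY(3), LZ(9), zcZ(3);
  cpc_chol_build(yW, 3, LW, zcW);
  cpc_chol_build(yY, 3, LY, zcY);
  cpc_chol_build(yZ, 3, LZ, zcZ);
  double tW[3], tY[3], tZ[3];
  for (int r = 0; r < 3; ++r) {
    tW[r] = std::exp(ltW[r]); tY[r] = std::exp(ltY[r]); tZ[r] = std::exp(ltZ[r]);
  }
  double AW[9], AY[9], AZ[9];
  for (int r = 0; r < 3; ++r) for (int j = 0; j < 3; ++j) {
    AW[r + 3 * j] = tW[r] * LW[r + 3 * j];
    AY[r + 3 * j] = tY[r] * LY[r + 3 * j];
    AZ[r + 3 * j] = tZ[r] * LZ[r + 3 * j];
  }
  std::vector<double> WV(3 * L), YV(3 * Bm), ZV(3 * Bf);
  auto fill_val = [](const double* z, const double* A, int nlev,
                     std::vector<double>& out) {
    for (int l = 0; l < nlev; ++l)
      for (int r = 0; r < 3; ++r) {
        double s = 0.0;
        for (int j = 0; j < 3; ++j) s += z[l + nlev * j] * A[r + 3 * j];
        out[l + nlev * r] = s;
      }
  };
  fill_val(zW, AW, L, WV); fill_val(zY, AY, Bm, YV); fill_val(zZ, AZ, Bf, ZV);

  NumericVector ll(n);
  NumericVector grad(npar);
  double* g = grad.begin();
  double* g_yd = g;             double* g_ltd = g_yd + Kdc;
  double* g_delta = g_ltd + Kd;
  double* g_yW = g_delta + Kd;  double* g_ltW = g_yW + 3;
  double* g_zW = g_ltW + 3;     double* g_yY = g_zW + 3 * L;
  double* g_ltY = g_yY + 3;     double* g_zY = g_ltY + 3;
  double* g_yZ = g_zY + 3 * Bm; double* g_ltZ = g_yZ + 3;
  double* g_zZ = g_ltZ + 3;

  std::vector<double> GW(3 * L, 0.0), GY(3 * Bm, 0.0), GZ(3 * Bf, 0.0);
  double loglik = 0.0;
  const double* xp = Xt.begin();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + (size_t)K * i;
    double eta[3];
    for (int r = 0; r < 3; ++r) {
      double s = WV[(li[i] - 1) + L * r] + YV[(mi[i] - 1) + Bm * r] +
        ZV[(fi[i] - 1) + Bf * r];
      const double* dr = delta + K * r;
      for (int k = 0; k < K; ++k) s += xi[k] * dr[k];
      eta[r] = s;
    }
    double mx = std::max(0.0, std::max(eta[0], std::max(eta[1], eta[2])));
    double se = std::exp(-mx);
    for (int r = 0; r < 3; ++r) se += std::exp(eta[r] - mx);
    double lse = mx + std::log(se);
    double l = (y[i] == 1 ? 0.0 : eta[y[i] - 2]) - lse;
    ll[i] = l; loglik += l;
    for (int r = 0; r < 3; ++r) {
      double gi = -std::exp(eta[r] - lse);
      if (y[i] == r + 2) gi += 1.0;
      double* dr = g_delta + K * r;
      for (int k = 0; k < K; ++k) dr[k] += xi[k] * gi;
      GW[(li[i] - 1) + L * r] += gi;
      GY[(mi[i] - 1) + Bm * r] += gi;
      GZ[(fi[i] - 1) + Bf * r] += gi;
    }
  }

  double lp = loglik;
  std::vector<double> GLd(Kd * Kd, 0.0);
  lp += mvn_centred(delta, nullptr, ltd, Ld.data(), Kd, g_delta, g_ltd,
                    GLd.data());
  cpc_chol_grad_acc(zcd.data(), Kd, Ld.data(), GLd.data(), g_yd);
  lp += lkj_cpc_lp(yd, Kd, eta_lkj, g_yd);
  lp += halfcauchy_lp(ltd, Kd, g_ltd);

  // varying-intercept blocks
  struct Blk {
    const double* zmat; const double* A; const double* Lc; const double* zc;
    const double* tau; const double* yv; const double* lt;
    std::vector<double>* GM; int nlev;
    double* g_y; double* g_lt; double* g_z;
  };
  Blk blocks[3] = {
    {zW, AW, LW.data(), zcW.data(), tW, yW, ltW, &GW, L, g_yW, g_ltW, g_zW},
    {zY, AY, LY.data(), zcY.data(), tY, yY, ltY, &GY, Bm, g_yY, g_ltY, g_zY},
    {zZ, AZ, LZ.data(), zcZ.data(), tZ, yZ, ltZ, &GZ, Bf, g_yZ, g_ltZ, g_zZ}
  };
  for (int bkt = 0; bkt < 3; ++bkt) {
    Blk& b = blocks[bkt];
    double dA[9] = {0,0,0,0,0,0,0,0,0};
    const std::vector<double>& GM = *b.GM;
    for (int l = 0; l < b.nlev; ++l) {
      for (int r = 0; r < 3; ++r) {
        double gi = GM[l + b.nlev * r];
        for (int j = 0; j < 3; ++j) dA[r + 3 * j] += gi * b.zmat[l + b.nlev * j];
      }
      for (int j = 0; j < 3; ++j) {
        double s = 0.0;
        for (int r = 0; r < 3; ++r) s += GM[l + b.nlev * r] * b.A[r + 3 * j];
        b.g_z[l + b.nlev * j] = s - b.zmat[l + b.nlev * j];
        lp += -0.5 * b.zmat[l + b.nlev * j] * b.zmat[l + b.nlev * j];
      }
    }
    double GL[9];
    for (int r = 0; r < 3; ++r) {
      double acc = 0.0;
      for (int j = 0; j < 3; ++j) {
        GL[r + 3 * j] = b.tau[r] * dA[r + 3 * j];
        acc += dA[r + 3 * j] * b.A[r + 3 * j];
      }
      b.g_lt[r] = acc;
    }
    cpc_chol_grad_acc(b.zc, 3, b.Lc, GL, b.g_y);
    lp += lkj_cpc_lp(b.yv, 3, eta_lkj, b.g_y);
    lp += halfcauchy_lp(b.lt, 3, b.g_lt);
  }
  return List::create(_["lp"] = lp, _["grad"] = grad, _["ll"] = ll);
}
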