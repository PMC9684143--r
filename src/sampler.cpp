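#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reversible-jump sampler over the number of emitters K, emitter positions mu_k,
// per-emitter linear drifts a_k, allocations Z of the N localizations, and the
// mean localizations-per-emitter parameter lambda (xi).
//
// Target density on a subregion with flat position prior over a box of area A:
//
//   pi(K, Z, mu, a, lambda) propto  P(N | K, xi) * K^(-N)
//                                  * prod_i Normal(x_i; mu_{Z_i} + a_{Z_i} t_i, s_i^2)
//                                  * A^(-K) * prod_k Normal(a_k; 0, sd_a^2) * p(lambda),
//
// restricted to allocations in which every emitter has at least one localization.
// P(N | K, xi) is Poisson(N; K*lambda) for the Poisson count model, or a negative
// binomial with size K*eta and mean K*gamma for the gamma-mixed (dSTORM) model.
// The allocation prior is uniform over the K^N labellings, so the fixed-K
// conditional of the counts n_k matches independent per-emitter Poisson counts
// conditioned on their total (Poisson splitting).
//
// Jumps: Move (exact Gibbs on mu,a; always accepted), Allocate (independence
// proposal from the likelihood-categorical, Metropolis-Hastings corrected),
// Birth/Death (RJMCMC with a 50:50 uniform/data-centred birth proposal density).
//
// The N x K likelihood-weight matrix is cached: only Move changes emitter
// positions, so Allocate reuses it unchanged, Birth appends one column and
// Death deletes one, making those jumps exp-free.

// Half squared Mahalanobis threshold (relative to the localization's best
// emitter) beyond which a proposal weight is treated as exactly zero (6
// sigma); the floor below keeps the proposal support intact regardless.
static const double TRUNC_Q = 18.0;

struct Sampler {
  int N;
  std::vector<double> x, y, sx, sy, wx, wy, t;
  double xmin, xmax, ymin, ymax, area;
  // state
  int K;
  std::vector<double> mux, muy, ax, ay;
  std::vector<int> z;       // 0-based allocation
  std::vector<int> cnt;     // per-emitter allocation counts
  double lambda;
  // cached proposal weights: W row-major N x cap, C = row sums over K cols
  int cap;
  std::vector<double> W, C;
  // config
  int count_model;          // 0 poisson, 1 gamma_poisson (NB)
  int xi_mode;              // 0 fixed, 1 hierarchical
  int xi_sampler;           // 0 gibbs, 1 mh
  double eta, gamma_, xi_mh_sd;
  int xi_stride;
  bool drift;
  double sd_a;

  // Proposal categoricals use truncated weights with a tiny floor so the
  // support never vanishes: without the floor, a Move that strands one
  // tight-precision localization just outside its emitter's truncation
  // radius would zero the reverse-proposal density and freeze every
  // subsequent global jump. Acceptance ratios use the exact log-likelihood
  // for the current and proposed allocation plus the floored proposal terms.
  static double wfloor() { return 1e-14; }

  double wexp(int i, int k) const {
    double dx = x[i] - (mux[k] + ax[k] * t[i]);
    double dy = y[i] - (muy[k] + ay[k] * t[i]);
    double q = dx * dx * wx[i] + dy * dy * wy[i];
    return (q > 2.0 * TRUNC_Q) ? 0.0 : std::exp(-0.5 * q);
  }

  // exact half-squared-Mahalanobis (no truncation): log L up to constants
  double lq(int i, int k) const {
    double dx = x[i] - (mux[k] + ax[k] * t[i]);
    double dy = y[i] - (muy[k] + ay[k] * t[i]);
    return -0.5 * (dx * dx * wx[i] + dy * dy * wy[i]);
  }

  static double lw_of(double w, double lq_exact) {
    return (w > 0.0) ? lq_exact : std::log(wfloor());
  }

  void grow_cap(int need) {
    if (need <= cap) return;
    int cap2 = cap;
    while (cap2 < need) cap2 *= 2;
    std::vector<double> W2((size_t)N * cap2, 0.0);
    for (int i = 0; i < N; ++i)
      std::copy(W.begin() + (size_t)i * cap, W.begin() + (size_t)i * cap + K,
                W2.begin() + (size_t)i * cap2);
    W.swap(W2);
    cap = cap2;
  }

  // Cached weights are stored relative to each localization's best emitter
  // (offset lqoff[i]): the nearest emitter always carries weight 1, and the
  // truncation drops only emitters ~6 sigma worse than the best, so a
  // localization's categorical never loses its sensible choices no matter
  // how far the whole model drifts from it.
  std::vector<double> lqoff, qrow;

  void rebuild_cache() {
    grow_cap(K);
    lqoff.resize(N);
    qrow.resize(cap);
    for (int i = 0; i < N; ++i) {
      double *row = &W[(size_t)i * cap];
      double xi_ = x[i], yi_ = y[i], wxi = wx[i], wyi = wy[i], ti = t[i];
      double qmin = R_PosInf;
      if (!drift) {
        for (int k = 0; k < K; ++k) {
          double dx = xi_ - mux[k];
          double dy = yi_ - muy[k];
          double q = dx * dx * wxi + dy * dy * wyi;
          qrow[k] = q;
          if (q < qmin) qmin = q;
        }
      } else {
        for (int k = 0; k < K; ++k) {
          double dx = xi_ - (mux[k] + ax[k] * ti);
          double dy = yi_ - (muy[k] + ay[k] * ti);
          double q = dx * dx * wxi + dy * dy * wyi;
          qrow[k] = q;
          if (q < qmin) qmin = q;
        }
      }
      lqoff[i] = 0.5 * qmin;   // log w = lq + lqoff for in-range entries
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double dq = 0.5 * (qrow[k] - qmin);
        // single-precision exp: the proposal density used for sampling and
        // in the acceptance ratio is this stored value, so MH stays exact
        double w = (dq > TRUNC_Q) ? 0.0 : (double)expf((float)-dq);
        row[k] = w; s += w;
      }
      C[i] = s;
    }
  }

  // log P(N | K) for the configured count model (K >= 1)
  double lp_count(int Kv) const {
    if (count_model == 0) {
      double m = Kv * lambda;
      return -m + N * std::log(m);   // - lgamma(N+1) constant, dropped
    } else {
      double s = Kv * eta;
      double p = eta / (eta + gamma_);   // NB success prob, K-independent
      return R::lgammafn(N + s) - R::lgammafn(s) + s * std::log(p) + N * std::log1p(-p);
    }
  }

  // count + uniform-allocation part of log pi(K)
  double lp_K(int Kv) const { return lp_count(Kv) - (double)N * std::log((double)Kv); }

  // birth proposal density at (px,py): 0.5 uniform over box, 0.5 localization-centred
  double birth_density(double px, double py) const {
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      double dx = px - x[i], dy = py - y[i];
      double q = dx * dx * wx[i] + dy * dy * wy[i];
      if (q > 2.0 * TRUNC_Q) continue;
      s += std::exp(-0.5 * q) * std::sqrt(wx[i] * wy[i]);
    }
    s /= (2.0 * M_PI * N);
    return 0.5 / area + 0.5 * s;
  }

  void move_update() {
    // accumulate weighted sums per emitter and axis
    std::vector<double> A11x(K, 0), A12x(K, 0), A22x(K, 0), b1x(K, 0), b2x(K, 0);
    std::vector<double> A11y(K, 0), A12y(K, 0), A22y(K, 0), b1y(K, 0), b2y(K, 0);
    for (int i = 0; i < N; ++i) {
      int k = z[i];
      double ti = t[i];
      A11x[k] += wx[i]; A12x[k] += wx[i] * ti; A22x[k] += wx[i] * ti * ti;
      b1x[k] += wx[i] * x[i]; b2x[k] += wx[i] * x[i] * ti;
      A11y[k] += wy[i]; A12y[k] += wy[i] * ti; A22y[k] += wy[i] * ti * ti;
      b1y[k] += wy[i] * y[i]; b2y[k] += wy[i] * y[i] * ti;
    }
    double pa = drift ? 1.0 / (sd_a * sd_a) : 0.0;
    for (int k = 0; k < K; ++k) {
      if (cnt[k] == 0) {  // unreachable in a valid state; proper fallback
        mux[k] = xmin + unif_rand() * (xmax - xmin);
        muy[k] = ymin + unif_rand() * (ymax - ymin);
        ax[k] = ay[k] = 0.0;
        continue;
      }
      if (!drift) {
        mux[k] = b1x[k] / A11x[k] + norm_rand() / std::sqrt(A11x[k]);
        muy[k] = b1y[k] / A11y[k] + norm_rand() / std::sqrt(A11y[k]);
        ax[k] = ay[k] = 0.0;
      } else {
        // bivariate Gaussian conditional per axis: precision [[A11,A12],[A12,A22+pa]]
        double P11, P12, P22, L11, L21, L22, v1, v2, m1, m2, u1, u2, e1, e2;
        // x axis
        P11 = A11x[k]; P12 = A12x[k]; P22 = A22x[k] + pa;
        L11 = std::sqrt(P11); L21 = P12 / L11; L22 = std::sqrt(P22 - L21 * L21);
        v1 = b1x[k] / L11; v2 = (b2x[k] - L21 * v1) / L22;
        m2 = v2 / L22; m1 = (v1 - L21 * m2) / L11;
        u1 = norm_rand(); u2 = norm_rand();
        e2 = u2 / L22; e1 = (u1 - L21 * e2) / L11;
        mux[k] = m1 + e1; ax[k] = m2 + e2;
        // y axis
        P11 = A11y[k]; P12 = A12y[k]; P22 = A22y[k] + pa;
        L11 = std::sqrt(P11); L21 = P12 / L11; L22 = std::sqrt(P22 - L21 * L21);
        v1 = b1y[k] / L11; v2 = (b2y[k] - L21 * v1) / L22;
        m2 = v2 / L22; m1 = (v1 - L21 * m2) / L11;
        u1 = norm_rand(); u2 = norm_rand();
        e2 = u2 / L22; e1 = (u1 - L21 * e2) / L11;
        muy[k] = m1 + e1; ay[k] = m2 + e2;
      }
    }
    rebuild_cache();
  }

  bool allocate_update() {
    const double f = wfloor();
    std::vector<int> znew(N);
    std::vector<int> cnew(K, 0);
    double logA = 0.0;
    for (int i = 0; i < N; ++i) {
      const double *row = &W[(size_t)i * cap];
      double Ct = C[i] + K * f;
      double u = unif_rand() * Ct, acc = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { acc += row[k] + f; if (u <= acc) { pick = k; break; } }
      znew[i] = pick; cnew[pick]++;
      if (pick != z[i]) {
        // exact likelihood ratio + floored proposal correction (cancels
        // whenever both allocations are inside the truncation radius)
        double lqo = lq(i, z[i]), lqn = lq(i, pick);
        logA += (lqn - lqo) + std::log(row[z[i]] + f) - std::log(row[pick] + f);
      }
    }
    for (int k = 0; k < K; ++k) if (cnew[k] == 0) return false;
    if (logA < 0 && std::log(unif_rand()) > logA) return false;
    z = znew; cnt = cnew;
    return true;
  }

  bool birth_update() {
    double px, py;
    if (unif_rand() < 0.5) {
      px = xmin + unif_rand() * (xmax - xmin);
      py = ymin + unif_rand() * (ymax - ymin);
    } else {
      int idx = (int)(unif_rand() * N); if (idx >= N) idx = N - 1;
      px = x[idx] + sx[idx] * norm_rand();
      py = y[idx] + sy[idx] * norm_rand();
    }
    double bnew_ax = 0.0, bnew_ay = 0.0;
    if (drift) { bnew_ax = sd_a * norm_rand(); bnew_ay = sd_a * norm_rand(); }
    double logb = std::log(birth_density(px, py));

    const double f = wfloor();
    std::vector<int> znew(N);
    std::vector<int> cnew(K + 1, 0);
    std::vector<double> wnew(N);
    double sumlog = 0.0;
    for (int i = 0; i < N; ++i) {
      const double *row = &W[(size_t)i * cap];
      double dx = x[i] - (px + bnew_ax * t[i]);
      double dy = y[i] - (py + bnew_ay * t[i]);
      double q = dx * dx * wx[i] + dy * dy * wy[i];
      double lqn_new = -0.5 * q;
      double lrel = lqn_new + lqoff[i];  // relative to the loc's cached best
      wnew[i] = (lrel < -TRUNC_Q) ? 0.0
                : (lrel > 80.0) ? std::exp(std::min(lrel, 650.0))
                : (double)expf((float)lrel);
      double Ct = C[i] + K * f;
      double Ctp = Ct + wnew[i] + f;
      sumlog += std::log(Ctp) - std::log(Ct);
      double u = unif_rand() * Ctp, acc = 0.0;
      int pick = K;
      for (int k = 0; k < K; ++k) { acc += row[k] + f; if (u <= acc) { pick = k; break; } }
      znew[i] = pick; cnew[pick]++;
      if (pick != z[i]) {
        double lqo = lq(i, z[i]);
        double lqn = (pick == K) ? lqn_new : lq(i, pick);
        double wn = (pick == K) ? wnew[i] : row[pick];
        sumlog += (lqn - lqo) + std::log(row[z[i]] + f) - std::log(wn + f);
      }
    }
    for (int k = 0; k <= K; ++k) if (cnew[k] == 0) return false;
    // no 1/(K+1) death-choice factor: the target is exchangeable over
    // emitter labels and birth appends, so the (K+1) relabelings reachable
    // by the reverse death cancel it exactly
    double logA = lp_K(K + 1) - lp_K(K) + sumlog - std::log(area) - logb;
    if (std::log(unif_rand()) > logA) return false;
    mux.push_back(px); muy.push_back(py); ax.push_back(bnew_ax); ay.push_back(bnew_ay);
    grow_cap(K + 1);
    for (int i = 0; i < N; ++i) {
      W[(size_t)i * cap + K] = wnew[i];
      C[i] += wnew[i];
    }
    K += 1; z = znew; cnt = cnew;
    return true;
  }

  bool death_update() {
    if (K <= 1) return false;
    int j = (int)(unif_rand() * K); if (j >= K) j = K - 1;
    double logb = std::log(birth_density(mux[j], muy[j]));
    const double f = wfloor();
    std::vector<int> znew(N);
    std::vector<int> cnew(K - 1, 0);
    double sumlog = 0.0;
    for (int i = 0; i < N; ++i) {
      const double *row = &W[(size_t)i * cap];
      double Ct = C[i] + K * f;
      double Ctp = Ct - row[j] - f;
      sumlog += std::log(Ctp) - std::log(Ct);
      double u = unif_rand() * Ctp, acc = 0.0;
      int pick = -1;
      for (int k = 0; k < K; ++k) {
        if (k == j) continue;
        acc += row[k] + f;
        if (u <= acc) { pick = k; break; }
      }
      if (pick < 0) { pick = (j == K - 1) ? K - 2 : K - 1; }
      if (pick != z[i]) {
        if (z[i] == j) {
          // the reverse birth re-proposes the removed emitter for this loc
          sumlog += (lq(i, pick) - lq(i, j)) +
                    std::log(row[j] + f) - std::log(row[pick] + f);
        } else {
          sumlog += (lq(i, pick) - lq(i, z[i])) +
                    std::log(row[z[i]] + f) - std::log(row[pick] + f);
        }
      }
      int lab = (pick > j) ? pick - 1 : pick;   // relabel after removal
      znew[i] = lab; cnew[lab]++;
    }
    for (int k = 0; k < K - 1; ++k) if (cnew[k] == 0) return false;
    double logA = lp_K(K - 1) - lp_K(K) + sumlog + std::log(area) + logb;
    if (std::log(unif_rand()) > logA) return false;
    mux.erase(mux.begin() + j); muy.erase(muy.begin() + j);
    ax.erase(ax.begin() + j); ay.erase(ay.begin() + j);
    for (int i = 0; i < N; ++i) {
      double *row = &W[(size_t)i * cap];
      C[i] -= row[j];
      for (int k = j; k < K - 1; ++k) row[k] = row[k + 1];
    }
    K -= 1; z = znew; cnt = cnew;
    return true;
  }

  // core box for the lambda update: emitters outside it sit near the data
  // window's edge, where their counts are censored (part of their
  // localizations falls outside the window), so they are excluded from the
  // count statistics; defaults to the whole box
  double core_x0, core_x1, core_y0, core_y1;

  bool xi_update() {
    if (xi_mode != 1 || count_model != 0) return false;
    double n_core = 0.0; int K_core = 0;
    for (int k = 0; k < K; ++k) {
      if (mux[k] >= core_x0 && mux[k] <= core_x1 &&
          muy[k] >= core_y0 && muy[k] <= core_y1) {
        n_core += cnt[k]; K_core += 1;
      }
    }
    if (K_core == 0) { n_core = N; K_core = K; }
    if (xi_sampler == 0) {
      lambda = R::rgamma(eta + n_core, 1.0 / (K_core + eta / gamma_));
      if (lambda <= 0) lambda = 1e-8;
      return true;
    }
    // Metropolis step on log(lambda), sd xi_mh_sd; prior Gamma(shape eta, mean gamma)
    double lp = std::log(lambda) + xi_mh_sd * norm_rand();
    double lam2 = std::exp(lp);
    double la = (eta + n_core) * (std::log(lam2) - std::log(lambda))
                - (K_core + eta / gamma_) * (lam2 - lambda);
    if (std::log(unif_rand()) <= la) { lambda = lam2; return true; }
    return false;
  }
};

// [[Rcpp::export]]
List rjmcmc_chain_cpp(NumericVector x, NumericVector y,
                      NumericVector sx, NumericVector sy, NumericVector t,
                      NumericVector box,
                      int n_burnin, int n_samples,
                      NumericVector jump_probs,
                      int count_model, int xi_mode, int xi_sampler,
                      double lambda_init, double eta, double gamma_,
                      double xi_mh_sd, int xi_stride,
                      bool drift, double sd_a,
                      IntegerVector z_init, NumericMatrix mu_init,
                      bool store_z, NumericVector core_box) {
  RNGScope scope;
  Sampler S;
  S.N = x.size();
  S.x = as<std::vector<double> >(x);
  S.y = as<std::vector<double> >(y);
  S.sx = as<std::vector<double> >(sx);
  S.sy = as<std::vector<double> >(sy);
  S.t = as<std::vector<double> >(t);
  S.wx.resize(S.N); S.wy.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.wx[i] = 1.0 / (S.sx[i] * S.sx[i]);
    S.wy[i] = 1.0 / (S.sy[i] * S.sy[i]);
  }
  S.xmin = box[0]; S.xmax = box[1]; S.ymin = box[2]; S.ymax = box[3];
  S.area = (S.xmax - S.xmin) * (S.ymax - S.ymin);
  S.count_model = count_model; S.xi_mode = xi_mode; S.xi_sampler = xi_sampler;
  S.lambda = lambda_init; S.eta = eta; S.gamma_ = gamma_;
  S.xi_mh_sd = xi_mh_sd; S.xi_stride = xi_stride;
  S.drift = drift; S.sd_a = sd_a;
  if (core_box.size() == 4) {
    S.core_x0 = core_box[0]; S.core_x1 = core_box[1];
    S.core_y0 = core_box[2]; S.core_y1 = core_box[3];
  } else {
    S.core_x0 = S.xmin; S.core_x1 = S.xmax;
    S.core_y0 = S.ymin; S.core_y1 = S.ymax;
  }

  S.K = mu_init.nrow();
  S.mux.resize(S.K); S.muy.resize(S.K); S.ax.assign(S.K, 0.0); S.ay.assign(S.K, 0.0);
  for (int k = 0; k < S.K; ++k) { S.mux[k] = mu_init(k, 0); S.muy[k] = mu_init(k, 1); }
  S.z.resize(S.N); S.cnt.assign(S.K, 0);
  for (int i = 0; i < S.N; ++i) { S.z[i] = z_init[i] - 1; S.cnt[S.z[i]]++; }
  S.cap = std::max(8, S.K);
  S.W.assign((size_t)S.N * S.cap, 0.0);
  S.C.assign(S.N, 0.0);
  S.rebuild_cache();

  double p_move = jump_probs[0], p_alloc = jump_probs[1], p_birth = jump_probs[2];
  int n_iter = n_burnin + n_samples;
  std::vector<int> recK; recK.reserve(n_samples);
  std::vector<double> recXi; recXi.reserve(n_samples);
  std::vector<double> rmux, rmuy, rax, ray; std::vector<int> rn, rsamp;
  std::vector<int> recZ;
  if (store_z) recZ.reserve((size_t)n_samples * S.N);
  long prop[5] = {0, 0, 0, 0, 0}, acc[5] = {0, 0, 0, 0, 0};

  for (int it = 0; it < n_iter; ++it) {
    double u = unif_rand();
    if (u < p_move) {
      prop[0]++; S.move_update(); acc[0]++;
    } else if (u < p_move + p_alloc) {
      prop[1]++; if (S.allocate_update()) acc[1]++;
    } else if (u < p_move + p_alloc + p_birth) {
      prop[2]++; if (S.birth_update()) acc[2]++;
    } else {
      prop[3]++; if (S.death_update()) acc[3]++;
    }
    if (S.xi_mode == 1 && ((it + 1) % S.xi_stride == 0)) {
      prop[4]++; if (S.xi_update()) acc[4]++;
    }
    if (it >= n_burnin) {
      int s = it - n_burnin + 1;
      recK.push_back(S.K);
      recXi.push_back(S.lambda);
      for (int k = 0; k < S.K; ++k) {
        rsamp.push_back(s);
        rmux.push_back(S.mux[k]); rmuy.push_back(S.muy[k]);
        rax.push_back(S.ax[k]); ray.push_back(S.ay[k]);
        rn.push_back(S.cnt[k]);
      }
      if (store_z) for (int i = 0; i < S.N; ++i) recZ.push_back(S.z[i] + 1);
    }
  }

  int M = rmux.size();
  NumericMatrix mu(M, 2), a(M, 2);
  IntegerVector nvec(M), sampvec(M);
  for (int r = 0; r < M; ++r) {
    mu(r, 0) = rmux[r]; mu(r, 1) = rmuy[r];
    a(r, 0) = rax[r]; a(r, 1) = ray[r];
    nvec[r] = rn[r]; sampvec[r] = rsamp[r];
  }
  NumericMatrix accmat(5, 2);
  for (int jj = 0; jj < 5; ++jj) { accmat(jj, 0) = prop[jj]; accmat(jj, 1) = acc[jj]; }
  List out = List::create(
    _["K"] = wrap(recK), _["xi"] = wrap(recXi),
    _["sample"] = sampvec, _["mu"] = mu, _["a"] = a, _["n_loc"] = nvec,
    _["accept"] = accmat);
  if (store_z) {
    IntegerMatrix zm(n_samples, S.N);
    for (int s = 0; s < n_samples; ++s)
      for (int i = 0; i < S.N; ++i) zm(s, i) = recZ[(size_t)s * S.N + i];
    out["z"] = zm;
  }
  return out;
}
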