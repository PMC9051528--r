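// Physics-informed neural network engine for 2CXM parameter inference.
//
// A small fully-connected network maps standardised time tau to the
// normalised concentrations of all K pixels plus the AIF:
//
//   tau -> [Cp_1..Cp_K, Ce_1..Ce_K, CAIF]   (2K + 1 outputs)
//
// Hidden layers are dense -> tanh -> batch normalisation.  The time
// derivative of every output w.r.t. tau is propagated alongside the
// forward pass (forward-mode tangent; exact for the network as defined,
// with the batch-normalisation statistics treated as constants).
// Reverse-mode differentiation then runs over the joint (value, tangent)
// graph, so the residual loss, which involves dC/dtau, contributes exact
// gradients to the weights and to the log-parameterised kinetic
// parameters.  Tangents are only propagated for the collocation block of
// the batch (the only place they are needed during training), and the
// residual/adjoint arithmetic is fused into single passes over the
// pixels-by-collocation block, which is where the bulk of the work sits.
//
// Everything is templated on the scalar type: float for training speed,
// double for gradient checks and prediction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using arma::uword;

static const double BN_EPS = 1e-5;

template <class T>
struct PNet {
  std::vector<arma::Mat<T>> W;          // L+1 dense layers
  std::vector<arma::Col<T>> b;
  std::vector<arma::Col<T>> g, be;      // batch-norm gain/shift per hidden layer
  int L;                                // number of hidden layers
  uword M;                              // output dimension = 2K + 1
};

template <class T>
struct Cache {
  std::vector<arma::Mat<T>> Z, S, dA, H, dH, Zhat;
  std::vector<arma::Col<T>> gs, mu, sd, invsd;
  arma::Mat<T> U;    // M x B outputs
  arma::Mat<T> Vc;   // M x nc output tangents at columns c0..c0+nc-1
};

template <class T>
struct Grads {
  std::vector<arma::Mat<T>> W;
  std::vector<arma::Col<T>> b, g, be;
};

template <class T>
PNet<T> net_from_list(const Rcpp::List& net) {
  PNet<T> out;
  Rcpp::List W = net["W"], b = net["b"], g = net["gamma"], be = net["beta"];
  out.L = W.size() - 1;
  for (int l = 0; l < (int)W.size(); ++l) {
    out.W.push_back(arma::conv_to<arma::Mat<T>>::from(
        Rcpp::as<arma::mat>(W[l])));
    out.b.push_back(arma::conv_to<arma::Col<T>>::from(
        Rcpp::as<arma::vec>(b[l])));
  }
  for (int l = 0; l < out.L; ++l) {
    out.g.push_back(arma::conv_to<arma::Col<T>>::from(
        Rcpp::as<arma::vec>(g[l])));
    out.be.push_back(arma::conv_to<arma::Col<T>>::from(
        Rcpp::as<arma::vec>(be[l])));
  }
  out.M = out.W.back().n_rows;
  return out;
}

template <class T>
Rcpp::List net_to_list(const PNet<T>& net) {
  Rcpp::List W(net.L + 1), b(net.L + 1), g(net.L), be(net.L);
  for (int l = 0; l <= net.L; ++l) {
    W[l] = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.W[l]));
    b[l] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.b[l]));
  }
  for (int l = 0; l < net.L; ++l) {
    g[l] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.g[l]));
    be[l] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.be[l]));
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b,
                            Rcpp::Named("gamma") = g, Rcpp::Named("beta") = be);
}

// Forward pass; output tangents for columns [c0, c0 + nc).  If use_stats,
// the supplied batch-norm statistics replace those of the current batch
// (prediction convention).
template <class T>
void forward_pass(const PNet<T>& net, const arma::Row<T>& tau, uword c0,
                  uword nc, bool use_stats,
                  const std::vector<arma::Col<T>>& mu_in,
                  const std::vector<arma::Col<T>>& sd_in, Cache<T>& C) {
  const int L = net.L;
  if ((int)C.Z.size() != L) {
    C.Z.resize(L); C.S.resize(L); C.dA.resize(L); C.H.resize(L);
    C.dH.resize(L); C.Zhat.resize(L); C.gs.resize(L); C.mu.resize(L);
    C.sd.resize(L); C.invsd.resize(L);
  }
  arma::Mat<T> X = tau;                                 // 1 x B
  arma::Mat<T> dX;
  if (nc > 0) dX.ones(1, nc);                           // d tau/d tau
  for (int l = 0; l < L; ++l) {
    arma::Mat<T> A = net.W[l] * X;
    A.each_col() += net.b[l];
    C.Z[l] = arma::tanh(A);
    C.S[l] = T(1) - C.Z[l] % C.Z[l];
    if (use_stats) {
      C.mu[l] = mu_in[l]; C.sd[l] = sd_in[l];
    } else {
      C.mu[l] = arma::mean(C.Z[l], 1);
      arma::Col<T> var = arma::mean(arma::square(C.Z[l]), 1) -
                         arma::square(C.mu[l]);
      var.clamp(T(0), std::numeric_limits<T>::max());
      C.sd[l] = arma::sqrt(var + T(BN_EPS));
    }
    C.invsd[l] = T(1) / C.sd[l];
    C.gs[l] = net.g[l] % C.invsd[l];
    C.Zhat[l] = C.Z[l].each_col() - C.mu[l];
    C.Zhat[l].each_col() %= C.invsd[l];
    C.H[l] = C.Zhat[l].each_col() % net.g[l];
    C.H[l].each_col() += net.be[l];
    if (nc > 0) {
      C.dA[l] = net.W[l] * dX;
      C.dH[l] = (C.S[l].cols(c0, c0 + nc - 1) % C.dA[l]).eval()
                    .each_col() % C.gs[l];
      dX = C.dH[l];
    }
    X = C.H[l];
  }
  C.U = net.W[L] * X;
  C.U.each_col() += net.b[L];
  if (nc > 0) C.Vc = net.W[L] * dX;
  else C.Vc.set_size(net.M, 0);
}

// Reverse pass over the joint (value, tangent) graph.  Ubar is M x B,
// Vbar is M x nc.  Tangent caches (dA, dH) are nc columns wide and refer
// to batch columns [c0, c0 + nc).  With batch_stats the batch-norm
// statistics are treated as functions of the pre-activations (the
// batch-mode convention of the reference deep-learning frameworks) and
// their gradient contributions — the centring/decorrelation terms on the
// primal path and the 1/sd sensitivity on the tangent path — are
// included, making the gradient exact for the batch-mode loss; without
// it the statistics are constants (frozen-statistics convention).
template <class T>
void backward_pass(const PNet<T>& net, const Cache<T>& C,
                   const arma::Row<T>& tau, const arma::Mat<T>& Ubar,
                   const arma::Mat<T>& Vbar, uword c0, uword nc,
                   bool batch_stats, Grads<T>& G) {
  const int L = net.L;
  if ((int)G.W.size() != L + 1) {
    G.W.resize(L + 1); G.b.resize(L + 1); G.g.resize(L); G.be.resize(L);
  }
  const arma::Mat<T> tau_mat(tau);
  const arma::Mat<T>& Xtop = (L > 0) ? C.H[L - 1] : tau_mat;
  G.W[L] = Ubar * Xtop.t();
  if (nc > 0) G.W[L] += Vbar * C.dH[L - 1].t();
  G.b[L] = arma::sum(Ubar, 1);
  arma::Mat<T> Hbar = net.W[L].t() * Ubar;               // nh x B
  arma::Mat<T> dHbar;                                    // nh x nc
  if (nc > 0) dHbar = net.W[L].t() * Vbar;
  for (int l = L - 1; l >= 0; --l) {
    const uword B = Hbar.n_cols;
    arma::Mat<T> dZbar, dZ;
    G.g[l] = arma::sum(Hbar % C.Zhat[l], 1);
    G.be[l] = arma::sum(Hbar, 1);
    if (nc > 0) {
      dZ = C.S[l].cols(c0, c0 + nc - 1) % C.dA[l];
      G.g[l] += arma::sum((dHbar % dZ).eval().each_col() % C.invsd[l], 1);
      dZbar = dHbar.each_col() % C.gs[l];
    }
    arma::Mat<T> Zbar;
    if (batch_stats) {
      // exact batch-mode backward: centre, remove the variance direction,
      // and add the tangent path's sensitivity to 1/sd
      arma::Col<T> m1 = arma::mean(Hbar, 1);
      arma::Col<T> m2 = arma::mean(Hbar % C.Zhat[l], 1);
      Zbar = Hbar.each_col() - m1;
      Zbar -= C.Zhat[l].each_col() % m2;
      Zbar.each_col() %= C.gs[l];
      if (nc > 0) {
        arma::Col<T> tm = arma::sum(dHbar % dZ, 1) / T(B);
        Zbar -= C.Zhat[l].each_col() %
                (C.gs[l] % tm % C.invsd[l]);
      }
    } else {
      Zbar = Hbar.each_col() % C.gs[l];
    }
    arma::Mat<T> Abar = C.S[l] % Zbar;
    arma::Mat<T> dAbar;
    if (nc > 0) {
      Abar.cols(c0, c0 + nc - 1) -=
          T(2) * (C.Z[l].cols(c0, c0 + nc - 1) %
                  C.S[l].cols(c0, c0 + nc - 1) % C.dA[l] % dZbar);
      dAbar = C.S[l].cols(c0, c0 + nc - 1) % dZbar;
    }
    if (l > 0) {
      G.W[l] = Abar * C.H[l - 1].t();
      if (nc > 0) G.W[l] += dAbar * C.dH[l - 1].t();
      G.b[l] = arma::sum(Abar, 1);
      Hbar = net.W[l].t() * Abar;
      if (nc > 0) dHbar = net.W[l].t() * dAbar;
    } else {
      G.W[0] = Abar * tau_mat.t();
      if (nc > 0) G.W[0] += arma::sum(dAbar, 1);
      G.b[0] = arma::sum(Abar, 1);
    }
  }
}

struct LossTerms {
  double LC, Lr, Lb, Lreg, LC_aif, Lb_aif, Lreg_aif, total;
};

// Losses, output adjoints and kinetic-parameter gradients, fused into
// single passes over each batch block.
// Column layout of the batch: [observed (B1) | collocation (Nr) | t = 0].
template <class T>
LossTerms loss_and_adjoints(const Cache<T>& C, const arma::Mat<T>& cobs,
                            const arma::Row<T>& aifobs,
                            const arma::Col<T>& Fp, const arma::Col<T>& vp,
                            const arma::Col<T>& ve, const arma::Col<T>& PS,
                            T kappa, double wC, double wr, double wb,
                            double wreg, int variant, arma::Mat<T>& Ubar,
                            arma::Mat<T>& Vbar, arma::Mat<T>& gkin) {
  const uword K = Fp.n_elem;
  const uword B1 = cobs.n_cols;
  const uword Nr = C.Vc.n_cols;
  const uword B = C.U.n_cols;
  const uword ib = B - 1;
  const uword c0 = B1;
  const bool use_cxm = (variant != 1);   // rp, re residuals
  const bool use_red = (variant != 0);   // reduced residual
  Ubar.zeros(C.U.n_rows, B);
  Vbar.zeros(C.U.n_rows, Nr);
  gkin.zeros(K, 4);   // d(total)/d(Fp, vp, ve, PS), natural scale

  const T* fp = Fp.memptr(); const T* vpp = vp.memptr();
  const T* vep = ve.memptr(); const T* psp = PS.memptr();
  arma::Col<T> vpk = vp * kappa, vek = ve * kappa;
  const T* vpkp = vpk.memptr(); const T* vekp = vek.memptr();
  T* gFp = gkin.colptr(0); T* gvp = gkin.colptr(1);
  T* gve = gkin.colptr(2); T* gPS = gkin.colptr(3);

  // --- data loss (observed block) --------------------------------------
  double LC = 0.0, LC_aif = 0.0;
  const T cC = T(2.0 * wC / (double)K);
  const T cCa = T(2.0 * wC);
  for (uword j = 0; j < B1; ++j) {
    const T* u = C.U.colptr(j);
    const T* co = cobs.colptr(j);
    T* ub = Ubar.colptr(j);
    for (uword i = 0; i < K; ++i) {
      const T cp = u[i], ce = u[K + i];
      const T e = vpp[i] * cp + vep[i] * ce - co[i];
      LC += (double)(e * e);
      ub[i] += cC * e * vpp[i];
      ub[K + i] += cC * e * vep[i];
      gvp[i] += cC * e * cp;
      gve[i] += cC * e * ce;
    }
    const T ea = u[2 * K] - aifobs(j);
    LC_aif += (double)(ea * ea);
    ub[2 * K] += cCa * ea;
  }
  LC /= (double)K;

  // --- boundary loss (last column, t = 0) ------------------------------
  double Lb = 0.0;
  {
    const T* u = C.U.colptr(ib);
    T* ub = Ubar.colptr(ib);
    const T cb = T(2.0 * wb / (double)K);
    for (uword i = 0; i < 2 * K; ++i) {
      Lb += (double)(u[i] * u[i]);
      ub[i] += cb * u[i];
    }
  }
  Lb /= (double)K;
  const double Lb_aif = (double)(C.U(2 * K, ib) * C.U(2 * K, ib));
  Ubar(2 * K, ib) += T(2.0 * wb) * C.U(2 * K, ib);

  // --- residual + non-negativity losses (collocation block) ------------
  double Lr = 0.0, Lreg = 0.0, Lreg_aif = 0.0;
  if (Nr > 0) {
    const T gsc = T(2.0 * wr / ((double)K * (double)Nr));
    const T creg = T(2.0 * wreg / ((double)K * (double)Nr));
    const T crega = T(2.0 * wreg / (double)Nr);
    for (uword j = 0; j < Nr; ++j) {
      const T* u = C.U.colptr(c0 + j);
      const T* v = C.Vc.colptr(j);
      T* ub = Ubar.colptr(c0 + j);
      T* vb = Vbar.colptr(j);
      const T ca = u[2 * K];
      T ub_aif = 0;
      for (uword i = 0; i < K; ++i) {
        const T cp = u[i], ce = u[K + i];
        const T vcp = v[i], vce = v[K + i];
        const T da = ca - cp, dpe = ce - cp;
        if (use_cxm) {
          const T rp = vpkp[i] * vcp - psp[i] * dpe - fp[i] * da;
          const T re = vekp[i] * vce + psp[i] * dpe;
          Lr += (double)(rp * rp + re * re);
          const T Rp = gsc * rp, Re = gsc * re;
          vb[i] += Rp * vpkp[i];
          vb[K + i] += Re * vekp[i];
          ub[i] += Rp * (psp[i] + fp[i]) - Re * psp[i];
          ub[K + i] += (Re - Rp) * psp[i];
          ub_aif -= Rp * fp[i];
          gFp[i] -= Rp * da;
          gvp[i] += kappa * Rp * vcp;
          gve[i] += kappa * Re * vce;
          gPS[i] += (Re - Rp) * dpe;
        }
        if (use_red) {
          const T rm = vpkp[i] * vcp + vekp[i] * vce - fp[i] * da;
          Lr += (double)(rm * rm);
          const T Rm = gsc * rm;
          vb[i] += Rm * vpkp[i];
          vb[K + i] += Rm * vekp[i];
          ub[i] += Rm * fp[i];
          ub_aif -= Rm * fp[i];
          gFp[i] -= Rm * da;
          gvp[i] += kappa * Rm * vcp;
          gve[i] += kappa * Rm * vce;
        }
        if (cp < T(0)) { Lreg += (double)(cp * cp); ub[i] += creg * cp; }
        if (ce < T(0)) {
          Lreg += (double)(ce * ce);
          ub[K + i] += creg * ce;
        }
      }
      if (ca < T(0)) {
        Lreg_aif += (double)(ca * ca);
        ub[2 * K] += crega * ca;
      }
      ub[2 * K] += ub_aif;
    }
    Lr /= (double)K * (double)Nr;
    Lreg /= (double)K * (double)Nr;
    Lreg_aif /= (double)Nr;
  }

  LossTerms out;
  out.LC = LC; out.Lr = Lr; out.Lb = Lb; out.Lreg = Lreg;
  out.LC_aif = LC_aif; out.Lb_aif = Lb_aif; out.Lreg_aif = Lreg_aif;
  out.total = wC * LC + wr * Lr + wb * Lb + wreg * Lreg + wC * LC_aif +
              wb * Lb_aif + wreg * Lreg_aif;
  return out;
}

template <class T>
struct AdamState {
  std::vector<arma::Mat<T>> mW, vW;
  std::vector<arma::Mat<T>> mb, vb, mg, vg, mbe, vbe;
  arma::Mat<T> mk, vk;
};

template <class T>
void adam_step(arma::Mat<T>& p, const arma::Mat<T>& grad, arma::Mat<T>& m,
               arma::Mat<T>& v, T lr, T b1, T b2, T eps, double c1,
               double c2) {
  m = b1 * m + (T(1) - b1) * grad;
  v = b2 * v + (T(1) - b2) * arma::square(grad);
  p -= lr * (m / T(c1)) / (arma::sqrt(v / T(c2)) + eps);
}

template <class T>
void adam_step_col(arma::Col<T>& p, const arma::Col<T>& grad,
                   arma::Mat<T>& m, arma::Mat<T>& v, T lr, T b1, T b2,
                   T eps, double c1, double c2) {
  arma::Mat<T> gm(grad);
  m = b1 * m + (T(1) - b1) * gm;
  v = b2 * v + (T(1) - b2) * arma::square(gm);
  p -= lr * arma::vectorise(m / T(c1)) /
       (arma::sqrt(arma::vectorise(v / T(c2))) + eps);
}

template <class T>
Rcpp::List train_impl(const Rcpp::List& net0, const arma::mat& logk0,
                      const arma::vec& tau_obs, const arma::mat& cobs0,
                      const arma::vec& aifobs0, const arma::vec& tau_col0,
                      double tau0, double kappa0, const arma::vec& wts,
                      int variant, int iterations, double lr0,
                      int decay_every, double decay_factor, int log_every,
                      bool train_net, bool train_kin, bool resample,
                      double tau_lo, double tau_hi, int seed) {
  PNet<T> net = net_from_list<T>(net0);
  arma::Mat<T> logk = arma::conv_to<arma::Mat<T>>::from(logk0);
  const uword K = logk.n_rows;
  const uword B1 = tau_obs.n_elem;
  const uword Nr = tau_col0.n_elem;
  const uword B = B1 + Nr + 1;
  const T kappa = T(kappa0);
  const double wC = wts(0), wr = wts(1), wb = wts(2), wreg = wts(3);
  arma::Mat<T> cobs = arma::conv_to<arma::Mat<T>>::from(cobs0);
  arma::Row<T> aifobs = arma::conv_to<arma::Row<T>>::from(aifobs0.t());

  arma::Row<T> tau(B);
  tau.cols(0, B1 - 1) = arma::conv_to<arma::Row<T>>::from(tau_obs.t());
  tau.cols(B1, B1 + Nr - 1) = arma::conv_to<arma::Row<T>>::from(tau_col0.t());
  tau(B - 1) = T(tau0);

  std::mt19937_64 rng((unsigned long long)seed);
  std::uniform_real_distribution<double> unif(tau_lo, tau_hi);

  AdamState<T> st;
  st.mW.resize(net.L + 1); st.vW.resize(net.L + 1);
  st.mb.resize(net.L + 1); st.vb.resize(net.L + 1);
  st.mg.resize(net.L); st.vg.resize(net.L);
  st.mbe.resize(net.L); st.vbe.resize(net.L);
  for (int l = 0; l <= net.L; ++l) {
    st.mW[l].zeros(arma::size(net.W[l])); st.vW[l].zeros(arma::size(net.W[l]));
    st.mb[l].zeros(net.b[l].n_elem, 1);   st.vb[l].zeros(net.b[l].n_elem, 1);
  }
  for (int l = 0; l < net.L; ++l) {
    st.mg[l].zeros(net.g[l].n_elem, 1);  st.vg[l].zeros(net.g[l].n_elem, 1);
    st.mbe[l].zeros(net.be[l].n_elem, 1); st.vbe[l].zeros(net.be[l].n_elem, 1);
  }
  st.mk.zeros(K, 4); st.vk.zeros(K, 4);
  const T b1 = T(0.9), b2 = T(0.999), aeps = T(1e-8);

  const int nlog = iterations / std::max(log_every, 1) + 2;
  arma::mat logmat(nlog, 11);
  int nlogged = 0;

  Cache<T> C;
  Grads<T> G;
  arma::Mat<T> Ubar, Vbar, gkin, glog(K, 4);
  std::vector<arma::Col<T>> dummy_mu, dummy_sd;

  for (int it = 1; it <= iterations; ++it) {
    if (resample && it > 1) {
      for (uword j = 0; j < Nr; ++j) tau(B1 + j) = T(unif(rng));
    }
    arma::Col<T> Fp = arma::exp(logk.col(0)), vp = arma::exp(logk.col(1));
    arma::Col<T> ve = arma::exp(logk.col(2)), PS = arma::exp(logk.col(3));
    forward_pass<T>(net, tau, B1, Nr, false, dummy_mu, dummy_sd, C);
    LossTerms Lt = loss_and_adjoints<T>(C, cobs, aifobs, Fp, vp, ve, PS,
                                        kappa, wC, wr, wb, wreg, variant,
                                        Ubar, Vbar, gkin);
    if (!std::isfinite(Lt.total)) {
      Rcpp::stop("non-finite loss at iteration %d (LC=%g Lr=%g Lb=%g "
                 "Lreg=%g LC_aif=%g)", it, Lt.LC, Lt.Lr, Lt.Lb, Lt.Lreg,
                 Lt.LC_aif);
    }
    backward_pass<T>(net, C, tau, Ubar, Vbar, B1, Nr, true, G);

    const double adt = (double)it;
    const double c1 = 1.0 - std::pow(0.9, adt);
    const double c2 = 1.0 - std::pow(0.999, adt);
    const T lr = T(lr0 / std::pow(decay_factor,
                                  std::floor((double)(it - 1) /
                                             (double)decay_every)));
    if (train_net) {
      for (int l = 0; l <= net.L; ++l) {
        adam_step<T>(net.W[l], G.W[l], st.mW[l], st.vW[l], lr, b1, b2,
                     aeps, c1, c2);
        adam_step_col<T>(net.b[l], G.b[l], st.mb[l], st.vb[l], lr, b1, b2,
                         aeps, c1, c2);
      }
      for (int l = 0; l < net.L; ++l) {
        adam_step_col<T>(net.g[l], G.g[l], st.mg[l], st.vg[l], lr, b1, b2,
                         aeps, c1, c2);
        adam_step_col<T>(net.be[l], G.be[l], st.mbe[l], st.vbe[l], lr, b1,
                         b2, aeps, c1, c2);
      }
    }
    if (train_kin) {
      glog.col(0) = Fp % gkin.col(0);
      glog.col(1) = vp % gkin.col(1);
      glog.col(2) = ve % gkin.col(2);
      glog.col(3) = PS % gkin.col(3);
      adam_step<T>(logk, glog, st.mk, st.vk, lr, b1, b2, aeps, c1, c2);
    }
    if (it == 1 || it % std::max(log_every, 1) == 0 || it == iterations) {
      logmat(nlogged, 0) = it;
      logmat(nlogged, 1) = Lt.LC;
      logmat(nlogged, 2) = Lt.Lr;
      logmat(nlogged, 3) = Lt.Lb;
      logmat(nlogged, 4) = Lt.Lreg;
      logmat(nlogged, 5) = Lt.LC_aif;
      logmat(nlogged, 6) = Lt.total;
      logmat(nlogged, 7) = arma::mean(arma::conv_to<arma::vec>::from(Fp));
      logmat(nlogged, 8) = arma::mean(arma::conv_to<arma::vec>::from(vp));
      logmat(nlogged, 9) = arma::mean(arma::conv_to<arma::vec>::from(ve));
      logmat(nlogged, 10) = arma::mean(arma::conv_to<arma::vec>::from(PS));
      ++nlogged;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  // final forward pass exposes the batch statistics used for prediction
  forward_pass<T>(net, tau, B1, Nr, false, dummy_mu, dummy_sd, C);
  Rcpp::List bn_mu(net.L), bn_sd(net.L);
  for (int l = 0; l < net.L; ++l) {
    bn_mu[l] = Rcpp::wrap(arma::conv_to<arma::vec>::from(C.mu[l]));
    bn_sd[l] = Rcpp::wrap(arma::conv_to<arma::vec>::from(C.sd[l]));
  }
  return Rcpp::List::create(
      Rcpp::Named("net") = net_to_list<T>(net),
      Rcpp::Named("logk") = arma::conv_to<arma::mat>::from(logk),
      Rcpp::Named("log") = logmat.rows(0, nlogged - 1),
      Rcpp::Named("bn_mu") = bn_mu, Rcpp::Named("bn_sd") = bn_sd);
}

// [[Rcpp::export]]
Rcpp::List pinn_train_cpp(Rcpp::List net0, arma::mat logk0, arma::vec tau_obs,
                          arma::mat cobs, arma::vec aifobs, arma::vec tau_col,
                          double tau0, double kappa, arma::vec wts,
                          int variant, int iterations, double lr0,
                          int decay_every, double decay_factor,
                          int log_every, bool train_net, bool train_kin,
                          bool resample, double tau_lo, double tau_hi,
                          int seed, bool single) {
  if (single)
    return train_impl<float>(net0, logk0, tau_obs, cobs, aifobs, tau_col,
                             tau0, kappa, wts, variant, iterations, lr0,
                             decay_every, decay_factor, log_every,
                             train_net, train_kin, resample, tau_lo,
                             tau_hi, seed);
  return train_impl<double>(net0, logk0, tau_obs, cobs, aifobs, tau_col,
                            tau0, kappa, wts, variant, iterations, lr0,
                            decay_every, decay_factor, log_every,
                            train_net, train_kin, resample, tau_lo, tau_hi,
                            seed);
}

// One forward/backward evaluation in double precision: loss terms plus
// all gradients.  With use_stats the supplied batch-norm statistics are
// frozen, making the objective a plain function of the parameters (the
// convention under which the gradients are exact; used by the
// finite-difference verification tests).
// [[Rcpp::export]]
Rcpp::List pinn_step_cpp(Rcpp::List net0, arma::mat logk0, arma::vec tau_obs,
                         arma::mat cobs, arma::vec aifobs, arma::vec tau_col,
                         double tau0, double kappa, arma::vec wts,
                         int variant, bool use_stats, Rcpp::List bn_mu,
                         Rcpp::List bn_sd) {
  PNet<double> net = net_from_list<double>(net0);
  const uword K = logk0.n_rows;
  const uword B1 = tau_obs.n_elem;
  const uword Nr = tau_col.n_elem;
  const uword B = B1 + Nr + 1;
  arma::Row<double> tau(B);
  tau.cols(0, B1 - 1) = tau_obs.t();
  if (Nr > 0) tau.cols(B1, B1 + Nr - 1) = tau_col.t();
  tau(B - 1) = tau0;
  arma::Col<double> Fp = arma::exp(logk0.col(0)), vp = arma::exp(logk0.col(1));
  arma::Col<double> ve = arma::exp(logk0.col(2)), PS = arma::exp(logk0.col(3));
  Cache<double> C;
  std::vector<arma::Col<double>> dmu, dsd;
  if (use_stats) {
    for (int l = 0; l < net.L; ++l) {
      dmu.push_back(Rcpp::as<arma::vec>(bn_mu[l]));
      dsd.push_back(Rcpp::as<arma::vec>(bn_sd[l]));
    }
  }
  forward_pass<double>(net, tau, B1, Nr, use_stats, dmu, dsd, C);
  arma::Mat<double> Ubar, Vbar, gkin;
  LossTerms Lt = loss_and_adjoints<double>(C, cobs, aifobs.t(), Fp, vp, ve,
                                           PS, kappa, wts(0), wts(1),
                                           wts(2), wts(3), variant, Ubar,
                                           Vbar, gkin);
  Grads<double> G;
  backward_pass<double>(net, C, tau, Ubar, Vbar, B1, Nr, !use_stats, G);
  arma::mat glog(K, 4);
  glog.col(0) = Fp % gkin.col(0);
  glog.col(1) = vp % gkin.col(1);
  glog.col(2) = ve % gkin.col(2);
  glog.col(3) = PS % gkin.col(3);
  Rcpp::List gW(net.L + 1), gb(net.L + 1), gg(net.L), gbe(net.L);
  for (int l = 0; l <= net.L; ++l) {
    gW[l] = Rcpp::wrap(G.W[l]);
    gb[l] = Rcpp::wrap(arma::vec(G.b[l]));
  }
  for (int l = 0; l < net.L; ++l) {
    gg[l] = Rcpp::wrap(arma::vec(G.g[l]));
    gbe[l] = Rcpp::wrap(arma::vec(G.be[l]));
  }
  return Rcpp::List::create(
      Rcpp::Named("LC") = Lt.LC, Rcpp::Named("Lr") = Lt.Lr,
      Rcpp::Named("Lb") = Lt.Lb, Rcpp::Named("Lreg") = Lt.Lreg,
      Rcpp::Named("LC_aif") = Lt.LC_aif, Rcpp::Named("Lb_aif") = Lt.Lb_aif,
      Rcpp::Named("Lreg_aif") = Lt.Lreg_aif,
      Rcpp::Named("total") = Lt.total, Rcpp::Named("gW") = gW,
      Rcpp::Named("gb") = gb, Rcpp::Named("ggamma") = gg,
      Rcpp::Named("gbeta") = gbe, Rcpp::Named("glogk") = glog);
}

// Forward evaluation (values and time-tangents of every output) in
// double precision.  Batch-norm statistics are either computed from this
// batch or supplied (frozen statistics, the prediction convention).
// [[Rcpp::export]]
Rcpp::List pinn_eval_cpp(Rcpp::List net0, arma::vec tau, bool use_stats,
                         Rcpp::List bn_mu, Rcpp::List bn_sd) {
  PNet<double> net = net_from_list<double>(net0);
  std::vector<arma::Col<double>> mu, sd;
  if (use_stats) {
    for (int l = 0; l < net.L; ++l) {
      mu.push_back(Rcpp::as<arma::vec>(bn_mu[l]));
      sd.push_back(Rcpp::as<arma::vec>(bn_sd[l]));
    }
  }
  Cache<double> C;
  arma::Row<double> taur = tau.t();
  forward_pass<double>(net, taur, 0, tau.n_elem, use_stats, mu, sd, C);
  Rcpp::List omu(net.L), osd(net.L);
  for (int l = 0; l < net.L; ++l) {
    omu[l] = Rcpp::wrap(arma::vec(C.mu[l]));
    osd[l] = Rcpp::wrap(arma::vec(C.sd[l]));
  }
  return Rcpp::List::create(Rcpp::Named("U") = C.U, Rcpp::Named("V") = C.Vc,
                            Rcpp::Named("bn_mu") = omu,
                            Rcpp::Named("bn_sd") = osd);
}
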