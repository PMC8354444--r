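// Core engine: forward simulation of the rectified-linear output circuit
// with dopamine-gated KC->MBON plasticity, and the exact reverse-mode
// gradient of the trial losses through the unrolled dynamics
// (backpropagation through time). The discrete forward model is
//
//   r_t   = (1-dt/tau) r_{t-1} + (dt/tau) [W r_{t-1} + b + I_t]_+
//   I_t   : MBONs <- Weff_{t-1} kc_t, FBNs <- Wext ext_t, DANs <- 0
//   u_t   = w_{t-1} + dt( (G dbar_{t-1}) kc_t' - (G d_t) kbar_{t-1}'
//                          + beta (G dbar_{t-1}) )
//   w_t   = clip(u_t, 0, w_max)            (clip optional)
//   Weff_t= (1-dt/tau_w) Weff_{t-1} + (dt/tau_w) w_t
//   kbar_t= (1-dt/tau_k) kbar_{t-1} + (dt/tau_k) kc_t   (likewise dbar)
//
// with d_t the DAN rates taken from r_t. The backward pass mirrors these
// assignments exactly; clipping and rectification use subgradients that are
// zero on the clamped side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct Par {
  int m, d, f, k, N;
  mat W, Wext, Wro, Wstate, G, Wkm;
  vec b, beta;
  double tau, dt, tau_w, tau_k, tau_d, w_max;
  bool clip, has_state, has_beta, has_km;
  vec r0;
  // navigation readouts (over FBN rates)
  vec Wu, Wom;
  double bu, bom;
  bool has_vel;
};

Par parse_par(const List& par) {
  Par p;
  p.m = Rcpp::as<int>(par["n_mbon"]);
  p.d = Rcpp::as<int>(par["n_dan"]);
  p.f = Rcpp::as<int>(par["n_fbn"]);
  p.k = Rcpp::as<int>(par["n_kc"]);
  p.N = p.m + p.d + p.f;
  p.W = Rcpp::as<mat>(par["W"]);
  p.b = Rcpp::as<vec>(par["b"]);
  p.Wext = Rcpp::as<mat>(par["W_ext"]);
  p.Wro = Rcpp::as<mat>(par["W_readout"]);
  p.G = Rcpp::as<mat>(par["G"]);
  p.has_state = !Rf_isNull(par["W_state"]);
  if (p.has_state) p.Wstate = Rcpp::as<mat>(par["W_state"]);
  p.has_beta = !Rf_isNull(par["beta"]);
  if (p.has_beta) p.beta = Rcpp::as<vec>(par["beta"]);
  p.has_km = !Rf_isNull(par["W_km"]);
  if (p.has_km) p.Wkm = Rcpp::as<mat>(par["W_km"]);
  p.tau = Rcpp::as<double>(par["tau"]);
  p.dt = Rcpp::as<double>(par["dt"]);
  p.tau_w = Rcpp::as<double>(par["tau_w"]);
  p.tau_k = Rcpp::as<double>(par["tau_elig_kc"]);
  p.tau_d = Rcpp::as<double>(par["tau_elig_dan"]);
  p.w_max = Rcpp::as<double>(par["w_max"]);
  p.clip = Rcpp::as<bool>(par["clip"]);
  p.r0 = zeros<vec>(p.N);
  p.r0.subvec(p.m, p.N - 1).fill(0.1);
  p.has_vel = !Rf_isNull(par["W_u"]);
  if (p.has_vel) {
    p.Wu = Rcpp::as<vec>(par["W_u"]);
    p.Wom = Rcpp::as<vec>(par["W_omega"]);
    p.bu = Rcpp::as<double>(par["b_u"]);
    p.bom = Rcpp::as<double>(par["b_omega"]);
  }
  return p;
}

struct Grads {
  mat gW, gWext, gWro, gWstate, gWkm, gWe0;
  vec gb, gbeta, gWu, gWom;
  double gbu = 0, gbom = 0;
  void init(const Par& p) {
    gW = zeros<mat>(p.N, p.N);
    gb = zeros<vec>(p.N);
    gWext = zeros<mat>(p.Wext.n_rows, p.Wext.n_cols);
    gWro = zeros<mat>(p.Wro.n_rows, p.Wro.n_cols);
    gWstate = p.has_state ? zeros<mat>(3, p.d) : mat();
    gbeta = p.has_beta ? zeros<vec>(p.m) : vec();
    gWkm = p.has_km ? zeros<mat>(p.m, p.k) : mat();
    gWu = p.has_vel ? zeros<vec>(p.f) : vec();
    gWom = p.has_vel ? zeros<vec>(p.f) : vec();
  }
  List as_list(const Par& p) const {
    List g = List::create(
      Named("W") = gW, Named("b") = gb, Named("W_ext") = gWext,
      Named("W_readout") = gWro);
    if (p.has_state) g["W_state"] = gWstate;
    if (p.has_beta) g["beta"] = gbeta;
    if (p.has_km) g["W_km"] = gWkm;
    if (p.has_vel) {
      g["W_u"] = gWu; g["b_u"] = gbu;
      g["W_omega"] = gWom; g["b_omega"] = gbom;
    }
    return g;
  }
};

// Storage for one simulated phase (shared by open- and closed-loop runs).
struct Store {
  mat R;        // N x (T+1), col 0 = state at phase start
  mat A;        // relu masks (0/1), N x T
  cube CM;      // clip masks, m x k x T (empty unless plastic & clip)
  mat TK, TD;   // traces, (T+1) cols
  mat V, S;     // readouts
};

// rectified rate update, recording the relu mask
inline void step_rates(const Par& p, const vec& a, vec& r, double* Acol) {
  const double al = p.dt / p.tau;
  for (int i = 0; i < p.N; ++i) {
    double ai = a(i);
    Acol[i] = ai > 0 ? 1.0 : 0.0;
    r(i) = (1 - al) * r(i) + al * (ai > 0 ? ai : 0.0);
  }
}

// fused latent-weight update, clip and effective-weight relaxation
inline void step_plastic(const Par& p, const vec& ddbar, const vec& dd,
                         const double* kcc, const vec& tk,
                         mat& w, mat& We, double* cm) {
  const double aw = p.dt / p.tau_w;
  vec bt;
  if (p.has_beta) bt = p.beta % ddbar;
  for (int j = 0; j < p.k; ++j) {
    const double kj = kcc[j], tkj = tk(j);
    double* wc = w.colptr(j);
    double* Wec = We.colptr(j);
    double* cmc = cm ? cm + (size_t)j * p.m : nullptr;
    for (int i = 0; i < p.m; ++i) {
      double u = wc[i] + p.dt * (ddbar(i) * kj - dd(i) * tkj +
                                 (p.has_beta ? bt(i) : 0.0));
      if (p.clip) {
        double cv = 1.0;
        if (u <= 0) { u = 0; cv = 0; }
        else if (u >= p.w_max) { u = p.w_max; cv = 0; }
        cmc[i] = cv;
      }
      wc[i] = u;
      Wec[i] = (1 - aw) * Wec[i] + aw * u;
    }
  }
}

// fused backward chain through Weff relaxation and clip: on exit gw holds
// the adjoint of the pre-clip update (= the adjoint passed to w_{t-1})
inline void back_plastic_weights(const Par& p, mat& gw, mat& gWe,
                                 const double* cm) {
  const double aw = p.dt / p.tau_w;
  const size_t n = (size_t)p.m * p.k;
  double* gwp = gw.memptr();
  double* gWep = gWe.memptr();
  for (size_t i = 0; i < n; ++i) {
    double gwe = gWep[i];
    double g = gwp[i] + aw * gwe;
    gWep[i] = (1 - aw) * gwe;
    gwp[i] = cm ? g * cm[i] : g;
  }
}

// Forward-simulate T steps of one phase; kc/ext are the realized inputs.
void phase_forward(const Par& p, const mat& kc, const mat& ext,
                   const Rcpp::LogicalVector* reset, bool plastic,
                   vec& r, mat& w, mat& We, vec& tk, vec& td,
                   Store& st, cube* WeStore) {
  const int T = kc.n_cols;
  const double ak = p.dt / p.tau_k, ad = p.dt / p.tau_d;
  st.R.set_size(p.N, T + 1);
  st.A.set_size(p.N, T);
  st.TK.set_size(p.k, T + 1);
  st.TD.set_size(p.d, T + 1);
  if (plastic && p.clip) st.CM.set_size(p.m, p.k, T);
  st.R.col(0) = r;
  st.TK.col(0) = tk;
  st.TD.col(0) = td;
  if (WeStore) { WeStore->set_size(p.m, p.k, T + 1); WeStore->slice(0) = We; }
  for (int t = 0; t < T; ++t) {
    if (reset && (*reset)[t]) r = p.r0;
    vec a = p.W * r + p.b;
    const mat& Wm = p.has_km ? p.Wkm : We;
    a.subvec(0, p.m - 1) += Wm * kc.col(t);
    a.subvec(p.m + p.d, p.N - 1) += p.Wext * ext.col(t);
    step_rates(p, a, r, st.A.colptr(t));
    st.R.col(t + 1) = r;
    vec dan = r.subvec(p.m, p.m + p.d - 1);
    if (plastic)
      step_plastic(p, p.G * td, p.G * dan, kc.colptr(t), tk, w, We,
                   p.clip ? st.CM.slice_memptr(t) : nullptr);
    tk = (1 - ak) * tk + ak * kc.col(t);
    td = (1 - ad) * td + ad * dan;
    st.TK.col(t + 1) = tk;
    st.TD.col(t + 1) = td;
    if (WeStore) WeStore->slice(t + 1) = We;
  }
}

inline vec softmax_vec(const vec& x) {
  vec z = exp(x - x.max());
  return z / accu(z);
}

// Backward through one phase. On entry the adjoint buffers hold d(loss)/d(.)
// of the phase-final quantities; per-step loss adjoints are added by `addl`.
// gkc_out, when non-null, receives d(loss)/d(kc_t) per step (closed loop).
template <class AddLoss, class SenseBack>
void phase_backward(const Par& p, const mat& kc, const mat& ext,
                    const Rcpp::LogicalVector* reset, bool plastic,
                    const Store& st, const cube* WeStore,
                    vec& gr, mat& gWe, mat& gw, vec& gtk, vec& gtd,
                    Grads& G, AddLoss addl, SenseBack sense) {
  const int T = kc.n_cols;
  const double al = p.dt / p.tau, aw = p.dt / p.tau_w,
               ak = p.dt / p.tau_k, ad = p.dt / p.tau_d;
  for (int t = T - 1; t >= 0; --t) {
    const vec rt = st.R.col(t + 1);
    const bool rs = reset && (*reset)[t];
    const vec rprev = rs ? p.r0 : vec(st.R.col(t));
    const vec dan = rt.subvec(p.m, p.m + p.d - 1);
    vec gkc = zeros<vec>(p.k);

    addl(t, rt, gr);  // per-step loss terms -> gr (and readout grads)

    vec gtk_add, gtd_add;
    if (plastic) {
      // after this, gw holds the pre-clip update adjoint (passed to w_{t-1})
      back_plastic_weights(p, gw, gWe,
                           p.clip ? st.CM.slice_memptr(t) : nullptr);
      const mat& gu = gw;
      vec q = p.dt * (gu * kc.col(t));
      if (p.has_beta) {
        vec rowg = sum(gu, 1);
        q += p.dt * (p.beta % rowg);
        G.gbeta += p.dt * ((p.G * st.TD.col(t)) % rowg);
      }
      gtd_add = p.G.t() * q;
      vec pvec = -p.dt * (gu * st.TK.col(t));
      gr.subvec(p.m, p.m + p.d - 1) += p.G.t() * pvec;
      gtk_add = -p.dt * (gu.t() * (p.G * dan));
      if (WeStore) gkc += p.dt * (gu.t() * (p.G * st.TD.col(t)));
    }

    // trace input chains (td_t <- dan_t, tk_t <- kc_t)
    gr.subvec(p.m, p.m + p.d - 1) += ad * gtd;
    gkc += ak * gtk;

    // rate chain
    vec ga = al * (gr % st.A.col(t));
    G.gb += ga;
    G.gW += ga * rprev.t();
    vec ga_m = ga.subvec(0, p.m - 1);
    if (p.has_km) {
      G.gWkm += ga_m * kc.col(t).t();
      if (WeStore) gkc += p.Wkm.t() * ga_m;
    } else {
      gWe += ga_m * kc.col(t).t();
      if (WeStore) gkc += WeStore->slice(t).t() * ga_m;
    }
    vec ga_f = ga.subvec(p.m + p.d, p.N - 1);
    G.gWext += ga_f * ext.col(t).t();
    vec gext = p.Wext.t() * ga_f;
    vec gr_prev = rs ? zeros<vec>(p.N) : vec((1 - al) * gr + p.W.t() * ga);

    sense(t, gkc, gext);  // closed-loop: push input adjoints to pos/heading

    gr = gr_prev;
    gtk *= (1 - ak);
    gtd *= (1 - ad);
    if (plastic) { gtk += gtk_add; gtd += gtd_add; }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_trial(List par, arma::mat kc, arma::mat ext, arma::mat target,
                   Rcpp::Nullable<arma::mat> state_target,
                   Rcpp::LogicalVector reset, arma::vec loss_mask,
                   arma::mat w_init, arma::mat weff_init,
                   arma::vec tk_init, arma::vec td_init,
                   bool plastic, bool use_penalty, double lambda,
                   double dan_base, bool want_grad, bool want_rates,
                   bool want_final) {
  Par p = parse_par(par);
  const int T = kc.n_cols;
  const bool has_st = state_target.isNotNull();
  mat starget;
  if (has_st) starget = Rcpp::as<mat>(state_target.get());

  vec r = p.r0;
  mat w = w_init, We = weff_init;
  vec tk = tk_init, td = td_init;
  Store st;
  phase_forward(p, kc, ext, &reset, plastic, r, w, We, tk, td, st, nullptr);

  // readouts and loss
  const int dro = p.Wro.n_rows;
  mat V(dro, T), S;
  if (p.has_state && has_st) S = mat(3, T);
  double loss_read = 0, loss_pen = 0, loss_state = 0;
  for (int t = 0; t < T; ++t) {
    vec rm = st.R.col(t + 1).subvec(0, p.m - 1);
    V.col(t) = p.Wro * rm;
    vec dv = V.col(t) - target.col(t);
    loss_read += loss_mask(t) * dot(dv, dv);
    if (use_penalty) {
      vec ex = clamp(vec(st.R.col(t + 1).subvec(p.m, p.m + p.d - 1))
                       - dan_base, 0.0, datum::inf);
      loss_pen += lambda * dot(ex, ex);
    }
    if (p.has_state && has_st) {
      S.col(t) = softmax_vec(p.Wstate *
                             st.R.col(t + 1).subvec(p.m, p.m + p.d - 1));
      vec ds = S.col(t) - starget.col(t);
      loss_state += dot(ds, ds);
    }
  }
  loss_read /= T; loss_pen /= T; loss_state /= T;
  double loss = loss_read + loss_pen + loss_state;

  List out = List::create(
    Named("loss") = loss, Named("loss_readout") = loss_read,
    Named("loss_penalty") = loss_pen, Named("loss_state") = loss_state,
    Named("readout") = V);
  if (want_final) {
    out["w_final"] = w; out["weff_final"] = We;
    out["trace_kc_final"] = tk; out["trace_dan_final"] = td;
  }
  if (p.has_state && has_st) out["state_probs"] = S;
  if (want_rates) out["rates"] = mat(st.R.cols(1, T));

  if (want_grad) {
    Grads G; G.init(p);
    vec gr = zeros<vec>(p.N), gtk = zeros<vec>(p.k), gtd = zeros<vec>(p.d);
    mat gWe = zeros<mat>(p.m, p.k), gw = zeros<mat>(p.m, p.k);
    auto addl = [&](int t, const vec& rt, vec& gr_) {
      vec rm = rt.subvec(0, p.m - 1);
      vec gv = (2.0 * loss_mask(t) / T) * (V.col(t) - target.col(t));
      G.gWro += gv * rm.t();
      gr_.subvec(0, p.m - 1) += p.Wro.t() * gv;
      if (use_penalty) {
        vec dvec = rt.subvec(p.m, p.m + p.d - 1);
        vec ex = clamp(dvec - dan_base, 0.0, datum::inf);
        gr_.subvec(p.m, p.m + p.d - 1) += (2.0 * lambda / T) * ex;
      }
      if (p.has_state && has_st) {
        vec sl = S.col(t);
        vec gs = (2.0 / T) * (sl - starget.col(t));
        vec gl = sl % (gs - dot(sl, gs));
        G.gWstate += gl * rt.subvec(p.m, p.m + p.d - 1).t();
        gr_.subvec(p.m, p.m + p.d - 1) += p.Wstate.t() * gl;
      }
    };
    auto nosense = [](int, const vec&, const vec&) {};
    phase_backward(p, kc, ext, &reset, plastic, st, nullptr,
                   gr, gWe, gw, gtk, gtd, G, addl, nosense);
    out["grads"] = G.as_list(p);
  }
  return out;
}

namespace {

struct PlumeSense {
  // geometry of the two-source plume environment
  mat src;       // 2 x 2, column s = source position
  vec winddir1;  // per-source wind x1 direction (from source toward origin)
  double half_h = 0.25;

  // c and its derivative wrt (dx1, dx2); dx1 = downwind displacement
  static double conc(double dx1, double dx2, double* dc1, double* dc2) {
    double g = 1.0 / (1.0 + 0.5 * dx1);
    double e = std::exp(-dx2 * dx2 / (0.1 * dx1));
    double c = g * e;
    if (dc1) *dc1 = c * (-0.5 * g + dx2 * dx2 / (0.1 * dx1 * dx1));
    if (dc2) *dc2 = c * (-2.0 * dx2 / (0.1 * dx1));
    return c;
  }

  // concentrations at pos; fills per-source dx1, dx2 and in-band flags
  void eval(const vec& pos, vec& c, vec& dx1, vec& dx2, uvec& in) const {
    c = zeros<vec>(2); dx1 = zeros<vec>(2); dx2 = zeros<vec>(2);
    in = zeros<uvec>(2);
    for (int s = 0; s < 2; ++s) {
      double d1 = (pos(0) - src(0, s)) * winddir1(s);
      double d2 = pos(1) - src(1, s);
      dx1(s) = d1; dx2(s) = d2;
      if (d1 > 1e-9 && std::abs(d2) <= half_h) {
        in(s) = 1;
        c(s) = conc(d1, d2, nullptr, nullptr);
      }
    }
  }
};

}  // namespace

// Closed-loop navigation run: an open-loop conditioning phase (inputs given)
// followed by a navigation phase in which Kenyon-cell drive and wind input
// are functions of the agent's position and heading, and forward/angular
// velocities are read out from FBN rates. Loss = squared distance from the
// rewarded source at the end of navigation; the gradient flows through the
// agent kinematics and through the smooth part of the sensory feedback
// (plume-band edges and the active-plume switch are treated as constant).
// [[Rcpp::export]]
List cpp_run_nav(List par, arma::mat kc_train, arma::mat ext_train,
                 arma::mat src, arma::vec winddir1, int rewarded,
                 arma::vec pat_r, arma::vec pat_n,
                 double theta0, int T_nav,
                 bool plastic_train, bool plastic_nav,
                 bool want_grad, bool want_traj) {
  Par p = parse_par(par);
  if (!p.has_vel) Rcpp::stop("velocity readout parameters are required");
  const int T1 = kc_train.n_cols;
  const double dt = p.dt;
  PlumeSense ps; ps.src = src; ps.winddir1 = winddir1;
  const int rw = rewarded - 1;  // 0-based rewarded source

  // conditioning phase (open loop, rates start at r0)
  vec r = p.r0;
  mat w = ones<mat>(p.m, p.k) * p.w_max, We = w;
  vec tk = zeros<vec>(p.k), td = zeros<vec>(p.d);
  Store st1;
  phase_forward(p, kc_train, ext_train, nullptr, plastic_train,
                r, w, We, tk, td, st1, nullptr);

  // navigation phase (rates reset, weights/traces carry over)
  r = p.r0;
  Store st2;
  cube WeStore;
  const int T2 = T_nav;
  mat kc2 = zeros<mat>(p.k, T2), ext2 = zeros<mat>(p.Wext.n_cols, T2);
  mat pos(2, T2 + 1); pos.col(0) = zeros<vec>(2);
  vec theta(T2 + 1); theta(0) = theta0;
  vec zu(T2), uu(T2), om(T2);
  mat wdot(4, T2);
  mat CC(2, T2), DX1(2, T2), DX2(2, T2);
  umat INP(2, T2);
  ivec act(T2);

  // manual forward for the closed loop (mirrors phase_forward + kinematics)
  {
    const double ak = dt / p.tau_k, ad = dt / p.tau_d;
    st2.R.set_size(p.N, T2 + 1);
    st2.A.set_size(p.N, T2);
    st2.TK.set_size(p.k, T2 + 1);
    st2.TD.set_size(p.d, T2 + 1);
    if (plastic_nav && p.clip) st2.CM.set_size(p.m, p.k, T2);
    WeStore.set_size(p.m, p.k, T2 + 1);
    st2.R.col(0) = r; st2.TK.col(0) = tk; st2.TD.col(0) = td;
    WeStore.slice(0) = We;
    for (int t = 0; t < T2; ++t) {
      // sense with the state at the end of step t-1
      vec c, d1, d2; uvec inb;
      ps.eval(pos.col(t), c, d1, d2, inb);
      CC.col(t) = c; DX1.col(t) = d1; DX2.col(t) = d2; INP.col(t) = inb;
      kc2.col(t) = pat_r * c(rw) + pat_n * c(1 - rw);
      int a_src = -1;
      if (c(0) > 0 || c(1) > 0) a_src = c(0) >= c(1) ? 0 : 1;
      act(t) = a_src;
      double th = theta(t);
      if (a_src >= 0) {
        vec wv = {winddir1(a_src), 0.0};
        wdot(0, t) = wv(0) * std::cos(th) + wv(1) * std::sin(th);
        wdot(1, t) = -wdot(0, t);
        wdot(2, t) = -wv(0) * std::sin(th) + wv(1) * std::cos(th);
        wdot(3, t) = -wdot(2, t);
        for (int i = 0; i < 4; ++i)
          ext2(2 + i, t) = std::max(wdot(i, t), 0.0);
      } else {
        wdot.col(t).zeros();
      }
      // circuit step
      vec a = p.W * r + p.b;
      a.subvec(0, p.m - 1) += (p.has_km ? p.Wkm : We) * kc2.col(t);
      a.subvec(p.m + p.d, p.N - 1) += p.Wext * ext2.col(t);
      step_rates(p, a, r, st2.A.colptr(t));
      st2.R.col(t + 1) = r;
      vec dan = r.subvec(p.m, p.m + p.d - 1);
      if (plastic_nav)
        step_plastic(p, p.G * td, p.G * dan, kc2.colptr(t), tk, w, We,
                     p.clip ? st2.CM.slice_memptr(t) : nullptr);
      tk = (1 - ak) * tk + ak * kc2.col(t);
      td = (1 - ad) * td + ad * dan;
      st2.TK.col(t + 1) = tk; st2.TD.col(t + 1) = td;
      WeStore.slice(t + 1) = We;
      // velocity readout from FBN rates, then kinematics
      vec rf = r.subvec(p.m + p.d, p.N - 1);
      zu(t) = dot(p.Wu, rf) + p.bu;
      uu(t) = zu(t) > 30 ? zu(t) : std::log1p(std::exp(zu(t)));
      om(t) = dot(p.Wom, rf) + p.bom;
      theta(t + 1) = theta(t) + dt * om(t);
      pos(0, t + 1) = pos(0, t) + dt * uu(t) * std::cos(theta(t + 1));
      pos(1, t + 1) = pos(1, t) + dt * uu(t) * std::sin(theta(t + 1));
      if (!pos.col(t + 1).is_finite())
        Rcpp::stop("navigation dynamics diverged (non-finite position)");
    }
  }

  vec dfin = pos.col(T2) - src.col(rw);
  double loss = dot(dfin, dfin);
  List out = List::create(
    Named("loss") = loss,
    Named("final_distance") = std::sqrt(loss),
    Named("final_position") = vec(pos.col(T2)));
  if (want_traj) {
    out["positions"] = mat(pos.t());
    out["theta"] = theta;
    out["u"] = uu; out["omega"] = om;
    out["concentration"] = mat(CC.t());
    out["rates"] = mat(st2.R.cols(1, T2));
    out["rates_train"] = mat(st1.R.cols(1, T1));
    out["w_final"] = w;
  }

  if (want_grad) {
    Grads G; G.init(p);
    vec gr = zeros<vec>(p.N), gtk = zeros<vec>(p.k), gtd = zeros<vec>(p.d);
    mat gWe = zeros<mat>(p.m, p.k), gw = zeros<mat>(p.m, p.k);
    vec gpos = 2.0 * dfin;
    double gth = 0;

    // navigation phase backward
    {
      auto addl = [&](int t, const vec& rt, vec& gr_) {
        // kinematics at step t: theta_{t+1}=theta_t+dt om; pos uses theta_{t+1}
        double th1 = theta(t + 1);
        double gu = dt * (std::cos(th1) * gpos(0) + std::sin(th1) * gpos(1));
        double gth1 = gth + dt * uu(t) *
          (-std::sin(th1) * gpos(0) + std::cos(th1) * gpos(1));
        double gom = dt * gth1;
        double sig = 1.0 / (1.0 + std::exp(-zu(t)));
        double gzu = gu * sig;
        vec rf = rt.subvec(p.m + p.d, p.N - 1);
        G.gWu += gzu * rf; G.gbu += gzu;
        G.gWom += gom * rf; G.gbom += gom;
        gr_.subvec(p.m + p.d, p.N - 1) += gzu * p.Wu + gom * p.Wom;
        // buffers for the sense callback / next iteration
        gth = gth1;           // now d(loss)/d(theta_t) via kinematics
        // gpos unchanged: d(loss)/d(pos_t) via kinematics = gpos_{t+1}
      };
      auto sense = [&](int t, const vec& gkc, const vec& gext) {
        // wind input used theta_t (heading before the step)
        int a_src = act(t);
        if (a_src >= 0) {
          double th = theta(t);
          vec wv = {winddir1(a_src), 0.0};
          // dh/dtheta for anterior, posterior, left, right
          double dh[4];
          dh[0] = -wv(0) * std::sin(th) + wv(1) * std::cos(th);
          dh[1] = -dh[0];
          dh[2] = -wv(0) * std::cos(th) - wv(1) * std::sin(th);
          dh[3] = -dh[2];
          for (int i = 0; i < 4; ++i)
            if (wdot(i, t) > 0) gth += gext(2 + i) * dh[i];
        }
        // concentration input used pos_t
        double gcr = dot(pat_r, gkc), gcn = dot(pat_n, gkc);
        double gc[2]; gc[rw] = gcr; gc[1 - rw] = gcn;
        for (int s = 0; s < 2; ++s) {
          if (INP(s, t) && CC(s, t) > 0) {
            double dc1, dc2;
            PlumeSense::conc(DX1(s, t), DX2(s, t), &dc1, &dc2);
            gpos(0) += gc[s] * dc1 * winddir1(s);
            gpos(1) += gc[s] * dc2;
          }
        }
      };
      phase_backward(p, kc2, ext2, nullptr, plastic_nav, st2, &WeStore,
                     gr, gWe, gw, gtk, gtd, G, addl, sense);
    }

    // conditioning phase backward: rates were reset at the phase boundary,
    // so the rate adjoint does not cross it; weight and trace adjoints do.
    gr.zeros();
    auto addl0 = [](int, const vec&, vec&) {};
    auto nosense = [](int, const vec&, const vec&) {};
    phase_backward(p, kc_train, ext_train, nullptr, plastic_train, st1,
                   nullptr, gr, gWe, gw, gtk, gtd, G, addl0, nosense);
    out["grads"] = G.as_list(p);
  }
  return out;
}
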