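// Core forward/backward passes for the causal sequential VAE.
//
// Architecture (all recurrences strictly forward in time, so every inferred
// quantity at bin t depends only on observations at bins <= t):
//
//   encoder GRU   e_t = GRU(e_{t-1}, y_t)
//   initial state q(g_0) = N(W_m e_1 + b_m, exp(W_v e_1 + b_v))
//   controller    c_t = GRU(c_{t-1}, [e_t; f_{t-1}])
//   input         q(u_t) = N(W_u c_t + b_u, exp(W_uv c_t + b_uv))
//   generator     g_t = GRU(g_{t-1}, u_t)
//   factors       f_t = W_f (g_t * dropout)
//   emission      y_t ~ N(W_y f_t + b_y, exp(r))   (r: per-neuron log-variance)
//
// GRU convention (z is the "keep" gate so z -> 1 freezes the state):
//   r = sigma(Wr x + Ur h + br)
//   z = sigma(Wz x + Uz h + bz)
//   n = tanh(Wn x + Un (r .* h) + bn)
//   h' = z .* h + (1 - z) .* n
//
// Gradients are hand-derived reverse-mode; verified against central finite
// differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::as;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GRU {
  mat Wr, Wz, Wn, Ur, Uz, Un;
  vec br, bz, bn;
  // gradient accumulators
  mat gWr, gWz, gWn, gUr, gUz, gUn;
  vec gbr, gbz, gbn;
  // per-step caches (forward order)
  std::vector<mat> cR, cZ, cN, cS, cHprev, cX;

  void load(const List& p, const std::string& pre) {
    Wr = as<mat>(p[pre + "_Wr"]); Wz = as<mat>(p[pre + "_Wz"]);
    Wn = as<mat>(p[pre + "_Wn"]);
    Ur = as<mat>(p[pre + "_Ur"]); Uz = as<mat>(p[pre + "_Uz"]);
    Un = as<mat>(p[pre + "_Un"]);
    br = as<vec>(p[pre + "_br"]); bz = as<vec>(p[pre + "_bz"]);
    bn = as<vec>(p[pre + "_bn"]);
  }
  void zero_grad() {
    gWr = zeros(size(Wr)); gWz = zeros(size(Wz)); gWn = zeros(size(Wn));
    gUr = zeros(size(Ur)); gUz = zeros(size(Uz)); gUn = zeros(size(Un));
    gbr = zeros(size(br)); gbz = zeros(size(bz)); gbn = zeros(size(bn));
  }
  mat step(const mat& Hprev, const mat& X, bool cache) {
    mat R = Wr * X + Ur * Hprev; R.each_col() += br; R = sigm(R);
    mat Z = Wz * X + Uz * Hprev; Z.each_col() += bz; Z = sigm(Z);
    mat S = R % Hprev;
    mat N = Wn * X + Un * S; N.each_col() += bn; N = tanh(N);
    mat H = Z % Hprev + (1.0 - Z) % N;
    if (cache) {
      cR.push_back(R); cZ.push_back(Z); cN.push_back(N);
      cS.push_back(S); cHprev.push_back(Hprev); cX.push_back(X);
    }
    return H;
  }
  // consumes the cache for step t (0-based); returns dX, accumulates grads,
  // writes dHprev
  mat backward(int t, const mat& dH, mat& dHprev) {
    const mat &R = cR[t], &Z = cZ[t], &N = cN[t], &S = cS[t],
              &Hp = cHprev[t], &X = cX[t];
    mat dZ = dH % (Hp - N) % Z % (1.0 - Z);
    mat dN = dH % (1.0 - Z);
    mat dAn = dN % (1.0 - N % N);
    mat dS = Un.t() * dAn;
    mat dR = dS % Hp;
    mat dAr = dR % R % (1.0 - R);
    dHprev = dH % Z + dS % R + Ur.t() * dAr + Uz.t() * dZ;
    gWr += dAr * X.t(); gWz += dZ * X.t(); gWn += dAn * X.t();
    gUr += dAr * Hp.t(); gUz += dZ * Hp.t(); gUn += dAn * S.t();
    gbr += sum(dAr, 1); gbz += sum(dZ, 1); gbn += sum(dAn, 1);
    return Wr.t() * dAr + Wz.t() * dZ + Wn.t() * dAn;
  }
};

static void put_gru(List& g, const GRU& c, const std::string& pre) {
  g[pre + "_Wr"] = c.gWr; g[pre + "_Wz"] = c.gWz; g[pre + "_Wn"] = c.gWn;
  g[pre + "_Ur"] = c.gUr; g[pre + "_Uz"] = c.gUz; g[pre + "_Un"] = c.gUn;
  g[pre + "_br"] = c.gbr; g[pre + "_bz"] = c.gbz; g[pre + "_bn"] = c.gbn;
}

// One pass through the network on a batch of trials.
//
// Y:        cube n_neurons x n_trials x n_bins (observations)
// noise:    list with eps_g0 (n_g x B), eps_u (n_u x B x T),
//           mask_in (N x B x T), mask_g (n_g x B x T); masks are already
//           scaled inverted-dropout masks (all ones when dropout is off)
// sample:   reparameterized draws when true, posterior means when false
// kl_ic_w / kl_u_w: KL warm-up weights used in the optimized loss
// l2:       penalty on generator+controller recurrent kernels
//
// Returns raw (unweighted) ELBO components plus the weighted training loss,
// optionally gradients and/or posterior outputs.
// [[Rcpp::export]]
List lfads_pass_cpp(List params, arma::cube Y, List noise,
                    double ic_prior_var, double kl_ic_w, double kl_u_w,
                    double l2, bool sample, bool want_grad,
                    bool want_outputs) {
  const int N = Y.n_rows, B = Y.n_cols, T = Y.n_slices;

  GRU enc, con, gen;
  enc.load(params, "enc"); con.load(params, "con"); gen.load(params, "gen");
  mat Wicm = as<mat>(params["ic_Wm"]), Wicv = as<mat>(params["ic_Wv"]);
  vec bicm = as<vec>(params["ic_bm"]), bicv = as<vec>(params["ic_bv"]);
  mat Wu = as<mat>(params["u_Wm"]), Wuv = as<mat>(params["u_Wv"]);
  vec bu = as<vec>(params["u_bm"]), buv = as<vec>(params["u_bv"]);
  mat Wf = as<mat>(params["fac_W"]);
  mat Wy = as<mat>(params["out_W"]);
  vec by = as<vec>(params["out_b"]), rlv = as<vec>(params["out_logvar"]);

  const int n_g = gen.br.n_elem, n_f = Wf.n_rows, n_u = Wu.n_rows;

  mat eps_g0 = as<mat>(noise["eps_g0"]);
  cube eps_u = as<cube>(noise["eps_u"]);
  cube mask_in = as<cube>(noise["mask_in"]);
  cube mask_g = as<cube>(noise["mask_g"]);

  // ---- forward: encoder over all bins
  std::vector<mat> E(T);
  mat Eprev = zeros(enc.br.n_elem, B);
  for (int t = 0; t < T; ++t) {
    mat Xt = Y.slice(t) % mask_in.slice(t);
    Eprev = enc.step(Eprev, Xt, want_grad);
    E[t] = Eprev;
  }

  // ---- initial condition posterior from the first bin only (causality)
  mat M0 = Wicm * E[0]; M0.each_col() += bicm;
  mat LV0 = Wicv * E[0]; LV0.each_col() += bicv;
  LV0 = clamp(LV0, -16.0, 10.0);
  mat G0 = sample ? mat(M0 + exp(0.5 * LV0) % eps_g0) : M0;

  // ---- controller / generator loop
  std::vector<mat> Gd(T), Fm(T), MU(T), LVu(T), Uu(T), Cc(T);
  mat Cprev = zeros(con.br.n_elem, B);
  mat Gprev = G0;
  mat Fprev = Wf * G0;
  mat F0 = Fprev;
  double recon = 0.0, kl_u = 0.0;
  vec varv = exp(rlv);
  cube denoised;
  if (want_outputs) denoised = cube(N, B, T);
  std::vector<mat> Ydiff(T);

  for (int t = 0; t < T; ++t) {
    mat cin = join_cols(E[t], Fprev);
    Cprev = con.step(Cprev, cin, want_grad);
    Cc[t] = Cprev;
    MU[t] = Wu * Cprev; MU[t].each_col() += bu;
    LVu[t] = Wuv * Cprev; LVu[t].each_col() += buv;
    LVu[t] = clamp(LVu[t], -16.0, 10.0);
    Uu[t] = sample ? mat(MU[t] + exp(0.5 * LVu[t]) % eps_u.slice(t)) : MU[t];
    Gprev = gen.step(Gprev, Uu[t], want_grad);
    Gd[t] = Gprev % mask_g.slice(t);
    Fm[t] = Wf * Gd[t];
    Fprev = Fm[t];
    mat Ymean = Wy * Fm[t]; Ymean.each_col() += by;
    mat D = Ymean - Y.slice(t);
    Ydiff[t] = D;
    mat D2 = D % D;
    recon += -0.5 * (B * accu(log(2.0 * datum::pi * varv)) +
                     accu(D2.each_col() / varv));
    kl_u += 0.5 * accu(exp(LVu[t]) + MU[t] % MU[t] - 1.0 - LVu[t]);
    if (want_outputs) denoised.slice(t) = Ymean;
  }

  // KL(q(g0) || N(0, ic_prior_var I))
  double kl_g0 = 0.5 * accu(
      (exp(LV0) + M0 % M0) / ic_prior_var - 1.0 - LV0 + log(ic_prior_var));

  double l2pen = 0.5 * l2 *
      (accu(gen.Ur % gen.Ur) + accu(gen.Uz % gen.Uz) + accu(gen.Un % gen.Un) +
       accu(con.Ur % con.Ur) + accu(con.Uz % con.Uz) + accu(con.Un % con.Un));
  const double sc = 1.0 / (double(B) * double(T));
  double loss = -(recon - kl_ic_w * kl_g0 - kl_u_w * kl_u) * sc + l2pen;

  List out = List::create(
      Named("loss") = loss, Named("recon") = recon,
      Named("kl_g0") = kl_g0, Named("kl_u") = kl_u,
      Named("elbo") = recon - kl_g0 - kl_u);

  if (want_outputs) {
    cube fac(n_f, B, T), uu(n_u, B, T), umean(n_u, B, T), ulv(n_u, B, T);
    cube gst(n_g, B, T);
    for (int t = 0; t < T; ++t) {
      fac.slice(t) = Fm[t]; uu.slice(t) = Uu[t];
      umean.slice(t) = MU[t]; ulv.slice(t) = LVu[t];
      gst.slice(t) = Gd[t];
    }
    out["gstates"] = gst;
    out["factors"] = fac; out["u"] = uu;
    out["u_mean"] = umean; out["u_logvar"] = ulv;
    out["denoised"] = denoised;
    out["ic_mean"] = M0; out["ic_logvar"] = LV0;
    out["g0"] = G0;
  }
  if (!want_grad) return out;

  // ---- backward
  enc.zero_grad(); con.zero_grad(); gen.zero_grad();
  mat gWicm = zeros(size(Wicm)), gWicv = zeros(size(Wicv));
  vec gbicm = zeros(size(bicm)), gbicv = zeros(size(bicv));
  mat gWu = zeros(size(Wu)), gWuv = zeros(size(Wuv));
  vec gbu = zeros(size(bu)), gbuv = zeros(size(buv));
  mat gWf = zeros(size(Wf));
  mat gWy = zeros(size(Wy));
  vec gby = zeros(size(by)), grlv = zeros(size(rlv));

  std::vector<mat> dE(T, zeros(enc.br.n_elem, B));
  mat dCnext = zeros(con.br.n_elem, B);   // dC_t carried from step t+1
  mat dGnext = zeros(n_g, B);             // dG_t carried from step t+1
  mat dFnext = zeros(n_f, B);             // dF_t via controller input at t+1

  for (int t = T - 1; t >= 0; --t) {
    // emission
    mat dYmean = sc * (Ydiff[t].each_col() / varv);
    mat D2 = Ydiff[t] % Ydiff[t];
    grlv += sc * 0.5 * (double(B) - sum(D2.each_col() / varv, 1));
    mat dF = Wy.t() * dYmean + dFnext;
    gWy += dYmean * Fm[t].t();
    gby += sum(dYmean, 1);
    // factors
    gWf += dF * Gd[t].t();
    mat dG = (Wf.t() * dF) % mask_g.slice(t) + dGnext;
    // generator step
    mat dGprev;
    mat dU = gen.backward(t, dG, dGprev);
    dGnext = dGprev;
    // input posterior: sampled u = mu + exp(lv/2) eps ; plus KL terms
    mat dMU = dU + sc * kl_u_w * MU[t];
    mat dLV = sc * kl_u_w * 0.5 * (exp(LVu[t]) - 1.0);
    if (sample) dLV += dU % eps_u.slice(t) % (0.5 * exp(0.5 * LVu[t]));
    mat dC = Wu.t() * dMU + Wuv.t() * dLV + dCnext;
    gWu += dMU * Cc[t].t(); gbu += sum(dMU, 1);
    gWuv += dLV * Cc[t].t(); gbuv += sum(dLV, 1);
    // controller step
    mat dCprev;
    mat dCin = con.backward(t, dC, dCprev);
    dCnext = dCprev;
    dE[t] += dCin.rows(0, enc.br.n_elem - 1);
    mat dFprev = dCin.rows(enc.br.n_elem, dCin.n_rows - 1);
    if (t > 0) {
      dFnext = dFprev;
    } else {
      // f_0 = Wf g_0 feeds the first controller step
      gWf += dFprev * G0.t();
      dGnext += Wf.t() * dFprev;  // lands in dG0 below
    }
  }

  // initial condition: dG0 collects generator carry + f_0 path
  mat dG0 = dGnext;
  mat dM0 = dG0 + sc * kl_ic_w * (M0 / ic_prior_var);
  mat dLV0 = sc * kl_ic_w * 0.5 * (exp(LV0) / ic_prior_var - 1.0);
  if (sample) dLV0 += dG0 % eps_g0 % (0.5 * exp(0.5 * LV0));
  gWicm += dM0 * E[0].t(); gbicm += sum(dM0, 1);
  gWicv += dLV0 * E[0].t(); gbicv += sum(dLV0, 1);
  dE[0] += Wicm.t() * dM0 + Wicv.t() * dLV0;

  // encoder chain
  mat dEnext = zeros(enc.br.n_elem, B);
  for (int t = T - 1; t >= 0; --t) {
    mat dEprev;
    enc.backward(t, dE[t] + dEnext, dEprev);
    dEnext = dEprev;
  }

  // sign: loss already includes the -1/(BT) scaling via dYmean etc. but the
  // accumulated grads above are for -ELBO*sc; KL and recon pieces carried sc.
  // (recon gradient sign: d(-recon*sc)/dYmean = sc*(Ymean-Y)/var = dYmean, ok)

  // L2 on recurrent kernels
  gen.gUr += l2 * gen.Ur; gen.gUz += l2 * gen.Uz; gen.gUn += l2 * gen.Un;
  con.gUr += l2 * con.Ur; con.gUz += l2 * con.Uz; con.gUn += l2 * con.Un;

  List g;
  put_gru(g, enc, "enc"); put_gru(g, con, "con"); put_gru(g, gen, "gen");
  g["ic_Wm"] = gWicm; g["ic_bm"] = gbicm;
  g["ic_Wv"] = gWicv; g["ic_bv"] = gbicv;
  g["u_Wm"] = gWu; g["u_bm"] = gbu;
  g["u_Wv"] = gWuv; g["u_bv"] = gbuv;
  g["fac_W"] = gWf;
  g["out_W"] = gWy; g["out_b"] = gby; g["out_logvar"] = grlv;
  out["grad"] = g;
  return out;
}

// Single generator GRU step for a batch of states (columns); used by the
// fixed-point search and in-silico rollouts.
// [[Rcpp::export]]
arma::mat gen_step_cpp(List params, arma::mat H, arma::mat U) {
  GRU gen; gen.load(params, "gen");
  return gen.step(H, U, false);
}

// Batched gradient of q(h) = ||F(h,u) - h||^2 with respect to h (per column).
// [[Rcpp::export]]
arma::mat speed_grad_cpp(List params, arma::mat H, arma::mat U) {
  GRU gen; gen.load(params, "gen");
  gen.zero_grad();
  mat F = gen.step(H, U, true);
  mat D = 2.0 * (F - H);
  mat dHprev;
  gen.backward(0, D, dHprev);   // dHprev = (dF/dh)^T D
  return dHprev - D;
}
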