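// Masked GRU -> (dense tanh) -> Weibull parameter heads, trained by
// backpropagation through time against the right-censored Weibull negative
// log-likelihood, with the Adam optimizer.
//
// Data layout (performance): X is (n_vars x n_steps x n_obs); `valid` is
// (n_steps x n_obs) with 1 for a step whose covariate vector is (at least
// partly) observed and 0 for a masked step. Windows are right-aligned, so
// masked padding occupies the leading steps and the parameter heads read the
// hidden state at the final step. Hidden states carry through masked steps
// unchanged, so fully-masked padding cannot perturb the recurrence.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Weights {
  mat Wz, Wr, Wh;   // H x V
  mat Uz, Ur, Uh;   // H x H
  vec bz, br, bh;   // H
  mat Wd;           // D x H
  vec bd;           // D
  mat Wo;           // 2 x D
  vec bo;           // 2
};

Weights from_list(const Rcpp::List& w) {
  Weights W;
  W.Wz = Rcpp::as<mat>(w["Wz"]); W.Wr = Rcpp::as<mat>(w["Wr"]);
  W.Wh = Rcpp::as<mat>(w["Wh"]); W.Uz = Rcpp::as<mat>(w["Uz"]);
  W.Ur = Rcpp::as<mat>(w["Ur"]); W.Uh = Rcpp::as<mat>(w["Uh"]);
  W.bz = Rcpp::as<vec>(w["bz"]); W.br = Rcpp::as<vec>(w["br"]);
  W.bh = Rcpp::as<vec>(w["bh"]);
  W.Wd = Rcpp::as<mat>(w["Wd"]); W.bd = Rcpp::as<vec>(w["bd"]);
  W.Wo = Rcpp::as<mat>(w["Wo"]); W.bo = Rcpp::as<vec>(w["bo"]);
  return W;
}

Rcpp::List to_list(const Weights& W) {
  return Rcpp::List::create(
    Rcpp::Named("Wz") = W.Wz, Rcpp::Named("Wr") = W.Wr,
    Rcpp::Named("Wh") = W.Wh, Rcpp::Named("Uz") = W.Uz,
    Rcpp::Named("Ur") = W.Ur, Rcpp::Named("Uh") = W.Uh,
    Rcpp::Named("bz") = W.bz, Rcpp::Named("br") = W.br,
    Rcpp::Named("bh") = W.bh, Rcpp::Named("Wd") = W.Wd,
    Rcpp::Named("bd") = W.bd, Rcpp::Named("Wo") = W.Wo,
    Rcpp::Named("bo") = W.bo);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

const double PAR_FLOOR = 1e-6;   // lower clamp for shape and scale
const double RAW_CLAMP = 30.0;   // |raw scale head| clamp before exp()

// Forward pass for a batch; optionally cache activations for backprop.
struct Cache {
  cube H;          // Hdim x B x (T+1), hidden states (slice 0 = h0 = 0)
  cube Z, R, C;    // Hdim x B x T
  mat d_act;       // D x B
  mat hT;          // Hdim x B
  vec k, lam;      // B
  vec raw_k, raw_l;
  uvec k_clamped, lam_clamped;
};

void forward_batch(const cube& X, const mat& valid, const uvec& idx,
                   const Weights& W, Cache& cc, bool keep) {
  const uword B = idx.n_elem;
  const uword T = X.n_slices > 0 ? X.n_cols : 0;   // steps
  const uword V = X.n_rows;
  const uword Hd = W.Uz.n_rows;

  // gather batch: per-step (V x B) matrices stacked as (V x B*T)
  mat Xb(V, B * T);
  mat M(T, B);
  for (uword b = 0; b < B; ++b) {
    const mat& sl = X.slice(idx(b));              // V x T
    for (uword t = 0; t < T; ++t) Xb.col(t * B + b) = sl.col(t);
    M.col(b) = valid.col(idx(b));
  }
  mat WzX = W.Wz * Xb, WrX = W.Wr * Xb, WhX = W.Wh * Xb;  // H x B*T

  if (keep) {
    cc.H.set_size(Hd, B, T + 1);
    cc.Z.set_size(Hd, B, T); cc.R.set_size(Hd, B, T); cc.C.set_size(Hd, B, T);
  }
  mat h(Hd, B, fill::zeros);
  if (keep) cc.H.slice(0) = h;
  for (uword t = 0; t < T; ++t) {
    mat z = WzX.cols(t * B, t * B + B - 1);
    mat r = WrX.cols(t * B, t * B + B - 1);
    z.each_col() += W.bz; r.each_col() += W.br;
    z = sigmoid(z + W.Uz * h);
    r = sigmoid(r + W.Ur * h);
    mat c = WhX.cols(t * B, t * B + B - 1);
    c.each_col() += W.bh;
    c = tanh(c + W.Uh * (r % h));
    mat hnew = (1.0 - z) % h + z % c;
    rowvec m = M.row(t);
    mat hnext = hnew.each_row() % m + h.each_row() % (1.0 - m);
    if (keep) {
      cc.Z.slice(t) = z; cc.R.slice(t) = r; cc.C.slice(t) = c;
      cc.H.slice(t + 1) = hnext;
    }
    h = hnext;
  }
  cc.hT = h;
  mat dpre = W.Wd * h; dpre.each_col() += W.bd;
  cc.d_act = tanh(dpre);
  mat o = W.Wo * cc.d_act; o.each_col() += W.bo;
  cc.raw_k = o.row(0).t();
  cc.raw_l = clamp(o.row(1).t(), -RAW_CLAMP, RAW_CLAMP);
  // softplus, stable on both tails
  vec a = cc.raw_k;
  vec k(B);
  for (uword b = 0; b < B; ++b)
    k(b) = a(b) > 0 ? a(b) + std::log1p(std::exp(-a(b)))
                    : std::log1p(std::exp(a(b)));
  vec lam = exp(cc.raw_l);
  cc.k_clamped = find(k < PAR_FLOOR);
  cc.lam_clamped = find(lam < PAR_FLOOR);
  k.elem(cc.k_clamped).fill(PAR_FLOOR);
  lam.elem(cc.lam_clamped).fill(PAR_FLOOR);
  cc.k = k; cc.lam = lam;
}

// Per-observation NLL and (optionally) gradient wrt the raw head outputs.
double nll_and_head_grads(const Cache& cc, const vec& t_lab, const vec& u_lab,
                          const uvec& idx, vec* d_raw_k, vec* d_raw_l) {
  const uword B = idx.n_elem;
  double total = 0.0;
  if (d_raw_k) { d_raw_k->zeros(B); d_raw_l->zeros(B); }
  for (uword b = 0; b < B; ++b) {
    double t = t_lab(idx(b)), u = u_lab(idx(b));
    double k = cc.k(b), lam = cc.lam(b);
    double lt = std::log(t) - std::log(lam);
    double e = std::exp(std::min(k * lt, 700.0));
    double nll = e - u * (std::log(k) + (k - 1.0) * lt - std::log(lam));
    total += nll;
    if (d_raw_k) {
      double dk = e * lt - u * (1.0 / k + lt);
      double dlam = (k / lam) * (u - e);
      double sig = 1.0 / (1.0 + std::exp(-cc.raw_k(b)));
      (*d_raw_k)(b) = dk * sig;
      (*d_raw_l)(b) = dlam * lam;
    }
  }
  if (d_raw_k) {
    // zero gradient where the clamp is active (subgradient of the floor)
    d_raw_k->elem(cc.k_clamped).zeros();
    d_raw_l->elem(cc.lam_clamped).zeros();
  }
  return total / B;
}

// Backward pass; gradients of the mean batch NLL wrt all weights.
void backward_batch(const cube& X, const mat& valid, const uvec& idx,
                    const Weights& W, const Cache& cc,
                    const vec& d_raw_k, const vec& d_raw_l, Weights& G) {
  const uword B = idx.n_elem;
  const uword T = X.n_cols;
  const uword V = X.n_rows;
  const uword Hd = W.Uz.n_rows;

  mat Xb(V, B * T);
  mat M(T, B);
  for (uword b = 0; b < B; ++b) {
    const mat& sl = X.slice(idx(b));
    for (uword t = 0; t < T; ++t) Xb.col(t * B + b) = sl.col(t);
    M.col(b) = valid.col(idx(b));
  }

  mat dO(2, B);
  dO.row(0) = d_raw_k.t() / B;
  dO.row(1) = d_raw_l.t() / B;
  G.Wo = dO * cc.d_act.t();
  G.bo = sum(dO, 1);
  mat dd = W.Wo.t() * dO;
  mat dd_pre = dd % (1.0 - cc.d_act % cc.d_act);
  G.Wd = dd_pre * cc.hT.t();
  G.bd = sum(dd_pre, 1);
  mat dh = W.Wd.t() * dd_pre;                    // Hd x B

  G.Wz.zeros(Hd, V); G.Wr.zeros(Hd, V); G.Wh.zeros(Hd, V);
  G.Uz.zeros(Hd, Hd); G.Ur.zeros(Hd, Hd); G.Uh.zeros(Hd, Hd);
  G.bz.zeros(Hd); G.br.zeros(Hd); G.bh.zeros(Hd);

  cube dG(3 * Hd, B, T, fill::zeros);            // stacked [dz;dr;dc] pre-acts
  for (uword t = T; t-- > 0;) {
    rowvec m = M.row(t);
    const mat& z = cc.Z.slice(t);
    const mat& r = cc.R.slice(t);
    const mat& c = cc.C.slice(t);
    mat hp = cc.H.slice(t);
    mat dh_eff = dh.each_row() % m;
    mat dhp = dh.each_row() % (1.0 - m);
    mat dz = dh_eff % (c - hp);
    mat dc = dh_eff % z;
    dhp += dh_eff % (1.0 - z);
    mat dc_pre = dc % (1.0 - c % c);
    mat drhp = W.Uh.t() * dc_pre;
    mat dr = drhp % hp;
    dhp += drhp % r;
    mat dz_pre = dz % z % (1.0 - z);
    mat dr_pre = dr % r % (1.0 - r);
    G.Uz += dz_pre * hp.t();
    G.Ur += dr_pre * hp.t();
    G.Uh += dc_pre * (r % hp).t();
    G.bz += sum(dz_pre, 1); G.br += sum(dr_pre, 1); G.bh += sum(dc_pre, 1);
    dhp += W.Uz.t() * dz_pre + W.Ur.t() * dr_pre;
    dG.slice(t).rows(0, Hd - 1) = dz_pre;
    dG.slice(t).rows(Hd, 2 * Hd - 1) = dr_pre;
    dG.slice(t).rows(2 * Hd, 3 * Hd - 1) = dc_pre;
    dh = dhp;
  }
  // input-weight gradients in one GEMM over all steps
  mat dGflat(3 * Hd, B * T);
  for (uword t = 0; t < T; ++t)
    dGflat.cols(t * B, t * B + B - 1) = dG.slice(t);
  mat dW = dGflat * Xb.t();                      // 3Hd x V
  G.Wz += dW.rows(0, Hd - 1);
  G.Wr += dW.rows(Hd, 2 * Hd - 1);
  G.Wh += dW.rows(2 * Hd, 3 * Hd - 1);
}

struct Adam {
  Weights m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  void init(const Weights& W) {
    auto zed = [](const mat& x) { return mat(x.n_rows, x.n_cols, fill::zeros); };
    auto zev = [](const vec& x) { return vec(x.n_elem, fill::zeros); };
    m.Wz = zed(W.Wz); m.Wr = zed(W.Wr); m.Wh = zed(W.Wh);
    m.Uz = zed(W.Uz); m.Ur = zed(W.Ur); m.Uh = zed(W.Uh);
    m.bz = zev(W.bz); m.br = zev(W.br); m.bh = zev(W.bh);
    m.Wd = zed(W.Wd); m.bd = zev(W.bd); m.Wo = zed(W.Wo); m.bo = zev(W.bo);
    v = m;
  }
  template <typename M>
  void upd1(M& w, M& mm, M& vv, const M& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    M mhat = mm / (1 - std::pow(b1, (double)step));
    M vhat = vv / (1 - std::pow(b2, (double)step));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
  void update(Weights& W, const Weights& G, double lr) {
    ++step;
    upd1(W.Wz, m.Wz, v.Wz, G.Wz, lr); upd1(W.Wr, m.Wr, v.Wr, G.Wr, lr);
    upd1(W.Wh, m.Wh, v.Wh, G.Wh, lr); upd1(W.Uz, m.Uz, v.Uz, G.Uz, lr);
    upd1(W.Ur, m.Ur, v.Ur, G.Ur, lr); upd1(W.Uh, m.Uh, v.Uh, G.Uh, lr);
    upd1(W.bz, m.bz, v.bz, G.bz, lr); upd1(W.br, m.br, v.br, G.br, lr);
    upd1(W.bh, m.bh, v.bh, G.bh, lr); upd1(W.Wd, m.Wd, v.Wd, G.Wd, lr);
    upd1(W.bd, m.bd, v.bd, G.bd, lr); upd1(W.Wo, m.Wo, v.Wo, G.Wo, lr);
    upd1(W.bo, m.bo, v.bo, G.bo, lr);
  }
};

// Global L2 gradient-norm clipping (standard recurrent-network practice).
void clip_gradients(Weights& G, double clipnorm) {
  if (clipnorm <= 0) return;
  double ss = accu(square(G.Wz)) + accu(square(G.Wr)) + accu(square(G.Wh)) +
              accu(square(G.Uz)) + accu(square(G.Ur)) + accu(square(G.Uh)) +
              accu(square(G.bz)) + accu(square(G.br)) + accu(square(G.bh)) +
              accu(square(G.Wd)) + accu(square(G.bd)) +
              accu(square(G.Wo)) + accu(square(G.bo));
  double nrm = std::sqrt(ss);
  if (nrm > clipnorm && std::isfinite(nrm)) {
    double f = clipnorm / nrm;
    G.Wz *= f; G.Wr *= f; G.Wh *= f; G.Uz *= f; G.Ur *= f; G.Uh *= f;
    G.bz *= f; G.br *= f; G.bh *= f; G.Wd *= f; G.bd *= f;
    G.Wo *= f; G.bo *= f;
  }
}

double dataset_cost(const cube& X, const mat& valid, const vec& t_lab,
                    const vec& u_lab, const Weights& W, uword batch) {
  const uword n = X.n_slices;
  if (n == 0) return NA_REAL;
  double tot = 0.0;
  Cache cc;
  for (uword s = 0; s < n; s += batch) {
    uword e = std::min(s + batch, n) - 1;
    uvec idx = regspace<uvec>(s, e);
    forward_batch(X, valid, idx, W, cc, false);
    tot += nll_and_head_grads(cc, t_lab, u_lab, idx, nullptr, nullptr)
           * idx.n_elem;
  }
  return tot / n;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List gru_train_cpp(const arma::cube& X, const arma::mat& valid,
                         const arma::vec& t_lab, const arma::vec& u_lab,
                         const arma::cube& Xv, const arma::mat& validv,
                         const arma::vec& tv, const arma::vec& uv,
                         const Rcpp::List& w0, int epochs, int batch_size,
                         double lr, double clipnorm, int seed,
                         bool checkpoint_best) {
  Weights W = from_list(w0);
  Adam opt; opt.init(W);
  const uword n = X.n_slices;
  const bool has_val = Xv.n_slices > 0;
  std::mt19937 rng((unsigned)seed);
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  std::vector<double> train_cost, val_cost;
  Weights best = W;
  double best_val = datum::inf;
  int best_epoch = 0, bad_streak = 0;
  bool aborted = false;
  std::string abort_msg;

  Cache cc;
  Weights G;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_cost = 0.0;
    uword seen = 0;
    for (uword s = 0; s < n; s += (uword)batch_size) {
      uword e = std::min(s + (uword)batch_size, n);
      uvec idx(e - s);
      for (uword i = s; i < e; ++i) idx(i - s) = order[i];
      forward_batch(X, valid, idx, W, cc, true);
      vec drk, drl;
      double c = nll_and_head_grads(cc, t_lab, u_lab, idx, &drk, &drl);
      backward_batch(X, valid, idx, W, cc, drk, drl, G);
      clip_gradients(G, clipnorm);
      opt.update(W, G, lr);
      ep_cost += c * idx.n_elem;
      seen += idx.n_elem;
    }
    ep_cost /= seen;
    double vcost = has_val
      ? dataset_cost(Xv, validv, tv, uv, W, (uword)batch_size)
      : NA_REAL;
    train_cost.push_back(ep_cost);
    val_cost.push_back(vcost);
    double track = has_val ? vcost : ep_cost;
    if (std::isfinite(track) && track < best_val) {
      best_val = track; best = W; best_epoch = ep + 1;
    }
    if (!std::isfinite(ep_cost)) {
      if (++bad_streak >= 3) {
        aborted = true;
        abort_msg = "non-finite training cost for 3 consecutive epochs (epoch "
                    + std::to_string(ep + 1) + ")";
        break;
      }
    } else {
      bad_streak = 0;
    }
    Rcpp::checkUserInterrupt();
  }
  Weights final_w = (checkpoint_best && best_epoch > 0) ? best : W;
  if (epochs == 0) { final_w = W; best_epoch = 0; }
  return Rcpp::List::create(
    Rcpp::Named("weights") = to_list(final_w),
    Rcpp::Named("last_weights") = to_list(W),
    Rcpp::Named("train_cost") = train_cost,
    Rcpp::Named("val_cost") = val_cost,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("aborted") = aborted,
    Rcpp::Named("abort_msg") = abort_msg);
}

// [[Rcpp::export]]
arma::mat gru_predict_cpp(const arma::cube& X, const arma::mat& valid,
                          const Rcpp::List& w, int batch_size) {
  Weights W = from_list(w);
  const uword n = X.n_slices;
  mat out(n, 2);
  Cache cc;
  for (uword s = 0; s < n; s += (uword)batch_size) {
    uword e = std::min(s + (uword)batch_size, n) - 1;
    uvec idx = regspace<uvec>(s, e);
    forward_batch(X, valid, idx, W, cc, false);
    for (uword b = 0; b < idx.n_elem; ++b) {
      out(idx(b), 0) = cc.k(b);
      out(idx(b), 1) = cc.lam(b);
    }
  }
  return out;
}

// Mean NLL and full weight gradient at fixed weights (finite-difference
// test hook and diagnostics).
// [[Rcpp::export]]
Rcpp::List gru_grad_cpp(const arma::cube& X, const arma::mat& valid,
                        const arma::vec& t_lab, const arma::vec& u_lab,
                        const Rcpp::List& w) {
  Weights W = from_list(w);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  Cache cc;
  forward_batch(X, valid, idx, W, cc, true);
  vec drk, drl;
  double cost = nll_and_head_grads(cc, t_lab, u_lab, idx, &drk, &drl);
  Weights G;
  backward_batch(X, valid, idx, W, cc, drk, drl, G);
  return Rcpp::List::create(Rcpp::Named("cost") = cost,
                            Rcpp::Named("grads") = to_list(G));
}

// [[Rcpp::export]]
double gru_cost_cpp(const arma::cube& X, const arma::mat& valid,
                    const arma::vec& t_lab, const arma::vec& u_lab,
                    const Rcpp::List& w, int batch_size) {
  return dataset_cost(X, valid, t_lab, u_lab, from_list(w),
                      (uword)batch_size);
}
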