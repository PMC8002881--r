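// Deep bidirectional LSTM binary classifier over fixed-length residue windows.
// Hand-rolled forward/backward (BPTT) with Adam, class-weighted binary
// cross-entropy, gradient-norm clipping, early stopping on validation F1,
// and optional freezing of the bottom recurrent layers (transfer learning).
//
// Parameter container (mirrors the R list):
//   params$layers[[l]]$fw$W (in x 4H), $U (H x 4H), $b (1 x 4H); same for $bw
//   params$dense$W (2H x D), $b (1 x D)
//   params$out$W (D x 1), $b (1 x 1)
// Gate column blocks within 4H: input, forget, candidate, output.
// Input cube x: n x features x time; slice t is the n x F matrix at window
// position t (positions ordered P4..P1, P1'..P4').

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;
using arma::cube;
using arma::span;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct DirParams { mat W, U, b; };

struct Net {
  std::vector<DirParams> fw, bw;
  mat Wd, bd, Wo, bo;
  int n_layers() const { return (int)fw.size(); }
  int hidden() const { return (int)fw[0].U.n_rows; }
};

static DirParams dir_from_list(const List& d) {
  DirParams p;
  p.W = as<mat>(d["W"]);
  p.U = as<mat>(d["U"]);
  p.b = as<mat>(d["b"]);
  return p;
}

static Net unpack(const List& params) {
  Net net;
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List lay = layers[l];
    net.fw.push_back(dir_from_list(as<List>(lay["fw"])));
    net.bw.push_back(dir_from_list(as<List>(lay["bw"])));
  }
  List dense = params["dense"];
  net.Wd = as<mat>(dense["W"]);
  net.bd = as<mat>(dense["b"]);
  List out = params["out"];
  net.Wo = as<mat>(out["W"]);
  net.bo = as<mat>(out["b"]);
  return net;
}

static List pack(const Net& net) {
  List layers(net.n_layers());
  for (int l = 0; l < net.n_layers(); ++l) {
    layers[l] = List::create(
      Named("fw") = List::create(Named("W") = net.fw[l].W, Named("U") = net.fw[l].U,
                                 Named("b") = net.fw[l].b),
      Named("bw") = List::create(Named("W") = net.bw[l].W, Named("U") = net.bw[l].U,
                                 Named("b") = net.bw[l].b));
  }
  return List::create(
    Named("layers") = layers,
    Named("dense") = List::create(Named("W") = net.Wd, Named("b") = net.bd),
    Named("out") = List::create(Named("W") = net.Wo, Named("b") = net.bo));
}

static Net zeros_like(const Net& net) {
  Net z;
  for (int l = 0; l < net.n_layers(); ++l) {
    DirParams f, b;
    f.W.zeros(net.fw[l].W.n_rows, net.fw[l].W.n_cols);
    f.U.zeros(net.fw[l].U.n_rows, net.fw[l].U.n_cols);
    f.b.zeros(net.fw[l].b.n_rows, net.fw[l].b.n_cols);
    b.W.zeros(net.bw[l].W.n_rows, net.bw[l].W.n_cols);
    b.U.zeros(net.bw[l].U.n_rows, net.bw[l].U.n_cols);
    b.b.zeros(net.bw[l].b.n_rows, net.bw[l].b.n_cols);
    z.fw.push_back(f);
    z.bw.push_back(b);
  }
  z.Wd.zeros(net.Wd.n_rows, net.Wd.n_cols);
  z.bd.zeros(net.bd.n_rows, net.bd.n_cols);
  z.Wo.zeros(net.Wo.n_rows, net.Wo.n_cols);
  z.bo.zeros(net.bo.n_rows, net.bo.n_cols);
  return z;
}

// pointers over every parameter matrix, in a fixed order
static std::vector<mat*> param_ptrs(Net& n) {
  std::vector<mat*> v;
  for (size_t l = 0; l < n.fw.size(); ++l) {
    v.push_back(&n.fw[l].W); v.push_back(&n.fw[l].U); v.push_back(&n.fw[l].b);
    v.push_back(&n.bw[l].W); v.push_back(&n.bw[l].U); v.push_back(&n.bw[l].b);
  }
  v.push_back(&n.Wd); v.push_back(&n.bd);
  v.push_back(&n.Wo); v.push_back(&n.bo);
  return v;
}

// index of the first parameter belonging to a non-frozen part of the net:
// each layer owns 6 matrices, bottom `freeze` layers are skipped
static size_t first_trainable(int freeze) { return (size_t)(6 * freeze); }

struct DirCache {
  std::vector<mat> gi, gf, gg, go, c, ct, h;
  DirCache(int T) : gi(T), gf(T), gg(T), go(T), c(T), ct(T), h(T) {}
};

struct Caches {
  std::vector<std::vector<mat> > in;  // per layer, per t: layer input
  std::vector<DirCache> fw, bw;
  mat final_h, z1, r1;
  vec p;
};

// one directional LSTM pass over a stored input sequence
static void run_dir(const DirParams& par, const std::vector<mat>& in, DirCache& cc,
                    bool forward_dir) {
  const int T = (int)in.size();
  const int n = (int)in[0].n_rows;
  const int H = (int)par.U.n_rows;
  mat h_prev(n, H, arma::fill::zeros), c_prev(n, H, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = forward_dir ? s : (T - 1 - s);
    mat A = in[t] * par.W + h_prev * par.U;
    A.each_row() += par.b.row(0);
    mat i = sigm(A.cols(0, H - 1));
    mat f = sigm(A.cols(H, 2 * H - 1));
    mat g = arma::tanh(A.cols(2 * H, 3 * H - 1));
    mat o = sigm(A.cols(3 * H, 4 * H - 1));
    mat c = f % c_prev + i % g;
    mat ct = arma::tanh(c);
    mat h = o % ct;
    cc.gi[t] = i; cc.gf[t] = f; cc.gg[t] = g; cc.go[t] = o;
    cc.c[t] = c; cc.ct[t] = ct; cc.h[t] = h;
    h_prev = h;
    c_prev = c;
  }
}

static void forward(const Net& net, const cube& x, Caches& C) {
  const int T = (int)x.n_slices;
  const int n = (int)x.n_rows;
  const int L = net.n_layers();
  const int H = net.hidden();
  C.in.assign(L, std::vector<mat>(T));
  C.fw.assign(L, DirCache(T));
  C.bw.assign(L, DirCache(T));
  for (int l = 0; l < L; ++l) {
    for (int t = 0; t < T; ++t) {
      if (l == 0) C.in[l][t] = x.slice(t);
      else C.in[l][t] = arma::join_rows(C.fw[l - 1].h[t], C.bw[l - 1].h[t]);
    }
    run_dir(net.fw[l], C.in[l], C.fw[l], true);
    run_dir(net.bw[l], C.in[l], C.bw[l], false);
  }
  // final representation: forward state after reading the whole window
  // left-to-right, backward state after reading it right-to-left
  C.final_h = arma::join_rows(C.fw[L - 1].h[T - 1], C.bw[L - 1].h[0]);
  C.z1 = C.final_h * net.Wd;
  C.z1.each_row() += net.bd.row(0);
  C.r1 = arma::clamp(C.z1, 0.0, arma::datum::inf);  // ReLU
  mat logit = C.r1 * net.Wo;
  logit.each_row() += net.bo.row(0);
  C.p = sigm(logit).col(0);
  (void)n; (void)H;
}

// backward pass for one direction; returns gradient wrt the layer inputs
static void back_dir(const DirParams& par, const std::vector<mat>& in,
                     const DirCache& cc, const std::vector<mat>& dh_ext,
                     bool forward_dir, DirParams& grad, std::vector<mat>& din) {
  const int T = (int)in.size();
  const int n = (int)in[0].n_rows;
  const int H = (int)par.U.n_rows;
  mat dh_rec(n, H, arma::fill::zeros), dc_next(n, H, arma::fill::zeros);
  // visit steps in reverse of the processing order
  for (int s = T - 1; s >= 0; --s) {
    int t = forward_dir ? s : (T - 1 - s);
    // state preceding step t in processing order
    bool has_prev = s > 0;
    int tprev = forward_dir ? t - 1 : t + 1;
    mat dh = dh_ext[t] + dh_rec;
    mat dout_g = dh % cc.ct[t];
    mat dc = dc_next + (dh % cc.go[t]) % (1.0 - arma::square(cc.ct[t]));
    mat di_g = dc % cc.gg[t];
    mat df_g = has_prev ? mat(dc % cc.c[tprev]) : mat(n, H, arma::fill::zeros);
    mat dg_g = dc % cc.gi[t];
    mat dA(n, 4 * H);
    dA.cols(0, H - 1) = di_g % cc.gi[t] % (1.0 - cc.gi[t]);
    dA.cols(H, 2 * H - 1) = df_g % cc.gf[t] % (1.0 - cc.gf[t]);
    dA.cols(2 * H, 3 * H - 1) = dg_g % (1.0 - arma::square(cc.gg[t]));
    dA.cols(3 * H, 4 * H - 1) = dout_g % cc.go[t] % (1.0 - cc.go[t]);
    grad.W += in[t].t() * dA;
    if (has_prev) grad.U += cc.h[tprev].t() * dA;
    grad.b += arma::sum(dA, 0);
    din[t] += dA * par.W.t();
    dh_rec = dA * par.U.t();
    dc_next = dc % cc.gf[t];
  }
}

// weighted-BCE gradient wrt logits feeds the whole backward pass
static void backward(const Net& net, const Caches& C, const vec& y, const vec& w,
                     int freeze, Net& grad) {
  const int L = net.n_layers();
  const int T = (int)C.in[0].size();
  const int n = (int)C.in[0][0].n_rows;
  const int H = net.hidden();
  vec dlogit = (w % (C.p - y)) / (double)n;
  grad.Wo += C.r1.t() * dlogit;
  grad.bo(0, 0) += arma::accu(dlogit);
  mat dr1 = dlogit * net.Wo.t();
  mat dz1 = dr1 % arma::conv_to<mat>::from(C.z1 > 0.0);
  grad.Wd += C.final_h.t() * dz1;
  grad.bd += arma::sum(dz1, 0);
  mat dfinal = dz1 * net.Wd.t();

  // external dh per layer/direction/position
  std::vector<std::vector<mat> > dh_fw(L), dh_bw(L);
  for (int l = 0; l < L; ++l) {
    dh_fw[l].assign(T, mat(n, H, arma::fill::zeros));
    dh_bw[l].assign(T, mat(n, H, arma::fill::zeros));
  }
  dh_fw[L - 1][T - 1] += dfinal.cols(0, H - 1);
  dh_bw[L - 1][0] += dfinal.cols(H, 2 * H - 1);

  for (int l = L - 1; l >= freeze; --l) {
    std::vector<mat> din(T, mat(n, (int)C.in[l][0].n_cols, arma::fill::zeros));
    back_dir(net.fw[l], C.in[l], C.fw[l], dh_fw[l], true, grad.fw[l], din);
    back_dir(net.bw[l], C.in[l], C.bw[l], dh_bw[l], false, grad.bw[l], din);
    if (l > 0) {
      for (int t = 0; t < T; ++t) {
        dh_fw[l - 1][t] += din[t].cols(0, H - 1);
        dh_bw[l - 1][t] += din[t].cols(H, 2 * H - 1);
      }
    }
  }
}

static double weighted_bce(const vec& p, const vec& y, const vec& w) {
  vec pc = arma::clamp(p, 1e-7, 1.0 - 1e-7);
  return arma::accu(-w % (y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc))) /
         (double)p.n_elem;
}

static cube rows_of(const cube& x, const uvec& idx) {
  cube out(idx.n_elem, x.n_cols, x.n_slices);
  for (arma::uword t = 0; t < x.n_slices; ++t) out.slice(t) = x.slice(t).rows(idx);
  return out;
}

static vec predict_net(const Net& net, const cube& x, int chunk = 2048) {
  const int n = (int)x.n_rows;
  vec p(n);
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk) - 1;
    uvec idx = arma::regspace<uvec>(s, e);
    cube xb = rows_of(x, idx);
    Caches C;
    forward(net, xb, C);
    p.subvec(s, e) = C.p;
  }
  return p;
}

static double f1_at_half(const vec& p, const vec& y) {
  double tp = 0, fp = 0, fn = 0;
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    bool pos = p(i) > 0.5, lab = y(i) > 0.5;
    if (pos && lab) tp++;
    else if (pos && !lab) fp++;
    else if (!pos && lab) fn++;
  }
  double den = 2 * tp + fp + fn;
  return den > 0 ? 2 * tp / den : 0.0;
}

// [[Rcpp::export(name = ".lstm_predict")]]
arma::vec lstm_predict_cpp(List params, const arma::cube& x) {
  Net net = unpack(params);
  return predict_net(net, x);
}

// loss and analytic gradient on one batch; exists so tests can verify the
// BPTT implementation against finite differences
// [[Rcpp::export(name = ".lstm_loss_grad")]]
List lstm_loss_grad_cpp(List params, const arma::cube& x, const arma::vec& y,
                        const arma::vec& w) {
  Net net = unpack(params);
  Caches C;
  forward(net, x, C);
  Net grad = zeros_like(net);
  backward(net, C, y, w, 0, grad);
  return List::create(Named("loss") = weighted_bce(C.p, y, w),
                      Named("grad") = pack(grad));
}

// [[Rcpp::export(name = ".lstm_fit")]]
List lstm_fit_cpp(List params, const arma::cube& x_train, const arma::vec& y_train,
                  const arma::vec& w_train, const arma::cube& x_val,
                  const arma::vec& y_val, int batch_size, double lr,
                  int max_epochs, int patience, int freeze_layers, int seed,
                  double clip_norm) {
  Net net = unpack(params);
  Net m = zeros_like(net), v = zeros_like(net);
  const int n = (int)x_train.n_rows;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long adam_t = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<arma::uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Net best = net;
  double best_f1 = -1.0;
  int best_epoch = 0;
  std::vector<double> log_loss, log_f1;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size);
      uvec idx((arma::uword)(e - s));
      for (int i = s; i < e; ++i) idx(i - s) = order[i];
      cube xb = rows_of(x_train, idx);
      vec yb = y_train(idx), wb = w_train(idx);
      Caches C;
      forward(net, xb, C);
      loss_sum += weighted_bce(C.p, yb, wb) * (double)(e - s);
      Net grad = zeros_like(net);
      backward(net, C, yb, wb, freeze_layers, grad);
      // global gradient-norm clipping for recurrent stability
      std::vector<mat*> gp = param_ptrs(grad), np = param_ptrs(net),
                        mp = param_ptrs(m), vp = param_ptrs(v);
      double sq = 0;
      for (size_t k = first_trainable(freeze_layers); k < gp.size(); ++k)
        sq += arma::accu(arma::square(*gp[k]));
      double gn = std::sqrt(sq);
      double scale = (clip_norm > 0 && gn > clip_norm) ? clip_norm / gn : 1.0;
      adam_t++;
      double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
      for (size_t k = first_trainable(freeze_layers); k < gp.size(); ++k) {
        mat g = (*gp[k]) * scale;
        *mp[k] = beta1 * (*mp[k]) + (1 - beta1) * g;
        *vp[k] = beta2 * (*vp[k]) + (1 - beta2) * arma::square(g);
        *np[k] -= lr * ((*mp[k]) / bc1) / (arma::sqrt((*vp[k]) / bc2) + eps);
      }
    }
    vec pv = predict_net(net, x_val);
    double f1 = f1_at_half(pv, y_val);
    log_loss.push_back(loss_sum / (double)n);
    log_f1.push_back(f1);
    if (f1 > best_f1) {
      best_f1 = f1;
      best = net;
      best_epoch = epoch;
    }
    if (epoch - best_epoch >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  int epochs_run = (int)log_loss.size();
  NumericMatrix log(epochs_run, 3);
  for (int i = 0; i < epochs_run; ++i) {
    log(i, 0) = i + 1;
    log(i, 1) = log_loss[i];
    log(i, 2) = log_f1[i];
  }
  colnames(log) = CharacterVector::create("epoch", "train_loss", "val_f1");
  return List::create(Named("params") = pack(best), Named("log") = log,
                      Named("best_epoch") = best_epoch,
                      Named("best_val_f1") = best_f1 < 0 ? NA_REAL : best_f1,
                      Named("epochs_run") = epochs_run);
}
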