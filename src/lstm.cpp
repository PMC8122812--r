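// Stacked-LSTM sequence-to-sequence network: seeded initialization, batched
// forward pass, backpropagation through time, Adam updates, inverted dropout
// on the last decoder layer, and validation-based early stopping.
//
// Parameter lists crossing the R boundary have the layout
//   list(layers = list(list(Wx, Wh, b), ...), W, b)
// where Wx is (in x 4H), Wh is (H x 4H), b is length 4H (gate order
// input, forget, candidate, output), and W/b form the per-timestep linear
// head (H x O).  W = NULL denotes a headless (encoder-only) stack.
//
// Activations are stored time-major in (T*B x K) matrices (row t*B + b is
// segment b at time t), so every product except the recurrent h * Wh —
// input projections, the linear head, and all weight gradients — is a
// single large GEMM.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::span;

namespace {

struct Layer {
  mat Wx, Wh;
  rowvec b;
};

struct Net {
  std::vector<Layer> layers;
  mat W;     // head weights; empty => encoder-only stack
  rowvec b;  // head bias
  bool has_head() const { return W.n_elem > 0; }
};

Net net_from_list(const List& params) {
  Net net;
  List ls = params["layers"];
  for (R_xlen_t i = 0; i < ls.size(); ++i) {
    List l = ls[i];
    Layer lay;
    lay.Wx = as<mat>(l["Wx"]);
    lay.Wh = as<mat>(l["Wh"]);
    lay.b = as<rowvec>(l["b"]);
    net.layers.push_back(std::move(lay));
  }
  if (params.containsElementNamed("W") && !Rf_isNull(SEXP(params["W"]))) {
    net.W = as<mat>(params["W"]);
    net.b = as<rowvec>(params["b"]);
  }
  return net;
}

List net_to_list(const Net& net) {
  List ls(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    ls[i] = List::create(_["Wx"] = net.layers[i].Wx,
                         _["Wh"] = net.layers[i].Wh,
                         _["b"] = net.layers[i].b);
  }
  if (net.has_head())
    return List::create(_["layers"] = ls, _["W"] = net.W, _["b"] = net.b);
  return List::create(_["layers"] = ls, _["W"] = R_NilValue,
                      _["b"] = R_NilValue);
}

struct LayerCache {
  mat X;                      // layer input, (T*B x In)
  mat Gi, Gf, Gg, Go, C, TC;  // gate/cell activations, (T*B x H)
  mat H;                      // layer output, (T*B x H)
};

inline double sigmoid1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// tanh through exp: measurably faster than libm tanh, identical to within
// rounding on the gate range
inline double tanh1(double x) { return 2.0 / (1.0 + std::exp(-2.0 * x)) - 1.0; }

// Forward one LSTM layer over the whole (time x batch) block.  The gate
// math runs in fused pointer loops over preallocated blocks: in the
// (T*B x H) layout, the rows of timestep t in column j start at
// j*TB + t*B and are contiguous over the batch.
void layer_forward(const Layer& L, const mat& Xin, int T, int B,
                   LayerCache& cc, bool keep_input) {
  const int H = (int)L.Wh.n_rows;
  const size_t TB = (size_t)T * B;
  if (keep_input) cc.X = Xin;
  cc.Gi.set_size(TB, H);
  cc.Gf.set_size(TB, H);
  cc.Gg.set_size(TB, H);
  cc.Go.set_size(TB, H);
  cc.C.set_size(TB, H);
  cc.TC.set_size(TB, H);
  cc.H.set_size(TB, H);
  mat P = Xin * L.Wx;  // one GEMM for every timestep's input projection
  P.each_row() += L.b;
  mat h_prev(B, H, arma::fill::zeros);
  mat z(B, 4 * H);
  const size_t Pcol = TB;  // column stride of P (TB x 4H)
  for (int t = 0; t < T; ++t) {
    const size_t off = (size_t)t * B;
    z = h_prev * L.Wh;
    double* zp = z.memptr();
    const double* pp = P.memptr() + off;
    for (int j = 0; j < 4 * H; ++j) {
      const double* pc = pp + (size_t)j * Pcol;
      double* zc = zp + (size_t)j * B;
      for (int b = 0; b < B; ++b) zc[b] += pc[b];
    }
    for (int j = 0; j < H; ++j) {
      const double* zi = zp + (size_t)j * B;
      const double* zf = zp + (size_t)(H + j) * B;
      const double* zg = zp + (size_t)(2 * H + j) * B;
      const double* zo = zp + (size_t)(3 * H + j) * B;
      double* gi = cc.Gi.memptr() + (size_t)j * TB + off;
      double* gf = cc.Gf.memptr() + (size_t)j * TB + off;
      double* gg = cc.Gg.memptr() + (size_t)j * TB + off;
      double* go = cc.Go.memptr() + (size_t)j * TB + off;
      double* c = cc.C.memptr() + (size_t)j * TB + off;
      double* tc = cc.TC.memptr() + (size_t)j * TB + off;
      double* h = cc.H.memptr() + (size_t)j * TB + off;
      const double* cp = c - B;  // previous timestep's cell state
      double* hprev = h_prev.memptr() + (size_t)j * B;
      for (int b = 0; b < B; ++b) {
        const double i_ = sigmoid1(zi[b]);
        const double f_ = sigmoid1(zf[b]);
        const double g_ = tanh1(zg[b]);
        const double o_ = sigmoid1(zo[b]);
        const double cprev = (t > 0) ? cp[b] : 0.0;
        const double c_ = f_ * cprev + i_ * g_;
        const double tc_ = tanh1(c_);
        gi[b] = i_;
        gf[b] = f_;
        gg[b] = g_;
        go[b] = o_;
        c[b] = c_;
        tc[b] = tc_;
        h[b] = o_ * tc_;
        hprev[b] = o_ * tc_;
      }
    }
  }
}

// dHtop: dLoss/d(layer output).  Fills dXin and the gradients in G.
void layer_backward(const Layer& L, const LayerCache& cc, const mat& dHtop,
                    int T, int B, mat& dXin, Layer& G) {
  const int H = (int)L.Wh.n_rows;
  const size_t TB = (size_t)T * B;
  mat dZ(TB, 4 * H);
  mat dh_next(B, H, arma::fill::zeros);
  mat dc_next(B, H, arma::fill::zeros);
  mat dZt(B, 4 * H);
  for (int t = T - 1; t >= 0; --t) {
    const size_t off = (size_t)t * B;
    double* dzp = dZt.memptr();
    for (int j = 0; j < H; ++j) {
      const double* gi = cc.Gi.memptr() + (size_t)j * TB + off;
      const double* gf = cc.Gf.memptr() + (size_t)j * TB + off;
      const double* gg = cc.Gg.memptr() + (size_t)j * TB + off;
      const double* go = cc.Go.memptr() + (size_t)j * TB + off;
      const double* c = cc.C.memptr() + (size_t)j * TB + off;
      const double* tc = cc.TC.memptr() + (size_t)j * TB + off;
      const double* cp = c - B;
      const double* dtop = dHtop.memptr() + (size_t)j * TB + off;
      double* dhn = dh_next.memptr() + (size_t)j * B;
      double* dcn = dc_next.memptr() + (size_t)j * B;
      double* dzi = dzp + (size_t)j * B;
      double* dzf = dzp + (size_t)(H + j) * B;
      double* dzg = dzp + (size_t)(2 * H + j) * B;
      double* dzo = dzp + (size_t)(3 * H + j) * B;
      for (int b = 0; b < B; ++b) {
        const double dh = dtop[b] + dhn[b];
        const double dc = dcn[b] + dh * go[b] * (1.0 - tc[b] * tc[b]);
        const double cprev = (t > 0) ? cp[b] : 0.0;
        dzi[b] = dc * gg[b] * gi[b] * (1.0 - gi[b]);
        dzf[b] = dc * cprev * gf[b] * (1.0 - gf[b]);
        dzg[b] = dc * gi[b] * (1.0 - gg[b] * gg[b]);
        dzo[b] = dh * tc[b] * go[b] * (1.0 - go[b]);
        dcn[b] = dc * gf[b];
      }
    }
    dh_next = dZt * L.Wh.t();
    // store this timestep's gate gradients into the big block
    double* big = dZ.memptr();
    for (int j = 0; j < 4 * H; ++j) {
      const double* src = dzp + (size_t)j * B;
      double* dst = big + (size_t)j * TB + off;
      std::copy(src, src + B, dst);
    }
  }
  G.Wx = cc.X.t() * dZ;
  G.Wh.zeros(L.Wh.n_rows, L.Wh.n_cols);
  if (T > 1)  // h_prev at t = 0 is zero and contributes nothing
    G.Wh = cc.H.rows(0, TB - B - 1).t() * dZ.rows(B, TB - 1);
  G.b = arma::sum(dZ, 0);
  dXin = dZ * L.Wx.t();
}

struct NetCache {
  std::vector<LayerCache> layers;
  mat Hdrop;  // last hidden block after dropout, (T*B x H)
  mat Mask;   // dropout mask (empty when dropout = 0)
};

// Full network forward on a (T*B x C) block; returns (T*B x O) predictions
// (or the last hidden block for headless stacks).
mat net_forward(const Net& net, const mat& X0, int T, int B, double dropout,
                std::mt19937* rng, NetCache* cache) {
  NetCache local;
  NetCache& cc = cache ? *cache : local;
  cc.layers.resize(net.layers.size());
  const mat* cur = &X0;
  for (size_t l = 0; l < net.layers.size(); ++l) {
    layer_forward(net.layers[l], *cur, T, B, cc.layers[l],
                  cache != nullptr);
    cur = &cc.layers[l].H;
  }
  if (!net.has_head()) return *cur;
  mat Hd = *cur;
  if (dropout > 0.0 && rng) {
    const double keep = 1.0 - dropout;
    std::uniform_real_distribution<double> U(0.0, 1.0);
    cc.Mask.set_size(Hd.n_rows, Hd.n_cols);
    for (arma::uword j = 0; j < cc.Mask.n_elem; ++j)
      cc.Mask(j) = (U(*rng) < keep) ? 1.0 / keep : 0.0;
    Hd %= cc.Mask;
  }
  if (cache) cc.Hdrop = Hd;
  mat Y = Hd * net.W;
  Y.each_row() += net.b;
  return Y;
}

void net_backward(const Net& net, const NetCache& cc, const mat& dY, int T,
                  int B, Net& G) {
  G.W = cc.Hdrop.t() * dY;
  G.b = arma::sum(dY, 0);
  mat dH = dY * net.W.t();
  if (cc.Mask.n_elem) dH %= cc.Mask;
  G.layers.resize(net.layers.size());
  mat dX;
  for (int l = (int)net.layers.size() - 1; l >= 0; --l) {
    layer_backward(net.layers[l], cc.layers[l], dH, T, B, dX, G.layers[l]);
    dH = std::move(dX);
  }
}

// Gather segments idx of cube (T x C x N) into the time-major block.
mat gather(const arma::cube& X, const std::vector<int>& idx) {
  const int T = (int)X.n_rows, C = (int)X.n_cols, B = (int)idx.size();
  mat out(T * B, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t)
        out(t * B + b, c) = X(t, c, idx[b]);
  return out;
}

double dataset_mse(const Net& net, const arma::cube& X, const arma::cube& Y,
                   int batch_size) {
  const int N = (int)X.n_slices, T = (int)X.n_rows;
  double s = 0.0, n = 0.0;
  for (int start = 0; start < N; start += batch_size) {
    std::vector<int> idx;
    for (int i = start; i < std::min(start + batch_size, N); ++i)
      idx.push_back(i);
    mat Xb = gather(X, idx);
    mat Yb = gather(Y, idx);
    mat P = net_forward(net, Xb, T, (int)idx.size(), 0.0, nullptr, nullptr);
    s += arma::accu(arma::square(P - Yb));
    n += (double)P.n_elem;
  }
  return s / n;
}

struct AdamState {
  Net m, v;
  long t = 0;
};

AdamState adam_like(const Net& net) {
  AdamState st;
  st.m.layers.resize(net.layers.size());
  st.v.layers.resize(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    st.m.layers[l].Wx.zeros(net.layers[l].Wx.n_rows,
                            net.layers[l].Wx.n_cols);
    st.m.layers[l].Wh.zeros(net.layers[l].Wh.n_rows,
                            net.layers[l].Wh.n_cols);
    st.m.layers[l].b.zeros(net.layers[l].b.n_elem);
    st.v.layers[l] = st.m.layers[l];
  }
  st.m.W.zeros(net.W.n_rows, net.W.n_cols);
  st.m.b.zeros(net.b.n_elem);
  st.v.W = st.m.W;
  st.v.b = st.m.b;
  return st;
}

template <typename M>
void adam_update_one(M& p, const M& g, M& m, M& v, double lr, double bc1,
                     double bc2) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

double grad_norm(const Net& G) {
  double s = 0.0;
  for (const Layer& l : G.layers)
    s += arma::accu(arma::square(l.Wx)) + arma::accu(arma::square(l.Wh)) +
         arma::accu(arma::square(l.b));
  s += arma::accu(arma::square(G.W)) + arma::accu(arma::square(G.b));
  return std::sqrt(s);
}

void scale_grads(Net& G, double f) {
  for (Layer& l : G.layers) {
    l.Wx *= f;
    l.Wh *= f;
    l.b *= f;
  }
  G.W *= f;
  G.b *= f;
}

void adam_step(Net& net, const Net& G, AdamState& st, double lr) {
  st.t += 1;
  const double bc1 = 1.0 - std::pow(0.9, (double)st.t);
  const double bc2 = 1.0 - std::pow(0.999, (double)st.t);
  for (size_t l = 0; l < net.layers.size(); ++l) {
    adam_update_one(net.layers[l].Wx, G.layers[l].Wx, st.m.layers[l].Wx,
                    st.v.layers[l].Wx, lr, bc1, bc2);
    adam_update_one(net.layers[l].Wh, G.layers[l].Wh, st.m.layers[l].Wh,
                    st.v.layers[l].Wh, lr, bc1, bc2);
    adam_update_one(net.layers[l].b, G.layers[l].b, st.m.layers[l].b,
                    st.v.layers[l].b, lr, bc1, bc2);
  }
  adam_update_one(net.W, G.W, st.m.W, st.v.W, lr, bc1, bc2);
  adam_update_one(net.b, G.b, st.m.b, st.v.b, lr, bc1, bc2);
}

}  // namespace

// [[Rcpp::export]]
List lstm_init_cpp(IntegerVector layer_inputs, int hidden, int out_ch,
                   int seed) {
  if (hidden < 1 || out_ch < 1 || layer_inputs.size() < 1)
    stop("layer sizes must be positive");
  std::mt19937 rng((unsigned)seed);
  const double k = 1.0 / std::sqrt((double)hidden);
  std::uniform_real_distribution<double> U(-k, k);
  Net net;
  for (int l = 0; l < layer_inputs.size(); ++l) {
    if (layer_inputs[l] < 1) stop("layer sizes must be positive");
    Layer L;
    L.Wx.set_size(layer_inputs[l], 4 * hidden);
    L.Wh.set_size(hidden, 4 * hidden);
    L.b.set_size(4 * hidden);
    for (arma::uword j = 0; j < L.Wx.n_elem; ++j) L.Wx(j) = U(rng);
    for (arma::uword j = 0; j < L.Wh.n_elem; ++j) L.Wh(j) = U(rng);
    L.b.zeros();
    // positive initial forget-gate bias keeps early gradients flowing
    L.b.subvec(hidden, 2 * hidden - 1).fill(1.0);
    net.layers.push_back(std::move(L));
  }
  net.W.set_size(hidden, out_ch);
  for (arma::uword j = 0; j < net.W.n_elem; ++j) net.W(j) = U(rng);
  net.b.zeros(out_ch);
  return net_to_list(net);
}

// Forward pass for a single segment, X: (T x C) -> (T x O).  No dropout.
// [[Rcpp::export]]
arma::mat lstm_forward_cpp(List params, const arma::mat& X) {
  Net net = net_from_list(params);
  return net_forward(net, X, (int)X.n_rows, 1, 0.0, nullptr, nullptr);
}

// Batched inference over a dataset cube (T x C x N) -> (T x O x N).
// [[Rcpp::export]]
arma::cube lstm_predict_cpp(List params, const arma::cube& X,
                            int batch_size) {
  Net net = net_from_list(params);
  const int T = (int)X.n_rows, N = (int)X.n_slices;
  const int O = net.has_head() ? (int)net.W.n_cols
                               : (int)net.layers.back().Wh.n_rows;
  arma::cube out(T, O, N);
  for (int start = 0; start < N; start += batch_size) {
    std::vector<int> idx;
    for (int i = start; i < std::min(start + batch_size, N); ++i)
      idx.push_back(i);
    const int B = (int)idx.size();
    mat Xb = gather(X, idx);
    mat P = net_forward(net, Xb, T, B, 0.0, nullptr, nullptr);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T; ++t)
        for (int o = 0; o < O; ++o)
          out(t, o, idx[b]) = P(t * B + b, o);
  }
  return out;
}

// Full-batch analytic gradient of the MSE loss (no dropout): the oracle
// hook for finite-difference verification of the backward pass.
// [[Rcpp::export]]
List lstm_grad_cpp(List params, const arma::cube& X, const arma::cube& Y) {
  Net net = net_from_list(params);
  const int N = (int)X.n_slices, T = (int)X.n_rows;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  mat Xb = gather(X, idx);
  mat Yb = gather(Y, idx);
  NetCache cache;
  mat P = net_forward(net, Xb, T, N, 0.0, nullptr, &cache);
  mat dY = (2.0 / (double)P.n_elem) * (P - Yb);
  Net G;
  net_backward(net, cache, dY, T, N, G);
  return net_to_list(G);
}

// Mini-batch MSE training with Adam, optional dropout on the last layer's
// output, gradient-norm clipping, and early stopping on validation loss.
// Returns the best-validation parameters when a validation set is given.
// [[Rcpp::export]]
List lstm_train_cpp(List params, const arma::cube& X, const arma::cube& Y,
                    const arma::cube& Xval, const arma::cube& Yval,
                    int epochs, int batch_size, double lr, double dropout,
                    int seed, int patience, double clip) {
  Net net = net_from_list(params);
  if (!net.has_head()) stop("training requires a network with a linear head");
  const int N = (int)X.n_slices, T = (int)X.n_rows;
  if ((int)Y.n_slices != N) stop("input and target counts differ");
  const bool has_val = Xval.n_slices > 0;
  std::mt19937 rng((unsigned)seed);

  const double init_train = dataset_mse(net, X, Y, batch_size);
  const double init_val =
      has_val ? dataset_mse(net, Xval, Yval, batch_size) : NA_REAL;

  AdamState st = adam_like(net);
  std::vector<double> train_hist, val_hist;
  Net best = net;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0;
  bool stopped_early = false;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0, ep_n = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      std::vector<int> idx(order.begin() + start,
                           order.begin() +
                               std::min<int>(start + batch_size, N));
      const int B = (int)idx.size();
      mat Xb = gather(X, idx);
      mat Yb = gather(Y, idx);
      NetCache cache;
      mat P = net_forward(net, Xb, T, B, dropout, &rng, &cache);
      mat diff = P - Yb;
      const double denom = (double)P.n_elem;
      ep_loss += arma::accu(arma::square(diff));
      ep_n += denom;
      mat dY = (2.0 / denom) * diff;
      Net G;
      net_backward(net, cache, dY, T, B, G);
      const double gn = grad_norm(G);
      if (!std::isfinite(gn))
        stop("non-finite gradient at epoch %d (lr=%g, batch=%d)", epoch, lr,
             batch_size);
      if (clip > 0 && gn > clip) scale_grads(G, clip / gn);
      adam_step(net, G, st, lr);
    }
    const double tl = ep_loss / ep_n;
    if (!std::isfinite(tl))
      stop("non-finite training loss at epoch %d (lr=%g, batch=%d)", epoch,
           lr, batch_size);
    train_hist.push_back(tl);
    if (has_val) {
      const double vl = dataset_mse(net, Xval, Yval, batch_size);
      if (!std::isfinite(vl))
        stop("non-finite validation loss at epoch %d (lr=%g, batch=%d)",
             epoch, lr, batch_size);
      val_hist.push_back(vl);
      if (vl < best_val - 1e-12) {
        best_val = vl;
        best = net;
        best_epoch = epoch;
        wait = 0;
      } else if (++wait >= patience && patience > 0) {
        stopped_early = true;
        break;
      }
    } else {
      best = net;
      best_epoch = epoch;
    }
  }
  if (epochs == 0) best = net;

  return List::create(
      _["params"] = net_to_list(best), _["train_loss"] = wrap(train_hist),
      _["val_loss"] = wrap(val_hist), _["best_epoch"] = best_epoch,
      _["stopped_early"] = stopped_early,
      _["initial_train_loss"] = init_train, _["initial_val_loss"] = init_val);
}
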