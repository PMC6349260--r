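// Bidirectional LSTM core: stacked BLSTM layers with a linear / averaged /
// softmax head, full backpropagation through time. Parameters live in one
// flat vector so the R side can run a generic Adam loop.
//
// Flat parameter layout, in order:
//   for layer l = 0..L-1, for direction d = 0 (forward), 1 (backward):
//     Wx (4H x D_l), Wh (4H x H), b (4H)       [gate order: i, f, o, g]
//   Wo (n_out x 2H), bo (n_out)
// with D_0 = n_in and D_l = 2H for l >= 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Layout {
  int n_in, H, L, n_out, T, N;
  int lstm_total;
  int d_in(int l) const { return l == 0 ? n_in : 2 * H; }
  int lstm_block(int l) const { return 4 * H * d_in(l) + 4 * H * H + 4 * H; }
  int offset(int l, int d) const {
    int off = 0;
    for (int k = 0; k < l; ++k) off += 2 * lstm_block(k);
    return off + d * lstm_block(l);
  }
  int total() const {
    int off = 0;
    for (int k = 0; k < L; ++k) off += 2 * lstm_block(k);
    return off + n_out * 2 * H + n_out;
  }
};

// non-owning matrix view into a flat vector
static inline mat view(vec& v, int off, int r, int c) {
  return mat(v.memptr() + off, r, c, false, true);
}
static inline mat cview(const vec& v, int off, int r, int c) {
  return mat(const_cast<double*>(v.memptr()) + off, r, c, false, true);
}

// [[Rcpp::export]]
int blstm_n_params(int n_in, int units, int layers, int n_out) {
  Layout lo; lo.n_in = n_in; lo.H = units; lo.L = layers; lo.n_out = n_out;
  return lo.total();
}

struct LayerCache {
  cube gates;  // N x 4H x T, post-activation
  cube c;      // N x H x T
  cube tc;     // tanh(c)
  cube h;      // N x H x T
};

// forward pass; fills caches when keep is true; returns per-step head input
static cube run_forward(const vec& params, const cube& X, const Layout& lo,
                        std::vector<LayerCache>* caches, cube* layer_in_store) {
  int N = lo.N, T = lo.T, H = lo.H;
  cube input = X;  // N x D x T
  for (int l = 0; l < lo.L; ++l) {
    int D = lo.d_in(l);
    cube out(N, 2 * H, T, fill::zeros);
    for (int d = 0; d < 2; ++d) {
      int off = lo.offset(l, d);
      mat Wx = cview(params, off, 4 * H, D);
      mat Wh = cview(params, off + 4 * H * D, 4 * H, H);
      vec b(const_cast<double*>(params.memptr()) + off + 4 * H * D + 4 * H * H,
            4 * H, false, true);
      LayerCache cache;
      if (caches) {
        cache.gates.set_size(N, 4 * H, T);
        cache.c.set_size(N, H, T);
        cache.tc.set_size(N, H, T);
        cache.h.set_size(N, H, T);
      }
      mat h_prev(N, H, fill::zeros), c_prev(N, H, fill::zeros);
      mat a(N, 4 * H);
      for (int s = 0; s < T; ++s) {
        int t = (d == 0) ? s : (T - 1 - s);
        a = input.slice(t) * Wx.t();
        a += h_prev * Wh.t();
        a.each_row() += b.t();
        // activate gates in place: sigmoid on i,f,o; tanh on g
        double* ap = a.memptr();
        const int n3 = N * 3 * H, n4 = N * 4 * H;
        for (int q = 0; q < n3; ++q) ap[q] = 1.0 / (1.0 + std::exp(-ap[q]));
        for (int q = n3; q < n4; ++q) ap[q] = std::tanh(ap[q]);
        mat c = a.cols(H, 2 * H - 1) % c_prev +
          a.cols(0, H - 1) % a.cols(3 * H, 4 * H - 1);
        mat tc = tanh(c);
        mat h = a.cols(2 * H, 3 * H - 1) % tc;
        if (caches) {
          cache.gates.slice(t) = a;
          cache.c.slice(t) = c;
          cache.tc.slice(t) = tc;
          cache.h.slice(t) = h;
        }
        out.slice(t).cols(d * H, (d + 1) * H - 1) = h;
        h_prev = std::move(h); c_prev = std::move(c);
      }
      if (caches) caches->push_back(std::move(cache));
    }
    if (layer_in_store) layer_in_store[l] = input;
    input = out;
  }
  return input;  // N x 2H x T
}

static cube head_outputs(const vec& params, const cube& top, const Layout& lo) {
  int N = lo.N, T = lo.T, H = lo.H;
  int off = lo.offset(lo.L - 1, 1) + lo.lstm_block(lo.L - 1);
  mat Wo = cview(params, off, lo.n_out, 2 * H);
  vec bo(const_cast<double*>(params.memptr()) + off + lo.n_out * 2 * H,
         lo.n_out, false, true);
  cube P(N, lo.n_out, T);
  for (int t = 0; t < T; ++t) {
    P.slice(t) = top.slice(t) * Wo.t();
    P.slice(t).each_row() += bo.t();
  }
  return P;
}

static mat softmax_rows(const mat& a) {
  mat m = a.each_col() - max(a, 1);
  mat e = exp(m);
  return e.each_col() / sum(e, 1);
}

// head = 0 physical (linear, mean squared error over all outputs)
//        1 yield (per-step outputs averaged to one scalar, squared error)
//        2 phenology (per-step softmax, cross-entropy against fractions)
// [[Rcpp::export]]
Rcpp::List blstm_loss_grad(const arma::vec& params, const arma::cube& X,
                           SEXP Y, int head, int layers, int units,
                           int n_out, bool want_grad) {
  Layout lo;
  lo.n_in = X.n_cols; lo.H = units; lo.L = layers; lo.n_out = n_out;
  lo.N = X.n_rows; lo.T = X.n_slices;
  if ((int)params.n_elem != lo.total())
    Rcpp::stop("parameter vector has the wrong length");

  std::vector<LayerCache> caches;
  std::vector<cube> layer_in(lo.L);
  cube top = run_forward(params, X, lo,
                         want_grad ? &caches : nullptr,
                         want_grad ? layer_in.data() : nullptr);
  if (!want_grad) {
    // still need top for loss
  }
  cube P = head_outputs(params, top, lo);

  int N = lo.N, T = lo.T, H = lo.H;
  double loss = 0.0;
  cube dOut(N, lo.n_out, T, fill::zeros);

  if (head == 0) {
    cube Yc = Rcpp::as<cube>(Y);
    double denom = (double)N * T * lo.n_out;
    cube diff = P - Yc;
    loss = accu(square(diff)) / denom;
    dOut = diff * (2.0 / denom);
  } else if (head == 1) {
    vec y = Rcpp::as<vec>(Y);
    vec yhat(N, fill::zeros);
    for (int t = 0; t < T; ++t) yhat += P.slice(t).col(0);
    yhat /= T;
    vec d = yhat - y;
    loss = accu(square(d)) / N;
    for (int t = 0; t < T; ++t)
      dOut.slice(t).col(0) = d * (2.0 / (N * (double)T));
  } else {
    cube Yc = Rcpp::as<cube>(Y);
    double denom = (double)N * T;
    for (int t = 0; t < T; ++t) {
      mat Q = softmax_rows(P.slice(t));
      loss += -accu(Yc.slice(t) % log(Q + 1e-12)) / denom;
      dOut.slice(t) = (Q - Yc.slice(t)) / denom;
    }
  }
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");

  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  }

  vec grad(lo.total(), fill::zeros);

  // head gradients
  int off_o = lo.offset(lo.L - 1, 1) + lo.lstm_block(lo.L - 1);
  mat Wo = cview(params, off_o, lo.n_out, 2 * H);
  mat dWo = view(grad, off_o, lo.n_out, 2 * H);
  vec dbo(grad.memptr() + off_o + lo.n_out * 2 * H, lo.n_out, false, true);
  cube dTop(N, 2 * H, T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    dWo += dOut.slice(t).t() * top.slice(t);
    dbo += sum(dOut.slice(t), 0).t();
    dTop.slice(t) = dOut.slice(t) * Wo;
  }

  cube dO = dTop;
  for (int l = lo.L - 1; l >= 0; --l) {
    int D = lo.d_in(l);
    cube dIn(N, D, T, fill::zeros);
    for (int d = 0; d < 2; ++d) {
      int off = lo.offset(l, d);
      mat Wx = cview(params, off, 4 * H, D);
      mat Wh = cview(params, off + 4 * H * D, 4 * H, H);
      mat dWx = view(grad, off, 4 * H, D);
      mat dWh = view(grad, off + 4 * H * D, 4 * H, H);
      vec db(grad.memptr() + off + 4 * H * D + 4 * H * H, 4 * H, false, true);
      const LayerCache& cache = caches[2 * l + d];

      mat dh_rec(N, H, fill::zeros), dC(N, H, fill::zeros);
      cube DA(N, 4 * H, T);
      const mat zeroH(N, H, fill::zeros);
      for (int s = T - 1; s >= 0; --s) {
        int t = (d == 0) ? s : (T - 1 - s);
        int tp = (d == 0) ? t - 1 : t + 1;  // previous step in time order
        const mat& h_prev = (s == 0) ? zeroH : cache.h.slice(tp);
        const mat& c_prev = (s == 0) ? zeroH : cache.c.slice(tp);
        const mat& gates = cache.gates.slice(t);
        auto gi = gates.cols(0, H - 1);
        auto gf = gates.cols(H, 2 * H - 1);
        auto go = gates.cols(2 * H, 3 * H - 1);
        auto gg = gates.cols(3 * H, 4 * H - 1);
        const mat& tc = cache.tc.slice(t);

        mat dh = dO.slice(t).cols(d * H, (d + 1) * H - 1) + dh_rec;
        dC += dh % go % (1.0 - square(tc));
        mat& da = DA.slice(t);
        da.cols(0, H - 1) = (dC % gg) % gi % (1.0 - gi);
        da.cols(H, 2 * H - 1) = (dC % c_prev) % gf % (1.0 - gf);
        da.cols(2 * H, 3 * H - 1) = (dh % tc) % go % (1.0 - go);
        da.cols(3 * H, 4 * H - 1) = (dC % gi) % (1.0 - square(gg));
        dWh += da.t() * h_prev;
        db += sum(da, 0).t();
        dh_rec = da * Wh;
        dC %= gf;
      }
      for (int t = 0; t < T; ++t) {
        dWx += DA.slice(t).t() * layer_in[l].slice(t);
        dIn.slice(t) += DA.slice(t) * Wx;
      }
    }
    dO = dIn;
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
Rcpp::List blstm_forward(const arma::vec& params, const arma::cube& X,
                         int head, int layers, int units, int n_out) {
  Layout lo;
  lo.n_in = X.n_cols; lo.H = units; lo.L = layers; lo.n_out = n_out;
  lo.N = X.n_rows; lo.T = X.n_slices;
  if ((int)params.n_elem != lo.total())
    Rcpp::stop("parameter vector has the wrong length");
  cube top = run_forward(params, X, lo, nullptr, nullptr);
  cube P = head_outputs(params, top, lo);
  if (head == 1) {
    vec yhat(lo.N, fill::zeros);
    for (int t = 0; t < lo.T; ++t) yhat += P.slice(t).col(0);
    yhat /= lo.T;
    return Rcpp::List::create(Rcpp::Named("pred") = yhat);
  }
  if (head == 2) {
    for (int t = 0; t < lo.T; ++t) P.slice(t) = softmax_rows(P.slice(t));
  }
  return Rcpp::List::create(Rcpp::Named("pred") = P);
}
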