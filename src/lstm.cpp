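// Recurrent network engine: stacked LSTM / bidirectional-LSTM layers with a
// softmax read-out, forward pass and backpropagation through time.
//
// Conventions (matching the common deep-learning-framework layout):
//  - gate order i, f, g (candidate), o along the 4H axis;
//  - per-direction parameters Wx (in x 4H), Wh (H x 4H), b (4H);
//  - layers 1..L-1 emit full sequences (bidirectional: forward and backward
//    hidden states concatenated per timestep), layer L emits its final
//    state(s) only;
//  - inverted dropout on the sequence output of selected layers, training
//    only;
//  - input cube X has dims (batch, features, time).
//
// Weight list order: for each layer, Wx, Wh, b (unidirectional) or
// Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b (bidirectional); then dense W, b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  cube gates;   // B x 4H x T (post-activation)
  cube cell;    // B x H x T
  cube hidden;  // B x H x T (aligned to original time axis)
};

// One direction of one layer. reverse = true processes time back-to-front;
// hidden/cell/gate caches stay aligned to the original time axis.
static void dir_forward(const cube& Xin, const mat& Wx, const mat& Wh,
                        const rowvec& b, bool reverse, DirCache& cc) {
  const uword B = Xin.n_rows, T = Xin.n_slices;
  const uword H = Wh.n_rows;
  cc.gates.set_size(B, 4 * H, T);
  cc.cell.set_size(B, H, T);
  cc.hidden.set_size(B, H, T);

  // input projection for the whole sequence
  cube proj(B, 4 * H, T);
  for (uword t = 0; t < T; ++t) {
    proj.slice(t) = Xin.slice(t) * Wx;
    proj.slice(t).each_row() += b;
  }

  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    const uword u = reverse ? (T - 1 - s) : s;
    mat z = proj.slice(u) + h * Wh;
    mat i = sigmoid(z.cols(0, H - 1));
    mat f = sigmoid(z.cols(H, 2 * H - 1));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.gates.slice(u) = join_rows(i, f, g, o);
    cc.cell.slice(u) = c;
    cc.hidden.slice(u) = h;
  }
}

// BPTT for one direction. dHseq is the gradient w.r.t. this direction's
// hidden output at every (original-time) step. Accumulates into gWx, gWh, gb
// and into dXin.
static void dir_backward(const cube& Xin, const mat& Wx, const mat& Wh,
                         bool reverse, const DirCache& cc, const cube& dHseq,
                         mat& gWx, mat& gWh, rowvec& gb, cube& dXin) {
  const uword B = Xin.n_rows, T = Xin.n_slices;
  const uword H = Wh.n_rows;
  gWx.zeros(Wx.n_rows, Wx.n_cols);
  gWh.zeros(H, 4 * H);
  gb.zeros(4 * H);

  mat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
  for (uword s = T; s-- > 0;) {
    const uword u = reverse ? (T - 1 - s) : s;
    const mat& gt = cc.gates.slice(u);
    mat i = gt.cols(0, H - 1);
    mat f = gt.cols(H, 2 * H - 1);
    mat g = gt.cols(2 * H, 3 * H - 1);
    mat o = gt.cols(3 * H, 4 * H - 1);
    mat tc = tanh(cc.cell.slice(u));

    mat dh = dHseq.slice(u) + dh_carry;
    mat do_ = dh % tc;
    mat dc = dc_carry + dh % o % (1.0 - tc % tc);

    mat c_prev(B, H, fill::zeros), h_prev(B, H, fill::zeros);
    if (s > 0) {
      const uword up = reverse ? (T - s) : (s - 1);
      c_prev = cc.cell.slice(up);
      h_prev = cc.hidden.slice(up);
    }
    mat di = dc % g;
    mat df = dc % c_prev;
    mat dg = dc % i;
    mat dz = join_rows(di % i % (1.0 - i),
                       df % f % (1.0 - f),
                       dg % (1.0 - g % g),
                       do_ % o % (1.0 - o));
    gWx += Xin.slice(u).t() * dz;
    gWh += h_prev.t() * dz;
    gb += sum(dz, 0);
    dXin.slice(u) += dz * Wx.t();
    dh_carry = dz * Wh.t();
    dc_carry = dc % f;
  }
}

struct LayerW {
  mat Wxf, Whf;
  rowvec bf;
  mat Wxb, Whb;
  rowvec bb;  // backward direction (bidirectional only)
};

struct Net {
  std::vector<LayerW> layers;
  mat Wd;
  rowvec bd;
  bool bidir;
  uvec units;
};

static Net unpack(const Rcpp::List& weights, const Rcpp::IntegerVector& units,
                  bool bidirectional) {
  Net net;
  net.bidir = bidirectional;
  net.units = uvec(units.size());
  size_t k = 0;
  for (int l = 0; l < units.size(); ++l) {
    net.units[l] = units[l];
    LayerW lw;
    lw.Wxf = Rcpp::as<mat>(weights[k++]);
    lw.Whf = Rcpp::as<mat>(weights[k++]);
    lw.bf = Rcpp::as<rowvec>(weights[k++]);
    if (bidirectional) {
      lw.Wxb = Rcpp::as<mat>(weights[k++]);
      lw.Whb = Rcpp::as<mat>(weights[k++]);
      lw.bb = Rcpp::as<rowvec>(weights[k++]);
    }
    net.layers.push_back(lw);
  }
  net.Wd = Rcpp::as<mat>(weights[k++]);
  net.bd = Rcpp::as<rowvec>(weights[k++]);
  return net;
}

static mat softmax_rows(const mat& logits) {
  mat z = logits;
  z.each_col() -= max(z, 1);
  mat e = exp(z);
  e.each_col() /= sum(e, 1);
  return e;
}

struct ForwardState {
  std::vector<cube> inputs;            // input cube of each layer
  std::vector<DirCache> fw, bw;        // per-layer caches
  std::vector<cube> masks;             // dropout masks (empty if unused)
  mat dense_in;                        // input to the dense read-out
  mat probs;
};

static void net_forward(const Net& net, const cube& X, bool training,
                        double dropout, const std::set<int>& drop_after,
                        std::mt19937_64& rng, ForwardState& st) {
  const uword L = net.layers.size();
  const uword B = X.n_rows, T = X.n_slices;
  st.inputs.resize(L);
  st.fw.resize(L);
  st.bw.resize(L);
  st.masks.assign(L, cube());

  cube cur = X;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (uword l = 0; l < L; ++l) {
    st.inputs[l] = cur;
    dir_forward(cur, net.layers[l].Wxf, net.layers[l].Whf, net.layers[l].bf,
                false, st.fw[l]);
    if (net.bidir) {
      dir_forward(cur, net.layers[l].Wxb, net.layers[l].Whb, net.layers[l].bb,
                  true, st.bw[l]);
    }
    if (l == L - 1) break;  // sequence output not needed past the caches
    const uword H = net.units[l];
    cube outseq(B, net.bidir ? 2 * H : H, T);
    for (uword t = 0; t < T; ++t) {
      if (net.bidir) {
        outseq.slice(t) =
            join_rows(st.fw[l].hidden.slice(t), st.bw[l].hidden.slice(t));
      } else {
        outseq.slice(t) = st.fw[l].hidden.slice(t);
      }
    }
    if (training && dropout > 0.0 && drop_after.count((int)l + 1)) {
      cube m(size(outseq));
      const double keep = 1.0 - dropout;
      for (uword idx = 0; idx < m.n_elem; ++idx) {
        m(idx) = unif(rng) < keep ? 1.0 / keep : 0.0;
      }
      st.masks[l] = m;
      outseq %= m;
    }
    cur = outseq;
  }
  const uword Llast = L - 1;
  if (net.bidir) {
    st.dense_in = join_rows(st.fw[Llast].hidden.slice(T - 1),
                            st.bw[Llast].hidden.slice(0));
  } else {
    st.dense_in = st.fw[Llast].hidden.slice(T - 1);
  }
  st.probs = softmax_rows(st.dense_in * net.Wd +
                          repmat(net.bd, st.dense_in.n_rows, 1));
}

// [[Rcpp::export(name = ".rnn_forward")]]
arma::mat rnn_forward_cpp(Rcpp::List weights, arma::cube X,
                          Rcpp::IntegerVector units, bool bidirectional) {
  Net net = unpack(weights, units, bidirectional);
  ForwardState st;
  std::mt19937_64 rng(0);
  net_forward(net, X, false, 0.0, std::set<int>(), rng, st);
  return st.probs;
}

// Forward + loss + gradients for one minibatch.
// [[Rcpp::export(name = ".rnn_grad")]]
Rcpp::List rnn_grad_cpp(Rcpp::List weights, arma::cube X, arma::mat Y,
                        Rcpp::IntegerVector units, bool bidirectional,
                        double dropout, Rcpp::IntegerVector dropout_layers,
                        bool training, double seed) {
  Net net = unpack(weights, units, bidirectional);
  const uword L = net.layers.size();
  const uword B = X.n_rows, T = X.n_slices;

  std::set<int> drop_after(dropout_layers.begin(), dropout_layers.end());
  std::mt19937_64 rng((uint64_t)seed);
  ForwardState st;
  net_forward(net, X, training, dropout, drop_after, rng, st);

  const double eps = 1e-12;
  double loss = -accu(Y % log(st.probs + eps)) / (double)B;

  // dense read-out
  mat dlogits = (st.probs - Y) / (double)B;
  mat gWd = st.dense_in.t() * dlogits;
  rowvec gbd = sum(dlogits, 0);
  mat ddense = dlogits * net.Wd.t();

  Rcpp::List grads(weights.size());
  int gi = (int)weights.size() - 1;
  grads[gi--] = gbd;
  grads[gi--] = gWd;

  // gradient flowing into each layer's output
  cube dout;  // for sequence layers: B x width x T
  for (uword l = L; l-- > 0;) {
    const uword H = net.units[l];
    cube dH_f(B, H, T, fill::zeros), dH_b;
    if (net.bidir) dH_b.zeros(B, H, T);

    if (l == L - 1) {
      if (net.bidir) {
        dH_f.slice(T - 1) = ddense.cols(0, H - 1);
        dH_b.slice(0) = ddense.cols(H, 2 * H - 1);
      } else {
        dH_f.slice(T - 1) = ddense;
      }
    } else {
      // dout currently holds gradient on this layer's (masked) output seq
      if (st.masks[l].n_elem) dout %= st.masks[l];
      for (uword t = 0; t < T; ++t) {
        dH_f.slice(t) = dout.slice(t).cols(0, H - 1);
        if (net.bidir) dH_b.slice(t) = dout.slice(t).cols(H, 2 * H - 1);
      }
    }

    cube dXin(B, st.inputs[l].n_cols, T, fill::zeros);
    mat gWxf, gWhf, gWxb, gWhb;
    rowvec gbf, gbb;
    dir_backward(st.inputs[l], net.layers[l].Wxf, net.layers[l].Whf, false,
                 st.fw[l], dH_f, gWxf, gWhf, gbf, dXin);
    if (net.bidir) {
      dir_backward(st.inputs[l], net.layers[l].Wxb, net.layers[l].Whb, true,
                   st.bw[l], dH_b, gWxb, gWhb, gbb, dXin);
      grads[gi--] = gbb;
      grads[gi--] = gWhb;
      grads[gi--] = gWxb;
    }
    grads[gi--] = gbf;
    grads[gi--] = gWhf;
    grads[gi--] = gWxf;
    dout = dXin;
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("probs") = st.probs,
                            Rcpp::Named("grads") = grads);
}
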