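// Stacked LSTM forward pass and backpropagation through time.
//
// Weight layout (shared with the R side):
//   weights$layers[[l]] : list(W_i = 4H x in_l, W_h = 4H x H, b = 4H)
//     gate row blocks, in order: input (i), forget (f), cell (g), output (o)
//   weights$W_out : C x H,  weights$b_out : C
// A single bias vector per layer is used (not two as in some frameworks).
//
// Input tensor x is an L x F x n cube: slice s is sample s's padded
// control-point matrix (rows = time steps, cols = features).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct Weights {
  std::vector<mat> Wi, Wh;
  std::vector<vec> b;
  mat Wo;
  vec bo;
  int H() const { return Wh[0].n_cols; }
  int nlayers() const { return (int)Wi.size(); }
};

Weights unpack(const List& w) {
  Weights W;
  List layers = w["layers"];
  for (R_xlen_t l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    W.Wi.push_back(as<mat>(ly["W_i"]));
    W.Wh.push_back(as<mat>(ly["W_h"]));
    W.b.push_back(as<vec>(ly["b"]));
  }
  W.Wo = as<mat>(w["W_out"]);
  W.bo = as<vec>(w["b_out"]);
  return W;
}

inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Reorganize the cube into per-timestep F x n input matrices.
std::vector<mat> timestep_inputs(const cube& x) {
  const uword L = x.n_rows, F = x.n_cols, n = x.n_slices;
  std::vector<mat> X(L, mat(F, n));
  for (uword s = 0; s < n; ++s) {
    const mat& sl = x.slice(s);
    for (uword t = 0; t < L; ++t) X[t].col(s) = sl.row(t).t();
  }
  return X;
}

// Per-sample readout step (0-based): last padded step, or last real step.
uvec readout_steps(const ivec& lengths, uword L, uword n, bool length_aware) {
  uvec r(n);
  for (uword s = 0; s < n; ++s) {
    if (length_aware) {
      int len = lengths[s];
      if (len < 1 || (uword)len > L) stop("true length out of range");
      r[s] = (uword)(len - 1);
    } else {
      r[s] = L - 1;
    }
  }
  return r;
}

struct Caches {
  // per layer: H (H x n x L+1, slice t+1 = state after step t), C likewise,
  // gates (4H x n x L) post-nonlinearity, dropout masks between layers.
  std::vector<cube> Hs, Cs, G;
  std::vector<cube> mask;  // mask[l] applied to layer l's output (l < top)
};

// Forward through the stack; fills caches when keep != nullptr.
mat forward_core(const Weights& W, const std::vector<mat>& X, uword L, uword n,
                 const uvec& rstep, Caches* keep, double dropout,
                 std::mt19937* rng) {
  const int H = W.H(), NL = W.nlayers();
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<mat> layer_in;  // current layer's input at each t
  mat logits(W.Wo.n_rows, n);

  for (int l = 0; l < NL; ++l) {
    const std::vector<mat>& in = (l == 0) ? X : layer_in;
    mat h(H, n, fill::zeros), c(H, n, fill::zeros);
    std::vector<mat> out(L);
    if (keep) {
      keep->Hs.emplace_back(H, n, L + 1);
      keep->Cs.emplace_back(H, n, L + 1);
      keep->G.emplace_back(4 * H, n, L);
      keep->Hs[l].slice(0).zeros();
      keep->Cs[l].slice(0).zeros();
    }
    for (uword t = 0; t < L; ++t) {
      mat z = W.Wi[l] * in[t] + W.Wh[l] * h;
      z.each_col() += W.b[l];
      mat gi = sigm(z.rows(0, H - 1));
      mat gf = sigm(z.rows(H, 2 * H - 1));
      mat gg = tanh(z.rows(2 * H, 3 * H - 1));
      mat go = sigm(z.rows(3 * H, 4 * H - 1));
      c = gf % c + gi % gg;
      h = go % tanh(c);
      if (keep) {
        keep->G[l].slice(t) = join_cols(join_cols(gi, gf), join_cols(gg, go));
        keep->Hs[l].slice(t + 1) = h;
        keep->Cs[l].slice(t + 1) = c;
      }
      out[t] = h;
    }
    if (l < NL - 1 && dropout > 0.0 && rng) {
      // inverted dropout on the layer's output fed upward (training only)
      cube m(H, n, L);
      for (uword t = 0; t < L; ++t)
        for (uword j = 0; j < (uword)H; ++j)
          for (uword s = 0; s < n; ++s)
            m(j, s, t) = (unif(*rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      for (uword t = 0; t < L; ++t) out[t] %= m.slice(t);
      if (keep) keep->mask.push_back(m);
    } else if (keep && l < NL - 1) {
      keep->mask.push_back(cube());  // no dropout applied
    }
    layer_in = out;
  }
  // readout from the top layer at each sample's readout step
  const std::vector<mat>& top = layer_in;
  mat hr(H, n);
  for (uword s = 0; s < n; ++s) hr.col(s) = top[rstep[s]].col(s);
  logits = W.Wo * hr;
  logits.each_col() += W.bo;
  return logits;
}

}  // namespace

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(List weights, arma::cube x, arma::ivec lengths,
                           bool length_aware) {
  Weights W = unpack(weights);
  const uword L = x.n_rows, n = x.n_slices;
  if ((int)x.n_cols != (int)W.Wi[0].n_cols)
    stop("feature width %d does not match model input size %d", (int)x.n_cols,
         (int)W.Wi[0].n_cols);
  std::vector<mat> X = timestep_inputs(x);
  uvec rstep = readout_steps(lengths, L, n, length_aware);
  mat logits = forward_core(W, X, L, n, rstep, nullptr, 0.0, nullptr);
  return logits.t();  // n x C
}

// [[Rcpp::export]]
List lstm_grad_cpp(List weights, arma::cube x, arma::ivec y,
                   arma::ivec lengths, bool length_aware, double dropout,
                   int dropout_seed) {
  Weights W = unpack(weights);
  const uword L = x.n_rows, n = x.n_slices;
  const int H = W.H(), NL = W.nlayers(), C = W.Wo.n_rows;
  if ((int)x.n_cols != (int)W.Wi[0].n_cols)
    stop("feature width %d does not match model input size %d", (int)x.n_cols,
         (int)W.Wi[0].n_cols);
  if (y.n_elem != n) stop("label/sample count mismatch");

  std::vector<mat> X = timestep_inputs(x);
  uvec rstep = readout_steps(lengths, L, n, length_aware);
  Caches K;
  std::mt19937 rng((unsigned)dropout_seed);
  mat logits = forward_core(W, X, L, n, rstep, &K, dropout,
                            dropout > 0.0 ? &rng : nullptr);

  // softmax cross-entropy, mean over the batch
  mat p = logits;
  p.each_row() -= max(p, 0);
  p = exp(p);
  p.each_row() /= sum(p, 0);
  double loss = 0.0;
  mat dlogits = p;
  for (uword s = 0; s < n; ++s) {
    int cls = y[s];
    if (cls < 0 || cls >= C) stop("class index out of range");
    loss -= std::log(std::max(p(cls, s), 1e-300));
    dlogits(cls, s) -= 1.0;
  }
  loss /= (double)n;
  dlogits /= (double)n;

  // head gradients
  mat hr(H, n);
  for (uword s = 0; s < n; ++s) hr.col(s) = K.Hs[NL - 1].slice(rstep[s] + 1).col(s);
  mat dWo = dlogits * hr.t();
  vec dbo = sum(dlogits, 1);

  std::vector<mat> dWi(NL), dWh(NL);
  std::vector<vec> db(NL);
  for (int l = 0; l < NL; ++l) {
    dWi[l] = mat(size(W.Wi[l]), fill::zeros);
    dWh[l] = mat(size(W.Wh[l]), fill::zeros);
    db[l] = vec(4 * H, fill::zeros);
  }

  // dOut[t]: gradient w.r.t. the (post-dropout) output of the layer above's
  // input at step t; for the top layer it holds only the readout injection.
  cube dOut(H, n, L, fill::zeros);
  for (uword s = 0; s < n; ++s)
    dOut.slice(rstep[s]).col(s) += W.Wo.t() * dlogits.col(s);

  for (int l = NL - 1; l >= 0; --l) {
    // dropout mask between layer l and l+1 was applied to layer l's output;
    // for the layer currently receiving dOut (layer l), the mask index is l.
    if (l < NL - 1 && K.mask[l].n_elem > 0) {
      for (uword t = 0; t < L; ++t) dOut.slice(t) %= K.mask[l].slice(t);
    }
    mat dh_next(H, n, fill::zeros), dc_next(H, n, fill::zeros);
    cube dIn;
    if (l > 0) dIn.set_size(W.Wi[l].n_cols, n, L);
    for (int t = (int)L - 1; t >= 0; --t) {
      mat dh = dOut.slice(t) + dh_next;
      const mat& g = K.G[l].slice(t);
      mat gi = g.rows(0, H - 1), gf = g.rows(H, 2 * H - 1),
          gg = g.rows(2 * H, 3 * H - 1), go = g.rows(3 * H, 4 * H - 1);
      mat tc = tanh(K.Cs[l].slice(t + 1));
      mat dgo = dh % tc % go % (1.0 - go);
      mat dc = dc_next + dh % go % (1.0 - tc % tc);
      mat dgi = dc % gg % gi % (1.0 - gi);
      mat dgf = dc % K.Cs[l].slice(t) % gf % (1.0 - gf);
      mat dgg = dc % gi % (1.0 - gg % gg);
      dc_next = dc % gf;
      mat dz = join_cols(join_cols(dgi, dgf), join_cols(dgg, dgo));
      mat in_t = (l == 0) ? X[t] : K.Hs[l - 1].slice(t + 1);
      if (l > 0 && K.mask[l - 1].n_elem > 0) in_t %= K.mask[l - 1].slice(t);
      dWi[l] += dz * in_t.t();
      dWh[l] += dz * K.Hs[l].slice(t).t();
      db[l] += sum(dz, 1);
      dh_next = W.Wh[l].t() * dz;
      if (l > 0) dIn.slice(t) = W.Wi[l].t() * dz;
    }
    if (l > 0) dOut = dIn;  // becomes dh injection for the layer below
  }

  List glayers(NL);
  for (int l = 0; l < NL; ++l)
    glayers[l] = List::create(_["W_i"] = dWi[l], _["W_h"] = dWh[l],
                              _["b"] = db[l]);
  List grads =
      List::create(_["layers"] = glayers, _["W_out"] = dWo, _["b_out"] = dbo);
  return List::create(_["loss"] = loss, _["logits"] = logits.t(),
                      _["grads"] = grads);
}
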