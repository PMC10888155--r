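// Network core for the dual-kernel residual CNN: batched forward pass,
// gradient backpropagation with Adam updates, and DeepLIFT (Rescale rule)
// multiplier backpropagation.  Sequences are one-hot 4xL matrices; a batch
// of B sequences is laid out as a single 4x(B*G) matrix with G = L + gap
// columns per sample, the trailing `gap` columns held at zero.  The zero
// gap is at least as wide as the largest kernel, so a "same"-padded
// convolution over the whole concatenated matrix reads only zeros across
// sample boundaries and one shifted GEMM per kernel tap implements the
// convolution without materialising an im2col matrix.
//
// Architecture (two branches with kernel sizes ka, kb; C channels):
//   Z1 = conv_k(X)            A1 = relu(Z1)
//   Z2 = conv_k(A1) + proj(X) A2 = relu(Z2)   (width-1 projection skip)
//   g  = global average pool over positions   (C per branch)
//   h  = [g_a ; g_b]          A3 = relu(W3 h + b3)
//   O  = W4 A3 + b4           (two logits: o1 constitutive, o2 gained)
// Convolution output position j reads input positions j - (k-1)/2 ..
// j + k/2, so lengths are preserved and the residual addition is
// shape-compatible for any L.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct Net {
  mat W1a, W2a, Wpa, W1b, W2b, Wpb, W3, W4;
  vec b1a, b2a, b1b, b2b, b3, b4;
  int ka, kb, C, H;
};

static Net unpack(const List& p) {
  Net n;
  n.W1a = as<mat>(p["W1a"]); n.b1a = as<vec>(p["b1a"]);
  n.W2a = as<mat>(p["W2a"]); n.b2a = as<vec>(p["b2a"]);
  n.Wpa = as<mat>(p["Wpa"]);
  n.W1b = as<mat>(p["W1b"]); n.b1b = as<vec>(p["b1b"]);
  n.W2b = as<mat>(p["W2b"]); n.b2b = as<vec>(p["b2b"]);
  n.Wpb = as<mat>(p["Wpb"]);
  n.W3  = as<mat>(p["W3"]);  n.b3  = as<vec>(p["b3"]);
  n.W4  = as<mat>(p["W4"]);  n.b4  = as<vec>(p["b4"]);
  n.ka = (int)(n.W1a.n_cols / 4);
  n.kb = (int)(n.W1b.n_cols / 4);
  n.C  = (int)n.W1a.n_rows;
  n.H  = (int)n.W3.n_rows;
  return n;
}

static List pack(const Net& n) {
  return List::create(
    _["W1a"] = n.W1a, _["b1a"] = n.b1a, _["W2a"] = n.W2a, _["b2a"] = n.b2a,
    _["Wpa"] = n.Wpa,
    _["W1b"] = n.W1b, _["b1b"] = n.b1b, _["W2b"] = n.W2b, _["b2b"] = n.b2b,
    _["Wpb"] = n.Wpb,
    _["W3"] = n.W3, _["b3"] = n.b3, _["W4"] = n.W4, _["b4"] = n.b4);
}

static void zero_gaps(mat& Z, int B, int L, int G) {
  if (G == L) return;
  for (int b = 0; b < B; ++b)
    Z.cols((uword)b * G + L, (uword)b * G + G - 1).zeros();
}

// Same-padded 1-D convolution as one shifted GEMM per kernel tap.
static void conv_fwd(const mat& X, const mat& W, const vec& b, int k,
                     int B, int L, int G, mat& Z) {
  const int Cin = (int)X.n_rows;
  const uword N = X.n_cols;
  const int pad = (k - 1) / 2;
  Z.zeros(W.n_rows, N);
  for (int t = 0; t < k; ++t) {
    const int s = t - pad;
    const uword j0 = s < 0 ? (uword)(-s) : 0;
    const uword j1 = s > 0 ? N - 1 - s : N - 1;
    Z.cols(j0, j1) += W.cols(t * Cin, (t + 1) * Cin - 1) *
                      X.cols(j0 + s, j1 + s);
  }
  Z.each_col() += b;
  zero_gaps(Z, B, L, G);
}

// Gradient of the convolution with respect to its weights and bias.
static void conv_dW(const mat& X, const mat& dZ, int k, mat& dW, vec& db) {
  const int Cin = (int)X.n_rows;
  const uword N = X.n_cols;
  const int pad = (k - 1) / 2;
  dW.set_size(dZ.n_rows, Cin * k);
  for (int t = 0; t < k; ++t) {
    const int s = t - pad;
    const uword j0 = s < 0 ? (uword)(-s) : 0;
    const uword j1 = s > 0 ? N - 1 - s : N - 1;
    dW.cols(t * Cin, (t + 1) * Cin - 1) =
      dZ.cols(j0, j1) * X.cols(j0 + s, j1 + s).t();
  }
  db = sum(dZ, 1);
}

// Transposed convolution: gradients (or DeepLIFT multipliers) with respect
// to the convolution input.
static mat conv_dX(const mat& dZ, const mat& W, int k, int Cin) {
  const uword N = dZ.n_cols;
  const int pad = (k - 1) / 2;
  mat dX(Cin, N, fill::zeros);
  for (int t = 0; t < k; ++t) {
    const int s = t - pad;
    const uword j0 = s < 0 ? (uword)(-s) : 0;
    const uword j1 = s > 0 ? N - 1 - s : N - 1;
    dX.cols(j0 + s, j1 + s) += W.cols(t * Cin, (t + 1) * Cin - 1).t() *
                               dZ.cols(j0, j1);
  }
  return dX;
}

static mat relu(const mat& z) {
  mat a = z;
  a.elem(find(a < 0)).zeros();
  return a;
}

struct BranchCache {
  mat Z1, A1, Z2, A2;
};

static void branch_forward(const mat& X, const mat& W1, const vec& b1,
                           const mat& W2, const vec& b2, const mat& Wp,
                           int k, int B, int L, int G, BranchCache& c,
                           mat& g) {
  conv_fwd(X, W1, b1, k, B, L, G, c.Z1);
  c.A1 = relu(c.Z1);
  conv_fwd(c.A1, W2, b2, k, B, L, G, c.Z2);
  c.Z2 += Wp * X;  // width-1 projection skip; zero at gap columns
  c.A2 = relu(c.Z2);
  const int C = (int)W1.n_rows;
  g.set_size(C, B);
  for (int b = 0; b < B; ++b)
    g.col(b) = mean(c.A2.cols((uword)b * G, (uword)b * G + L - 1), 1);
}

struct HeadCache {
  mat ga, gb, h, Z3, A3, O;
};

static void full_forward(const Net& n, const mat& X, int B, int L, int G,
                         BranchCache& ca, BranchCache& cb, HeadCache& hc) {
  branch_forward(X, n.W1a, n.b1a, n.W2a, n.b2a, n.Wpa, n.ka, B, L, G, ca,
                 hc.ga);
  branch_forward(X, n.W1b, n.b1b, n.W2b, n.b2b, n.Wpb, n.kb, B, L, G, cb,
                 hc.gb);
  hc.h = join_cols(hc.ga, hc.gb);
  hc.Z3 = n.W3 * hc.h;
  hc.Z3.each_col() += n.b3;
  hc.A3 = relu(hc.Z3);
  hc.O = n.W4 * hc.A3;
  hc.O.each_col() += n.b4;
}

// Weighted binary cross-entropy of the softmax head; fills the gradient at
// the logits (softmax minus one-hot, weight-normalised over the batch).
static double softmax_bce(const mat& O, const vec& yb, const vec& wb,
                          mat& dO) {
  const int B = (int)O.n_cols;
  dO.set_size(2, B);
  const double sw = accu(wb);
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    const double m = std::max(O(0, b), O(1, b));
    const double e0 = std::exp(O(0, b) - m), e1 = std::exp(O(1, b) - m);
    const double p = e1 / (e0 + e1);
    const double pc = std::min(std::max(p, 1e-7), 1.0 - 1e-7);
    const double y = yb(b);
    loss += wb(b) * (-(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc)));
    dO(0, b) = wb(b) * ((1.0 - p) - (1.0 - y)) / sw;
    dO(1, b) = wb(b) * (p - y) / sw;
  }
  return loss / sw;
}

struct BranchGrads {
  mat dW1, dW2, dWp;
  vec db1, db2;
};

static void branch_backward(const mat& X, const mat& W2, const mat& dg,
                            const BranchCache& c, int k, int B, int L,
                            int G, BranchGrads& g) {
  const int C = (int)dg.n_rows;
  mat dA2(C, X.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b)
    dA2.cols((uword)b * G, (uword)b * G + L - 1) =
      repmat(dg.col(b) / (double)L, 1, L);
  mat dZ2 = dA2;
  dZ2.elem(find(c.Z2 <= 0)).zeros();
  conv_dW(c.A1, dZ2, k, g.dW2, g.db2);
  g.dWp = dZ2 * X.t();
  mat dA1 = conv_dX(dZ2, W2, k, C);
  mat dZ1 = dA1;
  dZ1.elem(find(c.Z1 <= 0)).zeros();  // gap columns have Z1 == 0: masked out
  conv_dW(X, dZ1, k, g.dW1, g.db1);
}

// Adam with decoupled weight decay (applied to weights, not biases).
template <typename T>
static void adam_step(T& w, T& m, T& v, const T& g, double lr, double b1,
                      double b2, double eps, double t, double wd) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * square(g);
  T mhat = m / (1.0 - std::pow(b1, t));
  T vhat = v / (1.0 - std::pow(b2, t));
  if (wd > 0) w -= lr * wd * w;
  w -= lr * mhat / (sqrt(vhat) + eps);
}

struct Moments {
  mat W1a, W2a, Wpa, W1b, W2b, Wpb, W3, W4;
  vec b1a, b2a, b1b, b2b, b3, b4;
};

static Moments unpack_mom(const List& p) {
  Moments n;
  n.W1a = as<mat>(p["W1a"]); n.b1a = as<vec>(p["b1a"]);
  n.W2a = as<mat>(p["W2a"]); n.b2a = as<vec>(p["b2a"]);
  n.Wpa = as<mat>(p["Wpa"]);
  n.W1b = as<mat>(p["W1b"]); n.b1b = as<vec>(p["b1b"]);
  n.W2b = as<mat>(p["W2b"]); n.b2b = as<vec>(p["b2b"]);
  n.Wpb = as<mat>(p["Wpb"]);
  n.W3 = as<mat>(p["W3"]); n.b3 = as<vec>(p["b3"]);
  n.W4 = as<mat>(p["W4"]); n.b4 = as<vec>(p["b4"]);
  return n;
}

static List pack_mom(const Moments& n) {
  return List::create(
    _["W1a"] = n.W1a, _["b1a"] = n.b1a, _["W2a"] = n.W2a, _["b2a"] = n.b2a,
    _["Wpa"] = n.Wpa,
    _["W1b"] = n.W1b, _["b1b"] = n.b1b, _["W2b"] = n.W2b, _["b2b"] = n.b2b,
    _["Wpb"] = n.Wpb,
    _["W3"] = n.W3, _["b3"] = n.b3, _["W4"] = n.W4, _["b4"] = n.b4);
}

static int gap_of(const Net& n) {
  return std::max(n.ka, n.kb);
}

// Copy cube slices into the padded concatenated batch layout.
static mat make_batch(const arma::cube& X, const int* idx, int B, int L,
                      int G) {
  mat Xb(4, (uword)B * G, fill::zeros);
  for (int j = 0; j < B; ++j)
    Xb.cols((uword)j * G, (uword)j * G + L - 1) = X.slice(idx[j]);
  return Xb;
}

// One training epoch over the supplied batches.  `batches` is a list of
// 1-based index vectors into the slices of X; `wts` are per-sample loss
// weights.  Returns updated parameters, Adam moments, step counter and the
// weight-averaged epoch loss.
// [[Rcpp::export]]
List cpp_train_epoch(List params, List adam_m, List adam_v, int adam_t,
                     const arma::cube& X, const arma::vec& y,
                     const arma::vec& wts, List batches, double lr,
                     double beta1, double beta2, double eps,
                     double weight_decay = 0.0) {
  Net net = unpack(params);
  Moments M = unpack_mom(adam_m);
  Moments V = unpack_mom(adam_v);
  const int L = (int)X.n_cols;
  const int G = L + gap_of(net);
  double loss_sum = 0.0, w_sum = 0.0;
  int t = adam_t;

  for (int bi = 0; bi < batches.size(); ++bi) {
    IntegerVector idx = batches[bi];
    const int B = idx.size();
    std::vector<int> id0(B);
    vec yb(B), wb(B);
    for (int j = 0; j < B; ++j) {
      id0[j] = idx[j] - 1;
      yb(j) = y(id0[j]);
      wb(j) = wts(id0[j]);
    }
    mat Xb = make_batch(X, id0.data(), B, L, G);

    BranchCache ca, cb;
    HeadCache hc;
    full_forward(net, Xb, B, L, G, ca, cb, hc);

    mat dO;
    const double loss = softmax_bce(hc.O, yb, wb, dO);
    loss_sum += loss * accu(wb);
    w_sum += accu(wb);

    // head backward
    mat dA3 = net.W4.t() * dO;
    mat dZ3 = dA3;
    dZ3.elem(find(hc.Z3 <= 0)).zeros();
    mat dW4 = dO * hc.A3.t();
    vec db4 = sum(dO, 1);
    mat dW3 = dZ3 * hc.h.t();
    vec db3 = sum(dZ3, 1);
    mat dh = net.W3.t() * dZ3;
    mat dga = dh.rows(0, net.C - 1);
    mat dgb = dh.rows(net.C, 2 * net.C - 1);

    BranchGrads gA, gB;
    branch_backward(Xb, net.W2a, dga, ca, net.ka, B, L, G, gA);
    branch_backward(Xb, net.W2b, dgb, cb, net.kb, B, L, G, gB);

    t += 1;
    const double tt = (double)t;
    const double wd = weight_decay;
    adam_step(net.W1a, M.W1a, V.W1a, gA.dW1, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.b1a, M.b1a, V.b1a, gA.db1, lr, beta1, beta2, eps, tt, 0.0);
    adam_step(net.W2a, M.W2a, V.W2a, gA.dW2, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.b2a, M.b2a, V.b2a, gA.db2, lr, beta1, beta2, eps, tt, 0.0);
    adam_step(net.Wpa, M.Wpa, V.Wpa, gA.dWp, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.W1b, M.W1b, V.W1b, gB.dW1, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.b1b, M.b1b, V.b1b, gB.db1, lr, beta1, beta2, eps, tt, 0.0);
    adam_step(net.W2b, M.W2b, V.W2b, gB.dW2, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.b2b, M.b2b, V.b2b, gB.db2, lr, beta1, beta2, eps, tt, 0.0);
    adam_step(net.Wpb, M.Wpb, V.Wpb, gB.dWp, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.W3, M.W3, V.W3, dW3, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.b3, M.b3, V.b3, db3, lr, beta1, beta2, eps, tt, 0.0);
    adam_step(net.W4, M.W4, V.W4, dW4, lr, beta1, beta2, eps, tt, wd);
    adam_step(net.b4, M.b4, V.b4, db4, lr, beta1, beta2, eps, tt, 0.0);
  }

  return List::create(_["params"] = pack(net), _["m"] = pack_mom(M),
                      _["v"] = pack_mom(V), _["t"] = t,
                      _["loss"] = loss_sum / std::max(w_sum, 1e-12));
}

// Loss and parameter gradients for one batch (no update); used to verify
// the backward pass against finite differences.
// [[Rcpp::export]]
List cpp_loss_grads(List params, const arma::cube& X, const arma::vec& y,
                    const arma::vec& wts) {
  Net net = unpack(params);
  const int L = (int)X.n_cols;
  const int B = (int)X.n_slices;
  const int G = L + gap_of(net);
  std::vector<int> id0(B);
  for (int j = 0; j < B; ++j) id0[j] = j;
  mat Xb = make_batch(X, id0.data(), B, L, G);
  vec yb(B), wb(B);
  for (int j = 0; j < B; ++j) { yb(j) = y(j); wb(j) = wts(j); }
  BranchCache ca, cb;
  HeadCache hc;
  full_forward(net, Xb, B, L, G, ca, cb, hc);
  mat dO;
  const double loss = softmax_bce(hc.O, yb, wb, dO);
  mat dA3 = net.W4.t() * dO;
  mat dZ3 = dA3;
  dZ3.elem(find(hc.Z3 <= 0)).zeros();
  mat dW4 = dO * hc.A3.t();
  vec db4 = sum(dO, 1);
  mat dW3 = dZ3 * hc.h.t();
  vec db3 = sum(dZ3, 1);
  mat dh = net.W3.t() * dZ3;
  BranchGrads gA, gB;
  branch_backward(Xb, net.W2a, dh.rows(0, net.C - 1), ca, net.ka, B, L, G,
                  gA);
  branch_backward(Xb, net.W2b, dh.rows(net.C, 2 * net.C - 1), cb, net.kb,
                  B, L, G, gB);
  List grads = List::create(
    _["W1a"] = gA.dW1, _["b1a"] = gA.db1, _["W2a"] = gA.dW2,
    _["b2a"] = gA.db2, _["Wpa"] = gA.dWp,
    _["W1b"] = gB.dW1, _["b1b"] = gB.db1, _["W2b"] = gB.dW2,
    _["b2b"] = gB.db2, _["Wpb"] = gB.dWp,
    _["W3"] = dW3, _["b3"] = db3, _["W4"] = dW4, _["b4"] = db4);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// Logits for every slice of X, computed in chunks.  Returns an n x 2
// matrix with columns (o1, o2).
// [[Rcpp::export]]
arma::mat cpp_forward_logits(List params, const arma::cube& X,
                             int chunk = 64) {
  Net net = unpack(params);
  const int L = (int)X.n_cols;
  const int n = (int)X.n_slices;
  const int G = L + gap_of(net);
  mat out(n, 2);
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int B = std::min(chunk, n - s0);
    std::vector<int> id0(B);
    for (int j = 0; j < B; ++j) id0[j] = s0 + j;
    mat Xb = make_batch(X, id0.data(), B, L, G);
    BranchCache ca, cb;
    HeadCache hc;
    full_forward(net, Xb, B, L, G, ca, cb, hc);
    out.rows(s0, s0 + B - 1) = hc.O.t();
  }
  return out;
}

// Rescale-rule multiplier for an elementwise ReLU: delta-activation over
// delta-pre-activation, falling back to the reference-point gradient when
// the pre-activation difference is below `thr`.
static mat rescale(const mat& zx, const mat& zr, double thr) {
  mat r(arma::size(zx));
  for (uword i = 0; i < zx.n_elem; ++i) {
    const double dz = zx(i) - zr(i);
    if (std::fabs(dz) < thr)
      r(i) = zr(i) > 0 ? 1.0 : 0.0;
    else
      r(i) = (std::max(zx(i), 0.0) - std::max(zr(i), 0.0)) / dz;
  }
  return r;
}

static mat branch_multipliers(const mat& mg, const BranchCache& cx,
                              const BranchCache& cr, const mat& W1,
                              const mat& W2, const mat& Wp, int k, int L,
                              int G, double thr) {
  const int C = (int)mg.n_rows;
  mat mA2(C, (uword)G, fill::zeros);
  mA2.cols(0, L - 1) = repmat(mg / (double)L, 1, L);
  mat mZ2 = mA2 % rescale(cx.Z2, cr.Z2, thr);
  mat mA1 = conv_dX(mZ2, W2, k, C);
  mat mXp = Wp.t() * mZ2;
  mat mZ1 = mA1 % rescale(cx.Z1, cr.Z1, thr);
  return conv_dX(mZ1, W1, k, 4) + mXp;
}

// DeepLIFT (Rescale) contributions of one input relative to a reference,
// targeting logit `target_index` (1 = o1 constitutive, 2 = o2 gained).
// Linear layers (convolutions, projections, pooling, dense) pass
// multipliers through their transposed linear maps; ReLUs use the Rescale
// rule; the residual addition routes multipliers into both summands.
// [[Rcpp::export]]
List cpp_deeplift(List params, const arma::mat& x, const arma::mat& ref,
                  int target_index = 2, double thr = 1e-7) {
  Net net = unpack(params);
  const int L = (int)x.n_cols;
  const int G = L + gap_of(net);
  mat xp(4, (uword)G, fill::zeros), rp(4, (uword)G, fill::zeros);
  xp.cols(0, L - 1) = x;
  rp.cols(0, L - 1) = ref;
  BranchCache cax, cbx, car, cbr;
  HeadCache hx, hr;
  full_forward(net, xp, 1, L, G, cax, cbx, hx);
  full_forward(net, rp, 1, L, G, car, cbr, hr);

  mat mO(2, 1, fill::zeros);
  mO(target_index - 1, 0) = 1.0;
  mat mA3 = net.W4.t() * mO;
  mat mZ3 = mA3 % rescale(hx.Z3, hr.Z3, thr);
  mat mh = net.W3.t() * mZ3;
  mat mga = mh.rows(0, net.C - 1);
  mat mgb = mh.rows(net.C, 2 * net.C - 1);

  mat mXa = branch_multipliers(mga, cax, car, net.W1a, net.W2a, net.Wpa,
                               net.ka, L, G, thr);
  mat mXb = branch_multipliers(mgb, cbx, cbr, net.W1b, net.W2b, net.Wpb,
                               net.kb, L, G, thr);
  mat contrib = (mXa.cols(0, L - 1) + mXb.cols(0, L - 1)) % (x - ref);

  return List::create(
    _["channel_scores"] = contrib,
    _["o_input"] = NumericVector::create(hx.O(0, 0), hx.O(1, 0)),
    _["o_reference"] = NumericVector::create(hr.O(0, 0), hr.O(1, 0)));
}
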