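// Full forward/backward core of the 1-D UNet.
//
// One .Call runs an entire minibatch step (forward, batch-level soft Dice
// loss, backward), so every activation cache lives and dies inside C++.
// Feature maps are (channels x positions) matrices, columns sample-major
// (sample i occupies columns [i*l, (i+1)*l)).
//
// Parameters arrive as a flat, unnamed list in canonical order (see
// flat_params() on the R side):
//   for each encoder level:  c1.W c1.b bn1.gamma bn1.beta bn1.rm bn1.rv
//                            c2.W c2.b bn2.gamma bn2.beta bn2.rm bn2.rv
//   bottleneck:              same 12 slots
//   for each decoder level (deepest first):
//                            up.W1 up.W2 up.b  + the same 12 conv/bn slots
//   head:                    W b
// The return mirrors the order: gradients for weight slots, refreshed
// running statistics for the rm/rv slots.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct ConvBN {
  mat W; vec b, gamma, beta, rm, rv;
};

struct Up {
  mat W1, W2; vec b;
};

struct Reader {
  const List& L; int i = 0;
  explicit Reader(const List& l) : L(l) {}
  mat m() { return as<mat>(L[i++]); }
  vec v() { return as<vec>(L[i++]); }
};

ConvBN read_convbn(Reader& r) {
  ConvBN c;
  c.W = r.m(); c.b = r.v(); c.gamma = r.v(); c.beta = r.v();
  c.rm = r.v(); c.rv = r.v();
  return c;
}

struct BlockCache {
  mat X;            // block input
  arma::Mat<unsigned char> pos;
  mat xhat;
  vec inv;
};

const double BN_EPS = 1e-5;
const double BN_MOM = 0.9;

// Same-padding convolution as k shifted channel-mixing GEMMs.
mat conv_sp(const mat& X, const mat& W, const vec& b, int n, int l) {
  const int c_in = X.n_rows;
  const int k = W.n_cols / c_in;
  const int p = (k - 1) / 2;
  mat R(W.n_rows, n * l);
  R.each_col() = b;
  for (int j = 0; j < k; ++j) {
    const mat T = W.cols(j * c_in, (j + 1) * c_in - 1) * X;
    const int sh = j - p;
    const int t0 = std::max(0, -sh);
    const int t1 = l - 1 - std::max(0, sh);
    if (t1 < t0) continue;
    for (int s = 0; s < n; ++s)
      R.cols(s * l + t0, s * l + t1) +=
          T.cols(s * l + t0 + sh, s * l + t1 + sh);
  }
  return R;
}

// conv -> ReLU -> BN forward; fills cache when keep_cache.
mat block_fwd(const mat& X, ConvBN& P, bool training, bool keep_cache,
              BlockCache* cache, int n, int l) {
  mat R = conv_sp(X, P.W, P.b, n, l);
  arma::Mat<unsigned char> pos(R.n_rows, R.n_cols);
  {
    const double* rp = R.memptr();
    unsigned char* pp = pos.memptr();
    const arma::uword nn = R.n_elem;
    double* rw = R.memptr();
    for (arma::uword q = 0; q < nn; ++q) {
      const bool on = rp[q] > 0.0;
      pp[q] = on;
      if (!on) rw[q] = 0.0;
    }
  }
  vec inv;
  if (training) {
    vec mu = arma::mean(R, 1);
    R.each_col() -= mu;
    vec v = arma::mean(arma::square(R), 1);
    inv = 1.0 / arma::sqrt(v + BN_EPS);
    R.each_col() %= inv;                       // R is now xhat
    P.rm = BN_MOM * P.rm + (1 - BN_MOM) * mu;  // refreshed running stats
    P.rv = BN_MOM * P.rv + (1 - BN_MOM) * v;
  } else {
    inv = 1.0 / arma::sqrt(P.rv + BN_EPS);
    R.each_col() -= P.rm;
    R.each_col() %= inv;
  }
  mat Y = R.each_col() % P.gamma;
  Y.each_col() += P.beta;
  if (keep_cache) {
    cache->X = X;
    cache->pos = std::move(pos);
    cache->xhat = std::move(R);
    cache->inv = std::move(inv);
  }
  return Y;
}

// Backward through conv -> ReLU -> BN.  Returns dX; appends gradients.
mat block_bwd(const mat& dY, const BlockCache& C, const ConvBN& P,
              int n, int l, List& out, int base) {
  vec dgamma = arma::sum(dY % C.xhat, 1);
  vec dbeta = arma::sum(dY, 1);
  mat dR = dY.each_col() % P.gamma;
  vec m1 = arma::mean(dR, 1);
  vec m2 = arma::mean(dR % C.xhat, 1);
  dR.each_col() -= m1;
  dR -= C.xhat.each_col() % m2;
  dR.each_col() %= C.inv;
  {
    double* dp = dR.memptr();
    const unsigned char* pp = C.pos.memptr();
    for (arma::uword q = 0; q < dR.n_elem; ++q)
      if (!pp[q]) dp[q] = 0.0;
  }
  const int c_in = C.X.n_rows;
  const int k = P.W.n_cols / c_in;
  const int p = (k - 1) / 2;
  mat dW(P.W.n_rows, P.W.n_cols, arma::fill::zeros);
  mat dX(c_in, n * l, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int sh = j - p;
    const int t0 = std::max(0, -sh);
    const int t1 = l - 1 - std::max(0, sh);
    if (t1 < t0) continue;
    mat dWj(P.W.n_rows, c_in, arma::fill::zeros);
    const mat U = P.W.cols(j * c_in, (j + 1) * c_in - 1).t() * dR;
    for (int s = 0; s < n; ++s) {
      dWj += dR.cols(s * l + t0, s * l + t1) *
             C.X.cols(s * l + t0 + sh, s * l + t1 + sh).t();
      dX.cols(s * l + t0 + sh, s * l + t1 + sh) +=
          U.cols(s * l + t0, s * l + t1);
    }
    dW.cols(j * c_in, (j + 1) * c_in - 1) = dWj;
  }
  out[base + 0] = dW;
  out[base + 1] = wrap(vec(arma::sum(dR, 1)));
  out[base + 2] = wrap(dgamma);
  out[base + 3] = wrap(dbeta);
  out[base + 4] = wrap(P.rm);   // refreshed running stats (from forward)
  out[base + 5] = wrap(P.rv);
  return dX;
}

mat pool2(const mat& X, arma::Mat<unsigned char>& keepA, int n, int l) {
  const int c = X.n_rows, half = l / 2;
  mat Y(c, n * half);
  keepA.set_size(c, n * half);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < half; ++t) {
      const double* a = X.colptr(s * l + 2 * t);
      const double* b2 = X.colptr(s * l + 2 * t + 1);
      double* y = Y.colptr(s * half + t);
      unsigned char* m = keepA.colptr(s * half + t);
      for (int ch = 0; ch < c; ++ch) {
        const bool left = a[ch] >= b2[ch];
        m[ch] = left;
        y[ch] = left ? a[ch] : b2[ch];
      }
    }
  return Y;
}

mat pool2_bwd(const mat& dY, const arma::Mat<unsigned char>& keepA,
              int n, int l) {
  const int c = dY.n_rows, half = l / 2;
  mat dX(c, n * l, arma::fill::zeros);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < half; ++t) {
      const double* g = dY.colptr(s * half + t);
      const unsigned char* m = keepA.colptr(s * half + t);
      double* a = dX.colptr(s * l + 2 * t);
      double* b2 = dX.colptr(s * l + 2 * t + 1);
      for (int ch = 0; ch < c; ++ch)
        (m[ch] ? a : b2)[ch] = g[ch];
    }
  return dX;
}

mat upconv2(const mat& X, const Up& P, int n, int l) {
  mat Y1 = P.W1 * X;
  mat Y2 = P.W2 * X;
  const int c = Y1.n_rows;
  mat Y(c, n * 2 * l);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < l; ++t) {
      std::memcpy(Y.colptr(s * 2 * l + 2 * t), Y1.colptr(s * l + t),
                  c * sizeof(double));
      std::memcpy(Y.colptr(s * 2 * l + 2 * t + 1), Y2.colptr(s * l + t),
                  c * sizeof(double));
    }
  Y.each_col() += P.b;
  return Y;
}

mat upconv2_bwd(const mat& dY, const mat& X, const Up& P, int n, int l,
                List& out, int base) {
  const int c = dY.n_rows;
  mat dY1(c, n * l), dY2(c, n * l);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < l; ++t) {
      std::memcpy(dY1.colptr(s * l + t), dY.colptr(s * 2 * l + 2 * t),
                  c * sizeof(double));
      std::memcpy(dY2.colptr(s * l + t), dY.colptr(s * 2 * l + 2 * t + 1),
                  c * sizeof(double));
    }
  out[base + 0] = wrap(mat(dY1 * X.t()));
  out[base + 1] = wrap(mat(dY2 * X.t()));
  out[base + 2] = wrap(vec(arma::sum(dY, 1)));
  return P.W1.t() * dY1 + P.W2.t() * dY2;
}

}  // namespace

// Run the UNet on one minibatch.
//   x:     length n*l input signal (one channel), sample-major
//   gold:  length n*l labels (only used when want_grad)
// Returns scores always; when want_grad also the loss and the flat
// gradient/stat list; when training, BN running stats are refreshed and
// returned in the rm/rv slots of that list.
// [[Rcpp::export]]
List unet_run_cpp(List params, const arma::vec& x, const arma::vec& gold,
                  int n, int l, int levels, bool training, bool want_grad,
                  double eps_dice) {
  Reader r(params);
  std::vector<ConvBN> enc1(levels), enc2(levels);
  for (int i = 0; i < levels; ++i) {
    enc1[i] = read_convbn(r);
    enc2[i] = read_convbn(r);
  }
  ConvBN bott1 = read_convbn(r), bott2 = read_convbn(r);
  std::vector<Up> dup(levels);
  std::vector<ConvBN> dec1(levels), dec2(levels);
  for (int i = levels - 1; i >= 0; --i) {
    dup[i].W1 = r.m(); dup[i].W2 = r.m(); dup[i].b = r.v();
    dec1[i] = read_convbn(r);
    dec2[i] = read_convbn(r);
  }
  mat headW = r.m();
  vec headb = r.v();

  const bool keep = want_grad;
  std::vector<BlockCache> ce1(levels), ce2(levels), cd1(levels), cd2(levels);
  BlockCache cb1, cb2;
  std::vector<arma::Mat<unsigned char>> keepA(levels);
  std::vector<mat> skips(levels), up_in(levels), up_out_cat(levels);

  mat cur(1, n * l);
  std::memcpy(cur.memptr(), x.memptr(), sizeof(double) * n * l);
  int cl = l;
  for (int i = 0; i < levels; ++i) {
    cur = block_fwd(cur, enc1[i], training, keep, &ce1[i], n, cl);
    cur = block_fwd(cur, enc2[i], training, keep, &ce2[i], n, cl);
    skips[i] = cur;
    cur = pool2(cur, keepA[i], n, cl);
    cl /= 2;
  }
  cur = block_fwd(cur, bott1, training, keep, &cb1, n, cl);
  cur = block_fwd(cur, bott2, training, keep, &cb2, n, cl);
  for (int i = levels - 1; i >= 0; --i) {
    if (keep) up_in[i] = cur;
    mat up = upconv2(cur, dup[i], n, cl);
    cl *= 2;
    mat cat = arma::join_cols(up, skips[i]);
    if (keep) up_out_cat[i] = cat;
    cur = block_fwd(cat, dec1[i], training, keep, &cd1[i], n, cl);
    cur = block_fwd(cur, dec2[i], training, keep, &cd2[i], n, cl);
  }
  arma::rowvec z = headW * cur;
  z += headb(0);
  vec scores = 1.0 / (1.0 + arma::exp(-z.t()));

  if (!want_grad)
    return List::create(_["scores"] = scores);

  // batch-level soft Dice loss
  const double num = 2.0 * arma::dot(gold, scores) + eps_dice;
  const double den = arma::accu(gold) + arma::accu(scores) + eps_dice;
  const double loss = 1.0 - num / den;
  vec dscores = -(2.0 * gold * den - num) / (den * den);
  vec dz = dscores % scores % (1.0 - scores);

  // Canonical slot bases: encoder level i at 12*i, bottleneck at 12*L,
  // decoder level i (deepest first in the flat list) at
  // 12*L + 12 + (L-1-i)*15, head at 12*L + 12 + 15*L.
  const int n_slots = 27 * levels + 14;
  List grads(n_slots);
  const int base_bott = 12 * levels;
  const int base_head = 12 * levels + 12 + 15 * levels;
  grads[base_head + 0] = wrap(mat(dz.t() * cur.t()));
  grads[base_head + 1] = wrap(vec{arma::accu(dz)});
  mat dcur = headW.t() * dz.t();
  for (int i = 0; i < levels; ++i) {       // shallowest decoder level first
    const int base_d = 12 * levels + 12 + (levels - 1 - i) * 15;
    dcur = block_bwd(dcur, cd2[i], dec2[i], n, cl, grads, base_d + 9);
    dcur = block_bwd(dcur, cd1[i], dec1[i], n, cl, grads, base_d + 3);
    const int c_up = dup[i].b.n_elem;
    mat d_up = dcur.rows(0, c_up - 1);
    mat d_skip = dcur.rows(c_up, dcur.n_rows - 1);
    cl /= 2;
    dcur = upconv2_bwd(d_up, up_in[i], dup[i], n, cl, grads, base_d);
    // route gradient into the skip connection of the matching encoder level
    skips[i] = d_skip;   // reuse storage
  }
  dcur = block_bwd(dcur, cb2, bott2, n, cl, grads, base_bott + 6);
  dcur = block_bwd(dcur, cb1, bott1, n, cl, grads, base_bott + 0);
  for (int i = levels - 1; i >= 0; --i) {
    mat dtop = pool2_bwd(dcur, keepA[i], n, cl * 2);
    cl *= 2;
    dtop += skips[i];
    const int base_e = 12 * i;
    dtop = block_bwd(dtop, ce2[i], enc2[i], n, cl, grads, base_e + 6);
    dtop = block_bwd(dtop, ce1[i], enc1[i], n, cl, grads, base_e + 0);
    dcur = dtop;
  }
  return List::create(_["scores"] = scores, _["loss"] = loss,
                      _["grads"] = grads);
}
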