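// Native implementation of the GSS convolutional network: im2col + BLAS
// convolutions, backpropagation, Adam, early stopping, and a stride-1
// whole-chromosome scanner that shares convolutions across overlapping
// windows via pooling-phase decomposition.
//
// Layout conventions (all column-major, double precision):
//   * a batch of one-hot windows is a cube (4, b, n); internally activations
//     are matrices (channels, positions * n) with per-sample blocks of
//     contiguous position-columns;
//   * im2col stacks the k covered input columns of each output position,
//     so a conv filter row is [w(., offset 0), w(., offset 1), ...];
//   * flattening the last pooled layer is a zero-copy reinterpretation of
//     the same memory (channels-fastest, position-major), and the dense
//     layer weight columns follow that order.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS_CLIP = 1e-7;

struct Net {
  mat W1, W2, W3, W4, W5;
  vec b1, b2, b3, b4, b5;
};

static Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<vec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<vec>(w["b2"]);
  n.W3 = Rcpp::as<mat>(w["W3"]); n.b3 = Rcpp::as<vec>(w["b3"]);
  n.W4 = Rcpp::as<mat>(w["W4"]); n.b4 = Rcpp::as<vec>(w["b4"]);
  n.W5 = Rcpp::as<mat>(w["W5"]); n.b5 = Rcpp::as<vec>(w["b5"]);
  return n;
}

static Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
    Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
    Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
    Rcpp::Named("W4") = n.W4, Rcpp::Named("b4") = n.b4,
    Rcpp::Named("W5") = n.W5, Rcpp::Named("b5") = n.b5);
}

// A: C x (T*n) with per-sample blocks of T columns -> (C*k) x (To*n).
// Columns t..t+k-1 of a sample are contiguous, so each output column is a
// single memcpy.
static mat im2col(const mat& A, uword T, uword n, uword k) {
  const uword C = A.n_rows, To = T - k + 1;
  mat out(C * k, To * n);
  for (uword i = 0; i < n; ++i)
    for (uword t = 0; t < To; ++t)
      std::memcpy(out.colptr(i * To + t), A.colptr(i * T + t),
                  sizeof(double) * C * k);
  return out;
}

// Scatter-add adjoint of im2col.
static mat col2im(const mat& dcol, uword C, uword T, uword n, uword k) {
  const uword To = T - k + 1;
  mat dA(C, T * n, fill::zeros);
  for (uword i = 0; i < n; ++i)
    for (uword t = 0; t < To; ++t) {
      double* dst = dA.colptr(i * T + t);
      const double* src = dcol.colptr(i * To + t);
      for (uword j = 0; j < C * k; ++j) dst[j] += src[j];
    }
  return dA;
}

// Length-2 max pooling along positions (remainder column dropped).
// mask records whether the right element won (ties go left).
static void pool_fwd(const mat& A, uword T, uword n, mat& P, umat& mask) {
  const uword F = A.n_rows, Th = T / 2;
  P.set_size(F, Th * n);
  mask.set_size(F, Th * n);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < Th; ++j) {
      const double* l = A.colptr(i * T + 2 * j);
      const double* r = l + F;  // next column, contiguous
      double* p = P.colptr(i * Th + j);
      uword* m = mask.colptr(i * Th + j);
      for (uword f = 0; f < F; ++f) {
        if (r[f] > l[f]) { p[f] = r[f]; m[f] = 1; }
        else             { p[f] = l[f]; m[f] = 0; }
      }
    }
}

static mat pool_bwd(const mat& dP, const umat& mask, uword T, uword n) {
  const uword F = dP.n_rows, Th = T / 2;
  mat dA(F, T * n, fill::zeros);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < Th; ++j) {
      const double* dp = dP.colptr(i * Th + j);
      const uword* m = mask.colptr(i * Th + j);
      double* l = dA.colptr(i * T + 2 * j);
      double* r = l + F;
      for (uword f = 0; f < F; ++f) {
        if (m[f]) r[f] += dp[f]; else l[f] += dp[f];
      }
    }
  return dA;
}

static inline void relu_inplace(mat& A) {
  A.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// Inverted dropout mask: 0 with probability p, else 1/(1-p).
static mat drop_mask(uword nr, uword nc, double p, std::mt19937_64& rng) {
  mat M(nr, nc);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < M.n_elem; ++j) M[j] = (U(rng) < p) ? 0.0 : scale;
  return M;
}

struct Shapes {
  uword c, b, k1, F1, T1, Th1, k2, F2, T2, Th2, k3, F3, T3, Th3, flat, dense;
};

static Shapes infer_shapes(const Net& net, uword c, uword b) {
  Shapes s;
  s.c = c; s.b = b;
  s.F1 = net.W1.n_rows; s.k1 = net.W1.n_cols / c;
  if (net.W1.n_cols != s.k1 * c)
    Rcpp::stop("conv1 weight shape inconsistent with %d input channels", (int)c);
  s.T1 = b - s.k1 + 1; s.Th1 = s.T1 / 2;
  s.F2 = net.W2.n_rows; s.k2 = net.W2.n_cols / s.F1;
  if (net.W2.n_cols != s.k2 * s.F1) Rcpp::stop("conv2 weight shape inconsistent");
  s.T2 = s.Th1 - s.k2 + 1; s.Th2 = s.T2 / 2;
  s.F3 = net.W3.n_rows; s.k3 = net.W3.n_cols / s.F2;
  if (net.W3.n_cols != s.k3 * s.F2) Rcpp::stop("conv3 weight shape inconsistent");
  s.T3 = s.Th2 - s.k3 + 1; s.Th3 = s.T3 / 2;
  s.flat = s.F3 * s.Th3;
  s.dense = net.W4.n_rows;
  if (net.W4.n_cols != s.flat)
    Rcpp::stop("dense layer expects %d inputs, flattened pool gives %d",
               (int)net.W4.n_cols, (int)s.flat);
  if (net.W5.n_cols != s.dense) Rcpp::stop("output layer shape inconsistent");
  return s;
}

struct Cache {
  mat col1, A1, P1, col2, A2, P2, col3, A3, P3;
  umat m1, m2, m3;
  mat d1, d2, d3, d4;   // dropout masks (empty when not training)
  mat Hr, Hd;           // dense hidden pre/post dropout
  rowvec yhat;
};

// Forward pass over a batch laid out as X (c, b*n).
static rowvec forward(const mat& X, const Net& net, const Shapes& s, uword n,
                      Cache* cc, const vec* dropout, std::mt19937_64* rng) {
  const bool train = dropout != nullptr;
  Cache local;
  Cache& C = cc ? *cc : local;

  C.col1 = im2col(X, s.b, n, s.k1);
  C.A1 = net.W1 * C.col1; C.A1.each_col() += net.b1; relu_inplace(C.A1);
  pool_fwd(C.A1, s.T1, n, C.P1, C.m1);
  if (train && (*dropout)[0] > 0) { C.d1 = drop_mask(C.P1.n_rows, C.P1.n_cols, (*dropout)[0], *rng); C.P1 %= C.d1; }

  C.col2 = im2col(C.P1, s.Th1, n, s.k2);
  C.A2 = net.W2 * C.col2; C.A2.each_col() += net.b2; relu_inplace(C.A2);
  pool_fwd(C.A2, s.T2, n, C.P2, C.m2);
  if (train && (*dropout)[1] > 0) { C.d2 = drop_mask(C.P2.n_rows, C.P2.n_cols, (*dropout)[1], *rng); C.P2 %= C.d2; }

  C.col3 = im2col(C.P2, s.Th2, n, s.k3);
  C.A3 = net.W3 * C.col3; C.A3.each_col() += net.b3; relu_inplace(C.A3);
  pool_fwd(C.A3, s.T3, n, C.P3, C.m3);
  if (train && (*dropout)[2] > 0) { C.d3 = drop_mask(C.P3.n_rows, C.P3.n_cols, (*dropout)[2], *rng); C.P3 %= C.d3; }

  // zero-copy flatten: (F3, Th3*n) -> (F3*Th3, n)
  mat D(C.P3.memptr(), s.flat, n, false, true);
  C.Hr = net.W4 * D; C.Hr.each_col() += net.b4; relu_inplace(C.Hr);
  C.Hd = C.Hr;
  if (train && (*dropout)[3] > 0) { C.d4 = drop_mask(C.Hd.n_rows, C.Hd.n_cols, (*dropout)[3], *rng); C.Hd %= C.d4; }

  mat z = net.W5 * C.Hd; z += net.b5[0];
  rowvec yh = 1.0 / (1.0 + exp(-z.row(0)));
  C.yhat = yh;
  return yh;
}

// Class-weighted binary cross-entropy, mean over samples; the y=1 term is
// multiplied by cw.  Predictions clipped away from {0,1}.
static double wbce(const rowvec& yhat, const rowvec& y, double cw) {
  rowvec yh = clamp(yhat, EPS_CLIP, 1.0 - EPS_CLIP);
  return as_scalar(mean(-(cw * y % log(yh) + (1.0 - y) % log(1.0 - yh)), 1));
}

struct Grads {
  mat W1, W2, W3, W4, W5;
  vec b1, b2, b3, b4, b5;
};

static Grads backward(const mat& X, const rowvec& y, const Net& net,
                      const Shapes& s, uword n, Cache& C, double cw) {
  Grads g;
  // d(mean weighted BCE)/dz with sigmoid output: w * (yhat - y) / n,
  // w = cw for positives, 1 for negatives.
  rowvec w = 1.0 + (cw - 1.0) * y;
  rowvec dz = (C.yhat - y) % w / double(n);

  g.W5 = dz * C.Hd.t();
  g.b5 = vec(1); g.b5[0] = accu(dz);
  mat dH = net.W5.t() * dz;
  if (!C.d4.is_empty()) dH %= C.d4;
  dH %= conv_to<mat>::from(C.Hr > 0);

  mat D(C.P3.memptr(), s.flat, n, false, true);
  g.W4 = dH * D.t();
  g.b4 = sum(dH, 1);
  mat dDfull = net.W4.t() * dH;                  // (flat, n)
  mat dP3(dDfull.memptr(), s.F3, s.Th3 * n, false, true);
  if (!C.d3.is_empty()) dP3 %= C.d3;
  mat dA3 = pool_bwd(dP3, C.m3, s.T3, n);
  dA3 %= conv_to<mat>::from(C.A3 > 0);
  g.W3 = dA3 * C.col3.t();
  g.b3 = sum(dA3, 1);
  mat dP2 = col2im(net.W3.t() * dA3, s.F2, s.Th2, n, s.k3);
  if (!C.d2.is_empty()) dP2 %= C.d2;
  mat dA2 = pool_bwd(dP2, C.m2, s.T2, n);
  dA2 %= conv_to<mat>::from(C.A2 > 0);
  g.W2 = dA2 * C.col2.t();
  g.b2 = sum(dA2, 1);
  mat dP1 = col2im(net.W2.t() * dA2, s.F1, s.Th1, n, s.k2);
  if (!C.d1.is_empty()) dP1 %= C.d1;
  mat dA1 = pool_bwd(dP1, C.m1, s.T1, n);
  dA1 %= conv_to<mat>::from(C.A1 > 0);
  g.W1 = dA1 * C.col1.t();
  g.b1 = sum(dA1, 1);
  return g;
}

// Gather selected samples of a (c, b, n) cube into a (c, b*m) batch matrix.
static mat gather(const cube& X, const uvec& idx) {
  const uword c = X.n_rows, b = X.n_cols;
  mat out(c, b * idx.n_elem);
  for (uword i = 0; i < idx.n_elem; ++i)
    std::memcpy(out.colptr(i * b), X.slice(idx[i]).memptr(),
                sizeof(double) * c * b);
  return out;
}

static rowvec predict_all(const cube& X, const Net& net, const Shapes& s,
                          uword batch) {
  const uword n = X.n_slices;
  rowvec out(n);
  for (uword start = 0; start < n; start += batch) {
    uword m = std::min(batch, n - start);
    uvec idx = regspace<uvec>(start, start + m - 1);
    mat Xb = gather(X, idx);
    out.subvec(start, start + m - 1) =
      forward(Xb, net, s, m, nullptr, nullptr, nullptr);
  }
  return out;
}

// ---- Adam ----
struct AdamState { mat mW, vW; vec mb, vb; };

static void adam_step(mat& W, vec& b, const mat& gW, const vec& gb,
                      AdamState& st, double lr, double b1, double b2,
                      double eps, uword t) {
  if (st.mW.is_empty()) {
    st.mW = zeros(size(W)); st.vW = zeros(size(W));
    st.mb = zeros(size(b)); st.vb = zeros(size(b));
  }
  const double c1 = 1.0 - std::pow(b1, double(t));
  const double c2 = 1.0 - std::pow(b2, double(t));
  st.mW = b1 * st.mW + (1 - b1) * gW; st.vW = b2 * st.vW + (1 - b2) * square(gW);
  W -= lr * (st.mW / c1) / (sqrt(st.vW / c2) + eps);
  st.mb = b1 * st.mb + (1 - b1) * gb; st.vb = b2 * st.vb + (1 - b2) * square(gb);
  b -= lr * (st.mb / c1) / (sqrt(st.vb / c2) + eps);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::cube& X, const arma::vec& y,
                         const arma::cube& Xval, const arma::vec& yval,
                         const Rcpp::List& weights, double cw, double lr,
                         int batch_size, int max_epochs, int patience,
                         const arma::vec& dropout, int seed) {
  Net net = net_from_list(weights);
  const uword n = X.n_slices, c = X.n_rows, b = X.n_cols;
  Shapes s = infer_shapes(net, c, b);
  if (y.n_elem != n) Rcpp::stop("length(y) != number of training samples");
  const bool has_val = Xval.n_slices > 0;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  AdamState st[5];
  const double ab1 = 0.9, ab2 = 0.999, aeps = 1e-7;
  uword t = 0;

  Net best = net;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;
  uvec perm = regspace<uvec>(0, n - 1);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0; uword seen = 0;
    for (uword start = 0; start < n; start += (uword)batch_size) {
      uword m = std::min<uword>(batch_size, n - start);
      uvec idx = perm.subvec(start, start + m - 1);
      mat Xb = gather(X, idx);
      rowvec yb(m);
      for (uword i = 0; i < m; ++i) yb[i] = y[idx[i]];
      Cache C;
      rowvec yh = forward(Xb, net, s, m, &C, &dropout, &rng);
      double L = wbce(yh, yb, cw);
      if (!std::isfinite(L))
        Rcpp::stop("training diverged (loss is not finite); try a lower learning rate");
      ep_loss += L * m; seen += m;
      Grads g = backward(Xb, yb, net, s, m, C, cw);
      ++t;
      adam_step(net.W1, net.b1, g.W1, g.b1, st[0], lr, ab1, ab2, aeps, t);
      adam_step(net.W2, net.b2, g.W2, g.b2, st[1], lr, ab1, ab2, aeps, t);
      adam_step(net.W3, net.b3, g.W3, g.b3, st[2], lr, ab1, ab2, aeps, t);
      adam_step(net.W4, net.b4, g.W4, g.b4, st[3], lr, ab1, ab2, aeps, t);
      adam_step(net.W5, net.b5, g.W5, g.b5, st[4], lr, ab1, ab2, aeps, t);
    }
    epochs_run = epoch + 1;
    tr_hist.push_back(ep_loss / double(seen));

    double vloss;
    if (has_val) {
      rowvec yv = predict_all(Xval, net, s, 1024);
      vloss = wbce(yv, rowvec(yval.t()), 1.0);  // monitored loss is unweighted
    } else {
      vloss = tr_hist.back();
    }
    val_hist.push_back(vloss);
    if (vloss < best_val - 1e-9) {
      best_val = vloss; best = net; best_epoch = epoch + 1; wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch == 0) { best = net; best_epoch = epochs_run; }

  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(best),
    Rcpp::Named("train_loss") = tr_hist,
    Rcpp::Named("val_loss") = val_hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(const arma::cube& X, const Rcpp::List& weights,
                          int batch_size) {
  Net net = net_from_list(weights);
  Shapes s = infer_shapes(net, X.n_rows, X.n_cols);
  rowvec out = predict_all(X, net, s, (uword)batch_size);
  return vec(out.t());
}

// Loss and exact gradients on a batch, no dropout: used by the
// finite-difference correctness test.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_loss_grad(const arma::cube& X, const arma::vec& y,
                             const Rcpp::List& weights, double cw) {
  Net net = net_from_list(weights);
  const uword n = X.n_slices;
  Shapes s = infer_shapes(net, X.n_rows, X.n_cols);
  uvec idx = regspace<uvec>(0, n - 1);
  mat Xb = gather(X, idx);
  Cache C;
  rowvec yb(y.t());
  rowvec yh = forward(Xb, net, s, n, &C, nullptr, nullptr);
  double L = wbce(yh, yb, cw);
  Grads g = backward(Xb, yb, net, s, n, C, cw);
  Net gn; gn.W1 = g.W1; gn.b1 = g.b1; gn.W2 = g.W2; gn.b2 = g.b2;
  gn.W3 = g.W3; gn.b3 = g.b3; gn.W4 = g.W4; gn.b4 = g.b4;
  gn.W5 = g.W5; gn.b5 = g.b5;
  return Rcpp::List::create(Rcpp::Named("loss") = L,
                            Rcpp::Named("grads") = net_to_list(gn));
}

// ---- stride-1 chromosome scan -----------------------------------------

// Convolution of one long sequence of activations (C x T) with chunked
// im2col; returns ReLU(W %*% im2col + b), F x (T-k+1).
static mat conv_seq(const mat& A, const mat& W, const vec& b, uword k) {
  const uword C = A.n_rows, T = A.n_cols;
  if (T < k) return mat(W.n_rows, 0);
  const uword To = T - k + 1;
  mat out(W.n_rows, To);
  const uword chunk = 16384;
  for (uword s0 = 0; s0 < To; s0 += chunk) {
    const uword m = std::min(chunk, To - s0);
    mat buf(C * k, m);
    for (uword t = 0; t < m; ++t)
      std::memcpy(buf.colptr(t), A.colptr(s0 + t), sizeof(double) * C * k);
    out.cols(s0, s0 + m - 1) = W * buf;
  }
  out.each_col() += b;
  relu_inplace(out);
  return out;
}

// Max-pool a long sequence starting at column `off`, pairs (off+2j, off+2j+1).
static mat pool_seq(const mat& A, uword off) {
  const uword F = A.n_rows;
  if (A.n_cols < off + 2) return mat(F, 0);
  const uword n = (A.n_cols - off) / 2;
  mat P(F, n);
  for (uword j = 0; j < n; ++j) {
    const double* l = A.colptr(off + 2 * j);
    const double* r = l + F;
    double* p = P.colptr(j);
    for (uword f = 0; f < F; ++f) p[f] = std::max(l[f], r[f]);
  }
  return P;
}

// Scan every window of length b at stride 1 along a chromosome given as
// integer codes (0=A, 1=T, 2=C, 3=G, 4=N; order matches one-hot rows).
// Sharing rationale: each max-pool halves resolution, so window starts that
// are congruent mod 2^d (d pooling layers) share all convolution results.
// For each of the 2^3 = 8 phases the full-length convolution chain is
// computed once and the dense head is applied as one more convolution.
// Tail elements dropped by odd-length pooling never reach the output, which
// keeps the phase chains exactly equivalent to per-window evaluation.
// [[Rcpp::export]]
arma::vec cpp_cnn_scan(const arma::ivec& codes, const Rcpp::List& weights,
                       int window) {
  Net net = net_from_list(weights);
  const uword b = (uword)window, L = codes.n_elem;
  if (L < b) Rcpp::stop("chromosome shorter than the %d bp window", window);
  Shapes s = infer_shapes(net, 4, b);
  const uword nwin = L - b + 1;
  vec scores(nwin, fill::value(datum::nan));

  mat X(4, L, fill::zeros);
  for (uword i = 0; i < L; ++i) {
    const sword cd = codes[i];
    if (cd >= 0 && cd < 4) X(cd, i) = 1.0;
  }

  mat C1 = conv_seq(X, net.W1, net.b1, s.k1);
  X.reset();
  mat P1[2] = { pool_seq(C1, 0), pool_seq(C1, 1) };
  C1.reset();

  for (uword p = 0; p < 2; ++p) {
    if (P1[p].n_cols < s.k2) continue;
    mat C2 = conv_seq(P1[p], net.W2, net.b2, s.k2);
    for (uword q = 0; q < 2; ++q) {
      mat P2 = pool_seq(C2, q);
      if (P2.n_cols < s.k3) continue;
      mat C3 = conv_seq(P2, net.W3, net.b3, s.k3);
      P2.reset();
      for (uword r = 0; r < 2; ++r) {
        mat P3 = pool_seq(C3, r);
        if (P3.n_cols < s.Th3) continue;
        const uword npos = P3.n_cols - s.Th3 + 1;
        const uword chunk = 4096;
        for (uword c0 = 0; c0 < npos; c0 += chunk) {
          const uword m = std::min(chunk, npos - c0);
          mat buf(s.flat, m);
          for (uword t = 0; t < m; ++t)  // cols c0+t .. c0+t+Th3-1 contiguous
            std::memcpy(buf.colptr(t), P3.colptr(c0 + t),
                        sizeof(double) * s.flat);
          mat H = net.W4 * buf; H.each_col() += net.b4; relu_inplace(H);
          mat z = net.W5 * H;
          for (uword t = 0; t < m; ++t) {
            const uword start = 8 * (c0 + t) + 4 * r + 2 * q + p;
            if (start < nwin)
              scores[start] = 1.0 / (1.0 + std::exp(-(z(0, t) + net.b5[0])));
          }
        }
      }
      C3.reset();
    }
  }
  return scores;
}
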