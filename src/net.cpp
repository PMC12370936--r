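// Convolutional dual-module network: forward pass, backpropagation and the
// SGD training loop on the ring-regularized pair loss. Single precision
// throughout; convolutions are im2col + GEMM.
//
// Architecture (input side s, 3 replicated channels):
//   conv(16, k2, s1, p1) -> ReLU
//   conv(32, k2, s1, p1) -> ReLU -> maxpool(k4, s4)
//   conv(32, k3, s1, p1) -> ReLU -> maxpool(k6, s6)
//   flatten -> linear -> scalar Z
// Pooling windows advance by their own extent; with s = 224 the flattened
// vector has 32 * 9 * 9 = 2592 entries.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::stop;

struct NetDims {
  int side, o1, o2, p1, o3, p2, flat;
};

static NetDims make_dims(int side) {
  NetDims d;
  d.side = side;
  d.o1 = side + 1;            // conv k2 p1
  d.o2 = d.o1 + 1;            // conv k2 p1
  d.p1 = (d.o2 - 4) / 4 + 1;  // pool k4 s4
  d.o3 = d.p1;                // conv k3 p1 (same size)
  d.p2 = (d.o3 - 6) / 6 + 1;  // pool k6 s6
  d.flat = 32 * d.p2 * d.p2;
  if (d.o2 < 4 || d.o3 < 6)
    stop("image side %d is too small for the network geometry", side);
  return d;
}

// [[Rcpp::export]]
IntegerVector cpp_net_dims(int side) {
  NetDims d = make_dims(side);
  return IntegerVector::create(
      Rcpp::Named("o1") = d.o1, Rcpp::Named("o2") = d.o2,
      Rcpp::Named("p1") = d.p1, Rcpp::Named("o3") = d.o3,
      Rcpp::Named("p2") = d.p2, Rcpp::Named("flat") = d.flat);
}

struct Params {
  fmat W1, W2, W3;      // (out, in*k*k)
  fvec b1, b2, b3, Wfc;
  float bfc, theta;
  // The 3 input channels carry identical values, so conv1 acts through the
  // channel-summed kernel only; W1e caches that 16 x 4 sum.
  fmat W1e;
  void refresh_w1e() {
    // channel-minor columns: (kk*3 + c); sum the 3 channels per offset kk
    W1e.set_size(16, 4);
    for (int kk = 0; kk < 4; ++kk)
      W1e.col(kk) = W1.col(3 * kk) + W1.col(3 * kk + 1) + W1.col(3 * kk + 2);
  }
};

static int n_par(const NetDims& d) {
  return 16 * 12 + 16 + 32 * 64 + 32 + 32 * 288 + 32 + d.flat + 1 + 1;
}

// The external parameter vector orders a conv layer's inputs channel-major
// (j = c*K*K + kx*K + ky); the im2col buffers below are laid out
// channel-minor (j' = (kx*K + ky)*C + c) so that gathers and scatters copy
// contiguous runs. Weight columns are permuted at load and save.
static fmat reorder_cols(const fmat& W, int C, int K, bool to_minor) {
  fmat out(W.n_rows, W.n_cols);
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < K * K; ++kk) {
      const int major = c * K * K + kk, minor = kk * C + c;
      if (to_minor) out.col(minor) = W.col(major);
      else out.col(major) = W.col(minor);
    }
  return out;
}
static fmat to_channel_minor(const fmat& W, int C, int K) {
  return reorder_cols(W, C, K, true);
}
static fmat to_channel_major(const fmat& W, int C, int K) {
  return reorder_cols(W, C, K, false);
}

static Params load_params(const NumericVector& par, const NetDims& d) {
  if ((int)par.size() != n_par(d))
    stop("parameter vector has length %d, expected %d", (int)par.size(), n_par(d));
  Params p;
  const double* q = par.begin();
  auto take_mat = [&](int r, int c) {
    fmat m(r, c);
    for (int j = 0; j < r * c; j++) m.memptr()[j] = (float)q[j];
    q += r * c;
    return m;
  };
  auto take_vec = [&](int n) {
    fvec v(n);
    for (int j = 0; j < n; j++) v[j] = (float)q[j];
    q += n;
    return v;
  };
  p.W1 = take_mat(16, 12);  p.b1 = take_vec(16);
  p.W2 = take_mat(32, 64);  p.b2 = take_vec(32);
  p.W3 = take_mat(32, 288); p.b3 = take_vec(32);
  p.Wfc = take_vec(d.flat);
  p.bfc = (float)*q++;
  p.theta = (float)*q++;
  // in-memory conv weights use the channel-minor input ordering of im2col
  p.W1 = to_channel_minor(p.W1, 3, 2);
  p.W2 = to_channel_minor(p.W2, 16, 2);
  p.W3 = to_channel_minor(p.W3, 32, 3);
  p.refresh_w1e();
  return p;
}

static NumericVector save_params(const Params& p, const NetDims& d) {
  NumericVector par(n_par(d));
  double* q = par.begin();
  auto put_mat = [&](const fmat& m) {
    for (uword j = 0; j < m.n_elem; j++) q[j] = (double)m.memptr()[j];
    q += m.n_elem;
  };
  auto put_vec = [&](const fvec& v) {
    for (uword j = 0; j < v.n_elem; j++) q[j] = (double)v[j];
    q += v.n_elem;
  };
  put_mat(to_channel_major(p.W1, 3, 2)); put_vec(p.b1);
  put_mat(to_channel_major(p.W2, 16, 2)); put_vec(p.b2);
  put_mat(to_channel_major(p.W3, 32, 3)); put_vec(p.b3);
  put_vec(p.Wfc);
  *q++ = (double)p.bfc;
  *q++ = (double)p.theta;
  return par;
}

// Feature maps are stored as fmat (channels x H*H), spatial index x*H + y.
// im2col for a KxK kernel with zero padding P, stride 1; column layout
// row = c*K*K + kx*K + ky, one column per output position (ox*O + oy).
static void im2col(const fmat& X, int H, int K, int P, fmat& cols) {
  const int C = X.n_rows;
  const int O = H + 2 * P - K + 1;
  // Positions skipped below (out-of-range source pixels) are always the
  // same, so the buffer only needs zeroing when it is (re)allocated.
  if ((int)cols.n_rows != C * K * K || cols.n_cols != (uword)O * O)
    cols.zeros(C * K * K, (uword)O * O);
  for (int ox = 0; ox < O; ++ox) {
    for (int kx = 0; kx < K; ++kx) {
      const int ix = ox - P + kx;
      if (ix < 0 || ix >= H) continue;
      for (int oy = 0; oy < O; ++oy) {
        const int col = ox * O + oy;
        float* dstc = cols.colptr(col);
        for (int ky = 0; ky < K; ++ky) {
          const int iy = oy - P + ky;
          if (iy < 0 || iy >= H) continue;
          float* dst = dstc + (kx * K + ky) * C;
          const float* src = X.colptr(ix * H + iy);
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        }
      }
    }
  }
}

// Scatter-add transpose of im2col (gradient w.r.t. the input maps).
static void col2im(const fmat& cols, int H, int K, int P, fmat& dX, int C) {
  const int O = H + 2 * P - K + 1;
  dX.zeros(C, (uword)H * H);
  for (int ox = 0; ox < O; ++ox) {
    for (int kx = 0; kx < K; ++kx) {
      const int ix = ox - P + kx;
      if (ix < 0 || ix >= H) continue;
      for (int oy = 0; oy < O; ++oy) {
        const int col = ox * O + oy;
        const float* srcc = cols.colptr(col);
        for (int ky = 0; ky < K; ++ky) {
          const int iy = oy - P + ky;
          if (iy < 0 || iy >= H) continue;
          const float* src = srcc + (kx * K + ky) * C;
          float* dst = dX.colptr(ix * H + iy);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// Max pooling with window K advancing by K (window = stride).
static void maxpool(const fmat& X, int H, int K, fmat& out, umat& arg) {
  const int C = X.n_rows;
  const int O = (H - K) / K + 1;
  out.set_size(C, (uword)O * O);
  arg.set_size(C, (uword)O * O);
  for (int px = 0; px < O; ++px) {
    for (int py = 0; py < O; ++py) {
      const int col = px * O + py;
      for (int c = 0; c < C; ++c) {
        float best = -std::numeric_limits<float>::infinity();
        uword besti = 0;
        for (int kx = 0; kx < K; ++kx) {
          const int ix = px * K + kx;
          for (int ky = 0; ky < K; ++ky) {
            const int iy = py * K + ky;
            const float v = X(c, (uword)ix * H + iy);
            if (v > best) { best = v; besti = (uword)ix * H + iy; }
          }
        }
        out(c, col) = best;
        arg(c, col) = besti;
      }
    }
  }
}

// Scatter pooled gradients back to the argmax positions, applying the ReLU
// mask of the forward activation A at the target. Pool windows are disjoint
// (stride = kernel), so each target receives at most one contribution.
static void unpool_masked(const fmat& dout, const umat& arg, int H, fmat& dX,
                          int C, const fmat& A) {
  dX.zeros(C, (uword)H * H);
  for (uword col = 0; col < dout.n_cols; ++col)
    for (int c = 0; c < C; ++c) {
      const uword j = arg(c, col);
      if (A(c, j) > 0.f) dX(c, j) = dout(c, col);
    }
}

struct Cache {
  fmat X0, cols1, A1, cols2, A2, P1, cols3, A3, P2;
  umat arg1, arg2;
  fvec flat;
};

// Forward pass; fills the cache when `keep` (needed for backprop). When
// `reuse_input` the image is unchanged since the previous call with this
// cache, so the input-layer im2col is not rebuilt.
static float forward_one(const Params& p, const NetDims& d, const float* img,
                         Cache& c, bool keep, bool reuse_input = false) {
  const int H = d.side;
  if (!reuse_input) {
    c.X0.set_size(1, (uword)H * H);
    std::copy(img, img + (uword)H * H, c.X0.memptr());
    im2col(c.X0, H, 2, 1, c.cols1);
  }
  c.A1 = p.W1e * c.cols1;
  c.A1.each_col() += p.b1;
  c.A1.transform([](float v) { return v > 0.f ? v : 0.f; });

  im2col(c.A1, d.o1, 2, 1, c.cols2);
  c.A2 = p.W2 * c.cols2;
  c.A2.each_col() += p.b2;
  c.A2.transform([](float v) { return v > 0.f ? v : 0.f; });
  maxpool(c.A2, d.o2, 4, c.P1, c.arg1);

  im2col(c.P1, d.p1, 3, 1, c.cols3);
  c.A3 = p.W3 * c.cols3;
  c.A3.each_col() += p.b3;
  c.A3.transform([](float v) { return v > 0.f ? v : 0.f; });
  maxpool(c.A3, d.o3, 6, c.P2, c.arg2);

  c.flat = vectorise(c.P2);  // channel-fastest flatten
  float z = dot(p.Wfc, c.flat) + p.bfc;
  if (!keep) {
    // buffers are reused across calls; nothing to release explicitly
  }
  return z;
}

struct Grads {
  fmat W1, W2, W3;
  fvec b1, b2, b3, Wfc;
  float bfc, theta;
  void zero(const NetDims& d) {
    W1.zeros(16, 4); W2.zeros(32, 64); W3.zeros(32, 288);
    b1.zeros(16); b2.zeros(32); b3.zeros(32);
    Wfc.zeros(d.flat); bfc = 0.f; theta = 0.f;
  }
};

// Preallocated backward temporaries, reused across calls.
struct Workspace {
  fmat dP2, dA3, dcols3, dP1, dA2, dcols2, dA1;
};

// Zero out entries of dX where the forward activation was clipped by ReLU.
static inline void relu_mask(fmat& dX, const fmat& A) {
  float* d = dX.memptr();
  const float* a = A.memptr();
  const uword n = dX.n_elem;
  for (uword j = 0; j < n; ++j)
    if (a[j] <= 0.f) d[j] = 0.f;
}

// Backward pass for one image given dL/dZ = g; accumulates into grads.
static void backward_one(const Params& p, const NetDims& d, const Cache& c,
                         float g, Grads& gr, Workspace& w) {
  gr.Wfc += g * c.flat;
  gr.bfc += g;
  // un-flatten (channel-fastest): dP2(ch, pos) = g * Wfc[pos*32 + ch]
  w.dP2.set_size(32, (uword)d.p2 * d.p2);
  for (uword pos = 0; pos < w.dP2.n_cols; ++pos)
    for (int ch = 0; ch < 32; ++ch) w.dP2(ch, pos) = g * p.Wfc[pos * 32 + ch];

  unpool_masked(w.dP2, c.arg2, d.o3, w.dA3, 32, c.A3);
  gr.W3 += w.dA3 * c.cols3.t();
  gr.b3 += sum(w.dA3, 1);
  w.dcols3 = p.W3.t() * w.dA3;
  col2im(w.dcols3, d.p1, 3, 1, w.dP1, 32);

  unpool_masked(w.dP1, c.arg1, d.o2, w.dA2, 32, c.A2);
  gr.W2 += w.dA2 * c.cols2.t();
  gr.b2 += sum(w.dA2, 1);
  w.dcols2 = p.W2.t() * w.dA2;
  col2im(w.dcols2, d.o1, 2, 1, w.dA1, 16);
  relu_mask(w.dA1, c.A1);
  // identical input channels: each channel block of W1 receives this same
  // channel-summed gradient (applied blockwise in the SGD step)
  gr.W1 += w.dA1 * c.cols1.t();
  gr.b1 += sum(w.dA1, 1);
  // gradient w.r.t. the input image is not needed
}

// Pair loss (dz - theta)^2 + lambda * (dz^2 + theta^2 - r^2)^2.
static inline double pair_loss_val(double dz, double th, double lam, double r2) {
  const double a = dz - th;
  const double b = dz * dz + th * th - r2;
  return a * a + lam * b * b;
}

// Presented order judged correct iff its loss is strictly below the loss of
// the swapped order (which negates dz); exact ties count as incorrect.
static inline bool order_correct(double dz, double th, double lam, double r2) {
  return pair_loss_val(dz, th, lam, r2) < pair_loss_val(-dz, th, lam, r2);
}

// [[Rcpp::export]]
NumericVector cpp_forward_batch(NumericVector par, int side, NumericVector imgs,
                                int n) {
  NetDims d = make_dims(side);
  Params p = load_params(par, d);
  if ((int)imgs.size() != side * side * n) stop("image array size mismatch");
  std::vector<float> buf((size_t)side * side);
  Cache c;
  NumericVector z(n);
  for (int i = 0; i < n; i++) {
    const double* src = imgs.begin() + (size_t)i * side * side;
    for (int j = 0; j < side * side; j++) buf[j] = (float)src[j];
    z[i] = (double)forward_one(p, d, buf.data(), c, false);
  }
  return z;
}

// [[Rcpp::export]]
List cpp_evaluate(NumericVector par, int side, NumericVector left,
                  NumericVector right, int n, double lambda, double r2) {
  NetDims d = make_dims(side);
  Params p = load_params(par, d);
  std::vector<float> buf((size_t)side * side);
  Cache c;
  NumericVector dz(n);
  int ncorrect = 0;
  for (int i = 0; i < n; i++) {
    const double* sl = left.begin() + (size_t)i * side * side;
    const double* sr = right.begin() + (size_t)i * side * side;
    for (int j = 0; j < side * side; j++) buf[j] = (float)sl[j];
    const float zl = forward_one(p, d, buf.data(), c, false);
    for (int j = 0; j < side * side; j++) buf[j] = (float)sr[j];
    const float zr = forward_one(p, d, buf.data(), c, false);
    dz[i] = (double)(zr - zl);
    if (order_correct(dz[i], p.theta, lambda, r2)) ncorrect++;
  }
  return List::create(
      Rcpp::Named("dz") = dz,
      Rcpp::Named("mean_dz") = n > 0 ? Rcpp::mean(dz) : NA_REAL,
      Rcpp::Named("accuracy") = n > 0 ? (double)ncorrect / n : NA_REAL,
      Rcpp::Named("theta") = (double)p.theta);
}

// Train on a sequence of image pairs: consecutive batches of `batch_pairs`
// pairs, `steps_per_batch` full-batch gradient steps each (mean loss over
// the batch). Probes (accuracy and mean dz over a held-out set) are
// evaluated every `checkpoint_every` batches and after the final batch.
// [[Rcpp::export]]
List cpp_train_phase(NumericVector par, int side, NumericVector left,
                     NumericVector right, int n_pairs, double lr,
                     double lambda, double r2, int batch_pairs,
                     int steps_per_batch, NumericVector probe_left,
                     NumericVector probe_right, int n_probe,
                     int checkpoint_every) {
  NetDims d = make_dims(side);
  Params p = load_params(par, d);
  const size_t npx = (size_t)side * side;

  const int n_batches = n_pairs > 0 ? (n_pairs + batch_pairs - 1) / batch_pairs : 0;
  std::vector<Cache> caches(2 * batch_pairs);
  std::vector<std::vector<float>> imgs(2 * batch_pairs,
                                       std::vector<float>(npx));
  Grads gr;
  Workspace wsp;
  Cache probe_cache;
  std::vector<float> pbuf(npx);

  auto probe_eval = [&](double* out_dz, double* out_acc) {
    if (n_probe <= 0) { *out_dz = NA_REAL; *out_acc = NA_REAL; return; }
    double sum_dz = 0; int ncorrect = 0;
    for (int i = 0; i < n_probe; i++) {
      const double* sl = probe_left.begin() + (size_t)i * npx;
      const double* sr = probe_right.begin() + (size_t)i * npx;
      for (size_t j = 0; j < npx; j++) pbuf[j] = (float)sl[j];
      const float zl = forward_one(p, d, pbuf.data(), probe_cache, false);
      for (size_t j = 0; j < npx; j++) pbuf[j] = (float)sr[j];
      const float zr = forward_one(p, d, pbuf.data(), probe_cache, false);
      const double dz = (double)(zr - zl);
      sum_dz += dz;
      if (order_correct(dz, p.theta, lambda, r2)) ncorrect++;
    }
    *out_dz = sum_dz / n_probe;
    *out_acc = (double)ncorrect / n_probe;
  };

  std::vector<double> ck_pairs, ck_theta, ck_dz, ck_acc, ck_loss;

  for (int b = 0; b < n_batches; b++) {
    const int first = b * batch_pairs;
    const int bp = std::min(batch_pairs, n_pairs - first);
    for (int i = 0; i < bp; i++) {
      const double* sl = left.begin() + (size_t)(first + i) * npx;
      const double* sr = right.begin() + (size_t)(first + i) * npx;
      for (size_t j = 0; j < npx; j++) imgs[2 * i][j] = (float)sl[j];
      for (size_t j = 0; j < npx; j++) imgs[2 * i + 1][j] = (float)sr[j];
    }
    double last_loss = NA_REAL;
    for (int s = 0; s < steps_per_batch; s++) {
      gr.zero(d);
      double batch_loss = 0;
      for (int i = 0; i < bp; i++) {
        const float zl = forward_one(p, d, imgs[2 * i].data(), caches[2 * i],
                                     true, s > 0);
        const float zr = forward_one(p, d, imgs[2 * i + 1].data(),
                                     caches[2 * i + 1], true, s > 0);
        const double dz = (double)(zr - zl);
        const double th = (double)p.theta;
        const double ring = dz * dz + th * th - r2;
        batch_loss += pair_loss_val(dz, th, lambda, r2);
        const double ddz = (2.0 * (dz - th) + 4.0 * lambda * ring * dz) / bp;
        gr.theta += (float)((-2.0 * (dz - th) + 4.0 * lambda * ring * th) / bp);
        backward_one(p, d, caches[2 * i + 1], (float)ddz, gr, wsp);
        backward_one(p, d, caches[2 * i], (float)-ddz, gr, wsp);
      }
      last_loss = batch_loss / bp;
      const float eta = (float)lr;
      // identical channel blocks share the channel-summed conv1 gradient
      for (int kk = 0; kk < 4; ++kk)
        for (int c = 0; c < 3; ++c)
          p.W1.col(3 * kk + c) -= eta * gr.W1.col(kk);
      p.refresh_w1e();
      p.b1 -= eta * gr.b1;
      p.W2 -= eta * gr.W2; p.b2 -= eta * gr.b2;
      p.W3 -= eta * gr.W3; p.b3 -= eta * gr.b3;
      p.Wfc -= eta * gr.Wfc;
      p.bfc -= eta * gr.bfc;
      p.theta -= eta * gr.theta;
    }
    const bool record = (checkpoint_every > 0 &&
                         ((b + 1) % checkpoint_every == 0 || b == n_batches - 1));
    if (record) {
      double pdz, pacc;
      probe_eval(&pdz, &pacc);
      ck_pairs.push_back(first + bp);
      ck_theta.push_back((double)p.theta);
      ck_dz.push_back(pdz);
      ck_acc.push_back(pacc);
      ck_loss.push_back(last_loss);
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix ck(ck_pairs.size(), 5);
  for (size_t i = 0; i < ck_pairs.size(); i++) {
    ck(i, 0) = ck_pairs[i]; ck(i, 1) = ck_theta[i]; ck(i, 2) = ck_dz[i];
    ck(i, 3) = ck_acc[i];   ck(i, 4) = ck_loss[i];
  }
  colnames(ck) = Rcpp::CharacterVector::create("pairs_seen", "theta",
                                               "mean_dz", "accuracy",
                                               "train_loss");
  return List::create(Rcpp::Named("par") = save_params(p, d),
                      Rcpp::Named("checkpoints") = ck);
}
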