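// Small VGG-style CNN: 3x3 same-padding convolutions with ReLU grouped in
// blocks ending in 2x2 max-pooling, a dense ReLU layer and a softmax pair
// output. Trained with Adam on cross-entropy, seeded end to end
// (initialisation and data order), with early stopping on validation
// accuracy and best-epoch weight retention. Single precision throughout.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::umat;

namespace {

struct Layer {      // one conv layer
  fmat W;           // C_out x (C_in * 9)
  arma::fvec b;     // C_out
  int c_in, c_out;
};

struct Net {
  std::vector<Layer> conv;          // all conv layers, in order
  std::vector<int> pool_after;      // conv layer indices followed by a pool
  fmat Wd; arma::fvec bd;           // dense
  fmat Wo; arma::fvec bo;           // output (2 units)
};

// im2col for 3x3 kernels, zero padding 1. act: H x W x (C*B).
// Column-friendly layout: result is (H*W*B) x (C*9), so every (c, k)
// kernel offset fills one column with contiguous per-column memcpy runs.
fmat im2col(const fcube& act, int C, int B) {
  const int H = act.n_rows, W = act.n_cols, HW = H * W;
  fmat M((size_t)HW * B, C * 9, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 9; ++k) {
      const int di = k / 3 - 1, dj = k % 3 - 1;
      float* col = M.colptr((size_t)c * 9 + k);
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      const int len = i1 - i0;
      if (len <= 0) continue;
      for (int b = 0; b < B; ++b) {
        const float* src = act.slice((size_t)b * C + c).memptr();
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          std::memcpy(col + (size_t)b * HW + (size_t)j * H + i0,
                      src + (size_t)jj * H + i0 + di,
                      (size_t)len * sizeof(float));
        }
      }
    }
  }
  return M;
}

// col2im: scatter-add gradient dM ((H*W*B) x (C*9)) back onto the input
// activation layout.
fcube col2im(const fmat& dM, int H, int W, int C, int B) {
  fcube dA(H, W, C * B, arma::fill::zeros);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 9; ++k) {
      const int di = k / 3 - 1, dj = k % 3 - 1;
      const float* col = dM.colptr((size_t)c * 9 + k);
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      const int len = i1 - i0;
      if (len <= 0) continue;
      for (int b = 0; b < B; ++b) {
        float* dst = dA.slice((size_t)b * C + c).memptr();
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const float* s = col + (size_t)b * HW + (size_t)j * H + i0;
          float* d = dst + (size_t)jj * H + i0 + di;
          for (int i = 0; i < len; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dA;
}

// reshape conv GEMM output ((H*W*B) x C_out) into activation cube
fcube to_cube(const fmat& Out, int H, int W, int C, int B) {
  fcube A(H, W, C * B);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const float* col = Out.colptr(c);
    for (int b = 0; b < B; ++b)
      std::memcpy(A.slice((size_t)b * C + c).memptr(),
                  col + (size_t)b * HW, (size_t)HW * sizeof(float));
  }
  return A;
}

fmat from_cube(const fcube& A, int C, int B) {
  const int H = A.n_rows, W = A.n_cols, HW = H * W;
  fmat Out((size_t)HW * B, C);
  for (int c = 0; c < C; ++c) {
    float* col = Out.colptr(c);
    for (int b = 0; b < B; ++b)
      std::memcpy(col + (size_t)b * HW,
                  A.slice((size_t)b * C + c).memptr(),
                  (size_t)HW * sizeof(float));
  }
  return Out;
}

struct PoolCache { umat argmax; int H2, W2; };

fcube maxpool(const fcube& A, int C, int B, PoolCache& cache) {
  const int H = A.n_rows, W = A.n_cols, H2 = H / 2, W2 = W / 2;
  fcube P(H2, W2, C * B);
  cache.argmax.set_size((size_t)H2 * W2, C * B);
  cache.H2 = H2; cache.W2 = W2;
  for (int s = 0; s < C * B; ++s) {
    const fmat& a = A.slice(s);
    fmat& p = P.slice(s);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        float best = a(2 * i, 2 * j); int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const float v = a(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        p(i, j) = best;
        cache.argmax((size_t)j * H2 + i, s) = (size_t)bj * A.n_rows + bi;
      }
  }
  return P;
}

fcube maxpool_back(const fcube& dP, int H, int W, int C, int B,
                   const PoolCache& cache) {
  fcube dA(H, W, C * B, arma::fill::zeros);
  for (int s = 0; s < C * B; ++s) {
    const fmat& dp = dP.slice(s);
    fmat& da = dA.slice(s);
    for (int j = 0; j < cache.W2; ++j)
      for (int i = 0; i < cache.H2; ++i)
        da(cache.argmax((size_t)j * cache.H2 + i, s)) += dp(i, j);
  }
  return dA;
}

// flatten activations to feature matrix (feat x B)
fmat flatten(const fcube& A, int C, int B) {
  const int HW = A.n_rows * A.n_cols;
  fmat F((size_t)HW * C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      F.submat((size_t)c * HW, b, (size_t)(c + 1) * HW - 1, b) =
        arma::vectorise(A.slice(b * C + c));
  return F;
}

fcube unflatten(const fmat& dF, int H, int W, int C, int B) {
  const int HW = H * W;
  fcube dA(H, W, C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      dA.slice(b * C + c) =
        arma::reshape(dF.submat((size_t)c * HW, b,
                                (size_t)(c + 1) * HW - 1, b), H, W);
  return dA;
}

struct FwdCache {
  std::vector<fcube> inputs;     // input to each conv layer
  std::vector<fmat> cols;        // im2col of each conv input
  std::vector<fcube> outputs;    // post-ReLU conv outputs
  std::vector<PoolCache> pools;  // one per block
  std::vector<fcube> pooled;     // post-pool activations
  fmat F, A1, probs;             // flatten, dense hidden, softmax
};

fmat forward(const Net& net, const fcube& X, int C0, int B,
             FwdCache* cache, int convs_per_block) {
  fcube A = X;
  int C = C0;
  FwdCache local;
  FwdCache& cc = cache ? *cache : local;
  cc.inputs.clear(); cc.cols.clear(); cc.outputs.clear();
  cc.pools.clear(); cc.pooled.clear();
  size_t li = 0;
  const size_t n_blocks = net.conv.size() / convs_per_block;
  for (size_t blk = 0; blk < n_blocks; ++blk) {
    for (int v = 0; v < convs_per_block; ++v, ++li) {
      const Layer& L = net.conv[li];
      fmat M = im2col(A, C, B);
      fmat Out = M * L.W.t();
      Out.each_row() += L.b.t();
      Out.transform([](float x) { return x > 0.f ? x : 0.f; });
      fcube Anew = to_cube(Out, A.n_rows, A.n_cols, L.c_out, B);
      if (cache) { cc.inputs.push_back(A); cc.cols.push_back(std::move(M)); }
      A = std::move(Anew);
      if (cache) cc.outputs.push_back(A);
      C = L.c_out;
    }
    PoolCache pc;
    A = maxpool(A, C, B, pc);
    if (cache) { cc.pools.push_back(pc); cc.pooled.push_back(A); }
  }
  fmat F = flatten(A, C, B);
  fmat A1 = net.Wd * F;
  A1.each_col() += net.bd;
  A1.transform([](float x) { return x > 0.f ? x : 0.f; });
  fmat Z2 = net.Wo * A1;
  Z2.each_col() += net.bo;
  // softmax columns
  fmat P = Z2;
  for (size_t j = 0; j < P.n_cols; ++j) {
    const float m = P.col(j).max();
    P.col(j) = arma::exp(P.col(j) - m);
    P.col(j) /= arma::accu(P.col(j));
  }
  if (cache) { cc.F = std::move(F); cc.A1 = std::move(A1); cc.probs = P; }
  return P;
}

struct Grads {
  std::vector<fmat> dW; std::vector<arma::fvec> db;
  fmat dWd; arma::fvec dbd; fmat dWo; arma::fvec dbo;
};

void backward(const Net& net, const FwdCache& cc, const arma::ivec& y,
              int B, int convs_per_block, Grads& g) {
  // softmax + cross-entropy
  fmat dZ2 = cc.probs;
  for (int b = 0; b < B; ++b) dZ2(y[b], b) -= 1.f;
  dZ2 /= (float)B;
  g.dWo = dZ2 * cc.A1.t();
  g.dbo = arma::sum(dZ2, 1);
  fmat dA1 = net.Wo.t() * dZ2;
  dA1.elem(arma::find(cc.A1 <= 0.f)).zeros();
  g.dWd = dA1 * cc.F.t();
  g.dbd = arma::sum(dA1, 1);
  fmat dF = net.Wd.t() * dA1;

  const size_t n_blocks = net.conv.size() / convs_per_block;
  const fcube& last = cc.pooled.back();
  const int C_last = net.conv.back().c_out;
  fcube dA = unflatten(dF, last.n_rows, last.n_cols, C_last, B);

  g.dW.resize(net.conv.size());
  g.db.resize(net.conv.size());
  int li = (int)net.conv.size() - 1;
  for (int blk = (int)n_blocks - 1; blk >= 0; --blk) {
    const fcube& pre_pool = cc.outputs[(size_t)(blk + 1) * convs_per_block - 1];
    dA = maxpool_back(dA, pre_pool.n_rows, pre_pool.n_cols,
                      net.conv[(size_t)(blk + 1) * convs_per_block - 1].c_out,
                      B, cc.pools[blk]);
    for (int v = convs_per_block - 1; v >= 0; --v, --li) {
      const Layer& L = net.conv[li];
      const fcube& out = cc.outputs[li];
      // ReLU gate
      for (size_t s = 0; s < dA.n_slices; ++s)
        dA.slice(s).elem(arma::find(out.slice(s) <= 0.f)).zeros();
      fmat dOut = from_cube(dA, L.c_out, B);
      g.dW[li] = dOut.t() * cc.cols[li];
      g.db[li] = arma::sum(dOut, 0).t();
      fmat dM = dOut * L.W;
      dA = col2im(dM, cc.inputs[li].n_rows, cc.inputs[li].n_cols, L.c_in, B);
    }
  }
}

struct Adam {
  std::vector<fmat> mW, vW; std::vector<arma::fvec> mb, vb;
  fmat mWd, vWd, mWo, vWo; arma::fvec mbd, vbd, mbo, vbo;
  long t = 0;
  void init(const Net& net) {
    for (const Layer& L : net.conv) {
      mW.push_back(arma::zeros<fmat>(arma::size(L.W)));
      vW.push_back(arma::zeros<fmat>(arma::size(L.W)));
      mb.push_back(arma::zeros<arma::fvec>(L.b.n_elem));
      vb.push_back(arma::zeros<arma::fvec>(L.b.n_elem));
    }
    mWd = arma::zeros<fmat>(arma::size(net.Wd));
    vWd = mWd; mbd = arma::zeros<arma::fvec>(net.bd.n_elem); vbd = mbd;
    mWo = arma::zeros<fmat>(arma::size(net.Wo));
    vWo = mWo; mbo = arma::zeros<arma::fvec>(net.bo.n_elem); vbo = mbo;
  }
  template <class M>
  void upd(M& w, M& m, M& v, const M& g, float lr) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const float c1 = 1 - std::pow(b1, (float)t);
    const float c2 = 1 - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  void step(Net& net, const Grads& g, float lr) {
    ++t;
    for (size_t i = 0; i < net.conv.size(); ++i) {
      upd(net.conv[i].W, mW[i], vW[i], g.dW[i], lr);
      upd(net.conv[i].b, mb[i], vb[i], g.db[i], lr);
    }
    upd(net.Wd, mWd, vWd, g.dWd, lr);
    upd(net.bd, mbd, vbd, g.dbd, lr);
    upd(net.Wo, mWo, vWo, g.dWo, lr);
    upd(net.bo, mbo, vbo, g.dbo, lr);
  }
};

fcube slice_batch(const fcube& X, const std::vector<int>& idx,
                  size_t from, size_t to, int C) {
  const int B = (int)(to - from);
  fcube Xb(X.n_rows, X.n_cols, (size_t)C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      Xb.slice((size_t)b * C + c) = X.slice((size_t)idx[from + b] * C + c);
  return Xb;
}

fcube as_cube(const NumericVector& x, int H, int W, int C, int N) {
  fcube X(H, W, (size_t)C * N);
  const double* p = REAL(x);
  float* q = X.memptr();
  const size_t n = (size_t)H * W * C * N;
  for (size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return X;
}

double accuracy(const Net& net, const fcube& X, const arma::ivec& y,
                int C, int convs_per_block) {
  const int N = (int)(X.n_slices / C);
  int correct = 0;
  const int BS = 256;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int s = 0; s < N; s += BS) {
    const int e = std::min(N, s + BS);
    fcube Xb = slice_batch(X, idx, s, e, C);
    fmat P = forward(net, Xb, C, e - s, nullptr, convs_per_block);
    for (int b = 0; b < e - s; ++b)
      if ((P(1, b) > P(0, b) ? 1 : 0) == y[s + b]) ++correct;
  }
  return (double)correct / N;
}

Net init_net(int C0, int H, const std::vector<int>& filters,
             int convs_per_block, int dense_width, std::mt19937& rng) {
  std::normal_distribution<float> nd(0.f, 1.f);
  Net net;
  int c_in = C0, side = H;
  for (int f : filters) {
    for (int v = 0; v < convs_per_block; ++v) {
      Layer L;
      L.c_in = c_in; L.c_out = f;
      const float sd = std::sqrt(2.f / (c_in * 9));
      L.W.set_size(f, c_in * 9);
      for (auto& w : L.W) w = sd * nd(rng);
      L.b = arma::zeros<arma::fvec>(f);
      net.conv.push_back(std::move(L));
      c_in = f;
    }
    side /= 2;
  }
  const int feat = side * side * c_in;
  const float sd_d = std::sqrt(2.f / feat);
  net.Wd.set_size(dense_width, feat);
  for (auto& w : net.Wd) w = sd_d * nd(rng);
  net.bd = arma::zeros<arma::fvec>(dense_width);
  const float sd_o = std::sqrt(2.f / dense_width);
  net.Wo.set_size(2, dense_width);
  for (auto& w : net.Wo) w = sd_o * nd(rng);
  net.bo = arma::zeros<arma::fvec>(2);
  return net;
}

List net_to_list(const Net& net) {
  List conv_w(net.conv.size()), conv_b(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i) {
    conv_w[i] = wrap(arma::conv_to<arma::mat>::from(net.conv[i].W));
    conv_b[i] = wrap(arma::conv_to<arma::vec>::from(net.conv[i].b));
  }
  return List::create(
    _["conv_w"] = conv_w, _["conv_b"] = conv_b,
    _["dense_w"] = wrap(arma::conv_to<arma::mat>::from(net.Wd)),
    _["dense_b"] = wrap(arma::conv_to<arma::vec>::from(net.bd)),
    _["out_w"] = wrap(arma::conv_to<arma::mat>::from(net.Wo)),
    _["out_b"] = wrap(arma::conv_to<arma::vec>::from(net.bo)));
}

Net net_from_list(const List& wl, int C0, int convs_per_block) {
  Net net;
  List conv_w = wl["conv_w"], conv_b = wl["conv_b"];
  int c_in = C0;
  for (int i = 0; i < conv_w.size(); ++i) {
    Layer L;
    L.W = arma::conv_to<fmat>::from(as<arma::mat>(conv_w[i]));
    L.b = arma::conv_to<arma::fvec>::from(as<arma::vec>(conv_b[i]));
    L.c_in = c_in; L.c_out = (int)L.W.n_rows;
    c_in = L.c_out;
    net.conv.push_back(std::move(L));
  }
  net.Wd = arma::conv_to<fmat>::from(as<arma::mat>(wl["dense_w"]));
  net.bd = arma::conv_to<arma::fvec>::from(as<arma::vec>(wl["dense_b"]));
  net.Wo = arma::conv_to<fmat>::from(as<arma::mat>(wl["out_w"]));
  net.bo = arma::conv_to<arma::fvec>::from(as<arma::vec>(wl["out_b"]));
  return net;
}

} // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(NumericVector x_train, IntegerVector y_train,
                   NumericVector x_val, IntegerVector y_val,
                   IntegerVector dims, IntegerVector filters,
                   int convs_per_block, int dense_width, double lr,
                   int batch_size, int max_epochs, int patience,
                   double min_delta, int seed) {
  const int H = dims[0], W = dims[1], C = dims[2];
  const int N = (int)(x_train.size() / ((size_t)H * W * C));
  const int Nv = (int)(x_val.size() / ((size_t)H * W * C));
  if (N == 0 || Nv == 0) stop("empty training or validation set");
  fcube X = as_cube(x_train, H, W, C, N);
  fcube Xv = as_cube(x_val, H, W, C, Nv);
  arma::ivec y(N), yv(Nv);
  for (int i = 0; i < N; ++i) y[i] = y_train[i];
  for (int i = 0; i < Nv; ++i) yv[i] = y_val[i];

  std::mt19937 rng((unsigned)seed);
  std::vector<int> filt(filters.begin(), filters.end());
  Net net = init_net(C, H, filt, convs_per_block, dense_width, rng);
  Adam opt; opt.init(net);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  std::vector<double> train_acc, val_acc;
  double best_val = -1.0;
  int best_epoch = 0, stall = 0;
  List best_weights = net_to_list(net);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    long correct = 0;
    for (int s = 0; s < N; s += batch_size) {
      const int e = std::min(N, s + batch_size);
      const int B = e - s;
      fcube Xb = slice_batch(X, idx, s, e, C);
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) yb[b] = y[idx[s + b]];
      FwdCache cc;
      forward(net, Xb, C, B, &cc, convs_per_block);
      if (!cc.probs.is_finite())
        stop("training diverged (non-finite loss) at epoch %d", epoch);
      for (int b = 0; b < B; ++b)
        if ((cc.probs(1, b) > cc.probs(0, b) ? 1 : 0) == yb[b]) ++correct;
      Grads g;
      backward(net, cc, yb, B, convs_per_block, g);
      opt.step(net, g, (float)lr);
    }
    const double tr = (double)correct / N;
    const double va = accuracy(net, Xv, yv, C, convs_per_block);
    train_acc.push_back(tr);
    val_acc.push_back(va);
    if (va > best_val + min_delta) {
      best_val = va; best_epoch = epoch; stall = 0;
      best_weights = net_to_list(net);
    } else {
      if (++stall >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["weights"] = best_weights,
    _["train_acc"] = wrap(train_acc),
    _["val_acc"] = wrap(val_acc),
    _["stopped_epoch"] = (int)train_acc.size(),
    _["best_epoch"] = best_epoch,
    _["best_val_acc"] = best_val);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(List weights, NumericVector x,
                              IntegerVector dims, int convs_per_block) {
  const int H = dims[0], W = dims[1], C = dims[2];
  const int N = (int)(x.size() / ((size_t)H * W * C));
  Net net = net_from_list(weights, C, convs_per_block);
  fcube X = as_cube(x, H, W, C, N);
  NumericMatrix out(N, 2);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  const int BS = 256;
  for (int s = 0; s < N; s += BS) {
    const int e = std::min(N, s + BS);
    fcube Xb = slice_batch(X, idx, s, e, C);
    fmat P = forward(net, Xb, C, e - s, nullptr, convs_per_block);
    for (int b = 0; b < e - s; ++b) {
      out(s + b, 0) = P(0, b);
      out(s + b, 1) = P(1, b);
    }
  }
  return out;
}

// Reference 3x3 same-padding convolution of a single channel with a single
// kernel (kernel given row-major as in im2col order), for unit testing the
// convolution path against a plain R loop.
// [[Rcpp::export(name = ".cnn_conv3x3_ref")]]
NumericMatrix cnn_conv3x3_ref(NumericMatrix img, NumericVector kernel9) {
  const int H = img.nrow(), W = img.ncol();
  fcube A(H, W, 1);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) A(i, j, 0) = (float)img(i, j);
  fmat M = im2col(A, 1, 1);
  fmat k(9, 1);
  for (int i = 0; i < 9; ++i) k(i, 0) = (float)kernel9[i];
  fmat Out = M * k;
  NumericMatrix res(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) res(i, j) = Out((size_t)j * H + i, 0);
  return res;
}
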