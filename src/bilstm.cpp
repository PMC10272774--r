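// Bidirectional LSTM sequence-to-sequence regressor.
//
// Stack of L bidirectional LSTM layers (H hidden units per direction, layer
// outputs are the 2H-concatenation of both directions) followed by a linear
// per-timestep read-out. Trained by backpropagation through time with Adam
// on mean squared error; inverted dropout after every recurrent layer.
//
// Data layout: a batch of B windows of length T is a single matrix of shape
// (features x B*T), time-major: columns [t*B, (t+1)*B) hold timestep t of
// all windows, so each timestep is a contiguous block and the per-step
// recurrence reduces to GEMMs. The input-to-hidden product for all
// timesteps is hoisted out of the recurrence as one large GEMM.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirParams { mat W; mat U; vec b; };

struct Net {
  int L, H, inDim;
  std::vector<DirParams> dirs;  // 2 per layer: forward then backward
  mat Wy;                       // 1 x 2H
  double by;
};

static Net netFromList(const Rcpp::List& lst) {
  Net net;
  net.L = Rcpp::as<int>(lst["nLayers"]);
  net.H = Rcpp::as<int>(lst["hidden"]);
  net.inDim = Rcpp::as<int>(lst["inputDim"]);
  Rcpp::List w = lst["weights"];
  for (int i = 0; i < 2 * net.L; ++i) {
    Rcpp::List d = w[i];
    DirParams dp;
    dp.W = Rcpp::as<mat>(d["W"]);
    dp.U = Rcpp::as<mat>(d["U"]);
    dp.b = Rcpp::as<vec>(d["b"]);
    net.dirs.push_back(dp);
  }
  net.Wy = Rcpp::as<mat>(lst["Wy"]);
  net.by = Rcpp::as<double>(lst["by"]);
  return net;
}

static Rcpp::List netToList(const Net& net) {
  Rcpp::List w(2 * net.L);
  for (int i = 0; i < 2 * net.L; ++i) {
    w[i] = Rcpp::List::create(Rcpp::Named("W") = net.dirs[i].W,
                              Rcpp::Named("U") = net.dirs[i].U,
                              Rcpp::Named("b") = net.dirs[i].b);
  }
  return Rcpp::List::create(
    Rcpp::Named("nLayers") = net.L, Rcpp::Named("hidden") = net.H,
    Rcpp::Named("inputDim") = net.inDim, Rcpp::Named("weights") = w,
    Rcpp::Named("Wy") = net.Wy, Rcpp::Named("by") = net.by);
}

static Net netZerosLike(const Net& net) {
  Net g = net;
  for (auto& d : g.dirs) { d.W.zeros(); d.U.zeros(); d.b.zeros(); }
  g.Wy.zeros();
  g.by = 0.0;
  return g;
}

struct DirCache { mat gates, c, h; };

// One direction of one layer over a time-major batch. X: (in x B*T).
static void lstmForward(const DirParams& p, const mat& X, int T, int B,
                        bool reverse, DirCache& cache) {
  const int H = p.U.n_cols;
  mat pre_all = p.W * X;
  pre_all.each_col() += p.b;
  cache.gates.set_size(4 * H, T * B);
  cache.c.set_size(H, T * B);
  cache.h.set_size(H, T * B);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (int step = 0; step < T; ++step) {
    const int t = reverse ? (T - 1 - step) : step;
    const int c0 = t * B, c1 = t * B + B - 1;
    mat pre = pre_all.cols(c0, c1) + p.U * h_prev;
    mat ig = sigm(pre.rows(0, H - 1));
    mat fg = sigm(pre.rows(H, 2 * H - 1));
    mat gg = tanh(pre.rows(2 * H, 3 * H - 1));
    mat og = sigm(pre.rows(3 * H, 4 * H - 1));
    mat ct = fg % c_prev + ig % gg;
    mat ht = og % tanh(ct);
    cache.gates.submat(0, c0, H - 1, c1) = ig;
    cache.gates.submat(H, c0, 2 * H - 1, c1) = fg;
    cache.gates.submat(2 * H, c0, 3 * H - 1, c1) = gg;
    cache.gates.submat(3 * H, c0, 4 * H - 1, c1) = og;
    cache.c.cols(c0, c1) = ct;
    cache.h.cols(c0, c1) = ht;
    h_prev = ht;
    c_prev = ct;
  }
}

// BPTT for one direction. dH: gradient wrt this direction's hidden outputs.
static void lstmBackward(const DirParams& p, const mat& X,
                         const DirCache& cache, const mat& dH, int T, int B,
                         bool reverse, DirParams& grad, mat& dX) {
  const int H = p.U.n_cols;
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  mat dgates_all(4 * H, T * B);
  for (int step = T - 1; step >= 0; --step) {
    const int t = reverse ? (T - 1 - step) : step;
    const int c0 = t * B, c1 = t * B + B - 1;
    mat ig = cache.gates.submat(0, c0, H - 1, c1);
    mat fg = cache.gates.submat(H, c0, 2 * H - 1, c1);
    mat gg = cache.gates.submat(2 * H, c0, 3 * H - 1, c1);
    mat og = cache.gates.submat(3 * H, c0, 4 * H - 1, c1);
    mat ct = cache.c.cols(c0, c1);
    mat tc = tanh(ct);
    mat dh = dH.cols(c0, c1) + dh_next;
    mat dog = dh % tc;
    mat dc = dh % og % (1.0 - tc % tc) + dc_next;
    mat c_prev, h_prev;
    if (step > 0) {
      const int tp = reverse ? (T - step) : (step - 1);
      c_prev = cache.c.cols(tp * B, tp * B + B - 1);
      h_prev = cache.h.cols(tp * B, tp * B + B - 1);
    } else {
      c_prev.zeros(H, B);
      h_prev.zeros(H, B);
    }
    mat dig = dc % gg;
    mat dfg = dc % c_prev;
    mat dgg = dc % ig;
    dc_next = dc % fg;
    mat dgate(4 * H, B);
    dgate.rows(0, H - 1) = dig % ig % (1.0 - ig);
    dgate.rows(H, 2 * H - 1) = dfg % fg % (1.0 - fg);
    dgate.rows(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    dgate.rows(3 * H, 4 * H - 1) = dog % og % (1.0 - og);
    dgates_all.cols(c0, c1) = dgate;
    grad.U += dgate * h_prev.t();
    dh_next = p.U.t() * dgate;
  }
  grad.W += dgates_all * X.t();
  grad.b += vec(sum(dgates_all, 1));
  dX += p.W.t() * dgates_all;
}

// Full forward + backward over one time-major batch; returns the MSE loss
// and fills `grad`. With dropout > 0 and rng != nullptr, inverted dropout
// is applied after every bidirectional layer.
static double lossGrad(const Net& net, const mat& X0, const rowvec& y, int T,
                       int B, double dropout, std::mt19937_64* rng,
                       Net& grad) {
  const int L = net.L, H = net.H;
  std::vector<mat> inputs(L + 1);   // layer inputs after dropout
  std::vector<mat> masks(L);
  std::vector<DirCache> caches(2 * L);
  inputs[0] = X0;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int l = 0; l < L; ++l) {
    lstmForward(net.dirs[2 * l], inputs[l], T, B, false, caches[2 * l]);
    lstmForward(net.dirs[2 * l + 1], inputs[l], T, B, true,
                caches[2 * l + 1]);
    mat out = join_cols(caches[2 * l].h, caches[2 * l + 1].h);
    if (dropout > 0.0 && rng != nullptr) {
      mat mask(out.n_rows, out.n_cols);
      const double keep = 1.0 - dropout;
      for (uword j = 0; j < mask.n_cols; ++j)
        for (uword i = 0; i < mask.n_rows; ++i)
          mask(i, j) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
      out %= mask;
      masks[l] = mask;
    }
    inputs[l + 1] = out;
  }
  rowvec pred = net.Wy * inputs[L] + net.by;
  rowvec err = pred - y;
  const double loss = accu(err % err) / err.n_elem;
  rowvec dy = 2.0 * err / err.n_elem;
  grad.Wy += dy * inputs[L].t();
  grad.by += accu(dy);
  mat dOut = net.Wy.t() * dy;
  for (int l = L - 1; l >= 0; --l) {
    if (dropout > 0.0 && rng != nullptr) dOut %= masks[l];
    mat dX(inputs[l].n_rows, inputs[l].n_cols, fill::zeros);
    lstmBackward(net.dirs[2 * l], inputs[l], caches[2 * l],
                 dOut.rows(0, H - 1), T, B, false, grad.dirs[2 * l], dX);
    lstmBackward(net.dirs[2 * l + 1], inputs[l], caches[2 * l + 1],
                 dOut.rows(H, 2 * H - 1), T, B, true, grad.dirs[2 * l + 1],
                 dX);
    dOut = dX;
  }
  return loss;
}

// [[Rcpp::export(name = ".bilstmInit")]]
Rcpp::List bilstmInit(int inputDim, int hidden, int nLayers, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  Net net;
  net.L = nLayers;
  net.H = hidden;
  net.inDim = inputDim;
  auto initMat = [&](int r, int c) {
    const double lim = 1.0 / std::sqrt(static_cast<double>(std::max(c, 1)));
    std::uniform_real_distribution<double> u(-lim, lim);
    mat M(r, c);
    for (int j = 0; j < c; ++j)
      for (int i = 0; i < r; ++i) M(i, j) = u(rng);
    return M;
  };
  for (int l = 0; l < nLayers; ++l) {
    const int in = (l == 0) ? inputDim : 2 * hidden;
    for (int d = 0; d < 2; ++d) {
      DirParams p;
      p.W = initMat(4 * hidden, in);
      p.U = initMat(4 * hidden, hidden);
      p.b = vec(4 * hidden, fill::zeros);
      p.b.subvec(hidden, 2 * hidden - 1).fill(1.0);  // open forget gates
      net.dirs.push_back(p);
    }
  }
  net.Wy = initMat(1, 2 * hidden);
  net.by = 0.0;
  return netToList(net);
}

// Gather windows `idx` (0-based) of cube X (features x N x T) into a
// time-major batch matrix (features x B*T).
static mat gatherBatch(const cube& X, const uvec& idx, int T) {
  const int B = idx.n_elem;
  mat out(X.n_rows, static_cast<uword>(B) * T);
  for (int t = 0; t < T; ++t)
    out.cols(t * B, t * B + B - 1) = X.slice(t).cols(idx);
  return out;
}

static rowvec gatherTargets(const mat& Y, const uvec& idx, int T) {
  const int B = idx.n_elem;
  rowvec out(static_cast<uword>(B) * T);
  for (int t = 0; t < T; ++t)
    out.subvec(t * B, t * B + B - 1) = Y.submat(idx, uvec{(uword)t}).t();
  return out;
}

// [[Rcpp::export(name = ".bilstmTrain")]]
Rcpp::List bilstmTrain(Rcpp::List params, arma::cube X, arma::mat Y,
                       int epochs, double lr, double dropout, int batchSize,
                       int seed) {
  Net net = netFromList(params);
  const int N = X.n_cols, T = X.n_slices;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  Net m = netZerosLike(net), v = netZerosLike(net);
  double beta1 = 0.9, beta2 = 0.999, epsA = 1e-8;
  long adamT = 0;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  vec lossLog(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epLoss = 0.0;
    int nBatch = 0;
    for (int start = 0; start < N; start += batchSize) {
      const int B = std::min(batchSize, N - start);
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = order[start + i];
      mat Xb = gatherBatch(X, idx, T);
      rowvec yb = gatherTargets(Y, idx, T);
      Net grad = netZerosLike(net);
      epLoss += lossGrad(net, Xb, yb, T, B, dropout, &rng, grad);
      ++nBatch;
      ++adamT;
      const double bc1 = 1.0 - std::pow(beta1, (double)adamT);
      const double bc2 = 1.0 - std::pow(beta2, (double)adamT);
      auto adamMat = [&](mat& w, mat& mm, mat& vv, const mat& g) {
        mm = beta1 * mm + (1 - beta1) * g;
        vv = beta2 * vv + (1 - beta2) * (g % g);
        w -= lr * (mm / bc1) / (sqrt(vv / bc2) + epsA);
      };
      for (int i = 0; i < 2 * net.L; ++i) {
        adamMat(net.dirs[i].W, m.dirs[i].W, v.dirs[i].W, grad.dirs[i].W);
        adamMat(net.dirs[i].U, m.dirs[i].U, v.dirs[i].U, grad.dirs[i].U);
        mat bw = net.dirs[i].b, bm = m.dirs[i].b, bv = v.dirs[i].b;
        adamMat(bw, bm, bv, mat(grad.dirs[i].b));
        net.dirs[i].b = bw;
        m.dirs[i].b = bm;
        v.dirs[i].b = bv;
      }
      adamMat(net.Wy, m.Wy, v.Wy, grad.Wy);
      m.by = beta1 * m.by + (1 - beta1) * grad.by;
      v.by = beta2 * v.by + (1 - beta2) * grad.by * grad.by;
      net.by -= lr * (m.by / bc1) / (std::sqrt(v.by / bc2) + epsA);
    }
    lossLog[ep] = epLoss / std::max(nBatch, 1);
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = netToList(net);
  out["log"] = Rcpp::NumericVector(lossLog.begin(), lossLog.end());
  return out;
}

// [[Rcpp::export(name = ".bilstmPredict")]]
arma::mat bilstmPredict(Rcpp::List params, arma::cube X) {
  Net net = netFromList(params);
  const int N = X.n_cols, T = X.n_slices;
  mat preds(N, T);
  const int chunk = 128;
  for (int start = 0; start < N; start += chunk) {
    const int B = std::min(chunk, N - start);
    uvec idx(B);
    for (int i = 0; i < B; ++i) idx[i] = start + i;
    mat Xb = gatherBatch(X, idx, T);
    std::vector<DirCache> caches(2 * net.L);
    mat in = Xb;
    for (int l = 0; l < net.L; ++l) {
      lstmForward(net.dirs[2 * l], in, T, B, false, caches[2 * l]);
      lstmForward(net.dirs[2 * l + 1], in, T, B, true, caches[2 * l + 1]);
      in = join_cols(caches[2 * l].h, caches[2 * l + 1].h);
    }
    rowvec y = net.Wy * in + net.by;
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < B; ++i) preds(start + i, t) = y[t * B + i];
  }
  return preds;
}

// [[Rcpp::export(name = ".bilstmLossGrad")]]
Rcpp::List bilstmLossGrad(Rcpp::List params, arma::cube X, arma::mat Y) {
  Net net = netFromList(params);
  const int N = X.n_cols, T = X.n_slices;
  uvec idx = regspace<uvec>(0, N - 1);
  mat Xb = gatherBatch(X, idx, T);
  rowvec yb = gatherTargets(Y, idx, T);
  Net grad = netZerosLike(net);
  const double loss = lossGrad(net, Xb, yb, T, N, 0.0, nullptr, grad);
  Rcpp::List g = netToList(grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = g);
}
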