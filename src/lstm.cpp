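// Stacked-LSTM sequence classifier: forward, backpropagation through time,
// batch normalization over the channel axis of the sequence output, inverted
// dropout and Adam, in single precision. The architecture is
//   LSTM(u1, sequence output) -> BatchNorm(u1) -> LSTM(u2) -> Dropout ->
//   Dense(d1, ReLU) -> Dropout -> Dense(d2, ReLU) -> Dense(1, sigmoid)
// All activations are stored transposed (channels x examples) and sequences
// time-major ((channels) x (T*B), block t in columns [t*B, (t+1)*B)): column
// blocks are contiguous in memory, and every non-recurrent product — input
// projections, weight gradients, batch norm — runs as one large GEMM across
// all timesteps. Only the recurrent products stay sequential.
// All randomness (init, shuffling, dropout) comes from one mt19937 stream so
// a fixed seed reproduces training bit-for-bit in single-threaded BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Rng {
  std::mt19937 eng;
  explicit Rng(uint32_t seed) : eng(seed) {}
  double unif() { return eng() * (1.0 / 4294967296.0); }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
  double gauss() {
    double u1 = std::max(unif(), 1e-12), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// weights live transposed: W is (out x in), applied as W * x
fmat glorot(Rng& rng, uword nout, uword nin) {
  double lim = std::sqrt(6.0 / double(nin + nout));
  fmat w(nout, nin);
  // fill in (in x out) iteration order so the draw sequence matches the
  // conventional orientation; layout is transposed, values are seed-stable
  for (uword j = 0; j < nin; ++j)
    for (uword i = 0; i < nout; ++i) w(i, j) = float(rng.unif(-lim, lim));
  return w;
}

// orthogonal recurrent initialization, one orthogonal block per gate;
// result is (4U x U)
fmat ortho_gates(Rng& rng, uword U) {
  fmat w(4 * U, U);
  for (int g = 0; g < 4; ++g) {
    mat a(U, U);
    for (uword j = 0; j < U; ++j)
      for (uword i = 0; i < U; ++i) a(i, j) = rng.gauss();
    mat Q, R;
    qr_econ(Q, R, a);
    for (uword j = 0; j < U; ++j)
      if (R(j, j) < 0) Q.col(j) *= -1.0;
    w.rows(g * U, (g + 1) * U - 1) = conv_to<fmat>::from(Q.t());
  }
  return w;
}

// Padé(7,6) tanh approximation, accurate to ~1e-7 on |x| < 4.97 and clamped
// to +/-1 beyond; branch-free polynomial loops auto-vectorize, unlike libm
// calls, and the transcendental work dominates the non-GEMM runtime.
inline float fast_tanh1(float x) {
  x = std::min(4.97f, std::max(-4.97f, x));
  float x2 = x * x;
  float a = x * (135135.0f + x2 * (17325.0f + x2 * (378.0f + x2)));
  float b = 135135.0f + x2 * (62370.0f + x2 * (3150.0f + x2 * 28.0f));
  return a / b;
}

inline void tanh_inplace(float* p, uword n) {
  for (uword k = 0; k < n; ++k) p[k] = fast_tanh1(p[k]);
}

inline void sigm_inplace(float* p, uword n) {
  for (uword k = 0; k < n; ++k) p[k] = 0.5f + 0.5f * fast_tanh1(0.5f * p[k]);
}

inline fmat fast_tanh(const fmat& x) {
  fmat out = x;
  tanh_inplace(out.memptr(), out.n_elem);
  return out;
}

inline fmat sigm(const fmat& x) {
  fmat out = x;
  sigm_inplace(out.memptr(), out.n_elem);
  return out;
}

struct Dims {
  uword T, D, U1, U2, D1, D2;
};

enum Par { WX1, WH1, B1, GAMMA, BETA, WX2, WH2, B2, W3, B3, W4, B4, W5, B5, NPAR };

std::vector<fmat> init_params(const Dims& dm, Rng& rng) {
  std::vector<fmat> p(NPAR);
  p[WX1] = glorot(rng, 4 * dm.U1, dm.D);
  p[WH1] = ortho_gates(rng, dm.U1);
  p[B1] = zeros<fmat>(4 * dm.U1, 1);
  p[B1].rows(dm.U1, 2 * dm.U1 - 1).fill(1.0f);  // forget bias
  p[GAMMA] = ones<fmat>(dm.U1, 1);
  p[BETA] = zeros<fmat>(dm.U1, 1);
  p[WX2] = glorot(rng, 4 * dm.U2, dm.U1);
  p[WH2] = ortho_gates(rng, dm.U2);
  p[B2] = zeros<fmat>(4 * dm.U2, 1);
  p[B2].rows(dm.U2, 2 * dm.U2 - 1).fill(1.0f);
  p[W3] = glorot(rng, dm.D1, dm.U2);
  p[B3] = zeros<fmat>(dm.D1, 1);
  p[W4] = glorot(rng, dm.D2, dm.D1);
  p[B4] = zeros<fmat>(dm.D2, 1);
  p[W5] = glorot(rng, 1, dm.D2);
  p[B5] = zeros<fmat>(1, 1);
  return p;
}

// activations of one LSTM layer over a batch, channels x (T*B)
struct LstmTape {
  fmat gates;  // 4U x (T*B), post-activation i|f|g|o
  fmat C;      // U x (T*B)
  fmat H;      // U x (T*B)
};

// X is D x (T*B) time-major; input projection is one GEMM, the recurrent
// part loops over contiguous column blocks
void lstm_forward(const fmat& X, const fmat& Wx, const fmat& Wh, const fmat& b,
                  uword T, uword U, LstmTape& tp) {
  const uword B = X.n_cols / T;
  tp.gates = Wx * X;
  tp.gates.each_col() += b.col(0);
  tp.C.set_size(U, T * B);
  tp.H.set_size(U, T * B);
  fmat H(U, B, fill::zeros), C(U, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const uword c0 = t * B, c1 = (t + 1) * B - 1;
    auto z = tp.gates.cols(c0, c1);
    z += Wh * H;
    // per-column gate segments are contiguous: i,f sigmoid | g tanh | o sigmoid
    for (uword col = 0; col < B; ++col) {
      float* p = tp.gates.colptr(c0 + col);
      sigm_inplace(p, 2 * U);
      tanh_inplace(p + 2 * U, U);
      sigm_inplace(p + 3 * U, U);
    }
    C = z.rows(U, 2 * U - 1) % C + z.rows(0, U - 1) % z.rows(2 * U, 3 * U - 1);
    H = z.rows(3 * U, 4 * U - 1) % fast_tanh(C);
    tp.C.cols(c0, c1) = C;
    tp.H.cols(c0, c1) = H;
  }
}

// BPTT; dH_seq (U x (T*B)) holds upstream gradients per timestep. Weight
// gradients and dX are single GEMMs over the flattened tapes.
void lstm_backward(const fmat& X, const fmat& Wx, const fmat& Wh, uword T,
                   uword U, const LstmTape& tp, const fmat& dH_seq, fmat& dWx,
                   fmat& dWh, fmat& db, fmat* dX, bool want_dx) {
  const uword B = X.n_cols / T;
  fmat dZall(4 * U, T * B);
  fmat dH(U, B, fill::zeros), dC(U, B, fill::zeros), tc;
  for (uword t = T; t-- > 0;) {
    const uword c0 = t * B, c1 = (t + 1) * B - 1;
    dH += dH_seq.cols(c0, c1);
    const auto gt = tp.gates.cols(c0, c1);
    const auto i = gt.rows(0, U - 1);
    const auto f = gt.rows(U, 2 * U - 1);
    const auto g = gt.rows(2 * U, 3 * U - 1);
    const auto o = gt.rows(3 * U, 4 * U - 1);
    tc = fast_tanh(tp.C.cols(c0, c1));
    dC += dH % o % (1.0f - tc % tc);
    auto dZ = dZall.cols(c0, c1);
    dZ.rows(0, U - 1) = (dC % g) % i % (1.0f - i);
    if (t == 0)
      dZ.rows(U, 2 * U - 1).zeros();
    else
      dZ.rows(U, 2 * U - 1) =
          (dC % tp.C.cols(c0 - B, c0 - 1)) % f % (1.0f - f);
    dZ.rows(2 * U, 3 * U - 1) = (dC % i) % (1.0f - g % g);
    dZ.rows(3 * U, 4 * U - 1) = (dH % tc) % o % (1.0f - o);
    dH = Wh.t() * dZ;
    dC = dC % f;
  }
  dWx = dZall * X.t();
  // recurrent gradient against H shifted one block (zeros enter at t = 0)
  fmat Hprev(U, T * B, fill::zeros);
  if (T > 1) Hprev.cols(B, T * B - 1) = tp.H.cols(0, (T - 1) * B - 1);
  dWh = dZall * Hprev.t();
  db = sum(dZall, 1);
  if (want_dx) *dX = Wx.t() * dZall;
}

struct Adam {
  std::vector<fmat> m, v;
  double lr, b1, b2, eps;
  long step = 0;
  Adam(const std::vector<fmat>& p, double lr_) : lr(lr_), b1(0.9), b2(0.999), eps(1e-7) {
    for (const fmat& w : p) {
      m.push_back(zeros<fmat>(w.n_rows, w.n_cols));
      v.push_back(zeros<fmat>(w.n_rows, w.n_cols));
    }
  }
  void update(std::vector<fmat>& p, const std::vector<fmat>& g) {
    ++step;
    double c1 = 1.0 - std::pow(b1, double(step));
    double c2 = 1.0 - std::pow(b2, double(step));
    for (size_t k = 0; k < p.size(); ++k) {
      m[k] = float(b1) * m[k] + float(1.0 - b1) * g[k];
      v[k] = float(b2) * v[k] + float(1.0 - b2) * (g[k] % g[k]);
      p[k] -= float(lr) * (m[k] / float(c1)) / (sqrt(v[k] / float(c2)) + float(eps));
    }
  }
};

// R array (N x T x D) -> D x (T*N) time-major
fmat as_time_major(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector dim = x.attr("dim");
  uword N = dim[0], T = dim[1], D = dim[2];
  fmat out(D, T * N);
  const double* p = x.begin();
  for (uword d = 0; d < D; ++d)
    for (uword t = 0; t < T; ++t)
      for (uword n = 0; n < N; ++n)
        out(d, t * N + n) = float(p[n + t * N + d * N * T]);
  return out;
}

// columns of every time block belonging to the minibatch
fmat batch_cols(const fmat& X, uword T, uword N, const uvec& idx) {
  const uword B = idx.n_elem;
  fmat out(X.n_rows, T * B);
  for (uword t = 0; t < T; ++t)
    out.cols(t * B, (t + 1) * B - 1) = X.cols(t * N + idx);
  return out;
}

vec predict_probs(const fmat& X, const std::vector<fmat>& p, const fmat& rmean,
                  const fmat& rvar, const Dims& dm) {
  const uword T = dm.T, B = X.n_cols / T;
  LstmTape tp1;
  lstm_forward(X, p[WX1], p[WH1], p[B1], T, dm.U1, tp1);
  fmat Y = tp1.H;
  Y.each_col() -= rmean.col(0);
  Y.each_col() %= p[GAMMA].col(0) / sqrt(rvar.col(0) + 1e-3f);
  Y.each_col() += p[BETA].col(0);
  LstmTape tp2;
  lstm_forward(Y, p[WX2], p[WH2], p[B2], T, dm.U2, tp2);
  fmat h2 = tp2.H.cols((T - 1) * B, T * B - 1);
  fmat a3 = p[W3] * h2;
  a3.each_col() += p[B3].col(0);
  a3 = clamp(a3, 0.0f, std::numeric_limits<float>::max());
  fmat a4 = p[W4] * a3;
  a4.each_col() += p[B4].col(0);
  a4 = clamp(a4, 0.0f, std::numeric_limits<float>::max());
  fmat z5 = p[W5] * a4;
  z5 += p[B5](0, 0);
  fmat pr = sigm(z5);
  vec out(B);
  for (uword b = 0; b < B; ++b) out(b) = double(pr(0, b));
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y,
                          Rcpp::NumericVector x_val, Rcpp::NumericVector y_val,
                          Rcpp::List dims, int epochs, int batch_size,
                          double learning_rate, double dropout_p,
                          double clip_norm, int seed, bool verbose) {
  Dims dm;
  dm.T = Rcpp::as<int>(dims["timesteps"]);
  dm.D = Rcpp::as<int>(dims["channels"]);
  dm.U1 = Rcpp::as<int>(dims["lstm1"]);
  dm.U2 = Rcpp::as<int>(dims["lstm2"]);
  dm.D1 = Rcpp::as<int>(dims["dense1"]);
  dm.D2 = Rcpp::as<int>(dims["dense2"]);

  fmat X = as_time_major(x);
  const uword N = X.n_cols / dm.T;
  fvec yv(N);
  for (uword i = 0; i < N; ++i) yv(i) = float(y[i]);
  bool has_val = x_val.size() > 0;
  fmat Xv;
  if (has_val) Xv = as_time_major(x_val);

  Rng rng{uint32_t(seed)};
  std::vector<fmat> par = init_params(dm, rng);
  Adam opt(par, learning_rate);
  fmat rmean(dm.U1, 1, fill::zeros), rvar(dm.U1, 1, fill::ones);
  const float bn_mom = 0.9f, bn_eps = 1e-3f;
  const float keep = float(1.0 - dropout_p);

  std::vector<double> h_loss, h_acc, h_vloss, h_vacc;
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // step decay: drop the step size for the final third of training to
    // settle the oscillation that plain Adam shows on recurrent nets
    if (epochs >= 3 && ep == (2 * epochs) / 3) opt.lr *= 0.3;
    for (uword i = N - 1; i > 0; --i) {
      uword j = uword(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    uword ep_correct = 0;
    for (uword b0 = 0; b0 < N; b0 += batch_size) {
      const uword b1i = std::min<uword>(b0 + batch_size - 1, N - 1);
      const uword B = b1i - b0 + 1;
      uvec idx(B);
      for (uword k = 0; k < B; ++k) idx(k) = order[b0 + k];
      fvec yb = yv(idx);
      fmat Xb = batch_cols(X, dm.T, N, idx);

      LstmTape tp1;
      lstm_forward(Xb, par[WX1], par[WH1], par[B1], dm.T, dm.U1, tp1);

      // batch norm over (batch x time) per channel — one flat pass
      const float Nbn = float(B * dm.T);
      fmat mu = sum(tp1.H, 1) / Nbn;
      fmat var = sum(tp1.H % tp1.H, 1) / Nbn - mu % mu;
      var = clamp(var, 0.0f, std::numeric_limits<float>::max());
      fmat invstd = 1.0f / sqrt(var + bn_eps);
      rmean = bn_mom * rmean + (1.0f - bn_mom) * mu;
      rvar = bn_mom * rvar + (1.0f - bn_mom) * var;
      fmat xhat = tp1.H;
      xhat.each_col() -= mu.col(0);
      xhat.each_col() %= invstd.col(0);
      fmat Y = xhat;
      Y.each_col() %= par[GAMMA].col(0);
      Y.each_col() += par[BETA].col(0);

      LstmTape tp2;
      lstm_forward(Y, par[WX2], par[WH2], par[B2], dm.T, dm.U2, tp2);
      fmat h2 = tp2.H.cols((dm.T - 1) * B, dm.T * B - 1);

      fmat mask1(dm.U2, B), mask2(dm.D1, B);
      for (uword j = 0; j < mask1.n_elem; ++j)
        mask1(j) = rng.unif() < keep ? 1.0f / keep : 0.0f;
      for (uword j = 0; j < mask2.n_elem; ++j)
        mask2(j) = rng.unif() < keep ? 1.0f / keep : 0.0f;

      fmat h2d = h2 % mask1;
      fmat z3 = par[W3] * h2d;
      z3.each_col() += par[B3].col(0);
      fmat a3 = clamp(z3, 0.0f, std::numeric_limits<float>::max());
      fmat a3d = a3 % mask2;
      fmat z4 = par[W4] * a3d;
      z4.each_col() += par[B4].col(0);
      fmat a4 = clamp(z4, 0.0f, std::numeric_limits<float>::max());
      fmat z5 = par[W5] * a4;
      z5 += par[B5](0, 0);
      fmat pr = sigm(z5);

      for (uword k = 0; k < B; ++k) {
        float pk = std::min(std::max(pr(0, k), 1e-7f), 1.0f - 1e-7f);
        ep_loss -= yb(k) * std::log(pk) + (1.0f - yb(k)) * std::log(1.0f - pk);
        if ((pr(0, k) > 0.5f) == (yb(k) > 0.5f)) ++ep_correct;
      }

      // ---- backward ----
      std::vector<fmat> grad(NPAR);
      fmat dz5 = pr - fmat(yb).t();
      dz5 /= float(B);
      grad[W5] = dz5 * a4.t();
      grad[B5] = sum(dz5, 1);
      fmat da4 = par[W5].t() * dz5;
      fmat dz4 = da4 % conv_to<fmat>::from(z4 > 0.0f);
      grad[W4] = dz4 * a3d.t();
      grad[B4] = sum(dz4, 1);
      fmat da3 = (par[W4].t() * dz4) % mask2;
      fmat dz3 = da3 % conv_to<fmat>::from(z3 > 0.0f);
      grad[W3] = dz3 * h2d.t();
      grad[B3] = sum(dz3, 1);
      fmat dh2 = (par[W3].t() * dz3) % mask1;

      fmat dH2(dm.U2, dm.T * B, fill::zeros);
      dH2.cols((dm.T - 1) * B, dm.T * B - 1) = dh2;
      fmat dY;
      lstm_backward(Y, par[WX2], par[WH2], dm.T, dm.U2, tp2, dH2, grad[WX2],
                    grad[WH2], grad[B2], &dY, true);

      // batch-norm backward, statistics shared across batch and time
      grad[GAMMA] = sum(dY % xhat, 1);
      grad[BETA] = sum(dY, 1);
      fmat dxhat = dY;
      dxhat.each_col() %= par[GAMMA].col(0);
      fmat s1 = sum(dxhat, 1);
      fmat s2 = sum(dxhat % xhat, 1);
      fmat dH1 = Nbn * dxhat;
      dH1.each_col() -= s1.col(0);
      xhat.each_col() %= s2.col(0);  // xhat reused as xhat * s2
      dH1 -= xhat;
      dH1.each_col() %= invstd.col(0) / Nbn;

      lstm_backward(Xb, par[WX1], par[WH1], dm.T, dm.U1, tp1, dH1, grad[WX1],
                    grad[WH1], grad[B1], nullptr, false);

      // global-norm gradient clipping keeps recurrent training stable
      double gn2 = 0.0;
      for (const fmat& g : grad) gn2 += double(accu(g % g));
      double gn = std::sqrt(gn2);
      if (clip_norm > 0.0 && gn > clip_norm) {
        float sc = float(clip_norm / gn);
        for (fmat& g : grad) g *= sc;
      }

      opt.update(par, grad);
    }
    double tr_loss = ep_loss / double(N);
    double tr_acc = double(ep_correct) / double(N);
    double vl = NA_REAL, va = NA_REAL;
    if (has_val) {
      vec pv = predict_probs(Xv, par, rmean, rvar, dm);
      double l = 0.0;
      uword cor = 0;
      for (uword k = 0; k < pv.n_elem; ++k) {
        double pk = std::min(std::max(pv(k), 1e-7), 1.0 - 1e-7);
        l -= y_val[k] * std::log(pk) + (1.0 - y_val[k]) * std::log(1.0 - pk);
        if ((pv(k) > 0.5) == (y_val[k] > 0.5)) ++cor;
      }
      vl = l / double(pv.n_elem);
      va = double(cor) / double(pv.n_elem);
    }
    h_loss.push_back(tr_loss);
    h_acc.push_back(tr_acc);
    h_vloss.push_back(vl);
    h_vacc.push_back(va);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs << " loss " << tr_loss
                  << " acc " << tr_acc << (has_val ? " val_acc " : "")
                  << (has_val ? std::to_string(va) : std::string("")) << "\n";
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List wts(NPAR);
  for (int k = 0; k < NPAR; ++k) wts[k] = Rcpp::wrap(conv_to<mat>::from(par[k]));
  return Rcpp::List::create(
      Rcpp::Named("weights") = wts,
      Rcpp::Named("running_mean") = Rcpp::wrap(conv_to<mat>::from(rmean)),
      Rcpp::Named("running_var") = Rcpp::wrap(conv_to<mat>::from(rvar)),
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq(1, epochs),
          Rcpp::Named("loss") = h_loss, Rcpp::Named("accuracy") = h_acc,
          Rcpp::Named("val_loss") = h_vloss, Rcpp::Named("val_accuracy") = h_vacc));
}

// [[Rcpp::export(name = ".lstm_predict_cpp")]]
Rcpp::NumericVector lstm_predict_cpp(Rcpp::NumericVector x, Rcpp::List weights,
                                     Rcpp::NumericMatrix running_mean,
                                     Rcpp::NumericMatrix running_var,
                                     Rcpp::List dims) {
  Dims dm;
  dm.T = Rcpp::as<int>(dims["timesteps"]);
  dm.D = Rcpp::as<int>(dims["channels"]);
  dm.U1 = Rcpp::as<int>(dims["lstm1"]);
  dm.U2 = Rcpp::as<int>(dims["lstm2"]);
  dm.D1 = Rcpp::as<int>(dims["dense1"]);
  dm.D2 = Rcpp::as<int>(dims["dense2"]);
  fmat X = as_time_major(x);
  std::vector<fmat> par(NPAR);
  for (int k = 0; k < NPAR; ++k)
    par[k] = conv_to<fmat>::from(Rcpp::as<mat>(weights[k]));
  fmat rm = conv_to<fmat>::from(Rcpp::as<mat>(running_mean));
  fmat rv = conv_to<fmat>::from(Rcpp::as<mat>(running_var));
  vec pr = predict_probs(X, par, rm, rv, dm);
  return Rcpp::wrap(pr);
}
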