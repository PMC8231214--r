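// 1D convolution kernels for the behaviour classifier.
//
// Layout conventions (fixed across the package):
//   activations: cube (channels x length x batch), one slice per window
//   conv weights: matrix (out_channels x in_channels*kernel), column index
//                 ci + in_channels*k  (input channel fastest) -- i.e. the
//                 flattening of an R array dim (out, in, kernel)
// Convolutions are "valid" (no padding); out_length = floor((L-K)/stride)+1.
// The single-precision path mirrors on-device FP32 inference and roughly
// doubles GEMM throughput; gradients are accumulated in the same precision.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

template <typename eT>
static void im2col(const arma::Mat<eT>& x, int K, int stride,
                   arma::Mat<eT>& xcol) {
  const int C = x.n_rows;
  const int Lout = xcol.n_cols;
  for (int l = 0; l < Lout; ++l) {
    // columns l*stride .. l*stride+K-1 of x are contiguous (column-major)
    std::memcpy(xcol.colptr(l), x.colptr(l * stride),
                sizeof(eT) * (size_t)C * K);
  }
}

template <typename eT>
static void conv_fw_impl(const arma::Cube<eT>& X, const arma::Mat<eT>& W,
                         const arma::Col<eT>& b, int stride,
                         arma::Cube<eT>& Y) {
  const int Cin = X.n_rows;
  const int K = W.n_cols / Cin;
  const int Lout = Y.n_cols;
  arma::Mat<eT> xcol(Cin * K, Lout);
  for (arma::uword n = 0; n < X.n_slices; ++n) {
    im2col<eT>(X.slice(n), K, stride, xcol);
    Y.slice(n) = W * xcol;
    Y.slice(n).each_col() += b;
  }
}

template <typename eT>
static void conv_bw_impl(const arma::Cube<eT>& X, const arma::Mat<eT>& W,
                         const arma::Cube<eT>& dY, int stride,
                         arma::Cube<eT>& dX, arma::Mat<eT>& dW,
                         arma::Col<eT>& db) {
  const int Cin = X.n_rows;
  const int K = W.n_cols / Cin;
  const int Lout = dY.n_cols;
  arma::Mat<eT> xcol(Cin * K, Lout);
  arma::Mat<eT> dxcol(Cin * K, Lout);
  dX.zeros();
  dW.zeros();
  db.zeros();
  for (arma::uword n = 0; n < X.n_slices; ++n) {
    im2col<eT>(X.slice(n), K, stride, xcol);
    const arma::Mat<eT>& dy = dY.slice(n);
    dW += dy * xcol.t();
    db += arma::sum(dy, 1);
    dxcol = W.t() * dy;
    // col2im: scatter-add each output column back over its receptive field
    arma::Mat<eT>& dx = dX.slice(n);
    for (int l = 0; l < Lout; ++l) {
      eT* dst = dx.colptr(l * stride);
      const eT* src = dxcol.colptr(l);
      const size_t m = (size_t)Cin * K;
      for (size_t i = 0; i < m; ++i) dst[i] += src[i];
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fw_cpp(const arma::cube& X, const arma::mat& W,
                         const arma::vec& b, int stride, bool single_prec) {
  const int Cin = X.n_rows;
  const int K = W.n_cols / Cin;
  const int Lout = (X.n_cols - K) / stride + 1;
  if (Lout < 1) Rcpp::stop("input length %d shorter than kernel %d",
                           (int)X.n_cols, K);
  arma::cube Y(W.n_rows, Lout, X.n_slices);
  if (single_prec) {
    arma::fcube Xf = arma::conv_to<arma::fcube>::from(X);
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
    arma::fvec bf = arma::conv_to<arma::fvec>::from(b);
    arma::fcube Yf(W.n_rows, Lout, X.n_slices);
    conv_fw_impl<float>(Xf, Wf, bf, stride, Yf);
    Y = arma::conv_to<arma::cube>::from(Yf);
  } else {
    conv_fw_impl<double>(X, W, b, stride, Y);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bw_cpp(const arma::cube& X, const arma::mat& W,
                         const arma::cube& dY, int stride, bool single_prec) {
  arma::cube dX(X.n_rows, X.n_cols, X.n_slices);
  arma::mat dW(W.n_rows, W.n_cols);
  arma::vec db(W.n_rows);
  if (single_prec) {
    arma::fcube Xf = arma::conv_to<arma::fcube>::from(X);
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
    arma::fcube dYf = arma::conv_to<arma::fcube>::from(dY);
    arma::fcube dXf(X.n_rows, X.n_cols, X.n_slices);
    arma::fmat dWf(W.n_rows, W.n_cols);
    arma::fvec dbf(W.n_rows);
    conv_bw_impl<float>(Xf, Wf, dYf, stride, dXf, dWf, dbf);
    dX = arma::conv_to<arma::cube>::from(dXf);
    dW = arma::conv_to<arma::mat>::from(dWf);
    db = arma::conv_to<arma::vec>::from(dbf);
  } else {
    conv_bw_impl<double>(X, W, dY, stride, dX, dW, db);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// ---- IEEE 754 binary16 rounding ------------------------------------------
// Round-to-nearest-even double -> half -> double, used to emulate FP16
// weight storage without a native half type.

static uint16_t float_to_half_bits(float f) {
  uint32_t x;
  std::memcpy(&x, &f, 4);
  const uint32_t sign = (x >> 16) & 0x8000u;
  const uint32_t fexp = (x >> 23) & 0xffu;
  uint32_t mant = x & 0x7fffffu;
  if (fexp == 0xffu) return (uint16_t)(sign | 0x7c00u | (mant ? 0x200u : 0u));
  int32_t hexp = (int32_t)fexp - 127 + 15;
  if (hexp >= 31) return (uint16_t)(sign | 0x7c00u); // overflow -> inf
  if (hexp <= 0) {                                   // subnormal half
    if (hexp < -10) return (uint16_t)sign;           // underflow -> 0
    mant |= 0x800000u;
    const int shift = 14 - hexp; // in [14, 24]
    uint32_t a = mant >> shift;
    const uint32_t rem = mant & ((1u << shift) - 1u);
    const uint32_t half = 1u << (shift - 1);
    if (rem > half || (rem == half && (a & 1u))) ++a;
    return (uint16_t)(sign | a);
  }
  uint32_t a = mant >> 13;
  const uint32_t rem = mant & 0x1fffu;
  if (rem > 0x1000u || (rem == 0x1000u && (a & 1u))) ++a;
  // mantissa carry propagates into the exponent field correctly
  return (uint16_t)(sign | (((uint32_t)hexp << 10) + a));
}

static float half_bits_to_float(uint16_t h) {
  const uint32_t sign = ((uint32_t)h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1fu;
  uint32_t mant = h & 0x3ffu;
  uint32_t x;
  if (exp == 0x1fu) {
    x = sign | 0x7f800000u | (mant << 13);
  } else if (exp == 0) {
    if (mant == 0) {
      x = sign;
    } else { // subnormal: renormalise
      int e = -1;
      do { ++e; mant <<= 1; } while (!(mant & 0x400u));
      mant &= 0x3ffu;
      x = sign | ((uint32_t)(127 - 15 - e) << 23) | (mant << 13);
    }
  } else {
    x = sign | ((exp - 15 + 127) << 23) | (mant << 13);
  }
  float f;
  std::memcpy(&f, &x, 4);
  return f;
}

// [[Rcpp::export]]
Rcpp::NumericVector fp16_round_cpp(Rcpp::NumericVector x) {
  Rcpp::NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = (double)half_bits_to_float(float_to_half_bits((float)x[i]));
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// mean over the time dimension: (C, L, N) -> (C, N)
// [[Rcpp::export]]
arma::mat pool_mean_cpp(const arma::cube& A) {
  arma::mat out(A.n_rows, A.n_slices);
  for (arma::uword n = 0; n < A.n_slices; ++n) {
    out.col(n) = arma::mean(A.slice(n), 1);
  }
  return out;
}

// adjoint of pool_mean: broadcast (C, N) / L over the time dimension
// [[Rcpp::export]]
arma::cube pool_expand_cpp(const arma::mat& dP, int L) {
  arma::cube out(dP.n_rows, L, dP.n_cols);
  for (arma::uword n = 0; n < dP.n_cols; ++n) {
    out.slice(n) = arma::repmat(dP.col(n) / (double)L, 1, L);
  }
  return out;
}

// ---- fused dropout + batch-norm + ReLU -----------------------------------
// One pass over the activation cube instead of ~8 vectorised R passes.
// The dropout mask (already scaled by 1/(1-p)) is generated in R so that
// training remains reproducible from R's RNG alone.

// [[Rcpp::export]]
Rcpp::List bn_act_fw_cpp(const arma::cube& Z,
                         Rcpp::Nullable<Rcpp::NumericVector> mask_,
                         const arma::vec& gamma, const arma::vec& beta,
                         const arma::vec& run_mean, const arma::vec& run_var,
                         bool train, bool keep_cache, double momentum,
                         double eps) {
  const arma::uword C = Z.n_rows, L = Z.n_cols, N = Z.n_slices;
  const size_t total = (size_t)C * L * N;
  const double* maskp = nullptr;
  Rcpp::NumericVector maskv;
  if (mask_.isNotNull()) {
    maskv = mask_.get();
    maskp = maskv.begin();
  }
  arma::cube U(C, L, N);
  const double* zp = Z.memptr();
  double* up = U.memptr();
  if (maskp) {
    for (size_t i = 0; i < total; ++i) up[i] = zp[i] * maskp[i];
  } else {
    std::memcpy(up, zp, total * sizeof(double));
  }
  arma::vec mu(C), var(C);
  if (train) {
    mu.zeros(); var.zeros();
    for (size_t j = 0; j < total; j += C) {
      for (arma::uword c = 0; c < C; ++c) {
        const double v = up[j + c];
        mu[c] += v; var[c] += v * v;
      }
    }
    const double inv = 1.0 / (double)(L * N);
    mu *= inv;
    var = var * inv - mu % mu;
    var.transform([](double v) { return v < 0 ? 0.0 : v; });
  } else {
    mu = run_mean; var = run_var;
  }
  const arma::vec sdinv = 1.0 / arma::sqrt(var + eps);
  arma::cube A(C, L, N);
  double* ap = A.memptr();
  arma::cube xhat;
  double* xp = nullptr;
  if (keep_cache) { xhat.set_size(C, L, N); xp = xhat.memptr(); }
  for (size_t j = 0; j < total; j += C) {
    for (arma::uword c = 0; c < C; ++c) {
      const double xh = (up[j + c] - mu[c]) * sdinv[c];
      if (xp) xp[j + c] = xh;
      const double v = gamma[c] * xh + beta[c];
      ap[j + c] = v > 0 ? v : 0.0;
    }
  }
  arma::vec nrm = run_mean, nrv = run_var;
  if (train) {
    nrm = (1 - momentum) * run_mean + momentum * mu;
    nrv = (1 - momentum) * run_var + momentum * var;
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("A") = A, Rcpp::Named("sdinv") = sdinv,
    Rcpp::Named("run_mean") = nrm, Rcpp::Named("run_var") = nrv);
  if (keep_cache) out["xhat"] = xhat;
  return out;
}

// backward of the fused op (batch-statistics normalisation):
// dA -> dZ plus batch-norm parameter gradients; the ReLU mask is
// reconstructed from the forward activation A.
// [[Rcpp::export]]
Rcpp::List bn_act_bw_cpp(const arma::cube& dA, const arma::cube& A,
                         const arma::cube& xhat, const arma::vec& sdinv,
                         const arma::vec& gamma,
                         Rcpp::Nullable<Rcpp::NumericVector> mask_) {
  const arma::uword C = dA.n_rows, L = dA.n_cols, N = dA.n_slices;
  const size_t total = (size_t)C * L * N;
  const double* dap = dA.memptr();
  const double* ap = A.memptr();
  const double* xp = xhat.memptr();
  const double* maskp = nullptr;
  Rcpp::NumericVector maskv;
  if (mask_.isNotNull()) {
    maskv = mask_.get();
    maskp = maskv.begin();
  }
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  arma::vec m_d(C, arma::fill::zeros), m_dx(C, arma::fill::zeros);
  arma::cube dxhat(C, L, N);
  double* dxp = dxhat.memptr();
  for (size_t j = 0; j < total; j += C) {
    for (arma::uword c = 0; c < C; ++c) {
      const double dv = ap[j + c] > 0 ? dap[j + c] : 0.0;
      dgamma[c] += dv * xp[j + c];
      dbeta[c] += dv;
      const double dxh = dv * gamma[c];
      dxp[j + c] = dxh;
      m_d[c] += dxh;
      m_dx[c] += dxh * xp[j + c];
    }
  }
  const double inv = 1.0 / (double)(L * N);
  m_d *= inv; m_dx *= inv;
  arma::cube dZ(C, L, N);
  double* dzp = dZ.memptr();
  for (size_t j = 0; j < total; j += C) {
    for (arma::uword c = 0; c < C; ++c) {
      const double du = sdinv[c] * (dxp[j + c] - m_d[c] - xp[j + c] * m_dx[c]);
      dzp[j + c] = maskp ? du * maskp[j + c] : du;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dZ") = dZ,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
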