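// Minimal CNN engine for the two reconstruction networks.
//
// Two fixed architecture families are implemented with explicit
// forward/backward passes on top of batched im2col + BLAS GEMM:
//   * a U-Net (encoder/decoder, concatenating skips, ELU) used for
//     emitter localization on an upsampled prediction grid;
//   * a plain residual DCNN (7 conv layers, ReLU, additive input skip)
//     used for spectral-PSF restoration.
// Activations live in a flat matrix of shape (B*H*W x C) — one column per
// channel, rows ordered sample-major then column-major within a sample —
// so every convolution in the whole batch is a single large GEMM.
// Parameters travel as named R lists of matrices/vectors; gradients are
// returned in the same structure so the R-side Adam loop stays generic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Tensor {
  fmat data;  // (B*H*W) x C
  int H = 0, W = 0, B = 0;
  int C() const { return data.n_cols; }
};

// Batched im2col for stride-1 same-padding convolution with odd kernel k.
// Output: (B*H*W) x (k*k*C); column c = di + k*dj + k*k*ch.
fmat im2col_b(const Tensor& X, const int k) {
  const int H = X.H, W = X.W, B = X.B, C = X.C(), p = (k - 1) / 2;
  const int HW = H * W;
  fmat M(B * HW, k * k * C);
  fmat pad(H + 2 * p, W + 2 * p);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < C; ++ch) {
      pad.zeros();
      pad.submat(p, p, p + H - 1, p + W - 1) =
          reshape(X.data.col(ch).subvec(b * HW, (b + 1) * HW - 1), H, W);
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          fmat blk = pad.submat(di, dj, di + H - 1, dj + W - 1);
          M.col(di + k * dj + k * k * ch)
              .subvec(b * HW, (b + 1) * HW - 1) = vectorise(blk);
        }
    }
  }
  return M;
}

// Transpose of im2col_b: scatter-add dM into an input-shaped tensor.
Tensor col2im_b(const fmat& dM, const int H, const int W, const int B,
                const int C, const int k) {
  const int p = (k - 1) / 2, HW = H * W;
  Tensor dX;
  dX.H = H; dX.W = W; dX.B = B;
  dX.data.zeros(B * HW, C);
  fmat pad(H + 2 * p, W + 2 * p);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < C; ++ch) {
      pad.zeros();
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          pad.submat(di, dj, di + H - 1, dj + W - 1) +=
              reshape(dM.col(di + k * dj + k * k * ch)
                          .subvec(b * HW, (b + 1) * HW - 1), H, W);
      dX.data.col(ch).subvec(b * HW, (b + 1) * HW - 1) =
          vectorise(pad.submat(p, p, p + H - 1, p + W - 1));
    }
  }
  return dX;
}

struct ConvCache {
  fmat M;   // im2col of the layer input
  fmat Z;   // pre-activation output (B*HW x Cout)
  int H = 0, W = 0, B = 0, Cin = 0, k = 0;
};

// act: 0 linear, 1 ELU, 2 ReLU
Tensor conv_fwd(const Tensor& X, const fmat& Wt, const fvec& b, const int k,
                const int act, ConvCache* cache) {
  Tensor Y;
  Y.H = X.H; Y.W = X.W; Y.B = X.B;
  fmat M = (k == 1) ? X.data : im2col_b(X, k);
  fmat Z = M * Wt;
  Z.each_row() += b.t();
  if (cache) {
    if (k != 1) cache->M = std::move(M);
    cache->Z = Z;
    cache->H = X.H; cache->W = X.W; cache->B = X.B;
    cache->Cin = X.C(); cache->k = k;
  }
  if (act == 1) Z.transform([](float v) { return v > 0 ? v : std::expm1(v); });
  else if (act == 2) Z.transform([](float v) { return v > 0 ? v : 0.0; });
  Y.data = std::move(Z);
  return Y;
}

// Backward through conv (+ activation); needs the layer input X again when
// k == 1 (its im2col is the input itself and is not cached).
Tensor conv_bwd(const ConvCache& cache, const fmat* Xdata, const fmat& Wt,
                const Tensor& dY, const int act, fmat& dW, fvec& db) {
  fmat dZ = dY.data;
  if (act == 1) {
    const fmat& Z = cache.Z;
    for (uword i = 0; i < dZ.n_elem; ++i)
      if (Z(i) <= 0) dZ(i) *= std::exp(Z(i));
  } else if (act == 2) {
    const fmat& Z = cache.Z;
    for (uword i = 0; i < dZ.n_elem; ++i)
      if (Z(i) <= 0) dZ(i) = 0.0;
  }
  const fmat& M = (cache.k == 1) ? *Xdata : cache.M;
  dW = M.t() * dZ;
  db = sum(dZ, 0).t();
  fmat dM = dZ * Wt.t();
  if (cache.k == 1) {
    Tensor dX;
    dX.H = cache.H; dX.W = cache.W; dX.B = cache.B;
    dX.data = std::move(dM);
    return dX;
  }
  return col2im_b(dM, cache.H, cache.W, cache.B, cache.Cin, cache.k);
}

// 2x2 max pooling (H, W even); idx stores the argmax row for each output.
Tensor maxpool2_fwd(const Tensor& X, umat& idx) {
  const int H = X.H, W = X.W, B = X.B, C = X.C();
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  Tensor Y;
  Y.H = Ho; Y.W = Wo; Y.B = B;
  Y.data.set_size(B * HWo, C);
  idx.set_size(B * HWo, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.data.colptr(c);
    float* yc = Y.data.colptr(c);
    uword* ic = idx.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          float best = -datum::inf;
          uword bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const uword r = b * HW + (2 * i + di) + (2 * j + dj) * H;
              if (xc[r] > best) { best = xc[r]; bi = r; }
            }
          yc[b * HWo + i + j * Ho] = best;
          ic[b * HWo + i + j * Ho] = bi;
        }
  }
  return Y;
}

Tensor maxpool2_bwd(const Tensor& dY, const umat& idx, const int H,
                    const int W) {
  Tensor dX;
  dX.H = H; dX.W = W; dX.B = dY.B;
  dX.data.zeros(dY.B * H * W, dY.C());
  for (int c = 0; c < dY.C(); ++c) {
    const float* dyc = dY.data.colptr(c);
    const uword* ic = idx.colptr(c);
    float* dxc = dX.data.colptr(c);
    for (uword r = 0; r < dY.data.n_rows; ++r) dxc[ic[r]] += dyc[r];
  }
  return dX;
}

// Transposed conv, kernel 2, stride 2 (doubles H and W).
// Weight rows ordered r = di + 2*dj + 4*ch.
uvec wrows(const int di, const int dj, const int Cin) {
  uvec rows(Cin);
  for (int ch = 0; ch < Cin; ++ch) rows(ch) = di + 2 * dj + 4 * ch;
  return rows;
}

Tensor convt2_fwd(const Tensor& X, const fmat& Wt, const fvec& b) {
  const int H = X.H, W = X.W, B = X.B, Cout = Wt.n_cols;
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  Tensor Y;
  Y.H = Ho; Y.W = Wo; Y.B = B;
  Y.data.set_size(B * HWo, Cout);
  Y.data.each_row() = b.t();
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      fmat Yb = X.data * Wt.rows(wrows(di, dj, X.C()));  // (B*HW x Cout)
      for (int co = 0; co < Cout; ++co) {
        const float* src = Yb.colptr(co);
        float* dst = Y.data.colptr(co);
        for (int b2 = 0; b2 < B; ++b2)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[b2 * HWo + (2 * i + di) + (2 * j + dj) * Ho] +=
                  src[b2 * HW + i + j * H];
      }
    }
  return Y;
}

Tensor convt2_bwd(const Tensor& X, const fmat& Wt, const Tensor& dY, fmat& dW,
                  fvec& db) {
  const int H = X.H, W = X.W, B = X.B, Cin = X.C(), Cout = Wt.n_cols;
  const int Ho = dY.H, HW = H * W, HWo = Ho * dY.W;
  dW.zeros(4 * Cin, Cout);
  db = sum(dY.data, 0).t();
  Tensor dX;
  dX.H = H; dX.W = W; dX.B = B;
  dX.data.zeros(B * HW, Cin);
  fmat dYb(B * HW, Cout);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      for (int co = 0; co < Cout; ++co) {
        const float* src = dY.data.colptr(co);
        float* dst = dYb.colptr(co);
        for (int b2 = 0; b2 < B; ++b2)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[b2 * HW + i + j * H] =
                  src[b2 * HWo + (2 * i + di) + (2 * j + dj) * Ho];
      }
      dW.rows(wrows(di, dj, Cin)) = X.data.t() * dYb;
      dX.data += dYb * Wt.rows(wrows(di, dj, Cin)).t();
    }
  return dX;
}

// Single-channel same-conv of one image with an arbitrary odd kernel
// (used for the Gaussian blur inside the localization loss).
fmat conv_same_1(const fmat& img, const fmat& kern) {
  Tensor X;
  X.H = img.n_rows; X.W = img.n_cols; X.B = 1;
  X.data = vectorise(img);
  fmat M = im2col_b(X, kern.n_rows);
  fvec w = vectorise(kern);
  return reshape(M * w, img.n_rows, img.n_cols);
}

// Same-conv of every sample/channel of a tensor with one kernel.
Tensor conv_same_t(const Tensor& X, const fmat& kern) {
  fmat M = im2col_b(X, kern.n_rows);
  // build a block weight applying the kernel channel-wise
  const int k2 = kern.n_elem, C = X.C();
  fmat Wt(k2 * C, C, fill::zeros);
  fvec w = vectorise(kern);
  for (int c = 0; c < C; ++c) Wt.col(c).subvec(c * k2, (c + 1) * k2 - 1) = w;
  Tensor Y;
  Y.H = X.H; Y.W = X.W; Y.B = X.B;
  Y.data = M * Wt;
  return Y;
}

// ------------------------------------------------------------- parameters

struct ParamSet {
  std::vector<std::string> names;
  std::vector<fmat> W;       // matrices (bias vectors stored as 1-col mats)
  std::vector<fmat> G;       // gradient accumulators
  int find(const std::string& nm) const {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == nm) return (int)i;
    Rcpp::stop("missing parameter: " + nm);
  }
  const fmat& get(const std::string& nm) const { return W[find(nm)]; }
  fvec getv(const std::string& nm) const { return vectorise(W[find(nm)]); }
  void accW(const std::string& nm, const fmat& g) { G[find(nm)] += g; }
  void accb(const std::string& nm, const fvec& g) { G[find(nm)] += g; }
};

ParamSet load_params(const Rcpp::List& P) {
  ParamSet ps;
  Rcpp::CharacterVector nms = P.names();
  for (int i = 0; i < P.size(); ++i) {
    ps.names.push_back(Rcpp::as<std::string>(nms[i]));
    Rcpp::NumericVector v = P[i];
    int nr = v.size(), nc = 1;
    if (v.hasAttribute("dim")) {
      Rcpp::IntegerVector d = v.attr("dim");
      nr = d[0]; nc = d[1];
    }
    fmat m(nr, nc);
    for (int e = 0; e < nr * nc; ++e) m(e) = (float)v[e];
    ps.W.push_back(m);
    ps.G.push_back(zeros<fmat>(m.n_rows, m.n_cols));
  }
  return ps;
}

Rcpp::List grads_to_list(const ParamSet& ps) {
  Rcpp::List G(ps.G.size());
  Rcpp::CharacterVector nms(ps.G.size());
  for (size_t i = 0; i < ps.G.size(); ++i) {
    nms[i] = ps.names[i];
    G[i] = Rcpp::wrap(conv_to<mat>::from(ps.G[i]));
  }
  G.names() = nms;
  return G;
}

Tensor from_cube(const cube& xb) {
  Tensor X;
  X.H = xb.n_rows; X.W = xb.n_cols; X.B = xb.n_slices;
  X.data.set_size(X.B * X.H * X.W, 1);
  const double* src = xb.memptr();
  float* dst = X.data.memptr();
  for (uword i = 0; i < xb.n_elem; ++i) dst[i] = (float)src[i];
  return X;
}

// ---------------------------------------------------------------- U-Net

struct UnetCaches {
  std::vector<ConvCache> enc1, enc2;
  std::vector<umat> pool_idx;
  std::vector<Tensor> enc_out;   // pre-pool activation (skip source)
  ConvCache bot1, bot2;
  std::vector<Tensor> up_in;     // input to each transposed conv
  std::vector<ConvCache> dec1, dec2;
  ConvCache out;
  Tensor out_in;                 // input of the 1x1 output conv
};

Tensor unet_forward(const ParamSet& P, const int depth, const Tensor& x,
                    UnetCaches* C) {
  Tensor a = x;
  std::vector<Tensor> skips(depth);
  if (C) {
    C->enc1.resize(depth); C->enc2.resize(depth);
    C->pool_idx.resize(depth); C->enc_out.resize(depth);
    C->up_in.resize(depth); C->dec1.resize(depth); C->dec2.resize(depth);
  }
  for (int d = 0; d < depth; ++d) {
    const std::string p = "enc" + std::to_string(d + 1);
    a = conv_fwd(a, P.get(p + "_c1_W"), P.getv(p + "_c1_b"), 3, 1,
                 C ? &C->enc1[d] : nullptr);
    a = conv_fwd(a, P.get(p + "_c2_W"), P.getv(p + "_c2_b"), 3, 1,
                 C ? &C->enc2[d] : nullptr);
    skips[d] = a;
    if (C) C->enc_out[d] = a;
    umat idx;
    a = maxpool2_fwd(a, idx);
    if (C) C->pool_idx[d] = std::move(idx);
  }
  a = conv_fwd(a, P.get("bot_c1_W"), P.getv("bot_c1_b"), 3, 1,
               C ? &C->bot1 : nullptr);
  a = conv_fwd(a, P.get("bot_c2_W"), P.getv("bot_c2_b"), 3, 1,
               C ? &C->bot2 : nullptr);
  for (int d = depth - 1; d >= 0; --d) {
    const std::string p = "dec" + std::to_string(d + 1);
    if (C) C->up_in[d] = a;
    Tensor up = convt2_fwd(a, P.get(p + "_up_W"), P.getv(p + "_up_b"));
    up.data = join_rows(up.data, skips[d].data);  // channel concat
    a = conv_fwd(up, P.get(p + "_c1_W"), P.getv(p + "_c1_b"), 3, 1,
                 C ? &C->dec1[d] : nullptr);
    a = conv_fwd(a, P.get(p + "_c2_W"), P.getv(p + "_c2_b"), 3, 1,
                 C ? &C->dec2[d] : nullptr);
  }
  if (C) C->out_in = a;
  a = conv_fwd(a, P.get("out_W"), P.getv("out_b"), 1, 0,
               C ? &C->out : nullptr);
  return a;
}

void unet_backward(ParamSet& P, const int depth, UnetCaches& C,
                   const Tensor& dOut) {
  fmat dW; fvec db;
  Tensor da = conv_bwd(C.out, &C.out_in.data, P.get("out_W"), dOut, 0, dW,
                       db);
  P.accW("out_W", dW); P.accb("out_b", db);
  std::vector<Tensor> skip_grads(depth);
  for (int d = 0; d < depth; ++d) {
    const std::string p = "dec" + std::to_string(d + 1);
    da = conv_bwd(C.dec2[d], nullptr, P.get(p + "_c2_W"), da, 1, dW, db);
    P.accW(p + "_c2_W", dW); P.accb(p + "_c2_b", db);
    da = conv_bwd(C.dec1[d], nullptr, P.get(p + "_c1_W"), da, 1, dW, db);
    P.accW(p + "_c1_W", dW); P.accb(p + "_c1_b", db);
    const int cout_up = P.get(p + "_up_W").n_cols;
    Tensor d_up;
    d_up.H = da.H; d_up.W = da.W; d_up.B = da.B;
    d_up.data = da.data.cols(0, cout_up - 1);
    skip_grads[d].H = da.H; skip_grads[d].W = da.W; skip_grads[d].B = da.B;
    skip_grads[d].data = da.data.cols(cout_up, da.data.n_cols - 1);
    da = convt2_bwd(C.up_in[d], P.get(p + "_up_W"), d_up, dW, db);
    P.accW(p + "_up_W", dW); P.accb(p + "_up_b", db);
  }
  da = conv_bwd(C.bot2, nullptr, P.get("bot_c2_W"), da, 1, dW, db);
  P.accW("bot_c2_W", dW); P.accb("bot_c2_b", db);
  da = conv_bwd(C.bot1, nullptr, P.get("bot_c1_W"), da, 1, dW, db);
  P.accW("bot_c1_W", dW); P.accb("bot_c1_b", db);
  for (int d = depth - 1; d >= 0; --d) {
    const std::string p = "enc" + std::to_string(d + 1);
    Tensor dpool = maxpool2_bwd(da, C.pool_idx[d], C.enc_out[d].H,
                                C.enc_out[d].W);
    dpool.data += skip_grads[d].data;
    da = conv_bwd(C.enc2[d], nullptr, P.get(p + "_c2_W"), dpool, 1, dW, db);
    P.accW(p + "_c2_W", dW); P.accb(p + "_c2_b", db);
    da = conv_bwd(C.enc1[d], nullptr, P.get(p + "_c1_W"), da, 1, dW, db);
    P.accW(p + "_c1_W", dW); P.accb(p + "_c1_b", db);
  }
}

cube tensor_to_cube(const Tensor& Y) {
  cube out(Y.H, Y.W, Y.B);
  const float* src = Y.data.memptr();
  double* dst = out.memptr();
  for (uword i = 0; i < Y.data.n_elem; ++i) dst[i] = (double)src[i];
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_unet_predict(Rcpp::List params, int depth,
                                     arma::cube xb) {
  ParamSet P = load_params(params);
  Tensor X = from_cube(xb);
  Tensor Y = unet_forward(P, depth, X, nullptr);
  return Rcpp::wrap(tensor_to_cube(Y));
}

// Combined localization loss over a batch:
//   L_i = || (pred_i - target_i) (x) g ||_2^2 + l1 * || pred_i ||_1,
// averaged over the batch; returns loss and gradient w.r.t. every parameter.
// [[Rcpp::export]]
Rcpp::List cpp_unet_loss_grad(Rcpp::List params, int depth, arma::cube xb,
                              arma::cube tb, arma::mat g, double l1_weight) {
  ParamSet P = load_params(params);
  const int B = xb.n_slices;
  const fmat gf = conv_to<fmat>::from(g);
  Tensor X = from_cube(xb);
  UnetCaches C;
  Tensor pred = unet_forward(P, depth, X, &C);
  Tensor D = pred;
  {
    Tensor T = from_cube(tb);
    D.data -= T.data;
  }
  Tensor Bl = conv_same_t(D, gf);
  const float loss =
      (accu(Bl.data % Bl.data) + l1_weight * accu(abs(pred.data))) / B;
  Tensor dPred = conv_same_t(Bl, gf);  // g is symmetric
  dPred.data = (2.0 * dPred.data + l1_weight * sign(pred.data)) / B;
  unet_backward(P, depth, C, dPred);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads_to_list(P));
}

static arma::mat conv_same_1d(const arma::mat& img, const arma::mat& kern) {
  const int k = kern.n_rows, p = (k - 1) / 2;
  const int H = img.n_rows, W = img.n_cols;
  arma::mat pad(H + 2 * p, W + 2 * p, arma::fill::zeros);
  pad.submat(p, p, p + H - 1, p + W - 1) = img;
  arma::mat out(H, W, arma::fill::zeros);
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di)
      out += kern(di, dj) * pad.submat(di, dj, di + H - 1, dj + W - 1);
  return out;
}

// [[Rcpp::export]]
double cpp_loss_loc(arma::mat pred, arma::mat target, arma::mat g,
                    double l1_weight) {
  arma::mat Bl = conv_same_1d(pred - target, g);
  return accu(Bl % Bl) + l1_weight * accu(abs(pred));
}

// [[Rcpp::export]]
arma::mat cpp_conv_same(arma::mat img, arma::mat kern) {
  return conv_same_1d(img, kern);
}

// ---------------------------------------------------------------- DCNN

namespace {

Tensor dcnn_forward(const ParamSet& P, const int n_layers, const Tensor& x,
                    std::vector<ConvCache>* C,
                    std::vector<Tensor>* inputs) {
  Tensor a = x;
  if (C) C->resize(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    const std::string p = "l" + std::to_string(l + 1);
    const int act = (l == n_layers - 1) ? 0 : 2;  // ReLU, last linear
    a = conv_fwd(a, P.get(p + "_W"), P.getv(p + "_b"), 3, act,
                 C ? &(*C)[l] : nullptr);
  }
  a.data += x.data;  // additive input skip
  return a;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_dcnn_predict(Rcpp::List params, int n_layers,
                                     arma::cube xb) {
  ParamSet P = load_params(params);
  Tensor X = from_cube(xb);
  Tensor Y = dcnn_forward(P, n_layers, X, nullptr, nullptr);
  return Rcpp::wrap(tensor_to_cube(Y));
}

// MSE enhancement loss (mean over pixels, averaged over the batch).
// [[Rcpp::export]]
Rcpp::List cpp_dcnn_loss_grad(Rcpp::List params, int n_layers, arma::cube xb,
                              arma::cube tb) {
  ParamSet P = load_params(params);
  const int B = xb.n_slices;
  const float npix = (float)xb.n_rows * xb.n_cols;
  Tensor X = from_cube(xb);
  std::vector<ConvCache> C;
  Tensor Y = dcnn_forward(P, n_layers, X, &C, nullptr);
  Tensor D = Y;
  {
    Tensor T = from_cube(tb);
    D.data -= T.data;
  }
  const float loss = accu(D.data % D.data) / (npix * B);
  Tensor da = D;
  da.data = 2.0 * D.data / (npix * B);
  fmat dW; fvec db;
  for (int l = n_layers - 1; l >= 0; --l) {
    const std::string p = "l" + std::to_string(l + 1);
    const int act = (l == n_layers - 1) ? 0 : 2;
    da = conv_bwd(C[l], nullptr, P.get(p + "_W"), da, act, dW, db);
    P.accW(p + "_W", dW); P.accb(p + "_b", db);
  }
  // the input skip contributes to dx only, not to any parameter
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads_to_list(P));
}
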