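// Hot inner loops of the 1-D CNN: valid convolution and max pooling,
// forward and backward. Activations are cubes of dim (length, batch,
// channels); convolution weights are (kernel * in_channels) x filters with
// the kernel index varying slowest, matching the R-side layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat build_x2(const arma::cube& A, int kernel) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int Lo = L - (kernel - 1);
  arma::mat X2(Lo * B, kernel * C);
  for (int k = 0; k < kernel; ++k)
    for (int c = 0; c < C; ++c) {
      double* dst = X2.colptr(k * C + c);
      for (int b = 0; b < B; ++b) {
        const double* src = A.slice_colptr(c, b) + k;
        std::copy(src, src + Lo, dst + b * Lo);
      }
    }
  return X2;
}

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::cube& A, const arma::mat& W,
                  const arma::vec& b, int kernel) {
  const int B = A.n_cols;
  const int Lo = A.n_rows - (kernel - 1);
  const int F = W.n_cols;
  arma::mat Z = build_x2(A, kernel) * W;
  Z.each_row() += b.t();
  Z.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::cube out(Z.memptr(), Lo, B, F);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& A, const arma::cube& out,
                  const arma::cube& dOut, const arma::mat& W, int kernel) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int Lo = dOut.n_rows, F = dOut.n_slices;
  arma::mat dZ(Lo * B, F);
  std::copy(dOut.memptr(), dOut.memptr() + dOut.n_elem, dZ.memptr());
  const double* relu = out.memptr();
  double* dz = dZ.memptr();
  for (size_t i = 0; i < dZ.n_elem; ++i)
    if (relu[i] <= 0) dz[i] = 0.0;
  arma::mat X2 = build_x2(A, kernel);
  arma::mat dW = X2.t() * dZ;
  arma::rowvec db = arma::sum(dZ, 0);
  arma::mat dX2 = dZ * W.t();
  arma::cube dA(L, B, C, arma::fill::zeros);
  for (int k = 0; k < kernel; ++k)
    for (int c = 0; c < C; ++c) {
      const double* src = dX2.colptr(k * C + c);
      for (int b = 0; b < B; ++b) {
        double* dst = dA.slice_colptr(c, b) + k;
        const double* s = src + b * Lo;
        for (int t = 0; t < Lo; ++t) dst[t] += s[t];
      }
    }
  return List::create(_["dA"] = dA, _["dW"] = dW,
                      _["db"] = arma::vec(db.t()));
}

// [[Rcpp::export]]
List cpp_pool_fwd(const arma::cube& A, int k, int stride) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int Lo = (L - k) / stride + 1;
  arma::cube out(Lo, B, C);
  arma::icube arg(Lo, B, C);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b) {
      const double* col = A.slice_colptr(c, b);
      double* o = out.slice_colptr(c, b);
      arma::sword* a = arg.slice_colptr(c, b);
      for (int t = 0; t < Lo; ++t) {
        int base = t * stride;
        double best = col[base];
        int bi = 0;
        for (int kk = 1; kk < k; ++kk)
          if (col[base + kk] > best) { best = col[base + kk]; bi = kk; }
        o[t] = best;
        a[t] = bi;
      }
    }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_pool_bwd(const arma::icube& arg, const arma::cube& dOut,
                        int L, int k, int stride) {
  const int Lo = dOut.n_rows, B = dOut.n_cols, C = dOut.n_slices;
  arma::cube dA(L, B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b) {
      const double* d = dOut.slice_colptr(c, b);
      const arma::sword* a = arg.slice_colptr(c, b);
      double* o = dA.slice_colptr(c, b);
      for (int t = 0; t < Lo; ++t)
        o[t * stride + a[t]] += d[t];
    }
  return dA;
}

// ---- full training loop ----------------------------------------------------
// One fold's entire Adam training run. All randomness (shuffling, dropout)
// is drawn from R's RNG so the R-level seed governs the result.

struct AdamState {
  arma::mat mW, vW;
  AdamState(int r, int c) : mW(r, c, arma::fill::zeros),
                            vW(r, c, arma::fill::zeros) {}
};

static void adam_update(arma::mat& p, const arma::mat& g, AdamState& s,
                        double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  s.mW = b1 * s.mW + (1 - b1) * g;
  s.vW = b2 * s.vW + (1 - b2) * arma::square(g);
  arma::mat mhat = s.mW / (1 - std::pow(b1, t));
  arma::mat vhat = s.vW / (1 - std::pow(b2, t));
  p -= lr * mhat / (arma::sqrt(vhat) + eps);
}

// [[Rcpp::export]]
List cpp_cnn_train(const arma::mat& X, const arma::ivec& yidx,
                   List conv_W, List conv_b,
                   arma::vec bn_gamma, arma::vec bn_beta,
                   arma::vec bn_mean, arma::vec bn_var,
                   arma::mat W1, arma::vec b1, arma::mat W2, arma::vec b2,
                   IntegerVector stage_convs, IntegerVector pool,
                   int pool_stride, int kernel, int classes,
                   double dropout, double lr, int batch_size, int epochs) {
  const int n = X.n_rows, L = X.n_cols;
  const int n_conv = conv_W.size();
  std::vector<arma::mat> Ws(n_conv), dWs(n_conv);
  std::vector<arma::vec> bs(n_conv);
  std::vector<AdamState> stW, stb;
  for (int i = 0; i < n_conv; ++i) {
    Ws[i] = as<arma::mat>(conv_W[i]);
    bs[i] = as<arma::vec>(conv_b[i]);
    stW.emplace_back(Ws[i].n_rows, Ws[i].n_cols);
    stb.emplace_back(bs[i].n_elem, 1);
  }
  AdamState stGamma(bn_gamma.n_elem, 1), stBeta(bn_beta.n_elem, 1);
  AdamState stW1(W1.n_rows, W1.n_cols), stb1(b1.n_elem, 1);
  AdamState stW2(W2.n_rows, W2.n_cols), stb2(b2.n_elem, 1);
  const double momentum = 0.9, bn_eps = 1e-5;
  double t_step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = Rcpp::sample(n, n);  // R RNG, 1-based
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int B = std::min(batch_size, n - b0);
      // assemble batch as cube (L, B, 1)
      arma::cube A(L, B, 1);
      arma::uvec rows(B);
      for (int i = 0; i < B; ++i) {
        rows[i] = ord[b0 + i] - 1;
        A.slice(0).col(i) = X.row(rows[i]).t();
      }
      // ---- forward ----
      std::vector<arma::cube> ins, outs;       // conv layer caches
      std::vector<arma::mat> x2s;              // cached im2col matrices
      std::vector<arma::icube> pargs;          // pool argmax caches
      std::vector<int> pool_inL;
      arma::mat bn_xhat; arma::vec bn_invstd;  // stage-1 batch norm cache
      int li = 0;
      for (int s = 0; s < stage_convs.size(); ++s) {
        for (int l = 0; l < stage_convs[s]; ++l, ++li) {
          ins.push_back(A);
          x2s.push_back(build_x2(A, kernel));
          arma::mat Z = x2s.back() * Ws[li];
          Z.each_row() += bs[li].t();
          Z.transform([](double v) { return v > 0 ? v : 0.0; });
          A = arma::cube(Z.memptr(), A.n_rows - (kernel - 1), B, Ws[li].n_cols);
          outs.push_back(A);
        }
        { // max pool
          const int k = pool[s];
          const int Li = A.n_rows, C = A.n_slices;
          const int Lo = (Li - k) / pool_stride + 1;
          pool_inL.push_back(Li);
          arma::cube po(Lo, B, C);
          arma::icube pa(Lo, B, C);
          for (int c = 0; c < C; ++c)
            for (int bb = 0; bb < B; ++bb) {
              const double* col = A.slice_colptr(c, bb);
              double* o = po.slice_colptr(c, bb);
              arma::sword* ai = pa.slice_colptr(c, bb);
              for (int t = 0; t < Lo; ++t) {
                int base = t * pool_stride;
                double best = col[base]; int bi = 0;
                for (int kk = 1; kk < k; ++kk)
                  if (col[base + kk] > best) { best = col[base + kk]; bi = kk; }
                o[t] = best; ai[t] = bi;
              }
            }
          pargs.push_back(pa);
          A = po;
        }
        if (s == 0) { // batch norm over (length x batch) per channel
          const int C = A.n_slices, N = A.n_rows * B;
          arma::mat Xm(A.memptr(), N, C);
          arma::rowvec mu = arma::mean(Xm, 0);
          arma::rowvec va = arma::mean(arma::square(Xm.each_row() - mu), 0);
          bn_mean = momentum * bn_mean + (1 - momentum) * mu.t();
          bn_var = momentum * bn_var + (1 - momentum) * va.t();
          bn_invstd = 1.0 / arma::sqrt(va.t() + bn_eps);
          bn_xhat = Xm.each_row() - mu;
          bn_xhat.each_row() %= bn_invstd.t();
          arma::mat Y = bn_xhat.each_row() % bn_gamma.t();
          Y.each_row() += bn_beta.t();
          A = arma::cube(Y.memptr(), A.n_rows, B, C);
        }
      }
      // flatten: (L, B, C) -> B x (L*C), length index fastest
      const int Lf = A.n_rows, Cf = A.n_slices, flat = Lf * Cf;
      arma::mat Xf(B, flat);
      for (int c = 0; c < Cf; ++c)
        for (int bb = 0; bb < B; ++bb)
          for (int t = 0; t < Lf; ++t)
            Xf(bb, c * Lf + t) = A(t, bb, c);
      arma::mat dmask;
      if (dropout > 0) {
        dmask.set_size(B, flat);
        const double keep = 1 - dropout;
        for (arma::uword i = 0; i < dmask.n_elem; ++i)
          dmask[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
        Xf %= dmask;
      }
      arma::mat Z1 = Xf * W1;
      Z1.each_row() += b1.t();
      arma::mat H = Z1;
      H.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat logits = H * W2;
      logits.each_row() += b2.t();
      arma::vec mx = arma::max(logits, 1);
      arma::mat P = arma::exp(logits.each_col() - mx);
      P.each_col() /= arma::sum(P, 1);
      // ---- backward ----
      arma::mat dlogits = P;
      for (int i = 0; i < B; ++i) dlogits(i, yidx[rows[i]] - 1) -= 1.0;
      dlogits /= B;
      arma::mat gW2 = H.t() * dlogits;
      arma::vec gb2 = arma::sum(dlogits, 0).t();
      arma::mat dH = dlogits * W2.t();
      arma::mat dZ1 = dH;
      for (arma::uword i = 0; i < dZ1.n_elem; ++i)
        if (Z1[i] <= 0) dZ1[i] = 0.0;
      arma::mat gW1 = Xf.t() * dZ1;
      arma::vec gb1 = arma::sum(dZ1, 0).t();
      arma::mat dXf = dZ1 * W1.t();
      if (dropout > 0) dXf %= dmask;
      arma::cube dA(Lf, B, Cf);
      for (int c = 0; c < Cf; ++c)
        for (int bb = 0; bb < B; ++bb)
          for (int t = 0; t < Lf; ++t)
            dA(t, bb, c) = dXf(bb, c * Lf + t);
      arma::vec gGamma(bn_gamma.n_elem, arma::fill::zeros);
      arma::vec gBeta(bn_beta.n_elem, arma::fill::zeros);
      std::vector<arma::mat> gWs(n_conv);
      std::vector<arma::vec> gbs(n_conv);
      li = n_conv - 1;
      for (int s = stage_convs.size() - 1; s >= 0; --s) {
        if (s == 0) { // batch-norm backward
          const int C = dA.n_slices, N = dA.n_rows * B;
          arma::mat dY(dA.memptr(), N, C);
          gGamma = arma::sum(dY % bn_xhat, 0).t();
          gBeta = arma::sum(dY, 0).t();
          arma::mat dxhat = dY.each_row() % bn_gamma.t();
          arma::rowvec s1 = arma::sum(dxhat, 0) / N;
          arma::rowvec s2 = arma::sum(dxhat % bn_xhat, 0) / N;
          arma::mat dX = dxhat;
          dX.each_row() -= s1;
          dX -= bn_xhat.each_row() % s2;
          dX.each_row() %= bn_invstd.t();
          dA = arma::cube(dX.memptr(), dA.n_rows, B, C);
        }
        { // pool backward
          const int k = pool[s];
          const int Li = pool_inL[s];
          const arma::icube& pa = pargs[s];
          const int Lo = dA.n_rows, C = dA.n_slices;
          arma::cube dAp(Li, B, C, arma::fill::zeros);
          for (int c = 0; c < C; ++c)
            for (int bb = 0; bb < B; ++bb) {
              const double* d = dA.slice_colptr(c, bb);
              const arma::sword* ai = pa.slice_colptr(c, bb);
              double* o = dAp.slice_colptr(c, bb);
              for (int t = 0; t < Lo; ++t)
                o[t * pool_stride + ai[t]] += d[t];
            }
          dA = dAp;
        }
        for (int l = stage_convs[s] - 1; l >= 0; --l, --li) {
          const arma::cube& Ain = ins[li];
          const arma::cube& Aout = outs[li];
          const int Lo = Aout.n_rows, F = Aout.n_slices;
          const int C = Ain.n_slices;
          arma::mat dZ(Lo * B, F);
          std::copy(dA.memptr(), dA.memptr() + dA.n_elem, dZ.memptr());
          const double* relu = Aout.memptr();
          for (arma::uword i = 0; i < dZ.n_elem; ++i)
            if (relu[i] <= 0) dZ[i] = 0.0;
          const arma::mat& X2 = x2s[li];
          gWs[li] = X2.t() * dZ;
          gbs[li] = arma::sum(dZ, 0).t();
          arma::mat dX2 = dZ * Ws[li].t();
          arma::cube dAi(Ain.n_rows, B, C, arma::fill::zeros);
          for (int k = 0; k < kernel; ++k)
            for (int c = 0; c < C; ++c) {
              const double* src = dX2.colptr(k * C + c);
              for (int bb = 0; bb < B; ++bb) {
                double* dst = dAi.slice_colptr(c, bb) + k;
                const double* sp = src + bb * Lo;
                for (int t = 0; t < Lo; ++t) dst[t] += sp[t];
              }
            }
          dA = dAi;
        }
      }
      // ---- Adam updates ----
      t_step += 1;
      for (int i = 0; i < n_conv; ++i) {
        adam_update(Ws[i], gWs[i], stW[i], lr, t_step);
        arma::mat btmp(bs[i].memptr(), bs[i].n_elem, 1, false, true);
        adam_update(btmp, gbs[i], stb[i], lr, t_step);
      }
      arma::mat gtmp(bn_gamma.memptr(), bn_gamma.n_elem, 1, false, true);
      adam_update(gtmp, gGamma, stGamma, lr, t_step);
      arma::mat btmp(bn_beta.memptr(), bn_beta.n_elem, 1, false, true);
      adam_update(btmp, gBeta, stBeta, lr, t_step);
      adam_update(W1, gW1, stW1, lr, t_step);
      arma::mat b1m(b1.memptr(), b1.n_elem, 1, false, true);
      adam_update(b1m, gb1, stb1, lr, t_step);
      adam_update(W2, gW2, stW2, lr, t_step);
      arma::mat b2m(b2.memptr(), b2.n_elem, 1, false, true);
      adam_update(b2m, gb2, stb2, lr, t_step);
    }
  }
  List convW_out(n_conv), convb_out(n_conv);
  for (int i = 0; i < n_conv; ++i) {
    convW_out[i] = Ws[i];
    convb_out[i] = bs[i];
  }
  return List::create(
    _["conv_W"] = convW_out, _["conv_b"] = convb_out,
    _["bn_gamma"] = bn_gamma, _["bn_beta"] = bn_beta,
    _["bn_mean"] = bn_mean, _["bn_var"] = bn_var,
    _["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2);
}
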