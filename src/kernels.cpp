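// Dense linear-algebra kernels for the network layers.
//
// Layout conventions:
//   1D signals:  cube (T x D x N)            -- one slice per trajectory
//   1D kernels:  cube (K x D x F)
//   2D images:   NumericVector dim (H, W, C, N)
//   2D kernels:  NumericVector dim (KH, KW, C, F)
// All convolutions are "valid" (no padding, stride 1); pooling drops the
// remainder, matching the shape arithmetic asserted in the R unit tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

// ---------------------------------------------------------------- conv1d ----

// [[Rcpp::export(name = ".conv1dForward")]]
arma::cube conv1dForward(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b) {
  const uword T = X.n_rows, D = X.n_cols, N = X.n_slices;
  const uword K = W.n_rows, F = W.n_slices;
  if (W.n_cols != D) stop("conv1d: channel mismatch");
  if (T < K) stop("conv1d: input shorter than kernel");
  const uword To = T - K + 1;
  cube out(To, F, N);
  // W.row(k) yields a D x F matrix (cols x slices)
  std::vector<mat> Wk(K);
  for (uword k = 0; k < K; ++k) Wk[k] = W.row(k);
  for (uword n = 0; n < N; ++n) {
    mat acc(To, F, arma::fill::zeros);
    for (uword k = 0; k < K; ++k)
      acc += X.slice(n).rows(k, k + To - 1) * Wk[k];
    acc.each_row() += b.t();
    out.slice(n) = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".conv1dBackward")]]
List conv1dBackward(const arma::cube& X, const arma::cube& W,
                    const arma::cube& dOut) {
  const uword T = X.n_rows, D = X.n_cols, N = X.n_slices;
  const uword K = W.n_rows, F = W.n_slices;
  const uword To = T - K + 1;
  if (dOut.n_rows != To || dOut.n_cols != F || dOut.n_slices != N)
    stop("conv1d backward: gradient shape mismatch");
  cube dX(T, D, N, arma::fill::zeros);
  cube dW(K, D, F, arma::fill::zeros);
  vec db(F, arma::fill::zeros);
  std::vector<mat> Wk(K), dWk(K, mat(D, F, arma::fill::zeros));
  for (uword k = 0; k < K; ++k) Wk[k] = W.row(k);
  for (uword n = 0; n < N; ++n) {
    const mat& G = dOut.slice(n);
    db += arma::sum(G, 0).t();
    for (uword k = 0; k < K; ++k) {
      dX.slice(n).rows(k, k + To - 1) += G * Wk[k].t();
      dWk[k] += X.slice(n).rows(k, k + To - 1).t() * G;
    }
  }
  for (uword k = 0; k < K; ++k) dW.row(k) = dWk[k];
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// -------------------------------------------------------------- maxpool1d ---

// [[Rcpp::export(name = ".maxpool1dForward")]]
List maxpool1dForward(const arma::cube& X, const int pool) {
  const uword T = X.n_rows, F = X.n_cols, N = X.n_slices;
  const uword p = (uword)pool;
  if (p < 1 || T < p) stop("maxpool1d: invalid pool size");
  const uword To = T / p;  // remainder frames dropped
  cube out(To, F, N);
  arma::ucube idx(To, F, N);  // 0-based source row
  for (uword n = 0; n < N; ++n)
    for (uword f = 0; f < F; ++f)
      for (uword t = 0; t < To; ++t) {
        uword best = t * p;
        double bv = X(best, f, n);
        for (uword j = 1; j < p; ++j)
          if (X(t * p + j, f, n) > bv) { bv = X(t * p + j, f, n); best = t * p + j; }
        out(t, f, n) = bv;
        idx(t, f, n) = best;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool1dBackward")]]
arma::cube maxpool1dBackward(const arma::ucube& idx, const arma::cube& dOut,
                             const int Tin) {
  const uword To = dOut.n_rows, F = dOut.n_cols, N = dOut.n_slices;
  cube dX((uword)Tin, F, N, arma::fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword f = 0; f < F; ++f)
      for (uword t = 0; t < To; ++t)
        dX(idx(t, f, n), f, n) += dOut(t, f, n);
  return dX;
}

// [[Rcpp::export(name = ".globalMaxpool1dForward")]]
List globalMaxpool1dForward(const arma::cube& X) {
  const uword T = X.n_rows, F = X.n_cols, N = X.n_slices;
  mat out(F, N);
  arma::umat idx(F, N);
  for (uword n = 0; n < N; ++n)
    for (uword f = 0; f < F; ++f) {
      uword best = 0; double bv = X(0, f, n);
      for (uword t = 1; t < T; ++t)
        if (X(t, f, n) > bv) { bv = X(t, f, n); best = t; }
      out(f, n) = bv; idx(f, n) = best;
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".globalMaxpool1dBackward")]]
arma::cube globalMaxpool1dBackward(const arma::umat& idx, const arma::mat& dOut,
                                   const int Tin) {
  const uword F = dOut.n_rows, N = dOut.n_cols;
  cube dX((uword)Tin, F, N, arma::fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword f = 0; f < F; ++f)
      dX(idx(f, n), f, n) = dOut(f, n);
  return dX;
}

// ---------------------------------------------------------------- conv2d ----
// gemm formulation: for each kernel offset (i,j),
//   out_flat(H'W' x F) += Xsub_flat(H'W' x C) * K[i,j,,](C x F)

static void dims4(const NumericVector& a, uword d[4]) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = (uword)dm[i];
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(const NumericVector& X, const NumericVector& Kn,
                            const arma::vec& b) {
  uword xd[4], kd[4];
  dims4(X, xd); dims4(Kn, kd);
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const uword KH = kd[0], KW = kd[1], F = kd[3];
  if (kd[2] != C) stop("conv2d: channel mismatch");
  if (H < KH || W < KW) stop("conv2d: input smaller than kernel");
  const uword Ho = H - KH + 1, Wo = W - KW + 1, P = Ho * Wo;
  NumericVector out(P * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  // kernel matrices per offset: C x F
  std::vector<mat> Km(KH * KW, mat(C, F));
  for (uword j = 0; j < KW; ++j)
    for (uword i = 0; i < KH; ++i)
      for (uword f = 0; f < F; ++f)
        for (uword c = 0; c < C; ++c)
          Km[j * KH + i](c, f) = Kn[i + KH * (j + KW * (c + C * f))];
  mat Xsub(P, C);
  for (uword n = 0; n < N; ++n) {
    const cube Xc(const_cast<double*>(&X[0]) + n * H * W * C, H, W, C, false, true);
    mat acc(P, F, arma::fill::zeros);
    for (uword j = 0; j < KW; ++j)
      for (uword i = 0; i < KH; ++i) {
        for (uword c = 0; c < C; ++c)
          Xsub.col(c) = arma::vectorise(Xc.slice(c).submat(i, j, i + Ho - 1, j + Wo - 1));
        acc += Xsub * Km[j * KH + i];
      }
    acc.each_row() += b.t();
    std::copy(acc.begin(), acc.end(), out.begin() + n * P * F);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(const NumericVector& X, const NumericVector& Kn,
                    const NumericVector& dOut) {
  uword xd[4], kd[4], od[4];
  dims4(X, xd); dims4(Kn, kd); dims4(dOut, od);
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const uword KH = kd[0], KW = kd[1], F = kd[3];
  const uword Ho = H - KH + 1, Wo = W - KW + 1, P = Ho * Wo;
  if (od[0] != Ho || od[1] != Wo || od[2] != F || od[3] != N)
    stop("conv2d backward: gradient shape mismatch");
  NumericVector dX(X.size());
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dK(Kn.size());
  dK.attr("dim") = IntegerVector::create(KH, KW, C, F);
  vec db(F, arma::fill::zeros);
  std::vector<mat> Km(KH * KW, mat(C, F)), dKm(KH * KW, mat(C, F, arma::fill::zeros));
  for (uword j = 0; j < KW; ++j)
    for (uword i = 0; i < KH; ++i)
      for (uword f = 0; f < F; ++f)
        for (uword c = 0; c < C; ++c)
          Km[j * KH + i](c, f) = Kn[i + KH * (j + KW * (c + C * f))];
  mat Xsub(P, C);
  for (uword n = 0; n < N; ++n) {
    const cube Xc(const_cast<double*>(&X[0]) + n * H * W * C, H, W, C, false, true);
    cube dXc(&dX[0] + n * H * W * C, H, W, C, false, true);
    const mat G(const_cast<double*>(&dOut[0]) + n * P * F, P, F, false, true);
    db += arma::sum(G, 0).t();
    for (uword j = 0; j < KW; ++j)
      for (uword i = 0; i < KH; ++i) {
        for (uword c = 0; c < C; ++c)
          Xsub.col(c) = arma::vectorise(Xc.slice(c).submat(i, j, i + Ho - 1, j + Wo - 1));
        dKm[j * KH + i] += Xsub.t() * G;
        mat dXsub = G * Km[j * KH + i].t();  // P x C
        for (uword c = 0; c < C; ++c)
          dXc.slice(c).submat(i, j, i + Ho - 1, j + Wo - 1) +=
            arma::reshape(dXsub.col(c), Ho, Wo);
      }
  }
  for (uword j = 0; j < KW; ++j)
    for (uword i = 0; i < KH; ++i)
      for (uword f = 0; f < F; ++f)
        for (uword c = 0; c < C; ++c)
          dK[i + KH * (j + KW * (c + C * f))] = dKm[j * KH + i](c, f);
  return List::create(_["dX"] = dX, _["dK"] = dK,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// -------------------------------------------------------------- maxpool2d ---

// [[Rcpp::export(name = ".maxpool2dForward")]]
List maxpool2dForward(const NumericVector& X, const int ph, const int pw) {
  uword xd[4]; dims4(X, xd);
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const uword PH = (uword)ph, PW = (uword)pw;
  if (PH < 1 || PW < 1 || H < PH || W < PW) stop("maxpool2d: invalid pool size");
  const uword Ho = H / PH, Wo = W / PW;
  NumericVector out(Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(out.size());  // 0-based linear index into X
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c) {
      const uword base = (n * C + c) * H * W;
      for (uword w = 0; w < Wo; ++w)
        for (uword h = 0; h < Ho; ++h) {
          uword best = base + (w * PW) * H + h * PH;
          double bv = X[best];
          for (uword jj = 0; jj < PW; ++jj)
            for (uword ii = 0; ii < PH; ++ii) {
              const uword k = base + (w * PW + jj) * H + h * PH + ii;
              if (X[k] > bv) { bv = X[k]; best = k; }
            }
          // column-major over (h, w) within (c, n)
          const uword oo = ((n * C + c) * Wo + w) * Ho + h;
          out[oo] = bv; idx[oo] = (int)best;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2dBackward")]]
NumericVector maxpool2dBackward(const IntegerVector& idx,
                                const NumericVector& dOut,
                                const IntegerVector& inDim) {
  NumericVector dX((int)(inDim[0] * inDim[1] * (double)inDim[2] * inDim[3]));
  dX.attr("dim") = inDim;
  for (int k = 0; k < dOut.size(); ++k) dX[idx[k]] += dOut[k];
  return dX;
}
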