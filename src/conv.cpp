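// Same-padded 3D convolution forward/backward on (nx, ny, nz, N, C)
// column-major tensors (kz = 1 degenerates to a 2D convolution). The hot
// path is a sum of K shifted GEMMs through Armadillo/BLAS; the shifted
// gather/scatter copies run over contiguous x-spans.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Geom {
  int nx, ny, nz, N, ci;
  int px, py, pz;        // padded spatial dims
  int p0, p1, p2;        // pad per axis
  long nsp, n, npadsp;
};

Geom geom(const IntegerVector& xdim, const IntegerVector& ksz) {
  Geom g;
  g.nx = xdim[0]; g.ny = xdim[1]; g.nz = xdim[2]; g.N = xdim[3]; g.ci = xdim[4];
  g.p0 = (ksz[0] - 1) / 2; g.p1 = (ksz[1] - 1) / 2; g.p2 = (ksz[2] - 1) / 2;
  g.px = g.nx + 2 * g.p0; g.py = g.ny + 2 * g.p1; g.pz = g.nz + 2 * g.p2;
  g.nsp = (long)g.nx * g.ny * g.nz;
  g.n = g.nsp * g.N;
  g.npadsp = (long)g.px * g.py * g.pz;
  return g;
}

// zero-padded copy of x, layout (px, py, pz, N, ci)
std::vector<double> pad_input(const NumericVector& x, const Geom& g) {
  std::vector<double> xp((size_t)g.npadsp * g.N * g.ci, 0.0);
  const double* xs = x.begin();
  for (int c = 0; c < g.ci; ++c)
    for (int s = 0; s < g.N; ++s)
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y) {
          const double* src = xs + ((((long)c * g.N + s) * g.nz + z) * g.ny + y) * g.nx;
          double* dst = &xp[(size_t)(((((long)c * g.N + s) * g.pz + (z + g.p2)) * g.py
                                      + (y + g.p1)) * g.px + g.p0)];
          std::copy(src, src + g.nx, dst);
        }
  return xp;
}

// gather the shifted slice for kernel offset (dx,dy,dz) into an (n, ci) matrix
void gather(const std::vector<double>& xp, const Geom& g, int dx, int dy, int dz,
            arma::mat& Xs) {
  for (int c = 0; c < g.ci; ++c) {
    double* col = Xs.colptr(c);
    for (int s = 0; s < g.N; ++s)
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y) {
          const double* src = &xp[(size_t)(((((long)c * g.N + s) * g.pz + (z + dz)) * g.py
                                            + (y + dy)) * g.px + dx)];
          std::copy(src, src + g.nx, col);
          col += g.nx;
        }
  }
}

// scatter-add an (n, ci) gradient slice back into the padded gradient buffer
void scatter_add(std::vector<double>& dxp, const Geom& g, int dx, int dy, int dz,
                 const arma::mat& dXs) {
  for (int c = 0; c < g.ci; ++c) {
    const double* col = dXs.colptr(c);
    for (int s = 0; s < g.N; ++s)
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y) {
          double* dst = &dxp[(size_t)(((((long)c * g.N + s) * g.pz + (z + dz)) * g.py
                                       + (y + dy)) * g.px + dx)];
          for (int i = 0; i < g.nx; ++i) dst[i] += col[i];
          col += g.nx;
        }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, IntegerVector xdim, NumericVector W,
                           IntegerVector ksz, NumericVector b) {
  Geom g = geom(xdim, ksz);
  const int K = ksz[0] * ksz[1] * ksz[2];
  const int co = W.size() / (K * g.ci);
  std::vector<double> xp = pad_input(x, g);
  arma::mat Y(g.n, co);
  for (int c = 0; c < co; ++c) Y.col(c).fill(b[c]);
  arma::mat Xs(g.n, g.ci);
  const double* Wp = W.begin();  // (K, ci, co)
  int k = 0;
  for (int dz = 0; dz < ksz[2]; ++dz)
    for (int dy = 0; dy < ksz[1]; ++dy)
      for (int dx = 0; dx < ksz[0]; ++dx, ++k) {
        gather(xp, g, dx, dy, dz, Xs);
        arma::mat Wk(g.ci, co);
        for (int c2 = 0; c2 < co; ++c2)
          for (int c1 = 0; c1 < g.ci; ++c1)
            Wk(c1, c2) = Wp[(long)c2 * K * g.ci + (long)c1 * K + k];
        Y += Xs * Wk;
      }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, g.N, co);
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, IntegerVector xdim, NumericVector dy,
                  NumericVector W, IntegerVector ksz) {
  Geom g = geom(xdim, ksz);
  const int K = ksz[0] * ksz[1] * ksz[2];
  const int co = W.size() / (K * g.ci);
  std::vector<double> xp = pad_input(x, g);
  std::vector<double> dxp((size_t)g.npadsp * g.N * g.ci, 0.0);
  arma::mat dY(dy.begin(), g.n, co, false);
  NumericVector dW(K * g.ci * co);
  NumericVector db(co);
  for (int c = 0; c < co; ++c) db[c] = arma::accu(dY.col(c));
  arma::mat Xs(g.n, g.ci);
  const double* Wp = W.begin();
  int k = 0;
  for (int dz = 0; dz < ksz[2]; ++dz)
    for (int dy_ = 0; dy_ < ksz[1]; ++dy_)
      for (int dx_ = 0; dx_ < ksz[0]; ++dx_, ++k) {
        gather(xp, g, dx_, dy_, dz, Xs);
        arma::mat dWk = Xs.t() * dY;            // (ci, co)
        for (int c2 = 0; c2 < co; ++c2)
          for (int c1 = 0; c1 < g.ci; ++c1)
            dW[(long)c2 * K * g.ci + (long)c1 * K + k] = dWk(c1, c2);
        arma::mat Wk(g.ci, co);
        for (int c2 = 0; c2 < co; ++c2)
          for (int c1 = 0; c1 < g.ci; ++c1)
            Wk(c1, c2) = Wp[(long)c2 * K * g.ci + (long)c1 * K + k];
        arma::mat dXs = dY * Wk.t();            // (n, ci)
        scatter_add(dxp, g, dx_, dy_, dz, dXs);
      }
  // unpad
  NumericVector dx((long)g.n * g.ci);
  double* dxs = dx.begin();
  for (int c = 0; c < g.ci; ++c)
    for (int s = 0; s < g.N; ++s)
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y) {
          const double* src = &dxp[(size_t)(((((long)c * g.N + s) * g.pz + (z + g.p2)) * g.py
                                             + (y + g.p1)) * g.px + g.p0)];
          double* dst = dxs + ((((long)c * g.N + s) * g.nz + z) * g.ny + y) * g.nx;
          std::copy(src, src + g.nx, dst);
        }
  dx.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, g.N, g.ci);
  dW.attr("dim") = IntegerVector::create(K, g.ci, co);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
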