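#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3-D "same"-padded cross-correlation support for the three-layer
// restoration network.  Activations are stored channel-major as
// (nvox x channels) blocks, voxels in column-major spatial order
// (x fastest).  Kernel weights use R's column-major array layout
// dim c(k, k, k, cin, cout), i.e. tap offsets fastest, then input
// channel, then output channel.

static inline size_t widx(int dx, int dy, int dz, int ci, int co, int k,
                          int cin) {
  return (size_t)dx +
         (size_t)k * ((size_t)dy +
                      (size_t)k * ((size_t)dz +
                                   (size_t)k * ((size_t)ci +
                                                (size_t)cin * (size_t)co)));
}

// out[., co] = b[co] + sum_ci W[., ci, co] (*) in[., ci], accumulated as
// shifted AXPY passes over contiguous x-runs.
static void conv_fwd(const double* in, double* out, const double* W,
                     const double* b, int d1, int d2, int d3, int k, int cin,
                     int cout) {
  const int nvox = d1 * d2 * d3;
  const int c = (k - 1) / 2;
  for (int co = 0; co < cout; ++co) {
    double* o = out + (size_t)co * nvox;
    for (int i = 0; i < nvox; ++i) o[i] = b[co];
    for (int ci = 0; ci < cin; ++ci) {
      const double* a = in + (size_t)ci * nvox;
      for (int dz = 0; dz < k; ++dz)
        for (int dy = 0; dy < k; ++dy)
          for (int dx = 0; dx < k; ++dx) {
            const double wv = W[widx(dx, dy, dz, ci, co, k, cin)];
            if (wv == 0.0) continue;
            const int ox0 = std::max(0, c - dx);
            const int ox1 = std::min(d1, d1 + c - dx);
            if (ox1 <= ox0) continue;
            for (int z = 0; z < d3; ++z) {
              const int zi = z + dz - c;
              if (zi < 0 || zi >= d3) continue;
              for (int y = 0; y < d2; ++y) {
                const int yi = y + dy - c;
                if (yi < 0 || yi >= d2) continue;
                const double* src =
                    a + ((size_t)zi * d2 + yi) * d1 + (ox0 + dx - c);
                double* dst = o + ((size_t)z * d2 + y) * d1 + ox0;
                const int n = ox1 - ox0;
                for (int i = 0; i < n; ++i) dst[i] += wv * src[i];
              }
            }
          }
    }
  }
}

static inline void relu_inplace(double* a, size_t n) {
  for (size_t i = 0; i < n; ++i)
    if (a[i] < 0) a[i] = 0;
}

// Forward pass of the residual three-layer network:
// out = (1 - w) * x + w * conv3(relu(conv2(relu(conv1(x))))).
// [[Rcpp::export]]
NumericVector srcnn_pass(NumericVector x, IntegerVector dims, List weights,
                         IntegerVector kernel_edges, IntegerVector channels,
                         double w) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int nvox = d1 * d2 * d3;
  if (x.size() != nvox) stop("input length does not match dims");
  const int k1 = kernel_edges[0], k2 = kernel_edges[1], k3 = kernel_edges[2];
  const int c1 = channels[0], c2 = channels[1];
  if (channels[2] != 1) stop("last layer must have one channel");

  List L1 = weights[0], L2 = weights[1], L3 = weights[2];
  NumericVector W1 = L1["W"], b1 = L1["b"], W2 = L2["W"], b2 = L2["b"],
                W3 = L3["W"], b3 = L3["b"];

  std::vector<double> A1((size_t)nvox * c1), A2((size_t)nvox * c2),
      f((size_t)nvox);
  conv_fwd(x.begin(), A1.data(), W1.begin(), b1.begin(), d1, d2, d3, k1, 1,
           c1);
  relu_inplace(A1.data(), A1.size());
  conv_fwd(A1.data(), A2.data(), W2.begin(), b2.begin(), d1, d2, d3, k2, c1,
           c2);
  relu_inplace(A2.data(), A2.size());
  conv_fwd(A2.data(), f.data(), W3.begin(), b3.begin(), d1, d2, d3, k3, c2,
           1);

  NumericVector out(nvox);
  for (int i = 0; i < nvox; ++i) out[i] = (1.0 - w) * x[i] + w * f[i];
  return out;
}

// Fill a preallocated (nvox x k^3*cin) matrix with the sliding k^3
// neighbourhoods of x (zero padded).  Column order: tap offsets
// column-major over (dx, dy, dz) with dx fastest, input channel slowest --
// the flattening R applies to an array of dim c(k, k, k, cin).  A "same"
// convolution is then a single GEMM with the flattened kernel, which is
// how the training loop reaches BLAS.  The buffer is modified in place
// and must arrive zero-initialised (matrix(0, ...)); zero-padded
// positions are never written, so they stay zero across reuses of the
// same buffer.  Callers own the buffer exclusively.
// [[Rcpp::export]]
void im2col_fill(NumericMatrix x, IntegerVector dims, int k,
                 NumericMatrix out) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int nvox = d1 * d2 * d3;
  const int cin = x.ncol();
  const int c = (k - 1) / 2;
  if (x.nrow() != nvox) stop("voxel count does not match dims");
  if (out.nrow() != nvox || out.ncol() != (R_xlen_t)k * k * k * cin)
    stop("workspace buffer has the wrong shape");
  const double* xp = x.begin();
  double* op = out.begin();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = xp + (size_t)ci * nvox;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const size_t col = ((size_t)((ci * k + dz) * k + dy)) * k + dx;
          double* o = op + col * nvox;
          const int ox0 = std::max(0, c - dx);
          const int ox1 = std::min(d1, d1 + c - dx);
          if (ox1 <= ox0) continue;
          for (int z = 0; z < d3; ++z) {
            const int zi = z + dz - c;
            if (zi < 0 || zi >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yi = y + dy - c;
              if (yi < 0 || yi >= d2) continue;
              const double* src =
                  xc + ((size_t)zi * d2 + yi) * d1 + (ox0 + dx - c);
              double* dst = o + ((size_t)z * d2 + y) * d1 + ox0;
              std::memcpy(dst, src, (size_t)(ox1 - ox0) * sizeof(double));
            }
          }
        }
  }
}
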