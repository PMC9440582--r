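#include <Rcpp.h>
using namespace Rcpp;

// Valid (no padding, stride 1) 1-D cross-correlation over a batch.
//
// X is an n x l x d array (sample, position, channel).  W is a (F*d) x C
// matrix whose row index is (f * d + k) for filter offset f (0-based) and
// input channel k; b has length C.  The result is an (n*P) x C matrix with
// P = l - F + 1 and row index (i * P + p) for sample i, output position p.

// [[Rcpp::export(name = ".conv1d_forward_cpp")]]
NumericMatrix conv1d_forward_cpp(NumericVector X, IntegerVector dims,
                                 NumericMatrix W, NumericVector b) {
  const int n = dims[0], l = dims[1], d = dims[2];
  const int Fd = W.nrow(), C = W.ncol();
  const int F = Fd / d;
  const int P = l - F + 1;
  if (F * d != Fd) stop("weight rows must equal filter size times channels");
  if (P < 1) stop("input length is smaller than the filter size");

  NumericMatrix Z(n * P, C);
  const double *x = X.begin();
  const double *w = W.begin();
  double *z = Z.begin();

  for (int c = 0; c < C; ++c) {
    const double *wc = w + (size_t)c * Fd;
    const double bc = b[c];
    for (int i = 0; i < n; ++i) {
      for (int p = 0; p < P; ++p) {
        double acc = bc;
        for (int k = 0; k < d; ++k) {
          // x[i + n*(pos) + n*l*k], pos = p + f
          const double *xk = x + i + (size_t)n * l * k + (size_t)n * p;
          const double *wk = wc + k;
          for (int f = 0; f < F; ++f) {
            acc += xk[(size_t)n * f] * wk[(size_t)d * f];
          }
        }
        z[(size_t)c * n * P + (size_t)i * P + p] = acc;
      }
    }
  }
  return Z;
}

// Gradient of the convolution with respect to weights and bias.  dZ is the
// (n*P) x C upstream gradient; rows holding only zeros are skipped, which
// makes the backward pass cheap after global max-pooling.

// [[Rcpp::export(name = ".conv1d_grad_cpp")]]
List conv1d_grad_cpp(NumericVector X, IntegerVector dims,
                     NumericMatrix dZ, int F) {
  const int n = dims[0], l = dims[1], d = dims[2];
  const int C = dZ.ncol();
  const int P = l - F + 1;
  if (dZ.nrow() != n * P) stop("gradient rows do not match batch layout");

  NumericMatrix dW(F * d, C);
  NumericVector db(C);
  const double *x = X.begin();
  const double *g = dZ.begin();
  double *dw = dW.begin();

  for (int c = 0; c < C; ++c) {
    const double *gc = g + (size_t)c * n * P;
    double *dwc = dw + (size_t)c * F * d;
    double accb = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int p = 0; p < P; ++p) {
        const double gv = gc[(size_t)i * P + p];
        if (gv == 0.0) continue;
        accb += gv;
        for (int k = 0; k < d; ++k) {
          const double *xk = x + i + (size_t)n * l * k + (size_t)n * p;
          double *dwk = dwc + k;
          for (int f = 0; f < F; ++f) {
            dwk[(size_t)d * f] += xk[(size_t)n * f] * gv;
          }
        }
      }
    }
    db[c] = accb;
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}
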