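#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 (as returned by the
// Butterworth designs used in this package). Single forward pass; the R
// wrapper composes forward and backward passes for zero-phase filtering.
// The 8-state case (order-4 band-pass, this package's default) is unrolled
// so the filter state stays in registers.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(na, nb) - 1;
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();

  if (nz == 8 && nb == 9 && na == 9) {
    const double b0=b[0],b1=b[1],b2=b[2],b3=b[3],b4=b[4],b5=b[5],b6=b[6],b7=b[7],b8=b[8];
    const double a1=a[1],a2=a[2],a3=a[3],a4=a[4],a5=a[5],a6=a[6],a7=a[7],a8=a[8];
    double z1=0,z2=0,z3=0,z4=0,z5=0,z6=0,z7=0,z8=0;
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0*xi + z1;
      z1 = b1*xi + z2 - a1*yi;
      z2 = b2*xi + z3 - a2*yi;
      z3 = b3*xi + z4 - a3*yi;
      z4 = b4*xi + z5 - a4*yi;
      z5 = b5*xi + z6 - a5*yi;
      z6 = b6*xi + z7 - a6*yi;
      z7 = b7*xi + z8 - a7*yi;
      z8 = b8*xi - a8*yi;
      yp[i] = yi;
    }
    return y;
  }

  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    yp[i] = yi;
  }
  return y;
}
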