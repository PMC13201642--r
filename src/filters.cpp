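#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3-D median filter over a cubic window with edge replication.
// window must be odd; the neighbourhood is window^3 voxels.
// [[Rcpp::export(name = ".median_filter3_cpp")]]
NumericVector median_filter3_cpp(NumericVector vol, IntegerVector dims, int window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = window / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)window * window * window);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -r; dk <= r; ++dk) {
          int kk = k + dk; kk = kk < 0 ? 0 : (kk >= nz ? nz - 1 : kk);
          for (int dj = -r; dj <= r; ++dj) {
            int jj = j + dj; jj = jj < 0 ? 0 : (jj >= ny ? ny - 1 : jj);
            for (int di = -r; di <= r; ++di) {
              int ii = i + di; ii = ii < 0 ? 0 : (ii >= nx ? nx - 1 : ii);
              buf.push_back(vol[(size_t)kk * nx * ny + (size_t)jj * nx + ii]);
            }
          }
        }
        size_t m = buf.size() / 2;  // window^3 is odd
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[(size_t)k * nx * ny + (size_t)j * nx + i] = buf[m];
      }
    }
  }
  return out;
}
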