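#include <Rcpp.h>
using namespace Rcpp;

// levels: flattened 3D integer array, 1..nlevels inside the mask, 0 outside.

static inline bool in_grid(int i, int j, int k, const IntegerVector& d) {
  return i >= 0 && i < d[0] && j >= 0 && j < d[1] && k >= 0 && k < d[2];
}

// Symmetric gray-level co-occurrence counts for one direction/distance:
// each in-mask voxel pair (p, p + dist*offset) contributes to both (a,b)
// and (b,a).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                              IntegerVector offset, int distance,
                              int nlevels) {
  NumericMatrix out(nlevels, nlevels);
  const int d1 = dims[0], d12 = dims[0] * dims[1];
  const int oi = offset[0] * distance, oj = offset[1] * distance,
            ok = offset[2] * distance;
  for (int k = 0; k < dims[2]; ++k) {
    for (int j = 0; j < dims[1]; ++j) {
      for (int i = 0; i < dims[0]; ++i) {
        int a = levels[i + j * d1 + k * d12];
        if (a == 0) continue;
        int ii = i + oi, jj = j + oj, kk = k + ok;
        if (!in_grid(ii, jj, kk, dims)) continue;
        int b = levels[ii + jj * d1 + kk * d12];
        if (b == 0) continue;
        out(a - 1, b - 1) += 1.0;
        out(b - 1, a - 1) += 1.0;
      }
    }
  }
  return out;
}

// Gray-level run-length counts for one direction: maximal runs of equal
// level along the direction, restricted to in-mask voxels (runs break at the
// mask boundary). Row = gray level, column = run length.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, IntegerVector dims,
                               IntegerVector offset, int nlevels) {
  const int d1 = dims[0], d12 = dims[0] * dims[1];
  const int oi = offset[0], oj = offset[1], ok = offset[2];
  int maxrun = std::max(dims[0], std::max(dims[1], dims[2]));
  NumericMatrix out(nlevels, maxrun);
  for (int k = 0; k < dims[2]; ++k) {
    for (int j = 0; j < dims[1]; ++j) {
      for (int i = 0; i < dims[0]; ++i) {
        int a = levels[i + j * d1 + k * d12];
        if (a == 0) continue;
        // run start: predecessor along -offset absent, out of mask, or
        // different level
        int pi = i - oi, pj = j - oj, pk = k - ok;
        if (in_grid(pi, pj, pk, dims) &&
            levels[pi + pj * d1 + pk * d12] == a)
          continue;
        int len = 1;
        int ci = i + oi, cj = j + oj, ck = k + ok;
        while (in_grid(ci, cj, ck, dims) &&
               levels[ci + cj * d1 + ck * d12] == a) {
          ++len;
          ci += oi; cj += oj; ck += ok;
        }
        out(a - 1, len - 1) += 1.0;
      }
    }
  }
  // trim trailing all-zero run-length columns (keep at least one)
  int last = 0;
  for (int c = 0; c < maxrun; ++c)
    for (int r = 0; r < nlevels; ++r)
      if (out(r, c) > 0) { last = c; break; }
  return out(Range(0, nlevels - 1), Range(0, last));
}
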