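#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Moving-window texture kernels on quantized grey levels.
// Conventions shared by all kernels:
//  * windows are odd-sized and must lie fully inside the grid; centers whose
//    window is incomplete get NA (no padding);
//  * NA cells never contribute to histograms or pair counts;
//  * a center that is itself NA yields NA.

// [[Rcpp::export]]
List cpp_firstorder(IntegerMatrix levels, int window, int n_levels) {
  int nr = levels.nrow(), nc = levels.ncol(), half = window / 2;
  NumericMatrix mean_(nr, nc), ent_(nr, nc), even_(nr, nc), var_(nr, nc);
  std::fill(mean_.begin(), mean_.end(), NA_REAL);
  std::fill(ent_.begin(), ent_.end(), NA_REAL);
  std::fill(even_.begin(), even_.end(), NA_REAL);
  std::fill(var_.begin(), var_.end(), NA_REAL);
  std::vector<int> hist(n_levels);

  for (int r = half; r < nr - half; ++r) {
    for (int c = half; c < nc - half; ++c) {
      if (levels(r, c) == NA_INTEGER) continue;
      std::fill(hist.begin(), hist.end(), 0);
      int n = 0;
      for (int i = r - half; i <= r + half; ++i)
        for (int j = c - half; j <= c + half; ++j) {
          int v = levels(i, j);
          if (v != NA_INTEGER) { hist[v]++; n++; }
        }
      if (n == 0) continue;
      double m = 0.0, ent = 0.0;
      int distinct = 0;
      for (int v = 0; v < n_levels; ++v) {
        if (hist[v] == 0) continue;
        double p = (double)hist[v] / n;
        m += v * p;
        ent -= p * std::log(p);
        distinct++;
      }
      double vv = 0.0;
      for (int v = 0; v < n_levels; ++v) {
        if (hist[v] == 0) continue;
        double p = (double)hist[v] / n;
        vv += (v - m) * (v - m) * p;
      }
      mean_(r, c) = m;
      ent_(r, c) = ent;
      even_(r, c) = (distinct == 1) ? 1.0 : ent / std::log((double)distinct);
      var_(r, c) = vv;
    }
  }
  return List::create(_["mean"] = mean_, _["entropy"] = ent_,
                      _["evenness"] = even_, _["variance"] = var_);
}

// GLCM statistics averaged over the four standard angles (0, 45, 90, 135
// degrees).  The co-occurrence matrix is symmetric: each ordered pair is
// counted in both directions.  Angles with zero valid pairs in a window are
// excluded from the average.
// [[Rcpp::export]]
List cpp_glcm(IntegerMatrix levels, int window, int distance, int n_levels) {
  int nr = levels.nrow(), nc = levels.ncol(), half = window / 2;
  // (dr, dc) offsets; dr < 0 means towards smaller row index
  const int drs[4] = {0, -1, -1, -1};
  const int dcs[4] = {1, 1, 0, -1};
  NumericMatrix con_(nr, nc), dis_(nr, nc), ent_(nr, nc), hom_(nr, nc);
  std::fill(con_.begin(), con_.end(), NA_REAL);
  std::fill(dis_.begin(), dis_.end(), NA_REAL);
  std::fill(ent_.begin(), ent_.end(), NA_REAL);
  std::fill(hom_.begin(), hom_.end(), NA_REAL);

  for (int r = half; r < nr - half; ++r) {
    for (int c = half; c < nc - half; ++c) {
      if (levels(r, c) == NA_INTEGER) continue;
      double con = 0, dis = 0, ent = 0, hom = 0;
      int n_angles = 0;
      for (int a = 0; a < 4; ++a) {
        int dr = drs[a] * distance, dc = dcs[a] * distance;
        std::map<int, int> counts;
        long npairs = 0;
        for (int i = r - half; i <= r + half; ++i) {
          for (int j = c - half; j <= c + half; ++j) {
            int i2 = i + dr, j2 = j + dc;
            if (i2 < r - half || i2 > r + half || j2 < c - half || j2 > c + half)
              continue;
            int v1 = levels(i, j), v2 = levels(i2, j2);
            if (v1 == NA_INTEGER || v2 == NA_INTEGER) continue;
            counts[v1 * n_levels + v2]++;
            counts[v2 * n_levels + v1]++;
            npairs++;
          }
        }
        if (npairs == 0) continue;
        double total = 2.0 * npairs;
        double a_con = 0, a_dis = 0, a_ent = 0, a_hom = 0;
        for (std::map<int, int>::iterator it = counts.begin();
             it != counts.end(); ++it) {
          int i_lev = it->first / n_levels, j_lev = it->first % n_levels;
          double p = it->second / total;
          double d = (double)(i_lev - j_lev);
          a_con += p * d * d;
          a_dis += p * std::fabs(d);
          a_ent -= p * std::log(p);
          a_hom += p / (1.0 + d * d);
        }
        con += a_con; dis += a_dis; ent += a_ent; hom += a_hom;
        n_angles++;
      }
      if (n_angles == 0) continue;
      con_(r, c) = con / n_angles;
      dis_(r, c) = dis / n_angles;
      ent_(r, c) = ent / n_angles;
      hom_(r, c) = hom / n_angles;
    }
  }
  return List::create(_["contrast"] = con_, _["dissimilarity"] = dis_,
                      _["entropy"] = ent_, _["homogeneity"] = hom_);
}

// Per-cell ruggedness: sqrt of summed squared elevation differences to the
// eight neighbours.  NA where the neighbourhood is incomplete or contains NA.
// [[Rcpp::export]]
NumericMatrix cpp_ruggedness(NumericMatrix dem) {
  int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int r = 1; r < nr - 1; ++r) {
    for (int c = 1; c < nc - 1; ++c) {
      double x0 = dem(r, c);
      if (NumericMatrix::is_na(x0)) continue;
      double s = 0.0;
      bool ok = true;
      for (int i = r - 1; i <= r + 1 && ok; ++i)
        for (int j = c - 1; j <= c + 1; ++j) {
          if (i == r && j == c) continue;
          double x = dem(i, j);
          if (NumericMatrix::is_na(x)) { ok = false; break; }
          s += (x - x0) * (x - x0);
        }
      if (ok) out(r, c) = std::sqrt(s);
    }
  }
  return out;
}

// Strict moving-window mean: NA where the window is incomplete or any cell NA.
// [[Rcpp::export]]
NumericMatrix cpp_boxmean(NumericMatrix x, int window) {
  int nr = x.nrow(), nc = x.ncol(), half = window / 2;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int r = half; r < nr - half; ++r) {
    for (int c = half; c < nc - half; ++c) {
      double s = 0.0;
      bool ok = true;
      for (int i = r - half; i <= r + half && ok; ++i)
        for (int j = c - half; j <= c + half; ++j) {
          double v = x(i, j);
          if (NumericMatrix::is_na(v)) { ok = false; break; }
          s += v;
        }
      if (ok) out(r, c) = s / (window * (double)window);
    }
  }
  return out;
}
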