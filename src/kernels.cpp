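// Computational kernels: EIGENSTRAT parsing, IBS sharing counts, the exact
// SNP-pair profile engine, and the FFT mesh-autocorrelation engine.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// IBS sharing count for one genotype pair; -1 encodes missing.
static inline int share_count(int ga, int gb) {
  if (ga == NA_INTEGER || gb == NA_INTEGER) return -1;
  if (ga == 1 || gb == 1) return 1;       // het in either: one shared allele
  return (ga == gb) ? 2 : 0;              // identical vs opposite homozygotes
}

// [[Rcpp::export]]
IntegerMatrix geno_parse_cpp(CharacterVector lines, int n_ind) {
  const int n = lines.size();
  IntegerMatrix out(n, n_ind);
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(lines, i));
    int len = (int) strlen(s);
    if (len != n_ind)
      stop("geno line %d has %d characters, expected %d (one per individual)",
           i + 1, len, n_ind);
    for (int j = 0; j < n_ind; j++) {
      char c = s[j];
      if (c == '0') out(i, j) = 0;
      else if (c == '1') out(i, j) = 1;
      else if (c == '2') out(i, j) = 2;
      else if (c == '9') out(i, j) = NA_INTEGER;
      else stop("geno line %d contains invalid character '%c'", i + 1, c);
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector geno_format_cpp(IntegerMatrix g) {
  const int n = g.nrow(), m = g.ncol();
  CharacterVector out(n);
  std::string buf(m, '9');
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < m; j++) {
      int v = g(i, j);
      buf[j] = (v == NA_INTEGER) ? '9' : (char)('0' + v);
    }
    out[i] = buf;
  }
  return out;
}

// Allele sharing matrix, SNPs x pairs (spec layout); NA where either member
// is missing. pairs is P x 2, 0-based column indices into geno.
// [[Rcpp::export]]
IntegerMatrix sharing_matrix_cpp(IntegerMatrix geno, IntegerMatrix pairs) {
  const int n = geno.nrow(), np = pairs.nrow();
  IntegerMatrix out(n, np);
  for (int p = 0; p < np; p++) {
    const int a = pairs(p, 0), b = pairs(p, 1);
    for (int i = 0; i < n; i++) {
      int s = share_count(geno(i, a), geno(i, b));
      out(i, p) = (s < 0) ? NA_INTEGER : s;
    }
  }
  return out;
}

// Exact per-SNP-pair profile. sharing_t is pairs x SNPs (transposed for
// cache-friendly access), pos_cM sorted non-decreasing genetic positions of
// one chromosome. mode 0 = Pearson correlation, 1 = weighted covariance
// (cov / (He_i * He_j), pairwise-complete, n-1 denominator).
// Returns per-bin sum of statistic values and count of SNP pairs used.
// [[Rcpp::export]]
List naive_profile_cpp(IntegerMatrix sharing_t, NumericVector pos_cM,
                       double min_d, double max_d, double step,
                       int mode, NumericVector he) {
  const int P = sharing_t.nrow(), N = sharing_t.ncol();
  const int nb = (int) std::lround((max_d - min_d) / step);
  NumericVector bsum(nb), bcnt(nb);
  const int *S = INTEGER(sharing_t);
  for (int i = 0; i < N; i++) {
    const int *ci = S + (size_t)i * P;
    for (int j = i + 1; j < N; j++) {
      double d = pos_cM[j] - pos_cM[i];
      if (d >= max_d - 1e-9) break;      // 1e-9 cM: FP jitter only
      if (d < min_d - 1e-9) continue;
      int b = (int) std::floor((d - min_d) / step + 1e-9);
      if (b < 0) b = 0;
      if (b >= nb) continue;
      const int *cj = S + (size_t)j * P;
      int n = 0;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      for (int p = 0; p < P; p++) {
        int xi = ci[p], xj = cj[p];
        if (xi == NA_INTEGER || xj == NA_INTEGER) continue;
        n++;
        sx += xi; sy += xj;
        sxx += (double)xi * xi; syy += (double)xj * xj;
        sxy += (double)xi * xj;
      }
      if (n < 2) continue;
      if (mode == 0) {
        double den1 = n * sxx - sx * sx, den2 = n * syy - sy * sy;
        if (den1 <= 0 || den2 <= 0) continue;  // zero variance: skip
        double r = (n * sxy - sx * sy) / std::sqrt(den1 * den2);
        if (r > 1) r = 1; else if (r < -1) r = -1;
        bsum[b] += r; bcnt[b] += 1;
      } else {
        // weighted covariance is defined on the shared-allele *fraction*
        // (0, 1/2, 1), i.e. a quarter of the count covariance: on that
        // scale its amplitude maps to founder intensity through the same
        // e * a transform as the correlation
        double cov = 0.25 * (sxy - sx * sy / n) / (n - 1.0);
        bsum[b] += cov / (he[i] * he[j]); bcnt[b] += 1;
      }
    }
  }
  return List::create(_["sum"] = bsum, _["n"] = bcnt);
}

// FFT mesh-autocorrelation profile for one chromosome.
//
// Each SNP's sharing counts are first standardised across individual pairs
// (mode 0: centred and scaled by the ML standard deviation, so that the
// mean over pairs of s~_i * s~_j is exactly the per-SNP-pair Pearson
// correlation of the exact engine; mode 1: centred and divided by the
// SNP's expected heterozygosity, so that the mean over pairs times
// P/(P-1) is the He-weighted covariance).  Standardised values are
// rasterised onto mesh cells (nearest cell); for every individual pair one
// FFT yields, at every lag, the sum of products of cell totals and the
// number of contributing SNP cross-pairs.  Accumulating those two sums
// over the lags of a distance bin and over individual pairs reproduces the
// exact engine's equal-weight-per-SNP-pair average, up to the mesh
// discretisation of the distances (the only approximation).
//
// sharing: SNPs x pairs sharing-count matrix (NA = missing); cell: 0-based
// mesh cell per SNP; delta in cM; he: per-SNP expected heterozygosity
// (mode 1); npad: 5-smooth FFT length >= ncell + maxlag + 1.
// Returns per-bin sum of products and count of (SNP pair x individual
// pair) product terms; the caller forms value = sum / count.
// [[Rcpp::export]]
List fft_profile_cpp(IntegerMatrix sharing,
                     IntegerVector cell, int ncell, double delta,
                     double min_d, double max_d, double step,
                     int mode, NumericVector he, int npad) {
  const int N = sharing.nrow(), P = sharing.ncol();
  const int nb = (int) std::lround((max_d - min_d) / step);
  int minlag = (int) std::ceil(min_d / delta - 1e-9);
  if (minlag < 1) minlag = 1;
  int maxlag = (int) std::floor(max_d / delta - 1e-9);
  if ((double) maxlag * delta >= max_d - 1e-12) maxlag--;
  if (maxlag > ncell - 2) maxlag = ncell - 2;
  NumericVector bsum(nb), bcnt(nb);
  if (maxlag < minlag) return List::create(_["sum"] = bsum, _["n"] = bcnt);

  std::vector<int> lag2bin(maxlag + 1, -1);
  for (int L = minlag; L <= maxlag; L++) {
    int b = (int) std::floor((L * delta - min_d) / step + 1e-9);
    if (b >= 0 && b < nb) lag2bin[L] = b;
  }

  // per-SNP moments across pairs (column sweep keeps access contiguous)
  std::vector<double> s1(N, 0.0), s2(N, 0.0);
  std::vector<int> nobs(N, 0);
  bool has_missing = false;
  const int *S = INTEGER(sharing);
  for (int p = 0; p < P; p++) {
    const int *Sp = S + (size_t)p * N;
    for (int i = 0; i < N; i++) {
      int v = Sp[i];
      if (v == NA_INTEGER) { has_missing = true; continue; }
      s1[i] += v; s2[i] += (double)v * v; nobs[i]++;
    }
  }
  std::vector<double> mu(N), sc(N);  // centre and scale per SNP
  std::vector<bool> usable(N);
  for (int i = 0; i < N; i++) {
    if (nobs[i] < 2) { usable[i] = false; continue; }
    mu[i] = s1[i] / nobs[i];
    double v = s2[i] / nobs[i] - mu[i] * mu[i];
    if (mode == 0) {
      usable[i] = v > 1e-12;   // zero-variance SNPs are skipped, as in the
      sc[i] = usable[i] ? std::sqrt(v) : 1.0;  // exact engine
    } else {
      usable[i] = he[i] > 0;
      sc[i] = usable[i] ? he[i] : 1.0;
    }
  }
  // mode 1: shared-allele-fraction scale (counts / 2 -> products / 4) and
  // the n/(n-1) covariance correction
  const double pair_factor = (mode == 1 && P > 1)
    ? 0.25 * (double)P / (P - 1.0) : 1.0;

  // with complete data every pair contributes the same SNP cross-pair
  // counts, so the count spectrum is computed once
  arma::vec cnt_shared;
  if (!has_missing) {
    arma::vec kv(npad, arma::fill::zeros);
    for (int i = 0; i < N; i++) if (usable[i]) kv[cell[i]] += 1.0;
    arma::cx_vec Fk = arma::fft(arma::cx_vec(kv, arma::vec(npad, arma::fill::zeros)));
    arma::cx_vec sp(npad);
    for (int k = 0; k < npad; k++)
      sp[k] = arma::cx_double(std::norm(Fk[k]), 0.0);
    cnt_shared = arma::real(arma::ifft(sp));
  }

  arma::vec a(npad), kv(npad);
  for (int p = 0; p < P; p++) {
    const int *Sp = S + (size_t)p * N;
    a.zeros(); kv.zeros();
    int nvals = 0;
    for (int i = 0; i < N; i++) {
      int v = Sp[i];
      if (v == NA_INTEGER || !usable[i]) continue;
      a[cell[i]] += (v - mu[i]) / sc[i];
      kv[cell[i]] += 1.0;
      nvals++;
    }
    if (nvals < 2) continue;
    // forward transform of (cell totals, cell counts) packed as a + i k
    arma::cx_vec Z = arma::fft(arma::cx_vec(a, kv));
    arma::cx_vec sp(npad);
    if (!has_missing) {
      for (int k = 0; k < npad; k++) {
        int kr = (k == 0) ? 0 : npad - k;
        arma::cx_double Fa = 0.5 * (Z[k] + std::conj(Z[kr]));
        sp[k] = arma::cx_double(std::norm(Fa), 0.0);
      }
    } else {
      for (int k = 0; k < npad; k++) {
        int kr = (k == 0) ? 0 : npad - k;
        arma::cx_double zc = std::conj(Z[kr]);
        arma::cx_double Fa = 0.5 * (Z[k] + zc);
        arma::cx_double Fk = arma::cx_double(0, -0.5) * (Z[k] - zc);
        sp[k] = arma::cx_double(std::norm(Fa), std::norm(Fk));
      }
    }
    arma::cx_vec inv = arma::ifft(sp);  // real: sum of products; imag: counts

    for (int L = minlag; L <= maxlag; L++) {
      int bb = lag2bin[L];
      if (bb < 0) continue;
      double nn = has_missing ? inv[L].imag() : cnt_shared[L];
      if (nn < 0.5) continue;
      bsum[bb] += pair_factor * inv[L].real();
      bcnt[bb] += nn;
    }
  }
  return List::create(_["sum"] = bsum, _["n"] = bcnt);
}
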