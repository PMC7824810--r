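#include <Rcpp.h>
using namespace Rcpp;

// Li-Stephens haplotype-copying forward-backward, evaluated at a silent
// focal site (the microsatellite position) inserted between SNP k-1 and
// SNP k of the window (0-based; k = number of SNPs left of the focus).
//
// Transition between adjacent sites with switch probability rho:
//   T(h, h') = (1 - rho) * I(h == h') + rho / H
// Emission at a SNP: match 1 - eps, mismatch eps; missing target emits 1.
// The focal site emits 1 for every state. rho[j] is the switch probability
// between SNP j and j+1 (entry k-1, which straddles the focus, is unused:
// it is replaced by rho_left then rho_right).

static inline void transition(std::vector<double>& f, double rho) {
  const int H = f.size();
  double s = 0.0;
  for (int h = 0; h < H; ++h) s += f[h];
  const double a = 1.0 - rho, b = rho * s / H;
  for (int h = 0; h < H; ++h) f[h] = a * f[h] + b;
}

static inline void normalize(std::vector<double>& f) {
  double s = 0.0;
  for (size_t h = 0; h < f.size(); ++h) s += f[h];
  if (s > 0) for (size_t h = 0; h < f.size(); ++h) f[h] /= s;
}

// [[Rcpp::export(name = ".ls_fb_focal_cpp")]]
NumericVector ls_fb_focal_cpp(IntegerMatrix ref, IntegerVector target,
                              NumericVector rho, double rho_left,
                              double rho_right, int k, double eps) {
  const int H = ref.nrow(), S = ref.ncol();
  if (target.size() != S) stop("target length != panel SNP count");
  if (k < 0 || k > S) stop("invalid focal index");
  std::vector<double> f(H, 1.0 / H), b(H, 1.0);

  // forward over SNPs 0..k-1, then across the left gap
  for (int j = 0; j < k; ++j) {
    if (j > 0) transition(f, rho[j - 1]);
    const int t = target[j];
    if (t != NA_INTEGER && t >= 0) {
      for (int h = 0; h < H; ++h)
        f[h] *= (ref(h, j) == t) ? (1.0 - eps) : eps;
    }
    normalize(f);
  }
  if (k > 0) transition(f, rho_left);

  // backward over SNPs S-1..k, then across the right gap
  if (k < S) {
    for (int j = S - 1; j >= k; --j) {
      const int t = target[j];
      if (t != NA_INTEGER && t >= 0) {
        for (int h = 0; h < H; ++h)
          b[h] *= (ref(h, j) == t) ? (1.0 - eps) : eps;
      }
      transition(b, j == k ? rho_right : rho[j - 1]);
      normalize(b);
    }
  }

  NumericVector post(H);
  double s = 0.0;
  for (int h = 0; h < H; ++h) { post[h] = f[h] * b[h]; s += post[h]; }
  if (s <= 0) { // all-missing / degenerate: uniform prior
    for (int h = 0; h < H; ++h) post[h] = 1.0 / H;
  } else {
    for (int h = 0; h < H; ++h) post[h] /= s;
  }
  return post;
}

// Diploid analogue over ordered pairs of reference haplotypes. The target
// is an unphased genotype vector in {0,1,2}, NA missing. Emission compares
// the pair's summed allele dosage with the observed genotype. The
// transition factorizes per copy; with a = 1-rho, b = rho/H and F the
// H x H state distribution:
//   (T F T)(h1,h2) = a^2 F + a b (rowsum_h1 + colsum_h2) + b^2 total.
static void transition2(std::vector<double>& F, int H, double rho) {
  std::vector<double> rs(H, 0.0), cs(H, 0.0);
  double tot = 0.0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < H; ++j) {
      const double v = F[i * H + j];
      rs[i] += v; cs[j] += v; tot += v;
    }
  const double a = 1.0 - rho, b = rho / H;
  const double a2 = a * a, ab = a * b, b2t = b * b * tot;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < H; ++j)
      F[i * H + j] = a2 * F[i * H + j] + ab * (rs[i] + cs[j]) + b2t;
}

static void normalize2(std::vector<double>& F) {
  double s = 0.0;
  for (size_t i = 0; i < F.size(); ++i) s += F[i];
  if (s > 0) for (size_t i = 0; i < F.size(); ++i) F[i] /= s;
}

static inline void emit2(std::vector<double>& F, const IntegerMatrix& ref,
                         int j, int t, int H, double eps) {
  if (t == NA_INTEGER || t < 0) return;
  for (int i = 0; i < H; ++i) {
    const int ri = ref(i, j);
    for (int h = 0; h < H; ++h)
      F[i * H + h] *= ((ri + ref(h, j)) == t) ? (1.0 - eps) : eps;
  }
}

// [[Rcpp::export(name = ".ls_fb_focal_diploid_cpp")]]
NumericMatrix ls_fb_focal_diploid_cpp(IntegerMatrix ref, IntegerVector target,
                                      NumericVector rho, double rho_left,
                                      double rho_right, int k, double eps) {
  const int H = ref.nrow(), S = ref.ncol();
  if (target.size() != S) stop("target length != panel SNP count");
  if (k < 0 || k > S) stop("invalid focal index");
  std::vector<double> F(H * H, 1.0 / (H * H)), B(H * H, 1.0);

  for (int j = 0; j < k; ++j) {
    if (j > 0) transition2(F, H, rho[j - 1]);
    emit2(F, ref, j, target[j], H, eps);
    normalize2(F);
  }
  if (k > 0) transition2(F, H, rho_left);

  if (k < S) {
    for (int j = S - 1; j >= k; --j) {
      emit2(B, ref, j, target[j], H, eps);
      transition2(B, H, j == k ? rho_right : rho[j - 1]);
      normalize2(B);
    }
  }

  NumericMatrix post(H, H);
  double s = 0.0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < H; ++j) {
      post(i, j) = F[i * H + j] * B[i * H + j];
      s += post(i, j);
    }
  if (s <= 0) {
    std::fill(post.begin(), post.end(), 1.0 / (H * H));
  } else {
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < H; ++j) post(i, j) /= s;
  }
  return post;
}
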