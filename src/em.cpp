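#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------- shared helpers ----------------------------------------------

// Dense 0-based recoding of an arbitrary integer vector; returns K.
static int recode_dense(const std::vector<int> &v, std::vector<int> &out) {
  std::vector<int> lev(v);
  std::sort(lev.begin(), lev.end());
  lev.erase(std::unique(lev.begin(), lev.end()), lev.end());
  out.resize(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    out[i] = std::lower_bound(lev.begin(), lev.end(), v[i]) - lev.begin();
  }
  return (int)lev.size();
}

struct EmFit {
  double pi, ll1, ll0, bic;
  int k0, delta_k, n_iter, n_degenerate;
  bool converged;
  std::vector<double> resp_fwd;      // unweighted P_fwd/(P_fwd+P_inv)
  std::vector<double> resp_post;     // pi-weighted EM posterior (forward)
  std::vector<double> trace;
  // compact tables over occupied (observed) cells; unobserved cells
  // hold probability floor_p / Z
  std::vector<double> f12, f34, r13, r24;
  std::vector<int> key12, key34, key13, key24; // cell -> k_row * Kcol + k_col
  double unocc12, unocc34, unocc13, unocc24;   // probability of an unoccupied cell
  int K1, K2, K3, K4;
};

// Floor occupied cells at `fl`, account for (ntot - occupied) implicit
// floored cells, and normalize; returns the unoccupied-cell probability.
static double floor_renorm_compact(std::vector<double> &p, double fl, double ntot) {
  double s = fl * (ntot - p.size());
  for (size_t i = 0; i < p.size(); ++i) {
    if (p[i] < fl) p[i] = fl;
    s += p[i];
  }
  for (size_t i = 0; i < p.size(); ++i) p[i] /= s;
  return fl / s;
}

// EM for the four-block forward/inverted mixture on dense 0-based codes.
// Component 1 ("forward") factorizes as joint(B1,B2) * joint(B3,B4);
// component 2 ("inverted") as joint(B1,B3) * joint(B2,B4).  Tables are
// initialized at the pooled empirical joints, pi at pi0; the E-step
// uses pi-weighted posteriors.  Also computes the null (forward-only)
// empirical log-likelihood and the BIC difference favouring the
// mixture, with parameter supports counted from the observed category
// pairs.
static EmFit em_fit(const std::vector<int> &b1, const std::vector<int> &b2,
                    const std::vector<int> &b3, const std::vector<int> &b4,
                    int K1, int K2, int K3, int K4,
                    double pi0, double tol, int max_iter, double floor_p) {
  const int m = b1.size();
  EmFit out;
  out.K1 = K1; out.K2 = K2; out.K3 = K3; out.K4 = K4;

  // aggregate identical observations, remembering each one's group
  std::map<long long, int> agg;
  std::vector<int> uid(m);
  for (int i = 0; i < m; ++i) {
    long long key = (((((long long)b1[i] * K2 + b2[i]) * K3) + b3[i]) * K4) + b4[i];
    agg[key] += 1;
  }
  const int u = agg.size();
  std::vector<int> c12(u), c34(u), c13(u), c24(u), cnt(u);
  {
    std::map<long long, int> uidx;
    int j = 0;
    for (std::map<long long, int>::iterator it = agg.begin(); it != agg.end(); ++it, ++j) {
      long long key = it->first;
      uidx[key] = j;
      int v4 = key % K4; key /= K4;
      int v3 = key % K3; key /= K3;
      int v2 = key % K2; key /= K2;
      int v1 = (int)key;
      c12[j] = v1 * K2 + v2;
      c34[j] = v3 * K4 + v4;
      c13[j] = v1 * K3 + v3;
      c24[j] = v2 * K4 + v4;
      cnt[j] = it->second;
    }
    for (int i = 0; i < m; ++i) {
      long long key = (((((long long)b1[i] * K2 + b2[i]) * K3) + b3[i]) * K4) + b4[i];
      uid[i] = uidx[key];
    }
  }

  // compact occupied-cell indexing per pairing: o12[j] indexes the
  // occupied cell of table f12 that quad j touches
  std::vector<int> o12(u), o34(u), o13(u), o24(u);
  int s12, s34, s13, s24;
  {
    std::map<int, int> m12, m34, m13, m24;
    for (int j = 0; j < u; ++j) {
      std::map<int, int>::iterator it;
      it = m12.find(c12[j]);
      if (it == m12.end()) { int id = m12.size(); m12[c12[j]] = id; o12[j] = id; }
      else o12[j] = it->second;
      it = m34.find(c34[j]);
      if (it == m34.end()) { int id = m34.size(); m34[c34[j]] = id; o34[j] = id; }
      else o34[j] = it->second;
      it = m13.find(c13[j]);
      if (it == m13.end()) { int id = m13.size(); m13[c13[j]] = id; o13[j] = id; }
      else o13[j] = it->second;
      it = m24.find(c24[j]);
      if (it == m24.end()) { int id = m24.size(); m24[c24[j]] = id; o24[j] = id; }
      else o24[j] = it->second;
    }
    s12 = m12.size(); s34 = m34.size(); s13 = m13.size(); s24 = m24.size();
    out.key12.resize(s12); out.key34.resize(s34);
    out.key13.resize(s13); out.key24.resize(s24);
    for (std::map<int, int>::iterator it = m12.begin(); it != m12.end(); ++it)
      out.key12[it->second] = it->first;
    for (std::map<int, int>::iterator it = m34.begin(); it != m34.end(); ++it)
      out.key34[it->second] = it->first;
    for (std::map<int, int>::iterator it = m13.begin(); it != m13.end(); ++it)
      out.key13[it->second] = it->first;
    for (std::map<int, int>::iterator it = m24.begin(); it != m24.end(); ++it)
      out.key24[it->second] = it->first;
  }

  // empirical joints (occupied cells); null log-likelihood and supports
  std::vector<double> e12(s12, 0.0), e34(s34, 0.0), e13(s13, 0.0), e24(s24, 0.0);
  for (int j = 0; j < u; ++j) {
    double w = (double)cnt[j] / m;
    e12[o12[j]] += w; e34[o34[j]] += w;
    e13[o13[j]] += w; e24[o24[j]] += w;
  }
  double ll0 = 0.0;
  for (int j = 0; j < u; ++j) {
    ll0 += cnt[j] * (std::log(e12[o12[j]]) + std::log(e34[o34[j]]));
  }
  out.ll0 = ll0;
  out.k0 = (s12 - 1) + (s34 - 1);
  out.delta_k = 1 + (s13 - 1) + (s24 - 1);

  const double n12 = (double)K1 * K2, n34 = (double)K3 * K4;
  const double n13 = (double)K1 * K3, n24 = (double)K2 * K4;
  std::vector<double> f12(e12), f34(e34), r13(e13), r24(e24);
  out.unocc12 = floor_renorm_compact(f12, floor_p, n12);
  out.unocc34 = floor_renorm_compact(f34, floor_p, n34);
  out.unocc13 = floor_renorm_compact(r13, floor_p, n13);
  out.unocc24 = floor_renorm_compact(r24, floor_p, n24);

  double pi = pi0;
  out.trace.reserve(64);
  bool converged = false;
  int iter = 0;
  double ll_prev = R_NegInf;
  std::vector<double> A12(s12), A34(s34), R13(s13), R24(s24);
  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(A12.begin(), A12.end(), 0.0);
    std::fill(A34.begin(), A34.end(), 0.0);
    std::fill(R13.begin(), R13.end(), 0.0);
    std::fill(R24.begin(), R24.end(), 0.0);
    double ll = 0.0, sw = 0.0;
    for (int j = 0; j < u; ++j) {
      double Pf = f12[o12[j]] * f34[o34[j]];
      double Pi_ = r13[o13[j]] * r24[o24[j]];
      double mix = (1.0 - pi) * Pf + pi * Pi_;
      if (mix < 1e-300) mix = 1e-300;
      ll += cnt[j] * std::log(mix);
      double w = pi * Pi_ / mix;
      sw += cnt[j] * w;
      A12[o12[j]] += cnt[j] * (1.0 - w);
      A34[o34[j]] += cnt[j] * (1.0 - w);
      R13[o13[j]] += cnt[j] * w;
      R24[o24[j]] += cnt[j] * w;
    }
    out.trace.push_back(ll);
    if (R_finite(ll_prev) && std::fabs(ll - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
    pi = sw / m;
    if (pi < 0.0) pi = 0.0;
    if (pi > 1.0) pi = 1.0;
    f12.assign(A12.begin(), A12.end());
    f34.assign(A34.begin(), A34.end());
    r13.assign(R13.begin(), R13.end());
    r24.assign(R24.begin(), R24.end());
    out.unocc12 = floor_renorm_compact(f12, floor_p, n12);
    out.unocc34 = floor_renorm_compact(f34, floor_p, n34);
    out.unocc13 = floor_renorm_compact(r13, floor_p, n13);
    out.unocc24 = floor_renorm_compact(r24, floor_p, n24);
  }
  if (iter > max_iter) iter = max_iter;
  out.n_iter = iter;
  out.converged = converged;

  // final responsibilities and log-likelihood (unique level, mapped back)
  std::vector<double> uresp(u), upost(u);
  out.n_degenerate = 0;
  double ll_final = 0.0;
  for (int j = 0; j < u; ++j) {
    double Pf = f12[o12[j]] * f34[o34[j]];
    double Pi_ = r13[o13[j]] * r24[o24[j]];
    double den = Pf + Pi_;
    if (den < 1e-300) {
      uresp[j] = 0.5;
      out.n_degenerate += cnt[j];
    } else {
      uresp[j] = Pf / den;
    }
    double mix = (1.0 - pi) * Pf + pi * Pi_;
    if (mix < 1e-300) mix = 1e-300;
    upost[j] = (1.0 - pi) * Pf / mix;
    ll_final += cnt[j] * std::log(mix);
  }
  out.resp_fwd.resize(m);
  out.resp_post.resize(m);
  for (int i = 0; i < m; ++i) {
    out.resp_fwd[i] = uresp[uid[i]];
    out.resp_post[i] = upost[uid[i]];
  }
  out.pi = pi;
  out.ll1 = ll_final;
  out.bic = 2.0 * (ll_final - ll0) - out.delta_k * std::log((double)m);
  out.f12.swap(f12); out.f34.swap(f34);
  out.r13.swap(r13); out.r24.swap(r24);
  return out;
}

static std::vector<int> as_vec(const IntegerVector &x) {
  return std::vector<int>(x.begin(), x.end());
}

// ---------- exported: single-quartet EM ----------------------------------

// [[Rcpp::export]]
List mixture_em_cpp(IntegerVector b1, IntegerVector b2, IntegerVector b3,
                    IntegerVector b4, int K1, int K2, int K3, int K4,
                    double pi0, double tol, int max_iter, double floor_p) {
  EmFit f = em_fit(as_vec(b1), as_vec(b2), as_vec(b3), as_vec(b4),
                   K1, K2, K3, K4, pi0, tol, max_iter, floor_p);
  // expand compact occupied-cell tables to dense matrices
  NumericMatrix f12(K1, K2), f34(K3, K4), r13(K1, K3), r24(K2, K4);
  std::fill(f12.begin(), f12.end(), f.unocc12);
  std::fill(f34.begin(), f34.end(), f.unocc34);
  std::fill(r13.begin(), r13.end(), f.unocc13);
  std::fill(r24.begin(), r24.end(), f.unocc24);
  for (size_t k = 0; k < f.key12.size(); ++k)
    f12(f.key12[k] / K2, f.key12[k] % K2) = f.f12[k];
  for (size_t k = 0; k < f.key34.size(); ++k)
    f34(f.key34[k] / K4, f.key34[k] % K4) = f.f34[k];
  for (size_t k = 0; k < f.key13.size(); ++k)
    r13(f.key13[k] / K3, f.key13[k] % K3) = f.r13[k];
  for (size_t k = 0; k < f.key24.size(); ++k)
    r24(f.key24[k] / K4, f.key24[k] % K4) = f.r24[k];
  return List::create(
    _["pi"] = f.pi,
    _["f12"] = f12,
    _["f34"] = f34,
    _["r13"] = r13,
    _["r24"] = r24,
    _["loglik"] = f.ll1,
    _["loglik0"] = f.ll0,
    _["bic"] = f.bic,
    _["k0"] = f.k0,
    _["delta_k"] = f.delta_k,
    _["trace"] = NumericVector(f.trace.begin(), f.trace.end()),
    _["resp_fwd"] = NumericVector(f.resp_fwd.begin(), f.resp_fwd.end()),
    _["resp_post_fwd"] = NumericVector(f.resp_post.begin(), f.resp_post.end()),
    _["n_iter"] = f.n_iter,
    _["converged"] = f.converged,
    _["n_degenerate"] = f.n_degenerate);
}

// Evaluate the mixture log-likelihood at given parameters (no fitting).
// [[Rcpp::export]]
double mixture_loglik_cpp(IntegerVector b1, IntegerVector b2, IntegerVector b3,
                          IntegerVector b4, double pi,
                          NumericMatrix f12, NumericMatrix f34,
                          NumericMatrix r13, NumericMatrix r24) {
  const int m = b1.size();
  double ll = 0.0;
  for (int i = 0; i < m; ++i) {
    double Pf = f12(b1[i], b2[i]) * f34(b3[i], b4[i]);
    double Pi_ = r13(b1[i], b3[i]) * r24(b2[i], b4[i]);
    double mix = (1.0 - pi) * Pf + pi * Pi_;
    if (mix < 1e-300) mix = 1e-300;
    ll += std::log(mix);
  }
  return ll;
}

// ---------- exported: batch window scoring -------------------------------

// Haplotype pathway: per window (li, ri are 0-based breakpoint column
// indices into the A/B caches), fit the detection mixture on the
// quartet (A[,li], B[,li], A[,ri], B[,ri]) over all chromosomes.
// Returns BIC, pi, convergence, and the per-chromosome inverted
// indicator (forward responsibility < 0.5).
// [[Rcpp::export]]
List scan_windows_hap_cpp(IntegerMatrix A, IntegerMatrix B,
                          IntegerVector li, IntegerVector ri,
                          double pi0, double tol, int max_iter,
                          double floor_p) {
  const int n = A.nrow(), W = li.size();
  NumericVector bic(W), pi(W);
  IntegerVector niter(W);
  LogicalVector conv(W);
  LogicalMatrix inv(n, W);
  std::vector<int> b1(n), b2(n), b3(n), b4(n), d1, d2, d3, d4;
  for (int w = 0; w < W; ++w) {
    for (int i = 0; i < n; ++i) {
      b1[i] = A(i, li[w]); b2[i] = B(i, li[w]);
      b3[i] = A(i, ri[w]); b4[i] = B(i, ri[w]);
    }
    int K1 = recode_dense(b1, d1), K2 = recode_dense(b2, d2);
    int K3 = recode_dense(b3, d3), K4 = recode_dense(b4, d4);
    EmFit f = em_fit(d1, d2, d3, d4, K1, K2, K3, K4, pi0, tol, max_iter, floor_p);
    bic[w] = f.bic;
    pi[w] = f.pi;
    conv[w] = f.converged;
    niter[w] = f.n_iter;
    for (int i = 0; i < n; ++i) inv(i, w) = f.resp_fwd[i] < 0.5;
  }
  return List::create(_["bic"] = bic, _["pi"] = pi, _["converged"] = conv,
                      _["n_iter"] = niter, _["inverted"] = inv);
}

// Genotype pathway: per window, (1) fit the pairing mixture on the
// quartet (L1, R1, R2, L2) of full 2N-SNP haplotype masks over
// subjects usable at both breakpoints, choosing each subject's
// chromosome pairing by dominant responsibility (ties -> parallel);
// (2) fit the detection mixture on the split N-SNP blocks over the
// 2*n paired chromosomes.  Returns BIC, pi, and the per-subject
// inverted-chromosome count (0/1/2; NA when the subject is excluded).
// h1A/h1B are the left/right N-SNP half-block masks of haplotype 1 at
// each breakpoint (columns), h2A/h2B likewise for haplotype 2.
// [[Rcpp::export]]
List scan_windows_geno_cpp(IntegerMatrix h1A, IntegerMatrix h1B,
                           IntegerMatrix h2A, IntegerMatrix h2B,
                           LogicalMatrix flagged,
                           IntegerVector li, IntegerVector ri, int N,
                           double pi0, double tol, int max_iter,
                           double floor_p) {
  const int n = h1A.nrow(), W = li.size();
  NumericVector bic(W), pi(W), pairing_pi(W);
  IntegerVector n_used(W);
  LogicalVector conv(W);
  IntegerMatrix count(n, W);
  std::fill(count.begin(), count.end(), NA_INTEGER);
  const int shift = 1 << N;

  for (int w = 0; w < W; ++w) {
    int L = li[w], R = ri[w];
    std::vector<int> ok;
    ok.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (!flagged(i, L) && !flagged(i, R)) ok.push_back(i);
    }
    const int no = ok.size();
    if (no < 2) {
      bic[w] = NA_REAL; pi[w] = NA_REAL; pairing_pi[w] = NA_REAL;
      n_used[w] = 0; conv[w] = false;
      continue;
    }
    // pairing fit on full 2N masks
    std::vector<int> L1(no), L2(no), R1(no), R2(no), d1, d2, d3, d4;
    for (int k = 0; k < no; ++k) {
      int i = ok[k];
      L1[k] = h1A(i, L) + shift * h1B(i, L);
      L2[k] = h2A(i, L) + shift * h2B(i, L);
      R1[k] = h1A(i, R) + shift * h1B(i, R);
      R2[k] = h2A(i, R) + shift * h2B(i, R);
    }
    int K1 = recode_dense(L1, d1), K2 = recode_dense(R1, d2);
    int K3 = recode_dense(R2, d3), K4 = recode_dense(L2, d4);
    EmFit pf = em_fit(d1, d2, d3, d4, K1, K2, K3, K4, pi0, tol, max_iter, floor_p);
    pairing_pi[w] = pf.pi;

    // detection fit on split blocks over 2*no chromosomes
    std::vector<int> b1(2 * no), b2(2 * no), b3(2 * no), b4(2 * no);
    for (int k = 0; k < no; ++k) {
      int i = ok[k];
      bool parallel = pf.resp_fwd[k] >= 0.5;
      b1[2 * k] = h1A(i, L); b2[2 * k] = h1B(i, L);
      b1[2 * k + 1] = h2A(i, L); b2[2 * k + 1] = h2B(i, L);
      if (parallel) {
        b3[2 * k] = h1A(i, R); b4[2 * k] = h1B(i, R);
        b3[2 * k + 1] = h2A(i, R); b4[2 * k + 1] = h2B(i, R);
      } else {
        b3[2 * k] = h2A(i, R); b4[2 * k] = h2B(i, R);
        b3[2 * k + 1] = h1A(i, R); b4[2 * k + 1] = h1B(i, R);
      }
    }
    K1 = recode_dense(b1, d1); K2 = recode_dense(b2, d2);
    K3 = recode_dense(b3, d3); K4 = recode_dense(b4, d4);
    EmFit f = em_fit(d1, d2, d3, d4, K1, K2, K3, K4, pi0, tol, max_iter, floor_p);
    bic[w] = f.bic;
    pi[w] = f.pi;
    conv[w] = f.converged;
    n_used[w] = 2 * no;
    for (int k = 0; k < no; ++k) {
      int c = (f.resp_fwd[2 * k] < 0.5 ? 1 : 0) +
              (f.resp_fwd[2 * k + 1] < 0.5 ? 1 : 0);
      count(ok[k], w) = c;
    }
  }
  return List::create(_["bic"] = bic, _["pi"] = pi,
                      _["pairing_pi"] = pairing_pi, _["converged"] = conv,
                      _["n_used"] = n_used, _["count"] = count);
}

// ---------- exported: local phasing EM -----------------------------------

// Haplotype-frequency EM for a short genotype window (<= 16 SNPs).
//
// geno: n x S integer matrix with codes 0/1/2 and NA for missing.
// Haplotypes are bitmasks over the S SNPs (bit j = SNP column j+1).
// Subjects with identical genotype patterns are pooled.  Returns the
// maximum-posterior haplotype pair per subject (lo mask first), its
// posterior probability, and a flag for uncallable subjects.
// [[Rcpp::export]]
List phase_em_cpp(IntegerMatrix geno, double tol, int max_iter) {
  const int n = geno.nrow(), S = geno.ncol();
  if (S > 16) stop("phase_em_cpp: more than 16 SNPs in window");

  // group subjects by genotype pattern (base-4 key, NA -> 3)
  std::map<long long, std::vector<int> > groups;
  for (int i = 0; i < n; ++i) {
    long long key = 0;
    for (int j = 0; j < S; ++j) {
      int g = geno(i, j);
      int d = (g == NA_INTEGER) ? 3 : g;
      key = key * 4 + d;
    }
    groups[key].push_back(i);
  }

  struct Pattern {
    std::vector<int> subjects;
    std::vector<std::pair<int, int> > pairs; // (lo, hi) haplotype indices
    bool flagged;
  };
  std::vector<Pattern> pats;
  std::map<int, int> hap_index; // mask -> registry index
  std::vector<int> hap_mask;

  for (std::map<long long, std::vector<int> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    long long key = it->first;
    std::vector<int> code(S);
    for (int j = S - 1; j >= 0; --j) { code[j] = key % 4; key /= 4; }
    Pattern pat;
    pat.subjects = it->second;
    pat.flagged = false;

    int n_obs = 0, nfree = 0;
    for (int j = 0; j < S; ++j) {
      if (code[j] != 3) ++n_obs;
      if (code[j] == 1) nfree += 1;       // het: one free bit
      else if (code[j] == 3) nfree += 2;  // missing: two free bits
    }
    if (n_obs == 0 || nfree > 18) {
      pat.flagged = true;
      pats.push_back(pat);
      continue;
    }

    // enumerate compatible (h1, h2), dedupe as unordered (lo, hi)
    std::map<std::pair<int, int>, bool> seen;
    long long ncomb = 1LL << nfree;
    for (long long cmb = 0; cmb < ncomb; ++cmb) {
      int h1 = 0, h2 = 0;
      long long bits = cmb;
      for (int j = 0; j < S; ++j) {
        int a1, a2;
        switch (code[j]) {
        case 0: a1 = 0; a2 = 0; break;
        case 2: a1 = 1; a2 = 1; break;
        case 1:
          a1 = bits & 1; bits >>= 1;
          a2 = 1 - a1;
          break;
        default: // missing: both alleles free
          a1 = bits & 1; bits >>= 1;
          a2 = bits & 1; bits >>= 1;
          break;
        }
        h1 |= a1 << j;
        h2 |= a2 << j;
      }
      int lo = h1 < h2 ? h1 : h2, hi = h1 < h2 ? h2 : h1;
      seen[std::make_pair(lo, hi)] = true;
    }
    for (std::map<std::pair<int, int>, bool>::iterator p = seen.begin();
         p != seen.end(); ++p) {
      int lo = p->first.first, hi = p->first.second;
      if (hap_index.find(lo) == hap_index.end()) {
        hap_index[lo] = hap_mask.size(); hap_mask.push_back(lo);
      }
      if (hap_index.find(hi) == hap_index.end()) {
        hap_index[hi] = hap_mask.size(); hap_mask.push_back(hi);
      }
      pat.pairs.push_back(std::make_pair(hap_index[lo], hap_index[hi]));
    }
    pats.push_back(pat);
  }

  const int H = hap_mask.size();
  int n_used = 0;
  for (size_t p = 0; p < pats.size(); ++p)
    if (!pats[p].flagged) n_used += pats[p].subjects.size();

  std::vector<double> freq(H > 0 ? H : 1, H > 0 ? 1.0 / H : 1.0);
  double ll = R_NegInf, ll_prev = R_NegInf;
  int iter = 0;
  bool converged = false;
  std::vector<double> counts(H > 0 ? H : 1);

  if (H > 0 && n_used > 0) {
    for (iter = 1; iter <= max_iter; ++iter) {
      std::fill(counts.begin(), counts.end(), 0.0);
      ll = 0.0;
      for (size_t p = 0; p < pats.size(); ++p) {
        if (pats[p].flagged) continue;
        double ng = (double)pats[p].subjects.size();
        double tot = 0.0;
        for (size_t q = 0; q < pats[p].pairs.size(); ++q) {
          int a = pats[p].pairs[q].first, b = pats[p].pairs[q].second;
          tot += freq[a] * freq[b] * (a == b ? 1.0 : 2.0);
        }
        if (tot < 1e-300) tot = 1e-300;
        ll += ng * std::log(tot);
        for (size_t q = 0; q < pats[p].pairs.size(); ++q) {
          int a = pats[p].pairs[q].first, b = pats[p].pairs[q].second;
          double w = freq[a] * freq[b] * (a == b ? 1.0 : 2.0) / tot;
          counts[a] += ng * w;
          counts[b] += ng * w;
        }
      }
      if (R_finite(ll_prev) && std::fabs(ll - ll_prev) < tol) {
        converged = true;
        break;
      }
      ll_prev = ll;
      double s = 0.0;
      for (int h = 0; h < H; ++h) {
        freq[h] = counts[h] / (2.0 * n_used);
        if (freq[h] < 1e-12) freq[h] = 1e-12;
        s += freq[h];
      }
      for (int h = 0; h < H; ++h) freq[h] /= s;
    }
    if (iter > max_iter) iter = max_iter;
  }

  IntegerMatrix hap1(n, S), hap2(n, S);
  NumericVector posterior(n);
  LogicalVector flagged(n);
  std::fill(hap1.begin(), hap1.end(), NA_INTEGER);
  std::fill(hap2.begin(), hap2.end(), NA_INTEGER);

  for (size_t p = 0; p < pats.size(); ++p) {
    if (pats[p].flagged) {
      for (size_t s = 0; s < pats[p].subjects.size(); ++s) {
        flagged[pats[p].subjects[s]] = true;
        posterior[pats[p].subjects[s]] = NA_REAL;
      }
      continue;
    }
    double tot = 0.0, best = -1.0;
    size_t best_q = 0;
    for (size_t q = 0; q < pats[p].pairs.size(); ++q) {
      int a = pats[p].pairs[q].first, b = pats[p].pairs[q].second;
      double w = freq[a] * freq[b] * (a == b ? 1.0 : 2.0);
      tot += w;
      if (w > best) { best = w; best_q = q; } // strict > keeps first on ties
    }
    int lo = hap_mask[pats[p].pairs[best_q].first];
    int hi = hap_mask[pats[p].pairs[best_q].second];
    double post = tot > 0 ? best / tot : 1.0 / pats[p].pairs.size();
    for (size_t s = 0; s < pats[p].subjects.size(); ++s) {
      int i = pats[p].subjects[s];
      flagged[i] = false;
      posterior[i] = post;
      for (int j = 0; j < S; ++j) {
        hap1(i, j) = (lo >> j) & 1;
        hap2(i, j) = (hi >> j) & 1;
      }
    }
  }

  NumericVector freq_out(H);
  IntegerVector mask_out(H);
  for (int h = 0; h < H; ++h) { freq_out[h] = freq[h]; mask_out[h] = hap_mask[h]; }

  return List::create(
    _["hap1"] = hap1,
    _["hap2"] = hap2,
    _["posterior"] = posterior,
    _["flagged"] = flagged,
    _["hap_mask"] = mask_out,
    _["hap_freq"] = freq_out,
    _["n_iter"] = iter,
    _["converged"] = converged,
    _["loglik"] = ll);
}
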