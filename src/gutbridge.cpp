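#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// 64-bit finalizer (splitmix64); platform-independent, no UB on overflow
// (unsigned arithmetic wraps).
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30;
  x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27;
  x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Bottom-s MinHash sketch of canonical k-mers over a set of sequences.
// Hash values are the top 53 bits of a seeded 64-bit mixing hash so they are
// exactly representable as R doubles. Returns the s smallest distinct values,
// ascending. k-mers containing non-ACGT symbols are skipped.
// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector seqs, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  if (s < 1) stop("sketch size must be >= 1");
  const uint64_t seed_mix =
    mix64(static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL + 0x2545f4914f6cdd1dULL);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);

  std::unordered_set<uint64_t> seen;
  bool any_kmer = false;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *p = CHAR(STRING_ELT(seqs, si));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
      rev = (rev >> 2) | (static_cast<uint64_t>(3 - b) << shift);
      if (++run >= k) {
        any_kmer = true;
        // numeric order of 2-bit codes == lexicographic order of k-mer strings
        uint64_t canon = fwd < rev ? fwd : rev;
        seen.insert(mix64(canon ^ seed_mix) >> 11);
      }
    }
  }
  if (!any_kmer) stop("no k-mer of length k found (sequences shorter than k?)");

  std::vector<uint64_t> h(seen.begin(), seen.end());
  if (static_cast<int>(h.size()) > s) {
    std::nth_element(h.begin(), h.begin() + s, h.end());
    h.resize(s);
  }
  std::sort(h.begin(), h.end());
  NumericVector out(h.size());
  for (size_t i = 0; i < h.size(); ++i) out[i] = static_cast<double>(h[i]);
  return out;
}

// Count of distinct canonical k-mers (exact, for small inputs / diagnostics).
// [[Rcpp::export]]
double cpp_count_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *p = CHAR(STRING_ELT(seqs, si));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
      rev = (rev >> 2) | (static_cast<uint64_t>(3 - b) << shift);
      if (++run >= k) seen.insert(fwd < rev ? fwd : rev);
    }
  }
  return static_cast<double>(seen.size());
}

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length L
// costs gap_open + L * gap_extend. qi/ti are 1-based indices into the rows of
// the substitution matrix. Traceback is deterministic: at each aligned cell
// ties are resolved diagonal > up (gap in target) > left (gap in query), the
// highest-scoring cell is the first encountered in row-major scan order, and
// gap runs close as early as possible.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector qi, IntegerVector ti, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int m = qi.size(), n = ti.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const double NEG = -1e30;
  const double go = gap_open + gap_extend; // cost of a gap's first position

  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG); // gap in target (vertical)
  std::vector<double> F((m + 1) * (n + 1), NEG); // gap in query (horizontal)
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[at(i, j)] = std::max(H[at(i - 1, j)] - go, E[at(i - 1, j)] - gap_extend);
      F[at(i, j)] = std::max(H[at(i, j - 1)] - go, F[at(i, j - 1)] - gap_extend);
      double diag = H[at(i - 1, j - 1)] + sub(qi[i - 1] - 1, ti[j - 1] - 1);
      double h = std::max(0.0, std::max(diag, std::max(E[at(i, j)], F[at(i, j)])));
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int matches = 0, aln_len = 0;
  int qend = bi, tend = bj, qstart = bi, tstart = bj;
  if (best > 0.0) {
    // All cell values are sums of integer substitution scores and integer gap
    // costs, hence exact in doubles: equality tests below are safe.
    int i = bi, j = bj, state = 0; // 0 = H, 1 = E (up), 2 = F (left)
    while (true) {
      if (state == 0) {
        double h = H[at(i, j)];
        if (h <= 0.0 || i == 0 || j == 0) { qstart = i + 1; tstart = j + 1; break; }
        double diag = H[at(i - 1, j - 1)] + sub(qi[i - 1] - 1, ti[j - 1] - 1);
        if (h == diag) {
          ++aln_len;
          if (qi[i - 1] == ti[j - 1]) ++matches;
          --i; --j;
        } else if (h == E[at(i, j)]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        ++aln_len; // query residue against gap in target
        bool close = (E[at(i, j)] == H[at(i - 1, j)] - go);
        --i;
        state = close ? 0 : 1;
      } else {
        ++aln_len; // gap in query against target residue
        bool close = (F[at(i, j)] == H[at(i, j - 1)] - go);
        --j;
        state = close ? 0 : 2;
      }
    }
  } else {
    qstart = qend = tstart = tend = 0;
  }

  double identity = aln_len > 0 ? 100.0 * matches / aln_len : 0.0;
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["aln_length"] = aln_len, _["identity"] = identity,
                      _["query_start"] = qstart, _["query_end"] = qend,
                      _["target_start"] = tstart, _["target_end"] = tend);
}
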