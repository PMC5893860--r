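#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Count, for each query k-mer, the number of (read, offset) windows in the
// dataset equal to the k-mer or its reverse complement. The window at offset 0
// of the query's own source read is never counted (self-match exclusion).
// k-mers are packed two bits per base into one 64-bit word (k <= 32), and the
// forward/reverse-complement codes are maintained incrementally so the scan is
// a single pass over the dataset, independent of the number of queries.
// [[Rcpp::export(name = ".kmer_counts_cpp")]]
IntegerVector kmer_counts_cpp(CharacterVector seqs, CharacterVector query_kmers,
                              IntegerVector query_src, int k) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  const int nq = query_kmers.size();
  if (query_src.size() != nq) stop("query_src length must match query_kmers");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_map<uint64_t, std::vector<int> > lookup;
  for (int q = 0; q < nq; ++q) {
    SEXP qs = STRING_ELT(query_kmers, q);
    if (LENGTH(qs) != k) stop("query k-mer %d is not %d bases long", q + 1, k);
    const char *s = CHAR(qs);
    uint64_t f = 0, r = 0;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) stop("query k-mer %d contains a non-ACGT base", q + 1);
      f = ((f << 2) | (uint64_t)c) & mask;
      r = (r >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
    }
    lookup[f < r ? f : r].push_back(q);
  }

  IntegerVector counts(nq, 0);
  const int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    SEXP rs = STRING_ELT(seqs, i);
    const char *s = CHAR(rs);
    const int L = LENGTH(rs);
    if (L < k) continue;
    uint64_t f = 0, r = 0;
    int valid = 0;  // consecutive ACGT bases ending at the current position
    for (int pos = 0; pos < L; ++pos) {
      int c = base_code(s[pos]);
      if (c < 0) { valid = 0; continue; }
      f = ((f << 2) | (uint64_t)c) & mask;
      r = (r >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
      if (++valid < k) continue;
      const uint64_t canon = f < r ? f : r;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        lookup.find(canon);
      if (it == lookup.end()) continue;
      const int off = pos - k + 1;
      const std::vector<int> &qs = it->second;
      for (size_t u = 0; u < qs.size(); ++u) {
        const int q = qs[u];
        if (off == 0 && query_src[q] == i + 1) continue;
        counts[q]++;
      }
    }
  }
  return counts;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Ungapped all-offset comparison of subject (both strands) against query.
// A candidate offset is accepted when the aligned overlap is at least
// min_ov * query length and the identity over the overlap (N never matches)
// is at least min_id. Mismatch counting aborts early once the identity
// threshold can no longer be met.
static bool align_pair(const char *q, int lq, const char *s, int ls,
                       double min_id, double min_ov) {
  int min_overlap = (int)std::ceil(min_ov * lq - 1e-9);
  if (min_overlap < 1) min_overlap = 1;
  if (min_overlap > ls) return false;
  for (int strand = 0; strand < 2; ++strand) {
    // d = query coordinate aligned with the subject's first base
    for (int d = -(ls - min_overlap); d <= lq - min_overlap; ++d) {
      const int start = d > 0 ? d : 0;
      const int end = std::min(lq, d + ls);
      const int ov = end - start;
      if (ov < min_overlap) continue;
      const int allowed = (int)std::floor((1.0 - min_id) * ov + 1e-9);
      int mism = 0;
      bool ok = true;
      for (int t = start; t < end; ++t) {
        const int j = t - d;
        const char sc = strand == 0 ? s[j] : comp_base(s[ls - 1 - j]);
        const char qc = q[t];
        if (qc == 'N' || sc == 'N' || qc != sc) {
          if (++mism > allowed) { ok = false; break; }
        }
      }
      if (ok) return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".align_match_cpp")]]
bool align_match_cpp(std::string query, std::string subject,
                     double min_id, double min_ov) {
  if (query.empty() || subject.empty()) stop("sequences must be non-empty");
  return align_pair(query.c_str(), (int)query.size(),
                    subject.c_str(), (int)subject.size(), min_id, min_ov);
}

// m_i = number of dataset reads (excluding the query's own source read)
// matched by align_pair.
// [[Rcpp::export(name = ".alignment_counts_cpp")]]
IntegerVector alignment_counts_cpp(CharacterVector seqs, IntegerVector query_src,
                                   double min_id, double min_ov) {
  const int nq = query_src.size();
  const int n = seqs.size();
  IntegerVector counts(nq, 0);
  for (int q = 0; q < nq; ++q) {
    const int src = query_src[q] - 1;
    if (src < 0 || src >= n) stop("query source index out of range");
    SEXP qs = STRING_ELT(seqs, src);
    const char *qp = CHAR(qs);
    const int lq = LENGTH(qs);
    if (lq == 0) continue;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      if (i == src) continue;
      SEXP ss = STRING_ELT(seqs, i);
      const int ls = LENGTH(ss);
      if (ls == 0) continue;
      if (align_pair(qp, lq, CHAR(ss), ls, min_id, min_ov)) m++;
    }
    counts[q] = m;
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(x, i);
    const char *p = CHAR(s);
    const int L = LENGTH(s);
    buf.assign(L, 'N');
    for (int j = 0; j < L; ++j) buf[L - 1 - j] = comp_base(p[j]);
    out[i] = buf;
  }
  return out;
}
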