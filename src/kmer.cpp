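// Kmer packing, canonicalization and the genome-wide repetitive-kmer filter.
#include "mv_core.h"
using namespace Rcpp;

uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// Sliding canonical codes over seq; valid[p] == false where the kmer at p
// overlaps a non-ACGT base. Rolling 2-bit packing: forward code extends on
// the right, reverse-complement code on the left, canonical = min of the two.
void kmer_codes_canonical(const std::string& seq, int k,
                          std::vector<uint64_t>& out,
                          std::vector<bool>& valid) {
  int64_t n = (int64_t)seq.size() - k + 1;
  out.assign(n > 0 ? n : 0, 0);
  valid.assign(n > 0 ? n : 0, false);
  if (n <= 0) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0; // count of consecutive valid bases ending at current position
  for (int64_t i = 0; i < (int64_t)seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) {
      run = 0; fwd = 0; rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++run;
    if (run >= k) {
      int64_t p = i - k + 1;
      out[p] = fwd < rev ? fwd : rev;
      valid[p] = true;
    }
  }
}

static std::string code_to_kmer(uint64_t code, int k) {
  static const char* b = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = b[code & 3ULL]; code >>= 2; }
  return s;
}

// [[Rcpp::export]]
List cpp_kmer_set(std::string seq, int k, SEXP filter_xp) {
  if ((int64_t)seq.size() < k) stop("sequence shorter than k");
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::vector<uint64_t> codes; std::vector<bool> ok;
  kmer_codes_canonical(seq, k, codes, ok);
  const KmerFilterCpp* flt = nullptr;
  if (filter_xp != R_NilValue) flt = XPtr<KmerFilterCpp>(filter_xp).get();
  std::vector<int> pos; std::vector<double> code_d; std::vector<std::string> km;
  for (size_t p = 0; p < codes.size(); ++p) {
    if (!ok[p]) continue;
    if (flt && flt->repetitive.count(codes[p])) continue;
    pos.push_back((int)p);
    code_d.push_back((double)codes[p]);
    km.push_back(code_to_kmer(codes[p], k));
  }
  return List::create(_["pos"] = pos, _["kmer"] = km, _["code"] = code_d);
}

// [[Rcpp::export]]
SEXP cpp_build_kmer_filter(std::vector<std::string> seqs, int k, int cmax) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  bool any_ok = false;
  std::unordered_map<uint64_t, int64_t> counts;
  for (const std::string& s : seqs) {
    if ((int64_t)s.size() < k) continue;
    any_ok = true;
    std::vector<uint64_t> codes; std::vector<bool> ok;
    kmer_codes_canonical(s, k, codes, ok);
    for (size_t p = 0; p < codes.size(); ++p)
      if (ok[p]) ++counts[codes[p]];
  }
  if (!any_ok) stop("k is larger than every reference sequence");
  XPtr<KmerFilterCpp> xp(new KmerFilterCpp(), true);
  xp->k = k; xp->cmax = cmax;
  for (auto& kv : counts)
    if (kv.second > cmax) xp->repetitive.insert(kv.first);
  return xp;
}

// [[Rcpp::export]]
int cpp_filter_size(SEXP filter_xp) {
  XPtr<KmerFilterCpp> xp(filter_xp);
  return (int)xp->repetitive.size();
}

// [[Rcpp::export]]
LogicalVector cpp_kmer_is_repetitive(SEXP filter_xp, std::vector<std::string> kmers) {
  XPtr<KmerFilterCpp> xp(filter_xp);
  LogicalVector out(kmers.size());
  for (size_t i = 0; i < kmers.size(); ++i) {
    std::vector<uint64_t> codes; std::vector<bool> ok;
    kmer_codes_canonical(kmers[i], xp->k, codes, ok);
    if (codes.empty() || (int)kmers[i].size() != xp->k)
      stop("kmer length does not match filter k");
    out[i] = !ok[0] || xp->repetitive.count(codes[0]) > 0;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmer(std::vector<std::string> kmers) {
  CharacterVector out(kmers.size());
  for (size_t i = 0; i < kmers.size(); ++i) {
    int k = (int)kmers[i].size();
    if (k > 26) stop("kmer longer than 26 bp");
    std::vector<uint64_t> codes; std::vector<bool> ok;
    kmer_codes_canonical(kmers[i], k, codes, ok);
    if (ok[0]) out[i] = code_to_kmer(codes[0], k); else out[i] = NA_STRING;
  }
  return out;
}
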