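// MinHash fingerprinting: universal hash family h_i(x) = a_i*x + b_i over
// base-mixed kmer codes, direct fingerprints, and the rolling computation
// over consecutive genome windows (per-function monotone deques, bit-identical
// to the direct per-window fingerprint).
#include "mv_core.h"
using namespace Rcpp;

HashFamily make_family(int L, uint64_t seed) {
  HashFamily f;
  f.seed = seed;
  MvRng rng(mv_stream_seed(seed, 0xFA111ULL));
  f.a.resize(L); f.b.resize(L);
  for (int i = 0; i < L; ++i) {
    f.a[i] = rng.next() | 1ULL; // odd => bijective mod 2^64
    f.b[i] = rng.next();
  }
  return f;
}

FingerprintCpp fingerprint_codes(const std::vector<uint64_t>& codes,
                                 const HashFamily& fam, int min_kmers) {
  FingerprintCpp fp;
  fp.n_kmers = (int)codes.size();
  fp.valid = fp.n_kmers >= min_kmers && fp.n_kmers > 0;
  int L = fam.L();
  fp.mins.assign(L, ~0ULL);
  for (uint64_t c : codes) {
    uint64_t h = splitmix64(c);
    for (int i = 0; i < L; ++i) {
      uint64_t v = fam.a[i] * h + fam.b[i];
      if (v < fp.mins[i]) fp.mins[i] = v;
    }
  }
  return fp;
}

// Rolling scan: one fingerprint per window start, each equal to the direct
// fingerprint of that window's filtered kmer set. A monotone deque per hash
// function keeps (position, value) with values increasing from the front;
// the front is the window minimum.
void rolling_scan(const std::string& seq, int W, int k, const HashFamily& fam,
                  const KmerFilterCpp* filter, int min_kmers,
                  const std::function<void(int64_t, const FingerprintCpp&)>& fn) {
  int64_t n = (int64_t)seq.size();
  if (W > n) Rcpp::stop("window length exceeds sequence length");
  int L = fam.L();
  std::vector<uint64_t> codes; std::vector<bool> ok;
  kmer_codes_canonical(seq, k, codes, ok);
  std::vector<bool> present(codes.size());
  for (size_t p = 0; p < codes.size(); ++p)
    present[p] = ok[p] && !(filter && filter->repetitive.count(codes[p]));
  // prefix counts of surviving kmer positions
  std::vector<int64_t> cum(codes.size() + 1, 0);
  for (size_t p = 0; p < codes.size(); ++p)
    cum[p + 1] = cum[p] + (present[p] ? 1 : 0);

  int km_per_win = W - k + 1;
  std::vector<std::deque<std::pair<int64_t, uint64_t>>> dq(L);
  FingerprintCpp fp;
  fp.mins.assign(L, 0);
  int64_t next_k = 0;
  for (int64_t p = 0; p + W <= n; ++p) {
    int64_t last_k = p + km_per_win - 1;
    for (; next_k <= last_k; ++next_k) {
      if (!present[next_k]) continue;
      uint64_t h = splitmix64(codes[next_k]);
      for (int i = 0; i < L; ++i) {
        uint64_t v = fam.a[i] * h + fam.b[i];
        auto& d = dq[i];
        while (!d.empty() && d.back().second >= v) d.pop_back();
        d.emplace_back(next_k, v);
      }
    }
    int n_kmers = (int)(cum[last_k + 1] - cum[p]);
    fp.n_kmers = n_kmers;
    fp.valid = n_kmers >= min_kmers && n_kmers > 0;
    if (fp.valid) {
      for (int i = 0; i < L; ++i) {
        auto& d = dq[i];
        while (!d.empty() && d.front().first < p) d.pop_front();
        fp.mins[i] = d.front().second;
      }
    } else {
      // still expire fronts so state stays consistent
      for (int i = 0; i < L; ++i) {
        auto& d = dq[i];
        while (!d.empty() && d.front().first < p) d.pop_front();
      }
    }
    fn(p, fp);
  }
}

// ---------------------------------------------------------------------------
// R surface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_hash_family(int L, double seed) {
  if (L < 1) stop("L must be >= 1");
  XPtr<HashFamily> xp(new HashFamily(make_family(L, (uint64_t)seed)), true);
  return xp;
}

// [[Rcpp::export]]
List cpp_family_coeffs(SEXP fam_xp) {
  XPtr<HashFamily> f(fam_xp);
  int L = f->L();
  NumericVector ah(L), al(L), bh(L), bl(L);
  for (int i = 0; i < L; ++i) {
    ah[i] = u64_hi(f->a[i]); al[i] = u64_lo(f->a[i]);
    bh[i] = u64_hi(f->b[i]); bl[i] = u64_lo(f->b[i]);
  }
  return List::create(_["a_hi"] = ah, _["a_lo"] = al,
                      _["b_hi"] = bh, _["b_lo"] = bl);
}

static List fp_to_list(const FingerprintCpp& fp) {
  int L = (int)fp.mins.size();
  NumericVector hi(L), lo(L);
  for (int i = 0; i < L; ++i) { hi[i] = u64_hi(fp.mins[i]); lo[i] = u64_lo(fp.mins[i]); }
  return List::create(_["hi"] = hi, _["lo"] = lo, _["valid"] = fp.valid,
                      _["n_kmers"] = fp.n_kmers);
}

FingerprintCpp fp_from_list(List fp) {
  FingerprintCpp out;
  NumericVector hi = fp["hi"], lo = fp["lo"];
  out.mins.resize(hi.size());
  for (int i = 0; i < hi.size(); ++i) out.mins[i] = u64_from(hi[i], lo[i]);
  out.valid = as<bool>(fp["valid"]);
  out.n_kmers = as<int>(fp["n_kmers"]);
  return out;
}

// [[Rcpp::export]]
List cpp_fingerprint(NumericVector codes, SEXP fam_xp, int min_kmers) {
  XPtr<HashFamily> f(fam_xp);
  std::vector<uint64_t> cs(codes.size());
  for (int i = 0; i < codes.size(); ++i) cs[i] = (uint64_t)codes[i];
  return fp_to_list(fingerprint_codes(cs, *f, min_kmers));
}

// [[Rcpp::export]]
List cpp_rolling_fingerprints(std::string seq, int W, int k, SEXP fam_xp,
                              SEXP filter_xp, int min_kmers) {
  XPtr<HashFamily> f(fam_xp);
  const KmerFilterCpp* flt = nullptr;
  if (filter_xp != R_NilValue) flt = XPtr<KmerFilterCpp>(filter_xp).get();
  if (W < k) stop("window length must be >= k");
  int L = f->L();
  int64_t nwin = (int64_t)seq.size() - W + 1;
  if (nwin < 1) stop("window length exceeds sequence length");
  NumericMatrix hi(L, nwin), lo(L, nwin);
  LogicalVector valid(nwin);
  IntegerVector nk(nwin), pos(nwin);
  rolling_scan(seq, W, k, *f, flt, min_kmers,
               [&](int64_t p, const FingerprintCpp& fp) {
                 pos[p] = (int)p;
                 valid[p] = fp.valid;
                 nk[p] = fp.n_kmers;
                 if (fp.valid)
                   for (int i = 0; i < L; ++i) {
                     hi(i, p) = u64_hi(fp.mins[i]);
                     lo(i, p) = u64_lo(fp.mins[i]);
                   }
               });
  return List::create(_["pos"] = pos, _["valid"] = valid, _["n_kmers"] = nk,
                      _["hi"] = hi, _["lo"] = lo);
}
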