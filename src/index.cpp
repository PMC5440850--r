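// The MinHash reference genome index (MHG): T hash tables of 2^M buckets,
// each bucket holding contig-compressed runs of consecutive genome windows
// whose fingerprint projection hashed there.
#include "mv_core.h"
#include <fstream>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

ProjectionSetCpp make_projections(int T, int b, int L, int M, uint64_t seed) {
  ProjectionSetCpp ps;
  ps.M = M;
  MvRng rng(mv_stream_seed(seed, 0x9807ULL));
  ps.P.resize(T);
  for (int t = 0; t < T; ++t) {
    // b distinct indices into [0, L) by partial Fisher-Yates
    std::vector<int> idx(L);
    for (int i = 0; i < L; ++i) idx[i] = i;
    ps.P[t].resize(b);
    for (int i = 0; i < b; ++i) {
      int j = i + (int)rng.next_below(L - i);
      std::swap(idx[i], idx[j]);
      ps.P[t][i] = idx[i];
    }
  }
  ps.A.resize(b);
  for (int i = 0; i < b; ++i) ps.A[i] = rng.next() | 1ULL;
  return ps;
}

// [[Rcpp::export]]
List cpp_init_projections(int T, int b, int L, int M, double seed) {
  if (b > L) stop("b must be <= L");
  if (T < 1) stop("T must be >= 1");
  if (M < 1 || M > 32) stop("M must be in [1, 32]");
  ProjectionSetCpp ps = make_projections(T, b, L, M, (uint64_t)seed);
  IntegerMatrix P(T, b);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < b; ++i) P(t, i) = ps.P[t][i];
  NumericVector ah(b), al(b);
  for (int i = 0; i < b; ++i) { ah[i] = u64_hi(ps.A[i]); al[i] = u64_lo(ps.A[i]); }
  return List::create(_["P"] = P, _["A_hi"] = ah, _["A_lo"] = al, _["M"] = M);
}

static ProjectionSetCpp proj_from_list(List pl) {
  ProjectionSetCpp ps;
  IntegerMatrix P = pl["P"];
  NumericVector ah = pl["A_hi"], al = pl["A_lo"];
  ps.M = as<int>(pl["M"]);
  ps.P.resize(P.nrow());
  for (int t = 0; t < P.nrow(); ++t) {
    ps.P[t].resize(P.ncol());
    for (int i = 0; i < P.ncol(); ++i) ps.P[t][i] = P(t, i);
  }
  ps.A.resize(ah.size());
  for (int i = 0; i < ah.size(); ++i) ps.A[i] = u64_from(ah[i], al[i]);
  return ps;
}

// [[Rcpp::export]]
double cpp_bucket_hash(List fp, int t, List proj) {
  FingerprintCpp f = fp_from_list(fp);
  if (!f.valid) stop("fingerprint is not valid");
  ProjectionSetCpp ps = proj_from_list(proj);
  if (t < 0 || t >= (int)ps.P.size()) stop("table id out of range");
  return (double)bucket_hash_cpp(f.mins, ps, t);
}

// ---------------------------------------------------------------------------
// index construction
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_build_index(std::vector<std::string> seqs,
                     std::vector<std::string> names, List params) {
  int W = as<int>(params["W"]), k = as<int>(params["k_mh"]);
  int L = as<int>(params["L"]), T = as<int>(params["T"]);
  int b = as<int>(params["b"]), M = as<int>(params["M"]);
  int min_kmers = as<int>(params["min_kmers"]);
  int bucket_cap = as<int>(params["bucket_cap"]);
  int cmax = as<int>(params["C_max"]);
  uint64_t seed = (uint64_t)as<double>(params["seed"]);

  XPtr<MHGIndexCpp> xp(new MHGIndexCpp(), true);
  MHGIndexCpp& idx = *xp;
  idx.W = W; idx.k_mh = k; idx.L = L; idx.T = T; idx.b = b; idx.M = M;
  idx.min_kmers = min_kmers; idx.bucket_cap = bucket_cap; idx.cmax = cmax;
  idx.seed = seed;
  idx.fam = make_family(L, seed);
  idx.proj = make_projections(T, b, L, M, seed);
  idx.tables.resize(T);

  // repetitive-kmer filter over the whole reference
  idx.filter.k = k; idx.filter.cmax = cmax;
  {
    std::unordered_map<uint64_t, int64_t> counts;
    for (const std::string& s : seqs) {
      std::vector<uint64_t> codes; std::vector<bool> ok;
      kmer_codes_canonical(s, k, codes, ok);
      for (size_t p = 0; p < codes.size(); ++p)
        if (ok[p]) ++counts[codes[p]];
    }
    for (auto& kv : counts)
      if (kv.second > cmax) idx.filter.repetitive.insert(kv.first);
  }

  int64_t off = 0;
  for (size_t s = 0; s < seqs.size(); ++s) {
    if ((int64_t)seqs[s].size() < W)
      stop("reference sequence '%s' is shorter than the window length",
           names[s].c_str());
    idx.seq_names.push_back(names[s]);
    idx.seq_offsets.push_back(off);
    idx.seq_lens.push_back((int64_t)seqs[s].size());

    rolling_scan(seqs[s], W, k, idx.fam, &idx.filter, min_kmers,
                 [&](int64_t p, const FingerprintCpp& fp) {
                   if (!fp.valid) return;
                   ++idx.n_valid_windows;
                   int64_t g = off + p;
                   for (int t = 0; t < T; ++t) {
                     uint32_t h = bucket_hash_cpp(fp.mins, idx.proj, t);
                     std::vector<ContigEntry>& v = idx.tables[t][h];
                     if (!v.empty() &&
                         v.back().start + v.back().len == g)
                       ++v.back().len; // extend the run
                     else
                       v.push_back(ContigEntry{g, 1});
                   }
                 });
    off += (int64_t)seqs[s].size();
  }
  idx.genome_len = off;
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idx_xp) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  int64_t n_entries = 0, n_buckets = 0, max_bucket = 0;
  for (auto& tab : xp->tables)
    for (auto& kv : tab) {
      ++n_buckets;
      n_entries += (int64_t)kv.second.size();
      max_bucket = std::max(max_bucket, (int64_t)kv.second.size());
    }
  return List::create(
      _["W"] = xp->W, _["k_mh"] = xp->k_mh, _["L"] = xp->L, _["T"] = xp->T,
      _["b"] = xp->b, _["M"] = xp->M, _["min_kmers"] = xp->min_kmers,
      _["bucket_cap"] = xp->bucket_cap, _["C_max"] = xp->cmax,
      _["seed"] = (double)xp->seed, _["genome_len"] = (double)xp->genome_len,
      _["n_valid_windows"] = (double)xp->n_valid_windows,
      _["n_entries"] = (double)n_entries, _["n_buckets"] = (double)n_buckets,
      _["max_bucket"] = (double)max_bucket,
      _["n_repetitive_kmers"] = (double)xp->filter.repetitive.size(),
      _["seq_names"] = wrap(xp->seq_names),
      _["seq_offsets"] = NumericVector(xp->seq_offsets.begin(), xp->seq_offsets.end()),
      _["seq_lens"] = NumericVector(xp->seq_lens.begin(), xp->seq_lens.end()));
}

// fingerprint a read with the index's own family and repeat filter
// [[Rcpp::export]]
List cpp_index_fingerprint(SEXP idx_xp, std::string seq, int min_kmers) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  std::vector<uint64_t> codes; std::vector<bool> ok;
  kmer_codes_canonical(seq, xp->k_mh, codes, ok);
  std::vector<uint64_t> kept;
  for (size_t p = 0; p < codes.size(); ++p)
    if (ok[p] && !xp->filter.repetitive.count(codes[p])) kept.push_back(codes[p]);
  FingerprintCpp fp = fingerprint_codes(kept, xp->fam, min_kmers);
  int L = xp->L;
  NumericVector hi(L), lo(L);
  for (int i = 0; i < L; ++i) { hi[i] = u64_hi(fp.mins[i]); lo[i] = u64_lo(fp.mins[i]); }
  return List::create(_["hi"] = hi, _["lo"] = lo, _["valid"] = fp.valid,
                      _["n_kmers"] = fp.n_kmers);
}

// [[Rcpp::export]]
List cpp_index_lookup(SEXP idx_xp, List fp) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  FingerprintCpp f = fp_from_list(fp);
  if (!f.valid) stop("fingerprint is not valid");
  if ((int)f.mins.size() != xp->L) stop("fingerprint length does not match index");
  List out(xp->T);
  for (int t = 0; t < xp->T; ++t) {
    uint32_t h = bucket_hash_cpp(f.mins, xp->proj, t);
    auto it = xp->tables[t].find(h);
    if (it == xp->tables[t].end() ||
        (int)it->second.size() > xp->bucket_cap) {
      out[t] = List::create(_["start"] = NumericVector(0),
                            _["len"] = IntegerVector(0),
                            _["bucket"] = (double)h);
      continue;
    }
    const std::vector<ContigEntry>& v = it->second;
    NumericVector st(v.size()); IntegerVector ln(v.size());
    for (size_t i = 0; i < v.size(); ++i) { st[i] = (double)v[i].start; ln[i] = v[i].len; }
    out[t] = List::create(_["start"] = st, _["len"] = ln, _["bucket"] = (double)h);
  }
  return out;
}

// expand every contig entry (for losslessness checks): one row per entry
// [[Rcpp::export]]
List cpp_index_entries(SEXP idx_xp) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  std::vector<int> tt; std::vector<double> bb, ss; std::vector<int> ll;
  for (int t = 0; t < xp->T; ++t) {
    // deterministic order: sort buckets by id
    std::vector<uint32_t> keys;
    keys.reserve(xp->tables[t].size());
    for (auto& kv : xp->tables[t]) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    for (uint32_t kk : keys) {
      for (const ContigEntry& e : xp->tables[t].at(kk)) {
        tt.push_back(t); bb.push_back((double)kk);
        ss.push_back((double)e.start); ll.push_back(e.len);
      }
    }
  }
  return List::create(_["table"] = tt, _["bucket"] = bb, _["start"] = ss,
                      _["len"] = ll);
}

// Brute-force oracle: per-window (window, table, bucket) assignments computed
// with DIRECT per-window fingerprints (no rolling, no compression).
// [[Rcpp::export]]
List cpp_window_buckets_direct(std::vector<std::string> seqs, List params) {
  int W = as<int>(params["W"]), k = as<int>(params["k_mh"]);
  int L = as<int>(params["L"]), T = as<int>(params["T"]);
  int b = as<int>(params["b"]), M = as<int>(params["M"]);
  int min_kmers = as<int>(params["min_kmers"]);
  int cmax = as<int>(params["C_max"]);
  uint64_t seed = (uint64_t)as<double>(params["seed"]);
  HashFamily fam = make_family(L, seed);
  ProjectionSetCpp ps = make_projections(T, b, L, M, seed);

  KmerFilterCpp flt; flt.k = k; flt.cmax = cmax;
  {
    std::unordered_map<uint64_t, int64_t> counts;
    for (const std::string& s : seqs) {
      std::vector<uint64_t> codes; std::vector<bool> ok;
      kmer_codes_canonical(s, k, codes, ok);
      for (size_t p = 0; p < codes.size(); ++p)
        if (ok[p]) ++counts[codes[p]];
    }
    for (auto& kv : counts)
      if (kv.second > cmax) flt.repetitive.insert(kv.first);
  }

  std::vector<double> gpos, bucket; std::vector<int> table;
  int64_t off = 0;
  for (const std::string& s : seqs) {
    std::vector<uint64_t> codes; std::vector<bool> ok;
    kmer_codes_canonical(s, k, codes, ok);
    int64_t nwin = (int64_t)s.size() - W + 1;
    for (int64_t p = 0; p < nwin; ++p) {
      std::vector<uint64_t> kept;
      for (int64_t q = p; q <= p + W - k; ++q)
        if (ok[q] && !flt.repetitive.count(codes[q])) kept.push_back(codes[q]);
      FingerprintCpp fp = fingerprint_codes(kept, fam, min_kmers);
      if (!fp.valid) continue;
      for (int t = 0; t < T; ++t) {
        gpos.push_back((double)(off + p));
        table.push_back(t);
        bucket.push_back((double)bucket_hash_cpp(fp.mins, ps, t));
      }
    }
    off += (int64_t)s.size();
  }
  return List::create(_["gpos"] = gpos, _["table"] = table, _["bucket"] = bucket);
}

// ---------------------------------------------------------------------------
// serialization: versioned little-endian binary with a JSON text header
// ---------------------------------------------------------------------------
static const char MV_MAGIC[8] = {'M','V','M','H','G','I','D','X'};
static const uint32_t MV_VERSION = 1;

template <typename Tv> static void wr(std::ofstream& f, Tv x) {
  f.write(reinterpret_cast<const char*>(&x), sizeof(Tv));
}
template <typename Tv> static Tv rd(std::ifstream& f) {
  Tv x; f.read(reinterpret_cast<char*>(&x), sizeof(Tv));
  if (!f) stop("corrupt or truncated index file");
  return x;
}
static void wr_str(std::ofstream& f, const std::string& s) {
  wr<uint32_t>(f, (uint32_t)s.size());
  f.write(s.data(), s.size());
}
static std::string rd_str(std::ifstream& f) {
  uint32_t n = rd<uint32_t>(f);
  std::string s(n, '\0');
  f.read(&s[0], n);
  if (!f) stop("corrupt or truncated index file");
  return s;
}

// [[Rcpp::export]]
void cpp_save_index(SEXP idx_xp, std::string path, std::string json_header) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  std::ofstream f(path, std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write(MV_MAGIC, 8);
  wr<uint32_t>(f, MV_VERSION);
  wr_str(f, json_header);
  const MHGIndexCpp& x = *xp;
  wr<int32_t>(f, x.W); wr<int32_t>(f, x.k_mh); wr<int32_t>(f, x.L);
  wr<int32_t>(f, x.T); wr<int32_t>(f, x.b); wr<int32_t>(f, x.M);
  wr<int32_t>(f, x.min_kmers); wr<int32_t>(f, x.bucket_cap);
  wr<int32_t>(f, x.cmax); wr<uint64_t>(f, x.seed);
  wr<int64_t>(f, x.genome_len); wr<int64_t>(f, x.n_valid_windows);
  wr<uint32_t>(f, (uint32_t)x.seq_names.size());
  for (size_t i = 0; i < x.seq_names.size(); ++i) {
    wr_str(f, x.seq_names[i]);
    wr<int64_t>(f, x.seq_offsets[i]);
    wr<int64_t>(f, x.seq_lens[i]);
  }
  wr<uint64_t>(f, (uint64_t)x.filter.repetitive.size());
  {
    std::vector<uint64_t> reps(x.filter.repetitive.begin(), x.filter.repetitive.end());
    std::sort(reps.begin(), reps.end());
    for (uint64_t r : reps) wr<uint64_t>(f, r);
  }
  for (int t = 0; t < x.T; ++t) {
    std::vector<uint32_t> keys;
    keys.reserve(x.tables[t].size());
    for (auto& kv : x.tables[t]) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    wr<uint32_t>(f, (uint32_t)keys.size());
    for (uint32_t kk : keys) {
      const std::vector<ContigEntry>& v = x.tables[t].at(kk);
      wr<uint32_t>(f, kk);
      wr<uint32_t>(f, (uint32_t)v.size());
      for (const ContigEntry& e : v) { wr<int64_t>(f, e.start); wr<int32_t>(f, e.len); }
    }
  }
  if (!f) stop("write to '%s' failed", path.c_str());
}

// [[Rcpp::export]]
List cpp_load_index(std::string path) {
  std::ifstream f(path, std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  char magic[8];
  f.read(magic, 8);
  if (!f || std::memcmp(magic, MV_MAGIC, 8) != 0)
    stop("'%s' is not an MHG index file", path.c_str());
  uint32_t version = rd<uint32_t>(f);
  if (version != MV_VERSION)
    stop("index format version %d not supported (expected %d)",
         (int)version, (int)MV_VERSION);
  std::string header = rd_str(f);
  XPtr<MHGIndexCpp> xp(new MHGIndexCpp(), true);
  MHGIndexCpp& x = *xp;
  x.W = rd<int32_t>(f); x.k_mh = rd<int32_t>(f); x.L = rd<int32_t>(f);
  x.T = rd<int32_t>(f); x.b = rd<int32_t>(f); x.M = rd<int32_t>(f);
  x.min_kmers = rd<int32_t>(f); x.bucket_cap = rd<int32_t>(f);
  x.cmax = rd<int32_t>(f); x.seed = rd<uint64_t>(f);
  x.genome_len = rd<int64_t>(f); x.n_valid_windows = rd<int64_t>(f);
  uint32_t nseq = rd<uint32_t>(f);
  for (uint32_t i = 0; i < nseq; ++i) {
    x.seq_names.push_back(rd_str(f));
    x.seq_offsets.push_back(rd<int64_t>(f));
    x.seq_lens.push_back(rd<int64_t>(f));
  }
  x.fam = make_family(x.L, x.seed);
  x.proj = make_projections(x.T, x.b, x.L, x.M, x.seed);
  x.filter.k = x.k_mh; x.filter.cmax = x.cmax;
  uint64_t nrep = rd<uint64_t>(f);
  for (uint64_t i = 0; i < nrep; ++i) x.filter.repetitive.insert(rd<uint64_t>(f));
  x.tables.resize(x.T);
  for (int t = 0; t < x.T; ++t) {
    uint32_t nb = rd<uint32_t>(f);
    for (uint32_t i = 0; i < nb; ++i) {
      uint32_t kk = rd<uint32_t>(f);
      uint32_t ne = rd<uint32_t>(f);
      std::vector<ContigEntry>& v = x.tables[t][kk];
      v.resize(ne);
      for (uint32_t j = 0; j < ne; ++j) {
        v[j].start = rd<int64_t>(f);
        v[j].len = rd<int32_t>(f);
      }
    }
  }
  return List::create(_["ptr"] = xp, _["header"] = header);
}
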