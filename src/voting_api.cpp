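// R surface for the voting module: fine-grained operations used by the
// package API and the tests. The batch aligner (align.cpp) shares the same
// internals.
#include "mv_core.h"
using namespace Rcpp;

List task_to_list(const VotingTaskCpp& t) {
  int nr = (int)t.read_k.size(), nc = (int)t.contig_k.size();
  NumericVector rhi(nr), rlo(nr), chi(nc), clo(nc);
  IntegerVector rbin(nr), cbin(nc);
  LogicalVector rm(nr), cm(nc);
  for (int i = 0; i < nr; ++i) {
    rhi[i] = u64_hi(t.read_k[i].h); rlo[i] = u64_lo(t.read_k[i].h);
    rbin[i] = t.read_k[i].bin;
    rm[i] = t.read_rec_masked.empty() ? false : (bool)t.read_rec_masked[i];
  }
  for (int i = 0; i < nc; ++i) {
    chi[i] = u64_hi(t.contig_k[i].h); clo[i] = u64_lo(t.contig_k[i].h);
    cbin[i] = t.contig_k[i].bin;
    cm[i] = t.contig_rec_masked.empty() ? false : (bool)t.contig_rec_masked[i];
  }
  LogicalVector rmask(t.read_mask.size()), cmask(t.contig_mask.size());
  for (size_t i = 0; i < t.read_mask.size(); ++i) rmask[i] = (bool)t.read_mask[i];
  for (size_t i = 0; i < t.contig_mask.size(); ++i) cmask[i] = (bool)t.contig_mask[i];
  return List::create(
      _["task_id"] = (double)t.task_id, _["beta"] = t.beta, _["rho"] = t.rho,
      _["v"] = t.v, _["n_read_pos"] = t.n_read_pos,
      _["n_contig_pos"] = t.n_contig_pos, _["pad"] = t.pad,
      _["chunk_off"] = (double)t.chunk_off,
      _["read_hi"] = rhi, _["read_lo"] = rlo, _["read_bin"] = rbin,
      _["read_masked"] = rm,
      _["contig_hi"] = chi, _["contig_lo"] = clo, _["contig_bin"] = cbin,
      _["contig_masked"] = cm,
      _["read_pos_mask"] = rmask, _["contig_pos_mask"] = cmask);
}

VotingTaskCpp list_to_task(List l) {
  VotingTaskCpp t;
  t.task_id = (uint64_t)as<double>(l["task_id"]);
  t.beta = as<int>(l["beta"]);
  t.rho = as<double>(l["rho"]);
  t.v = as<int>(l["v"]);
  t.n_read_pos = as<int>(l["n_read_pos"]);
  t.n_contig_pos = as<int>(l["n_contig_pos"]);
  t.pad = as<int>(l["pad"]);
  t.chunk_off = (int64_t)as<double>(l["chunk_off"]);
  NumericVector rhi = l["read_hi"], rlo = l["read_lo"];
  IntegerVector rbin = l["read_bin"];
  NumericVector chi = l["contig_hi"], clo = l["contig_lo"];
  IntegerVector cbin = l["contig_bin"];
  t.read_k.resize(rhi.size());
  for (int i = 0; i < rhi.size(); ++i)
    t.read_k[i] = VKmer{u64_from(rhi[i], rlo[i]), rbin[i]};
  t.contig_k.resize(chi.size());
  for (int i = 0; i < chi.size(); ++i)
    t.contig_k[i] = VKmer{u64_from(chi[i], clo[i]), cbin[i]};
  return t;
}

// [[Rcpp::export]]
List cpp_make_task_keys(double master_seed, double task_id) {
  TaskKeysCpp k = make_task_keys((uint64_t)master_seed, (uint64_t)task_id);
  RawVector K(32);
  for (int i = 0; i < 32; ++i) K[i] = k.K[i];
  return List::create(_["K"] = K,
                      _["k1_hi"] = u64_hi(k.k1), _["k1_lo"] = u64_lo(k.k1),
                      _["k2_hi"] = u64_hi(k.k2), _["k2_lo"] = u64_lo(k.k2));
}

// ((h_K(s) XOR k1) * k2) mod 2^64 with h_K(s) = first 64 bits of SHA-1(K||s)
// [[Rcpp::export]]
List cpp_keyed_kmer_hash(NumericVector codes, RawVector K,
                         double k1_hi, double k1_lo,
                         double k2_hi, double k2_lo) {
  if (K.size() != 32) stop("K must be a 32-byte (256-bit) key");
  TaskKeysCpp keys;
  for (int i = 0; i < 32; ++i) keys.K[i] = K[i];
  keys.k1 = u64_from(k1_hi, k1_lo);
  keys.k2 = u64_from(k2_hi, k2_lo);
  if ((keys.k2 & 1ULL) == 0) stop("k2 must be odd");
  NumericVector hi(codes.size()), lo(codes.size());
  for (int i = 0; i < codes.size(); ++i) {
    uint64_t base = keyed_base_hash(keys.K, (uint64_t)codes[i]);
    uint64_t h = (base ^ keys.k1) * keys.k2;
    hi[i] = u64_hi(h); lo[i] = u64_lo(h);
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// [[Rcpp::export]]
List cpp_prepare_tasks(std::string read_seq, std::string contig_seq, int v,
                       int beta, double rho, bool secure, double master_seed,
                       double task_id0, int chunk_cap_mult) {
  if ((int64_t)read_seq.size() < v) stop("read shorter than the voting kmer length");
  if (contig_seq.size() < read_seq.size())
    stop("contig must be at least as long as the read");
  std::vector<uint64_t> rc, cc; std::vector<bool> rok, cok;
  kmer_codes_canonical(read_seq, v, rc, rok);
  kmer_codes_canonical(contig_seq, v, cc, cok);
  TaskKeysCpp session = make_task_keys((uint64_t)master_seed, 0);
  std::vector<uint64_t> rbase(rc.size()), cbase(cc.size());
  for (size_t i = 0; i < rc.size(); ++i)
    rbase[i] = !rok[i] ? 0
               : (secure ? keyed_base_hash(session.K, rc[i]) : splitmix64(rc[i]));
  for (size_t i = 0; i < cc.size(); ++i)
    cbase[i] = !cok[i] ? 0
               : (secure ? keyed_base_hash(session.K, cc[i]) : splitmix64(cc[i]));
  uint64_t counter = (uint64_t)task_id0;
  std::vector<uint8_t> cok8(cok.size());
  for (size_t i = 0; i < cok.size(); ++i) cok8[i] = cok[i] ? 1 : 0;
  std::vector<VotingTaskCpp> ts = make_pair_tasks(
      rbase, rok, cbase.data(), cok8.data(),
      (int64_t)contig_seq.size(), v, beta, rho, secure, (uint64_t)master_seed,
      counter, (int)read_seq.size(), chunk_cap_mult);
  List out(ts.size());
  for (size_t i = 0; i < ts.size(); ++i) out[i] = task_to_list(ts[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_cast_votes(List task) {
  VotingTaskCpp t = list_to_task(task);
  VoteVec vv = cast_votes_cpp(t);
  return List::create(_["phi0"] = vv.phi0,
                      _["V"] = IntegerVector(vv.V.begin(), vv.V.end()));
}

// [[Rcpp::export]]
IntegerVector cpp_convolve(IntegerVector V, int n_conv) {
  if (n_conv < 0) stop("n_conv must be >= 0");
  std::vector<int32_t> v(V.begin(), V.end());
  std::vector<int32_t> out = convolve_cpp(v, n_conv);
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_score_votes(IntegerVector Vconv, int phi0) {
  std::vector<int32_t> v(Vconv.begin(), Vconv.end());
  std::pair<int, int32_t> r = argmax_middle(v);
  bool none = r.first < 0;
  return List::create(_["phi"] = none ? NA_INTEGER : (phi0 + r.first),
                      _["score"] = (int)r.second,
                      _["no_evidence"] = none);
}

// [[Rcpp::export]]
RawVector cpp_serialize_task(List task) {
  VotingTaskCpp t = list_to_task(task);
  std::vector<uint8_t> buf;
  serialize_task(t, buf);
  return RawVector(buf.begin(), buf.end());
}

// [[Rcpp::export]]
double cpp_task_bytes(List task) {
  return (double)task_payload_bytes(list_to_task(task));
}

// cloud-side evaluation of a serialized task stream: deserialize, vote,
// convolve, score; never touches sequences or keys
// [[Rcpp::export]]
List cpp_score_serialized_stream(RawVector stream, int n_conv) {
  std::vector<double> ids, chunk; std::vector<int> phi, score;
  size_t used = 0, len = stream.size();
  const uint8_t* buf = (const uint8_t*)RAW(stream);
  while (used < len) {
    VotingTaskCpp t = deserialize_task(buf, len, used);
    VoteVec vv = cast_votes_cpp(t);
    std::vector<int32_t> vc = convolve_cpp(vv.V, n_conv);
    std::pair<int, int32_t> r = argmax_middle(vc);
    ids.push_back((double)t.task_id);
    chunk.push_back((double)t.chunk_off);
    phi.push_back(r.first < 0 ? NA_INTEGER : vv.phi0 + r.first);
    score.push_back(r.second);
  }
  return List::create(_["task_id"] = ids, _["chunk_off"] = chunk,
                      _["phi"] = phi, _["score"] = score);
}

// number of equal 64-bit values occurring in two different tasks (pairs)
// [[Rcpp::export]]
double cpp_count_cross_collisions(NumericVector hi, NumericVector lo,
                                  IntegerVector task) {
  size_t n = hi.size();
  std::vector<std::pair<uint64_t, int>> v(n);
  for (size_t i = 0; i < n; ++i)
    v[i] = {u64_from(hi[i], lo[i]), task[i]};
  std::sort(v.begin(), v.end());
  double collisions = 0;
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j + 1 < n && v[j + 1].first == v[i].first) ++j;
    size_t run = j - i + 1;
    if (run > 1) {
      double total = (double)run * (run - 1) / 2.0;
      // subtract same-task pairs
      std::unordered_map<int, int> per;
      for (size_t q = i; q <= j; ++q) ++per[v[q].second];
      for (auto& kv : per)
        total -= (double)kv.second * (kv.second - 1) / 2.0;
      collisions += total;
    }
    i = j + 1;
  }
  return collisions;
}
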