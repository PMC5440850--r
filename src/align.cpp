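// End-to-end alignment loop: per read, fingerprint + candidate selection
// ("client"), secure transform + serialization ("client"), vote casting on
// the serialized task bytes only ("cloud"), then final position and mapping
// quality on the client. Byte counts and per-phase wall times are recorded.
#include "mv_core.h"
#include <chrono>
#include <cmath>
using namespace Rcpp;

static inline double usec_since(std::chrono::steady_clock::time_point t0) {
  return std::chrono::duration<double, std::micro>(
             std::chrono::steady_clock::now() - t0)
      .count();
}

// [[Rcpp::export]]
List cpp_align_batch(SEXP idx_xp, std::vector<std::string> read_seqs,
                     std::vector<std::string> ref_seqs, List params,
                     bool secure, double master_seed_d, bool via_serialization) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  const MHGIndexCpp& idx = *xp;
  const int v = as<int>(params["v"]);
  const int beta = as<int>(params["beta"]);
  const double rho = as<double>(params["rho"]);
  const int n_conv = as<int>(params["n_conv"]);
  const int b_min_hits = as<int>(params["b_min_hits"]);
  const int alpha = as<int>(params["alpha"]);
  const int chunk_cap_mult = as<int>(params["chunk_cap_mult"]);
  const uint64_t master_seed = (uint64_t)master_seed_d;

  // reference layout must match the index
  {
    int64_t off = 0;
    if ((int)ref_seqs.size() != (int)idx.seq_lens.size())
      stop("reference does not match the index (sequence count differs)");
    for (size_t s = 0; s < ref_seqs.size(); ++s) {
      if ((int64_t)ref_seqs[s].size() != idx.seq_lens[s])
        stop("reference does not match the index (sequence lengths differ)");
      off += (int64_t)ref_seqs[s].size();
    }
    if (off != idx.genome_len) stop("reference does not match the index");
  }

  TaskKeysCpp session = make_task_keys(master_seed, 0);

  // precomputed per-position voting-kmer base hashes over the whole reference
  std::vector<uint64_t> ref_base(idx.genome_len, 0);
  std::vector<uint8_t> ref_ok(idx.genome_len, 0);
  {
    int64_t off = 0;
    for (const std::string& s : ref_seqs) {
      std::vector<uint64_t> codes; std::vector<bool> ok;
      kmer_codes_canonical(s, v, codes, ok);
      for (size_t p = 0; p < codes.size(); ++p) {
        if (!ok[p]) continue;
        ref_ok[off + p] = 1;
        ref_base[off + p] =
            secure ? keyed_base_hash(session.K, codes[p]) : splitmix64(codes[p]);
      }
      off += (int64_t)s.size();
    }
  }

  const int n = (int)read_seqs.size();
  LogicalVector mapped(n);
  NumericVector gpos(n);
  IntegerVector strand(n), mapq(n), r1v(n), r2v(n), ncand(n), ntask(n);
  double task_bytes = 0, result_bytes = 0;
  double t_fp = 0, t_sel = 0, t_enc = 0, t_vote = 0, t_fin = 0;
  uint64_t task_counter = 1; // 0 reserved for the session key stream

  struct TaskMeta { int64_t gstart; int st; };

  for (int i = 0; i < n; ++i) {
    const std::string& rseq = read_seqs[i];
    const int read_len = (int)rseq.size();
    mapped[i] = false; gpos[i] = NA_REAL; strand[i] = NA_INTEGER;
    mapq[i] = 0; r1v[i] = 0; r2v[i] = 0; ncand[i] = 0; ntask[i] = 0;
    if (read_len < idx.k_mh || read_len < v) continue;

    // --- client: fingerprint
    auto t0 = std::chrono::steady_clock::now();
    int min_kmers = (read_len == idx.W)
                        ? idx.min_kmers
                        : std::max(1, (int)std::ceil(0.8 * (read_len - idx.k_mh + 1)));
    std::vector<uint64_t> codes; std::vector<bool> okc;
    kmer_codes_canonical(rseq, idx.k_mh, codes, okc);
    std::vector<uint64_t> kept;
    for (size_t p = 0; p < codes.size(); ++p)
      if (okc[p] && !idx.filter.repetitive.count(codes[p])) kept.push_back(codes[p]);
    FingerprintCpp fp = fingerprint_codes(kept, idx.fam, min_kmers);
    t_fp += usec_since(t0);
    if (!fp.valid) continue;

    // --- client: candidate contig selection
    t0 = std::chrono::steady_clock::now();
    std::vector<CandidateCpp> cands =
        select_candidates_cpp(fp, idx, read_len, b_min_hits);
    t_sel += usec_since(t0);
    ncand[i] = (int)cands.size();
    if (cands.empty()) continue;

    // --- client: secure transform of every task, serialized
    t0 = std::chrono::steady_clock::now();
    std::vector<uint64_t> rcodes; std::vector<bool> rok;
    kmer_codes_canonical(rseq, v, rcodes, rok);
    std::vector<uint64_t> rbase(rcodes.size());
    for (size_t p = 0; p < rcodes.size(); ++p)
      rbase[p] = !rok[p] ? 0
                 : (secure ? keyed_base_hash(session.K, rcodes[p])
                           : splitmix64(rcodes[p]));
    // reverse-complement read: canonical codes in reverse order
    std::vector<uint64_t> rbase_rc(rbase.rbegin(), rbase.rend());
    std::vector<bool> rok_rc(rok.rbegin(), rok.rend());

    std::vector<uint8_t> stream;
    std::vector<TaskMeta> metas;
    std::vector<VotingTaskCpp> plain_tasks;
    for (const CandidateCpp& c : cands) {
      int64_t clen = c.gend - c.gstart;
      for (int st = 0; st < 2; ++st) {
        std::vector<VotingTaskCpp> ts = make_pair_tasks(
            st == 0 ? rbase : rbase_rc, st == 0 ? rok : rok_rc,
            ref_base.data() + c.gstart, ref_ok.data() + c.gstart, clen, v,
            beta, rho, secure, master_seed, task_counter, read_len,
            chunk_cap_mult);
        for (VotingTaskCpp& t : ts) {
          task_bytes += (double)task_payload_bytes(t);
          result_bytes += 24.0; // task id + best displacement + score
          metas.push_back(TaskMeta{c.gstart, st});
          if (via_serialization)
            serialize_task(t, stream);
          else
            plain_tasks.push_back(std::move(t));
        }
      }
    }
    ntask[i] = (int)metas.size();
    t_enc += usec_since(t0);

    // --- cloud: vote, convolve, score (sees only the serialized bytes)
    t0 = std::chrono::steady_clock::now();
    std::vector<int64_t> t_pos(metas.size());
    std::vector<int32_t> t_score(metas.size());
    std::vector<int> t_strand(metas.size());
    size_t used = 0;
    for (size_t ti = 0; ti < metas.size(); ++ti) {
      VotingTaskCpp t = via_serialization
                            ? deserialize_task(stream.data(), stream.size(), used)
                            : std::move(plain_tasks[ti]);
      VoteVec vv = cast_votes_cpp(t);
      std::vector<int32_t> vc = convolve_cpp(vv.V, n_conv);
      std::pair<int, int32_t> r = argmax_middle(vc);
      t_score[ti] = r.second;
      t_strand[ti] = metas[ti].st;
      t_pos[ti] = r.first < 0
                      ? -1
                      : metas[ti].gstart + t.chunk_off + (int64_t)(vv.phi0 + r.first);
    }
    t_vote += usec_since(t0);

    // --- client: best/second-best, final position, mapping quality
    t0 = std::chrono::steady_clock::now();
    int best = -1;
    for (size_t ti = 0; ti < metas.size(); ++ti)
      if (t_score[ti] > (best < 0 ? 0 : t_score[best])) best = (int)ti;
    if (best >= 0) {
      int32_t r1 = t_score[best];
      int64_t p1 = t_pos[best];
      int32_t r2 = 0;
      for (size_t ti = 0; ti < metas.size(); ++ti) {
        if ((int)ti == best || t_pos[ti] < 0) continue;
        int64_t d = t_pos[ti] - p1;
        if (d < 0) d = -d;
        if (d > read_len && t_score[ti] > r2) r2 = t_score[ti];
      }
      int64_t p = p1 < 0 ? 0 : p1;
      if (p >= idx.genome_len) p = idx.genome_len - 1;
      mapped[i] = true;
      gpos[i] = (double)p;
      strand[i] = t_strand[best];
      r1v[i] = r1; r2v[i] = r2;
      int q = (int)std::llround((double)alpha * (double)(r1 - r2) / (double)r1);
      if (q < 0) q = 0;
      if (q > alpha) q = alpha;
      mapq[i] = q;
    }
    t_fin += usec_since(t0);
  }

  NumericVector timings = NumericVector::create(
      _["fingerprinting"] = t_fp / 1e6, _["selection"] = t_sel / 1e6,
      _["encryption_masking"] = t_enc / 1e6, _["voting"] = t_vote / 1e6,
      _["reporting"] = t_fin / 1e6);
  return List::create(_["mapped"] = mapped, _["gpos"] = gpos,
                      _["strand"] = strand, _["mapq"] = mapq, _["r1"] = r1v,
                      _["r2"] = r2v, _["n_candidates"] = ncand,
                      _["n_tasks"] = ntask, _["task_bytes"] = task_bytes,
                      _["result_bytes"] = result_bytes, _["timings"] = timings);
}
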