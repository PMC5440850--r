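// Phase-1 candidate selection: n-way merge of the T bucket contig lists with
// a min-priority heap, interval merging within W bp, b_hits counting and the
// b_min_hits / b_best_hits filter.
#include "mv_core.h"
#include <queue>
#include <algorithm>
using namespace Rcpp;

namespace {
struct HeapItem {
  int64_t start;
  int b_id; // table id (one bucket per table is consulted)
  size_t pos;
  bool operator>(const HeapItem& o) const {
    if (start != o.start) return start > o.start;
    return b_id > o.b_id;
  }
};
} // namespace

std::vector<CandidateCpp> select_candidates_cpp(const FingerprintCpp& fp,
                                                const MHGIndexCpp& idx,
                                                int read_len, int b_min_hits) {
  std::vector<CandidateCpp> out;
  if (!fp.valid) return out;
  const int W = idx.W;
  const int ext = read_len > W ? read_len : W;

  // gather the T bucket lists (already sorted by start from construction)
  std::vector<const std::vector<ContigEntry>*> lists(idx.T, nullptr);
  for (int t = 0; t < idx.T; ++t) {
    uint32_t h = bucket_hash_cpp(fp.mins, idx.proj, t);
    auto it = idx.tables[t].find(h);
    if (it == idx.tables[t].end()) continue;
    if ((int)it->second.size() > idx.bucket_cap) continue; // high-frequency
    lists[t] = &it->second;
  }

  std::priority_queue<HeapItem, std::vector<HeapItem>, std::greater<HeapItem>> pq;
  for (int t = 0; t < idx.T; ++t)
    if (lists[t] && !lists[t]->empty())
      pq.push(HeapItem{(*lists[t])[0].start, t, 0});

  // streaming interval merge; a merged candidate accumulates distinct tables
  int64_t cur_s = -1, cur_e = -1;
  int cur_seq = -1;
  std::vector<uint8_t> seen(idx.T, 0);
  std::vector<int> seen_tables;
  auto flush = [&]() {
    if (cur_s < 0) return;
    CandidateCpp c;
    c.gstart = cur_s; c.gend = cur_e;
    c.b_hits = (int)seen_tables.size();
    // pad to at least read_len, staying inside the reference sequence
    int64_t soff = idx.seq_offsets[cur_seq];
    int64_t send = soff + idx.seq_lens[cur_seq];
    if (c.gend - c.gstart < read_len) c.gend = c.gstart + read_len;
    if (c.gend > send) c.gend = send;
    if (c.gend - c.gstart < read_len) c.gstart = std::max(soff, c.gend - read_len);
    out.push_back(c);
    for (int t : seen_tables) seen[t] = 0;
    seen_tables.clear();
    cur_s = -1; cur_e = -1; cur_seq = -1;
  };

  while (!pq.empty()) {
    HeapItem it = pq.top(); pq.pop();
    const std::vector<ContigEntry>& lst = *lists[it.b_id];
    const ContigEntry& e = lst[it.pos];
    if (it.pos + 1 < lst.size())
      pq.push(HeapItem{lst[it.pos + 1].start, it.b_id, it.pos + 1});

    int64_t s = e.start;
    int64_t en = e.start + e.len - 1 + ext; // union of the merged windows
    int sq = idx.seq_of(s);
    if (cur_s >= 0 && sq == cur_seq && s <= cur_e + W) {
      if (en > cur_e) cur_e = en;
    } else {
      flush();
      cur_s = s; cur_e = en; cur_seq = sq;
    }
    if (!seen[it.b_id]) { seen[it.b_id] = 1; seen_tables.push_back(it.b_id); }
  }
  flush();

  int b_best = 0;
  for (const CandidateCpp& c : out) b_best = std::max(b_best, c.b_hits);
  int thr = std::max(b_min_hits, (b_best + 1) / 2);
  std::vector<CandidateCpp> kept;
  for (const CandidateCpp& c : out)
    if (c.b_hits >= thr) kept.push_back(c);
  std::stable_sort(kept.begin(), kept.end(),
                   [](const CandidateCpp& a, const CandidateCpp& b) {
                     if (a.b_hits != b.b_hits) return a.b_hits > b.b_hits;
                     return a.gstart < b.gstart;
                   });
  return kept;
}

// [[Rcpp::export]]
List cpp_select_candidates(SEXP idx_xp, List fp, int read_len, int b_min_hits) {
  XPtr<MHGIndexCpp> xp(idx_xp);
  FingerprintCpp f = fp_from_list(fp);
  std::vector<CandidateCpp> cs =
      select_candidates_cpp(f, *xp, read_len, b_min_hits);
  NumericVector gs(cs.size()), ge(cs.size());
  IntegerVector bh(cs.size());
  for (size_t i = 0; i < cs.size(); ++i) {
    gs[i] = (double)cs[i].gstart; ge[i] = (double)cs[i].gend;
    bh[i] = cs[i].b_hits;
  }
  return List::create(_["gstart"] = gs, _["gend"] = ge, _["b_hits"] = bh);
}
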