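// Phase-2 kmer voting and the secure transform applied on the client before
// a task is shipped: keyed hashing with per-task rekeying, local-repeat
// masking (>= v masked kmers around each repeat), position binning with
// within-bin shuffling, contig kmer sampling, chunk splitting and padding.
#include "mv_core.h"
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// keys
// ---------------------------------------------------------------------------
TaskKeysCpp make_task_keys(uint64_t master_seed, uint64_t task_id) {
  TaskKeysCpp keys;
  MvRng krng(mv_stream_seed(master_seed, 0x5EC4E7ULL));
  for (int i = 0; i < 4; ++i) {
    uint64_t w = krng.next();
    for (int j = 0; j < 8; ++j) keys.K[8 * i + j] = (uint8_t)(w >> (8 * j));
  }
  MvRng trng(mv_stream_seed(master_seed, 0xBEEF00ULL + task_id));
  keys.k1 = trng.next();
  keys.k2 = trng.next() | 1ULL;
  return keys;
}

static inline uint64_t rekey(uint64_t base, const TaskKeysCpp& k) {
  return (base ^ k.k1) * k.k2;
}

// ---------------------------------------------------------------------------
// secure transform of one chunk
// ---------------------------------------------------------------------------

// mask every repeated base value together with its neighbourhood
// [p-(v-1), p+(v-1)], then extend maximal masked runs to length >= v
static void lrs_mask(const std::vector<uint64_t>& base,
                     const std::vector<bool>& ok, int v,
                     std::vector<bool>& mask) {
  int64_t n = (int64_t)base.size();
  mask.assign(n, false);
  for (int64_t p = 0; p < n; ++p) mask[p] = !ok[p];
  std::unordered_map<uint64_t, int> cnt;
  for (int64_t p = 0; p < n; ++p)
    if (ok[p]) ++cnt[base[p]];
  for (int64_t p = 0; p < n; ++p) {
    if (!ok[p] || cnt[base[p]] <= 1) continue;
    int64_t lo = std::max<int64_t>(0, p - (v - 1));
    int64_t hi = std::min<int64_t>(n - 1, p + (v - 1));
    for (int64_t q = lo; q <= hi; ++q) mask[q] = true;
  }
  // enforce minimum masked-run length v
  bool any = false;
  for (int64_t p = 0; p < n; ++p) any = any || mask[p];
  if (!any) return;
  if (n < v) {
    mask.assign(n, true);
    return;
  }
  int64_t p = 0;
  while (p < n) {
    if (!mask[p]) { ++p; continue; }
    int64_t q = p;
    while (q + 1 < n && mask[q + 1]) ++q;
    int64_t run = q - p + 1;
    if (run < v) {
      int64_t need = v - run;
      int64_t add_r = std::min(need, n - 1 - q);
      for (int64_t j = 1; j <= add_r; ++j) mask[q + j] = true;
      need -= add_r;
      for (int64_t j = 1; j <= need; ++j) mask[p - j] = true;
      q += add_r;
      // merged with a following run? keep scanning from q
    }
    p = q + 1;
  }
}

static inline int per_bin_sample(int n_bin, double rho) {
  int s = (int)std::floor((double)n_bin * rho);
  return s < 1 ? 1 : s;
}

// record count of a contig list with n_pos kmer positions after per-bin
// sampling at rate rho (used to size padding targets)
static int sampled_record_count(int n_pos, int beta, double rho) {
  int total = 0;
  for (int b0 = 0; b0 < n_pos; b0 += beta)
    total += per_bin_sample(std::min(beta, n_pos - b0), rho);
  return total;
}

VotingTaskCpp prepare_chunk(const std::vector<uint64_t>& read_base,
                            const std::vector<bool>& read_ok,
                            const std::vector<uint64_t>& contig_base,
                            const std::vector<bool>& contig_ok,
                            int v, int beta, double rho, bool secure,
                            const TaskKeysCpp& keys, uint64_t task_id,
                            int pad_to, int64_t chunk_off, MvRng& rng) {
  VotingTaskCpp t;
  t.task_id = task_id;
  t.beta = secure ? beta : 1;
  t.rho = rho;
  t.v = v;
  t.n_read_pos = (int)read_base.size();
  t.n_contig_pos = (int)contig_base.size();
  t.chunk_off = chunk_off;

  if (secure) {
    lrs_mask(read_base, read_ok, v, t.read_mask);
    lrs_mask(contig_base, contig_ok, v, t.contig_mask);
  } else {
    t.read_mask.assign(read_base.size(), false);
    t.contig_mask.assign(contig_base.size(), false);
  }

  // hashed values per position
  std::vector<uint64_t> rh(read_base.size()), ch(contig_base.size());
  for (size_t p = 0; p < read_base.size(); ++p) {
    bool usable = read_ok[p] && !t.read_mask[p];
    rh[p] = usable ? (secure ? rekey(read_base[p], keys) : read_base[p])
                   : rng.next();
  }
  for (size_t p = 0; p < contig_base.size(); ++p) {
    bool usable = contig_ok[p] && !t.contig_mask[p];
    ch[p] = usable ? (secure ? rekey(contig_base[p], keys) : contig_base[p])
                   : rng.next();
  }

  const int B = t.beta;
  // read list: all positions, shuffled within bins
  t.read_k.reserve(rh.size());
  for (size_t b0 = 0; b0 < rh.size(); b0 += B) {
    size_t b1 = std::min(rh.size(), b0 + B);
    std::vector<int> ord(b1 - b0);
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)(b0 + i);
    if (secure)
      for (size_t i = ord.size(); i > 1; --i)
        std::swap(ord[i - 1], ord[rng.next_below(i)]);
    for (int p : ord) {
      t.read_k.push_back(VKmer{rh[p], (int32_t)(p / B)});
      t.read_rec_masked.push_back(t.read_mask[p] || !read_ok[p]);
    }
  }

  // contig list: per-bin sampling; a bin ships s = max(1, floor(n_bin*rho))
  // records -- sampled unmasked kmers if it has at least s of them, otherwise
  // the whole bin is masked and s random values are shipped
  for (size_t b0 = 0; b0 < ch.size(); b0 += B) {
    size_t b1 = std::min(ch.size(), b0 + B);
    int n_bin = (int)(b1 - b0);
    int s = per_bin_sample(n_bin, rho);
    std::vector<int> unmasked;
    for (size_t p = b0; p < b1; ++p)
      if (!t.contig_mask[p] && contig_ok[p]) unmasked.push_back((int)p);
    if (!secure) {
      for (size_t p = b0; p < b1; ++p) {
        t.contig_k.push_back(VKmer{ch[p], (int32_t)(p / B)});
        t.contig_rec_masked.push_back(!contig_ok[p]);
      }
    } else if ((int)unmasked.size() >= s) {
      // sample s without replacement (partial Fisher-Yates => random order)
      for (int i = 0; i < s; ++i) {
        size_t j = i + rng.next_below(unmasked.size() - i);
        std::swap(unmasked[i], unmasked[j]);
        t.contig_k.push_back(VKmer{ch[unmasked[i]], (int32_t)(b0 / B)});
        t.contig_rec_masked.push_back(false);
      }
    } else {
      for (size_t p = b0; p < b1; ++p) t.contig_mask[p] = true;
      for (int i = 0; i < s; ++i) {
        t.contig_k.push_back(VKmer{rng.next(), (int32_t)(b0 / B)});
        t.contig_rec_masked.push_back(true);
      }
    }
  }

  // pad with random kmers in fresh bins up to the uniform chunk size
  if (pad_to > (int)t.contig_k.size()) {
    int s = per_bin_sample(B, rho);
    int32_t bin_next = (int32_t)((t.n_contig_pos + B - 1) / B);
    int emitted_in_bin = 0;
    while ((int)t.contig_k.size() < pad_to) {
      t.contig_k.push_back(VKmer{rng.next(), bin_next});
      t.contig_rec_masked.push_back(true);
      ++t.pad;
      if (++emitted_in_bin == s) { ++bin_next; emitted_in_bin = 0; }
    }
  }
  return t;
}

// ---------------------------------------------------------------------------
// vote casting, convolution, scoring
// ---------------------------------------------------------------------------
VoteVec cast_votes_cpp(const VotingTaskCpp& task) {
  VoteVec out;
  const int B = task.beta;
  int32_t max_bin = 0;
  for (const VKmer& k : task.contig_k) max_bin = std::max(max_bin, k.bin);
  int64_t ncp = (int64_t)(max_bin + 1) * B;
  if (ncp < task.n_contig_pos) ncp = task.n_contig_pos;
  out.phi0 = -(task.n_read_pos + B + 1);
  int64_t size = ncp + B + 1 - out.phi0;
  std::vector<int32_t> diff(size + 1, 0);

  std::unordered_map<uint64_t, std::vector<int32_t>> cmap;
  cmap.reserve(task.contig_k.size() * 2);
  for (const VKmer& k : task.contig_k) cmap[k.h].push_back(k.bin);

  for (const VKmer& r : task.read_k) {
    auto it = cmap.find(r.h);
    if (it == cmap.end()) continue;
    for (int32_t bc : it->second) {
      int64_t a, b;
      if (B == 1) {
        a = (int64_t)bc - r.bin;       // exact displacement
        b = a + 1;
      } else {
        int64_t lC = (int64_t)bc * B, hC = lC + B;
        int64_t lR = (int64_t)r.bin * B, hR = lR + B;
        a = lC - hR + 1;               // [l^C - h^R + 1, h^C - l^R)
        b = hC - lR;
      }
      ++diff[a - out.phi0];
      --diff[b - out.phi0];
    }
  }
  out.V.assign(size, 0);
  int32_t acc = 0;
  for (int64_t j = 0; j < size; ++j) {
    acc += diff[j];
    out.V[j] = acc;
  }
  return out;
}

std::vector<int32_t> convolve_cpp(const std::vector<int32_t>& V, int n_conv) {
  int64_t n = (int64_t)V.size();
  std::vector<int64_t> cum(n + 1, 0);
  for (int64_t i = 0; i < n; ++i) cum[i + 1] = cum[i] + V[i];
  std::vector<int32_t> out(n, 0);
  for (int64_t j = 0; j < n; ++j) {
    int64_t lo = std::max<int64_t>(0, j - n_conv);
    int64_t hi = std::min<int64_t>(n, j + n_conv + 1);
    out[j] = (int32_t)(cum[hi] - cum[lo]);
  }
  return out;
}

std::pair<int, int32_t> argmax_middle(const std::vector<int32_t>& Vconv) {
  if (Vconv.empty()) return {-1, 0};
  int32_t best = Vconv[0];
  for (int32_t x : Vconv) best = std::max(best, x);
  if (best <= 0) return {-1, 0};
  int first = -1, last = -1;
  for (int j = 0; j < (int)Vconv.size(); ++j) {
    if (Vconv[j] == best) {
      if (first < 0) first = j;
      last = j;
    }
  }
  return {(first + last) / 2, best};
}

// ---------------------------------------------------------------------------
// serialization: what the untrusted side receives. 40-byte header +
// 12 bytes per kmer record (hval u64, bin i32); no keys, no mask flags.
// ---------------------------------------------------------------------------
template <typename Tv> static void put(std::vector<uint8_t>& o, Tv x) {
  const uint8_t* p = reinterpret_cast<const uint8_t*>(&x);
  o.insert(o.end(), p, p + sizeof(Tv));
}
template <typename Tv> static Tv get(const uint8_t* buf, size_t& at) {
  Tv x;
  std::memcpy(&x, buf + at, sizeof(Tv));
  at += sizeof(Tv);
  return x;
}

size_t task_payload_bytes(const VotingTaskCpp& t) {
  return 40 + 12 * (t.read_k.size() + t.contig_k.size());
}

void serialize_task(const VotingTaskCpp& t, std::vector<uint8_t>& out) {
  out.reserve(out.size() + task_payload_bytes(t));
  put<uint64_t>(out, t.task_id);
  put<int32_t>(out, t.beta);
  put<double>(out, t.rho);
  put<uint32_t>(out, (uint32_t)t.read_k.size());
  put<uint32_t>(out, (uint32_t)t.contig_k.size());
  put<int32_t>(out, t.pad);
  put<int64_t>(out, t.chunk_off);
  for (const VKmer& k : t.read_k) { put<uint64_t>(out, k.h); put<int32_t>(out, k.bin); }
  for (const VKmer& k : t.contig_k) { put<uint64_t>(out, k.h); put<int32_t>(out, k.bin); }
}

VotingTaskCpp deserialize_task(const uint8_t* buf, size_t len, size_t& used) {
  if (len - used < 40) stop("truncated voting-task stream");
  VotingTaskCpp t;
  t.task_id = get<uint64_t>(buf, used);
  t.beta = get<int32_t>(buf, used);
  t.rho = get<double>(buf, used);
  uint32_t nr = get<uint32_t>(buf, used);
  uint32_t nc = get<uint32_t>(buf, used);
  t.pad = get<int32_t>(buf, used);
  t.chunk_off = get<int64_t>(buf, used);
  if (len - used < 12ULL * (nr + nc)) stop("truncated voting-task stream");
  t.read_k.resize(nr);
  for (uint32_t i = 0; i < nr; ++i) {
    t.read_k[i].h = get<uint64_t>(buf, used);
    t.read_k[i].bin = get<int32_t>(buf, used);
  }
  t.contig_k.resize(nc);
  for (uint32_t i = 0; i < nc; ++i) {
    t.contig_k[i].h = get<uint64_t>(buf, used);
    t.contig_k[i].bin = get<int32_t>(buf, used);
  }
  // the receiver only knows bins; reconstruct position counts from them
  t.n_read_pos = (int)nr;
  int32_t mb = 0;
  for (const VKmer& k : t.contig_k) mb = std::max(mb, k.bin);
  t.n_contig_pos = (int)((mb + 1) * t.beta);
  return t;
}

// ---------------------------------------------------------------------------
// read/contig pair -> one or more tasks (chunk splitting + padding)
// ---------------------------------------------------------------------------
std::vector<VotingTaskCpp> make_pair_tasks(
    const std::vector<uint64_t>& read_base, const std::vector<bool>& read_ok,
    const uint64_t* contig_base, const uint8_t* contig_ok, int64_t contig_len_bp,
    int v, int beta, double rho, bool secure, uint64_t master_seed,
    uint64_t& task_counter, int read_len_bp, int chunk_cap_mult) {
  std::vector<VotingTaskCpp> out;
  int64_t cap = (int64_t)chunk_cap_mult * read_len_bp;
  if (cap < read_len_bp + v) cap = read_len_bp + v;
  std::vector<std::pair<int64_t, int64_t>> chunks; // [off, end) in bp
  if (contig_len_bp <= cap) {
    chunks.emplace_back(0, contig_len_bp);
  } else {
    int64_t off = 0;
    while (true) {
      int64_t end = std::min(off + cap, contig_len_bp);
      if (end - off >= read_len_bp) chunks.emplace_back(off, end);
      if (end == contig_len_bp) break;
      off += cap - read_len_bp; // overlap so no read-length window is cut
    }
  }
  int eff_beta = secure ? beta : 1;
  int pad_to = 0;
  if (chunks.size() > 1) {
    int n_pos_full = (int)(cap - v + 1);
    pad_to = secure ? sampled_record_count(n_pos_full, eff_beta, rho)
                    : n_pos_full;
  }
  for (auto& ck : chunks) {
    int64_t n_pos = ck.second - ck.first - v + 1;
    if (n_pos < 1) continue;
    std::vector<uint64_t> cb(contig_base + ck.first, contig_base + ck.first + n_pos);
    std::vector<bool> co(n_pos);
    for (int64_t i = 0; i < n_pos; ++i) co[i] = contig_ok[ck.first + i] != 0;
    uint64_t id = task_counter++;
    TaskKeysCpp keys = make_task_keys(master_seed, id);
    MvRng rng(mv_stream_seed(master_seed, 0x7A5C000000ULL + id));
    out.push_back(prepare_chunk(read_base, read_ok, cb, co, v, eff_beta, rho,
                                secure, keys, id, pad_to, ck.first, rng));
  }
  return out;
}
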