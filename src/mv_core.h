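#ifndef MINIVOTE_CORE_H
#define MINIVOTE_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <deque>
#include <unordered_map>
#include <unordered_set>
#include <functional>

// ---------------------------------------------------------------------------
// 64-bit utilities. R has no native unsigned 64-bit type, so hash values
// cross the R boundary as (hi, lo) pairs of doubles < 2^32, and kmer codes
// (<= 2^52 for k <= 26) as exact-integer doubles.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// deterministic stream RNG (splitmix64 counter mode)
struct MvRng {
  uint64_t state;
  explicit MvRng(uint64_t seed) : state(seed) {}
  uint64_t next() { return splitmix64(state += 0x9E3779B97F4A7C15ULL); }
  // uniform integer in [0, n)
  uint64_t next_below(uint64_t n) { return n ? next() % n : 0; }
  double next_unit() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline uint64_t mv_stream_seed(uint64_t master, uint64_t stream) {
  return splitmix64(master ^ splitmix64(stream + 0x1234567887654321ULL));
}

static inline double u64_hi(uint64_t x) { return (double)(x >> 32); }
static inline double u64_lo(uint64_t x) { return (double)(x & 0xFFFFFFFFULL); }
static inline uint64_t u64_from(double hi, double lo) {
  return ((uint64_t)hi << 32) | (uint64_t)lo;
}

// ---------------------------------------------------------------------------
// DNA 2-bit packing; code 255 = invalid (N / other)
// ---------------------------------------------------------------------------
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// canonical kmer codes of every position of seq; code = UINT64_MAX where the
// kmer overlaps a non-ACGT base. k <= 31.
void kmer_codes_canonical(const std::string& seq, int k,
                          std::vector<uint64_t>& out,
                          std::vector<bool>& valid);

uint64_t revcomp_code(uint64_t code, int k);

// ---------------------------------------------------------------------------
// SHA-1 (needed for the keyed kmer hash; see sha1.cpp)
// ---------------------------------------------------------------------------
void sha1_digest(const uint8_t* data, size_t len, uint8_t out[20]);

// first 64 bits (big-endian) of SHA-1(K || code_bytes_be)
uint64_t keyed_base_hash(const uint8_t K[32], uint64_t code);

// ---------------------------------------------------------------------------
// MinHash hash family: h_i(x) = a_i * x + b_i (mod 2^64), a_i odd,
// applied to base-mixed kmer codes H(s) = splitmix64(s).
// ---------------------------------------------------------------------------
struct HashFamily {
  std::vector<uint64_t> a, b;
  uint64_t seed;
  int L() const { return (int)a.size(); }
};

HashFamily make_family(int L, uint64_t seed);

struct KmerFilterCpp {
  std::unordered_set<uint64_t> repetitive; // canonical codes with count > cmax
  int k;
  int cmax;
};

struct FingerprintCpp {
  std::vector<uint64_t> mins;
  bool valid;
  int n_kmers; // surviving (position-wise) kmer count
};

// direct fingerprint over a vector of (already filtered) canonical codes
FingerprintCpp fingerprint_codes(const std::vector<uint64_t>& codes,
                                 const HashFamily& fam, int min_kmers);

FingerprintCpp fp_from_list(Rcpp::List fp);

// ---------------------------------------------------------------------------
// MHG index
// ---------------------------------------------------------------------------
struct ContigEntry {
  int64_t start; // global window start
  int32_t len;   // number of consecutive merged windows
};

struct ProjectionSetCpp {
  std::vector<std::vector<int>> P; // T x b index vectors into [0, L)
  std::vector<uint64_t> A;         // b odd 64-bit multipliers
  int M;                           // bucket-address bits
};

ProjectionSetCpp make_projections(int T, int b, int L, int M, uint64_t seed);

static inline uint32_t bucket_hash_cpp(const std::vector<uint64_t>& mins,
                                       const ProjectionSetCpp& ps, int t) {
  uint64_t acc = 0;
  const std::vector<int>& p = ps.P[t];
  for (size_t i = 0; i < p.size(); ++i) acc += ps.A[i] * mins[p[i]];
  return (uint32_t)(acc >> (64 - ps.M));
}

struct MHGIndexCpp {
  // parameters frozen at build time
  int W, k_mh, L, T, b, M;
  int min_kmers, bucket_cap, cmax;
  uint64_t seed;
  HashFamily fam;
  ProjectionSetCpp proj;
  KmerFilterCpp filter;
  // one hash table per projection; bucket id -> sorted contig runs
  std::vector<std::unordered_map<uint32_t, std::vector<ContigEntry>>> tables;
  // reference layout (global, concatenated coordinates)
  std::vector<std::string> seq_names;
  std::vector<int64_t> seq_offsets;
  std::vector<int64_t> seq_lens;
  int64_t genome_len = 0;
  int64_t n_valid_windows = 0;

  // which reference sequence contains global position g
  int seq_of(int64_t g) const {
    int lo = 0, hi = (int)seq_offsets.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (seq_offsets[mid] <= g) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

// rolling fingerprint callback: called once per window start with the
// fingerprint (mins only meaningful when valid)
void rolling_scan(const std::string& seq, int W, int k, const HashFamily& fam,
                  const KmerFilterCpp* filter, int min_kmers,
                  const std::function<void(int64_t, const FingerprintCpp&)>& fn);

// candidate selection core
struct CandidateCpp {
  int64_t gstart, gend; // half-open global interval
  int b_hits;
};

std::vector<CandidateCpp> select_candidates_cpp(const FingerprintCpp& fp,
                                                const MHGIndexCpp& idx,
                                                int read_len, int b_min_hits);

// ---------------------------------------------------------------------------
// Voting
// ---------------------------------------------------------------------------
struct TaskKeysCpp {
  uint8_t K[32];
  uint64_t k1, k2; // k2 odd
};

struct VKmer {
  uint64_t h;
  int32_t bin; // bin index (beta positions per bin); with beta==1, exact pos
};

struct VotingTaskCpp {
  uint64_t task_id = 0;
  int beta = 1;
  double rho = 1.0;
  int v = 20;
  int n_read_pos = 0;    // read kmer positions (pre-binning)
  int n_contig_pos = 0;  // contig kmer positions (pre-sampling)
  int pad = 0;           // random padding kmers appended to contig list
  int64_t chunk_off = 0; // offset of this chunk within the candidate contig
  std::vector<VKmer> read_k, contig_k; // shipped payload
  // client-side bookkeeping (never serialized)
  std::vector<bool> read_mask, contig_mask; // per-position mask, pre-sampling
  std::vector<bool> read_rec_masked, contig_rec_masked; // per shipped record
};

struct VoteVec {
  int phi0 = 0;             // displacement of V[0]
  std::vector<int32_t> V;   // raw votes
};

// secure transform of one read/contig pair (single chunk)
VotingTaskCpp prepare_chunk(const std::vector<uint64_t>& read_codes,
                            const std::vector<bool>& read_ok,
                            const std::vector<uint64_t>& contig_codes,
                            const std::vector<bool>& contig_ok,
                            int v, int beta, double rho, bool secure,
                            const TaskKeysCpp& keys, uint64_t task_id,
                            int pad_to, int64_t chunk_off, MvRng& rng);

VoteVec cast_votes_cpp(const VotingTaskCpp& task);
std::vector<int32_t> convolve_cpp(const std::vector<int32_t>& V, int n_conv);
// returns (index into Vconv of the plateau middle, max value)
std::pair<int, int32_t> argmax_middle(const std::vector<int32_t>& Vconv);

size_t task_payload_bytes(const VotingTaskCpp& t);
void serialize_task(const VotingTaskCpp& t, std::vector<uint8_t>& out);
VotingTaskCpp deserialize_task(const uint8_t* buf, size_t len, size_t& used);

TaskKeysCpp make_task_keys(uint64_t master_seed, uint64_t task_id);

// all voting tasks for one read/contig pair, splitting long contigs into
// overlapping chunks (length chunk_cap_mult*read_len, stride read_len) padded
// to a uniform record count
std::vector<VotingTaskCpp> make_pair_tasks(
    const std::vector<uint64_t>& read_base, const std::vector<bool>& read_ok,
    const uint64_t* contig_base, const uint8_t* contig_ok, int64_t contig_len_bp,
    int v, int beta, double rho, bool secure, uint64_t master_seed,
    uint64_t& task_counter, int read_len_bp, int chunk_cap_mult);

Rcpp::List task_to_list(const VotingTaskCpp& t);
VotingTaskCpp list_to_task(Rcpp::List l);

#endif
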