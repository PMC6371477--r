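// Bit-level kernels: packed bit codes, Hamming distances, CRC-32 for the
// database container, and multi-index hashing (MIH) for exact k-NN in
// Hamming space.
//
// Bit codes are stored column-major as raw matrices with ceil(T/8) byte rows
// per cell.  Bit i of a code (hyperplane i, 0-based) lives in byte i >> 3 at
// position i & 7 (little-endian within bytes).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>
#include <queue>

using namespace Rcpp;

static inline int popcount8(uint8_t x) { return __builtin_popcount((unsigned)x); }

static inline int hamming_bytes(const uint8_t* a, const uint8_t* b, int nbytes) {
  int d = 0;
  int i = 0;
  for (; i + 8 <= nbytes; i += 8) {
    uint64_t wa, wb;
    std::memcpy(&wa, a + i, 8);
    std::memcpy(&wb, b + i, 8);
    d += __builtin_popcountll(wa ^ wb);
  }
  for (; i < nbytes; ++i) d += popcount8(a[i] ^ b[i]);
  return d;
}

// [[Rcpp::export]]
RawMatrix pack_bits_cpp(LogicalMatrix bits) {
  const int T = bits.nrow(), N = bits.ncol();
  const int nbytes = (T + 7) / 8;
  RawMatrix out(nbytes, N);
  for (int j = 0; j < N; ++j) {
    Rbyte* col = &out(0, j);
    for (int i = 0; i < T; ++i) {
      if (bits(i, j)) col[i >> 3] |= (Rbyte)(1u << (i & 7));
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix unpack_bits_cpp(RawMatrix codes, int T) {
  const int N = codes.ncol();
  LogicalMatrix out(T, N);
  for (int j = 0; j < N; ++j) {
    const Rbyte* col = &codes(0, j);
    for (int i = 0; i < T; ++i)
      out(i, j) = (col[i >> 3] >> (i & 7)) & 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector hamming_all_cpp(RawMatrix codes, RawVector query) {
  const int nbytes = codes.nrow(), N = codes.ncol();
  if ((int)query.size() != nbytes) stop("query byte length does not match codes");
  IntegerVector out(N);
  const uint8_t* q = (const uint8_t*)RAW(query);
  for (int j = 0; j < N; ++j)
    out[j] = hamming_bytes((const uint8_t*)&codes(0, j), q, nbytes);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(RawMatrix codes, RawMatrix queries) {
  const int nbytes = codes.nrow(), N = codes.ncol(), Q = queries.ncol();
  if (queries.nrow() != nbytes) stop("byte length mismatch between code sets");
  IntegerMatrix out(N, Q);
  for (int q = 0; q < Q; ++q) {
    const uint8_t* qp = (const uint8_t*)&queries(0, q);
    for (int j = 0; j < N; ++j)
      out(j, q) = hamming_bytes((const uint8_t*)&codes(0, j), qp, nbytes);
  }
  return out;
}

// Sum of Hamming distances between one query code and a subset of database
// codes, used when re-scoring candidate unions across multiple hash indexes.
// [[Rcpp::export]]
IntegerVector hamming_subset_cpp(RawMatrix codes, RawVector query, IntegerVector idx0) {
  const int nbytes = codes.nrow();
  IntegerVector out(idx0.size());
  const uint8_t* q = (const uint8_t*)RAW(query);
  for (int t = 0; t < (int)idx0.size(); ++t)
    out[t] = hamming_bytes((const uint8_t*)&codes(0, idx0[t]), q, nbytes);
  return out;
}

// ---- CRC-32 (IEEE 802.3 polynomial), for section checksums ----

static uint32_t crc_table[256];
static bool crc_ready = false;

static void crc_init() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int kk = 0; kk < 8; ++kk)
      c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
    crc_table[i] = c;
  }
  crc_ready = true;
}

// [[Rcpp::export]]
double crc32_cpp(RawVector data) {
  if (!crc_ready) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  const uint8_t* p = (const uint8_t*)RAW(data);
  const R_xlen_t n = data.size();
  for (R_xlen_t i = 0; i < n; ++i)
    c = crc_table[(c ^ p[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// ---- Multi-index hashing ----

static inline uint32_t extract_subcode(const uint8_t* code, int lo, int nbits) {
  uint32_t v = 0;
  for (int t = 0; t < nbits; ++t) {
    int bit = lo + t;
    v |= (uint32_t)((code[bit >> 3] >> (bit & 7)) & 1) << t;
  }
  return v;
}

// Build one subindex per block of s bits (last block may be shorter).  Each
// subindex is the filled/offsets/buckets triple: `filled` marks occupied
// subcode values, `offsets` delimits bucket extents in rank order, and
// `buckets` lists 0-based database positions in ascending order.
// [[Rcpp::export]]
List mih_build_cpp(RawMatrix codes, int T, int s) {
  const int N = codes.ncol();
  if (s < 1 || s > std::min(T, 24)) stop("subcode length s out of range");
  const int m = (T + s - 1) / s;
  List blocks(m);
  std::vector<uint32_t> sub(N);
  for (int b = 0; b < m; ++b) {
    const int lo = b * s;
    const int nb = std::min(s, T - lo);
    const uint32_t nvals = 1u << nb;
    for (int j = 0; j < N; ++j)
      sub[j] = extract_subcode((const uint8_t*)&codes(0, j), lo, nb);
    std::vector<int> cnt(nvals, 0);
    for (int j = 0; j < N; ++j) cnt[sub[j]]++;
    // filled bit vector + offsets over occupied values in increasing order
    RawVector filled((nvals + 7) / 8);
    int nfilled = 0;
    for (uint32_t v = 0; v < nvals; ++v) {
      if (cnt[v] > 0) {
        filled[v >> 3] |= (Rbyte)(1u << (v & 7));
        ++nfilled;
      }
    }
    IntegerVector offsets(nfilled + 1);
    std::vector<int> slot(nvals, -1);  // rank of each occupied value
    {
      int r = 0, acc = 0;
      for (uint32_t v = 0; v < nvals; ++v) {
        if (cnt[v] > 0) {
          slot[v] = r;
          offsets[r] = acc;
          acc += cnt[v];
          ++r;
        }
      }
      offsets[nfilled] = acc;
    }
    IntegerVector buckets(N);
    std::vector<int> cursor(nfilled, 0);
    for (int j = 0; j < N; ++j) {  // ascending j => ascending positions per bucket
      int r = slot[sub[j]];
      buckets[offsets[r] + cursor[r]] = j;
      cursor[r]++;
    }
    blocks[b] = List::create(_["bit_lo"] = lo, _["nbits"] = nb,
                             _["filled"] = filled, _["offsets"] = offsets,
                             _["buckets"] = buckets);
  }
  return blocks;
}

struct SubIndexView {
  int lo, nbits;
  const uint8_t* filled;
  const int* offsets;
  const int* buckets;
  std::vector<int> rank_byte;  // filled-count before each byte
};

static inline bool subindex_lookup(const SubIndexView& si, uint32_t v,
                                   int& from, int& to) {
  uint8_t byte = si.filled[v >> 3];
  if (!((byte >> (v & 7)) & 1)) return false;
  int idx = si.rank_byte[v >> 3] + popcount8((uint8_t)(byte & ((1u << (v & 7)) - 1)));
  from = si.offsets[idx];
  to = si.offsets[idx + 1];
  return true;
}

// Exact k-NN by progressive radius expansion with the generalized pigeonhole
// bound: any vector unseen after probing radius r in every block has full
// distance >= m*(r+1), so the search stops once the current k-th best beats
// that bound.  Ties at equal distance are resolved by ascending position.
// [[Rcpp::export]]
List mih_knn_cpp(RawMatrix codes, int T, List blocks, RawMatrix queries, int k) {
  const int N = codes.ncol(), Q = queries.ncol();
  if (k < 1) stop("k must be >= 1");
  if (N == 0) stop("empty index");
  const int m = blocks.size();
  const int kout = std::min(k, N);

  std::vector<SubIndexView> sub(m);
  std::vector<IntegerVector> keep_off(m);
  std::vector<IntegerVector> keep_buck(m);
  std::vector<RawVector> keep_fill(m);
  int max_nbits = 0;
  for (int b = 0; b < m; ++b) {
    List blk = blocks[b];
    keep_fill[b] = as<RawVector>(blk["filled"]);
    keep_off[b] = as<IntegerVector>(blk["offsets"]);
    keep_buck[b] = as<IntegerVector>(blk["buckets"]);
    sub[b].lo = as<int>(blk["bit_lo"]);
    sub[b].nbits = as<int>(blk["nbits"]);
    sub[b].filled = (const uint8_t*)RAW(keep_fill[b]);
    sub[b].offsets = INTEGER(keep_off[b]);
    sub[b].buckets = INTEGER(keep_buck[b]);
    max_nbits = std::max(max_nbits, sub[b].nbits);
    // byte-level rank cache over the filled bit vector
    const int nbytes_f = keep_fill[b].size();
    sub[b].rank_byte.resize(nbytes_f);
    int acc = 0;
    for (int i = 0; i < nbytes_f; ++i) {
      sub[b].rank_byte[i] = acc;
      acc += popcount8(sub[b].filled[i]);
    }
  }

  IntegerMatrix out_pos(kout, Q), out_dist(kout, Q);
  std::vector<uint8_t> visited(N);
  typedef std::pair<int, int> DP;  // (distance, position)
  std::vector<uint32_t> qsub(m);
  std::vector<int> comb;

  for (int q = 0; q < Q; ++q) {
    const uint8_t* qp = (const uint8_t*)&queries(0, q);
    std::fill(visited.begin(), visited.end(), 0);
    std::priority_queue<DP> heap;  // max-heap of the k current best
    int nvisited = 0;
    for (int b = 0; b < m; ++b)
      qsub[b] = extract_subcode(qp, sub[b].lo, sub[b].nbits);

    const int nbytes = codes.nrow();
    for (int r = 0; r <= max_nbits; ++r) {
      bool any_block = false;
      for (int b = 0; b < m && nvisited < N; ++b) {
        const int nb = sub[b].nbits;
        if (r > nb) continue;
        any_block = true;
        // enumerate all masks with r of nb bits set
        comb.assign(r, 0);
        for (int t = 0; t < r; ++t) comb[t] = t;
        bool more = true;
        while (more) {
          uint32_t mask = 0;
          for (int t = 0; t < r; ++t) mask |= (1u << comb[t]);
          int from, to;
          if (subindex_lookup(sub[b], qsub[b] ^ mask, from, to)) {
            for (int t = from; t < to; ++t) {
              const int pos = sub[b].buckets[t];
              if (!visited[pos]) {
                visited[pos] = 1;
                ++nvisited;
                const int d = hamming_bytes((const uint8_t*)&codes(0, pos), qp, nbytes);
                DP cand(d, pos);
                if ((int)heap.size() < kout) heap.push(cand);
                else if (cand < heap.top()) { heap.pop(); heap.push(cand); }
              }
            }
          }
          if (r == 0) break;
          // next combination
          int t = r - 1;
          while (t >= 0 && comb[t] == nb - r + t) --t;
          if (t < 0) more = false;
          else {
            ++comb[t];
            for (int u = t + 1; u < r; ++u) comb[u] = comb[u - 1] + 1;
          }
        }
      }
      if (nvisited >= N) break;
      if ((int)heap.size() == kout && heap.top().first < m * (r + 1)) break;
      if (!any_block) break;
    }

    // drain heap: largest first
    int filled_k = heap.size();
    for (int t = filled_k - 1; t >= 0; --t) {
      out_dist(t, q) = heap.top().first;
      out_pos(t, q) = heap.top().second + 1;  // 1-based for R
      heap.pop();
    }
  }
  return List::create(_["positions"] = out_pos, _["distances"] = out_dist);
}
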