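// Smith-Waterman local alignment core used by read recruitment.
//
// Scoring convention (nucleotide defaults +1/-1, gap open -2, gap extend -1):
// a gap of length L costs gap_open + (L-1) * gap_extend, i.e. gap_open is the
// score of the first gapped column.  N never counts as a match and scores as
// a mismatch against every base including N.
//
// Three engines compute identical scores: a scalar DP with full traceback,
// a striped SSE2 score-only kernel (Farrar-style) used for the
// all-references scan inside recruit(), and an AVX2 variant of the same
// kernel selected at run time when the CPU supports it (the binary stays
// runnable on any x86-64).  The score-only kernels also report the smallest
// reference column at which the maximum score is attained, which matches
// the scalar DP's smallest-reference-end tie-break and lets the traceback
// run on a short reference window instead of the whole reference.
// Tie-breaking is fully deterministic and documented in the R-level
// wrappers.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cstring>
#include <unordered_map>
#include <algorithm>

#ifdef __SSE2__
#include <emmintrin.h>
#if (defined(__GNUC__) || defined(__clang__)) && !defined(SW_NO_AVX2)
#define SW_AVX2_DISPATCH 1
#include <immintrin.h>
#endif
#endif

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N or anything else
  }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

static inline int sub_score(uint8_t a, uint8_t b, int ma, int mi) {
  // code 4 (N/ambiguous) never matches
  return (a == b && a < 4) ? ma : mi;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// Scalar affine-gap Smith-Waterman with traceback.
//
// H[i][j]: best local alignment score ending at read i / ref j.
// E: alignment ends in a gap column consuming a reference base (gap in read).
// F: alignment ends in a gap column consuming a read base (gap in reference).
//
// Best cell: maximum H; ties resolved to the smallest reference end, then the
// smallest read end.  Traceback preference at equal score: diagonal, then E,
// then F; within E/F, closing the gap (coming from H) is preferred over
// extending it.  These rules make the reported coordinates deterministic.
// ---------------------------------------------------------------------------

struct SWResult {
  int score;
  int matches;
  int columns;
  int read_start, read_end; // 0-based half-open
  int ref_start, ref_end;   // 0-based half-open
  bool found;
};

static SWResult sw_align_scalar(const std::vector<uint8_t>& q,
                                const std::vector<uint8_t>& r,
                                int ma, int mi, int go, int ge) {
  const int m = (int) q.size(), n = (int) r.size();
  SWResult out; out.score = 0; out.found = false;
  out.matches = out.columns = 0;
  out.read_start = out.read_end = out.ref_start = out.ref_end = 0;
  if (m == 0 || n == 0) return out;

  const int NEG = -1000000000;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  auto idx = [n](int i, int j) { return (size_t) i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[idx(i, j - 1)] + go, E[idx(i, j - 1)] + ge);
      int f = std::max(H[idx(i - 1, j)] + go, F[idx(i - 1, j)] + ge);
      int d = H[idx(i - 1, j - 1)] + sub_score(q[i - 1], r[j - 1], ma, mi);
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  if (best <= 0) return out;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int matches = 0, columns = 0;
  int ri_end = bi, rj_end = bj;
  while (true) {
    if (state == 0) {
      int h = H[idx(i, j)];
      if (h == 0) break;
      int d = H[idx(i - 1, j - 1)] + sub_score(q[i - 1], r[j - 1], ma, mi);
      if (i > 0 && j > 0 && h == d) {
        ++columns;
        if (q[i - 1] == r[j - 1] && q[i - 1] < 4) ++matches;
        --i; --j;
      } else if (h == E[idx(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // gap column consuming r[j-1]
      ++columns;
      int e = E[idx(i, j)];
      if (e == H[idx(i, j - 1)] + go) { state = 0; }
      --j;
      if (state == 1 && e != E[idx(i, j)] + ge) state = 0; // safety, should not trigger
    } else {
      ++columns;
      int f = F[idx(i, j)];
      if (f == H[idx(i - 1, j)] + go) { state = 0; }
      --i;
      if (state == 2 && f != F[idx(i, j)] + ge) state = 0; // safety
    }
  }
  out.score = best;
  out.found = true;
  out.matches = matches;
  out.columns = columns;
  out.read_start = i; out.read_end = ri_end;
  out.ref_start = j; out.ref_end = rj_end;
  return out;
}

// ---------------------------------------------------------------------------
// Score-only kernels
// ---------------------------------------------------------------------------

static int sw_score_scalar(const std::vector<uint8_t>& q,
                           const std::vector<uint8_t>& r,
                           int ma, int mi, int go, int ge) {
  const int m = (int) q.size(), n = (int) r.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> H(m + 1, 0), Ecol(m + 1, 0);
  int best = 0;
  for (int j = 1; j <= n; ++j) {
    int diag = 0; // H[i-1][j-1]
    int f = 0;    // F for current column (floored at 0; see note below)
    uint8_t rc = r[j - 1];
    for (int i = 1; i <= m; ++i) {
      int e = std::max(H[i] + go, Ecol[i] + ge); // gap in read dim: wait, see note
      if (e < 0) e = 0;
      int h = diag + sub_score(q[i - 1], rc, ma, mi);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[i];
      H[i] = h;
      Ecol[i] = e;
      int fo = h + go, fe = f + ge;
      f = fo > fe ? fo : fe;
      if (f < 0) f = 0;
      if (h > best) best = h;
    }
  }
  return best;
}

#ifdef __SSE2__
// Farrar striped SW, 16-bit lanes, score only.  E/F/H are floored at zero,
// which is equivalent for local alignment scores (a free restart is always
// available).  Query profile is built once per (read, strand) and reused
// across all references.
struct StripedProfile {
  int m;          // query length
  int seglen;     // ceil(m / 8)
  std::vector<__m128i> prof; // 5 * seglen vectors
};

static void build_profile(const std::vector<uint8_t>& q, int ma, int mi,
                          StripedProfile& P) {
  P.m = (int) q.size();
  P.seglen = (P.m + 7) / 8;
  P.prof.assign(5 * (size_t) P.seglen, _mm_setzero_si128());
  int16_t tmp[8];
  for (int a = 0; a < 5; ++a) {
    for (int k = 0; k < P.seglen; ++k) {
      for (int l = 0; l < 8; ++l) {
        int i = l * P.seglen + k;
        tmp[l] = (i < P.m) ? (int16_t) sub_score(q[i], (uint8_t) a, ma, mi)
                           : (int16_t) -30000;
      }
      P.prof[(size_t) a * P.seglen + k] =
        _mm_loadu_si128((const __m128i*) tmp);
    }
  }
}

// 8-bit unsigned variant (16 lanes).  H is stored unbiased (profile adds
// score + 1 then subtracts 1 with unsigned saturation, which floors H at 0).
// Returns 255 on saturation; callers must then fall back to the 16-bit
// kernel.  Only valid while the true score fits in 8 bits, which holds for
// any query shorter than 255 / match_score.
struct StripedProfile8 {
  int m;
  int seglen; // ceil(m / 16)
  int bias;   // -min substitution score, so profile entries are nonnegative
  std::vector<__m128i> prof;
};

static inline int profile8_bias(int ma, int mi) {
  int lo = ma < mi ? ma : mi;
  return lo < 0 ? -lo : 1;
}

static void build_profile8(const std::vector<uint8_t>& q, int ma, int mi,
                           StripedProfile8& P) {
  P.m = (int) q.size();
  P.seglen = (P.m + 15) / 16;
  P.bias = profile8_bias(ma, mi);
  P.prof.assign(5 * (size_t) P.seglen, _mm_setzero_si128());
  uint8_t tmp[16];
  for (int a = 0; a < 5; ++a) {
    for (int k = 0; k < P.seglen; ++k) {
      for (int l = 0; l < 16; ++l) {
        int i = l * P.seglen + k;
        int v = (i < P.m) ? sub_score(q[i], (uint8_t) a, ma, mi) + P.bias : 0;
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        tmp[l] = (uint8_t) v;
      }
      P.prof[(size_t) a * P.seglen + k] =
        _mm_loadu_si128((const __m128i*) tmp);
    }
  }
}

static inline int hmax_epu8_128(__m128i v) {
  v = _mm_max_epu8(v, _mm_srli_si128(v, 8));
  v = _mm_max_epu8(v, _mm_srli_si128(v, 4));
  v = _mm_max_epu8(v, _mm_srli_si128(v, 2));
  v = _mm_max_epu8(v, _mm_srli_si128(v, 1));
  return _mm_extract_epi16(v, 0) & 0xFF;
}

static inline int hmax_epi16_128(__m128i v) {
  v = _mm_max_epi16(v, _mm_srli_si128(v, 8));
  v = _mm_max_epi16(v, _mm_srli_si128(v, 4));
  v = _mm_max_epi16(v, _mm_srli_si128(v, 2));
  return (int16_t) _mm_extract_epi16(v, 0);
}

// `end_out`, when non-null, receives the smallest 1-based reference column
// whose DP column attains the final maximum score (0 if the score is 0);
// this equals the scalar DP's tie-broken best reference end.
static int sw_score_striped8(const StripedProfile8& P,
                             const std::vector<uint8_t>& r,
                             int go, int ge, int* end_out = 0) {
  const int seglen = P.seglen;
  if (end_out) *end_out = 0;
  if (P.m == 0 || r.empty()) return 0;
  std::vector<__m128i> Hload(seglen, _mm_setzero_si128());
  std::vector<__m128i> Hstore(seglen, _mm_setzero_si128());
  std::vector<__m128i> Evec(seglen, _mm_setzero_si128());
  const __m128i vGo = _mm_set1_epi8((char) (uint8_t) (-go));
  const __m128i vGe = _mm_set1_epi8((char) (uint8_t) (-ge));
  const __m128i vBias = _mm_set1_epi8((char) (uint8_t) P.bias);
  __m128i vMax = _mm_setzero_si128();
  __m128i vSeen = _mm_setzero_si128();
  int gbest = 0, gend = 0;

  for (size_t j = 0; j < r.size(); ++j) {
    const __m128i* prof = &P.prof[(size_t) r[j] * seglen];
    __m128i vF = _mm_setzero_si128();
    __m128i vH = _mm_slli_si128(Hstore[seglen - 1], 1);
    std::swap(Hload, Hstore);
    for (int k = 0; k < seglen; ++k) {
      vH = _mm_subs_epu8(_mm_adds_epu8(vH, prof[k]), vBias);
      vH = _mm_max_epu8(vH, Evec[k]);
      vH = _mm_max_epu8(vH, vF);
      vMax = _mm_max_epu8(vMax, vH);
      Hstore[k] = vH;
      __m128i vHgo = _mm_subs_epu8(vH, vGo);
      Evec[k] = _mm_max_epu8(_mm_subs_epu8(Evec[k], vGe), vHgo);
      vF = _mm_max_epu8(_mm_subs_epu8(vF, vGe), vHgo);
      vH = Hload[k];
    }
    vF = _mm_slli_si128(vF, 1);
    int k = 0;
    while (true) {
      __m128i vT = _mm_subs_epu8(Hstore[k], vGo);
      __m128i vC = _mm_cmpeq_epi8(_mm_max_epu8(vF, vT), vT);
      if (_mm_movemask_epi8(vC) == 0xFFFF) break;
      Hstore[k] = _mm_max_epu8(Hstore[k], vF);
      vMax = _mm_max_epu8(vMax, Hstore[k]);
      Evec[k] = _mm_max_epu8(Evec[k], _mm_subs_epu8(Hstore[k], vGo));
      vF = _mm_subs_epu8(vF, vGe);
      ++k;
      if (k == seglen) { k = 0; vF = _mm_slli_si128(vF, 1); }
    }
    if (_mm_movemask_epi8(_mm_cmpeq_epi8(vMax, vSeen)) != 0xFFFF) {
      vSeen = vMax;
      int h = hmax_epu8_128(vMax);
      if (h > gbest) { gbest = h; gend = (int) j + 1; }
    }
  }
  if (end_out) *end_out = gend;
  return gbest;
}

static int sw_score_striped(const StripedProfile& P,
                            const std::vector<uint8_t>& r,
                            int go, int ge, int* end_out = 0) {
  const int seglen = P.seglen;
  if (end_out) *end_out = 0;
  if (P.m == 0 || r.empty()) return 0;
  std::vector<__m128i> Hload(seglen, _mm_setzero_si128());
  std::vector<__m128i> Hstore(seglen, _mm_setzero_si128());
  std::vector<__m128i> Evec(seglen, _mm_setzero_si128());
  const __m128i vGo = _mm_set1_epi16((int16_t) (-go)); // positive penalty
  const __m128i vGe = _mm_set1_epi16((int16_t) (-ge));
  const __m128i vZero = _mm_setzero_si128();
  __m128i vMax = _mm_setzero_si128();
  __m128i vSeen = _mm_setzero_si128();
  int gbest = 0, gend = 0;

  for (size_t j = 0; j < r.size(); ++j) {
    const __m128i* prof = &P.prof[(size_t) r[j] * seglen];
    __m128i vF = vZero;
    __m128i vH = _mm_slli_si128(Hstore[seglen - 1], 2);
    std::swap(Hload, Hstore);
    for (int k = 0; k < seglen; ++k) {
      vH = _mm_adds_epi16(vH, prof[k]);
      vH = _mm_max_epi16(vH, Evec[k]);
      vH = _mm_max_epi16(vH, vF);
      vH = _mm_max_epi16(vH, vZero);
      vMax = _mm_max_epi16(vMax, vH);
      Hstore[k] = vH;
      __m128i vHgo = _mm_subs_epi16(vH, vGo);
      Evec[k] = _mm_max_epi16(_mm_subs_epi16(Evec[k], vGe), vHgo);
      Evec[k] = _mm_max_epi16(Evec[k], vZero);
      vF = _mm_max_epi16(_mm_subs_epi16(vF, vGe), vHgo);
      vF = _mm_max_epi16(vF, vZero);
      vH = Hload[k];
    }
    // lazy-F propagation
    vF = _mm_slli_si128(vF, 2);
    int k = 0;
    while (true) {
      __m128i vTemp = _mm_subs_epi16(Hstore[k], vGo);
      vTemp = _mm_cmpgt_epi16(vF, vTemp);
      if (_mm_movemask_epi8(vTemp) == 0) break;
      Hstore[k] = _mm_max_epi16(Hstore[k], vF);
      vMax = _mm_max_epi16(vMax, Hstore[k]);
      __m128i vHgo = _mm_subs_epi16(Hstore[k], vGo);
      Evec[k] = _mm_max_epi16(Evec[k], vHgo);
      vF = _mm_subs_epi16(vF, vGe);
      ++k;
      if (k == seglen) { k = 0; vF = _mm_slli_si128(vF, 2); }
    }
    if (_mm_movemask_epi8(_mm_cmpeq_epi16(vMax, vSeen)) != 0xFFFF) {
      vSeen = vMax;
      int h = hmax_epi16_128(vMax);
      if (h > gbest) { gbest = h; gend = (int) j + 1; }
    }
  }
  if (end_out) *end_out = gend;
  return gbest;
}

// ---------------------------------------------------------------------------
// AVX2 variants (32 x 8-bit / 16 x 16-bit lanes), compiled with a function-
// level target attribute so the translation unit itself needs only the
// baseline x86-64 flags; selected at run time via __builtin_cpu_supports.
// Buffers are manually 32-byte aligned to stay independent of the allocator.
// ---------------------------------------------------------------------------
#ifdef SW_AVX2_DISPATCH

struct AlignedBuf256 {
  std::vector<uint8_t> raw;
  void* p;
  AlignedBuf256() : p(0) {}
  void alloc_bytes(size_t nbytes) {
    raw.assign(nbytes + 31, 0);
    p = (void*) (((uintptr_t) raw.data() + 31) & ~(uintptr_t) 31);
  }
};

struct AvxProfile8 { int m; int seglen; int bias; AlignedBuf256 buf; };
struct AvxProfile16 { int m; int seglen; AlignedBuf256 buf; };

static void build_profile8_avx2(const std::vector<uint8_t>& q, int ma, int mi,
                                AvxProfile8& P) {
  P.m = (int) q.size();
  P.seglen = (P.m + 31) / 32;
  P.bias = profile8_bias(ma, mi);
  P.buf.alloc_bytes((size_t) 5 * P.seglen * 32);
  uint8_t* b = (uint8_t*) P.buf.p;
  for (int a = 0; a < 5; ++a)
    for (int k = 0; k < P.seglen; ++k)
      for (int l = 0; l < 32; ++l) {
        int i = l * P.seglen + k;
        int v = (i < P.m) ? sub_score(q[i], (uint8_t) a, ma, mi) + P.bias : 0;
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        b[((size_t) a * P.seglen + k) * 32 + l] = (uint8_t) v;
      }
}

static void build_profile16_avx2(const std::vector<uint8_t>& q, int ma, int mi,
                                 AvxProfile16& P) {
  P.m = (int) q.size();
  P.seglen = (P.m + 15) / 16;
  P.buf.alloc_bytes((size_t) 5 * P.seglen * 32);
  int16_t* b = (int16_t*) P.buf.p;
  for (int a = 0; a < 5; ++a)
    for (int k = 0; k < P.seglen; ++k)
      for (int l = 0; l < 16; ++l) {
        int i = l * P.seglen + k;
        b[((size_t) a * P.seglen + k) * 16 + l] =
          (i < P.m) ? (int16_t) sub_score(q[i], (uint8_t) a, ma, mi)
                    : (int16_t) -30000;
      }
}

// whole-register left shift by one / two bytes (crosses the 128-bit lanes)
__attribute__((target("avx2")))
static inline __m256i shl_byte_256(__m256i v) {
  __m256i t = _mm256_permute2x128_si256(v, v, 0x08); // [hi = v.lo, lo = 0]
  return _mm256_alignr_epi8(v, t, 15);
}

__attribute__((target("avx2")))
static inline __m256i shl_word_256(__m256i v) {
  __m256i t = _mm256_permute2x128_si256(v, v, 0x08);
  return _mm256_alignr_epi8(v, t, 14);
}

__attribute__((target("avx2")))
static inline int hmax_epu8_256(__m256i v) {
  __m128i a = _mm256_castsi256_si128(v);
  __m128i b = _mm256_extracti128_si256(v, 1);
  return hmax_epu8_128(_mm_max_epu8(a, b));
}

__attribute__((target("avx2")))
static inline int hmax_epi16_256(__m256i v) {
  __m128i a = _mm256_castsi256_si128(v);
  __m128i b = _mm256_extracti128_si256(v, 1);
  return hmax_epi16_128(_mm_max_epi16(a, b));
}

__attribute__((target("avx2")))
static int sw_score_striped8_avx2(const AvxProfile8& P,
                                  const std::vector<uint8_t>& r,
                                  int go, int ge, int* end_out) {
  const int seglen = P.seglen;
  if (end_out) *end_out = 0;
  if (P.m == 0 || r.empty()) return 0;
  AlignedBuf256 bufs[3];
  for (int b = 0; b < 3; ++b) bufs[b].alloc_bytes((size_t) seglen * 32);
  __m256i* Hload = (__m256i*) bufs[0].p;
  __m256i* Hstore = (__m256i*) bufs[1].p;
  __m256i* Evec = (__m256i*) bufs[2].p;
  const __m256i* prof_all = (const __m256i*) P.buf.p;
  const __m256i vGo = _mm256_set1_epi8((char) (uint8_t) (-go));
  const __m256i vGe = _mm256_set1_epi8((char) (uint8_t) (-ge));
  const __m256i vBias = _mm256_set1_epi8((char) (uint8_t) P.bias);
  __m256i vMax = _mm256_setzero_si256();
  __m256i vSeen = _mm256_setzero_si256();
  int gbest = 0, gend = 0;

  for (size_t j = 0; j < r.size(); ++j) {
    const __m256i* prof = prof_all + (size_t) r[j] * seglen;
    __m256i vF = _mm256_setzero_si256();
    __m256i vH = shl_byte_256(Hstore[seglen - 1]);
    std::swap(Hload, Hstore);
    for (int k = 0; k < seglen; ++k) {
      vH = _mm256_subs_epu8(_mm256_adds_epu8(vH, prof[k]), vBias);
      vH = _mm256_max_epu8(vH, Evec[k]);
      vH = _mm256_max_epu8(vH, vF);
      vMax = _mm256_max_epu8(vMax, vH);
      Hstore[k] = vH;
      __m256i vHgo = _mm256_subs_epu8(vH, vGo);
      Evec[k] = _mm256_max_epu8(_mm256_subs_epu8(Evec[k], vGe), vHgo);
      vF = _mm256_max_epu8(_mm256_subs_epu8(vF, vGe), vHgo);
      vH = Hload[k];
    }
    vF = shl_byte_256(vF);
    int k = 0;
    while (true) {
      __m256i vT = _mm256_subs_epu8(Hstore[k], vGo);
      __m256i vC = _mm256_cmpeq_epi8(_mm256_max_epu8(vF, vT), vT);
      if (_mm256_movemask_epi8(vC) == -1) break;
      Hstore[k] = _mm256_max_epu8(Hstore[k], vF);
      vMax = _mm256_max_epu8(vMax, Hstore[k]);
      Evec[k] = _mm256_max_epu8(Evec[k], _mm256_subs_epu8(Hstore[k], vGo));
      vF = _mm256_subs_epu8(vF, vGe);
      ++k;
      if (k == seglen) { k = 0; vF = shl_byte_256(vF); }
    }
    if (_mm256_movemask_epi8(_mm256_cmpeq_epi8(vMax, vSeen)) != -1) {
      vSeen = vMax;
      int h = hmax_epu8_256(vMax);
      if (h > gbest) { gbest = h; gend = (int) j + 1; }
    }
  }
  if (end_out) *end_out = gend;
  return gbest;
}

__attribute__((target("avx2")))
static int sw_score_striped16_avx2(const AvxProfile16& P,
                                   const std::vector<uint8_t>& r,
                                   int go, int ge, int* end_out) {
  const int seglen = P.seglen;
  if (end_out) *end_out = 0;
  if (P.m == 0 || r.empty()) return 0;
  AlignedBuf256 bufs[3];
  for (int b = 0; b < 3; ++b) bufs[b].alloc_bytes((size_t) seglen * 32);
  __m256i* Hload = (__m256i*) bufs[0].p;
  __m256i* Hstore = (__m256i*) bufs[1].p;
  __m256i* Evec = (__m256i*) bufs[2].p;
  const __m256i* prof_all = (const __m256i*) P.buf.p;
  const __m256i vGo = _mm256_set1_epi16((int16_t) (-go));
  const __m256i vGe = _mm256_set1_epi16((int16_t) (-ge));
  const __m256i vZero = _mm256_setzero_si256();
  __m256i vMax = _mm256_setzero_si256();
  __m256i vSeen = _mm256_setzero_si256();
  int gbest = 0, gend = 0;

  for (size_t j = 0; j < r.size(); ++j) {
    const __m256i* prof = prof_all + (size_t) r[j] * seglen;
    __m256i vF = vZero;
    __m256i vH = shl_word_256(Hstore[seglen - 1]);
    std::swap(Hload, Hstore);
    for (int k = 0; k < seglen; ++k) {
      vH = _mm256_adds_epi16(vH, prof[k]);
      vH = _mm256_max_epi16(vH, Evec[k]);
      vH = _mm256_max_epi16(vH, vF);
      vH = _mm256_max_epi16(vH, vZero);
      vMax = _mm256_max_epi16(vMax, vH);
      Hstore[k] = vH;
      __m256i vHgo = _mm256_subs_epi16(vH, vGo);
      Evec[k] = _mm256_max_epi16(_mm256_subs_epi16(Evec[k], vGe), vHgo);
      Evec[k] = _mm256_max_epi16(Evec[k], vZero);
      vF = _mm256_max_epi16(_mm256_subs_epi16(vF, vGe), vHgo);
      vF = _mm256_max_epi16(vF, vZero);
      vH = Hload[k];
    }
    vF = shl_word_256(vF);
    int k = 0;
    while (true) {
      __m256i vTemp = _mm256_subs_epi16(Hstore[k], vGo);
      vTemp = _mm256_cmpgt_epi16(vF, vTemp);
      if (_mm256_movemask_epi8(vTemp) == 0) break;
      Hstore[k] = _mm256_max_epi16(Hstore[k], vF);
      vMax = _mm256_max_epi16(vMax, Hstore[k]);
      __m256i vHgo = _mm256_subs_epi16(Hstore[k], vGo);
      Evec[k] = _mm256_max_epi16(Evec[k], vHgo);
      vF = _mm256_subs_epi16(vF, vGe);
      ++k;
      if (k == seglen) { k = 0; vF = shl_word_256(vF); }
    }
    if (_mm256_movemask_epi8(_mm256_cmpeq_epi16(vMax, vSeen)) != -1) {
      vSeen = vMax;
      int h = hmax_epi16_256(vMax);
      if (h > gbest) { gbest = h; gend = (int) j + 1; }
    }
  }
  if (end_out) *end_out = gend;
  return gbest;
}
#endif // SW_AVX2_DISPATCH
#endif // __SSE2__

static bool avx2_enabled() {
#ifdef SW_AVX2_DISPATCH
  static const bool v = __builtin_cpu_supports("avx2") != 0;
  return v;
#else
  return false;
#endif
}

static bool sse2_enabled() {
#ifdef __SSE2__
  return true;
#else
  return false;
#endif
}

// [[Rcpp::export(name = ".sw_engines_cpp")]]
CharacterVector sw_engines_cpp() {
  std::vector<std::string> e;
  e.push_back("scalar");
  if (sse2_enabled()) e.push_back("sse2");
  if (avx2_enabled()) e.push_back("avx2");
  return wrap(e);
}

static List sw_result_to_list(const SWResult& a) {
  return List::create(
    _["score"] = a.score,
    _["matches"] = a.matches,
    _["columns"] = a.columns,
    _["read_start"] = a.read_start,
    _["read_end"] = a.read_end,
    _["ref_start"] = a.ref_start,
    _["ref_end"] = a.ref_end,
    _["found"] = a.found);
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  SWResult a = sw_align_scalar(encode_seq(read), encode_seq(ref),
                               match, mismatch, gap_open, gap_extend);
  return sw_result_to_list(a);
}

// score + smallest best reference end from one named engine ("scalar",
// "sse2", "avx2" or "auto"); the testing surface for kernel agreement
// [[Rcpp::export(name = ".sw_score_cpp")]]
List sw_score_cpp(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend,
                  std::string engine = "auto") {
  std::vector<uint8_t> q = encode_seq(read), r = encode_seq(ref);
  if (engine == "auto")
    engine = avx2_enabled() ? "avx2" : (sse2_enabled() ? "sse2" : "scalar");
  int sc = 0, jend = 0;
  if (engine == "scalar") {
    SWResult a = sw_align_scalar(q, r, match, mismatch, gap_open, gap_extend);
    sc = a.score; jend = a.found ? a.ref_end : 0;
  } else if (engine == "sse2") {
#ifdef __SSE2__
    StripedProfile8 P8;
    build_profile8(q, match, mismatch, P8);
    sc = sw_score_striped8(P8, r, gap_open, gap_extend, &jend);
    if (sc >= 255 - P8.bias) {
      StripedProfile P;
      build_profile(q, match, mismatch, P);
      sc = sw_score_striped(P, r, gap_open, gap_extend, &jend);
    }
#else
    stop("sse2 engine not available on this build");
#endif
  } else if (engine == "avx2") {
#ifdef SW_AVX2_DISPATCH
    if (!avx2_enabled()) stop("avx2 engine not available on this CPU");
    AvxProfile8 P8;
    build_profile8_avx2(q, match, mismatch, P8);
    sc = sw_score_striped8_avx2(P8, r, gap_open, gap_extend, &jend);
    if (sc >= 255 - P8.bias) {
      AvxProfile16 P16;
      build_profile16_avx2(q, match, mismatch, P16);
      sc = sw_score_striped16_avx2(P16, r, gap_open, gap_extend, &jend);
    }
#else
    stop("avx2 engine not available on this build");
#endif
  } else {
    stop("unknown engine '%s'", engine.c_str());
  }
  return List::create(_["score"] = sc, _["ref_end"] = jend);
}

// ---------------------------------------------------------------------------
// Windowed traceback.  `jend` is the smallest 1-based reference column that
// attains `expect_score` (from a score-only kernel).  Any local alignment
// with a positive score spans fewer than span_max reference columns, and the
// DP cells a traceback can consult are exact whenever the alignment keeps
// span_max + gap_max columns of margin to the window's left edge; the margin
// is checked after aligning and the window widened to a reference prefix
// (exact by construction: DP columns never depend on later columns) if the
// alignment sits too close to the cut.
// ---------------------------------------------------------------------------
static SWResult align_candidate(const std::vector<uint8_t>& q,
                                const std::vector<uint8_t>& r,
                                int jend, int expect_score,
                                int ma, int mi, int go, int ge) {
  const int m = (int) q.size(), n = (int) r.size();
  if (jend <= 0 || jend > n || m == 0)
    return sw_align_scalar(q, r, ma, mi, go, ge);
  long per_col = -ge < -go ? -ge : -go;
  if (per_col < 1) per_col = 1;
  long top = (long) m * (ma > 0 ? ma : 1);
  long span_max = (long) m + top / per_col + 2;
  long gap_max = top / per_col + 1;
  long wlen = (long) m + span_max + gap_max + 8;
  int wstart = (long) jend > wlen ? (int) (jend - wlen) : 0;
  for (;;) {
    std::vector<uint8_t> sub(r.begin() + wstart, r.begin() + jend);
    SWResult a = sw_align_scalar(q, sub, ma, mi, go, ge);
    bool ok = a.found && a.score == expect_score &&
      a.ref_end == jend - wstart &&
      (wstart == 0 || (long) a.ref_start >= span_max + gap_max);
    if (ok) {
      a.ref_start += wstart;
      a.ref_end += wstart;
      return a;
    }
    if (wstart == 0) // cannot happen; align the full reference to be safe
      return sw_align_scalar(q, r, ma, mi, go, ge);
    wstart = 0;
  }
}

// ---------------------------------------------------------------------------
// Batch recruitment: best hit per read over all references and both strands.
//
// Best hit = highest Smith-Waterman score; ties broken by higher identity
// (matches / alignment columns), then longer alignment (more columns), then
// the reference that comes first in `refs` (the R wrapper passes references
// sorted by id), then the forward strand.
// ---------------------------------------------------------------------------

// ---------------------------------------------------------------------------
// Exact k-mer score bound (q-gram lemma) used to skip hopeless scans.
//
// Consider any local alignment of read q (length m) against reference r with
// score S, under match ma > 0 and per-event penalty p = min(-mismatch,
// -gap_open) >= 0 (a gap of any length costs at least -gap_open).  Its M
// match columns fall into runs of read positions that are contiguous in both
// sequences; every k-mer inside a run occurs in r.  With E = mismatches +
// gaps, there are at most E + 1 runs, so the read shares at least
// c >= M - (E+1)(k-1) k-mers with r.  Using S <= ma*M - p*E and M <= m:
//   S <= ma*m - p * max(0, ceil((m - c) / (k-1)) - 1).
// A (reference, strand) whose bound is strictly below the best score seen so
// far can be skipped: it can neither win nor tie.  k-mers containing N are
// ignored on both sides, which only lowers c and keeps the bound valid (N
// never matches, so no match run contains one).
// ---------------------------------------------------------------------------
static const int PREFILTER_K = 11;

static void index_ref_kmers(const std::vector<uint8_t>& r, int j,
                            std::unordered_map<uint32_t, uint64_t>& idx) {
  const int k = PREFILTER_K;
  const int n = (int) r.size();
  uint32_t code = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int valid = 0;
  for (int p = 0; p < n; ++p) {
    if (r[p] >= 4) { valid = 0; code = 0; continue; }
    code = ((code << 2) | r[p]) & mask;
    if (++valid >= k) idx[code] |= (uint64_t) 1 << j;
  }
}

static void count_shared_kmers(const std::vector<uint8_t>& q,
                               const std::unordered_map<uint32_t, uint64_t>& idx,
                               int* c, int nf) {
  const int k = PREFILTER_K;
  for (int j = 0; j < nf; ++j) c[j] = 0;
  const int m = (int) q.size();
  uint32_t code = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int valid = 0;
  for (int p = 0; p < m; ++p) {
    if (q[p] >= 4) { valid = 0; code = 0; continue; }
    code = ((code << 2) | q[p]) & mask;
    if (++valid < k) continue;
    std::unordered_map<uint32_t, uint64_t>::const_iterator it =
      idx.find(code);
    if (it == idx.end()) continue;
    uint64_t bits = it->second;
    while (bits) {
#if defined(__GNUC__) || defined(__clang__)
      int j = __builtin_ctzll(bits);
      bits &= bits - 1;
      ++c[j];
#else
      for (int j = 0; j < nf; ++j) if (bits & ((uint64_t) 1 << j)) ++c[j];
      bits = 0;
#endif
    }
  }
}

static inline int kmer_score_bound(int m, int c, int ma, int pen) {
  const int k = PREFILTER_K;
  int deficit = m - c;
  int events = (deficit + k - 2) / (k - 1) - 1;
  if (events < 0) events = 0;
  return ma * m - pen * events;
}

// [[Rcpp::export(name = ".recruit_best_cpp")]]
DataFrame recruit_best_cpp(CharacterVector reads, CharacterVector refs,
                           int match, int mismatch, int gap_open,
                           int gap_extend) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::vector<uint8_t>> refenc(nf);
  for (int j = 0; j < nf; ++j) refenc[j] = encode_seq(as<std::string>(refs[j]));

  // per-event penalty for the score bound; 0 disables skipping (bound
  // becomes the trivial ma * m)
  int pen = -mismatch < -gap_open ? -mismatch : -gap_open;
  if (pen < 0) pen = 0;
  const bool prefilter = nf <= 64 && match > 0;
  std::unordered_map<uint32_t, uint64_t> kindex;
  if (prefilter)
    for (int j = 0; j < nf; ++j) index_ref_kmers(refenc[j], j, kindex);

  IntegerVector ref_idx(nr), score(nr), matches(nr), columns(nr),
    read_start(nr), read_end(nr), ref_start(nr), ref_end(nr);
  CharacterVector strand(nr);
  LogicalVector found(nr);

  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_str(fwd);
    std::vector<uint8_t> qf = encode_seq(fwd), qr = encode_seq(rev);

    int best_score = 0;
    struct Cand { int j, s, jend; };
    std::vector<Cand> cand;
    const bool use_avx2 = avx2_enabled();

#ifdef __SSE2__
    StripedProfile8 Pf8, Pr8;
    StripedProfile Pf, Pr;
    bool have16 = false;
    if (!use_avx2) {
      build_profile8(qf, match, mismatch, Pf8);
      build_profile8(qr, match, mismatch, Pr8);
    }
#endif
#ifdef SW_AVX2_DISPATCH
    AvxProfile8 Af8, Ar8;
    AvxProfile16 Af16, Ar16;
    bool have16a = false;
    if (use_avx2) {
      build_profile8_avx2(qf, match, mismatch, Af8);
      build_profile8_avx2(qr, match, mismatch, Ar8);
    }
#endif
    // shared k-mer counts per (reference, strand); scan in decreasing order
    // so strong hits raise best_score before weak ones are considered
    const int m_read = (int) qf.size();
    std::vector<int> cshare(2 * nf, 0);
    std::vector<int> order(2 * nf);
    for (int t = 0; t < 2 * nf; ++t) order[t] = t;
    if (prefilter) {
      count_shared_kmers(qf, kindex, &cshare[0], nf);
      count_shared_kmers(qr, kindex, &cshare[nf], nf);
      std::stable_sort(order.begin(), order.end(),
                       [&cshare](int a, int b) {
                         return cshare[a] > cshare[b];
                       });
    }

    const int sat8 = 255 - profile8_bias(match, mismatch);
    for (int t = 0; t < 2 * nf; ++t) {
      {
        const int s = order[t] / nf, j = order[t] % nf;
        if (prefilter && best_score > 0 &&
            kmer_score_bound(m_read, cshare[order[t]], match, pen) <
              best_score)
          continue;
        int sc = 0, jend = 0;
#ifdef SW_AVX2_DISPATCH
        if (use_avx2) {
          sc = sw_score_striped8_avx2(s == 0 ? Af8 : Ar8, refenc[j],
                                      gap_open, gap_extend, &jend);
          if (sc >= sat8) { // possibly saturated; redo in 16-bit
            if (!have16a) {
              build_profile16_avx2(qf, match, mismatch, Af16);
              build_profile16_avx2(qr, match, mismatch, Ar16);
              have16a = true;
            }
            sc = sw_score_striped16_avx2(s == 0 ? Af16 : Ar16, refenc[j],
                                         gap_open, gap_extend, &jend);
          }
        } else
#endif
        {
#ifdef __SSE2__
          sc = sw_score_striped8(s == 0 ? Pf8 : Pr8, refenc[j], gap_open,
                                 gap_extend, &jend);
          if (sc >= sat8) { // possibly saturated; redo in 16-bit
            if (!have16) {
              build_profile(qf, match, mismatch, Pf);
              build_profile(qr, match, mismatch, Pr);
              have16 = true;
            }
            sc = sw_score_striped(s == 0 ? Pf : Pr, refenc[j], gap_open,
                                  gap_extend, &jend);
          }
#else
          sc = sw_score_scalar(s == 0 ? qf : qr, refenc[j], match, mismatch,
                               gap_open, gap_extend);
          jend = 0; // unknown; align_candidate falls back to the full DP
#endif
        }
        if (sc > best_score) {
          best_score = sc;
          cand.clear();
          Cand c; c.j = j; c.s = s; c.jend = jend;
          cand.push_back(c);
        } else if (sc == best_score && sc > 0) {
          Cand c; c.j = j; c.s = s; c.jend = jend;
          cand.push_back(c);
        }
      }
    }

    if (best_score <= 0 || cand.empty()) {
      found[i] = false;
      ref_idx[i] = NA_INTEGER; score[i] = 0;
      matches[i] = columns[i] = 0;
      read_start[i] = read_end[i] = ref_start[i] = ref_end[i] = NA_INTEGER;
      strand[i] = NA_STRING;
      continue;
    }

    // full alignment for each candidate, deterministic tie-break
    SWResult best; best.found = false;
    int best_j = -1, best_s = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      int j = cand[c].j, s = cand[c].s;
      SWResult a = align_candidate(s == 0 ? qf : qr, refenc[j],
                                   cand[c].jend, best_score, match,
                                   mismatch, gap_open, gap_extend);
      bool take = false;
      if (!best.found) take = true;
      else {
        // identity = matches / columns; compare cross-multiplied
        long li = (long) a.matches * best.columns;
        long lb = (long) best.matches * a.columns;
        if (li > lb) take = true;
        else if (li == lb) {
          if (a.columns > best.columns) take = true;
          else if (a.columns == best.columns) {
            if (j < best_j) take = true;
            else if (j == best_j && s < best_s) take = true;
          }
        }
      }
      if (take) { best = a; best_j = j; best_s = s; }
    }

    found[i] = true;
    ref_idx[i] = best_j + 1; // 1-based for R
    score[i] = best.score;
    matches[i] = best.matches;
    columns[i] = best.columns;
    read_start[i] = best.read_start;
    read_end[i] = best.read_end;
    ref_start[i] = best.ref_start;
    ref_end[i] = best.ref_end;
    strand[i] = best_s == 0 ? "+" : "-";
  }

  return DataFrame::create(
    _["found"] = found, _["ref_idx"] = ref_idx, _["score"] = score,
    _["matches"] = matches, _["columns"] = columns,
    _["read_start"] = read_start, _["read_end"] = read_end,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end,
    _["strand"] = strand, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Semi-global "fit" alignment for rRNA fragment classification: the read is
// aligned end-to-end against the best-fitting region of the reference
// (reference end gaps free).  Returns the minimum number of differences
// (mismatches + gap columns), the quantity minimised by the miTag best-hit
// rule.  N in the read never matches (reads with N are rejected upstream).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fit_diffs_cpp")]]
int fit_diffs_cpp(std::string read, std::string ref) {
  std::vector<uint8_t> q = encode_seq(read), r = encode_seq(ref);
  const int m = (int) q.size(), n = (int) r.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int j = 0; j <= n; ++j) prev[j] = 0; // free leading ref gap
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + ((q[i - 1] == r[j - 1] && q[i - 1] < 4) ? 0 : 1);
      int up = prev[j] + 1;
      int lf = cur[j - 1] + 1;
      int v = d < up ? d : up;
      if (lf < v) v = lf;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] < best) best = prev[j];
  return best;
}

// ---------------------------------------------------------------------------
// k-mer complexity statistics.  Windows containing an ambiguous base are
// skipped and do not count as k-mer windows.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".kmer_stats_cpp")]]
IntegerVector kmer_stats_cpp(std::string seq, int k) {
  std::vector<uint8_t> s = encode_seq(seq);
  const int n = (int) s.size();
  IntegerVector out(3); // distinct, max_count, windows
  if (k <= 0 || n < k) { out[0] = 0; out[1] = 0; out[2] = 0; return out; }
  size_t space = 1;
  for (int i = 0; i < k; ++i) space *= 4;
  std::vector<int> counts(space, 0);
  int windows = 0;
  for (int i = 0; i + k <= n; ++i) {
    size_t code = 0; bool ok = true;
    for (int l = 0; l < k; ++l) {
      if (s[i + l] >= 4) { ok = false; break; }
      code = code * 4 + s[i + l];
    }
    if (!ok) continue;
    ++windows;
    ++counts[code];
  }
  int distinct = 0, maxc = 0;
  for (size_t c = 0; c < space; ++c) {
    if (counts[c] > 0) ++distinct;
    if (counts[c] > maxc) maxc = counts[c];
  }
  out[0] = distinct; out[1] = maxc; out[2] = windows;
  return out;
}

// ---------------------------------------------------------------------------
// Profile alignment: map a query amino-acid fragment onto the fixed columns
// of a reference alignment.  Query residues are assigned to strictly
// increasing profile columns; internal column skips are penalised with
// affine gap costs, leading and trailing skips are free, and no new columns
// may be created (add-to-alignment contract).  colscore is a (query length
// x profile width) matrix of position-specific scores.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix colscore, double gap_open,
                       double gap_extend) {
  const int m = colscore.nrow();  // query residues
  const int W = colscore.ncol();  // profile columns
  if (m == 0 || W == 0 || m > W)
    return List::create(_["score"] = R_NegInf,
                        _["columns"] = IntegerVector(0));
  const double NEG = -1e18;
  // best[i][j]: residue i placed at column j; skip[i][j]: residue i placed
  // at some column < j, columns up to j skipped (internal gap open charge).
  NumericMatrix best(m + 1, W + 1), skip(m + 1, W + 1);
  IntegerMatrix from(m + 1, W + 1); // 0 = via best(i-1,j-1), 1 = via skip(i-1,j-1)
  IntegerMatrix skipfrom(m + 1, W + 1); // column where residue i actually sits
  for (int j = 0; j <= W; ++j) { best(0, j) = 0.0; skip(0, j) = 0.0; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= W; ++j) { best(i, j) = NEG; skip(i, j) = NEG; }
    for (int j = i; j <= W; ++j) { // need at least i columns for i residues
      double a = best(i - 1, j - 1), b = skip(i - 1, j - 1);
      double base = a >= b ? a : b;
      if (base > NEG / 2) {
        best(i, j) = base + colscore(i - 1, j - 1);
        from(i, j) = a >= b ? 0 : 1;
      }
      // skip recurrence
      double open_ = best(i, j - 1) + gap_open;
      double ext_ = skip(i, j - 1) + gap_extend;
      if (open_ >= ext_) { skip(i, j) = open_; skipfrom(i, j) = j - 1; }
      else { skip(i, j) = ext_; skipfrom(i, j) = skipfrom(i, j - 1); }
    }
  }
  double total = NEG; int endj = -1;
  for (int j = m; j <= W; ++j)
    if (best(m, j) > total) { total = best(m, j); endj = j; }
  if (endj < 0)
    return List::create(_["score"] = R_NegInf,
                        _["columns"] = IntegerVector(0));
  IntegerVector cols(m);
  int i = m, j = endj;
  while (i >= 1) {
    cols[i - 1] = j;
    int f = from(i, j);
    if (f == 0) { --i; --j; }
    else {
      // previous residue i-1 sits at skipfrom(i-1, j-1)
      int pj = skipfrom(i - 1, j - 1);
      --i;
      j = pj;
    }
  }
  return List::create(_["score"] = total, _["columns"] = cols);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
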