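// Core of the k-mer -> gene-set index and the shared-base read scan.
//
// Bit conventions (shared with the R level):
//  * packed bit vectors are RawVector; bit p (0-based) lives at byte p>>3,
//    bit p&7, little-endian within the byte (matches base R rawToBits()).
//  * rank1(B, i) follows the 1-based half-open convention: the number of 1s
//    in B[1, i), i.e. strictly before 1-based position i.  In 0-based terms
//    that is popcount of positions [0, i-1).
//  * select1(B, j) is the 1-based position of the j-th set bit.
//
// k-mer encoding: 2 bits per base, A=0 C=1 G=2 T=3, leftmost base in the
// most-significant occupied bits, so unsigned comparison of two encoded
// k-mers of equal k is exactly lexicographic comparison under A<C<G<T.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

const char BASES[4] = {'A', 'C', 'G', 'T'};

// murmur3 64-bit finaliser: well mixed, branch-free, platform independent.
inline uint64_t fmix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

inline uint64_t hashPos(uint64_t value, uint64_t m, uint64_t seed) {
  return fmix64(value ^ (seed * 0x9e3779b97f4a7c15ULL)) % m;
}

// Encode one k-length window; returns false on an ambiguous base.
bool encodeWindow(const char* s, int k, uint64_t& fwd, uint64_t& rc) {
  fwd = 0;
  rc = 0;
  const int shiftRC = 2 * (k - 1);
  for (int i = 0; i < k; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (uint64_t)c;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shiftRC);
  }
  return true;
}

std::string decodeKmer(uint64_t v, int k) {
  std::string out(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    out[i] = BASES[v & 3ULL];
    v >>= 2;
  }
  return out;
}

// Rolling scan over a sequence collecting canonical k-mer values at each
// admissible start.  A window is admissible when every base is A/C/G/T and
// (when q > 0 and qualities are given) every base quality is >= q.
void collectCanonical(const char* s, int n, const int* quals, int k, int q,
                      std::vector<int>& starts, std::vector<uint64_t>& values) {
  if (k > n) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shiftRC = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;  // consecutive admissible bases ending at position i
  for (int i = 0; i < n; ++i) {
    int c = baseCode(s[i]);
    bool ok = (c >= 0) && (q <= 0 || quals == nullptr || quals[i] >= q);
    if (!ok) {
      run = 0;
      fwd = 0;
      rc = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shiftRC);
    if (++run >= k) {
      starts.push_back(i - k + 1);
      values.push_back(fwd < rc ? fwd : rc);
    }
  }
}

inline bool getBit(const Rbyte* p, uint64_t pos) {
  return (p[pos >> 3] >> (pos & 7)) & 1;
}

inline void setBit(Rbyte* p, uint64_t pos) {
  p[pos >> 3] |= (Rbyte)(1u << (pos & 7));
}

// Rank support over a packed bit vector: cumulative popcounts per 512-bit
// superblock plus a byte scan inside the block (constant work per query).
struct BitRank {
  const Rbyte* p = nullptr;
  uint64_t nbits = 0;
  uint64_t nbytes = 0;
  std::vector<uint64_t> super;  // ones strictly before each 64-byte block

  void init(const Rbyte* p_, uint64_t nbits_) {
    p = p_;
    nbits = nbits_;
    nbytes = (nbits + 7) / 8;
    uint64_t nblocks = nbytes / 64 + 1;
    super.assign(nblocks, 0);
    uint64_t acc = 0;
    for (uint64_t b = 0; b < nblocks; ++b) {
      super[b] = acc;
      uint64_t end = std::min(nbytes, (b + 1) * 64);
      for (uint64_t i = b * 64; i < end; ++i)
        acc += __builtin_popcount((unsigned)p[i]);
    }
    total_ = acc;
  }

  // ones in 0-based positions [0, pos)
  uint64_t rankBefore(uint64_t pos) const {
    if (pos > nbits) pos = nbits;
    uint64_t byteEnd = pos >> 3;
    uint64_t b = byteEnd / 64;
    uint64_t r = super[b];
    for (uint64_t i = b * 64; i < byteEnd; ++i)
      r += __builtin_popcount((unsigned)p[i]);
    unsigned rem = pos & 7;
    if (rem) r += __builtin_popcount((unsigned)(p[byteEnd] & ((1u << rem) - 1u)));
    return r;
  }

  bool get(uint64_t pos) const { return getBit(p, pos); }
  uint64_t total() const { return total_; }

 private:
  uint64_t total_ = 0;
};

// 0-based positions of all set bits, in order (select table).
std::vector<uint64_t> onesPositions(const Rbyte* p, uint64_t nbits) {
  std::vector<uint64_t> pos;
  uint64_t nbytes = (nbits + 7) / 8;
  for (uint64_t i = 0; i < nbytes; ++i) {
    unsigned byte = p[i];
    while (byte) {
      unsigned b = __builtin_ctz(byte);
      uint64_t bit = i * 8 + b;
      if (bit < nbits) pos.push_back(bit);
      byte &= byte - 1;
    }
  }
  return pos;
}

uint64_t encodeCanonicalOrStop(const std::string& s) {
  int k = (int)s.size();
  if (k < 1 || k > 32) stop("k-mer length must be in [1, 32], got %d", k);
  uint64_t fwd, rc;
  if (!encodeWindow(s.c_str(), k, fwd, rc))
    stop("ambiguous base in k-mer '%s'", s.c_str());
  return fwd < rc ? fwd : rc;
}

// Shared helper: the segment of I for the set bit at Bloom position h.
// v = rank1(BF, h) + 1 (h holds a 1); boundaries via the select table of P.
inline void segmentBounds(const BitRank& bfRank, uint64_t h,
                          const std::vector<uint64_t>& selP, uint64_t& lo,
                          uint64_t& hi) {
  uint64_t v = bfRank.rankBefore(h) + 1;  // ordinal of this set bit
  lo = (v == 1) ? 0 : selP[v - 2] + 1;    // 0-based start into I
  hi = selP[v - 1];                        // 0-based inclusive end
}

}  // namespace

// [[Rcpp::export(name = ".cpp_canonical")]]
CharacterVector cpp_canonical(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    uint64_t v = encodeCanonicalOrStop(s);
    out[i] = decodeKmer(v, (int)s.size());
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_encode")]]
NumericVector cpp_encode(CharacterVector seqs) {
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (double)encodeCanonicalOrStop(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export(name = ".cpp_hash")]]
NumericVector cpp_hash(CharacterVector kmers, double m_, int seed) {
  if (m_ < 1) stop("Bloom size m must be >= 1");
  uint64_t m = (uint64_t)m_;
  int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t v = encodeCanonicalOrStop(as<std::string>(kmers[i]));
    out[i] = (double)hashPos(v, m, (uint64_t)(int64_t)seed);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_extract")]]
List cpp_extract(std::string seq, Nullable<IntegerVector> quals_, int k, int q) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::vector<int> qv;
  const int* qp = nullptr;
  if (quals_.isNotNull()) {
    IntegerVector quals(quals_);
    if ((size_t)quals.size() != seq.size())
      stop("quality length (%d) != sequence length (%d)", (int)quals.size(),
           (int)seq.size());
    qv.assign(quals.begin(), quals.end());
    qp = qv.data();
  }
  std::vector<int> starts;
  std::vector<uint64_t> values;
  collectCanonical(seq.c_str(), (int)seq.size(), qp, k, q, starts, values);
  int n = (int)starts.size();
  CharacterVector km(n);
  NumericVector val(n);
  for (int i = 0; i < n; ++i) {
    km[i] = decodeKmer(values[i], k);
    val[i] = (double)values[i];
  }
  return List::create(_["start"] = wrap(starts), _["kmer"] = km,
                      _["value"] = val);
}

// [[Rcpp::export(name = ".cpp_build_index")]]
List cpp_build_index(CharacterVector seqs, int k, double m_, int seed) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  if (m_ < 1) stop("Bloom size m must be >= 1");
  uint64_t m = (uint64_t)m_;
  uint64_t seed64 = (uint64_t)(int64_t)seed;
  int nGenes = seqs.size();
  if (nGenes < 1) stop("empty gene panel");

  uint64_t nbytes = (m + 7) / 8;
  RawVector bf((R_xlen_t)nbytes);  // zero-initialised
  Rbyte* bfp = bf.begin();

  // Phase 1: set one Bloom bit per canonical gene k-mer (single hash).
  // Cache per-gene values so phase 2 does not re-extract.
  std::vector<std::vector<uint64_t>> geneVals(nGenes);
  for (int g = 0; g < nGenes; ++g) {
    std::string s = as<std::string>(seqs[g]);
    std::vector<int> starts;
    collectCanonical(s.c_str(), (int)s.size(), nullptr, k, 0, starts,
                     geneVals[g]);
    for (uint64_t v : geneVals[g]) setBit(bfp, hashPos(v, m, seed64));
  }

  BitRank bfRank;
  bfRank.init(bfp, m);
  uint64_t ell = bfRank.total();

  // Phase 2: one list L_r per set bit; genes scanned in ID order append
  // their ID unless it already terminates the list, so duplicates (which
  // are adjacent by construction) are removed and segments stay strictly
  // increasing.
  std::vector<std::vector<int>> lists((size_t)ell);
  uint64_t totalIds = 0;
  for (int g = 0; g < nGenes; ++g) {
    for (uint64_t v : geneVals[g]) {
      uint64_t r = bfRank.rankBefore(hashPos(v, m, seed64));
      std::vector<int>& L = lists[(size_t)r];
      if (L.empty() || L.back() != g) {
        L.push_back(g);
        ++totalIds;
      }
    }
  }

  // Phase 3: concatenate lists into I; P gets a 1 at each cumulative
  // list end (1s mark the end of each list).
  IntegerVector I((R_xlen_t)totalIds);
  uint64_t pbytes = (totalIds + 7) / 8;
  RawVector P((R_xlen_t)std::max<uint64_t>(pbytes, 1));
  Rbyte* pp = P.begin();
  uint64_t cum = 0;
  for (uint64_t r = 0; r < ell; ++r) {
    for (int g : lists[(size_t)r]) I[(R_xlen_t)cum++] = g;
    if (!lists[(size_t)r].empty()) setBit(pp, cum - 1);
  }

  return List::create(_["bloom"] = bf, _["boundary"] = P, _["geneIds"] = I,
                      _["onesCount"] = (double)ell,
                      _["nKmers"] = (double)totalIds);
}

// [[Rcpp::export(name = ".cpp_query")]]
List cpp_query(CharacterVector kmers, RawVector bf, double m_, int seed, int k,
               RawVector boundary, IntegerVector geneIds) {
  uint64_t m = (uint64_t)m_;
  uint64_t seed64 = (uint64_t)(int64_t)seed;
  BitRank bfRank;
  bfRank.init(bf.begin(), m);
  std::vector<uint64_t> selP =
      onesPositions(boundary.begin(), (uint64_t)geneIds.size());

  int n = kmers.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k)
      stop("query k-mer length (%d) does not match index k (%d)",
           (int)s.size(), k);
    uint64_t v = encodeCanonicalOrStop(s);
    uint64_t h = hashPos(v, m, seed64);
    if (!bfRank.get(h)) {
      out[i] = IntegerVector(0);
      continue;
    }
    uint64_t lo, hi;
    segmentBounds(bfRank, h, selP, lo, hi);
    IntegerVector seg((R_xlen_t)(hi - lo + 1));
    for (uint64_t j = lo; j <= hi; ++j) seg[(R_xlen_t)(j - lo)] = geneIds[(R_xlen_t)j];
    out[i] = seg;
  }
  return out;
}

// Scan a batch of reads against the index, accumulating per-gene shared-base
// counts with the (pos_g, card_g) recurrence: at a matching window starting
// at 0-based i, card_g += min(k, i + k - pos_g) and pos_g := i + k (pos_g is
// the exclusive end of the last covering window, initialised to -1).
// Returns parallel vectors (read 1-based, gene 0-based, card).
// [[Rcpp::export(name = ".cpp_classify")]]
List cpp_classify(CharacterVector seqs, CharacterVector quals, RawVector bf,
                  double m_, int seed, int k, RawVector boundary,
                  IntegerVector geneIds, int nGenes, int q) {
  uint64_t m = (uint64_t)m_;
  uint64_t seed64 = (uint64_t)(int64_t)seed;
  BitRank bfRank;
  bfRank.init(bf.begin(), m);
  std::vector<uint64_t> selP =
      onesPositions(boundary.begin(), (uint64_t)geneIds.size());

  bool haveQuals = quals.size() == seqs.size();
  // dense accumulators + touched list: O(hits) reset per read
  std::vector<int64_t> posArr((size_t)nGenes, -1);
  std::vector<int> cardArr((size_t)nGenes, 0);
  std::vector<int> touched;

  std::vector<int> outRead, outGene, outCard;
  std::vector<int> starts;
  std::vector<uint64_t> values;
  std::vector<int> qv;

  int n = seqs.size();
  for (int ri = 0; ri < n; ++ri) {
    std::string s = as<std::string>(seqs[ri]);
    const int* qp = nullptr;
    if (haveQuals && q > 0) {
      std::string qs = as<std::string>(quals[ri]);
      if (qs.size() > 0) {
        if (qs.size() != s.size())
          stop("read %d: quality length (%d) != sequence length (%d)", ri + 1,
               (int)qs.size(), (int)s.size());
        qv.resize(s.size());
        for (size_t j = 0; j < qs.size(); ++j) qv[j] = (int)qs[j] - 33;
        qp = qv.data();
      }
    }
    starts.clear();
    values.clear();
    collectCanonical(s.c_str(), (int)s.size(), qp, k, q, starts, values);

    for (size_t w = 0; w < starts.size(); ++w) {
      uint64_t h = hashPos(values[w], m, seed64);
      if (!bfRank.get(h)) continue;
      uint64_t lo, hi;
      segmentBounds(bfRank, h, selP, lo, hi);
      int64_t i = starts[w];
      for (uint64_t j = lo; j <= hi; ++j) {
        int g = geneIds[(R_xlen_t)j];
        if (cardArr[g] == 0 && posArr[g] == -1) touched.push_back(g);
        int64_t add = (int64_t)i + k - posArr[g];
        if (add > k) add = k;
        cardArr[g] += (int)add;
        posArr[g] = i + k;
      }
    }
    for (int g : touched) {
      outRead.push_back(ri + 1);
      outGene.push_back(g);
      outCard.push_back(cardArr[g]);
      cardArr[g] = 0;
      posArr[g] = -1;
    }
    touched.clear();
  }
  return List::create(_["read"] = wrap(outRead), _["gene"] = wrap(outGene),
                      _["card"] = wrap(outCard));
}

// [[Rcpp::export(name = ".cpp_rank1")]]
double cpp_rank1(RawVector bits, double nbits, double i) {
  uint64_t nb = (uint64_t)nbits;
  if (i < 1 || i > nbits + 1) stop("rank1: position out of range");
  BitRank r;
  r.init(bits.begin(), nb);
  return (double)r.rankBefore((uint64_t)i - 1);
}

// [[Rcpp::export(name = ".cpp_select1")]]
double cpp_select1(RawVector bits, double nbits, double j) {
  uint64_t nb = (uint64_t)nbits;
  if (j < 1) stop("select1: j must be >= 1");
  std::vector<uint64_t> pos = onesPositions(bits.begin(), nb);
  if ((uint64_t)j > pos.size())
    stop("select1: fewer than %d set bits", (int)j);
  return (double)(pos[(size_t)j - 1] + 1);  // 1-based position
}

// [[Rcpp::export(name = ".cpp_popcount")]]
double cpp_popcount(RawVector bits, double nbits) {
  BitRank r;
  r.init(bits.begin(), (uint64_t)nbits);
  return (double)r.total();
}
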