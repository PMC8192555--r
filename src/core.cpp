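#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Lehmer permutation modulus: smallest prime above 2^32, so every 32-bit
// FNV hash is a valid residue and any a in [1, mod) is invertible.
static const uint64_t LEHMER_MOD = 4294967311ULL;

static inline uint32_t fnv1a(const uint8_t* d, size_t n) {
  uint32_t h = 2166136261u;           // FNV-1a 32-bit offset basis
  for (size_t i = 0; i < n; ++i) {
    h ^= d[i];
    h *= 16777619u;                   // FNV 32-bit prime
  }
  return h;
}

// [[Rcpp::export(name = ".fnv1a_raw")]]
double fnv1a_raw(RawVector data) {
  return (double) fnv1a(data.length() ? RAW(data) : nullptr, data.length());
}

// (a * x + b) mod LEHMER_MOD, exact for a, b, x < mod via 128-bit product.
// [[Rcpp::export(name = ".lehmer_permute")]]
NumericVector lehmer_permute(NumericVector x, double a, double b) {
  R_xlen_t n = x.length();
  NumericVector out(n);
  uint64_t ua = (uint64_t) a, ub = (uint64_t) b;
  for (R_xlen_t i = 0; i < n; ++i) {
    unsigned __int128 v = (unsigned __int128) ua * (uint64_t) x[i] + ub;
    out[i] = (double) (uint64_t) (v % LEHMER_MOD);
  }
  return out;
}

// Positional shingle hashes for one slice.
// alleles: n_hap x n_snp 0/1 integer matrix; slice is [snp_start, snp_end],
// 1-based inclusive. Shingle j (0-based ordinal) covers `shingle_size` SNPs
// starting at snp_start + j*step. Hash input is a 4-byte little-endian
// ordinal followed by the alleles as ASCII '0'/'1'.
// Returns n_shingle x n_hap matrix of 32-bit FNV-1a values (as doubles).
// [[Rcpp::export(name = ".shingle_hash_matrix")]]
NumericMatrix shingle_hash_matrix(IntegerMatrix alleles, int snp_start,
                                  int snp_end, int shingle_size, int step) {
  int width = snp_end - snp_start + 1;
  if (width < shingle_size) stop("slice narrower than shingle_size");
  int n_sh = (width - shingle_size) / step + 1;
  int n_hap = alleles.nrow();
  NumericMatrix out(n_sh, n_hap);
  std::vector<uint8_t> buf(4 + (size_t) shingle_size);
  for (int h = 0; h < n_hap; ++h) {
    for (int j = 0; j < n_sh; ++j) {
      uint32_t ord = (uint32_t) j;
      buf[0] = ord & 0xFF; buf[1] = (ord >> 8) & 0xFF;
      buf[2] = (ord >> 16) & 0xFF; buf[3] = (ord >> 24) & 0xFF;
      int off = snp_start - 1 + j * step;
      for (int k = 0; k < shingle_size; ++k)
        buf[4 + k] = (uint8_t) ('0' + alleles(h, off + k));
      out(j, h) = (double) fnv1a(buf.data(), buf.size());
    }
  }
  return out;
}

// Minhash signatures: per permutation p, min over shingles of the Lehmer
// permutation (a_p * x + b_p) mod LEHMER_MOD.
// shingles: n_shingle x n_hap; returns n_perm x n_hap.
// [[Rcpp::export(name = ".minhash_matrix")]]
NumericMatrix minhash_matrix(NumericMatrix shingles, NumericVector a,
                             NumericVector b) {
  int n_sh = shingles.nrow(), n_hap = shingles.ncol(), n_perm = a.length();
  if (n_sh == 0) stop("empty shingle set");
  NumericMatrix out(n_perm, n_hap);
  for (int h = 0; h < n_hap; ++h) {
    for (int p = 0; p < n_perm; ++p) {
      uint64_t ua = (uint64_t) a[p], ub = (uint64_t) b[p];
      uint64_t best = UINT64_MAX;
      for (int j = 0; j < n_sh; ++j) {
        unsigned __int128 v =
          (unsigned __int128) ua * (uint64_t) shingles(j, h) + ub;
        uint64_t m = (uint64_t) (v % LEHMER_MOD);
        if (m < best) best = m;
      }
      out(p, h) = (double) best;
    }
  }
  return out;
}

// Banded LSH signatures: band i hashes its r consecutive minhash values,
// each serialized as 8 little-endian bytes (values may exceed 32 bits
// because the modulus is slightly above 2^32).
// minhash: n_perm x n_hap; returns bands x n_hap.
// [[Rcpp::export(name = ".band_hash_matrix")]]
NumericMatrix band_hash_matrix(NumericMatrix minhash, int bands) {
  int n_perm = minhash.nrow(), n_hap = minhash.ncol();
  if (n_perm % bands != 0) stop("perm_count not divisible by bucket_count");
  int r = n_perm / bands;
  NumericMatrix out(bands, n_hap);
  std::vector<uint8_t> buf(8 * (size_t) r);
  for (int h = 0; h < n_hap; ++h) {
    for (int b = 0; b < bands; ++b) {
      for (int k = 0; k < r; ++k) {
        uint64_t v = (uint64_t) minhash(b * r + k, h);
        for (int byte = 0; byte < 8; ++byte)
          buf[8 * k + byte] = (v >> (8 * byte)) & 0xFF;
      }
      out(b, h) = (double) fnv1a(buf.data(), buf.size());
    }
  }
  return out;
}

// Box-1 style outward extension with a per-side mismatch budget; the
// returned extent never starts or ends on a mismatching SNP.
// ha, hb: full 0/1 haplotype vectors; start/end 1-based inclusive.
// [[Rcpp::export(name = ".extend_bounds")]]
IntegerVector extend_bounds(IntegerVector ha, IntegerVector hb, int start,
                            int end, int max_error) {
  int n = ha.length();
  int s = start, e = end, errs;
  errs = 0;
  for (int i = start - 1; i >= 1; --i) {
    if (ha[i - 1] == hb[i - 1]) s = i;
    else if (++errs > max_error) break;
  }
  errs = 0;
  for (int i = end + 1; i <= n; ++i) {
    if (ha[i - 1] == hb[i - 1]) e = i;
    else if (++errs > max_error) break;
  }
  return IntegerVector::create(s, e);
}
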