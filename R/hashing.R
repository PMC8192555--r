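# Shingling, FNV hashing, Lehmer-permutation minhash and LSH banding — the
# per-slice machinery that turns haplotype bits into candidate pairs.

LEHMER_MODULUS <- 4294967311  # smallest prime above 2^32

# evaluate expr under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

#' Hashing and LSH banding parameters
#'
#' Bundles the shingling geometry (`shingle_size` SNPs per k-mer,
#' `shingle_overlap` SNPs shared by consecutive k-mers), the minhash size
#' (`perm_count` permutations, realised as Lehmer maps
#' `(a x + b) mod 4294967311` over 32-bit FNV shingle hashes) and the LSH
#' banding (`bucket_count` bands of `r = perm_count / bucket_count` values).
#' Coefficients `a` (nonzero, hence invertible modulo the prime) and `b` are
#' drawn reproducibly from `seed`. Defaults follow the published
#' array-data settings: 20-SNP shingles, 20 permutations in 5 bands.
#'
#' @param shingle_size SNPs per shingle.
#' @param shingle_overlap SNPs of overlap between consecutive shingles
#'   (less than `shingle_size`).
#' @param perm_count Number of minhash permutations; must be divisible by
#'   `bucket_count`.
#' @param bucket_count Number of LSH bands.
#' @param seed Seed for the coefficient draws.
#' @return An object of class `hash_params`.
#' @export
hash_params <- function(shingle_size = 20, shingle_overlap = 0,
                        perm_count = 20, bucket_count = 5, seed = 1) {
  if (shingle_overlap < 0 || shingle_overlap >= shingle_size)
    stop("shingle_overlap must satisfy 0 <= shingle_overlap < shingle_size")
  if (perm_count %% bucket_count != 0)
    stop(sprintf("perm_count (%d) must be divisible by bucket_count (%d)",
                 perm_count, bucket_count))
  coeffs <- with_seed(seed, list(
    a = floor(stats::runif(perm_count, 1, LEHMER_MODULUS)),
    b = floor(stats::runif(perm_count, 0, LEHMER_MODULUS))))
  structure(list(shingle_size = as.integer(shingle_size),
                 shingle_overlap = as.integer(shingle_overlap),
                 perm_count = as.integer(perm_count),
                 bucket_count = as.integer(bucket_count),
                 r = as.integer(perm_count %/% bucket_count),
                 coeff_a = coeffs$a, coeff_b = coeffs$b,
                 modulus = LEHMER_MODULUS, seed = seed),
            class = "hash_params")
}

#' @export
print.hash_params <- function(x, ...) {
  cat(sprintf(paste0("Hash parameters: %d-SNP shingles (overlap %d), ",
                     "%d permutations in %d bands of %d (seed %s)\n"),
              x$shingle_size, x$shingle_overlap, x$perm_count,
              x$bucket_count, x$r, format(x$seed)))
  invisible(x)
}

#' FNV-1a 32-bit hash
#'
#' @param x A raw vector, or a single string hashed as its ASCII bytes.
#' @return The 32-bit FNV-1a digest as a double (values may exceed
#'   `.Machine$integer.max`).
#' @export
fnv_hash <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("character input must be a single string")
    x <- charToRaw(x)
  }
  if (!is.raw(x)) stop("x must be a raw vector or a single string")
  .fnv1a_raw(x)
}

#' Lehmer permutation of 32-bit hash indices
#'
#' Maps a shingle-hash index `x` to `(a x + b) mod 4294967311`, the random
#' permutation used to realise minhash without materialising permutation
#' tables. With `a != 0` the map is a bijection of the residues because the
#' modulus is prime.
#'
#' @param x Vector of indices in `[0, 4294967311)`.
#' @param a,b Permutation coefficients, `a` in `[1, 4294967311)`, `b` in
#'   `[0, 4294967311)`.
#' @return The permuted indices (doubles).
#' @export
permute_index <- function(x, a, b) {
  if (a < 1 || a >= LEHMER_MODULUS || b < 0 || b >= LEHMER_MODULUS)
    stop("coefficients out of range")
  if (any(x < 0 | x >= LEHMER_MODULUS)) stop("x out of range")
  .lehmer_permute(as.numeric(x), a, b)
}

#' Jaccard similarity of two sets
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return `|A intersect B| / |A union B|`; two empty sets are flagged with
#'   a warning and scored 1 (identical emptiness).
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) {
    warning("both sets empty; Jaccard similarity defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Shingle a slice of a panel into positional k-mer hashes
#'
#' Within the slice, shingle `j` (0-based ordinal) covers `shingle_size`
#' SNPs starting at offset `j * (shingle_size - shingle_overlap)`; trailing
#' SNPs that do not fill a shingle are ignored. Each shingle is hashed with
#' FNV-1a over the 4-byte little-endian ordinal followed by the alleles as
#' ASCII `'0'`/`'1'` — the ordinal prefix makes shingling positional, so an
#' identical k-mer at a different offset is a different set element (IBD is
#' positional; a pure content set would score shuffled slices as matches).
#'
#' @param panel A [haplotype_panel()].
#' @param slice One row of the [compute_slices()] table (or any list with
#'   `snp_start`, `snp_end`, `skipped`).
#' @param params A [hash_params()].
#' @return An `n_shingles x n_haplotypes` numeric matrix of 32-bit hashes;
#'   each column is that haplotype's shingle set (columns carry `hap_ids`
#'   as names).
#' @export
tokenize_slice <- function(panel, slice, params) {
  if (isTRUE(slice$skipped)) stop("cannot tokenize a skipped slice")
  width <- slice$snp_end - slice$snp_start + 1L
  if (width < params$shingle_size)
    stop(sprintf("slice of %d SNPs narrower than shingle_size %d",
                 width, params$shingle_size))
  step <- params$shingle_size - params$shingle_overlap
  out <- .shingle_hash_matrix(panel$alleles, as.integer(slice$snp_start),
                              as.integer(slice$snp_end),
                              params$shingle_size, step)
  colnames(out) <- panel$hap_ids
  out
}

#' Minhash signatures for tokenized slice content
#'
#' For permutation `p`, the signature component is the minimum of the
#' Lehmer-permuted shingle hashes — the position of the first of the
#' haplotype's shingles under that random permutation of the 32-bit hash
#' space. Two haplotypes agree on a component with probability equal to the
#' Jaccard similarity of their shingle sets.
#'
#' @param shingles Matrix from [tokenize_slice()] (shingles x haplotypes).
#' @param params A [hash_params()].
#' @return A `perm_count x n_haplotypes` numeric matrix of signature values.
#' @export
minhash_signatures <- function(shingles, params) {
  out <- .minhash_matrix(shingles, params$coeff_a, params$coeff_b)
  colnames(out) <- colnames(shingles)
  out
}

#' Banded LSH signatures from minhash signatures
#'
#' Groups the `perm_count` minhash values into `bucket_count` bands of `r`
#' consecutive values and hashes each band (FNV-1a over the values
#' serialized as fixed-width 8-byte little-endian integers). Two haplotypes
#' with slice Jaccard similarity `s` share at least one band hash with
#' probability [hit_probability()]`(s, r, b)`.
#'
#' @param sig Matrix from [minhash_signatures()].
#' @param params A [hash_params()].
#' @return A `bucket_count x n_haplotypes` numeric matrix of band hashes.
#' @export
band_signatures <- function(sig, params) {
  if (nrow(sig) != params$perm_count)
    stop(sprintf("signature has %d values but perm_count is %d",
                 nrow(sig), params$perm_count))
  out <- .band_hash_matrix(sig, params$bucket_count)
  colnames(out) <- colnames(sig)
  out
}

#' LSH band-collision probability
#'
#' Probability that two sets with Jaccard similarity `s` agree on at least
#' one of `b` bands of `r` minhash values: `1 - (1 - s^r)^b`. This logistic
#' step function is what the banding parameters tune: steepness around the
#' match threshold trades retrieval probability against candidate volume.
#'
#' @param s Jaccard similarity in `[0, 1]` (vectorised).
#' @param r Minhash values per band.
#' @param b Number of bands.
#' @return The collision probability.
#' @export
hit_probability <- function(s, r, b) {
  stopifnot(all(s >= 0 & s <= 1), r >= 1, b >= 1)
  1 - (1 - s^r)^b
}

#' Minhash value of a set under an explicit permutation
#'
#' The conceptual definition of minhash: the 1-based position, in the
#' permuted universe ordering, of the first element the set contains.
#' The production pipeline realises the same quantity with Lehmer maps over
#' hashed shingles; this explicit form exists for exposition and testing.
#'
#' @param set Vector of set elements.
#' @param permutation Vector giving the permuted ordering of the universe.
#' @return The 1-based index of the first element of `permutation` present
#'   in `set`.
#' @export
minhash_index <- function(set, permutation) {
  pos <- which(permutation %in% set)
  if (length(pos) == 0L) stop("set has no element in the permuted universe")
  pos[1]
}
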