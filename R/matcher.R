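# Candidate generation: group haplotypes sharing LSH band hashes within a
# slice, estimate slice similarity from the resident minhash signatures,
# and classify against the match / interest thresholds.

#' Build per-band hash tables for one slice
#'
#' @param bands Band-hash matrix from [band_signatures()] (bands x
#'   haplotypes).
#' @return A list with one element per band, each a named list mapping a
#'   band-hash value to the integer haplotype ordinals holding it (only
#'   hashes held by more than one haplotype are kept — singletons can never
#'   seed a candidate).
#' @export
build_band_tables <- function(bands) {
  n_hap <- ncol(bands)
  lapply(seq_len(nrow(bands)), function(b) {
    groups <- split(seq_len(n_hap), bands[b, ])
    groups[lengths(groups) > 1L]
  })
}

#' Collect candidate pairs from band tables
#'
#' Every unordered haplotype pair co-occurring under at least one band hash
#' becomes one candidate with `band_hits` equal to the number of bands on
#' which the pair collides. Pairs of haplotypes belonging to the same
#' sample are excluded unless `allow_within_sample` (runs of homozygosity
#' are a different analysis).
#'
#' @param tables Output of [build_band_tables()].
#' @param hap_ids Haplotype identifiers (ordinals index into this).
#' @param slice_index Slice ordinal the tables belong to.
#' @param allow_within_sample Keep pairs from the same diploid sample?
#' @return A data frame `slice_index, hap_a, hap_b, band_hits` with
#'   `hap_a < hap_b` (ordinals), sorted by `(hap_a, hap_b)`.
#' @export
collect_candidates <- function(tables, hap_ids, slice_index,
                               allow_within_sample = FALSE) {
  pair_a <- integer(0)
  pair_b <- integer(0)
  for (band in tables) {
    for (grp in band) {
      pr <- utils::combn(grp, 2L)
      pair_a <- c(pair_a, pr[1L, ])
      pair_b <- c(pair_b, pr[2L, ])
    }
  }
  empty <- data.frame(slice_index = integer(), hap_a = integer(),
                      hap_b = integer(), band_hits = integer())
  if (length(pair_a) == 0L) return(empty)
  a <- pmin(pair_a, pair_b)
  b <- pmax(pair_a, pair_b)
  if (!allow_within_sample) {
    keep <- hap_sample(hap_ids[a]) != hap_sample(hap_ids[b])
    a <- a[keep]
    b <- b[keep]
  }
  if (length(a) == 0L) return(empty)
  key <- a * (length(hap_ids) + 1) + b
  hits <- table(key)
  first <- !duplicated(key)
  a <- a[first]
  b <- b[first]
  band_hits <- as.integer(hits[as.character(a * (length(hap_ids) + 1) + b)])
  ord <- order(a, b)
  data.frame(slice_index = slice_index, hap_a = a[ord], hap_b = b[ord],
             band_hits = band_hits[ord])
}

#' Estimate slice Jaccard similarity for candidate pairs
#'
#' The default estimator is the fraction of equal components across the two
#' stored minhash signatures — unbiased for the Jaccard similarity with
#' binomial variance `s(1-s)/perm_count`. The alternative `"band_hits"`
#' estimator inverts the band-collision count through the banding curve
#' (`(hits/b)^(1/r)`), a coarser lower-bound style estimate that needs no
#' signature storage.
#'
#' @param candidates Data frame from [collect_candidates()].
#' @param sig Minhash signature matrix for the slice (perms x haplotypes).
#' @param params A [hash_params()] (used by the `"band_hits"` estimator).
#' @param method `"minhash"` (default) or `"band_hits"`.
#' @return `candidates` with an `est_similarity` column appended.
#' @export
estimate_similarity <- function(candidates, sig, params,
                                method = c("minhash", "band_hits")) {
  method <- match.arg(method)
  if (nrow(candidates) == 0L) {
    candidates$est_similarity <- numeric(0)
    return(candidates)
  }
  if (method == "minhash") {
    eq <- sig[, candidates$hap_a, drop = FALSE] ==
      sig[, candidates$hap_b, drop = FALSE]
    candidates$est_similarity <- colMeans(eq)
  } else {
    candidates$est_similarity <-
      (candidates$band_hits / params$bucket_count)^(1 / params$r)
  }
  candidates
}

#' Classify candidates against the match / interest thresholds
#'
#' A candidate at or above the match threshold `MT` is declared a slice
#' match outright (its full slice extent enters extension); one at or above
#' the interest threshold `IT` but below `MT` is marked for shingle-level
#' boundary refinement; the rest are rejected and never reach extension.
#'
#' The thresholds are expressed on the *shared-fraction* scale — the
#' fraction of a slice's shingles the pair has in common — which is the
#' scale on which a slice half-covered by a true IBD tract scores 50%.
#' The union-based Jaccard estimate `s` in `est_similarity` is converted
#' via `2s / (1 + s)` (exact for equal-size shingle sets) before the
#' comparison, so e.g. `IT = 0.70` admits slices where at least ~70% of
#' the shingles match, i.e. Jaccard above ~0.54.
#'
#' @param candidates Data frame with an `est_similarity` column (Jaccard
#'   scale).
#' @param match_threshold,interest_threshold Thresholds with
#'   `0 <= IT <= MT <= 1`, on the shared-fraction scale.
#' @return `candidates` with a `status` factor column
#'   (`match`/`interest`/`reject`).
#' @export
classify_candidates <- function(candidates, match_threshold = 0.99,
                                interest_threshold = 0.70) {
  if (interest_threshold > match_threshold)
    stop("interest_threshold must not exceed match_threshold")
  if (match_threshold > 1 || interest_threshold < 0)
    stop("thresholds must lie in [0, 1]")
  s <- 2 * candidates$est_similarity / (1 + candidates$est_similarity)
  status <- rep("reject", length(s))
  status[s >= interest_threshold] <- "interest"
  status[s >= match_threshold] <- "match"
  candidates$status <- factor(status, levels = c("match", "interest",
                                                 "reject"))
  candidates
}
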