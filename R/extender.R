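# From slice-level matches to maximal IBD segments: shingle-level boundary
# refinement inside interest slices, merging of adjacent matched slices,
# and SNP-by-SNP outward extension.

# maximal mismatch-free intervals of a haplotype pair, as a 2-column matrix
# (start, end), 1-based inclusive
identical_runs <- function(ha, hb) {
  mm <- which(ha != hb)
  starts <- c(1L, mm + 1L)
  ends <- c(mm - 1L, length(ha))
  keep <- ends >= starts
  cbind(start = starts[keep], end = ends[keep])
}

#' Refine an interest-level candidate to its matching shingle run
#'
#' A candidate below the match threshold but above the interest threshold
#' is inspected shingle by shingle: the longest run of consecutive shingles
#' on which the two haplotypes carry identical alleles is converted to a
#' SNP extent (the likely IBD boundary runs through this slice).
#'
#' @param panel A [haplotype_panel()].
#' @param hap_a,hap_b Haplotype ordinals.
#' @param slice One row of the [compute_slices()] table.
#' @param params A [hash_params()].
#' @return `c(snp_start, snp_end)` (1-based inclusive) of the longest
#'   equal-shingle run, or `NULL` when no shingle matches.
#' @export
refine_interest <- function(panel, hap_a, hap_b, slice, params) {
  size <- params$shingle_size
  step <- size - params$shingle_overlap
  lo <- slice$snp_start
  hi <- slice$snp_end
  n_sh <- (hi - lo + 1L - size) %/% step + 1L
  ha <- panel$alleles[hap_a, lo:hi]
  hb <- panel$alleles[hap_b, lo:hi]
  mm_cum <- c(0L, cumsum(ha != hb))
  j <- seq_len(n_sh)
  w_start <- (j - 1L) * step + 1L
  eq <- (mm_cum[w_start + size] - mm_cum[w_start]) == 0L
  if (!any(eq)) return(NULL)
  runs <- rle(eq)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  j1 <- run_start[best]
  j2 <- run_end[best]
  c(lo + (j1 - 1L) * step, lo + (j2 - 1L) * step + size - 1L)
}

#' Merge accepted slice extents into maximal runs per haplotype pair
#'
#' Accepted extents (full slices for matches, refined sub-extents for
#' interest candidates) belonging to one haplotype pair are sorted by
#' position and merged whenever they overlap or abut — overlapping slices
#' both matching one physical tract collapse to a single run, and adjacent
#' matched slices chain into one long segment seed.
#'
#' @param extents Data frame with columns `hap_a`, `hap_b`, `snp_start`,
#'   `snp_end`, `est_similarity` (one row per accepted slice extent).
#' @return A data frame of runs (`hap_a`, `hap_b`, `snp_start`, `snp_end`,
#'   `sim` = minimum estimated similarity over the merged extents).
#' @export
merge_runs <- function(extents) {
  if (nrow(extents) == 0L)
    return(data.frame(hap_a = integer(), hap_b = integer(),
                      snp_start = integer(), snp_end = integer(),
                      sim = numeric()))
  ord <- order(extents$hap_a, extents$hap_b, extents$snp_start)
  extents <- extents[ord, , drop = FALSE]
  new_pair <- c(TRUE, diff(extents$hap_a) != 0 | diff(extents$hap_b) != 0)
  # running maximum of snp_end within each pair block
  run_id <- integer(nrow(extents))
  cur_end <- -1L
  rid <- 0L
  for (i in seq_len(nrow(extents))) {
    if (new_pair[i] || extents$snp_start[i] > cur_end + 1L) {
      rid <- rid + 1L
      cur_end <- extents$snp_end[i]
    } else {
      cur_end <- max(cur_end, extents$snp_end[i])
    }
    run_id[i] <- rid
  }
  data.frame(
    hap_a = tapply(extents$hap_a, run_id, `[`, 1L),
    hap_b = tapply(extents$hap_b, run_id, `[`, 1L),
    snp_start = as.integer(tapply(extents$snp_start, run_id, min)),
    snp_end = as.integer(tapply(extents$snp_end, run_id, max)),
    sim = as.numeric(tapply(extents$est_similarity, run_id, min)),
    row.names = NULL)
}

#' Extend a run SNP-by-SNP to its maximal extent
#'
#' With `max_error = 0` the pair's mismatch positions partition the
#' chromosome into maximal identical runs, and the seed extent expands to
#' every identical run it intersects (normally exactly one; a seed that
#' straddles a stray mismatch — possible because the match threshold is
#' estimated from minhash components — is split rather than allowed to emit
#' a discordant segment). With `max_error > 0` the boundary walks outward
#' tolerating up to that many mismatching SNPs per side, never ending on a
#' mismatch.
#'
#' @param run One row of the [merge_runs()] output (list-like with
#'   `hap_a`, `hap_b`, `snp_start`, `snp_end`, `sim`).
#' @param panel A [haplotype_panel()].
#' @param max_error Per-side mismatch budget.
#' @return A data frame of extended runs (one row, or several when a
#'   zero-error seed is split).
#' @export
extend_boundaries <- function(run, panel, max_error = 0) {
  ha <- panel$alleles[run$hap_a, ]
  hb <- panel$alleles[run$hap_b, ]
  if (max_error == 0) {
    runs <- identical_runs(ha, hb)
    hit <- runs[, "start"] <= run$snp_end & runs[, "end"] >= run$snp_start
    runs <- runs[hit, , drop = FALSE]
    if (nrow(runs) == 0L)
      return(data.frame(hap_a = integer(), hap_b = integer(),
                        snp_start = integer(), snp_end = integer(),
                        sim = numeric()))
    data.frame(hap_a = run$hap_a, hap_b = run$hap_b,
               snp_start = runs[, "start"], snp_end = runs[, "end"],
               sim = run$sim)
  } else {
    ext <- .extend_bounds(ha, hb, run$snp_start, run$snp_end,
                          as.integer(max_error))
    data.frame(hap_a = run$hap_a, hap_b = run$hap_b, snp_start = ext[1],
               snp_end = ext[2], sim = run$sim)
  }
}

# batch extension: one mismatch scan per haplotype pair, all its seeds
# resolved against the same identical-run decomposition
extend_all <- function(runs, panel, max_error = 0) {
  if (nrow(runs) == 0L) return(runs)
  grp <- split(seq_len(nrow(runs)), paste(runs$hap_a, runs$hap_b))
  out <- lapply(grp, function(idx) {
    one <- runs[idx, , drop = FALSE]
    if (max_error == 0) {
      iv <- identical_runs(panel$alleles[one$hap_a[1], ],
                           panel$alleles[one$hap_b[1], ])
      hits <- lapply(seq_len(nrow(one)), function(i)
        which(iv[, "start"] <= one$snp_end[i] &
                iv[, "end"] >= one$snp_start[i]))
      n_hit <- lengths(hits)
      if (sum(n_hit) == 0L) return(NULL)
      src <- rep(seq_len(nrow(one)), n_hit)
      sel <- unlist(hits)
      data.frame(hap_a = one$hap_a[src], hap_b = one$hap_b[src],
                 snp_start = iv[sel, "start"], snp_end = iv[sel, "end"],
                 sim = one$sim[src])
    } else {
      do.call(rbind, lapply(seq_len(nrow(one)), function(i)
        extend_boundaries(one[i, ], panel, max_error)))
    }
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) runs[0, , drop = FALSE] else out
}

#' Convert extended runs to reported IBD segments
#'
#' Deduplicates identical (pair, extent) runs — overlapping slices can seed
#' one physical tract several times — drops runs shorter than
#' `min_length_cm`, and recomputes similarity exactly as the fraction of
#' equal alleles over the extent (1.0 by construction when `max_error = 0`).
#' Haplotype identifiers are ordered lexicographically within each pair.
#'
#' @param runs Data frame of extended runs.
#' @param panel A [haplotype_panel()].
#' @param min_length_cm Minimum reportable genetic length.
#' @return A segment table (`id_a`, `id_b`, `snp_start`, `snp_end`,
#'   `bp_start`, `bp_end`, `n_snps`, `cm_length`, `similarity`), sorted by
#'   `(id_a, id_b, bp_start)`.
#' @export
finalize_segments <- function(runs, panel, min_length_cm = 3) {
  map <- panel$map
  if (nrow(runs) == 0L) return(empty_segments())
  key <- paste(runs$hap_a, runs$hap_b, runs$snp_start, runs$snp_end)
  runs <- runs[!duplicated(key), , drop = FALSE]
  cm_length <- map$cm[runs$snp_end] - map$cm[runs$snp_start]
  keep <- cm_length >= min_length_cm
  runs <- runs[keep, , drop = FALSE]
  cm_length <- cm_length[keep]
  if (nrow(runs) == 0L) return(empty_segments())
  sim <- vapply(seq_len(nrow(runs)), function(i) {
    ext <- runs$snp_start[i]:runs$snp_end[i]
    mean(panel$alleles[runs$hap_a[i], ext] ==
           panel$alleles[runs$hap_b[i], ext])
  }, 0)
  ida <- panel$hap_ids[runs$hap_a]
  idb <- panel$hap_ids[runs$hap_b]
  swap <- ida > idb
  tmp <- ida[swap]; ida[swap] <- idb[swap]; idb[swap] <- tmp
  sort_segments(data.frame(
    id_a = ida, id_b = idb,
    snp_start = runs$snp_start, snp_end = runs$snp_end,
    bp_start = map$bp[runs$snp_start], bp_end = map$bp[runs$snp_end],
    n_snps = runs$snp_end - runs$snp_start + 1L,
    cm_length = cm_length, similarity = sim,
    stringsAsFactors = FALSE))
}
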