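# Brute-force reference scanner: enumerates, for every haplotype pair, the
# maximal mismatch-free runs and reports those at least min_cm long. It is
# quadratic in haplotypes and shares no code path with the LSH pipeline, so
# it serves as the independent ground truth on small panels.

#' Exhaustive all-pairs IBD scan (reference implementation)
#'
#' For every unordered haplotype pair, finds all maximal runs of identical
#' alleles and reports those of genetic length at least `min_cm`. The scan
#' is exact and deterministic but quadratic in the number of haplotypes —
#' intended for validating the hash-based detector on small panels, not
#' for production use.
#'
#' @param panel A [haplotype_panel()].
#' @param min_cm Minimum genetic length to report.
#' @param allow_within_sample Include the two haplotypes of one sample?
#' @return A segment table in the same layout as [detect_ibd()] output.
#' @export
scan_ibd_exhaustive <- function(panel, min_cm = 3,
                                allow_within_sample = FALSE) {
  n <- nrow(panel$alleles)
  cm <- panel$map$cm
  samples <- hap_sample(panel$hap_ids)
  found <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!allow_within_sample && samples[i] == samples[j]) next
      runs <- identical_runs(panel$alleles[i, ], panel$alleles[j, ])
      if (nrow(runs) == 0L) next
      len <- cm[runs[, "end"]] - cm[runs[, "start"]]
      keep <- len >= min_cm
      if (!any(keep)) next
      k <- k + 1L
      found[[k]] <- data.frame(hap_a = i, hap_b = j,
                               snp_start = runs[keep, "start"],
                               snp_end = runs[keep, "end"], sim = 1)
    }
  }
  if (k == 0L) return(empty_segments())
  finalize_segments(do.call(rbind, found), panel, min_cm)
}
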