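# Dynamic slicing: fixed-boundary genetic-distance windows shared by all
# haplotypes, the unit on which the LSH machinery operates.

#' Partition a genetic map into fixed-boundary slices
#'
#' Dynamic slicing cuts the chromosome into windows of `slice_cm`
#' centimorgans; consecutive windows overlap by `cm_overlap`, i.e. window
#' `i` spans `[i * (slice_cm - cm_overlap), i * (slice_cm - cm_overlap) +
#' slice_cm)` relative to the first SNP. The overlap guarantees that an IBD
#' tract at least as long as `slice_cm` always has a window covering most of
#' it, so its slice-level Jaccard similarity stays high. Windows holding
#' fewer than `min_snp_count` SNPs — low array density usually marks a
#' low-complexity region that breeds false positives — are retained but
#' flagged `skipped` so downstream stages never seed matches inside them
#' while slice indices stay contiguous. The trailing partial window is
#' emitted subject to the same SNP floor.
#'
#' With `static_snp_count` set, fixed-size SNP-count slices (no overlap) are
#' produced instead.
#'
#' @param map A [genetic_map()].
#' @param slice_cm Slice genetic length in cM (default 3, close to the
#'   usual minimum reportable IBD length).
#' @param cm_overlap Overlap between consecutive slices in cM; must be
#'   strictly less than `slice_cm`.
#' @param min_snp_count Minimum SNPs a slice needs to participate.
#' @param static_snp_count If non-`NULL`, use static slices of this many
#'   SNPs instead of genetic-distance windows.
#' @return A data frame with one row per slice: `index`, `snp_start`,
#'   `snp_end` (1-based inclusive), `cm_start`, `cm_end`, `n_snps`,
#'   `skipped`.
#' @export
compute_slices <- function(map, slice_cm = 3, cm_overlap = 1.4,
                           min_snp_count = 50, static_snp_count = NULL) {
  if (min_snp_count < 1) stop("min_snp_count must be >= 1")
  if (!is.null(static_snp_count)) {
    m <- length(map)
    starts <- seq(1L, m, by = as.integer(static_snp_count))
    ends <- pmin(starts + as.integer(static_snp_count) - 1L, m)
    n_snps <- ends - starts + 1L
    return(data.frame(index = seq_along(starts), snp_start = starts,
                      snp_end = ends, cm_start = map$cm[starts],
                      cm_end = map$cm[ends], n_snps = n_snps,
                      skipped = n_snps < min_snp_count))
  }
  if (cm_overlap < 0 || cm_overlap >= slice_cm)
    stop("cm_overlap must satisfy 0 <= cm_overlap < slice_cm")
  cm <- map$cm
  cm0 <- cm[1]
  span <- cm[length(cm)] - cm0
  stride <- slice_cm - cm_overlap
  tol <- 1e-9
  n_slices <- floor(span / stride + tol) + 1L
  i <- seq_len(n_slices) - 1L
  cm_start <- cm0 + i * stride
  cm_end <- cm_start + slice_cm
  # half-open [cm_start, cm_end) membership with a tolerance so boundary
  # SNPs land deterministically despite binary rounding of the stride
  first <- findInterval(cm_start - tol, cm, left.open = TRUE) + 1L
  last <- findInterval(cm_end - tol, cm, left.open = TRUE)
  n_snps <- pmax(last - first + 1L, 0L)
  data.frame(index = seq_len(n_slices), snp_start = first, snp_end = last,
             cm_start = cm_start, cm_end = cm_end, n_snps = n_snps,
             skipped = n_snps < min_snp_count)
}
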