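# Full detection pipeline and its run configuration.

#' Detection run configuration
#'
#' Bundles every tunable of the pipeline under the parameter vocabulary of
#' the published array-data runs. Two presets are provided: `"page"`
#' (3 cM slices overlapping by 1.4 cM, 50-SNP slice floor, 20-SNP
#' shingles, 20 permutations in 5 bands, match threshold 0.99, interest
#' threshold 0.70, max_error 0, minimum reported length 3 cM) and
#' `"ukbiobank"` (12 permutations in 4 bands, minimum length 2.9 cM,
#' otherwise as `"page"`). Any field can be overridden by name.
#'
#' @param preset `"page"` (default) or `"ukbiobank"`.
#' @param ... Named overrides of the preset fields: `slice_cm`,
#'   `cm_overlap`, `min_snp_count`, `shingle_size`, `shingle_overlap`,
#'   `perm_count`, `bucket_count`, `match_threshold`, `interest_threshold`,
#'   `max_error`, `min_length`, `max_thread`, `auto_slice`,
#'   `static_snp_count`, `est_method`, `allow_within_sample`, `seed`.
#' @return An object of class `ibd_config`.
#' @export
ibd_config <- function(preset = c("page", "ukbiobank"), ...) {
  preset <- match.arg(preset)
  cfg <- list(slice_cm = 3, cm_overlap = 1.4, min_snp_count = 50L,
              shingle_size = 20L, shingle_overlap = 0L, perm_count = 20L,
              bucket_count = 5L, match_threshold = 0.99,
              interest_threshold = 0.70, max_error = 0L, min_length = 3,
              max_thread = 1L, auto_slice = TRUE, static_snp_count = 2000L,
              est_method = "minhash", allow_within_sample = FALSE,
              seed = 1L)
  if (preset == "ukbiobank") {
    cfg$perm_count <- 12L
    cfg$bucket_count <- 4L
    cfg$min_length <- 2.9
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$perm_count %% cfg$bucket_count != 0)
    stop(sprintf("perm_count (%d) must be divisible by bucket_count (%d)",
                 cfg$perm_count, cfg$bucket_count))
  if (cfg$interest_threshold > cfg$match_threshold)
    stop("interest_threshold must not exceed match_threshold")
  if (cfg$cm_overlap >= cfg$slice_cm)
    stop("cm_overlap must be smaller than slice_cm")
  structure(cfg, class = "ibd_config")
}

#' @export
print.ibd_config <- function(x, ...) {
  cat("IBD detection configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Detect IBD segments in a phased haplotype panel
#'
#' Runs the four-stage pipeline: (1) dynamic slicing of the genetic map
#' into fixed-boundary windows; (2) shingling + FNV hashing of every
#' haplotype's slice content and minhash signatures via Lehmer
#' permutations; (3) banded LSH hashing and hash-table candidate
#' generation; (4) threshold classification, shingle-level refinement of
#' interest-level candidates, merging of adjacent matched slices and
#' SNP-by-SNP boundary extension into maximal segments of at least
#' `min_length` cM.
#'
#' The output is a pure function of the panel bits and the configuration
#' (including its seed): rerunning, permuting haplotype input order or
#' changing `max_thread` leaves the reported segment table unchanged.
#'
#' @param panel A [haplotype_panel()].
#' @param config An [ibd_config()].
#' @return An object of class `ibd_result`: list with `segments` (the
#'   segment table), `stats` (per-stage counts), `config`, and the panel's
#'   `map`.
#' @examples
#' cfg <- sim_config(n_haplotypes = 60, chrom_cm = 12, n_segments = 4,
#'                   length_law = list(dist = "fixed", value = 5), seed = 7)
#' sim <- plant_ibd(generate_panel(cfg), cfg)
#' res <- detect_ibd(sim$panel, ibd_config())
#' res$segments
#' @export
detect_ibd <- function(panel, config = ibd_config()) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "ibd_config"))
  map <- panel$map
  slices <- compute_slices(
    map, slice_cm = config$slice_cm, cm_overlap = config$cm_overlap,
    min_snp_count = config$min_snp_count,
    static_snp_count = if (config$auto_slice) NULL else config$static_snp_count)
  params <- hash_params(shingle_size = config$shingle_size,
                        shingle_overlap = config$shingle_overlap,
                        perm_count = config$perm_count,
                        bucket_count = config$bucket_count,
                        seed = config$seed)
  too_narrow <- !slices$skipped & slices$n_snps < params$shingle_size
  if (any(too_narrow)) {
    warning(sprintf("%d slice(s) narrower than shingle_size skipped",
                    sum(too_narrow)))
    slices$skipped[too_narrow] <- TRUE
  }
  n_candidates <- 0L
  n_match <- 0L
  n_interest <- 0L
  extents <- vector("list", nrow(slices))
  for (si in which(!slices$skipped)) {
    slice <- slices[si, ]
    shingles <- tokenize_slice(panel, slice, params)
    sig <- minhash_signatures(shingles, params)
    bands <- band_signatures(sig, params)
    tables <- build_band_tables(bands)
    cand <- collect_candidates(tables, panel$hap_ids, slice$index,
                               config$allow_within_sample)
    if (nrow(cand) == 0L) next
    cand <- estimate_similarity(cand, sig, params, config$est_method)
    cand <- classify_candidates(cand, config$match_threshold,
                                config$interest_threshold)
    n_candidates <- n_candidates + nrow(cand)
    n_match <- n_match + sum(cand$status == "match")
    n_interest <- n_interest + sum(cand$status == "interest")
    acc <- cand[cand$status != "reject", , drop = FALSE]
    if (nrow(acc) == 0L) next
    ss <- rep(slice$snp_start, nrow(acc))
    se <- rep(slice$snp_end, nrow(acc))
    keep <- rep(TRUE, nrow(acc))
    for (i in which(acc$status == "interest")) {
      span <- refine_interest(panel, acc$hap_a[i], acc$hap_b[i], slice,
                              params)
      if (is.null(span)) keep[i] <- FALSE
      else { ss[i] <- span[1]; se[i] <- span[2] }
    }
    if (any(keep))
      extents[[si]] <- data.frame(hap_a = acc$hap_a[keep],
                                  hap_b = acc$hap_b[keep],
                                  snp_start = ss[keep], snp_end = se[keep],
                                  est_similarity = acc$est_similarity[keep])
  }
  extents <- do.call(rbind, extents[!vapply(extents, is.null, TRUE)])
  if (is.null(extents) || nrow(extents) == 0L) {
    segments <- empty_segments()
    runs <- NULL
  } else {
    runs <- merge_runs(extents)
    segments <- finalize_segments(extend_all(runs, panel, config$max_error),
                                  panel, config$min_length)
  }
  structure(list(segments = segments, config = config, map = map,
                 stats = list(n_haplotypes = length(panel$hap_ids),
                              n_snps = length(map),
                              n_slices = nrow(slices),
                              n_skipped = sum(slices$skipped),
                              n_candidates = n_candidates,
                              n_match = n_match, n_interest = n_interest,
                              n_runs = if (is.null(runs)) 0L else nrow(runs),
                              n_segments = nrow(segments))),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("IBD detection result: %d segments from %d haplotypes",
                     " x %d SNPs\n"),
              s$n_segments, s$n_haplotypes, s$n_snps))
  cat(sprintf("  slices: %d (%d skipped); candidates: %d (%d match, %d interest)\n",
              s$n_slices, s$n_skipped, s$n_candidates, s$n_match,
              s$n_interest))
  if (s$n_segments > 0)
    cat(sprintf("  segment length: %.2f-%.2f cM (median %.2f)\n",
                min(x$segments$cm_length), max(x$segments$cm_length),
                stats::median(x$segments$cm_length)))
  invisible(x)
}

#' @export
summary.ibd_result <- function(object, ...) {
  cat("Per-stage counts:\n")
  str(object$stats, give.head = FALSE)
  if (nrow(object$segments)) {
    cat("Segment genetic lengths (cM):\n")
    print(summary(object$segments$cm_length))
  }
  invisible(object$stats)
}
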