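# Readers/writers for PLINK-style phased haplotype text and the
# GERMLINE-compatible match format, plus genetic-map interpolation.

#' Read a phased haplotype panel from PLINK-style text
#'
#' Two dialects are auto-detected from the column arithmetic of the first
#' data line against the number of map rows `M`:
#' \describe{
#'   \item{haplotype rows}{one row per haplotype: an identifier followed by
#'     `M` space-separated `0`/`1` alleles (`M + 1` columns). Identifiers
#'     already carrying a `.0`/`.1` phase suffix are used verbatim;
#'     otherwise consecutive row pairs are suffixed `.0` and `.1`.}
#'   \item{PED}{one row per sample: the six standard leading columns
#'     (family, individual, father, mother, sex, phenotype) followed by
#'     `2 M` alleles (`2 M + 6` columns); odd allele positions form the
#'     `.0` haplotype, even positions the `.1` haplotype.}
#' }
#' The map file is whitespace-separated `chrom snp_id cm bp`.
#'
#' @param haps_path Path to the haplotype file.
#' @param map_path Path to the map file.
#' @return A [haplotype_panel()].
#' @export
read_panel <- function(haps_path, map_path) {
  map <- read_genetic_map(map_path)
  m <- length(map)
  lines <- readLines(haps_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty haplotype file: ", haps_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    stop(sprintf("ragged haplotype file: line %d has %d fields, line 1 has %d",
                 which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]))
  if (ncols[1] == m + 1L) {
    ids <- vapply(fields, `[`, "", 1L)
    allele_chr <- lapply(fields, `[`, -1L)
    if (!all(grepl("\\.[01]$", ids))) {
      if (length(ids) %% 2L != 0L)
        stop("haplotype rows without phase suffixes must come in sample pairs")
      ids <- paste0(rep(ids[seq(1L, length(ids), 2L)], each = 2L),
                    c(".0", ".1"))
    }
    alleles <- parse_alleles(allele_chr, haps_path)
  } else if (ncols[1] == 2L * m + 6L) {
    samples <- vapply(fields, `[`, "", 2L)
    allele_chr <- lapply(fields, `[`, -(1:6))
    geno <- parse_alleles(allele_chr, haps_path)
    n <- nrow(geno)
    alleles <- matrix(0L, 2L * n, m)
    alleles[seq(1L, 2L * n, 2L), ] <- geno[, seq(1L, 2L * m, 2L), drop = FALSE]
    alleles[seq(2L, 2L * n, 2L), ] <- geno[, seq(2L, 2L * m, 2L), drop = FALSE]
    ids <- paste0(rep(samples, each = 2L), c(".0", ".1"))
  } else {
    stop(sprintf(paste0("cannot reconcile haplotype file (%d columns) with ",
                        "map (%d SNPs): expected %d (haplotype rows) or %d ",
                        "(PED) columns"),
                 ncols[1], m, m + 1L, 2L * m + 6L))
  }
  haplotype_panel(ids, alleles, map)
}

parse_alleles <- function(allele_chr, path) {
  out <- matrix(0L, length(allele_chr), length(allele_chr[[1]]))
  for (i in seq_along(allele_chr)) {
    v <- allele_chr[[i]]
    bad <- which(v != "0" & v != "1")
    if (length(bad))
      stop(sprintf("non-binary allele symbol '%s' at %s line %d, field %d",
                   v[bad[1]], path, i, bad[1]))
    out[i, ] <- as.integer(v)
  }
  out
}

#' Read a PLINK-style map file (chrom, snp id, cM, bp)
#'
#' @param map_path Path to the whitespace-separated map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(map_path) {
  df <- utils::read.table(map_path, header = FALSE,
                          col.names = c("chrom", "snp_id", "cm", "bp"),
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  if (length(unique(df$chrom)) != 1L)
    stop("map file must cover a single chromosome")
  genetic_map(df$chrom[1], df$snp_id, df$cm, df$bp)
}

#' Write a panel in haplotype-row dialect (plus its map file)
#'
#' @param panel A [haplotype_panel()].
#' @param haps_path,map_path Output paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, haps_path, map_path) {
  rows <- apply(panel$alleles, 1L, paste, collapse = " ")
  writeLines(paste(panel$hap_ids, rows), haps_path)
  map <- panel$map
  utils::write.table(
    data.frame(map$chrom, map$snp_ids, format(map$cm, trim = TRUE,
               digits = 15), format(map$bp, trim = TRUE, scientific = FALSE)),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(panel)
}

#' Interpolate genetic positions from a reference map
#'
#' Fills the cM column of a map by piecewise-linear interpolation of a
#' reference map at the query physical positions. Outside the reference
#' range the nearest interval's slope is extended; the result is forced
#' non-decreasing.
#'
#' @param map_without_cm A [genetic_map()] whose cm values are placeholders.
#' @param reference A [genetic_map()] with trusted cm values.
#' @return A [genetic_map()] with interpolated cm.
#' @export
interpolate_cm <- function(map_without_cm, reference) {
  if (!inherits(reference, "genetic_map") || length(reference) == 0L)
    stop("reference map is empty")
  rb <- reference$bp
  rc <- reference$cm
  q <- map_without_cm$bp
  if (length(rb) == 1L) {
    cm <- rep(rc, length(q))
  } else {
    cm <- stats::approx(rb, rc, xout = q, rule = 2, ties = "ordered")$y
    lo_slope <- (rc[2] - rc[1]) / (rb[2] - rb[1])
    n <- length(rb)
    hi_slope <- (rc[n] - rc[n - 1]) / (rb[n] - rb[n - 1])
    below <- q < rb[1]
    above <- q > rb[n]
    cm[below] <- rc[1] + (q[below] - rb[1]) * lo_slope
    cm[above] <- rc[n] + (q[above] - rb[n]) * hi_slope
  }
  genetic_map(map_without_cm$chrom, map_without_cm$snp_ids, cummax(cm),
              map_without_cm$bp)
}

# canonical empty segment table
empty_segments <- function() {
  data.frame(id_a = character(), id_b = character(),
             snp_start = integer(), snp_end = integer(),
             bp_start = numeric(), bp_end = numeric(),
             n_snps = integer(), cm_length = numeric(),
             similarity = numeric(), stringsAsFactors = FALSE)
}

# canonical segment ordering: (id_a, id_b, bp_start)
sort_segments <- function(segments) {
  segments[order(segments$id_a, segments$id_b, segments$bp_start), ,
           drop = FALSE]
}

#' Write IBD segments as a GERMLINE-compatible match file
#'
#' Tab-separated, no header, one row per segment:
#' `sample_a hap_a sample_b hap_b chrom bp_start bp_end snp_count cm_length
#' similarity`, with `cm_length` printed to 4 decimals and rows sorted by
#' `(id_a, id_b, bp_start)` so output is a pure function of segment content.
#' Physical extents are 1-based inclusive.
#'
#' @param segments Segment table as returned by [detect_ibd()].
#' @param map The [genetic_map()] the segments refer to.
#' @param out_path Output path.
#' @return Invisibly, the path.
#' @export
write_match_file <- function(segments, map, out_path) {
  segments <- sort_segments(segments)
  if (nrow(segments) == 0L) {
    writeLines(character(), out_path)
    return(invisible(out_path))
  }
  rows <- sprintf("%s\t%s\t%s\t%s\t%s\t%.0f\t%.0f\t%d\t%.4f\t%g",
                  hap_sample(segments$id_a), segments$id_a,
                  hap_sample(segments$id_b), segments$id_b,
                  map$chrom, segments$bp_start, segments$bp_end,
                  segments$n_snps, segments$cm_length, segments$similarity)
  writeLines(rows, out_path)
  invisible(out_path)
}

#' Read a match file written by [write_match_file()]
#'
#' @param path Match file path.
#' @param map Optional [genetic_map()]; when given, SNP index extents are
#'   reconstructed from the physical positions.
#' @return A segment table.
#' @export
read_match_file <- function(path, map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_segments())
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("sample_a", "hap_a", "sample_b",
                                        "hap_b", "chrom", "bp_start",
                                        "bp_end", "snp_count", "cm_length",
                                        "similarity"),
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "character", "numeric", "numeric",
                                         "integer", "numeric", "numeric"))
  seg <- data.frame(id_a = df$hap_a, id_b = df$hap_b,
                    snp_start = NA_integer_, snp_end = NA_integer_,
                    bp_start = df$bp_start, bp_end = df$bp_end,
                    n_snps = df$snp_count, cm_length = df$cm_length,
                    similarity = df$similarity, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    seg$snp_start <- match(seg$bp_start, map$bp)
    seg$snp_end <- match(seg$bp_end, map$bp)
    if (anyNA(seg$snp_start) || anyNA(seg$snp_end))
      stop("match file physical positions not found in the map")
  }
  sort_segments(seg)
}

#' Write / read planted ground-truth segment tables (TSV)
#'
#' @param truth Ground-truth table from [plant_ibd()].
#' @param path File path.
#' @return `write_truth_file`: invisibly the path; `read_truth_file`: the
#'   truth table.
#' @export
write_truth_file <- function(truth, path) {
  utils::write.table(truth, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth_file
#' @export
read_truth_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(hap_a = "character", hap_b = "character"),
                    stringsAsFactors = FALSE)
}
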