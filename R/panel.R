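#' Construct a genetic map
#'
#' A genetic map carries, for each SNP on one chromosome, its identifier, its
#' genetic position in centimorgans (cM) and its physical position in base
#' pairs (1-based). Genetic positions must be non-decreasing and physical
#' positions strictly increasing; all slicing and segment-length arithmetic
#' in the package is driven by this object.
#'
#' @param chrom Chromosome label (single string).
#' @param snp_ids Character vector of SNP identifiers.
#' @param cm Numeric vector of genetic positions in cM (non-decreasing).
#' @param bp Integer-valued vector of physical positions (strictly
#'   increasing).
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(chrom, snp_ids, cm, bp) {
  chrom <- as.character(chrom)
  snp_ids <- as.character(snp_ids)
  cm <- as.numeric(cm)
  bp <- as.numeric(bp)
  if (length(snp_ids) == 0L)
    stop("genetic map must contain at least one SNP")
  if (length(snp_ids) != length(cm) || length(cm) != length(bp))
    stop(sprintf("map field lengths differ: %d ids, %d cm, %d bp",
                 length(snp_ids), length(cm), length(bp)))
  if (any(diff(cm) < 0))
    stop("genetic positions (cm) must be non-decreasing")
  if (any(diff(bp) <= 0))
    stop("physical positions (bp) must be strictly increasing")
  structure(list(chrom = chrom, snp_ids = snp_ids, cm = cm, bp = bp),
            class = "genetic_map")
}

#' @export
length.genetic_map <- function(x) length(x$snp_ids)

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: chromosome %s, %d SNPs, %.3f-%.3f cM, %d-%d bp\n",
              x$chrom, length(x), x$cm[1], x$cm[length(x)],
              x$bp[1], x$bp[length(x)]))
  invisible(x)
}

#' Construct a phased haplotype panel
#'
#' A panel is a haplotype-by-SNP binary matrix (0 = major allele, 1 = minor
#' allele) together with the genetic map of its SNP columns. Haplotype
#' identifiers follow the `"<sample>.0"` / `"<sample>.1"` convention so each
#' diploid sample contributes two rows.
#'
#' @param hap_ids Character vector of unique haplotype identifiers, one per
#'   matrix row.
#' @param alleles Integer matrix over \{0, 1\}, haplotypes in rows, SNPs in
#'   columns.
#' @param map A [genetic_map()] with one entry per allele column.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(hap_ids, alleles, map) {
  hap_ids <- as.character(hap_ids)
  if (!inherits(map, "genetic_map")) stop("map must be a genetic_map")
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != length(hap_ids))
    stop(sprintf("allele matrix has %d rows but %d haplotype ids given",
                 nrow(alleles), length(hap_ids)))
  if (ncol(alleles) != length(map))
    stop(sprintf("allele matrix has %d SNP columns but map has %d SNPs",
                 ncol(alleles), length(map)))
  if (anyDuplicated(hap_ids)) stop("haplotype ids must be unique")
  if (!all(alleles == 0L | alleles == 1L))
    stop("allele matrix entries must all be 0 or 1")
  rownames(alleles) <- hap_ids
  structure(list(hap_ids = hap_ids, alleles = alleles, map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Phased haplotype panel: %d haplotypes x %d SNPs (chr %s, %.2f cM)\n",
              length(x$hap_ids), length(x$map), x$map$chrom,
              x$map$cm[length(x$map)] - x$map$cm[1]))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

# sample id part of "<sample>.<phase>" haplotype ids
hap_sample <- function(hap_ids) sub("\\.[01]$", "", hap_ids)

# phase suffix of "<sample>.<phase>" haplotype ids
hap_phase <- function(hap_ids) sub("^.*\\.", "", hap_ids)
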