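# Synthetic phased panels with known ground truth: random or LD-block
# backgrounds, planted IBD tracts, composite-individual shuffles and SNP
# thinning.

#' Simulation configuration
#'
#' Describes a synthetic chromosome: `n_haplotypes` phased haplotypes (two
#' per sample, so the count must be even) over `chrom_cm` centimorgans at
#' `snp_density` SNPs/cM with uniform genetic spacing and 1 cM = 1 Mb
#' physical scale. Minor-allele frequencies follow `maf_law` (default
#' Uniform(0.05, 0.5), an array-like spectrum). The background is either
#' `"iid"` (independent Bernoulli draws per SNP — maximally IBD-free) or
#' `"mosaic"` (each haplotype is a founder mosaic with `switch_per_cm`
#' switch points over `n_founders` founders, producing LD-like local
#' structure and background sharing). `n_segments` IBD tracts with lengths
#' from `length_law` are planted by [plant_ibd()].
#'
#' @param n_haplotypes Even number of haplotypes.
#' @param chrom_cm Chromosome genetic length in cM.
#' @param snp_density SNPs per cM.
#' @param maf_law `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "fixed", p=)`.
#' @param n_segments Number of IBD tracts to plant.
#' @param length_law `list(dist = "fixed", value=)`,
#'   `list(dist = "uniform", min=, max=)` or `list(dist = "expmix",
#'   min=, rate=)` (minimum plus an exponential tail).
#' @param background `"iid"` or `"mosaic"`.
#' @param n_founders,switch_per_cm Mosaic background parameters.
#' @param seed RNG seed; every generator below is a pure function of
#'   (config, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_haplotypes = 1000, chrom_cm = 30, snp_density = 200,
                       maf_law = list(dist = "uniform", min = 0.05,
                                      max = 0.5),
                       n_segments = 500,
                       length_law = list(dist = "uniform", min = 3,
                                         max = 20),
                       background = c("iid", "mosaic"), n_founders = 30,
                       switch_per_cm = 0.5, seed = 1) {
  background <- match.arg(background)
  if (n_haplotypes < 4 || n_haplotypes %% 2 != 0)
    stop("n_haplotypes must be an even number >= 4")
  if (chrom_cm <= 0 || snp_density <= 0) stop("counts must be positive")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 chrom_cm = chrom_cm, snp_density = snp_density,
                 maf_law = maf_law, n_segments = as.integer(n_segments),
                 length_law = length_law, background = background,
                 n_founders = as.integer(n_founders),
                 switch_per_cm = switch_per_cm, seed = seed),
            class = "sim_config")
}

draw_maf <- function(law, m) {
  switch(law$dist,
         uniform = stats::runif(m, law$min, law$max),
         fixed = rep(law$p, m),
         stop("unknown maf_law: ", law$dist))
}

draw_lengths <- function(law, n) {
  switch(law$dist,
         fixed = rep(law$value, n),
         uniform = stats::runif(n, law$min, law$max),
         expmix = law$min + stats::rexp(n, law$rate),
         stop("unknown length_law: ", law$dist))
}

#' Generate a synthetic phased panel
#'
#' Builds the uniform-spacing genetic map (cm step `1/snp_density`, bp at
#' 1 cM = 1 Mb) and draws the background alleles per `config`.
#'
#' @param config A [sim_config()].
#' @return A [haplotype_panel()] with haplotype ids `S0001.0`, `S0001.1`,
#'   ...
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- as.integer(round(config$chrom_cm * config$snp_density))
  n <- config$n_haplotypes
  cm <- (seq_len(m) - 1L) / config$snp_density
  map <- genetic_map("1", sprintf("snp%06d", seq_len(m)), cm,
                     1 + round(cm * 1e6))
  ids <- paste0(rep(sprintf("S%04d", seq_len(n %/% 2L)), each = 2L),
                c(".0", ".1"))
  alleles <- with_seed(config$seed, {
    maf <- draw_maf(config$maf_law, m)
    if (config$background == "iid") {
      matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)
    } else {
      founders <- matrix(stats::rbinom(config$n_founders * m, 1L,
                                       rep(maf, each = config$n_founders)),
                         config$n_founders, m)
      p_switch <- config$switch_per_cm / config$snp_density
      out <- matrix(0L, n, m)
      for (h in seq_len(n)) {
        switches <- stats::rbinom(m, 1L, p_switch)
        switches[1] <- 1L
        path_draws <- sample.int(config$n_founders, sum(switches),
                                 replace = TRUE)
        path <- path_draws[cumsum(switches)]
        out[h, ] <- founders[cbind(path, seq_len(m))]
      }
      out
    }
  })
  haplotype_panel(ids, alleles, map)
}

#' Plant ground-truth IBD tracts into a panel
#'
#' For each tract a donor and a recipient haplotype from different samples
#' and a random start are drawn; the donor's alleles over the extent are
#' copied onto the recipient, making the pair exactly identical there. A
#' tract length `L` cM maps to `round(L * snp_density)` map intervals so
#' the planted genetic length is exact on the uniform map. Plants
#' overlapping a previous plant on either involved haplotype are redrawn
#' (bounded retries) so no truth record is later overwritten.
#'
#' @param panel A [haplotype_panel()] from [generate_panel()].
#' @param config The same [sim_config()].
#' @param max_retries Redraw budget per tract.
#' @return `list(panel=, truth=)` where `truth` is a data frame
#'   `hap_a, hap_b, snp_start, snp_end, cm_length` with lexicographically
#'   ordered haplotype ids.
#' @export
plant_ibd <- function(panel, config, max_retries = 100) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "sim_config"))
  n <- nrow(panel$alleles)
  m <- ncol(panel$alleles)
  cm <- panel$map$cm
  samples <- hap_sample(panel$hap_ids)
  used <- vector("list", n)  # planted intervals per haplotype
  truth <- vector("list", config$n_segments)
  with_seed(config$seed + 1, {
    lengths_cm <- draw_lengths(config$length_law, config$n_segments)
    for (k in seq_len(config$n_segments)) {
      span <- as.integer(round(lengths_cm[k] * config$snp_density))
      if (span >= m) stop("tract longer than the chromosome")
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        pair <- sample.int(n, 2L)
        if (samples[pair[1]] == samples[pair[2]]) next
        i <- sample.int(m - span, 1L)
        j <- i + span
        clash <- any(vapply(used[pair], function(iv)
          !is.null(iv) && any(iv[, 1] <= j & iv[, 2] >= i), TRUE))
        if (clash) next
        panel$alleles[pair[2], i:j] <- panel$alleles[pair[1], i:j]
        used[[pair[1]]] <- rbind(used[[pair[1]]], c(i, j))
        used[[pair[2]]] <- rbind(used[[pair[2]]], c(i, j))
        ids <- sort(panel$hap_ids[pair])
        truth[[k]] <- data.frame(hap_a = ids[1], hap_b = ids[2],
                                 snp_start = i, snp_end = j,
                                 cm_length = cm[j] - cm[i],
                                 stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place tract %d without overlap after %d tries",
                     k, max_retries))
    }
  })
  list(panel = panel, truth = do.call(rbind, truth))
}

#' Composite-individual shuffle: destroy IBD, keep local allele structure
#'
#' Cuts the chromosome into genetic windows of `window_cm` and, within each
#' window independently, permutes which haplotype carries which row. Allele
#' counts at every SNP are untouched (row permutation), local LD within a
#' window survives, but any identity tract longer than a couple of windows
#' is broken up with overwhelming probability — the classic null panel for
#' false-positive measurement.
#'
#' @param panel A [haplotype_panel()].
#' @param window_cm Shuffle window length in cM (0.2 in the published
#'   false-positive design).
#' @param seed RNG seed.
#' @return The shuffled [haplotype_panel()].
#' @export
composite_shuffle <- function(panel, window_cm = 0.2, seed = 1) {
  stopifnot(window_cm > 0)
  cm <- panel$map$cm
  rel <- cm - cm[1]
  win <- floor(rel / window_cm)
  n <- nrow(panel$alleles)
  alleles <- panel$alleles
  with_seed(seed, {
    for (w in unique(win)) {
      cols <- which(win == w)
      alleles[, cols] <- alleles[sample.int(n), cols, drop = FALSE]
    }
  })
  haplotype_panel(panel$hap_ids, alleles, panel$map)
}

#' Thin the SNP content of a panel
#'
#' Either deterministic thinning — drop every `drop_every`-th SNP, e.g.
#' `drop_every = 3` keeps two thirds of the array — or seeded random
#' thinning to `keep_frac`. The genetic map is subset alongside, so
#' cM-based tract lengths are unchanged by construction.
#'
#' @param panel A [haplotype_panel()].
#' @param drop_every Drop SNPs at indices divisible by this integer
#'   (`Inf` = keep all).
#' @param keep_frac If non-`NULL`, random thinning keeping this fraction.
#' @param seed Seed for random thinning.
#' @return The thinned [haplotype_panel()].
#' @export
downsample_snps <- function(panel, drop_every = 3, keep_frac = NULL,
                            seed = 1) {
  m <- ncol(panel$alleles)
  keep <- if (!is.null(keep_frac)) {
    with_seed(seed, sort(sample.int(m, round(keep_frac * m))))
  } else if (is.finite(drop_every)) {
    which(seq_len(m) %% drop_every != 0)
  } else seq_len(m)
  map <- panel$map
  haplotype_panel(panel$hap_ids, panel$alleles[, keep, drop = FALSE],
                  genetic_map(map$chrom, map$snp_ids[keep], map$cm[keep],
                              map$bp[keep]))
}
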