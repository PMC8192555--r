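# Synthetic panel generation, tract planting, composite shuffle, thinning
# — checked against the exhaustive reference scanner where IBD content
# matters.

test_that("generation is a pure function of (config, seed)", {
  cfg <- sim_config(n_haplotypes = 20, chrom_cm = 5, snp_density = 100,
                    n_segments = 3, seed = 11)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$map$cm, b$map$cm)
  cfg2 <- sim_config(n_haplotypes = 20, chrom_cm = 5, snp_density = 100,
                     n_segments = 3, seed = 12)
  expect_false(identical(generate_panel(cfg2)$alleles, a$alleles))
  # generation leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_panel(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("panel geometry and allele frequencies follow the config", {
  cfg <- sim_config(n_haplotypes = 200, chrom_cm = 10, snp_density = 150,
                    maf_law = list(dist = "fixed", p = 0.3), seed = 4)
  p <- generate_panel(cfg)
  expect_equal(dim(p$alleles), c(200L, 1500L))
  expect_equal(p$hap_ids[1:4], c("S0001.0", "S0001.1", "S0002.0", "S0002.1"))
  expect_equal(diff(p$map$cm)[1], 1 / 150)
  expect_true(all(p$alleles %in% 0:1))
  freq <- mean(p$alleles)
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / length(p$alleles)))
  expect_error(sim_config(n_haplotypes = 7), "even")
})

test_that("an iid background contains no reportable IBD", {
  cfg <- sim_config(n_haplotypes = 40, chrom_cm = 6, snp_density = 200,
                    n_segments = 0, seed = 21)
  p <- generate_panel(cfg)
  expect_equal(nrow(scan_ibd_exhaustive(p, min_cm = 3)), 0L)
})

test_that("planted tracts are exact and respect the length law", {
  cfg <- sim_config(n_haplotypes = 60, chrom_cm = 20, snp_density = 100,
                    n_segments = 12,
                    length_law = list(dist = "fixed", value = 3), seed = 8)
  sim <- plant_ibd(generate_panel(cfg), cfg)
  truth <- sim$truth
  expect_equal(nrow(truth), 12L)
  expect_equal(truth$cm_length, rep(3, 12), tolerance = 1e-12)
  expect_true(all(truth$hap_a < truth$hap_b))
  expect_true(all(hap_sample(truth$hap_a) != hap_sample(truth$hap_b)))
  idx <- match(truth$hap_a, sim$panel$hap_ids)
  jdx <- match(truth$hap_b, sim$panel$hap_ids)
  for (k in seq_len(nrow(truth))) {
    ext <- truth$snp_start[k]:truth$snp_end[k]
    expect_identical(sim$panel$alleles[idx[k], ext],
                     sim$panel$alleles[jdx[k], ext])
  }
  # uniform law stays inside its support
  cfg2 <- sim_config(n_haplotypes = 100, chrom_cm = 30, snp_density = 100,
                     n_segments = 30,
                     length_law = list(dist = "uniform", min = 3, max = 20),
                     seed = 9)
  t2 <- plant_ibd(generate_panel(cfg2), cfg2)$truth
  expect_true(all(t2$cm_length >= 3 - 0.01 & t2$cm_length <= 20 + 0.01))
  # replanting is reproducible
  t2b <- plant_ibd(generate_panel(cfg2), cfg2)$truth
  expect_identical(t2, t2b)
})

test_that("the reference scanner recovers every planted tract", {
  cfg <- sim_config(n_haplotypes = 30, chrom_cm = 12, snp_density = 150,
                    n_segments = 5,
                    length_law = list(dist = "fixed", value = 4), seed = 15)
  sim <- plant_ibd(generate_panel(cfg), cfg)
  det <- scan_ibd_exhaustive(sim$panel, min_cm = 3)
  acc <- evaluate_ibd(sim$truth, det, sim$panel$map)
  expect_equal(acc$per_segment, rep(1, 5))
  expect_equal(acc$fp_count, 0L)
})

test_that("composite shuffle preserves allele counts and destroys IBD", {
  cfg <- sim_config(n_haplotypes = 40, chrom_cm = 10, snp_density = 150,
                    n_segments = 6,
                    length_law = list(dist = "fixed", value = 5), seed = 30)
  sim <- plant_ibd(generate_panel(cfg), cfg)
  shuf <- composite_shuffle(sim$panel, window_cm = 0.2, seed = 2)
  # per-SNP allele counts are invariant under row permutation
  expect_equal(colSums(shuf$alleles), colSums(sim$panel$alleles))
  expect_false(identical(shuf$alleles, sim$panel$alleles))
  # no identity tract of reportable length survives
  expect_equal(nrow(scan_ibd_exhaustive(shuf, min_cm = 3,
                                        allow_within_sample = TRUE)), 0L)
  # a window at least as long as the chromosome degenerates to one global
  # row permutation
  one <- composite_shuffle(sim$panel, window_cm = 1000, seed = 5)
  row_key <- function(m) sort(unname(apply(m, 1, paste, collapse = "")))
  expect_identical(row_key(one$alleles), row_key(sim$panel$alleles))
  # shuffling is seeded
  expect_identical(composite_shuffle(sim$panel, 0.2, seed = 2)$alleles,
                   shuf$alleles)
})

test_that("SNP thinning keeps the genetic extent of planted tracts", {
  cfg <- sim_config(n_haplotypes = 20, chrom_cm = 10, snp_density = 300,
                    n_segments = 3,
                    length_law = list(dist = "fixed", value = 5), seed = 3)
  sim <- plant_ibd(generate_panel(cfg), cfg)
  thin <- downsample_snps(sim$panel, drop_every = 3)
  expect_equal(ncol(thin$alleles), 2000L)  # two thirds of 3000
  expect_true(all(diff(thin$map$bp) > 0))
  # the tracts are still exact identity runs of ~5 cM on the thinned map:
  # compare in genetic coordinates, which thinning preserves
  det <- scan_ibd_exhaustive(thin, min_cm = 3)
  full_cm <- sim$panel$map$cm
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    d <- det[det$id_a == tr$hap_a & det$id_b == tr$hap_b, ]
    expect_gte(nrow(d), 1L)
    lo <- full_cm[tr$snp_start]
    hi <- full_cm[tr$snp_end]
    cover <- sum(pmin(thin$map$cm[d$snp_end], hi) -
                   pmax(thin$map$cm[d$snp_start], lo))
    expect_gt(cover, 0.95 * (hi - lo))
  }

  frac <- downsample_snps(sim$panel, keep_frac = 0.5, seed = 7)
  expect_equal(ncol(frac$alleles), 1500L)
  expect_identical(downsample_snps(sim$panel, keep_frac = 0.5,
                                   seed = 7)$alleles, frac$alleles)
  expect_identical(downsample_snps(sim$panel, drop_every = Inf)$alleles,
                   sim$panel$alleles)
})
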