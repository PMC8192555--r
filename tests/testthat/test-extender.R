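# Interest refinement, run merging, boundary extension and segment
# finalization.

# a 2-haplotype panel whose rows agree except at `mismatch` SNP positions
pair_panel <- function(n_snp, mismatch, density = 100) {
  base <- rep(0L, n_snp)
  other <- base
  other[mismatch] <- 1L
  haplotype_panel(c("S0001.0", "S0002.0"), rbind(base, other),
                  uniform_map(n_snp / density, density))
}

test_that("refine_interest finds the longest equal-shingle run", {
  # rows agree on SNPs 1-150; one flip in every later 20-SNP shingle
  p <- pair_panel(300, c(155, 175, 195, 215, 235, 255, 275, 295))
  params <- hash_params()
  slice <- list(snp_start = 1L, snp_end = 300L, skipped = FALSE)
  ext <- refine_interest(p, 1, 2, slice, params)
  expect_equal(ext, c(1L, 140L))  # shingles 1-7 = SNPs 1-140

  # fully identical -> the whole shingled extent
  q <- pair_panel(300, integer(0))
  expect_equal(refine_interest(q, 1, 2, slice, params), c(1L, 300L))

  # a flip in every shingle -> nothing to refine
  r <- pair_panel(300, seq(10, 300, by = 20))
  expect_null(refine_interest(r, 1, 2, slice, params))

  # the longest run wins, not the first: equal shingles 1, 3-4 and 7-15
  s <- pair_panel(300, c(30, 90, 110))
  expect_equal(refine_interest(s, 1, 2, slice, params), c(121L, 300L))
})

test_that("merge_runs chains overlapping and abutting extents per pair", {
  ext <- data.frame(
    hap_a = c(1L, 1L, 1L, 1L, 3L),
    hap_b = c(2L, 2L, 2L, 2L, 4L),
    snp_start = c(100L, 300L, 601L, 2000L, 100L),
    snp_end   = c(400L, 600L, 900L, 2100L, 200L),
    est_similarity = c(1, 0.9, 0.95, 1, 1))
  out <- merge_runs(ext)
  expect_equal(nrow(out), 3L)
  one <- out[out$hap_a == 1 & out$snp_start == 100, ]
  expect_equal(one$snp_end, 900L)   # overlap 300-400, abutment 600|601
  expect_equal(one$sim, 0.9)        # minimum over merged extents
  expect_true(any(out$snp_start == 2000))
  expect_true(any(out$hap_a == 3))
  expect_equal(nrow(merge_runs(ext[0, ])), 0L)
})

test_that("zero-error extension expands a seed to its full identical run", {
  p <- pair_panel(1000, c(100, 601))
  run <- list(hap_a = 1L, hap_b = 2L, snp_start = 300L, snp_end = 400L,
              sim = 1)
  out <- extend_boundaries(run, p, max_error = 0)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$snp_start, out$snp_end), c(101L, 600L))

  # identical everywhere -> the whole chromosome
  q <- pair_panel(1000, integer(0))
  full <- extend_boundaries(run, q, max_error = 0)
  expect_equal(c(full$snp_start, full$snp_end), c(1L, 1000L))

  # a seed straddling a mismatch splits instead of reporting discordance
  wide <- list(hap_a = 1L, hap_b = 2L, snp_start = 90L, snp_end = 610L,
               sim = 1)
  split_out <- extend_boundaries(wide, p, max_error = 0)
  expect_equal(nrow(split_out), 3L)
  expect_true(any(split_out$snp_start == 101 & split_out$snp_end == 600))
  for (i in seq_len(nrow(split_out))) {
    ext <- split_out$snp_start[i]:split_out$snp_end[i]
    expect_equal(sum(p$alleles[1, ext] != p$alleles[2, ext]), 0L)
  }
})

test_that("positive error budgets walk through isolated mismatches per side", {
  run <- list(hap_a = 1L, hap_b = 2L, snp_start = 300L, snp_end = 400L,
              sim = 1)
  # single flanking mismatch on each side: budget 1 steps over both
  p <- pair_panel(1000, c(100, 601))
  out <- extend_boundaries(run, p, max_error = 1)
  expect_equal(c(out$snp_start, out$snp_end), c(1L, 1000L))
  # two mismatches per side exhaust the budget; boundary never sits on a
  # mismatch
  q <- pair_panel(1000, c(98, 100, 601, 603))
  out2 <- extend_boundaries(run, q, max_error = 1)
  expect_equal(c(out2$snp_start, out2$snp_end), c(99L, 602L))
  expect_equal(unname(q$alleles[1, 99]), unname(q$alleles[2, 99]))
  expect_equal(unname(q$alleles[1, 602]), unname(q$alleles[2, 602]))
})

test_that("batch extension equals one-at-a-time extension", {
  set.seed(44)
  p <- random_panel(10, 800, seed = 44)
  al <- p$alleles
  al[4, 101:450] <- al[1, 101:450]
  al[6, 301:700] <- al[1, 301:700]
  q <- haplotype_panel(p$hap_ids, al, p$map)
  runs <- data.frame(hap_a = c(1L, 1L), hap_b = c(4L, 6L),
                     snp_start = c(150L, 350L), snp_end = c(400L, 650L),
                     sim = 1)
  batch <- extend_all(runs, q, max_error = 0)
  single <- do.call(rbind, lapply(1:2, function(i)
    extend_boundaries(runs[i, ], q, max_error = 0)))
  o1 <- batch[order(batch$hap_b, batch$snp_start), ]
  o2 <- single[order(single$hap_b, single$snp_start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # extended extents are maximal: flanks mismatch or touch the edge
  for (i in seq_len(nrow(batch))) {
    a <- q$alleles[batch$hap_a[i], ]
    b <- q$alleles[batch$hap_b[i], ]
    s <- batch$snp_start[i]
    e <- batch$snp_end[i]
    expect_true(s == 1 || a[s - 1] != b[s - 1])
    expect_true(e == length(a) || a[e + 1] != b[e + 1])
  }
})

test_that("finalize_segments filters, deduplicates and reports exactly", {
  p <- pair_panel(1000, c(100, 601), density = 100)  # 10 cM chromosome
  runs <- data.frame(hap_a = c(1L, 1L, 1L),
                     hap_b = c(2L, 2L, 2L),
                     snp_start = c(101L, 101L, 700L),
                     snp_end = c(600L, 600L, 950L),
                     sim = 1)
  seg <- finalize_segments(runs, p, min_length_cm = 3)
  expect_equal(nrow(seg), 1L)  # duplicate collapsed, 2.5 cM run dropped
  expect_equal(seg$snp_start, 101L)
  expect_equal(seg$snp_end, 600L)
  expect_equal(seg$cm_length, p$map$cm[600] - p$map$cm[101])
  expect_equal(seg$similarity, 1)
  expect_equal(seg$n_snps, 500L)
  expect_equal(seg$id_a, "S0001.0")
  expect_equal(seg$id_b, "S0002.0")
  expect_equal(seg$bp_start, p$map$bp[101])
  # a run of exactly 3.90 cM sits on the inclusive side of the filter
  runs2 <- data.frame(hap_a = 1L, hap_b = 2L, snp_start = 202L,
                      snp_end = 592L, sim = 1)
  expect_equal(nrow(finalize_segments(runs2, p, min_length_cm = 3.9)), 1L)
  expect_equal(nrow(finalize_segments(runs2, p, min_length_cm = 3.91)), 0L)
  expect_equal(nrow(finalize_segments(runs[0, ], p)), 0L)
})
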