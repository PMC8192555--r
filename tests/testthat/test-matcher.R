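# Band tables, candidate collection and threshold classification.

test_that("band tables keep only multiply-occupied hash buckets", {
  bands <- matrix(c(1, 1, 2, 2,
                    5, 6, 5, 7), nrow = 2, byrow = TRUE)
  tabs <- build_band_tables(bands)
  expect_length(tabs, 2L)
  expect_equal(unname(tabs[[1]]), list(c(1L, 2L), c(3L, 4L)))
  expect_equal(unname(tabs[[2]]), list(c(1L, 3L)))
})

test_that("an identical haplotype pair collides on every band", {
  p <- random_panel(6, 300, seed = 21)
  al <- p$alleles
  al[3, ] <- al[1, ]  # S0001.0 == S0002.0
  q <- haplotype_panel(p$hap_ids, al, p$map)
  params <- hash_params()
  sl <- compute_slices(q$map, slice_cm = 3, cm_overlap = 0)
  sig <- minhash_signatures(tokenize_slice(q, sl[1, ], params), params)
  tabs <- build_band_tables(band_signatures(sig, params))
  cand <- collect_candidates(tabs, q$hap_ids, 1L)
  hit <- cand[cand$hap_a == 1 & cand$hap_b == 3, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$band_hits, 5L)
  expect_equal(hit$slice_index, 1L)
})

test_that("unrelated haplotypes rarely become candidates", {
  p <- random_panel(100, 300, seed = 33)
  params <- hash_params()
  sl <- compute_slices(p$map, slice_cm = 3, cm_overlap = 0)
  sig <- minhash_signatures(tokenize_slice(p, sl[1, ], params), params)
  cand <- collect_candidates(build_band_tables(band_signatures(sig, params)),
                             p$hap_ids, 1L)
  # 4950 possible pairs; iid Bernoulli(0.5) haplotypes share next to nothing
  expect_lt(nrow(cand), 50L)
  if (nrow(cand) > 0) {
    expect_true(all(cand$hap_a < cand$hap_b))
    expect_false(is.unsorted(cand$hap_a))
  }
})

test_that("within-sample pairs are excluded unless requested", {
  p <- random_panel(4, 300, seed = 5)
  al <- p$alleles
  al[2, ] <- al[1, ]  # S0001.0 == S0001.1: same sample
  al[4, ] <- al[1, ]  # S0002.1: different sample
  q <- haplotype_panel(p$hap_ids, al, p$map)
  params <- hash_params()
  sl <- compute_slices(q$map, slice_cm = 3, cm_overlap = 0)
  sig <- minhash_signatures(tokenize_slice(q, sl[1, ], params), params)
  tabs <- build_band_tables(band_signatures(sig, params))
  cand <- collect_candidates(tabs, q$hap_ids, 1L)
  expect_false(any(cand$hap_a == 1 & cand$hap_b == 2))
  expect_true(any(cand$hap_a == 1 & cand$hap_b == 4))
  cand2 <- collect_candidates(tabs, q$hap_ids, 1L,
                              allow_within_sample = TRUE)
  expect_true(any(cand2$hap_a == 1 & cand2$hap_b == 2))
})

test_that("similarity estimation from signatures is exact on constructed cases", {
  cand <- data.frame(slice_index = 1L, hap_a = 1L, hap_b = 2L,
                     band_hits = 5L)
  params <- hash_params()
  sig <- matrix(1, 20, 2)
  expect_equal(estimate_similarity(cand, sig, params)$est_similarity, 1)
  sig[1:10, 2] <- 2  # 10 of 20 components differ
  expect_equal(estimate_similarity(cand, sig, params)$est_similarity, 0.5)
  # band-hits estimator inverts the collision count: (5/5)^(1/4) = 1
  expect_equal(estimate_similarity(cand, sig, params,
                                   method = "band_hits")$est_similarity, 1)
  cand$band_hits <- 1L
  expect_equal(estimate_similarity(cand, sig, params,
                                   method = "band_hits")$est_similarity,
               0.2^(1 / 4))
  # empty candidate set passes through
  e <- estimate_similarity(cand[0, ], sig, params)
  expect_equal(nrow(e), 0L)
  expect_true("est_similarity" %in% names(e))
})

test_that("estimated similarity is statistically faithful at J = 0.7", {
  params <- hash_params(perm_count = 400, bucket_count = 5, seed = 2)
  sets <- sets_with_jaccard(21, 4, 5)  # Jaccard 21/30 = 0.7
  sig <- cbind(set_signature(sets$a, params), set_signature(sets$b, params))
  cand <- data.frame(slice_index = 1L, hap_a = 1L, hap_b = 2L,
                     band_hits = 5L)
  est <- estimate_similarity(cand, sig, params)$est_similarity
  expect_lt(abs(est - 0.7), 3 * sqrt(0.7 * 0.3 / 400))
})

test_that("classification thresholds act on the shared-fraction scale", {
  # shared fraction f relates to union Jaccard s by f = 2s/(1+s):
  # a fully shared slice, an 80%-shared slice and a half-shared slice
  cand <- data.frame(slice_index = 1L, hap_a = 1:3, hap_b = 4:6,
                     band_hits = 5L, est_similarity = c(1, 2 / 3, 1 / 3))
  out <- classify_candidates(cand, match_threshold = 0.99,
                             interest_threshold = 0.70)
  expect_equal(as.character(out$status), c("match", "interest", "reject"))
  # boundary cases land on the inclusive side
  at <- classify_candidates(data.frame(est_similarity = c(0.99 / 1.01,
                                                          0.7 / 1.3)),
                            0.99, 0.70)
  expect_equal(as.character(at$status), c("match", "interest"))
  expect_error(classify_candidates(cand, 0.5, 0.7), "must not exceed")
  expect_error(classify_candidates(cand, 1.2, 0.7), "\\[0, 1\\]")
})

test_that("candidate discovery is invariant to haplotype row order", {
  p <- random_panel(30, 300, seed = 61)
  al <- p$alleles
  al[9, ] <- al[2, ]   # plant one identical pair across samples
  q <- haplotype_panel(p$hap_ids, al, p$map)
  params <- hash_params()
  sl <- compute_slices(q$map, slice_cm = 3, cm_overlap = 0)

  pairs_of <- function(panel) {
    sig <- minhash_signatures(tokenize_slice(panel, sl[1, ], params), params)
    cand <- collect_candidates(build_band_tables(band_signatures(sig,
                                                                 params)),
                               panel$hap_ids, 1L)
    ida <- panel$hap_ids[cand$hap_a]
    idb <- panel$hap_ids[cand$hap_b]
    sort(paste(pmin(ida, idb), pmax(ida, idb)))
  }
  set.seed(8)
  perm <- sample.int(30)
  qp <- haplotype_panel(q$hap_ids[perm], q$alleles[perm, , drop = FALSE],
                        q$map)
  expect_identical(pairs_of(q), pairs_of(qp))
  expect_true(paste("S0001.1", "S0005.0") %in% pairs_of(q))
})
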