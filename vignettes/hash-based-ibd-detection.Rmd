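---
title: "Hash-based detection of identity-by-descent segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hash-based detection of identity-by-descent segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two individuals who share a recent common ancestor carry chromosomal
stretches that are *identical by descent* (IBD): the same haplotype,
inherited intact because recombination has not yet broken it up. On phased
genotype data an IBD segment shows up as a long run of identical alleles
between two haplotypes, and its genetic length (in centimorgans, cM) is
the quantity of interest — segment length decays with the number of
generations to the common ancestor, so 3 cM is roughly the threshold below
which segments stop being reliable evidence of recent relatedness.

The naive detector compares all haplotype pairs SNP by SNP: quadratic in
sample size and hopeless at biobank scale. `hashIBD` instead treats IBD
detection as a *similarity search* problem and solves it with
locality-sensitive hashing (LSH): almost all of the quadratic pair space
is never touched, because only pairs that collide in a hash table are ever
compared directly.

## The pipeline

`detect_ibd()` runs four stages; every stage is exposed as ordinary
functions so each can be used (and tested) in isolation.

### 1. Slicing (`compute_slices`)

The genetic map is cut into windows of `slice_cm` (default 3 cM) whose
boundaries are identical across all haplotypes; consecutive windows
overlap by `cm_overlap` (default 1.4 cM). The overlap is what makes short
segments detectable: a tract of length at least `slice_cm + (slice_cm -
cm_overlap)` = 4.6 cM is guaranteed to fully contain some slice, and a
3 cM tract covers at least ~73% of its best-aligned slice. Slices holding
fewer than `min_snp_count` SNPs (default 50) mark low array density —
typically a low-complexity region that breeds false positives — and are
retained but flagged `skipped`, so slice indices stay contiguous while no
candidate is ever seeded there.

### 2. Shingling and minhash (`tokenize_slice`, `minhash_signatures`)

Within a slice, each haplotype's alleles are cut into consecutive 20-SNP
*shingles*. Each shingle is hashed with 32-bit FNV-1a over its 4-byte
little-endian ordinal followed by its alleles as ASCII `'0'`/`'1'`. The
ordinal prefix makes the representation positional: the same 20 alleles at
a different offset is a different set element, because IBD is identity *at
the same place*, not anagram similarity.

The shingle set of a haplotype's slice is then summarised by a minhash
signature: for each of `perm_count` (default 20) random permutations of
the 32-bit hash space, keep the minimum permuted value over the set. Two
haplotypes agree on one signature component with probability equal to the
Jaccard similarity of their shingle sets, so the fraction of equal
components is an unbiased similarity estimator with binomial variance
`s(1 - s)/perm_count`.

Permutations are Lehmer maps `x -> (a x + b) mod 4294967311`. The modulus
is the smallest prime above 2^32, so every 32-bit hash is a valid residue
and any `a != 0` yields a bijection; the multiplication is done in 128-bit
integer arithmetic in C++ because `a * x` overflows 64-bit doubles'
exact-integer range.

### 3. Banding and candidate generation (`band_signatures`, `collect_candidates`)

The 20 signature values are grouped into `bucket_count` = 5 bands of
`r = 4` consecutive values, and each band is hashed to a single value. Two
haplotypes collide on a band with probability `s^r`, hence on at least one
band with probability

\[ P(\text{hit}) = 1 - (1 - s^r)^b, \]

the S-shaped curve computed by `hit_probability()`. With `r = 4, b = 5`
this passes ~28% at `s = 0.5`, ~75% at `s = 0.7` and ~99.98% at
`s = 0.95`: near-identical slices are essentially never missed, while
weakly similar background pairs almost never surface. Candidate generation is then linear-ish: haplotypes
are bucketed per band hash, and only pairs sharing a bucket are emitted.

### 4. Classification, refinement, extension (`classify_candidates`, `refine_interest`, `extend_boundaries`)

Candidates are classified by estimated similarity against a *match
threshold* (MT = 0.99) and an *interest threshold* (IT = 0.70). The
thresholds live on the **shared-fraction** scale — the fraction of a
slice's shingles the pair has in common — because that is the scale on
which the interesting geometric cases sit: a slice half-covered by a true
IBD tract shares half its shingles. The minhash estimate `s` is a
union-based Jaccard value, so classification converts it with
`f = 2s/(1 + s)` (exact for equal-size sets: a pair sharing half its
shingles has Jaccard 1/3, and `2(1/3)/(4/3) = 1/2`). Matches enter
extension with their full slice extent; interest-level candidates are
inspected shingle-by-shingle and contribute their longest identical run;
the rest are discarded.

Accepted extents of one pair are merged when they overlap or abut
(`merge_runs`) and extended SNP-by-SNP (`extend_boundaries`). With the
default `max_error = 0` the extension is exact: the pair's mismatch
positions partition the chromosome into maximal identical runs, and each
seed expands to the run(s) it intersects. Two properties follow by
construction and are asserted in the test suite: every reported segment
has hamming distance zero over its extent, and every reported segment is
maximal (flanked by a mismatch or a chromosome end). `max_error > 0`
instead walks outward with a per-side mismatch budget, never ending on a
mismatch — useful for genotyping-error tolerance at the cost of the
exactness guarantee. Runs shorter than `min_length` (default 3 cM) are
dropped; survivors are written in a GERMLINE-style tab-separated match
format (`write_match_file`).

## Parameter summary

| Parameter            | Default | Why |
|----------------------|---------|-----|
| `slice_cm`           | 3       | matches the minimum reportable segment length |
| `cm_overlap`         | 1.4     | nearly half a slice: short tracts always overlap some slice well |
| `min_snp_count`      | 50      | skips low-density windows that breed false positives |
| `shingle_size`       | 20      | ~0.1–0.13 cM of alleles per set element at array density |
| `perm_count`         | 20      | signature variance `s(1-s)/20`; storage per slice stays small |
| `bucket_count`       | 5       | with `r = 4` places the retrieval knee near `s ≈ 0.7` |
| `match_threshold`    | 0.99    | accept only (near-)fully shared slices outright |
| `interest_threshold` | 0.70    | inspect partially covered slices instead of dropping them |
| `max_error`          | 0       | exact extension; reported segments carry zero discordance |
| `min_length`         | 3       | conventional reporting floor in cM |

The `"ukbiobank"` preset (12 permutations in 4 bands, minimum length
2.9 cM) trades a little retrieval steepness for speed on very large dense
panels.

## The synthetic generator and its limits

`generate_panel()` + `plant_ibd()` produce the ground-truth data used by
the test suite: a uniform genetic map (1 cM = 1 Mb, default 200 SNPs/cM),
minor-allele frequencies uniform on [0.05, 0.5], and either an iid
Bernoulli background (maximally IBD-free) or a founder-mosaic background
(haplotypes are mosaics of 30 founders with 0.5 switch points per cM,
producing LD-like local structure and realistic background sharing).
Tracts are planted by copying the donor's alleles onto the recipient over
the extent, so planted truth is exact identity by construction.
`composite_shuffle()` builds the false-positive null: permuting which
haplotype carries which row within short genetic windows (0.2 cM)
preserves per-SNP allele counts and local LD but destroys any long-range
identity. `downsample_snps()` thins markers to probe density sensitivity.

What the generator does *not* model: real recombination maps (hotspots,
cold regions), genotyping and phasing error, population structure beyond
the founder mosaic, and low-complexity regions of the genome. Absolute
false-positive counts on real data depend heavily on the latter, which is
why the package measures false positives against the composite-shuffle
null rather than claiming a real-data rate.

## Numerical notes

* All hash values are 32-bit quantities carried in R doubles (exact for
  integers up to 2^53); the Lehmer multiplication alone needs 128-bit
  intermediate arithmetic and lives in C++.
* 4294967311 = 2^32 + 15 is the smallest prime above 2^32. Primality of
  the modulus is what makes every `a != 0` map a bijection.
* SNP extents are 1-based inclusive throughout; genetic lengths are
  `cm[end] - cm[start]` on the panel's map.
* The pipeline is deterministic given the configuration seed: permutation
  coefficients are drawn under an isolated RNG state, so library calls
  never disturb the caller's RNG stream.

## Problem sizes

The shipped tests exercise panels up to 2,000 haplotypes × 6,000 SNPs
(30 cM at 200 SNPs/cM); at that scale a full detection run takes seconds
on one CPU. The design scales further in the number of haplotypes because
candidate generation only touches colliding pairs, but the R
implementation holds the full allele matrix in memory, so panels far
beyond ~10^4 haplotypes × 10^5 SNPs would need chunked I/O that this
package does not provide.

## Limitations

* Input must be phased and biallelic; phasing errors fragment segments
  (mitigate with `max_error > 0` at the cost of exactness).
* Within-sample segments (runs of homozygosity) are excluded by default;
  set `allow_within_sample = TRUE` to include them.
* Segment endpoints are resolved to the SNP grid; sub-marker precision is
  not meaningful and not attempted.
* A single chromosome per run; multi-chromosome panels should be run per
  chromosome.

## A minimal session

```{r}
library(hashIBD)

cfg <- sim_config(n_haplotypes = 200, chrom_cm = 20, snp_density = 150,
                  n_segments = 15,
                  length_law = list(dist = "uniform", min = 4, max = 10),
                  seed = 7)
sim <- plant_ibd(generate_panel(cfg), cfg)
res <- detect_ibd(sim$panel, ibd_config(preset = "page"))
evaluate_ibd(sim$truth, res$segments, sim$panel$map)
```
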