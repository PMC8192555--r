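# Shared fixture builders: everything is generated in code at test time.

# uniform-spacing map over [0, n_cm) at `density` SNPs/cM
uniform_map <- function(n_cm, density = 100, chrom = "1") {
  m <- round(n_cm * density)
  cm <- (seq_len(m) - 1) / density
  genetic_map(chrom, sprintf("s%05d", seq_len(m)), cm, 1 + round(cm * 1e6))
}

# panel from an explicit allele matrix (ids S0001.0, S0001.1, S0002.0, ...)
panel_from_matrix <- function(alleles, density = 100) {
  n <- nrow(alleles)
  ids <- paste0(rep(sprintf("S%04d", seq_len(ceiling(n / 2))), each = 2L),
                c(".0", ".1"))[seq_len(n)]
  haplotype_panel(ids, alleles, uniform_map(ncol(alleles) / density,
                                            density))
}

# random panel with iid Bernoulli(0.5) alleles
random_panel <- function(n_hap, n_snp, seed, density = 100) {
  set.seed(seed)
  panel_from_matrix(matrix(rbinom(n_hap * n_snp, 1, 0.5), n_hap, n_snp),
                    density)
}

# two integer "shingle sets" with an exact Jaccard similarity i / u
sets_with_jaccard <- function(n_shared, n_only_a, n_only_b) {
  univ <- seq_len(n_shared + n_only_a + n_only_b) * 7919
  list(a = univ[seq_len(n_shared + n_only_a)],
       b = univ[c(seq_len(n_shared),
                  n_shared + n_only_a + seq_len(n_only_b))])
}

# minhash signature of an explicit value set under params
set_signature <- function(values, params) {
  minhash_signatures(matrix(values, ncol = 1), params)
}
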