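# Shared fixture builders; everything is generated in code.

# One pileup row (single site x sample) with explicit allele counts.
pileup_row <- function(a = 0L, c = 0L, g = 0L, t = 0L, species = "spX",
                       contig = "spX_ctg1", pos = 1L, ref = "A",
                       sample = "S1", coding = TRUE) {
  data.table::data.table(species = species, contig = contig, pos = pos,
                         ref = ref, sample = sample,
                         count_A = as.integer(a), count_C = as.integer(c),
                         count_G = as.integer(g), count_T = as.integer(t),
                         coding = coding)
}

# A pileup over `n_sites` sites for several samples, from a matrix of
# per-sample polymorphism (TRUE: 50/50 A/C, FALSE: pure A), depth `d`.
presence_pileup <- function(poly, d = 30L) {
  rows <- list()
  for (s in colnames(poly)) for (i in seq_len(nrow(poly))) {
    rows[[length(rows) + 1L]] <-
      if (poly[i, s]) pileup_row(a = d / 2, c = d / 2, pos = i, sample = s)
      else pileup_row(a = d, pos = i, sample = s)
  }
  data.table::rbindlist(rows)
}

# Independent brute-force oracle for shared-polymorphism Jaccard:
# plain set arithmetic over lists of polymorphic site ids.
jaccard_oracle <- function(poly_sets, covered_sets) {
  n <- length(poly_sets)
  d <- matrix(0, n, n, dimnames = list(names(poly_sets), names(poly_sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    both <- intersect(covered_sets[[i]], covered_sets[[j]])
    pi <- intersect(poly_sets[[i]], both)
    pj <- intersect(poly_sets[[j]], both)
    u <- union(pi, pj)
    d[i, j] <- if (length(u) == 0) 0 else 1 - length(intersect(pi, pj)) / length(u)
  }
  d
}

# Random DNA / mutated copy, for genome-comparison tests.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
mutate_dna <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  k <- stats::rbinom(1, length(x), rate)
  if (k > 0) {
    i <- sample(length(x), k)
    x[i] <- vapply(x[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  paste(x, collapse = "")
}

# DNA from a skewed 3rd-order Markov chain: carries genuine 4-mer
# compositional signal beyond the 2nd-order TETRA null, like a real
# genome (uniform-random DNA has none).
markov_dna <- function(L, seed) {
  set.seed(seed)
  B <- c("A", "C", "G", "T")
  ctx <- expand.grid(B, B, B)
  P <- matrix(stats::rgamma(64 * 4, 0.5), 64,
              dimnames = list(paste0(ctx[, 1], ctx[, 2], ctx[, 3]), B))
  P <- P / rowSums(P)
  x <- character(L)
  x[1:3] <- sample(B, 3, TRUE)
  for (i in 4:L)
    x[i] <- sample(B, 1, prob = P[paste0(x[i - 3], x[i - 2], x[i - 1]), ])
  paste(x, collapse = "")
}

# A tiny two-strain community (one dominant fast grower, one rare slow
# grower) used by the enrichment-mechanism tests.
rare_vs_dominant_community <- function(rare_abundance = 1e-4,
                                       rare_rate = 0.15, fast_rate = 0.6) {
  strains <- data.frame(strain = c("dom_st1", "rare_st1"),
                        species = c("dom", "rare"),
                        abundance = c(1 - rare_abundance, rare_abundance),
                        is_rare = c(FALSE, TRUE))
  rates <- matrix(c(fast_rate, rare_rate, fast_rate, rare_rate), ncol = 2,
                  dimnames = list(strains$strain, c("BHI", "MRS")))
  structure(list(species = c("dom", "rare"), strains = strains,
                 growth_rate = rates,
                 reference = c(dom = "dom_ref", rare = "rare_ref")),
            class = "strain_community")
}
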