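# TETRA signatures, ANIb, species rule, ortholog clustering, NJ trees.

test_that("tetranucleotide z-scores behave under the Markov null", {
  # homopolymer: observed = expected, z ~ 0 for AAAA
  z <- suppressWarnings(tetra_zscores(strrep("A", 6000)))
  expect_lt(abs(z[["AAAA"]]), 0.1)
  # signature is reverse-complement symmetric by construction
  set.seed(1)
  s <- random_dna(20000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(tetra_zscores(s), tetra_zscores(rc), tolerance = 1e-9)
  # random sequence: z-scores essentially standard-normal scaled
  z2 <- tetra_zscores(random_dna(100000))
  expect_gt(mean(abs(z2) < 4), 0.99)
  expect_error(tetra_zscores(""), class = "dropstrain_domain_error")
  expect_warning(tetra_zscores(random_dna(1000)), "5 kb")
})

test_that("TETRA correlation separates same-species from random pairs", {
  # genomes with higher-order compositional structure, as real ones have
  ref <- markov_dna(60000, seed = 2)
  set.seed(3)
  sib <- mutate_dna(ref, 0.01)
  indep <- markov_dna(60000, seed = 4)
  expect_equal(tetra_correlation(tetra_zscores(ref), tetra_zscores(ref)), 1.0)
  r_sib <- tetra_correlation(tetra_zscores(ref), tetra_zscores(sib))
  r_ind <- tetra_correlation(tetra_zscores(ref), tetra_zscores(indep))
  expect_gt(r_sib, 0.99)
  expect_lt(abs(r_ind), 0.2)
  expect_gt(r_sib - r_ind, 0.1)
  expect_warning(r0 <- tetra_correlation(rep(0, 256), rnorm(256)),
                 "zero-variance")
  expect_true(is.na(r0))
  expect_error(tetra_correlation(1:10, 1:5), class = "dropstrain_domain_error")
})

test_that("ANI of a genome against itself is 100 with full coverage", {
  set.seed(3)
  g <- random_dna(30000)
  a <- anib(g, g)
  expect_equal(a$ani, 100)
  expect_equal(a$aligned_fraction, 1.0)
})

test_that("ANI tracks planted divergence and decreases with it", {
  set.seed(4)
  ref <- random_dna(50000)
  a3 <- anib(mutate_dna(ref, 0.03), ref)
  expect_lt(abs(a3$ani - 97), 0.5)
  anis <- vapply(c(0, 0.01, 0.03, 0.05),
                 function(d) anib(mutate_dna(ref, d), ref)$ani, 0)
  expect_true(all(diff(anis) < 0.3))   # monotone decrease within ±0.3
  expect_lt(abs(anis[2] - 99), 0.5)
  expect_lt(abs(anis[4] - 95), 0.7)
})

test_that("unrelated random genomes yield no qualifying fragments", {
  set.seed(5)
  a <- anib(random_dna(50000), random_dna(50000))
  expect_true(is.na(a$ani))
  expect_equal(a$aligned_fraction, 0)
})

test_that("both-direction ANI reports each direction plus the mean", {
  set.seed(6)
  ref <- random_dna(20000)
  q <- mutate_dna(ref, 0.02)
  ab <- anib_both(q, ref)
  expect_lt(abs(ab$ani_12 - ab$ani_21), 0.5)
  expect_equal(ab$ani_mean, mean(c(ab$ani_12, ab$ani_21)))
})

test_that("the 95% species rule is inclusive at the boundary", {
  expect_equal(classify_species(96.2), "same_species")
  expect_equal(classify_species(89), "different_species")
  expect_equal(classify_species(95.0), "same_species")
  expect_equal(classify_species(NA), "undefined")
  expect_error(classify_species(101), class = "dropstrain_domain_error")
})

aa_alpha <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
rand_prot <- function(n) paste(sample(aa_alpha, n, TRUE), collapse = "")
mut_prot <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  i <- sample(length(x), k)
  x[i] <- sample(aa_alpha, k, TRUE)
  paste(x, collapse = "")
}

test_that("identical protein sets across genomes are fully core", {
  set.seed(7)
  ps <- setNames(replicate(4, rand_prot(100)), paste0("p", 1:4))
  prots <- list(g1 = setNames(ps, paste0("g1_", names(ps))),
                g2 = setNames(ps, paste0("g2_", names(ps))),
                g3 = setNames(ps, paste0("g3_", names(ps))))
  cl <- cluster_orthologs(prots)
  expect_equal(cl$n_clusters, 4)
  expect_equal(cl$n_core, 4)
  expect_equal(core_fraction(cl), 100)
})

test_that("orthologs cluster across genomes; orphans stay singletons", {
  set.seed(8)
  fam <- replicate(3, rand_prot(120))
  orphan <- rand_prot(90)
  prots <- list(
    g1 = setNames(c(vapply(fam, mut_prot, "", k = 6), orphan),
                  paste0("g1_p", 1:4)),
    g2 = setNames(vapply(fam, mut_prot, "", k = 6), paste0("g2_p", 1:3)))
  cl <- cluster_orthologs(prots)
  expect_equal(cl$n_clusters, 4)
  expect_equal(cl$n_core, 3)
  orphan_cl <- cl$membership$cluster[cl$membership$protein == "g1_p4"]
  expect_equal(sum(cl$membership$cluster == orphan_cl), 1)
  # each protein appears in exactly one cluster
  expect_equal(anyDuplicated(cl$membership$protein), 0)
})

test_that("clustering is invariant to genome and protein input order", {
  set.seed(9)
  fam <- replicate(4, rand_prot(100))
  prots <- list(gA = setNames(vapply(fam, mut_prot, "", k = 5), paste0("a", 1:4)),
                gB = setNames(vapply(fam, mut_prot, "", k = 5), paste0("b", 1:4)))
  cl1 <- cluster_orthologs(prots)
  prots2 <- list(gB = rev(prots$gB), gA = prots$gA)
  cl2 <- cluster_orthologs(prots2)
  expect_equal(cl1$n_clusters, cl2$n_clusters)
  expect_equal(cl1$n_core, cl2$n_core)
  m1 <- cl1$membership[order(cl1$membership$protein), ]
  m2 <- cl2$membership[order(cl2$membership$protein), ]
  expect_equal(m1$cluster, m2$cluster)
  expect_error(cluster_orthologs(list(g1 = character(0), g2 = "AA")),
               class = "dropstrain_domain_error")
})

test_that("core fraction arithmetic matches worked values", {
  expect_equal(round(core_fraction(510, 1710), 1), 29.8)
  expect_equal(core_fraction(5, 5), 100)
  expect_equal(round(core_fraction(1, 3), 1), 33.3)
  expect_error(core_fraction(1, 0), class = "dropstrain_domain_error")
})

test_that("NJ recovers exact branch lengths for 3 additive taxa", {
  # closed form: x = (dAB + dAC - dBC)/2 etc.
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nw <- nj_tree(d)
  expect_match(nw, ";$")
  tr <- ape::read.tree(text = nw)
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(bl[["A"]], 2)
  expect_equal(bl[["B"]], 3)
  expect_equal(bl[["C"]], 7)
})

test_that("NJ recovers random additive-tree topologies (oracle round-trip)", {
  skip_if_not_installed("phangorn")
  set.seed(10)
  for (i in 1:20) {
    nt <- sample(4:8, 1)
    tr <- ape::rtree(nt)
    d <- ape::cophenetic.phylo(tr)
    tr2 <- ape::read.tree(text = nj_tree(d))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
    expect_setequal(tr2$tip.label, tr$tip.label)
  }
})

test_that("NJ input validation and negative-branch clamping", {
  expect_error(nj_tree(matrix(0, 2, 2)), class = "dropstrain_domain_error")
  # a distance matrix violating additivity can produce negative branches
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 1.99,
                1, 1, 1.99, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  nw <- suppressWarnings(nj_tree(d))
  tr <- ape::read.tree(text = nw)
  expect_true(all(tr$edge.length >= 0))
})
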