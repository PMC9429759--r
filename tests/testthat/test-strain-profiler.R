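# SNV calling, catalog filtering, diversity statistic, shared-SNV Jaccard.

test_that("site calls apply depth, MAF and minor-count thresholds", {
  mono <- call_sites(pileup_row(a = 10))
  expect_true(mono$covered)
  expect_false(mono$polymorphic)
  expect_equal(mono$major, "A")
  # minor count 1 fails min_minor_count = 2 even though MAF = 0.1 >= 0.05
  low <- call_sites(pileup_row(a = 9, c = 1))
  expect_false(low$polymorphic)
  expect_equal(low$maf, 0.1)
  poly <- call_sites(pileup_row(a = 6, c = 4))
  expect_true(poly$polymorphic)
  expect_equal(poly$maf, 0.4)
  expect_equal(poly$major, "A")
  expect_equal(poly$minor, "C")
  shallow <- call_sites(pileup_row(a = 2, c = 2))
  expect_false(shallow$covered)
  expect_false(shallow$polymorphic)
})

test_that("allele ties break by the fixed base order A < C < G < T", {
  tie <- call_sites(pileup_row(a = 5, c = 5, g = 5))
  expect_equal(tie$major, "A")
  expect_equal(tie$minor, "C")
  tie2 <- call_sites(pileup_row(g = 5, t = 5))
  expect_equal(tie2$major, "G")
  expect_equal(tie2$minor, "T")
  expect_equal(tie2$maf, 0.5)
})

test_that("malformed pileups are rejected with a parse error", {
  bad <- pileup_row(a = 5)
  bad$count_C <- -1L
  expect_error(call_sites(bad), class = "dropstrain_parse_error")
  expect_error(call_sites(data.frame(x = 1)), class = "dropstrain_parse_error")
})

test_that("catalog keeps bi-allelic sites above the prevalence threshold", {
  # site 1: polymorphic in 1 of 10 covered samples -> prevalence 0.1, kept
  poly <- matrix(FALSE, 2, 10, dimnames = list(NULL, paste0("S", 1:10)))
  poly[1, 1] <- TRUE
  cat1 <- build_catalog(call_sites(presence_pileup(poly)))
  expect_equal(nrow(cat1$sites), 1)
  expect_equal(cat1$sites$pos, 1L)
  expect_equal(cat1$sites$prevalence, 0.1)
  expect_equal(sort(c(cat1$sites$allele1, cat1$sites$allele2)), c("A", "C"))
  # polymorphic in 0 samples -> excluded (site 2 above)
  expect_false(2L %in% cat1$sites$pos)
})

test_that("tri-allelic sites pooled across samples are excluded", {
  pu <- rbind(pileup_row(a = 15, c = 15, sample = "S1"),
              pileup_row(a = 15, g = 15, sample = "S2"))
  cat3 <- build_catalog(call_sites(pu))
  expect_equal(nrow(cat3$sites), 0)
  # whereas the same two alleles in both samples stay bi-allelic
  pu2 <- rbind(pileup_row(a = 15, c = 15, sample = "S1"),
               pileup_row(a = 15, c = 15, sample = "S2"))
  expect_equal(nrow(build_catalog(call_sites(pu2))$sites), 1)
})

test_that("prevalence uses covered samples as denominator", {
  # polymorphic in 1 sample, covered in 2 (third sample uncovered):
  # prevalence must be 1/2, not 1/3
  pu <- rbind(pileup_row(a = 15, c = 15, sample = "S1"),
              pileup_row(a = 30, sample = "S2"),
              pileup_row(a = 1, sample = "S3"))
  ct <- build_catalog(call_sites(pu))
  expect_equal(ct$sites$n_covered, 2L)
  expect_equal(ct$sites$prevalence, 0.5)
})

test_that("SNV fraction divides polymorphic coding sites by covered length", {
  # 20 polymorphic coding sites over 1000 covered coding bp -> 0.02
  poly <- matrix(FALSE, 1000, 2, dimnames = list(NULL, c("S1", "S2")))
  poly[1:20, "S1"] <- TRUE
  calls <- call_sites(presence_pileup(poly))
  ct <- build_catalog(calls)
  fr <- snv_fraction(ct, calls)
  expect_equal(fr["spX", "S1"], 0.02)
  expect_equal(fr["spX", "S2"], 0)
})

test_that("non-coding polymorphisms are excluded from the fraction", {
  pu <- rbind(pileup_row(a = 15, c = 15, pos = 1, coding = TRUE),
              pileup_row(a = 15, c = 15, pos = 2, coding = FALSE),
              pileup_row(a = 30, pos = 3, coding = TRUE))
  calls <- call_sites(pu)
  fr <- snv_fraction(build_catalog(calls), calls)
  expect_equal(fr["spX", "S1"], 0.5)  # 1 coding SNV / 2 covered coding bp
})

test_that("simulator truth: SNV fraction approaches the divergence rate", {
  cm <- make_community(n_species = 1, strains_per_species = 2,
                       rare_strain_fraction = 0, seed = 51)
  cm$strains$abundance <- c(0.5, 0.5)
  d_rate <- 0.01
  g <- make_strain_genomes(cm, genome_length = 20000, coding_fraction = 1,
                           divergence_rate = d_rate, seed = 51)
  oc <- grow_bulk(cm, "BHI", hours = 0)
  pu <- sequence_to_pileup(oc, g, mean_coverage = 100, error_rate = 0, seed = 52)
  calls <- call_sites(pu)
  fr <- snv_fraction(build_catalog(calls), calls)
  # two strains each mutated at rate d: differing-site fraction ~ 2d(1-d)
  expected <- 2 * d_rate * (1 - d_rate)
  sigma <- sqrt(expected / 20000)
  expect_lt(abs(fr["sp01", "S1"] - expected), 3 * sigma)
})

test_that("catalog equals planted differing sites at zero error (recovery)", {
  cm <- make_community(n_species = 1, strains_per_species = 2,
                       rare_strain_fraction = 0, seed = 61)
  cm$strains$abundance <- c(0.5, 0.5)
  g <- make_strain_genomes(cm, genome_length = 8000, divergence_rate = 0.01,
                           seed = 61)
  oc <- grow_bulk(cm, "BHI", hours = 0)
  pu <- sequence_to_pileup(oc, g, mean_coverage = 100, error_rate = 0, seed = 62)
  depth <- rowSums(as.matrix(pu[, c("count_A", "count_C", "count_G", "count_T")]))
  expect_gte(min(depth), 20)   # deep enough everywhere for exact recovery
  ct <- build_catalog(call_sites(pu))
  s1 <- strain_sequence(g, cm$strains$strain[1], "sp01")
  s2 <- strain_sequence(g, cm$strains$strain[2], "sp01")
  truth <- which(s1 != s2)
  expect_setequal(ct$sites$pos, truth)   # no FP, no FN
})

test_that("raising thresholds is monotone in calls", {
  set.seed(71)
  pu <- data.table::rbindlist(lapply(1:200, function(i) {
    d <- sample(0:40, 1)
    a <- rbinom(1, d, 0.8)
    pileup_row(a = a, c = d - a, pos = i)
  }))
  cov5 <- sum(call_sites(pu, min_depth = 5)$covered)
  cov10 <- sum(call_sites(pu, min_depth = 10)$covered)
  expect_lte(cov10, cov5)
  p05 <- sum(call_sites(pu, min_maf = 0.05)$polymorphic)
  p20 <- sum(call_sites(pu, min_maf = 0.20)$polymorphic)
  expect_lte(p20, p05)
  m2 <- sum(call_sites(pu, min_minor_count = 2)$polymorphic)
  m5 <- sum(call_sites(pu, min_minor_count = 5)$polymorphic)
  expect_lte(m5, m2)
})

test_that("shared-SNV Jaccard matches hand examples", {
  # profiles {1,2,3} vs {2,3,4}: similarity 2/4, distance 0.5
  poly <- matrix(FALSE, 4, 2, dimnames = list(NULL, c("S1", "S2")))
  poly[1:3, "S1"] <- TRUE
  poly[2:4, "S2"] <- TRUE
  d <- shared_snv_jaccard(build_catalog(call_sites(presence_pileup(poly))))
  expect_equal(d["S1", "S2"], 0.5)
  # identical profiles -> 0
  same <- matrix(TRUE, 3, 2, dimnames = list(NULL, c("S1", "S2")))
  d0 <- shared_snv_jaccard(build_catalog(call_sites(presence_pileup(same))))
  expect_equal(d0["S1", "S2"], 0)
  # disjoint profiles with non-empty union -> 1
  disj <- matrix(FALSE, 4, 2, dimnames = list(NULL, c("S1", "S2")))
  disj[1:2, "S1"] <- TRUE; disj[3:4, "S2"] <- TRUE
  d1 <- shared_snv_jaccard(build_catalog(call_sites(presence_pileup(disj))))
  expect_equal(d1["S1", "S2"], 1)
})

test_that("shared-SNV Jaccard equals the brute-force set oracle", {
  set.seed(81)
  for (trial in 1:5) {
    n_samp <- sample(3:10, 1); n_site <- 50
    poly <- matrix(runif(n_site * n_samp) < 0.3, n_site, n_samp,
                   dimnames = list(NULL, paste0("S", seq_len(n_samp))))
    # ensure every site is polymorphic somewhere (stays in the catalog)
    poly[cbind(seq_len(n_site), sample(n_samp, n_site, TRUE))] <- TRUE
    calls <- call_sites(presence_pileup(poly))
    ct <- build_catalog(calls)
    d <- shared_snv_jaccard(ct)
    poly_sets <- lapply(colnames(poly), function(s) which(poly[, s]))
    cov_sets <- rep(list(seq_len(n_site)), n_samp)
    names(poly_sets) <- names(cov_sets) <- colnames(poly)
    oracle <- jaccard_oracle(poly_sets, cov_sets)
    expect_equal(d, oracle[rownames(d), colnames(d)], tolerance = 1e-12)
  }
})

test_that("single-sample catalogs cannot be compared", {
  poly <- matrix(TRUE, 3, 1, dimnames = list(NULL, "S1"))
  ct <- build_catalog(call_sites(presence_pileup(poly)))
  expect_error(shared_snv_jaccard(ct), class = "dropstrain_domain_error")
})

test_that("replicate mixtures sit closer than different mixtures", {
  cm <- make_community(n_species = 1, strains_per_species = 3,
                       rare_strain_fraction = 0, seed = 91)
  g <- make_strain_genomes(cm, genome_length = 10000, divergence_rate = 0.005,
                           seed = 91)
  mix <- function(w, sid, seed) {
    cm2 <- cm; cm2$strains$abundance <- w
    sequence_to_pileup(grow_bulk(cm2, "BHI", hours = 0), g,
                       mean_coverage = 80, error_rate = 0, seed = seed,
                       sample_id = sid)
  }
  # two replicates of mixture A (strains 1+2), two of B (strains 1+3)
  pu <- data.table::rbindlist(list(
    mix(c(0.5, 0.5, 0), "A1", 1), mix(c(0.5, 0.5, 0), "A2", 2),
    mix(c(0.5, 0, 0.5), "B1", 3), mix(c(0.5, 0, 0.5), "B2", 4)))
  d <- shared_snv_jaccard(build_catalog(call_sites(pu)))
  within <- c(d["A1", "A2"], d["B1", "B2"])
  between <- c(d["A1", "B1"], d["A1", "B2"], d["A2", "B1"], d["A2", "B2"])
  expect_lt(max(within), min(between))
})

test_that("the profiler is deterministic for fixed input", {
  poly <- matrix(runif(60) < 0.4, 20, 3, dimnames = list(NULL, paste0("S", 1:3)))
  pu <- presence_pileup(poly)
  a <- build_catalog(call_sites(pu))
  b <- build_catalog(call_sites(pu))
  expect_identical(a$sites, b$sites)
  expect_identical(shared_snv_jaccard(a), shared_snv_jaccard(b))
})
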