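# Strain-level SNV profiling from per-site allele-count pileups.
#
# The procedure: (1) call per-site, per-sample major/minor alleles from
# allele counts with depth/frequency thresholds; (2) pool calls across
# samples into a catalog of bi-allelic sites prevalent in more than a
# given fraction of covered samples; (3) summarise per-sample strain
# diversity as the fraction of polymorphic coding sites over covered
# coding length; (4) compare samples by Jaccard distance on shared
# polymorphic sites. All steps are deterministic; no RNG.

.site_id <- function(species, contig, pos) paste(species, contig, pos, sep = ":")

#' Call major/minor alleles per site and sample
#'
#' A (site, sample) with depth below `min_depth` is uncovered. Otherwise
#' the major and minor alleles are the two most frequent bases, ties
#' broken by the fixed base order A < C < G < T; the call is polymorphic
#' iff the minor allele frequency is at least `min_maf` and the minor
#' count at least `min_minor_count`.
#'
#' @param pileup pileup data.frame/data.table (see
#'   [sequence_to_pileup()] for the columns).
#' @param min_depth minimum depth for a site to count as covered
#'   (default 5).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param min_minor_count minimum minor allele count (default 2).
#' @return A `site_calls` data.table: `species`, `contig`, `pos`,
#'   `sample`, `coding`, `depth`, `major`, `minor` (`NA` when no second
#'   base observed), `maf`, `covered`, `polymorphic`, with the thresholds
#'   kept as attributes.
#' @export
call_sites <- function(pileup, min_depth = 5L, min_maf = 0.05,
                       min_minor_count = 2L) {
  req <- c("species", "contig", "pos", "ref", "sample",
           "count_A", "count_C", "count_G", "count_T", "coding")
  if (!all(req %in% names(pileup)))
    .err("dropstrain_parse_error", "pileup is missing column(s): %s",
         paste(setdiff(req, names(pileup)), collapse = ", "))
  m <- as.matrix(pileup[, c("count_A", "count_C", "count_G", "count_T")])
  if (any(m < 0) || any(m != floor(m)))
    .err("dropstrain_parse_error", "allele counts must be non-negative integers")
  depth <- rowSums(m)
  maj_ix <- max.col(m, ties.method = "first")        # column order is A C G T
  m2 <- m
  m2[cbind(seq_len(nrow(m)), maj_ix)] <- -1L
  min_ix <- max.col(m2, ties.method = "first")
  minor_count <- m[cbind(seq_len(nrow(m)), min_ix)]
  covered <- depth >= min_depth
  maf <- ifelse(depth > 0, minor_count / depth, 0)
  calls <- data.table::data.table(
    species = pileup$species, contig = pileup$contig, pos = pileup$pos,
    sample = pileup$sample, coding = pileup$coding,
    depth = depth,
    major = ifelse(depth > 0, .BASES[maj_ix], NA_character_),
    minor = ifelse(minor_count > 0, .BASES[min_ix], NA_character_),
    maf = maf,
    covered = covered,
    polymorphic = covered & maf >= min_maf & minor_count >= min_minor_count)
  data.table::setattr(calls, "thresholds",
                      list(min_depth = min_depth, min_maf = min_maf,
                           min_minor_count = min_minor_count))
  calls
}

#' Build the bi-allelic SNV catalog across samples
#'
#' Alleles are pooled across covered samples per site (major alleles of
#' covered calls plus minor alleles of polymorphic calls). Sites with
#' exactly two pooled alleles are kept when their prevalence — the
#' fraction of covered samples in which they are polymorphic — strictly
#' exceeds `prevalence_threshold`. The denominator counts covered
#' samples, not all samples, so low-coverage samples are not penalised.
#'
#' @param calls a `site_calls` table.
#' @param prevalence_threshold minimum fraction of covered samples that
#'   must be polymorphic (default 0.05, i.e. "more than 5% of samples").
#' @return An `snv_catalog`: list with `sites` (data.table: species,
#'   contig, pos, site, allele1, allele2, coding, n_covered,
#'   n_polymorphic, prevalence) and `presence` (data.table restricted to
#'   catalog sites: site, sample, covered, polymorphic).
#' @export
build_catalog <- function(calls, prevalence_threshold = 0.05) {
  covered <- polymorphic <- major <- minor <- site <- NULL # data.table NSE
  cc <- calls[covered == TRUE]
  if (!nrow(cc))
    return(structure(list(sites = data.table::data.table(),
                          presence = data.table::data.table()),
                     class = "snv_catalog"))
  cc[, site := .site_id(species, contig, pos)]
  pooled <- cc[, {
    al <- unique(c(major, minor[polymorphic]))
    al <- sort(al[!is.na(al)])
    list(species = species[1L], contig = contig[1L], pos = pos[1L],
         coding = coding[1L],
         n_alleles = length(al),
         allele1 = al[1L], allele2 = if (length(al) >= 2L) al[2L] else NA_character_,
         n_covered = .N, n_polymorphic = sum(polymorphic))
  }, by = site]
  keep <- pooled[pooled$n_alleles == 2L &
                   pooled$n_polymorphic / pooled$n_covered > prevalence_threshold]
  keep[, prevalence := n_polymorphic / n_covered]
  keep[, n_alleles := NULL]
  data.table::setcolorder(keep, c("species", "contig", "pos", "site"))
  presence <- cc[site %in% keep$site,
                 list(site, sample, covered, polymorphic)]
  structure(list(sites = keep[], presence = presence[]),
            class = "snv_catalog")
}

#' @export
print.snv_catalog <- function(x, ...) {
  cat(sprintf("snv_catalog: %d bi-allelic sites across %d species\n",
              nrow(x$sites),
              if (nrow(x$sites)) length(unique(x$sites$species)) else 0L))
  invisible(x)
}

#' Per-sample SNV fraction in protein-coding genes
#'
#' The strain-diversity statistic: for each (species, sample), the number
#' of catalog SNV sites in coding regions that are polymorphic in that
#' sample, divided by the coding-region length (bp) covered at the call
#' depth threshold in that sample.
#'
#' @param catalog an `snv_catalog`.
#' @param calls the `site_calls` the catalog was built from (supplies the
#'   per-sample covered coding length).
#' @param denominator `"covered"` (default: coding bp covered in the
#'   sample) or `"total"` (all coding bp in the pileup).
#' @return Species x sample matrix of SNV fractions; `NA` (with a
#'   warning) where the covered coding length is zero.
#' @export
snv_fraction <- function(catalog, calls,
                         denominator = c("covered", "total")) {
  stopifnot(inherits(catalog, "snv_catalog"))
  denominator <- match.arg(denominator)
  coding <- covered <- polymorphic <- site <- N <- n <- NULL # data.table NSE
  calls <- data.table::as.data.table(calls)
  species_all <- sort(unique(calls$species))
  samples_all <- sort(unique(calls$sample))
  den <- if (denominator == "covered") {
    calls[coding == TRUE & covered == TRUE, list(N = .N),
          by = list(species, sample)]
  } else {
    tot <- calls[coding == TRUE,
                 list(N = data.table::uniqueN(paste(contig, pos))),
                 by = species]
    grid <- data.table::CJ(species = tot$species, sample = samples_all)
    tot[grid, on = "species"][, list(species, sample, N)]
  }
  out <- matrix(NA_real_, length(species_all), length(samples_all),
                dimnames = list(species_all, samples_all))
  out[cbind(match(den$species, species_all),
            match(den$sample, samples_all))] <- ifelse(den$N > 0, 0, NA_real_)
  if (nrow(catalog$sites)) {
    cod_sites <- catalog$sites$site[catalog$sites$coding]
    pres <- catalog$presence[site %in% cod_sites & polymorphic == TRUE]
    if (nrow(pres)) {
      num <- pres[, list(species = sub(":.*$", "", site), sample)][
        , list(N = .N), by = list(species, sample)]
      for (i in seq_len(nrow(num))) {
        d <- den[species == num$species[i] & sample == num$sample[i]]
        if (nrow(d) && d$N > 0)
          out[num$species[i], num$sample[i]] <- num$N[i] / d$N
      }
    }
  }
  if (any(is.na(out)))
    warning("species/sample cells with zero covered coding length are NA")
  out
}

#' Jaccard distance on shared polymorphic sites
#'
#' For each pair of samples, catalog sites covered in both are compared:
#' similarity = |polymorphic in both| / |polymorphic in either|, distance
#' = 1 - similarity. An empty union gives distance 0 with a warning.
#'
#' @param catalog an `snv_catalog` with calls from >= 2 samples.
#' @param species optional species id to restrict the catalog to.
#' @return Symmetric samples x samples distance matrix.
#' @export
shared_snv_jaccard <- function(catalog, species = NULL) {
  stopifnot(inherits(catalog, "snv_catalog"))
  pres <- catalog$presence
  if (!is.null(species)) {
    keep <- catalog$sites$site[catalog$sites$species == species]
    pres <- pres[pres$site %in% keep]
  }
  if (!nrow(pres)) .err("dropstrain_domain_error", "empty catalog")
  samples <- sort(unique(pres$sample))
  if (length(samples) < 2)
    .err("dropstrain_domain_error", "need >= 2 samples with catalog sites")
  sites <- sort(unique(pres$site))
  cov <- poly <- matrix(FALSE, length(sites), length(samples),
                        dimnames = list(sites, samples))
  cov[cbind(match(pres$site, sites), match(pres$sample, samples))] <- pres$covered
  poly[cbind(match(pres$site, sites), match(pres$sample, samples))] <- pres$polymorphic
  d <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  warned <- FALSE
  for (i in seq_along(samples)) for (j in seq_len(i - 1L)) {
    both_cov <- cov[, i] & cov[, j]
    u <- sum((poly[, i] | poly[, j]) & both_cov)
    if (u == 0) { warned <- TRUE; d[i, j] <- d[j, i] <- 0; next }
    s <- sum(poly[, i] & poly[, j] & both_cov) / u
    d[i, j] <- d[j, i] <- 1 - s
  }
  if (warned) warning("sample pair(s) with empty polymorphic union; distance 0")
  d
}
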