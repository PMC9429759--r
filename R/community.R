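# Ground-truth strain-structured communities.
#
# A StrainCommunity is the simulator's ground truth: a set of species,
# each split into strains, with global strain relative abundances (summing
# to 1), per-medium exponential growth rates, and a genome reference id
# per species. Downstream modules are tested by recovering what was
# planted here.

#' Generate a strain-structured community
#'
#' Species abundances are drawn log-normally (heavily skewed, as in real
#' gut communities) and partitioned among that species' strains by a
#' symmetric Dirichlet. A fraction of strains is then designated "rare"
#' and forced below `rare_threshold` relative abundance (the regime in
#' which droplet cultivation is claimed to rescue strains that bulk
#' culture loses). Per-strain, per-medium growth rates are drawn uniformly
#' on `rate_range`; rare strains get the lower half of the range so they
#' are also slow growers.
#'
#' @param n_species number of species (>= 1).
#' @param strains_per_species strains per species (>= 1).
#' @param media character vector of medium ids (rates drawn per medium).
#' @param abundance_sdlog sd(log) of the species log-normal (default 1.5).
#' @param dirichlet_alpha symmetric Dirichlet concentration for strain
#'   splits within a species (default 1).
#' @param rare_strain_fraction fraction of strains forced rare (default 0.2).
#' @param rare_threshold abundance ceiling defining "rare" (default 1e-4,
#'   i.e. below 0.01% relative abundance).
#' @param rate_range per-hour growth-rate range (default c(0.05, 0.9)).
#' @param seed integer seed; the same seed reproduces the same community.
#' @return A `strain_community`: list with `species` (character),
#'   `strains` (data.frame: strain, species, abundance, is_rare),
#'   `growth_rate` (strain x medium matrix, per hour), `reference`
#'   (named character, species -> genome id).
#' @export
make_community <- function(n_species = 5L, strains_per_species = 3L,
                           media = c("BHI", "MRS"),
                           abundance_sdlog = 1.5, dirichlet_alpha = 1,
                           rare_strain_fraction = 0.2,
                           rare_threshold = 1e-4,
                           rate_range = c(0.05, 0.9),
                           seed = 1L) {
  if (n_species < 1 || strains_per_species < 1)
    .err("dropstrain_config_error",
         "n_species and strains_per_species must be >= 1")
  if (!is.numeric(abundance_sdlog) || abundance_sdlog < 0 ||
      dirichlet_alpha <= 0 || rare_strain_fraction < 0 ||
      rare_strain_fraction >= 1 || rare_threshold <= 0)
    .err("dropstrain_config_error", "invalid distribution parameters")
  set.seed(derive_seed(seed, "make_community"))

  species <- sprintf("sp%02d", seq_len(n_species))
  sp_ab <- stats::rlnorm(n_species, meanlog = 0, sdlog = abundance_sdlog)
  sp_ab <- sp_ab / sum(sp_ab)

  strains <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    w <- stats::rgamma(strains_per_species, shape = dirichlet_alpha)
    w <- w / sum(w)
    data.frame(strain = sprintf("%s_st%02d", species[i],
                                seq_len(strains_per_species)),
               species = species[i],
               abundance = sp_ab[i] * w,
               stringsAsFactors = FALSE)
  }))

  n_strains <- nrow(strains)
  n_rare <- floor(rare_strain_fraction * n_strains)
  strains$is_rare <- FALSE
  if (n_rare > 0) {
    # never strip a species of all its non-rare strains
    eligible <- unlist(lapply(split(seq_len(n_strains), strains$species),
                              function(ix) ix[-which.max(strains$abundance[ix])]))
    rare_ix <- sample(eligible, min(n_rare, length(eligible)))
    strains$is_rare[rare_ix] <- TRUE
    # push rare strains below the threshold, renormalise the rest up
    strains$abundance[rare_ix] <-
      rare_threshold * stats::runif(length(rare_ix), 0.1, 0.9)
    keep <- !strains$is_rare
    strains$abundance[keep] <- strains$abundance[keep] *
      (1 - sum(strains$abundance[!keep])) / sum(strains$abundance[keep])
  }

  rates <- matrix(stats::runif(n_strains * length(media),
                               rate_range[1], rate_range[2]),
                  nrow = n_strains,
                  dimnames = list(strains$strain, media))
  mid <- mean(rate_range)
  rates[strains$is_rare, ] <- stats::runif(sum(strains$is_rare) * length(media),
                                           rate_range[1], mid)

  structure(list(species = species,
                 strains = strains,
                 growth_rate = rates,
                 reference = stats::setNames(paste0(species, "_ref"), species)),
            class = "strain_community")
}

#' @export
print.strain_community <- function(x, ...) {
  cat(sprintf("strain_community: %d species, %d strains (%d rare), media: %s\n",
              length(x$species), nrow(x$strains), sum(x$strains$is_rare),
              paste(colnames(x$growth_rate), collapse = ", ")))
  invisible(x)
}

#' Plant strain genomes on random species references
#'
#' Each species gets a uniform-random ACGT reference split into
#' `n_contigs` contigs, with non-overlapping coding intervals covering
#' roughly `coding_fraction` of the genome. Each strain of the species
#' carries `Binomial(genome_length, divergence_rate)` substitutions at
#' uniform positions; the planted variant lists are the ground truth for
#' SNV-recovery tests.
#'
#' @param community a `strain_community`.
#' @param genome_length reference length per species in bp (>= 1000).
#' @param n_contigs contigs per reference (default 1).
#' @param coding_fraction fraction of genome in coding intervals (0, 1].
#' @param divergence_rate per-base substitution probability per strain
#'   (0 <= rate < 0.1).
#' @param seed integer seed.
#' @return A `strain_genomes`: list with `reference` (named character of
#'   species reference sequences), `contigs` (data.frame: species, contig,
#'   start, length), `coding` (data.frame of 0-based half-open intervals:
#'   species, contig, start, end), `variants` (data.frame: strain,
#'   species, contig, pos0, ref, alt), `genome_length`.
#' @export
make_strain_genomes <- function(community, genome_length = 20000L,
                                n_contigs = 1L, coding_fraction = 0.85,
                                divergence_rate = 0.01, seed = 1L) {
  stopifnot(inherits(community, "strain_community"))
  if (genome_length < 1000)
    .err("dropstrain_config_error", "genome_length must be >= 1000")
  if (coding_fraction <= 0 || coding_fraction > 1)
    .err("dropstrain_config_error", "coding_fraction must be in (0, 1]")
  if (divergence_rate < 0 || divergence_rate >= 0.1)
    .err("dropstrain_config_error", "divergence_rate must be in [0, 0.1)")
  set.seed(derive_seed(seed, "make_strain_genomes"))

  contig_len <- rep(genome_length %/% n_contigs, n_contigs)
  contig_len[n_contigs] <- genome_length - sum(contig_len[-n_contigs])

  refs <- character(0); contigs <- list(); coding <- list(); variants <- list()
  for (sp in community$species) {
    seq_chars <- sample(.BASES, genome_length, replace = TRUE)
    refs[sp] <- paste(seq_chars, collapse = "")
    offs <- cumsum(c(0L, contig_len))[seq_len(n_contigs)]
    ctg <- sprintf("%s_ctg%d", sp, seq_len(n_contigs))
    contigs[[sp]] <- data.frame(species = sp, contig = ctg,
                                start = offs, length = contig_len)
    # alternating gene/intergenic blocks reaching ~coding_fraction coverage
    coding[[sp]] <- do.call(rbind, lapply(seq_len(n_contigs), function(i) {
      L <- contig_len[i]
      gene <- 900L; gap <- max(1L, round(gene * (1 - coding_fraction) /
                                           coding_fraction))
      starts <- seq(0L, L - 1L, by = gene + gap)
      ends <- pmin(starts + gene, L)
      data.frame(species = sp, contig = ctg[i], start = starts, end = ends)
    }))
    for (st in community$strains$strain[community$strains$species == sp]) {
      k <- stats::rbinom(1, genome_length, divergence_rate)
      if (k == 0) next
      pos <- sample.int(genome_length, k) - 1L     # 0-based, unique
      ref_b <- seq_chars[pos + 1L]
      alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1), "")
      ci <- findInterval(pos, offs)
      variants[[st]] <- data.frame(strain = st, species = sp,
                                   contig = ctg[ci],
                                   pos0 = pos - offs[ci],
                                   gpos0 = pos,
                                   ref = ref_b, alt = unname(alt_b),
                                   stringsAsFactors = FALSE)
    }
  }
  structure(list(reference = refs,
                 contigs = do.call(rbind, contigs),
                 coding = do.call(rbind, coding),
                 variants = if (length(variants))
                   do.call(rbind, c(variants, make.row.names = FALSE))
                 else data.frame(strain = character(0), species = character(0),
                                 contig = character(0), pos0 = integer(0),
                                 gpos0 = integer(0), ref = character(0),
                                 alt = character(0)),
                 genome_length = genome_length),
            class = "strain_genomes")
}

#' Per-strain base at every genomic position of its species reference
#'
#' @param genomes a `strain_genomes`.
#' @param strain strain id.
#' @param species species id.
#' @return Character vector of bases (length `genome_length`), the
#'   reference with that strain's planted substitutions applied.
#' @export
strain_sequence <- function(genomes, strain, species) {
  s <- strsplit(genomes$reference[[species]], "")[[1]]
  v <- genomes$variants[genomes$variants$strain == strain, ]
  if (nrow(v)) s[v$gpos0 + 1L] <- v$alt
  s
}
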