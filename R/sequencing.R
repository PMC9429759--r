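# In-silico sequencing of a pooled post-culture community.
#
# Read simulation and mapping are deliberately bypassed: per-site allele
# counts are sampled directly, which preserves exactly the statistical
# structure the strain profiler assumes (per-site depth ~ Poisson thinned
# by species abundance; bases drawn from the within-species strain
# mixture; a uniform, strand-agnostic per-base error to the three
# alternative bases).

#' Sequence a culture outcome into a per-site allele-count pileup
#'
#' For every reference site of every species: depth is
#' Poisson(`mean_coverage` x species relative abundance in the pool);
#' each base is drawn from the strain mixture at that site (strain
#' weights = the within-species post-culture composition), then flipped
#' to one of the three other bases with probability `error_rate`.
#'
#' @param outcome a `culture_outcome` (defines the pool composition).
#' @param genomes the `strain_genomes` carrying references and variants.
#' @param mean_coverage expected depth for a species at 100% abundance
#'   (> 0).
#' @param error_rate per-base error probability (0 <= e < 0.25).
#' @param seed integer seed.
#' @param sample_id sample label written into the pileup rows.
#' @return A pileup `data.table` with columns `species`, `contig`, `pos`
#'   (1-based within contig), `ref`, `sample`, `count_A`, `count_C`,
#'   `count_G`, `count_T`, `coding` (logical). Depth-0 sites are retained
#'   as uncovered.
#' @export
sequence_to_pileup <- function(outcome, genomes, mean_coverage = 100,
                               error_rate = 0, seed = 1L,
                               sample_id = "S1") {
  stopifnot(inherits(outcome, "culture_outcome"),
            inherits(genomes, "strain_genomes"))
  .check_positive(mean_coverage, "mean_coverage")
  if (error_rate < 0 || error_rate >= 0.25)
    .err("dropstrain_domain_error", "error_rate must be in [0, 0.25)")
  set.seed(derive_seed(seed, paste0("sequence_to_pileup/", sample_id)))

  cnt <- outcome$counts
  total <- sum(cnt$count)
  out <- vector("list", length(unique(cnt$species)))
  names(out) <- unique(cnt$species)

  for (sp in names(out)) {
    L <- genomes$genome_length
    ref_chars <- strsplit(genomes$reference[[sp]], "")[[1]]
    sp_rows <- cnt[cnt$species == sp, ]
    share <- if (total > 0) sum(sp_rows$count) / total else 0

    # strain-mixture base probabilities, per site x base
    P <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, .BASES))
    P[cbind(seq_len(L), match(ref_chars, .BASES))] <- 1
    if (share > 0) {
      w <- sp_rows$count / sum(sp_rows$count)
      names(w) <- sp_rows$strain
      for (st in sp_rows$strain[w > 0]) {
        v <- genomes$variants[genomes$variants$strain == st, ]
        if (!nrow(v)) next
        i <- v$gpos0 + 1L
        P[cbind(i, match(v$ref, .BASES))] <-
          P[cbind(i, match(v$ref, .BASES))] - w[[st]]
        P[cbind(i, match(v$alt, .BASES))] <-
          P[cbind(i, match(v$alt, .BASES))] + w[[st]]
      }
    }
    # uniform error to the three alternative bases
    P <- P * (1 - error_rate) + (1 - P) * (error_rate / 3)

    depth <- stats::rpois(L, mean_coverage * share)
    # sequential binomial thinning: multinomial per site, vectorised
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, .BASES))
    rem <- depth; pleft <- rep(1, L)
    for (b in .BASES[1:3]) {
      pr <- ifelse(pleft > 0, pmin(pmax(P[, b] / pleft, 0), 1), 0)
      nb <- stats::rbinom(L, rem, pr)
      counts[, b] <- nb
      rem <- rem - nb
      pleft <- pleft - P[, b]
    }
    counts[, "T"] <- rem

    # map genome positions to contigs; flag coding membership
    ctg <- genomes$contigs[genomes$contigs$species == sp, ]
    ci <- findInterval(seq_len(L) - 1L, ctg$start)
    coding <- logical(L)
    cod <- genomes$coding[genomes$coding$species == sp, ]
    for (j in seq_len(nrow(cod))) {
      off <- ctg$start[match(cod$contig[j], ctg$contig)]
      coding[(off + cod$start[j] + 1L):(off + cod$end[j])] <- TRUE
    }
    out[[sp]] <- data.table::data.table(
      species = sp, contig = ctg$contig[ci],
      pos = seq_len(L) - ctg$start[ci],
      ref = ref_chars, sample = sample_id,
      count_A = counts[, "A"], count_C = counts[, "C"],
      count_G = counts[, "G"], count_T = counts[, "T"],
      coding = coding)
  }
  data.table::rbindlist(out)
}

#' Default phylogenetic-marker table for a simulated community
#'
#' @param community a `strain_community`.
#' @param n_markers single-copy markers per species (default 3).
#' @param lengths marker gene lengths in bp, recycled (default
#'   900/1200/1500).
#' @return data.frame: species, gene, length.
#' @export
default_markers <- function(community, n_markers = 3L,
                            lengths = c(900L, 1200L, 1500L)) {
  stopifnot(inherits(community, "strain_community"))
  data.frame(species = rep(community$species, each = n_markers),
             gene = paste0(rep(community$species, each = n_markers),
                           "_marker", seq_len(n_markers)),
             length = rep_len(lengths, length(community$species) * n_markers))
}

#' Sample marker-gene read counts from a culture outcome
#'
#' Per (species, marker): reads ~ Poisson(`depth` x species relative
#' abundance x gene length / `read_length`), so the length-normalised
#' coverage estimator is unbiased for the pool composition.
#'
#' @param outcome a `culture_outcome`.
#' @param markers marker table from [default_markers()].
#' @param depth expected marker coverage for a species at 100% abundance.
#' @param read_length read length in bp (default 150).
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return A marker-count data.frame: sample, species, gene, count,
#'   length.
#' @export
simulate_marker_counts <- function(outcome, markers, depth = 200,
                                   read_length = 150L, seed = 1L,
                                   sample_id = "S1") {
  stopifnot(inherits(outcome, "culture_outcome"))
  .check_positive(depth, "depth")
  set.seed(derive_seed(seed, paste0("simulate_marker_counts/", sample_id)))
  cnt <- outcome$counts
  sp_share <- tapply(cnt$count, cnt$species, sum) / sum(cnt$count)
  mu <- depth * sp_share[markers$species] * markers$length / read_length
  data.frame(sample = sample_id, species = markers$species,
             gene = markers$gene,
             count = stats::rpois(nrow(markers), mu),
             length = markers$length, stringsAsFactors = FALSE)
}
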