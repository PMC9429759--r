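# Pairwise genome relatedness and ortholog clustering.
#
# ANIb-style identity: the query is cut into ~1 kb fragments, each
# fragment is anchored in the reference by shared k-mer seeds and aligned
# with a gapped extension; ANI is the mean identity of qualifying hits.
# TETRA: tetranucleotide z-score signatures under a second-order Markov
# null, compared by Pearson correlation. Ortholog clusters: reciprocal
# normalised-score hits, connected components.

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.contig_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || !length(genome) || any(nchar(genome) == 0))
    .err("dropstrain_domain_error", "genome must be one or more non-empty sequences")
  toupper(genome)
}

#' Tetranucleotide z-score signature
#'
#' Overlapping 2-, 3- and 4-mers are counted on each contig and its
#' reverse complement. Under the second-order Markov null the expected
#' 4-mer count is `E(w1w2w3w4) = c(w1w2w3) c(w2w3w4) / c(w2w3)` with
#' variance `E (c(w2w3) - c(w1w2w3)) (c(w2w3) - c(w2w3w4)) / c(w2w3)^2`;
#' the signature is `z = (obs - E) / sqrt(var)` over the 256 4-mers
#' (0 where the variance is 0). Ambiguous bases never enter the counts.
#'
#' @param genome character vector of contig sequences (or
#'   `DNAStringSet`).
#' @return Named numeric vector of 256 z-scores.
#' @export
tetra_zscores <- function(genome) {
  ctgs <- .contig_set(genome)
  if (sum(nchar(ctgs)) < 5000)
    warning("total sequence below 5 kb; tetranucleotide signal will be noisy")
  both <- Biostrings::DNAStringSet(c(ctgs, vapply(ctgs, .revcomp, "")))
  cnt <- function(w) {
    m <- Biostrings::oligonucleotideFrequency(both, width = w)
    colSums(m)
  }
  c2 <- cnt(2); c3 <- cnt(3); c4 <- cnt(4)
  w4 <- names(c4)
  left3 <- substr(w4, 1, 3)
  right3 <- substr(w4, 2, 4)
  mid2 <- substr(w4, 2, 3)
  E <- ifelse(c2[mid2] > 0, c3[left3] * c3[right3] / c2[mid2], 0)
  v <- ifelse(c2[mid2] > 0,
              E * (c2[mid2] - c3[left3]) * (c2[mid2] - c3[right3]) / c2[mid2]^2,
              0)
  z <- ifelse(v > 0, (c4 - E) / sqrt(v), 0)
  stats::setNames(as.numeric(z), w4)
}

#' Pearson correlation of two tetranucleotide signatures
#'
#' @param sig1,sig2 256-component signatures from [tetra_zscores()].
#' @return Pearson r, or `NA` (with warning) if either signature has
#'   zero variance.
#' @export
tetra_correlation <- function(sig1, sig2) {
  if (length(sig1) != length(sig2))
    .err("dropstrain_domain_error", "signatures must have equal length")
  if (stats::sd(sig1) == 0 || stats::sd(sig2) == 0) {
    warning("zero-variance signature; correlation undefined")
    return(NA_real_)
  }
  stats::cor(sig1, sig2)
}

#' Fragment-based average nucleotide identity (ANIb convention)
#'
#' The query is cut into consecutive fragments of `fragment_length`
#' (a trailing remainder is kept when at least half that length). Each
#' fragment is anchored in the reference by exact `seed_k`-mer matches:
#' seeds are taken at a fixed stride across the fragment, and a
#' candidate locus requires at least two seeds agreeing on a diagonal
#' (within +/- 30 bp). The fragment is then aligned to the candidate
#' reference window by gapped global-local alignment (match +1,
#' mismatch -1, gap open -5, gap extend -2); a hit qualifies when its
#' identity is at least `min_identity` over at least `min_aln_frac` of
#' the fragment. ANI is the mean identity of qualifying hits x 100.
#'
#' @param query,reference genomes (character contig vectors or
#'   `DNAStringSet`).
#' @param fragment_length query fragment size in bp (default 1020).
#' @param min_identity minimum hit identity (default 0.30).
#' @param min_aln_frac minimum alignable fraction of a fragment
#'   (default 0.70).
#' @param seed_k anchor k-mer size (default 15).
#' @return List: `ani` (percent, `NA` if no fragment qualifies),
#'   `aligned_fraction` (qualifying / total fragments), `n_fragments`.
#' @export
anib <- function(query, reference, fragment_length = 1020L,
                 min_identity = 0.30, min_aln_frac = 0.70, seed_k = 15L) {
  q <- .contig_set(query); r <- .contig_set(reference)
  rseq <- paste(r, collapse = paste(rep("N", seed_k), collapse = "")) # hard break
  rlen <- nchar(rseq)

  # reference seed index: k-mer -> positions (1-based)
  starts <- seq_len(rlen - seed_k + 1L)
  kmer <- pos <- NULL # data.table NSE
  idx <- data.table::data.table(kmer = substring(rseq, starts,
                                                 starts + seed_k - 1L),
                                pos = starts)
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  data.table::setkey(idx, kmer)

  frags <- unlist(lapply(q, function(ctg) {
    L <- nchar(ctg)
    st <- seq(1L, L, by = fragment_length)
    f <- substring(ctg, st, pmin(st + fragment_length - 1L, L))
    f[nchar(f) >= fragment_length / 2]
  }), use.names = FALSE)
  if (!length(frags)) .err("dropstrain_domain_error", "query has no fragments")

  stride <- max(1L, fragment_length %/% 21L)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  ids <- rep(NA_real_, length(frags))
  for (i in seq_along(frags)) {
    f <- frags[i]
    fl <- nchar(f)
    off <- seq(1L, fl - seed_k + 1L, by = stride)
    seeds <- data.table::data.table(kmer = substring(f, off, off + seed_k - 1L),
                                    off = off)
    hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hits)) next
    diag <- hits$pos - hits$off
    band <- round(diag / 30)
    tb <- table(band)
    best <- as.integer(names(tb)[which.max(tb)])
    support <- diag[band == best]
    if (length(support) < 2L) next
    d0 <- stats::median(support)
    ws <- max(1L, round(d0) - 50L)
    we <- min(rlen, round(d0) + fl + 50L)
    win <- substr(rseq, ws, we)
    aln <- Biostrings::pairwiseAlignment(f, win, type = "global-local",
                                         substitutionMatrix = sm,
                                         gapOpening = 5, gapExtension = 2)
    wid <- Biostrings::nchar(aln)
    identity <- Biostrings::nmatch(aln) / wid
    aligned <- (wid - sum(width(Biostrings::deletion(aln)[[1]]))) / fl
    if (identity >= min_identity && aligned >= min_aln_frac)
      ids[i] <- identity
  }
  kept <- !is.na(ids)
  list(ani = if (any(kept)) 100 * mean(ids[kept]) else NA_real_,
       aligned_fraction = mean(kept),
       n_fragments = length(frags))
}

#' Both-direction ANI between two genomes
#'
#' @param g1,g2 genomes.
#' @param ... passed to [anib()].
#' @return List: `ani_12`, `ani_21` (directional), `ani_mean` (used for
#'   classification).
#' @export
anib_both <- function(g1, g2, ...) {
  a <- anib(g1, g2, ...); b <- anib(g2, g1, ...)
  list(ani_12 = a$ani, ani_21 = b$ani,
       ani_mean = mean(c(a$ani, b$ani), na.rm = TRUE))
}

#' Species-boundary call from an ANI value
#'
#' Applies the conventional 95% nucleotide-identity species rule; the
#' boundary is inclusive (>= 95 is the same species).
#'
#' @param ani_percent ANI on the 0-100 scale, or `NA`.
#' @return `"same_species"`, `"different_species"` or `"undefined"`.
#' @export
classify_species <- function(ani_percent) {
  if (is.na(ani_percent)) return("undefined")
  if (ani_percent < 0 || ani_percent > 100)
    .err("dropstrain_domain_error", "ANI must be in [0, 100]")
  if (ani_percent >= 95) "same_species" else "different_species"
}

.self_score <- function(aa, sm) {
  Biostrings::pairwiseAlignment(aa, aa, type = "local",
                                substitutionMatrix = sm,
                                gapOpening = 11, gapExtension = 1)@score
}

#' Cluster proteins into ortholog families across genomes
#'
#' All-vs-all local alignment (BLOSUM62, gap open -11, extend -1) with a
#' shared 5-mer prefilter; an edge joins two proteins when the alignment
#' score divided by the self-score of the shorter protein reaches
#' `score_threshold` (the reciprocal criterion is symmetric under this
#' normalisation). Clusters are connected components — the degenerate
#' inflation-1.0 case of Markov clustering.
#'
#' @param proteins named list: genome id -> named character vector of
#'   protein sequences (ids unique across genomes).
#' @param score_threshold normalised-score cutoff in (0, 1]
#'   (default 0.3).
#' @return An `ortholog_clustering`: list with `membership` (data.frame:
#'   protein, genome, cluster), `n_clusters`, `n_core` (clusters present
#'   in every genome), `genomes`.
#' @export
cluster_orthologs <- function(proteins, score_threshold = 0.3) {
  if (!is.list(proteins) || length(proteins) < 2)
    .err("dropstrain_domain_error", "need protein sets for >= 2 genomes")
  for (g in names(proteins))
    if (!length(proteins[[g]]))
      .err("dropstrain_domain_error", "empty protein set for genome %s", g)
  tab <- data.frame(
    protein = unlist(lapply(proteins, names), use.names = FALSE),
    genome = rep(names(proteins), lengths(proteins)),
    seq = toupper(unlist(proteins, use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$protein))
    .err("dropstrain_domain_error", "protein ids must be unique across genomes")
  # deterministic order regardless of input order
  tab <- tab[order(tab$protein), ]
  n <- nrow(tab)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- get("BLOSUM62", envir = environment())
  kmers <- lapply(tab$seq, function(s) {
    L <- nchar(s)
    if (L < 5) return(character(0))
    unique(substring(s, 1:(L - 4), 5:L))
  })
  selfsc <- vapply(tab$seq, .self_score, 0, sm = sm)
  edges <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (!length(intersect(kmers[[i]], kmers[[j]]))) next
    sc <- Biostrings::pairwiseAlignment(tab$seq[i], tab$seq[j], type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 11, gapExtension = 1)@score
    shorter <- if (nchar(tab$seq[i]) <= nchar(tab$seq[j])) i else j
    if (selfsc[shorter] > 0 && sc / selfsc[shorter] >= score_threshold)
      edges <- c(edges, i, j)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # relabel clusters by first member for input-order invariance
  cluster <- match(comp, unique(comp))
  member <- data.frame(protein = tab$protein, genome = tab$genome,
                       cluster = cluster, stringsAsFactors = FALSE)
  pres <- tapply(member$genome, member$cluster,
                 function(x) length(unique(x)))
  structure(list(membership = member,
                 n_clusters = max(cluster),
                 n_core = sum(pres == length(proteins)),
                 genomes = sort(names(proteins))),
            class = "ortholog_clustering")
}

#' Core-genome fraction of an ortholog clustering
#'
#' @param n_core an `ortholog_clustering`, or the number of core
#'   clusters.
#' @param n_clusters total clusters (ignored when a clustering is
#'   given).
#' @return Percentage `100 n_core / n_clusters` (full precision;
#'   conventionally reported to one decimal).
#' @examples
#' core_fraction(510, 1710) # 29.8% — a typical core-genome share
#' @export
core_fraction <- function(n_core, n_clusters = NULL) {
  if (inherits(n_core, "ortholog_clustering")) {
    n_clusters <- n_core$n_clusters
    n_core <- n_core$n_core
  }
  if (is.null(n_clusters) || n_clusters < 1)
    .err("dropstrain_domain_error", "need at least one cluster")
  100 * n_core / n_clusters
}

#' Neighbour-joining tree as a Newick string
#'
#' Standard neighbour joining (via \code{ape::nj}); negative branch
#' lengths are clamped to zero with a warning.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with taxon names.
#' @return Newick string, semicolon-terminated.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) .err("dropstrain_domain_error", "need >= 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  ape::write.tree(tr)
}
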