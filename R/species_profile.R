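# Species-level community profiling from marker-gene read counts:
# length-normalised relative abundance, alpha diversity (Shannon,
# Simpson), beta diversity (Bray-Curtis, Jaccard) and principal
# coordinate analysis.

#' Species relative abundances from marker-gene counts
#'
#' Per sample, a species' coverage is the mean over its markers of
#' `count x read_length / gene_length`; abundances are coverages
#' normalised to sum to 1 within the sample. Averaging markers (rather
#' than summing) keeps the estimate robust to unequal marker counts per
#' species.
#'
#' @param counts marker-count data.frame with columns `sample`,
#'   `species`, `gene`, `count` (non-negative integers), `length` (bp).
#' @param read_length read length in bp (default 150).
#' @return Samples x species matrix of relative abundances; a sample with
#'   zero total coverage keeps an all-zero row (with a warning).
#' @export
relative_abundance <- function(counts, read_length = 150L) {
  req <- c("sample", "species", "gene", "count", "length")
  if (!is.data.frame(counts) || !all(req %in% names(counts)) || !nrow(counts))
    .err("dropstrain_parse_error",
         "counts must be a non-empty data.frame with columns %s",
         paste(req, collapse = ", "))
  if (any(counts$count < 0) || any(counts$length <= 0))
    .err("dropstrain_domain_error", "counts must be >= 0 and lengths > 0")
  cov <- counts$count * read_length / counts$length
  m <- tapply(cov, list(counts$sample, counts$species), mean, default = 0)
  m[is.na(m)] <- 0
  tot <- rowSums(m)
  if (any(tot == 0))
    warning("sample(s) with zero total coverage kept as all-zero rows: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
  m[tot > 0, ] <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
  m
}

#' Alpha diversity per sample
#'
#' Shannon `H = -sum p ln p` (natural log, zero terms skipped) or
#' Simpson `1 - sum p^2`.
#'
#' @param abundance samples x species relative-abundance matrix.
#' @param metric `"shannon"` or `"simpson"`.
#' @return Named per-sample vector; all-zero rows are `NA`.
#' @export
alpha_diversity <- function(abundance, metric = c("shannon", "simpson")) {
  metric <- match.arg(metric)
  p <- as.matrix(abundance)
  d <- if (metric == "shannon")
    -rowSums(ifelse(p > 0, p * log(p), 0))
  else
    1 - rowSums(p^2)
  d[rowSums(p) == 0] <- NA_real_
  stats::setNames(as.numeric(d), rownames(p))
}

#' Beta diversity between samples
#'
#' Bray-Curtis `1 - 2 sum min(p, q) / sum(p + q)` on relative abundances,
#' or Jaccard `1 - |A n B| / |A u B|` on presence/absence at
#' `presence_threshold` (strictly greater than; default 0). Both via
#' \code{vegan::vegdist}.
#'
#' @param abundance samples x species relative-abundance matrix (>= 2
#'   samples).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @param presence_threshold abundance above which a species counts as
#'   present (Jaccard only).
#' @return Symmetric samples x samples distance matrix with zero
#'   diagonal; pairs involving only all-zero samples get distance 0 with
#'   a warning.
#' @export
beta_diversity <- function(abundance, metric = c("bray_curtis", "jaccard"),
                           presence_threshold = 0) {
  metric <- match.arg(metric)
  if (nrow(abundance) < 2)
    .err("dropstrain_domain_error", "need at least 2 samples")
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(abundance, method = "bray")
  } else {
    vegan::vegdist(1 * (abundance > presence_threshold),
                   method = "jaccard", binary = TRUE)
  }
  m <- as.matrix(d)
  if (any(!is.finite(m))) {
    warning("all-zero sample pair(s); distance set to 0")
    m[!is.finite(m)] <- 0
  }
  diag(m) <- 0
  m
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centres the squared distance matrix (`B = -1/2 J D^2 J`),
#' eigendecomposes, retains positive eigenvalues only, and scales
#' eigenvectors by the square root of their eigenvalues. Proportions of
#' inertia are relative to the sum of positive eigenvalues; negative
#' eigenvalues (non-Euclidean distances) are dropped without correction.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param n_axes number of axes requested (>= 1); capped at the number of
#'   positive eigenvalues.
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, sorted descending), `proportion` (per retained
#'   axis).
#' @export
pcoa <- function(d, n_axes = 2L) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    .err("dropstrain_domain_error", "distance matrix must be symmetric")
  if (n_axes < 1) .err("dropstrain_domain_error", "n_axes must be >= 1")
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12 & e$values > 0)
  if (!length(pos)) {
    warning("degenerate distance matrix: no positive eigenvalues")
    return(structure(list(coordinates = matrix(0, n, 0,
                                               dimnames = list(rownames(m), NULL)),
                          eigenvalues = e$values, proportion = numeric(0)),
                     class = "pcoa_result"))
  }
  k <- min(n_axes, length(pos))
  if (k < n_axes)
    warning(sprintf("only %d positive axes available (requested %d)",
                    length(pos), n_axes))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  dimnames(coords) <- list(rownames(m), paste0("PCo", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion = e$values[pos[seq_len(k)]] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes (%.1f%% inertia)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$proportion)))
  invisible(x)
}
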