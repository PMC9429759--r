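# Encapsulation and cultivation.
#
# Droplet cultivation is modelled as independent logistic growth within
# each droplet: every founding lineage grows exponentially at its
# medium-specific rate, jointly capped by a carrying capacity shared only
# among co-occupants of that droplet. Bulk culture is the same model with
# a single shared capacity for the whole vessel (Lotka-Volterra with equal
# competition coefficients), so fast growers crowd everyone else out.
# Droplets therefore protect rare slow growers from community-wide
# competition: a singly-occupied droplet always reaches capacity.

#' Encapsulate a community into droplets
#'
#' Per-droplet founding counts are Poisson(`lambda`); founder identities
#' are drawn i.i.d. from the community's strain abundances.
#'
#' @param community a `strain_community`.
#' @param n_droplets number of droplets (>= 1).
#' @param lambda mean cells per droplet (>= 0).
#' @param seed integer seed.
#' @return A `droplet_ensemble`: list with `founders` (data.table:
#'   droplet, strain), `occupancy` (named table of droplets per founding
#'   count, including zeros), `n_droplets`.
#' @export
encapsulate <- function(community, n_droplets, lambda, seed = 1L) {
  stopifnot(inherits(community, "strain_community"))
  if (n_droplets < 1) .err("dropstrain_domain_error", "n_droplets must be >= 1")
  .check_nonnegative(lambda, "lambda")
  set.seed(derive_seed(seed, "encapsulate"))
  occ <- stats::rpois(n_droplets, lambda)
  total <- sum(occ)
  founders <- if (total > 0)
    data.table::data.table(
      droplet = rep(which(occ > 0L), occ[occ > 0L]),
      strain = sample(community$strains$strain, total, replace = TRUE,
                      prob = community$strains$abundance))
  else data.table::data.table(droplet = integer(0), strain = character(0))
  structure(list(founders = founders,
                 occupancy = table(factor(occ, levels = 0:max(occ, 1))),
                 n_droplets = n_droplets),
            class = "droplet_ensemble")
}

# Right-hand side of the shared-capacity logistic system
# dN_i/dt = r_i N_i (1 - sum(N)/K); r_i = 0 lineages stay constant.
.lv_rhs <- function(t, N, parms) {
  list(parms$r * N * (1 - sum(N) / parms$K))
}

# Closed-form single-lineage logistic from n0 founders.
.logistic1 <- function(n0, r, K, t) {
  if (r == 0) return(n0)
  K * n0 * exp(r * t) / (K + n0 * (exp(r * t) - 1))
}

#' Grow an encapsulated ensemble inside droplets
#'
#' Singly-occupied droplets follow the closed-form logistic to
#' `droplet_capacity`; multiply-occupied droplets share the capacity among
#' their co-occupants and are integrated numerically (one solve per
#' distinct founder composition). Zero-rate strains remain at their
#' founding count. Deterministic given the ensemble.
#'
#' @param ensemble a `droplet_ensemble`.
#' @param community the `strain_community` it was drawn from.
#' @param medium medium id (must be a column of `community$growth_rate`).
#' @param hours incubation time (default 120 h).
#' @param droplet_capacity carrying capacity per droplet in cells
#'   (default 1e4, an order-of-magnitude figure for a ~14 pL droplet).
#' @return A `culture_outcome`: data.frame `counts` (strain, species,
#'   count) of pooled post-culture cell counts, plus `medium`, `hours`,
#'   `mode = "droplet"`.
#' @export
grow_droplets <- function(ensemble, community, medium, hours = 120,
                          droplet_capacity = 1e4) {
  stopifnot(inherits(ensemble, "droplet_ensemble"),
            inherits(community, "strain_community"))
  if (!medium %in% colnames(community$growth_rate))
    .err("dropstrain_config_error", "unknown medium id: %s", medium)
  .check_nonnegative(hours, "hours")
  if (droplet_capacity < 1)
    .err("dropstrain_domain_error", "droplet_capacity must be >= 1")
  r <- community$growth_rate[, medium]

  f <- ensemble$founders
  pooled <- stats::setNames(numeric(nrow(community$strains)),
                            community$strains$strain)
  if (nrow(f) == 0 || hours == 0) {
    if (nrow(f)) { tb <- table(f$strain); pooled[names(tb)] <- as.numeric(tb) }
    return(.outcome(pooled, community, medium, hours, "droplet"))
  }

  # founding counts per (droplet, strain); one composition signature per droplet
  strain <- count <- droplet <- sig <- n_drop <- NULL # data.table NSE
  fc <- f[, .(count = .N), by = .(droplet, strain)]
  data.table::setorder(fc, droplet, strain)
  comp <- fc[, .(sig = paste(strain, count, sep = ":", collapse = "|")),
             by = droplet]
  comp_n <- comp[, .(n_drop = .N), by = sig]

  for (i in seq_len(nrow(comp_n))) {
    parts <- strsplit(strsplit(comp_n$sig[i], "|", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    sts <- vapply(parts, `[`, "", 1L)
    n0 <- as.numeric(vapply(parts, `[`, "", 2L))
    if (length(sts) == 1L) {
      final <- .logistic1(n0, r[[sts]], droplet_capacity, hours)
    } else {
      sol <- deSolve::ode(y = n0, times = c(0, hours), func = .lv_rhs,
                          parms = list(r = unname(r[sts]),
                                       K = droplet_capacity))
      final <- pmax(sol[nrow(sol), -1], 0)
    }
    pooled[sts] <- pooled[sts] + final * comp_n$n_drop[i]
  }
  .outcome(pooled, community, medium, hours, "droplet")
}

#' Grow the community in bulk culture
#'
#' All lineages are inoculated into one vessel and share a single
#' logistic carrying capacity (equal competition coefficients), so the
#' fastest growers dominate the final composition.
#'
#' @param community a `strain_community`.
#' @param medium medium id.
#' @param hours incubation time (default 120 h).
#' @param bulk_capacity vessel carrying capacity in cells (default 1e9).
#' @param inoculum_size total founding cells (default 1e6), split across
#'   strains in proportion to their abundances.
#' @return A `culture_outcome` with `mode = "bulk"`.
#' @export
grow_bulk <- function(community, medium, hours = 120, bulk_capacity = 1e9,
                      inoculum_size = 1e6) {
  stopifnot(inherits(community, "strain_community"))
  if (!medium %in% colnames(community$growth_rate))
    .err("dropstrain_config_error", "unknown medium id: %s", medium)
  .check_nonnegative(hours, "hours")
  if (bulk_capacity < 1 || inoculum_size <= 0)
    .err("dropstrain_domain_error", "capacity and inoculum must be positive")
  r <- community$growth_rate[, medium]
  n0 <- inoculum_size * community$strains$abundance
  names(n0) <- community$strains$strain
  if (hours == 0) return(.outcome(n0, community, medium, hours, "bulk"))
  sol <- deSolve::ode(y = unname(n0), times = c(0, hours), func = .lv_rhs,
                      parms = list(r = unname(r[names(n0)]),
                                   K = bulk_capacity))
  final <- stats::setNames(pmax(sol[nrow(sol), -1], 0), names(n0))
  .outcome(final, community, medium, hours, "bulk")
}

.outcome <- function(pooled, community, medium, hours, mode) {
  structure(list(counts = data.frame(strain = community$strains$strain,
                                     species = community$strains$species,
                                     count = unname(pooled[community$strains$strain]),
                                     stringsAsFactors = FALSE),
                 medium = medium, hours = hours, mode = mode),
            class = "culture_outcome")
}

#' Relative strain abundances of a culture outcome
#'
#' @param outcome a `culture_outcome`.
#' @return Named numeric vector of per-strain relative abundances.
#' @export
outcome_composition <- function(outcome) {
  stopifnot(inherits(outcome, "culture_outcome"))
  with(outcome$counts, stats::setNames(count / sum(count), strain))
}

#' @export
print.culture_outcome <- function(x, ...) {
  cat(sprintf("culture_outcome (%s, %s, %g h): %d strains, %.3g cells total\n",
              x$mode, x$medium, x$hours, nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}
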