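# Poisson single-cell loading design.
#
# When a dilute cell suspension is partitioned into monodisperse droplets,
# the number of cells per droplet follows a Poisson distribution with mean
# lambda = rho * V, where rho is the cell density (CFU/mL) and V the
# droplet volume (pL, converted to mL). These functions compute occupancy
# probabilities, expected droplet counts per occupancy class, and the
# suspension density required to hit a target lambda.

#' Droplet volume from diameter
#'
#' Volume of a spherical droplet, `(pi/6) d^3`, converted from cubic
#' micrometres to picolitres (1000 um^3 = 1 pL). A 30 um droplet is
#' approximately 14 pL.
#'
#' @param diameter_um droplet diameter in micrometres (> 0).
#' @return Volume in picolitres.
#' @examples
#' droplet_volume(30) # ~14.14 pL
#' @export
droplet_volume <- function(diameter_um) {
  .check_positive(diameter_um, "diameter_um")
  (pi / 6) * diameter_um^3 / .UM3_PER_PL
}

#' Expected cells per droplet (lambda = rho V)
#'
#' @param cell_density cell density rho in CFU/mL (>= 0).
#' @param volume_pl droplet volume V in picolitres (> 0).
#' @return lambda, the mean number of cells per droplet.
#' @examples
#' loading_lambda(2e7, 14) # 0.28, the lambda ~ 0.3 design point
#' @export
loading_lambda <- function(cell_density, volume_pl) {
  .check_nonnegative(cell_density, "cell_density")
  .check_positive(volume_pl, "volume_pl")
  cell_density * volume_pl / .PL_PER_ML
}

#' Poisson occupancy probability P(X = n)
#'
#' Probability that a droplet contains exactly `n` cells at loading rate
#' `lambda`, `exp(-lambda) lambda^n / n!`. Computed in log space (via
#' `lgamma`) so large `n` does not overflow the factorial.
#'
#' @param lambda mean cells per droplet (>= 0).
#' @param n occupancy, a non-negative integer (vectorised).
#' @return P(X = n).
#' @examples
#' occupancy_pmf(0.3, 1) # ~0.222: ~22% of droplets hold exactly one cell
#' @export
occupancy_pmf <- function(lambda, n) {
  .check_nonnegative(lambda, "lambda")
  if (any(n < 0) || any(n != floor(n)))
    .err("dropstrain_domain_error", "n must be a non-negative integer")
  if (lambda == 0) return(as.numeric(n == 0))
  exp(-lambda + n * log(lambda) - lgamma(n + 1))
}

#' Poisson tail probability P(X >= k)
#'
#' @param lambda mean cells per droplet (>= 0).
#' @param k occupancy threshold, a non-negative integer.
#' @return P(X >= k) = 1 - sum_{n < k} P(X = n).
#' @examples
#' prob_at_least(0.3, 2) # ~0.037: fewer than 5% of droplets multi-loaded
#' @export
prob_at_least <- function(lambda, k) {
  .check_nonnegative(lambda, "lambda")
  if (length(k) != 1L || k < 0 || k != floor(k))
    .err("dropstrain_domain_error", "k must be a non-negative integer")
  if (k == 0) return(1)
  1 - sum(occupancy_pmf(lambda, 0:(k - 1)))
}

#' Cell density required for a target loading rate
#'
#' Exact inverse of [loading_lambda()]: `rho = lambda / V` with V in mL.
#'
#' @param lambda_target target mean cells per droplet (> 0).
#' @param volume_pl droplet volume in picolitres (> 0).
#' @return Required density in CFU/mL.
#' @examples
#' required_density(0.3, 14) # ~2.14e7, i.e. dilute to ~2e7 CFU/mL
#' @export
required_density <- function(lambda_target, volume_pl) {
  .check_positive(lambda_target, "lambda_target")
  .check_positive(volume_pl, "volume_pl")
  lambda_target / (volume_pl / .PL_PER_ML)
}

#' Expected droplet counts by occupancy class
#'
#' Splits `n_droplets` into the expected numbers of empty, singly and
#' multiply occupied droplets at loading rate `lambda`.
#'
#' @param n_droplets total droplets generated (>= 0).
#' @param lambda mean cells per droplet.
#' @return Named numeric vector `c(empty, single, multiple)` summing to
#'   `n_droplets`.
#' @examples
#' expected_counts(2e8, 0.3) # ~4.4e7 single-cell droplets
#' @export
expected_counts <- function(n_droplets, lambda) {
  .check_nonnegative(n_droplets, "n_droplets")
  .check_nonnegative(lambda, "lambda")
  p0 <- occupancy_pmf(lambda, 0)
  p1 <- occupancy_pmf(lambda, 1)
  c(empty = n_droplets * p0,
    single = n_droplets * p1,
    multiple = n_droplets * (1 - p0 - p1))
}

#' Full occupancy distribution up to n_max
#'
#' @param lambda mean cells per droplet (>= 0).
#' @param n_max largest occupancy tabulated; defaults to `ceiling(lambda) + 40`,
#'   at which the tabulated mass is 1 to within 1e-9.
#' @return List with elements `lam` and `probs` (probabilities for
#'   occupancies `0:n_max`).
#' @export
occupancy_distribution <- function(lambda, n_max = ceiling(lambda) + 40L) {
  .check_nonnegative(lambda, "lambda")
  list(lam = lambda, probs = occupancy_pmf(lambda, 0:n_max))
}

#' Loading-design report for one droplet geometry
#'
#' Convenience wrapper producing the numbers needed to set up an
#' encapsulation run: droplet volume, achieved or target lambda, occupancy
#' class probabilities and the required suspension density. Supply either
#' `density` (the suspension you have) or `target_lambda` (the loading you
#' want).
#'
#' @param diameter_um droplet diameter in micrometres.
#' @param density available cell density in CFU/mL, or `NULL`.
#' @param target_lambda desired mean cells per droplet, or `NULL`.
#' @return One-row data.frame: `volume_pL`, `lambda`, `p_empty`,
#'   `p_single`, `p_multi`, `required_density_cfu_per_ml`.
#' @export
design_report <- function(diameter_um, density = NULL, target_lambda = NULL) {
  v <- droplet_volume(diameter_um)
  if (is.null(density) == is.null(target_lambda))
    .err("dropstrain_config_error",
         "supply exactly one of `density` or `target_lambda`")
  lam <- if (is.null(density)) target_lambda else loading_lambda(density, v)
  data.frame(volume_pL = v,
             lambda = lam,
             p_empty = occupancy_pmf(lam, 0),
             p_single = occupancy_pmf(lam, 1),
             p_multi = prob_at_least(lam, 2),
             required_density_cfu_per_ml = required_density(lam, v))
}
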