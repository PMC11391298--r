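#' Weibull dispersal kernel
#'
#' Dispersal events are drawn from a Weibull distribution with fixed shape
#' `phi = 2` and a scale `psi = 1 + 49 d` mapped linearly from the dispersal
#' trait, so `d = 0` gives psi = 1 (short, concentrated events) and `d = 1`
#' gives psi = 50 (long tails).
#'
#' @param d dispersal trait in `[0, 1]`.
#' @return list of class `isle_kernel` with fields `shape`, `scale`, `d`.
#' @export
dispersal_kernel <- function(d) {
  if (any(d < 0 | d > 1)) stop("d must lie in [0, 1]", call. = FALSE)
  structure(list(shape = 2, scale = 1 + 49 * d, d = d), class = "isle_kernel")
}

#' Species-level dispersal trait
#'
#' The population-size-weighted mean of the population dispersal traits;
#' falls back to the unweighted mean when all abundances are zero.
#'
#' @param n population abundances.
#' @param d population dispersal traits.
#' @export
species_dispersal_trait <- function(n, d) {
  stopifnot(length(n) == length(d), length(d) >= 1)
  if (sum(n) <= 0) mean(d) else sum(n * d) / sum(n)
}

#' Draw dispersal distances
#'
#' @param kernel an [dispersal_kernel()].
#' @param n number of draws.
#' @return positive dispersal distances.
#' @export
sample_dispersal <- function(kernel, n) {
  stats::rweibull(n, shape = kernel$shape, scale = kernel$scale)
}

#' Colonization of unoccupied suitable sites
#'
#' For each unoccupied suitable site one dispersal event is drawn and
#' compared to the minimal least-cost distance from any occupied site;
#' the site is colonized (arriving population size `arrival_n`) when the
#' event reaches that cost. The arrival copies its traits from the occupied
#' source achieving the minimal cost (ties: the most abundant source).
#'
#' @param occupied positions (row indices of `cost`) of the species'
#'   occupied sites.
#' @param targets positions of unoccupied suitable sites.
#' @param cost least-cost matrix over sites.
#' @param kernel an [dispersal_kernel()].
#' @param occupied_n abundances of the occupied sites (for tie-breaking);
#'   default equal.
#' @param draws optional pre-drawn dispersal events (length of `targets`),
#'   mainly for testing; default fresh Weibull draws.
#' @param arrival_n arriving population size (default 0.05).
#' @return tibble with one row per target: `site` (position), `cost`,
#'   `source` (position of the minimal-cost occupied site), `draw`,
#'   `success`, `n`.
#' @export
colonize <- function(occupied, targets, cost, kernel,
                     occupied_n = NULL, draws = NULL, arrival_n = 0.05) {
  if (length(occupied) == 0 || length(targets) == 0) {
    return(tibble::tibble(site = integer(0), cost = numeric(0),
                          source = integer(0), draw = numeric(0),
                          success = logical(0), n = numeric(0)))
  }
  if (is.null(occupied_n)) occupied_n <- rep(1, length(occupied))
  res <- colonize_core(occupied, targets, cost, kernel, occupied_n, draws)
  tibble::tibble(
    site = as.integer(targets),
    cost = res$cost,
    source = as.integer(res$source),
    draw = res$draw,
    success = res$success,
    n = ifelse(res$success, arrival_n, 0)
  )
}

# engine-facing colonization without the tibble wrapper
colonize_core <- function(occupied, targets, cost, kernel, occupied_n,
                          draws = NULL) {
  mins <- colonization_minima_cpp(cost, as.integer(occupied - 1L),
                                  as.integer(targets - 1L), occupied_n)
  if (is.null(draws)) draws <- sample_dispersal(kernel, length(targets))
  list(
    cost = mins$cost,
    source = occupied[mins$source],
    draw = draws,
    success = is.finite(mins$cost) & draws >= mins$cost
  )
}

#' Partition occupied sites into population clusters
#'
#' For every pair of occupied sites an independent dispersal event is
#' compared against the pairwise least-cost distance; clusters are the
#' connected components of the resulting graph (sites mutually reachable by
#' dispersal this time step).
#'
#' @inheritParams colonize
#' @param p_min pairs whose per-step connection probability falls below this
#'   threshold are treated as unconnected without sampling (default 1e-12).
#' @return integer vector of cluster ids (1-based), one per occupied site.
#' @export
population_clusters <- function(occupied, cost, kernel, p_min = 1e-12) {
  if (length(occupied) == 0) return(integer(0))
  cluster_partition_cpp(cost, as.integer(occupied - 1L), kernel$scale, p_min)
}
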