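#' Gaussian thermal niche response
#'
#' Growth response of a population to an environmental temperature on the
#' normalized scale: `(1/omega) * exp(-(t_env - t_opt)^2 / (2 omega^2))`.
#' The height `1/omega` imposes the specialist-generalist trade-off: narrow
#' thermal ranges grow fast near the optimum, wide ranges grow slowly
#' everywhere.
#'
#' @param t_env environmental temperature, normalized scale.
#' @param t_opt thermal optimum in `[0, 1]` (1 = warmest available).
#' @param omega thermal range in `(0, 1]`.
#' @return numeric response value(s).
#' @export
niche_response <- function(t_env, t_opt, omega) {
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  (1 / omega) * exp(-(t_env - t_opt)^2 / (2 * omega^2))
}

#' Maximum per-capita growth rate at a site
#'
#' Combines the niche response at the site's minimum and maximum temperature
#' with the species-independent growth constant `g`:
#' `r = g * n(tmin) * n(tmax)` (the default), or the geometric-mean variant
#' `r = g * sqrt(n(tmin) * n(tmax))`.
#'
#' @param tmin_env,tmax_env site temperature extremes, normalized scale.
#' @param t_opt,omega thermal niche traits.
#' @param g growth constant (default 0.1).
#' @param combiner `"product"` (default) or `"geometric_mean"`.
#' @return non-negative growth rate(s), per 5-year ecological time step.
#' @export
growth_rate <- function(tmin_env, tmax_env, t_opt, omega, g = 0.1,
                        combiner = c("product", "geometric_mean")) {
  combiner <- match.arg(combiner)
  prod <- niche_response(tmin_env, t_opt, omega) *
    niche_response(tmax_env, t_opt, omega)
  if (combiner == "geometric_mean") g * sqrt(prod) else g * prod
}

#' Heterospecific competition coefficient from the tolerance trait
#'
#' `alpha_fh = alpha_max * (1 - l)`: full tolerance (`l = 1`) removes
#' heterospecific competition; zero tolerance gives the maximal coefficient.
#'
#' @param l tolerance to other species in `[0, 1]`.
#' @param alpha_max maximal heterospecific coefficient (default 0.1).
#' @export
tolerance_to_alpha <- function(l, alpha_max = 0.1) {
  if (any(l < 0 | l > 1)) stop("l must lie in [0, 1]", call. = FALSE)
  alpha_max * (1 - l)
}

#' Analytic Lotka-Volterra diffuse-competition equilibrium
#'
#' Solves the within-site coexistence equilibrium of
#' `dN_f/dt / N_f = r_f - alpha_ff N_f - alpha_fh sum_{k != f} N_k`
#' in closed form: with `Ntot = sum_f r_f / (alpha_ff - alpha_fh_f)` divided
#' by `1 + sum_f alpha_fh_f / (alpha_ff - alpha_fh_f)`, each species'
#' abundance is `(r_f - alpha_fh_f Ntot) / (alpha_ff - alpha_fh_f)`. While
#' any candidate abundance is negative, the most negative one is
#' competitively excluded (set to zero) and the remaining community
#' re-solved. The result does not depend on the input ordering.
#'
#' @param community data frame with columns `r` (growth rate) and `alpha_fh`
#'   (heterospecific coefficient experienced by that species), one row per
#'   species; extra columns are carried through.
#' @param alpha_ff conspecific coefficient; must exceed every `alpha_fh`.
#' @return the input as a tibble with an added column `n` of equilibrium
#'   abundances (hundreds of implicit individuals per km^2), zero for
#'   excluded species.
#' @export
equilibrium_abundances <- function(community, alpha_ff = 0.2) {
  community <- tibble::as_tibble(community)
  if (nrow(community) == 0) {
    return(dplyr::mutate(community, n = numeric(0)))
  }
  if (any(community$alpha_fh >= alpha_ff)) {
    stop("alpha_ff must exceed every alpha_fh for a stable equilibrium",
         call. = FALSE)
  }
  community$n <- lv_equilibrium_cpp(community$r, community$alpha_fh, alpha_ff)
  community
}
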