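# Trait vectors are rows of a numeric matrix with columns t_opt, omega, d, l.

trait_names <- c("t_opt", "omega", "d", "l")

#' Full trait homogenization within a population cluster
#'
#' All connected populations receive the population-size-weighted average of
#' each trait as their new value; the unweighted mean is used when the total
#' abundance is zero.
#'
#' @param traits numeric matrix (populations x traits) or data frame with
#'   columns `t_opt`, `omega`, `d`, `l`.
#' @param n population abundances.
#' @return named numeric vector: the cluster's homogenized trait values.
#' @export
homogenize_traits <- function(traits, n) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) >= 1, nrow(traits) == length(n))
  w <- if (sum(n) <= 0) rep(1 / length(n), length(n)) else n / sum(n)
  colSums(traits * w)
}

#' Partial trait homogenization
#'
#' Each population is pulled halfway towards the cluster's weighted mean:
#' `x <- (x + mean) / 2`. Repeated application converges geometrically to
#' full homogenization while preserving within-cluster variation.
#'
#' @inheritParams homogenize_traits
#' @return matrix of the same shape with updated per-population traits.
#' @export
partial_homogenize_traits <- function(traits, n) {
  traits <- as.matrix(traits)
  centre <- homogenize_traits(traits, n)
  (traits + matrix(centre, nrow(traits), ncol(traits), byrow = TRUE)) / 2
}

#' Non-directional trait mutation
#'
#' Adds independent Gaussian increments (mean zero, standard deviation `sd`)
#' to each trait of each population, then clips to the trait bounds `[0, 1]`
#' (`omega` is floored at `omega_floor` to keep the niche response finite).
#'
#' @inheritParams homogenize_traits
#' @param sd mutation standard deviation on the trait scale (default 0.001).
#' @param evolve logical vector naming which traits mutate; defaults to all.
#'   Under the fixed-trait model the dispersal and tolerance entries are
#'   switched off.
#' @param omega_floor lower bound for the thermal range.
#' @return matrix of mutated traits.
#' @export
mutate_traits <- function(traits, sd = 0.001,
                          evolve = c(t_opt = TRUE, omega = TRUE, d = TRUE, l = TRUE),
                          omega_floor = 1e-3) {
  traits <- as.matrix(traits)
  if (sd > 0) {
    k <- which(evolve[colnames(traits)])
    noise <- matrix(stats::rnorm(nrow(traits) * length(k), 0, sd),
                    nrow(traits), length(k))
    traits[, k] <- traits[, k] + noise
  }
  traits[] <- pmin(1, pmax(0, traits))
  traits[, "omega"] <- pmax(omega_floor, traits[, "omega"])
  traits
}

#' Dispersal-competition trade-off surface
#'
#' The boundary in `(d, l)` space separating physiologically plausible
#' combinations (on or below) from implausible ones (above). The default is
#' the linear boundary `d + l = 1`; a concave power-law family
#' `d^a + l^a = 1` is available via `exponent`.
#'
#' @param type `"linear"` or `"power"`.
#' @param exponent exponent `a` for the power boundary (ignored for linear).
#' @param jitter_sd standard deviation of the random tangential displacement
#'   applied after projection (default 0.01).
#' @return list of class `isle_tradeoff`.
#' @export
tradeoff_surface <- function(type = c("linear", "power"), exponent = 2,
                             jitter_sd = 0.01) {
  type <- match.arg(type)
  structure(list(type = type, exponent = exponent, jitter_sd = jitter_sd),
            class = "isle_tradeoff")
}

tradeoff_excess <- function(d, l, surface) {
  if (surface$type == "linear") d + l - 1 else d^surface$exponent + l^surface$exponent - 1
}

#' Project trait combinations back onto the trade-off surface
#'
#' Plausible `(d, l)` points are returned unchanged; implausible points are
#' mapped to the nearest boundary point and displaced by a small random
#' tangential jitter ("randomly to the closest possible combinations"),
#' then clamped so the result is plausible and in bounds.
#'
#' @param d,l trait vectors in `[0, 1]`.
#' @param surface an [tradeoff_surface()].
#' @return tibble with columns `d` and `l`.
#' @export
tradeoff_project <- function(d, l, surface = tradeoff_surface()) {
  stopifnot(length(d) == length(l))
  bad <- tradeoff_excess(d, l, surface) > 1e-12
  if (any(bad)) {
    if (surface$type == "linear") {
      excess <- (d[bad] + l[bad] - 1) / 2
      pd <- d[bad] - excess
      pl <- l[bad] - excess
    } else {
      a <- surface$exponent
      proj1 <- function(x, y) {
        f <- function(t) (t - x)^2 + ((1 - t^a)^(1 / a) - y)^2
        t <- stats::optimize(f, c(0, 1))$minimum
        c(t, (1 - t^a)^(1 / a))
      }
      p <- vapply(which(bad), function(i) proj1(d[i], l[i]), numeric(2))
      pd <- p[1, ]
      pl <- p[2, ]
    }
    if (surface$jitter_sd > 0) {
      eps <- stats::rnorm(sum(bad), 0, surface$jitter_sd)
      pd <- pd + eps / sqrt(2)
      pl <- pl - eps / sqrt(2)
    }
    pd <- pmin(1, pmax(0, pd))
    pl <- pmin(1, pmax(0, pl))
    over <- tradeoff_excess(pd, pl, surface) > 0
    if (any(over)) {
      if (surface$type == "linear") {
        pl[over] <- 1 - pd[over]
      } else {
        pl[over] <- (1 - pd[over]^surface$exponent)^(1 / surface$exponent)
      }
    }
    d[bad] <- pd
    l[bad] <- pl
  }
  tibble::tibble(d = d, l = l)
}
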