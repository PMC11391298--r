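#' Simulation configuration
#'
#' Parameters for one simulation run. The three model variants differ in how
#' the dispersal (`d`) and tolerance (`l`) traits behave: `M0` keeps them
#' fixed at their initial values, `ME` lets them evolve freely, `MET` lets
#' them evolve under the dispersal-competition trade-off surface.
#'
#' @param model `"M0"`, `"ME"` or `"MET"`.
#' @param d_init,l_init initial dispersal and tolerance traits in `[0, 1]`
#'   (one factorial point).
#' @param s_threshold speciation threshold in time steps (default 65, i.e.
#'   650 kyr of uninterrupted isolation).
#' @param homogenization `"full"` (connected populations receive the
#'   weighted-average traits) or `"partial"` (populations are pulled halfway
#'   towards the average).
#' @param g species-independent growth constant.
#' @param alpha_ff conspecific competition coefficient.
#' @param alpha_max heterospecific coefficient at zero tolerance.
#' @param omega_init initial thermal range.
#' @param arrival_n arriving population size.
#' @param n_min minimum viable population size; equilibrium populations
#'   below this are removed (default: the propagule size `arrival_n`).
#' @param mutation_sd trait mutation standard deviation per step.
#' @param alpha_mutation_sd mutation s.d. of the tolerance trait expressed
#'   on the `alpha_fh` scale (default 0.01, i.e. `0.1` on the `l` scale);
#'   set `NULL` to mutate `l` with `mutation_sd` like the other traits.
#'   Only relevant when `l` evolves (`ME`, `MET`).
#' @param omega_floor lower bound of the thermal range.
#' @param growth_combiner see [growth_rate()].
#' @param tradeoff an [tradeoff_surface()] (used by `MET`).
#' @param p_min probability floor for pairwise cluster sampling.
#' @param rng_seed seed for the run.
#' @return list of class `isle_sim_config`.
#' @export
simulation_config <- function(model = c("M0", "ME", "MET"),
                              d_init = 0.3, l_init = 1,
                              s_threshold = 65L,
                              homogenization = c("full", "partial"),
                              g = 0.1, alpha_ff = 0.2, alpha_max = 0.1,
                              omega_init = 0.4, arrival_n = 0.05,
                              n_min = arrival_n,
                              mutation_sd = 0.001,
                              alpha_mutation_sd = 0.01,
                              omega_floor = 1e-3,
                              growth_combiner = c("product", "geometric_mean"),
                              tradeoff = tradeoff_surface(),
                              p_min = 1e-12,
                              rng_seed = 1L) {
  cfg <- list(
    model = match.arg(model),
    d_init = d_init, l_init = l_init,
    s_threshold = as.integer(s_threshold),
    homogenization = match.arg(homogenization),
    g = g, alpha_ff = alpha_ff, alpha_max = alpha_max,
    omega_init = omega_init, arrival_n = arrival_n, n_min = n_min,
    mutation_sd = mutation_sd, alpha_mutation_sd = alpha_mutation_sd,
    omega_floor = omega_floor,
    growth_combiner = match.arg(growth_combiner),
    tradeoff = tradeoff, p_min = p_min,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$d_init >= 0, cfg$d_init <= 1, cfg$l_init >= 0, cfg$l_init <= 1,
    cfg$s_threshold >= 1, cfg$alpha_ff > cfg$alpha_max,
    cfg$omega_init > 0, cfg$omega_init <= 1
  )
  class(cfg) <- "isle_sim_config"
  cfg
}

# cached per-step geometry: suitable sites, least-cost matrix, normalized
# temperatures and static island assignment of the suitable sites
step_geometry <- function(landscape, step) {
  man <- landscape$manifest
  key <- sprintf("g_%.6f_%.6f", man$sea_level[step], man$d_uplift[step])
  hit <- landscape$cache[[key]]
  if (is.null(hit)) {
    hit <- cost_matrix(landscape, step)
  }
  if (is.null(hit$tmin)) {
    temps <- site_temperatures(landscape, step)
    rng <- landscape$config$temp_range_c
    hit$tmin <- norm_temperature(temps$tmin[hit$sites], rng)
    hit$tmax <- norm_temperature(temps$tmax[hit$sites], rng)
    hit$island <- landscape$topo$island_map[hit$sites]
    assign(key, hit, envir = landscape$cache)
  }
  hit
}

evolve_flags <- function(model) {
  c(t_opt = TRUE, omega = TRUE, d = model != "M0", l = model != "M0")
}

#' Initialize the simulated world
#'
#' Places three founding species on islands A, B and C: populations of the
#' arrival size on every suitable site of the respective island, thermal
#' optimum equal to the normalized mean site temperature, thermal range
#' `omega_init`, and dispersal/tolerance traits from the configuration
#' (projected onto the trade-off surface under `MET`). A first ecological
#' equilibrium pass is applied.
#'
#' @param config an [simulation_config()].
#' @param landscape an `isle_landscape` whose first step has three islands.
#' @return world state (list), see [run_simulation()].
#' @export
initialize_world <- function(config, landscape) {
  if (n_islands(landscape, 1) != 3) {
    stop("landscape must have exactly 3 islands at the first step", call. = FALSE)
  }
  geom <- step_geometry(landscape, 1)
  labels <- island_labels(landscape, 1)
  centres <- landscape$topo$centres

  dl <- c(config$d_init, config$l_init)
  if (config$model == "MET") {
    proj <- tradeoff_project(dl[1], dl[2], config$tradeoff)
    dl <- c(proj$d[1], proj$l[1])
  }

  species <- list()
  for (k in 1:3) {
    isl <- c("A", "B", "C")[k]
    centre_cell <- centres[isl, "x"] + (centres[isl, "y"] - 1) * landscape$config$grid[1]
    comp <- labels[centre_cell]
    sites <- which(!is.na(labels) & labels == comp)
    pos <- match(sites, geom$sites)
    tmid <- (geom$tmin[pos] + geom$tmax[pos]) / 2
    traits <- cbind(t_opt = tmid, omega = config$omega_init,
                    d = dl[1], l = dl[2])
    species[[as.character(k)]] <- list(
      id = k, sites = sites, n = rep(config$arrival_n, length(sites)),
      traits = traits, deme = rep(1L, length(sites)),
      div = matrix(0L, 1, 1), cluster = rep(1L, length(sites))
    )
  }

  state <- list(
    species = species,
    phylo = new_phylogeny(1:3, step = 1L),
    events = list(),
    next_id = 4L,
    step = 1L
  )
  apply_ecology(state, geom, config)
}

site_islands <- function(geom, pos) unique(geom$island[pos])

add_event <- function(state, step, event, species, parent, islands, type) {
  state$events[[length(state$events) + 1]] <- tibble::tibble(
    step = step, event = event, species = species,
    parent = parent, islands = paste(sort(islands), collapse = ","),
    type = type
  )
  state
}

# Ecological phase: per-site Lotka-Volterra equilibria across all species;
# populations below the viability threshold are removed and species left
# without populations are recorded extinct.
apply_ecology <- function(state, geom, config, step = state$step) {
  sp <- state$species
  if (length(sp) == 0) return(state)
  lens <- vapply(sp, function(s) length(s$sites), integer(1))
  sp_row <- rep(seq_along(sp), lens)
  pos <- unlist(lapply(sp, function(s) match(s$sites, geom$sites)), use.names = FALSE)
  t_opt <- unlist(lapply(sp, function(s) s$traits[, "t_opt"]), use.names = FALSE)
  omega <- unlist(lapply(sp, function(s) s$traits[, "omega"]), use.names = FALSE)
  lvec <- unlist(lapply(sp, function(s) s$traits[, "l"]), use.names = FALSE)

  r <- growth_rate(geom$tmin[pos], geom$tmax[pos], t_opt, omega,
                   g = config$g, combiner = config$growth_combiner)
  afh <- tolerance_to_alpha(lvec, config$alpha_max)

  ord <- order(pos)
  first <- c(0L, cumsum(tabulate(pos[ord])[unique(pos[ord])]))
  n_eq <- numeric(length(pos))
  n_eq[ord] <- lv_equilibrium_groups_cpp(r[ord], afh[ord], as.integer(first),
                                         config$alpha_ff)

  offset <- c(0L, cumsum(lens))
  for (i in seq_along(sp)) {
    rows <- (offset[i] + 1):offset[i + 1]
    if (lens[i] == 0) next
    ni <- n_eq[rows]
    keep <- ni >= config$n_min & ni > 0
    s <- sp[[i]]
    if (!any(keep)) {
      isl <- site_islands(geom, match(s$sites, geom$sites))
      state <- add_event(state, step, "extinction", s$id, NA_integer_, isl, NA_character_)
      state$phylo <- record_extinction(state$phylo, s$id, step)
      sp[i] <- list(NULL)
      next
    }
    s$n <- ni[keep]
    s$sites <- s$sites[keep]
    s$traits <- s$traits[keep, , drop = FALSE]
    s$cluster <- s$cluster[keep]
    s$deme <- s$deme[keep]
    s <- compact_demes(s)
    sp[[i]] <- s
  }
  state$species <- sp[!vapply(sp, is.null, logical(1))]
  state
}

# drop demes that lost all populations; relabel compactly
compact_demes <- function(s) {
  present <- sort(unique(s$deme))
  if (length(present) < nrow(s$div)) {
    s$div <- s$div[present, present, drop = FALSE]
    s$deme <- match(s$deme, present)
  }
  s
}

# Phase 1: divergence update and speciation on the previous step's clusters.
phase_speciation <- function(state, geom, config, step) {
  out <- list()
  for (s in state$species) {
    k <- nrow(s$div)
    if (k > 1) {
      membership <- vapply(seq_len(k), function(dd) s$cluster[match(dd, s$deme)],
                           integer(1))
      s$div <- update_divergence(s$div, membership)
      comp <- speciate(s$div, config$s_threshold)
      if (max(comp) > 1) {
        totals <- vapply(seq_len(max(comp)), function(ci) {
          sum(s$n[s$deme %in% which(comp == ci)])
        }, numeric(1))
        keep_comp <- which.max(totals)
        parent_rows <- s$deme %in% which(comp == keep_comp)
        parent_isl <- site_islands(geom, match(s$sites[parent_rows], geom$sites))
        for (ci in seq_len(max(comp))) {
          demes_ci <- which(comp == ci)
          rows <- s$deme %in% demes_ci
          child <- list(
            id = if (ci == keep_comp) s$id else state$next_id,
            sites = s$sites[rows], n = s$n[rows],
            traits = s$traits[rows, , drop = FALSE],
            deme = match(s$deme[rows], demes_ci),
            div = s$div[demes_ci, demes_ci, drop = FALSE],
            cluster = s$cluster[rows]
          )
          if (ci != keep_comp) {
            child_isl <- site_islands(geom, match(child$sites, geom$sites))
            state$phylo <- record_speciation(state$phylo, child$id, s$id, step)
            state <- add_event(state, step, "speciation", child$id, s$id,
                               union(child_isl, parent_isl),
                               if (length(union(child_isl, parent_isl)) > 1)
                                 "between" else "within")
            state$next_id <- state$next_id + 1L
          }
          out[[as.character(child$id)]] <- child
        }
        next
      }
      # demes that re-homogenized (zero divergence within one cluster) merge
      zero <- s$div == 0L & outer(membership, membership, `==`)
      diag(zero) <- TRUE
      pairs <- which(zero & upper.tri(zero), arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        g <- igraph::make_empty_graph(n = k, directed = FALSE)
        g <- igraph::add_edges(g, t(pairs))
        groups <- as.integer(igraph::components(g)$membership)
        if (max(groups) < k) {
          wts <- vapply(seq_len(k), function(dd) sum(s$n[s$deme == dd]), numeric(1))
          s$div <- merge_divergence(s$div, groups, wts)
          ug <- unique(groups)
          s$deme <- match(groups[s$deme], ug)
        }
      }
    }
    out[[as.character(s$id)]] <- s
  }
  state$species <- out
  state
}

# Phase 2: colonization of unoccupied suitable sites, then re-clustering and
# deme bookkeeping.
phase_dispersal <- function(state, geom, config) {
  nsuit <- length(geom$sites)
  for (nm in names(state$species)) {
    s <- state$species[[nm]]
    pos <- match(s$sites, geom$sites)
    d_bar <- species_dispersal_trait(s$n, s$traits[, "d"])
    kernel <- dispersal_kernel(d_bar)

    occ <- logical(nsuit)
    occ[pos] <- TRUE
    targets <- which(!occ)
    if (length(targets) > 0) {
      col <- colonize_core(pos, targets, geom$cost, kernel, s$n)
      hit <- which(col$success)
      if (length(hit) > 0) {
        src_row <- match(col$source[hit], pos)
        new_sites <- targets[hit]
        s$sites <- c(s$sites, geom$sites[new_sites])
        s$n <- c(s$n, rep(config$arrival_n, length(hit)))
        s$traits <- rbind(s$traits, s$traits[src_row, , drop = FALSE])
        s$deme <- c(s$deme, s$deme[src_row])
        s$cluster <- c(s$cluster, s$cluster[src_row])
        pos <- c(pos, new_sites)
      }
    }

    s$cluster <- population_clusters(pos, geom$cost, kernel, config$p_min)

    # a deme split across clusters becomes several demes (mutual divergence 0)
    combo <- s$deme * (max(s$cluster) + 1L) + s$cluster
    ucombo <- unique(combo)
    if (length(ucombo) > nrow(s$div) || length(ucombo) > length(unique(s$deme))) {
      parents <- s$deme[match(ucombo, combo)]
      s$div <- split_divergence(s$div, parents)
      s$deme <- match(combo, ucombo)
    }
    state$species[[nm]] <- s
  }
  state
}

# Phase 3: trait homogenization within clusters, mutation, and (MET) the
# trade-off projection.
phase_traits <- function(state, config) {
  evolve <- evolve_flags(config$model)
  sd_vec <- rep(config$mutation_sd, 4)
  names(sd_vec) <- trait_names
  if (!is.null(config$alpha_mutation_sd)) {
    sd_vec["l"] <- config$alpha_mutation_sd / config$alpha_max
  }
  for (nm in names(state$species)) {
    s <- state$species[[nm]]
    cl <- s$cluster
    wsum <- rowsum(s$traits * s$n, cl)
    ntot <- rowsum(s$n, cl)
    cnt <- rowsum(rep(1, length(cl)), cl)
    zero <- ntot[, 1] <= 0
    means <- wsum / ntot[, 1]
    if (any(zero)) {
      means[zero, ] <- rowsum(s$traits, cl)[zero, , drop = FALSE] / cnt[zero, 1]
    }
    assigned <- means[match(cl, as.integer(rownames(means))), , drop = FALSE]
    frozen <- s$traits[, !evolve, drop = FALSE]
    s$traits <- if (config$homogenization == "full") assigned
                else (s$traits + assigned) / 2
    colnames(s$traits) <- trait_names
    # non-evolving traits are uniform within a species; skipping their
    # homogenization keeps them bit-identical to the initial values
    s$traits[, !evolve] <- frozen

    s$traits <- mutate_traits_vec(s$traits, sd_vec, evolve, config$omega_floor)
    if (config$model == "MET") {
      proj <- tradeoff_project(s$traits[, "d"], s$traits[, "l"], config$tradeoff)
      s$traits[, "d"] <- proj$d
      s$traits[, "l"] <- proj$l
    }
    state$species[[nm]] <- s
  }
  state
}

# per-trait mutation sds (engine-internal; mutate_traits() is the scalar API)
mutate_traits_vec <- function(traits, sd_vec, evolve, omega_floor) {
  for (tn in trait_names) {
    if (!evolve[[tn]] || sd_vec[[tn]] <= 0) next
    traits[, tn] <- traits[, tn] + stats::rnorm(nrow(traits), 0, sd_vec[[tn]])
  }
  traits[] <- pmin(1, pmax(0, traits))
  traits[, "omega"] <- pmax(omega_floor, traits[, "omega"])
  traits
}

# Phase 0: the landscape advances; populations on newly submerged sites die.
phase_submergence <- function(state, geom, config, step, imap) {
  for (nm in names(state$species)) {
    s <- state$species[[nm]]
    keep <- s$sites %in% geom$sites
    if (all(keep)) next
    if (!any(keep)) {
      state <- add_event(state, step, "extinction", s$id, NA_integer_,
                         unique(imap[s$sites]), NA_character_)
      state$phylo <- record_extinction(state$phylo, s$id, step)
      state$species[[nm]] <- NULL
      next
    }
    s$sites <- s$sites[keep]
    s$n <- s$n[keep]
    s$traits <- s$traits[keep, , drop = FALSE]
    s$deme <- s$deme[keep]
    s$cluster <- s$cluster[keep]
    s <- compact_demes(s)
    state$species[[nm]] <- s
  }
  state
}

#' Advance the world by one time step
#'
#' Executes, in order: (1) divergence update and speciation on the previous
#' step's population clusters; (2) dispersal (colonization, then
#' re-clustering); (3) trait homogenization, mutation and, under `MET`, the
#' trade-off projection; (4) per-site ecological equilibria, removal of
#' non-viable populations and extinction bookkeeping. Populations on sites
#' submerged by the advancing sea level are vacated as the step begins.
#'
#' @param state world state.
#' @param landscape an `isle_landscape`.
#' @param config an [simulation_config()].
#' @param step landscape step to advance to (default `state$step + 1`).
#' @return updated world state.
#' @export
step_world <- function(state, landscape, config, step = state$step + 1L) {
  geom <- step_geometry(landscape, step)
  state <- phase_submergence(state, geom, config, step, landscape$topo$island_map)
  state <- phase_speciation(state, geom, config, step)
  state <- phase_dispersal(state, geom, config)
  state <- phase_traits(state, config)
  state <- apply_ecology(state, geom, config, step)
  state$step <- step
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulation
#'
#' Initializes the world on the landscape's first step and advances it to
#' the final step. Deterministic given `rng_seed`.
#'
#' @param config an [simulation_config()].
#' @param landscape an `isle_landscape`.
#' @param keep_series record the per-step summary time series (default TRUE).
#' @return object of class `isle_sim`: a list with the final `species`
#'   tables, `phylo` lineage tibble, `events` tibble, per-step `series`
#'   tibble, the configurations, and `n_steps`.
#' @export
run_simulation <- function(config, landscape, keep_series = TRUE) {
  set.seed(config$rng_seed)
  n_steps <- landscape$config$n_steps
  state <- initialize_world(config, landscape)

  series <- if (keep_series) {
    matrix(NA_real_, n_steps, 5,
           dimnames = list(NULL, c("n_species", "n_populations",
                                   "mean_d", "mean_l", "mean_omega")))
  }
  record <- function(state, t) {
    if (is.null(series)) return()
    ns <- length(state$species)
    npop <- sum(vapply(state$species, function(s) length(s$sites), integer(1)))
    tr <- if (ns > 0) {
      m <- do.call(rbind, lapply(state$species, function(s) s$traits))
      colMeans(m)
    } else c(t_opt = NA, omega = NA, d = NA, l = NA)
    series[t, ] <<- c(ns, npop, tr[["d"]], tr[["l"]], tr[["omega"]])
  }
  record(state, 1L)

  if (n_steps > 1) {
    for (t in 2:n_steps) {
      state <- step_world(state, landscape, config, t)
      record(state, t)
    }
  }

  events <- if (length(state$events) > 0) {
    dplyr::bind_rows(state$events)
  } else {
    tibble::tibble(step = integer(0), event = character(0),
                   species = integer(0), parent = integer(0),
                   islands = character(0), type = character(0))
  }

  geom_final <- step_geometry(landscape, n_steps)
  island_sites <- table(factor(geom_final$island, levels = c("A", "B", "C", "D")))

  structure(
    list(
      config = config,
      landscape_config = landscape$config,
      final_island_sites = stats::setNames(as.integer(island_sites),
                                           names(island_sites)),
      n_suitable_final = length(geom_final$sites),
      species = species_table(state, landscape),
      phylo = state$phylo,
      events = events,
      series = if (keep_series) {
        tibble::as_tibble(series) |>
          dplyr::mutate(step = dplyr::row_number(), .before = 1)
      },
      n_steps = n_steps
    ),
    class = "isle_sim"
  )
}

# final state as a tidy per-population table
species_table <- function(state, landscape) {
  imap <- landscape$topo$island_map
  nx <- landscape$config$grid[1]
  rows <- lapply(state$species, function(s) {
    tibble::tibble(
      species = s$id,
      site = s$sites,
      x = ((s$sites - 1) %% nx) + 1,
      y = ((s$sites - 1) %/% nx) + 1,
      island = imap[s$sites],
      n = s$n,
      t_opt = s$traits[, "t_opt"],
      omega = s$traits[, "omega"],
      d = s$traits[, "d"],
      l = s$traits[, "l"],
      cluster = s$cluster
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.isle_sim <- function(x, ...) {
  cat("<isle_sim> model", x$config$model,
      sprintf("(d=%.2f, l=%.2f, seed=%d)", x$config$d_init, x$config$l_init,
              x$config$rng_seed), "\n")
  cat("  ", x$n_steps, "steps;", length(unique(x$species$species)),
      "extant species;", nrow(x$events), "events\n")
  invisible(x)
}

#' Internal consistency audit of a world state
#'
#' Checks that populations sit on suitable sites, cluster and deme labels
#' are complete, divergence matrices are symmetric with zero diagonal and
#' match the deme count, and the phylogeny covers all living species.
#' Intended for tests.
#'
#' @param state world state.
#' @param landscape an `isle_landscape`.
#' @param step landscape step the state refers to.
#' @return TRUE (invisibly); errors on any violation.
#' @export
audit_state <- function(state, landscape, step = state$step) {
  geom <- step_geometry(landscape, step)
  for (s in state$species) {
    stopifnot(
      all(s$sites %in% geom$sites),
      all(s$n > 0),
      length(s$n) == length(s$sites),
      nrow(s$traits) == length(s$sites),
      length(s$deme) == length(s$sites),
      all(s$deme >= 1), all(s$deme <= nrow(s$div)),
      all(sort(unique(s$deme)) == seq_len(nrow(s$div))),
      isTRUE(all.equal(s$div, t(s$div))),
      all(diag(s$div) == 0), all(s$div >= 0),
      s$id %in% state$phylo$lineage
    )
    # every deme lies within a single cluster
    for (dd in seq_len(nrow(s$div))) {
      stopifnot(length(unique(s$cluster[s$deme == dd])) == 1)
    }
  }
  extant <- state$phylo$lineage[is.na(state$phylo$death_step)]
  living <- vapply(state$species, function(s) s$id, integer(1))
  stopifnot(setequal(extant, living))
  invisible(TRUE)
}
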