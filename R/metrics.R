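#' Gamma diversity
#'
#' Final regional taxonomic richness: the number of species alive at the
#' last time step.
#'
#' @param sim an `isle_sim` result.
#' @export
gamma_diversity <- function(sim) {
  sum(is.na(sim$phylo$death_step))
}

#' Proportional Whittaker turnover across islands
#'
#' `beta = 1 - mean(alpha_i / gamma)` over islands, where `alpha_i` is the
#' species richness of island `i`. Zero means every island hosts the whole
#' regional species pool.
#'
#' @param island_richness per-island species richness (islands with
#'   suitable sites, including unoccupied ones).
#' @param gamma regional richness.
#' @return proportion in `[0, 1]`, or `NA` when `gamma` is zero.
#' @export
beta_whittaker <- function(island_richness, gamma) {
  if (length(island_richness) == 0 || is.na(gamma) || gamma == 0) return(NA_real_)
  1 - mean(island_richness / gamma)
}

#' Mean local (per-site) richness
#'
#' @param sim an `isle_sim` result.
#' @param over average over `"suitable"` sites (default; empty sites count
#'   zero) or `"occupied"` sites only.
#' @export
alpha_mean <- function(sim, over = c("suitable", "occupied")) {
  over <- match.arg(over)
  if (nrow(sim$species) == 0) return(0)
  per_site <- dplyr::count(sim$species, .data$site)
  if (over == "occupied") return(mean(per_site$n))
  sum(per_site$n) / sim$n_suitable_final
}

# root-path pieces of one extant lineage: for each ancestor lineage the
# interval [birth, branch-off]; on its own lineage [birth, final step]
lineage_path <- function(phylo, tip, final_step) {
  pieces <- list()
  lin <- tip
  end <- final_step
  repeat {
    i <- which(phylo$lineage == lin)
    pieces[[length(pieces) + 1]] <- c(lin, phylo$birth_step[i], end)
    par <- phylo$parent[i]
    if (is.na(par) || !(par %in% phylo$lineage)) break
    end <- phylo$birth_step[i]
    lin <- par
  }
  do.call(rbind, pieces)
}

# Faith's PD of a species set on the lineage table (in steps). All pieces on
# one lineage start at its birth, so their union is [birth, max end].
community_pd_steps <- function(phylo, species, final_step, include_root = TRUE) {
  if (length(species) == 0) return(0)
  pieces <- do.call(rbind, lapply(species, lineage_path,
                                  phylo = phylo, final_step = final_step))
  ends <- tapply(pieces[, 3], pieces[, 1], max)
  births <- phylo$birth_step[match(as.integer(names(ends)), phylo$lineage)]
  pd <- sum(ends - births)
  if (!include_root) {
    pd <- pd - root_chain_steps(phylo, as.integer(names(ends)), births, ends)
  }
  pd
}

# length of the unbranched basal chain(s) from each founder root down to the
# first node where the spanning subtree branches
root_chain_steps <- function(phylo, lineages, births, ends) {
  in_union <- function(l) l %in% lineages
  total <- 0
  roots <- lineages[is.na(phylo$parent[match(lineages, phylo$lineage)]) |
                      !(phylo$parent[match(lineages, phylo$lineage)] %in% lineages)]
  for (r in roots) {
    lin <- r
    a <- births[match(lin, lineages)]
    repeat {
      e <- ends[match(lin, lineages)]
      kids <- phylo$lineage[!is.na(phylo$parent) & phylo$parent == lin]
      kids <- kids[in_union(kids)]
      kb <- phylo$birth_step[match(kids, phylo$lineage)]
      kb <- kb[kb > a & kb <= e]
      if (length(kb) == 0) { total <- total + (e - a); break }
      b <- min(kb)
      n_branches <- sum(kb == b) + as.integer(e > b)
      total <- total + (b - a)
      if (n_branches >= 2) break
      lin <- kids[which.min(kb)]
      a <- b
    }
  }
  total
}

#' Mean per-site phylogenetic diversity
#'
#' For each site, the total branch length (Myr) of the minimal subtree of
#' the extant-pruned phylogeny spanning the site's community - by default
#' including the path to the root (Faith's convention) - averaged over
#' sites.
#'
#' @param sim an `isle_sim` result.
#' @param include_root include the root path (default TRUE).
#' @param over average over `"occupied"` sites (default) or `"suitable"`
#'   sites (empty sites contribute zero).
#' @param step_myr duration of one step in Myr.
#' @export
pd_mean <- function(sim, include_root = TRUE, over = c("occupied", "suitable"),
                    step_myr = 0.01) {
  over <- match.arg(over)
  if (nrow(sim$species) == 0) return(0)
  comm <- split(sim$species$species, sim$species$site)
  keys <- vapply(comm, function(x) paste(sort(unique(x)), collapse = ","),
                 character(1))
  uniq <- !duplicated(keys)
  pd_by_key <- vapply(comm[uniq], function(x) {
    community_pd_steps(sim$phylo, unique(x), sim$n_steps, include_root)
  }, numeric(1))
  names(pd_by_key) <- keys[uniq]
  pds <- pd_by_key[keys] * step_myr
  if (over == "occupied") mean(pds) else sum(pds) / sim$n_suitable_final
}

#' Speciation and extinction event proportions
#'
#' Event counts over the whole simulation divided by the final gamma
#' diversity.
#'
#' @param events event tibble (columns `event`, ...).
#' @param gamma final regional richness.
#' @return tibble with columns `event`, `n`, `proportion`.
#' @export
event_proportions <- function(events, gamma) {
  counts <- table(factor(events$event, levels = c("speciation", "extinction")))
  tibble::tibble(
    event = names(counts),
    n = as.integer(counts),
    proportion = if (is.na(gamma) || gamma == 0) NA_real_ else
      as.integer(counts) / gamma
  )
}

#' Island involvement in speciation events
#'
#' Classifies speciation events as within-island (both daughter ranges on
#' one island) or between-island, and reports, per island, the proportion
#' of speciation events that involved it.
#'
#' @param events event tibble with `islands` (comma-joined) and `type`.
#' @return tibble with columns `island`, `n_within`, `n_between`,
#'   `prop_involved`.
#' @export
island_involvement <- function(events) {
  sp <- events[events$event == "speciation", , drop = FALSE]
  islands <- c("A", "B", "C", "D")
  if (nrow(sp) == 0) {
    return(tibble::tibble(island = islands, n_within = 0L, n_between = 0L,
                          prop_involved = 0))
  }
  lists <- strsplit(sp$islands, ",", fixed = TRUE)
  tibble::tibble(
    island = islands,
    n_within = vapply(islands, function(i) {
      sum(vapply(lists, function(x) i %in% x, logical(1)) & sp$type == "within")
    }, integer(1), USE.NAMES = FALSE),
    n_between = vapply(islands, function(i) {
      sum(vapply(lists, function(x) i %in% x, logical(1)) & sp$type == "between")
    }, integer(1), USE.NAMES = FALSE),
    prop_involved = vapply(islands, function(i) {
      mean(vapply(lists, function(x) i %in% x, logical(1)))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Mean regional occupancy
#'
#' The mean number of sites (km^2) occupied per species, pooled over all
#' time steps and living species.
#'
#' @param series per-step tibble with `n_species` and `n_populations`
#'   (an `isle_sim$series`).
#' @export
occupancy_mean <- function(series) {
  alive <- series$n_species > 0
  if (!any(alive)) return(0)
  sum(series$n_populations[alive]) / sum(series$n_species[alive])
}

#' Regression of speciation on extinction proportions
#'
#' Ordinary least squares across runs of the speciation event proportion on
#' the extinction event proportion, with a t-based 95% confidence interval.
#'
#' @param summaries tibble with columns `speciation_prop` and
#'   `extinction_prop` (one row per run).
#' @return one-row tibble: `slope`, `conf_low`, `conf_high`, `r_squared`,
#'   `n`.
#' @export
regress_events <- function(summaries) {
  df <- summaries[stats::complete.cases(summaries[, c("speciation_prop",
                                                      "extinction_prop")]), ]
  if (nrow(df) < 3) stop("need at least 3 runs", call. = FALSE)
  if (stats::var(df$extinction_prop) == 0) {
    stop("zero variance in extinction proportions", call. = FALSE)
  }
  fit <- stats::lm(speciation_prop ~ extinction_prop, data = df)
  ci <- stats::confint(fit, "extinction_prop", level = 0.95)
  tibble::tibble(
    slope = stats::coef(fit)[["extinction_prop"]],
    conf_low = ci[1], conf_high = ci[2],
    r_squared = summary(fit)$r.squared,
    n = nrow(df)
  )
}

#' Connectivity regime of a dispersal trait value
#'
#' Bands of the dispersal trait within which a given subset of islands is
#' mutually colonizable: `k0` (`d < 0.15`, no inter-island colonization),
#' `k1` (`0.15 <= d < 0.55`, islands A and B), `k2` (`d >= 0.55`, all
#' islands).
#'
#' @param d dispersal trait value(s) in `[0, 1]`.
#' @return factor with levels `k0`, `k1`, `k2`.
#' @export
classify_regime <- function(d) {
  if (any(d < 0 | d > 1)) stop("d must lie in [0, 1]", call. = FALSE)
  cut(d, breaks = c(-Inf, 0.15, 0.55, Inf), labels = c("k0", "k1", "k2"),
      right = FALSE)
}

#' One-row summary of a finished run
#'
#' @param sim an `isle_sim` result.
#' @return tibble with the model, initial traits, connectivity regime and
#'   the diversity/event metrics.
#' @export
run_summary <- function(sim) {
  gamma <- gamma_diversity(sim)
  islands <- names(sim$final_island_sites)[sim$final_island_sites > 0]
  rich <- vapply(islands, function(i) {
    length(unique(sim$species$species[sim$species$island == i]))
  }, integer(1))
  props <- event_proportions(sim$events, gamma)
  tibble::tibble(
    model = sim$config$model,
    d_init = sim$config$d_init,
    l_init = sim$config$l_init,
    seed = sim$config$rng_seed,
    regime = as.character(classify_regime(sim$config$d_init)),
    gamma = gamma,
    beta = beta_whittaker(rich, gamma),
    alpha_mean = alpha_mean(sim),
    pd_mean = pd_mean(sim),
    speciation_prop = props$proportion[props$event == "speciation"],
    extinction_prop = props$proportion[props$event == "extinction"],
    n_speciation_within = sum(sim$events$event == "speciation" &
                                sim$events$type == "within"),
    n_speciation_between = sum(sim$events$event == "speciation" &
                                 sim$events$type == "between"),
    occupancy = occupancy_mean(sim$series)
  )
}

#' @rdname run_summary
#' @param x an `isle_sim`.
#' @param ... unused.
#' @importFrom generics glance
#' @method glance isle_sim
#' @export
glance.isle_sim <- function(x, ...) run_summary(x)

#' @export
generics::glance

#' Per-step time series of a run
#'
#' @param x an `isle_sim`.
#' @param ... unused.
#' @method tidy isle_sim
#' @export
tidy.isle_sim <- function(x, ...) x$series

#' Factorial simulation experiment
#'
#' Runs the full factorial of initial dispersal and tolerance values for
#' the requested models and seeds, returning one [run_summary()] row per
#' run.
#'
#' @param landscape an `isle_landscape` (shared across runs; least-cost
#'   caches are reused).
#' @param models character vector of model names.
#' @param d_grid,l_grid initial trait values.
#' @param seeds RNG seeds (one run per seed per factorial cell).
#' @param ... further arguments to [simulation_config()].
#' @param progress print a progress line per run.
#' @return tibble of class `isle_experiment`.
#' @export
run_experiment <- function(landscape, models = "M0",
                           d_grid = seq(0.05, 1, by = 0.05),
                           l_grid = 1, seeds = 1L, ...,
                           progress = FALSE) {
  grid <- tidyr::expand_grid(model = models, d = d_grid, l = l_grid,
                             seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(model, d, l, seed) {
    cfg <- simulation_config(model = model, d_init = d, l_init = l,
                             rng_seed = seed, ...)
    sim <- run_simulation(cfg, landscape)
    if (progress) {
      message(sprintf("%s d=%.2f l=%.2f seed=%d: gamma=%d",
                      model, d, l, seed, gamma_diversity(sim)))
    }
    run_summary(sim)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("isle_experiment", class(out))
  out
}

#' Aggregate an experiment per factorial cell
#'
#' Mean metric values per model x d x l cell, in the style of a
#' dispersal-gradient summary table.
#'
#' @param experiment an [run_experiment()] result.
#' @export
experiment_cells <- function(experiment) {
  dplyr::summarise(
    dplyr::group_by(experiment, .data$model, .data$d_init, .data$l_init),
    dplyr::across(c("gamma", "beta", "alpha_mean", "pd_mean",
                    "speciation_prop", "extinction_prop", "occupancy"),
                  ~ mean(.x, na.rm = TRUE)),
    n_runs = dplyr::n(),
    .groups = "drop"
  )
}
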