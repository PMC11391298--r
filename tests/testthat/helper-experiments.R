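# Shared simulation experiments for the acceptance checks. Runs are
# memoized so the connectivity-regime and dispersal-gradient checks reuse
# the same simulations.

# founder ancestor (1, 2 or 3) of every species in a run
founder_of <- function(phylo) {
  anc <- phylo$lineage
  repeat {
    par <- phylo$parent[match(anc, phylo$lineage)]
    done <- is.na(par) | !(par %in% phylo$lineage)
    if (all(done)) break
    anc[!done] <- par[!done]
  }
  stats::setNames(anc, phylo$lineage)
}

# one M0 zero-competition run reduced to the fields the checks need
run_m0_summary <- function(lsc, d, seed) {
  sim <- run_simulation(
    simulation_config("M0", d_init = d, l_init = 1, rng_seed = seed), lsc
  )
  anc <- founder_of(sim$phylo)
  home <- c(`1` = "A", `2` = "B", `3` = "C")
  sp_home <- home[as.character(anc[as.character(sim$species$species)])]
  away <- sim$species$island != sp_home
  crossed_ab <- any(away & sim$species$island %in% c("A", "B")) ||
    any(sim$events$type %in% "between")
  dplyr::mutate(
    run_summary(sim),
    crossed_ab = crossed_ab,
    reached_c = any(away & sim$species$island == "C"),
    reached_d = any(sim$species$island == "D"),
    islands_occupied = length(unique(sim$species$island))
  )
}

m0_gradient <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lsc <- desk_landscape()
    grid <- rbind(
      tidyr::expand_grid(d = c(0.05, 0.2, 0.35, 0.5, 0.55, 0.7, 0.85, 1.0),
                         seed = 1:10),
      tidyr::expand_grid(d = c(0.05, 0.35, 0.8), seed = 11:20),
      tidyr::expand_grid(d = 0.8, seed = 1:10)
    )
    cache <<- dplyr::bind_rows(purrr::pmap(grid, function(d, seed) {
      run_m0_summary(lsc, d, seed)
    }))
    cache
  }
})

model_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lsc <- desk_landscape()
    d_grid <- seq(0.05, 0.95, by = 0.1)
    l_grid <- seq(0.05, 0.95, by = 0.1)
    cache <<- dplyr::bind_rows(
      run_experiment(lsc, models = "MET", d_grid = d_grid, l_grid = l_grid,
                     seeds = 1L),
      run_experiment(lsc, models = "M0", d_grid = d_grid, l_grid = l_grid,
                     seeds = 1L)
    )
    cache
  }
})
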