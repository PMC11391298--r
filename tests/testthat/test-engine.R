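test_that("the world initializes with three island endemics", {
  lsc <- mini_landscape()
  cfg <- simulation_config("M0", d_init = 0.3, l_init = 0.8, rng_seed = 1)
  set.seed(1)
  state <- initialize_world(cfg, lsc)
  expect_equal(length(state$species), 3)

  imap <- island_assignment(lsc)
  geom1 <- suitability(lsc, 1)
  temps <- site_temperatures(lsc, 1)
  for (k in 1:3) {
    s <- state$species[[as.character(k)]]
    isl <- unique(imap[s$sites])
    expect_equal(isl, c("A", "B", "C")[k])  # own island only
    expect_true(all(s$traits[, "omega"] == 0.4))
    expect_true(all(s$traits[, "d"] == 0.3))
    expect_true(all(s$traits[, "l"] == 0.8))
    # thermal optimum equals the normalized mean site temperature
    tmid <- norm_temperature((temps$tmin[s$sites] + temps$tmax[s$sites]) / 2)
    expect_equal(unname(s$traits[, "t_opt"]), unname(tmid), tolerance = 1e-12)
    # the first ecological pass has already equilibrated single-species sites
    r <- growth_rate(norm_temperature(temps$tmin[s$sites]),
                     norm_temperature(temps$tmax[s$sites]),
                     s$traits[, "t_opt"], s$traits[, "omega"])
    expect_equal(s$n, unname(r / 0.2), tolerance = 1e-12)
  }
})

test_that("normalized temperature midpoint maps 17.5 C to 0.5", {
  expect_equal(norm_temperature(17.5), 0.5)
  expect_equal(norm_temperature(26), 1)
  expect_equal(norm_temperature(9), 0)
})

test_that("initialization requires three islands", {
  lsc <- mini_landscape()
  fake <- lsc
  fake$manifest$sea_level[1] <- lsc$config$bridge_saddle_m - 5  # bridge up
  fake$cache <- new.env(parent = emptyenv())
  cfg <- simulation_config("M0")
  expect_error(initialize_world(cfg, fake), "3 islands")
})

test_that("MET initial traits are projected onto the trade-off surface", {
  lsc <- mini_landscape()
  cfg <- simulation_config("MET", d_init = 0.9, l_init = 0.9, rng_seed = 1)
  set.seed(1)
  state <- initialize_world(cfg, lsc)
  s <- state$species[["1"]]
  expect_lte(s$traits[1, "d"] + s$traits[1, "l"], 1 + 1e-9)
})

test_that("runs are reproducible and internally consistent", {
  lsc <- mini_landscape()
  cfg <- simulation_config("M0", d_init = 0.35, l_init = 0.7, rng_seed = 42)
  a <- run_simulation(cfg, lsc)
  b <- run_simulation(cfg, lsc)
  expect_identical(a$events, b$events)
  expect_identical(a$species, b$species)
  expect_identical(a$series, b$series)

  # a state advanced by hand passes the audit at every step
  set.seed(7)
  state <- initialize_world(cfg, lsc)
  for (t in 2:20) {
    state <- step_world(state, lsc, cfg, t)
    expect_true(audit_state(state, lsc, t))
  }
})

test_that("M0 freezes dispersal and tolerance traits exactly", {
  lsc <- mini_landscape()
  sim <- run_simulation(simulation_config("M0", d_init = 0.35, l_init = 0.6,
                                          rng_seed = 3), lsc)
  expect_true(all(sim$species$d == 0.35))
  expect_true(all(sim$species$l == 0.6))
  # thermal traits do evolve
  expect_gt(sd(sim$species$t_opt), 0)
})

test_that("ME lets dispersal and tolerance drift; MET keeps them plausible", {
  lsc <- mini_landscape()
  me <- run_simulation(simulation_config("ME", d_init = 0.35, l_init = 0.6,
                                         rng_seed = 3), lsc)
  expect_gt(sd(me$species$d), 0)
  expect_false(all(me$species$d == 0.35))

  met <- run_simulation(simulation_config("MET", d_init = 0.5, l_init = 0.5,
                                          rng_seed = 3), lsc)
  expect_true(all(met$species$d + met$species$l <= 1 + 1e-9))
})

test_that("populations on submerged sites are vacated", {
  lsc <- desk_landscape()
  cfg <- simulation_config("M0", d_init = 0.3, l_init = 1, rng_seed = 5)
  set.seed(5)
  state <- initialize_world(cfg, lsc)
  # run into the first glacial cycle and back to the highstand
  for (t in 2:21) state <- step_world(state, lsc, cfg, t)
  suit <- which(suitability(lsc, 21))
  for (s in state$species) expect_true(all(s$sites %in% suit))
  # at the highstand the range has contracted back to the 0-Ma island
  expect_true(audit_state(state, lsc, 21))
})

test_that("two permanently isolated populations speciate on the s clock", {
  lsc <- desk_landscape()
  cfg <- simulation_config("M0", d_init = 0, l_init = 1, rng_seed = 9)
  set.seed(9)
  state <- initialize_world(cfg, lsc)
  # strip species 2 and 3; give species 1 one site on A and one on C
  geom <- islesim:::step_geometry(lsc, 1)
  imap <- island_assignment(lsc)[geom$sites]
  s1 <- state$species[["1"]]
  keep_a <- which(imap == "A")[1]
  keep_c <- which(imap == "C")[1]
  sites <- geom$sites[c(keep_a, keep_c)]
  state$species <- list(`1` = list(
    id = 1L, sites = sites, n = c(0.5, 0.5),
    traits = s1$traits[c(1, 1), , drop = FALSE],
    deme = c(1L, 1L), div = matrix(0L, 1, 1), cluster = c(1L, 1L)
  ))
  state$phylo <- new_phylogeny(1, step = 1L)

  for (t in 2:80) {
    state <- step_world(state, lsc, cfg, t)
    if (length(state$events) > 0) break
  }
  ev <- dplyr::bind_rows(state$events)
  expect_equal(ev$event[1], "speciation")
  # demes separate at the first re-clustering (step 2); divergence then
  # counts 65 isolated steps before the split
  expect_equal(ev$step[1], 2 + 65)
  expect_equal(ev$type[1], "between")
  expect_setequal(strsplit(ev$islands[1], ",")[[1]], c("A", "C"))
})

test_that("tidy and glance return the documented shapes", {
  lsc <- mini_landscape()
  sim <- run_simulation(simulation_config("M0", rng_seed = 2), lsc)
  td <- tidy(sim)
  expect_true(all(c("step", "n_species", "n_populations") %in% names(td)))
  expect_equal(nrow(td), lsc$config$n_steps)
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("gamma", "beta", "alpha_mean", "pd_mean",
                    "speciation_prop", "extinction_prop", "occupancy")
                  %in% names(gl)))
  expect_gte(gl$gamma, 1)
  expect_true(gl$beta >= 0 && gl$beta <= 1)
})

test_that("run outputs round-trip through the standard files", {
  lsc <- mini_landscape()
  sim <- run_simulation(simulation_config("M0", rng_seed = 2), lsc)
  dir <- tempfile()
  write_run_outputs(sim, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  expect_equal(nrow(ev), nrow(sim$events))
  tr <- ape::read.tree(file.path(dir, "phylogeny_extant.nwk"))
  expect_equal(length(tr$tip.label), gamma_diversity(sim))
})
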