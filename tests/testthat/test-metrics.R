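# hand-built minimal sim objects for metric checks
fake_sim <- function(phylo, species, events = NULL, series = NULL,
                     n_steps = 501L, n_suitable = NULL,
                     island_sites = c(A = 100L, B = 100L, C = 100L, D = 100L),
                     d_init = 0.3, l_init = 1) {
  if (is.null(events)) {
    events <- tibble::tibble(step = integer(0), event = character(0),
                             species = integer(0), parent = integer(0),
                             islands = character(0), type = character(0))
  }
  if (is.null(series)) {
    series <- tibble::tibble(step = 1:2, n_species = c(1, 1),
                             n_populations = c(1, 1), mean_d = 0.3,
                             mean_l = 1, mean_omega = 0.4)
  }
  if (is.null(n_suitable)) n_suitable <- sum(island_sites)
  structure(
    list(config = simulation_config("M0", d_init = d_init, l_init = l_init),
         landscape_config = NULL, final_island_sites = island_sites,
         n_suitable_final = n_suitable, species = species, phylo = phylo,
         events = events, series = series, n_steps = n_steps),
    class = "isle_sim"
  )
}

pop_row <- function(species, site, island, n = 0.5) {
  tibble::tibble(species = species, site = site, x = 0, y = 0,
                 island = island, n = n, t_opt = 0.5, omega = 0.4,
                 d = 0.3, l = 1, cluster = 1L)
}

test_that("gamma diversity counts extant lineages", {
  ph <- new_phylogeny(1:3)
  expect_equal(gamma_diversity(fake_sim(ph, pop_row(1, 1, "A"))), 3)

  ph2 <- record_speciation(ph, 4, 1, 100)
  ph2 <- record_speciation(ph2, 5, 2, 150)
  for (i in 1:5) ph2 <- record_speciation(ph2, 5 + i, 3, 160 + i)
  ph2 <- record_extinction(ph2, 4, 300)
  ph2 <- record_extinction(ph2, 6, 350)
  # founders + speciations - extinctions = 3 + 7 - 2
  expect_equal(gamma_diversity(fake_sim(ph2, pop_row(1, 1, "A"))), 8)

  ph3 <- record_extinction(new_phylogeny(1), 1, 10)
  expect_equal(gamma_diversity(fake_sim(ph3, pop_row(1, 1, "A")[0, ])), 0)
})

test_that("Whittaker turnover matches its worked cases", {
  expect_equal(beta_whittaker(c(3, 3), 3), 0)            # full homogenization
  expect_equal(beta_whittaker(c(2, 2), 4), 0.5)
  expect_equal(beta_whittaker(c(1, 1, 1, 1), 4), 0.75)   # fully disjoint
  expect_true(is.na(beta_whittaker(c(0, 0), 0)))
})

test_that("mean local richness averages over the requested site set", {
  sp <- dplyr::bind_rows(pop_row(1, 1, "A"), pop_row(2, 1, "A"),
                         pop_row(1, 2, "A"), pop_row(2, 2, "A"),
                         pop_row(3, 2, "A"), pop_row(4, 2, "A"))
  sim <- fake_sim(new_phylogeny(1:4), sp, n_suitable = 4)
  expect_equal(alpha_mean(sim, over = "occupied"), 3)    # sites with 2 and 4
  expect_equal(alpha_mean(sim, over = "suitable"), 6 / 4)
  empty <- fake_sim(new_phylogeny(1), sp[0, ])
  expect_equal(alpha_mean(empty), 0)
})

test_that("per-site phylogenetic diversity matches hand-computed trees", {
  # single founder alive over the whole run: root-to-tip path of 5 Myr
  sim1 <- fake_sim(new_phylogeny(1), pop_row(1, 1, "A"))
  expect_equal(pd_mean(sim1), 5)

  # two sister species splitting 1 Ma on a 5-Myr root: PD = 4 + 1 + 1
  ph <- record_speciation(new_phylogeny(1), 2, 1, 401)
  both <- dplyr::bind_rows(pop_row(1, 1, "A"), pop_row(2, 1, "A"))
  sim2 <- fake_sim(ph, both)
  expect_equal(pd_mean(sim2), 6)

  # identical communities on every site: mean PD equals any site's PD
  three <- dplyr::bind_rows(both, pop_row(1, 2, "A"), pop_row(2, 2, "A"))
  sim3 <- fake_sim(ph, three)
  expect_equal(pd_mean(sim3), 6)

  # a site hosting only one of the sisters: 4 + 1
  mixed <- dplyr::bind_rows(both, pop_row(1, 2, "A"))
  sim4 <- fake_sim(ph, mixed)
  expect_equal(pd_mean(sim4), (6 + 5) / 2)
})

test_that("phylogenetic diversity agrees with picante on a random tree", {
  set.seed(21)
  ph <- new_phylogeny(1)
  next_id <- 2
  for (i in 1:6) {
    parent <- sample(ph$lineage, 1)
    birth <- sample(seq(ph$birth_step[ph$lineage == parent] + 10, 480, by = 7), 1)
    ph <- record_speciation(ph, next_id, parent, birth)
    next_id <- next_id + 1
  }
  tr <- ape::read.tree(text = to_newick(ph, 501))
  for (k in c(2, 4, 7)) {
    tips <- sample(ph$lineage, k)
    comm <- matrix(as.integer(ph$lineage %in% tips), 1,
                   dimnames = list("s", paste0("sp", ph$lineage)))
    ref <- picante::pd(comm, tr, include.root = TRUE)$PD
    sp <- dplyr::bind_rows(lapply(tips, function(t) pop_row(t, 1, "A")))
    sim <- fake_sim(ph, sp)
    expect_equal(pd_mean(sim), ref, tolerance = 1e-9)
  }
})

test_that("event proportions divide counts by gamma", {
  ev <- tibble::tibble(event = c(rep("speciation", 10), rep("extinction", 4)))
  pr <- event_proportions(ev, gamma = 5)
  expect_equal(pr$proportion[pr$event == "speciation"], 2)
  expect_equal(pr$proportion[pr$event == "extinction"], 0.8)
  none <- event_proportions(ev[0, ], gamma = 3)
  expect_equal(none$proportion, c(0, 0))
  expect_true(all(is.na(event_proportions(ev, gamma = 0)$proportion)))
})

test_that("island involvement classifies within and between events", {
  ev <- tibble::tibble(
    step = 1:3, event = "speciation", species = 4:6, parent = 1L,
    islands = c("A,B", "A", "B,C"), type = c("between", "within", "between")
  )
  inv <- island_involvement(ev)
  expect_equal(inv$n_within[inv$island == "A"], 1L)
  expect_equal(inv$n_between[inv$island == "A"], 1L)
  expect_equal(inv$n_between[inv$island == "B"], 2L)
  expect_equal(inv$prop_involved[inv$island == "A"], 2 / 3)
  expect_equal(inv$prop_involved[inv$island == "D"], 0)
  zero <- island_involvement(ev[0, ])
  expect_true(all(zero$prop_involved == 0))
})

test_that("occupancy pools sites over steps and species", {
  one <- tibble::tibble(n_species = rep(1, 10), n_populations = rep(100, 10))
  expect_equal(occupancy_mean(one), 100)
  grow <- tibble::tibble(n_species = rep(1, 101),
                         n_populations = seq(0, 100))
  expect_equal(occupancy_mean(grow), 50)
  expect_equal(occupancy_mean(tibble::tibble(n_species = 0,
                                             n_populations = 0)), 0)
})

test_that("the speciation~extinction regression matches closed-form OLS", {
  df <- tibble::tibble(extinction_prop = c(0, 1, 2, 3),
                       speciation_prop = c(0, 0.5, 1, 1.5))
  fit <- suppressWarnings(regress_events(df))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(31)
  x <- runif(10); y <- runif(10)
  hand_slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit2 <- regress_events(tibble::tibble(extinction_prop = x,
                                        speciation_prop = y))
  expect_equal(fit2$slope, hand_slope, tolerance = 1e-12)
  expect_true(fit2$conf_low < fit2$slope & fit2$slope < fit2$conf_high)

  expect_error(regress_events(tibble::tibble(extinction_prop = c(1, 1, 1),
                                             speciation_prop = c(1, 2, 3))),
               "variance")
  expect_error(regress_events(df[1:2, ]), "3 runs")
})

test_that("constant response gives a zero slope", {
  df <- tibble::tibble(extinction_prop = c(0, 1, 2, 4),
                       speciation_prop = 1)
  expect_equal(suppressWarnings(regress_events(df))$slope, 0, tolerance = 1e-12)
})

test_that("dispersal values map onto connectivity regimes", {
  expect_equal(as.character(classify_regime(c(0.1, 0.3, 0.7))),
               c("k0", "k1", "k2"))
  expect_equal(as.character(classify_regime(c(0.15, 0.55))), c("k1", "k2"))
  expect_error(classify_regime(1.2), "d must")
})
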