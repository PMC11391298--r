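test_that("configuration defaults and validation", {
  cfg <- landscape_config()
  expect_equal(cfg$n_steps, 501L)           # 5 Myr at 10-kyr steps
  expect_equal(cfg$start_ma, 5)
  expect_equal(cfg$temp_range_c, c(9, 26))
  expect_error(landscape_config(sea_amp_pre_m = 120), "sea_amp_quat_m")
  expect_error(landscape_config(seafloor_m = -10), "seafloor_m")
  expect_error(landscape_config(trange_max_c = 0), "trange_max_c")
})

test_that("sea level is periodic, anchored at zero, and intensifies in the Quaternary", {
  cfg <- landscape_config()
  s <- sea_level(cfg)
  expect_equal(s[1], 0)                       # 5 Ma sits on a cycle top
  expect_equal(s[length(s)], 0)               # levels are relative to 0 Ma
  t_ma <- cfg$start_ma - (seq_along(s) - 1) * 0.01
  # lowest sea level lies in the Quaternary
  expect_lt(t_ma[which.min(s)], cfg$quaternary_ma)
  # stationary pre-Quaternary phase repeats every 10th step (100 kyr)
  pre <- which(t_ma > cfg$quaternary_ma + cfg$ramp_myr)
  pre <- pre[pre + 10 <= max(pre)]
  expect_equal(s[pre], s[pre + 10], tolerance = 1e-9)
  # amplitude strictly larger in the Quaternary
  expect_lt(min(s[t_ma < cfg$quaternary_ma - cfg$ramp_myr]),
            min(s[t_ma > cfg$quaternary_ma + cfg$ramp_myr]) - 1)
})

test_that("the generated landscape satisfies its global invariants", {
  lsc <- desk_landscape()
  cfg <- lsc$config
  expect_equal(n_islands(lsc, 1), 3)
  expect_equal(n_islands(lsc, cfg$n_steps), 4)

  mn <- Inf; mx <- -Inf; emn <- Inf; emx <- -Inf; spmax <- -Inf
  for (s in seq(1, cfg$n_steps, by = 5)) {
    elev <- elevation_grid(lsc, s)
    suit <- suitability(lsc, s)
    expect_identical(suit, elev > lsc$manifest$sea_level[s])
    tt <- site_temperatures(lsc, s, elev)
    spread <- tt$tmax - tt$tmin
    expect_true(all(spread >= 0 & spread <= cfg$trange_max_c + 1e-9))
    mn <- min(mn, min(tt$tmin[suit])); mx <- max(mx, max(tt$tmax[suit]))
    emn <- min(emn, min(elev)); emx <- max(emx, max(elev))
    spmax <- max(spmax, max(spread))
  }
  # calibrated extremes are exact (the coarse step grid still hits the
  # anchor phases where the extremes occur)
  expect_equal(mn, cfg$temp_range_c[1], tolerance = 1e-6)
  expect_equal(mx, cfg$temp_range_c[2], tolerance = 1e-6)
  expect_equal(emn, cfg$seafloor_m)
  expect_equal(emx, max(cfg$peak_elevations_m))
  expect_equal(spmax, cfg$trange_max_c, tolerance = 1e-9)

  # suitable sites per island at the 0-Ma highstand sit near the target
  suit1 <- suitability(lsc, 1)
  counts <- table(island_assignment(lsc)[suit1])
  expect_true(all(abs(counts - cfg$island_target_sites) / cfg$island_target_sites
                  < 0.05))
})

test_that("mean temperature decreases with elevation at the lapse rate", {
  lsc <- desk_landscape()
  flat <- matrix(0, lsc$config$grid[1], lsc$config$grid[2])
  hill <- flat; hill[5, 5] <- 100
  t0 <- site_temperatures(lsc, 3, flat)
  t1 <- site_temperatures(lsc, 3, hill)
  mean0 <- (t0$tmin + t0$tmax) / 2
  mean1 <- (t1$tmin + t1$tmax) / 2
  # +100 m at a 5.5 C/km lapse rate: mean temperature 0.55 C lower
  expect_equal(mean0[5, 5] - mean1[5, 5], 0.55, tolerance = 1e-9)
  # equal elevations share identical temperatures
  expect_equal(t0$tmin[1, 1], t0$tmin[10, 20])
})

test_that("edge costs follow the resistance rule", {
  elev <- matrix(0, 3, 3)
  elev[2, 1] <- 200
  suit <- matrix(TRUE, 3, 3)
  suit[3, ] <- FALSE  # ocean column
  ec <- edge_costs(elev, suit)
  cost_of <- function(a, b) ec$cost[(ec$from == a & ec$to == b) |
                                      (ec$from == b & ec$to == a)]
  expect_equal(cost_of(1, 4), 1)          # flat suitable neighbours
  expect_equal(cost_of(1, 2), 1.2)        # 200 m difference: +0.1 per 100 m
  expect_equal(cost_of(2, 3), 4)          # step onto ocean
  expect_equal(cost_of(1, 5), sqrt(2) + 0)  # flat diagonal
  expect_equal(cost_of(5, 3), 4 * sqrt(2))  # ocean diagonal
})

test_that("least-cost distances match a brute-force oracle", {
  set.seed(8)
  elev <- matrix(runif(25, 0, 400), 5, 5)
  suit <- matrix(TRUE, 5, 5)
  suit[, 3] <- FALSE  # ocean strait through the middle
  d <- least_cost_distances(elev, suit, sites = 1:25)
  eo <- oracle_grid_edges(elev, suit)
  ref <- floyd_warshall(25, eo$from, eo$to, eo$w)
  expect_equal(unname(d), ref, tolerance = 1e-9)
  expect_equal(diag(d), setNames(rep(0, 25), 1:25))
  expect_equal(d, t(d))
  # triangle inequality
  for (k in c(2, 13, 24)) {
    expect_true(all(d <= outer(d[, k], d[k, ], `+`) + 1e-9))
  }
})

test_that("a straight flat strip accumulates unit costs", {
  elev <- matrix(c(1, 1, 1), 3, 1)
  suit <- matrix(TRUE, 3, 1)
  d <- least_cost_distances(elev, suit)
  expect_equal(unname(d["1", "3"]), 2)  # two unit steps via the middle site
})

test_that("ocean crossings accumulate the unsuitable cost", {
  elev <- matrix(-50, 5, 1)
  elev[c(1, 5)] <- 10
  suit <- elev > 0
  d <- least_cost_distances(elev, suit, sites = which(suit))
  expect_equal(unname(d[1, 2]), 16)  # four 1-km steps touching ocean at 4/km
})

test_that("island labels equal flood-fill components", {
  lsc <- desk_landscape()
  for (s in c(1, 15, 120)) {
    lab <- island_labels(lsc, s)
    ref <- flood_fill_labels(suitability(lsc, s))
    # same partition up to renaming
    key <- paste(lab[!is.na(lab)], ref[!is.na(ref)])
    expect_equal(length(unique(key)), length(unique(lab[!is.na(lab)])))
    expect_equal(length(unique(lab[!is.na(lab)])),
                 length(unique(ref[!is.na(ref)])))
  }
})

test_that("the A-B bridge is exposed exactly below the saddle elevation", {
  lsc <- desk_landscape()
  cfg <- lsc$config
  for (s in seq(1, 60, by = 3)) {
    lab <- island_labels(lsc, s)
    centres <- lsc$topo$centres
    cell <- function(i) centres[i, "x"] + (centres[i, "y"] - 1) * cfg$grid[1]
    joined <- lab[cell("A")] == lab[cell("B")]
    expect_equal(joined, lsc$manifest$sea_level[s] < cfg$bridge_saddle_m)
  }
})

test_that("exposing the bridge shortens the A-B least-cost distance", {
  lsc <- desk_landscape()
  man <- lsc$manifest
  s_open <- which(man$sea_level < lsc$config$bridge_saddle_m)[1]
  s_shut <- which(man$sea_level >= 0)[1]
  centres <- lsc$topo$centres
  ab_cost <- function(s) {
    cm <- cost_matrix(lsc, s)
    imap <- island_assignment(lsc)[cm$sites]
    suppressWarnings(min(cm$cost[imap == "A", imap == "B"]))
  }
  expect_lt(ab_cost(s_open), ab_cost(s_shut))
})

test_that("lower sea level never shrinks a static island", {
  lsc <- desk_landscape()
  imap <- island_assignment(lsc)
  pre_d <- which(lsc$manifest$d_uplift == 0)
  area_a <- vapply(pre_d, function(s) sum(imap[suitability(lsc, s)] == "A"),
                   numeric(1))
  sea <- lsc$manifest$sea_level[pre_d]
  ord <- order(sea)
  expect_true(all(diff(area_a[ord]) <= 0))
})

test_that("island D emerges at the configured time and grows", {
  lsc <- desk_landscape()
  cfg <- lsc$config
  man <- lsc$manifest
  imap <- island_assignment(lsc)
  d_sites <- vapply(seq_len(cfg$n_steps), function(s) {
    sum(imap[suitability(lsc, s)] == "D")
  }, numeric(1))
  before <- man$time_ma >= cfg$d_emergence_ma
  expect_true(all(d_sites[before] == 0))
  expect_gt(d_sites[cfg$n_steps], 0)
  # at constant sea-level phase, uplift makes the area non-decreasing
  tops <- which(man$sea_level == 0)
  expect_true(all(diff(d_sites[tops]) >= 0))
})

test_that("regeneration is bit-identical", {
  a <- generate_landscape(desk_landscape_config(n_steps = 31L))
  b <- generate_landscape(desk_landscape_config(n_steps = 31L))
  expect_identical(a$manifest, b$manifest)
  expect_identical(elevation_grid(a, 17), elevation_grid(b, 17))
  expect_identical(site_temperatures(a, 17), site_temperatures(b, 17))
})

test_that("config round-trips through a YAML file", {
  f <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(island_target_sites = 40L, n_steps = 21L), f)
  cfg <- landscape_config(file = f)
  expect_equal(cfg$island_target_sites, 40L)
  expect_equal(cfg$n_steps, 21L)
})
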