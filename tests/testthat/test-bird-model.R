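# brute-force per-pixel oracles, written with the (independently tested)
# landscape primitives

brute_fledglings <- function(ls, p) {
  tot <- 0
  for (r in seq_len(nrow(ls$grid))) {
    for (cc in seq_len(ncol(ls$grid))) {
      if (ls$grid[r, cc] != G) next
      nb <- neighborhood_counts(ls, r, cc, 1)
      f_non <- (nb[["AGRICULTURE"]] + nb[["FOREST"]]) / sum(nb)
      tot <- tot + p$nest_density * p$fledglings_per_nest * p$nest_survival *
        (1 - p$edge_penalty * f_non)
    }
  }
  tot
}

brute_stopover <- function(ls, N, p) {
  o <- s <- matrix(0, nrow(ls$grid), ncol(ls$grid))
  for (r in seq_len(nrow(ls$grid))) {
    for (cc in seq_len(ncol(ls$grid))) {
      nb <- neighborhood_counts(ls, r, cc, 1)
      mean_occ <- sum(nb * p$occupancy[land_covers()]) / sum(nb)
      o[r, cc] <- p$occupancy[[land_covers()[ls$grid[r, cc]]]] * mean_occ
      s[r, cc] <- patch_quality(ls, r, cc, p$stopover_survival)
    }
  }
  K <- p$k_stopover * sum(ls$grid == G)
  if (sum(o) <= 0 || K <= 0) return(p$matrix_survival_floor)
  settled <- min(N, K)
  (settled * sum(o * s) / sum(o) + (N - settled) * p$matrix_survival_floor) / N
}

test_that("fledgling potential matches the brute-force per-pixel sum", {
  p <- hand_params()
  for (seed in c(1, 5)) {
    ls <- generate_landscape(c(0.5, 0.3, 0.2), 12, 12, "BREEDING", seed = seed)
    expect_equal(fledgling_potential(ls, p), brute_fledglings(ls, p))
  }
  # all-grassland grid: edge effects only at the borders
  allg <- landscape(matrix(G, 6, 6), role = "BREEDING")
  expect_equal(fledgling_potential(allg, p),
               36 * p$nest_density * p$fledglings_per_nest * p$nest_survival)
})

test_that("reproduction is per-capita below capacity and saturates above", {
  p <- hand_params()
  allg <- landscape(matrix(G, 6, 6), role = "BREEDING")
  K_b <- p$k_breeding * 36
  F_pot <- fledgling_potential(allg, p)
  expect_equal(reproduction(allg, K_b / 2, p), F_pot / K_b)   # constant per capita
  expect_equal(reproduction(allg, K_b, p), F_pot / K_b)
  expect_equal(reproduction(allg, 2 * K_b, p), F_pot / (2 * K_b))  # saturated total
  expect_equal(reproduction(uniform_landscape(A, 6), 100, p), 0)   # no grassland
  expect_equal(reproduction(allg, 0, p), 0)                        # empty population
  expect_error(reproduction(uniform_landscape(G, 6, role = "STOPOVER"), 10, p),
               "BREEDING")
})

test_that("stopover survival matches exhaustive per-pixel enumeration", {
  p <- hand_params()
  toy <- make_landscape(c(G, A, A, FR), nrow = 2, role = "STOPOVER")
  for (N in c(1, 30, 100)) {
    expect_equal(stopover_survival(toy, N, p), brute_stopover(toy, N, p))
  }
  ls <- generate_landscape(c(0.4, 0.4, 0.2), 9, 7, "STOPOVER", seed = 4)
  expect_equal(stopover_survival(ls, 50, p), brute_stopover(ls, 50, p))
})

test_that("stopover edge cases: perfect grassland, zero occupancy, role guard", {
  p <- hand_params()
  allg <- uniform_landscape(G, 8, role = "STOPOVER")
  expect_equal(stopover_survival(allg, 10, p), 1)  # occupancy 1, survival 1
  p0 <- hand_params(occupancy = c(GRASSLAND = 0, AGRICULTURE = 0, FOREST = 0))
  expect_equal(stopover_survival(allg, 10, p0), p0$matrix_survival_floor)
  expect_error(stopover_survival(uniform_landscape(G, 4), 10, p), "STOPOVER")
})

test_that("migration survival multiplies sequential stopover survivals", {
  allg <- uniform_landscape(G, 8, role = "STOPOVER")
  p <- hand_params()
  expect_equal(migration_survival(list(allg, allg, allg), 10, p), 1)
  p9 <- hand_params(stopover_survival = c(GRASSLAND = 0.9, AGRICULTURE = 0.9, FOREST = 0.9))
  expect_equal(migration_survival(list(allg, allg, allg), 10, p9), 0.9^3)
  p_dead <- hand_params(stopover_survival = c(GRASSLAND = 0, AGRICULTURE = 0, FOREST = 0),
                        matrix_survival_floor = 0)
  expect_equal(migration_survival(list(allg, allg, allg), 10, p_dead), 0)
  expect_error(migration_survival(list(allg, allg), 10, p), "3 stopover")
  # with a capacity binding at the first stop, direction matters
  small <- uniform_landscape(G, 2, role = "STOPOVER")  # K = 4 * k_stopover
  mixed <- list(small, allg, allg)
  p_cap <- hand_params(k_stopover = 0.5,
                       stopover_survival = c(GRASSLAND = 0.9, AGRICULTURE = 0.9, FOREST = 0.9),
                       matrix_survival_floor = 0.1)
  s_south <- migration_survival(mixed, 100, p_cap, "southbound")
  s_north <- migration_survival(mixed, 100, p_cap, "northbound")
  expect_false(isTRUE(all.equal(s_south, s_north)))
})

test_that("winter survival mixes habitat survival with the overflow floor", {
  p <- hand_params()
  allg <- uniform_landscape(G, 5, role = "WINTERING")
  K <- p$k_winter * 25
  expect_equal(winter_survival(allg, K / 2, p), 0.8)
  expect_equal(winter_survival(allg, 2 * K, p), (0.8 + p$matrix_survival_floor) / 2)
  p0 <- hand_params(occupancy = c(GRASSLAND = 1, AGRICULTURE = 0, FOREST = 0))
  expect_equal(winter_survival(uniform_landscape(A, 5, role = "WINTERING"), 10, p0),
               p0$matrix_survival_floor)
  expect_error(winter_survival(allg, -1, p), ">= 0")
  expect_error(winter_survival(uniform_landscape(G, 4), 10, p), "WINTERING")
})

test_that("all seasonal rates stay within bounds on random inputs", {
  withr::with_seed(2024, {
    for (i in 1:20) {
      p <- random_params()
      d <- as.numeric(stats::rmultinom(1, 10, runif(3, 0.05, 1))) / 10
      br <- generate_landscape(d, 8, 8, "BREEDING", seed = i)
      st <- generate_landscape(d, 8, 8, "STOPOVER", seed = i + 100)
      wi <- generate_landscape(d, 8, 8, "WINTERING", seed = i + 200)
      N <- runif(1, 0, 500)
      expect_gte(reproduction(br, N, p), 0)
      s1 <- stopover_survival(st, N, p)
      s2 <- winter_survival(wi, N, p)
      expect_true(s1 >= 0 && s1 <= 1)
      expect_true(s2 >= 0 && s2 <= 1)
    }
  })
})

test_that("the annual recursion multiplies out exactly", {
  expect_equal(step_population(100, 0.5, 1, 1, 1), 150)
  expect_equal(step_population(0, 0.5, 0.9, 0.8, 0.9), 0)
  expect_equal(step_population(100, 0, 0.9, 0.8, 0.9), 64.8)
  expect_error(step_population(-1, 0, 1, 1, 1), ">= 0")
  expect_error(step_population(100, 0, 1.2, 1, 1), "\\[0,1\\]")
})

test_that("simulation matches the closed-form geometric trajectory when no capacity binds", {
  p <- hand_params(k_breeding = 1e7, k_stopover = 1e7, k_winter = 1e7)
  br <- generate_landscape(c(0.6, 0.3, 0.1), 20, 20, "BREEDING", seed = 1)
  stops <- lapply(2:4, function(s) generate_landscape(c(0.6, 0.3, 0.1), 20, 20, "STOPOVER", seed = s))
  wi <- generate_landscape(c(0.6, 0.3, 0.1), 20, 20, "WINTERING", seed = 5)
  tr <- simulate_population(hand_scenario(br, stops, wi, p, n0 = 100, horizon = 30))
  lam <- (1 + tr$R_b[2]) * tr$S_f[2] * tr$S_w[2] * tr$S_s[2]
  expect_equal(tr$N, 100 * lam^(0:30), tolerance = 1e-11)
  expect_lt(lam, 1)
  expect_true(all(diff(tr$N) < 0))  # monotone decay when lambda < 1
})

test_that("population is conserved when nothing is born and nothing dies", {
  ones <- c(GRASSLAND = 1, AGRICULTURE = 1, FOREST = 1)
  p <- demographic_params(nest_density = 0, occupancy = ones,
                          stopover_survival = ones, winter_survival = ones,
                          matrix_survival_floor = 1)
  br <- generate_landscape(rep(1 / 3, 3), 10, 10, "BREEDING", seed = 1)
  stops <- lapply(2:4, function(s) generate_landscape(rep(1 / 3, 3), 10, 10, "STOPOVER", seed = s))
  wi <- generate_landscape(rep(1 / 3, 3), 10, 10, "WINTERING", seed = 5)
  tr <- simulate_population(hand_scenario(br, stops, wi, p, n0 = 77, horizon = 25))
  expect_equal(tr$N, rep(77, 26))
})

test_that("a binding capacity suppresses growth to a stable ceiling", {
  p <- hand_params(k_breeding = 1, k_winter = 0.1, matrix_survival_floor = 0.1,
                   nest_density = 1, nest_survival = 0.9)
  br <- uniform_landscape(G, 10, role = "BREEDING")
  stops <- lapply(1:3, function(i) uniform_landscape(G, 10, role = "STOPOVER"))
  wi <- uniform_landscape(G, 10, role = "WINTERING")
  tr <- simulate_population(hand_scenario(br, stops, wi, p, n0 = 2, horizon = 60))
  lam0 <- (1 + tr$R_b[2]) * tr$S_f[2] * tr$S_w[2] * tr$S_s[2]
  expect_gt(lam0, 1)         # below the winter cap the population booms
  expect_lt(tr$N[61], 20)    # the cap pins it near the winter ceiling (K_w = 10)
  expect_lt(abs(tr$N[61] - tr$N[60]) / tr$N[60], 1e-6)  # settled at equilibrium
})

test_that("degenerate horizons and failed populations are handled", {
  p <- hand_params()
  br <- uniform_landscape(G, 5, role = "BREEDING")
  stops <- lapply(1:3, function(i) uniform_landscape(G, 5, role = "STOPOVER"))
  wi <- uniform_landscape(G, 5, role = "WINTERING")
  tr0 <- simulate_population(hand_scenario(br, stops, wi, p, n0 = 42, horizon = 0))
  expect_equal(tr0$N, 42)
  expect_error(simulate_population(hand_scenario(br, stops[1:2], wi, p)), "3 STOPOVER")
})

test_that("stochastic demography is seeded and leaves the deterministic path untouched", {
  p <- hand_params()
  br <- generate_landscape(c(0.7, 0.2, 0.1), 15, 15, "BREEDING", seed = 1)
  stops <- lapply(2:4, function(s) generate_landscape(c(0.7, 0.2, 0.1), 15, 15, "STOPOVER", seed = s))
  wi <- generate_landscape(c(0.7, 0.2, 0.1), 15, 15, "WINTERING", seed = 5)
  scen <- hand_scenario(br, stops, wi, p, n0 = 200, horizon = 10)
  scen$stochastic <- TRUE
  a <- simulate_population(scen, seed = 31)
  b <- simulate_population(scen, seed = 31)
  expect_identical(a$N, b$N)
  expect_true(all(a$N == floor(a$N)))  # whole birds once survival is binomial
  expect_false(identical(a$N, simulate_population(scen, seed = 32)$N))
  scen$stochastic <- FALSE
  expect_identical(simulate_population(scen, seed = 31)$N,
                   simulate_population(scen, seed = 99)$N)
})

test_that("growth rate is the geometric mean annual rate", {
  flat <- structure(data.frame(year = 0:5, N = rep(10, 6)),
                    class = c("birdscape_trajectory", "data.frame"))
  expect_equal(growth_rate(flat), 0)
  oct <- structure(data.frame(year = 0:3, N = c(100, 180, 350, 800)),
                   class = c("birdscape_trajectory", "data.frame"))
  expect_equal(growth_rate(oct), 1)  # 8^(1/3) = 2
  lam <- 1.037
  geom <- structure(data.frame(year = 0:12, N = 50 * lam^(0:12)),
                    class = c("birdscape_trajectory", "data.frame"))
  expect_equal(growth_rate(geom), lam - 1)
  expect_equal(growth_rate(geom, "arithmetic"), lam - 1)
  dead <- structure(data.frame(year = 0:2, N = c(10, 1, 0)),
                    class = c("birdscape_trajectory", "data.frame"))
  expect_equal(growth_rate(dead), -1)
  bad <- structure(data.frame(year = 0:1, N = c(0, 0)),
                   class = c("birdscape_trajectory", "data.frame"))
  expect_error(growth_rate(bad), "positive")
})
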