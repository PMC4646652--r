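test_that("scenarios wire policies into landscapes deterministically", {
  scen <- build_scenario("PROFIT_MAXIMIZING_PRODUCER", "STATUS_QUO", seed = 4)
  roles <- sort(vapply(scen$landscapes, function(l) l$role, ""))
  expect_equal(roles, c("BREEDING", "STOPOVER", "STOPOVER", "STOPOVER", "WINTERING"))
  # profit weight 1.00 + agriculture-dominant profit utility => agriculture
  expect_gt(scen$dist[["AGRICULTURE"]], 0.95)
  scen2 <- build_scenario("PROFIT_MAXIMIZING_PRODUCER", "STATUS_QUO", seed = 4)
  for (k in 1:5) expect_identical(scen$landscapes[[k]]$grid, scen2$landscapes[[k]]$grid)
  expect_false(identical(
    scen$landscapes[[1]]$grid,
    build_scenario("PROFIT_MAXIMIZING_PRODUCER", "STATUS_QUO", seed = 5)$landscapes[[1]]$grid))
})

test_that("consequence table has 21 cells and is a pure function of its seed", {
  tbl <- run_consequence_table(replicates = 2, base_seed = 3)
  expect_equal(dim(tbl$mean), c(7L, 3L))
  expect_equal(dim(tbl$se), c(7L, 3L))
  expect_true(all(is.finite(tbl$mean)))
  tbl2 <- run_consequence_table(replicates = 2, base_seed = 3)
  expect_identical(tbl$mean, tbl2$mean)
  expect_false(identical(tbl$mean, run_consequence_table(replicates = 2, base_seed = 4)$mean))
})

test_that("batched table replicates agree with scalar scenario simulation", {
  cfg <- default_config()
  tbl <- run_consequence_table(cfg, replicates = 1, base_seed = 11)
  for (cell in c(1L, 10L, 21L)) {  # (policy, landowner) with landowner fastest
    pi <- (cell - 1L) %/% 3L + 1L
    li <- (cell - 1L) %% 3L + 1L
    scen <- build_scenario(landowner_types()[li], policy_alternatives()[pi], cfg,
                           seed = derive_seed(11, cell, 1))
    g <- growth_rate(simulate_population(scen))
    expect_equal(tbl$mean[pi, li], g, tolerance = 1e-12)
  }
})

test_that("policy ranking sorts by growth with canonical tie-breaking", {
  tbl <- run_consequence_table(replicates = 1, base_seed = 2)
  tbl$mean[, 1] <- seq(0.7, 0.1, by = -0.1)          # strictly decreasing
  expect_equal(rank_policies(tbl, "PROFIT_MAXIMIZING_PRODUCER"), policy_alternatives())
  tbl$mean[, 2] <- 0.02                               # all equal -> enum order
  expect_equal(rank_policies(tbl, "SMALL_SCALE_FARMER"), policy_alternatives())
  tbl$mean[, 3] <- c(0.1, 0.5, 0.2, 0.5, 0.3, 0.1, 0.4)
  expect_equal(rank_policies(tbl, "CONSERVATIONIST")[1:2],
               c("REGULATORY_ENFORCEMENT", "BEST_MANAGEMENT_PRACTICES"))
})

test_that("replicate dispersion mirrors the elicited structure", {
  tbl <- run_consequence_table(replicates = 40, base_seed = 6)
  rng <- apply(tbl$mean, 2, function(x) diff(range(x)))
  expect_lt(rng[["CONSERVATIONIST"]], rng[["SMALL_SCALE_FARMER"]])
  expect_lt(rng[["SMALL_SCALE_FARMER"]], rng[["PROFIT_MAXIMIZING_PRODUCER"]])
})

test_that("calibration round-trips a self-generated target and respects its budget", {
  cfg <- validate_config(list(simulation = list(replicates = 8)))
  # the target the model itself produces at the packaged parameters, under
  # the calibration's own replicate/seed scheme
  cd <- birdscape:::cell_dists(cfg)
  bs <- birdscape:::batch_summaries(cd$dists, 8, 77, cfg)
  g <- birdscape:::batch_growth(bs, cfg$demography, 100, 30)
  target <- matrix(as.numeric(tapply(g, bs$cell_of, mean)), 7, 3, byrow = TRUE,
                   dimnames = list(policy_alternatives(), landowner_types()))
  cal0 <- calibrate_defaults(target, tolerance = 1e-9, budget = 0, seed = 77,
                             cfg = cfg, replicates = 8)
  expect_equal(cal0$achieved_error, 0)
  expect_equal(cal0$evaluations, 1L)      # zero budget: incumbent only
  expect_true(cal0$signs_ok)
  expect_equal(unclass(cal0$params)[names(cal0$params)],
               unclass(cfg$demography)[names(cfg$demography)])
  cal1 <- calibrate_defaults(target, tolerance = 0.005, budget = 25, seed = 77,
                             cfg = cfg, replicates = 8)
  expect_lte(cal1$achieved_error, 0.005)  # search never loses the incumbent
  expect_lte(cal1$evaluations, 25L + 3L)
})

test_that("calibration rejects infeasible bounds and flags sign failures", {
  target <- reference_growth_table()
  expect_error(calibrate_defaults(target, bounds = list(nest_density = c(2, 1))),
               "infeasible")
  expect_error(calibrate_defaults(target, bounds = list(nest_survival = c(0.2, 1.4))),
               "\\[0,1\\]")
  expect_error(calibrate_defaults(target[1:3, ]), "7 x 3")
  # two policies with identical preference weights (hence identical cover
  # distributions) cannot carry opposite signs
  hopeless <- target
  hopeless["PUBLIC_LAND_ACQUISITION", "PROFIT_MAXIMIZING_PRODUCER"] <- 0.5
  hopeless["BEST_MANAGEMENT_PRACTICES", "PROFIT_MAXIMIZING_PRODUCER"] <- -0.5
  cfg <- validate_config(list(simulation = list(replicates = 4)))
  expect_warning(
    cal <- calibrate_defaults(hopeless, budget = 5, seed = 3, cfg = cfg, replicates = 4),
    "sign mismatch")
  expect_false(cal$signs_ok)
})

test_that("the grassland response curve has the requested shape", {
  cfg <- default_config()
  cv <- grassland_response_curve(cfg, steps = 5, replicates = 10, seed = 2)
  expect_equal(nrow(cv), 5L)
  expect_equal(cv$p_grassland, seq(0, 1, length.out = 5))
  expect_lt(cv$mean_growth[1], cv$mean_growth[5])  # endpoints ordered
  expect_error(grassland_response_curve(cfg, steps = 1), ">= 2")
})
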