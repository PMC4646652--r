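# shared fixtures, built in code

G <- 1L; A <- 2L; FR <- 3L

make_landscape <- function(codes, role = "BREEDING", nrow = NULL) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = nrow, byrow = TRUE)
  landscape(codes, role = role)
}

uniform_landscape <- function(code, n = 5, role = "BREEDING") {
  landscape(matrix(code, n, n), role = role)
}

# demography with simple round numbers for hand computation
hand_params <- function(...) {
  base <- list(
    nest_density = 0.5, nest_survival = 0.5, edge_penalty = 0.5,
    fledglings_per_nest = 2,
    occupancy = c(GRASSLAND = 1, AGRICULTURE = 0.5, FOREST = 0.25),
    stopover_survival = c(GRASSLAND = 1, AGRICULTURE = 0.5, FOREST = 0.75),
    winter_survival = c(GRASSLAND = 0.8, AGRICULTURE = 0.4, FOREST = 0.6),
    k_breeding = 10, k_stopover = 10, k_winter = 10,
    matrix_survival_floor = 0.2)
  do.call(demographic_params, modifyList(base, list(...)))
}

# scenario-shaped list over explicit landscapes
hand_scenario <- function(breeding, stops, winter, params, n0 = 100, horizon = 30) {
  list(landscapes = c(list(breeding), stops, list(winter)),
       params = params, n0 = n0, horizon = horizon, stochastic = FALSE, seed = 1L)
}

random_params <- function() {
  rmap <- function() setNames(runif(3), land_covers())
  demographic_params(
    nest_density = runif(1, 0, 1), nest_survival = runif(1),
    edge_penalty = runif(1), fledglings_per_nest = runif(1, 0, 5),
    occupancy = rmap(), stopover_survival = rmap(), winter_survival = rmap(),
    k_breeding = runif(1, 0, 5), k_stopover = runif(1, 0, 20),
    k_winter = runif(1, 0, 20), matrix_survival_floor = runif(1))
}
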