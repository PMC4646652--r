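#' Full-annual-cycle grassland bird population model
#'
#' The population at the start of the breeding season follows
#' `N[t] = N[t-1] * (1 + R_b) * S_f * S_w * S_s`,
#' where `R_b` is per-capita reproductive output on the breeding landscape
#' and `S_f`, `S_w`, `S_s` are survival through fall migration (three
#' stopovers), winter, and spring migration (the same stopovers, reversed).
#' Each rate is a function of the land-cover composition and configuration
#' of the corresponding landscape, with seasonal carrying capacities tied
#' to the amount of grassland.
#'
#' @name bird_model
NULL

# ---- internal: vectorized neighborhood machinery --------------------------

# sum of M over the 3x3 window centered on each cell (edge-truncated)
box_sum3 <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- M
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + P[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  }
  out
}

# Per-landscape sufficient statistics for the annual-cycle rates.
# All are pure functions of the cover grid, independent of the demographic
# parameters, so a landscape is summarized once per simulation:
#  - n_pix, counts: pixel totals per cover
#  - n_grass, edge_sum: grassland pixel count and the summed non-grassland
#    Moore-ring fraction over grassland pixels (reproduction)
#  - M[a, c]: sum over pixels of focal cover a of n_c / m  (occupancy
#    quadratic form; n_c = ring count of cover c, m = ring size)
#  - TT[a, c, b]: as M but additionally weighted by the 3x3-window share
#    w_b / (m + 1) of cover b (couples occupancy weights to patch quality)
landscape_summary <- function(ls) {
  g <- ls$grid
  ind <- lapply(1:3, function(k) (g == k) + 0)          # indicator per cover
  nbr <- lapply(ind, function(I) box_sum3(I) - I)        # Moore ring counts
  m <- nbr[[1L]] + nbr[[2L]] + nbr[[3L]]                 # ring sizes (3/5/8)
  wtot <- m + 1                                          # 3x3 window sizes
  counts <- vapply(ind, sum, 0)
  n_grass <- counts[1L]
  f_nonG <- (nbr[[2L]] + nbr[[3L]]) / m                  # non-grassland ring fraction
  edge_sum <- sum(f_nonG[g == 1L])
  M <- matrix(0, 3L, 3L)
  TT <- array(0, c(3L, 3L, 3L))
  for (a in 1:3) {
    sel <- ind[[a]] == 1
    for (cc in 1:3) {
      ratio <- (nbr[[cc]] / m)[sel]
      M[a, cc] <- sum(ratio)
      for (b in 1:3) {
        win_b <- (nbr[[b]] + ind[[b]])  # 3x3 window counts of cover b
        TT[a, cc, b] <- sum(ratio * ((win_b / wtot)[sel]))
      }
    }
  }
  list(n_pix = length(g), counts = counts, n_grass = n_grass,
       edge_sum = edge_sum, M = M, TT = TT)
}

rb_from_summary <- function(s, N, p) {
  if (N <= 0 || s$n_grass == 0) return(0)
  K_b <- p$k_breeding * s$n_grass
  if (K_b <= 0) return(0)
  F_pot <- p$nest_density * p$fledglings_per_nest * p$nest_survival *
    (s$n_grass - p$edge_penalty * s$edge_sum)
  breeders <- min(N, K_b)
  F_pot * (breeders / K_b) / N
}

stopover_from_summary <- function(s, N, p) {
  occ <- p$occupancy
  denom <- as.numeric(occ %*% s$M %*% occ)  # sum of occupancy weights
  K <- p$k_stopover * s$n_grass
  if (denom <= 0 || K <= 0) return(p$matrix_survival_floor)
  sv <- p$stopover_survival
  numer <- sum(vapply(1:3, function(b) sv[b] * as.numeric(occ %*% s$TT[, , b] %*% occ), 0))
  s_settled <- numer / denom
  if (N <= 0) return(s_settled)
  settled <- min(N, K)
  (settled * s_settled + (N - settled) * p$matrix_survival_floor) / N
}

winter_from_summary <- function(s, N, p) {
  occ <- p$occupancy
  denom <- sum(occ * s$counts)
  K <- p$k_winter * s$n_grass
  if (denom <= 0 || K <= 0) return(p$matrix_survival_floor)
  s_settled <- sum(occ * p$winter_survival * s$counts) / denom
  if (N <= 0) return(s_settled)
  settled <- min(N, K)
  (settled * s_settled + (N - settled) * p$matrix_survival_floor) / N
}

check_role <- function(ls, role, what) {
  stopifnot(inherits(ls, "birdscape_landscape"))
  if (ls$role != role) {
    stop(sprintf("%s requires a landscape with role %s, got %s", what, role, ls$role),
         call. = FALSE)
  }
}

# ---- reproduction ---------------------------------------------------------

#' Potential fledgling production of a breeding landscape
#'
#' The per-pixel expected fledgling output, summed over the grid: each
#' grassland pixel contributes
#' `nest_density * fledglings_per_nest * nest_survival * (1 - edge_penalty * f_nonG)`,
#' where `f_nonG` is the non-grassland fraction of its radius-1 Moore ring
#' (edge-truncated); non-grassland pixels contribute nothing. This is the
#' landscape's fledgling output when breeding is at capacity.
#'
#' @param breeding A [landscape()] with role `"BREEDING"`.
#' @param p [demographic_params()].
#' @return Expected fledglings (non-negative scalar).
#' @export
fledgling_potential <- function(breeding, p) {
  check_role(breeding, "BREEDING", "fledgling_potential")
  s <- landscape_summary(breeding)
  p$nest_density * p$fledglings_per_nest * p$nest_survival *
    (s$n_grass - p$edge_penalty * s$edge_sum)
}

#' Per-capita reproductive output on the breeding landscape
#'
#' Nesting is limited by the breeding capacity `K_b = k_breeding * n_grass`:
#' `min(N, K_b)` birds breed, producing a share `min(N, K_b) / K_b` of the
#' landscape's [fledgling_potential()]. `R_b` is total fledglings divided
#' by `N`. Below capacity the per-capita output is therefore constant
#' (density-independent growth); above it, total output saturates and
#' `R_b` declines as `1/N`. Zero grassland, or `N = 0`, gives `R_b = 0`.
#'
#' @param breeding A [landscape()] with role `"BREEDING"`.
#' @param N Abundance at the start of the breeding season.
#' @param p [demographic_params()].
#' @return Per-capita reproductive output `R_b >= 0`.
#' @export
reproduction <- function(breeding, N, p) {
  check_role(breeding, "BREEDING", "reproduction")
  if (N < 0) stop("abundance must be >= 0", call. = FALSE)
  rb_from_summary(landscape_summary(breeding), N, p)
}

# ---- migration and winter -------------------------------------------------

#' Survival through one migratory stopover
#'
#' Stopover survival separates occupancy from survivorship. A pixel's
#' occupancy weight is `occupancy[cover] * mean(occupancy over its Moore
#' ring)` — a pixel is found and used as a function of both its own cover
#' and its immediate surroundings. Birds settle on pixels proportionally to
#' these weights, up to the stop's capacity `k_stopover * n_grass`; birds
#' beyond capacity (or with no usable habitat at all) survive at
#' `matrix_survival_floor`. A settled bird survives with probability equal
#' to the forage quality of its one-hectare patch
#' ([patch_quality()] under `stopover_survival`). The returned value is the
#' abundance-weighted mean survival.
#'
#' @param stop A [landscape()] with role `"STOPOVER"`.
#' @param N Abundance arriving at the stop.
#' @param p [demographic_params()].
#' @return Survival probability in `[0, 1]`.
#' @export
stopover_survival <- function(stop, N, p) {
  check_role(stop, "STOPOVER", "stopover_survival")
  if (N < 0) stop("abundance must be >= 0", call. = FALSE)
  # reference per-pixel computation (simulate_population uses the
  # algebraically identical landscape_summary fast path)
  g <- stop$grid
  occ_map <- p$occupancy[g]; dim(occ_map) <- dim(g)
  m <- box_sum3(matrix(1, nrow(g), ncol(g))) - 1
  nbr_mean_occ <- (box_sum3(occ_map) - occ_map) / m
  o <- occ_map * nbr_mean_occ
  K <- p$k_stopover * sum(g == 1L)
  if (sum(o) <= 0 || K <= 0) return(p$matrix_survival_floor)
  sv_map <- p$stopover_survival[g]; dim(sv_map) <- dim(g)
  s_pix <- box_sum3(sv_map) / (m + 1)       # patch quality incl. focal pixel
  s_settled <- sum(o * s_pix) / sum(o)
  if (N <= 0) return(s_settled)
  settled <- min(N, K)
  (settled * s_settled + (N - settled) * p$matrix_survival_floor) / N
}

#' Survival across one migration (three stopovers)
#'
#' The three stopover survivals are evaluated sequentially at the running
#' abundance — the flock shrinks between stops, which matters where a
#' stop's capacity binds — and multiplied. Southbound (fall) visits the
#' stops in list order; northbound (spring) reverses them.
#'
#' @param stops List of exactly three [landscape()]s with role `"STOPOVER"`.
#' @param N Abundance entering migration.
#' @param p [demographic_params()].
#' @param direction `"southbound"` (fall, `S_f`) or `"northbound"`
#'   (spring, `S_s`).
#' @return Migration survival probability in `[0, 1]`.
#' @export
migration_survival <- function(stops, N, p, direction = c("southbound", "northbound")) {
  direction <- match.arg(direction)
  if (!is.list(stops) || length(stops) != 3L) {
    stop("migration requires exactly 3 stopover landscapes", call. = FALSE)
  }
  if (direction == "northbound") stops <- rev(stops)
  S <- 1
  Ncur <- N
  for (st in stops) {
    s <- stopover_survival(st, Ncur, p)
    S <- S * s
    Ncur <- Ncur * s
  }
  S
}

#' Over-winter survival
#'
#' Winter works like a stopover but without any neighborhood effect:
#' occupancy weight and survival depend on the pixel's own cover only.
#' Birds settle proportionally to `occupancy[cover]` up to
#' `k_winter * n_grass`; overflow survives at `matrix_survival_floor`.
#'
#' @param win A [landscape()] with role `"WINTERING"`.
#' @param N Abundance entering winter.
#' @param p [demographic_params()].
#' @return Winter survival probability in `[0, 1]`.
#' @export
winter_survival <- function(win, N, p) {
  check_role(win, "WINTERING", "winter_survival")
  if (N < 0) stop("abundance must be >= 0", call. = FALSE)
  winter_from_summary(landscape_summary(win), N, p)
}

# ---- the annual recursion -------------------------------------------------

#' One step of the annual population recursion
#'
#' `N * (1 + R_b) * S_f * S_w * S_s`.
#'
#' @param N Abundance at the start of the breeding season.
#' @param R_b Per-capita reproductive output (>= 0).
#' @param S_f,S_w,S_s Fall, winter and spring survival probabilities.
#' @return Next year's abundance.
#' @export
step_population <- function(N, R_b, S_f, S_w, S_s) {
  if (N < 0 || R_b < 0) stop("N and R_b must be >= 0", call. = FALSE)
  for (s in c(S_f, S_w, S_s)) {
    if (s < 0 || s > 1) stop("survival probabilities must lie in [0,1]", call. = FALSE)
  }
  N * (1 + R_b) * S_f * S_w * S_s
}

#' Simulate the annual cycle over a scenario's five landscapes
#'
#' Iterates breed, fall migration, winter, spring migration for `horizon`
#' years over static landscapes, with the census at the start of the
#' breeding season. Demography is expected-value (deterministic) by
#' default; with `scen$stochastic = TRUE`, fledglings are Poisson and
#' survivors binomial, drawn from a private RNG stream seeded by `seed`.
#'
#' @param scen A [build_scenario()] result (or any list with elements
#'   `landscapes` (1 breeding, 3 stopovers, 1 wintering), `params`, `n0`,
#'   and optionally `stochastic`).
#' @param horizon Number of years to simulate (default from the scenario,
#'   else 30).
#' @param seed Seed for demographic stochasticity (unused in the default
#'   deterministic mode).
#' @return A `birdscape_trajectory` data frame with columns `year`
#'   (0..horizon), `N`, and the rates `R_b`, `S_f`, `S_w`, `S_s` applied in
#'   the transition ending at that row's year (NA in year 0).
#' @export
simulate_population <- function(scen, horizon = NULL, seed = NULL) {
  roles <- vapply(scen$landscapes, function(l) l$role, "")
  if (sum(roles == "BREEDING") != 1L || sum(roles == "STOPOVER") != 3L ||
      sum(roles == "WINTERING") != 1L) {
    stop("a scenario needs exactly 1 BREEDING, 3 STOPOVER and 1 WINTERING landscape; got roles: ",
         paste(roles, collapse = ", "), call. = FALSE)
  }
  horizon <- as.integer(horizon %||% scen$horizon %||% 30L)
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  p <- scen$params
  stochastic <- isTRUE(scen$stochastic)
  seed <- seed %||% scen$seed %||% 1L

  breeding <- landscape_summary(scen$landscapes[[which(roles == "BREEDING")]])
  stops <- lapply(scen$landscapes[which(roles == "STOPOVER")], landscape_summary)
  winter <- landscape_summary(scen$landscapes[[which(roles == "WINTERING")]])

  N <- as.numeric(scen$n0 %||% 100)
  if (N <= 0) stop("initial abundance n0 must be > 0", call. = FALSE)

  run_year <- function(N) {
    rb <- rb_from_summary(breeding, N, p)
    Fled <- N * rb
    if (stochastic && Fled > 0) Fled <- stats::rpois(1L, Fled)
    N1 <- N + Fled
    stage_survive <- function(N1, s) {
      if (stochastic) {
        if (N1 <= 0) 0 else stats::rbinom(1L, round(N1), s)
      } else N1 * s
    }
    sf <- 1
    for (st in stops) {
      s <- stopover_from_summary(st, N1, p)
      sf <- sf * s
      N1 <- stage_survive(N1, s)
    }
    sw <- winter_from_summary(winter, N1, p)
    N1 <- stage_survive(N1, sw)
    ss <- 1
    for (st in rev(stops)) {
      s <- stopover_from_summary(st, N1, p)
      ss <- ss * s
      N1 <- stage_survive(N1, s)
    }
    list(N = N1, R_b = rb, S_f = sf, S_w = sw, S_s = ss)
  }

  do_run <- function() {
    out <- data.frame(year = 0:horizon, N = NA_real_, R_b = NA_real_,
                      S_f = NA_real_, S_w = NA_real_, S_s = NA_real_)
    out$N[1L] <- N
    Ncur <- N
    if (horizon > 0) {
      for (t in seq_len(horizon)) {
        yr <- run_year(Ncur)
        Ncur <- yr$N
        out[t + 1L, c("N", "R_b", "S_f", "S_w", "S_s")] <-
          c(yr$N, yr$R_b, yr$S_f, yr$S_w, yr$S_s)
      }
    }
    out
  }
  tr <- if (stochastic) withr::with_seed(as.integer(seed), do_run()) else do_run()
  class(tr) <- c("birdscape_trajectory", "data.frame")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean annual population growth rate of a trajectory
#'
#' The geometric mean annual rate `(N_T / N_0)^(1/T) - 1` (default), or the
#' arithmetic mean of the per-year rates `N_t / N_{t-1} - 1`. A trajectory
#' that hits zero has geometric rate -1.
#'
#' @param tr A trajectory from [simulate_population()].
#' @param type `"geometric"` (default) or `"arithmetic"`.
#' @return Mean annual growth rate.
#' @export
growth_rate <- function(tr, type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  N <- tr$N
  if (length(N) < 2L) stop("trajectory must span at least one year", call. = FALSE)
  if (N[1L] <= 0) stop("trajectory must start from positive abundance", call. = FALSE)
  TT <- length(N) - 1L
  if (type == "geometric") {
    if (N[length(N)] == 0) return(-1)
    (N[length(N)] / N[1L])^(1 / TT) - 1
  } else {
    mean(N[-1L] / N[-length(N)] - 1)
  }
}
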