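#' Hierarchical seed derivation
#'
#' All randomness in a run flows from one base seed. Sub-seeds for cells,
#' replicates and landscape slots are derived by folding the index path
#' into the seed with a fixed multiplicative congruence:
#' `s <- (s * 1000003 + k) mod (2^31 - 1)` for each index `k`, then mapped
#' into `1..2^31-2`. Adding replicates or cells never perturbs the seeds of
#' earlier ones.
#'
#' @param base Integer base seed.
#' @param ... Integer indices (cell, replicate, landscape slot, ...).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(base, ...) {
  s <- as.numeric(base) %% 2147483647
  for (k in c(...)) {
    s <- (s * 1000003 + as.numeric(k)) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

#' Assemble a policy-by-landowner scenario
#'
#' Wires one `(landowner, policy)` pair into a runnable scenario: looks up
#' the elicited preference weights, normalizes them, converts them to a
#' cover distribution through the utility matrix and choice model, and
#' generates the five landscapes (1 breeding, 3 stopover, 1 wintering)
#' from that distribution with per-slot sub-seeds. Each landscape is owned
#' entirely by the one landowner type.
#'
#' @param landowner One of `landowner_types()`.
#' @param policy One of `policy_alternatives()`.
#' @param cfg A [default_config()]-shaped configuration.
#' @param seed Integer seed; landscape slot `k` uses `derive_seed(seed, k)`.
#' @return A `birdscape_scenario` list with elements `landowner`, `policy`,
#'   `weights`, `dist`, `landscapes`, `params`, `n0`, `horizon`,
#'   `stochastic`, `seed`.
#' @export
build_scenario <- function(landowner, policy, cfg = default_config(), seed = 1L) {
  cfg <- validate_config(cfg)
  w <- normalize_weights(apply_policy(landowner, policy))
  dist <- choice_probabilities(w, cfg$utility, cfg$choice)
  roles <- c("BREEDING", "STOPOVER", "STOPOVER", "STOPOVER", "WINTERING")
  lsc <- cfg$landscape
  landscapes <- lapply(seq_along(roles), function(k) {
    d <- stage_dist(cfg, roles[k]) %||% dist
    generate_landscape(d, n_rows = lsc$n_rows, n_cols = lsc$n_cols,
                       role = roles[k], seed = derive_seed(seed, k),
                       pixel_size_m = lsc$pixel_size_m,
                       label = sprintf("%s/%s %s", landowner, policy, tolower(roles[k])))
  })
  structure(
    list(landowner = landowner, policy = policy, weights = w, dist = dist,
         landscapes = landscapes, params = cfg$demography,
         n0 = cfg$simulation$n0, horizon = cfg$simulation$horizon,
         stochastic = cfg$simulation$stochastic, seed = seed),
    class = "birdscape_scenario"
  )
}

# experimental hook: per-role cover distributions override the ABM output
stage_dist <- function(cfg, role) {
  sd <- cfg$stage_distributions
  if (is.null(sd)) return(NULL)
  if (!is.null(sd[[role]])) cover_distribution(unlist(sd[[role]])) else NULL
}

# ---- batched simulation over many generated landscape sets ----------------
#
# The consequence table, response curve and calibration all simulate many
# independent replicate landscape sets. Landscape summaries are pure
# functions of the grids, so they are computed once and stacked into flat
# matrices; the annual-cycle recursion then runs vectorized across all
# replicates at once (the per-year rates depend on N only through the
# capacity overflow, so each stage is a handful of vector operations).

# dists: list of cover distributions ("cells"); returns stacked summaries
# for n_rep replicate landscape sets per cell, with slot seeds
# derive_seed(derive_seed(base_seed, cell, rep), slot) so that a single
# scenario built with seed derive_seed(base_seed, cell, rep) reproduces
# replicate rep exactly.
batch_summaries <- function(dists, n_rep, base_seed, cfg) {
  lsc <- cfg$landscape
  n_cells <- length(dists)
  n_runs <- n_cells * n_rep
  roles <- c("BREEDING", "STOPOVER", "STOPOVER", "STOPOVER", "WINTERING")
  b_grass <- b_edge <- numeric(n_runs)
  stop_TT <- lapply(1:3, function(j) matrix(0, n_runs, 27L))
  stop_M <- lapply(1:3, function(j) matrix(0, n_runs, 9L))
  stop_grass <- lapply(1:3, function(j) numeric(n_runs))
  w_counts <- matrix(0, n_runs, 3L)
  w_grass <- numeric(n_runs)
  cell_of <- integer(n_runs)
  i <- 0L
  for (ci in seq_len(n_cells)) {
    for (r in seq_len(n_rep)) {
      i <- i + 1L
      cell_of[i] <- ci
      scen_seed <- derive_seed(base_seed, ci, r)
      sj <- 0L
      for (k in seq_along(roles)) {
        d <- stage_dist(cfg, roles[k]) %||% dists[[ci]]
        ls <- generate_landscape(d, n_rows = lsc$n_rows, n_cols = lsc$n_cols,
                                 role = roles[k], seed = derive_seed(scen_seed, k),
                                 pixel_size_m = lsc$pixel_size_m)
        s <- landscape_summary(ls)
        if (roles[k] == "BREEDING") {
          b_grass[i] <- s$n_grass; b_edge[i] <- s$edge_sum
        } else if (roles[k] == "STOPOVER") {
          sj <- sj + 1L
          stop_TT[[sj]][i, ] <- as.vector(s$TT)
          stop_M[[sj]][i, ] <- as.vector(s$M)
          stop_grass[[sj]][i] <- s$n_grass
        } else {
          w_counts[i, ] <- s$counts; w_grass[i] <- s$n_grass
        }
      }
    }
  }
  list(n_runs = n_runs, cell_of = cell_of,
       b_grass = b_grass, b_edge = b_edge,
       stop_TT = stop_TT, stop_M = stop_M, stop_grass = stop_grass,
       w_counts = w_counts, w_grass = w_grass)
}

# vectorized annual-cycle recursion over stacked summaries; returns the
# geometric mean annual growth rate of every run
batch_growth <- function(bs, p, n0, horizon) {
  occ <- unname(p$occupancy)
  occ2 <- as.vector(outer(occ, occ))                 # occ_a * occ_c, a fastest
  tts <- as.vector(outer(occ2, unname(p$stopover_survival)))
  floor_s <- p$matrix_survival_floor

  # N-independent stage constants per run
  K_b <- p$k_breeding * bs$b_grass
  F_pot <- p$nest_density * p$fledglings_per_nest * p$nest_survival *
    (bs$b_grass - p$edge_penalty * bs$b_edge)
  rho <- ifelse(K_b > 0, F_pot / K_b, 0)             # per-breeder output

  stop_s <- stop_K <- stop_bad <- vector("list", 3L)
  for (j in 1:3) {
    denom <- as.vector(bs$stop_M[[j]] %*% occ2)
    numer <- as.vector(bs$stop_TT[[j]] %*% tts)
    K <- p$k_stopover * bs$stop_grass[[j]]
    bad <- denom <= 0 | K <= 0
    stop_s[[j]] <- ifelse(bad, floor_s, numer / pmax(denom, 1e-300))
    stop_K[[j]] <- K
    stop_bad[[j]] <- bad
  }
  w_denom <- as.vector(bs$w_counts %*% occ)
  w_numer <- as.vector(bs$w_counts %*% (occ * unname(p$winter_survival)))
  K_w <- p$k_winter * bs$w_grass
  w_bad <- w_denom <= 0 | K_w <= 0
  w_s <- ifelse(w_bad, floor_s, w_numer / pmax(w_denom, 1e-300))

  survive_stage <- function(N, s_set, K, bad) {
    ifelse(bad, N * floor_s, pmin(N, K) * s_set + pmax(N - K, 0) * floor_s)
  }

  N <- rep(as.numeric(n0), bs$n_runs)
  for (t in seq_len(horizon)) {
    N <- N + rho * pmin(N, K_b)                      # breeding
    for (j in 1:3) N <- survive_stage(N, stop_s[[j]], stop_K[[j]], stop_bad[[j]])
    N <- survive_stage(N, w_s, K_w, w_bad)
    for (j in 3:1) N <- survive_stage(N, stop_s[[j]], stop_K[[j]], stop_bad[[j]])
  }
  ifelse(N <= 0, -1, (N / n0)^(1 / horizon) - 1)
}

cell_dists <- function(cfg) {
  pairs <- expand.grid(landowner = landowner_types(), policy = policy_alternatives(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # row-major over policies, landowner fastest: cell index (pi-1)*3 + li
  pairs <- pairs[order(match(pairs$policy, policy_alternatives()),
                       match(pairs$landowner, landowner_types())), ]
  dists <- lapply(seq_len(nrow(pairs)), function(i) {
    w <- normalize_weights(apply_policy(pairs$landowner[i], pairs$policy[i]))
    choice_probabilities(w, cfg$utility, cfg$choice)
  })
  list(pairs = pairs, dists = dists)
}

#' Policy-by-landowner consequence table of population growth rates
#'
#' For each of the 21 (policy, landowner) combinations, runs `replicates`
#' independent seeded scenarios — fresh landscapes drawn from the
#' policy-conditioned cover distribution each time — simulates the annual
#' cycle over the configured horizon, and records the mean and standard
#' error of the geometric mean annual growth rate. The whole table is a
#' pure function of `(cfg, replicates, base_seed)`.
#'
#' @param cfg A [default_config()]-shaped configuration.
#' @param replicates Replicate scenarios per cell (default from config, 100).
#' @param base_seed Integer base seed; replicate `r` of cell `ci` uses
#'   `derive_seed(base_seed, ci, r)`.
#' @return A `birdscape_consequence_table`: list with 7 x 3 matrices `mean`
#'   and `se` (policies x landowner types), plus `replicates` and
#'   `base_seed`.
#' @export
run_consequence_table <- function(cfg = default_config(), replicates = NULL,
                                  base_seed = 1L) {
  cfg <- validate_config(cfg)
  replicates <- as.integer(replicates %||% cfg$simulation$replicates)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  cd <- cell_dists(cfg)
  bs <- batch_summaries(cd$dists, replicates, base_seed, cfg)
  g <- batch_growth(bs, cfg$demography, cfg$simulation$n0, cfg$simulation$horizon)
  means <- tapply(g, bs$cell_of, mean)
  ses <- tapply(g, bs$cell_of, function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0)
  shape <- function(x) {
    m <- matrix(as.numeric(x), nrow = 7L, ncol = 3L, byrow = TRUE,
                dimnames = list(policy_alternatives(), landowner_types()))
    m
  }
  structure(list(mean = shape(means), se = shape(ses),
                 replicates = replicates, base_seed = as.integer(base_seed)),
            class = "birdscape_consequence_table")
}

#' @export
print.birdscape_consequence_table <- function(x, ...) {
  cat(sprintf("<consequence table> mean annual growth rate, %d replicates/cell, base seed %d\n",
              x$replicates, x$base_seed))
  print(round(x$mean, 4))
  invisible(x)
}

#' Write a consequence table to CSV
#'
#' Writes the replicate-mean growth rates as an RFC-4180 CSV (policy rows
#' in the canonical order, landowner columns), plus a companion
#' `*_se.csv` with the replicate standard errors.
#'
#' @param tbl A [run_consequence_table()] result.
#' @param path Output CSV path; the SE companion replaces `.csv` with
#'   `_se.csv`.
#' @return `path`, invisibly.
#' @export
write_consequence_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "birdscape_consequence_table"))
  as_df <- function(m) data.frame(policy = rownames(m), m, check.names = FALSE,
                                  row.names = NULL)
  write_csv_lf(as_df(tbl$mean), path)
  write_csv_lf(as_df(tbl$se), sub("\\.csv$", "_se.csv", path))
  invisible(path)
}

write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
}

#' Rank policies for a landowner type
#'
#' Policies sorted by descending mean growth rate in the landowner's
#' column; exact ties keep the canonical `policy_alternatives()` order.
#'
#' @param tbl A [run_consequence_table()] result.
#' @param landowner One of `landowner_types()`.
#' @return Character vector of policies, best first.
#' @export
rank_policies <- function(tbl, landowner) {
  stopifnot(inherits(tbl, "birdscape_consequence_table"))
  landowner <- match_enum(landowner, landowner_types(), "landowner type")
  v <- tbl$mean[, landowner]
  policy_alternatives()[order(-v, seq_along(v))]
}

#' Growth-rate response to grassland cover
#'
#' Sweeps the grassland proportion shared by all five landscapes from 0 to
#' 1, splitting the remaining cover mass between agriculture and forest in
#' a configurable ratio, and records the replicate mean and standard error
#' of the annual growth rate at each step. Under the packaged parameters
#' the curve is non-decreasing: more grassland never hurts the population.
#'
#' @param cfg Configuration; `cfg$curve_split` (default
#'   `c(agriculture = 0.5, forest = 0.5)`) sets how non-grassland mass is
#'   divided.
#' @param steps Number of grassland proportions, evenly spaced over
#'   `[0, 1]` (>= 2).
#' @param replicates Replicate landscape sets per step.
#' @param seed Base seed.
#' @return Data frame with columns `p_grassland`, `mean_growth`, `se`.
#' @export
grassland_response_curve <- function(cfg = default_config(), steps = 11L,
                                     replicates = 50L, seed = 1L) {
  cfg <- validate_config(cfg)
  if (steps < 2) stop("steps must be >= 2", call. = FALSE)
  split <- cfg$curve_split %||% c(agriculture = 0.5, forest = 0.5)
  split <- split / sum(split)
  pg <- seq(0, 1, length.out = steps)
  dists <- lapply(pg, function(p) {
    cover_distribution(c(p, (1 - p) * split[[1L]], (1 - p) * split[[2L]]))
  })
  bs <- batch_summaries(dists, as.integer(replicates), seed, cfg)
  g <- batch_growth(bs, cfg$demography, cfg$simulation$n0, cfg$simulation$horizon)
  means <- as.numeric(tapply(g, bs$cell_of, mean))
  ses <- as.numeric(tapply(g, bs$cell_of, function(x) sd(x) / sqrt(length(x))))
  data.frame(p_grassland = pg, mean_growth = means, se = ses)
}

#' Packaged reference consequence table
#'
#' The reference consequence table bundled with the package: elicited mean
#' annual growth rates for the seven policies and three landowner types,
#' serving as the calibration target for
#' [calibrate_defaults()].
#'
#' @return A 7 x 3 numeric matrix, policies x landowner types.
#' @export
reference_growth_table <- function() {
  path <- system.file("extdata", "reference_growth_rates.csv", package = "birdscape",
                      mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, landowner_types()])
  rownames(m) <- df$policy
  m[policy_alternatives(), ]
}
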