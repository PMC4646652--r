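#' Run configuration
#'
#' A configuration bundles everything a run needs: the utility matrix, the
#' choice model, the demographic parameters, landscape geometry, and
#' simulation settings. [default_config()] returns the packaged defaults
#' (calibrated demography, documented utility matrix, softmax temperature
#' 0.15, 40 x 40 x 30 m landscapes, horizon 30, N0 = 100, 100 replicates,
#' deterministic demography); [load_config()] reads a YAML file and fills
#' unset keys from those defaults, rejecting unknown keys and invariant
#' violations with the offending key named.
#'
#' Recognized YAML keys (all optional):
#' \preformatted{
#' choice:      temperature, deterministic
#' utility:     GRASSLAND/AGRICULTURE/FOREST: BIRDS, CARBON, WATER_QUALITY,
#'              FINANCIAL_PROFIT, BIODIVERSITY
#' demography:  nest_density, nest_survival, edge_penalty,
#'              fledglings_per_nest, k_breeding, k_stopover, k_winter,
#'              matrix_survival_floor, occupancy/stopover_survival/
#'              winter_survival: GRASSLAND, AGRICULTURE, FOREST
#' landscape:   n_rows, n_cols, pixel_size_m
#' simulation:  horizon, n0, replicates, stochastic
#' curve_split: agriculture, forest
#' stage_distributions:  (experimental) per-role cover distributions
#' output_dir
#' }
#' A commented template ships at
#' `system.file("extdata", "config-template.yaml", package = "birdscape")`.
#'
#' @return A validated `birdscape_config` list.
#' @export
default_config <- function() {
  validate_config(list())
}

#' @param path Path to a YAML config file (may be empty: all defaults).
#' @rdname default_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  validate_config(raw)
}

config_defaults_raw <- function() {
  list(
    choice = list(temperature = 0.15, deterministic = FALSE),
    utility = NULL,        # NULL -> utility_matrix() default
    demography = calibrated_demography_values(),
    landscape = list(n_rows = 40L, n_cols = 40L, pixel_size_m = 30),
    simulation = list(horizon = 30L, n0 = 100, replicates = 100L, stochastic = FALSE),
    curve_split = list(agriculture = 0.5, forest = 0.5),
    stage_distributions = NULL,
    output_dir = "."
  )
}

#' @param cfg A raw or validated configuration list.
#' @rdname default_config
#' @export
validate_config <- function(cfg) {
  if (inherits(cfg, "birdscape_config")) return(cfg)
  if (!is.list(cfg)) stop("config must be a list", call. = FALSE)
  defaults <- config_defaults_raw()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sect in c("choice", "landscape", "simulation", "demography", "curve_split")) {
    extra <- setdiff(names(cfg[[sect]]), names(defaults[[sect]]))
    if (length(extra)) {
      stop(sprintf("unknown config key(s) under '%s': %s", sect,
                   paste(paste0(sect, ".", extra), collapse = ", ")), call. = FALSE)
    }
  }
  merged <- modifyList(defaults, cfg, keep.null = TRUE)

  utility <- if (is.null(merged$utility)) utility_matrix() else {
    u <- merged$utility
    if (is.list(u)) {
      u <- do.call(rbind, lapply(land_covers(), function(cv) {
        row <- u[[cv]]
        if (is.null(row)) stop(sprintf("config utility is missing cover '%s'", cv), call. = FALSE)
        vapply(objectives(), function(o) {
          if (is.null(row[[o]])) stop(sprintf("config utility.%s is missing objective '%s'", cv, o),
                                      call. = FALSE)
          as.numeric(row[[o]])
        }, 0)
      }))
      rownames(u) <- land_covers()
    }
    utility_matrix(u)
  }

  ch <- merged$choice
  choice <- choice_model(temperature = as.numeric(ch$temperature),
                         deterministic = isTRUE(ch$deterministic))

  dem <- merged$demography
  for (f in c("occupancy", "stopover_survival", "winter_survival")) {
    if (is.list(dem[[f]])) dem[[f]] <- unlist(dem[[f]])
  }
  demography <- tryCatch(do.call(demographic_params, dem),
                         error = function(e) stop(sprintf("config demography: %s", conditionMessage(e)),
                                                  call. = FALSE))

  lsc <- merged$landscape
  if (lsc$n_rows < 1 || lsc$n_cols < 1) {
    stop("config landscape.n_rows / n_cols must be >= 1", call. = FALSE)
  }
  if (lsc$pixel_size_m <= 0) stop("config landscape.pixel_size_m must be > 0", call. = FALSE)

  sim <- merged$simulation
  if (sim$horizon < 0) stop("config simulation.horizon must be >= 0", call. = FALSE)
  if (sim$n0 <= 0) stop("config simulation.n0 must be > 0", call. = FALSE)
  if (sim$replicates < 1) stop("config simulation.replicates must be >= 1", call. = FALSE)

  cs <- unlist(merged$curve_split)
  if (any(cs < 0) || sum(cs) <= 0) {
    stop("config curve_split entries must be non-negative with a positive sum", call. = FALSE)
  }

  sd_cfg <- merged$stage_distributions
  if (!is.null(sd_cfg)) {
    bad <- setdiff(names(sd_cfg), landscape_roles())
    if (length(bad)) {
      stop("unknown config key(s) under 'stage_distributions': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (role in names(sd_cfg)) cover_distribution(unlist(sd_cfg[[role]]))
  }

  structure(
    list(utility = utility, choice = choice, demography = demography,
         landscape = list(n_rows = as.integer(lsc$n_rows), n_cols = as.integer(lsc$n_cols),
                          pixel_size_m = as.numeric(lsc$pixel_size_m)),
         simulation = list(horizon = as.integer(sim$horizon), n0 = as.numeric(sim$n0),
                           replicates = as.integer(sim$replicates),
                           stochastic = isTRUE(sim$stochastic)),
         curve_split = setNames(as.numeric(cs), names(cs)),
         stage_distributions = sd_cfg,
         output_dir = merged$output_dir),
    class = "birdscape_config"
  )
}

#' Serialize the effective configuration
#'
#' Renders a validated config back into the YAML schema understood by
#' [load_config()]; dumping and re-loading reproduces the same effective
#' configuration.
#'
#' @param cfg A configuration.
#' @param path Optional file to write; if `NULL` the YAML text is returned.
#' @return The YAML string (invisibly when written to `path`).
#' @export
dump_config <- function(cfg, path = NULL) {
  cfg <- validate_config(cfg)
  as_plain <- function(v) as.list(setNames(as.numeric(v), names(v)))
  u <- cfg$utility
  out <- list(
    choice = list(temperature = cfg$choice$temperature,
                  deterministic = cfg$choice$deterministic),
    utility = setNames(lapply(land_covers(), function(cv) as_plain(u[cv, ])), land_covers()),
    demography = {
      d <- unclass(cfg$demography)
      d$occupancy <- as_plain(d$occupancy)
      d$stopover_survival <- as_plain(d$stopover_survival)
      d$winter_survival <- as_plain(d$winter_survival)
      d
    },
    landscape = cfg$landscape,
    simulation = cfg$simulation,
    curve_split = as_plain(cfg$curve_split),
    output_dir = cfg$output_dir
  )
  if (!is.null(cfg$stage_distributions)) out$stage_distributions <- cfg$stage_distributions
  txt <- yaml::as.yaml(out)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Hash of the effective configuration
#'
#' MD5 of the canonical YAML serialization; used in run manifests so two
#' runs can be compared for configuration identity.
#'
#' @param cfg A configuration.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(dump_config(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run next to its outputs:
#' config hash, base seed, package version, timestamp, and an MD5 checksum
#' per output file. Re-running with the same config and seed reproduces
#' files with identical checksums.
#'
#' @param path Manifest path (JSON).
#' @param cfg The configuration used.
#' @param seed The base seed used.
#' @param outputs Character vector of output file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, cfg, seed, outputs = character()) {
  man <- list(
    config_hash = config_hash(cfg),
    seed = as.integer(seed),
    package = "birdscape",
    version = as.character(packageVersion("birdscape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns `year, N, R_b, S_f, S_w, S_s` (rates are those applied in the
#' transition ending at that year; empty in year 0).
#'
#' @param tr A [simulate_population()] trajectory.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  stopifnot(inherits(tr, "birdscape_trajectory"))
  write_csv_lf(as.data.frame(tr), path)
  invisible(path)
}
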