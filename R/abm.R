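#' Policy-conditioned landowner preference weights
#'
#' Each landowner archetype weights the five management objectives
#' (grassland birds, carbon storage, water quality, financial profit,
#' biodiversity) differently, and each policy alternative shifts those
#' weights. The full 3 landowner x 7 policy table of elicited weights ships
#' with the package, transcribed exactly as elicited; rows sum to 1 only up
#' to rounding (0.99-1.01), so use [normalize_weights()] before scoring.
#'
#' `preference_weight_table()` returns the whole table as a data frame;
#' `apply_policy()` returns the raw (un-normalized) weight vector for one
#' `(landowner, policy)` pair.
#'
#' @param landowner One of `landowner_types()`.
#' @param policy One of `policy_alternatives()`.
#' @return `apply_policy()`: a named numeric vector over `objectives()`.
#' @examples
#' apply_policy("CONSERVATIONIST", "STATUS_QUO")
#' @export
apply_policy <- function(landowner, policy) {
  landowner <- match_enum(landowner, landowner_types(), "landowner type")
  policy <- match_enum(policy, policy_alternatives(), "policy alternative")
  tbl <- preference_weight_table()
  row <- tbl[tbl$landowner == landowner & tbl$policy == policy, objectives()]
  if (nrow(row) != 1L) {
    stop(sprintf("no preference weights for (%s, %s)", landowner, policy), call. = FALSE)
  }
  unlist(row[1L, ])
}

#' @rdname apply_policy
#' @export
preference_weight_table <- function() {
  env <- pkg_cache_env()
  if (is.null(env$weights)) {
    path <- system.file("extdata", "preference_weights.csv", package = "birdscape",
                        mustWork = TRUE)
    tbl <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(identical(names(tbl), c("landowner", "policy", objectives())))
    env$weights <- tbl
  }
  env$weights
}

pkg_cache_env <- local({
  env <- new.env(parent = emptyenv())
  function() env
})

#' Normalize preference weights to sum to one
#'
#' As-elicited weight rows carry rounding, so they sum to 0.99-1.01;
#' normalization divides by the sum, preserving proportions.
#'
#' @param w Named non-negative numeric vector over `objectives()`.
#' @return Weights summing to 1.
#' @export
normalize_weights <- function(w) {
  w <- check_weights(w)
  s <- sum(w)
  if (s <= 0) stop("cannot normalize all-zero preference weights", call. = FALSE)
  w / s
}

check_weights <- function(w) {
  if (length(w) != 5L) {
    stop("preference weights must have one entry per objective (5)", call. = FALSE)
  }
  if (is.null(names(w))) names(w) <- objectives()
  w <- w[objectives()]
  if (anyNA(w)) stop("weight names must match objectives()", call. = FALSE)
  bad <- which(w < 0)
  if (length(bad)) {
    stop(sprintf("preference weight for %s is %g; weights must be non-negative",
                 names(w)[bad[1L]], w[bad[1L]]), call. = FALSE)
  }
  w
}

#' Utility of each land cover for each objective
#'
#' A 3 x 5 matrix (rows `land_covers()`, columns `objectives()`) with
#' entries in `[0, 1]`: the attractiveness of keeping a pixel in each cover
#' from the standpoint of each objective. Together with preference weights
#' it drives the multi-attribute score in [total_utility()].
#'
#' The packaged default encodes the ordinal structure of the system:
#' agriculture dominates financial profit; grassland dominates bird and
#' biodiversity value and scores well for carbon and water quality; forest
#' is intermediate. It can be overridden wholesale via the config file.
#'
#' @param values Optional 3 x 5 numeric matrix (or NULL for the default).
#' @return A validated utility matrix with canonical dimnames.
#' @export
utility_matrix <- function(values = NULL) {
  if (is.null(values)) {
    values <- rbind(
      GRASSLAND   = c(0.90, 0.80, 0.80, 0.20, 0.90),
      AGRICULTURE = c(0.05, 0.10, 0.10, 1.00, 0.05),
      FOREST      = c(0.30, 0.90, 0.70, 0.30, 0.60)
    )
    colnames(values) <- objectives()
  }
  if (!is.matrix(values) || !all(dim(values) == c(3L, 5L))) {
    stop("a utility matrix is 3 land covers x 5 objectives", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- land_covers()
  if (is.null(colnames(values))) colnames(values) <- objectives()
  values <- values[land_covers(), objectives()]
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    stop("utility entries must all be present and lie in [0,1]", call. = FALSE)
  }
  values
}

#' Multi-attribute utility of one land cover
#'
#' Simple multi-attribute rating: the weighted sum over objectives of the
#' cover's per-objective utilities, `sum_o w[o] * U[cover, o]`. With
#' normalized weights and utilities in `[0, 1]` the score lies in `[0, 1]`.
#'
#' @param w Normalized preference weights (see [normalize_weights()]).
#' @param U A [utility_matrix()].
#' @param cover One of `land_covers()`.
#' @return Scalar utility in `[0, 1]`.
#' @export
total_utility <- function(w, U, cover) {
  w <- check_weights(w)
  U <- utility_matrix(U)
  cover <- match_enum(cover, land_covers(), "land cover")
  sum(w * U[cover, ])
}

#' Choice model linking utilities to cover probabilities
#'
#' The landowner model needs both a rational reading (each owner picks the
#' cover that maximizes utility) and a per-pixel stochastic one (pixels are
#' assigned covers with policy-dependent probabilities). A softmax with a
#' sharpness temperature reconciles the two: at the default temperature
#' 0.15 choices concentrate strongly on the best cover, and the
#' deterministic argmax is the temperature-to-zero limit, available
#' directly via `deterministic = TRUE`.
#'
#' @param temperature Positive softmax temperature (sharpness; smaller is
#'   closer to argmax). Utilities live on a 0-1 scale, so 0.15 means a 0.15
#'   utility gap shifts odds by a factor e.
#' @param deterministic If TRUE, put all mass on the argmax cover (ties
#'   split uniformly) and ignore `temperature`.
#' @return A `birdscape_choice_model`.
#' @export
choice_model <- function(temperature = 0.15, deterministic = FALSE) {
  if (!isTRUE(deterministic) && (!is.numeric(temperature) || temperature <= 0)) {
    stop("softmax temperature must be > 0 (or set deterministic = TRUE)", call. = FALSE)
  }
  structure(list(temperature = temperature, deterministic = isTRUE(deterministic)),
            class = "birdscape_choice_model")
}

#' Cover-choice probabilities for a landowner
#'
#' Scores the three land covers by [total_utility()] and maps the scores to
#' a cover distribution: softmax at the model's temperature, or the argmax
#' indicator (ties split uniformly) in deterministic mode.
#'
#' @param w Normalized preference weights.
#' @param U A [utility_matrix()].
#' @param cm A [choice_model()].
#' @return A [cover_distribution()] (named, sums to 1).
#' @examples
#' w <- normalize_weights(apply_policy("SMALL_SCALE_FARMER", "STATUS_QUO"))
#' choice_probabilities(w, utility_matrix(), choice_model())
#' @export
choice_probabilities <- function(w, U = utility_matrix(), cm = choice_model()) {
  w <- check_weights(w)
  U <- utility_matrix(U)
  stopifnot(inherits(cm, "birdscape_choice_model"))
  u <- as.numeric(U %*% w)  # total utility per cover
  if (cm$deterministic) {
    top <- abs(u - max(u)) < 1e-12
    p <- as.numeric(top) / sum(top)
  } else {
    z <- (u - max(u)) / cm$temperature  # shift-invariant, overflow-safe
    p <- exp(z) / sum(exp(z))
  }
  cover_distribution(setNames(p, land_covers()))
}
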