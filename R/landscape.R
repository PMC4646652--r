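#' Raster landscapes of land-cover codes
#'
#' A `birdscape_landscape` is a rectangular grid of land-cover codes
#' (1 = GRASSLAND, 2 = AGRICULTURE, 3 = FOREST) with a fixed pixel size and
#' an annual-cycle role. The default geometry is a 40 x 40 grid of 30-m
#' pixels, i.e. 1600 pixels covering 1.44 km^2 — one simulated landholding.
#'
#' @param grid Integer matrix of cover codes in 1..3. Rows index grid rows;
#'   indexing is 1-based `(row, col)`.
#' @param pixel_size_m Pixel edge length in meters (default 30).
#' @param role One of `landscape_roles()`: the annual-cycle phase this
#'   landscape serves (`"BREEDING"`, `"STOPOVER"` or `"WINTERING"`).
#' @param label Free-text label carried through to output files.
#' @return A `birdscape_landscape` object.
#' @seealso [generate_landscape()], [composition()], [read_ascii_grid()]
#' @export
landscape <- function(grid, pixel_size_m = 30, role = "BREEDING", label = "") {
  if (!is.matrix(grid) || length(grid) == 0L) {
    stop("grid must be a non-empty matrix of cover codes", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  if (anyNA(grid) || any(grid < 1L) || any(grid > 3L)) {
    stop("grid entries must be land-cover codes 1 (GRASSLAND), 2 (AGRICULTURE) or 3 (FOREST)",
         call. = FALSE)
  }
  role <- match_enum(role, landscape_roles(), "landscape role")
  if (!is.numeric(pixel_size_m) || pixel_size_m <= 0) {
    stop("pixel_size_m must be a positive length in meters", call. = FALSE)
  }
  structure(
    list(grid = grid, pixel_size_m = as.numeric(pixel_size_m),
         role = role, label = as.character(label)),
    class = "birdscape_landscape"
  )
}

#' @export
print.birdscape_landscape <- function(x, ...) {
  comp <- composition(x)
  cat(sprintf("<birdscape_landscape> %dx%d px (%.0f m), role %s%s\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_m, x$role,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  cat(sprintf("  area %.4g km^2; cover: %s\n", area_km2(x),
              paste(sprintf("%s %.1f%%", names(comp), 100 * comp), collapse = ", ")))
  invisible(x)
}

#' Landscape area in square kilometers
#'
#' `n_pixels * pixel_size_m^2 / 1e6`; 1.44 for the default 40 x 40 grid of
#' 30-m pixels.
#'
#' @param ls A [landscape()].
#' @return Area in km^2.
#' @export
area_km2 <- function(ls) {
  stopifnot(inherits(ls, "birdscape_landscape"))
  length(ls$grid) * ls$pixel_size_m^2 / 1e6
}

#' Validate a cover distribution
#'
#' A cover distribution is a numeric vector of three probabilities
#' (grassland, agriculture, forest) that sums to one. Used as the per-pixel
#' sampling law when generating landscapes.
#'
#' @param dist Numeric vector of length 3, optionally named after
#'   `land_covers()`.
#' @return The distribution as a named numeric vector.
#' @export
cover_distribution <- function(dist) {
  if (length(dist) != 3L || !is.numeric(dist)) {
    stop("a cover distribution needs exactly three probabilities (grassland, agriculture, forest)",
         call. = FALSE)
  }
  if (is.null(names(dist))) names(dist) <- land_covers()
  dist <- dist[land_covers()]
  if (anyNA(dist)) stop("cover distribution names must match land_covers()", call. = FALSE)
  bad <- which(dist < 0 | dist > 1)
  if (length(bad)) {
    stop(sprintf("cover probability for %s is %g; probabilities must lie in [0,1]",
                 names(dist)[bad[1L]], dist[bad[1L]]), call. = FALSE)
  }
  if (abs(sum(dist) - 1) > 1e-9) {
    stop(sprintf("cover probabilities sum to %.10g, not 1 (GRASSLAND=%g, AGRICULTURE=%g, FOREST=%g)",
                 sum(dist), dist[1L], dist[2L], dist[3L]), call. = FALSE)
  }
  dist
}

#' Generate a random landscape from a cover distribution
#'
#' Each pixel is drawn independently from `dist`. Draws consume a single
#' seeded RNG stream in row-major pixel order, so a given
#' `(dist, n_rows, n_cols, seed)` always yields the same grid, and the
#' global RNG state is left untouched.
#'
#' @param dist A [cover_distribution()] (or plain length-3 vector).
#' @param n_rows,n_cols Grid dimensions (default 40 x 40).
#' @param role Annual-cycle role of the landscape.
#' @param seed Integer seed for the landscape's private RNG stream.
#' @param pixel_size_m Pixel edge length in meters.
#' @param label Optional label.
#' @return A [landscape()].
#' @examples
#' ls <- generate_landscape(c(0.6, 0.3, 0.1), seed = 1)
#' composition(ls)
#' @export
generate_landscape <- function(dist, n_rows = 40, n_cols = 40, role = "BREEDING",
                               seed = 1L, pixel_size_m = 30, label = "") {
  dist <- cover_distribution(dist)
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1", call. = FALSE)
  n <- as.integer(n_rows) * as.integer(n_cols)
  codes <- withr::with_seed(as.integer(seed), {
    sample.int(3L, n, replace = TRUE, prob = dist)
  })
  grid <- matrix(codes, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  landscape(grid, pixel_size_m = pixel_size_m, role = role, label = label)
}

#' Land-cover composition of a landscape
#'
#' @param ls A [landscape()].
#' @return Named numeric vector of cover proportions summing to 1.
#' @export
composition <- function(ls) {
  stopifnot(inherits(ls, "birdscape_landscape"))
  counts <- tabulate(ls$grid, nbins = 3L)
  setNames(counts / length(ls$grid), land_covers())
}

check_focal <- function(ls, row, col) {
  if (row < 1 || row > nrow(ls$grid) || col < 1 || col > ncol(ls$grid)) {
    stop(sprintf("focal pixel (%d, %d) lies outside the %d x %d grid",
                 row, col, nrow(ls$grid), ncol(ls$grid)), call. = FALSE)
  }
}

#' Moore-neighborhood cover counts around a focal pixel
#'
#' Counts each land cover among the cells within Chebyshev distance
#' `radius` of `(row, col)`, excluding the focal pixel itself. Cells beyond
#' the grid edge are simply absent, so totals shrink at edges and corners
#' (8 neighbors in the interior at radius 1, 5 on an edge, 3 in a corner).
#'
#' @param ls A [landscape()].
#' @param row,col 1-based focal pixel indices.
#' @param radius Neighborhood radius (>= 1).
#' @return Named integer vector of counts per cover.
#' @export
neighborhood_counts <- function(ls, row, col, radius = 1L) {
  stopifnot(inherits(ls, "birdscape_landscape"))
  check_focal(ls, row, col)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  g <- ls$grid
  rows <- max(1L, row - radius):min(nrow(g), row + radius)
  cols <- max(1L, col - radius):min(ncol(g), col + radius)
  block <- g[rows, cols, drop = FALSE]
  counts <- tabulate(block, nbins = 3L)
  counts[g[row, col]] <- counts[g[row, col]] - 1L  # exclude the focal pixel
  setNames(as.integer(counts), land_covers())
}

#' Patch quality around a focal pixel
#'
#' Mean of a per-cover quality score over the 3 x 3 window centered on the
#' focal pixel (the window is truncated at grid edges). The 3 x 3 window of
#' 30-m pixels (0.81 ha) is the package's fixed "one-hectare patch": the
#' closest odd-sided square to one hectare.
#'
#' @param ls A [landscape()].
#' @param row,col 1-based focal pixel indices.
#' @param quality_by_cover Named numeric vector over `land_covers()`, each
#'   entry in `[0, 1]`.
#' @return Patch quality in `[0, 1]`.
#' @export
patch_quality <- function(ls, row, col, quality_by_cover) {
  stopifnot(inherits(ls, "birdscape_landscape"))
  check_focal(ls, row, col)
  q <- check_cover_map(quality_by_cover, "quality_by_cover")
  g <- ls$grid
  rows <- max(1L, row - 1L):min(nrow(g), row + 1L)
  cols <- max(1L, col - 1L):min(ncol(g), col + 1L)
  mean(q[g[rows, cols]])
}

# validate a named LandCover -> [0,1] mapping, return in canonical order
check_cover_map <- function(x, what) {
  if (length(x) != 3L || is.null(names(x))) {
    stop(sprintf("%s must be a named length-3 vector over %s", what,
                 paste(land_covers(), collapse = ", ")), call. = FALSE)
  }
  x <- x[land_covers()]
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s entries must cover all three land covers and lie in [0,1]", what),
         call. = FALSE)
  }
  unname(x)
}

#' Read and write land-cover grids as ESRI ASCII rasters
#'
#' Plain-text single-band rasters in the ESRI ASCII grid layout
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value`
#' header, then one row of integer codes per line, north row first).
#' Codes are 1 = GRASSLAND, 2 = AGRICULTURE, 3 = FOREST. Writing then
#' reading a landscape reproduces the grid bit-exactly.
#'
#' @param path File path.
#' @param role,label Metadata attached to the landscape on read (the ASCII
#'   format itself carries neither).
#' @return `read_ascii_grid()` returns a [landscape()]; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, role = "BREEDING", label = "") {
  if (!file.exists(path)) stop(sprintf("raster file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path)
  header <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    header[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(header[[key]])) {
      stop(sprintf("raster header is missing '%s'", key), call. = FALSE)
    }
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != header$nrows) {
    stop(sprintf("raster body has %d data rows but header declares nrows %d",
                 length(body), header$nrows), call. = FALSE)
  }
  rows <- lapply(body, function(l) as.integer(strsplit(trimws(l), "[[:space:]]+")[[1L]]))
  if (any(lengths(rows) != header$ncols)) {
    stop("raster data rows do not all match the declared ncols", call. = FALSE)
  }
  grid <- do.call(rbind, rows)
  landscape(grid, pixel_size_m = header$cellsize, role = role, label = label)
}

#' @param ls A [landscape()] to write.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(ls, path) {
  stopifnot(inherits(ls, "birdscape_landscape"))
  g <- ls$grid
  header <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", format(ls$pixel_size_m)),
    "NODATA_value -9999"
  )
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}
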