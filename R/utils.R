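#' @keywords internal
"_PACKAGE"

# Log arguments are clamped here to avoid -log(0) overflow in loss terms.
.LOG_EPS <- 1e-12

clog <- function(x) log(pmax(x, .LOG_EPS))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (simulation,
#' weight init, shuffling) never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of per-item seeds from a master seed, kept < 2^31.
derive_seeds <- function(master, n) {
  (as.numeric(master) * 7919 + 104729 * seq_len(n)) %% .Machine$integer.max
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count_scalar <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == round(x)

#' Validate and normalise a point matrix
#'
#' Points are 1-based (row, col) integer pixel coordinates, origin at the
#' top-left. Accepts an n x 2 matrix, a 2-vector, a list of 2-vectors, or
#' NULL/empty (0 points).
#' @keywords internal
as_points <- function(points) {
  if (is.null(points) || length(points) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  if (is.list(points)) points <- do.call(rbind, points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  if (ncol(points) != 2) stopf("points must have two columns (row, col)")
  storage.mode(points) <- "integer"
  dimnames(points) <- list(NULL, c("row", "col"))
  points
}

check_points_in_bounds <- function(points, h, w, what = "point") {
  if (nrow(points) == 0) return(invisible(points))
  bad <- points[, 1] < 1 | points[, 1] > h | points[, 2] < 1 | points[, 2] > w
  if (any(bad))
    stopf("%d %s(s) fall outside the %d x %d raster", sum(bad), what, h, w)
  invisible(points)
}

# Deduplicate identical (row, col) pairs; warn when any are dropped.
dedupe_points <- function(points, warn = TRUE, context = "points") {
  if (nrow(points) < 2) return(points)
  key <- paste(points[, 1], points[, 2])
  dup <- duplicated(key)
  if (any(dup)) {
    if (warn) warnf("%d duplicate %s dropped (a 1-pixel mask cannot encode multiplicity)",
                    sum(dup), context)
    points <- points[!dup, , drop = FALSE]
  }
  points
}
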