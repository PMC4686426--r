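#' Single-cell field
#'
#' A `cell_field` is a data frame of cells with planar positions in
#' micrometres (y-down frame), a scalar response (maximum-over-time reporter
#' activity, arbitrary units) and a covariate (ligand dose in uM, or a
#' distance in um). Field geometry (bounding rectangle, optional wound disk
#' or source cell) and the generating seed travel as attributes so every
#' field is self-describing and reproducible.
#'
#' @param x,y Numeric vectors of cell-center coordinates (um).
#' @param response Non-negative numeric vector of scalar responses.
#' @param covariate Numeric vector (>= 0): dose or distance per cell.
#' @param group Optional character labels (dose well, cluster id,
#'   `"source"`/`"neighbor"`, ...).
#' @param geometry List describing the field: `width`, `height` (um) and
#'   optionally `min_spacing`, `wound_center`, `wound_radius`, `source_id`,
#'   plus generator parameters.
#' @param seed Integer seed the field was generated with (`NA` if external).
#'
#' @return A data frame of class `cell_field` with columns
#'   `id, x, y, response, covariate, group`.
#' @export
cell_field <- function(x, y, response = NA_real_, covariate = NA_real_,
                       group = NA_character_, geometry = list(),
                       seed = NA_integer_) {
  n <- length(x)
  stopifnot(length(y) == n)
  df <- data.frame(
    id = seq_len(n),
    x = as.numeric(x),
    y = as.numeric(y),
    response = rep_len(as.numeric(response), n),
    covariate = rep_len(as.numeric(covariate), n),
    group = rep_len(as.character(group), n),
    stringsAsFactors = FALSE
  )
  attr(df, "geometry") <- geometry
  attr(df, "seed") <- seed
  class(df) <- c("cell_field", "data.frame")
  df
}

#' Field geometry accessor
#' @param field A `cell_field`.
#' @return The geometry list attribute.
#' @export
field_geometry <- function(field) attr(field, "geometry")

#' @export
print.cell_field <- function(x, ...) {
  geom <- attr(x, "geometry")
  cat(sprintf("<cell_field> %d cells", nrow(x)))
  if (!is.null(geom$width)) {
    cat(sprintf(", %g x %g um", geom$width, geom$height))
  }
  if (!is.null(geom$wound_radius)) {
    cat(sprintf(", wound r=%g um", geom$wound_radius))
  }
  cat("\n")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Validate a cell field against its stated geometry
#'
#' Checks that positions lie inside the field rectangle, that no cell sits
#' inside a declared wound disk, that pairwise spacing respects the declared
#' minimum, and that responses are finite and non-negative (where defined).
#'
#' @param field A `cell_field`.
#' @return `field` invisibly; signals an error on any violation.
#' @export
validate_cell_field <- function(field) {
  stopifnot(inherits(field, "cell_field"))
  geom <- attr(field, "geometry")
  if (!is.null(geom$width)) {
    x0 <- geom$x0 %||% 0
    y0 <- geom$y0 %||% 0
    ok <- field$x >= x0 & field$x <= x0 + geom$width &
      field$y >= y0 & field$y <= y0 + geom$height
    if (!all(ok)) stop("cells outside the stated field rectangle")
  }
  if (!is.null(geom$wound_radius) && !is.null(geom$wound_center)) {
    d <- sqrt((field$x - geom$wound_center[1])^2 +
                (field$y - geom$wound_center[2])^2)
    if (any(d < geom$wound_radius - 1e-9)) {
      stop("cells inside the wound disk")
    }
  }
  if (!is.null(geom$min_spacing) && is.finite(geom$min_spacing) &&
      nrow(field) >= 2L) {
    dmin <- min_pair_distance(field$x, field$y)
    if (dmin < geom$min_spacing - 1e-9) {
      stop(sprintf("pairwise spacing %.3f um below stated minimum %g um",
                   dmin, geom$min_spacing))
    }
  }
  r <- field$response
  r <- r[!is.na(r)]
  if (length(r) && (any(!is.finite(r)) || any(r < 0))) {
    stop("responses must be finite and non-negative")
  }
  invisible(field)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum pairwise distance between points
#'
#' Grid-bucketed closest-pair search; linear in the number of points for
#' roughly uniform fields.
#'
#' @param x,y Coordinate vectors.
#' @return Smallest Euclidean pairwise distance (Inf for < 2 points).
#' @export
min_pair_distance <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(Inf)
  if (n <= 400L) return(min(stats::dist(cbind(x, y))))
  os <- order(x, y)
  xs <- x[os]; ys <- y[os]
  # seed the bound with consecutive x-neighbors so the sweep window stays small
  best <- min(sqrt(diff(xs)^2 + diff(ys)^2))
  # plane sweep: compare each point to predecessors within current best dx
  for (i in 2:n) {
    j <- i - 1L
    while (j >= 1L && xs[i] - xs[j] < best) {
      dy <- ys[i] - ys[j]
      if (abs(dy) < best) {
        d <- sqrt((xs[i] - xs[j])^2 + dy * dy)
        if (d < best) best <- d
      }
      j <- j - 1L
    }
  }
  best
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' generators never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
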