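#' Multiplicative noise model for cell-to-cell variability
#'
#' Cell responses are modeled as a deterministic mean profile times an
#' independent mean-1 multiplicative factor, reflecting the large
#' between-cell variability of reporter maxima. Factors are lognormal,
#' parameterized so `E[factor] = 1` with the given coefficient of variation.
#'
#' @param cv Coefficient of variation of the factor (> 0, or 0 for no noise).
#' @param kind Noise law; only `"lognormal-multiplicative"` is implemented.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv, kind = "lognormal-multiplicative") {
  kind <- match.arg(kind)
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) {
    stop("cv must be a single non-negative number")
  }
  structure(list(kind = kind, cv = cv), class = "noise_model")
}

#' Draw mean-1 multiplicative noise factors
#'
#' @param n Number of factors.
#' @param noise A [noise_model()] (or a bare non-negative cv).
#' @param cv Optional per-draw cv vector overriding `noise$cv` (used for
#'   locally averaged components whose cv shrinks with neighborhood size).
#' @return Numeric vector of length `n` with expectation 1.
#' @export
noise_factors <- function(n, noise, cv = NULL) {
  if (is.numeric(noise)) noise <- noise_model(noise)
  cv <- if (is.null(cv)) rep_len(noise$cv, n) else rep_len(cv, n)
  f <- rep(1, n)
  pos <- cv > 0
  if (any(pos)) {
    sdl <- sqrt(log1p(cv[pos]^2))          # lognormal sigma for E[f] = 1
    f[pos] <- exp(stats::rnorm(sum(pos), mean = -sdl^2 / 2, sd = sdl))
  }
  f
}

#' Scatter cells over a rectangular field
#'
#' Places cell centers at a target density with a hard minimum spacing
#' (cell diameter). At low packing fractions a Poisson-like dart-throwing
#' scatter is used; above the random-sequential-adsorption regime, cells are
#' placed on a jittered triangular lattice, as appropriate for a confluent
#' epithelial monolayer. Densities beyond 75% of the hexagonal packing bound
#' are rejected.
#'
#' @param width,height Field extent (um).
#' @param target_density Target density (cells/um^2).
#' @param min_spacing Minimum center-to-center distance (um); default 20,
#'   one cell diameter.
#' @param seed Integer seed.
#' @return A `cell_field` with positions only (`response`/`covariate` NA).
#' @export
scatter_cells <- function(width, height, target_density, min_spacing = 20,
                          seed = 1L) {
  stopifnot(width > 0, height > 0, target_density > 0, min_spacing > 0)
  hex_max <- 2 / (sqrt(3) * min_spacing^2)  # hexagonal close packing density
  if (target_density > 0.75 * hex_max) {
    stop(sprintf(
      paste0("target_density %.3g exceeds 75%% of the hexagonal packing ",
             "bound %.3g cells/um^2 for min_spacing %g um"),
      target_density, hex_max, min_spacing))
  }
  area <- width * height
  phi <- target_density * pi * (min_spacing / 2)^2  # hard-disk area fraction
  pts <- with_seed(seed, {
    if (phi <= 0.30) {
      .scatter_darts(width, height, target_density, min_spacing)
    } else {
      .scatter_lattice(width, height, target_density, min_spacing)
    }
  })
  cell_field(
    x = pts[, 1], y = pts[, 2],
    geometry = list(width = width, height = height, x0 = 0, y0 = 0,
                    min_spacing = min_spacing,
                    target_density = target_density),
    seed = as.integer(seed)
  )
}

# Poisson-like random sequential placement with a hard-core exclusion.
.scatter_darts <- function(width, height, target_density, min_spacing) {
  n_target <- stats::rpois(1L, target_density * width * height)
  if (n_target == 0L) return(matrix(numeric(0), ncol = 2))
  h <- min_spacing                       # grid cell = exclusion distance
  nx <- max(1L, ceiling(width / h))
  ny <- max(1L, ceiling(height / h))
  grid <- vector("list", nx * ny)
  px <- numeric(n_target); py <- numeric(n_target)
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 40L * n_target
  batch <- max(1000L, n_target)
  while (accepted < n_target && attempts < max_attempts) {
    m <- min(batch, max_attempts - attempts)
    cx <- stats::runif(m, 0, width)
    cy <- stats::runif(m, 0, height)
    for (t in seq_len(m)) {
      ix <- min(nx - 1L, floor(cx[t] / h)); iy <- min(ny - 1L, floor(cy[t] / h))
      ok <- TRUE
      for (gx in max(0L, ix - 1L):min(nx - 1L, ix + 1L)) {
        for (gy in max(0L, iy - 1L):min(ny - 1L, iy + 1L)) {
          idx <- grid[[gx + gy * nx + 1L]]
          if (length(idx) &&
              any((px[idx] - cx[t])^2 + (py[idx] - cy[t])^2 <
                    min_spacing^2)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        accepted <- accepted + 1L
        px[accepted] <- cx[t]; py[accepted] <- cy[t]
        cell <- ix + iy * nx + 1L
        grid[[cell]] <- c(grid[[cell]], accepted)
        if (accepted == n_target) break
      }
    }
    attempts <- attempts + m
  }
  cbind(px[seq_len(accepted)], py[seq_len(accepted)])
}

# Jittered triangular lattice for packing fractions beyond the RSA regime.
.scatter_lattice <- function(width, height, target_density, min_spacing) {
  n_target <- round(target_density * width * height)
  # site spacing: 85% occupancy where possible, never closer than 1.02x the
  # hard-core distance (jitter keeps the spacing guarantee)
  s_occ <- sqrt(2 / (sqrt(3) * target_density / 0.85))
  s <- max(1.02 * min_spacing, min(s_occ, sqrt(2 / (sqrt(3) * target_density))))
  jit <- (s - min_spacing) / 2
  dy <- s * sqrt(3) / 2
  ys <- seq(jit, height - jit, by = dy)
  sites <- do.call(rbind, lapply(seq_along(ys), function(k) {
    off <- if (k %% 2L == 0L) s / 2 else 0
    xs <- seq(jit + off, width - jit, by = s)
    cbind(xs, ys[k])
  }))
  if (nrow(sites) < n_target) n_target <- nrow(sites)
  keep <- sample.int(nrow(sites), n_target)
  ang <- stats::runif(n_target, 0, 2 * pi)
  rad <- jit * sqrt(stats::runif(n_target))
  cbind(sites[keep, 1] + rad * cos(ang), sites[keep, 2] + rad * sin(ang))
}

#' Saturating dose-response field
#'
#' Assigns each cell the Hill-curve mean response to a spatially uniform
#' ligand dose, times an independent mean-1 lognormal factor. Emulates a
#' single well of a multi-well dose-response experiment with large
#' between-cell variability.
#'
#' @param positions A `cell_field` (positions used; responses overwritten).
#' @param dose Ligand dose (uM, >= 0).
#' @param hill List with `Rmax`, `K`, `h` (all > 0).
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draw.
#' @return A `cell_field` with `response` set and `covariate = dose`.
#' @export
dose_response_field <- function(positions, dose,
                                hill = list(Rmax = 3, K = 1, h = 2),
                                noise = noise_model(0.5), seed = 1L) {
  stopifnot(inherits(positions, "cell_field"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    stop("dose must be a single non-negative number")
  }
  stopifnot(hill$Rmax > 0, hill$K > 0, hill$h > 0)
  mu <- hill$Rmax * dose^hill$h / (hill$K^hill$h + dose^hill$h)
  f <- with_seed(seed, noise_factors(nrow(positions), noise))
  out <- positions
  out$response <- mu * f
  out$covariate <- dose
  out$group <- format(dose, trim = TRUE)
  geom <- attr(out, "geometry")
  geom$hill <- hill
  geom$noise_cv <- noise$cv
  attr(out, "geometry") <- geom
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Multi-well dose-response series as one field
#'
#' Generates one well per dose (independent cell layouts), offsetting wells
#' far apart along x so that kernel averaging at any realistic PCD never
#' mixes wells. Cells carry their dose as both covariate and group label,
#' ready for by-group SNR analysis.
#'
#' @param doses Numeric vector of doses (uM).
#' @param width,height Per-well extent (um).
#' @param target_density Cells/um^2 per well.
#' @param min_spacing Minimum spacing (um).
#' @param hill,noise As in [dose_response_field()].
#' @param seed Integer base seed; each well uses a derived sub-seed.
#' @param well_gap Gap between wells (um); default 1e5 makes cross-well
#'   kernel weights numerically zero.
#' @return A combined `cell_field`.
#' @export
dose_response_wells <- function(doses, width = 450, height = 450,
                                target_density = 2e-3, min_spacing = 20,
                                hill = list(Rmax = 3, K = 1, h = 2),
                                noise = noise_model(0.5), seed = 1L,
                                well_gap = 1e5) {
  stopifnot(length(doses) >= 2L, all(doses >= 0))
  wells <- lapply(seq_along(doses), function(i) {
    sub <- (as.integer(seed) * 101L + i) %% .Machine$integer.max
    pos <- scatter_cells(width, height, target_density, min_spacing,
                         seed = sub)
    w <- dose_response_field(pos, doses[i], hill, noise, seed = sub + 1L)
    w$x <- w$x + (i - 1) * (width + well_gap)
    w
  })
  df <- do.call(rbind, lapply(wells, as.data.frame))
  out <- cell_field(df$x, df$y, df$response, df$covariate, df$group,
                    geometry = list(
                      width = length(doses) * (width + well_gap),
                      height = height, x0 = 0, y0 = 0,
                      min_spacing = min_spacing,
                      target_density = target_density,
                      doses = doses, hill = hill, noise_cv = noise$cv),
                    seed = as.integer(seed))
  out
}

#' Wound-response field with a radial signaling gradient
#'
#' Removes cells inside a circular wound and assigns responses whose mean
#' decays with distance from the wound edge, times mean-1 multiplicative
#' noise. The covariate is the raw distance to the wound center (the axis
#' used when binning wound data); the wound-edge offset appears only inside
#' the mean profile.
#'
#' @param positions A `cell_field`.
#' @param wound_center Numeric length-2; defaults to the field center.
#' @param wound_radius Wound radius (um, >= 0); default 150 (300 um wound).
#' @param gradient List with amplitude `A`, length scale `lambda` (um) and
#'   baseline `b`. The default Gaussian profile with `lambda = 200` um
#'   gives a gradient extending > 500 um from the wound edge.
#' @param noise A [noise_model()]; the default CV of 0.8 reproduces a
#'   pre-averaging SNR near 0.9 under the default gradient.
#' @param profile Mean profile shape in `r - wound_radius`: `"gaussian"`
#'   (default; the profile a diffusing damage signal released at the wound
#'   produces), `"exponential"`, or `"power"` (inverse-square).
#' @param seed Integer seed for the noise draw.
#' @return A `cell_field` with `covariate` = distance to wound center.
#' @export
wound_field <- function(positions, wound_center = NULL, wound_radius = 150,
                        gradient = list(A = 3, lambda = 200, b = 0.3),
                        noise = noise_model(0.8),
                        profile = c("gaussian", "exponential", "power"),
                        seed = 1L) {
  stopifnot(inherits(positions, "cell_field"))
  profile <- match.arg(profile)
  stopifnot(gradient$lambda > 0, gradient$A >= 0, gradient$b >= 0,
            wound_radius >= 0)
  geom <- attr(positions, "geometry")
  if (is.null(wound_center)) {
    wound_center <- c((geom$x0 %||% 0) + geom$width / 2,
                      (geom$y0 %||% 0) + geom$height / 2)
  }
  r <- sqrt((positions$x - wound_center[1])^2 +
              (positions$y - wound_center[2])^2)
  keep <- r >= wound_radius
  out <- positions[keep, , drop = FALSE]
  r <- r[keep]
  u <- (r - wound_radius) / gradient$lambda
  mu <- switch(profile,
    exponential = gradient$A * exp(-u) + gradient$b,
    gaussian    = gradient$A * exp(-u^2 / 2) + gradient$b,
    power       = gradient$A * (1 + u)^(-2) + gradient$b
  )
  f <- with_seed(seed, noise_factors(nrow(out), noise))
  out$response <- mu * f
  out$covariate <- r
  out$id <- seq_len(nrow(out))
  geom$wound_center <- wound_center
  geom$wound_radius <- wound_radius
  geom$gradient <- gradient
  geom$profile <- profile
  geom$noise_cv <- noise$cv
  attr(out, "geometry") <- geom
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cell_field", "data.frame")
  out
}

#' Point-source activation field
#'
#' One labeled source cell secretes; the mean response of every cell decays
#' as a Gaussian of distance from the source (spread `sigma`, the ground
#' truth for PCD estimation) above a basal level, times mean-1 noise.
#'
#' @param positions A `cell_field`.
#' @param source_cell Id of the source cell; default: the cell nearest the
#'   field center.
#' @param profile List with amplitude `A`, spread `sigma` (um) and baseline
#'   `c`.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draw.
#' @return A `cell_field`; `covariate` = distance to source, `group` is
#'   `"source"`/`"neighbor"`.
#' @export
point_source_field <- function(positions, source_cell = NULL,
                               profile = list(A = 1, sigma = 100, c = 0.2),
                               noise = noise_model(0.25), seed = 1L) {
  stopifnot(inherits(positions, "cell_field"), profile$sigma > 0)
  geom <- attr(positions, "geometry")
  if (is.null(source_cell)) {
    cx <- (geom$x0 %||% 0) + geom$width / 2
    cy <- (geom$y0 %||% 0) + geom$height / 2
    source_cell <- positions$id[which.min((positions$x - cx)^2 +
                                            (positions$y - cy)^2)]
  }
  si <- match(source_cell, positions$id)
  if (is.na(si)) stop(sprintf("unknown source cell id: %s", source_cell))
  d <- sqrt((positions$x - positions$x[si])^2 +
              (positions$y - positions$y[si])^2)
  mu <- profile$A * exp(-d^2 / (2 * profile$sigma^2)) + profile$c
  f <- with_seed(seed, noise_factors(nrow(positions), noise))
  out <- positions
  out$response <- mu * f
  out$covariate <- d
  out$group <- ifelse(seq_len(nrow(out)) == si, "source", "neighbor")
  geom$source_id <- positions$id[si]
  geom$profile <- profile
  geom$noise_cv <- noise$cv
  attr(out, "geometry") <- geom
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Spatially clustered field with coordination-dependent variability
#'
#' Scatters well-separated cell clusters and assigns responses
#' `mu * (alpha * a_i + (1 - alpha) * f_i)`, where `f_i` is a raw mean-1
#' per-cell factor (CV `cv`) and `a_i` is a coordinated mean-1 factor whose
#' CV is `cv / sqrt(n_i)`, with `n_i` the number of cells within the
#' communication distance `pcd` of cell i. This reproduces the statistical
#' signature of paracrine averaging: for `alpha` near 1 (coordinated,
#' ERK-like) within-cluster variability falls with local density; for
#' `alpha = 0` (uncoordinated, Ca-like) it is density-independent.
#'
#' @param n_clusters Number of clusters.
#' @param cells_per_cluster_mean Mean cluster size. Each cluster draws its
#'   own density (log-uniform, 1/4x to 4x the implied mean density) and a
#'   Poisson membership (truncated at 5, the smallest group size the
#'   cluster statistics are stable for) at that density, so cluster density
#'   varies widely at roughly fixed extent.
#' @param cluster_spread Cluster radius (um); members are uniform in the
#'   disk of this radius around the center.
#' @param inter_cluster_min Minimum center separation (um); must exceed the
#'   200 um maximal communication distance so clusters are independent.
#' @param response_model List with `alpha` in \[0, 1\], `cv` > 0, mean level
#'   `mu` and communication distance `pcd` (um).
#' @param seed Integer seed.
#' @return A `cell_field`; `group` = cluster id, `covariate` = distance to
#'   own cluster center.
#' @export
clustered_field <- function(n_clusters = 60, cells_per_cluster_mean = 12,
                            cluster_spread = 65, inter_cluster_min = 400,
                            response_model = list(alpha = 0.8, cv = 0.6,
                                                  mu = 1, pcd = 100),
                            seed = 1L) {
  stopifnot(n_clusters >= 1, cells_per_cluster_mean >= 2,
            cluster_spread > 0)
  if (inter_cluster_min <= 200) {
    stop("inter_cluster_min must exceed the 200 um maximal communication distance")
  }
  alpha <- response_model$alpha %||% 0.8
  cv <- response_model$cv %||% 0.6
  mu <- response_model$mu %||% 1
  pcd <- response_model$pcd %||% 100
  stopifnot(alpha >= 0, alpha <= 1, cv >= 0, mu > 0, pcd > 0)
  # field sized so random placement of centers stays dilute (area
  # fraction ~0.2 of the exclusion disks)
  side <- ceiling(sqrt(n_clusters * pi * (inter_cluster_min / 2)^2 / 0.2))
  with_seed(seed, {
    cxs <- numeric(n_clusters); cys <- numeric(n_clusters)
    placed <- 0L
    for (try in seq_len(400L * n_clusters)) {
      cx <- stats::runif(1, 0, side); cy <- stats::runif(1, 0, side)
      if (placed == 0L ||
          all((cxs[seq_len(placed)] - cx)^2 + (cys[seq_len(placed)] - cy)^2 >=
                inter_cluster_min^2)) {
        placed <- placed + 1L
        cxs[placed] <- cx; cys[placed] <- cy
        if (placed == n_clusters) break
      }
    }
    if (placed < n_clusters) {
      stop("cluster centers cannot be packed at the requested separation")
    }
    centers <- cbind(cxs, cys)
    dens_mult <- exp(stats::runif(n_clusters, log(1 / 4), log(4)))
    sizes <- pmax(5L, stats::rpois(n_clusters,
                                   cells_per_cluster_mean * dens_mult))
    k <- rep.int(seq_len(n_clusters), sizes)
    n <- length(k)
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- cluster_spread * sqrt(stats::runif(n))
    x <- centers[k, 1] + rad * cos(ang)
    y <- centers[k, 2] + rad * sin(ang)
    # local neighborhood size within the communication distance
    n_local <- vapply(seq_len(n), function(i) {
      sum((x - x[i])^2 + (y - y[i])^2 <= pcd^2)
    }, integer(1))
    f <- noise_factors(n, cv)
    a <- noise_factors(n, cv, cv = cv / sqrt(n_local))
    resp <- mu * (alpha * a + (1 - alpha) * f)
    covar <- sqrt((x - centers[k, 1])^2 + (y - centers[k, 2])^2)
    cell_field(
      x = x, y = y, response = resp, covariate = covar,
      group = sprintf("c%03d", k),
      geometry = list(width = side + 12 * cluster_spread,
                      height = side + 12 * cluster_spread,
                      x0 = -6 * cluster_spread, y0 = -6 * cluster_spread,
                      min_spacing = NA_real_,
                      n_clusters = n_clusters,
                      cluster_spread = cluster_spread,
                      inter_cluster_min = inter_cluster_min,
                      response_model = list(alpha = alpha, cv = cv, mu = mu,
                                            pcd = pcd)),
      seed = as.integer(seed)
    )
  })
}
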