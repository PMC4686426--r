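#' Group cells into spatial clusters and summarize responses
#'
#' Single-linkage hierarchical clustering on cell-center distances, cut at
#' the maximal communication distance (MCD): cells linked within `mcd` of
#' each other share a cluster; cells in different clusters are farther than
#' `mcd` (equivalently, connected components of the <= mcd proximity
#' graph). Per cluster: member count, maximal pairwise distance `d`,
#' effective area `EA = pi (d/2)^2` (circle with diameter `d`, exactly as
#' defined even though it underestimates elongated clusters), density
#' `n / EA`, and the response mean and SD. The SD is the c4-bias-corrected
#' sample SD (`s / c4(n)`): the raw sample SD is systematically low for
#' small clusters, and since cluster density scales with membership that
#' bias would masquerade as a density trend. Clusters wider than `d_max` are
#' flagged `filtered` (too extended for a single communication
#' neighborhood, given an empirical PCD near 100 um) and excluded from
#' correlation analyses, as are singletons (SD undefined).
#'
#' @param field A `cell_field` (>= 2 cells).
#' @param mcd Maximal communication distance (um), default 200.
#' @param d_max Cluster-diameter filter (um), default 150.
#' @return A data frame of class `cluster_table` with one row per cluster
#'   (`cluster, n, d, ea, density, mean, sd, filtered`); per-cell
#'   membership in the `"membership"` attribute.
#' @export
cluster_cells <- function(field, mcd = 200, d_max = 150) {
  stopifnot(inherits(field, "cell_field"), mcd > 0)
  if (nrow(field) < 2L) stop("need at least 2 cells")
  dmat <- stats::dist(cbind(field$x, field$y))
  hc <- stats::hclust(dmat, method = "single")
  memb <- stats::cutree(hc, h = mcd)
  dfull <- as.matrix(dmat)
  c4 <- function(n) {
    sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
  }
  rows <- lapply(sort(unique(memb)), function(cl) {
    idx <- which(memb == cl)
    n <- length(idx)
    d <- if (n >= 2L) max(dfull[idx, idx]) else 0
    ea <- if (n >= 2L) pi * (d / 2)^2 else NA_real_
    data.frame(
      cluster = cl, n = n, d = d, ea = ea,
      density = if (n >= 2L) n / ea else NA_real_,
      mean = mean(field$response[idx]),
      sd = if (n >= 2L) stats::sd(field$response[idx]) / c4(n) else NA_real_,
      filtered = d > d_max
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "membership") <- memb
  attr(out, "mcd") <- mcd
  attr(out, "d_max") <- d_max
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Correlation of cluster response variability with cluster density
#'
#' Pearson correlation (two-sided) of the per-cluster response SD (or mean)
#' against cluster density, over unfiltered non-singleton clusters. A
#' significantly negative SD correlation is the signature of
#' paracrine-coordinated responses; uncoordinated responses show none.
#'
#' @param table A `cluster_table` from [cluster_cells()].
#' @param statistic `"sd"` (default) or `"mean"`.
#' @return List with `r` (Pearson), `p_value`, `n_clusters`.
#' @export
density_variability_test <- function(table, statistic = c("sd", "mean")) {
  stopifnot(inherits(table, "cluster_table"))
  statistic <- match.arg(statistic)
  keep <- !table$filtered & table$n >= 2L & is.finite(table$density)
  x <- table[[statistic]][keep]
  dens <- table$density[keep]
  if (length(x) < 3L) {
    stop("need at least 3 unfiltered, non-singleton clusters")
  }
  if (stats::sd(x) == 0 || stats::sd(dens) == 0) {
    # a constant statistic carries no density trend
    return(list(r = 0, p_value = 1, n_clusters = length(x)))
  }
  ct <- stats::cor.test(x, dens, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_clusters = length(x))
}
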