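#' Paracrine averaging kernel specification
#'
#' The kernel is an isotropic Gaussian whose spread is the Paracrine
#' Communication Distance (PCD) -- how far a secreted ligand travels to
#' activate neighbors. An optional diffusion cap limits the effective PCD to
#' the rms distance `sqrt(6 D T)` a ligand diffuses within the integration
#' window `T`.
#'
#' @param pcd PCD in um (> 0; 0 allowed and means no averaging).
#' @param include_self Should a cell's own secretion enter its average
#'   (autocrine term)? Default `TRUE`.
#' @param cap Optional list `list(D = , T = )`: diffusion coefficient
#'   (um^2/s) and integration time (s). With `D = 50`, `T = 300` the cap is
#'   300 um.
#' @param convention `"sigma"` (default): `pcd` is the Gaussian sigma, the
#'   convention under which the empirical PCD is reported as the sigma of a
#'   fitted Gaussian. `"exp-r2-over-pcd2"`: exponent `-r^2/PCD^2`, an
#'   alternative printed convention; equivalent to sigma `pcd/sqrt(2)`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(pcd, include_self = TRUE, cap = NULL,
                        convention = c("sigma", "exp-r2-over-pcd2")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(pcd), length(pcd) == 1L, pcd >= 0)
  if (!is.null(cap)) {
    stopifnot(is.list(cap), cap$D > 0, cap$T > 0)
  }
  structure(list(pcd = pcd, include_self = isTRUE(include_self),
                 cap = cap, convention = convention),
            class = "kernel_spec")
}

#' Effective PCD under an optional diffusion cap
#'
#' @param spec A [kernel_spec()].
#' @return `pcd` when no cap is set, else `min(pcd, sqrt(6 D T))`.
#' @export
effective_pcd <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.null(spec$cap)) return(spec$pcd)
  min(spec$pcd, sqrt(6 * spec$cap$D * spec$cap$T))
}

#' Gaussian kernel weight
#'
#' `w(dx, dy) = exp(-(dx^2 + dy^2) / (2 pcd^2)) / (2 pi pcd^2)`, the
#' isotropic bivariate Gaussian density; integrates to 1 over the plane.
#'
#' @param dx,dy Displacements (um).
#' @param pcd Kernel spread (um, > 0).
#' @return Non-negative weight(s).
#' @export
kernel_weight <- function(dx, dy, pcd) {
  stopifnot(pcd > 0)
  exp(-(dx^2 + dy^2) / (2 * pcd^2)) / (2 * pi * pcd^2)
}

#' Predict post-paracrine responses by Gaussian local averaging
#'
#' For each cell i the predicted response is the kernel-weighted average of
#' all cells' responses,
#' `P_i = sum_j w(d_ij) R_j / sum_j w(d_ij)`,
#' the local mean ligand level cell i is exposed to. Normalization makes the
#' prediction a convex combination of observed responses and independent of
#' cell density; the raw (unnormalized) areal convolution is available with
#' `normalize = FALSE` for comparison.
#'
#' @param field A non-empty `cell_field` with responses.
#' @param spec A [kernel_spec()]. `pcd = 0` returns the field unchanged.
#' @param normalize Divide by the summed weights (default `TRUE`).
#' @param chunk Rows per block for the distance computation (memory cap).
#' @param .d2 Optional precomputed squared-distance matrix (used by
#'   [sweep_pcd()] to share distances across the PCD grid).
#' @return A `cell_field` with predicted responses; positions, covariates
#'   and groups carried through. The PCD used is recorded in the geometry.
#' @export
paracrine_average <- function(field, spec, normalize = TRUE, chunk = 2048L,
                              .d2 = NULL) {
  stopifnot(inherits(field, "cell_field"))
  if (nrow(field) == 0L) stop("empty field")
  if (!inherits(spec, "kernel_spec")) spec <- kernel_spec(spec)
  pcd_eff <- effective_pcd(spec)
  sigma <- if (spec$convention == "sigma") pcd_eff else pcd_eff / sqrt(2)
  out <- field
  geom <- attr(out, "geometry")
  geom$pcd_used <- pcd_eff
  attr(out, "geometry") <- geom
  if (sigma == 0) {
    if (!spec$include_self) stop("pcd = 0 with include_self = FALSE is undefined")
    return(out)
  }
  x <- field$x; y <- field$y; r <- field$response
  n <- length(x)
  pred <- numeric(n)
  inv2s2 <- 1 / (2 * sigma^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    d2 <- if (is.null(.d2)) {
      outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    } else {
      .d2[idx, , drop = FALSE]
    }
    w <- exp(-d2 * inv2s2)
    if (!spec$include_self) {
      w[cbind(seq_along(idx), idx)] <- 0
    }
    sw <- rowSums(w)
    if (any(sw == 0)) {
      stop("some cells have zero total kernel weight (pcd too small without self-weight)")
    }
    pred[idx] <- if (normalize) (w %*% r) / sw else {
      (w %*% r) / (2 * pi * sigma^2)
    }
  }
  out$response <- pred
  out
}
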