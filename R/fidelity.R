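#' Binning schemes
#'
#' Constructors for the three ways cells are grouped before computing
#' fidelity statistics: by a discrete label (dose wells), into k bins of
#' (near-)equal cell count over the covariate, or into k equal-width
#' covariate bins.
#'
#' @param k Number of bins (>= 2).
#' @return An object of class `bin_scheme`.
#' @name bin_scheme
NULL

#' @rdname bin_scheme
#' @export
equal_count <- function(k) {
  stopifnot(k >= 2)
  structure(list(type = "equal-count", k = as.integer(k)),
            class = "bin_scheme")
}

#' @rdname bin_scheme
#' @export
equal_width <- function(k) {
  stopifnot(k >= 2)
  structure(list(type = "equal-width", k = as.integer(k)),
            class = "bin_scheme")
}

#' @rdname bin_scheme
#' @export
by_group <- function() {
  structure(list(type = "by-group"), class = "bin_scheme")
}

# deterministic per-cell bin index (NA for unassignable cells)
.bin_assign <- function(field, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  n <- nrow(field)
  if (scheme$type == "by-group") {
    if (all(is.na(field$group))) stop("by-group binning requires group labels")
    return(match(field$group, sort(unique(field$group))))
  }
  v <- field$covariate
  if (any(is.na(v))) stop("covariate contains NA")
  if (diff(range(v)) == 0) {
    stop("all covariates identical: cannot form 2 covariate bins")
  }
  k <- scheme$k
  if (scheme$type == "equal-count") {
    ord <- order(v, field$id)                       # deterministic tie-break
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bin <- integer(n)
    bin[ord] <- rep.int(seq_len(k), sizes)
    bin
  } else {
    edges <- seq(min(v), max(v), length.out = k + 1L)
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), k)
  }
}

#' Bin cells and summarize responses per bin
#'
#' Deterministically assigns cells to bins (equal-count bins differ in size
#' by at most one) and computes per-bin count, mean, sample variance
#' (n - 1), SD and CV of the responses. Bins with fewer than 2 cells are
#' dropped with a warning; fewer than 2 usable bins is an error.
#'
#' @param field A `cell_field` with responses.
#' @param scheme A [bin_scheme] (`equal_count(k)`, `equal_width(k)`,
#'   `by_group()`).
#' @param covariate_range Optional `c(lo, hi)` analysis window: only cells
#'   with covariate inside it are binned (an imaging-window analog — the
#'   field may extend beyond the analyzed region).
#' @return A data frame of class `bin_summary` with columns
#'   `bin, n, mean, var, sd, cv, covariate_mean`; the per-cell assignment is
#'   kept in the `"assignment"` attribute.
#' @export
bin_cells <- function(field, scheme = equal_count(15),
                      covariate_range = NULL) {
  stopifnot(inherits(field, "cell_field"))
  if (!is.null(covariate_range)) {
    stopifnot(length(covariate_range) == 2L)
    keep <- !is.na(field$covariate) &
      field$covariate >= covariate_range[1] &
      field$covariate <= covariate_range[2]
    geom <- attr(field, "geometry")
    field <- field[keep, , drop = FALSE]
    class(field) <- c("cell_field", "data.frame")
    attr(field, "geometry") <- geom
    if (nrow(field) < 4L) stop("fewer than 4 cells inside covariate_range")
  }
  bin <- .bin_assign(field, scheme)
  labs <- sort(unique(bin))
  rows <- lapply(labs, function(b) {
    r <- field$response[bin == b]
    data.frame(bin = b, n = length(r), mean = mean(r),
               var = stats::var(r), sd = stats::sd(r),
               cv = stats::sd(r) / mean(r),
               covariate_mean = mean(field$covariate[bin == b]))
  })
  out <- do.call(rbind, rows)
  small <- out$n < 2L
  if (any(small)) {
    warning(sprintf("dropping %d bin(s) with fewer than 2 cells", sum(small)))
    bin[bin %in% out$bin[small]] <- NA_integer_
    out <- out[!small, , drop = FALSE]
  }
  if (nrow(out) < 2L) stop("fewer than 2 usable bins")
  attr(out, "assignment") <- bin
  attr(out, "scheme") <- scheme
  class(out) <- c("bin_summary", "data.frame")
  out
}

#' Signal-to-noise ratio of binned responses
#'
#' Signal is the sample variance across bins of the per-bin mean responses;
#' noise is the unweighted average across bins of the within-bin sample
#' variances; SNR is their ratio. Binning is over dose wells (by-group) or
#' distance to the wound (covariate bins).
#'
#' @param field A `cell_field`.
#' @param scheme A [bin_scheme].
#' @param weighted Count-weight the within-bin variances instead of the
#'   unweighted bin average (default `FALSE`).
#' @param covariate_range Optional analysis window; see [bin_cells()].
#' @return A list of class `fidelity_result` with `signal`, `noise`, `snr`,
#'   `n_cells`, `n_bins`, `pcd` (if recorded on the field).
#' @export
snr <- function(field, scheme = equal_count(15), weighted = FALSE,
                covariate_range = NULL) {
  bs <- bin_cells(field, scheme, covariate_range)
  signal <- stats::var(bs$mean)
  noise <- if (weighted) {
    sum(bs$n * bs$var) / sum(bs$n)
  } else {
    mean(bs$var)
  }
  if (noise == 0) stop("zero noise: all responses identical within every bin")
  structure(list(signal = signal, noise = noise, snr = signal / noise,
                 n_cells = sum(bs$n), n_bins = nrow(bs),
                 pcd = field_geometry(field)$pcd_used %||% NA_real_,
                 scheme = scheme),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("<fidelity_result> %d cells, %s bins\n", x$n_cells,
              x$n_bins %||% "?"))
  if (!is.null(x$snr)) {
    cat(sprintf("  signal %.4g  noise %.4g  SNR %.4g\n",
                x$signal, x$noise, x$snr))
  }
  if (!is.null(x$mi_bits)) {
    cat(sprintf("  MI %.4g bits (%.4g nats); extrapolation slope %.3g/bin\n",
                x$mi_bits, x$mi_nats, x$fit_slope))
  }
  invisible(x)
}

#' Per-bin coefficient of variation
#'
#' CV (SD over mean) of the responses in each bin; the per-bin statistic
#' used to compare the variability of primary and post-paracrine responses.
#'
#' @inheritParams snr
#' @return A `bin_summary` (see [bin_cells()]); use the `cv` column.
#' @export
cv_by_bin <- function(field, scheme = equal_count(15),
                      covariate_range = NULL) {
  bin_cells(field, scheme, covariate_range)
}

#' Compare per-bin CVs of two fields
#'
#' Two-sample two-sided t-test on the per-bin CV values, e.g. primary
#' (Ca-like) versus paracrine-averaged (ERK-like) responses over the same
#' binning scheme.
#'
#' @param a,b `bin_summary` objects from [cv_by_bin()] with the same scheme.
#' @return List with `t`, `p_value`, `mean_cv_a`, `mean_cv_b`.
#' @export
cv_compare <- function(a, b) {
  stopifnot(inherits(a, "bin_summary"), inherits(b, "bin_summary"))
  if (!identical(attr(a, "scheme"), attr(b, "scheme"))) {
    warning("comparing bin summaries built with different schemes")
  }
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 bins on each side")
  if (stats::sd(a$cv) == 0 && stats::sd(b$cv) == 0 &&
      isTRUE(all.equal(mean(a$cv), mean(b$cv)))) {
    return(list(t = 0, p_value = 1, mean_cv_a = mean(a$cv),
                mean_cv_b = mean(b$cv)))
  }
  tt <- stats::t.test(a$cv, b$cv)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_cv_a = mean(a$cv), mean_cv_b = mean(b$cv))
}

#' kNN probability-density estimate in one dimension
#'
#' For each value, the density is estimated as `k / (n * w_i)` where `w_i`
#' is twice the distance to the value's k-th nearest neighbor (the width of
#' the symmetric window holding its k nearest neighbors). Zero widths from
#' >= k duplicates are replaced by half the smallest nonzero width, with a
#' warning.
#'
#' @param values Numeric vector (length > k).
#' @param k Neighbor order (default 10).
#' @return Density estimates, in the input order.
#' @export
knn_density <- function(values, k = 10L) {
  n <- length(values)
  if (n <= k) stop("need more than k values")
  ord <- order(values, seq_len(n))      # ties broken by index order
  s <- values[ord]
  # the k nearest neighbors of s[i] occupy a contiguous sorted window
  # [lo, lo + k] containing i; the k-th NN distance is the best such window
  pad <- c(rep(-Inf, k), s, rep(Inf, k))
  i_pad <- seq_len(n) + k
  dk <- rep(Inf, n)
  for (m in 0:k) {
    lo <- i_pad - (k - m)
    dk <- pmin(dk, pmax(s - pad[lo], pad[lo + k] - s))
  }
  w <- 2 * dk
  if (any(w == 0)) {
    nz <- w[w > 0]
    if (!length(nz)) stop("all kNN window widths are zero")
    warning("zero kNN width from duplicated values; substituting half the smallest nonzero width")
    w[w == 0] <- 0.5 * min(nz)
  }
  dens <- numeric(n)
  dens[ord] <- k / (n * w)
  dens
}

# kNN entropy of a sample, in bits
.knn_entropy_bits <- function(values, k) {
  -mean(log2(knn_density(values, k)))
}

#' Mutual information between covariate bin and response
#'
#' Estimates `I = H[R] - sum_b (n_b/n) H[R | bin b]` with kNN entropy
#' estimates (see [knn_density()]), over equal-count covariate binnings with
#' several bin counts, then extrapolates the per-bin-count estimates
#' linearly back to zero bins to remove the dependence on bin number. The
#' intercept is the reported mutual information.
#'
#' @param field A `cell_field`.
#' @param bin_counts Equal-count bin numbers to evaluate.
#' @param k_nn kNN order for the entropy estimates (default 10).
#' @param covariate_range Optional analysis window; see [bin_cells()].
#' @return A `fidelity_result` with `mi_bits`, `mi_nats`, the per-bin-count
#'   estimates (`bin_counts`, `mi_by_bins`), and the extrapolation
#'   `fit_intercept`/`fit_slope`.
#' @export
mutual_information <- function(field, bin_counts = c(4, 6, 8, 10, 12, 16, 20),
                               k_nn = 10L, covariate_range = NULL) {
  stopifnot(inherits(field, "cell_field"), length(bin_counts) >= 2L)
  if (!is.null(covariate_range)) {
    stopifnot(length(covariate_range) == 2L)
    keep <- !is.na(field$covariate) &
      field$covariate >= covariate_range[1] &
      field$covariate <= covariate_range[2]
    geom <- attr(field, "geometry")
    field <- field[keep, , drop = FALSE]
    class(field) <- c("cell_field", "data.frame")
    attr(field, "geometry") <- geom
  }
  n <- nrow(field)
  h_r <- .knn_entropy_bits(field$response, k_nn)
  i_b <- vapply(bin_counts, function(B) {
    bin <- .bin_assign(field, equal_count(B))
    counts <- table(bin)
    if (any(counts <= k_nn)) {
      stop(sprintf("bin %s has %d cells (need > k_nn = %d) at %d bins",
                   names(counts)[which.min(counts)], min(counts), k_nn, B))
    }
    h_cond <- sum(vapply(split(field$response, bin), function(r) {
      (length(r) / n) * .knn_entropy_bits(r, k_nn)
    }, numeric(1)))
    h_r - h_cond
  }, numeric(1))
  fit <- stats::lm(i_b ~ bin_counts)
  mi <- unname(stats::coef(fit)[1])
  if (mi < 0) {
    warning("negative MI intercept clamped to 0")
    mi <- 0
  }
  structure(list(mi_bits = mi, mi_nats = mi * log(2),
                 bin_counts = bin_counts, mi_by_bins = i_b,
                 fit_intercept = unname(stats::coef(fit)[1]),
                 fit_slope = unname(stats::coef(fit)[2]),
                 n_cells = n, k_nn = k_nn,
                 pcd = field_geometry(field)$pcd_used %||% NA_real_),
            class = "fidelity_result")
}
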