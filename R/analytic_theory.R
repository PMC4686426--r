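#' Geometry and signal parameters of the diffusion theory
#'
#' A point-source ligand bolus diffuses from a cylindrical secreting cell
#' (radius `rho`, height `h_c`) into a chamber of height `h_f`. Two derived
#' dimensionless numbers control the theory: `eta = h_c / h_f`, the height
#' fraction cells occupy, and `S_strength = N_r / N_d`, the signal strength
#' (molecules released over molecules needed for detection). `S_strength`
#' is deliberately named apart from the SNR signal `S`.
#'
#' @param rho Cell radius (um), default 10.
#' @param h_c Cell height (um), default 15.
#' @param h_f Chamber height (um), default 60.
#' @param N_r Molecules released per cell (default 1e5).
#' @param N_d Molecules required for detection (default 100).
#' @param D Diffusion coefficient (um^2/s), default 50 (EGF-like).
#' @param v Interstitial flow speed (um/s), default 0.3.
#' @return A list of class `theory_params` with derived `eta`, `S_strength`.
#' @export
theory_params <- function(rho = 10, h_c = 15, h_f = 60, N_r = 1e5,
                          N_d = 100, D = 50, v = 0.3) {
  stopifnot(rho > 0, h_c > 0, h_f > 0, N_r > 0, N_d > 0, D > 0, v >= 0)
  if (h_c > h_f) stop("cell height h_c cannot exceed chamber height h_f")
  structure(list(rho = rho, h_c = h_c, h_f = h_f, N_r = N_r, N_d = N_d,
                 D = D, v = v, eta = h_c / h_f, S_strength = N_r / N_d),
            class = "theory_params")
}

#' Ligand concentration after a point-source bolus
#'
#' 2D slab solution for `N_r` molecules released at the origin at t = 0:
#' `C(r, t) = N_r / (h_f 4 pi D t) * exp(-r^2 / (4 D t))` (molecules/um^3).
#'
#' @param r Distance from the source (um).
#' @param t Time since release (s, > 0).
#' @param p A [theory_params()].
#' @return Concentration(s), vectorized over `r` and `t`.
#' @export
ligand_concentration <- function(r, t, p) {
  stopifnot(inherits(p, "theory_params"))
  if (any(t <= 0)) stop("t must be positive")
  p$N_r / (p$h_f * 4 * pi * p$D * t) * exp(-r^2 / (4 * p$D * t))
}

#' Detection-threshold concentration
#'
#' The critical concentration a neighboring cell must see: the required
#' molecule count over the sensed cell volume,
#' `C_detect = N_d / (h_c pi rho^2)`.
#'
#' @param p A [theory_params()].
#' @return Threshold concentration (molecules/um^3).
#' @export
detection_threshold <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  p$N_d / (p$h_c * pi * p$rho^2)
}

#' Detectable radius at time t
#'
#' Radius where the diffusing bolus just reaches the detection threshold:
#' `r(t) = 2 sqrt(D t ln(rho^2 h_c N_r / (4 D t N_d h_f)))`. Once dilution
#' pushes the log argument to or below 1 there is no detectable radius and
#' a flagged 0 is returned (attribute `detectable`), keeping downstream
#' maximization total.
#'
#' @param t Time (s, > 0); vectorized.
#' @param p A [theory_params()].
#' @return Radius (um) with logical attribute `detectable`.
#' @export
detection_radius <- function(t, p) {
  stopifnot(inherits(p, "theory_params"))
  if (any(t <= 0)) stop("t must be positive")
  arg <- p$rho^2 * p$eta * p$S_strength / (4 * p$D * t)
  det <- arg > 1
  r <- ifelse(det, 2 * sqrt(p$D * t * log(pmax(arg, 1))), 0)
  attr(r, "detectable") <- det
  r
}

#' Closed-form paracrine communication distance
#'
#' The maximum of [detection_radius()] over time:
#' `PCD = exp(-1/2) rho sqrt(eta S_strength)`. Independent of the diffusion
#' coefficient by construction -- diffusing faster reaches farther but
#' dilutes sooner, and the two effects cancel in the maximal detectable
#' radius.
#'
#' @param p A [theory_params()].
#' @return PCD (um).
#' @export
pcd_closed_form <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  exp(-0.5) * p$rho * sqrt(p$eta * p$S_strength)
}

#' Signal strength required for a target PCD
#'
#' Inverts [pcd_closed_form()]: `S_strength = (PCD e^{1/2} / rho)^2 / eta`.
#'
#' @param pcd Target PCD (um).
#' @param p A [theory_params()] supplying `rho` and `eta`.
#' @return Dimensionless signal strength.
#' @export
signal_strength_for_pcd <- function(pcd, p) {
  stopifnot(inherits(p, "theory_params"), pcd > 0)
  (pcd * exp(0.5) / p$rho)^2 / p$eta
}

#' Paracrine integration time
#'
#' Time at which the detectable radius is maximal:
#' `T_int = rho^2 eta S_strength / (4 e D)`. Grows linearly with signal
#' strength and inversely with the diffusion coefficient.
#'
#' @param p A [theory_params()].
#' @return Integration time (s).
#' @export
integration_time <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  p$rho^2 * p$eta * p$S_strength / (4 * exp(1) * p$D)
}

#' Characteristic diffusion time over a distance
#'
#' `t = r^2 / (4 D)`: 12.5 s for 50 um at D = 50 um^2/s.
#'
#' @param r Distance (um).
#' @param D Diffusion coefficient (um^2/s).
#' @return Time (s).
#' @export
diffusion_time <- function(r, D) {
  stopifnot(D > 0)
  r^2 / (4 * D)
}

#' Peclet number
#'
#' Ratio of advective to diffusive transport, `P = v L / D`.
#'
#' @param v Flow speed (um/s).
#' @param L Characteristic length (um).
#' @param D Diffusion coefficient (um^2/s).
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(v, L, D) {
  stopifnot(D > 0)
  v * L / D
}

#' Peclet number at the signal-strength-determined PCD
#'
#' With `L` set to the closed-form PCD the Peclet number becomes
#' `P = sqrt(S_strength eta) rho v / (D sqrt(e))`.
#'
#' @param p A [theory_params()].
#' @return Dimensionless Peclet number.
#' @export
peclet_from_signal <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  sqrt(p$S_strength * p$eta) * p$rho * p$v / (p$D * sqrt(exp(1)))
}

#' Advection displacement over the communication length
#'
#' @param peclet Peclet number.
#' @param L Communication length scale (um).
#' @return Advection distance `P * L` (um).
#' @export
advection_distance <- function(peclet, L) peclet * L

#' Positional-accuracy error induced by flow
#'
#' Fraction of the signaling-gradient extent displaced by advection:
#' 50 um of advection over a > 500 um wound gradient is a < 10% error.
#'
#' @param advection_distance Advective displacement (um).
#' @param gradient_extent Extent of the signaling gradient (um).
#' @return Error fraction.
#' @export
advection_error <- function(advection_distance, gradient_extent) {
  stopifnot(gradient_extent > 0)
  advection_distance / gradient_extent
}

#' Time-averaged ligand concentration (temporal-decoding model)
#'
#' Under instantaneous release at t = 0 and simple temporal averaging over
#' `(0, t0]`, the average concentration at distance r has the closed form
#' `C_avg = N_r / (4 pi D h_f t0) * E1(r^2 / (4 D t0))`, with `E1` the
#' exponential integral (`E1(x) = -Ei(-x)` for x > 0). Diverges
#' logarithmically at r = 0, which is an error.
#'
#' @param r Distance (um, > 0); vectorized.
#' @param t0 Averaging window (s, > 0).
#' @param p A [theory_params()].
#' @return Average concentration (molecules/um^3).
#' @export
time_averaged_concentration <- function(r, t0, p) {
  stopifnot(inherits(p, "theory_params"))
  if (any(t0 <= 0)) stop("t0 must be positive")
  if (any(r <= 0)) stop("r must be positive (logarithmic divergence at r = 0)")
  p$N_r / (4 * p$D * pi * p$h_f * t0) * pracma::expint_E1(r^2 / (4 * p$D * t0))
}

#' Compare Gaussian and temporal-averaging decoding weights
#'
#' Puts the Gaussian paracrine weight profile `exp(-r^2 / (2 pcd^2))` and
#' the instant-release temporal-average profile
#' ([time_averaged_concentration()]) on a shared radial grid, each
#' normalized to its own maximum over the comparison range
#' `r >= r_min_compare`, and reports their maximum absolute discrepancy. If
#' `t0` is not given, it is chosen to match the length scales (minimizing
#' that discrepancy), since the bolus model has no intrinsic PCD.
#'
#' @param pcd Gaussian spread (um).
#' @param p A [theory_params()].
#' @param t0 Averaging window (s); `NULL` to match length scales.
#' @param r Radial grid (um, > 0).
#' @param r_min_compare Lower end of the comparison range (um, default 50;
#'   the models are expected to disagree below it, where the instant-release
#'   assumption concentrates mass near the source).
#' @return List with the profile `table` (columns `r`, `gaussian`,
#'   `temporal`), the `t0` used, `max_abs_discrepancy` (r >= r_min_compare)
#'   and `max_abs_discrepancy_below`.
#' @export
compare_decoding_weights <- function(pcd, p, t0 = NULL,
                                     r = seq(5, 300, by = 5),
                                     r_min_compare = 50) {
  stopifnot(inherits(p, "theory_params"), pcd > 0, all(r > 0))
  cmp <- r >= r_min_compare
  if (!any(cmp)) stop("no grid points at or above r_min_compare")
  gauss <- exp(-r^2 / (2 * pcd^2))
  gauss_n <- gauss / max(gauss[cmp])
  disc <- function(log_t0) {
    e <- pracma::expint_E1(r^2 / (4 * p$D * exp(log_t0)))
    max(abs(e / max(e[cmp]) - gauss_n)[cmp])
  }
  if (is.null(t0)) {
    t_diff <- diffusion_time(pcd, p$D)
    opt <- stats::optimize(disc, log(c(t_diff / 20, t_diff * 200)))
    t0 <- exp(opt$minimum)
  }
  temporal <- pracma::expint_E1(r^2 / (4 * p$D * t0))
  temporal_n <- temporal / max(temporal[cmp])
  dev <- abs(temporal_n - gauss_n)
  list(
    table = data.frame(r = r, gaussian = gauss_n, temporal = temporal_n),
    t0 = t0,
    max_abs_discrepancy = max(dev[cmp]),
    max_abs_discrepancy_below = if (any(!cmp)) max(dev[!cmp]) else NA_real_
  )
}
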