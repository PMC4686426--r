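# Closed-form diffusion theory against independent numeric oracles.

test_that("point-source concentration conserves mass and has the Gaussian shape", {
  p <- theory_params(N_r = 1e5, N_d = 100, D = 50)
  t <- 120
  expect_equal(ligand_concentration(0, t, p),
               p$N_r / (p$h_f * 4 * pi * p$D * t))
  # mass: integral of C * h_f over the plane = N_r
  mass <- stats::integrate(function(r) {
    ligand_concentration(r, t, p) * p$h_f * 2 * pi * r
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, p$N_r, tolerance = 1e-6)
  # e-fold radius
  r_e <- sqrt(4 * p$D * t)
  expect_equal(ligand_concentration(r_e, t, p),
               ligand_concentration(0, t, p) / exp(1))
  expect_error(ligand_concentration(10, 0, p), "positive")
})

test_that("detection threshold is molecules over sensed cell volume", {
  p <- theory_params(N_d = 100, h_c = 15, rho = 10)
  expect_equal(detection_threshold(p), 100 / (15 * pi * 100))
  p2 <- theory_params(N_d = 200, h_c = 15, rho = 10)
  expect_equal(detection_threshold(p2), 2 * detection_threshold(p))
})

test_that("detection radius matches root-finding on the concentration profile", {
  p <- theory_params(N_r = 1e5, N_d = 100, D = 50)
  cd <- detection_threshold(p)
  for (t in c(10, 50, 200, 400)) {
    r <- detection_radius(t, p)
    if (attr(r, "detectable")) {
      # independent oracle: where does C(r, t) cross the threshold?
      root <- stats::uniroot(function(rr) {
        ligand_concentration(rr, t, p) - cd
      }, c(1e-9, 1e5), tol = 1e-10)$root
      expect_equal(as.numeric(r), root, tolerance = 1e-6)
    }
  }
  # substitution identity: log argument e gives r = 2 sqrt(D t)
  t_e <- p$rho^2 * p$eta * p$S_strength / (4 * p$D * exp(1))
  expect_equal(as.numeric(detection_radius(t_e, p)),
               2 * sqrt(p$D * t_e), tolerance = 1e-12)
  # extreme dilution: flagged zero
  r_late <- detection_radius(1e9, p)
  expect_identical(as.numeric(r_late), 0)
  expect_false(attr(r_late, "detectable"))
})

test_that("closed-form PCD and integration time equal the numeric maximum of the detection radius", {
  # spec'd reference geometry
  p0 <- theory_params(rho = 10, h_c = 15, h_f = 60, N_r = 1e5, N_d = 100)
  expect_equal(pcd_closed_form(p0), exp(-0.5) * 10 * sqrt(0.25 * 1000))
  expect_equal(pcd_closed_form(p0), 95.90092, tolerance = 1e-6)
  # quadrupling signal strength doubles the PCD
  p4 <- theory_params(rho = 10, h_c = 15, h_f = 60, N_r = 4e5, N_d = 100)
  expect_equal(pcd_closed_form(p4), 2 * pcd_closed_form(p0))
  # oracle across random parameter draws and diffusion coefficients
  set.seed(42)
  for (i in 1:100) {
    h_c <- stats::runif(1, 5, 50)
    p <- theory_params(
      rho = stats::runif(1, 3, 30), h_c = h_c,
      h_f = h_c + stats::runif(1, 1, 100),
      N_r = 10^stats::runif(1, 3, 7), N_d = 10^stats::runif(1, 1, 3),
      D = sample(c(1, 10, 100, 2000), 1))
    t_up <- p$rho^2 * p$eta * p$S_strength / (4 * p$D)
    opt <- stats::optimize(function(t) as.numeric(detection_radius(t, p)),
                           c(t_up * 1e-8, t_up), maximum = TRUE,
                           tol = t_up * 1e-10)
    expect_equal(opt$objective, pcd_closed_form(p), tolerance = 1e-6)
    expect_equal(opt$maximum, integration_time(p),
                 tolerance = 1e-5 * integration_time(p))
  }
})

test_that("closed-form PCD is independent of the diffusion coefficient", {
  for (D in c(1, 10, 100, 2000)) {
    p <- theory_params(D = D, N_r = 1e5, N_d = 100)
    t_up <- p$rho^2 * p$eta * p$S_strength / (4 * p$D)
    opt <- stats::optimize(function(t) as.numeric(detection_radius(t, p)),
                           c(t_up * 1e-8, t_up), maximum = TRUE,
                           tol = t_up * 1e-10)
    expect_equal(opt$objective, pcd_closed_form(p), tolerance = 1e-6)
  }
})

test_that("dimensional rescaling behaves as the closed forms require", {
  p <- theory_params(rho = 10, h_c = 15, h_f = 60, N_r = 2e5, N_d = 50,
                     D = 50, v = 0.3)
  c_len <- 3 # lengths x c, times x c^2, D invariant
  p2 <- theory_params(rho = p$rho * c_len, h_c = p$h_c * c_len,
                      h_f = p$h_f * c_len, N_r = p$N_r, N_d = p$N_d,
                      D = p$D, v = p$v / c_len)
  expect_equal(pcd_closed_form(p2), c_len * pcd_closed_form(p))
  expect_equal(integration_time(p2), c_len^2 * integration_time(p))
  expect_equal(peclet_from_signal(p2), peclet_from_signal(p))
  expect_equal(diffusion_time(c_len * 50, p$D),
               c_len^2 * diffusion_time(50, p$D))
})

test_that("diffusion time and Peclet arithmetic", {
  expect_equal(diffusion_time(50, 50), 12.5)
  expect_equal(diffusion_time(0, 50), 0)
  expect_equal(diffusion_time(100, 50), 50)
  expect_equal(peclet(0.3, 100, 60), 0.5)
  expect_equal(peclet(0, 100, 60), 0)
  expect_equal(advection_distance(0.5, 100), 50)
  expect_equal(advection_error(50, 500), 0.10)
  expect_equal(advection_error(0, 500), 0)
})

test_that("signal-form Peclet equals v PCD / D for random valid parameters", {
  set.seed(7)
  for (i in 1:20) {
    h_c <- stats::runif(1, 5, 40)
    p <- theory_params(rho = stats::runif(1, 5, 20), h_c = h_c,
                       h_f = h_c + stats::runif(1, 5, 80),
                       N_r = 10^stats::runif(1, 3, 6),
                       N_d = 10^stats::runif(1, 1, 3),
                       D = stats::runif(1, 5, 500),
                       v = stats::runif(1, 0, 2))
    expect_equal(peclet_from_signal(p),
                 peclet(p$v, pcd_closed_form(p), p$D),
                 tolerance = 1e-12)
  }
})

test_that("signal strength inversion hits a requested PCD", {
  p <- theory_params(D = 10)
  s <- signal_strength_for_pcd(100, p)
  p2 <- theory_params(D = 10, N_r = s * p$N_d, N_d = p$N_d)
  expect_equal(pcd_closed_form(p2), 100, tolerance = 1e-12)
})

test_that("time-averaged concentration matches quadrature of the bolus profile", {
  p <- theory_params(N_r = 1e5, N_d = 100, D = 50)
  for (r in c(10, 50, 150, 500)) {
    for (t0 in c(10, 100, 1000)) {
      quad <- stats::integrate(function(t) {
        ligand_concentration(r, t, p) / t0
      }, 0, t0, rel.tol = 1e-12, abs.tol = 0)$value
      expect_equal(time_averaged_concentration(r, t0, p), quad,
                   tolerance = 1e-8)
    }
  }
  # monotone decreasing in r; linear in N_r; positive
  r <- seq(10, 500, by = 10)
  ca <- time_averaged_concentration(r, 300, p)
  expect_true(all(diff(ca) < 0))
  expect_true(all(ca > 0))
  p2 <- theory_params(N_r = 2e5, N_d = 100, D = 50)
  expect_equal(time_averaged_concentration(r, 300, p2), 2 * ca)
  expect_error(time_averaged_concentration(0, 300, p), "divergence")
})

test_that("Gaussian and temporal-averaging decoding weights agree away from the source", {
  p <- theory_params(D = 50)
  cmp <- compare_decoding_weights(100, p)
  expect_lte(cmp$max_abs_discrepancy, 0.15)
  expect_gt(cmp$max_abs_discrepancy_below, cmp$max_abs_discrepancy)
  # both radial profiles decrease with distance
  expect_true(all(diff(cmp$table$gaussian) < 0))
  expect_true(all(diff(cmp$table$temporal) < 0))
})
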