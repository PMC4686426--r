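# shared fixtures, all generated in code

# small positions-only field (fast; dart-throwing regime)
small_positions <- function(seed = 1L, width = 400, height = 400,
                            density = 1e-3, min_spacing = 20) {
  scatter_cells(width, height, density, min_spacing, seed = seed)
}

# wound replicate at reduced desk scale (package-default gradient)
make_wound_replicate <- function(seed, side = 1500, cv = 0.8) {
  wound_field(scatter_cells(side, side, 2e-3, 20, seed = seed),
              noise = noise_model(cv), seed = seed + 1000L)
}

# default analysis window for wound binning (um from wound center)
wound_window <- c(0, 800)

# Shared wound-sweep computation for the sweep and acceptance tests:
# 5 replicate 2x2 mm wound fields, PCD grid 0-600 um, SNR (40 equal-count
# bins in the window, with its signal/noise parts) and MI (bin counts
# matched to the SNR resolution) on the same predicted fields. Cached on
# disk for the session so several test files can share one computation.
wound_reference_sweep <- function() {
  cache <- file.path(tempdir(), "paracrine-wound-sweep.rds")
  if (file.exists(cache)) return(readRDS(cache))
  grid <- seq(0, 600, by = 50)
  n_rep <- 5L
  S <- N <- SNR <- MI <- matrix(NA_real_, n_rep, length(grid))
  for (i in seq_len(n_rep)) {
    w <- make_wound_replicate(i, side = 2000)
    d2 <- outer(w$x, w$x, "-")^2 + outer(w$y, w$y, "-")^2
    for (g in seq_along(grid)) {
      pred <- paracrine_average(w, kernel_spec(grid[g]), .d2 = d2)
      r <- snr(pred, equal_count(40), covariate_range = wound_window)
      S[i, g] <- r$signal; N[i, g] <- r$noise; SNR[i, g] <- r$snr
      MI[i, g] <- mutual_information(pred, c(10, 15, 20, 30, 40),
                                     covariate_range = wound_window)$mi_bits
    }
  }
  refine <- paracrine:::.refine_argmax
  out <- list(
    grid = grid, signal = S, noise = N, snr = SNR, mi = MI,
    argmax_snr = apply(SNR, 1, refine, x = grid),
    argmax_mi = apply(MI, 1, refine, x = grid)
  )
  saveRDS(out, cache)
  out
}

# multi-well dose series at reduced desk scale
make_dose_replicate <- function(seed, doses = c(0.1, 0.3, 1, 3, 10, 30),
                                cv = 0.5, width = 350) {
  dose_response_wells(doses, width = width, height = width,
                      target_density = 2e-3, noise = noise_model(cv),
                      seed = seed)
}

# hand-built field from explicit coordinates
field_from_xy <- function(x, y, response = NA_real_, covariate = NA_real_,
                          group = NA_character_) {
  cell_field(x, y, response, covariate, group)
}
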