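#' Write a cell field to CSV (with JSON sidecar)
#'
#' Columns `id,x_um,y_um,response,covariate,group`. Numeric columns are
#' written with 17 significant digits so doubles round-trip exactly.
#' Geometry and the generating seed go to a `<stem>_meta.json` sidecar.
#'
#' @param field A `cell_field`.
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, sidecar = TRUE) {
  stopifnot(inherits(field, "cell_field"))
  df <- data.frame(
    id = field$id,
    x_um = .num17(field$x),
    y_um = .num17(field$y),
    response = .num17(field$response),
    covariate = .num17(field$covariate),
    group = field$group,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (sidecar) {
    meta <- list(geometry = attr(field, "geometry"),
                 seed = attr(field, "seed"),
                 n_cells = nrow(field))
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

.num17 <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.json")
}

#' Read a cell field from CSV
#'
#' Validates the header (`id,x_um,y_um,response,covariate,group` required;
#' unknown columns are preserved) and reports malformed rows with their
#' line numbers. Geometry is restored from the `<stem>_meta.json` sidecar
#' when present.
#'
#' @param path CSV path written by [write_field()] (or compatible).
#' @return A `cell_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0) stop(sprintf("empty file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("", "NA"))
  required <- c("id", "x_um", "y_um", "response", "covariate", "group")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("x_um", "y_um", "response", "covariate")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop(sprintf("malformed value in column %s at line %d", col,
                     bad[1] + 1L))  # +1 for the header line
      }
      df[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  bad_pos <- which(is.na(df$x_um) | is.na(df$y_um))
  if (length(bad_pos)) {
    stop(sprintf("missing position at line %d", bad_pos[1] + 1L))
  }
  out <- cell_field(df$x_um, df$y_um, df$response, df$covariate,
                    df$group %||% NA_character_)
  out$id <- df$id
  extra <- setdiff(names(df), required)
  for (col in extra) out[[col]] <- df[[col]]
  meta_path <- .sidecar_path(path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    geom <- meta$geometry
    for (nm in c("wound_center")) {
      if (!is.null(geom[[nm]])) geom[[nm]] <- as.numeric(geom[[nm]])
    }
    attr(out, "geometry") <- geom
    attr(out, "seed") <- meta$seed %||% NA_integer_
  }
  out
}

#' Run a configured analysis pipeline end-to-end
#'
#' Generates replicate synthetic fields for a scenario, applies the
#' configured analysis (PCD sweep for `"wound"`/`"dose"`, cluster
#' density-variability analysis for `"cluster"`, Gaussian PCD fit for
#' `"point_source"`) and writes fields, results and a manifest linking
#' every artifact to its inputs, parameters and seed. All randomness flows
#' from the single `seed` via fixed per-replicate sub-seeds, so the same
#' config always yields the same bundle.
#'
#' @param config A list (or path to a JSON file) with elements `scenario`
#'   (`"wound"`, `"dose"`, `"cluster"`, `"point_source"`), `seed`,
#'   `n_replicates`, and optional scenario parameters (`width`, `height`,
#'   `density`, `min_spacing`, `grid`, `statistic`, `bins`, `cap`, plus the
#'   generator arguments of the matching `*_field()` function).
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @return A results bundle (list) with the generated `fields`, the
#'   analysis `result`, and the resolved `config`, invisibly written to
#'   `out_dir` with a `manifest.json` when requested.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  sc <- config$scenario %||% stop("config$scenario is required")
  if (!sc %in% c("wound", "dose", "cluster", "point_source")) {
    stop(sprintf("unknown scenario: %s", sc))
  }
  seed <- as.integer(config$seed %||% 1L)
  n_rep <- as.integer(config$n_replicates %||% 5L)
  if (n_rep < 1L) stop("n_replicates must be >= 1")
  width <- config$width %||% 1500
  height <- config$height %||% 1500
  density <- config$density %||% 2e-3
  min_spacing <- config$min_spacing %||% 20
  cv <- config$noise_cv %||% switch(sc, wound = 0.8, dose = 0.5,
                                    point_source = 0.25, cluster = 0.6)
  sub_seed <- function(i) (seed * 7919L + i) %% .Machine$integer.max

  fields <- lapply(seq_len(n_rep), function(i) {
    s <- sub_seed(i)
    switch(sc,
      wound = wound_field(
        scatter_cells(width, height, density, min_spacing, seed = s),
        wound_radius = config$wound_radius %||% 150,
        gradient = config$gradient %||% list(A = 3, lambda = 200, b = 0.3),
        noise = noise_model(cv), seed = s + 1L),
      dose = dose_response_wells(
        doses = config$doses %||% c(0.1, 0.3, 1, 3, 10, 30),
        width = config$well_width %||% 450,
        height = config$well_height %||% 450,
        target_density = density, min_spacing = min_spacing,
        noise = noise_model(cv), seed = s),
      cluster = clustered_field(
        n_clusters = config$n_clusters %||% 60,
        cells_per_cluster_mean = config$cells_per_cluster_mean %||% 8,
        response_model = config$response_model %||%
          list(alpha = 0.8, cv = cv, mu = 1, pcd = 100),
        seed = s),
      point_source = point_source_field(
        scatter_cells(width, height, density, min_spacing, seed = s),
        profile = config$profile %||% list(A = 1, sigma = 100, c = 0.2),
        noise = noise_model(cv), seed = s + 1L)
    )
  })

  result <- switch(sc,
    wound = ,
    dose = sweep_pcd(
      fields,
      grid = config$grid %||% seq(0, 600, by = 10),
      statistic = config$statistic %||% "snr",
      scheme = if (sc == "dose") by_group()
               else equal_count(config$bins %||% 40),
      covariate_range = if (sc == "wound") {
        config$covariate_range %||% c(0, 800)
      },
      cap = config$cap),
    cluster = lapply(fields, function(f) {
      density_variability_test(cluster_cells(f))
    }),
    point_source = estimate_pcd(fields)
  )

  config$scenario <- sc
  config$seed <- seed
  config$n_replicates <- n_rep
  bundle <- list(fields = fields, result = result, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(seq_along(fields), function(i) {
      f <- file.path(out_dir, sprintf("field_%02d.csv", i))
      write_field(fields[[i]], f)
      f
    }, character(1))
    res_path <- file.path(out_dir, "result.json")
    jsonlite::write_json(.serialize_result(result), res_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(
      scenario = sc, seed = seed, n_replicates = n_rep,
      config = bundle$config,
      fields = basename(files),
      result = basename(res_path),
      package_version = as.character(utils::packageVersion("paracrine"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}

.serialize_result <- function(result) {
  if (inherits(result, "sweep_result")) {
    list(grid = result$grid,
         curves = lapply(result$curves, function(m) {
           lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
         }),
         argmax = result$argmax, mean = result$mean, sem = result$sem,
         mode = result$mode, n_replicates = result$n_replicates)
  } else if (!is.null(result$sigmas)) {          # estimate_pcd bundle
    list(sigmas = result$sigmas, mean = result$mean, sem = result$sem,
         n_sources = result$n_sources)
  } else {
    result
  }
}
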