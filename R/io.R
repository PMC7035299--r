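#' Read and write sampled time series
#'
#' Time series are written as plain CSV with the fixed header
#' `time_h, n, B, I_total, P, produced_cells` and full double precision, so a
#' read-back equals the original.
#'
#' @param ts A tibble with the columns above (extra columns such as `lysed`
#'   are dropped), e.g. `tidy()` of a `phage_run`.
#' @param path Output CSV path.
#' @return `write_timeseries()` returns `path` invisibly; `read_timeseries()`
#'   a tibble.
#' @export
write_timeseries <- function(ts, path) {
  cols <- c("time_h", "n", "B", "I_total", "P", "produced_cells")
  missing <- setdiff(cols, names(ts))
  if (length(missing) > 0)
    abort(paste0("time series lacks column(s): ", paste(missing, collapse = ", ")))
  readr::write_csv(ts[, cols], path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                  progress = FALSE)
}

#' Read and write lattice snapshots
#'
#' A snapshot is one self-contained JSON document holding the 3-D fields
#' (`B`, `I` summed and per stage, `P`, `n`, `n_c`), the lattice shape, the
#' simulation time, and the resolved parameters. Integer-valued fields
#' round-trip exactly; the continuous nutrient field is written at full
#' precision.
#'
#' @param state A `lattice_state`.
#' @param path Output `.json` path.
#' @param params Optional [phage_params()] to embed as provenance.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()` a
#'   `lattice_state` (with a `params` attribute when embedded).
#' @export
write_snapshot <- function(state, path, params = NULL) {
  doc <- list(
    format = "spatphage-snapshot",
    version = 1L,
    t = state$t,
    shape = state$shape,
    box_len = state$box_len,
    produced_cells = state$produced_cells,
    seed = state$seed,
    fields = list(
      B = as.numeric(state$B),
      I = as.numeric(state$I),
      n_stages = dim(state$I)[4],
      P = as.numeric(state$P),
      n = as.numeric(state$n),
      n_c = as.numeric(state$n_c)
    ),
    params = if (!is.null(params)) unclass(validate_params(params))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "spatphage-snapshot"))
    abort("not a spatphage snapshot file")
  shape <- as.integer(doc$shape)
  st <- structure(
    list(
      shape = shape,
      box_len = doc$box_len,
      t = doc$t,
      B = array(as.numeric(doc$fields$B), dim = shape),
      I = array(as.numeric(doc$fields$I), dim = c(shape, doc$fields$n_stages)),
      P = array(as.numeric(doc$fields$P), dim = shape),
      n = array(as.numeric(doc$fields$n), dim = shape),
      n_c = array(as.numeric(doc$fields$n_c), dim = shape),
      produced_cells = doc$produced_cells,
      seed = doc$seed
    ),
    class = "lattice_state"
  )
  if (!is.null(doc$params)) {
    pp <- doc$params
    pp$lattice_shape <- as.integer(pp$lattice_shape)
    pp$seed <- if (length(pp$seed)) as.integer(pp$seed) else NULL
    attr(st, "params") <- do.call(
      phage_params, c(pp, list(eta_unit = "um3/h")))
  }
  st
}

#' Write a run with its reproducibility manifest
#'
#' Writes the sampled time series (CSV), the resolved parameters (JSON), any
#' snapshots (JSON), and a `manifest.json` carrying the package version, the
#' model level, the seed, wall-clock times, the output file list and their
#' MD5 checksums — enough to reproduce the run exactly.
#'
#' @param run A `phage_run`.
#' @param dir Output directory (created if needed).
#' @param name Basename prefix for the files.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(run, dir, name = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ts_path <- file.path(dir, paste0(name, "_timeseries.csv"))
  write_timeseries(run$series, ts_path)
  par_path <- file.path(dir, paste0(name, "_params.json"))
  write_params(run$params, par_path)
  files <- c(ts_path, par_path)
  if (!is.null(run$snapshots) && length(run$snapshots) > 0) {
    for (nm in names(run$snapshots)) {
      sp <- file.path(dir, sprintf("%s_snapshot_t%s.json", name, nm))
      write_snapshot(run$snapshots[[nm]], sp, params = run$params)
      files <- c(files, sp)
    }
  }
  manifest <- list(
    package = "spatphage",
    version = as.character(packageVersion("spatphage")),
    engine = run$engine,
    level = run$level,
    seed = run$seed,
    stopped = run$stopped,
    written_at = started,
    files = basename(files),
    md5 = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  man_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man_path)
}

#' Deterministic lattice fixtures
#'
#' Small reproducible states used throughout the test suite and the
#' experiment harnesses:
#' * `uniform` — [lattice_init()] placement of `B_total`/`P_total` particles;
#' * `single_colony_plate` — a single founder bacterium in the centre box
#'   (the plating scenario start);
#' * `point_source_phage` — all phages concentrated in one box, for diffusion
#'   checks;
#' * `empty` — all populations zero.
#'
#' @param kind One of `"uniform"`, `"single_colony_plate"`,
#'   `"point_source_phage"`, `"empty"`.
#' @param params A [phage_params()] object (geometry and `n0`).
#' @param seed Integer seed (placement for `uniform`).
#' @param B_total,P_total Particle totals where applicable.
#' @return A `lattice_state`.
#' @export
make_fixture <- function(kind, params, seed = 1L, B_total = 100,
                         P_total = 100) {
  switch(
    kind,
    uniform = lattice_init(params, B_total, P_total, seed = seed),
    empty = lattice_init(params, 0, 0, seed = seed),
    single_colony_plate = {
      st <- lattice_init(params, 0, 0, seed = seed)
      centre <- pmax(1L, ceiling(st$shape / 2))
      st$B[centre[1], centre[2], centre[3]] <- 1
      st$n_c <- st$B
      st
    },
    point_source_phage = {
      st <- lattice_init(params, 0, 0, seed = seed)
      centre <- pmax(1L, ceiling(st$shape / 2))
      st$P[centre[1], centre[2], centre[3]] <- P_total
      st
    },
    abort(sprintf("unknown fixture kind '%s'", kind))
  )
}
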