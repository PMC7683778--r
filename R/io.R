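#' Write / read an oscillation-probability sweep as CSV
#'
#' `write_sweep_csv()` writes one row per grid point with header
#' `w_inh,w_exc,w_self,n_samples,p_osc,se,seed`, at full double precision
#' (17 significant digits), so that `read_sweep_csv()` round-trips the
#' values exactly. Reading is header-keyed: column order is free; a
#' malformed header, row length, or non-numeric cell raises an error with
#' the offending line number.
#'
#' @param result An [osc_sweep][sweep_oscillation] data frame.
#' @param path File path.
#' @return `read_sweep_csv()`: an `osc_sweep` data frame.
#' @examples
#' sw <- sweep_oscillation(w_inh = c(1, 5), n_samples = 200, seed = 1)
#' p <- tempfile(fileext = ".csv")
#' write_sweep_csv(sw, p)
#' all.equal(read_sweep_csv(p)$p_osc, sw$p_osc)
#' @export
write_sweep_csv <- function(result, path) {
  stopifnot(inherits(result, "osc_sweep") || is.data.frame(result))
  cols <- c("w_inh", "w_exc", "w_self", "n_samples", "p_osc", "se", "seed")
  if (!all(cols %in% names(result)))
    stop("missing sweep columns: ",
         paste(setdiff(cols, names(result)), collapse = ", "), call. = FALSE)
  m <- vapply(cols, function(cn) format(result[[cn]], digits = 17,
                                        trim = TRUE, scientific = FALSE),
              character(nrow(result)))
  if (nrow(result) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, cols))
  writeLines(c(paste(cols, collapse = ","),
               apply(m, 1, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty sweep file", call. = FALSE)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  cols <- c("w_inh", "w_exc", "w_self", "n_samples", "p_osc", "se", "seed")
  if (!setequal(hdr, cols))
    stop("malformed header at line 1: expected columns ",
         paste(cols, collapse = ","), call. = FALSE)
  rows <- lapply(seq_along(lines)[-1], function(i) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != length(hdr))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i, length(hdr), length(parts)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop(sprintf("parse error at line %d: non-numeric cell", i),
           call. = FALSE)
    vals
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- hdr
  df <- df[, cols]
  df$n_samples <- as.integer(df$n_samples)
  class(df) <- c("osc_sweep", "data.frame")
  df
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  J <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    do.call(rbind, lapply(jsonlite::fromJSON(path, simplifyMatrix = FALSE),
                          as.numeric))
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
  storage.mode(J) <- "double"
  if (!all(dim(J) == c(4, 4)) || !all(is.finite(J)))
    stop("expected a finite 4x4 matrix (CSV rows or JSON array of arrays)",
         call. = FALSE)
  dimnames(J) <- NULL
  J
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run a named experiment from a configuration
#'
#' Dispatches a self-contained experiment -- `"inhibition_sweep"`,
#' `"self_inhibition_sweep"` (the two standard weight sweeps),
#' `"posture_demo"`, `"plasticity_demo"`, `"full_chain"` or `"classify"`
#' -- writes its outputs (CSV tables, JSON reports) into `out_dir`, and
#' records a run manifest (`run_record.json`: config hash, seeds, package
#' version, file checksums). Every output is reproducible from the
#' configuration and master seed alone.
#'
#' @param config A named list, or path to a JSON file with the same
#'   structure. Required: `experiment`. Optional: `seed` (default 1),
#'   `out_dir` (default `tempfile()`), plus experiment-specific parameters
#'   (`n_samples`, `step`, `rho`, `frequency`, `kind`, `g0`, `cgrp`,
#'   `matrix` (a file path, for `classify`), ...).
#' @return The run record, invisibly (class `run_record`).
#' @examples
#' rec <- run_experiment(list(experiment = "plasticity_demo", cgrp = 1.5,
#'                            out_dir = tempfile()))
#' rec$manifest
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (!is.list(config)) stop("'config' must be a list or a JSON file path",
                             call. = FALSE)
  known <- c("inhibition_sweep", "self_inhibition_sweep", "posture_demo",
             "plasticity_demo", "full_chain", "classify")
  if (is.null(config$experiment) || !config$experiment %in% known)
    stop("unknown experiment; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  seed <- config$seed %||% 1
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("invalid field 'seed': must be a single finite number",
         call. = FALSE)
  out_dir <- config$out_dir %||% tempfile("mddsloops_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- character(0)
  stage_seeds <- list()
  emit <- function(name) {
    files <<- c(files, name)
    file.path(out_dir, name)
  }

  if (config$experiment %in% c("inhibition_sweep", "self_inhibition_sweep")) {
    n_samples <- config$n_samples %||% 1e5
    step <- config$step %||% 1
    if (!is.numeric(n_samples) || n_samples < 1)
      stop("invalid field 'n_samples': must be >= 1", call. = FALSE)
    stage_seeds$sweep <- derive_seed(seed, 1)
    sw <- if (config$experiment == "inhibition_sweep")
      inhibition_sweep(n_samples = n_samples, step = step,
                       seed = stage_seeds$sweep)
    else self_inhibition_sweep(n_samples = n_samples, step = step,
                               seed = stage_seeds$sweep)
    write_sweep_csv(sw, emit("sweep.csv"))
  } else if (config$experiment == "posture_demo") {
    stage_seeds$disturbance <- derive_seed(seed, 1)
    spec <- disturbance_spec(
      kind = config$kind %||% "pure_sine",
      amplitude = config$amplitude %||% 0.05,
      frequency = config$frequency %||% 0.25,
      noise_level = config$noise_level %||% 0.3,
      t_aboard = config$t_aboard %||% 300,
      t_ashore = config$t_ashore %||% 400,
      dt = config$dt %||% 0.05, seed = stage_seeds$disturbance)
    model <- posture_model(rho = config$rho %||% 0.05,
                           omega_c = 2 * pi * (config$frequency %||% 0.25))
    traj <- simulate_posture(model, spec)
    utils::write.csv(as.data.frame(traj), emit("trajectory.csv"),
                     row.names = FALSE)
    write_report_json(list(
      steady_state_residual = steady_state_residual(traj),
      post_removal = post_removal_response(traj)),
      emit("analysis.json"))
  } else if (config$experiment == "plasticity_demo") {
    par <- plasticity_params(delta = config$delta %||% 1,
                             g0 = config$g0 %||% 1.2,
                             cgrp = config$cgrp %||% 0,
                             hill = config$hill %||% 4)
    bif <- bifurcation_scan(par, B_range = c(config$scan_min %||% 0,
                                             config$scan_max %||% 1.5))
    utils::write.csv(bif$branches, emit("bifurcation.csv"),
                     row.names = FALSE)
    hy <- hysteresis_trace(par, B_max = config$scan_max %||% 1.5)
    utils::write.csv(as.data.frame(hy), emit("hysteresis.csv"),
                     row.names = FALSE)
    write_report_json(list(regime = bif$regime, B_on = bif$B_on,
                           B_off = bif$B_off,
                           equilibria_at_zero = bif$equilibria_at_zero),
                      emit("summary.json"))
  } else if (config$experiment == "full_chain") {
    stage_seeds$chain <- derive_seed(seed, 1)
    ch <- full_chain(
      cgrp_low = config$cgrp_low %||% 0,
      cgrp_high = config$cgrp_high %||% 1.5,
      B_pulse = config$B_pulse %||% 1,
      n_samples = config$n_samples %||% 1e4,
      disturbance = disturbance_spec(
        t_aboard = config$t_aboard %||% 300,
        t_ashore = config$t_ashore %||% 400),
      seed = stage_seeds$chain)
    write_report_json(unclass(ch), emit("chain_report.json"))
  } else if (config$experiment == "classify") {
    if (is.null(config$matrix))
      stop("invalid config: field 'matrix' (file path) is required for 'classify'",
           call. = FALSE)
    J <- read_matrix_file(config$matrix)
    sc <- classify_spectrum(J)
    td <- classify_time_domain(J)
    write_report_json(list(
      eigenvalues = data.frame(re = Re(sc$eigenvalues),
                               im = Im(sc$eigenvalues)),
      category = sc$category, oscillatory = sc$oscillatory,
      time_domain = list(oscillatory = td$oscillatory,
                         growth_rates = td$growth_rates,
                         resolution = td$resolution)),
      emit("classification.json"))
  }

  cfg_norm <- config[order(names(config))]
  cfg_norm$out_dir <- NULL
  cfg_file <- file.path(out_dir, "config.json")
  write_report_json(cfg_norm, cfg_file)
  record <- list(
    experiment = config$experiment,
    config_hash = unname(tools::md5sum(cfg_file)),
    master_seed = seed,
    stage_seeds = stage_seeds,
    package_version = as.character(utils::packageVersion("mddsloops")),
    timestamp = format(Sys.time(), tz = "UTC"),
    manifest = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      row.names = NULL))
  write_report_json(record, file.path(out_dir, "run_record.json"))
  record$out_dir <- out_dir
  class(record) <- "run_record"
  invisible(record)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("Run record: %s (seed %s, config %s)\n", x$experiment,
              format(x$master_seed), substr(x$config_hash, 1, 8)))
  print(x$manifest)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
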