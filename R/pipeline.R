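#' End-to-end depth-from-focus pipeline
#'
#' Runs the full chain on a scene: simulate the event camera over one focal
#' sweep, detect per-pixel focus times with the chosen engine (spiking
#' network or the polarity-inversion reference detector), assemble the depth
#' map, and — since the scene carries ground truth — evaluate it.
#'
#' @param scene A [dff_scene()].
#' @param profile A [sweep_profile()].
#' @param cfg An [optical_config()].
#' @param engine `"snn"` or `"oracle"`.
#' @param dt_render Render step for the event simulation (s).
#' @param snn_params A [circuit_params()] (snn engine only).
#' @param evaluate Compute the error report against the scene ground truth.
#' @return A list with `events`, `tf` (focus-time tibble), `depth_map`,
#'   `report` (a `dff_error_report`, or `NULL`), and `engine`.
#' @examples
#' \donttest{
#' res <- dff_pipeline(make_fixture("sphere", z = 0.3), engine = "oracle")
#' glance(res$report)
#' }
#' @export
dff_pipeline <- function(scene, profile = sweep_profile(),
                         cfg = optical_config(),
                         engine = c("snn", "oracle"),
                         dt_render = 25e-6,
                         snn_params = circuit_params(),
                         evaluate = TRUE) {
  engine <- match.arg(engine)
  events <- generate_events(scene, profile, cfg, dt = dt_render)
  tf <- focus_times_for(events, engine, dim(scene$depth), snn_params, profile)
  dm <- assemble_depth_map(tf, profile, cfg, shape = dim(scene$depth))
  report <- if (evaluate && any(dm$valid & !is.na(scene$depth[
    cbind(dm$y + 1L, dm$x + 1L)]))) evaluate_depth(dm, scene) else NULL
  list(events = events, tf = tf, depth_map = dm, report = report,
       engine = engine)
}

# Dispatch an event stream to the chosen focus-detection engine.
focus_times_for <- function(events, engine, shape, snn_params, profile) {
  if (engine == "oracle") {
    detect_focus_times(events)
  } else {
    net <- build_network(shape, params = snn_params)
    rec <- run_network(net, events, sync_times = profile$t_end)
    snn_focus_times(rec)
  }
}

#' Run configuration for the command-line driver
#'
#' Collects everything one end-to-end run needs; with a fixed `seed` the
#' deterministic stages reproduce byte-identical outputs.
#'
#' @param fixture Fixture kind for [make_fixture()].
#' @param fixture_params Named list of extra [make_fixture()] arguments.
#' @param cfg,profile,snn Component configurations.
#' @param engine Default focus engine.
#' @param dt_render Render step (s).
#' @param seed Integer seed.
#' @param out_dir Output directory (created on demand).
#' @return A list of class `run_config`.
#' @export
run_config <- function(fixture = "sphere", fixture_params = list(),
                       cfg = optical_config(), profile = sweep_profile(),
                       snn = circuit_params(), engine = "snn",
                       dt_render = 25e-6, seed = 1L,
                       out_dir = tempfile("eventdff-run-")) {
  structure(list(fixture = fixture, fixture_params = fixture_params,
                 cfg = cfg, profile = profile, snn = snn, engine = engine,
                 dt_render = dt_render, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

provenance_log <- function(rc, extra = list()) {
  log <- c(list(
    config_hash = rlang::hash(rc[setdiff(names(rc), "out_dir")]),
    seed = rc$seed,
    package = "eventdff",
    package_version = as.character(utils::packageVersion("eventdff")),
    r_version = as.character(getRversion())
  ), extra)
  jsonlite::write_json(log, file.path(rc$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}

#' Command-line entry points
#'
#' Thin, scriptable wrappers around the pipeline, mirroring the
#' `simulate` / `depth` / `evaluate` / `demo` subcommands of the
#' `inst/cli/eventdff` driver script. `cmd_simulate()` renders the fixture
#' and writes `events.csv`, `truth_depth.csv`, the flat config file and a
#' provenance log. `cmd_depth()` runs a focus engine over an event file and
#' writes the depth map (`depth.csv`, 16-bit and color PNG), the masks and,
#' when ground truth is present, `report.json` with the error metrics.
#' `cmd_evaluate()` recomputes the report from a written depth map and
#' truth file. `cmd_demo()` chains all three on the sphere fixture.
#'
#' @param rc A [run_config()].
#' @param events_path Path to an `events.csv` (defaults to the one
#'   `cmd_simulate()` wrote into `rc$out_dir`).
#' @param engine Focus engine override (`"snn"` or `"oracle"`).
#' @return Invisibly, a named list of the files written (plus key results).
#' @export
cmd_simulate <- function(rc = run_config()) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(rc$seed)
  scene <- do.call(make_fixture,
                   c(list(kind = rc$fixture, seed = rc$seed),
                     rc$fixture_params))
  events <- generate_events(scene, rc$profile, rc$cfg, dt = rc$dt_render)
  ev_path <- file.path(rc$out_dir, "events.csv")
  write_event_csv(events, ev_path)
  truth_path <- file.path(rc$out_dir, "truth_depth.csv")
  utils::write.table(scene$depth, truth_path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  cfg_path <- file.path(rc$out_dir, "config.txt")
  write_dff_config(cfg_path, cfg = rc$cfg, profile = rc$profile)
  span <- rc$profile$t_end - rc$profile$t_start
  message(sprintf("simulate: %d events in %.3g ms (%.3g Mev/s)",
                  nrow(events), span * 1e3, nrow(events) / span / 1e6))
  provenance_log(rc, list(stage = "simulate", n_events = nrow(events),
                          event_rate_hz = nrow(events) / span))
  invisible(list(events = ev_path, truth = truth_path, config = cfg_path,
                 n_events = nrow(events)))
}

#' @rdname cmd_simulate
#' @export
cmd_depth <- function(rc = run_config(), events_path = NULL,
                      engine = rc$engine) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  events_path <- events_path %||% file.path(rc$out_dir, "events.csv")
  truth_path <- file.path(rc$out_dir, "truth_depth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- as.matrix(utils::read.table(truth_path, sep = ",",
                                         na.strings = c("NA", "")))
    dimnames(truth) <- NULL
  }
  events <- read_event_csv(events_path,
                           sensor_shape = if (!is.null(truth)) dim(truth))
  shape <- attr(events, "sensor_shape")
  attr(events, "sweep") <- rc$profile
  tf <- focus_times_for(events, engine, shape, rc$snn, rc$profile)
  dm <- assemble_depth_map(tf, rc$profile, rc$cfg, shape = shape)
  paths <- list(
    depth_csv = write_depth_csv(dm, file.path(rc$out_dir, "depth.csv")),
    depth_png = write_depth_png(dm, file.path(rc$out_dir, "depth.png")),
    depth_color = write_depth_color_png(
      dm, file.path(rc$out_dir, "depth_color.png"))
  )
  masks <- dplyr::select(tibble::as_tibble(dm), "x", "y", "valid",
                         "ambiguous")
  readr::write_csv(masks, file.path(rc$out_dir, "masks.csv"))
  report <- NULL
  if (!is.null(truth)) {
    scene <- dff_scene(matrix(0.5, nrow(truth), ncol(truth)), truth)
    report <- evaluate_depth(dm, scene)
    jsonlite::write_json(
      list(mean_relative_error = report$mean_relative_error,
           std_relative_error = report$std_relative_error,
           n_pixels = report$n_pixels,
           n_valid = sum(dm$valid),
           n_ambiguous = sum(dm$ambiguous, na.rm = TRUE),
           engine = engine),
      file.path(rc$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  } else {
    warn("no ground truth found; error report omitted.")
  }
  provenance_log(rc, list(stage = "depth", engine = engine))
  invisible(c(paths, list(depth_map = dm, report = report)))
}

#' @rdname cmd_simulate
#' @param depth_path,truth_path CSV files for standalone evaluation.
#' @export
cmd_evaluate <- function(rc = run_config(),
                         depth_path = file.path(rc$out_dir, "depth.csv"),
                         truth_path = file.path(rc$out_dir,
                                                "truth_depth.csv")) {
  read_mat <- function(p) {
    m <- as.matrix(utils::read.table(p, sep = ",",
                                     na.strings = c("NA", "")))
    dimnames(m) <- NULL
    m
  }
  est <- read_mat(depth_path)
  truth <- read_mat(truth_path)
  keep <- !is.na(est) & !is.na(truth)
  if (!any(keep)) abort("no valid pixel overlaps the ground truth.")
  rel <- 100 * abs(est[keep] - truth[keep]) / truth[keep]
  out <- list(mean_relative_error = mean(rel),
              std_relative_error = stats::sd(rel), n_pixels = sum(keep))
  jsonlite::write_json(out, file.path(rc$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @rdname cmd_simulate
#' @export
cmd_demo <- function(rc = run_config(fixture = "sphere")) {
  sim <- cmd_simulate(rc)
  dep <- cmd_depth(rc)
  if (!is.null(dep$report)) {
    message(sprintf("demo: mean relative depth error %.2f%%",
                    dep$report$mean_relative_error))
  }
  invisible(list(simulate = sim, depth = dep))
}
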