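`%||%` <- function(a, b) if (is.null(a)) b else a

.conditions <- list(
  # main experiment: 5 groups, 44.4 ms group interval, 4.5 Hz full cycle
  # (also labeled "5 Hz" in the follow-up configurations)
  main = list(n_groups = 5L, frames_per_group = 4L, preset = "5Hz",
              temporal_on = TRUE),
  # baseline: all electrodes every frame, temporal effects still on
  no_raster = list(n_groups = 5L, frames_per_group = 4L, preset = "5Hz",
                   temporal_on = TRUE, pattern = "none"),
  # follow-up "18 Hz": one render frame per group, 55.5 ms cycle
  fast = list(n_groups = 5L, frames_per_group = 1L, preset = "20Hz",
              temporal_on = TRUE),
  # follow-up "four groups": cycle rate kept at 4.5 Hz (5 frames per group)
  four_group = list(n_groups = 4L, frames_per_group = 5L, preset = "5Hz",
                    temporal_on = TRUE)
)

#' Simulation configuration
#'
#' Bundles every tunable of the pipeline into one validated object. Named
#' conditions reproduce the study settings: `"main"` (5 groups, 44.4 ms group
#' interval, 4.5 Hz cycle), `"no_raster"` (all electrodes every frame,
#' temporal model on), `"fast"` (5 groups at the 11.1 ms render period, 18
#' full cycles per second) and `"four_group"` (4 groups, cycle kept at
#' 4.5 Hz). Any field can be overridden through `...` using the nested names
#' shown in the defaults (e.g. `axon = list(n_axons = 300)`).
#'
#' @param condition one of `"main"`, `"no_raster"`, `"fast"`, `"four_group"`.
#' @param pattern raster pattern: `"horizontal"`, `"vertical"`,
#'   `"checkerboard"`, `"random"`, or `"none"`.
#' @param seed master seed for all randomness in the run.
#' @param ... nested overrides (see Details in the package vignette).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(condition = c("main", "no_raster", "fast", "four_group"),
                       pattern = c("checkerboard", "horizontal", "vertical",
                                   "random", "none"),
                       seed = 1L, ...) {
  condition <- match.arg(condition)
  pattern <- match.arg(pattern)
  cnd <- .conditions[[condition]]
  if (!is.null(cnd$pattern)) pattern <- cnd$pattern
  cfg <- list(
    condition = condition,
    pattern = pattern,
    seed = as.integer(seed),
    array = list(rows = 10L, cols = 10L, pitch_um = 400, center_um = c(0, 0)),
    retina = list(um_per_degree = 280, extent_deg = 12, step_deg = 0.25,
                  eye = "right"),
    axon = list(n_axons = 500L, step_um = 50, disc_deg = c(15, 2)),
    params = list(rho = 300, lam = 1000),
    clock = list(render_rate_hz = 90, frames_per_group = cnd$frames_per_group,
                 n_groups = cnd$n_groups),
    temporal = list(on = cnd$temporal_on, preset = cnd$preset),
    raster = list(reshuffle_every = 5L),
    gaze = list(mode = "fixation", noise_deg = 1.9),
    stimulus = list(size_deg = 41.1, duration_s = 5, canvas_px = 200L,
                    canvas_fov_deg = 60, bar_width_frac = 0.1),
    gain = 1
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    raster_clock(clock$render_rate_hz, clock$frames_per_group,
                 clock$n_groups)  # errors on inconsistent clocks
    half_x <- (array$cols - 1) / 2 * array$pitch_um + abs(array$center_um[1])
    half_y <- (array$rows - 1) / 2 * array$pitch_um + abs(array$center_um[2])
    need_um <- max(half_x, half_y) + 3 * params$rho
    if (retina$extent_deg * retina$um_per_degree < need_um)
      stop(sprintf(paste0("percept grid extent (%g deg) must cover the array ",
                          "footprint plus a 3*rho margin (%.1f deg)"),
                   retina$extent_deg, need_um / retina$um_per_degree))
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  ck <- raster_clock(x$clock$render_rate_hz, x$clock$frames_per_group,
                     x$clock$n_groups)
  cat(sprintf(paste0("<sim_config> condition '%s', pattern '%s', %d groups @ ",
                     "%.1f ms (cycle %.1f ms), rho=%g lam=%g, preset %s, seed %d\n"),
              x$condition, x$pattern, ck$n_groups, ck$group_interval_ms,
              ck$cycle_ms, x$params$rho, x$params$lam,
              if (x$temporal$on) x$temporal$preset else "off", x$seed))
  invisible(x)
}

#' Write/read a simulation config as YAML
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- c(list(condition = raw$condition, pattern = raw$pattern,
                 seed = raw$seed),
            raw[setdiff(names(raw), c("condition", "pattern", "seed"))])
  do.call(sim_config, args)
}

#' Build the static simulation state for a config
#'
#' Constructs the retina spec, electrode array, axon map and spatial-model
#' basis once; reuse the result across [run_simulation()] calls with the
#' same geometry.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_state`.
#' @export
build_sim <- function(cfg) {
  spec <- do.call(retina_spec, cfg$retina)
  array <- do.call(build_electrode_array, cfg$array)
  axons <- build_axon_map(spec, n_axons = cfg$axon$n_axons,
                          step_um = cfg$axon$step_um,
                          disc_deg = cfg$axon$disc_deg)
  params <- do.call(axon_map_params, cfg$params)
  basis <- phosphene_basis(array, axons, params)
  clock <- raster_clock(cfg$clock$render_rate_hz, cfg$clock$frames_per_group,
                        cfg$clock$n_groups)
  tparams <- temporal_params(cfg$temporal$preset)
  structure(list(spec = spec, array = array, axons = axons, params = params,
                 basis = basis, clock = clock, tparams = tparams),
            class = "sim_state")
}

#' Run the simulation pipeline on one stimulus clip
#'
#' Executes, per render frame: preprocessing, gaze-contingent shift, raster
#' group selection from the frame clock, electrode activation, the axon-map
#' spatial model, and (optionally) the leaky-integrator temporal model.
#'
#' @param stimulus a `stimulus_clip`.
#' @param gaze a `gaze_trace` (sample rate >= render rate), or `NULL` for
#'   perfect central fixation.
#' @param cfg a [sim_config()].
#' @param sim optional prebuilt [build_sim()] state.
#' @param schedule_seed seed for the random raster pattern (defaults to
#'   `cfg$seed`).
#' @return a `percept_clip`: brightness frames (`[ny, nx, T]` array, row 1 =
#'   top) at the render rate plus per-frame clock metadata (`raster_frame`,
#'   `cycle`, `group`).
#' @export
run_simulation <- function(stimulus, gaze, cfg, sim = NULL,
                           schedule_seed = NULL) {
  if (is.null(sim)) sim <- build_sim(cfg)
  ck <- sim$clock
  n_frames <- as.integer(round(stimulus$duration_s * ck$render_rate_hz))
  n_raster <- (n_frames - 1L) %/% ck$frames_per_group + 1L
  n_epochs <- ceiling(n_raster / cfg$raster$reshuffle_every)
  sched <- make_schedule(cfg$pattern, sim$array, ck$n_groups,
                         seed = schedule_seed %||% cfg$seed,
                         reshuffle_every = cfg$raster$reshuffle_every,
                         n_epochs = n_epochs)
  fov <- stimulus$canvas_fov_deg
  dt <- 1 / ck$render_rate_hz

  frames <- array(0, dim = c(sim$basis$ny, sim$basis$nx, n_frames))
  raster_frame <- integer(n_frames); grp <- integer(n_frames)
  state <- NULL
  for (i in seq_len(n_frames)) {
    t_i <- (i - 1) * dt
    si <- min(stimulus$n_frames, max(1L, as.integer(round(t_i * stimulus$fps)) + 1L))
    fr <- preprocess_frame(clip_frame(stimulus, si), cfg$stimulus$canvas_px)
    if (!is.null(gaze)) {
      gi <- min(nrow(gaze), max(1L, which.min(abs(gaze$t - t_i))))
      fr <- apply_gaze_shift(fr, c(gaze$x_deg[gi], gaze$y_deg[gi]), fov)
    }
    r <- (i - 1L) %/% ck$frames_per_group
    act_idx <- active_electrodes(sched, sim$array, r)
    a <- electrode_activation(fr, sim$array, act_idx, sim$spec, fov)
    b_I <- spatial_percept(a, sim$basis)
    if (cfg$temporal$on) {
      state <- temporal_step(state, b_I, sim$tparams, dt)
      frames[, , i] <- state$b
    } else {
      frames[, , i] <- b_I
    }
    raster_frame[i] <- r
    grp[i] <- if (is.null(sched)) 0L else sched$group_order[r %% ck$n_groups + 1L]
  }
  structure(list(
    frames = frames,
    times = (seq_len(n_frames) - 1L) * dt,
    render_rate_hz = ck$render_rate_hz,
    frames_per_group = ck$frames_per_group,
    n_groups = ck$n_groups,
    raster_frame = raster_frame,
    cycle = raster_frame %/% ck$n_groups,
    group = grp,
    grid_x_deg = sim$basis$grid_x_deg,
    grid_y_deg = sim$basis$grid_y_deg,
    pattern = cfg$pattern, condition = cfg$condition,
    label = stimulus$label
  ), class = "percept_clip")
}

#' @export
print.percept_clip <- function(x, ...) {
  cat(sprintf("<percept_clip> '%s' (%s/%s): %d frames @ %g Hz, grid %dx%d\n",
              x$label, x$condition, x$pattern, dim(x$frames)[3],
              x$render_rate_hz, dim(x$frames)[1], dim(x$frames)[2]))
  invisible(x)
}

.task_alternatives <- function(task)
  switch(task, letter = optotype_letters(), motion = motion_directions(),
         stop("unknown task: ", task))

.make_stimulus <- function(task, label, cfg) {
  st <- cfg$stimulus
  if (task == "letter")
    render_optotype(label, size_deg = st$size_deg, duration_s = st$duration_s,
                    fps = cfg$clock$render_rate_hz, canvas_px = st$canvas_px,
                    canvas_fov_deg = st$canvas_fov_deg)
  else
    render_moving_bar(label, duration_s = st$duration_s,
                      fps = cfg$clock$render_rate_hz, canvas_px = st$canvas_px,
                      canvas_fov_deg = st$canvas_fov_deg,
                      bar_width_frac = st$bar_width_frac)
}

#' Run a full 8AFC experiment for one condition
#'
#' Emits `n_blocks` blocks of `n_per_block` trials; each block presents each
#' of the 8 stimuli exactly once in seeded random order (48 trials per
#' condition at the defaults). Each trial renders the stimulus through
#' [run_simulation()] and queries the virtual observer.
#'
#' @param task `"letter"` or `"motion"`.
#' @param cfg a [sim_config()].
#' @param n_blocks number of blocks (default 6).
#' @param n_per_block trials per block; must equal the number of distinct
#'   stimuli (8).
#' @param observer an [observer_spec()].
#' @param seed experiment seed (default `cfg$seed`).
#' @param sim optional prebuilt [build_sim()] state.
#' @return data.frame of `TrialRecord`s: `trial`, `block`, `task`,
#'   `condition`, `pattern`, `stimulus`, `choice`, `correct`, `seed`.
#' @export
run_experiment <- function(task = c("letter", "motion"), cfg,
                           n_blocks = 6, n_per_block = 8,
                           observer = observer_spec("template"),
                           seed = NULL, sim = NULL) {
  task <- match.arg(task)
  alts <- .task_alternatives(task)
  if (n_per_block != length(alts))
    stop("`n_per_block` must equal the number of distinct stimuli (",
         length(alts), ")")
  if (!inherits(observer, "observer_spec")) stop("`observer` must be an observer_spec")
  seed <- as.integer(seed %||% cfg$seed)
  if (is.null(sim)) sim <- build_sim(cfg)

  bank <- NULL
  if (observer$kind == "template" && task == "letter")
    bank <- template_bank(cfg, sim)

  records <- .with_seed(seed, {
    rows <- vector("list", n_blocks * n_per_block)
    trial <- 0L
    for (b in seq_len(n_blocks)) {
      order_b <- sample(alts)
      for (p in seq_len(n_per_block)) {
        trial <- trial + 1L
        lab <- order_b[p]
        gaze_seed <- sample.int(2^30, 1)
        sched_seed <- sample.int(2^30, 1)
        obs_seed <- sample.int(2^30, 1)
        gaze <- simulate_gaze(cfg$stimulus$duration_s,
                              rate_hz = cfg$clock$render_rate_hz,
                              mode = cfg$gaze$mode,
                              noise_deg = cfg$gaze$noise_deg, seed = gaze_seed)
        stim <- .make_stimulus(task, lab, cfg)
        clip <- run_simulation(stim, gaze, cfg, sim = sim,
                               schedule_seed = sched_seed)
        choice <- if (observer$kind == "random")
          alts[random_observer(length(alts), 1, seed = obs_seed)]
        else if (task == "letter")
          template_observer(clip, bank)
        else
          choose_motion(clip)
        rows[[trial]] <- data.frame(
          trial = trial, block = b, task = task, condition = cfg$condition,
          pattern = cfg$pattern, stimulus = lab, choice = choice,
          correct = choice == lab, seed = seed, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  records
}

#' Write percept frames, trial records and a config echo to disk
#'
#' Percept frames are written as 8-bit grayscale PNGs (`frame_000001.png`,
#' ...) with a fixed gain (no per-frame autoscaling, so fading stays
#' visible); records as a headered CSV; the config as YAML.
#'
#' @param clip a `percept_clip`, or `NULL` to skip frames.
#' @param records a trial-record data.frame, or `NULL` to skip.
#' @param dir output directory (created if needed).
#' @param cfg optional [sim_config()] to echo alongside the outputs.
#' @param gain fixed display gain mapping brightness to `[0, 1]`
#'   (default `cfg$gain` or 1).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(clip = NULL, records = NULL, dir, cfg = NULL,
                          gain = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  gain <- gain %||% (if (!is.null(cfg)) cfg$gain else 1)
  paths <- character(0)
  if (!is.null(clip)) {
    nT <- dim(clip$frames)[3]
    for (i in seq_len(nT)) {
      p <- file.path(dir, sprintf("frame_%06d.png", i))
      png::writePNG(pmin(pmax(clip$frames[, , i] * gain, 0), 1), p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(records)) {
    p <- file.path(dir, "records.csv")
    utils::write.csv(records, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(cfg)) {
    p <- file.path(dir, "config.yaml")
    write_sim_config(cfg, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read trial records written by [write_outputs()]
#' @param path path to a records CSV.
#' @return data.frame.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$correct <- as.logical(df$correct)
  df
}
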