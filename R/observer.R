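#' Virtual-observer specification
#'
#' The virtual observer stands in for the human participant in the two 8AFC
#' tasks. `"template"` matches the time-averaged percept against a bank of
#' the 8 alternatives by normalized cross-correlation (letters) or uses the
#' motion-energy drift direction (motion); `"random"` answers uniformly at
#' random (chance = 1/8). Ties are broken by the fixed alternative order
#' (alphabetical letters; compass directions clockwise from "up").
#'
#' @param kind `"template"` or `"random"`.
#' @param seed seed for the random observer.
#' @return list of class `observer_spec`.
#' @export
observer_spec <- function(kind = c("template", "random"), seed = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = seed), class = "observer_spec")
}

#' Render the template bank for the letter task
#'
#' Templates are the 8 optotype percepts rendered under the reference
#' condition: no rastering (all electrodes active), temporal model off, zero
#' gaze, at the evaluation rho/lambda. The observer therefore carries the
#' same spatial distortions as the signal, isolating raster effects.
#'
#' @param cfg a [sim_config()].
#' @param sim optional prebuilt [build_sim()] state.
#' @return named list of brightness fields, one per letter, with attribute
#'   `"alternatives"`.
#' @export
template_bank <- function(cfg, sim = NULL) {
  if (is.null(sim)) sim <- build_sim(cfg)
  fov <- cfg$stimulus$canvas_fov_deg
  all_e <- seq_len(nrow(sim$array))
  bank <- lapply(optotype_letters(), function(L) {
    stim <- render_optotype(L, size_deg = cfg$stimulus$size_deg,
                            duration_s = 1 / cfg$clock$render_rate_hz,
                            fps = cfg$clock$render_rate_hz,
                            canvas_px = cfg$stimulus$canvas_px,
                            canvas_fov_deg = fov)
    fr <- preprocess_frame(clip_frame(stim, 1), cfg$stimulus$canvas_px)
    a <- electrode_activation(fr, sim$array, all_e, sim$spec, fov)
    spatial_percept(a, sim$basis)
  })
  names(bank) <- optotype_letters()
  attr(bank, "alternatives") <- optotype_letters()
  bank
}

#' Template-matching observer (letter task)
#'
#' Chooses the alternative whose template has the highest normalized
#' cross-correlation with the time-averaged percept. Degenerate scores
#' (zero-variance percept) fall back to the first alternative in bank order.
#'
#' @param clip a `percept_clip` (or a single brightness field).
#' @param bank a [template_bank()].
#' @return chosen label (character scalar).
#' @export
template_observer <- function(clip, bank) {
  avg <- if (inherits(clip, "percept_clip")) {
    if (!length(clip$frames) || dim(clip$frames)[3] < 1)
      stop("empty percept clip")
    rowMeans(matrix(clip$frames, prod(dim(clip$frames)[1:2]),
                    dim(clip$frames)[3]))
  } else as.vector(clip)
  if (!length(avg)) stop("empty percept clip")
  scores <- vapply(bank, function(tmpl) {
    tv <- as.vector(tmpl)
    if (stats::sd(avg) == 0 || stats::sd(tv) == 0) return(-Inf)
    stats::cor(avg, tv)
  }, numeric(1))
  names(bank)[which.max(scores)]  # which.max = first max = fixed tie-break
}

#' Uniform random observer
#'
#' @param n_alternatives number of response alternatives.
#' @param n number of choices to draw.
#' @param seed RNG seed (required).
#' @return integer vector of chosen alternative indices.
#' @export
random_observer <- function(n_alternatives, n = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  .with_seed(seed, sample.int(n_alternatives, n, replace = TRUE))
}

#' Motion-energy drift of a percept clip
#'
#' Estimates apparent motion by brightness-centroid differencing (suited to
#' the near-binary fields the simulator produces): the brightness-weighted
#' centroid is computed per frame, successive displacements are scaled to
#' deg/s, and two summaries are returned. `drift_dps` is the signed mean
#' displacement (net drift; a cyclic raster's wobble largely cancels here),
#' `wobble_dps` the mean displacement magnitude (sensitive to raster-induced
#' jumping regardless of direction). Frames with (near-)zero total
#' brightness are skipped; a constant clip yields zeros.
#'
#' @param clip a `percept_clip`.
#' @return list with `drift_dps` (length-2, x/y in deg/s), `wobble_dps`
#'   (scalar), `n_pairs`.
#' @export
motion_energy <- function(clip) {
  nT <- dim(clip$frames)[3]
  if (is.null(nT) || nT < 2) stop("motion_energy needs at least 2 frames")
  xs <- clip$grid_x_deg; ys <- clip$grid_y_deg
  cx <- numeric(nT); cy <- numeric(nT); ok <- logical(nT)
  for (i in seq_len(nT)) {
    f <- clip$frames[, , i]
    s <- sum(f)
    if (s > 1e-9) {
      cx[i] <- sum(colSums(f) * xs) / s
      cy[i] <- sum(rowSums(f) * ys) / s
      ok[i] <- TRUE
    }
  }
  idx <- which(ok)
  if (length(idx) < 2)
    return(list(drift_dps = c(x = 0, y = 0), wobble_dps = 0, n_pairs = 0L))
  # displacements between consecutive valid frames, per second
  dtv <- diff(clip$times[idx])
  dx <- diff(cx[idx]) / dtv
  dy <- diff(cy[idx]) / dtv
  list(drift_dps = c(x = mean(dx), y = mean(dy)),
       wobble_dps = mean(sqrt(dx^2 + dy^2)),
       n_pairs = length(dx))
}

#' Motion decision from the drift vector
#'
#' Maps [motion_energy()]'s net drift onto the nearest of the 8 compass
#' directions. A (near-)zero drift falls back to the first direction in
#' [motion_directions()] order.
#'
#' @param clip a `percept_clip`.
#' @return chosen direction (character scalar).
#' @export
choose_motion <- function(clip) {
  me <- motion_energy(clip)
  v <- me$drift_dps
  dirs <- motion_directions()
  if (.norm2(v) < 1e-9) return(dirs[1])
  dots <- vapply(dirs, function(d) sum(.direction_vector(d) * v), numeric(1))
  dirs[which.max(dots)]
}

#' Confusion matrix and response-bias indices
#'
#' Tabulates presented stimulus (rows) against observer choice (columns)
#' over the 8 task alternatives, and computes a per-response bias index:
#' the fraction of all error trials in which that response was chosen.
#'
#' @param records trial records from [run_experiment()] (a single task).
#' @return list with `confusion` (8x8 counts), `bias` (named numeric,
#'   `NA` if there are no errors), `n_trials`, `accuracy`.
#' @export
confusion_and_bias <- function(records) {
  if (!nrow(records)) stop("`records` is empty")
  if (length(unique(records$task)) != 1)
    stop("`records` mixes tasks; pass a single task's records")
  alts <- .task_alternatives(records$task[1])
  cm <- table(factor(records$stimulus, levels = alts),
              factor(records$choice, levels = alts))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("stimulus", "choice")
  err <- !records$correct
  bias <- if (any(err))
    vapply(alts, function(a) mean(records$choice[err] == a), numeric(1))
  else stats::setNames(rep(NA_real_, length(alts)), alts)
  list(confusion = cm, bias = bias, n_trials = nrow(records),
       accuracy = mean(records$correct))
}

#' Save a confusion-matrix heatmap as PNG
#'
#' @param cm an 8x8 confusion matrix (counts), e.g.
#'   `confusion_and_bias(records)$confusion`.
#' @param path output PNG path.
#' @param main plot title.
#' @export
plot_confusion <- function(cm, path, main = "Confusion matrix") {
  grDevices::png(path, width = 600, height = 560)
  on.exit(grDevices::dev.off())
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), t(cm[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "choice", ylab = "stimulus",
                  main = main)
  graphics::axis(1, seq_len(n), colnames(cm))
  graphics::axis(2, seq_len(n), rev(rownames(cm)))
  invisible(path)
}
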