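#' Raster clock
#'
#' The frame clock tying raster-group activation to the render loop. The group
#' interval is stored exactly, as an integer number of render frames, so the
#' derived quantities are exact: at 90 Hz with 4 frames per group the interval
#' is 44.44 ms (printed elsewhere as 44.4 ms), the group-event rate exactly
#' 22.5 Hz, and a 5-group cycle 222.2 ms (4.5 Hz).
#'
#' @param render_rate_hz render-loop rate in Hz (default 90).
#' @param frames_per_group render frames per raster group event (default 4).
#'   May instead be derived from `group_interval_ms`.
#' @param n_groups number of timing groups (default 5).
#' @param group_interval_ms optional; if given, must be an integer multiple of
#'   the render period (within 2%), and overrides `frames_per_group`.
#' @return An object of class `raster_clock` with fields `render_rate_hz`,
#'   `frames_per_group`, `n_groups`, `group_interval_ms`, `cycle_ms`,
#'   `group_event_rate_hz`, `cycle_rate_hz`.
#' @export
raster_clock <- function(render_rate_hz = 90, frames_per_group = 4,
                         n_groups = 5, group_interval_ms = NULL) {
  if (render_rate_hz <= 0) stop("`render_rate_hz` must be > 0")
  period_ms <- 1000 / render_rate_hz
  if (!is.null(group_interval_ms)) {
    fpg <- group_interval_ms / period_ms
    if (abs(fpg - round(fpg)) > 0.02 * max(1, round(fpg)))
      stop("`group_interval_ms` must be an integer multiple of the render period (",
           signif(period_ms, 4), " ms)")
    frames_per_group <- as.integer(round(fpg))
  }
  if (frames_per_group < 1 || frames_per_group != round(frames_per_group))
    stop("`frames_per_group` must be a positive integer")
  if (n_groups < 1 || n_groups != round(n_groups))
    stop("`n_groups` must be a positive integer")
  gi <- frames_per_group * period_ms
  structure(list(
    render_rate_hz = render_rate_hz,
    frames_per_group = as.integer(frames_per_group),
    n_groups = as.integer(n_groups),
    group_interval_ms = gi,
    cycle_ms = n_groups * gi,
    group_event_rate_hz = 1000 / gi,
    cycle_rate_hz = 1000 / (n_groups * gi)
  ), class = "raster_clock")
}

.new_schedule <- function(pattern, array, n_groups, assignments, group_order,
                          reshuffle_every = Inf, seed = NA_integer_,
                          group_interval_ms = 1000 / 22.5) {
  stopifnot(is.matrix(assignments))
  structure(list(
    pattern = pattern,
    electrode_id = array$electrode_id,
    n_groups = as.integer(n_groups),
    assignments = assignments,          # n_elec x n_epochs, values 1..n_groups
    group_order = as.integer(group_order),
    reshuffle_every = reshuffle_every,  # raster frames per epoch (Inf = fixed)
    seed = seed,
    group_interval_ms = group_interval_ms
  ), class = "raster_schedule")
}

#' @export
print.raster_schedule <- function(x, ...) {
  cat(sprintf("<raster_schedule> pattern '%s', %d groups, %d electrodes, %d epoch(s)\n",
              x$pattern, x$n_groups, length(x$electrode_id), ncol(x$assignments)))
  invisible(x)
}

.check_band_divisible <- function(n, n_groups, what) {
  if (n %% n_groups != 0)
    stop(sprintf("%d %s cannot be divided into %d contiguous bands", n, what,
                 n_groups))
}

#' Raster patterns: ordered timing-group partitions of the array
#'
#' Each scheduler partitions the electrode array into `n_groups` equal-size
#' timing groups and fixes their activation order; only one group is
#' stimulated per raster frame (charge-safety rastering).
#'
#' * `horizontal_schedule()`: contiguous row bands, activated top to bottom
#'   (two adjacent rows per group on a 10-row array with 5 groups).
#' * `vertical_schedule()`: contiguous column bands, activated left to right.
#' * `checkerboard_schedule()`: modular (Latin-square) assignment
#'   `g(i, j) = (a i + b j) mod n_groups`, with `(a, b)` chosen by exhaustive
#'   search to maximize the minimum within-group nearest-neighbor distance
#'   (ties: smallest `(a, b)` lexicographically), and the group order chosen
#'   by exhaustive search over permutations to minimize the
#'   [apparent_motion_index()] consistency (ties: lexicographic). Both
#'   searches are tiny and certifiably optimal over their space.
#' * `random_schedule()`: seeded equal-size random partition, re-drawn every
#'   `reshuffle_every` raster frames.
#'
#' @param array an [build_electrode_array()] result.
#' @param n_groups number of timing groups.
#' @return A `raster_schedule`.
#' @name raster-patterns
NULL

#' @rdname raster-patterns
#' @export
horizontal_schedule <- function(array, n_groups = 5) {
  rows <- attr(array, "rows")
  .check_band_divisible(rows, n_groups, "rows")
  per <- rows %/% n_groups
  g <- array$row %/% per + 1L
  .new_schedule("horizontal", array, n_groups,
                matrix(g, ncol = 1), seq_len(n_groups))
}

#' @rdname raster-patterns
#' @export
vertical_schedule <- function(array, n_groups = 5) {
  cols <- attr(array, "cols")
  .check_band_divisible(cols, n_groups, "columns")
  per <- cols %/% n_groups
  g <- array$col %/% per + 1L
  .new_schedule("vertical", array, n_groups,
                matrix(g, ncol = 1), seq_len(n_groups))
}

# minimum over groups of the within-group nearest-neighbor distance
.min_within_group_nn <- function(assign, array) {
  xy <- cbind(array$x_um, array$y_um)
  mins <- vapply(split(seq_len(nrow(xy)), assign), function(ii) {
    if (length(ii) < 2) return(Inf)
    d <- stats::dist(xy[ii, , drop = FALSE])
    min(d)
  }, numeric(1))
  min(mins)
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' @rdname raster-patterns
#' @export
checkerboard_schedule <- function(array, n_groups = 5) {
  rows <- attr(array, "rows"); cols <- attr(array, "cols")
  if (is.null(rows) || is.null(cols))
    stop("checkerboard_schedule requires a regular grid array")
  n_elec <- nrow(array)
  if (n_elec %% n_groups != 0)
    stop("electrode count must be divisible by `n_groups`")
  target <- n_elec / n_groups

  best <- NULL
  for (a in 0:(n_groups - 1)) for (b in 0:(n_groups - 1)) {
    g <- (a * array$row + b * array$col) %% n_groups + 1L
    if (any(tabulate(g, n_groups) != target)) next  # unbalanced (a, b)
    d <- .min_within_group_nn(g, array)
    if (is.null(best) || d > best$d + 1e-9) best <- list(a = a, b = b, g = g, d = d)
  }
  if (is.null(best))
    stop("no balanced modular assignment exists for this grid and group count")

  sched0 <- .new_schedule("checkerboard", array, n_groups,
                          matrix(best$g, ncol = 1), seq_len(n_groups))
  perms <- .permutations(seq_len(n_groups))
  cons <- vapply(perms, function(p) {
    s <- sched0; s$group_order <- p
    apparent_motion_index(s, array)$consistency
  }, numeric(1))
  order_best <- perms[[which.min(cons)]]  # which.min = first = lexicographic tie-break

  out <- .new_schedule("checkerboard", array, n_groups,
                       matrix(best$g, ncol = 1), order_best)
  attr(out, "modular_ab") <- c(a = best$a, b = best$b)
  attr(out, "min_within_group_nn_um") <- best$d
  out
}

#' @rdname raster-patterns
#' @param reshuffle_every re-randomize the partition every this many raster
#'   frames (default 5, i.e. once per full 5-group cycle).
#' @param seed RNG seed (required, for reproducibility).
#' @param n_epochs number of reshuffle epochs to pre-draw (default 1; the
#'   pipeline asks for as many as the clip needs).
#' @export
random_schedule <- function(array, n_groups = 5, reshuffle_every = 5, seed,
                            n_epochs = 1) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  n_elec <- nrow(array)
  if (n_elec %% n_groups != 0)
    stop("electrode count must be divisible by `n_groups`")
  per <- n_elec %/% n_groups
  assignments <- .with_seed(seed, {
    vapply(seq_len(n_epochs), function(ep) {
      g <- rep(seq_len(n_groups), each = per)
      g[sample.int(n_elec)]
    }, integer(n_elec))
  })
  .new_schedule("random", array, n_groups, assignments, seq_len(n_groups),
                reshuffle_every = reshuffle_every, seed = seed)
}

#' Active electrodes for a raster frame
#'
#' @param sched a `raster_schedule`, or `NULL` for the no-raster condition
#'   (all electrodes active every frame).
#' @param array the electrode array.
#' @param raster_frame 0-based raster frame index.
#' @return integer vector of electrode row indices into `array`.
#' @export
active_electrodes <- function(sched, array, raster_frame) {
  if (is.null(sched)) return(seq_len(nrow(array)))
  epoch <- if (is.finite(sched$reshuffle_every))
    raster_frame %/% sched$reshuffle_every + 1L else 1L
  epoch <- min(epoch, ncol(sched$assignments))
  pos <- raster_frame %% sched$n_groups + 1L
  grp <- sched$group_order[pos]
  which(sched$assignments[, epoch] == grp)
}

#' Apparent-motion index of a raster schedule
#'
#' Quantifies the coherent drift a raster pattern's group-to-group
#' transitions could induce. For each within-cycle transition in the group
#' order (the cycle-wrap transition is excluded), every electrode of the
#' incoming group contributes its displacement from the nearest electrode of
#' the outgoing group. `drift_um` is the mean displacement vector;
#' `consistency` is the norm of the mean unit displacement (1 = perfectly
#' coherent scan, 0 = no preferred direction).
#'
#' @param sched a `raster_schedule`.
#' @param array the electrode array it partitions.
#' @return list with `drift_um` (length-2), `consistency` (scalar in `[0,1]`),
#'   and `n_displacements`.
#' @export
apparent_motion_index <- function(sched, array) {
  if (sched$n_groups < 2)
    return(list(drift_um = c(0, 0), consistency = 0, n_displacements = 0L))
  xy <- cbind(array$x_um, array$y_um)
  disp <- matrix(numeric(0), ncol = 2)
  for (epoch in seq_len(ncol(sched$assignments))) {
    assign <- sched$assignments[, epoch]
    ord <- sched$group_order
    for (t in seq_len(sched$n_groups - 1L)) {
      from <- which(assign == ord[t])
      to <- which(assign == ord[t + 1L])
      if (!length(from) || !length(to)) next
      d2 <- outer(rowSums(xy[to, , drop = FALSE]^2),
                  rowSums(xy[from, , drop = FALSE]^2), "+") -
        2 * xy[to, , drop = FALSE] %*% t(xy[from, , drop = FALSE])
      nn <- from[max.col(-d2, ties.method = "first")]
      disp <- rbind(disp, xy[to, , drop = FALSE] - xy[nn, , drop = FALSE])
    }
  }
  if (!nrow(disp))
    return(list(drift_um = c(0, 0), consistency = 0, n_displacements = 0L))
  nrm <- sqrt(rowSums(disp^2))
  unit <- disp / ifelse(nrm > 0, nrm, 1)
  unit[nrm == 0, ] <- 0
  list(drift_um = colMeans(disp),
       consistency = sqrt(sum(colMeans(unit)^2)),
       n_displacements = nrow(disp))
}

#' Serialize a raster schedule to a plain table (and back)
#'
#' One row per electrode and reshuffle epoch: `electrode_id`, `epoch`,
#' `group`, `order` (the group's position in the activation order).
#'
#' @param sched a `raster_schedule`.
#' @return a data.frame.
#' @export
schedule_table <- function(sched) {
  n_ep <- ncol(sched$assignments)
  pos <- match(seq_len(sched$n_groups), sched$group_order)
  do.call(rbind, lapply(seq_len(n_ep), function(ep) {
    g <- sched$assignments[, ep]
    data.frame(electrode_id = sched$electrode_id, epoch = ep, group = g,
               order = pos[g], stringsAsFactors = FALSE)
  }))
}

#' Build a named raster schedule
#'
#' @param pattern one of `"horizontal"`, `"vertical"`, `"checkerboard"`,
#'   `"random"`, `"none"`.
#' @param array electrode array.
#' @param n_groups number of timing groups.
#' @param seed seed for the random pattern.
#' @param reshuffle_every,n_epochs passed to [random_schedule()].
#' @return a `raster_schedule`, or `NULL` for `"none"`.
#' @export
make_schedule <- function(pattern, array, n_groups = 5, seed = NULL,
                          reshuffle_every = 5, n_epochs = 1) {
  switch(pattern,
    horizontal = horizontal_schedule(array, n_groups),
    vertical = vertical_schedule(array, n_groups),
    checkerboard = checkerboard_schedule(array, n_groups),
    random = random_schedule(array, n_groups, reshuffle_every, seed, n_epochs),
    none = NULL,
    stop("unknown raster pattern: ", pattern)
  )
}
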