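#' Stimulus clips
#'
#' A `stimulus_clip` is a timed sequence of 2-D intensity frames (values in
#' `[0, 1]`) defined on a square canvas measured in visual-field degrees.
#' Frames are computed on demand by [clip_frame()] so long clips stay cheap;
#' the frame count is always `round(fps * duration_s)`.
#'
#' @name stimulus_clip
NULL

.new_clip <- function(type, label, fps, duration_s, canvas_px, canvas_fov_deg,
                      params = list()) {
  n <- as.integer(round(fps * duration_s))
  if (n < 1) stop("clip must contain at least one frame")
  structure(list(type = type, label = label, fps = fps,
                 duration_s = duration_s, n_frames = n,
                 canvas_px = as.integer(canvas_px),
                 canvas_fov_deg = canvas_fov_deg, params = params,
                 cache = new.env(parent = emptyenv())),
            class = "stimulus_clip")
}

#' @export
print.stimulus_clip <- function(x, ...) {
  cat(sprintf("<stimulus_clip> %s '%s': %d frames @ %g fps, %dpx / %g deg\n",
              x$type, x$label, x$n_frames, x$fps, x$canvas_px,
              x$canvas_fov_deg))
  invisible(x)
}

# pixel-center coordinates (degrees) of a square canvas; row 1 = top (+y)
.canvas_axes <- function(npx, fov_deg) {
  step <- fov_deg / npx
  x <- (seq_len(npx) - (npx + 1) / 2) * step
  list(x = x, y = rev(x), step = step)
}

# Sloan-style 5x5 stroke-grid letter masks (stroke = 1/5 of letter height),
# rows top to bottom. The eight-letter optotype set used by the tasks.
.optotype_masks <- local({
  rows_to_mask <- function(...) {
    m <- do.call(rbind, lapply(list(...), function(s)
      as.integer(strsplit(s, "")[[1]])))
    storage.mode(m) <- "double"
    m
  }
  list(
    C = rows_to_mask("11111", "10000", "10000", "10000", "11111"),
    D = rows_to_mask("11110", "10001", "10001", "10001", "11110"),
    E = rows_to_mask("11111", "10000", "11111", "10000", "11111"),
    F = rows_to_mask("11111", "10000", "11111", "10000", "10000"),
    L = rows_to_mask("10000", "10000", "10000", "10000", "11111"),
    O = rows_to_mask("11111", "10001", "10001", "10001", "11111"),
    P = rows_to_mask("11111", "10001", "11111", "10000", "10000"),
    T = rows_to_mask("11111", "00100", "00100", "00100", "00100")
  )
})

#' The eight optotype letters
#' @return character vector `c("C","D","E","F","L","O","P","T")`.
#' @export
optotype_letters <- function() names(.optotype_masks)

#' Render a Sloan-style optotype clip
#'
#' White letter on black, built on a 5x5 stroke grid (stroke width = 1/5 of
#' the letter height), the standard construction for acuity optotypes. The
#' letter square subtends `size_deg` of visual angle, centered on the canvas.
#'
#' @param letter one of `C, D, E, F, L, O, P, T`.
#' @param size_deg letter height/width in degrees (default 41.1).
#' @param duration_s clip duration in seconds (default 5).
#' @param fps frames per second (default 90).
#' @param canvas_px canvas size in pixels (default 200).
#' @param canvas_fov_deg canvas field of view in degrees (default 60).
#' @return a static `stimulus_clip` labeled with the letter.
#' @export
render_optotype <- function(letter, size_deg = 41.1, duration_s = 5, fps = 90,
                            canvas_px = 200, canvas_fov_deg = 60) {
  if (!is.character(letter) || length(letter) != 1 ||
      !letter %in% names(.optotype_masks))
    stop("`letter` must be one of: ",
         paste(names(.optotype_masks), collapse = ", "))
  .new_clip("optotype", letter, fps, duration_s, canvas_px, canvas_fov_deg,
            params = list(size_deg = size_deg))
}

#' The eight motion directions
#' @return character vector of compass directions, clockwise from `"up"`.
#' @export
motion_directions <- function()
  c("up", "up-right", "right", "down-right", "down", "down-left", "left",
    "up-left")

.direction_vector <- function(direction) {
  u <- switch(direction,
    "up" = c(0, 1), "down" = c(0, -1), "left" = c(-1, 0), "right" = c(1, 0),
    "up-right" = c(1, 1), "up-left" = c(-1, 1),
    "down-right" = c(1, -1), "down-left" = c(-1, -1),
    stop("unknown direction: ", direction))
  u / .norm2(u)
}

#' Render a moving-bar clip
#'
#' A single full-field bar oriented perpendicular to its motion direction,
#' traversing the whole canvas over the clip duration (it starts just outside
#' one edge and exits the opposite edge).
#'
#' @param direction one of the eight compass directions
#'   ([motion_directions()]).
#' @param duration_s,fps,canvas_px,canvas_fov_deg as in [render_optotype()].
#' @param bar_width_frac bar width as a fraction of the canvas field of view
#'   (default 0.1).
#' @return a `stimulus_clip` labeled with the direction.
#' @export
render_moving_bar <- function(direction, duration_s = 5, fps = 90,
                              canvas_px = 200, canvas_fov_deg = 60,
                              bar_width_frac = 0.1) {
  if (duration_s <= 0 || fps <= 0) stop("`duration_s` and `fps` must be > 0")
  u <- .direction_vector(direction)  # validates
  .new_clip("bar", direction, fps, duration_s, canvas_px, canvas_fov_deg,
            params = list(dir = u, width_deg = bar_width_frac * canvas_fov_deg))
}

#' Wrap precomputed frames as a clip
#'
#' @param frames a list of numeric matrices in `[0, 1]` (equal dimensions) or
#'   a 3-D array with time as the third dimension.
#' @param fps frames per second.
#' @param label stimulus label.
#' @param canvas_fov_deg canvas field of view in degrees.
#' @return a `stimulus_clip`.
#' @export
frames_clip <- function(frames, fps, label = "frames", canvas_fov_deg = 60) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!length(frames)) stop("`frames` is empty")
  clip <- .new_clip("frames", label, fps, length(frames) / fps,
                    nrow(frames[[1]]), canvas_fov_deg)
  clip$params$frames <- frames
  clip
}

#' Compute one frame of a stimulus clip
#'
#' @param clip a `stimulus_clip`.
#' @param i frame index, 1-based.
#' @return numeric matrix (`canvas_px` square), values in `[0, 1]`.
#' @export
clip_frame <- function(clip, i) {
  if (i < 1 || i > clip$n_frames) stop("frame index out of range")
  switch(clip$type,
    optotype = {
      if (is.null(clip$cache$frame)) {
        ax <- .canvas_axes(clip$canvas_px, clip$canvas_fov_deg)
        h <- clip$params$size_deg / 2
        mask <- .optotype_masks[[clip$label]]
        ucell <- pmin(5L, pmax(1L, floor((ax$x + h) / clip$params$size_deg * 5) + 1L))
        vcell <- pmin(5L, pmax(1L, floor((h - ax$y) / clip$params$size_deg * 5) + 1L))
        inside_x <- abs(ax$x) <= h
        inside_y <- abs(ax$y) <= h
        f <- mask[vcell, ucell, drop = FALSE]
        f[!inside_y, ] <- 0
        f[, !inside_x] <- 0
        clip$cache$frame <- f
      }
      clip$cache$frame
    },
    bar = {
      ax <- .canvas_axes(clip$canvas_px, clip$canvas_fov_deg)
      u <- clip$params$dir
      w <- clip$params$width_deg
      reach <- clip$canvas_fov_deg / 2 * (abs(u[1]) + abs(u[2])) + w / 2
      frac <- if (clip$n_frames > 1) (i - 1) / (clip$n_frames - 1) else 0.5
      off <- -reach + frac * 2 * reach
      proj <- outer(ax$y * u[2], ax$x * u[1], "+")
      (abs(proj - off) <= w / 2) * 1
    },
    frames = clip$params$frames[[i]],
    stop("unknown clip type: ", clip$type)
  )
}

#' Preprocess a frame for the simulation pipeline
#'
#' Grayscale conversion, resize to `size` x `size` pixels, and a 3x3 unit-sum
#' Gaussian blur (sigma = 0.85 px, a binomial-like kernel) with
#' edge-replication padding, clamped to `[0, 1]`.
#'
#' @param frame numeric matrix, or array with a trailing channel dimension.
#' @param size output side length in pixels (default 200).
#' @return `size` x `size` numeric matrix in `[0, 1]`.
#' @export
preprocess_frame <- function(frame, size = 200) {
  if (is.null(frame) || !length(frame)) stop("`frame` is empty")
  if (is.array(frame) && length(dim(frame)) == 3) {
    nch <- dim(frame)[3]
    frame <- if (nch >= 3)
      0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    else frame[, , 1]
  }
  frame <- as.matrix(frame)
  if (!all(dim(frame) == c(size, size)))
    frame <- EBImage::resize(frame, w = size, h = size)
  g <- exp(-(-1:1)^2 / (2 * 0.85^2))
  k <- outer(g, g); k <- k / sum(k)
  out <- .conv3x3(frame, k)
  pmin(pmax(out, 0), 1)
}
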