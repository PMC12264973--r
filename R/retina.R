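#' Retinal coordinate system
#'
#' The package works in a single retinal coordinate frame, documented here and
#' used everywhere else:
#'
#' * Units are micrometers (um) on the retina; the fovea is at the origin.
#' * Positive x is nasal, positive y is superior, for a right eye. The optic
#'   disc therefore sits in the (+x, +y) quadrant.
#' * The horizontal raphe is the half-line `{y = 0, x < 0}` (temporal of the
#'   fovea). Axon paths never cross it.
#' * Visual-field degrees map to retinal um by a single linear constant
#'   (`um_per_degree`, default 280). The retina-to-field image inversion is
#'   absorbed into this convention: percepts are rendered on the same axes the
#'   stimulus uses, so x/y here can be read directly as field coordinates.
#' * Percept fields and image frames are stored as matrices with row 1 at the
#'   top (largest y), matching image conventions.
#'
#' @param um_per_degree linear scale between visual-field degrees and retinal
#'   micrometers (um/deg). Default 280 um/deg, a standard human value.
#' @param extent_deg half-extent of the percept grid per axis, in degrees.
#'   The grid spans `[-extent_deg, +extent_deg]` on both axes.
#' @param step_deg percept grid sampling step in degrees per sample.
#' @param eye `"right"` or `"left"`. Left eyes mirror the optic-disc x
#'   position.
#' @return An object of class `retina_spec`.
#' @export
retina_spec <- function(um_per_degree = 280, extent_deg = 12,
                        step_deg = 0.25, eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (um_per_degree <= 0) stop("`um_per_degree` must be > 0")
  if (step_deg <= 0) stop("`step_deg` must be > 0")
  if (extent_deg <= 0) stop("`extent_deg` must be > 0")
  x_deg <- seq(-extent_deg, extent_deg, by = step_deg)
  structure(list(
    um_per_degree = um_per_degree,
    extent_deg = extent_deg,
    step_deg = step_deg,
    eye = eye,
    grid_x_deg = x_deg,
    grid_y_deg = rev(x_deg)  # row 1 = top = +y
  ), class = "retina_spec")
}

#' Convert visual-field degrees to retinal micrometers (and back)
#'
#' @param v value(s) in degrees (`deg_to_um`) or um (`um_to_deg`).
#' @param spec a [retina_spec()].
#' @return numeric vector, linearly rescaled.
#' @export
deg_to_um <- function(v, spec) v * spec$um_per_degree

#' @rdname deg_to_um
#' @export
um_to_deg <- function(v, spec) v / spec$um_per_degree

#' Build a regular epiretinal electrode array
#'
#' Places `rows x cols` electrodes on a regular grid with the given pitch,
#' centered at `center_um`. Row index 0 is the top (most superior) row,
#' column index 0 the leftmost (most temporal, right eye) column.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param pitch_um center-to-center electrode spacing in um (> 0).
#' @param center_um length-2 numeric, array center (x, y) in retinal um.
#' @return An object of class `electrode_array`: a data.frame with columns
#'   `electrode_id`, `row`, `col`, `x_um`, `y_um`, plus attributes `rows`,
#'   `cols`, `pitch_um`, `center_um`.
#' @examples
#' arr <- build_electrode_array(10, 10, 400)
#' nrow(arr)  # 100
#' @export
build_electrode_array <- function(rows, cols, pitch_um, center_um = c(0, 0)) {
  if (length(rows) != 1 || length(cols) != 1 || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("`rows` and `cols` must be positive integers")
  if (length(pitch_um) != 1 || pitch_um <= 0)
    stop("`pitch_um` must be a positive scalar")
  idx <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  idx <- idx[order(idx$row, idx$col), , drop = FALSE]
  x <- (idx$col - (cols - 1) / 2) * pitch_um + center_um[1]
  y <- ((rows - 1) / 2 - idx$row) * pitch_um + center_um[2]
  # Argus-style labels: letter = row, number = column
  lab <- paste0(LETTERS[(idx$row %% 26) + 1L],
                ifelse(idx$row >= 26, idx$row %/% 26, ""), idx$col + 1L)
  out <- data.frame(electrode_id = lab, row = idx$row, col = idx$col,
                    x_um = x, y_um = y, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, rows = as.integer(rows), cols = as.integer(cols),
            pitch_um = pitch_um, center_um = center_um,
            class = c("electrode_array", "data.frame"))
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d x %d, pitch %g um, center (%g, %g) um\n",
              attr(x, "rows"), attr(x, "cols"), attr(x, "pitch_um"),
              attr(x, "center_um")[1], attr(x, "center_um")[2]))
  invisible(x)
}

# ---- axon map ---------------------------------------------------------------

# Spiral axon-bundle family, in optic-disc-centered polar coordinates.
# phi is the position angle around the disc, measured from the temporal
# direction (pointing from the disc across the fovea); phi > 0 superior.
# A bundle emitted at angle phi0 follows
#   phi(r) = phi0 + sign(phi0) * beta(phi0) * ((r - r0) / 10)^c
# with beta(phi0) = 15 * sin(|phi0|) degrees and c = 1.7, so bundles curve
# away from the horizontal raphe as they run outward; near-horizontal and
# nasal bundles are nearly straight. Versioned so cached maps stay valid.
.axon_family_version <- "spiral-1"

.axon_path_deg <- function(phi0, disc_deg, r0_deg, r_max_deg, step_deg) {
  r <- seq(r0_deg, r_max_deg, by = step_deg)
  beta <- 15 * sin(abs(phi0) * pi / 180)
  phi <- phi0 + sign(phi0) * beta * ((r - r0_deg) / 10)^1.7
  phi_rad <- phi * pi / 180
  cbind(x = disc_deg[1] - r * cos(phi_rad),
        y = disc_deg[2] + r * sin(phi_rad))
}

# Truncate a disc-to-terminal polyline (rows ordered disc -> outward) just
# before its first segment crossing of the temporal raphe {y = 0, x < 0}.
.truncate_at_raphe <- function(p) {
  n <- nrow(p)
  if (n < 2) return(p)
  y1 <- p[-n, 2]; y2 <- p[-1, 2]
  cross <- (y1 > 0 & y2 <= 0) | (y1 < 0 & y2 >= 0) | (y1 == 0 & y2 != 0)
  if (!any(cross)) return(p)
  tt <- ifelse(y2 == y1, 0, -y1 / (y2 - y1))
  xc <- p[-n, 1] + tt * (p[-1, 1] - p[-n, 1])
  bad <- which(cross & xc < 0)
  if (!length(bad)) return(p)
  p[seq_len(bad[1]), , drop = FALSE]
}

#' Build a discretized retinal-axon map
#'
#' Generates a family of retinal ganglion cell axon bundles emanating from the
#' optic disc and arcing around the horizontal raphe, discretizes them at
#' `step_um`, and assigns every percept-grid sample to its nearest bundle
#' point. The bundle trajectories follow a documented spiral family in
#' disc-centered polar coordinates (see the methods vignette); any bundle that
#' would cross the temporal raphe is truncated just before the crossing, so
#' the no-crossing invariant holds by construction.
#'
#' Each stored path is a matrix of points ordered from the peripheral terminal
#' toward the disc, with strictly increasing cumulative arc length measured
#' from the terminal.
#'
#' @param spec a [retina_spec()].
#' @param n_axons number of bundles (>= 2). Default 500.
#' @param step_um discretization step along each bundle, um (> 0, <= 50
#'   recommended). Default 50.
#' @param disc_deg optic-disc center in degrees (x nasal, y superior);
#'   default `c(15, 2)`. Mirrored in x for a left eye.
#' @return An object of class `axon_map`: paths, percept grid, and the
#'   per-sample nearest-path assignment.
#' @export
build_axon_map <- function(spec, n_axons = 500, step_um = 50,
                           disc_deg = c(15, 2)) {
  if (!inherits(spec, "retina_spec")) stop("`spec` must be a retina_spec")
  if (n_axons < 2) stop("`n_axons` must be >= 2")
  if (step_um <= 0) stop("`step_um` must be > 0")
  if (spec$eye == "left") disc_deg[1] <- -disc_deg[1]

  step_deg <- step_um / spec$um_per_degree
  r0_deg <- 2   # disc edge
  # far enough that every grid sample has a bundle running past it
  r_max_deg <- sqrt(sum((abs(disc_deg) + spec$extent_deg)^2)) + 3

  phi0 <- seq(-180, 180, length.out = n_axons + 1L)[-1L]
  phi0[phi0 == 0] <- 1e-6  # keep sign() well-defined on the horizontal bundle

  paths <- vector("list", n_axons)
  for (k in seq_len(n_axons)) {
    p_deg <- .axon_path_deg(phi0[k], disc_deg, r0_deg, r_max_deg, step_deg)
    p_deg <- .truncate_at_raphe(p_deg)
    p_um <- p_deg * spec$um_per_degree
    n <- nrow(p_um)
    # reorder terminal -> disc; arc length from the terminal
    p_um <- p_um[n:1, , drop = FALSE]
    seg <- sqrt(rowSums((p_um[-1, , drop = FALSE] -
                           p_um[-n, , drop = FALSE])^2))
    paths[[k]] <- cbind(x_um = p_um[, 1], y_um = p_um[, 2],
                        arc_um = c(0, cumsum(seg)))
  }

  # nearest-bundle-point assignment over the percept grid (brute force over
  # points inside the working window, chunked to bound memory)
  margin_deg <- 2
  win <- (spec$extent_deg + margin_deg) * spec$um_per_degree
  pt_path <- rep.int(seq_len(n_axons), vapply(paths, nrow, 1L))
  pt_row <- unlist(lapply(paths, function(p) seq_len(nrow(p))), use.names = FALSE)
  pts <- do.call(rbind, lapply(paths, function(p) p[, 1:2, drop = FALSE]))
  keep <- abs(pts[, 1]) <= win & abs(pts[, 2]) <= win
  if (!any(keep)) stop("percept grid and axon family do not overlap; check extents")
  pts <- pts[keep, , drop = FALSE]
  pt_path <- pt_path[keep]; pt_row <- pt_row[keep]

  gx <- spec$grid_x_deg * spec$um_per_degree
  gy <- spec$grid_y_deg * spec$um_per_degree
  g <- cbind(x = rep(gx, each = length(gy)), y = rep(gy, times = length(gx)))
  npx <- nrow(g)
  assign_idx <- integer(npx)
  assign_d2 <- numeric(npx)
  chunk <- max(1L, floor(4e6 / nrow(pts)))
  p2 <- rowSums(pts^2)
  for (s in seq(1L, npx, by = chunk)) {
    e <- min(npx, s + chunk - 1L)
    gc_ <- g[s:e, , drop = FALSE]
    # squared distances via the expansion |g - p|^2 = |g|^2 - 2 g.p + |p|^2
    d2 <- outer(rowSums(gc_^2), p2, "+") - 2 * gc_ %*% t(pts)
    j <- max.col(-d2, ties.method = "first")
    assign_idx[s:e] <- j
    assign_d2[s:e] <- d2[cbind(seq_len(e - s + 1L), j)]
  }

  structure(list(
    spec = spec, n_axons = n_axons, step_um = step_um, disc_deg = disc_deg,
    family = .axon_family_version, phi0 = phi0, paths = paths,
    grid_x_deg = spec$grid_x_deg, grid_y_deg = spec$grid_y_deg,
    grid_um = g,
    assign_path = pt_path[assign_idx],
    assign_point = pt_row[assign_idx],
    assign_dist_um = sqrt(pmax(assign_d2, 0))
  ), class = "axon_map")
}

#' @export
print.axon_map <- function(x, ...) {
  cat(sprintf(
    "<axon_map> %d bundles (%s), step %g um, disc (%g, %g) deg, grid %dx%d\n",
    x$n_axons, x$family, x$step_um, x$disc_deg[1], x$disc_deg[2],
    length(x$grid_y_deg), length(x$grid_x_deg)))
  invisible(x)
}

#' Content hash of an axon map's defining parameters
#'
#' Used as a cache key when persisting axon maps to disk: two maps with equal
#' keys are bit-identical by construction (the build is deterministic).
#'
#' @param axons an `axon_map`.
#' @return a character scalar.
#' @export
axon_map_key <- function(axons) {
  s <- axons$spec
  paste(axons$family, s$um_per_degree, s$extent_deg, s$step_deg, s$eye,
        axons$n_axons, axons$step_um, axons$disc_deg[1], axons$disc_deg[2],
        sep = "_")
}
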