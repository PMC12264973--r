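#' Electrode activation from a processed frame
#'
#' Implements the camera-to-electrode step: each electrode takes the
#' intensity of the single pixel nearest its visual-field position (the frame
#' has already been Gaussian-smoothed by [preprocess_frame()], so this pixel
#' carries a local average). Electrodes outside the current raster group get
#' amplitude exactly 0, as do electrodes mapping outside the frame.
#'
#' @param frame processed frame (square matrix in `[0, 1]`).
#' @param array electrode array.
#' @param active integer indices (rows of `array`) of the currently active
#'   raster group.
#' @param spec a [retina_spec()] (for the um-to-degree conversion).
#' @param fov_deg the frame's field of view in degrees (default 60).
#' @return named numeric vector of per-electrode amplitudes in `[0, 1]`
#'   (names = electrode ids).
#' @export
electrode_activation <- function(frame, array, active, spec, fov_deg = 60) {
  n_elec <- nrow(array)
  a <- stats::setNames(numeric(n_elec), array$electrode_id)
  if (!length(active)) return(a)
  npx_c <- ncol(frame); npx_r <- nrow(frame)
  x_deg <- um_to_deg(array$x_um[active], spec)
  y_deg <- um_to_deg(array$y_um[active], spec)
  cc <- as.integer(round(x_deg / (fov_deg / npx_c) + (npx_c + 1) / 2))
  rr <- as.integer(round((npx_r + 1) / 2 - y_deg / (fov_deg / npx_r)))
  ok <- cc >= 1 & cc <= npx_c & rr >= 1 & rr <= npx_r
  a[active[ok]] <- frame[cbind(rr[ok], cc[ok])]
  a
}

#' Axon-map phosphene parameters
#'
#' @param rho radial spread of the phosphene around an electrode, um (> 0).
#'   Default 300, a realistic value for current epiretinal devices.
#' @param lam axonal elongation scale along the stimulated bundle, um (> 0).
#'   Default 1000.
#' @return list of class `axon_map_params`.
#' @export
axon_map_params <- function(rho = 300, lam = 1000) {
  if (rho <= 0 || lam <= 0) stop("`rho` and `lam` must be > 0")
  structure(list(rho = rho, lam = lam), class = "axon_map_params")
}

#' Precompute the spatial-model basis
#'
#' The axon-map brightness of percept sample `(r, theta)` is
#' `b_I = max over points p on the sample's axon path of
#' sum_e a_e * exp(-d_e^2 / (2 rho^2)) * exp(-d_soma^2 / (2 lambda^2))`,
#' where `d_e` is the distance from `p` to electrode `e` and `d_soma` the arc
#' length from `p` back to the cell body at the sample. Because the max sits
#' outside the electrode sum, per-electrode percepts cannot be precomputed
#' and summed; instead this basis precomputes, once per
#' (array, axon map, rho, lambda):
#'
#' * the electrode-distance Gaussians for every needed path point and for
#'   every percept sample itself (the sample is its own path start, with
#'   `d_soma = 0`; the path then joins the nearest discretized bundle point,
#'   the joining distance counting toward arc length), and
#' * the per-sample arc-length weights `exp(-d_soma^2 / (2 lambda^2))`.
#'
#' [spatial_percept()] then evaluates each frame as a max of weighted sums.
#'
#' @param array electrode array.
#' @param axons an [build_axon_map()] result (same retina spec).
#' @param params an [axon_map_params()].
#' @return an object of class `phosphene_basis`.
#' @export
phosphene_basis <- function(array, axons, params) {
  if (!inherits(axons, "axon_map")) stop("`axons` must be an axon_map")
  if (!inherits(params, "axon_map_params")) params <- do.call(axon_map_params, params)
  npx <- nrow(axons$grid_um)
  n_elec <- nrow(array)

  # union of needed path-point rows: for each path, from the smallest
  # assigned point index out to the disc end
  used <- split(axons$assign_point, axons$assign_path)
  first_used <- rep(NA_integer_, axons$n_axons)
  first_used[as.integer(names(used))] <- vapply(used, min, 1L)
  offs <- integer(axons$n_axons)
  tab_xy <- vector("list", axons$n_axons)
  tab_arc <- vector("list", axons$n_axons)
  cur <- 0L
  for (k in seq_len(axons$n_axons)) {
    if (is.na(first_used[k])) next
    p <- axons$paths[[k]]
    rows <- first_used[k]:nrow(p)
    offs[k] <- cur
    tab_xy[[k]] <- p[rows, 1:2, drop = FALSE]
    tab_arc[[k]] <- p[rows, 3]
    cur <- cur + length(rows)
  }
  tab_xy <- do.call(rbind, tab_xy)
  tab_arc <- unlist(tab_arc, use.names = FALSE)

  # per-sample tails into the unified point table (samples first, then paths)
  tail_len <- vapply(seq_len(npx), function(i) {
    nrow(axons$paths[[axons$assign_path[i]]]) - axons$assign_point[i] + 1L
  }, 1L)
  width <- 1L + max(tail_len)
  IDX <- matrix(1L, npx, width)   # padding points at row 1 with weight 0
  W <- matrix(0, npx, width)
  IDX[, 1] <- seq_len(npx)
  W[, 1] <- 1
  inv2lam2 <- 1 / (2 * params$lam^2)
  for (i in seq_len(npx)) {
    k <- axons$assign_path[i]
    j <- axons$assign_point[i]
    L <- tail_len[i]
    glob <- npx + offs[k] + (j - first_used[k]) + seq_len(L)
    arc0 <- axons$paths[[k]][j, 3]
    d_soma <- axons$assign_dist_um[i] + (tab_arc[glob - npx] - arc0)
    IDX[i, 1 + seq_len(L)] <- glob
    W[i, 1 + seq_len(L)] <- exp(-d_soma^2 * inv2lam2)
  }

  # electrode-distance Gaussians for all points (samples + path points)
  allpts <- rbind(axons$grid_um, tab_xy)
  ex <- array$x_um; ey <- array$y_um
  inv2rho2 <- 1 / (2 * params$rho^2)
  d2 <- outer(rowSums(allpts^2), ex^2 + ey^2, "+") -
    2 * allpts %*% rbind(ex, ey)
  S <- exp(-d2 * inv2rho2)

  structure(list(
    params = params, n_elec = n_elec, npx = npx,
    ny = length(axons$grid_y_deg), nx = length(axons$grid_x_deg),
    grid_x_deg = axons$grid_x_deg, grid_y_deg = axons$grid_y_deg,
    electrode_id = array$electrode_id,
    S = S, IDX = IDX, W = W,
    axon_key = axon_map_key(axons)
  ), class = "phosphene_basis")
}

#' Instantaneous spatial percept (axon-map model)
#'
#' Evaluates the axon-map brightness field for one activation vector: a
#' maximum over each sample's axon path of the amplitude-weighted sum of
#' electrode Gaussians (see [phosphene_basis()] for the equation). The max
#' over the path is what produces elongated, comet-like phosphenes and the
#' nonlinear (non-additive) interaction between co-active electrodes.
#'
#' @param act named amplitude vector from [electrode_activation()].
#' @param basis a [phosphene_basis()] (electrode ids must match), or pass
#'   `array`, `axons`, `params` to build one on the fly.
#' @param array,axons,params used only when `basis` is `NULL`.
#' @return `BrightnessField`: an `ny x nx` non-negative matrix (row 1 = top)
#'   with attributes `x_deg`, `y_deg`.
#' @export
spatial_percept <- function(act, basis = NULL, array = NULL, axons = NULL,
                            params = NULL) {
  if (is.null(basis)) basis <- phosphene_basis(array, axons, params)
  if (length(act) != basis$n_elec)
    stop("activation length does not match the basis electrode count")
  if (!is.null(names(act)) && !identical(names(act), basis$electrode_id))
    stop("activation electrode ids do not match the basis")
  on <- which(act > 0)
  if (!length(on)) {
    field <- matrix(0, basis$ny, basis$nx)
  } else {
    u <- as.vector(basis$S[, on, drop = FALSE] %*% act[on])
    acc <- u[basis$IDX[, 1]] * basis$W[, 1]
    for (cc in 2:ncol(basis$IDX))
      acc <- pmax(acc, u[basis$IDX[, cc]] * basis$W[, cc])
    field <- matrix(acc, basis$ny, basis$nx)
  }
  structure(field, x_deg = basis$grid_x_deg, y_deg = basis$grid_y_deg)
}

#' Temporal-model parameters (coupled leaky integrators)
#'
#' The temporal model is the pair of coupled leaky integrators
#' `dn/dt = -tau_n * n + b_I` (neural desensitization) and
#' `db/dt = -tau_b * b - alpha * n + b_I` (perceived brightness), with `b`
#' clamped to be non-negative after each step. `tau_n`, `tau_b` are decay
#' rate coefficients (1/s) exactly as they appear in the equations; `alpha`
#' couples accumulated desensitization into brightness, producing fading
#' under sustained stimulation.
#'
#' Two named presets are provided, fitted for 5 Hz and 20 Hz stimulation:
#' `"5Hz"` = (0.2, 5, 0.2) and `"20Hz"` = (0.2, 5, 0.25).
#'
#' @param preset `"5Hz"` or `"20Hz"`; or pass the three coefficients.
#' @param tau_n,tau_b,alpha coefficients (all >= 0), overriding the preset.
#' @return list of class `temporal_params`.
#' @export
temporal_params <- function(preset = c("5Hz", "20Hz"), tau_n = NULL,
                            tau_b = NULL, alpha = NULL) {
  if (is.null(tau_n) || is.null(tau_b) || is.null(alpha)) {
    preset <- match.arg(preset)
    p <- switch(preset, "5Hz" = c(0.2, 5, 0.2), "20Hz" = c(0.2, 5, 0.25))
    if (is.null(tau_n)) tau_n <- p[1]
    if (is.null(tau_b)) tau_b <- p[2]
    if (is.null(alpha)) alpha <- p[3]
  }
  if (tau_n < 0 || tau_b < 0 || alpha < 0)
    stop("temporal coefficients must be >= 0")
  structure(list(tau_n = tau_n, tau_b = tau_b, alpha = alpha),
            class = "temporal_params")
}

#' One forward-Euler step of the temporal model
#'
#' @param state list with numeric `n` and `b` (any matching shapes), or
#'   `NULL` for the zero state.
#' @param b_I instantaneous brightness input (same shape).
#' @param params a [temporal_params()].
#' @param dt time step in seconds (> 0; default 1/90, the render period).
#' @return updated state list.
#' @export
temporal_step <- function(state, b_I, params, dt = 1 / 90) {
  if (dt <= 0) stop("`dt` must be > 0")
  if (is.null(state)) state <- list(n = b_I * 0, b = b_I * 0)
  n_new <- state$n + dt * (-params$tau_n * state$n + b_I)
  b_new <- state$b + dt * (-params$tau_b * state$b - params$alpha * state$n + b_I)
  list(n = n_new, b = pmax(b_new, 0))
}

#' Integrate the temporal model over a brightness sequence
#'
#' Forward-Euler integration of the coupled leaky integrators over a sequence
#' of instantaneous-brightness fields, with the non-negativity clamp applied
#' to `b` after every step.
#'
#' @param b_I_series a 3-D array with time as the third dimension, a matrix
#'   with time in columns (one row per pixel), or a list of equal-shape
#'   fields.
#' @param params a [temporal_params()].
#' @param dt time step in seconds (default 1/90).
#' @param state0 optional initial state (as in [temporal_step()]).
#' @return perceived-brightness sequence, same container shape as the input,
#'   with the final state attached as attribute `"state"`.
#' @export
integrate_temporal <- function(b_I_series, params, dt = 1 / 90,
                               state0 = NULL) {
  if (dt <= 0) stop("`dt` must be > 0")
  as_list <- is.list(b_I_series)
  if (as_list) {
    frames <- b_I_series
  } else if (is.array(b_I_series) && length(dim(b_I_series)) == 3) {
    frames <- lapply(seq_len(dim(b_I_series)[3]), function(i) b_I_series[, , i])
  } else {
    m <- as.matrix(b_I_series)
    frames <- lapply(seq_len(ncol(m)), function(i) m[, i])
  }
  state <- state0
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    state <- temporal_step(state, frames[[i]], params, dt)
    out[[i]] <- state$b
  }
  res <- if (as_list) out
  else if (is.array(b_I_series) && length(dim(b_I_series)) == 3)
    array(unlist(out, use.names = FALSE), dim = dim(b_I_series))
  else do.call(cbind, out)
  attr(res, "state") <- state
  res
}
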