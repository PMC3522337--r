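#' Active-contour (snake) parameters
#'
#' Controls the per-slice parametric snake used by [segment_lungs()].  The
#' contour minimizes the discrete energy
#' \deqn{E = \sum_i \alpha \|x_{i+1}-x_i\|^2 + \beta \|x_{i+1}-2x_i+x_{i-1}\|^2
#'       - \kappa \sum_i M(x_i),}
#' where \eqn{M = |\nabla (G_\sigma * I)|^2} is the squared gradient magnitude
#' of the Gaussian-smoothed slice: the internal terms penalise stretch and
#' curvature, the external term attracts the contour to intensity edges.
#' Evolution combines an implicit (semi-implicit banded solve) internal step
#' with an explicit external-force step, with backtracking on the step size so
#' the total energy never increases.
#'
#' @param alpha elasticity (stretch) weight, >= 0.
#' @param beta curvature (rigidity) weight, >= 0.
#' @param gamma evolution step size, > 0.
#' @param kappa_ext external (image force) weight, >= 0.
#' @param sigma Gaussian smoothing bandwidth for the edge map, pixels.
#' @param max_iter maximum number of iterations, >= 1.
#' @param conv_tol mean point displacement (pixels) below which evolution
#'   stops.
#' @param min_area minimum physical contour area in mm^2; smaller seed
#'   components are discarded and a contour shrinking below it during
#'   evolution raises a collapse error.
#' @return an object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.1, gamma = 1.0,
                         kappa_ext = 2.0, sigma = 2, max_iter = 500L,
                         conv_tol = 0.1, min_area = 50) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, kappa_ext = kappa_ext,
            sigma = sigma, max_iter = as.integer(max_iter),
            conv_tol = conv_tol, min_area = min_area)
  if (any(!is.finite(unlist(p[c("alpha", "beta", "gamma", "kappa_ext")]))))
    abort("snake weights must be finite", "airtrapcad_parameter_error")
  if (p$alpha < 0 || p$beta < 0 || p$kappa_ext < 0)
    abort("alpha, beta and kappa_ext must be >= 0", "airtrapcad_parameter_error")
  if (p$gamma <= 0)
    abort("gamma must be > 0", "airtrapcad_parameter_error")
  if (p$max_iter < 1L)
    abort("max_iter must be >= 1", "airtrapcad_parameter_error")
  structure(p, class = "snake_params")
}

# Label sub-threshold (air) components of a slice, discarding any component
# touching the image border (background air outside the body).
#' @noRd
label_air_components <- function(slice_hu, air_threshold) {
  bin <- matrix(as.numeric(slice_hu < air_threshold),
                nrow(slice_hu), ncol(slice_hu))
  lab <- EBImage::bwlabel(bin)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) lab[lab %in% border] <- 0
  lab
}

# Resample a closed polyline to n points, uniform in arc length.
#' @noRd
resample_contour <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(matrix(rep(pts[1, ], each = n), n, 2))
  t_new <- seq(0, total, length.out = n + 1)[seq_len(n)]
  r <- approx(cum, closed[, 1], xout = t_new)$y
  c_ <- approx(cum, closed[, 2], xout = t_new)$y
  cbind(r, c_, deparse.level = 0)
}

# Signed polygon area (shoelace) in pixel^2; orientation-independent abs().
#' @noRd
contour_area_px <- function(pts) {
  r <- pts[, 1]; c_ <- pts[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c_[-1], c_[1])
  abs(sum(r * c2 - r2 * c_)) / 2
}

#' Seed initial lung contours on a slice
#'
#' Thresholds the slice at `air_threshold`, keeps connected low-density
#' components fully inside the body envelope (components touching the image
#' border are background air and are excluded), discards components below
#' `min_area` mm^2, and returns the traced boundary of each kept component as
#' an initial contour.
#'
#' @param slice_hu 2-D matrix of Hounsfield units (row, col).
#' @param air_threshold HU threshold below which a voxel counts as air.
#' @param spacing in-plane spacing `c(dy, dx)` in mm.
#' @param min_area minimum physical component area, mm^2.
#' @return a list of contours, each an `n x 2` matrix of (row, col) positions
#'   (sub-pixel precision, >= 8 points); empty list when no candidate exists.
#' @export
seed_contours <- function(slice_hu, air_threshold = -320, spacing = c(1, 1),
                          min_area = 50) {
  lab <- label_air_components(slice_hu, air_threshold)
  if (max(lab) == 0) return(list())
  px_area <- prod(spacing)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * px_area >= min_area)
  if (!length(keep)) return(list())
  out <- list()
  for (k in keep) {
    oc <- EBImage::ocontour(matrix(as.numeric(lab == k), nrow(lab), ncol(lab)))
    pts <- oc[[1]] + 1           # ocontour is 0-based (row, col)
    n <- max(16L, min(200L, as.integer(round(nrow(pts) / 2))))
    out[[length(out) + 1L]] <- resample_contour(pts, n)
  }
  out
}

# Precompute the external force fields for a slice: the edge map
# M = |grad(G_sigma * I)|^2 and its partial derivatives.
#' @noRd
snake_forces <- function(slice_hu, sigma) {
  sm <- if (sigma > 0) EBImage::gblur(slice_hu, sigma = sigma) else slice_hu
  grad_r <- sm * 0; grad_c <- sm * 0
  nr <- nrow(sm); nc <- ncol(sm)
  grad_r[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  grad_c[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  edge <- grad_r^2 + grad_c^2
  # normalize to [0, 1] so kappa_ext is independent of the intensity scale
  if (max(edge) > 0) edge <- edge / max(edge)
  f_r <- edge * 0; f_c <- edge * 0
  f_r[2:(nr - 1), ] <- (edge[3:nr, ] - edge[1:(nr - 2), ]) / 2
  f_c[, 2:(nc - 1)] <- (edge[, 3:nc] - edge[, 1:(nc - 2)]) / 2
  list(edge = edge, f_r = f_r, f_c = f_c)
}

# Cyclic pentadiagonal internal-energy matrix for n points.
#' @noRd
snake_internal_matrix <- function(n, alpha, beta) {
  A <- matrix(0, n, n)
  a <- beta
  b <- -alpha - 4 * beta
  c0 <- 2 * alpha + 6 * beta
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, idx(i - 2)] <- A[i, idx(i - 2)] + a
    A[i, idx(i - 1)] <- A[i, idx(i - 1)] + b
    A[i, i] <- A[i, i] + c0
    A[i, idx(i + 1)] <- A[i, idx(i + 1)] + b
    A[i, idx(i + 2)] <- A[i, idx(i + 2)] + a
  }
  A
}

# Discrete snake energy of a contour.
#' @noRd
snake_energy <- function(pts, edge, alpha, beta, kappa) {
  closed <- rbind(pts, pts[1:2, , drop = FALSE])
  d1 <- diff(closed)[seq_len(nrow(pts)), , drop = FALSE]
  d2 <- diff(closed, differences = 2)[seq_len(nrow(pts)), , drop = FALSE]
  alpha * sum(d1^2) + beta * sum(d2^2) -
    kappa * sum(bilinear(edge, pts[, 1], pts[, 2]))
}

#' Evolve a snake on a slice
#'
#' Iteratively minimizes the contour energy (see [snake_params()]) with a
#' semi-implicit update: the internal (stretch + curvature) force is applied
#' implicitly through a banded linear solve, the external image force
#' explicitly.  The step is backtracked (halved) whenever it would increase
#' the total energy, so the energy trace is non-increasing; evolution stops
#' when the mean point displacement drops below `conv_tol` or after
#' `max_iter` iterations.
#'
#' @param slice_hu 2-D matrix of Hounsfield units.
#' @param c0 initial contour, an `n x 2` matrix of (row, col) with n >= 8.
#' @param p a [snake_params()].
#' @param spacing in-plane spacing `c(dy, dx)` mm (for the collapse check).
#' @param forces optional precomputed [snake_forces()] for this slice (reused
#'   by [segment_lungs()] across contours on the same slice).
#' @return the evolved contour with attributes `iterations` and `energy`
#'   (per-iteration energy trace, non-increasing).
#' @export
evolve_snake <- function(slice_hu, c0, p = snake_params(), spacing = c(1, 1),
                         forces = NULL) {
  if (!inherits(p, "snake_params")) abort("p must be snake_params",
                                          "airtrapcad_parameter_error")
  if (!is.matrix(c0) || ncol(c0) != 2 || nrow(c0) < 8)
    abort("initial contour must be an n x 2 matrix with n >= 8",
          "airtrapcad_input_error")
  if (any(!is.finite(slice_hu)))
    abort("slice contains non-finite values", "airtrapcad_input_error")
  if (is.null(forces)) forces <- snake_forces(slice_hu, p$sigma)
  n <- nrow(c0)
  px_area <- prod(spacing)
  solv <- new.env(parent = emptyenv())   # cache of (I + g A)^-1 per step size
  inv_for <- function(g) {
    key <- format(g, digits = 17)
    if (is.null(solv[[key]]))
      solv[[key]] <- solve(diag(n) + g * snake_internal_matrix(n, p$alpha, p$beta))
    solv[[key]]
  }
  x <- c0
  energy <- snake_energy(x, forces$edge, p$alpha, p$beta, p$kappa_ext)
  trace <- energy
  iterations <- 0L
  for (it in seq_len(p$max_iter)) {
    fr <- p$kappa_ext * bilinear(forces$f_r, x[, 1], x[, 2])
    fc <- p$kappa_ext * bilinear(forces$f_c, x[, 1], x[, 2])
    g <- p$gamma
    accepted <- FALSE
    for (try in 1:12) {
      xn <- inv_for(g) %*% (x + g * cbind(fr, fc))
      en <- snake_energy(xn, forces$edge, p$alpha, p$beta, p$kappa_ext)
      if (en <= energy + 1e-9) { accepted <- TRUE; break }
      g <- g / 2
    }
    if (!accepted) break                   # no descent step available: done
    disp <- mean(sqrt(rowSums((xn - x)^2)))
    x <- xn
    energy <- en
    trace <- c(trace, energy)
    iterations <- it
    if (contour_area_px(x) * px_area < p$min_area)
      abort(sprintf("contour collapsed below %g mm^2 after %d iterations",
                    p$min_area, it),
            "airtrapcad_collapse_error")
    if (disp < p$conv_tol) break
  }
  attr(x, "iterations") <- iterations
  attr(x, "energy") <- trace
  x
}

# Rasterize a closed contour to a binary matrix (even-odd scanline fill at
# pixel centres).
#' @noRd
rasterize_contour <- function(pts, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  r1 <- pts[, 1]; c1 <- pts[, 2]
  r2 <- c(r1[-1], r1[1]); c2 <- c(c1[-1], c1[1])
  for (row in max(1L, ceiling(min(r1))):min(nr, floor(max(r1)))) {
    cross <- ((r1 > row) != (r2 > row))
    if (!any(cross)) next
    xc <- c1[cross] + (row - r1[cross]) * (c2[cross] - c1[cross]) /
      (r2[cross] - r1[cross])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[k]); hi <- floor(xc[k + 1])
      if (hi >= lo) out[row, max(1L, lo):min(nc, hi)] <- TRUE
    }
  }
  out
}

#' Segment the lungs of a CT volume
#'
#' Per axial slice: seeds contours from air-density thresholding
#' ([seed_contours()]), evolves each with the snake ([evolve_snake()]), and
#' rasterizes the final contours into a binary mask.  The conducting-airway
#' lumen (trachea and main bronchi, as tracked by [track_trachea()]) is then
#' subtracted from the mask - dilated by one in-plane voxel so no boundary
#' ring survives - because parenchymal air trapping, not the airway, is the
#' quantity of interest.  Left and right lungs are evolved as separate
#' contours and merged; `per_lung = TRUE` labels voxels 1/2 by side instead.
#'
#' @param v a [ct_volume()].
#' @param p a [snake_params()].
#' @param air_threshold seeding threshold, HU.
#' @param exclude_airway subtract the tracked airway lumen (skipped with a
#'   warning if tracking fails, e.g. on airway-free phantoms).
#' @param airway_track optional precomputed [track_trachea()] result.
#' @param per_lung label voxels by lung side (1 = left of the slice midline,
#'   2 = right) instead of a single binary label.
#' @return a [lung_mask()] aligned with `v`.
#' @export
segment_lungs <- function(v, p = snake_params(), air_threshold = -320,
                          exclude_airway = TRUE, airway_track = NULL,
                          per_lung = FALSE) {
  if (!inherits(v, "ct_volume")) abort("v must be a ct_volume",
                                       "airtrapcad_input_error")
  d <- dim(v$voxels)
  mask <- array(0L, d)
  sp2 <- v$spacing[2:3]
  found <- FALSE
  for (s in seq_len(d[1])) {
    slice <- v$voxels[s, , ]
    seeds <- seed_contours(slice, air_threshold, sp2, p$min_area)
    if (!length(seeds)) next
    forces <- snake_forces(slice, p$sigma)
    sl_mask <- matrix(FALSE, d[2], d[3])
    mid <- (d[3] + 1) / 2
    for (ct in seeds) {
      ev <- tryCatch(evolve_snake(slice, ct, p, sp2, forces),
                     airtrapcad_collapse_error = function(e) {
                       warning(sprintf("slice %d: %s (contour dropped)", s,
                                       conditionMessage(e)), call. = FALSE)
                       NULL
                     })
      if (is.null(ev)) next
      ras <- rasterize_contour(ev, d[2], d[3])
      if (per_lung) {
        side <- if (mean(ev[, 2]) < mid) 1L else 2L
        sl_lab <- mask[s, , ]
        sl_lab[ras] <- side
        mask[s, , ] <- sl_lab
      } else sl_mask <- sl_mask | ras
    }
    if (!per_lung) mask[s, , ] <- as.integer(sl_mask)
    if (any(mask[s, , ] > 0)) found <- TRUE
  }
  if (!found)
    abort("no lung component found in any slice", "airtrapcad_segmentation_error")
  if (exclude_airway) {
    track <- airway_track
    if (is.null(track))
      track <- tryCatch(track_trachea(v, air_threshold),
                        airtrapcad_tracking_error = function(e) {
                          warning("airway tracking failed (",
                                  conditionMessage(e),
                                  "); mask includes the airway lumen",
                                  call. = FALSE)
                          NULL
                        })
    if (!is.null(track)) mask <- subtract_airway(mask, track, d)
  }
  if (per_lung) {
    # labelled variant (0 = background, 1 = left, 2 = right); shares the
    # lung_mask container but not its binary invariant
    storage.mode(mask) <- "integer"
    return(structure(list(voxels = mask, spacing = v$spacing, phase = v$phase,
                          subject_id = v$subject_id),
                     class = c("lung_labels", "lung_mask")))
  }
  out <- (mask > 0L) * 1L
  storage.mode(out) <- "integer"
  lung_mask(out, v$spacing, v$phase, v$subject_id)
}

# Zero out tracked airway lumen voxels (dilated by 1 in-plane voxel).
#' @noRd
subtract_airway <- function(mask, track, d) {
  for (entry in track$slices) {
    s <- entry$slice
    if (s > d[1]) next
    sl <- matrix(FALSE, d[2], d[3])
    for (comp in entry$components) sl[comp$pixels] <- TRUE
    if (!any(sl)) next
    ker <- matrix(1, 3, 3)
    sl <- EBImage::dilate(matrix(as.numeric(sl), d[2], d[3]), ker) > 0
    slm <- mask[s, , ]
    slm[sl] <- 0L
    mask[s, , ] <- slm
  }
  mask
}
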