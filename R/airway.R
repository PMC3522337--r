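#' Track the tracheal air column
#'
#' Starting from the air component(s) of plausible tracheal area found in the
#' most superior slices, follows overlapping air components slice by slice
#' inferiorly, recording per-slice component centroids and areas.  Components
#' are matched between consecutive slices by footprint overlap (shared voxel
#' columns), which is robust at 3 mm slice spacing; a component whose area
#' exceeds `max_area` (e.g. the lumen merging into lung parenchyma) is not
#' followed.  Tracking stops when no overlapping component remains or the
#' volume ends.
#'
#' @param v a [ct_volume()].
#' @param air_threshold HU threshold for the air lumen.
#' @param seed_area area range (mm^2) a component must fall in to seed the
#'   track (plausible tracheal cross-sections).
#' @param max_area components larger than this (mm^2) are not followed.
#' @param apex_fraction fraction of the most superior slices searched for the
#'   seed.
#' @return an object of class `airway_track`: list with `start_slice` and
#'   `slices`, each entry holding the slice index and its tracked components
#'   (`pixels` - linear indices into the slice, `centroid` - (row, col),
#'   `area_mm2`, and `parents` - indices of overlapped components one slice
#'   up).
#' @export
track_trachea <- function(v, air_threshold = -320, seed_area = c(50, 500),
                          max_area = 800, apex_fraction = 0.1) {
  if (!inherits(v, "ct_volume")) abort("v must be a ct_volume",
                                       "airtrapcad_input_error")
  d <- dim(v$voxels)
  px_area <- v$spacing[2] * v$spacing[3]
  comps_of <- function(s) {
    lab <- label_air_components(v$voxels[s, , ], air_threshold)
    if (max(lab) == 0) return(list())
    out <- list()
    for (k in seq_len(max(lab))) {
      pix <- which(lab == k)
      if (!length(pix)) next
      rc <- arrayInd(pix, c(d[2], d[3]))
      out[[length(out) + 1L]] <- list(pixels = pix,
                                      centroid = colMeans(rc),
                                      area_mm2 = length(pix) * px_area,
                                      parents = integer())
    }
    out
  }
  n_apex <- max(1L, ceiling(apex_fraction * d[1]))
  start <- NA_integer_
  current <- NULL
  for (s in seq_len(n_apex)) {
    cand <- comps_of(s)
    cand <- Filter(function(co) co$area_mm2 >= seed_area[1] &&
                                co$area_mm2 <= seed_area[2], cand)
    if (length(cand)) { start <- s; current <- cand; break }
  }
  if (is.na(start))
    abort(sprintf("no tracheal air component (area %g-%g mm^2) in the top %d slices",
                  seed_area[1], seed_area[2], n_apex),
          "airtrapcad_tracking_error")
  slices <- list(list(slice = start, components = current))
  if (start < d[1]) for (s in (start + 1L):d[1]) {
    cand <- comps_of(s)
    nxt <- list()
    cur_pix <- lapply(current, `[[`, "pixels")
    for (co in cand) {
      if (co$area_mm2 > max_area) next
      par <- which(vapply(cur_pix, function(p) any(co$pixels %in% p), logical(1)))
      if (length(par)) {
        co$parents <- par
        nxt[[length(nxt) + 1L]] <- co
      }
    }
    if (!length(nxt)) break
    current <- nxt
    slices[[length(slices) + 1L]] <- list(slice = s, components = nxt)
  }
  structure(list(start_slice = start, slices = slices,
                 spacing = v$spacing, n_slices = d[1]),
            class = "airway_track")
}

#' @export
print.airway_track <- function(x, ...) {
  ns <- length(x$slices)
  cat(sprintf("<airway_track> %d tracked slices starting at slice %d\n",
              ns, x$start_slice))
  ncomp <- vapply(x$slices, function(e) length(e$components), integer(1))
  cat(sprintf("  components per slice: %s\n",
              paste(rle(ncomp)$values, "x", rle(ncomp)$lengths,
                    collapse = ", ")))
  invisible(x)
}

#' Detect the carina slice
#'
#' The carina is the ridge at the bifurcation of the trachea into the two
#' main bronchi.  It is located as the most superior tracked slice at which
#' the airway has split into two or more components that each persist for at
#' least two further slices (a single-slice split is treated as noise and
#' ignored).
#'
#' @param track an [track_trachea()] result.
#' @return the carina slice index (1-based, absolute in the volume).
#' @export
detect_carina <- function(track) {
  if (!inherits(track, "airway_track"))
    abort("track must be an airway_track", "airtrapcad_input_error")
  sl <- track$slices
  n <- length(sl)
  # persists(i, j, depth): component j of tracked slice i has a descendant
  # chain of `depth` further slices
  persists <- function(i, j, depth) {
    if (depth == 0L) return(TRUE)
    if (i + 1L > n) return(FALSE)
    kids <- which(vapply(sl[[i + 1L]]$components,
                         function(co) j %in% co$parents, logical(1)))
    any(vapply(kids, function(k) persists(i + 1L, k, depth - 1L), logical(1)))
  }
  for (i in seq_len(n)) {
    m <- length(sl[[i]]$components)
    if (m < 2L) next
    ok <- sum(vapply(seq_len(m), function(j) persists(i, j, 2L), logical(1)))
    if (ok >= 2L) return(sl[[i]]$slice)
  }
  abort("no persistent airway bifurcation found (no carina)",
        "airtrapcad_no_carina_error")
}
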