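#' Systematic point grid test system
#'
#' Builds a square point grid with a uniformly random offset, the classical
#' test system for Cavalieri point counting and Delesse area-fraction
#' estimation. Each test point represents an area `area_per_point`
#' (a/p, square micrometres), so the grid pitch is `sqrt(area_per_point)`.
#'
#' @param area_per_point Area represented by one test point (um^2).
#' @param extent Rectangle `c(xmin, xmax, ymin, ymax)` (um) the grid must
#'   cover.
#' @param seed Integer seed for the random offset; `NULL` draws from the
#'   current RNG stream.
#' @param offset Optional fixed offset `c(dx, dy)` with each coordinate in
#'   `[0, spacing)`; overrides the random draw.
#' @return An object of class `point_grid`.
#' @examples
#' g <- point_grid(23470, c(-500, 500, -500, 500), seed = 1)
#' nrow(grid_points(g))
#' @export
point_grid <- function(area_per_point, extent, seed = NULL, offset = NULL) {
  area_per_point <- check_positive_scalar(area_per_point, "area_per_point")
  extent <- as_rect(extent)
  spacing <- sqrt(area_per_point)
  if (is.null(offset)) {
    offset <- with_seed(seed, stats::runif(2, 0, spacing))
  } else {
    if (!is.numeric(offset) || length(offset) != 2L ||
        any(offset < 0) || any(offset >= spacing)) {
      abort_invalid("`offset` must be two numbers in [0, spacing).")
    }
  }
  structure(
    list(
      area_per_point = area_per_point,
      spacing = spacing,
      offset = as.numeric(offset),
      extent = extent
    ),
    class = "point_grid"
  )
}

#' Enumerate the points of a point grid
#'
#' Enumerates grid points inside the grid's extent, treated half-open
#' (`[xmin, xmax)` by `[ymin, ymax)`), optionally enlarged by `margin` on
#' every side. Enumeration is deterministic given the grid.
#'
#' @param grid A [point_grid()].
#' @param margin Extra border (um) added around the extent.
#' @return A tibble with columns `x`, `y`.
#' @export
grid_points <- function(grid, margin = 0) {
  stopifnot(inherits(grid, "point_grid"))
  sp <- grid$spacing
  ex <- grid$extent + c(-margin, margin, -margin, margin)
  ix <- seq(ceiling((ex[1] - grid$offset[1]) / sp),
            ceiling((ex[2] - grid$offset[1]) / sp) - 1)
  iy <- seq(ceiling((ex[3] - grid$offset[2]) / sp),
            ceiling((ex[4] - grid$offset[2]) / sp) - 1)
  if (length(ix) == 0 || length(iy) == 0) {
    return(tibble::new_tibble(list(x = numeric(), y = numeric()), nrow = 0L))
  }
  xs <- grid$offset[1] + ix * sp
  ys <- grid$offset[2] + iy * sp
  tibble::new_tibble(
    list(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs))),
    nrow = length(xs) * length(ys)
  )
}

# Number of polyline segments needed so that both the chord sagitta stays
# below `tol` and the rendered length is within 0.1% of the true arc length.
# For a cycloid of generating radius r, sagitta per step <= r * dtheta^2 / 8
# and the relative length deficit is ~ dtheta^2 / 96.
cycloid_segments <- function(r, tol) {
  dtheta <- sqrt(8 * tol / r)
  max(24L, as.integer(ceiling(pi / dtheta)))
}

#' Cycloid test system for vertical sections
#'
#' Builds a systematic array of half cycloid arcs (parameter range `[0, pi]`,
#' arc length `4 r`) with the minor axis parallel to the section's vertical
#' direction. On vertical sections this sine-weighting of tangent directions
#' makes intersection counting an unbiased surface probe. One test point is
#' associated with each arc; `length_per_point` (l/p) is the curve length
#' carried by each point.
#'
#' @param length_per_point Test-curve length per test point (um); the
#'   generating radius is `length_per_point / 4`.
#' @param extent Rectangle `c(xmin, xmax, ymin, ymax)` (um) to tile.
#' @param vertical In-plane direction of the vertical axis (2-vector,
#'   normalized internally).
#' @param seed Integer seed for the random offset; `NULL` uses the current
#'   stream.
#' @param area_per_point Optional tile area (um^2) per arc. The default
#'   (`NULL`) tiles arcs contiguously (`pi r` by `2 r`); supplying the point
#'   grid's a/p spaces one arc per grid tile so that point and curve systems
#'   share one set of reference points.
#' @param phase_mirror Mirror alternate rows of arcs (classical rendering;
#'   does not affect the orientation weighting).
#' @param polyline_tolerance Maximum chord (sagitta) error when discretizing
#'   arcs (um).
#' @param offset Optional fixed offset within one tile.
#' @return An object of class `cycloid_system`.
#' @export
cycloid_system <- function(length_per_point, extent, vertical = c(0, 1),
                           seed = NULL, area_per_point = NULL,
                           phase_mirror = TRUE, polyline_tolerance = 0.25,
                           offset = NULL) {
  length_per_point <- check_positive_scalar(length_per_point, "length_per_point")
  polyline_tolerance <- check_positive_scalar(polyline_tolerance, "polyline_tolerance")
  extent <- as_rect(extent)
  r <- length_per_point / 4
  if (!is.numeric(vertical) || length(vertical) != 2L || all(vertical == 0)) {
    abort_invalid("`vertical` must be a nonzero 2-vector.")
  }
  vertical <- vertical / sqrt(sum(vertical^2))
  if (is.null(area_per_point)) {
    tile <- c(pi * r, 2 * r)
  } else {
    area_per_point <- check_positive_scalar(area_per_point, "area_per_point")
    side <- sqrt(area_per_point)
    if (side < pi * r || side < 2 * r) {
      abort_invalid("`area_per_point` tile is too small to host one arc.")
    }
    tile <- c(side, side)
  }
  if (is.null(offset)) {
    offset <- with_seed(seed, stats::runif(2, 0, 1)) * tile
  } else {
    if (!is.numeric(offset) || length(offset) != 2L || any(offset < 0) ||
        any(offset >= tile)) {
      abort_invalid("`offset` must be two numbers within one tile.")
    }
  }
  structure(
    list(
      length_per_point = length_per_point,
      arc_scale = r,
      area_per_point = tile[1] * tile[2],
      tile = tile,
      vertical = vertical,
      offset = as.numeric(offset),
      phase_mirror = isTRUE(phase_mirror),
      polyline_tolerance = polyline_tolerance,
      n_segments = cycloid_segments(r, polyline_tolerance),
      extent = extent
    ),
    class = "cycloid_system"
  )
}

#' Render the arcs of a cycloid system
#'
#' Discretizes every arc whose tile touches the system's extent into a
#' polyline. Coordinates are in plane coordinates (the pattern is rotated so
#' that the cycloid minor axis lies along `vertical`).
#'
#' @param sys A [cycloid_system()].
#' @return A list with matrices `x`, `y` (one column per arc, one row per
#'   polyline vertex) and a tibble `points` of the per-arc test points.
#' @export
cycloid_arcs <- function(sys) {
  stopifnot(inherits(sys, "cycloid_system"))
  r <- sys$arc_scale
  n_seg <- sys$n_segments
  theta <- seq(0, pi, length.out = n_seg + 1)
  ax <- r * (theta - sin(theta)) # local horizontal, 0 .. pi r
  ay <- r * (1 - cos(theta))     # local vertical,   0 .. 2 r
  v <- sys$vertical
  u <- c(v[2], -v[1]) # local horizontal axis in plane coordinates
  ex <- sys$extent
  corners <- rbind(
    c(ex[1], ex[3]), c(ex[2], ex[3]), c(ex[1], ex[4]), c(ex[2], ex[4])
  )
  # extent corners in local (u, v) coordinates
  lu <- corners[, 1] * u[1] + corners[, 2] * u[2]
  lv <- corners[, 1] * v[1] + corners[, 2] * v[2]
  tw <- sys$tile[1]
  th <- sys$tile[2]
  ix <- seq(floor((min(lu) - sys$offset[1]) / tw) - 1,
            ceiling((max(lu) - sys$offset[1]) / tw) + 1)
  iy <- seq(floor((min(lv) - sys$offset[2]) / th) - 1,
            ceiling((max(lv) - sys$offset[2]) / th) + 1)
  n_arcs <- length(ix) * length(iy)
  IX <- rep(ix, times = length(iy))
  IY <- rep(iy, each = length(ix))
  x0 <- IX * tw + sys$offset[1] + (tw - pi * r) / 2
  y0 <- IY * th + sys$offset[2] + (th - 2 * r) / 2
  mirror <- if (sys$phase_mirror) IY %% 2 != 0 else rep(FALSE, n_arcs)
  AX <- matrix(ax, n_seg + 1, n_arcs)
  AX[, mirror] <- pi * r - AX[, mirror]
  LX <- sweep(AX, 2, x0, "+")
  LY <- matrix(ay, n_seg + 1, n_arcs) + rep(y0, each = n_seg + 1)
  px <- IX * tw + sys$offset[1] + tw / 2
  py <- IY * th + sys$offset[2] + th / 2
  list(
    x = LX * u[1] + LY * v[1],
    y = LX * u[2] + LY * v[2],
    points = tibble::tibble(
      arc = seq_len(n_arcs),
      x = px * u[1] + py * v[1],
      y = px * u[2] + py * v[2]
    )
  )
}

#' Test points of a cycloid system
#'
#' @param sys A [cycloid_system()].
#' @return Tibble of per-arc test points (`arc`, `x`, `y`).
#' @export
cycloid_points <- function(sys) {
  cycloid_arcs(sys)$points
}

# Total polyline length of the rendered arcs clipped to a rectangle
# (Liang-Barsky parameter clipping, vectorized over segments).
cycloid_length_in <- function(sys, rect = sys$extent) {
  rect <- as_rect(rect, "rect")
  arcs <- cycloid_arcs(sys)
  n <- nrow(arcs$x)
  x1 <- as.vector(arcs$x[-n, ]); y1 <- as.vector(arcs$y[-n, ])
  x2 <- as.vector(arcs$x[-1, ]); y2 <- as.vector(arcs$y[-1, ])
  dx <- x2 - x1
  dy <- y2 - y1
  t0 <- rep(0, length(x1))
  t1 <- rep(1, length(x1))
  clip1 <- function(p, q, t0, t1) {
    # p * t <= q along the segment parameter t
    hit <- p != 0
    tt <- ifelse(hit, q / p, Inf)
    t0 <- ifelse(hit & p < 0, pmax(t0, tt), t0)
    t1 <- ifelse(hit & p > 0, pmin(t1, tt), t1)
    dead <- !hit & q < 0
    t1 <- ifelse(dead, -Inf, t1)
    list(t0 = t0, t1 = t1)
  }
  for (side in list(
    list(p = -dx, q = x1 - rect[1]),
    list(p = dx, q = rect[2] - x1),
    list(p = -dy, q = y1 - rect[3]),
    list(p = dy, q = rect[4] - y1)
  )) {
    cl <- clip1(side$p, side$q, t0, t1)
    t0 <- cl$t0
    t1 <- cl$t1
  }
  len <- sqrt(dx^2 + dy^2) * pmax(0, t1 - t0)
  sum(len)
}

#' Set of unbiased counting frames
#'
#' Places `n_frames` congruent square frames at systematic uniform random
#' positions inside a rectangular region: the region is divided into a grid
#' of cells, one frame is dropped uniformly at random inside each used cell,
#' so frames are pairwise disjoint and all lie inside the region.
#'
#' @param area Frame area Af (um^2).
#' @param n_frames Number of frames (0 gives an empty set).
#' @param region Rectangle `c(xmin, xmax, ymin, ymax)` (um).
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return An object of class `frame_set`: a tibble of frames (`frame`,
#'   `x0`, `y0`, `width`, `height`, `area`) with attribute `n_frames`.
#' @export
counting_frames <- function(area, n_frames, region, seed = NULL) {
  area <- check_positive_scalar(area, "area")
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 0 ||
      n_frames != round(n_frames)) {
    abort_invalid("`n_frames` must be a non-negative integer.")
  }
  n_frames <- as.integer(n_frames)
  side <- sqrt(area)
  empty <- tibble::tibble(
    frame = integer(), x0 = numeric(), y0 = numeric(),
    width = numeric(), height = numeric(), area = numeric()
  )
  if (n_frames == 0L) {
    return(structure(empty, n_frames = 0L, class = c("frame_set", class(empty))))
  }
  region <- as_rect(region, "region")
  rw <- region[2] - region[1]
  rh <- region[4] - region[3]
  if (rw < side) {
    abort_infeasible(sprintf(
      "region width %.4g um cannot host a frame of side %.4g um.", rw, side))
  }
  if (rh < side) {
    abort_infeasible(sprintf(
      "region height %.4g um cannot host a frame of side %.4g um.", rh, side))
  }
  # cell layout roughly matching the region's aspect ratio
  nx <- max(1L, round(sqrt(n_frames * rw / rh)))
  ny <- ceiling(n_frames / nx)
  while (rw / nx < side && nx > 1L) {
    nx <- nx - 1L
    ny <- ceiling(n_frames / nx)
  }
  while (rh / ny < side && ny > 1L) {
    ny <- ny - 1L
    nx <- ceiling(n_frames / ny)
  }
  if (rw / nx < side) {
    abort_infeasible("region width is the limiting dimension for disjoint frames.")
  }
  if (rh / ny < side) {
    abort_infeasible("region height is the limiting dimension for disjoint frames.")
  }
  cw <- rw / nx
  ch <- rh / ny
  cells <- expand.grid(ixx = seq_len(nx) - 1L, iyy = seq_len(ny) - 1L)
  cells <- cells[seq_len(n_frames), , drop = FALSE]
  uu <- with_seed(seed, matrix(stats::runif(2 * n_frames), ncol = 2))
  frames <- tibble::tibble(
    frame = seq_len(n_frames),
    x0 = region[1] + cells$ixx * cw + uu[, 1] * (cw - side),
    y0 = region[3] + cells$iyy * ch + uu[, 2] * (ch - side),
    width = side,
    height = side,
    area = area
  )
  structure(frames, n_frames = n_frames, class = c("frame_set", class(frames)))
}

# Half-open counting rule of the unbiased frame: a point counts if it lies in
# the interior or on the top or right edge; the left and bottom (forbidden)
# edges and their corner extensions are excluded. With frames tiling a
# rectangle every point is counted exactly once.
point_in_frame <- function(x, y, x0, y0, width, height) {
  x > x0 & x <= x0 + width & y > y0 & y <= y0 + height
}

#' Count labelled cell profiles in a set of frames
#'
#' Applies the unbiased-frame rule (interior plus top/right acceptance edges;
#' left/bottom forbidden edges excluded) to a labelled point pattern.
#' A chondrocyte profile counts toward `q_isolated` or `q_group_cells`
#' according to its `kind`; an isogenous group enters `q_groups` when at
#' least one of its members is counted.
#'
#' @param pattern Tibble with columns `x`, `y`, `kind` (`"isolated"` or
#'   `"group"`), and `group_id` (`NA` for isolated profiles).
#' @param frames A [counting_frames()] set (or any tibble with `x0`, `y0`,
#'   `width`, `height`).
#' @return Named integer vector `q_isolated`, `q_group_cells`, `q_groups`,
#'   `frames_used`.
#' @export
count_in_frames <- function(pattern, frames) {
  stopifnot(is.data.frame(frames))
  if (nrow(frames) > 1) {
    # positive-area overlap (shared edges are fine under the half-open rule)
    for (i in seq_len(nrow(frames) - 1)) {
      j <- seq(i + 1, nrow(frames))
      ov <- frames$x0[i] < frames$x0[j] + frames$width[j] &
        frames$x0[j] < frames$x0[i] + frames$width[i] &
        frames$y0[i] < frames$y0[j] + frames$height[j] &
        frames$y0[j] < frames$y0[i] + frames$height[i]
      if (any(ov)) abort_invalid("frames overlap with positive area.")
    }
  }
  out <- c(q_isolated = 0L, q_group_cells = 0L, q_groups = 0L,
           frames_used = nrow(frames))
  if (nrow(pattern) == 0 || nrow(frames) == 0) {
    return(out)
  }
  counted <- rep(FALSE, nrow(pattern))
  for (i in seq_len(nrow(frames))) {
    counted <- counted | point_in_frame(
      pattern$x, pattern$y,
      frames$x0[i], frames$y0[i], frames$width[i], frames$height[i]
    )
  }
  iso <- pattern$kind == "isolated"
  out["q_isolated"] <- sum(counted & iso)
  out["q_group_cells"] <- sum(counted & !iso)
  out["q_groups"] <- length(unique(pattern$group_id[counted & !iso]))
  out
}
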