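#' Vertical uniform random section planes
#'
#' Generates the section stack of the vertical design: one random azimuth
#' about the vertical axis shared by all sections of a specimen, and
#' systematic plane positions at spacing `t_spacing` with a single uniform
#' random start. The number of planes hitting the phantom is
#' `floor(extent / T)` or one more, depending on the start.
#'
#' @param phantom A [joint_phantom()].
#' @param t_spacing Section spacing T (um).
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return Tibble with `section_index` (0-based), `position` (signed
#'   distance of the plane from the origin along its normal, um) and
#'   `angle` (shared azimuth, radians in `[0, pi)`).
#' @export
section_planes <- function(phantom, t_spacing, seed = NULL) {
  stopifnot(inherits(phantom, "joint_phantom"))
  t_spacing <- check_positive_scalar(t_spacing, "t_spacing")
  r5 <- phantom$radii[5] # horizontal semi-extent (stretch is vertical only)
  with_seed(seed, {
    angle <- stats::runif(1, 0, pi)
    s0 <- stats::runif(1, 0, t_spacing)
    pos <- if (-r5 + s0 < r5) {
      seq(-r5 + s0, r5, by = t_spacing)
    } else {
      numeric(0)
    }
    pos <- pos[pos < r5]
    if (length(pos) == 0) {
      rlang::abort("no section plane hits the phantom (T exceeds its extent).",
                   class = "stereojoint_zero_sections")
    }
    tibble::tibble(section_index = seq_along(pos) - 1L, position = pos,
                   angle = angle)
  })
}

# Map in-plane coordinates (h horizontal, w vertical) of the plane at signed
# distance d and azimuth a to 3-D coordinates. The plane contains the
# vertical (z) axis direction; its normal is horizontal.
section_to_world <- function(position, angle, h, w) {
  list(
    x = position * cos(angle) - h * sin(angle),
    y = position * sin(angle) + h * cos(angle),
    z = w
  )
}

# In-plane bounding rectangle of the phantom profile (same for every
# vertical section).
section_extent <- function(phantom) {
  r5 <- phantom$radii[5]
  c(-r5, r5, -phantom$axis_scale * r5, phantom$axis_scale * r5)
}

#' Count grid points on one section
#'
#' Classifies every grid point of the section plane by phantom membership:
#' `p_ref` counts points inside the joint (any compartment), and each
#' compartment gets its own count. Membership ties on boundaries follow the
#' half-open rule of [phantom_membership()], so the component counts always
#' partition `p_ref`.
#'
#' @param plane A row (or list) with `position` and `angle`.
#' @param phantom A [joint_phantom()].
#' @param grid A [point_grid()] in section coordinates.
#' @return Named integer vector: `p_ref` plus `p_<component>`.
#' @export
count_points_on_section <- function(plane, phantom, grid) {
  pts <- grid_points(grid)
  comp <- joint_components()
  out <- stats::setNames(integer(length(comp) + 1),
                         c("p_ref", paste0("p_", comp)))
  if (nrow(pts) == 0) return(out)
  w3 <- section_to_world(plane$position, plane$angle, pts$x, pts$y)
  m <- phantom_membership(phantom, w3$x, w3$y, w3$z)
  out["p_ref"] <- sum(m > 0)
  tab <- tabulate(m, nbins = 5)
  out[paste0("p_", comp)] <- tab
  out
}

# Indicator of being inside a tracked interface, by surface label.
inside_surface <- function(phantom, surface, x, y, z) {
  zb <- z / phantom$axis_scale
  rho <- sqrt(x^2 + y^2 + zb^2)
  if (surface == "cartilage") {
    rho <= phantom$radii[2]
  } else {
    if (is.null(phantom$villosity)) {
      rho <= phantom$radii[3]
    } else {
      theta <- acos(pmin(1, pmax(-1, ifelse(rho > 0, zb / rho, 1))))
      rho <= membrane_inner_radius(phantom, theta)
    }
  }
}

# Transversal crossings of polylines with an interface: number of adjacent
# vertex pairs whose inside/outside indicator differs, per polyline column.
count_polyline_crossings <- function(indicator) {
  n <- nrow(indicator)
  sum(indicator[-1, , drop = FALSE] != indicator[-n, , drop = FALSE])
}

#' Count cycloid intersections on one section
#'
#' Counts transversal crossings of the rendered cycloid polylines with the
#' two tracked interfaces (sign changes of the inside/outside indicator
#' along each polyline).
#'
#' @param plane A row (or list) with `position` and `angle`.
#' @param phantom A [joint_phantom()].
#' @param cycloids A [cycloid_system()] in section coordinates (vertical
#'   direction along the section's vertical axis).
#' @return Named integer vector `i_cartilage`, `i_synovial_membrane`.
#' @export
count_intersections_on_section <- function(plane, phantom, cycloids) {
  arcs <- cycloid_arcs(cycloids)
  n <- nrow(arcs$x)
  w3 <- section_to_world(plane$position, plane$angle,
                         as.vector(arcs$x), as.vector(arcs$y))
  out <- c(i_cartilage = 0L, i_synovial_membrane = 0L)
  for (surf in joint_surfaces()) {
    ind <- matrix(inside_surface(phantom, surf, w3$x, w3$y, w3$z), nrow = n)
    out[paste0("i_", surf)] <- count_polyline_crossings(ind)
  }
  out
}

# Uniform points in the cartilage profile of a section, by rejection from
# the profile's bounding box.
sample_in_cartilage <- function(n, plane, phantom) {
  r2 <- phantom$radii[2]
  a2 <- sqrt(max(0, r2^2 - plane$position^2))
  out_x <- numeric(0)
  out_y <- numeric(0)
  if (n == 0 || a2 == 0) {
    return(list(x = out_x, y = out_y))
  }
  b2 <- phantom$axis_scale * a2
  guard <- 0L
  while (length(out_x) < n && guard < 1000L) {
    m <- max(64L, 3L * (n - length(out_x)))
    h <- stats::runif(m, -a2, a2)
    w <- stats::runif(m, -b2, b2)
    w3 <- section_to_world(plane$position, plane$angle, h, w)
    keep <- phantom_membership(phantom, w3$x, w3$y, w3$z) == 2L
    out_x <- c(out_x, h[keep])
    out_y <- c(out_y, w[keep])
    guard <- guard + 1L
  }
  list(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# Analytic area (um^2) of the cartilage profile on the section at signed
# distance d: elliptical annulus of the (possibly stretched) shell.
cartilage_profile_area <- function(plane, phantom) {
  r <- phantom$radii
  d <- plane$position
  phantom$axis_scale * pi *
    (max(0, r[2]^2 - d^2) - max(0, r[1]^2 - d^2))
}

#' Scatter chondrocyte profiles on one section
#'
#' Simulates the planar chondrocyte field of the section's cartilage
#' profile: isolated profiles as a Poisson process with intensity
#' `lambda_isolated`, and isogenous groups as a Poisson cluster process
#' (parents with at least two member profiles within `cluster_radius`).
#' All profiles lie inside the cartilage region.
#'
#' @param plane A row (or list) with `position` and `angle`.
#' @param phantom A [joint_phantom()].
#' @param cell_params A [cell_field_params()].
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return Tibble `x`, `y`, `kind` (`"isolated"`/`"group"`), `group_id`.
#' @export
scatter_cell_profiles <- function(plane, phantom, cell_params, seed = NULL) {
  stopifnot(inherits(cell_params, "cell_field_params"))
  area_um2 <- cartilage_profile_area(plane, phantom)
  empty <- tibble::tibble(x = numeric(), y = numeric(), kind = character(),
                          group_id = integer())
  if (area_um2 == 0) return(empty)
  with_seed(seed, {
    lam_iso <- cell_params$lambda_isolated / UM2_PER_MM2 # per um^2
    lam_par <- cell_params$lambda_parents / UM2_PER_MM2
    n_iso <- stats::rpois(1, lam_iso * area_um2)
    iso <- sample_in_cartilage(n_iso, plane, phantom)
    n_par <- stats::rpois(1, lam_par * area_um2)
    parents <- sample_in_cartilage(n_par, plane, phantom)
    gx <- numeric(0); gy <- numeric(0); gid <- integer(0)
    if (n_par > 0) {
      sizes <- 2L + stats::rpois(n_par, cell_params$offspring_mean - 2)
      gid <- rep(seq_len(n_par), sizes)
      # members inside the cartilage region near their parents; batched
      # rejection with the parent position as deterministic fallback
      gx <- parents$x[gid]
      gy <- parents$y[gid]
      todo <- seq_along(gid)
      for (try in 1:100) {
        if (length(todo) == 0) break
        ang <- stats::runif(length(todo), 0, 2 * pi)
        rad <- cell_params$cluster_radius * sqrt(stats::runif(length(todo)))
        cx <- parents$x[gid[todo]] + rad * cos(ang)
        cy <- parents$y[gid[todo]] + rad * sin(ang)
        w3 <- section_to_world(plane$position, plane$angle, cx, cy)
        ok <- phantom_membership(phantom, w3$x, w3$y, w3$z) == 2L
        gx[todo[ok]] <- cx[ok]
        gy[todo[ok]] <- cy[ok]
        todo <- todo[!ok]
      }
    }
    n_iso_final <- length(iso$x)
    tibble::new_tibble(list(
      x = c(iso$x, gx),
      y = c(iso$y, gy),
      kind = rep(c("isolated", "group"), c(n_iso_final, length(gx))),
      group_id = c(rep(NA_integer_, n_iso_final), gid)
    ), nrow = n_iso_final + length(gx))
  })
}

#' Place counting frames inside the cartilage profile of a section
#'
#' Tries systematic angular positions (with a random rotational start)
#' around the cartilage ring and keeps frames that lie entirely inside the
#' cartilage profile and do not overlap frames already placed. Sections
#' whose cartilage profile cannot host all requested frames get fewer;
#' the number actually placed is the section's `frames_used`.
#'
#' @param plane A row (or list) with `position` and `angle`.
#' @param phantom A [joint_phantom()].
#' @param frame_area Frame area Af (um^2).
#' @param n_frames Frames requested per section.
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return Tibble of frames (`frame`, `x0`, `y0`, `width`, `height`,
#'   `area`), possibly with fewer than `n_frames` rows.
#' @export
place_frames_on_section <- function(plane, phantom, frame_area, n_frames,
                                    seed = NULL) {
  side <- sqrt(frame_area)
  empty <- tibble::tibble(frame = integer(), x0 = numeric(), y0 = numeric(),
                          width = numeric(), height = numeric(),
                          area = numeric())
  r <- phantom$radii
  d <- plane$position
  if (n_frames == 0 || r[2]^2 - d^2 <= 0) return(empty)
  a1 <- sqrt(max(0, r[1]^2 - d^2))
  a2 <- sqrt(r[2]^2 - d^2)
  c_ax <- phantom$axis_scale
  inside_cartilage <- function(h, w) {
    w3 <- section_to_world(plane$position, plane$angle, h, w)
    all(phantom_membership(phantom, w3$x, w3$y, w3$z) == 2L)
  }
  with_seed(seed, {
    u <- stats::runif(1)
    px0 <- numeric(0)
    py0 <- numeric(0)
    n_try <- max(4L * n_frames, 24L)
    fractions <- c(0.5, 0.35, 0.65, 0.2, 0.8)
    probe_x <- c(0, 0.5, 1, 0, 1, 0, 0.5, 1, 0.5) * side
    probe_y <- c(0, 0, 0, 0.5, 0.5, 1, 1, 1, 0.5) * side
    for (k in seq_len(n_try)) {
      if (length(px0) >= n_frames) break
      phi <- 2 * pi * (k - 1 + u) / n_try
      for (fr in fractions) {
        am <- a1 + fr * (a2 - a1)
        x0 <- am * cos(phi) - side / 2
        y0 <- c_ax * am * sin(phi) - side / 2
        if (!inside_cartilage(x0 + probe_x, y0 + probe_y)) next
        if (length(px0) > 0 &&
            any(x0 < px0 + side & px0 < x0 + side &
                y0 < py0 + side & py0 < y0 + side)) next
        px0 <- c(px0, x0)
        py0 <- c(py0, y0)
        break
      }
    }
    tibble::new_tibble(list(
      frame = seq_along(px0), x0 = px0, y0 = py0,
      width = rep(side, length(px0)), height = rep(side, length(px0)),
      area = rep(frame_area, length(px0))), nrow = length(px0))
  })
}

#' Simulate the full counting protocol on one specimen
#'
#' Runs vertical uniform random sectioning of a phantom and all three
#' probes on every section, producing the per-section counts table with its
#' ground truth. Random draws come from hierarchically split streams
#' (specimen, then section, then probe), so the result is reproducible
#' bit-for-bit from `seed` and independent across probes.
#'
#' @param phantom A [joint_phantom()].
#' @param probes A [probe_set()].
#' @param cell_params A [cell_field_params()] (needed when `"cells"` is
#'   measured).
#' @param specimen_id,group Labels copied into the counts table.
#' @param seed Integer seed (required; the simulation is fully seeded).
#' @param measure Which probes to run: any of `"points"`, `"surfaces"`,
#'   `"cells"`. Unmeasured probes yield zero counts.
#' @param include_truth Attach [phantom_truth()] (set `FALSE` in large
#'   Monte-Carlo loops over one fixed phantom).
#' @return An object of class `simulated_specimen`: list with `counts`
#'   (the per-section tibble), `truth`, `cell_params`, `probes`, `seed`.
#' @export
simulate_specimen <- function(phantom, probes = probe_set(),
                              cell_params = NULL,
                              specimen_id = "specimen-1", group = "group-1",
                              seed = 1,
                              measure = c("points", "surfaces", "cells"),
                              include_truth = TRUE) {
  stopifnot(inherits(phantom, "joint_phantom"), inherits(probes, "probe_set"))
  measure <- match.arg(measure, several.ok = TRUE)
  if ("cells" %in% measure && is.null(cell_params)) {
    abort_invalid("`cell_params` is required when measuring cells.")
  }
  planes <- section_planes(phantom, probes$t_spacing_um,
                           seed = child_seed(seed, 1))
  ext <- section_extent(phantom)
  m <- nrow(planes)
  comp <- joint_components()
  cnt <- matrix(0L, m, length(counts_schema()) - 3L,
                dimnames = list(NULL, setdiff(counts_schema(),
                  c("specimen_id", "group", "section_index"))))
  for (j in seq_len(m)) {
    plane <- list(position = planes$position[j], angle = planes$angle[j])
    sec_seed <- child_seed(seed, 1000 + j)
    if ("points" %in% measure) {
      grid <- point_grid(probes$area_per_point_um2, ext,
                         seed = child_seed(sec_seed, 1))
      pc <- count_points_on_section(plane, phantom, grid)
      cnt[j, names(pc)] <- pc
    }
    if ("surfaces" %in% measure) {
      cyc <- cycloid_system(probes$length_per_point_um, ext,
                            seed = child_seed(sec_seed, 2),
                            area_per_point = probes$area_per_point_um2)
      ic <- count_intersections_on_section(plane, phantom, cyc)
      cnt[j, names(ic)] <- ic
    }
    if ("cells" %in% measure) {
      frames <- place_frames_on_section(plane, phantom,
                                        probes$frame_area_um2,
                                        probes$n_frames,
                                        seed = child_seed(sec_seed, 3))
      pattern <- scatter_cell_profiles(plane, phantom, cell_params,
                                       seed = child_seed(sec_seed, 4))
      qc <- count_in_frames(pattern, frames)
      cnt[j, names(qc)] <- qc
    }
  }
  counts <- tibble::as_tibble(as.data.frame(cnt))
  counts <- dplyr::bind_cols(
    tibble::tibble(specimen_id = specimen_id, group = group,
                   section_index = planes$section_index),
    counts
  )
  counts$t_spacing_um <- probes$t_spacing_um
  counts$area_per_point_um2 <- probes$area_per_point_um2
  counts$length_per_point_um <- probes$length_per_point_um
  counts$frame_area_um2 <- probes$frame_area_um2
  structure(
    list(
      counts = counts,
      truth = if (include_truth) phantom_truth(phantom) else NULL,
      cell_params = cell_params,
      probes = probes,
      seed = seed,
      planes = planes
    ),
    class = "simulated_specimen"
  )
}
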