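#' Nested-shell joint phantom
#'
#' A parametric metatarsophalangeal-joint phantom built from five nested
#' compartments: bone core (`0..r1`), cartilage shell (`r1..r2`), synovial
#' space (`r2..r3`), synovial membrane (`r3..r4`) and capsule (`r4..r5`).
#' The base geometry is spherical; an optional prolate stretch along the
#' vertical axis (`axis_scale`) and a villous perturbation of the membrane's
#' inner boundary make the tracked surfaces anisotropic, which is what the
#' vertical-design cycloid estimator must cope with. Every compartment has
#' closed-form or quadrature ground truth, so estimators can be validated
#' against known values.
#'
#' @param radii Strictly increasing positive radii `c(r1, r2, r3, r4, r5)`
#'   (um).
#' @param axis_scale Stretch factor applied along the vertical (z) axis;
#'   1 keeps the phantom spherical.
#' @param villosity Optional `list(amplitude =, frequency =)` perturbing the
#'   membrane inner boundary as `r3 + amplitude * cos(frequency * theta)`
#'   with `theta` the polar angle; amplitude must stay below
#'   `(r3 - r2) / 2` and below `r4 - r3` so compartments never
#'   self-intersect.
#' @return An object of class `joint_phantom`.
#' @examples
#' ph <- joint_phantom(c(500, 700, 800, 850, 905))
#' phantom_truth(ph)$volume_mm3[["joint"]]
#' @export
joint_phantom <- function(radii, axis_scale = 1, villosity = NULL) {
  if (!is.numeric(radii) || length(radii) != 5L || anyNA(radii) ||
      any(radii <= 0) || any(diff(radii) <= 0)) {
    rlang::abort("`radii` must be five strictly increasing positive lengths.",
                 class = "stereojoint_invalid_geometry")
  }
  axis_scale <- check_positive_scalar(axis_scale, "axis_scale")
  if (!is.null(villosity)) {
    if (!is.list(villosity) || is.null(villosity$amplitude) ||
        is.null(villosity$frequency)) {
      abort_invalid("`villosity` must be list(amplitude =, frequency =).")
    }
    a <- villosity$amplitude
    if (a < 0 || a >= (radii[3] - radii[2]) / 2 || radii[3] + a >= radii[4]) {
      rlang::abort(
        "villosity amplitude must satisfy 0 <= a < (r3 - r2)/2 and r3 + a < r4.",
        class = "stereojoint_invalid_geometry")
    }
    if (villosity$frequency <= 0) {
      abort_invalid("villosity frequency must be positive.")
    }
    if (a == 0) villosity <- NULL
  }
  structure(
    list(radii = as.numeric(radii), axis_scale = axis_scale,
         villosity = villosity),
    class = "joint_phantom"
  )
}

# Membrane inner boundary radius as a function of polar angle theta.
membrane_inner_radius <- function(phantom, theta) {
  r3 <- phantom$radii[3]
  if (is.null(phantom$villosity)) {
    rep(r3, length(theta))
  } else {
    r3 + phantom$villosity$amplitude *
      cos(phantom$villosity$frequency * theta)
  }
}

#' Compartment membership of 3-D points
#'
#' Maps points to compartments with the half-open tie-break rule: a point
#' exactly on a compartment's outer boundary belongs to the inner
#' compartment, so membership is a deterministic partition.
#'
#' @param phantom A [joint_phantom()].
#' @param x,y,z Point coordinates (um), vectorized.
#' @return Integer vector: 0 outside, 1 bone, 2 cartilage, 3 synovial space,
#'   4 synovial membrane, 5 capsule (see [joint_components()] for names).
#' @export
phantom_membership <- function(phantom, x, y, z) {
  stopifnot(inherits(phantom, "joint_phantom"))
  r <- phantom$radii
  zb <- z / phantom$axis_scale
  rho <- sqrt(x^2 + y^2 + zb^2)
  if (is.null(phantom$villosity)) {
    r3v <- r[3]
  } else {
    theta <- acos(pmin(1, pmax(-1, ifelse(rho > 0, zb / rho, 1))))
    r3v <- membrane_inner_radius(phantom, theta)
  }
  code <- (rho > r[1]) + (rho > r[2]) + (rho > r3v) + (rho > r[4]) +
    (rho > r[5]) + 1L
  code[code == 6L] <- 0L
  as.integer(code)
}

#' Ground truth volumes and surfaces of a phantom
#'
#' Spherical unstretched phantoms use closed forms (shell volume
#' `4/3 pi (r_out^3 - r_in^3)`, sphere surface `4 pi r^2`); stretched or
#' villous phantoms use 1-D quadrature on the axisymmetric profile
#' (relative tolerance 1e-9). The two tracked surfaces are the
#' cartilage-synovial interface at `r2` and the membrane inner boundary at
#' `r3`.
#'
#' @param phantom A [joint_phantom()].
#' @return An object of class `compartment_truth`: list with `volume_mm3`
#'   (named, five compartments plus `joint`), `surface_mm2` (named,
#'   `cartilage` and `synovial_membrane`) and `provenance`
#'   (`"closed_form"` or `"quadrature"`).
#' @export
phantom_truth <- function(phantom) {
  stopifnot(inherits(phantom, "joint_phantom"))
  r <- phantom$radii
  c_ax <- phantom$axis_scale
  closed <- c_ax == 1 && is.null(phantom$villosity)
  sphere_vol <- function(rr) 4 / 3 * pi * rr^3
  quad <- function(f) {
    out <- tryCatch(
      stats::integrate(f, 0, pi, rel.tol = 1e-9, subdivisions = 1000L),
      error = function(e) rlang::abort(
        paste0("quadrature for phantom truth failed: ", conditionMessage(e)),
        class = "stereojoint_truth_unavailable")
    )
    out$value
  }
  # volumes: stretch multiplies base volumes by c_ax; villosity moves volume
  # between synovial space and membrane, quadrature on r3(theta)
  base_cum <- sphere_vol(r)
  if (is.null(phantom$villosity)) {
    v3 <- base_cum[3]
  } else {
    v3 <- quad(function(th) {
      2 * pi / 3 * membrane_inner_radius(phantom, th)^3 * sin(th)
    })
  }
  vol_um3 <- c_ax * c(
    bone = base_cum[1],
    cartilage = base_cum[2] - base_cum[1],
    synovial_space = v3 - base_cum[2],
    synovial_membrane = base_cum[4] - v3,
    capsule = base_cum[5] - base_cum[4]
  )
  vol_um3 <- c(vol_um3, joint = c_ax * base_cum[5])

  # surfaces of revolution: profile s(theta) = rr(theta) sin(theta),
  # z(theta) = c_ax rr(theta) cos(theta)
  stretched_sphere_surface <- function(rr) {
    if (closed) return(4 * pi * rr^2)
    2 * pi * rr^2 *
      quad(function(th) sin(th) * sqrt(cos(th)^2 + c_ax^2 * sin(th)^2))
  }
  surf_cart <- stretched_sphere_surface(r[2])
  if (is.null(phantom$villosity)) {
    surf_memb <- stretched_sphere_surface(r[3])
  } else {
    a <- phantom$villosity$amplitude
    f <- phantom$villosity$frequency
    surf_memb <- 2 * pi * quad(function(th) {
      rr <- membrane_inner_radius(phantom, th)
      dr <- -a * f * sin(f * th)
      ds <- dr * sin(th) + rr * cos(th)
      dz <- c_ax * (dr * cos(th) - rr * sin(th))
      rr * sin(th) * sqrt(ds^2 + dz^2)
    })
  }
  structure(
    list(
      volume_mm3 = vol_um3 / UM3_PER_MM3,
      surface_mm2 = c(cartilage = surf_cart,
                      synovial_membrane = surf_memb) / UM2_PER_MM2,
      provenance = if (closed) "closed_form" else "quadrature"
    ),
    class = "compartment_truth"
  )
}

#' Chondrocyte field parameters
#'
#' Planar point-process model of chondrocyte profiles in the cartilage
#' profile of a section: isolated profiles follow a Poisson process, and
#' isogenous groups follow a Poisson cluster process whose parents carry at
#' least two member profiles each.
#'
#' @param lambda_isolated Intensity of isolated profiles (profiles/mm^2).
#' @param lambda_parents Intensity of isogenous groups (groups/mm^2).
#' @param offspring_mean Expected member profiles per group (>= 2; realized
#'   as `2 + Poisson(offspring_mean - 2)`).
#' @param cluster_radius Radius (um) of the disc holding a group's members.
#' @return An object of class `cell_field_params`.
#' @export
cell_field_params <- function(lambda_isolated = 1500, lambda_parents = 100,
                              offspring_mean = 2.5, cluster_radius = 15) {
  if (lambda_isolated < 0 || lambda_parents < 0) {
    abort_invalid("intensities must be non-negative.")
  }
  if (offspring_mean < 2) {
    abort_invalid("`offspring_mean` must be at least 2.")
  }
  cluster_radius <- check_positive_scalar(cluster_radius, "cluster_radius")
  structure(
    list(lambda_isolated = lambda_isolated, lambda_parents = lambda_parents,
         offspring_mean = offspring_mean, cluster_radius = cluster_radius),
    class = "cell_field_params"
  )
}

#' Default group calibration
#'
#' Mean and between-specimen standard deviation of compartment volumes
#' (mm^3) and chondrocyte profile intensities (profiles/mm^2, groups/mm^2)
#' for the five study groups of the adjuvant-arthritis experiment the
#' synthetic study emulates. These are the generator's study conditions.
#'
#' @return A tibble, one row per group.
#' @export
default_group_calibration <- function() {
  tibble::tribble(
    ~group, ~joint, ~joint_sd, ~cartilage, ~cartilage_sd, ~bone, ~bone_sd,
    ~capsule, ~capsule_sd, ~synovial_space, ~synovial_space_sd,
    ~synovial_membrane, ~synovial_membrane_sd,
    ~chondrocytes, ~chondrocytes_sd, ~isogenous_groups, ~isogenous_groups_sd,
    "Arthritis", 3.02, 0.08, 0.50, 0.10, 1.20, 0.05,
    0.97, 0.14, 0.16, 0.01, 0.08, 0.02, 1416, 126.3, 80.55, 8.77,
    "LNC", 2.80, 0.32, 0.36, 0.08, 1.08, 0.16,
    0.89, 0.15, 0.17, 0.01, 0.04, 0.01, 1543, 49.92, 111.5, 4.51,
    "Diclofenac", 2.46, 0.12, 0.34, 0.03, 1.02, 0.12,
    0.67, 0.02, 0.19, 0.02, 0.03, 0.00, 1627, 95.61, 161.1, 11.84,
    "Diclofenac-LNC", 2.10, 0.10, 0.21, 0.01, 0.75, 0.05,
    0.58, 0.02, 0.26, 0.01, 0.02, 0.00, 1894, 47.00, 226.8, 20.5,
    "No Arthritis", 1.95, 0.05, 0.23, 0.03, 0.61, 0.06,
    0.52, 0.03, 0.41, 0.03, 0.01, 0.05, 2208, 217.4, 297.9, 19.5
  )
}

# Invert target compartment volumes (mm^3) into nested radii (um). Bone,
# cartilage, synovial space and membrane radii come from cumulative
# compartment volumes; the outer radius comes from the joint total, so the
# capsule absorbs the remainder (the printed compartment means do not sum to
# the printed joint volume).
radii_from_volumes <- function(bone, cartilage, synovial_space,
                               synovial_membrane, joint, axis_scale = 1) {
  cum <- cumsum(c(bone, cartilage, synovial_space, synovial_membrane))
  vols <- c(cum, joint) * UM3_PER_MM3 / axis_scale
  if (any(diff(vols) <= 0) || any(vols <= 0)) {
    rlang::abort(
      paste0("infeasible volume targets: cumulative compartment volumes must ",
             "be positive and increasing up to the joint total (capsule ",
             "remainder must be positive)."),
      class = "stereojoint_calibration_error")
  }
  (3 * vols / (4 * pi))^(1 / 3)
}

#' Draw a calibrated phantom for a study group
#'
#' Draws per-specimen compartment volume targets from the group's
#' calibration (normal, truncated to stay positive), inverts them into
#' nested radii (deterministically given the targets), and pairs the phantom
#' with the group's chondrocyte field. With all SDs zero the phantom is
#' identical across seeds and its truth volumes equal the targets exactly.
#'
#' @param group Group label present in `calibration`.
#' @param calibration Tibble as from [default_group_calibration()].
#' @param seed Integer seed; `NULL` uses the current stream.
#' @param axis_scale,villosity Passed to [joint_phantom()].
#' @param sd_scale Multiplier on all calibration SDs (0 gives deterministic
#'   group-mean phantoms).
#' @param offspring_mean,cluster_radius Chondrocyte group geometry, passed
#'   to [cell_field_params()].
#' @return List with elements `phantom`, `cell_params` and `targets`.
#' @export
calibrate_phantom <- function(group, calibration = default_group_calibration(),
                              seed = NULL, axis_scale = 1, villosity = NULL,
                              sd_scale = 1, offspring_mean = 2.5,
                              cluster_radius = 15) {
  row <- calibration[calibration$group == group, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("group '%s' is not in the calibration table.", group),
                 class = "stereojoint_calibration_error")
  }
  draw <- function(mean, sd, floor_at = 1e-4) {
    if (sd * sd_scale == 0) return(mean)
    max(floor_at, stats::rnorm(1, mean, sd * sd_scale))
  }
  with_seed(seed, {
    for (try in 1:100) {
      tg <- list(
        bone = draw(row$bone, row$bone_sd),
        cartilage = draw(row$cartilage, row$cartilage_sd),
        synovial_space = draw(row$synovial_space, row$synovial_space_sd),
        synovial_membrane = draw(row$synovial_membrane, row$synovial_membrane_sd),
        joint = draw(row$joint, row$joint_sd)
      )
      ok <- tg$joint > tg$bone + tg$cartilage + tg$synovial_space +
        tg$synovial_membrane
      if (ok) break
    }
    if (!ok) {
      rlang::abort(
        "could not draw feasible volume targets (capsule remainder <= 0).",
        class = "stereojoint_calibration_error")
    }
    radii <- radii_from_volumes(tg$bone, tg$cartilage, tg$synovial_space,
                                tg$synovial_membrane, tg$joint, axis_scale)
    cells <- cell_field_params(
      lambda_isolated = draw(row$chondrocytes, row$chondrocytes_sd, 1),
      lambda_parents = draw(row$isogenous_groups, row$isogenous_groups_sd, 1),
      offspring_mean = offspring_mean,
      cluster_radius = cluster_radius
    )
    list(
      phantom = joint_phantom(radii, axis_scale = axis_scale,
                              villosity = villosity),
      cell_params = cells,
      targets = tg
    )
  })
}
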