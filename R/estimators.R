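#' Probe constants of the three test systems
#'
#' Bundles the constants of the point grid, cycloid system and counting
#' frames used throughout the study: section spacing T, area per test point
#' a/p, test-curve length per point l/p, frame area Af and frames per
#' section.
#'
#' @param t_spacing_um Distance between consecutive sections T (um).
#' @param area_per_point_um2 Area per grid point a/p (um^2).
#' @param length_per_point_um Cycloid curve length per test point l/p (um).
#' @param frame_area_um2 Counting-frame area Af (um^2).
#' @param n_frames Counting frames per section.
#' @return An object of class `probe_set`.
#' @export
probe_set <- function(t_spacing_um = 50, area_per_point_um2 = 23470,
                      length_per_point_um = 100, frame_area_um2 = 2700.28,
                      n_frames = 6) {
  for (nm in c("t_spacing_um", "area_per_point_um2", "length_per_point_um",
               "frame_area_um2")) {
    check_positive_scalar(get(nm), nm)
  }
  if (n_frames < 0 || n_frames != round(n_frames)) {
    abort_invalid("`n_frames` must be a non-negative integer.")
  }
  structure(
    list(t_spacing_um = t_spacing_um,
         area_per_point_um2 = area_per_point_um2,
         length_per_point_um = length_per_point_um,
         frame_area_um2 = frame_area_um2,
         n_frames = as.integer(n_frames)),
    class = "probe_set"
  )
}

#' Coefficient-of-error prediction parameters
#'
#' Controls the Gundersen-Jensen prediction of the Cavalieri coefficient of
#' error. The `shape_coefficient` is the dimensionless boundary-to-area
#' ratio B/sqrt(A) of the section profiles; its theoretical minimum is the
#' circle's `2 sqrt(pi)`, which is also the default (exact for the spherical
#' phantoms' circular profiles).
#'
#' @param shape_coefficient B/sqrt(A) of the section profiles
#'   (>= `2*sqrt(pi)`).
#' @param variant `"gundersen_noise"` (default):
#'   `CE = sqrt(0.0724 * (B/sqrt(A)) * sqrt(n) / (sum P)^(3/2))`, the
#'   point-count noise prediction; or `"sqrt_ratio"`:
#'   `CE = 0.0724 * (B/sqrt(A)) * sqrt(n / sum P)`.
#' @return An object of class `ce_control`.
#' @export
ce_control <- function(shape_coefficient = 2 * sqrt(pi),
                       variant = c("gundersen_noise", "sqrt_ratio")) {
  variant <- match.arg(variant)
  if (!is.numeric(shape_coefficient) || length(shape_coefficient) != 1L ||
      shape_coefficient < 2 * sqrt(pi) - 1e-9) {
    abort_invalid(
      "`shape_coefficient` must be >= 2*sqrt(pi) (the circle is the minimizer).")
  }
  structure(list(shape_coefficient = shape_coefficient, variant = variant),
            class = "ce_control")
}

counts_schema <- function() {
  c("specimen_id", "group", "section_index", "p_ref", "p_cartilage",
    "p_bone", "p_capsule", "p_synovial_space", "p_synovial_membrane",
    "i_cartilage", "i_synovial_membrane", "q_isolated", "q_group_cells",
    "q_groups", "frames_used")
}

probe_columns <- function() {
  c("t_spacing_um", "area_per_point_um2", "length_per_point_um",
    "frame_area_um2")
}

#' Validate a per-section counts table
#'
#' Checks the raw-counts schema: one row per section with non-negative
#' integer counts, component point counts bounded by the reference count,
#' at least one counted member per counted isogenous group, strictly
#' increasing section indices within each specimen, and positive,
#' specimen-constant probe columns (`t_spacing_um`, `area_per_point_um2`,
#' `length_per_point_um`, `frame_area_um2`).
#'
#' @param counts Data frame of per-section counts.
#' @return The validated counts as a tibble (invisibly usable in pipes).
#' @export
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  missing <- setdiff(c(counts_schema(), probe_columns()), names(counts))
  if (length(missing) > 0) {
    abort_invalid(paste0("counts table is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  cnt_cols <- setdiff(counts_schema(),
                      c("specimen_id", "group", "section_index"))
  for (cc in cnt_cols) {
    v <- counts[[cc]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      abort_invalid(sprintf("column `%s` must hold non-negative integers.", cc))
    }
  }
  comp_cols <- paste0("p_", joint_components())
  for (cc in comp_cols) {
    if (any(counts[[cc]] > counts$p_ref)) {
      abort_invalid(sprintf("`%s` exceeds `p_ref` on some section.", cc))
    }
  }
  if (any(counts$q_group_cells < counts$q_groups)) {
    abort_invalid("`q_group_cells` must be at least `q_groups`.")
  }
  for (pc in probe_columns()) {
    if (any(counts[[pc]] <= 0)) {
      abort_invalid(sprintf("`%s` must be positive.", pc))
    }
  }
  bad <- counts |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(
      ordered = all(diff(.data$section_index) > 0) || dplyr::n() == 1,
      const = dplyr::n_distinct(.data$t_spacing_um) == 1 &&
        dplyr::n_distinct(.data$area_per_point_um2) == 1 &&
        dplyr::n_distinct(.data$length_per_point_um) == 1 &&
        dplyr::n_distinct(.data$frame_area_um2) == 1,
      .groups = "drop"
    )
  if (any(!bad$ordered)) {
    abort_invalid("section_index must be strictly increasing within a specimen.")
  }
  if (any(!bad$const)) {
    abort_invalid("probe constants must be constant within a specimen.")
  }
  dup <- duplicated(counts[c("specimen_id", "section_index")])
  if (any(dup)) {
    abort_invalid("duplicate (specimen_id, section_index) rows.")
  }
  counts
}

#' Cavalieri volume from point counts
#'
#' The Cavalieri estimator of absolute volume from equidistant sections with
#' a uniform random start: `V = sum(P) * T * (a/p)`, computed in um^3 and
#' returned in mm^3.
#'
#' @param counts Per-section counts table (see [validate_counts()]).
#' @return Tibble with one row per specimen: `specimen_id`, `group`,
#'   `n_sections`, `sum_p_ref`, `volume_mm3`.
#' @examples
#' counts <- tibble::tibble(
#'   specimen_id = "a", group = "g", section_index = 0:3,
#'   p_ref = c(10, 40, 40, 10), p_cartilage = 0, p_bone = 0, p_capsule = 0,
#'   p_synovial_space = 0, p_synovial_membrane = 0, i_cartilage = 0,
#'   i_synovial_membrane = 0, q_isolated = 0, q_group_cells = 0,
#'   q_groups = 0, frames_used = 0, t_spacing_um = 50,
#'   area_per_point_um2 = 23470, length_per_point_um = 100,
#'   frame_area_um2 = 2700.28
#' )
#' cavalieri_volume(counts)$volume_mm3 # 100 * 50 * 23470 / 1e9
#' @export
cavalieri_volume <- function(counts) {
  counts <- validate_counts(counts)
  counts |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      sum_p_ref = sum(.data$p_ref),
      volume_mm3 = sum(.data$p_ref) * .data$t_spacing_um[1] *
        .data$area_per_point_um2[1] / UM3_PER_MM3,
      .groups = "drop"
    )
}

ce_from_sums <- function(sum_p, n, ce) {
  if (ce$variant == "gundersen_noise") {
    sqrt(0.0724 * ce$shape_coefficient * sqrt(n) / sum_p^1.5)
  } else {
    0.0724 * ce$shape_coefficient * sqrt(n / sum_p)
  }
}

#' Predicted coefficient of error of the Cavalieri estimate
#'
#' Gundersen-Jensen prediction of the sampling error of systematic point
#' counting; see [ce_control()] for the two formula variants.
#'
#' @param counts Per-section counts table.
#' @param ce A [ce_control()].
#' @return Tibble `specimen_id`, `group`, `ce`, `ce_variant`,
#'   `shape_coefficient`.
#' @export
predicted_ce <- function(counts, ce = ce_control()) {
  counts <- validate_counts(counts)
  stopifnot(inherits(ce, "ce_control"))
  sums <- counts |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(sum_p = sum(.data$p_ref), n = dplyr::n(),
                     .groups = "drop")
  if (any(sums$sum_p == 0)) {
    abort_undefined("CE is undefined when no points hit the reference space.")
  }
  if (any(sums$n < 2)) {
    abort_undefined("CE prediction requires at least two sections.")
  }
  ce_values <- ce_from_sums(sums$sum_p, sums$n, ce)
  variant <- ce$variant
  shape <- ce$shape_coefficient
  tibble::tibble(
    specimen_id = sums$specimen_id,
    group = sums$group,
    ce = ce_values,
    ce_variant = variant,
    shape_coefficient = shape
  )
}

#' Shape coefficient from section profiles
#'
#' Mean boundary-to-area ratio `B_i / sqrt(A_i)` over sections, the
#' dimensionless shape coefficient entering the CE prediction. A circle
#' gives `2 sqrt(pi)`, a square gives 4; the value is scale invariant.
#'
#' @param boundary_length Per-section profile boundary lengths (um).
#' @param profile_area Per-section profile areas (um^2).
#' @return A single number.
#' @export
shape_coefficient <- function(boundary_length, profile_area) {
  if (length(boundary_length) != length(profile_area) ||
      length(profile_area) == 0) {
    abort_invalid("boundary and area vectors must have equal positive length.")
  }
  if (any(boundary_length <= 0) || any(profile_area <= 0)) {
    abort_invalid("boundary lengths and profile areas must be positive.")
  }
  mean(boundary_length / sqrt(profile_area))
}

#' Delesse volume fraction of a joint component
#'
#' Area-fraction (hence volume-fraction) estimator
#' `Vv = sum(P_comp) / sum(P_ref)`.
#'
#' @param counts Per-section counts table.
#' @param component One of [joint_components()].
#' @return Tibble `specimen_id`, `group`, `component`, `vv`.
#' @export
volume_fraction <- function(counts, component) {
  counts <- validate_counts(counts)
  if (!component %in% joint_components()) {
    abort_invalid(sprintf(
      "unknown component '%s'; expected one of: %s.",
      component, paste(joint_components(), collapse = ", ")))
  }
  col <- paste0("p_", component)
  out <- counts |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(sum_comp = sum(.data[[col]]),
                     sum_ref = sum(.data$p_ref), .groups = "drop")
  if (any(out$sum_ref == 0)) {
    abort_undefined("volume fraction is undefined when sum(P_ref) = 0.")
  }
  out |>
    dplyr::transmute(.data$specimen_id, .data$group, component = component,
                     vv = .data$sum_comp / .data$sum_ref)
}

#' Absolute volume from a volume fraction
#'
#' @param vv Volume fraction(s) in `[0, 1]`.
#' @param volume_mm3 Cavalieri reference volume(s) (mm^3).
#' @return `vv * volume_mm3` (mm^3).
#' @export
absolute_volume <- function(vv, volume_mm3) {
  if (any(vv < 0 | vv > 1, na.rm = TRUE) || any(volume_mm3 < 0, na.rm = TRUE)) {
    abort_invalid("`vv` must lie in [0, 1] and `volume_mm3` must be >= 0.")
  }
  vv * volume_mm3
}

#' Surface density from cycloid intersection counts
#'
#' Vertical-design surface density `Sv = 2 sum(I) / (sum(P) * l/p)`,
#' computed in 1/um and returned in 1/mm.
#'
#' @param counts Per-section counts table.
#' @param surface One of [joint_surfaces()].
#' @return Tibble `specimen_id`, `group`, `surface`, `sv_mm1`.
#' @export
surface_density <- function(counts, surface) {
  counts <- validate_counts(counts)
  if (!surface %in% joint_surfaces()) {
    abort_invalid(sprintf(
      "unknown surface '%s'; expected one of: %s.",
      surface, paste(joint_surfaces(), collapse = ", ")))
  }
  col <- paste0("i_", surface)
  out <- counts |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(sum_i = sum(.data[[col]]), sum_p = sum(.data$p_ref),
                     lp = .data$length_per_point_um[1], .groups = "drop")
  if (any(out$sum_p == 0)) {
    abort_undefined("surface density is undefined when sum(P_ref) = 0.")
  }
  out |>
    dplyr::transmute(.data$specimen_id, .data$group, surface = surface,
                     sv_mm1 = 2 * .data$sum_i / (.data$sum_p * .data$lp) * 1e3)
}

#' Absolute surface area from a surface density
#'
#' @param sv_mm1 Surface density (1/mm).
#' @param volume_mm3 Cavalieri reference volume (mm^3).
#' @return Surface area `sv_mm1 * volume_mm3` (mm^2).
#' @export
absolute_surface <- function(sv_mm1, volume_mm3) {
  if (any(sv_mm1 < 0, na.rm = TRUE) || any(volume_mm3 < 0, na.rm = TRUE)) {
    abort_invalid("`sv_mm1` and `volume_mm3` must be non-negative.")
  }
  sv_mm1 * volume_mm3
}

#' Chondrocyte profile density from frame counts
#'
#' 2-D numerical profile density `N = sum(Q) / (N_frames * Af)`, computed
#' in 1/um^2 and returned in profiles/mm^2.
#'
#' @param counts Per-section counts table.
#' @param which One of `"isolated"`, `"group_cells"`, `"isogenous_groups"`,
#'   `"total"` (`total = isolated + group_cells`).
#' @return Tibble `specimen_id`, `group`, `which`, `density_mm2`.
#' @export
profile_density <- function(counts,
                            which = c("isolated", "group_cells",
                                      "isogenous_groups", "total")) {
  which <- match.arg(which)
  counts <- validate_counts(counts)
  out <- counts |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(
      sum_q = switch(which,
        isolated = sum(.data$q_isolated),
        group_cells = sum(.data$q_group_cells),
        isogenous_groups = sum(.data$q_groups),
        total = sum(.data$q_isolated) + sum(.data$q_group_cells)
      ),
      n_frames = sum(.data$frames_used),
      af = .data$frame_area_um2[1],
      .groups = "drop"
    )
  if (any(out$n_frames == 0)) {
    abort_undefined("profile density is undefined when no frames were used.")
  }
  out |>
    dplyr::transmute(.data$specimen_id, .data$group, which = which,
                     density_mm2 = .data$sum_q / (.data$n_frames * .data$af) *
                       UM2_PER_MM2)
}

#' All stereological estimates for each specimen
#'
#' Runs every estimator on a per-section counts table and returns one row
#' per specimen: Cavalieri volume and predicted CE, per-component volume
#' fractions and absolute volumes, per-surface densities and absolute
#' surface areas, and chondrocyte profile densities. The internal
#' identities hold exactly: `vol_<c>_mm3 = vv_<c> * volume_mm3`,
#' `surf_<s>_mm2 = sv_<s>_mm1 * volume_mm3`, and
#' `nv_total_mm2 = nv_isolated_mm2 + nv_group_cells_mm2`.
#'
#' Specimens on which the CE is undefined (a single section, or no point
#' hitting the reference space) get `ce = NA` with a warning; densities with
#' zero frames are `NA` likewise.
#'
#' @param counts Per-section counts table.
#' @param ce A [ce_control()].
#' @return Tibble, one row per specimen, probe constants and CE variant
#'   echoed as columns.
#' @export
estimate_specimens <- function(counts, ce = ce_control()) {
  counts <- validate_counts(counts)
  stopifnot(inherits(ce, "ce_control"))
  base <- cavalieri_volume(counts)
  probes <- counts |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(probe_columns()),
                                   dplyr::first), .groups = "drop")
  est <- dplyr::left_join(base, probes, by = "specimen_id")

  # predicted CE, NA (with warning) where undefined
  est$ce <- NA_real_
  ok <- est$sum_p_ref > 0 & est$n_sections >= 2
  if (any(!ok)) {
    rlang::warn(paste0("CE unavailable for specimen(s): ",
                       paste(est$specimen_id[!ok], collapse = ", ")))
  }
  est$ce[ok] <- ce_from_sums(est$sum_p_ref[ok], est$n_sections[ok], ce)
  est$ce_variant <- ce$variant
  est$shape_coefficient <- ce$shape_coefficient

  sums <- counts |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(
        paste0("p_", joint_components()),
        paste0("i_", joint_surfaces()),
        "q_isolated", "q_group_cells", "q_groups", "frames_used")), sum),
      .groups = "drop")
  est <- dplyr::left_join(est, sums, by = "specimen_id")

  zero_ref <- est$sum_p_ref == 0
  for (comp in joint_components()) {
    vvc <- ifelse(zero_ref, ifelse(est[[paste0("p_", comp)]] == 0, 0, NA),
                  est[[paste0("p_", comp)]] / est$sum_p_ref)
    est[[paste0("vv_", comp)]] <- vvc
    est[[paste0("vol_", comp, "_mm3")]] <- vvc * est$volume_mm3
  }
  for (surf in joint_surfaces()) {
    sv <- ifelse(zero_ref, ifelse(est[[paste0("i_", surf)]] == 0, 0, NA),
                 2 * est[[paste0("i_", surf)]] /
                   (est$sum_p_ref * est$length_per_point_um) * 1e3)
    est[[paste0("sv_", surf, "_mm1")]] <- sv
    est[[paste0("surf_", surf, "_mm2")]] <- sv * est$volume_mm3
  }
  # with zero frames a density is undefined, except for the all-zero
  # specimen, whose estimates are all zero by convention
  zero_frames <- est$frames_used == 0
  denom <- est$frames_used * est$frame_area_um2
  nv <- function(q) {
    ifelse(zero_frames, ifelse(q == 0, 0, NA), q / denom * UM2_PER_MM2)
  }
  est$nv_isolated_mm2 <- nv(est$q_isolated)
  est$nv_group_cells_mm2 <- nv(est$q_group_cells)
  est$nv_total_mm2 <- est$nv_isolated_mm2 + est$nv_group_cells_mm2
  est$nv_isogenous_groups_mm2 <- nv(est$q_groups)
  est |>
    dplyr::select(-dplyr::all_of(c(
      paste0("p_", joint_components()),
      paste0("i_", joint_surfaces()),
      "q_isolated", "q_group_cells", "q_groups"))) |>
    dplyr::rename(sum_frames_used = "frames_used")
}

#' Keep every k-th section of each specimen
#'
#' The section-reduction device: retains sections at positions
#' `start, start + step, ...` (0-based, in index order) and multiplies the
#' section spacing T by `step`, so the subsample is again a valid
#' systematic sample. Averaged over the `step` possible starts, the
#' Cavalieri volume of the subsamples equals the full-section volume
#' exactly.
#'
#' @param counts Per-section counts table.
#' @param step Keep every `step`-th section (>= 1).
#' @param start 0-based offset of the first retained section
#'   (`0 <= start < step`).
#' @return A counts table of the retained sections, re-indexed, with
#'   `t_spacing_um` multiplied by `step`.
#' @export
subsample_sections <- function(counts, step, start = 0) {
  counts <- validate_counts(counts)
  if (step < 1 || step != round(step)) {
    abort_invalid("`step` must be a positive integer.")
  }
  if (start < 0 || start >= step || start != round(start)) {
    abort_invalid("`start` must satisfy 0 <= start < step.")
  }
  out <- counts |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::arrange(.data$section_index, .by_group = TRUE) |>
    dplyr::filter((dplyr::row_number() - 1) %% step == start) |>
    dplyr::mutate(section_index = dplyr::row_number() - 1L,
                  t_spacing_um = .data$t_spacing_um * step) |>
    dplyr::ungroup()
  lost <- setdiff(unique(counts$specimen_id), unique(out$specimen_id))
  if (nrow(out) == 0 || length(lost) > 0) {
    abort_invalid(paste0(
      "subsample is empty",
      if (length(lost)) paste0(" for specimen(s): ",
                               paste(lost, collapse = ", ")), "."))
  }
  out
}
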