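test_that("Cavalieri volume follows sum(P) * T * a/p with unit conversion", {
  # 100 points, T = 50 um, a/p = 23470 um^2 -> 0.11735 mm^3
  counts <- make_counts(c(10, 40, 40, 10))
  expect_equal(cavalieri_volume(counts)$volume_mm3, 0.11735)
  # the split over sections is irrelevant
  expect_equal(cavalieri_volume(make_counts(c(100)))$volume_mm3, 0.11735)

  expect_equal(cavalieri_volume(make_counts(c(0, 0)))$volume_mm3, 0)

  one <- make_counts(1, t_spacing_um = 1, area_per_point_um2 = 1)
  expect_equal(cavalieri_volume(one)$volume_mm3, 1e-9)
})

test_that("counts validation enforces the schema invariants", {
  bad <- make_counts(c(10, 10))
  bad$p_cartilage <- c(11L, 0L)
  expect_error(validate_counts(bad), class = "stereojoint_invalid_parameter")

  bad <- make_counts(c(10, 10))
  bad$section_index <- c(1L, 0L)
  expect_error(validate_counts(bad), class = "stereojoint_invalid_parameter")

  bad <- make_counts(c(10, 10))
  bad$q_groups <- c(3L, 0L)
  bad$q_group_cells <- c(2L, 0L)
  expect_error(validate_counts(bad), class = "stereojoint_invalid_parameter")

  bad <- make_counts(c(10, 10))
  bad$section_index <- c(0L, 0L)
  expect_error(validate_counts(bad), class = "stereojoint_invalid_parameter")

  bad <- make_counts(c(10, 10))
  bad$p_ref <- c(-1L, 5L)
  expect_error(validate_counts(bad), class = "stereojoint_invalid_parameter")
})

test_that("predicted CE matches hand arithmetic and its scaling laws", {
  # B/sqrt(A) = 2 sqrt(pi), n = 10, sum P = 2500
  counts <- make_counts(rep(250, 10))
  ce <- predicted_ce(counts)
  expect_equal(ce$ce, sqrt(0.0724 * 2 * sqrt(pi) * sqrt(10) / 2500^1.5),
               tolerance = 1e-12)
  expect_equal(ce$ce, 2.55e-3, tolerance = 0.002)
  expect_equal(ce$ce_variant, "gundersen_noise")

  alt <- predicted_ce(counts, ce_control(variant = "sqrt_ratio"))
  expect_equal(alt$ce, 0.0724 * 2 * sqrt(pi) * sqrt(10 / 2500),
               tolerance = 1e-12)

  # doubling sum(P) with n fixed strictly decreases CE under both variants
  for (v in c("gundersen_noise", "sqrt_ratio")) {
    cc <- ce_control(variant = v)
    expect_lt(predicted_ce(make_counts(rep(500, 10)), cc)$ce,
              predicted_ce(make_counts(rep(250, 10)), cc)$ce)
  }
  # n -> 4n with sum(P) -> 4 sum(P) halves the default CE
  ce4 <- predicted_ce(make_counts(rep(250, 40)))
  expect_equal(ce4$ce, ce$ce / 2, tolerance = 1e-12)

  expect_error(predicted_ce(make_counts(c(0, 0))),
               class = "stereojoint_undefined")
  expect_error(predicted_ce(make_counts(5)),
               class = "stereojoint_undefined")
  expect_error(ce_control(shape_coefficient = 3.0),
               class = "stereojoint_invalid_parameter")
})

test_that("shape coefficient reproduces closed forms and is scale free", {
  r <- c(3, 10, 0.2)
  expect_equal(shape_coefficient(2 * pi * r, pi * r^2), 2 * sqrt(pi))
  s <- c(1, 7)
  expect_equal(shape_coefficient(4 * s, s^2), 4)
  b <- c(13, 29); a <- c(5, 17)
  expect_equal(shape_coefficient(10 * b, 100 * a),
               shape_coefficient(b, a))
  expect_error(shape_coefficient(1, 0),
               class = "stereojoint_invalid_parameter")
})

test_that("Delesse fractions and absolute volumes behave", {
  counts <- make_counts(c(50, 50), p_cartilage = c(15L, 10L))
  expect_equal(volume_fraction(counts, "cartilage")$vv, 0.25)
  full <- make_counts(c(30), p_bone = 30L)
  expect_equal(volume_fraction(full, "bone")$vv, 1)
  expect_equal(volume_fraction(full, "capsule")$vv, 0)
  expect_error(volume_fraction(counts, "gristle"),
               class = "stereojoint_invalid_parameter")
  expect_error(volume_fraction(make_counts(c(0, 0)), "bone"),
               class = "stereojoint_undefined")

  # consistent with the published Arthritis row: 0.16556 * 3.02 ~ 0.50
  expect_equal(absolute_volume(0.16556, 3.02), 0.50, tolerance = 1e-3)
  expect_equal(absolute_volume(0, 3.02), 0)
  expect_equal(absolute_volume(1, 3.02), 3.02)
  expect_error(absolute_volume(1.2, 1),
               class = "stereojoint_invalid_parameter")
})

test_that("surface density and absolute surface follow the cycloid formula", {
  counts <- make_counts(c(60, 40), i_cartilage = c(30L, 20L),
                        length_per_point_um = 20)
  # 2*50 / (100*20) = 0.05 1/um = 50 1/mm
  expect_equal(surface_density(counts, "cartilage")$sv_mm1, 50)
  expect_equal(surface_density(counts, "synovial_membrane")$sv_mm1, 0)
  double_lp <- make_counts(c(60, 40), i_cartilage = c(30L, 20L),
                           length_per_point_um = 40)
  expect_equal(surface_density(double_lp, "cartilage")$sv_mm1, 25)

  # consistent with the published Arthritis row: 12.667 * 3.02 ~ 38.25
  expect_equal(absolute_surface(12.667, 3.02), 38.25, tolerance = 1e-3)
  expect_equal(absolute_surface(0, 3.02), 0)
})

test_that("profile densities follow sum(Q) / (N_frames * Af)", {
  counts <- make_counts(c(10), q_isolated = 6L, frames_used = 6L)
  expect_equal(profile_density(counts, "isolated")$density_mm2,
               6 / (6 * 2700.28) * 1e6)
  expect_equal(profile_density(counts, "isolated")$density_mm2, 370.33,
               tolerance = 1e-4)
  expect_equal(profile_density(counts, "total")$density_mm2,
               profile_density(counts, "isolated")$density_mm2)
  zero <- make_counts(c(10), frames_used = 6L)
  expect_equal(profile_density(zero, "isolated")$density_mm2, 0)
  twice <- make_counts(c(10), q_isolated = 6L, frames_used = 12L)
  expect_equal(twice$frames_used, 12L)
  expect_equal(profile_density(twice, "isolated")$density_mm2,
               profile_density(counts, "isolated")$density_mm2 / 2)
  expect_error(profile_density(make_counts(c(10)), "isolated"),
               class = "stereojoint_undefined")
})

test_that("estimate_specimens fills every field with exact identities", {
  set.seed(31)
  counts <- dplyr::bind_rows(random_counts("a", 8), random_counts("b", 12))
  est <- estimate_specimens(counts)
  expect_equal(nrow(est), 2)
  for (i in 1:2) {
    row <- est[i, ]
    for (comp in joint_components()) {
      expect_identical(row[[paste0("vol_", comp, "_mm3")]],
                       row[[paste0("vv_", comp)]] * row$volume_mm3)
    }
    for (surf in joint_surfaces()) {
      expect_identical(row[[paste0("surf_", surf, "_mm2")]],
                       row[[paste0("sv_", surf, "_mm1")]] * row$volume_mm3)
    }
    expect_identical(row$nv_total_mm2,
                     row$nv_isolated_mm2 + row$nv_group_cells_mm2)
    vvs <- unlist(row[paste0("vv_", joint_components())])
    expect_true(all(vvs >= 0 & vvs <= 1))
    expect_lte(sum(vvs), 1 + 1e-9)
    expect_lte(sum(unlist(row[paste0("vol_", joint_components(), "_mm3")])),
               row$volume_mm3 + 1e-12)
  }
  # determinism: recomputation is bit-identical
  expect_identical(est, estimate_specimens(counts))

  # zero-count specimen: all-zero estimates, CE flagged missing
  expect_warning(z <- estimate_specimens(make_counts(c(0, 0))), "CE")
  expect_equal(z$volume_mm3, 0)
  expect_true(is.na(z$ce))
  expect_equal(z$vv_cartilage, 0)
  expect_equal(z$nv_total_mm2, 0)
})

test_that("every estimator agrees exactly with its brute-force oracle", {
  set.seed(32)
  for (rep in 1:40) {
    counts <- random_counts("x", sample(3:15, 1))
    est <- estimate_specimens(counts)
    expect_equal(est$volume_mm3, oracle_volume(counts), tolerance = 1e-14)
    expect_equal(est$ce, oracle_ce(counts), tolerance = 1e-14)
    for (comp in joint_components()) {
      expect_equal(est[[paste0("vv_", comp)]], oracle_vv(counts, comp),
                   tolerance = 1e-14)
    }
    for (surf in joint_surfaces()) {
      expect_equal(est[[paste0("sv_", surf, "_mm1")]],
                   oracle_sv_mm1(counts, surf), tolerance = 1e-14)
    }
    expect_equal(est$nv_isolated_mm2,
                 oracle_density_mm2(counts, "q_isolated"), tolerance = 1e-14)
    expect_equal(est$nv_isogenous_groups_mm2,
                 oracle_density_mm2(counts, "q_groups"), tolerance = 1e-14)
  }
})

test_that("estimates are additive over disjoint section sets with equal T", {
  set.seed(33)
  a <- random_counts("s", 6)
  b <- random_counts("s", 6)
  b$section_index <- b$section_index + 6L
  ab <- dplyr::bind_rows(a, b)
  est <- estimate_specimens(ab)
  expect_equal(est$volume_mm3,
               oracle_volume(a) + oracle_volume(b), tolerance = 1e-14)
  # ratio quantities combine count-weighted, not as averages of ratios
  pa <- sum(a$p_ref); pb <- sum(b$p_ref)
  expect_equal(est$vv_bone,
               (oracle_vv(a, "bone") * pa + oracle_vv(b, "bone") * pb) /
                 (pa + pb), tolerance = 1e-12)
})

test_that("estimates scale linearly in the probe constants", {
  set.seed(34)
  counts <- random_counts("s", 9)
  base <- estimate_specimens(counts)
  t2 <- counts; t2$t_spacing_um <- t2$t_spacing_um * 3
  expect_equal(estimate_specimens(t2)$volume_mm3, 3 * base$volume_mm3,
               tolerance = 1e-12)
  a2 <- counts; a2$area_per_point_um2 <- a2$area_per_point_um2 * 2
  expect_equal(estimate_specimens(a2)$volume_mm3, 2 * base$volume_mm3,
               tolerance = 1e-12)
  l2 <- counts; l2$length_per_point_um <- l2$length_per_point_um * 2
  expect_equal(estimate_specimens(l2)$sv_cartilage_mm1,
               base$sv_cartilage_mm1 / 2, tolerance = 1e-12)
})

test_that("section subsampling halves the stack and preserves the mean", {
  set.seed(35)
  counts <- random_counts("s", 28)
  expect_identical(
    subsample_sections(counts, 1)$p_ref, counts$p_ref)

  half <- subsample_sections(counts, 2, 0)
  expect_equal(nrow(half), 14)
  expect_equal(unique(half$t_spacing_um), 100)
  expect_equal(half$p_ref, counts$p_ref[seq(1, 28, by = 2)])

  # mean over the k possible starts equals the full-section volume exactly
  for (k in c(2, 3, 5, 7)) {
    vols <- vapply(seq_len(k) - 1L, function(s) {
      cavalieri_volume(subsample_sections(counts, k, s))$volume_mm3
    }, 1)
    expect_equal(mean(vols), cavalieri_volume(counts)$volume_mm3,
                 tolerance = 1e-12)
  }

  expect_error(subsample_sections(counts, 2, 2),
               class = "stereojoint_invalid_parameter")
  expect_error(subsample_sections(random_counts("s", 2), 5, 3),
               class = "stereojoint_invalid_parameter")
})
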