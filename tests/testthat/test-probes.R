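test_that("point grid geometry follows a/p and the half-open enumeration", {
  g <- point_grid(23470, c(-500, 500, -500, 500), seed = 1)
  expect_equal(g$spacing, sqrt(23470))
  expect_equal(g$spacing^2, g$area_per_point, tolerance = 1e-9)
  expect_true(all(g$offset >= 0 & g$offset < g$spacing))

  unit <- point_grid(1, c(0, 10, 0, 10), offset = c(0, 0))
  expect_equal(nrow(grid_points(unit)), 100)

  # determinism: same seed, same offsets and enumeration
  g2 <- point_grid(23470, c(-500, 500, -500, 500), seed = 1)
  expect_identical(grid_points(g), grid_points(g2))

  expect_error(point_grid(-1, c(0, 1, 0, 1)),
               class = "stereojoint_invalid_parameter")
  expect_error(point_grid(1, c(1, 1, 0, 1)),
               class = "stereojoint_invalid_parameter")
})

test_that("every point of the extent lies within one spacing of a grid point", {
  for (seed in 1:5) {
    g <- point_grid(23470, c(-310, 290, -150, 410), seed = seed)
    pts <- grid_points(g)
    xs <- seq(g$extent[1], g$extent[2], length.out = 21)
    ys <- seq(g$extent[3], g$extent[4], length.out = 21)
    probe <- expand.grid(x = xs, y = ys)
    dx <- outer(probe$x, pts$x, function(a, b) abs(a - b))
    dy <- outer(probe$y, pts$y, function(a, b) abs(a - b))
    cheb <- apply(pmax(dx, dy), 1, min)
    expect_lt(max(cheb), g$spacing + 1e-9)
  }
})

test_that("expected grid hits in a fixed region equal area / (a/p)", {
  # Monte Carlo over uniform random offsets; disc of radius 120 um
  ap <- 23470
  R <- 120
  reps <- 100000
  set.seed(101)
  off <- matrix(runif(2 * reps, 0, sqrt(ap)), ncol = 2)
  sp <- sqrt(ap)
  total <- 0
  ij <- expand.grid(i = -3:3, j = -3:3)
  for (r in seq_len(reps)) {
    gx <- off[r, 1] + ij$i * sp
    gy <- off[r, 2] + ij$j * sp
    total <- total + sum(gx^2 + gy^2 <= R^2)
  }
  expected <- pi * R^2 / ap
  expect_lt(abs(total / reps - expected) / expected, 0.005)
})

test_that("cycloid arcs have length l/p and sine-weighted tangents", {
  lp <- 100
  sys <- cycloid_system(lp, c(0, 500, 0, 500), seed = 3)
  expect_equal(sys$arc_scale, lp / 4) # half-arc length 4r = l/p
  arcs <- cycloid_arcs(sys)
  seg_len <- sqrt(diff(arcs$x[, 1])^2 + diff(arcs$y[, 1])^2)
  expect_lt(abs(sum(seg_len) - lp) / lp, 0.001)
  # refining the tolerance makes the rendered length error non-increasing
  errs <- vapply(c(0.5, 0.25, 0.125, 0.0625), function(tol) {
    s <- cycloid_system(lp, c(0, 500, 0, 500), seed = 3,
                        polyline_tolerance = tol)
    a <- cycloid_arcs(s)
    abs(sum(sqrt(diff(a$x[, 1])^2 + diff(a$y[, 1])^2)) - lp)
  }, 1)
  expect_true(all(diff(errs) <= 1e-12))

  # tangent angle from the vertical axis, length weighted over a dense
  # polyline, must follow the sin(psi) density on [0, pi/2]
  dense <- cycloid_system(lp, c(0, 500, 0, 500), seed = 3,
                          polyline_tolerance = 2e-6)
  a <- cycloid_arcs(dense)
  dx <- diff(a$x[, 1]); dy <- diff(a$y[, 1])
  w <- sqrt(dx^2 + dy^2)
  psi <- acos(pmin(1, abs(dy) / w)) # angle from vertical (y) axis
  breaks <- seq(0, pi / 2, length.out = 9)
  obs <- unname(tapply(w, cut(psi, breaks, include.lowest = TRUE), sum))
  obs[is.na(obs)] <- 0
  p_exp <- diff(1 - cos(breaks)) # integral of sin over each bin
  n_samp <- 1e6
  chi2 <- sum((obs / sum(w) * n_samp - p_exp * n_samp)^2 / (p_exp * n_samp))
  expect_gt(pchisq(chi2, df = length(p_exp) - 1, lower.tail = FALSE), 0.01)
})

test_that("cycloid pattern rotates rigidly with the vertical direction", {
  lp <- 80
  s0 <- cycloid_system(lp, c(-200, 200, -200, 200), offset = c(10, 5),
                       vertical = c(0, 1))
  al <- 0.7
  s1 <- cycloid_system(lp, c(-200, 200, -200, 200), offset = c(10, 5),
                       vertical = c(-sin(al), cos(al)))
  a0 <- cycloid_arcs(s0)
  a1 <- cycloid_arcs(s1)
  # rotate the unrotated arcs by al and compare vertex sets on a common arc
  rx <- cos(al) * a0$x - sin(al) * a0$y
  ry <- sin(al) * a0$x + cos(al) * a0$y
  key0 <- sort(round(as.vector(rx) + 1000 * as.vector(ry), 6))
  key1 <- sort(round(as.vector(a1$x) + 1000 * as.vector(a1$y), 6))
  common <- intersect(key0, key1)
  expect_gt(length(common) / length(key0), 0.8) # tiling margins may differ
})

test_that("total clipped arc length matches points-inside times l/p", {
  lp <- 100
  ext <- c(0, 3000, 0, 3000)
  for (seed in 1:3) {
    sys <- cycloid_system(lp, ext, seed = seed)
    pts <- cycloid_points(sys)
    inside <- pts$x >= ext[1] & pts$x < ext[2] &
      pts$y >= ext[3] & pts$y < ext[4]
    len <- cycloid_length_in(sys, ext)
    expect_lt(abs(len - sum(inside) * lp) / (sum(inside) * lp), 0.01)
  }
})

test_that("counting frames are congruent, disjoint and inside the region", {
  af <- 2700.28
  fs <- counting_frames(af, 6, c(0, 400, 0, 300), seed = 2)
  expect_equal(nrow(fs), 6)
  expect_equal(attr(fs, "n_frames"), 6L)
  expect_equal(unique(fs$width), sqrt(af)) # side 51.964...
  expect_equal(fs$width * fs$height, rep(af, 6))
  expect_true(all(fs$x0 >= 0 & fs$x0 + fs$width <= 400))
  expect_true(all(fs$y0 >= 0 & fs$y0 + fs$height <= 300))
  for (i in 1:5) for (j in (i + 1):6) {
    disjoint <- fs$x0[i] + fs$width[i] <= fs$x0[j] ||
      fs$x0[j] + fs$width[j] <= fs$x0[i] ||
      fs$y0[i] + fs$height[i] <= fs$y0[j] ||
      fs$y0[j] + fs$height[j] <= fs$y0[i]
    expect_true(disjoint)
  }

  empty <- counting_frames(af, 0, c(0, 10, 0, 10))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_frames"), 0L)

  err <- tryCatch(counting_frames(af, 2, c(0, 40, 0, 500)),
                  error = function(e) e)
  expect_s3_class(err, "stereojoint_infeasible")
  expect_match(conditionMessage(err), "width")
})

test_that("frame tiling counts every point exactly once (half-open rule)", {
  side <- 10
  frames <- tibble::tibble(
    frame = 1:9,
    x0 = rep(c(0, 10, 20), 3),
    y0 = rep(c(0, 10, 20), each = 3),
    width = side, height = side, area = side^2
  )
  set.seed(7)
  pattern <- tibble::tibble(
    x = c(runif(200, 0.001, 29.999), 10, 20, 10, 0.0001),
    y = c(runif(200, 0.001, 29.999), 10, 10, 20, 15),
    kind = "isolated", group_id = NA_integer_
  )
  per_frame <- vapply(1:9, function(i) {
    unname(count_in_frames(pattern, frames[i, ])["q_isolated"])
  }, 1L)
  # the tiling covers (0,30] x (0,30]; all constructed points are inside
  expect_equal(sum(per_frame), nrow(pattern))

  # the forbidden (left/bottom) edges exclude, acceptance (top/right) include
  one <- tibble::tibble(frame = 1L, x0 = 0, y0 = 0, width = 10, height = 10,
                        area = 100)
  on_left <- tibble::tibble(x = 0, y = 5, kind = "isolated",
                            group_id = NA_integer_)
  on_right <- tibble::tibble(x = 10, y = 5, kind = "isolated",
                             group_id = NA_integer_)
  on_bottom <- tibble::tibble(x = 5, y = 0, kind = "isolated",
                              group_id = NA_integer_)
  expect_equal(unname(count_in_frames(on_left, one)["q_isolated"]), 0L)
  expect_equal(unname(count_in_frames(on_bottom, one)["q_isolated"]), 0L)
  expect_equal(unname(count_in_frames(on_right, one)["q_isolated"]), 1L)

  overlapping <- tibble::tibble(frame = 1:2, x0 = c(0, 5), y0 = c(0, 5),
                                width = 10, height = 10, area = 100)
  expect_error(count_in_frames(on_left, overlapping),
               class = "stereojoint_invalid_parameter")
})

test_that("isogenous groups count once however many frames their members hit", {
  frames <- tibble::tibble(frame = 1:2, x0 = c(0, 20), y0 = 0,
                           width = 10, height = 10, area = 100)
  pattern <- tibble::tibble(
    x = c(5, 25, 5, 50), y = c(5, 5, 6, 5),
    kind = c("group", "group", "group", "group"),
    group_id = c(1L, 1L, 1L, 2L)
  )
  out <- count_in_frames(pattern, frames)
  expect_equal(unname(out["q_group_cells"]), 3L)
  expect_equal(unname(out["q_groups"]), 1L) # group 2 is outside all frames
})
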