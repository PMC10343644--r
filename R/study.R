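#' Configuration of a synthetic five-group study
#'
#' Bundles the design of the simulated arthritis study: group labels,
#' specimens per group, probe constants, phantom calibration, CE
#' prediction settings and phantom shape options.
#'
#' @param groups Ordered group labels.
#' @param n_per_group Specimens per group.
#' @param probes A [probe_set()].
#' @param calibration Group calibration tibble
#'   ([default_group_calibration()]).
#' @param ce A [ce_control()].
#' @param axis_scale,villosity Phantom shape options, see
#'   [joint_phantom()].
#' @param sd_scale Multiplier on calibration SDs (0 = deterministic
#'   group-mean phantoms).
#' @param offspring_mean,cluster_radius Chondrocyte group geometry.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups = c("Arthritis", "LNC", "Diclofenac",
                                    "Diclofenac-LNC", "No Arthritis"),
                         n_per_group = 4,
                         probes = probe_set(),
                         calibration = default_group_calibration(),
                         ce = ce_control(),
                         axis_scale = 1, villosity = NULL, sd_scale = 1,
                         offspring_mean = 2.5, cluster_radius = 15) {
  if (length(groups) == 0 || anyDuplicated(groups)) {
    abort_invalid("`groups` must be non-empty and unique.")
  }
  if (n_per_group < 1 || n_per_group != round(n_per_group)) {
    abort_invalid("`n_per_group` must be a positive integer.")
  }
  missing <- setdiff(groups, calibration$group)
  if (length(missing) > 0) {
    abort_invalid(paste0("groups missing from calibration: ",
                         paste(missing, collapse = ", ")))
  }
  structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         probes = probes, calibration = calibration, ce = ce,
         axis_scale = axis_scale, villosity = villosity,
         sd_scale = sd_scale, offspring_mean = offspring_mean,
         cluster_radius = cluster_radius),
    class = "study_config"
  )
}

#' Simulate a whole study
#'
#' Draws a calibrated phantom per specimen and runs the full virtual
#' counting protocol, producing one combined counts table plus per-specimen
#' ground truth. Fully reproducible from `seed` via hierarchical stream
#' splitting.
#'
#' @param config A [study_config()].
#' @param seed Master seed.
#' @param measure Probes to run, see [simulate_specimen()].
#' @return An object of class `stereo_study`: list with `counts` (all
#'   specimens), `truth` (tibble of true volumes/surfaces per specimen),
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = study_config(), seed = 1,
                           measure = c("points", "surfaces", "cells")) {
  stopifnot(inherits(config, "study_config"))
  measure <- match.arg(measure, several.ok = TRUE)
  counts <- list()
  truth <- list()
  k <- 0L
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    for (i in seq_len(config$n_per_group)) {
      k <- k + 1L
      sp_seed <- child_seed(seed, gi * 1000L + i)
      cal <- calibrate_phantom(
        g, config$calibration, seed = child_seed(sp_seed, 7),
        axis_scale = config$axis_scale, villosity = config$villosity,
        sd_scale = config$sd_scale, offspring_mean = config$offspring_mean,
        cluster_radius = config$cluster_radius
      )
      sim <- simulate_specimen(
        cal$phantom, config$probes, cal$cell_params,
        specimen_id = sprintf("%s-%02d", g, i), group = g,
        seed = sp_seed, measure = measure, include_truth = TRUE
      )
      counts[[k]] <- sim$counts
      truth[[k]] <- tibble::tibble(
        specimen_id = sprintf("%s-%02d", g, i), group = g,
        !!!as.list(stats::setNames(
          sim$truth$volume_mm3,
          paste0("true_vol_", names(sim$truth$volume_mm3), "_mm3"))),
        true_surf_cartilage_mm2 = sim$truth$surface_mm2[["cartilage"]],
        true_surf_synovial_membrane_mm2 =
          sim$truth$surface_mm2[["synovial_membrane"]],
        true_lambda_isolated_mm2 = cal$cell_params$lambda_isolated,
        true_lambda_parents_mm2 = cal$cell_params$lambda_parents
      )
    }
  }
  structure(
    list(counts = dplyr::bind_rows(counts), truth = dplyr::bind_rows(truth),
         config = config, seed = seed),
    class = "stereo_study"
  )
}

#' Read and write per-section counts tables
#'
#' The counts CSV carries one row per section with the raw counts only;
#' probe constants come from the study configuration and are attached as
#' columns on read. `write_counts()` writes the schema columns,
#' deterministically.
#'
#' @param path CSV file path.
#' @param probes A [probe_set()] supplying the constants.
#' @return `read_counts()`: validated counts tibble.
#' @export
read_counts <- function(path, probes = probe_set()) {
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(counts_schema(), names(counts))
  if (length(missing) > 0) {
    abort_invalid(paste0("counts CSV is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  counts <- counts[counts_schema()]
  counts$t_spacing_um <- probes$t_spacing_um
  counts$area_per_point_um2 <- probes$area_per_point_um2
  counts$length_per_point_um <- probes$length_per_point_um
  counts$frame_area_um2 <- probes$frame_area_um2
  validate_counts(counts)
}

#' @rdname read_counts
#' @param counts Counts tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_csv(counts[counts_schema()], path, progress = FALSE)
  invisible(path)
}

#' Estimate every specimen of a counts table
#'
#' Thin orchestration over [estimate_specimens()]: accepts a counts tibble
#' or a CSV path, validates it, and returns the estimates table. An empty
#' table yields an empty result with a warning rather than an error.
#'
#' @param counts Counts tibble or path to a counts CSV.
#' @param config A [study_config()] supplying probe constants (for CSV
#'   input) and CE settings.
#' @return Estimates tibble, one row per specimen.
#' @export
run_estimation <- function(counts, config = study_config()) {
  if (is.character(counts)) {
    counts <- read_counts(counts, config$probes)
  }
  if (nrow(counts) == 0) {
    rlang::warn("counts table is empty; returning empty estimates.")
    return(tibble::tibble())
  }
  estimate_specimens(counts, ce = config$ce)
}

summary_quantities <- function() {
  c("volume_mm3",
    paste0("vol_", c("cartilage", "bone", "capsule", "synovial_space",
                     "synovial_membrane"), "_mm3"),
    "surf_cartilage_mm2", "surf_synovial_membrane_mm2",
    "nv_isolated_mm2", "nv_isogenous_groups_mm2", "nv_total_mm2")
}

#' Group means and standard deviations of the estimates
#'
#' Mean, SD (n - 1 denominator) and n per group for the joint and component
#' volumes, the two surface areas and the chondrocyte densities, in the
#' familiar published-table order. Groups with a single specimen report
#' `NA` SD (with a warning), not 0.
#'
#' @param estimates Estimates tibble from [estimate_specimens()].
#' @return A tibble of class `stereo_group_summary`: `quantity`, `group`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(estimates) {
  qs <- intersect(summary_quantities(), names(estimates))
  out <- estimates |>
    tidyr::pivot_longer(dplyr::all_of(qs), names_to = "quantity",
                        values_to = "value") |>
    dplyr::group_by(.data$quantity, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(quantity = factor(.data$quantity, levels = qs)) |>
    dplyr::arrange(.data$quantity) |>
    dplyr::mutate(quantity = as.character(.data$quantity))
  if (any(out$n == 1)) {
    rlang::warn("groups with a single specimen: SD reported as NA.")
  }
  class(out) <- c("stereo_group_summary", class(out))
  out
}

sidak_adjust <- function(p, m) {
  pmin(1, 1 - (1 - pmin(p, 1))^m)
}

# Brown-Forsythe one-way test statistic F* with Satterthwaite-type df.
brown_forsythe_anova <- function(values, groups) {
  gs <- split(values, groups)
  ni <- vapply(gs, length, 1L)
  mi <- vapply(gs, mean, 1)
  vi <- vapply(gs, stats::var, 1)
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  num <- sum(ni * (mi - grand)^2)
  wi <- (1 - ni / N) * vi
  den <- sum(wi)
  if (den == 0) {
    return(list(statistic = if (num == 0) 0 else Inf,
                df1 = length(ni) - 1, df2 = Inf,
                p_value = if (num == 0) 1 else 0))
  }
  fstar <- num / den
  ci <- wi / den
  df2 <- 1 / sum(ci^2 / (ni - 1))
  df1 <- length(ni) - 1
  list(statistic = fstar, df1 = df1, df2 = df2,
       p_value = stats::pf(fstar, df1, df2, lower.tail = FALSE))
}

welch_pair <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    return(list(estimate = diff, statistic = if (diff == 0) 0 else Inf,
                df = nx + ny - 2,
                p = if (diff == 0) 1 else 0))
  }
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(estimate = diff, statistic = tt, df = df,
       p = 2 * stats::pt(-abs(tt), df))
}

#' Compare a quantity across study groups
#'
#' The study's standard inferential battery: one-way ANOVA with Sidak
#' multiple-comparison adjustment when group variances look homogeneous,
#' the Brown-Forsythe heteroscedastic one-way test with Dunnett-T3-type
#' pairwise comparisons (Welch t with a Sidak-type correction approximating
#' the studentized maximum modulus) otherwise, or pairwise Mann-Whitney
#' tests. In `"auto"` mode a Bartlett variance-homogeneity diagnostic at
#' alpha = 0.05 selects between the first two.
#'
#' @param estimates Estimates tibble from [estimate_specimens()].
#' @param quantity Column of `estimates` to compare.
#' @param method `"auto"`, `"anova_sidak"`,
#'   `"brown_forsythe_dunnett_t3"` or `"mann_whitney"`.
#' @return An object of class `stereo_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @export
compare_groups <- function(estimates, quantity,
                           method = c("auto", "anova_sidak",
                                      "brown_forsythe_dunnett_t3",
                                      "mann_whitney")) {
  method <- match.arg(method)
  if (!quantity %in% names(estimates)) {
    abort_invalid(sprintf("quantity '%s' is not a column of the estimates.",
                          quantity))
  }
  df <- estimates[!is.na(estimates[[quantity]]), c("group", quantity)]
  names(df) <- c("group", "value")
  ni <- table(df$group)
  if (length(ni) < 2) {
    abort_invalid("at least two groups are required.")
  }
  if (any(ni < 2)) {
    abort_invalid(paste0("insufficient data (n < 2) in group(s): ",
                         paste(names(ni)[ni < 2], collapse = ", ")))
  }
  groups <- names(ni)
  gs <- split(df$value, df$group)

  # variance-homogeneity diagnostic (degenerate all-equal groups pass)
  bart <- tryCatch(stats::bartlett.test(df$value, factor(df$group)),
                   error = function(e) NULL)
  hom_p <- if (is.null(bart) || is.na(bart$p.value)) 1 else bart$p.value
  used <- if (method == "auto") {
    if (hom_p < 0.05) "brown_forsythe_dunnett_t3" else "anova_sidak"
  } else {
    method
  }

  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  pw <- vector("list", m)

  if (used == "anova_sidak") {
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    omnibus <- list(statistic = an[["F value"]][1], df1 = an[["Df"]][1],
                    df2 = an[["Df"]][2],
                    p_value = an[["Pr(>F)"]][1])
    mse <- an[["Mean Sq"]][2]
    dfe <- an[["Df"]][2]
    for (j in seq_len(m)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      diff <- mean(gs[[a]]) - mean(gs[[b]])
      se <- sqrt(mse * (1 / length(gs[[a]]) + 1 / length(gs[[b]])))
      if (se == 0) {
        tt <- if (diff == 0) 0 else Inf
        p <- if (diff == 0) 1 else 0
      } else {
        tt <- diff / se
        p <- 2 * stats::pt(-abs(tt), dfe)
      }
      pw[[j]] <- tibble::tibble(group1 = a, group2 = b, estimate = diff,
                                statistic = tt, df = dfe, p_value = p)
    }
  } else if (used == "brown_forsythe_dunnett_t3") {
    omnibus <- brown_forsythe_anova(df$value, df$group)
    for (j in seq_len(m)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      wp <- welch_pair(gs[[a]], gs[[b]])
      pw[[j]] <- tibble::tibble(group1 = a, group2 = b,
                                estimate = wp$estimate,
                                statistic = wp$statistic, df = wp$df,
                                p_value = wp$p)
    }
  } else {
    kw <- stats::kruskal.test(df$value, factor(df$group))
    omnibus <- list(statistic = unname(kw$statistic),
                    df1 = unname(kw$parameter), df2 = NA_real_,
                    p_value = kw$p.value)
    for (j in seq_len(m)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      wt <- suppressWarnings(stats::wilcox.test(gs[[a]], gs[[b]],
                                                exact = FALSE))
      pw[[j]] <- tibble::tibble(group1 = a, group2 = b,
                                estimate = stats::median(gs[[a]]) -
                                  stats::median(gs[[b]]),
                                statistic = unname(wt$statistic),
                                df = NA_real_, p_value = wt$p.value)
    }
  }
  pairwise <- dplyr::bind_rows(pw)
  pairwise$p_adjusted <- sidak_adjust(pairwise$p_value, m)
  structure(
    list(quantity = quantity, method_requested = method, method_used = used,
         homogeneity = list(test = "bartlett", p_value = hom_p),
         omnibus = omnibus, pairwise = pairwise,
         groups = groups, n = as.integer(ni)),
    class = "stereo_comparison"
  )
}

#' @export
print.stereo_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s)\n", x$quantity, x$method_used))
  cat(sprintf("  omnibus: stat = %.4g, p = %.4g; Bartlett p = %.4g\n",
              x$omnibus$statistic, x$omnibus$p_value, x$homogeneity$p_value))
  print(x$pairwise, ...)
  invisible(x)
}

#' Section-reduction efficiency report
#'
#' For each reduction step k, subsamples every k-th section over all k
#' starts, and reports per specimen the mean subsampled Cavalieri volume
#' (whose mean over starts equals the full-section volume exactly), the
#' mean predicted CE, and the empirical CE across starts (SD/mean of the
#' subsampled volumes; `NA` at k = 1, which has a single start). Steps
#' exceeding a specimen's section count are skipped with a warning.
#'
#' @param counts Per-section counts table (pilot-style specimens with many
#'   sections).
#' @param steps Integer reduction steps k.
#' @param ce A [ce_control()].
#' @return A tibble of class `stereo_reduction`: `specimen_id`, `step`,
#'   `n_sections`, `volume_mm3`, `predicted_ce`, `empirical_ce`.
#' @export
reduction_report <- function(counts, steps = c(1, 2, 3), ce = ce_control()) {
  counts <- validate_counts(counts)
  rows <- list()
  for (k in sort(unique(as.integer(steps)))) {
    n_avail <- counts |>
      dplyr::count(.data$specimen_id) |>
      dplyr::pull(.data$n)
    if (k > min(n_avail)) {
      rlang::warn(sprintf("step %d exceeds the section count; skipped.", k))
      next
    }
    per_start <- lapply(seq_len(k) - 1L, function(s) {
      sub <- subsample_sections(counts, k, s)
      vol <- cavalieri_volume(sub)
      pce <- tryCatch(predicted_ce(sub, ce)[c("specimen_id", "ce")],
                      error = function(e) NULL)
      out <- vol[c("specimen_id", "n_sections", "volume_mm3")]
      out$ce <- if (is.null(pce)) NA_real_ else {
        pce$ce[match(out$specimen_id, pce$specimen_id)]
      }
      out
    })
    all_starts <- dplyr::bind_rows(per_start)
    rows[[length(rows) + 1L]] <- all_starts |>
      dplyr::group_by(.data$specimen_id) |>
      dplyr::summarise(
        step = k,
        n_sections = mean(.data$n_sections),
        empirical_ce = if (k > 1) {
          stats::sd(.data$volume_mm3) / mean(.data$volume_mm3)
        } else NA_real_,
        volume_mm3 = mean(.data$volume_mm3),
        predicted_ce = mean(.data$ce),
        .groups = "drop"
      ) |>
      dplyr::relocate("empirical_ce", .after = "predicted_ce")
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stereo_reduction", class(out))
  out
}
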