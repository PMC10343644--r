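# Fixtures and independent brute-force oracles used across the suite.
# The oracles re-derive every estimator by explicit row-wise summation so
# the package's grouped/vectorized code path is checked against a second,
# independent implementation.

blank_counts_row <- function(specimen_id, group, section_index) {
  tibble::tibble(
    specimen_id = specimen_id, group = group, section_index = section_index,
    p_ref = 0L, p_cartilage = 0L, p_bone = 0L, p_capsule = 0L,
    p_synovial_space = 0L, p_synovial_membrane = 0L,
    i_cartilage = 0L, i_synovial_membrane = 0L,
    q_isolated = 0L, q_group_cells = 0L, q_groups = 0L, frames_used = 0L,
    t_spacing_um = 50, area_per_point_um2 = 23470,
    length_per_point_um = 100, frame_area_um2 = 2700.28
  )
}

# counts table with given per-section reference counts (other counts zero
# unless overridden)
make_counts <- function(p_ref, specimen_id = "s1", group = "g1", ...) {
  n <- length(p_ref)
  df <- dplyr::bind_rows(lapply(seq_len(n) - 1L, function(i) {
    blank_counts_row(specimen_id, group, i)
  }))
  df$p_ref <- as.integer(p_ref)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# random valid counts table for one specimen
random_counts <- function(specimen_id, n_sections, rng) {
  p_ref <- rpois(n_sections, 60)
  split_counts <- function(total) {
    # random partition of `total` over the five components
    if (total == 0) return(rep(0L, 5))
    as.integer(rmultinom(1, total, prob = runif(5) + 0.1))
  }
  parts <- vapply(p_ref, split_counts, integer(5))
  q_groups <- rpois(n_sections, 2)
  make_counts(
    p_ref, specimen_id = specimen_id,
    p_bone = parts[1, ], p_cartilage = parts[2, ],
    p_synovial_space = parts[3, ], p_synovial_membrane = parts[4, ],
    p_capsule = parts[5, ],
    i_cartilage = rpois(n_sections, 10),
    i_synovial_membrane = rpois(n_sections, 5),
    q_isolated = rpois(n_sections, 20),
    q_group_cells = q_groups * 2L + rpois(n_sections, 3),
    q_groups = q_groups,
    frames_used = pmax(1L, rpois(n_sections, 5))
  )
}

# ---- brute-force oracles (explicit loops over rows) ----

oracle_volume <- function(counts) {
  tot <- 0
  for (i in seq_len(nrow(counts))) {
    tot <- tot + counts$p_ref[i] * counts$t_spacing_um[i] *
      counts$area_per_point_um2[i]
  }
  tot / 1e9
}

oracle_ce <- function(counts, shape = 2 * sqrt(pi),
                      variant = "gundersen_noise") {
  P <- 0
  for (i in seq_len(nrow(counts))) P <- P + counts$p_ref[i]
  n <- nrow(counts)
  if (variant == "gundersen_noise") {
    sqrt(0.0724 * shape * sqrt(n) / P^(3 / 2))
  } else {
    0.0724 * shape * sqrt(n / P)
  }
}

oracle_vv <- function(counts, component) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(counts))) {
    num <- num + counts[[paste0("p_", component)]][i]
    den <- den + counts$p_ref[i]
  }
  num / den
}

oracle_sv_mm1 <- function(counts, surface) {
  si <- 0
  sp <- 0
  for (i in seq_len(nrow(counts))) {
    si <- si + counts[[paste0("i_", surface)]][i]
    sp <- sp + counts$p_ref[i]
  }
  2 * si / (sp * counts$length_per_point_um[1]) * 1e3
}

oracle_density_mm2 <- function(counts, col) {
  q <- 0
  f <- 0
  for (i in seq_len(nrow(counts))) {
    q <- q + counts[[col]][i]
    f <- f + counts$frames_used[i]
  }
  q / (f * counts$frame_area_um2[1]) * 1e6
}
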