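# Internal helpers: classed errors, rectangles, reproducible sub-seeds.

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "stereojoint_invalid_parameter", ...)
}

abort_infeasible <- function(msg, ...) {
  rlang::abort(msg, class = "stereojoint_infeasible", ...)
}

abort_undefined <- function(msg, ...) {
  rlang::abort(msg, class = "stereojoint_undefined", ...)
}

# A rectangle is c(xmin, xmax, ymin, ymax) in micrometres.
as_rect <- function(extent, what = "extent") {
  if (!is.numeric(extent) || length(extent) != 4L || anyNA(extent)) {
    abort_invalid(sprintf("`%s` must be numeric c(xmin, xmax, ymin, ymax).", what))
  }
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    abort_invalid(sprintf("`%s` is degenerate: xmax > xmin and ymax > ymin required.", what))
  }
  unname(extent)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}

# Deterministic seed derivation so the RNG stream splits hierarchically
# (study -> specimen -> section -> probe): adding sections or probes never
# perturbs draws made elsewhere. Two rounds of a Lehmer-style mix keep all
# intermediates below 2^53 so the arithmetic is exact in doubles.
child_seed <- function(seed, key) {
  m <- 2147483629
  x <- (as.numeric(seed) %% m) * 69069 + as.numeric(key) %% m + 1234567
  x <- x %% m
  x <- (x * 69069 + 69) %% m
  as.integer(x + 1)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

UM3_PER_MM3 <- 1e9
UM2_PER_MM2 <- 1e6

#' Compartment and surface labels
#'
#' `joint_components()` lists the five joint compartments innermost first
#' (matching the membership codes of [phantom_membership()]);
#' `joint_surfaces()` lists the two tracked interfaces: the cartilage edge
#' in contact with the synovial space, and the synovial membrane inner
#' boundary.
#'
#' @return Character vector of labels.
#' @export
joint_components <- function() {
  c("bone", "cartilage", "synovial_space", "synovial_membrane", "capsule")
}

#' @rdname joint_components
#' @export
joint_surfaces <- function() {
  c("cartilage", "synovial_membrane")
}
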