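# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit. All exported functions that consume randomness take an explicit
# `seed` argument and route through this helper, so no generator ever
# touches global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Euclidean distance between rows of an n x 2 coordinate matrix and a
# single point.
dist_to_point <- function(xy, p) {
  sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
}

# Total length of a polyline given as an n x 2 matrix.
polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Close a polyline (append the first vertex) unless already closed.
close_polyline <- function(xy) {
  if (!isTRUE(all.equal(xy[1, ], xy[nrow(xy), ], check.attributes = FALSE))) {
    xy <- rbind(xy, xy[1, ])
  }
  xy
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be positive", call. = FALSE)
  }
  invisible(x)
}
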