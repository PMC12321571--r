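#' Migratory stream path
#'
#' An ordered open polyline tracing a migratory stream (e.g. from the
#' subventricular Arc out to a cortical region), used to order cells
#' topographically along the stream.
#'
#' @param vertices n x 2 numeric matrix of polyline vertices in pixels
#'   (>= 2 rows); consecutive duplicate vertices are not allowed.
#' @return Object of class `stream_path` with the cumulative arc length in
#'   element `cumlen`.
#' @export
stream_path <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 2L) {
    stop("`vertices` must be an n x 2 matrix with n >= 2", call. = FALSE)
  }
  seg <- sqrt(rowSums(diff(v)^2))
  if (any(seg == 0)) {
    stop("degenerate path: consecutive vertices coincide", call. = FALSE)
  }
  structure(
    list(vertices = v, seglen = seg, cumlen = c(0, cumsum(seg)),
         total = sum(seg)),
    class = "stream_path"
  )
}

#' Project cells onto a migratory stream path
#'
#' Maps each cell to its nearest point on the stream polyline and reports
#' the normalized arc-length position in \[0, 1\] (0 = start of the path,
#' near the Arc; 1 = the far cortical end) together with the perpendicular
#' offset from the path. The offset is signed by the side of the local
#' segment (positive to the left of the direction of travel).
#'
#' @param cells A `cell_map` or data frame with columns `x` and `y`.
#' @param path A [stream_path()].
#' @return Data frame with columns `cell_id` (if available), `position`
#'   in \[0, 1\] and `offset` in pixels (signed perpendicular distance).
#' @export
map_to_stream <- function(cells, path) {
  stopifnot(inherits(path, "stream_path"))
  v <- path$vertices
  n_seg <- nrow(v) - 1L
  pos <- numeric(nrow(cells)); off <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- c(cells$x[i], cells$y[i])
    best <- c(dist = Inf, arc = 0, side = 0)
    for (s in seq_len(n_seg)) {
      a <- v[s, ]; b <- v[s + 1L, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      q <- a + t * ab
      dq <- sqrt(sum((p - q)^2))
      if (dq < best["dist"]) {
        cross <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
        best <- c(dist = dq, arc = path$cumlen[s] + t * path$seglen[s],
                  side = sign(cross))
      }
    }
    pos[i] <- best["arc"] / path$total
    off[i] <- best["dist"] * ifelse(best["side"] == 0, 1, best["side"])
  }
  out <- data.frame(position = pos, offset = off)
  if (!is.null(cells$cell_id)) out <- cbind(cell_id = cells$cell_id, out)
  out
}
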