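# Independent brute-force oracles. These deliberately use plain loops and
# textbook formulas, sharing no code with the package implementation.

# Exhaustive Renyi-entropy threshold on the 256-bin histogram: direct
# per-order search plus the ordering-and-weighting blend, all written out
# naively. Returns the selected 0-based bin.
oracle_renyi_bin <- function(image, alpha_set = c(0.5, 1, 2)) {
  v <- as.numeric(image)
  rng <- range(v)
  bw <- (rng[2] - rng[1]) / 256
  bins <- pmin(floor((v - rng[1]) / bw), 255)
  p <- tabulate(bins + 1L, 256L) / length(v)
  P1 <- cumsum(p)
  first <- which(P1 > .Machine$double.eps)[1] - 1L
  last <- max(which((1 - P1) > .Machine$double.eps)) - 1L

  split_for <- function(a) {
    best <- -Inf; bt <- first
    for (t in first:last) {
      lo <- p[1:(t + 1)]
      hi <- p[(t + 2):256]
      lo <- lo[lo > 0] / P1[t + 1]
      hi <- hi[hi > 0] / (1 - P1[t + 1])
      H <- if (a == 1) {
        -sum(lo * log(lo)) - sum(hi * log(hi))
      } else {
        (log(sum(lo^a)) + log(sum(hi^a))) / (1 - a)
      }
      if (H > best) { best <- H; bt <- t }
    }
    bt
  }
  ts <- sort(vapply(alpha_set, split_for, numeric(1)))
  if (length(ts) == 1L) return(as.integer(ts))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  b <- if (abs(t1 - t2) <= 5 && abs(t2 - t3) <= 5) c(1, 2, 1)
       else if (abs(t1 - t2) <= 5) c(0, 1, 3)
       else if (abs(t2 - t3) <= 5) c(3, 1, 0)
       else c(1, 2, 1)
  om <- P1[t3 + 1] - P1[t1 + 1]
  as.integer(floor(
    t1 * (P1[t1 + 1] + 0.25 * om * b[1]) +
      0.25 * t2 * om * b[2] +
      t3 * (1 - P1[t3 + 1] + 0.25 * om * b[3])
  ))
}

# All-pairs neighbor edges by a double loop (strict < threshold).
oracle_edges <- function(cells, threshold) {
  n <- nrow(cells)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d < threshold) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Mean count of B-neighbors per A-cell by direct tallying.
oracle_interaction_stat <- function(cells, labels, pair, threshold) {
  idx_a <- which(labels == pair[1])
  if (length(idx_a) == 0) return(NA_real_)
  total <- 0
  for (i in idx_a) {
    for (j in seq_len(nrow(cells))) {
      if (j == i || labels[j] != pair[2]) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d < threshold) total <- total + 1
    }
  }
  total / length(idx_a)
}

# Fixed seed base shared by the suite's generated fixtures.
fixture_seed <- 20260927L
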