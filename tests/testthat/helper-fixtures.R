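# Geometry fixtures and small independent oracles shared across tests.

disk_ring <- function(cx, cy, r, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polygon_ring(cx + r * cos(th), cy + r * sin(th))
}

square_ring <- function(x0, y0, side) {
  polygon_ring(c(x0, x0 + side, x0 + side, x0),
               c(y0, y0, y0 + side, y0 + side))
}

# random simple star-shaped polygon around a center
random_blob <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rr <- r * (1 + 0.25 * sin(3 * th + runif(1, 0, 2 * pi)) +
               0.12 * cos(5 * th + runif(1, 0, 2 * pi)))
  polygon_ring(cx + rr * cos(th), cy + rr * sin(th))
}

# independent shoelace oracle, written as the explicit vertex loop
shoelace_oracle <- function(ring) {
  n <- length(ring$x)
  acc <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    acc <- acc + ring$x[i] * ring$y[j] - ring$x[j] * ring$y[i]
  }
  abs(acc) / 2
}

# brute-force min distance to boundary: boundary densely resampled at `step`
brute_boundary_distance <- function(px, py, mp, step = 0.01) {
  bx <- numeric(0)
  by <- numeric(0)
  for (ring in mp) {
    n <- length(ring$x)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      len <- sqrt((ring$x[j] - ring$x[i])^2 + (ring$y[j] - ring$y[i])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      bx <- c(bx, ring$x[i] + t * (ring$x[j] - ring$x[i]))
      by <- c(by, ring$y[i] + t * (ring$y[j] - ring$y[i]))
    }
  }
  vapply(seq_along(px), function(k) {
    sqrt(min((bx - px[k])^2 + (by - py[k])^2))
  }, numeric(1))
}

# naive product-limit oracle
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_i <- sum(time >= ut[i])
    d_i <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# two-group log-rank oracle by explicit risk-set enumeration
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
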