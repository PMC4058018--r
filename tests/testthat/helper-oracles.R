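# Independent oracles and small fixture builders used across tests.

# exhaustive intermeans fixed-point scan: all t in 0..254 satisfying
# t == round((mean(<=t) + mean(>t)) / 2)
isodata_fixed_points <- function(h) {
  v <- 0:255
  Filter(function(t) {
    lo <- v <= t
    sb <- sum(h[lo]); sa <- sum(h[!lo])
    if (sb == 0 || sa == 0) return(FALSE)
    round((sum(v[lo] * h[lo]) / sb + sum(v[!lo] * h[!lo]) / sa) / 2) == t
  }, 0:254)
}

random_bimodal_hist <- function() {
  m1 <- sample(20:90, 1); m2 <- sample(120:240, 1)
  vals <- c(round(rnorm(400, m1, 10)), round(rnorm(300, m2, 15)))
  tabulate(pmin(255L, pmax(0L, as.integer(vals))) + 1L, 256L)
}

# digital shapes
disk_mask <- function(r, pad = 6) {
  d <- 2 * r + 2 * pad + 1
  cx <- r + pad + 1
  m <- matrix(0, d, d)
  m[(row(m) - cx)^2 + (col(m) - cx)^2 <= r^2] <- 1
  m
}
ellipse_mask <- function(a, b, pad = 6) {
  d <- 2 * max(a, b) + 2 * pad + 1
  cx <- max(a, b) + pad + 1
  m <- matrix(0, d, d)
  m[((row(m) - cx) / a)^2 + ((col(m) - cx) / b)^2 <= 1] <- 1
  m
}
square_mask <- function(s, pad = 6) {
  m <- matrix(0, s + 2 * pad, s + 2 * pad)
  m[pad + seq_len(s), pad + seq_len(s)] <- 1
  m
}

# brute-force exact Mann-Whitney two-sided p by enumerating every labeling
mw_enumerate <- function(a, b) {
  pooled <- c(a, b); m <- length(a); N <- length(pooled)
  r <- rank(pooled)
  robs <- sum(r[seq_len(m)])
  sums <- apply(utils::combn(N, m), 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  lo <- mean(sums <= robs + eps); hi <- mean(sums >= robs - eps)
  min(1, 2 * min(lo, hi))
}

# Breslow log partial likelihood for a single covariate (distinct or tied
# event times), used as a grid-search oracle for the Cox fit
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in unique(times[events])) {
    d <- which(times == t & events)
    risk <- which(times >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# hand log-rank statistic from the observed-minus-expected table
logrank_oracle <- function(times, events, group) {
  g <- as.integer(as.factor(group))
  o1 <- 0; e1 <- 0; v1 <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v1
}

# a hand-built single-nucleus FOV for measurement edge cases
tiny_fov <- function(nr = 40, nc = 40, cr = 20, cc = 20, r = 6,
                     green_bg = 8) {
  dapi <- matrix(0L, nr, nc)
  sel <- (row(dapi) - cr)^2 + (col(dapi) - cc)^2 <= r^2
  dapi[sel] <- 200L
  structure(list(channels = list(dapi = dapi,
                                 red = matrix(0L, nr, nc),
                                 green = matrix(as.integer(green_bg), nr, nc)),
                 fov_index = 1L, grid_pos = c(1L, 1L)),
            class = "fov_image")
}
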