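# shared fixtures and independent oracles

# build a sample table quickly; valid recycles over rows
make_samples <- function(t, x, y, valid = TRUE, pupil = NA_real_) {
  n <- length(t)
  data.frame(t = t, x = rep_len(x, n), y = rep_len(y, n),
             valid_left = rep_len(valid, n), valid_right = rep_len(valid, n),
             pupil_left = rep_len(pupil, n), pupil_right = rep_len(pupil, n))
}

# 100x100 screen, AOI "A" = left strip, AOI "B" = right strip, two blocks
# with pathway A then B
tiny_spec <- function(duration_ms = 1000, pathway = c("A", "B")) {
  a <- aoi_region("A", rbind(c(0, 0), c(40, 0), c(40, 100), c(0, 100)))
  b <- aoi_region("B", rbind(c(60, 0), c(100, 0), c(100, 100), c(60, 100)))
  half <- duration_ms / 2
  stimulus_spec("tiny", 100, 100, duration_ms, list(a, b),
                list(time_block(1, 0, half, pathway[1]),
                     time_block(2, half, duration_ms, pathway[2])))
}

tiny_recording <- function(t, x, y, valid = TRUE, subject = "s1",
                           stimulus = "tiny") {
  gaze_recording(subject, stimulus, make_samples(t, x, y, valid))
}

# plain even-odd ray casting with an explicit on-edge check; the
# boundary-inclusive oracle for point-in-polygon
ray_cast_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  on_edge <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
      cross <- (x - x1) * (y2 - y1) - (y - y1) * (x2 - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_edge(x, y)) return(TRUE)
    inside <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# random simple polygon: star-shaped around a center, hence non-self-
# intersecting by construction
random_simple_polygon <- function(nv = sample(3:8, 1), cx = 50, cy = 50) {
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, 5, 45)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# per-sample brute-force switch counter: walk the sequence, remember the
# last AOI seen, count every change (no debouncing)
asc_loop_oracle <- function(labels) {
  non_aoi <- c("VACANT", "OFFSCREEN", "INVALID")
  last <- NA_character_
  cnt <- 0L
  for (lab in labels) {
    if (lab %in% non_aoi) next
    if (!is.na(last) && lab != last) cnt <- cnt + 1L
    last <- lab
  }
  cnt
}

# exact two-sided rank-sum p by enumerating all group assignments
rank_sum_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  min(1, p)
}

# normal-approximation rank-sum p with tie-corrected variance and
# continuity correction, coded independently of stats::wilcox.test
rank_sum_normal_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

# random row-stochastic 4x4 matrix (normalised gamma draws)
random_transition <- function() {
  m <- matrix(stats::rgamma(16, shape = 1), 4, 4)
  m / rowSums(m)
}

# integrated-autocovariance standard error of state occupancy for a
# stationary Markov chain, from matrix powers of P
occupancy_se_oracle <- function(P, state, n, kmax = 5000) {
  pi <- markov_stationary(P)
  p <- pi[state]
  var_sum <- p * (1 - p)
  Pk <- P
  for (k in seq_len(kmax)) {
    ck <- p * (Pk[state, state] - p)
    var_sum <- var_sum + 2 * ck
    if (abs(ck) < 1e-13 && k > 10) break
    Pk <- Pk %*% P
  }
  sqrt(var_sum / n)
}
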