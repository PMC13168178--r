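# Shared fixtures (analytic masks) and independent oracles used across the
# suite. Oracles are deliberately written as direct enumerations, separate
# from the package's vectorized implementations.

make_disk <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1L
}

make_ellipse_mask <- function(n, a, b, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  (((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1) * 1L
}

# Star: sinusoidally perturbed disk, `lobes` lobes of relative amplitude amp.
make_star <- function(n, r, amp = 0.3, lobes = 4, cx = (n + 1) / 2,
                      cy = (n + 1) / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  th <- atan2(ys - cy, xs - cx)
  rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
  (rad <= r * (1 + amp * sin(lobes * th))) * 1L
}

# Noiseless points sampled on an analytic ellipse.
ellipse_points <- function(a, b, angle_deg = 0, cx = 0, cy = 0, n = 180) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  phi <- angle_deg * pi / 180
  tibble::tibble(
    x = cx + a * cos(t) * cos(phi) - b * sin(t) * sin(phi),
    y = cy + a * cos(t) * sin(phi) + b * sin(t) * cos(phi))
}

# Brute-force symmetric GLCM statistics via explicit pixel-pair enumeration.
glcm_oracle <- function(gray, mask, levels, angle) {
  q <- pmin(floor(pmax(pmin(gray, 1), 0) * levels), levels - 1)
  off <- round(c(-sin(angle * pi / 180), cos(angle * pi / 180)))
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
      if (mask[i, j] != 1 || mask[i2, j2] != 1) next
      a <- q[i, j] + 1; b <- q[i2, j2] + 1
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  if (sum(P) > 0) P <- P / sum(P)
  lv <- 0:(levels - 1)
  X <- matrix(lv, levels, levels); Y <- t(X)
  mu_x <- sum(X * P); mu_y <- sum(Y * P)
  s_x <- sqrt(sum(P * (X - mu_x)^2)); s_y <- sqrt(sum(P * (Y - mu_y)^2))
  list(contrast = sum((X - Y)^2 * P),
       dissimilarity = sum(abs(X - Y) * P),
       homogeneity = sum(P / (1 + abs(X - Y))),
       asm = sum(P^2),
       energy = sqrt(sum(P^2)),
       correlation = if (s_x < 1e-12 || s_y < 1e-12) 1 else
         sum((X - mu_x) * (Y - mu_y) * P) / (s_x * s_y))
}

# Four-term closed-form MI of a 2x2 joint probability table (nats).
mi4_oracle <- function(p11, p12, p21, p22) {
  P <- c(p11, p12, p21, p22)
  px <- c(p11 + p12, p21 + p22)
  py <- c(p11 + p21, p12 + p22)
  marg <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
  sum(ifelse(P > 0, P * log(P / marg), 0))
}

# Pair-counting adjusted Rand index.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_i * sum_j / n
  (sum_ij - exp_idx) / ((sum_i + sum_j) / 2 - exp_idx)
}

# Confusion counts by explicit looping (metrics oracle).
confusion_oracle <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1L
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Random simple (star-shaped) polygon for area oracles.
random_polygon <- function(n_vertices, seed) {
  withr::with_seed(seed, {
    ang <- sort(runif(n_vertices, 0, 2 * pi))
    rad <- runif(n_vertices, 1, 10)
    cbind(x = rad * cos(ang), y = rad * sin(ang))
  })
}

# Direct cross-product polygon area (independent of the shoelace code).
polygon_area_oracle <- function(pts) {
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + (pts[i, 1] * pts[j, 2] - pts[j, 1] * pts[i, 2])
  }
  unname(abs(s) / 2)
}

tiny_mlp <- function(...) mlp_config(max_epochs = 15, seed = 7, ...)
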