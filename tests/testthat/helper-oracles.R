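# Independent oracles and shared fixtures.

# Brute-force 3x3 window means (double loop).
oracle_mean_3x3 <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(NA_real_, h - 2, w - 2)
  for (i in 1:(h - 2)) {
    for (j in 1:(w - 2)) {
      out[i, j] <- mean(mat[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

# Prefix minimum by explicit loop.
oracle_prefix_min <- function(x) {
  out <- numeric(length(x))
  cur <- Inf
  for (i in seq_along(x)) {
    cur <- min(cur, x[i])
    out[i] <- cur
  }
  out
}

# Brute-force binary erosion/dilation with an odd square element; pixels
# outside the image are treated as foreground for erosion and background for
# dilation (the shrink-free border convention).
oracle_erode <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask); half <- (k - 1) / 2
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    rs <- max(1, i - half):min(h, i + half)
    cs <- max(1, j - half):min(w, j + half)
    out[i, j] <- all(mask[rs, cs])
  }
  out
}

oracle_dilate <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask); half <- (k - 1) / 2
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    rs <- max(1, i - half):min(h, i + half)
    cs <- max(1, j - half):min(w, j + half)
    out[i, j] <- any(mask[rs, cs])
  }
  out
}

# Literal exhaustive saturation sweep: evaluate every step from 255 down to
# 0 and apply the stopping rule exactly as stated.
oracle_adaptive_threshold <- function(s, step = 5) {
  thresholds <- seq(255, 0, by = -step)
  P <- vapply(thresholds, function(t) sum(s >= t), numeric(1))
  G <- c(NA, diff(P) / length(s))
  for (n in 3:length(thresholds)) {
    if (G[n] < G[n - 1]) return(thresholds[n])
  }
  thresholds[which.max(G[-1]) + 1]
}

# Shared 80-frame fixtures (computed once per test run).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

indoor_fixture <- function() {
  fixture("indoor", function() {
    generate_eye_sequence(n = 80, scene = eye_scene(mode = "indoor"), seed = 7)
  })
}

outdoor_fixture <- function() {
  fixture("outdoor", function() {
    generate_eye_sequence(n = 80, scene = eye_scene(mode = "outdoor"), seed = 7)
  })
}

indoor_prssm <- function() {
  fixture("indoor_prssm", function() run_prssm(indoor_fixture()$frames))
}

indoor_cclpf <- function() {
  fixture("indoor_cclpf", function() run_cclpf(indoor_fixture()$frames))
}

small_rgb <- function(seed = 1, h = 12, w = 15) {
  set.seed(seed)
  rgb_image(matrix(sample(0:255, h * w, TRUE), h, w),
            matrix(sample(0:255, h * w, TRUE), h, w),
            matrix(sample(0:255, h * w, TRUE), h, w))
}

disk_gray <- function(h, w, cx, cy, r, inside, outside) {
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1, h, w)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  gray_image(ifelse(d <= r, inside, outside))
}

disk_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1, h, w)
  binary_mask((xs - cx)^2 + (ys - cy)^2 <= r^2)
}
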