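# Independent brute-force oracles, written straight from the defining
# formulas with explicit loops; deliberately share no code with the package.

# class statistics of a 256-level histogram split at T (levels 0..255)
oracle_split <- function(counts, T) {
  n <- sum(counts)
  lev <- 0:255
  s0 <- lev[lev <= T]; s1 <- lev[lev > T]
  n0 <- sum(counts[s0 + 1]); n1 <- sum(counts[s1 + 1])
  p0 <- n0 / n; p1 <- n1 / n
  mu0 <- if (n0 > 0) sum(counts[s0 + 1] * s0) / n0 else NA_real_
  mu1 <- if (n1 > 0) sum(counts[s1 + 1] * s1) / n1 else NA_real_
  var0 <- if (n0 > 0) sum(counts[s0 + 1] * (s0 - mu0)^2) / n0 else NA_real_
  var1 <- if (n1 > 0) sum(counts[s1 + 1] * (s1 - mu1)^2) / n1 else NA_real_
  list(p0 = p0, p1 = p1, mu0 = mu0, mu1 = mu1, var0 = var0, var1 = var1,
       mu = sum(counts * lev) / n)
}

# exhaustive scan of the between-class variance (smallest maximizer)
oracle_otsu_max <- function(counts) {
  best <- -Inf; bestT <- NA_integer_
  for (T in 0:255) {
    s <- oracle_split(counts, T)
    if (s$p0 == 0 || s$p1 == 0) next
    obj <- s$p0 * s$p1 * (s$mu0 - s$mu1)^2
    if (obj > best + 1e-12) { best <- obj; bestT <- T }
  }
  bestT
}

# exhaustive scan of the within-class variance (smallest minimizer)
oracle_otsu_min <- function(counts) {
  best <- Inf; bestT <- NA_integer_
  for (T in 0:255) {
    s <- oracle_split(counts, T)
    if (s$p0 == 0 || s$p1 == 0) next
    obj <- s$p0 * s$var0 + s$p1 * s$var1
    if (obj < best - 1e-12) { best <- obj; bestT <- T }
  }
  bestT
}

# exhaustive scan of the improved objective, straight from its printed form
oracle_iotsu <- function(counts) {
  best <- -Inf; bestT <- NA_integer_
  for (T in 0:255) {
    s <- oracle_split(counts, T)
    if (s$p0 == 0 || s$p1 == 0) next
    mu <- s$p0 * s$mu0 + s$p1 * s$mu1
    obj <- s$p0 * s$p1 * (s$mu0 - s$mu1)^2 + (s$mu0 - mu)^2 + (s$mu1 - mu)^2
    if (obj > best + 1e-12) { best <- obj; bestT <- T }
  }
  bestT
}

# random histogram with at least two occupied levels
random_histogram <- function(max_levels = 256) {
  k <- sample(2:12, 1)
  lev <- sample(0:(max_levels - 1), k)
  counts <- integer(256)
  counts[lev + 1] <- sample(1:500, k, replace = TRUE)
  counts
}

# flood-fill connected-component labeller (BFS), independent of the package
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# reflect-padded brute-force median filter (upper-middle order statistic,
# even windows anchored at ceil(h/2), ceil(w/2))
oracle_median_filter <- function(img, wh, ww) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {  # 0-based index
    p <- 2 * n
    j <- i %% p
    ifelse(j >= n, p - 1 - j, j)
  }
  up <- ceiling(wh / 2) - 1; down <- wh - 1 - up
  left <- ceiling(ww / 2) - 1; right <- ww - 1 - left
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- refl((i - 1) + (-up):down, nr) + 1
    cj <- refl((j - 1) + (-left):right, nc) + 1
    v <- sort(as.vector(img[ri, cj]))
    out[i, j] <- v[floor(length(v) / 2) + 1]  # upper middle
  }
  out
}

# small fast phantom spec for unit tests
tiny_spec <- function(..., seed = 1) {
  phantom_spec(image_size = c(64, 64), disc_radius = 28,
               n_dark_spots = 1, seed = seed, ...)
}
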