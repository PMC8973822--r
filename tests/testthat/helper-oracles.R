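# Independent brute-force oracles used to pin expected values.

# Literal Huang-Wang fuzziness scan: explicit loop over every candidate
# threshold, class means and entropy computed directly from the formula.
huang_oracle <- function(image, bins = 256) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  idx <- pmin(floor((v - lo) / (hi - lo) * bins), bins - 1)
  h <- tabulate(idx + 1L, nbins = bins)
  occ <- which(h > 0) - 1
  C <- max(occ) - min(occ)
  g <- 0:(bins - 1)
  best_t <- NA_integer_; best_s <- Inf
  for (t in 0:(bins - 2)) {
    below <- g <= t
    n0 <- sum(h[below]); n1 <- sum(h[!below])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(g[below] * h[below]) / n0
    mu1 <- sum(g[!below] * h[!below]) / n1
    mu <- ifelse(below, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    hterm <- ifelse(mu <= 0 | mu >= 1, 0, -mu * log(mu) - (1 - mu) * log(1 - mu))
    s <- sum(h * hterm)
    if (s < best_s - 1e-12) { best_s <- s; best_t <- t }
  }
  lo + (best_t + 1) * (hi - lo) / bins
}

# Naive sliding-window circular median: per-pixel neighbourhood gather + sort.
median_oracle <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  r <- floor(radius)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (di in -r:r) for (dj in -r:r) {
        if (di^2 + dj^2 > radius^2) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          vals <- c(vals, img[ii, jj])
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

# Definitional two-pass Pearson correlation.
pearson_oracle <- function(a, b) {
  am <- sum(a) / length(a); bm <- sum(b) / length(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Welch ANOVA written long-hand from the defining sums.
welch_oracle <- function(samples) {
  k <- length(samples)
  ns <- sapply(samples, length)
  ms <- sapply(samples, mean)
  vs <- sapply(samples, function(x) sum((x - mean(x))^2) / (length(x) - 1))
  w <- ns / vs
  W <- sum(w)
  xw <- sum(w * ms) / W
  num <- sum(w * (ms - xw)^2) / (k - 1)
  lam <- sum((1 - w / W)^2 / (ns - 1))
  F <- num / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2 <- (k^2 - 1) / (3 * lam)
  list(F = F, df1 = k - 1, df2 = df2,
       p = pf(F, k - 1, df2, lower.tail = FALSE))
}

# Best Jaccard overlap of one true-cell pixel set against any segmented label.
best_jaccard <- function(true_mask, label, seg_labels) {
  tm <- true_mask == label
  labs <- setdiff(unique(as.vector(seg_labels)), 0L)
  if (!length(labs)) return(0)
  max(vapply(labs, function(k) {
    sm <- seg_labels == k
    sum(tm & sm) / sum(tm | sm)
  }, numeric(1)))
}

# Small fast scene spec for unit tests: one or two large cells in a modest
# frame so segmentation and correlation behave as in full-size scenes.
test_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_height = 160, image_width = 160, n_cells = 1,
                   cell_radius_range = c(34, 42), seed = 1L)
  do.call(scene_spec, utils::modifyList(defaults, args))
}

noise_off <- list(poisson_gain = 0, gaussian_sd = 0)
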