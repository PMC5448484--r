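# Independent oracles used to cross-check the vectorized implementations.
# These are deliberately naive re-codings from first principles and share
# no code with the package internals.

# Per-pixel loop classifier for the three RGB rules.
naive_classify <- function(image, rule, thr = rgb_thresholds()) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      R <- px[i, j, 1]; G <- px[i, j, 2]; B <- px[i, j, 3]
      out[i, j] <- switch(rule,
        mineral = G != 0 && B / G < thr$mineral_bg_max &&
          R / G > thr$mineral_rg_min,
        matrix = R > thr$matrix_red_low && R < thr$matrix_red_high,
        nucleus = G != 0 && B / G > thr$nucleus_bg_min)
    }
  }
  out
}

# Random 8-bit RGB image straddling all the thresholds.
random_image <- function(h, w, stain = "VON_KOSSA") {
  px <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  stained_image(px, stain = stain)
}

# Brute-force evaluation of the volume-composition equations.
composition_oracle <- function(X, Y, f, Z = 1.5) {
  Vx <- X / f; Vy <- Y / f; Vz <- Z / f
  fib <- 100 * (1 - Vx / 100 - Vy / 100 - Vz / 100)
  c(Vx = Vx, Vy = Vy, Vz = Vz, fibrin = fib)
}

# Pooled-variance two-sample Student t-test p-value from first principles.
student_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Stack-based flood fill, 8- or 4-connectivity, labels in raster
# (column-major) order of first pixel.
flood_fill_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Strip component_mask attributes down to a bare logical matrix.
as_logical_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# Small pixel constructor for rule unit tests.
one_pixel_image <- function(r, g, b, stain = "VON_KOSSA") {
  stained_image(array(c(r, g, b), dim = c(1, 1, 3)), stain = stain)
}
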