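# Independent oracles used to freeze expected values. These deliberately use
# brute force / enumeration, never the package's own code paths.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments:
# every way of labelling n_x of the pooled observations as "x" is equally
# likely under the null; the two-sided p doubles the smaller tail of the
# (symmetric) U distribution.
mw_enum_p <- function(x, y, alternative = "two_sided") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, u_of)
  lo <- mean(all_u <= u_obs); hi <- mean(all_u >= u_obs)
  switch(alternative,
         two_sided = min(1, 2 * min(lo, hi)),
         less = lo,
         greater = hi)
}

# Holm step-down applied literally: sort ascending, adjusted(k) =
# max_{j<=k} min(1, (m-j+1) * p_(j)), mapped back to input order.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  run <- 0
  for (j in seq_len(m)) {
    run <- max(run, min(1, (m - j + 1) * p[o[j]]))
    adj_sorted[j] <- run
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# 8-connected component labelling by plain flood fill over a logical matrix.
flood_fill_labels <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (x0 in seq_len(nx)) for (y0 in seq_len(ny)) {
    if (!mask[y0, x0] || lab[y0, x0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y0, x0)); lab[y0, x0] <- nxt
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- nxt
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

# Rasterize ground-truth disks at sub-pixel resolution and count source
# objects whose pixels touch any target-channel disk: a pixel-level audit of
# the geometric overlap fractions reported by the generator.
raster_overlap_frac <- function(objects, src, tgt, grid_nm = 25) {
  s <- objects[objects$channel == src, , drop = FALSE]
  t <- objects[objects$channel == tgt, , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  if (nrow(t) == 0) return(0)
  hits <- vapply(seq_len(nrow(s)), function(i) {
    r <- s$radius_nm[i]
    ys <- seq(s$center_y_nm[i] - r, s$center_y_nm[i] + r, by = grid_nm)
    xs <- seq(s$center_x_nm[i] - r, s$center_x_nm[i] + r, by = grid_nm)
    g <- expand.grid(y = ys, x = xs)
    g <- g[(g$y - s$center_y_nm[i])^2 + (g$x - s$center_x_nm[i])^2 <= r^2, ]
    for (j in seq_len(nrow(t))) {
      if (any((g$y - t$center_y_nm[j])^2 + (g$x - t$center_x_nm[j])^2 <=
              t$radius_nm[j]^2)) return(TRUE)
    }
    FALSE
  }, logical(1))
  mean(hits)
}

# Small helper: wrap a matrix as a calibrated image (100 nm/px default).
as_img <- function(m, ps = 100) image2d(m, ps)

# A tiny clean two-channel stack builder for I/O tests.
tiny_stack <- function(nz = 3, ny = 8, nx = 8, seed = 1) {
  set.seed(seed)
  px <- array(sample(0:255, 2 * nz * ny * nx, replace = TRUE),
              dim = c(2, nz, ny, nx))
  calibrated_stack(px, c("green", "red"), pixel_size_nm = 100)
}
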