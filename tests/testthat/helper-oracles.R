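# Independent oracles used to cross-check the implementation. Each oracle is
# a deliberately naive computation (grid search, enumeration, Monte Carlo)
# sharing no code with the package internals it checks.

# OLS by brute-force SSE minimization over a grid, refined to the requested
# precision. The search runs in the centred parameterization
# y ~ a + b (x - mean(x)), where the two parameters are uncorrelated and the
# shrinking grid cannot zigzag past the joint optimum; the intercept is
# mapped back at the end.
oracle_ols_grid <- function(x, y, precision = 1e-5) {
  xc <- x - mean(x)
  a_range <- range(y) + c(-1, 1) * (diff(range(y)) + 1)
  b_range <- c(-20, 20)
  steps <- 101
  for (pass in 1:8) {
    as <- seq(a_range[1], a_range[2], length.out = steps)
    bs <- seq(b_range[1], b_range[2], length.out = steps)
    sse <- outer(as, bs, function(a, b)
      vapply(seq_along(a), function(m)
        sum((y - a[m] - b[m] * xc)^2), numeric(1)))
    best <- arrayInd(which.min(sse), dim(sse))
    wa <- diff(a_range) / (steps - 1)
    wb <- diff(b_range) / (steps - 1)
    if (wa < precision && wb < precision) break
    a_range <- as[best[1]] + c(-2, 2) * wa
    b_range <- bs[best[2]] + c(-2, 2) * wb
  }
  c(intercept = as[best[1]] - bs[best[2]] * mean(x), slope = bs[best[2]])
}

# Monte-Carlo distance from a point to a box: minimum distance to random
# points drawn on the box surface (exterior points), or 0 if inside. The
# minimum over finitely many samples approaches the true distance from
# above; near a corner the excess shrinks only like 1/sqrt(n).
oracle_box_distance_mc <- function(point, center, half, n = 1e6) {
  inside <- all(abs(point - center) <= half)
  if (inside) return(0)
  faces <- rbind(c(1, -1), c(1, 1), c(2, -1), c(2, 1), c(3, -1), c(3, 1))
  areas <- apply(faces, 1, function(f) prod(2 * half[-f[1]]))
  pick <- sample.int(6, n, replace = TRUE, prob = areas)
  pts <- matrix(stats::runif(3 * n, -1, 1), ncol = 3) * rep(half, each = n)
  for (m in 1:6) {
    sel <- pick == m
    pts[sel, faces[m, 1]] <- faces[m, 2] * half[faces[m, 1]]
  }
  pts <- sweep(pts, 2, center, "+")
  min(sqrt(colSums((t(pts) - point)^2)))
}

# Farthest point of a neighbour box from an infected box by maximizing over
# a regular grid of neighbour points.
oracle_farthest_grid <- function(nc, nh, ic, ih, step = 0.5) {
  gx <- seq(nc[1] - nh[1], nc[1] + nh[1], by = step)
  gy <- seq(nc[2] - nh[2], nc[2] + nh[2], by = step)
  gz <- seq(nc[3] - nh[3], nc[3] + nh[3], by = step)
  dx <- pmax(abs(gx - ic[1]) - ih[1], 0)
  dy <- pmax(abs(gy - ic[2]) - ih[2], 0)
  dz <- pmax(abs(gz - ic[3]) - ih[3], 0)
  sqrt(max(dx)^2 + max(dy)^2 + max(dz)^2)
}

# Exhaustive-offset brute force for the lattice coverage count: plain triple
# loop over offsets, classifying each neighbour with straightforward
# per-point arithmetic (voxel criteria use an expand.grid of voxel centres).
oracle_count_affected <- function(cell_dims, radius, criterion,
                                  classify = "analytic", resolution = 1,
                                  packing = "axis_aligned",
                                  imax = 3, jmax = 9, kmax = 9) {
  l <- cell_dims; h <- l / 2
  count <- 0
  for (i in -imax:imax) for (j in -jmax:jmax) for (k in -kmax:kmax) {
    if (i == 0 && j == 0 && k == 0) next
    cx <- l[1] * i + if (packing == "brick_staggered_x" && (j %% 2) != 0) l[1] / 2 else 0
    cy <- l[2] * j; cz <- l[3] * k
    hit <- if (criterion == "center_in") {
      sqrt(max(abs(cx) - h[1], 0)^2 + max(abs(cy) - h[2], 0)^2 +
           max(abs(cz) - h[3], 0)^2) <= radius
    } else if (criterion == "whole_cell" && classify == "analytic") {
      sqrt(max(abs(cx) + h[1] - h[1], 0)^2 + max(abs(cy) + h[2] - h[2], 0)^2 +
           max(abs(cz) + h[3] - h[3], 0)^2) <= radius
    } else {
      g <- expand.grid(
        x = seq(cx - h[1] + resolution / 2, cx + h[1] - resolution / 2, by = resolution),
        y = seq(cy - h[2] + resolution / 2, cy + h[2] - resolution / 2, by = resolution),
        z = seq(cz - h[3] + resolution / 2, cz + h[3] - resolution / 2, by = resolution))
      d <- sqrt(pmax(abs(g$x) - h[1], 0)^2 + pmax(abs(g$y) - h[2], 0)^2 +
                pmax(abs(g$z) - h[3], 0)^2)
      frac <- mean(d <= radius)
      if (criterion == "whole_cell") frac == 1 else frac >= 0.5
    }
    if (hit) count <- count + 1
  }
  count
}

# Permutation p-value for a difference in means.
oracle_perm_p <- function(a, b, nperm = 1e4) {
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  hits <- replicate(nperm, {
    idx <- sample(length(pool), length(a))
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  })
  mean(hits)
}
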