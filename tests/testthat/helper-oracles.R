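# Independent brute-force oracles. These deliberately use plain loops and
# first-principles formulas, never the package's own code paths.

# voxelwise threshold by explicit loop
bf_threshold <- function(vals, lo, hi) {
  d <- dim(vals)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    out[i, j, k] <- vals[i, j, k] >= lo && vals[i, j, k] <= hi
  out
}

# breadth-first flood fill over a logical domain from 1-based seed rows
bf_flood <- function(domain, seeds, connectivity = 26) {
  d <- dim(domain)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3), ]
  visited <- array(FALSE, d)
  queue <- lapply(seq_len(nrow(seeds)), function(r) seeds[r, ])
  for (s in queue) visited[s[1], s[2], s[3]] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      w <- v + c(offs$dx[r], offs$dy[r], offs$dz[r])
      if (any(w < 1) || any(w > d)) next
      if (domain[w[1], w[2], w[3]] && !visited[w[1], w[2], w[3]]) {
        visited[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  visited
}

# 2D morphology with a clipped disk element (outside = background for
# dilation, foreground for erosion), by explicit loops
bf_disk_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= r^2, ]
}

bf_dilate2d <- function(m, r) {
  d <- dim(m); offs <- bf_disk_offsets(r)
  out <- matrix(FALSE, d[1], d[2])
  for (i in 1:d[1]) for (j in 1:d[2]) {
    hit <- FALSE
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs$di[o]; jj <- j + offs$dj[o]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && m[ii, jj]) {
        hit <- TRUE; break
      }
    }
    out[i, j] <- hit
  }
  out
}

bf_erode2d <- function(m, r) {
  d <- dim(m); offs <- bf_disk_offsets(r)
  out <- matrix(FALSE, d[1], d[2])
  for (i in 1:d[1]) for (j in 1:d[2]) {
    keep <- TRUE
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs$di[o]; jj <- j + offs$dj[o]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && !m[ii, jj]) {
        keep <- FALSE; break
      }
    }
    out[i, j] <- keep
  }
  out
}

bf_close2d <- function(m, r) bf_erode2d(bf_dilate2d(m, r), r)

# Pearson r, t-transform p and regression line from first principles
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tv <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tv), n - 2),
       slope = sxy / sxx, intercept = my - (sxy / sxx) * mx)
}

# one-sample t on the differences, from first principles
bf_paired_t <- function(left, right) {
  d <- right - left
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  tv <- md / (sd_d / sqrt(n))
  list(t = tv, p = 2 * pt(-abs(tv), n - 1), mean_diff = md)
}

# tiny phantom on a 4 mm grid for fast end-to-end tests
small_phantom <- function(joint, tracer = "NaF", bone_suv = 1.587, ...) {
  make_joint_phantom(phantom_spec(joint, tracer = tracer,
                                  bone_suv = bone_suv,
                                  dims = c(64L, 64L, 64L),
                                  spacing_mm = c(4, 4, 4), ...))
}

# flat-field volume helper
flat_volume <- function(value, dims = c(6, 5, 4), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), modality = "CT") {
  volume(array(value, dims), spacing, origin, modality)
}
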