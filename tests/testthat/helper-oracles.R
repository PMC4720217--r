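# Independent brute-force oracles, deliberately implemented without the
# package's distance-transform machinery. Only usable on small grids.

# squared Euclidean distance to the nearest TRUE voxel, O(n * sites)
brute_edt_sq <- function(mask) {
  d <- dim(mask)
  co <- arrayInd(which(mask), d)
  out <- array(Inf, d)
  for (v in seq_len(prod(d))) {
    p <- arrayInd(v, d)
    out[v] <- min((co[, 1] - p[1])^2 + (co[, 2] - p[2])^2 + (co[, 3] - p[3])^2)
  }
  out
}

# dilation/erosion by explicit ball offsets (shift-and-combine)
ball_offsets <- function(r) {
  g <- expand.grid(z = -r:r, y = -r:r, x = -r:r)
  as.matrix(g[g$z^2 + g$y^2 + g$x^2 <= r^2, ])
}

shift_or <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(nrow(off))) {
    s <- off[k, ]
    src <- dst <- vector("list", 3)
    ok <- TRUE
    for (ax in 1:3) {
      if (d[ax] - abs(s[ax]) <= 0) { ok <- FALSE; break }
      if (s[ax] >= 0) {
        src[[ax]] <- seq_len(d[ax] - s[ax]); dst[[ax]] <- src[[ax]] + s[ax]
      } else {
        src[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]; dst[[ax]] <- seq_len(d[ax] + s[ax])
      }
    }
    if (!ok) next
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

brute_dilate <- function(mask, r) shift_or(mask, ball_offsets(r))

brute_erode <- function(mask, r) {
  # erode = complement of dilated complement (exact lattice duality)
  !brute_dilate(!mask, r)
}

# closing on a grid padded so the dilation never clips
brute_close <- function(mask, r) {
  d <- dim(mask)
  p <- r + 2L
  big <- array(FALSE, d + 2L * p)
  big[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])] <- mask
  closed <- brute_erode(brute_dilate(big, r), r)
  closed[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])]
}

# random blob: union of k random balls, seeded
random_blob <- function(dims, k = 4, rmax = 5, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dims)
  gz <- seq_len(dims[1]); gy <- seq_len(dims[2]); gx <- seq_len(dims[3])
  for (i in seq_len(k)) {
    c0 <- c(sample(gz, 1), sample(gy, 1), sample(gx, 1))
    r <- sample(2:rmax, 1)
    for (z in max(1, c0[1] - r):min(dims[1], c0[1] + r)) {
      d2 <- outer((gy - c0[2])^2, (gx - c0[3])^2, "+") + (z - c0[1])^2
      m[z, , ] <- m[z, , ] | (d2 <= r^2)
    }
  }
  m
}

# slab with circular through-holes along z; returns mask and hole table
slab_with_holes <- function(thickness = 10, side = 48, margin = 4,
                            holes = data.frame(y = 24, x = 24, dia = 10)) {
  d <- c(thickness + 2 * margin, side + 2 * margin, side + 2 * margin)
  m <- array(FALSE, d)
  zr <- (margin + 1):(margin + thickness)
  m[zr, (margin + 1):(margin + side), (margin + 1):(margin + side)] <- TRUE
  for (i in seq_len(nrow(holes))) {
    h2 <- outer((seq_len(d[2]) - margin - holes$y[i])^2,
                (seq_len(d[3]) - margin - holes$x[i])^2, "+") < (holes$dia[i] / 2)^2
    for (z in zr) m[z, , ][h2] <- FALSE
    holes$mouth[i] <- sum(h2)
  }
  list(mask = m, holes = holes, zr = zr, margin = margin)
}

# 90 degree rotation about the slice axis
rot90_z <- function(mask) {
  m <- aperm(mask, c(1, 3, 2))
  m[, , rev(seq_len(dim(m)[3])), drop = FALSE]
}
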