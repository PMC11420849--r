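# Test helpers: independent brute-force oracles and small mask generators.

# HU-RSP table mapping every in-body HU to exactly 1 (water), air to 0; turns
# the phantom into a uniform medium where WEL equals geometric depth.
uniform_rsp_table <- function() hu_rsp_table(hu = c(-400, -300), rsp = c(0, 1))

all_ones_spmap <- function() stopping_power_map(C = 1, T = 1, L = 1, S = 1)

# Closed-form simple-regression oracle (normal equations), independent of lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) /
           (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
       sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  list(slope = slope, intercept = intercept, r = r)
}

# Brute-force boundary of a 2-D mask: explicit loop, 4-neighborhood,
# out-of-grid treated as background.
oracle_boundary_points <- function(m) {
  pts <- NULL
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j]) next
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < nrow(m)) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < ncol(m)) m[i, j + 1] else FALSE)
    if (!all(nb)) pts <- rbind(pts, c(i, j))
  }
  pts
}

# Brute-force slice-averaged Hausdorff and MDA via pairwise point loops.
oracle_slice_metrics <- function(A, B) {
  sp <- A$spacing
  hvals <- mvals <- numeric(0)
  for (z in seq_len(dim(A$mask)[3])) {
    a <- A$mask[, , z]; b <- B$mask[, , z]
    if (!any(a) || !any(b)) next
    pa <- oracle_boundary_points(a); pb <- oracle_boundary_points(b)
    mins_a <- apply(pa, 1, function(p)
      min(sqrt(((p[1] - pb[, 1]) * sp[1])^2 + ((p[2] - pb[, 2]) * sp[2])^2)))
    mins_b <- apply(pb, 1, function(p)
      min(sqrt(((p[1] - pa[, 1]) * sp[1])^2 + ((p[2] - pa[, 2]) * sp[2])^2)))
    hvals <- c(hvals, max(max(mins_a), max(mins_b)))
    mvals <- c(mvals, (mean(mins_a) + mean(mins_b)) / 2)
  }
  list(dH = mean(hvals), MDA = mean(mvals))
}

# Random non-empty box-per-slice mask on a small grid.
random_mask <- function(dims = c(12, 12, 4), spacing = c(1.5, 2, 2.5)) {
  m <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    x0 <- sample(seq_len(dims[1] - 2), 1); x1 <- min(dims[1], x0 + sample(1:5, 1))
    y0 <- sample(seq_len(dims[2] - 2), 1); y1 <- min(dims[2], y0 + sample(1:5, 1))
    m[x0:x1, y0:y1, z] <- TRUE
  }
  structure_volume(m, spacing)
}

# Minimal hand-built spine: one vertebra, square canal, ventral shell and
# dorsal spinous process in a soft-tissue body.
toy_spine <- function(N = 10, shell = 3L, spin = 2L, nz = 3L,
                      spacing = c(1, 1, 1)) {
  nx <- 21L; ny <- 40L
  ct <- array(-1000, c(nx, ny, nz))
  labels <- array(0L, c(nx, ny, nz))
  canal <- body <- array(FALSE, c(nx, ny, nz))
  body[3:19, 2:36, ] <- TRUE
  canal[9:13, 16:20, ] <- TRUE
  lab <- matrix(FALSE, nx, ny)
  lab[5:17, (16 - shell):15] <- TRUE          # ventral shell
  lab[c(7:8, 14:15), 16:20] <- TRUE           # pedicles
  lab[10:12, 21:(20 + spin)] <- TRUE          # spinous process
  for (z in seq_len(nz)) labels[, , z] <- lab * N
  ct[body] <- 40; ct[labels > 0] <- 700; ct[canal] <- 10
  list(ct = ct_volume(ct, spacing),
       spine = labeled_spine(labels, canal, body, spacing),
       canal = structure_volume(canal, spacing))
}
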