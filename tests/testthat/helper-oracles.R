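# Independent brute-force oracles used against the package's implementations.
# These are written as plain enumerations (explicit loops over voxels, pairs,
# runs, group splits) so they share no code path with the package.

make_volume <- function(dim = c(8, 8, 8), values = 0, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  vb_volume(array(values, dim = dim), spacing = spacing, origin = origin)
}

# count voxel centres within diameter/2 of a world point, full-grid scan
bf_sphere_count <- function(volume, center, diameter) {
  d <- dim(volume$intensities)
  sp <- volume$spacing
  n <- 0L
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
    w <- volume$origin + c(i, j, k) * sp
    if (sum((w - center)^2) <= (diameter / 2)^2 + 1e-9) n <- n + 1L
  }
  n
}

# GLCM autocorrelation for one offset: accumulate a symmetric co-occurrence
# matrix from every ordered voxel pair, normalize, take sum(i * j * p)
bf_glcm_autocorr_dir <- function(bin_arr, off) {
  d <- dim(bin_arr)
  ng <- max(bin_arr, na.rm = TRUE)
  cm <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- bin_arr[i, j, k]
    if (is.na(a)) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    b <- bin_arr[ii, jj, kk]
    if (is.na(b)) next
    cm[a, b] <- cm[a, b] + 1  # forward orientation
    cm[b, a] <- cm[b, a] + 1  # symmetrize
  }
  if (sum(cm) == 0) return(NA_real_)
  p <- cm / sum(cm)
  acc <- 0
  for (a in seq_len(ng)) for (b in seq_len(ng)) acc <- acc + a * b * p[a, b]
  acc
}

bf_glcm_autocorr <- function(bin_arr) {
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  vals <- apply(dirs, 1, function(o) bf_glcm_autocorr_dir(bin_arr, o))
  mean(vals, na.rm = TRUE)
}

# enumerate runs along one direction of a 2D slice by explicit walking
bf_slice_runs <- function(slice, step) {
  nr <- nrow(slice); nc <- ncol(slice)
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    # a run starts where the backward neighbour is outside or breaks the run
    prev <- if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) slice[pr, pc] else NA
    cur <- slice[r, c]
    if (!is.na(cur) && (is.na(prev) || prev != cur))
      starts[[length(starts) + 1L]] <- c(r, c)
  }
  levels <- integer(0); lengths <- integer(0)
  for (s in starts) {
    r <- s[1]; c <- s[2]
    val <- slice[r, c]
    len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc &&
           !is.na(slice[r, c]) && slice[r, c] == val) {
      len <- len + 1L
      r <- r + step[1]; c <- c + step[2]
    }
    levels <- c(levels, val); lengths <- c(lengths, len)
  }
  list(levels = levels, lengths = lengths)
}

bf_gln_slice_dir <- function(slice, step) {
  runs <- bf_slice_runs(slice, step)
  if (length(runs$levels) == 0L) return(NULL)
  tot <- 0
  for (lev in unique(runs$levels))
    tot <- tot + sum(runs$levels == lev)^2
  tot / length(runs$levels)
}

# mean GLN over axial slices and the four in-plane directions
bf_gln <- function(bin_arr) {
  steps <- list("0" = c(0, 1), "45" = c(1, 1), "90" = c(1, 0),
                "135" = c(1, -1))
  vals <- numeric(0)
  for (z in seq_len(dim(bin_arr)[1])) {
    slice <- matrix(bin_arr[z, , ], nrow = dim(bin_arr)[2])
    for (st in steps) {
      g <- bf_gln_slice_dir(slice, st)
      if (!is.null(g)) vals <- c(vals, g)
    }
  }
  mean(vals)
}

# exact Mann-Whitney p by split enumeration with the U statistic computed
# from direct pairwise comparisons (not ranks)
bf_mw_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

bf_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  u_obs <- bf_mw_u(a, b)
  splits <- utils::combn(n, n1)
  us <- numeric(ncol(splits))
  for (s in seq_len(ncol(splits))) {
    ga <- pooled[splits[, s]]
    gb <- pooled[-splits[, s]]
    us[s] <- bf_mw_u(ga, gb)
  }
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# AUC by counting all positive/negative pairs, ties half
bf_auc <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan over all observed cutoffs, both orientations
bf_youden <- function(values, labels, positive) {
  best <- -Inf
  for (direction in c("greater", "less")) {
    v <- if (direction == "greater") values else -values
    pos <- v[labels == positive]; neg <- v[labels != positive]
    for (cc in sort(unique(v))) {
      j <- mean(pos >= cc) + mean(neg < cc) - 1
      if (j > best) best <- j
    }
  }
  best
}

# random masked discretized sample on a small grid, as a vb_discrete-like
# object accepted by glcm_autocorrelation / glrlm_gln
random_discrete <- function(dim3, ng = 4, p_mask = 0.7) {
  bins <- array(sample.int(ng, prod(dim3), replace = TRUE), dim = dim3)
  mask <- array(stats::runif(prod(dim3)) < p_mask, dim = dim3)
  if (!any(mask)) mask[1] <- TRUE
  bin_arr <- array(NA_integer_, dim = dim3)
  bin_arr[mask] <- bins[mask]
  structure(list(bin_arr = bin_arr, Ng = ng, mask = mask),
            class = "vb_discrete")
}
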