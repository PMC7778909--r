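# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::t.test) so that agreement is a real
# cross-check.

# Welch two-sample t-test from the textbook formulas: statistic,
# Welch-Satterthwaite degrees of freedom, two-tailed p via pt().
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(mean_difference = mean(x) - mean(y),
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

# Minimal RMSD over proper rotations by brute force: coarse Euler-angle grid
# followed by Nelder-Mead refinement. Centres both point sets (optimal
# translation) and never uses the SVD route.
euler_rotation <- function(a, b, g) {
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

grid_rmsd_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  step <- 20 * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi, by = step),
                      b = seq(0, pi, by = step),
                      g = seq(0, 2 * pi, by = step))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit$value
}

# Brute-force per-column, per-group conservation by direct membership count.
brute_conservation <- function(aln, groups) {
  n <- nrow(aln$matrix)
  out <- matrix(0, nrow(groups), ncol(aln$matrix),
                dimnames = list(groups$group, NULL))
  for (g in seq_len(nrow(groups))) {
    for (j in seq_len(ncol(aln$matrix))) {
      out[g, j] <- 100 * sum(aln$matrix[, j] %in% groups$members[[g]]) / n
    }
  }
  out
}

# A random alignment over the full symbol set (amino acids, X and gaps).
random_alignment <- function(n_receptors, n_columns, gap_prob = 0.15) {
  syms <- c(gpcrsig:::AA_CODES, "X", "-")
  w <- c(rep(1, 20), 0.5, 20 * gap_prob / (1 - gap_prob))
  m <- matrix(sample(syms, n_receptors * n_columns, replace = TRUE,
                     prob = w),
              n_receptors, n_columns)
  seqs <- stats::setNames(apply(m, 1, paste, collapse = ""),
                          sprintf("r%03d", seq_len(n_receptors)))
  cols <- tibble::tibble(position = sprintf("1x%02d", seq_len(n_columns) + 29),
                         segment = "TM1")
  gpcr_alignment(seqs, cols)
}

# A random, valid offset-annotation set for one helix: anchors away from 50,
# unique, no adjacent bulges.
random_offset_set <- function(segment = "TM5", max_offsets = 3) {
  k <- sample(0:max_offsets, 1)
  if (k == 0) return(offset_annotations())
  anchors <- sample(c(35:45, 55:65), k)
  anchors <- anchors[!duplicated(anchors)]
  kinds <- sample(c("bulge", "constriction"), length(anchors), replace = TRUE)
  # drop later members of adjacent bulge pairs
  repeat {
    b <- sort(anchors[kinds == "bulge"])
    adj <- b[c(FALSE, diff(b) == 1)]
    if (!length(adj)) break
    drop <- match(adj[1], anchors)
    anchors <- anchors[-drop]; kinds <- kinds[-drop]
  }
  offset_annotations(segment, kinds, anchors, anchors < 50)
}

random_rigid_transform <- function(df) {
  R <- gpcrsig:::random_rotation()
  t0 <- stats::rnorm(3, sd = 5)
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R) +
    matrix(t0, nrow(df), 3, byrow = TRUE)
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}
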