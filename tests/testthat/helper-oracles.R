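# Independent oracles and small fixture builders used across the suite.

# breadth-first flood-fill component count: independent of the C++
# labeling kernel
bfs_count <- function(mask, connectivity = 8, min_size = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)
  dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  nn <- if (connectivity == 8) 8 else 4
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    area <- 0
    queue <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      area <- area + 1
      for (k in seq_len(nn)) {
        qi <- p[1] + dr[k]; qj <- p[2] + dc[k]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
    if (area >= min_size) count <- count + 1L
  }
  count
}

# exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed)
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(g) sum(r[g]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# paint a filled disk into a logical matrix (1-based center row/col)
disk <- function(mask, cy, cx, r) {
  d2 <- outer((seq_len(nrow(mask)) - cy)^2,
              (seq_len(ncol(mask)) - cx)^2, "+")
  mask[d2 <= r^2] <- TRUE
  mask
}

# minimal valid count-table data frame
make_counts <- function(ma, hma = 0L, he = NA_integer_,
                        grade = "moderate", dataset_id = "d1") {
  n <- length(ma)
  data.frame(dataset_id = rep_len(dataset_id, n),
             image_id = sprintf("img%04d", seq_len(n)),
             grade = rep_len(grade, n),
             ma_count = as.integer(ma),
             hma_count = rep_len(as.integer(hma), n),
             rl_count = as.integer(ma) + rep_len(as.integer(hma), n),
             he_count = rep_len(as.integer(he), n),
             he_area_px = NA_integer_, he_area_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

# published per-grade means and 95% CIs the synthetic profiles are
# calibrated against
PRINTED_CI <- list(
  MA_mild = c(3.8, 4.8), MA_moderate = c(12.8, 15.5),
  MA_severe = c(46.7, 59.6),
  Hma_moderate = c(7.9, 9.4), Hma_severe = c(46.9, 55.6),
  RL_mild = c(4.1, 5.2), RL_moderate = c(21.0, 26.6),
  RL_severe = c(96.5, 111.9),
  HE_moderate = c(23.3, 36.6), HE_severe = c(38.2, 79.3))

# the four-dataset cohort at triple size, as used for calibration
# recovery (stable strata)
calibration_cohort <- function(seed) {
  cohort_spec(sizes = c(dataset1 = 432, dataset2 = 1758,
                        dataset3 = 4185, dataset4 = 150),
              seed = seed)
}
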