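# Independent oracles used across the suite. These deliberately avoid the
# code paths they validate.

# random sequence with mildly AT-rich composition so repeat runs occur
random_seq <- function(n, prob = c(0.35, 0.15, 0.15, 0.35)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# naive smallest period: try every p directly on the character vector
oracle_period <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  for (p in 1:n) {
    ok <- TRUE
    for (i in seq_len(n)) {
      if (i > p && x[i] != x[i - p]) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  n
}

# per-nucleotide overlap count: iterate every feature nucleotide and test
# membership in the territory interval set
oracle_overlap_multiplex <- function(features, territory) {
  iv <- territory$intervals
  k <- 0L
  for (i in seq_len(nrow(features))) {
    for (g in seq(features$start[i], features$end[i] - 1L)) {
      hit <- any(iv$chrom == features$chrom[i] & iv$start <= g & g < iv$end)
      if (hit) k <- k + 1L
    }
  }
  k
}

oracle_overlap_singleton <- function(features, territory) {
  iv <- territory$intervals
  k <- 0L
  for (i in seq_len(nrow(features))) {
    any_hit <- FALSE
    for (g in seq(features$start[i], features$end[i] - 1L)) {
      if (any(iv$chrom == features$chrom[i] & iv$start <= g & g < iv$end))
        any_hit <- TRUE
    }
    if (any_hit) k <- k + 1L
  }
  k
}

# two-sample KS statistic by evaluating both ECDFs at every data point
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Pearson r from the textbook covariance/variance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# order records canonically and drop attributes for comparisons
norm_tracts <- function(df) {
  df <- df[order(df$chrom, df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "seq_lengths") <- NULL
  df
}

expect_same_tracts <- function(a, b) {
  expect_identical(norm_tracts(a), norm_tracts(b))
}
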