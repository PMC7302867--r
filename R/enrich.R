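# Locational enrichment of genomic features within polytract territory.
#
# For a genome of N nucleotides and a territory of n nucleotides, a
# feature with k of M instances inside the territory is tested against
# the binomial null X ~ Binomial(M, n/N): over-representation is the
# upper tail P(X >= k), under-representation the lower tail P(X <= k).
# The relative risk RR = (k/M) / (n/N) compares the feature's in-territory
# rate with the territory's genomic occupancy rate.

.features_df <- function(features) {
  if (methods::is(features, "GRanges"))
    return(data.frame(
      chrom = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features) - 1L,
      end = GenomicRanges::end(features), stringsAsFactors = FALSE))
  stopifnot(is.data.frame(features),
            all(c("chrom", "start", "end") %in% names(features)))
  features
}

#' Count overlaps between features and a territory
#'
#' Quantifies the overlap between a set of genomic features (points or
#' intervals) and a polytract territory in one of two modes. In
#' `singleton` mode every feature instance contributes at most one
#' overlap: `k` is the number of instances intersecting the territory by
#' at least one nucleotide and `M` the number of instances. In
#' `multiplex` mode overlap is counted in nucleotides: `k` is the total
#' number of feature nucleotides inside the territory and `M` the total
#' feature length.
#'
#' @param features A data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) or a [GenomicRanges::GRanges].
#' @param territory A [polytract_territory()].
#' @param mode `"singleton"` or `"multiplex"`.
#' @return A list with `mode`, `k` and `M`.
#' @examples
#' tr <- scan_sequence("AAAAAA")
#' terr <- polytract_territory(tr, seq_lengths = c(seq = 100),
#'                             extend = FALSE)
#' feats <- data.frame(chrom = "seq", start = 2, end = 3)
#' compute_overlap(feats, terr)  # k = 1 of M = 1
#' @export
compute_overlap <- function(features, territory,
                            mode = c("singleton", "multiplex")) {
  mode <- match.arg(mode)
  stopifnot(inherits(territory, "polytract_territory"))
  fd <- .features_df(features)
  sl <- territory$seq_lengths
  known <- fd$chrom %in% names(sl)
  if (!all(known)) {
    warning(sum(!known), " feature(s) on unknown sequences skipped")
    fd <- fd[known, , drop = FALSE]
  }
  if (nrow(fd)) {
    lim <- unname(sl[fd$chrom])
    if (any(fd$start < 0 | fd$end > lim)) {
      warning("feature(s) beyond sequence bounds clipped")
      fd$start <- pmax(fd$start, 0L)
      fd$end <- pmin(fd$end, lim)
    }
    fd <- fd[fd$end > fd$start, , drop = FALSE]
  }
  if (!nrow(fd)) return(list(mode = mode, k = 0, M = 0))
  fgr <- GenomicRanges::GRanges(fd$chrom,
                                IRanges::IRanges(fd$start + 1L, fd$end))
  tiv <- territory$intervals
  tgr <- GenomicRanges::GRanges(tiv$chrom,
                                IRanges::IRanges(tiv$start + 1L, tiv$end))
  if (mode == "singleton") {
    k <- sum(IRanges::overlapsAny(fgr, tgr))
    M <- length(fgr)
  } else {
    hits <- GenomicRanges::findOverlaps(fgr, tgr)
    ov <- IRanges::pintersect(fgr[S4Vectors::queryHits(hits)],
                              tgr[S4Vectors::subjectHits(hits)])
    # territory intervals are disjoint, so per-instance widths add up
    k <- sum(as.numeric(GenomicRanges::width(ov)))
    M <- sum(as.numeric(GenomicRanges::width(fgr)))
  }
  list(mode = mode, k = k, M = M)
}

#' Exact binomial tail probability of locational overlap
#'
#' Tail probability of observing the overlap `k` out of `M` under the
#' binomial null `X ~ Binomial(M, n/N)`: `P(X >= k)` for
#' over-representation and `P(X <= k)` for under-representation. The tail
#' is exact (no normal approximation). The alternative
#' `parameterization = "printed"` swaps the roles of the feature and the
#' territory, using `X ~ Binomial(n, M/N)`; the two parameterizations
#' differ numerically and the instance-based one is the default.
#'
#' @param k Observed overlap count.
#' @param M Number of feature instances (or nucleotides in multiplex
#'   mode).
#' @param n Territory size in nucleotides.
#' @param N Genome size in nucleotides.
#' @param direction `"over"` or `"under"`.
#' @param parameterization `"instances"` (default) or `"printed"`.
#' @return The tail probability.
#' @examples
#' binom_p(2, 2, 50, 100, "over")   # 0.25
#' binom_p(0, 10, 50, 100, "over")  # 1
#' @export
binom_p <- function(k, M, n, N, direction = c("over", "under"),
                    parameterization = c("instances", "printed")) {
  direction <- match.arg(direction)
  parameterization <- match.arg(parameterization)
  stopifnot(length(k) == 1L, length(M) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (n <= 0 || n > N) stop("binom_p(): need 0 < n <= N")
  if (k < 0 || k > M) stop("binom_p(): need 0 <= k <= M")
  size <- if (parameterization == "instances") M else n
  prob <- if (parameterization == "instances") n / N else M / N
  if (direction == "over") {
    pbinom(k - 1, size = size, prob = prob, lower.tail = FALSE)
  } else {
    pbinom(k, size = size, prob = prob, lower.tail = TRUE)
  }
}

#' Relative risk of territory-borne features with Katz 95% CI
#'
#' `RR = (k/M) / (n/N)`: the rate at which feature instances fall in the
#' territory divided by the territory's occupancy rate of the genome. The
#' confidence interval uses the Katz log method,
#' `exp(log RR +/- z * SE)` with `SE = sqrt(1/k - 1/M + 1/n - 1/N)`.
#' When `k = 0` the RR is 0 and the CI is undefined (`NA`, flagged).
#'
#' @inheritParams binom_p
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `RR`, `ci_low`, `ci_high`, `ci_defined`.
#' @examples
#' relative_risk(10, 10, 50, 100)  # RR = 2
#' @export
relative_risk <- function(k, M, n, N, conf_level = 0.95) {
  if (M <= 0 || n <= 0) stop("relative_risk(): need M > 0 and n > 0")
  if (k < 0 || k > M) stop("relative_risk(): need 0 <= k <= M")
  rr <- (k / M) / (n / N)
  if (k == 0)
    return(list(RR = 0, ci_low = NA_real_, ci_high = NA_real_,
                ci_defined = FALSE))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / k - 1 / M + 1 / n - 1 / N)
  list(RR = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se),
       ci_defined = TRUE)
}

#' Hypergeometric test of polytract embedding in enhancers
#'
#' Tests whether enhancers (or any interval class) embed polytracts more
#' often than expected, from four numbers: the number of enhancers `E`,
#' the number `k_e` of enhancers embedding at least one polytract, the
#' genome size `N` and the territory size `n`. The p-value is
#' `P(X >= k_e)` for `X` hypergeometric with population `N`, `n` success
#' states and `E` draws. Note the parameterization mixes units (enhancer
#' counts drawn against nucleotide counts); it is provided as stated, and
#' [binom_p()] with per-enhancer success probability is the
#' dimensionally-consistent alternative.
#'
#' @param E Number of enhancers.
#' @param k_e Number of enhancers embedding at least one polytract.
#' @param N Genome size (nt).
#' @param n Territory size (nt).
#' @return Upper-tail p-value `P(X >= k_e)`.
#' @export
hypergeom_embed_test <- function(E, k_e, N, n) {
  if (E > N) stop("hypergeom_embed_test(): E must not exceed N")
  if (k_e < 0 || k_e > E) stop("hypergeom_embed_test(): need 0 <= k_e <= E")
  if (n < 0 || n > N) stop("hypergeom_embed_test(): need 0 <= n <= N")
  phyper(k_e - 1, m = n, n = N - n, k = E, lower.tail = FALSE)
}

#' Bonferroni significance flags
#'
#' Flags p-values significant at `alpha / m_tests`. With the default
#' `alpha = 0.01` a single test uses 0.01; a landscape of ~100 features
#' tested simultaneously uses `m_tests` equal to the number of features
#' (e.g. 94 features give an effective threshold of about 1e-4).
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Family-wise error rate.
#' @param m_tests Number of simultaneous tests.
#' @return Logical vector.
#' @export
bonferroni_flag <- function(pvals, alpha = 0.01, m_tests = 1L) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m_tests >= 1)
  pvals < alpha / m_tests
}

#' Impute relative risks for heatmap reporting
#'
#' Reporting rule for RR heatmaps: in the over-representation view, cells
#' with `RR < 1` or `p > alpha` are imputed with `RR = 1` so that only
#' significant elevations remain visible; the under-representation view
#' symmetrically imputes `RR > 1` or `p > alpha` cells.
#'
#' @param RR Numeric vector of relative risks.
#' @param p Numeric vector of matching p-values.
#' @param direction `"over"` or `"under"`.
#' @param alpha Significance gate (default 0.01).
#' @return Numeric vector of display values.
#' @export
rr_heatmap_impute <- function(RR, p, direction = c("over", "under"),
                              alpha = 0.01) {
  direction <- match.arg(direction)
  stopifnot(length(RR) == length(p))
  out <- RR
  mask <- if (direction == "over") RR < 1 | p > alpha else RR > 1 | p > alpha
  out[mask] <- 1
  out
}

#' Full enrichment test of a feature set against a territory
#'
#' Runs [compute_overlap()], [binom_p()] and [relative_risk()] for one
#' feature set against one territory and returns a single result row.
#'
#' @inheritParams compute_overlap
#' @param direction `"over"` or `"under"`.
#' @param alpha Family-wise error rate for the significance flag.
#' @param m_tests Number of simultaneous tests (Bonferroni).
#' @param feature_id,subset_id Labels recorded in the result.
#' @return A one-row data.frame with columns `feature`, `subset`, `mode`,
#'   `direction`, `k`, `M`, `n`, `N`, `p`, `RR`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
polytract_enrichment <- function(features, territory,
                                 mode = c("singleton", "multiplex"),
                                 direction = c("over", "under"),
                                 alpha = 0.01, m_tests = 1L,
                                 feature_id = "feature",
                                 subset_id = territory$subset) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  ov <- compute_overlap(features, territory, mode)
  if (ov$M == 0) stop("no usable feature instances")
  p <- binom_p(ov$k, ov$M, territory$n, territory$N, direction)
  rr <- relative_risk(ov$k, ov$M, territory$n, territory$N)
  data.frame(feature = feature_id, subset = subset_id, mode = mode,
             direction = direction, k = ov$k, M = ov$M, n = territory$n,
             N = territory$N, p = p, RR = rr$RR, ci_low = rr$ci_low,
             ci_high = rr$ci_high,
             significant = bonferroni_flag(p, alpha, m_tests),
             stringsAsFactors = FALSE)
}

#' Pairwise Kolmogorov-Smirnov matrix of length distributions
#'
#' Computes the two-sample Kolmogorov-Smirnov statistic
#' `D = sup |ECDF_i - ECDF_j|` for every pair of species length samples
#' and clusters the species hierarchically on the rows of `D` with
#' distance one minus the Pearson correlation and average linkage.
#'
#' @param length_samples Named list of numeric vectors (one per species).
#'   Species with fewer than 2 observations are excluded with a warning.
#' @return An object of class `ks_matrix`: list with `labels`, `D`
#'   (symmetric matrix, zero diagonal) and `hclust` (the dendrogram;
#'   `NULL` when fewer than 3 species remain).
#' @export
ks_species_matrix <- function(length_samples) {
  stopifnot(is.list(length_samples), !is.null(names(length_samples)))
  sizes <- vapply(length_samples, length, integer(1))
  if (any(sizes < 2L)) {
    warning("excluding species with < 2 observations: ",
            paste(names(length_samples)[sizes < 2L], collapse = ", "))
    length_samples <- length_samples[sizes >= 2L]
  }
  if (length(length_samples) < 2L)
    stop("need at least 2 species with >= 2 observations")
  labs <- names(length_samples)
  m <- length(labs)
  D <- matrix(0, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- suppressWarnings(
        ks.test(length_samples[[i]], length_samples[[j]]))$statistic
      D[i, j] <- D[j, i] <- unname(d)
    }
  }
  hc <- NULL
  if (m >= 3L) {
    dd <- as.dist(1 - cor(t(D)))
    hc <- hclust(dd, method = "average")
  }
  structure(list(labels = labs, D = D, hclust = hc), class = "ks_matrix")
}

#' @export
print.ks_matrix <- function(x, ...) {
  cat("pairwise Kolmogorov-Smirnov matrix over", length(x$labels),
      "species\n")
  print(round(x$D, 3))
  invisible(x)
}
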