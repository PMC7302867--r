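# Polytract territory: the merged set of genome nucleotides occupied by a
# chosen subset of polytracts (or hinge sites), the unit of all locational
# enrichment statistics. Carries the genome size N and territory size n.

#' Build a polytract territory
#'
#' Merges the intervals of a polytract subset (or of hinge sites) into a
#' disjoint territory and records the genome size `N` and territory size
#' `n`. By default each polytract is first extended by one neighboring
#' nucleotide bi-directionally (adjacency extension), the default mode of
#' the enrichment analysis; set `extend = FALSE` for the exact territory.
#' Hinge records (with a `pos` column) are accepted as width-1 intervals
#' and are not extended unless requested.
#'
#' @param tracts Polytract records (from [scan_sequence()],
#'   [scan_genome()] or a subset thereof), or hinge records from
#'   [find_hinges()].
#' @param seq_lengths Named vector of sequence lengths; defaults to the
#'   `seq_lengths` attribute of `tracts`. `N` is the sum of these lengths
#'   (all bases, Ns included).
#' @param extend Apply +/- 1 nt adjacency extension before merging.
#'   Defaults to `TRUE` for tracts and `FALSE` for hinges.
#' @param subset Free-text description of the subset (recorded in
#'   reports).
#' @return An object of class `polytract_territory`: a list with elements
#'   `intervals` (disjoint sorted data.frame, 0-based half-open), `N`,
#'   `n`, `extended`, `subset`, `seq_lengths`.
#' @examples
#' tr <- scan_sequence("AAAAAACCCCCCCC")
#' polytract_territory(tr, seq_lengths = c(seq = 14), extend = FALSE)
#' @export
polytract_territory <- function(tracts, seq_lengths = NULL, extend = NULL,
                                subset = "all") {
  seq_lengths <- .get_seq_lengths(tracts, seq_lengths)
  is_hinge <- "pos" %in% names(tracts)
  if (is.null(extend)) extend <- !is_hinge
  if (is_hinge)
    tracts <- data.frame(chrom = tracts$chrom, start = tracts$pos,
                         end = tracts$pos + 1L, stringsAsFactors = FALSE)
  if (nrow(tracts)) {
    bad <- !(tracts$chrom %in% names(seq_lengths))
    if (any(bad)) {
      warning(sum(bad), " record(s) on sequences absent from seq_lengths ",
              "were skipped")
      tracts <- tracts[!bad, , drop = FALSE]
    }
  }
  iv <- if (extend) {
    extend_adjacency(tracts, seq_lengths)
  } else {
    .merge_intervals(tracts[, c("chrom", "start", "end"), drop = FALSE])
  }
  N <- sum(as.numeric(seq_lengths))
  n <- sum(as.numeric(iv$end - iv$start))
  if (n > N) stop("territory larger than genome; check seq_lengths")
  structure(list(intervals = iv, N = N, n = n, extended = extend,
                 subset = subset, seq_lengths = seq_lengths),
            class = "polytract_territory")
}

#' @export
print.polytract_territory <- function(x, ...) {
  cat(sprintf(
    "polytract territory '%s': n = %s of N = %s nt (%.3f%%), %d interval(s)%s\n",
    x$subset, format(x$n, big.mark = ",", scientific = FALSE),
    format(x$N, big.mark = ",", scientific = FALSE),
    100 * x$n / x$N, nrow(x$intervals),
    if (x$extended) ", adjacency-extended" else ""))
  invisible(x)
}

#' Summarize a polytract catalog
#'
#' Per-bin summary of a polytract catalog: record count, nucleotides
#' enclosed, percentage of the genome, mean and median record length, and
#' density (records per million base pairs). The genome size is the sum
#' of `seq_lengths` (Ns included). For `by = "chromosome"` the density
#' denominator is the chromosome's own length; otherwise the whole
#' genome.
#'
#' @param tracts Polytract records.
#' @param seq_lengths Named vector of sequence lengths.
#' @param by Binning: `"species"`, `"clade"` or `"chromosome"`.
#' @return A data.frame with one row per bin (empty bins retained with
#'   zero counts and `empty = TRUE`) and columns `bin`, `count`,
#'   `nucleotides`, `percent`, `mean_length`, `median_length`,
#'   `density_per_mb`, `empty`.
#' @export
summarize_catalog <- function(tracts, seq_lengths = NULL,
                              by = c("species", "clade", "chromosome")) {
  by <- match.arg(by)
  seq_lengths <- .get_seq_lengths(tracts, seq_lengths)
  N <- sum(as.numeric(seq_lengths))
  bins <- switch(by,
    species = {
      cat <- species_catalog()
      unique(cat[order(match(cat$clade, names(.CLADES))), "species"])
    },
    clade = names(.CLADES),
    chromosome = names(seq_lengths))
  key <- switch(by, species = tracts$species, clade = tracts$clade,
                chromosome = tracts$chrom)
  denom <- if (by == "chromosome") as.numeric(seq_lengths[bins]) else N
  rows <- lapply(seq_along(bins), function(i) {
    b <- bins[i]
    len <- tracts$length[key == b]
    d <- if (by == "chromosome") denom[i] else N
    data.frame(
      bin = b, count = length(len), nucleotides = sum(as.numeric(len)),
      percent = 100 * sum(as.numeric(len)) / N,
      mean_length = if (length(len)) mean(len) else 0,
      median_length = if (length(len)) median(len) else 0,
      density_per_mb = length(len) / (d / 1e6),
      empty = length(len) == 0L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Correlation between mean polytract length and density
#'
#' Pearson correlation (with a two-sided test of r != 0) between
#' per-chromosome mean polytract length and per-chromosome density,
#' typically computed on one clade at a time.
#'
#' @param mean_length Numeric vector of per-chromosome mean lengths.
#' @param density Numeric vector of per-chromosome densities (per Mb).
#' @return A list with `r`, `p` and `n` (chromosomes used). If either
#'   input has zero variance, `r` and `p` are `NA` with
#'   `degenerate = TRUE`.
#' @export
length_density_correlation <- function(mean_length, density) {
  stopifnot(length(mean_length) == length(density))
  keep <- is.finite(mean_length) & is.finite(density)
  x <- mean_length[keep]; y <- density[keep]
  if (length(x) < 3L)
    stop("need at least 3 chromosomes for a correlation test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}
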