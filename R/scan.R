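# Polytract scanning.
#
# A polytract is a maximal perfect run of a 1/2/3-nt unit, with any
# incomplete terminal unit included. Minimum 6 repeated units for MNR and 3
# for DNR/TNR, i.e. >= 6/6/9 nt. Clade membership is decided by the
# smallest period of the run, so AAAAAA is an MNR only and ATATAT a DNR
# only; scans for different clades are independent and their records may
# overlap each other (never records of the same clade). Non-ACGT
# characters terminate runs; scanning is case-insensitive.

.CLADES <- c(MNR = 1L, DNR = 2L, TNR = 3L)
.MIN_LEN <- c(MNR = 6L, DNR = 6L, TNR = 9L)

.empty_tracts <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             clade = character(0), species = character(0),
             unit_len = integer(0), length = integer(0),
             complete_units = integer(0), stringsAsFactors = FALSE)
}

# Scan one chromosome held as an uppercase raw vector.
.scan_raw <- function(x, chrom, clades) {
  n <- length(x)
  valid <- x == charToRaw("A") | x == charToRaw("C") |
           x == charToRaw("G") | x == charToRaw("T")
  out <- vector("list", length(clades))
  for (ci in seq_along(clades)) {
    clade <- clades[ci]
    p <- .CLADES[[clade]]
    minlen <- .MIN_LEN[[clade]]
    if (n < minlen) { out[[ci]] <- .empty_tracts(); next }
    # eq[j] <=> x[j + p] matches x[j] and both are ACGT; a maximal TRUE run
    # over eq indices [a, b] is a maximal period-p region [a, b + p]
    # (1-based, inclusive): extending one base on either side breaks the
    # lagged equality, which is exactly the maximality invariant.
    eq <- x[(1L + p):n] == x[1L:(n - p)] &
          valid[(1L + p):n] & valid[1L:(n - p)]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & r$lengths >= (minlen - p)
    if (!any(keep)) { out[[ci]] <- .empty_tracts(); next }
    a <- run_start[keep]
    b <- run_end[keep]
    start0 <- a - 1L          # 0-based inclusive
    end0 <- b + p             # 0-based exclusive
    # Reject runs whose smallest period is below p. For p = 2 a shorter
    # period means period 1; for p = 3, any run >= 9 nt with an additional
    # period 1 or 2 collapses to a homopolymer (Fine and Wilf), so both
    # cases reduce to "the leading unit is a homopolymer".
    if (p > 1L) {
      u1 <- x[start0 + 1L]
      degenerate <- u1 == x[start0 + 2L]
      if (p == 3L) degenerate <- degenerate & (x[start0 + 2L] == x[start0 + 3L])
      start0 <- start0[!degenerate]
      end0 <- end0[!degenerate]
    }
    if (!length(start0)) { out[[ci]] <- .empty_tracts(); next }
    units <- vapply(start0, function(s) rawToChar(x[(s + 1L):(s + p)]),
                    character(1))
    len <- end0 - start0
    out[[ci]] <- data.frame(
      chrom = chrom, start = start0, end = end0, clade = clade,
      species = .species_of(units), unit_len = p, length = len,
      complete_units = len %/% p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_raw_seq <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "XString"))
    seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  charToRaw(chartr("acgtn", "ACGTN", seq))
}

#' Scan a sequence for maximal perfect polytracts
#'
#' Finds every maximal perfect mono-/di-/tri-nucleotide repeat run (MNR,
#' DNR, TNR) in a nucleotide sequence, including any incomplete terminal
#' unit. Minimum run lengths are 6 nt for MNR and DNR (6 and 3 complete
#' units) and 9 nt for TNR (3 complete units). Each run is assigned the
#' clade of its smallest period and the canonical species of its unit.
#' Scans per clade are independent, so records of different clades may
#' overlap; records of the same clade never do. Lowercase (soft-masked)
#' input is treated as uppercase; N and other non-ACGT characters break
#' runs.
#'
#' @param seq A character string or [Biostrings::DNAString].
#' @param clades Clades to scan, subset of `c("MNR", "DNR", "TNR")`.
#' @param chrom Sequence name recorded in the output.
#' @return A data.frame of polytract records with columns `chrom`,
#'   `start`, `end` (0-based half-open), `clade`, `species`, `unit_len`,
#'   `length`, `complete_units`, sorted by start.
#' @examples
#' scan_sequence("TTTTTT")          # one MNR, species A/T
#' scan_sequence("GTGTGTG")         # one 7-nt DNR with a partial unit
#' scan_sequence("AACAACAA")        # empty: 8 nt < the 9-nt TNR minimum
#' @seealso [scan_genome()], [scan_bruteforce()], [find_hinges()]
#' @export
scan_sequence <- function(seq, clades = c("MNR", "DNR", "TNR"),
                          chrom = "seq") {
  clades <- match.arg(clades, c("MNR", "DNR", "TNR"), several.ok = TRUE)
  x <- .as_raw_seq(seq)
  if (!length(x)) return(.empty_tracts())
  .scan_raw(x, chrom, clades)
}

#' Scan a multi-sequence genome for polytracts
#'
#' Applies [scan_sequence()] to every sequence of a genome given as a
#' FASTA file or a [Biostrings::DNAStringSet].
#'
#' @param genome Path to a FASTA file (plain or bgzipped) or a
#'   `DNAStringSet`.
#' @param clades Clades to scan.
#' @param seqnames Optional character vector restricting which sequences
#'   are scanned.
#' @return A data.frame of polytract records sorted by (chrom, start),
#'   with attribute `seq_lengths` (named integer vector of the scanned
#'   sequence lengths, Ns included).
#' @export
scan_genome <- function(genome, clades = c("MNR", "DNR", "TNR"),
                        seqnames = NULL) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  nm <- names(genome)
  if (is.null(nm)) nm <- paste0("seq", seq_along(genome))
  # FASTA headers: keep the first word as the sequence name
  nm <- sub("\\s.*$", "", nm)
  names(genome) <- nm
  if (!is.null(seqnames)) {
    missing <- setdiff(seqnames, nm)
    if (length(missing))
      warning("sequences not found and skipped: ",
              paste(missing, collapse = ", "))
    genome <- genome[intersect(seqnames, nm)]
  }
  res <- lapply(names(genome), function(ch)
    scan_sequence(as.character(genome[[ch]]), clades = clades, chrom = ch))
  res <- do.call(rbind, res)
  if (is.null(res)) res <- .empty_tracts()
  lens <- setNames(Biostrings::width(genome), names(genome))
  res <- res[order(match(res$chrom, names(genome)), res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "seq_lengths") <- lens
  res
}

#' Brute-force reference polytract scanner
#'
#' A deliberately naive scanner that enumerates every interval of the
#' sequence, tests its smallest period, the clade length minimum and
#' two-sided maximality directly, and returns the surviving records. It is
#' shipped as an independent reference implementation for validating
#' [scan_sequence()]; it is orders of magnitude slower and intended for
#' sequences of at most a few kilobases.
#'
#' @inheritParams scan_sequence
#' @return A data.frame in the same format as [scan_sequence()].
#' @export
scan_bruteforce <- function(seq, clades = c("MNR", "DNR", "TNR"),
                            chrom = "seq") {
  clades <- match.arg(clades, c("MNR", "DNR", "TNR"), several.ok = TRUE)
  x <- .as_raw_seq(seq)
  if (!length(x)) return(.empty_tracts())
  m <- scan_bruteforce_cpp(x, .CLADES[clades])
  if (!nrow(m)) return(.empty_tracts())
  units <- vapply(seq_len(nrow(m)), function(i)
    rawToChar(x[(m$start[i] + 1L):(m$start[i] + m$unit_len[i])]),
    character(1))
  len <- m$end - m$start
  res <- data.frame(
    chrom = chrom, start = m$start, end = m$end,
    clade = names(.CLADES)[m$unit_len], species = .species_of(units),
    unit_len = m$unit_len, length = len,
    complete_units = len %/% m$unit_len, stringsAsFactors = FALSE)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

#' Find hinge sites between tandem polytracts
#'
#' A hinge is a single nucleotide separating two tandem polytracts: some
#' polytract ends exactly at the hinge position and another starts
#' immediately after it, and the hinge base itself lies inside no
#' polytract of any clade. The two flanking species are reported as an
#' unordered duplex label. When several tracts share the boundary, the
#' longest abutting tract per side labels the hinge (ties broken by clade
#' priority MNR > DNR > TNR).
#'
#' @param tracts Polytract records from [scan_sequence()] or
#'   [scan_genome()], scanned over all three clades.
#' @param seq_lengths Optional named vector of sequence lengths (taken
#'   from the `seq_lengths` attribute of `tracts` when present).
#' @return A data.frame with columns `chrom`, `pos` (0-based),
#'   `left_species`, `right_species`, `duplex`.
#' @examples
#' tr <- scan_sequence("AAAAAAGTTTTTT")
#' find_hinges(tr)   # one hinge at pos 6, duplex A/T+A/T
#' @export
find_hinges <- function(tracts, seq_lengths = NULL) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      left_species = character(0),
                      right_species = character(0), duplex = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(tracts)) return(empty)
  res <- lapply(split(tracts, tracts$chrom), function(tr) {
    pos <- intersect(tr$end, tr$start - 1L)
    if (!length(pos)) return(empty)
    # the hinge base must not be covered by any tract of any clade
    cov <- IRanges::reduce(IRanges::IRanges(tr$start + 1L, tr$end))
    inside <- IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), cov)
    pos <- sort(pos[!inside])
    if (!length(pos)) return(empty)
    pick <- function(cand) {
      cand <- cand[order(-cand$length, match(cand$clade, names(.CLADES))), ]
      cand$species[1]
    }
    left <- vapply(pos, function(g) pick(tr[tr$end == g, ]), character(1))
    right <- vapply(pos, function(g) pick(tr[tr$start == g + 1L, ]),
                    character(1))
    duplex <- mapply(function(l, r) paste(sort(c(l, r)), collapse = "+"),
                     left, right)
    data.frame(chrom = tr$chrom[1], pos = pos, left_species = left,
               right_species = right, duplex = unname(duplex),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Extend polytracts by one nucleotide bi-directionally
#'
#' Widens each polytract interval by a single immediately neighboring
#' nucleotide on both sides (clipped at sequence bounds) and merges the
#' result into disjoint intervals. This adjacency extension captures
#' features at repeat boundaries and is the default territory mode of the
#' enrichment analysis.
#'
#' @param tracts Polytract records.
#' @param seq_lengths Named vector of sequence lengths; defaults to the
#'   `seq_lengths` attribute of `tracts`.
#' @return A data.frame of disjoint intervals (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @export
extend_adjacency <- function(tracts, seq_lengths = NULL) {
  seq_lengths <- .get_seq_lengths(tracts, seq_lengths)
  if (!nrow(tracts))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  start <- pmax(0L, tracts$start - 1L)
  end <- pmin(unname(seq_lengths[tracts$chrom]), tracts$end + 1L)
  .merge_intervals(data.frame(chrom = tracts$chrom, start = start,
                              end = end, stringsAsFactors = FALSE))
}

#' Keep long trinucleotide repeats
#'
#' Subsets TNR records to those spanning at least `min_len` nucleotides
#' (default 18 nt, i.e. six or more complete or incomplete trimer units),
#' matching the long-repeat convention of earlier trinucleotide surveys.
#'
#' @param tracts Polytract records.
#' @param min_len Minimum length in nucleotides.
#' @return The TNR subset of `tracts` with `length >= min_len`.
#' @export
filter_long_tnr <- function(tracts, min_len = 18L) {
  res <- tracts[tracts$clade == "TNR" & tracts$length >= min_len, ,
                drop = FALSE]
  rownames(res) <- NULL
  res
}

# seq_lengths resolution used across the package
.get_seq_lengths <- function(tracts, seq_lengths = NULL) {
  if (is.null(seq_lengths)) seq_lengths <- attr(tracts, "seq_lengths")
  if (is.null(seq_lengths)) {
    if (!nrow(tracts))
      stop("seq_lengths required when tracts carry no seq_lengths attribute")
    # fall back to the rightmost record per chromosome
    seq_lengths <- tapply(tracts$end, tracts$chrom, max)
    seq_lengths <- setNames(as.integer(seq_lengths), names(seq_lengths))
    warning("seq_lengths missing; using rightmost record end per sequence")
  }
  stopifnot(!is.null(names(seq_lengths)))
  seq_lengths
}

# merge possibly-overlapping 0-based intervals into disjoint sorted ones
.merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end))
  gr <- GenomicRanges::reduce(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
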