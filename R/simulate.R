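# Synthetic genomes with planted polytracts and feature sets with
# controlled enrichment. The generator makes every statistic in the
# package testable without any external genome: backgrounds are guaranteed
# repeat-free, planted repeats are recovered exactly by the scanner, and
# features are placed inside the territory with a designed probability
# pi = c * n/N so the relative risk converges to the multiplier c.

.ACGT_RAW <- charToRaw("ACGT")

# first base distinct from every base in `forbid` (raw vector)
.pick_base <- function(forbid) {
  for (b in .ACGT_RAW) if (!any(b == forbid)) return(b)
  stop("no admissible base")  # unreachable: at most 3 distinct constraints
}

# replace x[i] (1-based) with a base differing from itself and neighbors
.break_at <- function(x, i) {
  n <- length(x)
  forbid <- x[unique(pmax(1L, pmin(n, c(i - 1L, i, i + 1L))))]
  x[i] <- .pick_base(forbid)
  x
}

#' Generate a repeat-free background sequence
#'
#' Draws an i.i.d. ACGT sequence and deterministically repairs every
#' qualifying polytract run (by substituting its center base with one
#' that differs from the run and its neighbors) until a full scan over
#' all three clades returns nothing. Output is reproducible for a given
#' seed.
#'
#' @param length Sequence length in nt.
#' @param seed Integer RNG seed.
#' @return A character string of `length` nt containing no polytract.
#' @export
generate_background <- function(length, seed = 1L) {
  stopifnot(length > 0)
  set.seed(seed)
  x <- sample(.ACGT_RAW, length, replace = TRUE)
  for (iter in 1:50) {
    tr <- .scan_raw(x, "bg", names(.CLADES))
    if (!nrow(tr)) return(rawToChar(x))
    for (i in seq_len(nrow(tr)))
      x <- .break_at(x, tr$start[i] + tr$length[i] %/% 2L + 1L)
  }
  stop("background repair did not converge")  # not observed in practice
}

#' Plant polytracts into a background sequence
#'
#' Writes the requested perfect repeats into a repeat-free background and
#' repairs the flanking bases so that each planted repeat is recovered by
#' [scan_sequence()] exactly as specified: flank bases that would extend
#' a repeat are substituted, and any residual accidental run created at a
#' junction is broken outside the planted intervals. The function
#' verifies recovery by scanning and errors if the truth cannot be
#' isolated.
#'
#' Planted repeats must not overlap and must be separated by at least two
#' nucleotides, except that a one-nucleotide gap (a hinge) is admitted
#' when `allow_hinge = TRUE`.
#'
#' @param background Character string from [generate_background()] (any
#'   repeat-free sequence works).
#' @param spec data.frame with columns `pos` (0-based start), `unit`
#'   (1-3 nt, non-degenerate), `n_units` (complete units) and
#'   `partial_nt` (0 to unit length - 1 extra nucleotides of an
#'   incomplete terminal unit).
#' @param chrom Sequence name used in the truth records.
#' @param allow_hinge Admit one-nucleotide gaps between planted repeats.
#' @return A list with `genome` (character string) and `truth` (polytract
#'   records in [scan_sequence()] format, carrying a `seq_lengths`
#'   attribute).
#' @examples
#' bg <- generate_background(500, seed = 3)
#' sp <- data.frame(pos = 100, unit = "CA", n_units = 3, partial_nt = 1)
#' pl <- plant_tracts(bg, sp)
#' pl$truth  # one DNR CA/GT at [100, 107)
#' @export
plant_tracts <- function(background, spec, chrom = "seq",
                         allow_hinge = FALSE) {
  stopifnot(is.data.frame(spec),
            all(c("pos", "unit", "n_units", "partial_nt") %in% names(spec)))
  x <- charToRaw(chartr("acgt", "ACGT", background))
  n <- length(x)
  spec <- spec[order(spec$pos), , drop = FALSE]
  p <- nchar(spec$unit)
  stopifnot(all(spec$partial_nt >= 0 & spec$partial_nt < p),
            all(spec$n_units >= 1))
  len <- spec$n_units * p + spec$partial_nt
  clade <- names(.CLADES)[p]
  if (any(len < .MIN_LEN[clade]))
    stop("planted tract shorter than its clade minimum")
  start <- as.integer(spec$pos)
  end <- start + as.integer(len)
  if (any(start < 0 | end > n)) stop("planted tract outside background")
  if (nrow(spec) > 1) {
    gap <- start[-1] - end[-nrow(spec)]
    if (any(gap < 1)) stop("planted tracts overlap or abut")
    if (any(gap == 1) && !allow_hinge)
      stop("one-nucleotide gaps form hinges; set allow_hinge = TRUE")
  }
  species <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    cs <- canonical_species(spec$unit[i])  # validates non-degeneracy
    species[i] <- cs$species
    run <- paste0(strrep(toupper(spec$unit[i]), spec$n_units[i]),
                  substr(toupper(spec$unit[i]), 1, spec$partial_nt[i]))
    x[(start[i] + 1L):end[i]] <- charToRaw(run)
  }
  truth <- data.frame(chrom = chrom, start = start, end = end,
                      clade = clade, species = species, unit_len = p,
                      length = as.integer(len),
                      complete_units = as.integer(len %/% p),
                      stringsAsFactors = FALSE)
  planted_cov <- rep(FALSE, n)
  for (i in seq_len(nrow(spec))) planted_cov[(start[i] + 1L):end[i]] <- TRUE
  # flank repair: a flank base equal to the base one period inside the
  # tract would extend the run, so it must differ; at a hinge both sides
  # constrain the same base
  forbid <- vector("list", n)
  for (i in seq_len(nrow(spec))) {
    lf <- start[i]           # 1-based index of the left flank base
    if (lf >= 1L) forbid[[lf]] <- c(forbid[[lf]], x[lf + p[i]])
    rf <- end[i] + 1L        # 1-based index of the right flank base
    if (rf <= n) forbid[[rf]] <- c(forbid[[rf]], x[rf - p[i]])
  }
  for (i in which(!vapply(forbid, is.null, logical(1)))) {
    if (any(x[i] == forbid[[i]])) {
      soft <- x[unique(pmax(1L, pmin(n, c(i - 1L, i + 1L))))]
      cand <- setdiff(as.integer(.ACGT_RAW),
                      as.integer(c(forbid[[i]], soft)))
      if (!length(cand))
        cand <- setdiff(as.integer(.ACGT_RAW), as.integer(forbid[[i]]))
      x[i] <- as.raw(cand[1])
    }
  }
  # verification: scan must return exactly the truth; break accidental
  # junction runs at a position outside every planted interval,
  # preferring positions that are not constrained flank bases (breaking
  # at a flank could re-extend a planted run and oscillate)
  flank_pos <- unique(c(start, end + 1L))  # 1-based flank base indices
  flank_pos <- flank_pos[flank_pos >= 1L & flank_pos <= n]
  sig <- function(df) paste(df$start, df$end, df$clade)
  for (iter in 1:40) {
    found <- .scan_raw(x, chrom, names(.CLADES))
    extra <- found[!(sig(found) %in% sig(truth)), , drop = FALSE]
    if (!nrow(extra) && nrow(found) == nrow(truth)) {
      out <- list(genome = rawToChar(x), truth = truth)
      attr(out$truth, "seq_lengths") <- setNames(n, chrom)
      return(out)
    }
    if (!nrow(extra)) break
    for (i in seq_len(nrow(extra))) {
      cand <- (extra$start[i] + 1L):extra$end[i]
      cand <- cand[!planted_cov[cand]]
      safe <- setdiff(cand, flank_pos)
      if (length(safe)) cand <- safe
      if (!length(cand)) next
      mid <- cand[which.min(abs(cand - (extra$start[i] + extra$end[i]) / 2))]
      x <- .break_at(x, mid)
    }
  }
  stop("could not isolate planted tracts from the background")
}

#' Random planting specification
#'
#' Draws a reproducible random set of non-overlapping repeat-planting
#' requests (random units across all species, random unit counts,
#' optional incomplete terminal units) spaced at least two nucleotides
#' apart, optionally with a number of one-nucleotide hinge gaps.
#'
#' @param genome_length Background length in nt.
#' @param n_tracts Number of repeats to plant.
#' @param seed Integer RNG seed.
#' @param n_hinges Number of adjacent pairs separated by exactly one
#'   nucleotide.
#' @return A `spec` data.frame for [plant_tracts()], with attribute
#'   `allow_hinge` set when `n_hinges > 0`.
#' @export
random_plant_spec <- function(genome_length, n_tracts, seed = 1L,
                              n_hinges = 0L) {
  stopifnot(n_tracts >= 1, n_hinges >= 0, n_hinges < n_tracts)
  set.seed(seed)
  cat <- species_catalog()
  unit <- sample(cat$unit, n_tracts, replace = TRUE)
  p <- nchar(unit)
  min_units <- ifelse(p == 1L, 6L, 3L)
  n_units <- min_units + sample(0:9, n_tracts, replace = TRUE)
  partial <- vapply(p, function(pp) sample(0:(pp - 1L), 1L), integer(1))
  len <- n_units * p + partial
  gaps <- rep(2L, n_tracts)  # gap before each tract
  if (n_hinges > 0)
    gaps[1L + sample(seq_len(n_tracts - 1L), n_hinges)] <- 1L
  slack <- genome_length - sum(len) - sum(gaps) - 2L
  if (slack < 0) stop("genome_length too small for the requested tracts")
  extra <- diff(c(0, sort(sample.int(slack + 1L, n_tracts) - 1L)))
  # hinge gaps stay exactly 1 nt wide
  extra[gaps == 1L] <- 0L
  pos <- cumsum(gaps + extra) + c(0L, cumsum(len))[seq_len(n_tracts)]
  spec <- data.frame(pos = pos, unit = unit, n_units = n_units,
                     partial_nt = partial, stringsAsFactors = FALSE)
  attr(spec, "allow_hinge") <- n_hinges > 0
  spec
}

#' Sample features with controlled territory enrichment
#'
#' Places `M` feature instances independently: with probability
#' `pi = c * n/N` an instance starts at a uniformly chosen territory
#' nucleotide, otherwise at a uniformly chosen nucleotide outside the
#' territory. For single-nucleotide features the expected singleton
#' overlap is exactly `M * pi`, so the empirical relative risk converges
#' to the multiplier `c` (`c = 1` is the uniform null of the binomial
#' test).
#'
#' @param territory A [polytract_territory()].
#' @param M Number of feature instances (> 0).
#' @param c Enrichment multiplier; `c * n/N` must be at most 1.
#' @param feature_length Instance length in nt (placement refers to the
#'   start nucleotide; ends are clipped at sequence bounds).
#' @param seed Integer RNG seed (`NULL` to use the current RNG state).
#' @return A data.frame with `chrom`, `start`, `end`.
#' @export
generate_features <- function(territory, M, c = 1, feature_length = 1L,
                              seed = NULL) {
  stopifnot(inherits(territory, "polytract_territory"), M > 0, c >= 0)
  pi_in <- c * territory$n / territory$N
  if (pi_in > 1) stop("c * n/N exceeds 1; reduce the multiplier")
  if (!is.null(seed)) set.seed(seed)
  inside <- runif(M) < pi_in
  iv_in <- territory$intervals
  iv_out <- .complement_intervals(iv_in, territory$seq_lengths)
  pos <- integer(M); ch <- character(M)
  place <- function(iv, total, count) {
    w <- iv$end - iv$start
    b <- c(0, cumsum(as.numeric(w)))
    u <- floor(runif(count) * total)
    idx <- findInterval(u, b, rightmost.closed = FALSE)
    list(chrom = iv$chrom[idx], pos = iv$start[idx] + (u - b[idx]))
  }
  if (any(inside)) {
    pl <- place(iv_in, territory$n, sum(inside))
    ch[inside] <- pl$chrom; pos[inside] <- pl$pos
  }
  if (any(!inside)) {
    pl <- place(iv_out, territory$N - territory$n, sum(!inside))
    ch[!inside] <- pl$chrom; pos[!inside] <- pl$pos
  }
  lim <- unname(territory$seq_lengths[ch])
  data.frame(chrom = ch, start = as.integer(pos),
             end = as.integer(pmin(pos + feature_length, lim)),
             stringsAsFactors = FALSE)
}

# complement of disjoint sorted intervals within [0, L) per chromosome
.complement_intervals <- function(iv, seq_lengths) {
  out <- lapply(names(seq_lengths), function(ch) {
    L <- seq_lengths[[ch]]
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    starts <- c(0L, sub$end)
    ends <- c(sub$start, L)
    keep <- ends > starts
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
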