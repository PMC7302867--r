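# Genomic region annotation of polytracts from Ensembl-dialect GTF gene
# models. Each polytract is assigned the highest-precedence category it
# overlaps:
#   exonic_splicing > UTR5 > UTR3 > ncRNA > intronic > up_down_stream >
#   intergenic
# "exonic_splicing" means the coding (CDS) part of protein-coding exons
# or a window around an intron/exon boundary; UTRs are the annotated
# 5'/3' untranslated exon parts; ncRNA means exons of non-protein-coding
# genes; intronic is the remaining gene body; up_down_stream is the
# 1-kb segment flanking a gene body anchored at the transcription
# start/end site; everything else is intergenic.

.REGION_CATEGORIES <- c("exonic_splicing", "UTR5", "UTR3", "ncRNA",
                        "intronic", "up_down_stream", "intergenic")

#' Load gene models from an Ensembl GTF
#'
#' Imports an Ensembl-dialect GTF and organizes the features needed for
#' region assignment: gene spans with biotype, unique exon intervals,
#' CDS, 5'/3' UTRs and per-transcript introns. Duplicate exon intervals
#' (same coordinates, strand and gene) are collapsed to unique intervals.
#' Records lacking a `gene_id` are rejected with a warning. Plain `UTR`
#' features (older GENCODE dialect) are split into 5'/3' by their
#' position relative to the transcript's CDS.
#'
#' @param gtf Path to a GTF file, or a [GenomicRanges::GRanges] as
#'   returned by [rtracklayer::import()].
#' @return An object of class `gene_models`: list of GRanges (`genes`,
#'   `exons`, `cds`, `utr5`, `utr3`, `nc_exons`, `introns`) plus
#'   `n_genes`.
#' @export
load_gene_models <- function(gtf) {
  gr <- if (is.character(gtf)) rtracklayer::import(gtf, format = "gtf")
        else gtf
  stopifnot(methods::is(gr, "GRanges"))
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc)) stop("GTF lacks a feature type column")
  bt_col <- intersect(c("gene_biotype", "gene_type"), names(mc))[1]
  if (is.na(bt_col)) {
    warning("GTF lacks gene_biotype/gene_type; treating all genes as ",
            "protein_coding")
    gr$gene_biotype <- "protein_coding"
    bt_col <- "gene_biotype"
  }
  if (!"gene_id" %in% names(mc)) stop("GTF lacks gene_id attributes")
  no_gene <- is.na(gr$gene_id)
  if (any(no_gene)) {
    warning(sum(no_gene), " record(s) without gene_id rejected")
    gr <- gr[!no_gene]
  }
  biotype <- S4Vectors::mcols(gr)[[bt_col]]
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) {
    # derive gene spans from any feature grouped by gene_id
    genes <- .group_spans(gr, gr$gene_id)
    genes$gene_id <- names(genes)
    genes$biotype <- vapply(split(as.character(biotype), gr$gene_id),
                            function(b) b[1], character(1))[genes$gene_id]
    warning("GTF has no gene lines; spans derived from other features")
  } else {
    genes$biotype <- S4Vectors::mcols(genes)[[bt_col]]
  }
  exons <- gr[gr$type == "exon"]
  exons$biotype <- biotype[gr$type == "exon"]
  if (!length(exons))
    warning("GTF contains no exon features; gene models have empty ",
            "exon sets")
  # unique exon intervals per gene
  key <- paste(GenomicRanges::seqnames(exons), GenomicRanges::start(exons),
               GenomicRanges::end(exons), GenomicRanges::strand(exons),
               exons$gene_id)
  exons <- exons[!duplicated(key)]
  cds <- gr[gr$type == "CDS"]
  utr5 <- gr[gr$type %in% c("five_prime_utr", "5UTR")]
  utr3 <- gr[gr$type %in% c("three_prime_utr", "3UTR")]
  plain_utr <- gr[gr$type == "UTR"]
  if (length(plain_utr) && length(cds)) {
    five <- .classify_plain_utr(plain_utr, cds)
    utr5 <- c(utr5, plain_utr[five])
    utr3 <- c(utr3, plain_utr[!five])
  }
  pc <- !is.na(exons$biotype) & exons$biotype == "protein_coding"
  nc_exons <- exons[!pc]
  introns <- .derive_introns(exons)
  structure(list(genes = genes, exons = exons, cds = cds, utr5 = utr5,
                 utr3 = utr3, nc_exons = nc_exons, introns = introns,
                 n_genes = length(genes)),
            class = "gene_models")
}

# one span [min(start), max(end)] per group of co-located features
.group_spans <- function(gr, grp) {
  s <- tapply(GenomicRanges::start(gr), grp, min)
  e <- tapply(GenomicRanges::end(gr), grp, max)
  ch <- tapply(as.character(GenomicRanges::seqnames(gr)), grp, `[`, 1)
  st <- tapply(as.character(GenomicRanges::strand(gr)), grp, `[`, 1)
  out <- GenomicRanges::GRanges(unname(ch), IRanges::IRanges(
    as.integer(s), as.integer(e)), strand = unname(st))
  names(out) <- names(s)
  out
}

# 5' vs 3' for dialects that only annotate "UTR": compare to the CDS span
# of the same transcript, honoring strand.
.classify_plain_utr <- function(utr, cds) {
  cds_rng <- .group_spans(cds, cds$transcript_id)
  mid <- (GenomicRanges::start(utr) + GenomicRanges::end(utr)) / 2
  vapply(seq_along(utr), function(i) {
    tid <- utr$transcript_id[i]
    if (is.na(tid) || !tid %in% names(cds_rng)) return(TRUE)
    r <- cds_rng[tid]
    upstream <- mid[i] < GenomicRanges::start(r)
    if (as.character(GenomicRanges::strand(utr)[i]) == "-") !upstream
    else upstream
  }, logical(1))
}

# per-transcript introns: gaps between consecutive (merged) exons
.derive_introns <- function(exons) {
  if (!length(exons)) return(GenomicRanges::GRanges())
  has_tx <- "transcript_id" %in% names(S4Vectors::mcols(exons)) &&
    !all(is.na(exons$transcript_id))
  grp <- if (has_tx) exons$transcript_id else exons$gene_id
  red <- GenomicRanges::reduce(S4Vectors::split(exons, grp))  # sorted within groups
  un <- unlist(red, use.names = FALSE)
  g <- rep(seq_along(red), S4Vectors::elementNROWS(red))
  n <- length(un)
  if (n < 2L) return(GenomicRanges::GRanges())
  i <- which(g[-n] == g[-1])  # consecutive exon pairs within a transcript
  s <- GenomicRanges::end(un)[i] + 1L
  e <- GenomicRanges::start(un)[i + 1L] - 1L
  keep <- e >= s
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(un))[i][keep],
    IRanges::IRanges(s[keep], e[keep]))
}

#' Assign genomic region categories to intervals
#'
#' Assigns each query interval the highest-precedence of the seven region
#' categories it overlaps: `exonic_splicing` (CDS of a protein-coding
#' exon or within `splice_window` nt of an intron/exon boundary), `UTR5`,
#' `UTR3`, `ncRNA` (exon of a non-protein-coding gene), `intronic` (gene
#' body otherwise), `up_down_stream` (within `updown_kb` kb of a gene
#' span) and `intergenic`. Assignment is deterministic and independent of
#' gene-model input order.
#'
#' @param intervals A data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or GRanges of query intervals, e.g. polytract records.
#' @param models A [load_gene_models()] object.
#' @param updown_kb Width of the up/downstream flank in kb (default 1).
#' @param splice_window Half-width in nt of the splice-junction window
#'   around each intron/exon boundary (default 2).
#' @return Character vector of categories, one per interval.
#' @export
assign_region <- function(intervals, models, updown_kb = 1,
                          splice_window = 2) {
  stopifnot(inherits(models, "gene_models"))
  iv <- .features_df(intervals)
  q <- GenomicRanges::GRanges(iv$chrom,
                              IRanges::IRanges(iv$start + 1L, iv$end))
  splice <- .splice_zones(models$introns, splice_window)
  updown <- .flanks(models$genes, updown_kb * 1000)
  sets <- list(
    exonic_splicing = c(GenomicRanges::granges(models$cds), splice),
    UTR5 = GenomicRanges::granges(models$utr5),
    UTR3 = GenomicRanges::granges(models$utr3),
    ncRNA = GenomicRanges::granges(models$nc_exons),
    intronic = GenomicRanges::granges(models$genes),
    up_down_stream = updown)
  out <- rep("intergenic", length(q))
  # lowest precedence first, higher categories overwrite
  for (catg in rev(names(sets))) {
    s <- sets[[catg]]
    if (length(s)) out[IRanges::overlapsAny(q, s)] <- catg
  }
  out
}

.splice_zones <- function(introns, w) {
  if (!length(introns) || w <= 0) return(GenomicRanges::GRanges())
  b <- GenomicRanges::start(introns)  # first intronic base (1-based)
  e <- GenomicRanges::end(introns)    # last intronic base
  ch <- as.character(GenomicRanges::seqnames(introns))
  # window of w bases on each side of both intron/exon boundaries
  GenomicRanges::reduce(GenomicRanges::GRanges(
    rep(ch, 2),
    IRanges::IRanges(c(pmax(1, b - w), pmax(1, e - w + 1)),
                     c(b + w - 1, e + w))))
}

.flanks <- function(genes, width) {
  if (!length(genes) || width <= 0) return(GenomicRanges::GRanges())
  s <- GenomicRanges::start(genes)
  e <- GenomicRanges::end(genes)
  ch <- as.character(GenomicRanges::seqnames(genes))
  up <- IRanges::IRanges(pmax(1, s - width), pmax(1, s - 1))
  down <- IRanges::IRanges(e + 1, e + width)
  keep_up <- s > 1
  GenomicRanges::reduce(c(
    GenomicRanges::GRanges(ch[keep_up], up[keep_up]),
    GenomicRanges::GRanges(ch, down)))
}

#' Region category distribution per species
#'
#' Assigns every polytract a region category and tabulates counts and
#' fractions per species; fractions sum to one within each species.
#'
#' @param tracts Polytract records.
#' @param models A [load_gene_models()] object.
#' @inheritParams assign_region
#' @return A data.frame with columns `species`, `category`, `count`,
#'   `fraction`.
#' @export
region_distribution <- function(tracts, models, updown_kb = 1,
                                splice_window = 2) {
  catg <- assign_region(tracts, models, updown_kb, splice_window)
  catg <- factor(catg, levels = .REGION_CATEGORIES)
  tab <- table(species = tracts$species, category = catg)
  res <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(res)[3] <- "count"
  tot <- tapply(res$count, res$species, sum)
  res$fraction <- res$count / as.numeric(tot[res$species])
  res[order(res$species, match(res$category, .REGION_CATEGORIES)), ,
      drop = FALSE]
}
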