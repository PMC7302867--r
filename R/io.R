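# File formats: FASTA in, BED out/in for tracts, hinges and features,
# chrom/pos TSV for point features, TSV reports with a reproducibility
# header. All BED coordinates are 0-based half-open; the points TSV is
# 1-based (converted on read).

#' Read a FASTA file
#'
#' @param path FASTA file (plain or gzip/bgzip compressed).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write polytract records as BED6
#'
#' One BED line per polytract: name is `clade:species`, score the length
#' in nt, strand `"."` (species already merge both strands).
#'
#' @param tracts Polytract records.
#' @param path Output path.
#' @export
write_tracts_bed <- function(tracts, path) {
  df <- data.frame(tracts$chrom, tracts$start, tracts$end,
                   paste0(tracts$clade, ":", tracts$species),
                   tracts$length, ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read polytract records from BED6
#'
#' Inverse of [write_tracts_bed()]: parses `clade:species` names back
#' into record fields and recomputes unit length and complete units.
#'
#' @param path BED file written by [write_tracts_bed()].
#' @return Polytract records.
#' @export
read_tracts_bed <- function(path) {
  bed <- read_bed(path)
  if (!nrow(bed)) return(.empty_tracts())
  parts <- strsplit(bed$name, ":", fixed = TRUE)
  clade <- vapply(parts, `[`, character(1), 1)
  species <- vapply(parts, `[`, character(1), 2)
  if (any(!clade %in% names(.CLADES)) || anyNA(species))
    stop("BED names are not clade:species labels; not a polytract BED")
  p <- .CLADES[clade]
  len <- bed$end - bed$start
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             clade = clade, species = species, unit_len = unname(p),
             length = len, complete_units = unname(len %/% p),
             stringsAsFactors = FALSE)
}

#' Write hinge records as BED4
#'
#' @param hinges Hinge records from [find_hinges()].
#' @param path Output path.
#' @export
write_hinges_bed <- function(hinges, path) {
  df <- data.frame(hinges$chrom, hinges$pos, hinges$pos + 1L,
                   hinges$duplex)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic features
#'
#' Tolerant BED3+ reader: malformed lines (fewer than three fields,
#' non-numeric or inverted coordinates) are skipped with a warning that
#' reports their count, and the run continues.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `name` (NA when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[\t ]+")
  ok <- vapply(fields, function(f) {
    length(f) >= 3 && !anyNA(suppressWarnings(as.integer(f[2:3]))) &&
      as.integer(f[2]) >= 0 && as.integer(f[3]) > as.integer(f[2])
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed BED line(s) skipped in ", path)
  fields <- fields[ok]
  if (!length(fields)) return(empty)
  data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    name = vapply(fields, function(f)
      if (length(f) >= 4) f[4] else NA_character_, character(1)),
    stringsAsFactors = FALSE)
}

#' Read point features from a two-column TSV
#'
#' Expects `chrom <TAB> pos` with 1-based positions (header optional;
#' a first line whose second field is non-numeric is skipped). Positions
#' are converted to 0-based internally.
#'
#' @param path TSV file.
#' @return data.frame with `chrom`, `start`, `end` (width-1 intervals).
#' @export
read_points_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "[\t ]+")
  ok <- vapply(fields, function(f)
    length(f) >= 2 && !is.na(suppressWarnings(as.integer(f[2]))) &&
      as.integer(f[2]) >= 1, logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0 && !(n_bad == 1 && !ok[1]))  # tolerate a header line
    warning(n_bad, " malformed line(s) skipped in ", path)
  fields <- fields[ok]
  pos1 <- as.integer(vapply(fields, `[`, character(1), 2))
  data.frame(chrom = vapply(fields, `[`, character(1), 1),
             start = pos1 - 1L, end = pos1, stringsAsFactors = FALSE)
}

#' Read a genome size table
#'
#' Two-column TSV `chrom <TAB> length`.
#'
#' @param path TSV file.
#' @return Named integer vector of sequence lengths.
#' @export
read_sizes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  setNames(df$length, df$chrom)
}

#' Write a genome size table
#' @param seq_lengths Named vector of sequence lengths.
#' @param path Output path.
#' @export
write_sizes_tsv <- function(seq_lengths, path) {
  write.table(data.frame(names(seq_lengths),
                         format(unname(seq_lengths), scientific = FALSE,
                                trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Writes result rows as TSV with a commented reproducibility header
#' (package version, configuration, seed). Column order and float
#' formatting are deterministic, so identical inputs produce
#' byte-identical reports.
#'
#' @param results data.frame of result rows (e.g. from
#'   [polytract_enrichment()]).
#' @param path Output path.
#' @param config Optional named list recorded in the header.
#' @export
write_report <- function(results, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# polytractr %s", packageVersion("polytractr")), con)
  for (nm in names(config))
    writeLines(sprintf("# %s=%s", nm,
                       paste(format(config[[nm]]), collapse = ",")), con)
  out <- results
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.6g", v))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a summary table
#' @param summary data.frame from [summarize_catalog()].
#' @param path Output path.
#' @export
write_summary_tsv <- function(summary, path) {
  write_report(summary, path)
}
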