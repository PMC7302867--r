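#' @useDynLib polytractr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median pbinom phyper ks.test hclust as.dist cor cor.test
#'   quantile runif setNames
#' @importFrom utils read.table write.table packageVersion
"_PACKAGE"

# Canonical species groups. Each repeat unit orbit (all cyclic rotations of
# the unit and of its reverse complement) maps to one field-standard label:
# 2 mononucleotide groups, 4 dinucleotide groups, 10 trinucleotide groups.
# Homopolymer di-/tri-nucleotide words (AA, CCC, ...) are degenerate (their
# smallest period is 1) and are deliberately unmapped.
.SPECIES_GROUPS <- list(
  MNR = list(
    "A/T" = c("A", "T"),
    "C/G" = c("C", "G")
  ),
  DNR = list(
    "TA"    = c("TA", "AT"),
    "CT/GA" = c("CT", "TC", "GA", "AG"),
    "CA/GT" = c("CA", "AC", "GT", "TG"),
    "GC"    = c("GC", "CG")
  ),
  TNR = list(
    "AAC" = c("AAC", "ACA", "CAA", "GTT", "TGT", "TTG"),
    "AAG" = c("AAG", "AGA", "GAA", "CTT", "TCT", "TTC"),
    "AAT" = c("AAT", "ATA", "TAA", "ATT", "TAT", "TTA"),
    "ACC" = c("ACC", "CCA", "CAC", "GGT", "TGG", "GTG"),
    "GAC" = c("GAC", "ACG", "CGA", "GTC", "CGT", "TCG"),
    "ACT" = c("ACT", "CTA", "TAC", "AGT", "TAG", "GTA"),
    "CAG" = c("CAG", "AGC", "GCA", "CTG", "GCT", "TGC"),
    "AGG" = c("AGG", "GGA", "GAG", "CCT", "TCC", "CTC"),
    "ATC" = c("ATC", "TCA", "CAT", "GAT", "TGA", "ATG"),
    "CGG" = c("CGG", "GGC", "GCG", "CCG", "GCC", "CGC")
  )
)

# Flat lookup environment: word -> c(clade, species)
.species_lookup <- local({
  env <- new.env(parent = emptyenv())
  for (clade in names(.SPECIES_GROUPS)) {
    for (label in names(.SPECIES_GROUPS[[clade]])) {
      for (w in .SPECIES_GROUPS[[clade]][[label]]) {
        assign(w, c(clade = clade, species = label), envir = env)
      }
    }
  }
  env
})

#' Species catalog of canonical repeat-unit groups
#'
#' Returns the full mapping from every non-degenerate ACGT word of length
#' 1-3 to its repeat clade (MNR/DNR/TNR) and canonical species label.
#' Labels are invariant under cyclic rotation of the unit and under reverse
#' complementation, so a repeat run receives one species regardless of
#' phase or strand. Degenerate words whose smallest period is shorter than
#' their length (AA, TTT, ...) are excluded: 4 + 12 + 60 words map to
#' 2 + 4 + 10 = 16 labels.
#'
#' @return A data.frame with columns `unit`, `clade`, `species`.
#' @examples
#' cat <- species_catalog()
#' table(cat$clade)
#' @export
species_catalog <- function() {
  rows <- do.call(rbind, lapply(names(.SPECIES_GROUPS), function(clade) {
    grp <- .SPECIES_GROUPS[[clade]]
    do.call(rbind, lapply(names(grp), function(label) {
      data.frame(unit = grp[[label]], clade = clade, species = label,
                 stringsAsFactors = FALSE)
    }))
  }))
  rows[order(nchar(rows$unit), rows$unit), , drop = FALSE]
}

#' Smallest period of a nucleotide word
#'
#' The smallest period of `s` is the least `p >= 1` such that
#' `s[i] == s[i - p]` for every `i > p`. A word with no internal repetition
#' has period equal to its length.
#'
#' @param s A single character string over A/C/G/T (case-insensitive).
#' @return Integer period.
#' @examples
#' smallest_period("AAAAAA")   # 1
#' smallest_period("CACACA")   # 2
#' smallest_period("AACAACAA") # 3
#' @export
smallest_period <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  x <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  if (!all(x %in% c("A", "C", "G", "T")))
    stop("smallest_period(): sequence must contain only A/C/G/T")
  n <- length(x)
  for (p in seq_len(n)) {
    if (p == n || all(x[(p + 1L):n] == x[1:(n - p)])) return(p)
  }
  n
}

#' Canonicalize a repeat unit into its species group
#'
#' Maps a 1-3 nt repeat unit to its clade and canonical species label. The
#' label is shared by all cyclic rotations of the unit and of its reverse
#' complement (e.g. GTT, TGT, TTG, AAC, ACA and CAA are all species "AAC").
#' Degenerate units whose smallest period is shorter than their length
#' ("AA", "CCC") are rejected: the corresponding runs are homopolymers and
#' belong to the MNR clade.
#'
#' @param unit A repeat unit, 1-3 nt, A/C/G/T (case-insensitive).
#' @return A list with elements `clade` and `species`.
#' @examples
#' canonical_species("T")    # MNR, "A/T"
#' canonical_species("GTT")  # TNR, "AAC"
#' canonical_species("TG")   # DNR, "CA/GT"
#' @export
canonical_species <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  u <- toupper(unit)
  if (!grepl("^[ACGT]{1,3}$", u))
    stop("canonical_species(): unit must be 1-3 nt over A/C/G/T, got '",
         unit, "'")
  if (nchar(u) > 1L && length(unique(strsplit(u, "")[[1]])) == 1L)
    stop("canonical_species(): degenerate unit '", unit,
         "'; a run of it is a homopolymer (MNR)")
  hit <- get0(u, envir = .species_lookup, inherits = FALSE)
  # unreachable for valid non-degenerate units; defensive
  if (is.null(hit)) stop("canonical_species(): unmapped unit '", unit, "'")
  list(clade = unname(hit["clade"]), species = unname(hit["species"]))
}

# Vectorized internal lookup used by the scanner; units must be valid.
.species_of <- function(units) {
  vapply(units, function(u) get(u, envir = .species_lookup)[["species"]],
         character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a nucleotide string
#'
#' @param s Character string over A/C/G/T/N (case-insensitive).
#' @return Reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                 collapse = ""))
}
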