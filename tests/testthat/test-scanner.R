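test_that("minimal qualifying runs and length thresholds", {
  r <- scan_sequence("TTTTTT")
  expect_identical(nrow(r), 1L)
  expect_identical(r$clade, "MNR")
  expect_identical(r$species, "A/T")
  expect_identical(c(r$start, r$end), c(0L, 6L))

  # 5-nt homopolymer misses the 6-unit MNR minimum
  expect_identical(nrow(scan_sequence("TTTTT")), 0L)

  # incomplete terminal motif is included in the run
  r <- scan_sequence("GTGTGTG")
  expect_identical(nrow(r), 1L)
  expect_identical(r$clade, "DNR")
  expect_identical(r$species, "CA/GT")
  expect_identical(r$length, 7L)
  expect_identical(r$complete_units, 3L)

  # 8 nt is below the 9-nt TNR minimum; period 3 excludes MNR/DNR
  expect_identical(nrow(scan_sequence("AACAACAA")), 0L)
  r <- scan_sequence("AACAACAAC")
  expect_identical(r$clade, "TNR")
  expect_identical(r$length, 9L)
})

test_that("clade is decided by the smallest period of the run", {
  # a homopolymer is an MNR only, never a DNR or TNR
  r <- scan_sequence("AAAAAAAAA")
  expect_identical(r$clade, "MNR")
  # an alternating dimer is a DNR only
  r <- scan_sequence("ATATATAT")
  expect_identical(r$clade, "DNR")
  expect_identical(r$species, "TA")
})

test_that("clade scans are independent and may overlap across clades", {
  # poly-A run abutting a CA run: MNR and DNR records share the A bases
  r <- scan_sequence("AAAAAACACACA")
  expect_setequal(r$clade, c("MNR", "DNR"))
  mnr <- r[r$clade == "MNR", ]
  dnr <- r[r$clade == "DNR", ]
  expect_identical(c(mnr$start, mnr$end), c(0L, 6L))
  # the DNR run starts inside the poly-A (ACACACA from position 5)
  expect_identical(c(dnr$start, dnr$end), c(5L, 12L))
})

test_that("non-ACGT characters terminate runs; case is ignored", {
  expect_identical(nrow(scan_sequence("AAANAAA")), 0L)
  r <- scan_sequence("AAAAAANAAAAAA")
  expect_identical(nrow(r), 2L)
  expect_identical(r$start, c(0L, 7L))
  expect_same_tracts(scan_sequence("aaaaaagtgtgtg"),
                     scan_sequence("AAAAAAGTGTGTG"))
  expect_identical(nrow(scan_sequence("")), 0L)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:150) {
    s <- random_seq(400)
    expect_same_tracts(scan_sequence(s), scan_bruteforce(s))
  }
  # adversarial: AT-only sequences are saturated with MNR/DNR runs
  set.seed(102)
  for (i in 1:30) {
    s <- paste(sample(c("A", "T"), 200, replace = TRUE), collapse = "")
    expect_same_tracts(scan_sequence(s), scan_bruteforce(s))
  }
  # three-letter alphabet favors TNR runs
  set.seed(103)
  for (i in 1:30) {
    s <- paste(sample(c("A", "A", "C"), 200, replace = TRUE), collapse = "")
    expect_same_tracts(scan_sequence(s), scan_bruteforce(s))
  }
})

test_that("reverse complement symmetry: mirrored coordinates, same species", {
  set.seed(104)
  for (i in 1:25) {
    s <- random_seq(500)
    fwd <- scan_sequence(s)
    rev <- scan_sequence(revcomp(s))
    n <- nchar(s)
    mirrored <- data.frame(chrom = rev$chrom, start = n - rev$end,
                           end = n - rev$start, clade = rev$clade,
                           species = rev$species, unit_len = rev$unit_len,
                           length = rev$length,
                           complete_units = rev$complete_units,
                           stringsAsFactors = FALSE)
    expect_same_tracts(fwd, mirrored)
  }
})

test_that("records of the same clade are disjoint", {
  set.seed(105)
  for (i in 1:20) {
    r <- scan_sequence(random_seq(800))
    for (cl in unique(r$clade)) {
      sub <- r[r$clade == cl, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
})

test_that("scan_genome handles multi-sequence input and name selection", {
  g <- Biostrings::DNAStringSet(c(chrA = "AAAAAACC", chrB = "GTGTGTGT"))
  r <- scan_genome(g)
  expect_identical(attr(r, "seq_lengths"), c(chrA = 8L, chrB = 8L))
  expect_setequal(r$chrom, c("chrA", "chrB"))
  rB <- scan_genome(g, seqnames = "chrB")
  expect_identical(unique(rB$chrom), "chrB")
  expect_warning(scan_genome(g, seqnames = c("chrB", "chrZ")), "chrZ")
})

test_that("long-TNR filter keeps the 18 nt boundary inclusive", {
  r <- scan_sequence(paste0("AACAACAACAACAACAAC", "G", "AACAACAACAACAACAA"))
  expect_identical(sort(r$length), c(17L, 18L))
  keep <- filter_long_tnr(r)
  expect_identical(nrow(keep), 1L)
  expect_identical(keep$length, 18L)
  expect_identical(nrow(filter_long_tnr(r, min_len = 19)), 0L)
})
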