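# Two-gene toy annotation: a protein-coding gene with UTRs, CDS and two
# introns on the + strand, and a lincRNA on the - strand.
toy_gtf_lines <- function() {
  att <- function(g, t = NULL, bt) {
    s <- sprintf('gene_id "%s"; gene_biotype "%s";', g, bt)
    if (!is.null(t)) s <- sprintf('%s transcript_id "%s";', s, t)
    s
  }
  l <- function(feature, start, end, strand, attrs)
    paste("c1", "toy", feature, start, end, ".", strand, ".", attrs,
          sep = "\t")
  c(
    l("gene", 2001, 4000, "+", att("g1", bt = "protein_coding")),
    l("transcript", 2001, 4000, "+", att("g1", "t1", "protein_coding")),
    l("exon", 2001, 2200, "+", att("g1", "t1", "protein_coding")),
    l("exon", 2801, 3000, "+", att("g1", "t1", "protein_coding")),
    l("exon", 3601, 4000, "+", att("g1", "t1", "protein_coding")),
    l("five_prime_utr", 2001, 2100, "+", att("g1", "t1", "protein_coding")),
    l("CDS", 2101, 2200, "+", att("g1", "t1", "protein_coding")),
    l("CDS", 2801, 3000, "+", att("g1", "t1", "protein_coding")),
    l("CDS", 3601, 3700, "+", att("g1", "t1", "protein_coding")),
    l("three_prime_utr", 3701, 4000, "+", att("g1", "t1", "protein_coding")),
    l("gene", 6001, 6500, "-", att("g2", bt = "lincRNA")),
    l("transcript", 6001, 6500, "-", att("g2", "t2", "lincRNA")),
    l("exon", 6001, 6100, "-", att("g2", "t2", "lincRNA")),
    l("exon", 6301, 6500, "-", att("g2", "t2", "lincRNA"))
  )
}

write_toy_gtf <- function(lines = toy_gtf_lines()) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

test_that("gene models load with correct structure and deduplication", {
  models <- load_gene_models(write_toy_gtf())
  expect_identical(models$n_genes, 2L)
  expect_identical(length(models$exons), 5L)
  expect_identical(length(models$cds), 3L)
  expect_identical(length(models$utr5), 1L)
  expect_identical(length(models$nc_exons), 2L)
  # g1 has two introns, g2 one
  expect_identical(length(models$introns), 3L)

  # duplicated exon lines collapse to unique intervals
  dup <- c(toy_gtf_lines(), toy_gtf_lines()[3])
  models2 <- load_gene_models(write_toy_gtf(dup))
  expect_identical(length(models2$exons), 5L)

  # gene-only GTF: empty exon sets, flagged
  expect_warning(m3 <- load_gene_models(write_toy_gtf(toy_gtf_lines()[1])),
                 "no exon")
  expect_identical(length(m3$exons), 0L)
})

test_that("region assignment follows the seven-category precedence", {
  models <- load_gene_models(write_toy_gtf())
  q <- function(start, end) data.frame(chrom = "c1", start = start,
                                       end = end)
  expect_identical(assign_region(q(2150, 2160), models), "exonic_splicing")
  expect_identical(assign_region(q(2020, 2030), models), "UTR5")
  expect_identical(assign_region(q(3800, 3810), models), "UTR3")
  expect_identical(assign_region(q(6020, 6030), models), "ncRNA")
  expect_identical(assign_region(q(2400, 2410), models), "intronic")
  # 500 nt upstream of the TSS, outside the gene body
  expect_identical(assign_region(q(1500, 1510), models), "up_down_stream")
  expect_identical(assign_region(q(100, 110), models), "intergenic")
  # splice junction: within 2 nt of the exon1/intron1 boundary
  expect_identical(assign_region(q(2198, 2199), models), "exonic_splicing")
  expect_identical(assign_region(q(2201, 2202), models), "exonic_splicing")
  # a batch call returns one category per interval
  batch <- rbind(q(2150, 2160), q(100, 110))
  expect_identical(assign_region(batch, models),
                   c("exonic_splicing", "intergenic"))
})

test_that("updown flank width is tunable and 0 kb collapses to intergenic", {
  models <- load_gene_models(write_toy_gtf())
  q <- data.frame(chrom = "c1", start = 1500, end = 1510)
  expect_identical(assign_region(q, models, updown_kb = 1),
                   "up_down_stream")
  expect_identical(assign_region(q, models, updown_kb = 0), "intergenic")
  # 0.4 kb flank no longer reaches a point 500 nt upstream
  expect_identical(assign_region(q, models, updown_kb = 0.4), "intergenic")
})

test_that("assignment is independent of gene-model input order", {
  lines <- toy_gtf_lines()
  set.seed(61)
  shuffled <- sample(lines)
  m1 <- load_gene_models(write_toy_gtf())
  m2 <- load_gene_models(write_toy_gtf(shuffled))
  q <- data.frame(chrom = "c1",
                  start = c(2150, 2020, 3800, 6020, 2400, 1500, 100),
                  end = c(2160, 2030, 3810, 6030, 2410, 1510, 110))
  expect_identical(assign_region(q, m1), assign_region(q, m2))
})

test_that("region distribution fractions sum to one per species", {
  models <- load_gene_models(write_toy_gtf())
  # plant all tracts inside g1 introns
  tr <- data.frame(chrom = "c1", start = c(2300L, 2500L, 3100L),
                   end = c(2310L, 2510L, 3110L), clade = "MNR",
                   species = "A/T", unit_len = 1L, length = 10L,
                   complete_units = 10L, stringsAsFactors = FALSE)
  d <- region_distribution(tr, models)
  expect_equal(d$fraction[d$species == "A/T" & d$category == "intronic"], 1)
  expect_equal(sum(d$fraction[d$species == "A/T"]), 1, tolerance = 1e-12)

  # mixed fixture against hand-counted categories
  tr2 <- tr
  tr2$start <- c(2150L, 6020L, 100L); tr2$end <- tr2$start + 10L
  tr2$species <- c("A/T", "A/T", "CA/GT")
  tr2$clade <- c("MNR", "MNR", "DNR")
  d2 <- region_distribution(tr2, models)
  at <- d2[d2$species == "A/T", ]
  expect_equal(at$fraction[at$category == "exonic_splicing"], 0.5)
  expect_equal(at$fraction[at$category == "ncRNA"], 0.5)
  expect_equal(d2$fraction[d2$species == "CA/GT" &
                             d2$category == "intergenic"], 1)
  for (sp in unique(d2$species))
    expect_equal(sum(d2$fraction[d2$species == sp]), 1, tolerance = 1e-12)
})
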