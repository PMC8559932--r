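test_that("GTF loading builds gene models and converts coordinates", {
  gtf <- write_toy_gtf(list(list(
    gene_id = "gA", chrom = "chr1", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300))))))
  models <- load_annotation(gtf)
  expect_length(models, 1L)
  tx <- models$gA$transcripts$t1
  expect_equal(unname(tx[, "start"]), c(0L, 200L))
  expect_equal(unname(tx[, "end"]), c(100L, 300L))
  intr <- lariatuss:::tx_introns(tx)
  expect_equal(unname(intr[1, ]), c(100L, 200L))  # one 100-nt intron
})

test_that("malformed and invalid GTF records fail naming the line", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "chr1\tt\texon\t5\t2"), f)
  expect_error(load_annotation(f), "line 2")
  writeLines(c(
    "chr1\tt\texon\t200\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"), f)
  expect_error(load_annotation(f), "end.*<.*start|line 1")
  writeLines(c(
    "chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id \"g\";"), f)
  expect_error(load_annotation(f), "transcript_id")
})

test_that("exons outside chromosome bounds are rejected when a genome is given", {
  gtf <- write_toy_gtf(list(list(
    gene_id = "gA", chrom = "chr1", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 500))))))
  genome <- c(chr1 = paste(rep("A", 400), collapse = ""))
  expect_error(load_annotation(gtf, genome), "bounds")
  expect_error(
    load_annotation(write_toy_gtf(list(list(
      gene_id = "gA", chrom = "chrX", strand = "+",
      transcripts = list(t1 = list(c(1, 10)))))), genome),
    "unknown chromosome")
})

test_that("splice sites are enumerated per distinct intron and deduplicated", {
  ## 3-exon transcript: 2 donors + 2 acceptors
  gtf <- write_toy_gtf(list(list(
    gene_id = "gA", chrom = "chr1", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300), c(401, 500)),
                       ## second isoform shares intron 1, adds nothing new
                       t2 = list(c(1, 100), c(201, 300))))))
  models <- load_annotation(gtf)
  sites <- enumerate_splice_sites(models)
  expect_equal(sum(sites$kind == "donor"), 2L)
  expect_equal(sum(sites$kind == "acceptor"), 2L)
  ## brute-force distinct (boundary, kind) count across transcripts
  all_introns <- unique(do.call(rbind, lapply(models$gA$transcripts,
                                              lariatuss:::tx_introns)))
  expect_equal(nrow(sites), 2L * nrow(all_introns))
  ## donor boundary = first intronic base (0-based) on the plus strand
  expect_true(all(sites$boundary[sites$kind == "donor"] %in% c(100L, 300L)))
  ## acceptor boundary = last intronic base (0-based), one left of exon start
  expect_true(all(sites$boundary[sites$kind == "acceptor"] %in% c(199L, 399L)))
})

test_that("single-exon transcripts yield no splice sites", {
  gtf <- write_toy_gtf(list(list(
    gene_id = "gA", chrom = "chr1", strand = "+",
    transcripts = list(t1 = list(c(1, 500))))))
  expect_equal(nrow(enumerate_splice_sites(load_annotation(gtf))), 0L)
})

test_that("gene models round-trip through GTF with identical site sets", {
  toy <- make_toy_genome(6, seed = 21)
  f <- tempfile(fileext = ".gtf")
  write_gtf(toy$models, f)
  reloaded <- load_annotation(f, toy$genome)
  s1 <- enumerate_splice_sites(toy$models, toy$genome)
  s2 <- enumerate_splice_sites(reloaded, toy$genome)
  expect_equal(s1, s2)
  expect_true(all(s1$canonical))  # generator plants GT/AG consensus
})

test_that("strand symmetry: mirrored minus-strand gene gives the same sites", {
  ## same gene on + and on - with mirrored coordinates over a 600-nt chrom
  glen <- 600
  plus <- list(gene_id = "gP", chrom = "chrP", strand = "+",
               transcripts = list(t1 = list(c(51, 150), c(251, 350))))
  mirror <- function(iv) c(glen - iv[2] + 1, glen - iv[1] + 1)
  minus <- list(gene_id = "gM", chrom = "chrM", strand = "-",
                transcripts = list(t1 = rev(lapply(plus$transcripts$t1, mirror))))
  set.seed(5)
  fwd <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = "")
  genome <- c(chrP = fwd, chrM = oracle_rc(fwd))
  models <- load_annotation(write_toy_gtf(list(plus, minus)), genome)
  sites <- enumerate_splice_sites(models, genome)
  sp <- sites[sites$chrom == "chrP", ]
  sm <- sites[sites$chrom == "chrM", ]
  ## identical site set after strand mapping: boundaries mirror, kinds match
  expect_setequal(glen - 1 - sm$boundary, sp$boundary)
  for (i in seq_len(nrow(sp))) {
    j <- which(sm$boundary == glen - 1 - sp$boundary[i])
    expect_equal(sm$kind[j], sp$kind[i])
    expect_equal(sm$dinucleotide[j], sp$dinucleotide[i])
  }
})

test_that("fetch_window returns sense windows with the documented layout", {
  toy <- make_toy_genome(8, seed = 31)
  sites <- enumerate_splice_sites(toy$models, toy$genome)
  don <- sites[sites$kind == "donor", ]
  acc <- sites[sites$kind == "acceptor", ]
  for (i in seq_len(nrow(don))) {
    w <- fetch_window(toy$genome, don[i, ], exonic_len = 3, intronic_len = 6)
    expect_equal(nchar(w), 9L)
    ## 4th-5th characters are the first two intron bases (planted GT)
    expect_equal(substr(w, 4, 5), "GT")
  }
  for (i in seq_len(nrow(acc))) {
    w <- fetch_window(toy$genome, acc[i, ], exonic_len = 3, intronic_len = 20)
    expect_equal(nchar(w), 23L)
    ## last two intronic bases (positions 19-20) are the planted AG
    expect_equal(substr(w, 19, 20), "AG")
  }
})

test_that("windows exceeding chromosome bounds raise a boundary error", {
  genome <- c(chr1 = "GTAAGTACGTACGT")
  site <- list(chrom = "chr1", strand = "+", boundary = 0L, kind = "donor")
  expect_error(fetch_window(genome, site, exonic_len = 3, intronic_len = 6),
               "bounds")
})

test_that("duplicate transcripts collapse with a warning", {
  gtf <- write_toy_gtf(list(list(
    gene_id = "gA", chrom = "chr1", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300)),
                       t2 = list(c(1, 100), c(201, 300))))))
  expect_warning(models <- load_annotation(gtf), "duplicate")
  expect_length(models$gA$transcripts, 1L)
})

test_that("BED6 export carries boundary, name and strand", {
  toy <- make_toy_genome(2, seed = 3)
  sites <- enumerate_splice_sites(toy$models)
  f <- tempfile(fileext = ".bed")
  sites_to_bed(sites, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(nrow(bed), nrow(sites))
  expect_equal(bed$V2, sites$boundary)
  expect_equal(bed$V3, sites$boundary + 1L)
  expect_true(all(bed$V6 %in% c("+", "-")))
})
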