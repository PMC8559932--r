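test_that("generators are deterministic under a fixed seed", {
  t1 <- make_toy_genome(5, seed = 99)
  t2 <- make_toy_genome(5, seed = 99)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(t1$genome, f1); write_fasta(t2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(); g2 <- tempfile()
  write_gtf(t1$models, g1); write_gtf(t2$models, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_identical(t1$truth, t2$truth)

  c1 <- simulate_counts(t1$truth, seed = 7)
  c2 <- simulate_counts(t2$truth, seed = 7)
  expect_identical(c1, c2)

  iseq <- paste0("GT", paste(rep("ACGT", 20), collapse = ""), "AG")
  r1 <- simulate_lariat_reads(iseq, c(`-20` = 1), n_clones = 30, seed = 5)
  r2 <- simulate_lariat_reads(iseq, c(`-20` = 1), n_clones = 30, seed = 5)
  expect_identical(r1, r2)
})

test_that("event mix is honoured and RI intron lengths are recorded in truth", {
  toy <- make_toy_genome(10, event_mix = c(RI = 1), seed = 4,
                         ri_intron_len = c(50L, 80L))
  expect_equal(nrow(toy$truth$events), 10L)
  expect_true(all(toy$truth$events$type == "RI"))
  expect_true(all(toy$truth$events$distance >= 50 & toy$truth$events$distance <= 80))
  ## each RI gene: retained-intron isoform pair
  expect_true(all(vapply(toy$models, function(g) length(g$transcripts), 0L) == 2L))
  expect_error(make_toy_genome(5, event_mix = c(RI = 0.5, SE = 0.4)), "sum to 1")
})

test_that("A3SS alternative-acceptor distance matches the emitted annotation", {
  toy <- make_toy_genome(8, event_mix = c(A3SS = 1), seed = 12)
  f <- tempfile(fileext = ".gtf")
  write_gtf(toy$models, f)
  reloaded <- load_annotation(f)
  for (gid in names(reloaded)) {
    ## brute force: the two isoforms' introns share a donor-side end and
    ## differ at the acceptor side by the recorded distance
    intr <- lapply(reloaded[[gid]]$transcripts, lariatuss:::tx_introns)
    i1 <- intr[[1]][1, ]; i2 <- intr[[2]][1, ]
    strand <- reloaded[[gid]]$strand
    d <- if (strand == "+") abs(i1["end"] - i2["end"]) else abs(i1["start"] - i2["start"])
    truth_d <- toy$truth$events$distance[toy$truth$events$gene_id == gid]
    expect_equal(unname(d), truth_d)
  }
})

test_that("simulated counts hit binomial boundaries and recover deep-data PSI", {
  toy <- make_toy_genome(6, seed = 8)
  toy$truth$events$psi_a <- 1
  toy$truth$events$psi_b <- 1
  cnt <- simulate_counts(toy$truth, n_replicates = 2, depth = 50, seed = 2)
  ev <- toy$truth$events
  skip_keys <- unlist(strsplit(ev$skipping_junctions, ";"))
  expect_true(all(cnt$junctions$count[cnt$junctions$junction %in% skip_keys] == 0))

  ## USS = 1 -> intronic window counts all zero
  toy$truth$sites$uss_a <- 1
  cnt2 <- simulate_counts(toy$truth, n_replicates = 1, depth = 10, seed = 2)
  expect_true(all(cnt2$windows$intronic_count[cnt2$windows$condition == "control"] == 0))

  ## PSI = 0.75 at depth 10000: empirical within +/- 0.02
  toy$truth$events$psi_a <- 0.75
  cnt3 <- simulate_counts(toy$truth, n_replicates = 1, depth = 10000, seed = 9)
  events <- extract_events(toy$models)
  q <- compute_psi(events, cnt3$junctions[cnt3$junctions$condition == "control", ],
                   warn_unmatched = FALSE)
  expect_true(all(abs(q$psi - 0.75) < 0.02))
})

test_that("lariat reads carry the designed junction, signature and orientation mix", {
  set.seed(1)
  iseq <- paste0("GT", paste(sample(c("A","C","G","T"), 60, TRUE), collapse = ""), "AG")
  ## single BP, no errors, no A->T, forward only -> identical junctions
  rs <- simulate_lariat_reads(iseq, c(`-20` = 1), n_clones = 12, a2t_rate = 0,
                              error_rate = 0, revcomp_frac = 0, seed = 3)
  L <- nchar(iseq); p <- L + 1 - 20
  juncs <- vapply(seq_len(12), function(i) {
    k <- rs$truth$bp_offset[i]  # all -20
    s <- rs$reads$seq[i]
    ## the 8 bases each side of the jump are fixed by construction
    pre <- substr(iseq, p - 7, p)
    regexpr(paste0(pre, substr(iseq, 1, 8)), s, fixed = TRUE) > 0
  }, logical(1))
  expect_true(all(juncs))

  ## a2t_rate = 1 with an A branch base: every read carries T pre-jump
  stopifnot(substr(iseq, p, p) != "")
  iseq_a <- `substr<-`(iseq, p, p, "A")
  rs2 <- simulate_lariat_reads(iseq_a, c(`-20` = 1), n_clones = 12, a2t_rate = 1,
                               error_rate = 0, revcomp_frac = 0, seed = 3)
  expect_true(all(rs2$truth$a2t))
  ## last pre-jump base is T in every read: it sits right before intron[1..]
  expect_true(all(vapply(rs2$reads$seq, function(s) {
    grepl(paste0("T", substr(iseq_a, 1, 8)), s, fixed = TRUE)
  }, logical(1))))

  ## multinomial BP sampling converges
  rs3 <- simulate_lariat_reads(iseq, c(`-25` = 0.6, `-54` = 0.4),
                               n_clones = 10000, seed = 6)
  fr <- table(rs3$truth$bp_offset) / 10000
  expect_lt(abs(fr[["-25"]] - 0.6), 0.02)
  expect_lt(abs(fr[["-54"]] - 0.4), 0.02)
  ## orientation mix near the 50% default
  expect_lt(abs(mean(rs3$truth$revcomped) - 0.5), 0.02)

  expect_error(simulate_lariat_reads(iseq, c(`-25` = 0.5, `-54` = 0.4)), "sum to 1")
  expect_error(simulate_lariat_reads(iseq, c(`-2` = 1)), "close to intron ends")
})

test_that("generated annotation validates against the loaders and truth maps 1:1", {
  toy <- make_toy_genome(15, seed = 44)
  f <- tempfile(fileext = ".gtf"); write_gtf(toy$models, f)
  fa <- tempfile(fileext = ".fa"); write_fasta(toy$genome, fa)
  models <- load_annotation(f, Biostrings::readDNAStringSet(fa))
  ev <- extract_events(models)
  expect_setequal(ev$event_id, toy$truth$events$event_id)
  expect_false(anyDuplicated(toy$truth$events$event_id) > 0)
  expect_true(all(toy$truth$events$psi_a >= 0 & toy$truth$events$psi_a <= 1))
  expect_true(all(toy$truth$sites$uss_a >= 0 & toy$truth$sites$uss_a <= 1))
  sites <- enumerate_splice_sites(models)
  expect_setequal(toy$truth$sites$site_id, sites$site_id)
})
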