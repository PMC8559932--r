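## build a one-sample counts table from a named junction=count vector
make_counts <- function(v) {
  data.frame(junction = names(v), count = as.numeric(v),
             stringsAsFactors = FALSE)
}

test_that("canonical isoform pairs yield the expected event patterns", {
  ## SE: E1-E2-E3 vs E1-E3
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300), c(401, 500)),
                       t2 = list(c(1, 100), c(401, 500))))))
  ev <- extract_events(load_annotation(gtf))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "SE")
  expect_equal(c(ev$pos1, ev$pos2), c(200L, 300L))  # cassette exon
  expect_equal(length(strsplit(ev$inclusion_junctions, ";")[[1]]), 2L)

  ## RI: spliced pair vs retained single exon
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300)),
                       t2 = list(c(1, 300))))))
  ev <- extract_events(load_annotation(gtf))
  expect_equal(ev$type, "RI")
  expect_equal(ev$distance, 100L)
  expect_match(ev$inclusion_junctions, "\\^")  # retention-evidence key

  ## A5SS on +: two donors, one acceptor; inclusion = long exon
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "+",
    transcripts = list(t1 = list(c(1, 120), c(201, 300)),
                       t2 = list(c(1, 100), c(201, 300))))))
  ev <- extract_events(load_annotation(gtf))
  expect_equal(ev$type, "A5SS")
  expect_equal(ev$distance, 20L)
  expect_equal(ev$pos1, 120L)  # inclusion donor boundary (long exon)
  expect_equal(ev$pos2, 100L)

  ## same structure on minus strand is an A3SS
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "-",
    transcripts = list(t1 = list(c(1, 120), c(201, 300)),
                       t2 = list(c(1, 100), c(201, 300))))))
  ev <- extract_events(load_annotation(gtf))
  expect_equal(ev$type, "A3SS")
  expect_equal(ev$distance, 20L)

  ## MXE: disjoint middle exons sharing flanks
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 260), c(501, 600)),
                       t2 = list(c(1, 100), c(301, 360), c(501, 600))))))
  ev <- extract_events(load_annotation(gtf))
  expect_equal(ev$type, "MXE")
  expect_equal(c(ev$pos1, ev$pos2), c(200L, 260L))  # upstream exclusive exon
  ## one-isoform genes yield nothing
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300))))))
  expect_equal(nrow(extract_events(load_annotation(gtf))), 0L)
})

test_that("extracted events equal generator truth across all types and strands", {
  toy <- make_toy_genome(30, seed = 77)
  ev <- extract_events(toy$models)
  expect_setequal(ev$event_id, toy$truth$events$event_id)
  tr <- toy$truth$events[match(ev$event_id, toy$truth$events$event_id), ]
  expect_equal(ev$inclusion_junctions, tr$inclusion_junctions)
  expect_equal(ev$skipping_junctions, tr$skipping_junctions)
  expect_equal(ev$distance, tr$distance)
})

test_that("PSI arithmetic follows I/(I+S) with undefined flagged", {
  gtf <- write_toy_gtf(list(list(
    gene_id = "g", chrom = "c", strand = "+",
    transcripts = list(t1 = list(c(1, 100), c(201, 300), c(401, 500)),
                       t2 = list(c(1, 100), c(401, 500))))))
  ev <- extract_events(load_annotation(gtf))
  incl <- strsplit(ev$inclusion_junctions, ";")[[1]]
  skip <- strsplit(ev$skipping_junctions, ";")[[1]]
  q <- compute_psi(ev, make_counts(structure(c(10, 0, 0), names = c(incl, skip))),
                   warn_unmatched = FALSE)
  expect_equal(q$psi, 1)
  q <- compute_psi(ev, make_counts(structure(c(0, 0, 7), names = c(incl, skip))),
                   warn_unmatched = FALSE)
  expect_equal(q$psi, 0)
  q <- compute_psi(ev, make_counts(structure(c(20, 10, 10), names = c(incl, skip))),
                   warn_unmatched = FALSE)
  expect_equal(q$psi, 0.75)
  ## zero counts -> undefined, flagged
  q <- compute_psi(ev, make_counts(structure(c(0, 0, 0), names = c(incl, skip))),
                   warn_unmatched = FALSE)
  expect_true(is.na(q$psi) && !q$defined)
  ## unknown junction keys are ignored with a warning
  expect_warning(compute_psi(ev, make_counts(c(`cX:1-2:+` = 5))), "no event")
})

test_that("differential PSI screen applies test, FDR and filters", {
  toy <- make_toy_genome(4, seed = 10)
  ev <- extract_events(toy$models)
  two_cond <- function(Ia, Sa, Ib, Sb) {
    ## one replicate per condition, counts placed on the first event only;
    ## remaining events get balanced counts
    incl <- strsplit(ev$inclusion_junctions, ";")
    skip <- strsplit(ev$skipping_junctions, ";")
    rows <- list()
    for (cond in c("A", "B")) {
      I <- if (cond == "A") Ia else Ib
      S <- if (cond == "A") Sa else Sb
      for (i in seq_len(nrow(ev))) {
        I_i <- if (i == 1) I else 50
        S_i <- if (i == 1) S else 50
        ki <- incl[[i]]; ks <- skip[[i]]
        rows[[length(rows) + 1]] <- data.frame(
          junction = c(ki, ks), sample = paste0(cond, "_r1"), condition = cond,
          count = c(rep(floor(I_i / length(ki)), length(ki)),
                    rep(floor(S_i / length(ks)), length(ks))))
      }
    }
    do.call(rbind, rows)
  }
  ## identical counts -> delta 0, not significant
  res <- differential_psi(ev, two_cond(500, 500, 500, 500), "A", "B")
  expect_equal(res$delta_psi[1], 0)
  expect_false(res$significant[1])
  ## (500,500) vs (700,300): delta +0.2, p < 1e-6, significant, and the
  ## p-value equals the enumeration oracle
  res <- differential_psi(ev, two_cond(500, 500, 700, 300), "A", "B")
  expect_equal(res$delta_psi[1], 0.2, tolerance = 1e-9)
  expect_lt(res$p_value[1], 1e-6)
  expect_true(res$significant[1])
  expect_equal(res$p_value[1], fisher_enum_p(500, 500, 700, 300), tolerance = 1e-9)
  ## supporting-reads filter boundary: (6,4) vs (4,6) tested, (3,2) vs (2,3)
  ## fails the reads >= 5 filter
  res <- differential_psi(ev, two_cond(6, 4, 4, 6), "A", "B")
  expect_true(res$testable[1] && res$supporting_reads[1] >= 5)
  res <- differential_psi(ev, two_cond(2, 2, 2, 2), "A", "B")
  expect_lt(res$supporting_reads[1], 5)
  expect_false(res$significant[1])
  ## record invariants
  res <- differential_psi(ev, two_cond(40, 10, 20, 30), "A", "B")
  ok <- res$testable
  expect_true(all(res$fdr[ok] >= res$p_value[ok]))
  expect_true(all(res$psi_a[ok] >= 0 & res$psi_a[ok] <= 1))
  expect_true(all(abs(res$delta_psi[ok]) <= 1))
})

test_that("events with zero counts in one condition are untestable", {
  toy <- make_toy_genome(3, seed = 13)
  ev <- extract_events(toy$models)
  cnt <- simulate_counts(toy$truth, n_replicates = 1, depth = 100, seed = 1)
  ## drop all mutant counts for the first event's junctions
  keys <- unlist(strsplit(c(ev$inclusion_junctions[1], ev$skipping_junctions[1]), ";"))
  cnt$junctions$count[cnt$junctions$condition == "mutant" &
                      cnt$junctions$junction %in% keys] <- 0
  res <- differential_psi(ev, cnt$junctions, "control", "mutant")
  expect_false(res$testable[res$event_id == ev$event_id[1]])
  expect_true(is.na(res$p_value[res$event_id == ev$event_id[1]]))
})

test_that("distance distribution reports RI intron length and modal bins", {
  toy <- make_toy_genome(40, event_mix = c(RI = 0.5, A3SS = 0.25, A5SS = 0.25),
                         seed = 19, ri_intron_len = c(50L, 80L), delta_psi = 0.3,
                         psi = c(0.2, 0.4))
  ev <- extract_events(toy$models)
  cnt <- simulate_counts(toy$truth, n_replicates = 2, depth = 2000, seed = 20)
  res <- differential_psi(ev, cnt$junctions, "control", "mutant")
  dd <- distance_distribution(res, ev, direction = "up")
  ## RI distance equals generator intron length exactly, for every event
  tr <- toy$truth$events
  ri <- dd$distances[dd$distances$type == "RI", ]
  expect_gt(nrow(ri), 0)
  expect_equal(ri$distance,
               tr$distance[match(ri$event_id, tr$event_id)])
  ## modal bin of the RI histogram is [50,80)
  h <- dd$histogram[dd$histogram$type == "RI", ]
  expect_equal(h$bin[which.max(h$count)], "[50,80)")
  ## A3SS distances are the alternative-acceptor separations
  a3 <- dd$distances[dd$distances$type == "A3SS", ]
  expect_equal(a3$distance, tr$distance[match(a3$event_id, tr$event_id)])
})
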