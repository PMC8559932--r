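## Synthetic-data generators: toy genomes carrying one designed alternative
## splicing event per gene, junction/window count tables with known PSI/USS
## truth, and lariat-derived read sets with known branch points.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate a toy genome, annotation and ground truth
#'
#' Builds one chromosome per gene, each carrying exactly one designed
#' alternative-splicing event of a known type (SE, RI, A5SS, A3SS or MXE)
#' encoded by an isoform pair. Intron-terminal dinucleotides are set to the
#' GT/AG consensus; gene strand is drawn at random so minus-strand handling
#' is always exercised. The returned truth table records each event's
#' defining coordinates, inclusion/skipping junction keys, inter-site
#' distance and per-condition PSI, plus per-splice-site USS truth.
#'
#' @param n_genes Number of genes (= chromosomes).
#' @param event_mix Named proportions over `c("SE","RI","A5SS","A3SS","MXE")`;
#'   must sum to 1.
#' @param seed Integer seed; fixed seed gives byte-identical FASTA/GTF.
#' @param exon_len,intron_len Ranges (nt) for exon and intron lengths.
#' @param ri_intron_len Range for retained introns of RI events (defaults to
#'   `intron_len`); set to `c(50, 80)` to plant the short-intron band that
#'   the distance analysis targets.
#' @param alt_shift Range (nt) of the distance between alternative donors
#'   (A5SS) or acceptors (A3SS).
#' @param flank Flanking sequence (nt) on each side of a gene.
#' @param psi Range of true control-condition PSI.
#' @param delta_psi True PSI difference (second condition minus first),
#'   applied to every event and clamped to [0, 1]. Edit `truth$events`
#'   afterwards for event-specific designs.
#' @param uss Range of true control-condition USS.
#' @param delta_uss True USS difference, applied to every site; edit
#'   `truth$sites` for site-specific designs.
#' @param conditions Two condition labels.
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   (`gene_models`), and `truth` (list of data.frames `events`, `sites`,
#'   plus `params`).
#' @export
make_toy_genome <- function(n_genes,
                            event_mix = c(SE = 0.2, RI = 0.2, A5SS = 0.2,
                                          A3SS = 0.2, MXE = 0.2),
                            seed = 1L,
                            exon_len = c(80L, 200L),
                            intron_len = c(80L, 300L),
                            ri_intron_len = intron_len,
                            alt_shift = c(6L, 40L),
                            flank = 150L,
                            psi = c(0.35, 0.65),
                            delta_psi = 0,
                            uss = c(0.6, 0.95),
                            delta_uss = 0,
                            conditions = c("control", "mutant")) {
  stopifnot(n_genes >= 1L, length(conditions) == 2L)
  if (is.null(names(event_mix)) ||
      !all(names(event_mix) %in% c("SE", "RI", "A5SS", "A3SS", "MXE"))) {
    stop("event_mix must be named with types among SE, RI, A5SS, A3SS, MXE")
  }
  if (abs(sum(event_mix) - 1) > 1e-9) stop("event_mix proportions must sum to 1")
  set.seed(seed)

  ## fixed per-type counts honouring the mix as closely as possible
  n_per <- floor(event_mix * n_genes)
  rem <- n_genes - sum(n_per)
  if (rem > 0) {
    top <- order(event_mix * n_genes - n_per, decreasing = TRUE)
    n_per[top[seq_len(rem)]] <- n_per[top[seq_len(rem)]] + 1L
  }
  types <- sample(rep(names(n_per), n_per))

  gw <- max(3L, nchar(as.character(n_genes)))
  seqs <- character(n_genes)
  chroms <- sprintf("chr%0*d", gw, seq_len(n_genes))
  gids <- sprintf("g%0*d", gw, seq_len(n_genes))
  models <- vector("list", n_genes)
  ev_rows <- vector("list", n_genes)

  rlen <- function(rng) if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

  for (i in seq_len(n_genes)) {
    type <- types[i]
    strand <- sample(c("+", "-"), 1L)
    g <- build_toy_gene(type, flank, exon_len,
                        if (type == "RI") ri_intron_len else intron_len,
                        alt_shift, rlen)
    L <- g$length
    seqc <- random_dna(L)
    for (d in g$dinucs) seqc <- `substr<-`(seqc, d$at + 1L, d$at + 2L, value = d$nt)
    if (strand == "-") {
      seqc <- rc_string(seqc)
      g$isoforms <- lapply(g$isoforms, function(m) {
        cbind(L - m[, 2], L - m[, 1])
      })
      g$introns <- lapply(g$introns, function(iv) c(L - iv[2], L - iv[1]))
      if (!is.null(g$exons)) g$exons <- lapply(g$exons, function(iv) c(L - iv[2], L - iv[1]))
    }
    g$isoforms <- lapply(g$isoforms, function(m) {
      m <- m[order(m[, 1]), , drop = FALSE]
      colnames(m) <- c("start", "end")
      m
    })
    seqs[i] <- seqc
    tids <- paste0(gids[i], ".iso", seq_along(g$isoforms))
    models[[i]] <- list(gene_id = gids[i], chrom = chroms[i], strand = strand,
                        transcripts = stats::setNames(g$isoforms, tids))
    ev_rows[[i]] <- toy_event_record(type, g, chroms[i], strand, gids[i])
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  models <- structure(stats::setNames(models, gids), class = "gene_models")

  events <- do.call(rbind, ev_rows)
  events$psi_a <- round(runif(nrow(events), psi[1], psi[2]), 4)
  events$psi_b <- clamp01(events$psi_a + delta_psi)

  sites <- enumerate_splice_sites(models, genome)
  sites$uss_a <- round(runif(nrow(sites), uss[1], uss[2]), 4)
  sites$uss_b <- clamp01(sites$uss_a + delta_uss)

  truth <- list(events = events,
                sites = sites[, c("site_id", "kind", "gene_id", "uss_a", "uss_b")],
                params = list(seed = seed, conditions = conditions,
                              event_mix = as.list(event_mix),
                              delta_psi = delta_psi, delta_uss = delta_uss))
  list(genome = genome, models = models, truth = truth)
}

## Lay out one gene in sense (plus-strand) coordinates.
## Returns isoform exon matrices, named intron intervals, defining exon
## intervals, dinucleotide plants, and total length.
build_toy_gene <- function(type, flank, exon_len, intron_len, alt_shift, rlen) {
  ex <- function() rlen(exon_len)
  il <- function() rlen(intron_len)
  dn <- list()
  plant <- function(at, nt) dn[[length(dn) + 1L]] <<- list(at = at, nt = nt)

  if (type == "SE") {
    a <- c(flank, flank + ex())
    i1 <- c(a[2], a[2] + il())
    b <- c(i1[2], i1[2] + ex())
    i2 <- c(b[2], b[2] + il())
    cc <- c(i2[2], i2[2] + ex())
    plant(i1[1], "GT"); plant(i1[2] - 2L, "AG")
    plant(i2[1], "GT"); plant(i2[2] - 2L, "AG")
    list(isoforms = list(rbind(a, b, cc), rbind(a, cc)),
         introns = list(up = i1, down = i2, skip = c(i1[1], i2[2])),
         exons = list(cassette = b),
         dinucs = dn, length = cc[2] + flank)
  } else if (type == "RI") {
    a <- c(flank, flank + ex())
    i1 <- c(a[2], a[2] + il())
    b <- c(i1[2], i1[2] + ex())
    plant(i1[1], "GT"); plant(i1[2] - 2L, "AG")
    list(isoforms = list(rbind(a, b), rbind(c(a[1], b[2]))),
         introns = list(intron = i1),
         exons = NULL, dinucs = dn, length = b[2] + flank)
  } else if (type == "A5SS") {
    a <- c(flank, flank + ex())
    len <- max(il(), alt_shift[2] + 30L)
    shift <- rlen(alt_shift)
    i_skip <- c(a[2], a[2] + len)
    i_incl <- c(a[2] + shift, a[2] + len)
    b <- c(i_skip[2], i_skip[2] + ex())
    plant(i_skip[1], "GT"); plant(i_incl[1], "GT"); plant(i_skip[2] - 2L, "AG")
    list(isoforms = list(rbind(c(a[1], i_incl[1]), b), rbind(a, b)),
         introns = list(incl = i_incl, skip = i_skip),
         exons = NULL, dinucs = dn, length = b[2] + flank)
  } else if (type == "A3SS") {
    a <- c(flank, flank + ex())
    len <- max(il(), alt_shift[2] + 30L)
    shift <- rlen(alt_shift)
    i_skip <- c(a[2], a[2] + len)
    i_incl <- c(a[2], a[2] + len - shift)
    b <- c(i_skip[2], i_skip[2] + ex())
    plant(i_skip[1], "GT"); plant(i_incl[2] - 2L, "AG"); plant(i_skip[2] - 2L, "AG")
    list(isoforms = list(rbind(a, c(i_incl[2], b[2])), rbind(a, b)),
         introns = list(incl = i_incl, skip = i_skip),
         exons = NULL, dinucs = dn, length = b[2] + flank)
  } else { # MXE
    a <- c(flank, flank + ex())
    i1 <- c(a[2], a[2] + il())
    m1 <- c(i1[2], i1[2] + ex())
    i2 <- c(m1[2], m1[2] + il())
    m2 <- c(i2[2], i2[2] + ex())
    i3 <- c(m2[2], m2[2] + il())
    b <- c(i3[2], i3[2] + ex())
    plant(a[2], "GT")
    plant(m1[1] - 2L, "AG"); plant(m1[2], "GT")
    plant(m2[1] - 2L, "AG"); plant(m2[2], "GT")
    plant(b[1] - 2L, "AG")
    list(isoforms = list(rbind(a, m1, b), rbind(a, m2, b)),
         introns = list(up1 = c(a[2], m1[1]), dn1 = c(m1[2], b[1]),
                        up2 = c(a[2], m2[1]), dn2 = c(m2[2], b[1])),
         exons = list(m1 = m1, m2 = m2),
         dinucs = dn, length = b[2] + flank)
  }
}

## truth event record in genomic coordinates (after any mirroring)
toy_event_record <- function(type, g, chrom, strand, gid) {
  jx <- function(iv) jx_key(chrom, iv[1], iv[2], strand)
  don_b <- function(iv) if (strand == "+") iv[1] else iv[2] - 1L
  acc_b <- function(iv) if (strand == "+") iv[2] - 1L else iv[1]
  if (type == "SE") {
    cs <- g$exons$cassette
    sk <- g$introns$skip
    rec <- list(pos1 = cs[1], pos2 = cs[2], pos3 = sk[1], pos4 = sk[2],
                incl = c(jx(g$introns$up), jx(g$introns$down)),
                skip = jx(sk), distance = NA_integer_)
  } else if (type == "RI") {
    iv <- g$introns$intron
    rec <- list(pos1 = iv[1], pos2 = iv[2], pos3 = NA_integer_, pos4 = NA_integer_,
                incl = ri_key(chrom, iv[1], iv[2], strand),
                skip = jx(iv), distance = iv[2] - iv[1])
  } else if (type == "A5SS") {
    d1 <- don_b(g$introns$incl); d2 <- don_b(g$introns$skip)
    rec <- list(pos1 = d1, pos2 = d2, pos3 = acc_b(g$introns$incl),
                pos4 = NA_integer_,
                incl = jx(g$introns$incl), skip = jx(g$introns$skip),
                distance = abs(d1 - d2))
  } else if (type == "A3SS") {
    a1 <- acc_b(g$introns$incl); a2 <- acc_b(g$introns$skip)
    rec <- list(pos1 = a1, pos2 = a2, pos3 = don_b(g$introns$incl),
                pos4 = NA_integer_,
                incl = jx(g$introns$incl), skip = jx(g$introns$skip),
                distance = abs(a1 - a2))
  } else { # MXE: inclusion = exclusive exon upstream on the transcribed strand
    m1 <- g$exons$m1; m2 <- g$exons$m2
    up_first <- if (strand == "+") m1[1] < m2[1] else m1[1] > m2[1]
    up <- if (up_first) m1 else m2
    dw <- if (up_first) m2 else m1
    up_jx <- if (up_first) c(jx(g$introns$up1), jx(g$introns$dn1))
             else c(jx(g$introns$up2), jx(g$introns$dn2))
    dw_jx <- if (up_first) c(jx(g$introns$up2), jx(g$introns$dn2))
             else c(jx(g$introns$up1), jx(g$introns$dn1))
    rec <- list(pos1 = up[1], pos2 = up[2], pos3 = dw[1], pos4 = dw[2],
                incl = up_jx, skip = dw_jx, distance = NA_integer_)
  }
  data.frame(event_id = paste(c(type, chrom, strand, rec$pos1, rec$pos2,
                                rec$pos3, rec$pos4), collapse = ":"),
             gene_id = gid, type = type, chrom = chrom, strand = strand,
             pos1 = rec$pos1, pos2 = rec$pos2, pos3 = rec$pos3, pos4 = rec$pos4,
             inclusion_junctions = join_keys(rec$incl),
             skipping_junctions = join_keys(rec$skip),
             distance = rec$distance, stringsAsFactors = FALSE)
}

#' Simulate junction-count and coverage-window tables
#'
#' For each event and sample the event read total is drawn
#' Poisson(`depth`), the inclusion count Binomial(total, true PSI), and the
#' inclusion/skipping counts are split multinomially across the event's
#' junction keys, so that summing counts over a junction set recovers the
#' event-level count exactly. For each splice site the paired 40-nt window
#' counts are drawn with exonic share equal to the true USS (the documented
#' inversion of the default USS formula a/(a+b)).
#'
#' @param truth Truth list from [make_toy_genome()] (possibly edited).
#' @param n_replicates Replicates per condition.
#' @param depth Expected reads per event.
#' @param window_depth Expected reads per window pair (total a+b is
#'   Poisson(2 * window_depth)).
#' @param seed Integer seed.
#' @return List with `junctions` (junction, sample, condition, count),
#'   `windows` (site_id, sample, condition, exonic_count, intronic_count) and
#'   `samples` (sample, condition).
#' @export
simulate_counts <- function(truth, n_replicates = 3L, depth = 100,
                            window_depth = 100, seed = 1L) {
  stopifnot(depth >= 1, n_replicates >= 1L)
  set.seed(seed)
  conds <- truth$params$conditions %||% c("control", "mutant")
  samples <- data.frame(
    sample = paste0(rep(conds, each = n_replicates), "_r", seq_len(n_replicates)),
    condition = rep(conds, each = n_replicates), stringsAsFactors = FALSE)

  ev <- truth$events
  incl_keys <- strsplit(ev$inclusion_junctions, ";", fixed = TRUE)
  skip_keys <- strsplit(ev$skipping_junctions, ";", fixed = TRUE)
  jx_out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    p <- if (samples$condition[s] == conds[1]) ev$psi_a else ev$psi_b
    n <- rpois(nrow(ev), depth)
    I <- rbinom(nrow(ev), n, p)
    S <- n - I
    split_counts <- function(total, keys) {
      k <- length(keys)
      if (k == 1L) return(total)
      as.integer(stats::rmultinom(1L, total, rep(1 / k, k)))
    }
    ji <- mapply(split_counts, I, incl_keys, SIMPLIFY = FALSE)
    js <- mapply(split_counts, S, skip_keys, SIMPLIFY = FALSE)
    jx_out[[s]] <- data.frame(
      junction = c(unlist(incl_keys), unlist(skip_keys)),
      sample = samples$sample[s], condition = samples$condition[s],
      count = c(unlist(ji), unlist(js)), stringsAsFactors = FALSE)
  }

  st <- truth$sites
  win_out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    u <- if (samples$condition[s] == conds[1]) st$uss_a else st$uss_b
    m <- rpois(nrow(st), 2 * window_depth)
    a <- rbinom(nrow(st), m, u)
    win_out[[s]] <- data.frame(
      site_id = st$site_id, sample = samples$sample[s],
      condition = samples$condition[s],
      exonic_count = a, intronic_count = m - a, stringsAsFactors = FALSE)
  }

  list(junctions = do.call(rbind, jx_out),
       windows = do.call(rbind, win_out),
       samples = samples)
}

#' Simulate lariat RT-PCR derived reads with known branch points
#'
#' Each read joins an intron segment ending at the branch point (BP) to the
#' intron 5' terminus, mimicking cDNA synthesized across the lariat's
#' 2',5'-phosphodiester bond: `read = intron[bp-L1+1..bp] ++ intron[1..L2]`.
#' When the BP reference base is A it is replaced by T with probability
#' `a2t_rate` (the reverse-transcription misincorporation signature);
#' uniform substitution errors are added elsewhere at `error_rate`; a
#' configurable fraction of reads is emitted reverse-complemented (TA-cloning
#' orientation is arbitrary).
#'
#' @param intron_seq Intron sequence (sense, 5' to 3', position 1 = first
#'   intronic base).
#' @param bp_freqs Named numeric: names are negative offsets from the intron
#'   3' end (-1 = last base), values are usage frequencies summing to 1.
#' @param n_clones Number of reads (clones).
#' @param a2t_rate Probability that an adenosine BP is read as T.
#' @param error_rate Per-base substitution error probability (BP excluded).
#' @param revcomp_frac Fraction of reads emitted reverse-complemented.
#' @param anchor_range Range (nt) of the pre-jump and post-jump segment
#'   lengths.
#' @param min_anchor Minimum distance of a BP from the intron ends.
#' @param seed Integer seed.
#' @param intron_id,strain Labels carried into the read set.
#' @return List (class `lariat_read_set`) with `reads` (read_id, seq),
#'   `intron_id`, `strain`, and `truth` (per-read bp_offset, a2t,
#'   revcomped).
#' @export
simulate_lariat_reads <- function(intron_seq, bp_freqs, n_clones = 12L,
                                  a2t_rate = 0.7, error_rate = 0.005,
                                  revcomp_frac = 0.5,
                                  anchor_range = c(min_anchor, 2L * min_anchor),
                                  min_anchor = 8L,
                                  seed = 1L, intron_id = "intron1",
                                  strain = "strain1") {
  if (abs(sum(bp_freqs) - 1) > 1e-9) stop("bp_freqs must sum to 1")
  L <- nchar(intron_seq)
  offs <- as.integer(names(bp_freqs))
  if (any(offs >= 0L) || any(offs < -L)) stop("BP offsets must lie in [-intron length, -1]")
  pos <- L + 1L + offs
  if (any(pos - 1L < min_anchor) || any(L - pos < min_anchor) ||
      any(pos < anchor_range[1])) {
    stop("BP too close to intron ends for the requested anchors")
  }
  set.seed(seed)
  ib <- strsplit(intron_seq, "", fixed = TRUE)[[1]]
  pick <- sample(seq_along(offs), n_clones, replace = TRUE, prob = bp_freqs)
  seqs <- character(n_clones)
  a2t <- logical(n_clones)
  rc <- runif(n_clones) < revcomp_frac
  for (r in seq_len(n_clones)) {
    p <- pos[pick[r]]
    L1 <- sample(seq(anchor_range[1], min(anchor_range[2], p)), 1L)
    L2 <- sample(seq(anchor_range[1], min(anchor_range[2], L)), 1L)
    rd <- c(ib[(p - L1 + 1L):p], ib[1:L2])
    if (ib[p] == "A" && runif(1) < a2t_rate) {
      rd[L1] <- "T"
      a2t[r] <- TRUE
    }
    err <- which(runif(length(rd)) < error_rate)
    err <- setdiff(err, L1)  # BP position carries only the A->T signature
    for (e in err) rd[e] <- sample(setdiff(BASES, rd[e]), 1L)
    s <- paste(rd, collapse = "")
    seqs[r] <- if (rc[r]) rc_string(s) else s
  }
  structure(list(
    reads = data.frame(read_id = sprintf("%s_clone%04d", strain, seq_len(n_clones)),
                       seq = seqs, stringsAsFactors = FALSE),
    intron_id = intron_id, strain = strain,
    truth = data.frame(read_id = sprintf("%s_clone%04d", strain, seq_len(n_clones)),
                       bp_offset = offs[pick], a2t = a2t, revcomped = rc,
                       stringsAsFactors = FALSE)),
    class = "lariat_read_set")
}

#' Write a DNA set to FASTA
#' @param x Named character vector or [Biostrings::DNAStringSet].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
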