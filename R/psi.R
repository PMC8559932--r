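## Five-type alternative-splicing event extraction from isoform pairs,
## PSI quantification from junction counts, differential screening, and
## inter-site distance distributions.

#' Extract alternative-splicing events from gene models
#'
#' Pairwise comparison of each gene's isoforms yields events of five types
#' by pattern matching on intron/exon structure: skipped exon (SE), retained
#' intron (RI), alternative 5'/3' splice site (A5SS/A3SS) and mutually
#' exclusive exons (MXE). Events are deduplicated on their defining
#' coordinates; each lists its inclusion and skipping junction keys. For
#' A5SS/A3SS the long-exon form (alternative site closer to its partner
#' across the intron) is "inclusion"; for RI, retention is inclusion; for
#' MXE, the exclusive exon upstream on the transcribed strand is inclusion.
#'
#' @param models A `gene_models` list.
#' @return Data.frame with one row per event: `event_id`, `gene_id`, `type`,
#'   `chrom`, `strand`, defining coordinates `pos1..pos4` (SE: cassette
#'   start/end + skip-intron start/end; RI: intron start/end; A5SS/A3SS:
#'   inclusion-site boundary, skip-site boundary, shared partner boundary;
#'   MXE: upstream then downstream exclusive exon start/end),
#'   `inclusion_junctions`, `skipping_junctions` (";"-joined keys) and
#'   `distance` (RI: intron length; A5SS/A3SS: alternative-site separation;
#'   NA otherwise).
#' @export
extract_events <- function(models) {
  out <- lapply(models, extract_gene_events)
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ev)) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), pos1 = integer(0),
                      pos2 = integer(0), pos3 = integer(0), pos4 = integer(0),
                      inclusion_junctions = character(0),
                      skipping_junctions = character(0),
                      distance = integer(0)))
  }
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

extract_gene_events <- function(g) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(NULL)
  rows <- list()
  add <- function(type, pos, incl, skip, distance = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = paste(c(type, g$chrom, g$strand, pos), collapse = ":"),
      gene_id = g$gene_id, type = type, chrom = g$chrom, strand = g$strand,
      pos1 = pos[1], pos2 = pos[2], pos3 = pos[3], pos4 = pos[4],
      inclusion_junctions = join_keys(incl),
      skipping_junctions = join_keys(skip),
      distance = distance, stringsAsFactors = FALSE)
  }
  jx <- function(s, e) jx_key(g$chrom, s, e, g$strand)
  don_b <- function(s, e) if (g$strand == "+") s else e - 1L
  acc_b <- function(s, e) if (g$strand == "+") e - 1L else s

  pairs <- utils::combn(length(txs), 2L, simplify = FALSE)
  for (pr in pairs) {
    for (swap in c(FALSE, TRUE)) {
      t1 <- txs[[if (swap) pr[2] else pr[1]]]  # candidate inclusion path
      t2 <- txs[[if (swap) pr[1] else pr[2]]]  # candidate skipping path
      in1 <- tx_introns(t1); in2 <- tx_introns(t2)

      ## SE: a T2 intron spanned by two consecutive T1 introns
      if (nrow(in2) >= 1L && nrow(in1) >= 2L) {
        for (j in seq_len(nrow(in2))) {
          S <- in2[j, 1]; E <- in2[j, 2]
          for (k in seq_len(nrow(in1) - 1L)) {
            if (in1[k, 1] == S && in1[k + 1L, 2] == E && in1[k, 2] < in1[k + 1L, 1]) {
              cass <- c(in1[k, 2], in1[k + 1L, 1])
              add("SE", c(cass[1], cass[2], S, E),
                  incl = c(jx(S, cass[1]), jx(cass[2], E)),
                  skip = jx(S, E))
            }
          }
        }
      }
      ## RI: a T2 intron strictly inside one T1 exon
      if (nrow(in2) >= 1L) {
        for (j in seq_len(nrow(in2))) {
          S <- in2[j, 1]; E <- in2[j, 2]
          spans <- t1[, "start"] < S & t1[, "end"] > E
          if (any(spans)) {
            add("RI", c(S, E, NA_integer_, NA_integer_),
                incl = ri_key(g$chrom, S, E, g$strand),
                skip = jx(S, E), distance = E - S)
          }
        }
      }
      if (swap) next  # the remaining patterns are symmetric in the pair

      ## A5SS / A3SS: intron pairs sharing one end, alternative exons overlap
      if (nrow(in1) >= 1L && nrow(in2) >= 1L) {
        for (j in seq_len(nrow(in1))) for (k in seq_len(nrow(in2))) {
          s1 <- in1[j, 1]; e1 <- in1[j, 2]; s2 <- in2[k, 1]; e2 <- in2[k, 2]
          if (e1 == e2 && s1 != s2) {
            ## shared right end; alternative left ends must come from
            ## overlapping exons (excludes SE-derived pairs)
            x1 <- t1[t1[, "end"] == s1, , drop = FALSE]
            x2 <- t2[t2[, "end"] == s2, , drop = FALSE]
            if (nrow(x1) && nrow(x2) &&
                max(x1[1, 1], x2[1, 1]) < min(s1, s2)) {
              ii <- if (s1 > s2) c(s1, e1) else c(s2, e2)  # shorter intron
              ss <- if (s1 > s2) c(s2, e2) else c(s1, e1)
              type <- if (g$strand == "+") "A5SS" else "A3SS"
              if (type == "A5SS") {
                add("A5SS", c(don_b(ii[1], ii[2]), don_b(ss[1], ss[2]),
                              acc_b(ii[1], ii[2]), NA_integer_),
                    incl = jx(ii[1], ii[2]), skip = jx(ss[1], ss[2]),
                    distance = abs(s1 - s2))
              } else {
                add("A3SS", c(acc_b(ii[1], ii[2]), acc_b(ss[1], ss[2]),
                              don_b(ii[1], ii[2]), NA_integer_),
                    incl = jx(ii[1], ii[2]), skip = jx(ss[1], ss[2]),
                    distance = abs(s1 - s2))
              }
            }
          } else if (s1 == s2 && e1 != e2) {
            x1 <- t1[t1[, "start"] == e1, , drop = FALSE]
            x2 <- t2[t2[, "start"] == e2, , drop = FALSE]
            if (nrow(x1) && nrow(x2) &&
                max(e1, e2) < min(x1[1, 2], x2[1, 2])) {
              ii <- if (e1 < e2) c(s1, e1) else c(s2, e2)  # shorter intron
              ss <- if (e1 < e2) c(s2, e2) else c(s1, e1)
              type <- if (g$strand == "+") "A3SS" else "A5SS"
              if (type == "A3SS") {
                add("A3SS", c(acc_b(ii[1], ii[2]), acc_b(ss[1], ss[2]),
                              don_b(ii[1], ii[2]), NA_integer_),
                    incl = jx(ii[1], ii[2]), skip = jx(ss[1], ss[2]),
                    distance = abs(e1 - e2))
              } else {
                add("A5SS", c(don_b(ii[1], ii[2]), don_b(ss[1], ss[2]),
                              acc_b(ii[1], ii[2]), NA_integer_),
                    incl = jx(ii[1], ii[2]), skip = jx(ss[1], ss[2]),
                    distance = abs(e1 - e2))
              }
            }
          }
        }
      }
      ## MXE: consecutive intron pairs sharing outer boundaries with
      ## non-overlapping middle exons
      if (nrow(in1) >= 2L && nrow(in2) >= 2L) {
        for (j in seq_len(nrow(in1) - 1L)) for (k in seq_len(nrow(in2) - 1L)) {
          if (in1[j, 1] == in2[k, 1] && in1[j + 1L, 2] == in2[k + 1L, 2]) {
            m1 <- c(in1[j, 2], in1[j + 1L, 1])
            m2 <- c(in2[k, 2], in2[k + 1L, 1])
            if (all(m1 == m2)) next
            if (m1[2] <= m2[1] || m2[2] <= m1[1]) {  # disjoint exons
              S <- in1[j, 1]; E <- in1[j + 1L, 2]
              up_is_m1 <- if (g$strand == "+") m1[1] < m2[1] else m1[1] > m2[1]
              up <- if (up_is_m1) m1 else m2
              dw <- if (up_is_m1) m2 else m1
              add("MXE", c(up[1], up[2], dw[1], dw[2]),
                  incl = c(jx(S, up[1]), jx(up[2], E)),
                  skip = c(jx(S, dw[1]), jx(dw[2], E)))
            }
          }
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Compute PSI for events from one sample's junction counts
#'
#' PSI = I / (I + S) where I and S are the summed counts over the event's
#' inclusion and skipping junction keys; undefined (NA, flagged) when
#' I + S = 0.
#'
#' @param events Data.frame from [extract_events()].
#' @param counts Data.frame with columns `junction` and `count` for one
#'   sample.
#' @param warn_unmatched Warn when `counts` contains junction keys not used
#'   by any event (counts may legitimately cover a superset).
#' @return Data.frame: `event_id`, `inclusion`, `skipping`, `psi`,
#'   `supporting` (= inclusion + skipping), `defined`.
#' @export
compute_psi <- function(events, counts, warn_unmatched = TRUE) {
  stopifnot(all(counts$count >= 0))
  tab <- tapply(counts$count, counts$junction, sum)
  used <- unique(unlist(strsplit(
    c(events$inclusion_junctions, events$skipping_junctions), ";", fixed = TRUE)))
  if (warn_unmatched) {
    n_un <- sum(!names(tab) %in% used)
    if (n_un > 0) warning(n_un, " junction keys in counts match no event; ignored")
  }
  lk <- function(keys) sum(tab[keys], na.rm = TRUE)
  I <- vapply(strsplit(events$inclusion_junctions, ";", fixed = TRUE), lk, numeric(1))
  S <- vapply(strsplit(events$skipping_junctions, ";", fixed = TRUE), lk, numeric(1))
  data.frame(event_id = events$event_id, inclusion = I, skipping = S,
             psi = ifelse(I + S > 0, I / (I + S), NA_real_),
             supporting = I + S, defined = I + S > 0,
             stringsAsFactors = FALSE)
}

#' Differential PSI screen between two conditions
#'
#' Counts are pooled within condition; each event is tested with a two-sided
#' Fisher exact test on the 2x2 table (I_A, S_A; I_B, S_B), corrected with
#' Benjamini-Hochberg across all tested events. An event is flagged
#' significant when |dPSI| > `delta_min`, FDR < `fdr_max`, and the
#' supporting-read minimum over samples is >= `min_reads` (defaults
#' |dPSI| > 0.05, FDR < 0.05, reads >= 5). Events with zero total counts in
#' either condition are reported as untestable.
#'
#' @param events Data.frame from [extract_events()].
#' @param counts Long data.frame `junction`, `sample`, `condition`, `count`.
#' @param condition_a,condition_b Condition labels; dPSI = PSI(b) - PSI(a).
#' @param delta_min,fdr_max,min_reads Screen thresholds.
#' @return Data.frame of PSI records: per-condition counts and PSI,
#'   `delta_psi`, `p_value`, `fdr`, `supporting_reads` (min over samples),
#'   `testable`, `significant`.
#' @export
differential_psi <- function(events, counts, condition_a, condition_b,
                             delta_min = 0.05, fdr_max = 0.05, min_reads = 5L) {
  stopifnot(c(condition_a, condition_b) %in% counts$condition)
  pool <- function(cond) {
    cc <- counts[counts$condition == cond, , drop = FALSE]
    compute_psi(events, cc, warn_unmatched = FALSE)
  }
  qa <- pool(condition_a); qb <- pool(condition_b)
  ## supporting reads: minimum over individual samples of I + S
  supp <- rep(Inf, nrow(events))
  for (sm in unique(counts$sample[counts$condition %in% c(condition_a, condition_b)])) {
    qs <- compute_psi(events, counts[counts$sample == sm, , drop = FALSE],
                      warn_unmatched = FALSE)
    supp <- pmin(supp, qs$supporting)
  }
  testable <- qa$supporting > 0 & qb$supporting > 0
  p <- rep(NA_real_, nrow(events))
  p[testable] <- fisher_p_2x2(qa$inclusion[testable], qa$skipping[testable],
                              qb$inclusion[testable], qb$skipping[testable])$p
  fdr <- rep(NA_real_, nrow(events))
  fdr[testable] <- p.adjust(p[testable], method = "BH")
  delta <- qb$psi - qa$psi
  res <- data.frame(
    event_id = events$event_id, type = events$type, gene_id = events$gene_id,
    inclusion_a = qa$inclusion, skipping_a = qa$skipping,
    inclusion_b = qb$inclusion, skipping_b = qb$skipping,
    psi_a = qa$psi, psi_b = qb$psi, delta_psi = delta,
    p_value = p, fdr = fdr, supporting_reads = supp,
    testable = testable, stringsAsFactors = FALSE)
  res$significant <- testable & !is.na(fdr) &
    abs(delta) > delta_min & fdr < fdr_max & supp >= min_reads
  res
}

#' Distance distribution of significant RI/A5SS/A3SS events
#'
#' For each significant event in the requested dPSI direction, the inter-site
#' distance is the RI intron length, the separation between the two
#' alternative donors (A5SS), or between the two alternative acceptors
#' (A3SS); SE and MXE are excluded. Distances are binned per type.
#'
#' @param records Data.frame from [differential_psi()].
#' @param events Data.frame from [extract_events()] (carries the defining
#'   coordinates).
#' @param direction `"up"` (dPSI > `threshold`) or `"down"`
#'   (dPSI < -`threshold`).
#' @param threshold dPSI direction threshold (default 0.05).
#' @param breaks Histogram breaks; default 30-nt bins anchored at 20 nt
#'   (..., 20, 50, 80, 110, ...), so the 50-80 nt short-intron band is one
#'   bin.
#' @param types Event types to include.
#' @return List with `distances` (event_id, type, distance) and `histogram`
#'   (type, bin, lower, upper, count).
#' @export
distance_distribution <- function(records, events, direction = c("up", "down"),
                                  threshold = 0.05, breaks = NULL,
                                  types = c("RI", "A5SS", "A3SS")) {
  direction <- match.arg(direction)
  sig <- records[records$significant &
                 (if (direction == "up") records$delta_psi > threshold
                  else records$delta_psi < -threshold), , drop = FALSE]
  ev <- events[match(sig$event_id, events$event_id), , drop = FALSE]
  keep <- ev$type %in% types & !is.na(ev$distance)
  dist_df <- data.frame(event_id = ev$event_id[keep], type = ev$type[keep],
                        distance = ev$distance[keep], stringsAsFactors = FALSE)
  if (is.null(breaks)) {
    if (nrow(dist_df)) {
      lo <- min(20, 20 + 30 * floor((min(dist_df$distance) - 20) / 30))
      hi <- 20 + 30 * ceiling((max(dist_df$distance) - 20) / 30)
      breaks <- seq(lo, max(hi, lo + 30), by = 30)
      if (min(dist_df$distance) < lo) breaks <- c(min(dist_df$distance), breaks)
    } else breaks <- c(20, 50, 80)
  }
  hists <- lapply(intersect(types, unique(dist_df$type)), function(tp) {
    d <- dist_df$distance[dist_df$type == tp]
    h <- hist(d, breaks = breaks, right = FALSE, plot = FALSE)
    data.frame(type = tp,
               bin = sprintf("[%g,%g)", h$breaks[-length(h$breaks)], h$breaks[-1]),
               lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1],
               count = h$counts, stringsAsFactors = FALSE)
  })
  list(distances = dist_df,
       histogram = if (length(hists)) do.call(rbind, hists) else
         data.frame(type = character(0), bin = character(0),
                    lower = numeric(0), upper = numeric(0), count = integer(0)))
}
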