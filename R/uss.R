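## Per-splice-site usage statistic (USS) from paired exonic/intronic
## coverage windows, differential screening, and event-type enrichment.

#' Paired exonic/intronic window intervals for splice sites
#'
#' For a 5'SS the exonic window is the last `window` nt of the upstream exon
#' and the intronic window the first `window` nt of the intron; for a 3'SS,
#' the first `window` nt of the downstream exon and the last `window` nt of
#' the intron. Intervals are strand-aware and truncated (and flagged) when
#' the exon or intron is shorter than `window`. When several isoforms flank
#' a site with different exon lengths the longest flanking exon is used.
#'
#' @param sites Data.frame from [enumerate_splice_sites()].
#' @param models The `gene_models` the sites came from.
#' @param window Window length in nt (default 40).
#' @return Data.frame: `site_id`, `kind`, genomic 0-based half-open
#'   `exonic_start`, `exonic_end`, `intronic_start`, `intronic_end`,
#'   `exonic_len`, `intronic_len`, `short_window`.
#' @export
site_windows <- function(sites, models, window = 40L) {
  ## flanking exon length per site: exon adjacent to the boundary, maximum
  ## over isoforms
  flank_len <- stats::setNames(rep(NA_integer_, nrow(sites)), sites$site_id)
  for (g in models) {
    for (m in g$transcripts) {
      intr <- tx_introns(m)
      if (!nrow(intr)) next
      for (j in seq_len(nrow(intr))) {
        s <- intr[j, 1]; e <- intr[j, 2]
        up_len <- m[j, "end"] - m[j, "start"]        # exon left of intron
        dn_len <- m[j + 1L, "end"] - m[j + 1L, "start"]
        don_b <- if (g$strand == "+") s else e - 1L
        acc_b <- if (g$strand == "+") e - 1L else s
        ## donor's exon is transcription-upstream; acceptor's downstream
        don_ex <- if (g$strand == "+") up_len else dn_len
        acc_ex <- if (g$strand == "+") dn_len else up_len
        di <- site_id(g$chrom, g$strand, don_b, "donor")
        ai <- site_id(g$chrom, g$strand, acc_b, "acceptor")
        if (di %in% names(flank_len)) {
          flank_len[di] <- max(flank_len[di], don_ex, na.rm = TRUE)
        }
        if (ai %in% names(flank_len)) {
          flank_len[ai] <- max(flank_len[ai], acc_ex, na.rm = TRUE)
        }
      }
    }
  }
  if (anyNA(flank_len)) {
    stop("site(s) not found in models: ",
         paste(utils::head(sites$site_id[is.na(flank_len)], 3), collapse = ", "))
  }
  ilen <- pmin(window, sites$intron_end - sites$intron_start)
  elen <- pmin(window, unname(flank_len[sites$site_id]))
  b <- sites$boundary
  left_edge <- (sites$kind == "donor") == (sites$strand == "+")
  ## left_edge: boundary at genomic left edge of intron (donor+ / acceptor-)
  exonic_start <- ifelse(left_edge, b - elen, b + 1L)
  exonic_end <- ifelse(left_edge, b, b + 1L + elen)
  intronic_start <- ifelse(left_edge, b, b + 1L - ilen)
  intronic_end <- ifelse(left_edge, b + ilen, b + 1L)
  data.frame(site_id = sites$site_id, kind = sites$kind,
             exonic_start = exonic_start, exonic_end = exonic_end,
             intronic_start = intronic_start, intronic_end = intronic_end,
             exonic_len = elen, intronic_len = ilen,
             short_window = elen < window | ilen < window,
             stringsAsFactors = FALSE)
}

#' Splice-site usage statistic from paired window counts
#'
#' The default formula is the exonic share of window coverage,
#' `uss = a / (a + b)`: a fully spliced intron has no intronic coverage
#' (b = 0) and usage 1; equal coverage gives 0.5. The alternative
#' `one_minus_ratio` strategy is `1 - b/a`, clipped to [0, 1]. Undefined
#' (NA) when a + b = 0.
#'
#' @param a Exonic-window count(s).
#' @param b Intronic-window count(s).
#' @param formula Usage formula strategy.
#' @return Numeric vector of usage values in [0, 1], NA where undefined.
#' @export
compute_uss <- function(a, b, formula = c("exonic_share", "one_minus_ratio")) {
  formula <- match.arg(formula)
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE))
  if (formula == "exonic_share") {
    ifelse(a + b > 0, a / (a + b), NA_real_)
  } else {
    ifelse(a + b > 0, pmin(1, pmax(0, 1 - b / pmax(a, 1e-300))), NA_real_)
  }
}

#' Differential splice-site usage screen between two conditions
#'
#' Window counts are pooled per condition; each site is tested with a
#' two-sided Fisher exact test on (a_A, b_A; a_B, b_B) and BH-corrected.
#' Two screen flags are computed: `sig_fdr` (|dUSS| > `delta_min` and
#' FDR < `fdr_max`; the default `significant` flag) and `sig_p`
#' (|dUSS| > `delta_min` and raw p < `p_max`). Sites with undefined usage
#' in either condition are reported untestable.
#'
#' @param windows Long data.frame `site_id`, `sample`, `condition`,
#'   `exonic_count`, `intronic_count`.
#' @param condition_a,condition_b Condition labels; dUSS = USS(b) - USS(a).
#' @param delta_min,fdr_max,p_max Screen thresholds (defaults 0.01, 0.05,
#'   0.05).
#' @param formula Usage formula, see [compute_uss()].
#' @return Data.frame of site usage records: pooled counts, per-condition
#'   USS, `delta_uss`, `p_value`, `fdr`, `testable`, `sig_fdr`, `sig_p`,
#'   `significant` (= `sig_fdr`).
#' @export
differential_uss <- function(windows, condition_a, condition_b,
                             delta_min = 0.01, fdr_max = 0.05, p_max = 0.05,
                             formula = "exonic_share") {
  stopifnot(all(windows$exonic_count >= 0), all(windows$intronic_count >= 0))
  pool <- function(cond) {
    w <- windows[windows$condition == cond, , drop = FALSE]
    a <- tapply(w$exonic_count, w$site_id, sum)
    b <- tapply(w$intronic_count, w$site_id, sum)
    data.frame(site_id = names(a), a = as.numeric(a),
               b = as.numeric(b[names(a)]), stringsAsFactors = FALSE)
  }
  pa <- pool(condition_a); pb <- pool(condition_b)
  ids <- union(pa$site_id, pb$site_id)
  ia <- match(ids, pa$site_id); ib <- match(ids, pb$site_id)
  a_A <- ifelse(is.na(ia), 0, pa$a[ia]); b_A <- ifelse(is.na(ia), 0, pa$b[ia])
  a_B <- ifelse(is.na(ib), 0, pb$a[ib]); b_B <- ifelse(is.na(ib), 0, pb$b[ib])
  uss_a <- compute_uss(a_A, b_A, formula)
  uss_b <- compute_uss(a_B, b_B, formula)
  testable <- !is.na(uss_a) & !is.na(uss_b)
  p <- rep(NA_real_, length(ids))
  p[testable] <- fisher_p_2x2(a_A[testable], b_A[testable],
                              a_B[testable], b_B[testable])$p
  fdr <- bh_adjust(p)
  delta <- uss_b - uss_a
  res <- data.frame(site_id = ids,
                    exonic_a = a_A, intronic_a = b_A,
                    exonic_b = a_B, intronic_b = b_B,
                    uss_a = uss_a, uss_b = uss_b, delta_uss = delta,
                    p_value = p, fdr = fdr, testable = testable,
                    stringsAsFactors = FALSE)
  res$sig_fdr <- testable & !is.na(fdr) & abs(delta) > delta_min & fdr < fdr_max
  res$sig_p <- testable & !is.na(p) & abs(delta) > delta_min & p < p_max
  res$significant <- res$sig_fdr
  res
}

## site ids touched by an event: donors/acceptors of its junctions (RI
## retention keys contribute the intron's own donor and acceptor, obtained
## from the spliced junction)
event_site_ids <- function(events) {
  lapply(seq_len(nrow(events)), function(i) {
    keys <- unlist(strsplit(c(events$inclusion_junctions[i],
                              events$skipping_junctions[i]), ";", fixed = TRUE))
    keys <- keys[!grepl("^.+:\\d+\\^", keys)]  # drop retention keys
    parts <- regmatches(keys, regexec("^(.+):(\\d+)-(\\d+):([+-])$", keys))
    unlist(lapply(parts, function(pp) {
      if (length(pp) != 5L) return(character(0))
      c(site_id(pp[2], pp[5], as.integer(pp[3]), "donor"),
        site_id(pp[2], pp[5], as.integer(pp[4]), "acceptor"))
    }))
  })
}

#' Enrichment of usage-changed sites within differentially spliced events
#'
#' For each AS event type and site kind (5'SS/3'SS), builds the 2x2 table
#' (site usage-changed yes/no) x (site participates in a significant DS
#' event of that type yes/no) over all tested sites of that kind, and tests
#' it with a Fisher exact test; BH correction across strata. Strata with an
#' empty margin are reported with NA odds ratio and p.
#'
#' @param uss_records Data.frame from [differential_uss()].
#' @param psi_records Data.frame from [differential_psi()].
#' @param events Data.frame from [extract_events()].
#' @return Data.frame: `type`, `kind`, table cells `n_changed_in`,
#'   `n_changed_out`, `n_unchanged_in`, `n_unchanged_out`, `odds_ratio`,
#'   `p_value`, `fdr`, `significant`.
#' @export
uss_event_enrichment <- function(uss_records, psi_records, events) {
  tested <- uss_records[uss_records$testable, , drop = FALSE]
  kind <- sub("^.*:", "", tested$site_id)
  changed <- tested$significant
  sig_ev <- events[match(psi_records$event_id[psi_records$significant],
                         events$event_id), , drop = FALSE]
  types <- c("SE", "RI", "A5SS", "A3SS", "MXE")
  rows <- list()
  for (tp in types) {
    ids_tp <- unique(unlist(event_site_ids(sig_ev[sig_ev$type == tp, , drop = FALSE])))
    for (kd in c("donor", "acceptor")) {
      sel <- kind == kd
      x <- changed[sel]
      y <- tested$site_id[sel] %in% ids_tp
      n11 <- sum(x & y); n10 <- sum(x & !y)
      n01 <- sum(!x & y); n00 <- sum(!x & !y)
      if (sum(x) == 0L || sum(!x) == 0L || sum(y) == 0L || sum(!y) == 0L) {
        or <- NA_real_; p <- NA_real_
      } else {
        ft <- fisher_p_2x2(n11, n10, n01, n00)
        or <- ft$or; p <- ft$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        type = tp, kind = kd, n_changed_in = n11, n_changed_out = n10,
        n_unchanged_in = n01, n_unchanged_out = n00,
        odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr < 0.05 &
    !is.na(res$odds_ratio) & res$odds_ratio > 1
  res
}
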