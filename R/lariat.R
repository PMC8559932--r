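## Branch-point calling from lariat RT-PCR derived reads. A read jumps from
## an internal intron position (the branch point, BP) to the intron 5'
## terminus; the caller searches both orientations and every split for the
## placement maximizing total matches, treating a BP-position A->T mismatch
## (the reverse-transcription signature of the 2',5'-phosphodiester bond)
## as free. Non-adenosine branch nucleotides are first-class: at a non-A BP
## the junction base must match exactly.

#' Construct an intron reference for branch-point calling
#'
#' @param intron_id Identifier.
#' @param sequence Intron sequence, sense 5' to 3' (position 1 = first
#'   intronic base, typically the G of GT).
#' @param primers Optional named list of intervals (1-based, within the
#'   intron) for primers P1/P1'/P2/P2'.
#' @param min_anchor Minimum anchor used downstream (the intron must be at
#'   least twice this long).
#' @return Object of class `intron_ref`.
#' @export
intron_ref <- function(intron_id, sequence, primers = NULL, min_anchor = 8L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L * min_anchor) {
    stop("intron shorter than 2 x min_anchor (", 2L * min_anchor, " nt)")
  }
  if (!is.null(primers)) {
    for (nm in names(primers)) {
      iv <- primers[[nm]]
      if (iv[1] < 1L || iv[2] > L) stop("primer ", nm, " outside the intron")
    }
  }
  structure(list(intron_id = intron_id, sequence = sequence, length = L,
                 primers = primers), class = "intron_ref")
}

## candidate table for one orientation: all (split k, BP position p)
## placements satisfying the anchor/mismatch constraints.
## r: read char vector, s: intron char vector.
bp_candidates <- function(r, s, min_anchor, max_mismatch) {
  n <- length(r); L <- length(s)
  M <- outer(r, s, "==")
  ## C[i,j]: matches of r[1..i] aligned ending at s[j] (diagonal cumsum)
  C <- matrix(0L, n, L)
  C[1, ] <- M[1, ]
  if (n > 1) for (i in 2:n) {
    C[i, 2:L] <- M[i, 2:L] + C[i - 1L, 1:(L - 1L)]
    C[i, 1] <- M[i, 1]
  }
  ## suffix alignment r[k+1..n] maps r[k+m] -> s[m] (intron 5' terminus);
  ## Tv[k] = total matches, Ev[k] = exact-match prefix run of that anchor
  Tv <- integer(n); Ev <- integer(n)
  for (k in seq_len(n - 1L)) {
    len <- n - k
    if (len > L) { Tv[k] <- -1L; next }
    d <- M[cbind(k + seq_len(len), seq_len(len))]
    Tv[k] <- sum(d)
    Ev[k] <- if (d[1]) which.min(c(d, FALSE)) - 1L else 0L
  }
  out <- list()
  ks <- seq.int(min_anchor, n - min_anchor)
  ks <- ks[ks >= 1 & ks <= L & (n - ks) <= L]
  for (k in ks) {
    if (Tv[k] < 0L) next
    post_mm <- (n - k) - Tv[k]
    if (post_mm > max_mismatch) next
    ps <- seq.int(k, L)
    pre_match <- C[k, ps]
    bp_match <- r[k] == s[ps]
    free <- (s[ps] == "A") & (r[k] == "T") & !bp_match
    valid <- bp_match | free
    pre_nonbp_mm <- k - pre_match - ifelse(free, 1L, 0L)
    tot_mm <- pre_nonbp_mm + post_mm
    ok <- valid & tot_mm <= max_mismatch
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      k = k, p = ps[ok],
      score = (k - pre_nonbp_mm[ok]) + Tv[k],
      mismatches = tot_mm[ok],
      signature = free[ok],
      exact_post = Ev[k])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## resolve the candidate set of ONE orientation to its best placement
resolve_orientation <- function(cand) {
  best <- cand[cand$score == max(cand$score), , drop = FALSE]
  best <- best[best$exact_post == max(best$exact_post), , drop = FALSE]
  best[which.max(best$p), , drop = FALSE]
}

#' Call the branch point of one lariat-derived read
#'
#' Searches both read orientations and all split positions for the
#' placement where the read prefix aligns to an intron segment ending at a
#' candidate BP and the read suffix aligns to the intron 5' terminus
#' (starting exactly at position 1), maximizing total matches. A mismatch at
#' the BP is tolerated only as the A->T misincorporation signature (intron
#' base A read as T). A call requires both anchors >= `min_anchor` and
#' non-BP mismatches <= `max_mismatch`. Ties within an orientation are
#' broken by the longest exact-match 5'-terminus anchor, then by the BP
#' closest to the 3' splice site; equal-scoring orientations disagreeing on
#' the BP give status `ambiguous`.
#'
#' @param read Read sequence (character).
#' @param intron An `intron_ref` (or plain intron sequence).
#' @param min_anchor Minimum pre-jump and post-jump anchor length (nt).
#' @param max_mismatch Maximum non-BP mismatches.
#' @param read_id Identifier copied into the result.
#' @return One-row data.frame: `read_id`, `status`
#'   (`called`/`ambiguous`/`unalignable`), `bp_offset` (-1 = last intron
#'   base), `bp_label`, `bp_ref_base`, `observed_base`, `a_to_t_signature`,
#'   `anchor_pre`, `anchor_post`, `mismatches`, `orientation`,
#'   `alt_bp_offset` (second candidate when ambiguous).
#' @export
call_branchpoint <- function(read, intron, min_anchor = 8L, max_mismatch = 1L,
                             read_id = NA_character_) {
  if (!inherits(intron, "intron_ref")) {
    intron <- intron_ref("intron", intron, min_anchor = min_anchor)
  }
  s <- strsplit(intron$sequence, "", fixed = TRUE)[[1]]
  L <- length(s)
  read <- toupper(read)
  no_call <- function(status, off1 = NA_integer_, alt = NA_integer_) {
    data.frame(read_id = read_id, status = status, bp_offset = off1,
               bp_label = NA_character_, bp_ref_base = NA_character_,
               observed_base = NA_character_, a_to_t_signature = NA,
               anchor_pre = NA_integer_, anchor_post = NA_integer_,
               mismatches = NA_integer_, orientation = NA_character_,
               alt_bp_offset = alt, stringsAsFactors = FALSE)
  }
  if (nchar(read) < 2L * min_anchor) return(no_call("unalignable"))
  orients <- list(forward = strsplit(read, "", fixed = TRUE)[[1]],
                  revcomp = strsplit(rc_string(read), "", fixed = TRUE)[[1]])
  picks <- list()
  for (o in names(orients)) {
    cand <- bp_candidates(orients[[o]], s, min_anchor, max_mismatch)
    if (!is.null(cand)) {
      pk <- resolve_orientation(cand)
      pk$orientation <- o
      picks[[o]] <- pk
    }
  }
  if (!length(picks)) return(no_call("unalignable"))
  if (length(picks) == 2L) {
    s1 <- picks$forward$score; s2 <- picks$revcomp$score
    if (s1 != s2) {
      pick <- if (s1 > s2) picks$forward else picks$revcomp
    } else if (picks$forward$p == picks$revcomp$p) {
      pick <- picks$forward
    } else {
      off <- sort(c(picks$forward$p, picks$revcomp$p) - (L + 1L))
      return(no_call("ambiguous", off1 = off[2], alt = off[1]))
    }
  } else {
    pick <- picks[[1]]
  }
  r <- orients[[pick$orientation]]
  p <- pick$p
  data.frame(read_id = read_id, status = "called",
             bp_offset = p - (L + 1L),
             bp_label = label_bp(p - (L + 1L), intron),
             bp_ref_base = s[p], observed_base = r[pick$k],
             a_to_t_signature = pick$signature,
             anchor_pre = pick$k, anchor_post = length(r) - pick$k,
             mismatches = pick$mismatches, orientation = pick$orientation,
             alt_bp_offset = NA_integer_, stringsAsFactors = FALSE)
}

#' Call branch points for a set of reads
#'
#' @param reads Data.frame with `read_id` and `seq` (e.g. from
#'   [simulate_lariat_reads()]`$reads`), or a `lariat_read_set`.
#' @param intron An `intron_ref` or intron sequence.
#' @param min_anchor,max_mismatch See [call_branchpoint()].
#' @return Data.frame of per-read calls.
#' @export
call_branchpoints <- function(reads, intron, min_anchor = 8L, max_mismatch = 1L) {
  if (inherits(reads, "lariat_read_set")) reads <- reads$reads
  if (!inherits(intron, "intron_ref")) {
    intron <- intron_ref("intron", intron, min_anchor = min_anchor)
  }
  out <- lapply(seq_len(nrow(reads)), function(i) {
    call_branchpoint(reads$seq[i], intron, min_anchor, max_mismatch,
                     read_id = reads$read_id[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate branch-point calls into per-strain usage frequencies
#'
#' Counts called reads per distinct (bp_offset, reference base); usage
#' frequencies are computed over called reads only, with ambiguous and
#' unalignable reads tallied separately.
#'
#' @param calls Data.frame from [call_branchpoints()] (one intron, one
#'   strain).
#' @param intron An `intron_ref` (for labels).
#' @param strain Strain label.
#' @return List (class `bp_usage_table`): `table` (bp_offset, ref_base,
#'   label, count, frequency), `n_called`, `n_ambiguous`, `n_unalignable`,
#'   `strain`, `intron_id`.
#' @export
aggregate_bp <- function(calls, intron, strain = "strain") {
  called <- calls[calls$status == "called", , drop = FALSE]
  if (nrow(called)) {
    tab <- as.data.frame(table(bp_offset = called$bp_offset),
                         stringsAsFactors = FALSE)
    tab$bp_offset <- as.integer(tab$bp_offset)
    tab <- tab[order(tab$bp_offset), , drop = FALSE]
    tab$ref_base <- vapply(tab$bp_offset, function(o) {
      substr(intron$sequence, intron$length + 1L + o, intron$length + 1L + o)
    }, character(1))
    tab$label <- vapply(tab$bp_offset, label_bp, character(1), intron = intron)
    tab$count <- tab$Freq
    tab$frequency <- tab$count / sum(tab$count)
    tab <- tab[, c("bp_offset", "ref_base", "label", "count", "frequency")]
  } else {
    tab <- data.frame(bp_offset = integer(0), ref_base = character(0),
                      label = character(0), count = integer(0),
                      frequency = numeric(0))
  }
  rownames(tab) <- NULL
  structure(list(table = tab, n_called = nrow(called),
                 n_ambiguous = sum(calls$status == "ambiguous"),
                 n_unalignable = sum(calls$status == "unalignable"),
                 strain = strain,
                 intron_id = if (inherits(intron, "intron_ref")) intron$intron_id else NA),
            class = "bp_usage_table")
}

#' Display label of a branch point
#'
#' Concatenates the offset and the reference base at that position, with U
#' substituted for T (RNA display convention), e.g. `"-25A"`, `"-54U"`.
#'
#' @param bp_offset Negative offset from the intron 3' end (-1 = last base).
#' @param intron An `intron_ref` or intron sequence.
#' @return Character label.
#' @export
label_bp <- function(bp_offset, intron) {
  seqc <- if (inherits(intron, "intron_ref")) intron$sequence else toupper(intron)
  L <- nchar(seqc)
  p <- L + 1L + as.integer(bp_offset)
  if (is.na(p) || p < 1L || p > L) stop("bp_offset ", bp_offset, " out of range for intron of length ", L)
  base <- substr(seqc, p, p)
  paste0(bp_offset, chartr("T", "U", base))
}

#' Parse a branch-point label back into offset and base
#' @param label Label like `"-25A"` or `"-54U"`.
#' @return List with `bp_offset` (integer) and `base` (DNA alphabet, U
#'   mapped back to T).
#' @export
parse_bp_label <- function(label) {
  m <- regexec("^(-\\d+)([ACGTU])$", label)[[1]]
  if (m[1] == -1) stop("malformed branch-point label: ", label)
  parts <- regmatches(label, regexec("^(-\\d+)([ACGTU])$", label))[[1]]
  list(bp_offset = as.integer(parts[2]), base = chartr("U", "T", parts[3]))
}
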