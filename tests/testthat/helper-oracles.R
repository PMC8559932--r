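## Independent brute-force oracles used across the suite. These are written
## naively (explicit loops, direct enumeration) on purpose: they share no
## code with the package's optimized implementations.

oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## exhaustive branch-point search over every orientation, split and BP
## position, applying the documented resolution rules step by step
bp_oracle <- function(read, intron_seq, min_anchor = 8L, max_mismatch = 1L) {
  s <- strsplit(toupper(intron_seq), "")[[1]]
  L <- length(s)
  best_of <- function(rchars) {
    n <- length(rchars)
    cands <- list()
    if (n < 2 * min_anchor) return(NULL)
    for (k in min_anchor:(n - min_anchor)) {
      if (k > L) next
      post <- rchars[(k + 1):n]
      if (length(post) > L) next
      post_mm <- sum(post != s[seq_along(post)])
      exact <- 0
      for (m in seq_along(post)) {
        if (post[m] == s[m]) exact <- exact + 1 else break
      }
      for (p in k:L) {
        pre <- rchars[1:k]
        ref <- s[(p - k + 1):p]
        bp_ok <- pre[k] == ref[k] || (ref[k] == "A" && pre[k] == "T")
        if (!bp_ok) next
        sig <- ref[k] == "A" && pre[k] == "T"
        mm <- sum(pre[-k] != ref[-k]) + post_mm
        if (mm > max_mismatch) next
        score <- (k - sum(pre[-k] != ref[-k])) + (n - k - post_mm)
        cands[[length(cands) + 1]] <- data.frame(
          k = k, p = p, score = score, exact = exact, mm = mm, sig = sig)
      }
    }
    if (!length(cands)) return(NULL)
    d <- do.call(rbind, cands)
    d <- d[d$score == max(d$score), , drop = FALSE]
    d <- d[d$exact == max(d$exact), , drop = FALSE]
    d[which.max(d$p), , drop = FALSE]
  }
  fw <- best_of(strsplit(toupper(read), "")[[1]])
  rv <- best_of(strsplit(oracle_rc(toupper(read)), "")[[1]])
  if (is.null(fw) && is.null(rv)) return(list(status = "unalignable"))
  if (!is.null(fw) && !is.null(rv)) {
    if (fw$score > rv$score) pick <- cbind(fw, orientation = "forward")
    else if (rv$score > fw$score) pick <- cbind(rv, orientation = "revcomp")
    else if (fw$p == rv$p) pick <- cbind(fw, orientation = "forward")
    else return(list(status = "ambiguous",
                    offsets = sort(c(fw$p, rv$p) - (L + 1))))
  } else if (!is.null(fw)) pick <- cbind(fw, orientation = "forward")
  else pick <- cbind(rv, orientation = "revcomp")
  list(status = "called", bp_offset = pick$p - (L + 1),
       signature = pick$sig, orientation = pick$orientation,
       mismatches = pick$mm)
}

## two-sided Fisher p by full hypergeometric enumeration on the 2x2 table
## (a b / c d): sum of probabilities of all tables with the same margins
## whose probability does not exceed the observed one
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp)
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## GTF text fixture builder: exons as list of 1-based closed (start, end)
write_toy_gtf <- function(genes, file = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(genes, function(g) {
    unlist(lapply(names(g$transcripts), function(tid) {
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              g$chrom, vapply(g$transcripts[[tid]], `[`, 0, 1),
              vapply(g$transcripts[[tid]], `[`, 0, 2),
              g$strand, g$gene_id, tid)
    }))
  }))
  writeLines(lines, file)
  file
}
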