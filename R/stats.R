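## Shared exact-test plumbing for the PSI, USS and enrichment screens.

#' Two-sided Fisher exact test on 2x2 tables, vectorized over rows
#'
#' Wraps [stats::fisher.test] on the table `rbind(c(a, b), c(c, d))` for each
#' row of the inputs. This is the single test path used by the PSI screen,
#' the USS screen and the enrichment analysis.
#'
#' @param a,b,c_,d_ Non-negative integer vectors (recycled to a common
#'   length): row 1 = (a, b), row 2 = (c_, d_).
#' @return List with numeric vectors `p` (two-sided p-value) and `or`
#'   (conditional MLE odds ratio; NA when undefined).
#' @export
fisher_p_2x2 <- function(a, b, c_, d_) {
  n <- max(length(a), length(b), length(c_), length(d_))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c_ <- rep_len(as.numeric(c_), n); d_ <- rep_len(as.numeric(d_), n)
  p <- numeric(n); or <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- matrix(round(c(a[i], c_[i], b[i], d_[i])), nrow = 2)
    if (any(is.na(m)) || any(m < 0)) {
      p[i] <- NA_real_
      next
    }
    ft <- fisher.test(m)
    p[i] <- ft$p.value
    or[i] <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
  }
  list(p = p, or = or)
}

#' Benjamini-Hochberg adjustment preserving NA entries
#' @param p Numeric vector of p-values (NAs allowed).
#' @return Adjusted p-values, NA where input was NA.
#' @keywords internal
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
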