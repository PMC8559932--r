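## Splice-site strength scoring: trainable log-odds position-weight model on
## the 9-nt donor (3 exonic + 6 intronic) and 23-nt acceptor (20 intronic +
## 3 exonic) windows, with group summaries across usage-change classes.

pwm_window <- function(kind) {
  switch(kind,
         donor = list(width = 9L, exonic = 3L, intronic = 6L),
         acceptor = list(width = 23L, exonic = 3L, intronic = 20L),
         stop("kind must be 'donor' or 'acceptor'"))
}

#' Train a log-odds position-weight model
#'
#' Per-position base frequencies (with pseudocount) over the training
#' windows are converted to log2 odds against a background composition
#' (default: the training set's overall base composition). N bases are
#' excluded from counts.
#'
#' @param sequences Character vector of window strings, all of the kind's
#'   window length (9 nt donor, 23 nt acceptor).
#' @param kind `"donor"` or `"acceptor"`.
#' @param background Optional named numeric over A,C,G,T summing to 1.
#' @param pseudocount Added to every per-position base count (must be > 0).
#' @return Object of class `pwm_model`: list with `kind`, `width`, `exonic`,
#'   `intronic`, `weights` (4 x width log2-odds matrix), `freqs`,
#'   `background`, `pseudocount`, `n_train`.
#' @export
train_pwm <- function(sequences, kind = c("donor", "acceptor"),
                      background = NULL, pseudocount = 0.5) {
  kind <- match.arg(kind)
  win <- pwm_window(kind)
  if (length(sequences) == 0L) stop("empty training set")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  sequences <- toupper(sequences)
  badlen <- which(nchar(sequences) != win$width)
  if (length(badlen)) {
    stop(sprintf("%d sequence(s) do not have the %d-nt %s window length (first offenders: %s)",
                 length(badlen), win$width, kind,
                 paste(utils::head(badlen, 5), collapse = ", ")))
  }
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  ncol = win$width, byrow = TRUE)
  bad <- !chars %in% c(BASES, "N")
  if (any(bad)) stop("sequences contain characters outside {A,C,G,T,N}")
  counts <- vapply(seq_len(win$width), function(j) {
    tabulate(match(chars[, j], BASES), nbins = 4L)
  }, numeric(4))
  rownames(counts) <- BASES
  freqs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  if (is.null(background)) {
    tot <- rowSums(counts)
    background <- (tot + pseudocount) / (sum(tot) + 4 * pseudocount)
  } else {
    if (is.null(names(background)) || !setequal(names(background), BASES) ||
        abs(sum(background) - 1) > 1e-6) {
      stop("background must be named over A,C,G,T and sum to 1")
    }
    background <- background[BASES]
  }
  weights <- log2(freqs / as.numeric(background))
  structure(list(kind = kind, width = win$width, exonic = win$exonic,
                 intronic = win$intronic, weights = weights, freqs = freqs,
                 background = stats::setNames(as.numeric(background), BASES),
                 pseudocount = pseudocount, n_train = length(sequences)),
            class = "pwm_model")
}

#' Score window sequences against a position-weight model
#'
#' The score in bits is the sum of per-position log2-odds weights. A
#' position with a non-ACGT base contributes 0 and the sequence is flagged
#' in `n_ambiguous`.
#'
#' @param model A `pwm_model`.
#' @param sequences Character vector of windows of the model's width.
#' @return Data.frame: `seq`, `score` (bits), `n_ambiguous`.
#' @export
score_sequences <- function(model, sequences) {
  stopifnot(inherits(model, "pwm_model"))
  sequences <- toupper(sequences)
  if (any(nchar(sequences) != model$width)) {
    stop("all sequences must have the model window length (", model$width, " nt)")
  }
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  ncol = model$width, byrow = TRUE)
  ridx <- match(chars, BASES)            # NA for non-ACGT (vector, col-major)
  cidx <- as.vector(col(chars))
  contrib <- matrix(0, nrow = nrow(chars), ncol = model$width)
  ok <- matrix(!is.na(ridx), nrow = nrow(chars))
  contrib[ok] <- model$weights[cbind(ridx[ok], cidx[ok])]
  data.frame(seq = sequences, score = rowSums(contrib),
             n_ambiguous = rowSums(!ok), stringsAsFactors = FALSE)
}

#' Consensus (per-position argmax) sequence of a model
#' @param model A `pwm_model`.
#' @return Character string of the model's width.
#' @export
pwm_consensus <- function(model) {
  paste(BASES[apply(model$weights, 2, which.max)], collapse = "")
}

#' Write a position-weight model to TSV
#'
#' Metadata lines prefixed `#` (kind, window split, pseudocount, training
#' size, background) followed by a position x A,C,G,T weight table. Weights
#' are serialized at full double precision so the model round-trips
#' bit-exactly through [read_pwm()].
#'
#' @param model A `pwm_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pwm <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#kind=%s", model$kind),
    sprintf("#width=%d", model$width),
    sprintf("#exonic=%d", model$exonic),
    sprintf("#intronic=%d", model$intronic),
    sprintf("#pseudocount=%s", sprintf("%.17g", model$pseudocount)),
    sprintf("#n_train=%d", model$n_train),
    sprintf("#background=%s",
            paste(sprintf("%s:%.17g", BASES, model$background), collapse = ",")),
    paste(c("position", BASES), collapse = "\t")), con)
  for (j in seq_len(model$width)) {
    writeLines(paste(c(j, sprintf("%.17g", model$weights[, j])), collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a position-weight model written by [write_pwm()]
#' @param file Path to a model TSV.
#' @return A `pwm_model` (without training frequencies).
#' @export
read_pwm <- function(file) {
  lines <- readLines(file)
  meta <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("^#", key, "="), "", meta[startsWith(meta, paste0("#", key, "="))])
  bg <- strsplit(strsplit(get("background"), ",")[[1]], ":")
  background <- stats::setNames(as.numeric(vapply(bg, `[`, "", 2)),
                                vapply(bg, `[`, "", 1))[BASES]
  body <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t")
  weights <- t(as.matrix(body[, BASES]))
  rownames(weights) <- BASES
  colnames(weights) <- NULL
  structure(list(kind = get("kind"), width = as.integer(get("width")),
                 exonic = as.integer(get("exonic")),
                 intronic = as.integer(get("intronic")),
                 weights = weights, freqs = NULL,
                 background = background,
                 pseudocount = as.numeric(get("pseudocount")),
                 n_train = as.integer(get("n_train"))),
            class = "pwm_model")
}

#' Summarize strength scores by usage-change group
#'
#' Reports per-group n, mean, median and standard error (NA for groups with
#' fewer than 2 members), plus two-sided Wilcoxon rank-sum tests for every
#' group pair, BH-corrected. With a single group only the summary is
#' returned.
#'
#' @param scores Numeric vector of strength scores.
#' @param groups Group label per score (e.g. `"decreased"`, `"increased"`,
#'   `"unchanged"`).
#' @return List with `summary` (group, n, mean, median, se) and `tests`
#'   (group1, group2, p_value, fdr; zero rows when < 2 groups).
#' @export
summarize_by_group <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  summ <- do.call(rbind, lapply(gs, function(g) {
    x <- scores[groups == g]
    data.frame(group = g, n = length(x), mean = mean(x), median = median(x),
               se = if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- data.frame(group1 = character(0), group2 = character(0),
                      p_value = numeric(0), fdr = numeric(0))
  if (length(gs) >= 2L) {
    prs <- utils::combn(gs, 2L, simplify = FALSE)
    p <- vapply(prs, function(pr) {
      x <- scores[groups == pr[1]]; y <- scores[groups == pr[2]]
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    }, numeric(1))
    tests <- data.frame(group1 = vapply(prs, `[`, "", 1),
                        group2 = vapply(prs, `[`, "", 2),
                        p_value = p, fdr = bh_adjust(p),
                        stringsAsFactors = FALSE)
  }
  list(summary = summ, tests = tests)
}

#' Classify sites into usage-change groups from a USS screen
#'
#' @param uss_records Data.frame from [differential_uss()].
#' @param delta_min The |dUSS| threshold separating changed from unchanged
#'   (default 0.01).
#' @return Character vector aligned with `uss_records`: `"increased"`,
#'   `"decreased"` (significant screen calls) or `"unchanged"`
#'   (|dUSS| < `delta_min`); NA for sites in neither class.
#' @export
usage_groups <- function(uss_records, delta_min = 0.01) {
  ifelse(uss_records$significant & uss_records$delta_uss > delta_min, "increased",
  ifelse(uss_records$significant & uss_records$delta_uss < -delta_min, "decreased",
  ifelse(!is.na(uss_records$delta_uss) & abs(uss_records$delta_uss) < delta_min,
         "unchanged", NA_character_)))
}

#' Draw window sequences from a position-weight model's frequencies
#'
#' Sampling utility for planted-effect designs: draws independent positions
#' from the model's per-position frequency columns.
#'
#' @param model A `pwm_model` with training frequencies.
#' @param n Number of sequences.
#' @return Character vector of `n` windows.
#' @export
sample_from_pwm <- function(model, n) {
  stopifnot(inherits(model, "pwm_model"), !is.null(model$freqs))
  cols <- vapply(seq_len(model$width), function(j) {
    sample(BASES, n, replace = TRUE, prob = model$freqs[, j])
  }, character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1, paste, collapse = "")
}
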