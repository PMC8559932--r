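## Annotation core: gene models, splice-site enumeration, windowed sequence
## access. Internal coordinates are 0-based half-open; GTF I/O converts
## from/to 1-based closed. A splice-site "boundary" is the 0-based position
## of the first intronic base (donor) / last intronic base (acceptor).

#' Load exon annotation into gene models
#'
#' Parses GTF/GFF exon records into a list of gene models. Each model holds
#' the gene's chromosome, strand and one exon table per transcript, in
#' internal 0-based half-open coordinates. Duplicate transcripts (identical
#' exon chains) within a gene are collapsed with a warning.
#'
#' @param gtf_file Path to a GTF/GFF file. Only `exon` features are used;
#'   attributes must carry `gene_id` and `transcript_id`.
#' @param genome Optional genome as a named [Biostrings::DNAStringSet] (or
#'   named character vector); when given, exon intervals are validated
#'   against chromosome lengths.
#' @return A named list of gene models (class `gene_models`). Each element is
#'   a list with `gene_id`, `chrom`, `strand` and `transcripts` (a named list
#'   of two-column matrices `start`,`end`, 0-based half-open, sorted).
#' @export
load_annotation <- function(gtf_file, genome = NULL) {
  lines <- readLines(gtf_file)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(recs) != 9L)
  if (length(bad)) {
    stop(sprintf("malformed GTF record at line %d: expected 9 tab-separated fields, found %d",
                 idx[bad[1]], lengths(recs)[bad[1]]))
  }
  m <- do.call(rbind, recs)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) stop("no exon features found in ", gtf_file)
  m <- m[is_exon, , drop = FALSE]
  lineno <- idx[is_exon]

  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    j <- which(is.na(start1) | is.na(end1))[1]
    stop(sprintf("malformed GTF record at line %d: non-numeric coordinates", lineno[j]))
  }
  if (any(end1 < start1)) {
    j <- which(end1 < start1)[1]
    stop(sprintf("invalid exon at line %d: end (%d) < start (%d)",
                 lineno[j], end1[j], start1[j]))
  }
  strand <- m[, 7]
  if (!all(strand %in% c("+", "-"))) {
    j <- which(!strand %in% c("+", "-"))[1]
    stop(sprintf("invalid strand '%s' at line %d", strand[j], lineno[j]))
  }
  gid <- attr_field(m[, 9], "gene_id", lineno)
  tid <- attr_field(m[, 9], "transcript_id", lineno)
  chrom <- m[, 1]

  if (!is.null(genome)) {
    lens <- if (inherits(genome, "DNAStringSet")) {
      stats::setNames(Biostrings::width(genome), names(genome))
    } else stats::setNames(nchar(genome), names(genome))
    unknown <- !(chrom %in% names(lens))
    if (any(unknown)) {
      j <- which(unknown)[1]
      stop(sprintf("exon at line %d references unknown chromosome '%s'",
                   lineno[j], chrom[j]))
    }
    oob <- end1 > lens[chrom] | start1 < 1L
    if (any(oob)) {
      j <- which(oob)[1]
      stop(sprintf("exon at line %d exceeds chromosome '%s' bounds (length %d)",
                   lineno[j], chrom[j], lens[[chrom[j]]]))
    }
  }

  exons <- data.frame(chrom = chrom, strand = strand, gene_id = gid,
                      transcript_id = tid,
                      start = start1 - 1L, end = end1,  # to 0-based half-open
                      stringsAsFactors = FALSE)
  models <- lapply(split(exons, exons$gene_id), build_gene_model)
  structure(models[order(names(models))], class = "gene_models")
}

attr_field <- function(attrs, field, lineno) {
  rx <- paste0(field, "[ =]+\"?([^\";]+)\"?")
  mm <- regmatches(attrs, regexec(rx, attrs))
  val <- vapply(mm, function(x) if (length(x) == 2L) x[2] else NA_character_,
                character(1))
  if (anyNA(val)) {
    stop(sprintf("GTF record at line %d lacks attribute '%s'",
                 lineno[which(is.na(val))[1]], field))
  }
  val
}

build_gene_model <- function(ex) {
  if (length(unique(ex$chrom)) != 1L || length(unique(ex$strand)) != 1L) {
    stop("gene ", ex$gene_id[1], " spans multiple chromosomes or strands")
  }
  txs <- lapply(split(ex, ex$transcript_id), function(t) {
    o <- order(t$start)
    mat <- cbind(start = t$start[o], end = t$end[o])
    if (nrow(mat) > 1L) {
      gaps <- mat[-1L, "start"] - mat[-nrow(mat), "end"]
      if (any(gaps < 1L)) {
        stop("transcript ", t$transcript_id[1],
             ": exons overlap or abut (derived intron length < 1)")
      }
    }
    mat
  })
  ## collapse duplicated exon chains
  sig <- vapply(txs, function(m) paste(t(m), collapse = ","), character(1))
  if (anyDuplicated(sig)) {
    warning("gene ", ex$gene_id[1], ": duplicate transcripts collapsed")
    txs <- txs[!duplicated(sig)]
  }
  list(gene_id = ex$gene_id[1], chrom = ex$chrom[1], strand = ex$strand[1],
       transcripts = txs)
}

#' Write gene models to GTF
#'
#' Inverse of [load_annotation()]: emits one `exon` record per exon with
#' `gene_id`/`transcript_id` attributes, converting internal 0-based
#' half-open coordinates back to 1-based closed GTF.
#'
#' @param models A `gene_models` list.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(models, file) {
  rows <- unlist(lapply(models, function(g) {
    unlist(lapply(names(g$transcripts), function(tid) {
      m <- g$transcripts[[tid]]
      sprintf("%s\tlariatuss\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              g$chrom, m[, "start"] + 1L, m[, "end"], g$strand, g$gene_id, tid)
    }))
  }), use.names = FALSE)
  writeLines(rows, file)
  invisible(file)
}

## introns of one exon matrix: 0-based half-open (start, end) pairs
tx_introns <- function(mat) {
  if (nrow(mat) < 2L) return(matrix(integer(0), ncol = 2,
                                    dimnames = list(NULL, c("start", "end"))))
  cbind(start = mat[-nrow(mat), "end"], end = mat[-1L, "start"])
}

#' Enumerate donor and acceptor splice sites
#'
#' Every distinct intron across all transcripts contributes one donor (5'SS)
#' and one acceptor (3'SS); sites shared between transcripts or genes are
#' deduplicated on (chrom, strand, boundary, kind). On the minus strand the
#' donor sits at the genomic right edge of the intron. Non-canonical
#' dinucleotides are retained and flagged, never dropped.
#'
#' @param models A `gene_models` list.
#' @param genome Optional genome ([Biostrings::DNAStringSet] or named
#'   character); when supplied, the two intron-terminal bases are recorded
#'   per site and checked against the GT/AG consensus.
#' @return A data.frame with columns `site_id`, `chrom`, `strand`,
#'   `boundary` (0-based position of the first/last intronic base),
#'   `kind` (`donor`/`acceptor`), `gene_id`, `intron_start`, `intron_end`,
#'   and, if `genome` was given, `dinucleotide` and `canonical`.
#' @export
enumerate_splice_sites <- function(models, genome = NULL) {
  per_gene <- lapply(models, function(g) {
    intr <- unique(do.call(rbind, lapply(g$transcripts, tx_introns)))
    if (is.null(intr) || nrow(intr) == 0L) return(NULL)
    don_b <- if (g$strand == "+") intr[, "start"] else intr[, "end"] - 1L
    acc_b <- if (g$strand == "+") intr[, "end"] - 1L else intr[, "start"]
    data.frame(chrom = g$chrom, strand = g$strand,
               boundary = c(don_b, acc_b),
               kind = rep(c("donor", "acceptor"), each = nrow(intr)),
               gene_id = g$gene_id,
               intron_start = rep(intr[, "start"], 2L),
               intron_end = rep(intr[, "end"], 2L),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, per_gene)
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(0), strand = character(0),
                        boundary = integer(0), kind = character(0),
                        gene_id = character(0), intron_start = integer(0),
                        intron_end = integer(0))
  }
  sites$site_id <- site_id(sites$chrom, sites$strand, sites$boundary, sites$kind)
  sites <- sites[!duplicated(sites$site_id), , drop = FALSE]
  rownames(sites) <- NULL
  if (!is.null(genome) && nrow(sites)) {
    dn <- character(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      s <- sites$intron_start[i]; e <- sites$intron_end[i]
      seqc <- as.character(get_chrom(genome, sites$chrom[i]))
      dn[i] <- if (sites$kind[i] == "donor") {
        if (sites$strand[i] == "+") substr(seqc, s + 1L, s + 2L)
        else rc_string(substr(seqc, e - 1L, e))
      } else {
        if (sites$strand[i] == "+") substr(seqc, e - 1L, e)
        else rc_string(substr(seqc, s + 1L, s + 2L))
      }
    }
    sites$dinucleotide <- dn
    sites$canonical <- ifelse(sites$kind == "donor", dn == "GT", dn == "AG")
  }
  sites[, c("site_id", "chrom", "strand", "boundary", "kind", "gene_id",
            "intron_start", "intron_end",
            intersect(c("dinucleotide", "canonical"), names(sites)))]
}

get_chrom <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) as.character(genome[[chrom]])
  else genome[[chrom]]
}

#' Fetch the sense-strand window around a splice site
#'
#' Returns the transcribed-strand sequence spanning `exonic_len` exonic and
#' `intronic_len` intronic bases around the exon/intron boundary; minus-strand
#' sites are reverse-complemented. With `exonic_len = 3, intronic_len = 6` a
#' donor yields the 9-nt window whose 4th and 5th characters are the first
#' two intron bases; an acceptor with `exonic_len = 3, intronic_len = 20`
#' yields the 23-nt window ending in the last intronic AG plus 3 exonic bases.
#'
#' @param genome Genome ([Biostrings::DNAStringSet] or named character).
#' @param site One row of the data.frame from [enumerate_splice_sites()] (or
#'   any list with `chrom`, `strand`, `boundary`, `kind`).
#' @param exonic_len,intronic_len Window arm lengths in nt.
#' @return A character string of length `exonic_len + intronic_len`. Donor
#'   windows read exon then intron; acceptor windows intron then exon.
#' @export
fetch_window <- function(genome, site, exonic_len, intronic_len) {
  b <- as.integer(site$boundary)
  kind <- as.character(site$kind); strand <- as.character(site$strand)
  ## 0-based half-open genomic interval covered by the window:
  ## donor+/acceptor- have the boundary at the genomic LEFT edge of the
  ## intron arm; donor-/acceptor+ at the RIGHT edge.
  iv <- if ((kind == "donor") == (strand == "+")) {
    c(b - exonic_len, b + intronic_len)
  } else {
    c(b + 1L - intronic_len, b + 1L + exonic_len)
  }
  seqc <- get_chrom(genome, as.character(site$chrom))
  if (iv[1] < 0L || iv[2] > nchar(seqc)) {
    stop(sprintf("window [%d,%d) for site %s exceeds chromosome bounds (length %d)",
                 iv[1], iv[2], site_id(site$chrom, strand, b, kind), nchar(seqc)))
  }
  w <- substr(seqc, iv[1] + 1L, iv[2])
  if (strand == "-") w <- rc_string(w)
  w
}

#' Export splice sites as BED6
#'
#' @param sites Data.frame from [enumerate_splice_sites()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
sites_to_bed <- function(sites, file) {
  bed <- data.frame(sites$chrom, sites$boundary, sites$boundary + 1L,
                    paste0(sites$gene_id, "|", sites$kind), 0L, sites$strand)
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
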