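#' @keywords internal
"_PACKAGE"

#' @importFrom stats fisher.test p.adjust rbinom rpois runif wilcox.test median sd setNames
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

## reverse complement of a plain character string (ACGTN alphabet)
rc_string <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## deterministic per-stage seeds derived from one global seed; kept < 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, counts = 211L, lariat = 307L, psi = 401L,
               uss = 503L, strength = 601L)
  stopifnot(stage %in% names(offsets))
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## splice-site identifier shared by annotation, uss and simulation layers
site_id <- function(chrom, strand, boundary, kind) {
  paste(chrom, strand, boundary, kind, sep = ":")
}

## junction key: internal (0-based) donor and acceptor boundary positions
jx_key <- function(chrom, intron_start, intron_end, strand) {
  donor <- ifelse(strand == "+", intron_start, intron_end - 1L)
  acceptor <- ifelse(strand == "+", intron_end - 1L, intron_start)
  paste0(chrom, ":", donor, "-", acceptor, ":", strand)
}

## retention-evidence key for RI events (distinct namespace from junctions)
ri_key <- function(chrom, intron_start, intron_end, strand) {
  paste0(chrom, ":", intron_start, "^", intron_end, ":", strand)
}

## canonical ";"-joined junction set (sorted, so provenance order is moot)
join_keys <- function(keys) paste(sort(keys), collapse = ";")

write_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(file, ...) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE, ...)
}
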