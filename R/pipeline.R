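## End-to-end orchestration: simulate -> quantify -> screen -> enrich ->
## score -> lariat, with config validation and a run manifest tying every
## output to parameters and seeds.

#' Default pipeline configuration
#'
#' Thresholds default to the screen conventions used throughout the
#' package: |dPSI| > 0.05 with FDR < 0.05 and >= 5 supporting reads;
#' |dUSS| > 0.01 with FDR < 0.05; 40-nt coverage windows; branch-point
#' calling with min_anchor 8 and max_mismatch 1; lariat simulation with
#' a2t_rate 0.7.
#'
#' @param outdir Output directory.
#' @param seed Global seed, expanded deterministically into per-stage seeds.
#' @return Named list (class `run_config`).
#' @export
default_config <- function(outdir = tempfile("lariatuss_run_"), seed = 1L) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    simulate = list(n_genes = 40L, depth = 200, window_depth = 200,
                    n_replicates = 3L, delta_psi = -0.2, delta_uss = -0.1,
                    conditions = c("control", "mutant")),
    thresholds = list(delta_psi = 0.05, fdr = 0.05, min_reads = 5L,
                      delta_uss = 0.01, window = 40L,
                      min_anchor = 8L, max_mismatch = 1L),
    lariat = list(bp_freqs = c(`-25` = 0.6, `-54` = 0.4), n_clones = 12L,
                  a2t_rate = 0.7, error_rate = 0.005),
    paths = list()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param file YAML path; missing keys fall back to [default_config()].
#' @return A `run_config`.
#' @export
read_config <- function(file) {
  user <- yaml::read_yaml(file)
  cfg <- default_config(outdir = user$outdir %||% tempfile("lariatuss_run_"),
                        seed = user$seed %||% 1L)
  for (sec in c("simulate", "thresholds", "lariat")) {
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  if (!is.null(user$paths)) cfg$paths <- user$paths
  cfg$lariat$bp_freqs <- unlist(cfg$lariat$bp_freqs)
  cfg
}

#' Validate pipeline inputs
#'
#' Schema checks for configured input files (FASTA/GTF/TSV) plus
#' cross-checks: junction keys resolvable against the annotation, window
#' counts non-negative. Returns a report instead of raising.
#'
#' @param config A `run_config`; its `paths` entries (`genome`,
#'   `annotation`, `junctions`, `windows`) are checked when present.
#' @return Data.frame with columns `check` and `message`; zero rows when
#'   everything passes.
#' @export
validate_inputs <- function(config) {
  fails <- list()
  add <- function(check, message) {
    fails[[length(fails) + 1L]] <<- data.frame(check = check, message = message,
                                               stringsAsFactors = FALSE)
  }
  th <- config$thresholds
  for (nm in names(th)) {
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0) {
      add("threshold", sprintf("threshold '%s' must be positive", nm))
    }
  }
  p <- config$paths
  for (nm in names(p)) {
    if (!file.exists(p[[nm]])) add("path", sprintf("missing input '%s': %s", nm, p[[nm]]))
  }
  genome <- NULL; models <- NULL
  if (!is.null(p$genome) && file.exists(p$genome)) {
    genome <- tryCatch(Biostrings::readDNAStringSet(p$genome),
                       error = function(e) { add("fasta", conditionMessage(e)); NULL })
  }
  if (!is.null(p$annotation) && file.exists(p$annotation)) {
    models <- tryCatch(load_annotation(p$annotation, genome),
                       error = function(e) { add("gtf", conditionMessage(e)); NULL })
  }
  if (!is.null(p$junctions) && file.exists(p$junctions)) {
    jx <- tryCatch(read_tsv(p$junctions), error = function(e) { add("tsv", conditionMessage(e)); NULL })
    if (!is.null(jx)) {
      need <- c("junction", "sample", "condition", "count")
      if (!all(need %in% names(jx))) {
        add("junctions", paste("missing columns:", paste(setdiff(need, names(jx)), collapse = ", ")))
      } else {
        if (any(jx$count < 0)) add("junctions", "negative junction counts")
        if (!is.null(models)) {
          chroms <- unique(sub(":.*$", "", jx$junction))
          known <- unique(vapply(models, `[[`, "", "chrom"))
          bad <- setdiff(chroms, known)
          if (length(bad)) {
            add("junctions", paste("junction keys reference unknown chromosome(s):",
                                   paste(utils::head(bad, 3), collapse = ", ")))
          }
        }
      }
    }
  }
  if (!is.null(p$windows) && file.exists(p$windows)) {
    w <- tryCatch(read_tsv(p$windows), error = function(e) { add("tsv", conditionMessage(e)); NULL })
    if (!is.null(w)) {
      need <- c("site_id", "sample", "condition", "exonic_count", "intronic_count")
      if (!all(need %in% names(w))) {
        add("windows", paste("missing columns:", paste(setdiff(need, names(w)), collapse = ", ")))
      } else if (any(w$exonic_count < 0) || any(w$intronic_count < 0)) {
        add("windows", "negative window counts")
      }
    }
  }
  if (length(fails)) do.call(rbind, fails) else
    data.frame(check = character(0), message = character(0))
}

#' Run the full pipeline
#'
#' Simulates a toy genome and count tables (or loads configured inputs),
#' runs the PSI and USS screens, the distance and enrichment analyses,
#' PWM strength scoring grouped by usage change, and a lariat
#' branch-point demonstration, writing every table under `config$outdir`
#' and a manifest (JSON) with md5 checksums, parameters and derived
#' per-stage seeds. Identical configs rerun bit-identically.
#'
#' @param config A `run_config` from [default_config()] or [read_config()].
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config = default_config()) {
  rep_ <- validate_inputs(config)
  if (nrow(rep_)) {
    stop("config validation failed: ", paste(rep_$message, collapse = "; "))
  }
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(genome = derive_seed(config$seed, "genome"),
                counts = derive_seed(config$seed, "counts"),
                lariat = derive_seed(config$seed, "lariat"))
  sm <- config$simulate
  th <- config$thresholds
  conds <- sm$conditions

  ## stage 1: genome + annotation + truth
  toy <- make_toy_genome(sm$n_genes, seed = seeds$genome,
                         delta_psi = sm$delta_psi, delta_uss = sm$delta_uss,
                         conditions = conds)
  write_fasta(toy$genome, file.path(out, "genome.fa"))
  write_gtf(toy$models, file.path(out, "annotation.gtf"))
  jsonlite::write_json(toy$truth[c("events", "sites")],
                       file.path(out, "truth.json"), digits = NA)

  ## stage 2: counts
  cnt <- simulate_counts(toy$truth, n_replicates = sm$n_replicates,
                         depth = sm$depth, window_depth = sm$window_depth,
                         seed = seeds$counts)
  write_tsv(cnt$junctions, file.path(out, "junction_counts.tsv"))
  write_tsv(cnt$windows, file.path(out, "window_counts.tsv"))

  ## stage 3: PSI screen + distances
  models <- load_annotation(file.path(out, "annotation.gtf"),
                            Biostrings::readDNAStringSet(file.path(out, "genome.fa")))
  events <- extract_events(models)
  psi <- differential_psi(events, cnt$junctions, conds[1], conds[2],
                          delta_min = th$delta_psi, fdr_max = th$fdr,
                          min_reads = th$min_reads)
  write_tsv(psi, file.path(out, "psi_records.tsv"))
  dd <- distance_distribution(psi, events,
                              direction = if (sm$delta_psi >= 0) "up" else "down",
                              threshold = th$delta_psi)
  write_tsv(dd$histogram, file.path(out, "distance_histogram.tsv"))

  ## stage 4: USS screen + enrichment
  uss <- differential_uss(cnt$windows, conds[1], conds[2],
                          delta_min = th$delta_uss, fdr_max = th$fdr)
  write_tsv(uss, file.path(out, "uss_records.tsv"))
  enr <- uss_event_enrichment(uss, psi, events)
  write_tsv(enr, file.path(out, "uss_event_enrichment.tsv"))

  ## stage 5: strength scoring grouped by usage change
  genome <- toy$genome
  sites <- enumerate_splice_sites(models, genome)
  don <- sites[sites$kind == "donor", , drop = FALSE]
  dwin <- vapply(seq_len(nrow(don)), function(i)
    fetch_window(genome, don[i, ], 3L, 6L), character(1))
  pwm <- train_pwm(dwin, "donor")
  write_pwm(pwm, file.path(out, "donor_pwm.tsv"))
  sc <- score_sequences(pwm, dwin)
  grp <- usage_groups(uss[match(don$site_id, uss$site_id), , drop = FALSE],
                      delta_min = th$delta_uss)
  keep <- !is.na(grp)
  strength <- data.frame(site_id = don$site_id[keep], score = sc$score[keep],
                         group = grp[keep], stringsAsFactors = FALSE)
  write_tsv(strength, file.path(out, "donor_strength_scores.tsv"))
  gsum <- summarize_by_group(strength$score, strength$group)
  write_tsv(gsum$summary, file.path(out, "strength_group_summary.tsv"))

  ## stage 6: lariat branch-point demo on the first RI intron (or any intron)
  la <- config$lariat
  ri <- toy$truth$events[toy$truth$events$type == "RI", , drop = FALSE]
  need_len <- max(abs(as.integer(names(la$bp_freqs)))) + th$min_anchor + 2L
  pickable <- sites[sites$kind == "donor" &
                    (sites$intron_end - sites$intron_start) >= need_len, , drop = FALSE]
  lariat_out <- NULL
  if (nrow(pickable)) {
    s1 <- pickable[1, ]
    iseq <- intron_sequence(genome, s1$chrom, s1$strand,
                            s1$intron_start, s1$intron_end)
    iref <- intron_ref(paste0(s1$gene_id, "_intron"), iseq,
                       min_anchor = th$min_anchor)
    rs <- simulate_lariat_reads(iseq, la$bp_freqs, n_clones = la$n_clones,
                                a2t_rate = la$a2t_rate,
                                error_rate = la$error_rate,
                                min_anchor = th$min_anchor,
                                seed = seeds$lariat,
                                intron_id = iref$intron_id, strain = "mutant")
    write_fasta(stats::setNames(rs$reads$seq, rs$reads$read_id),
                file.path(out, "lariat_reads.fa"))
    calls <- call_branchpoints(rs, iref, min_anchor = th$min_anchor,
                               max_mismatch = th$max_mismatch)
    write_tsv(calls, file.path(out, "bp_calls.tsv"))
    bpt <- aggregate_bp(calls, iref, strain = "mutant")
    write_tsv(bpt$table, file.path(out, "bp_usage.tsv"))
    lariat_out <- list(intron_id = iref$intron_id, n_called = bpt$n_called,
                       n_ambiguous = bpt$n_ambiguous,
                       n_unalignable = bpt$n_unalignable)
  }

  files <- list.files(out, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "lariatuss",
    config = unclass(config),
    seeds = seeds,
    warnings = list(short_window_sites = sum(site_windows(sites, models, th$window)$short_window),
                    untestable_events = sum(!psi$testable),
                    untestable_sites = sum(!uss$testable),
                    lariat = lariat_out),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out, f))),
           bytes = file.size(file.path(out, f)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Sense-strand sequence of an intron
#' @param genome Genome ([Biostrings::DNAStringSet] or named character).
#' @param chrom,strand Chromosome and strand.
#' @param intron_start,intron_end 0-based half-open intron interval.
#' @return Character string, 5' to 3' on the transcribed strand.
#' @export
intron_sequence <- function(genome, chrom, strand, intron_start, intron_end) {
  seqc <- get_chrom(genome, chrom)
  s <- substr(seqc, intron_start + 1L, intron_end)
  if (strand == "-") rc_string(s) else s
}
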