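# End-to-end orchestration: reads -> filtered metagene alignments ->
# novel-exon discovery -> augmented metagene + realignment -> exon-level
# isoform models + quantification -> genome projection -> junction
# catalogue, breakpoint correction and junction-level models -> coding
# impact.

#' Pipeline parameters
#'
#' All stage thresholds in one place, at their published defaults: q-score
#' >= 9, >= 50 percent of the read aligned, inserts >= 9 nt within 6 nt of
#' a junction, candidate exons >= 6 nt from existing exons with >= 5 reads
#' per library in >= 2 individuals or tissues, transcripts >= 24 reads in
#' >= 2 libraries (high confidence >= 100), splice sites flagged at >= 10
#' reads, breakpoint snapping within 15 nt.
#'
#' @param min_qscore,min_fraction read filters.
#' @param min_insert,insert_window insert mining.
#' @param min_dist,min_reads_per_lib,min_groups novel-exon filters.
#' @param min_cov exon coverage fraction for chain membership.
#' @param min_reads,min_libraries,high_conf_reads transcript filters.
#' @param flank,min_intron,max_shift,min_site_reads junction stage.
#' @param scores,min_read_len built-in aligner settings.
#' @param realign `"all"` (remap every read to the augmented metagene, as
#'   the assay's analysis does) or `"carriers"` (realign only reads with a
#'   mined junction insertion and lift the rest — faster, at the cost of
#'   missing novel-exon copies whose insertion was not mined).
#' @return named list.
#' @export
pipeline_params <- function(min_qscore = 9, min_fraction = 0.5,
                            min_insert = 9L, insert_window = 6L,
                            min_dist = 6L, min_reads_per_lib = 5L,
                            min_groups = 2L, min_cov = 0.5,
                            min_reads = 24, min_libraries = 2,
                            high_conf_reads = 100,
                            flank = 8L, min_intron = 30L, max_shift = 15L,
                            min_site_reads = 10,
                            scores = align_scores(), min_read_len = 200L,
                            realign = c("all", "carriers")) {
  realign <- match.arg(realign)
  as.list(environment())
}

#' Run the full isoform-annotation pipeline
#'
#' @param reads data.frame of reads (read_id, seq, qscore, library_id), as
#'   from [read_fastq()] or [simulate_reads()].
#' @param annotation list with `metagene` and `catalogue`, as from
#'   [load_annotation()].
#' @param libraries optional library metadata (library_id, individual,
#'   tissue, run) for novel-exon breadth counting.
#' @param params see [pipeline_params()].
#' @param alignments optional precomputed metagene-space
#'   `spliced_alignments` (skips the built-in aligner).
#' @return a list of class `isoamp_run` with every stage's result; see the
#'   vignette for a walk-through.
#' @export
run_pipeline <- function(reads, annotation, libraries = NULL,
                         params = pipeline_params(), alignments = NULL) {
  mg <- annotation$metagene
  catalogue <- annotation$catalogue

  if (is.null(alignments))
    alignments <- align_reads(reads, mg, params$scores, params$min_read_len)
  filt <- filter_reads(alignments, target_id = mg$gene_id,
                       min_qscore = params$min_qscore,
                       min_fraction = params$min_fraction)
  alns <- filt$alignments

  # novel exon discovery on the annotated-only metagene
  events <- mine_inserts(alns, mg, params$min_insert, params$insert_window)
  cands <- candidate_novel_exons(events, mg, libraries)
  cands <- filter_candidate_exons(cands, params$min_dist,
                                  params$min_reads_per_lib, params$min_groups)
  accepted <- cands[cands$status == "accepted", , drop = FALSE]

  # augment and bring all alignments into the new coordinate system;
  # reads that showed a junction insert are realigned, the rest lifted
  if (nrow(accepted) > 0L) {
    mg2 <- insert_novel_exons(mg, accepted)
    if (identical(params$realign, "carriers")) {
      # realign reads showing a sizeable insertion anywhere near a
      # junction (wide window); lift everything else
      wide <- mine_inserts(alns, mg, params$min_insert,
                           window = 5L * params$insert_window)
      carriers <- unique(c(events$read_id, wide$read_id))
      is_carrier <- alns$read_id %in% carriers
      lifted <- lift_alignments(alns[!is_carrier, , drop = FALSE], mg, mg2)
      realn <- if (any(is_carrier)) {
        rr <- reads[reads$read_id %in% alns$read_id[is_carrier], , drop = FALSE]
        align_reads(rr, mg2, params$scores, params$min_read_len)
      } else NULL
      alns2 <- rbind(lifted, realn)
      class(alns2) <- class(alns)
    } else {
      rr <- reads[reads$read_id %in% alns$read_id, , drop = FALSE]
      alns2 <- align_reads(rr, mg2, params$scores, params$min_read_len)
    }
  } else {
    mg2 <- mg
    alns2 <- alns
  }

  # exon-level models
  paths <- exon_paths(alns2, mg2, params$min_cov)
  models <- cluster_paths(paths)
  models <- name_models(models, catalogue, mg$gene_id)
  sets <- filter_transcripts(models, params$min_reads, params$min_libraries,
                             params$high_conf_reads)

  # quantification on the filtered set
  quant <- NULL
  if (nrow(sets$filtered) > 0L) {
    raw <- assign_reads(paths, sets$filtered)
    quant <- list(raw = raw)
    if (ncol(raw$values) >= 2L && all(colSums(raw$values) > 0)) {
      tmm <- tmm_normalise(raw)
      quant$tmm <- tmm
      quant$log10 <- log_transform(tmm$matrix)
    }
  }

  # splice-site-level analysis in genome space
  galns <- project_to_genome(alns2, mg2)
  jcat <- extract_perfect_junctions(galns, mg2$genome, catalogue,
                                    params$flank, params$min_intron)
  jchains <- correct_breakpoints(galns, jcat, params$max_shift,
                                 params$min_intron)
  jmodels <- junction_chain_transcripts(jchains, params$min_reads,
                                        params$min_site_reads,
                                        exon_models = sets$filtered, mg = mg2,
                                        max_small_diff = params$max_shift)

  structure(list(metagene = mg, metagene_augmented = mg2,
                 catalogue = catalogue,
                 alignments = alns2, filter_qc = filt$qc,
                 insert_events = events, candidate_exons = cands,
                 accepted_exons = accepted,
                 paths = paths, models = sets$all,
                 filtered = sets$filtered,
                 high_confidence = sets$high_confidence,
                 quant = quant,
                 junction_catalogue = jcat, junction_chains = jchains,
                 junction_models = jmodels,
                 params = params),
            class = "isoamp_run")
}

#' @export
print.isoamp_run <- function(x, ...) {
  cat("isoamp_run:\n")
  cat("  reads retained:      ", sum(x$filter_qc$retained), "/",
      nrow(x$filter_qc), "\n")
  cat("  novel exons accepted:", nrow(x$accepted_exons), "\n")
  cat("  exon-level models:   ", nrow(x$models), "(",
      nrow(x$filtered), "filtered,", nrow(x$high_confidence),
      "high confidence )\n")
  cat("  junction models:     ", nrow(x$junction_models$models), "\n")
  invisible(x)
}
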