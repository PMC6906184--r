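# Exon-level isoform annotation: read exon chains from CIGARs, clustering
# of chains into a unique maximal isoform set ("longest possible
# variants"), abundance filters, deterministic naming and export.

CHAIN_SEP <- "|"

chain_key <- function(ids) paste(ids, collapse = CHAIN_SEP)
chain_ids <- function(key) strsplit(key, CHAIN_SEP, fixed = TRUE)[[1]]

# is `small` a contiguous infix of `big` (both chain keys)?
chain_is_infix <- function(small, big) {
  grepl(paste0(CHAIN_SEP, small, CHAIN_SEP), paste0(CHAIN_SEP, big, CHAIN_SEP),
        fixed = TRUE)
}

#' Extract per-read exon chains from metagene alignments
#'
#' An exon is part of a read's chain iff the alignment's matched blocks
#' cover at least `min_cov` of the exon; target gaps spanning whole exons
#' therefore encode skipping. Reads covering the first and last metagene
#' exon are flagged `complete_ends`. Alignments covering no exon above
#' threshold are dropped and counted in attribute `n_rejected`.
#'
#' @param alns `spliced_alignments` in metagene space (post-filtering).
#' @param mg the `metagene` aligned against.
#' @param min_cov minimum covered fraction of an exon (default 0.5).
#' @return data.frame of class `exon_paths`: read_id, chain, complete_ends,
#'   library_id.
#' @export
exon_paths <- function(alns, mg, min_cov = 0.5) {
  ex <- mg$exons
  n <- nrow(alns)
  empty <- structure(
    data.frame(read_id = character(), chain = character(),
               complete_ends = logical(), library_id = character(),
               stringsAsFactors = FALSE),
    class = c("exon_paths", "data.frame"), n_rejected = 0L)
  if (n == 0L) return(empty)
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alns$cigar, pos = alns$pos + 1L, ops = c("M", "=", "X"))
  flat <- unlist(rng, use.names = FALSE)
  readidx <- rep(seq_len(n), lengths(rng))
  exr <- IRanges::IRanges(ex$offset + 1L, ex$offset + ex$length)
  hits <- IRanges::findOverlaps(flat, exr)
  ovw <- IRanges::width(IRanges::pintersect(
    flat[S4Vectors::queryHits(hits)], exr[S4Vectors::subjectHits(hits)]))
  cov <- matrix(0L, nrow = n, ncol = nrow(ex))
  ij <- cbind(readidx[S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits))
  for (k in seq_len(nrow(ij))) cov[ij[k, 1L], ij[k, 2L]] <- cov[ij[k, 1L], ij[k, 2L]] + ovw[k]
  pres <- sweep(cov, 2L, pmax(1L, ex$length), "/") >= min_cov
  chains <- apply(pres, 1L, function(p) chain_key(ex$exon_id[p]))
  nonzero <- rowSums(pres) > 0L
  out <- data.frame(read_id = alns$read_id[nonzero],
                    chain = chains[nonzero],
                    complete_ends = pres[nonzero, 1L] & pres[nonzero, ncol(pres)],
                    library_id = alns$library_id[nonzero],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("exon_paths", "data.frame")
  attr(out, "n_rejected") <- sum(!nonzero)
  out
}

#' Cluster exon chains into the unique maximal isoform set
#'
#' Identical chains collapse to one model. Only chains observed with
#' complete ends found a model ("longest possible variants"); an incomplete
#' chain that matches a model exactly, or is a contiguous truncated
#' sub-chain of exactly one model, adds its read support to that model.
#' Incomplete chains compatible with several models are kept aside as
#' ambiguous (they are down-weighted at quantification); chains compatible
#' with none are counted as unassigned.
#'
#' @param paths an `exon_paths` data.frame.
#' @return data.frame of class `transcript_models` with columns `chain`,
#'   `n_exons`, `support_total` and a per-library support matrix in
#'   attribute `support`; ambiguous and unassigned paths are kept in
#'   attributes `ambiguous` and `unassigned`.
#' @export
cluster_paths <- function(paths) {
  libs <- sort(unique(ifelse(is.na(paths$library_id), "library1", paths$library_id)))
  paths$library_id[is.na(paths$library_id)] <- "library1"
  complete <- paths[paths$complete_ends, , drop = FALSE]
  incomplete <- paths[!paths$complete_ends, , drop = FALSE]
  model_chains <- sort(unique(complete$chain))
  supp <- matrix(0, nrow = length(model_chains), ncol = length(libs),
                 dimnames = list(model_chains, libs))
  tab <- table(complete$chain, complete$library_id)
  supp[rownames(tab), colnames(tab)] <- supp[rownames(tab), colnames(tab)] + tab
  amb <- unas <- list()
  if (nrow(incomplete) > 0L) {
    for (ck in unique(incomplete$chain)) {
      d <- incomplete[incomplete$chain == ck, , drop = FALSE]
      if (ck %in% model_chains) {
        t2 <- table(d$library_id)
        supp[ck, names(t2)] <- supp[ck, names(t2)] + t2
        next
      }
      compat <- model_chains[vapply(model_chains, function(mk)
        chain_is_infix(ck, mk), logical(1))]
      if (length(compat) == 1L) {
        t2 <- table(d$library_id)
        supp[compat, names(t2)] <- supp[compat, names(t2)] + t2
      } else if (length(compat) > 1L) {
        amb[[length(amb) + 1L]] <- d
      } else {
        unas[[length(unas) + 1L]] <- d
      }
    }
  }
  models <- data.frame(chain = model_chains,
                       n_exons = lengths(strsplit(model_chains, CHAIN_SEP, fixed = TRUE)),
                       support_total = unname(rowSums(supp)),
                       stringsAsFactors = FALSE)
  rownames(models) <- NULL
  class(models) <- c("transcript_models", "data.frame")
  attr(models, "support") <- supp
  attr(models, "ambiguous") <- if (length(amb)) do.call(rbind, amb) else NULL
  attr(models, "unassigned") <- if (length(unas)) do.call(rbind, unas) else NULL
  models
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x), "models,",
      sum(x$support_total), "supporting reads\n")
  print.data.frame(head(as.data.frame(x)[, setdiff(names(x), "chain_seq")], 8L))
  invisible(x)
}

#' Apply the transcript abundance filters
#'
#' Models supported by a single read are always dropped. The filtered set
#' keeps models with at least `min_reads` reads in total across at least
#' `min_libraries` libraries; the high-confidence set additionally requires
#' `high_conf_reads` reads in total.
#'
#' @param models `transcript_models` from [cluster_paths()].
#' @param min_reads minimum total raw read support.
#' @param min_libraries minimum number of libraries with support.
#' @param high_conf_reads total-read threshold of the high-confidence set.
#' @return list with `all` (models annotated with a `confidence` column),
#'   `filtered` and `high_confidence` subsets.
#' @export
filter_transcripts <- function(models, min_reads = 24, min_libraries = 2,
                               high_conf_reads = 100) {
  supp <- attr(models, "support")
  nlib <- rowSums(supp[models$chain, , drop = FALSE] > 0)
  total <- models$support_total
  in_filtered <- total > 1 & total >= min_reads & nlib >= min_libraries
  in_high <- in_filtered & total >= high_conf_reads
  models$n_libraries <- unname(nlib)
  models$confidence <- ifelse(in_high, "high_confidence",
                              ifelse(in_filtered, "filtered", "dropped"))
  keepattr <- function(m, sel) {
    out <- m[sel, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(m)
    attr(out, "support") <- supp[out$chain, , drop = FALSE]
    attr(out, "ambiguous") <- attr(m, "ambiguous")
    attr(out, "unassigned") <- attr(m, "unassigned")
    out
  }
  list(all = keepattr(models, rep(TRUE, nrow(models))),
       filtered = keepattr(models, in_filtered),
       high_confidence = keepattr(models, in_high))
}

#' Name transcript models
#'
#' A model is `annotated` iff its chain equals an annotation transcript
#' chain exactly (it then keeps the annotation id); novel models are named
#' `"<gene> n<k>"` with `k` assigned by descending total support, ties
#' broken by lexicographic chain order, so naming is deterministic.
#'
#' @param models `transcript_models`.
#' @param catalogue an `annotation_catalogue`.
#' @param gene_id gene identifier used in novel names.
#' @return `models` with `transcript_id` and `status` columns.
#' @export
name_models <- function(models, catalogue, gene_id) {
  ann_keys <- vapply(catalogue$transcripts, chain_key, character(1))
  m <- match(models$chain, ann_keys)
  models$status <- ifelse(is.na(m), "novel", "annotated")
  models$transcript_id <- names(ann_keys)[m]
  novel <- which(is.na(m))
  if (length(novel)) {
    ord <- novel[order(-models$support_total[novel], models$chain[novel])]
    models$transcript_id[ord] <- paste0(gene_id, " n", seq_along(ord))
  }
  models
}

# exon table (metagene exon rows, transcription order) for one chain
chain_exon_table <- function(chain, mg) {
  ids <- chain_ids(chain)
  mg$exons[match(ids, mg$exons$exon_id), , drop = FALSE]
}

# spliced sequence of a chain from the metagene
chain_sequence <- function(chain, mg) {
  ext <- chain_exon_table(chain, mg)
  paste(substring(mg$seq, ext$offset + 1L, ext$offset + ext$length),
        collapse = "")
}

#' Export transcript models as GTF, BED12, FASTA and a support matrix
#'
#' Genomic coordinates are reconstructed through the metagene exon table.
#'
#' @param models named `transcript_models` (see [name_models()]).
#' @param mg the `metagene`.
#' @param prefix output path prefix; writes `<prefix>.gtf`, `<prefix>.bed`,
#'   `<prefix>.fa`, `<prefix>.support.tsv`.
#' @return invisibly, the written paths.
#' @export
export_models <- function(models, mg, prefix) {
  stopifnot(!is.null(models$transcript_id))
  grl <- lapply(seq_len(nrow(models)), function(i) {
    ext <- chain_exon_table(models$chain[i], mg)
    GenomicRanges::GRanges(mg$chrom,
                           IRanges::IRanges(sort(ext$start) + 1L, sort(ext$end)),
                           strand = mg$strand)
  })
  names(grl) <- models$transcript_id
  grl <- GenomicRanges::GRangesList(grl)
  # GTF
  gtf <- unlist(grl)
  gtf$type <- "exon"
  gtf$gene_id <- mg$gene_id
  gtf$transcript_id <- rep(models$transcript_id, lengths(grl))
  rtracklayer::export(gtf, paste0(prefix, ".gtf"), format = "gtf")
  # BED12 (blocked)
  bed <- rtracklayer::asBED(grl)
  rtracklayer::export(bed, paste0(prefix, ".bed"), format = "bed")
  # FASTA of spliced sequences
  seqs <- Biostrings::DNAStringSet(vapply(models$chain, chain_sequence,
                                          character(1), mg = mg))
  names(seqs) <- models$transcript_id
  Biostrings::writeXStringSet(seqs, paste0(prefix, ".fa"))
  # raw support matrix
  supp <- attr(models, "support")
  tab <- data.frame(transcript_id = models$transcript_id,
                    supp[models$chain, , drop = FALSE],
                    check.names = FALSE)
  write.table(tab, paste0(prefix, ".support.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, c(".gtf", ".bed", ".fa", ".support.tsv")))
}
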