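# Locus annotation -> metagene (exon concatenation) with bidirectional
# genome/metagene coordinate maps. All internal coordinates are 0-based
# half-open; GTF I/O converts to/from 1-based inclusive.

#' Load a single-gene annotation and build its metagene
#'
#' Parses a GTF/GFF3 annotation restricted to one gene, takes the union of
#' its distinct annotated exon intervals (identical intervals are merged;
#' overlapping-but-different intervals are kept as separate exon records
#' with a warning), orders them in transcription direction and concatenates
#' their sequences into a metagene. Minus-strand genes are reverse
#' complemented exon-wise so the metagene always reads in transcription
#' orientation.
#'
#' @param gtf_path path to a GTF/GFF3 file (GENCODE dialect: `gene_id` and
#'   `transcript_id` attributes on exon features).
#' @param gene_id gene identifier to extract.
#' @param genome a named `DNAStringSet` (or path to a FASTA file) covering
#'   the gene's chromosome.
#' @return a list with components `metagene` (class `metagene`) and
#'   `catalogue` (class `annotation_catalogue`: per-transcript exon-id
#'   chains plus the annotated splice-site table).
#' @export
load_annotation <- function(gtf_path, gene_id, genome) {
  gr <- rtracklayer::import(gtf_path)
  genome <- load_genome(genome)
  gr <- gr[!is.na(gr$gene_id) & gr$gene_id == gene_id & gr$type == "exon"]
  if (length(gr) == 0L) stop("gene not found: ", gene_id)
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(BiocGenerics::strand(gr))[1]
  if (!chrom %in% names(genome)) stop("missing FASTA contig: ", chrom)

  # distinct exon intervals, 0-based half-open
  ex <- unique(data.frame(start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr)))
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  if (nrow(ex) > 1L) {
    ov <- ex$start[-1L] < ex$end[-nrow(ex)]
    if (any(ov))
      warning("gene ", gene_id, ": ", sum(ov),
              " pair(s) of overlapping annotated exons kept as distinct records")
  }
  ex$exon_id <- paste0("E", seq_len(nrow(ex)))
  ex$origin <- "annotated"

  mg <- new_metagene(gene_id, chrom, strand, ex, genome)

  # per-transcript exon chains, in transcription order
  key <- paste(ex$start, ex$end)
  idmap <- setNames(ex$exon_id, key)
  txdf <- data.frame(tx = gr$transcript_id,
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
  chains <- lapply(split(txdf, txdf$tx), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    ids <- unname(idmap[paste(d$start, d$end)])
    if (strand == "-") rev(ids) else ids
  })
  catalogue <- structure(
    list(transcripts = chains,
         splice_sites = annotated_splice_sites(chains, mg)),
    class = "annotation_catalogue")
  list(metagene = mg, catalogue = catalogue)
}

load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(names(genome))) names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# Construct a metagene object from a 0-based exon table. Exons must be
# non-overlapping for concatenation; overlapping records are allowed in the
# table (they concatenate in genomic order as distinct units).
new_metagene <- function(gene_id, chrom, strand, exons, genome) {
  stopifnot(all(exons$start < exons$end))
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  exons$length <- exons$end - exons$start
  exons$offset <- cumsum(c(0L, head(exons$length, -1L)))
  chromseq <- genome[[chrom]]
  pieces <- Biostrings::DNAStringSet(chromseq,
                                     start = exons$start + 1L, end = exons$end)
  if (strand == "-") pieces <- Biostrings::reverseComplement(pieces)
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons[, c("exon_id", "start", "end", "origin",
                                   "length", "offset")],
                 seq = as.character(unlist(pieces)),
                 genome = genome),
            class = "metagene")
}

#' @export
print.metagene <- function(x, ...) {
  cat("metagene of", x$gene_id, " (", x$chrom, x$strand, ")\n")
  cat(" ", nrow(x$exons), "exons,", nchar(x$seq), "nt;",
      sum(x$exons$origin == "novel"), "novel\n")
  invisible(x)
}

# annotated donor/acceptor positions implied by the transcript chains.
# Donor = first intronic base after the upstream exon; acceptor = last
# intronic base before the downstream exon (transcribed-strand convention,
# stored as 0-based genomic positions).
annotated_splice_sites <- function(chains, mg) {
  ex <- mg$exons
  rows <- list()
  for (chain in chains) {
    idx <- match(chain, ex$exon_id)
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      up <- ex[idx[k], ]; dn <- ex[idx[k + 1L], ]
      if (mg$strand == "+") {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = c(up$end, dn$start - 1L), side = c("donor", "acceptor"))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = c(up$start - 1L, dn$end), side = c("donor", "acceptor"))
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pos = integer(), side = character()))
  unique(do.call(rbind, rows))
}

#' Map genomic positions into metagene coordinates
#'
#' @param pos vector of 0-based genomic positions.
#' @param mg a `metagene`.
#' @return integer vector of 0-based metagene offsets; `NA` for intronic or
#'   out-of-locus positions. Inverse of [metagene_to_genome()] on exonic
#'   positions.
#' @export
genome_to_metagene <- function(pos, mg) {
  ex <- mg$exons
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(pos) & pos >= ex$start[i] & pos < ex$end[i] & is.na(out)
    if (!any(hit)) next
    out[hit] <- if (mg$strand == "+") ex$offset[i] + (pos[hit] - ex$start[i])
                else ex$offset[i] + (ex$end[i] - 1L - pos[hit])
  }
  out
}

#' Map metagene offsets back to genomic positions
#'
#' @param mpos vector of 0-based metagene offsets.
#' @param mg a `metagene`.
#' @return integer vector of 0-based genomic positions (`NA` if out of range).
#' @export
metagene_to_genome <- function(mpos, mg) {
  ex <- mg$exons
  out <- rep(NA_integer_, length(mpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(mpos) & mpos >= ex$offset[i] &
      mpos < ex$offset[i] + ex$length[i] & is.na(out)
    if (!any(hit)) next
    out[hit] <- if (mg$strand == "+") ex$start[i] + (mpos[hit] - ex$offset[i])
                else ex$end[i] - 1L - (mpos[hit] - ex$offset[i])
  }
  out
}

#' Splice accepted novel exons into a metagene
#'
#' Novel exons must lie strictly inside introns of the current metagene;
#' offsets and the concatenated sequence are recomputed, existing exon ids
#' are preserved and novel exons are inserted in transcription order.
#'
#' @param mg a `metagene`.
#' @param exons data.frame of accepted novel exons with 0-based `start`,
#'   `end` columns (e.g. the output of [filter_candidate_exons()]), or an
#'   empty/NULL list for the identity.
#' @return a new `metagene`.
#' @export
insert_novel_exons <- function(mg, exons) {
  if (is.null(exons) || nrow(exons) == 0L) return(mg)
  ex <- mg$exons
  for (k in seq_len(nrow(exons))) {
    s <- exons$start[k]; e <- exons$end[k]
    if (any(s < ex$end & e > ex$start))
      stop("novel exon ", s, "-", e, " overlaps an existing exon")
  }
  novel <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  novel <- novel[order(novel$start), , drop = FALSE]
  novel$exon_id <- if (!is.null(exons$exon_id)) {
    exons$exon_id[order(exons$start)]
  } else paste0("N", seq_len(nrow(novel)))
  novel$origin <- "novel"
  all_ex <- rbind(ex[, c("start", "end", "exon_id", "origin")],
                  novel[, c("start", "end", "exon_id", "origin")])
  new_metagene(mg$gene_id, mg$chrom, mg$strand, all_ex, mg$genome)
}

# 0-based intron table (between consecutive metagene exons, genomic coords).
metagene_introns <- function(mg) {
  ex <- mg$exons[order(mg$exons$start), , drop = FALSE]
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(), end = integer(),
                      up = character(), dn = character()))
  d <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L],
                  up = ex$exon_id[-nrow(ex)], dn = ex$exon_id[-1L])
  if (mg$strand == "-") { # transcription order: swap up/down labels
    d <- data.frame(start = d$start, end = d$end, up = d$dn, dn = d$up)
  }
  d
}

#' Write the metagene FASTA and exon table
#'
#' @param mg a `metagene`.
#' @param prefix output path prefix; writes `<prefix>.fa` and
#'   `<prefix>.exons.tsv` (exon_id, chrom, start, end, strand, origin,
#'   metagene_offset).
#' @return invisibly, the two file paths.
#' @export
write_metagene <- function(mg, prefix) {
  fa <- paste0(prefix, ".fa")
  seq <- Biostrings::DNAStringSet(mg$seq)
  names(seq) <- mg$gene_id
  Biostrings::writeXStringSet(seq, fa)
  tsv <- paste0(prefix, ".exons.tsv")
  tab <- data.frame(exon_id = mg$exons$exon_id, chrom = mg$chrom,
                    start = mg$exons$start, end = mg$exons$end,
                    strand = mg$strand, origin = mg$exons$origin,
                    metagene_offset = mg$exons$offset)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}
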