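# Built-in reference spliced aligner (banded two-piece-gap Gotoh, see
# src/spliced_align.cpp) plus coordinate transforms between metagene
# versions and from metagene to genome space. The built-in aligner targets
# fixture-scale loci; production data may come from any spliced aligner via
# read_alignments().

#' Alignment scoring parameters
#'
#' Defaults favour whole-exon target gaps over forcing noisy sequence
#' through an absent exon: short target gaps (sequencing deletions) are
#' affine `gap_open_del`/`gap_ext_del`, long gaps (exon skips, CIGAR `N`)
#' use a high open but near-free extension.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open_read,gap_ext_read affine cost of read insertions.
#' @param gap_open_del,gap_ext_del affine cost of short target deletions.
#' @param gap_open_skip,gap_ext_skip cost of long target gaps (skips).
#' @param band_slack half-width slack of the alignment band; must exceed
#'   the largest expected read insertion (novel exon length).
#' @return a named list of scores.
#' @export
align_scores <- function(match = 2, mismatch = -4,
                         gap_open_read = 6, gap_ext_read = 3,
                         gap_open_del = 6, gap_ext_del = 3,
                         gap_open_skip = 18, gap_ext_skip = 0.2,
                         band_slack = 150L) {
  list(match = match, mismatch = mismatch,
       gap_open_read = gap_open_read, gap_ext_read = gap_ext_read,
       gap_open_del = gap_open_del, gap_ext_del = gap_ext_del,
       gap_open_skip = gap_open_skip, gap_ext_skip = gap_ext_skip,
       band_slack = as.integer(band_slack))
}

#' Align one read to a metagene
#'
#' Optimal semi-global alignment under the configured scores: the read is
#' aligned end to end, target overhangs are free, and target deletions are
#' permitted at any position so exon skipping appears as target gaps.
#' Deterministic given the scores.
#'
#' @param read a character sequence, or a one-row data.frame with `read_id`,
#'   `seq` and optionally `qscore`, `library_id`.
#' @param mg a `metagene`.
#' @param scores see [align_scores()].
#' @param min_read_len reads shorter than this are rejected with an error.
#' @return a one-row `spliced_alignments` data.frame.
#' @export
align_read <- function(read, mg, scores = align_scores(), min_read_len = 200L) {
  if (is.character(read))
    read <- data.frame(read_id = "read1", seq = read, stringsAsFactors = FALSE)
  align_reads(read, mg, scores, min_read_len, on_short = "error")
}

# Normalize target-gap placement. A D/N run bounded by M can slide one
# step left (right) whenever the target base leaving the gap equals the
# base entering it, so the alignment and its score are unchanged; gap
# placement inside such repeats is an arbitrary DP tie-break. Within the
# valid slide range the gap is snapped so its endpoints coincide with
# exon boundaries where possible (a slid whole-exon skip otherwise leaves
# a sequence-equivalent but boundary-straddling placement); ties and
# boundary-free gaps resolve leftmost.
normalize_gaps <- function(cigar, pos, target, boundaries = integer(0)) {
  w <- cigar_walk_v(cigar, pos)
  nops <- length(w$op)
  op <- w$op; len <- w$len
  changed <- FALSE
  for (k in seq_len(nops)) {
    if (k == 1L || k == nops) next
    if (!(op[k] %in% c("D", "N")) || !(op[k - 1L] %in% c("M", "=", "X")) ||
        !(op[k + 1L] %in% c("M", "=", "X"))) next
    wts <- pos + cumsum(len * (op %in% c("M", "D", "N", "=", "X")))
    s <- wts[k] - len[k]; e <- wts[k]   # 0-based half-open gap on target
    # valid slide range: d in [-L, R]
    L <- 0L
    while (L < len[k - 1L] && s - L > 0L &&
           substr(target, s - L, s - L) == substr(target, e - L, e - L))
      L <- L + 1L
    R <- 0L
    while (R < len[k + 1L] && e + R + 1L <= nchar(target) &&
           substr(target, s + R + 1L, s + R + 1L) ==
             substr(target, e + R + 1L, e + R + 1L))
      R <- R + 1L
    if (L == 0L && R == 0L) next
    cand <- (-L):R
    hits <- vapply(cand, function(d)
      sum((s + d) %in% boundaries, (e + d) %in% boundaries), numeric(1))
    best <- cand[order(-hits, abs(cand), cand)][1L]
    if (best == 0L) next
    len[k - 1L] <- len[k - 1L] + best
    len[k + 1L] <- len[k + 1L] - best
    changed <- TRUE
  }
  if (!changed) return(cigar)
  ops_to_cigar(op, len)
}

#' Align a set of reads to a metagene
#'
#' @param reads data.frame with `read_id`, `seq` and optionally `qscore`,
#'   `library_id` (see [read_fastq()]).
#' @param mg a `metagene`.
#' @param scores see [align_scores()].
#' @param min_read_len minimum read length.
#' @param on_short `"skip"` (drop short reads, count them in attribute
#'   `n_too_short`) or `"error"`.
#' @return a `spliced_alignments` data.frame in metagene space.
#' @export
align_reads <- function(reads, mg, scores = align_scores(),
                        min_read_len = 200L, on_short = "skip") {
  lens <- nchar(reads$seq)
  short <- lens < min_read_len
  if (any(short) && on_short == "error")
    stop("read shorter than minimum length (", min_read_len, " nt)")
  reads <- reads[!short, , drop = FALSE]
  if (nrow(reads) == 0L) {
    out <- new_alignments(
      data.frame(read_id = character(), target_id = character(),
                 pos = integer(), strand = character(), cigar = character(),
                 seq = character(), stringsAsFactors = FALSE), "metagene")
    attr(out, "n_too_short") <- sum(short)
    return(out)
  }
  target <- mg$seq
  n <- nrow(reads)
  pos <- integer(n); cig <- character(n); sc <- numeric(n)
  for (i in seq_len(n)) {
    a <- .spliced_align_cpp(reads$seq[i], target,
                            scores$match, scores$mismatch,
                            scores$gap_open_read, scores$gap_ext_read,
                            scores$gap_open_del, scores$gap_ext_del,
                            scores$gap_open_skip, scores$gap_ext_skip,
                            scores$band_slack)
    pos[i] <- a$pos
    cig[i] <- normalize_gaps(a$cigar, a$pos, target, mg$exons$offset)
    sc[i] <- a$score
  }
  df <- data.frame(read_id = reads$read_id, target_id = mg$gene_id,
                   pos = pos, strand = "+", cigar = cig, seq = reads$seq,
                   qscore = if (is.null(reads$qscore)) NA_real_ else reads$qscore,
                   library_id = if (is.null(reads$library_id)) NA_character_
                                else reads$library_id,
                   score = sc, stringsAsFactors = FALSE)
  out <- new_alignments(df, "metagene")
  attr(out, "n_too_short") <- sum(short)
  out
}

# Lift alignments from one metagene to an augmented version of it (same
# exons plus inserted novel exons). Target-consuming ops are remapped
# through the piecewise offset shift; an 'N' gap of the inserted length is
# introduced wherever a novel exon now sits between two old exons. Reads
# that actually contain a novel exon should be realigned instead.
lift_alignments <- function(alns, mg_old, mg_new) {
  if (nrow(alns) == 0L) return(alns)
  old_ex <- mg_old$exons
  idx_new <- match(old_ex$exon_id, mg_new$exons$exon_id)
  if (anyNA(idx_new)) stop("augmented metagene must preserve all exon ids")
  new_off <- mg_new$exons$offset[idx_new]
  # per old exon: offset shift and the gap inserted after it
  shift <- new_off - old_ex$offset
  gap_after <- c(new_off[-1L] - (new_off[-nrow(old_ex)] + old_ex$length[-nrow(old_ex)]),
                 0L)
  bnd <- old_ex$offset + old_ex$length  # old-exon end offsets
  pos <- integer(nrow(alns)); cig <- character(nrow(alns))
  for (r in seq_len(nrow(alns))) {
    w <- cigar_walk_v(alns$cigar[r], alns$pos[r])
    nops <- length(w$op)
    p <- alns$pos[r]
    tgt <- w$op %in% c("M", "=", "X", "D", "N")
    last_target <- if (any(tgt)) max(which(tgt)) else 0L
    op_out <- vector("list", nops); len_out <- vector("list", nops)
    cur <- p
    for (k in seq_len(nops)) {
      op <- w$op[k]; L <- w$len[k]
      if (!tgt[k]) { op_out[[k]] <- op; len_out[[k]] <- L; next }
      ops_k <- character(0); len_k <- integer(0)
      while (L > 0L) {
        exi <- findInterval(cur, old_ex$offset)
        take <- min(L, bnd[exi] - cur)
        ops_k <- c(ops_k, op); len_k <- c(len_k, take)
        cur <- cur + take; L <- L - take
        if (cur == bnd[exi] && gap_after[exi] > 0L &&
            (L > 0L || k < last_target)) {
          ops_k <- c(ops_k, "N"); len_k <- c(len_k, gap_after[exi])
        }
      }
      op_out[[k]] <- ops_k; len_out[[k]] <- len_k
    }
    pos[r] <- p + shift[findInterval(p, old_ex$offset)]
    cig[r] <- ops_to_cigar(unlist(op_out), unlist(len_out))
  }
  out <- alns
  out$pos <- pos; out$cigar <- cig
  out$target_id <- mg_new$gene_id
  new_alignments(as.data.frame(out), unique(alns$space))
}

#' Project metagene alignments into genome space
#'
#' Rewrites each metagene-space alignment as a genomic spliced alignment:
#' aligned segments are mapped through the exon table and introns appear as
#' `N` gaps. For minus-strand genes the genomic record is reported on the
#' plus strand (ops reversed, sequence reverse-complemented, SAM flag 16
#' semantics via `strand = "-"`).
#'
#' @param alns `spliced_alignments` in metagene space.
#' @param mg the `metagene` they are aligned to.
#' @return a `spliced_alignments` data.frame in genome space.
#' @export
project_to_genome <- function(alns, mg) {
  if (nrow(alns) == 0L) {
    out <- alns; out$space <- character(0); return(out)
  }
  ex <- mg$exons  # transcription order
  bnd <- ex$offset + ex$length
  # intron length after exon i in transcription order
  gap_after <- integer(nrow(ex))
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      gap_after[i] <- if (mg$strand == "+") ex$start[i + 1L] - ex$end[i]
                      else ex$start[i] - ex$end[i + 1L]
    }
  }
  pos <- integer(nrow(alns)); cig <- character(nrow(alns))
  seqs <- character(nrow(alns)); strand <- character(nrow(alns))
  for (r in seq_len(nrow(alns))) {
    w <- cigar_walk_v(alns$cigar[r], alns$pos[r])
    nops <- length(w$op)
    p <- alns$pos[r]
    tgt <- w$op %in% c("M", "=", "X", "D", "N")
    last_target <- if (any(tgt)) max(which(tgt)) else 0L
    op_l <- vector("list", nops); len_l <- vector("list", nops)
    cur <- p
    for (k in seq_len(nops)) {
      op <- w$op[k]; L <- w$len[k]
      if (!tgt[k]) { op_l[[k]] <- op; len_l[[k]] <- L; next }
      ops_k <- character(0); len_k <- integer(0)
      while (L > 0L) {
        exi <- findInterval(cur, ex$offset)
        take <- min(L, bnd[exi] - cur)
        ops_k <- c(ops_k, op); len_k <- c(len_k, take)
        cur <- cur + take; L <- L - take
        if (cur == bnd[exi] && exi < nrow(ex) && gap_after[exi] > 0L &&
            (L > 0L || k < last_target)) {
          ops_k <- c(ops_k, "N"); len_k <- c(len_k, gap_after[exi])
        }
      }
      op_l[[k]] <- ops_k; len_l[[k]] <- len_k
    }
    op_out <- unlist(op_l); len_out <- unlist(len_l)
    gstart_tx <- metagene_to_genome(p, mg)  # genomic pos of first aligned base
    if (mg$strand == "+") {
      pos[r] <- gstart_tx
      cig[r] <- ops_to_cigar(op_out, len_out)
      seqs[r] <- alns$seq[r]
      strand[r] <- "+"
    } else {
      # reverse to genome-forward orientation
      keep <- len_out > 0L
      cig[r] <- ops_to_cigar(rev(op_out[keep]), rev(len_out[keep]))
      tw <- sum(len_out[op_out %in% c("M", "=", "X", "D", "N")])
      pos[r] <- gstart_tx - tw + 1L
      seqs[r] <- if (is.na(alns$seq[r])) NA_character_ else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(alns$seq[r])))
      strand[r] <- "-"
    }
  }
  df <- data.frame(read_id = alns$read_id, target_id = mg$chrom,
                   pos = pos, strand = strand, cigar = cig, seq = seqs,
                   qscore = alns$qscore, library_id = alns$library_id,
                   score = alns$score, stringsAsFactors = FALSE)
  new_alignments(df, "genome")
}
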