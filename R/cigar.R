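# CIGAR arithmetic shared across modules. Parsing/expansion is delegated to
# GenomicAlignments; the helpers here add the alignment-walking views the
# pipeline needs (per-op read/target extents, block decomposition).

#' Split CIGAR strings into operation/length pairs
#'
#' @param cigar character vector of CIGAR strings.
#' @return a list (one element per input) of data.frames with columns
#'   `op` and `len`.
#' @keywords internal
cigar_ops <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  Map(function(o, l) data.frame(op = o, len = l, stringsAsFactors = FALSE),
      ops, lens)
}

# Per-op walk of one alignment: for every CIGAR op, its half-open read
# interval [rs, re) and target interval [ts, te) relative to `pos` (0-based
# target start). S/H consume read only/nothing per SAM. The list variant
# avoids data.frame overhead on hot paths.
cigar_walk_v <- function(cigar, pos = 0L) {
  op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  re <- cumsum(len * (op %in% c("M", "I", "S", "=", "X")))
  te <- pos + cumsum(len * (op %in% c("M", "D", "N", "=", "X")))
  list(op = op, len = len,
       rs = c(0L, re[-length(re)]), re = re,
       ts = c(pos, te[-length(te)]), te = te)
}

cigar_walk <- function(cigar, pos = 0L) {
  as.data.frame(cigar_walk_v(cigar, pos), stringsAsFactors = FALSE)
}

# Aligned blocks (maximal runs of target+read-consuming ops, split at D/N/I):
# list of half-open (read_start, read_end, target_start, target_end) rows.
cigar_blocks <- function(cigar, pos = 0L) {
  w <- cigar_walk(cigar, pos)
  w <- w[w$op %in% c("M", "=", "X"), , drop = FALSE]
  if (nrow(w) == 0L)
    return(data.frame(read_start = integer(), read_end = integer(),
                      target_start = integer(), target_end = integer()))
  # merge ops that are contiguous in both read and target
  keep_new <- c(TRUE, !(w$rs[-1L] == w$re[-nrow(w)] & w$ts[-1L] == w$te[-nrow(w)]))
  grp <- cumsum(keep_new)
  data.frame(
    read_start = tapply(w$rs, grp, min)[unique(grp)],
    read_end = tapply(w$re, grp, max)[unique(grp)],
    target_start = tapply(w$ts, grp, min)[unique(grp)],
    target_end = tapply(w$te, grp, max)[unique(grp)],
    row.names = NULL)
}

# Reference (target) width consumed by each CIGAR.
cigar_target_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar, N.regions.removed = FALSE)
}

# Read width consumed by each CIGAR (including soft clips).
cigar_read_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

# Collapse an op/len data.frame back to a CIGAR string, merging adjacent
# same-op runs and dropping zero-length ops.
ops_to_cigar <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0L) return("")
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  len <- as.integer(tapply(len, grp, sum))
  op <- op[!duplicated(grp)]
  paste0(paste0(len, op), collapse = "")
}
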