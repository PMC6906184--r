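# Ingest spliced alignments from standard formats into one internal record
# (a data.frame of class "spliced_alignments"), write SAM, and apply the
# read-retention filters (q-score, uniqueness, fraction of read aligned).

new_alignments <- function(df, space = "metagene") {
  need <- c("read_id", "target_id", "pos", "strand", "cigar")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$seq)) df$seq <- rep(NA_character_, nrow(df))
  if (is.null(df$qscore)) df$qscore <- rep(NA_real_, nrow(df))
  if (is.null(df$library_id)) df$library_id <- rep(NA_character_, nrow(df))
  if (is.null(df$score)) df$score <- rep(NA_real_, nrow(df))
  df$space <- rep(space, nrow(df))
  optab <- GenomicAlignments::cigarOpTable(df$cigar)
  aligned <- optab[, "M", drop = TRUE] + optab[, "=", drop = TRUE] +
    optab[, "X", drop = TRUE]
  rlen <- cigar_read_width(df$cigar) + optab[, "H", drop = TRUE]
  df$frac_aligned <- ifelse(rlen > 0, aligned / rlen, 0)
  rownames(df) <- NULL
  class(df) <- c("spliced_alignments", "data.frame")
  df
}

#' @export
print.spliced_alignments <- function(x, ...) {
  cat("spliced_alignments:", nrow(x), "records in",
      paste(unique(x$space), collapse = "/"), "space\n")
  print.data.frame(head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read spliced alignments from SAM/BAM, PSL or MAF
#'
#' Converts each record losslessly into the internal spliced-alignment
#' record; PSL block lists and MAF column alignments are converted to
#' equivalent CIGARs (target gaps of at least `min_intron` nt become `N`
#' ops). Malformed records are skipped with a warning; the number skipped
#' is attached as attribute `n_skipped`.
#'
#' @param path input file.
#' @param format one of `"sam"`, `"bam"`, `"psl"`, `"maf"` (default guessed
#'   from the file extension).
#' @param space label for the target coordinate space
#'   (`"metagene"`, `"genome"` or `"transcriptome"`).
#' @param min_intron minimum target-gap length written as `N` when
#'   converting PSL/MAF gaps.
#' @return a `spliced_alignments` data.frame.
#' @export
read_alignments <- function(path, format = tools::file_ext(path),
                            space = "metagene", min_intron = 30L) {
  format <- tolower(format)
  switch(format,
         sam = read_sam(path, space),
         bam = read_bam(path, space),
         psl = read_psl(path, space, min_intron),
         maf = read_maf(path, space, min_intron),
         stop("unknown alignment format: ", format))
}

read_sam <- function(path, space) {
  bam <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE), add = TRUE)
  Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                   indexDestination = FALSE)
  read_bam(bam, space)
}

read_bam <- function(path, space) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual", "mapq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos) & !is.na(b$cigar)
  df <- data.frame(
    read_id = b$qname[keep],
    target_id = as.character(b$rname[keep]),
    pos = b$pos[keep] - 1L,
    strand = ifelse(bitwAnd(b$flag[keep], 16L) > 0L, "-", "+"),
    cigar = b$cigar[keep],
    seq = as.character(b$seq[keep]),
    stringsAsFactors = FALSE)
  df$seq[df$seq == ""] <- NA_character_
  qual <- as.character(b$qual[keep])
  df$qscore <- ifelse(qual == "" | qual == "*", NA_real_,
                      vapply(qual, mean_phred, numeric(1)))
  new_alignments(df, space)
}

mean_phred <- function(qual) {
  mean(as.integer(charToRaw(qual)) - 33L)
}

# BLAT PSL, 21 columns, optionally with the 5-line header.
read_psl <- function(path, space, min_intron = 30L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(psLayout|match|\\s*-+\\s*$|\\s*$)", lines)]
  rows <- list(); skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 21L) { skipped <- skipped + 1L; next }
    ok <- tryCatch({
      strand <- substr(f[9], 1, 1)
      qsize <- as.integer(f[11])
      bs <- as.integer(strsplit(f[19], ",")[[1]])
      qs <- as.integer(strsplit(f[20], ",")[[1]])
      ts <- as.integer(strsplit(f[21], ",")[[1]])
      if (strand == "-") { # PSL '-' qStarts are in reversed-query coords
        qs <- rev(qsize - (qs + bs))
        bs <- rev(bs); ts <- rev(ts)
      }
      op <- character(0); len <- integer(0)
      if (qs[1] > 0L) { op <- "S"; len <- qs[1] }
      for (k in seq_along(bs)) {
        if (k > 1L) {
          qgap <- qs[k] - (qs[k - 1L] + bs[k - 1L])
          tgap <- ts[k] - (ts[k - 1L] + bs[k - 1L])
          if (qgap > 0L) { op <- c(op, "I"); len <- c(len, qgap) }
          if (tgap > 0L) {
            op <- c(op, if (tgap >= min_intron) "N" else "D")
            len <- c(len, tgap)
          }
        }
        op <- c(op, "M"); len <- c(len, bs[k])
      }
      tailclip <- qsize - (qs[length(qs)] + bs[length(bs)])
      if (tailclip > 0L) { op <- c(op, "S"); len <- c(len, tailclip) }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = f[10], target_id = f[14], pos = ts[1], strand = strand,
        cigar = ops_to_cigar(op, len), stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) skipped <- skipped + 1L
  }
  if (skipped > 0L) warning("psl: skipped ", skipped, " malformed record(s)")
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), target_id = character(),
               pos = integer(), strand = character(), cigar = character())
  out <- new_alignments(df, space)
  attr(out, "n_skipped") <- skipped
  out
}

# MAF as written by LAST: 'a' line then an 's' line for the target followed
# by an 's' line for the query.
read_maf <- function(path, space, min_intron = 30L) {
  lines <- readLines(path)
  rows <- list(); skipped <- 0L
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "a")) { i <- i + 1L; next }
    sidx <- i + which(startsWith(lines[(i + 1):min(i + 6L, length(lines))], "s"))
    if (length(sidx) < 2L) { skipped <- skipped + 1L; i <- i + 1L; next }
    tf <- strsplit(lines[sidx[1]], "\\s+")[[1]]
    qf <- strsplit(lines[sidx[2]], "\\s+")[[1]]
    ok <- tryCatch({
      talign <- strsplit(toupper(tf[7]), "")[[1]]
      qalign <- strsplit(toupper(qf[7]), "")[[1]]
      stopifnot(length(talign) == length(qalign))
      op <- ifelse(talign == "-", "I", ifelse(qalign == "-", "D", "M"))
      r <- rle(op)
      op2 <- r$values; len2 <- r$lengths
      op2[op2 == "D" & len2 >= min_intron] <- "N"
      qstart <- as.integer(qf[3]); qsize <- as.integer(qf[6])
      qalen <- as.integer(qf[4])
      if (qstart > 0L) { op2 <- c("S", op2); len2 <- c(qstart, len2) }
      tailclip <- qsize - qstart - qalen
      if (tailclip > 0L) { op2 <- c(op2, "S"); len2 <- c(len2, tailclip) }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = qf[2], target_id = tf[2], pos = as.integer(tf[3]),
        strand = qf[5], cigar = ops_to_cigar(op2, len2),
        seq = gsub("-", "", qf[7]), stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) skipped <- skipped + 1L
    i <- sidx[2] + 1L
  }
  if (skipped > 0L) warning("maf: skipped ", skipped, " malformed record(s)")
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), target_id = character(),
               pos = integer(), strand = character(), cigar = character(),
               seq = character())
  out <- new_alignments(df, space)
  attr(out, "n_skipped") <- skipped
  out
}

#' Write spliced alignments as SAM
#'
#' Leading/trailing insertion ops are converted to soft clips for SAM
#' validity; internal CIGAR ops and positions are preserved bit-exactly.
#'
#' @param alns a `spliced_alignments` data.frame.
#' @param path output SAM path.
#' @param target_lengths named integer vector of target sequence lengths
#'   for the `@SQ` header lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(alns, path, target_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (tn in names(target_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tn, as.integer(target_lengths[[tn]])), con)
  if (nrow(alns) > 0L) {
    cig <- vapply(alns$cigar, sam_safe_cigar, character(1), USE.NAMES = FALSE)
    flag <- ifelse(alns$strand == "-", 16L, 0L)
    seq <- ifelse(is.na(alns$seq), "*", alns$seq)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     alns$read_id, flag, alns$target_id, alns$pos + 1L,
                     60L, cig, seq)
    writeLines(lines, con)
  }
  invisible(path)
}

sam_safe_cigar <- function(cigar) {
  df <- cigar_ops(cigar)[[1]]
  n <- nrow(df)
  if (n > 0L && df$op[1] == "I") df$op[1] <- "S"
  if (n > 1L && df$op[n] == "I") df$op[n] <- "S"
  ops_to_cigar(df$op, df$len)
}

#' Read long reads from FASTQ
#'
#' @param path FASTQ file.
#' @param metadata optional data.frame mapping `read_id` to `library_id`
#'   (and any other per-library columns).
#' @return data.frame with `read_id`, `seq`, `qscore` (mean Phred) and
#'   `library_id`.
#' @export
read_fastq <- function(path, metadata = NULL) {
  # Biostrings warns that FASTQ metadata columns are dropped; none are used
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  q <- methods::as(Biostrings::quality(x), "IntegerList")
  df <- data.frame(read_id = sub("\\s.*$", "", names(x)),
                   seq = as.character(x),
                   qscore = vapply(q, mean, numeric(1)),
                   library_id = NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    m <- match(df$read_id, metadata$read_id)
    df$library_id <- metadata$library_id[m]
  }
  rownames(df) <- NULL
  df
}

#' Apply the read-retention filters
#'
#' A read is retained iff (a) its mean q-score is at least `min_qscore`
#' (when a q-score is available), (b) its best alignment is to the target
#' gene and no equally good alignment exists to another target, and (c) at
#' least `min_fraction` of its length is aligned. Filtering is idempotent
#' and never errors on content.
#'
#' @param alns `spliced_alignments` possibly containing several alignments
#'   per read (including alignments to decoy targets).
#' @param target_id the gene/metagene target reads must map uniquely to.
#' @param min_qscore minimum mean read q-score (inclusive).
#' @param min_fraction minimum fraction of the read aligned (inclusive).
#' @param qscores optional named vector of per-read mean q-scores
#'   overriding `alns$qscore`.
#' @return list with `alignments` (best retained alignment per read) and
#'   `qc` (per-read table: read_id, qscore, fraction_aligned, retained,
#'   reason).
#' @export
filter_reads <- function(alns, target_id, min_qscore = 9, min_fraction = 0.5,
                         qscores = NULL) {
  if (nrow(alns) == 0L)
    return(list(alignments = alns,
                qc = data.frame(read_id = character(), qscore = numeric(),
                                fraction_aligned = numeric(),
                                retained = logical(), reason = character())))
  score <- alns$score
  # external alignments without a score: rank by aligned fraction
  score[is.na(score)] <- alns$frac_aligned[is.na(score)] * 1e6
  qs <- alns$qscore
  if (!is.null(qscores)) qs <- unname(qscores[alns$read_id])
  ord <- order(alns$read_id, -score, alns$target_id)
  best <- ord[!duplicated(alns$read_id[ord])]       # best row per read
  reads <- alns$read_id[best]
  maxs <- score[best][match(alns$read_id, reads)]
  tie_other <- tapply(score == maxs & alns$target_id != target_id,
                      alns$read_id, any)[reads]
  q <- as.numeric(tapply(qs, alns$read_id,
                         function(x) x[!is.na(x)][1])[reads])
  frac <- alns$frac_aligned[best]
  reason <- rep("", length(best))
  reason[!is.na(q) & q < min_qscore] <- "qscore"
  nonuni <- reason == "" & (alns$target_id[best] != target_id | tie_other)
  reason[nonuni] <- "non-unique"
  reason[reason == "" & frac < min_fraction] <- "fraction"
  qc <- data.frame(read_id = reads, qscore = q, fraction_aligned = frac,
                   retained = reason == "", reason = reason,
                   stringsAsFactors = FALSE)
  qc <- qc[order(qc$read_id), , drop = FALSE]
  rownames(qc) <- NULL
  out <- alns[sort(best[reason == ""]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(alns)
  list(alignments = out, qc = qc)
}

#' Write the read-filter QC table
#'
#' @param qc the `qc` component of [filter_reads()].
#' @param path output TSV.
#' @export
write_filter_qc <- function(qc, path) {
  write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
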