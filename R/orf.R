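# Predicted coding impact: reading-frame maintenance relative to the
# reference CDS, premature-stop detection, and in-frame indel events in
# reference protein coordinates with optional protein-region labels.

#' Splice the CDS of a transcript model
#'
#' Concatenates the model's exonic sequence in transcription order between
#' the annotated CDS anchors. Anchors are the genomic CDS span, 0-based
#' half-open and strand-agnostic: `cds_start` is the lowest genomic CDS
#' position, `cds_end` one past the highest; the span must begin and end
#' inside the chain's terminal exons (in transcription order).
#'
#' @param chain a chain key (see [name_models()]) or vector of exon ids.
#' @param mg the `metagene`.
#' @param anchors list with `cds_start` and `cds_end` genomic positions.
#' @return list with `seq` (character CDS) and `incomplete_ends` (TRUE when
#'   the model lacks the anchor exons, in which case `seq` is `NA`).
#' @export
splice_cds <- function(chain, mg, anchors) {
  ids <- if (length(chain) == 1L && grepl(CHAIN_SEP, chain, fixed = TRUE))
    chain_ids(chain) else as.character(chain)
  ext <- mg$exons[match(ids, mg$exons$exon_id), , drop = FALSE]
  if (anyNA(ext$start)) stop("unknown exon id in chain")
  first <- ext[1L, ]; last <- ext[nrow(ext), ]
  if (mg$strand == "+") {
    has_start <- anchors$cds_start >= first$start & anchors$cds_start < first$end
    has_end <- anchors$cds_end > last$start & anchors$cds_end <= last$end
  } else {
    has_start <- anchors$cds_end > first$start & anchors$cds_end <= first$end
    has_end <- anchors$cds_start >= last$start & anchors$cds_start < last$end
  }
  if (!has_start || !has_end)
    return(list(seq = NA_character_, incomplete_ends = TRUE))
  # transcription-oriented clip amounts within the anchor exons
  off1 <- if (mg$strand == "+") anchors$cds_start - first$start
          else first$end - anchors$cds_end
  keep_last <- if (mg$strand == "+") anchors$cds_end - last$start
               else last$end - anchors$cds_start
  pieces <- substring(mg$seq, ext$offset + 1L, ext$offset + ext$length)
  nlast <- length(pieces)
  if (nlast == 1L) {
    pieces[1L] <- substr(pieces[1L], off1 + 1L, keep_last)
  } else {
    pieces[1L] <- substr(pieces[1L], off1 + 1L, nchar(pieces[1L]))
    pieces[nlast] <- substr(pieces[nlast], 1L, keep_last)
  }
  list(seq = paste(pieces, collapse = ""), incomplete_ends = FALSE)
}

#' Classify reading-frame impact of a CDS against the reference
#'
#' The frame is maintained iff the length difference to the reference CDS
#' is a multiple of 3; a premature stop is any in-frame stop codon strictly
#' before the final 3 codons. Classification is `putative_coding` iff the
#' frame is maintained and there is no premature stop. Insertion/deletion
#' events are derived by global alignment against the reference CDS and
#' reported in 1-based reference protein coordinates.
#'
#' @param cds character CDS of the model (starting at the ATG).
#' @param reference_cds character reference CDS.
#' @param transcript_id optional id carried through to the output.
#' @return list of class `coding_assessment`: transcript_id,
#'   frame_maintained, premature_stop, classification, events (data.frame:
#'   kind, nt_length, aa_start, aa_end, aa_length, region_label).
#' @export
classify_frame <- function(cds, reference_cds, transcript_id = NA_character_) {
  stopifnot(is.character(cds), is.character(reference_cds))
  dlen <- nchar(cds) - nchar(reference_cds)
  frame_maintained <- (dlen %% 3L) == 0L
  premature_stop <- has_premature_stop(cds)
  events <- indel_events(cds, reference_cds)
  structure(list(transcript_id = transcript_id,
                 frame_maintained = frame_maintained,
                 premature_stop = premature_stop,
                 classification = if (frame_maintained && !premature_stop)
                   "putative_coding" else "putative_noncoding",
                 events = events),
            class = "coding_assessment")
}

#' @export
print.coding_assessment <- function(x, ...) {
  cat("coding_assessment", if (!is.na(x$transcript_id)) x$transcript_id else "",
      ":", x$classification,
      "( frame", if (x$frame_maintained) "maintained," else "shifted,",
      if (x$premature_stop) "premature stop )" else "no premature stop )", "\n")
  if (nrow(x$events)) print.data.frame(x$events)
  invisible(x)
}

has_premature_stop <- function(cds) {
  ncod <- nchar(cds) %/% 3L
  if (ncod < 4L) return(FALSE)
  codons <- substring(cds, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
  any(codons[seq_len(ncod - 3L)] %in% c("TAA", "TAG", "TGA"))
}

# indel events from a global alignment of the model CDS against the
# reference CDS, in reference protein coordinates. aa_start/aa_end are the
# 1-based reference codons touched by the event; for insertions the event
# is anchored at the codon containing the insertion point.
indel_events <- function(cds, reference_cds) {
  empty <- data.frame(kind = character(), nt_length = integer(),
                      aa_start = integer(), aa_end = integer(),
                      aa_length = numeric(), region_label = character(),
                      stringsAsFactors = FALSE)
  if (identical(cds, reference_cds)) return(empty)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(reference_cds), Biostrings::DNAString(cds),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -4, baseOnly = FALSE),
    gapOpening = 10, gapExtension = 0.5)
  rows <- list()
  # gaps in the pattern (reference) = insertions in the model CDS,
  # reported at the reference position where they occur
  ins <- Biostrings::indel(Biostrings::pattern(pa))[[1]]
  del <- Biostrings::indel(Biostrings::subject(pa))[[1]]
  # indel() ranges are in the coordinates of the *other* sequence's
  # ungapped space: ranges of pattern gaps are positions in the subject,
  # and vice versa; anchor both onto the reference via the alignment.
  if (length(del)) {
    for (k in seq_along(del)) {
      s <- IRanges::start(del)[k]; wdt <- IRanges::width(del)[k]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "deletion", nt_length = wdt,
        aa_start = (s - 1L) %/% 3L + 1L,
        aa_end = (s + wdt - 2L) %/% 3L + 1L,
        aa_length = wdt / 3, region_label = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(ins)) {
    for (k in seq_along(ins)) {
      s <- IRanges::start(ins)[k]; wdt <- IRanges::width(ins)[k]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "insertion", nt_length = wdt,
        aa_start = (s - 1L) %/% 3L + 1L,
        aa_end = (s - 1L) %/% 3L + 1L,
        aa_length = wdt / 3, region_label = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$aa_start), , drop = FALSE]
}

#' Load a protein-region table
#'
#' Tab-separated file with columns `region`, `aa_start`, `aa_end` (1-based
#' inclusive protein coordinates). Overlapping regions are an error.
#'
#' @param path TSV path.
#' @return data.frame of regions.
#' @export
load_region_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "aa_start", "aa_end") %in% names(tab)))
  tab <- tab[order(tab$aa_start), , drop = FALSE]
  if (nrow(tab) > 1L &&
      any(tab$aa_start[-1L] <= tab$aa_end[-nrow(tab)]))
    stop("overlapping regions in region table")
  tab
}

#' Label indel events with protein regions
#'
#' Each event is labelled with every region it overlaps (semicolon
#' separated); events outside all regions are labelled "unannotated".
#'
#' @param events the `events` data.frame of a `coding_assessment`.
#' @param region_table data.frame from [load_region_table()] (or NULL /
#'   empty for no regions).
#' @return `events` with `region_label` filled in.
#' @export
annotate_regions <- function(events, region_table) {
  if (nrow(events) == 0L) return(events)
  if (is.null(region_table) || nrow(region_table) == 0L) {
    events$region_label <- "unannotated"
    return(events)
  }
  events$region_label <- vapply(seq_len(nrow(events)), function(i) {
    hit <- region_table$region[region_table$aa_start <= events$aa_end[i] &
                                 region_table$aa_end >= events$aa_start[i]]
    if (length(hit) == 0L) "unannotated" else paste(hit, collapse = ";")
  }, character(1))
  events
}

#' Assess the coding impact of a set of transcript models
#'
#' Splices each model's CDS, classifies frame maintenance and premature
#' stops against the reference chain's CDS, and labels events with protein
#' regions. Models missing an anchor exon are marked `incomplete_ends` and
#' not classified.
#'
#' @param models named `transcript_models`.
#' @param mg the `metagene`.
#' @param anchors CDS anchors (see [splice_cds()]).
#' @param reference_chain chain key of the reference (CDS-defining) model.
#' @param region_table optional protein-region table.
#' @return data.frame: transcript_id, frame_maintained, premature_stop,
#'   classification, n_events, events (list column).
#' @export
assess_coding <- function(models, mg, anchors, reference_chain,
                          region_table = NULL) {
  ref <- splice_cds(reference_chain, mg, anchors)
  stopifnot(!ref$incomplete_ends)
  out <- lapply(seq_len(nrow(models)), function(i) {
    sp <- splice_cds(models$chain[i], mg, anchors)
    id <- if (!is.null(models$transcript_id)) models$transcript_id[i]
          else models$chain[i]
    if (sp$incomplete_ends)
      return(data.frame(transcript_id = id, frame_maintained = NA,
                        premature_stop = NA, classification = "incomplete_ends",
                        n_events = NA_integer_, stringsAsFactors = FALSE,
                        events = I(list(NULL))))
    ca <- classify_frame(sp$seq, ref$seq, id)
    ev <- annotate_regions(ca$events, region_table)
    data.frame(transcript_id = id, frame_maintained = ca$frame_maintained,
               premature_stop = ca$premature_stop,
               classification = ca$classification,
               n_events = nrow(ev), stringsAsFactors = FALSE,
               events = I(list(ev)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
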