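# Novel exon discovery: mine metagene alignments for read insertions at
# exon-exon boundaries, place each insert inside its host intron by local
# alignment, merge overlapping placements and apply the support filters
# (distance to existing exons, per-library read floor, breadth across
# individuals or tissues).

#' Mine alignments for junction insertions
#'
#' One event is reported per read and junction when the read's insertion
#' runs at that junction total at least `min_insert` nt. Noisy long
#' insertions are frequently fragmented by spurious micro-matches, so all
#' insertion runs of at least 3 nt whose target position falls within
#' `window` nt of the same exon-exon boundary are pooled into one event;
#' the event sequence is the read span from the first to the last such
#' run. Insertions interior to an exon are ignored.
#'
#' @param alns `spliced_alignments` in metagene space.
#' @param mg the `metagene`.
#' @param min_insert minimum total insertion length (nt).
#' @param window maximum distance (nt) between the insertion point and an
#'   exon boundary.
#' @return data.frame of insert events: read_id, insert_seq, insert_len,
#'   flank_left_exon, flank_right_exon, junction_metagene_pos, library_id.
#' @export
mine_inserts <- function(alns, mg, min_insert = 9L, window = 6L) {
  empty <- data.frame(read_id = character(), insert_seq = character(),
                      insert_len = integer(), flank_left_exon = character(),
                      flank_right_exon = character(),
                      junction_metagene_pos = integer(),
                      library_id = character(), stringsAsFactors = FALSE)
  if (nrow(alns) == 0L) return(empty)
  boundaries <- mg$exons$offset[-1L]  # internal exon-exon boundaries
  if (length(boundaries) == 0L) return(empty)
  rows <- list()
  min_frag <- 3L   # ignore 1-2 nt insertion runs (point sequencing errors)
  chain_gap <- 10L # micro-matches up to this many target nt do not break a run
  for (r in seq_len(nrow(alns))) {
    w <- cigar_walk_v(alns$cigar[r], alns$pos[r])
    sel <- which(w$op == "I" & w$len >= min_frag)
    if (length(sel) == 0L) next
    i_len <- w$len[sel]; i_rs <- w$rs[sel]; i_re <- w$re[sel]; i_ts <- w$ts[sel]
    grp <- cumsum(c(TRUE, diff(i_ts) > chain_gap))
    for (gi in unique(grp)) {
      g <- grp == gi
      total <- sum(i_len[g])
      if (total < min_insert) next
      d <- abs(outer(i_ts[g], boundaries, "-"))
      bi <- arrayInd(which.min(d), dim(d))[1L, 2L]
      if (min(d[, bi]) > window) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = alns$read_id[r],
        insert_seq = if (is.na(alns$seq[r])) NA_character_ else
          substr(alns$seq[r], min(i_rs[g]) + 1L, max(i_re[g])),
        insert_len = total,
        flank_left_exon = mg$exons$exon_id[bi],
        flank_right_exon = mg$exons$exon_id[bi + 1L],
        junction_metagene_pos = boundaries[bi],
        library_id = alns$library_id[r],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Place one insert sequence inside its host intron
#'
#' Locally aligns the insert against the intron between the event's
#' flanking exons (in transcription orientation) and returns the best-hit
#' genomic interval when alignment identity and insert coverage both reach
#' `min_identity`/`min_coverage`; otherwise `NULL`.
#'
#' @param ev one insert event (a one-row data.frame from [mine_inserts()]).
#' @param mg the `metagene` (carries the genome).
#' @param min_identity minimum alignment identity over the aligned region.
#' @param min_coverage minimum fraction of the insert that must align.
#' @return a list `(start, end, identity)` in 0-based genomic coordinates,
#'   or `NULL` for an unplaceable insert.
#' @export
place_insert_on_genome <- function(ev, mg, min_identity = 0.8,
                                   min_coverage = 0.8) {
  if (is.na(ev$insert_seq) || nchar(ev$insert_seq) == 0L) return(NULL)
  ex <- mg$exons
  up <- ex[ex$exon_id == ev$flank_left_exon, ]
  dn <- ex[ex$exon_id == ev$flank_right_exon, ]
  if (mg$strand == "+") {
    istart <- up$end; iend <- dn$start
  } else {
    istart <- dn$end; iend <- up$start
  }
  if (iend - istart < 1L) return(NULL)
  intron <- Biostrings::subseq(mg$genome[[mg$chrom]], istart + 1L, iend)
  if (mg$strand == "-") intron <- Biostrings::reverseComplement(intron)
  pat <- Biostrings::DNAString(ev$insert_seq)
  pa <- Biostrings::pairwiseAlignment(pat, intron, type = "local",
                                      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
                                        match = 2, mismatch = -3, baseOnly = FALSE),
                                      gapOpening = 4, gapExtension = 2)
  if (length(Biostrings::score(pa)) == 0L || Biostrings::score(pa) <= 0) return(NULL)
  salign <- Biostrings::subject(pa)
  qalign <- Biostrings::pattern(pa)
  alen <- Biostrings::nchar(pa)  # alignment length incl gaps
  ident <- Biostrings::nmatch(pa) / alen
  cov <- (Biostrings::end(qalign) - Biostrings::start(qalign) + 1L) / length(pat)
  if (ident < min_identity || cov < min_coverage) return(NULL)
  s_local <- Biostrings::start(salign) - 1L  # 0-based within oriented intron
  e_local <- Biostrings::end(salign)
  if (mg$strand == "+") {
    list(start = istart + s_local, end = istart + e_local, identity = ident)
  } else {
    ilen <- iend - istart
    list(start = istart + (ilen - e_local), end = istart + (ilen - s_local),
         identity = ident)
  }
}

#' Place and merge insert events into candidate novel exons
#'
#' Places every event on the genome, then merges placements whose genomic
#' intervals overlap reciprocally by at least `min_reciprocal`; the merged
#' interval is the support-weighted modal boundary pair. Support is pooled
#' per library. Optionally snaps candidate edges to the nearest canonical
#' splice motifs (intronic `AG` immediately upstream, `GT` immediately
#' downstream, transcribed strand) within `snap_window` nt.
#'
#' @param events data.frame from [mine_inserts()].
#' @param mg the `metagene`.
#' @param libraries optional data.frame with `library_id`, `individual`,
#'   `tissue` (used downstream for breadth counting).
#' @param min_reciprocal reciprocal-overlap fraction for merging.
#' @param snap_to_motif logical; snap edges to AG/GT flanks.
#' @param snap_window maximum snap distance (nt).
#' @param min_identity,min_coverage passed to [place_insert_on_genome()].
#' @return data.frame of candidate novel exons: start, end, n_reads,
#'   support (list column: named per-library counts), n_individuals,
#'   n_tissues, distance_to_nearest_exon, host_up, host_dn, status.
#' @export
candidate_novel_exons <- function(events, mg, libraries = NULL,
                                  min_reciprocal = 0.5,
                                  snap_to_motif = TRUE, snap_window = 6L,
                                  min_identity = 0.8, min_coverage = 0.8) {
  empty <- data.frame(start = integer(), end = integer(), n_reads = integer(),
                      n_individuals = integer(), n_tissues = integer(),
                      distance_to_nearest_exon = integer(),
                      host_up = character(), host_dn = character(),
                      status = character(), stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0L) { empty$support <- list(); return(empty) }
  # batch the local alignments per host intron (same subject for all
  # events at one junction)
  placed <- list()
  key <- paste(events$flank_left_exon, events$flank_right_exon)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  for (kk in unique(key)) {
    idx <- which(key == kk & !is.na(events$insert_seq) &
                   nzchar(events$insert_seq))
    if (length(idx) == 0L) next
    ev1 <- events[idx[1], , drop = FALSE]
    ex <- mg$exons
    up <- ex[ex$exon_id == ev1$flank_left_exon, ]
    dn <- ex[ex$exon_id == ev1$flank_right_exon, ]
    if (mg$strand == "+") { istart <- up$end; iend <- dn$start }
    else { istart <- dn$end; iend <- up$start }
    if (iend - istart < 1L) next
    intron <- Biostrings::subseq(mg$genome[[mg$chrom]], istart + 1L, iend)
    if (mg$strand == "-") intron <- Biostrings::reverseComplement(intron)
    pats <- Biostrings::DNAStringSet(events$insert_seq[idx])
    pa <- Biostrings::pairwiseAlignment(pats, intron, type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = 4, gapExtension = 2)
    ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    qal <- Biostrings::pattern(pa); sal <- Biostrings::subject(pa)
    cov <- (Biostrings::end(qal) - Biostrings::start(qal) + 1L) /
      nchar(events$insert_seq[idx])
    ok <- Biostrings::score(pa) > 0 & ident >= min_identity &
      cov >= min_coverage
    if (!any(ok)) next
    s_local <- Biostrings::start(sal)[ok] - 1L
    e_local <- Biostrings::end(sal)[ok]
    # maximal extension: local alignment stops short when the insert's
    # terminal bases equal the adjacent intron sequence (e.g. an exon
    # ending in GT next to the intron's GT); extend while unaligned
    # insert bases match the genome so boundary votes are not truncated
    ichar <- as.character(intron)
    ilen0 <- nchar(ichar)
    qs0 <- Biostrings::start(qal)[ok]; qe0 <- Biostrings::end(qal)[ok]
    pats_ok <- events$insert_seq[idx][ok]
    for (z in seq_along(s_local)) {
      p <- pats_ok[z]
      while (qe0[z] < nchar(p) && e_local[z] < ilen0 &&
             substr(p, qe0[z] + 1L, qe0[z] + 1L) ==
               substr(ichar, e_local[z] + 1L, e_local[z] + 1L)) {
        qe0[z] <- qe0[z] + 1L; e_local[z] <- e_local[z] + 1L
      }
      while (qs0[z] > 1L && s_local[z] > 0L &&
             substr(p, qs0[z] - 1L, qs0[z] - 1L) ==
               substr(ichar, s_local[z], s_local[z])) {
        qs0[z] <- qs0[z] - 1L; s_local[z] <- s_local[z] - 1L
      }
    }
    if (mg$strand == "+") {
      gs <- istart + s_local; ge <- istart + e_local
    } else {
      ilen <- iend - istart
      gs <- istart + (ilen - e_local); ge <- istart + (ilen - s_local)
    }
    placed[[length(placed) + 1L]] <- data.frame(
      start = gs, end = ge, read_id = events$read_id[idx][ok],
      library_id = events$library_id[idx][ok], stringsAsFactors = FALSE)
  }
  placed <- do.call(rbind, placed)
  if (is.null(placed) || nrow(placed) == 0L) { empty$support <- list(); return(empty) }
  # snap each placement to canonical flanks first, so placements of the
  # same exon with small indel jitter collapse to one boundary pair
  if (snap_to_motif) {
    chromchar <- as.character(mg$genome[[mg$chrom]])
    # snap each distinct raw interval once, then apply to all placements
    ukey <- unique(paste(placed$start, placed$end))
    snapmap <- vapply(ukey, function(k) {
      sv <- as.integer(strsplit(k, " ")[[1]])
      sn <- snap_exon_to_motif(sv[1], sv[2], mg, snap_window, chromchar)
      paste(sn[1], sn[2])
    }, character(1))
    snapped <- strsplit(unname(snapmap[paste(placed$start, placed$end)]), " ")
    placed$start <- as.integer(vapply(snapped, `[`, character(1), 1L))
    placed$end <- as.integer(vapply(snapped, `[`, character(1), 2L))
  }
  # deterministic merge independent of input order: sort, then single-link
  # cluster on reciprocal overlap
  placed <- placed[order(placed$start, placed$end, placed$read_id), , drop = FALSE]
  grp <- integer(nrow(placed)); g <- 0L
  cur_start <- cur_end <- -1L
  for (i in seq_len(nrow(placed))) {
    s <- placed$start[i]; e <- placed$end[i]
    ov <- min(cur_end, e) - max(cur_start, s)
    recip <- g > 0L && ov >= min_reciprocal * (e - s) &&
      ov >= min_reciprocal * (cur_end - cur_start)
    if (!recip) { g <- g + 1L; cur_start <- s; cur_end <- e }
    else { cur_start <- min(cur_start, s); cur_end <- max(cur_end, e) }
    grp[i] <- g
  }
  introns <- metagene_introns(mg)
  ann <- mg$exons
  out <- lapply(split(placed, grp), function(d) {
    # support-weighted modal boundary pair (ties: smaller interval first)
    key <- paste(d$start, d$end)
    tab <- sort(table(key), decreasing = TRUE)
    mode_key <- names(tab)[1]
    sv <- as.integer(strsplit(mode_key, " ")[[1]])
    s <- sv[1]; e <- sv[2]
    host <- introns[introns$start <= s & introns$end >= e, , drop = FALSE]
    # gap to the nearest exon on either side; overlap counts as distance 0
    if (any(ann$start < e & ann$end > s)) {
      dist <- 0L
    } else {
      dist <- suppressWarnings(min(c(s - ann$end[ann$end <= s],
                                     ann$start[ann$start >= e] - e)))
      if (!is.finite(dist)) dist <- 0L
    }
    libs <- table(d$library_id)
    data.frame(start = s, end = e, n_reads = nrow(d),
               n_individuals = NA_integer_, n_tissues = NA_integer_,
               distance_to_nearest_exon = as.integer(dist),
               host_up = if (nrow(host)) host$up[1] else NA_character_,
               host_dn = if (nrow(host)) host$dn[1] else NA_character_,
               status = "candidate", stringsAsFactors = FALSE,
               support = I(list(setNames(as.integer(libs), names(libs)))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(libraries)) {
    out$n_individuals <- vapply(out$support, function(s)
      length(unique(libraries$individual[match(names(s), libraries$library_id)])),
      integer(1))
    out$n_tissues <- vapply(out$support, function(s)
      length(unique(libraries$tissue[match(names(s), libraries$library_id)])),
      integer(1))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# Snap a candidate interval to canonical intronic flanks: acceptor AG ending
# immediately before the exon start and donor GT starting immediately after
# the exon end (transcribed strand), searched within +/- window nt.
# `chromchar` optionally carries the chromosome as a character string.
snap_exon_to_motif <- function(start, end, mg, window = 6L,
                               chromchar = NULL) {
  if (is.null(chromchar)) chromchar <- as.character(mg$genome[[mg$chrom]])
  clen <- nchar(chromchar)
  fix <- function(posn, offs, motif) {
    cand <- (posn - window):(posn + window)
    ok <- cand + offs >= 1L & cand + offs + 1L <= clen
    cand <- cand[ok]
    hit <- cand[vapply(cand, function(p)
      substr(chromchar, p + offs, p + offs + 1L) == motif, logical(1))]
    if (length(hit)) hit[which.min(abs(hit - posn))] else posn
  }
  if (mg$strand == "+") {
    start2 <- fix(start, -1L, "AG")  # AG at [start-1, start] 1-based
    end2 <- fix(end, 1L, "GT")       # GT at [end+1, end+2] 1-based
  } else {
    end2 <- fix(end, 1L, "CT")
    start2 <- fix(start, -1L, "AC")
  }
  if (end2 <= start2) return(c(start, end))  # refuse degenerate snap
  c(start2, end2)
}

#' Filter candidate novel exons
#'
#' A candidate is accepted iff it lies at least `min_dist` nt from every
#' existing exon, was observed in at least `min_groups` individuals or
#' `min_groups` tissues, and every contributing library supports it with at
#' least `min_reads_per_lib` reads. When two accepted candidates still
#' overlap (sub-spans of one exon that survived merging), only the one
#' with the most supporting reads is kept.
#'
#' @param cands data.frame from [candidate_novel_exons()].
#' @param min_dist minimum distance (nt) to the nearest existing exon.
#' @param min_reads_per_lib per-library read floor.
#' @param min_groups minimum number of individuals or tissues.
#' @return `cands` with `status` set to `"accepted"`/`"rejected"`; accepted
#'   rows carry `exon_id`s of the form `N1`, `N2`, ... in genomic order.
#' @export
filter_candidate_exons <- function(cands, min_dist = 6L,
                                   min_reads_per_lib = 5L, min_groups = 2L) {
  if (nrow(cands) == 0L) { cands$exon_id <- character(0); return(cands) }
  ok_dist <- cands$distance_to_nearest_exon >= min_dist
  ok_breadth <- (!is.na(cands$n_individuals) & cands$n_individuals >= min_groups) |
    (!is.na(cands$n_tissues) & cands$n_tissues >= min_groups)
  ok_floor <- vapply(cands$support, function(s)
    length(s) > 0L && all(s >= min_reads_per_lib), logical(1))
  cands$status <- ifelse(ok_dist & ok_breadth & ok_floor, "accepted", "rejected")
  # overlap dedup among accepted: keep the best-supported span
  acc_i <- which(cands$status == "accepted")
  if (length(acc_i) > 1L) {
    acc_i <- acc_i[order(-cands$n_reads[acc_i])]
    kept <- integer(0)
    for (i in acc_i) {
      clash <- any(cands$start[i] < cands$end[kept] &
                     cands$end[i] > cands$start[kept])
      if (clash) cands$status[i] <- "rejected" else kept <- c(kept, i)
    }
  }
  cands <- cands[order(cands$start, cands$end), , drop = FALSE]
  cands$exon_id <- NA_character_
  acc <- cands$status == "accepted"
  cands$exon_id[acc] <- paste0("N", seq_len(sum(acc)))
  rownames(cands) <- NULL
  cands
}

#' Write accepted novel exons as BED6 plus a support table
#'
#' @param cands output of [filter_candidate_exons()].
#' @param mg the `metagene`.
#' @param prefix path prefix; writes `<prefix>.bed` (accepted exons) and
#'   `<prefix>.support.tsv` (all candidates with per-library counts).
#' @export
write_novel_exons <- function(cands, mg, prefix) {
  acc <- cands[cands$status == "accepted", , drop = FALSE]
  bed <- paste0(prefix, ".bed")
  if (nrow(acc) > 0L) {
    gr <- GenomicRanges::GRanges(mg$chrom,
                                 IRanges::IRanges(acc$start + 1L, acc$end),
                                 strand = mg$strand,
                                 name = acc$exon_id,
                                 score = pmin(1000L, acc$n_reads))
    rtracklayer::export(gr, bed, format = "bed")
  } else {
    file.create(bed)
  }
  tsv <- paste0(prefix, ".support.tsv")
  tab <- cands
  tab$support <- vapply(cands$support, function(s)
    paste(sprintf("%s=%d", names(s), s), collapse = ";"), character(1))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed, tsv))
}
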