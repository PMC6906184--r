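# Splice-site-level analysis: catalogue of canonical junctions observed
# with error-free flanks in genome-space alignments, breakpoint correction
# of noisy reads to the closest catalogued site, and junction-chain
# transcript models.
#
# Site convention (0-based, transcribed strand): a donor is the first
# intronic base after the upstream exon, an acceptor the last intronic base
# before the downstream exon.

# Merged gap runs of one alignment. A gap run contains at least one N op;
# immediately adjacent D and I ops are absorbed (a target deletion flush
# against an intron is indistinguishable from a longer intron), and so
# are aligned islands shorter than `min_island` nt between two gap ops:
# such micro-matches inside a gap are alignment noise (the aligner
# preferentially routes junction-adjacent error bases through the gap
# edge because a few chance matches are cheaper than an insertion run),
# and no analysable exon is that small. Returns 0-based half-open genomic
# intervals [gs, ge) per merged run, with `clean`: the run consumes only
# N/D target bases, and the flanking op indices (`p`, `nx`).
gap_runs <- function(w, min_intron = 30L, min_island = 8L) {
  nops <- length(w$op)
  gapop <- w$op %in% c("N", "D", "I")
  island <- which(!gapop & w$op %in% c("M", "=", "X") & w$len < min_island)
  island <- island[island > 1L & island < nops]
  island <- island[vapply(island, function(i)
    gapop[i - 1L] && gapop[i + 1L], logical(1))]
  gapop[island] <- TRUE
  runs <- rle(gapop)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  out <- list()
  for (ri in which(runs$values)) {
    idx <- starts[ri]:ends[ri]
    nidx <- idx[w$op[idx] == "N"]
    if (length(nidx) == 0L) next
    gs <- min(w$ts[idx]); ge <- max(w$te[idx])
    if (ge - gs < min_intron) next
    out[[length(out) + 1L]] <- list(
      gs = gs, ge = ge,
      # inner extremes of the pure-N part: alternative raw breakpoints
      # when absorbed edge indels displace the merged-run edge
      ngs = min(w$ts[nidx]), nge = max(w$te[nidx]),
      clean = all(w$op[idx] %in% c("N", "D")),
      p = starts[ri] - 1L, nx = ends[ri] + 1L)
  }
  out
}

# Shift a gap among its sequence-equivalent placements (moving the gap by
# one is valid when the base entering equals the base leaving, so the
# alignment is unchanged) until the transcribed-strand intron motif is
# canonical; at most `max_shift` steps each way. Gap placement inside
# repeats is otherwise an arbitrary DP tie-break, and only the
# motif-consistent placement is the junction's canonical form.
canonicalize_gap <- function(gs, ge, chromchar, strand, max_shift = 3L) {
  is_canon <- function(s, e) {
    if (strand == "+")
      substr(chromchar, s + 1L, s + 2L) == "GT" &&
        substr(chromchar, e - 1L, e) == "AG"
    else
      substr(chromchar, s + 1L, s + 2L) == "CT" &&
        substr(chromchar, e - 1L, e) == "AC"
  }
  if (is_canon(gs, ge)) return(c(gs, ge))
  s <- gs; e <- ge
  for (k in seq_len(max_shift)) {  # rightward
    if (substr(chromchar, s + 1L, s + 1L) !=
        substr(chromchar, e + 1L, e + 1L)) break
    s <- s + 1L; e <- e + 1L
    if (is_canon(s, e)) return(c(s, e))
  }
  s <- gs; e <- ge
  for (k in seq_len(max_shift)) {  # leftward
    if (s < 1L || substr(chromchar, s, s) != substr(chromchar, e, e)) break
    s <- s - 1L; e <- e - 1L
    if (is_canon(s, e)) return(c(s, e))
  }
  c(gs, ge)
}

# per-alignment perfect-junction assessment: merged gap intervals plus
# whether the gap is error-free (clean N/D-only gap with `flank` exactly
# matching M bases on both sides). Clean gaps are canonicalized among
# sequence-equivalent placements. `chromchar` is the chromosome as a
# plain character string (cheap substr on the hot path).
alignment_gaps <- function(cigar, pos, seq, chromchar, flank = 8L,
                           min_intron = 30L, strand = "+") {
  w <- cigar_walk_v(cigar, pos)
  if (!any(w$op == "N")) return(NULL)
  runs <- gap_runs(w, min_intron)
  if (length(runs) == 0L) return(NULL)
  nops <- length(w$op)
  gs_v <- ge_v <- integer(length(runs)); pf_v <- logical(length(runs))
  for (k in seq_along(runs)) {
    g <- runs[[k]]
    perfect <- FALSE
    if (g$clean && g$p >= 1L && g$nx <= nops && !is.na(seq)) {
      p <- g$p; nx <- g$nx
      if (w$op[p] %in% c("M", "=", "X") && w$op[nx] %in% c("M", "=", "X") &&
          w$len[p] >= flank && w$len[nx] >= flank) {
        perfect <-
          substr(seq, w$re[p] - flank + 1L, w$re[p]) ==
            substr(chromchar, w$te[p] - flank + 1L, w$te[p]) &&
          substr(seq, w$rs[nx] + 1L, w$rs[nx] + flank) ==
            substr(chromchar, w$ts[nx] + 1L, w$ts[nx] + flank)
      }
    }
    gge <- c(g$gs, g$ge)
    if (perfect) gge <- canonicalize_gap(g$gs, g$ge, chromchar, strand)
    gs_v[k] <- gge[1L]; ge_v[k] <- gge[2L]; pf_v[k] <- perfect
  }
  list(gs = gs_v, ge = ge_v, perfect = pf_v)
}

intron_motif <- function(genome, chrom, gs, ge, strand) {
  chromseq <- genome[[chrom]]
  left <- as.character(Biostrings::subseq(chromseq, gs + 1L, gs + 2L))
  right <- as.character(Biostrings::subseq(chromseq, ge - 1L, ge))
  if (strand == "+") paste0(left, "-", right)
  else paste0(as.character(Biostrings::reverseComplement(Biostrings::DNAString(right))),
              "-",
              as.character(Biostrings::reverseComplement(Biostrings::DNAString(left))))
}

# donor/acceptor genomic positions of an intron [gs, ge) on `strand`
intron_sites <- function(gs, ge, strand) {
  if (strand == "+") c(donor = gs, acceptor = ge - 1L)
  else c(donor = ge - 1L, acceptor = gs)
}

#' Build the canonical junction catalogue from genome-space alignments
#'
#' A junction enters the catalogue iff a read maps with zero
#' mismatches/indels for `flank` bases on both sides of the intron gap and
#' the intron bears a canonical motif on the transcribed strand
#' (GT-AG by default; GC-AG/AT-AC via `motifs`).
#'
#' @param alns `spliced_alignments` in genome space (with read sequences).
#' @param genome named `DNAStringSet`.
#' @param catalogue_ann optional `annotation_catalogue` used to label
#'   sites/junctions as annotated or novel.
#' @param flank error-free bases required on each side of the gap.
#' @param min_intron minimum intron length (nt).
#' @param motifs accepted transcribed-strand intron motifs.
#' @param min_support minimum number of perfect reads before a junction
#'   enters the catalogue (screens out junctions created by isolated
#'   sequencing deletions flush against a real intron).
#' @param min_site_sep novel sites within this many nt of a
#'   better-supported site of the same side are collapsed away: breakpoint
#'   resolution below a few nt is not achievable at long-read indel rates,
#'   and a deletion error flush against an intron mimics a 1-2 nt splice
#'   shift. The default (2) keeps sites 3 nt apart distinct, i.e. variants
#'   differing by one codon.
#' @param shift_ratio a novel junction sharing one endpoint with a
#'   junction at least `shift_ratio` times better supported, with the
#'   other endpoint within `max_shift_prune` nt, is treated as an error
#'   echo of that junction and dropped.
#' @param max_shift_prune window (nt) for the `shift_ratio` rule.
#' @return a list of class `junction_catalogue`: `junctions` (data.frame:
#'   intron_start, intron_end, donor, acceptor, strand, motif, support,
#'   status) and `sites` (data.frame: pos, side, support, status).
#' @export
extract_perfect_junctions <- function(alns, genome, catalogue_ann = NULL,
                                      flank = 8L, min_intron = 30L,
                                      motifs = "GT-AG", min_support = 3L,
                                      min_site_sep = 2L, shift_ratio = 20,
                                      max_shift_prune = 15L) {
  chromchar <- lapply(genome, as.character)
  rows <- list()
  for (r in seq_len(nrow(alns))) {
    g <- alignment_gaps(alns$cigar[r], alns$pos[r], alns$seq[r],
                        chromchar[[alns$target_id[r]]], flank, min_intron,
                        strand = alns$strand[r])
    if (is.null(g)) next
    keep <- g$perfect
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gs = g$gs[keep], ge = g$ge[keep], perfect = TRUE,
      strand = alns$strand[r], chrom = alns$target_id[r],
      stringsAsFactors = FALSE)
  }
  empty_j <- data.frame(intron_start = integer(), intron_end = integer(),
                        donor = integer(), acceptor = integer(),
                        strand = character(), motif = character(),
                        support = integer(), status = character())
  if (length(rows) == 0L)
    return(structure(list(junctions = empty_j,
                          sites = data.frame(pos = integer(), side = character(),
                                             support = integer(), status = character())),
                     class = "junction_catalogue"))
  g <- do.call(rbind, rows)
  g$motif <- mapply(intron_motif, gs = g$gs, ge = g$ge, strand = g$strand,
                    MoreArgs = list(genome = genome, chrom = g$chrom[1]))
  g <- g[g$motif %in% motifs, , drop = FALSE]
  if (nrow(g) == 0L)
    return(structure(list(junctions = empty_j,
                          sites = data.frame(pos = integer(), side = character(),
                                             support = integer(), status = character())),
                     class = "junction_catalogue"))
  agg <- stats::aggregate(list(support = rep(1L, nrow(g))),
                          by = list(intron_start = g$gs, intron_end = g$ge,
                                    strand = g$strand, motif = g$motif), FUN = sum)
  agg <- agg[agg$support >= min_support, , drop = FALSE]
  if (nrow(agg) == 0L)
    return(structure(list(junctions = empty_j,
                          sites = data.frame(pos = integer(), side = character(),
                                             support = integer(), status = character())),
                     class = "junction_catalogue"))
  st <- t(mapply(intron_sites, agg$intron_start, agg$intron_end, agg$strand))
  agg$donor <- st[, "donor"]; agg$acceptor <- st[, "acceptor"]
  ann_sites <- if (!is.null(catalogue_ann)) catalogue_ann$splice_sites else
    data.frame(pos = integer(), side = character())
  agg$status <- ifelse(
    agg$donor %in% ann_sites$pos[ann_sites$side == "donor"] &
      agg$acceptor %in% ann_sites$pos[ann_sites$side == "acceptor"],
    "annotated", "novel")
  agg <- prune_junctions(agg, min_site_sep, shift_ratio, max_shift_prune)
  agg <- agg[order(agg$intron_start, agg$intron_end), , drop = FALSE]
  rownames(agg) <- NULL
  sites <- rbind(
    stats::aggregate(list(support = agg$support),
                     by = list(pos = agg$donor), FUN = sum) |>
      transform(side = "donor"),
    stats::aggregate(list(support = agg$support),
                     by = list(pos = agg$acceptor), FUN = sum) |>
      transform(side = "acceptor"))
  sites$status <- ifelse(paste(sites$pos, sites$side) %in%
                           paste(ann_sites$pos, ann_sites$side),
                         "annotated", "novel")
  sites <- sites[order(sites$pos, sites$side), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(junctions = agg[, c("intron_start", "intron_end", "donor",
                                     "acceptor", "strand", "motif",
                                     "support", "status")],
                 sites = sites),
            class = "junction_catalogue")
}

# Catalogue noise control. Two statistical screens against junctions
# manufactured by sequencing deletions flush to real introns (which pass
# the perfect-flank test because the deleted bases are target bases):
#  (a) site resolution: a novel donor/acceptor within `min_site_sep` nt of
#      a better-supported site of the same side is collapsed away;
#  (b) error echo: a novel junction that shares one endpoint with a
#      junction >= `shift_ratio` times better supported, with its other
#      endpoint within `max_shift_prune` nt of that junction's, is dropped.
# Annotated junctions are never pruned. Genuine small splice variants at a
# few percent abundance pass both screens; per-base-rate error echoes do
# not.
prune_junctions <- function(agg, min_site_sep = 2L, shift_ratio = 20,
                            max_shift_prune = 15L) {
  if (nrow(agg) < 2L) return(agg)
  keep_sites <- function(pos, support, protected) {
    o <- order(-support, pos)
    kept <- integer(0); keep <- logical(length(pos))
    for (i in o) {
      if (protected[i] || !any(abs(pos[i] - kept) <= min_site_sep)) {
        keep[i] <- TRUE
        kept <- c(kept, pos[i])
      }
    }
    keep
  }
  dsup <- tapply(agg$support, agg$donor, sum)
  asup <- tapply(agg$support, agg$acceptor, sum)
  ann <- agg$status == "annotated"
  dpos <- as.integer(names(dsup)); apos <- as.integer(names(asup))
  dkeep <- keep_sites(dpos, as.numeric(dsup),
                      dpos %in% agg$donor[ann])
  akeep <- keep_sites(apos, as.numeric(asup),
                      apos %in% agg$acceptor[ann])
  ok <- agg$donor %in% dpos[dkeep] & agg$acceptor %in% apos[akeep]
  agg <- agg[ok | ann, , drop = FALSE]
  # error-echo rule
  drop <- logical(nrow(agg))
  for (i in which(agg$status == "novel")) {
    same_d <- agg$donor == agg$donor[i] &
      abs(agg$acceptor - agg$acceptor[i]) <= max_shift_prune &
      agg$acceptor != agg$acceptor[i]
    same_a <- agg$acceptor == agg$acceptor[i] &
      abs(agg$donor - agg$donor[i]) <= max_shift_prune &
      agg$donor != agg$donor[i]
    rivals <- agg$support[same_d | same_a]
    if (length(rivals) && max(rivals) >= shift_ratio * agg$support[i])
      drop[i] <- TRUE
  }
  agg[!drop, , drop = FALSE]
}

#' @export
print.junction_catalogue <- function(x, ...) {
  cat("junction_catalogue:", nrow(x$junctions), "junctions (",
      sum(x$junctions$status == "novel"), "novel ),",
      nrow(x$sites), "sites\n")
  invisible(x)
}

# snap one breakpoint to the nearest catalogued site of the given side
# within max_shift; ties by higher support, then by the upstream site in
# transcription direction. Returns the raw position if nothing is in range.
snap_site <- function(pos, side, sites, max_shift, strand) {
  r <- snap_site2(pos, sites[sites$side == side, , drop = FALSE],
                  max_shift, strand)
  c(pos = r[[1L]], corrected = r[[2L]])
}

snap_site2 <- function(pos, cand, max_shift, strand) {
  if (nrow(cand) == 0L) return(list(pos, NA))
  d <- abs(cand$pos - pos)
  inr <- which(d <= max_shift)
  if (length(inr) == 0L) return(list(pos, NA))
  dd <- d[inr]; sup <- cand$support[inr]; pp <- cand$pos[inr]
  upstream_rank <- if (strand == "+") pp else -pp
  o <- order(dd, -sup, upstream_rank)
  list(pp[o[1L]], pp[o[1L]] != pos)
}

# snap against several candidate raw positions (merged-run edge first,
# then the inner N edge); the first raw position is the reference for the
# `corrected` flag
snap_site_multi <- function(raws, cand, max_shift, strand) {
  best <- list(raws[1L], NA); bestd <- Inf
  for (p in unique(raws)) {
    s <- snap_site2(p, cand, max_shift, strand)
    if (is.na(s[[2L]])) next
    d <- abs(s[[1L]] - p)
    if (d < bestd) { bestd <- d; best <- list(s[[1L]], s[[1L]] != raws[1L]) }
  }
  best
}

#' Correct junction breakpoints against the catalogue
#'
#' Every read gap's endpoints are snapped to the nearest catalogued
#' donor/acceptor within `max_shift` nt (ties: higher-support site, then
#' the upstream site). Gaps with no catalogued site in range keep their raw
#' breakpoints and are flagged uncorrected. Catalogue-perfect reads are
#' returned unchanged.
#'
#' @param alns `spliced_alignments` in genome space.
#' @param catalogue a `junction_catalogue`.
#' @param max_shift maximum snap distance (nt).
#' @param min_intron minimum target-gap length treated as an intron.
#' @return data.frame of per-read junctions: read_id, library_id, k (index
#'   along the read), intron_start, intron_end, donor, acceptor, corrected,
#'   uncorrected, chain (per-read junction-chain key, repeated on each row).
#' @export
correct_breakpoints <- function(alns, catalogue, max_shift = 15L,
                                min_intron = 30L) {
  sites <- catalogue$sites
  dsites <- sites[sites$side == "donor", , drop = FALSE]
  asites <- sites[sites$side == "acceptor", , drop = FALSE]
  acc <- vector("list", nrow(alns))
  for (r in seq_len(nrow(alns))) {
    w <- cigar_walk_v(alns$cigar[r], alns$pos[r])
    if (!any(w$op == "N")) next
    runs <- gap_runs(w, min_intron)
    strand <- alns$strand[r]
    r_is <- r_ie <- r_d <- r_a <- integer(0)
    r_corr <- r_unc <- logical(0)
    for (g in runs) {
      gs <- g$gs; ge <- g$ge
      if (ge - gs < min_intron) next
      s5 <- intron_sites(gs, ge, strand)
      s5i <- intron_sites(g$ngs, g$nge, strand)
      dsn <- snap_site_multi(c(s5[["donor"]], s5i[["donor"]]),
                             dsites, max_shift, strand)
      asn <- snap_site_multi(c(s5[["acceptor"]], s5i[["acceptor"]]),
                             asites, max_shift, strand)
      if (strand == "+") {
        n_gs <- dsn[[1L]]; n_ge <- asn[[1L]] + 1L
      } else {
        n_gs <- asn[[1L]]; n_ge <- dsn[[1L]] + 1L
      }
      r_is <- c(r_is, n_gs); r_ie <- c(r_ie, n_ge)
      r_d <- c(r_d, dsn[[1L]]); r_a <- c(r_a, asn[[1L]])
      r_corr <- c(r_corr, isTRUE(dsn[[2L]] > 0) || isTRUE(asn[[2L]] > 0))
      r_unc <- c(r_unc, is.na(dsn[[2L]]) || is.na(asn[[2L]]))
    }
    nk <- length(r_is)
    if (nk == 0L) next
    o <- order(r_is)
    chain <- paste(paste0(r_is[o], "-", r_ie[o]), collapse = ";")
    acc[[r]] <- list(read_id = rep(alns$read_id[r], nk),
                     library_id = rep(alns$library_id[r], nk),
                     intron_start = r_is[o], intron_end = r_ie[o],
                     donor = r_d[o], acceptor = r_a[o],
                     corrected = r_corr[o], uncorrected = r_unc[o],
                     k = seq_len(nk), chain = rep(chain, nk))
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0L)
    return(data.frame(read_id = character(), library_id = character(),
                      intron_start = integer(), intron_end = integer(),
                      donor = integer(), acceptor = integer(),
                      corrected = logical(), uncorrected = logical(),
                      k = integer(), chain = character()))
  data.frame(lapply(setNames(names(acc[[1]]), names(acc[[1]])), function(f)
    unlist(lapply(acc, `[[`, f), use.names = FALSE)),
    stringsAsFactors = FALSE)
}

#' Collapse corrected junction chains into junction-level transcripts
#'
#' Identical junction chains collapse to one model; models are filtered at
#' `min_reads` total support. Per-site support is reported with a flag at
#' `min_site_reads`. When exon-level models are supplied, each junction
#' model is compared against them and annotated as identical, a small-scale
#' variant (total boundary difference of at most `max_small_diff` nt with
#' the same junction count), or distinct.
#'
#' @param chains output of [correct_breakpoints()].
#' @param min_reads minimum reads per junction model.
#' @param min_site_reads support threshold for the per-site flag.
#' @param exon_models optional named exon-level `transcript_models`.
#' @param mg `metagene` (required with `exon_models`).
#' @param max_small_diff small-scale variant threshold (nt).
#' @return list of class `junction_models`: `models` (chain, support,
#'   n_junctions, exon_level_match), `site_support` (pos, side, support,
#'   passes_min), `n_input_chains`.
#' @export
junction_chain_transcripts <- function(chains, min_reads = 24,
                                       min_site_reads = 10,
                                       exon_models = NULL, mg = NULL,
                                       max_small_diff = 15L) {
  per_read <- unique(chains[, c("read_id", "chain")])
  tab <- table(per_read$chain)
  first <- chains[!duplicated(chains$chain), , drop = FALSE]
  models <- data.frame(chain = names(tab), support = as.integer(tab),
                       stringsAsFactors = FALSE)
  models$n_junctions <- lengths(strsplit(models$chain, ";", fixed = TRUE))
  models <- models[models$support >= min_reads, , drop = FALSE]
  models <- models[order(-models$support, models$chain), , drop = FALSE]
  rownames(models) <- NULL
  # per-site support over all (corrected) read junctions
  dsup <- stats::aggregate(list(support = rep(1L, nrow(chains))),
                           by = list(pos = chains$donor), FUN = sum)
  dsup$side <- "donor"
  asup <- stats::aggregate(list(support = rep(1L, nrow(chains))),
                           by = list(pos = chains$acceptor), FUN = sum)
  asup$side <- "acceptor"
  site_support <- rbind(dsup, asup)
  site_support$passes_min <- site_support$support >= min_site_reads
  # complementarity with the exon-level models
  models$exon_level_match <- NA_character_
  if (!is.null(exon_models) && nrow(models) > 0L) {
    stopifnot(!is.null(mg))
    echains <- lapply(exon_models$chain, function(ck) {
      ext <- chain_exon_table(ck, mg)
      ext <- ext[order(ext$start), , drop = FALSE]
      if (nrow(ext) < 2L) return(NULL)
      data.frame(gs = ext$end[-nrow(ext)], ge = ext$start[-1L])
    })
    for (i in seq_len(nrow(models))) {
      jv <- do.call(rbind, lapply(strsplit(models$chain[i], ";")[[1]],
                                  function(s) as.integer(strsplit(s, "-")[[1]])))
      best <- Inf
      for (ec in echains) {
        if (is.null(ec) || nrow(ec) != nrow(jv)) next
        diff <- sum(abs(ec$gs - jv[, 1])) + sum(abs(ec$ge - jv[, 2]))
        best <- min(best, diff)
      }
      models$exon_level_match[i] <-
        if (!is.finite(best)) "distinct"
        else if (best == 0) "identical"
        else if (best <= max_small_diff) sprintf("small-scale variant (<=%d nt)", max_small_diff)
        else "distinct"
    }
  }
  structure(list(models = models, site_support = site_support,
                 n_input_chains = length(tab)),
            class = "junction_models")
}

#' Write the junction catalogue as a splice-junction TSV
#'
#' STAR SJ.out.tab-like layout: chrom, intron start (1-based), intron end,
#' strand, motif, support, status.
#'
#' @param catalogue a `junction_catalogue`.
#' @param chrom chromosome name.
#' @param path output TSV.
#' @export
write_junctions <- function(catalogue, chrom, path) {
  j <- catalogue$junctions
  tab <- data.frame(chrom = chrom, intron_start = j$intron_start + 1L,
                    intron_end = j$intron_end, strand = j$strand,
                    motif = j$motif, support = j$support, status = j$status)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
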