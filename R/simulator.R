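# Synthetic single-gene amplicon assay with full ground truth: a random
# multi-exon locus with canonical GT-AG introns, planted intronic novel
# exons, junction-shift microdeletion variants, a library design
# (individuals x tissues) with a cerebellum-style isoform switch, and
# noisy full-length reads under an indel-dominant error model with extra
# indels near junctions.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulator configuration
#'
#' Defaults emulate a full-length CDS amplicon assay of one multi-exon
#' gene at a locus scale the built-in aligner handles comfortably: 12
#' annotated exons at the per-exon scale of a large channel gene, three
#' intronic novel exons, sub-exon junction deletions of 9/12/15 nt (the
#' 3/4/5-amino-acid microdeletion case) plus one frame-shifting 4-nt
#' deletion, ten isoforms, and six libraries (three individuals, two
#' tissues) of 3000 reads with ~10 percent total error dominated by
#' indels.
#'
#' @param n_exons number of annotated exons.
#' @param exon_len_range,intron_len_range exon/intron length ranges (nt).
#' @param n_novel_exons planted intronic novel exons.
#' @param novel_len_range novel exon length range (nt).
#' @param microdeletion_lengths in-frame junction-adjacent deletions (nt).
#' @param frameshift_deletion_lengths frame-shifting junction deletions (nt).
#' @param n_isoforms number of expressed isoforms (>= 6).
#' @param libraries data.frame: library_id, individual, tissue, run, depth.
#' @param error_rates per-base substitution/insertion/deletion
#'   probabilities (named vector `sub`, `ins`, `del`).
#' @param junction_jitter per-junction per-read probability of one extra
#'   1-6 nt indel within 10 nt of the junction.
#' @param isoform_switch make the top novel isoform near-equal to the
#'   reference in cerebellum libraries (5:1 elsewhere).
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 12L,
                       exon_len_range = c(60L, 250L),
                       intron_len_range = c(300L, 800L),
                       n_novel_exons = 3L,
                       novel_len_range = c(9L, 120L),
                       microdeletion_lengths = c(9L, 12L, 15L),
                       frameshift_deletion_lengths = 4L,
                       n_isoforms = 10L,
                       libraries = default_libraries(),
                       error_rates = c(sub = 0.03, ins = 0.03, del = 0.04),
                       junction_jitter = 0.15,
                       isoform_switch = TRUE,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(error_rates >= 0 & error_rates <= 1),
            junction_jitter >= 0 && junction_jitter <= 1,
            all(libraries$depth >= 1), n_isoforms >= 6L)
  structure(list(n_exons = as.integer(n_exons),
                 exon_len_range = exon_len_range,
                 intron_len_range = intron_len_range,
                 n_novel_exons = as.integer(n_novel_exons),
                 novel_len_range = novel_len_range,
                 microdeletion_lengths = microdeletion_lengths,
                 frameshift_deletion_lengths = frameshift_deletion_lengths,
                 n_isoforms = as.integer(n_isoforms),
                 libraries = libraries,
                 error_rates = error_rates,
                 junction_jitter = junction_jitter,
                 isoform_switch = isoform_switch,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default library design: 3 individuals x 2 tissues, one run, depth 3000
#' @export
default_libraries <- function(depth = 3000L) {
  d <- expand.grid(individual = c("I1", "I2", "I3"),
                   tissue = c("cortex", "cerebellum"),
                   stringsAsFactors = FALSE)
  d$run <- "one"
  d$depth <- as.integer(depth)
  d$library_id <- paste(d$individual, d$tissue, d$run, sep = "_")
  d[, c("library_id", "individual", "tissue", "run", "depth")]
}

# draw from an inclusive integer range (safe when lo == hi)
sample_range <- function(lo, hi, n = 1L) {
  v <- seq.int(lo, hi)
  v[sample.int(length(v), n, replace = TRUE)]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  paste(c("ATG", sample(codons, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

#' Simulate the locus: genome, annotation and isoform truth
#'
#' Draws a random plus-strand gene with GT-AG introns whose full exon
#' concatenation is a stop-free CDS, plants novel exons inside introns
#' (with canonical AG/GT flanks, at least 20 nt from annotated exons) and
#' junction-shift deletion variants (AG engineered at the shifted
#' acceptor), and defines the expressed isoform set with a
#' library-structured abundance matrix. Isoforms intended as coding are
#' re-drawn until their spliced CDSs are premature-stop-free, so coding
#' truth is exact by construction. Deterministic given the seed.
#'
#' @param cfg a `sim_config`.
#' @return list of class `sim_locus`; see Details in the package vignette.
#' @export
simulate_locus <- function(cfg) {
  set.seed(cfg$seed)
  for (attempt in 1:25) {
    loc <- try(build_locus_once(cfg), silent = TRUE)
    if (!inherits(loc, "try-error")) return(loc)
    if (grepl("cannot place novel exon", loc)) stop(attr(loc, "condition"))
  }
  stop("failed to draw a premature-stop-free locus in 25 attempts")
}

build_locus_once <- function(cfg) {
  n <- cfg$n_exons
  exlen <- sample_range(cfg$exon_len_range[1], cfg$exon_len_range[2], n)
  # half of the internal exons are made frame-neutral (length % 3 == 0)
  internal <- 2:(n - 1L)
  neutral <- internal[seq_along(internal) %% 2L == 0L]
  exlen[neutral] <- pmax(60L, exlen[neutral] - exlen[neutral] %% 3L)
  exlen[n] <- exlen[n] + (3L - sum(exlen) %% 3L) %% 3L
  inlen <- sample_range(cfg$intron_len_range[1], cfg$intron_len_range[2],
                        n - 1L)

  cds <- rand_cds(sum(exlen) %/% 3L)
  exseq <- substring(cds, cumsum(c(0L, head(exlen, -1L))) + 1L, cumsum(exlen))
  introns <- vapply(inlen, function(L)
    paste0("GT", rand_dna(L - 4L), "AG"), character(1))
  pad5 <- rand_dna(100L); pad3 <- rand_dna(100L)

  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- exseq
  pieces[seq(2L, 2L * n - 2L, by = 2L)] <- introns
  genome_chars <- strsplit(paste0(pad5, paste(pieces, collapse = ""), pad3),
                           "")[[1]]
  starts <- 100L + cumsum(c(0L, head(exlen + c(inlen, 0L), -1L)))
  exons <- data.frame(exon_id = paste0("E", seq_len(n)),
                      start = starts, end = starts + exlen,
                      origin = "annotated", stringsAsFactors = FALSE)

  # plant novel exons inside distinct introns; the margin keeps both
  # flanking intron fragments above the junction-level minimum intron
  # length (30 nt) with room for jitter, so planted junctions are
  # structurally analysable
  margin <- 40L
  novel <- list()
  host_introns <- if (cfg$n_novel_exons > 0L)
    sample(seq_len(n - 1L), cfg$n_novel_exons) else integer(0)
  for (k in seq_len(cfg$n_novel_exons)) {
    i <- host_introns[k]
    ilen <- inlen[i]
    nlen <- sample_range(cfg$novel_len_range[1], cfg$novel_len_range[2])
    room <- ilen - 2L * margin - nlen
    if (room < 1L)
      stop("cannot place novel exon >=6 nt from exon edges: intron ", i,
           " too short (", ilen, " nt) for a ", nlen, " nt exon")
    offs <- margin + sample(room, 1L)
    s <- exons$end[i] + offs
    e <- s + nlen
    genome_chars[(s - 1L):s] <- c("A", "G")     # acceptor AG before exon
    genome_chars[(e + 1L):(e + 2L)] <- c("G", "T")  # donor GT after exon
    # non-degenerate boundaries: an exon starting AG or ending GT makes
    # the splice position sequence-ambiguous (both placements spell the
    # same transcript), so the planted truth would be unidentifiable
    if (genome_chars[s + 1L] == "A" && genome_chars[s + 2L] == "G")
      genome_chars[s + 2L] <- "C"
    if (genome_chars[e - 1L] == "G" && genome_chars[e] == "T")
      genome_chars[e - 1L] <- "C"
    novel[[k]] <- data.frame(exon_id = paste0("NV", k), start = s, end = e,
                             host_intron = i, stringsAsFactors = FALSE)
  }
  novel <- if (length(novel)) do.call(rbind, novel) else
    data.frame(exon_id = character(), start = integer(), end = integer(),
               host_intron = integer(), stringsAsFactors = FALSE)
  novel <- novel[order(novel$start), , drop = FALSE]
  novel$exon_id <- if (nrow(novel)) paste0("NV", seq_len(nrow(novel)))
                   else character(0)
  rownames(novel) <- NULL

  # junction-shift deletion variants at exon acceptors: engineer AG so the
  # shifted intron stays canonical
  del_lens <- c(cfg$microdeletion_lengths, cfg$frameshift_deletion_lengths)
  internal_pool <- setdiff(internal, c(1L, n))
  md_exon <- internal_pool[which.max(exlen[internal_pool])]
  fs_pool <- setdiff(internal_pool, md_exon)
  fs_exon <- fs_pool[which.max(exlen[fs_pool])]
  del_exon <- c(rep(md_exon, length(cfg$microdeletion_lengths)),
                rep(fs_exon, length(cfg$frameshift_deletion_lengths)))
  for (k in seq_along(del_lens)) {
    d <- del_lens[k]; s <- exons$start[del_exon[k]]
    genome_chars[(s + d - 1L):(s + d)] <- c("A", "G")
  }

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chrSim"

  ref_intervals <- exons[, c("start", "end")]
  iso <- list()
  add_iso <- function(id, intervals, chain, coding_intent) {
    intervals <- intervals[order(intervals$start), , drop = FALSE]
    rownames(intervals) <- NULL
    iso[[length(iso) + 1L]] <<- list(id = id, intervals = intervals,
                                     chain = chain,
                                     coding_intent = coding_intent)
  }
  ref_chain <- exons$exon_id
  add_iso("iso_ref", ref_intervals, ref_chain, TRUE)
  for (k in seq_along(cfg$microdeletion_lengths)) {
    d <- cfg$microdeletion_lengths[k]
    iv <- ref_intervals
    iv$start[md_exon] <- iv$start[md_exon] + d
    add_iso(paste0("iso_del", d), iv, ref_chain, TRUE)
  }
  for (k in seq_along(cfg$frameshift_deletion_lengths)) {
    d <- cfg$frameshift_deletion_lengths[k]
    iv <- ref_intervals
    iv$start[fs_exon] <- iv$start[fs_exon] + d
    add_iso(paste0("iso_fsdel", d), iv, ref_chain, FALSE)
  }
  for (k in seq_len(nrow(novel))) {
    iv <- rbind(ref_intervals,
                data.frame(start = novel$start[k], end = novel$end[k]))
    pos <- sum(exons$end <= novel$start[k])
    chain <- append(ref_chain, novel$exon_id[k], after = pos)
    add_iso(paste0("iso_nov", k), iv, chain, NA)
  }
  skip_pool <- setdiff(internal, c(md_exon, fs_exon))
  inframe_sk <- skip_pool[exlen[skip_pool] %% 3L == 0L]
  shift_sk <- skip_pool[exlen[skip_pool] %% 3L != 0L]
  if (length(inframe_sk)) {
    e <- inframe_sk[1L]
    add_iso("iso_skip_inframe", ref_intervals[-e, , drop = FALSE],
            ref_chain[-e], TRUE)
  }
  if (length(shift_sk)) {
    e <- shift_sk[1L]
    add_iso("iso_skip_frameshift", ref_intervals[-e, , drop = FALSE],
            ref_chain[-e], FALSE)
  }
  # pad with further in-frame skip combinations if more isoforms are asked
  extra_pool <- setdiff(inframe_sk, inframe_sk[1L])
  while (length(iso) < cfg$n_isoforms && length(extra_pool) > 0L) {
    e <- extra_pool[1L]; extra_pool <- extra_pool[-1L]
    add_iso(paste0("iso_skip_E", e), ref_intervals[-e, , drop = FALSE],
            ref_chain[-e], NA)
  }
  iso <- iso[seq_len(min(length(iso), cfg$n_isoforms))]

  # coding truth by construction: intended-coding isoforms must be
  # premature-stop-free; otherwise redraw the whole locus
  for (x in iso) {
    sq <- spliced_sequence(x$intervals, genome[["chrSim"]])
    if (isTRUE(x$coding_intent)) {
      if ((nchar(sq) %% 3L) != 0L || has_premature_stop(sq))
        stop("intended-coding isoform has a premature stop; redraw")
    }
  }
  truth_class <- vapply(iso, function(x) {
    sq <- spliced_sequence(x$intervals, genome[["chrSim"]])
    dlen <- nchar(sq) - sum(exlen)
    if (dlen %% 3L == 0L && !has_premature_stop(sq)) "putative_coding"
    else "putative_noncoding"
  }, character(1))

  annotated_transcripts <- list(T1 = ref_chain)
  if (any(vapply(iso, function(x) x$id == "iso_skip_inframe", logical(1))))
    annotated_transcripts$T2 <-
      iso[[which(vapply(iso, function(x) x$id, character(1)) == "iso_skip_inframe")]]$chain

  abundance <- sim_abundance(cfg, vapply(iso, `[[`, character(1), "id"))

  structure(list(cfg = cfg, gene_id = "GENE1", chrom = "chrSim", strand = "+",
                 genome = genome, exons = exons, novel_exons = novel,
                 exon_lengths = exlen,
                 md_exon = md_exon, fs_exon = fs_exon,
                 isoforms = iso, truth_class = truth_class,
                 annotated_transcripts = annotated_transcripts,
                 abundance = abundance,
                 anchors = list(cds_start = exons$start[1L],
                                cds_end = exons$end[n])),
            class = "sim_locus")
}

#' @export
print.sim_locus <- function(x, ...) {
  cat("sim_locus:", nrow(x$exons), "annotated exons,",
      nrow(x$novel_exons), "novel exons,", length(x$isoforms), "isoforms,",
      length(x$genome[[1]]), "nt genome\n")
  invisible(x)
}

# per-library isoform proportions: reference dominant, a designated switch
# partner near-equal in cerebellum, mild per-library jitter
sim_abundance <- function(cfg, iso_ids) {
  k <- length(iso_ids)
  libs <- cfg$libraries
  base <- c(0.45, 0.09, rep(0, k - 2L))
  rest <- exp(-0.35 * seq_len(k - 2L))
  base[3:k] <- 0.46 * rest / sum(rest)
  # slot 2 is the switch partner: prefer the first novel-exon isoform
  partner <- which(grepl("^iso_nov", iso_ids))[1]
  if (is.na(partner)) partner <- 2L
  ord <- c(1L, partner, setdiff(seq_len(k), c(1L, partner)))
  prop <- numeric(k); prop[ord] <- base
  mat <- matrix(0, nrow = k, ncol = nrow(libs),
                dimnames = list(iso_ids, libs$library_id))
  for (j in seq_len(nrow(libs))) {
    p <- prop
    if (cfg$isoform_switch && libs$tissue[j] == "cerebellum") {
      tot <- p[1L] + p[partner]
      p[1L] <- 0.52 * tot; p[partner] <- 0.48 * tot
    }
    p <- p * exp(rnorm(k, 0, 0.05))
    mat[, j] <- p / sum(p)
  }
  mat
}

spliced_sequence <- function(intervals, chromseq) {
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  paste(vapply(seq_len(nrow(intervals)), function(i)
    as.character(Biostrings::subseq(chromseq, intervals$start[i] + 1L,
                                    intervals$end[i])), character(1)),
    collapse = "")
}

#' Simulate reads with the error model
#'
#' For each library, reads are drawn from its isoform proportions
#' (multinomial, so column sums equal library depths exactly); each read
#' is the full spliced isoform sequence corrupted by i.i.d. per-base
#' substitutions/insertions/deletions plus, per junction, an occasional
#' extra 1-6 nt indel within 10 nt of the junction. Per-read q-scores are
#' Phred-consistent with the realised error count.
#'
#' @param cfg a `sim_config`.
#' @param locus a `sim_locus`.
#' @return list with `reads` (data.frame: read_id, seq, qual, qscore,
#'   library_id), `truth` (read_id, isoform_id, library_id) and `counts`
#'   (true isoform x library count matrix).
#' @export
simulate_reads <- function(cfg, locus) {
  set.seed((cfg$seed + 7919L) %% .Machine$integer.max)
  chromseq <- locus$genome[[locus$chrom]]
  iso_seq <- lapply(locus$isoforms, function(x)
    spliced_sequence(x$intervals, chromseq))
  iso_junc <- lapply(locus$isoforms, function(x) {
    iv <- x$intervals[order(x$intervals$start), , drop = FALSE]
    cumsum(iv$end - iv$start)[-nrow(iv)]
  })
  iso_ids <- vapply(locus$isoforms, `[[`, character(1), "id")
  libs <- cfg$libraries
  counts <- matrix(0L, nrow = length(iso_ids), ncol = nrow(libs),
                   dimnames = list(iso_ids, libs$library_id))
  reads <- vector("list", nrow(libs))
  truth <- vector("list", nrow(libs))
  er <- cfg$error_rates
  for (j in seq_len(nrow(libs))) {
    depth <- libs$depth[j]
    cnt <- as.integer(rmultinom(1L, depth, locus$abundance[, j]))
    counts[, j] <- cnt
    origin <- rep(seq_along(iso_ids), cnt)
    seqs <- character(depth); quals <- character(depth); qs <- numeric(depth)
    for (r in seq_len(depth)) {
      cr <- corrupt_read(iso_seq[[origin[r]]], iso_junc[[origin[r]]],
                         er[["sub"]], er[["ins"]], er[["del"]],
                         cfg$junction_jitter)
      seqs[r] <- cr$seq; quals[r] <- cr$qual; qs[r] <- cr$qscore
    }
    ids <- sprintf("%s_r%05d", libs$library_id[j], seq_len(depth))
    reads[[j]] <- data.frame(read_id = ids, seq = seqs, qual = quals,
                             qscore = qs, library_id = libs$library_id[j],
                             stringsAsFactors = FALSE)
    truth[[j]] <- data.frame(read_id = ids, isoform_id = iso_ids[origin],
                             library_id = libs$library_id[j],
                             stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth),
       counts = counts)
}

corrupt_read <- function(seq, junctions, p_sub, p_ins, p_del, jitter) {
  L <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  del <- runif(L) < p_del
  sub <- runif(L) < p_sub & !del
  ins <- runif(L) < p_ins
  # junction-proximity extra indels
  for (jp in junctions) {
    if (runif(1) >= jitter) next
    len <- sample(1:6, 1L)
    at <- jp + sample(-10:9, 1L)
    at <- max(1L, min(L - len, at))
    if (runif(1) < 0.7) del[at:(at + len - 1L)] <- TRUE
    else s[at] <- paste0(s[at], rand_dna(len))
  }
  n_err <- sum(del) + sum(sub) + sum(ins) +
    sum(nchar(s)) - L  # jitter insertions already concatenated
  if (any(sub))
    s[sub] <- vapply(s[sub], function(b)
      sample(setdiff(bases, substr(b, 1L, 1L)), 1L), character(1))
  if (any(ins))
    s[ins] <- paste0(s[ins], sample(bases, sum(ins), replace = TRUE))
  s[del] <- sub("^.", "", s[del])  # delete the original base, keep insertions
  out <- paste(s, collapse = "")
  err_frac <- max(n_err / L, 1e-4)
  q <- max(2, min(40, -10 * log10(err_frac) + rnorm(1, 0, 0.3)))
  list(seq = out, qual = strrep(rawToChar(as.raw(33L + round(q))), nchar(out)),
       qscore = q)
}

#' Write simulated reads as FASTQ
#'
#' @param reads the `reads` data.frame from [simulate_reads()].
#' @param path output FASTQ.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write the simulated locus (genome FASTA + annotation GTF + truth TSVs)
#'
#' @param locus a `sim_locus`.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of written paths.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(locus$genome, fa)
  gtf <- file.path(dir, "annotation.gtf")
  ex <- locus$exons
  rows <- list()
  for (tx in names(locus$annotated_transcripts)) {
    chain <- locus$annotated_transcripts[[tx]]
    d <- ex[match(chain, ex$exon_id), , drop = FALSE]
    rows[[tx]] <- GenomicRanges::GRanges(
      locus$chrom, IRanges::IRanges(d$start + 1L, d$end),
      strand = locus$strand, type = "exon", gene_id = locus$gene_id,
      transcript_id = tx)
  }
  gr <- do.call(c, unname(rows))
  rtracklayer::export(gr, gtf, format = "gtf")
  nov <- file.path(dir, "novel_exons.truth.tsv")
  write.table(locus$novel_exons, nov, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ab <- file.path(dir, "abundance.truth.tsv")
  write.table(data.frame(isoform_id = rownames(locus$abundance),
                         locus$abundance, check.names = FALSE),
              ab, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genome = fa, gtf = gtf, novel = nov, abundance = ab))
}

# metagene + catalogue straight from a simulated locus (equivalent to
# writing the GTF and reloading it with load_annotation)
locus_annotation <- function(locus) {
  mg <- new_metagene(locus$gene_id, locus$chrom, locus$strand,
                     locus$exons, locus$genome)
  catalogue <- structure(
    list(transcripts = locus$annotated_transcripts,
         splice_sites = annotated_splice_sites(locus$annotated_transcripts, mg)),
    class = "annotation_catalogue")
  list(metagene = mg, catalogue = catalogue)
}
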