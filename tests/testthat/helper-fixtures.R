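# In-code fixtures shared across tests: a deterministic toy locus with
# known exon structure, and small builders for reads/alignments.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A 3-exon plus-strand toy gene on a 1000 nt chromosome:
#   E1 = [100,160), E2 = [300,390), E3 = [600,720)
# with canonical GT..AG introns and two annotated transcripts
# T1 = E1-E2-E3 and T2 = E1-E3.
toy_locus <- function(seed = 99) {
  set.seed(seed)
  chars <- strsplit(rand_seq(1000), "")[[1]]
  ex <- data.frame(exon_id = c("E1", "E2", "E3"),
                   start = c(100L, 300L, 600L),
                   end = c(160L, 390L, 720L),
                   origin = "annotated", stringsAsFactors = FALSE)
  for (i in 1:2) { # GT at intron starts, AG at intron ends
    chars[(ex$end[i] + 1L):(ex$end[i] + 2L)] <- c("G", "T")
    chars[(ex$start[i + 1L] - 1L):ex$start[i + 1L]] <- c("A", "G")
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrT"
  list(genome = genome, exons = ex, chrom = "chrT")
}

toy_metagene <- function(strand = "+", seed = 99) {
  tl <- toy_locus(seed)
  isoamp:::new_metagene("GENE1", tl$chrom, strand, tl$exons, tl$genome)
}

toy_catalogue <- function(mg) {
  chains <- list(T1 = c("E1", "E2", "E3"), T2 = c("E1", "E3"))
  structure(list(transcripts = chains,
                 splice_sites = isoamp:::annotated_splice_sites(chains, mg)),
            class = "annotation_catalogue")
}

# write a toy GTF for load_annotation tests (1-based inclusive coords)
write_toy_gtf <- function(path, exons, transcripts, chrom = "chrT",
                          strand = "+", gene_id = "GENE1") {
  lines <- character(0)
  for (tx in names(transcripts)) {
    d <- exons[match(transcripts[[tx]], exons$exon_id), , drop = FALSE]
    lines <- c(lines, sprintf(
      '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      chrom, d$start + 1L, d$end, strand, gene_id, tx))
  }
  writeLines(lines, path)
  path
}

# an alignments data.frame row without going through the aligner
make_aln <- function(read_id, pos, cigar, seq = NA_character_,
                     target_id = "GENE1", strand = "+", qscore = NA_real_,
                     library_id = NA_character_, score = NA_real_,
                     space = "metagene") {
  isoamp:::new_alignments(
    data.frame(read_id = read_id, target_id = target_id, pos = pos,
               strand = strand, cigar = cigar, seq = seq, qscore = qscore,
               library_id = library_id, score = score,
               stringsAsFactors = FALSE), space)
}

# substring of the metagene (0-based half-open)
mg_sub <- function(mg, from, to) substr(mg$seq, from + 1L, to)

# small simulated dataset reused by several acceptance tests
small_sim <- function(seed = 7, depth = 250L) {
  cfg <- sim_config(seed = seed, libraries = default_libraries(depth = depth))
  loc <- simulate_locus(cfg)
  sim <- simulate_reads(cfg, loc)
  list(cfg = cfg, loc = loc, sim = sim, ann = isoamp:::locus_annotation(loc))
}
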