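# Canonical junction catalogue, breakpoint correction, junction-level
# transcript models.

# genome-space alignment of an error-free two-exon read over the toy locus
toy_genome_aln <- function(mg, read_id = "r1", mutate_at = NULL,
                           exons = c(1L, 2L)) {
  ex <- mg$exons[exons, ]
  seq <- paste(substring(mg$seq, ex$offset + 1L, ex$offset + ex$length),
               collapse = "")
  if (!is.null(mutate_at)) {  # mutate the read base at this read offset
    b <- substr(seq, mutate_at, mutate_at)
    substr(seq, mutate_at, mutate_at) <- chartr("ACGT", "CATG", b)
  }
  gaps <- ex$start[-1L] - ex$end[-nrow(ex)]
  cigar <- paste0(ex$length[1],
                  paste(mapply(function(g, l) sprintf("M%dN%d", g, l),
                               gaps, ex$length[-1L]), collapse = ""), "M")
  make_aln(read_id, ex$start[1L], cigar, seq = seq, target_id = mg$chrom,
           space = "genome")
}

test_that("perfect GT-AG junctions enter the catalogue; errors near the gap
           or non-canonical motifs exclude them", {
  mg <- toy_metagene()
  cat0 <- toy_catalogue(mg)
  # clean read over intron 1 -> catalogued, annotated status
  a <- toy_genome_aln(mg)
  jc <- extract_perfect_junctions(a, mg$genome, cat0, min_support = 1L)
  expect_equal(nrow(jc$junctions), 1L)
  expect_equal(jc$junctions$intron_start, 160L)
  expect_equal(jc$junctions$intron_end, 300L)
  expect_equal(jc$junctions$motif, "GT-AG")
  expect_equal(jc$junctions$status, "annotated")
  # same junction with a mismatch 3 nt before the gap (flank 8) -> excluded
  a2 <- toy_genome_aln(mg, "r2", mutate_at = mg$exons$length[1] - 2L)
  jc2 <- extract_perfect_junctions(a2, mg$genome, cat0, min_support = 1L)
  expect_equal(nrow(jc2$junctions), 0L)
  # ... but a mismatch 12 nt before the gap is outside the flank
  a3 <- toy_genome_aln(mg, "r3", mutate_at = mg$exons$length[1] - 11L)
  expect_equal(nrow(extract_perfect_junctions(a3, mg$genome, cat0, min_support = 1L)$junctions), 1L)
  # non-canonical intron (GT..AC): break the acceptor AG
  g2 <- mg
  chars <- strsplit(as.character(mg$genome[[1]]), "")[[1]]
  chars[299:300] <- c("A", "C")
  g2$genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(g2$genome) <- mg$chrom
  jc3 <- extract_perfect_junctions(toy_genome_aln(mg), g2$genome, cat0, min_support = 1L)
  expect_equal(nrow(jc3$junctions), 0L)
})

test_that("support accumulates per junction and novel sites are labelled", {
  mg <- toy_metagene()
  cat0 <- toy_catalogue(mg)
  alns <- do.call(rbind, lapply(1:5, function(i) toy_genome_aln(mg, paste0("r", i))))
  class(alns) <- c("spliced_alignments", "data.frame")
  jc <- extract_perfect_junctions(alns, mg$genome, cat0)
  expect_equal(jc$junctions$support, 5L)
  expect_true(all(jc$sites$status == "annotated"))
})

test_that("correct_breakpoints snaps within max_shift, honours the tie rule,
           and leaves exact breakpoints unchanged", {
  sites <- data.frame(pos = c(100L, 120L, 300L, 500L),
                      side = c("donor", "donor", "acceptor", "acceptor"),
                      support = c(10L, 3L, 5L, 5L), status = "novel")
  catalogue <- structure(list(junctions = NULL, sites = sites),
                         class = "junction_catalogue")
  mk <- function(gapstart, gapend, id = "r") {
    # 50M gap 50M with the gap [gapstart, gapend)
    make_aln(id, gapstart - 50L, sprintf("50M%dN50M", gapend - gapstart),
             space = "genome", target_id = "chrT")
  }
  # breakpoint 3 nt upstream of the catalogued donor 100 -> snapped to it
  ch <- correct_breakpoints(mk(97L, 301L), catalogue)
  expect_equal(ch$donor, 100L)
  expect_equal(ch$acceptor, 300L)
  expect_true(ch$corrected)
  expect_false(ch$uncorrected)
  # equidistant (10 nt) between donors 100 and 120 -> higher support wins
  ch2 <- correct_breakpoints(mk(110L, 301L), catalogue)
  expect_equal(ch2$donor, 100L)
  # equal support ties -> upstream site; acceptors 300/500 too far apart to
  # tie here, so test the donor-side tie with equal support
  sites2 <- sites; sites2$support <- 5L
  cat2 <- structure(list(junctions = NULL, sites = sites2),
                    class = "junction_catalogue")
  ch3 <- correct_breakpoints(mk(110L, 301L), cat2)
  expect_equal(ch3$donor, 100L)  # upstream on the plus strand
  # exact breakpoints are unchanged (idempotence)
  ch4 <- correct_breakpoints(mk(100L, 301L), catalogue)
  expect_equal(ch4$donor, 100L)
  expect_false(ch4$corrected)
  # nothing within max_shift -> raw breakpoints, flagged uncorrected
  ch5 <- correct_breakpoints(mk(200L, 260L), catalogue)
  expect_equal(ch5$donor, 200L)
  expect_true(ch5$uncorrected)
})

test_that("junction-adjacent deletions merge into the gap before snapping", {
  sites <- data.frame(pos = c(100L, 300L), side = c("donor", "acceptor"),
                      support = c(5L, 5L), status = "novel")
  catalogue <- structure(list(junctions = NULL, sites = sites),
                         class = "junction_catalogue")
  # 12 nt deletion immediately before a 188 nt gap: raw donor at 88
  a <- make_aln("r", 38L, "50M12D188N50M", space = "genome", target_id = "chrT")
  ch <- correct_breakpoints(a, catalogue)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$donor, 100L)  # snapped from the merged-gap edge 88
  expect_equal(ch$acceptor, 300L)
})

test_that("junction chains collapse into filtered junction-level models with
           the small-scale variant annotation", {
  mkchain <- function(n, ch, lib = "L1")
    data.frame(read_id = paste0(ch, "_", seq_len(n)), library_id = lib,
               intron_start = as.integer(sub("-.*", "", ch)),
               intron_end = as.integer(sub(".*-", "", ch)),
               donor = as.integer(sub("-.*", "", ch)),
               acceptor = as.integer(sub(".*-", "", ch)) - 1L,
               corrected = FALSE, uncorrected = FALSE, k = 1L, chain = ch,
               stringsAsFactors = FALSE)
  chains <- rbind(mkchain(30L, "160-300"),   # retained (>= 24)
                  mkchain(23L, "160-312"))   # dropped  (23 < 24)
  mg <- toy_metagene()
  exon_models <- cluster_paths(data.frame(
    read_id = paste0("e", 1:30), chain = "E1|E2|E3", complete_ends = TRUE,
    library_id = "L1", stringsAsFactors = FALSE))
  jm <- junction_chain_transcripts(chains, exon_models = exon_models, mg = mg)
  expect_equal(nrow(jm$models), 1L)
  expect_equal(jm$models$support, 30L)
  # the exon-level model implies introns 160-300 and 390-600; the junction
  # model has a single junction so no same-length chain match -> distinct
  expect_equal(jm$models$exon_level_match, "distinct")
  # with both introns, identical chains are annotated as identical
  two <- rbind(mkchain(30L, "160-300"))
  two$chain <- "160-300;390-600"
  extra <- two; extra$intron_start <- 390L; extra$intron_end <- 600L
  extra$k <- 2L
  jm2 <- junction_chain_transcripts(rbind(two, extra),
                                    exon_models = exon_models, mg = mg)
  expect_equal(jm2$models$exon_level_match, "identical")
  # a 12 nt acceptor shift on one junction -> small-scale variant flag
  shift <- rbind(two, extra)
  shift$chain <- "160-312;390-600"
  shift$intron_end[shift$k == 1L] <- 312L
  jm3 <- junction_chain_transcripts(shift, exon_models = exon_models, mg = mg)
  expect_match(jm3$models$exon_level_match, "small-scale variant")
  # per-site support threshold flag
  expect_true(all(jm$site_support$passes_min ==
                    (jm$site_support$support >= 10)))
})

test_that("simulated junction noise is repaired against the data-derived
           catalogue and corrected endpoints are catalogued sites", {
  s <- small_sim(seed = 13, depth = 150L)
  mg <- s$ann$metagene
  al <- align_reads(s$sim$reads, mg)
  alns <- filter_reads(al, mg$gene_id)$alignments
  ga <- project_to_genome(alns, mg)
  jc <- extract_perfect_junctions(ga, mg$genome, s$ann$catalogue)
  ch <- correct_breakpoints(ga, jc)
  snapped <- ch[!ch$uncorrected, ]
  expect_gt(nrow(snapped), 0L)
  expect_true(all(snapped$donor %in% jc$sites$pos[jc$sites$side == "donor"]))
  expect_true(all(snapped$acceptor %in%
                    jc$sites$pos[jc$sites$side == "acceptor"]))
})
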