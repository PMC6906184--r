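# Novel-exon mining, genomic placement and the support filters.

test_that("mine_inserts honours the 9 nt threshold and the junction window", {
  mg <- toy_metagene()
  bnd <- mg$exons$offset[2]  # E1|E2 boundary at metagene 60
  mk <- function(ilen, at) {
    # read with an insertion of ilen at metagene position `at`
    cigar <- sprintf("%dM%dI%dM", at, ilen, nchar(mg$seq) - at)
    seq <- paste0(mg_sub(mg, 0, at), strrep("T", ilen),
                  mg_sub(mg, at, nchar(mg$seq)))
    make_aln("r1", 0L, cigar, seq = seq, library_id = "L1")
  }
  # 12 nt at the boundary -> one event of length 12
  ev <- mine_inserts(mk(12L, bnd), mg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$insert_len, 12L)
  expect_equal(ev$flank_left_exon, "E1")
  expect_equal(ev$flank_right_exon, "E2")
  expect_identical(ev$insert_seq, strrep("T", 12L))
  # 8 nt at the boundary -> no event
  expect_equal(nrow(mine_inserts(mk(8L, bnd), mg)), 0L)
  # 9 nt at the boundary -> event (threshold inclusive)
  expect_equal(nrow(mine_inserts(mk(9L, bnd), mg)), 1L)
  # 15 nt insert 30 nt away from any boundary -> no event
  expect_equal(nrow(mine_inserts(mk(15L, bnd + 30L), mg)), 0L)
  # 6 nt from the boundary is still inside the default window
  expect_equal(nrow(mine_inserts(mk(9L, bnd + 6L), mg)), 1L)
  expect_equal(nrow(mine_inserts(mk(9L, bnd + 7L), mg)), 0L)
})

test_that("fragmented insertion runs at one junction pool into one event", {
  mg <- toy_metagene()
  bnd <- mg$exons$offset[2]
  # 7I 3M 8I: micro-match splits a 15 nt insert; total pooled = 15
  cigar <- sprintf("%dM7I3M8I%dM", bnd, nchar(mg$seq) - bnd - 3L)
  seq <- paste0(mg_sub(mg, 0, bnd), strrep("A", 7),
                mg_sub(mg, bnd, bnd + 3L), strrep("C", 8),
                mg_sub(mg, bnd + 3L, nchar(mg$seq)))
  ev <- mine_inserts(make_aln("r1", 0L, cigar, seq = seq), mg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$insert_len, 15L)
})

test_that("place_insert_on_genome recovers planted intronic sequence and
           rejects absent sequence", {
  mg <- toy_metagene()
  chrom <- mg$genome[[mg$chrom]]
  # plant: intron 2 position 450-462 copied verbatim as the insert
  ins <- as.character(Biostrings::subseq(chrom, 451, 462))
  ev <- data.frame(read_id = "r", insert_seq = ins, insert_len = 12L,
                   flank_left_exon = "E2", flank_right_exon = "E3",
                   junction_metagene_pos = mg$exons$offset[3],
                   library_id = "L1", stringsAsFactors = FALSE)
  hit <- place_insert_on_genome(ev, mg)
  expect_equal(hit$start, 450L)
  expect_equal(hit$end, 462L)
  expect_equal(hit$identity, 1.0)
  # a 12-mer absent from the intron places nowhere;
  # oracle: exhaustive substring scan finds no hit of >= 80% identity
  absent <- "TTTTTTTTTTTT"
  intron <- as.character(Biostrings::subseq(chrom, 391, 600))
  worst <- max(vapply(seq_len(nchar(intron) - 11L), function(i) {
    sum(strsplit(substr(intron, i, i + 11L), "")[[1]] ==
          strsplit(absent, "")[[1]])
  }, numeric(1))) / 12
  expect_lt(worst, 0.8)  # fixed-seed intron has no gap-free near-match
  expect_null(place_insert_on_genome(transform(ev, insert_seq = absent), mg))
})

test_that("candidate merging is order-independent and support-pooled", {
  mg <- toy_metagene()
  chrom <- mg$genome[[mg$chrom]]
  ins_full <- as.character(Biostrings::subseq(chrom, 441, 480))
  ins_jit <- as.character(Biostrings::subseq(chrom, 443, 478))
  mkev <- function(seqs, libs, reads) data.frame(
    read_id = reads, insert_seq = seqs, insert_len = nchar(seqs),
    flank_left_exon = "E2", flank_right_exon = "E3",
    junction_metagene_pos = mg$exons$offset[3], library_id = libs,
    stringsAsFactors = FALSE)
  ev <- mkev(c(ins_full, ins_full, ins_jit, ins_full),
             c("L1", "L1", "L2", "L2"), paste0("r", 1:4))
  libs <- data.frame(library_id = c("L1", "L2"),
                     individual = c("I1", "I2"), tissue = c("ctx", "ctx"))
  a <- candidate_novel_exons(ev, mg, libs, snap_to_motif = FALSE)
  b <- candidate_novel_exons(ev[c(3, 1, 4, 2), ], mg, libs, snap_to_motif = FALSE)
  expect_equal(nrow(a), 1L)
  expect_identical(a[, c("start", "end", "n_reads")],
                   b[, c("start", "end", "n_reads")])
  expect_equal(a$n_reads, 4L)
  expect_equal(a$n_individuals, 2L)
  # modal boundary pair: 3 of 4 placements at 440-480
  expect_equal(a$start, 440L)
  expect_equal(a$end, 480L)
})

test_that("filter_candidate_exons enforces distance, breadth and the
           per-library floor", {
  base <- data.frame(start = 450L, end = 470L, n_reads = 10L,
                     n_individuals = 1L, n_tissues = 2L,
                     distance_to_nearest_exon = 6L,
                     host_up = "E2", host_dn = "E3",
                     status = "candidate", stringsAsFactors = FALSE)
  base$support <- I(list(c(L1 = 5L, L2 = 5L)))
  # 6 nt away, 2 tissues, 5 reads in each library -> accepted
  expect_equal(filter_candidate_exons(base)$status, "accepted")
  # 5 nt from an exon -> rejected
  d5 <- base; d5$distance_to_nearest_exon <- 5L
  expect_equal(filter_candidate_exons(d5)$status, "rejected")
  # 5 reads in each of 2 tissues of 1 individual -> accepted
  expect_equal(base$n_individuals, 1L)
  expect_equal(filter_candidate_exons(base)$status, "accepted")
  # breadth of 1 -> rejected
  b1 <- base; b1$n_tissues <- 1L
  expect_equal(filter_candidate_exons(b1)$status, "rejected")
  # 4 reads in one library, 20 in another -> rejected (per-library floor)
  fl <- base; fl$support <- I(list(c(L1 = 4L, L2 = 20L)))
  expect_equal(filter_candidate_exons(fl)$status, "rejected")
})

test_that("accepted exons lie strictly inside one annotated intron", {
  s <- small_sim(seed = 5, depth = 400L)
  mg <- s$ann$metagene
  al <- align_reads(s$sim$reads, mg)
  alns <- filter_reads(al, mg$gene_id)$alignments
  ev <- mine_inserts(alns, mg)
  cands <- filter_candidate_exons(
    candidate_novel_exons(ev, mg, s$cfg$libraries))
  acc <- cands[cands$status == "accepted", ]
  expect_gte(nrow(acc), 1L)
  introns <- isoamp:::metagene_introns(mg)
  for (i in seq_len(nrow(acc))) {
    host <- introns$start < acc$start[i] & introns$end > acc$end[i]
    expect_equal(sum(host), 1L)
  }
})
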