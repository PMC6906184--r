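# Reading-frame classification, premature stops, protein-coordinate indel
# events and region annotation.


test_that("splice_cds reproduces the reference CDS and tracks chain edits", {
  mg <- toy_metagene()
  anchors <- list(cds_start = 100L, cds_end = 720L)  # full amplicon span
  ref <- splice_cds("E1|E2|E3", mg, anchors)
  expect_false(ref$incomplete_ends)
  expect_identical(ref$seq, mg$seq)
  # dropping the 90 nt internal exon shortens the CDS by 90
  skip <- splice_cds("E1|E3", mg, anchors)
  expect_equal(nchar(skip$seq), nchar(ref$seq) - 90L)
  # a 12 nt novel exon lengthens the CDS by 12
  mg2 <- insert_novel_exons(mg, data.frame(start = 450L, end = 462L,
                                           exon_id = "N1"))
  nov <- splice_cds("E1|E2|N1|E3", mg2, anchors)
  expect_equal(nchar(nov$seq), nchar(ref$seq) + 12L)
  # a model missing the anchor exon is incomplete
  expect_true(splice_cds("E2|E3", mg, anchors)$incomplete_ends)
  # partial-exon anchors clip the terminal exons
  part <- splice_cds("E1|E2|E3", mg, list(cds_start = 110L, cds_end = 700L))
  expect_equal(nchar(part$seq), nchar(ref$seq) - 10L - 20L)
})

test_that("frame classification over indel lengths 3..30 is exact", {
  ref <- make_cds(60)  # 180 nt
  for (L in 3:30) {
    # deletion of L nt starting at nt 31 (codon 11)
    del <- paste0(substr(ref, 1, 30), substr(ref, 31 + L, nchar(ref)))
    ca <- classify_frame(del, ref)
    expect_equal(ca$frame_maintained, L %% 3 == 0)
    if (L %% 3 == 0 && !ca$premature_stop) {
      expect_equal(ca$classification, "putative_coding")
      expect_equal(ca$events$kind, "deletion")
      expect_equal(ca$events$nt_length, L)
      expect_equal(ca$events$aa_length, L / 3)
    }
    if (L %% 3 != 0)
      expect_equal(ca$classification, "putative_noncoding")
  }
})

test_that("9/12/15 nt deletions report 3/4/5 aa events at the planted
           protein coordinates", {
  # pick a fixed seed whose CDS admits no 1 nt gap slide at the planted
  # deletion boundaries, so protein coordinates are unambiguous
  ref <- NULL
  for (s in 1:50) {
    cand <- make_cds(120, seed = s)  # 360 nt
    ok <- all(vapply(c(9L, 12L, 15L), function(L) {
      substr(cand, 61, 61) != substr(cand, 61 + L, 61 + L) &&
        substr(cand, 60, 60) != substr(cand, 60 + L, 60 + L)
    }, logical(1)))
    if (ok) { ref <- cand; break }
  }
  expect_false(is.null(ref))
  # delete codons 21..(20+k): nt 61..60+3k
  for (k in 3:5) {
    L <- 3 * k
    del <- paste0(substr(ref, 1, 60), substr(ref, 61 + L, nchar(ref)))
    ca <- classify_frame(del, ref)
    expect_equal(ca$classification, "putative_coding")
    expect_equal(nrow(ca$events), 1L)
    expect_equal(ca$events$aa_start, 21L)
    expect_equal(ca$events$aa_end, 20L + k)
    expect_equal(ca$events$aa_length, k)
  }
})

test_that("in-frame insertions are reported with aa length and anchor", {
  ref <- make_cds(60)
  ins <- paste0(substr(ref, 1, 30), "TGGTGGTGG", substr(ref, 31, nchar(ref)))
  ca <- classify_frame(ins, ref)
  expect_equal(ca$classification, "putative_coding")
  expect_equal(ca$events$kind, "insertion")
  expect_equal(ca$events$aa_length, 3)
  expect_equal(ca$events$aa_start, 11L)
})

test_that("premature stops force the non-coding call even in frame", {
  ref <- make_cds(60)
  # replace codon 10 (nt 28-30) with TAA
  mut <- ref
  substr(mut, 28, 30) <- "TAA"
  ca <- classify_frame(mut, ref)
  expect_true(ca$frame_maintained)
  expect_true(ca$premature_stop)
  expect_equal(ca$classification, "putative_noncoding")
  # a stop in the final 3 codons does not count as premature
  tail_stop <- ref
  substr(tail_stop, nchar(ref) - 5, nchar(ref) - 3) <- "TAA"
  expect_false(classify_frame(tail_stop, ref)$premature_stop)
  # classification invariant
  for (ca2 in list(ca, classify_frame(ref, ref))) {
    expect_equal(ca2$classification == "putative_coding",
                 ca2$frame_maintained && !ca2$premature_stop)
  }
})

test_that("signed event lengths balance the CDS length difference", {
  ref <- make_cds(120)
  del <- paste0(substr(ref, 1, 60), substr(ref, 73, nchar(ref)))        # -12
  both <- paste0(substr(del, 1, 120), "CATCATCAT", substr(del, 121, nchar(del))) # +9
  ca <- classify_frame(both, ref)
  signed <- sum(ifelse(ca$events$kind == "deletion", -1, 1) * ca$events$nt_length)
  expect_equal(signed, nchar(both) - nchar(ref))
  # reference vs itself: zero events
  expect_equal(nrow(classify_frame(ref, ref)$events), 0L)
})

test_that("region annotation labels overlapping events and flags the rest", {
  tab <- data.frame(region = c("IS5-6 linker", "IIS1"),
                    aa_start = c(300L, 400L), aa_end = c(320L, 430L))
  ev <- data.frame(kind = "deletion", nt_length = 12L, aa_start = 306L,
                   aa_end = 309L, aa_length = 4, region_label = NA_character_)
  out <- annotate_regions(ev, tab)
  expect_equal(out$region_label, "IS5-6 linker")
  ev2 <- transform(ev, aa_start = 2000L, aa_end = 2003L)
  expect_equal(annotate_regions(ev2, tab)$region_label, "unannotated")
  expect_equal(annotate_regions(ev, NULL)$region_label, "unannotated")
  # overlapping regions are rejected at load
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(region = c("a", "b"), aa_start = c(1, 10),
                         aa_end = c(20, 30)), bad, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_region_table(bad), "overlapping")
  # the shipped example table loads cleanly
  shipped <- system.file("extdata", "cav12_regions_synthetic.tsv",
                         package = "isoamp")
  expect_true(nzchar(shipped))
  reg <- load_region_table(shipped)
  expect_true(all(c("region", "aa_start", "aa_end") %in% names(reg)))
})

test_that("assess_coding classifies a model set against the reference chain", {
  mg <- toy_metagene()
  anchors <- list(cds_start = 100L, cds_end = 720L)
  models <- data.frame(chain = c("E1|E2|E3", "E1|E3", "E2|E3"),
                       transcript_id = c("ref", "skip", "trunc"),
                       stringsAsFactors = FALSE)
  out <- assess_coding(models, mg, anchors, "E1|E2|E3")
  expect_equal(out$classification[out$transcript_id == "ref"],
               ifelse(isoamp:::has_premature_stop(mg$seq), "putative_noncoding",
                      "putative_coding"))
  expect_equal(out$n_events[out$transcript_id == "ref"], 0L)
  # E2 is 90 nt (in frame); classification depends only on stops
  skiprow <- out[out$transcript_id == "skip", ]
  expect_equal(skiprow$frame_maintained, TRUE)
  expect_equal(out$classification[out$transcript_id == "trunc"],
               "incomplete_ends")
})
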