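# Synthetic locus and read generator: determinism, structural guarantees,
# error-model calibration.

test_that("simulate_locus is deterministic and writes byte-identical outputs", {
  cfg <- sim_config(seed = 123, libraries = default_libraries(depth = 10))
  a <- simulate_locus(cfg)
  b <- simulate_locus(cfg)
  expect_identical(as.character(a$genome[[1]]), as.character(b$genome[[1]]))
  expect_identical(a$exons, b$exons)
  d1 <- file.path(tempdir(), "locA"); d2 <- file.path(tempdir(), "locB")
  write_locus(a, d1); write_locus(b, d2)
  for (f in c("genome.fa", "annotation.gtf", "novel_exons.truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the locus respects the configured structure", {
  cfg <- sim_config(seed = 42, libraries = default_libraries(depth = 10))
  loc <- simulate_locus(cfg)
  expect_equal(nrow(loc$exons), cfg$n_exons)
  expect_equal(nrow(loc$novel_exons), cfg$n_novel_exons)
  expect_equal(length(loc$isoforms), cfg$n_isoforms)
  g <- as.character(loc$genome[[1]])
  # canonical introns: GT after each exon end, AG before each exon start
  for (i in seq_len(nrow(loc$exons) - 1L)) {
    expect_equal(substr(g, loc$exons$end[i] + 1L, loc$exons$end[i] + 2L), "GT")
    expect_equal(substr(g, loc$exons$start[i + 1L] - 1L,
                        loc$exons$start[i + 1L]), "AG")
  }
  # planted novel exons sit inside introns, >= 6 nt from annotated exons,
  # with canonical AG/GT flanks
  for (k in seq_len(nrow(loc$novel_exons))) {
    s <- loc$novel_exons$start[k]; e <- loc$novel_exons$end[k]
    expect_true(all(e <= loc$exons$start | s >= loc$exons$end))
    gaps <- c(s - loc$exons$end[loc$exons$end <= s],
              loc$exons$start[loc$exons$start >= e] - e)
    expect_gte(min(gaps), 6L)
    expect_equal(substr(g, s - 1L, s), "AG")
    expect_equal(substr(g, e + 1L, e + 2L), "GT")
  }
  # intended-coding isoforms have stop-free in-frame CDSs by construction
  for (i in seq_along(loc$isoforms)) {
    x <- loc$isoforms[[i]]
    if (isTRUE(x$coding_intent)) {
      sq <- isoamp:::spliced_sequence(x$intervals, loc$genome[[1]])
      expect_equal(nchar(sq) %% 3L, 0L)
      expect_false(isoamp:::has_premature_stop(sq))
      expect_equal(unname(loc$truth_class[i]), "putative_coding")
    }
  }
  # the frameshift deletion isoform is non-coding truth
  ids <- vapply(loc$isoforms, `[[`, character(1), "id")
  expect_equal(unname(loc$truth_class[grepl("fsdel", ids)]),
               "putative_noncoding")
})

test_that("a 9 nt novel exon is simulable (boundary case)", {
  cfg <- sim_config(seed = 8, n_novel_exons = 1L, novel_len_range = c(9L, 9L),
                    libraries = default_libraries(depth = 10))
  loc <- simulate_locus(cfg)
  expect_equal(loc$novel_exons$end - loc$novel_exons$start, 9L)
})

test_that("impossible novel-exon placement errors out with an explanation", {
  cfg <- sim_config(seed = 8, intron_len_range = c(31L, 40L),
                    novel_len_range = c(120L, 120L),
                    libraries = default_libraries(depth = 10))
  expect_error(simulate_locus(cfg), "cannot place novel exon")
})

test_that("read counts match library depths exactly and reads are
           deterministic given the seed", {
  libs <- default_libraries(depth = 30L)
  libs$depth <- c(100L, 25L, 30L, 30L, 30L, 27L)
  cfg <- sim_config(seed = 5, libraries = libs)
  loc <- simulate_locus(cfg)
  r1 <- simulate_reads(cfg, loc)
  expect_equal(unname(colSums(r1$counts)), libs$depth)
  expect_equal(as.integer(table(r1$reads$library_id)[libs$library_id]),
               libs$depth)
  expect_equal(nrow(r1$truth), sum(libs$depth))
  r2 <- simulate_reads(cfg, loc)
  expect_identical(r1$reads$seq, r2$reads$seq)
  expect_identical(r1$reads$qual, r2$reads$qual)
})

test_that("zero error rates reproduce the isoform sequences exactly", {
  cfg <- sim_config(seed = 9, libraries = default_libraries(depth = 5),
                    error_rates = c(sub = 0, ins = 0, del = 0),
                    junction_jitter = 0)
  loc <- simulate_locus(cfg)
  r <- simulate_reads(cfg, loc)
  iso_seq <- vapply(loc$isoforms, function(x)
    isoamp:::spliced_sequence(x$intervals, loc$genome[[1]]), character(1))
  names(iso_seq) <- vapply(loc$isoforms, `[[`, character(1), "id")
  m <- match(r$reads$read_id, r$truth$read_id)
  expect_identical(r$reads$seq, unname(iso_seq[r$truth$isoform_id[m]]))
})

test_that("realised read lengths match the indel-rate expectation", {
  del <- 0.05; ins <- 0.02
  cfg <- sim_config(seed = 14,
                    libraries = default_libraries(depth = 180L)[1:2, ],
                    error_rates = c(sub = 0.01, ins = ins, del = del),
                    junction_jitter = 0)
  loc <- simulate_locus(cfg)
  r <- simulate_reads(cfg, loc)
  iso_len <- vapply(loc$isoforms, function(x)
    sum(x$intervals$end - x$intervals$start), numeric(1))
  names(iso_len) <- vapply(loc$isoforms, `[[`, character(1), "id")
  L0 <- unname(iso_len[r$truth$isoform_id[match(r$reads$read_id,
                                                r$truth$read_id)]])
  # oracle: binomial expectation, length ~ L0 * (1 - del + ins)
  delta <- nchar(r$reads$seq) - L0 * (1 - del + ins)
  se <- sd(delta) / sqrt(length(delta))
  expect_lt(abs(mean(delta)), 3 * se + 0.5)
})

test_that("FASTQ round trip preserves sequences and q-scores", {
  cfg <- sim_config(seed = 3, libraries = default_libraries(depth = 5))
  loc <- simulate_locus(cfg)
  r <- simulate_reads(cfg, loc)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(r$reads, fq)
  back <- read_fastq(fq)
  m <- match(r$reads$read_id, back$read_id)
  expect_identical(back$seq[m], r$reads$seq)
  expect_equal(back$qscore[m], round(r$reads$qscore), tolerance = 0.51)
})

test_that("the cerebellum isoform switch shapes the abundance matrix", {
  cfg <- sim_config(seed = 21, libraries = default_libraries(depth = 10))
  loc <- simulate_locus(cfg)
  ab <- loc$abundance
  libs <- cfg$libraries
  cer <- libs$library_id[libs$tissue == "cerebellum"]
  ctx <- libs$library_id[libs$tissue == "cortex"]
  partner <- rownames(ab)[grepl("^iso_nov", rownames(ab))][1]
  ratio_ctx <- ab["iso_ref", ctx] / ab[partner, ctx]
  ratio_cer <- ab["iso_ref", cer] / ab[partner, cer]
  expect_true(all(ratio_ctx > 3))
  expect_true(all(ratio_cer < 1.5))
})
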