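# Exon-chain extraction, chain clustering ("longest possible variants"),
# abundance filters and deterministic naming/export.

paths_df <- function(chain, n, complete = TRUE, lib = "L1") {
  data.frame(read_id = paste0(chain, "_", lib, "_", seq_len(n)),
             chain = chain, complete_ends = complete, library_id = lib,
             stringsAsFactors = FALSE)
}

test_that("exon_path_from_cigar applies the 50% coverage rule", {
  mg <- toy_metagene()  # exon lengths 60, 90, 120
  ex <- mg$exons
  # full-length error-free read
  a <- make_aln("r1", 0L, paste0(nchar(mg$seq), "M"))
  p <- exon_paths(a, mg)
  expect_equal(p$chain, "E1|E2|E3")
  expect_true(p$complete_ends)
  # target gap exactly over E2
  a2 <- make_aln("r2", 0L, sprintf("%dM%dN%dM", ex$length[1], ex$length[2],
                                   ex$length[3]))
  expect_equal(exon_paths(a2, mg)$chain, "E1|E3")
  # read covering only 40% of E2 (36 of 90 nt) -> E2 excluded
  a3 <- make_aln("r3", 0L, sprintf("%dM%dN%dM", ex$length[1] + 36L,
                                   ex$length[2] - 36L, ex$length[3]))
  expect_equal(exon_paths(a3, mg)$chain, "E1|E3")
  # read covering 50% exactly -> included (threshold inclusive)
  a4 <- make_aln("r4", 0L, sprintf("%dM%dN%dM", ex$length[1] + 45L,
                                   ex$length[2] - 45L, ex$length[3]))
  expect_equal(exon_paths(a4, mg)$chain, "E1|E2|E3")
  # alignment covering no exon above threshold -> rejected and counted
  a5 <- make_aln("r5", ex$offset[2] + 80L, "20M")
  p5 <- exon_paths(a5, mg)
  expect_equal(nrow(p5), 0L)
  expect_equal(attr(p5, "n_rejected"), 1L)
})

test_that("cluster_paths absorbs end-truncations into the unique longer model", {
  p <- rbind(paths_df("E1|E2|E3", 10), paths_df("E2|E3", 2, complete = FALSE))
  m <- cluster_paths(p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$chain, "E1|E2|E3")
  expect_equal(m$support_total, 12)
})

test_that("internal skipping is never merged; both complete chains survive", {
  p <- rbind(paths_df("E1|E2|E3", 5), paths_df("E1|E3", 5))
  m <- cluster_paths(p)
  expect_equal(nrow(m), 2L)
  expect_setequal(m$chain, c("E1|E2|E3", "E1|E3"))
  expect_equal(m$support_total, c(5, 5))
})

test_that("a truncation compatible with two longer chains stays ambiguous", {
  p <- rbind(paths_df("E1|E2|E3|E4", 5), paths_df("E2|E3|E4|E5", 5),
             paths_df("E2|E3|E4", 3, complete = FALSE))
  m <- cluster_paths(p)
  expect_equal(nrow(m), 2L)
  expect_equal(m$support_total, c(5, 5))  # ambiguous reads not added
  amb <- attr(m, "ambiguous")
  expect_equal(nrow(amb), 3L)
  expect_equal(unique(amb$chain), "E2|E3|E4")
  # oracle: exhaustive containment check
  contains <- vapply(m$chain, function(mk)
    isoamp:::chain_is_infix("E2|E3|E4", mk), logical(1))
  expect_equal(sum(contains), 2L)
})

test_that("incomplete chains matching no model are unassigned", {
  p <- rbind(paths_df("E1|E2|E3", 5), paths_df("E1|E4", 2, complete = FALSE))
  m <- cluster_paths(p)
  expect_equal(nrow(attr(m, "unassigned")), 2L)
})

test_that("clustering conserves read support", {
  set.seed(31)
  chains <- c("E1|E2|E3|E4", "E1|E3|E4", "E1|E2|E4")
  p <- do.call(rbind, lapply(seq_along(chains), function(i)
    paths_df(chains[i], 5 + i, lib = sample(c("L1", "L2"), 1))))
  p2 <- rbind(p, paths_df("E2|E3|E4", 4, complete = FALSE))  # unique truncation
  m <- cluster_paths(p2)
  expect_equal(sum(m$support_total), nrow(p2))
  supp <- attr(m, "support")
  expect_equal(sum(supp), nrow(p2))
})

test_that("filter_transcripts applies the 24-read / 2-library / 100-read rules", {
  mk <- function(chain, per_lib) {
    keep <- which(per_lib > 0)
    do.call(rbind, lapply(keep, function(j)
      paths_df(chain, per_lib[j], lib = paste0("L", j))))
  }
  p <- rbind(mk("E1|E2|E3|E4|E5", c(12, 12)),    # 24 across 2 -> filtered
             mk("E1|E2|E3|E5", c(23, 0)),        # 23 reads -> out
             mk("E1|E2|E4|E5", c(150, 0)),       # 150 in 1 library -> out
             mk("E1|E3|E4|E5", c(50, 49)),       # 99 in 2 -> filtered only
             mk("E1|E2|E5", c(60, 41)),          # 101 -> high confidence
             mk("E1|E5", c(1, 0)))               # singleton -> always out
  m <- cluster_paths(p)
  sets <- filter_transcripts(m)
  expect_setequal(sets$filtered$chain,
                  c("E1|E2|E3|E4|E5", "E1|E3|E4|E5", "E1|E2|E5"))
  expect_equal(sets$high_confidence$chain, "E1|E2|E5")
  # monotonicity: raising min_reads never adds a transcript
  for (thr in c(24, 50, 80, 120)) {
    f <- filter_transcripts(m, min_reads = thr)$filtered$chain
    expect_true(all(f %in% sets$filtered$chain) || thr < 24)
  }
})

test_that("annotated status is exact two-way chain equality and novel naming
           is deterministic by support then chain order", {
  mg <- toy_metagene()
  cat <- toy_catalogue(mg)
  p <- rbind(paths_df("E1|E2|E3", 50), paths_df("E1|E3", 10),
             paths_df("E2|E3", 30), paths_df("E1|E2", 30))
  m <- name_models(cluster_paths(p), cat, "GENE1")
  expect_equal(m$transcript_id[m$chain == "E1|E2|E3"], "T1")
  expect_equal(m$status[m$chain == "E1|E2|E3"], "annotated")
  expect_equal(m$transcript_id[m$chain == "E1|E3"], "T2")
  # novel: same support 30 -> lexicographic chain order breaks the tie
  expect_equal(m$transcript_id[m$chain == "E1|E2"], "GENE1 n1")
  expect_equal(m$transcript_id[m$chain == "E2|E3"], "GENE1 n2")
  expect_true(all(m$status[m$transcript_id %in% c("GENE1 n1", "GENE1 n2")] ==
                    "novel"))
  # rerun on the same input gives identical ids
  m2 <- name_models(cluster_paths(p), cat, "GENE1")
  expect_identical(m2$transcript_id, m$transcript_id)
})

test_that("BED12 export reconstructs the exon chain intervals exactly", {
  mg <- toy_metagene()
  cat <- toy_catalogue(mg)
  p <- rbind(paths_df("E1|E2|E3", 30), paths_df("E1|E3", 25))
  m <- name_models(cluster_paths(p), cat, "GENE1")
  pre <- tempfile()
  export_models(m, mg, pre)
  bed <- rtracklayer::import(paste0(pre, ".bed"), format = "bed")
  blocks <- rtracklayer::blocks(bed)
  got <- lapply(blocks, function(b)
    paste(GenomicRanges::start(b) - 1L, GenomicRanges::end(b), sep = "-"))
  ex <- mg$exons
  want <- lapply(m$chain, function(ck) {
    d <- ex[match(isoamp:::chain_ids(ck), ex$exon_id), ]
    d <- d[order(d$start), ]
    paste(d$start, d$end, sep = "-")
  })
  names(want) <- m$transcript_id
  expect_equal(got[sort(names(got))], want[sort(names(want))])
  # GTF export reloads with the same transcript structure
  gr <- rtracklayer::import(paste0(pre, ".gtf"))
  expect_setequal(unique(gr$transcript_id), m$transcript_id)
})
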