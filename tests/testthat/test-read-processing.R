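mk_read <- function(seq, qual = strrep("I", nchar(seq)), id = "r1") {
  data.frame(id = id, sequence = seq, quality = qual)
}

A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("cleaning counters reproduce the generator ledger exactly", {
  p <- get_small_processed()
  ft <- p$study$truth$filter_truth
  for (lib in rownames(ft)) {
    s <- p$cleaned[[lib]]$stats
    expect_equal(s$removed_low_quality, ft[lib, "low_quality"])
    expect_equal(s$removed_5prime_contaminant, ft[lib, "contaminant5"])
    expect_equal(s$removed_no_3adapter_or_insert, ft[lib, "no_3adapter"])
    expect_equal(s$removed_short, ft[lib, "short"])
    expect_equal(s$raw_total,
                 s$clean_total + s$removed_low_quality +
                   s$removed_5prime_contaminant +
                   s$removed_no_3adapter_or_insert + s$removed_short)
    expect_equal(sum(s$length_histogram), s$clean_total)
  }
})

test_that("individual filter semantics follow the cascade order", {
  ins16 <- strrep("ACGT", 4) # 16 nt: below the 18-nt floor
  r <- clean_reads(mk_read(paste0(ins16, A3, "ACGTACGTACGTA")), A3, A5)
  expect_equal(r$stats$removed_short, 1L)
  expect_equal(r$stats$clean_total, 0L)

  perfect <- mk_read(paste0(strrep("ACTG", 6), A3, "AAAAA"))
  r <- clean_reads(perfect, A3, A5)
  expect_equal(r$stats$clean_total, 1L)
  expect_equal(unname(unlist(r$stats[grepl("removed", names(r$stats))])),
               rep(0L, 4))
  expect_equal(r$inserts$sequence, strrep("ACTG", 6))

  # low quality wins over every later filter
  lowq <- mk_read(paste0(ins16, A3), strrep("#", 16 + nchar(A3)))
  r <- clean_reads(lowq, A3, A5)
  expect_equal(r$stats$removed_low_quality, 1L)
  expect_equal(r$stats$removed_short, 0L)

  # a 5' contaminant is counted before the 3'-adapter check
  contam <- mk_read(paste0(substr(A5, 1, 8), strrep("C", 30)))
  r <- clean_reads(contam, A3, A5)
  expect_equal(r$stats$removed_5prime_contaminant, 1L)

  noad <- mk_read(strrep("ACTG", 10))
  r <- clean_reads(noad, A3, A5)
  expect_equal(r$stats$removed_no_3adapter_or_insert, 1L)
})

test_that("malformed records raise parse errors naming the read", {
  expect_error(clean_reads(mk_read("ACGT", "II", id = "bad1"), A3, A5),
               "bad1")
  expect_error(clean_reads(mk_read("ACXT", "IIII", id = "bad2"), A3, A5),
               "bad2")
})

test_that("tag collapsing counts and orders deterministically", {
  tags <- collapse_tags(list(lib1 = c("AAAT", "AAAT", "AAAT", "CCCG"),
                             lib2 = c("AAAT", "AAAT")))
  expect_equal(tags$sequence[1], "AAAT")
  expect_equal(tags$lib1[1], 3L)
  expect_equal(tags$lib2[1], 2L)
  expect_equal(tags$total, c(5L, 1L))
  # per-library conservation on the simulated study
  p <- get_small_processed()
  for (lib in names(p$cleaned))
    expect_equal(sum(p$tags[[lib]]), p$cleaned[[lib]]$stats$clean_total)
  # descending total, ties lexicographic
  expect_true(all(diff(p$tags$total) <= 0))
  ties <- split(p$tags$sequence, p$tags$total)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

test_that("length distribution is read-weighted and handles empty libraries", {
  tags <- collapse_tags(list(lib1 = rep(strrep("A", 22), 10),
                             lib2 = character(0)))
  ld <- length_distribution(tags)
  expect_equal(ld$freq[ld$library == "lib1" & ld$length == 22], 1)
  expect_true(all(is.na(ld$freq[ld$library == "lib2"])))
  expect_equal(sum(ld$count[ld$library == "lib2"]), 0)
})

test_that("exact mapping matches a naive all-positions scan on both strands", {
  set.seed(7)
  gs <- random_seq(2000)
  genome <- Biostrings::DNAStringSet(c(chr1 = gs))
  tag_plus <- substr(gs, 101, 122)
  tag_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 51, 72))))
  hits <- map_tags(c(tag_plus, tag_minus), genome)
  hp <- hits[hits$sequence == tag_plus & hits$strand == "+", ]
  expect_true(any(hp$start == 100 & hp$end == 122))
  hm <- hits[hits$sequence == tag_minus & hits$strand == "-", ]
  expect_true(any(hm$start == 50 & hm$end == 72))

  naive_scan <- function(tag, gs) {
    n <- nchar(tag); L <- nchar(gs)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
    out <- NULL
    for (s in seq_len(L - n + 1)) {
      w <- substr(gs, s, s + n - 1)
      if (w == tag) out <- rbind(out, data.frame(start = s - 1L, strand = "+"))
      if (w == rc) out <- rbind(out, data.frame(start = s - 1L, strand = "-"))
    }
    out
  }
  tags <- c(tag_plus, tag_minus,
            vapply(1:15, function(i) random_seq(sample(18:25, 1)), ""),
            substr(gs, 501, 524))
  hits <- map_tags(tags, genome)
  for (tg in unique(tags)) {
    got <- hits[hits$sequence == tg, c("start", "strand")]
    want <- naive_scan(tg, gs)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      got <- got[order(got$start, got$strand), ]
      want <- want[order(want$start, want$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("annotation follows the class priority and ignores record order", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 101, 501, 801),
                                                width = c(200, 200, 100, 120)),
                               type = c("rRNA", "pre_miRNA", "intron",
                                        "repeat_region"))
  hits <- data.frame(sequence = c("t1", "t2", "t3"), seqname = "chr1",
                     start = c(150L, 520L, 820L), end = c(172L, 542L, 842L),
                     strand = "+")
  tags <- data.frame(sequence = c("t1", "t2", "t3", "t4"))
  cls <- annotate_tags(tags, hits, gr)
  expect_equal(cls$class, c("rRNA", "intron", "repeat", "unannotated"))
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1)))
    expect_equal(annotate_tags(tags, hits, gr[perm])$class, cls$class)
})

test_that("per-class annotation totals equal the generator ledger", {
  p <- get_small_processed()
  ct <- p$study$truth$class_truth
  cls <- p$classes
  libs <- colnames(ct)
  got <- sapply(libs, function(lib) {
    vapply(rownames(ct), function(cl)
      sum(p$tags[[lib]][cls$class == cl]), numeric(1))
  })
  expect_equal(got, ct)
})
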