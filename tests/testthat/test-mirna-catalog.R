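test_that("catalog matching honours the 5'-anchored isomiR rule", {
  catalog <- data.frame(name = c("mir-a", "mir-b"),
                        sequence = c("ACGTACGTACGTACGTACGTAC", # 22 nt
                                     "TGCATGCATGCATGCATGCAT")) # 21 nt
  tags <- collapse_tags(list(
    l1 = c(rep("ACGTACGTACGTACGTACGTAC", 5),   # exact
           rep("ACGTACGTACGTACGTACGTA", 3),    # 3' -1 isomiR
           rep("ACGTACGTACGTACGTACGTACGT", 2), # 3' +2 isomiR
           rep("ACGTACGTACGTACGTACG", 1),      # -3: too short
           rep("CCGTACGTACGTACGTACGTAC", 4)))) # 5' mismatch
  mk <- match_known(tags, catalog)
  expect_equal(mk$records$l1[mk$records$mirna == "mir-a"], 10L)
  expect_equal(mk$records$l1[mk$records$mirna == "mir-b"], 0L)
  expect_setequal(mk$assignment$mirna, "mir-a")
  expect_error(match_known(tags, data.frame(name = c("x", "x"),
                                            sequence = c("A", "C"))),
               "duplicate")
})

test_that("per-miRNA counts equal the generator ledger", {
  p <- get_small_processed()
  study <- p$study
  mk <- match_known(p$tags, study$catalog)
  truth <- study$truth$counts
  libs <- study$config$library_names
  for (m in study$catalog$name)
    expect_equal(unname(unlist(mk$records[mk$records$mirna == m, libs])),
                 unname(truth[m, libs]))
})

test_that("the low-count filter uses 'at least 10 in some library'", {
  rec <- data.frame(mirna = c("a", "b", "c"),
                    l1 = c(9L, 0L, 10L), l2 = c(9L, 0L, 10L),
                    l3 = c(9L, 10L, 10L), l4 = c(9L, 0L, 10L))
  kept <- filter_low_count(rec)
  expect_setequal(kept$mirna, c("b", "c"))
})

test_that("hairpin folding matches exhaustive enumeration on short sequences", {
  f <- fold_hairpin("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$n_pairs, 3L)
  f <- fold_hairpin("AAAAAAAAAA")
  expect_equal(f$structure, "..........")
  expect_equal(f$mfe, 0)
  expect_error(fold_hairpin("ACGX"), "alphabet")

  en <- default_stack_energies()
  set.seed(11)
  for (i in 1:60) {
    s <- random_seq(sample(6:12, 1))
    f <- fold_hairpin(s)
    o <- oracle_fold(s)
    expect_equal(f$mfe, o$mfe, tolerance = 1e-9, label = s)
    # the returned structure's own stacked energy equals the reported MFE
    pr <- matrix(integer(0), 0, 2)
    st <- strsplit(f$structure, "")[[1]]
    stack <- integer(0)
    for (k in seq_along(st)) {
      if (st[k] == "(") stack <- c(stack, k)
      else if (st[k] == ")") {
        pr <- rbind(pr, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    expect_equal(oracle_stack_energy(strsplit(s, "")[[1]], pr, en), f$mfe,
                 tolerance = 1e-9)
    # tie-break: among MFE-optimal structures, pair count is maximal
    expect_equal(f$n_pairs, o$max_pairs_at_mfe, label = s)
    expect_equal(nchar(f$structure), nchar(s))
  }
})

test_that("MFE-only folding agrees with the structure-returning fold", {
  set.seed(3)
  seqs <- vapply(1:25, function(i) random_seq(sample(20:90, 1)), "")
  expect_equal(dtxmir:::fold_mfe_cpp(seqs,
                                     dtxmir:::stack16(default_stack_energies()),
                                     3L),
               vapply(seqs, function(s) fold_hairpin(s)$mfe, numeric(1),
                      USE.NAMES = FALSE))
})

test_that("dinucleotide shuffles preserve composition and endpoints", {
  set.seed(5)
  for (i in 1:10) {
    s <- random_seq(sample(10:60, 1))
    sh <- dinucleotide_shuffle(s, 5)
    dinuc <- function(x) {
      v <- strsplit(x, "")[[1]]
      sort(table(paste0(v[-length(v)], v[-1])))
    }
    for (x in sh) {
      expect_equal(dinuc(x), dinuc(s))
      expect_equal(substr(x, 1, 1), substr(s, 1, 1))
      expect_equal(substr(x, nchar(x), nchar(x)), substr(s, nchar(s), nchar(s)))
    }
  }
  expect_error(dinucleotide_shuffle("ACG"), "too short")
})

test_that("randomization p has the documented floor and determinism", {
  # a long perfect stem always beats its shuffles: p = 1/(n+1)
  set.seed(2)
  arm <- random_seq(28)
  stem <- paste0(arm, "TTCGAA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(arm))))
  expect_equal(randfold_test(stem, n_shuffles = 199, seed = 2), 1 / 200)
  expect_equal(randfold_test(stem, n_shuffles = 99, seed = 9), 1 / 100)
  p1 <- randfold_test(random_seq(40), 99, seed = 4)
  p2 <- randfold_test(random_seq(40), 99, seed = 4)
  expect_gte(p1, 1 / 100)
  expect_error(randfold_test("ACGTACGT", n_shuffles = 50), ">= 99")
  expect_error(randfold_test("ACG", 99), "too short")
})

test_that("novel discovery recovers a constructed hairpin and rejects noise", {
  set.seed(21)
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  loop <- "TCTCGGAT"
  lower <- random_seq(12)
  star <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mature)))
  substr(star, 5, 5) <- "A"
  pre <- paste0(lower, mature, loop, star,
                as.character(Biostrings::reverseComplement(Biostrings::DNAString(lower))))
  gs <- paste0(random_seq(1500), pre, random_seq(1500))
  genome <- Biostrings::DNAStringSet(c(chr1 = gs))
  bg_tag <- substr(gs, 301, 322)
  tags <- collapse_tags(list(l1 = c(rep(mature, 120), rep(bg_tag, 60))))
  hits <- map_tags(tags, genome)
  classes <- data.frame(sequence = tags$sequence, class = "unannotated")
  cand <- discover_novel(tags, classes, hits, genome, seed = 1)
  hp <- cand[cand$tag == mature, ]
  expect_equal(nrow(hp), 1L)
  expect_lt(hp$mfe, -19)
  expect_gt(hp$simplified_score, 1)
  expect_lt(hp$randfold_p, 0.05)
  # the mature arm is reported at its planted offset within the candidate
  expect_equal(substr(hp$sequence, hp$mature_start + 1L, hp$mature_end),
               mature)
  expect_equal(nchar(hp$structure), nchar(hp$sequence))
  acc <- filter_novel(cand)
  expect_true(mature %in% acc$tag)
})

test_that("the novel acceptance triple is strict on every boundary", {
  cand <- data.frame(tag = c("a", "b", "c", "d"),
                     simplified_score = c(1.5, 1.5, 1.0, 1.5),
                     randfold_p = c(0.01, 0.01, 0.01, 0.06),
                     mfe = c(-25, -19, -25, -25))
  acc <- filter_novel(cand)
  expect_equal(acc$tag, "a")
})
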