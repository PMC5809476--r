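test_that("seed scan classifies canonical site types at exact coordinates", {
  mir <- "UUCAGGAUGCGGAUCGAUCGAU" # seed (2-8) = UCAGGAU
  # 8mer: revcomp(seed) = ATCCTGA followed by A
  utr8 <- paste0(strrep("C", 20), "ATCCTGAA", strrep("C", 20))
  s <- seed_scan(mir, utr8)
  expect_equal(s$site_type, "8mer")
  expect_equal(c(s$start, s$end), c(20L, 28L))
  expect_equal(substr(utr8, s$start + 1, s$end), "ATCCTGAA")
  # 7mer-m8: no A; 7mer-A1: drop the m8 base
  s <- seed_scan(mir, paste0(strrep("C", 20), "ATCCTGA", strrep("G", 20)))
  expect_equal(s$site_type, "7mer-m8")
  s <- seed_scan(mir, paste0(strrep("G", 20), "TCCTGAA", strrep("G", 20)))
  expect_equal(s$site_type, "7mer-A1")
  # 6mer filtered out at the default threshold but visible when asked
  utr6 <- paste0(strrep("G", 20), "TCCTGAG", strrep("G", 20))
  expect_equal(nrow(seed_scan(mir, utr6)), 0L)
  expect_equal(seed_scan(mir, utr6, min_type = "6mer")$site_type, "6mer")
  expect_equal(nrow(seed_scan(mir, strrep("A", 50))), 0L)
})

test_that("seed-site counting matches a naive window scan on random UTRs", {
  set.seed(9)
  for (i in 1:10) {
    mir <- random_seq(22)
    utr <- random_seq(300)
    got <- seed_scan(mir, utr, min_type = "6mer")
    core <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(mir, 2, 7))))
    naive <- 0L
    for (s in 1:(nchar(utr) - 5))
      if (substr(utr, s, s + 5) == core) naive <- naive + 1L
    expect_equal(nrow(got), naive)
  }
})

test_that("alignment scoring reproduces the stated arithmetic", {
  set.seed(4)
  mir <- random_seq(22)
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mir)))
  utr <- paste0(random_seq(40), site, random_seq(40))
  a <- align_scan(mir, utr)
  expect_equal(max(a$align_score), 22 * 5 + 7 * 5) # 145: seed doubling
  expect_equal(a$start[which.max(a$align_score)], 40L)
  expect_equal(a$end[which.max(a$align_score)], 62L)
})

test_that("local alignment DP equals exhaustive enumeration on small cases", {
  set.seed(14)
  for (i in 1:30) {
    mir <- random_seq(8)
    utr <- random_seq(sample(8:12, 1))
    got <- align_scan(mir, utr, threshold = 1, max_sites = 1)
    want <- oracle_align(mir, utr)
    got_best <- if (nrow(got)) max(got$align_score) else 0
    if (want >= 1) expect_equal(got_best, want, label = paste(mir, utr))
    else expect_equal(nrow(got), 0L)
  }
})

test_that("duplex energies: stacking monotonicity and enumeration oracle", {
  set.seed(8)
  mir <- "GCGCAAGCUGCAAGGCAUCGAU"
  site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", mir))))
  utr <- paste0(random_seq(30), site, random_seq(30))
  perfect <- duplex_scan(mir, utr)
  expect_true(nrow(perfect) >= 1)
  e_perfect <- min(perfect$duplex_energy)
  # any single mismatch in the site weakens the duplex
  for (pos in c(5L, 11L, 18L)) {
    utr_mm <- utr
    old <- substr(utr_mm, 30 + pos, 30 + pos)
    substr(utr_mm, 30 + pos, 30 + pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    mm <- duplex_scan(mir, utr_mm, energy_max = 0)
    expect_gt(min(mm$duplex_energy), e_perfect)
  }
  for (i in 1:20) {
    mir <- random_seq(sample(6:10, 1))
    utr <- random_seq(sample(6:10, 1))
    got <- duplex_scan(mir, utr, energy_max = -0.1, min_pairs = 1L)
    want <- oracle_duplex(mir, utr)
    got_best <- if (nrow(got)) min(got$duplex_energy) else 0
    if (want <= -0.1) expect_equal(got_best, want, tolerance = 1e-9,
                                   label = paste(mir, utr))
    else expect_equal(nrow(got), 0L, label = paste(mir, utr))
  }
})

test_that("consensus requires all three predictors and Venn counts nest", {
  seed_sites <- data.frame(mirna = "m", transcript = "t", start = 10L,
                           end = 18L, site_type = "8mer")
  align_sites <- data.frame(mirna = "m", transcript = "t", start = 5L,
                            end = 20L, align_score = 100)
  duplex_sites <- data.frame(mirna = character(0), transcript = character(0),
                             start = integer(0), end = integer(0),
                             duplex_energy = numeric(0))
  two <- consensus_intersect(seed_sites, align_sites, duplex_sites)
  expect_false(any(two$sites$consensus))
  expect_equal(unname(two$venn[["seed_align"]]), 1L)
  expect_equal(unname(two$venn[["triple"]]), 0L)
  duplex_sites <- data.frame(mirna = "m", transcript = "t", start = 12L,
                             end = 25L, duplex_energy = -30)
  three <- consensus_intersect(seed_sites, align_sites, duplex_sites)
  expect_true(all(three$sites$consensus))
  expect_equal(unname(three$venn[["triple"]]), 1L)
  # non-overlapping or different-transcript calls never merge
  far <- consensus_intersect(
    seed_sites,
    data.frame(mirna = "m", transcript = "t", start = 100L, end = 120L,
               align_score = 90),
    data.frame(mirna = "m", transcript = "u", start = 10L, end = 20L,
               duplex_energy = -25))
  expect_equal(unname(far$venn[["triple"]]), 0L)
  expect_false(any(far$sites$consensus))
  # triple <= every pairwise on random inputs
  set.seed(31)
  rnd <- function(p) {
    n <- sample(3:12, 1)
    st <- sample(0:80, n, replace = TRUE)
    d <- data.frame(mirna = sample(c("m1", "m2"), n, TRUE),
                    transcript = sample(c("tA", "tB"), n, TRUE),
                    start = st, end = st + sample(6:15, n, TRUE))
    d[[p]] <- if (p == "site_type") "7mer-m8" else -25
    d
  }
  for (i in 1:10) {
    v <- consensus_intersect(rnd("site_type"), rnd("align_score"),
                             rnd("duplex_energy"))$venn
    expect_lte(v[["triple"]], min(v[["seed_align"]], v[["seed_duplex"]],
                                  v[["align_duplex"]]))
  }
})

test_that("reversing a UTR removes its plus-orientation sites", {
  set.seed(12)
  mir <- random_seq(22)
  site <- paste0(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(mir, 2, nchar(mir))))), "A")
  utr <- paste0(random_seq(60), site, random_seq(60))
  fwd <- seed_scan(mir, utr)
  expect_gte(nrow(fwd), 1L)
  rev_utr <- paste(rev(strsplit(utr, "")[[1]]), collapse = "")
  expect_equal(nrow(seed_scan(mir, rev_utr)), 0L)
})
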