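# Novel-miRNA discovery: hairpin excision around unannotated tag loci,
# folding, a simplified candidate score, and the randomization test.

db_pairs <- function(db) {
  s <- strsplit(db, "")[[1]]
  stack <- integer(0)
  res <- matrix(integer(0), 0L, 2L)
  for (i in seq_along(s)) {
    if (s[i] == "(") stack <- c(stack, i)
    else if (s[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      res <- rbind(res, c(j, i))
    }
  }
  res
}

#' Discover novel miRNA hairpin candidates from unannotated tags
#'
#' For each unannotated mapped tag with enough reads, excises the genomic
#' region around the tag locus with a 70-nt flank on the far side (the tag
#' taken as putative 5p arm and, separately, as putative 3p arm; the
#' better-folding excision is kept), trims the excision to the hairpin span
#' that pairs with the mature arm, folds it, and attaches a simplified score
#' `log2(tag count) + 1` if at least 60% of mature positions are paired
#' (a plausible star arm) and `log2(tag count) - 1` otherwise. The
#' [randfold_test()] p-value is computed on the two untrimmed excision
#' windows and Bonferroni-combined (`min(1, 2 min(p))`): keeping the
#' better-folding of two windows is a selection step that would otherwise
#' inflate the false-positive rate. The score is a documented
#' simplification (recorded as `simplified_score`), not a probabilistic
#' read-signature model.
#'
#' @param tags output of [collapse_tags()].
#' @param classes output of [annotate_tags()].
#' @param hits output of [map_tags()].
#' @param genome `DNAStringSet`.
#' @param params [pipeline_params()] (uses `novel_min_count`, `novel_flank`,
#'   `n_shuffles`).
#' @param energies stack-energy table.
#' @param seed integer seed for the randomization test substreams.
#' @return data.frame of hairpin candidates (one per tag): locus, sequence,
#'   structure, mfe, simplified_score, randfold_p, mature interval within the
#'   candidate (0-based half-open).
#' @export
discover_novel <- function(tags, classes, hits, genome,
                           params = pipeline_params(),
                           energies = default_stack_energies(),
                           seed = 1L) {
  un <- classes$sequence[classes$class == "unannotated"]
  cand_tags <- tags[tags$sequence %in% un &
                      tags$total >= params$novel_min_count, , drop = FALSE]
  flank <- params$novel_flank
  arm_off <- 15L # near-side flank: room for a few unpaired nt past the arm
  out <- list()
  for (r in seq_len(nrow(cand_tags))) {
    tseq <- cand_tags$sequence[r]
    h <- hits[hits$sequence == tseq, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[1L, ]
    chr_seq <- as.character(genome[[h$seqname]])
    Lc <- nchar(chr_seq)
    lo <- h$start - flank; hi <- h$end + flank # widest excision, 0-based
    if (lo < 0L || hi > Lc) {
      message("skipping candidate near contig edge: ", tseq)
      next
    }
    windows <- list(
      c(h$start - arm_off, h$end + flank),  # tag as 5p arm
      c(h$start - flank, h$end + arm_off))  # tag as 3p arm
    best <- NULL
    p_win <- numeric(2)
    for (wi in seq_along(windows)) {
      w <- windows[[wi]]
      wseq <- substr(chr_seq, w[1] + 1L, w[2])
      if (h$strand == "-") wseq <- revcomp(wseq)
      f <- fold_hairpin(wseq, energies)
      p_win[wi] <- randfold_test(wseq, params$n_shuffles,
                                 seed = derive_seed(seed, paste0(tseq, wi)),
                                 energies = energies)
      if (is.null(best) || f$mfe < best$mfe)
        best <- list(mfe = f$mfe, seq = wseq, str = f$structure, w = w)
    }
    # the better of two overlapping excisions is kept, so the randomization
    # p is Bonferroni-combined over the two windows
    p_rand <- min(1, 2 * min(p_win))
    # mature-arm coordinates inside the kept window (1-based)
    if (h$strand == "+") {
      m1 <- h$start - best$w[1] + 1L
    } else {
      m1 <- best$w[2] - h$end + 1L
    }
    m2 <- m1 + nchar(tseq) - 1L
    pr <- db_pairs(best$str)
    touch <- pr[pr[, 1] %in% m1:m2 | pr[, 2] %in% m1:m2, , drop = FALSE]
    if (nrow(touch)) {
      s1 <- min(min(touch), m1); s2 <- max(max(touch), m2)
    } else {
      s1 <- m1; s2 <- m2
    }
    cand_seq <- substr(best$seq, s1, s2)
    f <- fold_hairpin(cand_seq, energies)
    cm1 <- m1 - s1 + 1L; cm2 <- m2 - s1 + 1L
    cpr <- db_pairs(f$structure)
    paired <- unique(c(cpr[, 1], cpr[, 2]))
    frac_paired <- mean(cm1:cm2 %in% paired)
    score <- log2(cand_tags$total[r]) + if (frac_paired >= 0.6) 1 else -1
    out[[length(out) + 1L]] <- data.frame(
      tag = tseq, count = cand_tags$total[r],
      chrom = h$seqname, start = h$start, end = h$end, strand = h$strand,
      sequence = cand_seq, structure = f$structure, mfe = f$mfe,
      simplified_score = score, randfold_p = p_rand,
      mature_start = cm1 - 1L, mature_end = cm2)
  }
  if (!length(out))
    return(data.frame(tag = character(0), count = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), structure = character(0),
                      mfe = numeric(0), simplified_score = numeric(0),
                      randfold_p = numeric(0), mature_start = integer(0),
                      mature_end = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter hairpin candidates into accepted novel miRNAs
#'
#' Accepts a candidate iff simplified score > 1, randomization p-value
#' < 0.05 and MFE < -19 kcal/mol; all three inequalities strict, so a
#' candidate at exactly -19 kcal/mol or score exactly 1 is rejected.
#'
#' @param candidates output of [discover_novel()].
#' @param params [pipeline_params()] (uses `novel_score_min`,
#'   `novel_randfold_alpha`, `novel_mfe_max`).
#' @return the accepted rows.
#' @export
filter_novel <- function(candidates, params = pipeline_params()) {
  keep <- candidates$simplified_score > params$novel_score_min &
    candidates$randfold_p < params$novel_randfold_alpha &
    candidates$mfe < params$novel_mfe_max
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
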