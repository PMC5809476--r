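# Target prediction: three independent in-house predictors (canonical seed
# scan, position-weighted local alignment, intermolecular duplex energy) and
# the all-three consensus intersection. All three are documented
# simplifications with configurable thresholds; the "common spot" rule is
# >= 1 nt interval overlap on the same transcript for the same miRNA.

site_type_rank <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L,
                    "6mer" = 1L, none = 0L)

#' Canonical seed-site scan
#'
#' Finds exact matches on the UTR to the reverse complement of miRNA seed
#' positions: 2-8 (7mer-m8), 2-7 with an A opposite position 1 (7mer-A1),
#' both (8mer), or 2-7 alone (6mer). Intervals are 0-based half-open on the
#' UTR.
#'
#' @param mirna miRNA sequence (>= 8 nt; RNA or DNA alphabet).
#' @param utr UTR sequence.
#' @param min_type weakest site type reported (default "7mer": 7mer-A1,
#'   7mer-m8 and 8mer).
#' @return data.frame: start, end, site_type.
#' @export
seed_scan <- function(mirna, utr, min_type = "7mer") {
  mirna <- as_dna(mirna); utr <- as_dna(utr)
  if (nchar(mirna) < 8L) stopf("miRNA shorter than 8 nt")
  core6 <- revcomp(substr(mirna, 2L, 7L))        # matches positions 2-7
  m8c <- revcomp(substr(mirna, 8L, 8L))          # base pairing position 8
  hits <- gregexpr(core6, utr, fixed = TRUE)[[1]]
  out <- data.frame(start = integer(0), end = integer(0),
                    site_type = character(0))
  if (hits[1] == -1L) return(out)
  min_rank <- switch(min_type, "8mer" = 4L, "7mer" = 2L, "7mer-m8" = 3L,
                     "7mer-A1" = 2L, "6mer" = 1L,
                     stopf("unknown min_type: %s", min_type))
  for (s in as.integer(hits)) { # 1-based start of the 6mer core
    has_m8 <- s > 1L && substr(utr, s - 1L, s - 1L) == m8c
    has_a1 <- substr(utr, s + 6L, s + 6L) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    if (site_type_rank[[type]] < min_rank) next
    st <- if (has_m8) s - 2L else s - 1L       # 0-based
    en <- if (has_a1) s + 6L else s + 5L       # half-open
    out <- rbind(out, data.frame(start = st, end = en, site_type = type))
  }
  out
}

#' Position-weighted local alignment scan
#'
#' Smith-Waterman local alignment of the miRNA reverse complement against
#' the UTR: +5 Watson-Crick, +1 G:U, -4 mismatch, gap 8 at opening plus 2
#' per gapped nt, with substitution scores at miRNA seed positions (2-8)
#' doubled. Maximal-scoring non-overlapping sites above the threshold are
#' reported greedily best-first.
#'
#' @param mirna,utr sequences.
#' @param threshold minimum reported score (default 80).
#' @param max_sites cap on reported sites per UTR.
#' @return data.frame: start, end (0-based half-open on the UTR), align_score.
#' @export
align_scan <- function(mirna, utr, threshold = 80, max_sites = 10L) {
  d <- align_scan_cpp(as_dna(mirna), as_dna(utr), threshold,
                      as.integer(max_sites))
  data.frame(start = d$start, end = d$end, align_score = d$score)
}

#' Intermolecular duplex-energy scan
#'
#' Hybridizes the miRNA against the UTR (no intramolecular structure):
#' stacks of adjacent pairs contribute the stack-table energy, bulges and
#' internal loops are penalized per skipped nt, and windows at or below the
#' energy threshold are reported (minimal-energy, non-overlapping).
#'
#' @param mirna,utr sequences.
#' @param energies stack-energy table ([default_stack_energies()]).
#' @param energy_max reporting threshold, kcal/mol (default -20).
#' @param loop_pen per-nt bulge/internal-loop penalty, kcal/mol (default 3,
#'   the order of magnitude real internal loops cost, so scattered chance
#'   complementarity does not accumulate into spurious sites).
#' @param max_skip largest bulge considered on either strand (nt).
#' @param min_pairs minimum base pairs a reported site must engage (default
#'   12): a strong hybridization threshold like -20 kcal/mol is meant to
#'   reflect extensive complementarity, not a short GC-rich helix, so a
#'   site must pair a substantial part of the miRNA to be reported.
#' @return data.frame: start, end (0-based half-open), duplex_energy.
#' @export
duplex_scan <- function(mirna, utr, energies = default_stack_energies(),
                        energy_max = -20, loop_pen = 3, max_skip = 4L,
                        min_pairs = 12L) {
  d <- duplex_scan_cpp(as_dna(mirna), as_dna(utr), stack16(energies),
                       as.integer(round(loop_pen * 10)), energy_max,
                       as.integer(max_skip), as.integer(min_pairs))
  data.frame(start = d$start, end = d$end, duplex_energy = d$energy)
}

#' Intersect the three predictors into consensus sites
#'
#' Calls from different predictors merge when they concern the same miRNA
#' and transcript and their intervals overlap by >= 1 nt; each connected
#' component of merged intervals is one "spot". A spot is consensus iff all
#' three predictors contribute to it, which guarantees the triple Venn count
#' never exceeds any pairwise count.
#'
#' @param seed_sites,align_sites,duplex_sites data.frames with columns
#'   mirna, transcript, start, end plus their per-predictor evidence.
#' @return list with `sites` (one row per spot: interval, best seed type,
#'   best align score, best duplex energy, predictors_hit, consensus) and
#'   `venn` (per-predictor, pairwise and triple spot counts).
#' @export
consensus_intersect <- function(seed_sites, align_sites, duplex_sites) {
  tag <- function(d, p) if (nrow(d)) cbind(d[c("mirna", "transcript", "start",
                                               "end")], predictor = p) else NULL
  all <- rbind(tag(seed_sites, "seed"), tag(align_sites, "align"),
               tag(duplex_sites, "duplex"))
  sites <- NULL
  venn <- c(seed = 0L, align = 0L, duplex = 0L, seed_align = 0L,
            seed_duplex = 0L, align_duplex = 0L, triple = 0L)
  if (!is.null(all) && nrow(all)) {
    for (key in unique(paste(all$mirna, all$transcript, sep = "\r"))) {
      parts <- strsplit(key, "\r")[[1]]
      g <- all[all$mirna == parts[1] & all$transcript == parts[2], ]
      ir <- IRanges::IRanges(g$start + 1L, g$end)
      comp <- IRanges::reduce(ir)
      memb <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, comp))
      for (ci in seq_along(comp)) {
        rows <- g[memb == ci, , drop = FALSE]
        preds <- unique(rows$predictor)
        venn[preds] <- venn[preds] + 1L
        pairs <- list(c("seed", "align"), c("seed", "duplex"),
                      c("align", "duplex"))
        for (pp in pairs)
          if (all(pp %in% preds))
            venn[[paste(pp, collapse = "_")]] <-
              venn[[paste(pp, collapse = "_")]] + 1L
        if (length(preds) == 3L) venn[["triple"]] <- venn[["triple"]] + 1L
        sr <- seed_sites[seed_sites$mirna == parts[1] &
                           seed_sites$transcript == parts[2] &
                           seed_sites$start < IRanges::end(comp)[ci] &
                           seed_sites$end > IRanges::start(comp)[ci] - 1L, ,
                         drop = FALSE]
        best_type <- if (nrow(sr))
          sr$site_type[which.max(site_type_rank[sr$site_type])] else "none"
        ar <- align_sites[align_sites$mirna == parts[1] &
                            align_sites$transcript == parts[2] &
                            align_sites$start < IRanges::end(comp)[ci] &
                            align_sites$end > IRanges::start(comp)[ci] - 1L, ,
                          drop = FALSE]
        dr <- duplex_sites[duplex_sites$mirna == parts[1] &
                             duplex_sites$transcript == parts[2] &
                             duplex_sites$start < IRanges::end(comp)[ci] &
                             duplex_sites$end > IRanges::start(comp)[ci] - 1L, ,
                           drop = FALSE]
        sites <- rbind(sites, data.frame(
          mirna = parts[1], transcript = parts[2],
          start = IRanges::start(comp)[ci] - 1L, end = IRanges::end(comp)[ci],
          site_type = best_type,
          align_score = if (nrow(ar)) max(ar$align_score) else NA_real_,
          duplex_energy = if (nrow(dr)) min(dr$duplex_energy) else NA_real_,
          predictors_hit = paste(sort(preds), collapse = ","),
          consensus = length(preds) == 3L))
      }
    }
  }
  if (is.null(sites))
    sites <- data.frame(mirna = character(0), transcript = character(0),
                        start = integer(0), end = integer(0),
                        site_type = character(0), align_score = numeric(0),
                        duplex_energy = numeric(0),
                        predictors_hit = character(0), consensus = logical(0))
  rownames(sites) <- NULL
  list(sites = sites, venn = venn)
}

#' Predict targets for a set of miRNAs over a UTR set
#'
#' Runs all three predictors on every miRNA x UTR combination and
#' intersects them; optionally aggregates consensus sites to genes.
#'
#' @param mirnas named character vector (name -> mature sequence).
#' @param utrs `DNAStringSet` of 3'-UTRs.
#' @param params [pipeline_params()].
#' @param energies stack-energy table.
#' @param gene_map optional data.frame transcript -> gene for gene-level
#'   aggregation.
#' @return list: `sites`, `venn`, and `genes` (consensus target genes).
#' @export
predict_targets <- function(mirnas, utrs, params = pipeline_params(),
                            energies = default_stack_energies(),
                            gene_map = NULL) {
  seed_all <- align_all <- duplex_all <- NULL
  for (m in names(mirnas)) {
    for (u in names(utrs)) {
      useq <- as.character(utrs[[u]])
      s <- seed_scan(mirnas[[m]], useq, min_type = params$seed_site_min)
      if (nrow(s)) seed_all <- rbind(seed_all,
                                     cbind(mirna = m, transcript = u, s))
      a <- align_scan(mirnas[[m]], useq, threshold = params$align_threshold)
      if (nrow(a)) align_all <- rbind(align_all,
                                      cbind(mirna = m, transcript = u, a))
      d <- duplex_scan(mirnas[[m]], useq, energies,
                       energy_max = params$duplex_energy_max)
      if (nrow(d)) duplex_all <- rbind(duplex_all,
                                       cbind(mirna = m, transcript = u, d))
    }
  }
  mk <- function(x, extra) {
    base <- data.frame(mirna = character(0), transcript = character(0),
                       start = integer(0), end = integer(0))
    base[[extra]] <- numeric(0)
    if (is.null(x)) base else x
  }
  seed_all <- if (is.null(seed_all))
    data.frame(mirna = character(0), transcript = character(0),
               start = integer(0), end = integer(0),
               site_type = character(0)) else seed_all
  align_all <- mk(align_all, "align_score")
  duplex_all <- mk(duplex_all, "duplex_energy")
  cons <- consensus_intersect(seed_all, align_all, duplex_all)
  genes <- character(0)
  if (!is.null(gene_map)) {
    tx <- unique(cons$sites$transcript[cons$sites$consensus])
    genes <- sort(unique(gene_map$gene[match(tx, gene_map$transcript)]))
    cons$sites$gene <- gene_map$gene[match(cons$sites$transcript,
                                           gene_map$transcript)]
  }
  c(cons, list(genes = genes))
}
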