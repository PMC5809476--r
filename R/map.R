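# Exact genome mapping of clean tags and priority-rule annotation.

#' Map tags to the genome by exact full-length matching
#'
#' Reports all perfect, full-length matches on both strands. This
#' deliberately uses exact matching only, which keeps a brute-force
#' all-positions oracle enumerable; unmapped is a valid outcome.
#'
#' @param tags output of [collapse_tags()], or a character vector.
#' @param genome a `DNAStringSet`.
#' @return data.frame: sequence, seqname, start, end (0-based half-open,
#'   genomic plus-strand coordinates), strand.
#' @export
map_tags <- function(tags, genome) {
  seqs <- unique(if (is.data.frame(tags)) tags$sequence else tags)
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  empty <- data.frame(sequence = character(0), seqname = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  if (!length(seqs)) return(empty)
  out <- list(empty)
  for (w in unique(nchar(seqs))) {
    grp <- seqs[nchar(seqs) == w]
    dict <- Biostrings::PDict(Biostrings::DNAStringSet(grp))
    for (chr in names(genome)) {
      subj <- genome[[chr]]
      Lc <- length(subj)
      m <- Biostrings::matchPDict(dict, subj)
      nh <- S4Vectors::elementNROWS(m)
      if (sum(nh)) {
        ir <- unlist(m)
        out[[length(out) + 1L]] <- data.frame(
          sequence = rep(grp, nh), seqname = chr,
          start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
          strand = "+")
      }
      mR <- Biostrings::matchPDict(dict, Biostrings::reverseComplement(subj))
      nh <- S4Vectors::elementNROWS(mR)
      if (sum(nh)) {
        ir <- unlist(mR)
        out[[length(out) + 1L]] <- data.frame(
          sequence = rep(grp, nh), seqname = chr,
          start = Lc - IRanges::end(ir), end = Lc - IRanges::start(ir) + 1L,
          strand = "-")
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$seqname, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Annotation class priority
#'
#' Non-coding RNA classes outrank known miRNA, which outranks repeat, exon
#' and intron; a tag overlapping several feature classes receives the
#' highest-priority one. The order within the ncRNA block is fixed as listed.
#' @export
annotation_priority <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                         "known_miRNA", "repeat", "exon", "intron")

gff_class <- function(types) {
  map <- c(rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA",
           scRNA = "scRNA", pre_miRNA = "known_miRNA",
           miRNA = "known_miRNA", miRNA_primary_transcript = "known_miRNA",
           repeat_region = "repeat", "repeat" = "repeat",
           exon = "exon", intron = "intron")
  unname(map[as.character(types)])
}

#' Annotate tags by the class-priority rule
#'
#' A tag inherits the classes of every feature any of its genomic hits
#' overlaps by at least 1 nt (strand-agnostic) and is assigned the
#' highest-priority class per [annotation_priority]; tags without hits or
#' feature overlap are `unannotated`. Feature record order never affects the
#' result.
#'
#' @param tags output of [collapse_tags()] (or data.frame with `sequence`).
#' @param hits output of [map_tags()].
#' @param annotation `GRanges` with a `type` column (GFF3 semantics), e.g.
#'   from `rtracklayer::import()`.
#' @return data.frame: sequence, class.
#' @export
annotate_tags <- function(tags, hits, annotation) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  cls <- rep("unannotated", length(seqs))
  if (nrow(hits) && length(annotation)) {
    gr <- GenomicRanges::GRanges(hits$seqname,
                                 IRanges::IRanges(hits$start + 1L, hits$end))
    ov <- GenomicRanges::findOverlaps(gr, annotation, minoverlap = 1L,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      fclass <- gff_class(annotation$type[S4Vectors::subjectHits(ov)])
      pr <- match(fclass, annotation_priority)
      ti <- match(hits$sequence[S4Vectors::queryHits(ov)], seqs)
      keep <- !is.na(pr) & !is.na(ti)
      if (any(keep)) {
        best <- tapply(pr[keep], ti[keep], min)
        cls[as.integer(names(best))] <- annotation_priority[best]
      }
    }
  }
  data.frame(sequence = seqs, class = cls)
}
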