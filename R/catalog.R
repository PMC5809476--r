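# Known-miRNA identification and the abundance filter.

#' Match clean tags to a mature miRNA catalog
#'
#' A tag is assigned to a mature miRNA when its 5' end is identical over
#' positions 1-18 and its 3' end differs by at most 2 nt (isomiR tolerance;
#' the 5' end is held fixed because it defines the seed). A tag matching
#' several catalog entries goes to the one with the longest exact match,
#' ties broken by lexicographically first name. Counts are summed over
#' assigned tags per library.
#'
#' @param tags output of [collapse_tags()].
#' @param catalog data.frame with columns `name`, `sequence` (mature miRNAs;
#'   names must be unique).
#' @param prefix_len length of the exact 5' anchor (18).
#' @param tail_tol allowed 3'-length difference (2).
#' @return list with `records` (one row per catalog miRNA: per-library raw
#'   counts) and `assignment` (tag sequence -> miRNA name).
#' @export
match_known <- function(tags, catalog, prefix_len = 18L, tail_tol = 2L) {
  if (anyDuplicated(catalog$name))
    stopf("duplicate catalog names: %s",
          paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))
  cat_seq <- as_dna(catalog$sequence)
  libs <- setdiff(colnames(tags), c("sequence", "total"))
  key <- substr(cat_seq, 1L, prefix_len)
  by_key <- split(seq_along(cat_seq), key)
  tag_key <- substr(tags$sequence, 1L, prefix_len)
  assigned <- rep(NA_character_, nrow(tags))
  for (i in which(tag_key %in% names(by_key))) {
    tseq <- tags$sequence[i]
    cand <- by_key[[tag_key[i]]]
    cand <- cand[abs(nchar(cat_seq[cand]) - nchar(tseq)) <= tail_tol]
    if (!length(cand)) next
    mlen <- pmin(nchar(cat_seq[cand]), nchar(tseq))
    exact <- substr(cat_seq[cand], 1L, mlen) == substr(tseq, 1L, mlen)
    cand <- cand[exact]; mlen <- mlen[exact]
    if (!length(cand)) next
    ord <- order(-mlen, catalog$name[cand])
    assigned[i] <- catalog$name[cand[ord[1]]]
  }
  counts <- matrix(0L, nrow(catalog), length(libs),
                   dimnames = list(catalog$name, libs))
  hit <- !is.na(assigned)
  if (any(hit)) {
    for (l in libs) {
      s <- tapply(tags[[l]][hit], assigned[hit], sum)
      counts[names(s), l] <- as.integer(s)
    }
  }
  records <- data.frame(mirna = catalog$name, counts, check.names = FALSE)
  rownames(records) <- NULL
  list(records = records,
       assignment = data.frame(sequence = tags$sequence[hit],
                               mirna = assigned[hit]))
}

#' Abundance filter for known miRNAs
#'
#' A miRNA is retained iff its raw count reaches `min_count` in at least one
#' library (i.e. miRNAs with read count below 10 in all libraries are
#' removed).
#'
#' @param records `records` from [match_known()] (or any data.frame whose
#'   non-`mirna` numeric columns are per-library counts).
#' @param min_count retention threshold (default 10).
#' @return the retained rows.
#' @export
filter_low_count <- function(records, min_count = 10L) {
  libs <- setdiff(colnames(records), "mirna")
  keep <- apply(as.matrix(records[libs]), 1L, max) >= min_count
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
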