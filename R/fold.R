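# Hairpin folding, the stack-energy model, and the dinucleotide-shuffle
# randomization test that backs the novel-miRNA filter.

#' Stacking energy table
#'
#' A simplified per-stack energy model: each stack of two adjacent base pairs
#' contributes one energy keyed by its 5'-side (outer) pair; Watson-Crick and
#' G:U pairs are allowed, isolated pairs contribute nothing, and the minimum
#' hairpin loop is 3 nt. The table ships as a plain-text file and is not a
#' full nearest-neighbour parameter set: the workflow only consumes an MFE
#' threshold, and all numeric checks run against an exhaustive enumeration
#' oracle rather than published energies.
#'
#' @return named numeric vector of stack energies (kcal/mol) keyed by the
#'   outer pair written 5' base then 3' base (DNA alphabet).
#' @export
default_stack_energies <- function() {
  path <- system.file("extdata", "stack_energies.tsv", package = "dtxmir")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$energy, tab$pair)
}

# energies as the length-16 integer (tenth-kcal) vector the C++ kernels use
stack16 <- function(energies) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- integer(16)
  for (p in names(energies)) {
    a <- code[[substr(p, 1, 1)]]; b <- code[[substr(p, 2, 2)]]
    v[a * 4L + b + 1L] <- as.integer(round(energies[[p]] * 10))
  }
  v
}

#' Fold a sequence into its maximum-stability hairpin structure
#'
#' Dynamic-programming fold minimizing total stack energy (equivalently,
#' maximizing stacked-pair stability) under the [default_stack_energies()]
#' model with a minimum hairpin loop of 3 nt. Deterministic tie-breaking:
#' among co-optimal energies the structure with the most base pairs is
#' returned, and the traceback prefers 5'-most closing pairs.
#'
#' @param sequence DNA/RNA string (U accepted).
#' @param energies stack-energy table, see [default_stack_energies()].
#' @param min_loop minimum unpaired hairpin-loop length (nt).
#' @return list with `structure` (dot-bracket), `mfe` (kcal/mol, `<= 0`) and
#'   `n_pairs`.
#' @export
fold_hairpin <- function(sequence, energies = default_stack_energies(),
                         min_loop = 3L) {
  sequence <- as_dna(sequence)
  if (!grepl("^[ACGT]*$", sequence))
    stopf("invalid alphabet in sequence (expected A/C/G/T/U)")
  fold_hairpin_cpp(sequence, stack16(energies), as.integer(min_loop))
}

fold_mfe <- function(sequences, energies = default_stack_energies(),
                     min_loop = 3L) {
  fold_mfe_cpp(as_dna(sequences), stack16(energies), as.integer(min_loop))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffle: each shuffle has exactly the
#' dinucleotide (and hence mononucleotide) composition of the input, with the
#' first and last bases fixed. Uses the current RNG state.
#'
#' @param sequence DNA/RNA string of length >= 4.
#' @param n number of shuffles.
#' @return character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n = 1L) {
  sequence <- as_dna(sequence)
  s <- strsplit(sequence, "")[[1]]
  len <- length(s)
  if (len < 4L) stopf("sequence too short to shuffle (< 4 nt)")
  last <- s[len]
  verts <- unique(s)
  edges <- split(s[-1], factor(s[-len], levels = verts))
  out <- character(n)
  for (it in seq_len(n)) {
    # choose per-vertex terminal edges forming an arborescence toward `last`
    repeat {
      lastEdge <- lapply(edges, function(e)
        if (length(e)) e[[sample.int(length(e), 1L)]] else NA_character_)
      ok <- TRUE
      for (v in verts) {
        if (v == last || !length(edges[[v]])) next
        seen <- character(0); cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(lastEdge[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- lastEdge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute remaining edges, terminal edge last
    pools <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (!length(e)) return(character(0))
      if (v == last) return(if (length(e) > 1L) sample(e) else e)
      le <- lastEdge[[v]]
      i <- match(le, e)
      rest <- e[-i]
      if (length(rest) > 1L) rest <- sample(rest)
      c(rest, le)
    })
    names(pools) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    res <- character(len)
    res[1] <- s[1]
    cur <- s[1]
    for (i in 2:len) {
      nxt <- pools[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    out[it] <- paste(res, collapse = "")
  }
  out
}

#' Randomization test for folding stability (randfold-style)
#'
#' Empirical p-value comparing the observed MFE with MFEs of
#' dinucleotide-preserving shuffles:
#' `p = (1 + #\{shuffles with MFE <= observed\}) / (1 + n_shuffles)`,
#' so p is bounded below by `1/(n_shuffles + 1)`.
#'
#' @param sequence DNA/RNA string (>= 4 nt).
#' @param n_shuffles number of shuffles (>= 99).
#' @param seed integer seed for the shuffle stream.
#' @param energies stack-energy table.
#' @return the empirical p-value.
#' @export
randfold_test <- function(sequence, n_shuffles = 199L, seed = 1L,
                          energies = default_stack_energies()) {
  if (n_shuffles < 99L) stopf("n_shuffles must be >= 99")
  if (nchar(sequence) < 4L) stopf("sequence too short to shuffle (< 4 nt)")
  obs <- fold_mfe(sequence, energies)
  shuf <- with_seed(seed, dinucleotide_shuffle(sequence, n_shuffles))
  mfes <- fold_mfe(shuf, energies)
  (1 + sum(mfes <= obs)) / (1 + n_shuffles)
}
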