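# Independent oracles used across the suite. These deliberately take the
# slow, enumerable route (direct summation, exhaustive structure /
# alignment enumeration, exact hypergeometric sums) so the dynamic
# programming and log-space implementations are checked against something
# that cannot share their bugs.

# --- exact-test oracle: direct summation of binomial-form point masses ----
oracle_ac_point <- function(y, x, r) {
  r^y * choose(x + y, y) / (1 + r)^(x + y + 1)
}

oracle_ac <- function(x, y, n1, n2) {
  r <- n2 / n1
  C <- sum(oracle_ac_point(0:y, x, r))
  p_obs <- oracle_ac_point(y, x, r)
  D <- 1 - C + p_obs
  list(C = C, D = D, p_value = min(1, 2 * min(C, D)))
}

# --- folding oracle: exhaustive enumeration of nested structures ----------
oracle_pairable <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

# all sets of non-crossing pairs on s[i..j] with hairpin loops >= min_loop;
# returns a list of k x 2 matrices (possibly the empty matrix)
oracle_structures <- function(s, i, j, min_loop = 3L) {
  if (j - i < min_loop + 1L) return(list(matrix(integer(0), 0L, 2L)))
  out <- oracle_structures(s, i + 1L, j, min_loop) # i unpaired
  for (k in seq(i + min_loop + 1L, j)) {
    if (!oracle_pairable(s[i], s[k])) next
    inner <- oracle_structures(s, i + 1L, k - 1L, min_loop)
    outer <- oracle_structures(s, k + 1L, j, min_loop)
    for (a in inner) for (b in outer)
      out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
  }
  out
}

oracle_stack_energy <- function(s, pairs, energies) {
  if (nrow(pairs) == 0L) return(0)
  key <- paste(pairs[, 1], pairs[, 2])
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    if (paste(pairs[r, 1] + 1L, pairs[r, 2] - 1L) %in% key)
      e <- e + energies[[paste0(s[pairs[r, 1]], s[pairs[r, 2]])]]
  }
  e
}

oracle_fold <- function(seq, energies = dtxmir::default_stack_energies(),
                        min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  structs <- oracle_structures(s, 1L, length(s), min_loop)
  es <- vapply(structs, oracle_stack_energy, numeric(1), s = s,
               energies = energies)
  best <- min(es)
  npairs <- vapply(structs, nrow, integer(1))
  list(mfe = round(best, 10),
       max_pairs_at_mfe = max(npairs[abs(es - best) < 1e-9]))
}

# --- duplex oracle: exhaustive monotone pairings --------------------------
# mirrors the duplex model: stacks keyed by the previous pair, per-nt loop
# penalty, bounded skips, free ends
oracle_duplex <- function(mirna, utr, energies = dtxmir::default_stack_energies(),
                          loop_pen = 3, max_skip = 4L) {
  a <- strsplit(mirna, "")[[1]]
  bR <- rev(strsplit(utr, "")[[1]]) # reversed target
  m <- length(a); n <- length(bR)
  comp <- oracle_pairable
  best <- Inf
  extend <- function(i, j, acc) {
    best <<- min(best, acc)
    for (di in 1:(max_skip + 1L)) for (dj in 1:(max_skip + 1L)) {
      i2 <- i + di; j2 <- j + dj
      if (i2 > m || j2 > n) next
      if (!comp(a[i2], bR[j2])) next
      cost <- if (di == 1L && dj == 1L) energies[[paste0(a[i], bR[j])]] else
        loop_pen * ((di - 1L) + (dj - 1L))
      extend(i2, j2, acc + cost)
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n))
    if (comp(a[i], bR[j])) extend(i, j, 0)
  if (is.infinite(best)) 0 else round(best, 10)
}

# --- local alignment oracle: exhaustive column enumeration ----------------
# columns are aligned (query, target) index pairs, strictly increasing;
# between consecutive columns at most one of the two sequences may skip
# (gap of length L costs 8 + 2L); substitution +5 WC / +1 G:U / -4, doubled
# at miRNA seed positions.
oracle_align <- function(mirna, utr) {
  L <- nchar(mirna)
  qc <- chartr("ACGT", "TGCA", paste(rev(strsplit(mirna, "")[[1]]),
                                     collapse = ""))
  q <- strsplit(qc, "")[[1]]
  t <- strsplit(utr, "")[[1]]
  seed_mul <- ifelse((L - seq_len(L) + 1L) >= 2 & (L - seq_len(L) + 1L) <= 8,
                     2L, 1L)
  sub <- function(i, j) {
    s <- if (q[i] == t[j]) 5 else if ((q[i] == "C" && t[j] == "T") ||
                                        (q[i] == "A" && t[j] == "G")) 1 else -4
    s * seed_mul[i]
  }
  gap <- function(len) if (len > 0L) -(8 + 2 * len) else 0
  best <- 0
  extend <- function(i, j, acc) {
    best <<- max(best, acc)
    if (i >= length(q) || j >= length(t)) return(invisible())
    for (i2 in (i + 1L):length(q)) for (j2 in (j + 1L):length(t)) {
      gq <- i2 - i - 1L; gt <- j2 - j - 1L
      if (gq > 0L && gt > 0L) next # DP cannot chain both gap types
      extend(i2, j2, acc + gap(gq) + gap(gt) + sub(i2, j2))
    }
  }
  for (i in seq_along(q)) for (j in seq_along(t))
    extend(i, j, sub(i, j))
  best
}

# --- hypergeometric upper tail by exact enumeration -----------------------
oracle_hyper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
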