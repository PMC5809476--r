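# Synthetic-study generator: reference genome with embedded small-RNA loci,
# miRNA catalog, four FASTQ read libraries with planted cleaning failures and
# fold-changes, a 3'-UTR set with planted target sites, term-annotation maps
# with planted enriched terms, and a qPCR Ct table -- all recorded in a
# machine-readable ground-truth ledger.

# internal feature layout (counts and length ranges, nt)
feature_spec <- function() {
  list(rRNA  = list(n = 3L, len = c(300L, 800L)),
       tRNA  = list(n = 6L, len = c(72L, 90L)),
       snRNA = list(n = 4L, len = c(100L, 160L)),
       snoRNA = list(n = 4L, len = c(80L, 130L)),
       "repeat" = list(n = 5L, len = c(200L, 400L)),
       exon  = list(n = 12L, len = c(150L, 400L)),
       intron = list(n = 12L, len = c(100L, 400L)))
}

# clean-read mass given to the genomic pool classes (fractions of clean reads)
pool_fracs <- c(rRNA = 0.08, tRNA = 0.05, snRNA = 0.02, snoRNA = 0.02,
                "repeat" = 0.012, exon = 0.012, intron = 0.012)

gff_type_for_class <- c(rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA",
                        snoRNA = "snoRNA", "repeat" = "repeat_region",
                        exon = "exon", intron = "intron")

# a trimmed insert is acceptable iff the cleaning scanner would recover it
# exactly: the first qualifying 3'-adapter hit sits at the insert boundary and
# the read does not begin with a 5'-adapter prefix
inserts_ok <- function(ins, adapter3, adapter5, prefix = 8L) {
  reads <- paste0(ins, adapter3)
  pos <- adapter3_pos_cpp(reads, adapter3, 6L, 1L)
  pos == nchar(ins) & substr(ins, 1L, prefix) != substr(adapter5, 1L, prefix)
}

sample_gap_insert <- function(n, genome_str, gaps, len_fun, cfg) {
  out <- character(n)
  need <- seq_len(n)
  gw <- IRanges::width(gaps)
  while (length(need)) {
    lens <- len_fun(length(need))
    idx <- which(gw >= max(lens) + 2L)
    gi <- idx[sample.int(length(idx), length(need), replace = TRUE,
                         prob = gw[idx] - max(lens))]
    st <- IRanges::start(gaps)[gi] +
      floor(stats::runif(length(need)) * (gw[gi] - lens))
    cand <- substring(genome_str, st, st + lens - 1L)
    good <- inserts_ok(cand, cfg$adapter3, cfg$adapter5)
    out[need[good]] <- cand[good]
    need <- need[!good]
  }
  out
}

# Sample recurring background (decoy) tags whose excision windows are
# certifiably unstructured: the windows a discovery stage would fold must
# not be exceptional against their own dinucleotide shuffles, otherwise the
# "decoy" would in truth be a chance hairpin and the ledger would be wrong.
sample_decoy_tags <- function(n, genome_str, gaps, cfg,
                              energies = default_stack_energies(),
                              flank = 70L, arm = 15L, n_shuf = 49L,
                              p_min = 0.3) {
  out <- character(n)
  got <- 0L
  gw <- IRanges::width(gaps)
  G <- nchar(genome_str)
  while (got < n) {
    len <- sample(20:24, 1L)
    idx <- which(gw >= len + 2L)
    gi <- idx[sample.int(length(idx), 1L, prob = gw[idx] - len)]
    st <- IRanges::start(gaps)[gi] +
      floor(stats::runif(1) * (gw[gi] - len)) # 1-based
    seq <- substring(genome_str, st, st + len - 1L)
    if (!inserts_ok(seq, cfg$adapter3, cfg$adapter5)) next
    if (seq %in% out[seq_len(got)]) next
    lo <- st - flank; hi <- st + len - 1L + flank
    if (lo < 1L || hi > G) next
    windows <- list(c(st - arm, st + len - 1L + flank),
                    c(st - flank, st + len - 1L + arm))
    ok <- TRUE
    for (w in windows) {
      ws <- substring(genome_str, w[1], w[2])
      obs <- fold_mfe(ws, energies)
      shm <- fold_mfe(dinucleotide_shuffle(ws, n_shuf), energies)
      if ((1 + sum(shm <= obs)) / (1 + n_shuf) < p_min) { ok <- FALSE; break }
    }
    if (!ok) next
    got <- got + 1L
    out[got] <- seq
  }
  out
}

sample_pool_insert <- function(n, fc, genome_str, cfg) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    lens <- sample(18:30, length(need), replace = TRUE)
    li <- sample.int(nrow(fc), length(need), replace = TRUE)
    st <- fc$start[li] + floor(stats::runif(length(need)) * (fc$len[li] - lens))
    cand <- substring(genome_str, st, st + lens - 1L)
    ok <- inserts_ok(cand, cfg$adapter3, cfg$adapter5)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate the synthetic reference genome, annotation and miRNA catalog
#'
#' Places non-overlapping precursor-miRNA loci (known and novel), rRNA / tRNA
#' / snRNA / snoRNA loci, repeats, exons and introns on a random genome.
#' Precursors are constructed hairpins: a mature arm, a short loop, and a
#' near-reverse-complement star arm, so they fold stably and are recoverable
#' by the discovery stage. Known precursors are written to the annotation;
#' novel ones are left unannotated on purpose. Deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (DNAStringSet), `annotation` (GRanges, GFF3
#'   semantics), `catalog` (known mature miRNAs), and `truth` (ledger so far).
#' @export
generate_genome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, "genome"), {
    n_mir <- cfg$n_known_mirnas + cfg$n_novel_mirnas
    # mature sequences, validated against the cleaning definitions and with
    # unique 18-nt 5' prefixes so catalogue matching is unambiguous
    matures <- character(0)
    while (length(matures) < n_mir) {
      lens <- sample(c(21L, 22L, 23L), n_mir, replace = TRUE,
                     prob = c(0.2, 0.6, 0.2))
      cand <- random_dna(n_mir, 23L)
      cand <- substr(cand, 1L, lens)
      cand <- cand[inserts_ok(cand, cfg$adapter3, cfg$adapter5)]
      matures <- c(matures, cand)
      matures <- matures[!duplicated(substr(matures, 1L, 18L))]
    }
    matures <- matures[seq_len(n_mir)]
    loops <- random_dna(n_mir, 10L)
    stars <- vapply(matures, function(m) {
      s <- strsplit(revcomp(m), "")[[1]]
      idx <- sample(3:(length(s) - 2L), 2L)
      for (i in idx) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
      paste(s, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    # lower stem extending beyond the mature arm, as in real pre-miRNAs:
    # the hairpin is mature-arm length + ~12 bp deep on each side
    lower <- random_dna(n_mir, 12L)
    precursors <- paste0(lower, matures, loops, stars, revcomp(lower))
    mature_offset <- 12L

    fs <- feature_spec()
    feat <- do.call(rbind, lapply(names(fs), function(cl) {
      data.frame(class = cl,
                 len = sample(seq(fs[[cl]]$len[1], fs[[cl]]$len[2]),
                              fs[[cl]]$n, replace = TRUE))
    }))
    mir_feat <- data.frame(class = "pre_miRNA", len = nchar(precursors))
    feat <- rbind(mir_feat, feat)
    if (10 * sum(feat$len) > cfg$genome_length)
      stopf(paste("placement failure: config infeasible, genome_length must be",
                  ">= 10x the total planted feature length (%d < 10 x %d)"),
            cfg$genome_length, sum(feat$len))
    occupied <- IRanges::IRanges()
    starts <- integer(nrow(feat))
    for (i in seq_len(nrow(feat))) {
      placed <- FALSE
      for (att in 1:2000) {
        st <- sample.int(cfg$genome_length - feat$len[i] - 1L, 1L)
        cand <- IRanges::IRanges(st, width = feat$len[i] + 10L)
        if (!length(IRanges::findOverlaps(cand, occupied))) {
          occupied <- c(occupied, cand)
          starts[i] <- st
          placed <- TRUE
          break
        }
      }
      if (!placed) stopf("placement failure: cannot place features without overlap")
    }
    feat$start <- starts # 1-based
    genome_str <- random_dna(1L, cfg$genome_length)
    for (i in seq_len(n_mir)) {
      st <- feat$start[i]
      substr(genome_str, st, st + nchar(precursors[i]) - 1L) <- precursors[i]
    }

    is_novel <- c(rep(FALSE, cfg$n_known_mirnas), rep(TRUE, cfg$n_novel_mirnas))
    mir_names <- ifelse(is_novel,
                        sprintf("sim-novel-%02d", cumsum(is_novel)),
                        sprintf("sim-miR-%03d", cumsum(!is_novel)))
    mirna_truth <- data.frame(
      name = mir_names, mature = matures, star = stars,
      precursor = precursors, is_novel = is_novel,
      chrom = "chr1", start = feat$start[seq_len(n_mir)] - 1L, # 0-based
      end = feat$start[seq_len(n_mir)] - 1L + nchar(precursors),
      mature_offset = mature_offset, strand = "+")

    de_names <- sample(mir_names[!is_novel], cfg$n_de_mirnas)
    lfc <- cfg$de_log2fc
    rownames(lfc) <- de_names

    other <- feat[-seq_len(n_mir), ]
    known <- !mirna_truth$is_novel
    anno <- GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(c(mirna_truth$start[known] + 1L, other$start),
                       width = c(nchar(precursors[known]), other$len)),
      strand = "+",
      type = c(rep("pre_miRNA", sum(known)),
               gff_type_for_class[other$class]),
      ID = c(mirna_truth$name[known],
             sprintf("%s_%02d", other$class, stats::ave(
               seq_len(nrow(other)), other$class, FUN = seq_along))))

    all_feats <- IRanges::reduce(IRanges::IRanges(feat$start, width = feat$len))
    gaps <- IRanges::gaps(all_feats, start = 1L, end = cfg$genome_length)
    gaps <- gaps[IRanges::width(gaps) >= 40L]

    catalog <- data.frame(name = mirna_truth$name[known],
                          sequence = mirna_truth$mature[known],
                          precursor_name = paste0(mirna_truth$name[known], "-pre"),
                          arm = "5p")
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))
    list(genome = genome, annotation = anno, catalog = catalog,
         truth = list(mirna_truth = mirna_truth, de_names = de_names,
                      de_log2fc = lfc, features = feat, gaps = gaps))
  })
}

rand_quals <- function(n, len, n_low = 0L) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    q <- sample(30:40, len, replace = TRUE)
    if (n_low > 0L) q[sample.int(len, n_low)] <- sample(2:15, n_low, TRUE)
    intToUtf8(q + 33L)
  }, character(1))
}

#' Generate the raw FASTQ read libraries
#'
#' Each read is insert + 3' adapter + random filler at a fixed raw read
#' length, with Phred+33 qualities. Clean-intended reads are allocated to
#' ground-truth classes (individual miRNAs, piRNA-like 28-nt tags, genomic
#' pool classes, recurring decoy tags, background) by a single multinomial
#' draw per library; cleaning failures (low-quality, 5' contaminant, missing
#' 3' adapter, short insert) are planted at exactly the configured counts.
#' Differentially expressed miRNAs carry the configured fold-changes, with
#' up- and down-regulated mass balanced so the planted per-miRNA fold-changes
#' are not confounded by global composition shifts.
#'
#' @param cfg a [sim_config()].
#' @param gen output of [generate_genome()].
#' @return list with `libraries` (per library data.frame id/sequence/quality),
#'   `filter_truth`, realized per-atom `counts`, expected counts and the
#'   annotation-class ledger.
#' @export
generate_read_libraries <- function(cfg, gen) {
  with_seed(derive_seed(cfg$seed, "reads"), {
    genome_str <- as.character(gen$genome[[1]])
    tr <- gen$truth
    libs <- cfg$library_names
    N <- cfg$reads_per_library
    fail_n <- c(low_quality = round(cfg$frac_quality_fail * N),
                contaminant5 = round(cfg$frac_5contaminant * N),
                no_3adapter = round(cfg$frac_no3adapter * N),
                short = round(cfg$frac_short * N))
    if (sum(fail_n) >= N) stopf("reads_per_library smaller than planted failure total")
    clean_n <- N - sum(fail_n)

    mt <- tr$mirna_truth
    n_known <- sum(!mt$is_novel); n_novel <- sum(mt$is_novel)
    de_idx <- match(tr$de_names, mt$name)
    # expected control counts: log-uniform for non-DE known miRNAs (so both
    # high-abundance and sub-threshold miRNAs exist); DE and novel miRNAs in
    # the upper range so the power / discovery study conditions are met
    # (floors scale with library depth; at the default depth they are 110
    # and 55 expected control reads)
    de_floor <- 0.00564 * clean_n
    nov_floor <- 0.00282 * clean_n
    for (attempt in 1:100) {
      raw <- numeric(nrow(mt))
      nonde <- setdiff(which(!mt$is_novel), de_idx)
      raw[nonde] <- 10^stats::runif(length(nonde), log10(0.4), log10(400))
      raw[de_idx] <- stats::runif(length(de_idx), 180, 300)
      down <- rowMeans(tr$de_log2fc) < 0
      raw[de_idx[down]] <- raw[de_idx[down]] * 4 # mass-balances +/-2 designs
      raw[mt$is_novel] <- stats::runif(n_novel, 120, 300)
      s <- (cfg$frac_len22_peak * clean_n) / sum(raw)
      lam <- raw * s
      if (cfg$n_de_mirnas == 0L ||
          (min(lam[de_idx]) >= de_floor &&
           (n_novel == 0L || min(lam[mt$is_novel]) >= nov_floor))) break
      if (attempt == 100L)
        stopf("could not satisfy the expected-count floors; config too small")
    }
    # per-library expected miRNA counts
    lam_lib <- matrix(lam, nrow = nrow(mt), ncol = length(libs),
                      dimnames = list(mt$name, libs))
    for (j in seq_along(tr$de_names))
      lam_lib[de_idx[j], -1] <- lam[de_idx[j]] * 2^tr$de_log2fc[j, ]

    # fixed recurring tag sets
    pi_seqs <- sample_gap_insert(40L, genome_str, tr$gaps,
                                 function(n) rep(28L, n), cfg)
    pi_w <- 10^stats::runif(40L, 0, log10(400))
    pi_lam <- pi_w / sum(pi_w) * cfg$frac_len28_peak * clean_n
    decoy_seqs <- sample_decoy_tags(cfg$n_decoy_tags, genome_str, tr$gaps, cfg)
    decoy_lam <- stats::runif(cfg$n_decoy_tags, 15, 60)

    pool_lam <- pool_fracs * clean_n
    feat_by_class <- split(tr$features[-seq_len(nrow(mt)), ],
                           tr$features$class[-seq_len(nrow(mt))])

    atoms <- c(mt$name, sprintf("piRNA_like_%02d", 1:40),
               sprintf("decoy_%02d", seq_len(cfg$n_decoy_tags)),
               names(pool_lam), "background")
    counts <- matrix(0L, length(atoms), length(libs),
                     dimnames = list(atoms, libs))
    expected <- counts
    libraries <- list()
    prefix5 <- substr(cfg$adapter5, 1L, 8L)

    for (lib in libs) {
      w <- c(lam_lib[, lib], pi_lam, decoy_lam, pool_lam)
      bg <- clean_n - sum(w)
      if (bg <= 0) stopf("class masses exceed the clean-read budget; lower the peak fractions")
      w <- c(w, background = bg)
      expected[, lib] <- w
      k <- as.integer(stats::rmultinom(1L, clean_n, w / sum(w)))
      counts[, lib] <- k
      names(k) <- atoms

      fixed_seqs <- c(mt$mature, pi_seqs, decoy_seqs)
      ins <- rep(fixed_seqs, k[seq_along(fixed_seqs)])
      cls <- rep(atoms[seq_along(fixed_seqs)], k[seq_along(fixed_seqs)])
      # genomic pool classes: random substrings of their loci
      for (cl in names(pool_lam)) {
        nk <- k[[cl]]
        if (nk == 0L) next
        ins <- c(ins, sample_pool_insert(nk, feat_by_class[[cl]], genome_str, cfg))
        cls <- c(cls, rep(cl, nk))
      }
      nb <- k[["background"]]
      if (nb > 0L) {
        bg_ins <- sample_gap_insert(nb, genome_str, tr$gaps,
                                    function(n) sample(18:30, n, TRUE), cfg)
        ins <- c(ins, bg_ins)
        cls <- c(cls, rep("background", nb))
      }

      # assemble clean-intended reads
      fill_len <- pmax(cfg$read_length - nchar(ins) - nchar(cfg$adapter3), 0L)
      fillers <- substr(random_dna(length(ins), 12L), 1L, fill_len)
      seqs <- substr(paste0(ins, cfg$adapter3, fillers), 1L, cfg$read_length)
      quals <- rand_quals(length(seqs), cfg$read_length)

      # planted failures
      f_lq <- sample_gap_insert(fail_n[["low_quality"]], genome_str, tr$gaps,
                                function(n) rep(22L, n), cfg)
      lq_seq <- substr(paste0(f_lq, cfg$adapter3,
                              random_dna(length(f_lq), 12L)), 1L, cfg$read_length)
      lq_qual <- rand_quals(length(f_lq), cfg$read_length,
                            n_low = ceiling(0.3 * cfg$read_length))
      f_ct <- sample_gap_insert(fail_n[["contaminant5"]], genome_str, tr$gaps,
                                function(n) rep(20L, n), cfg)
      ct_seq <- substr(paste0(substr(cfg$adapter5, 1L, 10L), f_ct, cfg$adapter3,
                              random_dna(length(f_ct), 12L)), 1L, cfg$read_length)
      na_seq <- character(fail_n[["no_3adapter"]])
      need <- seq_along(na_seq)
      while (length(need)) {
        cand <- random_dna(length(need), cfg$read_length)
        ok <- adapter3_pos_cpp(cand, cfg$adapter3, 6L, 1L) == -1L &
          substr(cand, 1L, 8L) != prefix5
        na_seq[need[ok]] <- cand[ok]
        need <- need[!ok]
      }
      f_sh <- character(fail_n[["short"]])
      need <- seq_along(f_sh)
      while (length(need)) {
        lens <- sample(8:17, length(need), replace = TRUE)
        cand <- substr(random_dna(length(need), 17L), 1L, lens)
        ok <- inserts_ok(cand, cfg$adapter3, cfg$adapter5)
        f_sh[need[ok]] <- cand[ok]
        need <- need[!ok]
      }
      sh_seq <- substr(paste0(f_sh, cfg$adapter3,
                              random_dna(length(f_sh), 30L)), 1L, cfg$read_length)

      all_seq <- c(seqs, lq_seq, ct_seq, na_seq, sh_seq)
      all_qual <- c(quals, lq_qual,
                    rand_quals(length(ct_seq) + length(na_seq) + length(sh_seq),
                               cfg$read_length))
      all_cls <- c(cls, rep("fail_low_quality", length(lq_seq)),
                   rep("fail_contaminant5", length(ct_seq)),
                   rep("fail_no_3adapter", length(na_seq)),
                   rep("fail_short", length(sh_seq)))
      ord <- sample.int(length(all_seq))
      libraries[[lib]] <- data.frame(
        id = sprintf("%s_r%06d", lib, seq_along(all_seq)),
        sequence = all_seq[ord], quality = all_qual[ord],
        class = all_cls[ord])
    }
    filter_truth <- as.data.frame(t(replicate(length(libs), fail_n)))
    rownames(filter_truth) <- libs
    # annotation-class ledger (counts of clean reads by eventual class)
    mir_rows <- seq_len(nrow(mt))
    class_truth <- sapply(libs, function(lib) {
      k <- counts[, lib]
      c(known_miRNA = sum(k[mir_rows][!mt$is_novel]),
        rRNA = k[["rRNA"]], tRNA = k[["tRNA"]], snRNA = k[["snRNA"]],
        snoRNA = k[["snoRNA"]], "repeat" = k[["repeat"]],
        exon = k[["exon"]], intron = k[["intron"]],
        unannotated = sum(k[mir_rows][mt$is_novel]) +
          sum(k[grep("^piRNA_like|^decoy", atoms)]) + k[["background"]])
    })
    list(libraries = libraries, filter_truth = filter_truth,
         counts = counts, expected = expected, class_truth = class_truth,
         pi_seqs = pi_seqs, decoy_seqs = decoy_seqs)
  })
}

#' Generate the 3'-UTR set with planted target sites
#'
#' For each differentially expressed miRNA, `planted_sites_per_de_mirna`
#' distinct UTRs carry a strong site (perfect 8mer seed plus full 3'
#' complementarity, detectable by all three predictors). Some decoy UTRs
#' carry a seed-only weak site; the rest carry none. "Carry no strong site"
#' is enforced, not assumed: decoy UTR backgrounds are rejection-sampled
#' until no region shows chance strong complementarity (an alignment call
#' overlapping a duplex call at the default predictor thresholds) to any DE
#' miRNA, since a 300-nt random sequence occasionally contains extensive
#' chance complementarity to a 22-nt miRNA. Intervals in the ledger are
#' 0-based half-open on the UTR.
#'
#' @param cfg a [sim_config()].
#' @param gen output of [generate_genome()].
#' @return list with `utrs` (DNAStringSet), `site_truth`, `gene_map`.
#' @export
generate_transcriptome_with_sites <- function(cfg, gen) {
  with_seed(derive_seed(cfg$seed, "utrs"), {
    tr <- gen$truth
    n_sites <- cfg$planted_sites_per_de_mirna
    de <- tr$de_names
    need <- length(de) * n_sites
    if (need > cfg$n_utrs)
      stopf("n_utrs too small for the planted sites (%d needed)", need)
    utr_len <- sample(200:400, cfg$n_utrs, replace = TRUE)
    utrs <- random_dna(cfg$n_utrs, max(utr_len))
    utrs <- substr(utrs, 1L, utr_len)
    ids <- sprintf("tx%04d", seq_len(cfg$n_utrs))
    mt <- tr$mirna_truth
    strong_utrs <- sample.int(cfg$n_utrs, need)
    site_truth <- NULL
    plant <- function(utr, site) {
      if (nchar(utr) < nchar(site) + 2L)
        stopf("placement error: UTR too short for a planted site")
      off <- sample.int(nchar(utr) - nchar(site) - 1L, 1L) # 1-based
      substr(utr, off, off + nchar(site) - 1L) <- site
      list(utr = utr, start = off - 1L, end = off - 1L + nchar(site))
    }
    k <- 0L
    for (m in de) {
      mseq <- mt$mature[mt$name == m]
      strong <- paste0(revcomp(substr(mseq, 2L, nchar(mseq))), "A")
      for (s in seq_len(n_sites)) {
        k <- k + 1L
        ui <- strong_utrs[k]
        p <- plant(utrs[ui], strong)
        utrs[ui] <- p$utr
        site_truth <- rbind(site_truth, data.frame(
          mirna = m, transcript = ids[ui], start = p$start, end = p$end,
          site_class = "strong"))
      }
    }
    rest <- setdiff(seq_len(cfg$n_utrs), strong_utrs)
    weak_utrs <- rest[seq_len(floor(length(rest) / 2))]
    for (ui in weak_utrs) {
      m <- sample(de, 1L)
      mseq <- mt$mature[mt$name == m]
      weak <- paste0(revcomp(substr(mseq, 2L, 7L)), "A") # 7mer-A1 seed only
      p <- plant(utrs[ui], weak)
      utrs[ui] <- p$utr
      site_truth <- rbind(site_truth, data.frame(
        mirna = m, transcript = ids[ui], start = p$start, end = p$end,
        site_class = "weak"))
    }
    # certify decoys: no chance strong complementarity to any DE miRNA
    pp <- pipeline_params()
    de_seqs <- mt$mature[match(de, mt$name)]
    chance_strong <- function(utr) {
      for (ms in de_seqs) {
        a <- align_scan(ms, utr, threshold = pp$align_threshold)
        if (!nrow(a)) next
        d <- duplex_scan(ms, utr, energy_max = pp$duplex_energy_max)
        if (!nrow(d)) next
        if (any(outer(a$start, d$end, `<`) & outer(a$end, d$start, `>`)))
          return(TRUE)
      }
      FALSE
    }
    for (ui in rest) {
      for (att in 1:50) {
        if (!chance_strong(utrs[ui])) break
        fresh <- substr(random_dna(1L, max(utr_len)), 1L, utr_len[ui])
        wk <- site_truth[site_truth$transcript == ids[ui], , drop = FALSE]
        if (nrow(wk)) { # replant the weak site at its recorded offset
          site <- substr(utrs[ui], wk$start + 1L, wk$end)
          substr(fresh, wk$start + 1L, wk$end) <- site
        }
        utrs[ui] <- fresh
        if (att == 50L) stopf("placement error: cannot build a decoy UTR")
      }
    }
    gene_map <- data.frame(transcript = ids,
                           gene = sub("^tx", "g", ids))
    list(utrs = Biostrings::DNAStringSet(stats::setNames(utrs, ids)),
         site_truth = site_truth, gene_map = gene_map,
         strong_utrs = ids[strong_utrs], weak_utrs = ids[weak_utrs],
         empty_utrs = ids[setdiff(rest, weak_utrs)])
  })
}

#' Generate gene-to-term annotation maps with planted enriched terms
#'
#' Random GO-like (three categories) and pathway-like term assignments over
#' all genes, plus two planted terms concentrated in the strong-site target
#' genes so term enrichment is recoverable.
#'
#' @param cfg a [sim_config()].
#' @param tx output of [generate_transcriptome_with_sites()].
#' @return list with `term_map` (gene_id, term_id, term_name, category) and
#'   `term_truth` (planted enriched term ids).
#' @export
generate_term_maps <- function(cfg, tx) {
  with_seed(derive_seed(cfg$seed, "terms"), {
    genes <- tx$gene_map$gene
    target_genes <- unique(tx$gene_map$gene[
      tx$gene_map$transcript %in% tx$strong_utrs])
    cats <- c("biological_process", "cellular_component",
              "molecular_function", "pathway")
    n_bg_terms <- 26L
    rows <- list()
    for (i in seq_len(n_bg_terms)) {
      K <- sample(6:18, 1L)
      cat_i <- cats[(i - 1L) %% 4L + 1L]
      rows[[i]] <- data.frame(
        gene_id = sample(genes, K),
        term_id = sprintf("T%04d", i),
        term_name = sprintf("background term %d", i),
        category = cat_i)
    }
    planted <- list(
      c(id = "T9001", name = "defense response to fungus",
        category = "biological_process"),
      c(id = "T9002", name = "innate immune signalling pathway",
        category = "pathway"))
    for (p in planted) {
      sel <- sample(target_genes, ceiling(0.7 * length(target_genes)))
      extra <- sample(setdiff(genes, target_genes), 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = c(sel, extra), term_id = p[["id"]],
        term_name = p[["name"]], category = p[["category"]])
    }
    term_map <- do.call(rbind, rows)
    rownames(term_map) <- NULL
    list(term_map = term_map,
         term_truth = vapply(planted, `[[`, "", "id"),
         target_genes = target_genes)
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Three replicates per group for up to ten differentially expressed miRNAs.
#' Target Ct = per-miRNA baseline - log2(true relative expression) + Gaussian
#' noise; the reference (U6-style) Ct is constant + noise, so the true
#' relative quantity is recoverable by the 2^-ddCt method.
#'
#' @param cfg a [sim_config()].
#' @param gen output of [generate_genome()].
#' @param noise_sd Ct noise; defaults to `cfg$qpcr_noise_sd`.
#' @return list with `ct_table` and `qpcr_truth` (true relative quantities).
#' @export
generate_qpcr_table <- function(cfg, gen, noise_sd = cfg$qpcr_noise_sd) {
  with_seed(derive_seed(cfg$seed, "qpcr"), {
    tr <- gen$truth
    targets <- utils::head(tr$de_names, 10L)
    libs <- cfg$library_names
    rows <- list(); truth <- list()
    for (m in targets) {
      base_ct <- stats::runif(1L, 22, 26)
      rq <- c(1, 2^tr$de_log2fc[m, ])
      names(rq) <- libs
      for (g in libs) for (r in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = m, group = g, replicate = r,
          ct_target = base_ct - log2(rq[[g]]) + stats::rnorm(1L, 0, noise_sd),
          ct_reference = 20 + stats::rnorm(1L, 0, noise_sd))
      }
      truth[[m]] <- data.frame(target = m, group = libs, true_rq = unname(rq))
    }
    list(ct_table = do.call(rbind, rows), qpcr_truth = do.call(rbind, truth))
  })
}

#' Run the whole generator
#'
#' Convenience wrapper producing every pipeline input plus the complete
#' ground-truth ledger.
#'
#' @param cfg a [sim_config()].
#' @return a named list (`genome`, `annotation`, `catalog`, `reads`, `utrs`,
#'   `terms`, `qpcr`, `truth`).
#' @export
simulate_study <- function(cfg) {
  gen <- generate_genome(cfg)
  reads <- generate_read_libraries(cfg, gen)
  tx <- generate_transcriptome_with_sites(cfg, gen)
  terms <- generate_term_maps(cfg, tx)
  qpcr <- generate_qpcr_table(cfg, gen)
  truth <- c(gen$truth,
             list(filter_truth = reads$filter_truth, counts = reads$counts,
                  expected_counts = reads$expected,
                  class_truth = reads$class_truth,
                  site_truth = tx$site_truth, gene_map = tx$gene_map,
                  strong_utrs = tx$strong_utrs, weak_utrs = tx$weak_utrs,
                  empty_utrs = tx$empty_utrs,
                  term_truth = terms$term_truth,
                  target_genes = terms$target_genes,
                  qpcr_truth = qpcr$qpcr_truth,
                  decoy_seqs = reads$decoy_seqs, pi_seqs = reads$pi_seqs))
  list(config = cfg, genome = gen$genome, annotation = gen$annotation,
       catalog = gen$catalog, reads = reads$libraries,
       utrs = tx$utrs, term_map = terms$term_map, ct_table = qpcr$ct_table,
       truth = truth)
}

#' Write a simulated study to disk
#'
#' FASTA genome / catalog / UTRs, GFF3 annotation, one FASTQ per library,
#' TSV term map and Ct table, and the ground truth as JSON.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(study$genome, file.path(dir, "genome.fa"))
  cat_set <- Biostrings::DNAStringSet(
    stats::setNames(study$catalog$sequence, study$catalog$name))
  Biostrings::writeXStringSet(cat_set, file.path(dir, "mature_mirnas.fa"))
  pre <- study$truth$mirna_truth
  pre <- pre[!pre$is_novel, ]
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(pre$precursor,
                                             paste0(pre$name, "-pre"))),
    file.path(dir, "precursor_mirnas.fa"))
  Biostrings::writeXStringSet(study$utrs, file.path(dir, "utrs.fa"))
  rtracklayer::export(study$annotation, file.path(dir, "annotation.gff3"),
                      format = "gff3")
  for (lib in names(study$reads)) {
    df <- study$reads[[lib]]
    out <- file.path(dir, paste0(lib, ".fastq"))
    writeLines(paste0("@", df$id, "\n", df$sequence, "\n+\n", df$quality), out)
  }
  utils::write.table(study$term_map, file.path(dir, "term_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$ct_table, file.path(dir, "ct_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- study$truth
  truth$gaps <- data.frame(start = IRanges::start(truth$gaps),
                           end = IRanges::end(truth$gaps))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
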