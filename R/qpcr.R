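# qPCR relative quantification (2^-ddCt) and group statistics.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate: `dCt = Ct_target - Ct_reference`;
#' `ddCt = dCt - mean dCt of the calibrator group` (per target);
#' `RQ = 2^-ddCt`. ddCt is computed per replicate (rather than on group
#' means) so that the SEM is defined on RQ. RQ is invariant to any constant
#' added to all Ct values of a run, and the calibrator-group mean RQ is 1
#' in the noise-free case.
#'
#' @param ct data.frame: target, group, replicate, ct_target, ct_reference.
#' @param calibrator calibrator (control) group label.
#' @return list with `records` (per-replicate dct/ddct/rq) and `summary`
#'   (per target x group: mean RQ +/- SEM).
#' @export
delta_delta_ct <- function(ct, calibrator = "control") {
  if (!calibrator %in% ct$group)
    stopf("missing calibrator group '%s'", calibrator)
  bad <- !stats::complete.cases(ct[c("ct_target", "ct_reference")])
  if (any(bad)) stopf("missing Ct values for %d record(s)", sum(bad))
  ct$dct <- ct$ct_target - ct$ct_reference
  recs <- do.call(rbind, lapply(split(ct, ct$target), function(g) {
    cal <- g$dct[g$group == calibrator]
    if (!length(cal)) stopf("missing calibrator group '%s' for target %s",
                            calibrator, g$target[1])
    g$ddct <- g$dct - mean(cal)
    g$rq <- 2^(-g$ddct)
    g
  }))
  rownames(recs) <- NULL
  agg <- do.call(rbind, lapply(split(recs, recs[c("group", "target")]),
                               function(g) {
    if (!nrow(g)) return(NULL)
    data.frame(target = g$target[1], group = g$group[1], n = nrow(g),
               mean_rq = mean(g$rq),
               sem_rq = stats::sd(g$rq) / sqrt(nrow(g)))
  }))
  rownames(agg) <- NULL
  list(records = recs, summary = agg)
}

# compact letter display by insert-and-absorb over significant pairs
cld_letters <- function(groups, means, sig_pairs, letters_pool = letters) {
  ord <- groups[order(-means)]
  sets <- list(ord)
  for (pr in sig_pairs) {
    repeat {
      offending <- which(vapply(sets, function(s) all(pr %in% s), logical(1)))
      if (!length(offending)) break
      i <- offending[1]
      s <- sets[[i]]
      sets <- c(sets[-i], list(setdiff(s, pr[1])), list(setdiff(s, pr[2])))
      # absorb sets contained in others
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) for (b in seq_along(sets))
        if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
            length(sets[[a]]) < length(sets[[b]])) keep[a] <- FALSE
      sets <- unique(sets[keep])
    }
  }
  # order letter sets by the best-ranked group they contain
  rank1 <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(rank1)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters_pool[i])
  out
}

#' Group statistics with compact letter displays
#'
#' Per target: one-way ANOVA of RQ across groups followed by Tukey's HSD;
#' compact letters are assigned at two levels (lowercase at p < 0.05,
#' uppercase at p < 0.01) by insert-and-absorb, ordered by decreasing group
#' mean. Groups sharing a letter are not significantly different at that
#' level.
#'
#' @param records `records` from [delta_delta_ct()].
#' @param alpha1,alpha2 the two display levels.
#' @return data.frame: target, group, mean_rq, sem_rq, letters at both
#'   levels.
#' @export
group_stats <- function(records, alpha1 = 0.05, alpha2 = 0.01) {
  out <- lapply(split(records, records$target), function(g) {
    tab <- table(g$group)
    if (length(tab) < 2L) stopf("need >= 2 groups for target %s", g$target[1])
    if (any(tab < 3L)) stopf("need >= 3 replicates per group for target %s",
                             g$target[1])
    v <- tapply(g$rq, g$group, stats::var)
    if (all(v == 0))
      stopf("degenerate variance: all groups have zero within-group variance")
    g$group <- factor(g$group)
    fit <- stats::aov(rq ~ group, data = g)
    tk <- stats::TukeyHSD(fit)$group
    pr <- strsplit(rownames(tk), "-", fixed = TRUE)
    means <- tapply(g$rq, g$group, mean)
    sems <- tapply(g$rq, g$group, function(x) stats::sd(x) / sqrt(length(x)))
    groups <- names(means)
    l1 <- cld_letters(groups, means, pr[tk[, "p adj"] < alpha1], letters)
    l2 <- cld_letters(groups, means, pr[tk[, "p adj"] < alpha2], LETTERS)
    data.frame(target = g$target[1], group = groups,
               mean_rq = as.numeric(means), sem_rq = as.numeric(sems),
               letters_p05 = unname(l1[groups]),
               letters_p01 = unname(l2[groups]),
               anova_p = summary(fit)[[1]][["Pr(>F)"]][1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
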