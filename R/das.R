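# Differential alternative splicing between control and salt conditions.
#
# For each event and sample context, FPKM is averaged over the two
# replicates and summed over the event's inclusion isoforms ("alternative"
# side), its exclusion isoforms ("constitutive" side) and all isoforms of
# the gene ("total"). A 2x2 Fisher exact test on the rounded
# constitutive/alternative x control/salt sums calls differential
# splicing, and the change frequency
#   (alt/total)_salt - (alt/total)_control
# measures the direction and size of the usage shift.

#' Per-event FPKM abundances for one sample context
#'
#' @param catalog an `as_catalog`.
#' @param table an `expr_table`.
#' @param tissue `"root"` or `"leaf"`.
#' @param condition `"control"` or `"salt"`.
#' @param timepoint timepoint in hours; the context must have both
#'   replicates.
#' @return data.frame with one row per event: `event_id`, `gene_id`,
#'   `fpkm_alternative` (inclusion isoforms), `fpkm_constitutive`
#'   (exclusion isoforms) and `fpkm_total` (all isoforms of the gene),
#'   each a replicate-mean sum.
#' @export
event_abundance <- function(catalog, table, tissue, condition, timepoint) {
  s <- table$samples
  sel <- s$tissue == tissue & s$condition == condition & s$timepoint_h == timepoint
  reps <- s$sample[sel]
  if (length(reps) != 2L)
    .fail("context %s/%s/%dh does not have exactly two replicates",
          tissue, condition, timepoint)
  v <- rowMeans(table$fpkm[, reps, drop = FALSE])
  gene_tot <- tapply(v, table$gene, sum)
  sum_ids <- function(ids) {
    ids <- ids[ids %in% names(v)]
    if (!length(ids)) 0 else sum(v[ids])
  }
  data.frame(
    event_id = catalog$event_id,
    gene_id = catalog$gene_id,
    fpkm_alternative = vapply(catalog$inclusion,
                              function(x) sum_ids(.split_ids(x)), 0),
    fpkm_constitutive = vapply(catalog$exclusion,
                               function(x) sum_ids(.split_ids(x)), 0),
    fpkm_total = unname(ifelse(catalog$gene_id %in% names(gene_tot),
                               gene_tot[catalog$gene_id], 0)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher exact test for differential splicing of one event
#'
#' Builds the 2x2 table \[constitutive, alternative\] x \[control, salt\]
#' from the four summed FPKMs, rounded half-up to integer counts, and
#' applies a two-sided Fisher exact test.
#'
#' @param abundance_control,abundance_salt one-row data.frames (or named
#'   lists) with `fpkm_alternative` and `fpkm_constitutive` for the same
#'   event in the two conditions.
#' @param alpha significance level (default 0.05).
#' @return list with the integer `table`, `p_value`, `significant`, and
#'   `change_frequency` when both contexts carry `fpkm_total`. With all
#'   four cells zero the p-value is undefined (`NA`) and `skipped` is set
#'   with the reason.
#' @export
das_test <- function(abundance_control, abundance_salt, alpha = 0.05) {
  tab <- matrix(round_half_up(c(abundance_control$fpkm_constitutive,
                                abundance_salt$fpkm_constitutive,
                                abundance_control$fpkm_alternative,
                                abundance_salt$fpkm_alternative)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("constitutive", "alternative"),
                                c("control", "salt")))
  cf <- if (!is.null(abundance_control$fpkm_total) &&
            !is.null(abundance_salt$fpkm_total))
    change_frequency(abundance_control, abundance_salt) else NA_real_
  if (sum(tab) == 0L)
    return(list(table = tab, p_value = NA_real_, significant = FALSE,
                change_frequency = cf, skipped = "all four cells zero"))
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p, significant = is.finite(p) && p < alpha,
       change_frequency = cf)
}

#' Change frequency of an event between conditions
#'
#' `(fpkm_alternative / fpkm_total)` under salt minus the same ratio under
#' control; positive values mean the alternative form gains usage under
#' salt stress. Undefined (`NA`) when either context has zero total FPKM.
#'
#' @param abundance_control,abundance_salt rows as produced by
#'   [event_abundance()].
#' @return numeric in \[-1, 1\], or `NA`.
#' @export
change_frequency <- function(abundance_control, abundance_salt) {
  tc <- abundance_control$fpkm_total; ts <- abundance_salt$fpkm_total
  if (is.na(tc) || is.na(ts) || tc <= 0 || ts <= 0) return(NA_real_)
  abundance_salt$fpkm_alternative / ts - abundance_control$fpkm_alternative / tc
}

#' Test every event for differential splicing across the design
#'
#' Runs [das_test()] per event, tissue and timepoint (control vs salt,
#' replicate-averaged), collecting p-values, significance calls and change
#' frequencies.
#'
#' @param catalog an `as_catalog`.
#' @param table an `expr_table` over the full design.
#' @param alpha significance level.
#' @return data.frame with one row per event x tissue x timepoint:
#'   the four table cells, `p_value`, `significant`, `change_frequency`.
#'   Events with an all-zero table at a context are reported with `NA`
#'   p-value and not significant.
#' @export
das_scan <- function(catalog, table, alpha = 0.05) {
  s <- table$samples
  out <- list()
  for (tis in unique(s$tissue)) {
    tps <- sort(unique(s$timepoint_h[s$tissue == tis]))
    for (tp in tps) {
      ac <- event_abundance(catalog, table, tis, "control", tp)
      as_ <- event_abundance(catalog, table, tis, "salt", tp)
      cc <- round_half_up(ac$fpkm_constitutive)
      ca <- round_half_up(ac$fpkm_alternative)
      sc <- round_half_up(as_$fpkm_constitutive)
      sa <- round_half_up(as_$fpkm_alternative)
      p <- rep(NA_real_, nrow(ac))
      nonzero <- (cc + ca + sc + sa) > 0
      for (i in which(nonzero))
        p[i] <- stats::fisher.test(matrix(c(cc[i], sc[i], ca[i], sa[i]),
                                          nrow = 2L, byrow = TRUE))$p.value
      cf <- ifelse(ac$fpkm_total > 0 & as_$fpkm_total > 0,
                   as_$fpkm_alternative / as_$fpkm_total -
                     ac$fpkm_alternative / ac$fpkm_total, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        event_id = ac$event_id, gene_id = ac$gene_id, tissue = tis,
        timepoint_h = tp, const_control = cc, const_salt = sc,
        alt_control = ca, alt_salt = sa, p_value = p,
        significant = !is.na(p) & p < alpha, change_frequency = cf,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Roll differential-splicing calls up to tissue level
#'
#' An event is differentially spliced (DAS) in a tissue if significant at
#' one or more timepoints; a gene is DAS if one or more of its events is.
#'
#' @param results data.frame from [das_scan()] (all timepoints).
#' @return list with `per_tissue` (DAS event and gene counts per tissue),
#'   `das_events` / `das_genes` (per-tissue id lists) and `gene_overlap`
#'   (genes DAS in both tissues, and tissue-specific counts).
#' @export
das_rollup <- function(results) {
  tissues <- unique(results$tissue)
  ev <- list(); gn <- list()
  for (tis in tissues) {
    r <- results[results$tissue == tis & results$significant, , drop = FALSE]
    ev[[tis]] <- unique(r$event_id)
    gn[[tis]] <- unique(r$gene_id)
  }
  per_tissue <- data.frame(tissue = tissues,
                           das_events = vapply(ev, length, 0L),
                           das_genes = vapply(gn, length, 0L),
                           row.names = NULL, stringsAsFactors = FALSE)
  overlap <- NULL
  if (all(c("root", "leaf") %in% tissues)) {
    common <- intersect(gn[["root"]], gn[["leaf"]])
    overlap <- c(common = length(common),
                 root_specific = length(setdiff(gn[["root"]], common)),
                 leaf_specific = length(setdiff(gn[["leaf"]], common)))
  }
  list(per_tissue = per_tissue, das_events = ev, das_genes = gn,
       gene_overlap = overlap)
}

#' Correlate splicing change frequency with gene expression change
#'
#' For each DAS event and tissue, pairs the per-timepoint change
#' frequencies with the gene's log2 fold changes and computes a Pearson
#' correlation with a two-sided test. Events with fewer than three usable
#' timepoint pairs, or a constant series, are excluded with a reason.
#'
#' @param das_results data.frame from [das_scan()].
#' @param gene_fold_changes data.frame with columns `gene_id`, `tissue`,
#'   `timepoint_h`, `log2fc`.
#' @param alpha significance level.
#' @return list with `per_event` (event, tissue, n, r, p, significant),
#'   `excluded` (event, tissue, reason) and `fraction_significant`.
#' @export
das_expression_correlation <- function(das_results, gene_fold_changes,
                                       alpha = 0.05) {
  keys <- unique(das_results[, c("event_id", "gene_id", "tissue")])
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    r <- das_results[das_results$event_id == k$event_id &
                       das_results$tissue == k$tissue, , drop = FALSE]
    fc <- gene_fold_changes[gene_fold_changes$gene_id == k$gene_id &
                              gene_fold_changes$tissue == k$tissue, , drop = FALSE]
    m <- merge(r[, c("timepoint_h", "change_frequency")],
               fc[, c("timepoint_h", "log2fc")], by = "timepoint_h")
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3L) {
      excl[[length(excl) + 1L]] <- data.frame(
        event_id = k$event_id, tissue = k$tissue,
        reason = "fewer than 3 paired timepoints", stringsAsFactors = FALSE)
      next
    }
    if (stats::sd(m$change_frequency) == 0 || stats::sd(m$log2fc) == 0) {
      excl[[length(excl) + 1L]] <- data.frame(
        event_id = k$event_id, tissue = k$tissue,
        reason = "constant series, correlation undefined",
        stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(m$change_frequency, m$log2fc, method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = k$event_id, tissue = k$tissue, n = nrow(m),
      r = unname(ct$estimate), p_value = ct$p.value,
      significant = ct$p.value < alpha, stringsAsFactors = FALSE)
  }
  per_event <- if (length(rows)) do.call(rbind, rows) else NULL
  list(per_event = per_event,
       excluded = if (length(excl)) do.call(rbind, excl) else NULL,
       fraction_significant = if (is.null(per_event)) NA_real_
       else mean(per_event$significant))
}

#' Fisher-test term enrichment with BH correction
#'
#' Generic singular enrichment analysis over a user-supplied gene-to-term
#' mapping: for every term with at least one foreground gene, a one-sided
#' (enrichment) Fisher exact test on the 2x2 foreground/background x
#' in-term/not-in-term table, with Benjamini-Hochberg adjustment across all
#' tested terms.
#'
#' @param foreground_genes genes of interest (must be a subset of the
#'   background).
#' @param background_genes the gene universe.
#' @param gene2term data.frame with columns `gene_id` and `term`.
#' @param fdr_cutoff FDR threshold for the `enriched` flag.
#' @return data.frame with one row per tested term: counts, `p_value`,
#'   `fdr`, `enriched`.
#' @export
term_enrichment <- function(foreground_genes, background_genes, gene2term,
                            fdr_cutoff = 0.05) {
  if (!length(foreground_genes)) .fail("empty foreground gene set")
  fg <- unique(foreground_genes); bg <- unique(background_genes)
  if (length(setdiff(fg, bg)))
    .fail("foreground genes must be a subset of the background")
  g2t <- gene2term[gene2term$gene_id %in% bg, , drop = FALSE]
  terms <- unique(g2t$term[g2t$gene_id %in% fg])
  if (!length(terms))
    return(data.frame(term = character(0), fg_in_term = integer(0),
                      bg_in_term = integer(0), p_value = numeric(0),
                      fdr = numeric(0), enriched = logical(0)))
  rows <- lapply(terms, function(tm) {
    tg <- unique(g2t$gene_id[g2t$term == tm])
    a <- length(intersect(fg, tg))
    b <- length(fg) - a
    c_ <- length(tg) - a
    d <- length(bg) - length(fg) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(term = tm, fg_in_term = a, bg_in_term = length(tg),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$fdr < fdr_cutoff
  out[order(out$p_value), , drop = FALSE]
}
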