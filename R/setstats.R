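# Group presence and overlap summaries (Venn logic over RC/RS/LC/LS flags)
# and the tissue-vs-treatment specificity test.

#' Overlap summary of event presence across the four groups
#'
#' Collapses per-group presence flags along two axes: tissue (root =
#' RC or RS, leaf = LC or LS) and condition (control = RC or LC, salt =
#' RS or LS), reporting shared and specific counts per axis, per-group
#' counts, all pairwise intersections, and the events common to all four
#' groups (also as an integer percent of the flagged total).
#'
#' @param catalog an `as_catalog` with group flags (only events flagged in
#'   at least one group are counted).
#' @return object of class `overlap_summary`.
#' @export
overlap_summary <- function(catalog) {
  grps <- names(.GROUPS)
  fl <- as.matrix(as.data.frame(catalog)[, grps, drop = FALSE])
  fl <- fl[rowSums(fl) > 0L, , drop = FALSE]
  n <- nrow(fl)
  root <- fl[, "RC"] | fl[, "RS"]; leaf <- fl[, "LC"] | fl[, "LS"]
  ctrl <- fl[, "RC"] | fl[, "LC"]; salt <- fl[, "RS"] | fl[, "LS"]
  pairs <- outer(grps, grps, Vectorize(function(a, b) sum(fl[, a] & fl[, b])))
  dimnames(pairs) <- list(grps, grps)
  common4 <- sum(rowSums(fl) == 4L)
  structure(list(
    total = n,
    per_group = colSums(fl),
    pairwise = pairs,
    common_all4 = common4,
    common_all4_pct = if (n) round_half_up(common4 / n * 100, 0) else NA_real_,
    tissue = c(shared = sum(root & leaf),
               root_specific = sum(root & !leaf),
               leaf_specific = sum(leaf & !root)),
    condition = c(shared = sum(ctrl & salt),
                  control_specific = sum(ctrl & !salt),
                  salt_specific = sum(salt & !ctrl))),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap_summary: %d events; %d (%d%%) present in all four groups\n",
              x$total, x$common_all4, x$common_all4_pct))
  cat(sprintf("  tissue axis: %d shared, %d root-specific, %d leaf-specific\n",
              x$tissue[["shared"]], x$tissue[["root_specific"]],
              x$tissue[["leaf_specific"]]))
  cat(sprintf("  condition axis: %d shared, %d control-specific, %d salt-specific\n",
              x$condition[["shared"]], x$condition[["control_specific"]],
              x$condition[["salt_specific"]]))
  invisible(x)
}

#' Tissue- vs condition-specificity test
#'
#' Asks whether events differ more between tissues than between
#' conditions: a two-sided Fisher exact test on the 2x2 table
#' \[shared, specific\] x \[tissue axis, condition axis\], where
#' "specific" pools the two one-sided cells of an axis.
#'
#' @param summary an [overlap_summary()] object, or a 2x2 matrix with rows
#'   = axes and columns = (shared, specific).
#' @return list with the `table`, `p_value`, `odds_ratio` and `direction`
#'   (`"tissue_more_specific"`, `"condition_more_specific"` or
#'   `"balanced"`).
#' @export
specificity_test <- function(summary) {
  if (inherits(summary, "overlap_summary")) {
    tab <- matrix(c(summary$tissue[["shared"]],
                    summary$tissue[["root_specific"]] +
                      summary$tissue[["leaf_specific"]],
                    summary$condition[["shared"]],
                    summary$condition[["control_specific"]] +
                      summary$condition[["salt_specific"]]),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("tissue", "condition"),
                                  c("shared", "specific")))
  } else {
    tab <- as.matrix(summary)
    if (!all(dim(tab) == c(2L, 2L))) .fail("expected a 2x2 table")
  }
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    .fail("specificity table has a zero margin")
  ft <- stats::fisher.test(tab)
  spec_t <- tab[1L, 2L] / sum(tab[1L, ])
  spec_c <- tab[2L, 2L] / sum(tab[2L, ])
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       direction = if (spec_t > spec_c) "tissue_more_specific"
       else if (spec_t < spec_c) "condition_more_specific" else "balanced")
}
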