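# Isoform abundance handling: the FPKM matrix, abundance summaries, the
# empirical expression-cutoff calibration and replicate-concordant filtering.

.TISSUES <- c("root", "leaf")
.CONDITIONS <- c("control", "salt")
.GROUPS <- c(RC = "root.control", RS = "root.salt",
             LC = "leaf.control", LS = "leaf.salt")

# parse sample names of the form <tissue>_<condition>_<time>h_r<rep>
.parse_samples <- function(nm) {
  m <- regmatches(nm, regexec("^(root|leaf)_(control|salt)_([0-9]+)h_r([0-9]+)$", nm))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    .fail("sample name(s) not of the form <tissue>_<condition>_<time>h_r<rep>: %s",
          paste(nm[bad], collapse = ", "))
  p <- do.call(rbind, m)
  grp <- ifelse(p[, 2L] == "root",
                ifelse(p[, 3L] == "control", "RC", "RS"),
                ifelse(p[, 3L] == "control", "LC", "LS"))
  data.frame(sample = nm, tissue = p[, 2L], condition = p[, 3L],
             timepoint_h = as.integer(p[, 4L]), replicate = as.integer(p[, 5L]),
             group = grp, stringsAsFactors = FALSE)
}

#' Construct an isoform expression table
#'
#' @param fpkm numeric matrix of FPKM values, rows = isoforms (rownames
#'   required), columns = libraries named `<tissue>_<condition>_<time>h_r<rep>`
#'   with tissue in \{root, leaf\} and condition in \{control, salt\}.
#' @param gene_map named character vector mapping each isoform id to its
#'   gene id; must cover all rownames of `fpkm`.
#' @return object of class `expr_table`: list with the matrix (`fpkm`),
#'   the map (`gene`) and parsed per-library metadata (`samples`).
#' @export
expression_table <- function(fpkm, gene_map) {
  if (!is.matrix(fpkm) || is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    .fail("fpkm must be a matrix with isoform rownames and sample colnames")
  if (any(fpkm < 0) || anyNA(fpkm)) .fail("FPKM values must be finite and >= 0")
  miss <- setdiff(rownames(fpkm), names(gene_map))
  if (length(miss))
    .fail("isoform(s) without gene mapping: %s",
          paste(utils::head(miss, 3L), collapse = ", "))
  structure(list(fpkm = fpkm,
                 gene = gene_map[rownames(fpkm)],
                 samples = .parse_samples(colnames(fpkm))),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d isoforms (%d genes) x %d libraries\n",
              nrow(x$fpkm), length(unique(x$gene)), ncol(x$fpkm)))
  invisible(x)
}

#' Read an expression table from TSV
#'
#' Expected layout: first column `isoform_id`, second `gene_id`, remaining
#' columns one per library named `<tissue>_<condition>_<time>h_r<rep>`.
#'
#' @param path TSV file path.
#' @return an [expression_table()] object.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "isoform_id" || names(df)[2L] != "gene_id")
    .fail("expression TSV must start with columns isoform_id, gene_id")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$isoform_id
  expression_table(m, stats::setNames(df$gene_id, df$isoform_id))
}

#' Write an expression table to TSV
#'
#' @param table an `expr_table`.
#' @param path output path.
#' @param digits significant digits used when serialising FPKM values
#'   (fixed so that output is byte-stable).
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path, digits = 6) {
  df <- data.frame(isoform_id = rownames(table$fpkm),
                   gene_id = unname(table$gene),
                   signif(table$fpkm, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fractions of isoform abundance values per FPKM bin
#'
#' Each isoform x library cell is counted once, into bins `<1`, `[1,10]`
#' and `>10` FPKM.
#'
#' @param table an `expr_table`.
#' @return named numeric vector of three fractions summing to 1.
#' @export
abundance_bins <- function(table) {
  v <- as.vector(table$fpkm)
  if (!length(v)) .fail("empty expression table")
  c(below_1 = mean(v < 1),
    from_1_to_10 = mean(v >= 1 & v <= 10),
    above_10 = mean(v > 10))
}

#' Per-gene abundance share of the top-k isoforms
#'
#' For every multi-isoform gene, FPKM is summed over the libraries of one
#' group (tissue x condition, pooling timepoints and replicates) and each
#' isoform's share of the gene total is computed; shares are sorted
#' decreasing and the first `k` ranks reported (ranks beyond a gene's
#' isoform count are 0, so per-gene shares over all ranks sum to 1).
#'
#' @param table an `expr_table`.
#' @param group one of `"RC"`, `"RS"`, `"LC"`, `"LS"`.
#' @param k number of top ranks to report.
#' @return list with `per_gene` (genes x k matrix of rank shares) and
#'   `mean_by_rank` (across-gene mean share per rank). Multi-isoform genes
#'   with zero group abundance are omitted.
#' @export
top_isoform_fractions <- function(table, group, k = 5) {
  if (!group %in% names(.GROUPS)) .fail("unknown group: %s", group)
  if (!.is_count(k) || k < 1) .fail("k must be a positive integer")
  cols <- table$samples$group == group
  if (!any(cols)) .fail("no libraries in group %s", group)
  iso_sum <- rowSums(table$fpkm[, cols, drop = FALSE])
  counts <- table(table$gene)
  multi <- names(counts)[counts >= 2L]
  rows <- list()
  for (g in multi) {
    v <- iso_sum[table$gene == g]
    tot <- sum(v)
    if (tot <= 0) next
    fr <- sort(v / tot, decreasing = TRUE)
    rows[[g]] <- c(fr, numeric(max(0L, k - length(fr))))[seq_len(k)]
  }
  if (!length(rows)) .fail("no expressed multi-isoform genes in group %s", group)
  per_gene <- do.call(rbind, rows)
  colnames(per_gene) <- paste0("top", seq_len(k))
  list(per_gene = per_gene, mean_by_rank = colMeans(per_gene))
}

#' Calibrate an empirical FPKM expression cutoff
#'
#' Scans a grid of candidate cutoffs and, at each, computes the false
#' negative rate (fraction of known isoforms with positive expression whose
#' maximum FPKM over all libraries falls below the cutoff) and the false
#' positive rate (fraction of decoy/artificial isoforms whose maximum FPKM
#' reaches the cutoff). The chosen cutoff is the smallest grid value at
#' which the FP rate drops to or below the FN rate (the curve crossing).
#'
#' @param table an `expr_table` quantified over known and decoy isoforms
#'   alike.
#' @param known_ids isoform ids present in the reference annotation.
#' @param artificial_ids decoy isoform ids.
#' @param grid candidate cutoffs, default 1 to 10 FPKM in steps of 0.1.
#' @return object of class `cutoff_calibration`: list with `grid`,
#'   `fn_rate`, `fp_rate` and `chosen_cutoff` (1 decimal).
#' @export
calibrate_cutoff <- function(table, known_ids, artificial_ids,
                             grid = seq(1, 10, by = 0.1)) {
  if (!length(known_ids) || !length(artificial_ids))
    .fail("known and artificial isoform sets must be non-empty")
  miss <- setdiff(c(known_ids, artificial_ids), rownames(table$fpkm))
  if (length(miss))
    .fail("isoform(s) absent from expression table: %s",
          paste(utils::head(miss, 3L), collapse = ", "))
  grid <- sort(grid)
  mx <- apply(table$fpkm, 1L, max)
  mk <- mx[known_ids]; mk <- mk[mk > 0]
  if (!length(mk)) .fail("no known isoform with positive expression")
  ma <- mx[artificial_ids]
  fn <- vapply(grid, function(c) mean(mk < c), 0)
  fp <- vapply(grid, function(c) mean(ma >= c), 0)
  stopifnot(all(diff(fn) >= 0), all(diff(fp) <= 0))  # monotone by construction
  hit <- which(fp <= fn)
  chosen <- if (length(hit)) round_half_up(grid[hit[1L]], 1) else NA_real_
  structure(list(grid = grid, fn_rate = fn, fp_rate = fp,
                 chosen_cutoff = chosen),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf("cutoff_calibration: grid [%g, %g], chosen cutoff %.1f FPKM\n",
              min(x$grid), max(x$grid), x$chosen_cutoff))
  invisible(x)
}

#' @export
plot.cutoff_calibration <- function(x, ...) {
  graphics::plot(x$grid, x$fn_rate, type = "l", col = "firebrick",
                 xlab = "FPKM cutoff", ylab = "rate", ylim = c(0, 1), ...)
  graphics::lines(x$grid, x$fp_rate, col = "steelblue")
  graphics::abline(v = x$chosen_cutoff, lty = 2)
  graphics::legend("right", c("false negative", "false positive"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Percent change of a count under treatment
#'
#' `(stress - control) / control * 100`, rounded half-up.
#'
#' @param stress,control counts (or any positive quantities).
#' @param digits decimal places of the result.
#' @return numeric percent change.
#' @export
percent_change <- function(stress, control, digits = 2) {
  round_half_up((stress - control) / control * 100, digits)
}

#' Filter isoforms by replicate-concordant expression
#'
#' An isoform is retained in a group (tissue x condition) if there is at
#' least one timepoint of that group at which BOTH biological replicates
#' have FPKM at or above the cutoff; it is retained overall if retained in
#' at least one group. This is the strict reading of requiring an isoform
#' to be repeatedly detected in each biological replicate.
#'
#' @param table an `expr_table` whose libraries form complete replicate
#'   pairs (replicates 1 and 2 at every tissue x condition x timepoint).
#' @param cutoff FPKM threshold (> 0), e.g. the calibrated 2.6.
#' @return object of class `isoform_filter`: list with `retained` (per
#'   group character vectors), `overall`, `counts` (per-group isoform and
#'   gene counts with isoforms per gene), `percent_change` (per tissue,
#'   salt vs control, on isoform counts) and the `cutoff`.
#' @export
filter_isoforms <- function(table, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0) .fail("cutoff must be > 0")
  s <- table$samples
  keys <- unique(s[, c("tissue", "condition", "timepoint_h")])
  retained <- list()
  for (grp in names(.GROUPS)) {
    gs <- s[s$group == grp, , drop = FALSE]
    if (!nrow(gs)) .fail("no libraries for group %s", grp)
    ok <- rep(FALSE, nrow(table$fpkm))
    for (tp in unique(gs$timepoint_h)) {
      r1 <- gs$sample[gs$timepoint_h == tp & gs$replicate == 1L]
      r2 <- gs$sample[gs$timepoint_h == tp & gs$replicate == 2L]
      if (length(r1) != 1L || length(r2) != 1L)
        .fail("incomplete replicate pair for group %s at %d h", grp, tp)
      ok <- ok | (table$fpkm[, r1] >= cutoff & table$fpkm[, r2] >= cutoff)
    }
    retained[[grp]] <- rownames(table$fpkm)[ok]
  }
  overall <- unique(unlist(retained, use.names = FALSE))
  counts <- do.call(rbind, lapply(names(retained), function(grp) {
    iso <- retained[[grp]]
    ng <- length(unique(table$gene[iso]))
    data.frame(group = grp, isoforms = length(iso), genes = ng,
               isoforms_per_gene = if (ng) round_half_up(length(iso) / ng, 2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  n <- stats::setNames(counts$isoforms, counts$group)
  pc <- data.frame(
    tissue = c("root", "leaf"),
    control = c(n[["RC"]], n[["LC"]]),
    salt = c(n[["RS"]], n[["LS"]]),
    pct_change = c(percent_change(n[["RS"]], n[["RC"]]),
                   percent_change(n[["LS"]], n[["LC"]])),
    stringsAsFactors = FALSE)
  structure(list(retained = retained, overall = overall, counts = counts,
                 percent_change = pc, cutoff = cutoff),
            class = "isoform_filter")
}

#' @export
print.isoform_filter <- function(x, ...) {
  cat(sprintf("isoform_filter (cutoff %.2f FPKM): %d isoforms retained overall\n",
              x$cutoff, length(x$overall)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
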