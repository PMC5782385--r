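# Alternative-splicing event detection and classification.
#
# Two isoforms of a gene are compared over their mutual span. Positions
# where their exonic coverage differs are grouped into "bubbles": maximal
# variable regions delimited by consecutive splice sites common to both
# splice chains (with virtual anchors at the mutual-span boundaries). Each
# bubble is typed against the four basic patterns:
#
#   IR  one isoform splices an intron that lies entirely inside an exon of
#       the other; length = retained intron length
#   ES  one or more exons internal to one isoform are absent from the
#       other, the outer splice sites of the flanking introns being shared;
#       length = summed skipped-exon length
#   AA  shared donor, different acceptor; length = acceptor shift
#   AD  shared acceptor, different donor; length = donor shift
#
# Anything else (combined patterns, mutually exclusive exons, several
# retained introns in one bubble, ...) is "other". Donor/acceptor are
# strand-aware: the donor is the 5' intron end in transcription direction,
# so on "-" the genomic right intron edge is the donor. Variable regions
# that touch the mutual-span boundary reflect differing transcript ends,
# not splicing, and are never emitted.

.EVENT_TYPES <- c("IR", "ES", "AA", "AD", "other")

.empty_events <- function() {
  data.frame(type = character(0), region_start = integer(0),
             region_end = integer(0), length = integer(0),
             flank_left = integer(0), flank_right = integer(0),
             inclusion = character(0), exclusion = character(0),
             stringsAsFactors = FALSE)
}

# splice sites of one exon matrix restricted to [os, oe]:
# matrix with columns pos, kind (1 = intron start, 2 = intron end)
.sites <- function(ex, os, oe) {
  im <- .introns(ex)
  if (!nrow(im)) return(cbind(pos = integer(0), kind = integer(0)))
  m <- rbind(cbind(pos = im[, 1L], kind = 1L),
             cbind(pos = im[, 2L], kind = 2L))
  m <- m[m[, 1L] >= os & m[, 1L] <= oe, , drop = FALSE]
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# maximal segments of [os, oe] where exonic coverage differs, found by a
# sweep over the combined exon boundaries
.diff_segments <- function(ex1, ex2, os, oe) {
  clip <- function(ex) {
    s <- pmax(ex[, 1L], os); e <- pmin(ex[, 2L], oe)
    keep <- s <= e
    cbind(s[keep], e[keep])
  }
  c1 <- clip(ex1); c2 <- clip(ex2)
  pts <- sort(unique(c(os, oe + 1L, c1[, 1L], c1[, 2L] + 1L,
                       c2[, 1L], c2[, 2L] + 1L)))
  pts <- pts[pts >= os & pts <= oe + 1L]
  covers <- function(cl, p) any(cl[, 1L] <= p & cl[, 2L] >= p)
  segs <- NULL
  for (i in seq_len(length(pts) - 1L)) {
    p <- pts[i]; q <- pts[i + 1L] - 1L
    if (covers(c1, p) != covers(c2, p)) {
      if (!is.null(segs) && segs[nrow(segs), 2L] == p - 1L)
        segs[nrow(segs), 2L] <- q
      else segs <- rbind(segs, c(p, q))
    }
  }
  segs
}

.has_intron <- function(im, s, e) any(im[, 1L] == s & im[, 2L] == e)
.exonic_over <- function(ex, s, e) any(ex[, 1L] <= s & ex[, 2L] >= e)

# exonic bp of ex within [s, e]
.exonic_bp <- function(ex, s, e) {
  w <- pmin(ex[, 2L], e) - pmax(ex[, 1L], s) + 1L
  sum(w[w > 0L])
}

# classify one bubble; returns a one-row event data.frame or NULL
.type_bubble <- function(segs, c1, c2, in1, in2, ex1, ex2, aL, aR, strand,
                         id1, id2) {
  n1 <- nrow(c1); n2 <- nrow(c2)
  other <- function() {
    rs <- min(segs[, 1L]); re <- max(segs[, 2L])
    len <- sum(segs[, 2L] - segs[, 1L] + 1L)
    inc1 <- .exonic_bp(ex1, rs, re) >= .exonic_bp(ex2, rs, re)
    data.frame(type = "other", region_start = rs, region_end = re,
               length = len, flank_left = rs - 1L, flank_right = re + 1L,
               inclusion = if (inc1) id1 else id2,
               exclusion = if (inc1) id2 else id1, stringsAsFactors = FALSE)
  }
  if ((n1 == 0L) != (n2 == 0L)) {
    if (n1 == 0L) { cN <- c2; inX <- in2; exX <- ex2; exY <- ex1
                    idX <- id2; idY <- id1; inY <- in1 }
    else          { cN <- c1; inX <- in1; exX <- ex1; exY <- ex2
                    idX <- id1; idY <- id2; inY <- in2 }
    n <- nrow(cN)
    # IR: the chain is exactly one intron of X, exonic in Y
    if (n == 2L && cN[1L, 2L] == 1L && cN[2L, 2L] == 2L &&
        .has_intron(inX, cN[1L, 1L], cN[2L, 1L]) &&
        .exonic_over(exY, cN[1L, 1L], cN[2L, 1L]) &&
        nrow(segs) == 1L && segs[1L, 1L] == cN[1L, 1L] &&
        segs[1L, 2L] == cN[2L, 1L]) {
      a <- cN[1L, 1L]; b <- cN[2L, 1L]
      return(data.frame(type = "IR", region_start = a, region_end = b,
                        length = b - a + 1L, flank_left = a - 1L,
                        flank_right = b + 1L, inclusion = idY,
                        exclusion = idX, stringsAsFactors = FALSE))
    }
    # ES: chain alternates intron-end, intron-start (complete exons of X),
    # Y splices one intron across the bubble, outer sites shared (= anchors)
    if (n >= 2L && n %% 2L == 0L &&
        all(cN[, 2L] == rep(c(2L, 1L), n / 2L)) &&
        !is.na(aL[1L]) && !is.na(aR[1L]) &&
        aL[2L] == 1L && aR[2L] == 2L) {
      D <- aL[1L]; A <- aR[1L]
      exs <- cbind(cN[seq(1L, n, 2L), 1L] + 1L, cN[seq(2L, n, 2L), 1L] - 1L)
      ok <- .has_intron(inY, D, A) && .has_intron(inX, D, cN[1L, 1L]) &&
        .has_intron(inX, cN[n, 1L], A) &&
        nrow(segs) == nrow(exs) && all(segs[, 1L] == exs[, 1L]) &&
        all(segs[, 2L] == exs[, 2L])
      if (ok) {
        return(data.frame(type = "ES", region_start = exs[1L, 1L],
                          region_end = exs[nrow(exs), 2L],
                          length = sum(exs[, 2L] - exs[, 1L] + 1L),
                          flank_left = D, flank_right = A,
                          inclusion = idX, exclusion = idY,
                          stringsAsFactors = FALSE))
      }
    }
    return(other())
  }
  if (n1 == 1L && n2 == 1L && c1[1L, 2L] == c2[1L, 2L] &&
      c1[1L, 1L] != c2[1L, 1L]) {
    p1 <- c1[1L, 1L]; p2 <- c2[1L, 1L]; kind <- c1[1L, 2L]
    if (kind == 2L) {                      # intron ends differ, starts shared
      d1 <- in1[match(p1, in1[, 2L]), 1L]
      d2 <- in2[match(p2, in2[, 2L]), 1L]
      if (!is.na(d1) && !is.na(d2) && d1 == d2 &&
          !is.na(aL[1L]) && aL[1L] == d1 && aL[2L] == 1L) {
        lo <- min(p1, p2); hi <- max(p1, p2)
        if (nrow(segs) == 1L && segs[1L, 1L] == lo + 1L && segs[1L, 2L] == hi) {
          inc1 <- p1 < p2                  # shorter intron keeps region exonic
          return(data.frame(
            type = if (strand == "+") "AA" else "AD",
            region_start = lo + 1L, region_end = hi, length = hi - lo,
            flank_left = d1, flank_right = hi + 1L,
            inclusion = if (inc1) id1 else id2,
            exclusion = if (inc1) id2 else id1, stringsAsFactors = FALSE))
        }
      }
    } else {                               # intron starts differ, ends shared
      a1 <- in1[match(p1, in1[, 1L]), 2L]
      a2 <- in2[match(p2, in2[, 1L]), 2L]
      if (!is.na(a1) && !is.na(a2) && a1 == a2 &&
          !is.na(aR[1L]) && aR[1L] == a1 && aR[2L] == 2L) {
        lo <- min(p1, p2); hi <- max(p1, p2)
        if (nrow(segs) == 1L && segs[1L, 1L] == lo && segs[1L, 2L] == hi - 1L) {
          inc1 <- p1 > p2                  # later donor keeps region exonic
          return(data.frame(
            type = if (strand == "+") "AD" else "AA",
            region_start = lo, region_end = hi - 1L, length = hi - lo,
            flank_left = lo - 1L, flank_right = a1,
            inclusion = if (inc1) id1 else id2,
            exclusion = if (inc1) id2 else id1, stringsAsFactors = FALSE))
        }
      }
    }
  }
  other()
}

# classify events between two exon matrices of the same gene/strand
.classify_exons <- function(ex1, ex2, strand, id1 = "t1", id2 = "t2") {
  os <- max(ex1[1L, 1L], ex2[1L, 1L])
  oe <- min(ex1[nrow(ex1), 2L], ex2[nrow(ex2), 2L])
  if (os > oe) return(.empty_events())
  segs <- .diff_segments(ex1, ex2, os, oe)
  if (is.null(segs)) return(.empty_events())
  s1 <- .sites(ex1, os, oe); s2 <- .sites(ex2, os, oe)
  k1 <- paste(s1[, 1L], s1[, 2L]); k2 <- paste(s2[, 1L], s2[, 2L])
  common <- s1[k1 %in% k2, , drop = FALSE]
  in1 <- .introns(ex1); in2 <- .introns(ex2)
  anchors <- common[order(common[, 1L]), , drop = FALSE]
  apos <- anchors[, 1L]
  bubble <- findInterval(segs[, 1L], apos)
  out <- list()
  for (b in unique(bubble)) {
    bs <- segs[bubble == b, , drop = FALSE]
    if (any(bs[, 1L] == os) || any(bs[, 2L] == oe)) next  # terminal difference
    aL <- if (b >= 1L) anchors[b, ] else c(NA_integer_, NA_integer_)
    aR <- if (b < length(apos)) anchors[b + 1L, ] else c(NA_integer_, NA_integer_)
    lo <- if (is.na(aL[1L])) os - 1L else aL[1L]
    hi <- if (is.na(aR[1L])) oe + 1L else aR[1L]
    c1 <- s1[s1[, 1L] > lo & s1[, 1L] < hi & !(k1 %in% k2), , drop = FALSE]
    c2 <- s2[s2[, 1L] > lo & s2[, 1L] < hi & !(k2 %in% k1), , drop = FALSE]
    ev <- .type_bubble(bs, c1, c2, in1, in2, ex1, ex2, aL, aR, strand, id1, id2)
    if (!is.null(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(.empty_events())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify alternative-splicing events between two isoforms
#'
#' Compares the splice chains of two transcripts of the same gene over
#' their mutual span and returns every internal variable region, typed as
#' intron retention (IR), exon skipping (ES), alternative acceptor (AA),
#' alternative donor (AD) or other (complex/combined patterns). The
#' `inclusion` isoform is the one carrying the variant region as exonic
#' sequence (e.g. retaining the intron); `exclusion` the one splicing it
#' out. Differences at the transcript termini are transcriptional, not
#' splicing, and are not reported.
#'
#' @param t1,t2 transcripts as returned by [get_transcript()].
#' @return data.frame with one row per event: `type`, `region_start`,
#'   `region_end`, `length` (bp), `flank_left`, `flank_right`, `inclusion`,
#'   `exclusion`.
#' @export
classify_pair <- function(t1, t2) {
  if (!identical(t1$gene_id, t2$gene_id))
    .fail("transcripts belong to different genes: %s vs %s", t1$gene_id, t2$gene_id)
  if (!identical(t1$strand, t2$strand))
    .fail("transcripts on different strands: %s vs %s",
          t1$transcript_id, t2$transcript_id)
  .classify_exons(t1$exons, t2$exons, t1$strand,
                  t1$transcript_id, t2$transcript_id)
}

#' Extract one transcript from a gene model collection
#'
#' @param models a [gene_models] object.
#' @param gene_id,transcript_id identifiers.
#' @return list with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `exons` (sorted start/end matrix) and `introns`.
#' @export
get_transcript <- function(models, gene_id, transcript_id) {
  g <- models[[gene_id]]
  if (is.null(g)) .fail("unknown gene: %s", gene_id)
  ex <- g$transcripts[[transcript_id]]
  if (is.null(ex)) .fail("unknown transcript %s in gene %s", transcript_id, gene_id)
  list(transcript_id = transcript_id, gene_id = gene_id, chrom = g$chrom,
       strand = g$strand, exons = ex, introns = .introns(ex))
}

.join_ids <- function(ids) paste(sort(unique(ids)), collapse = ",")
.split_ids <- function(s) if (!nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1L]]

#' Build a deduplicated event catalog over all isoform pairs
#'
#' Runs [classify_pair()] over every isoform pair of every gene and
#' deduplicates events on (gene, type, region, flanks), merging inclusion
#' and exclusion isoform sets. If a replicate-concordance filter is
#' supplied, only isoforms retained in at least one group participate, and
#' each event is flagged present in a group when at least one inclusion and
#' one exclusion isoform are retained in that group.
#'
#' @param models a [gene_models] object.
#' @param retained optional [filter_isoforms()] result (or a named list of
#'   per-group isoform id vectors).
#' @return object of class `as_catalog`: a data.frame of events with
#'   coordinates, lengths, flanks, comma-joined isoform sets and logical
#'   group presence flags.
#' @export
build_catalog <- function(models, retained = NULL) {
  groups <- names(.GROUPS)
  ret <- NULL
  if (!is.null(retained)) {
    ret <- if (inherits(retained, "isoform_filter")) retained$retained else retained
    participate <- unique(unlist(ret, use.names = FALSE))
  }
  rows <- list()
  for (g in models) {
    tids <- names(g$transcripts)
    if (!is.null(ret)) tids <- intersect(tids, participate)
    if (length(tids) < 2L) next
    for (i in seq_len(length(tids) - 1L)) for (j in seq((i + 1L), length(tids))) {
      ev <- .classify_exons(g$transcripts[[tids[i]]], g$transcripts[[tids[j]]],
                            g$strand, tids[i], tids[j])
      if (nrow(ev)) {
        ev$gene_id <- g$gene_id; ev$chrom <- g$chrom; ev$strand <- g$strand
        rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  if (!length(rows)) {
    cat0 <- .empty_events()
    cat0$gene_id <- character(0); cat0$chrom <- character(0)
    cat0$strand <- character(0); cat0$event_id <- character(0)
    for (grp in groups) cat0[[grp]] <- logical(0)
    return(structure(cat0, class = c("as_catalog", "data.frame")))
  }
  all <- do.call(rbind, rows)
  key <- paste(all$gene_id, all$type, all$region_start, all$region_end,
               all$flank_left, all$flank_right, sep = "|")
  first <- !duplicated(key)
  cat <- all[first, , drop = FALSE]
  idx <- split(seq_len(nrow(all)), key)[key[first]]
  cat$inclusion <- vapply(idx, function(k) .join_ids(all$inclusion[k]), "")
  cat$exclusion <- vapply(idx, function(k) .join_ids(all$exclusion[k]), "")
  # an isoform seen on both sides of a complex "other" region across pairs
  # stays on the inclusion side
  both <- mapply(function(i, e) {
    ii <- .split_ids(i); ee <- .split_ids(e)
    paste(setdiff(ee, ii), collapse = ",")
  }, cat$inclusion, cat$exclusion)
  cat$exclusion <- unname(both)
  cat <- cat[order(cat$gene_id, cat$region_start, cat$region_end, cat$type), ]
  cat$event_id <- sprintf("%s.e%03d", cat$gene_id,
                          stats::ave(seq_len(nrow(cat)), cat$gene_id,
                                     FUN = seq_along))
  for (grp in groups) {
    if (is.null(ret)) cat[[grp]] <- TRUE
    else {
      rg <- ret[[grp]]
      cat[[grp]] <- mapply(function(i, e) {
        any(.split_ids(i) %in% rg) && any(.split_ids(e) %in% rg)
      }, cat$inclusion, cat$exclusion)
    }
  }
  rownames(cat) <- NULL
  structure(cat, class = c("as_catalog", "data.frame"))
}

#' @export
print.as_catalog <- function(x, ...) {
  cat(sprintf("as_catalog: %d events in %d genes\n",
              nrow(x), length(unique(x$gene_id))))
  if (nrow(x)) print(table(x$type))
  invisible(x)
}

#' Summarise event-type counts, shares and per-gene rates
#'
#' The worked-example entry point behind [catalog_summary()]: takes per-type
#' event counts (and optionally per-type gene counts) and computes the
#' percentage table: event share, gene share of all AS genes, events per
#' gene. Percentages are rounded half-up to 2 decimals.
#'
#' @param event_counts named numeric vector of event counts per type.
#' @param gene_counts optional named numeric vector of gene counts per type.
#' @param total_as_genes number of distinct AS genes (denominator of the
#'   gene rate); required when `gene_counts` is given.
#' @param multiexonic_genes optional number of multi-exonic genes; when
#'   given, the fraction of them that undergo AS is reported.
#' @return data.frame with one row per type plus a `Total` row; when
#'   `multiexonic_genes` is supplied the AS fraction (percent) is attached
#'   as attribute `multi_exonic_as_pct`.
#' @export
as_type_summary <- function(event_counts, gene_counts = NULL,
                            total_as_genes = NULL, multiexonic_genes = NULL) {
  total <- sum(event_counts)
  if (total == 0) .fail("empty event catalog")
  df <- data.frame(type = names(event_counts),
                   events = as.vector(event_counts),
                   event_rate_pct = round_half_up(event_counts / total * 100, 2),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(gene_counts)) {
    if (is.null(total_as_genes)) .fail("total_as_genes required with gene_counts")
    df$genes <- as.vector(gene_counts[df$type])
    df$gene_rate_pct <- round_half_up(df$genes / total_as_genes * 100, 2)
    df$as_per_gene <- round_half_up(df$events / df$genes, 2)
  }
  tot <- data.frame(type = "Total", events = total, event_rate_pct = 100,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_counts)) {
    tot$genes <- total_as_genes
    tot$gene_rate_pct <- round_half_up(sum(df$genes) / total_as_genes * 100, 2)
    tot$as_per_gene <- round_half_up(total / total_as_genes, 2)
  }
  out <- rbind(df, tot)
  if (!is.null(multiexonic_genes) && !is.null(total_as_genes))
    attr(out, "multi_exonic_as_pct") <-
      round_half_up(total_as_genes / multiexonic_genes * 100, 2)
  out
}

#' Summarise an event catalog
#'
#' @param catalog an `as_catalog`.
#' @param multiexonic_genes optional count of multi-exonic genes for the
#'   AS-gene fraction.
#' @return list with `by_type` (the [as_type_summary()] table over the full
#'   catalog) and `per_group` (per-type event counts restricted to events
#'   flagged present in each group).
#' @export
catalog_summary <- function(catalog, multiexonic_genes = NULL) {
  if (!nrow(catalog)) .fail("empty event catalog")
  types <- intersect(.EVENT_TYPES, unique(catalog$type))
  ec <- vapply(types, function(t) sum(catalog$type == t), 0)
  gc <- vapply(types, function(t)
    length(unique(catalog$gene_id[catalog$type == t])), 0)
  nag <- length(unique(catalog$gene_id))
  per_group <- lapply(stats::setNames(nm = names(.GROUPS)), function(grp) {
    sub <- catalog[catalog[[grp]], , drop = FALSE]
    vapply(types, function(t) sum(sub$type == t), 0)
  })
  list(by_type = as_type_summary(ec, gc, nag, multiexonic_genes),
       per_group = per_group)
}

#' Write an event catalog as BED-like TSV
#'
#' Columns: chrom, 0-based start, end, event_id, type, strand, gene_id,
#' comma-joined inclusion and exclusion isoforms, and one presence flag per
#' group.
#'
#' @param catalog an `as_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(chrom = catalog$chrom, start = catalog$region_start - 1L,
                   end = catalog$region_end, event_id = catalog$event_id,
                   type = catalog$type, strand = catalog$strand,
                   gene_id = catalog$gene_id, inclusion = catalog$inclusion,
                   exclusion = catalog$exclusion, stringsAsFactors = FALSE)
  for (grp in names(.GROUPS)) df[[grp]] <- catalog[[grp]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
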