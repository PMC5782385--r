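# In-memory transcript model
#
# A "gene_models" object is a named list (one element per gene). Each gene is
# a list(gene_id, chrom, strand, transcripts) where transcripts is a named
# list of integer matrices with columns start,end: one row per exon, rows
# sorted by start, 1-based inclusive coordinates (GTF convention).

#' Build a validated gene/transcript model from an exon table
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`; one row per exon, coordinates 1-based
#'   inclusive.
#' @return an object of class `gene_models`: a named list of genes, each
#'   carrying its transcripts as sorted exon matrices. Validation enforces
#'   start <= end, one chromosome and strand per transcript (and per gene),
#'   and non-overlapping, non-adjacent exons (every intron has length >= 1).
#' @export
gene_models <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    .fail("exon table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(exons) == 0L) {
    out <- structure(list(), class = "gene_models")
    return(out)
  }
  if (any(is.na(exons$start)) || any(is.na(exons$end)))
    .fail("exon coordinates contain NA")
  bad <- exons$start > exons$end
  if (any(bad))
    .fail("exon with start > end in transcript %s",
          exons$transcript_id[which(bad)[1L]])
  if (!all(exons$strand %in% c("+", "-")))
    .fail("strand must be '+' or '-'")

  genes <- list()
  for (gid in unique(as.character(exons$gene_id))) {
    ge <- exons[exons$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in unique(as.character(ge$transcript_id))) {
      te <- ge[ge$transcript_id == tid, , drop = FALSE]
      if (length(unique(te$chrom)) != 1L || length(unique(te$strand)) != 1L)
        .fail("transcript %s has exons on multiple chromosomes or strands", tid)
      m <- cbind(start = as.integer(te$start), end = as.integer(te$end))
      m <- m[order(m[, 1L]), , drop = FALSE]
      if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L] + 1L))
        .fail("transcript %s has overlapping or adjacent exons", tid)
      txs[[tid]] <- m
    }
    if (length(unique(ge$chrom)) != 1L || length(unique(ge$strand)) != 1L)
      .fail("gene %s has transcripts on multiple chromosomes or strands", gid)
    genes[[gid]] <- list(gene_id = gid,
                         chrom = as.character(ge$chrom[1L]),
                         strand = as.character(ge$strand[1L]),
                         transcripts = txs)
  }
  structure(genes, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  ntx <- sum(vapply(x, function(g) length(g$transcripts), 0L))
  cat(sprintf("gene_models: %d genes, %d transcripts\n", length(x), ntx))
  invisible(x)
}

# introns of one exon matrix: integer matrix (start, end); zero rows for
# single-exon transcripts
.introns <- function(ex) {
  n <- nrow(ex)
  if (n < 2L)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = ex[-n, 2L] + 1L, end = ex[-1L, 1L] - 1L)
}

# union span of a gene
.gene_span <- function(g) {
  r <- range(unlist(lapply(g$transcripts, function(m) c(m[, 1L], m[, 2L]))))
  c(start = r[1L], end = r[2L])
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; records of other feature types are
#' ignored. Each exon line must carry `gene_id` and `transcript_id`
#' attributes. Lines that do not have nine tab-separated fields, or whose
#' coordinate fields are not integers, raise a parse error naming the
#' offending line number.
#'
#' @param path path to a GTF file.
#' @return a [gene_models] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) .fail("GTF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      .fail("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
            i, length(f))
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L]))))
      .fail("GTF parse error at line %d: non-integer coordinates", i)
  }
  if (!any(body)) return(gene_models(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), gene_id = character(0),
    transcript_id = character(0))))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    .fail("GTF contains no exon features: %s", path)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    .fail("exon records without gene_id/transcript_id attributes in %s", path)
  df <- as.data.frame(gr)
  gene_models(data.frame(
    chrom = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    stringsAsFactors = FALSE))
}

#' Write transcript models to a GTF file
#'
#' Output is deterministic: genes and transcripts are written in their
#' stored order, exons by coordinate, so identical models yield
#' byte-identical files. The file round-trips through [read_gtf()] into an
#' equal model.
#'
#' @param models a [gene_models] object.
#' @param path output file path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "splicescape") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 2", con)
  for (g in models) {
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      writeLines(sprintf(
        '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        g$chrom, source, ex[, 1L], ex[, 2L], g$strand, g$gene_id, tid), con)
    }
  }
  invisible(path)
}

#' Genome-wide exon and intron length multisets
#'
#' Every exon and every intron of every transcript contributes one length,
#' in bp. These are the genome-wide baselines the event-length comparisons
#' are made against.
#'
#' @param models a [gene_models] object.
#' @return list with numeric vectors `exon` and `intron`.
#' @export
exon_and_intron_lengths <- function(models) {
  if (length(models) == 0L) .fail("empty model collection")
  exl <- list(); inl <- list()
  for (g in models) for (m in g$transcripts) {
    exl[[length(exl) + 1L]] <- m[, 2L] - m[, 1L] + 1L
    im <- .introns(m)
    if (nrow(im)) inl[[length(inl) + 1L]] <- im[, 2L] - im[, 1L] + 1L
  }
  list(exon = as.integer(unlist(exl)),
       intron = as.integer(unlist(inl)))
}

# isoform -> gene map as a named character vector
.isoform_gene_map <- function(models) {
  tid <- unlist(lapply(models, function(g) names(g$transcripts)), use.names = FALSE)
  gid <- unlist(lapply(models, function(g)
    rep(g$gene_id, length(g$transcripts))), use.names = FALSE)
  stats::setNames(gid, tid)
}
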