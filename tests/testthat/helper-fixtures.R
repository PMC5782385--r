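# Shared fixture builders: small exon matrices, random transcript pairs
# and a compact expression-table constructor.

exm <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# transcript object as classify_pair expects it
tx <- function(exons, id = "t1", gene = "G1", strand = "+", chrom = "chr1") {
  list(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
       exons = exons, introns = splicescape:::.introns(exons))
}

# random multi-exon structure: alternating exon/intron walk
random_exons <- function(max_exons = 6, max_exon = 12, max_intron = 8,
                         origin = NULL) {
  n <- sample(seq_len(max_exons), 1)
  start <- if (is.null(origin)) sample(1:20, 1) else origin
  ex <- matrix(0L, n, 2)
  p <- start
  for (i in seq_len(n)) {
    w <- sample(seq_len(max_exon), 1)
    ex[i, ] <- c(p, p + w - 1L)
    p <- p + w + sample(2:max_intron, 1)   # gap >= 2 so intron >= 2
  }
  ex
}

# random local edit of a base structure, exercising all event patterns
edit_exons <- function(ex) {
  n <- nrow(ex)
  op <- sample(c("ir", "es", "aa", "ad", "merge2", "none"), 1)
  im <- splicescape:::.introns(ex)
  if (op == "ir" && n >= 2) {
    i <- sample(n - 1L, 1)
    ex[i, 2] <- ex[i + 1L, 2]
    return(ex[-(i + 1L), , drop = FALSE])
  }
  if (op == "es" && n >= 3) {
    e <- sample(2:(n - 1L), 1)
    return(ex[-e, , drop = FALSE])
  }
  if (op == "aa" && n >= 2) {
    i <- sample(n - 1L, 1)
    k <- sample(1:4, 1)
    exw <- ex[i + 1L, 2] - ex[i + 1L, 1] + 1L
    ilen <- im[i, 2] - im[i, 1] + 1L
    if (exw > k + 1L && sample(c(TRUE, FALSE), 1)) ex[i + 1L, 1] <- ex[i + 1L, 1] + k
    else if (ilen > k + 1L) ex[i + 1L, 1] <- ex[i + 1L, 1] - k
    return(ex)
  }
  if (op == "ad" && n >= 2) {
    i <- sample(n - 1L, 1)
    k <- sample(1:4, 1)
    exw <- ex[i, 2] - ex[i, 1] + 1L
    ilen <- im[i, 2] - im[i, 1] + 1L
    if (exw > k + 1L && sample(c(TRUE, FALSE), 1)) ex[i, 2] <- ex[i, 2] - k
    else if (ilen > k + 1L) ex[i, 2] <- ex[i, 2] + k
    return(ex)
  }
  if (op == "merge2" && n >= 3) {
    i <- sample(n - 2L, 1)
    ex[i, 2] <- ex[i + 2L, 2]
    return(ex[-c(i + 1L, i + 2L), , drop = FALSE])
  }
  ex
}

# expression table over explicit isoforms for the standard 40-library
# design; `values` is a named list isoform -> either a single mean used
# everywhere or a full 40-vector (library order as in lib_names())
lib_names <- function() {
  g <- expand.grid(r = 1:2, t = c(12, 24, 48, 96, 144),
                   cond = c("control", "salt"), tis = c("root", "leaf"),
                   stringsAsFactors = FALSE)
  sprintf("%s_%s_%dh_r%d", g$tis, g$cond, g$t, g$r)
}

make_table <- function(values, genes) {
  nms <- lib_names()
  m <- t(vapply(values, function(v) {
    if (length(v) == 1L) rep(v, 40L) else v
  }, numeric(40)))
  colnames(m) <- nms
  rownames(m) <- names(values)
  expression_table(m, genes)
}

# set one context (tissue, condition, timepoint, both replicates) of an
# existing matrix row
set_context <- function(m, iso, tissue, condition, tp, value) {
  for (r in 1:2)
    m[iso, sprintf("%s_%s_%dh_r%d", tissue, condition, tp, r)] <- value
  m
}
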