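# Synthetic transcriptome generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: multi-isoform
# loci whose alternative isoforms each realise one injected splicing event
# (built by a local edit of the gene's base isoform, so the classifier has
# a unique correct answer), log-scale isoform abundances with ~70% of
# values below 1 FPKM, a 2 tissue x 2 condition x 5 timepoint x 2
# replicate library design with concordant replicates, condition-dependent
# usage-ratio shifts for a subset of events, and intergenic single-exon
# decoy transcripts with near-zero abundance for cutoff calibration.

#' Simulation configuration
#'
#' Defaults emulate the salt-stress study design: 40 libraries (root/leaf
#' x control/salt x 12-144 h x 2 replicates), event-type injection
#' probabilities close to the observed type mix, isoform abundances
#' log-normal with bin fractions ~0.70/0.20/0.10 (below 1 / 1-10 / above
#' 10 FPKM), multiplicative replicate noise, and a usage shift of
#' `das_delta` injected into salt libraries for a fraction of events.
#'
#' @param n_genes number of multi-exon gene loci.
#' @param seed integer random seed; the whole simulation is deterministic
#'   given the seed.
#' @param exons_per_gene integer range (min, max) of exons of the base
#'   isoform.
#' @param exon_meanlog,exon_sdlog,exon_min exon length model (log-normal,
#'   bp, floored at `exon_min`).
#' @param intron_meanlog,intron_sdlog,intron_min intron length model.
#' @param n_events_probs probabilities of 0..3 injected events per gene.
#' @param type_probs injection probabilities for IR/ES/AA/AD/other (the
#'   "other" injection is a two-intron retention, a combined pattern).
#' @param abund_meanlog,abund_sdlog per-isoform mean FPKM model; the
#'   defaults place 70/20/10% of values below 1 / in 1-10 / above 10 FPKM.
#' @param noise_sdlog replicate noise: each cell is the isoform mean times
#'   `exp(rnorm(1, 0, noise_sdlog))` (log-normal model only).
#' @param noise_model `"lognormal"` (multiplicative measurement noise, the
#'   default) or `"poisson"` (each cell drawn as a Poisson count with the
#'   isoform mean as rate; gives exact counting statistics, under which the
#'   Fisher test is calibrated).
#' @param das_fraction fraction of eligible events given a usage shift.
#' @param das_delta usage-ratio shift (inclusion share goes from r under
#'   control to r + delta under salt), in (0, 1).
#' @param das_tissues,das_timepoints where the shift applies.
#' @param timepoints timepoints of the design, hours.
#' @param n_decoys number of intergenic single-exon decoy transcripts
#'   (default 20% of `n_genes`).
#' @param decoy_mean mean FPKM of decoy cells (exponential).
#' @param truth_cutoff FPKM cutoff at which ground-truth filter flags are
#'   recorded.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, seed = 1L,
                              exons_per_gene = c(3L, 8L),
                              exon_meanlog = log(170), exon_sdlog = 0.6,
                              exon_min = 30L,
                              intron_meanlog = log(300), intron_sdlog = 0.9,
                              intron_min = 60L,
                              n_events_probs = c(0.5, 0.3, 0.15, 0.05),
                              type_probs = c(IR = 0.36, ES = 0.08, AA = 0.29,
                                             AD = 0.13, other = 0.14),
                              abund_meanlog = -1.595, abund_sdlog = 3.041,
                              noise_sdlog = 0.15,
                              noise_model = c("lognormal", "poisson"),
                              das_fraction = 0.3, das_delta = 0.25,
                              das_tissues = "root",
                              das_timepoints = c(12, 24, 48, 96, 144),
                              timepoints = c(12, 24, 48, 96, 144),
                              n_decoys = NULL, decoy_mean = 0.2,
                              truth_cutoff = 2.6) {
  noise_model <- match.arg(noise_model)
  if (n_genes < 1) .fail("n_genes must be >= 1")
  if (das_delta <= 0 || das_delta >= 1) .fail("das_delta must be in (0, 1)")
  if (abs(sum(n_events_probs) - 1) > 1e-8) .fail("n_events_probs must sum to 1")
  if (any(type_probs < 0)) .fail("type_probs must be >= 0")
  if (exons_per_gene[1L] < 2L) .fail("base isoforms need at least 2 exons")
  if (is.null(n_decoys)) n_decoys <- max(10L, round(0.2 * n_genes))
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d genes, %d decoys, seed %d, ",
                     "delta %.2f in %s\n"),
              x$n_genes, x$n_decoys, x$seed, x$das_delta,
              paste(x$das_tissues, collapse = "/")))
  invisible(x)
}

# one AA/AD boundary-shift size: modal 3 bp (AA) / 4 bp (AD) with a
# geometric tail
.shift_size <- function(type) {
  mode <- if (type == "AA") 3L else 4L
  alt <- if (type == "AA") 4L else 3L
  u <- stats::runif(1)
  if (u < 0.40) mode else if (u < 0.60) alt else 5L + stats::rgeom(1L, 0.3)
}

# derive an isoform from base exons `ex` realising one event of `type`;
# returns list(exons, region, length, derived_includes, target) or NULL
.derive_isoform <- function(ex, type, strand, used_introns, used_exons) {
  n <- nrow(ex)
  im <- .introns(ex)
  free_in <- setdiff(seq_len(n - 1L), used_introns)
  if (type == "IR") {
    if (!length(free_in)) return(NULL)
    i <- if (length(free_in) == 1L) free_in else sample(free_in, 1L)
    ex2 <- ex; ex2[i, 2L] <- ex[i + 1L, 2L]; ex2 <- ex2[-(i + 1L), , drop = FALSE]
    return(list(exons = ex2, region = c(im[i, 1L], im[i, 2L]),
                length = im[i, 2L] - im[i, 1L] + 1L,
                derived_includes = TRUE, intron = i, exon = NA_integer_))
  }
  if (type == "ES") {
    free_ex <- setdiff(seq(2L, n - 1L), used_exons)
    if (n < 3L || !length(free_ex)) return(NULL)
    e <- if (length(free_ex) == 1L) free_ex else sample(free_ex, 1L)
    ex2 <- ex[-e, , drop = FALSE]
    return(list(exons = ex2, region = c(ex[e, 1L], ex[e, 2L]),
                length = ex[e, 2L] - ex[e, 1L] + 1L,
                derived_includes = FALSE, intron = NA_integer_, exon = e))
  }
  if (type %in% c("AA", "AD")) {
    # genomic edge realising the requested transcript-direction type
    right_edge <- (type == "AA") == (strand == "+")
    if (!length(free_in)) return(NULL)
    for (i in sample(rep(free_in, 2L))) {
      k <- .shift_size(type)
      ilen <- im[i, 2L] - im[i, 1L] + 1L
      if (right_edge) {
        exw <- ex[i + 1L, 2L] - ex[i + 1L, 1L] + 1L
        dirs <- c(if (exw - k >= 5L) 1L, if (ilen - k >= 5L) -1L)
        if (!length(dirs)) next
        d <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
        A <- im[i, 2L]; A2 <- A + d * k
        ex2 <- ex; ex2[i + 1L, 1L] <- A2 + 1L
        return(list(exons = ex2,
                    region = c(min(A, A2) + 1L, max(A, A2)), length = k,
                    derived_includes = d < 0L, intron = i, exon = NA_integer_))
      } else {
        exw <- ex[i, 2L] - ex[i, 1L] + 1L
        dirs <- c(if (exw - k >= 5L) -1L, if (ilen - k >= 5L) 1L)
        if (!length(dirs)) next
        d <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
        D <- im[i, 1L]; D2 <- D + d * k
        ex2 <- ex; ex2[i, 2L] <- D2 - 1L
        return(list(exons = ex2,
                    region = c(min(D, D2), max(D, D2) - 1L), length = k,
                    derived_includes = d > 0L, intron = i, exon = NA_integer_))
      }
    }
    return(NULL)
  }
  # "other": retain two consecutive introns (a combined pattern)
  ok <- intersect(free_in, free_in - 1L)          # i with i and i+1 free
  ok <- ok[ok >= 1L & ok + 1L <= n - 1L]
  if (!length(ok)) return(NULL)
  i <- if (length(ok) == 1L) ok else sample(ok, 1L)
  ex2 <- ex; ex2[i, 2L] <- ex[i + 2L, 2L]
  ex2 <- ex2[-c(i + 1L, i + 2L), , drop = FALSE]
  len <- (im[i, 2L] - im[i, 1L] + 1L) + (im[i + 1L, 2L] - im[i + 1L, 1L] + 1L)
  list(exons = ex2, region = c(im[i, 1L], im[i + 1L, 2L]), length = len,
       derived_includes = TRUE, intron = c(i, i + 1L), exon = i + 1L)
}

#' Simulate an annotated transcriptome with known splicing truth
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes `genome.gtf`,
#'   `expression.tsv` and `truth.json` there.
#' @return list with `models` ([gene_models]), `table` (`expr_table`),
#'   `truth` (event table, per-isoform filter flags at the truth cutoff,
#'   decoy ids) and `paths` (when written).
#' @export
simulate_splicing <- function(config, dir = NULL) {
  cf <- config
  set.seed(cf$seed)
  tissues <- .TISSUES; conditions <- .CONDITIONS
  lib <- expand.grid(replicate = 1:2, timepoint = cf$timepoints,
                     condition = conditions, tissue = tissues,
                     stringsAsFactors = FALSE)
  lib$name <- sprintf("%s_%s_%dh_r%d", lib$tissue, lib$condition,
                      lib$timepoint, lib$replicate)

  cursor <- 1000L
  exon_rows <- list(); truth_ev <- list()
  iso_ids <- character(0); iso_gene <- character(0); iso_mean <- numeric(0)
  das_adjust <- list()   # isoform id -> salt-adjusted mean
  type_names <- names(cf$type_probs)

  for (gi in seq_len(cf$n_genes)) {
    gid <- sprintf("G%04d", gi)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq(cf$exons_per_gene[1L], cf$exons_per_gene[2L]), 1L)
    exl <- pmax(cf$exon_min, round(stats::rlnorm(n_ex, cf$exon_meanlog, cf$exon_sdlog)))
    inl <- pmax(cf$intron_min,
                round(stats::rlnorm(max(0L, n_ex - 1L), cf$intron_meanlog,
                                    cf$intron_sdlog)))
    starts <- cursor + c(0L, cumsum(exl[-n_ex] + inl))
    ex <- cbind(start = as.integer(starts),
                end = as.integer(starts + exl - 1L))
    cursor <- ex[n_ex, 2L] + 5000L

    n_ev <- sample(0:3, 1L, prob = cf$n_events_probs)
    txs <- list(t1 = ex)
    used_in <- integer(0); used_ex <- integer(0)
    gene_truth <- list()
    for (k in seq_len(n_ev)) {
      dv <- NULL
      for (try in 1:20) {
        ty <- sample(type_names, 1L, prob = cf$type_probs)
        dv <- .derive_isoform(ex, ty, strand, used_in, used_ex)
        if (!is.null(dv)) break
      }
      if (is.null(dv)) next
      used_in <- c(used_in, dv$intron[!is.na(dv$intron)])
      used_ex <- c(used_ex, dv$exon[!is.na(dv$exon)])
      tid <- sprintf("t%d", length(txs) + 1L)
      txs[[tid]] <- dv$exons
      gene_truth[[length(gene_truth) + 1L]] <- list(
        type = ty, region = dv$region, length = dv$length,
        derived = tid, derived_includes = dv$derived_includes)
    }
    tids <- sprintf("%s.%s", gid, names(txs))
    for (t in seq_along(txs))
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        chrom = "chr1", start = txs[[t]][, 1L], end = txs[[t]][, 2L],
        strand = strand, gene_id = gid, transcript_id = tids[t],
        stringsAsFactors = FALSE)
    m <- stats::rlnorm(length(txs), cf$abund_meanlog, cf$abund_sdlog)
    iso_ids <- c(iso_ids, tids); iso_gene <- c(iso_gene, rep(gid, length(txs)))
    iso_mean <- c(iso_mean, m)
    names(m) <- tids
    tot <- sum(m)
    for (gt in gene_truth) {
      did <- sprintf("%s.%s", gid, gt$derived)
      others <- setdiff(tids, did)
      base_id <- sprintf("%s.t1", gid)
      if (gt$derived_includes) { inc <- did; exc <- base_id
      } else { inc <- .join_ids(others); exc <- did }
      r <- if (gt$derived_includes) m[[did]] / tot else (tot - m[[did]]) / tot
      truth_ev[[length(truth_ev) + 1L]] <- data.frame(
        gene_id = gid, type = gt$type,
        region_start = gt$region[1L], region_end = gt$region[2L],
        length = gt$length, frame_class = paste0("AS_", gt$length %% 3),
        inclusion = inc, exclusion = exc, derived = did,
        derived_includes = gt$derived_includes, usage_ratio = unname(r),
        das = FALSE, delta = 0, stringsAsFactors = FALSE)
    }
  }

  truth <- if (length(truth_ev)) do.call(rbind, truth_ev) else NULL

  # usage shifts: one eligible event per gene, a das_fraction of them
  if (!is.null(truth) && nrow(truth)) {
    q <- truth$usage_ratio + cf$das_delta
    eligible <- which(q > 0.02 & q < 0.95)
    eligible <- eligible[!duplicated(truth$gene_id[eligible])]
    n_das <- round(cf$das_fraction * length(eligible))
    if (n_das > 0L) {
      pick <- if (length(eligible) == 1L) eligible
      else sample(eligible, n_das)
      truth$das[pick] <- TRUE
      truth$delta[pick] <- cf$das_delta
      for (i in pick) {
        did <- truth$derived[i]
        gid <- truth$gene_id[i]
        gm <- iso_mean[iso_gene == gid]
        names(gm) <- iso_ids[iso_gene == gid]
        others <- sum(gm) - gm[[did]]
        qq <- truth$usage_ratio[i] + cf$das_delta
        das_adjust[[did]] <- if (truth$derived_includes[i])
          qq * others / (1 - qq) else others * (1 - qq) / qq
      }
    }
  }

  # decoys: intergenic single-exon transcripts
  decoy_ids <- character(0)
  if (cf$n_decoys > 0L) {
    for (d in seq_len(cf$n_decoys)) {
      did <- sprintf("decoy%04d", d)
      len <- pmax(cf$exon_min,
                  round(stats::rlnorm(1L, cf$exon_meanlog, cf$exon_sdlog)))
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        chrom = "chr1", start = cursor, end = cursor + len - 1L,
        strand = "+", gene_id = did, transcript_id = paste0(did, ".t1"),
        stringsAsFactors = FALSE)
      cursor <- cursor + len + 2000L
      decoy_ids <- c(decoy_ids, paste0(did, ".t1"))
    }
  }

  models <- gene_models(do.call(rbind, exon_rows))

  # expression matrix
  all_ids <- c(iso_ids, decoy_ids)
  gene_map <- stats::setNames(c(iso_gene, sub("\\.t1$", "", decoy_ids)), all_ids)
  fpkm <- matrix(0, nrow = length(all_ids), ncol = nrow(lib),
                 dimnames = list(all_ids, lib$name))
  das_ctx <- lib$tissue %in% cf$das_tissues & lib$condition == "salt" &
    lib$timepoint %in% cf$das_timepoints
  for (j in seq_len(nrow(lib))) {
    mu <- c(stats::setNames(iso_mean, iso_ids),
            stats::setNames(rep(0, length(decoy_ids)), decoy_ids))
    if (das_ctx[j]) for (did in names(das_adjust)) mu[[did]] <- das_adjust[[did]]
    v <- if (cf$noise_model == "poisson")
      stats::rpois(length(all_ids), mu)
    else mu * exp(stats::rnorm(length(all_ids), 0, cf$noise_sdlog))
    names(v) <- all_ids
    if (length(decoy_ids))
      v[decoy_ids] <- stats::rexp(length(decoy_ids), rate = 1 / cf$decoy_mean)
    fpkm[, j] <- v
  }
  fpkm <- signif(fpkm, 6)   # fixed serialisation precision
  table <- expression_table(fpkm, gene_map)

  # ground-truth replicate-concordance flags at the truth cutoff
  flags <- data.frame(isoform_id = all_ids, stringsAsFactors = FALSE)
  for (grp in names(.GROUPS)) {
    tis <- if (grp %in% c("RC", "RS")) "root" else "leaf"
    cond <- if (grp %in% c("RC", "LC")) "control" else "salt"
    pass <- rep(FALSE, length(all_ids))
    for (tp in cf$timepoints) {
      c1 <- sprintf("%s_%s_%dh_r1", tis, cond, tp)
      c2 <- sprintf("%s_%s_%dh_r2", tis, cond, tp)
      pass <- pass | (fpkm[, c1] >= cf$truth_cutoff & fpkm[, c2] >= cf$truth_cutoff)
    }
    flags[[grp]] <- pass
  }

  truth_out <- list(seed = cf$seed, events = truth, filter_flags = flags,
                    decoys = decoy_ids, truth_cutoff = cf$truth_cutoff,
                    das_tissues = cf$das_tissues,
                    das_timepoints = cf$das_timepoints)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(gtf = file.path(dir, "genome.gtf"),
                  expression = file.path(dir, "expression.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_gtf(models, paths$gtf)
    write_expression(table, paths$expression)
    jsonlite::write_json(truth_out, paths$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  list(models = models, table = table, truth = truth_out, config = cf,
       paths = paths)
}

#' Recovery metrics of a pipeline run against simulation truth
#'
#' Matches catalog events to injected truth on (gene, type, region) and
#' reports per-type recall and precision; optionally scores differential
#' splicing detection (per injected delta, and the false positive rate on
#' non-shifted events) and agreement of the expression filter with the
#' ground-truth flags.
#'
#' @param truth the `truth` element of [simulate_splicing()] (or the same
#'   structure read back from `truth.json`).
#' @param catalog an `as_catalog` built from the simulated data.
#' @param das_results optional [das_scan()] table.
#' @param filter optional [filter_isoforms()] result.
#' @return list with `by_type` (truth events, matched, recall, catalog
#'   events, precision), `das` (detection rate per delta, false positive
#'   rate, mean recovered change frequency) and `filter_agreement`. All
#'   metrics are `NA` when the truth is empty.
#' @export
evaluate_recovery <- function(truth, catalog, das_results = NULL,
                              filter = NULL) {
  tev <- truth$events
  if (is.null(tev) || !nrow(tev))
    return(list(by_type = NA, das = NA, filter_agreement = NA))
  tkey <- paste(tev$gene_id, tev$type, tev$region_start, tev$region_end)
  ckey <- paste(catalog$gene_id, catalog$type, catalog$region_start,
                catalog$region_end)
  tev$matched <- tkey %in% ckey
  types <- unique(tev$type)
  by_type <- do.call(rbind, lapply(types, function(ty) {
    tt <- tev[tev$type == ty, ]
    nc <- sum(catalog$type == ty)
    data.frame(type = ty, truth_events = nrow(tt), matched = sum(tt$matched),
               recall = mean(tt$matched), catalog_events = nc,
               precision = if (nc) sum(ckey[catalog$type == ty] %in% tkey) / nc
               else NA_real_, stringsAsFactors = FALSE)
  }))
  das <- NULL
  if (!is.null(das_results)) {
    ev_map <- stats::setNames(catalog$event_id, ckey)
    tev$event_id <- ev_map[tkey]
    ctx <- das_results$tissue %in% truth$das_tissues &
      das_results$timepoint_h %in% truth$das_timepoints
    sig_events <- unique(das_results$event_id[ctx & das_results$significant])
    deltas <- sort(unique(tev$delta[tev$das]))
    per_delta <- vapply(deltas, function(d) {
      ids <- tev$event_id[tev$das & tev$delta == d & tev$matched]
      mean(ids %in% sig_events)
    }, 0)
    null_ids <- tev$event_id[!tev$das & tev$matched]
    cf_inj <- das_results$change_frequency[
      ctx & das_results$event_id %in% tev$event_id[tev$das & tev$matched]]
    das <- list(detection_rate = stats::setNames(per_delta, deltas),
                null_positive_rate = if (length(null_ids))
                  mean(null_ids %in% sig_events) else NA_real_,
                mean_change_frequency = mean(cf_inj, na.rm = TRUE))
  }
  fa <- NULL
  if (!is.null(filter)) {
    tf <- truth$filter_flags
    agree <- vapply(names(.GROUPS), function(grp) {
      mean((tf$isoform_id %in% filter$retained[[grp]]) == tf[[grp]])
    }, 0)
    fa <- agree
  }
  list(by_type = by_type, das = das, filter_agreement = fa)
}
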