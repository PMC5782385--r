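# Event-length characterisation: reading-frame preservation classes and
# length comparisons against genome-wide exon/intron baselines.
#
# An event of length divisible by 3 (class AS_0) leaves the downstream
# reading frame intact; remainders 1 and 2 (AS_1, AS_2) shift it,
# potentially introducing premature termination codons.

#' Reading-frame class of an event length
#'
#' @param length event length(s) in bp, >= 1.
#' @return character vector: `"AS_0"`, `"AS_1"` or `"AS_2"` for remainder
#'   0, 1 or 2 when the length is divided by 3.
#' @examples
#' frame_class(c(3, 4, 83))  # AS_0, AS_1, AS_2
#' @export
frame_class <- function(length) {
  if (any(is.na(length)) || any(length < 1)) .fail("event lengths must be >= 1")
  paste0("AS_", length %% 3)
}

#' Frame-class spectrum of event lengths
#'
#' Fractions of AS_0/AS_1/AS_2 among a set of lengths; for a catalog, one
#' spectrum per basic event type ("other" events mix heterogeneous
#' structures and are excluded from frame analyses).
#'
#' @param x numeric vector of lengths, or an `as_catalog`.
#' @return for lengths: named numeric vector of three fractions summing
#'   to 1; for a catalog: matrix with one row per event type.
#' @export
frame_spectrum <- function(x) {
  if (inherits(x, "as_catalog")) {
    types <- intersect(c("IR", "ES", "AA", "AD"), unique(x$type))
    if (!length(types)) .fail("no basic-type events in catalog")
    return(t(vapply(stats::setNames(nm = types), function(t)
      frame_spectrum(x$length[x$type == t]), numeric(3))))
  }
  if (!length(x)) .fail("empty length set")
  cl <- factor(frame_class(x), levels = c("AS_0", "AS_1", "AS_2"))
  p <- prop.table(table(cl))
  stats::setNames(as.numeric(p), names(p))
}

#' Binned length distribution of events of one type
#'
#' Bin width is 1 bp for the short boundary-shift events (AA/AD) and 3 bp
#' for IR/ES, whose lengths spread over hundreds of bp.
#'
#' @param events an `as_catalog` (or any data.frame with `type` and
#'   `length`).
#' @param type one of `"IR"`, `"ES"`, `"AA"`, `"AD"`.
#' @return list with `breaks`/`counts` (histogram), `min`, `max` and
#'   `mode` (the most frequent exact length; ties resolve to the
#'   smallest).
#' @export
length_histogram <- function(events, type) {
  if (!type %in% c("IR", "ES", "AA", "AD")) .fail("unknown event type: %s", type)
  len <- events$length[events$type == type]
  if (!length(len)) .fail("no events of type %s", type)
  bw <- if (type %in% c("AA", "AD")) 1L else 3L
  lo <- min(len) - 0.5
  breaks <- seq(lo, max(len) + bw, by = bw)
  h <- graphics::hist(len, breaks = breaks, plot = FALSE)
  tab <- table(len)
  list(breaks = h$breaks, counts = h$counts, min = min(len), max = max(len),
       mode = as.numeric(names(tab)[which.max(tab)]))
}

#' Welch two-sample comparison of length distributions
#'
#' Used to compare event lengths (retained introns, skipped exons) against
#' the genome-wide intron/exon baselines. Welch's unequal-variance t test
#' is applied, two-sided.
#'
#' @param sample_a,sample_b numeric length samples (each n >= 2 with
#'   nonzero variance).
#' @return list with `t`, `p_value`, `mean_a`, `mean_b` and `direction`
#'   (`"a_shorter"`, `"b_shorter"` or `"equal"`).
#' @export
compare_lengths <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    .fail("both samples must have n >= 2")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0 &&
      mean(sample_a) == mean(sample_b))
    return(list(t = 0, p_value = 1, mean_a = mean(sample_a),
                mean_b = mean(sample_b), direction = "equal"))
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    .fail("degenerate samples: both have zero variance")
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  ma <- mean(sample_a); mb <- mean(sample_b)
  list(t = unname(tt$statistic), p_value = tt$p.value, mean_a = ma,
       mean_b = mb,
       direction = if (ma < mb) "a_shorter" else if (ma > mb) "b_shorter" else "equal")
}
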