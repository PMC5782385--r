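test_that("classify_pair types the canonical event patterns", {
  t1 <- tx(exm(1, 100, 201, 300), "t1")
  t2 <- tx(exm(1, 300), "t2")
  ev <- classify_pair(t1, t2)
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$region_start, ev$region_end, ev$length), c(101, 200, 100))
  expect_equal(ev$inclusion, "t2")   # t2 retains the intron

  ev <- classify_pair(tx(exm(1, 100, 201, 250, 301, 400), "t1"),
                      tx(exm(1, 100, 301, 400), "t2"))
  expect_equal(ev$type, "ES")
  expect_equal(ev$length, 50)
  expect_equal(ev$inclusion, "t1")

  # NAGNAG-scale 3 bp acceptor shift
  ev <- classify_pair(tx(exm(1, 100, 201, 300), "t1"),
                      tx(exm(1, 100, 204, 300), "t2"))
  expect_equal(ev$type, "AA")
  expect_equal(ev$length, 3)
  expect_equal(c(ev$region_start, ev$region_end), c(201, 203))

  # same shift on the minus strand is a donor shift
  ev <- classify_pair(tx(exm(1, 100, 201, 300), "t1", strand = "-"),
                      tx(exm(1, 100, 204, 300), "t2", strand = "-"))
  expect_equal(ev$type, "AD")

  # identity yields nothing
  expect_equal(nrow(classify_pair(t1, tx(exm(1, 100, 201, 300), "t3"))), 0)

  # contract violations
  expect_error(classify_pair(t1, tx(exm(1, 50), "t9", gene = "G2")),
               "different genes")
  expect_error(classify_pair(t1, tx(exm(1, 50), "t9", strand = "-")),
               "different strands")
})

test_that("complex bubbles (two retained introns, no shared site) are other", {
  ev <- classify_pair(tx(exm(1, 100, 201, 300, 401, 500), "t1"),
                      tx(exm(1, 500), "t2"))
  expect_equal(ev$type, "other")
  expect_equal(ev$length, 200)     # sum of the two variable regions
  expect_equal(c(ev$region_start, ev$region_end), c(101, 400))
})

test_that("classifier matches the per-base oracle on random structures", {
  set.seed(1234)
  norm <- function(df) {
    df <- df[, c("type", "region_start", "region_end", "length")]
    df[order(df$type, df$region_start, df$region_end), , drop = FALSE]
  }
  for (i in 1:800) {
    strand <- sample(c("+", "-"), 1)
    e1 <- random_exons()
    e2 <- if (runif(1) < 0.5) edit_exons(e1)
          else random_exons(origin = sample(1:15, 1))
    got <- splicescape:::.classify_exons(e1, e2, strand)
    want <- oracle_classify(e1, e2, strand)
    expect_equal(norm(got), norm(want), ignore_attr = TRUE,
                 label = sprintf("case %d", i))
  }
})

test_that("classify_pair is symmetric with swapped isoform roles", {
  set.seed(77)
  for (i in 1:150) {
    e1 <- random_exons(); e2 <- edit_exons(e1)
    a <- classify_pair(tx(e1, "x"), tx(e2, "y"))
    b <- classify_pair(tx(e2, "y"), tx(e1, "x"))
    o <- function(d) d[order(d$region_start, d$type), ]
    a <- o(a); b <- o(b)
    expect_equal(a$type, b$type)
    expect_equal(a$region_start, b$region_start)
    expect_equal(a$length, b$length)
    expect_equal(a$inclusion, b$inclusion)  # roles depend on structure only
  }
})

test_that("events are invariant under coordinate mirroring with strand flip", {
  set.seed(88)
  for (i in 1:150) {
    e1 <- random_exons(); e2 <- edit_exons(e1)
    strand <- sample(c("+", "-"), 1)
    a <- splicescape:::.classify_exons(e1, e2, strand)
    C <- max(e1, e2) + 7L
    mirror <- function(ex) {
      m <- cbind(C - ex[, 2], C - ex[, 1])
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    }
    b <- splicescape:::.classify_exons(mirror(e1), mirror(e2),
                                       if (strand == "+") "-" else "+")
    o <- function(d) sort(paste(d$type, d$length))
    expect_equal(o(a), o(b))
  }
})

test_that("build_catalog deduplicates shared regions and merges isoform sets", {
  # three isoforms; t2 and t3 both splice the same intron retained in t1
  df <- data.frame(
    chrom = "chr1",
    start = c(1, 1, 201, 1, 201, 401),
    end = c(300, 100, 300, 100, 300, 500),
    strand = "+",
    gene_id = "G1",
    transcript_id = c("t1", "t2", "t2", "t3", "t3", "t3"))
  m <- gene_models(df)
  catl <- build_catalog(m)
  ir <- catl[catl$type == "IR", ]
  expect_equal(nrow(ir), 1)
  expect_equal(ir$inclusion, "t1")
  expect_equal(ir$exclusion, "t2,t3")
})

test_that("group presence flags require inclusion and exclusion retained", {
  df <- data.frame(chrom = "chr1", start = c(1, 1, 201), end = c(300, 100, 300),
                   strand = "+", gene_id = "G1",
                   transcript_id = c("t1", "t2", "t2"))
  m <- gene_models(df)
  ret <- list(RC = c("t1", "t2"), RS = c("t1", "t2"), LC = "t1", LS = character(0))
  catl <- build_catalog(m, ret)
  expect_equal(nrow(catl), 1)
  expect_true(catl$RC && catl$RS)
  expect_false(catl$LC)   # exclusion isoform not retained in LC
  expect_false(catl$LS)
})

test_that("catalog recovers injected events completely and type-exactly", {
  cf <- simulation_config(n_genes = 200, seed = 31, abund_meanlog = log(100),
                          abund_sdlog = 0.4)
  sim <- simulate_splicing(cf)
  filt <- filter_isoforms(sim$table, 2.6)
  catl <- build_catalog(sim$models, filt)
  ev <- evaluate_recovery(sim$truth, catl)
  expect_true(all(ev$by_type$recall == 1))
  # every catalog event's region lies within its isoforms' pairwise overlap
  for (i in seq_len(nrow(catl))) {
    g <- sim$models[[catl$gene_id[i]]]
    ids <- c(splicescape:::.split_ids(catl$inclusion[i]),
             splicescape:::.split_ids(catl$exclusion[i]))
    spans <- vapply(g$transcripts[ids], function(ex) range(ex), numeric(2))
    expect_gte(catl$region_start[i], max(spans[1, ]))
    expect_lte(catl$region_end[i], min(spans[2, ]))
  }
})

test_that("catalog summary reproduces worked percentages and tallies", {
  s <- as_type_summary(
    c(AA = 4146, AD = 1809, ES = 1093, IR = 5063, other = 2061),
    gene_counts = c(AA = 3065, AD = 1526, ES = 888, IR = 3492, other = 1171),
    total_as_genes = 6798, multiexonic_genes = 21527)
  expect_equal(s$event_rate_pct[s$type == "IR"], 35.73)
  expect_equal(s$event_rate_pct[s$type == "ES"], 7.71)
  expect_equal(s$as_per_gene[s$type == "IR"], 1.45)

  # single type: 100% / 0% split, and an independent tally on a catalog
  one <- as_type_summary(c(IR = 5))
  expect_equal(one$event_rate_pct, c(100, 100))

  sim <- simulate_splicing(simulation_config(n_genes = 120, seed = 55,
                                             abund_meanlog = log(50),
                                             abund_sdlog = 0.5))
  catl <- build_catalog(sim$models)
  cs <- catalog_summary(catl)$by_type
  tally <- table(catl$type)
  for (ty in names(tally))
    expect_equal(cs$events[cs$type == ty], unname(tally[ty]))
  expect_equal(sum(cs$event_rate_pct[cs$type != "Total"]), 100,
               tolerance = 0.02)
})
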