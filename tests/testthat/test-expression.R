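test_that("abundance bins count each isoform x library cell once", {
  tab <- make_table(list(a = 0.5, b = 2, c = 20),
                    c(a = "G1", b = "G1", c = "G2"))
  expect_equal(unname(abundance_bins(tab)), c(1, 1, 1) / 3)
  zero <- make_table(list(a = 0, b = 0), c(a = "G1", b = "G2"))
  expect_equal(unname(abundance_bins(zero)), c(1, 0, 0))
})

test_that("survey abundance model reproduces the 70/20/10 bin fractions", {
  cfg <- simulation_config(n_genes = 2500, seed = 101, n_decoys = 0,
                           n_events_probs = c(0, 1, 0, 0), das_fraction = 0)
  sim <- simulate_splicing(cfg)
  expect_gt(nrow(sim$table$fpkm), 4500)
  b <- abundance_bins(sim$table)
  expect_equal(unname(b), c(0.70, 0.20, 0.10), tolerance = 0.02)
})

test_that("top-isoform fractions are ordered shares of the gene total", {
  tab <- make_table(list(a = 8, b = 2, c = 5),
                    c(a = "G1", b = "G1", c = "G2"))
  tf <- top_isoform_fractions(tab, "RC", k = 5)
  expect_equal(rownames(tf$per_gene), "G1")   # single-isoform G2 excluded
  expect_equal(unname(tf$per_gene["G1", 1:2]), c(0.8, 0.2))
  expect_equal(sum(tf$per_gene["G1", ]), 1)
  expect_error(top_isoform_fractions(tab, "RC", k = 0), "positive")

  # brute-force recomputation on random Dirichlet-like usage
  set.seed(42)
  vals <- list(); genes <- c()
  for (g in 1:20) {
    n <- sample(2:6, 1)
    w <- rgamma(n, 1); w <- 10 * w / sum(w)
    for (i in seq_len(n)) {
      id <- sprintf("g%d.i%d", g, i)
      vals[[id]] <- w[i]
      genes[id] <- sprintf("g%d", g)
    }
  }
  tab2 <- make_table(vals, genes)
  tf2 <- top_isoform_fractions(tab2, "LS", k = 3)
  manual_rank1 <- vapply(unique(genes), function(g) {
    v <- unlist(vals[names(genes)[genes == g]])
    max(v) / sum(v)
  }, 0)
  expect_equal(unname(tf2$mean_by_rank[1]), mean(manual_rank1))
})

test_that("cutoff calibration crosses FP below FN and matches a brute scan", {
  ids_k <- sprintf("k%04d", 1:5000)
  ids_a <- sprintf("a%04d", 1:5000)
  set.seed(7)
  vk <- rlnorm(5000, meanlog = 2, sdlog = 1)
  va <- rexp(5000, rate = 1 / 0.8)
  vals <- c(as.list(vk), as.list(va))
  names(vals) <- c(ids_k, ids_a)
  genes <- setNames(c(ids_k, ids_a), c(ids_k, ids_a))
  tab <- make_table(vals, genes)
  cal <- calibrate_cutoff(tab, ids_k, ids_a)
  # monotone rates
  expect_true(all(diff(cal$fn_rate) >= 0))
  expect_true(all(diff(cal$fp_rate) <= 0))
  expect_true(all(cal$fn_rate >= 0 & cal$fn_rate <= 1))
  # independent exhaustive scan of the same crossing rule
  mx <- apply(tab$fpkm, 1, max)
  grid <- seq(1, 10, by = 0.1)
  chosen <- NA
  for (cut in grid) {
    fn <- mean(mx[ids_k][mx[ids_k] > 0] < cut)
    fp <- mean(mx[ids_a] >= cut)
    if (fp <= fn) { chosen <- round_half_up(cut, 1); break }
  }
  expect_equal(cal$chosen_cutoff, chosen)

  # degenerate decoys: zero FPKM everywhere -> grid minimum
  tab0 <- make_table(list(k1 = 100, a1 = 0), c(k1 = "G1", a1 = "A1"))
  expect_equal(calibrate_cutoff(tab0, "k1", "a1")$chosen_cutoff, 1)
  expect_error(calibrate_cutoff(tab0, character(0), "a1"), "non-empty")
})

test_that("replicate-concordant filtering retains isoforms per group", {
  m <- matrix(0, 2, 40, dimnames = list(c("i1", "i2"), lib_names()))
  m <- set_context(m, "i1", "root", "control", 12, 3.0)
  # i2 passes in one replicate only, at every timepoint
  for (tp in c(12, 24, 48, 96, 144))
    for (cond in c("control", "salt"))
      for (tis in c("root", "leaf"))
        m["i2", sprintf("%s_%s_%dh_r1", tis, cond, tp)] <- 3.0
  tab <- expression_table(m, c(i1 = "G1", i2 = "G2"))
  f <- filter_isoforms(tab, 2.6)
  expect_equal(f$retained$RC, "i1")
  expect_length(f$retained$RS, 0)
  expect_length(f$retained$LC, 0)
  expect_equal(f$overall, "i1")   # discordant replicates never retained

  # monotone in the cutoff: raising it never adds an isoform
  set.seed(5)
  m2 <- matrix(rlnorm(40 * 40, 0.5, 1.5), 40, 40,
               dimnames = list(sprintf("i%02d", 1:40), lib_names()))
  tab2 <- expression_table(m2, setNames(sprintf("g%02d", 1:40),
                                        sprintf("i%02d", 1:40)))
  prev <- filter_isoforms(tab2, 1)$overall
  for (cut in c(2, 4, 8)) {
    cur <- filter_isoforms(tab2, cut)$overall
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("filter flags match simulation ground truth exactly", {
  sim <- simulate_splicing(simulation_config(n_genes = 80, seed = 17,
                                             abund_meanlog = 0.5,
                                             abund_sdlog = 1.5))
  f <- filter_isoforms(sim$table, sim$truth$truth_cutoff)
  tf <- sim$truth$filter_flags
  for (grp in c("RC", "RS", "LC", "LS"))
    expect_equal(tf$isoform_id %in% f$retained[[grp]], tf[[grp]])
})

test_that("percent change reproduces the worked salt-stress increases", {
  expect_equal(percent_change(41443, 40016), 3.57)
  expect_equal(percent_change(40572, 39758), 2.05)
})

test_that("incomplete replicate pairs are rejected", {
  m <- matrix(1, 1, 39, dimnames = list("i1", lib_names()[-40]))
  expect_error(filter_isoforms(expression_table(m, c(i1 = "G1")), 2.6),
               "replicate pair")
})

test_that("expression tables round-trip through TSV", {
  sim <- simulate_splicing(simulation_config(n_genes = 10, seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_expression(sim$table, path)
  tab2 <- read_expression(path)
  expect_equal(tab2$fpkm, sim$table$fpkm)
  expect_equal(tab2$gene, sim$table$gene)
})
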