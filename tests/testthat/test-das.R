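test_that("event abundance averages replicates and sums isoform sets", {
  df <- data.frame(chrom = "chr1", start = c(1, 1, 201), end = c(300, 100, 300),
                   strand = "+", gene_id = "G1",
                   transcript_id = c("t1", "t2", "t2"))
  catl <- build_catalog(gene_models(df))
  m <- matrix(0, 2, 40, dimnames = list(c("t1", "t2"), lib_names()))
  m["t1", "root_control_12h_r1"] <- 4
  m["t1", "root_control_12h_r2"] <- 6
  m["t2", "root_control_12h_r1"] <- 3
  m["t2", "root_control_12h_r2"] <- 3
  tab <- expression_table(m, c(t1 = "G1", t2 = "G1"))
  ab <- event_abundance(catl, tab, "root", "control", 12)
  expect_equal(ab$fpkm_alternative, 5)    # inclusion isoform t1, mean(4, 6)
  expect_equal(ab$fpkm_constitutive, 3)
  expect_equal(ab$fpkm_total, 8)
  expect_error(event_abundance(catl, tab, "root", "control", 13),
               "two replicates")
})

test_that("das_test matches hypergeometric enumeration and handles extremes", {
  bal <- das_test(list(fpkm_constitutive = 50, fpkm_alternative = 50),
                  list(fpkm_constitutive = 50, fpkm_alternative = 50))
  expect_equal(bal$p_value, 1)
  expect_false(bal$significant)

  skewed <- das_test(list(fpkm_constitutive = 90, fpkm_alternative = 10),
                     list(fpkm_constitutive = 50, fpkm_alternative = 50))
  expect_lt(skewed$p_value, 0.05)
  expect_equal(skewed$p_value, oracle_fisher2x2(skewed$table), tolerance = 1e-9)

  extreme <- das_test(list(fpkm_constitutive = 0, fpkm_alternative = 10),
                      list(fpkm_constitutive = 10, fpkm_alternative = 0))
  expect_lt(extreme$p_value, 1e-4)
  expect_equal(extreme$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  zero <- das_test(list(fpkm_constitutive = 0, fpkm_alternative = 0),
                   list(fpkm_constitutive = 0, fpkm_alternative = 0.2))
  expect_true(is.na(zero$p_value))
  expect_match(zero$skipped, "zero")

  # FPKM cells are rounded half-up before testing
  r <- das_test(list(fpkm_constitutive = 1.5, fpkm_alternative = 0.4),
                list(fpkm_constitutive = 0.5, fpkm_alternative = 2.5))
  expect_equal(unname(as.vector(r$table)), c(2, 0, 1, 3))
})

test_that("das_test p-values equal enumeration across random tables", {
  set.seed(3)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(3, 20, 80), 1))
    r <- das_test(list(fpkm_constitutive = cells[1], fpkm_alternative = cells[2]),
                  list(fpkm_constitutive = cells[3], fpkm_alternative = cells[4]))
    if (!is.na(r$p_value))
      expect_equal(r$p_value, oracle_fisher2x2(r$table), tolerance = 1e-7)
  }
})

test_that("change frequency is the condition difference of usage ratios", {
  expect_equal(change_frequency(
    list(fpkm_alternative = 2, fpkm_total = 10),
    list(fpkm_alternative = 5, fpkm_total = 10)), 0.3)
  expect_equal(change_frequency(
    list(fpkm_alternative = 4, fpkm_total = 8),
    list(fpkm_alternative = 5, fpkm_total = 10)), 0)
  expect_true(is.na(change_frequency(
    list(fpkm_alternative = 0, fpkm_total = 0),
    list(fpkm_alternative = 5, fpkm_total = 10))))
})

test_that("injected usage shifts are recovered with the right sign", {
  cf <- simulation_config(n_genes = 400, seed = 19, abund_meanlog = log(100),
                          abund_sdlog = 0.4, das_fraction = 1,
                          das_delta = 0.25, noise_model = "poisson")
  sim <- simulate_splicing(cf)
  catl <- build_catalog(sim$models)
  das <- das_scan(catl, sim$table)
  ev <- evaluate_recovery(sim$truth, catl, das)
  expect_gt(sum(sim$truth$events$das), 150)
  expect_true(abs(ev$das$mean_change_frequency - 0.25) <= 0.03)
  # sign agreement for every detected shifted event
  tkey <- with(sim$truth$events[sim$truth$events$das, ],
               paste(gene_id, type, region_start, region_end))
  ckey <- paste(catl$gene_id, catl$type, catl$region_start, catl$region_end)
  das_ids <- catl$event_id[ckey %in% tkey]
  hit <- das$significant & das$event_id %in% das_ids & das$tissue == "root"
  expect_gt(sum(hit), 100)
  expect_true(all(das$change_frequency[hit] > 0))
})

test_that("rollup counts DAS events and genes per tissue", {
  res <- data.frame(
    event_id = c("e1", "e1", "e2", "e3"),
    gene_id = c("g1", "g1", "g1", "g2"),
    tissue = c("root", "root", "leaf", "root"),
    timepoint_h = c(12, 96, 12, 24),
    p_value = c(0.2, 0.01, 0.5, 0.9),
    significant = c(FALSE, TRUE, FALSE, FALSE),
    change_frequency = 0)
  r <- das_rollup(res)
  expect_equal(r$per_tissue$das_events[r$per_tissue$tissue == "root"], 1)
  expect_equal(r$per_tissue$das_events[r$per_tissue$tissue == "leaf"], 0)
  expect_equal(r$das_genes$root, "g1")
  expect_equal(unname(r$gene_overlap), c(0, 1, 0))

  none <- das_rollup(transform(res, significant = FALSE))
  expect_true(all(none$per_tissue$das_events == 0))
})

test_that("change-frequency / fold-change correlation behaves at the poles", {
  mk <- function(cf_vals) data.frame(
    event_id = "e1", gene_id = "g1", tissue = "root",
    timepoint_h = c(12, 24, 48, 96, 144), p_value = 0.01, significant = TRUE,
    change_frequency = cf_vals)
  fc <- data.frame(gene_id = "g1", tissue = "root",
                   timepoint_h = c(12, 24, 48, 96, 144),
                   log2fc = c(-1, 0, 1, 2, 3))
  perfect <- das_expression_correlation(mk(c(-1, 0, 1, 2, 3)), fc)
  expect_equal(perfect$per_event$r, 1)
  expect_true(perfect$per_event$significant)

  const <- das_expression_correlation(mk(rep(0.2, 5)), fc)
  expect_null(const$per_event)
  expect_match(const$excluded$reason, "constant")

  short <- das_expression_correlation(mk(c(1, 2, NA, NA, NA)), fc)
  expect_match(short$excluded$reason, "fewer than 3")
})

test_that("correlation test is calibrated under an independent null", {
  set.seed(4)
  n <- 1000
  res <- data.frame(
    event_id = rep(sprintf("e%04d", 1:n), each = 5),
    gene_id = rep(sprintf("g%04d", 1:n), each = 5),
    tissue = "root", timepoint_h = rep(c(12, 24, 48, 96, 144), n),
    p_value = 1, significant = FALSE,
    change_frequency = rnorm(5 * n))
  fc <- data.frame(gene_id = rep(sprintf("g%04d", 1:n), each = 5),
                   tissue = "root",
                   timepoint_h = rep(c(12, 24, 48, 96, 144), n),
                   log2fc = rnorm(5 * n))
  out <- das_expression_correlation(res, fc)
  expect_true(abs(out$fraction_significant - 0.05) <= 0.02)
})

test_that("term enrichment ranks a planted term first and stays null-calm", {
  bg <- sprintf("g%03d", 1:100)
  g2t <- data.frame(gene_id = bg, term = rep(sprintf("T%d", 1:10), each = 10))
  # foreground exactly the genes of one term
  r <- term_enrichment(bg[11:20], bg, g2t)
  expect_equal(r$term[1], "T2")
  expect_true(r$enriched[1])
  # a term covering every background gene is uninformative
  g2t_all <- rbind(g2t, data.frame(gene_id = bg, term = "ALL"))
  r2 <- term_enrichment(bg[11:20], bg, g2t_all)
  expect_equal(r2$p_value[r2$term == "ALL"], 1)
  expect_error(term_enrichment(character(0), bg, g2t), "empty foreground")
  expect_error(term_enrichment("zz", bg, g2t), "subset")
})
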