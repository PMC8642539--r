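# Species assignment, QC filtering, module scoring, phases, proportions,
# volcano classification.

test_that("the five-cell QC table keeps exactly the two boundary-legal cells", {
  met <- data.frame(
    barcode = paste0("c", 1:5),
    n_genes_detected = c(150, 200, 3000, 6000, 6500),
    pct_mito = c(1, 5, 12, 9, 2))
  kept <- qc_filter(met)
  expect_equal(kept, c("c2", "c4"))
  expect_length(kept, 2)
})

test_that("QC boundary semantics retain cells exactly at the limits", {
  met <- data.frame(barcode = paste0("c", 1:3),
                    n_genes_detected = c(200, 6000, 200),
                    pct_mito = c(10, 10, 10))
  expect_equal(qc_filter(met), met$barcode)
  empty <- met[0, ]
  expect_length(qc_filter(empty), 0)
})

test_that("QC filtering is order-invariant and idempotent", {
  set.seed(4)
  met <- data.frame(barcode = paste0("c", 1:100),
                    n_genes_detected = sample(c(50, 300, 7000), 100, TRUE),
                    pct_mito = runif(100, 0, 20))
  k1 <- qc_filter(met)
  k2 <- qc_filter(met[sample(nrow(met)), ])
  expect_setequal(k1, k2)
  expect_setequal(qc_filter(met[met$barcode %in% k1, ]), k1)
})

test_that("species assignment follows the threshold rule", {
  counts <- Matrix::Matrix(matrix(c(98, 2, 55, 45), 2, 2), sparse = TRUE)
  rownames(counts) <- c("HUM1", "mm-1"); colnames(counts) <- c("b1", "b2")
  x <- structure(list(
    counts = counts,
    features = data.frame(gene = c("HUM1", "mm-1"),
                          species = c("human", "mouse"),
                          mito = FALSE, program = "background"),
    barcodes = data.frame(barcode = c("b1", "b2"), arm = NA,
                          true_species = NA, true_phase = NA,
                          true_cluster = NA)),
    class = "sc_counts")
  ann <- species_assign(x)
  expect_equal(ann$species, c("human", "ambiguous"))
  x$features$species <- NA
  expect_error(species_assign(x), "species tags")
})

test_that("barnyard species recovery is near-perfect at 5% ambient", {
  d <- sc_design(n_cells = 600, n_genes = 500, ambient_rate = 0.05, seed = 9)
  b <- generate_barnyard(d)
  ann <- species_assign(b)
  expect_gte(mean(ann$species == ann$true_species), 0.99)
})

test_that("module scores are invariant to constant shifts and need programs", {
  set.seed(8)
  norm <- Matrix::Matrix(matrix(rpois(50 * 30, 3), 50, 30), sparse = TRUE)
  rownames(norm) <- paste0("g", 1:50)
  s1 <- module_score(norm, c("g1", "g2", "g3"), seed = 2)
  s2 <- module_score(norm + 5, c("g1", "g2", "g3"), seed = 2)
  expect_equal(s1, s2, tolerance = 1e-10)
  expect_error(module_score(norm, c("zz1", "zz2")), "no program genes")
  expect_warning(module_score(norm, c("g1", "zz")), "absent")
})

test_that("null programs score near zero; planted programs separate", {
  # fold effect 1: program indistinguishable from background
  d0 <- sc_design(n_cells = 600, n_genes = 800, fold_effect = 1, seed = 31)
  coh0 <- generate_cycle_cohort(d0)
  norm0 <- normalize_log1p(coh0)
  s0 <- module_score(norm0, cell_cycle_genes()$S, seed = 3,
                     exclude = unlist(cell_cycle_genes()))
  se <- sd(s0) / sqrt(length(s0))
  expect_lt(abs(mean(s0)), 4 * se + 1e-3)
  # AUC of the S score for true-S vs other cells is ~ 0.5
  is_s <- coh0$barcodes$true_phase == "S"
  auc <- (mean(rank(s0)[is_s]) - (sum(is_s) + 1) / 2) / sum(!is_s)
  expect_lt(abs(auc - 0.5), 0.05)

  # fold effect 4: true S cells clearly outscore true G1 cells
  d4 <- sc_design(n_cells = 500, n_genes = 800, fold_effect = 4, seed = 37)
  coh4 <- generate_cycle_cohort(d4)
  ann <- score_cell_cycle(coh4, seed = 3)
  tt <- t.test(ann$s_score[ann$true_phase == "S"],
               ann$s_score[ann$true_phase == "G1"], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("phase binning follows the score rules", {
  expect_equal(assign_phase(0.3, -0.1), "S")
  expect_equal(assign_phase(-0.2, -0.3), "G1")
  expect_equal(assign_phase(0.1, 0.4), "G2M")
  expect_equal(assign_phase(0, 0), "G1")       # both non-positive
  expect_equal(assign_phase(0.2, 0.2), "S")    # positive tie breaks to S
  expect_equal(assign_phase(c(0.3, -0.2, 0.1), c(-0.1, -0.3, 0.4)),
               c("S", "G1", "G2M"))
})

test_that("phase recovery at fold-effect 4 exceeds 90%", {
  d <- sc_design(n_cells = 700, n_genes = 1000, fold_effect = 4, seed = 41)
  coh <- generate_cycle_cohort(d)
  ann <- score_cell_cycle(subset_cells(coh, qc_filter(coh)), seed = 1)
  expect_gte(mean(ann$phase == ann$true_phase), 0.9)
})

test_that("at fold-effect 1 assignments are independent of planted phase", {
  # chi-square independence between truth and assignment should look null
  ok <- 0L
  for (r in 1:25) {
    d <- sc_design(n_cells = 250, n_genes = 500, fold_effect = 1,
                   seed = 100 + r)
    coh <- generate_cycle_cohort(d)
    ann <- score_cell_cycle(coh, seed = r)
    p <- suppressWarnings(
      chisq.test(table(ann$true_phase, ann$phase))$p.value)
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 0.8 * 25)
})

test_that("proportion shifts compute percentage-point deltas", {
  ann <- data.frame(
    arm = rep(c("a1", "a2"), c(10, 10)),
    phase = c(rep(c("G1", "S", "G2M"), c(5, 3, 2)),
              rep(c("G1", "S", "G2M"), c(7, 2, 1))))
  ps <- proportion_shift(ann, "phase", arms = c("a1", "a2"))
  expect_equal(ps$delta_pct[ps$category == "G1"], 20)
  expect_equal(ps$delta_pct[ps$category == "S"], -10)
  expect_equal(ps$delta_pct[ps$category == "G2M"], -10)
  expect_equal(sum(ps$pct_arm1), 100)
  expect_equal(sum(ps$pct_arm2), 100)

  same <- data.frame(arm = rep(c("a1", "a2"), each = 6),
                     phase = rep(c("G1", "S", "G2M"), 4))
  expect_true(all(proportion_shift(same, "phase")$delta_pct == 0))

  expect_error(proportion_shift(ann, "phase", arms = c("a1", "zz")),
               "arm|two arms")
})

test_that("the proportion estimator is unbiased over multinomial replicates", {
  set.seed(55)
  p1 <- c(G1 = 0.55, S = 0.25, G2M = 0.20)
  p2 <- c(G1 = 0.70, S = 0.17, G2M = 0.13)
  deltas <- replicate(200, {
    ann <- data.frame(
      arm = rep(c("a1", "a2"), each = 400),
      phase = c(sample(names(p1), 400, TRUE, p1),
                sample(names(p2), 400, TRUE, p2)))
    ps <- proportion_shift(ann, "phase", arms = c("a1", "a2"))
    ps$delta_pct[ps$category == "G1"]
  })
  expect_lt(abs(mean(deltas) - 15), 0.5)
})

test_that("pass-filter cell counts aggregate to the printed total", {
  ann <- data.frame(arm = rep(c("DMSO", "UM-002"), c(14878, 13996)))
  tab <- tabulate_arms(ann)
  expect_equal(tab$n_cells[tab$arm == "DMSO"], 14878)
  expect_equal(tab$n_cells[tab$arm == "UM-002"], 13996)
  expect_equal(attr(tab, "total"), 28874)
  expect_equal(attr(tab, "total"),
               sum(tab$n_cells[tab$arm != "total"]))
})

test_that("volcano classification applies strict thresholds and partitions", {
  rec <- data.frame(
    gene = paste0("g", 1:6),
    log2fc = c(0.5, 0.23, -0.4, -0.4, 0.3, 0),
    p_bonferroni = c(1e-12, 1e-12, 1e-3, 1e-12, 1e-8, 1e-20))
  v <- volcano_classify(rec)
  expect_equal(as.character(v$category),
               c("up", "ns", "ns", "down", "ns", "ns"))
  expect_equal(sum(table(v$category)), nrow(rec))

  # Bonferroni helper uses the full feature count and caps at 1
  expect_equal(bonferroni_correct(c(1e-6, 0.5), m = 1000),
               c(1e-3, 1))
})

test_that("planted marker genes surface as volcano hits", {
  d <- sc_design(n_cells = 300, n_genes = 600, marker_fold = 3, seed = 61,
                 phase_proportions = list(
                   arm1 = c(G1 = 0.6, S = 0.2, G2M = 0.2),
                   arm2 = c(G1 = 0.6, S = 0.2, G2M = 0.2)))
  coh <- generate_cycle_cohort(d, arms = c("a1", "a2"))
  # make arm 2 over-express cluster-1 markers by planting cluster labels
  m1 <- coh$features$gene[coh$features$program == "marker" &
                            coh$features$cluster == 1]
  de <- rank_sum_de(coh, arms = c("a1", "a2"), genes = m1[1:5])
  v <- volcano_classify(de)
  # identical arms: nothing should pass the thresholds
  expect_true(all(v$category == "ns"))
})
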