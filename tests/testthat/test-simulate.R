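small_config <- function(...) {
  simulation_config(
    category_counts = c(not_detected = 20, tissue_enriched = 15,
                        group_enriched = 15, tissue_enhanced = 15,
                        expressed_in_all = 20, mixed = 15),
    ...
  )
}

test_that("simulation is deterministic given a seed and books its truth", {
  s1 <- simulate_dataset(small_config(), seed = 5)
  s2 <- simulate_dataset(small_config(), seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_dataset(small_config(), seed = 6)
  expect_false(identical(s1$fpkm, s3$fpkm))

  counts <- table(s1$truth$category)
  expect_identical(as.integer(counts["not_detected"]), 20L)
  expect_identical(as.integer(counts["tissue_enriched"]), 15L)
  expect_identical(sum(counts), 100L)
  # written outputs are byte-identical across runs too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "matrix.tsv")),
                   readLines(file.path(d2, "matrix.tsv")))
})

test_that("noiseless planted panels are recovered perfectly end to end", {
  sim <- simulate_dataset(small_config(noise_cv = 0, leakage_rate = 0), seed = 9)
  prof <- average_replicates(sim$fpkm, sim$annotation)
  cl <- classify_tissue_specificity(prof, "pancreas")
  rr <- recovery_report(sim$truth, cl)
  expect_equal(rr$accuracy, 1)
  # planted groups are recovered as the exact tissue sets
  tg <- sim$truth[sim$truth$category == "group_enriched", ]
  pg <- cl$group[match(tg$gene, cl$gene)]
  expect_identical(
    lapply(strsplit(pg, ";"), sort),
    lapply(strsplit(tg$group, ";"), sort)
  )
})

test_that("planted rows satisfy their defining inequality with the margin", {
  sim <- simulate_dataset(small_config(noise_cv = 0, leakage_rate = 0), seed = 13)
  prof <- sim$profile_clean
  m <- as.matrix(prof[, -1]); rownames(m) <- prof$gene
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    v <- m[truth$gene[i], ]
    tv <- v[["pancreas"]]
    cat_i <- as.character(truth$category[i])
    if (cat_i == "tissue_enriched") {
      expect_gte(tv, 8 * max(v[names(v) != "pancreas"]))
    } else if (cat_i == "group_enriched") {
      members <- strsplit(truth$group[i], ";")[[1]]
      expect_gte(min(v[members]), 8 * max(v[setdiff(names(v), members)]))
    } else if (cat_i == "tissue_enhanced") {
      expect_gte(tv, 8 * mean(v))
    } else if (cat_i == "not_detected") {
      expect_lt(tv, 1)
    } else if (cat_i == "expressed_in_all") {
      expect_true(all(v >= 1))
    }
  }
})

test_that("barcode leakage mixes exactly the specified shares", {
  fpkm <- tibble::tibble(gene = "g", s1 = 1000, s2 = 0)
  ann <- annotation_tbl(c("s1", "s2"), c("a", "b"), lane = c("L1", "L1"))
  out <- apply_barcode_leakage(fpkm, ann, 0.001)
  expect_equal(out$s1, 999)
  expect_equal(out$s2, 1)

  expect_identical(apply_barcode_leakage(fpkm, ann, 0), fpkm)
  expect_error(apply_barcode_leakage(fpkm, ann, 1.2), "rate")
  ann_nolane <- annotation_tbl(c("s1", "s2"), c("a", "b"))
  expect_error(apply_barcode_leakage(fpkm, ann_nolane, 0.001), "lane")
})

test_that("leakage conserves per-gene lane totals and is linear", {
  set.seed(61)
  smp <- sprintf("s%d", 1:9)
  lanes <- rep(c("L1", "L2", "L3"), times = c(4, 4, 1))
  m <- matrix(stats::rlnorm(25 * 9, 1, 2), 25, 9, dimnames = list(NULL, smp))
  x <- fpkm_tbl(m)
  ann <- annotation_tbl(smp, paste0("t", 1:9), lane = lanes)
  out <- apply_barcode_leakage(x, ann, 0.01)
  mo <- as.matrix(out[, -1])
  for (ln in unique(lanes)) {
    cols <- which(lanes == ln)
    expect_equal(rowSums(mo[, cols, drop = FALSE]),
                 rowSums(m[, cols, drop = FALSE]), tolerance = 1e-9)
  }
  # single-sample lane untouched
  expect_identical(mo[, 9], m[, 9])
  # linearity: leakage of a sum = sum of leakages
  y <- fpkm_tbl(2 * m)
  out2 <- apply_barcode_leakage(y, ann, 0.01)
  expect_equal(as.matrix(out2[, -1]), 2 * mo, tolerance = 1e-12)
})

test_that("recovery report books the confusion matrix and accuracies", {
  truth <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    category = factor(c("mixed", "mixed", "tissue_enriched", "not_detected"),
                      levels = spec_categories())
  )
  pred_exact <- truth
  rr <- recovery_report(truth, pred_exact)
  expect_equal(rr$accuracy, 1)
  expect_equal(sum(diag(rr$confusion)), 4)

  pred_allmixed <- truth
  pred_allmixed$category <- factor("mixed", levels = spec_categories())
  rr2 <- recovery_report(truth, pred_allmixed)
  expect_equal(rr2$accuracy, 0.5)  # the planted mixed fraction

  expect_error(recovery_report(truth, pred_exact[1:2, ]), "different gene sets")
})

test_that("modest noise and leakage keep planted enriched genes elevated", {
  sim <- simulate_dataset(small_config(noise_cv = 0.05, leakage_rate = 0.001),
                          seed = 17)
  prof <- average_replicates(sim$fpkm, sim$annotation)
  cl <- classify_tissue_specificity(prof, "pancreas")
  enr <- sim$truth$gene[sim$truth$category == "tissue_enriched"]
  pred <- as.character(cl$category[match(enr, cl$gene)])
  expect_gte(mean(pred %in% elevated_categories()), 0.99)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(category_counts = c(mixed = 0)), "sum > 0")
  expect_error(simulation_config(n_tissues = 2), "3 tissues")
  expect_error(simulation_config(margin = 4), "margin > fold")
  expect_error(simulation_config(leakage_rate = 1), "leakage_rate < 1")
})
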