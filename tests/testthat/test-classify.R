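test_that("the tissue-specific score follows the ratio conventions", {
  expect_equal(specificity_score(c(p = 10, a = 2, b = 1), "p"), 5)
  expect_identical(specificity_score(c(p = 3, a = 0, b = 0), "p"), Inf)
  expect_identical(specificity_score(c(p = 0, a = 2), "p"), 0)
  expect_true(is.na(specificity_score(c(p = 0, a = 0), "p")))
  expect_error(specificity_score(c(a = 1, b = 2), "p"), "absent")
})

test_that("group search finds obvious groups and rejects non-qualifying rows", {
  row <- c(p = 8, q = 7, setNames(stats::runif(25, 0, 1), sprintf("t%02d", 1:25)))
  expect_setequal(find_enriched_group(row, "p"), c("p", "q"))

  # second tissue at 3: {8,3} fails (3 < 5 * 1); exhaustive enumeration agrees
  row2 <- c(p = 8, q = 3, setNames(rep(1, 25), sprintf("t%02d", 1:25)))
  expect_null(find_enriched_group(row2, "p"))
  expect_false(exhaustive_group_search(row2, "p")$found)
})

test_that("sorted-prefix group search is equivalent to exhaustive enumeration", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:100) {
    row <- random_row(10)
    got <- find_enriched_group(row, "t01")
    oracle <- exhaustive_group_search(row, "t01")
    expect_identical(!is.null(got), oracle$found)
    if (oracle$found) {
      expect_identical(length(got), oracle$min_size)
      expect_true(group_qualifies(row, got))
      expect_true("t01" %in% got)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 5)  # the draw must actually exercise positive cases
})

test_that("single-gene classification applies the rules in precedence order", {
  cl <- classify_gene(c(p = 10, a = 2, b = 1, c = 0.4), "p")
  expect_identical(as.character(cl$category), "tissue_enriched")
  expect_equal(cl$score, 5)

  cl <- classify_gene(c(p = 0.5, a = 0, b = 0), "p")
  expect_identical(as.character(cl$category), "not_detected")

  # 27 tissues: 10 vs one 4 and twenty-five 1s -> enhanced
  row <- c(p = 10, q = 4, setNames(rep(1, 25), sprintf("t%02d", 1:25)))
  expect_equal(mean(row), 39 / 27)        # independent arithmetic
  expect_true(10 >= 5 * mean(row))        # enhanced rule
  expect_false(10 >= 5 * 4)               # not enriched
  expect_false(exhaustive_group_search(row, "p")$found)  # no group
  cl <- classify_gene(row, "p")
  expect_identical(as.character(cl$category), "tissue_enhanced")

  row_all <- setNames(rep(2, 27), c("p", sprintf("t%02d", 1:26)))
  cl <- classify_gene(row_all, "p")
  expect_identical(as.character(cl$category), "expressed_in_all")
  expect_identical(cl$n_detected, 27L)
})

test_that("classification of a profile partitions genes and counts them", {
  prof <- tibble::tibble(
    gene = c("enr", "nd", "enh", "all"),
    p = c(10, 0.5, 10, 2),
    q = c(2, 0, 4, 2),
    r = c(1, 0, 1, 2),
    s = c(0.4, 0, 1, 2)
  )
  # 4 tissues: row "enh" has mean (10+4+1+1)/4 = 4 so 10 < 5*4 is not
  # enhanced, and with all four values detected it lands in expressed_in_all
  cl <- classify_tissue_specificity(prof, "p")
  cen <- category_census(cl)
  expect_identical(sum(cen$n_genes), nrow(prof))
  expect_identical(
    as.character(cl$category),
    c("tissue_enriched", "not_detected", "expressed_in_all", "expressed_in_all")
  )
  expect_setequal(elevated_genes(cl), "enr")
  g <- glance(cl)
  expect_identical(g$elevated, 1L)
  expect_identical(g$n_genes, 4L)
})

test_that("every gene gets exactly one category on random panels", {
  set.seed(202)
  for (rep in 1:5) {
    m <- matrix(stats::rlnorm(60 * 8, 1, 2), 60, 8,
                dimnames = list(NULL, sprintf("t%d", 1:8)))
    m[stats::runif(length(m)) < 0.25] <- 0
    prof <- fpkm_tbl(m)
    cl <- classify_tissue_specificity(prof, "t1")
    expect_false(any(is.na(cl$category)))
    expect_identical(sum(category_census(cl)$n_genes), 60L)
    # group column populated iff group_enriched
    expect_identical(!is.na(cl$group), as.character(cl$category) == "group_enriched")
  }
})

test_that("raising target expression never demotes an elevated gene", {
  set.seed(303)
  for (rep in 1:40) {
    row <- random_row(12, target = "t01")
    cl1 <- classify_gene(row, "t01")
    row2 <- row
    row2["t01"] <- row2["t01"] * stats::runif(1, 1, 10)
    cl2 <- classify_gene(row2, "t01")
    if (as.character(cl1$category) %in% elevated_categories()) {
      expect_true(as.character(cl2$category) %in% elevated_categories())
    }
  }
})

test_that("category assignments are invariant under global rescaling", {
  set.seed(404)
  for (rep in 1:20) {
    row <- random_row(10, target = "t01")
    # keep detection calls unchanged: scale up only, and only rows whose
    # nonzero values already sit above the cutoff
    row[row > 0 & row < 1] <- 0
    row["t01"] <- max(row["t01"], 1)
    s <- stats::runif(1, 1, 50)
    c1 <- classify_gene(row, "t01")
    c2 <- classify_gene(row * s, "t01")
    expect_identical(as.character(c1$category), as.character(c2$category))
    expect_equal(c1$score, c2$score)
  }
})

test_that("score >= fold coincides with the tissue_enriched rule when detected", {
  set.seed(505)
  for (rep in 1:50) {
    row <- random_row(9, target = "t01")
    cl <- classify_gene(row, "t01")
    detected <- row[["t01"]] >= 1
    if (detected) {
      expect_identical(cl$score >= 5, as.character(cl$category) == "tissue_enriched")
    }
  }
})

test_that("classification table survives the TSV writer conventions", {
  prof <- tibble::tibble(gene = c("a", "b"), p = c(3, 0), q = c(0, 0), r = c(0, 0))
  cl <- classify_tissue_specificity(prof, "p")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cl, f)
  txt <- readr::read_tsv(f, na = character(),
                         col_types = readr::cols(.default = readr::col_character()))
  expect_identical(txt$score[1], "inf")   # infinite sentinel
  expect_identical(txt$score[2], "NA")    # undefined (all-zero elsewhere row)
})
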