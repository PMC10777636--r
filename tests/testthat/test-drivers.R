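test_that("random-forest importance singles out the true predictor", {
  set.seed(20)
  n <- 24
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c("x1", paste0("noise", 1:20))))
  y <- X[, "x1"]
  imp <- rf_importance(X, y, n_trees = 500, n_permutations = 0, seed = 1)
  expect_identical(imp$otu_id[which.max(imp$importance)], "x1")
  # an exact duplicate splits credit but the pair stays on top
  X2 <- cbind(X, x1b = X[, "x1"])
  imp2 <- rf_importance(X2, y, n_trees = 500, n_permutations = 0, seed = 1)
  top <- imp2$otu_id[order(-imp2$importance)][1:2]
  expect_true("x1" %in% top || "x1b" %in% top)
  expect_error(rf_importance(X, rep(1, n)), "constant")
})

test_that("permutation p-values are calibrated and bounded", {
  set.seed(21)
  X <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(NULL, paste0("t", 1:10)))
  y <- X[, 1] + rnorm(12, sd = 0.1)
  imp <- rf_importance(X, y, n_trees = 200, n_permutations = 30, seed = 2)
  expect_true(all(imp$p.value > 0 & imp$p.value <= 1))
  expect_lt(imp$p.value[1], 0.1)  # the real driver is detected
})

test_that("core-vs-other importance contrast uses exact small-sample tests", {
  imp <- structure(
    data.frame(otu_id = paste0("t", 1:10),
               importance = c(10, 9, 8, 7, 6, 1, 2, 3, 4, 5),
               is_core = rep(c(TRUE, FALSE), each = 5)),
    class = c("importance_result", "data.frame"))
  ct <- compare_core_importance(imp)
  expect_equal(ct$p.value, 2 / 252)
  expect_equal(ct$direction, 1)
  imp$importance <- rep(4, 10)
  expect_equal(compare_core_importance(imp)$p.value, 1)
  imp$is_core <- rep(TRUE, 10)
  expect_error(compare_core_importance(imp), "nonempty")
})

test_that("cluster-EMF regressions match closed-form least squares", {
  ab <- rbind(cluster1 = c(0.1, 0.2, 0.3, 0.4, 0.5),
              cluster2 = rep(0.2, 5))
  colnames(ab) <- paste0("s", 1:5)
  emf <- setNames(2 * ab["cluster1", ] + 1, colnames(ab))
  reg <- suppressWarnings(ols_cluster_emf(ab, emf))
  expect_equal(reg$slope[1], 2)
  expect_equal(reg$r_squared[1], 1)
  expect_true(is.na(reg$slope[2]))  # zero-variance abundance

  set.seed(30)
  ab2 <- rbind(cluster1 = rnorm(12))
  colnames(ab2) <- paste0("s", 1:12)
  y <- setNames(rnorm(12), colnames(ab2))
  reg2 <- ols_cluster_emf(ab2, y)
  expect_equal(reg2$r_squared, cor(ab2[1, ], y)^2, tolerance = 1e-12)
  expect_equal(reg2$p.value,
               summary(lm(y ~ ab2[1, ]))$coefficients[2, 4])
})

test_that("trophic ratios follow the configured phylum map", {
  labels <- setNames(c(1L, 1L, 1L, 1L, 2L), paste0("t", 1:5))
  tax <- data.frame(otu_id = paste0("t", 1:5),
                    kingdom = "Bacteria",
                    phylum = c("Proteobacteria", "Actinobacteria",
                               "Firmicutes", "Acidobacteria", "Chloroflexi"))
  tr <- trophic_ratio(labels, tax)
  c1 <- tr[tr$cluster == "cluster1", ]
  expect_equal(c1$ratio, 3)
  expect_equal(c1$pct_copiotroph, 75)
  c2 <- tr[tr$cluster == "cluster2", ]
  expect_true(c2$ratio_infinite == FALSE && c2$copiotroph == 0)
  # oligotroph-free cluster flags an infinite ratio
  tax2 <- tax; tax2$phylum <- "Proteobacteria"
  tr2 <- trophic_ratio(labels, tax2)
  expect_true(all(tr2$ratio_infinite))
  expect_equal(tr2$pct_copiotroph, c(100, 100))
  # unclassified-only input is an error
  tax3 <- tax; tax3$phylum <- "Gemmatimonadetes"
  expect_error(trophic_ratio(labels, tax3), "no classified members")
})

test_that("zone-wise cluster comparisons report exact pairwise floors", {
  meta <- make_meta(12)
  ab <- rbind(cluster1 = c(1, 2, 3, 4, 11, 12, 13, 14, 5, 6, 7, 8))
  colnames(ab) <- meta$sample_id  # RZ strictly above AL and TZ
  rep <- compare_cluster_abundance_by_zone(ab, meta)
  pw <- rep$cluster1$pairwise
  expect_equal(pw$p.value[pw$group_a == "AL" & pw$group_b == "RZ"], 2 / 70)
  expect_lt(rep$cluster1$kruskal$p.value, 0.05)
})
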