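test_that("taxon profiles slice, transform, and exclude constants", {
  x <- make_counts(20, 10, seed = 2, sparsity = 0)
  ids <- otu_ids(x)[c(3, 7, 11)]
  p <- taxon_profiles(x, ids)
  rel <- sweep(x$values, 2, colSums(x$values), "/")
  expect_equal(p, rel[ids, ])
  plog <- taxon_profiles(x, ids, transform = "log")
  pc <- min(rel[ids, ][rel[ids, ] > 0]) / 2
  expect_equal(plog, log(rel[ids, ] + pc))

  # constant (zero-variance) profiles are excluded with a warning
  m <- rel
  m[ids[1], ] <- mean(m[ids[1], ])
  x2 <- list(values = m, kind = "relative")
  class(x2) <- "otu_table"
  expect_warning(p2 <- taxon_profiles(x2, ids), "zero-variance")
  expect_identical(rownames(p2), ids[2:3])
  expect_error(taxon_profiles(x, c("nope")), "absent")
})

test_that("soft-thresholded adjacency follows the stated formulas", {
  set.seed(4)
  p <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(paste0("t", 1:8), NULL))
  cc <- cor(t(p))
  A_u <- adjacency_matrix(p, beta = 6)
  expect_equal(A_u[2, 5], abs(cc[2, 5])^6)
  expect_equal(unname(diag(A_u)), rep(1, 8))
  A_s <- adjacency_matrix(p, beta = 2, type = "signed")
  expect_equal(A_s[3, 7], ((1 + cc[3, 7]) / 2)^2)
  # identical profiles connect at 1 for any power
  p2 <- rbind(a = p[1, ], b = p[1, ], c = p[2, ])
  expect_equal(adjacency_matrix(p2, 11)["a", "b"], 1)
  # unsigned is invariant to a sign flip, signed is not
  p3 <- p; p3[4, ] <- -p3[4, ]
  expect_equal(adjacency_matrix(p3, 6), adjacency_matrix(p, 6))
  expect_false(isTRUE(all.equal(adjacency_matrix(p3, 2, type = "signed"),
                                adjacency_matrix(p2 <- p, 2, type = "signed"))))
  expect_equal(connectivity(A_u), rowSums(A_u) - 1)
})

test_that("TOM matches hand values and a triple-loop oracle", {
  # empty graph
  A0 <- diag(4); dimnames(A0) <- list(letters[1:4], letters[1:4])
  t0 <- tom_similarity(A0)
  expect_equal(unname(t0), diag(4))
  # one full edge in an otherwise empty graph: TOM = 1
  A1 <- A0; A1["a", "b"] <- A1["b", "a"] <- 1
  expect_equal(tom_similarity(A1)["a", "b"], 1)

  tom_loop <- function(A) {
    n <- nrow(A); out <- diag(n)
    k <- rowSums(A) - diag(A)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      L <- sum(sapply(setdiff(seq_len(n), c(i, j)),
                      function(u) A[i, u] * A[u, j]))
      out[i, j] <- (L + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    out
  }
  set.seed(10)
  M <- matrix(runif(64), 8, 8); M <- (M + t(M)) / 2; diag(M) <- 1
  dimnames(M) <- list(paste0("t", 1:8), paste0("t", 1:8))
  expect_equal(unname(tom_similarity(M)), tom_loop(M), tolerance = 1e-12)
  expect_true(all(tom_similarity(M) >= 0 & tom_similarity(M) <= 1))
  expect_error(tom_similarity(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("scale-free fit is exact on a planted power law", {
  k <- rep(1:10, times = round(1e4 / (1:10)^2))
  sf <- suppressWarnings(scale_free_fit(k))
  expect_gte(sf$r2, 0.999)
  expect_equal(sf$slope, -2, tolerance = 0.01)
  # increasing degree distributions get a negative signed index
  k_up <- rep(1:10, times = round(10 * (1:10)^2))
  expect_lt(suppressWarnings(scale_free_fit(k_up))$r2, 0)
})

test_that("soft-threshold selection hits targets or warns on noise", {
  # two perfectly separated blocks produce high fit at low power
  set.seed(1)
  f1 <- rnorm(12); f2 <- rnorm(12)
  p <- rbind(t(replicate(15, f1 + rnorm(12, sd = 0.1))),
             t(replicate(15, f2 + rnorm(12, sd = 0.1))))
  rownames(p) <- paste0("t", 1:30)
  ps <- suppressWarnings(pick_soft_threshold(p))
  expect_true(ps$beta %in% 1:9)  # sample-size cap for n = 12
  # independent noise: warning path, no power reaches 0.9
  set.seed(2)
  noise <- matrix(rnorm(100 * 12), 100, 12,
                  dimnames = list(paste0("n", 1:100), paste0("s", 1:12)))
  expect_warning(res <- pick_soft_threshold(noise), "no candidate power")
  expect_false(res$reached_target)
  expect_true(all(res$report$r2 < 0.9))
})

test_that("module detection recovers planted blocks and ignores order", {
  set.seed(3)
  f1 <- rnorm(12); f2 <- rnorm(12)
  p <- rbind(t(replicate(25, f1 + rnorm(12, sd = 0.05))),
             t(replicate(25, f2 + rnorm(12, sd = 0.05))),
             matrix(rnorm(5 * 12), 5, 12))
  rownames(p) <- paste0("t", sprintf("%02d", 1:55))
  A <- adjacency_matrix(p, 6)
  tom <- tom_similarity(A)
  lab <- cluster_modules(tom, min_cluster_size = 20)
  expect_equal(max(lab), 2)
  expect_true(all(lab[1:25] == lab[1]))
  expect_true(all(lab[26:50] == lab[26]))
  expect_true(lab[1] != lab[26])
  # label assignment is invariant to taxon input order
  perm <- sample(55)
  lab2 <- cluster_modules(tom[perm, perm], min_cluster_size = 20)
  expect_identical(lab2[names(lab)], lab)
})

test_that("eigengenes summarize modules like a rank-1 factorization", {
  set.seed(7)
  base <- rnorm(10)
  p <- rbind(a = 2 * base + 1, b = -3 * base + 2, c = 0.5 * base - 1)
  colnames(p) <- paste0("s", 1:10)
  labels <- c(a = 1L, b = 1L, c = 1L)
  E <- module_eigengenes(p, labels)
  # members are exact multiples of one factor: |cor| = 1 each
  kme <- module_membership(p, E)
  expect_equal(abs(unname(kme[, 1])), rep(1, 3), tolerance = 1e-10)
  # orientation: mean kME of own members >= 0
  expect_gte(mean(kme[, 1]), 0)
  # agrees with an independent factorization (first eigenvector of X'X)
  X <- t(scale(t(p)))
  ev <- eigen(crossprod(X))$vectors[, 1]
  expect_equal(abs(as.numeric(E[, 1])), abs(ev), tolerance = 1e-8)
  # the eigengene explains at least as much member variance as random vectors
  expl <- function(v) sum((X %*% v)^2) / sum(X^2)
  e_expl <- expl(E[, 1])
  for (i in 1:20) {
    v <- rnorm(10); v <- v / sqrt(sum(v^2))
    expect_lte(expl(v), e_expl + 1e-10)
  }
  # singleton cluster: eigengene is the standardized profile
  E1 <- module_eigengenes(p, c(a = 1L, b = 0L, c = 0L))
  expect_equal(abs(cor(E1[, 1], p["a", ])), 1)
})

test_that("hub calls use a strict kME threshold", {
  kme <- matrix(c(0.95, 0.9, 0.2), 3, 1,
                dimnames = list(c("a", "b", "c"), "ME1"))
  labels <- c(a = 1L, b = 1L, c = 1L)
  expect_identical(hub_taxa(kme, labels, threshold = 0.9)$cluster1, "a")
  # membership in another cluster never makes a hub there
  labels2 <- c(a = 1L, b = 2L, c = 2L)
  kme2 <- cbind(kme, ME2 = c(0.99, 0.95, 0.1))
  hubs <- hub_taxa(kme2, labels2)
  expect_identical(hubs$cluster1, "a")
  expect_identical(hubs$cluster2, "b")
})

test_that("cluster abundance averages member z-scores", {
  x <- make_counts(12, 8, seed = 15, sparsity = 0)
  labels <- setNames(rep(c(1L, 2L, 0L), c(5, 4, 3)), otu_ids(x))
  ca <- cluster_abundance(x, labels)
  expect_equal(rownames(ca), c("cluster1", "cluster2"))
  expect_equal(unname(rowMeans(ca)), c(0, 0), tolerance = 1e-12)
  rel <- sweep(x$values, 2, colSums(x$values), "/")
  z <- t(scale(t(rel[1:5, ])))
  expect_equal(unname(ca["cluster1", ]), unname(colMeans(z)))
  # a single-member cluster is that member's z-score
  ca1 <- cluster_abundance(x, setNames(rep(c(1L, 0L), c(1, 11)), otu_ids(x)))
  expect_equal(unname(ca1[1, ]), unname(t(scale(t(rel[1, , drop = FALSE])))[1, ]))
})
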