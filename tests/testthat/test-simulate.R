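test_that("identical config and seed reproduce tables bitwise", {
  a <- synth_community(synth_config(seed = 11))
  b <- synth_community(synth_config(seed = 11))
  expect_identical(a$otu$values, b$otu$values)
  expect_identical(a$fx$values, b$fx$values)
  expect_identical(a$taxonomy, b$taxonomy)
  expect_identical(a$truth$latent_factors, b$truth$latent_factors)
  c <- synth_community(synth_config(seed = 12))
  expect_false(identical(a$otu$values, c$otu$values))
})

test_that("generated design matches the zoned layout", {
  d <- synth_community(synth_config(seed = 1))
  expect_equal(table(d$meta$zone), table(c(rep("AL", 4), rep("RZ", 4), rep("TZ", 4))))
  expect_identical(d$meta$sample_id, sort(d$meta$sample_id))
  expect_equal(dim(d$otu$values), c(400, 12))
  expect_equal(ncol(d$fx$values), 10)
  expect_identical(colnames(d$fx$values)[1:4], c("SOC", "TN", "AN", "AP"))
  # vector replicate counts give unbalanced designs
  d2 <- synth_community(synth_config(seed = 1, reps_per_zone = c(14, 13, 13)))
  expect_equal(nrow(d2$meta), 40)
  expect_equal(unname(table(d2$meta$zone)[c("AL", "RZ", "TZ")]), c(14, 13, 13),
               ignore_attr = TRUE)
})

test_that("planted core taxa are ubiquitous and top-decile abundant", {
  d <- synth_community(synth_config(seed = 3))
  occ <- compute_occupancy(d$otu)
  expect_true(all(occ[d$truth$core_set] == 1))
  rel <- to_relative(d$otu)
  rk <- rank(-rowMeans(rel$values))
  expect_true(all(rk[d$truth$core_set] <= 40))
})

test_that("core taxa are spread across module blocks", {
  d <- synth_community(synth_config(seed = 1))
  spread <- table(d$truth$module_label[d$truth$core_set])
  expect_equal(unname(spread), rep(8L, 5), ignore_attr = TRUE)
  expect_equal(sum(d$truth$driver_sign), 0)
  expect_equal(d$truth$driver_sign[1], 1)
})

test_that("near-unit within-module correlation shows in log profiles", {
  # many modules keep any single factor from dominating total community
  # size, so compositional closure only mildly attenuates pair correlations
  med_cors <- sapply(1:3, function(s) {
    cfg <- synth_config(seed = s, n_taxa = 200, n_core = 100, n_modules = 5,
                        module_sizes = rep(20, 5), within_module_cor = 0.99,
                        effect_size_zone = 0, reps_per_zone = 8, depth = 5e5)
    d <- synth_community(cfg)
    m1 <- names(d$truth$module_label)[d$truth$module_label == 1]
    p <- taxon_profiles(d$otu, m1, transform = "log")
    cc <- cor(t(p))
    median(cc[upper.tri(cc)])
  })
  expect_true(all(med_cors >= 0.95))
})

test_that("zone effect size raises between-zone ANOSIM R on average", {
  mean_R <- function(es) {
    mean(sapply(1:5, function(s) {
      d <- synth_community(synth_config(seed = s, effect_size_zone = es))
      core <- d$truth$core_set
      rel <- to_relative(d$otu)
      sub <- otu_table(sweep(rel$values[core, ], 2,
                             colSums(rel$values[core, ]), "/"), "relative")
      dm <- bray_curtis(sub)
      zones <- d$meta$zone[match(rownames(dm), d$meta$sample_id)]
      anosim(dm, zones, n_permutations = 99, seed = s)$R
    }))
  }
  expect_gt(mean_R(2), mean_R(0))
})

test_that("trophic assignment biases driver and antagonist modules", {
  d <- synth_community(synth_config(seed = 2))
  map <- default_trophic_map()
  lab <- d$truth$module_label
  cls <- function(m) {
    phy <- d$taxonomy$phylum[match(names(lab)[lab == m], d$taxonomy$otu_id)]
    mean(map[phy] == "copiotroph", na.rm = TRUE)
  }
  expect_gt(cls(1), 0.5)   # driver leans copiotrophic
  expect_lt(cls(2), 0.5)   # antagonist leans oligotrophic
})

test_that("unrealizable occupancy at low depth warns with achieved value", {
  expect_warning(
    synth_community(synth_config(seed = 1, depth = 200)),
    "occupancy"
  )
})
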