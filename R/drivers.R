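#' Random-forest permutation importance of taxa for multifunctionality
#'
#' Fits a regression random forest of EMF on taxon relative-abundance
#' profiles and reports percentage increase in out-of-bag MSE (%IncMSE):
#' importance_j = 100 * (OOB MSE with predictor j permuted - OOB MSE) /
#' OOB MSE. Optional per-taxon p-values come from refitting under response
#' permutation: p = (1 + #\{null importance >= observed\}) /
#' (1 + n_permutations).
#'
#' @param X Samples x taxa predictor matrix (e.g. `t(taxon_profiles(...))`).
#' @param y Per-sample EMF (aligned to rows of X).
#' @param is_core Logical vector flagging core taxa (columns of X).
#' @param n_trees Trees per forest.
#' @param n_permutations Response permutations for per-taxon p-values
#'   (0 skips them).
#' @param seed RNG seed.
#' @return Data.frame of class `importance_result`: `otu_id`, `importance`
#'   (%IncMSE), `is_core`, and `p.value` when permutations were run.
#' @export
rf_importance <- function(X, y, is_core = NULL, n_trees = 1000,
                          n_permutations = 100, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must align with y")
  if (nrow(X) < 8) warning("fewer than 8 samples: importance is unstable")
  if (length(unique(y)) < 2) stop("constant response")
  if (is.null(is_core)) is_core <- rep(FALSE, ncol(X))
  set.seed(seed)
  fit_imp <- function(resp) {
    rf <- randomForest::randomForest(
      x = X, y = resp, ntree = n_trees,
      mtry = max(floor(ncol(X) / 3), 1), importance = TRUE)
    raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    100 * raw / rf$mse[n_trees]
  }
  obs <- fit_imp(y)
  out <- data.frame(otu_id = colnames(X), importance = unname(obs),
                    is_core = is_core, stringsAsFactors = FALSE)
  if (n_permutations > 0) {
    null_ge <- numeric(ncol(X))
    for (b in seq_len(n_permutations)) {
      imp_b <- fit_imp(sample(y))
      null_ge <- null_ge + (imp_b >= obs)
    }
    out$p.value <- (1 + null_ge) / (1 + n_permutations)
  }
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Compare importance of core vs non-core taxa
#'
#' Wilcoxon rank-sum test ([rank_sum_test()]: exact enumeration for small
#' groups) of %IncMSE between core and non-core taxa.
#'
#' @param imp An `importance_result` from [rf_importance()].
#' @param alternative `"two.sided"` (default), `"greater"` (core tends
#'   larger) or `"less"`.
#' @return List: `statistic`, `p.value`, `direction` (+1 when the core
#'   median exceeds the non-core median), `median_core`, `median_other`.
#' @export
compare_core_importance <- function(imp,
                                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- imp$importance[imp$is_core]
  b <- imp$importance[!imp$is_core]
  if (length(a) == 0 || length(b) == 0)
    stop("both core and non-core groups must be nonempty")
  ts <- rank_sum_test(a, b, alternative = alternative)
  list(statistic = ts$statistic, p.value = ts$p.value,
       direction = ts$direction,
       median_core = stats::median(a), median_other = stats::median(b))
}

#' OLS regressions of EMF on cluster abundance
#'
#' Per cluster: least-squares fit of EMF on the cluster's abundance profile;
#' R^2 is the squared Pearson correlation and p the two-sided t-test on the
#' slope. Zero-variance cluster abundances yield NA rows.
#'
#' @param cluster_ab Clusters x samples matrix from [cluster_abundance()].
#' @param emf An `emf_result` or named per-sample EMF vector.
#' @return Data.frame: `cluster`, `slope`, `intercept`, `r_squared`,
#'   `p.value`, `n`.
#' @export
ols_cluster_emf <- function(cluster_ab, emf) {
  v <- if (inherits(emf, "emf_result")) emf$emf else emf
  samples <- intersect(colnames(cluster_ab), names(v))
  if (length(samples) < 3) stop("need at least 3 shared samples")
  do.call(rbind, lapply(rownames(cluster_ab), function(q) {
    ab <- cluster_ab[q, samples]
    if (anyNA(ab) || stats::var(ab) == 0)
      return(data.frame(cluster = q, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, p.value = NA_real_,
                        n = length(samples)))
    fit <- stats::lm(v[samples] ~ ab)
    sm <- summary(fit)
    data.frame(cluster = q,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p.value = sm$coefficients[2, 4],
               n = length(samples))
  }))
}

#' Default phylum-level trophic classification
#'
#' A conventional copiotroph/oligotroph mapping: copiotrophs =
#' Proteobacteria, Actinobacteria, Bacteroidetes, Firmicutes; oligotrophs =
#' Acidobacteria, Chloroflexi, Planctomycetes, Verrucomicrobia; all other
#' phyla unclassified. The mapping is a convention, not a measurement;
#' supply your own named vector (`phylum -> "copiotroph"/"oligotroph"`) to
#' override.
#'
#' @return Named character vector.
#' @export
default_trophic_map <- function() {
  c(stats::setNames(rep("copiotroph", length(copiotroph_phyla)), copiotroph_phyla),
    stats::setNames(rep("oligotroph", length(oligotroph_phyla)), oligotroph_phyla))
}

#' Copiotroph/oligotroph composition per cluster
#'
#' Per cluster: counts (or summed mean relative abundance) of copiotrophic
#' and oligotrophic members, their ratio, and the copiotroph percentage
#' 100 * cop / (cop + olig). Unclassified phyla are excluded from both.
#'
#' @param labels Named cluster labels.
#' @param taxonomy Taxonomy data.frame (`otu_id`, `phylum`).
#' @param map Named vector phylum -> trophic class
#'   (default [default_trophic_map()]).
#' @param basis `"count"` (number of OTUs) or `"abundance"` (summed mean
#'   relative abundance; requires `x`).
#' @param x An [otu_table()], needed for `basis = "abundance"`.
#' @return Data.frame: `cluster`, `copiotroph`, `oligotroph`, `ratio`
#'   (Inf flagged via `ratio_infinite`), `pct_copiotroph`.
#' @export
trophic_ratio <- function(labels, taxonomy, map = default_trophic_map(),
                          basis = c("count", "abundance"), x = NULL) {
  basis <- match.arg(basis)
  ks <- sort(unique(labels[labels > 0]))
  if (length(ks) == 0) stop("no labelled clusters")
  if (basis == "abundance") {
    if (is.null(x)) stop("basis = 'abundance' requires the OTU table")
    rel <- if (x$kind == "counts") to_relative(x) else x
    weight <- rowMeans(rel$values)
  }
  rows <- lapply(ks, function(q) {
    members <- names(labels)[labels == q]
    phy <- taxonomy$phylum[match(members, taxonomy$otu_id)]
    cls <- unname(map[phy])
    w <- if (basis == "count") rep(1, length(members)) else weight[members]
    cop <- sum(w[!is.na(cls) & cls == "copiotroph"])
    olig <- sum(w[!is.na(cls) & cls == "oligotroph"])
    data.frame(cluster = paste0("cluster", q), copiotroph = cop,
               oligotroph = olig,
               ratio = if (olig > 0) cop / olig else Inf,
               ratio_infinite = olig == 0,
               pct_copiotroph = if (cop + olig > 0) 100 * cop / (cop + olig)
                                else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (all(out$copiotroph + out$oligotroph == 0))
    stop("no classified members in any cluster")
  out
}

#' Compare cluster abundance across zones
#'
#' Per cluster: Kruskal-Wallis across zones plus pairwise exact Wilcoxon
#' rank-sum tests and percent differences of zone means (reference = second
#' group of each pair).
#'
#' @param cluster_ab Clusters x samples matrix.
#' @param meta Metadata data.frame (`sample_id`, `zone`).
#' @return Named list per cluster, each as returned by
#'   [compare_emf_groups()].
#' @export
compare_cluster_abundance_by_zone <- function(cluster_ab, meta) {
  out <- lapply(rownames(cluster_ab), function(q) {
    v <- cluster_ab[q, ]
    compare_emf_groups(v, meta)
  })
  names(out) <- rownames(cluster_ab)
  out
}
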