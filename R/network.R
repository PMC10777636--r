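#' Taxon profiles for network construction
#'
#' Extracts the relative-abundance profiles (taxa x samples) of a taxon
#' subset — by default the core set — in canonical sample order.
#' Zero-variance taxa are excluded with a warning (their correlations are
#' undefined). With `transform = "log"` profiles are log relative
#' abundances with a pseudocount of half the smallest nonzero value —
#' abundance data are approximately log-normal, and network correlations
#' assume roughly Gaussian profiles, so [build_network()] uses the log
#' scale.
#'
#' @param x An [otu_table()]; counts are converted to relative abundance.
#' @param subset Character vector of OTU ids (default all).
#' @param transform `"none"` (raw relative abundance) or `"log"`.
#' @return Numeric matrix (taxa x samples).
#' @export
taxon_profiles <- function(x, subset = NULL, transform = c("none", "log")) {
  transform <- match.arg(transform)
  stopifnot(inherits(x, "otu_table"))
  rel <- if (x$kind == "counts") to_relative(x) else x
  if (is.null(subset)) subset <- otu_ids(rel)
  if (length(subset) == 0) stop("empty taxon subset")
  missing <- setdiff(subset, otu_ids(rel))
  if (length(missing)) stop("subset taxa absent from table: ",
                            paste(missing, collapse = ", "))
  p <- rel$values[subset, , drop = FALSE]
  v <- apply(p, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance taxon profile(s) excluded")
    p <- p[v > 0, , drop = FALSE]
  }
  if (transform == "log") {
    pc <- min(p[p > 0]) / 2
    p <- log(p + pc)
  }
  p
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned: A_ij = |cor(x_i, x_j)|^beta; signed: A_ij = ((1 + cor)/2)^beta.
#' The diagonal is set to 1 by convention but excluded from connectivity.
#'
#' @param profiles Taxa x samples matrix.
#' @param beta Soft threshold power (>= 1).
#' @param type `"unsigned"` or `"signed"`.
#' @param correlation `"pearson"` or `"spearman"`.
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
adjacency_matrix <- function(profiles, beta,
                             type = c("unsigned", "signed"),
                             correlation = c("pearson", "spearman")) {
  type <- match.arg(type)
  correlation <- match.arg(correlation)
  stopifnot(beta >= 1)
  cc <- stats::cor(t(profiles), method = correlation)
  A <- if (type == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(A) <- 1
  A
}

#' Connectivity (weighted degree)
#'
#' k_i = sum over j != i of A_ij.
#'
#' @param A Adjacency matrix with unit diagonal.
#' @return Numeric vector.
#' @export
connectivity <- function(A) rowSums(A) - diag(A)

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins k into `nbins` equal-width intervals, then regresses log10 of the
#' per-bin node frequency on log10 of the per-bin mean connectivity; empty
#' bins are dropped. The signed fit index is R^2 when the slope is negative
#' and -R^2 otherwise, so only decreasing (scale-free-like) degree
#' distributions can satisfy the criterion.
#'
#' @param k Connectivity vector.
#' @param nbins Number of bins.
#' @return List: `r2` (signed fit index), `slope`, `n_bins_used`.
#' @export
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(k) < nbins) stop("too few nonzero connectivities to bin")
  bins <- cut(k, breaks = nbins)
  freq <- tapply(k, bins, length) / length(k)
  kbar <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = NA_real_, n_bins_used = sum(keep)))
  lx <- log10(kbar[keep]); ly <- log10(freq[keep])
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2 = -sign(slope) * r2, slope = slope, n_bins_used = sum(keep))
}

#' Choose the soft threshold power by the scale-free criterion
#'
#' For each candidate power, builds the adjacency, computes connectivity,
#' and evaluates [scale_free_fit()]. The chosen power is the smallest with
#' signed fit R^2 >= `target_r2`; if none reaches the target the power
#' maximizing the fit is chosen with a warning.
#'
#' The default candidate set is capped by sample size (unsigned: powers up
#' to 9 below 20 samples, 12 below 30, 14 below 40, 16 otherwise; doubled
#' for signed networks): with few samples, high powers make even
#' independent noise look scale-free — connectivity degenerates to a
#' near-empty network whose binned degree distribution is trivially
#' decreasing — so uncapped scans overfit.
#'
#' @param profiles Taxa x samples matrix (>= 10 taxa, >= 4 samples).
#' @param candidate_powers Integer vector of powers to scan; NULL applies
#'   the sample-size cap.
#' @param target_r2 Scale-free criterion threshold.
#' @param type,correlation Passed to [adjacency_matrix()].
#' @return List: `beta` (chosen power), `reached_target` (logical),
#'   `report` (data.frame: power, r2, slope, mean_k, max_k).
#' @export
pick_soft_threshold <- function(profiles, candidate_powers = NULL,
                                target_r2 = 0.9,
                                type = c("unsigned", "signed"),
                                correlation = c("pearson", "spearman")) {
  type <- match.arg(type)
  correlation <- match.arg(correlation)
  if (nrow(profiles) < 10) stop("need at least 10 taxa")
  if (ncol(profiles) < 4) stop("need at least 4 samples")
  if (is.null(candidate_powers))
    candidate_powers <- seq_len(max_power(ncol(profiles), type))
  cc <- stats::cor(t(profiles), method = correlation)
  base <- if (type == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  rows <- lapply(candidate_powers, function(b) {
    k <- rowSums(base^b)
    if (all(k == 0)) stop("all connectivities zero at power ", b)
    sf <- scale_free_fit(k)
    data.frame(power = b, r2 = sf$r2, slope = sf$slope,
               mean_k = mean(k), max_k = max(k))
  })
  report <- do.call(rbind, rows)
  hit <- which(report$r2 >= target_r2)
  if (length(hit)) {
    beta <- report$power[hit[1]]
    reached <- TRUE
  } else {
    beta <- report$power[which.max(report$r2)]
    reached <- FALSE
    warning(sprintf(
      "no candidate power reaches scale-free R^2 %.2f; using power %d (R^2 = %.3f)",
      target_r2, beta, max(report$r2)))
  }
  list(beta = beta, reached_target = reached, report = report)
}

# sample-size-aware cap on the soft-threshold scan
max_power <- function(n_samples, type) {
  cap <- if (n_samples < 20) 9 else if (n_samples < 30) 12
         else if (n_samples < 40) 14 else 16
  if (type == "signed") cap <- 2 * cap
  cap
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij) for i != j, with
#' L_ij = sum over u != i,j of A_iu A_uj and k_i the connectivity; the
#' diagonal is 1. For adjacency in \[0, 1\] the TOM is symmetric with values
#' in \[0, 1\].
#'
#' @param A Symmetric adjacency matrix, entries in \[0, 1\], unit diagonal.
#' @return TOM matrix.
#' @export
tom_similarity <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(A < 0) || any(A > 1 + 1e-12)) stop("adjacency entries must lie in [0, 1]")
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  L <- A0 %*% A0          # L_ij = sum_{u != i,j} A_iu A_uj (diag(A0) = 0)
  kmin <- outer(k, k, pmin)
  tom <- (L + A0) / (kmin + 1 - A0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Cluster taxa from the TOM by dynamic branch cutting
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' followed by a tree-based dynamic branch cut: the cut height is chosen
#' adaptively as the highest merge height maximizing the number of branches
#' of size at least `min_cluster_size`, so accepted branches are taken
#' complete, just before merges that would fuse them (soft-thresholded
#' dissimilarities saturate near 1 at high powers, so no fixed height or
#' quantile works across powers). Branches below the cut of sufficient size
#' become
#' clusters, labelled 1..K by descending size (ties broken by smallest
#' member id); all other taxa get label 0. Deterministic given the TOM.
#'
#' @param tom TOM matrix with taxon dimnames.
#' @param min_cluster_size Smallest branch accepted as a cluster.
#' @param cut_height Absolute cut height overriding the adaptive choice.
#' @return Named integer vector of cluster labels (0 = unassigned).
#' @export
cluster_modules <- function(tom, min_cluster_size = 20, cut_height = NULL) {
  n <- nrow(tom)
  if (min_cluster_size > n)
    stop("min_cluster_size exceeds the number of taxa")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    best_k <- -1L
    for (h in sort(unique(hc$height))) {
      k <- sum(table(stats::cutree(hc, h = h)) >= min_cluster_size)
      if (k >= best_k) { best_k <- k; cut_height <- h }
    }
  }
  raw <- stats::cutree(hc, h = cut_height)
  relabel_by_size(raw, rownames(tom), min_cluster_size)
}

relabel_by_size <- function(raw, ids, min_cluster_size) {
  names(raw) <- ids
  tab <- table(raw)
  accepted <- names(tab)[tab >= min_cluster_size]
  # order by descending size, ties by smallest member id
  first_id <- vapply(accepted, function(g) min(ids[raw == g]), character(1))
  accepted <- accepted[order(-tab[accepted], first_id)]
  out <- integer(length(raw))
  names(out) <- ids
  for (q in seq_along(accepted)) out[raw == accepted[q]] <- q
  out
}

#' Module eigengenes
#'
#' Per cluster: member profiles are standardized to zero mean and unit
#' variance across samples and the eigengene is the first right singular
#' vector (the sample-space component) of the member x sample matrix,
#' oriented so its average correlation with member profiles is
#' non-negative, at unit norm. A singleton cluster's eigengene is its
#' standardized profile (unit-normalized).
#'
#' @param profiles Taxa x samples matrix.
#' @param labels Named integer cluster labels from [cluster_modules()].
#' @return Samples x clusters matrix of eigengenes (columns `ME1..`).
#' @export
module_eigengenes <- function(profiles, labels) {
  labels <- labels[rownames(profiles)]
  ks <- sort(unique(labels[labels > 0]))
  if (length(ks) == 0) stop("no labelled clusters")
  E <- sapply(ks, function(q) {
    members <- rownames(profiles)[labels == q]
    Xq <- t(scale(t(profiles[members, , drop = FALSE])))
    if (length(members) == 1) {
      e <- as.numeric(Xq)
      e <- e / sqrt(sum(e^2))
    } else {
      e <- svd(Xq, nu = 0, nv = 1)$v[, 1]
    }
    mean_cor <- mean(stats::cor(e, t(profiles[members, , drop = FALSE])))
    if (mean_cor < 0) e <- -e
    e
  })
  rownames(E) <- colnames(profiles)
  colnames(E) <- paste0("ME", ks)
  E
}

#' Module membership (kME) and hub taxa
#'
#' kME_iq is the Pearson correlation of taxon i's profile with eigengene q.
#' Hub taxa of a cluster are its members with kME strictly greater than the
#' threshold (0.9 by default, so kME = 0.9 exactly is not a hub).
#'
#' @param profiles Taxa x samples matrix.
#' @param eigengenes Samples x clusters matrix from [module_eigengenes()].
#' @return Taxa x clusters kME matrix.
#' @export
module_membership <- function(profiles, eigengenes) {
  kme <- stats::cor(t(profiles), eigengenes)
  colnames(kme) <- colnames(eigengenes)
  kme
}

#' @rdname module_membership
#' @param kme kME matrix.
#' @param labels Cluster labels.
#' @param threshold Strict hub cutoff on kME.
#' @return `hub_taxa()`: named list (one element per cluster) of hub OTU ids.
#' @export
hub_taxa <- function(kme, labels, threshold = 0.9) {
  labels <- labels[rownames(kme)]
  ks <- sort(unique(labels[labels > 0]))
  out <- lapply(ks, function(q) {
    col <- paste0("ME", q)
    members <- rownames(kme)[labels == q]
    members[kme[members, col] > threshold]
  })
  names(out) <- paste0("cluster", ks)
  out
}

#' Cluster relative abundance over samples
#'
#' Each member OTU's relative-abundance profile is z-scored across samples;
#' a cluster's abundance in a sample is the mean of its members' z-scores
#' (so every cluster-abundance row has mean zero). Zero-variance members
#' are excluded with a warning.
#'
#' @param x An [otu_table()] (counts converted to relative abundance).
#' @param labels Named integer cluster labels.
#' @return Clusters x samples matrix (rows `cluster1..`).
#' @export
cluster_abundance <- function(x, labels) {
  stopifnot(inherits(x, "otu_table"))
  rel <- if (x$kind == "counts") to_relative(x) else x
  ks <- sort(unique(labels[labels > 0]))
  if (length(ks) == 0) stop("no labelled clusters")
  out <- t(sapply(ks, function(q) {
    members <- intersect(names(labels)[labels == q], otu_ids(rel))
    P <- rel$values[members, , drop = FALSE]
    v <- apply(P, 1, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance member(s) excluded from cluster ", q)
      P <- P[v > 0, , drop = FALSE]
    }
    if (nrow(P) == 0) return(rep(NA_real_, ncol(rel$values)))
    colMeans(t(scale(t(P))))
  }))
  rownames(out) <- paste0("cluster", ks)
  colnames(out) <- colnames(rel$values)
  out
}

#' Build the full co-occurrence network
#'
#' Convenience wrapper running soft-threshold selection, adjacency, TOM,
#' clustering, eigengenes, kME, hub detection and cluster abundance on a
#' taxon subset (default: all taxa in `x`; pass the core set for the
#' core-microbiota network).
#'
#' @param x An [otu_table()].
#' @param subset Taxon subset (OTU ids).
#' @param beta Soft threshold power; NULL picks it by the scale-free
#'   criterion.
#' @param min_cluster_size Smallest accepted cluster; NULL adapts to the
#'   network size as `min(20, max(3, floor(n_nodes / 8)))`, the usual 20 for
#'   networks of 160+ nodes while still resolving structure in small desk
#'   networks.
#' @param kme_threshold,target_r2,candidate_powers,type,correlation
#'   Stage parameters (see the stage functions).
#' @param transform Profile transform for correlation computation
#'   (default `"log"`; see [taxon_profiles()]).
#' @return List of class `network_result`: `beta`, `power_report`,
#'   `adjacency`, `tom`, `connectivity`, `labels`, `eigengenes`, `kme`,
#'   `hubs`, `cluster_abundance`, `profiles`.
#' @export
build_network <- function(x, subset = NULL, beta = NULL,
                          min_cluster_size = NULL, kme_threshold = 0.9,
                          target_r2 = 0.9, candidate_powers = NULL,
                          type = "unsigned", correlation = "pearson",
                          transform = "log") {
  profiles <- taxon_profiles(x, subset, transform = transform)
  if (is.null(min_cluster_size))
    min_cluster_size <- min(20, max(3, floor(nrow(profiles) / 8)))
  power_report <- NULL
  if (is.null(beta)) {
    ps <- pick_soft_threshold(profiles, candidate_powers, target_r2,
                              type = type, correlation = correlation)
    beta <- ps$beta
    power_report <- ps$report
  }
  A <- adjacency_matrix(profiles, beta, type = type, correlation = correlation)
  tom <- tom_similarity(A)
  labels <- cluster_modules(tom, min_cluster_size = min_cluster_size)
  E <- module_eigengenes(profiles, labels)
  kme <- module_membership(profiles, E)
  hubs <- hub_taxa(kme, labels, threshold = kme_threshold)
  ca <- cluster_abundance(x, labels)
  structure(list(beta = beta, power_report = power_report, adjacency = A,
                 tom = tom, connectivity = connectivity(A), labels = labels,
                 eigengenes = E, kme = kme, hubs = hubs,
                 cluster_abundance = ca, profiles = profiles),
            class = "network_result")
}
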