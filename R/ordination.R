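#' Bray-Curtis distance matrix between samples
#'
#' d(u, v) = 1 - 2 sum_i min(u_i, v_i) / (sum_i u_i + sum_i v_i), computed on
#' the raw sample vectors (counts or relative abundance) via
#' [vegan::vegdist()].
#'
#' @param x An [otu_table()].
#' @return A symmetric matrix with zero diagonal and entries in \[0, 1\],
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  zero <- colSums(x$values) == 0
  if (sum(zero) >= 2)
    stop("distance undefined between all-zero samples: ",
         paste(colnames(x$values)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(x$values), method = "bray"))
  dimnames(d) <- list(colnames(x$values), colnames(x$values))
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes it; coordinates are
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (Bray-Curtis is generally non-Euclidean) are dropped
#' from the coordinates and, by default, from the explained-variance
#' denominator.
#'
#' @param d Symmetric distance matrix.
#' @param negative `"drop"` (default: explained = eigenvalue / sum of
#'   positive eigenvalues) or `"absolute"` (denominator = sum of absolute
#'   eigenvalues).
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues`, `explained` (non-increasing proportions).
#' @export
pcoa <- function(d, negative = c("drop", "absolute")) {
  negative <- match.arg(negative)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  # cmdscale warns when fewer than k axes have positive eigenvalues; the
  # positive set is extracted explicitly below
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- sc$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  denom <- if (negative == "drop") sum(eig[pos]) else sum(abs(eig))
  structure(list(coordinates = coords, eigenvalues = eig,
                 explained = eig[pos] / denom),
            class = "pcoa_result")
}

# All distinct assignments of a label multiset to positions (matrix, one
# column per assignment). Count = n! / prod(n_g!).
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  recurse <- function(remaining) {
    if (length(remaining) == 0) return(matrix(character(0), nrow = 0, ncol = 1))
    out <- NULL
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      sub <- recurse(rest)
      out <- cbind(out, rbind(u, sub))
    }
    out
  }
  unname(recurse(sort(labels)))
}

n_distinct_assignments <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group distances exceed within-group
#' distances. R = (mean between-group rank - mean within-group rank) /
#' (M / 2) with M = n(n-1)/2, mid-ranks over all pairwise distances. The
#' p-value is obtained by label permutation with the estimator
#' p = (1 + #\{R_perm >= R_obs\}) / (1 + n_permutations); when the number of
#' distinct label assignments is at most `exhaustive_max` all of them are
#' enumerated instead and p = #\{R >= R_obs\} / #assignments.
#'
#' @param d Symmetric distance matrix with sample dimnames.
#' @param groups Group label per sample (recycled against `rownames(d)` by
#'   position).
#' @param n_permutations Monte Carlo permutation count.
#' @param seed RNG seed for the permutation draw.
#' @param exhaustive_max Enumerate exactly when the distinct-assignment count
#'   is at most this.
#' @return List of class `anosim_result`: `R`, `p.value`, `n_permutations`,
#'   `exhaustive`, `seed`.
#' @export
anosim <- function(d, groups, n_permutations = 9999, seed = 1,
                   exhaustive_max = 20000) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 members")
  iu <- which(upper.tri(d))
  r <- rank(d[iu])  # mid-ranks of all pairwise distances
  pair_i <- row(d)[iu]; pair_j <- col(d)[iu]
  M <- length(r)
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- stat(groups)
  n_assign <- n_distinct_assignments(groups)
  if (n_assign <= exhaustive_max) {
    perms <- multiset_permutations(groups)
    R_perm <- apply(perms, 2, stat)
    p <- mean(R_perm >= R_obs - 1e-12)
    exhaustive <- TRUE
    n_permutations <- ncol(perms)
  } else {
    set.seed(seed)
    R_perm <- replicate(n_permutations, stat(sample(groups)))
    p <- (1 + sum(R_perm >= R_obs - 1e-12)) / (1 + n_permutations)
    exhaustive <- FALSE
  }
  structure(list(R = R_obs, p.value = p, n_permutations = n_permutations,
                 exhaustive = exhaustive, seed = seed),
            class = "anosim_result")
}
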