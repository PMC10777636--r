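#' Exact mid-rank Wilcoxon rank-sum test
#'
#' Rank-sum test with exact enumeration of all group assignments when both
#' groups have at most `exact_max` members (choose(16, 8) = 12870 splits at
#' the default), using mid-ranks so ties are handled exactly; otherwise the
#' normal approximation with continuity correction via [stats::wilcox.test()].
#' Small zoned designs (4 vs 4 replicates) make asymptotic p-values invalid,
#' hence the enumeration: with complete separation of 4 vs 4 the two-sided
#' floor is 2/70, and 2/252 for 5 vs 5.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max Largest per-group size for which enumeration is used.
#' @return List: `statistic` (rank sum W of `x`), `p.value`, `exact`
#'   (logical), `direction` (sign of median difference).
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))  # mid-ranks
  w_obs <- sum(r[seq_len(nx)])
  direction <- sign(stats::median(x) - stats::median(y))
  eps <- 1e-9
  if (nx <= exact_max && ny <= exact_max) {
    splits <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[splits], nrow = nx))
    mu <- nx * (n + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(w_all - mu) >= abs(w_obs - mu) - eps),
      greater   = mean(w_all >= w_obs - eps),
      less      = mean(w_all <= w_obs + eps))
    exact <- TRUE
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative,
                         exact = FALSE, correct = TRUE))
    p <- wt$p.value
    exact <- FALSE
  }
  list(statistic = w_obs, p.value = p, exact = exact, direction = direction)
}

#' Min-max standardization to \[0, 1\]
#'
#' @param v Numeric vector, length >= 2, not constant.
#' @return `(v - min(v)) / (max(v) - min(v))`.
#' @export
minmax_standardize <- function(v) {
  if (length(v) < 2) stop("need at least 2 values")
  rng <- range(v)
  if (rng[1] == rng[2]) stop("degenerate (constant) variable: min equals max")
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Transform soil functions toward normality
#'
#' Per function: keep raw values when the Shapiro-Wilk test does not reject
#' normality at `alpha`; otherwise try the natural log (requires all values
#' > 0) then the square root (requires values >= 0), keeping the first
#' transform whose Shapiro-Wilk p-value reaches `alpha`, else the candidate
#' with the largest p-value. Constant functions are left untouched and
#' flagged degenerate.
#'
#' @param fx A [function_table()].
#' @param alpha Normality screening level.
#' @return List: `fx` (transformed [function_table()]) and `log` (data.frame
#'   with `fn`, `transform`, `shapiro_p_raw`, `shapiro_p_final`).
#' @export
transform_for_normality <- function(fx, alpha = 0.05) {
  stopifnot(inherits(fx, "function_table"))
  vals <- fx$values
  log_rows <- vector("list", ncol(vals))
  for (j in seq_len(ncol(vals))) {
    fn <- colnames(vals)[j]
    v <- vals[, j]
    if (length(unique(v)) < 2) {
      log_rows[[j]] <- data.frame(fn = fn, transform = "none",
                                  shapiro_p_raw = NA_real_,
                                  shapiro_p_final = NA_real_)
      next
    }
    p_raw <- stats::shapiro.test(v)$p.value
    cands <- list(none = v)
    if (all(v > 0)) cands$log <- log(v)
    if (all(v >= 0)) cands$sqrt <- sqrt(v)
    ps <- vapply(cands, function(u) {
      if (length(unique(u)) < 2) return(NA_real_)
      stats::shapiro.test(u)$p.value
    }, numeric(1))
    ok <- which(!is.na(ps) & ps >= alpha)
    pick <- if (length(ok)) names(ps)[ok[1]] else names(ps)[which.max(ps)]
    if (is.na(ps[pick])) pick <- "none"
    if (pick != "none" && ps[pick] < alpha && p_raw >= ps[pick]) pick <- "none"
    vals[, j] <- cands[[pick]]
    log_rows[[j]] <- data.frame(fn = fn, transform = pick,
                                shapiro_p_raw = p_raw,
                                shapiro_p_final = unname(ps[pick]))
  }
  list(fx = function_table(vals), log = do.call(rbind, log_rows))
}

#' Averaged ecosystem multifunctionality index
#'
#' Each non-degenerate function variable is min-max standardized to \[0, 1\]
#' and the EMF of a sample is the mean of its standardized values. A sample
#' attaining the maximum of every function scores exactly 1. Degenerate
#' (constant) functions are excluded with a warning.
#'
#' @param fx A [function_table()] (optionally already normality-transformed;
#'   min-max standardization is invariant to increasing affine maps, so raw
#'   vs transformed matters only for non-affine transforms).
#' @return List of class `emf_result`: `emf` (named per-sample vector),
#'   `standardized` (samples x functions matrix), `excluded` (function
#'   names).
#' @export
emf_index <- function(fx) {
  stopifnot(inherits(fx, "function_table"))
  vals <- fx$values
  if (nrow(vals) < 2) stop("EMF needs at least 2 samples")
  degen <- colnames(vals)[apply(vals, 2, function(v) length(unique(v)) < 2)]
  if (length(degen) == ncol(vals)) stop("all functions are degenerate")
  if (length(degen))
    warning("excluding degenerate function(s): ", paste(degen, collapse = ", "))
  keep <- setdiff(colnames(vals), degen)
  std <- apply(vals[, keep, drop = FALSE], 2, minmax_standardize)
  rownames(std) <- rownames(vals)
  structure(list(emf = rowMeans(std), standardized = std, excluded = degen),
            class = "emf_result")
}

#' Compare EMF across zones
#'
#' Global Kruskal-Wallis test across zones plus pairwise two-sided exact
#' Wilcoxon rank-sum tests ([rank_sum_test()]); percent change of group means
#' is reported as 100 * (mean_a - mean_b) / mean_b with the second-named
#' group as reference.
#'
#' @param emf An `emf_result` from [emf_index()], or a named numeric vector
#'   of per-sample EMF values.
#' @param meta Metadata data.frame (`sample_id`, `zone`).
#' @return List: `kruskal` (statistic, df, p.value), `pairwise` (data.frame
#'   with group_a, group_b, statistic, p.value, mean_a, mean_b,
#'   pct_change).
#' @export
compare_emf_groups <- function(emf, meta) {
  v <- if (inherits(emf, "emf_result")) emf$emf else emf
  zone <- meta$zone[match(names(v), meta$sample_id)]
  if (anyNA(zone)) stop("metadata is missing some EMF samples")
  sizes <- table(zone)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding zone(s) with < 2 samples: ", paste(small, collapse = ", "))
    keep <- !(zone %in% small)
    v <- v[keep]; zone <- zone[keep]
  }
  groups <- sort(unique(zone))
  if (length(groups) < 2) stop("need at least 2 zones with >= 2 samples")
  kw <- stats::kruskal.test(v, factor(zone))
  pairs <- utils::combn(groups, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ts <- rank_sum_test(v[zone == a], v[zone == b])
    ma <- mean(v[zone == a]); mb <- mean(v[zone == b])
    data.frame(group_a = a, group_b = b, statistic = ts$statistic,
               p.value = ts$p.value, mean_a = ma, mean_b = mb,
               pct_change = 100 * (ma - mb) / mb)
  }))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value),
       pairwise = pw)
}
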