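#' Per-OTU occupancy
#'
#' Occupancy is the fraction of samples in which a taxon has nonzero
#' abundance.
#'
#' @param x An [otu_table()] (counts or relative).
#' @return Named numeric vector in \[0, 1\], one entry per OTU.
#' @export
compute_occupancy <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rowSums(x$values > 0) / ncol(x$values)
}

#' Identify the core microbiota by the dual abundance-occupancy criterion
#'
#' An OTU is core when it is both (1) highly abundant — within the top
#' `top_frac` of OTUs ranked by mean relative abundance across samples
#' (rank <= ceiling(top_frac * n_taxa), ties at the boundary included) — and
#' (2) ubiquitous — occupancy >= `occ_frac`. With 12 samples and
#' `occ_frac = 0.95` this requires presence in all 12 (11/12 < 0.95).
#'
#' @param x An [otu_table()]; counts are converted to relative abundance
#'   internally.
#' @param top_frac Abundance criterion: fraction of top-ranked OTUs kept.
#' @param occ_frac Occupancy criterion threshold.
#' @param taxonomy Optional taxonomy data.frame; when given with
#'   `scope = "per_kingdom"` the abundance ranking is done within each
#'   kingdom separately (mirroring separate 16S and ITS tables).
#' @param scope `"all"` (one pooled ranking) or `"per_kingdom"`.
#' @return A data.frame of class `core_assignment` with one row per OTU:
#'   `otu_id`, `mean_rel_abundance`, `abundance_rank_fraction`, `occupancy`,
#'   `is_core`.
#' @export
identify_core <- function(x, top_frac = 0.10, occ_frac = 0.95,
                          taxonomy = NULL, scope = c("all", "per_kingdom")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "otu_table"))
  if (nrow(x$values) == 0) stop("empty OTU table")
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  if (occ_frac <= 0 || occ_frac > 1) stop("occ_frac must be in (0, 1]")
  rel <- if (x$kind == "counts") to_relative(x) else x

  if (scope == "per_kingdom") {
    if (is.null(taxonomy)) stop("scope = 'per_kingdom' requires a taxonomy table")
    kg <- taxonomy$kingdom[match(otu_ids(rel), taxonomy$otu_id)]
    if (anyNA(kg)) stop("taxonomy is missing entries for some OTUs")
    parts <- lapply(split(otu_ids(rel), kg), function(ids) {
      # within-kingdom columns no longer sum to 1; the ranking only needs order
      sub <- list(values = rel$values[ids, , drop = FALSE], kind = "relative")
      core_one_table(sub, top_frac, occ_frac)
    })
    out <- do.call(rbind, parts)
    out <- out[match(otu_ids(rel), out$otu_id), ]
    rownames(out) <- NULL
  } else {
    out <- core_one_table(rel, top_frac, occ_frac)
  }
  class(out) <- c("core_assignment", "data.frame")
  out
}

core_one_table <- function(rel, top_frac, occ_frac) {
  mean_ab <- rowMeans(rel$values)
  n <- length(mean_ab)
  rk <- rank(-mean_ab, ties.method = "min")
  n_top <- ceiling(top_frac * n)
  # boundary ties included: pass iff mean abundance >= value at rank n_top
  thresh <- sort(mean_ab, decreasing = TRUE)[n_top]
  abundant <- mean_ab >= thresh
  occ <- rowSums(rel$values > 0) / ncol(rel$values)
  # integer comparison guards float noise in occ_frac * n_samples
  ubiquitous <- rowSums(rel$values > 0) >= occ_frac * ncol(rel$values) - 1e-9
  data.frame(
    otu_id = names(mean_ab),
    mean_rel_abundance = unname(mean_ab),
    abundance_rank_fraction = unname(rk) / n,
    occupancy = unname(occ),
    is_core = unname(abundant & ubiquitous),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Core set membership as OTU ids
#'
#' @param assignment A `core_assignment` from [identify_core()].
#' @return Character vector of core OTU ids.
#' @export
core_set <- function(assignment) {
  assignment$otu_id[assignment$is_core]
}
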