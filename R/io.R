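#' Construct an OTU abundance table
#'
#' A taxa-by-samples abundance matrix with a `kind` flag distinguishing raw
#' counts from relative abundances. Row names are OTU ids, column names are
#' sample ids; both must be unique and all cells non-negative and finite.
#'
#' @param values Numeric matrix (taxa x samples) with dimnames.
#' @param kind Either `"counts"` or `"relative"`. Relative tables must have
#'   columns summing to 1 (tolerance 1e-9).
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(values, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry OTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate OTU id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("OTU table contains missing or non-finite cells")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at row '%s', column '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (kind == "relative") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      stop("relative-abundance columns must sum to 1 (max deviation ",
           format(max(abs(cs - 1))), ")")
  }
  structure(list(values = values, kind = kind), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d taxa x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
otu_ids <- function(x) rownames(x$values)

#' @rdname otu_table
#' @export
sample_ids <- function(x) {
  if (inherits(x, "otu_table")) colnames(x$values)
  else if (inherits(x, "function_table")) rownames(x$values)
  else stop("no sample ids for this object")
}

#' Construct a soil-function table
#'
#' Samples-by-functions matrix of soil function measurements (nutrients,
#' fertility, enzyme activities). Functions with fewer than two distinct
#' values across samples are retained but flagged degenerate; downstream EMF
#' computation excludes them.
#'
#' @param values Numeric matrix (samples x functions) with dimnames.
#' @return An object of class `function_table` with a `degenerate` attribute
#'   naming constant functions.
#' @export
function_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids as rownames and function names as colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate sample id or function name")
  if (anyNA(values) || any(!is.finite(values)))
    stop("function table contains missing or non-finite cells")
  degen <- colnames(values)[apply(values, 2, function(v) length(unique(v)) < 2)]
  structure(list(values = values, degenerate = degen), class = "function_table")
}

#' @export
print.function_table <- function(x, ...) {
  cat(sprintf("<function_table> %d samples x %d functions",
              nrow(x$values), ncol(x$values)))
  if (length(x$degenerate))
    cat(sprintf(" (%d degenerate)", length(x$degenerate)))
  cat("\n")
  invisible(x)
}

#' Read an OTU table from TSV
#'
#' Expects a header row of sample ids and a first column of OTU ids; all body
#' cells numeric. Counts are never silently normalized.
#'
#' @param path Path to a tab-separated file.
#' @param kind `"counts"` or `"relative"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("OTU table needs an id column plus at least one sample")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   ids[i], colnames(body)[j], path))
    }
    m[, j] <- v
  }
  otu_table(m, kind = kind)
}

#' Write an OTU table to TSV
#'
#' Numeric content survives a write/read round trip to at least 12
#' significant digits.
#'
#' @param x An [otu_table()].
#' @param path Output path.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  write_tsv_matrix(x$values, path, id_col = "otu_id")
  invisible(path)
}

write_tsv_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), format(m, digits = 15, trim = TRUE,
                                       scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a taxonomy table from TSV
#'
#' Columns: `otu_id`, `kingdom`, `phylum`. Unknown phyla may be
#' `"Unclassified"`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns otu_id, kingdom, phylum.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("otu_id", "kingdom", "phylum")
  if (!all(need %in% colnames(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy table")
  df[need]
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy data.frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `zone`, `replicate`. Zones are arbitrary labels
#' (AL/RZ/TZ in the motivating design); group tests require at least two
#' samples per zone.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns sample_id, zone, replicate.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "zone", "replicate")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df$replicate <- as.integer(df$replicate)
  df[need]
}

#' @rdname read_metadata
#' @param meta Metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a soil-function table from TSV
#'
#' Header row of function names, first column of sample ids.
#'
#' @param path Path to a tab-separated file.
#' @return A [function_table()].
#' @export
read_function_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in function table ", path)
  rownames(m) <- ids
  function_table(m)
}

#' @rdname read_function_table
#' @param x A `function_table`.
#' @export
write_function_table <- function(x, path) {
  stopifnot(inherits(x, "function_table"))
  write_tsv_matrix(x$values, path, id_col = "sample_id")
  invisible(path)
}

#' Convert a count table to relative abundance
#'
#' Divides each sample column by its total. Refuses already-relative input
#' (double-normalization guard) and samples with zero total reads. Exact
#' zeros stay zero.
#'
#' @param x An [otu_table()] of kind `"counts"`.
#' @return An [otu_table()] of kind `"relative"`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (x$kind == "relative")
    stop("table is already relative abundance; refusing to normalize twice")
  cs <- colSums(x$values)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(x$values)[cs == 0], collapse = ", "))
  otu_table(sweep(x$values, 2, cs, "/"), kind = "relative")
}

#' Align OTU, metadata and function tables on shared samples
#'
#' Restricts all three to the intersection of their sample ids, in
#' lexicographic order (the canonical sample order used by every downstream
#' matrix). Dropped ids are reported via message.
#'
#' @param otu An [otu_table()].
#' @param meta Metadata data.frame (`sample_id`, `zone`, `replicate`).
#' @param fx A [function_table()], or NULL.
#' @return List with elements `otu`, `meta`, `fx` restricted to the common
#'   samples.
#' @export
align_tables <- function(otu, meta, fx = NULL) {
  ids <- list(colnames(otu$values), meta$sample_id)
  if (!is.null(fx)) ids <- c(ids, list(rownames(fx$values)))
  common <- sort(Reduce(intersect, ids))
  if (length(common) == 0) stop("no sample ids shared by all tables")
  dropped <- setdiff(unique(unlist(ids)), common)
  if (length(dropped))
    message("align_tables: dropping samples absent from some table: ",
            paste(sort(dropped), collapse = ", "))
  out <- list(
    otu = otu_table(otu$values[, common, drop = FALSE], kind = otu$kind),
    meta = meta[match(common, meta$sample_id), , drop = FALSE],
    fx = if (!is.null(fx)) function_table(fx$values[common, , drop = FALSE])
  )
  rownames(out$meta) <- NULL
  out
}
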