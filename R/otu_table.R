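# OTU table construction, input/output, normalization and artifact filtering.
#
# The canonical in-memory form throughout the package is a plain numeric
# matrix of non-negative integer counts with samples as rows and OTUs as
# columns, carrying sample ids as rownames and OTU ids as colnames. All
# downstream modules consume this form.

#' Construct and validate an OTU count table
#'
#' Validates a samples-by-OTUs matrix of non-negative integer counts with
#' unique sample and OTU identifiers. Empty rows or columns are allowed at
#' construction; use [prune_empty()] to drop them explicitly.
#'
#' @param counts Numeric matrix of non-negative integers, samples in rows.
#' @param sample_ids,otu_ids Character vectors of unique identifiers;
#'   default to the matrix dimnames.
#' @return The validated counts matrix with dimnames set.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("sample and OTU identifiers are required (dimnames or arguments)",
         call. = FALSE)
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("identifier lengths do not match table dimensions", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1],
         call. = FALSE)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1], call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  dimnames(counts) <- list(sample_ids, otu_ids)
  counts
}

#' Drop all-zero samples and OTUs
#'
#' Explicit prune step: removes rows and columns whose counts are all zero,
#' reporting what was dropped.
#'
#' @param table OTU table ([otu_table()]).
#' @param quiet Suppress the message describing dropped rows/columns.
#' @return The pruned table.
#' @export
prune_empty <- function(table, quiet = FALSE) {
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!quiet && (!all(keep_r) || !all(keep_c)))
    message(sprintf("prune_empty: dropped %d empty sample(s), %d empty OTU(s)",
                    sum(!keep_r), sum(!keep_c)))
  table[keep_r, keep_c, drop = FALSE]
}

#' Read an OTU table from a mothur `.shared` file or plain TSV
#'
#' The `.shared` dialect has header columns `label Group numOtus` followed by
#' one column per OTU and one row per sample; the `label` and `numOtus`
#' columns are checked for consistency and dropped. Plain TSV files have a
#' header row and identifiers in the first column; `orientation` says whether
#' rows are samples or OTUs.
#'
#' @param path File path.
#' @param format `"shared"` or `"tsv"`.
#' @param orientation For TSV input, `"samples_as_rows"` (default) or
#'   `"otus_as_rows"` (the table is transposed on read).
#' @return OTU table (samples x OTUs), ids in file order.
#' @export
read_otu_table <- function(path,
                           format = c("shared", "tsv"),
                           orientation = c("samples_as_rows", "otus_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (format == "shared") {
    need <- c("label", "Group", "numOtus")
    if (ncol(df) < 4L || !identical(tolower(names(df)[1:3]), tolower(need)))
      stop("malformed .shared header in ", path,
           ": expected columns 'label Group numOtus Otu...'", call. = FALSE)
    n_otu_cols <- ncol(df) - 3L
    bad <- which(df[[3]] != n_otu_cols)
    if (length(bad))
      stop(sprintf("%s row %d: numOtus = %s but %d count columns present",
                   path, bad[1], df[bad[1], 3], n_otu_cols), call. = FALSE)
    ids <- as.character(df[[2]])
    counts <- as.matrix(df[, -(1:3), drop = FALSE])
  } else {
    ids <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
  }
  if (!is.numeric(counts))
    stop("non-numeric count cell in ", path, call. = FALSE)
  bad <- which(counts < 0 | counts != round(counts))
  if (length(bad))
    stop(sprintf("%s: negative or non-integer count at cell %d", path, bad[1]),
         call. = FALSE)
  rownames(counts) <- ids
  if (format == "tsv" && orientation == "otus_as_rows") counts <- t(counts)
  otu_table(counts)
}

#' Write an OTU table as a mothur `.shared` file
#'
#' @param table OTU table.
#' @param path Output path.
#' @param label Distance label for the first column (default `"0.03"`).
#' @return `path`, invisibly.
#' @export
write_shared <- function(table, path, label = "0.03") {
  df <- data.frame(label = label, Group = rownames(table),
                   numOtus = ncol(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove presumed sequencing artifacts from an OTU table
#'
#' Discards every OTU whose total count over all samples is at most two
#' (singletons and doubletons) or that has positive counts in only a single
#' sample. Survivor order is preserved. Idempotent.
#'
#' @param table OTU table of raw or rarefied integer counts.
#' @return Filtered table.
#' @export
filter_artifacts <- function(table) {
  tot <- colSums(table)
  occ <- colSums(table > 0)
  keep <- tot > 2 & occ >= 2
  if (!any(keep))
    stop("artifact filter removed every OTU; inspect the input table",
         call. = FALSE)
  table[, keep, drop = FALSE]
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (multivariate hypergeometric draw per sample). Deterministic for a
#' fixed `seed`.
#'
#' @param table OTU table.
#' @param depth Target reads per sample.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param drop_small Drop samples with fewer than `depth` reads instead of
#'   raising an error.
#' @return Rarefied table; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL, drop_small = FALSE) {
  if (length(depth) != 1L || depth < 1 || depth != round(depth))
    stop("`depth` must be a positive integer", call. = FALSE)
  sums <- rowSums(table)
  if (any(sums < depth)) {
    if (drop_small) {
      table <- table[sums >= depth, , drop = FALSE]
      if (nrow(table) == 0L)
        stop("no sample reaches the requested depth", call. = FALSE)
    } else {
      small <- rownames(table)[sums < depth][1]
      stop(sprintf("sample '%s' has fewer than %d reads (set drop_small = TRUE to discard it)",
                   small, depth), call. = FALSE)
    }
  }
  with_seed(seed, {
    out <- table
    for (i in seq_len(nrow(table))) {
      row <- table[i, ]
      if (sum(row) == depth) next   # identity at full depth
      pool <- rep.int(seq_along(row), row)
      draw <- sample(pool, depth, replace = FALSE)
      out[i, ] <- tabulate(draw, nbins = length(row))
    }
    out
  })
}

#' Convert counts to per-sample relative abundances
#'
#' @param table OTU table with positive row sums.
#' @return Matrix of proportions; each row sums to 1.
#' @export
to_relative <- function(table) {
  sums <- rowSums(table)
  if (any(sums == 0))
    stop("all-zero sample row: ", rownames(table)[sums == 0][1], call. = FALSE)
  table / sums
}

#' Hellinger transformation
#'
#' Square root of per-sample relative abundance; makes Euclidean-based
#' ordinations appropriate for count data.
#'
#' @param table OTU table with positive row sums.
#' @return Matrix with entries `sqrt(count / row sum)`.
#' @export
hellinger <- function(table) sqrt(to_relative(table))

#' Write a provenance sidecar JSON next to an output file
#'
#' Records seed, parameters and package version so any table written by the
#' workflow can be regenerated.
#'
#' @param path Path of the output file the sidecar describes.
#' @param params Named list of parameters (seeds included).
#' @return Sidecar path, invisibly.
#' @export
write_provenance <- function(path, params = list()) {
  side <- paste0(path, ".provenance.json")
  info <- list(
    file = basename(path),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "otuassembly",
    version = as.character(utils::packageVersion("otuassembly")),
    params = params
  )
  jsonlite::write_json(info, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(side)
}
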