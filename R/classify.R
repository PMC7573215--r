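# Classification of OTUs into six abundance/rarity categories from the range
# of their relative abundance across samples.

#' The six abundance/rarity categories
#'
#' `AT` abundant taxa, `CAT` conditionally abundant taxa, `MT` moderate
#' taxa, `CRAT` conditionally rare and abundant taxa, `CRT` conditionally
#' rare taxa, `RT` rare taxa.
#'
#' @export
abundance_categories <- c("AT", "CAT", "MT", "CRAT", "CRT", "RT")

#' Classify OTUs into the six abundance/rarity categories
#'
#' With `Mn`/`Mx` the minimum/maximum relative abundance of an OTU over all
#' samples (zeros included for samples where it is absent):
#' \itemize{
#'   \item AT: `Mn >= abund_cut` (abundant in every sample);
#'   \item CAT: `Mn > rare_cut`, `Mx >= abund_cut`, not AT;
#'   \item MT: `Mn > rare_cut` and `Mx < abund_cut` (always intermediate);
#'   \item CRAT: `Mn <= rare_cut` and `Mx >= abund_cut` (oscillates between
#'     rare and abundant);
#'   \item CRT: `Mn <= rare_cut` and `rare_cut < Mx < abund_cut`;
#'   \item RT: `Mx <= rare_cut` (rare everywhere).
#' }
#' The predicates partition every OTU into exactly one category; the
#' rare-side boundaries are inclusive, so an OTU absent from at least one
#' sample can never be AT, CAT or MT.
#'
#' @param rel Relative-abundance matrix (samples x OTUs, rows summing to 1),
#'   e.g. from [to_relative()].
#' @param rare_cut Rarity threshold (default 0.001, i.e. 0.1%).
#' @param abund_cut Abundance threshold (default 0.01, i.e. 1%).
#' @return Tibble: `otu_id`, `category` (factor over the six levels),
#'   `min_rel`, `max_rel`, `occupancy`.
#' @export
classify_otus <- function(rel, rare_cut = 0.001, abund_cut = 0.01) {
  if (!(rare_cut > 0 && rare_cut < abund_cut && abund_cut < 1))
    stop("need 0 < rare_cut < abund_cut < 1", call. = FALSE)
  Mn <- apply(rel, 2, min)
  Mx <- apply(rel, 2, max)
  category <- ifelse(Mn >= abund_cut, "AT",
              ifelse(Mn > rare_cut & Mx >= abund_cut, "CAT",
              ifelse(Mn > rare_cut, "MT",
              ifelse(Mx >= abund_cut, "CRAT",
              ifelse(Mx > rare_cut, "CRT", "RT")))))
  tibble::tibble(otu_id = colnames(rel),
                 category = factor(category, levels = abundance_categories),
                 min_rel = unname(Mn), max_rel = unname(Mx),
                 occupancy = unname(colSums(rel > 0)))
}

#' Summarize sub-communities by category
#'
#' Per-category OTU richness, total reads, and percentages of OTUs and of
#' reads. Percentages sum to 100 over categories.
#'
#' @param cls Classification from [classify_otus()].
#' @param table OTU count table sharing `otu_id`s with `cls`.
#' @return Tibble with one row per category present.
#' @export
category_summary <- function(cls, table) {
  if (!setequal(cls$otu_id, colnames(table)))
    stop("classification and table OTU ids do not match", call. = FALSE)
  cat_of <- cls$category[match(colnames(table), cls$otu_id)]
  reads <- colSums(table)
  tot_reads <- sum(reads)
  present <- levels(cat_of)[table(cat_of) > 0]
  rows <- lapply(present, function(cc) {
    sel <- cat_of == cc
    cat_reads <- sum(reads[sel])
    tibble::tibble(category = cc,
                   n_otus = sum(sel),
                   reads = cat_reads,
                   pct_otus = 100 * sum(sel) / ncol(table),
                   pct_reads = 100 * cat_reads / tot_reads)
  })
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = abundance_categories)
  out[order(out$category), ]
}

#' Extract the OTU sub-table of one category
#'
#' @param cls Classification from [classify_otus()].
#' @param table OTU table.
#' @param category One of [abundance_categories].
#' @return The count sub-table of that category's OTUs.
#' @export
subcommunity <- function(cls, table, category) {
  category <- match.arg(category, abundance_categories)
  ids <- cls$otu_id[cls$category == category]
  table[, colnames(table) %in% ids, drop = FALSE]
}
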