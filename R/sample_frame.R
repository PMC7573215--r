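# Per-sample metadata: study-design factors, coordinates and environmental
# variables.

#' Names of the environmental variables carried by a sample frame
#'
#' Temperature (degC), salinity (psu), dissolved oxygen (mg/L), ammonium,
#' nitrate, nitrite and dissolved inorganic phosphorus (umol/L), chlorophyll a
#' (ug/ml), and Synechococcus, picoeukaryote and heterotrophic-bacteria
#' abundances (cells/ml).
#'
#' @export
env_variables <- c("Temp", "Sal", "DO", "NH4_N", "NO3_N", "NO2_N", "DIP",
                   "Chl_a", "Syn", "PEUK", "HB")

#' Validate a per-sample metadata frame
#'
#' Checks the design columns (`sample_id`, `month`, `habitat`, `layer`,
#' `lon`, `lat`, `depth`) and any environmental columns for range and
#' finiteness, and optionally that the sample set matches an OTU table.
#'
#' @param df Data frame of per-sample metadata.
#' @param table Optional OTU table whose rownames must equal `df$sample_id`.
#' @param months,habitats,layers Allowed factor levels.
#' @return `df` as a tibble with design columns as factors.
#' @export
sample_frame <- function(df, table = NULL,
                         months = c("May", "Aug", "Oct"),
                         habitats = c("coast", "shelf"),
                         layers = c("S", "B")) {
  need <- c("sample_id", "month", "habitat", "layer", "lon", "lat", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample frame is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample frame", call. = FALSE)
  for (col in c("month", "habitat", "layer")) {
    lev <- switch(col, month = months, habitat = habitats, layer = layers)
    bad <- setdiff(unique(as.character(df[[col]])), lev)
    if (length(bad))
      stop(sprintf("unknown %s level: %s", col, bad[1]), call. = FALSE)
    df[[col]] <- factor(as.character(df[[col]]), levels = lev)
  }
  if (any(df$lat < -90 | df$lat > 90) || any(df$lon < -180 | df$lon > 180))
    stop("coordinates out of range", call. = FALSE)
  env_cols <- intersect(env_variables, names(df))
  for (col in env_cols)
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]])))
      stop("non-finite environmental values in column ", col, call. = FALSE)
  if (!is.null(table) && !setequal(rownames(table), df$sample_id))
    stop("sample_id set does not match the OTU table's samples", call. = FALSE)
  tibble::as_tibble(df)
}

#' Month-by-habitat analysis groups
#'
#' @param samples Sample frame.
#' @return Factor of `month-habitat` group labels, one per sample.
#' @export
analysis_groups <- function(samples) {
  factor(paste(samples$month, samples$habitat, sep = "-"))
}
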