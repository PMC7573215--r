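# Sloan neutral community model: predicted occurrence frequency as a
# function of source-pool relative abundance, least-squares estimation of
# the immigration rate m, goodness of fit, confidence band and per-OTU
# partition.

#' Predicted occurrence frequency under the neutral model
#'
#' Under neutral assembly with local community size `N` and immigration rate
#' `m`, an OTU with source-pool relative abundance `p` has local relative
#' abundance distributed Beta(Nmp, Nm(1-p)); the probability that it exceeds
#' the detection limit `d` — its expected occurrence frequency — is
#' `1 - I_d(Nmp, Nm(1-p))`, the upper tail of the regularized incomplete
#' beta function.
#'
#' @param p Mean relative abundance(s), in (0, 1).
#' @param N Reads per sample (community size).
#' @param m Immigration rate (> 0).
#' @param d Detection limit as a relative abundance, in (0, 1).
#' @return Predicted occurrence frequency in `[0, 1]`, same length as `p`.
#' @export
ncm_predict <- function(p, N, m, d) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (d <= 0 || d >= 1) stop("d must lie strictly in (0, 1)", call. = FALSE)
  if (N < 1) stop("N must be at least 1", call. = FALSE)
  if (m <= 0) stop("m must be positive", call. = FALSE)
  shape1 <- N * m * p
  shape2 <- N * m * (1 - p)
  bad <- !is.finite(shape1) | !is.finite(shape2) | shape1 <= 0 | shape2 <= 0
  if (any(bad))
    stop("degenerate beta parameters for OTU index ", which(bad)[1],
         call. = FALSE)
  stats::pbeta(d, shape1, shape2, lower.tail = FALSE)
}

#' Exact detection probability for a rarefied count table
#'
#' For count data the detection event is "at least one of the N reads",
#' not "relative abundance above a threshold". Integrating the binomial
#' zero class over the Beta(Nmp, Nm(1-p)) abundance distribution gives the
#' exact occurrence frequency
#' `1 - B(Nmp, Nm(1-p) + N) / B(Nmp, Nm(1-p))`
#' (the beta-binomial zero probability). This closes the loop with
#' Dirichlet-multinomial sampling, where the threshold approximation with
#' `d = 1/N` is biased upward.
#'
#' @inheritParams ncm_predict
#' @return Predicted occurrence frequency in `[0, 1]`.
#' @export
ncm_predict_discrete <- function(p, N, m) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (N < 1) stop("N must be at least 1", call. = FALSE)
  if (m <= 0) stop("m must be positive", call. = FALSE)
  a <- N * m * p
  b <- N * m * (1 - p)
  1 - exp(lbeta(a, b + N) - lbeta(a, b))
}

# Wilson score interval for a proportion phat with n trials
wilson_interval <- function(phat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  mid <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, mid - half), upper = pmin(1, mid + half))
}

#' Fit the Sloan neutral community model to an OTU table
#'
#' Estimates the immigration rate `m` by least squares on the relationship
#' between each OTU's occurrence frequency across samples and its mean
#' relative abundance, using a bounded one-dimensional search over (0, 1].
#' `R2 = 1 - SSE/SST` measures the fit and may be negative when the data do
#' not follow the neutral expectation.
#'
#' Two detection models are available for the predicted frequency:
#' `"betabinomial"` (default) uses the exact probability of drawing at
#' least one read at depth N ([ncm_predict_discrete()]), which is unbiased
#' for rarefied count tables; `"threshold"` uses the classical
#' relative-abundance detection limit `d` ([ncm_predict()]). A 95% Wilson score band around the
#' predicted frequency (with `n = n_samples`) partitions OTUs into those
#' occurring more often (`above`), consistently (`within`) or less often
#' (`below`) than predicted.
#'
#' @param table Rarefied OTU table: every row must sum to the same depth N.
#'   Tables whose depths vary slightly (e.g. after artifact filtering of a
#'   rarefied table) are accepted with `allow_unequal = TRUE`, which uses
#'   the mean depth as N and per-sample relative abundances.
#' @param d Detection limit; default `1/N`, one read at the rarefied depth.
#' @param conf Confidence level of the band.
#' @param allow_unequal Permit unequal row depths (N = rounded mean).
#' @param detection `"betabinomial"` (exact, default) or `"threshold"`
#'   (classical detection limit `d`).
#' @return An `ncm_fit` list: `m`, `N`, `Nm`, `d`, `R2`, `n_samples`,
#'   `n_otus`, per-OTU tibble `otus` (`p`, `freq`, `freq_pred`, `lower`,
#'   `upper`, `partition`), and flags `boundary` (optimizer at a bound) and
#'   `undefined` (zero frequency variance, R2 undefined).
#' @export
fit_ncm <- function(table, d = NULL, conf = 0.95, allow_unequal = FALSE,
                    detection = c("betabinomial", "threshold")) {
  detection <- match.arg(detection)
  depths <- rowSums(table)
  if (length(unique(depths)) != 1 && !allow_unequal)
    stop("all samples must be rarefied to a common depth before fitting ",
         "(or set allow_unequal = TRUE to use the mean depth)",
         call. = FALSE)
  N <- round(mean(depths))
  if (is.null(d)) d <- 1 / N
  n_samples <- nrow(table)
  p <- colMeans(table / depths)
  f <- colMeans(table > 0)
  keep <- p > 0 & p < 1
  p <- p[keep]; f <- f[keep]
  ids <- colnames(table)[keep]
  if (length(p) < 10)
    stop("fewer than 10 OTUs with non-degenerate abundance; cannot fit",
         call. = FALSE)
  predict_f <- if (detection == "betabinomial")
    function(m) ncm_predict_discrete(p, N, m)
  else function(m) ncm_predict(p, N, m, d)
  sse <- function(m) sum((f - predict_f(m))^2)
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-9)
  m_hat <- opt$minimum
  boundary <- m_hat < 1e-5 || m_hat > 1 - 1e-5
  if (boundary)
    warning("estimated m lies at the boundary of (0, 1]; fit may be degraded")
  F_hat <- predict_f(m_hat)
  sst <- sum((f - mean(f))^2)
  undefined <- sst == 0
  if (undefined) warning("zero variance in occurrence frequencies; R2 undefined")
  R2 <- if (undefined) NA_real_ else 1 - opt$objective / sst
  ci <- wilson_interval(F_hat, n_samples, conf)
  partition <- ifelse(f > ci[, "upper"], "above",
               ifelse(f < ci[, "lower"], "below", "within"))
  structure(list(
    m = m_hat, N = N, Nm = N * m_hat, d = d, R2 = R2,
    n_samples = n_samples, n_otus = length(p),
    otus = tibble::tibble(otu_id = ids, p = unname(p), freq = unname(f),
                          freq_pred = unname(F_hat),
                          lower = unname(ci[, "lower"]),
                          upper = unname(ci[, "upper"]),
                          partition = unname(partition)),
    boundary = boundary, undefined = undefined
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: %d OTUs, %d samples\n",
              x$n_otus, x$n_samples))
  cat(sprintf("  m = %.4f, Nm = %.1f, R2 = %s\n", x$m, x$Nm,
              if (is.na(x$R2)) "undefined" else sprintf("%.3f", x$R2)))
  tab <- table(x$otus$partition)
  cat("  partition:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Compare several neutral-model fits
#'
#' @param fits List of `ncm_fit` objects.
#' @param labels One label per fit.
#' @return Tibble: label, m, Nm, R2, n_otus and the percentage of OTUs
#'   above/within/below the confidence band (summing to 100).
#' @export
compare_fits <- function(fits, labels = names(fits)) {
  if (length(fits) < 2) stop("at least 2 fits are required", call. = FALSE)
  if (is.null(labels)) labels <- paste0("fit", seq_along(fits))
  rows <- Map(function(fit, lab) {
    part <- fit$otus$partition
    tibble::tibble(label = lab, m = fit$m, Nm = fit$Nm, R2 = fit$R2,
                   n_otus = fit$n_otus,
                   pct_above = 100 * mean(part == "above"),
                   pct_within = 100 * mean(part == "within"),
                   pct_below = 100 * mean(part == "below"))
  }, fits, labels)
  do.call(rbind, rows)
}
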