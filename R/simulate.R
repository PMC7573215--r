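# Synthetic community generator emulating the study design: a lognormal
# source pool sampled into 60 local communities (10 sites x 2 layers x 3
# months) under either neutral (Dirichlet-multinomial) or niche
# (Gaussian-response) assembly, with a coast/shelf environmental contrast.

#' Describe the sampling design of a simulated study
#'
#' Defaults reproduce the study layout: 10 sites (5 coastal, 5 on the
#' continental shelf) spanning roughly 27.6-32.8 N and 122-127 E, sampled at
#' surface and bottom layers in three months, at 1,172 reads per sample.
#'
#' @param n_sites Number of sites (split coast/shelf by `n_coast`).
#' @param n_coast Number of coastal sites among the first sites.
#' @param months,layers Factor levels of the temporal and vertical design.
#' @param reads_per_sample Sequencing depth after rarefaction.
#' @return A `study_design` list with per-site coordinates, depths and
#'   habitat labels.
#' @export
study_design <- function(n_sites = 10, n_coast = 5,
                         months = c("May", "Aug", "Oct"),
                         layers = c("S", "B"),
                         reads_per_sample = 1172) {
  if (n_coast > n_sites) stop("n_coast cannot exceed n_sites", call. = FALSE)
  # fixed transect-like coordinates inside the study box (27.6-32.8N, 122-127E)
  frac <- if (n_sites > 1) (seq_len(n_sites) - 1) / (n_sites - 1) else 0.5
  habitat <- rep(c("coast", "shelf"), c(n_coast, n_sites - n_coast))
  lon <- ifelse(habitat == "coast", 122.2 + 1.2 * frac, 124.5 + 2.4 * frac)
  lat <- 32.6 - 4.8 * frac
  depth <- ifelse(habitat == "coast",
                  20 + 25 * frac,    # < 50 m
                  58 + 50 * frac)    # 50-110 m
  structure(list(
    sites = sprintf("S%02d", seq_len(n_sites)),
    habitat = habitat, lon = lon, lat = lat, depth = depth,
    months = months, layers = layers,
    reads_per_sample = reads_per_sample
  ), class = "study_design")
}

#' Draw a lognormal metacommunity (source pool)
#'
#' Relative source-pool abundances from a lognormal species-abundance
#' distribution: `p` proportional to `exp(Normal(0, sigma^2))`, normalized.
#'
#' @param S Number of OTUs (>= 2).
#' @param sigma Lognormal shape; larger values give steeper rank-abundance
#'   curves.
#' @param seed Integer seed.
#' @return List with `otu_ids` and `p` (sums to 1).
#' @export
lognormal_metacommunity <- function(S, sigma = 2, seed = NULL) {
  if (S < 2) stop("S must be at least 2", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  p <- with_seed(seed, exp(stats::rnorm(S, 0, sigma)))
  list(otu_ids = sprintf("Otu%04d", seq_len(S)), p = p / sum(p))
}

#' Simulate local communities under neutral assembly
#'
#' Dirichlet-multinomial sampling: each local community's composition is a
#' Dirichlet draw with concentration `reads * m * p`, then counts are a
#' multinomial draw at depth `reads`. The marginal per-OTU relative
#' abundance is Beta(Nmp, Nm(1-p)) — exactly the distribution the Sloan
#' neutral-model fit assumes, so parameter recovery is well-posed.
#'
#' @param meta Metacommunity from [lognormal_metacommunity()].
#' @param n_samples Number of local communities.
#' @param reads Depth per sample (N).
#' @param m Immigration rate in (0, 1].
#' @param seed Integer seed.
#' @return OTU table (`n_samples` x S), every row summing to `reads`.
#' @export
simulate_neutral_samples <- function(meta, n_samples, reads, m, seed = NULL) {
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]", call. = FALSE)
  alpha <- reads * m * meta$p
  S <- length(alpha)
  with_seed(seed, {
    counts <- matrix(0L, n_samples, S,
                     dimnames = list(sprintf("sample%03d", seq_len(n_samples)),
                                     meta$otu_ids))
    for (i in seq_len(n_samples)) {
      g <- stats::rgamma(S, shape = alpha)
      if (sum(g) == 0) g <- meta$p   # degenerate-concentration fallback
      counts[i, ] <- stats::rmultinom(1, reads, g / sum(g))
    }
    counts
  })
}

#' Simulate local communities under niche (environmental-filtering) assembly
#'
#' Gaussian response: sampling weights `w_ij` proportional to
#' `p_j * exp(-(env_i - optimum_j)^2 / (2 tolerance^2))`, row-normalized,
#' with multinomial counts at depth `reads`. As `tolerance` grows the model
#' reduces to plain multinomial sampling from the source pool.
#'
#' @param meta Metacommunity.
#' @param env Per-sample environmental value (one gradient).
#' @param optima Per-OTU environmental optimum.
#' @param tolerance Common niche breadth (> 0), in `env` units.
#' @param reads Depth per sample.
#' @param seed Integer seed.
#' @return OTU table (length(env) x S).
#' @export
simulate_niche_samples <- function(meta, env, optima, tolerance, reads,
                                   seed = NULL) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (length(optima) != length(meta$p))
    stop("one optimum per OTU is required", call. = FALSE)
  n <- length(env)
  with_seed(seed, {
    counts <- matrix(0L, n, length(meta$p),
                     dimnames = list(sprintf("sample%03d", seq_len(n)),
                                     meta$otu_ids))
    for (i in seq_len(n)) {
      w <- meta$p * exp(-(env[i] - optima)^2 / (2 * tolerance^2))
      if (sum(w) == 0) w <- meta$p
      counts[i, ] <- stats::rmultinom(1, reads, w / sum(w))
    }
    counts
  })
}

# Environmental table for a study design: one dominant temperature-like
# seasonal gradient whose amplitude is larger on the coast (riverine plume)
# than on the shelf, a negatively correlated salinity, and coast-enriched
# nutrients/chlorophyll/picoplankton with multiplicative noise.
build_env_table <- function(design, month, habitat, layer) {
  n <- length(month)
  coast <- habitat == "coast"
  temp_mean <- ifelse(coast,
                      c(May = 18, Aug = 28, Oct = 21)[month],
                      c(May = 21, Aug = 26, Oct = 23)[month])
  temp <- temp_mean - 0.8 * (layer == "B") + stats::rnorm(n, 0, 0.5)
  sal_mean <- ifelse(coast,
                     c(May = 30, Aug = 27, Oct = 31)[month],
                     34)
  sal <- sal_mean + 0.3 * (layer == "B") + stats::rnorm(n, 0, 0.4)
  do <- 10 - 0.15 * temp + stats::rnorm(n, 0, 0.3)
  lnoise <- function(sd = 0.3) exp(stats::rnorm(n, 0, sd))
  nut <- function(coast_mean, shelf_mean)
    ifelse(coast, coast_mean, shelf_mean) * lnoise()
  data.frame(
    Temp = temp, Sal = sal, DO = do,
    NH4_N = nut(2.5, 0.6), NO3_N = nut(12, 3), NO2_N = nut(0.8, 0.2),
    DIP = nut(0.9, 0.2), Chl_a = nut(2.0, 0.5),
    Syn = nut(1.2e4, 6e3) * (1 + 0.05 * (temp - 22)),
    PEUK = nut(8e3, 4e3),
    HB = nut(9e5, 5e5)
  )
}

#' Generate a full synthetic study fixture
#'
#' Builds the 60-sample design (sites x layers x months under the default
#' [study_design()]), an environmental table with month and habitat main
#' effects (coastal months differ more than shelf months), and an OTU table
#' from the chosen generative mode. Ground-truth parameters are returned in
#' `$truth` for provenance.
#'
#' The niche mode uses the (noise-free) seasonal temperature signal as the
#' single filtering gradient, with OTU optima spread uniformly over its
#' range; small `tolerance` produces strong compositional turnover between
#' months, strongest on the coast where the seasonal amplitude is largest.
#'
#' @param design A [study_design()].
#' @param mode `"neutral"`, `"niche"`, or `"mixed"` (Dirichlet draw filtered
#'   by Gaussian response before multinomial sampling).
#' @param m Immigration rate for the neutral component.
#' @param S,sigma Metacommunity richness and lognormal shape.
#' @param tolerance Niche breadth (degC) for the niche component.
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @return List with `table` (OTU counts), `samples` (sample frame with
#'   environmental columns) and `truth` (generator parameters).
#' @export
generate_study_fixture <- function(design = study_design(),
                                   mode = c("neutral", "niche", "mixed"),
                                   m = 0.1, S = 1000, sigma = 2,
                                   tolerance = 1.5, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    meta <- lognormal_metacommunity(S, sigma)
    grid <- expand.grid(site = seq_along(design$sites),
                        layer = design$layers, month = design$months,
                        stringsAsFactors = FALSE)
    month <- as.character(grid$month)
    layer <- as.character(grid$layer)
    habitat <- design$habitat[grid$site]
    sample_id <- sprintf("%s%s%s", substr(month, 1, 1),
                         design$sites[grid$site], layer)
    env <- build_env_table(design, month, habitat, layer)
    n <- nrow(grid)
    reads <- design$reads_per_sample

    # noise-free filtering gradient: seasonal temperature signal
    temp_signal <- ifelse(habitat == "coast",
                          c(May = 18, Aug = 28, Oct = 21)[month],
                          c(May = 21, Aug = 26, Oct = 23)[month])
    optima <- stats::runif(S, min(temp_signal) - 1, max(temp_signal) + 1)

    counts <- matrix(0L, n, S, dimnames = list(sample_id, meta$otu_ids))
    alpha <- reads * m * meta$p
    for (i in seq_len(n)) {
      w <- switch(mode,
        neutral = {
          g <- stats::rgamma(S, shape = alpha)
          if (sum(g) == 0) meta$p else g
        },
        niche = meta$p *
          exp(-(temp_signal[i] - optima)^2 / (2 * tolerance^2)),
        mixed = {
          g <- stats::rgamma(S, shape = alpha)
          if (sum(g) == 0) g <- meta$p
          g * exp(-(temp_signal[i] - optima)^2 / (2 * tolerance^2))
        })
      if (sum(w) == 0) w <- meta$p
      counts[i, ] <- stats::rmultinom(1, reads, w / sum(w))
    }

    samples <- sample_frame(cbind(
      data.frame(sample_id = sample_id, month = month, habitat = habitat,
                 layer = layer,
                 lon = design$lon[grid$site], lat = design$lat[grid$site],
                 depth = design$depth[grid$site] - 3 * (layer == "S"),
                 stringsAsFactors = FALSE),
      env), table = counts,
      months = design$months, layers = design$layers)

    list(table = counts, samples = samples,
         truth = list(mode = mode, m = m, S = S, sigma = sigma,
                      tolerance = tolerance, seed = seed,
                      reads_per_sample = reads))
  })
}
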