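# Config-driven orchestration of the full analysis surface on real or
# synthetic inputs, with a manifest that replays every numeric output
# exactly.

#' Build a run configuration
#'
#' Either `shared_path` + `samples_path` (real inputs) or `simulation`
#' (a list of [generate_study_fixture()] arguments) must be provided.
#' Groups for the group-wise analyses are month-by-habitat by default.
#'
#' @param simulation List of arguments for [generate_study_fixture()]
#'   (e.g. `list(mode = "neutral", m = 0.1, seed = 1)`), or `NULL`.
#' @param shared_path,samples_path Paths to a `.shared` OTU table and a
#'   sample metadata TSV, or `NULL`.
#' @param depth Rarefaction depth; `NULL` uses the minimum library size.
#' @param rare_cut,abund_cut Classification thresholds.
#' @param n_perm Permutations for ANOSIM/Mantel/PROTEST.
#' @param seed Master seed for every stochastic stage.
#' @param stages Character vector of stages to run, a subset of the default.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, shared_path = NULL,
                       samples_path = NULL, depth = NULL,
                       rare_cut = 0.001, abund_cut = 0.01,
                       n_perm = 999, seed = 1,
                       stages = c("classify", "diversity", "ordination",
                                  "anosim", "mantel", "procrustes", "ncm",
                                  "network")) {
  if (is.null(simulation) && (is.null(shared_path) || is.null(samples_path)))
    stop("provide either a simulation spec or input paths", call. = FALSE)
  structure(list(simulation = simulation, shared_path = shared_path,
                 samples_path = samples_path, depth = depth,
                 rare_cut = rare_cut, abund_cut = abund_cut,
                 n_perm = n_perm, seed = seed, stages = stages),
            class = "run_config")
}

write_stage_tsv <- function(df, outdir, name, params) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(path, params)
  path
}

# pairwise ANOSIM comparisons emulating the study's table layout
anosim_comparisons <- function(samples) {
  g <- list()
  months <- levels(samples$month)
  add <- function(name, sel1, sel2) g[[name]] <<- list(a = sel1, b = sel2)
  for (i in seq_along(months)) for (j in seq_along(months)) if (i < j) {
    m1 <- months[i]; m2 <- months[j]
    add(paste0(m1, " vs ", m2),
        samples$month == m1, samples$month == m2)
    for (h in levels(samples$habitat))
      add(sprintf("%s_%s vs %s_%s", m1, h, m2, h),
          samples$month == m1 & samples$habitat == h,
          samples$month == m2 & samples$habitat == h)
  }
  add("coast vs shelf", samples$habitat == "coast", samples$habitat == "shelf")
  add("B vs S", samples$layer == "B", samples$layer == "S")
  g
}

#' Run the full analysis workflow
#'
#' Generates or loads the inputs, rarefies and filters the OTU table, and
#' runs the configured stages, writing one TSV per output (with provenance
#' sidecars) plus a `manifest.json` from which the run can be replayed
#' bit-identically via [replay_run()]. A failing non-blocking stage is
#' logged into `errors.tsv` and skipped.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  prov <- list(seed = seed, n_perm = config$n_perm,
               rare_cut = config$rare_cut, abund_cut = config$abund_cut)

  if (!is.null(config$simulation)) {
    fix <- do.call(generate_study_fixture, config$simulation)
    table <- fix$table
    samples <- fix$samples
  } else {
    table <- read_otu_table(config$shared_path, format = "shared")
    samples <- sample_frame(utils::read.table(config$samples_path,
                                              header = TRUE, sep = "\t",
                                              stringsAsFactors = FALSE),
                            table = table)
  }
  samples <- samples[match(rownames(table), samples$sample_id), ]

  depth <- if (is.null(config$depth)) min(rowSums(table)) else config$depth
  table <- rarefy(table, depth, seed = seed, drop_small = TRUE)
  table <- filter_artifacts(table)
  table <- prune_empty(table, quiet = TRUE)
  samples <- samples[samples$sample_id %in% rownames(table), ]
  rel <- to_relative(table)
  groups <- analysis_groups(samples)

  errors <- list()
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message(sprintf("stage '%s' failed and was skipped: %s", name,
                      conditionMessage(e)))
      NULL
    })
  }

  run_stage("classify", {
    cls <- classify_otus(rel, config$rare_cut, config$abund_cut)
    write_stage_tsv(cls, outdir, "classification", prov)
    write_stage_tsv(category_summary(cls, table), outdir,
                    "classification_summary", prov)
  })

  run_stage("diversity", {
    write_stage_tsv(alpha_diversity(table), outdir, "alpha_diversity", prov)
    sac <- species_accumulation(table, n_perm = 100, seed = seed)
    write_stage_tsv(sac, outdir, "species_accumulation", prov)
  })

  run_stage("ordination", {
    bc <- bray_curtis(hellinger(table))
    fit <- nmds(bc, seed = seed)
    df <- data.frame(sample_id = rownames(fit$scores), fit$scores,
                     stress = fit$stress)
    write_stage_tsv(df, outdir, "nmds_scores", prov)
  })

  run_stage("anosim", {
    bc <- bray_curtis(table)
    comps <- anosim_comparisons(samples)
    rows <- lapply(names(comps), function(nm) {
      sel <- comps[[nm]]$a | comps[[nm]]$b
      if (sum(comps[[nm]]$a) < 2 || sum(comps[[nm]]$b) < 2) return(NULL)
      res <- anosim(bc[sel, sel],
                    ifelse(comps[[nm]]$a[sel], "a", "b"),
                    n_perm = config$n_perm, seed = seed)
      data.frame(comparison = nm, R = res$statistic, p = res$p)
    })
    write_stage_tsv(do.call(rbind, rows), outdir, "anosim", prov)
  })

  env_cols <- intersect(env_variables, names(samples))
  run_stage("mantel", {
    rows <- lapply(levels(groups), function(g) {
      sel <- groups == g
      if (sum(sel) < 5) return(NULL)
      bc <- bray_curtis(table[sel, , drop = FALSE])
      de <- env_distance(as.matrix(samples[sel, env_cols]))
      dg <- haversine_matrix(samples$lon[sel], samples$lat[sel])
      dimnames(de) <- dimnames(bc); dimnames(dg) <- dimnames(bc)
      me <- mantel(bc, de, n_perm = config$n_perm, seed = seed)
      mg <- mantel(bc, dg, n_perm = config$n_perm, seed = seed)
      data.frame(group = g,
                 r_env = me$statistic, p_env = me$p,
                 r_geo = mg$statistic, p_geo = mg$p)
    })
    write_stage_tsv(do.call(rbind, rows), outdir, "mantel", prov)
  })

  run_stage("procrustes", {
    bc <- bray_curtis(table)
    comm <- pcoa(bc)$scores
    envs <- pca(sqrt(as.matrix(samples[, env_cols])), scale. = TRUE)$scores
    pr <- procrustes(envs, comm, symmetric = TRUE)
    pt <- protest(envs, comm, n_perm = config$n_perm, seed = seed)
    df <- data.frame(M2 = pr$M2, statistic = pt$statistic, p = pt$p,
                     mean_residual = mean(pr$residuals))
    write_stage_tsv(df, outdir, "procrustes", prov)
  })

  run_stage("ncm", {
    fits <- list(); labels <- character(0)
    for (h in levels(samples$habitat)) {
      sel <- samples$habitat == h
      sub <- prune_empty(table[sel, , drop = FALSE], quiet = TRUE)
      fits[[length(fits) + 1]] <- fit_ncm(sub, allow_unequal = TRUE)
      labels <- c(labels, h)
    }
    all_fit <- fit_ncm(table, allow_unequal = TRUE)
    fits[[length(fits) + 1]] <- all_fit
    labels <- c(labels, "all")
    write_stage_tsv(compare_fits(fits, labels), outdir, "ncm_summary", prov)
    write_stage_tsv(all_fit$otus, outdir, "ncm_otus", prov)
  })

  run_stage("network", {
    rows <- lapply(c("all", levels(groups)), function(g) {
      sel <- if (g == "all") rep(TRUE, nrow(table)) else groups == g
      if (sum(sel) < 4) return(NULL)
      sub <- prune_empty(table[sel, , drop = FALSE], quiet = TRUE)
      minp <- max(3, ceiling(sum(sel) / 5))
      cors <- correlation_screen(sub, min_prevalence = minp, seed = seed)
      cors$q <- storey_qvalues(cors$p)
      net <- suppressWarnings(build_network(cors))
      if (igraph::ecount(net) == 0) return(NULL)
      cbind(group = g, as.data.frame(topology(net, seed = seed)))
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) write_stage_tsv(out, outdir, "network_metrics", prov)
  })

  if (length(errors))
    utils::write.table(
      data.frame(stage = names(errors), error = unlist(errors)),
      file.path(outdir, "errors.tsv"), sep = "\t", row.names = FALSE)

  manifest <- list(config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("otuassembly")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(outdir)
}

#' Replay a pipeline run from its manifest
#'
#' Reads `manifest.json` from a previous run and re-executes the pipeline
#' with the identical configuration; all numeric outputs are reproduced
#' exactly.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param outdir Output directory for the replay.
#' @return `outdir`, invisibly.
#' @export
replay_run <- function(manifest_path, outdir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  sim <- if (is.null(cfg$simulation)) NULL else as.list(cfg$simulation)
  config <- run_config(simulation = sim,
                       shared_path = cfg$shared_path,
                       samples_path = cfg$samples_path,
                       depth = cfg$depth,
                       rare_cut = cfg$rare_cut, abund_cut = cfg$abund_cut,
                       n_perm = cfg$n_perm, seed = cfg$seed,
                       stages = cfg$stages)
  run_pipeline(config, outdir)
}
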