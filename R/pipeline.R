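#' Default pipeline configuration
#'
#' @return Named list of every pipeline parameter with its validated
#'   default. Fields: input paths (`x1`, `x2`) or simulation settings
#'   (`simulate`, a list with `n`, `p`, `q`, `sigma_noise`,
#'   `frac_correlated`), hypergraph neighbour sizes `k1`/`k2`,
#'   regularization weights `lambda1`/`lambda2` (`NULL` triggers grid
#'   selection over `lambda_grid`), `rank` (`"auto"` applies
#'   [suggest_rank()]), module `threshold` and `min_size`, network
#'   `pcc_threshold` (`"mean"` uses the mean off-diagonal association),
#'   `top`, `seed`, `max_iter`, `tol`, `out_dir`.
#' @export
default_config <- function() {
  list(x1 = NULL, x2 = NULL,
       simulate = NULL,
       k1 = 5L, k2 = 5L,
       lambda1 = NULL, lambda2 = NULL,
       lambda_grid = c(0.0001, 0.001, 0.01, 0.1),
       rank = "auto",
       threshold = 1, min_size = 5,
       pcc_threshold = 0.9, top = 10L,
       seed = 1L, max_iter = 500L, tol = 1e-6,
       out_dir = "hgnetnmf_run")
}

#' Run the full module-discovery pipeline
#'
#' Orchestrates the stages end to end: load (or simulate) the paired
#' matrices, build absolute-Pearson association networks and KNN feature
#' hypergraphs, select regularization weights on the grid when none are
#' given, fit the tri-factorization, extract filtered paired modules, build
#' thresholded interaction networks inside the significant module, and rank
#' hubs by maximal clique centrality. All artifacts are written to
#' `config$out_dir` as labelled TSV plus a `metrics.json` and a plain-text
#' run log recording the seed and every parameter.
#'
#' @param config Named list overriding fields of [default_config()], or a
#'   path to a YAML/JSON file with those fields.
#' @return Invisibly, a list with the fitted model, networks, module set,
#'   hub rankings and the resolved configuration.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                                append = TRUE)
  cat(sprintf("hgnetnmf %s run, seed %d\n",
              as.character(utils::packageVersion("hgnetnmf")), cfg$seed),
      file = log_path)
  for (nm in setdiff(names(cfg), c("x1", "x2", "simulate")))
    log_line("  %s = %s", nm, paste(format(cfg[[nm]]), collapse = ", "))

  # --- inputs ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- modifyList(list(seed = cfg$seed), cfg$simulate)
    sim <- do.call(simulate_paired_data, sim_args)
    X1 <- sim$X; X2 <- sim$Y
    log_line("stage simulate: n=%d p=%d q=%d sigma=%g", nrow(X1), ncol(X1),
             ncol(X2), sim$truth$sigma_noise)
  } else if (!is.null(cfg$x1) && !is.null(cfg$x2)) {
    X1 <- read_matrix(cfg$x1)
    X2 <- read_matrix(cfg$x2)
    log_line("stage load: %s (%d x %d), %s (%d x %d)", cfg$x1, nrow(X1),
             ncol(X1), cfg$x2, nrow(X2), ncol(X2))
  } else stop("config must provide either 'x1'/'x2' paths or 'simulate' settings")

  # --- networks and hypergraphs --------------------------------------------
  nets <- association_networks(X1, X2)
  write_matrix(nets$R11, file.path(cfg$out_dir, "R11.tsv"))
  write_matrix(nets$R22, file.path(cfg$out_dir, "R22.tsv"))
  write_matrix(nets$R12, file.path(cfg$out_dir, "R12.tsv"))
  hg1 <- feature_hypergraph(X1, cfg$k1)
  hg2 <- feature_hypergraph(X2, cfg$k2)
  log_line("stage networks: built R11/R22/R12 and hypergraphs (k1=%d, k2=%d)",
           cfg$k1, cfg$k2)

  rank <- if (identical(cfg$rank, "auto"))
    suggest_rank(nrow(X1), ncol(X1), ncol(X2)) else as.integer(cfg$rank)

  # --- lambda selection -----------------------------------------------------
  if (is.null(cfg$lambda1) || is.null(cfg$lambda2)) {
    sel <- select_lambdas(nets, hg1, hg2, lambda_grid = cfg$lambda_grid,
                          rank = rank, seed = cfg$seed,
                          max_iter = cfg$max_iter, tol = cfg$tol)
    utils::write.table(sel$grid, file.path(cfg$out_dir, "lambda_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg$lambda1 <- sel$best$lambda1
    cfg$lambda2 <- sel$best$lambda2
    log_line("stage select: lambda grid -> (%g, %g)", cfg$lambda1, cfg$lambda2)
  }

  # --- fit ------------------------------------------------------------------
  fit <- hgnetnmf(nets, rank = rank, lambda1 = cfg$lambda1,
                  lambda2 = cfg$lambda2, hg1 = hg1, hg2 = hg2,
                  seed = cfg$seed, max_iter = cfg$max_iter, tol = cfg$tol)
  write_matrix(fit$G1, file.path(cfg$out_dir, "G1.tsv"))
  write_matrix(fit$G2, file.path(cfg$out_dir, "G2.tsv"))
  write_matrix(fit$S11, file.path(cfg$out_dir, "S11.tsv"))
  write_matrix(fit$S22, file.path(cfg$out_dir, "S22.tsv"))
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trace) - 1L,
               objective = fit$objective_trace),
    file.path(cfg$out_dir, "trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rc <- reconstruction_correlations(fit, nets)
  metrics <- list(seed = cfg$seed, rank = rank,
                  lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                  objective = fit$objective_trace[length(fit$objective_trace)],
                  n_iter = fit$n_iter, converged = fit$converged,
                  relative_error = relative_error(fit, nets),
                  corr_r11 = unname(rc["r11"]), corr_r22 = unname(rc["r22"]),
                  corr_r12 = unname(rc["r12"]))
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("stage fit: rank=%d, %d iterations, relative error %.4f",
           rank, fit$n_iter, metrics$relative_error)

  # --- modules --------------------------------------------------------------
  mods <- extract_modules(fit, nets, threshold = cfg$threshold,
                          min_size = cfg$min_size)
  mod_rows <- do.call(rbind, lapply(seq_len(mods$k), function(j) {
    rbind(
      if (length(mods$roi_members[[j]]))
        data.frame(module = j, side = "roi", label = mods$roi_members[[j]],
                   z = mods$z_roi[mods$roi_members[[j]], j],
                   retained = mods$retained[j]),
      if (length(mods$gene_members[[j]]))
        data.frame(module = j, side = "gene", label = mods$gene_members[[j]],
                   z = mods$z_gene[mods$gene_members[[j]], j],
                   retained = mods$retained[j]))
  }))
  utils::write.table(mod_rows, file.path(cfg$out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("stage modules: %d of %d retained, significant = %s",
           sum(mods$retained), mods$k, format(mods$significant))

  # --- hub networks inside the significant module --------------------------
  hubs <- NULL
  if (!is.na(mods$significant)) {
    j <- mods$significant
    hubs <- list()
    for (side in c("roi", "gene")) {
      members <- if (side == "roi") mods$roi_members[[j]] else mods$gene_members[[j]]
      R <- if (side == "roi") nets$R11 else nets$R22
      Rsub <- R[members, members, drop = FALSE]
      thr <- if (identical(cfg$pcc_threshold, "mean"))
        mean(Rsub[upper.tri(Rsub)]) else cfg$pcc_threshold
      net <- threshold_network(Rsub, thr)
      sc <- mcc_hub_scores(net, top = cfg$top)
      hubs[[side]] <- sc
      utils::write.table(net$edges,
                         file.path(cfg$out_dir, sprintf("edges_%s.tsv", side)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sc$ranking,
                         file.path(cfg$out_dir, sprintf("hubs_%s.tsv", side)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("stage hubs (%s): threshold %.3g, %d edges, top hub %s",
               side, thr, nrow(net$edges),
               if (nrow(sc$ranking)) sc$ranking$node[1] else "<none>")
    }
  }

  invisible(list(config = cfg, nets = nets, fit = fit, modules = mods,
                 hubs = hubs))
}
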