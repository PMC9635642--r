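#' Fit one of the named multi-omics BLUP models
#'
#' Convenience wrapper that assembles the kernel set for a named model from
#' preprocessed genotype and transcript matrices and runs [gibbs_fit()]. For
#' GTCBLUP the ridge parameter `lambda = m sigma_e^2 / sigma_g^2` is taken
#' from the posterior-mean variances of a GBLUP fit of the same trait
#' (supplied via `gblup_fit` or fitted internally with the same chain
#' settings). If the GBLUP genomic variance is degenerate (posterior mean
#' below `1e-6` of the phenotypic variance) conditioning is skipped with a
#' warning, since lambda diverges and there is nothing to condition on.
#'
#' @param y Phenotype vector (`NA` = validation individuals).
#' @param Z Standardized genotypes ([center_standardize()] output).
#' @param W Standardized transcripts (required for all models but GBLUP).
#' @param model One of `"GBLUP"`, `"TBLUP"`, `"GTBLUP"`, `"GTIBLUP"`,
#'   `"GTCBLUP"`.
#' @param chain [chain_settings()].
#' @param R2_prior,df Prior hyperparameters (see [compute_prior_scales()]).
#' @param gblup_fit Optional previously fitted GBLUP `blup_fit` supplying the
#'   GTCBLUP lambda.
#' @return A `blup_fit` (with the kernels used attached as `$kernels`).
#' @export
fit_omics_blup <- function(y, Z, W = NULL,
                           model = c("GBLUP", "TBLUP", "GTBLUP", "GTIBLUP",
                                     "GTCBLUP"),
                           chain = chain_settings(), R2_prior = 0.5, df = 5,
                           gblup_fit = NULL) {
  model <- match.arg(model)
  Zv <- if (inherits(Z, "standardized_matrix")) Z$values else
    if (!is.null(Z)) as.matrix(Z) else NULL
  Wv <- if (inherits(W, "standardized_matrix")) W$values else
    if (!is.null(W)) as.matrix(W) else NULL
  if (model != "GBLUP" && is.null(Wv))
    stop("model ", model, " requires a transcript matrix")
  if (model != "TBLUP" && is.null(Zv))
    stop("model ", model, " requires a genotype matrix")

  kernels <- switch(model,
    GBLUP = list(g = build_genomic_kernel(Zv)),
    TBLUP = list(t = build_transcript_kernel(Wv)),
    GTBLUP = list(g = build_genomic_kernel(Zv),
                  t = build_transcript_kernel(Wv)),
    GTIBLUP = {
      g <- build_genomic_kernel(Zv); t_ <- build_transcript_kernel(Wv)
      list(g = g, t = t_, gt = build_interaction_kernel(g, t_))
    },
    GTCBLUP = {
      if (is.null(gblup_fit))
        gblup_fit <- fit_omics_blup(y, Zv, model = "GBLUP", chain = chain,
                                    R2_prior = R2_prior, df = df)
      s2 <- gblup_fit$posterior_mean$sigma2
      if (s2[["g"]] < 1e-6 * gblup_fit$sigma_p2) {
        warning("GBLUP genomic variance is degenerate; ",
                "skipping genotype conditioning of transcripts")
        Wc <- Wv
      } else {
        lambda <- compute_lambda(s2[["e"]], s2[["g"]], ncol(Zv))
        Wc <- condition_transcripts(Wv, Zv, lambda)
      }
      list(g = build_genomic_kernel(Zv),
           tc = build_conditioned_kernel(Wc, ncol(Wv)))
    })
  fit <- gibbs_fit(y, kernels, chain = chain, R2_prior = R2_prior, df = df)
  fit$kernels <- kernels
  fit
}

#' Serialize a fit summary to JSON
#'
#' Writes posterior means and SDs, the variance partition, chain settings and
#' seed — everything needed to report a fit without the raw draws.
#'
#' @param fit A `blup_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  vp <- variance_partition(fit)
  out <- list(
    model = fit$model_name,
    n_individuals = length(fit$ids),
    n_unobserved = length(fit$missing_ids),
    posterior_mean = list(mu = fit$posterior_mean$mu,
                          sigma2 = as.list(fit$posterior_mean$sigma2)),
    posterior_sd = list(mu = fit$posterior_sd$mu,
                        sigma2 = as.list(fit$posterior_sd$sigma2)),
    variance_partition = list(mean = as.list(stats::setNames(vp$mean, rownames(vp))),
                              sd = as.list(stats::setNames(vp$sd, rownames(vp)))),
    chain = fit$chain[c("n_iter", "burn_in", "thin", "seed", "retained")],
    priors = list(df = fit$priors$df_component,
                  R2_prior = fit$priors$R2_prior,
                  S_component = as.list(fit$priors$S_component),
                  S_residual = fit$priors$S_residual),
    package_version = as.character(utils::packageVersion("omicsblup")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read/write a phenotype table
#'
#' TSV with columns `id`, `y` and optionally `generation`.
#'
#' @param path File path.
#' @return List with `y` (named numeric, `NA` allowed) and `generations`
#'   (named character or `NULL`).
#' @export
read_phenotype <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("id", "y") %in% names(dt)))
    stop("phenotype table needs columns 'id' and 'y': ", path)
  y <- stats::setNames(as.numeric(dt$y), as.character(dt$id))
  gens <- if ("generation" %in% names(dt))
    stats::setNames(as.character(dt$generation), as.character(dt$id))
  else NULL
  list(y = y, generations = gens)
}

#' @rdname read_phenotype
#' @param y Named phenotype vector.
#' @param generations Optional named generation labels.
#' @export
write_phenotype <- function(y, path, generations = NULL) {
  df <- data.frame(id = names(y), y = as.numeric(y))
  if (!is.null(generations)) df$generation <- generations[names(y)]
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

pipeline_schema <- list(
  top = c("seed", "out_dir", "model", "simulate", "inputs", "qc", "chain",
          "split", "evaluate", "R2_prior", "df"),
  simulate = c("n_individuals", "n_markers", "n_genes", "maf_range",
               "ld_autocorr", "h2_direct", "t2_mediated", "prop_cis", "gt2",
               "coupling", "n_cis_per_gene", "generation_sizes"),
  inputs = c("genotypes", "transcripts", "phenotype"),
  qc = c("maf_min", "call_rate_min", "corr_max"),
  chain = c("n_iter", "burn_in", "thin"),
  split = c("validation_generation"),
  evaluate = c("n_boot"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration for [run_pipeline()]. Unknown keys are errors
#' (fail-fast reproducibility). All randomness flows from the single
#' top-level `seed`: the simulator uses `seed`, the Gibbs chain `seed + 1`,
#' and the bootstrap `seed + 2`.
#'
#' @param path YAML file path, or a list already parsed.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  if (!is.list(path) && (length(path) != 1 || !nzchar(path) ||
                         !file.exists(path)))
    stop("config file not found: '", paste(path, collapse = ", "), "'")
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  check_keys(cfg, pipeline_schema$top, "top level")
  for (sec in c("simulate", "inputs", "qc", "chain", "split", "evaluate"))
    if (!is.null(cfg[[sec]]))
      check_keys(cfg[[sec]], pipeline_schema[[sec]], sec)
  if (is.null(cfg$model)) stop("config requires 'model'")
  if (!cfg$model %in% c("GBLUP", "TBLUP", "GTBLUP", "GTIBLUP", "GTCBLUP"))
    stop("unknown model name: ", cfg$model)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either 'simulate' or 'inputs'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) stop("config requires 'out_dir'")
  cfg
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # hash identifies the analysis, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the simulate -> kernel -> fit -> evaluate pipeline
#'
#' Executes the full workflow from a validated configuration and writes all
#' artifacts (study matrices when simulating, fit and evaluation JSON, run
#' log) under `out_dir`. Inputs are never mutated; rerunning with the same
#' configuration reproduces every stochastic output bit-exactly.
#'
#' @param config Path to a YAML config or a list (see [read_run_config()]).
#' @return Invisibly, a list with the fit, evaluation result and output
#'   directory.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  logf <- file.path(cfg$out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("omicsblup %s run %s\nconfig md5 %s  seed %d\n",
              utils::packageVersion("omicsblup"),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), hash,
              as.integer(cfg$seed)),
      file = logf)

  # --- data stage -----------------------------------------------------------
  generations <- NULL
  if (!is.null(cfg$simulate)) {
    study <- stage("simulate", {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      simulate_study(sc)
    })
    X <- study$genotypes; Wraw <- study$transcripts
    y <- study$phenotype; generations <- study$generations
    stage("simulate", {
      write_matrix(X, file.path(cfg$out_dir, "genotypes.tsv"))
      write_matrix(Wraw, file.path(cfg$out_dir, "transcripts.tsv"))
      write_phenotype(y, file.path(cfg$out_dir, "phenotype.tsv"), generations)
      jsonlite::write_json(
        list(fractions = as.list(study$truth$fractions)),
        file.path(cfg$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    })
    logline("simulated study: n=%d m=%d k=%d", nrow(X), ncol(X), ncol(Wraw))
  } else {
    X <- stage("read", read_matrix(cfg$inputs$genotypes, kind = "genotype"))
    Wraw <- if (!is.null(cfg$inputs$transcripts))
      stage("read", read_matrix(cfg$inputs$transcripts, kind = "transcript"))
    ph <- stage("read", read_phenotype(cfg$inputs$phenotype))
    y <- ph$y; generations <- ph$generations
  }

  # --- kernel stage ---------------------------------------------------------
  qc_args <- cfg$qc %||% list()
  prep <- stage("kernel", {
    qc <- do.call(qc_filter_genotypes, c(list(X = X), qc_args))
    Z <- center_standardize(impute_mean(qc$matrix))
    W <- if (!is.null(Wraw)) center_standardize(rank_z_transform(Wraw))
    list(qc = qc, Z = Z, W = W)
  })
  logline("QC: %d -> %d markers (maf %d, call rate %d, corr %d)",
          prep$qc$report$n_input, prep$qc$report$n_retained,
          prep$qc$report$n_removed_maf, prep$qc$report$n_removed_callrate,
          prep$qc$report$n_removed_corr)

  # --- split / mask ---------------------------------------------------------
  split <- NULL
  y_fit <- y
  if (!is.null(cfg$split)) {
    split <- stage("split",
                   forward_split(generations, cfg$split$validation_generation))
    y_fit[split$validation_ids] <- NA
    logline("forward split: %d reference, %d validation (%s)",
            length(split$reference_ids), length(split$validation_ids),
            split$rule)
  }

  # --- fit stage ------------------------------------------------------------
  ch_args <- cfg$chain %||% list()
  chain <- do.call(chain_settings, c(ch_args, list(seed = cfg$seed + 1L)))
  fit <- stage("fit", fit_omics_blup(
    y_fit, prep$Z, prep$W, model = cfg$model, chain = chain,
    R2_prior = cfg$R2_prior %||% 0.5, df = cfg$df %||% 5))
  write_fit_json(fit, file.path(cfg$out_dir, "fit.json"))
  logline("fit %s: chain %d/%d/%d seed %d; priors df+2 convention, R2 %.2f split equally",
          fit$model_name, chain$n_iter, chain$burn_in, chain$thin,
          chain$seed, fit$priors$R2_prior)

  # --- evaluate stage -------------------------------------------------------
  ev <- NULL
  if (!is.null(split)) {
    n_boot <- cfg$evaluate$n_boot %||% 10000L
    ev <- stage("evaluate",
                evaluate_fit(fit, y, split, n_boot = n_boot,
                             seed = cfg$seed + 2L))
    ccs <- ev$component_correlations
    jsonlite::write_json(
      list(model = ev$model_name, accuracy = ev$accuracy,
           accuracy_se = as.numeric(ev$accuracy_se), rrmse = ev$rrmse,
           bias_slope = ev$bias_slope,
           model_r2_reference = ev$model_r2_reference,
           gebv_accuracy = ev$gebv_accuracy,
           n_validation = ev$n_validation,
           component_correlations = as.data.frame(ccs),
           config_md5 = hash, seed = cfg$seed),
      file.path(cfg$out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
    logline("evaluate: accuracy %.4f rrmse %.4f bias %.4f (bootstrap n=%d seed %d)",
            ev$accuracy, ev$rrmse, ev$bias_slope, n_boot, cfg$seed + 2L)
  }

  invisible(list(fit = fit, evaluation = ev, qc_report = prep$qc$report,
                 out_dir = cfg$out_dir, config_md5 = hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
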