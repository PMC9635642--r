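#' Simulation configuration
#'
#' Defines a desk-scale synthetic study with the statistical structure the
#' multi-omics BLUP models assume: SNP dosages with mild adjacent-marker
#' linkage disequilibrium, liver-style transcripts whose variance is partly
#' of genetic (cis) origin, and a pre-corrected phenotype
#' `y = g_direct + t_mediated + gt + e`. The defaults emulate the outbred
#' mouse design: 478 individuals in nonoverlapping generations 4/5/7/11 of
#' sizes 47/47/192/192, with a strongly redundant genome-transcriptome
#' structure (`prop_cis = 0.7`).
#'
#' @param n_individuals Number of individuals (default 478).
#' @param n_markers SNP markers (default 1000).
#' @param n_genes Transcripts (default 300).
#' @param maf_range Interval in `(0, 0.5]` from which per-marker minor allele
#'   frequencies are drawn uniformly (default `c(0.03, 0.5)` so the MAF < 0.05
#'   QC filter has markers to remove).
#' @param ld_autocorr Probability that an individual's dosage at a marker is
#'   copied from the previous marker (first-order Markov LD; default 0.3).
#' @param h2_direct Fraction of phenotypic variance from marker effects not
#'   mediated by transcripts (default 0.15).
#' @param t2_mediated Fraction of phenotypic variance carried by the
#'   transcript->phenotype path at full coupling (default 0.45).
#' @param prop_cis Fraction of each gene's (pre rank-Z) variance explained by
#'   genotypes — the redundancy strength (default 0.7).
#' @param gt2 Interaction variance fraction (default 0).
#' @param coupling Fraction in `[0, 1]` scaling the realized
#'   transcript-mediated variance to `coupling * t2_mediated`; models the
#'   time gap between phenotyping and transcript sampling (1 = phenotype
#'   measured at RNA sampling time; the default 0.5 reflects a trait recorded
#'   weeks before the tissue was sampled, as in the emulated design).
#' @param n_cis_per_gene Number of causal cis markers per gene (default 5).
#' @param litter_size Individuals per full-sib family (default 8); families
#'   are nested within generations.
#' @param family_fst Balding-Nichols differentiation between family allele
#'   frequencies. The default 1/3 makes the within-family dosage correlation
#'   `2 fst / (1 + fst) = 0.5`, the full-sib value, giving the genomic kernel
#'   the kinship block spectrum of a litter-structured outbred population.
#' @param n_expr_factors Number of latent co-expression factors shared across
#'   genes (default 10), mimicking the module structure of real
#'   transcriptomes.
#' @param expr_factor_share Fraction of each gene's nongenetic variance
#'   carried by the shared factors (default 0.5); the rest is idiosyncratic.
#' @param generation_sizes Named integer vector of generation label -> count;
#'   must sum to `n_individuals`.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 478L, n_markers = 1000L,
                       n_genes = 300L, maf_range = c(0.03, 0.5),
                       ld_autocorr = 0.3, h2_direct = 0.15,
                       t2_mediated = 0.45, prop_cis = 0.7, gt2 = 0,
                       coupling = 0.5, n_cis_per_gene = 5L,
                       litter_size = 8L, family_fst = 1/3,
                       n_expr_factors = 10L, expr_factor_share = 0.5,
                       generation_sizes = c(`4` = 47L, `5` = 47L,
                                            `7` = 192L, `11` = 192L),
                       seed = 1L) {
  generation_sizes <- unlist(generation_sizes)
  maf_range <- as.numeric(unlist(maf_range))
  fr <- c(h2_direct = h2_direct, t2_mediated = t2_mediated,
          prop_cis = prop_cis, gt2 = gt2, coupling = coupling)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (h2_direct + t2_mediated * coupling + gt2 > 1 + 1e-12)
    stop("h2_direct + t2_mediated * coupling + gt2 must be <= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (ld_autocorr < 0 || ld_autocorr >= 1) stop("ld_autocorr must be in [0, 1)")
  if (n_individuals < 2 || n_markers < 1 || n_genes < 1)
    stop("empty simulation configuration")
  if (sum(generation_sizes) != n_individuals)
    stop("generation_sizes must sum to n_individuals")
  if (litter_size < 1) stop("litter_size must be >= 1")
  if (family_fst < 0 || family_fst >= 1) stop("family_fst must be in [0, 1)")
  if (expr_factor_share < 0 || expr_factor_share > 1)
    stop("expr_factor_share must be in [0, 1]")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 n_genes = as.integer(n_genes), maf_range = maf_range,
                 ld_autocorr = ld_autocorr, h2_direct = h2_direct,
                 t2_mediated = t2_mediated, prop_cis = prop_cis, gt2 = gt2,
                 coupling = coupling,
                 n_cis_per_gene = as.integer(n_cis_per_gene),
                 litter_size = as.integer(litter_size),
                 family_fst = family_fst,
                 n_expr_factors = as.integer(n_expr_factors),
                 expr_factor_share = expr_factor_share,
                 generation_sizes = generation_sizes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# scale a vector to an exact target sample variance (0 target -> zero vector)
scale_to_var <- function(x, v) {
  if (v == 0) return(x * 0)
  s <- stats::sd(x)
  if (s == 0) stop("cannot scale a constant component to positive variance")
  (x - mean(x)) / s * sqrt(v)
}

#' Simulate SNP genotype dosages
#'
#' Dosages in \{0, 1, 2\} drawn binomially from allele frequencies. Two
#' features of the emulated outbred population are modelled. First, family
#' structure: individuals belong to litters of `litter_size` (nested within
#' generations) and each litter draws its own allele frequencies around the
#' population frequency from a Balding-Nichols beta distribution with
#' differentiation `family_fst`, so the genomic relationship matrix has the
#' kinship block spectrum of a litter-structured population. Second,
#' adjacent-marker LD via a first-order Markov copy rule: with probability
#' `ld_autocorr` an individual's dosage at marker j is copied from marker
#' j-1, otherwise drawn fresh — enough correlation structure to exercise the
#' sequential-correlation QC pruning. Population allele frequencies are
#' uniform on `maf_range`.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return An [omics_matrix()] of kind `"genotype"` with a `family`
#'   attribute giving each individual's litter index.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- cfg$n_individuals; m <- cfg$n_markers
    p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    fam <- rep(seq_len(ceiling(n / cfg$litter_size)),
               each = cfg$litter_size)[seq_len(n)]
    theta <- cfg$family_fst
    # per-family allele frequencies (Balding-Nichols); theta = 0 keeps the
    # population frequency exactly
    pfam <- if (theta > 0) {
      shp <- (1 - theta) / theta
      vapply(seq_len(max(fam)), function(f)
        stats::rbeta(m, p * shp, (1 - p) * shp), numeric(m))
    } else matrix(p, m, max(fam))
    X <- matrix(0, n, m)
    pmat <- t(pfam[, fam, drop = FALSE])  # n x m individual frequencies
    X[, 1] <- stats::rbinom(n, 2, pmat[, 1])
    if (m > 1) for (j in 2:m) {
      fresh <- stats::rbinom(n, 2, pmat[, j])
      copy <- stats::runif(n) < cfg$ld_autocorr
      X[, j] <- ifelse(copy, X[, j - 1], fresh)
    }
    dimnames(X) <- list(sprintf("ind_%03d", seq_len(n)),
                        sprintf("snp_%04d", seq_len(m)))
    out <- omics_matrix(X, kind = "genotype")
    attr(out, "family") <- fam
    out
  })
}

#' Simulate transcript levels with a genetic (cis) component
#'
#' Each gene is `w_j = Z beta_j + eps_j` with `n_cis_per_gene` causal markers
#' and the genetic share of the gene's variance scaled to `prop_cis` exactly
#' (empirical scaling), then rank-Z transformed across individuals to mirror
#' the expression preprocessing the models expect. The nongenetic part
#' `eps_j` is itself structured: a share `expr_factor_share` loads on
#' `n_expr_factors` latent co-expression factors shared across genes (the
#' module structure dominating real transcriptomes), the remainder is
#' idiosyncratic noise.
#'
#' @param Z Standardized genotypes (`standardized_matrix` or plain matrix).
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed + 1`).
#' @return A list: `transcripts` (rank-Z [omics_matrix()]), `genetic_values`
#'   (n x k matrix of the true genetic parts, pre rank-Z).
#' @export
simulate_transcripts <- function(Z, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  Zv <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  with_seed(seed, {
    n <- nrow(Zv); m <- ncol(Zv); k <- cfg$n_genes
    ncis <- min(cfg$n_cis_per_gene, m)
    # sparse effect matrix: each gene gets ncis causal markers
    B <- matrix(0, m, k)
    for (j in seq_len(k))
      B[sample.int(m, ncis), j] <- stats::rnorm(ncis)
    Gval <- Zv %*% B
    q <- cfg$n_expr_factors
    Fac <- matrix(stats::rnorm(n * q), n, q)
    L <- matrix(stats::rnorm(q * k), q, k)
    v_fac <- (1 - cfg$prop_cis) * cfg$expr_factor_share
    v_idio <- (1 - cfg$prop_cis) * (1 - cfg$expr_factor_share)
    W <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      gpart <- scale_to_var(Gval[, j], cfg$prop_cis)
      fpart <- scale_to_var(as.vector(Fac %*% L[, j]), v_fac)
      ipart <- scale_to_var(stats::rnorm(n), v_idio)
      W[, j] <- gpart + fpart + ipart
      Gval[, j] <- gpart
    }
    dimnames(W) <- list(rownames(Zv), sprintf("gene_%04d", seq_len(k)))
    dimnames(Gval) <- dimnames(W)
    wm <- omics_matrix(W, kind = "transcript")
    list(transcripts = rank_z_transform(wm), genetic_values = Gval)
  })
}

#' Simulate a pre-corrected phenotype
#'
#' `y = g_direct + t_mediated + gt + e`, each latent component scaled to its
#' exact target variance: `h2_direct` for the polygenic direct path,
#' `coupling * t2_mediated` for the transcript-mediated path (the coupling
#' knob attenuates the realized transcript variance, emulating a time gap
#' between phenotyping and RNA sampling), `gt2` for the interaction (an
#' elementwise product of the standardized direct and mediated scores), and
#' the remainder for the residual.
#'
#' @param Z Standardized genotypes.
#' @param W Transcripts (rank-Z [omics_matrix()] or matrix).
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed + 2`).
#' @return A list: `phenotype` (named vector) and `truth` (latent components
#'   and realized variance fractions).
#' @export
simulate_phenotype <- function(Z, W, cfg, seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  Zv <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  Wv <- as.matrix(W)
  with_seed(seed, {
    n <- nrow(Zv)
    t2_real <- cfg$coupling * cfg$t2_mediated
    e2 <- 1 - cfg$h2_direct - t2_real - cfg$gt2
    if (e2 < -1e-12) stop("variance fractions sum above 1")
    e2 <- max(e2, 0)

    a <- stats::rnorm(ncol(Zv))
    g_direct <- scale_to_var(as.vector(Zv %*% a), cfg$h2_direct)
    b <- stats::rnorm(ncol(Wv))
    Wstd <- scale(Wv)
    t_score_raw <- as.vector(Wstd %*% b)
    t_effect <- scale_to_var(t_score_raw, t2_real)
    gt_effect <- if (cfg$gt2 > 0) {
      gs <- as.vector(scale(as.vector(Zv %*% a)))
      ts <- as.vector(scale(t_score_raw))
      scale_to_var(gs * ts, cfg$gt2)
    } else rep(0, n)
    e <- if (e2 > 0) scale_to_var(stats::rnorm(n), e2) else rep(0, n)
    y <- g_direct + t_effect + gt_effect + e
    names(y) <- rownames(Zv)
    vy <- stats::var(y)
    truth <- list(
      g_direct = g_direct, t_effect = t_effect, gt_effect = gt_effect,
      residual = e,
      fractions = c(h2_direct = stats::var(g_direct) / vy,
                    t2_mediated = stats::var(t_effect) / vy,
                    gt2 = stats::var(gt_effect) / vy,
                    e2 = stats::var(e) / vy),
      config = cfg)
    list(phenotype = y, truth = truth)
  })
}

#' Simulate a complete genotype-transcript-phenotype study
#'
#' Composes [simulate_genotypes()], [simulate_transcripts()] and
#' [simulate_phenotype()] (standardizing genotypes in between) and assigns
#' generation labels by `cfg$generation_sizes`, ready for [forward_split()].
#' All randomness derives from `cfg$seed`, so the same configuration
#' reproduces the study bit-exactly.
#'
#' @param cfg A [sim_config()].
#' @return A `simulated_study`: list with `genotypes`, `transcripts`
#'   (both [omics_matrix()]), `phenotype`, `generations` (named labels),
#'   `truth`, and `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  X <- simulate_genotypes(cfg)
  Z <- center_standardize(impute_mean(X))
  tr <- simulate_transcripts(Z, cfg)
  ph <- simulate_phenotype(Z, tr$transcripts, cfg)
  gens <- rep(names(cfg$generation_sizes), cfg$generation_sizes)
  names(gens) <- rownames(X)
  structure(list(genotypes = X, transcripts = tr$transcripts,
                 phenotype = ph$phenotype, generations = gens,
                 truth = c(ph$truth,
                           list(transcript_genetic_values = tr$genetic_values)),
                 config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "simulated_study: %d individuals, %d markers, %d genes; generations: %s\n",
    nrow(x$genotypes), ncol(x$genotypes), ncol(x$transcripts),
    paste(sprintf("%s (%d)", names(x$config$generation_sizes),
                  x$config$generation_sizes), collapse = ", ")))
  cat("realized variance fractions:\n")
  print(round(x$truth$fractions, 3))
  invisible(x)
}
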