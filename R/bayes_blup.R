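#' Model specification from a kernel set
#'
#' The five model variants are configurations of one multi-kernel linear
#' mixed model `y* = 1 mu + sum(components) + e`:
#' GBLUP = \{g\}, TBLUP = \{t\}, GTBLUP = \{g, t\}, GTIBLUP = \{g, t, gt\},
#' GTCBLUP = \{g, tc\}. An interaction kernel requires both of its factors;
#' `t` and `tc` are mutually exclusive.
#'
#' @param kernels Named list of [relationship_kernel] objects; names must be
#'   a nonempty subset of `g`, `t`, `tc`, `gt` matching each kernel's
#'   component label.
#' @return A `model_spec` with elements `kernels` and `model_name`.
#' @export
model_spec <- function(kernels) {
  if (inherits(kernels, "relationship_kernel")) kernels <- list(kernels)
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- vapply(kernels, function(k) k$component, character(1))
  comps <- names(kernels)
  if (length(comps) == 0L) stop("at least one kernel required")
  if (!all(comps %in% c("g", "t", "tc", "gt")))
    stop("unknown kernel component(s): ",
         paste(setdiff(comps, c("g", "t", "tc", "gt")), collapse = ", "))
  if (anyDuplicated(comps)) stop("duplicate kernel components")
  for (c in comps)
    if (!identical(kernels[[c]]$component, c))
      stop("kernel list name '", c, "' does not match its component label '",
           kernels[[c]]$component, "'")
  if ("gt" %in% comps && !("g" %in% comps && any(c("t", "tc") %in% comps)))
    stop("gt interaction requires both g and a transcript kernel")
  if (all(c("t", "tc") %in% comps))
    stop("t and tc kernels cannot enter the same model")
  n <- nrow(kernels[[1]]$values)
  ids <- rownames(kernels[[1]]$values)
  for (k in kernels) {
    if (nrow(k$values) != n) stop("kernel dimensions differ")
    if (!identical(rownames(k$values), ids))
      stop("kernel individual orderings differ")
  }
  name <- switch(paste(sort(comps), collapse = "+"),
                 "g" = "GBLUP", "t" = "TBLUP", "g+t" = "GTBLUP",
                 "g+gt+t" = "GTIBLUP", "g+tc" = "GTCBLUP", "custom")
  structure(list(kernels = kernels, model_name = name, ids = ids),
            class = "model_spec")
}

#' Gibbs chain settings
#'
#' Defaults mirror the analysis-scale chain: 60,000 iterations, 20,000
#' burn-in, thinning 10, hence 4,000 retained draws. A reduced chain
#' (e.g. `chain_settings(6000, 2000, 5)`) is ample for desk-scale kernels.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Burn-in iterations discarded before retention.
#' @param thin Thinning interval.
#' @param seed Integer RNG seed (optional but recommended).
#' @return A `chain_settings` list with the derived `retained` count.
#' @export
chain_settings <- function(n_iter = 60000L, burn_in = 20000L, thin = 10L,
                           seed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, retained = (n_iter - burn_in) %/% thin),
            class = "chain_settings")
}

#' Scaled-inverse-chi-squared prior scales
#'
#' Each variance component carries a scaled-inverse-chi-squared prior with
#' `df` degrees of freedom. Scales are chosen so the prior mode matches a
#' target split of the phenotypic variance: the residual gets
#' `S_e = sigma_p2 (1 - R2) (df + 2)` and each of the `n_c` kernel components
#' `S_c = sigma_p2 (R2 / n_c) (df + 2) / meandiag(K_c)`, with `R2` the prior
#' expectation of the proportion of variance explained by the model, split
#' equally across components. The `(df + 2)` factor is used for the residual
#' as well as the components (the mode of a scaled-inverse-chi-squared with
#' scale S is `S / (df + 2)`).
#'
#' @param sigma_p2 Phenotypic variance (> 0).
#' @param R2_prior Prior proportion of variance explained, in `[0, 1)`.
#' @param df Prior degrees of freedom (default 5, used for every component).
#' @param kernels Named list of [relationship_kernel] objects.
#' @return A `prior_spec`: `df_component`, `df_residual`, `S_component`
#'   (named), `S_residual`, `R2_prior`.
#' @export
compute_prior_scales <- function(sigma_p2, R2_prior = 0.5, df = 5,
                                 kernels) {
  if (sigma_p2 <= 0) stop("sigma_p2 must be > 0")
  if (R2_prior < 0 || R2_prior >= 1) stop("R2_prior must lie in [0, 1)")
  if (df <= 0) stop("df must be > 0")
  nc <- length(kernels)
  S_c <- vapply(kernels, function(k) {
    md <- mean(diag(k$values))
    if (md == 0) stop("kernel '", k$component, "' has zero mean diagonal")
    sigma_p2 * (R2_prior / nc) * (df + 2) / md
  }, numeric(1))
  structure(list(df_component = df, df_residual = df,
                 S_component = S_c,
                 S_residual = sigma_p2 * (1 - R2_prior) * (df + 2),
                 R2_prior = R2_prior),
            class = "prior_spec")
}

# initial-positive-sequence effective sample size (reporting only)
ess_ips <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 500L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Fit a multi-kernel BLUP model by Gibbs sampling
#'
#' Samples the joint posterior of the intercept, per-kernel individual
#' effects, and variance components of `y* = 1 mu + sum_c u_c + e`,
#' `u_c ~ N(0, K_c sigma_c^2)`, `e ~ N(0, I sigma_e^2)`, under
#' scaled-inverse-chi-squared variance priors and a flat prior on `mu`.
#' Sampling is performed in the eigenbasis of each kernel (eigenvalues below
#' `1e-8` of the largest are truncated), so each component update reduces to
#' independent normal draws. Individuals with missing phenotypes are handled
#' by data augmentation and thereby receive effect draws from their
#' conditional distribution — this is how validation-set predictions are
#' produced under forward validation.
#'
#' @param y Numeric phenotype vector (NA = unobserved), optionally named by
#'   individual ID; length must match the kernel dimension and at least 30
#'   entries must be observed.
#' @param spec A [model_spec()] or named list of kernels.
#' @param chain [chain_settings()].
#' @param priors A `prior_spec` from [compute_prior_scales()], or `NULL` to
#'   derive one from the observed phenotypic variance with `R2_prior`/`df`.
#' @param R2_prior,df Used only when `priors` is `NULL`.
#' @param fix_variances Optional named numeric vector (components plus `"e"`)
#'   holding all variance components fixed — no variance updates are made.
#'   Used for sampler validation against the closed-form [blup_solve()].
#' @param keep_effects Retain per-draw effect vectors (needed by
#'   [predict.blup_fit()]; default `TRUE`).
#' @return A `blup_fit` with posterior means/SDs, retained draws, per-draw
#'   effect matrices, convergence summaries, and the settings used.
#' @export
gibbs_fit <- function(y, spec, chain = chain_settings(), priors = NULL,
                      R2_prior = 0.5, df = 5, fix_variances = NULL,
                      keep_effects = TRUE) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  kernels <- spec$kernels
  comps <- names(kernels)
  n <- length(spec$ids)
  if (length(y) != n) stop("phenotype length does not match kernel dimension")
  if (!is.null(names(y))) {
    if (!setequal(names(y), spec$ids)) stop("phenotype IDs do not match kernels")
    y <- y[spec$ids]
  }
  obs <- which(!is.na(y))
  miss <- which(is.na(y))
  if (length(obs) < 30) stop("at least 30 non-missing phenotypes required")
  sigma_p2 <- stats::var(y[obs])
  if (sigma_p2 <= 0) stop("zero phenotypic variance")
  if (is.null(priors))
    priors <- compute_prior_scales(sigma_p2, R2_prior, df, kernels)

  # eigendecompositions; truncation keeps the numerically nonzero spectrum
  eig <- lapply(kernels, function(k) {
    e <- eigen(k$values, symmetric = TRUE)
    dmax <- max(e$values)
    if (min(e$values) < -1e-8 * max(dmax, 1e-300))
      stop("kernel '", k$component, "' is not positive semidefinite")
    keep <- which(e$values > 1e-8 * dmax)
    list(V = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })

  fixed <- !is.null(fix_variances)
  if (fixed && !all(c(comps, "e") %in% names(fix_variances)))
    stop("fix_variances must name every component and 'e'")

  if (!is.null(chain$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(chain$seed)
  }

  # initial state
  nc <- length(comps)
  if (fixed) {
    s2 <- fix_variances[comps]
    se2 <- fix_variances[["e"]]
  } else {
    s2 <- stats::setNames(vapply(kernels, function(k)
      sigma_p2 * priors$R2_prior / max(nc, 1) / mean(diag(k$values)),
      numeric(1)), comps)
    se2 <- sigma_p2 * (1 - priors$R2_prior)
    if (se2 <= 0) se2 <- sigma_p2 * 0.5
  }
  mu <- mean(y[obs])
  u <- matrix(0, n, nc, dimnames = list(spec$ids, comps))
  alpha <- lapply(eig, function(e) numeric(length(e$d)))
  ywork <- y
  ywork[miss] <- mu
  e_res <- ywork - mu  # residual vector, kept current throughout

  n_ret <- chain$retained
  draw_mu <- numeric(n_ret)
  draw_s2 <- matrix(NA_real_, n_ret, nc + 1,
                    dimnames = list(NULL, c(comps, "e")))
  draw_u <- if (keep_effects)
    lapply(stats::setNames(comps, comps),
           function(c) matrix(NA_real_, n, n_ret, dimnames = list(spec$ids, NULL)))
  else NULL

  df_c <- priors$df_component
  df_e <- priors$df_residual
  S_c <- priors$S_component
  S_e <- priors$S_residual
  ridx <- 0L

  for (it in seq_len(chain$n_iter)) {
    # intercept (flat prior)
    e_res <- e_res + mu
    mu <- stats::rnorm(1, mean(e_res), sqrt(se2 / n))
    e_res <- e_res - mu

    # component effects in each kernel eigenbasis
    for (ci in seq_len(nc)) {
      V <- eig[[ci]]$V; d <- eig[[ci]]$d
      e_res <- e_res + u[, ci]
      rhs <- crossprod(V, e_res)
      cvar <- 1 / (1 / se2 + 1 / (d * s2[ci]))
      a <- cvar * rhs / se2 + sqrt(cvar) * stats::rnorm(length(d))
      alpha[[ci]] <- a
      u[, ci] <- as.vector(V %*% a)
      e_res <- e_res - u[, ci]
      if (!fixed)
        s2[ci] <- (S_c[ci] + sum(a^2 / d)) /
          stats::rchisq(1, df_c + length(d))
    }

    if (!fixed)
      se2 <- (S_e + sum(e_res^2)) / stats::rchisq(1, df_e + n)

    # data augmentation: redraw residuals of unobserved phenotypes
    if (length(miss))
      e_res[miss] <- stats::rnorm(length(miss), 0, sqrt(se2))

    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0L) {
      ridx <- ridx + 1L
      draw_mu[ridx] <- mu
      draw_s2[ridx, ] <- c(s2, se2)
      if (keep_effects)
        for (ci in seq_len(nc)) draw_u[[ci]][, ridx] <- u[, ci]
    }
  }

  post_u <- if (keep_effects)
    lapply(draw_u, rowMeans)
  else NULL
  half <- n_ret %/% 2L
  convergence <- data.frame(
    parameter = c("mu", colnames(draw_s2)),
    ess = c(ess_ips(draw_mu), apply(draw_s2, 2, ess_ips)),
    split_mean_diff = c(
      mean(draw_mu[seq_len(half)]) - mean(draw_mu[half + seq_len(half)]),
      colMeans(draw_s2[seq_len(half), , drop = FALSE]) -
        colMeans(draw_s2[half + seq_len(half), , drop = FALSE])))

  structure(list(
    model_name = spec$model_name, components = comps, ids = spec$ids,
    missing_ids = spec$ids[miss],
    draws = list(mu = draw_mu, sigma2 = draw_s2, effects = draw_u),
    posterior_mean = list(mu = mean(draw_mu),
                          sigma2 = colMeans(draw_s2), effects = post_u),
    posterior_sd = list(mu = stats::sd(draw_mu),
                        sigma2 = apply(draw_s2, 2, stats::sd)),
    sigma_p2 = sigma_p2, priors = priors, chain = chain,
    fixed_variances = fix_variances, convergence = convergence),
    class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d (%d unobserved), %d retained draws\n",
              x$model_name, length(x$ids), length(x$missing_ids),
              length(x$draws$mu)))
  vc <- x$posterior_mean$sigma2
  cat("posterior-mean variances:\n")
  print(round(vc, 4))
  invisible(x)
}

#' Closed-form multi-kernel BLUP at fixed variances
#'
#' Solves the mixed-model system for `y = 1 mu + sum_c u_c + e` with all
#' variance components known: the GLS intercept and
#' `u_c = sigma_c^2 K_c[, obs] V_obs^-1 (y_obs - mu)` with
#' `V_obs = sum_c sigma_c^2 K_c[obs, obs] + sigma_e^2 I`. Effects are
#' returned for every individual, including those with unobserved phenotypes
#' (kernel extension). Serves as the exact oracle for [gibbs_fit()] run with
#' `fix_variances`.
#'
#' @param y Phenotype vector, `NA` for unobserved.
#' @param spec [model_spec()] or named kernel list.
#' @param variances Named numeric vector: one entry per component plus `"e"`,
#'   all > 0.
#' @return List with `mu`, `effects` (named list of length-n vectors) and
#'   `y_hat = mu + sum(effects)`.
#' @export
blup_solve <- function(y, spec, variances) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  kernels <- spec$kernels
  comps <- names(kernels)
  if (!all(c(comps, "e") %in% names(variances)))
    stop("variances must name every component and 'e'")
  if (any(variances[c(comps, "e")] <= 0)) stop("all variances must be > 0")
  n <- length(spec$ids)
  if (length(y) != n) stop("phenotype length mismatch")
  obs <- which(!is.na(y))
  if (length(obs) < 2) stop("need at least 2 observed phenotypes")
  Vobs <- diag(variances[["e"]], length(obs))
  for (c in comps)
    Vobs <- Vobs + variances[[c]] * kernels[[c]]$values[obs, obs]
  ones <- rep(1, length(obs))
  Vi <- tryCatch(solve(Vobs), error = function(e)
    stop("singular mixed-model system: ", conditionMessage(e)))
  mu <- sum(Vi %*% y[obs]) / sum(Vi)
  resid <- Vi %*% (y[obs] - mu)
  effects <- lapply(stats::setNames(comps, comps), function(c)
    stats::setNames(as.vector(variances[[c]] *
                                kernels[[c]]$values[, obs] %*% resid),
                    spec$ids))
  y_hat <- mu + Reduce(`+`, effects)
  list(mu = mu, effects = effects, y_hat = y_hat)
}

#' Posterior variance partition
#'
#' For each retained draw the proportions of phenotypic variance attributed
#' to the genomic (`h2`), transcriptomic (`t2`, including the conditioned
#' `tc` component), interaction (`gt2`) and residual (`e2`) parts are
#' computed, then summarized by posterior mean and SD. Absent components
#' contribute 0.
#'
#' Two estimators are available. `method = "component"` uses the variance
#' components directly: per draw, `h2 = sigma_g2 / (sum sigma2 + sigma_e2)`
#' and likewise for the others. This reads each `sigma_c2` as the variance
#' the component explains, which is accurate when its kernel has mean
#' diagonal ~1 (true for G and T built from standardized features).
#' `method = "realized"` uses the realized variance of each sampled effect
#' vector, `var(u_c)`, in place of `sigma_c2`; this measures the variance a
#' component actually explains regardless of its kernel's scale, which
#' matters for the conditioned kernel Tc, whose diagonal is deliberately not
#' rescaled and is well below 1 — there `sigma_tc2` overstates the explained
#' variance by roughly `1 / meandiag(Tc)`.
#'
#' @param fit A `blup_fit` (for `method = "realized"` it must have been run
#'   with `keep_effects = TRUE`).
#' @param method `"component"` (variance-component ratios) or `"realized"`
#'   (realized effect-variance ratios).
#' @return A `variance_partition`: data frame with rows `h2`, `t2`, `gt2`,
#'   `e2` and columns `mean`, `sd`.
#' @export
variance_partition <- function(fit, method = c("component", "realized")) {
  stopifnot(inherits(fit, "blup_fit"))
  method <- match.arg(method)
  s2 <- fit$draws$sigma2
  if (nrow(s2) == 0) stop("no retained draws")
  if (method == "realized") {
    if (is.null(fit$draws$effects))
      stop("realized partition needs a fit with keep_effects = TRUE")
    n <- length(fit$ids)
    s2 <- cbind(
      vapply(fit$draws$effects,
             function(U) colSums(U^2) / n - colMeans(U)^2, # per-draw var(u_c)
             numeric(nrow(s2))) * n / (n - 1),
      e = s2[, "e"])
  }
  tot <- rowSums(s2)
  grab <- function(comp) if (comp %in% colnames(s2)) s2[, comp] / tot else
    rep(0, nrow(s2))
  prop <- cbind(h2 = grab("g"),
                t2 = grab("t") + grab("tc"),
                gt2 = grab("gt"),
                e2 = s2[, "e"] / tot)
  out <- data.frame(mean = colMeans(prop), sd = apply(prop, 2, stats::sd))
  structure(out, class = c("variance_partition", "data.frame"))
}

#' Posterior predictions for individuals in a fit
#'
#' Posterior means of the component effects and of
#' `y_hat = mu + sum(components)` for the requested individuals (observed or
#' unobserved in the fit; unobserved individuals' effects come from their
#' conditional draws under data augmentation).
#'
#' @param object A `blup_fit` produced with `keep_effects = TRUE`.
#' @param individuals Character IDs (default: all individuals in the fit).
#' @param ... Unused.
#' @return A data frame with `id`, `y_hat`, and one column per component
#'   (`g`, `t`, `tc`, `gt` as present).
#' @export
predict.blup_fit <- function(object, individuals = NULL, ...) {
  if (is.null(object$posterior_mean$effects))
    stop("fit was run with keep_effects = FALSE")
  ids <- object$ids
  if (is.null(individuals)) individuals <- ids
  unknown <- setdiff(individuals, ids)
  if (length(unknown))
    stop("unknown individual(s): ", paste(unknown, collapse = ", "))
  idx <- match(individuals, ids)
  eff <- lapply(object$posterior_mean$effects, function(v) v[idx])
  y_hat <- object$posterior_mean$mu + Reduce(`+`, eff)
  out <- data.frame(id = individuals, y_hat = y_hat)
  for (c in names(eff)) out[[c]] <- eff[[c]]
  rownames(out) <- NULL
  out
}
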