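#' Forward-validation split by generation
#'
#' Individuals with the validation generation label form the validation set;
#' everyone else is reference. Mimics deployment in a breeding program, where
#' older generations predict the youngest.
#'
#' @param generations Vector of per-individual generation labels, named by
#'   individual ID (or IDs supplied via `ids`).
#' @param validation_generation The label defining the validation subset.
#' @param ids Optional individual IDs if `generations` is unnamed.
#' @return A `validation_split`: list with `reference_ids`, `validation_ids`,
#'   `rule`.
#' @export
forward_split <- function(generations, validation_generation, ids = NULL) {
  if (is.null(names(generations))) {
    if (is.null(ids)) ids <- paste0("id_", seq_along(generations))
    names(generations) <- ids
  }
  labs <- as.character(generations)
  vg <- as.character(validation_generation)
  if (!vg %in% labs)
    stop("validation generation '", vg, "' absent from labels")
  val <- names(generations)[labs == vg]
  ref <- names(generations)[labs != vg]
  if (length(ref) == 0L) stop("empty reference set: all individuals are in the validation generation")
  if (length(val) == 0L) stop("empty validation set")
  structure(list(reference_ids = ref, validation_ids = val,
                 rule = paste0("generation:", vg)),
            class = "validation_split")
}

check_nonconstant <- function(x, what) {
  if (stats::sd(x) == 0)
    stop(what, " is constant; correlation undefined")
}

#' Prediction accuracy (Pearson correlation)
#'
#' @param y_star Corrected phenotypes.
#' @param y_hat Model predictions.
#' @return Pearson correlation between `y_star` and `y_hat`.
#' @export
accuracy <- function(y_star, y_hat) {
  if (length(y_star) != length(y_hat)) stop("length mismatch")
  if (length(y_star) < 3) stop("need at least 3 pairs")
  check_nonconstant(y_star, "y_star"); check_nonconstant(y_hat, "y_hat")
  stats::cor(y_star, y_hat)
}

#' Relative root-mean-squared error of prediction
#'
#' `sqrt(mean((y_star - y_hat)^2)) / sigma_p`. By default `sigma_p` is the
#' phenotypic standard deviation of the validation phenotypes (n-1
#' denominator).
#'
#' @param y_star,y_hat As in [accuracy()].
#' @param sigma_p Phenotypic SD; defaults to `sd(y_star)`.
#' @return Nonnegative relative error; values near 1 mean the average
#'   prediction error equals one phenotypic SD.
#' @export
rrmse <- function(y_star, y_hat, sigma_p = stats::sd(y_star)) {
  if (length(y_star) != length(y_hat)) stop("length mismatch")
  if (sigma_p <= 0) stop("sigma_p must be > 0")
  sqrt(mean((y_star - y_hat)^2)) / sigma_p
}

#' Dispersion bias of predictions
#'
#' OLS slope of corrected phenotypes on predictions. 1 means unbiased
#' dispersion; values above 1 indicate deflated (under-dispersed), below 1
#' inflated (over-dispersed) predictions.
#'
#' @param y_star,y_hat As in [accuracy()].
#' @return The regression coefficient.
#' @export
bias_slope <- function(y_star, y_hat) {
  if (length(y_star) != length(y_hat)) stop("length mismatch")
  check_nonconstant(y_hat, "y_hat")
  stats::cov(y_star, y_hat) / stats::var(y_hat)
}

#' Model R-squared within the reference set
#'
#' Squared Pearson correlation between corrected phenotypes and fitted values
#' (equal to the OLS R-squared of the simple regression of one on the other).
#'
#' @param y_star_reference,y_hat_reference Observed and fitted values on the
#'   reference individuals.
#' @return Coefficient of determination in `[0, 1]`.
#' @export
model_r2 <- function(y_star_reference, y_hat_reference) {
  accuracy(y_star_reference, y_hat_reference)^2
}

#' Bootstrap standard error of a prediction accuracy
#'
#' Standard deviation of the Pearson correlation over paired resamples with
#' replacement. Resamples for which the correlation is undefined (a constant
#' vector) are redrawn and counted.
#'
#' @param y_star,y_hat Paired vectors, length >= 10.
#' @param n_boot Number of bootstrap samples (>= 100; the analysis scale is
#'   10,000).
#' @param seed Integer seed; same seed gives the identical SE.
#' @return Numeric SE with attribute `n_redrawn`.
#' @export
bootstrap_se <- function(y_star, y_hat, n_boot = 10000L, seed = NULL) {
  n <- length(y_star)
  if (n < 10) stop("need at least 10 pairs")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (length(y_hat) != n) stop("length mismatch")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  rs <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(y_star[idx]) > 0 && stats::sd(y_hat[idx]) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot) stop("degenerate bootstrap input")
    }
    rs[b] <- stats::cor(y_star[idx], y_hat[idx])
  }
  structure(stats::sd(rs), n_redrawn = redrawn)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Williams' t statistic (Steiger's formulation) comparing `r12` and `r13`,
#' two correlations sharing variable 1 and measured on the same `n`
#' individuals, with `r23` the correlation between the two competing
#' variables:
#' `t = (r12 - r13) sqrt((n-1)(1+r23) / (2 |R| (n-1)/(n-3) + rbar^2 (1-r23)^3))`
#' where `|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23` and
#' `rbar = (r12 + r13)/2`; two-sided p from the t distribution with `n - 3`
#' degrees of freedom.
#'
#' @param r12,r13 The two correlations being compared, each in `(-1, 1)`.
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 4).
#' @return List with `t`, `p_value`, `df`.
#' @export
hotelling_williams_test <- function(r12, r13, r23, n) {
  if (n < 4) stop("n must be >= 4")
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must lie in (-1, 1)")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0)
    stop("correlation triple is not positive definite (|R| = ",
         signif(detR, 3), ")")
  rbar <- (r12 + r13) / 2
  tstat <- (r12 - r13) *
    sqrt((n - 1) * (1 + r23) /
           (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  list(t = tstat, p_value = 2 * stats::pt(abs(tstat), df = n - 3,
                                          lower.tail = FALSE),
       df = n - 3)
}

#' Pairwise correlations among model components and the phenotype
#'
#' Pearson correlations among the posterior-mean component solutions (g-hat,
#' t-hat or tc-hat, gt-hat) and the corrected phenotype on the validation
#' individuals. A constant vector yields `NA` entries rather than an error.
#'
#' @param components Named list of numeric vectors (e.g. `list(g = ..., t =
#'   ...)`), all on the same individuals.
#' @param y_star Corrected phenotypes on the same individuals, or `NULL` to
#'   correlate components only.
#' @return Symmetric correlation matrix with unit diagonal, labelled by
#'   component names plus `"y_star"`.
#' @export
component_correlation_table <- function(components, y_star = NULL) {
  mats <- components
  if (!is.null(y_star)) mats <- c(mats, list(y_star = y_star))
  lens <- lengths(mats)
  if (length(unique(lens)) != 1) stop("vector length mismatch")
  M <- do.call(cbind, mats)
  sds <- apply(M, 2, stats::sd)
  out <- suppressWarnings(stats::cor(M))
  out[, sds == 0] <- NA_real_
  out[sds == 0, ] <- NA_real_
  diag(out) <- 1
  out
}

#' Forward-validation evaluation of a fitted model
#'
#' Computes every prediction statistic on a fit in which the validation
#' individuals' phenotypes were set to `NA`: accuracy with bootstrap SE,
#' RRMSE, bias slope on the validation set, model R-squared on the reference
#' set, and the component-correlation table (components vs each other and vs
#' `y_star`) on the validation set.
#'
#' @param fit A `blup_fit` in which validation phenotypes were unobserved.
#' @param y_star Full vector of corrected phenotypes (named by ID or ordered
#'   as the fit's individuals), including the validation values.
#' @param split A [forward_split()] result.
#' @param n_boot Bootstrap samples for the accuracy SE.
#' @param seed Seed for the bootstrap.
#' @return An `eval_result`: list with `accuracy`, `accuracy_se`, `rrmse`,
#'   `bias_slope`, `model_r2_reference`, `component_correlations`,
#'   `gebv_accuracy` (correlation of g-hat with validation `y_star`, when a
#'   genomic component is present), and `n_validation`.
#' @export
evaluate_fit <- function(fit, y_star, split, n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(fit, "blup_fit"), inherits(split, "validation_split"))
  if (!is.null(names(y_star))) y_star <- y_star[fit$ids]
  if (length(y_star) != length(fit$ids)) stop("phenotype length mismatch")
  names(y_star) <- fit$ids
  pred <- stats::predict(fit)
  rownames(pred) <- pred$id
  val <- split$validation_ids
  ref <- split$reference_ids
  yv <- y_star[val]; yhv <- pred[val, "y_hat"]
  comps <- fit$components
  comp_vec <- lapply(stats::setNames(comps, comps),
                     function(c) pred[val, c])
  res <- list(
    accuracy = accuracy(yv, yhv),
    accuracy_se = bootstrap_se(yv, yhv, n_boot = n_boot, seed = seed),
    rrmse = rrmse(yv, yhv),
    bias_slope = bias_slope(yv, yhv),
    model_r2_reference = model_r2(y_star[ref], pred[ref, "y_hat"]),
    component_correlations = component_correlation_table(comp_vec, yv),
    gebv_accuracy = if ("g" %in% comps) accuracy(yv, comp_vec$g) else NA_real_,
    n_validation = length(val), model_name = fit$model_name)
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "%s forward validation (n = %d): accuracy %.3f (SE %.3f), RRMSE %.3f, bias slope %.3f, reference R2 %.3f\n",
    x$model_name, x$n_validation, x$accuracy, x$accuracy_se, x$rrmse,
    x$bias_slope, x$model_r2_reference))
  cat("component correlations:\n")
  print(round(x$component_correlations, 3))
  invisible(x)
}
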