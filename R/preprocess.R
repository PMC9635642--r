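#' Quality-control filtering of genotype markers
#'
#' Applies the three marker filters in order: minor allele frequency, call
#' rate, then sequential-correlation pruning. A marker is removed by the
#' pruning step when its absolute Pearson correlation with the most recently
#' retained marker to its left exceeds `corr_max` (the earlier marker of a
#' violating pair is kept).
#'
#' @param X An [omics_matrix()] of kind `"genotype"` (dosages in `[0, 2]`,
#'   `NA` allowed).
#' @param maf_min Minimum minor allele frequency; markers with MAF strictly
#'   below are removed. Default 0.05.
#' @param call_rate_min Minimum call rate (fraction non-missing); markers
#'   strictly below are removed. Default 0.90.
#' @param corr_max Maximum absolute correlation with the preceding retained
#'   marker; markers strictly above are removed. Default 0.80.
#'
#' @return A list with `matrix` (the filtered [omics_matrix()]) and `report`,
#'   a `qc_report` with fields `n_input`, `n_removed_maf`,
#'   `n_removed_callrate`, `n_removed_corr`, `n_retained` and the thresholds.
#' @export
qc_filter_genotypes <- function(X, maf_min = 0.05, call_rate_min = 0.90,
                                corr_max = 0.80) {
  stopifnot(is_omics_matrix(X), identical(attr(X, "kind"), "genotype"))
  if (any(c(maf_min, call_rate_min, corr_max) <= 0) ||
      any(c(maf_min, call_rate_min, corr_max) >= 1))
    stop("QC thresholds must lie in (0, 1)")
  V <- unclass(X)
  p_in <- ncol(V)

  # allele frequency from mean dosage / 2; MAF folds to [0, 0.5]
  af <- colMeans(V, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_maf <- !is.na(maf) & maf >= maf_min
  n_rm_maf <- sum(!keep_maf)

  call_rate <- colMeans(!is.na(V))
  keep_cr <- call_rate >= call_rate_min & keep_maf
  n_rm_cr <- sum(keep_maf & !keep_cr)

  idx <- which(keep_cr)
  if (length(idx) == 0L) stop("empty matrix after QC (MAF/call-rate filters)")

  # left-to-right pruning against the last retained marker
  retained <- idx[1]
  last <- idx[1]
  n_rm_corr <- 0L
  for (j in idx[-1]) {
    r <- suppressWarnings(
      stats::cor(V[, last], V[, j], use = "pairwise.complete.obs"))
    if (!is.na(r) && abs(r) > corr_max) {
      n_rm_corr <- n_rm_corr + 1L
    } else {
      retained <- c(retained, j)
      last <- j
    }
  }
  if (length(retained) == 0L) stop("empty matrix after QC")

  report <- structure(
    list(n_input = p_in, n_removed_maf = n_rm_maf,
         n_removed_callrate = n_rm_cr, n_removed_corr = n_rm_corr,
         n_retained = length(retained),
         thresholds = c(maf_min = maf_min, call_rate_min = call_rate_min,
                        corr_max = corr_max)),
    class = "qc_report")
  list(matrix = X[, retained, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "genotype QC: %d markers in; removed %d (MAF < %.3g), %d (call rate < %.3g), %d (|r| > %.3g); %d retained\n",
    x$n_input, x$n_removed_maf, x$thresholds["maf_min"],
    x$n_removed_callrate, x$thresholds["call_rate_min"],
    x$n_removed_corr, x$thresholds["corr_max"], x$n_retained))
  invisible(x)
}

#' Mean-impute missing genotype dosages
#'
#' Replaces missing dosages by the per-marker mean. Intended to run after
#' [qc_filter_genotypes()] and before [center_standardize()].
#'
#' @param X An [omics_matrix()].
#' @return An [omics_matrix()] with no missing values.
#' @export
impute_mean <- function(X) {
  stopifnot(is_omics_matrix(X))
  if (!anyNA(X)) return(X)
  V <- unclass(X)
  mu <- colMeans(V, na.rm = TRUE)
  na_idx <- which(is.na(V), arr.ind = TRUE)
  V[na_idx] <- mu[na_idx[, 2]]
  omics_matrix(V, kind = attr(X, "kind"))
}

#' Rank-based inverse normal (rank Z) transformation
#'
#' Replaces each feature's values by normal quantiles of their ranks across
#' individuals: value of rank r (average ranks for ties) maps to
#' `qnorm(r / (n + 1))`. After the transform every feature has the same
#' empirical distribution, so the operation is idempotent up to ties.
#'
#' @param X An [omics_matrix()] of kind `"transcript"` with no missing
#'   values.
#' @return The transformed [omics_matrix()].
#' @export
rank_z_transform <- function(X) {
  stopifnot(is_omics_matrix(X))
  if (anyNA(X)) stop("rank_z_transform requires complete data")
  V <- unclass(X)
  n <- nrow(V)
  tied <- which(matrixStats_colVars(V) == 0)
  if (length(tied))
    stop("all-tied feature(s), rank Z undefined: ",
         paste(colnames(V)[tied], collapse = ", "))
  out <- apply(V, 2, function(col) stats::qnorm(rank(col) / (n + 1)))
  dimnames(out) <- dimnames(V)
  omics_matrix(out, kind = attr(X, "kind"))
}

# column variances without an extra dependency
matrixStats_colVars <- function(V) {
  n <- nrow(V)
  if (n < 2) return(rep(NA_real_, ncol(V)))
  mu <- colMeans(V)
  (colSums(V^2) - n * mu^2) / (n - 1)
}

#' Center and standardize feature columns
#'
#' Columns are centered to mean zero and scaled to unit sample standard
#' deviation (n-1 denominator). Zero-variance columns are dropped and
#' reported.
#'
#' @param X An [omics_matrix()] or plain matrix with at least 2 rows and no
#'   missing values (impute first, see [impute_mean()]).
#' @return A `standardized_matrix`: list with `values` (n x p matrix),
#'   `feature_means`, `feature_sds`, and `dropped_features`.
#' @export
center_standardize <- function(X) {
  V <- as.matrix(X)
  if (is_omics_matrix(X)) {
    V <- unclass(V)
    attr(V, "kind") <- NULL
  }
  if (nrow(V) < 2) stop("center_standardize requires at least 2 individuals")
  if (anyNA(V)) stop("missing values; impute before standardizing")
  mu <- colMeans(V)
  sds <- sqrt(matrixStats_colVars(V))
  drop <- sds == 0 | !is.finite(sds)
  dropped <- colnames(V)[drop]
  keep <- which(!drop)
  if (length(keep) == 0L) stop("all features have zero variance")
  Z <- sweep(V[, keep, drop = FALSE], 2, mu[keep], "-")
  Z <- sweep(Z, 2, sds[keep], "/")
  structure(list(values = Z, feature_means = mu[keep],
                 feature_sds = sds[keep], dropped_features = dropped),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("standardized_matrix: %d x %d (dropped %d zero-variance)\n",
              nrow(x$values), ncol(x$values), length(x$dropped_features)))
  invisible(x)
}
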