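#' Construct a relationship kernel object
#'
#' A relationship kernel is an n x n symmetric positive-semidefinite
#' similarity matrix among individuals, labelled by the model component it
#' feeds: `g` (genomic), `t` (transcriptomic), `tc` (genotype-conditioned
#' transcriptomic) or `gt` (Hadamard interaction).
#'
#' @param values Numeric n x n matrix with individual IDs as dimnames.
#' @param component One of `"g"`, `"t"`, `"tc"`, `"gt"`.
#' @param n_features Number of features (markers m or genes k) used as the
#'   cross-product divisor; `NA` for interaction kernels.
#' @param check Validate symmetry and positive semidefiniteness.
#' @return A `relationship_kernel`.
#' @export
relationship_kernel <- function(values, component = c("g", "t", "tc", "gt"),
                                n_features = NA_integer_, check = TRUE) {
  component <- match.arg(component)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("id_", seq_len(nrow(values)))
  if (check) {
    asym <- max(abs(values - t(values)))
    if (asym >= 1e-10 * max(1, max(abs(values))))
      stop("kernel is not symmetric (max asymmetry ", signif(asym, 3), ")")
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
      stop("kernel is not positive semidefinite (min eigenvalue ",
           signif(min(ev), 3), ")")
  }
  structure(list(values = values, component = component,
                 n_features = n_features),
            class = "relationship_kernel")
}

#' @export
print.relationship_kernel <- function(x, ...) {
  cat(sprintf("relationship_kernel [%s]: %d x %d%s\n", x$component,
              nrow(x$values), ncol(x$values),
              if (is.na(x$n_features)) "" else
                sprintf(", %d features", x$n_features)))
  invisible(x)
}

cross_product_kernel <- function(Z, component, divisor) {
  if (divisor < 1) stop("kernel divisor must be >= 1 (no features)")
  K <- tcrossprod(Z) / divisor
  K <- (K + t(K)) / 2
  relationship_kernel(K, component = component, n_features = divisor,
                      check = FALSE)
}

#' Genomic relationship matrix
#'
#' VanRaden's second method: `G = Z Z' / m` with `Z` the centered and
#' standardized genotype matrix and `m` the number of markers.
#'
#' @param Z A `standardized_matrix` from [center_standardize()] (or a plain
#'   centered/standardized matrix).
#' @return A [relationship_kernel] with component `"g"`.
#' @export
build_genomic_kernel <- function(Z) {
  V <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  cross_product_kernel(V, "g", ncol(V))
}

#' Transcriptomic relationship matrix
#'
#' `T = W W' / k` with `W` the centered and standardized transcript matrix
#' and `k` the number of genes.
#'
#' @param W A `standardized_matrix` (or plain matrix) of transcript levels.
#' @return A [relationship_kernel] with component `"t"`.
#' @export
build_transcript_kernel <- function(W) {
  V <- if (inherits(W, "standardized_matrix")) W$values else as.matrix(W)
  cross_product_kernel(V, "t", ncol(V))
}

#' Hadamard interaction kernel
#'
#' Elementwise product `G # T` of the genomic and a transcriptomic kernel;
#' positive semidefinite by the Schur product theorem.
#'
#' @param G A [relationship_kernel] with component `"g"`.
#' @param T_ A [relationship_kernel] with component `"t"` or `"tc"`.
#' @return A [relationship_kernel] with component `"gt"`.
#' @export
build_interaction_kernel <- function(G, T_) {
  stopifnot(inherits(G, "relationship_kernel"),
            inherits(T_, "relationship_kernel"))
  if (G$component != "g" || !T_$component %in% c("t", "tc"))
    stop("interaction kernel requires a g kernel and a t/tc kernel")
  if (!identical(dim(G$values), dim(T_$values)))
    stop("kernel dimensions differ")
  if (!identical(rownames(G$values), rownames(T_$values)))
    stop("kernel individual orderings differ")
  relationship_kernel(G$values * T_$values, component = "gt", check = FALSE)
}

#' Ridge parameter for the genotype smoother
#'
#' `lambda = m * sigma_e^2 / sigma_g^2`, with both variances taken from a
#' GBLUP fit of the same trait (posterior means). Reflects that marker
#' effects are shrunk as random effects rather than projected out as fixed
#' effects.
#'
#' @param sigma_e2 Residual variance (>= 0).
#' @param sigma_g2 Additive genomic variance (> 0).
#' @param m Number of markers.
#' @return The scalar ridge parameter.
#' @export
compute_lambda <- function(sigma_e2, sigma_g2, m) {
  if (m < 1) stop("m must be >= 1")
  if (sigma_e2 < 0) stop("sigma_e2 must be >= 0")
  if (sigma_g2 <= 0)
    stop("sigma_g2 must be > 0: with (near-)zero genomic variance the ",
         "smoother diverges; skip conditioning when the GBLUP heritability ",
         "is degenerate (see condition_transcripts 'skip' policy)")
  m * sigma_e2 / sigma_g2
}

#' Condition transcript levels on SNP genotypes
#'
#' Removes the genotype-predictable part of each transcript column via the
#' ridge-regression smoother matrix: `Wc = (I - Z (Z'Z + lambda I_m)^-1 Z') W`.
#' Because the number of markers m typically far exceeds the number of
#' individuals n, the computation uses the algebraically identical
#' n-dimensional form `Wc = (I - ZZ' (ZZ' + lambda I_n)^-1) W`. Columns of
#' `Wc` are deliberately not re-standardized.
#'
#' @param W A `standardized_matrix` (or matrix) of transcript levels, same
#'   individual ordering as `Z`.
#' @param Z A `standardized_matrix` (or matrix) of genotypes.
#' @param lambda Ridge parameter from [compute_lambda()]; `lambda = 0` gives
#'   the exact projection (pseudo-inverse used when `ZZ'` is singular).
#' @return Numeric matrix `Wc` with the dimnames of `W`.
#' @export
condition_transcripts <- function(W, Z, lambda) {
  Wv <- if (inherits(W, "standardized_matrix")) W$values else as.matrix(W)
  Zv <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  if (nrow(Wv) != nrow(Zv)) stop("W and Z must have the same individuals")
  if (!is.null(rownames(Wv)) && !is.null(rownames(Zv)) &&
      !identical(rownames(Wv), rownames(Zv)))
    stop("W and Z individual orderings differ")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(Zv)
  ZZt <- tcrossprod(Zv)
  A <- ZZt + diag(lambda, n)
  # S W = ZZ' (ZZ' + lambda I)^-1 W ; fall back to the pseudo-inverse when
  # lambda = 0 leaves the system singular
  SW <- tryCatch(ZZt %*% solve(A, Wv),
                 error = function(e) ZZt %*% (MASS::ginv(A) %*% Wv))
  Wc <- Wv - SW
  dimnames(Wc) <- dimnames(Wv)
  Wc
}

#' Conditioned transcriptomic relationship matrix
#'
#' `Tc = Wc Wc' / k` from the genotype-conditioned transcript matrix.
#'
#' @param Wc Matrix from [condition_transcripts()].
#' @param k Number of genes (divisor); defaults to `ncol(Wc)`.
#' @return A [relationship_kernel] with component `"tc"`.
#' @export
build_conditioned_kernel <- function(Wc, k = ncol(Wc)) {
  cross_product_kernel(as.matrix(Wc), "tc", k)
}

#' Build the full kernel set for a model
#'
#' Convenience wrapper assembling any of the kernels `g`, `t`, `tc`, `gt`
#' from preprocessed genotype and transcript matrices.
#'
#' @param Z Standardized genotypes ([center_standardize()] output).
#' @param W Standardized transcripts (after [rank_z_transform()]).
#' @param make Character vector of kernel labels to build.
#' @param lambda Ridge parameter, required when `"tc"` is requested.
#' @param interaction_on For `"gt"`, which transcript kernel to interact with
#'   (`"t"` or `"tc"`).
#' @return Named list of [relationship_kernel] objects.
#' @export
build_kernels <- function(Z, W = NULL, make = c("g", "t"), lambda = NULL,
                          interaction_on = "t") {
  make <- match.arg(make, c("g", "t", "tc", "gt"), several.ok = TRUE)
  out <- list()
  if ("g" %in% make) out$g <- build_genomic_kernel(Z)
  if (any(c("t", "tc", "gt") %in% make) && is.null(W))
    stop("transcript matrix required for t/tc/gt kernels")
  if ("t" %in% make) out$t <- build_transcript_kernel(W)
  if ("tc" %in% make) {
    if (is.null(lambda)) stop("lambda required for the tc kernel")
    Wv <- if (inherits(W, "standardized_matrix")) W$values else as.matrix(W)
    Wc <- condition_transcripts(W, Z, lambda)
    out$tc <- build_conditioned_kernel(Wc, ncol(Wv))
  }
  if ("gt" %in% make) {
    tk <- if (interaction_on == "tc") out$tc else out$t
    if (is.null(tk)) stop("gt kernel needs the ", interaction_on, " kernel")
    out$gt <- build_interaction_kernel(out$g, tk)
  }
  out
}
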