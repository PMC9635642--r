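# deterministic random fixtures built in code

rand_matrix <- function(n, p, seed, rfun = stats::rnorm) {
  set.seed(seed)
  m <- matrix(rfun(n * p), n, p)
  dimnames(m) <- list(sprintf("i%02d", seq_len(n)), sprintf("f%03d", seq_len(p)))
  m
}

rand_std <- function(n, p, seed) {
  center_standardize(rand_matrix(n, p, seed))
}

rand_dosage <- function(n, p, seed, freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- stats::runif(p, 0.05, 0.5)
  m <- matrix(stats::rbinom(n * p, 2, rep(freq, each = n)), n, p)
  dimnames(m) <- list(sprintf("i%02d", seq_len(n)), sprintf("s%03d", seq_len(p)))
  omics_matrix(m, kind = "genotype")
}

# random PSD kernel via crossproduct of a wide matrix
rand_kernel <- function(n, seed, component = "g") {
  Z <- rand_std(n, 3 * n, seed)
  cross_kernel <- tcrossprod(Z$values) / ncol(Z$values)
  relationship_kernel(cross_kernel, component = component,
                      n_features = ncol(Z$values))
}

# small single-kernel study with known variance split, for sampler tests
gblup_instance <- function(n, m, h2, seed) {
  Z <- center_standardize(rand_dosage(n, m, seed))
  set.seed(seed + 1000)
  g <- as.vector(Z$values %*% stats::rnorm(ncol(Z$values)))
  g <- (g - mean(g)) / stats::sd(g) * sqrt(h2)
  e <- stats::rnorm(n); e <- (e - mean(e)) / stats::sd(e) * sqrt(1 - h2)
  y <- g + e
  names(y) <- rownames(Z$values)
  list(Z = Z, y = y, g_true = g, G = build_genomic_kernel(Z))
}
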