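# Riemannian geometry helpers for the tangent-space classifier.
# Per-epoch channel covariance matrices are symmetric positive definite
# (SPD); they are mapped to the tangent space at their geometric
# (affine-invariant Riemannian) mean, where a linear classifier applies.

spd_eig_fun <- function(m, fun) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (fun(pmax(e$values, .Machine$double.eps)) * t(e$vectors))
}

spd_logm <- function(m) spd_eig_fun(m, log)
spd_sqrtm <- function(m) spd_eig_fun(m, sqrt)
spd_invsqrtm <- function(m) spd_eig_fun(m, function(v) 1 / sqrt(v))

# geometric mean of SPD matrices by fixed-point iteration on the
# matrix exponential barycenter condition
geometric_mean_spd <- function(covs, tol = 1e-8, max_iter = 50) {
  g <- Reduce(`+`, covs) / length(covs)
  for (it in seq_len(max_iter)) {
    gi <- spd_invsqrtm(g)
    gs <- spd_sqrtm(g)
    s <- Reduce(`+`, lapply(covs, function(cc) spd_logm(gi %*% cc %*% gi))) /
      length(covs)
    g <- gs %*% spd_eig_fun(s, exp) %*% gs
    g <- (g + t(g)) / 2
    if (norm(s, "F") < tol) break
  }
  g
}

# covariance of each epoch's channel x time block, with automatic
# shrinkage toward the scaled identity when near-singular
epoch_covariances <- function(X, n_channels, n_samples) {
  lapply(seq_len(nrow(X)), function(i) {
    m <- matrix(X[i, ], nrow = n_channels, byrow = TRUE)
    m <- m - rowMeans(m)
    cc <- tcrossprod(m) / (n_samples - 1)
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8 * max(ev, 1e-12)) {
      cc <- cc + (1e-6 + 1e-4 * mean(diag(cc))) * diag(n_channels)
      message("epoch_covariances: shrinkage applied to a singular covariance")
    }
    cc
  })
}

# vectorize log-mapped matrices: upper triangle, off-diagonals x sqrt(2)
# so that Euclidean distance equals the Riemannian metric at the reference
tangent_map <- function(covs, ref) {
  gi <- spd_invsqrtm(ref)
  ut <- upper.tri(ref, diag = TRUE)
  w <- ifelse(row(ref)[ut] == col(ref)[ut], 1, sqrt(2))
  t(vapply(covs, function(cc) {
    s <- spd_logm(gi %*% cc %*% gi)
    s[ut] * w
  }, numeric(sum(ut))))
}
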