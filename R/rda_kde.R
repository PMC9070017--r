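# Reference ERP classifier: principal component reduction, regularized
# discriminant analysis, and kernel density estimation of the
# class-conditional discriminant scores (RDA/KDE).

rda_kde_fit_predict <- function(Xtr, ytr, Xte, var_frac = 0.95,
                                lambda = 0.9, gamma = 0.1) {
  sds <- apply(Xtr, 2, stats::sd)
  if (all(sds == 0)) stop("zero-variance input: no informative components")
  pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > 1e-12
  if (sum(pos) < 2) stop("fewer informative components than classes")
  cum <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
  ncomp <- max(2L, which(cum >= var_frac)[1])
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  Ztr <- scale(Xtr, center = pc$center, scale = FALSE) %*% rot
  Zte <- scale(Xte, center = pc$center, scale = FALSE) %*% rot

  classes <- c("target", "nontarget")
  stats_by <- lapply(classes, function(cl) {
    z <- Ztr[ytr == cl, , drop = FALSE]
    list(mu = colMeans(z), S = stats::cov(z), n = nrow(z))
  })
  names(stats_by) <- classes
  Sp <- (stats_by$target$S * (stats_by$target$n - 1) +
           stats_by$nontarget$S * (stats_by$nontarget$n - 1)) /
    (stats_by$target$n + stats_by$nontarget$n - 2)
  discr <- function(Z) {
    d <- sapply(classes, function(cl) {
      S <- (1 - lambda) * stats_by[[cl]]$S + lambda * Sp
      S <- (1 - gamma) * S + gamma * (sum(diag(S)) / ncol(S)) * diag(ncol(S))
      ch <- chol(S)
      dev <- sweep(Z, 2, stats_by[[cl]]$mu)
      maha <- colSums(backsolve(ch, t(dev), transpose = TRUE)^2)
      -0.5 * (2 * sum(log(diag(ch))) + maha)
    })
    d[, "target"] - d[, "nontarget"]
  }
  str_tr <- discr(Ztr)
  str_te <- discr(Zte)
  ld_t <- kde_logdens(str_te, str_tr[ytr == "target"])
  ld_n <- kde_logdens(str_te, str_tr[ytr == "nontarget"])
  ifelse(ld_t - ld_n > 0, "target", "nontarget")
}

# Gaussian KDE with Silverman's bandwidth, evaluated in log space
kde_logdens <- function(x_eval, x_train) {
  bw <- tryCatch(stats::bw.nrd0(x_train), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(x_train), 1e-6)
  vapply(x_eval, function(x0)
    log(mean(stats::dnorm(x0, x_train, bw)) + 1e-300), numeric(1))
}

#' Evaluate the RDA/KDE ERP reference classifier
#'
#' Flattens 0-500 ms ERP epochs (all channels) into feature vectors and
#' evaluates the PCA -> regularized discriminant analysis -> kernel
#' density pipeline by cross-validated balanced accuracy via
#' [train_eval()].  Shrinkage follows the regularized-discriminant
#' convention: class covariances are pulled toward the pooled covariance
#' (`lambda`) and then toward a scaled identity (`gamma`); the
#' class-conditional kernel density estimates of the 1-D discriminant
#' score are compared by log-density ratio at threshold 0.
#'
#' @param erp_epochs An `rsvp_epochs` covering 0..+500 ms (2-45 Hz
#'   filtered in the reference pipeline), with all recorded channels.
#' @param cv_spec A [cv_spec()] list.
#' @param seed Integer seed.
#' @param channels Channels to include (default: all except `"POOL"`).
#' @param var_frac Variance fraction retained by the PCA step.
#' @param lambda,gamma RDA shrinkage parameters.
#' @return A `ClassifierResult` list (see [train_eval()]).
#' @export
rda_kde_eval <- function(erp_epochs, cv_spec = cv_spec(), seed = 1L,
                         channels = NULL, var_frac = 0.95,
                         lambda = 0.9, gamma = 0.1) {
  stopifnot(inherits(erp_epochs, "rsvp_epochs"))
  if (is.null(channels))
    channels <- setdiff(erp_epochs$channels, "POOL")
  ci <- match(channels, erp_epochs$channels)
  if (anyNA(ci)) stop("channel(s) not present")
  n_ep <- dim(erp_epochs$data)[1]
  n_s <- dim(erp_epochs$data)[3]
  X <- matrix(0, n_ep, length(ci) * n_s)
  for (j in seq_along(ci))
    X[, (j - 1) * n_s + seq_len(n_s)] <-
      matrix(erp_epochs$data[, ci[j], ], nrow = n_ep)
  feats <- new_features(X, erp_epochs$labels,
                        meta = list(n_channels = length(ci),
                                    n_samples = n_s, channels = channels))
  train_eval(feats, "rda_kde", cv_spec, seed,
             rda = list(var_frac = var_frac, lambda = lambda, gamma = gamma))
}
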