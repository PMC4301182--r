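# Internal Gaussian GLS machinery shared by the signal statistics and the
# PGLS fits. The error covariance is sigma2 * V(lambda), where V is the
# Brownian matrix of shared path lengths and V(lambda) multiplies the
# off-diagonal by lambda (diagonal intact). sigma2 is profiled out by ML
# (sigma2_hat = RSS_V / n).

# lambda-transformed covariance
lambda_vcv <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# Profile-ML GLS at fixed lambda. Returns NULL if V(lambda) is not
# positive definite (the caller shrinks its search bound).
gls_profile <- function(X, y, V, lambda) {
  Vl <- lambda_vcv(V, lambda)
  R <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  n <- length(y)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, yw)
  fitted_w <- Xw %*% beta
  resid_w <- yw - fitted_w
  rss <- sum(resid_w^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(R)))
  logL <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  # coefficient covariance with the usual residual-df variance estimate
  XtVX_inv <- chol2inv(qr.R(qrX)[, order(qrX$pivot), drop = FALSE])
  s2_df <- rss / max(n - ncol(X), 1)
  list(beta = beta, sigma2 = sigma2, rss = rss, logL = logL,
       logdetV = logdetV, vcov_beta = s2_df * XtVX_inv,
       resid = as.numeric(y - X %*% beta), lambda = lambda)
}

# Maximize the profile log-likelihood over lambda in [0, upper]. For
# ultrametric trees V(lambda) is positive definite on [0, 1]; if a
# proposed lambda gives a non-PD matrix the bound is shrunk, never a
# crash.
optimize_lambda <- function(X, y, V, upper = 1, tol = 1e-8) {
  obj <- function(l) {
    f <- gls_profile(X, y, V, l)
    if (is.null(f)) return(-Inf)
    f$logL
  }
  while (upper > 1e-4 && !is.finite(obj(upper))) upper <- upper * 0.95
  opt <- stats::optimize(obj, interval = c(0, upper), maximum = TRUE,
                         tol = tol)
  # the optimum may sit at a boundary that optimize() only approaches
  cand <- c(opt$maximum, 0, upper)
  ll <- vapply(cand, obj, numeric(1))
  cand[which.max(ll)]
}

# design matrix for a response ~ terms formula on a dataset; treatment
# coding with the reference level first alphabetically
build_design <- function(data, terms) {
  if (!length(terms)) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  df <- data
  for (cc in names(df))
    if (is.character(df[[cc]])) df[[cc]] <- factor(df[[cc]], sort(unique(df[[cc]])))
  stats::model.matrix(fml, df)
}
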