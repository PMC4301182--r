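# Independent oracles used to check the package's own implementations.
# Each one recomputes the target quantity by a different route (brute
# force, grid search, EM, numerical optimization) and must stay
# independent of the code path it validates.

# Shared path lengths between all tip pairs by explicit root-path
# enumeration (checks vcv_matrix).
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    # edges (as child-node ids) from tip back to root
    out <- integer(0)
    node <- tip
    while (node != root) {
      out <- c(out, node)
      node <- parent_of[node]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(len_of[shared])
    }
  V
}

# Intercept-only profile log-likelihood at a given lambda, computed with
# generic dense linear algebra (checks optimize_lambda / gls_profile).
dense_lambda_loglik <- function(tree, x, lambda) {
  V <- ape::vcv.phylo(tree)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  n <- length(x)
  Vi <- solve(Vl)
  mu <- sum(Vi %*% x[rownames(Vl)]) / sum(Vi)
  r <- x[rownames(Vl)] - mu
  s2 <- as.numeric(t(r) %*% Vi %*% r) / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) +
                       determinant(Vl)$modulus + n))
}

grid_search_lambda <- function(tree, x, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(l) dense_lambda_loglik(tree, x, l),
               numeric(1))
  grid[which.max(ll)]
}

# GLS coefficients by explicit whitening with an eigen square root
# (checks fit_pgls at fixed lambda).
whitened_ols <- function(X, y, V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  e <- eigen(Vl, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  stats::lm.fit(W %*% X, as.numeric(W %*% y))$coefficients
}

# Joint-ML ancestral states by numerical maximization of the full
# Brownian likelihood over all internal node states (checks
# ancestral_states). The argmax does not depend on the rate, so it is
# fixed at 1.
numopt_ancestral <- function(tree, x) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  obj <- function(a) {
    states <- c(x[tree$tip.label], a)
    d <- states[tree$edge[, 2]] - states[tree$edge[, 1]]
    sum(d^2 / tree$edge.length)
  }
  start <- rep(mean(x), m)
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  stats::setNames(fit$par, n + seq_len(m))
}

# EM algorithm for the nested random-effects ML fit (checks
# fit_nested_vc). Random effects are the missing data; mu is a fixed
# parameter updated in the M-step.
em_nested <- function(tab, trait = "value", genus = "genus",
                      species = "species", tol = 1e-10, maxit = 100000) {
  y <- tab[[trait]]
  g <- factor(tab[[genus]])
  sp <- factor(paste(tab[[genus]], tab[[species]], sep = "/"))
  G <- nlevels(g)
  S <- nlevels(sp)
  n <- length(y)
  Z <- cbind(stats::model.matrix(~ g - 1), stats::model.matrix(~ sp - 1))
  s2 <- rep(stats::var(y) / 3, 3)
  mu <- mean(y)
  ZtZ <- crossprod(Z)
  for (it in seq_len(maxit)) {
    Dinv <- diag(c(rep(1 / s2[1], G), rep(1 / s2[2], S)))
    A <- ZtZ / s2[3] + Dinv
    Ainv <- solve(A)
    b <- Ainv %*% crossprod(Z, y - mu) / s2[3]
    Eb2 <- as.numeric(b)^2 + diag(Ainv)
    r <- y - mu - Z %*% b
    s2_new <- c(mean(Eb2[seq_len(G)]),
                mean(Eb2[G + seq_len(S)]),
                (sum(r^2) + sum(Z * (Z %*% Ainv))) / n)
    mu_new <- mean(y - Z %*% b)
    delta <- max(abs(c(s2_new - s2, mu_new - mu)))
    s2 <- s2_new
    mu <- mu_new
    if (delta < tol) break
  }
  list(sigma2 = s2, mu = mu, iterations = it)
}

# lambda transform of a covariance matrix, re-stated locally
lambda_vcv_for_test <- function(V, lam) {
  Vl <- V * lam
  diag(Vl) <- diag(V)
  Vl
}

# Two-loop pooled SD of log10 values within samples (checks
# pooled_log_sd).
pooled_sd_loops <- function(values, ids) {
  lx <- log10(values)
  num <- 0
  den <- 0
  for (s in unique(ids)) {
    v <- lx[ids == s]
    if (length(v) >= 2) {
      for (r in v) num <- num + (r - mean(v))^2
      den <- den + length(v) - 1
    }
  }
  sqrt(num / den)
}
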