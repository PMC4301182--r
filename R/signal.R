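# Phylogenetic signal statistics for continuous traits: Blomberg's K with
# a tip-permutation test, Pagel's lambda by profile ML with a likelihood
# ratio test, and GLS (maximum likelihood) ancestral states under Brownian
# motion.

# match a named trait vector to tree tips
match_trait <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label))
      stop("unnamed trait vector must have one value per tip")
    names(x) <- tree$tip.label
    return(x)
  }
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips))
    stop("trait values missing for tips: ",
         paste(utils::head(missing_tips, 5), collapse = ", "))
  x[tree$tip.label]
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of the non-phylogenetic to the
#' phylogenetic mean squared error, `MSE0/MSE`, with its expectation under
#' Brownian motion on the given tree; K = 1 under Brownian evolution,
#' K < 1 means less signal than Brownian motion, K > 1 more. The p-value
#' permutes trait values across tips and asks how often the phylogenetic
#' MSE of a permutation is at most the observed one (small observed MSE =
#' strong signal), with the +1 correction
#' `p = (1 + #permuted MSE <= observed) / (n_perm + 1)`.
#'
#' @param tree An ultrametric `"phylo"` tree (n >= 3 tips).
#' @param x Named numeric trait vector (names = tip labels), typically on
#'   the log scale.
#' @param n_perm Number of permutations; 0 skips the test (`p = NA`).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `"blomberg_k"`: list with `K`, `p`,
#'   `n_perm`, `seed`, `n`.
#' @examples
#' tr <- simulate_tree(20, seed = 1)
#' x <- simulate_bm_trait(tr, sigma2 = 0.01, seed = 2)
#' blomberg_k(tr, x, n_perm = 99, seed = 3)
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = NULL) {
  x <- match_trait(tree, x)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  if (stats::sd(x) == 0)
    stop("trait is constant across tips; K is undefined")
  V <- vcv_matrix(tree)
  Vi <- chol2inv(chol(V))
  ones <- rep(1, n)
  s_all <- sum(Vi)
  wa <- colSums(Vi) / s_all              # weights giving the GLS mean
  mse_of <- function(y) {
    a <- sum(wa * y)
    r <- y - a
    sum(r * (Vi %*% r)) / (n - 1)
  }
  a_hat <- sum(wa * x)
  mse0 <- sum((x - a_hat)^2) / (n - 1)
  mse <- mse_of(x)
  expected <- (sum(diag(V)) - n / s_all) / (n - 1)
  K <- (mse0 / mse) / expected

  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(n_perm, sample(x))
    # vectorized permutation MSEs
    a_perm <- crossprod(wa, perm)[1, ]
    Rm <- sweep(perm, 2, a_perm, "-")
    mse_perm <- colSums(Rm * (Vi %*% Rm)) / (n - 1)
    p <- (1 + sum(mse_perm <= mse)) / (n_perm + 1)
  } else {
    p <- NA_real_   # statistic only, no test
  }
  structure(list(K = K, p = p, MSE = mse, MSE0 = mse0,
                 n_perm = n_perm, seed = seed, n = n),
            class = "blomberg_k")
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4g (p = %.4g, %d permutations, n = %d)\n",
              x$K, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Pagel's lambda by maximum likelihood
#'
#' Estimates the branch-length transformation lambda that scales the
#' off-diagonal of the Brownian covariance matrix, by maximizing the
#' profile Gaussian log-likelihood of an intercept-only GLS model over
#' `[0, 1]` (1 is the upper bound keeping V(lambda) positive definite on
#' ultrametric trees). The p-value is a likelihood-ratio test of
#' lambda-hat against lambda = 0 on chi-square(1); no boundary correction
#' is applied, which is conservative when the truth sits at lambda = 0.
#'
#' @inheritParams blomberg_k
#' @return An object of class `"pagel_lambda"`: list with `lambda`,
#'   `logL`, `logL0` (at lambda = 0), `p`, `sigma2`, `n`.
#' @examples
#' tr <- simulate_tree(30, seed = 1)
#' x <- simulate_bm_trait(tr, sigma2 = 0.01, seed = 2)
#' pagel_lambda_ml(tr, x)
#' @export
pagel_lambda_ml <- function(tree, x) {
  x <- match_trait(tree, x)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  if (stats::sd(x) == 0)
    stop("trait is constant across tips; lambda is undefined")
  V <- vcv_matrix(tree)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  lam <- optimize_lambda(X, x, V)
  fit <- gls_profile(X, x, V, lam)
  fit0 <- gls_profile(X, x, V, 0)
  lr <- 2 * (fit$logL - fit0$logL)
  p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  structure(list(lambda = lam, logL = fit$logL, logL0 = fit0$logL,
                 p = p, sigma2 = fit$sigma2, n = n),
            class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda = %.4g (logL = %.4g, logL[lambda=0] = %.4g, LR p = %.4g)\n",
    x$lambda, x$logL, x$logL0, x$p))
  invisible(x)
}

#' Maximum likelihood ancestral states for a continuous trait
#'
#' Under Brownian motion the joint-ML estimate at internal node k is the
#' GLS prediction
#' `a_k = a_root + C_k V^-1 (y - a_root 1)`,
#' where `a_root` is the GLS mean at the root and `C_k` holds the shared
#' path lengths (root-to-MRCA) between node k and each tip. Estimates are
#' affine-equivariant in the trait.
#'
#' @inheritParams blomberg_k
#' @param x Named trait vector on the analysis (log) scale.
#' @return Named numeric vector of estimates for internal nodes, names
#'   being ape node numbers (`n+1` is the root).
#' @export
ancestral_states <- function(tree, x) {
  x <- match_trait(tree, x)
  n <- length(x)
  if (n < 2) stop("need at least 2 tips")
  V <- vcv_matrix(tree)
  Vi <- chol2inv(chol(V))
  a_root <- sum(colSums(Vi) * x) / sum(Vi)
  depths <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)   # over tips + internal nodes
  internal <- n + seq_len(tree$Nnode)
  C <- matrix(depths[M[internal, seq_len(n)]], nrow = tree$Nnode)
  est <- a_root + as.numeric(C %*% (Vi %*% (x - a_root)))
  names(est) <- internal
  est
}
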