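# Gaussian process regression engine: isotropic RBF kernel plus white
# noise, hyperparameters by marginal-likelihood maximization (L-BFGS-B on
# log-parameters, analytic gradients, seeded multi-start).  Inputs are
# assumed already standardized by the caller.

.sq_dist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

.gp_nll <- function(theta, D2, y) {
  n <- length(y)
  Kf <- exp(theta[1]) * exp(-0.5 * D2 / exp(theta[2]))
  K <- Kf + diag(exp(theta[3]) + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = c(0, 0, 0)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- Kinv - tcrossprod(alpha)      # d nll / dK = W / 2
  g <- c(0.5 * sum(W * Kf),
         0.5 * sum(W * (Kf * 0.5 * D2 / exp(theta[2]))),
         0.5 * sum(diag(W)) * exp(theta[3]))
  list(value = nll, grad = g)
}

# Fit on standardized X (n x d) and y (centered, unit variance).
.gp_fit <- function(X, y, seed = 1L, n_restarts = 5L, maxit = 80L) {
  D2 <- .sq_dist(X)
  med_d2 <- median(D2[upper.tri(D2)])
  if (!is.finite(med_d2) || med_d2 <= 0) med_d2 <- 1
  base <- c(log(max(var(y), 1e-3)), log(med_d2), log(0.1 * max(var(y), 1e-3)))
  lower <- c(-8, log(med_d2) - 6, log(1e-6))
  upper <- c(6, log(med_d2) + 6, 4)
  starts <- .with_seed(seed, lapply(seq_len(n_restarts), function(r) {
    if (r == 1L) base else base + rnorm(3, 0, 1)
  }))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(th0, lower), upper),
            fn = function(th) .gp_nll(th, D2, y)$value,
            gr = function(th) .gp_nll(th, D2, y)$grad,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed for all starts")
  theta <- best$par
  n <- length(y)
  K <- exp(theta[1]) * exp(-0.5 * D2 / exp(theta[2])) +
    diag(exp(theta[3]) + 1e-10, n)
  L <- chol(K)                         # upper triangular, K = t(L) %*% L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  list(theta = setNames(theta, c("log_sf2", "log_ell2", "log_sn2")),
       L = L, alpha = alpha, nll = best$value)
}

# Posterior predictive mean and SD (including the noise term) at Xs.
.gp_predict <- function(fit, X, Xs) {
  D2s <- .sq_dist(Xs, X)
  Ks <- exp(fit$theta[["log_sf2"]]) * exp(-0.5 * D2s / exp(fit$theta[["log_ell2"]]))
  mu <- drop(Ks %*% fit$alpha)
  V <- forwardsolve(t(fit$L), t(Ks))   # solves t(L) V = t(Ks)
  var_f <- exp(fit$theta[["log_sf2"]]) - colSums(V^2)
  var_y <- pmax(var_f, 0) + exp(fit$theta[["log_sn2"]])
  list(mean = mu, sd = sqrt(var_y))
}
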