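## Independent oracles used across the suite.  These deliberately avoid the
## package's own algorithms: d-separation is checked by literal path
## blocking over every enumerated path, and the Savage-Dickey Bayes factor
## by numerical quadrature of the two marginal likelihoods.

## Node sequence of a path as returned by enumerate_paths()
path_nodes <- function(p, x) {
  v <- x
  for (i in seq_len(nrow(p)))
    v <- c(v, if (p$forward[i]) p$to[i] else p$from[i])
  v
}

## Literal reading of the d-separation definition: a path is blocked by z
## iff it has a chain/fork middle node in z, or a collider middle node
## with no descendant (itself included) in z.
oracle_path_blocked <- function(g, p, x, z) {
  if (nrow(p) < 2L) return(FALSE)          # single edge: no middle node
  v <- path_nodes(p, x)
  for (k in 2:(length(v) - 1L)) {
    into_left <- p$forward[k - 1L]          # edge v[k-1]-v[k] points into v[k]
    into_right <- !p$forward[k]             # edge v[k]-v[k+1] points into v[k]
    collider <- into_left && into_right
    if (!collider && v[k] %in% z) return(TRUE)
    if (collider &&
        !(v[k] %in% z) &&
        !any(descendants_of(g, v[k]) %in% z)) return(TRUE)
  }
  FALSE
}

oracle_d_separated <- function(g, x, y, z = character()) {
  paths <- enumerate_paths(g, x, y)
  all(vapply(paths, oracle_path_blocked, logical(1), g = g, x = x, z = z))
}

## All subsets (including the empty set) of a node pool
subsets_of <- function(pool) {
  out <- list(character())
  for (k in seq_along(pool))
    out <- c(out, utils::combn(pool, k, simplify = FALSE))
  out
}

## Random DAG on n nodes: random topological order, independent edges.
random_dag <- function(n_nodes, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  labels <- LETTERS[seq_len(n_nodes)]
  order <- sample(labels)
  edges <- list()
  for (i in seq_len(n_nodes - 1L))
    for (j in (i + 1L):n_nodes)
      if (stats::runif(1) < p_edge)
        edges[[length(edges) + 1L]] <- c(order[i], order[j])
  dag(labels, edges)
}

## Partial correlation of x and y given z, from a covariance matrix.
pcor_from_cov <- function(S, x, y, z = character()) {
  idx <- c(x, y, z)
  P <- solve(S[idx, idx, drop = FALSE])
  -P[x, y] / sqrt(P[x, x] * P[y, y])
}

## log of trapezoid-rule integral given log integrand values on a uniform grid
log_trapez <- function(logf, h) {
  w <- rep(1, length(logf)); w[c(1L, length(logf))] <- 0.5
  m <- max(logf)
  m + log(sum(w * exp(logf - m))) + log(h)
}

## Quadrature Bayes factor BF01 for the coefficient of `regressor`, under
## the same model as bf01(): fixed residual variance from the full-model
## OLS fit, flat intercept, N(0, prior_sd^2) priors on all slopes.
## Supports zero or one adjustment covariates (2D / 3D quadrature).
quad_bf01 <- function(data, outcome, regressor, adjustment = character(),
                      prior_sd = 1, K = 201L, width = 12) {
  stopifnot(length(adjustment) <= 1L)
  y <- data[, outcome]
  n <- length(y)
  preds <- c(regressor, adjustment)
  X <- cbind(1, data[, preds, drop = FALSE])
  fit <- lm.fit(X, y)
  sigma2 <- sum(fit$residuals^2) / (n - ncol(X))

  grid_for <- function(Xm) {
    f <- lm.fit(Xm, y)
    s2 <- sum(f$residuals^2) / max(n - ncol(Xm), 1L)
    se <- sqrt(diag(chol2inv(chol(crossprod(Xm)))) * s2)
    lapply(seq_len(ncol(Xm)), function(j) {
      lo <- min(0, f$coefficients[j]) - width * se[j] - 0.5
      hi <- max(0, f$coefficients[j]) + width * se[j] + 0.5
      seq(lo, hi, length.out = K)
    })
  }

  loglik <- function(Xm, coefs) {
    ## coefs: list of grids, one per column of Xm; returns log-likelihood
    ## array over the grid via the quadratic sufficient statistics
    XtX <- crossprod(Xm); Xty <- drop(crossprod(Xm, y)); yty <- sum(y * y)
    dims <- lengths(coefs)
    idx <- as.matrix(expand.grid(lapply(dims, seq_len)))
    B <- mapply(function(g, k) g[idx[, k]], coefs, seq_along(coefs))
    B <- matrix(B, ncol = length(coefs))
    sse <- yty - 2 * (B %*% Xty) + rowSums((B %*% XtX) * B)
    array(-n / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2), dim = dims)
  }

  marginal <- function(cols, penalized) {
    Xm <- cbind(1, data[, cols, drop = FALSE])
    grids <- grid_for(Xm)
    ll <- loglik(Xm, grids)
    for (j in seq_along(penalized)) {
      if (penalized[j])
        ll <- sweep(ll, j, stats::dnorm(grids[[j]], 0, prior_sd, log = TRUE), "+")
    }
    ## integrate out dimensions one at a time, last dimension first
    for (d in rev(seq_along(grids))) {
      h <- diff(grids[[d]][1:2])
      ll <- if (d == 1L) log_trapez(as.vector(ll), h)
            else apply(ll, seq_len(d - 1L), log_trapez, h = h)
    }
    ll
  }

  log_m1 <- marginal(preds, c(FALSE, rep(TRUE, length(preds))))
  log_m0 <- if (length(adjustment))
    marginal(adjustment, c(FALSE, TRUE))
  else {
    Xm <- matrix(1, n, 1L)
    grids <- grid_for(Xm)
    log_trapez(drop(loglik(Xm, grids)), diff(grids[[1L]][1:2]))
  }
  exp(log_m0 - log_m1)
}

## Fixed fixture datasets for the quadrature cross-check: single regressor,
## varying sample size, slope and noise scale.
bf_fixture_datasets <- function() {
  out <- list()
  specs <- expand.grid(n = c(8, 12, 15, 20, 30),
                       slope = c(0, 0.3, 0.9, 2),
                       KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(specs))) {
    set.seed(100 + i)
    n <- specs$n[i]
    x <- rnorm(n)
    y <- 0.5 + specs$slope[i] * x + rnorm(n, sd = 0.8)
    out[[i]] <- cbind(X = x, Y = y)
  }
  out
}
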