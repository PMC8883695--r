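#' Linear Gaussian Markovian structural causal model
#'
#' Each node is a linear function of its graph parents plus an independent
#' Gaussian error: `V = sum_p coef[p -> V] * p + U_V`, `U_V ~ N(0, sd_V^2)`.
#' Errors are mutually independent by construction (Markovian); no error
#' covariance parameters exist.
#'
#' @param g a [dag()].
#' @param coef named numeric vector of structural coefficients, one per
#'   edge, named `"from->to"`; or a numeric vector in `g$edges` row order.
#' @param error_sd positive error standard deviations: a single value
#'   recycled to all nodes, or a named vector over `g$nodes`.  Default 1.
#' @return an object of class `linear_scm`.
#' @export
linear_scm <- function(g, coef, error_sd = 1) {
  stopifnot(inherits(g, "dag"))
  keys <- edge_keys(g)
  if (is.null(names(coef))) {
    if (length(coef) != nrow(g$edges))
      stop("'coef' must supply one coefficient per edge")
    names(coef) <- keys
  } else if (!setequal(names(coef), keys) || length(coef) != length(keys)) {
    stop("'coef' names must match the graph edges exactly: ",
         paste(keys, collapse = ", "))
  }
  coef <- coef[keys]
  if (length(error_sd) == 1L && is.null(names(error_sd)))
    error_sd <- stats::setNames(rep(error_sd, length(g$nodes)), g$nodes)
  if (!setequal(names(error_sd), g$nodes))
    stop("'error_sd' must be named over all graph nodes")
  error_sd <- error_sd[g$nodes]
  if (any(!is.finite(error_sd)) || any(error_sd <= 0))
    stop("'error_sd' must be strictly positive")
  structure(list(dag = g, coef = coef, error_sd = error_sd),
            class = "linear_scm")
}

#' @export
print.linear_scm <- function(x, ...) {
  cat("linear Gaussian SCM on nodes:", paste(x$dag$nodes, collapse = ", "), "\n")
  if (length(x$coef))
    cat(paste0("  ", names(x$coef), "  coef = ", format(x$coef), collapse = "\n"), "\n")
  cat("  error sd:", paste(paste0(names(x$error_sd), "=", x$error_sd), collapse = ", "), "\n")
  invisible(x)
}

#' Confounder and collider model constructors
#'
#' `confounder_model()` builds the treatment/outcome/confounder SCM
#' `C = U_C`, `X = beta C + U_X`, `Y = alpha X + gamma C + U_Y`.
#' `collider_model()` builds the collider SCM `C = alpha X + beta W + U_C`,
#' `Y = gamma C + U_Y` with exogenous `X` and `W`.  All error terms are
#' standard normal by default.
#'
#' @param alpha,beta,gamma structural coefficients (see above for which
#'   edge each labels in the two motifs).
#' @param error_sd error standard deviations, as in [linear_scm()].
#' @return a [linear_scm()].
#' @examples
#' confounder_model(0.25, 0.25, 0.25)  # the balanced confounder
#' collider_model(1/3, 2/3, 0.25)      # an unbalanced collider
#' @export
confounder_model <- function(alpha, beta, gamma, error_sd = 1) {
  linear_scm(confounder_dag(),
             c("C->X" = beta, "X->Y" = alpha, "C->Y" = gamma), error_sd)
}

#' @rdname confounder_model
#' @export
collider_model <- function(alpha, beta, gamma, error_sd = 1) {
  linear_scm(collider_dag(),
             c("X->C" = alpha, "W->C" = beta, "C->Y" = gamma), error_sd)
}

topological_order <- function(g) {
  order <- character()
  nodes <- g$nodes
  em <- g$edges
  while (length(nodes)) {
    sources <- setdiff(nodes, em[, 2L])
    order <- c(order, sources)
    nodes <- setdiff(nodes, sources)
    em <- em[!(em[, 1L] %in% sources), , drop = FALSE]
  }
  order
}

#' Draw samples from a linear SCM
#'
#' Rows are drawn by evaluating the structural equations in topological
#' order with fresh independent Gaussian errors.
#'
#' @param m a [linear_scm()].
#' @param n number of rows (>= 1).
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return an `n x p` numeric matrix with one column per observable node,
#'   in graph node order.
#' @export
simulate_scm <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "linear_scm"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive sample count")
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  g <- m$dag
  out <- matrix(0, n, length(g$nodes), dimnames = list(NULL, g$nodes))
  for (node in topological_order(g)) {
    val <- stats::rnorm(n, sd = m$error_sd[[node]])
    for (pa in parents_of(g, node))
      val <- val + m$coef[[paste0(pa, "->", node)]] * out[, pa]
    out[, node] <- val
  }
  out
}

#' Exact covariance matrix implied by a linear SCM
#'
#' With `B[i, j]` the coefficient on edge `i -> j` and `D` the diagonal
#' matrix of squared error standard deviations, the observable vector has
#' covariance `(I - B')^{-1} D (I - B')^{-T}`.
#'
#' @param m a [linear_scm()].
#' @return a `p x p` covariance matrix over the observable nodes.
#' @export
implied_covariance <- function(m) {
  stopifnot(inherits(m, "linear_scm"))
  g <- m$dag
  p <- length(g$nodes)
  B <- matrix(0, p, p, dimnames = list(g$nodes, g$nodes))
  for (i in seq_len(nrow(g$edges)))
    B[g$edges[i, 1L], g$edges[i, 2L]] <- m$coef[[i]]
  ImBt <- diag(p) - t(B)
  inv <- solve(ImBt)
  S <- inv %*% diag(m$error_sd^2, p) %*% t(inv)
  dimnames(S) <- list(g$nodes, g$nodes)
  S
}

#' True causal effects by path tracing
#'
#' The average causal effect of `x` on `y` is the sum over all directed
#' paths from `x` to `y` of the product of structural coefficients along
#' the path (Wright's path tracing); the direct effect is the coefficient
#' on the edge `x -> y` if present (else 0), and the indirect effect is
#' their difference, so that `ace = de + ie` holds exactly.
#'
#' @param m a [linear_scm()].
#' @param x,y distinct node labels.
#' @return an object of class `effect_triple`: a list with numeric
#'   components `ace`, `de`, `ie`.
#' @examples
#' true_effects(confounder_model(0.25, 1, 1), "X", "Y")  # ace = de = 0.25
#' true_effects(collider_model(0.5, 0.5, 0.5), "X", "Y") # ace = ie = 0.25
#' @export
true_effects <- function(m, x, y) {
  stopifnot(inherits(m, "linear_scm"))
  paths <- directed_paths(m$dag, x, y)
  ace <- 0
  for (p in paths)
    ace <- ace + prod(m$coef[paste0(p$from, "->", p$to)])
  de <- if (has_edge(m$dag, x, y)) m$coef[[paste0(x, "->", y)]] else 0
  effect_triple(ace, de, ace - de)
}

effect_triple <- function(ace, de, ie) {
  structure(list(ace = ace, de = de, ie = ie), class = "effect_triple")
}

#' @export
print.effect_triple <- function(x, ...) {
  cat(sprintf("ACE = %s, DE = %s, IE = %s\n",
              format(x$ace), format(x$de), format(x$ie)))
  invisible(x)
}

#' Column-wise z-scoring of a sample matrix
#'
#' Rescales every column to mean 0 and standard deviation 1.  Used for the
#' optional sensitivity analysis in which each simulated dataset is
#' standardized before the regressions are run.
#'
#' @param data a numeric sample matrix with named columns.
#' @return the standardized matrix.
#' @export
standardize_sample <- function(data) {
  scaled <- scale(data)
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  scaled
}
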