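#' Testable implications of the two motifs
#'
#' Each implication is a statement about a partial regression coefficient:
#' the confounder motif entails three non-vanishing coefficients
#' (`b_YX.C`, `b_YC.X`, `b_XC`; the X-C implication is tested marginally so
#' as not to open the collider at Y), while the collider motif entails six
#' implications, three vanishing (`b_YX.C`, `b_YW.C`, `b_WX`) and three
#' non-vanishing (`b_CW.XY`, `b_CX.WY`, `b_YC.WX`).  The seventh candidate
#' `b_WX.C != 0` is superfluous: its information is already carried by
#' `b_WX` and `b_CW.XY`, so it is excluded.
#'
#' @return a data frame with one row per implication and columns `label`,
#'   `outcome`, `regressor`, `adjustment` (list column of character
#'   vectors) and `expected` (`"zero"` or `"nonzero"`).
#' @examples
#' confounder_implications()
#' nrow(collider_implications())  # 6
#' @export
confounder_implications <- function() {
  data.frame(
    label = c("b_YX.C", "b_YC.X", "b_XC"),
    outcome = c("Y", "Y", "X"),
    regressor = c("X", "C", "C"),
    adjustment = I(list("C", "X", character())),
    expected = c("nonzero", "nonzero", "nonzero"),
    stringsAsFactors = FALSE)
}

#' @rdname confounder_implications
#' @export
collider_implications <- function() {
  data.frame(
    label = c("b_YX.C", "b_YW.C", "b_CW.XY", "b_WX", "b_CX.WY", "b_YC.WX"),
    outcome = c("Y", "Y", "C", "W", "C", "Y"),
    regressor = c("X", "W", "W", "X", "X", "C"),
    adjustment = I(list("C", "C", c("X", "Y"), character(),
                        c("W", "Y"), c("W", "X"))),
    expected = c("zero", "zero", "nonzero", "zero", "nonzero", "nonzero"),
    stringsAsFactors = FALSE)
}

motif_implications <- function(motif) {
  switch(motif,
         confounder = confounder_implications(),
         collider = collider_implications(),
         stop("unknown motif: ", motif))
}

motif_dag <- function(motif) {
  switch(motif,
         confounder = confounder_dag(),
         collider = collider_dag(),
         stop("unknown motif: ", motif))
}

## label -> DAG edit, per motif.  Violating an expected-nonzero implication
## deletes the corresponding arrow; violating an expected-zero implication
## adds an arrow whose orientation is fixed by subject-domain/temporal
## knowledge (W -> X, W -> Y, X -> Y).
edit_map <- list(
  confounder = list(
    "b_YX.C" = list(op = "delete", from = "X", to = "Y"),
    "b_YC.X" = list(op = "delete", from = "C", to = "Y"),
    "b_XC"   = list(op = "delete", from = "C", to = "X")),
  collider = list(
    "b_YX.C"  = list(op = "add",    from = "X", to = "Y"),
    "b_YW.C"  = list(op = "add",    from = "W", to = "Y"),
    "b_WX"    = list(op = "add",    from = "W", to = "X"),
    "b_CW.XY" = list(op = "delete", from = "W", to = "C"),
    "b_CX.WY" = list(op = "delete", from = "X", to = "C"),
    "b_YC.WX" = list(op = "delete", from = "C", to = "Y")))

#' Modify a motif's DAG according to a violation pattern
#'
#' Applies the rule-based edits that an investigator who trusts the data
#' over the hypothesized model would make: a violated non-vanishing
#' implication deletes the corresponding arrow, a violated vanishing
#' implication adds an arrow whose direction is fixed by assumption
#' (`W -> X`, `W -> Y`, `X -> Y` for the collider motif).  Edits are
#' set-based on disjoint edges, so they commute, and the empty pattern is
#' the identity.
#'
#' @param motif `"confounder"` or `"collider"`.
#' @param violated character vector of violated implication labels (a
#'   subset of the motif's labels; possibly empty).
#' @return the modified [dag()].
#' @examples
#' apply_edits("confounder", c("b_YC.X", "b_XC"))  # only X -> Y remains
#' apply_edits("collider", "b_CX.WY")              # X -> C removed
#' @export
apply_edits <- function(motif, violated = character()) {
  motif <- match.arg(motif, c("confounder", "collider"))
  rules <- edit_map[[motif]]
  unknown <- setdiff(violated, names(rules))
  if (length(unknown))
    stop("unknown implication label(s): ", paste(unknown, collapse = ", "))
  g <- motif_dag(motif)
  for (lab in names(rules)) {          # fixed order: edits commute anyway
    if (!(lab %in% violated)) next
    r <- rules[[lab]]
    g <- if (r$op == "delete") delete_edge(g, r$from, r$to)
         else add_edge(g, r$from, r$to)
  }
  g
}

#' Estimand plan for the causal effects on a (possibly modified) DAG
#'
#' Derives how ACE, DE and IE of `x` on `y` are to be estimated on the
#' given DAG: the ACE is the sum over directed `x -> y` paths of the
#' product of edge coefficients, each edge coefficient identified by its
#' minimal single-door adjustment set; the DE is the coefficient on the
#' edge `x -> y` when present (else exactly 0); IE = ACE - DE.
#'
#' @param g a [dag()] (typically the output of [apply_edits()]).
#' @param x,y treatment and outcome node labels.
#' @return a list of class `estimand_plan` with components `dag`, `x`, `y`,
#'   `paths` (list of paths, each a character matrix of edges), `edges`
#'   (data frame of the distinct edges needing estimation, with list column
#'   `adjustment`), `de_edge` (`NULL` or row index into `edges`) and
#'   `identifiable`.
#' @export
estimand_plan <- function(g, x = "X", y = "Y") {
  check_node(g, x, y)
  paths <- directed_paths(g, x, y)
  edge_key <- character()
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  adj <- list()
  identifiable <- TRUE
  for (p in paths) {
    for (i in seq_len(nrow(p))) {
      key <- paste0(p$from[i], "->", p$to[i])
      if (key %in% edge_key) next
      z <- single_door_set(g, p$from[i], p$to[i])
      edge_key <- c(edge_key, key)
      edges <- rbind(edges, data.frame(from = p$from[i], to = p$to[i],
                                       stringsAsFactors = FALSE))
      adj[[length(adj) + 1L]] <- z
      if (is.null(z)) identifiable <- FALSE
    }
  }
  de_edge <- NULL
  if (has_edge(g, x, y)) {
    key <- paste0(x, "->", y)
    de_edge <- match(key, edge_key)   # always on a directed path, so present
  }
  edges$adjustment <- I(adj)
  structure(list(dag = g, x = x, y = y, paths = paths, edges = edges,
                 edge_key = edge_key, de_edge = de_edge,
                 identifiable = identifiable),
            class = "estimand_plan")
}

#' @export
print.estimand_plan <- function(x, ...) {
  cat("estimand plan for ACE(", x$x, ",", x$y, ") on:\n", sep = "")
  print(x$dag)
  if (!length(x$paths)) {
    cat("  no directed path: ACE = DE = IE = 0\n")
  } else {
    for (i in seq_len(nrow(x$edges))) {
      z <- x$edges$adjustment[[i]]
      cat(sprintf("  %s -> %s | {%s}\n", x$edges$from[i], x$edges$to[i],
                  paste(z, collapse = ", ")))
    }
  }
  if (!x$identifiable) cat("  NOT identifiable from observables\n")
  invisible(x)
}

#' Estimate causal effects on data according to an estimand plan
#'
#' Every edge coefficient in the plan is estimated as the posterior mean of
#' the Bayesian regression of the edge's child on its parent plus the
#' plan's single-door adjustment set; ACE, DE and IE are then assembled by
#' path tracing.  Components the plan declares absent are exactly 0.
#'
#' @param data numeric sample matrix with named columns.
#' @param plan an [estimand_plan()]; must be identifiable.
#' @param prior_sd prior standard deviation of the regression slopes.
#' @return an `effect_triple` with components `ace`, `de`, `ie`.
#' @export
estimate_effects <- function(data, plan, prior_sd = 1) {
  stopifnot(inherits(plan, "estimand_plan"))
  if (!plan$identifiable)
    stop("plan is not identifiable from the observable nodes")
  if (!length(plan$paths)) return(effect_triple(0, 0, 0))
  coefs <- numeric(nrow(plan$edges))
  for (i in seq_len(nrow(plan$edges))) {
    fit <- bayes_linreg(data, outcome = plan$edges$to[i],
                        regressor = plan$edges$from[i],
                        adjustment = plan$edges$adjustment[[i]],
                        prior_sd = prior_sd)
    coefs[i] <- fit$post_mean[[plan$edges$from[i]]]
  }
  names(coefs) <- plan$edge_key
  ace <- 0
  for (p in plan$paths)
    ace <- ace + prod(coefs[paste0(p$from, "->", p$to)])
  de <- if (is.null(plan$de_edge)) 0 else coefs[[plan$de_edge]]
  effect_triple(ace, de, ace - de)
}

#' Symbolic estimand lookup for the eight confounder violation patterns
#'
#' Case enumeration for the confounder motif: any violation of `b_YX.C`
#' removes the treatment arrow and zeroes all effects; otherwise a
#' violation of `b_YC.X` or `b_XC` de-identifies the confounder and the
#' effect is the unadjusted `b_YX`; with no violation the effect is the
#' C-adjusted `b_YX.C`.  In every case ACE = DE and IE = 0.  Used to
#' cross-validate the generic estimand engine.
#'
#' @param violated character vector of violated confounder implication
#'   labels.
#' @return a list with `ace` (one of `"zero"`, `"b_YX"`, `"b_YX.C"`), `de`
#'   (always equal to `ace`) and `ie` (always `"zero"`).
#' @export
confounder_case_table <- function(violated = character()) {
  labels <- confounder_implications()$label
  unknown <- setdiff(violated, labels)
  if (length(unknown))
    stop("unknown implication label(s): ", paste(unknown, collapse = ", "))
  ace <- if ("b_YX.C" %in% violated) "zero"
         else if (any(c("b_YC.X", "b_XC") %in% violated)) "b_YX"
         else "b_YX.C"
  list(ace = ace, de = ace, ie = "zero")
}
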