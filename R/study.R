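#' Specify one Monte Carlo study setting
#'
#' A setting fixes the data-generating motif, its structural coefficients,
#' the per-variable sample size, the number of Monte Carlo replicates and
#' the master seed.  Per-replicate seeds are derived deterministically from
#' the master seed and the replicate index, so any single replicate is
#' reproducible in isolation and extending `reps` leaves earlier replicates
#' unchanged.
#'
#' @param motif `"confounder"` or `"collider"`.
#' @param alpha,beta,gamma structural coefficients (see
#'   [confounder_model()] / [collider_model()] for the edge each labels).
#' @param n per-variable sample size of each simulated dataset.
#' @param reps number of Monte Carlo replicates.
#' @param master_seed integer master seed for the whole study.
#' @param standardize z-score each simulated dataset before analysis
#'   (sensitivity option; default `FALSE`, i.e. raw simulated scale).
#' @param prior_sd prior standard deviation of the regression slopes.
#' @return a list of class `study_setting`.
#' @export
study_setting <- function(motif, alpha, beta, gamma, n = 100, reps = 2000,
                          master_seed = 1, standardize = FALSE,
                          prior_sd = 1) {
  motif <- match.arg(motif, c("confounder", "collider"))
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (!is.numeric(n) || n < 10) stop("'n' must be a sample size >= 10")
  if (!is.numeric(reps) || reps < 1) stop("'reps' must be >= 1")
  if (!is.numeric(prior_sd) || prior_sd <= 0) stop("'prior_sd' must be positive")
  structure(list(motif = motif, alpha = alpha, beta = beta, gamma = gamma,
                 n = as.integer(n), reps = as.integer(reps),
                 master_seed = as.integer(master_seed),
                 standardize = isTRUE(standardize), prior_sd = prior_sd),
            class = "study_setting")
}

setting_model <- function(setting) {
  switch(setting$motif,
         confounder = confounder_model(setting$alpha, setting$beta, setting$gamma),
         collider = collider_model(setting$alpha, setting$beta, setting$gamma))
}

replicate_seed <- function(master_seed, index) {
  ## counter-based derivation in double arithmetic; stays below 2^31
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(index) * 9973) %%
               2147483629)
}

#' Run a single Monte Carlo replicate
#'
#' Pipeline: simulate one dataset from the true model, test every testable
#' implication with the Bayes factor at threshold 1, collect the violation
#' pattern, modify the DAG by the motif's edit rules, derive the estimand
#' plan on the modified DAG and estimate ACE, DE and IE from the same
#' dataset.  Deterministic given `(master_seed, index)`.
#'
#' @param setting a [study_setting()].
#' @param index replicate index (1-based).
#' @return a one-row data frame with the replicate index, the violation
#'   pattern (semicolon-joined labels), the modified DAG (edge-list
#'   string), identifiability, the estimated `ace`, `de`, `ie` and one
#'   `bf_<label>` column per implication.
#' @export
run_replicate <- function(setting, index) {
  stopifnot(inherits(setting, "study_setting"))
  data <- simulate_scm(setting_model(setting), setting$n,
                       seed = replicate_seed(setting$master_seed, index))
  if (setting$standardize) data <- standardize_sample(data)
  imps <- motif_implications(setting$motif)
  violated <- logical(nrow(imps))
  bf <- numeric(nrow(imps))
  for (i in seq_len(nrow(imps))) {
    chk <- check_implication(data, imps$outcome[i], imps$regressor[i],
                             imps$adjustment[[i]], imps$expected[i],
                             prior_sd = setting$prior_sd)
    violated[i] <- chk$violated
    bf[i] <- chk$detail$bf01
  }
  pattern <- imps$label[violated]
  g2 <- apply_edits(setting$motif, pattern)
  plan <- estimand_plan(g2, "X", "Y")
  if (plan$identifiable) {
    eff <- estimate_effects(data, plan, prior_sd = setting$prior_sd)
  } else {
    eff <- effect_triple(NA_real_, NA_real_, NA_real_)
  }
  rec <- data.frame(rep = as.integer(index),
                    pattern = paste(pattern, collapse = ";"),
                    modified_dag = paste(edge_keys(g2), collapse = ";"),
                    identifiable = plan$identifiable,
                    ace = eff$ace, de = eff$de, ie = eff$ie,
                    stringsAsFactors = FALSE)
  bf_cols <- as.data.frame(as.list(bf))
  names(bf_cols) <- paste0("bf_", imps$label)
  cbind(rec, bf_cols)
}

#' Run a Monte Carlo study for one setting
#'
#' Aggregates [run_replicate()] over all replicates.  The causal
#' false-positive risk (FPR) is the fraction of replicates with at least
#' one violated testable implication; effect means average over all
#' replicates with identifiable effects (zero-valued estimands enter as
#' 0), with Monte Carlo standard errors reported alongside.
#'
#' @param setting a [study_setting()].
#' @param keep_records keep the per-replicate data frame in the result
#'   (default `TRUE`).
#' @return a list of class `study_result` with components `setting`,
#'   `fpr`, `fpr_se`, `mean_ace`, `mean_de`, `mean_ie`, matching `se_*`
#'   Monte Carlo standard errors, `true_ace`, `true_de`, `true_ie`,
#'   `pattern_frequencies` (named counts summing to `reps`),
#'   `undefined_count` and (optionally) `records`.
#' @export
run_study <- function(setting, keep_records = TRUE) {
  stopifnot(inherits(setting, "study_setting"))
  records <- do.call(rbind, lapply(seq_len(setting$reps), run_replicate,
                                   setting = setting))
  truth <- true_effects(setting_model(setting), "X", "Y")
  ok <- records$identifiable
  mc_mean <- function(v) mean(v[ok])
  mc_se <- function(v) stats::sd(v[ok]) / sqrt(sum(ok))
  fpr <- mean(nzchar(records$pattern))
  res <- list(setting = setting,
              fpr = fpr,
              fpr_se = sqrt(fpr * (1 - fpr) / setting$reps),
              mean_ace = mc_mean(records$ace), se_ace = mc_se(records$ace),
              mean_de = mc_mean(records$de), se_de = mc_se(records$de),
              mean_ie = mc_mean(records$ie), se_ie = mc_se(records$ie),
              true_ace = truth$ace, true_de = truth$de, true_ie = truth$ie,
              pattern_frequencies = table(records$pattern),
              undefined_count = sum(!ok))
  if (keep_records) res$records <- records
  structure(res, class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  s <- x$setting
  cat(sprintf("%s motif, alpha=%g beta=%g gamma=%g, n=%d, reps=%d\n",
              s$motif, s$alpha, s$beta, s$gamma, s$n, s$reps))
  cat(sprintf("  causal false-positive risk: %.3f (MC-SE %.3f)\n",
              x$fpr, x$fpr_se))
  cat(sprintf("  mean ACE %.4f (true %.4f)   mean DE %.4f (true %.4f)   mean IE %.4f (true %.4f)\n",
              x$mean_ace, x$true_ace, x$mean_de, x$true_de, x$mean_ie, x$true_ie))
  if (x$undefined_count > 0)
    cat("  replicates with unidentifiable effects:", x$undefined_count, "\n")
  invisible(x)
}

#' The printed grids of simulation settings
#'
#' Returns the full coefficient grid studied for each motif: 16 confounder
#' rows (balanced `beta = gamma` in \{0.125, 0.25, 0.5, 1\} and unbalanced
#' `(beta, gamma)` pairs, each crossed with `alpha` in \{0.25, 0.5\}) and
#' 22 collider rows (balanced `alpha = beta` in \{0.25, 0.5, 1\} and
#' unbalanced pairs, each crossed with `gamma` in \{0.25, 0.5, 1\}).
#'
#' @param motif `"confounder"` or `"collider"`.
#' @return a data frame with columns `setting` (a descriptive name),
#'   `alpha`, `beta`, `gamma`.
#' @export
settings_registry <- function(motif) {
  motif <- match.arg(motif, c("confounder", "collider"))
  if (motif == "confounder") {
    bal <- data.frame(setting = rep(c("Weak Confounder", "Balanced Confounder",
                                      "Strong Confounder", "Very strong Confounder"), 2),
                      alpha = rep(c(0.25, 0.5), each = 4),
                      beta = rep(c(0.125, 0.25, 0.5, 1.0), 2),
                      gamma = rep(c(0.125, 0.25, 0.5, 1.0), 2))
    unb <- data.frame(setting = "Unbalanced Confounder",
                      alpha = rep(c(0.25, 0.5), each = 4),
                      beta = rep(c(0.25, 0.75, 0.1, 0.9), 2),
                      gamma = rep(c(0.75, 0.25, 0.9, 0.1), 2))
    rbind(bal, unb)
  } else {
    bal <- data.frame(setting = "Balanced",
                      alpha = rep(c(0.25, 0.5, 1.0), 3),
                      beta = rep(c(0.25, 0.5, 1.0), 3),
                      gamma = rep(c(0.25, 0.5, 1.0), each = 3))
    unb <- data.frame(setting = "Unbalanced",
                      alpha = rep(c(1/3, 2/3, 0.1, 0.9), 3),
                      beta = rep(c(2/3, 1/3, 0.9, 0.1), 3),
                      gamma = rep(c(0.25, 0.5, 1.0), each = 4))
    ## unbalanced rows are printed 1/3-2/3 pairs first for every gamma,
    ## then the 0.1/0.9 pairs for every gamma
    third <- unb[unb$alpha %in% c(1/3, 2/3), ]
    tenth <- unb[unb$alpha %in% c(0.1, 0.9), ]
    rbind(bal, third, tenth)
  }
}

#' Absolute and relative bias of the Monte Carlo effect estimates
#'
#' @param result a [run_study()] result.
#' @return a data frame with one row per effect (`ace`, `de`, `ie`) and
#'   columns `mean`, `true`, `abs_bias` (mean - true) and `rel_bias`
#'   ((mean - true)/true, `NA` when the true effect is 0).
#' @export
bias_summary <- function(result) {
  stopifnot(inherits(result, "study_result"))
  mean_v <- c(ace = result$mean_ace, de = result$mean_de, ie = result$mean_ie)
  true_v <- c(ace = result$true_ace, de = result$true_de, ie = result$true_ie)
  data.frame(effect = names(mean_v),
             mean = unname(mean_v),
             true = unname(true_v),
             abs_bias = unname(mean_v - true_v),
             rel_bias = ifelse(true_v == 0, NA_real_,
                               unname((mean_v - true_v) / true_v)),
             row.names = NULL)
}

#' Run every setting of a motif's registry over a sample-size grid
#'
#' @param motif `"confounder"` or `"collider"`.
#' @param n_grid per-variable sample sizes to sweep (the studied range is
#'   10 to 100 per variable).
#' @param reps replicates per setting and sample size.
#' @param master_seed integer master seed; each (setting, n) cell derives
#'   its own sub-seed.
#' @param standardize,prior_sd passed to [study_setting()].
#' @param verbose print one progress line per cell to standard error.
#' @return a data frame of class `study_grid`, one row per setting and
#'   sample size, with the setting fields, `fpr`, effect means, true
#'   effects and Monte Carlo standard errors.
#' @export
run_registry <- function(motif, n_grid = seq(10, 100, by = 10), reps = 2000,
                         master_seed = 1, standardize = FALSE, prior_sd = 1,
                         verbose = FALSE) {
  registry <- settings_registry(motif)
  rows <- list()
  cell <- 0L
  for (i in seq_len(nrow(registry))) {
    for (n in n_grid) {
      cell <- cell + 1L
      setting <- study_setting(motif, registry$alpha[i], registry$beta[i],
                               registry$gamma[i], n = n, reps = reps,
                               master_seed = replicate_seed(master_seed, cell),
                               standardize = standardize, prior_sd = prior_sd)
      t0 <- proc.time()[["elapsed"]]
      res <- run_study(setting, keep_records = FALSE)
      if (verbose)
        message(sprintf("[%s] %s alpha=%g beta=%g gamma=%g n=%d: fpr=%.3f (%.1fs)",
                        motif, registry$setting[i], registry$alpha[i],
                        registry$beta[i], registry$gamma[i], n, res$fpr,
                        proc.time()[["elapsed"]] - t0))
      rows[[cell]] <- data.frame(
        setting = registry$setting[i], motif = motif,
        alpha = registry$alpha[i], beta = registry$beta[i],
        gamma = registry$gamma[i], n = as.integer(n), reps = as.integer(reps),
        fpr = res$fpr, fpr_se = res$fpr_se,
        mean_ace = res$mean_ace, se_ace = res$se_ace,
        mean_de = res$mean_de, se_de = res$se_de,
        mean_ie = res$mean_ie, se_ie = res$se_ie,
        true_ace = res$true_ace, true_de = res$true_de, true_ie = res$true_ie,
        undefined = res$undefined_count,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_grid", class(out))
  out
}

#' Plot false-positive risk or mean effect against sample size
#'
#' Convenience line plot over a [run_registry()] grid: one line per
#' coefficient setting, the requested quantity on the vertical axis.
#'
#' @param x a `study_grid`.
#' @param what one of `"fpr"`, `"ace"`, `"de"`, `"ie"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.study_grid <- function(x, what = c("fpr", "ace", "de", "ie"), ...) {
  what <- match.arg(what)
  col <- switch(what, fpr = "fpr", ace = "mean_ace", de = "mean_de",
                ie = "mean_ie")
  key <- paste(x$alpha, x$beta, x$gamma)
  n_grid <- sort(unique(x$n))
  mat <- sapply(unique(key), function(k) {
    sub <- x[key == k, ]
    sub[[col]][match(n_grid, sub$n)]
  })
  graphics::matplot(n_grid, mat, type = "l", lty = 1,
                    xlab = "sample size n per variable",
                    ylab = switch(what, fpr = "causal false-positive risk",
                                  paste("Monte Carlo mean", toupper(what))), ...)
  invisible(x)
}
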