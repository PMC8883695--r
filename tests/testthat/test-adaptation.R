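test_that("the confounder motif has the three stated implications", {
  imps <- confounder_implications()
  expect_identical(nrow(imps), 3L)
  expect_true(all(imps$expected == "nonzero"))
  expect_false(anyDuplicated(imps$label) > 0)
  xc <- imps[imps$label == "b_XC", ]
  expect_identical(xc$adjustment[[1]], character())  # marginal X-C test
  expect_identical(xc$outcome, "X")
})

test_that("the collider motif has six implications, three of each kind", {
  imps <- collider_implications()
  expect_identical(nrow(imps), 6L)
  expect_identical(sum(imps$expected == "zero"), 3L)
  expect_identical(sum(imps$expected == "nonzero"), 3L)
  expect_false("b_WX.C" %in% imps$label)   # the superfluous implication
  ## the nonempty violation patterns number 2^6 - 1 = 63
  expect_identical(sum(choose(6, 1:6)), 63)
})

test_that("violation patterns drive the documented DAG edits", {
  g <- apply_edits("confounder", c("b_YC.X", "b_XC"))
  expect_identical(nrow(g$edges), 1L)
  expect_true(has_edge(g, "X", "Y"))       # C no longer a confounder
  g2 <- apply_edits("collider", "b_CX.WY")
  expect_false(has_edge(g2, "X", "C"))
  expect_true(has_edge(g2, "W", "C") && has_edge(g2, "C", "Y"))
  g3 <- apply_edits("collider", "b_WX")    # directionality fixed W -> X
  expect_true(has_edge(g3, "W", "X"))
  g4 <- apply_edits("collider", "b_YW.C")  # presumed W -> Y orientation
  expect_true(has_edge(g4, "W", "Y"))
  expect_identical(apply_edits("confounder", character()),
                   confounder_dag())
  expect_error(apply_edits("collider", "b_nope"), "unknown implication")
})

test_that("edits are order-independent and stay within the motif node set", {
  labels <- collider_implications()$label
  full_edge_pool <- c("X->C", "W->C", "C->Y", "X->Y", "W->Y", "W->X")
  for (pat in subsets_of(labels)) {
    g <- apply_edits("collider", pat)
    g_rev <- apply_edits("collider", rev(pat))
    expect_identical(g$edges, g_rev$edges)
    expect_identical(g$nodes, collider_dag()$nodes)
    keys <- if (nrow(g$edges)) paste0(g$edges[, 1], "->", g$edges[, 2])
            else character()
    expect_true(all(keys %in% full_edge_pool))
  }
})

test_that("estimand plans reproduce the motif identification results", {
  plan <- estimand_plan(confounder_dag())
  expect_true(plan$identifiable)
  expect_identical(plan$edges$adjustment[[1]], "C")  # ACE = b_YX.C
  expect_identical(plan$de_edge, 1L)
  planc <- estimand_plan(collider_dag())
  expect_true(planc$identifiable)
  expect_identical(nrow(planc$edges), 2L)            # X -> C and C -> Y
  expect_true(all(lengths(planc$edges$adjustment) == 0))
  expect_null(planc$de_edge)                         # DE = 0 exactly
  plan0 <- estimand_plan(delete_edge(confounder_dag(), "C", "X"))
  expect_identical(plan0$edges$adjustment[[1]], character())  # ACE = b_YX
})

test_that("the generic engine reproduces the confounder case lookup", {
  labels <- confounder_implications()$label
  for (pat in subsets_of(labels)) {
    lk <- confounder_case_table(pat)
    expect_identical(lk$de, lk$ace)
    expect_identical(lk$ie, "zero")
    plan <- estimand_plan(apply_edits("confounder", pat))
    if (lk$ace == "zero") {
      expect_length(plan$paths, 0L)
    } else {
      expect_length(plan$paths, 1L)
      z <- plan$edges$adjustment[[1]]
      expect_identical(z, if (lk$ace == "b_YX.C") "C" else character())
    }
  }
  expect_error(confounder_case_table("b_nope"), "unknown implication")
})

test_that("every collider violation pattern yields an identifiable plan", {
  pats <- subsets_of(collider_implications()$label)
  expect_length(pats, 64L)
  for (pat in pats) {
    plan <- estimand_plan(apply_edits("collider", pat))
    expect_true(plan$identifiable)
  }
})

test_that("effect estimation follows the plan and the additive identity", {
  ## all implications violated: empty confounder DAG, all effects exactly 0
  d <- simulate_scm(confounder_model(0.25, 0.25, 0.25), 50, seed = 71)
  plan_empty <- estimand_plan(apply_edits("confounder",
                                          confounder_implications()$label))
  eff0 <- estimate_effects(d, plan_empty)
  expect_identical(c(eff0$ace, eff0$de, eff0$ie), c(0, 0, 0))
  ## large-sample consistency of the C-adjusted estimator
  dl <- simulate_scm(confounder_model(0.25, 1, 1), 2e4, seed = 72)
  plan <- estimand_plan(confounder_dag())
  eff <- estimate_effects(dl, plan)
  fit <- bayes_linreg(dl, "Y", "X", "C")
  expect_lt(abs(eff$ace - 0.25), 2 * fit$post_sd[["X"]])
  expect_identical(eff$de, eff$ace)
  ## collider: DE is structurally zero, IE is the product estimand
  dc <- simulate_scm(collider_model(0.5, 0.5, 0.5), 2e4, seed = 73)
  effc <- estimate_effects(dc, estimand_plan(collider_dag()))
  expect_identical(effc$de, 0)
  expect_lt(abs(effc$ie - 0.25), 0.02)
  expect_equal(effc$ace, effc$de + effc$ie, tolerance = 1e-12)
  expect_equal(effc$ie,
               bayes_linreg(dc, "C", "X")$post_mean[["X"]] *
                 bayes_linreg(dc, "Y", "C")$post_mean[["C"]],
               tolerance = 1e-12)
})
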