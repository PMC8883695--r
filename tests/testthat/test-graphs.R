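test_that("dag construction enforces acyclicity and well-formed edges", {
  g <- dag(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_s3_class(g, "dag")
  expect_identical(g$nodes, c("A", "B", "C"))
  expect_error(dag(c("A", "A")), "duplicate node")
  expect_error(dag(c("A", "B"), list(c("A", "Z"))), "unknown node")
  expect_error(dag("A", list(c("A", "A"))), "self-loop")
  expect_error(dag(c("A", "B"), list(c("A", "B"), c("A", "B"))), "duplicate edges")
  expect_error(dag(c("A", "B", "C"),
                   list(c("A", "B"), c("B", "C"), c("C", "A"))), "cycle")
})

test_that("path enumeration finds all simple paths in deterministic order", {
  conf <- confounder_dag()
  p <- enumerate_paths(conf, "X", "Y")
  expect_length(p, 2L)                       # X -> Y and X <- C -> Y
  expect_setequal(sapply(p, nrow), c(1L, 2L))
  expect_identical(p, enumerate_paths(conf, "X", "Y"))
  expect_length(enumerate_paths(collider_dag(), "W", "X"), 1L)  # W -> C <- X
  expect_length(enumerate_paths(dag(c("A", "B")), "A", "B"), 0L)
  expect_error(enumerate_paths(conf, "X", "Q"), "not found")
  expect_error(enumerate_paths(conf, "X", "X"), "distinct")
})

test_that("directed paths keep only edges pointing toward the target", {
  expect_length(directed_paths(confounder_dag(), "X", "Y"), 1L)
  colp <- directed_paths(collider_dag(), "X", "Y")
  expect_length(colp, 1L)
  expect_identical(colp[[1]]$to, c("C", "Y"))                   # X -> C -> Y
  expect_length(directed_paths(collider_dag(), "Y", "X"), 0L)
})

test_that("d-separation matches the motif analyses", {
  conf <- confounder_dag()
  coll <- collider_dag()
  expect_false(d_separated(conf, "X", "Y", "C"))  # X -> Y stays open
  expect_false(d_separated(conf, "Y", "C", "X"))
  expect_false(d_separated(conf, "X", "C"))
  expect_true(d_separated(coll, "W", "X"))        # blocked by the collider C
  expect_false(d_separated(coll, "W", "X", "C"))  # conditioning opens it
  expect_false(d_separated(coll, "W", "X", "Y"))  # Y is a descendant of C
  expect_true(d_separated(coll, "X", "Y", "C"))
  expect_true(d_separated(dag(c("A", "B")), "A", "B"))
  expect_error(d_separated(conf, "X", "Q", character()), "not found")
  expect_error(d_separated(conf, "X", "Y", "X"), "conditioning set")
})

test_that("d-separation engine agrees with the path-blocking oracle", {
  graphs <- c(list(confounder_dag(), collider_dag()),
              lapply(1:25, function(s) random_dag(4L, 0.5, seed = s)),
              lapply(26:45, function(s) random_dag(5L, 0.45, seed = s)))
  for (g in graphs) {
    pairs <- utils::combn(g$nodes, 2L)
    for (k in seq_len(ncol(pairs))) {
      x <- pairs[1L, k]; y <- pairs[2L, k]
      for (z in subsets_of(setdiff(g$nodes, c(x, y)))) {
        got <- d_separated(g, x, y, z)
        expect_identical(got, oracle_d_separated(g, x, y, z))
        expect_identical(got, d_separated(g, y, x, z))   # symmetry
      }
    }
  }
})

test_that("deleting an edge never un-separates a separated pair", {
  for (g in list(confounder_dag(), collider_dag())) {
    pairs <- utils::combn(g$nodes, 2L)
    for (e in seq_len(nrow(g$edges))) {
      g2 <- delete_edge(g, g$edges[e, 1L], g$edges[e, 2L])
      for (k in seq_len(ncol(pairs))) {
        x <- pairs[1L, k]; y <- pairs[2L, k]
        for (z in subsets_of(setdiff(g$nodes, c(x, y)))) {
          if (d_separated(g, x, y, z)) expect_true(d_separated(g2, x, y, z))
        }
      }
    }
  }
})

test_that("d-separated triples have vanishing model partial correlations", {
  models <- list(confounder_model(0.25, 0.5, 0.5),
                 collider_model(0.5, 0.25, 0.75),
                 collider_model(1/3, 2/3, 1))
  for (m in models) {
    S <- implied_covariance(m)
    g <- m$dag
    pairs <- utils::combn(g$nodes, 2L)
    for (k in seq_len(ncol(pairs))) {
      x <- pairs[1L, k]; y <- pairs[2L, k]
      for (z in subsets_of(setdiff(g$nodes, c(x, y)))) {
        if (d_separated(g, x, y, z))
          expect_lt(abs(pcor_from_cov(S, x, y, z)), 1e-10)
      }
    }
  }
})

test_that("single-door search returns minimal admissible sets", {
  conf <- confounder_dag()
  coll <- collider_dag()
  expect_identical(single_door_set(conf, "X", "Y"), "C")
  expect_identical(single_door_set(conf, "C", "Y"), "X")  # blocks C -> X -> Y
  expect_identical(single_door_set(coll, "X", "C"), character())
  expect_identical(single_door_set(coll, "C", "Y"), character())
  expect_error(single_door_set(coll, "X", "Y"), "not present")
})

test_that("backdoor search returns minimal admissible sets", {
  conf <- confounder_dag()
  expect_identical(backdoor_set(conf, "X", "Y"), "C")
  expect_identical(backdoor_set(delete_edge(conf, "C", "X"), "X", "Y"),
                   character())
  expect_identical(backdoor_set(collider_dag(), "X", "Y"), character())
})

test_that("adjustment-set estimands match the true structural coefficients", {
  ## regression coefficients computed from the exact implied covariance at
  ## the adjustment set certify the single-door / backdoor identification
  beta_from_cov <- function(S, outcome, preds) {
    unname(drop(solve(S[preds, preds, drop = FALSE], S[preds, outcome]))[1L])
  }
  m <- confounder_model(0.25, 1, 1)
  S <- implied_covariance(m)
  z <- single_door_set(m$dag, "X", "Y")
  expect_equal(beta_from_cov(S, "Y", c("X", z)), 0.25, tolerance = 1e-12)
  mc <- collider_model(0.5, 0.25, 0.75)
  Sc <- implied_covariance(mc)
  expect_equal(beta_from_cov(Sc, "C", "X"), 0.5, tolerance = 1e-12)
  expect_equal(beta_from_cov(Sc, "Y", "C"), 0.75, tolerance = 1e-12)
})

test_that("DAG JSON serialization round-trips", {
  g <- collider_dag()
  path <- withr::local_tempfile(fileext = ".json")
  dag_to_json(g, path)
  g2 <- dag_from_json(path)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges, g$edges)
  e <- dag(c("A", "B"))
  expect_identical(dag_from_json(dag_to_json(e))$edges, e$edges)
})
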