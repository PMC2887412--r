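example_spec <- function(...) design_spec("EX_P1", min_growth = 0.1, ...)

test_that("the regulated designer finds the TF-deletion double knockout", {
  m <- example_network(uptake = 10)
  des <- optorf(m, orf_environment(), example_spec(k1 = 2, k2 = 0))
  expect_true(des$feasible)
  expect_equal(des$tf_deletions, "TF1")
  expect_length(c(des$deletions, des$tf_deletions), 2)
  expect_true(des$deletions %in% c("G4", "G6"))
  expect_equal(des$product, 10, tolerance = 1e-6)
  expect_equal(des$growth, 0.8, tolerance = 1e-6)
  expect_lt(des$duality_gap, 1e-6)
})

test_that("without TF deletions the designer overexpresses the repressed subunit", {
  m <- example_network(uptake = 10)
  des <- optorf(m, orf_environment(),
                example_spec(k1 = 2, k2 = 1, allow_tf_deletion = FALSE))
  expect_true(des$feasible)
  expect_equal(des$overexpressions, "G1A")
  expect_true(identical(sort(des$deletions), c("G3", "G4")) ||
                identical(sort(des$deletions), c("G5", "G6")))
  expect_equal(des$product, 10, tolerance = 1e-6)
})

test_that("zero caps return the wild type with zero product term", {
  m <- example_network(uptake = 10)
  des <- optorf(m, orf_environment(), example_spec(k1 = 0, k2 = 0))
  expect_true(des$feasible)
  expect_length(c(des$deletions, des$tf_deletions, des$overexpressions), 0)
  expect_equal(des$product, 0, tolerance = 1e-6)
  expect_equal(des$objective, 0, tolerance = 1e-6)
})

test_that("enumeration returns the two strategy families in objective order", {
  m <- example_network(uptake = 10)
  designs <- enumerate_optorf(m, orf_environment(),
                              example_spec(k1 = 2, k2 = 1), n = 6)
  expect_length(designs, 4)
  key <- function(d) paste(paste(sort(c(d$deletions, d$tf_deletions)),
                                 collapse = "+"),
                           paste(sort(d$overexpressions), collapse = "+"),
                           sep = "|")
  keys <- vapply(designs, key, "")
  expect_setequal(keys[1:2], c("G4+TF1|", "G6+TF1|"))
  expect_setequal(keys[3:4], c("G3+G4|G1A", "G5+G6|G1A"))
  objs <- vapply(designs, function(d) d$objective, 0)
  expect_true(all(diff(objs) <= 1e-9))
  # every pair differs in >= delta interventions
  for (a in 1:3) for (b in (a + 1):4) {
    da <- designs[[a]]; db <- designs[[b]]
    ia <- c(paste0("z", c(da$deletions, da$tf_deletions)),
            paste0("w", da$overexpressions))
    ib <- c(paste0("z", c(db$deletions, db$tf_deletions)),
            paste0("w", db$overexpressions))
    expect_gte(length(union(setdiff(ia, ib), setdiff(ib, ia))), 1)
  }
})

test_that("delta = 2 forces at least two intervention differences", {
  m <- example_network(uptake = 10)
  designs <- enumerate_optorf(m, orf_environment(),
                              example_spec(k1 = 2, k2 = 1, delta = 2), n = 3)
  expect_gte(length(designs), 2)
  for (a in seq_along(designs)) for (b in seq_along(designs)) {
    if (a >= b) next
    da <- designs[[a]]; db <- designs[[b]]
    ia <- c(paste0("z", c(da$deletions, da$tf_deletions)),
            paste0("w", da$overexpressions))
    ib <- c(paste0("z", c(db$deletions, db$tf_deletions)),
            paste0("w", db$overexpressions))
    expect_gte(length(union(setdiff(ia, ib), setdiff(ib, ia))), 2)
  }
})

test_that("with regulation disabled gene deletions alone suffice", {
  m <- example_network(uptake = 10)
  des <- optorf(m, orf_environment(),
                example_spec(k1 = 2, k2 = 1, regulation = FALSE))
  expect_true(des$feasible)
  expect_length(des$tf_deletions, 0)
  expect_length(des$overexpressions, 0)
  expect_true(identical(sort(des$deletions), c("G3", "G4")) ||
                identical(sort(des$deletions), c("G5", "G6")))
  expect_equal(des$product, 10, tolerance = 1e-6)
})

test_that("the optimal objective is monotone in the intervention caps", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  vals <- sapply(0:2, function(k) {
    optorf(m, env, example_spec(k1 = k, k2 = 0))$objective
  })
  expect_true(all(diff(vals) >= -1e-9))
  v20 <- optorf(m, env, example_spec(k1 = 2, k2 = 0))$objective
  v21 <- optorf(m, env, example_spec(k1 = 2, k2 = 1))$objective
  expect_gte(v21 + 1e-9, v20)
})

test_that("penalties make returned designs leave-one-out minimal", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  spec <- example_spec(k1 = 2, k2 = 1)
  des <- optorf(m, env, spec)
  expect_true(optorf:::design_is_minimal(m, env, spec, des))
})

test_that("verification reproduces the MILP claims and flags corruption", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  des <- optorf(m, env, example_spec(k1 = 2, k2 = 0))
  vr <- verify_design(m, env, des)
  expect_true(vr$verified)
  expect_lt(vr$growth_delta, 1e-6)
  expect_lt(vr$product_delta, 1e-6)
  # a coupled design has positive minimum product at optimal growth
  expect_gt(vr$product_min, 0)
  # corrupt the solution: inject an extra deletion
  bad <- des
  bad$deletions <- c(bad$deletions, "G2")
  vb <- verify_design(m, env, bad)
  expect_false(vb$verified)
})

test_that("optorf matches exhaustive enumeration on random networks", {
  for (seed in c(6, 23)) {
    m <- random_toy_model(n_reactions = 7, n_genes = 5, n_tfs = 2, seed = seed)
    env <- orf_environment()
    spec <- design_spec("EX_P1", k1 = 2, k2 = 1, min_growth = 0.05)
    des <- optorf(m, env, spec)
    oracle <- brute_force_optorf(m, env, spec)
    if (!is.finite(oracle)) {
      expect_false(des$feasible)
    } else {
      expect_true(des$feasible)
      expect_equal(des$objective, oracle, tolerance = 1e-6)
    }
  }
})
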