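test_that("FBA reproduces the hand-solved example network optima", {
  m <- example_network(uptake = 10)
  env1 <- orf_environment(c(EX_S = -1))
  # regulation ignored: best route via R5 yields 0.12 per unit substrate
  f <- solve_fba(m, env1)
  expect_equal(f$status, "optimal")
  expect_equal(f$growth, 0.12, tolerance = 1e-9)
  expect_equal(unname(f$flux["EX_P2"]), 1, tolerance = 1e-9)
  # with R3 and R4 removed only the R1-R2 route remains: 0.08 and P1
  f2 <- solve_fba(m, env1, d = c(R3 = 0, R4 = 0))
  expect_equal(f2$growth, 0.08, tolerance = 1e-9)
  expect_equal(unname(f2$flux["EX_P1"]), 1, tolerance = 1e-9)
  # all internal reactions off: no growth
  f3 <- solve_fba(m, env1, d = c(R1 = 0, R2 = 0, R3 = 0, R4 = 0, R5 = 0))
  expect_equal(f3$growth, 0, tolerance = 1e-9)
})

test_that("infeasible and unbounded LPs are signalled distinctly", {
  m <- example_network()
  inf <- solve_fba(m, orf_environment(), min_growth = 100)
  expect_equal(inf$status, "infeasible")
  # an internal two-reaction cycle carries arbitrarily large flux
  cyc <- integrated_model(
    data.frame(id = c("A", "Bm"), stringsAsFactors = FALSE),
    list(list(id = "R1", stoich = c(A = -1, Bm = 1)),
         list(id = "R2", stoich = c(Bm = -1, A = 1)),
         list(id = "EX_A", stoich = c(A = -1), lb = -1)),
    biomass = "EX_A"
  )
  unb <- solve_fba(cyc, orf_environment(),
                   objective = stats::setNames(1, "R1"), maximize = TRUE)
  expect_equal(unb$status, "unbounded")
})

test_that("regulated FBA finds consistent flux/regulatory fixed points", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  wt <- solve_regulated_fba(m, env)
  expect_equal(wt$growth, 1.2, tolerance = 1e-6)
  expect_equal(unname(wt$flux["R1"]), 0, tolerance = 1e-6)
  expect_gt(unname(wt$flux["EX_P2"]), 0)
  # the returned Boolean state re-evaluates consistently
  st <- evaluate_state(compile_regulation(m), compile_gpr(m), m, env, wt$flux)
  expect_equal(st$y[names(wt$state$y)], wt$state$y)

  mt <- solve_regulated_fba(m, env, deletions = c("TF1", "G4"))
  expect_equal(mt$growth, 0.8, tolerance = 1e-6)
  expect_equal(unname(mt$flux["EX_P1"]), 10, tolerance = 1e-6)

  # double isozyme deletion starves the cell (R1 stays repressed): only the
  # sub-threshold indicator leak remains
  lethal <- solve_regulated_fba(m, env, deletions = c("G5", "G6"))
  expect_lt(lethal$growth, 1e-3)
})

test_that("strong-duality block reproduces FBA optima at fixed availability", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  for (dfix in list(NULL, c(R3 = 0, R4 = 0))) {
    blk <- build_strong_duality(m, env, d = dfix)
    lp <- blk$lp
    optorf:::lp_set_objective(lp, optorf:::lin_var(blk$v[[m$biomass]]),
                              maximize = TRUE)
    res <- optorf:::milp_solve(lp)
    expect_equal(res$status, "optimal")
    ref <- solve_fba(m, env, d = dfix)
    expect_equal(res$objective, ref$objective, tolerance = 1e-6)
    # objective equality: growth equals the dual bound value
    x <- res$x
    lbv <- attr(blk$v, "lb"); ubv <- attr(blk$v, "ub")
    dual_obj <- 0
    for (j in names(blk$duals$lambda)) {
      dual_obj <- dual_obj - x[blk$duals$lambda[[j]]] * lbv[j]
    }
    for (j in names(blk$duals$mu)) {
      dual_obj <- dual_obj + x[blk$duals$mu[[j]]] * ubv[j]
    }
    expect_equal(unname(dual_obj), res$objective, tolerance = 1e-6)
    # h multipliers honor their configured bounds
    hs <- x[unlist(blk$duals$h)]
    if (length(hs)) expect_true(all(abs(hs) <= 1 + 1e-9))
  }
})

test_that("weak duality holds against an independently built dual LP", {
  for (seed in c(3, 9, 21)) {
    m <- random_toy_model(n_reactions = 8, n_genes = 6, n_tfs = 0, seed = seed)
    env <- orf_environment()
    primal <- solve_fba(m, env)
    expect_equal(primal$status, "optimal")
    # dual LP assembled from scratch: min -sum(lambda lb) + sum(mu ub)
    # s.t. S'u - lambda + mu = p, lambda >= 0, mu >= 0
    lp <- optorf:::lp_new(maximize = FALSE)
    st <- optorf:::stoich_triplets(m)
    b <- optorf:::reaction_bounds(m, env)
    u <- stats::setNames(integer(length(st$metabolites)), st$metabolites)
    for (i in st$metabolites) u[i] <- optorf:::lp_add_var(lp, paste0("u.", i))
    obj <- optorf:::lin()
    for (j in names(m$reactions)) {
      jn <- match(j, st$reactions)
      sel <- st$j == jn
      stat <- optorf:::lin(u[st$i[sel]], st$x[sel])
      p_j <- as.numeric(j == m$biomass)
      if (is.finite(b$lb[j])) {
        lam <- optorf:::lp_add_var(lp, paste0("lam.", j), 0, Inf)
        stat <- optorf:::lin_sum(stat, optorf:::lin_var(lam, -1))
        obj <- optorf:::lin_sum(obj, optorf:::lin_var(lam, -b$lb[j]))
      }
      if (is.finite(b$ub[j])) {
        mu <- optorf:::lp_add_var(lp, paste0("mu.", j), 0, Inf)
        stat <- optorf:::lin_sum(stat, optorf:::lin_var(mu, 1))
        obj <- optorf:::lin_sum(obj, optorf:::lin_var(mu, b$ub[j]))
      }
      optorf:::lp_add_con(lp, stat, "=", p_j)
    }
    optorf:::lp_set_objective(lp, obj, maximize = FALSE)
    dual <- optorf:::milp_solve(lp)
    expect_equal(dual$status, "optimal")
    # LP strong duality: optima coincide; any dual-feasible value bounds
    # the primal from above
    expect_equal(dual$objective, primal$objective, tolerance = 1e-6)
    expect_gte(dual$objective + 1e-6, primal$objective)
  }
})

test_that("production envelopes distinguish uncoupled and coupled designs", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  # wild type: P1 is uncoupled (zero at maximal growth)
  wt <- production_envelope(m, env, "EX_P1", n_points = 6)
  expect_true(all(wt$product_min <= wt$product_max + 1e-9))
  expect_equal(wt$product_max[nrow(wt)], 0, tolerance = 1e-6)
  # the TF1/G4 deletion strain: P1 coupled (positive minimum at max growth)
  mt <- production_envelope(m, env, "EX_P1", n_points = 6, regulated = TRUE,
                            deletions = c("TF1", "G4"))
  expect_gt(mt$product_min[nrow(mt)], 0)
  expect_equal(mt$growth[nrow(mt)], 0.8, tolerance = 1e-6)
})

test_that("the regulated envelope is contained in the unregulated envelope", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  unreg <- production_envelope(m, env, "EX_P2", n_points = 5)
  reg <- production_envelope(m, env, "EX_P2", n_points = 5, regulated = TRUE)
  # same maximal growth here, so the grids align
  expect_equal(reg$growth, unreg$growth, tolerance = 1e-9)
  ok <- is.finite(reg$product_min) & is.finite(reg$product_max)
  expect_true(all(reg$product_max[ok] <= unreg$product_max[ok] + 1e-6))
  expect_true(all(reg$product_min[ok] >= unreg$product_min[ok] - 1e-6))
})

test_that("regulated growth never exceeds unregulated growth", {
  for (seed in c(2, 5, 13, 31)) {
    m <- random_toy_model(n_reactions = 8, n_genes = 6, n_tfs = 2, seed = seed)
    env <- orf_environment()
    f <- solve_fba(m, env)
    r <- solve_regulated_fba(m, env)
    expect_equal(r$status, "optimal")
    expect_lte(r$growth, f$growth + 1e-6)
  }
})
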