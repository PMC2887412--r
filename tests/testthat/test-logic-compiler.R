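test_that("GPR compilation expands complexes and isozymes", {
  m <- example_network()
  gpr <- compile_gpr(m)
  expect_equal(gpr$R1, list(c("G1A", "G1B")))
  expect_equal(sort(vapply(gpr$R5, paste, "", collapse = "+")),
               c("G5", "G6"))
  # reactions without GPR (the exchanges) are absent from the index
  expect_false(any(c("EX_S", "EX_P1", "EX_P2", "EX_B") %in% names(gpr)))

  # isozyme pair like the two-transketolase case
  mets <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  m2 <- integrated_model(
    mets,
    list(list(id = "TKT", stoich = c(A = -1, B = 1), gpr = "tktA or tktB"),
         list(id = "EX_A", stoich = c(A = 1), lb = -1),
         list(id = "EX_B", stoich = c(B = -1))),
    biomass = "EX_B"
  )
  expect_equal(compile_gpr(m2)$TKT, list("tktA", "tktB"))
})

test_that("regulation compiles to activator/repressor effector conditions", {
  m <- example_network()
  reg <- compile_regulation(m)
  # TF1: active iff substrate uptake (negative-flux indicator on EX_S)
  tf1 <- reg$targets$TF1
  expect_length(tf1, 1)
  expect_length(tf1[[1]]$activators, 1)
  eff <- tf1[[1]]$activators[[1]]
  expect_equal(eff$kind, "nf")
  expect_equal(eff$id, "EX_S")
  expect_equal(eff$threshold, 1e-3)
  expect_length(tf1[[1]]$repressors, 0)
  # G1A: repressed by TF1
  g1a <- reg$targets$G1A
  expect_length(g1a[[1]]$activators, 0)
  expect_equal(g1a[[1]]$repressors[[1]]$id, "TF1")
  expect_equal(g1a[[1]]$repressors[[1]]$kind, "tf")
  # constitutive genes carry no conditions at all
  expect_false("G2" %in% names(reg$targets))
})

test_that("perturbation algebra matches the four admissible cases", {
  # (y, z, w) -> y_hat on the admissible combinations
  expect_equal(unname(apply_perturbations(1, 1, 0)), 0)
  expect_equal(unname(apply_perturbations(0, 0, 1)), 1)
  expect_equal(unname(apply_perturbations(1, 0, 0)), 1)
  expect_equal(unname(apply_perturbations(0, 0, 0)), 0)
  # forbidden combinations are errors, not no-ops
  expect_error(apply_perturbations(0, 1, 0), "unexpressed")
  expect_error(apply_perturbations(1, 0, 1), "expressed")
  expect_error(apply_perturbations(1, 1, 1), "simultaneously")
  # vectorized
  expect_equal(unname(apply_perturbations(c(1, 0, 1), c(1, 0, 0), c(0, 1, 0))),
               c(0, 1, 1))
})

test_that("reaction feasibility follows complex-AND / isozyme-OR logic", {
  m <- example_network()
  gpr <- compile_gpr(m)
  yh <- stats::setNames(rep(1L, nrow(m$genes)), m$genes$id)
  yh["G5"] <- 0L
  d <- reaction_feasibility(gpr, yh, names(m$reactions))
  expect_true(d[["R5"]])        # isozyme G6 still present
  yh["G1A"] <- 0L
  d <- reaction_feasibility(gpr, yh, names(m$reactions))
  expect_false(d[["R1"]])       # complex requires both subunits
  expect_true(d[["EX_S"]])      # no GPR, never constrained
  yh[] <- 0L
  d <- reaction_feasibility(gpr, yh, names(m$reactions))
  expect_false(any(d[names(gpr)]))
  expect_true(all(d[setdiff(names(m$reactions), names(gpr))]))
})

test_that("reaction feasibility agrees with truth-table evaluation of GPRs", {
  for (seed in 1:5) {
    m <- random_toy_model(n_reactions = 7, n_genes = 5, n_tfs = 0, seed = seed)
    gpr <- compile_gpr(m)
    genes <- m$genes$id
    n <- length(genes)
    for (mask in 0:(2^n - 1)) {
      yh <- stats::setNames(as.integer(intToBits(mask)[1:n]), genes)
      d <- reaction_feasibility(gpr, yh, names(m$reactions))
      for (j in names(gpr)) {
        direct <- optorf:::eval_expr(m$reactions[[j]]$gpr,
                                     function(l) yh[[l$id]] == 1L)
        expect_identical(unname(d[j]), direct)
      }
    }
  }
})

test_that("state evaluation reproduces the worked-example regulatory logic", {
  m <- example_network()
  env <- orf_environment()
  gpr <- compile_gpr(m)
  reg <- compile_regulation(m)
  flux0 <- stats::setNames(rep(0, length(m$reactions)), names(m$reactions))

  # substrate being taken up: TF1 active, G1A repressed, G3/G5 induced
  flux <- flux0; flux["EX_S"] <- -1
  st <- evaluate_state(reg, gpr, m, env, flux)
  expect_equal(unname(st$y[c("TF1", "G1A", "G3", "G5")]), c(1L, 0L, 1L, 1L))
  expect_false(st$d[["R1"]])

  # TF deletion flips the regulon
  st2 <- evaluate_state(reg, gpr, m, env, flux, deletions = "TF1")
  expect_equal(unname(st2$y_hat[c("TF1", "G3", "G5", "G1A")]),
               c(0L, 0L, 0L, 1L))

  # no uptake: TF1 inactive, G1A expressed
  st3 <- evaluate_state(reg, gpr, m, env, flux0)
  expect_equal(unname(st3$y[c("TF1", "G1A")]), c(0L, 1L))
  expect_equal(st3$n_fixed_points, 1L)
})

test_that("contradictory regulatory cycles are reported", {
  mets <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  m <- integrated_model(
    mets,
    list(list(id = "R1", stoich = c(A = -1, B = 1), gpr = "G1"),
         list(id = "EX_A", stoich = c(A = 1), lb = -1),
         list(id = "EX_B", stoich = c(B = -1))),
    rules = data.frame(target = c("TF1", "TF2", "G1"),
                       rule = c("not TF2", "TF1", "TF1")),
    biomass = "EX_B"
  )
  gpr <- compile_gpr(m)
  reg <- compile_regulation(m)
  flux <- stats::setNames(rep(0, 3), names(m$reactions))
  expect_error(evaluate_state(reg, gpr, m, orf_environment(), flux),
               "no consistent regulatory state")
})

test_that("compiled indices export as (j,n,g) and (g,m,r) triples", {
  m <- example_network()
  txt <- write_index_json(compile_gpr(m), compile_regulation(m))
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  gpr_keys <- vapply(obj$GPR, function(t) paste(t$j, t$g), "")
  expect_true("R1 G1A" %in% gpr_keys && "R1 G1B" %in% gpr_keys)
  tr <- obj$TR[[which(vapply(obj$TR, function(t) t$g == "G1A", NA))[1]]]
  expect_equal(tr$kind, "tf")
  expect_equal(tr$role, "repressor")
  expect_equal(obj$epsilon, 1e-3)
})
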