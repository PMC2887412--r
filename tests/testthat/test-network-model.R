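test_that("the worked-example network has the documented structure", {
  m <- example_network()
  internal <- names(m$reactions)[!vapply(m$reactions, function(r) r$exchange, NA)]
  exchanges <- names(m$reactions)[vapply(m$reactions, function(r) r$exchange, NA)]
  expect_length(internal, 5)
  expect_length(exchanges, 4)
  expect_equal(sum(m$genes$kind == "metabolic"), 7)
  expect_equal(sum(m$genes$kind == "tf"), 1)
  expect_equal(unname(m$reactions$R2$stoich["B"]), 0.08)
  expect_equal(unname(m$reactions$R5$stoich["B"]), 0.12)

  # TF1 regulon: activates G3 and G5, represses G1A
  reg <- compile_regulation(m)
  act_of <- function(tg) vapply(reg$targets[[tg]][[1]]$activators,
                                function(e) e$id, "")
  rep_of <- function(tg) vapply(reg$targets[[tg]][[1]]$repressors,
                                function(e) e$id, "")
  expect_equal(act_of("G3"), "TF1")
  expect_equal(act_of("G5"), "TF1")
  expect_equal(rep_of("G1A"), "TF1")
})

test_that("models round-trip through JSON with all fields intact", {
  m <- example_network()
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(names(m2$reactions), names(m$reactions))
  for (j in names(m$reactions)) {
    expect_equal(m2$reactions[[j]]$stoich[order(names(m2$reactions[[j]]$stoich))],
                 m$reactions[[j]]$stoich[order(names(m$reactions[[j]]$stoich))])
    expect_equal(m2$reactions[[j]]$lb, m$reactions[[j]]$lb)
    expect_equal(m2$reactions[[j]]$ub, m$reactions[[j]]$ub)
  }
  expect_equal(sort(m2$genes$id), sort(m$genes$id))
  expect_equal(names(m2$rules), names(m$rules))
  expect_equal(m2$biomass, m$biomass)
})

test_that("models round-trip through the tabular dialect", {
  m <- random_toy_model(n_reactions = 7, n_genes = 5, n_tfs = 2, seed = 7)
  dir <- tempfile()
  write_model_tsv(m, dir)
  m2 <- read_model_tsv(file.path(dir, "reactions.tsv"),
                       rules_path = file.path(dir, "rules.tsv"),
                       metabolites_path = file.path(dir, "metabolites.tsv"),
                       biomass = "EX_B")
  expect_equal(names(m2$reactions), names(m$reactions))
  for (j in names(m$reactions)) {
    s1 <- m$reactions[[j]]$stoich
    s2 <- m2$reactions[[j]]$stoich
    expect_equal(s2[sort(names(s2))], s1[sort(names(s1))])
  }
  expect_equal(names(m2$rules), names(m$rules))
  # same phenotype
  f1 <- solve_fba(m, orf_environment())
  f2 <- solve_fba(m2, orf_environment())
  expect_equal(f2$growth, f1$growth, tolerance = 1e-9)
})

test_that("the SBML-fbc reader reproduces the bundled example network", {
  xml <- system.file("extdata", "example_network.xml", package = "optorf")
  rules <- system.file("extdata", "example_rules.tsv", package = "optorf")
  m <- load_model(xml, rules)
  ref <- example_network()
  expect_equal(sort(names(m$reactions)), sort(names(ref$reactions)))
  expect_equal(unname(m$reactions$R2$stoich["B"]), 0.08)
  expect_equal(unname(m$reactions$R5$stoich["B"]), 0.12)
  expect_equal(m$biomass, "EX_B")
  expect_equal(sort(m$genes$id[m$genes$kind == "tf"]), "TF1")
  expect_equal(unname(m$reactions$EX_S$lb), -10)
  # gene kinds inferred: rule targets not in GPRs are TFs
  expect_equal(sort(m$genes$id[m$genes$kind == "metabolic"]),
               sort(ref$genes$id[ref$genes$kind == "metabolic"]))
})

test_that("validation reports offending records", {
  mets <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  rxn <- list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = Inf)
  ex <- list(id = "EX_B", stoich = c(B = -1), lb = 0, ub = Inf)
  expect_error(
    integrated_model(mets, list(rxn, list(id = "R2", stoich = c(A = -1, C = 1)),
                                ex), biomass = "EX_B"),
    "R2.*undeclared metabolite"
  )
  expect_error(
    integrated_model(mets, list(rxn, ex),
                     rules = data.frame(target = "TF1", rule = "Q9 > 0"),
                     biomass = "EX_B"),
    "undeclared reaction"
  )
  expect_error(
    integrated_model(mets, list(rxn, rxn, ex), biomass = "EX_B"),
    "duplicate reaction"
  )
  expect_error(
    integrated_model(mets, list(rxn, ex), biomass = "EX_X"),
    "biomass"
  )
  expect_error(
    integrated_model(mets, list(list(id = "R1", stoich = c(A = -1, B = 1),
                                     gpr = "not G1"), ex), biomass = "EX_B"),
    "AND/OR"
  )
})

test_that("random toy models are deterministic in the seed", {
  m1 <- random_toy_model(n_reactions = 8, n_genes = 6, n_tfs = 2, seed = 11)
  m2 <- random_toy_model(n_reactions = 8, n_genes = 6, n_tfs = 2, seed = 11)
  expect_identical(write_model_json(m1), write_model_json(m2))
  m3 <- random_toy_model(n_reactions = 8, n_genes = 6, n_tfs = 2, seed = 12)
  expect_false(identical(write_model_json(m1), write_model_json(m3)))
})

test_that("random toy models satisfy their construction invariants", {
  for (seed in 1:8) {
    m <- random_toy_model(n_reactions = 5 + seed %% 5, n_genes = 6,
                          n_tfs = seed %% 4, seed = seed)
    expect_silent(validate_model(m))
    # every internal metabolite produced and consumed at least once
    internal <- m$metabolites$id[!m$metabolites$extracellular]
    for (met in internal) {
      coefs <- unlist(lapply(m$reactions, function(r) r$stoich[met]))
      coefs <- coefs[!is.na(coefs)]
      expect_true(any(coefs > 0), label = paste(met, "produced"))
      expect_true(any(coefs < 0), label = paste(met, "consumed"))
    }
    # every GPR literal references a declared gene (validate_model checks,
    # but assert the generator used only its own gene pool)
    gpr_ids <- unlist(lapply(m$reactions, function(r) {
      if (is.null(r$gpr)) character() else optorf:::expr_literals(r$gpr)$id
    }))
    expect_true(all(gpr_ids %in% m$genes$id))
    # biomass reachable: the backbone guarantees growth
    f <- solve_fba(m, orf_environment())
    expect_equal(f$status, "optimal")
    expect_gt(f$growth, 0)
  }
})

test_that("environment bounds apply to exchange lower bounds", {
  m <- example_network(uptake = 10)
  f <- solve_fba(m, orf_environment(c(EX_S = -2)))
  expect_equal(f$growth, 0.24, tolerance = 1e-9)
  expect_error(orf_environment(c(5)), "named")
  expect_error(solve_fba(m, orf_environment(c(EX_missing = -1))),
               "undeclared exchange")
})
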