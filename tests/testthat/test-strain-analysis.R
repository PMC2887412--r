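test_that("minimal gene covers hit all complexes of the targets", {
  m <- example_network()
  cov5 <- minimal_gene_cover(m, "R5")
  expect_equal(cov5$genes, c("G5", "G6"))       # both isozymes
  cov1 <- minimal_gene_cover(m, "R1")
  expect_length(cov1$genes, 1)                  # either subunit suffices
  expect_true(cov1$genes %in% c("G1A", "G1B"))
  expect_error(minimal_gene_cover(m, "EX_S"), "no GPR")
})

test_that("cover cardinality matches brute-force subset search", {
  for (seed in c(8, 19, 27)) {
    m <- random_toy_model(n_reactions = 7, n_genes = 5, n_tfs = 0, seed = seed)
    gpr <- compile_gpr(m)
    targets <- utils::head(names(gpr), 2)
    cov <- minimal_gene_cover(m, targets)
    genes <- m$genes$id
    covers <- function(set) {
      yh <- stats::setNames(rep(1L, length(genes)), genes)
      yh[set] <- 0L
      d <- reaction_feasibility(gpr, yh, targets)
      !any(d)
    }
    # the reported set covers, and no smaller subset does
    expect_true(covers(cov$genes))
    best <- Inf
    for (k in 0:length(genes)) {
      for (s in utils::combn(genes, k, simplify = FALSE)) {
        if (covers(s)) { best <- k; break }
      }
      if (is.finite(best)) break
    }
    expect_equal(length(cov$genes), best)
    # a gene-level cover disables at least the targets (superset of effects)
    yh <- stats::setNames(rep(1L, length(genes)), genes)
    yh[cov$genes] <- 0L
    d <- reaction_feasibility(gpr, yh, names(m$reactions))
    expect_false(any(d[targets]))
  }
})

test_that("reaction designs audit lethal under regulation while gene designs survive", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  aud <- reevaluate_designs(
    m, env,
    list(list(reactions = "R5"),        # reaction design, cover {G5, G6}
         c("TF1", "G4"),                # regulated gene design
         character()),                  # wild type
    product = "EX_P1", regulated = TRUE, min_growth = 0.1
  )
  expect_equal(aud$deletions, c("G5;G6", "TF1;G4", ""))
  expect_true(aud$lethal[1])
  expect_false(aud$lethal[2])
  expect_equal(aud$growth[2], 0.8, tolerance = 1e-6)
  expect_equal(aud$product[2], 10, tolerance = 1e-6)
  expect_equal(aud$yield_pct[2], 100, tolerance = 1e-4)
  # wild-type row: viable, no product
  expect_false(aud$lethal[3])
  expect_equal(aud$product[3], 0, tolerance = 1e-6)

  # the same reaction design is viable when regulation is ignored
  aud2 <- reevaluate_designs(m, env, list(list(reactions = "R5")),
                             product = "EX_P1", regulated = FALSE,
                             min_growth = 0.1)
  expect_false(aud2$lethal[1])
  expect_equal(aud2$product[1], 10, tolerance = 1e-6)
})

test_that("minimal overexpression rescue restores the unregulated yield", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  r <- min_overexpression_rescue(m, env, c("G5", "G6"), "EX_P1")
  expect_true(r$reachable)
  expect_equal(r$genes, "G1A")
  expect_equal(r$target, 10, tolerance = 1e-6)
  expect_equal(r$achieved, 10, tolerance = 1e-6)
  # a design already meeting its target needs nothing
  r2 <- min_overexpression_rescue(m, env, c("TF1", "G4"), "EX_P1")
  expect_true(r2$reachable)
  expect_length(r2$genes, 0)
  # unreachable targets are flagged
  r3 <- min_overexpression_rescue(m, env, c("G5", "G6"), "EX_P1",
                                  target = 99)
  expect_false(r3$reachable)
})

test_that("yield is measured against the no-growth theoretical maximum", {
  m <- example_network(uptake = 10)
  env <- orf_environment()
  # theoretical max P1: all substrate through R1-R2 (regulation ignored)
  expect_equal(optorf:::theoretical_max(m, env, "EX_P1"), 10, tolerance = 1e-9)
  expect_equal(yield_percent(m, env, "EX_P1", 10), 100, tolerance = 1e-9)
  expect_equal(yield_percent(m, env, "EX_P1", 0), 0)
  expect_equal(yield_percent(m, env, "EX_P1", 2.5), 25, tolerance = 1e-9)
})

test_that("intervention statistics report frequencies and correlations", {
  lists <- list(
    knock = list(c("pta", "eutD", "pgi"), c("pta", "eutD"), c("pgi", "fnr")),
    orf = list(c("fnr", "pgi"), c("arcA", "pgi"))
  )
  st <- intervention_stats(lists, pooled_threshold = 0.15,
                           method_threshold = 0.10)
  # pta and eutD always co-occur
  cm <- st$correlation$knock
  expect_equal(cm["pta", "eutD"], 1, tolerance = 1e-12)
  # fnr and arcA are mutually exclusive in the second list
  expect_lt(st$correlation$orf["fnr", "arcA"], 0)
  # pooled frequency of pgi: 4 of 5 designs
  expect_equal(st$frequency_all$pooled[st$frequency_all$gene == "pgi"], 0.8)
  # threshold filter applies to the pooled table
  expect_true(all(st$frequency$pooled >= 0.15))
  # single design: correlations undefined, reported as missing
  st1 <- intervention_stats(list(one = list(c("a", "b"))))
  expect_null(st1$correlation$one)
})
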