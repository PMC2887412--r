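# Seeded random small-network generator used for property tests and
# brute-force oracle comparisons.

#' Generate a random small integrated network
#'
#' Builds a mass-balanced toy network in the style of the worked example: a
#' substrate exchange feeding a layered set of internal metabolites, two or
#' more terminal reactions secreting distinct by-products with differing
#' biomass stoichiometry (so deletion strategies can trade growth for
#' product), random GPRs mixing single genes, two-subunit complexes and
#' isozyme pairs, and random activator/repressor rules over the requested
#' number of transcription factors (the first TF senses substrate uptake).
#' Every internal metabolite has at least one producing and one consuming
#' reaction, all internal reactions are irreversible, and identical seeds
#' give identical models.
#'
#' @param n_reactions number of internal reactions (>= 4, <= ~15).
#' @param n_genes number of metabolic genes.
#' @param n_tfs number of transcription factors (>= 0).
#' @param seed integer seed.
#' @param uptake substrate uptake capacity (lower bound of `EX_S` is
#'   `-uptake`).
#' @return an `orf_model`.
#' @export
random_toy_model <- function(n_reactions = 8, n_genes = 6, n_tfs = 2,
                             seed = 1, uptake = 10) {
  stopifnot(n_reactions >= 4, n_genes >= 2, n_tfs >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  n_int <- sample(2:3, 1L)              # internal metabolites I1..In
  n_prod <- 2L                          # by-products P1, P2
  ints <- paste0("I", seq_len(n_int))
  prods <- paste0("P", seq_len(n_prod))

  rxns <- list()
  add <- function(id, stoich, lb = 0, ub = Inf, gpr = NULL, exchange = FALSE) {
    rxns[[length(rxns) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                       ub = ub, gpr = gpr, exchange = exchange)
  }

  # guaranteed backbone: S -> I1 -> ... -> In, and two terminal reactions
  # from the last two layers to distinct by-products with different biomass
  # yields
  add("R1", c(S = -1, I1 = 1))
  k <- 1L
  if (n_int > 1L) {
    for (m in seq_len(n_int - 1L)) {
      k <- k + 1L
      add(paste0("R", k), stats::setNames(c(-1, 1), c(ints[m], ints[m + 1L])))
    }
  }
  yields <- sort(round(stats::runif(n_prod, 0.05, 0.3), 3))
  src_terminal <- if (n_int > 1L) c(ints[n_int - 1L], ints[n_int]) else rep(ints[1L], 2L)
  for (p in seq_len(n_prod)) {
    k <- k + 1L
    add(paste0("R", k),
        stats::setNames(c(-1, 1, yields[p]), c(src_terminal[p], prods[p], "B")))
  }
  # random extra internal conversions up to n_reactions
  while (k < n_reactions) {
    k <- k + 1L
    from <- sample(c("S", ints), 1L)
    to_pool <- setdiff(c(ints, prods), from)
    to <- sample(to_pool, 1L)
    st <- stats::setNames(c(-1, 1), c(from, to))
    if (to %in% prods && stats::runif(1) < 0.7) {
      st <- c(st, B = round(stats::runif(1, 0.05, 0.3), 3))
    }
    add(paste0("R", k), st)
  }

  add("EX_S", c(S = -1), lb = -abs(uptake), exchange = TRUE)
  for (p in prods) add(paste0("EX_", p), stats::setNames(-1, p), exchange = TRUE)
  add("EX_B", c(B = -1), exchange = TRUE)

  # GPRs over the internal reactions: single gene / complex / isozyme pair
  genes <- paste0("G", seq_len(n_genes))
  internal_ids <- paste0("R", seq_len(k))
  for (id in internal_ids) {
    i <- which(vapply(rxns, function(r) r$id == id, NA))
    form <- sample(c("single", "complex", "isozyme"), 1L,
                   prob = c(0.5, 0.25, 0.25))
    gs <- sample(genes, if (form == "single") 1L else 2L, replace = FALSE)
    rxns[[i]]$gpr <- switch(form,
      single = gs[1L],
      complex = paste(gs, collapse = " and "),
      isozyme = paste(gs, collapse = " or "))
  }

  rules <- data.frame(target = character(), rule = character(),
                      stringsAsFactors = FALSE)
  if (n_tfs > 0L) {
    tfs <- paste0("TF", seq_len(n_tfs))
    rules <- rbind(rules, data.frame(target = tfs[1L],
                                     rule = "not (EX_S > 0)",
                                     stringsAsFactors = FALSE))
    if (n_tfs > 1L) {
      for (t in 2:n_tfs) {
        dep <- sample(tfs[seq_len(t - 1L)], 1L)
        rl <- if (stats::runif(1) < 0.5) dep else paste("not", dep)
        rules <- rbind(rules, data.frame(target = tfs[t], rule = rl,
                                         stringsAsFactors = FALSE))
      }
    }
    # regulate a random subset of the metabolic genes that appear in GPRs
    used_genes <- unique(unlist(lapply(rxns, function(r) {
      if (is.null(r$gpr)) character() else
        regmatches(r$gpr, gregexpr("G[0-9]+", r$gpr))[[1L]]
    })))
    n_reg <- min(length(used_genes), sample(1:3, 1L))
    reg_genes <- sample(used_genes, n_reg)
    for (g in reg_genes) {
      tf <- sample(tfs, 1L)
      rl <- if (stats::runif(1) < 0.5) tf else paste("not", tf)
      rules <- rbind(rules, data.frame(target = g, rule = rl,
                                       stringsAsFactors = FALSE))
    }
  }

  mets <- data.frame(
    id = c("S", ints, prods, "B"),
    compartment = c("e", rep("c", n_int), rep("e", n_prod), "c"),
    stringsAsFactors = FALSE
  )
  mets$extracellular <- mets$compartment == "e"
  mets$name <- mets$id
  integrated_model(mets, rxns, if (nrow(rules)) rules else NULL,
                   biomass = "EX_B")
}
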