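# Brute-force oracles: exhaustive enumeration over intervention subsets and
# regulatory states with plain inner LP solves.  Deliberately independent of
# the strong-duality MILP path they are used to check.

milp_batch <- optorf:::milp_solve_batch
lp_con <- optorf:::lp_add_con
lvar <- optorf:::lin_var
fba_lp <- optorf:::build_fba_lp

all_subsets <- function(x, max_size) {
  out <- list(character())
  for (k in seq_len(min(max_size, length(x)))) {
    cmb <- utils::combn(x, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Flux-indicator effectors (pf/nf) of a compiled regulatory index.
pn_effectors <- function(reg) {
  effs <- list()
  for (conds in reg$targets) {
    for (cd in conds) {
      for (eff in c(cd$activators, cd$repressors)) {
        if (eff$kind %in% c("pf", "nf")) {
          effs[[optorf:::effector_key(eff)]] <- eff
        }
      }
    }
  }
  effs
}

# All consistent expression vectors y over regulated targets, given a fixed
# flux-indicator assignment.  Enumerates every assignment (toy scale only).
consistent_y <- function(model, env, reg, x_assign, deletions, overexpressions) {
  regulated <- names(reg$targets)
  gene_ids <- model$genes$id
  n <- length(regulated)
  sols <- list()
  y_base <- stats::setNames(rep(1L, length(gene_ids)), gene_ids)
  for (mask in 0:(2^n - 1)) {
    y <- y_base
    if (n > 0) {
      bits <- as.integer(intToBits(mask)[seq_len(n)])
      y[regulated] <- bits
    }
    yh <- y
    yh[deletions] <- 0L
    yh[overexpressions] <- 1L
    x_of <- function(eff) {
      switch(eff$kind,
        tf = yh[[eff$id]] == 1L,
        es = eff$id %in% env$stimuli,
        x_assign[[optorf:::effector_key(eff)]]
      )
    }
    ok <- TRUE
    for (tg in regulated) {
      val <- any(vapply(reg$targets[[tg]], optorf:::condition_holds, NA,
                        x_of = x_of))
      if (as.integer(val) != y[[tg]]) { ok <- FALSE; break }
    }
    if (ok) sols[[length(sols) + 1L]] <- y
  }
  sols
}

# Exhaustive gene-level designer.  Mirrors the single-level MILP semantics:
# an intervention state is admissible if some consistent Boolean state has
# deletions on expressed genes and overexpressions on repressed regulated
# metabolic genes; its value is the max product over inner-growth-optimal
# flux states consistent with the flux indicators, minus the intervention
# penalties.  Returns -Inf when nothing is admissible.
brute_force_optorf <- function(model, env, spec) {
  gpr <- compile_gpr(model)
  reg <- if (spec$regulation) compile_regulation(model, epsilon = spec$epsilon)
         else list(targets = list(), epsilon = spec$epsilon)
  genes <- model$genes
  del_pool <- setdiff(genes$id, spec$excluded_genes)
  if (!spec$allow_tf_deletion) {
    del_pool <- setdiff(del_pool, genes$id[genes$kind == "tf"])
  }
  oe_pool <- if (spec$regulation) {
    intersect(setdiff(genes$id[genes$kind == "metabolic"], spec$excluded_genes),
              names(reg$targets))
  } else character()
  effs <- pn_effectors(reg)
  eff_keys <- names(effs)

  cands <- list()     # list of list(d, xcons, penalty)
  seen <- new.env(parent = emptyenv())
  add_candidate <- function(d, x_assign, penalty) {
    key <- paste(paste(as.integer(d), collapse = ""),
                 paste(vapply(eff_keys, function(k) as.integer(x_assign[[k]]), 0L),
                       collapse = ""),
                 format(penalty, digits = 12), sep = "|")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    cands[[length(cands) + 1L]] <<- list(d = d, x = x_assign, penalty = penalty)
  }

  x_grids <- if (length(eff_keys)) {
    g <- expand.grid(rep(list(c(FALSE, TRUE)), length(eff_keys)))
    lapply(seq_len(nrow(g)), function(r) stats::setNames(as.list(g[r, ]), eff_keys))
  } else list(stats::setNames(list(), character()))

  for (D in all_subsets(del_pool, spec$k1)) {
    for (O in all_subsets(setdiff(oe_pool, D), spec$k2)) {
      penalty <- spec$alpha * length(D) + spec$beta * length(O)
      if (!spec$regulation) {
        if (length(O)) next
        yh <- stats::setNames(rep(1L, nrow(genes)), genes$id)
        yh[D] <- 0L
        d <- reaction_feasibility(gpr, yh, names(model$reactions))
        add_candidate(d, stats::setNames(list(), character()), penalty)
        next
      }
      for (x_assign in x_grids) {
        for (y in consistent_y(model, env, reg, x_assign, D, O)) {
          if (length(D) && any(y[D] != 1L)) next      # delete expressed only
          if (length(O) && any(y[O] != 0L)) next      # overexpress repressed only
          yh <- y
          yh[D] <- 0L
          yh[O] <- 1L
          d <- reaction_feasibility(gpr, yh, names(model$reactions))
          # indicator consistency with switched-off reactions is settled by
          # the LP stage (a pf effector on a dead reaction forces x = FALSE
          # there via the flux constraint v = 0)
          add_candidate(d, x_assign, penalty)
        }
      }
    }
  }

  value_of_candidates(model, env, spec, effs, cands)
}

value_of_candidates <- function(model, env, spec, effs, cands) {
  if (!length(cands)) return(-Inf)
  bio <- model$biomass
  lps1 <- lapply(cands, function(cn) {
    fba_lp(model, env, d = cn$d, min_growth = spec$min_growth)
  })
  res1 <- milp_batch(lps1)
  lps2 <- list()
  map <- integer()
  for (k in seq_along(cands)) {
    if (res1[[k]]$status != "optimal") next
    cn <- cands[[k]]
    lp <- fba_lp(model, env, d = cn$d,
                 objective = stats::setNames(1, spec$product),
                 fix = stats::setNames(res1[[k]]$objective, bio),
                 min_growth = spec$min_growth)
    v <- lp$flux_idx
    for (key in names(cn$x)) {
      eff <- effs[[key]]
      on <- isTRUE(cn$x[[key]])
      if (eff$kind == "pf") {
        lp_con(lp, lvar(v[eff$id]), if (on) ">=" else "<=", eff$threshold)
      } else {
        lp_con(lp, lvar(v[eff$id]), if (on) "<=" else ">=", -eff$threshold)
      }
    }
    lps2[[length(lps2) + 1L]] <- lp
    map[[length(map) + 1L]] <- k
  }
  res2 <- milp_batch(lps2)
  best <- -Inf
  for (i in seq_along(res2)) {
    if (res2[[i]]$status != "optimal") next
    val <- res2[[i]]$objective - cands[[map[i]]]$penalty
    if (val > best) best <- val
  }
  best
}

# Exhaustive reaction-deletion designer (no regulation, no GPR).
brute_force_optknock <- function(model, env, product, cap,
                                 excluded = character(), min_growth = 0.1) {
  deletable <- optorf:::default_deletable(model, excluded)
  subsets <- all_subsets(deletable, cap)
  bio <- model$biomass
  dvecs <- lapply(subsets, function(s) {
    d <- stats::setNames(rep(1, length(model$reactions)), names(model$reactions))
    d[s] <- 0
    d
  })
  res1 <- milp_batch(lapply(dvecs, function(d) {
    fba_lp(model, env, d = d, min_growth = min_growth)
  }))
  lps2 <- list(); map <- integer()
  for (k in seq_along(subsets)) {
    if (res1[[k]]$status != "optimal") next
    lps2[[length(lps2) + 1L]] <- fba_lp(
      model, env, d = dvecs[[k]],
      objective = stats::setNames(1, product),
      fix = stats::setNames(res1[[k]]$objective, bio),
      min_growth = min_growth
    )
    map[[length(map) + 1L]] <- k
  }
  res2 <- milp_batch(lps2)
  best <- -Inf
  best_set <- NULL
  for (i in seq_along(res2)) {
    if (res2[[i]]$status != "optimal") next
    if (res2[[i]]$objective > best) {
      best <- res2[[i]]$objective
      best_set <- subsets[[map[i]]]
    }
  }
  list(value = best, deletions = best_set)
}

# Random Boolean expression over the given identifiers (for DNF-equivalence
# property tests).
random_bool_expr <- function(ids, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    e <- optorf:::expr_lit(sample(ids, 1))
    if (stats::runif(1) < 0.3) e <- optorf:::expr_not(e)
    return(e)
  }
  op <- sample(c("and", "or", "not"), 1, prob = c(0.4, 0.4, 0.2))
  if (op == "not") {
    optorf:::expr_not(random_bool_expr(ids, depth - 1))
  } else {
    k <- sample(2:3, 1)
    args <- lapply(seq_len(k), function(i) random_bool_expr(ids, depth - 1))
    list(type = op, args = args)
  }
}

eval_dnf <- function(terms, assign) {
  if (!length(terms)) return(FALSE)
  any(vapply(terms, function(conj) {
    all(vapply(conj, function(l) {
      v <- assign[[l$id]]
      if (isTRUE(l$negated)) !v else v
    }, NA))
  }, NA))
}

example_env <- function() orf_environment()
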