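# Flux balance analysis, regulated FBA (MILP), the strong-duality block,
# and production envelopes.
#
# Primal LP shape: maximize p'v subject to S v = 0, v_j >= lb_j for the
# bounded set J_LB (uptake, secretion and irreversible reactions; reversible
# fluxes with lb = -Inf are constrained only by mass balance), v_j <= ub_j
# for finite upper bounds, and v_j = 0 for reactions switched off by gene
# states.  The dual carries free u_i per metabolite, lambda_j >= 0 per
# finite lower bound, mu_j >= 0 per finite upper bound, and h_j (bounded to
# [-h_bound, h_bound]) per deletable reaction, active only when the
# reaction is off.

add_flux_vars <- function(lp, model, env, min_growth = 0) {
  b <- reaction_bounds(model, env)
  if (min_growth > 0) {
    b$lb[model$biomass] <- max(b$lb[model$biomass], min_growth)
  }
  v <- stats::setNames(integer(length(model$reactions)), names(model$reactions))
  for (j in names(model$reactions)) {
    v[j] <- lp_add_var(lp, paste0("v.", j), b$lb[j], b$ub[j])
  }
  attr(v, "lb") <- b$lb
  attr(v, "ub") <- b$ub
  v
}

add_mass_balance <- function(lp, model, v) {
  st <- stoich_triplets(model)
  for (i in seq_along(st$metabolites)) {
    sel <- st$i == i
    if (!any(sel)) next
    lp_add_con(lp, lin(v[st$j[sel]], st$x[sel]), "=", 0)
  }
  invisible(lp)
}

# ---------------------------------------------------------------------------
# Boolean layer emitter.
#
# ctrl fields:
#   regulation            logical: include the regulatory constraints
#   deletions, overexpressions   fixed intervention sets (forced semantics)
#   z_candidates, w_candidates   gene ids with free binary z / w variables
#   K1, K2                intervention caps for the free binaries
#   strict                TRUE: z <= y, w <= 1 - y (design contract)
#   epsilon, big_M        flux-indicator threshold and linearization bound
#
# Returns exprs/vars: y, y_hat (named lin), z, w (named var indices),
# d (named lin per reaction incl. constant 1 entries), x (per effector key).
add_boolean_layer <- function(lp, model, env, v, gpr, reg, ctrl) {
  genes <- model$genes$id
  M <- ctrl$big_M
  regulated <- if (ctrl$regulation) names(reg$targets) else character()

  y <- list()
  for (g in genes) {
    y[[g]] <- if (g %in% regulated) {
      lin_var(lp_add_var(lp, paste0("y.", g), 0, 1, type = "B"))
    } else lin_const(1)
  }

  z <- list(); w <- list()
  for (g in intersect(ctrl$z_candidates, genes)) {
    z[[g]] <- lp_add_var(lp, paste0("z.", g), 0, 1, type = "B")
  }
  for (g in intersect(ctrl$w_candidates, genes)) {
    # overexpression only exists for genes that can be off
    if (!(g %in% regulated)) next
    w[[g]] <- lp_add_var(lp, paste0("w.", g), 0, 1, type = "B")
  }
  if (length(z) && !is.null(ctrl$K1)) {
    lp_add_con(lp, lin(unlist(z), rep(1, length(z))), "<=", ctrl$K1)
  }
  if (length(w) && !is.null(ctrl$K2)) {
    lp_add_con(lp, lin(unlist(w), rep(1, length(w))), "<=", ctrl$K2)
  }

  y_hat <- list()
  for (g in genes) {
    if (g %in% ctrl$deletions) { y_hat[[g]] <- lin_const(0); next }
    if (g %in% ctrl$overexpressions) { y_hat[[g]] <- lin_const(1); next }
    e <- y[[g]]
    if (!is.null(z[[g]])) {
      if (ctrl$strict) lp_add_con(lp, lin_sum(lin_var(z[[g]]), lin_scale(e, -1)), "<=", 0)
      e <- lin_sum(e, lin_var(z[[g]], -1))
    }
    if (!is.null(w[[g]])) {
      if (ctrl$strict) {
        lp_add_con(lp, lin_sum(lin_var(w[[g]]), y[[g]]), "<=", 1)
      }
      e <- lin_sum(e, lin_var(w[[g]], 1))
    }
    y_hat[[g]] <- e
  }

  x_exprs <- list()
  if (ctrl$regulation) {
    effector_expr <- function(eff) {
      key <- effector_key(eff)
      if (!is.null(x_exprs[[key]])) return(x_exprs[[key]])
      e <- switch(eff$kind,
        tf = {
          if (eff$id %in% genes) y_hat[[eff$id]]
          else stop("effector references undeclared gene: ", eff$id, call. = FALSE)
        },
        es = lin_const(as.integer(eff$id %in% env$stimuli)),
        pf = {
          xk <- lp_add_var(lp, paste0("x.", key), 0, 1, type = "B")
          # x = 1 => v >= theta ; x = 0 => v <= theta
          lp_add_con(lp, lin(c(v[eff$id], xk), c(1, -M)), ">=", eff$threshold - M)
          lp_add_con(lp, lin(c(v[eff$id], xk), c(1, -M)), "<=", eff$threshold)
          lin_var(xk)
        },
        nf = {
          xk <- lp_add_var(lp, paste0("x.", key), 0, 1, type = "B")
          # x = 1 => v <= -theta ; x = 0 => v >= -theta
          lp_add_con(lp, lin(c(v[eff$id], xk), c(1, M)), "<=", -eff$threshold + M)
          lp_add_con(lp, lin(c(v[eff$id], xk), c(1, M)), ">=", -eff$threshold)
          lin_var(xk)
        }
      )
      x_exprs[[key]] <<- e
      e
    }

    for (tg in regulated) {
      conds <- reg$targets[[tg]]
      a_exprs <- list()
      for (m in seq_along(conds)) {
        cd <- conds[[m]]
        acts <- lapply(cd$activators, effector_expr)
        reps <- lapply(cd$repressors, effector_expr)
        ntot <- length(acts) + length(reps)
        if (ntot == 0L) { a_exprs[[m]] <- lin_const(1); next }
        am <- lp_add_var(lp, paste0("a.", tg, ".", m), 0, 1, type = "B")
        for (e in acts) {
          lp_add_con(lp, lin_sum(lin_var(am), lin_scale(e, -1)), "<=", 0)
        }
        for (e in reps) {
          lp_add_con(lp, lin_sum(lin_var(am), e), "<=", 1)
        }
        big <- lin_var(am, -1)
        for (e in acts) big <- lin_sum(big, e)
        for (e in reps) big <- lin_sum(big, lin_scale(e, -1))
        # a >= sum(act) + sum(1 - rep) - (ntot - 1)
        lp_add_con(lp, big, "<=", ntot - 1 - length(reps))
        a_exprs[[m]] <- lin_var(am)
      }
      yv <- y[[tg]]
      if (length(a_exprs) == 1L && !is.null(a_exprs[[1L]]$const) &&
          !length(a_exprs[[1L]]$idx)) {
        lp_add_con(lp, yv, "=", a_exprs[[1L]]$const)
      } else {
        tot <- lin_scale(yv, -1)
        for (e in a_exprs) {
          lp_add_con(lp, lin_sum(yv, lin_scale(e, -1)), ">=", 0)
          tot <- lin_sum(tot, e)
        }
        lp_add_con(lp, tot, ">=", 0)
      }
    }
  }

  # GPR layer on surrogate expression
  d_exprs <- list()
  for (j in names(model$reactions)) d_exprs[[j]] <- lin_const(1)
  for (j in names(gpr)) {
    complexes <- gpr[[j]]
    b_exprs <- list()
    for (n in seq_along(complexes)) {
      gs <- complexes[[n]]
      exprs <- lapply(gs, function(g) y_hat[[g]])
      consts <- vapply(exprs, function(e) !length(e$idx), NA)
      if (all(consts)) {
        b_exprs[[n]] <- lin_const(as.integer(all(vapply(exprs, `[[`, 0, "const") >= 0.5)))
        next
      }
      if (length(gs) == 1L) { b_exprs[[n]] <- exprs[[1L]]; next }
      bn <- lp_add_var(lp, paste0("b.", j, ".", n), 0, 1, type = "B")
      tot <- lin_var(bn, -1)
      for (e in exprs) {
        lp_add_con(lp, lin_sum(lin_var(bn), lin_scale(e, -1)), "<=", 0)
        tot <- lin_sum(tot, e)
      }
      lp_add_con(lp, tot, "<=", length(gs) - 1)
      b_exprs[[n]] <- lin_var(bn)
    }
    consts <- vapply(b_exprs, function(e) !length(e$idx), NA)
    if (all(consts)) {
      dj <- lin_const(as.integer(any(vapply(b_exprs, `[[`, 0, "const") >= 0.5)))
    } else if (length(b_exprs) == 1L) {
      dj <- b_exprs[[1L]]
    } else {
      dv <- lp_add_var(lp, paste0("d.", j), 0, 1, type = "B")
      tot <- lin_var(dv, -1)
      for (e in b_exprs) {
        lp_add_con(lp, lin_sum(lin_var(dv), lin_scale(e, -1)), ">=", 0)
        tot <- lin_sum(tot, e)
      }
      lp_add_con(lp, tot, ">=", 0)
      dj <- lin_var(dv)
    }
    d_exprs[[j]] <- dj
    # flux gating |v_j| <= M d_j
    lp_add_con(lp, lin_sum(lin_var(v[j]), lin_scale(dj, -M)), "<=", 0)
    lp_add_con(lp, lin_sum(lin_var(v[j]), lin_scale(dj, M)), ">=", 0)
  }

  list(y = y, y_hat = y_hat, z = z, w = w, d = d_exprs, x = x_exprs)
}

default_ctrl <- function(regulation = TRUE, deletions = character(),
                         overexpressions = character(),
                         z_candidates = character(),
                         w_candidates = character(),
                         K1 = NULL, K2 = NULL, strict = FALSE,
                         epsilon = 1e-3, big_M = 1000) {
  list(regulation = regulation, deletions = deletions,
       overexpressions = overexpressions, z_candidates = z_candidates,
       w_candidates = w_candidates, K1 = K1, K2 = K2, strict = strict,
       epsilon = epsilon, big_M = big_M)
}

# ---------------------------------------------------------------------------
# Strong-duality block: primal feasibility is assumed already emitted (flux
# vars + mass balance); this adds dual variables, stationarity, h-gating
# and the objective-equality row.  `d_exprs` supplies the on/off expression
# per reaction (constant 1 entries dualize without an h variable).
add_duality_block <- function(lp, model, v, p_obj, d_exprs = NULL,
                              h_bound = 1) {
  lb <- attr(v, "lb"); ub <- attr(v, "ub")
  st <- stoich_triplets(model)
  u <- stats::setNames(integer(length(st$metabolites)), st$metabolites)
  for (i in st$metabolites) u[i] <- lp_add_var(lp, paste0("u.", i))
  lam <- integer(); mu <- integer(); h <- integer()
  duality_lhs <- lin()   # p'v - dual objective = 0
  for (j in names(model$reactions)) {
    p_j <- if (!is.null(p_obj[[j]])) p_obj[[j]] else 0
    duality_lhs <- lin_sum(duality_lhs, lin_var(v[j], p_j))
  }
  for (j in names(model$reactions)) {
    jn <- match(j, st$reactions)
    sel <- st$j == jn
    stat <- lin(u[st$i[sel]], st$x[sel])
    if (is.finite(lb[j])) {
      lam[[j]] <- lp_add_var(lp, paste0("lam.", j), 0, Inf)
      stat <- lin_sum(stat, lin_var(lam[[j]], -1))
      duality_lhs <- lin_sum(duality_lhs, lin_var(lam[[j]], lb[j]))
    }
    if (is.finite(ub[j])) {
      mu[[j]] <- lp_add_var(lp, paste0("mu.", j), 0, Inf)
      stat <- lin_sum(stat, lin_var(mu[[j]], 1))
      duality_lhs <- lin_sum(duality_lhs, lin_var(mu[[j]], -ub[j]))
    }
    dj <- if (!is.null(d_exprs)) d_exprs[[j]] else lin_const(1)
    deletable <- length(dj$idx) > 0L || dj$const < 0.5
    if (deletable) {
      h[[j]] <- lp_add_var(lp, paste0("h.", j), -h_bound, h_bound)
      stat <- lin_sum(stat, lin_var(h[[j]], 1))
      # h_j = 0 when the reaction is on
      lp_add_con(lp, lin_sum(lin_var(h[[j]]), lin_scale(dj, h_bound)), "<=", h_bound)
      lp_add_con(lp, lin_sum(lin_var(h[[j]]), lin_scale(dj, -h_bound)), ">=", -h_bound)
    }
    p_j <- if (!is.null(p_obj[[j]])) p_obj[[j]] else 0
    lp_add_con(lp, stat, "=", p_j)
  }
  lp_add_con(lp, duality_lhs, "=", 0)
  list(u = u, lambda = lam, mu = mu, h = h)
}

#' Build the strong-duality constraint block
#'
#' Constructs the single-level optimality encoding of the inner growth LP:
#' primal feasibility (mass balance and bounds), dual feasibility
#' (stationarity with multipliers for bounds and reaction removal), the
#' objective-equality row, and the conditional constraints that force
#' `v_j = 0` and release the removal dual `h_j` only when a reaction is
#' off.  With all reactions on, any feasible point of the block attains
#' exactly the FBA optimum.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param d optional named 0/1 vector fixing reaction availability
#'   (default: all available).
#' @param min_growth lower bound imposed on the biomass flux.
#' @param h_bound bound on the reaction-removal duals.
#' @return list with the assembled `lp`, flux indices `v` and dual indices.
#' @export
build_strong_duality <- function(model, env, d = NULL, min_growth = 0,
                                 h_bound = 1) {
  lp <- lp_new()
  v <- add_flux_vars(lp, model, env, min_growth = min_growth)
  add_mass_balance(lp, model, v)
  d_exprs <- NULL
  if (!is.null(d)) {
    d_exprs <- list()
    for (j in names(model$reactions)) d_exprs[[j]] <- lin_const(1)
    for (j in names(d)) {
      d_exprs[[j]] <- lin_const(as.numeric(d[[j]]))
      if (d[[j]] < 0.5) {
        lp$lb[v[j]] <- 0
        lp$ub[v[j]] <- 0
      }
    }
  }
  p_obj <- stats::setNames(list(1), model$biomass)
  duals <- add_duality_block(lp, model, v, p_obj, d_exprs, h_bound = h_bound)
  list(lp = lp, v = v, duals = duals, model = model)
}

#' Solve a flux balance analysis LP
#'
#' Maximizes (or minimizes) a linear flux objective subject to steady-state
#' mass balance and reaction bounds.  `d` switches reactions off (their
#' flux is fixed to zero); regulation is not consulted.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param d optional named logical/0-1 vector of reaction availability.
#' @param objective named coefficient vector (default: biomass = 1).
#' @param maximize direction.
#' @param fix optional named fluxes to pin (equality constraints).
#' @param min_growth optional lower bound on biomass flux.
#' @return an `orf_fba` object: `status` ("optimal", "infeasible",
#'   "unbounded"), `objective`, `flux`, `growth`.
#' @export
solve_fba <- function(model, env = orf_environment(), d = NULL,
                      objective = NULL, maximize = TRUE, fix = NULL,
                      min_growth = 0) {
  lp <- build_fba_lp(model, env, d, objective, maximize, fix, min_growth)
  res <- milp_solve(lp)
  fba_result(res, model)
}

build_fba_lp <- function(model, env = orf_environment(), d = NULL,
                         objective = NULL, maximize = TRUE, fix = NULL,
                         min_growth = 0) {
  if (is.null(objective)) objective <- stats::setNames(1, model$biomass)
  lp <- lp_new(maximize = maximize)
  v <- add_flux_vars(lp, model, env, min_growth = min_growth)
  add_mass_balance(lp, model, v)
  if (!is.null(d)) {
    off <- names(d)[as.numeric(d) < 0.5]
    for (j in off) { lp$lb[v[j]] <- 0; lp$ub[v[j]] <- 0 }
  }
  if (!is.null(fix)) {
    for (j in names(fix)) lp_add_con(lp, lin_var(v[j]), "=", fix[[j]])
  }
  bad <- setdiff(names(objective), names(model$reactions))
  if (length(bad)) stop("objective references unknown reaction(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  lp_set_objective(lp, lin(v[names(objective)], as.numeric(objective)),
                   maximize = maximize)
  lp$flux_idx <- v
  lp
}

fba_result <- function(res, model) {
  flux <- if (!is.null(res$x)) res$x[grepl("^v\\.", names(res$x))] else NULL
  if (!is.null(flux)) names(flux) <- sub("^v\\.", "", names(flux))
  structure(list(
    status = res$status,
    objective = res$objective,
    flux = flux,
    growth = if (!is.null(flux)) unname(flux[model$biomass]) else NA_real_
  ), class = "orf_fba")
}

#' @export
print.orf_fba <- function(x, ...) {
  cat(sprintf("FBA solution [%s]", x$status))
  if (!is.na(x$objective)) cat(sprintf("  objective = %.6g", x$objective))
  if (!is.null(x$flux)) cat(sprintf("  growth = %.6g", x$growth))
  cat("\n")
  invisible(x)
}

#' Solve regulated flux balance analysis
#'
#' Maximizes the objective over fluxes and Boolean regulatory variables
#' jointly: gene expression follows the compiled regulatory rules (with
#' flux indicators coupling expression to the flux state), reaction
#' feasibility follows the GPRs on the surrogate expression states, and
#' fluxes are forced to zero for infeasible reactions.  Deletions force
#' genes off and overexpressions force them on (simulation semantics for
#' externally supplied designs).
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param deletions,overexpressions character vectors of gene ids.
#' @param objective named coefficients (default biomass = 1).
#' @param maximize direction.
#' @param fix optional named fluxes to pin.
#' @param min_growth optional biomass lower bound (default 0: lethality is
#'   observable as near-zero growth rather than infeasibility).
#' @param epsilon flux-indicator threshold.
#' @param big_M linearization bound on fluxes.
#' @return an `orf_rfba` object: `status`, `objective`, `flux`, `growth`,
#'   `state` (a `boolean_state`), `lethal` (growth below `1e-6`).
#' @export
solve_regulated_fba <- function(model, env = orf_environment(),
                                deletions = character(),
                                overexpressions = character(),
                                objective = NULL, maximize = TRUE,
                                fix = NULL, min_growth = 0,
                                epsilon = 1e-3, big_M = 1000) {
  if (is.null(objective)) objective <- stats::setNames(1, model$biomass)
  gpr <- compile_gpr(model)
  reg <- compile_regulation(model, epsilon = epsilon)
  lp <- lp_new()
  v <- add_flux_vars(lp, model, env, min_growth = min_growth)
  add_mass_balance(lp, model, v)
  if (!is.null(fix)) {
    for (j in names(fix)) lp_add_con(lp, lin_var(v[j]), "=", fix[[j]])
  }
  ctrl <- default_ctrl(regulation = TRUE, deletions = deletions,
                       overexpressions = overexpressions,
                       epsilon = epsilon, big_M = big_M)
  bl <- add_boolean_layer(lp, model, env, v, gpr, reg, ctrl)
  lp_set_objective(lp, lin(v[names(objective)], as.numeric(objective)),
                   maximize = maximize)
  res <- milp_solve(lp)
  flux <- if (!is.null(res$x)) res$x[grepl("^v\\.", names(res$x))] else NULL
  if (!is.null(flux)) names(flux) <- sub("^v\\.", "", names(flux))
  state <- NULL
  if (!is.null(res$x)) {
    eval_lin <- function(e) {
      val <- e$const
      if (length(e$idx)) val <- val + sum(e$coef * res$x[e$idx])
      val
    }
    y <- vapply(bl$y, eval_lin, 0)
    yh <- vapply(bl$y_hat, eval_lin, 0)
    dv <- vapply(bl$d, eval_lin, 0)
    state <- structure(list(
      y = round(y), y_hat = round(yh), d = round(dv) >= 1,
      x = lapply(bl$x, eval_lin), a = NULL,
      n_fixed_points = NA_integer_
    ), class = "boolean_state")
  }
  growth <- if (!is.null(flux)) unname(flux[model$biomass]) else NA_real_
  structure(list(
    status = res$status, objective = res$objective, flux = flux,
    growth = growth, state = state,
    lethal = if (res$status == "optimal") growth < 1e-6 else res$status == "infeasible"
  ), class = "orf_rfba")
}

#' @export
print.orf_rfba <- function(x, ...) {
  cat(sprintf("Regulated FBA [%s]", x$status))
  if (!is.na(x$objective)) cat(sprintf("  objective = %.6g  growth = %.6g",
                                       x$objective, x$growth))
  if (isTRUE(x$lethal)) cat("  (lethal)")
  cat("\n")
  invisible(x)
}

#' Compute a production envelope
#'
#' For a grid of growth levels between 0 and the maximum attainable
#' growth, reports the minimum and maximum product flux with growth fixed
#' at each level.  The regulated variant imposes the full Boolean layer in
#' every sub-solve.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param product product reaction id.
#' @param n_points number of growth levels (>= 2).
#' @param regulated apply regulatory constraints.
#' @param deletions,overexpressions interventions applied throughout.
#' @param epsilon,big_M regulated-layer parameters.
#' @return an `orf_envelope` data.frame with columns `growth`,
#'   `product_min`, `product_max`.
#' @export
production_envelope <- function(model, env = orf_environment(), product,
                                n_points = 11, regulated = FALSE,
                                deletions = character(),
                                overexpressions = character(),
                                epsilon = 1e-3, big_M = 1000) {
  stopifnot(n_points >= 2)
  solve_at <- function(objective, maximize, fix = NULL) {
    if (regulated) {
      build_rfba_lp(model, env, deletions, overexpressions, objective,
                    maximize, fix, epsilon = epsilon, big_M = big_M)
    } else {
      dels <- deletions
      d <- NULL
      if (length(dels)) {
        gpr <- compile_gpr(model)
        yh <- stats::setNames(rep(TRUE, nrow(model$genes)), model$genes$id)
        yh[dels] <- FALSE
        d <- reaction_feasibility(gpr, yh, names(model$reactions))
      }
      build_fba_lp(model, env, d, objective, maximize, fix)
    }
  }
  obj_bio <- stats::setNames(1, model$biomass)
  obj_prod <- stats::setNames(1, product)
  res_max <- milp_solve(solve_at(obj_bio, TRUE))
  if (res_max$status != "optimal" || res_max$objective < 1e-9) {
    row <- grid_row(model, env, product, 0, solve_at)
    out <- data.frame(growth = 0, product_min = row[1], product_max = row[2])
    return(structure(out, class = c("orf_envelope", "data.frame")))
  }
  gmax <- res_max$objective
  levels <- seq(0, gmax, length.out = n_points)
  lps <- list()
  for (g in levels) {
    lps[[length(lps) + 1L]] <- solve_at(obj_prod, FALSE, fix = stats::setNames(g, model$biomass))
    lps[[length(lps) + 1L]] <- solve_at(obj_prod, TRUE, fix = stats::setNames(g, model$biomass))
  }
  res <- milp_solve_batch(lps)
  pmin_ <- vapply(seq_along(levels), function(k) res[[2 * k - 1L]]$objective, 0)
  pmax_ <- vapply(seq_along(levels), function(k) res[[2 * k]]$objective, 0)
  out <- data.frame(growth = levels, product_min = pmin_, product_max = pmax_)
  structure(out, class = c("orf_envelope", "data.frame"))
}

grid_row <- function(model, env, product, g, solve_at) {
  obj_prod <- stats::setNames(1, product)
  lo <- milp_solve(solve_at(obj_prod, FALSE, fix = stats::setNames(g, model$biomass)))
  hi <- milp_solve(solve_at(obj_prod, TRUE, fix = stats::setNames(g, model$biomass)))
  c(lo$objective, hi$objective)
}

# Regulated-FBA problem without solving (shared by the envelope batcher).
build_rfba_lp <- function(model, env, deletions, overexpressions, objective,
                          maximize, fix = NULL, min_growth = 0,
                          epsilon = 1e-3, big_M = 1000) {
  gpr <- compile_gpr(model)
  reg <- compile_regulation(model, epsilon = epsilon)
  lp <- lp_new()
  v <- add_flux_vars(lp, model, env, min_growth = min_growth)
  add_mass_balance(lp, model, v)
  if (!is.null(fix)) {
    for (j in names(fix)) lp_add_con(lp, lin_var(v[j]), "=", fix[[j]])
  }
  ctrl <- default_ctrl(regulation = TRUE, deletions = deletions,
                       overexpressions = overexpressions,
                       epsilon = epsilon, big_M = big_M)
  add_boolean_layer(lp, model, env, v, gpr, reg, ctrl)
  lp_set_objective(lp, lin(v[names(objective)], as.numeric(objective)),
                   maximize = maximize)
  lp$flux_idx <- v
  lp
}

#' @export
print.orf_envelope <- function(x, ...) {
  cat("Production envelope (", nrow(x), " growth levels)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
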