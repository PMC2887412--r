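# Reaction-deletion bilevel designer: the comparison baseline.  Deletions
# act directly on reactions (GPRs and regulation are not consulted), which
# is exactly the semantics whose pitfalls the gene-level designer avoids:
# reactions without genes remain "deletable" here, and the gene deletions
# actually required to remove a reaction may knock out more.

build_optknock_milp <- function(model, env, product, max_deletions,
                                deletable, min_growth, big_M, h_bound,
                                alpha = 0, cuts = list(), time_limit = NULL,
                                product_target = NULL, minimize_deletions = FALSE) {
  lp <- lp_new()
  v <- add_flux_vars(lp, model, env, min_growth = min_growth)
  add_mass_balance(lp, model, v)
  d_exprs <- list()
  for (j in names(model$reactions)) d_exprs[[j]] <- lin_const(1)
  dvar <- list()
  for (j in deletable) {
    dvar[[j]] <- lp_add_var(lp, paste0("d.", j), 0, 1, type = "B")
    d_exprs[[j]] <- lin_var(dvar[[j]])
    lp_add_con(lp, lin(c(v[j], dvar[[j]]), c(1, -big_M)), "<=", 0)
    lp_add_con(lp, lin(c(v[j], dvar[[j]]), c(1, big_M)), ">=", 0)
  }
  if (length(dvar)) {
    # at most `max_deletions` reactions switched off
    lp_add_con(lp, lin(unlist(dvar), rep(1, length(dvar))), ">=",
               length(dvar) - max_deletions)
  }
  p_obj <- stats::setNames(list(1), model$biomass)
  duals <- add_duality_block(lp, model, v, p_obj, d_exprs, h_bound = h_bound)
  for (cut in cuts) {
    # exclude the stored deletion set and all its supersets: at least one
    # of its reactions must stay available
    expr <- lin()
    for (j in intersect(cut, names(dvar))) {
      expr <- lin_sum(expr, lin_var(dvar[[j]], 1))
    }
    if (length(expr$idx)) lp_add_con(lp, expr, ">=", 1)
  }
  if (!is.null(product_target)) {
    lp_add_con(lp, lin_var(v[product]), ">=", product_target)
  }
  if (minimize_deletions) {
    obj <- lin()
    for (j in names(dvar)) obj <- lin_sum(obj, lin_var(dvar[[j]], 1))
    lp_set_objective(lp, obj, maximize = TRUE)  # max sum d = min deletions
  } else {
    obj <- lin_var(v[product])
    for (j in names(dvar)) obj <- lin_sum(obj, lin_var(dvar[[j]], alpha))
    lp_set_objective(lp, obj, maximize = TRUE)
  }
  lp$time_limit <- time_limit
  list(lp = lp, v = v, dvar = dvar, duals = duals, model = model,
       product = product)
}

extract_optknock <- function(built, res) {
  if (res$status %in% c("infeasible", "error")) {
    return(structure(list(status = res$status, feasible = FALSE,
                          message = res$message), class = "orf_design"))
  }
  x <- res$x
  flux <- x[grepl("^v\\.", names(x))]
  names(flux) <- sub("^v\\.", "", names(flux))
  deleted <- names(built$dvar)[vapply(built$dvar, function(k) x[k] < 0.5, NA)]
  duals <- built$duals
  lbv <- attr(built$v, "lb"); ubv <- attr(built$v, "ub")
  dual_obj <- 0
  for (j in names(duals$lambda)) dual_obj <- dual_obj - x[duals$lambda[[j]]] * lbv[j]
  for (j in names(duals$mu)) dual_obj <- dual_obj + x[duals$mu[[j]]] * ubv[j]
  growth <- unname(flux[built$model$biomass])
  structure(list(
    status = res$status, feasible = TRUE, kind = "reaction",
    deletions = deleted, tf_deletions = character(),
    overexpressions = character(),
    growth = growth,
    product = unname(flux[built$product]),
    product_id = built$product,
    objective = unname(flux[built$product]),
    flux = flux,
    duality_gap = abs(growth - unname(dual_obj)),
    dual = list(
      u = extract_named(x, duals$u),
      lambda = extract_named(x, unlist(duals$lambda)),
      mu = extract_named(x, unlist(duals$mu)),
      h = extract_named(x, unlist(duals$h))
    ),
    mip_gap = res$mip_gap,
    regulation = FALSE
  ), class = "orf_design")
}

# Recompute the exact optimum for a fixed deletion set (the deletion-
# minimizing stage works against a slack product target, so its incidental
# flux vector can sit a hair below the true optimum).
refine_optknock <- function(model, env, des, min_growth) {
  d <- stats::setNames(rep(1, length(model$reactions)), names(model$reactions))
  d[des$deletions] <- 0
  g <- solve_fba(model, env, d = d, min_growth = min_growth)
  if (g$status != "optimal") return(des)
  p <- solve_fba(model, env, d = d,
                 objective = stats::setNames(1, des$product_id),
                 fix = stats::setNames(g$growth, model$biomass),
                 min_growth = min_growth)
  if (p$status != "optimal") return(des)
  des$growth <- g$growth
  des$product <- p$objective
  des$objective <- p$objective
  des$flux <- p$flux
  des
}

default_deletable <- function(model, excluded = character()) {
  ids <- names(model$reactions)
  exch <- vapply(model$reactions, function(r) r$exchange, NA)
  setdiff(ids[!exch & ids != model$biomass], excluded)
}

#' Reaction-deletion growth-coupled strain design
#'
#' Maximizes product secretion at inner-optimal growth over deletion sets
#' of at most `max_deletions` reactions, via the strong-duality MILP.
#' Transcriptional regulation and GPRs are not applied.  After the optimum
#' is found, a second stage discards deletions that do not contribute to
#' it (smallest deletion set attaining the optimal production).
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param product product (secretion) reaction id.
#' @param max_deletions deletion cap.
#' @param excluded reaction ids never considered for deletion (exchanges
#'   and the biomass reaction are always excluded).
#' @param min_growth minimum growth demanded (1/hr).
#' @param big_M,h_bound,time_limit solver parameters.
#' @param tidy run the deletion-minimizing second stage.
#' @return an `orf_design` with `kind = "reaction"`.
#' @export
optknock <- function(model, env = orf_environment(), product,
                     max_deletions = 2, excluded = character(),
                     min_growth = 0.1, big_M = 1000, h_bound = 1,
                     time_limit = NULL, tidy = TRUE) {
  deletable <- default_deletable(model, excluded)
  built <- build_optknock_milp(model, env, product, max_deletions,
                               deletable, min_growth, big_M, h_bound,
                               time_limit = time_limit)
  res <- milp_solve(built$lp)
  des <- extract_optknock(built, res)
  if (tidy && isTRUE(des$feasible) && length(des$deletions)) {
    built2 <- build_optknock_milp(model, env, product, max_deletions,
                                  deletable, min_growth, big_M, h_bound,
                                  time_limit = time_limit,
                                  product_target = des$product - 1e-7,
                                  minimize_deletions = TRUE)
    res2 <- milp_solve(built2$lp)
    if (res2$status == "optimal") {
      des <- refine_optknock(model, env, extract_optknock(built2, res2),
                             min_growth)
    }
  }
  des
}

#' Enumerate alternative reaction-deletion designs
#'
#' Successive solves with integer cuts excluding previously returned
#' deletion sets; the objective sequence is non-increasing and all sets
#' are distinct.
#'
#' @inheritParams optknock
#' @param n maximum number of designs.
#' @param min_product discard designs below this product flux.
#' @return an `orf_design_list`.
#' @export
enumerate_optknock <- function(model, env = orf_environment(), product,
                               max_deletions = 2, n = 5,
                               excluded = character(), min_growth = 0.1,
                               big_M = 1000, h_bound = 1,
                               min_product = 1e-6, time_limit = NULL) {
  deletable <- default_deletable(model, excluded)
  out <- list()
  cuts <- list()
  for (k in seq_len(n)) {
    built <- build_optknock_milp(model, env, product, max_deletions,
                                 deletable, min_growth, big_M, h_bound,
                                 cuts = cuts, time_limit = time_limit)
    res <- milp_solve(built$lp)
    des <- extract_optknock(built, res)
    if (!isTRUE(des$feasible)) break
    if (des$product < min_product) break
    if (length(des$deletions)) {
      # prune tie-broken deletions that do not contribute to the optimum
      built2 <- build_optknock_milp(model, env, product, max_deletions,
                                    deletable, min_growth, big_M, h_bound,
                                    cuts = cuts, time_limit = time_limit,
                                    product_target = des$product - 1e-7,
                                    minimize_deletions = TRUE)
      res2 <- milp_solve(built2$lp)
      if (res2$status == "optimal") {
        des <- refine_optknock(model, env, extract_optknock(built2, res2),
                               min_growth)
      }
    }
    out[[length(out) + 1L]] <- des
    cuts[[length(cuts) + 1L]] <- des$deletions
  }
  structure(out, class = "orf_design_list")
}
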