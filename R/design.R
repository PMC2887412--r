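# Bilevel strain design: the gene-level designer (deletions of metabolic
# genes and TFs, overexpression of repressed metabolic genes) and shared
# machinery.  The inner growth-maximization LP is replaced by its strong-
# duality optimality conditions, giving a single-level MILP whose outer
# objective maximizes product secretion with small penalties on the number
# of interventions.

#' Specify a strain-design problem
#'
#' Collects the knobs of the gene-level designer.  The penalties `alpha`
#' and `beta` charge each deletion and overexpression so that an
#' intervention only appears when it buys more product than the penalty;
#' at their default `1e-6` they prune unnecessary modifications without
#' affecting the attainable production.  `delta` is the minimum number of
#' intervention differences enforced between successively enumerated
#' designs.
#'
#' @param product product (secretion) reaction id.
#' @param k1 maximum number of gene/TF deletions.
#' @param k2 maximum number of metabolic-gene overexpressions.
#' @param alpha,beta per-intervention penalties in the outer objective.
#' @param delta diversity parameter for enumeration (>= 1).
#' @param min_growth minimum growth rate demanded of designs (1/hr).
#' @param excluded_genes genes that must not be deleted.
#' @param regulation apply the transcriptional regulatory constraints.
#' @param allow_tf_deletion allow deletion of transcription factors.
#' @param epsilon flux-indicator threshold.
#' @param big_M flux linearization bound (mmol/gDW/hr).
#' @param h_bound bound on the reaction-removal duals.
#' @param time_limit optional solver time limit in seconds per solve.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(product, k1 = 2, k2 = 0, alpha = 1e-6, beta = 1e-6,
                        delta = 1, min_growth = 0.1,
                        excluded_genes = character(), regulation = TRUE,
                        allow_tf_deletion = TRUE, epsilon = 1e-3,
                        big_M = 1000, h_bound = 1, time_limit = NULL) {
  stopifnot(k1 >= 0, k2 >= 0, alpha >= 0, beta >= 0, delta >= 1,
            min_growth >= 0)
  structure(list(product = product, k1 = k1, k2 = k2, alpha = alpha,
                 beta = beta, delta = delta, min_growth = min_growth,
                 excluded_genes = excluded_genes, regulation = regulation,
                 allow_tf_deletion = allow_tf_deletion, epsilon = epsilon,
                 big_M = big_M, h_bound = h_bound, time_limit = time_limit),
            class = "design_spec")
}

# Assemble the single-level design MILP.  opts extends a design_spec with:
#   objective        "product" or "min_w"
#   fixed_deletions  genes forced off (audit/rescue semantics, no z vars)
#   product_target   optional lower bound on product flux
#   cuts             list of list(deletions, overexpressions)
build_design_milp <- function(model, env, spec, opts = list()) {
  lp <- lp_new()
  v <- add_flux_vars(lp, model, env, min_growth = spec$min_growth)
  add_mass_balance(lp, model, v)
  gpr <- compile_gpr(model)
  reg <- if (spec$regulation) compile_regulation(model, epsilon = spec$epsilon)
         else structure(list(targets = list(), epsilon = spec$epsilon),
                        class = "reg_index")
  genes <- model$genes
  z_cand <- character()
  if (identical(opts$objective, "min_w") || spec$k1 > 0) {
    z_cand <- setdiff(genes$id, c(spec$excluded_genes, opts$fixed_deletions))
    if (!spec$allow_tf_deletion) {
      z_cand <- setdiff(z_cand, genes$id[genes$kind == "tf"])
    }
    if (identical(opts$objective, "min_w")) z_cand <- character()
  }
  w_cand <- if (spec$k2 > 0 || identical(opts$objective, "min_w")) {
    setdiff(genes$id[genes$kind == "metabolic"], spec$excluded_genes)
  } else character()

  ctrl <- default_ctrl(
    regulation = spec$regulation,
    deletions = opts$fixed_deletions %||% character(),
    z_candidates = z_cand,
    w_candidates = w_cand,
    K1 = spec$k1, K2 = if (identical(opts$objective, "min_w")) NULL else spec$k2,
    strict = TRUE, epsilon = spec$epsilon, big_M = spec$big_M
  )
  bl <- add_boolean_layer(lp, model, env, v, gpr, reg, ctrl)
  p_obj <- stats::setNames(list(1), model$biomass)
  duals <- add_duality_block(lp, model, v, p_obj, bl$d,
                             h_bound = spec$h_bound)

  if (!is.null(opts$product_target)) {
    lp_add_con(lp, lin_var(v[spec$product]), ">=", opts$product_target)
  }
  for (cut in opts$cuts %||% list()) {
    expr <- lin()
    base <- 0
    for (g in names(bl$z)) {
      if (g %in% cut$deletions) {
        expr <- lin_sum(expr, lin_var(bl$z[[g]], -1)); base <- base + 1
      } else {
        expr <- lin_sum(expr, lin_var(bl$z[[g]], 1))
      }
    }
    for (g in names(bl$w)) {
      if (g %in% cut$overexpressions) {
        expr <- lin_sum(expr, lin_var(bl$w[[g]], -1)); base <- base + 1
      } else {
        expr <- lin_sum(expr, lin_var(bl$w[[g]], 1))
      }
    }
    lp_add_con(lp, expr, ">=", spec$delta - base)
  }

  if (identical(opts$objective, "min_w")) {
    obj <- lin()
    for (g in names(bl$w)) obj <- lin_sum(obj, lin_var(bl$w[[g]], 1))
    lp_set_objective(lp, obj, maximize = FALSE)
  } else {
    obj <- lin_var(v[spec$product])
    for (g in names(bl$z)) obj <- lin_sum(obj, lin_var(bl$z[[g]], -spec$alpha))
    for (g in names(bl$w)) obj <- lin_sum(obj, lin_var(bl$w[[g]], -spec$beta))
    lp_set_objective(lp, obj, maximize = TRUE)
  }
  lp$time_limit <- spec$time_limit
  list(lp = lp, v = v, bl = bl, duals = duals, model = model, spec = spec)
}

extract_design <- function(built, res, kind = "gene") {
  if (res$status %in% c("infeasible", "error")) {
    return(structure(list(status = res$status, feasible = FALSE,
                          message = res$message),
                     class = "orf_design"))
  }
  x <- res$x
  v <- built$v; bl <- built$bl; model <- built$model; spec <- built$spec
  flux <- x[grepl("^v\\.", names(x))]
  names(flux) <- sub("^v\\.", "", names(flux))
  zs <- names(bl$z)[vapply(bl$z, function(k) x[k] > 0.5, NA)]
  ws <- names(bl$w)[vapply(bl$w, function(k) x[k] > 0.5, NA)]
  tf_ids <- model$genes$id[model$genes$kind == "tf"]
  duals <- built$duals
  dual_obj <- 0
  lbv <- attr(built$v, "lb"); ubv <- attr(built$v, "ub")
  for (j in names(duals$lambda)) dual_obj <- dual_obj - x[duals$lambda[[j]]] * lbv[j]
  for (j in names(duals$mu)) dual_obj <- dual_obj + x[duals$mu[[j]]] * ubv[j]
  growth <- unname(flux[model$biomass])
  structure(list(
    status = res$status, feasible = TRUE, kind = kind,
    deletions = setdiff(zs, tf_ids), tf_deletions = intersect(zs, tf_ids),
    overexpressions = ws,
    growth = growth,
    product = unname(flux[spec$product]),
    product_id = spec$product,
    objective = res$objective,
    flux = flux,
    duality_gap = abs(growth - unname(dual_obj)),
    dual = list(
      u = extract_named(x, duals$u),
      lambda = extract_named(x, unlist(duals$lambda)),
      mu = extract_named(x, unlist(duals$mu)),
      h = extract_named(x, unlist(duals$h))
    ),
    mip_gap = res$mip_gap,
    regulation = spec$regulation
  ), class = "orf_design")
}

extract_named <- function(x, idx) {
  if (!length(idx)) return(stats::setNames(numeric(), character()))
  stats::setNames(unname(x[idx]), names(idx))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-level growth-coupled strain design
#'
#' Searches for up to `k1` gene or transcription-factor deletions and up to
#' `k2` overexpressions of repressed metabolic genes that maximize product
#' secretion at the inner-optimal growth rate, subject to GPR and (when
#' enabled) transcriptional regulatory constraints.  The bilevel program is
#' solved as a single MILP via strong duality; deletions are only admitted
#' on expressed genes and overexpressions on repressed metabolic genes (TF
#' overexpression is never allowed).
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param spec a [design_spec()] (or a product reaction id, with the other
#'   settings at their defaults).
#' @param ... passed to [design_spec()] when `spec` is a reaction id.
#' @return an `orf_design`.
#' @examples
#' \dontrun{
#' m <- example_network()
#' optorf(m, orf_environment(), design_spec("EX_P1", k1 = 2, min_growth = 0.1))
#' }
#' @export
optorf <- function(model, env = orf_environment(), spec, ...) {
  if (is.character(spec)) spec <- design_spec(spec, ...)
  built <- build_design_milp(model, env, spec)
  res <- milp_solve(built$lp)
  extract_design(built, res)
}

#' Enumerate alternative gene-level designs
#'
#' Solves the design MILP repeatedly, adding after each solution an integer
#' cut that demands at least `delta` intervention differences from every
#' stored solution.  Objectives are non-increasing; enumeration stops early
#' when the problem becomes infeasible or designs drop below usefulness
#' (product below `min_product`).
#'
#' @inheritParams optorf
#' @param n maximum number of designs.
#' @param min_product discard designs whose product falls below this value.
#' @param prune drop enumerated designs containing an intervention whose
#'   removal does not lower production (the intervention penalties make a
#'   single solve minimal, but inside cut-constrained subproblems a
#'   redundant intervention can tie with a genuine alternative; pruned
#'   designs still contribute their integer cut).
#' @return an `orf_design_list` (list of `orf_design`).
#' @export
enumerate_optorf <- function(model, env = orf_environment(), spec, n = 10,
                             min_product = 1e-6, prune = TRUE, ...) {
  if (is.character(spec)) spec <- design_spec(spec, ...)
  out <- list()
  cuts <- list()
  max_iter <- 3L * n + 5L
  for (k in seq_len(max_iter)) {
    if (length(out) >= n) break
    built <- build_design_milp(model, env, spec, opts = list(cuts = cuts))
    res <- milp_solve(built$lp)
    des <- extract_design(built, res)
    if (!isTRUE(des$feasible)) break
    if (des$product < min_product) break
    cuts[[length(cuts) + 1L]] <- list(
      deletions = c(des$deletions, des$tf_deletions),
      overexpressions = des$overexpressions
    )
    if (!prune || design_is_minimal(model, env, spec, des)) {
      out[[length(out) + 1L]] <- des
    }
  }
  structure(out, class = "orf_design_list")
}

# Max product at inner-optimal growth for a fixed intervention set; -Inf
# when the minimum-growth requirement is unreachable.
simulate_design_product <- function(model, env, spec, deletions,
                                    overexpressions) {
  if (spec$regulation) {
    g <- solve_regulated_fba(model, env, deletions = deletions,
                             overexpressions = overexpressions,
                             min_growth = spec$min_growth,
                             epsilon = spec$epsilon, big_M = spec$big_M)
    if (g$status != "optimal") return(-Inf)
    p <- solve_regulated_fba(model, env, deletions = deletions,
                             overexpressions = overexpressions,
                             objective = stats::setNames(1, spec$product),
                             fix = stats::setNames(g$growth, model$biomass),
                             epsilon = spec$epsilon, big_M = spec$big_M)
  } else {
    gpr <- compile_gpr(model)
    yh <- stats::setNames(rep(TRUE, nrow(model$genes)), model$genes$id)
    yh[deletions] <- FALSE
    d <- reaction_feasibility(gpr, yh, names(model$reactions))
    g <- solve_fba(model, env, d = d, min_growth = spec$min_growth)
    if (g$status != "optimal") return(-Inf)
    p <- solve_fba(model, env, d = d,
                   objective = stats::setNames(1, spec$product),
                   fix = stats::setNames(g$growth, model$biomass))
  }
  if (p$status != "optimal") return(-Inf)
  p$objective
}

design_is_minimal <- function(model, env, spec, des, tol = 1e-7) {
  dels <- c(des$deletions, des$tf_deletions)
  oes <- des$overexpressions
  for (g in dels) {
    val <- simulate_design_product(model, env, spec, setdiff(dels, g), oes)
    if (is.finite(val) && val >= des$product - tol) return(FALSE)
  }
  for (g in oes) {
    val <- simulate_design_product(model, env, spec, dels, setdiff(oes, g))
    if (is.finite(val) && val >= des$product - tol) return(FALSE)
  }
  TRUE
}

#' Re-verify a design by direct simulation
#'
#' Guards against linearization or dual-bound artifacts: re-solves the
#' regulated (or plain) FBA with the design's interventions fixed, and
#' compares the recomputed maximal growth and the product range at that
#' growth against the design's claims.  The reported coupling robustness is
#' the minimum product flux among growth-optimal states; it is positive for
#' a genuinely growth-coupled design.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param design an `orf_design` from [optorf()] or [optknock()].
#' @param tol verification tolerance.
#' @return list with `verified`, recomputed `growth`, `product_max`,
#'   `product_min` (robustness) and the absolute deviations.
#' @export
verify_design <- function(model, env = orf_environment(), design,
                          tol = 1e-6) {
  stopifnot(inherits(design, "orf_design"))
  product <- design$product_id
  if (identical(design$kind, "reaction")) {
    d <- stats::setNames(rep(1, length(model$reactions)), names(model$reactions))
    d[design$deletions] <- 0
    g <- solve_fba(model, env, d = d)
    pmax_ <- solve_fba(model, env, d = d,
                       objective = stats::setNames(1, product),
                       fix = stats::setNames(g$growth, model$biomass))
    pmin_ <- solve_fba(model, env, d = d,
                       objective = stats::setNames(1, product),
                       maximize = FALSE,
                       fix = stats::setNames(g$growth, model$biomass))
  } else if (isTRUE(design$regulation)) {
    dels <- c(design$deletions, design$tf_deletions)
    g <- solve_regulated_fba(model, env, deletions = dels,
                             overexpressions = design$overexpressions)
    pmax_ <- solve_regulated_fba(model, env, deletions = dels,
                                 overexpressions = design$overexpressions,
                                 objective = stats::setNames(1, product),
                                 fix = stats::setNames(g$growth, model$biomass))
    pmin_ <- solve_regulated_fba(model, env, deletions = dels,
                                 overexpressions = design$overexpressions,
                                 objective = stats::setNames(1, product),
                                 maximize = FALSE,
                                 fix = stats::setNames(g$growth, model$biomass))
  } else {
    # gene design evaluated without regulation: all genes expressed except
    # the deleted ones, reaction availability through the GPRs
    gpr <- compile_gpr(model)
    yh <- stats::setNames(rep(TRUE, nrow(model$genes)), model$genes$id)
    yh[c(design$deletions, design$tf_deletions)] <- FALSE
    d <- reaction_feasibility(gpr, yh, names(model$reactions))
    g <- solve_fba(model, env, d = d)
    pmax_ <- solve_fba(model, env, d = d,
                       objective = stats::setNames(1, product),
                       fix = stats::setNames(g$growth, model$biomass))
    pmin_ <- solve_fba(model, env, d = d,
                       objective = stats::setNames(1, product),
                       maximize = FALSE,
                       fix = stats::setNames(g$growth, model$biomass))
  }
  dg <- abs(g$growth - design$growth)
  dp <- abs(pmax_$objective - design$product)
  list(
    verified = is.finite(dg) && is.finite(dp) && dg <= tol && dp <= tol,
    growth = g$growth,
    product_max = pmax_$objective,
    product_min = pmin_$objective,
    growth_delta = dg,
    product_delta = dp
  )
}

#' @export
print.orf_design <- function(x, ...) {
  if (!isTRUE(x$feasible)) {
    cat("Strain design: infeasible (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  kind <- if (identical(x$kind, "reaction")) "reaction deletions" else "gene-level"
  cat(sprintf("Strain design (%s%s)\n", kind,
              if (isTRUE(x$regulation)) ", regulated" else ""))
  del <- c(x$deletions, x$tf_deletions)
  cat("  deletions:      ",
      if (length(del)) paste(del, collapse = ", ") else "(none)", "\n")
  if (!identical(x$kind, "reaction")) {
    cat("  overexpressions:",
        if (length(x$overexpressions)) paste(x$overexpressions, collapse = ", ")
        else "(none)", "\n")
  }
  cat(sprintf("  growth = %.6g 1/hr   product(%s) = %.6g\n",
              x$growth, x$product_id, x$product))
  cat(sprintf("  objective = %.6g   |primal - dual| = %.2e\n",
              x$objective, x$duality_gap))
  invisible(x)
}

#' @export
print.orf_design_list <- function(x, ...) {
  cat("Design enumeration:", length(x), "solution(s)\n")
  for (k in seq_along(x)) {
    d <- x[[k]]
    ints <- c(paste0("Δ", c(d$deletions, d$tf_deletions)),
              if (length(d$overexpressions)) paste0("+", d$overexpressions))
    cat(sprintf("  %2d. %-40s product = %.6g  growth = %.6g\n", k,
                paste(ints, collapse = " "), d$product, d$growth))
  }
  invisible(x)
}

#' @export
as.data.frame.orf_design_list <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x), function(k) {
    d <- x[[k]]
    data.frame(
      id = k,
      deletions = paste(c(d$deletions, d$tf_deletions), collapse = ";"),
      overexpressions = paste(d$overexpressions, collapse = ";"),
      growth = d$growth,
      product = d$product,
      objective = d$objective,
      stringsAsFactors = FALSE
    )
  }))
}
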