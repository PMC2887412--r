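# Design-audit analyses: minimal gene covers for reaction sets, regulated
# re-evaluation of designs, minimal overexpression rescue, yield, and
# intervention statistics.

#' Minimum gene deletions removing a set of reactions
#'
#' Finds a minimum-cardinality gene set whose deletion disables every
#' target reaction through the GPR logic (a hitting set over the enzyme
#' complexes of the targets, solved as a small MILP), and reports the
#' collateral damage: other reactions disabled by the same deletions.
#' A target without a GPR cannot be removed by gene deletion (the
#' spontaneous / orphan-reaction case) and is an error.
#'
#' @param model an `orf_model`.
#' @param target_reactions reaction ids to disable.
#' @return an object of class `gene_cover`: `genes`, `collateral`
#'   (additionally disabled reactions), `targets`.
#' @export
minimal_gene_cover <- function(model, target_reactions) {
  gpr <- compile_gpr(model)
  missing <- setdiff(target_reactions, names(gpr))
  if (length(missing)) {
    stop("not removable by gene deletion (no GPR): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genes <- unique(unlist(gpr[target_reactions]))
  lp <- lp_new()
  zv <- stats::setNames(integer(length(genes)), genes)
  obj <- lin()
  for (g in genes) {
    zv[g] <- lp_add_var(lp, paste0("z.", g), 0, 1, type = "B")
    obj <- lin_sum(obj, lin_var(zv[g], 1))
  }
  for (j in target_reactions) {
    for (cx in gpr[[j]]) {
      lp_add_con(lp, lin(zv[cx], rep(1, length(cx))), ">=", 1)
    }
  }
  lp_set_objective(lp, obj, maximize = FALSE)
  res <- milp_solve(lp)
  if (res$status != "optimal") stop("cover MILP failed: ", res$status,
                                    call. = FALSE)
  cover <- genes[res$x[zv] > 0.5]
  yh <- stats::setNames(rep(TRUE, nrow(model$genes)), model$genes$id)
  yh[cover] <- FALSE
  d <- reaction_feasibility(gpr, yh, names(model$reactions))
  disabled <- names(d)[!d]
  structure(list(
    genes = sort(cover),
    collateral = sort(setdiff(disabled, target_reactions)),
    targets = target_reactions
  ), class = "gene_cover")
}

#' @export
print.gene_cover <- function(x, ...) {
  cat("Minimal gene cover for {", paste(x$targets, collapse = ", "), "}\n",
      sep = "")
  cat("  genes:     ", paste(x$genes, collapse = ", "), "\n")
  cat("  collateral:",
      if (length(x$collateral)) paste(x$collateral, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Re-evaluate designs under the integrated model
#'
#' Audits a list of designs by direct simulation: maximal growth, the
#' maximal product flux among growth-optimal states, yield, and lethality
#' (growth below `min_growth`).  Reaction-deletion designs are first
#' converted to gene deletions via [minimal_gene_cover()]; with
#' `regulated = TRUE` the transcriptional constraints are imposed, which is
#' where reaction-based designs often collapse.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param designs list; each element either a character vector (gene
#'   deletions), a list with `deletions`/`overexpressions`/`reactions`, or
#'   an `orf_design`.
#' @param product product reaction id for the audit.
#' @param regulated impose regulatory constraints.
#' @param min_growth lethality threshold (1/hr).
#' @param epsilon,big_M regulated-layer parameters.
#' @return data.frame of class `orf_audit`: one row per design with
#'   columns `id`, `deletions`, `overexpressions`, `growth`, `product`,
#'   `yield_pct`, `lethal`.
#' @export
reevaluate_designs <- function(model, env = orf_environment(), designs,
                               product, regulated = TRUE, min_growth = 0.1,
                               epsilon = 1e-3, big_M = 1000) {
  theo <- theoretical_max(model, env, product)
  rows <- lapply(seq_along(designs), function(k) {
    des <- normalize_design(model, designs[[k]])
    if (regulated) {
      g <- solve_regulated_fba(model, env, deletions = des$deletions,
                               overexpressions = des$overexpressions,
                               epsilon = epsilon, big_M = big_M)
    } else {
      gpr <- compile_gpr(model)
      yh <- stats::setNames(rep(TRUE, nrow(model$genes)), model$genes$id)
      yh[des$deletions] <- FALSE
      d <- reaction_feasibility(gpr, yh, names(model$reactions))
      g <- solve_fba(model, env, d = d)
    }
    growth <- if (g$status == "optimal") g$growth else 0
    lethal <- g$status != "optimal" || growth < min_growth
    prod_flux <- 0
    if (g$status == "optimal") {
      if (regulated) {
        p <- solve_regulated_fba(model, env, deletions = des$deletions,
                                 overexpressions = des$overexpressions,
                                 objective = stats::setNames(1, product),
                                 fix = stats::setNames(growth, model$biomass),
                                 epsilon = epsilon, big_M = big_M)
      } else {
        gpr <- compile_gpr(model)
        yh <- stats::setNames(rep(TRUE, nrow(model$genes)), model$genes$id)
        yh[des$deletions] <- FALSE
        d <- reaction_feasibility(gpr, yh, names(model$reactions))
        p <- solve_fba(model, env, d = d,
                       objective = stats::setNames(1, product),
                       fix = stats::setNames(growth, model$biomass))
      }
      if (p$status == "optimal") prod_flux <- p$objective
    }
    data.frame(
      id = k,
      deletions = paste(des$deletions, collapse = ";"),
      overexpressions = paste(des$overexpressions, collapse = ";"),
      growth = growth,
      product = prod_flux,
      yield_pct = if (theo > 1e-12) 100 * prod_flux / theo else NA_real_,
      lethal = lethal,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("orf_audit", "data.frame")
  out
}

normalize_design <- function(model, des) {
  if (inherits(des, "orf_design")) {
    if (identical(des$kind, "reaction")) {
      cov <- minimal_gene_cover(model, des$deletions)
      return(list(deletions = cov$genes, overexpressions = character()))
    }
    return(list(deletions = c(des$deletions, des$tf_deletions),
                overexpressions = des$overexpressions))
  }
  if (is.character(des)) return(list(deletions = des,
                                     overexpressions = character()))
  if (!is.null(des$reactions)) {
    cov <- minimal_gene_cover(model, des$reactions)
    return(list(deletions = cov$genes,
                overexpressions = des$overexpressions %||% character()))
  }
  list(deletions = des$deletions %||% character(),
       overexpressions = des$overexpressions %||% character())
}

theoretical_max <- function(model, env, product) {
  res <- solve_fba(model, env, objective = stats::setNames(1, product))
  if (res$status != "optimal") return(NA_real_)
  res$objective
}

#' Yield as percent of the theoretical maximum
#'
#' The denominator is the LP-maximal product flux under the same
#' environment with no growth requirement and regulation ignored.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param product product reaction id.
#' @param product_flux achieved product flux.
#' @return percent (0-100 scale).
#' @export
yield_percent <- function(model, env = orf_environment(), product,
                          product_flux) {
  theo <- theoretical_max(model, env, product)
  if (!is.finite(theo) || theo <= 1e-12) return(NA_real_)
  100 * product_flux / theo
}

#' Minimal overexpression set rescuing a design under regulation
#'
#' For a gene-deletion design whose production collapses under the
#' regulatory constraints, finds the smallest set of repressed metabolic
#' genes whose overexpression restores a target product flux at the
#' regulated growth optimum (a MILP minimizing the number of
#' overexpressions over the strong-duality design block).  The default
#' target is the design's product flux when regulation is ignored.
#'
#' @param model an `orf_model`.
#' @param env an `orf_environment`.
#' @param deletions gene deletions defining the design.
#' @param product product reaction id.
#' @param target target product flux; default: the unregulated optimum of
#'   the same design.
#' @param min_growth minimum growth demanded.
#' @param tol target slack.
#' @param ... further [design_spec()] settings (epsilon, big_M, h_bound).
#' @return list with `genes` (the overexpression set), `target`,
#'   `achieved`, and `reachable` (FALSE when no overexpression set can
#'   reach the target).
#' @export
min_overexpression_rescue <- function(model, env = orf_environment(),
                                      deletions, product, target = NULL,
                                      min_growth = 0.1, tol = 1e-6, ...) {
  spec0 <- design_spec(product, k1 = 0, k2 = 0, min_growth = min_growth,
                       regulation = FALSE, ...)
  if (is.null(target)) {
    target <- simulate_design_product(model, env, spec0, deletions,
                                      character())
    if (!is.finite(target)) {
      return(list(genes = character(), target = NA_real_,
                  achieved = NA_real_, reachable = FALSE))
    }
  }
  spec <- design_spec(product, k1 = 0, k2 = length(model$genes$id),
                      min_growth = min_growth, regulation = TRUE, ...)
  built <- build_design_milp(model, env, spec,
                             opts = list(objective = "min_w",
                                         fixed_deletions = deletions,
                                         product_target = target - tol))
  res <- milp_solve(built$lp)
  if (res$status != "optimal") {
    return(list(genes = character(), target = target, achieved = NA_real_,
                reachable = FALSE))
  }
  ws <- names(built$bl$w)[vapply(built$bl$w, function(k) res$x[k] > 0.5, NA)]
  achieved <- simulate_design_product(model, env,
                                      design_spec(product, min_growth = min_growth,
                                                  regulation = TRUE, ...),
                                      deletions, ws)
  list(genes = sort(ws), target = target, achieved = achieved,
       reachable = TRUE)
}

#' Intervention frequencies and co-occurrence correlations
#'
#' Summarizes lists of designs from one or more methods: per-gene
#' intervention frequencies (pooled across methods and per method, with
#' the usual reporting thresholds), and the Pearson correlation between
#' intervention indicator vectors within each method.  Gene pairs with
#' zero variance (never or always intervened) have undefined correlation
#' and are reported as `NA`.
#'
#' @param design_lists named list of design lists (each design as accepted
#'   by [reevaluate_designs()]).
#' @param model optional `orf_model` for design normalization.
#' @param pooled_threshold report genes at or above this pooled frequency.
#' @param method_threshold per-method frequency threshold for the
#'   correlation matrices.
#' @return list with `frequency` (data.frame: gene, per-method and pooled
#'   frequencies) and `correlation` (named list of matrices).
#' @export
intervention_stats <- function(design_lists, model = NULL,
                               pooled_threshold = 0.15,
                               method_threshold = 0.10) {
  stopifnot(length(design_lists) >= 1L)
  if (is.null(names(design_lists)) || any(!nzchar(names(design_lists)))) {
    names(design_lists) <- paste0("method", seq_along(design_lists))
  }
  to_genes <- function(des) {
    if (inherits(des, "orf_design")) {
      return(c(des$deletions, des$tf_deletions, des$overexpressions))
    }
    if (is.character(des)) return(des)
    c(des$deletions %||% character(), des$overexpressions %||% character())
  }
  gene_sets <- lapply(design_lists, function(lst) lapply(lst, to_genes))
  all_genes <- sort(unique(unlist(gene_sets)))
  indicator <- function(sets) {
    m <- matrix(0L, nrow = length(all_genes), ncol = length(sets),
                dimnames = list(all_genes, NULL))
    for (k in seq_along(sets)) m[sets[[k]], k] <- 1L
    m
  }
  mats <- lapply(gene_sets, indicator)
  freq <- data.frame(gene = all_genes, stringsAsFactors = FALSE)
  for (nm in names(mats)) freq[[nm]] <- rowMeans(mats[[nm]])
  total <- sum(vapply(mats, ncol, 0L))
  freq$pooled <- Reduce(`+`, lapply(mats, rowSums)) / total
  freq <- freq[order(-freq$pooled), , drop = FALSE]
  freq_reported <- freq[freq$pooled >= pooled_threshold, , drop = FALSE]

  correlation <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    if (ncol(m) < 2L) return(NULL)  # correlation undefined for one design
    keep <- rowMeans(m) >= method_threshold
    if (!sum(keep)) return(NULL)
    mk <- m[keep, , drop = FALSE]
    suppressWarnings(stats::cor(t(mk)))  # zero-variance rows give NA
  })
  names(correlation) <- names(mats)
  list(frequency = freq_reported, frequency_all = freq,
       correlation = correlation)
}
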