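# Compilation of GPR and regulatory Boolean structures into the indexed
# (DNF) form used by the MILP emitters, plus direct Boolean evaluation.

#' Compile GPR associations
#'
#' Expands every GPR into disjunctive normal form: a reaction is feasible if
#' any of its enzyme complexes is present, and a complex is present if all
#' of its subunit genes are expressed.  Duplicate complexes and complexes
#' that are supersets of another (redundant isozyme listings) are pruned.
#' Reactions without a GPR are absent from the index and are never
#' constrained by gene states.
#'
#' @param model an `orf_model`.
#' @param max_terms cap on the number of DNF terms per reaction; exceeding
#'   it is an error naming the reaction.
#' @return an object of class `gpr_index`: a named list, one element per
#'   reaction with a GPR, each a list of character vectors (gene complexes).
#' @export
compile_gpr <- function(model, max_terms = 4096L) {
  idx <- list()
  for (r in model$reactions) {
    if (is.null(r$gpr)) next
    terms <- tryCatch(
      expr_dnf(r$gpr, max_terms = max_terms),
      error = function(e) stop("reaction ", r$id, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    complexes <- lapply(terms, function(conj) {
      sort(unique(vapply(conj, function(l) l$id, "")))
    })
    if (!length(complexes) || any(!lengths(complexes))) {
      stop("reaction ", r$id, ": GPR reduces to a trivial expression",
           call. = FALSE)
    }
    idx[[r$id]] <- complexes
  }
  structure(idx, class = "gpr_index")
}

# Effector key used to share indicator variables between conditions.
effector_key <- function(eff) {
  paste(eff$kind, eff$id, format(eff$threshold, digits = 15), sep = "|")
}

#' Compile transcriptional regulation
#'
#' Converts every regulatory rule to disjunctive normal form: a target is
#' on iff some condition holds; a condition holds iff all its activator
#' effectors are active and all its repressor effectors are inactive.
#' Positive identifier literals become activator effectors; negated
#' identifier literals become repressor effectors.  Flux predicates become
#' activator effectors of kind `pf` (flux >= threshold) or, when negated,
#' `nf` (flux <= -threshold); the default threshold is `epsilon`.
#' Identifier literals resolve to kind `tf` when they name a declared
#' gene/TF and to kind `es` (environmental stimulus) otherwise.
#'
#' @param model an `orf_model`.
#' @param epsilon flux-indicator threshold (default `1e-3`).
#' @param max_terms DNF term cap per rule.
#' @return an object of class `reg_index`: `$targets` is a named list (one
#'   element per regulated target) of condition lists with `activators` and
#'   `repressors` effector sets; `$epsilon` the threshold.
#' @export
compile_regulation <- function(model, epsilon = 1e-3, max_terms = 4096L) {
  gene_ids <- model$genes$id
  targets <- list()
  for (tg in names(model$rules)) {
    terms <- tryCatch(
      expr_dnf(model$rules[[tg]]$expr, max_terms = max_terms),
      error = function(e) stop("rule for ", tg, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    conds <- lapply(terms, function(conj) {
      act <- list(); rep <- list()
      for (l in conj) {
        if (l$kind == "flux") {
          rid <- resolve_flux_reaction(model, l$id)
          thr <- if (is.na(l$threshold) || l$threshold <= 0) epsilon else l$threshold
          kind <- if (isTRUE(l$negated)) "nf" else "pf"
          act[[length(act) + 1L]] <- list(kind = kind, id = rid, threshold = thr)
        } else {
          kind <- if (l$id %in% gene_ids) "tf" else "es"
          eff <- list(kind = kind, id = l$id, threshold = NA_real_)
          if (isTRUE(l$negated)) {
            rep[[length(rep) + 1L]] <- eff
          } else {
            act[[length(act) + 1L]] <- eff
          }
        }
      }
      list(activators = act, repressors = rep)
    })
    targets[[tg]] <- conds
  }
  structure(list(targets = targets, epsilon = epsilon), class = "reg_index")
}

#' Apply deletion/overexpression perturbations to expression states
#'
#' Computes the surrogate expression state: a deletion turns an expressed
#' gene off; an overexpression turns a repressed gene on.  Deleting an
#' unexpressed gene or overexpressing an expressed gene is a contract
#' violation (these combinations are forbidden in the design formulation,
#' not silent no-ops), as is requesting both on one gene.
#'
#' @param y logical (or 0/1) vector of expression states.
#' @param z logical deletion indicators.
#' @param w logical overexpression indicators.
#' @return surrogate expression as 0/1 integer vector.
#' @export
apply_perturbations <- function(y, z, w) {
  y <- as.logical(y); z <- as.logical(z); w <- as.logical(w)
  stopifnot(length(z) == length(y), length(w) == length(y))
  if (any(z & w)) {
    stop("a gene cannot be simultaneously deleted and overexpressed",
         call. = FALSE)
  }
  if (any(z & !y)) {
    stop("deletion requested for unexpressed gene(s): ",
         paste(which(z & !y), collapse = ", "), call. = FALSE)
  }
  if (any(w & y)) {
    stop("overexpression requested for expressed gene(s): ",
         paste(which(w & y), collapse = ", "), call. = FALSE)
  }
  out <- as.integer((y & !z) | (!y & w))
  names(out) <- names(y)
  out
}

#' Reaction feasibility from gene states
#'
#' Evaluates the GPR index against a (surrogate) expression vector: a
#' complex is present iff all its genes are on; a reaction is feasible iff
#' some complex is present.  Reactions outside the index are always
#' feasible.
#'
#' @param gpr a `gpr_index` from [compile_gpr()].
#' @param y_hat named logical/0-1 vector over genes.
#' @param reaction_ids reactions to report (default: those in the index).
#' @return named logical vector of reaction feasibility.
#' @export
reaction_feasibility <- function(gpr, y_hat, reaction_ids = NULL) {
  yv <- as.logical(y_hat)
  names(yv) <- names(y_hat)
  if (is.null(reaction_ids)) reaction_ids <- names(gpr)
  out <- stats::setNames(rep(TRUE, length(reaction_ids)), reaction_ids)
  for (j in intersect(reaction_ids, names(gpr))) {
    out[j] <- any(vapply(gpr[[j]], function(cx) all(yv[cx]), NA))
  }
  out
}

# Evaluate one compiled condition against effector status lookup.
condition_holds <- function(cond, x_of) {
  for (eff in cond$activators) if (!x_of(eff)) return(FALSE)
  for (eff in cond$repressors) if (x_of(eff)) return(FALSE)
  TRUE
}

#' Evaluate the regulatory Boolean state at fixed fluxes
#'
#' Computes a consistent fixed point of the Boolean regulatory system given
#' a flux vector (which fixes all positive/negative flux indicators), the
#' environment (which fixes stimulus effectors; absent stimuli are
#' inactive), and a fixed set of perturbations.  Deleted genes are forced
#' off and overexpressed genes forced on regardless of their regulated
#' state (the simulation semantics used when auditing externally supplied
#' designs).  TF-over-TF dependencies may be cyclic; fixed points are then
#' enumerated over the strongly coupled targets and the lexicographically
#' smallest consistent assignment is returned, with the number of fixed
#' points reported.
#'
#' @param reg a `reg_index` from [compile_regulation()].
#' @param gpr a `gpr_index` from [compile_gpr()].
#' @param model the `orf_model`.
#' @param env an `orf_environment`.
#' @param flux named flux vector supplying every flux-predicate reaction.
#' @param deletions,overexpressions character vectors of gene ids.
#' @return a `boolean_state` list with components `y`, `y_hat`, `d`
#'   (reaction feasibility), `x` (effector status by key), `a` (condition
#'   status per target), and `n_fixed_points`.
#' @export
evaluate_state <- function(reg, gpr, model, env, flux,
                           deletions = character(),
                           overexpressions = character()) {
  gene_ids <- model$genes$id
  regulated <- names(reg$targets)
  stopifnot(all(deletions %in% gene_ids), all(overexpressions %in% gene_ids))

  flux_x <- function(eff) {
    v <- flux[[eff$id]]
    if (is.null(v) || is.na(v)) {
      stop("flux vector does not cover reaction ", eff$id, call. = FALSE)
    }
    if (eff$kind == "pf") v >= eff$threshold else v <= -eff$threshold
  }

  # dependency graph among regulated targets via tf effectors
  deps <- lapply(reg$targets, function(conds) {
    ids <- unlist(lapply(conds, function(cd) {
      c(vapply(cd$activators, function(e) if (e$kind == "tf") e$id else NA_character_, ""),
        vapply(cd$repressors, function(e) if (e$kind == "tf") e$id else NA_character_, ""))
    }))
    intersect(unique(ids[!is.na(ids)]), regulated)
  })

  surrogate <- function(y) {
    yh <- y
    yh[deletions] <- 0L
    yh[overexpressions] <- 1L
    yh
  }

  eval_target <- function(tg, y) {
    yh <- surrogate(y)
    x_of <- function(eff) {
      switch(eff$kind,
        tf = {
          if (eff$id %in% names(yh)) yh[[eff$id]] == 1L
          else !(eff$id %in% deletions)  # constitutive gene effector
        },
        es = eff$id %in% env$stimuli,
        flux_x(eff)
      )
    }
    as.integer(any(vapply(reg$targets[[tg]], condition_holds, NA, x_of = x_of)))
  }

  # iterate to a fixed point; on cycles, enumerate unresolved targets
  y <- stats::setNames(rep(1L, length(gene_ids)), gene_ids)
  y[regulated] <- 0L
  changed <- TRUE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ynew <- y
    for (tg in regulated) ynew[tg] <- eval_target(tg, y)
    if (identical(ynew, y)) { changed <- FALSE; break }
    if (iter > length(regulated) + 2L) break
    y <- ynew
  }
  n_fp <- 1L
  if (changed) {
    # enumerate assignments over targets involved in cycles
    cyc <- regulated[vapply(regulated, function(tg) length(deps[[tg]]) > 0L, NA)]
    fixed <- setdiff(regulated, cyc)
    solutions <- list()
    n_cyc <- length(cyc)
    for (mask in 0:(2L^n_cyc - 1L)) {
      cand <- y
      bits <- as.integer(intToBits(mask)[seq_len(max(n_cyc, 1L))])
      cand[cyc] <- bits[seq_len(n_cyc)]
      for (tg in fixed) cand[tg] <- eval_target(tg, cand)
      ok <- all(vapply(regulated, function(tg) {
        eval_target(tg, cand) == cand[[tg]]
      }, NA))
      if (ok) solutions[[length(solutions) + 1L]] <- cand
    }
    if (!length(solutions)) {
      stop("no consistent regulatory state (contradictory cycle over: ",
           paste(cyc, collapse = ", "), ")", call. = FALSE)
    }
    n_fp <- length(solutions)
    y <- solutions[[1L]]
  }

  yh <- surrogate(y)
  x <- list()
  a <- list()
  for (tg in regulated) {
    x_of <- function(eff) {
      switch(eff$kind,
        tf = if (eff$id %in% names(yh)) yh[[eff$id]] == 1L else !(eff$id %in% deletions),
        es = eff$id %in% env$stimuli,
        flux_x(eff)
      )
    }
    sat <- vapply(reg$targets[[tg]], condition_holds, NA, x_of = x_of)
    a[[tg]] <- as.integer(sat)
    for (cd in reg$targets[[tg]]) {
      for (eff in c(cd$activators, cd$repressors)) {
        x[[effector_key(eff)]] <- as.integer(x_of(eff))
      }
    }
  }
  d <- reaction_feasibility(gpr, yh, names(model$reactions))
  structure(list(y = y, y_hat = yh, d = d, x = x, a = a,
                 n_fixed_points = n_fp),
            class = "boolean_state")
}

#' Export compiled indices as JSON triples
#'
#' Mirrors the three-dimensional array encoding of the constraint
#' formulation: GPR as (reaction, complex, gene) triples and regulation as
#' (target, condition, effector) triples with effector kinds.
#'
#' @param gpr a `gpr_index`.
#' @param reg a `reg_index`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @export
write_index_json <- function(gpr, reg, path = NULL) {
  gpr_triples <- list()
  for (j in names(gpr)) {
    for (n in seq_along(gpr[[j]])) {
      for (g in gpr[[j]][[n]]) {
        gpr_triples[[length(gpr_triples) + 1L]] <- list(j = j, n = n, g = g)
      }
    }
  }
  tr_triples <- list()
  for (g in names(reg$targets)) {
    conds <- reg$targets[[g]]
    for (m in seq_along(conds)) {
      for (role in c("activators", "repressors")) {
        for (eff in conds[[m]][[role]]) {
          tr_triples[[length(tr_triples) + 1L]] <- list(
            g = g, m = m, r = eff$id, kind = eff$kind,
            role = sub("s$", "", role),
            threshold = if (is.na(eff$threshold)) NULL else eff$threshold
          )
        }
      }
    }
  }
  txt <- jsonlite::toJSON(list(GPR = gpr_triples, TR = tr_triples,
                               epsilon = reg$epsilon),
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
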