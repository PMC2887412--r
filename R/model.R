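# Integrated metabolic / transcriptional-regulatory model container.
#
# An `orf_model` is a plain list:
#   metabolites: data.frame(id, name, compartment, extracellular)
#   reactions:   named list; each element has id, stoich (named numeric over
#                metabolite ids), lb, ub (flux bounds; uptake is negative
#                flux on the exchange reaction), exchange (logical),
#                gpr (expression or NULL), gpr_text
#   genes:       data.frame(id, kind) with kind in {"metabolic", "tf"}
#   rules:       named list target-id -> list(expr, text); targets without a
#                rule are constitutively expressed
#   biomass:     id of the biomass (growth) reaction, in 1/hr

#' Construct an integrated metabolic and regulatory model
#'
#' Builds and validates the model container used throughout the package.
#' Gene kinds are inferred when a `genes` table is not supplied: identifiers
#' appearing in GPRs are metabolic genes; regulatory-rule targets that never
#' appear in a GPR are transcription factors.
#'
#' @param metabolites data.frame with columns `id` and optionally `name`,
#'   `compartment`, `extracellular`.
#' @param reactions list of reactions; each a list with `id`, `stoich`
#'   (named numeric vector over metabolite ids), `lb`, `ub`, and optionally
#'   `gpr` (rule string or parsed expression).
#' @param rules named character vector or two-column data.frame
#'   (`target`, `rule`) of regulatory rules; empty rules are constitutive.
#' @param biomass id of the biomass reaction.
#' @param genes optional data.frame(id, kind) overriding kind inference.
#' @return an object of class `orf_model`.
#' @export
integrated_model <- function(metabolites, reactions, rules = NULL,
                             biomass, genes = NULL) {
  if (!is.data.frame(metabolites)) {
    metabolites <- data.frame(id = as.character(metabolites),
                              stringsAsFactors = FALSE)
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$extracellular)) {
    metabolites$extracellular <- metabolites$compartment == "e"
  }
  metabolites <- metabolites[, c("id", "name", "compartment", "extracellular")]
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "),
         call. = FALSE)
  }

  rxns <- list()
  for (r in reactions) {
    if (is.null(r$id)) stop("reaction without an id", call. = FALSE)
    if (!is.null(rxns[[r$id]])) {
      stop("duplicate reaction id: ", r$id, call. = FALSE)
    }
    st <- r$stoich
    if (is.null(st) || !length(st) || is.null(names(st)) || any(!nzchar(names(st)))) {
      stop("reaction ", r$id, ": malformed stoichiometry", call. = FALSE)
    }
    st <- st[st != 0]
    if (!length(st)) stop("reaction ", r$id, ": empty stoichiometry", call. = FALSE)
    lb <- if (is.null(r$lb)) 0 else as.numeric(r$lb)
    ub <- if (is.null(r$ub)) Inf else as.numeric(r$ub)
    if (is.na(lb) || is.na(ub) || lb > ub) {
      stop("reaction ", r$id, ": invalid bounds", call. = FALSE)
    }
    gpr <- r$gpr
    gpr_text <- r$gpr_text
    if (is.character(gpr)) {
      gpr_text <- gpr
      gpr <- parse_rule(gpr)
    }
    if (!is.null(gpr) && is_true_expr(gpr)) gpr <- NULL
    if (!is.null(gpr) && !is_gpr_expr(gpr)) {
      stop("reaction ", r$id,
           ": GPR must use only AND/OR over gene identifiers", call. = FALSE)
    }
    if (is.null(gpr_text)) gpr_text <- if (is.null(gpr)) "" else deparse_rule(gpr)
    exch <- if (!is.null(r$exchange)) isTRUE(r$exchange) else length(st) == 1L
    rxns[[r$id]] <- list(id = r$id, stoich = st, lb = lb, ub = ub,
                         exchange = exch, gpr = gpr, gpr_text = gpr_text)
  }

  rule_list <- list()
  if (!is.null(rules)) {
    if (is.data.frame(rules)) {
      tg <- as.character(rules[[1L]])
      tx <- as.character(rules[[2L]])
    } else {
      tg <- names(rules)
      tx <- as.character(rules)
    }
    for (k in seq_along(tg)) {
      if (!nzchar(trimws(tx[k]))) next
      if (!is.null(rule_list[[tg[k]]])) {
        stop("duplicate regulatory rule for target: ", tg[k], call. = FALSE)
      }
      rule_list[[tg[k]]] <- list(expr = parse_rule(tx[k]), text = tx[k])
    }
  }

  gpr_genes <- unique(unlist(lapply(rxns, function(r) {
    if (is.null(r$gpr)) character() else expr_literals(r$gpr)$id
  })))
  if (is.null(genes)) {
    tf_ids <- setdiff(names(rule_list), gpr_genes)
    genes <- data.frame(
      id = c(gpr_genes, tf_ids),
      kind = c(rep("metabolic", length(gpr_genes)), rep("tf", length(tf_ids))),
      stringsAsFactors = FALSE
    )
  } else {
    genes <- data.frame(id = as.character(genes$id),
                        kind = as.character(genes$kind),
                        stringsAsFactors = FALSE)
    if (!all(genes$kind %in% c("metabolic", "tf"))) {
      stop("gene kind must be 'metabolic' or 'tf'", call. = FALSE)
    }
  }
  if (anyDuplicated(genes$id)) stop("duplicate gene ids", call. = FALSE)

  model <- structure(
    list(metabolites = metabolites, reactions = rxns, genes = genes,
         rules = rule_list, biomass = biomass),
    class = "orf_model"
  )
  validate_model(model)
  model
}

#' Validate an integrated model
#'
#' Checks referential integrity: stoichiometry references declared
#' metabolites, GPR literals reference declared genes, regulatory literals
#' resolve to a gene, TF, reaction (flux predicates) or environmental
#' stimulus, the biomass reaction exists, and exchange reactions touch
#' exactly one metabolite.  Flux-predicate ids of the form `x(e)` resolve to
#' the unique exchange reaction of extracellular metabolite `x` when no
#' reaction has that literal id.
#'
#' @param model an `orf_model`.
#' @return the model, invisibly; errors name the offending record.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- names(model$reactions)
  gene_ids <- model$genes$id
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoich), met_ids)
    if (length(bad)) {
      stop("reaction ", r$id, ": undeclared metabolite(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (r$exchange && length(r$stoich) != 1L) {
      stop("exchange reaction ", r$id, " must touch exactly one metabolite",
           call. = FALSE)
    }
    if (!is.null(r$gpr)) {
      bad <- setdiff(expr_literals(r$gpr)$id, gene_ids)
      if (length(bad)) {
        stop("reaction ", r$id, ": GPR references undeclared gene(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!model$biomass %in% rxn_ids) {
    stop("biomass reaction '", model$biomass, "' not present", call. = FALSE)
  }
  for (tg in names(model$rules)) {
    if (!tg %in% gene_ids) {
      stop("regulatory rule targets undeclared gene/TF: ", tg, call. = FALSE)
    }
    lits <- expr_literals(model$rules[[tg]]$expr)
    for (k in seq_len(nrow(lits))) {
      if (lits$kind[k] == "flux") {
        if (is.na(resolve_flux_reaction(model, lits$id[k]))) {
          stop("rule for ", tg, ": flux predicate references undeclared reaction '",
               lits$id[k], "'", call. = FALSE)
        }
      }
      # identifier literals may be genes, TFs, or environmental stimuli;
      # stimuli are free identifiers supplied by the environment
    }
  }
  invisible(model)
}

# Resolve a flux-predicate identifier to a reaction id.  `x(e)` falls back to
# the unique exchange reaction of extracellular metabolite `x`.
resolve_flux_reaction <- function(model, id) {
  if (id %in% names(model$reactions)) return(id)
  m <- regmatches(id, regexec("^(.*)\\(e\\)$", id))[[1L]]
  if (length(m) == 2L) {
    met <- m[2L]
    hits <- vapply(model$reactions, function(r) {
      r$exchange && identical(names(r$stoich), met)
    }, NA)
    if (sum(hits) == 1L) return(names(model$reactions)[hits])
    hits2 <- vapply(model$reactions, function(r) {
      r$exchange && length(r$stoich) == 1L &&
        sub("\\[e\\]$|_e$", "", names(r$stoich)) == met
    }, NA)
    if (sum(hits2) == 1L) return(names(model$reactions)[hits2])
  }
  NA_character_
}

# Stoichiometric matrix as triplets (i = metabolite index, j = reaction
# index, x = coefficient), plus dimension names.
stoich_triplets <- function(model) {
  met_idx <- stats::setNames(seq_len(nrow(model$metabolites)), model$metabolites$id)
  i <- integer(); j <- integer(); x <- numeric()
  rj <- 0L
  for (r in model$reactions) {
    rj <- rj + 1L
    i <- c(i, met_idx[names(r$stoich)])
    j <- c(j, rep(rj, length(r$stoich)))
    x <- c(x, unname(r$stoich))
  }
  list(i = unname(i), j = j, x = x,
       metabolites = model$metabolites$id, reactions = names(model$reactions))
}

#' Specify an environment (medium and stimuli)
#'
#' Exchange-reaction lower bounds define the medium: uptake is negative flux,
#' so a maximum glucose uptake rate of 18.5 mmol/gDW/hr is the lower bound
#' -18.5 on the glucose exchange.  Environmental stimuli absent from
#' `stimuli` are treated as inactive.
#'
#' @param uptake named numeric vector of exchange-reaction lower bounds.
#' @param stimuli character vector of active environmental stimulus ids.
#' @return an object of class `orf_environment`.
#' @export
orf_environment <- function(uptake = numeric(), stimuli = character()) {
  stopifnot(is.numeric(uptake))
  if (length(uptake) && is.null(names(uptake))) {
    stop("uptake bounds must be named by exchange reaction id", call. = FALSE)
  }
  structure(list(uptake = uptake, stimuli = as.character(stimuli)),
            class = "orf_environment")
}

# Effective reaction bounds under an environment.
reaction_bounds <- function(model, env = NULL) {
  ids <- names(model$reactions)
  lb <- vapply(model$reactions, function(r) r$lb, 0)
  ub <- vapply(model$reactions, function(r) r$ub, 0)
  if (!is.null(env) && length(env$uptake)) {
    bad <- setdiff(names(env$uptake), ids)
    if (length(bad)) {
      stop("environment references undeclared exchange reaction(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lb[names(env$uptake)] <- pmin(env$uptake, ub[names(env$uptake)])
  }
  list(lb = stats::setNames(lb, ids), ub = stats::setNames(ub, ids))
}

#' The five-reaction worked-example network
#'
#' A small integrated network used throughout the documentation and tests.
#' Substrate S is converted to biomass B via intermediate I1 (reactions R1,
#' R2; R2 also secretes by-product P1 with 0.08 B per S) or via I2 (R3 or
#' R4 feeding R5, which secretes P2 with 0.12 B per S).  R1 requires the
#' two-subunit enzyme encoded by G1A and G1B; R5 is catalysed by either of
#' two isozymes (G5 or G6).  Transcription factor TF1 is active whenever S is
#' being taken up; it activates G3 and G5 and represses G1A.  All other genes
#' are constitutive.  Because the R5 route yields more biomass, P2 is the
#' preferred by-product and P1 production is uncoupled from growth in the
#' wild type.
#'
#' @param uptake maximum substrate uptake rate (positive number; sets the
#'   lower bound of `EX_S` to `-uptake`).
#' @return an `orf_model` with biomass reaction `EX_B`.
#' @export
example_network <- function(uptake = 10) {
  mets <- data.frame(
    id = c("S", "I1", "I2", "P1", "P2", "B"),
    name = c("substrate", "intermediate 1", "intermediate 2",
             "by-product 1", "by-product 2", "biomass"),
    compartment = c("e", "c", "c", "e", "e", "c"),
    extracellular = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  rxn <- function(id, stoich, lb = 0, ub = Inf, gpr = NULL, exchange = FALSE) {
    list(id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr,
         exchange = exchange)
  }
  reactions <- list(
    rxn("R1", c(S = -1, I1 = 1), gpr = "G1A and G1B"),
    rxn("R2", c(I1 = -1, P1 = 1, B = 0.08), gpr = "G2"),
    rxn("R3", c(S = -1, I2 = 1), gpr = "G3"),
    rxn("R4", c(I1 = -1, I2 = 1), gpr = "G4"),
    rxn("R5", c(I2 = -1, P2 = 1, B = 0.12), gpr = "G5 or G6"),
    rxn("EX_S", c(S = -1), lb = -abs(uptake), exchange = TRUE),
    rxn("EX_P1", c(P1 = -1), exchange = TRUE),
    rxn("EX_P2", c(P2 = -1), exchange = TRUE),
    rxn("EX_B", c(B = -1), exchange = TRUE)
  )
  rules <- data.frame(
    target = c("TF1", "G3", "G5", "G1A"),
    rule = c("not (EX_S > 0)", "TF1", "TF1", "not TF1"),
    stringsAsFactors = FALSE
  )
  integrated_model(mets, reactions, rules, biomass = "EX_B")
}

#' @export
print.orf_model <- function(x, ...) {
  n_exch <- sum(vapply(x$reactions, function(r) r$exchange, NA))
  cat("Integrated metabolic/regulatory model\n")
  cat(sprintf("  metabolites: %d   reactions: %d (%d exchange)\n",
              nrow(x$metabolites), length(x$reactions), n_exch))
  cat(sprintf("  genes: %d metabolic, %d TF   regulatory rules: %d\n",
              sum(x$genes$kind == "metabolic"), sum(x$genes$kind == "tf"),
              length(x$rules)))
  cat(sprintf("  biomass reaction: %s\n", x$biomass))
  invisible(x)
}

#' @export
summary.orf_model <- function(object, ...) {
  print(object)
  with_gpr <- names(object$reactions)[!vapply(object$reactions,
                                              function(r) is.null(r$gpr), NA)]
  cat("  reactions with GPR:", length(with_gpr), "\n")
  if (length(object$rules)) {
    cat("  regulated targets:", paste(names(object$rules), collapse = ", "), "\n")
  }
  invisible(object)
}
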