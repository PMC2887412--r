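# Model input/output: JSON serialization, the tabular dialect
# (metabolites.tsv / reactions.tsv / rules.tsv), and a compact SBML Level 3
# (fbc) reader.

#' Serialize a model to JSON
#'
#' Writes all model fields (metabolites, reactions with stoichiometry,
#' bounds and GPR strings, gene kinds, regulatory rule strings, biomass id)
#' so that [read_model_json()] reproduces an equal model.
#'
#' @param model an `orf_model`.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(
    metabolites = model$metabolites,
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id,
           stoich = as.list(r$stoich),
           lb = if (is.finite(r$lb)) r$lb else "-inf",
           ub = if (is.finite(r$ub)) r$ub else "inf",
           exchange = r$exchange,
           gpr = r$gpr_text)
    }),
    genes = model$genes,
    rules = lapply(model$rules, function(rl) rl$text),
    biomass = model$biomass
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path path to a JSON file written by [write_model_json()] (a JSON
#'   string is also accepted).
#' @return an `orf_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num_bound <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.character(x)) {
      return(switch(x, "inf" = Inf, "-inf" = -Inf, as.numeric(x)))
    }
    as.numeric(x)
  }
  chr_field <- function(recs, field, default = NA_character_) {
    vapply(recs, function(r) {
      if (is.null(r[[field]])) default else as.character(r[[field]])
    }, "")
  }
  metabolites <- data.frame(
    id = chr_field(obj$metabolites, "id"),
    name = chr_field(obj$metabolites, "name"),
    compartment = chr_field(obj$metabolites, "compartment", "c"),
    stringsAsFactors = FALSE
  )
  metabolites$extracellular <- vapply(obj$metabolites, function(r) {
    isTRUE(as.logical(r$extracellular))
  }, NA)
  reactions <- lapply(obj$reactions, function(r) {
    st <- vapply(r$stoich, as.numeric, 0)
    list(id = as.character(r$id), stoich = st,
         lb = num_bound(r$lb, 0), ub = num_bound(r$ub, Inf),
         exchange = isTRUE(as.logical(r$exchange)),
         gpr = if (!is.null(r$gpr) && nzchar(r$gpr)) as.character(r$gpr) else NULL)
  })
  rules <- NULL
  if (length(obj$rules)) {
    rules <- data.frame(target = names(obj$rules),
                        rule = unlist(obj$rules, use.names = FALSE),
                        stringsAsFactors = FALSE)
  }
  genes <- NULL
  if (length(obj$genes)) {
    genes <- data.frame(id = chr_field(obj$genes, "id"),
                        kind = chr_field(obj$genes, "kind"),
                        stringsAsFactors = FALSE)
  }
  integrated_model(metabolites, reactions, rules,
                   biomass = obj$biomass, genes = genes)
}

# Parse a reaction equation string, e.g. "I2 -> P2 + 0.12 B" or
# "A + 2 B <-> C".  "<->" marks reversibility only; bounds come from the
# lb/ub columns.
parse_equation <- function(eq, id = "?") {
  sides <- strsplit(eq, "<->|<=>|->|=>", perl = TRUE)[[1L]]
  if (length(sides) > 2L) stop("reaction ", id, ": malformed equation", call. = FALSE)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    parts <- trimws(strsplit(txt, "\\+")[[1L]])
    out <- numeric()
    for (p in parts) {
      if (!nzchar(p)) next
      m <- regmatches(p, regexec(
        "^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?\\s+)?(\\S+)$", p))[[1L]]
      if (length(m) != 3L || !nzchar(m[3L])) {
        stop("reaction ", id, ": malformed term '", p, "'", call. = FALSE)
      }
      coef <- if (nzchar(trimws(m[2L]))) as.numeric(trimws(m[2L])) else 1
      out[m[3L]] <- (if (is.na(out[m[3L]])) 0 else out[m[3L]]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1L], -1)
  rhs <- if (length(sides) == 2L) parse_side(sides[2L], 1) else numeric()
  st <- lhs
  for (k in names(rhs)) st[k] <- (if (is.na(st[k])) 0 else st[k]) + rhs[k]
  st[!is.na(st) & st != 0]
}

format_equation <- function(stoich) {
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  side <- function(v) {
    if (!length(v)) return("")
    paste(vapply(seq_along(v), function(k) {
      co <- abs(v[k])
      if (co == 1) names(v)[k] else sprintf("%.15g %s", co, names(v)[k])
    }, ""), collapse = " + ")
  }
  paste(side(lhs), "->", side(rhs))
}

#' Read a model from the tabular dialect
#'
#' Expects `reactions.tsv` (columns `id`, `equation`, `lb`, `ub`, `gpr`),
#' optionally `metabolites.tsv` (`id`, `name`, `compartment`,
#' `extracellular`), and `rules.tsv` (`target`, `rule`).  Metabolites absent
#' from `metabolites.tsv` are declared from the equations.
#'
#' @param reactions_path path to reactions.tsv.
#' @param rules_path optional path to rules.tsv.
#' @param metabolites_path optional path to metabolites.tsv.
#' @param biomass biomass reaction id.
#' @return an `orf_model`.
#' @export
read_model_tsv <- function(reactions_path, rules_path = NULL,
                           metabolites_path = NULL, biomass) {
  rx <- utils::read.delim(reactions_path, stringsAsFactors = FALSE)
  need <- c("id", "equation")
  if (!all(need %in% names(rx))) {
    stop("reactions table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  num_bound <- function(x, default) {
    if (is.null(x) || is.na(x) || !nzchar(as.character(x))) return(default)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) switch(as.character(x), "inf" = Inf, "-inf" = -Inf,
                         stop("bad bound: ", x, call. = FALSE)) else v
  }
  reactions <- lapply(seq_len(nrow(rx)), function(k) {
    list(id = rx$id[k],
         stoich = parse_equation(rx$equation[k], rx$id[k]),
         lb = num_bound(rx$lb[k], 0),
         ub = num_bound(rx$ub[k], Inf),
         gpr = if (!is.null(rx$gpr) && !is.na(rx$gpr[k]) && nzchar(rx$gpr[k]))
           rx$gpr[k] else NULL)
  })
  mets_seen <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (!is.null(metabolites_path)) {
    mets <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE)
    missing <- setdiff(mets_seen, mets$id)
    if (length(missing)) {
      extra <- data.frame(id = missing, stringsAsFactors = FALSE)
      for (cn in setdiff(names(mets), "id")) {
        extra[[cn]] <- if (cn == "extracellular") FALSE else
          if (cn == "compartment") "c" else missing
      }
      mets <- rbind(mets, extra[, names(mets), drop = FALSE])
    }
  } else {
    mets <- data.frame(id = mets_seen, stringsAsFactors = FALSE)
  }
  rules <- NULL
  if (!is.null(rules_path)) {
    rules <- utils::read.delim(rules_path, stringsAsFactors = FALSE)
    rules <- rules[, c("target", "rule")]
    rules$rule[is.na(rules$rule)] <- ""
  }
  integrated_model(mets, reactions, rules, biomass = biomass)
}

#' Write a model to the tabular dialect
#'
#' @param model an `orf_model`.
#' @param dir output directory (created if needed); writes
#'   `metabolites.tsv`, `reactions.tsv` and `rules.tsv`.
#' @export
write_model_tsv <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bnd <- function(x) ifelse(is.finite(x), format(x, digits = 15),
                            ifelse(x > 0, "inf", "-inf"))
  rx <- data.frame(
    id = names(model$reactions),
    equation = vapply(model$reactions, function(r) format_equation(r$stoich), ""),
    lb = bnd(vapply(model$reactions, function(r) r$lb, 0)),
    ub = bnd(vapply(model$reactions, function(r) r$ub, 0)),
    gpr = vapply(model$reactions, function(r) r$gpr_text, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rules <- data.frame(
    target = names(model$rules),
    rule = vapply(model$rules, function(r) r$text, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(rules, file.path(dir, "rules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read the metabolic part of a model from SBML Level 3 (fbc)
#'
#' A compact reader for SBML Level 3 files using the `fbc` package:
#' species, reactions with stoichiometry, flux bounds resolved through the
#' parameter list, gene products, and `fbc:geneProductAssociation` trees
#' (AND/OR over gene product references).  Regulatory rules are supplied
#' separately (SBML has no standard encoding for them).
#'
#' @param path path to the SBML file.
#' @param rules optional rules table as in [integrated_model()].
#' @param biomass biomass reaction id; defaults to the active fbc objective.
#' @return an `orf_model`.
#' @export
read_model_sbml <- function(path, rules = NULL, biomass = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # fbc attributes may or may not retain their prefix after namespace stripping
  xattr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (length(v) == 1L && is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }
  params <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )
  species <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE
  )
  mets$extracellular <- mets$compartment %in% c("e", "ext", "extracellular")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  mets <- mets[!boundary, , drop = FALSE]

  gpa_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(xattr(node, "geneProduct"))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_text, "")
    op <- switch(nm, "and" = " and ", "or" = " or ",
                 stop("unsupported geneProductAssociation node: ", nm,
                      call. = FALSE))
    paste0("(", paste(parts, collapse = op), ")")
  }

  rnodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      sp <- xml2::xml_attr(sr, "species")
      co <- xml2::xml_attr(sr, "stoichiometry")
      st[sp] <- (if (is.na(st[sp])) 0 else st[sp]) -
        (if (is.na(co)) 1 else as.numeric(co))
    }
    for (sr in xml2::xml_find_all(rn, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      sp <- xml2::xml_attr(sr, "species")
      co <- xml2::xml_attr(sr, "stoichiometry")
      st[sp] <- (if (is.na(st[sp])) 0 else st[sp]) +
        (if (is.na(co)) 1 else as.numeric(co))
    }
    st <- st[names(st) %in% mets$id]
    lbref <- xattr(rn, "lowerFluxBound")
    ubref <- xattr(rn, "upperFluxBound")
    rev <- xml2::xml_attr(rn, "reversible") %in% c("true", "1")
    lb <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
          else if (rev) -Inf else 0
    ub <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else Inf
    if (is.finite(lb) && abs(lb) >= 1e29) lb <- -Inf
    if (is.finite(ub) && abs(ub) >= 1e29) ub <- Inf
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- NULL
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpr <- gpa_to_text(kids[[1L]])
    }
    list(id = id, stoich = st, lb = lb, ub = ub, gpr = gpr)
  })

  # map fbc gene product ids to their labels where present
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  if (length(gps)) {
    lab <- stats::setNames(vapply(gps, function(g) xattr(g, "label"), ""), vapply(gps, function(g) xattr(g, "id"), ""))
    lab[is.na(lab)] <- names(lab)[is.na(lab)]
    reactions <- lapply(reactions, function(r) {
      if (!is.null(r$gpr)) {
        for (gid in names(lab)) {
          r$gpr <- gsub(paste0("\\b", gid, "\\b"), lab[[gid]], r$gpr)
        }
      }
      r
    })
  }

  if (is.null(biomass)) {
    obj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(obj, "xml_missing")) {
      biomass <- xattr(obj, "reaction")
    } else {
      stop("no fbc objective found; supply `biomass`", call. = FALSE)
    }
  }
  integrated_model(mets, reactions, rules, biomass = biomass)
}

#' Load an integrated model from files
#'
#' Dispatches on file type: `.xml`/`.sbml` via [read_model_sbml()], `.json`
#' via [read_model_json()], and a directory or `reactions.tsv` path via
#' [read_model_tsv()].  `rules_source` is a two-column TSV (`target`,
#' `rule`).
#'
#' @param metabolic_source path to the metabolic model.
#' @param rules_source optional path to the regulatory rule table.
#' @param biomass biomass reaction id (required for tabular/JSON without one).
#' @return a validated `orf_model`.
#' @export
load_model <- function(metabolic_source, rules_source = NULL, biomass = NULL) {
  rules <- NULL
  if (!is.null(rules_source)) {
    rules <- utils::read.delim(rules_source, stringsAsFactors = FALSE)
    rules <- rules[, c("target", "rule")]
    rules$rule[is.na(rules$rule)] <- ""
  }
  ext <- tolower(tools::file_ext(metabolic_source))
  if (dir.exists(metabolic_source)) {
    return(read_model_tsv(
      file.path(metabolic_source, "reactions.tsv"),
      rules_path = rules_source,
      metabolites_path = if (file.exists(file.path(metabolic_source, "metabolites.tsv")))
        file.path(metabolic_source, "metabolites.tsv") else NULL,
      biomass = biomass
    ))
  }
  if (ext %in% c("xml", "sbml")) {
    return(read_model_sbml(metabolic_source, rules = rules, biomass = biomass))
  }
  if (ext == "json") {
    model <- read_model_json(metabolic_source)
    if (!is.null(rules)) {
      model <- integrated_model(
        model$metabolites,
        unname(model$reactions),
        rules,
        biomass = model$biomass
      )
    }
    return(model)
  }
  read_model_tsv(metabolic_source, rules_path = rules_source, biomass = biomass)
}
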