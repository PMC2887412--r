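# Boolean expressions over genes/TFs, flux predicates and environmental
# stimuli.  Nodes are plain lists:
#   list(type = "true")
#   list(type = "lit", kind = "id",   id = "G1A", negated = FALSE)
#   list(type = "lit", kind = "flux", id = "EX_S", sign = "pos",
#        threshold = 0, negated = FALSE)
#   list(type = "not", arg = <expr>)
#   list(type = "and"/"or", args = list(<expr>, ...))
# Identifier literals are resolved to gene/TF/stimulus at model validation;
# the parser only distinguishes identifiers from flux predicates (`rxn>t`,
# `rxn(e)>t`).

expr_true <- function() list(type = "true")
expr_lit <- function(id) list(type = "lit", kind = "id", id = id, negated = FALSE)
expr_flux <- function(id, threshold = 0, sign = "pos") {
  list(type = "lit", kind = "flux", id = id, sign = sign,
       threshold = threshold, negated = FALSE)
}
expr_not <- function(arg) list(type = "not", arg = arg)
expr_and <- function(...) list(type = "and", args = list(...))
expr_or <- function(...) list(type = "or", args = list(...))

is_true_expr <- function(e) identical(e$type, "true")

rule_tokenize <- function(text) {
  # identifiers may carry a trailing "(e)" marker (extracellular predicate
  # shorthand); numbers may be signed reals
  pat <- paste0(
    "\\s+",                                       # 1 whitespace
    "|[A-Za-z_][A-Za-z0-9_.:-]*(?:\\(e\\))?",     # identifier
    "|[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", # number
    "|[()>]"                                      # punctuation
  )
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substring(text, pos), perl = TRUE)
    if (m != 1L) {
      stop(sprintf("rule syntax error at position %d: unexpected character '%s'",
                   pos, substring(text, pos, pos)), call. = FALSE)
    }
    len <- attr(m, "match.length")
    val <- substring(text, pos, pos + len - 1L)
    if (!grepl("^\\s+$", val)) {
      toks[[length(toks) + 1L]] <- list(value = val, pos = pos)
    }
    pos <- pos + len
  }
  toks
}

#' Parse a Boolean rule string
#'
#' Parses GPR strings and transcriptional regulatory rules written as Boolean
#' expressions over identifiers with `AND`, `OR`, `NOT` (case-insensitive) and
#' parentheses.  Flux predicates are written `rxn>t` or `rxn(e)>t` and denote
#' "flux through `rxn` at least `t`" (a positive-flux indicator); their
#' negation denotes a negative-flux indicator when compiled.  The empty string
#' parses to the always-true expression (a constitutive target).
#'
#' @param text rule string.
#' @return a Boolean expression tree (plain nested list).
#' @examples
#' parse_rule("(G1A and G1B)")
#' parse_rule("(GlnL AND Not (nh4(e)>2))")
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(expr_true())
  toks <- rule_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { tok <- peek(); st$i <- st$i + 1L; tok }
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) nchar(text) + 1L else tok$pos
    stop(sprintf("rule syntax error at position %d: %s", where, msg),
         call. = FALSE)
  }
  kw <- function(tok) {
    if (is.null(tok)) return("")
    v <- tolower(tok$value)
    if (v %in% c("and", "or", "not")) v else ""
  }
  parse_or <- function() {
    terms <- list(parse_and())
    while (kw(peek()) == "or") {
      advance()
      terms[[length(terms) + 1L]] <- parse_and()
    }
    if (length(terms) == 1L) terms[[1L]] else list(type = "or", args = terms)
  }
  parse_and <- function() {
    factors <- list(parse_factor())
    while (kw(peek()) == "and") {
      advance()
      factors[[length(factors) + 1L]] <- parse_factor()
    }
    if (length(factors) == 1L) factors[[1L]] else list(type = "and", args = factors)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) fail("unexpected end of rule")
    if (kw(tok) == "not") {
      advance()
      return(expr_not(parse_factor()))
    }
    if (tok$value == "(") {
      advance()
      e <- parse_or()
      cl <- peek()
      if (is.null(cl) || cl$value != ")") fail("expected ')'", cl)
      advance()
      return(e)
    }
    if (grepl("^[A-Za-z_]", tok$value)) {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$value == ">") {
        advance()
        num <- peek()
        if (is.null(num) || is.na(suppressWarnings(as.numeric(num$value)))) {
          fail("expected a numeric threshold after '>'", num)
        }
        advance()
        return(expr_flux(tok$value, threshold = as.numeric(num$value)))
      }
      return(expr_lit(tok$value))
    }
    fail(sprintf("unexpected token '%s'", tok$value), tok)
  }
  out <- parse_or()
  if (!is.null(peek())) fail(sprintf("unexpected token '%s'", peek()$value))
  out
}

# Deparse an expression back to the rule grammar (round-trip serialization).
deparse_rule <- function(e) {
  switch(e$type,
    true = "",
    lit = {
      base <- if (e$kind == "flux") sprintf("%s>%.15g", e$id, e$threshold) else e$id
      if (isTRUE(e$negated)) sprintf("not (%s)", base) else base
    },
    not = sprintf("not (%s)", deparse_rule(e$arg)),
    and = paste0("(", paste(vapply(e$args, deparse_rule, ""), collapse = " and "), ")"),
    or = paste0("(", paste(vapply(e$args, deparse_rule, ""), collapse = " or "), ")"),
    stop("malformed expression")
  )
}

# Literals appearing in the tree, as a data.frame(kind, id, threshold).
expr_literals <- function(e) {
  acc <- list()
  walk <- function(x) {
    switch(x$type,
      true = NULL,
      lit = acc[[length(acc) + 1L]] <<- x,
      not = walk(x$arg),
      { for (a in x$args) walk(a) }
    )
    invisible(NULL)
  }
  walk(e)
  if (!length(acc)) {
    return(data.frame(kind = character(), id = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    kind = vapply(acc, function(l) l$kind, ""),
    id = vapply(acc, function(l) l$id, ""),
    threshold = vapply(acc, function(l) if (l$kind == "flux") l$threshold else NA_real_, 0),
    stringsAsFactors = FALSE
  )
}

# Evaluate a tree against an assignment function lit -> logical.
eval_expr <- function(e, lit_value) {
  switch(e$type,
    true = TRUE,
    lit = {
      v <- lit_value(e)
      if (isTRUE(e$negated)) !v else v
    },
    not = !eval_expr(e$arg, lit_value),
    and = all(vapply(e$args, eval_expr, NA, lit_value = lit_value)),
    or = any(vapply(e$args, eval_expr, NA, lit_value = lit_value)),
    stop("malformed expression")
  )
}

# Push negations down to literals (negation normal form).  Literals carry a
# `negated` flag; for flux literals negation flips the sign of the indicator
# when compiled (positive-flux vs negative-flux).
expr_nnf <- function(e, neg = FALSE) {
  switch(e$type,
    true = if (neg) list(type = "false") else e,
    false = if (neg) expr_true() else e,
    lit = { e$negated <- xor(isTRUE(e$negated), neg); e },
    not = expr_nnf(e$arg, !neg),
    and = {
      args <- lapply(e$args, expr_nnf, neg = neg)
      list(type = if (neg) "or" else "and", args = args)
    },
    or = {
      args <- lapply(e$args, expr_nnf, neg = neg)
      list(type = if (neg) "and" else "or", args = args)
    },
    stop("malformed expression")
  )
}

# Disjunctive normal form: a list of conjunctions, each a list of literal
# nodes.  TRUE => list(list()) (one empty conjunction); FALSE => list().
# Duplicate and absorbed (superset) conjunctions are pruned.
expr_dnf <- function(e, max_terms = 4096L) {
  nnf <- expr_nnf(e)
  rec <- function(x) {
    switch(x$type,
      true = list(list()),
      false = list(),
      lit = list(list(x)),
      or = {
        out <- list()
        for (a in x$args) out <- c(out, rec(a))
        if (length(out) > max_terms) stop("DNF term cap exceeded", call. = FALSE)
        out
      },
      and = {
        out <- list(list())
        for (a in x$args) {
          sub <- rec(a)
          nxt <- vector("list", length(out) * length(sub))
          k <- 0L
          for (c1 in out) for (c2 in sub) {
            k <- k + 1L
            nxt[[k]] <- c(c1, c2)
          }
          out <- nxt
          if (length(out) > max_terms) stop("DNF term cap exceeded", call. = FALSE)
        }
        out
      },
      stop("malformed expression")
    )
  }
  terms <- rec(nnf)
  # canonical literal keys; drop contradictory, duplicate and absorbed terms
  term_keys <- lapply(terms, function(conj) {
    keys <- vapply(conj, function(l) {
      paste(l$kind, l$id,
            if (l$kind == "flux") paste(l$sign, l$threshold) else "",
            if (isTRUE(l$negated)) "!" else "", sep = "|")
    }, "")
    sort(unique(keys))
  })
  dedup_lits <- function(conj) {
    seen <- character()
    out <- list()
    for (l in conj) {
      k <- paste(l$kind, l$id,
                 if (l$kind == "flux") paste(l$sign, l$threshold) else "",
                 if (isTRUE(l$negated)) "!" else "", sep = "|")
      if (!k %in% seen) {
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- l
      }
    }
    out
  }
  contradictory <- vapply(seq_along(terms), function(i) {
    k <- term_keys[[i]]
    base <- sub("\\|!$", "|", k)
    any(duplicated(base))
  }, NA)
  terms <- terms[!contradictory]
  term_keys <- term_keys[!contradictory]
  keystr <- vapply(term_keys, paste, "", collapse = "&")
  keep <- !duplicated(keystr)
  terms <- terms[keep]
  term_keys <- term_keys[keep]
  # absorption: drop any term that is a strict superset of another
  n <- length(terms)
  if (n > 1L) {
    absorbed <- rep(FALSE, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !absorbed[j] &&
            length(term_keys[[j]]) < length(term_keys[[i]]) &&
            all(term_keys[[j]] %in% term_keys[[i]])) {
          absorbed[i] <- TRUE
          break
        }
      }
    }
    terms <- terms[!absorbed]
  }
  lapply(terms, dedup_lits)
}

# TRUE if the expression uses only AND/OR over plain identifier literals
# (the admissible GPR fragment: no NOT, no flux predicates).
is_gpr_expr <- function(e) {
  switch(e$type,
    true = TRUE,
    lit = e$kind == "id" && !isTRUE(e$negated),
    not = FALSE,
    and = all(vapply(e$args, is_gpr_expr, NA)),
    or = all(vapply(e$args, is_gpr_expr, NA)),
    FALSE
  )
}
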