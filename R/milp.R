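# Linear / mixed-integer program builder and the HiGHS solver bridge.
#
# Problems are assembled in an environment-backed builder (variables with
# bounds/objective/type, constraint rows as sparse triplets) and solved by
# the HiGHS solver through `scipy.optimize.milp`, called as a python
# subprocess on a JSON batch.  Batching matters: the brute-force oracles in
# the test-suite solve thousands of tiny LPs, and one interpreter start per
# batch keeps that cheap.

lp_new <- function(maximize = TRUE) {
  lp <- new.env(parent = emptyenv())
  lp$maximize <- maximize
  lp$nvar <- 0L
  lp$names <- character()
  lp$lb <- numeric()
  lp$ub <- numeric()
  lp$obj <- numeric()
  lp$vtype <- character()
  lp$con_i <- list()   # per-row variable indices
  lp$con_x <- list()   # per-row coefficients
  lp$sense <- character()
  lp$rhs <- numeric()
  lp$time_limit <- NULL
  lp
}

lp_add_var <- function(lp, name, lb = -Inf, ub = Inf, obj = 0, type = "C") {
  lp$nvar <- lp$nvar + 1L
  k <- lp$nvar
  lp$names[k] <- name
  lp$lb[k] <- lb
  lp$ub[k] <- ub
  lp$obj[k] <- obj
  lp$vtype[k] <- type
  k
}

# A linear expression: list(idx = variable indices, coef, const).
lin <- function(idx = integer(), coef = numeric(), const = 0) {
  list(idx = as.integer(idx), coef = as.numeric(coef), const = const)
}
lin_var <- function(k, coef = 1) lin(k, coef)
lin_const <- function(c) lin(const = c)
lin_sum <- function(...) {
  terms <- list(...)
  lin(unlist(lapply(terms, `[[`, "idx")),
      unlist(lapply(terms, `[[`, "coef")),
      sum(vapply(terms, `[[`, 0, "const")))
}
lin_scale <- function(e, s) lin(e$idx, e$coef * s, e$const * s)

# Add constraint  sum(expr) (sense) rhs ; expr may be a `lin` or a pair of
# idx/coef vectors.  Duplicate variable indices are accumulated.
lp_add_con <- function(lp, expr, sense, rhs) {
  if (!is.list(expr) || is.null(expr$idx)) stop("expr must be a lin()")
  idx <- expr$idx
  coef <- expr$coef
  if (length(idx)) {
    agg <- rowsum(coef, idx)
    idx <- as.integer(rownames(agg))
    coef <- as.numeric(agg)
    keep <- coef != 0
    idx <- idx[keep]; coef <- coef[keep]
  }
  k <- length(lp$sense) + 1L
  lp$con_i[[k]] <- idx
  lp$con_x[[k]] <- coef
  lp$sense[k] <- sense
  lp$rhs[k] <- rhs - expr$const
  invisible(k)
}

lp_set_objective <- function(lp, expr, maximize = TRUE) {
  lp$obj <- numeric(lp$nvar)
  if (length(expr$idx)) {
    agg <- rowsum(expr$coef, expr$idx)
    lp$obj[as.integer(rownames(agg))] <- as.numeric(agg)
  }
  lp$obj_const <- expr$const
  lp$maximize <- maximize
  invisible(lp)
}

lp_serialize <- function(lp) {
  cap <- function(v) pmax(pmin(v, 1e30), -1e30)
  m <- length(lp$sense)
  row_len <- if (m) lengths(lp$con_i) else integer()
  list(
    ncol = lp$nvar,
    obj = as.numeric(lp$obj[seq_len(lp$nvar)]),
    maximize = isTRUE(lp$maximize),
    lb = cap(as.numeric(lp$lb)),
    ub = cap(as.numeric(lp$ub)),
    vtype = as.character(lp$vtype),
    A = list(i = rep(seq_len(m), row_len),
             j = as.integer(unlist(lp$con_i)),
             x = as.numeric(unlist(lp$con_x))),
    sense = as.character(lp$sense),
    rhs = as.numeric(lp$rhs),
    time_limit = lp$time_limit
  )
}

solver_script <- function() {
  path <- system.file("python", "milp.py", package = "optorf")
  if (!nzchar(path)) {
    # during development (pkgload), fall back to the source tree
    path <- file.path("inst", "python", "milp.py")
  }
  if (!file.exists(path)) stop("solver bridge script not found", call. = FALSE)
  path
}

#' @keywords internal
milp_solve_batch <- function(lps) {
  if (!length(lps)) return(list())
  payload <- lapply(lps, lp_serialize)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- suppressWarnings(
    system2("python", c(solver_script(), fin, fout),
            stdout = tempfile(), stderr = tempfile())
  )
  if (status != 0L || !file.exists(fout)) {
    stop("HiGHS solver bridge failed (exit status ", status, ")", call. = FALSE)
  }
  res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  lapply(seq_along(res), function(k) {
    r <- res[[k]]
    lp <- lps[[k]]
    x <- if (!is.null(r$x)) {
      stats::setNames(vapply(r$x, as.numeric, 0), lp$names)
    } else NULL
    obj <- if (!is.null(r$objective)) {
      as.numeric(r$objective) + (if (is.null(lp$obj_const)) 0 else lp$obj_const)
    } else NA_real_
    list(status = r$status, objective = obj, x = x,
         mip_gap = if (!is.null(r$mip_gap)) as.numeric(r$mip_gap) else NA_real_,
         message = r$message)
  })
}

milp_solve <- function(lp) milp_solve_batch(list(lp))[[1L]]
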