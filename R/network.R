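#' Discrete Bayesian networks
#'
#' A Bayesian network is a DAG over discrete variables together with one
#' conditional probability table (CPT) per variable, defined on the
#' variable's family: the variable plus its parents.  The joint distribution
#' factorizes as the product of the CPTs.
#'
#' @param states named list mapping each variable name to its ordered vector
#'   of state labels; the list order fixes the global variable order used for
#'   canonical potential scopes.
#' @param parents named list mapping each variable to the character vector of
#'   its parents (missing or NULL means no parents).
#' @param cpts named list mapping each variable to its CPT, either a
#'   [potential()] on the family or a numeric array whose values are laid out
#'   over `(variable, parents in the order given)` with the first dimension
#'   (the variable itself) varying fastest.
#' @param strict logical; if `TRUE` a CPT column deviating from sum 1 by more
#'   than 1e-6 is an error, otherwise a warning.  Structural defects (cycles,
#'   scope mismatches) are always errors.
#' @return an object of class `bn`.
#' @examples
#' chain <- bayesian_network(
#'   states  = list(X1 = c("0", "1"), X2 = c("0", "1"), X3 = c("0", "1")),
#'   parents = list(X2 = "X1", X3 = "X2"),
#'   cpts    = list(X1 = c(0.4, 0.6),
#'                  X2 = c(0.7, 0.3, 0.2, 0.8),
#'                  X3 = c(0.5, 0.5, 0.1, 0.9)))
#' bn_family(chain, "X2")
#' @export
bayesian_network <- function(states, parents = list(), cpts, strict = FALSE) {
  vars <- names(states)
  if (is.null(vars) || anyDuplicated(vars))
    stop("states must be a named list with unique variable names")
  states <- lapply(states, as.character)
  parents <- parents[intersect(names(parents), vars)]
  pa <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    p <- parents[[v]]
    if (is.null(p)) p <- character()
    p <- as.character(p)
    if (!all(p %in% vars))
      stop(sprintf("unknown parent of '%s': %s", v,
                   paste(setdiff(p, vars), collapse = ", ")))
    if (v %in% p) stop(sprintf("variable '%s' is its own parent", v))
    if (anyDuplicated(p)) stop(sprintf("duplicate parents of '%s'", v))
    pa[[v]] <- p
  }
  if (is.null(topological_order(vars, pa)))
    stop("parent graph is cyclic")
  idx <- stats::setNames(seq_along(vars), vars)
  if (missing(cpts) || !all(vars %in% names(cpts)))
    stop("a CPT is required for every variable")
  tabs <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    fam <- c(v, pa[[v]])
    cp <- cpts[[v]]
    if (inherits(cp, "bn_pot")) {
      if (!setequal(cp$vars, fam))
        stop(sprintf("CPT scope of '%s' is not its family", v))
      cp$idx <- idx[cp$vars]
      cp <- canonical_pot(cp)
    } else {
      cp <- potential(cp, fam, states[fam], idx = idx[fam])
    }
    tabs[[v]] <- cp
  }
  net <- structure(list(vars = vars, idx = idx, states = states,
                        parents = pa, cpts = tabs),
                   class = "bn")
  bad <- cpt_normalization_errors(net, tol = 1e-6)
  if (length(bad)) {
    msg <- paste(bad, collapse = "; ")
    if (strict) stop(msg) else warning(msg)
  }
  net
}

# Kahn's algorithm; NULL if cyclic
topological_order <- function(vars, parents) {
  indeg <- vapply(parents, length, integer(1))[vars]
  children <- stats::setNames(lapply(vars, function(v) character()), vars)
  for (v in vars) for (p in parents[[v]])
    children[[p]] <- c(children[[p]], v)
  queue <- vars[indeg == 0L]
  out <- character()
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) == length(vars)) out else NULL
}

cpt_normalization_errors <- function(net, tol = 1e-9) {
  out <- character()
  for (v in net$vars) {
    cp <- net$cpts[[v]]
    cond <- pot_sum_out(cp, v)
    dev <- max(abs(as.numeric(cond$values) - 1))
    if (dev > tol)
      out <- c(out, sprintf(
        "CPT of '%s' deviates from normalization by %.3g", v, dev))
  }
  out
}

#' @export
print.bn <- function(x, ...) {
  cat(sprintf("<bayesian network> %d variables, %d arcs, %d parameters\n",
              length(x$vars), bn_arc_count(x), bn_parameter_count(x)))
  for (v in x$vars) {
    pa <- x$parents[[v]]
    cat(sprintf("  %s (%d states)%s\n", v, length(x$states[[v]]),
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", "))
                else ""))
  }
  invisible(x)
}

bn_arc_count <- function(net) sum(vapply(net$parents, length, integer(1)))

bn_parameter_count <- function(net)
  sum(vapply(net$cpts, function(p) length(p$values), numeric(1)))

#' Family of a variable
#'
#' The family of a variable is the variable together with its parents: the
#' scope of its CPT.  Returned in canonical (declaration) order.
#'
#' @param net a `bn` object.
#' @param var variable name.
#' @return character vector of family members.
#' @export
bn_family <- function(net, var) {
  if (!var %in% net$vars) stop(sprintf("unknown variable '%s'", var))
  fam <- c(var, net$parents[[var]])
  fam[order(net$idx[fam])]
}

#' Joint distribution of a network
#'
#' Multiplies all CPTs into the full joint table.  Exponential in the number
#' of variables; intended as a desk-scale oracle, so the total state-space
#' size is capped.
#'
#' @param net a `bn` object.
#' @param max_cells cap on the number of joint table entries.
#' @return a potential over all variables summing to 1.
#' @export
bn_joint <- function(net, max_cells = 2^22) {
  cells <- prod(vapply(net$states, length, integer(1)))
  if (cells > max_cells)
    stop(sprintf("joint table would hold %.3g cells (cap %.3g)",
                 cells, max_cells))
  Reduce(pot_multiply, net$cpts)
}

#' Validate a network
#'
#' Report-only check of acyclicity, CPT scope/family agreement and CPT
#' normalization.
#'
#' @param net a `bn` object.
#' @param tol tolerance on CPT column sums.
#' @return character vector of violation messages; empty when well-formed.
#' @export
bn_validate <- function(net, tol = 1e-9) {
  out <- character()
  if (is.null(topological_order(net$vars, net$parents)))
    out <- c(out, "parent graph is cyclic")
  for (v in net$vars) {
    fam <- c(v, net$parents[[v]])
    if (!setequal(net$cpts[[v]]$vars, fam))
      out <- c(out, sprintf("CPT scope of '%s' is not its family", v))
  }
  c(out, cpt_normalization_errors(net, tol = tol))
}

#' Ancestors of a set of variables
#'
#' Transitive closure of the parent relation.
#'
#' @param net a `bn` object.
#' @param vars character vector of variables.
#' @param include_self logical; include `vars` themselves in the result.
#' @return character vector of ancestors, in declaration order.
#' @export
bn_ancestors <- function(net, vars, include_self = FALSE) {
  vars <- as.character(vars)
  if (!all(vars %in% net$vars))
    stop(sprintf("unknown variable(s): %s",
                 paste(setdiff(vars, net$vars), collapse = ", ")))
  seen <- character()
  frontier <- vars
  while (length(frontier)) {
    ps <- unique(unlist(net$parents[frontier], use.names = FALSE))
    frontier <- setdiff(ps, c(seen, vars))
    seen <- union(seen, ps)
  }
  out <- if (include_self) union(seen, vars) else setdiff(seen, vars)
  out[order(net$idx[out])]
}

# both networks must share variables and state spaces exactly
check_same_domain <- function(net_a, net_b) {
  if (!setequal(net_a$vars, net_b$vars))
    stop("networks are defined on different variable sets")
  for (v in net_a$vars)
    if (!identical(net_a$states[[v]], net_b$states[[v]]))
      stop(sprintf("variable '%s' has mismatched state spaces", v))
  invisible(TRUE)
}
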