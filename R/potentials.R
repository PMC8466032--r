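#' Discrete potentials
#'
#' A potential is a nonnegative real-valued table over the joint
#' configurations of an ordered set of discrete variables (its scope).
#' Conditional probability tables are potentials on a variable's family;
#' intermediate factors arising during variable elimination are potentials
#' too.  The empty-scope potential is a plain scalar.
#'
#' Scopes are kept in a canonical order: variables are sorted by their global
#' index (their position in the network's declaration order), carried in the
#' `idx` field.  All operations return canonically ordered results, so two
#' potentials over the same variables are comparable entry by entry and can
#' serve as cache keys.
#'
#' @param values numeric vector or array of table values, in the order of
#'   `vars` as supplied (first variable varying fastest).
#' @param vars character vector of variable names (empty for a scalar).
#' @param states named list mapping each variable to its ordered state labels.
#' @param idx named integer vector of global variable indices; defaults to
#'   `seq_along(vars)` for standalone use.
#' @return an object of class `bn_pot`.
#' @examples
#' a <- potential(c(0.3, 0.7), "X1", list(X1 = c("no", "yes")))
#' b <- potential(c(0.9, 0.1, 0.2, 0.8), c("X2", "X1"),
#'                list(X2 = c("no", "yes"), X1 = c("no", "yes")),
#'                idx = c(X2 = 2, X1 = 1))
#' pot_multiply(a, b)
#' @export
potential <- function(values, vars = character(), states = list(),
                      idx = NULL) {
  vars <- as.character(vars)
  if (anyDuplicated(vars)) stop("duplicate variables in scope")
  if (is.null(idx)) idx <- stats::setNames(seq_along(vars), vars)
  idx <- idx[vars]
  if (anyNA(idx)) stop("missing global index for some scope variable")
  states <- states[vars]
  card <- vapply(states, length, integer(1))
  if (length(vars) && any(card < 1L)) stop("every variable needs >= 1 state")
  n <- if (length(vars)) prod(card) else 1L
  values <- as.numeric(values)
  if (length(values) != n)
    stop(sprintf("table has %d entries, scope requires %d", length(values), n))
  if (any(!is.finite(values)) || any(values < 0))
    stop("potential values must be finite and nonnegative")
  p <- structure(list(vars = vars, idx = idx, states = states,
                      values = if (length(vars)) array(values, dim = card)
                               else values),
                 class = "bn_pot")
  canonical_pot(p)
}

# reorder scope (and table) into ascending global-index order
canonical_pot <- function(p) {
  if (length(p$vars) < 2L) return(p)
  ord <- order(p$idx)
  if (all(ord == seq_along(ord))) return(p)
  p$values <- aperm(p$values, ord)
  p$vars <- p$vars[ord]
  p$idx <- p$idx[ord]
  p$states <- p$states[ord]
  p
}

pot_card <- function(p) vapply(p$states, length, integer(1))

#' @export
print.bn_pot <- function(x, ...) {
  if (!length(x$vars)) {
    cat("<potential> scalar:", x$values, "\n")
    return(invisible(x))
  }
  cat("<potential> on {", paste(x$vars, collapse = ", "), "}\n", sep = "")
  tab <- x$values
  dimnames(tab) <- x$states
  print(tab)
  invisible(x)
}

#' Project a configuration onto a sub-scope
#'
#' A configuration assigns one state index to each variable of a scope; it is
#' represented as a named integer vector of 1-based state indices.  Projection
#' drops the variables outside `vars`.
#'
#' @param x named integer vector, a configuration.
#' @param vars character vector, the target scope (must be a subset of
#'   `names(x)`).
#' @return the restriction of `x` to `vars`.
#' @export
config_project <- function(x, vars) {
  vars <- as.character(vars)
  if (!all(vars %in% names(x)))
    stop("projection scope is not a subset of the configuration's scope")
  x[vars]
}

# all configurations of a scope as an integer matrix, one row per
# configuration, first variable varying fastest (linear table order)
config_grid <- function(card) {
  if (!length(card)) return(matrix(integer(), nrow = 1L, ncol = 0L))
  m <- as.matrix(do.call(expand.grid, lapply(card, seq_len)))
  dimnames(m) <- NULL
  m
}

#' Multiply two potentials
#'
#' Pointwise multiplication on the union scope: the value at a joint
#' configuration y is the product of each factor evaluated at y projected on
#' its own scope.  Shared variables must carry identical state spaces.
#'
#' @param a,b potentials (`bn_pot`).
#' @return a potential on the union of the two scopes, canonically ordered.
#' @export
pot_multiply <- function(a, b) {
  stopifnot(inherits(a, "bn_pot"), inherits(b, "bn_pot"))
  shared <- intersect(a$vars, b$vars)
  for (v in shared) {
    if (!identical(a$states[[v]], b$states[[v]]))
      stop(sprintf("variable '%s' has mismatched state spaces", v))
    if (a$idx[[v]] != b$idx[[v]])
      stop(sprintf("variable '%s' has conflicting global indices", v))
  }
  if (!length(a$vars)) {
    b$values <- b$values * as.numeric(a$values)
    return(b)
  }
  if (!length(b$vars)) {
    a$values <- a$values * as.numeric(b$values)
    return(a)
  }
  uvars <- union(a$vars, b$vars)
  uidx <- c(a$idx, b$idx[setdiff(b$vars, a$vars)])[uvars]
  ord <- order(uidx)
  uvars <- uvars[ord]
  uidx <- uidx[uvars]
  ustates <- c(a$states, b$states[setdiff(b$vars, a$vars)])[uvars]
  ucard <- vapply(ustates, length, integer(1))
  va <- expand_table(a, uvars, ucard)
  vb <- expand_table(b, uvars, ucard)
  structure(list(vars = uvars, idx = uidx, states = ustates,
                 values = array(va * vb, dim = ucard)),
            class = "bn_pot")
}

# replicate a potential's table over the extra dimensions of a superset scope
expand_table <- function(p, uvars, ucard) {
  pos <- match(p$vars, uvars)
  extra <- setdiff(seq_along(uvars), pos)
  arr <- array(p$values, dim = c(pot_card(p), ucard[extra]))
  aperm(arr, match(seq_along(uvars), c(pos, extra)))
}

#' Sum a variable out of a potential
#'
#' Removes `var` from the scope by summing the table over its states; the
#' total table mass is conserved.
#'
#' @param p a potential.
#' @param var variable name to remove (must be in the scope).
#' @return a potential on `scope(p)` minus `var`.
#' @export
pot_sum_out <- function(p, var) {
  pos <- match(var, p$vars)
  if (is.na(pos)) stop(sprintf("variable '%s' not in scope", var))
  keep <- setdiff(seq_along(p$vars), pos)
  if (!length(keep)) {
    vals <- sum(p$values)
  } else {
    vals <- apply(p$values, keep, sum)
    vals <- array(vals, dim = pot_card(p)[keep])
  }
  structure(list(vars = p$vars[keep], idx = p$idx[keep],
                 states = p$states[keep], values = vals),
            class = "bn_pot")
}

#' Marginalize a potential onto a sub-scope
#'
#' Sums out every scope variable not in `vars`; the result is independent of
#' the removal order.
#'
#' @param p a potential.
#' @param vars character vector, the variables to keep (subset of the scope).
#' @return the marginal potential on `vars`.
#' @export
pot_marginalize <- function(p, vars) {
  vars <- as.character(vars)
  if (!all(vars %in% p$vars))
    stop("marginalization target is not a subset of the scope")
  for (v in setdiff(p$vars, vars)) p <- pot_sum_out(p, v)
  p
}

#' Restrict (select) a potential to a configuration
#'
#' Slices the table at the given values of the configured variables and drops
#' them from the scope.  Variables of the configuration outside the scope are
#' ignored; a fully disjoint configuration returns the potential unchanged.
#'
#' @param p a potential.
#' @param config named integer vector of 1-based state indices.
#' @return a potential on `scope(p)` minus the configured variables.
#' @export
pot_restrict <- function(p, config) {
  common <- intersect(names(config), p$vars)
  if (!length(common)) return(p)
  card <- pot_card(p)
  for (v in common) {
    k <- config[[v]]
    if (!is.numeric(k) || k < 1L || k > card[[v]])
      stop(sprintf("state index %s out of range for variable '%s'",
                   format(k), v))
  }
  ix <- lapply(p$vars, function(v)
    if (v %in% common) as.integer(config[[v]]) else seq_len(card[[v]]))
  vals <- do.call(`[`, c(list(p$values), ix, list(drop = FALSE)))
  keep <- which(!(p$vars %in% common))
  if (!length(keep)) {
    vals <- as.numeric(vals)
  } else {
    vals <- array(as.numeric(vals), dim = card[keep])
  }
  structure(list(vars = p$vars[keep], idx = p$idx[keep],
                 states = p$states[keep], values = vals),
            class = "bn_pot")
}

# look up a single table value at a full configuration of the scope
pot_value <- function(p, config) {
  if (!length(p$vars)) return(as.numeric(p$values))
  ix <- as.list(as.integer(config[p$vars]))
  do.call(`[`, c(list(p$values), ix))
}
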