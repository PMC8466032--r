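#' Delete a variable from a factor set
#'
#' The elementary step of variable elimination: every potential mentioning
#' the variable is combined (pairwise, in current list order), the variable
#' is summed out of the product, and the result replaces the combined
#' factors.  The product over the set is preserved with the variable summed
#' out.
#'
#' @param pots list of potentials.
#' @param var variable name to delete.
#' @return the updated list of potentials, none of which mentions `var`.
#' @export
delete_variable <- function(pots, var) {
  hit <- vapply(pots, function(p) var %in% p$vars, logical(1))
  if (!any(hit)) {
    warning(sprintf("variable '%s' occurs in no potential; nothing deleted",
                    var))
    return(pots)
  }
  prod_pot <- Reduce(pot_multiply, pots[hit])
  c(pots[!hit], list(pot_sum_out(prod_pot, var)))
}

# resolve an elimination-order argument into an order function
elim_order_fun <- function(order) {
  if (is.function(order)) return(order)
  if (identical(order, "min_weight")) return(min_weight_order)
  stop("order must be \"min_weight\" or a function(scopes, eliminate, card, idx)")
}

#' Unnormalized family marginal under parent evidence
#'
#' Computes q on the states of `target` with q(x) = p(x, e): the joint of
#' the target with the evidence configuration `xpa`, taken under the
#' network's distribution.  This is one inner run of the evidence-propagation
#' engine: requisite CPTs are selected by Bayes-ball, restricted to the
#' evidence, and all other variables are deleted.  No normalization is
#' applied — the evidence mass is part of the result.
#'
#' @param net a `bn` object (the reference distribution).
#' @param target variable kept in the result.
#' @param xpa named integer vector of 1-based state indices, the evidence
#'   configuration (typically a parent configuration in the other network).
#' @param order elimination-order heuristic: `"min_weight"` or a function
#'   with the signature of [min_weight_order()].
#' @return a potential on `target`.
#' @export
marginal_given_parent_config <- function(net, target, xpa = integer(),
                                         order = "min_weight") {
  ev <- names(xpa)
  if (!all(ev %in% net$vars))
    stop(sprintf("unknown evidence variable(s): %s",
                 paste(setdiff(ev, net$vars), collapse = ", ")))
  rel <- requisite_cpts(net, target, ev)
  pots <- lapply(net$cpts[rel], pot_restrict, config = xpa)
  scopes <- lapply(pots, `[[`, "vars")
  elim <- setdiff(unique(unlist(scopes, use.names = FALSE)), target)
  if (length(elim)) {
    card <- vapply(net$states, length, integer(1))
    eo <- elim_order_fun(order)(scopes, elim, card, net$idx)
    for (v in eo) pots <- delete_variable(pots, v)
  }
  Reduce(pot_multiply, pots)
}

#' Expected log-likelihood by evidence propagation
#'
#' Computes LL(net_a, net_b), the expectation under net_a's joint of the log
#' of net_b's joint, by running one evidence-restricted variable-elimination
#' pass per variable of net_b and per configuration of its parents in net_b.
#' The number of runs is the sum over variables of the number of parent
#' configurations in net_b (see [propagation_run_count()]).
#'
#' @param net_a,net_b `bn` objects on the same variables and state spaces.
#' @param log_base `"e"` (nats) or `"2"` (bits).
#' @param zero_policy `"extended"` (0 log 0 = 0; positive mass on a zero CPT
#'   entry yields -Inf with a warning) or `"strict"` (that case is an error).
#' @param order elimination-order heuristic, as in
#'   [marginal_given_parent_config()].
#' @return list with `ll` (the expected log-likelihood) and `runs` (number
#'   of elimination runs performed).
#' @export
ll_propagation <- function(net_a, net_b, log_base = c("e", "2"),
                           zero_policy = c("extended", "strict"),
                           order = "min_weight") {
  log_base <- match.arg(log_base)
  zero_policy <- match.arg(zero_policy)
  check_same_domain(net_a, net_b)
  total <- 0
  runs <- 0L
  for (v in net_b$vars) {
    pa <- net_b$parents[[v]]
    grid <- config_grid(vapply(net_b$states[pa], length, integer(1)))
    for (r in seq_len(nrow(grid))) {
      xpa <- stats::setNames(as.integer(grid[r, ]), pa)
      runs <- runs + 1L
      q <- marginal_given_parent_config(net_a, v, xpa, order = order)
      cpt_slice <- pot_restrict(net_b$cpts[[v]], xpa)
      nc <- length(net_b$states[[v]])
      qv <- vapply(seq_len(nc), function(k)
        pot_value(q, stats::setNames(k, v)), numeric(1))
      bv <- vapply(seq_len(nc), function(k)
        pot_value(cpt_slice, stats::setNames(k, v)), numeric(1))
      total <- total + ll_terms(qv, bv, zero_policy)
    }
  }
  list(ll = apply_log_base(total, log_base), runs = runs)
}

# sum of m * log(c) with the 0 log 0 convention and the zero policy
ll_terms <- function(mass, cpt, zero_policy) {
  pos <- mass > 0
  if (any(pos & cpt == 0)) {
    if (zero_policy == "strict")
      stop(errorCondition(
        "zero CPT entry carries positive mass under the reference network",
        class = c("klbn_zero_error", "error", "condition")))
    warning("zero CPT entry carries positive mass; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(mass[pos] * log(cpt[pos]))
}

apply_log_base <- function(x, log_base) {
  if (identical(log_base, "2")) x / log(2) else x
}

#' Number of elimination runs of the propagation engine
#'
#' For each variable, one run per configuration of its parents: the total is
#' the sum over variables of the product of parent cardinalities.
#'
#' @param net a `bn` object (the network whose families drive the runs).
#' @return integer run count.
#' @export
propagation_run_count <- function(net) {
  sum(vapply(net$vars, function(v)
    prod(vapply(net$states[net$parents[[v]]], length, integer(1))),
    numeric(1)))
}
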