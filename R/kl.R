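#' Expected log-likelihood from family marginals
#'
#' Evaluates LL(p, net) = sum over variables and family configurations of
#' the family marginal of p times the log of the network's CPT entry: the
#' family decomposition of the expected log-likelihood.  Terms with zero
#' marginal mass contribute 0 regardless of the CPT value.
#'
#' @param net a `bn` object supplying the CPTs (and families).
#' @param marginals named list, one potential per variable, each defined on
#'   exactly that variable's family in `net` and computed under the
#'   reference distribution p.
#' @param log_base `"e"` or `"2"`.
#' @param zero_policy `"extended"` or `"strict"`; see [ll_propagation()].
#' @return the expected log-likelihood (a scalar; `-Inf` if the reference
#'   puts mass on a zero CPT entry under the extended policy).
#' @export
ll_from_marginals <- function(net, marginals, log_base = c("e", "2"),
                              zero_policy = c("extended", "strict")) {
  log_base <- match.arg(log_base)
  zero_policy <- match.arg(zero_policy)
  total <- 0
  for (v in net$vars) {
    m <- marginals[[v]]
    if (is.null(m)) stop(sprintf("no marginal supplied for '%s'", v))
    cp <- net$cpts[[v]]
    if (!setequal(m$vars, cp$vars))
      stop(sprintf("marginal scope for '%s' is not its family", v))
    if (!identical(m$vars, cp$vars)) {
      m$idx <- net$idx[m$vars]
      m <- canonical_pot(m)
    }
    total <- total + ll_terms(as.numeric(m$values), as.numeric(cp$values),
                              zero_policy)
  }
  apply_log_base(total, log_base)
}

#' Kullback-Leibler divergence between two Bayesian networks
#'
#' Computes KL(net_a, net_b) = LL(net_a, net_a) - LL(net_a, net_b), the
#' divergence between the joint distributions of two networks on the same
#' variables.  Three engines are available:
#' \describe{
#'   \item{`cache`}{plans all family marginals of both networks over net_a
#'     once, symbolically, reusing repeated factor operations through an
#'     operation repository, then executes the plan numerically
#'     ([plan_marginals()], [execute_plan()]).  Reports `ops`/`rep`/`del`
#'     counters.}
#'   \item{`propagation`}{one evidence-restricted variable-elimination run
#'     per variable and parent configuration ([ll_propagation()]).}
#'   \item{`brute`}{full joint enumeration; exponential, oracle use only.}
#' }
#'
#' @param net_a reference network (the "true" distribution).
#' @param net_b approximating network.
#' @param method `"cache"`, `"propagation"`, or `"brute"`.
#' @param log_base `"e"` (nats, default) or `"2"` (bits).
#' @param zero_policy `"extended"` or `"strict"`; see [ll_propagation()].
#' @param order elimination-order heuristic for the two elimination engines.
#' @return an object of class `bn_kl`: `kl`, `ll_self`, `ll_cross`,
#'   `engine`, and engine `stats`.
#' @examples
#' a <- random_bn(5, seed = 1)
#' b <- perturb_bn(a, 2, seed = 2)
#' kl_divergence(a, b)
#' @export
kl_divergence <- function(net_a, net_b,
                          method = c("cache", "propagation", "brute"),
                          log_base = c("e", "2"),
                          zero_policy = c("extended", "strict"),
                          order = "min_weight") {
  method <- match.arg(method)
  log_base <- match.arg(log_base)
  zero_policy <- match.arg(zero_policy)
  switch(method,
    cache = kl_cached(net_a, net_b, log_base, zero_policy, order),
    propagation = kl_propagation(net_a, net_b, log_base, zero_policy, order),
    brute = {
      check_same_domain(net_a, net_b)
      ja <- bn_joint(net_a)
      jb <- bn_joint(net_b)
      pb <- align_joint(jb, ja)
      pa <- as.numeric(ja$values)
      pos <- pa > 0
      ll_self <- sum(pa[pos] * log(pa[pos]))
      ll_cross <- ll_terms(pa, pb, zero_policy)
      kl_result(apply_log_base(ll_self, log_base),
                apply_log_base(ll_cross, log_base), "brute", NULL, log_base)
    })
}

align_joint <- function(p, template) {
  perm <- match(template$vars, p$vars)
  if (anyNA(perm)) stop("joints are defined on different variables")
  as.numeric(if (all(perm == seq_along(perm))) p$values
             else aperm(p$values, perm))
}

kl_result <- function(ll_self, ll_cross, engine, stats, log_base) {
  structure(list(kl = ll_self - ll_cross, ll_self = ll_self,
                 ll_cross = ll_cross, engine = engine, stats = stats,
                 log_base = log_base),
            class = "bn_kl")
}

#' @export
print.bn_kl <- function(x, ...) {
  unit <- if (identical(x$log_base, "2")) "bits" else "nats"
  cat(sprintf("KL divergence: %.10g %s  [engine: %s]\n", x$kl, unit,
              x$engine))
  cat(sprintf("  LL(A,A) = %.10g   LL(A,B) = %.10g\n",
              x$ll_self, x$ll_cross))
  if (!is.null(x$stats)) {
    flds <- intersect(c("ops", "rep", "del", "runs_self", "runs_cross"),
                      names(x$stats))
    cat("  ", paste(sprintf("%s=%s", flds, unlist(x$stats[flds])),
                    collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname kl_divergence
#' @export
kl_cached <- function(net_a, net_b, log_base = c("e", "2"),
                      zero_policy = c("extended", "strict"),
                      order = "min_weight") {
  log_base <- match.arg(log_base)
  zero_policy <- match.arg(zero_policy)
  fams <- family_query_set(net_a, net_b)
  plan <- plan_marginals(net_a, fams$queries, order = order)
  ex <- execute_plan(plan)
  marg_a <- stats::setNames(ex$marginals[fams$map_a], names(fams$map_a))
  marg_b <- stats::setNames(ex$marginals[fams$map_b], names(fams$map_b))
  ll_self <- ll_from_marginals(net_a, marg_a, log_base, zero_policy)
  ll_cross <- ll_from_marginals(net_b, marg_b, log_base, zero_policy)
  kl_result(ll_self, ll_cross, "cache", ex$stats, log_base)
}

#' @rdname kl_divergence
#' @export
kl_propagation <- function(net_a, net_b, log_base = c("e", "2"),
                           zero_policy = c("extended", "strict"),
                           order = "min_weight") {
  log_base <- match.arg(log_base)
  zero_policy <- match.arg(zero_policy)
  self <- ll_propagation(net_a, net_a, log_base, zero_policy, order)
  cross <- ll_propagation(net_a, net_b, log_base, zero_policy, order)
  kl_result(self$ll, cross$ll, "propagation",
            list(runs_self = self$runs, runs_cross = cross$runs), log_base)
}

#' Brute-force KL by joint enumeration
#'
#' Exact divergence by enumerating every joint configuration; exponential in
#' the number of variables and capped accordingly.  Serves as the
#' independent oracle for the elimination engines.
#'
#' @inheritParams kl_divergence
#' @param max_cells cap on the joint table size.
#' @return the divergence as a plain number.
#' @export
brute_force_kl <- function(net_a, net_b, log_base = c("e", "2"),
                           zero_policy = c("extended", "strict"),
                           max_cells = 2^22) {
  log_base <- match.arg(log_base)
  zero_policy <- match.arg(zero_policy)
  check_same_domain(net_a, net_b)
  ja <- bn_joint(net_a, max_cells = max_cells)
  jb <- bn_joint(net_b, max_cells = max_cells)
  pa <- as.numeric(ja$values)
  pb <- align_joint(jb, ja)
  pos <- pa > 0
  if (any(pos & pb == 0)) {
    if (zero_policy == "strict")
      stop(errorCondition(
        "reference mass on a configuration with zero probability",
        class = c("klbn_zero_error", "error", "condition")))
    return(Inf)
  }
  apply_log_base(sum(pa[pos] * log(pa[pos] / pb[pos])), log_base)
}
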