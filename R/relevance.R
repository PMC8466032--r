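#' Ancestrally relevant CPTs for a marginal query
#'
#' When computing the marginal of the joint on a set of variables, only the
#' CPTs of those variables and of their ancestors matter: the remaining CPTs
#' sum out to 1.  This is the pruning rule used by the cached engine.
#'
#' @param net a `bn` object.
#' @param targets character vector of query variables.
#' @return character vector of variables whose CPTs are relevant, in
#'   declaration order.
#' @export
relevant_cpts <- function(net, targets) {
  bn_ancestors(net, targets, include_self = TRUE)
}

#' Requisite CPTs via Bayes-ball
#'
#' Determines which CPTs are needed to compute the unnormalized joint of a
#' target variable with an evidence configuration, q(x) = p(x, e).  The set
#' is the union of Shachter's top-marked (requisite probability) nodes for
#' the conditional query with the ancestral closure of the evidence
#' variables, which supplies the evidence mass p(e).  It is never larger
#' than the ancestral closure of target plus evidence.
#'
#' @param net a `bn` object.
#' @param target variable whose marginal is queried.
#' @param evidence_vars character vector of observed variables (values are
#'   irrelevant for pruning).
#' @return character vector of variables whose CPTs are requisite, in
#'   declaration order.
#' @export
requisite_cpts <- function(net, target, evidence_vars = character()) {
  evidence_vars <- as.character(evidence_vars)
  if (!target %in% net$vars) stop(sprintf("unknown variable '%s'", target))
  if (target %in% evidence_vars) stop("target must not be observed")
  top <- bayes_ball_top(net, target, evidence_vars)
  out <- union(top,
               bn_ancestors(net, evidence_vars, include_self = TRUE))
  out[order(net$idx[out])]
}

# Shachter's Bayes-ball; returns top-marked nodes (requisite CPTs for the
# conditional query target | evidence)
bayes_ball_top <- function(net, target, evidence_vars) {
  children <- stats::setNames(lapply(net$vars, function(v) character()),
                              net$vars)
  for (v in net$vars) for (p in net$parents[[v]])
    children[[p]] <- c(children[[p]], v)
  observed <- net$vars %in% evidence_vars
  names(observed) <- net$vars
  top <- bottom <- stats::setNames(logical(length(net$vars)), net$vars)
  # each schedule item: visit node, ball arriving from a child or a parent
  queue <- list(list(node = target, from = "child"))
  while (length(queue)) {
    it <- queue[[1L]]; queue <- queue[-1L]
    v <- it$node
    if (it$from == "child") {
      if (observed[[v]]) next
      if (!top[[v]]) {
        top[[v]] <- TRUE
        for (p in net$parents[[v]])
          queue <- c(queue, list(list(node = p, from = "child")))
      }
      if (!bottom[[v]]) {
        bottom[[v]] <- TRUE
        for (ch in children[[v]])
          queue <- c(queue, list(list(node = ch, from = "parent")))
      }
    } else {
      if (observed[[v]]) {
        if (!top[[v]]) {
          top[[v]] <- TRUE
          for (p in net$parents[[v]])
            queue <- c(queue, list(list(node = p, from = "child")))
        }
      } else if (!bottom[[v]]) {
        bottom[[v]] <- TRUE
        for (ch in children[[v]])
          queue <- c(queue, list(list(node = ch, from = "parent")))
      }
    }
  }
  net$vars[top[net$vars]]
}

#' Min-weight elimination order
#'
#' Greedy triangulation heuristic on the interaction graph induced by a set
#' of potential scopes: repeatedly eliminate the variable whose closed
#' neighborhood has the smallest product of cardinalities, connecting its
#' neighbors before removing it.  Ties are broken by the lowest global
#' variable index, so the order is deterministic.
#'
#' @param scopes list of character vectors, the current potential scopes.
#' @param eliminate character vector of variables to eliminate (subset of the
#'   union of scopes).
#' @param card named integer vector of cardinalities for every variable
#'   appearing in the scopes.
#' @param idx named integer vector of global variable indices (tie-break);
#'   defaults to the order of `card`.
#' @return character vector: `eliminate` in elimination order.
#' @export
min_weight_order <- function(scopes, eliminate, card,
                             idx = stats::setNames(seq_along(card),
                                                   names(card))) {
  eliminate <- as.character(eliminate)
  all_vars <- unique(unlist(scopes, use.names = FALSE))
  if (!all(eliminate %in% all_vars))
    stop("eliminate must be a subset of the union of scopes")
  adj <- stats::setNames(lapply(all_vars, function(v) character()), all_vars)
  for (sc in scopes) for (v in sc)
    adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  remaining <- eliminate
  out <- character()
  while (length(remaining)) {
    w <- vapply(remaining, function(v)
      prod(card[c(v, adj[[v]])]), numeric(1))
    best <- remaining[w == min(w)]
    pick <- best[which.min(idx[best])]
    nb <- adj[[pick]]
    for (u in nb) adj[[u]] <- setdiff(union(adj[[u]], nb), c(u, pick))
    adj[[pick]] <- NULL
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}
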