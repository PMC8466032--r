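#' Ordered family-marginal query set for a network pair
#'
#' The cached engine computes, under net_a's joint, one marginal per family
#' of either network: net_a's families (for the self log-likelihood) followed
#' by net_b's (for the cross term), in variable order, with duplicate
#' families collapsed to their first occurrence.  Back-mappings record which
#' query serves which variable's family in each network.
#'
#' @param net_a,net_b `bn` objects on the same variables and state spaces.
#' @return list with `queries` (list of character scopes), `map_a` and
#'   `map_b` (named integer vectors: variable -> query position).
#' @export
family_query_set <- function(net_a, net_b) {
  check_same_domain(net_a, net_b)
  queries <- list()
  keys <- character()
  push <- function(fam) {
    key <- paste(fam, collapse = "\r")
    pos <- match(key, keys)
    if (is.na(pos)) {
      queries[[length(queries) + 1L]] <<- fam
      keys <<- c(keys, key)
      pos <- length(keys)
    }
    pos
  }
  map_a <- stats::setNames(integer(length(net_a$vars)), net_a$vars)
  for (v in net_a$vars) map_a[[v]] <- push(bn_family(net_a, v))
  map_b <- stats::setNames(integer(length(net_b$vars)), net_b$vars)
  for (v in net_b$vars)
    map_b[[v]] <- push(sort_by_index(bn_family(net_b, v), net_a$idx))
  list(queries = queries, map_a = map_a, map_b = map_b)
}

# scopes are canonicalized against the planning network's variable order
sort_by_index <- function(vars, idx) vars[order(idx[vars])]

#' Plan all marginal queries symbolically
#'
#' First stage of the cached engine.  Every query is processed by variable
#' elimination over its ancestrally relevant CPTs, but operations are only
#' planned: a symbolic combination or marginalization records scopes, never
#' tables.  Two repositories are kept — potentials (with a time stamp, the
#' id of the last operation needing each entry; -1 protects query results)
#' and operations (registers `(id, type, arg1, arg2, result)`).  A planned
#' operation requested again is a cache hit: no new register, only time
#' updates.  The planner clock increments after every conditional call, hit
#' or miss, and register ids equal the clock at creation, so ids may skip
#' values.
#'
#' @param net a `bn` object (the reference distribution).
#' @param queries list of character vectors, the marginal scopes to compute.
#' @param order elimination-order heuristic: `"min_weight"` or a function
#'   with the signature of [min_weight_order()].
#' @return an object of class `bn_plan`; see [execute_plan()].
#' @export
plan_marginals <- function(net, queries, order = "min_weight") {
  order_fun <- elim_order_fun(order)
  queries <- lapply(queries, function(q) {
    q <- as.character(q)
    if (!all(q %in% net$vars))
      stop(sprintf("unknown query variable(s): %s",
                   paste(setdiff(q, net$vars), collapse = ", ")))
    sort_by_index(q, net$idx)
  })
  card <- vapply(net$states, length, integer(1))

  st <- new.env(parent = emptyenv())
  st$entries <- lapply(net$vars, function(v)
    list(vars = bn_family(net, v), time = 0L))
  st$cpt_id <- stats::setNames(seq_along(net$vars), net$vars)
  st$ops <- list()
  st$op_key <- new.env(parent = emptyenv())
  st$t <- 1L
  st$calls <- 0L
  st$hits <- 0L
  st$hit_log <- list()
  st$k <- 0L

  update_time <- function(id, t) {
    if (st$entries[[id]]$time != -1L) st$entries[[id]]$time <- t
  }
  new_entry <- function(vars, t) {
    st$entries[[length(st$entries) + 1L]] <- list(vars = vars, time = t)
    length(st$entries)
  }
  cond_call <- function(key, mk_entry, reg) {
    st$calls <- st$calls + 1L
    t <- st$t
    hit <- get0(key, envir = st$op_key)
    if (!is.null(hit)) {
      st$hits <- st$hits + 1L
      op <- st$ops[[hit]]
      update_time(op$arg1, t)
      if (op$type == "comb") update_time(op$arg2, t)
      update_time(op$result, t)
      st$hit_log[[length(st$hit_log) + 1L]] <-
        list(t = t, k = st$k, op_id = op$id, created_k = op$k)
      res <- op$result
    } else {
      res <- mk_entry(t)
      reg$id <- t
      reg$result <- res
      reg$k <- st$k
      st$ops[[length(st$ops) + 1L]] <- reg
      assign(key, length(st$ops), envir = st$op_key)
    }
    st$t <- t + 1L
    res
  }
  cond_scombine <- function(id1, id2) {
    cond_call(paste0("C\r", id1, "\r", id2),
              mk_entry = function(t) {
                update_time(id1, t); update_time(id2, t)
                new_entry(sort_by_index(
                  union(st$entries[[id1]]$vars, st$entries[[id2]]$vars),
                  net$idx), t)
              },
              reg = list(type = "comb", arg1 = id1, arg2 = id2))
  }
  cond_smarginalize <- function(id, var) {
    cond_call(paste0("M\r", id, "\r", var),
              mk_entry = function(t) {
                update_time(id, t)
                new_entry(setdiff(st$entries[[id]]$vars, var), t)
              },
              reg = list(type = "marg", arg1 = id, arg2 = var))
  }

  lr <- integer(length(queries))
  for (k in seq_along(queries)) {
    st$k <- k
    y <- queries[[k]]
    rel <- relevant_cpts(net, y)
    cur <- sort(unname(st$cpt_id[rel]))
    scopes <- lapply(st$entries[cur], `[[`, "vars")
    elim <- setdiff(unique(unlist(scopes, use.names = FALSE)), y)
    if (length(elim)) {
      eo <- order_fun(scopes, elim, card, net$idx)
      for (xi in eo) {
        phi_i <- cur[vapply(cur, function(id)
          xi %in% st$entries[[id]]$vars, logical(1))]
        psi <- phi_i[[1L]]
        for (id in phi_i[-1L]) psi <- cond_scombine(psi, id)
        psi <- cond_smarginalize(psi, xi)
        cur <- sort(c(setdiff(cur, phi_i), psi))
      }
    }
    psi_k <- cur[[1L]]
    for (id in cur[-1L]) psi_k <- cond_scombine(psi_k, id)
    lr[[k]] <- psi_k
    st$entries[[psi_k]]$time <- -1L
  }

  structure(list(net = net, queries = queries,
                 entries = st$entries, ops = st$ops, lr = lr,
                 calls = st$calls, hits = st$hits, hit_log = st$hit_log,
                 cpt_id = st$cpt_id),
            class = "bn_plan")
}

#' Execute a symbolic plan numerically
#'
#' Second stage of the cached engine: registers are executed in id order,
#' each exactly once; after a register with id t completes, every
#' unprotected repository entry whose time stamp has expired (time <= t) is
#' deleted.  Entries whose stamp was set by a cache hit after the last
#' register are swept at the end, so every potential an operation touched is
#' eventually reclaimed; the surviving repository holds the protected
#' (time -1) query results plus any inputs the plan never used.
#'
#' @param plan a `bn_plan` from [plan_marginals()].
#' @return an object of class `bn_plan_result`: `marginals` (one potential
#'   per query, in query order), `stats` (`ops`, `rep`, `del`, `calls`,
#'   `exec_ops`), and `repository` (the surviving entries).
#' @export
execute_plan <- function(plan) {
  net <- plan$net
  n <- length(net$vars)
  values <- vector("list", length(plan$entries))
  for (v in net$vars) values[[plan$cpt_id[[v]]]] <- net$cpts[[v]]
  alive <- rep.int(TRUE, length(plan$entries))
  del <- 0L
  exec_ops <- 0L
  for (op in plan$ops) {
    a1 <- values[[op$arg1]]
    if (is.null(a1) || !alive[[op$arg1]])
      stop("planning bug: register argument missing from the repository")
    if (op$type == "comb") {
      if (is.null(values[[op$arg2]]) || !alive[[op$arg2]])
        stop("planning bug: register argument missing from the repository")
      res <- pot_multiply(a1, values[[op$arg2]])
    } else {
      res <- pot_sum_out(a1, op$arg2)
    }
    if (!identical(res$vars, plan$entries[[op$result]]$vars))
      stop("planning bug: executed scope differs from the planned scope")
    values[[op$result]] <- res
    exec_ops <- exec_ops + 1L
    expired <- which(alive &
                     vapply(plan$entries, function(e)
                       e$time != -1L && e$time <= op$id, logical(1)) &
                     !vapply(values, is.null, logical(1)))
    for (i in expired) { alive[[i]] <- FALSE; values[i] <- list(NULL) }
    del <- del + length(expired)
  }
  marginals <- lapply(plan$lr, function(id) values[[id]])
  # entries whose stamp was set by a trailing cache hit (a clock value past
  # the last register) expire now; untouched inputs (time 0) are left alone
  stale <- which(alive & vapply(plan$entries, function(e)
    e$time > 0L, logical(1)))
  for (i in stale) { alive[[i]] <- FALSE; values[i] <- list(NULL) }
  del <- del + length(stale)
  repository <- lapply(which(alive), function(i)
    list(id = i, vars = plan$entries[[i]]$vars,
         time = plan$entries[[i]]$time))
  structure(list(marginals = marginals,
                 stats = list(ops = length(plan$ops), rep = plan$hits,
                              del = del, calls = plan$calls,
                              exec_ops = exec_ops),
                 repository = repository),
            class = "bn_plan_result")
}

#' Operation counters of a plan
#'
#' `ops` is the number of registers in the operation repository, `rep` the
#' number of conditional calls answered from the cache, and `del` (executed
#' plans only) the number of potentials reclaimed during execution.
#'
#' @param x a `bn_plan` or `bn_plan_result`.
#' @return list with `ops`, `rep`, `calls`, and `del` (`NA` for an
#'   unexecuted plan).
#' @export
plan_stats <- function(x) {
  if (inherits(x, "bn_plan_result"))
    return(x$stats[c("ops", "rep", "calls", "del")])
  if (inherits(x, "bn_plan"))
    return(list(ops = length(x$ops), rep = x$hits, calls = x$calls,
                del = NA_integer_))
  stop("not a plan")
}

#' @export
print.bn_plan <- function(x, ...) {
  cat(sprintf("<marginal plan> %d queries, %d registers, %d cache hits\n",
              length(x$queries), length(x$ops), x$hits))
  cat("Potential repository:\n")
  for (i in seq_along(x$entries)) {
    e <- x$entries[[i]]
    cat(sprintf("  %3d  {%s}  time %d\n", i,
                paste(e$vars, collapse = ","), e$time))
  }
  cat("Operation repository:\n")
  for (op in x$ops)
    cat(sprintf("  %3d  %s  %s  %s  -> %d\n", op$id,
                if (op$type == "comb") "Comb" else "Marg",
                format(op$arg1), format(op$arg2), op$result))
  invisible(x)
}

#' Export a plan's repositories
#'
#' A plain-list dump of the potential and operation repositories (ids,
#' scopes, times, register arguments), suitable for
#' `jsonlite::toJSON()` and for asserting planner traces in tests.
#'
#' @param plan a `bn_plan`.
#' @return list with `potentials` and `operations` data.frames.
#' @export
plan_export <- function(plan) {
  pot <- data.frame(
    id = seq_along(plan$entries),
    scope = vapply(plan$entries, function(e)
      paste(e$vars, collapse = ","), character(1)),
    time = vapply(plan$entries, `[[`, integer(1), "time"))
  ops <- data.frame(
    id = vapply(plan$ops, `[[`, integer(1), "id"),
    type = vapply(plan$ops, `[[`, character(1), "type"),
    arg1 = vapply(plan$ops, function(o) format(o$arg1), character(1)),
    arg2 = vapply(plan$ops, function(o) format(o$arg2), character(1)),
    result = vapply(plan$ops, `[[`, integer(1), "result"),
    query = vapply(plan$ops, `[[`, integer(1), "k"))
  list(potentials = pot, operations = ops)
}
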