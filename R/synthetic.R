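# run code under a local RNG state; leaves the caller's stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random Bayesian network
#'
#' Samples a random DAG by drawing, for each variable along a random
#' topological order, up to `max_parents` parents among its predecessors,
#' and fills every CPT column with a symmetric Dirichlet(`alpha`) draw.
#' Reproducible from `seed`.
#'
#' The defaults (8 binary variables, at most 3 parents, Dirichlet(1) — i.e.
#' uniform on the simplex) give small but structurally varied networks whose
#' exact joint is cheap to enumerate, the regime used throughout the test
#' suite as an oracle.
#'
#' @param n_vars number of variables (named `X1 ... Xn`).
#' @param max_parents maximum number of parents per variable.
#' @param card integer pair, inclusive range of variable cardinalities.
#' @param alpha Dirichlet concentration for CPT columns.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a `bn` object.
#' @export
random_bn <- function(n_vars = 8, max_parents = 3, card = c(2, 2),
                      alpha = 1, seed = NULL) {
  stopifnot(n_vars >= 1, max_parents < n_vars, all(card >= 2))
  with_seed(seed, {
    vars <- paste0("X", seq_len(n_vars))
    cards <- if (card[1] == card[2]) rep.int(card[1], n_vars)
             else sample(card[1]:card[2], n_vars, replace = TRUE)
    states <- stats::setNames(
      lapply(cards, function(k) paste0("s", seq_len(k))), vars)
    topo <- sample(vars)
    parents <- stats::setNames(vector("list", n_vars), vars)
    for (j in seq_along(topo)) {
      avail <- topo[seq_len(j - 1L)]
      k <- if (length(avail)) sample.int(min(max_parents, length(avail)) + 1L,
                                         1L) - 1L else 0L
      parents[[topo[[j]]]] <-
        if (k > 0L) sample(avail, k) else character()
    }
    cpts <- stats::setNames(lapply(vars, function(v)
      rdirichlet_cpt(states, v, parents[[v]], alpha)), vars)
    bayesian_network(states, parents, cpts)
  })
}

# CPT array over (v, parents), child varying fastest; one Dirichlet draw per
# parent configuration
rdirichlet_cpt <- function(states, v, pa, alpha) {
  nc <- length(states[[v]])
  ncfg <- prod(vapply(states[pa], length, integer(1)))
  g <- matrix(stats::rgamma(nc * ncfg, shape = alpha), nrow = nc)
  as.numeric(sweep(g, 2, colSums(g), `/`))
}

#' Randomly perturb a network's structure
#'
#' Applies `n_edge_moves` random structural moves (arc addition, removal, or
#' reversal), each chosen uniformly among the feasible moves that keep the
#' graph acyclic and within `max_parents`.  CPTs of families changed by a
#' move are re-sampled from Dirichlet(`alpha`); all other CPTs are kept.
#' This emulates the role of a structure-learned second network when
#' evaluating divergence from a reference model.
#'
#' @param net a `bn` object.
#' @param n_edge_moves number of moves; 0 returns the network unchanged.
#' @param seed integer seed, or `NULL`.
#' @param alpha Dirichlet concentration for re-sampled CPTs.
#' @param max_parents cap on parents per variable after a move.
#' @return a `bn` object on the same variables and state spaces.
#' @export
perturb_bn <- function(net, n_edge_moves, seed = NULL, alpha = 1,
                       max_parents = 3) {
  stopifnot(n_edge_moves >= 0)
  if (n_edge_moves == 0) return(net)
  with_seed(seed, {
    parents <- net$parents
    changed <- character()
    reachable <- function(from, to) {
      # TRUE if `to` is an ancestor of `from` (or equal)
      frontier <- from
      seen <- character()
      while (length(frontier)) {
        if (to %in% frontier) return(TRUE)
        seen <- union(seen, frontier)
        frontier <- setdiff(
          unique(unlist(parents[frontier], use.names = FALSE)), seen)
      }
      FALSE
    }
    arcs <- function() {
      do.call(rbind, lapply(net$vars, function(v)
        if (length(parents[[v]]))
          data.frame(from = parents[[v]], to = v) else NULL))
    }
    for (m in seq_len(n_edge_moves)) {
      cand <- list()
      for (u in net$vars) for (v in net$vars) {
        if (u == v || u %in% parents[[v]]) next
        # u -> v is addable if it creates no cycle (u must not descend from v)
        if (length(parents[[v]]) < max_parents && !reachable(u, v))
          cand[[length(cand) + 1L]] <- list(op = "add", from = u, to = v)
      }
      ar <- arcs()
      if (!is.null(ar)) for (r in seq_len(nrow(ar))) {
        u <- ar$from[[r]]; v <- ar$to[[r]]
        cand[[length(cand) + 1L]] <- list(op = "remove", from = u, to = v)
        parents[[v]] <- setdiff(parents[[v]], u)
        rev_ok <- length(parents[[u]]) < max_parents && !reachable(v, u)
        parents[[v]] <- c(parents[[v]], u)
        if (rev_ok)
          cand[[length(cand) + 1L]] <- list(op = "reverse", from = u, to = v)
      }
      if (!length(cand)) break
      mv <- cand[[sample.int(length(cand), 1L)]]
      if (mv$op == "add") {
        parents[[mv$to]] <- c(parents[[mv$to]], mv$from)
        changed <- union(changed, mv$to)
      } else if (mv$op == "remove") {
        parents[[mv$to]] <- setdiff(parents[[mv$to]], mv$from)
        changed <- union(changed, mv$to)
      } else {
        parents[[mv$to]] <- setdiff(parents[[mv$to]], mv$from)
        parents[[mv$from]] <- c(parents[[mv$from]], mv$to)
        changed <- union(changed, c(mv$from, mv$to))
      }
    }
    cpts <- net$cpts
    for (v in changed)
      cpts[[v]] <- rdirichlet_cpt(net$states, v, parents[[v]], alpha)
    bayesian_network(net$states, parents, cpts)
  })
}

#' Forward (ancestral) sampling
#'
#' Draws `n` joint samples by visiting variables in a topological order and
#' sampling each from its CPT given the already-sampled parents.
#'
#' @param net a `bn` object.
#' @param n number of rows.
#' @param seed integer seed, or `NULL`.
#' @return a data.frame with one character column per variable (declaration
#'   order), `n` rows.
#' @export
bn_sample <- function(net, n, seed = NULL) {
  stopifnot(n >= 0)
  topo <- topological_order(net$vars, net$parents)
  with_seed(seed, {
    cards <- vapply(net$states, length, integer(1))
    x <- matrix(NA_integer_, nrow = n, ncol = length(net$vars),
                dimnames = list(NULL, net$vars))
    for (v in topo) {
      pa <- net$parents[[v]]
      fam <- bn_family(net, v)
      nc <- cards[[v]]
      # probability matrix: states of v x parent configurations
      grid <- config_grid(cards[pa])
      pm <- matrix(NA_real_, nrow = nc, ncol = nrow(grid))
      for (r in seq_len(nrow(grid))) {
        cfg <- stats::setNames(as.integer(grid[r, ]), pa)
        row <- pot_restrict(net$cpts[[v]], cfg)
        pm[, r] <- vapply(seq_len(nc), function(k)
          pot_value(row, stats::setNames(k, v)), numeric(1))
      }
      if (n > 0) {
        if (length(pa)) {
          stride <- cumprod(c(1L, cards[pa]))[seq_along(pa)]
          cfg_idx <- 1L + as.integer(
            (x[, pa, drop = FALSE] - 1L) %*% stride)
        } else cfg_idx <- rep.int(1L, n)
        cs <- matrix(apply(pm, 2L, cumsum), nrow = nc)
        u <- stats::runif(n)
        th <- cs[, cfg_idx, drop = FALSE]
        x[, v] <- colSums(th < rep(u, each = nc)) + 1L
      }
    }
    out <- as.data.frame(lapply(net$vars, function(v)
      net$states[[v]][x[, v]]), stringsAsFactors = FALSE,
      col.names = net$vars)
    if (n == 0)
      out <- stats::setNames(
        as.data.frame(lapply(net$vars, function(v) character())), net$vars)
    out
  })
}
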