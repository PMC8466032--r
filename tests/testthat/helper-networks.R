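# shared fixture builders (all constructed in code)

binary_states <- function(vars)
  stats::setNames(rep(list(c("0", "1")), length(vars)), vars)

# the three-variable chain X1 -> X2 -> X3
chain3 <- function() {
  bayesian_network(
    binary_states(c("X1", "X2", "X3")),
    parents = list(X2 = "X1", X3 = "X2"),
    cpts = list(X1 = c(0.4, 0.6),
                X2 = c(0.7, 0.3, 0.2, 0.8),
                X3 = c(0.5, 0.5, 0.1, 0.9)))
}

# the worked-example pair: net a has X1 -> X2 and X1 -> X3,
# net b is the chain X1 -> X2 -> X3
fig_pair <- function() {
  st <- binary_states(c("X1", "X2", "X3"))
  list(
    a = bayesian_network(st, list(X2 = "X1", X3 = "X1"),
          cpts = list(X1 = c(0.3, 0.7),
                      X2 = c(0.2, 0.8, 0.6, 0.4),
                      X3 = c(0.5, 0.5, 0.9, 0.1))),
    b = bayesian_network(st, list(X2 = "X1", X3 = "X2"),
          cpts = list(X1 = c(0.4, 0.6),
                      X2 = c(0.1, 0.9, 0.7, 0.3),
                      X3 = c(0.8, 0.2, 0.25, 0.75))))
}

# a seeded random reference/perturbed pair at oracle scale
random_pair <- function(seed, n_vars = 8, max_parents = 3, edge_moves = 3) {
  a <- random_bn(n_vars, max_parents = max_parents, card = c(2, 2),
                 alpha = 1, seed = seed)
  b <- perturb_bn(a, edge_moves, seed = seed + 10000L,
                  max_parents = max_parents)
  list(a = a, b = b)
}

# random potential on the given variables (for algebra property tests)
random_potential <- function(vars, card = 2, idx = NULL) {
  states <- stats::setNames(
    lapply(rep_len(card, length(vars)), function(k) paste0("s", seq_len(k))),
    vars)
  n <- prod(rep_len(card, length(vars)))
  potential(stats::runif(max(n, 1)), vars, states, idx = idx)
}

# independent nested-loop product over all joint configurations
brute_multiply <- function(a, b) {
  uvars <- union(a$vars, b$vars)
  uidx <- c(a$idx, b$idx[setdiff(b$vars, a$vars)])[uvars]
  uvars <- uvars[order(uidx)]
  states <- c(a$states, b$states)[uvars]
  card <- vapply(states, length, integer(1))
  grid <- config_grid(card)
  vals <- vapply(seq_len(nrow(grid)), function(r) {
    cfg <- stats::setNames(as.integer(grid[r, ]), uvars)
    va <- if (length(a$vars)) pot_value(a, cfg[a$vars]) else a$values
    vb <- if (length(b$vars)) pot_value(b, cfg[b$vars]) else b$values
    va * vb
  }, numeric(1))
  list(vars = uvars, values = vals)
}
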