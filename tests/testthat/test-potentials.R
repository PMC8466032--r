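test_that("configuration projection restricts to the requested scope", {
  x <- c(X2 = 1L, X1 = 1L)
  expect_identical(config_project(x, "X2"), c(X2 = 1L))
  expect_identical(config_project(x, c("X2", "X1")), x)
  expect_identical(config_project(x, character()),
                   stats::setNames(integer(), character()))
  expect_error(config_project(x, "X9"), "subset")
})

test_that("multiplication matches a nested-loop product on random scopes", {
  set.seed(101)
  cases <- list(
    list(a = c("X1", "X2"), b = c("X2", "X3")),
    list(a = c("X1"), b = c("X2", "X3")),
    list(a = c("X2", "X3"), b = c("X2", "X3")),
    list(a = c("X3", "X1"), b = c("X2")))
  idx <- c(X1 = 1L, X2 = 2L, X3 = 3L)
  for (cs in cases) {
    a <- random_potential(cs$a, idx = idx[cs$a])
    b <- random_potential(cs$b, idx = idx[cs$b])
    got <- pot_multiply(a, b)
    want <- brute_multiply(a, b)
    expect_identical(got$vars, want$vars)
    expect_equal(as.numeric(got$values), want$values, tolerance = 1e-12)
  }
})

test_that("scope of a product is the union scope, in canonical order", {
  idx <- c(X1 = 1L, X2 = 2L, X3 = 3L)
  p2 <- random_potential(c("X2", "X1"), idx = idx[c("X2", "X1")])
  p3 <- random_potential(c("X3", "X2"), idx = idx[c("X3", "X2")])
  expect_identical(pot_multiply(p2, p3)$vars, c("X1", "X2", "X3"))
})

test_that("multiplying by the empty-scope unit leaves values unchanged", {
  p <- random_potential(c("X1", "X2"))
  unit <- potential(1)
  expect_equal(pot_multiply(p, unit)$values, p$values)
  expect_equal(pot_multiply(unit, p)$values, p$values)
})

test_that("multiplication is commutative and associative", {
  set.seed(7)
  idx <- c(X1 = 1L, X2 = 2L, X3 = 3L, X4 = 4L)
  for (rep in 1:5) {
    a <- random_potential(c("X1", "X2"), idx = idx[c("X1", "X2")])
    b <- random_potential(c("X2", "X3"), idx = idx[c("X2", "X3")])
    d <- random_potential(c("X3", "X4"), idx = idx[c("X3", "X4")])
    ab <- pot_multiply(a, b)
    ba <- pot_multiply(b, a)
    expect_identical(ab$vars, ba$vars)
    expect_equal(ab$values, ba$values, tolerance = 1e-12)
    l <- pot_multiply(pot_multiply(a, b), d)
    r <- pot_multiply(a, pot_multiply(b, d))
    expect_equal(l$values, r$values, tolerance = 1e-12)
  }
})

test_that("multiplication rejects mismatched shared state spaces", {
  a <- potential(c(1, 2), "X1", list(X1 = c("a", "b")))
  b <- potential(c(1, 2, 3), "X1", list(X1 = c("a", "b", "c")))
  expect_error(pot_multiply(a, b), "mismatched state spaces")
})

test_that("summing a variable out of a CPT column gives all ones", {
  net <- chain3()
  out <- pot_sum_out(net$cpts[["X3"]], "X3")
  expect_identical(out$vars, "X2")
  expect_equal(as.numeric(out$values), c(1, 1))
})

test_that("sum_out conserves total mass and matches enumeration", {
  set.seed(33)
  p <- random_potential(c("X1", "X2", "X3"), card = 3)
  for (v in p$vars) {
    out <- pot_sum_out(p, v)
    expect_equal(sum(out$values), sum(p$values), tolerance = 1e-12)
    # explicit enumeration over the kept configurations
    keep <- setdiff(p$vars, v)
    grid <- config_grid(vapply(p$states[keep], length, integer(1)))
    want <- vapply(seq_len(nrow(grid)), function(r) {
      cfg <- stats::setNames(as.integer(grid[r, ]), keep)
      s <- 0
      for (k in seq_along(p$states[[v]]))
        s <- s + pot_value(p, c(cfg, stats::setNames(k, v)))
      s
    }, numeric(1))
    expect_equal(as.numeric(out$values), want, tolerance = 1e-12)
  }
  expect_error(pot_sum_out(p, "X9"), "not in scope")
})

test_that("marginalization is removal-order invariant and handles identities", {
  set.seed(12)
  p <- random_potential(c("X1", "X2", "X3", "X4"))
  m1 <- pot_marginalize(p, c("X2", "X4"))
  # different removal order by hand
  m2 <- pot_sum_out(pot_sum_out(p, "X3"), "X1")
  expect_identical(m1$vars, m2$vars)
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
  expect_equal(pot_marginalize(p, p$vars)$values, p$values)
  empty <- pot_marginalize(p, character())
  expect_length(empty$vars, 0)
  expect_equal(as.numeric(empty$values), sum(p$values), tolerance = 1e-12)
  expect_error(pot_marginalize(p, "X9"), "subset")
})

test_that("selection slices the table and ignores foreign variables", {
  net <- chain3()
  p3 <- net$cpts[["X3"]]  # scope {X2, X3}
  z <- c(X1 = 1L, X2 = 2L)
  sel <- pot_restrict(p3, z)
  expect_identical(sel$vars, "X3")
  expect_equal(
    as.numeric(sel$values),
    vapply(1:2, function(k) pot_value(p3, c(X2 = 2L, X3 = k)), numeric(1)))
  # disjoint configuration: unchanged
  expect_identical(pot_restrict(p3, c(X9 = 1L)), p3)
  expect_error(pot_restrict(p3, c(X2 = 5L)), "out of range")
})

test_that("restriction distributes over multiplication", {
  set.seed(9)
  idx <- c(X1 = 1L, X2 = 2L, X3 = 3L)
  for (rep in 1:5) {
    a <- random_potential(c("X1", "X2"), idx = idx[c("X1", "X2")])
    b <- random_potential(c("X2", "X3"), idx = idx[c("X2", "X3")])
    z <- c(X2 = sample(1:2, 1))
    l <- pot_restrict(pot_multiply(a, b), z)
    r <- pot_multiply(pot_restrict(a, z), pot_restrict(b, z))
    expect_identical(l$vars, r$vars)
    expect_equal(l$values, r$values, tolerance = 1e-12)
  }
})

test_that("restrict-then-sum equals a slice sum by enumeration", {
  set.seed(4)
  p <- random_potential(c("X1", "X2", "X3"))
  z <- c(X2 = 2L)
  sliced <- pot_restrict(p, z)
  total <- pot_marginalize(sliced, character())
  grid <- config_grid(c(2L, 2L))
  want <- sum(vapply(seq_len(nrow(grid)), function(r)
    pot_value(p, c(X1 = grid[r, 1], X2 = 2L, X3 = grid[r, 2])),
    numeric(1)))
  expect_equal(as.numeric(total$values), want, tolerance = 1e-12)
})

test_that("potentials reject malformed tables", {
  expect_error(potential(c(1, 2, 3), "X1", list(X1 = c("a", "b"))),
               "entries")
  expect_error(potential(c(1, -2), "X1", list(X1 = c("a", "b"))),
               "nonnegative")
  expect_error(potential(c(1, NaN), "X1", list(X1 = c("a", "b"))),
               "finite")
})
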