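test_that("the query set is both networks' families, deduplicated in order", {
  pr <- fig_pair()
  fq <- family_query_set(pr$a, pr$b)
  expect_identical(fq$queries,
                   list("X1", c("X1", "X2"), c("X1", "X3"), c("X2", "X3")))
  expect_identical(unname(fq$map_a), c(1L, 2L, 3L))
  expect_identical(unname(fq$map_b), c(1L, 2L, 4L))
  # identical networks: at most one query per variable
  fq2 <- family_query_set(pr$a, pr$a)
  expect_lte(length(fq2$queries), length(pr$a$vars))
  # every family of either network appears exactly once
  for (seed in 1:5) {
    pr <- random_pair(seed + 700)
    fq <- family_query_set(pr$a, pr$b)
    keys <- vapply(fq$queries, paste, character(1), collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    for (v in pr$a$vars) {
      expect_identical(fq$queries[[fq$map_a[[v]]]], bn_family(pr$a, v))
      expect_setequal(fq$queries[[fq$map_b[[v]]]], bn_family(pr$b, v))
    }
  }
})

test_that("the worked-example plan reproduces the printed repository trace", {
  pr <- fig_pair()
  fq <- family_query_set(pr$a, pr$b)
  plan <- plan_marginals(pr$a, fq$queries)
  ops <- plan_export(plan)$operations

  # after the second query the repository holds exactly one register:
  # the combination of CPT 1 and CPT 2, with id 1
  upto_k2 <- ops[ops$query <= 2, ]
  expect_identical(nrow(upto_k2), 1L)
  expect_identical(upto_k2$id, 1L)
  expect_identical(upto_k2$type, "comb")
  expect_identical(upto_k2$arg1, "1")
  expect_identical(upto_k2$arg2, "2")

  # the combination of CPT 1 and CPT 3 is planned during the third query
  # with id 2
  comb13 <- ops[ops$type == "comb" & ops$arg1 == "1" & ops$arg2 == "3", ]
  expect_identical(comb13$id, 2L)
  expect_identical(comb13$query, 3L)

  # the final marginalization removing X1 carries id 5 under the
  # hit-inclusive planner clock
  marg <- ops[ops$type == "marg", ]
  expect_identical(nrow(marg), 1L)
  expect_identical(marg$id, 5L)
  expect_identical(marg$arg2, "X1")

  # planning the fourth query reuses the combination created at the second
  expect_length(plan$hit_log, 1)
  expect_identical(plan$hit_log[[1]]$k, 4L)
  expect_identical(plan$hit_log[[1]]$created_k, 2L)
  expect_identical(plan$hit_log[[1]]$op_id, 1L)

  # no duplicate register for a repeated operation
  keys <- with(ops, paste(type, arg1, arg2))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("a single-CPT query plans no operations", {
  pr <- fig_pair()
  plan <- plan_marginals(pr$a, list("X1"))
  expect_length(plan$ops, 0)
  expect_identical(plan_stats(plan)$ops, 0L)
  ex <- execute_plan(plan)
  expect_equal(ex$marginals[[1]]$values, pr$a$cpts[["X1"]]$values)
  expect_identical(plan_stats(ex)[c("ops", "rep", "del")],
                   list(ops = 0L, rep = 0L, del = 0L))
})

test_that("executed marginals equal joint-oracle marginals and sum to one", {
  for (seed in 1:10) {
    pr <- random_pair(seed + 800, n_vars = sample(6:10, 1))
    fq <- family_query_set(pr$a, pr$b)
    plan <- plan_marginals(pr$a, fq$queries)
    ex <- execute_plan(plan)
    j <- bn_joint(pr$a)
    for (k in seq_along(fq$queries)) {
      got <- ex$marginals[[k]]
      want <- pot_marginalize(j, fq$queries[[k]])
      expect_identical(got$vars, want$vars)
      expect_equal(got$values, want$values, tolerance = 1e-9)
      expect_equal(sum(got$values), 1, tolerance = 1e-9)
    }
  }
})

test_that("cache accounting and the memory contract hold", {
  for (seed in 1:10) {
    pr <- random_pair(seed + 900)
    fq <- family_query_set(pr$a, pr$b)
    plan <- plan_marginals(pr$a, fq$queries)
    ex <- execute_plan(plan)
    s <- ex$stats
    # every conditional call is either a new register or a cache hit
    expect_identical(s$calls, s$ops + s$rep)
    # each register is computed exactly once
    expect_identical(s$exec_ops, s$ops)
    # with the cache, executed numeric operations are strictly fewer than
    # conditional calls whenever something was reused
    if (s$rep > 0) expect_lt(s$exec_ops, s$calls)
    # after execution only protected entries survive: the query results
    expect_true(all(vapply(ex$repository, function(e) e$time == -1L,
                           logical(1))))
    expect_true(all(plan$lr %in% vapply(ex$repository, `[[`, integer(1),
                                        "id")))
  }
})

test_that("cache soundness: recomputing a register reproduces its table", {
  pr <- random_pair(321)
  fq <- family_query_set(pr$a, pr$b)
  plan <- plan_marginals(pr$a, fq$queries)
  # replay all registers independently with the core algebra, keeping every
  # intermediate table
  vals <- vector("list", length(plan$entries))
  for (v in pr$a$vars) vals[[plan$cpt_id[[v]]]] <- pr$a$cpts[[v]]
  for (op in plan$ops) {
    res <- if (op$type == "comb")
      pot_multiply(vals[[op$arg1]], vals[[op$arg2]])
    else pot_sum_out(vals[[op$arg1]], op$arg2)
    expect_identical(res$vars, plan$entries[[op$result]]$vars)
    vals[[op$result]] <- res
  }
  ex <- execute_plan(plan)
  for (k in seq_along(plan$lr))
    expect_equal(ex$marginals[[k]]$values, vals[[plan$lr[[k]]]]$values,
                 tolerance = 0)
})

test_that("duplicated family structures produce cache hits", {
  # identical networks share every family, so each family marginal is
  # planned once and the duplicate queries are collapsed; a tree with
  # overlapping families still reuses sub-plans across queries
  net <- chain3()
  fq <- family_query_set(net, net)
  expect_identical(length(fq$queries), 3L)
  pr <- fig_pair()
  plan <- plan_marginals(pr$a, family_query_set(pr$a, pr$b)$queries)
  expect_gt(plan$hits, 0)
})

test_that("plans refuse unknown query variables", {
  net <- chain3()
  expect_error(plan_marginals(net, list(c("X1", "X9"))), "unknown query")
})
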