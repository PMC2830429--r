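test_that("annealing finds a one-dimensional convex optimum", {
  b <- tibble::tibble(param = "x", lower = 0, upper = 1)
  evals <- sa_search(function(p) (p[["x"]] - 0.3)^2, b,
                     sa_config(n_iterations = 2000, seed = 11))
  expect_equal(nrow(evals), 2000L)
  best <- evals[attr(evals, "best"), ]
  expect_lt(abs(best$x - 0.3), 0.02)
  # the running best never worsens
  expect_true(all(diff(cummin(evals$score)) <= 0))
})

test_that("the search honours its determinism and edge-case contracts", {
  b <- tibble::tibble(param = c("x", "y"), lower = c(0, 0), upper = c(1, 1))
  f <- function(p) (p[["x"]] - 0.5)^2 + (p[["y"]] - 0.2)^2
  e1 <- sa_search(f, b, sa_config(n_iterations = 500, seed = 4))
  e2 <- sa_search(f, b, sa_config(n_iterations = 500, seed = 4))
  expect_identical(e1$score, e2$score)
  expect_identical(e1$x, e2$x)
  expect_identical(min(e1$score), min(e2$score))

  # a single iteration is just the recorded initial random draw
  e3 <- sa_search(f, b, sa_config(n_iterations = 1, seed = 4))
  expect_equal(nrow(e3), 1L)

  # frozen (zero-width) parameters never move
  bf <- tibble::tibble(param = c("x", "y"), lower = c(0, 0.4),
                       upper = c(1, 0.4))
  e4 <- sa_search(f, bf, sa_config(n_iterations = 200, seed = 4))
  expect_true(all(e4$y == 0.4))

  # non-finite objective aborts and names the offending vector
  expect_error(
    sa_search(function(p) NaN, b, sa_config(n_iterations = 10, seed = 1)),
    "non-finite"
  )
})

test_that("zero temperature reduces to stochastic hill-descent", {
  b <- tibble::tibble(param = "x", lower = 0, upper = 1)
  evals <- sa_search(
    function(p) (p[["x"]] - 0.7)^2, b,
    sa_config(n_iterations = 800, seed = 2, initial_temperature = 0,
              restarts = 1, jump_prob = 0)
  )
  # the accepted scores must never increase
  acc <- evals$score[evals$accepted]
  expect_true(all(diff(acc) <= 0))
  expect_true(any(!evals$accepted))       # some proposals were rejected
})

test_that("bound narrowing keeps the best fraction's envelope", {
  # hand-constructed ranking: value 0.1 .. 1.0, GOF ascending with value
  ev <- tibble::tibble(iteration = 1:10, x = seq(0.1, 1, by = 0.1),
                       score = seq(0.1, 1, by = 0.1))
  nb <- narrow_bounds(ev, keep_fraction = 0.2, param_names = "x")
  expect_equal(nb$lower, 0.1)
  expect_equal(nb$upper, 0.2)

  # keep everything -> envelope of all evaluations; idempotent on itself
  nb_all <- narrow_bounds(ev, keep_fraction = 1, param_names = "x")
  expect_equal(c(nb_all$lower, nb_all$upper), c(0.1, 1.0))
  ev_kept <- ev[ev$x >= nb_all$lower & ev$x <= nb_all$upper, ]
  expect_equal(narrow_bounds(ev_kept, 1, param_names = "x"), nb_all)

  # identical kept sets give degenerate zero-width bounds
  ev_same <- tibble::tibble(iteration = 1:5, x = rep(0.4, 5), score = 1:5)
  nb_same <- narrow_bounds(ev_same, keep_fraction = 0.4, param_names = "x")
  expect_equal(nb_same$lower, nb_same$upper)

  # narrowed bounds nest within the original bounds
  b <- tibble::tibble(param = "x", lower = 0, upper = 1)
  evals <- sa_search(function(p) (p[["x"]] - 0.5)^2, b,
                     sa_config(n_iterations = 300, seed = 8))
  nb2 <- narrow_bounds(evals, 0.1)
  expect_gte(nb2$lower, 0)
  expect_lte(nb2$upper, 1)
  expect_error(narrow_bounds(ev[0, ]), "no evaluations")
})

test_that("ties in the kept fraction break by evaluation order", {
  ev <- tibble::tibble(iteration = 1:4, x = c(0.9, 0.1, 0.5, 0.3),
                       score = c(1, 1, 1, 1))
  nb <- narrow_bounds(ev, keep_fraction = 0.5, param_names = "x")
  # earliest two evaluations win: envelope of {0.9, 0.1}
  expect_equal(c(nb$lower, nb$upper), c(0.1, 0.9))
})

test_that("annealing agrees with an independent optimizer on a smooth objective", {
  # cross-check against stats::optim on a 2-d quadratic
  f <- function(p) (p[["a"]] - 0.32)^2 + 2 * (p[["b"]] - 0.64)^2 +
    (p[["a"]] - 0.32) * (p[["b"]] - 0.64)
  b <- tibble::tibble(param = c("a", "b"), lower = c(0, 0), upper = c(1, 1))
  ref <- stats::optim(c(0.5, 0.5), function(x) f(c(a = x[1], b = x[2])),
                      method = "L-BFGS-B", lower = 0, upper = 1)
  evals <- sa_search(f, b, sa_config(n_iterations = 4000, seed = 21))
  best <- evals[attr(evals, "best"), ]
  expect_lt(abs(best$a - ref$par[1]), 0.03)
  expect_lt(abs(best$b - ref$par[2]), 0.03)
})
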