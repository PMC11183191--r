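test_that("basis sets match textbook cases and brute-force counts", {
  chain <- basis_set(sem_spec(c("A -> B", "B -> C")))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$lhs, "A")
  expect_equal(chain$rhs, "C")
  expect_equal(chain$conditioning, "B")

  full <- basis_set(sem_spec(c("A -> B", "A -> C", "B -> C")))
  expect_equal(nrow(full), 0L)

  # claim count equals the number of non-adjacent pairs on random DAGs
  withr::with_seed(20, {
    for (rep in 1:5) {
      vars <- LETTERS[1:5]
      pool <- t(combn(vars, 2))  # i < j: acyclic by construction
      take <- sample(nrow(pool), 5)
      paths <- sprintf("%s -> %s", pool[take, 1], pool[take, 2])
      bs <- basis_set(sem_spec(paths))
      expect_equal(nrow(bs),
                   count_nonadjacent(vars[vars %in% unlist(pool[take, ])],
                                     pool[take, 1], pool[take, 2]))
    }
  })

  # deterministic ordering across repeated calls
  spec <- sem_spec(c("A -> B", "B -> C", "A -> D"))
  expect_identical(basis_set(spec), basis_set(spec))
  expect_error(sem_spec(c("A -> B", "B -> A")), "cyclic")
})

test_that("Fisher's C matches its closed forms", {
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$fisher_c, 4 * log(2), tolerance = 1e-7)
  expect_equal(fc$df, 4L)
  ones <- fishers_c(c(1, 1, 1))
  expect_equal(ones$fisher_c, 0)
  expect_equal(ones$p_value, 1)
  sat <- fishers_c(numeric(0))
  expect_equal(sat$fisher_c, 0)
  expect_equal(sat$p_value, 1)
  expect_error(fishers_c(c(0.2, 0)), "p = 0")

  # independent chi-square tail evaluation
  withr::with_seed(6, p <- runif(7))
  fc2 <- fishers_c(p)
  expect_equal(fc2$p_value,
               1 - pchisq(-2 * sum(log(p)), 2 * length(p)),
               tolerance = 1e-10)

  # additive over disjoint claim sets; monotone in each p
  a <- fishers_c(p[1:3])$fisher_c
  b <- fishers_c(p[4:7])$fisher_c
  expect_equal(a + b, fc2$fisher_c, tolerance = 1e-10)
  p2 <- p
  p2[1] <- p[1] / 2
  expect_gt(fishers_c(p2)$fisher_c, fc2$fisher_c)
})

test_that("noiseless paths are identified exactly", {
  # saturated single-path models: standardized coefficients are +-1 and
  # the variance is fully explained (a noiseless fork would make the
  # d-separation claim regressions collinear, so each path is checked
  # in its own saturated model)
  withr::with_seed(30, a <- rnorm(40))
  d <- tibble::tibble(a = a, b = 2 * a, c = -0.5 * a)
  up <- suppressWarnings(fit_piecewise_sem(d, sem_spec("a -> b")))
  expect_equal(tidy(up)$std_estimate, 1, tolerance = 1e-9)
  expect_equal(up$r2$r_squared, 1, tolerance = 1e-9)
  expect_equal(glance(up)$p_value, 1)  # saturated: no claims
  down <- suppressWarnings(fit_piecewise_sem(d, sem_spec("a -> c")))
  expect_equal(tidy(down)$std_estimate, -1, tolerance = 1e-9)
  expect_equal(down$r2$r_squared, 1, tolerance = 1e-9)
})

test_that("claims pass for the true DAG under small noise", {
  withr::with_seed(41, {
    a <- rnorm(60)
    b <- 1.5 * a + rnorm(60, sd = 0.4)
    cc <- -b + rnorm(60, sd = 0.4)
  })
  d <- tibble::tibble(a = a, b = b, c = cc)
  fit <- fit_piecewise_sem(d, sem_spec(c("a -> b", "b -> c")))
  expect_equal(nrow(fit$claims), 1L)
  expect_gt(glance(fit)$p_value, 0.05)
  td <- tidy(fit)
  expect_gt(td$std_estimate[td$child == "b"], 0)
  expect_lt(td$std_estimate[td$child == "c"], 0)
})

test_that("permuting a response destroys its path signal", {
  withr::with_seed(52, {
    a <- rnorm(50)
    b <- 2 * a + rnorm(50, sd = 0.5)
  })
  d <- tibble::tibble(a = a, b = b)
  spec <- sem_spec("a -> b")
  base <- tidy(fit_piecewise_sem(d, spec))
  expect_lt(base$p_value, 1e-10)
  dulled <- 0
  withr::with_seed(53, {
    for (i in 1:50) {
      dp <- d
      dp$b <- sample(dp$b)
      p <- tidy(fit_piecewise_sem(dp, spec))$p_value
      dulled <- dulled + (p > 0.05)
    }
  })
  expect_gte(dulled / 50, 0.9)
})

test_that("standardized paths are invariant to affine rescaling", {
  withr::with_seed(61, {
    a <- rnorm(45)
    b <- a + rnorm(45, sd = 0.7)
    cc <- -b + rnorm(45, sd = 0.7)
  })
  d <- tibble::tibble(a = a, b = b, c = cc)
  spec <- sem_spec(c("a -> b", "b -> c"))
  t1 <- tidy(fit_piecewise_sem(d, spec))
  d2 <- dplyr::mutate(d, a = 100 * a + 3, c = 0.01 * c - 5)
  t2 <- tidy(fit_piecewise_sem(d2, spec))
  expect_equal(t1$std_estimate, t2$std_estimate, tolerance = 1e-9)
})

test_that("incomplete rows are dropped with a record", {
  withr::with_seed(70, {
    a <- rnorm(30)
    b <- a + rnorm(30, 0, 0.5)
  })
  d <- tibble::tibble(a = a, b = b)
  d$a[c(2, 9)] <- NA
  fit <- fit_piecewise_sem(d, sem_spec("a -> b"))
  expect_equal(fit$n_used, 28L)
  expect_equal(fit$n_dropped, 2L)
})

test_that("the default DAG has the documented shape", {
  spec <- default_sem_spec()
  expect_equal(nrow(spec$paths), 9L)
  expect_setequal(spec$exogenous, "n_dose")
  expect_true(all(c("din", "ph", "rk_pc1", "richness",
                    "total_cohesion", "plant_richness") %in% spec$vars))
  expect_equal(nrow(basis_set(spec)), 12L)
})
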