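test_that("toy network FVA matches the analytic ranges", {
  f100 <- fva(toy_model(), opt_perc = 100)
  expect_equal(f100$Z, 10, tolerance = 1e-9)
  expect_equal(f100$table$min_flux, c(10, 10, 0), tolerance = 1e-7)
  expect_equal(f100$table$max_flux, c(10, 10, 0), tolerance = 1e-7)

  f50 <- fva(toy_model(), opt_perc = 50)
  expect_equal(f50$table$min_flux, c(5, 5, 0), tolerance = 1e-7)
  expect_equal(f50$table$max_flux, c(10, 10, 5), tolerance = 1e-7)
})

test_that("the objective reaction is pinned to Z at full optimality", {
  for (seed in c(3L, 7L)) {
    m <- small_model(seed)
    f <- fva(m, opt_perc = 100)
    i <- which(m$obj != 0)
    expect_equal(f$table$min_flux[i], f$Z, tolerance = 1e-6)
    expect_equal(f$table$max_flux[i], f$Z, tolerance = 1e-6)
  }
})

test_that("fva_single solves one direction over the constrained polytope", {
  p <- lp_problem(toy_model())
  p <- apply_optimality_constraint(p, 10, 100)
  expect_equal(fva_single(p, 3, "min")$value, 0, tolerance = 1e-7)
  expect_equal(fva_single(p, 3, "max")$value, 0, tolerance = 1e-7)

  p50 <- apply_optimality_constraint(lp_problem(toy_model()), 10, 50)
  expect_equal(fva_single(p50, 3, "min")$value, 0, tolerance = 1e-8)
  expect_equal(fva_single(p50, 3, "max")$value, 5, tolerance = 1e-8)
  expect_error(fva_single(p50, 9, "max"), "range")
})

test_that("a fixed reaction reports its pinned value in both directions", {
  m <- toy_model()
  m$lb[3] <- m$ub[3] <- 3
  p <- apply_optimality_constraint(lp_problem(m), fba(m)$objective, 50)
  expect_equal(fva_single(p, 3, "min")$value, 3, tolerance = 1e-9)
  expect_equal(fva_single(p, 3, "max")$value, 3, tolerance = 1e-9)
})

test_that("optimality constraint arithmetic and corner cases", {
  p <- lp_problem(toy_model())
  p90 <- apply_optimality_constraint(p, 10, 90)
  k <- nrow(p90$A)
  expect_equal(p90$rhs[k], 9)                      # 90% of 10
  expect_equal(p90$sense[k], "G")
  expect_equal(p90$A[k, ], p$obj0, ignore_attr = TRUE)

  p0 <- apply_optimality_constraint(p, 10, 0)
  expect_equal(p0$rhs[nrow(p0$A)], 0)

  expect_error(apply_optimality_constraint(p, 10, 150), "opt_perc")
  expect_error(apply_optimality_constraint(p, Inf, 90), "finite")

  # negative optimum: the literal fraction tightens the bound -> warning
  expect_warning(pn <- apply_optimality_constraint(p, -5, 90), "tighter")
  expect_equal(pn$rhs[nrow(pn$A)], -4.5)
})

test_that("a negative-optimum model sweeps with a warning and matches the oracle", {
  m <- negative_optimum_model()
  expect_equal(fba(m)$objective, -2, tolerance = 1e-9)
  expect_warning(f <- fva(m, opt_perc = 90), "tighter")
  orc <- oracle_fva(m, 90)
  expect_equal(f$table$min_flux, orc$min_flux, tolerance = 1e-7)
  expect_equal(f$table$max_flux, orc$max_flux, tolerance = 1e-7)
})

test_that("reaction subsets solve exactly two LPs per reaction", {
  f <- fva(toy_model(), rxns = "R2")
  expect_equal(nrow(f$table), 1L)
  expect_equal(f$n_lps, 2L)
  expect_equal(sum(f$workers$iterations), 2L)
  expect_error(fva(toy_model(), rxns = c("R2", "nope")), "nope")
})

test_that("unbounded directions report infinite range endpoints", {
  f <- fva(cycle_fva_model(), opt_perc = 100)
  expect_equal(f$Z, 10, tolerance = 1e-9)
  expect_equal(f$table$max_flux[3:4], c(Inf, Inf))
  expect_equal(f$table$status_max[3:4], c("unbounded", "unbounded"))
  expect_equal(f$table$min_flux[3:4], c(0, 0), tolerance = 1e-9)
  expect_equal(f$table$min_flux[1:2], c(10, 10), tolerance = 1e-7)
  # an unbounded FBA objective cannot anchor the optimality constraint
  expect_error(fva(cycle_model()), "unbounded")
})

test_that("lowering optPerc never shrinks a range, and ranges stay in bounds", {
  for (seed in c(2L, 6L, 11L)) {
    m <- small_model(seed, reversible = 0.4)
    f100 <- fva(m, opt_perc = 100)
    f50 <- fva(m, opt_perc = 50)
    tol <- 1e-7
    expect_true(all(f50$table$min_flux <= f100$table$min_flux + tol))
    expect_true(all(f50$table$max_flux >= f100$table$max_flux - tol))
    for (f in list(f100, f50)) {
      expect_true(all(f$table$min_flux <= f$table$max_flux + tol))
      expect_true(all(f$table$min_flux >= m$lb - tol))
      expect_true(all(f$table$max_flux <= m$ub + tol))
    }
  }
})

test_that("FVA results serialize to CSV and JSON with run metadata", {
  f <- fva(toy_model())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fva(f, csv, js)
  tab <- utils::read.csv(csv)
  expect_equal(names(tab),
               c("reaction_id", "min_flux", "max_flux", "status_min", "status_max"))
  expect_equal(nrow(tab), 3L)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$opt_perc, 100)
  expect_equal(meta$n_lps, 6)
  expect_equal(meta$schedule$policy, "dynamic")
})
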