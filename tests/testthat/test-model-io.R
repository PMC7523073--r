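test_that("hand-written MPS fixture parses field by field", {
  path <- withr::local_tempfile(fileext = ".mps")
  write_toy_mps_2rxn(path)
  m <- read_mps(path)
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(as.matrix(m$S), matrix(c(1, -1), 1, 2), ignore_attr = TRUE)
  expect_equal(m$lb, c(0, 0))
  expect_equal(m$ub, c(10, 10))
  expect_equal(m$obj, c(1, 0))
  expect_equal(m$b, 0)
  expect_equal(m$reaction_ids, c("R1", "R2"))
  expect_equal(m$metabolite_ids, "A")
})

test_that("MPS defaults and malformed sections behave per convention", {
  path <- withr::local_tempfile(fileext = ".mps")
  writeLines(c("ROWS", " N  OBJ", " E  A", "COLUMNS",
               "    R1  OBJ  1  A  1", "    R2  A  -1", "ENDATA"), path)
  m <- read_mps(path)
  expect_equal(m$lb, c(0, 0))           # no BOUNDS: [0, +Inf)
  expect_equal(m$ub, c(Inf, Inf))

  writeLines(c("ROWS", " N  OBJ", " E  A", "ENDATA"), path)
  expect_error(read_mps(path), "COLUMNS")

  writeLines(c("ROWS", " N  OBJ", " E  A", "COLUMNS",
               "    R1  OBJ  notanumber", "ENDATA"), path)
  expect_error(read_mps(path), "line 5")

  writeLines(c("ROWS", " N  OBJ", " E  A", "COLUMNS", "    R1  A  1",
               "RANGES", "    RNG  A  5", "ENDATA"), path)
  expect_error(read_mps(path), "RANGES|ranged")

  writeLines(c("ROWS", " N  OBJ", " N  OBJ2", " E  A", "COLUMNS",
               "    R1  A  1", "ENDATA"), path)
  expect_error(read_mps(path), "objective")
})

test_that("bound magnitudes >= 1e30 read as infinite", {
  path <- withr::local_tempfile(fileext = ".mps")
  writeLines(c("ROWS", " N  OBJ", " E  A", "COLUMNS",
               "    R1  OBJ  1  A  1", "    R2  A  -1",
               "BOUNDS", " UP  BND  R1  1e30", " LO  BND  R2  -2e30",
               "ENDATA"), path)
  m <- read_mps(path)
  expect_equal(m$ub[1], Inf)
  expect_equal(m$lb[2], -Inf)
})

test_that("MPS round-trip is lossless at double precision", {
  path <- withr::local_tempfile(fileext = ".mps")
  for (seed in c(2L, 9L, 14L)) {
    m <- small_model(seed, reversible = 0.5)
    # salt the model with awkward values: fixed, free and infinite bounds
    m$ub[1] <- Inf
    m$lb[2] <- m$ub[2] <- pi
    m$lb[3] <- -Inf
    m$lb[4] <- -1 / 3
    write_mps(m, path)
    m2 <- read_mps(path)
    expect_identical(as.matrix(m2$S), as.matrix(m$S))
    expect_identical(m2$lb, m$lb)
    expect_identical(m2$ub, m$ub)
    expect_identical(m2$obj, m$obj)
    expect_identical(m2$b, m$b)
    expect_identical(m2$reaction_ids, m$reaction_ids)
    expect_identical(m2$metabolite_ids, m$metabolite_ids)
    expect_identical(m2$objective_sense, m$objective_sense)
  }
})

test_that("inequality rows are kept as auxiliary constraints and round-trip", {
  m <- toy_model()
  m$aux <- list(C = matrix(c(1, 1, 0), 1, 3), sense = "L", rhs = 12,
                ids = "CAP")
  path <- withr::local_tempfile(fileext = ".mps")
  write_mps(m, path)
  m2 <- read_mps(path)
  expect_equal(m2$aux$C, m$aux$C, ignore_attr = TRUE)
  expect_identical(unname(m2$aux$sense), "L")
  expect_identical(unname(m2$aux$rhs), 12)
  # the constraint binds the LP: v1 + v2 <= 12 caps the optimum at 6
  expect_equal(fba(m2)$objective, 6, tolerance = 1e-9)
})

test_that("fixed dialect enforces identifier width on write", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".mps")
  expect_silent(write_mps(m, path, dialect = "fixed"))
  m$reaction_ids[1] <- "a_very_long_reaction_identifier"
  expect_error(write_mps(m, path, dialect = "fixed"), "free")
})

test_that("writing an empty model is refused", {
  m <- toy_model()
  m$S <- m$S[, 0, drop = FALSE]
  m$lb <- m$ub <- m$obj <- numeric(0)
  m$reaction_ids <- character(0)
  path <- withr::local_tempfile(fileext = ".mps")
  expect_error(write_mps(m, path), "empty")
})

test_that("structured container conversion follows COBRA conventions", {
  x <- list(S = matrix(1:6, 2, 3), lb = c(0, 0, 0), ub = c(1, 1, 1),
            c = c(0, 0, 1))
  m <- as_metabolic_model(x)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m$b, c(0, 0))                       # absent b -> zeros
  expect_equal(m$reaction_ids, c("R1", "R2", "R3"))# generated ids

  expect_warning(m2 <- as_metabolic_model(x[c("S", "lb", "ub")]),
                 "objective")
  expect_equal(m2$obj, c(0, 0, 0))

  bad <- x; bad$lb <- c(0, 0, 0, 0)
  expect_error(as_metabolic_model(bad), "mismatch")
  expect_error(as_metabolic_model(list(lb = 1, ub = 2)), "'S'")
})

test_that("container JSON archive round-trips through file", {
  m <- small_model(5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_container(m, path)
  m2 <- read_model_container(path)
  expect_identical(as.matrix(m2$S), as.matrix(m$S))
  expect_identical(m2$lb, m$lb)
  expect_identical(m2$obj, m$obj)
  expect_identical(m2$reaction_ids, m$reaction_ids)
})

test_that("model validation catches structural violations", {
  expect_error(metabolic_model(S = matrix(1, 1, 2), lb = c(0, 5), ub = c(10, 2),
                               obj = c(1, 0)), "lb > ub")
  expect_error(metabolic_model(S = matrix(1, 1, 2), lb = c(0, 0), ub = c(1, 1),
                               obj = c(1, 0), reaction_ids = c("R1", "R1")),
               "duplicated")
  expect_error(metabolic_model(S = matrix(1, 1, 2), lb = c(0, 0), ub = c(1, 1),
                               obj = c(1, 0), reaction_ids = c("R 1", "R2")),
               "whitespace")
  rep <- model_validation_report(toy_model())
  expect_true(rep$valid)
  expect_length(rep$errors, 0)
})
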