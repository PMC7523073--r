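test_that("static partition produces contiguous near-equal blocks", {
  blocks <- partition_static(27452, 16)
  sizes <- lengths(blocks)
  expect_setequal(unique(sizes), c(1715L, 1716L))
  expect_equal(sum(sizes == 1716L), 12L)
  expect_equal(sum(sizes == 1715L), 4L)
  expect_equal(unlist(blocks), 1:27452)

  expect_equal(lengths(partition_static(10, 10)), rep(1L, 10))
  expect_equal(lengths(partition_static(3, 5)), c(1L, 1L, 1L, 0L, 0L))

  for (n in c(1L, 13L, 100L, 2047L)) {
    for (w in c(1L, 3L, 7L, 16L)) {
      sz <- lengths(partition_static(n, w))
      expect_lte(max(sz) - min(sz), 1L)
      expect_equal(sum(sz), n)
      expect_equal(unlist(partition_static(n, w)), seq_len(n))
    }
  }
})

test_that("guided chunks start at 2n/workers and decay with the remainder", {
  expect_equal(next_chunk_guided(200, 4), 50L)
  expect_equal(next_chunk_guided(7, 4), 2L)
  expect_equal(next_chunk_guided(0, 4), 0L)
  for (n2 in c(10L, 64L, 501L)) {
    for (w in c(1L, 4L, 9L)) {
      expect_equal(next_chunk_guided(n2, w), max(1L, as.integer(ceiling(n2 / w))))
      # simulate the full decay: chunks cover everything, each is the
      # ceiling of the remainder over the workers, floored at one
      rem <- n2; total <- 0L
      while (rem > 0L) {
        ch <- next_chunk_guided(rem, w)
        expect_gte(ch, 1L)
        expect_equal(ch, max(1L, as.integer(ceiling(rem / w))))
        rem <- rem - ch; total <- total + ch
      }
      expect_equal(total, n2)
    }
  }
})

test_that("every item is processed exactly once, results in input order", {
  items <- as.list(1:47)
  fn <- function(item, state, ctx) list(result = item * 10L, state = NULL)
  specs <- list(schedule_spec("static", nproc = 3L),
                schedule_spec("guided", nproc = 2L, nthreads = 2L),
                schedule_spec("dynamic", chunk = 5L, nproc = 4L),
                schedule_spec("dynamic", chunk = 100L))
  for (spec in specs) {
    run <- run_schedule(items, fn, spec)
    expect_equal(unlist(run$results), (1:47) * 10L)
    expect_equal(sum(run$reports$iterations), 47L)
  }
})

test_that("a chunk larger than the queue goes to a single worker", {
  run <- run_schedule(as.list(1:6),
                      function(item, state, ctx) list(result = item, state = NULL),
                      schedule_spec("dynamic", chunk = 50L, nproc = 2L, nthreads = 2L))
  expect_equal(sum(run$reports$iterations), 6L)
  expect_equal(sum(run$reports$iterations > 0L), 1L)
  expect_equal(sum(run$reports$chunks), 1L)
})

test_that("warm-start state chains only within one chunk", {
  seen <- list()
  fn <- function(item, state, ctx) {
    seen[[length(seen) + 1L]] <<- list(item = item, state = state)
    list(result = item, state = item)  # state := previous item id
  }
  run_schedule(as.list(1:10), fn, schedule_spec("dynamic", chunk = 3L))
  for (rec in seen) {
    if ((rec$item - 1L) %% 3L == 0L) {
      expect_null(rec$state)                       # chunk start: fresh state
    } else {
      expect_equal(rec$state, rec$item - 1L)       # chained inside the chunk
    }
  }
})

test_that("worker groups receive private contexts and slots share them", {
  built <- integer(0)
  fn <- function(item, state, ctx) list(result = ctx, state = NULL)
  run <- run_schedule(as.list(1:8), fn,
                      schedule_spec("static", nproc = 2L, nthreads = 2L),
                      init_group = function(g) { built <<- c(built, g); g })
  expect_equal(built, 1:2)                         # one context per group
  expect_setequal(unlist(run$results), 1:2)
})

test_that("dynamic chunk=1 balances a skewed workload better than static", {
  wins <- 0L
  for (seed in 1:5) {
    costs <- heterogeneous_workload(200, skew = 100, seed = seed)
    fn <- function(item, state, ctx) list(result = item, state = NULL)
    cv <- function(x) stats::sd(x) / mean(x)
    rs <- run_schedule(as.list(1:200), fn, schedule_spec("static", nproc = 4L),
                       costs = costs)
    rd <- run_schedule(as.list(1:200), fn,
                       schedule_spec("dynamic", chunk = 1L, nproc = 4L),
                       costs = costs)
    expect_equal(sum(rs$reports$iterations), 200L)
    expect_equal(sum(rd$reports$iterations), 200L)
    if (cv(rd$reports$busy_seconds) < cv(rs$reports$busy_seconds)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("per-chunk setup cost makes chunk=1 costlier than a moderate chunk", {
  # losing the basis at every dispatch (chunk=1) re-pays the setup cost
  # per item; a moderate chunk amortizes it
  costs <- heterogeneous_workload(200, skew = 10, seed = 3)
  fn <- function(item, state, ctx) list(result = item, state = NULL)
  r1 <- run_schedule(as.list(1:200), fn,
                     schedule_spec("dynamic", chunk = 1L, nproc = 4L),
                     costs = costs, chunk_setup = 0.05)
  r50 <- run_schedule(as.list(1:200), fn,
                      schedule_spec("dynamic", chunk = 50L, nproc = 4L),
                      costs = costs, chunk_setup = 0.05)
  expect_gt(sum(r1$reports$busy_seconds), sum(r50$reports$busy_seconds))
})

test_that("a crashing chunk is re-queued once, then failures are per item", {
  attempts <- new.env(parent = emptyenv())
  flaky <- function(item, state, ctx) {
    if (item == 5L) {
      k <- get0("n5", attempts, ifnotfound = 0L) + 1L
      assign("n5", k, attempts)
      if (k == 1L) stop("transient solver crash")
    }
    list(result = item, state = NULL)
  }
  run <- run_schedule(as.list(1:8), flaky, schedule_spec("dynamic", chunk = 4L))
  expect_equal(unlist(run$results), 1:8)           # recovered on retry
  expect_equal(sum(run$reports$iterations), 8L)

  always <- function(item, state, ctx) {
    if (item == 5L) stop("hard failure")
    list(result = item, state = NULL)
  }
  run2 <- run_schedule(as.list(1:8), always, schedule_spec("dynamic", chunk = 4L))
  expect_s3_class(run2$results[[5L]], "schedule_failure")
  expect_equal(unlist(run2$results[-5L]), (1:8)[-5L])
  expect_equal(sum(run2$reports$iterations), 8L)
})

test_that("schedule specification validates its fields", {
  expect_error(schedule_spec("dynamic", chunk = 0L), "chunk")
  expect_error(schedule_spec(nproc = 0L), "nproc")
  expect_error(schedule_spec("bogus"), "arg")
})
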