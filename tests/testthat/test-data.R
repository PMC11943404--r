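test_that("read_long parses, validates and drops missing scores", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Person,Item,Score", "P1,I1,5", "P1,I2,3", "P2,I1,0"), f)
  d <- read_long(f)
  expect_s3_class(d, "count_data")
  expect_equal(length(d$persons), 2L)
  expect_equal(length(d$items), 2L)
  expect_equal(nrow(d$records), 3L)
  expect_equal(d$records$count, c(5L, 3L, 0L))

  writeLines(c("Person,Item,Score", "P1,I1,2.5"), f)
  expect_error(read_long(f), "non-integer")
  writeLines(c("Person,Item,Score", "P1,I1,-1"), f)
  expect_error(read_long(f), "negative")
  writeLines(c("Person,Item,Points", "P1,I1,1"), f)
  expect_error(read_long(f), "Score")

  writeLines(c("Person,Item,Score", "P1,I1,5", "P1,I2,", "P2,I1,7"), f)
  expect_message(d2 <- read_long(f), "dropped 1")
  expect_equal(nrow(d2$records), 2L)
})

test_that("count_data enforces its invariants", {
  expect_error(count_data("P1", "I1", -2), "negative")
  expect_error(count_data("P1", "I1", 1.5), "non-integer")
  expect_error(count_data(c("P1", "P1"), c("I1", "I1"), c(1, 2)),
               "duplicate")
  expect_error(count_data("P1", c("I1", "I2"), 1), "equal length")
})

test_that("paper-shaped synthetic fixture has 3*(n-1)+1 records", {
  ex <- simulate_example_dataset(seed = 5)
  expect_equal(nrow(ex$data$records), 3L * 201L + 1L)
  expect_equal(length(ex$data$persons), 202L)
  expect_equal(length(ex$data$items), 3L)
  # the single-record person survives a write/read round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_long(ex$data, f)
  d2 <- read_long(f)
  expect_equal(nrow(d2$records), 604L)
  expect_equal(sum(d2$records$person == "P202"), 1L)
})

test_that("read_wide pivots, handles empty cells and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Person,I1,I2,I3", "P1,4,,2", "P2,1,3,5"), f)
  d <- read_wide(f)
  expect_equal(nrow(d$records), 5L)
  expect_false(any(d$records$person == "P1" & d$records$item == "I2"))

  writeLines(c("Person,I1", "P1,7"), f)
  d1 <- read_wide(f)
  expect_equal(nrow(d1$records), 1L)
  expect_equal(d1$records$count, 7L)

  writeLines(c("Person,I1,I2", "P1,1,2", "P1,3,4"), f)
  expect_error(read_wide(f), "duplicate")
})

test_that("long and wide round trips are the identity", {
  ip <- random_params(3)
  set.seed(42)
  sim <- simulate_dataset(sim_config(20, ip, seed = 8))
  fl <- withr::local_tempfile(fileext = ".csv")
  fw <- withr::local_tempfile(fileext = ".csv")
  write_long(sim$data, fl)
  expect_equal(read_long(fl), sim$data)
  write_wide(sim$data, fw)
  dw <- read_wide(fw)
  expect_equal(dw, sim$data)
})

test_that("simulate_dataset is seed-deterministic and respects missingness", {
  ip <- item_params(c("A", "B", "C"), c(1.5, 2, 1), 0.4,
                    model_kind = "RPCM")
  miss <- rbind(c(1L, 2L), c(5L, 1L), c(5L, 3L))
  cfg <- sim_config(10, ip, missing_pattern = miss, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$data$records), 30L - 3L)
  expect_false(any(s1$data$records$person == "P1" &
                     s1$data$records$item == "B"))
  # invariants hold for simulated output across seeds
  for (seed in 1:5) {
    s <- simulate_dataset(sim_config(15, ip, missing_pattern = miss,
                                     seed = seed))
    expect_true(all(s$data$records$count >= 0))
    expect_true(all(table(s$data$records$person) >= 1))
    expect_no_error(count_data(s$data$records$person,
                               s$data$records$item,
                               s$data$records$count))
  }
  # dropping all of a person's records is rejected up front
  expect_error(sim_config(10, ip,
                          missing_pattern = rbind(c(2L, 1L), c(2L, 2L),
                                                  c(2L, 3L))),
               "all records")
})

test_that("simulated item means match the Poisson-lognormal moment", {
  # a = 0: plain Poisson mean
  ip0 <- item_params("I1", log(5), 0)
  s0 <- simulate_dataset(sim_config(10000, ip0, seed = 100))
  expect_lt(abs(mean(s0$data$records$count) - 5), 3 * sqrt(5 / 10000))
  # a > 0: mixing over theta; oracle by numeric integration
  b <- 2.06; a <- 0.34
  ip1 <- item_params("I1", b, a)
  s1 <- simulate_dataset(sim_config(20000, ip1, seed = 101))
  grid <- seq(-8, 8, length.out = 4001)
  mu <- sum(exp(b + a * grid) * dnorm(grid)) * (grid[2] - grid[1])
  expect_equal(mu, exp(b + a^2 / 2), tolerance = 1e-6)  # oracle sanity
  sd_mix <- sqrt(mu + exp(2 * b + a^2) * (exp(a^2) - 1))
  expect_lt(abs(mean(s1$data$records$count) - mu),
            3 * sd_mix / sqrt(20000))
})
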