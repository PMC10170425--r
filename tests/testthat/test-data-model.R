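test_that("long-format round trip preserves values and missingness mask", {
  d <- toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  d$responses[2, 5, 1] <- NA           # one genuinely missing cell
  write_panel(d, path)
  d2 <- read_panel(path, schema = d$schema,
                   format_config = list(format = "long", waves = d$waves,
                                        aux = c(sex = "sex",
                                                ethnicity = "ethnicity",
                                                age = "age")))
  expect_equal(unname(d2$responses), unname(d$responses))
  expect_identical(d2$subjects, d$subjects)
  expect_equal(d2$aux$age, d$aux$age)
  expect_true(is.na(d2$responses[2, 5, 1]))
  expect_equal(sum(is.na(d2$responses)), 1)
})

test_that("declared sentinel codes become missing; others are errors", {
  d <- toy_panel()
  long <- as.data.frame(d)
  long$value[3] <- -9
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  d2 <- read_panel(path, schema = d$schema,
                   format_config = list(format = "long", waves = d$waves,
                                        na_codes = -9))
  expect_equal(sum(is.na(d2$responses)), 1)
  # same file without declaring the sentinel: -9 is out of range
  expect_error(
    read_panel(path, schema = d$schema,
               format_config = list(format = "long", waves = d$waves)),
    "out of range")
  long$value[3] <- "x"
  write.csv(long, path, row.names = FALSE)
  expect_error(
    read_panel(path, schema = d$schema,
               format_config = list(format = "long", waves = d$waves)),
    "unparseable")
})

test_that("out-of-range responses and missing columns are schema errors", {
  d <- toy_panel()
  long <- as.data.frame(d)
  long$value[long$item == "concentrate"][1] <- 7
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  expect_error(
    read_panel(path, schema = d$schema,
               format_config = list(format = "long", waves = d$waves)),
    "concentrate")
  names(long)[names(long) == "value"] <- "score"
  write.csv(long, path, row.names = FALSE)
  expect_error(
    read_panel(path, schema = d$schema,
               format_config = list(format = "long", waves = d$waves)),
    "column")
})

test_that("wide format reads item_wave columns", {
  d <- toy_panel()
  wide <- data.frame(subject = d$subjects)
  for (i in d$schema$item_id) for (w in d$waves)
    wide[[paste0(i, "_", w)]] <- d$responses[, i, w]
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, path, row.names = FALSE)
  d2 <- read_panel(path, schema = d$schema,
                   format_config = list(format = "wide", waves = d$waves))
  expect_equal(unname(d2$responses), unname(d$responses))
})

test_that("recode_items reflects flagged items and is an involution", {
  schema <- default_item_schema(recoded = FALSE)
  arr <- array(0, c(3, 13, 2))
  arr[, , ] <- 1
  arr[1, 1, 1] <- 0  # concentrate is reverse-coded in the raw schema
  arr[2, 1, 1] <- 2
  arr[3, 2, 1] <- 2  # sleep is not
  d <- panel_dataset(arr, paste0("S", 1:3), c("1", "2"), schema)
  r <- recode_items(d)
  expect_equal(r$responses[1, 1, 1], 3)   # 0 -> 3 endpoint reflection
  expect_equal(r$responses[2, 1, 1], 1)   # 2 -> 1
  expect_equal(r$responses[3, 2, 1], 2)   # untouched item
  rr <- recode_items(r)
  expect_equal(rr$responses, d$responses)
  expect_equal(rr$schema$reverse_coded, d$schema$reverse_coded)
})

test_that("GHQ sum and caseness follow the >11 rule and flag missingness", {
  schema <- default_item_schema()
  arr <- array(0, c(4, 13, 1))
  arr[, 13, 1] <- 1                       # loneliness at scale minimum
  arr[1, 1:12, 1] <- 3                    # sum 36
  arr[2, 1:12, 1] <- c(3, 3, 3, 2, rep(0, 8))   # sum 11
  arr[3, 1:12, 1] <- c(3, 3, 3, 3, rep(0, 8))   # sum 12
  arr[4, 1:12, 1] <- 1
  arr[4, 6, 1] <- NA                      # one missing GHQ item
  d <- panel_dataset(arr, paste0("S", 1:4), "1", schema)
  s <- ghq_sum_and_caseness(d, "1")
  expect_equal(s$ghq_sum[1:3], c(36, 11, 12))
  expect_equal(s$case[1:3], c(TRUE, FALSE, TRUE))
  expect_true(is.na(s$ghq_sum[4]) && is.na(s$case[4]))
  # loneliness never enters the sum
  arr[2, 13, 1] <- 3
  d2 <- panel_dataset(arr, paste0("S", 1:4), "1", schema)
  expect_equal(ghq_sum_and_caseness(d2, "1")$ghq_sum[2], 11)
})

test_that("GHQ sum is item-order invariant and caseness is monotone", {
  set.seed(11)
  schema <- default_item_schema()
  for (rep in 1:20) {
    vals <- sample(0:3, 12, replace = TRUE)
    arr <- array(c(vals, 1), c(1, 13, 1))
    d <- panel_dataset(arr, "S1", "1", schema)
    base <- ghq_sum_and_caseness(d, "1")
    perm <- sample(12)
    arr2 <- array(c(vals[perm], 1), c(1, 13, 1))
    d2 <- panel_dataset(arr2, "S1", "1", schema)
    expect_equal(ghq_sum_and_caseness(d2, "1")$ghq_sum, base$ghq_sum)
    # raising any item never turns a case into a non-case
    i <- sample(which(vals < 3), 1)
    vals_up <- vals; vals_up[i] <- vals_up[i] + 1
    d3 <- panel_dataset(array(c(vals_up, 1), c(1, 13, 1)), "S1", "1", schema)
    expect_gte(ghq_sum_and_caseness(d3, "1")$ghq_sum, base$ghq_sum)
    if (base$case) expect_true(ghq_sum_and_caseness(d3, "1")$case)
  }
})

test_that("schema invariants are enforced", {
  expect_error(item_schema("a", 2, 2), "strictly below")
  expect_error(item_schema(c("a", "a"), 0, 3), "unique")
  s <- default_item_schema()
  expect_equal(nrow(s), 13)
  expect_equal(s$scale_min[s$item_id == "loneliness"], 1)
  expect_equal(sum(s$scale_max == 3 & s$scale_min == 0), 12)
})
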