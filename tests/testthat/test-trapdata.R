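test_that("read_catch_csv parses valid rows and reports them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,village,trap,taxon,hour,count",
               "2015-04-01,Lupiro,SUN,an_arabiensis,20,3",
               "2015-04-01,Lupiro,ITT-C,culex,,12"), path)
  expect_message(rec <- read_catch_csv(path), "2 rows read")
  expect_s3_class(rec, "catch_records")
  expect_equal(rec$count, c(3L, 12L))
  expect_equal(rec$hour, c(20L, NA_integer_))
  expect_equal(rec$trap, c("SUN", "ITTC")) # hyphen normalised
  expect_equal(rec$date[1], as.Date("2015-04-01"))
})

test_that("read_catch_csv handles an empty file with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("date,village,trap,taxon,hour,count", path)
  expect_warning(rec <- suppressMessages(read_catch_csv(path)), "no data rows")
  expect_equal(nrow(rec), 0L)
})

test_that("read_catch_csv rejects malformed input with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,village,trap,taxon,hour,count",
               "2015-04-01,Lupiro,SUN,an_arabiensis,20,3",
               "2015-04-02,Lupiro,SUN,an_arabiensis,20,-1"), path)
  expect_error(read_catch_csv(path), "non-negative integer.*line.*3")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,village,trap,taxon,count",
               "2015-04-01,Lupiro,XTRAP,culex,3"), path2)
  expect_error(read_catch_csv(path2), "unknown trap code")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,village,taxon,count", "2015-04-01,Lupiro,culex,3"), path3)
  expect_error(read_catch_csv(path3), "missing mandatory column.*trap")
})

test_that("catch CSV round-trips through write and read exactly", {
  tab <- quick_table_k2(seed = 5, nights = 12)
  rec <- as_catch_records(tab, trap = "BGS", taxon = "an_funestus")
  path <- withr::local_tempfile(fileext = ".csv")
  write_catch_csv(rec, path)
  back <- suppressMessages(read_catch_csv(path))
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("pool_hourly sums hourly cups per trap-night and is idempotent", {
  rec <- data.frame(
    date = as.Date("2015-04-01"),
    village = c("Lupiro", "Lupiro", "Minepa"),
    trap = "SUN", taxon = "culex",
    hour = c(20L, 23L, 20L), count = c(2L, 3L, 6L),
    stringsAsFactors = FALSE)
  class(rec) <- c("catch_records", "data.frame")
  pooled <- pool_hourly(rec)
  expect_equal(nrow(pooled), 2L) # one per village
  expect_equal(pooled$count[pooled$village == "Lupiro"], 5L)
  expect_true(all(is.na(pooled$hour)))
  expect_equal(pool_hourly(pooled), pooled)
})

test_that("pool_hourly keeps all-zero nights and rejects double entries", {
  zeros <- data.frame(date = as.Date("2015-04-01"), village = "Lupiro",
                      trap = "SUN", taxon = "culex", hour = c(18:23, 0:5),
                      count = 0L, stringsAsFactors = FALSE)
  class(zeros) <- c("catch_records", "data.frame")
  pooled <- pool_hourly(zeros)
  expect_equal(pooled$count, 0L)

  dup <- data.frame(date = as.Date("2015-04-01"), village = "Lupiro",
                    trap = "SUN", taxon = "culex", hour = NA_integer_,
                    count = c(3L, 4L), stringsAsFactors = FALSE)
  class(dup) <- c("catch_records", "data.frame")
  expect_error(pool_hourly(dup), "ambiguous double entry")
})

test_that("build_catch_table aligns HLC with the focal trap per night", {
  tab <- suppressMessages(
    build_catch_table(one_night_records(), focal_taxon = "an_arabiensis",
                      trap = "SUN"))
  expect_equal(tab$N, 7L)
  expect_equal(tab$n, 4L)
  expect_equal(tab$m, 11L)
  expect_equal(as.vector(tab$s), c(1L, 10L)) # an_funestus, culex (sorted)
  expect_equal(tab$K, 2L)
})

test_that("build_catch_table drops nights lacking either method, with a log", {
  rec <- one_night_records()
  extra <- rec[rec$trap == "SUN", ]
  extra$date <- as.Date("2015-04-02") # SUN ran, HLC did not
  both <- rbind(rec, extra)
  class(both) <- c("catch_records", "data.frame")
  expect_message(
    tab <- build_catch_table(both, focal_taxon = "an_arabiensis", trap = "SUN"),
    "dropped 1 night")
  expect_equal(length(tab), 1L)

  only_sun <- extra
  class(only_sun) <- c("catch_records", "data.frame")
  expect_error(build_catch_table(only_sun, "an_arabiensis", "SUN"),
               "no overlapping nights")
})

test_that("build_catch_table validates configuration and degenerate cases", {
  rec <- one_night_records()
  expect_error(
    build_catch_table(rec, focal_taxon = "an_arabiensis", trap = "SUN",
                      other_taxa = c("culex", "an_arabiensis")),
    "must not appear in other_taxa")
  tab0 <- suppressMessages(
    build_catch_table(rec, "an_arabiensis", "SUN", other_taxa = character(0)))
  expect_equal(tab0$m, 0L)
  expect_equal(tab0$K, 0L)
  expect_error(model_spec(3, K = tab0$K), "other-taxa group")
})

test_that("catch tables conserve counts between m and s", {
  for (seed in 1:5) {
    tab <- quick_table_k2(seed = seed, nights = 30)
    expect_identical(tab$m, as.integer(rowSums(tab$s)))
  }
  expect_error(catch_table(N = 1L, n = 1L, m = 5L,
                           s = matrix(1L, 1, 2)),
               "m must equal")
  expect_error(catch_table(N = -1L, n = 1L), "non-negative")
})
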