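write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

test_that("long tables parse into per-(sample, well) curves", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(sample = "s1", well = "A1", time = 0:3,
                       od = c(0.05, 0.06, 0.2, 0.5)), path)
  ds <- read_long_table(path)
  expect_s3_class(ds, "plate_dataset")
  expect_length(ds$curves, 1L)
  cv <- ds$curves[[1]]
  expect_length(cv$time, 4L)
  expect_identical(cv$well_id, "A01")  # zero-padded on read

  # two samples x two wells group into four curves with keys preserved
  grid <- expand.grid(sample = c("s1", "s2"), well = c("A01", "B05"),
                      time = 0:2, stringsAsFactors = FALSE)
  grid$od <- 0.1
  write_tsv(grid, path)
  ds2 <- read_long_table(path)
  expect_length(ds2$curves, 4L)
  expect_setequal(names(ds2$curves),
                  c("s1/A01", "s1/B05", "s2/A01", "s2/B05"))

  # extra columns ride along as metadata
  tab <- data.frame(sample = "s1", well = "A01", time = 0:2,
                    od = c(0.05, 0.1, 0.3), temp = c(37, 37, 37.2))
  write_tsv(tab, path)
  ds3 <- read_long_table(path)
  expect_equal(ds3$metadata$extra_columns$temp, c(37, 37, 37.2))
})

test_that("long-table errors name the offending column, line, or well", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(sample = "s", well = "A01", time = 0:3), path)
  expect_error(read_long_table(path), "missing required column: od")

  write_tsv(data.frame(sample = "s", well = "A01", time = c(0, 1, 2, 3),
                       od = c(0.1, "oops", 0.3, 0.4)), path)
  expect_error(read_long_table(path), "line 3")

  write_tsv(data.frame(sample = "s", well = "A01", time = c(0, 1, 1, 2),
                       od = 0.1), path)
  expect_error(read_long_table(path), "duplicate reading.*A01")

  # unsorted times are sorted with a notice, not an error
  write_tsv(data.frame(sample = "s", well = "A01", time = c(2, 0, 1, 3),
                       od = c(0.3, 0.1, 0.2, 0.4)), path)
  expect_message(ds <- read_long_table(path), "sorting")
  expect_identical(ds$curves[[1]]$od, c(0.1, 0.2, 0.3, 0.4))
})

test_that("wide CSVs parse one curve per well column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A01,H12", "0,0.05,0.06", "1,0.1,0.12", "2,0.4,0.5"),
             path)
  ds <- read_wide_csv(path)
  expect_length(ds$curves, 2L)
  expect_identical(ds$curves$H12$od, c(0.06, 0.12, 0.5))
  expect_false(ds$metadata$ragged)

  writeLines(c("hour,A01", "0,0.05", "1,0.1", "2,0.2"), path)
  expect_error(read_wide_csv(path), "first column must be 'time'")

  writeLines(c("time,I13", "0,0.05", "1,0.1", "2,0.2"), path)
  expect_error(read_wide_csv(path), "not a 96-well label")

  writeLines(c("time,A01,B02", "0,0.05,", "1,0.1,", "2,0.2,"), path)
  expect_warning(ds2 <- read_wide_csv(path), "B02.*empty")
  expect_length(ds2$curves, 1L)
})

test_that("time units convert to hours on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A01", "0,0.05", "30,0.1", "60,0.3"), path)
  ds <- read_wide_csv(path, time_unit = "minutes")
  expect_equal(ds$curves$A01$time, c(0, 0.5, 1))
  expect_error(read_wide_csv(path, time_unit = "days"), "time_unit")
})

test_that("condition maps resolve wells and default to unknown", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(well = sprintf("%s%02d", rep(LETTERS[1:8], each = 12),
                                      1:12),
                       condition = paste0("media_", 1:96)), path)
  map <- read_condition_map(path)
  expect_length(map, 96L)
  expect_identical(condition_of(map, "A1"), "media_1")
  expect_identical(condition_of(map, "Z99"), "unknown")
  expect_identical(condition_of(NULL, c("A01", "B02")),
                   c("unknown", "unknown"))

  write_tsv(data.frame(well = c("A01", "A1"), condition = c("x", "y")), path)
  expect_error(read_condition_map(path), "duplicate well")
  write_tsv(data.frame(well = c("A01", ""), condition = c("x", "y")), path)
  expect_error(read_condition_map(path), "line 3")
  write_tsv(data.frame(well = "A01", compound = "x"), path)
  expect_error(read_condition_map(path), "missing required column: condition")
})

test_that("results tables are deterministic, ordered, and round-trip as JSON", {
  res <- data.frame(sample = c("s2", "s1"), well = c("A01", "B02"),
                    condition = "unknown",
                    y0 = c(0.0512345678, 0.06), lag = c(10, 20),
                    mu = c(0.3, 0.4), A = c(1, 1.1), rss = c(1e-8, 2e-8),
                    converged = TRUE, gl = c(1.2, 1.3), gs = c(1.0, 1.14),
                    gl_class = "++", gs_class = "+++",
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_match(lines[2], "^s1\\tB02")       # sorted by sample then well
  expect_match(lines[3], "0\\.0512346")     # 6 significant digits
  first <- readBin(path, "raw", file.size(path))
  write_results(res, path)
  expect_identical(readBin(path, "raw", file.size(path)), first)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_results(res, jpath, format = "json")
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_identical(names(back), names(res))
  expect_equal(back$gs, c(1.14, 1.0))
})

test_that("a simulated plate survives the wide-CSV round trip", {
  co <- simulate_cohort(simulation_config(n_curves = 6, seed = 31))
  wells <- sprintf("A%02d", 1:6)
  path <- withr::local_tempfile(fileext = ".csv")
  wide <- data.frame(time = co$time, t(co$od))
  names(wide) <- c("time", wells)
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)

  ds <- read_wide_csv(path)
  expect_length(ds$curves, 6L)
  sc <- cohort_scores(co)
  for (i in 1:6) {
    fit <- fit_logistic(ds$curves[[wells[i]]])
    expect_lt(abs(growth_score(fit$params) - sc$gs[i]), 1e-3)
  }
})

test_that("score_plate assembles one ordered row per well", {
  co <- simulate_cohort(simulation_config(n_curves = 3, seed = 37))
  curves <- lapply(1:3, function(i) {
    cv <- cohort_curve(co, i)
    cv$well_id <- sprintf("B%02d", 4 - i)   # deliberately reverse order
    cv$sample <- "plate1"
    cv
  })
  ds <- growthscore:::.plate_dataset(curves)
  cond <- stats::setNames("glucose", "B01")
  res <- score_plate(ds, conditions = cond)
  expect_identical(res$well, c("B01", "B02", "B03"))
  expect_identical(res$condition, c("glucose", "unknown", "unknown"))
  expect_true(all(res$converged))
  expect_equal(res$gs, rev((co$params$A - co$params$y0) +
                             0.25 * co$params$mu), tolerance = 1e-4)
})
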