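write_toy_roster <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

toy_rows <- function(n = 3) {
  items <- as.data.frame(matrix(1L, n, 17))
  names(items) <- c(paste0("gad", 1:7), paste0("cesd", 1:10))
  cbind(data.frame(id = paste0("r", seq_len(n)), age = 70, sex = "female",
                   residence = "rural", living = 2L,
                   stringsAsFactors = FALSE),
        items)
}

test_that("well-formed rosters parse into complete records", {
  path <- write_toy_roster(toy_rows(3))
  r <- parse_roster(path)
  expect_s3_class(r, "participant_roster")
  expect_equal(nrow(r), 3)
  expect_false(anyNA(r))
})

test_that("out-of-range item codes become missing with a warning, record kept", {
  df <- toy_rows(2)
  df$gad3[1] <- 9L
  path <- write_toy_roster(df)
  expect_warning(r <- parse_roster(path), "out-of-range")
  expect_true(is.na(r$gad3[1]))
  expect_equal(nrow(r), 2)
})

test_that("a roster lacking a mapped column errors naming it", {
  df <- toy_rows(2)
  df$living <- NULL
  path <- write_toy_roster(df)
  expect_error(parse_roster(path), "living")
})

test_that("column mapping renames file columns to canonical fields", {
  df <- toy_rows(2)
  names(df)[names(df) == "age"] <- "trueage"
  path <- write_toy_roster(df)
  r <- parse_roster(path, column_map = list(age = "trueage"))
  expect_equal(r$age, c(70, 70))
})

test_that("the staged exclusion cascade reproduces engineered flow counts", {
  X <- random_items(2477, seed = 42)
  roster <- inject_missingness(X, c(318L, 120L, 87L), seed = 42)
  res <- apply_exclusions(roster)
  expect_equal(res$report$n_initial, 2477)
  expect_equal(res$report$n_excluded_demographic_or_incomplete, 318)
  expect_equal(res$report$n_excluded_missing_gad, 120)
  expect_equal(res$report$n_excluded_missing_cesd, 87)
  expect_equal(res$report$n_final, 1952)
  expect_equal(nrow(res$retained), 1952)
})

test_that("exclusion stages conserve records and are idempotent", {
  roster <- inject_missingness(random_items(500, 3), c(40L, 25L, 10L),
                               seed = 3)
  res <- apply_exclusions(roster)
  rpt <- res$report
  expect_equal(rpt$n_final + rpt$n_excluded_demographic_or_incomplete +
                 rpt$n_excluded_missing_gad + rpt$n_excluded_missing_cesd,
               rpt$n_initial)
  expect_equal(length(unlist(rpt$excluded_ids_by_stage)),
               rpt$n_initial - rpt$n_final)
  again <- apply_exclusions(res$retained)
  expect_equal(again$report$n_final, rpt$n_final)
  expect_equal(again$report$n_excluded_demographic_or_incomplete, 0)
})

test_that("stage attribution is first-match: demographics trump scale gaps", {
  roster <- complete_roster(4, seed = 9)
  roster$age[1] <- NA          # stage 1
  roster$gad2[1] <- NA         # would also fail stage 2
  roster$gad5[2] <- NA         # stage 2 only
  roster[3, paste0("cesd", 1:6)] <- NA  # 6/17 > 1/3 -> stage 1
  res <- apply_exclusions(roster)
  rpt <- res$report
  expect_equal(rpt$n_excluded_demographic_or_incomplete, 2)
  expect_equal(rpt$n_excluded_missing_gad, 1)
  expect_equal(rpt$n_excluded_missing_cesd, 0)
  expect_equal(rpt$n_final, 1)
})

test_that("complete records pass untouched and empty input yields zeros", {
  res <- apply_exclusions(complete_roster(10, seed = 5))
  expect_equal(res$report$n_final, 10)
  expect_equal(res$report$n_excluded_missing_gad, 0)
  empty <- apply_exclusions(complete_roster(5, 1)[0, ])
  expect_equal(empty$report$n_initial, 0)
  expect_equal(empty$report$n_final, 0)
})

test_that("scale scoring hits bounds, cutoffs, and rejects missing items", {
  roster <- complete_roster(3, seed = 7)
  roster[1, paste0("cesd", 1:10)] <- 3L
  roster[1, paste0("gad", 1:7)] <- 0L
  roster[2, paste0("gad", 1:7)] <- c(1L, 1L, 1L, 1L, 1L, 0L, 0L)
  sc <- score_scales(roster)
  expect_equal(sc$cesd_total[1], 30)
  expect_true(sc$depressive_flag[1])
  expect_equal(sc$gad_total[1], 0)
  expect_false(sc$anxiety_flag[1])
  expect_equal(sc$gad_total[2], 5)
  expect_true(sc$anxiety_flag[2])
  expect_true(all(sc$gad_total >= 0 & sc$gad_total <= 21))
  expect_true(all(sc$cesd_total >= 0 & sc$cesd_total <= 30))
  roster$gad1[3] <- NA
  expect_error(score_scales(roster), "complete")
})

test_that("descriptives use the n-1 denominator and report prevalences", {
  roster <- complete_roster(2, seed = 11)
  roster[, paste0("gad", 1:7)] <- 0L
  roster[, paste0("cesd", 1:10)] <- 1L
  roster$cesd1 <- c(0L, 2L)
  d <- descriptives(roster)
  row <- d$items[d$items$node == "CESD1", ]
  expect_equal(row$mean, 1.0)
  expect_equal(row$sd, 1.4142, tolerance = 1e-4)
  expect_equal(unname(d$prevalence["anxiety_pct"]), 0)
})

test_that("a 263-of-1952 anxiety-flag fixture yields 13.47% prevalence", {
  roster <- complete_roster(1952, seed = 13)
  roster[, paste0("gad", 1:7)] <- 0L
  roster[seq_len(263), paste0("gad", 1:5)] <- 1L   # totals exactly 5
  d <- descriptives(roster)
  expect_equal(round(unname(d$prevalence["anxiety_pct"]), 2), 13.47)
})
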