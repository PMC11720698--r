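test_that("long_table validates roles, response and uniqueness", {
  df <- data.frame(participant = rep(1:4, each = 2),
                   cond = rep(c("a", "b"), 4),
                   score = rnorm(8))
  lt <- long_table(df, "score", "participant", factors = "cond")
  expect_s3_class(lt, "long_table")
  expect_equal(nrow(lt), 8)
  expect_identical(response_col(lt), "score")

  expect_error(long_table(df, "absent", "participant"), "not found")
  df_bad <- df; df_bad$score <- as.character(df_bad$score)
  expect_error(long_table(df_bad, "score", "participant"), "not numeric")
  df_inf <- df; df_inf$score[3] <- Inf
  expect_error(long_table(df_inf, "score", "participant", factors = "cond"),
               "non-finite")
  df_dup <- rbind(df, df[1, ])
  expect_error(long_table(df_dup, "score", "participant", factors = "cond"),
               "uniquely")
  df_const <- df; df_const$cond <- "a"
  expect_error(long_table(df_const, "score", "participant",
                          factors = "cond"), "fewer than 2")
})

test_that("read_long_csv reads labels as labels and reports bad rows", {
  lt0 <- load_fixture("wm_between")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(lt0), path, row.names = FALSE)
  lt <- read_long_csv(path, response = "score", participant = "participant",
                      factors = "group", replicate = "replicate")
  expect_equal(nrow(lt), 40)
  expect_setequal(unique(lt$group), c("65yr", "75yr"))
  expect_type(lt$group, "character")
  expect_equal(sum(lt$score), sum(lt0$score))

  expect_error(read_long_csv(path, response = "nope",
                             participant = "participant"), "schema error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_long_csv(empty, "score", "participant"), "no data")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,score", "p1,3", "p2,oops"), bad)
  expect_error(read_long_csv(bad, "score", "participant"), "row 2")
})

test_that("wide_to_long preserves values and round-trips", {
  wide <- data.frame(unit = c("u1", "u2", "u3"),
                     a1 = c(1.25, 2.5, 3.75), a2 = c(4, 5, 6))
  lt <- wide_to_long(wide, list(a1 = c(cond = "a1"), a2 = c(cond = "a2")),
                     id_cols = "unit", response = "y")
  expect_equal(nrow(lt), 6)
  # bit-exact value preservation and the reverse reshape as identity
  back <- t(vapply(c("u1", "u2", "u3"), function(u) {
    c(lt$y[lt$unit == u & lt$cond == "a1"],
      lt$y[lt$unit == u & lt$cond == "a2"])
  }, numeric(2)))
  expect_identical(unname(back), unname(as.matrix(wide[, c("a1", "a2")])))

  expect_error(wide_to_long(wide, list(zz = c(cond = "x")), "unit"),
               "absent")
  expect_error(wide_to_long(wide, list(a1 = c(cond = "x"),
                                       a2 = c(cond = "x")), "unit"),
               "duplicate mapping")
})

test_that("wide reshapes of the printed tables have the documented sizes", {
  expect_equal(nrow(load_fixture("wm_between")), 40)     # 20 units x 2 days
  expect_equal(nrow(load_fixture("twobytwo")), 80)       # 10 x 2 x 2 x 2
  # one-column wide table: identity, one row per unit
  wide <- data.frame(unit = c("u1", "u2"), only = c(1, 2))
  lt <- wide_to_long(wide, list(only = c(replicate = "r1")),
                     id_cols = "unit", response = "y")
  expect_equal(nrow(lt), 2)
  expect_identical(lt$y, wide$only)
})

test_that("center_by_unit subtracts the unit mean and is idempotent", {
  lt <- load_fixture("twobytwo")
  # averaging the two measurements reproduces the worked centering table:
  # Participant 1, cell d1s1: 3 with participant mean 3.625 -> -0.625
  agg <- stats::aggregate(score ~ participant + day + stimtype,
                          as.data.frame(lt), mean)
  lt4 <- long_table(agg, "score", "participant",
                    factors = c("day", "stimtype"))
  cen <- center_by_unit(lt4, "participant")
  p1 <- cen$score[cen$participant == "Participant 1" &
                  cen$day == "day1" & cen$stimtype == "s1"]
  expect_equal(p1, -0.625)
  # per-unit means are zero
  expect_true(all(abs(tapply(cen$score, cen$participant, mean)) < 1e-12))
  # idempotent
  cen2 <- center_by_unit(cen, "participant")
  expect_equal(cen2$score, cen$score)
  # constant unit -> all zeros
  cst <- data.frame(participant = rep("p1", 3), cond = c("a", "b", "a"),
                    rep = 1:3, y = c(7, 7, 7))
  ltc <- long_table(cst, "y", "participant", factors = "cond",
                    replicate = "rep")
  expect_equal(center_by_unit(ltc, "participant")$y, c(0, 0, 0))
  expect_error(center_by_unit(lt4, "nope"), "unknown unit")
})

test_that("cell_summaries reproduces the printed group and cell tables", {
  wm <- load_fixture("wm_between")
  cs <- cell_summaries(wm, "group", collapse_replicates = TRUE)
  expect_equal(cs$mean, c(39.5, 34.5))
  expect_equal(round(cs$sd, 2), c(11.23, 10.78))
  expect_equal(cs$n, c(10L, 10L))

  tb <- load_fixture("twobytwo")
  cs2 <- cell_summaries(tb, c("day", "stimtype"), collapse_replicates = TRUE)
  expect_equal(cs2$mean[order(cs2$day, cs2$stimtype)],
               c(4.5, 5.65, 5.9, 5.05))

  one <- long_table(data.frame(participant = c("p1", "p2"),
                               cond = c("a", "b"), y = c(1, 2)),
                    "y", "participant", factors = "cond")
  expect_warning(cs3 <- cell_summaries(one, "cond"), "single observation")
  expect_true(all(is.na(cs3$sd)))
})

test_that("cell variances and between-cell SS add up to the total SS", {
  lt <- make_within_design(8, c("a", "b"), seed = 42, noise_sd = 2,
                           subj_sd = 3)
  y <- lt$score
  cell <- interaction(lt$a, lt$b)
  cs <- cell_summaries(lt)
  within_ss <- sum((cs$n - 1) * cs$sd^2)
  between_ss <- sum(cs$n * (cs$mean - mean(y))^2)
  expect_equal(within_ss + between_ss, sum((y - mean(y))^2))
})
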