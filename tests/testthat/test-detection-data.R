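make_records <- function(site, species, times, counts = 1, burst = NULL) {
  data.frame(site_id = site, species = species, datetime = times,
             count = rep_len(counts, length(times)),
             burst_id = if (is.null(burst)) rep(NA_character_, length(times))
                        else burst)
}

test_that("a 3-photo burst collapses to one event with first time and max count", {
  rec <- make_records("S1", "tiger",
                      c("2023-01-05T06:00:00", "2023-01-05T06:00:01",
                        "2023-01-05T06:00:02"),
                      counts = c(2, 2, 1), burst = "b1")
  ev <- collapse_bursts(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$count, 2)
  expect_equal(ev$n_photos, 3L)
  expect_equal(format(ev$datetime, "%H:%M:%S"), "06:00:00")
})

test_that("zero records collapse to zero events", {
  ev <- collapse_bursts(make_records(character(), character(), character())[0, ])
  expect_equal(nrow(ev), 0)
})

test_that("burst ids partition interleaved photos into the right events", {
  rec <- make_records("S1", "tiger",
                      paste0("2023-01-05T06:00:0", 0:5),
                      burst = rep(c("a", "b"), 3))
  ev <- collapse_bursts(rec)
  # brute force: one event per distinct (site, species, burst_id)
  expect_equal(nrow(ev), length(unique(paste(rec$site_id, rec$species, rec$burst_id))))
})

test_that("the 30 s gap rule groups photos when burst ids are absent", {
  rec <- make_records("S1", "tiger",
                      c("2023-01-05 06:00:00", "2023-01-05 06:00:20",
                        "2023-01-05 06:00:45", "2023-01-05 08:00:00"))
  ev <- collapse_bursts(rec)
  expect_equal(nrow(ev), 2)  # 0/20/45 chain (gaps <= 30 s) then 08:00
  ev10 <- collapse_bursts(rec, gap = 10)
  expect_equal(nrow(ev10), 4)
})

test_that("unparseable timestamps are rejected with a warning and counted", {
  rec <- make_records("S1", "tiger",
                      c("2023-01-05 06:00:00", "not-a-time"), burst = c("a", "b"))
  expect_warning(ev <- collapse_bursts(rec), "unparseable")
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "n_rejected"), 1)
})

test_that("event tables are invariant to input row order", {
  st <- sim_study(tiny_config(seed = 19))
  rec <- st$records
  set.seed(1)
  shuffled <- rec[sample.int(nrow(rec)), ]
  a <- collapse_bursts(rec)
  b <- collapse_bursts(shuffled)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("build_history places events in the right occasion cells", {
  effort <- data.frame(site_id = c("A", "B", "C"),
                       start = as.Date("2023-01-01"),
                       end = as.Date("2023-01-04"))
  ev <- data.frame(site_id = c("A", "A", "B", "C", "C"),
                   species = "tiger",
                   datetime = as.POSIXct(c("2023-01-01 05:00:00",
                                           "2023-01-03 22:00:00",
                                           "2023-01-02 10:00:00",
                                           "2023-01-04 01:00:00",
                                           "2023-01-04 02:00:00"), tz = "UTC"))
  h <- build_history(ev, "tiger", effort)
  manual <- rbind(A = c(1, 0, 1, 0), B = c(0, 1, 0, 0), C = c(0, 0, 0, 1))
  expect_equal(unname(h$y), unname(manual))
  # two same-day events at C collapse to a single binary cell
  expect_equal(unname(h$y["C", 4]), 1)
  # total 1-cells cannot exceed total events
  expect_lte(sum(h$y == 1), nrow(ev))
})

test_that("no events give an all-zero unmasked history", {
  effort <- data.frame(site_id = c("A", "B"), start = as.Date("2023-01-01"),
                       end = as.Date("2023-01-03"))
  ev <- collapse_bursts(make_records(character(), character(), character())[0, ])
  h <- build_history(ev, "tiger", effort)
  expect_true(all(h$y == 0))
  expect_false(anyNA(h$y))
})

test_that("occasions outside a camera's active range are masked", {
  effort <- data.frame(site_id = c("A", "B"),
                       start = as.Date(c("2023-01-01", "2023-01-03")),
                       end = as.Date(c("2023-01-02", "2023-01-04")))
  ev <- data.frame(site_id = "A", species = "tiger",
                   datetime = as.POSIXct("2023-01-01 12:00:00", tz = "UTC"))
  h <- build_history(ev, "tiger", effort)
  expect_true(all(is.na(h$y["A", 3:4])))
  expect_true(all(is.na(h$y["B", 1:2])))
  expect_equal(unname(h$y["A", 1]), 1)
})

test_that("multi-day occasions aggregate dates", {
  effort <- data.frame(site_id = "A", start = as.Date("2023-01-01"),
                       end = as.Date("2023-01-06"))
  ev <- data.frame(site_id = "A", species = "tiger",
                   datetime = as.POSIXct(c("2023-01-02 12:00:00",
                                           "2023-01-06 12:00:00"), tz = "UTC"))
  h <- build_history(ev, "tiger", effort, occasion_days = 3)
  expect_equal(unname(h$y), matrix(c(1, 1), 1))
})

test_that("events at unknown sites are an error naming the site", {
  effort <- data.frame(site_id = "A", start = as.Date("2023-01-01"),
                       end = as.Date("2023-01-03"))
  ev <- data.frame(site_id = "ZZ", species = "tiger",
                   datetime = as.POSIXct("2023-01-01 12:00:00", tz = "UTC"))
  expect_error(build_history(ev, "tiger", effort), "ZZ")
})

test_that("count covariate sums photo-level counts, not events", {
  rec <- rbind(
    make_records("S1", "human", paste0("2023-01-05T06:00:0", 0:2),
                 counts = c(2, 2, 1), burst = "b1"),
    make_records("S1", "cattle", "2023-01-05T07:00:00", counts = 4, burst = "b2"),
    make_records("S2", "human", "2023-01-05T08:00:00", counts = 3, burst = "b3"))
  expect_equal(count_covariate(rec, "human"),
               c(S1 = 5, S2 = 3))  # photo-level sum across the burst
  expect_equal(count_covariate(rec, c("cattle", "buffalo", "goat")),
               c(S1 = 4, S2 = 0))
  expect_equal(unname(count_covariate(rec, "leopard")), c(0, 0))
  # brute force on a shuffled mixed table
  set.seed(4)
  shuf <- rec[sample.int(nrow(rec)), ]
  brute <- tapply(shuf$count[shuf$species == "human"],
                  shuf$site_id[shuf$species == "human"], sum)
  got <- count_covariate(shuf, "human")[names(brute)]
  expect_equal(as.numeric(got), as.numeric(brute))
})

test_that("clock times map to the circle as 2*pi * fraction of day", {
  expect_equal(to_radians("00:00:00"), 0)
  expect_equal(to_radians("12:00:00"), pi)
  expect_equal(to_radians("18:00:00"), 3 * pi / 2)
  expect_equal(to_radians(6), pi / 2)
  tt <- as.POSIXct("2023-01-05 12:00:00", tz = "UTC")
  expect_equal(to_radians(tt), pi)
  expect_true(all(to_radians(runif(50, 0, 24)) < 2 * pi))
})

test_that("diel samples use collapsed events, optionally thinned to one per hour", {
  rec <- rbind(
    make_records("S1", "tiger", c("2023-01-05T06:10:00", "2023-01-05T06:40:00"),
                 burst = c("a", "b")),
    make_records("S1", "tiger", "2023-01-05T09:00:00", burst = "c"))
  ev <- collapse_bursts(rec)
  expect_length(diel_sample(ev, "tiger"), 3)
  expect_length(diel_sample(ev, "tiger", mode = "hourly"), 2)
})
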