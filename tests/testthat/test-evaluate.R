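make_events <- function(starts, ends, dirs) {
  data.frame(start_s = starts, end_s = ends,
             duration = ends - starts, direction = dirs,
             klass = rep("effective", length(starts)),
             delta_dz = ifelse(dirs == "SiSt", 0.25, -0.25),
             stringsAsFactors = FALSE)
}

test_that("matching handles identical, empty and jittered event lists", {
  ref <- annotation_set(c(10, 40, 70, 100, 130),
                        c(12, 42, 72, 102, 132),
                        rep(c("SiSt", "StSi"), length.out = 5))
  det <- make_events(ref$start, ref$end, ref$direction)
  m <- match_events(det, ref)
  expect_equal(m$tp, 5L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  met <- contingency_metrics(m$tp, m$fp, m$fn)
  expect_equal(met$sensitivity, 100)
  expect_equal(met$ppv, 100)

  m0 <- match_events(make_events(numeric(0), numeric(0), character(0)), ref)
  expect_equal(m0$tp, 0L)
  expect_equal(m0$fn, 5L)

  # jitter below the tolerance: everything still matches one-to-one
  set.seed(6)
  starts <- seq(10, 200, by = 10)[1:20]
  ref2 <- annotation_set(starts, starts + 2,
                         rep(c("SiSt", "StSi"), 10))
  jit <- runif(20, -1, 1)
  det2 <- make_events(starts + jit, starts + 2 + jit, ref2$direction)
  m2 <- match_events(det2, ref2)
  expect_equal(m2$tp, 20L)
  expect_equal(m2$direction_matches, 20L)
})

test_that("greedy midpoint matching is optimal on small instances", {
  # exhaustive assignment oracle: maximize matched pairs within tolerance
  exhaustive_best <- function(mid_d, mid_r, tol) {
    best <- 0L
    assign_next <- function(d, used_r, count) {
      if (d > length(mid_d)) { best <<- max(best, count); return() }
      assign_next(d + 1L, used_r, count)
      for (r in seq_along(mid_r)) {
        if (!used_r[r] && abs(mid_d[d] - mid_r[r]) <= tol) {
          used_r[r] <- TRUE
          assign_next(d + 1L, used_r, count + 1L)
          used_r[r] <- FALSE
        }
      }
    }
    assign_next(1L, logical(length(mid_r)), 0L)
    best
  }
  set.seed(77)
  for (rep in 1:20) {
    nd <- sample(0:5, 1); nr <- sample(1:5, 1)
    mid_d <- sort(runif(nd, 0, 30))
    mid_r <- cumsum(runif(nr, 2, 8))  # spaced: reference events disjoint
    det <- make_events(mid_d - 1, mid_d + 1, rep("SiSt", nd))
    ref <- annotation_set(mid_r - 0.5, mid_r + 0.5, rep("SiSt", nr))
    m <- match_events(det, ref, tolerance_s = 2)
    expect_equal(m$tp, exhaustive_best(mid_d, mid_r, 2))
  }
})

test_that("shrinking the tolerance never gains true positives", {
  set.seed(15)
  starts <- 20 * (1:15) + runif(15, -5, 5)
  ref <- annotation_set(starts, starts + 2, rep("SiSt", 15))
  det <- make_events(starts + runif(15, -3, 3),
                     starts + 2 + runif(15, -3, 3), rep("SiSt", 15))
  tps <- sapply(c(4, 2, 1, 0.5), function(tol)
    match_events(det, ref, tolerance_s = tol)$tp)
  expect_true(all(diff(tps) <= 0))
})

test_that("contingency metrics reproduce printed validation rows and
           handle undefined cases", {
  rows <- list(
    list(tp = 888, fp = 176, fn = 113, sens = 89, ppv = 83),
    list(tp = 265, fp = 42, fn = 6, sens = 98, ppv = 86),
    list(tp = 533, fp = 61, fn = 67, sens = 89, ppv = 90),
    list(tp = 89, fp = 73, fn = 40, sens = 69, ppv = 55))
  for (r in rows) {
    met <- contingency_metrics(r$tp, r$fp, r$fn)
    expect_equal(round(met$sensitivity), r$sens)
    expect_equal(round(met$ppv), r$ppv)
  }
  und <- contingency_metrics(0, 0, 5)
  expect_equal(und$sensitivity, 0)
  expect_true(is.na(und$ppv))
  expect_error(contingency_metrics(-1, 0, 0), "negative")
})

test_that("group-wise matching counts sum to the pooled report", {
  # two participants with disjoint time ranges; pooling their events and
  # references must pool the contingency counts
  refA <- annotation_set(c(10, 30, 50), c(12, 32, 52),
                         c("SiSt", "StSi", "SiSt"))
  detA <- make_events(c(10.2, 50.3), c(12.2, 52.3), c("SiSt", "SiSt"))
  refB <- annotation_set(c(110, 130), c(112, 132), c("StSi", "SiSt"))
  detB <- make_events(c(110.1, 120, 130.4), c(112.1, 122, 132.4),
                      c("StSi", "SiSt", "SiSt"))
  mA <- match_events(detA, refA)
  mB <- match_events(detB, refB)
  pooled <- match_events(rbind(detA, detB),
                         annotation_set(c(refA$start, refB$start),
                                        c(refA$end, refB$end),
                                        c(refA$direction, refB$direction)))
  expect_equal(pooled$tp, mA$tp + mB$tp)
  expect_equal(pooled$fp, mA$fp + mB$fp)
  expect_equal(pooled$fn, mA$fn + mB$fn)
})

test_that("duration agreement statistics follow their definitions", {
  m0 <- data.frame(dur_alg = c(2, 3, 2.5), dur_ref = c(2, 3, 2.5))
  d0 <- duration_agreement(m0)
  expect_equal(d0$mean_duration_diff, 0)
  expect_equal(d0$diff_ci95, c(0, 0))

  m1 <- data.frame(dur_alg = c(2.5, 1.5), dur_ref = c(2, 2))
  d1 <- duration_agreement(m1)
  expect_equal(d1$mean_duration_diff, 0)
  expect_equal(d1$sd_duration_diff, sqrt(0.5), tolerance = 1e-12)

  expect_error(duration_agreement(m1[1, , drop = FALSE]), "insufficient")

  # Welch comparison of two groups of durations
  m2 <- data.frame(dur_alg = c(rnorm(10, 2, 0.1), rnorm(10, 1.7, 0.1)),
                   dur_ref = 2)
  d2 <- duration_agreement(m2, group = rep(c("PD", "OA"), each = 10))
  expect_s3_class(d2$welch, "htest")
  oracle <- stats::t.test(m2$dur_alg[11:20], m2$dur_alg[1:10])  # OA first
  expect_equal(d2$welch$statistic, oracle$statistic)
})
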