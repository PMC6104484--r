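#' Match detected transitions to reference annotations
#'
#' Greedy one-to-one matching by ascending midpoint distance: the closest
#' detected/reference pair within the tolerance is matched first, then
#' the next closest among the remaining events, and so on. Matched pairs
#' are true positives, unmatched detections false positives, unmatched
#' references false negatives. Only effective transitions should be
#' supplied (attempts are excluded from validation).
#'
#' @param detected a `pt_events` data.frame of effective events.
#' @param reference an [annotation_set()].
#' @param tolerance_s maximum midpoint distance for a match, s.
#' @return list with counts `tp`, `fp`, `fn`, `direction_matches`, and a
#'   `matches` data.frame (`det`, `ref` row indices, `offset_s`,
#'   `dur_alg`, `dur_ref`, `dir_alg`, `dir_ref`).
#' @export
match_events <- function(detected, reference, tolerance_s = 2) {
  nd <- nrow(detected)
  nr <- nrow(reference)
  mid_d <- (detected$start_s + detected$end_s) / 2
  mid_r <- (reference$start + reference$end) / 2
  pairs <- NULL
  if (nd && nr) {
    diff <- abs(outer(mid_d, mid_r, "-"))
    ok <- which(diff <= tolerance_s, arr.ind = TRUE)
    if (nrow(ok)) {
      o <- order(diff[ok], ok[, 1], ok[, 2])
      ok <- ok[o, , drop = FALSE]
      used_d <- logical(nd); used_r <- logical(nr)
      keep <- logical(nrow(ok))
      for (i in seq_len(nrow(ok))) {
        d <- ok[i, 1]; r <- ok[i, 2]
        if (!used_d[d] && !used_r[r]) {
          keep[i] <- TRUE
          used_d[d] <- TRUE; used_r[r] <- TRUE
        }
      }
      ok <- ok[keep, , drop = FALSE]
      pairs <- data.frame(det = ok[, 1], ref = ok[, 2],
                          offset_s = mid_d[ok[, 1]] - mid_r[ok[, 2]],
                          dur_alg = detected$duration[ok[, 1]],
                          dur_ref = reference$end[ok[, 2]] -
                            reference$start[ok[, 2]],
                          dir_alg = detected$direction[ok[, 1]],
                          dir_ref = reference$direction[ok[, 2]],
                          stringsAsFactors = FALSE)
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(det = integer(0), ref = integer(0),
                        offset_s = numeric(0), dur_alg = numeric(0),
                        dur_ref = numeric(0), dir_alg = character(0),
                        dir_ref = character(0), stringsAsFactors = FALSE)
  tp <- nrow(pairs)
  list(tp = tp, fp = nd - tp, fn = nr - tp,
       direction_matches = sum(pairs$dir_alg == pairs$dir_ref),
       matches = pairs)
}

#' Event-level contingency metrics
#'
#' Sensitivity `100 TP / (TP + FN)`, positive predictive value
#' `100 TP / (TP + FP)` and accuracy `100 TP / (TP + FP + FN)` from
#' event-matching counts. Metrics with a zero denominator are undefined
#' and returned as `NA`. Full precision is retained; round only for
#' display.
#'
#' @param tp,fp,fn true positive, false positive and false negative
#'   counts.
#' @return list with `sensitivity`, `ppv`, `accuracy`, in percent.
#' @export
contingency_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("validation error: negative counts")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  acc <- if (tp + fp + fn > 0) 100 * tp / (tp + fp + fn) else NA_real_
  list(sensitivity = sens, ppv = ppv, accuracy = acc)
}

#' Duration agreement between algorithm and reference
#'
#' Per-pair duration differences (algorithm minus reference) with mean,
#' SD and limits of agreement (mean plus/minus 1.96 SD), plus group
#' means/SDs of the algorithm durations. When two groups of algorithm
#' durations are supplied, a Welch two-sample t test compares them.
#'
#' @param matches a matches data.frame from [match_events()] with at
#'   least 2 rows.
#' @param group optional factor splitting the matches into two groups for
#'   the Welch test.
#' @return list with `n`, `duration_mean_alg`, `duration_sd_alg`,
#'   `duration_mean_ref`, `mean_duration_diff`, `sd_duration_diff`,
#'   `diff_ci95` (length-2), `mean_abs_diff`, and when `group` is given,
#'   `group_stats` and `welch` (the `htest`).
#' @export
duration_agreement <- function(matches, group = NULL) {
  if (nrow(matches) < 2L)
    stop("insufficient data: need at least 2 matched pairs")
  d <- matches$dur_alg - matches$dur_ref
  m <- mean(d); s <- stats::sd(d)
  out <- list(n = nrow(matches),
              duration_mean_alg = mean(matches$dur_alg),
              duration_sd_alg = stats::sd(matches$dur_alg),
              duration_mean_ref = mean(matches$dur_ref),
              mean_duration_diff = m,
              sd_duration_diff = s,
              diff_ci95 = c(m - 1.96 * s, m + 1.96 * s),
              mean_abs_diff = mean(abs(d)))
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
    sp <- split(matches$dur_alg, group)
    out$group_stats <- lapply(sp, function(x)
      c(mean = mean(x), sd = stats::sd(x), n = length(x)))
    out$welch <- stats::t.test(sp[[1]], sp[[2]])
  }
  out
}

#' Evaluate a detection result against reference annotations
#'
#' Matches effective detected transitions to the reference and assembles
#' the full validation report: contingency counts and metrics, direction
#' accuracy over matched pairs, and duration agreement.
#'
#' @param detection a `pt_detection` object (from [pt_detect()]) or a
#'   `pt_events` data.frame of effective events.
#' @param reference an [annotation_set()].
#' @param tolerance_s matching tolerance on event midpoints, s.
#' @return An object of class `pt_evaluation`: list with `tp`, `fp`,
#'   `fn`, `sensitivity`, `ppv`, `accuracy`, `direction_accuracy`
#'   (percent over matched pairs), `duration` (see
#'   [duration_agreement()]; `NULL` with fewer than 2 matches) and
#'   `matches`.
#' @export
pt_evaluate <- function(detection, reference, tolerance_s = 2) {
  detected <- if (inherits(detection, "pt_detection"))
    detection$effective else detection
  mt <- match_events(detected, reference, tolerance_s)
  met <- contingency_metrics(mt$tp, mt$fp, mt$fn)
  dir_acc <- if (mt$tp > 0) 100 * mt$direction_matches / mt$tp else NA_real_
  dur <- if (mt$tp >= 2L) duration_agreement(mt$matches) else NULL
  structure(c(list(tp = mt$tp, fp = mt$fp, fn = mt$fn),
              met,
              list(direction_accuracy = dir_acc, duration = dur,
                   matches = mt$matches, tolerance_s = tolerance_s)),
            class = "pt_evaluation")
}

#' @export
print.pt_evaluation <- function(x, ...) {
  cat("Postural transition evaluation (tolerance",
      x$tolerance_s, "s)\n")
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.0f%%", v)
  cat("  sensitivity:", fmt(x$sensitivity),
      " PPV:", fmt(x$ppv), " accuracy:", fmt(x$accuracy), "\n")
  cat("  direction accuracy:", fmt(x$direction_accuracy), "\n")
  if (!is.null(x$duration))
    cat(sprintf(
      "  duration: alg %.2f (%.2f) s, diff %.2f s, 95%% LoA [%.2f, %.2f]\n",
      x$duration$duration_mean_alg, x$duration$duration_sd_alg,
      x$duration$mean_duration_diff, x$duration$diff_ci95[1],
      x$duration$diff_ci95[2]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `pt_evaluation`.
#' @param path output file path.
#' @export
write_evaluation_json <- function(report, path) {
  out <- unclass(report)
  out$matches <- NULL
  if (!is.null(out$duration)) out$duration$welch <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Run the simulate/detect/evaluate pipeline on the synthetic benchmark
#'
#' Convenience wrapper: simulates the default benchmark session for a
#' seed, runs detection and evaluates against the simulated ground
#' truth. Deterministic per seed.
#'
#' @param seed integer seed for [default_benchmark()].
#' @param control a [pt_control()] list.
#' @param dyskinesia passed to [default_benchmark()].
#' @return a `pt_evaluation` with the `pt_detection` attached as
#'   attribute `"detection"`.
#' @export
run_pipeline <- function(seed = 1L, control = pt_control(),
                         dyskinesia = FALSE) {
  sim <- default_benchmark(seed, dyskinesia = dyskinesia)
  det <- pt_detect(sim$recording, control, keep_series = FALSE)
  ev <- pt_evaluate(det, sim$truth$annotation,
                    tolerance_s = control$evaluate$tolerance_s)
  attr(ev, "detection") <- det
  ev
}
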