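abstract_ds <- function(conf, area, ...) {
  detection_set(masks = NULL, confidence = conf, area_px = area, ...)
}

test_that("seed-set selection follows the nearest-rank percentile with ties kept", {
  ds <- abstract_ds(seq(0.50, 0.95, by = 0.05), rep(100, 10))
  expect_equal(sort(ds$confidence[select_top_confidence(ds, 0.90)]), c(0.90, 0.95))
  # all confidences equal: everything is at the threshold, all selected
  ds_eq <- abstract_ds(rep(0.8, 7), rep(100, 7))
  expect_equal(select_top_confidence(ds_eq, 0.90), 1:7)
  # a single detection is its own seed set
  expect_equal(select_top_confidence(abstract_ds(0.6, 50), 0.90), 1L)
  expect_equal(select_top_confidence(abstract_ds(numeric(), numeric()), 0.9), integer())
})

test_that("mean-area partition assigns equality to the large side", {
  p <- partition_by_mean_area(c(100, 100, 100))
  expect_equal(p$mean_area, 100)
  expect_length(p$small, 0)
  expect_equal(p$large, 1:3)
  p2 <- partition_by_mean_area(c(50, 150))
  expect_equal(p2$small, 1L)
  expect_equal(p2$large, 2L)
  p3 <- partition_by_mean_area(c(10, 10, 10, 300))
  expect_equal(p3$mean_area, 82.5)
  expect_length(p3$small, 3)
  expect_length(p3$large, 1)
})

test_that("optimal-area inference takes the documented branch in each regime", {
  # small side more numerous AND more confident -> small branch
  areas <- c(10, 10, 10, 300)
  confs <- c(0.95, 0.95, 0.95, 0.91)
  opt <- infer_area_optimal(areas, confs)
  expect_equal(opt$branch, "small")
  expect_equal(opt$area_optimal, 10)
  # small side more numerous but less confident -> fallback to the large side
  opt_fb <- infer_area_optimal(areas, c(0.80, 0.80, 0.80, 0.99))
  expect_equal(opt_fb$branch, "fallback")
  expect_equal(opt_fb$area_optimal, 300)
  # equal-sized sides -> mean of the whole seed set
  opt_tie <- infer_area_optimal(c(50, 150), c(0.9, 0.9))
  expect_equal(opt_tie$branch, "tie")
  expect_equal(opt_tie$area_optimal, 100)
  # single detection sits at (>=) its own mean: large branch, survives
  opt_one <- infer_area_optimal(100, 0.7)
  expect_equal(opt_one$branch, "large")
  expect_equal(opt_one$area_optimal, 100)
})

test_that("acceptance band is strict below and inclusive above", {
  # ten confident detections pin area_optimal at exactly 100; two low-confidence
  # probes sit exactly on the band edges
  ds <- abstract_ds(
    conf = c(rep(0.9, 10), 0.5, 0.5),
    area = c(rep(100, 10), 150, 65)
  )
  out <- apply_statistical_filter(ds)
  tr <- filter_trace(out)
  expect_equal(tr$area_optimal, 100)
  expect_true(11L %in% tr$accepted)   # area == 1.5 * area_optimal: kept
  expect_false(12L %in% tr$accepted)  # area == 0.65 * area_optimal: rejected
})

test_that("empty and singleton detection sets pass through the filter sanely", {
  empty <- abstract_ds(numeric(), numeric())
  out <- apply_statistical_filter(empty)
  expect_equal(nrow(out), 0)
  expect_equal(filter_trace(out)$note, "empty input")
  single <- abstract_ds(0.8, 440)
  out1 <- apply_statistical_filter(single)
  expect_equal(nrow(out1), 1) # own band always contains own area
  expect_equal(filter_trace(out1)$branch_taken, "large")
})

test_that("a constructed mixed set keeps exactly the true-scale detections", {
  withr::with_seed(11, {
    ds <- abstract_ds(
      conf = c(runif(15, 0.92, 0.98), runif(5, 0.5, 0.6)),
      area = c(rnorm(15, 400, 12), rnorm(5, 50, 5)),
      is_true = rep(c(TRUE, FALSE), c(15, 5))
    )
  })
  out <- apply_statistical_filter(ds)
  expect_equal(nrow(out), 15)
  expect_true(all(out$is_true))
  # agrees with the independent step-by-step oracle
  expect_equal(filter_trace(out)$accepted, brute_force_filter(ds$confidence, ds$area_px))
})

test_that("filter matches the brute-force oracle across random detection sets", {
  withr::with_seed(2024, {
    for (k in 1:200) {
      ds <- random_detection_tibble(sample(0:60, 1))
      got <- filter_trace(apply_statistical_filter(ds))$accepted
      want <- brute_force_filter(ds$confidence, ds$area_px)
      expect_equal(got, want)
    }
  })
})

test_that("filter output is a subset and never grows", {
  withr::with_seed(5, {
    for (k in 1:20) {
      ds <- random_detection_tibble(sample(1:80, 1))
      out <- apply_statistical_filter(ds)
      expect_lte(nrow(out), nrow(ds))
      expect_true(all(filter_trace(out)$accepted %in% seq_len(nrow(ds))))
    }
  })
})

test_that("filter is invariant to a global rescaling of areas", {
  withr::with_seed(13, {
    for (k in 1:20) {
      ds <- random_detection_tibble(sample(1:60, 1))
      base <- apply_statistical_filter(ds)
      for (scale in c(3, 7, 1e3)) {
        scaled <- abstract_ds(ds$confidence, ds$area_px * scale)
        out <- apply_statistical_filter(scaled)
        expect_equal(filter_trace(out)$accepted, filter_trace(base)$accepted)
        expect_equal(
          filter_trace(out)$area_optimal,
          filter_trace(base)$area_optimal * scale,
          tolerance = 1e-12
        )
      }
    }
  })
})

test_that("adding a below-threshold in-band detection never evicts accepted ones", {
  withr::with_seed(21, {
    for (k in 1:20) {
      ds <- random_detection_tibble(sample(2:60, 1))
      tr <- filter_trace(apply_statistical_filter(ds))
      if (!length(tr$accepted)) next
      thr <- min(ds$confidence[tr$set_A])
      new_conf <- max(0, thr - 0.05)
      if (new_conf >= thr) next
      new_area <- mean(ds$area_px[tr$accepted]) # safely inside the band
      ds2 <- abstract_ds(c(ds$confidence, new_conf), c(ds$area_px, new_area))
      tr2 <- filter_trace(apply_statistical_filter(ds2))
      expect_true(all(tr$accepted %in% tr2$accepted))
    }
  })
})

test_that("filter traces serialise to JSON with the full audit trail", {
  ds <- abstract_ds(c(0.9, 0.95, 0.5), c(100, 110, 20))
  tr <- filter_trace(apply_statistical_filter(ds))
  js <- jsonlite::fromJSON(filter_trace_json(tr))
  expect_equal(js$n_input, 3)
  expect_equal(js$area_optimal, tr$area_optimal)
  expect_equal(js$accepted, tr$accepted)
  expect_equal(js$config$coeff_low, 0.65)
})

test_that("filter configuration validates its invariants", {
  expect_error(filter_config(confidence_quantile = 1))
  expect_error(filter_config(coeff_low = 1.2))
  expect_error(filter_config(coeff_high = 0.9))
})
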