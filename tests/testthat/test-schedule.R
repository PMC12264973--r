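arr10 <- build_electrode_array(10, 10, 400)

expect_partition <- function(sched, n_elec, n_groups) {
  for (ep in seq_len(ncol(sched$assignments))) {
    g <- sched$assignments[, ep]
    expect_setequal(unique(g), seq_len(n_groups))
    sizes <- tabulate(g, n_groups)
    expect_true(max(sizes) - min(sizes) <= 1)
    expect_equal(sum(sizes), n_elec)
  }
}

test_that("raster clock arithmetic is exact in render-frame units", {
  ck <- raster_clock(90, frames_per_group = 4, n_groups = 5)
  expect_equal(ck$group_event_rate_hz, 22.5)
  expect_equal(ck$cycle_ms, 5 * 4 * 1000 / 90)
  expect_equal(round(ck$group_interval_ms, 1), 44.4)
  expect_equal(round(ck$cycle_ms), 222)
  # the fast configuration: one frame per group, 18 full cycles per second
  fast <- raster_clock(90, frames_per_group = 1, n_groups = 5)
  expect_equal(fast$cycle_rate_hz, 18)
  expect_equal(round(fast$cycle_ms, 1), 55.6)
  # group interval may be given in ms if consistent with the render period
  ck2 <- raster_clock(90, group_interval_ms = 44.4, n_groups = 5)
  expect_equal(ck2$frames_per_group, 4L)
  expect_error(raster_clock(90, group_interval_ms = 30), "multiple")
})

test_that("horizontal and vertical schedules band rows/columns in scan order", {
  h <- horizontal_schedule(arr10, 5)
  expect_equal(sort(which(h$assignments[, 1] == 1)),
               which(arr10$row %in% 0:1))
  expect_length(which(h$assignments[, 1] == 1), 20)
  expect_equal(h$group_order, 1:5)

  v <- vertical_schedule(arr10, 5)
  expect_equal(sort(which(v$assignments[, 1] == 1)),
               which(arr10$col %in% 0:1))

  # vertical equals horizontal applied to the transposed grid
  tr <- arr10
  tmp <- tr$row; tr$row <- tr$col; tr$col <- tmp
  attr(tr, "rows") <- attr(arr10, "cols"); attr(tr, "cols") <- attr(arr10, "rows")
  ht <- horizontal_schedule(tr, 5)
  expect_equal(ht$assignments[, 1], v$assignments[, 1])

  # single group and indivisible geometry
  expect_equal(unique(horizontal_schedule(arr10, 1)$assignments[, 1]), 1L)
  expect_error(horizontal_schedule(arr10, 4), "bands")
})

test_that("every pattern yields an equal-size partition for 4 and 5 groups", {
  for (ng in c(4L, 5L)) {
    pats <- if (ng == 5L) c("horizontal", "vertical", "checkerboard", "random")
            else c("checkerboard", "random")  # 10 rows do not band into 4
    for (p in pats) {
      s <- make_schedule(p, arr10, ng, seed = 7, n_epochs = 3)
      expect_partition(s, 100, ng)
    }
  }
})

test_that("checkerboard search certifies the modular optimum", {
  cb <- checkerboard_schedule(arr10, 5)
  expect_equal(unname(attr(cb, "modular_ab")), c(1, 2))
  d_cb <- attr(cb, "min_within_group_nn_um")
  expect_equal(d_cb, sqrt(5) * 400, tolerance = 1e-9)

  # brute-force recomputation of the objective from the assignment itself
  g <- cb$assignments[, 1]
  mins <- sapply(1:5, function(k) {
    xy <- cbind(arr10$x_um, arr10$y_um)[g == k, ]
    min(dist(xy))
  })
  expect_equal(min(mins), sqrt(5) * 400, tolerance = 1e-9)
  expect_equal(tabulate(g, 5), rep(20L, 5))

  # strictly better spacing than the band patterns (1 x pitch)
  for (s in list(horizontal_schedule(arr10, 5), vertical_schedule(arr10, 5))) {
    gb <- s$assignments[, 1]
    d <- min(sapply(1:5, function(k)
      min(dist(cbind(arr10$x_um, arr10$y_um)[gb == k, ]))))
    expect_equal(d, 400)
    expect_gt(d_cb, d)
  }
})

test_that("random schedule is seeded, balanced, and long-run uniform", {
  s1 <- random_schedule(arr10, 5, reshuffle_every = 5, seed = 42, n_epochs = 10)
  s2 <- random_schedule(arr10, 5, reshuffle_every = 5, seed = 42, n_epochs = 10)
  expect_identical(s1$assignments, s2$assignments)
  s3 <- random_schedule(arr10, 5, reshuffle_every = 5, seed = 43, n_epochs = 10)
  expect_false(identical(s1$assignments, s3$assignments))
  expect_error(random_schedule(arr10, 5, 5), "seed")

  # 1000 reshuffles: electrode-group frequencies are uniform. 500
  # simultaneous binomial counts are checked, so the per-cell band is 4
  # sigma (family-wise ~0.03 expected violations; a per-cell 3-sigma band
  # would flag ~1.4 cells for any correct sampler), plus an aggregate
  # goodness-of-fit check
  big <- random_schedule(arr10, 5, reshuffle_every = 5, seed = 11,
                         n_epochs = 1000)
  counts <- t(apply(big$assignments, 1, tabulate, nbins = 5))
  sigma <- sqrt(1000 * 0.2 * 0.8)
  expect_true(all(abs(counts - 200) <= 4 * sigma))
  expect_lt(mean(abs(counts - 200) > 3 * sigma), 0.01)
  chisq <- sum((counts - 200)^2 / 200)
  expect_lt(chisq, qchisq(0.999, df = 100 * 4))
})

test_that("apparent motion index captures scan coherence", {
  # single group: no transitions, zero index
  one <- horizontal_schedule(arr10, 1)
  am1 <- apparent_motion_index(one, arr10)
  expect_equal(am1$consistency, 0)
  expect_equal(am1$drift_um, c(0, 0))

  # horizontal scan: pure downward drift, perfectly consistent
  amh <- apparent_motion_index(horizontal_schedule(arr10, 5), arr10)
  expect_equal(amh$consistency, 1)
  expect_equal(amh$drift_um[1], 0)
  expect_lt(amh$drift_um[2], 0)  # top-to-bottom scan, y decreasing

  # vertical scan: pure rightward drift
  amv <- apparent_motion_index(vertical_schedule(arr10, 5), arr10)
  expect_equal(amv$consistency, 1)
  expect_gt(amv$drift_um[1], 0)
  expect_equal(amv$drift_um[2], 0)

  # checkerboard beats both band scans
  amc <- apparent_motion_index(checkerboard_schedule(arr10, 5), arr10)
  expect_lt(amc$consistency, min(amh$consistency, amv$consistency))
})

test_that("schedules serialize to a plain table", {
  s <- random_schedule(arr10, 5, reshuffle_every = 5, seed = 3, n_epochs = 2)
  tab <- schedule_table(s)
  expect_equal(nrow(tab), 200)
  expect_named(tab, c("electrode_id", "epoch", "group", "order"))
  # table reproduces the assignment matrix exactly
  for (ep in 1:2)
    expect_equal(tab$group[tab$epoch == ep], s$assignments[, ep])
  # round trip through CSV is lossless
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_equal(read.csv(f, stringsAsFactors = FALSE), tab)
})
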