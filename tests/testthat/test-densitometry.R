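dens_table <- function(species, time, intensity, replicate = 1L) {
  data.frame(species = species, time = time, replicate = replicate,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("constant intensities normalize to a flat series at 1", {
  tab <- rbind(dens_table("mature", c(0, 30, 60), c(5, 5, 5)),
               dens_table("Actin", c(0, 30, 60), c(2, 2, 2)))
  out <- normalize_timecourse(tab)
  expect_equal(out$per_replicate$normalized, c(1, 1, 1))
})

test_that("halving species or doubling control both give the same decay", {
  times <- c(0, 30, 60)
  halving <- rbind(dens_table("x", times, c(8, 4, 2)),
                   dens_table("Actin", times, c(3, 3, 3)))
  doubling <- rbind(dens_table("x", times, c(8, 8, 8)),
                    dens_table("Actin", times, c(3, 6, 12)))
  expect_equal(normalize_timecourse(halving)$per_replicate$normalized,
               c(1, 0.5, 0.25))
  # hand-computed ratio chain: (8/6)/(8/3) = 0.5, (8/12)/(8/3) = 0.25
  expect_equal(normalize_timecourse(doubling)$per_replicate$normalized,
               c(1, 0.5, 0.25))
})

test_that("normalization is invariant to per-replicate exposure rescaling", {
  times <- c(0, 20, 40)
  base <- rbind(dens_table("x", times, c(6, 3, 2)),
                dens_table("Actin", times, c(2, 2.2, 1.9)))
  scaled <- base
  scaled$intensity <- scaled$intensity * 7.3
  expect_equal(normalize_timecourse(base)$per_replicate$normalized,
               normalize_timecourse(scaled)$per_replicate$normalized)
})

test_that("replicate summary aggregates mean and standard error", {
  tab <- rbind(dens_table("x", c(0, 30), c(4, 2), replicate = 1L),
               dens_table("x", c(0, 30), c(6, 2.4), replicate = 2L),
               dens_table("Actin", c(0, 30), c(2, 2), replicate = 1L),
               dens_table("Actin", c(0, 30), c(2, 2), replicate = 2L))
  out <- normalize_timecourse(tab)
  s30 <- out$summary[out$summary$time == 30, ]
  expect_equal(s30$mean, mean(c(0.5, 0.4)))
  expect_equal(s30$se, sd(c(0.5, 0.4)) / sqrt(2))
  expect_equal(s30$n, 2L)
})

test_that("normalization errors on missing controls or missing t0", {
  no_t0 <- rbind(dens_table("x", c(10, 30), c(4, 2)),
                 dens_table("Actin", c(10, 30), c(2, 2)))
  expect_error(normalize_timecourse(no_t0), "t = 0")
  zero_ctrl <- rbind(dens_table("x", c(0, 30), c(4, 2)),
                     dens_table("Actin", c(0, 30), c(2, 0)))
  expect_error(normalize_timecourse(zero_ctrl), "> 0")
  expect_error(normalize_timecourse(dens_table("x", 0, 1)), "control")
})

test_that("time to half interpolates exactly and log-linearly", {
  expect_equal(time_to_half(c(0, 30), c(1, 0.5)), 30)
  # exponential decay with 40-min half-life sampled coarsely:
  # log-linear interpolation is exact on an exponential
  tt <- c(0, 15, 30, 60, 120)
  v <- exp(-log(2) / 40 * tt)
  expect_equal(time_to_half(tt, v), 40, tolerance = 0.02)
  expect_equal(time_to_half(tt, v, method = "exponential"), 40,
               tolerance = 1e-6)
})

test_that("time to half on noisy exponentials stays within 2%", {
  set.seed(101)
  lambda <- log(2) / 35
  tt <- c(0, 10, 20, 35, 50, 70)
  v <- exp(-lambda * tt)
  v[-1] <- v[-1] * exp(rnorm(length(tt) - 1, 0, 0.005))
  expect_equal(time_to_half(tt, v), 35, tolerance = 0.02)
})

test_that("series never reaching 50% returns the not-reached sentinel", {
  res <- time_to_half(c(0, 30, 60), c(1, 0.9, 0.8))
  expect_true(is.na(res))
  expect_equal(attr(res, "last_time"), 60)
})

test_that("non-monotone series use the first downward crossing", {
  res <- time_to_half(c(0, 10, 20, 30), c(1, 0.4, 0.7, 0.3))
  expect_lt(res, 10)
  expect_gt(res, 0)
})

test_that("fold change matches a hand-computed Student's t on toy triplets", {
  x <- c(2.0, 2.2, 1.8)
  y <- c(1.0, 1.1, 0.9)
  res <- fold_change_test(x, y)
  expect_equal(res$fold_change, 2.0)
  # textbook pooled-variance t: sp^2 = (2*0.04 + 2*0.01)/4 = 0.025,
  # t = 1 / sqrt(0.025 * 2/3) = sqrt(60) = 7.7459667, df = 4
  expect_equal(res$t, 7.7459666924, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.001496481056, tolerance = 1e-9)
  expect_equal(res$se, sd(x / mean(y)) / sqrt(3))
})

test_that("fold change test is antisymmetric under group swap", {
  x <- c(2.0, 2.2, 1.8); y <- c(1.0, 1.3, 0.9)
  ab <- fold_change_test(x, y)
  ba <- fold_change_test(y, x)
  expect_equal(ab$fold_change * ba$fold_change, 1)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("degenerate and under-replicated inputs are flagged", {
  same <- fold_change_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  diff <- fold_change_test(c(2, 2, 2), c(1, 1, 1))
  expect_equal(diff$fold_change, 2)
  expect_equal(diff$p_value, 0)
  expect_true(diff$degenerate)
  single <- fold_change_test(3, c(1, 1.2))
  expect_equal(single$fold_change, 3 / 1.1)
  expect_true(is.na(single$p_value))
})

test_that("densitometry TSV reader validates its columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- rbind(dens_table("x", c(0, 30), c(4, 2)),
               dens_table("Actin", c(0, 30), c(2, 2)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_densitometry(path), tab)
  write.table(tab[, 1:3], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_densitometry(path), "columns")
})
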