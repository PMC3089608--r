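eight_layer_design <- function(cells = 120000) {
  layers <- paste0("L", 1:8)
  stack_design("s1", layers,
               data.frame(layer_id = layers, condition = "H",
                          cells = cells, fluorophore = "GFP"))
}

test_that("stack totals: cells summed over layers, thickness from count", {
  tot <- stack_total(eight_layer_design())
  expect_equal(tot$cells, 960000)
  expect_equal(tot$thickness_um, 1600)
  expect_equal(stack_total(eight_layer_design(12000))$cells, 96000)
  empty <- stack_design("s0")
  expect_equal(stack_total(empty)$cells, 0)
  expect_equal(stack_total(empty)$thickness_um, 0)
})

test_that("stacks are enumerated per (geometry, replicate) pair", {
  pm <- expand.grid(experiment = paste0("e", 1:6),
                    replicate = paste0("r", 1:8), stringsAsFactors = FALSE)
  maps <- setNames(rep(list(pm), 8), paste0("L", 1:8))
  st <- enumerate_stacks(maps)
  expect_equal(nrow(st), 48L)
  expect_equal(nrow(enumerate_stacks(list(L1 = pm[1, ]))), 1L)
  broken <- maps
  broken$L5 <- pm[-3, ]
  expect_error(enumerate_stacks(broken), "missing on some layers.*L5")
})

test_that("growth table recovers per-layer multipliers and replicate SDs", {
  des <- eight_layer_design()
  mult <- c(2, 1.5, 1, 1, 0.8, 0.6, 0.5, 0.4)
  res <- expand.grid(layer_id = paste0("L", 1:8),
                     replicate = paste0("r", 1:4), stringsAsFactors = FALSE)
  res$cells_est <- 120000 * mult[match(res$layer_id, paste0("L", 1:8))]
  g <- growth_table(res, des)
  expect_equal(g$ratio, mult)
  expect_equal(g$sd_est, rep(0, 8))
  # estimated = seeded everywhere -> all ratios 1
  res1 <- res; res1$cells_est <- 120000
  expect_equal(growth_table(res1, des)$ratio, rep(1, 8))
  # replicate labels are bookkeeping only
  res_shuffled <- res[sample(nrow(res)), ]
  expect_equal(growth_table(res_shuffled, des)$ratio, g$ratio)
  # single replicate: SD absent, not zero
  g1 <- growth_table(res[res$replicate == "r1", ], des)
  expect_true(all(is.na(g1$sd_est)))
  expect_equal(g1$n, rep(1L, 8))
})

test_that("condition comparison handles regular and degenerate groups", {
  x <- c(1, 2, 3, 4)
  same <- compare_conditions(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # constant unequal groups: direction fixed, p at the degenerate limit
  lohi <- compare_conditions(c(1, 1, 1, 1), c(2, 2, 2, 2))
  expect_equal(lohi$statistic, -Inf)
  expect_equal(lohi$p_value, 0)
  expect_gt(compare_conditions(c(2, 2, 2, 2), c(1, 1, 1, 1))$statistic, 0)
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
  # agrees with Welch's t-test on non-degenerate data
  set.seed(31)
  a <- rnorm(8, 10); b <- rnorm(6, 12, 2)
  got <- compare_conditions(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("migration fractions follow receiver / (receiver + sender)", {
  expect_equal(migration_fraction(80, 20), 0.2)
  expect_equal(migration_fraction(50, 50), 0.5)
  expect_equal(migration_fraction(10, 0), 0)
  # scale invariance
  s <- c(3, 8, 1); r <- c(1, 2, 5)
  expect_equal(migration_fraction(7 * s, 7 * r), migration_fraction(s, r))
  expect_warning(f0 <- migration_fraction(0, 0), "undefined")
  expect_true(is.na(f0))
  expect_error(migration_fraction(-1, 2), "non-negative")
})

test_that("directionality pairs up/down fractions per sender", {
  reps <- paste0("r", 1:6)
  base <- expand.grid(replicate = reps, direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  # up = down in every replicate -> ratio 1, p = 1
  eq <- cbind(sender = "L5", base, fraction = 0.1)
  deq <- directionality(eq)
  expect_equal(deq$ratio, 1)
  expect_equal(deq$p_value, 1)
  expect_equal(deq$statistic, 0)
  # up = 2.5 x down, with replicate scatter
  set.seed(8)
  down <- runif(6, 0.04, 0.08)
  both <- rbind(
    data.frame(sender = "L5", replicate = reps, direction = "up",
               fraction = 2.5 * down),
    data.frame(sender = "L5", replicate = reps, direction = "down",
               fraction = down))
  d <- directionality(both)
  expect_equal(d$ratio, 2.5, tolerance = 1e-9)
  expect_lt(d$p_value, 0.01)
  expect_equal(d$n_pairs, 6L)
  # a sender with only an upward neighbour is reported unpaired
  mix <- rbind(both,
               data.frame(sender = "L2", replicate = reps, direction = "up",
                          fraction = 0.2))
  expect_warning(dm <- directionality(mix), "unmatched")
  l2 <- dm[dm$sender == "L2", ]
  expect_false(l2$paired)
  expect_equal(l2$mean_up, 0.2)
  expect_true(is.na(l2$ratio))
  expect_error(directionality(data.frame(a = 1)), "must have columns")
})
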