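model_fixture <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- cea_model()
    m
  }
})

test_that("one-way analysis agrees with direct endpoint evaluation", {
  m <- model_fixture()
  ow <- one_way_sa(m, c("comply_internet", "platform_overhead"))
  direct <- function(name, value) {
    p <- load_parameters(stats::setNames(list(value), name))
    cmp <- compare_strategies(run_strategy("internet", p, keep_trace = FALSE),
                              run_strategy("in_person", p, keep_trace = FALSE))
    cmp$icer
  }
  row <- ow[ow$parameter == "comply_internet", ]
  expect_equal(row$icer_low, direct("comply_internet", 0.730))
  expect_equal(row$icer_high, direct("comply_internet", 0.887))
  row2 <- ow[ow$parameter == "platform_overhead", ]
  expect_equal(row2$icer_low, direct("platform_overhead", 20))
  expect_equal(row2$icer_high, direct("platform_overhead", 29))
  # evaluating a parameter at its base value reproduces the base-case ICER
  expect_equal(direct("comply_internet", 0.808), m$comparison$icer)
})

test_that("one-way analysis rejects unknown and degenerate parameters", {
  m <- model_fixture()
  expect_error(one_way_sa(m, "not_a_parameter"), "unknown")
  expect_error(one_way_sa(m, "utility_age"), "degenerate")
})

test_that("internet stays dominant across every one-way range", {
  m <- model_fixture()
  ow <- one_way_sa(m)
  expect_true(all(ow$dominant_low))
  expect_true(all(ow$dominant_high))
  expect_true(all(ow$nmb_low > 0))
  expect_true(all(ow$nmb_high > 0))
  # compliance rates are the most influential inputs on the ICER
  expect_setequal(ow$parameter[1:2], c("comply_internet", "comply_inperson"))
})

test_that("two-way compliance grid is monotone and matches the scalar rule", {
  m <- model_fixture()
  tw <- two_way_sa(m, step = 0.01)
  v <- tw$internet_preferred
  # raising internet compliance never flips a cell away from internet
  expect_true(all(apply(v, 2, function(col) all(diff(col) >= 0))))
  # raising in-person compliance never flips a cell toward internet
  expect_true(all(apply(v, 1, function(row) all(diff(row) <= 0))))

  # spot-check cells against the scalar verdict
  set.seed(4)
  for (k in 1:12) {
    i <- sample(length(tw$comply_internet), 1)
    j <- sample(length(tw$comply_inperson), 1)
    p <- load_parameters(list(comply_internet = tw$comply_internet[i],
                              comply_inperson = tw$comply_inperson[j]),
                         strict = FALSE)
    cmp <- compare_strategies(run_strategy("internet", p, keep_trace = FALSE),
                              run_strategy("in_person", p, keep_trace = FALSE))
    expect_identical(unname(v[i, j]), is_cost_effective(cmp, m$wtp))
  }
})

test_that("two-way grid reproduces the published boundary statements", {
  m <- model_fixture()
  tw <- two_way_sa(m, step = 0.01)
  xi <- tw$comply_internet
  xp <- tw$comply_inperson
  # low in-person compliance (< 60%): internet preferred at any compliance
  expect_true(all(tw$internet_preferred[, xp < 0.60]))
  # high in-person compliance (> 90%) with internet compliance at 60%:
  # in-person preferred
  expect_false(any(tw$internet_preferred[which.min(abs(xi - 0.60)), xp > 0.905]))
  # extreme corner: full internet compliance vs half in-person compliance
  expect_true(tw$internet_preferred[length(xi), 1])
})

test_that("two-way grid rejects invalid arguments", {
  m <- model_fixture()
  expect_error(two_way_sa(m, step = 0), "positive")
  expect_error(two_way_sa(m, range = c(0.8, 0.2)), "interval")
})

test_that("threshold search brackets the verdict flip", {
  m <- model_fixture()
  th <- threshold_search(m, "platform_overhead", c(24, 2000))
  expect_false(is.na(th$threshold))
  # the verdict genuinely differs across the reported threshold
  verdict_at <- function(v) {
    p <- load_parameters(list(platform_overhead = v), strict = FALSE)
    cmp <- compare_strategies(run_strategy("internet", p, keep_trace = FALSE),
                              run_strategy("in_person", p, keep_trace = FALSE))
    is_cost_effective(cmp, m$wtp)
  }
  expect_true(verdict_at(th$threshold - 2 * th$tol))
  expect_false(verdict_at(th$threshold + 2 * th$tol))
})

test_that("threshold search reports no crossing when the verdict is constant", {
  m <- model_fixture()
  expect_true(is.na(threshold_search(m, "platform_overhead", c(24, 100))$threshold))
  expect_true(is.na(threshold_search(m, "therapist_time_share_internet",
                                     c(0.0923, 0.50))$threshold))
  expect_error(threshold_search(m, "platform_overhead", c(100, 24)), "interval")
})
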