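test_that("default parameter set carries the published base values", {
  p <- load_parameters()
  expect_s3_class(p, "cea_parameters")
  expect_equal(p$recovery_low_cbt, 0.639)
  expect_equal(p$deterioration_none, 0.091)
  expect_equal(p$accept_internet, 0.753)
  expect_equal(p$comply_inperson, 0.839)
  expect_equal(p$mortality_monthly, 2.5e-5)
  expect_equal(p$rr_mortality_depressed, 1.81)
  expect_equal(p$outpatient_monthly, 231)
  expect_equal(p$horizon_months, 60)
  expect_equal(p$cycle_months, 1)
  expect_equal(p$discount_annual, 0.03)
  expect_equal(p$wtp, 48119)
  reg <- attr(p, "registry")
  probs <- reg$name[reg$scale %in% c("probability", "proportion", "utility")]
  for (nm in probs) {
    expect_gte(p[[nm]], 0)
    expect_lte(p[[nm]], 1)
  }
  ranged <- !is.na(reg$low)
  expect_true(all(reg$low[ranged] <= reg$base[ranged]))
  expect_true(all(reg$base[ranged] <= reg$high[ranged]))
  expect_true(all((reg$dist == "fixed") == !ranged))
})

test_that("overrides apply to the named parameter only and are validated", {
  p <- load_parameters(list(wtp = 0))
  expect_equal(p$wtp, 0)
  expect_equal(p$recovery_low_cbt, 0.639)

  expect_error(load_parameters(list(accept_internet = 1.2)), "\\[0, 1\\]")
  expect_error(load_parameters(list(nonexistent = 1)), "unknown parameter")
  expect_error(load_parameters(list(outpatient_monthly = -5)), "non-negative")
  # envelope enforcement is strict by default, relaxed on request
  expect_error(load_parameters(list(platform_overhead = 500)), "outside")
  p2 <- load_parameters(list(platform_overhead = 500), strict = FALSE)
  expect_equal(p2$platform_overhead, 500)
})

test_that("a written configuration reloads to the identical parameter set", {
  p <- load_parameters(list(wtp = 40000, platform_overhead = 27))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  p2 <- load_parameters(path)
  expect_identical(unclass(p)[order(names(p))], unclass(p2)[order(names(p2))])
  expect_equal(attr(p, "registry"), attr(p2, "registry"))
})

test_that("samplers honour their family: support, mode and moments", {
  p <- load_parameters()

  tri <- make_sampler(param_spec(p, "rel_effect_internet"))
  expect_identical(attr(tri, "family"), "triangular")
  set.seed(1)
  x <- tri(1e6)
  expect_gte(min(x), 0.95)
  expect_lte(max(x), 1.05)
  # triangular(0.95, 1, 1.05) has mean 1 and sd (b - a)/sqrt(24)
  expect_within_se(mean(x), 1.0, 0.1 / sqrt(24) / sqrt(1e6))

  fx <- make_sampler(param_spec(p, "utility_age"))
  expect_identical(unique(fx(500)), 0.92)

  # method-of-moments beta: Monte Carlo mean/sd agree with the target
  bt <- make_sampler(list(base = 0.639, low = 0.511, high = 0.767, dist = "beta"))
  set.seed(2)
  y <- bt(1e5)
  sd_target <- (0.767 - 0.511) / 3.92
  expect_within_se(mean(y), 0.639, sd_target / sqrt(1e5))
  expect_equal(stats::sd(y), sd_target, tolerance = 0.02)

  gm <- make_sampler(param_spec(p, "outpatient_monthly"))
  set.seed(3)
  z <- gm(1e5)
  sd_g <- (335 - 160) / 3.92
  expect_within_se(mean(z), 231, sd_g / sqrt(1e5))
  expect_gte(min(z), 0)

  expect_error(make_sampler(list(base = 0.5, low = 0, high = 4, dist = "beta")),
               "method-of-moments")
})

test_that("sampler percentile intervals cover the range midpoint", {
  p <- load_parameters()
  reg <- attr(p, "registry")
  set.seed(42)
  for (nm in reg$name[reg$dist != "fixed"]) {
    spec <- param_spec(p, nm)
    q <- stats::quantile(make_sampler(spec)(1e5), c(0.025, 0.975))
    mid <- (spec$low + spec$high) / 2
    expect_gte(mid, q[[1]])
    expect_lte(mid, q[[2]])
  }
})

test_that("parameter-set draws are reproducible and respect invariants", {
  p <- load_parameters()
  d1 <- sample_parameter_set(p, seed = 7)
  d2 <- sample_parameter_set(p, seed = 7)
  expect_identical(unclass(d1), unclass(d2))
  expect_false(identical(d1$recovery_low_cbt, p$recovery_low_cbt))
  # fixed parameters never move
  expect_equal(d1$utility_age, 0.92)
  expect_equal(d1$horizon_months, 60)

  # degenerate case: all distributions fixed reproduces the base set
  expect_identical(unclass(sample_parameter_set(all_fixed_params(), seed = 1)),
                   unclass(all_fixed_params()))

  # long-run mean of a sampled parameter matches its base value
  set.seed(99)
  draws <- replicate(2000, sample_parameter_set(p)$comply_internet)
  sd_c <- (0.887 - 0.730) / 3.92
  expect_within_se(mean(draws), 0.808, sd_c / sqrt(2000))

  # every draw satisfies the scale invariants
  reg <- attr(p, "registry")
  unit_scaled <- reg$name[reg$scale %in% c("probability", "proportion", "utility")]
  for (s in 11:15) {
    d <- sample_parameter_set(p, seed = s)
    for (nm in unit_scaled) {
      expect_gte(d[[nm]], 0)
      expect_lte(d[[nm]], 1)
    }
    for (nm in setdiff(reg$name, unit_scaled)) expect_gte(d[[nm]], 0)
  }
})

test_that("correlated pairs share a quantile; independent mode does not", {
  p <- load_parameters()
  set.seed(5)
  acc_i <- acc_p <- com_i <- com_p <- numeric(300)
  for (i in 1:300) {
    d <- sample_parameter_set(p)
    acc_i[i] <- d$accept_internet; acc_p[i] <- d$accept_inperson
    com_i[i] <- d$comply_internet; com_p[i] <- d$comply_inperson
  }
  expect_gt(stats::cor(acc_i, acc_p, method = "spearman"), 0.999)
  expect_gt(stats::cor(com_i, com_p, method = "spearman"), 0.999)
  set.seed(6)
  for (i in 1:300) {
    d <- sample_parameter_set(p, correlated_pairs = FALSE)
    acc_i[i] <- d$accept_internet; acc_p[i] <- d$accept_inperson
  }
  expect_lt(abs(stats::cor(acc_i, acc_p, method = "spearman")), 0.2)
})
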