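# MOE/SE/CV algebra and error propagation

test_that("MOE-to-SE conversion uses the 90% divisor and round-trips", {
  expect_equal(round(moe_to_se(114.5), 1), 69.6)
  expect_equal(moe_to_se(0), 0)
  expect_equal(moe_to_se(1.645), 1)
  m <- c(0, 0.3, 12, 114.5, 9e6)
  expect_equal(se_to_moe(moe_to_se(m)), m)
  expect_error(moe_to_se(-1), "nonnegative")
})

test_that("cv reproduces published worked values", {
  # percent-scale housing/poverty indicators for four adjacent tracts
  expect_equal(round(cv(94.9, 3.6), 3), 0.023)
  expect_equal(round(cv(32, 9.1), 3), 0.173)
  expect_equal(round(cv(28.4, 10.2), 3), 0.218)
  expect_equal(round(cv(89.7, 19.5), 3), 0.132)
  expect_equal(round(cv(74.7, 7.5), 3), 0.061)
  # a population of 5000 +/- 822 has a CV of 0.1
  expect_equal(round(cv(5000, 822), 1), 0.1)
})

test_that("cv zero conventions are explicit", {
  expect_equal(cv(0, 0), 0)
  expect_equal(cv(10, 0), 0)
  expect_equal(cv(0, 5), Inf)
  expect_error(cv(-1, 2), "nonnegative")
})

test_that("truncated 90% intervals match hand arithmetic", {
  brooklyn <- cv_interval(169, 174)
  expect_equal(brooklyn$lower, 0)
  expect_equal(brooklyn$upper, 343)
  expect_equal(unlist(cv_interval(10, 0)), c(lower = 10, upper = 10))
  expect_equal(unlist(cv_interval(10, 4, nonnegative = FALSE)), c(lower = 6, upper = 14))
})

test_that("count aggregation follows root-sum-of-squares", {
  agg <- aggregate_count(data.frame(estimate = c(10, 20), se = c(3, 4)))
  expect_equal(agg$estimate, 30)
  expect_equal(agg$se, 5)
  one <- aggregate_count(data.frame(estimate = 7, se = 2))
  expect_equal(unlist(one), c(estimate = 7, se = 2))
  expect_error(aggregate_count(data.frame(estimate = numeric(), se = numeric())), "empty")
})

test_that("count aggregation is permutation-invariant and associative", {
  set.seed(31)
  d <- data.frame(estimate = runif(6, 10, 100), se = runif(6, 1, 9))
  a <- aggregate_count(d)
  b <- aggregate_count(d[sample(6), ])
  expect_equal(a, b)
  left <- aggregate_count(rbind(as.data.frame(aggregate_count(d[1:3, ])), d[4:6, ]))
  expect_equal(left$estimate, a$estimate)
  expect_equal(left$se, a$se, tolerance = 1e-12)
})

test_that("aggregated SE matches a Monte-Carlo sd of the sum", {
  set.seed(71)
  mu <- c(120, 45, 300, 80, 15)
  se <- c(12, 9, 25, 4, 3)
  draws <- matrix(rnorm(5 * 1e6, mean = rep(mu, each = 1e6), sd = rep(se, each = 1e6)), ncol = 5)
  mc_sd <- sd(rowSums(draws))
  agg <- aggregate_count(data.frame(estimate = mu, se = se))
  expect_lt(abs(agg$se - mc_sd) / mc_sd, 0.02)
})

test_that("derived proportion SEs follow the subtract-then-fallback rule", {
  exact <- derived_se(50, 6, 100, 0, "proportion")
  expect_equal(exact$estimate, 0.5)
  expect_equal(exact$se, 0.06)
  sub <- derived_se(50, 6, 100, 8, "proportion")
  expect_equal(sub$se, 0.01 * sqrt(36 - 0.25 * 64))
  expect_false(sub$fallback)
  # negative radicand: se of the numerator smaller than p * se of denominator
  fb <- derived_se(50, 1, 100, 8, "proportion")
  expect_true(fb$fallback)
  expect_equal(fb$se, 0.01 * sqrt(1 + 0.25 * 64))
  expect_error(derived_se(50, 6, 0, 8, "proportion"), "positive")
})

test_that("ratio-mean SE matches hand arithmetic and a Monte-Carlo oracle", {
  m <- derived_se(50, 6, 100, 8, "mean")
  expect_equal(m$se, 0.01 * sqrt(36 + 0.25 * 64))
  set.seed(72)
  x <- rnorm(1e6, 50, 6)
  y <- rnorm(1e6, 100, 8)
  expect_lt(abs(m$se - sd(x / y)) / sd(x / y), 0.03)
})

test_that("region_cv_table is the identity on singletons", {
  sv <- generate_survey(3, 3, seed = 2, n_counts = 1)
  rt <- region_cv_table(sv$table, sv$table$area_id[5], sv$specs)
  v <- sv$specs$name[sv$specs$kind == "count"][1]
  row <- rt[rt$variable == v, ]
  expect_equal(row$estimate, sv$table[[v]][5])
  expect_equal(row$moe, sv$table[[paste0(v, "_moe")]][5])
  expect_equal(row$cv, cv(sv$table[[v]][5], sv$table[[paste0(v, "_moe")]][5]))
})

test_that("merging m identical count areas divides the CV by sqrt(m)", {
  tab <- count_table(est = rep(100, 4), moe = rep(16.45, 4))
  one <- region_cv_table(tab, tab$area_id[1], count_specs())
  for (m in 2:4) {
    agg <- region_cv_table(tab, tab$area_id[1:m], count_specs())
    expect_equal(agg$estimate, m * 100)
    expect_equal(agg$se, sqrt(m) * one$se)
    expect_equal(agg$cv, one$cv / sqrt(m), tolerance = 1e-12)
  }
})

test_that("region_cv_table agrees with an independent straight-line oracle", {
  sv <- generate_survey(4, 3, seed = 9, n_counts = 2)
  set.seed(5)
  for (rep in 1:5) {
    region <- sample(sv$table$area_id, 3)
    got <- region_cv_table(sv$table, region, sv$specs)
    want <- naive_region_cv(sv$table, region, sv$specs)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
    expect_equal(got$cv, want$cv, tolerance = 1e-12)
  }
})

test_that("small-proportion exemption is region-level, strict, proportions only", {
  tab <- tibble::tibble(
    area_id = c("a", "b"), households = 10, population = c(1000, 1000),
    population_moe = c(0, 0),
    low_num = c(30, 70), low_num_moe = c(30, 30),     # aggregate exactly 5%
    tiny_num = c(10, 20), tiny_num_moe = c(20, 20),   # aggregate 1.5%
    n_cnt = c(3, 4), n_cnt_moe = c(5, 5)
  )
  specs <- dplyr::bind_rows(
    variable_spec("low", "proportion", "low_num", "low_num_moe", "population", "population_moe"),
    variable_spec("tiny", "proportion", "tiny_num", "tiny_num_moe", "population", "population_moe"),
    variable_spec("cnt", "count", "n_cnt", "n_cnt_moe")
  )
  rt <- region_cv_table(tab, c("a", "b"), specs)
  expect_false(rt$exempt[rt$variable == "low"])  # exactly 5%: strict <
  expect_true(rt$exempt[rt$variable == "tiny"])
  expect_false(rt$exempt[rt$variable == "cnt"])  # counts never exempt
})
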