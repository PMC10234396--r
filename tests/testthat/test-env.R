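make_weather <- function(values_fn, loc = "env1", year = 2018,
                         from = as.Date("2018-04-01"), days = 120) {
  dates <- seq(from, by = "day", length.out = days)
  v <- values_fn(seq_len(days))
  d <- data.frame(location = loc, year = year, date = dates,
                  variable = "tmean", value = v,
                  stringsAsFactors = FALSE)
  class(d) <- c("weather_series", "data.frame")
  d
}

test_that("window means: constant, linear and hand-enumerated series", {
  hd <- data.frame(line = "L1", environment = "env1", year = 2018,
                   heading_date = as.Date("2018-07-15"))
  wc <- make_weather(function(t) rep(10, length(t)))
  mc <- window_means(wc, hd)
  expect_equal(nrow(mc), 3L)
  expect_true(all(mc$value == 10))
  expect_setequal(mc$factor, c("tmean_0_30d", "tmean_15_45d",
                               "tmean_30_60d"))
  ## linear daily series: the window mean is the mid-window value
  wl <- make_weather(function(t) 2 * t + 1)
  ml <- window_means(wl, hd)
  day0 <- as.integer(hd$heading_date - as.Date("2018-04-01")) + 1L
  mid <- function(a, b) 2 * (day0 - (a + b) / 2) + 1
  expect_equal(ml$value[ml$factor == "tmean_0_30d"], mid(0, 30))
  expect_equal(ml$value[ml$factor == "tmean_15_45d"], mid(15, 45))
  expect_equal(ml$value[ml$factor == "tmean_30_60d"], mid(30, 60))
  ## 31 days valued 1..31 with heading on day 31: mean of days 1..31 = 16
  w31 <- make_weather(function(t) t, from = as.Date("2018-06-01"),
                      days = 31)
  h31 <- data.frame(line = "L1", environment = "env1", year = 2018,
                    heading_date = as.Date("2018-07-01"))
  m31 <- window_means(w31, h31, windows = list(c(0, 30)))
  expect_equal(m31$value, 16)
})

test_that("gaps inside a window raise an error naming the missing days", {
  w <- make_weather(function(t) t)
  w <- w[w$date != as.Date("2018-07-01"), ]
  hd <- data.frame(line = "L1", environment = "env1", year = 2018,
                   heading_date = as.Date("2018-07-15"))
  expect_error(window_means(w, hd), "2018-07-01")
})

test_that("window means ignore the order of weather records", {
  set.seed(9)
  w <- make_weather(function(t) rnorm(length(t)))
  hd <- data.frame(line = "L1", environment = "env1", year = 2018,
                   heading_date = as.Date("2018-07-10"))
  m1 <- window_means(w, hd)
  m2 <- window_means(w[sample(nrow(w)), ], hd)
  expect_equal(m2[order(m2$factor), "value"],
               m1[order(m1$factor), "value"])
})

env_cov <- function(vals, fac = "tmean_0_30d") {
  data.frame(environment = sprintf("env%d", seq_along(vals)), year = 2018,
             factor = fac, value = vals, stringsAsFactors = FALSE)
}

test_that("interaction test recovers a simulated genotype-by-factor effect", {
  tp <- tiny_pop()
  E3 <- c(16, 21, 27)
  qtl <- data.frame(marker = tp$qtl_marker, beta = 0.4,
                    dev1 = 0.5 * E3[1], dev2 = 0.5 * E3[2],
                    dev3 = 0.5 * E3[3])
  sim <- simulate_phenotypes(tp$G, qtl = qtl, sigma_u2 = 1,
                             sigma_eps2 = 1,
                             env_intercepts = c(-1, 0, 1), seed = 41)
  r <- test_env_factor(sim$phenotypes, tp$K, tp$G, tp$qtl_marker,
                       env_cov(E3), "tmean_0_30d", "trait1", 2018,
                       seed = 1)
  sdE <- sd(rep(E3, each = length(tp$G$line_ids)))
  expect_equal(r$beta_interaction / sdE, 0.5, tolerance = 0.2)
  expect_lt(r$p, 0.01)
  expect_equal(r$df, 1)
})

test_that("the LRT is invariant to affine rescaling of the covariate", {
  tp <- tiny_pop()
  r1 <- test_env_factor(tp$P, tp$K, tp$G, tp$qtl_marker,
                        env_cov(c(16, 21, 27)), "tmean_0_30d",
                        "trait1", 2018, seed = 1)
  r2 <- test_env_factor(tp$P, tp$K, tp$G, tp$qtl_marker,
                        env_cov(100 * c(16, 21, 27) - 42), "tmean_0_30d",
                        "trait1", 2018, seed = 1)
  expect_equal(r1$lrt, r2$lrt, tolerance = 1e-8)
})

test_that("constant factors are rejected as unidentifiable", {
  tp <- tiny_pop()
  expect_error(test_env_factor(tp$P, tp$K, tp$G, tp$qtl_marker,
                               env_cov(c(5, 5, 5)), "tmean_0_30d",
                               "trait1", 2018),
               "unidentifiable")
})

test_that("factor ranking applies BH across the factor family", {
  tp <- tiny_pop()
  cv <- rbind(env_cov(c(16, 21, 27), "tmean_0_30d"),
              env_cov(c(3, 9, 2), "precipitation_0_30d"),
              env_cov(c(7, 5, 6), "sunshine_15_45d"))
  res <- rank_env_factors(tp$P, tp$K, tp$G, tp$qtl_marker, cv,
                          "trait1", 2018, seed = 1)
  expect_equal(sort(res$q), sort(bh_fdr(res$p)))
  expect_equal(res$q, res$q[order(res$q)])
  ## permuting the factor table leaves the factor -> q map unchanged
  res2 <- rank_env_factors(tp$P, tp$K, tp$G, tp$qtl_marker,
                           cv[sample(nrow(cv)), ], "trait1", 2018,
                           seed = 1)
  expect_equal(res2$q[match(res$factor, res2$factor)], res$q,
               tolerance = 1e-10)
  ## a single factor keeps q = p
  r1 <- rank_env_factors(tp$P, tp$K, tp$G, tp$qtl_marker,
                         env_cov(c(16, 21, 27)), "trait1", 2018,
                         seed = 1)
  expect_equal(r1$q, r1$p)
})
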