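iid_design <- function(y) {
  n <- length(y)
  structure(list(y = y, Z = diag(n), W = matrix(1, n, 1), V = diag(n),
                 X = NULL, S = NULL, E = NULL,
                 obs = data.frame(line = as.character(seq_len(n)),
                                  environment = "e1", year = 2018),
                 line_ids = as.character(seq_len(n)), env_ids = "e1",
                 balanced = FALSE), class = "stacked_design")
}

test_that("iid model reproduces the closed-form Gaussian likelihood", {
  y <- c(1, 2, 3)
  m <- make_lmm(iid_design(y), fixed = "mu", random = character(0),
                backend = "dense")
  s2 <- mean((y - mean(y))^2)  # ML variance, denominator N
  expect_equal(lmm_loglik(m, list(sigma_eps2 = s2)),
               sum(dnorm(y, mean(y), sqrt(s2), log = TRUE)),
               tolerance = 1e-10)
  f <- fit_lmm(m)
  expect_equal(f$var_params$sigma_eps2, s2, tolerance = 1e-6)
  expect_equal(f$loglik, sum(dnorm(y, mean(y), sqrt(s2), log = TRUE)),
               tolerance = 1e-8)
})

test_that("a kernel with weight zero leaves the likelihood unchanged", {
  tp <- tiny_pop()
  d <- tiny_design(tp$qtl_marker)
  m0 <- make_lmm(d, K = tp$K, fixed = c("mu", "snp"), random = "env",
                 backend = "dense")
  m1 <- make_lmm(d, K = tp$K, fixed = c("mu", "snp"),
                 random = c("polygenic", "env"), backend = "dense")
  vp0 <- list(sigma_e2 = 0.5, sigma_eps2 = 1.2)
  expect_equal(lmm_loglik(m1, c(vp0, sigma_u2 = 0)),
               lmm_loglik(m0, vp0), tolerance = 1e-10)
})

test_that("engine log-likelihood matches the dense brute-force oracle", {
  tp <- tiny_pop()
  P10 <- tp$P[tp$P$line %in% tp$G$line_ids[1:10], ]
  d <- suppressMessages(build_stacked_design(tp$G, P10, trait = "trait1",
                                             year = 2018,
                                             marker_id = tp$qtl_marker))
  specs <- list(
    list(fixed = c("mu", "snp"), random = c("polygenic", "env")),
    list(fixed = c("mu", "snp"), random = c("polygenic", "slope_block")),
    list(fixed = c("mu", "snp"),
         random = c("polygenic", "env", "snp_slope")),
    list(fixed = "mu", random = c("polygenic", "env", "gxe")))
  set.seed(42)
  for (sp in specs) {
    m <- make_lmm(d, K = tp$K, fixed = sp$fixed, random = sp$random,
                  backend = "dense")
    for (i in 1:5) {
      vp <- lapply(setNames(nm = m$param_info), function(x) runif(1, 0.2, 2))
      if ("sigma_e01" %in% m$param_info)
        vp$sigma_e01 <- runif(1, -0.9, 0.9) *
          sqrt(vp$sigma_e02 * vp$sigma_e12)
      Sig <- sigma_oracle(d, tp$K, vp, sp$random)
      for (reml in c(FALSE, TRUE))
        expect_equal(lmm_loglik(m, vp, reml = reml),
                     mvn_profile_oracle(d$y, m$Xfix, Sig, reml = reml),
                     tolerance = 1e-6)
    }
  }
})

test_that("rotated and dense backends agree to 1e-8 on balanced designs", {
  tp <- tiny_pop()
  d <- tiny_design(tp$qtl_marker)
  expect_true(d$balanced)
  specs <- list(
    list(fixed = c("mu", "snp"), random = c("polygenic", "env")),
    list(fixed = c("mu", "snp"), random = c("polygenic", "slope_block")),
    list(fixed = c("mu", "snp"),
         random = c("polygenic", "env", "snp_slope")),
    list(fixed = "mu", random = c("polygenic", "env", "gxe")),
    list(fixed = c("mu", "snp"), random = "polygenic"))
  set.seed(33)
  for (sp in specs) {
    mr <- make_lmm(d, K = tp$K, fixed = sp$fixed, random = sp$random,
                   backend = "rotated")
    md <- make_lmm(d, K = tp$K, fixed = sp$fixed, random = sp$random,
                   backend = "dense")
    for (i in 1:4) {
      vp <- lapply(setNames(nm = mr$param_info), function(x) runif(1, 0.2, 2))
      if ("sigma_e01" %in% mr$param_info)
        vp$sigma_e01 <- runif(1, -0.9, 0.9) *
          sqrt(vp$sigma_e02 * vp$sigma_e12)
      expect_equal(lmm_loglik(mr, vp), lmm_loglik(md, vp),
                   tolerance = 1e-8)
      expect_equal(lmm_loglik(mr, vp, reml = TRUE),
                   lmm_loglik(md, vp, reml = TRUE), tolerance = 1e-8)
    }
  }
})

test_that("fitted variances are nonnegative and slope correlation bounded", {
  tp <- tiny_pop()
  d <- tiny_design(tp$qtl_marker)
  f2 <- fit_model2(d, tp$K, seed = 4)
  vp <- f2$var_params
  expect_true(all(unlist(vp[c("sigma_u2", "sigma_e02", "sigma_e12",
                              "sigma_eps2")]) >= 0))
  denom <- sqrt(vp$sigma_e02 * vp$sigma_e12)
  if (denom > 0) expect_lte(abs(vp$sigma_e01) / denom, 1)
})

test_that("likelihood-ratio test arithmetic and df counting", {
  f0 <- structure(list(loglik = -100, n_params = 5), class = "lmm_fit")
  f1 <- structure(list(loglik = -100, n_params = 7), class = "lmm_fit")
  t0 <- lrt(f0, f1)
  expect_equal(t0$stat, 0)
  expect_equal(t0$df, 2)
  expect_equal(t0$p, 1)
  f2 <- structure(list(loglik = -100 + 5.991 / 2, n_params = 7),
                  class = "lmm_fit")
  t1 <- lrt(f0, f2)
  expect_equal(t1$stat, 5.991)
  expect_equal(t1$p, 0.05, tolerance = 1e-3)
  expect_error(lrt(f1, f0), "not nested")
  ## Model 1 vs Model 2 differ by exactly two parameters
  tp <- tiny_pop()
  d <- tiny_design(tp$qtl_marker)
  fit1 <- fit_model1(d, tp$K)
  fit2 <- fit_model2(d, tp$K, fit1 = fit1)
  expect_equal(fit2$n_params - fit1$n_params, 2L)
})

test_that("warm-started nested fits never lose likelihood", {
  tp <- tiny_pop()
  d <- tiny_design(tp$qtl_marker)
  fit1 <- fit_model1(d, tp$K, seed = 9)
  fit2 <- fit_model2(d, tp$K, fit1 = fit1, seed = 9)
  expect_gte(fit2$loglik, fit1$loglik)
})
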