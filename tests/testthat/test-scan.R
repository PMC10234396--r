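test_that("GxE scan output satisfies its invariants", {
  sp <- small_scan_pop()
  res <- scan_gxe(sp$G, sp$P, sp$K, "trait1", 2018, restarts = 1, seed = 1)
  sc <- res$scan
  expect_equal(nrow(sc), 20L)
  expect_true(all(sc$lrt >= 0))
  expect_true(all(sc$p > 0 & sc$p <= 1))
  expect_equal(sc$q, bh_fdr(sc$p))
  expect_equal(sc$candidate, sc$q < 0.01)
  expect_equal(sc$df, rep(2, 20))
  ## loglik nesting holds for every marker
  expect_true(all(sc$loglik_alt >= sc$loglik_null))
  ## deterministic ordering by (chrom, pos)
  expect_equal(order(sc$chrom, sc$pos), seq_len(nrow(sc)))
  ## the designed-in GxE QTL is found
  expect_lt(sc$q[sc$marker == sp$qm], 0.01)
})

test_that("scan results do not depend on marker order", {
  sp <- small_scan_pop()
  res1 <- scan_gxe(sp$G, sp$P, sp$K, "trait1", 2018, restarts = 1,
                   seed = 1)
  perm <- sample(ncol(sp$G$codes))
  G2 <- genotype_matrix(sp$G$codes[, perm], sp$G$line_ids,
                        sp$G$map[perm, ])
  res2 <- scan_gxe(G2, sp$P, sp$K, "trait1", 2018, restarts = 1, seed = 1)
  expect_equal(res2$scan, res1$scan, tolerance = 1e-8)
})

test_that("association scan targets the constant effect, GxE scan the slopes", {
  sp <- small_scan_pop()
  ## additive-only trait: association flags, GxE stays quiet
  qtl_add <- data.frame(marker = sp$qm, beta = 1.2, dev1 = 0, dev2 = 0,
                        dev3 = 0)
  sim <- simulate_phenotypes(sp$G, qtl = qtl_add, sigma_u2 = 0.5,
                             sigma_eps2 = 1,
                             env_intercepts = c(-1, 0, 1), seed = 16)
  ra <- scan_association(sp$G, sim$phenotypes, sp$K, "trait1", 2018,
                         restarts = 1, seed = 1)
  rg <- scan_gxe(sp$G, sim$phenotypes, sp$K, "trait1", 2018,
                 restarts = 1, seed = 1)
  expect_lt(ra$scan$q[ra$scan$marker == sp$qm], 0.01)
  expect_gt(rg$scan$q[rg$scan$marker == sp$qm], 0.01)
  expect_equal(ra$scan$df, rep(1, 20))
  ## balanced sign-flipping slopes around beta = 0: GxE flags,
  ## association typically does not
  rg2 <- scan_gxe(sp$G, sp$P, sp$K, "trait1", 2018, restarts = 1,
                  seed = 1)
  ra2 <- scan_association(sp$G, sp$P, sp$K, "trait1", 2018,
                          restarts = 1, seed = 1)
  expect_lt(rg2$scan$q[rg2$scan$marker == sp$qm], 0.01)
  expect_gt(ra2$scan$q[ra2$scan$marker == sp$qm], 0.01)
})

test_that("LOCO kinship changes the background but keeps the QTL signal", {
  sp <- small_scan_pop()
  res <- scan_gxe(sp$G, sp$P, sp$K, "trait1", 2018, restarts = 1,
                  seed = 1, loco = TRUE)
  expect_equal(nrow(res$scan), 20L)
  expect_lt(res$scan$q[res$scan$marker == sp$qm], 0.01)
  G1 <- genotype_matrix(sp$G$codes[, 1:10], sp$G$line_ids,
                        sp$G$map[1:10, ])
  expect_error(scan_gxe(G1, sp$P, sp$K, "trait1", 2018, loco = TRUE),
               "one chromosome")
})

test_that("constant phenotypes abort the scan with a clear error", {
  sp <- small_scan_pop()
  P <- sp$P
  P$value <- 5
  expect_error(scan_gxe(sp$G, P, sp$K, "trait1", 2018),
               "degenerate")
})

test_that("candidate regions bridge at most one empty thinning window", {
  sc <- data.frame(marker = paste0("m", 1:6), chrom = "chr1",
                   pos = c(1e4, 2e4, 4e4, 9e4, 9.5e4, 2e5),
                   p = c(1e-5, 2e-6, 1e-5, 1e-5, 3e-6, 1e-5),
                   candidate = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                   stringsAsFactors = FALSE)
  reg <- candidate_regions(sc, bridge_bp = 10000)
  ## gaps of up to two window widths (one empty window) are bridged:
  ## {1e4, 2e4, 4e4}, {9e4, 9.5e4}, {2e5}
  expect_equal(nrow(reg), 3L)
  expect_equal(reg$start, c(1e4, 9e4, 2e5))
  expect_equal(reg$end, c(4e4, 9.5e4, 2e5))
  expect_equal(reg$best_marker, c("m2", "m5", "m6"))
  expect_equal(reg$n_markers, c(3L, 2L, 1L))
  ## a chromosome break always splits regions
  sc$chrom <- c("chr1", "chr1", "chr2", "chr2", "chr2", "chr2")
  reg2 <- candidate_regions(sc, bridge_bp = 10000)
  expect_equal(nrow(reg2), 4L)
})
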