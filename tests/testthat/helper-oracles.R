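## Independent oracles and shared fixtures, built in code at test time.

## brute-force Benjamini-Hochberg step-up: for each p_i, the minimum over
## all p_(j) >= p_i of m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- (m * ps[i:m]) / (i:m)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

## dense multivariate-normal log-likelihood with fixed effects profiled
## by GLS, computed the slow way: explicit covariance assembly and solve()
mvn_profile_oracle <- function(y, X, Sigma, reml = FALSE) {
  N <- length(y)
  p <- ncol(X)
  Si <- solve(Sigma)
  XtSX <- t(X) %*% Si %*% X
  beta <- solve(XtSX, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Si %*% r)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  ll <- -0.5 * (N * log(2 * pi) + ld + quad)
  if (reml)
    ll <- ll + 0.5 * p * log(2 * pi) -
      0.5 * determinant(XtSX, logarithm = TRUE)$modulus
  as.numeric(ll)
}

## covariance assembly straight from the incidence matrices of a
## stacked design (independent of the package's kernel bookkeeping)
sigma_oracle <- function(design, K, vp, random) {
  N <- length(design$y)
  Km <- if (inherits(K, "kinship_matrix")) K$K else K
  Sig <- diag(vp$sigma_eps2, N)
  ZKZ <- if (!is.null(Km))
    design$Z %*% Km[design$line_ids, design$line_ids] %*% t(design$Z)
  for (r in random) {
    Sig <- Sig + switch(r,
      polygenic = vp$sigma_u2 * ZKZ,
      env = vp$sigma_e2 * tcrossprod(design$W),
      gxe = vp$sigma_x2 * (ZKZ * tcrossprod(design$W)),
      snp_slope = vp$sigma_gamma2 * tcrossprod(design$S),
      slope_block = vp$sigma_e02 * tcrossprod(design$W) +
        vp$sigma_e12 * tcrossprod(design$S) +
        vp$sigma_e01 * (tcrossprod(design$W, design$S) +
                          tcrossprod(design$S, design$W)))
  }
  Sig
}

## double-loop VanRaden kinship
kinship_oracle <- function(codes) {
  M <- codes * 1.0
  for (j in seq_len(ncol(M))) {
    z <- M[, j] == 0
    if (any(z)) M[z, j] <- mean(M[!z, j])
  }
  p <- colMeans((M + 1) / 2)
  c0 <- sum(2 * p * (1 - p))
  n <- nrow(M)
  K <- matrix(0, n, n)
  mbar <- colMeans(M)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sum((M[i, ] - mbar) * (M[j, ] - mbar)) / c0
  K
}

## small cached population shared across test files
tiny_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      G <- suppressMessages(simulate_ril_genotypes(
        60, data.frame(chrom = "chr1", length_cM = 100, n_markers = 40,
                       length_bp = 1e6), seed = 3))
      K <- compute_kinship(G)
      qtl <- data.frame(marker = colnames(G$codes)[20], beta = 0,
                        dev1 = 1, dev2 = 0, dev3 = -1)
      sim <- simulate_phenotypes(G, qtl = qtl, sigma_u2 = 1,
                                 sigma_eps2 = 1,
                                 env_intercepts = c(-1, 0, 1), seed = 5)
      cache <<- list(G = G, K = K, P = sim$phenotypes, truth = sim$truth,
                     qtl_marker = colnames(G$codes)[20])
    }
    cache
  }
})

tiny_design <- function(marker = NULL, env_covariate = NULL) {
  tp <- tiny_pop()
  suppressMessages(build_stacked_design(tp$G, tp$P, trait = "trait1",
                                        year = 2018, marker_id = marker,
                                        env_covariate = env_covariate))
}

## shared mid-sized scan population with one strong GxE QTL
small_scan_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      G <- suppressMessages(simulate_ril_genotypes(
        150, data.frame(chrom = c("chr1", "chr2"), length_cM = 50,
                        n_markers = 10, length_bp = 9e4), seed = 14))
      K <- compute_kinship(G)
      qm <- colnames(G$codes)[15]  # middle of chr2
      qtl <- data.frame(marker = qm, beta = 0, dev1 = 1.2, dev2 = 0,
                        dev3 = -1.2)
      sim <- simulate_phenotypes(G, qtl = qtl, sigma_u2 = 1,
                                 sigma_eps2 = 1,
                                 env_intercepts = c(-1, 0, 1), seed = 15)
      cache <<- list(G = G, K = K, P = sim$phenotypes, qm = qm)
    }
    cache
  }
})

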