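#' Simulate biparental RIL genotypes by single seed descent
#'
#' Each line descends from a fully heterozygous F1: one meiosis pair
#' produces the F2 individual, then \code{selfing_generations} rounds
#' of single-seed selfing (default 7, i.e. F2 to F9). Crossovers follow
#' a no-interference (Poisson) model on the cM map: recombination
#' between adjacent markers at map distance d cM is Haldane's
#' r = (1 - exp(-2d/100))/2. Loci still heterozygous at the end are
#' resolved to a random homozygote by a fair coin flip (mimicking
#' post-imputation homozygous calls); the pre-resolution rate is
#' reported via a message and an attribute.
#'
#' @param n_lines number of RILs.
#' @param chromosomes data.frame with columns \code{chrom},
#'   \code{length_cM}, \code{n_markers}, \code{length_bp}; markers are
#'   evenly spaced on both maps.
#' @param selfing_generations selfing rounds after F2 (default 7).
#' @param seed RNG seed.
#' @return A [genotype_matrix] with attribute
#'   \code{het_rate_pre_resolution}.
#' @export
simulate_ril_genotypes <- function(n_lines,
                                   chromosomes = data.frame(
                                     chrom = c("chr1", "chr2"),
                                     length_cM = 100, n_markers = 250,
                                     length_bp = 3e7),
                                   selfing_generations = 7, seed = 1) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  stopifnot(all(chromosomes$n_markers >= 2), all(chromosomes$length_cM > 0),
            all(chromosomes$length_bp > 0))
  set.seed(seed)
  maps <- list(); rec <- list()
  for (i in seq_len(nrow(chromosomes))) {
    ch <- chromosomes[i, ]
    nm <- ch$n_markers
    cm <- seq(0, ch$length_cM, length.out = nm)
    bp <- round(seq(1, ch$length_bp, length.out = nm))
    maps[[i]] <- data.frame(
      marker = sprintf("%s_m%04d", ch$chrom, seq_len(nm)),
      chrom = ch$chrom, pos = bp, cM = cm, stringsAsFactors = FALSE)
    rec[[i]] <- (1 - exp(-2 * diff(cm) / 100)) / 2
  }
  map <- do.call(rbind, lapply(maps, function(m) m[c("marker", "chrom", "pos")]))
  total_m <- nrow(map)
  ## a gamete from a (possibly heterozygous) parent: per chromosome, walk
  ## markers choosing parental strand, switching with prob r between
  ## adjacent markers (equivalent to Poisson crossovers + Haldane)
  gamete <- function(h1, h2) {
    g <- integer(total_m)
    off <- 0L
    for (i in seq_along(maps)) {
      nm <- nrow(maps[[i]])
      sw <- stats::runif(nm - 1L) < rec[[i]]
      strand <- cumsum(c(stats::runif(1) < 0.5, sw)) %% 2L
      idx <- off + seq_len(nm)
      g[idx] <- ifelse(strand == 0L, h1[idx], h2[idx])
      off <- off + nm
    }
    g
  }
  codes <- matrix(0L, n_lines, total_m)
  n_het <- 0L
  for (l in seq_len(n_lines)) {
    h1 <- rep(1L, total_m); h2 <- rep(-1L, total_m)  # F1
    for (gen in seq_len(selfing_generations + 1L)) {  # F2 + selfings
      g1 <- gamete(h1, h2); g2 <- gamete(h1, h2)
      h1 <- g1; h2 <- g2
    }
    het <- h1 != h2
    n_het <- n_het + sum(het)
    resolved <- h1
    if (any(het))
      resolved[het] <- ifelse(stats::runif(sum(het)) < 0.5, 1L, -1L)
    codes[l, ] <- resolved
  }
  het_rate <- n_het / (n_lines * total_m)
  message(sprintf("pre-resolution heterozygosity: %.4f (%d loci resolved by coin flip)",
                  het_rate, n_het))
  G <- genotype_matrix(codes, sprintf("RIL%04d", seq_len(n_lines)), map)
  attr(G, "het_rate_pre_resolution") <- het_rate
  G
}

#' Simulate multi-environment phenotypes over RIL genotypes
#'
#' Generative twin of the environment-deviation model:
#' y_ij = mu + sum_q X_iq (beta_q + delta_qj) + u_i + x_ij + e0_j + eps_ij
#' with polygenic u ~ N(0, K sigma_u2) using K from [compute_kinship()],
#' an optional generic GxE term x_ij ~ N(0, K sigma_x2) independently
#' per environment, environment intercepts e0 either fixed constants or
#' drawn N(0, sigma_e2), and iid residual.
#'
#' @param G a [genotype_matrix].
#' @param qtl data.frame (marker, beta, plus one column per environment
#'   of slope deviations named dev1..devE), or NULL for no QTL.
#' @param mu grand mean.
#' @param sigma_u2,sigma_x2,sigma_eps2 variance components (>= 0).
#' @param env_intercepts numeric vector of fixed e0 (length n_env), or
#'   NULL to draw from N(0, sigma_e2).
#' @param sigma_e2 variance of drawn environment intercepts.
#' @param n_env number of environments (default 3).
#' @param trait,year labels for the output table.
#' @param seed RNG seed.
#' @return list with \code{phenotypes} (a [phenotype_table]) and
#'   \code{truth} (all parameters plus the realized u, x and e0).
#' @export
simulate_phenotypes <- function(G, qtl = NULL, mu = 0, sigma_u2 = 1,
                                sigma_x2 = 0, sigma_eps2 = 1,
                                env_intercepts = NULL, sigma_e2 = 1,
                                n_env = 3, trait = "trait1", year = 2018,
                                seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"),
            sigma_u2 >= 0, sigma_x2 >= 0, sigma_eps2 >= 0, sigma_e2 >= 0)
  set.seed(seed)
  n <- length(G$line_ids)
  envs <- sprintf("env%d", seq_len(n_env))
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl, stringsAsFactors = FALSE)
    for (mk in qtl$marker) {
      if (!mk %in% colnames(G$codes)) stop("QTL marker not in G: ", mk)
      if (length(unique(G$codes[, mk])) < 2L)
        stop("QTL marker monomorphic: ", mk)
    }
  }
  u <- rep(0, n); Kobj <- NULL
  xmat <- matrix(0, n, n_env)
  if (sigma_u2 > 0 || sigma_x2 > 0) {
    Kobj <- compute_kinship(G)
    e <- eigen(Kobj$K, symmetric = TRUE)
    L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    if (sigma_u2 > 0) u <- sqrt(sigma_u2) * as.vector(L %*% stats::rnorm(n))
    if (sigma_x2 > 0)
      for (j in seq_len(n_env))
        xmat[, j] <- sqrt(sigma_x2) * as.vector(L %*% stats::rnorm(n))
  }
  e0 <- if (is.null(env_intercepts)) stats::rnorm(n_env, 0, sqrt(sigma_e2))
        else rep_len(env_intercepts, n_env)
  rows <- vector("list", n_env)
  for (j in seq_len(n_env)) {
    y <- rep(mu + e0[j], n) + u + xmat[, j]
    if (!is.null(qtl)) {
      for (qi in seq_len(nrow(qtl))) {
        dev <- qtl[[paste0("dev", j)]][qi] %||% 0
        y <- y + G$codes[, qtl$marker[qi]] * (qtl$beta[qi] + dev)
      }
    }
    if (sigma_eps2 > 0) y <- y + stats::rnorm(n, 0, sqrt(sigma_eps2))
    rows[[j]] <- data.frame(line = G$line_ids, environment = envs[j],
                            year = year, trait = trait, value = y,
                            stringsAsFactors = FALSE)
  }
  P <- phenotype_table(do.call(rbind, rows), G)
  truth <- list(mu = mu, qtl = qtl, sigma_u2 = sigma_u2,
                sigma_e2 = sigma_e2, sigma_x2 = sigma_x2,
                sigma_eps2 = sigma_eps2, u = u, x = xmat, e0 = e0,
                env_ids = envs, seed = seed)
  list(phenotypes = P, truth = truth)
}

#' Write the canonical simulated fixture suite
#'
#' A small end-to-end dataset: 200 F9 RILs on 2 chromosomes x 250
#' markers, 3 environments, one additive QTL (constant effect) and one
#' GxE QTL (effects of opposite sign across environments), plus daily
#' weather for 3 locations with environment-varying factors, a soil
#' table, and a flat key-value truth record. Files are byte-identical
#' for a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param overwrite allow writing into an existing directory.
#' @param n_lines,n_markers_per_chr size knobs (defaults are the
#'   canonical fixture).
#' @return invisibly, the named character vector of file paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 42, overwrite = FALSE,
                               n_lines = 200, n_markers_per_chr = 250) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- suppressMessages(simulate_ril_genotypes(
    n_lines,
    chromosomes = data.frame(chrom = c("chr1", "chr2"), length_cM = 100,
                             n_markers = n_markers_per_chr,
                             length_bp = 2.5e6),
    seed = seed))
  mk <- colnames(G$codes)
  add_q <- mk[[max(1L, round(n_markers_per_chr / 5))]]        # on chr1
  gxe_q <- mk[[n_markers_per_chr + ceiling(n_markers_per_chr / 2)]] # chr2
  qtl <- data.frame(marker = c(add_q, gxe_q), beta = c(1.0, 0),
                    dev1 = c(0, 0.6), dev2 = c(0, 0), dev3 = c(0, -0.6),
                    stringsAsFactors = FALSE)
  sim <- simulate_phenotypes(G, qtl = qtl, mu = 10, sigma_u2 = 1,
                             sigma_eps2 = 1,
                             env_intercepts = c(-1, 0, 1), n_env = 3,
                             trait = "heading", year = 2018,
                             seed = seed + 1)
  ## heading-trait values double as days-to-heading for the weather windows
  paths <- c(geno = file.path(out_dir, "geno.tsv"),
             map = file.path(out_dir, "geno.tsv.map"),
             pheno = file.path(out_dir, "pheno.csv"),
             weather = file.path(out_dir, "weather.csv"),
             soil = file.path(out_dir, "soil.csv"),
             truth = file.path(out_dir, "truth.txt"))
  write_genotypes(G, paths[["geno"]])
  P <- sim$phenotypes
  P$value <- round(60 + 10 * (P$value - mean(P$value)) / stats::sd(P$value), 3)
  utils::write.csv(P, paths[["pheno"]], row.names = FALSE, quote = FALSE)
  ## daily weather: location-specific smooth seasonal curves, fixed noise
  set.seed(seed + 2)
  dates <- seq(as.Date("2018-04-01"), as.Date("2018-09-30"), by = "day")
  wx <- do.call(rbind, lapply(seq_len(3L), function(j) {
    t <- as.integer(dates - dates[1L])
    tmin <- 8 + 2.5 * j + 10 * sin(pi * t / length(t)) +
      round(stats::rnorm(length(t), 0, 0.8), 2)
    data.frame(location = sprintf("env%d", j), year = 2018,
               date = as.character(dates),
               tmin = round(tmin, 2), tmax = round(tmin + 8 + 0.5 * j, 2),
               precipitation = round(pmax(0, stats::rnorm(length(t), 4 + j, 4)), 1),
               sunshine = round(pmax(0, 7 - 0.5 * j +
                                       stats::rnorm(length(t), 0, 2)), 1),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(wx, paths[["weather"]], row.names = FALSE, quote = FALSE)
  soil <- data.frame(location = sprintf("env%d", 1:3), year = 2018,
                     pH = c(5.6, 6.1, 6.4), EC = c(0.12, 0.18, 0.09),
                     CEC = c(18.2, 22.5, 15.1), NH4 = c(1.1, 0.8, 1.6),
                     NO3 = c(0.4, 0.9, 0.3), CaO = c(210, 260, 180),
                     MgO = c(42, 55, 38), K2O = c(28, 22, 35),
                     P2O5 = c(14, 19, 11))
  utils::write.csv(soil, paths[["soil"]], row.names = FALSE, quote = FALSE)
  tr <- sim$truth
  kv <- c(seed = seed, n_lines = n_lines, n_env = 3,
          additive_qtl = add_q, additive_beta = 1.0,
          gxe_qtl = gxe_q, gxe_dev = "0.6,0,-0.6",
          mu = tr$mu, sigma_u2 = tr$sigma_u2, sigma_eps2 = tr$sigma_eps2,
          env_intercepts = paste(tr$e0, collapse = ","),
          pheno_rescale = "60 + 10 * z-score",
          het_rate_pre_resolution =
            sprintf("%.6f", attr(G, "het_rate_pre_resolution")))
  writeLines(paste(names(kv), kv, sep = "="), paths[["truth"]])
  invisible(paths)
}
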