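#' Fit the constant-SNP-effect model (Model 1)
#'
#' y = mu + X beta + Zu + We + eps: fixed overall SNP effect, random
#' polygenic effect u ~ N(0, K sigma_u2), random environment intercept
#' e ~ N(0, sigma_e2 I), iid residual.
#'
#' @param design a \code{stacked_design} with a SNP column.
#' @param K kinship matrix covering the design lines.
#' @param reml,restarts,seed,init passed to [fit_lmm()].
#' @param eig optional precomputed eigendecomposition of the line-subset K.
#' @return An \code{lmm_fit}.
#' @export
fit_model1 <- function(design, K, reml = FALSE, restarts = 3, seed = 1,
                       init = NULL, eig = NULL) {
  model <- make_lmm(design, K = K, fixed = c("mu", "snp"),
                    random = c("polygenic", "env"), eig = eig)
  fit_lmm(model, init = init, restarts = restarts, reml = reml, seed = seed)
}

#' Fit the environment-deviation model (Model 2)
#'
#' y = mu + X (beta + W e1) + Zu + W e0 + eps: the SNP effect deviates
#' by environment through the random slope e1, correlated with the
#' random environment intercept e0 via a 2x2 covariance
#' (sigma_e02, sigma_e12, sigma_e01). Adds two variance parameters to
#' Model 1.
#'
#' The fit is warm-started at the Model 1 solution (sigma_e12 = 0,
#' correlation 0), and the Model 1 boundary value is an admissible
#' parameter point of Model 2, so the returned log-likelihood is never
#' below Model 1's.
#'
#' @param design a \code{stacked_design} with a SNP column and >= 2
#'   environments.
#' @param K kinship matrix.
#' @param fit1 optional Model 1 fit used for the warm start (computed
#'   if absent).
#' @inheritParams fit_model1
#' @return An \code{lmm_fit}.
#' @export
fit_model2 <- function(design, K, fit1 = NULL, reml = FALSE, restarts = 3,
                       seed = 1, eig = NULL) {
  if (length(design$env_ids) < 2L)
    stop("Model 2 needs at least 2 environments")
  model <- make_lmm(design, K = K, fixed = c("mu", "snp"),
                    random = c("polygenic", "slope_block"), eig = eig)
  if (is.null(fit1))
    fit1 <- fit_model1(design, K, reml = reml, restarts = restarts,
                       seed = seed, eig = eig)
  init <- list(sigma_u2 = fit1$var_params$sigma_u2,
               sigma_e02 = fit1$var_params$sigma_e2,
               sigma_e12 = fit1$var_params$sigma_e2 * 1e-4,
               sigma_e01 = 0,
               sigma_eps2 = fit1$var_params$sigma_eps2)
  fit <- fit_lmm(model, init = init, restarts = restarts, reml = reml,
                 seed = seed)
  if (fit$loglik < fit1$loglik) {
    ## the boundary point sigma_e12 = 0, sigma_e01 = 0 reproduces Model 1's
    ## covariance exactly, so Model 1's maximum is attainable in Model 2
    fit$var_params <- list(sigma_u2 = fit1$var_params$sigma_u2,
                           sigma_e02 = fit1$var_params$sigma_e2,
                           sigma_e12 = 0, sigma_e01 = 0,
                           sigma_eps2 = fit1$var_params$sigma_eps2)
    fit$beta_hat <- fit1$beta_hat
    fit$loglik <- fit1$loglik
  }
  fit
}

#' Genome-wide QTL-by-environment interaction scan
#'
#' For each marker, fits Model 1 (constant SNP effect) and Model 2
#' (per-environment random SNP slope) and performs the likelihood-ratio
#' test -2 log Lambda with df = 2 (the slope variance and the
#' intercept-slope covariance), then Benjamini-Hochberg FDR across all
#' scanned markers. Candidate SNPs (q below the threshold) are grouped
#' into candidate regions: maximal runs of candidate markers per
#' chromosome, bridged across gaps of at most one thinning window.
#'
#' @param G a [genotype_matrix] (thinned markers recommended).
#' @param P a [phenotype_table].
#' @param K kinship matrix (computed once from all thinned markers).
#' @param trait,year slice to scan.
#' @param fdr_threshold candidate threshold on q (default 0.01).
#' @param df_override optional LRT df replacing the parameter-count
#'   difference of 2.
#' @param reml fit criterion (default ML).
#' @param restarts,seed optimizer controls.
#' @param bridge_bp gap tolerance when assembling candidate regions
#'   (default 10 kb, one thinning window).
#' @param loco use a leave-one-chromosome-out kinship (recomputed from
#'   \code{G} without the focal marker's chromosome) instead of the
#'   single whole-genome \code{K}; guards against proximal
#'   contamination at the cost of one kinship per chromosome.
#' @return list with \code{scan}: data.frame (marker, chrom, pos,
#'   loglik_m1, loglik_m2, lrt, df, p, q, candidate) ordered by
#'   (chrom, pos), and \code{regions}: data.frame (chrom, start, end,
#'   best_marker, best_p, n_markers).
#' @export
scan_gxe <- function(G, P, K, trait, year, fdr_threshold = 0.01,
                     df_override = NULL, reml = FALSE, restarts = 2,
                     seed = 1, bridge_bp = 10000, loco = FALSE) {
  scan_markers(G, P, K, trait, year, kind = "gxe",
               fdr_threshold = fdr_threshold, df_override = df_override,
               reml = reml, restarts = restarts, seed = seed,
               bridge_bp = bridge_bp, loco = loco)
}

#' Cross-environment association scan
#'
#' Per-marker test of the overall SNP effect: Model 1 against the same
#' model without the fixed X beta term (df = 1), with BH FDR flagging.
#' This is the GWAS-style companion to [scan_gxe()]: it detects loci
#' whose effect is consistent across environments, whereas
#' [scan_gxe()] detects loci whose effect changes with the environment.
#'
#' @inheritParams scan_gxe
#' @return As [scan_gxe()] (loglik columns are null/alternative).
#' @export
scan_association <- function(G, P, K, trait, year, fdr_threshold = 0.01,
                             df_override = NULL, reml = FALSE,
                             restarts = 2, seed = 1, bridge_bp = 10000,
                             loco = FALSE) {
  scan_markers(G, P, K, trait, year, kind = "assoc",
               fdr_threshold = fdr_threshold, df_override = df_override,
               reml = reml, restarts = restarts, seed = seed,
               bridge_bp = bridge_bp, loco = loco)
}

scan_markers <- function(G, P, K, trait, year, kind, fdr_threshold,
                         df_override, reml, restarts, seed, bridge_bp,
                         loco = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  P <- phenotype_table(P, G)
  markers <- G$map$marker
  if (!length(markers)) stop("no markers to scan")
  Km <- if (inherits(K, "kinship_matrix")) K$K else as.matrix(K)
  Kloco <- NULL
  if (loco) {
    Kloco <- lapply(unique(G$map$chrom), function(ch) {
      keep <- G$map$chrom != ch
      if (!any(keep)) stop("LOCO impossible: only one chromosome")
      compute_kinship(genotype_matrix(G$codes[, keep, drop = FALSE],
                                      G$line_ids,
                                      G$map[keep, , drop = FALSE]))$K
    })
    names(Kloco) <- unique(G$map$chrom)
  }
  eig_cache <- list(key = NULL, eig = NULL)
  rows <- vector("list", length(markers))
  warm <- NULL
  n_poly <- 0L
  if (stats::var(P$value[P$trait == trait & P$year == year]) == 0)
    stop("phenotype is constant for trait '", trait, "', year ", year,
         ": every fit is degenerate")
  for (i in seq_along(markers)) {
    mk <- markers[i]
    design <- tryCatch(
      suppressMessages(build_stacked_design(G, P, trait = trait,
                                            year = year, marker_id = mk)),
      error = function(e) e)
    if (inherits(design, "error")) {
      rows[[i]] <- NULL
      next
    }
    Kuse <- if (loco) Kloco[[G$map$chrom[i]]] else Km
    key <- paste(if (loco) G$map$chrom[i] else "all",
                 paste(design$line_ids, collapse = "\r"))
    if (!identical(eig_cache$key, key)) {
      Ks <- Kuse[design$line_ids, design$line_ids]
      eig_cache <- list(key = key, eig = eigen(Ks, symmetric = TRUE))
      warm <- NULL
    }
    n_poly <- n_poly + 1L
    fit1 <- fit_model1(design, Kuse, reml = reml, restarts = restarts,
                       seed = seed, init = warm, eig = eig_cache$eig)
    warm <- fit1$var_params
    if (kind == "gxe") {
      fit2 <- fit_model2(design, Kuse, fit1 = fit1, reml = reml,
                         restarts = restarts, seed = seed,
                         eig = eig_cache$eig)
      tst <- lrt(fit1, fit2, df_override = df_override)
      ll0 <- fit1$loglik; ll1 <- fit2$loglik
    } else {
      model0 <- make_lmm(design, K = Kuse, fixed = "mu",
                         random = c("polygenic", "env"),
                         eig = eig_cache$eig)
      fit0 <- fit_lmm(model0, init = warm, restarts = restarts,
                      reml = reml, seed = seed)
      if (fit0$loglik > fit1$loglik) {
        ## beta = 0 is admissible in Model 1: never let the null win
        refit <- fit_lmm(make_lmm(design, K = Kuse, fixed = c("mu", "snp"),
                                  random = c("polygenic", "env"),
                                  eig = eig_cache$eig),
                         init = fit0$var_params, restarts = 1,
                         reml = reml, seed = seed)
        if (refit$loglik > fit1$loglik) fit1 <- refit
        if (fit0$loglik > fit1$loglik) fit1$loglik <- fit0$loglik
      }
      tst <- lrt(fit0, fit1, df_override = df_override)
      ll0 <- fit0$loglik; ll1 <- fit1$loglik
    }
    rows[[i]] <- data.frame(marker = mk, chrom = G$map$chrom[i],
                            pos = G$map$pos[i], loglik_null = ll0,
                            loglik_alt = ll1, lrt = tst$stat, df = tst$df,
                            p = tst$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res) || nrow(res) == 0L)
    stop("zero polymorphic markers: nothing to scan")
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  res$candidate <- res$q < fdr_threshold
  regions <- candidate_regions(res, bridge_bp = bridge_bp)
  list(scan = res, regions = regions, trait = trait, year = year,
       kind = kind, fdr_threshold = fdr_threshold,
       n_markers = nrow(res))
}

#' Assemble candidate regions from flagged markers
#'
#' Maximal runs of candidate markers per chromosome; consecutive
#' candidates separated by more than \code{bridge_bp} (one thinning
#' window by default) start a new region.
#'
#' @param scan scan data.frame with columns chrom, pos, marker, p,
#'   candidate.
#' @param bridge_bp maximum bp gap bridged between candidate markers.
#' @return data.frame (chrom, start, end, best_marker, best_p,
#'   n_markers), possibly empty.
#' @export
candidate_regions <- function(scan, bridge_bp = 10000) {
  cand <- scan[scan$candidate, , drop = FALSE]
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), best_marker = character(0),
                    best_p = numeric(0), n_markers = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(out)
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  ## a gap of at most one empty thinning window (positions at most two
  ## windows apart) is bridged
  new_run <- c(TRUE, cand$chrom[-1L] != cand$chrom[-nrow(cand)] |
                 diff(cand$pos) > 2 * bridge_bp)
  grp <- cumsum(new_run)
  for (g in unique(grp)) {
    s <- cand[grp == g, , drop = FALSE]
    b <- which.min(s$p)
    out <- rbind(out, data.frame(chrom = s$chrom[1L], start = min(s$pos),
                                 end = max(s$pos),
                                 best_marker = s$marker[b],
                                 best_p = s$p[b], n_markers = nrow(s),
                                 stringsAsFactors = FALSE))
  }
  out
}
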