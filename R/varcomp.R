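#' Variance-component decomposition with a GxE kernel
#'
#' Fits y = mu + Zu + We + Vx + eps with u ~ N(0, K sigma_u2),
#' e ~ N(0, sigma_e2 I) over environments, the GxE effect
#' x ~ N(0, (ZKZ' o WW') sigma_x2) (Hadamard product of the polygenic
#' and environment kernels) and iid residual, and reports the four
#' variance components and their proportions of the total.
#'
#' @param P a [phenotype_table] (or coercible data.frame).
#' @param K a \code{kinship_matrix} (or plain matrix with line dimnames).
#' @param G a [genotype_matrix] (supplies the design skeleton).
#' @param trait,year slice to analyse.
#' @param reml use REML (default) or ML for the variance estimates.
#'   REML is the default here because with a handful of environments
#'   the ML estimate of the environment variance is biased low; all
#'   likelihood-ratio scans use ML.
#' @param restarts,seed optimizer multi-start controls.
#' @return Object of class \code{variance_components}: list with the
#'   named components (\code{sigma_u2}, \code{sigma_e2}, \code{sigma_x2},
#'   \code{sigma_eps2}), \code{proportions} (summing to 1), \code{n_env},
#'   \code{loglik}, \code{fit}.
#' @export
estimate_variance_components <- function(P, K, G, trait, year,
                                         reml = TRUE, restarts = 3,
                                         seed = 1) {
  design <- build_stacked_design(G, P, trait = trait, year = year)
  model <- make_lmm(design, K = K, fixed = "mu",
                    random = c("polygenic", "env", "gxe"))
  fit <- fit_lmm(model, restarts = restarts, reml = reml, seed = seed)
  vp <- fit$var_params
  comps <- c(sigma_u2 = vp$sigma_u2, sigma_e2 = vp$sigma_e2,
             sigma_x2 = vp$sigma_x2, sigma_eps2 = vp$sigma_eps2)
  structure(list(sigma_u2 = vp$sigma_u2, sigma_e2 = vp$sigma_e2,
                 sigma_x2 = vp$sigma_x2, sigma_eps2 = vp$sigma_eps2,
                 proportions = comps / sum(comps),
                 n_env = length(design$env_ids),
                 loglik = fit$loglik, fit = fit),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  comp <- unlist(x[intersect(c("sigma_u2", "sigma_e2", "sigma_x2",
                               "sigma_gamma2", "sigma_eps2"), names(x))])
  cat("variance components:\n")
  print(round(comp, 6))
  cat("proportions:\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' H2 = sigma_u2 / (sigma_u2 + sigma_e2/ne + sigma_x2/ne + sigma_eps2/ne)
#' where ne is the number of trial locations; line means over ne
#' environments average down every non-genetic component.
#'
#' @param vc a \code{variance_components} object or a named list/vector
#'   with \code{sigma_u2}, \code{sigma_e2}, \code{sigma_x2},
#'   \code{sigma_eps2}.
#' @param ne number of trial locations (>= 1); defaults to
#'   \code{vc$n_env} when available.
#' @return H2 in [0, 1).
#' @export
broad_sense_heritability <- function(vc, ne = NULL) {
  v <- as.list(vc)
  if (is.null(ne)) ne <- v$n_env
  stopifnot(is.numeric(ne), ne >= 1)
  s <- c(v$sigma_u2, v$sigma_e2, v$sigma_x2, v$sigma_eps2)
  if (any(s < 0)) stop("variance components must be nonnegative")
  if (sum(s) == 0) stop("all variance components are zero: H2 undefined")
  v$sigma_u2 / (v$sigma_u2 + v$sigma_e2 / ne + v$sigma_x2 / ne +
                  v$sigma_eps2 / ne)
}

#' SNP-by-environment variance decomposition at a focal marker
#'
#' Fits y = mu + X beta + Zu + We + S gamma + eps with a fixed SNP
#' effect beta and iid per-environment SNP slopes
#' gamma ~ N(0, sigma_gamma2 I), and reports the share of the SxE
#' component in the total of the four random components (the
#' denominator excludes the fixed SNP effect).
#'
#' @param P,K,G,trait,year as in [estimate_variance_components()].
#' @param marker_id focal SNP (must be polymorphic among phenotyped
#'   lines).
#' @inheritParams estimate_variance_components
#' @return A \code{variance_components} object with components
#'   \code{sigma_u2}, \code{sigma_e2}, \code{sigma_gamma2},
#'   \code{sigma_eps2}, \code{proportions}, \code{beta_snp}.
#' @export
sxe_variance <- function(P, K, G, marker_id, trait, year, reml = TRUE,
                         restarts = 3, seed = 1) {
  design <- suppressMessages(
    build_stacked_design(G, P, trait = trait, year = year,
                         marker_id = marker_id))
  model <- make_lmm(design, K = K, fixed = c("mu", "snp"),
                    random = c("polygenic", "env", "snp_slope"))
  fit <- fit_lmm(model, restarts = restarts, reml = reml, seed = seed)
  vp <- fit$var_params
  comps <- c(sigma_u2 = vp$sigma_u2, sigma_e2 = vp$sigma_e2,
             sigma_gamma2 = vp$sigma_gamma2, sigma_eps2 = vp$sigma_eps2)
  structure(list(sigma_u2 = vp$sigma_u2, sigma_e2 = vp$sigma_e2,
                 sigma_gamma2 = vp$sigma_gamma2,
                 sigma_eps2 = vp$sigma_eps2,
                 proportions = comps / sum(comps),
                 beta_snp = unname(fit$beta_hat["snp"]),
                 n_env = length(design$env_ids),
                 marker_id = marker_id,
                 loglik = fit$loglik, fit = fit),
            class = "variance_components")
}
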