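## Gaussian linear mixed model engine.
##
## Every model in the pipeline is a weighted sum of fixed covariance
## kernels plus an iid residual:
##   Sigma(theta) = sigma_u2 ZKZ' + sigma_e2 WW' + sigma_x2 (ZKZ' o WW')
##                + sigma_gamma2 SS'
##                + [slope block: sigma_e02 WW' + sigma_e01 (WS'+SW')
##                   + sigma_e12 SS']
##                + sigma_eps2 I
## with fixed effects profiled out by generalized least squares.
##
## Two evaluation backends:
##  * dense  — forms Sigma, Cholesky; reference path, any design.
##  * rotated — for balanced complete designs (every line in every
##    environment): rotating observations by Q' x U', where U
##    diagonalizes the line kernel K and Q diagonalizes the
##    all-ones environment matrix, turns every kernel into a diagonal
##    plus a rank <= 2 update per environment block, so one likelihood
##    evaluation costs O(n_lines) instead of O(N^3).

#' Construct a linear mixed model over a stacked design
#'
#' @param design a \code{stacked_design} from [build_stacked_design()].
#' @param K kinship matrix (matrix or [compute_kinship()] output); required
#'   when \code{random} includes \code{"polygenic"} or \code{"gxe"}.
#' @param fixed character vector of fixed-effect terms among
#'   \code{"mu"} (intercept), \code{"snp"} (marker codes), \code{"E"}
#'   (environmental covariate), \code{"snp:E"} (their product).
#' @param random character vector of random components among
#'   \code{"polygenic"} (ZKZ'), \code{"env"} (WW'), \code{"gxe"}
#'   (Hadamard product ZKZ' o WW'), \code{"snp_slope"} (iid
#'   per-environment SNP slopes, SS'), \code{"slope_block"} (correlated
#'   per-environment intercept e0 and SNP slope e1 with 2x2 covariance).
#'   An iid residual is always included.
#' @param backend \code{"auto"} (rotated when the design is balanced),
#'   \code{"dense"}, or \code{"rotated"}.
#' @param eig optional precomputed \code{eigen()} of the line-subset K
#'   (list with \code{vectors}, \code{values}) to share across markers.
#' @return An object of class \code{lmm_model}.
#' @export
make_lmm <- function(design, K = NULL, fixed = c("mu", "snp"),
                     random = c("polygenic", "env"),
                     backend = c("auto", "dense", "rotated"), eig = NULL) {
  stopifnot(inherits(design, "stacked_design"))
  backend <- match.arg(backend)
  known_f <- c("mu", "snp", "E", "snp:E")
  known_r <- c("polygenic", "env", "gxe", "snp_slope", "slope_block")
  stopifnot(all(fixed %in% known_f), all(random %in% known_r))
  N <- length(design$y)
  cols <- list()
  for (f in fixed) {
    cols[[f]] <- switch(f,
      "mu" = rep(1, N),
      "snp" = design$X %||% stop("design has no SNP column"),
      "E" = design$E %||% stop("design has no environmental covariate"),
      "snp:E" = (design$X %||% stop("design has no SNP column")) *
                (design$E %||% stop("design has no environmental covariate")))
  }
  Xf <- do.call(cbind, cols)
  colnames(Xf) <- fixed
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1L):ncol(Xf)]]
    if ("snp" %in% bad)
      stop("SNP fixed effect is collinear with the intercept (monomorphic marker)")
    stop("collinear fixed-effect column(s): ", paste(bad, collapse = ", "))
  }
  needK <- any(c("polygenic", "gxe") %in% random)
  Ksub <- NULL
  if (needK) {
    if (is.null(K)) stop("kinship matrix K required for polygenic/gxe terms")
    Km <- if (inherits(K, "kinship_matrix")) K$K else as.matrix(K)
    if (!all(design$line_ids %in% rownames(Km)))
      stop("kinship matrix does not cover all design lines")
    Ksub <- Km[design$line_ids, design$line_ids, drop = FALSE]
  }
  if (any(c("snp_slope", "slope_block") %in% random) && is.null(design$S))
    stop("design has no SNP incidence S (no marker given)")
  use_rot <- switch(backend,
                    dense = FALSE,
                    rotated = TRUE,
                    auto = isTRUE(design$balanced))
  if (use_rot && !isTRUE(design$balanced))
    stop("rotated backend requires a balanced complete design")
  m <- list(design = design, Xfix = Xf, fixed = fixed, random = random,
            K = Ksub, backend = if (use_rot) "rotated" else "dense")
  m$param_info <- lmm_param_info(random)
  if (use_rot) m$rot <- rotate_model(m, eig) else m$mats <- dense_kernels(m)
  class(m) <- "lmm_model"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## parameter layout: named natural-scale variance parameters, in order
lmm_param_info <- function(random) {
  nm <- character(0)
  for (r in random) nm <- c(nm, switch(r,
    polygenic = "sigma_u2", env = "sigma_e2", gxe = "sigma_x2",
    snp_slope = "sigma_gamma2",
    slope_block = c("sigma_e02", "sigma_e12", "sigma_e01")))
  c(nm, "sigma_eps2")
}

dense_kernels <- function(m) {
  d <- m$design
  mats <- list()
  ZKZ <- NULL
  if (!is.null(m$K)) ZKZ <- d$Z %*% m$K %*% t(d$Z)
  for (r in m$random) mats[[r]] <- switch(r,
    polygenic = list(ZKZ),
    env = list(tcrossprod(d$W)),
    gxe = list(ZKZ * tcrossprod(d$W)),
    snp_slope = list(tcrossprod(d$S)),
    slope_block = list(tcrossprod(d$W), tcrossprod(d$S),
                       tcrossprod(d$W, d$S) + tcrossprod(d$S, d$W)))
  mats
}

## rotated backend precomputation: eigendecompose K, build the orthogonal
## environment rotation Q (first column 1/sqrt(E)), rotate y and fixed
## columns, and express each random component as per-block diagonal
## coefficients on eigenvalues d plus a shared low-rank F Gamma F' update.
rotate_model <- function(m, eig = NULL) {
  d <- m$design
  n <- length(d$line_ids); ne <- length(d$env_ids); N <- length(d$y)
  stopifnot(N == n * ne)
  if (!is.null(m$K)) {
    if (is.null(eig)) eig <- eigen(m$K, symmetric = TRUE)
    U <- eig$vectors
    ev <- pmax(eig$values, 0)
  } else {
    U <- diag(n); ev <- rep(0, n)
  }
  Q <- qr.Q(qr(cbind(rep(1, ne), diag(ne)[, -1L, drop = FALSE])))
  if (Q[1L, 1L] < 0) Q <- -Q
  rot_vec <- function(v) as.vector(crossprod(U, matrix(v, n, ne)) %*% Q)
  yr <- rot_vec(d$y)
  Xr <- apply(m$Xfix, 2L, rot_vec)
  dim(Xr) <- dim(m$Xfix); colnames(Xr) <- colnames(m$Xfix)
  ## F columns in the line space (shared across environment blocks)
  Fcols <- list(); Gmap <- list()
  for (r in m$random) {
    if (r == "env") {
      Fcols$u1 <- crossprod(U, rep(1, n))
      Gmap[[length(Gmap) + 1L]] <- list(type = "var", col = "u1",
                                        par = "sigma_e2")
    } else if (r == "snp_slope") {
      Fcols$ux <- crossprod(U, d$X[seq_len(n)])
      Gmap[[length(Gmap) + 1L]] <- list(type = "var", col = "ux",
                                        par = "sigma_gamma2")
    } else if (r == "slope_block") {
      Fcols$u1 <- crossprod(U, rep(1, n))
      Fcols$ux <- crossprod(U, d$X[seq_len(n)])
      Gmap[[length(Gmap) + 1L]] <- list(type = "block2",
                                        cols = c("u1", "ux"),
                                        pars = c("sigma_e02", "sigma_e12",
                                                 "sigma_e01"))
    }
  }
  Fm <- if (length(Fcols)) do.call(cbind, Fcols) else
    matrix(0, n, 0)
  colnames(Fm) <- names(Fcols)
  list(U = U, ev = ev, Q = Q, y = yr, X = Xr, Fm = Fm, Gmap = Gmap,
       n = n, ne = ne)
}

## assemble the r x r Gamma matrix of the low-rank update
rot_gamma <- function(rot, vp) {
  r <- ncol(rot$Fm)
  G <- matrix(0, r, r, dimnames = list(colnames(rot$Fm), colnames(rot$Fm)))
  for (g in rot$Gmap) {
    if (g$type == "var") {
      G[g$col, g$col] <- G[g$col, g$col] + vp[[g$par]]
    } else {
      G[g$cols, g$cols] <- G[g$cols, g$cols] +
        matrix(c(vp[["sigma_e02"]], vp[["sigma_e01"]],
                 vp[["sigma_e01"]], vp[["sigma_e12"]]), 2L, 2L)
    }
  }
  G
}

## GLS pieces shared by both backends: solves the normal equations and
## returns the residual quadratic form, log det Sigma and
## log det(X' Sigma^-1 X)
gls_parts <- function(XtSX, XtSy, ytSy, logdet, N, p) {
  ch <- tryCatch(chol(XtSX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, XtSy, transpose = TRUE))
  quad <- ytSy - sum(XtSy * beta)
  if (quad < 0) quad <- 0
  list(quad = as.numeric(quad), logdet = logdet,
       logdetX = 2 * sum(log(diag(ch))), beta = as.vector(beta),
       N = N, p = p)
}

## full log-likelihood (ML or REML) from the GLS pieces
parts_to_loglik <- function(parts, reml) {
  if (is.null(parts))
    return(list(loglik = -Inf, beta = NULL))
  ll <- -0.5 * (parts$N * log(2 * pi) + parts$logdet + parts$quad)
  if (reml)
    ll <- ll + 0.5 * parts$p * log(2 * pi) - 0.5 * parts$logdetX
  list(loglik = as.numeric(ll), beta = parts$beta)
}

## log-likelihood with the overall scale profiled out: the evaluators are
## called with sigma_eps2 = 1 and the remaining variances as ratios to
## the residual; the residual variance maximizing the likelihood is then
## quad/N (ML) or quad/(N - p) (REML) in closed form
parts_to_profiled <- function(parts, reml) {
  if (is.null(parts)) return(list(loglik = -Inf, scale = NA_real_))
  N <- parts$N; p <- parts$p
  if (parts$quad <= 0) return(list(loglik = -Inf, scale = NA_real_))
  if (reml) {
    s2 <- parts$quad / (N - p)
    ll <- -0.5 * ((N - p) * (log(2 * pi) + log(s2) + 1) + parts$logdet +
                    parts$logdetX)
  } else {
    s2 <- parts$quad / N
    ll <- -0.5 * (N * (log(2 * pi) + log(s2) + 1) + parts$logdet)
  }
  list(loglik = as.numeric(ll), scale = s2, beta = parts$beta)
}

lmm_parts <- function(m, vp) {
  if (m$backend == "rotated") lmm_eval_rotated(m, vp)
  else lmm_eval_dense(m, vp)
}

lmm_eval <- function(m, vp, reml = FALSE) {
  parts_to_loglik(lmm_parts(m, vp), reml)
}

lmm_eval_dense <- function(m, vp) {
  d <- m$design
  N <- length(d$y)
  Sig <- diag(vp[["sigma_eps2"]], N)
  for (r in m$random) {
    ms <- m$mats[[r]]
    if (r == "slope_block") {
      Sig <- Sig + vp[["sigma_e02"]] * ms[[1L]] + vp[["sigma_e12"]] * ms[[2L]] +
        vp[["sigma_e01"]] * ms[[3L]]
    } else {
      w <- vp[[switch(r, polygenic = "sigma_u2", env = "sigma_e2",
                      gxe = "sigma_x2", snp_slope = "sigma_gamma2")]]
      Sig <- Sig + w * ms[[1L]]
    }
  }
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Xs <- backsolve(ch, m$Xfix, transpose = TRUE)
  ys <- backsolve(ch, d$y, transpose = TRUE)
  gls_parts(crossprod(Xs), crossprod(Xs, ys), sum(ys^2),
            2 * sum(log(diag(ch))), N, ncol(m$Xfix))
}

lmm_eval_rotated <- function(m, vp) {
  rot <- m$rot
  n <- rot$n; ne <- rot$ne; N <- n * ne
  p <- ncol(rot$X)
  su <- if ("polygenic" %in% m$random) vp[["sigma_u2"]] else 0
  sx <- if ("gxe" %in% m$random) vp[["sigma_x2"]] else 0
  se2 <- vp[["sigma_eps2"]]
  if (se2 <= 0) return(NULL)
  G <- rot_gamma(rot, vp)
  r <- ncol(rot$Fm)
  Ir <- diag(1, r)
  XtSX <- matrix(0, p, p); XtSy <- numeric(p); ytSy <- 0; logdet <- 0
  for (b in seq_len(ne)) {
    a <- ne * su * (b == 1) + sx
    mdiag <- a * rot$ev + se2
    if (any(mdiag <= 0)) return(NULL)
    idx <- ((b - 1L) * n + 1L):(b * n)
    B <- cbind(rot$X[idx, , drop = FALSE], rot$y[idx])
    Bo <- B / mdiag
    if (r > 0L) {
      Fo <- rot$Fm / mdiag
      S <- crossprod(rot$Fm, Fo)
      M <- Ir + S %*% G
      dt <- det(M)
      if (!is.finite(dt) || dt <= 0) return(NULL)
      Tm <- crossprod(rot$Fm, Bo)
      Bo <- Bo - Fo %*% (G %*% solve(M, Tm))
      logdet <- logdet + sum(log(mdiag)) + log(dt)
    } else {
      logdet <- logdet + sum(log(mdiag))
    }
    Gfull <- crossprod(B, Bo)
    XtSX <- XtSX + Gfull[seq_len(p), seq_len(p), drop = FALSE]
    XtSy <- XtSy + Gfull[seq_len(p), p + 1L]
    ytSy <- ytSy + Gfull[p + 1L, p + 1L]
  }
  gls_parts(XtSX, XtSy, ytSy, logdet, N, p)
}

#' Evaluate the profiled log-likelihood of a mixed model
#'
#' Fixed effects are profiled out by GLS at the supplied variance
#' parameters; the returned value is the exact multivariate-normal
#' log-likelihood at the GLS estimates.
#'
#' @param model an [make_lmm()] object.
#' @param var_params named list/vector of variance parameters on the
#'   natural scale (see \code{model$param_info} for the names; always
#'   includes \code{sigma_eps2}).
#' @param reml use the REML criterion instead of ML.
#' @return log-likelihood (scalar; \code{-Inf} for an invalid
#'   parameter combination).
#' @export
lmm_loglik <- function(model, var_params, reml = FALSE) {
  vp <- as.list(var_params)
  miss <- setdiff(model$param_info, names(vp))
  if (length(miss)) stop("missing variance parameter(s): ",
                         paste(miss, collapse = ", "))
  res <- lmm_eval(model, vp, reml)
  if (!is.finite(res$loglik) && !is.null(vp$sigma_eps2) &&
      vp$sigma_eps2 <= 0)
    stop("singular covariance: sigma_eps2 must be > 0")
  res$loglik
}

## natural <-> transformed parameter scale: log for variances, atanh for
## the slope-block correlation (keeps the 2x2 block PSD by construction)
par_to_theta <- function(vp, info) {
  th <- numeric(length(info))
  for (i in seq_along(info)) {
    nm <- info[i]
    if (nm == "sigma_e01") {
      denom <- sqrt(vp[["sigma_e02"]] * vp[["sigma_e12"]])
      rho <- if (denom > 0) vp[["sigma_e01"]] / denom else 0
      th[i] <- atanh(max(-0.99, min(0.99, rho)))
    } else th[i] <- log(max(vp[[nm]], 1e-12))
  }
  th
}

theta_to_par <- function(th, info) {
  vp <- list()
  for (i in seq_along(info)) {
    nm <- info[i]
    if (nm == "sigma_e01") next
    vp[[nm]] <- exp(min(th[i], 50))
  }
  i01 <- match("sigma_e01", info)
  if (!is.na(i01)) {
    rho <- tanh(th[i01])
    vp[["sigma_e01"]] <- rho * sqrt(vp[["sigma_e02"]] * vp[["sigma_e12"]])
  }
  vp
}

## run fn with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Fit a mixed model by ML (or REML)
#'
#' Maximizes the profiled log-likelihood over variance parameters by
#' Nelder-Mead on a transformed scale (log variances, atanh slope
#' correlation) with multi-start: a method-of-moments start plus
#' jittered restarts, deterministic given \code{seed}. Supplying
#' \code{init} adds a warm start, which guarantees the fitted
#' log-likelihood is at least the warm start's.
#'
#' @param model an [make_lmm()] object.
#' @param init optional named variance parameters used as a warm start.
#' @param restarts number of starts (>= 1).
#' @param reml logical.
#' @param seed integer controlling restart jitter.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param max_iter Nelder-Mead iteration cap per start.
#' @return An object of class \code{lmm_fit}: \code{beta_hat},
#'   \code{var_params} (natural scale), \code{loglik}, \code{n_params}
#'   (fixed + variance), \code{converged}, \code{n_restarts_used}.
#' @export
fit_lmm <- function(model, init = NULL, restarts = 3, reml = FALSE,
                    seed = NULL, tol = 1e-8, max_iter = 2000) {
  info <- model$param_info
  ## the overall scale is profiled out analytically: optimize over the
  ## component-to-residual variance ratios with sigma_eps2 fixed at 1
  free <- setdiff(info, "sigma_eps2")
  nfree <- length(free)
  ratio_vp <- function(th) c(theta_to_par(th, free), list(sigma_eps2 = 1))
  negll <- function(th) {
    pl <- parts_to_profiled(lmm_parts(model, ratio_vp(th)), reml)
    if (!is.finite(pl$loglik)) 1e10 else -pl$loglik
  }
  finish <- function(th, converged, used) {
    vpr <- ratio_vp(th)
    pl <- parts_to_profiled(lmm_parts(model, vpr), reml)
    if (!is.finite(pl$loglik))
      stop("all restarts diverged: no valid parameter point found")
    vp <- lapply(vpr, function(v) v * pl$scale)
    res <- lmm_eval(model, vp, reml)
    beta <- res$beta
    names(beta) <- colnames(model$Xfix)
    structure(list(beta_hat = beta, var_params = vp, loglik = res$loglik,
                   n_params = ncol(model$Xfix) + length(info),
                   converged = converged, n_restarts_used = used,
                   reml = reml, fixed = model$fixed, random = model$random),
              class = "lmm_fit")
  }
  if (nfree == 0L)
    return(finish(numeric(0), TRUE, 0L))
  to_ratio_start <- function(vp) {
    vp <- as.list(vp)
    s <- max(vp$sigma_eps2, 1e-10)
    vp <- lapply(vp, function(v) v / s)
    par_to_theta(vp, free)
  }
  vtot <- stats::var(model$design$y)
  if (!is.finite(vtot) || vtot <= 0) vtot <- 1
  mom <- list()
  for (nm in info) mom[[nm]] <- if (nm == "sigma_e01") 0 else
    vtot / sum(info != "sigma_e01")
  starts <- list(to_ratio_start(mom))
  if (!is.null(init)) starts <- c(list(to_ratio_start(init)), starts)
  extra <- restarts - length(starts)
  if (extra > 0) {
    jit <- with_local_seed(seed, function()
      matrix(stats::runif(extra * nfree, -1.5, 1.5), extra, nfree))
    for (j in seq_len(extra)) starts <- c(starts, list(starts[[1L]] + jit[j, ]))
  }
  best <- NULL
  used <- 0L
  for (st in starts) {
    used <- used + 1L
    if (nfree == 1L) {
      o <- stats::optimize(function(z) negll(z), interval = c(-25, 25),
                           tol = 1e-9)
      o <- list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      o <- stats::optim(st, negll, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = max_iter))
      ## restart the collapsed simplex once at the optimum
      o2 <- stats::optim(o$par, negll, method = "Nelder-Mead",
                         control = list(reltol = tol, maxit = max_iter))
      if (o2$value <= o$value) o2$convergence <- 0L else o2 <- o
      o <- o2
    }
    if (is.null(best) || o$value < best$value) best <- o
    if (nfree == 1L) break  # optimize() is global on the interval
  }
  if (best$value >= 1e10)
    stop("all restarts diverged; best objective ", best$value)
  finish(best$par, best$convergence == 0, used)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: logLik %.4f (%s), %d parameters%s\n",
              x$loglik, if (x$reml) "REML" else "ML", x$n_params,
              if (x$converged) "" else " [not converged]"))
  cat("fixed effects:\n"); print(x$beta_hat)
  cat("variance parameters:\n"); print(unlist(x$var_params))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' The statistic is \eqn{-2 \log \Lambda = 2 (\ell_{alt} - \ell_{null})},
#' floored at zero, referred to a chi-squared distribution whose degrees
#' of freedom equal the difference in total parameter counts. For
#' variance-component boundaries this plain chi-squared reference is
#' conservative; \code{df_override} substitutes another df.
#'
#' @param fit_null,fit_alt [fit_lmm()] results for nested models.
#' @param df_override optional df replacing the parameter-count difference.
#' @return list with \code{stat}, \code{df}, \code{p}.
#' @export
lrt <- function(fit_null, fit_alt, df_override = NULL) {
  if (fit_null$n_params >= fit_alt$n_params)
    stop("models are not nested: null must have fewer parameters")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6)
    warning(sprintf("negative LRT statistic (%.3g): optimizer failure in the alternative fit", stat))
  stat <- max(stat, 0)
  df <- if (is.null(df_override)) fit_alt$n_params - fit_null$n_params
        else df_override
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
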