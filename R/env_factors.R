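#' Read a daily weather CSV
#'
#' Columns: location, year, date (YYYY-MM-DD), tmin, tmax,
#' precipitation, sunshine. A derived variable tmean = (tmin + tmax)/2
#' is added. Values are reshaped to long form, one row per
#' (location, year, date, variable).
#'
#' @param path CSV path.
#' @return data.frame (location, year, date, variable, value) of class
#'   \code{weather_series}.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "year", "date", "tmin", "tmax", "precipitation",
            "sunshine")
  if (!all(need %in% names(d)))
    stop("weather CSV needs columns: ", paste(need, collapse = ", "))
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable date in weather CSV")
  d$tmean <- (d$tmin + d$tmax) / 2
  vars <- c("tmin", "tmax", "tmean", "precipitation", "sunshine")
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(location = d$location, year = as.integer(d$year),
               date = d$date, variable = v, value = as.numeric(d[[v]]),
               stringsAsFactors = FALSE)))
  key <- paste(long$location, long$year, long$date, long$variable)
  if (anyDuplicated(key)) stop("duplicate weather record")
  class(long) <- c("weather_series", "data.frame")
  long
}

#' Read a soil composition CSV
#'
#' Wide CSV with columns location, year and one column per soil
#' property (e.g. pH, EC, CEC, NH4, NO3, CaO, MgO, K2O, P2O5); values
#' are constant within a (location, year).
#'
#' @param path CSV path.
#' @return data.frame (location, year, factor, value).
#' @export
read_soil <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("location", "year") %in% names(d)))
    stop("soil CSV needs columns location, year")
  props <- setdiff(names(d), c("location", "year"))
  do.call(rbind, lapply(props, function(pv)
    data.frame(location = d$location, year = as.integer(d$year),
               factor = pv, value = as.numeric(d[[pv]]),
               stringsAsFactors = FALSE)))
}

#' Windowed weather means ahead of heading
#'
#' For each (line, environment, year) with a heading date, averages each
#' daily weather variable over the closed windows
#' [heading - b, heading - a] days for (a, b) in \code{windows}
#' (defaults 0-30, 15-45 and 30-60 days prior to heading; each window
#' spans b - a + 1 days, both ends inclusive). Missing days inside a
#' window raise an error listing the gaps; nothing is interpolated.
#'
#' @param weather a \code{weather_series} from [read_weather()].
#' @param heading data.frame (line, environment, year, heading_date);
#'   \code{heading_date} coercible to Date. The environment id must
#'   match the weather \code{location}.
#' @param windows list of c(a, b) day offsets.
#' @return data.frame (line, environment, year, factor, value) with
#'   factor names \code{<variable>_<a>_<b>d}, class
#'   \code{env_covariate_table}.
#' @export
window_means <- function(weather, heading,
                         windows = list(c(0, 30), c(15, 45), c(30, 60))) {
  heading <- as.data.frame(heading, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "environment", "year", "heading_date") %in%
                  names(heading)))
  heading$heading_date <- as.Date(heading$heading_date)
  vars <- unique(weather$variable)
  out <- vector("list", 0L)
  wkey <- paste(weather$location, weather$year, weather$variable)
  for (i in seq_len(nrow(heading))) {
    h <- heading[i, ]
    for (v in vars) {
      sel <- weather[wkey == paste(h$environment, h$year, v), , drop = FALSE]
      for (w in windows) {
        a <- w[1L]; b <- w[2L]
        days <- seq(h$heading_date - b, h$heading_date - a, by = "day")
        idx <- match(days, sel$date)
        if (anyNA(idx)) {
          gaps <- days[is.na(idx)]
          stop(sprintf("weather gap for %s/%d %s, window %d-%d d: %s",
                       h$environment, h$year, v, a, b,
                       paste(utils::head(gaps, 5L), collapse = ", ")))
        }
        out[[length(out) + 1L]] <- data.frame(
          line = h$line, environment = h$environment, year = h$year,
          factor = sprintf("%s_%d_%dd", v, a, b),
          value = mean(sel$value[idx]), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("env_covariate_table", "data.frame")
  res
}

#' Test one environmental factor for interaction with a focal locus
#'
#' Compares Model 3 (y = mu + X beta + E betaE + Zu + eps) against
#' Model 4, which adds the fixed interaction X*E betai, by a
#' likelihood-ratio test with df = 1. The covariate E is standardized
#' to mean 0, sd 1 before fitting (the LRT is invariant to this affine
#' rescaling). Random structure per the model statements: polygenic
#' effect and iid residual only.
#'
#' @param P a [phenotype_table].
#' @param K kinship matrix.
#' @param G a [genotype_matrix].
#' @param marker_id focal SNP.
#' @param covariates an \code{env_covariate_table} (long data.frame
#'   line/environment/year/factor/value, or environment-level rows
#'   without a line column).
#' @param factor_name which factor to test.
#' @param trait,year phenotype slice.
#' @param reml,restarts,seed fitting controls.
#' @return one-row data.frame: factor, beta_interaction, loglik_m3,
#'   loglik_m4, lrt, df, p.
#' @export
test_env_factor <- function(P, K, G, marker_id, covariates, factor_name,
                            trait, year, reml = FALSE, restarts = 2,
                            seed = 1) {
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  cv <- cv[cv$factor == factor_name, , drop = FALSE]
  if (!nrow(cv)) stop("no covariate values for factor ", factor_name)
  if ("line" %in% names(cv) && all(is.na(cv$line)))
    cv$line <- NULL  # location-constant factor (e.g. soil)
  if (stats::sd(cv$value) == 0)
    stop("factor '", factor_name,
         "' is constant: interaction unidentifiable")
  design <- suppressMessages(
    build_stacked_design(G, P, trait = trait, year = year,
                         marker_id = marker_id, env_covariate = cv))
  env_mean <- tapply(design$E, design$obs$environment, mean)
  if (max(abs(design$E - env_mean[design$obs$environment])) < 1e-12)
    message("factor '", factor_name, "' is constant within environments: ",
            "with few environments it is confounded with the environment labels")
  design$E <- as.numeric(scale(design$E))
  m3 <- make_lmm(design, K = K, fixed = c("mu", "snp", "E"),
                 random = "polygenic")
  fit3 <- fit_lmm(m3, restarts = restarts, reml = reml, seed = seed)
  m4 <- make_lmm(design, K = K, fixed = c("mu", "snp", "E", "snp:E"),
                 random = "polygenic")
  fit4 <- fit_lmm(m4, init = fit3$var_params, restarts = restarts,
                  reml = reml, seed = seed)
  if (fit4$loglik < fit3$loglik) fit4$loglik <- fit3$loglik
  tst <- lrt(fit3, fit4)
  data.frame(factor = factor_name,
             beta_interaction = unname(fit4$beta_hat["snp:E"]),
             loglik_m3 = fit3$loglik, loglik_m4 = fit4$loglik,
             lrt = tst$stat, df = tst$df, p = tst$p,
             stringsAsFactors = FALSE)
}

#' Test and rank all environmental factors at a locus
#'
#' Runs [test_env_factor()] for every factor in the covariate table and
#' applies Benjamini-Hochberg FDR across the full factor list within
#' the (trait, year); rows are sorted by q then p.
#'
#' @inheritParams test_env_factor
#' @param fdr_threshold flag threshold on q.
#' @return data.frame with the per-factor test columns plus q and
#'   significant.
#' @export
rank_env_factors <- function(P, K, G, marker_id, covariates, trait, year,
                             fdr_threshold = 0.01, reml = FALSE,
                             restarts = 2, seed = 1) {
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  facs <- unique(cv$factor)
  if (!length(facs)) stop("no factors to test")
  rows <- lapply(facs, function(f)
    test_env_factor(P, K, G, marker_id, cv, f, trait, year,
                    reml = reml, restarts = restarts, seed = seed))
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < fdr_threshold
  res[order(res$q, res$p), , drop = FALSE]
}
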