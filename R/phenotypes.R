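#' Validate a long-format multi-environment phenotype table
#'
#' Observations are line means per trial: one row per
#' (line, environment, year, trait), column \code{value} numeric and
#' finite. Missing observations are simply absent rows.
#'
#' @param df data.frame with columns \code{line}, \code{environment},
#'   \code{year}, \code{trait}, \code{value}.
#' @param G optional [genotype_matrix]; if given, every line must be
#'   genotyped.
#' @return The validated data.frame with class \code{phenotype_table}.
#' @export
phenotype_table <- function(df, G = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("line", "environment", "year", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$line <- as.character(df$line)
  df$environment <- as.character(df$environment)
  df$year <- as.integer(df$year)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value)))
    stop("phenotype values must be finite")
  key <- paste(df$line, df$environment, df$year, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, environment, year, trait) record")
  if (!is.null(G)) {
    miss <- setdiff(df$line, G$line_ids)
    if (length(miss))
      stop("phenotyped line(s) absent from genotype matrix: ",
           paste(utils::head(miss, 3L), collapse = ", "))
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a phenotype CSV
#'
#' @param path CSV with columns line, environment, year, trait, value.
#' @param G optional [genotype_matrix] for cross-validation.
#' @return A [phenotype_table].
#' @export
read_phenotypes <- function(path, G = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE), G)
}

#' Stack a multi-environment design for mixed-model fitting
#'
#' Builds the observation vector y and the incidence structure relating
#' observations to lines (Z), environments (W) and line-by-environment
#' cells (V), plus the per-observation SNP covariate X and its
#' environment-wise broadcast S when a marker is given. Rows are ordered
#' (environment, line). Rows with missing phenotype are dropped, never
#' imputed; lines coded 0 at the focal marker are dropped from that
#' marker's design.
#'
#' @param G a [genotype_matrix].
#' @param P a [phenotype_table].
#' @param trait,year which trait/year slice to analyse (analyses are per
#'   trait and per year; years are never pooled).
#' @param marker_id optional focal SNP.
#' @param env_covariate optional data.frame (line, environment, year,
#'   value) giving a per-observation environmental covariate E.
#' @return A \code{stacked_design} list: \code{y}, \code{Z}, \code{W},
#'   \code{V}, \code{X} (NULL without marker), \code{S}, \code{E},
#'   \code{obs} (line/environment per row), \code{line_ids},
#'   \code{env_ids}, \code{balanced}.
#' @export
build_stacked_design <- function(G, P, trait, year, marker_id = NULL,
                                 env_covariate = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  P <- phenotype_table(P, G)
  d <- P[P$trait == trait & P$year == year, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no phenotype records for trait '", trait, "', year ", year)
  env_ids <- sort(unique(d$environment))
  if (length(env_ids) < 2L)
    stop("only one environment present: GxE is untestable")
  x_line <- NULL
  if (!is.null(marker_id)) {
    if (!marker_id %in% colnames(G$codes))
      stop("marker not found: ", marker_id)
    x_line <- G$codes[, marker_id]
    dropped <- names(x_line)[x_line == 0L]
    if (length(dropped))
      message(sprintf("marker %s: dropping %d line(s) with unresolved code 0",
                      marker_id, length(dropped)))
    d <- d[!d$line %in% dropped, , drop = FALSE]
    if (length(unique(x_line[unique(d$line)])) < 2L)
      stop("marker ", marker_id, " is monomorphic among phenotyped lines")
  }
  line_ids <- sort(unique(d$line))
  ## order rows (environment, line)
  d <- d[order(match(d$environment, env_ids), match(d$line, line_ids)), ,
         drop = FALSE]
  N <- nrow(d)
  n <- length(line_ids); ne <- length(env_ids)
  li <- match(d$line, line_ids)
  ei <- match(d$environment, env_ids)
  Z <- matrix(0, N, n, dimnames = list(NULL, line_ids))
  Z[cbind(seq_len(N), li)] <- 1
  W <- matrix(0, N, ne, dimnames = list(NULL, env_ids))
  W[cbind(seq_len(N), ei)] <- 1
  V <- matrix(0, N, n * ne)
  V[cbind(seq_len(N), (ei - 1L) * n + li)] <- 1
  X <- S <- NULL
  if (!is.null(x_line)) {
    X <- as.numeric(x_line[d$line])
    S <- W * X
  }
  E <- NULL
  if (!is.null(env_covariate)) {
    ec <- as.data.frame(env_covariate, stringsAsFactors = FALSE)
    if (!"line" %in% names(ec)) {       # location-constant covariate
      idx <- match(paste(d$environment, d$year),
                   paste(ec$environment, ec$year))
    } else {
      idx <- match(paste(d$line, d$environment, d$year),
                   paste(ec$line, ec$environment, ec$year))
    }
    if (anyNA(idx)) stop("environmental covariate missing for ",
                         sum(is.na(idx)), " observation(s)")
    E <- as.numeric(ec$value[idx])
  }
  counts <- table(factor(d$line, line_ids), factor(d$environment, env_ids))
  balanced <- all(counts == 1L)
  structure(list(y = d$value, Z = Z, W = W, V = V, X = X, S = S, E = E,
                 obs = d[c("line", "environment", "year")],
                 line_ids = line_ids, env_ids = env_ids,
                 trait = trait, year = year, marker_id = marker_id,
                 balanced = balanced),
            class = "stacked_design")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q for the i-th smallest p is
#' min over j >= i of m * p_(j) / j, capped at 1.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values))) stop("NaN/NA p-value in bh_fdr input")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
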