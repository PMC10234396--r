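#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' K = M M' / c with M the column-centered code matrix and
#' c = sum_m 2 p_m (1 - p_m), p_m the observed frequency of the +1
#' allele at marker m. Codes of 0 (missing/unresolved) are mean-imputed
#' per marker for K only. The result is symmetrized and its spectrum
#' clipped at zero (eigenvalues above -1e-8 only are expected).
#'
#' @param G a [genotype_matrix].
#' @return Object of class \code{kinship_matrix}: list with \code{K}
#'   (n x n, dimnames = line ids) and \code{line_ids}.
#' @export
compute_kinship <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  M <- G$codes * 1.0
  if (nrow(M) < 2L || ncol(M) < 1L)
    stop("need at least 2 lines and 1 marker")
  ## allele frequency of the +1 allele on the 0..1 scale: code -1,+1 -> 0,1
  for (j in seq_len(ncol(M))) {
    z <- M[, j] == 0
    if (any(z)) M[z, j] <- mean(M[!z, j])
  }
  p <- colMeans((M + 1) / 2)
  c0 <- sum(2 * p * (1 - p))
  if (c0 <= 0) stop("all markers monomorphic: kinship undefined")
  Mc <- sweep(M, 2L, colMeans(M))
  K <- tcrossprod(Mc) / c0
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < 0)
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(K) <- list(G$line_ids, G$line_ids)
  structure(list(K = K, line_ids = G$line_ids), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d lines, mean diagonal %.3f\n",
              nrow(x$K), mean(diag(x$K))))
  invisible(x)
}

#' Read / write a kinship matrix as square TSV
#'
#' Line ids form the header row and first column. Any symmetric PSD
#' matrix supplied this way is accepted in place of the marker-derived K.
#'
#' @param path TSV path.
#' @return [read_kinship()]: a \code{kinship_matrix}.
#' @export
read_kinship <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  K <- as.matrix(d)
  if (nrow(K) != ncol(K) || !isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
    stop("kinship file must hold a square symmetric matrix")
  K <- (K + t(K)) / 2
  structure(list(K = K, line_ids = rownames(K)), class = "kinship_matrix")
}

#' @rdname read_kinship
#' @param kin a \code{kinship_matrix}.
#' @export
write_kinship <- function(kin, path) {
  d <- data.frame(line = kin$line_ids, kin$K, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
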