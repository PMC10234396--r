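#' Genotype matrix for a biparental RIL population
#'
#' Container for parental-origin coded genotypes: rows are lines, columns
#' are markers. Codes are +1 (allele from the common parent), -1 (allele
#' from the alternate parent) and 0 (missing or unresolved heterozygote).
#' The symmetric coding makes the SNP fixed effect beta half the
#' homozygote contrast.
#'
#' @param codes integer/numeric matrix, lines x markers, entries in
#'   \{-1, 0, +1\}.
#' @param line_ids character vector of unique line identifiers, one per row.
#' @param map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos} (1-based bp), one row per column of \code{codes}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{codes} (matrix with dimnames), \code{line_ids}, \code{map}.
#' @export
genotype_matrix <- function(codes, line_ids, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("genotype codes must be -1, 0 or +1")
  line_ids <- as.character(line_ids)
  if (length(line_ids) != nrow(codes))
    stop("length(line_ids) != nrow(codes)")
  if (anyDuplicated(line_ids))
    stop("duplicate line id: ", line_ids[duplicated(line_ids)][1L])
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("map must have columns marker, chrom, pos")
  map <- map[need]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != ncol(codes))
    stop("nrow(map) != ncol(codes)")
  if (anyDuplicated(map$marker))
    stop("duplicate marker id: ", map$marker[duplicated(map$marker)][1L])
  key <- paste(map$chrom, map$pos)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1L]
    stop("duplicate (chromosome, position): ", bad)
  }
  ## markers must be sorted by (chrom, pos), positions strictly increasing
  ## within chromosome
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    codes <- codes[, ord, drop = FALSE]
    map <- map[ord, , drop = FALSE]
    rownames(map) <- NULL
  }
  dimnames(codes) <- list(line_ids, map$marker)
  structure(list(codes = codes, line_ids = line_ids, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  tab <- table(factor(x$codes, levels = c(-1, 0, 1)))
  cat(sprintf("codes: -1 x %d, 0 x %d, +1 x %d\n", tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Read RIL genotypes from a VCF or a delimited code matrix
#'
#' For \code{format = "tsv_matrix"} the file holds the code matrix directly
#' (rows = lines, first column = line id, remaining columns = markers coded
#' A/B/H or +1/-1/0) and a sidecar map file \code{<path>.map} (TSV with
#' columns marker, chrom, pos) supplies coordinates. For
#' \code{format = "vcf"} biallelic SNP records are recoded against the two
#' parental samples: a RIL genotype matching \code{parent_a_id}'s homozygous
#' call is +1, matching \code{parent_b_id} is -1, heterozygous or missing
#' is 0. Non-biallelic records are skipped with a warning count.
#'
#' @param path input file.
#' @param format one of \code{"tsv_matrix"}, \code{"vcf"}.
#' @param parent_a_id,parent_b_id sample names of the common (+1) and
#'   alternate (-1) parent; required for VCF and for letter-coded matrices.
#' @param map_path map file for \code{tsv_matrix} (default \code{<path>.map}).
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("tsv_matrix", "vcf"),
                           parent_a_id = NULL, parent_b_id = NULL,
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  G <- switch(format,
              tsv_matrix = read_genotypes_tsv(path, map_path),
              vcf = read_genotypes_vcf(path, parent_a_id, parent_b_id))
  tab <- table(factor(G$codes, levels = c(-1, 0, 1)))
  message(sprintf("read %d lines x %d markers (codes: +1 x %d, -1 x %d, 0 x %d)",
                  nrow(G$codes), ncol(G$codes), tab[3L], tab[1L], tab[2L]))
  G
}

read_genotypes_tsv <- function(path, map_path = NULL) {
  if (is.null(map_path)) map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  line_ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (is.character(m)) {
    lut <- c(A = 1L, B = -1L, H = 0L, N = 0L)
    bad <- setdiff(unique(as.vector(m)), names(lut))
    if (length(bad)) stop("unknown genotype letter(s): ",
                          paste(bad, collapse = ", "))
    m <- matrix(lut[m], nrow = nrow(m), dimnames = dimnames(m))
  }
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  map <- map[match(colnames(m), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("map file missing markers present in matrix")
  genotype_matrix(m, line_ids, map)
}

read_genotypes_vcf <- function(path, parent_a_id, parent_b_id) {
  if (is.null(parent_a_id) || is.null(parent_b_id))
    stop("parent_a_id and parent_b_id are required for VCF input")
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  if (any(multi)) {
    warning(sum(multi), " non-biallelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  for (p in c(parent_a_id, parent_b_id))
    if (!p %in% colnames(gt)) stop("parent sample not in VCF: ", p)
  ## dosage of ALT allele: 0, 1, 2 or NA
  dose <- function(g) {
    g <- sub(":.*", "", g)
    a <- substr(g, 1L, 1L); b <- substr(g, 3L, 3L)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  }
  dos <- apply(gt, 2L, dose)
  dim(dos) <- dim(gt); dimnames(dos) <- dimnames(gt)
  pa <- dos[, parent_a_id]; pb <- dos[, parent_b_id]
  informative <- !is.na(pa) & !is.na(pb) & (pa %in% c(0L, 2L)) &
    (pb %in% c(0L, 2L)) & pa != pb
  dos <- dos[informative, , drop = FALSE]
  fix <- fix[informative, , drop = FALSE]
  pa <- pa[informative]
  ril <- setdiff(colnames(dos), c(parent_a_id, parent_b_id))
  codes <- matrix(0L, nrow = length(ril), ncol = nrow(dos),
                  dimnames = list(ril, NULL))
  for (i in seq_along(ril)) {
    d <- dos[, ril[i]]
    codes[i, ] <- ifelse(is.na(d) | d == 1L, 0L,
                         ifelse(d == pa, 1L, -1L))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  genotype_matrix(codes, ril, map)
}

#' Write a genotype matrix as TSV plus sidecar map
#'
#' Inverse of \code{read_genotypes(format = "tsv_matrix")}: writes
#' \code{path} (line id + numeric codes) and \code{path.map}.
#'
#' @param G a [genotype_matrix].
#' @param path output TSV path.
#' @export
write_genotypes <- function(G, path) {
  d <- data.frame(line = G$line_ids, G$codes, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Thin markers to one SNP per genomic window
#'
#' Keeps the first marker in each non-overlapping window of
#' \code{window_bp} base pairs per chromosome; windows are anchored at
#' position 0 (window k covers [k*window_bp, (k+1)*window_bp)). Thinning
#' is idempotent.
#'
#' @param G a [genotype_matrix].
#' @param window_bp window width in bp (default 10 kb).
#' @return A [genotype_matrix] with the retained markers, order preserved.
#' @export
thin_markers <- function(G, window_bp = 10000) {
  stopifnot(inherits(G, "genotype_matrix"), window_bp > 0)
  if (ncol(G$codes) == 0L) return(G)
  win <- floor(G$map$pos / window_bp)
  keep <- !duplicated(paste(G$map$chrom, win))
  genotype_matrix(G$codes[, keep, drop = FALSE], G$line_ids,
                  G$map[keep, , drop = FALSE])
}
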