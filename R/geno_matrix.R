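#' Genotype matrix container
#'
#' Bundles an individuals-by-sites matrix of diploid genotypes coded as
#' alternate-allele counts (0, 1, 2, or `NA` for missing) with a site table
#' holding chromosome, 1-based position and the two alleles.
#'
#' @param genotypes Integer matrix, individuals in rows, sites in columns.
#'   Non-missing values must be 0, 1 or 2.
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`; one row
#'   per genotype column. Positions must be strictly increasing within a
#'   chromosome and the two alleles must differ.
#' @param individual_ids Character vector of unique individual labels;
#'   defaults to the matrix rownames or `ind1, ind2, ...`.
#' @return An object of class `geno_matrix`: a list with elements
#'   `genotypes` (matrix with individual ids as rownames) and `sites`.
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                   sites = data.frame(chrom = "1", pos = c(100L, 200L),
#'                                      ref = "A", alt = "G"))
#' n_sites(gm)
#' @export
geno_matrix <- function(genotypes, sites, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(individual_ids)) {
    individual_ids <- rownames(genotypes)
    if (is.null(individual_ids))
      individual_ids <- paste0("ind", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  if (length(individual_ids) != nrow(genotypes))
    stop("individual_ids length does not match genotype rows")
  rownames(genotypes) <- individual_ids
  sites <- as.data.frame(sites)
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(sites)))
    stop("site table needs columns: ", paste(required, collapse = ", "))
  if (nrow(sites) != ncol(genotypes))
    stop("site table rows (", nrow(sites), ") do not match genotype columns (",
         ncol(genotypes), ")")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing genotypes must be 0, 1 or 2")
  if (nrow(sites)) {
    if (any(sites$ref == sites$alt))
      stop("ref and alt alleles must differ")
    for (chr in unique(sites$chrom)) {
      p <- sites$pos[sites$chrom == chr]
      if (any(diff(p) <= 0))
        stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  structure(list(genotypes = genotypes, sites = sites), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "sites\n")
  nmiss <- sum(is.na(x$genotypes))
  cat("  chromosomes:", length(unique(x$sites$chrom)),
      " missing calls:", nmiss, "\n")
  invisible(x)
}

#' @rdname geno_matrix
#' @param gm A `geno_matrix`.
#' @export
n_sites <- function(gm) ncol(gm$genotypes)

#' @rdname geno_matrix
#' @export
n_individuals <- function(gm) nrow(gm$genotypes)

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param i Individual index (row) selector.
#' @param j Site index (column) selector.
#' @param ... Ignored.
#' @return A `geno_matrix` restricted to the selected individuals and sites.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  geno_matrix(x$genotypes[i, j, drop = FALSE], x$sites[j, , drop = FALSE])
}

## Per-site minor allele frequency from non-missing genotypes.
site_maf <- function(gm) {
  f <- colMeans(gm$genotypes, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

## Per-site fraction of missing genotypes.
site_missingness <- function(gm) colMeans(is.na(gm$genotypes))
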