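#' Read a genotype matrix from VCF or TSV
#'
#' VCF input is parsed with \pkg{vcfR}; only biallelic SNP records with a GT
#' field are used, and diploid genotypes are recoded as alternate-allele
#' counts. Multiallelic or indel records are skipped with a message giving
#' the count. The TSV dialect is the one produced by [write_genotypes()]:
#' one row per site with columns `chrom`, `pos`, `ref`, `alt` followed by one
#' column per individual, missing genotypes written as `NA`.
#'
#' @param path Path to the input file.
#' @param format Either `"vcf"` or `"tsv"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = NA, check.names = FALSE,
                             comment.char = "", stringsAsFactors = FALSE)
    meta <- c("chrom", "pos", "ref", "alt")
    if (!all(meta %in% names(tab)))
      stop("TSV genotype file needs columns chrom, pos, ref, alt")
    ids <- setdiff(names(tab), meta)
    g <- t(as.matrix(tab[, ids, drop = FALSE]))
    storage.mode(g) <- "integer"
    if (nrow(tab) == 0L)
      return(geno_matrix(matrix(integer(0), nrow = length(ids), ncol = 0),
                         sites = tab[, meta, drop = FALSE],
                         individual_ids = ids))
    return(geno_matrix(g, sites = tab[, meta], individual_ids = ids))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  snp <- vcfR::is.biallelic(vcf) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message("skipped ", n_skipped, " non-biallelic-SNP record(s)")
  if (!any(snp)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  g <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  g[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  geno_matrix(t(g), sites = sites, individual_ids = colnames(gt))
}

#' Write a genotype matrix to VCF or TSV
#'
#' The TSV dialect round-trips bit-exactly through [read_genotypes()]. VCF
#' output carries a minimal conformant header and a GT-only FORMAT field;
#' missing genotypes are written as `./.` (VCF) or `NA` (TSV).
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @param format Either `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "geno_matrix"))
  if (format == "tsv") {
    tab <- cbind(gm$sites[, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                 as.data.frame(t(gm$genotypes)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  ids <- rownames(gm$genotypes)
  header <- c("##fileformat=VCFv4.2",
              "##source=admixstats",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  lines <- character(n_sites(gm))
  for (s in seq_len(n_sites(gm))) {
    g <- gm$genotypes[, s]
    gt <- ifelse(is.na(g), "./.", code[g + 1L])
    lines[s] <- paste(c(gm$sites$chrom[s], gm$sites$pos[s], ".",
                        gm$sites$ref[s], gm$sites$alt[s], ".", "PASS", ".",
                        "GT", gt), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Admixture-proportion container
#'
#' Per-individual ancestry proportion vectors over K ancestral populations,
#' as estimated by model-based clustering software (an ADMIXTURE-style Q
#' matrix). Rows must lie in the unit simplex.
#'
#' @param q Numeric matrix, individuals in rows, one column per ancestry.
#' @param labels Ancestry labels (column names); default `anc1, anc2, ...`.
#' @param tol Maximum tolerated deviation of a row sum from 1 (rows within
#'   `tol` are renormalized; larger deviations are an error).
#' @return Numeric matrix of class `admix_props` with rows summing to 1.
#' @export
admix_props <- function(q, labels = NULL, tol = 1e-6) {
  q <- as.matrix(q)
  if (is.null(labels)) {
    labels <- colnames(q)
    if (is.null(labels)) labels <- paste0("anc", seq_len(ncol(q)))
  }
  if (length(labels) != ncol(q)) stop("one label per ancestry required")
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("admixture proportions must lie in [0, 1]")
  rs <- rowSums(q)
  if (any(abs(rs - 1) > tol))
    stop("admixture proportion rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  q <- q / rs
  colnames(q) <- labels
  if (is.null(rownames(q))) rownames(q) <- paste0("ind", seq_len(nrow(q)))
  structure(q, class = c("admix_props", "matrix", "array"))
}

#' @export
print.admix_props <- function(x, ...) {
  cat("admix_props:", nrow(x), "individuals,", ncol(x), "ancestries (",
      paste(colnames(x), collapse = ", "), ")\n")
  cat("  mean proportions:",
      paste(format(round(colMeans(x), 4)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an ADMIXTURE-style Q matrix
#'
#' Whitespace-separated numeric table with one row per individual and one
#' column per ancestry, no header. Rows whose sum deviates from 1 by at most
#' `1e-3` are renormalized; larger deviations are an error.
#'
#' @param path Path to the Q file.
#' @param labels Ancestry labels for the columns.
#' @param ids Optional individual ids (defaults to `ind1, ind2, ...`).
#' @return An [admix_props()] matrix.
#' @export
read_admixture_q <- function(path, labels = NULL, ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  q <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(q)) stop("non-numeric field in Q matrix")
  rs <- rowSums(q)
  if (any(abs(rs - 1) > 1e-3))
    stop("Q matrix row sum deviates from 1 by more than 1e-3 (row ",
         which.max(abs(rs - 1)), ")")
  q <- q / rs
  if (!is.null(ids)) rownames(q) <- ids
  admix_props(q, labels = labels)
}

#' Ancestry-tract container
#'
#' Per-haplotype local-ancestry tracts in half-open, 0-based `[start, end)`
#' coordinates, with lengths carried both in base pairs and centimorgans.
#'
#' @param tracts Data frame with columns `chrom`, `start`, `end`,
#'   `individual`, `haplotype`, `ancestry` and either `length_cM` or none (in
#'   which case `rate_morgans_per_bp` must be given).
#' @param rate_morgans_per_bp Uniform recombination rate used to convert
#'   base-pair lengths to centimorgans (`cM = bp * rate * 100`).
#' @return Data frame of class `tract_set` with an added `length_bp` column
#'   and a `length_cM` column.
#' @export
tract_set <- function(tracts, rate_morgans_per_bp = NULL) {
  tracts <- as.data.frame(tracts)
  need <- c("chrom", "start", "end", "individual", "haplotype", "ancestry")
  if (!all(need %in% names(tracts)))
    stop("tract table needs columns: ", paste(need, collapse = ", "))
  if (nrow(tracts)) {
    if (any(tracts$end <= tracts$start))
      stop("tract end must exceed start (half-open [start, end))")
    key <- interaction(tracts$individual, tracts$haplotype, tracts$chrom,
                       drop = TRUE)
    for (k in levels(key)) {
      tr <- tracts[key == k, ]
      tr <- tr[order(tr$start), ]
      if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
        stop("overlapping tracts on one haplotype (", k, ")")
    }
  }
  tracts$length_bp <- tracts$end - tracts$start
  if (!"length_cM" %in% names(tracts)) {
    if (is.null(rate_morgans_per_bp))
      stop("supply a length_cM column or rate_morgans_per_bp")
    tracts$length_cM <- tracts$length_bp * rate_morgans_per_bp * 100
  }
  class(tracts) <- c("tract_set", "data.frame")
  tracts
}

#' Read a BED-like local-ancestry tract table
#'
#' Tab-separated with a header naming at least `chrom`, `start`, `end`,
#' `individual`, `haplotype`, `ancestry`, optionally `length_cM`. Coordinates
#' are half-open 0-based (BED convention).
#'
#' @inheritParams tract_set
#' @param path Path to the tract file.
#' @param ancestries Optional vector of allowed ancestry labels; any other
#'   label is an error.
#' @return A [tract_set()].
#' @export
read_tracts <- function(path, rate_morgans_per_bp = NULL, ancestries = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), individual = character(),
                        haplotype = integer(), ancestry = character())
    return(tract_set(empty, rate_morgans_per_bp = rate_morgans_per_bp %||% 1e-8))
  }
  if (!is.null(ancestries) && !all(tab$ancestry %in% ancestries))
    stop("unknown ancestry label: ",
         paste(setdiff(unique(tab$ancestry), ancestries), collapse = ", "))
  tract_set(tab, rate_morgans_per_bp = rate_morgans_per_bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
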