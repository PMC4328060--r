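#' Genotype matrix over an ordered marker map
#'
#' Dense biallelic SNP calls (array-like) for a set of individuals. Calls
#' are coded `0` = homozygous reference, `1` = heterozygous, `2` =
#' homozygous alternate, `NA` = missing.
#'
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param calls integer matrix, individuals x markers, rownames = ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(map, calls) {
  stopifnot(is.data.frame(map),
            all(c("chrom", "pos") %in% names(map)),
            is.matrix(calls), ncol(calls) == nrow(map))
  if (is.null(rownames(calls))) stop("'calls' must have individual rownames")
  bad <- !calls %in% c(0L, 1L, 2L, NA)
  if (any(bad, na.rm = TRUE)) stop("calls must be 0, 1, 2 or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("marker positions must be strictly increasing on chromosome ", ch)
    }
  }
  structure(list(map = map, calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  invisible(x)
}

#' Write / read a genotype matrix as transposed genotype text
#'
#' A PLINK `--recode A-transpose`-like dialect: tab-separated header
#' `CHROM POS REF ALT <id1> <id2> ...`, one marker per row, calls coded
#' 0/1/2 as alternate-allele dosage and `NA` for missing.
#'
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @return `path` (writer, invisibly) or a [genotype_matrix()] (reader).
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(CHROM = gm$map$chrom, POS = gm$map$pos,
                   REF = gm$map$ref, ALT = gm$map$alt,
                   t(gm$calls), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  calls <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  storage.mode(calls) <- "integer"
  genotype_matrix(data.frame(chrom = df$CHROM, pos = df$POS,
                             ref = df$REF, alt = df$ALT,
                             stringsAsFactors = FALSE), calls)
}

#' Build a genotype matrix from a multi-sample VCF
#'
#' Diploid GT fields are converted to alternate-allele dosage; half-missing
#' or missing genotypes become `NA`. Sites are assumed biallelic (decompose
#' upstream if needed).
#'
#' @param path VCF file path.
#' @return A [genotype_matrix()].
#' @export
genotype_matrix_from_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dosage <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(a, function(x) {
      if (length(x) != 2L || any(x == ".")) return(NA_integer_)
      sum(as.integer(x) > 0L)
    }, integer(1))
  }
  calls <- apply(gt, 2L, dosage)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L,
                                           dimnames = list(NULL, colnames(gt)))
  calls <- t(calls)
  genotype_matrix(data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                             ref = fix$REF, alt = fix$ALT,
                             stringsAsFactors = FALSE), calls)
}
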