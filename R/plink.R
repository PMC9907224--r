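#' Genotype container for additive minor-allele dosages
#'
#' Bundles an `n x p` matrix of minor-allele counts in `{0, 1, 2}` (with `NA`
#' for missing calls) together with sample and variant metadata and per-SNP
#' minor allele frequencies. Alleles are always oriented so that the counted
#' allele is the minor one; columns whose stored allele1 turned out to be the
#' major allele are flipped at construction time.
#'
#' @param counts integer or numeric `n x p` matrix with entries in
#'   `{0, 1, 2, NA}`; rows are samples, columns are SNPs.
#' @param sample_ids character vector of length `n` of unique sample ids.
#' @param variants data frame with one row per SNP and columns `id`,
#'   `chrom`, `pos`, `allele1`, `allele2` (`allele1` is the counted allele).
#'   May be `NULL`, in which case placeholder records are created.
#' @param orient logical; flip columns with frequency of the counted allele
#'   above 0.5 so that `maf <= 0.5` holds (default `TRUE`).
#'
#' @return An object of class `GenotypeData`: a list with elements `counts`,
#'   `samples` (character ids), `variants` (data frame) and `maf` (length-`p`
#'   frequency of the counted allele, computed ignoring missing entries).
#' @export
genotype_data <- function(counts, sample_ids = NULL, variants = NULL,
                          orient = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  p <- ncol(counts)
  if (n < 1L || p < 1L) stop("need at least one sample and one SNP")
  bad <- !(counts %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length does not match counts")
  if (is.null(variants)) {
    variants <- data.frame(
      id = paste0("snp", seq_len(p)), chrom = rep("1", p),
      pos = seq_len(p), allele1 = rep("A", p), allele2 = rep("B", p),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(variants) != p) stop("variants table does not match counts")

  freq <- colMeans(counts, na.rm = TRUE) / 2
  if (orient) {
    flip <- which(!is.na(freq) & freq > 0.5)
    if (length(flip)) {
      counts[, flip] <- 2L - counts[, flip]
      a1 <- variants$allele1[flip]
      variants$allele1[flip] <- variants$allele2[flip]
      variants$allele2[flip] <- a1
      freq[flip] <- 1 - freq[flip]
      message(length(flip), " SNP(s) flipped so the counted allele is minor")
    }
  }
  structure(
    list(counts = counts, samples = sample_ids, variants = variants,
         maf = freq),
    class = "GenotypeData"
  )
}

#' @export
print.GenotypeData <- function(x, ...) {
  cat("GenotypeData:", length(x$samples), "samples x",
      nrow(x$variants), "SNPs\n")
  cat("  missing rate:", format(mean(is.na(x$counts)), digits = 3),
      " median MAF:", format(stats::median(x$maf), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.GenotypeData <- function(x) dim(x$counts)

# 2-bit PLINK codes within a byte, least-significant pair first:
# 00 = homozygous allele1 (count 2), 01 = missing, 10 = het, 11 = hom allele2.
.plink_lut <- local({
  codes <- c(2L, NA_integer_, 1L, 0L)
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    for (k in 1:4) {
      lut[b + 1L, k] <- codes[bitwAnd(bitwShiftR(b, 2L * (k - 1L)), 3L) + 1L]
    }
  }
  lut
})

#' Read PLINK 1 binary genotypes
#'
#' Reads a `.bed`/`.bim`/`.fam` triple (SNP-major PLINK 1 format), decodes the
#' 2-bit genotype codes to additive dosages of allele1, and orients alleles so
#' that the counted allele is the minor one.
#'
#' @param prefix path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return A [genotype_data()] object.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))
  }
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam)
  p <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK 1 .bed file (bad magic bytes): ", paths[1])
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported (mode byte != 0x01)")
  }
  bps <- (n + 3L) %/% 4L
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bps * p) {
    stop(".bed payload has ", length(body), " bytes; expected ", bps * p)
  }
  bytes <- matrix(body, nrow = bps, ncol = p)
  counts <- matrix(NA_integer_, n, p)
  for (k in 1:4) {
    rows <- seq.int(k, n, by = 4L)
    if (!length(rows)) next
    byte_rows <- (rows - 1L) %/% 4L + 1L
    counts[rows, ] <- .plink_lut[bytes[byte_rows, , drop = FALSE] + 1L, k]
  }
  variants <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                         allele1 = bim$allele1, allele2 = bim$allele2,
                         stringsAsFactors = FALSE)
  gd <- genotype_data(counts, sample_ids = fam$iid, variants = variants)
  gd$fam <- fam
  gd
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [read_plink()]: writes `<prefix>.bed` (SNP-major), `<prefix>.bim`
#' and `<prefix>.fam`.
#'
#' @param g a [genotype_data()] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  counts <- g$counts
  n <- nrow(counts)
  p <- ncol(counts)
  # code per dosage: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(1L, n, p)
  code[!is.na(counts) & counts == 2L] <- 0L
  code[!is.na(counts) & counts == 1L] <- 2L
  code[!is.na(counts) & counts == 0L] <- 3L
  bps <- (n + 3L) %/% 4L
  padded <- matrix(0L, bps * 4L, p)
  padded[seq_len(n), ] <- code
  bytes <- padded[seq.int(1L, bps * 4L, by = 4L), , drop = FALSE] +
    bitwShiftL(padded[seq.int(2L, bps * 4L, by = 4L), , drop = FALSE], 2L) +
    bitwShiftL(padded[seq.int(3L, bps * 4L, by = 4L), , drop = FALSE], 4L) +
    bitwShiftL(padded[seq.int(4L, bps * 4L, by = 4L), , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  fam <- if (!is.null(g$fam)) {
    g$fam
  } else {
    data.frame(fid = g$samples, iid = g$samples, pat = 0, mat = 0,
               sex = 0, pheno = -9)
  }
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a covariate/phenotype table and align it to genotype sample order
#'
#' Reads a CSV with a header, maps the phenotype column to `{0, 1}` (accepting
#' `{0,1}`, PLINK-style `{1,2}`, or `{control,case}` coding), pulls out the
#' requested covariate columns, prepends an intercept column of ones, and
#' reorders rows to match the sample order of a genotype container.
#'
#' @param path CSV file with a header; must contain an id column.
#' @param pheno name of the binary phenotype column.
#' @param covars character vector of covariate column names (may be empty).
#' @param samples character vector giving the required sample order (e.g.
#'   `g$samples` from [read_plink()]); if `NULL` the file order is kept.
#' @param id_col name of the sample-id column (default `"id"`).
#' @return A list of class `CovariateTable` with elements `X` (numeric
#'   `n x (1 + length(covars))` matrix, first column the intercept), `y`
#'   (integer vector in `{0,1}`), `names` (column labels of `X`) and
#'   `samples`.
#' @export
read_covariates <- function(path, pheno, covars = character(), samples = NULL,
                            id_col = "id") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(id_col, pheno, covars)) {
    if (!col %in% names(tab)) stop("column not found in ", path, ": ", col)
  }
  if (!is.null(samples)) {
    idx <- match(samples, as.character(tab[[id_col]]))
    if (anyNA(idx)) {
      stop("samples missing from covariate file: ",
           paste(utils::head(samples[is.na(idx)], 5), collapse = ", "))
    }
    tab <- tab[idx, , drop = FALSE]
  }
  y <- .recode_binary(tab[[pheno]], pheno)
  X <- cbind(`(Intercept)` = 1)
  if (length(covars)) {
    cv <- as.matrix(tab[, covars, drop = FALSE])
    storage.mode(cv) <- "double"
    if (anyNA(cv)) {
      bad <- which(rowSums(is.na(cv)) > 0)
      stop("missing covariate value(s) in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    X <- cbind(`(Intercept)` = 1, cv)
  }
  X <- matrix(as.numeric(X), nrow(tab), 1L + length(covars),
              dimnames = list(NULL, c("(Intercept)", covars)))
  structure(
    list(X = X, y = y, names = colnames(X),
         samples = as.character(tab[[id_col]])),
    class = "CovariateTable"
  )
}

.recode_binary <- function(v, label) {
  u <- sort(unique(stats::na.omit(v)))
  if (anyNA(v)) stop("missing phenotype values in column ", label)
  if (is.numeric(v)) {
    if (all(u %in% c(0, 1))) return(as.integer(v))
    if (all(u %in% c(1, 2))) return(as.integer(v) - 1L) # PLINK case/control
  } else {
    lv <- tolower(as.character(v))
    if (all(lv %in% c("control", "case"))) return(as.integer(lv == "case"))
  }
  stop("phenotype column ", label, " is not binary ({0,1}, {1,2} or ",
       "{control,case}); saw values: ", paste(utils::head(u, 5), collapse = ", "))
}

#' Standardize genotype dosages
#'
#' Centers and scales each SNP column by its binomial moments,
#' `(g - 2p) / sqrt(2 p (1 - p))` with `p` the minor allele frequency, and
#' mean-imputes missing calls to 0 after standardization. Monomorphic SNPs
#' (MAF 0 or 1) are dropped with a warning.
#'
#' @param g a [genotype_data()] object, or a raw dosage matrix.
#' @param maf optional externally supplied frequencies (e.g. training MAFs
#'   when standardizing a test set); defaults to the frequencies stored in
#'   (or computed from) `g`.
#' @return Numeric matrix with attribute `kept` giving the retained column
#'   indices.
#' @export
standardize_genotypes <- function(g, maf = NULL) {
  counts <- if (inherits(g, "GenotypeData")) g$counts else as.matrix(g)
  if (is.null(maf)) {
    maf <- if (inherits(g, "GenotypeData")) g$maf
           else colMeans(counts, na.rm = TRUE) / 2
  }
  if (ncol(counts) != length(maf)) stop("maf length does not match columns")
  all_missing <- colSums(!is.na(counts)) == 0L
  if (any(all_missing)) {
    stop("all-missing genotype column(s): ",
         paste(utils::head(which(all_missing), 5), collapse = ", "))
  }
  keep <- which(maf > 0 & maf < 1)
  if (length(keep) < ncol(counts)) {
    warning(ncol(counts) - length(keep), " monomorphic SNP(s) dropped")
  }
  if (!length(keep)) stop("no polymorphic SNPs left to standardize")
  x <- counts[, keep, drop = FALSE]
  storage.mode(x) <- "double"
  p <- maf[keep]
  x <- sweep(x, 2L, 2 * p, `-`)
  x <- sweep(x, 2L, sqrt(2 * p * (1 - p)), `/`)
  x[is.na(x)] <- 0
  cn <- colnames(counts)
  if (!is.null(cn)) colnames(x) <- cn[keep]
  attr(x, "kept") <- keep
  attr(x, "maf") <- p
  x
}
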