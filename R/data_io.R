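#' Read genotypes from PLINK binary or plain-text dosage files
#'
#' Reads a variant-major PLINK fileset (`.bed`/`.bim`/`.fam`) or a
#' whitespace-delimited text dosage matrix (header row of variant IDs, first
#' column sample IDs, `NA` for missing). Dosages count copies of the first
#' allele column of the `.bim` (the alternative allele `a1`), so values are in
#' \{0, 1, 2, NA\}.
#'
#' @param path For `format = "bed"`, the fileset prefix (or the `.bed` path);
#'   for `format = "text"`, the path of the dosage table.
#' @param format Either `"bed"` or `"text"`.
#' @return A list with `genotypes` (N x M numeric matrix, `NA` = missing),
#'   `variants` (data.frame with columns `chrom`, `id`, `pos`, `a0`, `a1`,
#'   `maf`, `info`), and `sample_ids`.
#' @export
read_genotypes <- function(path, format = c("bed", "text")) {
  format <- match.arg(format)
  if (format == "bed") read_plink(path) else read_genotype_text(path)
}

#' @rdname read_genotypes
#' @export
read_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character", "numeric",
                                             "integer", "character", "character"))
  names(bim_df) <- c("chrom", "id", "cm", "pos", "a1", "a0")
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(fam_df[[2]])
  n <- length(sample_ids)
  m <- nrow(bim_df)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("malformed .bed file: bad magic bytes")
  }
  if (raw[3] != as.raw(0x01)) stop("only variant-major .bed files are supported")
  bytes_per_variant <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_variant * m) {
    stop("inconsistent PLINK fileset: .bed payload is ", length(raw) - 3L,
         " bytes but .bim/.fam imply ", bytes_per_variant * m)
  }
  body <- as.integer(raw[-(1:3)])
  # 2-bit codes, sample index little-endian within byte:
  # 00 hom a1 (dosage 2), 10 het (1), 11 hom a0 (0), 01 missing
  codes <- matrix(0L, nrow = 4L * bytes_per_variant, ncol = m)
  shifted <- body
  for (k in 1:4) {
    codes[seq.int(k, by = 4L, length.out = bytes_per_variant), ] <- shifted %% 4L
    shifted <- shifted %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # code 0,1,2,3
  geno <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  dimnames(geno) <- list(sample_ids, bim_df$id)

  variants <- data.frame(chrom = bim_df$chrom, id = bim_df$id, pos = bim_df$pos,
                         a0 = bim_df$a0, a1 = bim_df$a1,
                         maf = compute_maf(geno), info = 1.0,
                         stringsAsFactors = FALSE)
  list(genotypes = geno, variants = variants, sample_ids = sample_ids)
}

#' @rdname read_genotypes
#' @export
read_genotype_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  sample_ids <- as.character(tab[[1]])
  geno <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(geno) <- "double"
  rownames(geno) <- sample_ids
  ids <- colnames(geno)
  variants <- data.frame(chrom = "1", id = ids, pos = seq_along(ids),
                         a0 = "A", a1 = "B", maf = compute_maf(geno),
                         info = 1.0, stringsAsFactors = FALSE)
  list(genotypes = geno, variants = variants, sample_ids = sample_ids)
}

#' Write a PLINK .bed/.bim/.fam fileset
#'
#' Inverse of [read_plink()]; dosages must be in \{0, 1, 2, NA\}.
#'
#' @param prefix Output fileset prefix.
#' @param genotypes N x M dosage matrix.
#' @param variants Data frame with `chrom`, `id`, `pos`, `a0`, `a1` columns
#'   (defaults are generated when `NULL`).
#' @param sample_ids Character vector of sample IDs.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(prefix, genotypes, variants = NULL, sample_ids = NULL) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", id = paste0("snp", seq_len(m)),
                           pos = seq_len(m), a0 = "A", a1 = "B",
                           stringsAsFactors = FALSE)
  }
  fam <- data.frame(fid = sample_ids, iid = sample_ids, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = variants$chrom, id = variants$id, cm = 0,
                    pos = variants$pos, a1 = variants$a1, a0 = variants$a0)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  bytes_per_variant <- ceiling(n / 4)
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # NA -> 1L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bytes_per_variant - n
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    codes <- ifelse(is.na(g), 1L, code_of[as.character(g)])
    codes <- c(codes, rep(0L, pad))
    cm <- matrix(codes, nrow = 4)
    bytes <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a whitespace-delimited sample table (phenotype/covariate/environment)
#'
#' Header row required; first column holds sample IDs; `NA` marks missing.
#'
#' @param path File path.
#' @return Data frame with sample IDs in the first column.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = "NA")
  tab[[1]] <- as.character(tab[[1]])
  tab
}

compute_maf <- function(geno) {
  f <- colMeans(geno, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Preprocessing configuration
#'
#' @param maf_min Minimum minor allele frequency for [filter_variants()]
#'   (variants with `maf >= maf_min` are kept).
#' @param info_min Minimum imputation info score (inclusive).
#' @param outlier_sd Phenotype values more than this many standard deviations
#'   from the mean are set to missing before any transform; `NULL` disables.
#' @param transform Phenotype transform: `"none"`, `"log"`, or `"group-INT"`
#'   (rank-based inverse normal transform applied within groups).
#' @param group_labels Group labels (length N) required for `"group-INT"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(maf_min = 0.01, info_min = 0.3, outlier_sd = NULL,
                              transform = c("none", "log", "group-INT"),
                              group_labels = NULL) {
  transform <- match.arg(transform)
  stopifnot(maf_min >= 0, maf_min < 0.5, info_min >= 0, info_min <= 1)
  structure(list(maf_min = maf_min, info_min = info_min,
                 outlier_sd = outlier_sd, transform = transform,
                 group_labels = group_labels),
            class = "preprocess_config")
}

#' Align genotype and sample tables on a common complete-case sample set
#'
#' Retains the samples present in all inputs with no missing phenotype,
#' covariate or environment values, ordered as in the genotype data. Every
#' environmental variable must also appear among the covariates; missing ones
#' are appended to the covariate matrix with a warning.
#'
#' @param genotypes N x M dosage matrix with rownames, or the list returned by
#'   [read_genotypes()].
#' @param phenotype Data frame: sample ID column then one phenotype column.
#' @param covariates Data frame: sample ID column then covariate columns. May
#'   be `NULL`.
#' @param environments Data frame: sample ID column then environment columns.
#' @param variants Variant data frame (taken from `genotypes` when that is a
#'   list).
#' @return A `lemma_dataset`: list with `sample_ids`, `genotypes`, `variants`,
#'   `phenotype`, `covariates`, `environments`, `chrom_index`.
#' @export
align_dataset <- function(genotypes, phenotype, covariates = NULL,
                          environments, variants = NULL) {
  if (is.list(genotypes) && !is.null(genotypes$genotypes)) {
    variants <- genotypes$variants
    genotypes <- genotypes$genotypes
  }
  gids <- rownames(genotypes)
  if (is.null(gids)) stop("genotype matrix must carry sample IDs as rownames")
  check_dup <- function(ids, what) {
    if (anyDuplicated(ids)) stop("duplicate sample IDs in ", what)
  }
  check_dup(gids, "genotypes")
  tabs <- list(phenotype = phenotype, environments = environments)
  if (!is.null(covariates)) tabs$covariates <- covariates
  keep <- gids
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    check_dup(tb[[1]], nm)
    complete <- tb[[1]][stats::complete.cases(tb[, -1, drop = FALSE])]
    keep <- intersect(keep, complete)
  }
  keep <- gids[gids %in% keep]  # genotype order
  if (length(keep) == 0) stop("no samples with complete data across all inputs")

  grab <- function(tb) {
    m <- as.matrix(tb[match(keep, tb[[1]]), -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- keep
    m
  }
  y <- drop(grab(phenotype))
  E <- grab(environments)
  C <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(keep), ncol = 0)
  } else {
    grab(covariates)
  }
  missing_env <- setdiff(colnames(E), colnames(C))
  if (length(missing_env) > 0) {
    if (ncol(C) > 0 || !is.null(covariates)) {
      warning("environment column(s) not among covariates, appending: ",
              paste(missing_env, collapse = ", "))
    }
    C <- cbind(C, E[, missing_env, drop = FALSE])
  }
  X <- genotypes[keep, , drop = FALSE]
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", id = colnames(X) %||% paste0("snp", seq_len(ncol(X))),
                           pos = seq_len(ncol(X)), a0 = "A", a1 = "B",
                           info = 1.0, stringsAsFactors = FALSE)
  }
  variants$maf <- compute_maf(X)
  new_dataset(keep, X, variants, y, C, E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_dataset <- function(sample_ids, X, variants, y, C, E) {
  structure(list(sample_ids = sample_ids, genotypes = X, variants = variants,
                 phenotype = y, covariates = C, environments = E,
                 chrom_index = split(seq_len(nrow(variants)), variants$chrom)),
            class = "lemma_dataset")
}

#' @export
print.lemma_dataset <- function(x, ...) {
  cat("lemma_dataset:", length(x$sample_ids), "samples,",
      ncol(x$genotypes), "variants on", length(x$chrom_index), "chromosome(s),",
      ncol(x$environments), "environment(s),", ncol(x$covariates),
      "covariate(s)\n")
  invisible(x)
}

#' Standardize matrix columns to mean zero, unit sample variance
#'
#' Uses the n-1 denominator. Errors on constant columns, naming the offender.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with standardized columns.
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m) + 0  # force a copy; the C++ kernel works in place
  storage.mode(m) <- "double"
  if (ncol(m) == 0) return(m)
  standardize_inplace_cpp(m)  # errors on constant columns, naming them
  m
}

#' Filter variants on MAF and imputation info score
#'
#' Keeps variants with `maf >= maf_min` and `info >= info_min` (both
#' inclusive), with MAF computed on the retained samples. Rebuilds the
#' chromosome index.
#'
#' @param dataset A `lemma_dataset`.
#' @param config A [preprocess_config()].
#' @return The filtered `lemma_dataset`.
#' @export
filter_variants <- function(dataset, config = preprocess_config()) {
  v <- dataset$variants
  v$maf <- compute_maf(dataset$genotypes)
  keep <- v$maf >= config$maf_min & v$info >= config$info_min
  if (!any(keep)) stop("all variants removed by MAF/info filtering")
  new_dataset(dataset$sample_ids,
              dataset$genotypes[, keep, drop = FALSE],
              v[keep, , drop = FALSE],
              dataset$phenotype, dataset$covariates, dataset$environments)
}

#' Clean and transform a phenotype vector
#'
#' Applies the outlier rule first (values more than `outlier_sd` standard
#' deviations from the mean are set to missing), then the configured
#' transform. The group-wise inverse normal transform maps within-group ranks
#' to Gaussian quantiles via (rank - 3/8) / (n + 1/4).
#'
#' @param y Numeric phenotype vector, possibly with missing values.
#' @param config A [preprocess_config()].
#' @return Transformed phenotype vector (same length, `NA` where masked).
#' @export
preprocess_phenotype <- function(y, config = preprocess_config()) {
  y <- as.numeric(y)
  if (!is.null(config$outlier_sd)) {
    mu <- mean(y, na.rm = TRUE)
    sd_y <- stats::sd(y, na.rm = TRUE)
    y[abs(y - mu) > config$outlier_sd * sd_y] <- NA
  }
  if (config$transform == "log") {
    if (any(y <= 0, na.rm = TRUE)) stop("log transform requires positive values")
    y <- log(y)
  } else if (config$transform == "group-INT") {
    g <- config$group_labels
    if (is.null(g)) stop("group-INT requires group labels")
    if (length(g) != length(y)) stop("group labels must match phenotype length")
    for (lev in unique(g)) {
      idx <- which(g == lev & !is.na(y))
      n <- length(idx)
      if (n > 0) {
        y[idx] <- stats::qnorm((rank(y[idx]) - 3 / 8) / (n + 1 / 4))
      }
    }
  }
  y
}

#' Mean-impute missing genotype dosages
#'
#' Missing entries are replaced by the column mean of the observed entries
#' (done before standardization). Errors on fully missing columns.
#'
#' @param m Dosage matrix with possible `NA` entries.
#' @return Complete matrix.
#' @export
impute_missing_genotypes <- function(m) {
  nas <- is.na(m)
  if (!any(nas)) return(m)
  cm <- colMeans(m, na.rm = TRUE)
  if (any(!is.finite(cm))) {
    stop("column ", which(!is.finite(cm))[1], " has no observed genotypes")
  }
  idx <- which(nas, arr.ind = TRUE)
  m[idx] <- cm[idx[, 2]]
  m
}

#' Standardize the genotype, environment and covariate matrices of a dataset
#'
#' Genotypes are mean-imputed then standardized; environment columns are
#' standardized; covariate columns are left as supplied except that constant
#' (intercept-like) columns are dropped, since the fit adds its own intercept
#' handling through the covariate prior.
#'
#' @param dataset A `lemma_dataset`.
#' @return The dataset with standardized matrices (attribute `standardized`).
#' @export
standardize_dataset <- function(dataset) {
  if (isTRUE(attr(dataset, "standardized"))) return(dataset)
  dataset$genotypes <- standardize_columns(impute_missing_genotypes(dataset$genotypes))
  dataset$environments <- standardize_columns(dataset$environments)
  if (ncol(dataset$covariates) > 0) {
    sds <- apply(dataset$covariates, 2, stats::sd)
    dataset$covariates <- standardize_columns(
      dataset$covariates[, sds > 0, drop = FALSE])
  }
  attr(dataset, "standardized") <- TRUE
  dataset
}
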