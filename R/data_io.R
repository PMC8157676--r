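# Readers, writers and preparation for dosage genotypes, marker maps and
# phenotypes. Dosages are 0/1/2 counts of the alternate (A1) allele; maps are
# 1-based base-pair coordinates sorted by (chromosome, position).

#' Construct a genotype matrix object
#'
#' Bundles an `n x p` dosage matrix with its marker map. Dosages count one of
#' the two alleles, so entries are 0, 1 or 2 (or `NA` before imputation).
#'
#' @param dosages Numeric matrix, samples in rows, markers in columns.
#' @param map Data frame with columns `marker_id`, `chromosome`, `position`
#'   (1-based bp), one row per column of `dosages`, sorted by chromosome then
#'   position with strictly increasing positions within a chromosome.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `geno_matrix` with elements `dosages` (dimnamed
#'   matrix) and `map`.
#' @export
genotype_matrix <- function(dosages, map, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) stop("sample_ids are required")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length does not match the number of rows")
  map <- validate_marker_map(map)
  if (nrow(map) != ncol(dosages))
    stop("map length (", nrow(map), ") does not match the number of ",
         "genotype columns (", ncol(dosages), ")")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "double"
  dimnames(dosages) <- list(sample_ids, map$marker_id)
  structure(list(dosages = dosages, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("genotype matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "markers on",
      length(unique(x$map$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Validate a marker map
#'
#' @param map Data frame with `marker_id`, `chromosome`, `position`.
#' @return The map, with ids and chromosomes coerced to character, after
#'   checking uniqueness, ordering and strictly increasing positions within
#'   each chromosome.
#' @export
validate_marker_map <- function(map) {
  req <- c("marker_id", "chromosome", "position")
  if (!all(req %in% names(map)))
    stop("map must have columns marker_id, chromosome, position")
  map <- data.frame(marker_id = as.character(map$marker_id),
                    chromosome = as.character(map$chromosome),
                    position = as.integer(map$position),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker_id)) stop("marker_ids must be unique")
  if (any(map$position < 1L)) stop("positions must be positive (1-based)")
  for (ch in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == ch]
    if (any(diff(pos) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  map
}

#' Load and align a genotype/phenotype dataset
#'
#' Reads genotypes, marker map and phenotypes; intersects the samples and
#' orders both outputs identically (genotype-file order); drops individuals
#' with missing phenotype; imputes remaining missing dosages to the column
#' mean rounded to the nearest integer dosage so the matrix stays 0/1/2 coded.
#'
#' @param genotype_path Delimited dosage table (first column `sample_id`,
#'   remaining columns one per marker, header row of marker ids), or the
#'   `.bed` file of a PLINK bed/bim/fam triple when `format = "plink"`.
#' @param map_path Tab-separated map (`marker_id`, `chromosome`, `position`);
#'   ignored for PLINK input (the `.bim` file is used).
#' @param phenotype_path Tab-separated phenotypes (`sample_id`, `value`). For
#'   PLINK input, `NULL` means use the sixth `.fam` column (-9 = missing).
#' @param format `"delim"` or `"plink"`.
#' @return List with `genotypes` (a [genotype_matrix()]), `phenotypes` (named
#'   numeric vector) and `report` (`n_dropped` phenotype-missing individuals,
#'   `n_imputed` imputed dosage cells).
#' @export
load_dataset <- function(genotype_path, map_path = NULL,
                         phenotype_path = NULL,
                         format = c("delim", "plink")) {
  format <- match.arg(format)
  if (format == "delim") {
    geno <- read_dosage_table(genotype_path)
    if (is.null(map_path)) stop("map_path is required for delimited input")
    map <- read_marker_map(map_path)
    missing_ids <- setdiff(colnames(geno), map$marker_id)
    if (length(missing_ids))
      stop("markers absent from map: ", paste(utils::head(missing_ids, 3),
                                              collapse = ", "))
    map <- map[match(colnames(geno), map$marker_id), , drop = FALSE]
    # genotype columns follow the (sorted) map order
    ord <- order(map$chromosome, map$position)
    map <- map[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    if (is.null(phenotype_path)) stop("phenotype_path is required")
    phen <- read_phenotype_table(phenotype_path)
  } else {
    pl <- read_plink(genotype_path)
    geno <- pl$dosages
    map <- pl$map
    phen <- if (is.null(phenotype_path)) pl$fam_phenotype else
      read_phenotype_table(phenotype_path)
  }

  common <- intersect(rownames(geno), names(phen))
  if (length(common) == 0L)
    stop("no overlapping samples between genotypes and phenotypes")
  common <- rownames(geno)[rownames(geno) %in% common]
  y <- phen[common]
  keep <- is.finite(y)
  n_dropped <- sum(!keep) + (length(phen) - length(common)) +
    (nrow(geno) - length(common))
  common <- common[keep]
  y <- y[common]
  geno <- geno[common, , drop = FALSE]

  n_imputed <- sum(is.na(geno))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(geno)) > 0)) {
      mj <- mean(geno[, j], na.rm = TRUE)
      geno[is.na(geno[, j]), j] <- min(2, max(0, round(mj)))
    }
  }
  G <- genotype_matrix(geno, map, sample_ids = common)
  list(genotypes = G, phenotypes = y,
       report = list(n_dropped = n_dropped, n_imputed = n_imputed))
}

read_dosage_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse genotype table ", path, ": ",
                             conditionMessage(e)))
  if (names(tab)[1] != "sample_id")
    stop("genotype table must start with a sample_id column: ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!(is.na(m) | m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-dosage value in ", path, " at line ", bad[1, 1] + 1L)
  rownames(m) <- as.character(tab$sample_id)
  m
}

read_marker_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse map ", path, ": ",
                             conditionMessage(e)))
  validate_marker_map(tab)
}

read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse phenotypes ", path, ": ",
                             conditionMessage(e)))
  if (!all(c("sample_id", "value") %in% names(tab)))
    stop("phenotype table needs columns sample_id, value: ", path)
  y <- as.numeric(tab$value)
  names(y) <- as.character(tab$sample_id)
  y
}

#' Filter markers on minor allele frequency
#'
#' The allele frequency of column j is `f = sum(dosages) / (2n)`; MAF is
#' `min(f, 1 - f)`. Columns with MAF >= `min_maf` are retained (ties kept),
#' in their original order.
#'
#' @param G A [genotype_matrix()] with no missing entries.
#' @param min_maf Minimum minor allele frequency in `[0, 0.5]`.
#' @return The filtered `geno_matrix`.
#' @export
filter_maf <- function(G, min_maf = 0.05) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf > 0.5)
    stop("min_maf must lie in [0, 0.5]")
  if (anyNA(G$dosages)) stop("genotypes contain missing values; impute first")
  f <- colMeans(G$dosages) / 2
  keep <- pmin(f, 1 - f) >= min_maf
  genotype_matrix(G$dosages[, keep, drop = FALSE],
                  G$map[keep, , drop = FALSE],
                  sample_ids = rownames(G$dosages))
}

#' Allele frequencies of a genotype matrix
#' @param G A [genotype_matrix()].
#' @return Per-marker alternate allele frequency `colSums/(2n)`.
#' @export
allele_freq <- function(G) colMeans(G$dosages) / 2

#' Write a dataset as delimited fixtures
#'
#' Writes the canonical delimited trio read by [load_dataset()]:
#' `genotypes.csv`, `map.tsv`, `phenotypes.tsv`.
#'
#' @param G A [genotype_matrix()].
#' @param y Named phenotype vector.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(G, y, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genotypes.csv")
  mp <- file.path(dir, "map.tsv")
  pp <- file.path(dir, "phenotypes.tsv")
  gt <- data.frame(sample_id = rownames(G$dosages), G$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(gt, gp, sep = ",", row.names = FALSE, quote = FALSE)
  write.table(G$map, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = names(y), value = unname(y)),
              pp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(genotypes = gp, map = mp, phenotypes = pp))
}
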