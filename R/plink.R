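# Minimal PLINK 1 bed/bim/fam support, SNP-major layout only. Dosage is the
# A1 (first bim allele) count: bed code 00 -> 2, 10 -> 1, 11 -> 0,
# 01 -> missing.

#' Read a PLINK bed/bim/fam triple
#'
#' @param bed_path Path to the `.bed` file (or the prefix without extension);
#'   `.bim` and `.fam` are looked up next to it.
#' @return List with `dosages` (n x p matrix, A1 counts, `NA` for missing),
#'   `map` (marker map from the bim), and `fam_phenotype` (named numeric from
#'   fam column 6, -9 mapped to `NA`).
#' @export
read_plink <- function(bed_path) {
  prefix <- sub("\\.bed$", "", bed_path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)

  bim_tab <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  map <- validate_marker_map(data.frame(
    marker_id = bim_tab[[2]], chromosome = bim_tab[[1]],
    position = bim_tab[[4]]))
  fam_tab <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(fam_tab[[2]])
  n <- length(ids)
  p <- nrow(map)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed)
  bpp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) < bpp * p) stop("truncated bed file: ", bed)

  # decode 2-bit genotype codes for all SNPs at once
  bytes <- matrix(as.integer(body[seq_len(bpp * p)]), nrow = bpp)
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, bytes %/% 64L)
  # interleave so sample order is restored within each SNP column
  idx <- as.vector(t(matrix(seq_len(4L * bpp), nrow = bpp)))
  codes <- codes[idx, , drop = FALSE][seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dos <- matrix(lut[codes + 1L], nrow = n, ncol = p,
                dimnames = list(ids, map$marker_id))

  phe <- suppressWarnings(as.numeric(fam_tab[[6]]))
  phe[!is.na(phe) & phe == -9] <- NA
  names(phe) <- ids
  list(dosages = dos, map = map, fam_phenotype = phe)
}

#' Write a PLINK bed/bim/fam triple
#'
#' Inverse of [read_plink()]; A1 is written as allele "A", A2 as "B", so the
#' stored dosage is the A1 count.
#'
#' @param G A [genotype_matrix()] (may contain `NA`).
#' @param prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @param phenotype Optional named phenotype vector for fam column 6
#'   (missing written as -9).
#' @return Invisibly, the bed path.
#' @export
write_plink <- function(G, prefix, phenotype = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  dos <- G$dosages
  n <- nrow(dos); p <- ncol(dos)
  ids <- rownames(dos)
  bim <- data.frame(G$map$chromosome, G$map$marker_id, 0L, G$map$position,
                    "A", "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  phe <- rep(-9, n)
  if (!is.null(phenotype)) {
    m <- phenotype[ids]
    phe[is.finite(m)] <- m[is.finite(m)]
  }
  fam <- data.frame(ids, ids, 0L, 0L, 0L, phe)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  code <- matrix(1L, nrow = n, ncol = p)   # 01 = missing
  code[!is.na(dos) & dos == 2] <- 0L
  code[!is.na(dos) & dos == 1] <- 2L
  code[!is.na(dos) & dos == 0] <- 3L
  bpp <- ceiling(n / 4)
  pad <- matrix(0L, nrow = bpp * 4L, ncol = p)
  pad[seq_len(n), ] <- code
  b <- pad[seq(1, 4 * bpp, by = 4), , drop = FALSE] +
       4L  * pad[seq(2, 4 * bpp, by = 4), , drop = FALSE] +
       16L * pad[seq(3, 4 * bpp, by = 4), , drop = FALSE] +
       64L * pad[seq(4, 4 * bpp, by = 4), , drop = FALSE]
  bed <- paste0(prefix, ".bed")
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(b)), con)
  invisible(bed)
}
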