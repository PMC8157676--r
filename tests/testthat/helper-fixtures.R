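# Shared fixtures: all built in code at test time.

# small random genotype matrix with a valid map (one chromosome unless asked)
make_toy_geno <- function(n, p, seed = 1, n_chrom = 1, maf = c(0.1, 0.5),
                          spacing = 1000L) {
  set.seed(seed)
  f <- runif(p, maf[1], maf[2])
  dos <- sapply(f, function(fj) rbinom(n, 2, fj))
  # redraw monomorphic columns until polymorphic (tiny n can fix a column)
  for (j in seq_len(p)) {
    while (length(unique(dos[, j])) < 2) dos[, j] <- rbinom(n, 2, f[j])
  }
  per_chr <- ceiling(p / n_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = per_chr)[seq_len(p)])
  pos <- unlist(lapply(split(seq_len(p), chrom), function(ix)
    seq_len(length(ix)) * spacing), use.names = FALSE)
  map <- data.frame(marker_id = paste0("m", seq_len(p)),
                    chromosome = chrom, position = pos,
                    stringsAsFactors = FALSE)
  ord <- order(map$chromosome, map$position)
  genotype_matrix(dos[, ord, drop = FALSE], map[ord, , drop = FALSE],
                  sample_ids = paste0("s", seq_len(n)))
}

# window set with prescribed per-window SNP counts on one chromosome
make_ws_with_counts <- function(counts, size_bp = 1e6) {
  pos <- integer(0)
  for (w in seq_along(counts)) {
    base <- (w - 1) * size_bp
    pos <- c(pos, base + seq_len(counts[w]) * 10L)
  }
  map <- data.frame(marker_id = paste0("m", seq_along(pos)),
                    chromosome = "chr1", position = pos,
                    stringsAsFactors = FALSE)
  build_windows_bp(map, size_bp)
}

# batch-means Monte-Carlo standard error for a correlated chain
mc_se <- function(x, batch = 50) {
  nb <- floor(length(x) / batch)
  bm <- vapply(seq_len(nb), function(b)
    mean(x[((b - 1) * batch + 1):(b * batch)]), numeric(1))
  stats::sd(bm) / sqrt(nb)
}

# a draws object built by hand (for window algebra tests)
fake_draws <- function(alpha_matrix, marker_ids = NULL) {
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(alpha_matrix)))
  colnames(alpha_matrix) <- marker_ids
  structure(list(alpha = alpha_matrix,
                 delta = (alpha_matrix != 0) + 0L,
                 mu = rep(0, nrow(alpha_matrix)),
                 pi = rep(0.5, nrow(alpha_matrix)),
                 sigma2_alpha = rep(1, nrow(alpha_matrix)),
                 sigma2_e = rep(1, nrow(alpha_matrix)),
                 n = NA_integer_, p = ncol(alpha_matrix),
                 marker_ids = marker_ids),
            class = "bayescpi_draws")
}
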