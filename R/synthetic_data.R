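# Synthetic genotype panels with heterogeneous SNP density and local LD,
# phenotype simulation under an additive QTL model, and phenotype
# permutation for null diagnostics.
#
# Marker positions follow a piecewise-constant intensity: a baseline density
# plus Mb-aligned hotspots where the density is multiplied by `fold`, which
# creates the long right tail of per-window SNP counts (rare dense windows)
# that drives the spurious-association problem. Haplotypes come from a
# thresholded AR(1)-type Gaussian copula: adjacent markers at distance t have
# latent correlation ld_rho * exp(-t / ld_scale_bp).

#' Genotype simulation settings
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Chromosome length in bp.
#' @param baseline_density Baseline marker density, SNPs per Mb.
#' @param hotspots Data frame with columns `count`, `fold`, `width_bp`: each
#'   row asks for `count` hotspot intervals of width `width_bp` in which the
#'   density is `fold` times the baseline. Hotspots are aligned to whole
#'   multiples of `width_bp` and placed uniformly without overlap.
#' @param ld_rho Latent adjacent-marker correlation at zero distance,
#'   `0 <= ld_rho < 1`.
#' @param ld_scale_bp Exponential decay scale of the latent correlation, bp.
#' @param maf_range Allele-frequency bounds; sites are simulated with
#'   `f ~ Uniform(maf_range)` and columns whose realized MAF falls below
#'   `maf_range[1]` are dropped.
#' @param seed Integer seed.
#' @return Object of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_individuals = 300, n_chromosomes = 4,
                            chrom_length_bp = 10e6, baseline_density = 75,
                            hotspots = data.frame(count = 2, fold = 8,
                                                  width_bp = 1e6),
                            ld_rho = 0.9, ld_scale_bp = 1e5,
                            maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(n_individuals >= 2, n_chromosomes >= 1, chrom_length_bp > 0,
            baseline_density > 0, ld_rho >= 0, ld_rho < 1, ld_scale_bp > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (nrow(hotspots) > 0) {
    stopifnot(all(hotspots$fold > 1), all(hotspots$width_bp > 0),
              all(hotspots$count >= 0))
    if (any(hotspots$width_bp > chrom_length_bp))
      stop("hotspot width exceeds chromosome length")
  }
  structure(list(n_individuals = n_individuals,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 baseline_density = baseline_density, hotspots = hotspots,
                 ld_rho = ld_rho, ld_scale_bp = ld_scale_bp,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "geno_sim_config")
}

#' Simulate a genotype panel
#'
#' See [geno_sim_config()] for the generating model. Deterministic given
#' `cfg$seed`. Dosages are haplotype sums, so entries are 0/1/2; positions
#' are strictly increasing within each chromosome.
#'
#' @param cfg A [geno_sim_config()].
#' @return A [genotype_matrix()] (map included) with sample ids
#'   `ind_1 ... ind_n`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "geno_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  base_rate <- cfg$baseline_density / 1e6   # SNPs per bp

  # lay out hotspot intervals on (chromosome, slot) grids without overlap
  hot <- list()
  if (nrow(cfg$hotspots) > 0) {
    for (r in seq_len(nrow(cfg$hotspots))) {
      cnt <- cfg$hotspots$count[r]
      if (cnt == 0) next
      width <- cfg$hotspots$width_bp[r]
      slots_per_chr <- floor(cfg$chrom_length_bp / width)
      all_slots <- expand.grid(chr = seq_len(cfg$n_chromosomes),
                               slot = seq_len(slots_per_chr))
      taken <- vapply(hot, function(h) paste(h$chr, h$start), character(1))
      avail <- !(paste(all_slots$chr, (all_slots$slot - 1) * width + 1)
                 %in% taken)
      free <- which(avail)
      if (length(free) < cnt) stop("not enough room for requested hotspots")
      pick <- all_slots[free[sample.int(length(free), cnt)], , drop = FALSE]
      for (i in seq_len(nrow(pick)))
        hot[[length(hot) + 1L]] <- list(
          chr = pick$chr[i], start = (pick$slot[i] - 1) * width + 1,
          end = pick$slot[i] * width, fold = cfg$hotspots$fold[r])
    }
  }

  dos_list <- list(); map_list <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    segs <- split_segments(cfg$chrom_length_bp, hot, ch, base_rate)
    pos <- integer(0)
    for (s in seq_len(nrow(segs))) {
      len <- segs$end[s] - segs$start[s] + 1
      k <- stats::rpois(1, segs$rate[s] * len)
      if (k > 0)
        pos <- c(pos, as.integer(floor(stats::runif(k, segs$start[s],
                                                    segs$end[s] + 1))))
    }
    pos <- sort(unique(pos))
    pc <- length(pos)
    if (pc == 0) next
    f <- stats::runif(pc, cfg$maf_range[1], cfg$maf_range[2])
    thr <- stats::qnorm(1 - f)
    # AR(1)-type latent field over 2n haplotypes
    H <- matrix(0L, nrow = 2 * n, ncol = pc)
    z <- stats::rnorm(2 * n)
    H[, 1] <- (z > thr[1]) + 0L
    if (pc > 1) for (j in 2:pc) {
      r <- cfg$ld_rho * exp(-(pos[j] - pos[j - 1]) / cfg$ld_scale_bp)
      z <- r * z + sqrt(1 - r^2) * stats::rnorm(2 * n)
      H[, j] <- (z > thr[j]) + 0L
    }
    dos <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
    dos_list[[length(dos_list) + 1L]] <- dos
    map_list[[length(map_list) + 1L]] <- data.frame(
      marker_id = sprintf("chr%d_%d", ch, pos),
      chromosome = paste0("chr", ch), position = pos,
      stringsAsFactors = FALSE)
  }
  dos <- do.call(cbind, dos_list)
  map <- do.call(rbind, map_list)
  rownames(dos) <- sprintf("ind_%d", seq_len(n))
  G <- genotype_matrix(dos, map)
  filter_maf(G, cfg$maf_range[1])
}

split_segments <- function(chrom_len, hot, ch, base_rate) {
  hs <- Filter(function(h) h$chr == ch, hot)
  hs <- hs[order(vapply(hs, function(h) h$start, numeric(1)))]
  segs <- data.frame(start = numeric(0), end = numeric(0),
                     rate = numeric(0))
  cursor <- 1
  for (h in hs) {
    if (h$start > cursor)
      segs <- rbind(segs, data.frame(start = cursor, end = h$start - 1,
                                     rate = base_rate))
    segs <- rbind(segs, data.frame(start = h$start, end = h$end,
                                   rate = base_rate * h$fold))
    cursor <- h$end + 1
  }
  if (cursor <= chrom_len)
    segs <- rbind(segs, data.frame(start = cursor, end = chrom_len,
                                   rate = base_rate))
  segs
}

#' Phenotype simulation settings
#'
#' @param n_qtl Number of QTL.
#' @param h2 Target heritability in `(0, 1]`.
#' @param exclude_dense Restrict QTL to SNPs outside dense windows.
#' @param seed Integer seed.
#' @return Object of class `pheno_sim_config`. QTL effects are i.i.d.
#'   standard normal (fixed, as in the additive model this emulates).
#' @export
pheno_sim_config <- function(n_qtl, h2 = 0.5, exclude_dense = TRUE, seed) {
  stopifnot(n_qtl >= 1, h2 > 0, h2 <= 1)
  if (missing(seed)) stop("a seed is required")
  structure(list(n_qtl = as.integer(n_qtl), h2 = h2,
                 exclude_dense = exclude_dense, seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Simulate phenotypes from sampled QTL
#'
#' QTL markers are drawn uniformly without replacement from the eligible
#' SNPs (all SNPs, or those outside `dense_ids` windows when
#' `cfg$exclude_dense`), with i.i.d. standard-normal effects. Residuals are
#' i.i.d. normal with variance `Var_pop(g) * (1 - h2) / h2`, anchoring h2 to
#' the realized (population-variance) genetic signal on this panel.
#'
#' @param G A [genotype_matrix()].
#' @param ws The `window_set` defining ground-truth window labels.
#' @param dense_ids Window ids QTL must avoid (used when
#'   `cfg$exclude_dense`).
#' @param cfg A [pheno_sim_config()].
#' @return List: `phenotypes` (named vector) and `truth` (class `sim_truth`:
#'   `qtl_idx`, `qtl_marker_ids`, `qtl_effects`, `window_labels` — logical
#'   per window of `ws` — and `realized_h2`).
#' @export
simulate_phenotypes <- function(G, ws, dense_ids = character(0), cfg) {
  stopifnot(inherits(G, "geno_matrix"), inherits(ws, "window_set"),
            inherits(cfg, "pheno_sim_config"))
  p <- ncol(G$dosages); n <- nrow(G$dosages)
  eligible <- seq_len(p)
  if (cfg$exclude_dense && length(dense_ids)) {
    dense_w <- which(ws$windows$window_id %in% dense_ids)
    excl <- unlist(ws$members[dense_w])
    eligible <- setdiff(eligible, excl)
  }
  if (length(eligible) < cfg$n_qtl)
    stop("fewer eligible SNPs (", length(eligible), ") than requested QTL")
  set.seed(cfg$seed)
  qtl <- sort(sample(eligible, cfg$n_qtl))
  eff <- stats::rnorm(cfg$n_qtl)
  g <- drop(G$dosages[, qtl, drop = FALSE] %*% eff)
  varg <- genetic_variance(g)
  if (cfg$h2 < 1) {
    e <- stats::rnorm(n, sd = sqrt(varg * (1 - cfg$h2) / cfg$h2))
  } else e <- rep(0, n)
  y <- g + e
  names(y) <- rownames(G$dosages)
  labels <- vapply(ws$members, function(m) any(m %in% qtl), logical(1))
  truth <- structure(list(qtl_idx = qtl,
                          qtl_marker_ids = G$map$marker_id[qtl],
                          qtl_effects = eff,
                          window_labels = labels,
                          window_id = ws$windows$window_id,
                          realized_h2 = varg / genetic_variance(y)),
                     class = "sim_truth")
  list(phenotypes = y, truth = truth)
}

#' Permute phenotype values
#'
#' Shuffles the trait values against a fixed sample order (the multiset of
#' values is preserved exactly), destroying the genotype-phenotype link while
#' keeping the genotypes and trait distribution intact.
#'
#' @param y Named phenotype vector, length >= 2.
#' @param seed Integer seed.
#' @return Permuted vector with the original names in the original order.
#' @export
permute_phenotypes <- function(y, seed) {
  if (length(y) < 2) stop("need at least 2 phenotypes")
  set.seed(seed)
  out <- unname(y)[sample(length(y))]
  names(out) <- names(y)
  out
}

#' Write simulation ground truth as TSV
#'
#' @param truth A `sim_truth` object.
#' @param qtl_path Output TSV (`marker_id`, `effect`).
#' @param labels_path Output TSV (`window_id`, `label`).
#' @return Invisibly, the two paths.
#' @export
write_sim_truth <- function(truth, qtl_path, labels_path) {
  write.table(data.frame(marker_id = truth$qtl_marker_ids,
                         effect = truth$qtl_effects),
              qtl_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(window_id = truth$window_id,
                         label = as.integer(truth$window_labels)),
              labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(qtl = qtl_path, labels = labels_path))
}
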