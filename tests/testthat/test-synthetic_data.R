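# The synthetic panel generator, phenotype simulator and permutation.

test_that("panel structure: dosage coding, ordering, seeded stability", {
  cfg <- geno_sim_config(n_individuals = 100, n_chromosomes = 2,
                         chrom_length_bp = 2e6, baseline_density = 50,
                         hotspots = data.frame(count = 1, fold = 8,
                                               width_bp = 1e6),
                         seed = 201)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$dosages, G2$dosages)
  expect_true(all(G1$dosages %in% c(0, 1, 2)))
  for (ch in unique(G1$map$chromosome))
    expect_true(all(diff(G1$map$position[G1$map$chromosome == ch]) > 0))
  maf <- pmin(allele_freq(G1), 1 - allele_freq(G1))
  expect_true(all(maf >= cfg$maf_range[1]))
})

test_that("ld_rho = 0 gives essentially uncorrelated adjacent markers", {
  cfg <- geno_sim_config(n_individuals = 500, n_chromosomes = 1,
                         chrom_length_bp = 2e6, baseline_density = 50,
                         hotspots = data.frame(count = numeric(0),
                                               fold = numeric(0),
                                               width_bp = numeric(0)),
                         ld_rho = 0, seed = 202)
  G <- simulate_genotypes(cfg)
  p <- ncol(G$dosages)
  r_adj <- vapply(seq_len(p - 1), function(j)
    cor(G$dosages[, j], G$dosages[, j + 1]), numeric(1))
  expect_lt(mean(abs(r_adj)), 0.1)
})

test_that("positive ld_rho induces adjacent-marker correlation", {
  cfg <- geno_sim_config(n_individuals = 400, n_chromosomes = 1,
                         chrom_length_bp = 2e6, baseline_density = 100,
                         hotspots = data.frame(count = numeric(0),
                                               fold = numeric(0),
                                               width_bp = numeric(0)),
                         ld_rho = 0.95, ld_scale_bp = 2e5, seed = 203)
  G <- simulate_genotypes(cfg)
  p <- ncol(G$dosages)
  r_adj <- vapply(seq_len(p - 1), function(j)
    cor(G$dosages[, j], G$dosages[, j + 1]), numeric(1))
  expect_gt(mean(r_adj), 0.3)
})

test_that("hotspots multiply window marker counts by roughly the fold", {
  cfg <- geno_sim_config(n_individuals = 50, n_chromosomes = 2,
                         chrom_length_bp = 8e6, baseline_density = 60,
                         hotspots = data.frame(count = 2, fold = 5,
                                               width_bp = 1e6),
                         seed = 204)
  G <- simulate_genotypes(cfg)
  ws <- build_windows_bp(G$map, 1e6)
  counts <- sort(ws$windows$p_w, decreasing = TRUE)
  hot_mean <- mean(counts[1:2])
  base_mean <- mean(counts[-(1:2)])
  expect_gt(hot_mean / base_mean, 3.5)
  expect_lt(hot_mean / base_mean, 6.5)
})

test_that("default panel has the long right tail of window densities", {
  G <- simulate_genotypes(geno_sim_config(seed = 205))
  ws <- build_windows_bp(G$map, 1e6)
  expect_gte(max(ws$windows$p_w) / median(ws$windows$p_w), 5)
  expect_gt(length(detect_dense_windows(ws)), 0)
})

test_that("phenotype simulation honors h2, QTL eligibility and labels", {
  G <- simulate_genotypes(geno_sim_config(n_individuals = 150,
                                          n_chromosomes = 2,
                                          chrom_length_bp = 5e6,
                                          seed = 206))
  ws <- build_windows_bp(G$map, 1e6)
  dense <- detect_dense_windows(ws)
  sim <- simulate_phenotypes(G, ws, dense,
                             pheno_sim_config(n_qtl = 8, h2 = 1, seed = 207))
  # h2 = 1: phenotype is exactly the genotypic value
  g <- drop(G$dosages[, sim$truth$qtl_idx] %*% sim$truth$qtl_effects)
  expect_equal(unname(sim$phenotypes), unname(g))
  expect_equal(sim$truth$realized_h2, 1)
  # no QTL inside a dense window
  dense_members <- unlist(ws$members[ws$windows$window_id %in% dense])
  expect_length(intersect(sim$truth$qtl_idx, dense_members), 0)
  # labels flag exactly the windows intersecting the QTL set
  oracle <- vapply(ws$members, function(m) any(m %in% sim$truth$qtl_idx),
                   logical(1))
  expect_equal(sim$truth$window_labels, oracle)
  expect_error(
    simulate_phenotypes(G, ws, dense,
                        pheno_sim_config(n_qtl = 10 * ws$p, seed = 1)),
    "eligible")
})

test_that("realized h2 concentrates near the target at large n", {
  G <- simulate_genotypes(geno_sim_config(n_individuals = 2000,
                                          n_chromosomes = 1,
                                          chrom_length_bp = 5e6,
                                          baseline_density = 50,
                                          hotspots = data.frame(
                                            count = numeric(0),
                                            fold = numeric(0),
                                            width_bp = numeric(0)),
                                          seed = 208))
  ws <- build_windows_bp(G$map, 1e6)
  for (k in 1:5) {
    sim <- simulate_phenotypes(G, ws, character(0),
                               pheno_sim_config(n_qtl = 90, h2 = 0.5,
                                                exclude_dense = FALSE,
                                                seed = 210 + k))
    expect_gte(sim$truth$realized_h2, 0.42)
    expect_lte(sim$truth$realized_h2, 0.58)
    # residuals uncorrelated with genetic values
    g <- drop(G$dosages[, sim$truth$qtl_idx] %*% sim$truth$qtl_effects)
    e <- unname(sim$phenotypes) - g
    expect_lt(abs(cor(g, e)), 0.1)
  }
})

test_that("phenotype permutation preserves the value multiset", {
  y <- setNames(rnorm(25), paste0("s", 1:25))
  yp <- permute_phenotypes(y, seed = 220)
  expect_identical(names(yp), names(y))
  expect_identical(sort(unname(yp)), sort(unname(y)))
  expect_identical(yp, permute_phenotypes(y, seed = 220))
  expect_false(identical(yp, permute_phenotypes(y, seed = 221)))

  # n = 2: both arrangements appear over repeated seeds
  y2 <- c(a = 1, b = 2)
  arrangements <- unique(vapply(1:30, function(s)
    paste(permute_phenotypes(y2, seed = s), collapse = ","),
    character(1)))
  expect_setequal(arrangements, c("1,2", "2,1"))
  expect_error(permute_phenotypes(c(a = 1), seed = 1), "at least 2")
})

test_that("truth tables round-trip through the TSV writers", {
  G <- simulate_genotypes(geno_sim_config(n_individuals = 60,
                                          n_chromosomes = 1,
                                          chrom_length_bp = 3e6, seed = 230))
  ws <- build_windows_bp(G$map, 1e6)
  sim <- simulate_phenotypes(G, ws, character(0),
                             pheno_sim_config(n_qtl = 5, h2 = 0.5,
                                              exclude_dense = FALSE,
                                              seed = 231))
  d <- withr::local_tempdir()
  write_sim_truth(sim$truth, file.path(d, "qtl.tsv"),
                  file.path(d, "labels.tsv"))
  qtl <- read.table(file.path(d, "qtl.tsv"), header = TRUE)
  lab <- read.table(file.path(d, "labels.tsv"), header = TRUE)
  expect_equal(qtl$marker_id, sim$truth$qtl_marker_ids)
  expect_equal(qtl$effect, sim$truth$qtl_effects, tolerance = 1e-12)
  expect_equal(as.logical(lab$label), sim$truth$window_labels)
})
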