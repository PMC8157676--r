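# Window construction, variance shares q_w, thresholds and WPPA.

test_that("bp windows bucket markers like a per-marker oracle", {
  # direct examples
  map <- data.frame(marker_id = c("a", "b"), chromosome = "chr1",
                    position = c(500000L, 1500000L))
  ws <- build_windows_bp(map, 1e6)
  expect_equal(ws$N, 2)
  expect_equal(ws$windows$p_w, c(1L, 1L))
  # a marker exactly on the boundary belongs to the lower window
  map2 <- data.frame(marker_id = c("a", "b", "c"), chromosome = "chr1",
                     position = c(1L, 1000000L, 1000001L))
  ws2 <- build_windows_bp(map2, 1e6)
  expect_equal(ws2$windows$p_w, c(2L, 1L))
  # all markers inside one interval
  map3 <- data.frame(marker_id = letters[1:5], chromosome = "chr2",
                     position = c(10L, 20L, 30L, 40L, 50L))
  ws3 <- build_windows_bp(map3, 1e6)
  expect_equal(ws3$N, 1)
  expect_equal(ws3$windows$p_w, 5L)

  # seeded random map vs brute-force bucketing
  set.seed(90)
  pos <- sort(sample(1:5e6, 250))
  map4 <- rbind(
    data.frame(marker_id = paste0("x", seq_along(pos)), chromosome = "chr1",
               position = pos),
    data.frame(marker_id = paste0("y", 1:250), chromosome = "chr2",
               position = sort(sample(1:5e6, 250))))
  ws4 <- build_windows_bp(map4, 1e6)
  oracle <- paste(map4$chromosome, floor((map4$position - 1) / 1e6))
  for (w in seq_len(ws4$N)) {
    members <- ws4$members[[w]]
    expect_equal(length(unique(oracle[members])), 1)
  }
  expect_equal(sum(ws4$windows$p_w), nrow(map4))
  expect_equal(length(unique(unlist(ws4$members))), nrow(map4))
})

test_that("count windows chunk within chromosomes and keep the remainder", {
  map <- data.frame(marker_id = paste0("m", 1:250), chromosome = "chr1",
                    position = seq_len(250) * 100L)
  ws <- build_windows_count(map, 100)
  expect_equal(ws$windows$p_w, c(100L, 100L, 50L))
  expect_equal(ws$windows$partial, c(FALSE, FALSE, TRUE))

  map2 <- data.frame(
    marker_id = paste0("m", 1:270),
    chromosome = rep(c("chr1", "chr2"), c(150, 120)),
    position = c(seq_len(150) * 100L, seq_len(120) * 100L))
  ws2 <- build_windows_count(map2, 100)
  expect_equal(ws2$windows$p_w, c(100L, 50L, 100L, 20L))

  ws3 <- build_windows_count(map2, 1000)   # k larger than any chromosome
  expect_equal(ws3$windows$p_w, c(150L, 120L))
  expect_error(build_windows_count(map2, 0), "positive")
})

test_that("genetic_variance is the population variance of the printed form", {
  expect_equal(genetic_variance(c(0, 2)), 1)
  expect_equal(genetic_variance(rep(3.7, 10)), 0)
  expect_equal(genetic_variance(c(1, 2, 3, 4)), 1.25)
  expect_error(genetic_variance(numeric(0)), "empty")
})

test_that("q_w algebra: whole-genome window, zero draws, orthogonal blocks", {
  G <- make_toy_geno(30, 6, seed = 91)
  A <- rbind(rnorm(6), numeric(6), rnorm(6))   # second draw all-zero
  draws <- fake_draws(A, colnames(G$dosages))
  ws_all <- build_windows_bp(G$map, 1e9)       # single window
  wp <- window_q_samples(G, draws, ws_all)
  expect_equal(unname(wp$q_samples[c(1, 3), 1]), c(1, 1))
  expect_equal(unname(wp$q_samples[2, 1]), 0)  # sigma2_g = 0 convention

  # two windows with exactly orthogonal centered blocks share all variance
  dos <- cbind(m1 = c(0, 0, 2, 2), m2 = c(0, 2, 0, 2), m3 = c(0, 2, 2, 0))
  map <- data.frame(marker_id = c("m1", "m2", "m3"), chromosome = "chr1",
                    position = c(1L, 2L, 1000001L))
  Go <- genotype_matrix(dos, map, sample_ids = paste0("s", 1:4))
  wso <- build_windows_bp(Go$map, 1e6)
  expect_equal(wso$N, 2)
  set.seed(92)
  Ao <- matrix(rnorm(15), nrow = 5, ncol = 3)
  wpo <- window_q_samples(Go, fake_draws(Ao, c("m1", "m2", "m3")), wso)
  expect_equal(unname(rowSums(wpo$q_samples)), rep(1, 5), tolerance = 1e-12)
  # brute-force recomputation of one draw (window 1 holds m1 and m2)
  g1 <- drop(dos[, 1:2] %*% Ao[1, 1:2])
  g <- drop(dos %*% Ao[1, ])
  q1_oracle <- (mean(g1^2) - mean(g1)^2) / (mean(g^2) - mean(g)^2)
  expect_equal(unname(wpo$q_samples[1, 1]), q1_oracle)
})

test_that("threshold schemes resolve to the documented values", {
  ws <- make_ws_with_counts(c(10, 20, 30, 40))
  expect_equal(resolve_thresholds("constant", ws, 0.001)$values,
               rep(0.001, 4))
  expect_equal(resolve_thresholds("one_over_N", ws)$values, rep(0.25, 4))
  pw <- resolve_thresholds("per_window", ws)
  expect_equal(pw$values, c(10, 20, 30, 40) / 100)
  expect_equal(sum(pw$values), 1)
  expect_error(resolve_thresholds("constant", ws, 1.5), "constant_value")

  # the 1/N threshold at the dimension of a 378-window genome
  ws378 <- make_ws_with_counts(rep(5L, 378))
  expect_equal(resolve_thresholds("one_over_N", ws378)$values[1],
               0.0026455, tolerance = 1e-4)
  # a 733-SNP window on a 33,701-SNP panel gets T_w ~ 0.0218
  counts <- c(733L, rep(164L, 201))
  counts[2] <- counts[2] + (33701L - sum(counts))
  ws_rice <- make_ws_with_counts(counts)
  expect_equal(ws_rice$p, 33701L)
  expect_equal(resolve_thresholds("per_window", ws_rice)$values[1],
               0.021750, tolerance = 1e-4)
})

test_that("WPPA counts strict exceedances and is monotone in T", {
  q <- c(0.001, 0.002, 0.003, 0.004)
  expect_equal(compute_wppa(q, 0.0025), 0.5)
  expect_equal(compute_wppa(q, 0), 1)
  expect_equal(compute_wppa(q, 0.004), 0)     # ties do not count
  expect_equal(compute_wppa(q, 0.9), 0)
  set.seed(93)
  for (k in 1:25) {
    qs <- runif(40)
    ts <- sort(runif(2))
    expect_gte(compute_wppa(qs, ts[1]), compute_wppa(qs, ts[2]))
  }
})

test_that("threshold scheme changes WPPA but never q", {
  G <- make_toy_geno(25, 8, seed = 94, spacing = 300000L)
  set.seed(95)
  draws <- fake_draws(matrix(rnorm(40), 5, 8), colnames(G$dosages))
  ws <- build_windows_bp(G$map, 1e6)
  wp1 <- window_q_samples(G, draws, ws)
  sc1 <- resolve_thresholds("one_over_N", ws)
  sc2 <- resolve_thresholds("per_window", ws)
  expect_identical(wp1$q_samples, window_q_samples(G, draws, ws)$q_samples)
  w1 <- compute_wppa(wp1$q_samples, sc1)
  w2 <- compute_wppa(wp1$q_samples, sc2)
  expect_false(identical(w1, w2))
  expect_identical(wp1$q_mean, window_q_samples(G, draws, ws)$q_mean)
})

test_that("dense-window detection applies the Tukey fence", {
  ws_eq <- make_ws_with_counts(rep(25, 6))
  expect_length(detect_dense_windows(ws_eq), 0)   # zero IQR

  set.seed(96)
  counts <- sample(50:120, 50, replace = TRUE)
  counts[c(7, 20)] <- c(600, 450)
  ws <- make_ws_with_counts(counts)
  got <- detect_dense_windows(ws)
  qs <- quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  oracle <- ws$windows$window_id[counts > qs[2] + 1.5 * (qs[2] - qs[1])]
  expect_setequal(got, oracle)
  expect_true(all(ws$windows$window_id[counts %in% c(600, 450)] %in% got))

  expect_error(detect_dense_windows(make_ws_with_counts(c(5, 5, 5))),
               "at least 4")
})

test_that("results table assembles coordinates, q, T, WPPA and dense flags", {
  G <- make_toy_geno(20, 10, seed = 97, spacing = 250000L)
  set.seed(98)
  draws <- fake_draws(matrix(rnorm(50), 5, 10), colnames(G$dosages))
  ws <- build_windows_bp(G$map, 1e6)
  wp <- window_q_samples(G, draws, ws)
  sc <- resolve_thresholds("per_window", ws)
  tab <- window_results_table(ws, wp, sc, dense_ids = character(0))
  expect_equal(nrow(tab), ws$N)
  expect_named(tab, c("window_id", "chromosome", "start", "end", "p_w",
                      "q_mean", "T", "WPPA", "dense_flag"))
  expect_equal(tab$WPPA, unname(compute_wppa(wp$q_samples, sc)))
})
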