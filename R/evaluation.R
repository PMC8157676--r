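# Power evaluation by partial AUC and density diagnostics.
#
# A window is a true positive iff it contains at least one QTL SNP. Scores
# are WPPA for the Bayesian schemes and -log10 p for the frequentist scan.
# Only the ROC up to a false positive rate of 5% is integrated (pAUC5); the
# area is rescaled by 0.00125 = 0.05^2/2 so a random classifier scores 1.

#' Partial AUC up to a false-positive-rate cap
#'
#' Empirical ROC with tied scores grouped into single steps (so a constant
#' score vector gives the diagonal), trapezoidal integration from FPR 0 to
#' `fpr_max` with linear interpolation at the cap.
#'
#' @param scores Per-window numeric scores (larger = more associated).
#' @param labels Per-window 0/1 (or logical) ground truth; both classes must
#'   be present.
#' @param fpr_max Upper false-positive-rate limit, default 0.05.
#' @return Object of class `pauc_result`: `raw_pauc` in `[0, fpr_max]`,
#'   `rescaled = raw_pauc / (fpr_max^2 / 2)` (random classifier = 1),
#'   `n_pos`, `n_neg`.
#' @export
pauc5 <- function(scores, labels, fpr_max = 0.05) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), fpr_max > 0, fpr_max <= 1)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present in labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- as.numeric(tapply(l, grp, sum))
  fp <- as.numeric(tapply(1 - l, grp, sum))
  tpr <- cumsum(tp) / n_pos
  fpr <- cumsum(fp) / n_neg
  xs <- c(0, fpr); ys <- c(0, tpr)
  area <- 0
  for (i in seq_len(length(xs) - 1)) {
    x0 <- xs[i]; x1 <- xs[i + 1]; y0 <- ys[i]; y1 <- ys[i + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  structure(list(raw_pauc = area, rescaled = area / (fpr_max^2 / 2),
                 n_pos = n_pos, n_neg = n_neg, fpr_max = fpr_max),
            class = "pauc_result")
}

#' Window-density diagnostics
#'
#' Pearson correlations of the per-window SNP count p_w with the posterior
#' variance share and with the association score, plus the identity of the
#' highest-scoring window. Large positive correlations under a permuted
#' (null) phenotype indicate density-driven spurious signal.
#'
#' @param ws A `window_set`.
#' @param score Per-window association score: WPPA, or -log10 p for a
#'   frequentist scan.
#' @param q_mean Optional per-window posterior mean variance share.
#' @param dense_ids Optional dense window ids for the argmax flag.
#' @return Object of class `density_diagnostic`: `r_pw_score`, `r_pw_q`
#'   (NA with `constant_score`/`constant_q` flags when an input has zero
#'   variance), `argmax_window_id`, `argmax_p_w`, `argmax_is_dense`.
#' @export
density_correlations <- function(ws, score, q_mean = NULL,
                                 dense_ids = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (ws$N < 3) stop("need at least 3 windows")
  stopifnot(length(score) == ws$N)
  pw <- ws$windows$p_w
  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  if (is.null(dense_ids))
    dense_ids <- if (ws$N >= 4) detect_dense_windows(ws) else character(0)
  amax <- which.max(score)
  structure(list(
    r_pw_score = safe_cor(pw, score),
    constant_score = stats::sd(score) == 0,
    r_pw_q = if (is.null(q_mean)) NA_real_ else safe_cor(pw, q_mean),
    constant_q = if (is.null(q_mean)) NA else stats::sd(q_mean) == 0,
    argmax_window_id = ws$windows$window_id[amax],
    argmax_p_w = pw[amax],
    argmax_is_dense = ws$windows$window_id[amax] %in% dense_ids),
    class = "density_diagnostic")
}

#' Multi-replicate method-comparison experiment
#'
#' Simulates one heterogeneous-density panel, then for each replicate draws a
#' fresh phenotype (QTL restricted to non-dense windows), runs the requested
#' window-testing methods and scores each with rescaled pAUC5 against the
#' window truth labels:
#' \describe{
#'   \item{1MbT}{bp windows, WPPA with constant threshold `T = 1/N`.}
#'   \item{1MbTw}{bp windows, WPPA with window-specific `T_w = p_w/p`.}
#'   \item{100T}{fixed-SNP-count windows, WPPA with `T = 1/N'`; truth labels
#'     are recomputed on the count-based windows (different windows are
#'     tested).}
#'   \item{1MbFre}{EMMAX windowed chi-square on bp windows, scored by
#'     -log10 p.}
#' }
#' One BayesC-pi chain per replicate serves all three Bayesian schemes.
#'
#' @param panel_cfg A [geno_sim_config()] (its own seed is overridden from
#'   `base_seed` so the whole experiment is reproducible).
#' @param methods Subset of `c("1MbT", "1MbTw", "100T", "1MbFre")`.
#' @param n_qtl QTL per replicate.
#' @param h2 Heritability.
#' @param n_replicates Number of phenotype replicates.
#' @param base_seed Integer; drives panel, phenotype and chain seeds.
#' @param chain A [chain_config()] template (its seed is ignored).
#' @param window_bp Physical window span.
#' @param window_count SNPs per count-based window.
#' @return Data frame of class `experiment_table`: `method`, `n_qtl`,
#'   `replicate`, `seed`, `pauc5_rescaled`, `failed`; attribute `n_failed`.
#' @export
run_experiment <- function(panel_cfg = geno_sim_config(),
                           methods = c("1MbT", "1MbTw", "100T", "1MbFre"),
                           n_qtl = 10, h2 = 0.5, n_replicates = 10,
                           base_seed = 1,
                           chain = chain_config(n_iter = 5000,
                                                burn_in = 1000, thin = 4,
                                                seed = 1),
                           window_bp = 1e6, window_count = 100) {
  methods <- match.arg(methods, c("1MbT", "1MbTw", "100T", "1MbFre"),
                       several.ok = TRUE)
  set.seed(base_seed)
  seeds <- sample.int(2^31 - 2, n_replicates + 1)
  panel_cfg$seed <- seeds[n_replicates + 1]
  G <- simulate_genotypes(panel_cfg)
  ws_bp <- build_windows_bp(G$map, window_bp)
  ws_ct <- build_windows_count(G$map, window_count)
  dense <- if (ws_bp$N >= 4) detect_dense_windows(ws_bp) else character(0)
  need_bayes <- any(c("1MbT", "1MbTw", "100T") %in% methods)
  K <- if ("1MbFre" %in% methods) compute_grm(G) else NULL

  rows <- list()
  n_failed <- 0
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      sim <- simulate_phenotypes(G, ws_bp, dense,
                                 pheno_sim_config(n_qtl = n_qtl, h2 = h2,
                                                  seed = seeds[r]))
      y <- sim$phenotypes
      labels_bp <- sim$truth$window_labels
      out <- list()
      if (need_bayes) {
        ch <- chain; ch$seed <- seeds[r]
        draws <- run_bayescpi(G, y, chain = ch)
        if (any(c("1MbT", "1MbTw") %in% methods)) {
          wp <- window_q_samples(G, draws, ws_bp)
          if ("1MbT" %in% methods)
            out$`1MbT` <- pauc5(compute_wppa(
              wp$q_samples, resolve_thresholds("one_over_N", ws_bp)),
              labels_bp)$rescaled
          if ("1MbTw" %in% methods)
            out$`1MbTw` <- pauc5(compute_wppa(
              wp$q_samples, resolve_thresholds("per_window", ws_bp)),
              labels_bp)$rescaled
        }
        if ("100T" %in% methods) {
          wp_ct <- window_q_samples(G, draws, ws_ct)
          labels_ct <- vapply(ws_ct$members,
                              function(m) any(m %in% sim$truth$qtl_idx),
                              logical(1))
          out$`100T` <- pauc5(compute_wppa(
            wp_ct$q_samples, resolve_thresholds("one_over_N", ws_ct)),
            labels_ct)$rescaled
        }
      }
      if ("1MbFre" %in% methods) {
        vc_r <- reml_null(y, K)
        tab <- emmax_scan(y, G, ws_bp, vc = vc_r)
        out$`1MbFre` <- pauc5(tab$neg_log10_p, labels_bp)$rescaled
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1
      for (m in methods)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, n_qtl = n_qtl, replicate = r, seed = seeds[r],
          pauc5_rescaled = NA_real_, failed = TRUE)
    } else {
      for (m in methods)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, n_qtl = n_qtl, replicate = r, seed = seeds[r],
          pauc5_rescaled = res[[m]], failed = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  attr(out, "base_seed") <- base_seed
  class(out) <- c("experiment_table", class(out))
  out
}
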