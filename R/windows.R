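# Genomic windows and window posterior probabilities of association (WPPA).
#
# For each stored MCMC draw, the window genotypic value is g_w = M_w alpha_w
# and the variance it explains is the population variance of g_w; q_w is the
# ratio of that to the variance of the whole-genome genotypic value g = M
# alpha. WPPA is the fraction of draws in which q_w exceeds a threshold T,
# which may be a constant (e.g. 0.1%), 1/N, or the window-specific p_w/p.

#' Build non-overlapping windows by physical span
#'
#' A marker at position `pos` (1-based bp) falls in window index
#' `floor((pos - 1) / size_bp)` of its chromosome, i.e. windows are the
#' intervals `[k * size_bp + 1, (k + 1) * size_bp]` and a marker exactly on a
#' boundary belongs to the lower window. Empty windows are omitted: `N`
#' counts only windows that contain markers.
#'
#' @param map A marker map (see [validate_marker_map()]).
#' @param size_bp Window span in bp (e.g. `1e6`).
#' @return An object of class `window_set`: `windows` (data frame with
#'   `window_id`, `chromosome`, `start`, `end`, `p_w`), `members` (list of
#'   marker index vectors into the map), `N`, `p`, `scheme_tag = "bp"`.
#' @export
build_windows_bp <- function(map, size_bp) {
  map <- validate_marker_map(map)
  if (!is.numeric(size_bp) || size_bp <= 0) stop("size_bp must be positive")
  idx <- floor((map$position - 1) / size_bp)
  key <- paste(map$chromosome, idx, sep = "\r")
  ord <- order(match(map$chromosome, unique(map$chromosome)), idx)
  ukey <- unique(key[ord])
  members <- split(seq_len(nrow(map)), factor(key, levels = ukey))
  chrom <- vapply(members, function(i) map$chromosome[i[1]], character(1))
  widx <- vapply(members, function(i) floor((map$position[i[1]] - 1) / size_bp),
                 numeric(1))
  windows <- data.frame(
    window_id = sprintf("%s:%d-%d", chrom, as.integer(widx * size_bp + 1),
                        as.integer((widx + 1) * size_bp)),
    chromosome = chrom,
    start = as.integer(widx * size_bp + 1),
    end = as.integer((widx + 1) * size_bp),
    p_w = lengths(members),
    row.names = NULL, stringsAsFactors = FALSE)
  new_window_set(windows, unname(members), nrow(map), "bp")
}

#' Build non-overlapping windows of fixed SNP count
#'
#' Consecutive runs of `k` markers within each chromosome; windows never span
#' chromosomes. A trailing window with fewer than `k` markers is kept and
#' flagged in the `partial` column.
#'
#' @param map A marker map.
#' @param k Markers per window (e.g. 100).
#' @return A `window_set` with `scheme_tag = "count"`; window `start`/`end`
#'   are the bp positions of the first and last member marker.
#' @export
build_windows_count <- function(map, k) {
  map <- validate_marker_map(map)
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
  k <- as.integer(k)
  members <- list(); chrom <- character(0); partial <- logical(0)
  for (ch in unique(map$chromosome)) {
    ix <- which(map$chromosome == ch)
    starts <- seq(1L, length(ix), by = k)
    for (s in starts) {
      grp <- ix[s:min(s + k - 1L, length(ix))]
      members[[length(members) + 1L]] <- grp
      chrom <- c(chrom, ch)
      partial <- c(partial, length(grp) < k)
    }
  }
  start <- vapply(members, function(i) map$position[i[1]], integer(1))
  end <- vapply(members, function(i) map$position[i[length(i)]], integer(1))
  windows <- data.frame(
    window_id = sprintf("%s:snp%d-%d", chrom,
                        vapply(members, min, integer(1)),
                        vapply(members, max, integer(1))),
    chromosome = chrom, start = start, end = end,
    p_w = lengths(members), partial = partial,
    row.names = NULL, stringsAsFactors = FALSE)
  new_window_set(windows, members, nrow(map), "count")
}

new_window_set <- function(windows, members, p, scheme_tag) {
  stopifnot(sum(windows$p_w) == p, all(windows$p_w >= 1))
  all_members <- sort(unlist(members))
  stopifnot(identical(all_members, seq_len(p)))
  structure(list(windows = windows, members = members,
                 N = nrow(windows), p = p, scheme_tag = scheme_tag),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window set (", x$scheme_tag, "): ", x$N, " windows over ", x$p,
      " markers; p_w range [", min(x$windows$p_w), ", ",
      max(x$windows$p_w), "]\n", sep = "")
  invisible(x)
}

#' Population variance of a genotypic-value vector
#'
#' `sum(g^2)/n - (sum(g)/n)^2` — the population (divide by n) variance used
#' for all window variance shares.
#'
#' @param g Numeric vector of genotypic values.
#' @return Non-negative scalar.
#' @export
genetic_variance <- function(g) {
  if (length(g) < 1) stop("empty vector")
  max(mean(g^2) - mean(g)^2, 0)
}

#' Per-draw window variance shares q_w
#'
#' For each stored draw: `g = M alpha` and `sigma2_g = genetic_variance(g)`;
#' per window `g_w = M_w alpha_w`, `sigma2_gw = genetic_variance(g_w)` and
#' `q_w = sigma2_gw / sigma2_g`. Draws with `sigma2_g = 0` (all effects zero)
#' contribute `q_w = 0` for every window, so all windows keep equal sample
#' counts. q_w does not depend on the threshold scheme.
#'
#' @param G The [genotype_matrix()] the chain was run on.
#' @param draws A `bayescpi_draws` object.
#' @param ws A `window_set` over the same markers.
#' @return Object of class `window_posterior`: `q_samples` (draws x N
#'   matrix), `q_mean`, `sigma2_g` (per draw), `window_id`, and the window
#'   set.
#' @export
window_q_samples <- function(G, draws, ws) {
  stopifnot(inherits(G, "geno_matrix"), inherits(draws, "bayescpi_draws"),
            inherits(ws, "window_set"))
  if (nrow(draws$alpha) < 1) stop("no stored draws")
  if (ws$p != ncol(draws$alpha) || ws$p != ncol(G$dosages))
    stop("window set, draws and genotypes disagree on marker count")
  A <- draws$alpha                       # S x p
  S <- nrow(A)
  gmat <- G$dosages %*% t(A)             # n x S
  s2g <- col_pop_var(gmat)
  q <- matrix(0, nrow = S, ncol = ws$N,
              dimnames = list(NULL, ws$windows$window_id))
  pos <- s2g > 0
  for (w in seq_len(ws$N)) {
    j <- ws$members[[w]]
    gw <- G$dosages[, j, drop = FALSE] %*% t(A[, j, drop = FALSE])
    s2gw <- col_pop_var(gw)
    q[pos, w] <- s2gw[pos] / s2g[pos]
  }
  structure(list(q_samples = q, q_mean = colMeans(q), sigma2_g = s2g,
                 window_id = ws$windows$window_id, window_set = ws),
            class = "window_posterior")
}

col_pop_var <- function(m) {
  mu <- colMeans(m)
  pmax(colMeans(m * m) - mu * mu, 0)
}

#' Resolve a WPPA threshold scheme
#'
#' @param kind `"constant"` (same `constant_value` for every window, e.g. the
#'   classic 0.1%), `"one_over_N"` (T = 1/N with N the number of windows), or
#'   `"per_window"` (T_w = p_w / p, which makes the null "every SNP explains
#'   an equal share of variance" and removes the density artifact).
#' @param ws A `window_set`.
#' @param constant_value Threshold used when `kind = "constant"`.
#' @return Object of class `threshold_scheme` with the per-window `values`.
#' @export
resolve_thresholds <- function(kind = c("constant", "one_over_N",
                                        "per_window"),
                               ws, constant_value = 0.001) {
  kind <- match.arg(kind)
  stopifnot(inherits(ws, "window_set"))
  values <- switch(kind,
    constant = {
      if (!is.numeric(constant_value) || constant_value <= 0 ||
          constant_value >= 1)
        stop("constant_value must lie in (0, 1)")
      rep(constant_value, ws$N)
    },
    one_over_N = rep(1 / ws$N, ws$N),
    per_window = ws$windows$p_w / ws$p)
  structure(list(kind = kind, values = values,
                 window_id = ws$windows$window_id),
            class = "threshold_scheme")
}

#' Window posterior probability of association
#'
#' The fraction of MCMC samples in which q_w strictly exceeds T; ties do not
#' count.
#'
#' @param q_samples Numeric vector of q_w samples for one window, or a
#'   (draws x N) matrix of samples for N windows.
#' @param threshold Scalar T, a per-window numeric vector, or a
#'   `threshold_scheme`.
#' @return Scalar (vector input) or per-window named vector (matrix input).
#' @export
compute_wppa <- function(q_samples, threshold) {
  if (inherits(threshold, "threshold_scheme")) threshold <- threshold$values
  if (is.matrix(q_samples)) {
    if (nrow(q_samples) < 1) stop("no samples")
    if (length(threshold) == 1) threshold <- rep(threshold, ncol(q_samples))
    stopifnot(length(threshold) == ncol(q_samples))
    out <- vapply(seq_len(ncol(q_samples)),
                  function(w) mean(q_samples[, w] > threshold[w]),
                  numeric(1))
    names(out) <- colnames(q_samples)
    out
  } else {
    if (length(q_samples) < 1) stop("no samples")
    stopifnot(length(threshold) == 1)
    mean(q_samples > threshold)
  }
}

#' Flag SNP-dense windows
#'
#' Windows whose SNP count exceeds `Q3 + 1.5 * (Q3 - Q1)` of the per-window
#' count distribution (Tukey upper fence; quartiles use the default
#' linear-interpolation convention, `quantile` type 7).
#'
#' @param ws A `window_set` with at least 4 windows.
#' @return Character vector of dense `window_id`s.
#' @export
detect_dense_windows <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (ws$N < 4) stop("need at least 4 windows to estimate quartiles")
  qs <- stats::quantile(ws$windows$p_w, c(0.25, 0.75), names = FALSE,
                        type = 7)
  cutoff <- qs[2] + 1.5 * (qs[2] - qs[1])
  ws$windows$window_id[ws$windows$p_w > cutoff]
}

#' Per-window GWAS results table
#'
#' One row per window: coordinates, SNP count, posterior mean variance share,
#' threshold, WPPA and dense flag. This is the Manhattan-plot input.
#'
#' @param ws A `window_set`.
#' @param wp The matching `window_posterior`.
#' @param scheme A `threshold_scheme`.
#' @param dense_ids Optional character vector from [detect_dense_windows()];
#'   computed from `ws` when `NULL` and N >= 4.
#' @return Data frame with columns `window_id`, `chromosome`, `start`, `end`,
#'   `p_w`, `q_mean`, `T`, `WPPA`, `dense_flag`.
#' @export
window_results_table <- function(ws, wp, scheme, dense_ids = NULL) {
  stopifnot(inherits(ws, "window_set"), inherits(wp, "window_posterior"))
  if (is.null(dense_ids))
    dense_ids <- if (ws$N >= 4) detect_dense_windows(ws) else character(0)
  data.frame(ws$windows[c("window_id", "chromosome", "start", "end", "p_w")],
             q_mean = unname(wp$q_mean),
             T = scheme$values,
             WPPA = unname(compute_wppa(wp$q_samples, scheme)),
             dense_flag = ws$windows$window_id %in% dense_ids,
             row.names = NULL, stringsAsFactors = FALSE)
}
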