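# EMMAX-style frequentist windowed association. The null model
#   y = mu 1 + u + eps,  u ~ N(0, sigma2_poly K), eps ~ N(0, sigma2_eps I)
# is fitted once by REML on the spectral decomposition of K; every window is
# then tested by generalized least squares with the variance components held
# at their null estimates (the EMMAX approximation: the tested window's SNPs
# stay in K). The joint Wald statistic is referred to chi-square with df
# equal to the rank of the projected window design (p_w when full rank).

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = Z Z' / d` with `Z` the column-centered dosages and
#' `d = sum_j 2 f_j (1 - f_j)`, so the diagonal averages ~1 for many
#' independent SNPs at Hardy-Weinberg proportions.
#'
#' @param G A [genotype_matrix()] with no missing entries and no monomorphic
#'   columns.
#' @return Symmetric positive semi-definite n x n matrix with sample ids as
#'   dimnames.
#' @export
compute_grm <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  if (anyNA(G$dosages)) stop("genotypes contain missing values")
  f <- colMeans(G$dosages) / 2
  if (any(f == 0 | f == 1))
    stop("monomorphic column present; run filter_maf first")
  Z <- sweep(G$dosages, 2, 2 * f)
  d <- sum(2 * f * (1 - f))
  K <- tcrossprod(Z) / d
  dimnames(K) <- list(rownames(G$dosages), rownames(G$dosages))
  K
}

#' REML fit of the polygenic null model
#'
#' Maximizes the restricted likelihood of `y = mu 1 + u + eps` over the
#' heritability-like ratio `h = sigma2_poly / (sigma2_poly + sigma2_eps)` on
#' the eigen-rotated representation of K (one decomposition, one-dimensional
#' bounded search). Deterministic given inputs.
#'
#' @param y Phenotype vector (non-constant, n >= 10).
#' @param K Kinship matrix from [compute_grm()].
#' @return Object of class `emmax_null`: `sigma2_poly`, `sigma2_eps`,
#'   `ratio`, `loglik`, the reusable eigendecomposition (`eigen$U`,
#'   `eigen$d`), and `identifiable` (FALSE, with a warning, when all
#'   eigenvalues of K are equal so the ratio is undetermined).
#' @export
reml_null <- function(y, K) {
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals")
  if (stats::sd(y) == 0) stop("phenotype is constant")
  stopifnot(nrow(K) == n, ncol(K) == n)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  identifiable <- diff(range(d)) > 1e-8 * max(max(d), 1)
  restricted_ll <- function(h) {
    v <- h * d + (1 - h)
    w <- 1 / v
    bhat <- sum(w * xt * yt) / sum(w * xt^2)
    r <- yt - xt * bhat
    rss <- sum(w * r^2)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(v)) +
              log(sum(w * xt^2)))
  }
  if (!identifiable) {
    warning("kinship has (numerically) equal eigenvalues; ",
            "variance ratio is not identifiable, reporting ratio = 0")
    h <- 0
  } else {
    opt <- stats::optimize(restricted_ll, interval = c(1e-8, 1 - 1e-8),
                           maximum = TRUE, tol = 1e-8)
    h <- opt$maximum
    # compare against the boundaries, optimize() can miss them
    cand <- c(1e-8, h, 1 - 1e-8)
    h <- cand[which.max(vapply(cand, restricted_ll, numeric(1)))]
  }
  v <- h * d + (1 - h)
  w <- 1 / v
  bhat <- sum(w * xt * yt) / sum(w * xt^2)
  s2_total <- sum(w * (yt - xt * bhat)^2) / (n - 1)
  structure(list(sigma2_poly = h * s2_total,
                 sigma2_eps = (1 - h) * s2_total,
                 ratio = h, loglik = restricted_ll(h),
                 eigen = list(U = U, d = d),
                 identifiable = identifiable),
            class = "emmax_null")
}

#' Windowed chi-square test under the EMMAX approximation
#'
#' Generalized least squares of `y` on `[1, M_w]` with
#' `Sigma = sigma2_poly K + sigma2_eps I` held at the null REML estimates.
#' The Wald statistic for the joint window effect is referred to
#' `chi-square(df)` with `df` the rank of the intercept-projected window
#' design: `p_w` for a full-rank window, fewer when columns are collinear
#' (rank from an eigen-threshold of `1e-8` times the largest eigenvalue of
#' the window cross-product, with a pseudo-inverse statistic).
#'
#' @param y Phenotype vector.
#' @param G The [genotype_matrix()].
#' @param window Integer vector of marker column indices (one window), or a
#'   single row index into `ws$members` when `ws` is supplied.
#' @param vc An `emmax_null` fit on the same `(y, K)`.
#' @param ws Optional `window_set` used to resolve `window` and label output.
#' @return Data frame row with `window_id`, `statistic`, `df`, `p_value`,
#'   `neg_log10_p`.
#' @export
window_chi2_test <- function(y, G, window, vc, ws = NULL) {
  stopifnot(inherits(vc, "emmax_null"))
  if (length(window) < 1) stop("window contains no SNPs")
  if (!is.null(ws) && length(window) == 1 && window <= ws$N) {
    wid <- ws$windows$window_id[window]
    window <- ws$members[[window]]
  } else {
    wid <- paste0("snp", min(window), "-", max(window))
  }
  if (length(window) < 1) stop("window contains no SNPs")
  U <- vc$eigen$U; d <- vc$eigen$d
  v <- vc$sigma2_poly * d + vc$sigma2_eps
  sw <- 1 / sqrt(v)
  yt <- sw * drop(crossprod(U, y))
  xt <- sw * drop(crossprod(U, rep(1, length(y))))
  B <- sw * crossprod(U, G$dosages[, window, drop = FALSE])
  # project out the intercept in the whitened metric
  xx <- sum(xt^2)
  B <- B - xt %*% (crossprod(xt, B) / xx)
  z <- yt - xt * (sum(xt * yt) / xx)
  C <- crossprod(B)
  eg <- eigen(C, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values, 0)
  keep <- eg$values > max(tol, 0)
  df <- sum(keep)
  if (df == 0) {
    stat <- 0; pval <- 1
  } else {
    t_vec <- drop(crossprod(B, z))
    proj <- drop(crossprod(eg$vectors[, keep, drop = FALSE], t_vec))
    stat <- sum(proj^2 / eg$values[keep])
    pval <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  data.frame(window_id = wid, statistic = stat, df = df,
             p_value = max(pval, .Machine$double.xmin),
             neg_log10_p = -log10(max(pval, .Machine$double.xmin)),
             stringsAsFactors = FALSE)
}

#' EMMAX windowed scan over a window set
#'
#' Convenience wrapper: GRM, one REML null fit, then [window_chi2_test()] for
#' every window.
#'
#' @param y Phenotype vector.
#' @param G The [genotype_matrix()].
#' @param ws A `window_set`.
#' @param vc Optional pre-fit `emmax_null` (reused across scans).
#' @return Data frame: `window_id`, `chromosome`, `start`, `end`, `p_w`,
#'   `statistic`, `df`, `p_value`, `neg_log10_p`.
#' @export
emmax_scan <- function(y, G, ws, vc = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(vc)) vc <- reml_null(y, compute_grm(G))
  rows <- lapply(seq_len(ws$N), function(w)
    window_chi2_test(y, G, ws$members[[w]], vc))
  out <- do.call(rbind, rows)
  out$window_id <- ws$windows$window_id
  cbind(ws$windows[c("window_id", "chromosome", "start", "end", "p_w")],
        out[c("statistic", "df", "p_value", "neg_log10_p")])
}
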