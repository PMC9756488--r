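#' Protein-group table construction
#'
#' @param intensities samples x protein-group matrix of nonnegative
#'   intensities; `NA` (or, by the MaxQuant dialect, 0 — see `zero_is_missing`)
#'   marks a group not quantified in a sample.
#' @param annotations data.frame with one row per group: columns `group`
#'   (id matching the matrix columns), `origin` (`"human"`/`"microbial"`),
#'   `genus` (label or `"unknown"`), `cog` (COG id or `NA`), `cog_category`
#'   (functional category or `NA`), `lead_protein`, `ig_variable` (logical),
#'   `ig_constant` (logical).
#' @param zero_is_missing treat exact zeros as missing (default `TRUE`,
#'   label-free dialect where zero means "not quantified").
#' @return object of class `protein_table`: list with `intensities` and
#'   `annotations` (rows aligned to the matrix columns).
#' @export
as_protein_table <- function(intensities, annotations, zero_is_missing = TRUE) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensities must carry sample and protein-group names")
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  if (zero_is_missing) intensities[intensities == 0] <- NA
  need <- c("group", "origin", "genus", "cog", "lead_protein", "ig_variable")
  if (!all(need %in% names(annotations)))
    stop("annotations must contain columns: ", paste(need, collapse = ", "))
  if (!all(colnames(intensities) %in% annotations$group))
    stop("every protein group needs an annotation row")
  annotations <- annotations[match(colnames(intensities), annotations$group), , drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(intensities = intensities, annotations = annotations),
            class = "protein_table")
}

#' Detection-prevalence filter
#'
#' Keeps protein groups detected (non-missing, nonzero) in at least
#' `min_frac` of samples, the filter applied jointly across all samples.
#'
#' @param table a [as_protein_table()] object.
#' @param min_frac minimum detected fraction (default 0.5).
#' @return filtered `protein_table` with attribute `filter_log`
#'   (`retained`, `total`).
#' @export
prevalence_filter <- function(table, min_frac = 0.5) {
  stopifnot(inherits(table, "protein_table"))
  frac <- colMeans(!is.na(table$intensities))
  keep <- frac >= min_frac
  out <- table
  out$intensities <- table$intensities[, keep, drop = FALSE]
  out$annotations <- table$annotations[keep, , drop = FALSE]
  rownames(out$annotations) <- NULL
  attr(out, "filter_log") <- list(retained = sum(keep), total = length(keep))
  out
}

#' Variance-stabilizing normalization (affine-arsinh calibration)
#'
#' Fits, per sample i, the generalized-log transform
#' `h_i(x) = asinh(a_i + b_i * x)` with `b_i > 0`, maximizing the likelihood
#' of a model where each feature's transformed values are Gaussian with a
#' feature-specific mean and a common variance.  Fitting alternates between
#' (feature means, common variance) and per-sample calibration parameters
#' until the penalized log-likelihood changes by less than `tol` relatively.
#' Missing entries are ignored in the fit and stay missing.
#'
#' @details The feature means and the common variance are profiled out in
#'   closed form, leaving a smooth objective in the `2n` calibration
#'   parameters that is maximized by quasi-Newton (BFGS) iteration with
#'   analytic gradients, to relative tolerance `tol`.
#' @param intensities samples x features nonnegative matrix with `NA`s.
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter maximum quasi-Newton iterations (default 200).
#' @return list of class `vsn_fit`: `h` (transformed matrix, same NA
#'   pattern), `a`, `b` (per-sample calibration), `sigma2`, `converged`.
#' @export
vsn_normalize <- function(intensities, tol = 1e-6, max_iter = 200L) {
  x <- as.matrix(intensities)
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  # exact zeros mean "not quantified" in label-free data; they also make the
  # calibration likelihood degenerate (their Jacobian term is unbounded in b)
  x[x == 0] <- NA
  n <- nrow(x); obs <- !is.na(x)
  if (any(rowSums(obs) < 2L)) stop("every sample needs >= 2 observed features")
  nobs <- sum(obs)
  x0 <- x; x0[!obs] <- 0
  # moment-based start: a = -mean/sd, b = 1/sd per sample (z-scoring inside asinh)
  s <- apply(x, 1L, stats::sd, na.rm = TRUE)
  m <- rowMeans(x, na.rm = TRUE)
  b <- 1 / pmax(s, .Machine$double.eps)
  a <- -m * b

  hmat <- function(a, b) asinh(sweep(sweep(x, 1L, b, "*"), 1L, a, "+"))
  # negative profile log-likelihood (mu, sigma2 profiled out) + Jacobian
  neg_ll <- function(par) {
    a <- par[seq_len(n)]; b <- exp(par[n + seq_len(n)])
    u <- sweep(sweep(x, 1L, b, "*"), 1L, a, "+")
    h <- asinh(u)
    mu <- colMeans(h, na.rm = TRUE)
    rss <- sum(sweep(h, 2L, mu, "-")^2, na.rm = TRUE)
    jac <- rowSums(obs) * log(b) - 0.5 * rowSums(log1p(u^2), na.rm = TRUE)
    nobs / 2 * log(rss / nobs) - sum(jac)
  }
  neg_gr <- function(par) {
    a <- par[seq_len(n)]; b <- exp(par[n + seq_len(n)])
    u <- sweep(sweep(x, 1L, b, "*"), 1L, a, "+")
    u[!obs] <- 0
    s2 <- 1 + u^2
    h <- asinh(u); h[!obs] <- NA
    mu <- colMeans(h, na.rm = TRUE)
    r <- sweep(h, 2L, mu, "-"); r[!obs] <- 0
    rss <- sum(r^2)
    w <- (nobs / rss) * r / sqrt(s2)     # d(rss-term)/dh * dh/du
    da <- rowSums(w) + rowSums((u / s2) * obs)
    db <- rowSums(w * x0) - rowSums(obs) / b + rowSums((u / s2) * x0)
    c(da, db * b)  # chain rule for log(b)
  }
  fit <- stats::optim(c(a, log(b)), neg_ll, neg_gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  a <- fit$par[seq_len(n)]; b <- exp(fit$par[n + seq_len(n)])
  converged <- fit$convergence == 0L
  if (!converged)
    warning("vsn_normalize: no convergence in ", max_iter,
            " iterations; returning best-so-far parameters")
  h <- hmat(a, b)
  mu <- colMeans(h, na.rm = TRUE)
  sigma2 <- sum(sweep(h, 2L, mu, "-")^2, na.rm = TRUE) / nobs
  dimnames(h) <- dimnames(x)
  structure(list(h = h, a = a, b = b, sigma2 = sigma2,
                 converged = converged, loglik = -fit$value),
            class = "vsn_fit")
}

#' Bayesian PCA imputation of missing intensities
#'
#' EM for probabilistic PCA with per-axis automatic-relevance (ARD)
#' precisions: the E-step infers factor scores and missing entries, the
#' M-step updates the axes, the noise variance and the axis precisions.
#' Iterates until the largest absolute change in any imputed value drops
#' below `tol`.  Observed entries are returned unchanged.
#'
#' @param x samples x features numeric matrix with `NA`s; every row and
#'   column must have at least one observed value.
#' @param n_components number of latent axes; default
#'   `min(dim(x)) - 1` capped at 20.
#' @param seed integer seed for the randomized initialization.
#' @param tol convergence tolerance on imputed values (default 1e-5).
#' @param max_iter maximum EM iterations (default 500).
#' @return completed matrix (same dimnames); attribute `bpca_fit` holds the
#'   axes `W`, means `mu`, noise variance `sigma2`, ARD precisions `alpha`
#'   and the iteration count.
#' @export
bpca_impute <- function(x, n_components = NULL, seed = 1L, tol = 1e-5,
                        max_iter = 500L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L)) stop("all-missing row")
  if (any(colSums(obs) == 0L)) stop("all-missing column")
  if (!any(!obs)) return(x)  # complete data: identity
  k <- if (is.null(n_components)) min(min(n, d) - 1L, 20L) else as.integer(n_components)
  if (k >= min(n, d)) stop("n_components must be < min(dim(x))")

  mu <- colMeans(x, na.rm = TRUE)
  xf <- sweep(x, 2L, mu, "-")
  xf[!obs] <- 0  # centered data with zeros at missing entries
  # seeded randomized range finder + SVD for the initial axes
  set.seed(as.integer(seed) %% .Machine$integer.max)
  om <- matrix(stats::rnorm(d * (k + 5L)), d)
  q <- qr.Q(qr(xf %*% om))
  sv <- svd(crossprod(q, xf), nu = k, nv = k)
  W <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)] / sqrt(n), k)
  sigma2 <- max(stats::var(as.numeric(xf[obs])) * 0.1, 1e-8)
  alpha <- rep(1, k)

  patt <- apply(obs, 1L, function(o) paste(which(o), collapse = ","))
  upatt <- unique(patt)
  n_obs_feat <- colSums(obs)
  ii <- rep(seq_len(k), k); jj <- rep(seq_len(k), each = k)
  imp_old <- rep(Inf, sum(!obs))
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # E-step: posterior score means and covariances, grouped by missingness
    # pattern (covariance is shared within a pattern)
    Z <- matrix(0, n, k)
    Svec <- matrix(0, n, k * k)  # per-sample vec(posterior covariance)
    for (p in upatt) {
      rows <- which(patt == p)
      o <- obs[rows[1L], ]
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + sigma2 * diag(k)
      Minv <- chol2inv(chol(M))
      Z[rows, ] <- xf[rows, o, drop = FALSE] %*% Wo %*% Minv
      Svec[rows, ] <- matrix(sigma2 * Minv, nrow = 1)[rep(1, length(rows)), ]
    }
    # per-feature sufficient statistics Sum_{n in O_d} (z z' + S_n)
    F2 <- Z[, ii, drop = FALSE] * Z[, jj, drop = FALSE] + Svec
    A <- crossprod(F2, obs)            # k^2 x d
    B <- crossprod(Z, xf)              # k x d  (zeros at missing contribute 0)
    # M-step: per-feature ridge solve with ARD precisions
    for (dd in seq_len(d)) {
      Ad <- matrix(A[, dd], k, k) + sigma2 * diag(alpha, k)
      W[dd, ] <- solve(Ad, B[, dd])
    }
    # update feature offsets from observed residuals
    rec <- Z %*% t(W)
    delta <- colSums((xf - rec) * obs) / n_obs_feat
    mu <- mu + delta
    xf <- sweep(x, 2L, mu, "-"); xf[!obs] <- 0
    # noise variance over observed entries, including score uncertainty
    res2 <- sum(((xf - rec) * obs)^2)
    quad <- sum((W[, ii] * W[, jj]) * t(crossprod(Svec, obs)))
    sigma2 <- max((res2 + quad) / sum(obs), 1e-12)
    alpha <- d / (colSums(W^2) + 1e-12)
    imp_new <- (sweep(rec, 2L, mu, "+"))[!obs]
    if (max(abs(imp_new - imp_old)) < tol) { converged <- TRUE; break }
    imp_old <- imp_new
  }
  if (!converged) warning("bpca_impute: no convergence in ", max_iter, " iterations")
  out <- x
  rec <- Z %*% t(W)
  out[!obs] <- sweep(rec, 2L, mu, "+")[!obs]
  attr(out, "bpca_fit") <- list(W = W, mu = mu, sigma2 = sigma2, alpha = alpha,
                                iterations = it, converged = converged)
  out
}

#' Aggregate microbial protein groups into COG functional sums
#'
#' Sums raw intensities of all non-human protein groups sharing the COG of
#' their lead protein; groups without a COG pool under `"unassigned"`.
#' Missing intensities count as 0 for the summation, so total microbial
#' intensity is conserved per sample.
#'
#' @param table a [as_protein_table()] object (raw, pre-filter intensities).
#' @return samples x COG matrix.
#' @export
cog_aggregate <- function(table) {
  stopifnot(inherits(table, "protein_table"))
  ann <- table$annotations
  microbial <- ann$origin != "human"
  x <- table$intensities[, microbial, drop = FALSE]
  x[is.na(x)] <- 0
  cog <- ann$cog[microbial]
  cog[is.na(cog) | !nzchar(cog)] <- "unassigned"
  t(rowsum(t(x), group = cog))
}

#' Per-sample metaproteome summary metrics
#'
#' @param table a [as_protein_table()] object.
#' @return data.frame per sample: `n_human`, `n_microbial`, `n_igv`
#'   (detected group counts) and `igv_fraction` (summed immunoglobulin
#'   variable-region intensity over total intensity).
#' @export
sample_summaries <- function(table) {
  stopifnot(inherits(table, "protein_table"))
  ann <- table$annotations
  det <- !is.na(table$intensities)
  x0 <- table$intensities; x0[is.na(x0)] <- 0
  total <- rowSums(x0)
  if (any(total <= 0)) stop("sample with zero total intensity")
  data.frame(
    sample = rownames(table$intensities),
    n_human = rowSums(det[, ann$origin == "human", drop = FALSE]),
    n_microbial = rowSums(det[, ann$origin != "human", drop = FALSE]),
    n_igv = rowSums(det[, ann$ig_variable, drop = FALSE]),
    igv_fraction = rowSums(x0[, ann$ig_variable, drop = FALSE]) / total,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal component analysis of a complete matrix
#'
#' Feature-centered (not scaled) PCA; components ordered by explained
#' variance.
#'
#' @param x complete samples x features matrix.
#' @param n_components number of components to keep (default
#'   `min(dim(x)) - 1`); values above the matrix rank are truncated with a
#'   warning.
#' @return list: `scores` (samples x k), `loadings` (features x k),
#'   `var_explained` (fractions).
#' @export
pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("pca requires a complete matrix; impute first")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  r <- sum(fit$sdev > fit$sdev[1L] * 1e-12)
  k <- if (is.null(n_components)) min(dim(x)) - 1L else as.integer(n_components)
  if (k > r) {
    warning("n_components exceeds matrix rank; truncated to ", r)
    k <- r
  }
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       loadings = fit$rotation[, seq_len(k), drop = FALSE],
       var_explained = vf[seq_len(k)])
}
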