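#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X beta + u_subject + e`, `u ~ N(0, sigma2_b)`,
#' `e ~ N(0, sigma2_e)`.  The single variance ratio
#' `lambda = sigma2_b / sigma2_e` is profiled out and optimized by a
#' bounded one-dimensional search (coarse log-scale grid, then golden
#' section to tolerance 1e-8, with the `lambda = 0` boundary checked
#' explicitly).  The ML log-likelihood is also evaluated at the chosen
#' ratio, for likelihood-ratio tests.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param subject per-observation subject ids.
#' @return object of class `lmm_fit`: `beta`, `se`, `sigma2_subject`,
#'   `sigma2_resid`, `lambda`, `loglik_reml`, `loglik_ml`, `n_obs`,
#'   `n_subjects`, `boundary` (logical: ratio at search bound).
#' @export
fit_lmm <- function(y, X, subject) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n || length(subject) != n) stop("y, X, subject lengths differ")
  if (n <= p + 1L) stop("need n_obs > n_fixed_effects + 1")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  core <- .lmm_core(y, X, subject)
  fit <- .lmm_profile(core)
  lam <- fit$lambda
  q <- .lmm_quad(core, lam)
  beta <- solve(q$XtMX, q$XtMy)
  rss <- max(q$yty - drop(crossprod(beta, q$XtMy)), 1e-300)
  sigma2_e <- rss / (n - p)
  vb <- sigma2_e * solve(q$XtMX)
  ll_reml <- -0.5 * (q$logdetM + determinant(q$XtMX)$modulus[1] +
                       (n - p) * log(rss / (n - p)) + (n - p) * (1 + log(2 * pi)))
  ll_ml <- -0.5 * (q$logdetM + n * log(rss / n) + n * (1 + log(2 * pi)))
  structure(list(beta = stats::setNames(drop(beta), colnames(X)),
                 se = stats::setNames(sqrt(diag(vb)), colnames(X)),
                 sigma2_subject = lam * sigma2_e, sigma2_resid = sigma2_e,
                 lambda = lam, loglik_reml = ll_reml, loglik_ml = ll_ml,
                 n_obs = n, n_subjects = core$G, boundary = fit$boundary),
            class = "lmm_fit")
}

# sufficient statistics shared by every lambda evaluation
.lmm_core <- function(y, X, subject) {
  sub <- as.factor(as.character(subject))
  Sx <- rowsum(X, sub)
  Sy <- drop(rowsum(y, sub))
  ng <- as.numeric(table(sub))
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y * y),
       Sx = Sx, Sy = Sy, ng = ng, n = length(y), p = ncol(X),
       G = nlevels(sub))
}

# M(lambda) = I + lambda Z Z';  block inverse gives all quadratic forms
.lmm_quad <- function(core, lam) {
  cg <- lam / (1 + lam * core$ng)
  XtMX <- core$XtX - crossprod(core$Sx, core$Sx * cg)
  XtMy <- core$Xty - drop(crossprod(core$Sx, core$Sy * cg))
  yty <- core$yty - sum(cg * core$Sy^2)
  list(XtMX = XtMX, XtMy = XtMy, yty = yty,
       logdetM = sum(log1p(lam * core$ng)))
}

.lmm_neg2reml <- function(core, lam) {
  q <- .lmm_quad(core, lam)
  beta <- solve(q$XtMX, q$XtMy)
  rss <- max(q$yty - drop(crossprod(beta, q$XtMy)), 1e-300)
  q$logdetM + determinant(q$XtMX)$modulus[1] + (core$n - core$p) * log(rss)
}

.lmm_neg2ml <- function(core, lam) {
  q <- .lmm_quad(core, lam)
  beta <- solve(q$XtMX, q$XtMy)
  rss <- max(q$yty - drop(crossprod(beta, q$XtMy)), 1e-300)
  q$logdetM + core$n * log(rss / core$n)
}

# profiled maximum-likelihood fit of the variance ratio; returns the ML
# log-likelihood and coefficient estimates for likelihood-ratio testing
.lmm_ml_fit <- function(core) {
  f <- function(phi) .lmm_neg2ml(core, exp(phi))
  grid <- seq(-14, 10, length.out = 25L)
  vals <- vapply(grid, f, numeric(1))
  v0 <- .lmm_neg2ml(core, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, interval = c(lo, hi), tol = 1e-8)
  lam <- if (v0 <= opt$objective + 1e-10) 0 else exp(opt$minimum)
  q <- .lmm_quad(core, lam)
  beta <- solve(q$XtMX, q$XtMy)
  rss <- max(q$yty - drop(crossprod(beta, q$XtMy)), 1e-300)
  ll <- -0.5 * (q$logdetM + core$n * log(rss / core$n) +
                  core$n * (1 + log(2 * pi)))
  list(lambda = lam, loglik = ll, beta = drop(beta))
}

.lmm_profile <- function(core) {
  f <- function(phi) .lmm_neg2reml(core, exp(phi))
  grid <- seq(-14, 10, length.out = 25L)
  vals <- vapply(grid, f, numeric(1))
  v0 <- .lmm_neg2reml(core, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, interval = c(lo, hi), tol = 1e-8)
  if (v0 <= opt$objective + 1e-10)
    return(list(lambda = 0, boundary = TRUE))
  boundary <- abs(opt$minimum - grid[1L]) < 1e-6 || abs(opt$minimum - grid[length(grid)]) < 1e-6
  if (boundary) warning("variance-ratio estimate at search bound")
  list(lambda = exp(opt$minimum), boundary = boundary)
}

#' Likelihood-ratio test of a fixed-effect term
#'
#' Fits the full and the reduced model (term's columns dropped) at their
#' maximum-likelihood variance ratios and refers `-2 (ll0 - ll1)` to a
#' chi-squared distribution with as many degrees of freedom as columns
#' dropped.
#'
#' @param y response vector.
#' @param X full fixed-effect design matrix with column names.
#' @param subject per-observation subject ids.
#' @param term name(s) of the design column(s) to test.
#' @return list: `statistic`, `df`, `p`, `estimate` (the full-model ML
#'   coefficient(s) of the tested columns).
#' @export
test_term <- function(y, X, subject, term) {
  X <- as.matrix(X)
  if (!all(term %in% colnames(X))) stop("term not in design: ",
                                        paste(setdiff(term, colnames(X)), collapse = ", "))
  drop_idx <- which(colnames(X) %in% term)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  full <- .lmm_ml_fit(.lmm_core(y, X, subject))
  null <- .lmm_ml_fit(.lmm_core(y, X[, -drop_idx, drop = FALSE], subject))
  stat <- max(0, -2 * (null$loglik - full$loglik))
  df <- length(drop_idx)
  est <- full$beta
  names(est) <- colnames(X)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       estimate = est[drop_idx],
       loglik_full = full$loglik, loglik_null = null$loglik)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back
#' to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Feature-wise mixed-model association scan
#'
#' Fits, for every feature column, the base random-intercept model
#' `feature ~ age + hla + case + time + case:time + (1 | subject)` and
#' tests the requested terms by likelihood-ratio test; optionally fits
#' separate virus-indicator models `feature ~ age + hla + case + indicator`
#' for each named indicator column of `metadata`.  Benjamini-Hochberg
#' correction is applied within each (model, term) family; features are
#' flagged at `q < q_sig`.
#'
#' @param x samples x features matrix (e.g. arcsin-sqrt TSS abundances,
#'   normalized-imputed intensities, or factor scores); rows must align
#'   with `metadata`.
#' @param metadata data.frame with columns `subject`, `case` (0/1), `time`
#'   (0/1 for pre/post), `age` (years), `hla` (0/1 for low/high risk), plus
#'   any virus indicator columns.
#' @param terms base-model terms to test; subset of
#'   `c("case", "time", "case:time")`.
#' @param virus character vector of metadata indicator columns tested in
#'   separate models (one model per indicator).
#' @param q_sig significance threshold on q (default 0.1).
#' @return data.frame of class `association_table`: one row per
#'   (feature, model, term) with `estimate`, `statistic`, `df`, `p`, `q`,
#'   `significant`; attribute `skipped` lists zero-variance features.
#' @export
associate_features <- function(x, metadata,
                               terms = c("case", "time", "case:time"),
                               virus = character(), q_sig = 0.1) {
  x <- as.matrix(x)
  need <- c("subject", "case", "time", "age", "hla")
  if (!all(need %in% names(metadata))) stop("metadata must contain: ",
                                            paste(need, collapse = ", "))
  if (nrow(x) != nrow(metadata)) stop("x rows must align with metadata rows")
  keep <- apply(x, 2L, function(v) stats::var(v) > 0)
  skipped <- colnames(x)[!keep]
  if (length(skipped)) message("skipping zero-variance feature(s): ",
                               paste(skipped, collapse = ", "))
  x <- x[, keep, drop = FALSE]
  X_base <- cbind(`(Intercept)` = 1, age = metadata$age, hla = metadata$hla,
                  case = metadata$case, time = metadata$time,
                  `case:time` = metadata$case * metadata$time)
  models <- list(base = list(X = X_base, terms = intersect(terms, colnames(X_base))))
  for (v in virus) {
    if (!v %in% names(metadata)) stop("virus indicator not in metadata: ", v)
    Xv <- cbind(`(Intercept)` = 1, age = metadata$age, hla = metadata$hla,
                case = metadata$case)
    Xv <- cbind(Xv, as.numeric(metadata[[v]]))
    colnames(Xv)[ncol(Xv)] <- v
    models[[v]] <- list(X = Xv, terms = v)
  }
  rows <- list()
  for (mname in names(models)) {
    m <- models[[mname]]
    for (term in m$terms) {
      res <- vapply(seq_len(ncol(x)), function(j) {
        tt <- test_term(x[, j], m$X, metadata$subject, term)
        c(tt$estimate[1L], tt$statistic, tt$df, tt$p)
      }, numeric(4))
      q <- bh_fdr(res[4L, ])
      rows[[paste(mname, term)]] <- data.frame(
        feature = colnames(x), model = mname, term = term,
        estimate = res[1L, ], statistic = res[2L, ], df = res[3L, ],
        p = res[4L, ], q = q, significant = q < q_sig,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- skipped
  class(out) <- c("association_table", class(out))
  out
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation from the analysis-of-covariance fit
#' `y ~ subject + x`:
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_residual))` with
#' `df = N - n_subjects - 1`.
#'
#' @param x,y paired numeric vectors.
#' @param subject per-observation subject ids.
#' @return list: `r`, `df`, `p`.
#' @export
rmcorr <- function(x, y, subject) {
  sub <- as.factor(as.character(subject))
  if (sum(table(sub) >= 2L) < 2L)
    stop("rmcorr needs >= 2 subjects with >= 2 observations each")
  m1 <- stats::lm(y ~ 0 + sub + x)
  m0 <- stats::lm(y ~ 0 + sub)
  ss_res <- sum(stats::resid(m1)^2)
  ss_x <- sum(stats::resid(m0)^2) - ss_res
  ss_x <- max(ss_x, 0)
  slope <- stats::coef(m1)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_res))
  df <- length(y) - nlevels(sub) - 1L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tval), df))
}
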