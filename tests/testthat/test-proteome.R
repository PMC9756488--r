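prot_fixture <- function(intens, n_human = 0L, igv = logical(ncol(intens))) {
  dimnames(intens) <- list(paste0("s", seq_len(nrow(intens))),
                           paste0("g", seq_len(ncol(intens))))
  ann <- data.frame(group = colnames(intens),
                    origin = rep(c("human", "microbial"),
                                 c(n_human, ncol(intens) - n_human)),
                    genus = "unknown", cog = NA_character_,
                    cog_category = NA_character_,
                    lead_protein = paste0(colnames(intens), "_lp"),
                    ig_variable = igv, ig_constant = FALSE,
                    stringsAsFactors = FALSE)
  as_protein_table(intens, ann, zero_is_missing = FALSE)
}

test_that("prevalence filter applies the >=50% rule at the study's boundary and is idempotent", {
  x <- matrix(1, 61, 2)
  x[31:61, 1] <- NA  # detected in 30/61 samples -> dropped
  x[32:61, 2] <- NA  # 31/61 -> kept
  tab <- prot_fixture(x)
  out <- prevalence_filter(tab)
  expect_equal(colnames(out$intensities), "g2")
  out2 <- prevalence_filter(out)
  expect_identical(out2$intensities, out$intensities)
  expect_equal(ncol(prevalence_filter(tab, min_frac = 0)$intensities), 2L)
  full <- prot_fixture(matrix(runif(30) + 1, 6))
  expect_equal(ncol(prevalence_filter(full, min_frac = 1)$intensities), 5L)
})

test_that("vsn calibration is monotone within sample and affine invariant", {
  set.seed(5)
  mu <- exp(rnorm(120, 2, 1.2))
  x <- outer(exp(rnorm(10, 0, 0.3)), mu) *
    exp(matrix(rnorm(1200, 0, 0.3), 10)) + matrix(rnorm(1200, 0, 2), 10)
  x[x <= 0] <- NA
  dimnames(x) <- list(paste0("s", 1:10), paste0("f", 1:120))
  v <- vsn_normalize(x)
  expect_true(v$converged)
  for (i in 1:3) {
    o <- order(x[i, ])
    h <- v$h[i, o]
    expect_true(all(diff(h[!is.na(h)]) >= 0))  # rank order preserved
  }
  # two samples identical up to an exact affine map calibrate together
  x2 <- x[1:2, ]; x2[2, ] <- 3 + 2 * x[1, ]
  v2 <- vsn_normalize(x2)
  expect_lt(max(abs(v2$h[1, ] - v2$h[2, ]), na.rm = TRUE), 1e-6)
})

test_that("BPCA imputation recovers noiseless low-rank structure and beats mean imputation", {
  set.seed(7)
  x <- outer(rnorm(200), rnorm(40)) + 5
  mask <- matrix(runif(8000) < 0.1, 200)
  xm <- x; xm[mask] <- NA
  dimnames(xm) <- list(paste0("s", 1:200), paste0("f", 1:40))
  xi <- bpca_impute(xm, n_components = 5, seed = 1)
  expect_lt(max(abs(xi[mask] - x[mask]) / pmax(abs(x[mask]), 1e-8)), 1e-3)
  expect_identical(xi[!mask], xm[!mask])  # observed entries bit-unchanged
  # complete data: identity
  expect_identical(bpca_impute(x, n_components = 3, seed = 1), x)
  # errors
  bad <- xm; bad[, 1] <- NA
  expect_error(bpca_impute(bad, n_components = 3), "all-missing")
  expect_error(bpca_impute(xm, n_components = 40), "n_components")
  # rank-2 + noise, 10% MCAR: at least halve the mean-imputation RMSE
  ratios <- vapply(1:5, function(s) {
    set.seed(s)
    xt <- matrix(rnorm(200), 100) %*% matrix(rnorm(100), 2) +
      matrix(rnorm(5000, 0, 0.3), 100)
    m <- matrix(runif(5000) < 0.1, 100)
    xm <- xt; xm[m] <- NA
    dimnames(xm) <- list(paste0("s", 1:100), paste0("f", 1:50))
    xi <- suppressWarnings(bpca_impute(xm, n_components = 8, seed = s))
    cm <- colMeans(xm, na.rm = TRUE)
    xmean <- sweep(matrix(0, 100, 50), 2, cm, "+")
    sqrt(mean((xi[m] - xt[m])^2)) / sqrt(mean((xmean[m] - xt[m])^2))
  }, numeric(1))
  expect_lt(mean(ratios), 0.5)
})

test_that("COG aggregation sums non-host intensities and conserves totals", {
  intens <- rbind(s1 = c(5, 3, 2, 7), s2 = c(1, NA, 4, 2))
  colnames(intens) <- paste0("g", 1:4)
  ann <- data.frame(group = paste0("g", 1:4),
                    origin = c("microbial", "microbial", "human", "microbial"),
                    genus = "unknown",
                    cog = c("COG0334", "COG0334", "COG0334", NA),
                    cog_category = NA, lead_protein = paste0("g", 1:4),
                    ig_variable = FALSE, ig_constant = FALSE)
  tab <- as_protein_table(intens, ann, zero_is_missing = FALSE)
  cg <- cog_aggregate(tab)
  expect_equal(cg["s1", "COG0334"], 8)       # 5 + 3; human g3 excluded
  expect_equal(cg["s1", "unassigned"], 7)
  expect_equal(cg["s2", "COG0334"], 1)       # missing counts as 0
  # conservation of total microbial intensity per sample
  mic <- intens[, c(1, 2, 4)]; mic[is.na(mic)] <- 0
  expect_equal(rowSums(cg), rowSums(mic))
  # no COG anywhere -> only "unassigned"
  ann2 <- ann; ann2$cog <- NA
  cg2 <- cog_aggregate(as_protein_table(intens, ann2, zero_is_missing = FALSE))
  expect_equal(colnames(cg2), "unassigned")
})

test_that("per-sample summaries count detections and intensity fractions", {
  intens <- rbind(s1 = c(2, 4, 10, 10, 74), s2 = c(NA, NA, NA, 5, 5))
  colnames(intens) <- paste0("g", 1:5)
  ann <- data.frame(group = paste0("g", 1:5),
                    origin = c("human", "human", "human", "microbial", "microbial"),
                    genus = "unknown", cog = NA, cog_category = NA,
                    lead_protein = paste0("g", 1:5),
                    ig_variable = c(FALSE, TRUE, TRUE, FALSE, FALSE),
                    ig_constant = FALSE)
  tab <- as_protein_table(intens, ann, zero_is_missing = FALSE)
  ss <- sample_summaries(tab)
  expect_equal(ss$n_human, c(3, 0))
  expect_equal(ss$n_microbial, c(2, 2))
  expect_equal(ss$n_igv, c(2, 0))
  expect_equal(ss$igv_fraction, c(14 / 100, 0))
})

test_that("PCA finds a line exactly and reconstructs centered data", {
  set.seed(8)
  t_ <- rnorm(30)
  x <- outer(t_, c(1, 2, -1))
  dimnames(x) <- list(paste0("s", 1:30), paste0("f", 1:3))
  p <- pca(x, n_components = 1)
  expect_equal(p$var_explained[1], 1)
  xr <- matrix(rnorm(150), 30)
  dimnames(xr) <- list(paste0("s", 1:30), paste0("f", 1:5))
  pf <- pca(xr, n_components = 5)
  rec <- pf$scores %*% t(pf$loadings)
  expect_equal(rec, scale(xr, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_warning(pca(x, n_components = 3), "rank")
})

test_that("PC1 of an age-gradient proteome tracks age through the vsn/imputation chain", {
  rs <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 60L; d <- 150L
    age <- runif(n, 0.3, 6)
    grad <- 1 - exp(-age / 1.5)
    # mixed-sign age slopes: a common-sign gradient would be a per-sample
    # scale shift, which the calibration step legitimately removes
    V <- matrix(rnorm(n * d, 14, 1.2), n) +
      outer(grad, rnorm(d, 0, 1.5)) + matrix(rnorm(n * d, 0, 0.5), n)
    x <- exp(V)
    x[matrix(runif(n * d) < 0.15, n)] <- NA
    dimnames(x) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(d)))
    v <- vsn_normalize(x)
    xn <- suppressWarnings(bpca_impute(v$h, n_components = 8, seed = s))
    p <- pca(xn, n_components = 2)
    abs(cor(p$scores[, 1], age))
  }, numeric(1))
  expect_gt(min(rs), 0.8)
})
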