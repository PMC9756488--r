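test_that("with no subject variance the fit reduces to OLS", {
  set.seed(1)
  n_sub <- 30L
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(60), time = rep(0:1, 30))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(60)
  sub <- rep(seq_len(n_sub), each = 2L)
  f <- fit_lmm(y, X, sub)
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-6)
  expect_lt(f$sigma2_subject, 1e-4)
})

test_that("REML estimates agree with lme4 on a random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(2)
  n_sub <- 30L
  d <- data.frame(x1 = rnorm(60), time = rep(0:1, 30),
                  sub = rep(seq_len(n_sub), each = 2L))
  d$y <- 0.4 * d$x1 + rep(rnorm(n_sub), each = 2L) + rnorm(60, 0, 0.7)
  X <- cbind(`(Intercept)` = 1, x1 = d$x1, time = d$time)
  f <- fit_lmm(d$y, X, d$sub)
  m <- lme4::lmer(y ~ x1 + time + (1 | sub), data = d, REML = TRUE)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 1e-5)
  expect_equal(f$sigma2_subject, unname(lme4::VarCorr(m)$sub[1]),
               tolerance = 1e-5)
  expect_equal(f$loglik_reml, as.numeric(logLik(m)), tolerance = 1e-8)
})

test_that("in a balanced paired design the time effect is the mean within-subject difference", {
  set.seed(3)
  n_sub <- 25L
  y <- rep(rnorm(n_sub, 0, 1.3), each = 2L) + rnorm(50) + rep(c(0, 0.8), n_sub)
  X <- cbind(`(Intercept)` = 1, time = rep(0:1, n_sub))
  sub <- rep(seq_len(n_sub), each = 2L)
  f <- fit_lmm(y, X, sub)
  diffs <- y[seq(2, 50, 2)] - y[seq(1, 50, 2)]
  expect_equal(unname(f$beta["time"]), mean(diffs), tolerance = 1e-6)
})

test_that("the interaction coefficient is recovered across simulated features", {
  est <- vapply(1:60, function(s) {
    set.seed(s + 400)
    n_sub <- 40L
    md <- data.frame(subject = rep(seq_len(n_sub), each = 2L),
                     case = rep(rep(0:1, each = 2L), length.out = 80L),
                     time = rep(0:1, n_sub))
    y <- rep(rnorm(n_sub), each = 2L) + rnorm(80) +
      0.8 * md$case * md$time
    X <- cbind(`(Intercept)` = 1, case = md$case, time = md$time,
               `case:time` = md$case * md$time)
    fit_lmm(y, X, md$subject)$beta[["case:time"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.1)
})

test_that("likelihood-ratio machinery rejects duplicates and flags strong effects", {
  set.seed(4)
  X <- cbind(`(Intercept)` = 1, x = rnorm(40), x2 = 0)
  X[, "x2"] <- X[, "x"]  # duplicated column
  y <- rnorm(40)
  sub <- rep(1:20, each = 2)
  expect_error(test_term(y, X, sub, "x"), "collinear")
  X2 <- cbind(`(Intercept)` = 1, x = rnorm(40))
  y2 <- 5 * X2[, "x"] + rnorm(40, 0, 0.3) + rep(rnorm(20, 0, 0.3), each = 2)
  tt <- test_term(y2, X2, sub, "x")
  expect_lt(tt$p, 1e-6)
  expect_error(test_term(y2, X2, sub, "nope"), "not in design")
})

test_that("Benjamini-Hochberg matches the hand example and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # independent double-loop implementation of the step-up definition
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m)) {
      best <- Inf
      for (j in i:m) best <- min(best, p[o[j]] * m / j)
      q[o[i]] <- min(best, 1)
    }
    q
  }
  set.seed(5)
  for (rep in 1:10) {
    p <- runif(sample(5:400, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("repeated-measures correlation is exact on common-slope data and antisymmetric", {
  set.seed(6)
  sub <- rep(1:10, each = 3)
  x <- rnorm(30)
  y <- 2 * x + rep(rnorm(10), each = 3)
  r <- rmcorr(x, y, sub)
  expect_equal(r$r, 1)
  expect_equal(r$df, 30 - 10 - 1)
  y2 <- 1.5 * x + rep(rnorm(10), each = 3) + rnorm(30, 0, 0.5)
  expect_equal(rmcorr(x, -y2, sub)$r, -rmcorr(x, y2, sub)$r)
  expect_error(rmcorr(1:4, 1:4, 1:4), "2 subjects")
  # null: distribution centered at zero
  rs <- vapply(1:200, function(s) {
    set.seed(s)
    rmcorr(rnorm(80), rep(rnorm(40), each = 2) + rnorm(80), rep(1:40, each = 2))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("associate_features skips constant features and fits virus models separately", {
  sim <- sim_lmm_features(1, n_sub = 20L, n_feat = 6L, n_true = 2L, delta = 2)
  y <- sim$y
  y[, 6] <- 1  # constant
  md <- sim$metadata
  md$any_virus <- rep(rbinom(20, 1, 0.4), each = 2L)
  expect_message(tab <- associate_features(y, md, virus = "any_virus"),
                 "zero-variance")
  expect_false("f6" %in% tab$feature)
  expect_setequal(unique(tab$model), c("base", "any_virus"))
  expect_setequal(unique(tab$term[tab$model == "base"]),
                  c("case", "time", "case:time"))
  # q within a family is BH of that family's p-values
  fam <- tab[tab$model == "base" & tab$term == "case:time", ]
  expect_equal(fam$q, bh_fdr(fam$p))
})
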