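#' Multi-view group factor analysis with ARD and spike-and-slab sparsity
#'
#' Fits the shared-factor model `x_nm = W_m z_n + e_nm` across several data
#' views by mean-field variational inference: `z_n ~ N(0, I)`, Gaussian
#' noise with feature-specific precision `tau_mj`, per-(view, factor)
#' automatic-relevance (ARD) precisions `alpha_mk` shrinking unneeded
#' weight columns, and a feature-wise spike-and-slab prior
#' `w_mjk = s_mjk * what_mjk`, `s ~ Bernoulli(theta_mk)`, that zeroes
#' individual weights so irrelevant factors collapse cleanly instead of
#' fitting sampling noise.  Samples missing a whole view contribute no
#' likelihood term for it and still receive factor scores from their
#' remaining views.  Binary views use a Bernoulli likelihood with logistic
#' link through the quadratic (Jaakkola-Jordan) variational bound, with a
#' per-feature intercept.
#'
#' After the fit, scores are rescaled to unit variance (all scale moved
#' into the weights), each factor's sign is set so its largest-magnitude
#' weight is positive, and factors are ordered by total variance explained.
#'
#' @param views named list of samples x features matrices sharing row
#'   names; a sample missing a view is a row of `NA`s.  Gaussian views are
#'   centered per feature over their observed samples before the fit.
#' @param K_init number of factors to start from (pruning happens through
#'   the sparsity priors plus post-hoc selection, not in-fit).
#' @param seed integer seed controlling the initialization.
#' @param tol relative convergence tolerance on the evidence lower bound
#'   (default 1e-5).
#' @param max_iter maximum update sweeps (default 2000).
#' @param binary character vector naming views with Bernoulli likelihood.
#' @param scale_views if `TRUE`, feature-scale Gaussian views to unit
#'   variance before the fit (default `FALSE`: inputs are assumed already
#'   variance-stabilized).
#' @param ard_iters inner iterations of the weight/precision block per
#'   sweep (default 10); higher values collapse irrelevant factors faster
#'   without changing the optimum.
#' @return object of class `gfa_model`: `Z` (samples x K scores), `W`
#'   (named list of features x K posterior mean weights), `tau`, `alpha`,
#'   `theta` (slab inclusion rates), `elbo` trace, `r2` (output of
#'   [variance_explained()]), `centers`, `obs` masks, `converged`.
#' @export
fit_gfa <- function(views, K_init = 15L, seed = 1L, tol = 1e-5,
                    max_iter = 2000L, binary = character(),
                    scale_views = FALSE, ard_iters = 10L) {
  if (is.null(names(views)) || any(!nzchar(names(views))))
    stop("views must be a named list")
  views <- lapply(views, as.matrix)
  ns <- vapply(views, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("all views need the same samples (rows)")
  n <- ns[[1L]]
  K <- as.integer(K_init)
  if (K >= n) stop("K_init must be < n_samples")
  if (any(vapply(views, ncol, integer(1)) < 2L)) stop("each view needs >= 2 features")
  M <- length(views)
  vnames <- names(views)
  is_bin <- vnames %in% binary

  obs <- lapply(views, function(x) rowSums(!is.na(x)) > 0L)
  if (any(!Reduce(`|`, obs))) stop("every sample must be observed in >= 1 view")
  for (m in seq_len(M)) {
    xo <- views[[m]][obs[[m]], , drop = FALSE]
    if (anyNA(xo)) stop("partial missingness inside view '", vnames[m],
                        "': mask whole samples only")
  }

  centers <- scales <- vector("list", M)
  X <- vector("list", M)
  for (m in seq_len(M)) {
    xo <- views[[m]][obs[[m]], , drop = FALSE]
    if (is_bin[m]) {
      if (!all(xo %in% c(0, 1))) stop("binary view '", vnames[m], "' must be 0/1")
      centers[[m]] <- rep(0, ncol(xo)); scales[[m]] <- rep(1, ncol(xo))
      X[[m]] <- xo
    } else {
      centers[[m]] <- colMeans(xo)
      s <- if (scale_views) apply(xo, 2L, stats::sd) else rep(1, ncol(xo))
      s[s == 0] <- 1
      scales[[m]] <- s
      X[[m]] <- sweep(sweep(xo, 2L, centers[[m]], "-"), 2L, s, "/")
    }
  }
  D <- vapply(X, ncol, integer(1))
  Nm <- vapply(X, nrow, integer(1))

  # ---- initialization -----------------------------------------------------
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # scores initialized from the Gaussian views only: the Bernoulli views
  # live on an arbitrary pseudo-data scale and would otherwise seed factors
  # aligned with their sampling noise
  init_views <- if (all(is_bin)) seq_len(M) else which(!is_bin)
  concat <- do.call(cbind, lapply(init_views, function(m) {
    full <- matrix(0, n, D[m])
    full[obs[[m]], ] <- if (is_bin[m]) X[[m]] - mean(X[[m]]) else X[[m]]
    full / sqrt(D[m])
  }))
  sv <- svd(concat, nu = K, nv = 0)
  Z <- sv$u[, seq_len(K), drop = FALSE] * sqrt(n)
  Z <- Z + matrix(stats::rnorm(n * K, sd = 0.05), n, K)
  Sigma_z <- rep(list(diag(1e-4, K)), n)
  W <- lapply(seq_len(M), function(m) matrix(0, D[m], K))    # <w> = Q * mu
  W2 <- lapply(seq_len(M), function(m) matrix(0, D[m], K))   # <w^2>
  Qs <- lapply(seq_len(M), function(m) matrix(0.5, D[m], K)) # q(s = 1)
  Mus <- lapply(seq_len(M), function(m) matrix(0, D[m], K))  # slab mean
  S2s <- lapply(seq_len(M), function(m) matrix(1, D[m], K))  # slab variance
  SwSum <- lapply(seq_len(M), function(m) matrix(0, K, K))
  tau_e <- lapply(seq_len(M), function(m)
    if (is_bin[m]) rep(1, D[m]) else 2 / pmax(apply(X[[m]], 2L, stats::var), 1e-8))
  tau_elog <- lapply(seq_len(M), function(m) rep(0, D[m]))
  alpha_e <- lapply(seq_len(M), function(m) rep(1, K))
  alpha_elog <- lapply(seq_len(M), function(m) rep(0, K))
  th_a <- lapply(seq_len(M), function(m) rep(1, K))          # Beta posterior
  th_b <- lapply(seq_len(M), function(m) rep(1, K))
  bias <- lapply(seq_len(M), function(m) rep(0, D[m]))
  xi <- lapply(seq_len(M), function(m)
    if (is_bin[m]) matrix(1, Nm[m], D[m]) else NULL)
  a0 <- b0 <- 1e-3       # ARD hyperprior
  c0 <- d0 <- 1e-3       # noise hyperprior
  ta0 <- tb0 <- 1        # Beta(1, 1) slab-inclusion hyperprior
  xx <- lapply(X, function(x) colSums(x^2))

  lambda_jj <- function(v) ifelse(v < 1e-6, 0.125, tanh(v / 2) / (4 * v))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

  elbo_trace <- numeric(0)
  converged <- FALSE
  Wstats <- vector("list", M)

  ## staged optimization: Gaussian views are fit to convergence first, then
  ## Bernoulli views join.  By then irrelevant factors are collapsed and
  ## stay collapsed, instead of latching onto the sampling noise of a small
  ## binary block (a local optimum with a demonstrably worse bound).  The
  ## reported trace is the final (full-model) phase.
  phases <- if (any(is_bin) && any(!is_bin))
    list(which(!is_bin), seq_len(M)) else list(seq_len(M))

  for (phase in seq_along(phases)) {
  active <- phases[[phase]]
  final_phase <- phase == length(phases)
  elbo_old <- -Inf
  converged <- FALSE
  ## rotation refinement: variational coordinate ascent can converge with
  ## factors entangled by a rotation of the shared subspace (the likelihood
  ## is invariant; only the sparsity priors prefer aligned axes).  At
  ## convergence we propose the oblique (promax) rotation of the stacked
  ## weights, resume the updates, and keep the result only if the bound
  ## ends higher.
  rot_attempts <- 0L; max_rot <- 2L
  in_trial <- FALSE; snap <- NULL; trial_trace <- numeric(0)
  has_gauss <- any(!is_bin[active])
  save_state <- function() list(Z = Z, Sigma_z = Sigma_z, W = W, W2 = W2,
                                Qs = Qs, Mus = Mus, S2s = S2s, tau_e = tau_e,
                                tau_elog = tau_elog, alpha_e = alpha_e,
                                alpha_elog = alpha_elog, th_a = th_a,
                                th_b = th_b, bias = bias, xi = xi,
                                SwSum = SwSum, Wstats = Wstats)
  rotate_scores <- function() {
    gw <- do.call(rbind, W[active[!is_bin[active]]])
    live <- which(colSums(gw^2) > 1e-10)
    if (length(live) < 2L) return(FALSE)
    pm <- tryCatch(stats::promax(gw[, live, drop = FALSE], m = 4),
                   error = function(e) NULL)
    if (is.null(pm)) return(FALSE)
    Tf <- diag(K); Tf[live, live] <- pm$rotmat
    A <- tryCatch(solve(Tf), error = function(e) NULL)
    if (is.null(A)) return(FALSE)
    Z <<- Z %*% t(A)
    for (i in seq_len(n)) Sigma_z[[i]] <<- A %*% Sigma_z[[i]] %*% t(A)
    TRUE
  }
  for (it in seq_len(max_iter)) {
    ## ---- update weights / precisions / inclusion, per view ---------------
    ## the whole block is iterated at fixed q(Z): repeated coordinate
    ## updates remain exact ascent steps and let the sparsity priors reach
    ## their collapsed solutions for irrelevant factors
    for (m in active) {
      rows <- which(obs[[m]])
      Zo <- Z[rows, , drop = FALSE]
      S <- crossprod(Zo) + Reduce(`+`, Sigma_z[rows])
      Sd <- diag(S)
      elth <- digamma(th_a[[m]]) - digamma(th_a[[m]] + th_b[[m]])
      elth1 <- digamma(th_b[[m]]) - digamma(th_a[[m]] + th_b[[m]])
      if (!is_bin[m]) {
        C <- crossprod(Zo, X[[m]])      # K x D
        for (inner in seq_len(ard_iters)) {
          for (k in seq_len(K)) {
            bk <- tau_e[[m]] * (C[k, ] - drop(W[[m]] %*% S[, k]) +
                                  W[[m]][, k] * Sd[k])
            s2 <- 1 / (alpha_e[[m]][k] + tau_e[[m]] * Sd[k])
            mu <- s2 * bk
            lo <- elth[k] - elth1[k] +
              0.5 * (alpha_elog[[m]][k] + log(s2)) + 0.5 * mu^2 / s2
            q <- stats::plogis(lo)
            Qs[[m]][, k] <- q; Mus[[m]][, k] <- mu; S2s[[m]][, k] <- s2
            W[[m]][, k] <- q * mu
            W2[[m]][, k] <- q * (mu^2 + s2)
          }
          # noise precisions
          resid <- xx[[m]] - 2 * rowSums(W[[m]] * t(C)) +
            rowSums((W[[m]] %*% S) * W[[m]]) +
            drop((W2[[m]] - W[[m]]^2) %*% Sd)
          resid <- pmax(resid, 1e-12)
          tau_shape <- c0 + Nm[m] / 2
          tau_rate <- d0 + resid / 2
          tau_e[[m]] <- tau_shape / tau_rate
          tau_elog[[m]] <- digamma(tau_shape) - log(tau_rate)
          # ARD precisions over slab values <what^2>
          what2 <- W2[[m]] + sweep(1 - Qs[[m]], 2L, alpha_e[[m]], "/")
          al_shape <- a0 + D[m] / 2
          al_rate <- b0 + colSums(what2) / 2
          alpha_e[[m]] <- al_shape / al_rate
          alpha_elog[[m]] <- digamma(al_shape) - log(al_rate)
          # inclusion rates
          th_a[[m]] <- ta0 + colSums(Qs[[m]])
          th_b[[m]] <- tb0 + D[m] - colSums(Qs[[m]])
          elth <- digamma(th_a[[m]]) - digamma(th_a[[m]] + th_b[[m]])
          elth1 <- digamma(th_b[[m]]) - digamma(th_a[[m]] + th_b[[m]])
        }
        SwSum[[m]] <- crossprod(W[[m]] * sqrt(tau_e[[m]])) +
          diag(drop(crossprod(W2[[m]] - W[[m]]^2, tau_e[[m]])), K)
        Wstats[[m]] <- list(C = C, tau_shape = tau_shape, tau_rate = tau_rate,
                            al_shape = al_shape, al_rate = al_rate,
                            elth = elth, elth1 = elth1)
      } else {
        ## Bernoulli view: Jaakkola bound; per-feature quadratic forms
        Y <- X[[m]]
        Sv <- t(vapply(rows, function(i) as.numeric(Sigma_z[[i]]),
                       numeric(K * K)))                     # Nm x K^2
        Z2S <- Zo^2 + Sv[, seq(1L, K * K, by = K + 1L), drop = FALSE]  # E[z_k^2]
        for (inner in seq_len(ard_iters)) {
          lam <- lambda_jj(xi[[m]])                          # Nm x D
          rho <- 2 * lam
          Yc <- Y - 0.5 - sweep(rho, 2L, bias[[m]], "*")
          for (j in seq_len(D[m])) {
            Pj <- crossprod(Zo * sqrt(rho[, j])) +
              matrix(colSums(rho[, j] * Sv), K, K)
            rj <- drop(crossprod(Zo, Yc[, j]))
            for (k in seq_len(K)) {
              bk <- rj[k] - sum(W[[m]][j, ] * Pj[, k]) + W[[m]][j, k] * Pj[k, k]
              s2 <- 1 / (alpha_e[[m]][k] + Pj[k, k])
              mu <- s2 * bk
              lo <- elth[k] - elth1[k] +
                0.5 * (alpha_elog[[m]][k] + log(s2)) + 0.5 * mu^2 / s2
              q <- stats::plogis(lo)
              Qs[[m]][j, k] <- q; Mus[[m]][j, k] <- mu; S2s[[m]][j, k] <- s2
              W[[m]][j, k] <- q * mu
              W2[[m]][j, k] <- q * (mu^2 + s2)
            }
          }
          # intercepts, then bound locations xi^2 = E[(w'z + b)^2]
          Ezh <- Zo %*% t(W[[m]])
          bias[[m]] <- colSums((Y - 0.5) - rho * Ezh) / pmax(colSums(rho), 1e-12)
          varw <- W2[[m]] - W[[m]]^2
          quad <- tensor_quad(Sv, Zo, W[[m]], K) + Z2S %*% t(varw)
          Eh2 <- sweep(Ezh, 2L, bias[[m]], "+")^2 + quad
          xi[[m]] <- sqrt(pmax(Eh2, 1e-12))
          what2 <- W2[[m]] + sweep(1 - Qs[[m]], 2L, alpha_e[[m]], "/")
          al_shape <- a0 + D[m] / 2
          al_rate <- b0 + colSums(what2) / 2
          alpha_e[[m]] <- al_shape / al_rate
          alpha_elog[[m]] <- digamma(al_shape) - log(al_rate)
          th_a[[m]] <- ta0 + colSums(Qs[[m]])
          th_b[[m]] <- tb0 + D[m] - colSums(Qs[[m]])
          elth <- digamma(th_a[[m]]) - digamma(th_a[[m]] + th_b[[m]])
          elth1 <- digamma(th_b[[m]]) - digamma(th_a[[m]] + th_b[[m]])
        }
        Wstats[[m]] <- list(al_shape = al_shape, al_rate = al_rate,
                            elth = elth, elth1 = elth1)
      }
    }

    ## ---- update Z --------------------------------------------------------
    patt <- vapply(seq_len(n), function(i)
      paste(vapply(obs, `[`, logical(1), i), collapse = ""), character(1))
    ## Bernoulli views inform q(Z) only for samples with no Gaussian view:
    ## their weights are still inferred (conditional fit), but a small
    ## binary block cannot bend the latent space toward its sampling noise
    gauss_obs <- if (any(!is_bin[active]))
      Reduce(`|`, obs[active[!is_bin[active]]]) else rep(FALSE, n)
    bin_informs <- lapply(seq_len(M), function(m)
      if (is_bin[m]) obs[[m]] & !gauss_obs else obs[[m]])
    lin <- matrix(0, n, K)
    for (m in active) {
      rows <- which(obs[[m]])
      if (!is_bin[m]) {
        lin[rows, ] <- lin[rows, ] + X[[m]] %*% (W[[m]] * tau_e[[m]])
      } else {
        keep <- bin_informs[[m]][rows]
        if (!any(keep)) next
        lam <- lambda_jj(xi[[m]])
        contrib <- (X[[m]] - 0.5 - 2 * lam * rep(bias[[m]], each = Nm[m])) %*% W[[m]]
        lin[rows[keep], ] <- lin[rows[keep], ] + contrib[keep, , drop = FALSE]
      }
    }
    if (!any(is_bin[active] & vapply(bin_informs[active], any, logical(1)))) {
      for (p in unique(patt)) {
        idx <- which(patt == p)
        P <- diag(K)
        for (m in active) if (!is_bin[m] && obs[[m]][idx[1L]]) P <- P + SwSum[[m]]
        Sig <- chol2inv(chol(P))
        Z[idx, ] <- lin[idx, , drop = FALSE] %*% Sig
        for (i in idx) Sigma_z[[i]] <- Sig
      }
    } else {
      binP <- vector("list", M)
      for (m in intersect(which(is_bin), active)) {
        # per-sample K x K precision contribution of the binary view
        lam <- lambda_jj(xi[[m]])
        varw <- W2[[m]] - W[[m]]^2
        binP[[m]] <- vector("list", Nm[m])
        for (r in seq_len(Nm[m])) {
          Pm <- matrix(0, K, K)
          for (j in seq_len(D[m]))
            Pm <- Pm + 2 * lam[r, j] *
              (tcrossprod(W[[m]][j, ]) + diag(varw[j, ], K))
          binP[[m]][[r]] <- Pm
        }
      }
      for (i in seq_len(n)) {
        P <- diag(K)
        for (m in active) {
          if (!is_bin[m]) {
            if (obs[[m]][i]) P <- P + SwSum[[m]]
          } else if (bin_informs[[m]][i]) {
            P <- P + binP[[m]][[match(i, which(obs[[m]]))]]
          }
        }
        Sig <- chol2inv(chol(P))
        Z[i, ] <- drop(Sig %*% lin[i, ])
        Sigma_z[[i]] <- Sig
      }
    }

    ## ---- ELBO ------------------------------------------------------------
    elbo <- 0
    for (i in seq_len(n)) {
      elbo <- elbo - 0.5 * (sum(Z[i, ]^2) + sum(diag(Sigma_z[[i]]))) +
        0.5 * determinant(Sigma_z[[i]])$modulus[1] + K / 2
    }
    for (m in active) {
      ws <- Wstats[[m]]
      rows <- which(obs[[m]])
      Zo <- Z[rows, , drop = FALSE]
      S <- crossprod(Zo) + Reduce(`+`, Sigma_z[rows])
      Sd <- diag(S)
      if (!is_bin[m]) {
        C <- crossprod(Zo, X[[m]])
        resid <- pmax(xx[[m]] - 2 * rowSums(W[[m]] * t(C)) +
                        rowSums((W[[m]] %*% S) * W[[m]]) +
                        drop((W2[[m]] - W[[m]]^2) %*% Sd), 1e-12)
        elbo <- elbo + sum(Nm[m] / 2 * (tau_elog[[m]] - log(2 * pi)) -
                             tau_e[[m]] * resid / 2)
        elbo <- elbo + sum(gamma_elbo(ws$tau_shape, ws$tau_rate, c0, d0))
      } else {
        lam <- lambda_jj(xi[[m]])
        Sv <- t(vapply(rows, function(i) as.numeric(Sigma_z[[i]]),
                       numeric(K * K)))
        Z2S <- Zo^2 + Sv[, seq(1L, K * K, by = K + 1L), drop = FALSE]
        Ezh <- Zo %*% t(W[[m]])
        varw <- W2[[m]] - W[[m]]^2
        Eh <- sweep(Ezh, 2L, bias[[m]], "+")
        Eh2 <- Eh^2 + tensor_quad(Sv, Zo, W[[m]], K) + Z2S %*% t(varw)
        elbo <- elbo + sum(log(stats::plogis(xi[[m]])) + (X[[m]] - 0.5) * Eh -
                             xi[[m]] / 2 - lam * (Eh2 - xi[[m]]^2))
      }
      # spike-and-slab weight terms
      Q <- Qs[[m]]
      slab <- Q * (0.5 * rep(alpha_elog[[m]], each = D[m]) -
                     0.5 * rep(alpha_e[[m]], each = D[m]) * (Mus[[m]]^2 + S2s[[m]]) +
                     0.5 * log(S2s[[m]]) + 0.5) +
        # spike branch: q(what | s = 0) = N(0, 1 / E[alpha]), leaving the
        # Jensen gap between E[log alpha] and log E[alpha]
        (1 - Q) * 0.5 * rep(alpha_elog[[m]] - log(alpha_e[[m]]), each = D[m])
      bern <- Q * rep(ws$elth, each = D[m]) +
        (1 - Q) * rep(ws$elth1, each = D[m]) - xlogx(Q) - xlogx(1 - Q)
      elbo <- elbo + sum(slab) + sum(bern)
      elbo <- elbo + sum(gamma_elbo(ws$al_shape, ws$al_rate, a0, b0))
      elbo <- elbo + sum(beta_elbo(th_a[[m]], th_b[[m]], ta0, tb0))
    }
    conv_now <- is.finite(elbo_old) &&
      abs(elbo - elbo_old) <= tol * (abs(elbo_old) + tol)
    if (in_trial) {
      trial_trace <- c(trial_trace, elbo)
      if (conv_now) {
        if (elbo > snap$elbo + tol * abs(snap$elbo)) {
          # rotation improved the bound: keep it; report the monotone tail
          if (final_phase) {
            first <- which(trial_trace >= snap$elbo)[1L]
            if (!is.na(first))
              elbo_trace <- c(elbo_trace, trial_trace[first:length(trial_trace)])
          }
          in_trial <- FALSE; snap <- NULL; trial_trace <- numeric(0)
          if (rot_attempts < max_rot && has_gauss && K >= 2L) {
            snap <- save_state(); snap$elbo <- elbo
            if (rotate_scores()) {
              rot_attempts <- rot_attempts + 1L
              in_trial <- TRUE; elbo_old <- -Inf
              next
            }
            snap <- NULL
          }
          converged <- TRUE
          break
        }
        # no improvement: restore the pre-rotation state
        Z <- snap$Z; Sigma_z <- snap$Sigma_z; W <- snap$W; W2 <- snap$W2
        Qs <- snap$Qs; Mus <- snap$Mus; S2s <- snap$S2s
        tau_e <- snap$tau_e; tau_elog <- snap$tau_elog
        alpha_e <- snap$alpha_e; alpha_elog <- snap$alpha_elog
        th_a <- snap$th_a; th_b <- snap$th_b
        bias <- snap$bias; xi <- snap$xi
        SwSum <- snap$SwSum; Wstats <- snap$Wstats
        in_trial <- FALSE; snap <- NULL; trial_trace <- numeric(0)
        converged <- TRUE
        break
      }
    } else {
      if (final_phase) elbo_trace <- c(elbo_trace, elbo)
      if (conv_now) {
        if (rot_attempts < max_rot && has_gauss && K >= 2L) {
          snap <- save_state(); snap$elbo <- elbo
          if (rotate_scores()) {
            rot_attempts <- rot_attempts + 1L
            in_trial <- TRUE; elbo_old <- -Inf
            next
          }
          snap <- NULL
        }
        converged <- TRUE
        break
      }
    }
    elbo_old <- elbo
  }
  }
  if (!converged) {
    nt <- length(elbo_trace)
    warning("fit_gfa: ELBO not converged in ", max_iter,
            " sweeps (last relative change ",
            signif(abs(elbo_trace[nt] - elbo_trace[nt - 1L]) /
                     abs(elbo_trace[nt - 1L]), 3), ")")
  }

  ## ---- post-processing: scale, sign, order -------------------------------
  sdz <- apply(Z, 2L, stats::sd)
  sdz[sdz == 0] <- 1
  Z <- sweep(Z, 2L, sdz, "/")
  for (m in seq_len(M)) W[[m]] <- sweep(W[[m]], 2L, sdz, "*")
  for (k in seq_len(K)) {
    allw <- unlist(lapply(W, function(w) w[, k]))
    if (length(allw) && allw[which.max(abs(allw))] < 0) {
      Z[, k] <- -Z[, k]
      for (m in seq_len(M)) W[[m]][, k] <- -W[[m]][, k]
    }
  }
  names(W) <- vnames
  for (m in seq_len(M)) rownames(W[[m]]) <- colnames(views[[m]])
  rownames(Z) <- rownames(views[[1L]])
  colnames(Z) <- paste0("LF", seq_len(K))
  theta <- lapply(seq_len(M), function(m) th_a[[m]] / (th_a[[m]] + th_b[[m]]))
  names(theta) <- names(tau_e) <- names(alpha_e) <- vnames
  model <- structure(list(
    Z = Z, W = W, tau = tau_e, alpha = alpha_e, theta = theta, bias = bias,
    centers = centers, scales = scales, obs = obs, binary = is_bin,
    X = X, xi = xi, elbo = elbo_trace, converged = converged, K = K),
    class = "gfa_model")
  r2 <- variance_explained(model)
  ord <- order(r2$per_factor_total, decreasing = TRUE)
  model$Z <- model$Z[, ord, drop = FALSE]
  colnames(model$Z) <- paste0("LF", seq_len(K))
  for (m in seq_len(M)) model$W[[m]] <- model$W[[m]][, ord, drop = FALSE]
  model$r2 <- variance_explained(model)
  model
}

# sum_kk' w_k w_k' E[z_k z_k']_n minus the mean-only part, i.e. the
# contribution of the score covariance: rows are samples, columns features
tensor_quad <- function(Sv, Zo, Wm, K) {
  # Sv: Nm x K^2 per-sample vec(Sigma_z); quadratic form w' Sigma_n w per
  # (sample, feature)
  ii <- rep(seq_len(K), K); jj <- rep(seq_len(K), each = K)
  Sv %*% t(Wm[, ii, drop = FALSE] * Wm[, jj, drop = FALSE])
}

# E_q[log p(g)] - E_q[log q(g)] for a Gamma(shape, rate) posterior against a
# Gamma(s0, r0) prior
gamma_elbo <- function(shape, rate, s0, r0) {
  elog <- digamma(shape) - log(rate)
  e <- shape / rate
  (s0 - 1) * elog - r0 * e + s0 * log(r0) - lgamma(s0) +
    (lgamma(shape) - (shape - 1) * digamma(shape) - log(rate) + shape)
}

# same for a Beta(a, b) posterior against a Beta(a0, b0) prior
beta_elbo <- function(a, b, a0, b0) {
  elth <- digamma(a) - digamma(a + b)
  elth1 <- digamma(b) - digamma(a + b)
  (a0 - 1) * elth + (b0 - 1) * elth1 - lbeta(a0, b0) +
    (lbeta(a, b) - (a - 1) * digamma(a) - (b - 1) * digamma(b) +
       (a + b - 2) * digamma(a + b))
}

#' Variance explained by a fitted factor model
#'
#' Per (view, factor): `R2_mk = 1 - sum((x - z_k w_k')^2) / sum(x^2)` over
#' observed entries of the centered view; per-view totals use the full
#' reconstruction `Z W'`; per-factor totals pool residual and total sums of
#' squares across views.  For Bernoulli views, whose reconstructions live
#' on the logit scale, the sums of squares are taken on the variational
#' Gaussian pseudo-data weighted by the bound's per-entry precisions, which
#' puts them on a scale comparable to the Gaussian views.  The per-factor
#' values add up to the total only when factor scores are
#' (near-)orthogonal.
#'
#' @param model a [fit_gfa()] object.
#' @return list: `per_view_factor` (views x factors matrix),
#'   `per_view_total`, `per_factor_total`, `total`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "gfa_model"))
  M <- length(model$W); K <- model$K
  vnames <- names(model$W)
  r2vf <- matrix(NA_real_, M, K, dimnames = list(vnames, colnames(model$Z)))
  tot_v <- numeric(M); res_k <- matrix(0, M, K); res_full <- numeric(M)
  ss_v <- numeric(M)
  for (m in seq_len(M)) {
    rows <- which(model$obs[[m]])
    Zo <- model$Z[rows, , drop = FALSE]
    W <- model$W[[m]]
    if (model$binary[m]) {
      # pseudo-data of the quadratic bound, centered by the per-feature
      # intercept, with per-entry precision weights
      lam <- ifelse(model$xi[[m]] < 1e-6, 0.125,
                    tanh(model$xi[[m]] / 2) / (4 * model$xi[[m]]))
      wts <- 2 * lam
      x <- (model$X[[m]] - 0.5) / wts -
        rep(model$bias[[m]], each = nrow(Zo))
    } else {
      x <- model$X[[m]]
      wts <- matrix(1, nrow(x), ncol(x))
    }
    ss <- sum(wts * x^2)
    ss_v[m] <- ss
    for (k in seq_len(K)) {
      res_k[m, k] <- sum(wts * (x - tcrossprod(Zo[, k], W[, k]))^2)
      r2vf[m, k] <- 1 - res_k[m, k] / ss
    }
    res_full[m] <- sum(wts * (x - tcrossprod(Zo, W))^2)
    tot_v[m] <- 1 - res_full[m] / ss
  }
  names(tot_v) <- vnames
  per_factor_total <- 1 - colSums(res_k) / sum(ss_v)
  names(per_factor_total) <- colnames(model$Z)
  list(per_view_factor = r2vf, per_view_total = tot_v,
       per_factor_total = per_factor_total,
       total = 1 - sum(res_full) / sum(ss_v))
}

#' Select latent factors by variance explained
#'
#' Retains factor k when its variance explained exceeds `r2_min` under the
#' chosen criterion: `"total"` (pooled across views, default) or `"max"`
#' (largest single-view value).
#'
#' @param model a [fit_gfa()] object (with `r2` computed).
#' @param r2_min threshold (default 0.05, i.e. more than 5% of variance).
#' @param criterion `"total"` or `"max"`.
#' @return character vector of selected factor names (possibly empty, with
#'   a warning).
#' @export
select_factors <- function(model, r2_min = 0.05, criterion = c("total", "max")) {
  criterion <- match.arg(criterion)
  r2 <- model$r2
  val <- switch(criterion,
                total = r2$per_factor_total,
                max = apply(r2$per_view_factor, 2L, max))
  sel <- names(val)[val > r2_min]
  if (length(sel) == 0L) warning("no factor exceeds r2_min = ", r2_min)
  sel
}

#' Top-weighted features of one factor
#'
#' Features ranked by absolute weight (weights are on the unit-variance
#' score scale); ties broken by stable feature order.  Optional annotations
#' (e.g. genus, COG category) are attached by feature id.
#'
#' @param model a [fit_gfa()] object.
#' @param factor factor name (`"LF3"`) or index.
#' @param n number of features to return (default 20).
#' @param annotations optional data.frame with a `feature` column to merge.
#' @return data.frame: `feature`, `view`, `weight`, `abs_weight` plus any
#'   annotation columns, strongest first.
#' @export
top_weights <- function(model, factor, n = 20L, annotations = NULL) {
  stopifnot(inherits(model, "gfa_model"))
  k <- if (is.character(factor)) match(factor, colnames(model$Z)) else as.integer(factor)
  if (is.na(k) || k < 1L || k > model$K) stop("unknown factor: ", factor)
  if (!is.null(model$r2)) {
    sel <- select_factors(model)
    fname <- colnames(model$Z)[k]
    if (!fname %in% sel)
      warning("factor ", fname, " was not selected by variance explained")
  }
  tab <- do.call(rbind, lapply(names(model$W), function(v) {
    data.frame(feature = rownames(model$W[[v]]), view = v,
               weight = model$W[[v]][, k], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  tab$abs_weight <- abs(tab$weight)
  tab <- tab[order(-tab$abs_weight), , drop = FALSE]  # stable: ties keep order
  tab <- utils::head(tab, n)
  if (!is.null(annotations))
    tab <- merge(tab, annotations, by = "feature", all.x = TRUE, sort = FALSE)
  tab[order(-tab$abs_weight), , drop = FALSE]
}
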