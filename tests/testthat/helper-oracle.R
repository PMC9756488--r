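# Brute-force amalgamation oracle, coded directly from the published rule:
# OTUs accounting for more than 0.1% of reads in at least 15% of samples are
# left unaltered; the rest are combined to their common parent taxa; the
# collapsing is repeated three times and features still failing are
# excluded.  Deliberately simple data structures (lists of features, string
# keys), no sharing with the package implementation.
oracle_amalgamate <- function(counts, lineages, abund = 0.001, prev = 0.15,
                              n_iter = 3L) {
  totals <- rowSums(counts)
  n_samp <- nrow(counts)
  feats <- lapply(seq_len(ncol(counts)), function(j) {
    list(ranks = triomic::parse_lineage(lineages[[j]]), level = 8L,
         counts = counts[, j])
  })
  retained <- list()
  passes <- function(f) {
    frac <- f$counts / totals
    sum(frac > abund) >= prev * n_samp
  }
  for (round in seq_len(n_iter)) {
    keep <- vapply(feats, passes, logical(1))
    retained <- c(retained, feats[keep])
    failing <- feats[!keep]
    if (length(failing) == 0L) { feats <- list(); break }
    groups <- list()
    stuck <- list()
    for (f in failing) {
      r <- f$level - 1L
      while (r >= 1L && !nzchar(f$ranks[r])) r <- r - 1L
      if (r < 1L) { stuck <- c(stuck, list(f)); next }
      key <- paste(f$ranks[seq_len(r)], collapse = "|")
      nr <- f$ranks; if (r < 7L) nr[(r + 1L):7L] <- ""
      if (is.null(groups[[key]]))
        groups[[key]] <- list(ranks = nr, level = r, counts = f$counts)
      else groups[[key]]$counts <- groups[[key]]$counts + f$counts
    }
    feats <- c(stuck, unname(groups))
  }
  keep <- vapply(feats, passes, logical(1))
  retained <- c(retained, feats[keep])
  excluded <- feats[!keep]
  list(retained = retained, excluded = excluded)
}

# canonical multiset signature of a feature set: sorted strings of
# "<lineage>#<counts>"
feat_signature <- function(ranks_list, counts_list) {
  if (length(ranks_list) == 0L) return(character(0))
  sort(mapply(function(r, ct) paste(paste(r, collapse = ";"),
                                    paste(ct, collapse = ","), sep = "#"),
              ranks_list, counts_list))
}

sig_from_oracle <- function(feats) {
  feat_signature(lapply(feats, `[[`, "ranks"), lapply(feats, `[[`, "counts"))
}

sig_from_package <- function(ft, status) {
  idx <- ft$info$status == status
  cts <- if (status == "retained") ft$counts else ft$excluded
  feat_signature(lapply(ft$info$lineage[idx],
                        function(l) triomic::parse_lineage(l)),
                 lapply(seq_len(sum(idx)), function(j) cts[, j]))
}

# random toy OTU table with a 4-level taxonomy (kingdom, phylum, genus,
# species), blanks at the lower ranks to exercise collapse edge cases
random_otu_table <- function(seed, max_otus = 30L, max_samples = 12L) {
  set.seed(seed)
  n_otu <- sample(4:max_otus, 1L)
  n_s <- sample(4:max_samples, 1L)
  lin <- character(n_otu)
  for (j in seq_len(n_otu)) {
    ph <- paste0("p__P", sample(1:3, 1L))
    ge <- if (runif(1) < 0.25) "g__" else paste0("g__G", sample(1:4, 1L))
    sp <- if (runif(1) < 0.5) "s__" else paste0("s__S", sample(1:6, 1L))
    lin[j] <- paste("k__Bacteria", ph, ge, sp, sep = "; ")
  }
  counts <- matrix(rnbinom(n_s * n_otu, mu = 30, size = 0.35), n_s, n_otu)
  counts[, 1L] <- counts[, 1L] + 50L  # keep per-sample totals positive
  dimnames(counts) <- list(paste0("s", seq_len(n_s)), paste0("otu", seq_len(n_otu)))
  list(counts = counts, lineages = stats::setNames(lin, colnames(counts)))
}

# multi-view Gaussian fixture with four planted factors of distinct view
# support (two shared across view pairs, one view-specific, one at noise
# level) at signal-to-noise 5, plus an optional pure-noise binary view
gfa_fixture <- function(seed, n = 250L, d = 40L, binary_noise = FALSE) {
  set.seed(seed)
  Zt <- matrix(rnorm(n * 4L), n)
  supp <- list(v1 = c(1, 0, 1, 0), v2 = c(0, 1, 0, 0.7), v3 = c(1, 1, 0, 0))
  views <- list()
  for (v in names(supp)) {
    W <- matrix(rnorm(4L * d), 4L) * supp[[v]]
    x <- Zt %*% W + matrix(rnorm(n * d, 0, sqrt(sum(supp[[v]]^2) / 5)), n)
    dimnames(x) <- list(paste0("s", seq_len(n)), paste0(v, "_f", seq_len(d)))
    views[[v]] <- x
  }
  if (binary_noise) {
    yb <- matrix(rbinom(n * 12L, 1L, 0.3), n)
    dimnames(yb) <- list(paste0("s", seq_len(n)), paste0("vir", 1:12))
    views$vb <- yb
  }
  list(views = views, Z = Zt)
}

# longitudinal feature matrix for association simulations: 40 subjects x 2
# timepoints, unit-SD features split sigma_b^2 = 0.65 / sigma_e^2 = 0.35,
# optional case-by-time shift (in feature-SD units) on the first n_true
# features
sim_lmm_features <- function(seed, n_sub = 40L, n_feat = 500L, n_true = 0L,
                             delta = 0) {
  set.seed(seed)
  n <- 2L * n_sub
  md <- data.frame(
    subject = rep(seq_len(n_sub), each = 2L),
    case = rep(rep(0:1, each = 2L), length.out = n),
    time = rep(0:1, n_sub),
    age = rep(runif(n_sub, 1, 6), each = 2L) + rep(c(0, 1.4), n_sub),
    hla = rep(rbinom(n_sub, 1L, 0.4), each = 2L))
  b <- matrix(rnorm(n_sub * n_feat, 0, sqrt(0.65)), n_sub)
  y <- b[md$subject, ] + matrix(rnorm(n * n_feat, 0, sqrt(0.35)), n)
  if (n_true > 0L)
    y[, seq_len(n_true)] <- y[, seq_len(n_true)] +
      delta * md$case * md$time
  colnames(y) <- paste0("f", seq_len(n_feat))
  list(y = y, metadata = md, true_idx = seq_len(n_true))
}
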