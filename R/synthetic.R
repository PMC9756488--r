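#' Parameters for the synthetic cohort generator
#'
#' Defaults reproduce the statistical structure of a paediatric islet-
#' autoimmunity case-control study: 20 case-control pairs sampled twice
#' (before and at seroconversion), seroconversion at 3.4 +/- 2.2 years,
#' 1.4 +/- 0.6 years between timepoints, 40% high-risk HLA, and planted
#' effects whose identities are returned as ground truth.
#'
#' @param n_pairs case-control pairs (default 20).
#' @param sero_age_mean,sero_age_sd age at seroconversion, years.
#' @param gap_mean,gap_sd years between the two timepoints.
#' @param seq_depth 16S reads per sample.
#' @param n_otus number of OTUs in the community pool.
#' @param n_proteins total protein groups (human + microbial).
#' @param n_human human protein groups (subset of `n_proteins`).
#' @param n_ig immunoglobulin variable-region groups (subset of human).
#' @param n_virus_genera virus genera in the virome table.
#' @param interaction_features size of the planted case-by-time cluster of
#'   Faecalibacterium-labelled ABC-transport proteins (default 20).
#' @param interaction_effect planted case-by-time shift in units of feature
#'   SD (default 1).
#' @param mastadeno_features number of proteins shifted in
#'   mastadenovirus-positive samples (default 28).
#' @param mastadeno_effect magnitude of those shifts in feature SDs.
#' @param missing_view_fraction fraction of samples to strip of one data
#'   type with [mask_views()] (default 0 here; masking is a separate op).
#' @param seed integer seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_pairs = 20L,
                          sero_age_mean = 3.4, sero_age_sd = 2.2,
                          gap_mean = 1.4, gap_sd = 0.6,
                          seq_depth = 10000L,
                          n_otus = 250L, n_proteins = 400L, n_human = 60L,
                          n_ig = 25L, n_virus_genera = 12L,
                          interaction_features = 20L, interaction_effect = 1,
                          mastadeno_features = 28L, mastadeno_effect = 0.8,
                          missing_view_fraction = 0, seed = 1L) {
  p <- as.list(environment())
  counts <- c("n_pairs", "seq_depth", "n_otus", "n_proteins", "n_human",
              "n_ig", "n_virus_genera")
  if (any(unlist(p[counts]) <= 0)) stop("all counts must be > 0")
  if (p$n_human >= p$n_proteins) stop("n_human must be < n_proteins")
  if (p$n_ig >= p$n_human) stop("n_ig must be < n_human")
  if (p$sero_age_sd < 0 || p$gap_sd < 0) stop("sd must be >= 0")
  if (p$missing_view_fraction < 0 || p$missing_view_fraction >= 1)
    stop("missing_view_fraction must be in [0, 1)")
  if (p$interaction_features > p$n_proteins - p$n_human ||
      p$mastadeno_features > p$n_proteins - p$n_human)
    stop("planted feature counts exceed the microbial protein pool")
  structure(p, class = "cohort_params")
}

rtnorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  x
}

# gut maturity: saturating in age, the shared latent coupling OTU richness
# and microbial protein detection
.maturity <- function(age) 1 - exp(-age / 1.5)

GENUS_POOL <- c("g__Faecalibacterium", "g__Bacteroides", "g__Blautia",
                "g__Dorea", "g__Ruminococcus", "g__Roseburia", "g__Sharpea",
                "g__Prevotella", "g__Bifidobacterium", "g__Clostridium",
                "g__Akkermansia", "g__Subdoligranulum", "g__Eubacterium",
                "g__Lachnospira", "g__Veillonella", "g__Streptococcus")

# random Greengenes-style taxonomy: ~6 phyla, lineages sometimes truncated
# at genus/species to exercise amalgamation edge cases
.random_taxonomy <- function(n_otus) {
  phyla <- c("p__Firmicutes", "p__Bacteroidetes", "p__Actinobacteria",
             "p__Proteobacteria", "p__Verrucomicrobia", "p__Fusobacteria")
  lineages <- character(n_otus)
  for (i in seq_len(n_otus)) {
    ph <- sample(phyla, 1L, prob = c(0.45, 0.25, 0.1, 0.1, 0.05, 0.05))
    cl <- paste0("c__", sub("p__", "", ph), "ia_", sample(1:2, 1L))
    or <- paste0("o__", sub("c__", "", cl), "les")
    fa <- paste0("f__", sub("p__", "", ph), "aceae_", sample(1:3, 1L))
    ge <- if (stats::runif(1) < 0.15) "g__" else sample(GENUS_POOL, 1L)
    sp <- if (stats::runif(1) < 0.45) "s__" else paste0("s__sp", sample(1:40, 1L))
    lineages[i] <- paste(c("k__Bacteria", ph, cl, or, fa, ge, sp), collapse = "; ")
  }
  lineages
}

#' Generate a complete synthetic cohort
#'
#' Emulates the study conditions every downstream stage is tested against:
#' age-increasing OTU richness and microbial protein detection (coupled
#' through a shared gut-maturity latent), age-declining immunoglobulin
#' variable-region counts and intensity, intensity-dependent (MNAR)
#' missingness, a planted case-by-time interaction on a correlated cluster
#' of Faecalibacterium-labelled ABC-transport proteins, protein shifts in
#' mastadenovirus-positive samples, and enterovirus positivity skewed
#' toward younger ages.  All planted identities and magnitudes are
#' returned in `truth`.
#'
#' @param params a [cohort_params()] object.
#' @return list: `metadata` (data.frame), `otu` ([as_otu_table()]),
#'   `protein` ([as_protein_table()]), `virome` (list `counts`,
#'   `genus_map`), `truth` (planted structure).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(params$seed) %% .Machine$integer.max)
  np <- params$n_pairs
  n <- 4L * np  # 2 subjects per pair x 2 timepoints

  ## ---- metadata ----------------------------------------------------------
  sero <- rtnorm(np, params$sero_age_mean, params$sero_age_sd, lower = 0.6)
  gap <- rtnorm(np, params$gap_mean, params$gap_sd, lower = 0.3)
  pre <- pmax(sero - gap, 0.15)
  sex <- stats::rbinom(np, 1L, 0.5)
  hla <- stats::rbinom(np, 1L, 0.4)  # 40% high-risk HLA
  jit <- stats::runif(np, -0.4, 0.4)
  metadata <- data.frame(
    sample = paste0(rep(c("case", "con"), each = 2L * np),
                    rep(rep(seq_len(np), each = 2L), 2L),
                    rep(c("_pre", "_post"), 2L * np)),
    subject = paste0(rep(c("case", "con"), each = 2L * np),
                     rep(rep(seq_len(np), each = 2L), 2L)),
    pair = rep(rep(seq_len(np), each = 2L), 2L),
    case = rep(c(1L, 0L), each = 2L * np),
    time = rep(c(0L, 1L), 2L * np),
    age = c(rbind(pre, sero), rbind(pmax(pre + jit, 0.15), sero + jit)),
    hla = rep(rep(hla, each = 2L), 2L),
    sex = rep(rep(sex, each = 2L), 2L),
    stringsAsFactors = FALSE)
  rownames(metadata) <- metadata$sample
  mat <- .maturity(metadata$age) +
    rep(stats::rnorm(2L * np, 0, 0.08), each = 2L) + stats::rnorm(n, 0, 0.04)

  # latent axes of co-variation beyond age: two community gradients
  # (enterotype-like, coupling OTU abundances with microbial proteins), a
  # host immune axis (human proteins incl. immunoglobulins), and a
  # microbial metabolic axis; subject-correlated across timepoints
  n_lf <- 4L
  lf_subj <- matrix(stats::rnorm(2L * np * n_lf, 0, 0.7), ncol = n_lf)
  lf_samp <- lf_subj[rep(seq_len(2L * np), each = 2L), ] +
    matrix(stats::rnorm(n * n_lf, 0, 0.7), n)

  ## ---- OTU table ---------------------------------------------------------
  n_otus <- params$n_otus
  lineages <- .random_taxonomy(n_otus)
  otu_ids <- paste0("otu", sprintf("%04d", seq_len(n_otus)))
  # occupancy rises with maturity; calibrated so observed richness matches
  # ~90 OTUs in the first year of life vs ~174 later at the default depth
  a_j <- stats::rnorm(n_otus, 0.45, 1.3)
  b_age <- 3.6
  mu_j <- stats::rnorm(n_otus, 0, 1.2)
  counts <- matrix(0L, n, n_otus, dimnames = list(metadata$sample, otu_ids))
  subj_idx <- match(metadata$subject, unique(metadata$subject))
  subj_pref <- matrix(stats::rnorm(length(unique(metadata$subject)) * n_otus, 0, 0.8),
                      ncol = n_otus)
  otu_load <- matrix(0, n_otus, n_lf)
  for (f in 1:2) {
    sel <- sample.int(n_otus, round(0.4 * n_otus))
    otu_load[sel, f] <- stats::rnorm(length(sel), 0, 0.8)
  }
  for (i in seq_len(n)) {
    pres <- stats::rbinom(n_otus, 1L, stats::plogis(a_j + b_age * (mat[i] - 0.55)))
    lam <- exp(mu_j + subj_pref[subj_idx[i], ] +
                 drop(otu_load %*% lf_samp[i, ]) +
                 stats::rnorm(n_otus, 0, 0.5)) * pres
    if (sum(lam) == 0) lam[sample.int(n_otus, 1L)] <- 1
    counts[i, ] <- stats::rmultinom(1L, params$seq_depth, lam)[, 1L]
  }
  otu <- as_otu_table(counts, stats::setNames(lineages, otu_ids))

  ## ---- virome ------------------------------------------------------------
  nv <- params$n_virus_genera
  core <- c("Mastadenovirus", "Enterovirus", "Norovirus", "Parechovirus")
  genera <- c(core, paste0("Othervirus", seq_len(max(nv - 4L, 0L))))[seq_len(max(nv, 4L))]
  genus_map <- stats::setNames(c("mastadenovirus", "enterovirus", "norovirus",
                                 "parechovirus",
                                 rep("other", length(genera) - 4L)), genera)
  ent_logit <- c(intercept = 0.8, age = -0.55)  # positivity skewed young
  p_pos <- cbind(
    Mastadenovirus = rep(0.22, n),
    Enterovirus = stats::plogis(ent_logit[1L] + ent_logit[2L] * metadata$age),
    Norovirus = rep(0.04, n), Parechovirus = rep(0.04, n))
  if (length(genera) > 4L)
    p_pos <- cbind(p_pos, matrix(0.05, n, length(genera) - 4L,
                                 dimnames = list(NULL, genera[-(1:4)])))
  vir_counts <- matrix(0L, n, length(genera),
                       dimnames = list(metadata$sample, genera))
  for (g in seq_along(genera)) {
    pos <- stats::rbinom(n, 1L, p_pos[, g]) == 1L
    vir_counts[pos, g] <- 101L + stats::rnbinom(sum(pos), mu = 2000, size = 1)
    neg_reads <- stats::rbinom(sum(!pos), 1L, 0.15) *
      sample.int(80L, sum(!pos), replace = TRUE)
    vir_counts[!pos, g] <- neg_reads
  }
  masta_pos <- vir_counts[, "Mastadenovirus"] > 100L

  ## ---- proteins ----------------------------------------------------------
  n_prot <- params$n_proteins; n_hum <- params$n_human; n_ig <- params$n_ig
  n_mic <- n_prot - n_hum
  prot_ids <- c(paste0("HUM", sprintf("%04d", seq_len(n_hum))),
                paste0("MIC", sprintf("%04d", seq_len(n_mic))))
  origin <- rep(c("human", "microbial"), c(n_hum, n_mic))
  ig_variable <- c(rep(c(TRUE, FALSE), c(n_ig, n_hum - n_ig)), rep(FALSE, n_mic))
  ig_constant <- c(rep(FALSE, n_ig), rep(c(TRUE, FALSE), c(3L, n_hum - n_ig - 3L)),
                   rep(FALSE, n_mic))
  genus <- c(rep("human", n_hum),
             sample(c(sub("g__", "", GENUS_POOL), "unknown"), n_mic, replace = TRUE))
  cog_pool <- paste0("COG", sprintf("%04d", sample.int(3000L, 120L)))
  cog <- c(rep(NA_character_, n_hum),
           sample(c(cog_pool, NA_character_), n_mic, replace = TRUE,
                  prob = c(rep(0.95 / 120, 120), 0.05)))
  cog_category <- ifelse(is.na(cog), NA_character_,
                         paste0("cat_", substr(cog, 5L, 5L)))
  # planted clusters live in the microbial pool
  mic_idx <- which(origin == "microbial")
  inter_idx <- mic_idx[seq_len(params$interaction_features)]
  mast_idx <- mic_idx[params$interaction_features +
                        seq_len(params$mastadeno_features)]
  genus[inter_idx] <- "Faecalibacterium"
  cog[inter_idx] <- paste0("COG", sprintf("%04d", 4000L + seq_along(inter_idx) %% 4L))
  cog_category[inter_idx] <- "ABC-type transport"
  mast_sign <- rep(c(-1, 1), c(20L, 8L))[seq_along(mast_idx)]

  # log-intensity model
  base_j <- stats::rnorm(n_prot, 14, 1.5)
  slope_j <- numeric(n_prot)
  slope_j[origin == "microbial"] <- rtnorm(n_mic, 1.6, 0.5, lower = 0.2)
  igv_slope <- -0.45
  slope_age <- numeric(n_prot)
  slope_age[ig_variable] <- igv_slope
  sd_b <- 0.55; sd_e <- 0.45; clust_load <- stats::runif(length(inter_idx), 1.0, 1.4)
  sd_feat <- sqrt(sd_b^2 + sd_e^2)
  subj_eff <- matrix(stats::rnorm(length(unique(metadata$subject)) * n_prot, 0, sd_b),
                     ncol = n_prot)
  h_subj <- stats::rnorm(length(unique(metadata$subject)), 0, 0.7)
  h_samp <- h_subj[subj_idx] + stats::rnorm(n, 0, 0.7)  # planted-cluster latent
  prot_load <- matrix(0, n_prot, n_lf)
  for (f in 1:2) {   # community gradients echo in the microbial proteome
    sel <- mic_idx[sample.int(n_mic, round(0.25 * n_mic))]
    prot_load[sel, f] <- stats::rnorm(length(sel), 0, 0.5)
  }
  hum_idx <- which(origin == "human")
  prot_load[hum_idx, 3L] <- stats::rnorm(n_hum, 0, 0.5)   # host immune axis
  sel4 <- mic_idx[sample.int(n_mic, round(0.3 * n_mic))]
  prot_load[sel4, 4L] <- stats::rnorm(length(sel4), 0, 0.5)
  V <- matrix(base_j, n, n_prot, byrow = TRUE) +
    outer(mat, slope_j) + outer(metadata$age, slope_age) +
    lf_samp %*% t(prot_load) +
    subj_eff[subj_idx, ] + matrix(stats::rnorm(n * n_prot, 0, sd_e), n)
  sd_clust <- sqrt(sd_b^2 + sd_e^2 + clust_load^2)
  V[, inter_idx] <- V[, inter_idx] + outer(h_samp, clust_load) +
    (params$interaction_effect * (metadata$case * metadata$time)) %o% sd_clust
  V[, mast_idx] <- V[, mast_idx] +
    (params$mastadeno_effect * as.numeric(masta_pos)) %o% (mast_sign * sd_feat)

  # MNAR missingness: decreasing logistic in latent log-intensity, steeper
  # at low intensity; human proteins mostly observed
  v0 <- stats::quantile(V, 0.3)
  p_miss <- stats::plogis(-(V - v0) / 0.9)
  p_miss[, origin == "human" & !ig_variable] <- p_miss[, origin == "human" & !ig_variable] * 0.4
  miss <- matrix(stats::rbinom(n * n_prot, 1L, p_miss), n) == 1L
  intens <- exp(V)
  intens[miss] <- NA
  # guarantee every group observed somewhere (pre-filter tables need it)
  empty <- colSums(!is.na(intens)) == 0L
  if (any(empty)) intens[1L, empty] <- exp(V[1L, empty])
  dimnames(intens) <- list(metadata$sample, prot_ids)
  annotations <- data.frame(
    group = prot_ids, origin = origin, genus = genus, cog = cog,
    cog_category = cog_category, lead_protein = paste0(prot_ids, "_lead"),
    ig_variable = ig_variable, ig_constant = ig_constant,
    stringsAsFactors = FALSE)
  protein <- as_protein_table(intens, annotations)

  truth <- list(
    interaction_features = prot_ids[inter_idx],
    interaction_effect = params$interaction_effect,
    mastadeno_features = prot_ids[mast_idx],
    mastadeno_effect = params$mastadeno_effect,
    mastadeno_signs = stats::setNames(mast_sign, prot_ids[mast_idx]),
    cluster_scores = h_samp +
      params$interaction_effect * metadata$case * metadata$time,
    igv_features = prot_ids[ig_variable],
    igv_age_slope = igv_slope,
    maturity_slopes = stats::setNames(slope_j, prot_ids),
    enterovirus_age_logit = ent_logit,
    latent_axes = list(n = n_lf, scores = lf_samp,
                       otu_loadings = otu_load, protein_loadings = prot_load),
    richness_curve = list(target_under1 = 90, target_over1 = 174,
                          occupancy_intercepts = a_j, maturity_slope = b_age),
    variance_components = c(sd_subject = sd_b, sd_resid = sd_e))
  list(metadata = metadata, otu = otu, protein = protein,
       virome = list(counts = vir_counts, genus_map = genus_map),
       truth = truth)
}

#' Strip whole samples of one data type
#'
#' Emulates cohorts where some samples lack one omic: a fraction of samples
#' is chosen and each loses exactly one randomly chosen view (OTU, protein
#' or virome); the affected rows are set to `NA`.  Every sample always
#' keeps at least its remaining views.
#'
#' @param cohort output of [generate_cohort()].
#' @param missing_view_fraction fraction of samples to mask, in `[0, 1)`.
#' @param seed integer seed.
#' @return the cohort with masked rows; attribute `masked` records
#'   (sample, view) pairs.
#' @export
mask_views <- function(cohort, missing_view_fraction, seed = 1L) {
  if (missing_view_fraction < 0 || missing_view_fraction >= 1)
    stop("missing_view_fraction must be in [0, 1)")
  if (missing_view_fraction == 0) {
    attr(cohort, "masked") <- data.frame(sample = character(), view = character())
    return(cohort)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  samples <- cohort$metadata$sample
  k <- round(missing_view_fraction * length(samples))
  hit <- sample(samples, k)
  view <- sample(c("otu", "protein", "virome"), k, replace = TRUE)
  for (i in seq_along(hit)) {
    s <- hit[i]
    switch(view[i],
           otu = {cohort$otu$counts[s, ] <- NA},
           protein = {cohort$protein$intensities[s, ] <- NA},
           virome = {cohort$virome$counts[s, ] <- NA})
  }
  attr(cohort, "masked") <- data.frame(sample = hit, view = view,
                                       stringsAsFactors = FALSE)
  cohort
}
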