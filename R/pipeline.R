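#' Write a synthetic cohort to the pipeline's on-disk formats
#'
#' TSV tables (features as columns, samples as rows for metadata-aligned
#' matrices; OTU counts written features-as-rows per the 16S convention)
#' plus a ground-truth JSON.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wt <- function(x, f, row_label) {
    df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- row_label
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(t(cohort$otu$counts), "otu_counts.tsv", "otu_id")
  utils::write.table(
    data.frame(otu_id = names(cohort$otu$lineages),
               lineage = unname(cohort$otu$lineages)),
    p("taxonomy.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$protein$intensities, "protein_intensities.tsv", "sample")
  utils::write.table(cohort$protein$annotations, p("protein_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$virome$counts, "virome_counts.tsv", "sample")
  utils::write.table(
    data.frame(genus = names(cohort$virome$genus_map),
               group = unname(cohort$virome$genus_map)),
    p("genus_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$metadata, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a cohort from the on-disk formats written by [write_cohort()]
#'
#' @param dir directory containing the TSVs.
#' @return a cohort list (`metadata`, `otu`, `protein`, `virome`, `truth`
#'   when present).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  rt <- function(f) utils::read.table(p(f), sep = "\t", header = TRUE,
                                      check.names = FALSE, stringsAsFactors = FALSE)
  oc <- rt("otu_counts.tsv")
  counts <- t(as.matrix(oc[, -1L, drop = FALSE]))
  colnames(counts) <- oc[[1L]]
  tax <- rt("taxonomy.tsv")
  otu <- as_otu_table(counts, stats::setNames(tax$lineage, tax$otu_id))
  pi_ <- rt("protein_intensities.tsv")
  intens <- as.matrix(pi_[, -1L, drop = FALSE]); rownames(intens) <- pi_[[1L]]
  ann <- rt("protein_annotations.tsv")
  protein <- as_protein_table(intens, ann)
  vc <- rt("virome_counts.tsv")
  vir <- as.matrix(vc[, -1L, drop = FALSE]); rownames(vir) <- vc[[1L]]
  gm <- rt("genus_map.tsv")
  metadata <- rt("metadata.tsv")
  rownames(metadata) <- metadata$sample
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  list(metadata = metadata, otu = otu, protein = protein,
       virome = list(counts = vir, genus_map = stats::setNames(gm$group, gm$genus)),
       truth = truth)
}

#' Run the full multi-omic integration pipeline
#'
#' Ties the stages together: 16S QC and taxonomy-guided amalgamation,
#' arcsin-sqrt transform; protein prevalence filter, variance-stabilizing
#' normalization and BPCA imputation; COG aggregation (with its own
#' normalization pass); virome detection categories; optional cubic-spline
#' age deflation of every view (analysis model 2); multi-view group factor
#' analysis; factor selection; and mixed-model association scans of OTUs,
#' proteins and factor scores (base case/time/interaction terms plus
#' separate virus-indicator models).  Deterministic given `seed`.
#'
#' @param cohort a cohort list as returned by [generate_cohort()] or
#'   [read_cohort()] (possibly after [mask_views()]).
#' @param model 1 = raw views; 2 = age-deflated views (default 2).
#' @param seed integer seed for the stochastic stages (BPCA init, GFA init).
#' @param out_dir optional output directory; when given, result tables and
#'   a run manifest are written there.
#' @param qc_min_reads,exclude_taxa,abund_thresh,prev_thresh,n_iter 16S
#'   stage parameters (see [qc_filter()], [amalgamate()]).
#' @param protein_min_frac detection-prevalence threshold (see
#'   [prevalence_filter()]).
#' @param spline_df age-deflation spline degrees of freedom.
#' @param K_init,r2_min factor-model parameters (see [fit_gfa()],
#'   [select_factors()]).
#' @param virome_view include the virome presence/absence matrix as a
#'   Bernoulli view in the factor model (default `FALSE`; the detection
#'   categories always enter the association models as covariates).
#' @param virus_min_reads virome detection threshold.
#' @return list of class `triomic_run`: processed tables, `factor_model`,
#'   `selected_factors`, association tables (`assoc_otu`, `assoc_protein`,
#'   `assoc_factors`), `virome_status`, `manifest`.
#' @export
run_pipeline <- function(cohort, model = 2L, seed = 1L, out_dir = NULL,
                         qc_min_reads = 100L, exclude_taxa = character(),
                         abund_thresh = 0.001, prev_thresh = 0.15, n_iter = 3L,
                         protein_min_frac = 0.5, spline_df = 4L,
                         K_init = 15L, r2_min = 0.05, virome_view = FALSE,
                         virus_min_reads = 100L) {
  if (!model %in% c(1L, 2L)) stop("model must be 1 (raw) or 2 (age-deflated)")
  md <- cohort$metadata
  all_samples <- md$sample

  ## ---- 16S ---------------------------------------------------------------
  otu_obs <- rowSums(!is.na(cohort$otu$counts)) > 0L
  otu_in <- as_otu_table(cohort$otu$counts[otu_obs, , drop = FALSE],
                         cohort$otu$lineages)
  otu_qc <- qc_filter(otu_in, min_reads = qc_min_reads, exclude_taxa = exclude_taxa)
  feat <- amalgamate(otu_qc, abund_thresh = abund_thresh,
                     prev_thresh = prev_thresh, n_iter = n_iter)
  abund <- arcsin_sqrt_tss(feat$counts)
  diversity <- data.frame(
    sample = rownames(otu_qc$counts),
    richness = apply(otu_qc$counts, 1L, observed_richness),
    shannon = apply(otu_qc$counts, 1L, shannon),
    row.names = NULL, stringsAsFactors = FALSE)

  ## ---- metaproteome ------------------------------------------------------
  prot_obs <- rowSums(!is.na(cohort$protein$intensities)) > 0L
  prot_in <- as_protein_table(
    cohort$protein$intensities[prot_obs, , drop = FALSE],
    cohort$protein$annotations, zero_is_missing = FALSE)
  prot_filt <- prevalence_filter(prot_in, min_frac = protein_min_frac)
  vsn <- vsn_normalize(prot_filt$intensities)
  prot_norm <- bpca_impute(vsn$h, seed = seed, max_iter = 1000L)
  summaries <- sample_summaries(prot_in)
  cogs <- cog_aggregate(prot_in)
  cogs_use <- cogs[, colMeans(cogs > 0) >= protein_min_frac, drop = FALSE]
  cog_norm <- NULL
  if (ncol(cogs_use) >= 2L) {
    cv <- cogs_use; cv[cv == 0] <- NA
    cog_vsn <- vsn_normalize(cv)
    cog_norm <- bpca_impute(cog_vsn$h, seed = seed + 1L, max_iter = 1000L)
  }

  ## ---- virome ------------------------------------------------------------
  vir_obs <- rowSums(!is.na(cohort$virome$counts)) > 0L
  vstat <- derive_status(cohort$virome$counts[vir_obs, , drop = FALSE],
                         cohort$virome$genus_map,
                         md$subject[match(rownames(cohort$virome$counts)[vir_obs],
                                          md$sample)],
                         min_reads = virus_min_reads)

  ## ---- views (aligned to the full sample list, NA rows = missing) --------
  expand <- function(x) {
    full <- matrix(NA_real_, length(all_samples), ncol(x),
                   dimnames = list(all_samples, colnames(x)))
    full[rownames(x), ] <- x
    full
  }
  ann <- prot_filt$annotations
  views <- list(
    microbial_abundance = expand(abund),
    microbial_protein = expand(prot_norm[, ann$origin != "human", drop = FALSE]),
    human_protein = expand(prot_norm[, ann$origin == "human", drop = FALSE]))
  if (virome_view) {
    pres <- matrix(as.numeric(detect(cohort$virome$counts[vir_obs, , drop = FALSE],
                                     virus_min_reads)),
                   sum(vir_obs), dimnames = list(rownames(cohort$virome$counts)[vir_obs],
                                                 colnames(cohort$virome$counts)))
    views$virome <- expand(pres)
  }
  if (model == 2L) {
    for (v in names(views)) {
      if (v == "virome") next  # presence/absence is not age-deflated
      o <- rowSums(!is.na(views[[v]])) > 0L
      ages <- md$age[match(all_samples[o], md$sample)]
      views[[v]][o, ] <- deflate_age(views[[v]][o, , drop = FALSE], ages,
                                     df = spline_df)
    }
  }

  ## ---- factor model ------------------------------------------------------
  fm <- fit_gfa(views, K_init = K_init, seed = seed,
                binary = if (virome_view) "virome" else character())
  selected <- select_factors(fm, r2_min = r2_min)

  ## ---- associations ------------------------------------------------------
  vir_cov <- vstat$samples[match(all_samples, vstat$samples$sample),
                           c("any_virus", "any_enterovirus", "any_mastadenovirus")]
  subj_cov <- vstat$subjects[match(md$subject, vstat$subjects$subject),
                             c("any_virus", "any_enterovirus", "any_mastadenovirus")]
  names(subj_cov) <- paste0("subject_", names(subj_cov))
  meta_full <- cbind(md, vir_cov, subj_cov)
  assoc_on <- function(x) {
    o <- rownames(x)[rowSums(!is.na(x)) > 0L]
    mrows <- meta_full[match(o, meta_full$sample), ]
    ok <- stats::complete.cases(mrows[, c("any_virus", "any_enterovirus",
                                          "any_mastadenovirus")])
    associate_features(x[o, , drop = FALSE][ok, , drop = FALSE], mrows[ok, ],
                       virus = c("any_virus", "any_enterovirus",
                                 "any_mastadenovirus"))
  }
  assoc_otu <- assoc_on(expand(abund))
  assoc_protein <- assoc_on(expand(prot_norm))
  scores <- fm$Z[, selected, drop = FALSE]
  assoc_factors <- if (ncol(scores) > 0L) {
    mrows <- meta_full[match(rownames(scores), meta_full$sample), ]
    ok <- stats::complete.cases(mrows[, c("any_virus", "any_enterovirus",
                                          "any_mastadenovirus")])
    associate_features(scores[ok, , drop = FALSE], mrows[ok, ],
                       virus = c("any_virus", "any_enterovirus",
                                 "any_mastadenovirus"))
  } else NULL

  manifest <- list(package_version = as.character(utils::packageVersion("triomic")),
                   model = model, seed = seed,
                   parameters = list(qc_min_reads = qc_min_reads,
                                     exclude_taxa = exclude_taxa,
                                     abund_thresh = abund_thresh,
                                     prev_thresh = prev_thresh, n_iter = n_iter,
                                     protein_min_frac = protein_min_frac,
                                     spline_df = spline_df, K_init = K_init,
                                     r2_min = r2_min, virome_view = virome_view,
                                     virus_min_reads = virus_min_reads),
                   n_samples = length(all_samples),
                   n_features = list(otu_retained = ncol(feat$counts),
                                     protein_retained = ncol(prot_norm),
                                     cog = ncol(cogs)))
  out <- structure(list(
    feature_table = feat, abundance = abund, diversity = diversity,
    protein_normalized = prot_norm, protein_summaries = summaries,
    cog_matrix = cogs, cog_normalized = cog_norm,
    virome_status = vstat, views = views, factor_model = fm,
    selected_factors = selected, assoc_otu = assoc_otu,
    assoc_protein = assoc_protein, assoc_factors = assoc_factors,
    manifest = manifest), class = "triomic_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write the tables of a pipeline run
#'
#' @param run a `triomic_run` object.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wm <- function(x, f) {
    df <- data.frame(sample = rownames(x), x, check.names = FALSE)
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$feature_table$info, p("feature_provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wm(run$abundance, "abundance_arcsin.tsv")
  utils::write.table(run$diversity, p("diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wm(run$protein_normalized, "protein_normalized.tsv")
  utils::write.table(run$protein_summaries, p("protein_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$virome_status$samples, p("virome_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wm(run$factor_model$Z, "factor_scores.tsv")
  for (v in names(run$factor_model$W)) {
    w <- run$factor_model$W[[v]]
    df <- data.frame(feature = rownames(w), w, check.names = FALSE)
    utils::write.table(df, p(paste0("weights_", v, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (a in c("assoc_otu", "assoc_protein", "assoc_factors"))
    if (!is.null(run[[a]]))
      utils::write.table(run[[a]], p(paste0(a, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list.files(dir, full.names = TRUE))
}

#' triomic: multi-omic integration for longitudinal gut cohorts
#'
#' See [run_pipeline()] for the end-to-end entry point and the package
#' vignette for the underlying models.
#' @keywords internal
"_PACKAGE"
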