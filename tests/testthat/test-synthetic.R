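small_params <- function(seed, ...) {
  cohort_params(n_pairs = 8L, n_otus = 80L, n_proteins = 120L, n_human = 30L,
                n_ig = 12L, seq_depth = 4000L, seed = seed, ...)
}

test_that("the generator is deterministic in its seed", {
  a <- generate_cohort(small_params(1))
  b <- generate_cohort(small_params(1))
  expect_identical(a$otu$counts, b$otu$counts)
  expect_identical(a$protein$intensities, b$protein$intensities)
  expect_identical(a$virome$counts, b$virome$counts)
  c_ <- generate_cohort(small_params(2))
  expect_false(identical(a$otu$counts, c_$otu$counts))
})

test_that("parameter validation rejects impossible cohorts", {
  expect_error(cohort_params(n_pairs = 0), "> 0")
  expect_error(cohort_params(n_ig = 100, n_human = 60), "n_ig")
  expect_error(cohort_params(missing_view_fraction = 1), "missing_view_fraction")
  expect_error(cohort_params(interaction_features = 1000), "planted")
})

test_that("cohort structure matches the study design it emulates", {
  co <- generate_cohort(cohort_params(seed = 4))
  md <- co$metadata
  expect_equal(nrow(md), 80L)               # 20 pairs x 2 subjects x 2 timepoints
  expect_equal(sum(md$case == 1), 40L)
  # matched pairs share sex, HLA and age to half a year
  for (p in 1:5) {
    pr <- md[md$pair == p, ]
    expect_equal(length(unique(pr$hla[pr$time == 0])), 1L)
    expect_lt(abs(diff(pr$age[pr$time == 0])), 0.5 + 1e-9)
  }
  # counts are nonnegative integers; intensities nonnegative or missing
  expect_true(all(co$otu$counts >= 0))
  expect_true(all(co$otu$counts == round(co$otu$counts)))
  expect_true(all(co$protein$intensities >= 0, na.rm = TRUE))
  # planted ids exist among the generated features
  expect_true(all(co$truth$interaction_features %in%
                    colnames(co$protein$intensities)))
  ann <- co$protein$annotations
  planted <- ann[ann$group %in% co$truth$interaction_features, ]
  expect_true(all(planted$genus == "Faecalibacterium"))
  expect_true(all(planted$cog_category == "ABC-type transport"))
})

test_that("richness increases with age in line with the first-year contrast", {
  young <- old <- c()
  for (s in 1:10) {
    co <- generate_cohort(cohort_params(seed = s))
    rich <- apply(co$otu$counts, 1L, observed_richness)
    young <- c(young, rich[co$metadata$age < 1])
    old <- c(old, rich[co$metadata$age >= 1])
  }
  tt <- t.test(young, old, alternative = "less")
  expect_lt(tt$p.value, 0.05)
  # and the absolute levels sit near the published first-year contrast
  expect_gt(mean(young), 60); expect_lt(mean(young), 120)
  expect_gt(mean(old), 140); expect_lt(mean(old), 210)
})

test_that("immunoglobulin variable regions decline with age while microbial detections rise", {
  co <- generate_cohort(cohort_params(seed = 6))
  ss <- sample_summaries(co$protein)
  expect_lt(cor(ss$n_igv, co$metadata$age), -0.3)
  expect_gt(cor(ss$n_microbial, co$metadata$age), 0.3)
  # missingness is intensity-dependent: observed intensities exceed the
  # overall latent mean where missingness is high
  expect_gt(cor(ss$igv_fraction, -co$metadata$age), 0.2)
})

test_that("enterovirus positivity is skewed toward younger ages", {
  ages_pos <- ages_neg <- c()
  for (s in 1:6) {
    co <- generate_cohort(cohort_params(seed = s))
    pos <- co$virome$counts[, "Enterovirus"] > 100
    ages_pos <- c(ages_pos, co$metadata$age[pos])
    ages_neg <- c(ages_neg, co$metadata$age[!pos])
  }
  expect_lt(t.test(ages_pos, ages_neg, alternative = "less")$p.value, 0.01)
})

test_that("the planted case-by-time contrast matches its nominal magnitude", {
  # standardized difference-in-differences across planted features, against
  # the generator's per-feature SDs; Monte-Carlo over 50 small cohorts
  did <- function(co) {
    lv <- log(co$protein$intensities[, co$truth$interaction_features])
    md <- co$metadata
    dd <- colMeans(lv[md$case == 1 & md$time == 1, ], na.rm = TRUE) -
      colMeans(lv[md$case == 1 & md$time == 0, ], na.rm = TRUE) -
      (colMeans(lv[md$case == 0 & md$time == 1, ], na.rm = TRUE) -
         colMeans(lv[md$case == 0 & md$time == 0, ], na.rm = TRUE))
    std <- dd / apply(lv, 2, sd, na.rm = TRUE)
    mean(std[is.finite(std)])
  }
  contrasts <- vapply(1:50, function(s)
    did(generate_cohort(small_params(s, interaction_effect = 1))), numeric(1))
  se <- sd(contrasts) / sqrt(length(contrasts))
  expect_lt(abs(mean(contrasts) - 1), 2 * se + 0.15)
  # and a null cohort shows no contrast
  null_c <- vapply(1:12, function(s)
    did(generate_cohort(small_params(s + 500, interaction_effect = 0))),
    numeric(1))
  expect_lt(abs(mean(null_c)), 3 * sd(null_c) / sqrt(length(null_c)) + 0.1)
})

test_that("mask_views removes exactly one view per chosen sample and records it", {
  co <- generate_cohort(small_params(3))
  same <- mask_views(co, 0)
  expect_identical(same$otu$counts, co$otu$counts)
  masked <- mask_views(co, 0.25, seed = 2)
  log <- attr(masked, "masked")
  expect_equal(nrow(log), round(0.25 * nrow(co$metadata)))
  for (i in seq_len(nrow(log))) {
    s <- log$sample[i]
    nas <- c(otu = all(is.na(masked$otu$counts[s, ])),
             protein = all(is.na(masked$protein$intensities[s, ])),
             virome = all(is.na(masked$virome$counts[s, ])))
    expect_equal(sum(nas), 1L)          # exactly one view lost
    expect_equal(names(which(nas)), log$view[i])
  }
  expect_error(mask_views(co, 1), "missing_view_fraction")
})

test_that("cohorts round-trip through the on-disk TSV formats", {
  co <- generate_cohort(small_params(9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$otu$counts, co$otu$counts)
  expect_equal(back$protein$intensities, co$protein$intensities)
  expect_equal(back$virome$counts, co$virome$counts)
  expect_equal(back$metadata$age, co$metadata$age)
  expect_equal(back$truth$interaction_features, co$truth$interaction_features)
})
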