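#' Virus detection call from read counts
#'
#' A virus is considered detected in a sample when it attracts strictly more
#' than `min_reads` reads.
#'
#' @param read_count nonnegative integer (vectorized).
#' @param min_reads detection threshold (default 100).
#' @return logical of the same length as `read_count`.
#' @export
detect <- function(read_count, min_reads = 100L) {
  if (any(read_count < 0)) stop("read counts must be nonnegative")
  read_count > min_reads
}

#' Sample- and subject-level virus detection categories
#'
#' Converts a samples x virus-genus read-count table into the binary
#' covariates used by the association models: detection of any virus, any
#' enterovirus and any mastadenovirus, at the sample level and (by OR over a
#' subject's samples) at the subject level, plus the 8-way combination label
#' of the three sample-level flags.
#'
#' @param counts samples x virus-genera nonnegative integer matrix.
#' @param genus_map named character vector mapping every genus (column) to a
#'   group: `"enterovirus"`, `"mastadenovirus"`, `"norovirus"`,
#'   `"parechovirus"` or `"other"`.
#' @param subject per-sample subject ids (same order as rows).
#' @param min_reads detection threshold passed to [detect()].
#' @return list of class `virome_status`: `samples` (data.frame of per-sample
#'   flags + `combo` label), `subjects` (per-subject flags).
#' @export
derive_status <- function(counts, genus_map, subject, min_reads = 100L) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% names(genus_map)))
    stop("unmapped virus genus: ",
         paste(setdiff(colnames(counts), names(genus_map)), collapse = ", "))
  if (length(subject) != nrow(counts))
    stop("one subject id required per sample")
  grp <- genus_map[colnames(counts)]
  det <- detect(counts, min_reads)
  dim(det) <- dim(counts)
  any_virus <- rowSums(det) > 0
  any_entero <- rowSums(det[, grp == "enterovirus", drop = FALSE]) > 0
  any_masta <- rowSums(det[, grp == "mastadenovirus", drop = FALSE]) > 0
  any_noro <- rowSums(det[, grp == "norovirus", drop = FALSE]) > 0
  any_parecho <- rowSums(det[, grp == "parechovirus", drop = FALSE]) > 0
  samples <- data.frame(
    sample = rownames(counts), subject = as.character(subject),
    any_virus = any_virus, any_enterovirus = any_entero,
    any_mastadenovirus = any_masta,
    any_norovirus = any_noro, any_parechovirus = any_parecho,
    combo = paste0("V", as.integer(any_virus), "E", as.integer(any_entero),
                   "M", as.integer(any_masta)),
    row.names = NULL, stringsAsFactors = FALSE)
  subj_or <- function(flag) tapply(flag, samples$subject, any)
  subj <- data.frame(
    subject = sort(unique(samples$subject)),
    stringsAsFactors = FALSE)
  for (f in c("any_virus", "any_enterovirus", "any_mastadenovirus",
              "any_norovirus", "any_parechovirus"))
    subj[[f]] <- as.logical(subj_or(samples[[f]])[subj$subject])
  structure(list(samples = samples, subjects = subj), class = "virome_status")
}
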