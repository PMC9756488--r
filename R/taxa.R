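#' OTU table construction and validation
#'
#' Bundles a samples x OTUs count matrix with Greengenes-style lineage
#' strings (`k__...; p__...; c__...; o__...; f__...; g__...; s__...`,
#' possibly blank at low ranks).  All downstream 16S operations consume this
#' object.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; must have
#'   row and column names.
#' @param lineages character vector of lineage strings, one per OTU, named
#'   by OTU id or in column order.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (samples x OTUs integer matrix) and `lineages` (character, per OTU).
#' @export
as_otu_table <- function(counts, lineages) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("sample ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (!is.null(names(lineages))) lineages <- lineages[colnames(counts)]
  if (length(lineages) != ncol(counts))
    stop("one lineage string required per OTU")
  ranks <- lapply(lineages, parse_lineage)
  if (any(vapply(ranks, function(r) !nzchar(r[1L]), logical(1))))
    stop("every OTU needs a nonempty kingdom label")
  structure(list(counts = counts, lineages = stats::setNames(lineages, colnames(counts))),
            class = "otu_table")
}

RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
RANK_NAMES <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Parse a Greengenes lineage string
#'
#' @param x single lineage string, ranks separated by ";".
#' @return character vector of length 7 (kingdom..species) holding the rank
#'   labels including their `k__`-style prefixes; absent ranks are `""`.
#' @export
parse_lineage <- function(x) {
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  out <- character(7L)
  for (p in parts) {
    if (!nzchar(p)) next
    i <- match(substr(p, 1L, 3L), RANK_PREFIXES)
    if (is.na(i)) stop("unrecognized rank prefix in lineage: ", p)
    # prefix alone (e.g. "g__") means unclassified at that rank
    if (nchar(p) > 3L) out[i] <- p
  }
  names(out) <- RANK_NAMES
  out
}

deparse_lineage <- function(r) paste(ifelse(nzchar(r), r, RANK_PREFIXES), collapse = "; ")

#' Quality-control filter for an OTU table
#'
#' Drops samples whose total read count falls below `min_reads` (failed
#' sequencing reactions) and OTUs whose lineage contains any excluded label
#' (e.g. a contaminant genus).
#'
#' @param table an [as_otu_table()] object.
#' @param min_reads samples with total reads strictly below this are removed
#'   (default 100).
#' @param exclude_taxa character vector of rank labels (with prefix, e.g.
#'   `"g__Methanobrevibacter"`); OTUs carrying any of them are removed.
#' @return A filtered `otu_table` with an attribute `qc_log` listing removed
#'   samples and OTUs.
#' @export
qc_filter <- function(table, min_reads = 100L, exclude_taxa = character()) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  drop_samples <- rownames(table$counts)[totals < min_reads]
  keep_s <- setdiff(rownames(table$counts), drop_samples)
  if (length(keep_s) == 0L)
    stop("qc_filter removed every sample (all totals < ", min_reads, ")")
  drop_otus <- character()
  if (length(exclude_taxa)) {
    hit <- vapply(table$lineages, function(l) any(parse_lineage(l) %in% exclude_taxa),
                  logical(1))
    drop_otus <- colnames(table$counts)[hit]
  }
  keep_o <- setdiff(colnames(table$counts), drop_otus)
  if (length(keep_o) == 0L) stop("qc_filter removed every OTU")
  out <- as_otu_table(table$counts[keep_s, keep_o, drop = FALSE],
                      table$lineages[keep_o])
  attr(out, "qc_log") <- list(removed_samples = drop_samples, removed_otus = drop_otus)
  out
}

#' Retention rule for a single feature
#'
#' A feature is retained when it accounts for more than `abund_thresh` of a
#' sample's reads in at least `prev_thresh` of samples.  The abundance
#' comparison is strict (`>`), the prevalence one is not (`>=`), and the
#' prevalence count is compared to `prev_thresh * n_samples` without
#' rounding.
#'
#' @param feature_fractions numeric vector of per-sample relative abundances
#'   in `[0, 1]`.
#' @param abund_thresh relative-abundance threshold (default 0.001 = 0.1%).
#' @param prev_thresh prevalence threshold as a fraction of samples
#'   (default 0.15).
#' @return `TRUE` if the feature meets the criterion.
#' @export
passes_retention <- function(feature_fractions, abund_thresh = 0.001, prev_thresh = 0.15) {
  if (any(feature_fractions < 0 | feature_fractions > 1))
    stop("fractions must lie in [0, 1]")
  sum(feature_fractions > abund_thresh) >= prev_thresh * length(feature_fractions)
}

# vectorised retention over a samples x features fraction matrix
.retained <- function(frac, abund_thresh, prev_thresh) {
  colSums(frac > abund_thresh) >= prev_thresh * nrow(frac)
}

#' Taxonomy-guided amalgamation of an OTU table
#'
#' Iteratively reduces the feature space: features meeting the retention
#' criterion (see [passes_retention()]) are frozen unaltered; failing
#' features are collapsed to their parent taxon (nearest non-empty ancestor
#' rank), counts summed within each truncated lineage, and the procedure is
#' repeated `n_iter` times.  Features still failing afterwards are excluded.
#' Frozen features never absorb later collapses: an aggregate landing on the
#' lineage of a frozen feature keeps its own identity (suffix `_agg`).
#' Per-sample totals over retained plus excluded features equal the input
#' totals exactly.
#'
#' @param table a qc-filtered [as_otu_table()] object.
#' @param abund_thresh,prev_thresh retention thresholds, see
#'   [passes_retention()].
#' @param n_iter number of collapse rounds (default 3).
#' @return A `feature_table`: list with `counts` (samples x retained
#'   features), `info` (data.frame: feature id, lineage, effective rank,
#'   member OTUs, status), `excluded` (samples x excluded features matrix),
#'   and `totals` (input per-sample totals).
#' @export
amalgamate <- function(table, abund_thresh = 0.001, prev_thresh = 0.15, n_iter = 3L) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (any(totals <= 0)) stop("qc-filter the table first: zero-total sample present")

  # working set: one entry per active/frozen feature
  feats <- lapply(colnames(table$counts), function(id) {
    list(id = id, ranks = parse_lineage(table$lineages[[id]]),
         rank_idx = 8L,  # OTUs sit below species
         counts = table$counts[, id], members = id, frozen = FALSE)
  })
  names(feats) <- colnames(table$counts)

  eval_round <- function(feats) {
    active <- !vapply(feats, `[[`, logical(1), "frozen")
    if (!any(active)) return(feats)
    frac <- vapply(feats[active], function(f) f$counts / totals,
                   numeric(nrow(table$counts)))
    frac <- matrix(frac, nrow = nrow(table$counts))
    pass <- .retained(frac, abund_thresh, prev_thresh)
    idx <- which(active)[pass]
    for (i in idx) feats[[i]]$frozen <- TRUE
    feats
  }

  for (iter in seq_len(n_iter)) {
    feats <- eval_round(feats)
    failing <- which(!vapply(feats, `[[`, logical(1), "frozen"))
    if (length(failing) == 0L) break
    # collapse each failing feature to its nearest non-empty ancestor rank;
    # grouping key is the full truncated lineage, so distinct unclassified
    # branches never merge across families
    keys <- rep(NA_character_, length(failing))
    targets <- vector("list", length(failing))
    for (j in seq_along(failing)) {
      f <- feats[[failing[j]]]
      r <- f$rank_idx - 1L
      while (r >= 1L && !nzchar(f$ranks[r])) r <- r - 1L
      if (r < 1L) next  # already at kingdom: carried to final evaluation
      new_ranks <- f$ranks
      if (r < 7L) new_ranks[(r + 1L):7L] <- ""
      keys[j] <- paste(new_ranks[seq_len(r)], collapse = "|")
      targets[[j]] <- list(ranks = new_ranks, rank_idx = r)
    }
    collapsible <- which(!is.na(keys))
    if (length(collapsible) == 0L) next
    keep <- feats[-failing[collapsible]]
    merged <- lapply(unique(keys[collapsible]), function(key) {
      grp <- collapsible[keys[collapsible] == key]
      gi <- failing[grp]
      tgt <- targets[[grp[1L]]]
      list(id = paste0(tgt$ranks[tgt$rank_idx], "_agg"),
           ranks = tgt$ranks, rank_idx = tgt$rank_idx,
           counts = Reduce(`+`, lapply(feats[gi], `[[`, "counts")),
           members = unlist(lapply(feats[gi], `[[`, "members"), use.names = FALSE),
           frozen = FALSE)
    })
    feats <- c(keep, merged)
    names(feats) <- make.unique(vapply(feats, `[[`, character(1), "id"))
  }
  # final evaluation: whatever still fails is excluded
  feats <- eval_round(feats)
  frozen <- vapply(feats, `[[`, logical(1), "frozen")

  ids <- make.unique(vapply(feats, `[[`, character(1), "id"))
  cts <- vapply(feats, `[[`, numeric(nrow(table$counts)), "counts")
  cts <- matrix(cts, nrow = nrow(table$counts),
                dimnames = list(rownames(table$counts), ids))
  info <- data.frame(
    feature = ids,
    lineage = vapply(feats, function(f) deparse_lineage(f$ranks), character(1)),
    effective_rank = vapply(feats, function(f)
      if (f$rank_idx == 8L) "otu" else RANK_NAMES[f$rank_idx], character(1)),
    n_members = vapply(feats, function(f) length(f$members), integer(1)),
    members = vapply(feats, function(f) paste(f$members, collapse = ";"), character(1)),
    status = ifelse(frozen, "retained", "excluded"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(counts = cts[, frozen, drop = FALSE],
                 excluded = cts[, !frozen, drop = FALSE],
                 info = info, totals = totals),
            class = "feature_table")
}

#' Observed richness of one sample
#'
#' @param counts nonnegative count vector for one sample.
#' @return Number of strictly positive entries.
#' @export
observed_richness <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  sum(counts > 0)
}

#' Shannon diversity index of one sample
#'
#' `-sum(p log p)` over positive proportions `p = count/total`; natural log
#' by default.
#'
#' @param counts nonnegative count vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index (numeric scalar).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("Shannon index undefined for an all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param rel samples x features matrix of relative abundances (rows sum
#'   to 1 after total-sum scaling).
#' @return Symmetric `dist`-convertible matrix of Bray-Curtis distances.
#' @export
bray_curtis <- function(rel) {
  d <- as.matrix(vegan::vegdist(rel, method = "bray"))
  dimnames(d) <- list(rownames(rel), rownames(rel))
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: eigendecomposition of the
#' double-centered `-D^2/2` matrix.  Axes with negative eigenvalues are
#' reported in `eig` but dropped from the coordinates; an optional Cailliez
#' correction makes the matrix Euclidean first.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param n_axes number of coordinate axes to return (default 2).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return list with `coords` (samples x axes), `eig` (all eigenvalues) and
#'   `prop_explained` (positive eigenvalues / their sum).
#' @export
pcoa <- function(d, n_axes = 2L, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10)) stop("distance matrix must be symmetric")
  fit <- stats::cmdscale(stats::as.dist(d), k = min(n_axes, nrow(d) - 1L),
                         eig = TRUE, add = correction == "cailliez")
  pos <- fit$eig[fit$eig > .Machine$double.eps * max(abs(fit$eig))]
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coords = coords, eig = fit$eig,
       prop_explained = pos / sum(pos))
}

#' Arcsine square-root transform of total-sum-scaled counts
#'
#' `y = asin(sqrt(count / sample_total))`, the variance-stabilizing
#' transform used for modelling relative abundances; range `[0, pi/2]`.
#'
#' @param counts samples x features nonnegative matrix.
#' @return transformed matrix of the same shape.
#' @export
arcsin_sqrt_tss <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals <= 0)) stop("zero-total sample: cannot total-sum scale")
  asin(sqrt(sweep(counts, 1L, totals, "/")))
}
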