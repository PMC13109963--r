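#' Quality control for spatial transcriptomics samples
#'
#' Each spatial technology class gets its own QC protocol, reflecting the
#' resolution and sequencing-depth differences between platforms:
#'
#' * `qc_multicell()` (spot-based platforms such as Visium): drop capture
#'   locations with fewer than `min_umi` UMIs, fewer than `min_genes`
#'   detected genes, or a mitochondrial read fraction at or above
#'   `max_mito`; then drop locations whose total UMI count or detected
#'   gene count falls more than three standard deviations below the
#'   median of the surviving locations; finally drop genes expressed
#'   (raw count > 0) in fewer than `min_locations` surviving locations.
#' * `qc_singlecell()` (imaging platforms): only the UMI and
#'   mitochondrial rules are applied — no gene filter, no
#'   detected-gene rule, no outlier rule.
#' * `qc_slideseq()` (bead platforms): genes with sample-wide total UMI
#'   below `min_gene_umi` are removed first, then locations whose
#'   (recomputed) total is not strictly greater than `min_umi` or whose
#'   mitochondrial fraction is at or above `max_mito`.
#'
#' The mitochondrial fraction is the raw count sum of flagged genes over
#' the location total. A location tripping several rules is tallied under
#' the first rule in the order UMI, detected genes, mitochondrial,
#' outlier, so the report reconciles exactly with the matrix shapes.
#'
#' @param s A [spatial_sample()] of the matching technology class.
#' @param min_umi Minimum UMI count per location (multi-cell and
#'   single-cell: locations below are removed; slide-seq: locations must
#'   be strictly greater).
#' @param min_genes Minimum detected genes per location (multi-cell only).
#' @param max_mito Locations with mitochondrial fraction `>=` this are
#'   removed.
#' @param n_sd Outlier rule width (multi-cell only): a location is an
#'   outlier when its UMI total or detected-gene count is more than
#'   `n_sd` standard deviations below the respective median of the
#'   locations surviving the hard thresholds.
#' @param min_locations Multi-cell gene filter: genes expressed in fewer
#'   surviving locations than this are removed.
#' @param min_gene_umi Slide-seq gene filter: genes with sample-wide
#'   total UMI below this are removed.
#' @param location_filter_first Slide-seq only: apply the location filter
#'   before the gene filter (sensitivity flag; default `FALSE`, gene
#'   filter first with location totals recomputed afterwards).
#'
#' @return A list with elements `sample` (the filtered
#'   `spatial_sample`) and `report` (a `qc_report`: one-row tibble of
#'   tallies and the thresholds used).
#' @name qc
NULL

qc_report <- function(locations_in, removed_umi = 0L, removed_genes = 0L,
                      removed_mito = 0L, removed_outlier = 0L,
                      genes_in, genes_removed = 0L, thresholds = list()) {
  rep <- tibble::tibble(
    locations_in = as.integer(locations_in),
    locations_removed_umi = as.integer(removed_umi),
    locations_removed_genes = as.integer(removed_genes),
    locations_removed_mito = as.integer(removed_mito),
    locations_removed_outlier = as.integer(removed_outlier),
    locations_out = as.integer(locations_in - removed_umi - removed_genes -
                                 removed_mito - removed_outlier),
    genes_in = as.integer(genes_in),
    genes_removed = as.integer(genes_removed),
    genes_out = as.integer(genes_in - genes_removed)
  )
  attr(rep, "thresholds") <- thresholds
  class(rep) <- c("qc_report", class(rep))
  rep
}

subset_sample <- function(s, genes = NULL, locations = NULL) {
  counts <- s$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(locations)) counts <- counts[, locations, drop = FALSE]
  s$counts <- counts
  s$coords <- s$coords[match(colnames(counts), s$coords$location_id), ]
  s$mito_genes <- intersect(s$mito_genes, rownames(counts))
  if (!is.null(s$annotations)) s$annotations <- s$annotations[colnames(counts)]
  s
}

location_metrics <- function(s) {
  m <- s$counts
  tot <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mito <- if (length(s$mito_genes)) {
    Matrix::colSums(m[s$mito_genes, , drop = FALSE])
  } else rep(0, ncol(m))
  frac <- ifelse(tot > 0, mito / tot, 0)
  list(total = tot, n_genes = ngene, mito_frac = frac)
}

#' @rdname qc
#' @export
qc_multicell <- function(s, min_umi = 500, min_genes = 500, max_mito = 0.25,
                         n_sd = 3, min_locations = 5) {
  stopifnot(inherits(s, "spatial_sample"), s$technology == "multi_cell")
  thr <- list(min_umi = min_umi, min_genes = min_genes, max_mito = max_mito,
              n_sd = n_sd, min_locations = min_locations)
  n_in <- ncol(s$counts); g_in <- nrow(s$counts)
  if (n_in == 0L) {
    return(list(sample = s,
                report = qc_report(0L, genes_in = g_in, thresholds = thr)))
  }
  met <- location_metrics(s)
  fail_umi <- met$total < min_umi
  fail_genes <- !fail_umi & met$n_genes < min_genes
  fail_mito <- !fail_umi & !fail_genes & met$mito_frac >= max_mito
  keep <- !(fail_umi | fail_genes | fail_mito)

  # outlier rule on the survivors of the hard thresholds: either metric
  # more than n_sd SDs below its own median. Iterated to a fixed point
  # (each trim tightens the cohort, which can expose further outliers);
  # at the fixed point a re-run removes nothing, so QC is idempotent.
  fail_out <- rep(FALSE, n_in)
  repeat {
    if (sum(keep) < 2L) break
    tot_k <- met$total[keep]; ng_k <- met$n_genes[keep]
    lo_tot <- median(tot_k) - n_sd * sd(tot_k)
    lo_ng <- median(ng_k) - n_sd * sd(ng_k)
    new_out <- keep & (met$total < lo_tot | met$n_genes < lo_ng)
    new_out[is.na(new_out)] <- FALSE
    if (!any(new_out)) break
    fail_out <- fail_out | new_out
    keep <- keep & !new_out
  }

  out <- subset_sample(s, locations = which(keep))
  expressed_in <- Matrix::rowSums(out$counts > 0)
  gene_keep <- expressed_in >= min_locations
  out <- subset_sample(out, genes = which(gene_keep))
  list(sample = out,
       report = qc_report(n_in, sum(fail_umi), sum(fail_genes),
                          sum(fail_mito), sum(fail_out),
                          genes_in = g_in, genes_removed = sum(!gene_keep),
                          thresholds = thr))
}

#' @rdname qc
#' @export
qc_singlecell <- function(s, min_umi = 500, max_mito = 0.25) {
  stopifnot(inherits(s, "spatial_sample"), s$technology == "single_cell")
  thr <- list(min_umi = min_umi, max_mito = max_mito)
  n_in <- ncol(s$counts); g_in <- nrow(s$counts)
  if (n_in == 0L) {
    return(list(sample = s,
                report = qc_report(0L, genes_in = g_in, thresholds = thr)))
  }
  met <- location_metrics(s)
  fail_umi <- met$total < min_umi
  fail_mito <- !fail_umi & met$mito_frac >= max_mito
  out <- subset_sample(s, locations = which(!(fail_umi | fail_mito)))
  list(sample = out,
       report = qc_report(n_in, sum(fail_umi), removed_mito = sum(fail_mito),
                          genes_in = g_in, thresholds = thr))
}

#' @rdname qc
#' @export
qc_slideseq <- function(s, min_gene_umi = 300, min_umi = 100,
                        max_mito = 0.25, location_filter_first = FALSE) {
  stopifnot(inherits(s, "spatial_sample"), s$technology == "slide_seq")
  thr <- list(min_gene_umi = min_gene_umi, min_umi = min_umi,
              max_mito = max_mito,
              location_filter_first = location_filter_first)
  n_in <- ncol(s$counts); g_in <- nrow(s$counts)

  filter_genes <- function(x) {
    subset_sample(x, genes = which(Matrix::rowSums(x$counts) >= min_gene_umi))
  }
  filter_locations <- function(x) {
    if (ncol(x$counts) == 0L) {
      return(list(s = x, n_umi = 0L, n_mito = 0L))
    }
    met <- location_metrics(x)
    fail_umi <- !(met$total > min_umi)         # strictly greater survives
    fail_mito <- !fail_umi & met$mito_frac >= max_mito
    list(s = subset_sample(x, locations = which(!(fail_umi | fail_mito))),
         n_umi = sum(fail_umi), n_mito = sum(fail_mito))
  }

  if (location_filter_first) {
    lf <- filter_locations(s)
    out <- filter_genes(lf$s)
  } else {
    out <- filter_genes(s)
    lf <- filter_locations(out)
    out <- lf$s
  }
  list(sample = out,
       report = qc_report(n_in, lf$n_umi, removed_mito = lf$n_mito,
                          genes_in = g_in,
                          genes_removed = g_in - nrow(out$counts),
                          thresholds = thr))
}

#' Normalize a post-QC sample
#'
#' Default method: each location's counts are scaled to the median
#' post-QC location total, then log-transformed with a pseudo-count
#' (`log(scaled + pseudo_count)`; the default `pseudo_count = 1` gives
#' `log1p`). A rank-preserving transformation — every downstream
#' statistic in the pipeline is rank-based or threshold-based, so results
#' are robust to the choice among monotone normalizations.
#'
#' @param s A post-QC [spatial_sample()].
#' @param method Currently `"median_log1p"`.
#' @param pseudo_count Added before the log (default 1).
#' @return A [normalized_sample()]; `normalization_tag` records method
#'   and parameters.
#' @export
normalize_sample <- function(s, method = "median_log1p", pseudo_count = 1) {
  method <- match.arg(method)
  tot <- Matrix::colSums(s$counts)
  if (any(tot == 0)) {
    abort(paste0("cannot scale location '",
                 colnames(s$counts)[which(tot == 0)[1]],
                 "' with zero total count; run QC first."))
  }
  target <- median(tot)
  scaled <- as.matrix(s$counts) %*% diag(target / tot, ncol(s$counts))
  dimnames(scaled) <- dimnames(s$counts)
  expr <- log(scaled + pseudo_count)
  tag <- sprintf("%s(target=%g,pseudo_count=%g)", method, target, pseudo_count)
  normalized_sample(s, expr, tag)
}
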