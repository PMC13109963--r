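#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact enumeration for
#' small tie-free samples, normal approximation with tie and continuity
#' correction otherwise. Kept as the single testing primitive shared by
#' marker detection and neighborhood interaction analysis.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return Named list: `statistic` (the rank-sum W for group `a`) and
#'   `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty.")
  ht <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
  p <- ht$p.value
  if (is.na(p)) p <- 1   # fully tied data carries no evidence
  list(statistic = unname(ht$statistic), p = p)
}

# vectorized one-vs-rest rank-sum p-values for all genes at once;
# normal approximation with tie correction (used for the big matrices,
# falls back to wilcox.test row-wise for small groups)
ranksum_matrix <- function(expr, in_idx, out_idx) {
  n1 <- length(in_idx); n2 <- length(out_idx)
  if (n1 + n2 <= 30L) {
    return(apply(expr, 1L, function(v)
      wilcoxon_rank_sum(v[in_idx], v[out_idx])$p))
  }
  sub <- expr[, c(in_idx, out_idx), drop = FALSE]
  ranks <- t(apply(sub, 1L, rank))
  R1 <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- apply(sub, 1L, function(v) {
    tt <- table(v); sum(tt^3 - tt)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma2[sigma2 <= 0] <- NA
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(p)] <- 1
  pmin(p, 1)
}

log2_fc <- function(mean_in, mean_out, pseudocount = 1) {
  log2((mean_in + pseudocount) / (mean_out + pseudocount))
}

#' One-vs-rest cell-type marker detection
#'
#' For every cell type, each gene is tested for differential expression
#' in that type against all other types with a Wilcoxon rank-sum test.
#' Testing is limited to genes with at least `min_lfc` absolute log fold
#' difference between the two groups and detected (expression > 0) in a
#' minimum fraction `min_pct` of observations in either group — genes
#' failing either filter are excluded before testing. p-values are
#' BH-adjusted within each cell type across the genes actually tested.
#'
#' The fold change is `log2((mean_in + 1)/(mean_out + 1))` on normalized
#' expression (natural-log base available via `lfc_base` for sensitivity
#' against conventions that filter on ln fold change).
#'
#' @param x A `pseudo_cells` object (multi-cell resolution) or an
#'   annotated [normalized_sample()] (single-cell resolution).
#' @param min_lfc Fold-change filter (default 0.1, in `lfc_base` units).
#' @param min_pct Detection-fraction filter (default 0.1).
#' @param lfc_base Base of the reported fold change, 2 or `exp(1)`
#'   (default 2).
#' @param min_cells Cell types with fewer observations are skipped with
#'   a warning (default 3).
#' @return Tibble `deg_table`: `gene`, `cell_type`, `log2_fc`, `pct_in`,
#'   `pct_out`, `p`, `q`, `direction` (`"up"`/`"down"`).
#' @export
find_markers <- function(x, min_lfc = 0.1, min_pct = 0.1, lfc_base = 2,
                         min_cells = 3) {
  em <- expr_matrix(x)
  labels <- if (inherits(x, "pseudo_cells")) x$cells$cell_type
            else x$annotations
  if (is.null(labels)) {
    abort("marker detection needs cell-type labels (pseudo-cells or annotations).")
  }
  types <- sort(unique(labels))
  if (length(types) < 2L) {
    warn("fewer than two cell types; no markers to find.")
    return(empty_deg_table())
  }
  res <- purrr::map(types, function(ct) {
    in_idx <- which(labels == ct)
    out_idx <- which(labels != ct)
    if (length(in_idx) < min_cells) {
      warn(paste0("cell type '", ct, "' has fewer than ", min_cells,
                  " observations; skipped."))
      return(NULL)
    }
    mean_in <- rowMeans(em[, in_idx, drop = FALSE])
    mean_out <- rowMeans(em[, out_idx, drop = FALSE])
    lfc <- log2_fc(mean_in, mean_out) * if (lfc_base == 2) 1 else log(2)
    pct_in <- rowMeans(em[, in_idx, drop = FALSE] > 0)
    pct_out <- rowMeans(em[, out_idx, drop = FALSE] > 0)
    keep <- abs(lfc) >= min_lfc & pmax(pct_in, pct_out) >= min_pct
    if (!any(keep)) return(NULL)
    p <- ranksum_matrix(em[keep, , drop = FALSE], in_idx, out_idx)
    tibble::tibble(gene = rownames(em)[keep], cell_type = ct,
                   log2_fc = unname(lfc[keep]),
                   pct_in = unname(pct_in[keep]),
                   pct_out = unname(pct_out[keep]),
                   p = unname(p), q = p.adjust(p, "BH"),
                   direction = unname(ifelse(lfc[keep] > 0, "up", "down")))
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0L) return(empty_deg_table())
  res <- dplyr::arrange(res, .data$cell_type, .data$q, .data$gene)
  class(res) <- c("deg_table", class(res))
  res
}

empty_deg_table <- function() {
  res <- tibble::tibble(gene = character(), cell_type = character(),
                        log2_fc = numeric(), pct_in = numeric(),
                        pct_out = numeric(), p = numeric(), q = numeric(),
                        direction = character())
  class(res) <- c("deg_table", class(res))
  res
}

#' Summarize a marker table
#'
#' @param x A `deg_table`.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return One row per cell type: tested genes, significant up/down
#'   counts.
#' @export
glance.deg_table <- function(x, alpha = 0.05, ...) {
  dplyr::summarise(
    dplyr::group_by(x, .data$cell_type),
    n_tested = dplyr::n(),
    n_sig_up = sum(.data$q < alpha & .data$direction == "up"),
    n_sig_down = sum(.data$q < alpha & .data$direction == "down"),
    .groups = "drop")
}

#' Plot a marker table as a volcano per cell type
#'
#' @param object A `deg_table`.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object faceted by cell type.
#' @export
autoplot.deg_table <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2_fc,
                                       y = -log10(.data$q),
                                       color = .data$q < alpha)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#0072B2",
                                           `FALSE` = "grey60"),
                                name = paste0("q < ", alpha)) +
    ggplot2::labs(x = expression(log[2]~fold~change),
                  y = expression(-log[10]~q)) +
    ggplot2::theme_minimal()
}
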