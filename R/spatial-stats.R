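#' Moran's I spatial autocorrelation with k-nearest-neighbor weights
#'
#' The spatial variability statistic used throughout the pipeline:
#' \deqn{I = \frac{n}{W} \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'                        {\sum_i (x_i-\bar x)^2}}
#' with binary, symmetrized k-nearest-neighbor weights (an edge when
#' either location counts the other among its `k_neighbors` nearest, no
#' self-neighbors) and \eqn{W} the total weight. k-NN weights rather than
#' a fixed radius keep the statistic technology-agnostic across spot,
#' bead and imaging platforms.
#'
#' @param values Numeric vector, one value per location.
#' @param coords Matrix or data frame of per-location (x, y) in
#'   micrometers.
#' @param k_neighbors Neighbors per location (capped at n - 1;
#'   default 6).
#' @return Moran's I, or `NA` for a constant vector (undefined
#'   statistic).
#' @export
morans_i <- function(values, coords, k_neighbors = 6) {
  coords <- as.matrix(coords)
  n <- length(values)
  stopifnot(n >= 3L, nrow(coords) == n)
  W <- knn_weights(coords, k_neighbors)
  morans_i_many(matrix(values, ncol = 1), W)[1]
}

# Binary symmetrized kNN adjacency as a sparse matrix; ties in distance
# broken by index order for determinism.
knn_weights <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  idx <- apply(d, 1L, function(row) order(row)[seq_len(k)])
  i <- rep(seq_len(n), each = k)
  j <- as.vector(idx)
  w <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  w <- w + Matrix::t(w)        # symmetrize: union of neighborhoods
  w <- methods::as(Matrix::drop0(w), "generalMatrix")
  w@x <- rep(1, length(w@x))   # back to binary weights
  w
}

# Moran's I for every column of a location x gene matrix under a shared
# weight matrix. Constant columns give NA.
morans_i_many <- function(x, W) {
  n <- nrow(x)
  Wsum <- sum(W)
  xc <- sweep(x, 2L, colMeans(x))
  num <- colSums(xc * as.matrix(W %*% xc))
  den <- colSums(xc^2)
  ifelse(den > 0, (n / Wsum) * num / den, NA_real_)
}

expr_matrix <- function(x) {
  if (inherits(x, "normalized_sample")) x$expr
  else if (inherits(x, "pseudo_cells")) x$expr
  else abort("expected a normalized_sample or pseudo_cells object.")
}

coords_matrix <- function(x) {
  if (inherits(x, "normalized_sample")) as.matrix(x$coords[, c("x", "y")])
  else if (inherits(x, "pseudo_cells")) as.matrix(x$cells[, c("x", "y")])
  else abort("expected a normalized_sample or pseudo_cells object.")
}

#' Spatially variable gene testing
#'
#' Scores every gene with Moran's I on a k-nearest-neighbor graph and
#' attaches a permutation p-value: expression values are shuffled across
#' locations `n_perm` times (one fresh permutation per iteration, shared
#' across genes) and the one-tailed add-one p-value
#' \eqn{p = (\#\{I_{perm} \ge I_{obs}\} + 1)/(B + 1)} is reported, so
#' positive spatial autocorrelation — smooth spatial structure — is what
#' counts as variability. q-values are Benjamini-Hochberg adjusted
#' across genes within each scope.
#'
#' With `scope = "whole"` the tissue-wide normalized expression is
#' tested. With `scope = "celltype"` a [build_pseudocells()] result (or
#' an annotated single-cell `normalized_sample`) is analyzed one cell
#' type at a time; types with fewer than `min_cells` observations are
#' skipped with a warning.
#'
#' @param x A [normalized_sample()] or `pseudo_cells` object.
#' @param scope `"whole"` or `"celltype"`.
#' @param n_perm Permutations per scope (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param k_neighbors Passed to the weight graph (default 6).
#' @param min_cells Minimum observations per cell type (default 10).
#' @return Tibble `sv_result`: `gene`, `scope`, `cell_type` (`NA` for
#'   whole-tissue), `statistic`, `p`, `q`, `n_locations`, sorted by `q`
#'   then `gene`. Constant genes carry `statistic = NA`, `p = 1`.
#' @export
sv_test <- function(x, scope = c("whole", "celltype"), n_perm = 1000,
                    seed = 1, k_neighbors = 6, min_cells = 10) {
  scope <- match.arg(scope)
  if (scope == "whole") {
    res <- sv_test_block(expr_matrix(x), coords_matrix(x), n_perm, seed,
                         k_neighbors)
    res$scope <- "whole"
    res$cell_type <- NA_character_
  } else {
    if (inherits(x, "pseudo_cells")) {
      groups <- split(seq_len(ncol(x$expr)), x$cells$cell_type)
    } else if (!is.null(x$annotations)) {
      groups <- split(seq_len(ncol(x$expr)), x$annotations)
    } else {
      abort("celltype scope needs pseudo-cells or per-location annotations.")
    }
    em <- expr_matrix(x); cm <- coords_matrix(x)
    res <- purrr::imap(groups, function(idx, ct) {
      if (length(idx) < min_cells) {
        warn(paste0("cell type '", ct, "' has fewer than ", min_cells,
                    " observations; skipped."))
        return(NULL)
      }
      out <- sv_test_block(em[, idx, drop = FALSE],
                           cm[idx, , drop = FALSE], n_perm, seed,
                           k_neighbors)
      out$cell_type <- ct
      out
    }) |> dplyr::bind_rows()
    if (nrow(res) == 0L) {
      return(empty_sv_result())
    }
    res$scope <- "celltype"
  }
  res <- res[, c("gene", "scope", "cell_type", "statistic", "p", "q",
                 "n_locations")]
  res <- dplyr::arrange(res, .data$q, .data$gene)
  class(res) <- c("sv_result", class(res))
  attr(res, "seed") <- seed
  attr(res, "n_perm") <- n_perm
  res
}

empty_sv_result <- function() {
  res <- tibble::tibble(gene = character(), scope = character(),
                        cell_type = character(), statistic = numeric(),
                        p = numeric(), q = numeric(),
                        n_locations = integer())
  class(res) <- c("sv_result", class(res))
  res
}

sv_test_block <- function(expr, coords, n_perm, seed, k_neighbors) {
  genes <- rownames(expr)
  n <- ncol(expr)
  if (length(genes) == 0L || n == 0L) return(empty_sv_result()[, -(2:3)])
  X <- t(expr)                             # locations x genes
  W <- knn_weights(coords, k_neighbors)
  obs <- morans_i_many(X, W)
  exceed <- integer(length(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      ip <- morans_i_many(X[perm, , drop = FALSE], W)
      exceed <- exceed + as.integer(!is.na(obs) & !is.na(ip) & ip >= obs)
    }
  })
  p <- ifelse(is.na(obs), 1, (exceed + 1) / (n_perm + 1))
  tibble::tibble(gene = genes, statistic = obs, p = p,
                 q = p.adjust(p, "BH"), n_locations = n)
}

#' Gene / cell-type colocalization by Kendall correlation
#'
#' Kendall's tau-b between a gene's normalized expression and a cell
#' type's predicted fraction across capture locations, with the
#' normal-approximation p-value (exact enumeration when n <= 8).
#'
#' @param ns A [normalized_sample()].
#' @param gene Gene symbol.
#' @param f A [fraction_matrix()] over the same locations.
#' @param cell_type Cell-type label in `f`.
#' @return One-row tibble: `gene`, `cell_type`, `tau`, `p`, `n`,
#'   `flag` (`"ok"` or `"constant"`; constant input gives `tau = NA`).
#' @export
colocalization_corr <- function(ns, gene, f, cell_type) {
  stopifnot(inherits(ns, "normalized_sample"), inherits(f, "fraction_matrix"))
  if (!gene %in% rownames(ns$expr)) abort(paste0("unknown gene: ", gene))
  if (!cell_type %in% f$cell_types) {
    abort(paste0("unknown cell type: ", cell_type))
  }
  locs <- intersect(colnames(ns$expr), colnames(f$fractions))
  x <- ns$expr[gene, locs]
  y <- f$fractions[cell_type, locs]
  n <- length(locs)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(tibble::tibble(gene = gene, cell_type = cell_type,
                          tau = NA_real_, p = 1, n = n, flag = "constant"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall",
                                  exact = n <= 8))
  tibble::tibble(gene = gene, cell_type = cell_type,
                 tau = unname(stats::cor(x, y, method = "kendall")),
                 p = ct$p.value, n = n, flag = "ok")
}

#' Correlate a two-gene expression ratio with marker genes
#'
#' Computes the per-observation ratio
#' `(num + pseudocount)/(den + pseudocount)` on normalized expression
#' and its Spearman correlation against each marker in a panel;
#' p-values are BH-adjusted across the panel.
#'
#' @param x A [normalized_sample()] or `pseudo_cells` object.
#' @param num_gene,den_gene Numerator / denominator genes of the ratio.
#' @param markers Character vector of marker genes.
#' @param pseudocount Ratio stabilizer (default 1).
#' @param cell_type Optional: restrict a `pseudo_cells` object to one
#'   cell type before computing the ratio.
#' @return Tibble: `marker`, `rho`, `p`, `q`, `n`, `flag`. A constant
#'   marker (or a constant ratio) is flagged with `p = 1`.
#' @export
gene_ratio_corr <- function(x, num_gene, den_gene, markers,
                            pseudocount = 1, cell_type = NULL) {
  em <- expr_matrix(x)
  if (!is.null(cell_type)) {
    stopifnot(inherits(x, "pseudo_cells"))
    em <- em[, x$cells$cell_type == cell_type, drop = FALSE]
  }
  need <- c(num_gene, den_gene, markers)
  miss <- setdiff(need, rownames(em))
  if (length(miss)) abort(paste0("unknown gene: ", miss[1]))
  ratio <- (em[num_gene, ] + pseudocount) / (em[den_gene, ] + pseudocount)
  ratio_const <- length(unique(ratio)) < 2L
  res <- purrr::map(markers, function(mk) {
    y <- em[mk, ]
    if (ratio_const || length(unique(y)) < 2L) {
      return(tibble::tibble(marker = mk, rho = NA_real_, p = 1,
                            n = length(y),
                            flag = if (ratio_const) "constant_ratio"
                                   else "constant_marker"))
    }
    ct <- suppressWarnings(cor.test(ratio, y, method = "spearman"))
    tibble::tibble(marker = mk, rho = unname(ct$estimate), p = ct$p.value,
                   n = length(y), flag = "ok")
  }) |> dplyr::bind_rows()
  res$q <- p.adjust(res$p, "BH")
  res[, c("marker", "rho", "p", "q", "n", "flag")]
}

#' Plot spatially variable gene results
#'
#' Volcano-style overview: Moran's I against -log10 q, colored by
#' significance at `alpha`.
#'
#' @param object An `sv_result` tibble from [sv_test()].
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sv_result <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(object, !is.na(.data$statistic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   y = -log10(.data$q),
                                   color = .data$q < alpha)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#D55E00",
                                           `FALSE` = "grey50"),
                                name = paste0("q < ", alpha)) +
    ggplot2::labs(x = "Moran's I", y = expression(-log[10]~q)) +
    ggplot2::theme_minimal()
}

#' Summarize an sv_result
#'
#' @param x An `sv_result`.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return One-row tibble: genes tested, significant count, scopes.
#' @export
glance.sv_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_genes = dplyr::n_distinct(x$gene),
                 n_tests = nrow(x),
                 n_significant = sum(x$q < alpha, na.rm = TRUE),
                 scopes = paste(unique(x$scope), collapse = ","))
}
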