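#' Build a cell adjacency map
#'
#' Neighborhood definition for cell-cell interaction analysis. For
#' pseudo-cells (multi-cell resolution) the natural notion is
#' `mode = "same_location"`: pseudo-cells deconvolved from the same
#' capture location are mutual neighbors. For single-cell resolution
#' data, `mode = "radius"` links cells within `radius_um` micrometers
#' (Euclidean, boundary inclusive).
#'
#' @param cells A `pseudo_cells` object or an annotated
#'   [normalized_sample()] with coordinates.
#' @param mode `"same_location"` (pseudo-cells only) or `"radius"`.
#' @param radius_um Neighborhood radius in micrometers (default 30).
#' @return An `adjacency_map`: list with `neighbors` (list of integer
#'   neighbor indices per cell, symmetric, no self-neighbors), `ids`,
#'   and `mode`.
#' @export
build_adjacency <- function(cells, mode = c("same_location", "radius"),
                            radius_um = 30) {
  mode <- match.arg(mode)
  if (mode == "same_location") {
    stopifnot(inherits(cells, "pseudo_cells"))
    ids <- cells$cells$pseudo_cell_id
    groups <- split(seq_along(ids), cells$cells$location_id)
    nb <- vector("list", length(ids))
    for (g in groups) for (i in g) nb[[i]] <- setdiff(g, i)
  } else {
    if (radius_um <= 0) abort("radius_um must be positive.")
    cm <- coords_matrix(cells)
    ids <- if (inherits(cells, "pseudo_cells")) cells$cells$pseudo_cell_id
           else colnames(cells$expr)
    d <- as.matrix(stats::dist(cm))
    diag(d) <- Inf
    nb <- lapply(seq_len(nrow(d)),
                 function(i) unname(which(d[i, ] <= radius_um)))
  }
  structure(list(neighbors = nb, ids = ids, mode = mode),
            class = "adjacency_map")
}

#' @export
print.adjacency_map <- function(x, ...) {
  cat("<adjacency_map> ", length(x$ids), " cells, mode = ", x$mode,
      ", mean degree = ",
      round(mean(lengths(x$neighbors)), 2), "\n", sep = "")
  invisible(x)
}

cell_labels <- function(cells) {
  if (inherits(cells, "pseudo_cells")) cells$cells$cell_type
  else cells$annotations
}

#' Neighborhood-based cell-cell interaction test
#'
#' Asks whether gene expression in a query cell type (CT_Q) is shifted
#' when an interacting cell type (CT_I) sits in its neighborhood.
#' Query cells with at least one CT_I neighbor form the "adjacent"
#' group; those with none form the "nonadjacent" group; each gene is
#' compared between the groups with a Wilcoxon rank-sum test under the
#' same fold-change/detection filters as [find_markers()] (disable with
#' `apply_filters = FALSE`). Positive `log2_fc` means the interacting
#' type appears to promote the gene in the query type.
#'
#' @param cells A `pseudo_cells` object or annotated sample.
#' @param adj An `adjacency_map` over the same cells.
#' @param ct_q Query cell type.
#' @param ct_i Interacting cell type.
#' @inheritParams find_markers
#' @param apply_filters Apply the marker inclusion filters before
#'   testing (default `TRUE`).
#' @return Tibble `cci_neighborhood`: `gene`, `query_type`,
#'   `interactor_type`, `log2_fc`, `p`, `q`, `n_adjacent`,
#'   `n_nonadjacent`. Empty (with a warning) when one of the groups is
#'   empty.
#' @export
neighborhood_cci <- function(cells, adj, ct_q, ct_i, min_lfc = 0.1,
                             min_pct = 0.1, apply_filters = TRUE) {
  stopifnot(inherits(adj, "adjacency_map"))
  em <- expr_matrix(cells)
  labels <- cell_labels(cells)
  stopifnot(length(labels) == length(adj$ids))
  if (!ct_q %in% labels || !ct_i %in% labels) {
    abort("both cell types must be present.")
  }
  q_idx <- which(labels == ct_q)
  has_i <- vapply(adj$neighbors[q_idx],
                  function(nb) any(labels[nb] == ct_i), logical(1))
  adj_idx <- q_idx[has_i]
  non_idx <- q_idx[!has_i]
  empty <- {
    out <- tibble::tibble(gene = character(), query_type = character(),
                          interactor_type = character(), log2_fc = numeric(),
                          p = numeric(), q = numeric(),
                          n_adjacent = integer(), n_nonadjacent = integer())
    class(out) <- c("cci_neighborhood", class(out))
    out
  }
  if (!length(adj_idx) || !length(non_idx)) {
    warn("no adjacent/nonadjacent split for this cell-type pair; empty result.")
    return(empty)
  }
  mean_a <- rowMeans(em[, adj_idx, drop = FALSE])
  mean_n <- rowMeans(em[, non_idx, drop = FALSE])
  lfc <- log2_fc(mean_a, mean_n)
  if (apply_filters) {
    pct_a <- rowMeans(em[, adj_idx, drop = FALSE] > 0)
    pct_n <- rowMeans(em[, non_idx, drop = FALSE] > 0)
    keep <- abs(lfc) >= min_lfc & pmax(pct_a, pct_n) >= min_pct
  } else {
    keep <- rep(TRUE, nrow(em))
  }
  if (!any(keep)) return(empty)
  p <- ranksum_matrix(em[keep, , drop = FALSE], adj_idx, non_idx)
  out <- tibble::tibble(gene = rownames(em)[keep], query_type = ct_q,
                        interactor_type = ct_i,
                        log2_fc = unname(lfc[keep]), p = unname(p),
                        q = p.adjust(p, "BH"),
                        n_adjacent = length(adj_idx),
                        n_nonadjacent = length(non_idx))
  out <- dplyr::arrange(out, .data$q, .data$gene)
  class(out) <- c("cci_neighborhood", class(out))
  out
}

#' Distance-based cell-cell interaction scoring
#'
#' Ligand-receptor signaling over distance: for each (pathway, sender
#' type, receiver type, distance threshold), the score of one
#' ligand-receptor pair is the mean over ordered cell pairs
#' (sender a, receiver b, a != b, distance <= d) of
#' `ligand_expr(a) * receptor_expr(b)` (0 when no pair is in range); a
#' pathway's score sums its pairs' scores. Significance comes from
#' permuting cell-type labels `n_perm` times (add-one rule, upper
#' tail), with BH adjustment across all result rows. Outputs are tagged
#' `method = "threshold_lr"`.
#'
#' @param cells A `pseudo_cells` object or annotated sample.
#' @param lr Ligand-receptor table (`pathway`, `ligand`, `receptor`);
#'   pairs with genes missing from the data are skipped with a warning.
#' @param thresholds_um Distance thresholds in micrometers
#'   (default 500, 1000, 1500).
#' @param n_perm Label permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @param sender_types,receiver_types Optional restriction of the
#'   type pairs scored (defaults: all ordered pairs of distinct types).
#' @return Tibble `cci_distance`: `pathway`, `sender_type`,
#'   `receiver_type`, `distance_threshold`, `score`, `p`, `q`, `method`.
#' @export
distance_cci <- function(cells, lr, thresholds_um = c(500, 1000, 1500),
                         n_perm = 1000, seed = 1, sender_types = NULL,
                         receiver_types = NULL) {
  em <- expr_matrix(cells)
  labels <- cell_labels(cells)
  cm <- coords_matrix(cells)
  lr <- tibble::as_tibble(lr)
  known <- lr$ligand %in% rownames(em) & lr$receptor %in% rownames(em)
  if (any(!known)) {
    warn(paste0(sum(!known), " ligand-receptor pair(s) skipped: gene(s) ",
                "absent from the expression data."))
    lr <- lr[known, , drop = FALSE]
  }
  types <- sort(unique(labels))
  sender_types <- sender_types %||% types
  receiver_types <- receiver_types %||% types
  d <- as.matrix(stats::dist(cm))

  # per (sender, receiver, threshold): mean over in-range ordered pairs
  # of L(a) * R(b), for each LR pair; pathway score sums its pairs
  score_block <- function(lab) {
    out <- list(); k <- 1L
    for (st in sender_types) for (rt in receiver_types) {
      if (st == rt && sum(lab == st) < 2L) next
      a_idx <- which(lab == st); b_idx <- which(lab == rt)
      if (!length(a_idx) || !length(b_idx)) next
      dd <- d[a_idx, b_idx, drop = FALSE]
      self <- outer(a_idx, b_idx, `==`)
      for (th in thresholds_um) {
        in_range <- dd <= th & !self
        n_pairs <- sum(in_range)
        sc <- purrr::pmap_dbl(lr, function(pathway, ligand, receptor, ...) {
          if (n_pairs == 0L) return(0)
          lp <- em[ligand, a_idx]; rp <- em[receptor, b_idx]
          as.numeric(lp %*% in_range %*% rp) / n_pairs
        })
        out[[k]] <- tibble::tibble(pathway = lr$pathway, sender_type = st,
                                   receiver_type = rt,
                                   distance_threshold = th, score = sc)
        k <- k + 1L
      }
    }
    dplyr::bind_rows(out) |>
      dplyr::summarise(score = sum(.data$score),
                       .by = c("pathway", "sender_type", "receiver_type",
                               "distance_threshold"))
  }

  obs <- score_block(labels)
  if (nrow(obs) == 0L || nrow(lr) == 0L) {
    out <- tibble::tibble(pathway = character(), sender_type = character(),
                          receiver_type = character(),
                          distance_threshold = numeric(), score = numeric(),
                          p = numeric(), q = numeric(), method = character())
    class(out) <- c("cci_distance", class(out))
    return(out)
  }
  exceed <- rep(0L, nrow(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_scores <- score_block(sample(labels))
      exceed <- exceed + as.integer(perm_scores$score >= obs$score)
    }
  })
  obs$p <- (exceed + 1) / (n_perm + 1)
  obs$q <- p.adjust(obs$p, "BH")
  obs$method <- "threshold_lr"
  class(obs) <- c("cci_distance", class(obs))
  attr(obs, "seed") <- seed
  obs
}
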