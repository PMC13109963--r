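#' Clip noisy cell-type fractions to zero
#'
#' Predicted fractions whose posterior coefficient of variation exceeds
#' `cv_max` are set to zero to reduce deconvolution noise. The bound is
#' strict: a fraction with CV exactly `cv_max` is retained. No
#' renormalization is performed, so per-location sums may fall below 1
#' after clipping.
#'
#' @param f A [fraction_matrix()].
#' @param cv_max Clip threshold on the coefficient of variation
#'   (default 0.5).
#' @return A `fraction_matrix` with the noisy entries zeroed.
#' @export
clip_fractions <- function(f, cv_max = 0.5) {
  stopifnot(inherits(f, "fraction_matrix"))
  if (any(f$cv < 0)) abort("coefficients of variation must be non-negative.")
  fr <- f$fractions
  fr[f$cv > cv_max] <- 0
  fraction_matrix(fr, f$cv)
}

#' Build pseudo-cells from deconvolved expression
#'
#' For every (cell type, capture location) pair with a positive clipped
#' fraction, one pseudo-cell is emitted whose expression is the
#' cell-type-specific deconvolved expression at that location divided by
#' the fraction, and whose coordinates are those of the origin location.
#' Pairs with zero fraction are discarded; the per-type record sets are
#' combined into one `pseudo_cells` object.
#'
#' Division by a vanishing fraction explodes expression values, so
#' fractions below `min_fraction` are also discarded (and counted in the
#' attribute `n_below_min_fraction`).
#'
#' @param d Named list of gene-by-location deconvolved expression
#'   matrices, one per cell type (see [read_deconvolved()]).
#' @param f A clipped [fraction_matrix()] covering the same cell types
#'   and locations.
#' @param s The parent [spatial_sample()] (source of coordinates).
#' @param min_fraction Positive fractions below this are discarded for
#'   numerical stability (default 0.01).
#' @return An object of class `pseudo_cells`: `expr` (gene x pseudo-cell
#'   matrix) and `cells` (tibble with `pseudo_cell_id`, `cell_type`,
#'   `location_id`, `x`, `y`).
#' @export
build_pseudocells <- function(d, f, s, min_fraction = 0.01) {
  stopifnot(inherits(f, "fraction_matrix"), inherits(s, "spatial_sample"))
  missing_types <- setdiff(f$cell_types[rowSums(f$fractions > 0) > 0],
                           names(d))
  if (length(missing_types)) {
    abort(paste0("cell type '", missing_types[1],
                 "' has positive fractions but no deconvolved expression."))
  }
  locs <- colnames(f$fractions)
  stopifnot(all(locs %in% s$coords$location_id))
  coord <- s$coords[match(locs, s$coords$location_id), ]

  n_small <- 0L
  pieces <- lapply(f$cell_types, function(ct) {
    fr <- f$fractions[ct, ]
    pos <- fr > 0
    small <- pos & fr < min_fraction
    n_small <<- n_small + sum(small)
    use <- which(pos & !small)
    if (!length(use)) return(NULL)
    dm <- d[[ct]]
    if (is.null(dm) || !all(locs[use] %in% colnames(dm))) {
      abort(paste0("positive fraction at a location lacking deconvolved ",
                   "expression for cell type '", ct, "'"))
    }
    expr <- sweep(dm[, locs[use], drop = FALSE], 2, fr[use], `/`)
    colnames(expr) <- paste(ct, locs[use], sep = "@")
    list(expr = expr,
         cells = tibble::tibble(pseudo_cell_id = colnames(expr),
                                cell_type = ct,
                                location_id = locs[use],
                                x = coord$x[use], y = coord$y[use]))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    ps <- structure(list(expr = matrix(0, 0, 0),
                         cells = tibble::tibble(pseudo_cell_id = character(),
                                                cell_type = character(),
                                                location_id = character(),
                                                x = numeric(), y = numeric())),
                    class = "pseudo_cells")
    attr(ps, "n_below_min_fraction") <- n_small
    return(ps)
  }
  ps <- structure(
    list(expr = do.call(cbind, lapply(pieces, `[[`, "expr")),
         cells = dplyr::bind_rows(lapply(pieces, `[[`, "cells"))),
    class = "pseudo_cells")
  attr(ps, "n_below_min_fraction") <- n_small
  ps
}

#' @export
print.pseudo_cells <- function(x, ...) {
  cat("<pseudo_cells> ", ncol(x$expr), " pseudo-cells x ", nrow(x$expr),
      " genes (", dplyr::n_distinct(x$cells$cell_type), " cell types)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.pseudo_cells <- function(x) dim(x$expr)

#' Tidy a pseudo-cell set into long format
#'
#' @param x A `pseudo_cells` object.
#' @param ... Unused.
#' @return Long tibble: `pseudo_cell_id`, `cell_type`, `location_id`,
#'   `x`, `y`, `gene`, `value`.
#' @export
tidy.pseudo_cells <- function(x, ...) {
  long <- tibble::as_tibble(x$expr, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "pseudo_cell_id",
                        values_to = "value")
  dplyr::left_join(long, x$cells, by = "pseudo_cell_id")[
    , c("pseudo_cell_id", "cell_type", "location_id", "x", "y",
        "gene", "value")]
}

#' Write pseudo-cells as long-format TSV
#'
#' @param ps A `pseudo_cells` object.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pseudocells <- function(ps, path) {
  readr::write_tsv(tidy(ps), path, progress = FALSE)
  invisible(path)
}
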