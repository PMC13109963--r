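#' Construct a spatial sample
#'
#' The universal pipeline input: a gene-by-capture-location matrix of raw
#' UMI counts together with Cartesian coordinates (micrometers) for each
#' capture location and a technology class that decides which quality
#' control protocol applies downstream.
#'
#' @param counts Non-negative integer matrix, genes in rows (unique
#'   symbols as rownames), capture locations in columns (unique ids as
#'   colnames). Dense or `Matrix` sparse.
#' @param coords Data frame with columns `location_id`, `x`, `y`
#'   (micrometers). Must cover exactly the columns of `counts`.
#' @param technology One of `"multi_cell"` (spot-based, several cells per
#'   location), `"single_cell"` (imaging-based, one cell per location) or
#'   `"slide_seq"` (bead-based).
#' @param sample_id Free-text sample identifier.
#' @param mito_genes Character vector of mitochondrial gene symbols;
#'   must be a subset of the rownames of `counts`.
#' @param annotations Optional named character vector of per-location
#'   cell-type labels (single-cell class only); names are location ids.
#'
#' @return An object of class `spatial_sample`.
#' @export
spatial_sample <- function(counts, coords, technology, sample_id = "sample",
                           mito_genes = character(), annotations = NULL) {
  technology <- match.arg(technology, c("multi_cell", "single_cell", "slide_seq"))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (nrow(counts) > 0 && is.null(rownames(counts)) ||
      ncol(counts) > 0 && is.null(colnames(counts))) {
    abort("`counts` must carry gene symbols as rownames and location ids as colnames.")
  }
  dimnames(counts) <- list(rownames(counts) %||% character(0),
                           colnames(counts) %||% character(0))
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort(paste0("duplicate gene symbol in counts: '", dup, "'"))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    abort(paste0("duplicate location id in counts: '", dup, "'"))
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != trunc(v)))) {
    abort("counts must be non-negative integers.")
  }
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("location_id", "x", "y") %in% names(coords)))
  coords$location_id <- as.character(coords$location_id)
  missing_in_coords <- setdiff(colnames(counts), coords$location_id)
  if (length(missing_in_coords)) {
    abort(paste0("location id mismatch between counts and coords: '",
                 missing_in_coords[1], "' has no coordinates."))
  }
  extra <- setdiff(coords$location_id, colnames(counts))
  if (length(extra)) {
    abort(paste0("location id mismatch between counts and coords: '",
                 extra[1], "' is absent from the count matrix."))
  }
  coords <- coords[match(colnames(counts), coords$location_id),
                   c("location_id", "x", "y")]
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    abort("coordinates must be finite.")
  }
  bad_mito <- setdiff(mito_genes, rownames(counts))
  if (length(bad_mito)) {
    abort(paste0("mito_genes not present in counts: '", bad_mito[1], "'"))
  }
  if (!is.null(annotations)) {
    annotations <- annotations[colnames(counts)]
    names(annotations) <- colnames(counts)
  }
  structure(
    list(sample_id = sample_id, technology = technology, counts = counts,
         coords = coords, mito_genes = as.character(mito_genes),
         annotations = annotations),
    class = "spatial_sample"
  )
}

#' @export
print.spatial_sample <- function(x, ...) {
  cat("<spatial_sample> ", x$sample_id, "\n",
      "  technology: ", x$technology, "\n",
      "  ", nrow(x$counts), " genes x ", ncol(x$counts), " locations\n",
      "  mitochondrial genes flagged: ", length(x$mito_genes), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_sample <- function(x) dim(x$counts)

gene_ids <- function(s) rownames(s$counts)
location_ids <- function(s) colnames(s$counts)

#' Read a spatial sample from disk
#'
#' Reads raw counts plus coordinates and returns a validated
#' [spatial_sample()]. Counts may be a gene-by-location TSV with a header
#' row (first column = gene symbol) or a MatrixMarket `.mtx` triplet file
#' with sidecar gene and location id lists (one id per line).
#'
#' @inheritParams spatial_sample
#' @param counts_path Path to the TSV or `.mtx` count matrix.
#' @param coords_path Path to a TSV with columns `location_id`, `x`, `y`.
#' @param mito_prefix Gene symbols starting with this prefix are flagged
#'   mitochondrial (default `"MT-"`).
#' @param genes_path,locations_path Sidecar id files, required when
#'   `counts_path` is MatrixMarket; default to `<counts_path>.genes` /
#'   `<counts_path>.locations`.
#'
#' @return A `spatial_sample`.
#' @export
read_spatial_sample <- function(counts_path, coords_path, technology,
                                mito_prefix = "MT-", sample_id = "sample",
                                genes_path = NULL, locations_path = NULL) {
  if (grepl("\\.mtx$", counts_path)) {
    m <- Matrix::readMM(counts_path)
    genes_path <- genes_path %||% paste0(counts_path, ".genes")
    locations_path <- locations_path %||% paste0(counts_path, ".locations")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(locations_path)
  } else {
    df <- readr::read_tsv(counts_path, show_col_types = FALSE,
                          progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  coords <- readr::read_tsv(coords_path, show_col_types = FALSE,
                            progress = FALSE)
  mito <- rownames(m)[startsWith(rownames(m), mito_prefix)]
  spatial_sample(m, coords, technology, sample_id = sample_id,
                 mito_genes = mito)
}

#' Write a spatial sample's counts and coordinates as TSV
#'
#' @param s A `spatial_sample`.
#' @param counts_path,coords_path Output paths.
#' @return `s`, invisibly.
#' @export
write_spatial_sample <- function(s, counts_path, coords_path) {
  df <- tibble::as_tibble(as.matrix(s$counts))
  df <- dplyr::bind_cols(tibble::tibble(gene = gene_ids(s)), df)
  readr::write_tsv(df, counts_path, progress = FALSE)
  readr::write_tsv(s$coords, coords_path, progress = FALSE)
  invisible(s)
}

#' Construct a normalized sample
#'
#' @param s The post-QC `spatial_sample` the expression derives from.
#' @param expr Finite real matrix, same dimnames as `s$counts`.
#' @param normalization_tag Text describing the method applied.
#' @return An object of class `normalized_sample`.
#' @export
normalized_sample <- function(s, expr, normalization_tag) {
  stopifnot(identical(dim(expr), dim(s$counts)),
            all(is.finite(expr)))
  structure(
    list(sample_id = s$sample_id, technology = s$technology,
         expr = expr, coords = s$coords, mito_genes = s$mito_genes,
         annotations = s$annotations, normalization_tag = normalization_tag),
    class = "normalized_sample"
  )
}

#' @export
print.normalized_sample <- function(x, ...) {
  cat("<normalized_sample> ", x$sample_id, " (", x$normalization_tag, ")\n",
      "  ", nrow(x$expr), " genes x ", ncol(x$expr), " locations\n", sep = "")
  invisible(x)
}

#' @export
dim.normalized_sample <- function(x) dim(x$expr)

#' Construct a cell-type fraction matrix
#'
#' Per-location predicted cell-type fractions from an upstream
#' deconvolution tool, together with the posterior coefficient of
#' variation of each prediction.
#'
#' @param fractions Cell-type-by-location matrix with entries in
#'   \eqn{[0, 1]}; per-location sums may not exceed 1 (tolerance 1e-6).
#' @param cv Non-negative matrix of the same shape: the coefficient of
#'   variation of each predicted fraction.
#' @return An object of class `fraction_matrix`.
#' @export
fraction_matrix <- function(fractions, cv) {
  fractions <- as.matrix(fractions)
  cv <- as.matrix(cv)
  stopifnot(identical(dim(fractions), dim(cv)),
            !is.null(rownames(fractions)), !is.null(colnames(fractions)))
  if (any(fractions < 0) || any(fractions > 1)) {
    abort("fractions must lie in [0, 1].")
  }
  if (any(cv < 0)) abort("coefficients of variation must be non-negative.")
  sums <- colSums(fractions)
  if (any(sums > 1 + 1e-6)) {
    abort(paste0("fractions at location '",
                 colnames(fractions)[which(sums > 1 + 1e-6)[1]],
                 "' sum to more than 1."))
  }
  dimnames(cv) <- dimnames(fractions)
  structure(list(fractions = fractions, cv = cv,
                 cell_types = rownames(fractions)),
            class = "fraction_matrix")
}

#' @export
print.fraction_matrix <- function(x, ...) {
  cat("<fraction_matrix> ", length(x$cell_types), " cell types x ",
      ncol(x$fractions), " locations\n", sep = "")
  invisible(x)
}

#' Read cell-type fractions and their coefficients of variation
#'
#' Both files are cell-type-by-location TSVs whose first column holds the
#' cell-type label.
#'
#' @param fractions_path,cv_path TSV paths.
#' @return A `fraction_matrix`.
#' @export
read_fraction_matrix <- function(fractions_path, cv_path) {
  rd <- function(p) {
    df <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  fraction_matrix(rd(fractions_path), rd(cv_path))
}

#' Read cell-type-specific deconvolved expression
#'
#' One gene-by-location TSV per cell type (first column = gene symbol);
#' `paths` is a named list/vector, names being the cell types.
#'
#' @param paths Named character vector of TSV paths.
#' @return Named list of gene-by-location matrices.
#' @export
read_deconvolved <- function(paths) {
  stopifnot(!is.null(names(paths)))
  lapply(paths, function(p) {
    df <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (any(m < 0)) abort("deconvolved expression must be non-negative.")
    m
  })
}
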