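#' Construct a drug perturbation profile library
#'
#' A gene-by-signature matrix of perturbation z-scores together with
#' signature metadata (compound, cell line, dose, treatment time). `r`,
#' the number of genes in the profile, is the denominator of the
#' enrichment-score rank ratios.
#'
#' @param zscores Finite real matrix, genes in rows, signatures in
#'   columns.
#' @param signatures Data frame with columns `signature_id`, `compound`
#'   and optionally `cell_line`, `dose`, `time_h`; one row per column of
#'   `zscores`.
#' @return An object of class `profile_library` with elements `zscores`,
#'   `signatures` (tibble) and `r`.
#' @export
profile_library <- function(zscores, signatures) {
  zscores <- as.matrix(zscores)
  stopifnot(!is.null(rownames(zscores)), !is.null(colnames(zscores)))
  if (!all(is.finite(zscores))) abort("z-scores must be finite.")
  signatures <- tibble::as_tibble(signatures)
  stopifnot(all(c("signature_id", "compound") %in% names(signatures)))
  signatures$signature_id <- as.character(signatures$signature_id)
  if (anyDuplicated(signatures$signature_id)) {
    abort("signature ids must be unique.")
  }
  orphans <- setdiff(colnames(zscores), signatures$signature_id)
  if (length(orphans)) {
    abort(paste0("signatures missing metadata: ",
                 paste(orphans, collapse = ", ")))
  }
  signatures <- signatures[match(colnames(zscores), signatures$signature_id), ]
  structure(list(zscores = zscores, signatures = signatures,
                 r = nrow(zscores)),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat("<profile_library> r = ", x$r, " genes x ", ncol(x$zscores),
      " signatures (", dplyr::n_distinct(x$signatures$compound),
      " compounds)\n", sep = "")
  invisible(x)
}

#' Read a perturbation library from GCT 1.2 or wide TSV
#'
#' GCT 1.2: a `#1.2` header line, a dimensions line (`n_genes n_signatures`),
#' then a header row (`Name`, `Description`, signature ids) and one row per
#' gene. Wide TSV: header row, first column = gene symbol. Signatures
#' present in the matrix but absent from the metadata are a hard error.
#'
#' @param path GCT (`.gct`) or wide TSV matrix of z-scores.
#' @param meta_path TSV with columns `signature_id`, `compound`, and
#'   optionally `cell_line`, `dose`, `time_h`.
#' @return A [profile_library()].
#' @export
read_profile_library <- function(path, meta_path) {
  if (grepl("\\.gct$", path)) {
    z <- read_gct(path)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    z <- as.matrix(df[, -1, drop = FALSE])
    rownames(z) <- as.character(df[[1]])
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  profile_library(z, meta)
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    abort("not a GCT 1.2 file: first line must be '#1.2'.")
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "[ \t]+")[[1]]))
  if (length(dims) != 2 || anyNA(dims) || any(dims < 0)) {
    abort(paste0("malformed GCT dims line: '", lines[2], "'"))
  }
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != dims[2] + 2) {
    abort("GCT header row does not match the dims line.")
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != dims[1]) {
    abort("GCT row count does not match the dims line.")
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  z <- t(vapply(fields, function(f) as.numeric(f[-(1:2)]),
                numeric(dims[2])))
  if (dims[2] == 1L) z <- matrix(z, ncol = 1L)
  rownames(z) <- vapply(fields, `[[`, character(1), 1L)
  colnames(z) <- header[-(1:2)]
  z
}

#' Write a z-score matrix as GCT 1.2
#'
#' @param zscores Gene-by-signature matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(zscores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(zscores), ncol(zscores), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(zscores)),
                   collapse = "\t"), con)
  body <- apply(zscores, 1, function(row)
    paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(zscores), "na", body, sep = "\t"), con)
  invisible(path)
}

#' Rank one signature's genes by perturbation z-score
#'
#' Rank 1 is the most down-regulated gene (lowest z-score); ties are
#' broken by gene symbol, lexicographically, for determinism. Set
#' `descending = TRUE` to flip the orientation (rank 1 = most
#' up-regulated) for sensitivity checks.
#'
#' @param lib A [profile_library()].
#' @param signature_id Signature to rank.
#' @param descending Flip the rank direction (default `FALSE`).
#' @return An object of class `ranked_profile`: `signature_id`, `rank`
#'   (named integer vector gene -> rank, a permutation of `1..r`) and `r`.
#' @export
rank_profile <- function(lib, signature_id, descending = FALSE) {
  stopifnot(inherits(lib, "profile_library"))
  if (!signature_id %in% colnames(lib$zscores)) {
    abort(paste0("unknown signature: '", signature_id, "'"))
  }
  z <- lib$zscores[, signature_id]
  if (descending) z <- -z
  genes <- rownames(lib$zscores)
  ord <- order(z, genes, method = "radix")
  rk <- integer(lib$r)
  rk[ord] <- seq_len(lib$r)
  structure(list(signature_id = signature_id,
                 rank = setNames(rk, genes), r = lib$r),
            class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat("<ranked_profile> ", x$signature_id, " (r = ", x$r, ")\n", sep = "")
  invisible(x)
}

#' Read a protein-protein interactome edge list
#'
#' Two-column TSV (header optional, detected) of undirected interactions.
#' Self-loops are dropped and edges deduplicated regardless of order.
#'
#' @param path Edge-list TSV.
#' @return A tibble with columns `gene_a`, `gene_b` (canonical order
#'   `gene_a < gene_b`), class `interactome`.
#' @export
read_interactome <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_names = c("gene_a", "gene_b"), skip = 0)
  if (identical(unname(tolower(as.character(df[1, ]))),
                c("gene_a", "gene_b"))) {
    df <- df[-1, ]
  }
  interactome(df)
}

#' Construct an interactome from an edge data frame
#'
#' @param edges Data frame whose first two columns are interacting gene
#'   symbols.
#' @return A deduplicated, self-loop-free `interactome` tibble.
#' @export
interactome <- function(edges) {
  edges <- tibble::as_tibble(edges)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- dplyr::distinct(tibble::tibble(gene_a = lo, gene_b = hi))
  class(out) <- c("interactome", class(out))
  out
}

#' Read a ligand-receptor pathway table
#'
#' Three-column TSV: `pathway`, `ligand`, `receptor`. Duplicate rows are
#' dropped.
#'
#' @param path TSV path.
#' @return A tibble with columns `pathway`, `ligand`, `receptor`.
#' @export
read_lr_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:3] <- c("pathway", "ligand", "receptor")
  dplyr::distinct(df[, c("pathway", "ligand", "receptor")])
}
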