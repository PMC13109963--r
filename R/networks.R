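#' Extract the PPI module of a cell type's top DEGs
#'
#' Takes up to `max_genes` most significant DEGs of one cell type
#' (smallest q, ties by `|log2_fc|` descending then symbol), optionally
#' filtered to the genes spatially variable in that cell type, and
#' returns the induced subgraph of the protein-protein interactome on
#' those genes. Genes without interactions stay as isolated nodes.
#'
#' @param deg A `deg_table`.
#' @param cell_type Cell type to extract.
#' @param ppi An [interactome()] edge tibble.
#' @param sv Optional `sv_result` (celltype scope) used as a filter.
#' @param max_genes Cap on selected DEGs (default 300).
#' @param alpha Significance threshold for DEGs and the SV filter
#'   (default 0.05).
#' @return An [igraph::graph] with vertex attributes `log2_fc` and `q`.
#' @export
extract_ppi_module <- function(deg, cell_type, ppi, sv = NULL,
                               max_genes = 300, alpha = 0.05) {
  rows <- deg[deg$cell_type == cell_type, ]
  if (nrow(rows) == 0L) {
    abort(paste0("cell type '", cell_type, "' absent from the DEG table."))
  }
  rows <- rows[rows$q < alpha, ]
  if (!is.null(sv) && any(sv$cell_type == cell_type, na.rm = TRUE)) {
    sv_genes <- sv$gene[!is.na(sv$cell_type) & sv$cell_type == cell_type &
                          sv$q < alpha]
    rows <- rows[rows$gene %in% sv_genes, ]
  }
  rows <- rows[order(rows$q, -abs(rows$log2_fc), rows$gene), ]
  rows <- head(rows, max_genes)
  genes <- rows$gene
  edges <- ppi[ppi$gene_a %in% genes & ppi$gene_b %in% genes, ]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = genes, log2_fc = rows$log2_fc,
                          q = rows$q))
  g
}

#' Build a drug perturbation network
#'
#' Overlays the strongest enrichment hits on a PPI module: up to
#' `top_n` significant inversely related compounds (`ES > 0`,
#' `q < alpha`, ranked by ES descending) and up to `top_n` significant
#' positively related compounds (`ES < 0`, ranked ascending) become
#' compound nodes; a drug-gene edge links a compound to every module
#' gene its summary signature perturbs with `|z| >= z_min`, weighted by
#' that z-score. Module genes keep their PPI edges and carry `log2_fc`
#' and degree attributes.
#'
#' @param records A `drug_enrichment` for one query (compound level
#'   used).
#' @param lib The scored [profile_library()] (source of z-scores).
#' @param module PPI module graph from [extract_ppi_module()].
#' @param deg The `deg_table` (source of gene fold changes).
#' @param top_n Cap per direction (default 500).
#' @param alpha Significance threshold (default 0.05).
#' @param z_min Perturbation edge threshold on `|z|` (default 2).
#' @return Object of class `perturbation_network`: list with `nodes`
#'   and `edges` tibbles and `graph` (igraph).
#' @export
build_perturbation_network <- function(records, lib, module, deg,
                                       top_n = 500, alpha = 0.05,
                                       z_min = 2) {
  cmp <- if (inherits(records, "drug_enrichment")) records$compounds
         else tibble::as_tibble(records)
  if (nrow(cmp) && dplyr::n_distinct(cmp$query) > 1L) {
    abort("build the network for one query at a time.")
  }
  sig <- cmp[cmp$q < alpha, ]
  inverse <- head(sig[sig$es > 0, ][order(-sig$es[sig$es > 0]), ], top_n)
  positive <- head(sig[sig$es < 0, ][order(sig$es[sig$es < 0]), ], top_n)
  drugs <- dplyr::bind_rows(
    dplyr::mutate(inverse, relation = "inverse"),
    dplyr::mutate(positive, relation = "positive"))

  genes <- igraph::V(module)$name
  gene_lfc <- setNames(igraph::V(module)$log2_fc, genes)

  drug_edges <- purrr::pmap(
    drugs[, c("compound", "signature_id")],
    function(compound, signature_id) {
      z <- lib$zscores[, signature_id]
      common <- intersect(genes, names(z))
      hit <- common[abs(z[common]) >= z_min]
      if (!length(hit)) return(NULL)
      tibble::tibble(from = compound, to = hit, type = "drug_gene",
                     weight = unname(z[hit]))
    }) |> dplyr::bind_rows()

  ppi_edges <- if (igraph::ecount(module)) {
    el <- igraph::as_data_frame(module, what = "edges")
    tibble::tibble(from = el$from, to = el$to, type = "ppi",
                   weight = NA_real_)
  } else {
    tibble::tibble(from = character(), to = character(),
                   type = character(), weight = numeric())
  }
  edges <- dplyr::bind_rows(drug_edges, ppi_edges)

  degree_of <- function(id) sum(edges$from == id | edges$to == id)
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = drugs$compound, type = "drug", es = drugs$es,
                   q = drugs$q, relation = drugs$relation,
                   log2_fc = NA_real_),
    tibble::tibble(node = genes, type = "gene", es = NA_real_,
                   q = NA_real_, relation = NA_character_,
                   log2_fc = unname(gene_lfc)))
  nodes$degree <- vapply(nodes$node, degree_of, integer(1))

  graph <- if (nrow(nodes)) {
    igraph::graph_from_data_frame(edges, directed = FALSE,
                                  vertices = as.data.frame(nodes))
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, graph = graph),
            class = "perturbation_network")
}

#' @export
print.perturbation_network <- function(x, ...) {
  cat("<perturbation_network> ",
      sum(x$nodes$type == "drug"), " drugs, ",
      sum(x$nodes$type == "gene"), " genes, ",
      sum(x$edges$type == "drug_gene"), " drug-gene edges, ",
      sum(x$edges$type == "ppi"), " PPI edges\n", sep = "")
  invisible(x)
}

#' Write a perturbation network to disk
#'
#' @param net A `perturbation_network`.
#' @param nodes_path,edges_path TSV outputs.
#' @param graphml_path Optional GraphML output.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, nodes_path, edges_path,
                          graphml_path = NULL) {
  readr::write_tsv(net$nodes, nodes_path, progress = FALSE)
  readr::write_tsv(net$edges, edges_path, progress = FALSE)
  if (!is.null(graphml_path) && igraph::vcount(net$graph) > 0) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(net)
}

#' Plot a perturbation network
#'
#' @param object A `perturbation_network`.
#' @param ... Unused.
#' @return A ggplot of the graph layout (drugs vs genes).
#' @export
autoplot.perturbation_network <- function(object, ...) {
  if (!nrow(object$nodes)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  lay <- igraph::layout_with_fr(object$graph)
  pts <- tibble::tibble(x = lay[, 1], y = lay[, 2],
                        node = igraph::V(object$graph)$name,
                        type = igraph::V(object$graph)$type)
  idx <- setNames(seq_len(nrow(pts)), pts$node)
  segs <- dplyr::mutate(object$edges,
                        x = pts$x[idx[.data$from]],
                        y = pts$y[idx[.data$from]],
                        xend = pts$x[idx[.data$to]],
                        yend = pts$y[idx[.data$to]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend,
                                       linetype = .data$type),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$type), size = 2) +
    ggplot2::theme_void()
}

#' Select candidate compounds across target and protected queries
#'
#' The compound-selection rule of the repurposing engine. A compound is
#' a candidate when:
#' 1. it is significantly inversely related to the target query
#'    (`ES > 0`, `q < alpha`);
#' 2. it is positively or neutrally related (`ES <= 0`) on every
#'    protected query — under the default
#'    `protected_rule = "significant_only"` a compound is only rejected
#'    by a protected query where it is significant (`q < alpha`) with
#'    `ES > 0`; `"point_estimate"` rejects any protected `ES > 0`.
#'    Compounds unscored on a protected query pass it (logged);
#' 3. its summary signature perturbs (`|z| >= z_min`) at least one
#'    module gene or a first neighbor of a module gene in the
#'    interactome.
#'
#' @param records_by_query Named list (query name -> `drug_enrichment`
#'   compound tibble or `drug_enrichment` object), or a single
#'   `drug_enrichment` covering all queries.
#' @param target_type Name of the target (pathological) query; must
#'   have been SV-filtered upstream.
#' @param protected_types Names of the protected (normal) queries.
#' @param module PPI module graph of the target cell type.
#' @param ppi The full [interactome()] (source of first neighbors).
#' @param lib The [profile_library()] (source of z-scores).
#' @param alpha Significance threshold (default 0.05).
#' @param z_min Perturbation threshold (default 2).
#' @param protected_rule `"significant_only"` (default) or
#'   `"point_estimate"`.
#' @return Tibble ranked by target ES: `compound`, `es`, `q`,
#'   `max_protected_es`, `n_perturbed_genes`.
#' @export
select_candidates <- function(records_by_query, target_type,
                              protected_types, module, ppi, lib,
                              alpha = 0.05, z_min = 2,
                              protected_rule = c("significant_only",
                                                 "point_estimate")) {
  protected_rule <- match.arg(protected_rule)
  cmp <- if (inherits(records_by_query, "drug_enrichment")) {
    records_by_query$compounds
  } else if (is.data.frame(records_by_query)) {
    tibble::as_tibble(records_by_query)
  } else {
    dplyr::bind_rows(lapply(records_by_query, function(x)
      if (inherits(x, "drug_enrichment")) x$compounds
      else tibble::as_tibble(x)))
  }
  target <- cmp[cmp$query == target_type, ]
  if (nrow(target) == 0L) {
    abort(paste0("target query '", target_type, "' missing from records."))
  }
  cand <- target[target$es > 0 & target$q < alpha, ]

  # (ii) protected queries
  keep <- vapply(cand$compound, function(co) {
    for (pt in protected_types) {
      row <- cmp[cmp$query == pt & cmp$compound == co, ]
      if (nrow(row) == 0L) {
        inform(paste0("compound '", co, "' unscored on protected query '",
                      pt, "'; passes that query."))
        next
      }
      bad <- if (protected_rule == "point_estimate") row$es[1] > 0
             else row$es[1] > 0 && row$q[1] < alpha
      if (bad) return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- cand[keep, ]

  # (iii) perturbs a module gene or a PPI first neighbor of one
  module_genes <- igraph::V(module)$name
  nb <- unique(c(ppi$gene_b[ppi$gene_a %in% module_genes],
                 ppi$gene_a[ppi$gene_b %in% module_genes]))
  reach <- union(module_genes, nb)
  n_hit <- vapply(seq_len(nrow(cand)), function(i) {
    z <- lib$zscores[, cand$signature_id[i]]
    sum(abs(z[intersect(reach, names(z))]) >= z_min)
  }, integer(1))
  cand$n_perturbed_genes <- if (nrow(cand)) n_hit else integer(0)
  cand <- cand[cand$n_perturbed_genes > 0, ]

  max_prot <- vapply(cand$compound, function(co) {
    rows <- cmp[cmp$query %in% protected_types & cmp$compound == co, ]
    if (nrow(rows)) max(rows$es) else NA_real_
  }, numeric(1))
  out <- tibble::tibble(compound = cand$compound, es = cand$es,
                        q = cand$q, max_protected_es = unname(max_prot),
                        n_perturbed_genes = cand$n_perturbed_genes)
  dplyr::arrange(out, dplyr::desc(.data$es))
}
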