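strx_version <- function() {
  as.character(utils::packageVersion("strx"))
}

# TSV with '#'-prefixed metadata header lines; deterministic content
# (no timestamps), so identical runs produce identical bytes.
write_stage_tsv <- function(df, path, stage, params = list(), seed = NULL) {
  meta <- c(
    paste0("# strx v", strx_version(), " stage=", stage),
    if (!is.null(seed)) paste0("# seed=", seed),
    if (length(params)) paste0("# params=", jsonlite::toJSON(
      params, auto_unbox = TRUE)))
  con <- file(path, "w")
  writeLines(meta, con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Per-stage parameter blocks mirroring the stage functions' arguments,
#' plus input paths and a global seed. [run_pipeline()] merges a user
#' configuration over these defaults and rejects unknown keys.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    out_dir = "strx_out",
    seed = 1L,
    inputs = list(counts = NULL, coords = NULL, technology = "multi_cell",
                  mito_prefix = "MT-", fractions = NULL, cv = NULL,
                  deconvolved = NULL, library = NULL, library_meta = NULL,
                  ppi = NULL, lr = NULL),
    qc = list(enabled = TRUE, min_umi = NULL, min_genes = NULL,
              max_mito = NULL, n_sd = NULL, min_locations = NULL,
              min_gene_umi = NULL, location_filter_first = NULL),
    normalize = list(pseudo_count = 1),
    pseudocell = list(cv_max = 0.5, min_fraction = 0.01),
    sv = list(n_perm = 1000L, k_neighbors = 6L, min_cells = 10L),
    deg = list(min_lfc = 0.1, min_pct = 0.1),
    cci = list(neighborhood = TRUE, distance = TRUE,
               thresholds_um = c(500, 1000, 1500), n_perm = 1000L),
    drugs = list(n_perm = 10000L, alpha = 0.05, collapse = "max_es"),
    network = list(top_n = 500L, alpha = 0.05, z_min = 2),
    select = list(target = NULL, protected = character(0))
  )
}

merge_config <- function(user) {
  base <- default_config()
  check <- function(u, b, path = "") {
    bad <- setdiff(names(u), names(b))
    if (length(bad)) {
      abort(paste0("unknown config key: ", path, bad[1]))
    }
    for (nm in names(u)) {
      if (is.list(b[[nm]]) && is.list(u[[nm]]) &&
          !is.null(names(b[[nm]]))) {
        check(u[[nm]], b[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check(user, base)
  modifyList(base, user)
}

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, pseudo-cell construction, spatial
#' variability, differential expression, cell-cell interaction,
#' drug enrichment, network construction and compound selection in
#' order, skipping any stage whose inputs are absent. Every output
#' table carries a `#`-prefixed header with the package version, stage
#' parameters and seed; the effective configuration is echoed to
#' `effective_config.yaml` in the output directory. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config Nested list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @param sample Optional in-memory [spatial_sample()] overriding the
#'   counts/coords input paths.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), sample = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "effective_config.yaml"))
  seed <- as.integer(cfg$seed)
  res <- list()
  stage <- "input"
  tryCatch({
    # --- input -----------------------------------------------------
    if (is.null(sample)) {
      if (is.null(cfg$inputs$counts)) {
        abort("no sample provided (inputs$counts / `sample`).")
      }
      sample <- read_spatial_sample(cfg$inputs$counts, cfg$inputs$coords,
                                    cfg$inputs$technology,
                                    mito_prefix = cfg$inputs$mito_prefix)
    }

    # --- qc --------------------------------------------------------
    stage <- "qc"
    if (isTRUE(cfg$qc$enabled)) {
      qc_fun <- switch(sample$technology,
                       multi_cell = qc_multicell,
                       single_cell = qc_singlecell,
                       slide_seq = qc_slideseq)
      qc_args <- cfg$qc[setdiff(names(cfg$qc), "enabled")]
      qc_args <- qc_args[!vapply(qc_args, is.null, logical(1))]
      qc_args <- qc_args[intersect(names(qc_args),
                                   names(formals(qc_fun)))]
      qc_res <- do.call(qc_fun, c(list(sample), qc_args))
      sample <- qc_res$sample
      res$qc_report <- qc_res$report
      jsonlite::write_json(
        c(as.list(qc_res$report), list(thresholds = attr(qc_res$report,
                                                         "thresholds"))),
        file.path(cfg$out_dir, "qc_report.json"), auto_unbox = TRUE,
        pretty = TRUE)
    }

    # --- normalize -------------------------------------------------
    stage <- "normalize"
    ns <- normalize_sample(sample, pseudo_count = cfg$normalize$pseudo_count)
    res$normalized <- ns

    # --- pseudocell ------------------------------------------------
    stage <- "pseudocell"
    ps <- NULL
    if (!is.null(cfg$inputs$fractions) && !is.null(cfg$inputs$cv)) {
      f <- read_fraction_matrix(cfg$inputs$fractions, cfg$inputs$cv)
      f <- clip_fractions(f, cv_max = cfg$pseudocell$cv_max)
      dpaths <- cfg$inputs$deconvolved
      if (is.null(dpaths)) {
        inform("no deconvolved expression supplied; pseudo-cell stage skipped.")
      } else {
        d <- read_deconvolved(dpaths)
        # restrict to post-QC locations
        keep <- intersect(colnames(f$fractions), location_ids(sample))
        f <- fraction_matrix(f$fractions[, keep, drop = FALSE],
                             f$cv[, keep, drop = FALSE])
        d <- lapply(d, function(m) m[, keep, drop = FALSE])
        ps <- build_pseudocells(d, f, sample,
                                min_fraction = cfg$pseudocell$min_fraction)
        res$pseudocells <- ps
        write_pseudocells(ps, file.path(cfg$out_dir, "pseudocells.tsv"))
      }
    } else {
      inform("no fraction/CV inputs; pseudo-cell and per-cell-type stages degrade gracefully.")
    }

    # --- spatial variability --------------------------------------
    stage <- "sv"
    sv_whole <- sv_test(ns, scope = "whole", n_perm = cfg$sv$n_perm,
                        seed = seed, k_neighbors = cfg$sv$k_neighbors)
    res$sv_whole <- sv_whole
    write_stage_tsv(sv_whole, file.path(cfg$out_dir, "sv_whole.tsv"),
                    "sv", cfg$sv, seed)
    ct_source <- ps %||% (if (!is.null(ns$annotations)) ns else NULL)
    sv_ct <- NULL
    if (!is.null(ct_source)) {
      sv_ct <- sv_test(ct_source, scope = "celltype",
                       n_perm = cfg$sv$n_perm, seed = seed,
                       k_neighbors = cfg$sv$k_neighbors,
                       min_cells = cfg$sv$min_cells)
      res$sv_celltype <- sv_ct
      write_stage_tsv(sv_ct, file.path(cfg$out_dir, "sv_celltype.tsv"),
                      "sv", cfg$sv, seed)
    }

    # --- differential expression ----------------------------------
    stage <- "deg"
    deg <- NULL
    if (!is.null(ct_source)) {
      deg <- find_markers(ct_source, min_lfc = cfg$deg$min_lfc,
                          min_pct = cfg$deg$min_pct)
      res$deg <- deg
      write_stage_tsv(deg, file.path(cfg$out_dir, "deg.tsv"), "deg",
                      cfg$deg, seed)
    }

    # --- cell-cell interaction ------------------------------------
    stage <- "cci"
    if (!is.null(ct_source) && isTRUE(cfg$cci$neighborhood)) {
      labels <- cell_labels(ct_source)
      types <- sort(unique(labels))
      mode <- if (inherits(ct_source, "pseudo_cells")) "same_location"
              else "radius"
      adj <- build_adjacency(ct_source, mode = mode)
      pairs <- expand.grid(q = types, i = types,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$q != pairs$i, ]
      ncci <- purrr::pmap(pairs, function(q, i) {
        suppressWarnings(neighborhood_cci(ct_source, adj, q, i,
                                          min_lfc = cfg$deg$min_lfc,
                                          min_pct = cfg$deg$min_pct))
      }) |> dplyr::bind_rows()
      res$cci_neighborhood <- ncci
      write_stage_tsv(ncci, file.path(cfg$out_dir,
                                      "cci_neighborhood.tsv"),
                      "cci", cfg$cci, seed)
    }
    if (!is.null(ct_source) && isTRUE(cfg$cci$distance) &&
        !is.null(cfg$inputs$lr)) {
      lr <- read_lr_table(cfg$inputs$lr)
      dcci <- suppressWarnings(
        distance_cci(ct_source, lr, thresholds_um = cfg$cci$thresholds_um,
                     n_perm = cfg$cci$n_perm, seed = seed))
      res$cci_distance <- dcci
      write_stage_tsv(dcci, file.path(cfg$out_dir, "cci_distance.tsv"),
                      "cci", cfg$cci, seed)
    }

    # --- drug discovery -------------------------------------------
    stage <- "drugs"
    if (!is.null(deg) && nrow(deg) && !is.null(cfg$inputs$library)) {
      lib <- read_profile_library(cfg$inputs$library,
                                  cfg$inputs$library_meta)
      queries <- eligible_deg_sets(deg, sv = sv_ct,
                                   alpha = cfg$drugs$alpha)
      if (length(queries)) {
        enr <- score_library(queries, lib, n_perm = cfg$drugs$n_perm,
                             seed = seed, alpha = cfg$drugs$alpha,
                             collapse = cfg$drugs$collapse)
        res$enrichment <- enr
        write_stage_tsv(enr$signatures,
                        file.path(cfg$out_dir,
                                  "enrichment_signatures.tsv"),
                        "drugs", cfg$drugs, seed)
        write_stage_tsv(enr$compounds,
                        file.path(cfg$out_dir,
                                  "enrichment_compounds.tsv"),
                        "drugs", cfg$drugs, seed)

        # --- network + selection ----------------------------------
        stage <- "network"
        target <- cfg$select$target %||% names(queries)[1]
        if (!is.null(cfg$inputs$ppi) && target %in% names(queries)) {
          ppi <- read_interactome(cfg$inputs$ppi)
          module <- extract_ppi_module(deg, target, ppi, sv = sv_ct,
                                       alpha = cfg$drugs$alpha)
          res$module <- module
          one_query <- enr$compounds[enr$compounds$query == target, ]
          net <- build_perturbation_network(
            one_query, lib, module, deg, top_n = cfg$network$top_n,
            alpha = cfg$network$alpha, z_min = cfg$network$z_min)
          res$network <- net
          write_network(net, file.path(cfg$out_dir, "network_nodes.tsv"),
                        file.path(cfg$out_dir, "network_edges.tsv"),
                        file.path(cfg$out_dir, "network.graphml"))

          stage <- "select"
          protected <- intersect(cfg$select$protected, names(queries))
          candidates <- select_candidates(
            enr, target, protected, module, ppi, lib,
            alpha = cfg$drugs$alpha, z_min = cfg$network$z_min)
          res$candidates <- candidates
          write_stage_tsv(candidates,
                          file.path(cfg$out_dir, "candidates.tsv"),
                          "select", cfg$select, seed)
        }
      } else {
        inform("no eligible DEG sets; drug stages skipped.")
      }
    }
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  invisible(res)
}
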