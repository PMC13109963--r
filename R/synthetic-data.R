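#' Simulation configuration
#'
#' Defaults describe a desk-scale spot-based (multi-cell resolution)
#' sample: a 20 x 20 grid at 100 micrometer spacing, 120 genes, 3 cell
#' types laid out in vertical region bands, negative-binomial UMI
#' counts with overdispersion, planted cell-type markers (4-fold),
#' planted spatially variable genes (smooth exponential gradient along
#' x), mitochondrial genes spanning a 2-10% per-location fraction
#' range, Dirichlet cell-type fractions tied to the region layout with
#' a 30% share of high-CV (clippable) entries, and a 200-compound
#' perturbation library with 5 planted reversal compounds at z
#' magnitude 3.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    grid_dims = c(20L, 20L),      # columns, rows
    spacing_um = 100,
    n_genes = 120L,
    n_cell_types = 3L,
    region_layout = "bands",      # vertical bands, one per cell type
    n_markers_per_type = 12L,   # up-regulated and down-regulated each
    marker_fold = 4,
    n_sv_genes = 5L,
    sv_effect = 2,                # log-scale gradient amplitude
    n_mito_genes = 5L,
    mito_frac_range = c(0.02, 0.10),
    libsize_mean = 3000,
    libsize_shape = 20,           # gamma shape of per-location scale
    dispersion = 2,               # negative-binomial size
    technology = "multi_cell",
    fraction_alpha_self = 8,      # Dirichlet weight of the region's type
    fraction_alpha_other = 1,
    cv_high_share = 0.3,          # share of CV entries above 0.5
    deconv_noise_sd = 0,          # lognormal sd on deconvolved expr
    n_compounds = 200L,
    n_signatures_per_compound = 1L,
    n_planted_reversal = 5L,
    planted_z = 3,
    lib_n_genes = NULL,           # default: the sample's gene universe
    ppi_n_edges = 300L,
    n_pathways = 3L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown sim_config field: ", bad[1]))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$n_genes >= cfg$n_mito_genes +
              2 * cfg$n_cell_types * cfg$n_markers_per_type + cfg$n_sv_genes,
            cfg$n_cell_types >= 1, all(cfg$grid_dims >= 1))
  structure(cfg, class = "sim_config")
}

# Shared scaffold of the generative model: grid coordinates, region
# bands, gene identities, cell-type mean expression, the spatial
# gradient, and the Dirichlet fractions tying locations to types.
# Pure function of cfg, so simulate_sample and simulate_fractions
# reconstruct the identical latent state independently.
sim_latent <- function(cfg) {
  nx <- cfg$grid_dims[1]; ny <- cfg$grid_dims[2]
  n_loc <- nx * ny
  if (cfg$n_cell_types > nx) {
    abort("region layout impossible: more cell types than grid columns.")
  }
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  coords <- tibble::tibble(
    location_id = sprintf("L%04d", seq_len(n_loc)),
    x = (col - 1) * cfg$spacing_um,
    y = (row - 1) * cfg$spacing_um)
  types <- paste0("CT", seq_len(cfg$n_cell_types))
  band <- pmin(cfg$n_cell_types, 1L + ((col - 1L) * cfg$n_cell_types) %/% nx)
  region_type <- types[band]

  n_mito <- cfg$n_mito_genes
  gene_ids <- c(paste0("MT-", seq_len(n_mito)),
                sprintf("G%03d", seq_len(cfg$n_genes - n_mito)))
  mito_genes <- gene_ids[seq_len(n_mito)]
  body_genes <- setdiff(gene_ids, mito_genes)
  n_mk <- cfg$n_markers_per_type * cfg$n_cell_types
  marker_genes <- matrix(body_genes[seq_len(n_mk)],
                         ncol = cfg$n_cell_types)
  colnames(marker_genes) <- types
  anti_genes <- matrix(body_genes[n_mk + seq_len(n_mk)],
                       ncol = cfg$n_cell_types)
  colnames(anti_genes) <- types
  sv_genes <- body_genes[2L * n_mk + seq_len(cfg$n_sv_genes)]

  withr::with_seed(sub_seed(cfg$seed, "latent"), {
    # relative abundances; scaled so expected non-mito location total
    # is the configured library size
    abun <- rgamma(length(body_genes), shape = 1, rate = 1) + 0.05
    abun <- abun / sum(abun)
    base_mu <- setNames(abun * cfg$libsize_mean, body_genes)
    mean_expr <- matrix(base_mu, nrow = length(body_genes),
                        ncol = cfg$n_cell_types,
                        dimnames = list(body_genes, types))
    for (ct in types) {
      mean_expr[marker_genes[, ct], ct] <-
        mean_expr[marker_genes[, ct], ct] * cfg$marker_fold
      mean_expr[anti_genes[, ct], ct] <-
        mean_expr[anti_genes[, ct], ct] / cfg$marker_fold
    }
    # Dirichlet fractions favoring the region's own type
    alpha <- matrix(cfg$fraction_alpha_other, nrow = length(types),
                    ncol = n_loc, dimnames = list(types, coords$location_id))
    alpha[cbind(band, seq_len(n_loc))] <- cfg$fraction_alpha_self
    g <- matrix(rgamma(length(alpha), shape = alpha), nrow = length(types))
    fractions <- sweep(g, 2, colSums(g), `/`)
    dimnames(fractions) <- dimnames(alpha)
    list(coords = coords, types = types, band = band,
         region_type = region_type, gene_ids = gene_ids,
         mito_genes = mito_genes, body_genes = body_genes,
         marker_genes = marker_genes, anti_genes = anti_genes,
         sv_genes = sv_genes,
         mean_expr = mean_expr, fractions = fractions,
         grad = exp(cfg$sv_effect * ((coords$x / max(coords$x)) - 0.5)))
  })
}

# Cell-type-specific expected expression at each location: the type's
# mean expression, with the spatial gradient applied to the planted SV
# genes (every type) and to the type's own marker genes — markers are
# both cell-type-specific and spatially variable within their type.
# Gradient directions alternate between graded genes and the graded
# block is rescaled per location to its baseline mass, so the expected
# location total is position-independent: library-size normalization
# then cannot leak spatial structure into the non-graded (null) genes.
sim_type_means <- function(lat, ct) {
  m <- matrix(lat$mean_expr[, ct], nrow = length(lat$body_genes),
              ncol = nrow(lat$coords),
              dimnames = list(lat$body_genes, lat$coords$location_id))
  graded <- c(lat$sv_genes, lat$marker_genes[, ct], lat$anti_genes[, ct])
  dirs <- rep(c(1, -1), length.out = length(graded))
  mult <- outer(dirs, log(lat$grad))      # genes x locations, log scale
  mult <- exp(mult)
  base <- lat$mean_expr[graded, ct]
  mass <- colSums(base * mult)
  mult <- sweep(mult, 2, sum(base) / mass, `*`)
  m[graded, ] <- base * mult
  m
}

#' Simulate a spatial sample with planted structure
#'
#' Counts are negative binomial around a mixture model: each capture
#' location mixes the cell-type expected expression profiles with its
#' Dirichlet cell-type fractions (concentrated on the location's region
#' band), so cell-type structure appears as soft spatial regions.
#' Marker genes are `marker_fold` times higher in their own type and
#' additionally follow the spatial gradient
#' `exp(sv_effect * (x/x_max - 1/2))` within that type; planted
#' spatially variable genes follow the same gradient in every type;
#' mitochondrial genes (`MT-*`) are scaled per location to hit a
#' mitochondrial fraction drawn uniformly from `mito_frac_range`.
#' Pure function of the config (including its seed).
#'
#' @param cfg A [sim_config()].
#' @return List: `sample` (a [spatial_sample()]) and `truth` (tibbles
#'   `markers`, `sv_genes`, `regions`; `mito_genes`; `mean_expr`, the
#'   gene-by-cell-type expected expression; `fractions`, the latent
#'   mixing fractions).
#' @export
simulate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lat <- sim_latent(cfg)
  n_loc <- nrow(lat$coords)
  withr::with_seed(sub_seed(cfg$seed, "sample"), {
    # location mean = fraction-weighted mixture of type means
    mu <- matrix(0, nrow = length(lat$body_genes), ncol = n_loc,
                 dimnames = list(lat$body_genes, lat$coords$location_id))
    for (ct in lat$types) {
      mu <- mu + sweep(sim_type_means(lat, ct), 2, lat$fractions[ct, ], `*`)
    }
    scale_l <- rgamma(n_loc, shape = cfg$libsize_shape,
                      rate = cfg$libsize_shape)
    mu <- sweep(mu, 2, scale_l, `*`)

    # mitochondrial genes scaled to a target per-location fraction
    mito_target <- runif(n_loc, cfg$mito_frac_range[1],
                         cfg$mito_frac_range[2])
    mito_share <- rgamma(cfg$n_mito_genes, shape = 1, rate = 1) + 0.05
    mito_share <- mito_share / sum(mito_share)
    mito_mu <- outer(mito_share,
                     colSums(mu) * mito_target / (1 - mito_target))
    full_mu <- rbind(mito_mu, mu)
    rownames(full_mu) <- c(lat$mito_genes, lat$body_genes)
    full_mu <- full_mu[lat$gene_ids, , drop = FALSE]

    counts <- matrix(rnbinom(length(full_mu), mu = full_mu,
                             size = cfg$dispersion),
                     nrow = nrow(full_mu),
                     dimnames = list(lat$gene_ids, lat$coords$location_id))

    annotations <- if (cfg$technology == "single_cell") {
      setNames(lat$region_type, lat$coords$location_id)
    } else NULL
    s <- spatial_sample(counts, lat$coords, cfg$technology,
                        sample_id = paste0("sim_seed", cfg$seed),
                        mito_genes = lat$mito_genes,
                        annotations = annotations)
    truth <- list(
      markers = dplyr::bind_rows(
        tidyr::pivot_longer(
          tibble::as_tibble(lat$marker_genes), dplyr::everything(),
          names_to = "cell_type", values_to = "gene") |>
          dplyr::mutate(fold = cfg$marker_fold, direction = "up"),
        tidyr::pivot_longer(
          tibble::as_tibble(lat$anti_genes), dplyr::everything(),
          names_to = "cell_type", values_to = "gene") |>
          dplyr::mutate(fold = 1 / cfg$marker_fold, direction = "down")),
      sv_genes = tibble::tibble(
        gene = lat$sv_genes, effect = cfg$sv_effect,
        direction = rep(c(1, -1), length.out = length(lat$sv_genes))),
      regions = tibble::tibble(location_id = lat$coords$location_id,
                               region = lat$band,
                               cell_type = lat$region_type),
      mito_genes = lat$mito_genes,
      mean_expr = lat$mean_expr,
      fractions = lat$fractions)
    list(sample = s, truth = truth)
  })
}

#' Simulate cell-type fractions and deconvolved expression
#'
#' Reconstructs the same latent Dirichlet fractions that generated the
#' sample's counts (both are pure functions of the config), then draws
#' coefficients of variation so that a `cv_high_share` share of entries
#' exceeds the 0.5 clipping bound (those entries are enumerated in the
#' truth table). Deconvolved expression is
#' `fraction * cell-type expected expression at that location`
#' (gradients included), optionally perturbed by mean-one lognormal
#' noise (`deconv_noise_sd`); at the default zero noise, pseudo-cell
#' construction recovers the cell-type expected expression exactly.
#'
#' @param cfg A [sim_config()].
#' @param sim A [simulate_sample()] result from the same `cfg`.
#' @return List: `fractions` (a [fraction_matrix()]), `deconvolved`
#'   (named list of gene-by-location matrices) and `truth` (tibble
#'   `clipped` of entries with CV > 0.5, and `type_means`, the named
#'   list of per-type expected expression matrices).
#' @export
simulate_fractions <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  lat <- sim_latent(cfg)
  fr <- lat$fractions
  types <- lat$types
  locs <- colnames(fr)
  n_loc <- length(locs); n_ct <- length(types)
  type_means <- lapply(setNames(types, types),
                       function(ct) sim_type_means(lat, ct))
  withr::with_seed(sub_seed(cfg$seed, "cv"), {
    high <- matrix(runif(n_ct * n_loc) < cfg$cv_high_share, nrow = n_ct)
    cv <- matrix(runif(n_ct * n_loc, 0, 0.5), nrow = n_ct,
                 dimnames = list(types, locs))
    cv[high] <- runif(sum(high), 0.5 + 1e-9, 1.5)

    noise <- function(n) {
      if (cfg$deconv_noise_sd > 0) {
        exp(rnorm(n, 0, cfg$deconv_noise_sd) - cfg$deconv_noise_sd^2 / 2)
      } else rep(1, n)
    }
    deconv <- lapply(types, function(ct) {
      m <- sweep(type_means[[ct]], 2, fr[ct, ], `*`) *
        matrix(noise(length(type_means[[ct]])),
               nrow = nrow(type_means[[ct]]))
      m
    })
    names(deconv) <- types

    clipped <- which(cv > 0.5, arr.ind = TRUE)
    list(fractions = fraction_matrix(fr, cv), deconvolved = deconv,
         truth = list(clipped = tibble::tibble(
                        cell_type = types[clipped[, 1]],
                        location_id = locs[clipped[, 2]]),
                      type_means = type_means))
  })
}

#' Simulate a perturbation library with planted reversal compounds
#'
#' Decoy signatures carry i.i.d. standard-normal z-scores. Each planted
#' reversal compound shifts the query's up-genes by `-planted_z` and
#' its down-genes by `+planted_z` on top of the same standard-normal
#' noise, so `planted_z = 0` reduces planted compounds to decoys
#' exactly.
#'
#' @param cfg A [sim_config()].
#' @param query A [deg_query()] naming the up/down genes to reverse.
#' @param genes Optional gene universe; defaults to the query genes
#'   padded with `LGxxx` filler genes up to `cfg$lib_n_genes` (or the
#'   query size plus 100 when unset).
#' @return List: `library` (a [profile_library()]) and `truth` (tibble
#'   `planted` of compound ids).
#' @export
simulate_perturbation_library <- function(cfg, query, genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(query, "deg_query"))
  qgenes <- c(query$up_genes, query$down_genes)
  if (is.null(genes)) {
    r <- cfg$lib_n_genes %||% (length(qgenes) + 100L)
    stopifnot(r >= length(qgenes))
    genes <- c(qgenes, sprintf("LG%04d", seq_len(r - length(qgenes))))
  }
  stopifnot(all(qgenes %in% genes))
  r <- length(genes)
  withr::with_seed(sub_seed(cfg$seed, "library"), {
    n_sig <- cfg$n_compounds * cfg$n_signatures_per_compound
    z <- matrix(rnorm(r * n_sig), nrow = r,
                dimnames = list(genes, sprintf("SIG%05d", seq_len(n_sig))))
    compounds <- sprintf("C%04d", seq_len(cfg$n_compounds))
    meta <- tibble::tibble(
      signature_id = colnames(z),
      compound = rep(compounds, each = cfg$n_signatures_per_compound),
      cell_line = "SIMCL", dose = 10, time_h = 6)
    planted <- compounds[seq_len(cfg$n_planted_reversal)]
    planted_sigs <- meta$signature_id[meta$compound %in% planted]
    z[query$up_genes, planted_sigs] <-
      z[query$up_genes, planted_sigs] - cfg$planted_z
    z[query$down_genes, planted_sigs] <-
      z[query$down_genes, planted_sigs] + cfg$planted_z
    list(library = profile_library(z, meta),
         truth = list(planted = tibble::tibble(compound = planted)))
  })
}

#' Simulate a protein-protein interactome over a gene universe
#'
#' Uniform random distinct undirected edges (no self-loops).
#'
#' @param cfg A [sim_config()].
#' @param genes Gene universe.
#' @return An [interactome()] tibble with `cfg$ppi_n_edges` edges (or
#'   fewer if the universe is small).
#' @export
simulate_interactome <- function(cfg, genes) {
  withr::with_seed(sub_seed(cfg$seed, "ppi"), {
    n <- length(genes)
    n_edges <- min(cfg$ppi_n_edges, n * (n - 1) / 2)
    seen <- character(0); rows <- list()
    while (length(rows) < n_edges) {
      pair <- sort(sample(genes, 2))
      key <- paste(pair, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- pair
    }
    m <- do.call(rbind, rows)
    interactome(tibble::tibble(gene_a = m[, 1], gene_b = m[, 2]))
  })
}

#' Simulate a ligand-receptor pathway table
#'
#' `n_pathways` pathways, each with 1-3 distinct ligand-receptor pairs
#' drawn from the gene universe.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene universe.
#' @return Tibble: `pathway`, `ligand`, `receptor`.
#' @export
simulate_lr_table <- function(cfg, genes) {
  withr::with_seed(sub_seed(cfg$seed, "lr"), {
    out <- purrr::map(seq_len(cfg$n_pathways), function(i) {
      k <- sample(1:3, 1)
      tibble::tibble(pathway = sprintf("PW%02d", i),
                     ligand = sample(genes, k),
                     receptor = sample(genes, k))
    }) |> dplyr::bind_rows()
    dplyr::distinct(out[out$ligand != out$receptor, ])
  })
}

#' Write a full set of simulated pipeline inputs to a directory
#'
#' Generates a sample, fractions/deconvolved expression, a perturbation
#' library (reversing the first cell type's marker genes), an
#' interactome and a ligand-receptor table, and writes them in the
#' formats the readers accept, plus the truth tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @return Named list of written paths, invisibly.
#' @export
simulate_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_sample(cfg)
  fr <- simulate_fractions(cfg, sim)
  types <- colnames(sim$truth$mean_expr)
  mk <- sim$truth$markers[sim$truth$markers$cell_type == types[1], ]
  q <- deg_query(types[1],
                 up_genes = mk$gene[mk$direction == "up"],
                 down_genes = mk$gene[mk$direction == "down"])
  lib <- simulate_perturbation_library(cfg, q,
                                       genes = gene_ids(sim$sample))
  ppi <- simulate_interactome(cfg, gene_ids(sim$sample))
  lr <- simulate_lr_table(cfg, gene_ids(sim$sample))

  p <- function(f) file.path(dir, f)
  write_spatial_sample(sim$sample, p("counts.tsv"), p("coords.tsv"))
  wr_mat <- function(m, path, id_col) {
    df <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)),
                           tibble::as_tibble(m))
    readr::write_tsv(df, path, progress = FALSE)
  }
  wr_mat(fr$fractions$fractions, p("fractions.tsv"), "cell_type")
  wr_mat(fr$fractions$cv, p("cv.tsv"), "cell_type")
  for (ct in names(fr$deconvolved)) {
    wr_mat(fr$deconvolved[[ct]], p(paste0("deconv_", ct, ".tsv")), "gene")
  }
  write_gct(lib$library$zscores, p("library.gct"))
  readr::write_tsv(lib$library$signatures, p("library_meta.tsv"),
                   progress = FALSE)
  readr::write_tsv(ppi, p("ppi.tsv"), progress = FALSE)
  readr::write_tsv(lr, p("lr.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$markers, p("truth_markers.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$sv_genes, p("truth_sv_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$regions, p("truth_regions.tsv"),
                   progress = FALSE)
  readr::write_tsv(lib$truth$planted, p("truth_planted.tsv"),
                   progress = FALSE)
  invisible(list(dir = dir, counts = p("counts.tsv"),
                 coords = p("coords.tsv"),
                 fractions = p("fractions.tsv"), cv = p("cv.tsv"),
                 library = p("library.gct"),
                 library_meta = p("library_meta.tsv"),
                 ppi = p("ppi.tsv"), lr = p("lr.tsv")))
}
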