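#' Build an enrichment query from up/down gene sets
#'
#' @param cell_type Label of the originating cell-type comparison.
#' @param up_genes,down_genes Disjoint character vectors of up- and
#'   down-regulated genes.
#' @param sv_filtered Were the genes intersected with spatially variable
#'   genes?
#' @return An object of class `deg_query` with `n_up`/`n_down` counts.
#' @export
deg_query <- function(cell_type, up_genes, down_genes, sv_filtered = FALSE) {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(intersect(up_genes, down_genes))) {
    abort("up and down gene sets must be disjoint.")
  }
  structure(list(cell_type = cell_type, up_genes = up_genes,
                 down_genes = down_genes, n_up = length(up_genes),
                 n_down = length(down_genes), sv_filtered = sv_filtered),
            class = "deg_query")
}

#' @export
print.deg_query <- function(x, ...) {
  cat("<deg_query> ", x$cell_type, ": ", x$n_up, " up / ", x$n_down,
      " down", if (x$sv_filtered) " (SV-filtered)", "\n", sep = "")
  invisible(x)
}

#' Assemble eligible enrichment queries from a marker table
#'
#' Per cell type, the significant genes (`q < alpha`) are split into
#' up-regulated (log fold change > `lfc_cut`) and down-regulated
#' (< `-lfc_cut`) sets; when a spatial variability result covers the
#' cell type, the significant set is first intersected with the genes
#' spatially variable (`q < alpha`) in that cell type. A query is
#' eligible when it has at least `min_genes` up- or at least `min_genes`
#' down-regulated genes and fewer than `max_total` significant genes in
#' total. Ineligible cell types are dropped with a logged reason.
#'
#' @param deg A `deg_table` from [find_markers()].
#' @param sv Optional `sv_result` from [sv_test()] (celltype scope).
#' @param alpha Significance threshold (default 0.05).
#' @param lfc_cut Fold-change cut defining up/down (default 0.5).
#' @param min_genes Minimum up or down set size (default 10).
#' @param max_total Exclusive cap on total significant genes
#'   (default 2000).
#' @return List of [deg_query()] objects.
#' @export
eligible_deg_sets <- function(deg, sv = NULL, alpha = 0.05, lfc_cut = 0.5,
                              min_genes = 10, max_total = 2000) {
  out <- list()
  for (ct in unique(deg$cell_type)) {
    rows <- deg[deg$cell_type == ct & deg$q < alpha, ]
    sv_filtered <- FALSE
    if (!is.null(sv) && any(sv$cell_type == ct, na.rm = TRUE)) {
      sv_genes <- sv$gene[!is.na(sv$cell_type) & sv$cell_type == ct &
                            sv$q < alpha]
      rows <- rows[rows$gene %in% sv_genes, ]
      sv_filtered <- TRUE
    }
    n_total <- nrow(rows)
    up <- rows$gene[rows$log2_fc > lfc_cut]
    down <- rows$gene[rows$log2_fc < -lfc_cut]
    if ((length(up) >= min_genes || length(down) >= min_genes) &&
        n_total < max_total) {
      out[[ct]] <- deg_query(ct, up, down, sv_filtered)
    } else {
      inform(paste0("cell type '", ct, "' ineligible: ", length(up),
                    " up, ", length(down), " down, ", n_total,
                    " total significant genes."))
    }
  }
  out
}

# One sub-list's enrichment score pieces. V: profile ranks of the
# sub-list genes; r: profile size. With the genes sorted by rank
# (j = 1..s):  a = max_j(j/s - V(j)/r), b = max_j(V(j)/r - (j-1)/s);
# sub-score = a when a >= b (ties resolved to +a), else -b.
es_sub <- function(V, r) {
  s <- length(V)
  if (s == 0L) return(list(s = 0L, a = NA_real_, b = NA_real_, es = 0))
  V <- sort(V)
  j <- seq_len(s)
  a <- max(j / s - V / r)
  b <- max(V / r - (j - 1) / s)
  list(s = s, a = a, b = b, es = if (a >= b) a else -b)
}

# Sign-rule combination: ES = ES_up - ES_down when the signs differ,
# 0 when they agree; a zero sub-score (empty or degenerate sub-list)
# counts as differing from any nonzero sign so the informative
# sub-list still scores.
es_combine <- function(es_up, es_down) {
  if (es_up != 0 && es_down != 0 && sign(es_up) == sign(es_down)) 0
  else es_up - es_down
}

#' Connectivity enrichment score of a query against a ranked profile
#'
#' The rank-based, weighted KS-style statistic of the repurposing
#' engine. Query genes are located in the drug profile's ranking
#' (rank 1 = most down-regulated gene); for each sub-list (up, down)
#' with its `s` genes sorted by profile rank ascending,
#' \deqn{a = \max_j\left(\frac{j}{s} - \frac{V(j)}{r}\right), \quad
#'       b = \max_j\left(\frac{V(j)}{r} - \frac{j-1}{s}\right)}
#' and the sub-score is `a` if `a > b`, else `-b` (the measure-zero tie
#' `a == b` resolves to `+a`). The combined score is
#' `ES = ES_up - ES_down` when the sub-score signs differ and 0 when
#' they agree, so only profiles that shift the two sub-lists toward
#' opposite ends score. `ES > 0` marks an inversely related (reversal)
#' compound, `ES < 0` a mimicking one.
#'
#' Query genes absent from the profile are dropped with a warning
#' before `s` is set; a query with both sub-lists empty after mapping
#' is an error. An empty sub-list contributes a sub-score of 0 and the
#' other sub-list still scores.
#'
#' @param query A [deg_query()].
#' @param rp A [rank_profile()] result.
#' @return One-row tibble: `signature_id`, `s_up`, `s_down`, `r`,
#'   `a_up`, `b_up`, `a_down`, `b_down`, `es_up`, `es_down`, `es`.
#' @export
enrichment_score <- function(query, rp) {
  stopifnot(inherits(query, "deg_query"), inherits(rp, "ranked_profile"))
  universe <- names(rp$rank)
  up <- intersect(query$up_genes, universe)
  down <- intersect(query$down_genes, universe)
  n_dropped <- query$n_up + query$n_down - length(up) - length(down)
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " query gene(s) absent from the profile; dropped."))
  }
  if (!length(up) && !length(down)) {
    abort("no query gene maps into the profile universe.")
  }
  su <- es_sub(rp$rank[up], rp$r)
  sd_ <- es_sub(rp$rank[down], rp$r)
  tibble::tibble(signature_id = rp$signature_id,
                 s_up = su$s, s_down = sd_$s, r = rp$r,
                 a_up = su$a, b_up = su$b, a_down = sd_$a, b_down = sd_$b,
                 es_up = su$es, es_down = sd_$es,
                 es = es_combine(su$es, sd_$es))
}

# Fast path used in permutation loops: ES from rank vectors only.
es_from_ranks <- function(up_ranks, down_ranks, r) {
  es_combine(es_sub(up_ranks, r)$es, es_sub(down_ranks, r)$es)
}

#' Null enrichment-score distribution for a query shape
#'
#' Draws `n_perm` random gene lists with the query's `n_up` and
#' `n_down` (distinct genes, sampled uniformly without replacement from
#' the `r`-gene profile universe, up/down disjoint) and returns their
#' enrichment scores. Because a ranked profile is a permutation of
#' `1..r`, this distribution depends only on `(r, n_up, n_down)` — it
#' is shared across every signature scored against the same query.
#'
#' @param r Profile size.
#' @param n_up,n_down Query sub-list sizes.
#' @param n_perm Number of draws (default 10000).
#' @param seed Seed.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
null_es_distribution <- function(r, n_up, n_down, n_perm = 10000, seed = 1) {
  if (n_up + n_down > r) {
    abort("query larger than the profile universe (n_up + n_down > r).")
  }
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      draw <- sample.int(r, n_up + n_down)
      es_from_ranks(draw[seq_len(n_up)],
                    draw[n_up + seq_len(n_down)], r)
    }, numeric(1))
  })
}

#' Permutation p-value for an observed enrichment score
#'
#' One-tailed add-one permutation test: when `ES > 0` the right tail
#' (`p = (#{ES_perm >= ES_obs} + 1)/(n_perm + 1)`), when `ES < 0` the
#' left tail, and `p = 1` when `ES = 0` (the sign rule makes a zero
#' score uninformative).
#'
#' @param query A [deg_query()].
#' @param rp The [rank_profile()] the observation was scored on.
#' @param obs The [enrichment_score()] row for `(query, rp)`.
#' @param n_perm Permutations (default 10000).
#' @param seed Seed.
#' @param null_es Optional precomputed [null_es_distribution()] to
#'   reuse across signatures.
#' @return `obs` with a `p` column added.
#' @export
permutation_pvalue <- function(query, rp, obs, n_perm = 10000, seed = 1,
                               null_es = NULL) {
  if (is.null(null_es)) {
    null_es <- null_es_distribution(rp$r, obs$s_up, obs$s_down,
                                    n_perm = n_perm, seed = seed)
  }
  obs$p <- es_pvalue(obs$es, null_es)
  obs
}

es_pvalue <- function(es, null_es) {
  B <- length(null_es)
  if (es > 0) (sum(null_es >= es) + 1) / (B + 1)
  else if (es < 0) (sum(null_es <= es) + 1) / (B + 1)
  else 1
}

#' Score a perturbation library against eligible queries
#'
#' Computes an enrichment score and permutation p-value for every
#' (query, signature) pair, BH-adjusts p across signatures within each
#' query, and collapses signatures (cell lines, doses) to one summary
#' row per compound. The default collapse picks, per compound, the
#' signature with maximal `|ES|` among its significant (`q < alpha`)
#' signatures — or among all of its signatures when none is significant,
#' with `significant = FALSE`.
#'
#' The permutation null for a query is drawn once and shared across
#' that query's signatures: random gene lists land on a uniform random
#' subset of ranks `1..r` for every signature, so the null law depends
#' only on the query shape (see [null_es_distribution()]).
#'
#' @param queries List of [deg_query()] objects (e.g. from
#'   [eligible_deg_sets()]).
#' @param lib A [profile_library()].
#' @param n_perm Permutations per query (default 10000).
#' @param seed Seed; each query uses a sub-seed derived from it.
#' @param alpha Significance threshold for the collapse (default 0.05).
#' @param collapse `"max_es"` (default), `"mean"` or `"best_q"`.
#' @param descending Passed to [rank_profile()].
#' @return Object of class `drug_enrichment`: list with `signatures`
#'   and `compounds` tibbles.
#' @export
score_library <- function(queries, lib, n_perm = 10000, seed = 1,
                          alpha = 0.05, collapse = c("max_es", "mean",
                                                     "best_q"),
                          descending = FALSE) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(lib, "profile_library"), length(queries) >= 1)
  sig_ids <- colnames(lib$zscores)
  ranked <- lapply(sig_ids, rank_profile, lib = lib,
                   descending = descending)
  names(ranked) <- sig_ids

  sig_tabs <- purrr::imap(queries, function(q, qname) {
    recs <- dplyr::bind_rows(lapply(ranked, enrichment_score, query = q))
    null_es <- null_es_distribution(
      lib$r, recs$s_up[1], recs$s_down[1], n_perm = n_perm,
      seed = sub_seed(seed, qname))
    recs$p <- vapply(recs$es, es_pvalue, numeric(1), null_es = null_es)
    recs$q <- p.adjust(recs$p, "BH")
    recs <- dplyr::left_join(recs, lib$signatures[, c("signature_id",
                                                      "compound")],
                             by = "signature_id")
    dplyr::bind_cols(tibble::tibble(query = q$cell_type), recs)
  })
  signatures <- dplyr::bind_rows(sig_tabs)

  compounds <- signatures |>
    dplyr::group_by(.data$query, .data$compound) |>
    dplyr::group_modify(function(df, key) {
      sig <- df$q < alpha
      pool <- if (any(sig)) df[sig, ] else df
      best <- switch(collapse,
        max_es = pool[order(-abs(pool$es), pool$signature_id), ][1, ],
        best_q = pool[order(pool$q, -abs(pool$es),
                            pool$signature_id), ][1, ],
        mean = {
          out <- pool[1, ]
          out$es <- mean(pool$es); out$p <- min(pool$p)
          out$q <- min(pool$q); out$signature_id <- NA_character_
          out
        })
      best$n_signatures <- nrow(df)
      best$significant <- any(sig)
      best[, c("signature_id", "es_up", "es_down", "es", "p", "q",
               "n_signatures", "significant")]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$query, dplyr::desc(.data$es))

  structure(list(signatures = signatures, compounds = compounds),
            class = "drug_enrichment")
}

# deterministic 32-bit sub-seed from a base seed and a label
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  (as.integer(seed) * 1009L + h) %% 2147483647L
}

#' @export
print.drug_enrichment <- function(x, ...) {
  cat("<drug_enrichment> ", nrow(x$signatures), " signature rows, ",
      nrow(x$compounds), " compound summaries across ",
      dplyr::n_distinct(x$signatures$query), " query set(s)\n", sep = "")
  invisible(x)
}

#' Tidy a drug enrichment result
#'
#' @param x A `drug_enrichment`.
#' @param level `"compounds"` (default) or `"signatures"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.drug_enrichment <- function(x, level = c("compounds", "signatures"),
                                 ...) {
  x[[match.arg(level)]]
}

#' Summarize a drug enrichment result
#'
#' @param x A `drug_enrichment`.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return One row per query: signature/compound counts, significant
#'   reversal (`es > 0`) and mimic (`es < 0`) compounds.
#' @export
glance.drug_enrichment <- function(x, alpha = 0.05, ...) {
  dplyr::summarise(
    dplyr::group_by(x$compounds, .data$query),
    n_compounds = dplyr::n(),
    n_inverse = sum(.data$es > 0 & .data$q < alpha),
    n_positive = sum(.data$es < 0 & .data$q < alpha),
    .groups = "drop")
}

#' Plot compound-level enrichment scores
#'
#' @param object A `drug_enrichment`.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot: compounds ranked by ES, colored by significance.
#' @export
autoplot.drug_enrichment <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(object$compounds,
                      rank = dplyr::row_number(dplyr::desc(.data$es)),
                      .by = "query")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$es,
                                   color = .data$q < alpha)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~query) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#D55E00",
                                           `FALSE` = "grey60"),
                                name = paste0("q < ", alpha)) +
    ggplot2::labs(x = "compound rank", y = "enrichment score") +
    ggplot2::theme_minimal()
}
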