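test_that("enrichment score reproduces the hand-worked examples", {
  rp <- identity_profile(10)
  # up at ranks {1,2}, down at ranks {9,10}: 0.8 - (-0.9) = 1.7
  q1 <- deg_query("ct", genes_at_ranks(1:2), genes_at_ranks(9:10))
  r1 <- enrichment_score(q1, rp)
  expect_equal(r1$es_up, 0.8)
  expect_equal(r1$es_down, -0.9)
  expect_equal(r1$es, 1.7)
  # up at {1,2}, down at {3,4}: both sub-scores positive -> ES = 0
  q2 <- deg_query("ct", genes_at_ranks(1:2), genes_at_ranks(3:4))
  r2 <- enrichment_score(q2, rp)
  expect_equal(r2$es_up, 0.8)
  expect_equal(r2$es_down, 0.6)
  expect_equal(r2$es, 0)
  # single up gene at rank 1: ES_up = 1 - 1/r
  q3 <- deg_query("ct", genes_at_ranks(1), character(0))
  expect_equal(enrichment_score(q3, rp)$es_up, 1 - 1 / 10)
})

test_that("enrichment score equals the brute-force oracle on random cases", {
  withr::with_seed(101, {
    for (i in 1:300) {
      r <- sample(20:100, 1)
      rp <- identity_profile(r)
      n_up <- sample(0:8, 1); n_down <- sample(0:8, 1)
      if (n_up + n_down == 0) n_up <- 1
      picked <- sample(r, n_up + n_down)
      up <- picked[seq_len(n_up)]
      down <- picked[n_up + seq_len(n_down)]
      q <- deg_query("ct", genes_at_ranks(up), genes_at_ranks(down))
      got <- enrichment_score(q, rp)
      expect_equal(got$es, oracle_es(up, down, r), tolerance = 1e-12)
    }
  })
})

test_that("reversing the profile negates sign-definite enrichment scores", {
  withr::with_seed(55, {
    r <- 60
    genes <- sprintf("g%02d", 1:r)
    z <- setNames(rnorm(r), genes)
    lib_fwd <- toy_library(z)
    lib_rev <- toy_library(-z)
    for (i in 1:20) {
      picked <- sample(genes, 10)
      q <- deg_query("ct", picked[1:5], picked[6:10])
      fwd <- enrichment_score(q, rank_profile(lib_fwd, "S1"))
      rev <- enrichment_score(q, rank_profile(lib_rev, "S1"))
      if (fwd$es != 0 && rev$es != 0 &&
          abs(fwd$es_up) > 1e-9 && abs(fwd$es_down) > 1e-9) {
        expect_equal(rev$es, -fwd$es, tolerance = 1e-9)
      }
    }
  })
})

test_that("same-end concentration zeroes the combined score", {
  rp <- identity_profile(50)
  withr::with_seed(77, {
    for (i in 1:20) {
      # both sub-lists drawn from the top quarter of the ranking
      picked <- sample(1:12, 8)
      q <- deg_query("ct", genes_at_ranks(picked[1:4]),
                     genes_at_ranks(picked[5:8]))
      got <- enrichment_score(q, rp)
      if (sign(got$es_up) == sign(got$es_down) && got$es_up != 0) {
        expect_equal(got$es, 0)
      }
    }
  })
})

test_that("genes absent from the profile are dropped; empty queries error", {
  rp <- identity_profile(10)
  q <- deg_query("ct", c("g01", "NOT_THERE"), character(0))
  expect_warning(res <- enrichment_score(q, rp), "dropped")
  expect_equal(res$s_up, 1L)
  q_bad <- deg_query("ct", "NOPE1", "NOPE2")
  expect_error(suppressWarnings(enrichment_score(q_bad, rp)), "universe")
})

test_that("permutation p-values hit the add-one boundary and are reproducible", {
  rp <- identity_profile(40)
  q <- deg_query("ct", genes_at_ranks(1:5), genes_at_ranks(36:40))
  obs <- enrichment_score(q, rp)   # maximal reversal, es close to 2
  p1 <- permutation_pvalue(q, rp, obs, n_perm = 1000, seed = 4)
  expect_equal(p1$p, 1 / 1001)     # beats every permutation
  p2 <- permutation_pvalue(q, rp, obs, n_perm = 1000, seed = 4)
  expect_identical(p1$p, p2$p)

  zero <- obs; zero$es <- 0
  expect_equal(permutation_pvalue(q, rp, zero, n_perm = 100, seed = 1)$p, 1)

  expect_error(null_es_distribution(10, 30, 11, 10, 1), "larger")
})

test_that("null-query p-values sit on the add-one grid with within-branch uniformity", {
  # The sign-conditional tail choice means the global null p-value
  # distribution is NOT U(0,1): zero scores map to p = 1 and each sign
  # branch spreads uniformly over its own attainable range. Check the
  # grid, the atom mass, and uniformity inside the positive branch.
  r <- 100; n_up <- 6; n_down <- 6; B <- 500
  null_es <- null_es_distribution(r, n_up, n_down, n_perm = B, seed = 9)
  rp <- identity_profile(r)
  genes <- names(rp$rank)
  withr::with_seed(123, {
    res <- t(replicate(300, {
      picked <- sample(genes, n_up + n_down)
      q <- deg_query("ct", picked[seq_len(n_up)],
                     picked[n_up + seq_len(n_down)])
      obs <- enrichment_score(q, rp)
      c(es = obs$es,
        p = permutation_pvalue(q, rp, obs, null_es = null_es)$p)
    }))
  })
  p <- res[, "p"]; es <- res[, "es"]
  expect_true(all(abs(p * (B + 1) - round(p * (B + 1))) < 1e-9))
  expect_equal(mean(p == 1), mean(es == 0))
  pos <- p[es > 0]
  pi_pos <- (sum(null_es > 0) + 1) / (B + 1)
  ks <- suppressWarnings(stats::ks.test(pos / pi_pos, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("eligibility thresholds follow the printed boundaries", {
  mk_deg <- function(n_up, n_down, n_null = 0) {
    tibble::tibble(
      gene = sprintf("G%04d", seq_len(n_up + n_down + n_null)),
      cell_type = "ct",
      log2_fc = c(rep(1, n_up), rep(-1, n_down), rep(0.2, n_null)),
      pct_in = 1, pct_out = 1, p = 0.001, q = 0.01,
      direction = c(rep("up", n_up), rep("down", n_down),
                    rep("up", n_null)))
  }
  expect_length(eligible_deg_sets(mk_deg(9, 0)), 0L)
  qs <- eligible_deg_sets(mk_deg(10, 0))
  expect_length(qs, 1L)
  expect_equal(qs[[1]]$n_up, 10L)
  # 2000 total significant genes -> ineligible (strictly fewer required)
  expect_length(eligible_deg_sets(mk_deg(10, 0, n_null = 1990)), 0L)
  expect_length(eligible_deg_sets(mk_deg(10, 0, n_null = 1989)), 1L)
  expect_length(eligible_deg_sets(empty_deg <- mk_deg(0, 0)), 0L)
})

test_that("the SV filter intersects queries with spatially variable genes", {
  deg <- tibble::tibble(
    gene = sprintf("G%03d", 1:30), cell_type = "ct",
    log2_fc = 1, pct_in = 1, pct_out = 1, p = 0.001, q = 0.01,
    direction = "up")
  sv <- tibble::tibble(gene = sprintf("G%03d", 1:12), scope = "celltype",
                       cell_type = "ct", statistic = 0.5, p = 0.001,
                       q = 0.01, n_locations = 100L)
  qs <- eligible_deg_sets(deg, sv = sv)
  expect_length(qs, 1L)
  expect_setequal(qs[[1]]$up_genes, sprintf("G%03d", 1:12))
  expect_true(qs[[1]]$sv_filtered)
  # SV filter can push a set below the 10-gene floor
  sv9 <- sv[1:9, ]
  expect_length(eligible_deg_sets(deg, sv = sv9), 0L)
})

test_that("planted reversal compounds are recovered ahead of all decoys", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, n_compounds = 60L,
                      n_planted_reversal = 3L)
    q <- deg_query("m", sprintf("U%02d", 1:12), sprintf("D%02d", 1:12))
    sl <- simulate_perturbation_library(cfg, q)
    enr <- score_library(list(m = q), sl$library, n_perm = 500,
                         seed = seed)
    cmp <- tidy(enr)
    planted <- sl$truth$planted$compound
    expect_identical(sort(cmp$compound[seq_along(planted)]),
                     sort(planted))
  }
})

test_that("a signature mirroring the query scores strongly negative", {
  r <- 50
  genes <- sprintf("g%02d", 1:r)
  # query up-genes sit at the very top of the ranking (high z), down at
  # the bottom: the drug mimics the disease signature
  q <- deg_query("ct", genes_at_ranks((r - 4):r), genes_at_ranks(1:5))
  got <- enrichment_score(q, identity_profile(r))
  expect_lt(got$es, -1.5)
})

test_that("compound collapse picks the max-|ES| significant signature", {
  genes <- sprintf("g%02d", 1:30)
  withr::with_seed(31, {
    z <- matrix(rnorm(30 * 4), nrow = 30,
                dimnames = list(genes, paste0("S", 1:4)))
  })
  # S1/S2 belong to drugA; make S2 a strong reversal
  q <- deg_query("ct", genes[1:6], genes[25:30])
  z[genes[1:6], "S2"] <- z[genes[1:6], "S2"] - 6
  z[genes[25:30], "S2"] <- z[genes[25:30], "S2"] + 6
  lib <- profile_library(z, data.frame(
    signature_id = paste0("S", 1:4),
    compound = c("drugA", "drugA", "drugB", "drugB")))
  enr <- score_library(list(ct = q), lib, n_perm = 500, seed = 2)
  a_row <- enr$compounds[enr$compounds$compound == "drugA", ]
  expect_identical(a_row$signature_id, "S2")
  expect_equal(a_row$n_signatures, 2L)
})

test_that("PPI module takes the top significant DEGs as an induced subgraph", {
  deg <- tibble::tibble(
    gene = c("A", "B", "C", "Z"), cell_type = "ct",
    log2_fc = c(2, 1.5, 1, 0.8), pct_in = 1, pct_out = 1,
    p = c(1e-5, 1e-4, 1e-3, 0.2), q = c(1e-4, 1e-3, 1e-2, 0.4),
    direction = "up")
  ppi <- interactome(data.frame(a = c("A", "B", "C"),
                                b = c("B", "D", "E")))
  mod <- extract_ppi_module(deg, "ct", ppi)
  expect_setequal(igraph::V(mod)$name, c("A", "B", "C"))  # Z not significant
  el <- igraph::as_data_frame(mod)
  expect_equal(nrow(el), 1L)   # only A-B is internal
  expect_setequal(unlist(el[, 1:2]), c("A", "B"))
  expect_error(extract_ppi_module(deg, "other", ppi), "absent")

  # the 300-gene cap
  big <- tibble::tibble(
    gene = sprintf("G%04d", 1:350), cell_type = "ct",
    log2_fc = 1, pct_in = 1, pct_out = 1,
    p = seq(1e-6, 1e-3, length.out = 350),
    q = seq(1e-5, 1e-2, length.out = 350), direction = "up")
  mod_big <- extract_ppi_module(big, "ct",
                                interactome(data.frame(a = "G0001",
                                                       b = "G0002")))
  expect_equal(igraph::vcount(mod_big), 300L)
})

test_that("perturbation network caps compounds per direction", {
  n <- 30
  cmp <- tibble::tibble(
    query = "ct", compound = sprintf("C%03d", 1:n),
    signature_id = sprintf("S%03d", 1:n),
    es_up = 0.5, es_down = -0.5,
    es = c(seq(2, 1, length.out = n / 2),
           seq(-1, -2, length.out = n / 2)),
    p = 0.001, q = 0.01, n_signatures = 1L, significant = TRUE)
  genes <- c("A", "B")
  z <- matrix(3, nrow = 2, ncol = n,
              dimnames = list(genes, cmp$signature_id))
  lib <- profile_library(z, data.frame(signature_id = cmp$signature_id,
                                       compound = cmp$compound))
  deg <- tibble::tibble(gene = genes, cell_type = "ct", log2_fc = 1,
                        pct_in = 1, pct_out = 1, p = 1e-4, q = 1e-3,
                        direction = "up")
  mod <- extract_ppi_module(deg, "ct",
                            interactome(data.frame(a = "A", b = "B")))
  net <- build_perturbation_network(cmp, lib, mod, deg, top_n = 10)
  expect_equal(sum(net$nodes$relation == "inverse", na.rm = TRUE), 10L)
  expect_equal(sum(net$nodes$relation == "positive", na.rm = TRUE), 10L)
  # every selected compound perturbs both module genes at |z| = 3
  expect_equal(sum(net$edges$type == "drug_gene"), 40L)
  expect_equal(sum(net$edges$type == "ppi"), 1L)

  # empty records -> empty network
  empty_net <- build_perturbation_network(cmp[0, ], lib, mod, deg)
  expect_equal(sum(empty_net$nodes$type == "drug"), 0L)
})

test_that("drug-gene edges honor the z threshold by enumeration", {
  genes <- c("A", "B", "C")
  sigs <- paste0("S", 1:3)
  z <- matrix(c(3, -2.5, 0.5,   2.2, 0.1, -4,   1, 1, 1),
              nrow = 3, dimnames = list(genes, sigs))
  cmp <- tibble::tibble(
    query = "ct", compound = paste0("D", 1:3), signature_id = sigs,
    es_up = 0.8, es_down = -0.8, es = c(1.5, 1.4, 1.3),
    p = 0.001, q = 0.01, n_signatures = 1L, significant = TRUE)
  lib <- profile_library(z, data.frame(signature_id = sigs,
                                       compound = paste0("D", 1:3)))
  deg <- tibble::tibble(gene = genes, cell_type = "ct", log2_fc = 1,
                        pct_in = 1, pct_out = 1, p = 1e-4, q = 1e-3,
                        direction = "up")
  mod <- extract_ppi_module(deg, "ct", interactome(
    data.frame(a = character(0), b = character(0))))
  net <- build_perturbation_network(cmp, lib, mod, deg, z_min = 2)
  de <- net$edges[net$edges$type == "drug_gene", ]
  expect_equal(nrow(de), 4L)   # D1: A,B; D2: A,C; D3: none
  expect_setequal(paste(de$from, de$to),
                  c("D1 A", "D1 B", "D2 A", "D2 C"))
  expect_equal(de$weight[de$from == "D2" & de$to == "C"], -4)
  expect_equal(igraph::ecount(mod), 0L)   # empty interactome: nodes only
})

test_that("candidate selection walks the three criteria", {
  mk_cmp <- function(query, compound, es, q, sig_id) {
    tibble::tibble(query = query, compound = compound,
                   signature_id = sig_id, es_up = 0.5, es_down = -0.5,
                   es = es, p = ifelse(q < 0.05, 0.001, 0.5), q = q,
                   n_signatures = 1L, significant = q < 0.05)
  }
  cmp <- dplyr::bind_rows(
    mk_cmp("target", "X", 1.2, 0.01, "SX"),
    mk_cmp("target", "Y", 1.5, 0.01, "SY"),
    mk_cmp("target", "W", 0.9, 0.01, "SW"),
    mk_cmp("immune", "X", -0.3, 0.2, "SX"),
    mk_cmp("immune", "Y", 0.8, 0.01, "SY"),
    mk_cmp("immune", "W", -0.1, 0.6, "SW"))
  genes <- c("A", "B", "NB")
  z <- matrix(c(3, 0, 0,  3, 0, 0,  0, 0, 3), nrow = 3,
              dimnames = list(genes, c("SX", "SY", "SW")))
  lib <- profile_library(z, data.frame(
    signature_id = c("SX", "SY", "SW"), compound = c("X", "Y", "W")))
  deg <- tibble::tibble(gene = c("A", "B"), cell_type = "target",
                        log2_fc = 1, pct_in = 1, pct_out = 1, p = 1e-4,
                        q = 1e-3, direction = "up")
  ppi <- interactome(data.frame(a = c("A", "B"), b = c("B", "NB")))
  mod <- extract_ppi_module(deg, "target", ppi)
  cand <- select_candidates(cmp, "target", "immune", mod, ppi, lib)
  # X passes all criteria; Y rejected (significant ES>0 on immune);
  # W passes via the first-neighbor gene NB
  expect_setequal(cand$compound, c("X", "W"))
  expect_equal(cand$compound[1], "X")   # ranked by target ES
  expect_error(select_candidates(cmp, "missing", "immune", mod, ppi,
                                 lib), "missing")
})

test_that("an empty significant set yields no candidates", {
  cmp <- tibble::tibble(query = "target", compound = "X",
                        signature_id = "SX", es_up = 0.2,
                        es_down = -0.2, es = 0.4, p = 0.4, q = 0.6,
                        n_signatures = 1L, significant = FALSE)
  z <- matrix(3, 1, 1, dimnames = list("A", "SX"))
  lib <- profile_library(z, data.frame(signature_id = "SX",
                                       compound = "X"))
  deg <- tibble::tibble(gene = "A", cell_type = "target", log2_fc = 1,
                        pct_in = 1, pct_out = 1, p = 1e-4, q = 1e-3,
                        direction = "up")
  ppi <- interactome(data.frame(a = "A", b = "B"))
  mod <- extract_ppi_module(deg, "target", ppi)
  expect_equal(nrow(select_candidates(cmp, "target", character(0), mod,
                                      ppi, lib)), 0L)
})
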