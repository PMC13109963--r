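test_that("checkerboard on a 2x2 grid gives Moran's I of -1", {
  coords <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(morans_i(c(1, 0, 0, 1), coords, k_neighbors = 2), -1)
})

test_that("Moran's I matches the O(n^2) double-sum oracle", {
  withr::with_seed(21, {
    for (n in c(10, 25, 50)) {
      coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
      vals <- rnorm(n)
      expect_equal(morans_i(vals, coords, k_neighbors = 6),
                   oracle_morans_i(vals, coords, k = 6),
                   tolerance = 1e-12)
    }
  })
})

test_that("constant values give an undefined statistic", {
  coords <- cbind(0:3, rep(0, 4))
  expect_true(is.na(morans_i(rep(2, 4), coords)))
})

test_that("permutation null of Moran's I centers at -1/(n-1)", {
  n <- 30
  withr::with_seed(8, {
    coords <- cbind(runif(n), runif(n))
    vals <- rnorm(n)
    sims <- replicate(4000, morans_i(sample(vals), coords))
  })
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - (-1 / (n - 1))), 4 * se)
})

test_that("sv_test recovers planted gradients and stays calibrated on nulls", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_sample(cfg)
  ns <- normalize_sample(qc_multicell(sim$sample, min_genes = 50)$sample)
  sv <- sv_test(ns, scope = "whole", n_perm = 500, seed = 7)
  planted <- sim$truth$sv_genes$gene
  expect_true(all(sv$q[sv$gene %in% planted] < 0.05))
  # null genes: not planted SV, not markers, not mitochondrial
  structured <- c(planted, sim$truth$markers$gene, sim$truth$mito_genes)
  null_p <- sv$p[!sv$gene %in% structured]
  expect_lte(mean(null_p < 0.1),
             0.1 + 2 * sqrt(0.1 * 0.9 / length(null_p)))
})

test_that("celltype scope skips small groups and tests within types", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_sample(cfg)
  fr <- simulate_fractions(cfg, sim)
  ps <- build_pseudocells(fr$deconvolved, clip_fractions(fr$fractions),
                          sim$sample)
  sv <- sv_test(ps, scope = "celltype", n_perm = 200, seed = 7)
  expect_setequal(unique(sv$cell_type), paste0("CT", 1:3))
  # planted SV genes are spatially variable within every cell type
  planted <- sim$truth$sv_genes$gene
  expect_true(all(sv$q[sv$gene %in% planted] < 0.05))

  # a type with < 10 pseudo-cells is skipped with a warning
  keep <- ps$cells$cell_type != "CT3" | seq_len(nrow(ps$cells)) %in%
    which(ps$cells$cell_type == "CT3")[1:5]
  ps_small <- ps
  ps_small$expr <- ps$expr[, keep]
  ps_small$cells <- ps$cells[keep, ]
  expect_warning(sv_small <- sv_test(ps_small, scope = "celltype",
                                     n_perm = 50, seed = 1),
                 "CT3")
  expect_false("CT3" %in% sv_small$cell_type)
})

test_that("empty gene set yields an empty result", {
  m <- named_matrix(integer(0), character(0), character(0))
  # construct a minimal normalized sample with zero genes
  s <- toy_sample(named_matrix(rep(1L, 4), "GA", paste0("L", 1:4)))
  ns <- normalize_sample(s)
  ns$expr <- ns$expr[0, , drop = FALSE]
  expect_equal(nrow(sv_test(ns, "whole", n_perm = 10, seed = 1)), 0L)
})

test_that("permutation p-values respect the add-one grid and BH is monotone", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_sample(cfg)
  ns <- normalize_sample(qc_multicell(sim$sample, min_genes = 50)$sample)
  B <- 99
  sv <- sv_test(ns, "whole", n_perm = B, seed = 2)
  expect_true(all(abs(sv$p * (B + 1) - round(sv$p * (B + 1))) < 1e-9))
  expect_true(all(sv$p >= 1 / (B + 1) & sv$p <= 1))
  ord <- order(sv$p)
  expect_true(all(diff(sv$q[ord]) >= -1e-12))
  expect_true(all(sv$q <= 1 & sv$q >= sv$p))
})

test_that("Kendall colocalization matches the pair-counting oracle", {
  s <- toy_sample(named_matrix(rep(1L, 5), "GA", paste0("L", 1:5)))
  ns <- normalize_sample(s)
  withr::with_seed(4, {
    expr_vals <- rnorm(5)
    frac_vals <- runif(5, 0, 0.3)
  })
  ns$expr["GA", ] <- expr_vals
  f <- fraction_matrix(named_matrix(frac_vals, "CT1", paste0("L", 1:5)),
                       named_matrix(rep(0, 5), "CT1", paste0("L", 1:5)))
  res <- colocalization_corr(ns, "GA", f, "CT1")
  expect_equal(res$tau, oracle_kendall_tau(expr_vals, frac_vals),
               tolerance = 1e-12)

  # perfect concordance / discordance
  ns$expr["GA", ] <- 1:5
  f1 <- fraction_matrix(named_matrix(seq(0.1, 0.5, 0.1), "CT1",
                                     paste0("L", 1:5)),
                        named_matrix(rep(0, 5), "CT1", paste0("L", 1:5)))
  expect_equal(colocalization_corr(ns, "GA", f1, "CT1")$tau, 1)
  f2 <- fraction_matrix(named_matrix(seq(0.5, 0.1, -0.1), "CT1",
                                     paste0("L", 1:5)),
                        named_matrix(rep(0, 5), "CT1", paste0("L", 1:5)))
  expect_equal(colocalization_corr(ns, "GA", f2, "CT1")$tau, -1)

  # constant side flagged
  ns$expr["GA", ] <- rep(1, 5)
  expect_identical(colocalization_corr(ns, "GA", f1, "CT1")$flag,
                   "constant")
})

test_that("gene-ratio correlations behave under rank invariance and nulls", {
  genes <- c("NUM", "DEN", "MK1", "MK2")
  withr::with_seed(11, {
    m <- named_matrix(rexp(4 * 40, 0.2), genes, sprintf("L%02d", 1:40))
  })
  s <- toy_sample(matrix(as.integer(round(m)), nrow = 4,
                         dimnames = dimnames(m)))
  ns <- normalize_sample(s)
  ratio <- (ns$expr["NUM", ] + 1) / (ns$expr["DEN", ] + 1)
  ns$expr["MK1", ] <- exp(ratio)              # monotone transform
  res <- gene_ratio_corr(ns, "NUM", "DEN", c("MK1", "MK2"))
  expect_equal(res$rho[res$marker == "MK1"], 1)
  expect_true(all(res$q >= res$p - 1e-12))

  # num == den -> constant ratio flagged
  ns2 <- ns
  ns2$expr["DEN", ] <- ns2$expr["NUM", ]
  res2 <- gene_ratio_corr(ns2, "NUM", "DEN", "MK2")
  expect_identical(res2$flag, "constant_ratio")
  expect_equal(res2$p, 1)
})

test_that("planted ratio-marker coupling is detected", {
  withr::with_seed(11, {
    n <- 60
    num <- rexp(n, 0.1); den <- rexp(n, 0.1)
    ratio <- (num + 1) / (den + 1)
    mk <- ratio * exp(rnorm(n, 0, 0.2))     # positive coupling + noise
    null_mks <- matrix(rexp(3 * n, 0.1), nrow = 3)
  })
  m <- rbind(NUM = num, DEN = den, MKP = mk, null_mks)
  rownames(m)[4:6] <- paste0("MKN", 1:3)
  colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  ns <- normalized_sample(toy_sample(matrix(1L, nrow(m), ncol(m),
                                            dimnames = dimnames(m))),
                          m, "precomputed")
  res <- gene_ratio_corr(ns, "NUM", "DEN", c("MKP", paste0("MKN", 1:3)))
  hit <- res[res$marker == "MKP", ]
  expect_gt(hit$rho, 0)
  expect_lt(hit$q, 0.05)
})
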