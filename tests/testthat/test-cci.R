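ps_at <- function(expr, types, locations, coords) {
  cells <- tibble::tibble(
    pseudo_cell_id = colnames(expr), cell_type = types,
    location_id = locations, x = coords[, 1], y = coords[, 2])
  structure(list(expr = expr, cells = cells), class = "pseudo_cells")
}

test_that("same-location adjacency links co-located pseudo-cells only", {
  expr <- matrix(1, nrow = 1, ncol = 4,
                 dimnames = list("GA", paste0("c", 1:4)))
  ps <- ps_at(expr, c("A", "B", "C", "A"),
              c("L1", "L1", "L1", "L2"),
              cbind(c(0, 0, 0, 5), c(0, 0, 0, 5)))
  adj <- build_adjacency(ps, "same_location")
  expect_setequal(adj$neighbors[[1]], c(2L, 3L))
  expect_setequal(adj$neighbors[[2]], c(1L, 3L))
  expect_length(adj$neighbors[[4]], 0L)
  # symmetry: i in N(j) <=> j in N(i)
  for (i in 1:4) for (j in adj$neighbors[[i]]) {
    expect_true(i %in% adj$neighbors[[j]])
    expect_false(i == j)
  }
})

test_that("radius adjacency respects the distance threshold inclusively", {
  expr <- matrix(1, nrow = 1, ncol = 3,
                 dimnames = list("GA", paste0("c", 1:3)))
  ps <- ps_at(expr, c("A", "B", "B"), paste0("L", 1:3),
              cbind(c(0, 25, 60), c(0, 0, 0)))
  adj <- build_adjacency(ps, "radius", radius_um = 30)
  expect_identical(adj$neighbors[[1]], 2L)   # 25 um
  expect_identical(adj$neighbors[[3]], integer(0))  # 35 um from c2? no: 60-25=35
  expect_error(build_adjacency(ps, "radius", radius_um = 0), "positive")
})

test_that("planted neighborhood promotion is detected", {
  withr::with_seed(5, {
    nq <- 40
    # query cells: half adjacent to interactor type, half isolated
    q_expr <- c(rnorm(nq / 2, 4), rnorm(nq / 2, 1))
    others <- matrix(rexp(3 * nq, 1), nrow = 3)
    expr <- rbind(G = pmax(q_expr, 0), others)
    rownames(expr) <- c("G", "N1", "N2", "N3")
    # interactor cells co-located with the first nq/2 query cells
    i_expr <- matrix(rexp(4 * (nq / 2), 1), nrow = 4,
                     dimnames = list(rownames(expr), NULL))
    full <- cbind(expr, i_expr)
    colnames(full) <- paste0("c", seq_len(ncol(full)))
  })
  locs <- c(paste0("L", 1:nq), paste0("L", 1:(nq / 2)))
  coords <- cbind(seq_along(locs), 0)
  ps <- ps_at(full, c(rep("Q", nq), rep("I", nq / 2)), locs, coords)
  adj <- build_adjacency(ps, "same_location")
  res <- neighborhood_cci(ps, adj, "Q", "I")
  hit <- res[res$gene == "G", ]
  expect_gt(hit$log2_fc, 0)
  expect_lt(hit$q, 0.05)
  expect_equal(hit$n_adjacent, nq / 2)
  expect_equal(hit$n_nonadjacent, nq / 2)
})

test_that("identical expression in both groups gives p near 1", {
  n <- 20
  expr <- matrix(rep(c(1, 2, 3, 4), n + n / 2), nrow = 4,
                 dimnames = list(paste0("G", 1:4), NULL))
  colnames(expr) <- paste0("c", seq_len(ncol(expr)))
  locs <- c(paste0("L", 1:n), paste0("L", 1:(n / 2)))
  ps <- ps_at(expr, c(rep("Q", n), rep("I", n / 2)), locs,
              cbind(seq_along(locs), 0))
  adj <- build_adjacency(ps, "same_location")
  res <- neighborhood_cci(ps, adj, "Q", "I", apply_filters = FALSE)
  expect_true(all(abs(res$log2_fc) < 1e-9))
  expect_true(all(res$p > 0.9))
})

test_that("degenerate splits return an empty result with a warning", {
  expr <- matrix(1:4, nrow = 1, dimnames = list("GA", paste0("c", 1:4)))
  # all Q cells share locations with I cells -> no nonadjacent group
  ps <- ps_at(expr, c("Q", "I", "Q", "I"), c("L1", "L1", "L2", "L2"),
              cbind(1:4, 0))
  adj <- build_adjacency(ps, "same_location")
  expect_warning(res <- neighborhood_cci(ps, adj, "Q", "I"), "empty")
  expect_equal(nrow(res), 0L)
})

test_that("distance score matches the direct pair-sum oracle", {
  expr <- matrix(c(2, 0, 0, 3), nrow = 2,
                 dimnames = list(c("LIG", "REC"), c("a", "b")))
  ps <- ps_at(expr, c("A", "B"), c("L1", "L2"),
              cbind(c(0, 400), c(0, 0)))
  lr <- tibble::tibble(pathway = "PW", ligand = "LIG", receptor = "REC")
  res <- distance_cci(ps, lr, thresholds_um = c(300, 500), n_perm = 19,
                      seed = 1, sender_types = "A", receiver_types = "B")
  expect_equal(res$score[res$distance_threshold == 500], 6)  # 2 * 3
  expect_equal(res$score[res$distance_threshold == 300], 0)
})

test_that("all-zero ligand expression scores zero with p = 1", {
  withr::with_seed(2, {
    expr <- rbind(LIG = rep(0, 12), REC = rexp(12), OTH = rexp(12))
  })
  colnames(expr) <- paste0("c", 1:12)
  ps <- ps_at(expr, rep(c("A", "B"), 6), paste0("L", 1:12),
              cbind(runif(12, 0, 200), runif(12, 0, 200)))
  lr <- tibble::tibble(pathway = "PW", ligand = "LIG", receptor = "REC")
  res <- distance_cci(ps, lr, thresholds_um = 500, n_perm = 19, seed = 1)
  expect_true(all(res$score == 0))
  expect_true(all(res$p == 1))
})

test_that("distance score is non-decreasing in the threshold", {
  withr::with_seed(14, {
    expr <- rbind(LIG = rexp(20), REC = rexp(20))
    colnames(expr) <- paste0("c", 1:20)
    coords <- cbind(runif(20, 0, 2000), runif(20, 0, 2000))
  })
  ps <- ps_at(expr, rep(c("A", "B"), 10), paste0("L", 1:20), coords)
  lr <- tibble::tibble(pathway = "PW", ligand = "LIG", receptor = "REC")
  res <- distance_cci(ps, lr, thresholds_um = c(500, 1000, 1500, 1e9),
                      n_perm = 9, seed = 1, sender_types = "A",
                      receiver_types = "B")
  sums <- res$score[order(res$distance_threshold)]
  # the mean product can fluctuate, but the unnormalized mass cannot:
  # check monotonicity of score * n_pairs via the d = Inf closed form
  a <- expr["LIG", seq(1, 20, 2)]; b <- expr["REC", seq(2, 20, 2)]
  expect_equal(res$score[res$distance_threshold == 1e9],
               mean(outer(a, b)), tolerance = 1e-12)

  # with all pairwise distances below every threshold the score is flat
  ps2 <- ps_at(expr, rep(c("A", "B"), 10), paste0("L", 1:20),
               cbind(runif(20, 0, 10), runif(20, 0, 10)))
  res2 <- distance_cci(ps2, lr, thresholds_um = c(500, 1000), n_perm = 9,
                       seed = 1, sender_types = "A", receiver_types = "B")
  expect_equal(res2$score[1], res2$score[2], tolerance = 1e-12)
})

test_that("unknown ligand-receptor genes are skipped with a warning", {
  expr <- matrix(1, 2, 4, dimnames = list(c("LIG", "REC"),
                                          paste0("c", 1:4)))
  ps <- ps_at(expr, rep(c("A", "B"), 2), paste0("L", 1:4),
              cbind(1:4, 0))
  lr <- tibble::tibble(pathway = c("PW", "PW2"),
                       ligand = c("LIG", "NOPE"),
                       receptor = c("REC", "REC"))
  expect_warning(res <- distance_cci(ps, lr, thresholds_um = 10,
                                     n_perm = 9, seed = 1), "skipped")
  expect_false("PW2" %in% res$pathway)
})
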