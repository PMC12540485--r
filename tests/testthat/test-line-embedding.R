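# Helper: a small graph from an explicit edge table via the TSV reader.
graph_from_edges <- function(src_a, src_q, dst_a, dst_q, w) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(src_area = src_a, src_quadrant = src_q,
               dst_area = dst_a, dst_quadrant = dst_q, weight = w),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_edge_list(f)
}

test_that("embedding is bitwise-deterministic under a fixed seed", {
  g <- graph_from_edges(c(0, 1, 2), "I", c(1, 2, 0), "II", c(1, 0.5, 2))
  e1 <- line_embed(g, dim = 8, n_samples = 5000, seed = 42)
  e2 <- line_embed(g, dim = 8, n_samples = 5000, seed = 42)
  expect_identical(e1, e2)
  e3 <- line_embed(g, dim = 8, n_samples = 5000, seed = 43)
  expect_false(identical(e1, e3))
})

test_that("analytic gradients of the second-order objective match finite differences", {
  set.seed(30)
  n <- 3; d <- 4
  u <- matrix(rnorm(n * d, sd = 0.3), n, d)
  ctx <- matrix(rnorm(n * d, sd = 0.3), n, d)
  edges <- data.frame(i = c(1L, 2L, 3L), j = c(2L, 3L, 1L), w = c(1.5, 0.7, 1.0))
  g <- emotraj:::.line_o2_grad(u, ctx, edges)
  eps <- 1e-6
  for (k in seq_len(n * d)) {
    up <- u; up[k] <- up[k] + eps
    um <- u; um[k] <- um[k] - eps
    fd <- (emotraj:::.line_o2_value(up, ctx, edges) -
           emotraj:::.line_o2_value(um, ctx, edges)) / (2 * eps)
    expect_equal(g$du[k], fd, tolerance = 1e-5)
    cp <- ctx; cp[k] <- cp[k] + eps
    cm <- ctx; cm[k] <- cm[k] - eps
    fd <- (emotraj:::.line_o2_value(u, cp, edges) -
           emotraj:::.line_o2_value(u, cm, edges)) / (2 * eps)
    expect_equal(g$dctx[k], fd, tolerance = 1e-5)
  }
})

test_that("first-order training pulls a connected pair together", {
  g <- graph_from_edges(c(0, 1), c("I", "II"), c(1, 0), c("II", "I"), c(1, 1))
  e <- line_embed(g, dim = 8, order = "first", n_samples = 2e4, seed = 7)
  cs <- sum(e[1, ] * e[2, ]) / sqrt(sum(e[1, ]^2) * sum(e[2, ]^2))
  expect_gt(cs, 0)
})

test_that("both-order embeddings concatenate the two objectives", {
  g <- graph_from_edges(c(0, 1, 2, 0), "I", c(1, 2, 0, 2), "II",
                        c(1, 1, 1, 1))
  e <- line_embed(g, dim = 16, order = "both", n_samples = 5000, seed = 1)
  expect_equal(ncol(e), 16L)
  e1 <- line_embed(g, dim = 8, order = "first", n_samples = 5000, seed = 1)
  expect_equal(ncol(e1), 8L)
  expect_error(line_embed(g, dim = 15, order = "both"), "even")
})

test_that("vertices with no incident edge keep initialization and are flagged", {
  tr <- build_trajectory(c(0, 100), c(0L, 1L), c("I", "I"), "u")
  g <- build_graph(list(tr), extra_vertices = "5:IV")
  e <- line_embed(g, dim = 4, n_samples = 1000, seed = 2)
  expect_true("5:IV" %in% rownames(e))
  expect_identical(attr(e, "untrained"), "5:IV")
  # dim 4 with order "both" trains two halves of dim 2: init bound 0.5/2
  expect_true(all(abs(e["5:IV", ]) <= 0.5 / 2))
})

test_that("trajectory matrices are exact embedding lookups", {
  set.seed(31)
  keys <- c("0:I", "1:II", "2:III", "3:IV")
  tab <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(keys, NULL))
  tr <- build_trajectory(c(0, 60, 120, 180, 240, 300),
                         c(0L, 1L, 2L, 3L, 0L, 1L),
                         c("I", "II", "III", "IV", "I", "II"), "u")
  fm <- trajectory_matrix(tr, tab)
  expect_equal(nrow(fm$rows), 5L)
  expect_equal(fm$rows[3, ], tab["2:III", ])
  expect_equal(fm$target_area, 1L)
  expect_equal(fm$target_quadrant, "II")
  # m = 2: one row, target is the second step
  tr2 <- build_trajectory(c(0, 60), c(0L, 1L), c("I", "II"), "u")
  fm2 <- trajectory_matrix(tr2, tab)
  expect_equal(nrow(fm2$rows), 1L)
  expect_equal(fm2$rows[1, ], tab["0:I", ])
  # permuting table row order leaves the matrix unchanged
  tab_perm <- tab[c(3, 1, 4, 2), ]
  expect_equal(trajectory_matrix(tr, tab_perm)$rows, fm$rows)
  # unknown vertex is named in the error
  tr3 <- build_trajectory(c(0, 60), c(9L, 1L), c("I", "II"), "u")
  expect_error(trajectory_matrix(tr3, tab), "9:I")
})

test_that("sliding-window samples honor the window cap and targets", {
  set.seed(32)
  keys <- paste0(0:3, ":I")
  tab <- matrix(rnorm(4 * 5), 4, 5, dimnames = list(keys, NULL))
  tr <- build_trajectory(cumsum(rep(60, 8)), rep(0:3, 2), rep("I", 8), "u")
  s <- make_training_samples(list(tr), tab, max_len = 3)
  expect_length(s, 7L)              # one sample per step j = 2..8
  expect_true(all(vapply(s, function(x) nrow(x$rows), 0) <= 3))
  expect_equal(vapply(s, `[[`, 0, "seq_len"), 2:8)
  last <- s[[7]]
  expect_equal(last$target_area, tr$area[8])
  expect_equal(last$rows, tab[tr$key[5:7], ], ignore_attr = TRUE)
})
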