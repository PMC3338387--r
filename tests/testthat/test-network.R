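make_toy_dataset <- function(n = 120, p_expr = 30, m = 8, q = 2,
                             seed = 1) {
  fx <- generate_fixture(
    fixture_spec(n = n, p_expr = p_expr, m = m, q = q,
                 planted = list(list(features = c(3, 7, p_expr + 2),
                                     effects = c(3, -3, 3)),
                                list(features = integer(0),
                                     effects = numeric(0)))),
    seed = seed)
  fx
}

test_that("expression_pcs returns ordered orthonormal components", {
  set.seed(30)
  u <- rnorm(25); v <- rnorm(40)
  rank1 <- u %*% t(v)
  pcs <- expression_pcs(rank1, k = 2)
  uc <- u - mean(u)
  expect_equal(abs(cor(pcs[, 1], uc)), 1, tolerance = 1e-8)
  X <- matrix(rnorm(30 * 50), 30)
  P <- expression_pcs(X, k = 5)
  expect_equal(crossprod(P), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # components match the left singular vectors up to sign, in order of
  # non-increasing singular value
  sv <- svd(scale(X, scale = FALSE))
  for (j in 1:5)
    expect_equal(abs(sum(P[, j] * sv$u[, j])), 1, tolerance = 1e-8)
  expect_true(all(diff(sv$d[1:5]) <= 1e-8))
  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(P, 2, function(x) x[which.max(abs(x))]) > 0))
  expect_error(expression_pcs(X, k = 30), "smaller")
})

test_that("phase 1 recovers planted phenotype parents only", {
  fx <- make_toy_dataset(n = 200, seed = 5)
  sc <- phase1_phenotypes(fx$dataset, n_restarts = 3, seed = 42,
                          n_pcs = 5)
  # responses are phenotypes; genotypes never appear as responses
  expect_true(all(sc$role_a == "phenotype"))
  expect_false(any(sc$b == sc$a))
  hit <- sc[sc$a == "pheno1" & sc$p_hat > 0.99, "b"]
  expect_setequal(hit, c("expr3", "expr7", "marker2"))
  # the pure-noise phenotype has an empty neighborhood at 0.99
  expect_equal(sum(sc$a == "pheno2" & sc$p_hat > 0.99), 0)
  # deterministic under the master seed
  sc2 <- phase1_phenotypes(fx$dataset, n_restarts = 3, seed = 42,
                           n_pcs = 5)
  expect_identical(sc$p_hat, sc2$p_hat)
})

test_that("phase 2 regressions exclude self and never use phenotypes", {
  fx <- make_toy_dataset(n = 100, p_expr = 12, m = 4, seed = 6)
  sc <- phase2_expression(fx$dataset, n_restarts = 2, seed = 7,
                          n_pcs = 3)
  expect_true(all(sc$role_a == "expression"))
  expect_false(any(sc$a == sc$b))
  expect_false(any(grepl("^pheno", sc$b)))
  # every trait scored against all other traits plus markers
  expect_equal(nrow(sc), 12 * (11 + 4))
})

test_that("average_directions averages pairs and passes singles through", {
  sc <- data.frame(
    a = c("e1", "e2", "ph", "e1"),
    b = c("e2", "e1", "e1", "g1"),
    role_a = c("expression", "expression", "phenotype", "expression"),
    role_b = c("expression", "expression", "expression", "genotype"),
    p_hat = c(1.0, 0.981, 0.7, 0.4), phase = 1L)
  sym <- average_directions(sc)
  ee <- sym[sym$node_a == "e1" & sym$node_b == "e2", ]
  expect_equal(ee$p_sym, 0.9905)
  expect_equal(ee$n_directions, 2L)
  single <- sym[sym$node_a == "e1" & sym$node_b == "ph", ]
  expect_equal(single$p_sym, 0.7)
  expect_equal(single$n_directions, 1L)
  # 0.99 cutoff keeps the averaged pair, strict inequality drops 0.5
  g <- build_union_graph(sym, NULL, threshold = 0.99)
  expect_true("e2" %in% g$edges$node_b | "e2" %in% g$edges$node_a)
  sc2 <- data.frame(a = "x", b = "y", role_a = "expression",
                    role_b = "expression", p_hat = c(1, 0), phase = 1L)
  sc2$a <- c("x", "y"); sc2$b <- c("y", "x")
  sym2 <- average_directions(sc2)
  expect_equal(sym2$p_sym, 0.5)
  g2 <- build_union_graph(sym2, NULL, threshold = 0.5)
  expect_equal(nrow(g2$edges), 0)  # 0.5 is not > 0.5
})

test_that("build_union_graph implements union semantics", {
  p1 <- data.frame(node_a = c("ph", "ph"), node_b = c("e1", "e2"),
                   role_a = "phenotype", role_b = "expression",
                   p_sym = c(0.995, 0.2), n_directions = 1L, phase = 1L)
  p2 <- data.frame(node_a = c("e1", "e3"), node_b = c("e2", "e4"),
                   role_a = "expression", role_b = "expression",
                   p_sym = c(0.999, 0.992), n_directions = 2L,
                   phase = 2L)
  g <- build_union_graph(p1, p2, threshold = 0.99)
  expect_equal(nrow(g$edges), 3)  # disjoint sets add up
  expect_setequal(g$vertices$id, c("ph", "e1", "e2", "e3", "e4"))
  # duplicate edge across phases: one row, provenance both, max score
  p2b <- rbind(p2, data.frame(node_a = "e1", node_b = "ph",
                              role_a = "expression",
                              role_b = "phenotype", p_sym = 0.991,
                              n_directions = 1L, phase = 2L))
  p2b$node_a[3] <- "e1"; p2b$node_b[3] <- "ph"
  # normalize ordering as average_directions would
  p2b[3, c("node_a", "node_b")] <- c("e1", "ph")
  p2b[3, c("role_a", "role_b")] <- c("expression", "phenotype")
  p1b <- p1
  p1b$node_a <- c("e1", "ph"); p1b$node_b <- c("ph", "e2")
  p1b$role_a <- c("phenotype", "phenotype")
  g2 <- build_union_graph(p1b, p2b, threshold = 0.99)
  dup <- g2$edges[g2$edges$node_a == "e1" & g2$edges$node_b == "ph", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$provenance, "both")
  expect_equal(dup$p_sym, 0.995)
  # empty inputs: phenotype-only vertex set
  g0 <- build_union_graph(p1[0, ], NULL, threshold = 0.99)
  expect_equal(nrow(g0$edges), 0)
  # threshold monotonicity
  gl <- build_union_graph(p1, p2, threshold = 0.5)
  expect_true(nrow(gl$edges) >= nrow(g$edges))
})

test_that("refit_ols_ci gives calibrated intervals", {
  fx <- make_toy_dataset(n = 250, seed = 9)
  # strong planted feature: tight interval excluding zero
  res <- refit_ols_ci(fx$dataset, "pheno1",
                      c("expr3", "expr7", "marker2"), n_pcs = 5)
  expect_equal(nrow(res), 3)
  expect_false(any(res$covers_zero))
  # a noise feature's interval covers zero at roughly the right rate
  cover <- 0
  for (s in 1:40) {
    set.seed(s)
    idx <- sample(setdiff(1:30, c(3, 7)), 1)
    r1 <- refit_ols_ci(fx$dataset, "pheno2", paste0("expr", idx),
                       n_pcs = 5)
    cover <- cover + r1$covers_zero
  }
  expect_gte(cover / 40, 0.8)
  # collinear duplicate is dropped with a warning
  ds <- fx$dataset
  ds$expression <- cbind(ds$expression,
                         expr_dup = ds$expression[, "expr3"])
  expect_warning(r2 <- refit_ols_ci(ds, "pheno1",
                                    c("expr3", "expr_dup"), n_pcs = 5),
                 "collinear")
  expect_equal(r2$feature, "expr3")
})

test_that("symmetrize_scores and edges_at behave as documented", {
  S <- matrix(0, 3, 3)
  S[1, 2] <- 1; S[2, 1] <- 0.98; S[1, 3] <- 0.6
  avg <- symmetrize_scores(S, "average")
  mx <- symmetrize_scores(S, "max")
  expect_equal(avg[1, 2], 0.99)
  expect_equal(mx[1, 2], 1)
  expect_equal(avg, t(avg))
  e <- edges_at(avg, 0.98)
  expect_equal(unname(e), matrix(c(1L, 2L), 1))
  # threshold monotonicity: higher threshold is a subset
  e_lo <- edges_at(avg, 0.2)
  expect_true(nrow(e_lo) >= nrow(e))
})
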