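mk_mat <- function(values, features, groups, reps = 3) {
  m <- matrix(values, nrow = length(features), byrow = TRUE)
  rownames(m) <- features
  colnames(m) <- paste(rep(groups, each = reps), 1:reps, sep = "_")
  m
}

test_that("quantifiability keeps features seen >= 2 of 3 in some tissue", {
  g <- rep(c("A", "B"), each = 3)
  m <- mk_mat(c(1, 2, NA, NA, NA, 1,     # 2 of 3 in A -> kept
                1, NA, NA, NA, 1, NA,    # once per tissue -> dropped
                1, 1, 1, 1, 1, 1),       # everywhere -> kept
              c("f1", "f2", "f3"), c("A", "B"))
  out <- quantifiable_filter(m, g)
  expect_setequal(rownames(out), c("f1", "f3"))
  expect_equal(quantifiable_filter(m[3, , drop = FALSE], g),
               m[3, , drop = FALSE])
  expect_error(quantifiable_filter(m, g, min_detections = 4),
               "min_detections")
})

test_that("DEP gate needs both the 1.5-fold change and p <= 0.05", {
  g <- rep(c("A", "B"), each = 3)
  # identical means, nonzero variance -> never a DEP
  m1 <- mk_mat(c(10, 11, 12, 10, 11, 12), "f1", c("A", "B"))
  d1 <- call_deps(m1, g, c("A", "B"))
  expect_false(d1$is_dep)
  # a clear 1.4-fold change fails the FC gate no matter how significant
  m2 <- mk_mat(c(1000, 1001, 1002, 1400, 1401, 1402), "f2", c("A", "B"))
  d2 <- call_deps(m2, g, c("A", "B"))
  expect_lt(d2$p_value, 0.05)
  expect_false(d2$is_dep)
  expect_equal(d2$direction, "up")
  # zero variance with equal means -> p = 1 by convention
  m3 <- mk_mat(rep(8, 6), "f3", c("A", "B"))
  expect_equal(call_deps(m3, g, c("A", "B"))$p_value, 1)
  expect_error(call_deps(m1[, c(1, 4), drop = FALSE], c("A", "B"),
                         c("A", "B")), "fewer than 2 replicates")
})

test_that("fold-change orientation is second tissue over first, log2", {
  g <- rep(c("A", "B"), each = 3)
  m <- mk_mat(c(100, 100, 100, 400, 400, 400), "f1", c("A", "B"))
  expect_equal(call_deps(m, g, c("A", "B"))$log2_fc, 2)
  expect_equal(call_deps(m, g, c("B", "A"))$log2_fc, -2)
})

test_that("scale invariance: global scaling changes no DEP call", {
  set.seed(5)
  g <- rep(c("A", "B"), each = 3)
  m <- matrix(2^rnorm(600, 10, 1), nrow = 100)
  rownames(m) <- paste0("f", 1:100)
  colnames(m) <- paste(rep(c("A", "B"), each = 3), 1:3, sep = "_")
  d1 <- call_deps(m, g, c("A", "B"))
  d2 <- call_deps(m * 1000, g, c("A", "B"))
  expect_equal(d1$is_dep, d2$is_dep)
  expect_equal(d1$log2_fc, d2$log2_fc, tolerance = 1e-12)
})

test_that("known 4-fold changes are recovered with BH-bounded false calls", {
  set.seed(6)
  n <- 1000; n_de <- 50
  g <- rep(c("A", "B"), each = 3)
  base <- matrix(rnorm(n * 6, 12, 0.2), nrow = n)
  base[1:n_de, 4:6] <- base[1:n_de, 4:6] + 2   # 4-fold in tissue B
  m <- 2^base
  rownames(m) <- paste0("f", 1:n)
  colnames(m) <- paste(g, 1:3, sep = "_")
  d <- call_deps(m, g, c("A", "B"))
  called <- d$feature[d$is_dep]
  expect_gte(sum(called %in% paste0("f", 1:n_de)), 45)
  expect_lte(sum(!called %in% paste0("f", 1:n_de)), 10)
  # BH q-values never fall below their p-values
  expect_true(all(d$q_value >= d$p_value - 1e-12))
  # strict-q mode is at least as stringent
  dq <- call_deps(m, g, c("A", "B"), strict_q = TRUE)
  expect_true(all(!dq$is_dep | d$is_dep))
})

test_that("trivial correlation cases: identity and antisymmetry", {
  set.seed(7)
  x <- setNames(rnorm(50), paste0("f", 1:50))
  r1 <- suppressWarnings(correlate_omics(x, x))  # opposite-trend set empty
  expect_equal(r1$r[r1$subset == "all"], 1, tolerance = 1e-12)
  expect_equal(r1$r[r1$subset == "same_trend"], 1, tolerance = 1e-12)
  expect_warning(r2 <- correlate_omics(x, -x), "same_trend")
  expect_equal(r2$r[r2$subset == "all"], -1, tolerance = 1e-12)
  expect_equal(r2$n[r2$subset == "same_trend"], 0)
  expect_error(correlate_omics(setNames(1:3, c("a", "b", "c")),
                               setNames(1:3, c("x", "y", "z"))),
               "no shared")
})

test_that("Pearson matches an independent sum-formula oracle", {
  set.seed(8)
  x <- setNames(rnorm(200), paste0("f", 1:200))
  y <- setNames(0.6 * x + rnorm(200, 0, 0.5), names(x))
  out <- correlate_omics(x, y)
  expect_equal(out$r[out$subset == "all"], oracle_pearson(x, y),
               tolerance = 1e-12)
})

test_that("cor-DEGs-DEPs and trend subsets are sized and ordered sensibly", {
  set.seed(9)
  n <- 300
  common <- rnorm(n, 0, 1)
  p <- setNames(common + rnorm(n, 0, 0.6), paste0("f", 1:n))
  t_ <- setNames(common + rnorm(n, 0, 0.6), names(p))
  dep <- abs(p) > 0.8
  deg <- abs(t_) > 0.8
  out <- suppressWarnings(correlate_omics(p, t_, dep, deg))
  expect_equal(out$n[out$subset == "cor_degs_deps"], sum(dep & deg))
  expect_equal(out$n[out$subset == "same_trend"] +
                 out$n[out$subset == "opposite_trend"],
               out$n[out$subset == "cor_degs_deps"])
  # same-trend r exceeds the all-features r under a shared-signal model
  expect_gt(out$r[out$subset == "same_trend"], out$r[out$subset == "all"])
})

test_that("same-trend r exceeds all-features r across repeated simulations", {
  set.seed(10)
  wins <- replicate(10, {
    n <- 200
    s <- rnorm(n)
    p <- setNames(s + rnorm(n, 0, 0.7), paste0("f", 1:n))
    t_ <- setNames(s + rnorm(n, 0, 0.7), names(p))
    out <- suppressWarnings(correlate_omics(p, t_))
    out$r[out$subset == "same_trend"] >= out$r[out$subset == "all"]
  })
  expect_gte(mean(wins), 0.9)
})
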