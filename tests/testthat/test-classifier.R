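block_similarity <- function(n1 = 10, n2 = 30, within = 0.9, between = 0.1) {
  n <- n1 + n2
  lab <- factor(rep(c("normal_benign", "ec_ein"), c(n1, n2)),
                c("normal_benign", "ec_ein"))
  S <- matrix(between, n, n)
  S[seq_len(n1), seq_len(n1)] <- within
  S[n1 + seq_len(n2), n1 + seq_len(n2)] <- within
  diag(S) <- 1
  structure(list(S = S, ids = sprintf("s%02d", seq_len(n)), labels = lab),
            class = "similarity_matrix")
}

test_that("cosine similarity matches the naive dot-product oracle", {
  set.seed(42)
  tab <- as.data.frame(matrix(abs(rnorm(50)), 10, 5))
  sim <- cosine_similarity(tab)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    xi <- as.numeric(tab[i, ]); xj <- as.numeric(tab[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2)) / sqrt(sum(xj^2))
  }
  expect_lt(max(abs(sim$S - oracle)), 1e-12)

  expect_equal(unname(diag(sim$S)), rep(1, 10))
  expect_identical(sim$S, t(sim$S))

  # identical and orthogonal rows
  t2 <- data.frame(a = c(1, 2, 1, 0), b = c(2, 4, 0, 1))
  s2 <- cosine_similarity(t2)
  expect_equal(s2$S[1, 2], 1)
  expect_equal(s2$S[3, 4], 0)

  # per-row positive rescaling leaves S unchanged
  t3 <- tab * matrix(runif(10, 0.5, 5), 10, 5)
  expect_equal(cosine_similarity(t3)$S, sim$S, tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero-norm row errors with the sample named; missing rows are dropped
  t4 <- data.frame(a = c(1, 0), b = c(1, 0))
  rownames(t4) <- c("good", "badrow")
  expect_error(cosine_similarity(rbind(t4, data.frame(a = 2, b = 1,
                                                      row.names = "x"))),
               "badrow")
  t5 <- data.frame(a = c(1, NA, 2, 3), b = c(1, 1, 2, 1))
  expect_warning(s5 <- cosine_similarity(t5), "missing")
  expect_equal(nrow(s5$S), 3)
})

test_that("force layout separates blocks and responds to edge weight", {
  # two nodes at increasing similarity end up closer
  d <- vapply(c(0.2, 0.5, 0.9), function(w) {
    S <- matrix(c(1, w, w, 1), 2)
    sm <- structure(list(S = S, ids = c("a", "b"), labels = NULL),
                    class = "similarity_matrix")
    xy <- force_layout(sm, seed = 3)$coords
    sqrt((xy$x[1] - xy$x[2])^2 + (xy$y[1] - xy$y[2])^2)
  }, numeric(1))
  expect_true(all(diff(d) < 0))

  # block structure embeds with within < between distances
  e <- force_layout(block_similarity(), seed = 5)
  xy <- as.matrix(e$coords[, c("x", "y")])
  D <- as.matrix(dist(xy))
  lab <- e$coords$label
  within <- c(D[lab == "ec_ein", lab == "ec_ein"],
              D[lab == "normal_benign", lab == "normal_benign"])
  between <- D[lab == "ec_ein", lab == "normal_benign"]
  expect_lt(mean(within), mean(between))

  # determinism
  expect_identical(force_layout(block_similarity(), seed = 11),
                   force_layout(block_similarity(), seed = 11))
  expect_error(force_layout(structure(list(S = matrix(1, 1, 1), ids = "a",
                                           labels = NULL),
                                      class = "similarity_matrix")),
               "at least two")
})

test_that("2D logistic boundary sides with separable labels", {
  coords <- data.frame(id = as.character(1:8),
                       x = c(-3, -2.5, -2, -3.5, 2, 2.5, 3, 3.5),
                       y = c(0.5, -0.5, 1, -1, 0.3, -0.2, 0.8, -0.6),
                       label = factor(rep(c("normal_benign", "ec_ein"),
                                          each = 4),
                                      c("normal_benign", "ec_ein")))
  emb <- structure(list(coords = coords, seed = 1, n_iter = 1, energy = 0),
                   class = "embedding_2d")
  b <- boundary_2d(emb)
  expect_equal(b$n_correct_side, 8)
  expect_true(all(is.finite(b$coefficients)))

  # random labels: no systematic separation, so the in-sample boundary
  # sits between chance (4/8) and the separable ceiling (8/8) on average
  set.seed(31)
  hits <- replicate(100, {
    lab <- factor(sample(rep(c("normal_benign", "ec_ein"), each = 4)),
                  c("normal_benign", "ec_ein"))
    boundary_2d(emb, labels = lab)$n_correct_side
  })
  expect_gte(mean(hits), 4)
  expect_lt(mean(hits), 7.8)
})

test_that("similarity summary matches hand arithmetic and excludes self", {
  lab <- factor(c("normal_benign", "normal_benign", "normal_benign",
                  "ec_ein", "ec_ein"), c("normal_benign", "ec_ein"))
  sims <- c(1.0, 0.8, 0.6, 0.4, 0.5)
  # training sample 1 (normal): own cluster stats exclude the self-sim 1.0
  v <- similarity_summary(sims, lab, self = 1)
  expect_equal(unname(v["mean_sim_normal"]), 0.7)
  expect_equal(unname(v["sd_sim_normal"]), sd(c(0.8, 0.6)))
  expect_equal(unname(v["mean_sim_ecein"]), 0.45)
  expect_equal(unname(v["sd_sim_ecein"]), sd(c(0.4, 0.5)))

  # held-out sample: nothing excluded
  h <- similarity_summary(sims, lab, self = NULL)
  expect_equal(unname(h["mean_sim_normal"]), 0.8)
  expect_equal(unname(h["sd_sim_normal"]), sd(c(1, 0.8, 0.6)))

  # constant similarities collapse to (c, 0, c, 0)
  u <- similarity_summary(rep(0.3, 5), lab)
  expect_equal(unname(u), c(0.3, 0, 0.3, 0))

  # order of training samples does not matter
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(similarity_summary(sims[perm], lab[perm], self = NULL), h)

  # a cluster collapsing below 2 usable samples is an error: excluding
  # self from a 2-sample cluster leaves a single value with no SD
  expect_error(similarity_summary(sims, lab, self = 4), "fewer than 2")
  lab2 <- factor(c("normal_benign", "ec_ein", "ec_ein", "ec_ein", "ec_ein"),
                 c("normal_benign", "ec_ein"))
  expect_error(similarity_summary(sims, lab2, self = 1), "fewer than 2")
})

test_that("LOOCV separates block structure and is leakage-free", {
  sim <- block_similarity()
  cv <- loocv_similarity(sim)
  expect_equal(cv$auc, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(sum(cv$confusion), 40)

  # leakage audit: each fold re-run from inputs with the held-out sample
  # deleted reproduces the pooled prediction exactly
  S <- sim$S; lab <- sim$labels
  for (i in seq_len(nrow(S))) {
    tr <- setdiff(seq_len(nrow(S)), i)
    fold <- pamvasc:::loocv_fold(S[tr, tr], lab[tr], S[i, tr])
    expect_identical(unname(cv$prob[i]), fold$prob)
  }

  # changing the held-out sample's label never changes its prediction
  lab2 <- sim$labels
  lab2[1] <- "ec_ein"
  sim2 <- sim; sim2$labels <- lab2
  cv2 <- loocv_similarity(sim2)
  expect_equal(unname(cv2$prob[1]), unname(cv$prob[1]))

  expect_error(loocv_similarity(block_similarity(n1 = 2, n2 = 10)), "labels")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  probs <- c(0.9, 0.8, 0.4, 0.3)
  lab <- factor(c("ec_ein", "normal_benign", "ec_ein", "normal_benign"),
                c("normal_benign", "ec_ein"))
  expect_equal(roc_auc(probs, lab), 0.75)
  expect_equal(roc_auc(probs, lab), pair_count_auc(probs, lab))

  # perfectly ordered and all-tied cases
  ord <- factor(rep(c("normal_benign", "ec_ein"), each = 5),
                c("normal_benign", "ec_ein"))
  expect_equal(roc_auc(c(1:5 / 10, 6:10 / 10), ord), 1)
  expect_equal(roc_auc(rep(0.5, 10), ord), 0.5)

  # random scores match the oracle across seeds
  for (s in 1:10) {
    set.seed(s)
    n <- sample(6:50, 1)
    p <- round(runif(n), 2)  # rounding forces ties
    l <- factor(sample(rep(c("normal_benign", "ec_ein"),
                           c(floor(n / 2), ceiling(n / 2)))),
                c("normal_benign", "ec_ein"))
    expect_equal(roc_auc(p, l), pair_count_auc(p, l))
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(roc_auc(p, l),
                   as.numeric(pROC::auc(pROC::roc(l, p, quiet = TRUE,
                                                  direction = "<",
                                                  levels = c("normal_benign",
                                                             "ec_ein")))))
  }

  cm <- confusion_at(c(0.9, 0.2, 0.7, 0.4), lab, 0.5)
  expect_equal(unname(cm$counts["TP"]), 2)
  expect_equal(unname(cm$counts["TN"]), 2)
  expect_equal(cm$accuracy, 1)
  expect_error(roc_auc(c(.1, .2), factor(c("a", "a"))), "labels")
})

test_that("the ridge-stabilized logistic fit matches glm away from separation", {
  set.seed(12)
  n <- 80
  X <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(0.4 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- pamvasc:::ridge_logistic(X, y, lambda = 1e-6)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)

  # perfect separation still yields finite coefficients and 0/1 fits
  Xs <- matrix(c(rep(-2, 5), rep(2, 5)), ncol = 1)
  ys <- rep(c(0, 1), each = 5)
  fs <- pamvasc:::ridge_logistic(Xs, ys, lambda = 1e-6)
  expect_true(all(is.finite(fs$beta)))
  expect_true(all(abs(ys - plogis(cbind(1, Xs) %*% fs$beta)) < 0.01))
})

test_that("roc_points traces a valid monotone curve", {
  set.seed(2)
  p <- runif(20)
  l <- factor(rep(c("normal_benign", "ec_ein"), 10),
              c("normal_benign", "ec_ein"))
  pts <- roc_points(p, l)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(tail(pts$fpr, 1), 1); expect_equal(tail(pts$tpr, 1), 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
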