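#' Cosine-similarity matrix of feature vectors
#'
#' Each sample's feature vector (restricted to `features`) is divided by
#' its Euclidean norm and pairwise similarities are the inner products of
#' the normalized vectors. Features are used on their raw scale by
#' default — the similarity is then invariant to per-sample positive
#' scaling but sensitive to the features' units; set `scale = TRUE` to
#' z-scale columns across samples first (an exposed alternative, not the
#' default).
#'
#' Rows with missing values in the selected columns are dropped with a
#' warning; a zero-norm row is an error naming the sample.
#'
#' @param table data.frame with feature columns, an optional `label`
#'   column, and row names as sample ids.
#' @param features character vector of feature columns to use; defaults
#'   to all numeric non-label columns.
#' @param scale z-scale columns before normalization (default `FALSE`).
#' @return An object of class `similarity_matrix`: `S` (symmetric,
#'   unit-diagonal), `ids`, `labels` (factor or `NULL`).
#' @export
cosine_similarity <- function(table, features = NULL, scale = FALSE) {
  check_that(is.data.frame(table), "table", "must be a data.frame")
  if (is.null(features))
    features <- setdiff(names(table), "label")[
      vapply(table[setdiff(names(table), "label")], is.numeric, logical(1))]
  check_that(all(features %in% names(table)), "features",
             "must name columns of `table`")
  X <- as.matrix(table[features])
  ids <- rownames(table) %||% as.character(seq_len(nrow(table)))
  keep <- complete.cases(X)
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with missing feature values: %s",
                    sum(!keep), paste(ids[!keep], collapse = ", ")))
    X <- X[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  check_that(nrow(X) >= 2, "table", "needs at least two complete samples")
  if (scale) X <- base::scale(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop(sprintf("zero-norm feature vector for sample(s): %s",
                 paste(ids[nrm == 0], collapse = ", ")), call. = FALSE)
  Xn <- X / nrm
  S <- Xn %*% t(Xn)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  labels <- if ("label" %in% names(table))
    factor(table$label[keep]) else NULL
  structure(list(S = S, ids = ids, labels = labels),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, similarity range [%.3f, 1]\n",
              nrow(x$S), ncol(x$S), min(x$S)))
  invisible(x)
}

#' Force-directed 2D embedding of a similarity network
#'
#' Embeds the weighted similarity graph (complete graph, edge weight =
#' cosine similarity) on a plane with the Fruchterman-Reingold spring
#' layout: high-similarity pairs attract more strongly, all nodes repel,
#' and positions are iterated toward an energy minimum. Deterministic
#' given `seed`.
#'
#' Cosine similarities of nonnegative feature vectors live in a
#' compressed range near 1, which leaves the spring forces almost
#' uniform; the off-diagonal similarities are therefore min-max rescaled
#' to `[0, 1]` before being used as attraction weights (the weakest
#' relation attracts not at all, the strongest fully). The rescaling is
#' monotone, so "higher similarity, stronger attraction" is preserved;
#' when all off-diagonal similarities are equal the raw values are used
#' unchanged.
#'
#' @param sim a [cosine_similarity()] result (or any `similarity_matrix`).
#' @param seed RNG seed for the layout initialization.
#' @param n_iter number of layout iterations.
#' @return An object of class `embedding_2d`: data.frame `coords`
#'   (`id`, `x`, `y`, `label`), `seed`, `n_iter`, `energy` (attractive
#'   spring energy `sum w * d^2 / 2`, a convergence diagnostic).
#' @export
force_layout <- function(sim, seed = 42L, n_iter = 500L) {
  if (!inherits(sim, "similarity_matrix"))
    stop("`sim` must be a similarity_matrix", call. = FALSE)
  n <- nrow(sim$S)
  if (n < 2) stop("need at least two samples to lay out", call. = FALSE)
  check_scalar_num(n_iter, "n_iter", lower = 1)
  W <- sim$S
  off <- W[upper.tri(W)]
  if (length(off) > 1L && max(off) > min(off))
    W <- (W - min(off)) / (max(off) - min(off))
  W <- pmax(W, 0)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  xy <- with_seed(seed, igraph::layout_with_fr(
    g, niter = as.integer(n_iter), weights = igraph::E(g)$weight))
  d2 <- as.matrix(dist(xy))^2
  energy <- sum(W * d2) / 4  # each pair counted twice in the sum
  structure(list(coords = data.frame(id = sim$ids, x = xy[, 1], y = xy[, 2],
                                     label = sim$labels %||%
                                       rep(NA, n)),
                 seed = seed, n_iter = as.integer(n_iter), energy = energy),
            class = "embedding_2d")
}

#' @export
print.embedding_2d <- function(x, ...) {
  cat(sprintf("<embedding_2d> %d points, seed %s, %d iterations\n",
              nrow(x$coords), format(x$seed), x$n_iter))
  invisible(x)
}

#' @export
plot.embedding_2d <- function(x, boundary = NULL, ...) {
  lab <- factor(x$coords$label)
  cols <- c("#2166AC", "#B2182B")[as.integer(lab)]
  plot(x$coords$x, x$coords$y, col = cols, pch = 19,
       xlab = "embedding x", ylab = "embedding y", ...)
  if (!is.null(boundary)) {
    b <- boundary$coefficients
    if (abs(b[3]) > 1e-12)
      abline(a = -b[1] / b[3], b = -b[2] / b[3], lty = 2, col = "darkgreen")
    else abline(v = -b[1] / b[2], lty = 2, col = "darkgreen")
  }
  if (nlevels(lab))
    graphics::legend("topleft", legend = levels(lab), col = c("#2166AC", "#B2182B"),
                     pch = 19, bty = "n")
  invisible(x)
}

#' In-sample logistic separation boundary on 2D embedding coordinates
#'
#' Fits a two-feature logistic regression (with a small ridge penalty so
#' perfectly separated layouts still yield a finite boundary) to the
#' embedding coordinates and reports the linear boundary (zero of the
#' linear score) together with how many samples fall on their own label's
#' side. This is the visualization companion of the LOOCV classifier, not
#' a validated classifier itself.
#'
#' @param emb an [force_layout()] embedding.
#' @param labels two-level factor; defaults to the labels stored in the
#'   embedding. The second level is the positive class.
#' @param lambda ridge penalty.
#' @return List of class `boundary_2d`: `coefficients` (intercept, x, y),
#'   `n_correct_side`, `n`, `fitted_prob`.
#' @export
boundary_2d <- function(emb, labels = NULL, lambda = 1e-6) {
  if (!inherits(emb, "embedding_2d"))
    stop("`emb` must be an embedding_2d", call. = FALSE)
  labels <- labels %||% emb$coords$label
  lab <- factor(labels)
  check_that(nlevels(lab) == 2 && all(table(lab) >= 1), "labels",
             "must contain both classes")
  X <- as.matrix(emb$coords[, c("x", "y")])
  y <- as.integer(lab) - 1L
  fit <- ridge_logistic(X, y, lambda = lambda)
  score <- cbind(1, X) %*% fit$beta
  correct <- sum((score > 0) == (y == 1L))
  structure(list(coefficients = setNames(drop(fit$beta),
                                         c("(Intercept)", "x", "y")),
                 n_correct_side = correct, n = length(y),
                 fitted_prob = drop(plogis(score))),
            class = "boundary_2d")
}

# Ridge-penalized logistic regression by damped Newton iterations.
# The intercept is unpenalized. Small lambda keeps the MLE behaviour on
# separable data finite (coefficients grow to O(1/sqrt(lambda)) instead
# of diverging).
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 200L,
                           tol = 1e-10) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    # numerically stable log(1 + exp(eta))
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    -sum(y * eta - lse) + sum(pen * b^2) / 2
  }
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    g <- drop(crossprod(Xd, y - mu)) - pen * beta
    H <- crossprod(Xd, Xd * w) + diag(pen, p)
    step <- solve(H, g)
    # backtracking line search on the penalized deviance
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- beta + alpha * step
    fn <- obj(beta)
    if (abs(f - fn) < tol * (abs(f) + 1)) { f <- fn; break }
    f <- fn
  }
  list(beta = beta, value = f)
}
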