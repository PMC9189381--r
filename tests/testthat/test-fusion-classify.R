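make_table <- function(ids, groups, n_feat, prefix = "f") {
  m <- matrix(stats::rnorm(length(ids) * n_feat), nrow = length(ids))
  if (n_feat > 0) colnames(m) <- paste0(prefix, seq_len(n_feat))
  mcifuse:::new_feature_table(ids, groups, m,
                              stats::setNames(rep("test", n_feat),
                                              colnames(m)))
}

test_that("fusion concatenates p + q columns and preserves provenance", {
  ids <- sprintf("s%02d", 1:6)
  g <- rep(c("A", "B"), 3)
  t1 <- make_table(ids, g, 3, "x")
  t2 <- make_table(ids, g, 4, "y")
  fused <- fuse_features(list(t1, t2))
  expect_equal(ncol(fused) - 2, 7)
  expect_equal(length(attr(fused, "provenance")), 7)
  expect_identical(fuse_features(list(t1))[, -(1:2)], t1[, -(1:2)])
  t0 <- make_table(ids, g, 0)
  expect_equal(ncol(fuse_features(list(t1, t0))) - 2, 3)
  t3 <- make_table(rev(ids), rev(g), 2)
  expect_error(fuse_features(list(t1, t3)), "mismatch")
})

test_that("LOOCV runs n folds and perfectly separated data scores 1", {
  set.seed(20)
  n <- 10
  X <- rbind(matrix(stats::rnorm(3 * 5, mean = 5), 5),
             matrix(stats::rnorm(3 * 5, mean = 0), 5))
  colnames(X) <- paste0("v", 1:3)
  y <- rep(c("A", "B"), each = 5)
  for (kind in c("nb", "lda", "lr", "svm")) {
    rep_ <- loocv_evaluate(X, y, classifier_spec(kind))
    expect_equal(nrow(rep_$predictions), n)
    expect_equal(rep_$tp + rep_$fn + rep_$fp + rep_$tn, n)
    expect_equal(rep_$acc, 1)
    expect_equal(rep_$auc, 1)
  }
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(21)
  X <- matrix(stats::rnorm(16 * 3), 16)
  colnames(X) <- paste0("v", 1:3)
  accs <- replicate(10, {
    y <- sample(rep(c("A", "B"), each = 8))
    loocv_evaluate(X, y, classifier_spec("nb"))$acc
  })
  # mean accuracy near 0.5 (binomial bounds over the 160 pooled folds)
  bounds <- stats::qbinom(c(0.005, 0.995), 160, 0.5) / 160
  expect_gte(mean(accs), bounds[1] - 0.05)
  expect_lte(mean(accs), bounds[2] + 0.05)
})

test_that("LDA boundary sits at the midpoint for symmetric 1-D classes", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1,
              dimnames = list(NULL, "v1"))
  y <- rep(c("B", "A"), each = 3)
  model <- train_classifier(classifier_spec("lda"), x, y)
  just_below <- matrix(5.9, 1, 1, dimnames = list(NULL, "v1"))
  just_above <- matrix(6.1, 1, 1, dimnames = list(NULL, "v1"))
  expect_equal(predict_classifier(model, just_below)$class, "B")
  expect_equal(predict_classifier(model, just_above)$class, "A")
})

test_that("LDA direction matches brute-force Fisher criterion maximization", {
  set.seed(22)
  x <- rbind(matrix(stats::rnorm(40, 0), ncol = 2),
             sweep(matrix(stats::rnorm(40, 0), ncol = 2), 2, c(2, 1), `+`))
  x[, 2] <- x[, 2] + 0.5 * x[, 1]   # correlated features
  colnames(x) <- c("v1", "v2")
  y <- rep(c("B", "A"), each = 20)
  model <- train_classifier(classifier_spec("lda"), x, y)
  w_pkg <- model$model$scaling[, 1]
  # dense grid over unit directions, maximizing (w'Sb w)/(w'Sw w)
  fisher <- function(theta) {
    w <- c(cos(theta), sin(theta))
    u0 <- colMeans(x[y == "B", ]); u1 <- colMeans(x[y == "A", ])
    sw <- crossprod(sweep(x[y == "B", ], 2, u0)) +
          crossprod(sweep(x[y == "A", ], 2, u1))
    sb <- tcrossprod(u0 - u1)
    drop(crossprod(w, sb %*% w) / crossprod(w, sw %*% w))
  }
  grid <- seq(0, pi, length.out = 3601)
  w_best <- c(cos(grid[which.max(sapply(grid, fisher))]),
              sin(grid[which.max(sapply(grid, fisher))]))
  cosang <- abs(sum(w_pkg * w_best)) / sqrt(sum(w_pkg^2))
  expect_gt(cosang, 0.999)
})

test_that("heavy L2 regularization shrinks LR toward the majority class", {
  set.seed(23)
  x <- matrix(stats::rnorm(30), ncol = 2,
              dimnames = list(NULL, c("v1", "v2")))
  y <- rep(c("A", "B"), c(10, 5))
  spec <- classifier_spec("lr", lambda_grid = 1e6)
  model <- train_classifier(spec, x, y)
  pred <- predict_classifier(model, x)
  expect_true(all(pred$class == "A"))  # majority class
  expect_lt(stats::sd(pred$score), 0.01)
})

test_that("metrics follow their defining formulas", {
  m <- compute_metrics(3, 1, 1, 2)
  expect_equal(m$acc, 5 / 7, tolerance = 1e-12)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$f1, 0.75)
  perfect <- compute_metrics(4, 0, 0, 4, scores = c(rep(1, 4), rep(0, 4)),
                             labels = rep(c("A", "B"), each = 4))
  expect_equal(perfect$acc, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  ties <- compute_metrics(2, 2, 2, 2, scores = rep(0.3, 8),
                          labels = rep(c("A", "B"), each = 4))
  expect_equal(ties$auc, 0.5)
  undef <- compute_metrics(0, 3, 0, 5)
  expect_true(undef$precision_undefined)
  expect_equal(undef$precision, 0)
})

test_that("AUC is invariant under strictly monotone score transformations", {
  set.seed(24)
  sc <- stats::rnorm(20)
  lab <- sample(rep(c("A", "B"), 10))
  a1 <- mcifuse:::rank_auc(sc, lab)
  expect_equal(mcifuse:::rank_auc(exp(sc), lab), a1)
  expect_equal(mcifuse:::rank_auc(sc * 100 - 3, lab), a1)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(lab, sc, levels = c("B", "A"),
                                              direction = "<")))
  expect_equal(a1, as.numeric(ref), tolerance = 1e-12)
})

test_that("F1 identity holds on LOOCV reports", {
  set.seed(25)
  X <- matrix(stats::rnorm(12 * 2), ncol = 2,
              dimnames = list(NULL, c("v1", "v2")))
  X[1:6, 1] <- X[1:6, 1] + 1.5
  y <- rep(c("A", "B"), each = 6)
  r <- loocv_evaluate(X, y, classifier_spec("lda"))
  if (r$precision + r$sensitivity > 0)
    expect_equal(r$f1, 2 * r$precision * r$sensitivity /
                   (r$precision + r$sensitivity), tolerance = 1e-12)
})
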