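# Multiscale feature fusion and LOOCV evaluation with NB / LDA / L2-logistic
# regression / RBF-SVM. Group "A" (aMCI) is the positive class throughout and
# every continuous score is oriented so that larger means more aMCI-like.

#' Fuse feature tables by column-wise concatenation
#'
#' If the inputs have p and q feature columns the fused table has p + q, with
#' provenance preserved. All tables must cover the same subjects in the same
#' order.
#'
#' @param tables List of `feature_table`s (see [mgswbc_maps()] etc.).
#' @return A fused `feature_table`.
#' @export
fuse_features <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- tables[[1]]$subject_id
  groups <- tables[[1]]$group
  for (tb in tables[-1]) {
    if (!identical(tb$subject_id, ids)) {
      bad <- union(setdiff(tb$subject_id, ids), setdiff(ids, tb$subject_id))
      if (length(bad) == 0) bad <- "(same set, different order)"
      stop("subject mismatch across tables: ", paste(bad, collapse = ", "))
    }
  }
  feats <- lapply(tables, function(tb)
    as.matrix(tb[, setdiff(colnames(tb), c("subject_id", "group")), drop = FALSE]))
  all_feat <- do.call(cbind, feats)
  prov <- do.call(c, lapply(tables, attr, "provenance"))
  new_feature_table(ids, groups, all_feat, prov)
}

#' Classifier specification
#'
#' @param kind One of "nb" (Gaussian naive Bayes), "lda" (Fisher linear
#'   discriminant), "lr" (L2-regularized logistic regression) or "svm"
#'   (soft-margin SVM with Gaussian RBF kernel).
#' @param lambda_grid Ridge penalties searched for "lr" on the training fold.
#' @param cost_grid SVM penalty parameters C searched on the training fold.
#' @param sigma2_factors Multipliers of the median squared pairwise distance
#'   defining the RBF width grid sigma^2.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("nb", "lda", "lr", "svm"),
                            lambda_grid = c(1, 0.1, 0.01),
                            cost_grid = c(0.1, 1, 10, 100),
                            sigma2_factors = c(0.1, 1, 10)) {
  kind <- match.arg(kind)
  stopifnot(all(lambda_grid > 0), all(cost_grid > 0), all(sigma2_factors > 0))
  structure(list(kind = kind, lambda_grid = lambda_grid,
                 cost_grid = cost_grid, sigma2_factors = sigma2_factors),
            class = "classifier_spec")
}

# glmnet warns about small binomial classes on every tiny training fold;
# that is expected at toy sizes and drowns real warnings.
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Deterministic stratified fold assignment (round-robin within class).
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

# Inner grid search: pick the grid row with best k-fold accuracy (first wins).
inner_grid_select <- function(grid, X, y, fit_predict, k = 5) {
  k <- min(k, min(table(y)))
  folds <- stratified_folds(y, k)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    hits <- 0L
    for (fo in seq_len(k)) {
      tr <- folds != fo
      if (length(unique(y[tr])) < 2) next
      pred <- fit_predict(grid[gi, , drop = FALSE],
                          X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE])
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  grid[which.max(acc), , drop = FALSE]
}

#' Train one classifier
#'
#' NB is Gaussian class-conditional Bayes; LDA is the closed-form Fisher
#' discriminant (via `MASS::lda`, with a ridge-stabilized fallback when the
#' within-class scatter is singular); LR minimizes the L2-penalized logistic
#' loss (via `glmnet`, ridge penalty chosen by an inner stratified 5-fold grid
#' search on the training data); SVM is a soft-margin RBF machine whose C and
#' kernel width are chosen the same way, the width grid being scaled by the
#' median squared pairwise distance of the training data.
#'
#' @param spec A [classifier_spec()].
#' @param x_train Numeric matrix (subjects x features), already standardized.
#' @param y_train Character/factor labels "A"/"B" with both classes present.
#' @return An opaque trained model for [predict_classifier()].
#' @export
train_classifier <- function(spec, x_train, y_train) {
  stopifnot(inherits(spec, "classifier_spec"))
  y_train <- as.character(y_train)
  if (length(unique(y_train)) < 2) stop("training data must contain both classes")
  if (min(table(y_train)) < 2) stop("need at least 2 samples per class")
  yf <- factor(y_train, levels = c("B", "A"))
  model <- switch(spec$kind,
    nb = e1071::naiveBayes(x = as.data.frame(x_train), y = yf),
    lda = tryCatch(
      withCallingHandlers(
        MASS::lda(x = x_train, grouping = yf),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warning("singular within-class scatter; using ridge-stabilized LDA")
        ridge_lda(x_train, yf)
      }),
    lr = {
      grid <- data.frame(lambda = spec$lambda_grid)
      best <- inner_grid_select(grid, x_train, y_train, function(g, Xt, yt, Xv) {
        fit <- quiet_small_class(
          glmnet::glmnet(Xt, factor(yt, levels = c("B", "A")),
                         family = "binomial", alpha = 0, lambda = g$lambda))
        ifelse(drop(stats::predict(fit, Xv, type = "response")) > 0.5, "A", "B")
      })
      quiet_small_class(
        glmnet::glmnet(x_train, yf, family = "binomial", alpha = 0,
                       lambda = best$lambda))
    },
    svm = {
      d2 <- stats::dist(x_train)^2
      med <- stats::median(d2[d2 > 0])
      if (!is.finite(med) || med <= 0) med <- 1
      grid <- expand.grid(cost = spec$cost_grid,
                          sigma2 = spec$sigma2_factors * med)
      best <- inner_grid_select(grid, x_train, y_train, function(g, Xt, yt, Xv) {
        fit <- e1071::svm(Xt, factor(yt, levels = c("B", "A")),
                          kernel = "radial", cost = g$cost,
                          gamma = 1 / g$sigma2, scale = FALSE)
        as.character(stats::predict(fit, Xv))
      })
      e1071::svm(x_train, yf, kernel = "radial", cost = best$cost,
                 gamma = 1 / best$sigma2, scale = FALSE)
    })
  structure(list(kind = spec$kind, model = model), class = "mcifuse_model")
}

# Closed-form Fisher LDA with a ridge on the within-class scatter.
ridge_lda <- function(x, yf, ridge = 1e-6) {
  x0 <- x[yf == "B", , drop = FALSE]
  x1 <- x[yf == "A", , drop = FALSE]
  u0 <- colMeans(x0); u1 <- colMeans(x1)
  sw <- crossprod(sweep(x0, 2, u0)) + crossprod(sweep(x1, 2, u1))
  sw <- sw + ridge * mean(diag(sw)) * diag(ncol(x))
  w <- solve(sw, u1 - u0)
  thr <- drop(crossprod(w, (u0 + u1) / 2))
  structure(list(w = w, threshold = thr), class = "ridge_lda")
}

#' Predict with a trained classifier
#'
#' @param model A model from [train_classifier()].
#' @param x_new Numeric matrix of new subjects (standardized like the
#'   training data).
#' @return List with `class` (character "A"/"B") and `score` (continuous,
#'   larger = more aMCI-like: posterior P(A) for NB/LDA/LR, oriented decision
#'   value for SVM).
#' @export
predict_classifier <- function(model, x_new) {
  stopifnot(inherits(model, "mcifuse_model"))
  switch(model$kind,
    nb = {
      pr <- stats::predict(model$model, as.data.frame(x_new), type = "raw")
      sc <- unname(pr[, "A"])
      list(class = ifelse(sc > 0.5, "A", "B"), score = sc)
    },
    lda = {
      if (inherits(model$model, "ridge_lda")) {
        proj <- drop(x_new %*% model$model$w)
        sc <- proj - model$model$threshold
        list(class = ifelse(sc > 0, "A", "B"), score = sc)
      } else {
        pr <- stats::predict(model$model, x_new)
        sc <- unname(pr$posterior[, "A"])
        list(class = ifelse(sc > 0.5, "A", "B"), score = sc)
      }
    },
    lr = {
      sc <- unname(drop(stats::predict(model$model, x_new, type = "response")))
      list(class = ifelse(sc > 0.5, "A", "B"), score = sc)
    },
    svm = {
      pr <- stats::predict(model$model, x_new, decision.values = TRUE)
      dvm <- attr(pr, "decision.values")
      dv <- unname(drop(dvm))
      # the decision-value column name "X/Y" says positive values favour X
      pos_class <- strsplit(colnames(dvm)[1], "/")[[1]][1]
      if (pos_class != "A") dv <- -dv
      list(class = unname(as.character(pr)), score = dv)
    })
}

#' Rank (Mann-Whitney) AUC of scores against labels
#'
#' @param scores Continuous scores, larger = more "A"-like.
#' @param labels "A"/"B" per score.
#' @return AUC in [0, 1]; 0.5 when all scores are tied.
#' @keywords internal
rank_auc <- function(scores, labels) {
  pos <- labels == "A"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics from a confusion matrix
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP), Sensitivity =
#' TP/(TP+FN), F1 = 2 * Precision * Sensitivity / (Precision + Sensitivity);
#' AUC is the Mann-Whitney rank statistic of the pooled scores.
#'
#' @param tp,fn,fp,tn Confusion counts ("A" = positive).
#' @param scores,labels Optional pooled continuous scores and true labels for
#'   the AUC.
#' @return An `evaluation_report`: list with the counts, `acc`, `precision`
#'   (0 with `precision_undefined = TRUE` when TP+FP = 0), `sensitivity`,
#'   `f1`, `auc`.
#' @export
compute_metrics <- function(tp, fn, fp, tn, scores = NULL, labels = NULL) {
  n <- tp + fn + fp + tn
  stopifnot(n >= 1, tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  acc <- (tp + tn) / n
  prec_undef <- (tp + fp) == 0
  precision <- if (prec_undef) 0 else tp / (tp + fp)
  sensitivity <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  auc <- if (is.null(scores)) NA_real_ else rank_auc(scores, labels)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, acc = acc,
                 precision = precision, precision_undefined = prec_undef,
                 sensitivity = sensitivity, f1 = f1, auc = auc),
            class = "evaluation_report")
}

#' Leave-one-out cross-validated evaluation
#'
#' One fold per subject: feature columns are standardized with the training
#' fold's mean and standard deviation (constant columns pass through
#' unscaled), the classifier is fit on the remaining n - 1 subjects, and the
#' held-out subject receives a predicted class and a continuous score. The
#' confusion matrix and metrics are computed over the pooled predictions and
#' the AUC from the pooled scores.
#'
#' @param features A `feature_table` or a plain numeric matrix.
#' @param labels "A"/"B" per subject (taken from the table when omitted).
#' @param spec A [classifier_spec()].
#' @return An `evaluation_report` with additional elements `predictions`
#'   (data.frame subject, truth, predicted, score) and `classifier`.
#' @export
loocv_evaluate <- function(features, labels = NULL, spec) {
  if (inherits(features, "feature_table")) {
    if (is.null(labels)) labels <- features$group
    ids <- features$subject_id
    X <- as.matrix(features[, setdiff(colnames(features),
                                      c("subject_id", "group")), drop = FALSE])
  } else {
    X <- as.matrix(features)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("sub-%03d", seq_len(nrow(X)))
  }
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 4) stop("LOOCV needs at least 4 subjects")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (ncol(X) == 0) stop("feature table has no feature columns")
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- labels[-i]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr_s <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Xte_s <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2, sdv, `/`)
    model <- train_classifier(spec, Xtr_s, ytr)
    out <- predict_classifier(model, Xte_s)
    pred[i] <- out$class
    score[i] <- out$score
  }
  tp <- sum(pred == "A" & labels == "A")
  fn <- sum(pred == "B" & labels == "A")
  fp <- sum(pred == "A" & labels == "B")
  tn <- sum(pred == "B" & labels == "B")
  rep <- compute_metrics(tp, fn, fp, tn, scores = score, labels = labels)
  rep$predictions <- data.frame(subject = ids, truth = labels,
                                predicted = pred, score = score,
                                stringsAsFactors = FALSE)
  rep$classifier <- spec$kind
  rep
}
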