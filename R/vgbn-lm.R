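# VGBN-LM: vectorize each subject's brain network by solving the generalized
# eigenproblem L y = lambda D y of the |PCC| graph Laplacian and keeping the
# optimal (smallest non-trivial) eigenvector as a 90-entry global feature.

#' Build the absolute-correlation brain graph
#'
#' Edge weights are |r_ij| with a zeroed diagonal; the full weighted graph is
#' kept (no Gaussian kernel, no k-nearest-neighbour sparsification). The
#' degree matrix has D_ii = sum_j w_ij and the Laplacian is L = D - W.
#'
#' @param cm A `connectivity_matrix` or a plain symmetric correlation matrix.
#' @return A `brain_graph`: list with `w`, `d` (diagonal vector) and `l`.
#' @export
build_graph <- function(cm) {
  r <- if (inherits(cm, "connectivity_matrix")) cm$r else cm
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (any(abs(r) > 1 + 1e-8)) stop("correlations must satisfy |r| <= 1")
  w <- abs(r)
  diag(w) <- 0
  d <- rowSums(w)
  l <- diag(d) - w
  structure(list(w = w, d = d, l = l), class = "brain_graph")
}

#' Solve the generalized eigenproblem L y = lambda D y
#'
#' Solved through the symmetric normalized Laplacian D^-1/2 L D^-1/2, whose
#' eigenvalues equal the generalized eigenvalues (all in [0, 2]) and whose
#' eigenvectors v give y = D^-1/2 v with y' D y = 1. Pairs are returned sorted
#' by ascending eigenvalue together with the residual norms ||L y - lambda D y||.
#'
#' @param g A `brain_graph` with strictly positive degrees.
#' @return A `spectral_solution`: list with `values` (ascending), `vectors`
#'   (columns y_k, normalized y' D y = 1) and `residuals`.
#' @export
solve_generalized_eigen <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  if (any(g$d <= 0))
    stop("isolated node(s) with zero degree: ",
         paste(which(g$d <= 0), collapse = ", "))
  dih <- 1 / sqrt(g$d)
  lsym <- g$l * tcrossprod(dih)
  lsym <- (lsym + t(lsym)) / 2
  es <- eigen(lsym, symmetric = TRUE)
  ord <- order(es$values)
  lam <- pmin(pmax(es$values[ord], 0), 2)  # clamp tiny numerical overshoot
  y <- dih * es$vectors[, ord, drop = FALSE]
  res <- vapply(seq_along(lam), function(k)
    sqrt(sum((g$l %*% y[, k] - lam[k] * g$d * y[, k])^2)), numeric(1))
  structure(list(values = lam, vectors = y, residuals = res),
            class = "spectral_solution")
}

# Deterministic sign rule: largest-magnitude entry positive (ties: first).
align_sign <- function(y) {
  i <- which.max(abs(y))
  if (y[i] < 0) -y else y
}

#' Sign-align a matrix of per-subject global feature vectors
#'
#' Eigenvectors are defined only up to sign; before any across-subject
#' statistic each vector is flipped so that its largest-magnitude entry is
#' positive. Applying this to vectors with arbitrarily flipped signs restores
#' a common orientation bit-exactly.
#'
#' @param y_mat Numeric matrix, subjects x regions.
#' @return The matrix with every row sign-aligned.
#' @export
align_global_vectors <- function(y_mat) {
  t(apply(y_mat, 1, align_sign))
}

#' Select the optimal global feature vector
#'
#' The constrained minimization of y' L y under y' D y fixed is solved by the
#' generalized eigenpairs; under the y' D y = 1 normalization the objective of
#' every candidate equals its eigenvalue (for the lambda != 1 branch,
#' lambda y' W y / (1 - lambda) = lambda; eigenpairs with W y = 0 sit at
#' lambda = 1 and are evaluated identically). The trivial pair (lambda ~ 0,
#' constant vector), whose objective is degenerately zero, is excluded; the
#' minimizer is therefore the Fiedler-type vector of (L, D). Ties are broken
#' by the smallest eigenvalue index and the sign is fixed so the
#' largest-magnitude entry is positive.
#'
#' @param sol A `spectral_solution`.
#' @param g The `brain_graph` it came from.
#' @param eps_eig Threshold below which an eigenvalue counts as trivial.
#' @return A `global_feature_vector`: list with `y_opt`,
#'   `selected_eigenvalue`, `objective` (y' L y) and `sign_convention`.
#' @export
select_global_vector <- function(sol, g, eps_eig = 1e-10) {
  stopifnot(inherits(sol, "spectral_solution"))
  nontrivial <- which(sol$values > eps_eig)
  if (length(nontrivial) == 0)
    stop("no non-trivial eigenpairs (empty or fully disconnected graph)")
  obj <- vapply(nontrivial, function(k) {
    y <- sol$vectors[, k]
    drop(crossprod(y, g$l %*% y))
  }, numeric(1))
  k <- nontrivial[which.min(obj)]  # which.min takes the first of tied minima
  y <- align_sign(sol$vectors[, k])
  structure(list(y_opt = y, selected_eigenvalue = sol$values[k],
                 objective = min(obj),
                 sign_convention = "largest-magnitude entry positive"),
            class = "global_feature_vector")
}

#' Compute the global feature vector of one subject's connectivity matrix
#'
#' Convenience wrapper: graph construction, generalized eigensolve and optimal
#' vector selection in one call.
#'
#' @param cm A `connectivity_matrix` or plain symmetric correlation matrix.
#' @return A `global_feature_vector` (see [select_global_vector()]).
#' @export
vgbn_vector <- function(cm) {
  g <- build_graph(cm)
  select_global_vector(solve_generalized_eigen(g), g)
}

#' Select discriminative regions of the global feature vectors
#'
#' Per-region two-sample t-test of the sign-aligned y_opt entries across
#' subjects; regions with p < alpha become the global feature columns.
#'
#' @param y_mat Numeric matrix, subjects x 90, of per-subject global vectors
#'   (sign-aligned; [align_global_vectors()] is applied again defensively).
#' @param subject_ids,groups Per-subject identifier and "A"/"B" label.
#' @param alpha Selection threshold on the per-region p-value (default 0.05).
#' @param region_names Optional atlas region names.
#' @return List with `table` (data.frame region, name, t, p, selected) and
#'   `features` (a `feature_table` of the selected regions' y_opt entries).
#' @export
ttest_select_regions <- function(y_mat, subject_ids, groups, alpha = 0.05,
                                 region_names = NULL) {
  stopifnot(is.matrix(y_mat), nrow(y_mat) == length(groups))
  y_mat <- align_global_vectors(y_mat)
  tt <- group_t_test(y_mat, groups)
  nms <- if (is.null(region_names)) sprintf("region_%02d", seq_len(ncol(y_mat)))
         else region_names
  tab <- data.frame(region = seq_len(ncol(y_mat)), name = nms,
                    t = tt$t, p = tt$p, selected = tt$p < alpha,
                    stringsAsFactors = FALSE)
  sel <- which(tab$selected)
  feat <- y_mat[, sel, drop = FALSE]
  cn <- sprintf("global_%s", gsub("[^A-Za-z0-9]+", "_", nms[sel]))
  colnames(feat) <- cn
  prov <- stats::setNames(
    sprintf("global y_opt entry | region=%s | p=%.4g", nms[sel], tab$p[sel]), cn)
  list(table = tab,
       features = new_feature_table(subject_ids, groups, feat, prov))
}

#' Number of edge features in a symmetric connectivity matrix
#'
#' The strictly-upper-triangular entry count n(n-1)/2; for the 90-region
#' atlas this is 4,005.
#'
#' @param cm A `connectivity_matrix` or plain square matrix.
#' @return Integer count.
#' @export
count_edge_features <- function(cm) {
  r <- if (inherits(cm, "connectivity_matrix")) cm$r else cm
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("input must be a square matrix")
  n <- nrow(r)
  as.integer(n * (n - 1) / 2)
}
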