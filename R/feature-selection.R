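# Feature standardization, PCA reduction and LARS-LASSO selection.
#
# The deep-feature route reduces each patch's 1024 CNN features to P_C
# principal components (one PCA pooled over all training subjects' patch
# rows), concatenates the 151 reduced patch blocks per subject, and selects
# L_C columns by least-angle regression; the structural route reduces the
# 325-column table to P_F components and selects L_F. The fused vector is
# the column-wise concatenation (L_C + L_F wide; 75 at the published
# defaults 29/150/35/40).

#' Fit a column standardizer
#'
#' Computes per-column mean and standard deviation on training rows.
#' Constant columns get scale 1 (their standardized values are exactly 0)
#' and a warning.
#'
#' @param x Numeric matrix (training rows only).
#' @return Object of class `feature_scaler` with `center` and `scale`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows to standardize")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  const <- scale == 0 | !is.finite(scale)
  if (any(const)) {
    warning(sum(const), " constant column(s) standardized to 0")
    scale[const] <- 1
  }
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' Apply a fitted standardizer
#'
#' Transforms rows with the training-set statistics (never the rows' own),
#' preserving train/test hygiene.
#'
#' @param scaler A [fit_standardizer()] object.
#' @param x Matrix with the same columns as the training matrix.
#' @return Standardized matrix.
#' @export
apply_standardizer <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$center))
    stop("column count does not match the fitted standardizer")
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Convenience: standardize a training matrix
#'
#' @param x Numeric matrix.
#' @return List with `values` (standardized `x`) and `scaler`.
#' @export
standardize <- function(x) {
  scaler <- fit_standardizer(x)
  list(values = apply_standardizer(scaler, x), scaler = scaler)
}

#' Fit a PCA model
#'
#' Principal components of the training matrix via singular value
#' decomposition of the centered data; components are orthonormal.
#'
#' @param x Numeric matrix (samples x features).
#' @param kept_dim Number of leading components to keep
#'   (`<= min(nrow, ncol)`).
#' @return Object of class `pca_model` with `center`, `components`
#'   (features x `kept_dim`), `kept_dim` and `explained_variance`.
#' @export
fit_pca <- function(x, kept_dim) {
  x <- as.matrix(x)
  if (kept_dim < 1 || kept_dim > min(dim(x)))
    stop("kept_dim must be in [1, min(n_samples, n_features)] = [1, ",
         min(dim(x)), "]")
  center <- colMeans(x)
  xc <- sweep(x, 2, center, "-")
  if (nrow(xc) > 2L * ncol(xc)) {
    # tall data: eigendecompose the d x d covariance instead of a full SVD
    ei <- eigen(crossprod(xc) / max(1, nrow(x) - 1), symmetric = TRUE)
    ev <- pmax(ei$values, 0)
    comp <- ei$vectors[, seq_len(kept_dim), drop = FALSE]
  } else {
    sv <- svd(xc, nu = 0, nv = kept_dim)
    ev <- sv$d^2 / max(1, nrow(x) - 1)
    comp <- sv$v
  }
  structure(list(center = center,
                 components = comp,
                 kept_dim = as.integer(kept_dim),
                 explained_variance = ev[seq_len(kept_dim)],
                 total_variance = sum(ev)),
            class = "pca_model")
}

#' Project rows onto fitted principal components
#'
#' @param model A [fit_pca()] model.
#' @param x Matrix with the training matrix's columns.
#' @return Matrix (samples x `kept_dim`).
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("column count does not match the fitted PCA")
  sweep(x, 2, model$center, "-") %*% model$components
}

#' Select features by least-angle-regression LASSO
#'
#' Runs the LARS path (with the lasso modification: a variable whose
#' coefficient would cross zero is dropped and the step truncated) on the
#' standardized feature matrix against the +/-1 label vector, and stops as
#' soon as `n_select` distinct variables have entered the path. The
#' selection is the entered variables in entry order, which makes the
#' selections for `n_select = k` a prefix of those for any larger
#' `n_select` (the LASSO objective `0.5*||y - D a||^2 + lambda*||a||_1` is
#' traced by the path; the stated penalty `lambda = 0.1` is retained as
#' context, the step count is the operative stop).
#'
#' @param features Numeric matrix (samples x features), expected
#'   standardized.
#' @param labels Vector in \{-1, +1\} (or \{0, 1\}, recoded).
#' @param n_select Number of features L to select.
#' @param lambda Penalty recorded with the selection (default 0.1).
#' @return Object of class `lasso_selection`: `selected` (entry-ordered
#'   indices, length `n_select`), `coefficients` (sparse vector at the
#'   stopping step), `lambda`, `n_select`.
#' @export
lars_lasso_select <- function(features, labels, n_select, lambda = 0.1) {
  X <- as.matrix(features)
  n <- nrow(X); p <- ncol(X)
  if (n_select < 0) stop("n_select must be >= 0")
  if (n_select > p) stop("cannot select ", n_select, " of ", p, " features")
  y <- as.numeric(labels)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be binary (+1/-1 or 1/0)")
  if (length(unique(y)) < 2) stop("labels are all identical")
  if (n_select == 0)
    return(structure(list(selected = integer(0), coefficients = numeric(p),
                          lambda = lambda, n_select = 0L),
                     class = "lasso_selection"))
  res <- lars_lasso_path(X, y - mean(y), n_select)
  structure(list(selected = res$entry_order, coefficients = res$beta,
                 lambda = lambda, n_select = as.integer(n_select)),
            class = "lasso_selection")
}

# LARS with lasso modification (Efron et al. style). X: n x p, y centered.
# Stops once `n_select` distinct variables have entered. Returns the entry
# order (first n_select entrants) and the coefficient vector at the stop.
lars_lasso_path <- function(X, y, n_select, eps = 1e-10, max_steps = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(max_steps)) max_steps <- 8 * p + 40
  beta <- numeric(p)
  mu <- numeric(n)
  active <- integer(0)
  entry_order <- integer(0)
  just_dropped <- integer(0)
  for (step in seq_len(max_steps)) {
    c_vec <- drop(crossprod(X, y - mu))
    inactive <- setdiff(seq_len(p), c(active, just_dropped))
    # a variable enters when its correlation has caught up with the
    # active set's shared maximum (exact equality at a path knot)
    if (length(inactive) > 0) {
      Cmax_in <- max(abs(c_vec[inactive]))
      caught_up <- length(active) == 0 ||
        Cmax_in >= max(abs(c_vec[active])) - 1e-8 * max(1, Cmax_in)
      if (caught_up) {
        j <- inactive[which.max(abs(c_vec[inactive]))]
        active <- c(active, j)
        if (!(j %in% entry_order)) entry_order <- c(entry_order, j)
        if (length(entry_order) >= n_select) {
          # the n_select-th variable has entered: selection is complete
          return(list(entry_order = entry_order[seq_len(n_select)], beta = beta))
        }
      }
    }
    just_dropped <- integer(0)
    if (length(active) == 0) break
    Cmax <- max(abs(c_vec[active]))
    if (Cmax < eps) break                      # residual correlation exhausted
    sA <- sign(c_vec[active])
    XA <- X[, active, drop = FALSE] * rep(sA, each = n)
    G <- crossprod(XA)
    w <- tryCatch(solve(G, rep(1, length(active))),
                  error = function(e) stop("LARS: singular active-set Gram matrix"))
    AA <- 1 / sqrt(sum(w))
    w <- AA * w
    u <- drop(XA %*% w)
    a <- drop(crossprod(X, u))
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive) == 0) {
      gamma <- Cmax / AA
    } else {
      g1 <- (Cmax - c_vec[inactive]) / (AA - a[inactive])
      g2 <- (Cmax + c_vec[inactive]) / (AA + a[inactive])
      cand <- c(g1[g1 > eps], g2[g2 > eps])
      gamma <- if (length(cand) == 0) Cmax / AA else min(cand, Cmax / AA)
    }
    d <- sA * w
    drop_idx <- NULL
    gtilde <- -beta[active] / d
    pos <- which(gtilde > eps & gtilde < gamma - eps)
    if (length(pos) > 0) {
      gamma <- min(gtilde[pos])
      drop_idx <- active[pos[which.min(gtilde[pos])]]
    }
    beta[active] <- beta[active] + gamma * d
    mu <- mu + gamma * u
    if (!is.null(drop_idx)) {
      beta[drop_idx] <- 0
      active <- setdiff(active, drop_idx)
      just_dropped <- drop_idx    # may not re-enter at the very next knot
    }
  }
  stop("LARS path ended after ", length(entry_order),
       " entries; cannot select ", n_select,
       " features from this design (rank/sample-size limit)")
}

#' Fuse selected deep and structural feature blocks
#'
#' Row-wise concatenation of the CNN-selected and structure-selected
#' blocks, CNN columns first. Subject ordering must agree (checked via row
#' names when present). Either block may be empty (single-route ablations).
#'
#' @param cnn_sel Matrix of selected deep features (or `NULL`).
#' @param struct_sel Matrix of selected structural features (or `NULL`).
#' @return Fused matrix, `ncol(cnn_sel) + ncol(struct_sel)` wide.
#' @export
build_fused_feature_vector <- function(cnn_sel, struct_sel) {
  if (is.null(cnn_sel) && is.null(struct_sel))
    stop("at least one feature block is required")
  if (is.null(cnn_sel)) return(as.matrix(struct_sel))
  if (is.null(struct_sel)) return(as.matrix(cnn_sel))
  cnn_sel <- as.matrix(cnn_sel); struct_sel <- as.matrix(struct_sel)
  if (nrow(cnn_sel) != nrow(struct_sel))
    stop("feature blocks have different numbers of subjects")
  rn_c <- rownames(cnn_sel); rn_s <- rownames(struct_sel)
  if (!is.null(rn_c) && !is.null(rn_s) && !identical(rn_c, rn_s))
    stop("subject ordering differs between the feature blocks")
  cbind(cnn_sel, struct_sel)
}
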