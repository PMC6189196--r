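# Mixture resolution and classification for trapped-particle spectra:
# univariate two-component Gaussian mixture EM (marker-band intensity
# histograms), PCA, Ward hierarchical clustering, PLS-DA with
# venetian-blinds cross-validation, and group band-area ratios.

#' Two-component univariate Gaussian mixture by EM
#'
#' Standard expectation-maximisation for a two-component 1-D Gaussian
#' mixture, used to resolve bimodal marker-band intensity histograms (e.g.
#' the C-D band of a deuterated/non-deuterated liposome mix). Component 1
#' is the lower-mean component by convention; hard labels are the argmax
#' responsibility. Initialisation splits the sample at its median and takes
#' component statistics from the two halves; variances are floored at
#' `1e-12 * range^2`.
#'
#' @param values numeric vector (>= 4 finite values with nonzero spread).
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @return list of class `gmm_fit` with `weights`, `means`, `sds`,
#'   `responsibilities` (n x 2, component 1 = low mean), `labels`,
#'   `loglik_trace`, `converged`, `variance_floored`.
#' @export
gmm2_em <- function(values, tol = 1e-8, max_iter = 500) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 finite values")
  rng2 <- diff(range(x))^2
  if (rng2 == 0) stop("degenerate input: all values equal")
  floor_var <- 1e-12 * rng2
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) { hi <- max(x); lo <- x[x < max(x)] }
  mu <- c(mean(lo), mean(hi))
  va <- pmax(c(stats::var(lo), stats::var(hi)), floor_var, na.rm = TRUE)
  va[is.na(va)] <- floor_var
  pi1 <- length(lo) / n
  w <- c(pi1, 1 - pi1)
  loglik <- function(mu, va, w) {
    sum(log(w[1] * stats::dnorm(x, mu[1], sqrt(va[1])) +
            w[2] * stats::dnorm(x, mu[2], sqrt(va[2]))))
  }
  trace <- loglik(mu, va, w)
  converged <- FALSE
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(va[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(va[2]))
    r1 <- d1 / (d1 + d2)
    n1 <- sum(r1); n2 <- n - n1
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    va_new <- c(sum(r1 * (x - mu[1])^2) / n1,
                sum((1 - r1) * (x - mu[2])^2) / n2)
    if (any(va_new < floor_var)) floored <- TRUE
    va <- pmax(va_new, floor_var)
    w <- c(n1 / n, n2 / n)
    ll <- loglik(mu, va, w)
    trace <- c(trace, ll)
    prev <- trace[length(trace) - 1L]
    if (is.finite(prev) && abs(ll - prev) <= tol * (abs(prev) + tol)) {
      converged <- TRUE
      break
    }
  }
  o <- order(mu)  # component 1 = lower mean
  d1 <- w[o[1]] * stats::dnorm(x, mu[o[1]], sqrt(va[o[1]]))
  d2 <- w[o[2]] * stats::dnorm(x, mu[o[2]], sqrt(va[o[2]]))
  resp <- cbind(d1, d2) / (d1 + d2)
  structure(list(weights = w[o], means = mu[o], sds = sqrt(va[o]),
                 responsibilities = resp,
                 labels = ifelse(resp[, 1] >= resp[, 2], 1L, 2L),
                 loglik_trace = trace, converged = converged,
                 variance_floored = floored),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> pi = %.3f/%.3f, mu = %.3g/%.3g, sd = %.3g/%.3g (%s)\n",
    x$weights[1], x$weights[2], x$means[1], x$means[2], x$sds[1], x$sds[2],
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Principal component analysis of a spectra matrix
#'
#' Mean-centred SVD. Scores are the centred rows projected on the loadings;
#' explained variance is ordered descending. Sign convention: the
#' largest-magnitude element of each loading is positive.
#'
#' @param x n_spectra x n_channels matrix (rows = spectra).
#' @param n_components number of components to keep.
#' @return list of class `pca_model` with `center`, `loadings` (channels x
#'   k, orthonormal), `scores` (n x k), `explained_variance`,
#'   `explained_fraction`.
#' @export
spectra_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  if (k < 1L) stop("need at least 2 rows for PCA")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = k, nv = k)
  load <- sv$v
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- xc %*% load
  ev <- sv$d^2 / max(1, nrow(x) - 1L)
  structure(list(center = ctr, loadings = load, scores = scores,
                 explained_variance = ev[seq_len(k)],
                 explained_fraction = ev[seq_len(k)] / sum(ev)),
            class = "pca_model")
}

#' Ward hierarchical clustering (Lance-Williams recurrence)
#'
#' Agglomerative minimum-variance clustering: at every step the pair of
#' clusters whose merge least increases the total within-cluster sum of
#' squares is joined. Implemented via the Lance-Williams update on merge
#' costs initialised to half the squared Euclidean distances, so the height
#' of each merge equals its increase in within-cluster sum of squares.
#' Ties are broken deterministically towards the lexicographically smallest
#' cluster pair (by smallest original member index).
#'
#' @param features numeric matrix (rows = samples), e.g. PCA scores covering
#'   >= 95 per cent of variance, or raw normalised spectra.
#' @param n_clusters requested cluster count for the cut.
#' @return list of class `ward_tree` with `merge` (hclust convention),
#'   `height` (within-SS increase per merge), `labels` (cluster index per
#'   sample at the cut), `n_clusters`.
#' @export
ward_cluster <- function(features, n_clusters = 2) {
  x <- rbind(as.matrix(features))
  n <- nrow(x)
  if (n_clusters > n) stop("n_clusters exceeds number of samples")
  # merge-cost matrix: Delta SSE of merging singletons = ||xi - xj||^2 / 2
  d <- as.matrix(stats::dist(x))^2 / 2
  diag(d) <- Inf
  size <- rep(1, n)
  active <- seq_len(n)
  node <- -seq_len(n)          # hclust convention: negatives = singletons
  minmember <- seq_len(n)      # smallest original index, for tie-breaks
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    dm <- d[active, active, drop = FALSE]
    best <- min(dm)
    cand <- which(dm <= best + 1e-12 * max(1, abs(best)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- cbind(minmember[active[cand[, 1]]], minmember[active[cand[, 2]]])
    pick <- order(key[, 1], key[, 2])[1]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    height[step] <- d[i, j]
    a <- sort(c(node[i], node[j]))
    merge[step, ] <- a
    # Lance-Williams update for Ward's method
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]; ni <- size[i]; nj <- size[j]
      dnew <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
      d[i, k] <- d[k, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    minmember[i] <- min(minmember[i], minmember[j])
    node[i] <- step
    active <- setdiff(active, j)
  }
  labels <- cut_ward(merge, n, n_clusters)
  structure(list(merge = merge, height = height, labels = labels,
                 n_clusters = n_clusters),
            class = "ward_tree")
}

# labels at a cut: undo the last (k-1) merges
cut_ward <- function(merge, n, k) {
  lab <- seq_len(n)
  if (k < n) {
    grp <- vector("list", n - 1L)
    for (step in seq_len(n - k)) {
      members <- function(a) if (a < 0) -a else grp[[a]]
      grp[[step]] <- c(members(merge[step, 1]), members(merge[step, 2]))
      lab[grp[[step]]] <- min(lab[grp[[step]]])
    }
  }
  as.integer(factor(lab, levels = unique(lab)))
}

#' Flag spectra not belonging to any cluster
#'
#' Distance-based outlier rule for cluster assignments: a sample whose
#' Euclidean distance to its cluster centroid exceeds the `quantile` of all
#' within-cluster distances is reported as unclassified.
#'
#' @param features matrix used for clustering.
#' @param labels cluster labels.
#' @param quantile cut-off quantile of within-cluster centroid distances.
#' @return logical vector, `TRUE` = not classified.
#' @export
unclassified_by_distance <- function(features, labels, quantile = 0.975) {
  x <- rbind(as.matrix(features))
  dist_to_centroid <- numeric(nrow(x))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ctr <- colMeans(x[idx, , drop = FALSE])
    dist_to_centroid[idx] <- sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2,
                                                ctr)^2))
  }
  dist_to_centroid > stats::quantile(dist_to_centroid, quantile)
}

# NIPALS PLS1 on centred data
nipals_pls1 <- function(xc, yc, n_lv) {
  p <- ncol(xc)
  W <- P <- matrix(0, p, n_lv)
  Q <- numeric(n_lv)
  Tm <- matrix(0, nrow(xc), n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { n_lv <- a - 1L; break }
    w <- w / nw
    t <- xc %*% w
    tt <- sum(t^2)
    pvec <- crossprod(xc, t) / tt
    q <- sum(yc * t) / tt
    xc <- xc - t %*% t(pvec)
    yc <- yc - q * t
    W[, a] <- w; P[, a] <- pvec; Q[a] <- q; Tm[, a] <- t
  }
  if (n_lv < 1L) stop("response has no covariance with the spectra")
  W <- W[, seq_len(n_lv), drop = FALSE]
  P <- P[, seq_len(n_lv), drop = FALSE]
  Q <- Q[seq_len(n_lv)]
  # regression vector in original X space
  b <- W %*% solve(t(P) %*% W, Q)
  list(weights = W, loadings = P, q = Q, scores = Tm[, seq_len(n_lv),
                                                     drop = FALSE], coef = b)
}

#' Venetian-blinds fold assignment
#'
#' Sample `i` (in acquisition order) goes to fold `((i - 1) mod k) + 1`, so
#' every fold interleaves through the run.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @return integer fold index per sample.
#' @export
venetian_blinds <- function(n, k = 10) ((seq_len(n) - 1L) %% k) + 1L

#' Train a two-class PLS-DA model
#'
#' NIPALS partial least squares with a 0/1 class-indicator response;
#' prediction thresholds the fitted response at 0.5. Cross-validation uses
#' venetian-blinds folds in acquisition order; when `n_lv = NULL` the number
#' of latent variables (1..`max_lv`) maximising CV balanced accuracy is
#' chosen. Sensitivity and specificity are reported for the first class
#' level (the "positive" class).
#'
#' @param x n x channels matrix of preprocessed, area-normalised spectra.
#' @param labels two-class factor or character vector, length n.
#' @param n_lv number of latent variables, or `NULL` to select by CV.
#' @param cv_folds venetian-blinds fold count (default 10).
#' @param max_lv largest latent-variable count tried during selection.
#' @return list of class `plsda_model` with `coef`, `intercept`, `classes`,
#'   `n_lv`, `cv` (confusion counts, sensitivity, specificity,
#'   balanced_accuracy), plus the NIPALS `weights`/`loadings`.
#' @export
plsda_train <- function(x, labels, n_lv = NULL, cv_folds = 10, max_lv = 10) {
  x <- as.matrix(x)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("PLS-DA here is two-class")
  if (min(table(f)) < cv_folds)
    stop("each class needs at least cv_folds samples")
  y <- as.numeric(f == levels(f)[1])  # class 1 coded 1
  n <- nrow(x)
  folds <- venetian_blinds(n, cv_folds)
  fit_fold <- function(train, nlv) {
    xm <- colMeans(x[train, , drop = FALSE])
    ym <- mean(y[train])
    m <- nipals_pls1(sweep(x[train, , drop = FALSE], 2, xm), y[train] - ym,
                     nlv)
    list(coef = m$coef, xm = xm, ym = ym)
  }
  cv_predict <- function(nlv) {
    pred <- numeric(n)
    for (fd in seq_len(cv_folds)) {
      test <- folds == fd
      m <- fit_fold(!test, nlv)
      pred[test] <- (sweep(x[test, , drop = FALSE], 2, m$xm) %*% m$coef) +
        m$ym
    }
    pred >= 0.5
  }
  balanced_acc <- function(hit) {
    sens <- mean(hit[y == 1]); spec <- mean(!hit[y == 0])
    (sens + spec) / 2
  }
  if (is.null(n_lv)) {
    cap <- min(max_lv, ncol(x), n - ceiling(n / cv_folds) - 1L)
    accs <- vapply(seq_len(cap), function(a) balanced_acc(cv_predict(a)),
                   numeric(1))
    n_lv <- which.max(accs)
  }
  hit <- cv_predict(n_lv)
  tp <- sum(hit & y == 1); fn <- sum(!hit & y == 1)
  tn <- sum(!hit & y == 0); fp <- sum(hit & y == 0)
  xm <- colMeans(x); ym <- mean(y)
  m <- nipals_pls1(sweep(x, 2, xm), y - ym, n_lv)
  structure(list(coef = m$coef, x_center = xm, y_center = ym,
                 classes = levels(f), n_lv = n_lv,
                 weights = m$weights, loadings = m$loadings,
                 scores = m$scores,
                 cv = list(tp = tp, fn = fn, tn = tn, fp = fp,
                           sensitivity = tp / (tp + fn),
                           specificity = tn / (tn + fp),
                           balanced_accuracy = (tp / (tp + fn) +
                                                  tn / (tn + fp)) / 2)),
            class = "plsda_model")
}

#' Predict classes with a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata n x channels matrix on the training axis.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- rbind(as.matrix(newdata))
  pred <- (sweep(newdata, 2, object$x_center) %*% object$coef) +
    object$y_center
  factor(ifelse(pred >= 0.5, object$classes[1], object$classes[2]),
         levels = object$classes)
}

#' Ratio of mean band areas between two groups of spectra
#'
#' For area-normalised spectra on a shared axis, sums the areas of the given
#' bands per spectrum and returns mean(group B) / mean(group A) -- e.g. the
#' PDMS 490 + 709 cm^-1 area of heparin-bearing polymersomes relative to the
#' plain formulation, to be compared with the theoretical weight-fraction
#' ratio from [component_weight_fractions()].
#'
#' @param spectra_a,spectra_b lists of `raman_spectrum` (AUC-normalised).
#' @param bands list of [band()]s whose areas are summed.
#' @return list with `ratio`, `mean_a`, `mean_b`.
#' @export
band_area_ratio <- function(spectra_a, spectra_b, bands) {
  total_area <- function(s) sum(vapply(bands, function(b) band_area(s, b),
                                       numeric(1)))
  a <- vapply(spectra_a, total_area, numeric(1))
  b <- vapply(spectra_b, total_area, numeric(1))
  list(ratio = mean(b) / mean(a), mean_a = mean(a), mean_b = mean(b))
}

#' Test PCA scores for a trend over acquisition order
#'
#' Spearman rank correlation of score against trap index with a permutation
#' p-value; used to verify that particle classes arrive in random order
#' (no drift or bias over the run).
#'
#' @param scores numeric scores (e.g. PCA component 1).
#' @param trap_index acquisition order.
#' @param alpha significance level for the trend decision.
#' @param n_perm permutations for the p-value.
#' @return list with `rho`, `p_value`, `trend` (logical).
#' @export
score_time_trend <- function(scores, trap_index = seq_along(scores),
                             alpha = 0.05, n_perm = 999) {
  rho <- stats::cor(scores, trap_index, method = "spearman")
  perm <- vapply(seq_len(n_perm), function(i)
    abs(stats::cor(sample(scores), trap_index, method = "spearman")),
    numeric(1))
  p <- (1 + sum(perm >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, trend = p < alpha)
}
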