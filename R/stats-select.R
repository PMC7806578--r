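## Statistics stack: percent-response normalization, PCA, nonparametric
## class-discriminant feature selection (Kruskal-Wallis + Dunn's post hoc
## with Bonferroni correction), PLS-DA with VIP scores, inter-channel
## regression, RSD utilities.

#' @noRd
fm_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x$volumes else as.matrix(x)
}

#' Percent-response normalization
#'
#' Expresses every feature volume as a percentage of its run's total
#' response: `cell * 100 / row sum`. Rows then sum to 100, making runs
#' comparable regardless of absolute loading (injection volume, detector
#' drift).
#'
#' @param x a `feature_matrix` or a numeric `[run, feature]` matrix.
#' @return same type as the input, with percent values (a `feature_matrix`
#'   gains `attr(, "percent") = TRUE`).
#' @export
percent_response <- function(x) {
  m <- fm_matrix(x)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    bad <- rownames(m)[rs <= 0] %||% which(rs <= 0)
    stop("run(s) with non-positive total response: ",
         paste(bad, collapse = ", "))
  }
  pm <- sweep(m, 1, rs, "/") * 100
  if (inherits(x, "feature_matrix")) {
    x$volumes <- pm
    attr(x, "percent") <- TRUE
    x
  } else {
    pm
  }
}

#' Principal component analysis of a feature matrix
#'
#' Columns are mean-centred (no scaling by default, matching the use of
#' percent responses); loadings are orthonormal and explained-variance
#' fractions are non-increasing.
#'
#' @param x `feature_matrix` or numeric matrix `[run, feature]`.
#' @param n_components number of components to keep.
#' @param scale. also scale columns to unit variance.
#' @return list with `scores`, `loadings`, `explained` (percent of total
#'   variance per component).
#' @export
pca_features <- function(x, n_components = 2, scale. = FALSE) {
  m <- fm_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 runs and >= 2 features")
  if (scale.) {
    keep <- apply(m, 2, sd) > 0
    m <- m[, keep, drop = FALSE]
  }
  p <- prcomp(m, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$rotation))
  ev <- p$sdev^2
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained = 100 * ev[seq_len(k)] / sum(ev))
}

## Tie-corrected Dunn z statistic for one pairwise comparison.
#' @noRd
dunn_pairwise <- function(ranks, groups, g1, g2) {
  N <- length(ranks)
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  r1 <- mean(ranks[groups == g1]); r2 <- mean(ranks[groups == g2])
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
  (r1 - r2) / se
}

#' Kruskal-Wallis feature selection with Dunn's post hoc and Bonferroni
#' correction
#'
#' Per feature: the (tie-corrected) Kruskal-Wallis test across groups;
#' for more than two groups, Dunn's pairwise z tests with Bonferroni
#' correction over the pairs. A feature is selected when its smallest
#' pairwise adjusted p-value (k > 2) or its Kruskal-Wallis p-value (k = 2,
#' where Dunn's test degenerates and Bonferroni over the single pair is
#' the identity) falls below `alpha`. An optional additional Bonferroni
#' correction across features is exposed but off by default.
#'
#' @param x `feature_matrix` or numeric matrix `[run, feature]`.
#' @param groups group label per run (>= 2 groups, each with >= 2 runs).
#' @param alpha selection level.
#' @param p_adjust_features `"none"` (default) or `"bonferroni"` across
#'   features.
#' @return data.frame of class `selection_result`: `feature`, `kw_p`,
#'   `p_adj` (the gating p-value after all corrections), `selected`.
#' @export
kw_dunn_bonferroni <- function(x, groups, alpha = 0.05,
                               p_adjust_features = c("none", "bonferroni")) {
  p_adjust_features <- match.arg(p_adjust_features)
  m <- fm_matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("groups length != number of runs")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) {
    stop("every group needs >= 2 runs; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  k <- length(tab)
  pairs <- utils::combn(names(tab), 2, simplify = FALSE)
  res <- data.frame(feature = colnames(m) %||% seq_len(ncol(m)),
                    kw_p = NA_real_, p_adj = NA_real_)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    kw <- suppressWarnings(kruskal.test(v, factor(groups)))
    res$kw_p[j] <- kw$p.value
    if (k == 2) {
      res$p_adj[j] <- kw$p.value
    } else {
      ranks <- rank(v)
      pz <- vapply(pairs, function(pr) {
        z <- dunn_pairwise(ranks, groups, pr[1], pr[2])
        2 * pnorm(-abs(z))
      }, numeric(1))
      res$p_adj[j] <- min(pmin(pz * length(pairs), 1))
    }
  }
  if (p_adjust_features == "bonferroni") {
    res$p_adj <- pmin(res$p_adj * ncol(m), 1)
  }
  res$selected <- !is.na(res$p_adj) & res$p_adj < alpha
  class(res) <- c("selection_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

#' PLS-DA with variable importance in projection (VIP)
#'
#' Two-class partial least squares discriminant analysis by NIPALS on the
#' autoscaled feature matrix with a centred one-hot class response. VIP of
#' feature j is
#' `sqrt(p * sum_a[SSY_a * (w_aj / ||w_a||)^2] / sum_a SSY_a)` where
#' `SSY_a` is the Y sum of squares explained by component a and `w_a` its
#' X weight vector; by construction the mean of the squared VIPs over
#' features is 1, so VIP >= 1 is the conventional "above average
#' influence" gate.
#'
#' @param x `feature_matrix` or numeric matrix `[run, feature]`.
#' @param labels two-class factor/character per run.
#' @param n_components number of latent components (default 2).
#' @param scale. autoscale features (unit variance) before fitting;
#'   alternatives are using percent responses directly (`FALSE`).
#' @return list of class `vip_result`: `vip` (named per-feature scores),
#'   `n_components`, `explained_y` (percent Y variance per component),
#'   `scores` (run scores), `weights`.
#' @export
plsda_vip <- function(x, labels, n_components = 2, scale. = TRUE) {
  m <- fm_matrix(x)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) {
    stop("PLS-DA needs exactly 2 classes, got ", length(classes))
  }
  keep <- apply(m, 2, sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped before PLS-DA")
  }
  X <- scale(m[, keep, drop = FALSE], center = TRUE, scale = scale.)
  Y <- scale(cbind(as.numeric(labels == classes[1]),
                   as.numeric(labels == classes[2])),
             center = TRUE, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  A <- min(n_components, p, n - 1)
  W <- matrix(0, p, A); Tm <- matrix(0, n, A); ssy <- numeric(A)
  ssy_tot <- sum(Y^2)
  a <- 0
  for (comp in seq_len(A)) {
    u <- Y[, 1]
    if (sum(Y^2) < 1e-12 * ssy_tot) break
    for (it in 1:500) {
      w <- crossprod(X, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t_ <- X %*% w
      c_ <- crossprod(Y, t_)[, 1] / sum(t_^2)
      u_new <- Y %*% c_ / sum(c_^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * sqrt(sum(u^2) + 1e-30)) {
        u <- u_new[, 1]; break
      }
      u <- u_new[, 1]
    }
    if (sqrt(sum(w^2)) < 1e-14 || sum(t_^2) < 1e-20) break
    a <- comp
    W[, a] <- w; Tm[, a] <- t_
    pl <- crossprod(X, t_)[, 1] / sum(t_^2)
    X <- X - t_ %*% t(pl)
    ssy[a] <- sum((t_ %*% t(c_))^2)
    Y <- Y - t_ %*% t(c_)
  }
  if (a == 0) stop("PLS-DA did not extract any component")
  W <- W[, seq_len(a), drop = FALSE]
  ssy <- ssy[seq_len(a)]
  vip2 <- p * (W^2 %*% ssy) / sum(ssy)  # columns of W have unit norm
  vip <- setNames(numeric(length(keep)), colnames(m))
  vip[keep] <- sqrt(vip2[, 1])
  structure(list(vip = vip, n_components = a,
                 explained_y = 100 * ssy / ssy_tot,
                 scores = Tm[, seq_len(a), drop = FALSE],
                 weights = W, classes = classes),
            class = "vip_result")
}

#' Per-feature linear regression between detection channels
#'
#' Ordinary least squares of a feature's responses on one channel against
#' the 70 eV reference channel, with the coefficient of determination.
#'
#' @param volumes_x per-run responses on the reference (70 eV) channel.
#' @param volumes_y per-run responses on the compared channel.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
channel_regression <- function(volumes_x, volumes_y) {
  if (length(volumes_x) != length(volumes_y)) stop("length mismatch")
  if (length(volumes_x) < 3) stop("need >= 3 paired observations")
  if (var(volumes_x) <= 0) stop("zero variance in the reference channel")
  f <- lm(volumes_y ~ volumes_x)
  sst <- sum((volumes_y - mean(volumes_y))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum(f$residuals^2) / sst
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r_squared = r2)
}

#' Percent relative standard deviation
#'
#' `100 * sample SD / mean`; scale invariant.
#'
#' @param values numeric vector with non-zero mean.
#' @return percent RSD.
#' @export
rsd <- function(values) {
  m <- mean(values)
  if (m == 0) stop("RSD is undefined for zero-mean values")
  100 * sd(values) / m
}
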