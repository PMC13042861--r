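#' Logit transform for bounded variables
#'
#' Percentages and ratios are rescaled to the unit interval where necessary,
#' clipped to [eps, 1 - eps], and mapped through log(p / (1 - p)) to remove
#' their hard bounds before univariate and multivariate analysis.
#'
#' @param p values on their native bounded scale.
#' @param lower,upper native bounds (0 and 1 by default; use `upper = 100` for
#'   percentages).
#' @param eps boundary clipping constant.
#' @return Transformed values; an attribute `clipped` counts clipped entries.
#' @export
logit_transform <- function(p, lower = 0, upper = 1, eps = 1e-6) {
  if (any(p < lower - 1e-12 | p > upper + 1e-12, na.rm = TRUE)) {
    stop("values outside native bounds [", lower, ", ", upper, "]")
  }
  q <- (p - lower) / (upper - lower)
  clipped <- sum(q < eps | q > 1 - eps, na.rm = TRUE)
  q <- pmin(pmax(q, eps), 1 - eps)
  structure(log(q / (1 - q)), clipped = clipped)
}

#' Project a circular variable into linear space
#'
#' Converts degrees to radians and returns cos(theta) + sin(theta). Axial
#' variables (period 180 degrees, such as texture directions) are doubled
#' first so that 0 and 180 degrees map to the same value.
#'
#' @param theta angles in degrees.
#' @param axial double the angles before conversion (default `TRUE` for
#'   orientation data).
#' @return Numeric vector.
#' @export
circular_to_linear <- function(theta, axial = TRUE) {
  t <- deg2rad(if (axial) 2 * theta else theta)
  cos(t) + sin(t)
}

#' Normality-routed univariate group comparison
#'
#' Shapiro-Wilk normality is assessed per group at `alpha`; when every group
#' is compatible with a Gaussian the groups are compared by one-way ANOVA,
#' otherwise by the Kruskal-Wallis rank-sum test. The routing decision is
#' recorded in the result.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha significance threshold (study-wide 0.003).
#' @param variable variable name for reporting.
#' @return A `univariate_result`.
#' @export
shapiro_route <- function(values, groups, alpha = 0.003, variable = "value") {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  split_v <- split(values, groups)
  if (any(vapply(split_v, length, 0L) < 3)) {
    stop("need at least 3 values per group")
  }
  sw <- vapply(split_v, function(v) {
    if (stats::sd(v) < 1e-12) return(0)  # constant: not Gaussian
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  gaussian <- all(sw > alpha)
  if (gaussian) {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    new_univariate_result(variable, "ANOVA", s$`F value`[1],
                          s$Df, s$`Pr(>F)`[1], alpha,
                          routing = "all groups Shapiro-Wilk Gaussian")
  } else {
    kt <- stats::kruskal.test(values, groups)
    new_univariate_result(variable, "Kruskal-Wallis",
                          unname(kt$statistic), unname(kt$parameter),
                          kt$p.value, alpha,
                          routing = "Shapiro-Wilk rejected in >= 1 group")
  }
}

#' Robust location and scale summary
#'
#' Median and the square root of the biweight midvariance (tuning constant 9),
#' the robust spread used for skewed texture parameters.
#'
#' @param values numeric vector.
#' @param const tuning constant.
#' @return List with `median`, `sqrt_bwmv` (`NA` flagged when n < 4).
#' @export
robust_summary <- function(values, const = 9) {
  med <- stats::median(values)
  if (length(values) < 4) {
    return(list(median = med, sqrt_bwmv = NA_real_, flag = "n < 4"))
  }
  madn <- stats::median(abs(values - med))
  if (madn == 0) return(list(median = med, sqrt_bwmv = 0))
  u <- (values - med) / (const * madn)
  w <- abs(u) < 1
  n <- length(values)
  num <- n * sum(((values - med)^2 * (1 - u^2)^4)[w])
  den <- sum(((1 - u^2) * (1 - 5 * u^2))[w])^2
  list(median = med, sqrt_bwmv = sqrt(num / den))
}

# mixed-type squared correlation between two columns
mixed_r2 <- function(x, y, class_x, class_y, n_perm = 0, seed = NULL) {
  if (class_x == "circular" && class_y == "circular") {
    r <- circ_corr(x, y, "circ-circ", n_perm = max(1, n_perm), seed = seed)
    list(R2 = r$R2, p = r$permutation_p, method = r$method)
  } else if (class_x == "circular" || class_y == "circular") {
    lin <- if (class_x == "circular") y else x
    circ <- if (class_x == "circular") x else y
    r <- circ_corr(lin, circ, "lin-circ", n_perm = max(1, n_perm), seed = seed)
    list(R2 = r$R2, p = r$permutation_p, method = r$method)
  } else {
    r <- stats::cor(x, y)
    list(R2 = r^2, p = NA_real_, method = "Pearson")
  }
}

#' Significance- and correlation-based variable selection
#'
#' Step 1 keeps the variables whose univariate group test is significant at
#' `alpha`. Step 2 computes the mixed correlation matrix over the retained
#' variables (Pearson for linear pairs, Jammalamadaka-Sarma for
#' circular-circular, Johnson-Wehrly-Mardia for linear-circular) and greedily
#' drops, from each pair with R^2 at or above the threshold, the variable with
#' the larger univariate p-value (ties broken alphabetically), so that only
#' one variable from each highly correlated pair is retained.
#'
#' @param table data frame of candidate variables (observations x variables).
#' @param classes named character vector: `"linear"`, `"circular"` or
#'   `"bounded"` per variable (bounded variables should already be
#'   logit-transformed and classed linear for correlation purposes).
#' @param p_values named numeric vector of univariate p-values per variable.
#' @param alpha significance threshold.
#' @param r2_threshold correlation exclusion threshold (pairs with R^2 >=
#'   threshold lose one member).
#' @param n_perm permutations for circular correlation p-values.
#' @param seed integer seed.
#' @return List with `retained` (character), `dropped` (data frame: variable,
#'   partner, R2, reason), and the pairwise `correlations` data frame.
#' @export
select_variables <- function(table, classes, p_values, alpha = 0.003,
                             r2_threshold = 0.7, n_perm = 199, seed = 1) {
  vars <- names(p_values)[!is.na(p_values) & p_values < alpha]
  dropped <- data.frame(variable = character(0), partner = character(0),
                        R2 = numeric(0), reason = character(0))
  if (length(vars) == 0) {
    stop("no variable is significant at alpha = ", alpha)
  }
  pairs <- if (length(vars) > 1) utils::combn(vars, 2) else
    matrix(character(0), 2, 0)
  cors <- data.frame(var1 = character(0), var2 = character(0), R2 = numeric(0),
                     method = character(0), permutation_p = numeric(0))
  if (ncol(pairs) > 0) {
    for (k in seq_len(ncol(pairs))) {
      v1 <- pairs[1, k]; v2 <- pairs[2, k]
      r <- mixed_r2(table[[v1]], table[[v2]], classes[[v1]], classes[[v2]],
                    n_perm = n_perm, seed = seed + k)
      cors <- rbind(cors, data.frame(var1 = v1, var2 = v2, R2 = r$R2,
                                     method = r$method,
                                     permutation_p = r$p))
    }
  }
  retained <- vars
  repeat {
    live <- cors[cors$var1 %in% retained & cors$var2 %in% retained &
                   is.finite(cors$R2) & cors$R2 >= r2_threshold, ]
    if (nrow(live) == 0) break
    worst <- live[which.max(live$R2), ]
    p1 <- p_values[[worst$var1]]; p2 <- p_values[[worst$var2]]
    drop <- if (p1 > p2) worst$var1 else if (p2 > p1) worst$var2 else
      max(worst$var1, worst$var2)  # tie: drop the alphabetically later one
    keep <- setdiff(c(worst$var1, worst$var2), drop)
    retained <- setdiff(retained, drop)
    dropped <- rbind(dropped, data.frame(
      variable = drop, partner = keep, R2 = worst$R2,
      reason = sprintf("R2 = %.3f >= %.2f with %s; larger univariate p",
                       worst$R2, r2_threshold, keep)))
  }
  if (length(retained) == 0) stop("variable selection removed every variable")
  list(retained = retained, dropped = dropped, correlations = cors)
}

#' Standardized principal component analysis
#'
#' PCA on z-scored variables (circular variables must already be linearised
#' and bounded variables logit-transformed); retains the smallest number of
#' components whose cumulative explained variance exceeds `retain`.
#'
#' @param table complete numeric data frame or matrix.
#' @param retain cumulative explained-variance target (0.95).
#' @param standardize z-score the columns (default `TRUE`).
#' @return A `pca_model`: `scores`, `loadings`, `explained`, `retained_k`,
#'   `center`, `scale`.
#' @export
pca_model <- function(table, retain = 0.95, standardize = TRUE) {
  X <- as.matrix(table)
  if (anyNA(X)) stop("PCA input contains missing cells; imputation is out of scope")
  keep <- apply(X, 2, stats::sd) > 1e-12
  Xk <- X[, keep, drop = FALSE]
  pr <- stats::prcomp(Xk, center = TRUE, scale. = standardize)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  k <- which(cumsum(expl) > retain)[1]
  structure(list(scores = pr$x, loadings = pr$rotation, explained = expl,
                 retained_k = k, center = pr$center, scale = pr$scale,
                 dropped_constant = names(keep)[!keep]),
            class = "pca_model")
}

# Cohen's kappa and derived statistics from a confusion matrix
# (rows = predicted, columns = reference)
kappa_from_confusion <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Cross-validated linear discriminant analysis with full reporting
#'
#' The observations are split into a stratified training set (fraction
#' `split`) and test set. k-fold cross-validation within the training set
#' gives an internal accuracy estimate; the final LDA is fitted on the whole
#' training set and evaluated on the held-out test set. The report follows the
#' standard confusion-matrix convention: overall accuracy with an exact
#' (Clopper-Pearson) 95% interval, the no-information rate (largest class
#' share), a one-sided exact binomial p-value of accuracy against the NIR,
#' Cohen's kappa, and per-class sensitivity, specificity and precision.
#'
#' @param scores numeric matrix of predictors (e.g. retained PC scores).
#' @param labels class labels.
#' @param k folds for cross-validation (default 10).
#' @param split training fraction (default 0.8).
#' @param seed integer seed controlling split and folds.
#' @return A `classifier_report`: `confusion`, `accuracy`, `accuracy_ci`,
#'   `nir`, `accuracy_p_value`, `kappa`, `by_class`, `cv_accuracy`,
#'   `fold_assignment`, `seed`.
#' @export
lda_cv <- function(scores, labels, k = 10, split = 0.8, seed = 1) {
  X <- as.matrix(scores)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  with_seed(seed, {
    idx_by_class <- split(seq_along(y), y)
    train <- sort(unlist(lapply(idx_by_class, function(ii) {
      sample(ii, max(1, round(length(ii) * split)))
    })))
    test <- setdiff(seq_along(y), train)
    if (length(test) == 0) stop("empty test set; lower `split`")
    if (nlevels(droplevels(y[train])) < nlevels(y)) {
      stop("a class is absent from the training set after the split")
    }
    # stratified k-fold CV within the training set
    kk <- min(k, min(table(y[train])))
    folds <- integer(length(train))
    for (ii in split(seq_along(train), y[train])) {
      folds[ii] <- sample(rep(seq_len(kk), length.out = length(ii)))
    }
    cv_pred <- factor(rep(NA, length(train)), levels = levels(y))
    for (f in seq_len(kk)) {
      tr <- train[folds != f]; ho <- train[folds == f]
      fit <- MASS::lda(X[tr, , drop = FALSE], grouping = droplevels(y[tr]))
      cv_pred[folds == f] <- predict(fit, X[ho, , drop = FALSE])$class
    }
    cv_accuracy <- mean(cv_pred == y[train], na.rm = TRUE)
    final <- MASS::lda(X[train, , drop = FALSE], grouping = y[train])
    pred <- predict(final, X[test, , drop = FALSE])$class
    cm <- caret::confusionMatrix(data = factor(pred, levels = levels(y)),
                                 reference = y[test])
    by_class <- if (nlevels(y) == 2) {
      m <- rbind(cm$byClass)
      rownames(m) <- levels(y)[1]
      m
    } else cm$byClass
    structure(list(
      confusion = cm$table,
      accuracy = unname(cm$overall["Accuracy"]),
      accuracy_ci = unname(cm$overall[c("AccuracyLower", "AccuracyUpper")]),
      nir = unname(cm$overall["AccuracyNull"]),
      accuracy_p_value = unname(cm$overall["AccuracyPValue"]),
      kappa = unname(cm$overall["Kappa"]),
      by_class = by_class[, intersect(c("Sensitivity", "Specificity",
                                        "Precision"), colnames(by_class)),
                          drop = FALSE],
      cv_accuracy = cv_accuracy, k = kk, split = split,
      fold_assignment = data.frame(index = train, fold = folds),
      test_indices = test, model = final, seed = seed
    ), class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> accuracy %.3f [%.3f, %.3f], NIR %.3f (p = %.3g), kappa %.3f\n",
    x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2], x$nir,
    x$accuracy_p_value, x$kappa))
  cat(sprintf("  %d-fold CV accuracy on training set: %.3f\n",
              x$k, x$cv_accuracy))
  invisible(x)
}

#' Canonical variate analysis with jackknifed scores
#'
#' Canonical axes maximise the between- to within-class scatter ratio
#' (min(p, g - 1) axes for g classes). Per-observation CV scores are computed
#' leave-one-out: each observation is projected on axes estimated without it.
#' A ridge regularisation is applied (and logged) when the within-class
#' scatter is singular.
#'
#' @param scores numeric matrix.
#' @param labels class labels.
#' @return List with `axes`, `scores` (jackknifed), `eigenvalues`,
#'   `regularized`.
#' @export
cva <- function(scores, labels) {
  X <- as.matrix(scores)
  y <- factor(labels)
  g <- nlevels(y)
  if (g < 2) stop("need at least 2 classes")
  n_axes <- min(ncol(X), g - 1)
  axes_of <- function(X, y) {
    mu <- colMeans(X)
    W <- matrix(0, ncol(X), ncol(X)); B <- matrix(0, ncol(X), ncol(X))
    for (lev in levels(y)) {
      Xi <- X[y == lev, , drop = FALSE]
      mi <- colMeans(Xi)
      W <- W + crossprod(sweep(Xi, 2, mi))
      B <- B + nrow(Xi) * tcrossprod(mi - mu)
    }
    reg <- FALSE
    if (rcond(W) < 1e-10) {
      W <- W + diag(1e-6 * mean(diag(W)), ncol(W))
      reg <- TRUE
    }
    e <- eigen(solve(W, B))
    ord <- order(Re(e$values), decreasing = TRUE)[seq_len(n_axes)]
    list(axes = Re(e$vectors[, ord, drop = FALSE]),
         values = Re(e$values[ord]), regularized = reg)
  }
  full <- axes_of(X, y)
  jack <- matrix(NA_real_, nrow(X), n_axes)
  for (i in seq_len(nrow(X))) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) < 2) next
    a <- axes_of(X[-i, , drop = FALSE], y[-i])$axes
    # align jackknife axis signs with the full-sample axes
    sgn <- sign(colSums(a * full$axes[, seq_len(ncol(a)), drop = FALSE]))
    sgn[sgn == 0] <- 1
    jack[i, seq_len(ncol(a))] <- (X[i, , drop = FALSE] %*% a) * sgn
  }
  list(axes = full$axes, eigenvalues = full$values, scores = jack,
       regularized = full$regularized)
}

# Wilks' lambda of X (n x p) across groups
wilks_lambda <- function(X, y) {
  X <- as.matrix(X)
  Tm <- crossprod(sweep(X, 2, colMeans(X)))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(y)) {
    Xi <- X[y == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  dT <- det(Tm)
  if (dT <= 0) return(1)
  max(min(det(W) / dT, 1), .Machine$double.xmin)
}

#' Permutation MANOVA on principal component scores
#'
#' Wilks' lambda on the first `components` score columns, with a permutation
#' p-value: labels are permuted `n_perm` times and
#' p = (1 + #permutations with lambda <= observed) / (n_perm + 1).
#'
#' @param pc_scores numeric matrix of PC scores.
#' @param labels group labels.
#' @param n_perm number of permutations (default 999).
#' @param components leading score columns to use (default 2).
#' @param seed integer seed.
#' @return List with `wilks_lambda`, `p_value`, `n_perm`.
#' @export
manova_permutation <- function(pc_scores, labels, n_perm = 999,
                               components = 2, seed = 1) {
  X <- as.matrix(pc_scores)
  if (components > ncol(X)) stop("fewer score columns than `components`")
  X <- X[, seq_len(components), drop = FALSE]
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 groups")
  obs <- wilks_lambda(X, y)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    wilks_lambda(X, sample(y))
  }, numeric(1)))
  p <- (1 + sum(perm <= obs)) / (n_perm + 1)
  list(wilks_lambda = obs, p_value = p, n_perm = n_perm)
}
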