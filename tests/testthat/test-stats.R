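test_that("logit transform matches closed forms and clips the boundary", {
  expect_equal(logit_transform(0.5)[1], 0)
  expect_equal(logit_transform(0.9)[1], log(9), tolerance = 1e-12)
  iso <- logit_transform(100, lower = 0, upper = 100)
  expect_true(is.finite(iso[1]))
  expect_equal(attr(iso, "clipped"), 1)
  expect_equal(iso[1], log((1 - 1e-6) / 1e-6))
  expect_error(logit_transform(1.2), "outside native bounds")
})

test_that("circular-to-linear projection is cos + sin with axial doubling", {
  expect_equal(circular_to_linear(0, axial = FALSE), 1)
  expect_equal(circular_to_linear(90, axial = FALSE), 1)
  expect_equal(circular_to_linear(45, axial = FALSE), sqrt(2))
  # axial: 0 and 180 degrees coincide
  expect_equal(circular_to_linear(0), circular_to_linear(180))
})

test_that("Shapiro routing picks ANOVA for Gaussian and KW for heavy tails", {
  set.seed(1)
  g <- rep(c("a", "b"), each = 50)
  r1 <- shapiro_route(rnorm(100), g)
  expect_equal(r1$test_name, "ANOVA")
  set.seed(2)
  r2 <- shapiro_route(rcauchy(100), g)
  expect_equal(r2$test_name, "Kruskal-Wallis")
  expect_error(shapiro_route(rnorm(10), rep("a", 10)), "2 groups")
})

test_that("biweight midvariance is consistent and outlier-resistant", {
  set.seed(3)
  x <- rnorm(1e4, 0, 2)
  r <- robust_summary(x)
  expect_equal(r$sqrt_bwmv, 2, tolerance = 0.03 * 2)
  r_out <- robust_summary(c(x, 1e6))
  expect_lt(abs(r_out$sqrt_bwmv - r$sqrt_bwmv) / r$sqrt_bwmv, 0.05)
  expect_equal(robust_summary(rep(3, 10))$sqrt_bwmv, 0)
  expect_true(is.na(robust_summary(c(1, 2, 3))$sqrt_bwmv))
})

test_that("variable selection keeps one member of each correlated pair", {
  set.seed(4)
  n <- 60
  x <- rnorm(n)
  tab <- data.frame(a = x, b = x, c = rnorm(n))
  classes <- c(a = "linear", b = "linear", c = "linear")
  p <- c(a = 1e-5, b = 1e-4, c = 1e-3)
  sel <- select_variables(tab, classes, p)
  expect_true("a" %in% sel$retained)   # smaller p survives
  expect_false("b" %in% sel$retained)
  expect_true("c" %in% sel$retained)
  expect_equal(sel$dropped$partner, "a")

  # three mutually correlated -> exactly one retained
  tab3 <- data.frame(a = x, b = x + rnorm(n, 0, 1e-4),
                     c = x + rnorm(n, 0, 1e-4))
  sel3 <- select_variables(tab3, c(a = "linear", b = "linear", c = "linear"),
                           c(a = 1e-5, b = 1e-4, c = 1e-3))
  expect_length(sel3$retained, 1)
  expect_equal(sel3$retained, "a")

  # an R^2 just below the threshold keeps both members
  y <- x * sqrt(0.69) + rnorm(n)
  # orthogonalise to force the exact sample correlation
  e <- residuals(lm(y ~ x))
  y <- sqrt(0.69) * scale(x)[, 1] + sqrt(0.31) * scale(e)[, 1]
  tabt <- data.frame(a = scale(x)[, 1], b = y)
  expect_equal(cor(tabt$a, tabt$b)^2, 0.69, tolerance = 1e-9)
  selt <- select_variables(tabt, c(a = "linear", b = "linear"),
                           c(a = 1e-5, b = 1e-4), r2_threshold = 0.7)
  expect_setequal(selt$retained, c("a", "b"))
})

test_that("standardized PCA retains components by cumulative variance", {
  set.seed(5)
  X <- matrix(rnorm(3000), ncol = 3)
  p <- pca_model(X, retain = 0.95)
  expect_equal(unname(p$explained), rep(1 / 3, 3), tolerance = 0.05)
  expect_equal(p$retained_k, 3)

  v <- rnorm(100)
  X1 <- cbind(v, 2 * v, -v) + matrix(rnorm(300, 0, 1e-6), ncol = 3)
  p1 <- pca_model(X1)
  expect_gt(p1$explained[1], 0.999)
  expect_equal(p1$retained_k, 1)

  # orthogonal reconstruction from all components
  Xs <- scale(X)
  rec <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(rec - Xs)), 1e-9)
})

test_that("cross-validated LDA reports accuracy, kappa and NIR correctly", {
  set.seed(6)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 6), ncol = 2))
  y <- rep(c("a", "b"), each = n)
  rep1 <- lda_cv(X, y, seed = 1)
  expect_gt(rep1$accuracy, 0.95)
  expect_gt(rep1$kappa, 0.9)
  expect_true(rep1$accuracy >= rep1$accuracy_ci[1] &&
                rep1$accuracy <= rep1$accuracy_ci[2])
  expect_equal(sum(rep1$confusion), length(rep1$test_indices))

  set.seed(7)
  yp <- sample(y)
  rep0 <- lda_cv(X, yp, seed = 2)
  expect_lt(abs(rep0$kappa), 0.25)
  expect_lt(abs(rep0$accuracy - rep0$nir), 0.25)
  # NIR equals the largest class share in the test set
  expect_equal(rep0$nir,
               max(table(yp[rep0$test_indices])) / length(rep0$test_indices))
})

test_that("kappa from a hand-built 3-class confusion matrix matches arithmetic", {
  pred <- factor(c(rep("a", 10), rep("b", 2), rep("c", 1),
                   rep("a", 3), rep("b", 8), rep("c", 2),
                   rep("a", 1), rep("b", 2), rep("c", 9)),
                 levels = c("a", "b", "c"))
  ref <- factor(c(rep("a", 13), rep("b", 13), rep("c", 12)),
                levels = c("a", "b", "c"))
  cm <- table(pred, ref)
  # hand computation: po = 27/38; pe from row x column margins
  po <- sum(diag(cm)) / 38
  pe <- sum(rowSums(cm) * colSums(cm)) / 38^2
  hand <- (po - pe) / (1 - pe)
  expect_equal(sculptrace:::kappa_from_confusion(cm), hand, tolerance = 1e-12)
  expect_equal(unname(caret::confusionMatrix(pred, ref)$overall["Kappa"]),
               hand, tolerance = 1e-9)
})

test_that("CVA produces g-1 jackknifed axes separating constructed classes", {
  set.seed(8)
  X2 <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 5), ncol = 2))
  y2 <- rep(c("a", "b"), each = 30)
  cv2 <- cva(X2, y2)
  expect_equal(ncol(cv2$scores), 1)

  # silhouette on the jackknifed scores
  s <- cv2$scores[, 1]
  sil <- vapply(seq_along(s), function(i) {
    own <- mean(abs(s[i] - s[y2 == y2[i]][-which(which(y2 == y2[i]) == i)]))
    oth <- mean(abs(s[i] - s[y2 != y2[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # 1-informative-variable data: class means ordered along CV1 as in the data
  set.seed(9)
  X3 <- cbind(c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 6)), rnorm(60))
  y3 <- rep(c("lo", "mid", "hi"), each = 20)
  cv3 <- cva(X3, y3)
  m <- tapply(cv3$scores[, 1], y3, mean, na.rm = TRUE)
  expect_true(all(diff(m[c("lo", "mid", "hi")]) > 0) ||
                all(diff(m[c("lo", "mid", "hi")]) < 0))
})

test_that("permutation MANOVA saturates for separated groups and bounds lambda", {
  # dual-route check of Wilks' lambda against stats::manova
  set.seed(10)
  X <- matrix(rnorm(120), ncol = 2)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  ours <- sculptrace:::wilks_lambda(X, y)
  ref <- summary(stats::manova(X ~ y), test = "Wilks")$stats[1, "Wilks"]
  expect_equal(ours, unname(ref), tolerance = 1e-9)

  Xs <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
  ys <- rep(c("a", "b"), each = 30)
  r <- manova_permutation(Xs, ys, n_perm = 999, seed = 3)
  expect_equal(r$p_value, 0.001)
  expect_true(r$wilks_lambda > 0 && r$wilks_lambda <= 1)
  expect_error(manova_permutation(Xs, rep("a", 60)), "2 groups")
})
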