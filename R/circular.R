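# --- basic circular helpers (angles in degrees unless noted) ---------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

circ_mean_rad <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# maximum-likelihood von Mises concentration from the resultant length
# (Fisher 1993 approximation)
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

# circular median: the data angle minimising the mean circular deviation
circ_median_rad <- function(theta) {
  dev <- vapply(theta, function(m) {
    d <- abs(((theta - m + pi) %% (2 * pi)) - pi)
    mean(pmin(d, 2 * pi - d))
  }, numeric(1))
  theta[which.min(dev)]
}

new_univariate_result <- function(variable, test_name, statistic, dof, p_value,
                                  alpha = 0.003, routing = NA_character_,
                                  extra = list()) {
  structure(c(list(variable = variable, test_name = test_name,
                   statistic = statistic, dof = dof, p_value = p_value,
                   significant = is.finite(p_value) && p_value < alpha,
                   alpha = alpha, routing = routing), extra),
            class = "univariate_result")
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  if (!is.na(x$routing)) cat("  routing:", x$routing, "\n")
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are uniformly distributed around the circle against a
#' unimodal preferred direction, using the mean resultant length with the
#' standard small-sample series correction for the p-value.
#'
#' @param angles angles in degrees.
#' @param alpha significance threshold.
#' @return A `univariate_result` with the resultant length attached.
#' @export
rayleigh_test <- function(angles, alpha = 0.003) {
  theta <- deg2rad(angles)
  n <- length(theta)
  if (n < 5) stop("Rayleigh test requires n >= 5")
  rbar <- resultant_length(theta)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(1, max(p, .Machine$double.xmin))
  new_univariate_result("angles", "Rayleigh", Z, NA, p, alpha,
                        routing = "circular uniformity",
                        extra = list(rbar = rbar,
                                     mean_direction = rad2deg(circ_mean_rad(theta)) %% 360))
}

#' Generalized Watson-Williams test for equal mean directions
#'
#' Multi-sample F-type test comparing circular mean directions across groups,
#' with the concentration correction factor 1 + 3/(8 kappa). A warning flag is
#' recorded when the pooled concentration estimate is low (kappa < 1), where
#' the test's assumptions are doubtful.
#'
#' @param angles angles in degrees.
#' @param groups group labels.
#' @param alpha significance threshold.
#' @return A `univariate_result`; group circular means are attached.
#' @export
watson_williams <- function(angles, groups, alpha = 0.003) {
  theta <- deg2rad(angles)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  n <- length(theta)
  split_t <- split(theta, groups)
  Ri <- vapply(split_t, function(t) length(t) * resultant_length(t), numeric(1))
  R <- n * resultant_length(theta)
  rbar_w <- sum(Ri) / n
  kappa <- kappa_from_rbar(rbar_w)
  dispersed <- kappa < 1
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((n - g) * (sum(Ri) - R)) / ((g - 1) * (n - sum(Ri)))
  p <- stats::pf(Fstat, g - 1, n - g, lower.tail = FALSE)
  means <- vapply(split_t, function(t) rad2deg(circ_mean_rad(t)) %% 360,
                  numeric(1))
  new_univariate_result("angles", "Watson-Williams", Fstat,
                        c(g - 1, n - g), p, alpha,
                        routing = "circular mean comparison",
                        extra = list(group_means = means, kappa = kappa,
                                     dispersed_warning = dispersed))
}

#' Mardia-Watson-Wheeler uniform-scores test
#'
#' Nonparametric comparison of circular distributions across groups using
#' uniform scores; W is asymptotically chi-squared with 2(g - 1) degrees of
#' freedom. Ties are broken by a minute deterministic jitter of the ranks;
#' with excessive ties a permutation p-value is used instead.
#'
#' @param angles angles in degrees.
#' @param groups group labels.
#' @param alpha significance threshold.
#' @param n_perm permutations for the tie fallback.
#' @return A `univariate_result`.
#' @export
mardia_watson_wheeler <- function(angles, groups, alpha = 0.003,
                                  n_perm = 999) {
  groups <- as.factor(groups)
  g <- nlevels(groups)
  n <- length(angles)
  if (g < 2) stop("need at least 2 groups")
  if (n < 10) stop("need n >= 10 in total")
  a <- angles %% 360
  tie_frac <- 1 - length(unique(a)) / n
  W_of <- function(a, groups) {
    r <- rank(a, ties.method = "average")
    beta <- 2 * pi * r / n
    Wi <- vapply(split(beta, groups), function(b) {
      (sum(cos(b))^2 + sum(sin(b))^2) / length(b)
    }, numeric(1))
    2 * sum(Wi)
  }
  W <- W_of(a, groups)
  if (tie_frac > 0.1) {
    perm <- vapply(seq_len(n_perm), function(i) W_of(a, sample(groups)),
                   numeric(1))
    p <- (1 + sum(perm >= W)) / (n_perm + 1)
    meth <- "permutation (ties)"
  } else {
    p <- stats::pchisq(W, df = 2 * (g - 1), lower.tail = FALSE)
    meth <- "chi-squared"
  }
  new_univariate_result("angles", "Mardia-Watson-Wheeler", W, 2 * (g - 1), p,
                        alpha, routing = meth)
}

#' Fisher's nonparametric test for a common circular median
#'
#' Tests whether several samples of angles share a common median direction
#' (Fisher 1993, 5.4.4): counts per group on one side of the pooled circular
#' median give a chi-squared statistic with g - 1 degrees of freedom.
#'
#' @param angles angles in degrees.
#' @param groups group labels.
#' @param alpha significance threshold.
#' @return A `univariate_result`.
#' @export
fisher_circular_test <- function(angles, groups, alpha = 0.003) {
  theta <- deg2rad(angles)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  n <- length(theta)
  med <- circ_median_rad(theta)
  # count angles strictly on the negative side of the pooled median
  side <- ((theta - med) %% (2 * pi)) > pi
  mi <- vapply(split(side, groups), sum, numeric(1))
  ni <- vapply(split(side, groups), length, numeric(1))
  M <- sum(mi)
  if (M == 0 || M == n) {
    return(new_univariate_result("angles", "Fisher common median", 0, g - 1, 1,
                                 alpha, routing = "degenerate: all on one side"))
  }
  P <- n^2 / (M * (n - M)) * sum(mi^2 / ni) - n * M / (n - M)
  p <- stats::pchisq(P, df = g - 1, lower.tail = FALSE)
  new_univariate_result("angles", "Fisher common median", P, g - 1, p, alpha,
                        routing = "common circular median")
}

#' Circular correlation with permutation p-value
#'
#' Squared correlation between two variables where at least one is circular:
#' circular-circular pairs use the Jammalamadaka-Sarma coefficient,
#' linear-circular pairs the Johnson-Wehrly-Mardia coefficient. The p-value is
#' a two-sided randomisation test with the add-one rule, permuting the second
#' variable.
#'
#' @param var1,var2 paired observations; circular variables in degrees. For
#'   `kind = "lin-circ"`, `var1` is linear and `var2` circular.
#' @param kind `"circ-circ"` or `"lin-circ"`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return List with `R2`, `permutation_p`, `method`.
#' @export
circ_corr <- function(var1, var2, kind = c("circ-circ", "lin-circ"),
                      n_perm = 999, seed = NULL) {
  kind <- match.arg(kind)
  n <- length(var1)
  stopifnot(length(var2) == n)
  if (n < 10) stop("need at least 10 paired observations")
  if (stats::sd(var1) < 1e-12 || stats::sd(var2) < 1e-12) {
    return(list(R2 = NA_real_, permutation_p = NA_real_, method = kind,
                flag = "constant variable"))
  }
  if (kind == "circ-circ") {
    t1 <- deg2rad(var1)
    stat <- function(t2) {
      s1 <- sin(t1 - circ_mean_rad(t1))
      s2 <- sin(t2 - circ_mean_rad(t2))
      sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2))
    }
    obs <- stat(deg2rad(var2))
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stat(deg2rad(sample(var2)))
    }, numeric(1)))
    method <- "Jammalamadaka-Sarma"
  } else {
    xv <- var1
    stat <- function(theta) {
      cs <- cos(theta); sn <- sin(theta)
      rxc <- stats::cor(xv, cs); rxs <- stats::cor(xv, sn)
      rcs <- stats::cor(cs, sn)
      sqrt(max(0, (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)))
    }
    obs <- stat(deg2rad(var2))
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stat(deg2rad(sample(var2)))
    }, numeric(1)))
    method <- "Johnson-Wehrly-Mardia"
  }
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(R2 = obs^2, permutation_p = p, method = method)
}
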