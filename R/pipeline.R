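#' Analysis configuration
#'
#' Bundles the tunable thresholds of the three analyses. Defaults follow the
#' study conventions: a study-wide significance threshold of 0.003, an R^2 of
#' 0.7 for correlation-based exclusion, a 95% cumulative-variance rule for the
#' retained principal components, 10-fold cross-validation with an 80/20
#' train/test split, 999 permutations, six Fourier harmonics, and nine
#' 10 x 10 mm sub-areas per worked square.
#'
#' @param alpha significance threshold.
#' @param r2_threshold correlation exclusion threshold.
#' @param pca_retain cumulative explained-variance target.
#' @param lda_folds cross-validation folds.
#' @param split training fraction.
#' @param n_perm permutations for permutation tests.
#' @param harmonics EFA harmonics for shape analysis.
#' @param tile sub-area side, mm.
#' @param n_tiles sub-areas per square.
#' @param smc_p,vvv_p material-ratio arguments, percent.
#' @param acf_threshold autocorrelation decay threshold.
#' @param pruning feature pruning, percent of Sz.
#' @param eplsar_scale epLsar scale, um (raised to twice the grid spacing
#'   when the grid is coarser).
#' @param seed integer master seed.
#' @return An `analysis_config` object (with a `hash` field).
#' @export
analysis_config <- function(alpha = 0.003, r2_threshold = 0.7,
                            pca_retain = 0.95, lda_folds = 10, split = 0.8,
                            n_perm = 999, harmonics = 6, tile = 10,
                            n_tiles = 9, smc_p = 10, vvv_p = 80,
                            acf_threshold = 0.2, pruning = 5,
                            eplsar_scale = 40, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, r2_threshold > 0, r2_threshold <= 1,
            pca_retain > 0, pca_retain <= 1, split > 0, split < 1,
            lda_folds >= 2, n_perm >= 1, harmonics >= 1)
  cfg <- list(alpha = alpha, r2_threshold = r2_threshold,
              pca_retain = pca_retain, lda_folds = lda_folds, split = split,
              n_perm = n_perm, harmonics = harmonics, tile = tile,
              n_tiles = n_tiles, smc_p = smc_p, vvv_p = vvv_p,
              acf_threshold = acf_threshold, pruning = pruning,
              eplsar_scale = eplsar_scale, seed = seed)
  cfg$hash <- sprintf("%08x",
                      sum(utf8ToInt(paste(deparse(cfg), collapse = "")) *
                            seq_along(utf8ToInt(paste(deparse(cfg),
                                                      collapse = "")))) %%
                        .Machine$integer.max)
  structure(cfg, class = "analysis_config")
}

#' Variable classes of the surface parameter set
#'
#' @return Named character vector mapping each of the 29 surface parameters to
#'   `"linear"`, `"bounded"` or `"circular"`.
#' @export
variable_classes <- function() {
  c(Sq = "linear", Smc = "linear", Sal = "linear", Str = "bounded",
    Std = "circular", Sdr = "linear", Vvv = "linear", Spd = "linear",
    Spc = "linear", Svd = "linear", Shrn = "linear", Shrnq = "linear",
    Sdrn = "linear", Sdrnq = "linear",
    Ymax = "linear", Asfc = "linear", Das = "linear", Smfc = "linear",
    HAsfc = "linear", MedianAsfc = "linear", epLsar = "linear",
    NewEplsar = "linear",
    Isotropy = "bounded", First.direction = "circular",
    Second.direction = "circular", Third.direction = "circular",
    Max.depth.furrows = "linear", Mean.depth.furrows = "linear",
    Mean.density.furrows = "linear")
}

# native scale of bounded variables for the logit transform
bounded_upper <- c(Str = 1, Isotropy = 100)

#' Collect the full surface parameter set for one sub-area
#'
#' Assembles the 14 ISO 25178 parameters, the 8 scale-sensitive fractal
#' parameters, the 3 furrow parameters and the 4 texture-direction parameters
#' from a levelled, form-removed height map. Any failing parameter is reported
#' as `NA` and recorded with its reason; the remaining parameters are still
#' computed.
#'
#' @param map a levelled, form-removed [height_map()].
#' @param config an [analysis_config()].
#' @return One-row data frame with 29 columns; attribute `flags` carries
#'   missing-with-reason notes.
#' @export
collect_parameters <- function(map, config = analysis_config()) {
  assert_heightmap(map)
  flags <- character(0)
  note <- function(name, reason) {
    flags[[name]] <<- reason
    NA_real_
  }
  grab <- function(name, expr) {
    tryCatch({
      v <- expr
      if (is.na(v)) note(name, attr(v, "reason") %||% "not computable") else
        as.numeric(v)
    }, error = function(e) note(name, conditionMessage(e)))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  if (sum(map$mask) == 0) {
    out <- as.data.frame(as.list(stats::setNames(
      rep(NA_real_, length(variable_classes())), names(variable_classes()))))
    attr(out, "flags") <- c(all = "all cells masked")
    return(out)
  }
  p <- list()
  p$Sq <- grab("Sq", sq(map))
  p$Smc <- grab("Smc", smc(map, p = config$smc_p))
  ap <- tryCatch(autocorrelation_params(map, s = config$acf_threshold),
                 error = function(e) list(Sal = NA, Str = NA))
  p$Sal <- grab("Sal", ap$Sal)
  p$Str <- grab("Str", ap$Str)
  spec <- tryCatch(direction_spectrum(map), error = function(e) NULL)
  dirs <- if (is.null(spec)) list(Isotropy = NA, First = NA, Second = NA,
                                  Third = NA) else
    texture_direction_params(spec)
  p$Std <- grab("Std", dirs$First)
  p$Sdr <- grab("Sdr", sdr(map))
  p$Vvv <- grab("Vvv", vvv(map, p = config$vvv_p))
  seg <- tryCatch(segment_features(map, pruning = config$pruning),
                  error = function(e) NULL)
  fp <- if (is.null(seg)) NULL else feature_params(seg, map)
  for (nm in c("Spd", "Spc", "Svd", "Shrn", "Shrnq", "Sdrn", "Sdrnq")) {
    p[[nm]] <- if (is.null(fp)) note(nm, "segmentation failed") else fp[[nm]]
  }
  ssfa_res <- tryCatch({
    cur <- relative_area_curve(map)
    asfc(cur)
  }, error = function(e) NULL)
  p$Ymax <- if (is.null(ssfa_res)) note("Ymax", "SSFA failed") else ssfa_res$Ymax
  p$Asfc <- if (is.null(ssfa_res)) note("Asfc", "SSFA failed") else ssfa_res$Asfc
  p$Das <- if (is.null(ssfa_res)) note("Das", "SSFA failed") else ssfa_res$Das
  p$Smfc <- if (is.null(ssfa_res)) note("Smfc", "SSFA failed") else {
    if (is.na(ssfa_res$Smfc)) note("Smfc", "flat relative-area curve") else
      ssfa_res$Smfc
  }
  ha <- tryCatch(hasfc_grid(map), error = function(e) NULL)
  p$HAsfc <- if (is.null(ha)) note("HAsfc", "3x3 grid failed") else ha$HAsfc
  p$MedianAsfc <- if (is.null(ha)) note("MedianAsfc", "3x3 grid failed") else
    ha$MedianAsfc
  scale_um <- max(config$eplsar_scale, 2 * map$spacing * 1000)
  ep <- tryCatch(eplsar(map, scale = scale_um), error = function(e) NULL)
  p$epLsar <- if (is.null(ep)) note("epLsar", "grid too coarse") else ep$epLsar
  p$NewEplsar <- if (is.null(ep)) note("NewEplsar", "grid too coarse") else
    ep$NewEplsar
  p$Isotropy <- grab("Isotropy", dirs$Isotropy)
  p$First.direction <- grab("First.direction", dirs$First)
  p$Second.direction <- grab("Second.direction", dirs$Second)
  p$Third.direction <- grab("Third.direction", dirs$Third)
  fur <- tryCatch(furrow_params(detect_furrows(map, pruning = config$pruning,
                                               seg = seg)),
                  error = function(e) NULL)
  p$Max.depth.furrows <- if (is.null(fur)) note("Max.depth.furrows", "furrow detection failed") else fur$max_depth
  p$Mean.depth.furrows <- if (is.null(fur)) note("Mean.depth.furrows", "furrow detection failed") else fur$mean_depth
  p$Mean.density.furrows <- if (is.null(fur)) note("Mean.density.furrows", "furrow detection failed") else fur$mean_density
  out <- as.data.frame(p)[, names(variable_classes())]
  attr(out, "flags") <- flags
  attr(out, "units") <- parameter_units()
  out
}

#' Units of the surface parameter set
#' @return Named character vector of units per parameter.
#' @export
parameter_units <- function() {
  c(Sq = "mm", Smc = "mm", Sal = "mm", Str = "unitless", Std = "deg",
    Sdr = "%", Vvv = "mm3/mm2", Spd = "1/mm2", Spc = "1/mm", Svd = "1/mm2",
    Shrn = "unitless", Shrnq = "unitless", Sdrn = "unitless",
    Sdrnq = "unitless", Ymax = "unitless", Asfc = "unitless",
    Das = "unitless", Smfc = "um2", HAsfc = "unitless",
    MedianAsfc = "unitless", epLsar = "unitless", NewEplsar = "unitless",
    Isotropy = "%", First.direction = "deg", Second.direction = "deg",
    Third.direction = "deg", Max.depth.furrows = "mm",
    Mean.depth.furrows = "mm", Mean.density.furrows = "cm/cm2")
}

# transform a raw feature table for univariate/multivariate analysis:
# bounded -> logit, circular left in degrees; returns the transformed table
# and the effective variable class per column
transform_features <- function(features) {
  classes <- variable_classes()
  classes <- classes[intersect(names(classes), names(features))]
  extra <- setdiff(names(features), names(classes))
  if (length(extra)) classes[extra] <- "linear"
  out <- features
  eff <- classes
  for (v in names(classes)) {
    if (classes[[v]] == "bounded") {
      up <- if (v %in% names(bounded_upper)) bounded_upper[[v]] else
        max(1, max(features[[v]], na.rm = TRUE))
      out[[v]] <- as.numeric(logit_transform(features[[v]], 0, up))
      eff[[v]] <- "linear"
    }
  }
  list(table = out, classes = eff)
}

# univariate screen: shapiro-routed for linear variables, MWW for circular
univariate_screen <- function(table, classes, labels, alpha) {
  res <- list()
  for (v in names(classes)) {
    vals <- table[[v]]
    ok <- is.finite(vals)
    if (sum(ok) < length(vals) * 0.9 || stats::sd(vals[ok]) < 1e-12) {
      res[[v]] <- NULL
      next
    }
    r <- tryCatch({
      if (classes[[v]] == "circular") {
        mardia_watson_wheeler(vals[ok], labels[ok], alpha = alpha)
      } else {
        shapiro_route(vals[ok], labels[ok], alpha = alpha, variable = v)
      }
    }, error = function(e) NULL)
    if (!is.null(r)) res[[v]] <- r
  }
  res
}

univariate_table <- function(screen) {
  do.call(rbind, lapply(names(screen), function(v) {
    r <- screen[[v]]
    data.frame(variable = v, test = r$test_name, statistic = r$statistic[1],
               p_value = r$p_value, significant = r$significant)
  }))
}

#' Run the technique (or any labelled) surface analysis
#'
#' Executes the full multivariate chain on a labelled feature table:
#' bounded-variable logit transform, normality-routed univariate screening
#' (Mardia-Watson-Wheeler for circular variables), correlation-based variable
#' selection, circular-to-linear projection, standardized PCA, cross-validated
#' LDA and CVA.
#'
#' @param features data frame of surface parameters (rows = sub-areas).
#' @param labels class labels (e.g. technique class or modality code).
#' @param config an [analysis_config()].
#' @return List with `univariate` (data frame), `selection`, `pca`, `lda`,
#'   `cva`, `retained`, `config_hash`.
#' @export
run_technique_analysis <- function(features, labels, config = analysis_config()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes for the analysis")
  tf <- transform_features(features)
  screen <- univariate_screen(tf$table, tf$classes, labels, config$alpha)
  if (length(screen) == 0) stop("no testable variables in the feature table")
  pvals <- vapply(screen, `[[`, numeric(1), "p_value")
  sel <- select_variables(tf$table, tf$classes, pvals,
                          alpha = config$alpha,
                          r2_threshold = config$r2_threshold,
                          n_perm = min(config$n_perm, 199),
                          seed = config$seed)
  # project retained variables into linear space for the PCA
  M <- tf$table[, sel$retained, drop = FALSE]
  for (v in sel$retained) {
    if (tf$classes[[v]] == "circular") {
      M[[v]] <- circular_to_linear(M[[v]], axial = TRUE)
    }
  }
  keep_rows <- stats::complete.cases(M)
  M <- M[keep_rows, , drop = FALSE]
  lab <- droplevels(labels[keep_rows])
  pca <- pca_model(M, retain = config$pca_retain)
  k <- pca$retained_k
  scores <- pca$scores[, seq_len(k), drop = FALSE]
  lda_rep <- lda_cv(scores, lab, k = config$lda_folds, split = config$split,
                    seed = config$seed)
  cva_res <- tryCatch(cva(scores, lab), error = function(e) NULL)
  list(univariate = univariate_table(screen), selection = sel,
       retained = sel$retained, pca = pca, lda = lda_rep, cva = cva_res,
       rows_used = which(keep_rows), config_hash = config$hash)
}

#' Run the expertise analysis per technique
#'
#' Applies the same selection + PCA + LDA chain within each technique subset,
#' classifying by skill level, and returns one classifier report per technique
#' code. Subsets with fewer than two skill classes or too few observations are
#' skipped with a log entry.
#'
#' @param features data frame of surface parameters.
#' @param technique technique/modality code per row.
#' @param skill skill label per row.
#' @param config an [analysis_config()].
#' @param min_per_class minimum observations per skill class in a subset.
#' @return List with `per_technique` (named list of analysis results),
#'   `summary` (one row per technique), `skipped`.
#' @export
run_expertise_analysis <- function(features, technique, skill,
                                   config = analysis_config(),
                                   min_per_class = 10) {
  technique <- as.character(technique)
  out <- list(); skipped <- list()
  for (te in unique(technique)) {
    rows <- technique == te
    sk <- factor(skill[rows])
    if (nlevels(droplevels(sk)) < 2 || min(table(droplevels(sk))) < min_per_class) {
      skipped[[te]] <- "fewer than 2 skill classes or too few observations"
      next
    }
    res <- tryCatch(
      run_technique_analysis(features[rows, , drop = FALSE],
                             droplevels(sk), config),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) skipped[[te]] <- res else out[[te]] <- res
  }
  summary <- do.call(rbind, lapply(names(out), function(te) {
    l <- out[[te]]$lda
    data.frame(technique = te, accuracy = l$accuracy, kappa = l$kappa,
               accuracy_lower = l$accuracy_ci[1],
               accuracy_upper = l$accuracy_ci[2], nir = l$nir,
               accuracy_p_value = l$accuracy_p_value)
  }))
  list(per_technique = out, summary = summary, skipped = skipped,
       config_hash = config$hash)
}

#' Run the engraving cross-section analysis
#'
#' For a set of labelled profiles: landmark detection and the D / WIS / theta
#' / A measurements; Rayleigh and Watson-Williams tests on the opening angles;
#' PCA of the metric variables (theta linearised) with per-set convex-hull
#' vertices exported as data; a normality-routed test on PC1; permutation
#' MANOVA on the first two PCs; and six-harmonic elliptic Fourier shape
#' analysis with normalization, allometry check and shape PCA.
#'
#' @param profiles list of [profile_trace()] objects.
#' @param sets set label per profile (e.g. Set A-I).
#' @param config an [analysis_config()].
#' @return List with `measurements`, `circular_tests`, `metric_pca`,
#'   `convex_hulls`, `pc1_test`, `manova`, `efa` (shape variables, allometry,
#'   shape PCA), `excluded_sets`.
#' @export
run_engraving_analysis <- function(profiles, sets, config = analysis_config()) {
  sets <- as.character(sets)
  tab <- table(sets)
  excluded <- names(tab)[tab < 2]
  keep <- !(sets %in% excluded)
  profiles <- profiles[keep]; sets <- sets[keep]
  if (length(profiles) < 4) stop("too few profiles after set exclusion")
  meas <- list(); shapes <- list(); sizes <- numeric(0)
  for (i in seq_along(profiles)) {
    lmk <- detect_landmarks(profiles[[i]])
    m <- measure_profile(profiles[[i]], lmk)
    meas[[i]] <- data.frame(set = sets[i], D = m$D * 1000,
                            WIS = m$WIS * 1000, theta = m$theta,
                            A = m$A, shallow = m$shallow)
    outline <- close_outline(profiles[[i]], lmk)
    e <- normalize_efa(efa(outline, h = config$harmonics))
    shapes[[i]] <- e$shape_variables
    sizes[i] <- efa(outline, h = config$harmonics)$centroid_size
  }
  meas <- do.call(rbind, meas)
  shapes <- do.call(rbind, shapes)
  circ <- list(
    rayleigh_all = rayleigh_test(meas$theta, alpha = config$alpha),
    watson_williams = tryCatch(
      watson_williams(meas$theta, meas$set, alpha = config$alpha),
      error = function(e) NULL)
  )
  metric <- data.frame(D = meas$D, WIS = meas$WIS, A = meas$A,
                       theta_lin = circular_to_linear(meas$theta, axial = FALSE))
  pca <- pca_model(metric, retain = config$pca_retain)
  hulls <- lapply(split(seq_len(nrow(metric)), meas$set), function(ii) {
    pts <- pca$scores[ii, 1:2, drop = FALSE]
    pts[grDevices::chull(pts), , drop = FALSE]
  })
  pc1_test <- shapiro_route(pca$scores[, 1], meas$set, alpha = config$alpha,
                            variable = "PC1")
  man <- manova_permutation(pca$scores, meas$set, n_perm = config$n_perm,
                            components = min(2, ncol(pca$scores)),
                            seed = config$seed)
  allo <- tryCatch(allometry_check(shapes, sizes, alpha = config$alpha),
                   error = function(e) NULL)
  shape_pca <- pca_model(shapes, retain = config$pca_retain)
  shape_man <- manova_permutation(shape_pca$scores, meas$set,
                                  n_perm = config$n_perm,
                                  components = min(2, ncol(shape_pca$scores)),
                                  seed = config$seed + 1)
  list(measurements = meas, circular_tests = circ, metric_pca = pca,
       convex_hulls = hulls, pc1_test = pc1_test, manova = man,
       efa = list(shape_variables = shapes, centroid_sizes = sizes,
                  allometry = allo, shape_pca = shape_pca,
                  shape_manova = shape_man),
       excluded_sets = excluded, config_hash = config$hash)
}

#' Serialize a parameter table to CSV with a units header
#'
#' Writes one row per sub-area with a second header row carrying the unit of
#' every parameter and a provenance column.
#'
#' @param features data frame of parameters.
#' @param path output CSV path.
#' @param provenance character scalar recorded per row.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(features, path, provenance = "") {
  units <- parameter_units()
  u <- ifelse(names(features) %in% names(units), units[names(features)], "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(names(features), "provenance"), collapse = ","), con)
  writeLines(paste(c(u, "units"), collapse = ","), con)
  utils::write.table(cbind(features, provenance = provenance), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
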