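#' Drop rows with missing values among selected features
#'
#' Complete-case filtering over the requested feature columns; with small
#' cohorts imputation is riskier than dropping, so rows carrying any missing
#' value among the requested features are removed.
#'
#' @param table A data frame of per-sample features.
#' @param features Column names to require; defaults to all columns.
#' @return The filtered data frame, with the number of dropped rows attached
#'   as attribute `"n_dropped"`.
#' @export
complete_cases <- function(table, features = names(table)) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols) > 0)
    stop("unknown features: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(table[, features, drop = FALSE])
  if (!any(keep)) stop("empty result: every row has missing data")
  out <- table[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# double-centered Euclidean distance matrix (V-statistic centering)
.dc_center <- function(x) {
  d <- as.matrix(stats::dist(x))
  sweep(sweep(d, 1L, rowMeans(d)), 2L, colMeans(d)) + mean(d)
}

#' Sample distance correlation
#'
#' The V-statistic (biased) estimator: pairwise Euclidean distance matrices
#' of `x` and `y` are double-centered and `dCov^2` is the mean of their
#' elementwise product; `dc = dCov / sqrt(dVar_x * dVar_y)`. Distance
#' correlation lies in `[0, 1]` and is zero (in population) iff the
#' variables are independent, so it captures nonlinear dependencies that
#' Pearson's r misses. If either variable is constant the statistic is
#' defined as 0 and a warning is raised. The bias-corrected U-statistic
#' variant is available with `unbiased = TRUE` (its square can be slightly
#' negative; the signed root is returned).
#'
#' @param x,y Numeric vectors (or matrices with observations in rows) of
#'   equal length `n >= 4`, finite values.
#' @param unbiased Use the U-statistic estimator.
#' @return Distance correlation in `[0, 1]`.
#' @export
distance_correlation <- function(x, y, unbiased = FALSE) {
  nx <- if (is.matrix(x)) nrow(x) else length(x)
  ny <- if (is.matrix(y)) nrow(y) else length(y)
  if (nx != ny) stop("x and y must have equal length")
  if (nx < 4L) stop("need at least 4 observations")
  if (!all(is.finite(as.numeric(x))) || !all(is.finite(as.numeric(y))))
    stop("values must be finite")
  if (unbiased) return(.dcor_unbiased(x, y))
  A <- .dc_center(x)
  B <- .dc_center(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx == 0 || dvy == 0) {
    warning("constant vector: distance correlation defined as 0")
    return(0)
  }
  dcov2 <- mean(A * B)
  sqrt(max(0, dcov2) / sqrt(dvx * dvy))
}

# U-centered estimator (Szekely & Rizzo bias-corrected form)
.dcor_unbiased <- function(x, y) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 4L) stop("need at least 4 observations")
  ucenter <- function(v) {
    d <- as.matrix(stats::dist(v))
    r <- rowSums(d) / (n - 2)
    s <- sum(d) / ((n - 1) * (n - 2))
    u <- d - outer(r, rep(1, n)) - outer(rep(1, n), r) + s
    diag(u) <- 0
    u
  }
  A <- ucenter(x)
  B <- ucenter(y)
  den <- n * (n - 3)
  dvx <- sum(A * A) / den
  dvy <- sum(B * B) / den
  if (dvx <= 0 || dvy <= 0) {
    warning("constant vector: distance correlation defined as 0")
    return(0)
  }
  r2 <- (sum(A * B) / den) / sqrt(dvx * dvy)
  sign(r2) * sqrt(abs(r2))
}

#' Permutation test of independence via distance correlation
#'
#' The null distribution is generated by randomly permuting the sample
#' labels of `y` (`n_resamples` times, default 2000) and recomputing the
#' distance correlation; because double-centering commutes with relabeling,
#' each permutation only requires re-indexing the centered matrix. The
#' p-value is `(1 + #(dc_perm >= dc_obs)) / (1 + n_resamples)`. A
#' with-replacement bootstrap null is available behind `method =
#' "bootstrap"`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_resamples Number of resamples (default 2000).
#' @param seed Optional seed for reproducibility.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param method `"permutation"` (canonical) or `"bootstrap"`.
#' @return An object of class `dependency_result`: `dc`, `p_value`,
#'   `n_resamples`, `n_used`, `significant`, `method`.
#' @export
dc_test <- function(x, y, n_resamples = 2000, seed = NULL, alpha = 0.05,
                    method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  constant <- stats::sd(x) == 0 || stats::sd(y) == 0
  A <- .dc_center(x)
  B <- .dc_center(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  obs <- if (dvx == 0 || dvy == 0) 0 else
    sqrt(max(0, mean(A * B)) / sqrt(dvx * dvy))
  if (constant) {
    warning("constant vector: dc = 0, p = 1")
    return(structure(list(dc = 0, p_value = 1, n_resamples = n_resamples,
                          n_used = n, significant = FALSE, method = method),
                     class = "dependency_result"))
  }
  exceed <- 0L
  for (b in seq_len(n_resamples)) {
    p <- if (method == "permutation") sample.int(n) else
      sample.int(n, replace = TRUE)
    if (method == "permutation") {
      Bp <- B[p, p]
      dvyp <- dvy
    } else {
      yb <- y[p]
      Bp <- .dc_center(yb)
      dvyp <- mean(Bp * Bp)
    }
    dcp <- if (dvyp == 0) 0 else sqrt(max(0, mean(A * Bp)) / sqrt(dvx * dvyp))
    if (dcp >= obs) exceed <- exceed + 1L
  }
  p_value <- (1 + exceed) / (1 + n_resamples)
  structure(list(dc = obs, p_value = p_value, n_resamples = n_resamples,
                 n_used = n, significant = p_value < alpha, method = method),
            class = "dependency_result")
}

#' @export
print.dependency_result <- function(x, ...) {
  cat(sprintf("dc = %.3f, p = %.4g (%d resamples, n = %d)%s\n",
              x$dc, x$p_value, x$n_resamples, x$n_used,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise distance-correlation screen over a feature table
#'
#' Runs [dc_test()] for every unordered pair of the requested feature
#' columns on the complete-case subset. No multiple-testing correction is
#' applied by default (each pair is reported at raw `alpha`); a
#' Benjamini-Hochberg adjustment can be switched on.
#'
#' @param table Data frame of per-sample features.
#' @param features Columns to include; defaults to all numeric columns.
#' @param alpha Significance level.
#' @param n_resamples Permutations per pair.
#' @param seed Optional seed (one stream across all pairs).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame with one row per pair: `feature_x`, `feature_y`,
#'   `dc`, `p_value`, `n_used`, `significant`; the square dc matrix is
#'   attached as attribute `"dc_matrix"`.
#' @export
pairwise_dependencies <- function(table, features = NULL, alpha = 0.05,
                                  n_resamples = 2000, seed = NULL,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(features))
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(features) < 2L) stop("need at least 2 features")
  tab <- complete_cases(table, features)
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(features, 2)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    fx <- pairs[1, k]; fy <- pairs[2, k]
    r <- tryCatch(
      suppressWarnings(dc_test(tab[[fx]], tab[[fy]],
                               n_resamples = n_resamples, alpha = alpha)),
      error = function(e) NULL)
    res[[k]] <- data.frame(
      feature_x = fx, feature_y = fy,
      dc = if (is.null(r)) NA_real_ else r$dc,
      p_value = if (is.null(r)) NA_real_ else r$p_value,
      n_used = nrow(tab),
      significant = if (is.null(r)) NA else r$significant,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  }
  m <- matrix(NA_real_, length(features), length(features),
              dimnames = list(features, features))
  diag(m) <- 1
  for (k in seq_len(nrow(out))) {
    m[out$feature_x[k], out$feature_y[k]] <- out$dc[k]
    m[out$feature_y[k], out$feature_x[k]] <- out$dc[k]
  }
  attr(out, "dc_matrix") <- m
  out
}

#' Compare the 3D orientation index across stress regions
#'
#' One-way ANOVA of per-sample 3DOI values grouped by stress region (toe,
#' heel, linear), followed by Tukey HSD pairwise comparisons with
#' significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001, ns
#' otherwise).
#'
#' @param oi_values Named list of numeric vectors, one per region (>= 2
#'   groups with >= 2 values each), or a data frame with columns `oi3d` and
#'   `region`.
#' @param channel Optional channel label carried into the output.
#' @return A list: `anova` (the ANOVA table), `f`, `p`, `tukey` (data frame
#'   of pairwise comparisons with `p_adj` and `stars`), `channel`.
#' @export
region_comparison <- function(oi_values, channel = NULL) {
  if (is.data.frame(oi_values)) {
    df <- data.frame(oi3d = oi_values$oi3d,
                     region = factor(oi_values$region))
  } else {
    df <- data.frame(
      oi3d = unlist(oi_values, use.names = FALSE),
      region = factor(rep(names(oi_values), lengths(oi_values))))
  }
  sizes <- table(df$region)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 values each")
  fit <- stats::aov(oi3d ~ region, data = df)
  tab <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$region
  stars <- cut(tuk[, "p adj"], c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", "ns"))
  tukey <- data.frame(comparison = rownames(tuk),
                      diff = tuk[, "diff"], lwr = tuk[, "lwr"],
                      upr = tuk[, "upr"], p_adj = tuk[, "p adj"],
                      stars = as.character(stars),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(anova = tab, f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       tukey = tukey, channel = channel)
}
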