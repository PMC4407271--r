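# Shared statistical machinery: binomial GLM for recombinant-fraction
# comparisons, variance F-test, merged-category chi-square, Yates 2x2
# chi-square, Benjamini-Hochberg FDR, windowed rank correlation.

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method),
            class = "ftl_test")
}

#' @export
print.ftl_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Binomial GLM comparison of recombinant fractions
#'
#' Fits \code{cbind(Y, n - Y) ~ replicate + genotype} (logit link, binomial
#' family) by iteratively reweighted least squares and tests the genotype
#' effect by likelihood ratio against the model without it.  Recombinant
#' counts \code{Y_i} out of totals \code{n_i} are modelled per observation;
#' replicates and genotypes enter as independent variables.
#'
#' @param data Data frame with columns \code{recombinant}, \code{total},
#'   \code{genotype} and optionally \code{replicate}.
#' @param include_replicate Include the replicate term when present
#'   (default \code{TRUE}).
#' @return List with \code{coefficients}, \code{deviance},
#'   \code{residual_df}, \code{test} (an \code{"ftl_test"} with the
#'   likelihood-ratio statistic), \code{separation} flag, and the fitted
#'   \code{glm} object.
#' @examples
#' d <- data.frame(genotype = rep(c("a", "b"), each = 2),
#'                 replicate = rep(1:2, 2),
#'                 recombinant = c(30, 28, 55, 60), total = rep(300, 4))
#' fit_binomial_glm(d)$test
#' @export
fit_binomial_glm <- function(data, include_replicate = TRUE) {
  need <- c("recombinant", "total", "genotype")
  if (!all(need %in% names(data)))
    stop("'data' needs columns: ", paste(need, collapse = ", "))
  if (any(data$recombinant < 0) || any(data$recombinant > data$total))
    stop("need 0 <= recombinant <= total")
  if (length(unique(data$genotype)) < 2)
    stop("need >= 2 genotype levels for testing")
  data$genotype <- factor(data$genotype)
  use_rep <- include_replicate && "replicate" %in% names(data) &&
    length(unique(data$replicate)) > 1
  if (use_rep) data$replicate <- factor(data$replicate)
  rhs1 <- if (use_rep) "replicate + genotype" else "genotype"
  rhs0 <- if (use_rep) "replicate" else "1"
  sep <- FALSE
  fit1 <- withCallingHandlers(
    glm(as.formula(paste("cbind(recombinant, total - recombinant) ~", rhs1)),
        family = binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(is.na(coef(fit1)))) {
    bad <- names(coef(fit1))[is.na(coef(fit1))]
    stop("rank-deficient design; aliased coefficients: ",
         paste(bad, collapse = ", "))
  }
  cf <- coef(fit1)
  if (sep) {
    warning("complete or quasi-complete separation detected; ",
            "coefficients clamped to |beta| <= 15")
    cf <- pmin(pmax(cf, -15), 15)
  }
  fit0 <- glm(as.formula(paste("cbind(recombinant, total - recombinant) ~",
                               rhs0)),
              family = binomial(), data = data)
  lrt <- max(0, fit0$deviance - fit1$deviance)
  df <- fit0$df.residual - fit1$df.residual
  list(coefficients = cf, deviance = fit1$deviance,
       residual_df = fit1$df.residual,
       test = new_test_result(lrt, df,
                              pchisq(lrt, df, lower.tail = FALSE),
                              "binomial GLM likelihood-ratio"),
       separation = sep, fit = fit1)
}

#' F-test for equality of variances of per-individual cM values
#'
#' @param groupA,groupB Numeric vectors (each of length >= 2).
#' @return An \code{"ftl_test"} with \code{F = var(A)/var(B)},
#'   \code{(nA - 1, nB - 1)} degrees of freedom and a two-sided p-value.
#' @export
variance_f_test <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  if (var(groupB) == 0) stop("zero variance in denominator group")
  vt <- var.test(groupA, groupB)
  new_test_result(vt$statistic, vt$parameter, vt$p.value,
                  "variance F-test")
}

#' Chi-square test with tail-inward category merging
#'
#' Pools adjacent count categories, starting from the distribution tails and
#' moving inward, until every expected cell of the groups x categories table
#' reaches \code{min_expected}; then applies the standard (uncorrected)
#' chi-square test to the merged table.  Used for count distributions with
#' sparse tails such as per-nucleus chiasmata counts.
#'
#' @param counts Matrix (or data frame) of counts, one row per group, one
#'   column per ordered category.
#' @param min_expected Minimum expected cell count after merging (default 5).
#' @return An \code{"ftl_test"}; attribute \code{"merged"} holds the merged
#'   table, whose column names record which categories were pooled.
#' @export
merged_chisq <- function(counts, min_expected = 5) {
  m <- as.matrix(counts)
  if (nrow(m) < 2) stop("need >= 2 groups")
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  repeat {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    if (all(E >= min_expected) || ncol(m) == 1) break
    bad <- which(apply(E, 2, min) < min_expected)
    # merge the offending category nearest a tail with its inward neighbour
    j <- if (min(bad) - 1 <= ncol(m) - max(bad)) min(bad) else max(bad)
    k <- if (j == 1 || (j != ncol(m) && min(bad) == j)) j + 1 else j - 1
    lo <- min(j, k); hi <- max(j, k)
    merged <- m[, lo] + m[, hi]
    nm <- paste(colnames(m)[lo], colnames(m)[hi], sep = "+")
    m <- cbind(m[, seq_len(lo - 1), drop = FALSE], merged,
               m[, seq(hi + 1, length.out = ncol(m) - hi), drop = FALSE])
    colnames(m)[lo] <- nm
  }
  if (ncol(m) == 1)
    stop("merging collapsed the distribution to a single category")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  res <- new_test_result(ct$statistic, ct$parameter, ct$p.value,
                         "chi-square with merged categories")
  attr(res, "merged") <- m
  res
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Chi-square with continuity correction,
#' \code{sum((|O - E| - 0.5)^2 / E)} on 1 degree of freedom.
#'
#' @param table 2x2 matrix of counts with all row and column margins > 0.
#' @return An \code{"ftl_test"}.
#' @examples
#' yates_chisq_2x2(matrix(c(5, 20, 15, 0), 2, 2))
#' @export
yates_chisq_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2)) stop("'table' must be 2x2")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins of the 2x2 table must be positive")
  ct <- suppressWarnings(chisq.test(m, correct = TRUE))
  new_test_result(ct$statistic, ct$parameter, ct$p.value,
                  "Yates chi-square")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; adjusted values are
#' never below the raw p-values and are capped at 1.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @return Vector of adjusted p-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 1.0))
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("all p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Re-bin a windowed track to a coarser scale
#'
#' Averages consecutive groups of \code{factor} windows (missing values
#' ignored; all-missing groups stay missing).
#'
#' @param x Numeric per-window values.
#' @param factor Number of fine windows per coarse window (>= 1).
#' @return Numeric vector of length \code{ceiling(length(x) / factor)}.
#' @export
rebin_track <- function(x, factor) {
  if (factor < 1) stop("'factor' must be >= 1")
  g <- (seq_along(x) - 1) %/% factor
  out <- tapply(x, g, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  as.numeric(out)
}

#' Spearman correlation between two windowed genomic tracks
#'
#' Rank correlation across aligned windows, dropping window pairs with a
#' missing value; fine tracks can be averaged to a coarser scale first with
#' \code{scale_factor}.
#'
#' @param trackA,trackB Numeric per-window values of equal length.
#' @param scale_factor Re-binning factor applied to both tracks before
#'   correlating (default 1 = native resolution).
#' @return List with \code{rho}, \code{n_windows} used and \code{p_value}.
#' @export
windowed_spearman <- function(trackA, trackB, scale_factor = 1) {
  if (length(trackA) != length(trackB))
    stop("tracks must have the same number of windows")
  if (scale_factor > 1) {
    trackA <- rebin_track(trackA, scale_factor)
    trackB <- rebin_track(trackB, scale_factor)
  }
  ok <- is.finite(trackA) & is.finite(trackB)
  if (sum(ok) < 3) stop("need at least 3 non-missing window pairs")
  ct <- suppressWarnings(cor.test(trackA[ok], trackB[ok],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), n_windows = sum(ok),
       p_value = ct$p.value)
}
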