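# Crossover-interference statistics: coefficient of coincidence from
# three-colour pollen classes, adjacent-interval tetrad interference, and
# combined-probability testing.

#' Coefficient of coincidence from three-colour pollen counts
#'
#' Observed double crossovers are the two classes recombinant in both
#' intervals, \code{N_-Y- + N_B-R}; the expectation under independence is
#' \code{(cM_b/100) (cM_c/100) N_total}.  The coefficient of coincidence is
#' observed/expected and interference strength is \code{1 - CoC}.  The
#' p-value is from a binomial test of the observed DCO count against the
#' expected DCO proportion.
#'
#' @param counts A \code{\link{threecolour_counts}} object.
#' @return A list of class \code{"interference_result"}: \code{observed_dco},
#'   \code{expected_dco}, \code{coc}, \code{interference}, \code{p_value},
#'   plus both interval estimates.
#' @export
coc_threecolour <- function(counts) {
  if (!inherits(counts, "threecolour_counts"))
    counts <- do.call(threecolour_counts, list(counts))
  cms <- threecolour_cms(counts)
  if (cms$b$cM <= 0 || cms$c$cM <= 0)
    stop("CoC undefined: both interval cM values must be positive")
  v <- counts$counts
  obs <- unname(v["-Y-"] + v["B-R"])
  exp_dco <- (cms$b$cM / 100) * (cms$c$cM / 100) * counts$N_total
  p <- binom.test(obs, counts$N_total, exp_dco / counts$N_total)$p.value
  structure(list(observed_dco = obs, expected_dco = exp_dco,
                 coc = obs / exp_dco, interference = 1 - obs / exp_dco,
                 p_value = p, cm_b = cms$b, cm_c = cms$c),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, ...) {
  cat(sprintf(
    "DCO observed %d, expected %.1f; CoC = %.3f, interference = %.3f (p = %.3g)\n",
    as.integer(x$observed_dco), x$expected_dco, x$coc, x$interference,
    x$p_value))
  invisible(x)
}

#' Adjacent-interval interference from per-tetrad calls
#'
#' Compares the map distance of a focal interval between tetrads that do and
#' do not carry a crossover in the adjacent interval.  Positive interference
#' makes the with-adjacent-crossover stratum shorter, so the ratio
#' without/with exceeds 1.  Significance is a two-sided z-test on the Perkins
#' estimates using their delta-method standard errors.
#'
#' Either supply per-tetrad calls (columns \code{focal} and \code{adjacent},
#' each \code{"PD"}, \code{"NPD"} or \code{"T"}; the adjacent interval "has a
#' crossover" when its class is not PD), or supply the two stratum estimates
#' directly.
#'
#' @param calls Data frame of per-tetrad interval classes (see above), or
#'   \code{NULL}.
#' @param est_without,est_with \code{"crossover_estimate"} objects (or lists
#'   with \code{cM} and \code{se}) for the two strata, used when \code{calls}
#'   is \code{NULL}.
#' @return A list of class \code{"adjacent_interference_result"}:
#'   \code{cm_without}, \code{cm_with}, \code{ratio}, \code{p_value}.
#' @examples
#' tetrad_adjacent_interference(est_without = list(cM = 7.65, se = 0.30),
#'                              est_with = list(cM = 1.90, se = 0.22))
#' @export
tetrad_adjacent_interference <- function(calls = NULL, est_without = NULL,
                                         est_with = NULL) {
  if (!is.null(calls)) {
    if (!all(c("focal", "adjacent") %in% names(calls)))
      stop("'calls' needs columns 'focal' and 'adjacent'")
    has_adj <- calls$adjacent != "PD"
    if (!any(has_adj) || all(has_adj))
      stop("both strata (with and without adjacent crossover) must be non-empty")
    strat <- function(sel) {
      cl <- calls$focal[sel]
      tetrad_cm(tetrad_counts(sum(cl == "PD"), sum(cl == "NPD"),
                              sum(cl == "T")))
    }
    est_without <- strat(!has_adj)
    est_with <- strat(has_adj)
  }
  if (is.null(est_without) || is.null(est_with))
    stop("supply either 'calls' or both stratum estimates")
  z <- (est_without$cM - est_with$cM) /
    sqrt(est_without$se^2 + est_with$se^2)
  ratio <- if (est_with$cM > 0) est_without$cM / est_with$cM else NA_real_
  structure(list(cm_without = est_without, cm_with = est_with,
                 ratio = ratio, p_value = 2 * pnorm(-abs(z))),
            class = "adjacent_interference_result")
}

#' @export
print.adjacent_interference_result <- function(x, ...) {
  cat(sprintf(
    "cM without adjacent CO %.2f +/- %.2f; with %.2f +/- %.2f; ratio %.2f (p = %.3g)\n",
    x$cm_without$cM, x$cm_without$se, x$cm_with$cM, x$cm_with$se,
    x$ratio, x$p_value))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values as \code{chi2 = -2 sum(log p)} on
#' \code{2k} degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in \code{(0, 1]}.
#' @return List with \code{chi2}, \code{df} and \code{p_value}.
#' @examples
#' fisher_combined(rep(0.05, 8))  # chi2 = 47.93, df = 16
#' @export
fisher_combined <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("all p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df,
       p_value = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Critical value of the chi-square distribution
#'
#' Upper-tail critical value at significance level \code{alpha}, the
#' reference point for Fisher's combined statistic.
#'
#' @param alpha Significance level in \code{(0, 1)}.
#' @param df Degrees of freedom.
#' @return Numeric scalar.
#' @examples
#' fisher_critical(0.001, 16)
#' @export
fisher_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  qchisq(1 - alpha, df = df)
}

#' Compare interference strength between two groups of replicates
#'
#' Models the double-crossover counts of each replicate as binomial with an
#' offset at the log-odds of the replicate's expected DCO proportion (from
#' its own interval estimates, i.e. the no-interference expectation), and
#' tests the group effect by likelihood ratio.  A group that deviates more
#' from its expectation than the other (stronger interference) yields a
#' significant group term.
#'
#' @param groupA,groupB Lists of \code{\link{threecolour_counts}} replicates
#'   (at least one each).
#' @return List with \code{p_value}, the fitted \code{glm}, and the
#'   per-replicate working table.
#' @export
compare_interference <- function(groupA, groupB) {
  if (inherits(groupA, "threecolour_counts")) groupA <- list(groupA)
  if (inherits(groupB, "threecolour_counts")) groupB <- list(groupB)
  if (length(groupA) < 1 || length(groupB) < 1)
    stop("need at least one replicate per group")
  row1 <- function(cc, grp) {
    v <- cc$counts; N <- cc$N_total
    cms <- threecolour_cms(cc)
    data.frame(group = grp, obs = unname(v["-Y-"] + v["B-R"]), total = N,
               exp_prop = (cms$b$cM / 100) * (cms$c$cM / 100))
  }
  tab <- rbind(do.call(rbind, lapply(groupA, row1, grp = "A")),
               do.call(rbind, lapply(groupB, row1, grp = "B")))
  if (all(tab$obs == 0))
    stop("no double crossovers observed in either group")
  tab$exp_prop <- pmin(pmax(tab$exp_prop, 1e-12), 1 - 1e-12)
  off <- qlogis(tab$exp_prop)
  fit1 <- glm(cbind(obs, total - obs) ~ group + offset(off),
              family = binomial(), data = tab)
  fit0 <- glm(cbind(obs, total - obs) ~ 1 + offset(off),
              family = binomial(), data = tab)
  lrt <- max(0, fit0$deviance - fit1$deviance)
  list(p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
       fit = fit1, table = tab)
}
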