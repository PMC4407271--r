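# Marker-vs-crossover-rate association in F2 reporter populations:
# hot/cold-quartile contingency tests and a permutation-thresholded
# single-marker LOD scan.

pool_hom <- function(g) ifelse(g == "HET", "HET",
                               ifelse(is.na(g), NA_character_, "HOM"))

#' Hot/cold-quartile marker association
#'
#' Ranks the F2 individuals by measured cM (ties broken by id for
#' determinism), takes the hottest and coldest \code{floor(n/4)}, and for
#' each marker builds the 2x2 table of heterozygous vs homozygous counts
#' (both homozygous classes pooled) in the two quartiles.  Each table gets a
#' Yates-corrected chi-square test; p-values are Benjamini-Hochberg adjusted
#' across the tested markers.  Markers where every scored individual falls in
#' one genotype class are untestable and reported with statistic 0, p 1.
#'
#' @param geno Character matrix or data frame (individuals x markers) with
#'   values \code{"HET"}, \code{"HOM_REF"}, \code{"HOM_ALT"} or \code{NA};
#'   alternatively an \code{"ftl_f2"} object from
#'   \code{\link{simulate_f2_population}}, in which case \code{cm} is taken
#'   from it.
#' @param cm Numeric per-individual cM estimates.
#' @param ids Individual identifiers used for deterministic tie-breaking
#'   (default row names or row numbers).
#' @return Data frame with one row per marker: quartile counts
#'   (\code{hot_het}, \code{hot_hom}, \code{cold_het}, \code{cold_hom}),
#'   \code{chi2}, \code{p}, \code{p_adj}.
#' @export
quartile_association <- function(geno, cm = NULL, ids = NULL) {
  if (inherits(geno, "ftl_f2")) {
    cm <- geno$pheno$cM
    ids <- geno$pheno$id
    geno <- geno$geno
  }
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(cm) || length(cm) != n)
    stop("'cm' must give one value per individual")
  if (n < 8) stop("need at least 8 individuals (quartile size >= 2)")
  if (is.null(ids)) ids <- rownames(geno) %||% as.character(seq_len(n))
  q <- n %/% 4L
  ord <- order(cm, ids)
  cold <- ord[seq_len(q)]
  hot <- ord[seq.int(n - q + 1L, n)]
  res <- lapply(seq_len(ncol(geno)), function(j) {
    gh <- pool_hom(geno[hot, j]); gc <- pool_hom(geno[cold, j])
    if (all(is.na(c(gh, gc))))
      stop("marker ", colnames(geno)[j] %||% j, " has no scored genotypes")
    tab <- quartile_chisq(sum(gh == "HET", na.rm = TRUE),
                          sum(gh == "HOM", na.rm = TRUE),
                          sum(gc == "HET", na.rm = TRUE),
                          sum(gc == "HOM", na.rm = TRUE))
    tab
  })
  out <- do.call(rbind, res)
  out <- data.frame(marker = colnames(geno) %||% seq_len(ncol(geno)), out,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- bh_fdr(out$p)
  out
}

# internal: one quartile 2x2 test; degenerate margins -> chi2 0, p 1
quartile_chisq <- function(hot_het, hot_hom, cold_het, cold_hom) {
  m <- matrix(c(hot_het, cold_het, hot_hom, cold_hom), 2, 2)
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  if (degenerate) {
    chi2 <- 0; p <- 1
  } else {
    t <- yates_chisq_2x2(m)
    chi2 <- t$statistic; p <- t$p_value
  }
  data.frame(hot_het = hot_het, hot_hom = hot_hom, cold_het = cold_het,
             cold_hom = cold_hom, chi2 = chi2, p = p)
}

#' Quartile association from pre-tabulated contingency counts
#'
#' Applies the same Yates chi-square + Benjamini-Hochberg pipeline as
#' \code{\link{quartile_association}} to already-tabulated per-marker
#' quartile counts (e.g. a published genotype-count table).
#'
#' @param tables Data frame with columns \code{hot_het}, \code{hot_hom},
#'   \code{cold_het}, \code{cold_hom} and optionally \code{marker}.
#' @return The input with \code{chi2}, \code{p} and \code{p_adj} columns
#'   appended.
#' @export
quartile_counts_test <- function(tables) {
  need <- c("hot_het", "hot_hom", "cold_het", "cold_hom")
  if (!all(need %in% names(tables)))
    stop("'tables' needs columns: ", paste(need, collapse = ", "))
  res <- do.call(rbind, lapply(seq_len(nrow(tables)), function(i)
    quartile_chisq(tables$hot_het[i], tables$hot_hom[i],
                   tables$cold_het[i], tables$cold_hom[i])))
  out <- cbind(tables[setdiff(names(tables), names(res))], res)
  out$p_adj <- bh_fdr(out$p)
  out
}

# internal: residual sums of squares for the single-marker regression
marker_rss <- function(y, g) {
  ok <- !is.na(g) & is.finite(y)
  y <- y[ok]; g <- g[ok]
  rss0 <- sum((y - mean(y))^2)
  mu <- tapply(y, g, mean)
  rss1 <- sum((y - mu[g])^2)
  c(rss0 = rss0, rss1 = rss1, n = length(y))
}

#' Single-marker LOD scan with a permutation genome-wide threshold
#'
#' Regresses the per-individual cM phenotype on each marker's genotype
#' classes and reports \code{LOD = (n/2) log10(RSS0 / RSS1)}.  The
#' genome-wide significance threshold is the \code{1 - alpha} quantile of the
#' maximum LOD over random permutations of the phenotype vector.
#'
#' @param geno Genotype matrix as in \code{\link{quartile_association}}, or
#'   an \code{"ftl_f2"} object.
#' @param cm Numeric per-individual phenotype.
#' @param n_permutations Number of phenotype permutations (default 1000).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed making the permutation threshold reproducible.
#' @return List with \code{lod} (data frame: marker, lod), \code{threshold},
#'   \code{max_lod}, \code{alpha}, \code{n_permutations}.
#' @export
lod_scan <- function(geno, cm = NULL, n_permutations = 1000, alpha = 0.05,
                     seed = NULL) {
  if (inherits(geno, "ftl_f2")) {
    cm <- geno$pheno$cM
    geno <- geno$geno
  }
  geno <- as.matrix(geno)
  if (is.null(cm) || length(cm) != nrow(geno))
    stop("'cm' must give one value per individual")
  if (var(cm, na.rm = TRUE) == 0) stop("constant phenotype")
  usable <- apply(geno, 2, function(g)
    length(unique(g[!is.na(g)])) >= 2)
  if (!any(usable)) stop("no marker has >= 2 genotype classes")
  if (!is.null(seed)) set.seed(seed)
  lod1 <- function(y) {
    vapply(which(usable), function(j) {
      r <- marker_rss(y, geno[, j])
      if (r["rss1"] <= 0) return(Inf)
      (r["n"] / 2) * log10(r["rss0"] / r["rss1"])
    }, numeric(1))
  }
  lod <- rep(NA_real_, ncol(geno))
  lod[usable] <- lod1(cm)
  perm_max <- vapply(seq_len(n_permutations),
                     function(i) max(lod1(sample(cm))), numeric(1))
  list(lod = data.frame(marker = colnames(geno) %||% seq_len(ncol(geno)),
                        lod = lod, stringsAsFactors = FALSE),
       threshold = unname(quantile(perm_max, 1 - alpha, type = 7)),
       max_lod = max(lod, na.rm = TRUE), alpha = alpha,
       n_permutations = n_permutations)
}
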