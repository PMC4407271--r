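# Genetic-distance estimators for the four FTL scoring modalities, plus
# seed-object intensity classification and ancillary per-interval metrics.

# counts are usually integers, but expected (model) counts are real-valued;
# strict integer validation happens at the I/O boundary (read_count_table)
chk_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0)
    stop("'", name, "' must be a single non-negative count")
  as.numeric(x)
}

#' Two-colour pollen class counts
#'
#' Container for flow-cytometry counts of a two-colour pollen reporter.
#' \code{R3} is the green+red (parental) class and \code{R5} the green-alone
#' (recombinant) class; red-alone and colourless counts are retained but do
#' not enter the genetic-distance estimate, which conditions on green pollen
#' because red-alone counts are inflated by non-hydrated pollen.
#'
#' @param R3 Green and red fluorescent pollen count.
#' @param R5 Green-alone fluorescent pollen count.
#' @param red_alone Red-alone count.
#' @param none Colourless count.
#' @return An object of class \code{"pollen2_counts"}.
#' @export
pollen2_counts <- function(R3, R5, red_alone = 0, none = 0) {
  structure(list(R3 = chk_count(R3, "R3"), R5 = chk_count(R5, "R5"),
                 red_alone = chk_count(red_alone, "red_alone"),
                 none = chk_count(none, "none")),
            class = "pollen2_counts")
}

#' Selfed-seed fluorescence class counts
#'
#' @param N_GR Seeds fluorescing in both channels.
#' @param N_G Green-alone seeds.
#' @param N_R Red-alone seeds.
#' @param N_N Non-fluorescent seeds.
#' @return An object of class \code{"seed_counts"} with total \code{N_T}.
#' @export
seed_counts <- function(N_GR, N_G, N_R, N_N) {
  x <- list(N_GR = chk_count(N_GR, "N_GR"), N_G = chk_count(N_G, "N_G"),
            N_R = chk_count(N_R, "N_R"), N_N = chk_count(N_N, "N_N"))
  x$N_T <- x$N_GR + x$N_G + x$N_R + x$N_N
  structure(x, class = "seed_counts")
}

#' Tetrad class counts
#'
#' @param PD Parental ditype count.
#' @param NPD Non-parental ditype count.
#' @param T Tetratype count.
#' @return An object of class \code{"tetrad_counts"}.
#' @export
tetrad_counts <- function(PD, NPD, T) {
  structure(list(PD = chk_count(PD, "PD"), NPD = chk_count(NPD, "NPD"),
                 T = chk_count(T, "T")),
            class = "tetrad_counts")
}

#' Three-colour pollen class counts
#'
#' The eight fluorescence classes of a three-reporter (B, Y, R) pollen
#' experiment, named by presence/absence of each colour, e.g. \code{"B-R"}
#' is blue and red but not yellow.
#'
#' @param ... The eight class counts, either as a single named numeric
#'   vector/list or as named arguments.  Names are \code{"BYR"},
#'   \code{"BY-"}, \code{"B-R"}, \code{"B--"}, \code{"-YR"}, \code{"-Y-"},
#'   \code{"--R"}, \code{"---"}; an \code{"N_"} prefix (TSV column style)
#'   is also accepted.
#' @return An object of class \code{"threecolour_counts"} with the eight
#'   counts in \code{$counts} (named vector) and their sum in \code{$N_total}.
#' @examples
#' threecolour_counts(c(BYR = 3550, `BY-` = 440, `B-R` = 110, `B--` = 890,
#'                      `-YR` = 890, `-Y-` = 110, `--R` = 440, `---` = 3550))
#' @export
threecolour_counts <- function(...) {
  args <- list(...)
  v <- if (length(args) == 1 && is.null(names(args)) &&
           length(args[[1]]) == 8) unlist(args[[1]]) else unlist(args)
  names(v) <- sub("^N_", "", names(v))
  canon <- c("BYR", "BY-", "B-R", "B--", "-YR", "-Y-", "--R", "---")
  if (!setequal(names(v), canon) || length(v) != 8)
    stop("three-colour counts need exactly the eight classes: ",
         paste(canon, collapse = " "))
  v <- v[canon]
  for (i in seq_along(v)) chk_count(v[[i]], names(v)[i])
  structure(list(counts = v, N_total = sum(v)), class = "threecolour_counts")
}

new_estimate <- function(cM, se, n, method, ...) {
  structure(list(cM = cM, se = se, n = n, method = method, ...),
            class = "crossover_estimate")
}

#' @export
print.crossover_estimate <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f cM  (%s, n = %d)\n",
              x$cM, x$se, x$method, as.integer(x$n)))
  invisible(x)
}

#' Genetic distance from two-colour pollen counts
#'
#' Estimates the recombination frequency between two linked pollen-expressed
#' transgenes as \code{cM = 100 R5 / (R3 + R5)}: among pollen carrying the
#' green transgene, the proportion that lost the red one.  Conditioning on
#' green pollen makes the estimate immune to the red-alone excess caused by
#' non-hydrated pollen; the estimated total number of recombinant pollen is
#' \code{2 R5}.
#'
#' @param counts A \code{\link{pollen2_counts}} object (or list/one-row data
#'   frame with fields \code{R3}, \code{R5}).
#' @return A \code{"crossover_estimate"} with binomial standard error and
#'   \code{recombinant_total = 2 * R5}.
#' @examples
#' pollen2_cm(pollen2_counts(R3 = 900, R5 = 100))
#' @export
pollen2_cm <- function(counts) {
  if (!inherits(counts, "pollen2_counts"))
    counts <- pollen2_counts(counts$R3, counts$R5,
                             counts$red_alone %||% 0, counts$none %||% 0)
  m <- counts$R3 + counts$R5
  if (m <= 0) stop("R3 + R5 must be positive for estimation")
  p <- counts$R5 / m
  new_estimate(cM = 100 * p, se = 100 * sqrt(p * (1 - p) / m), n = m,
               method = "pollen2", recombinant_total = 2 * counts$R5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genetic distance from selfed-seed counts
#'
#' Inverts the segregation model of a selfed two-colour seed reporter: with
#' recombinant gamete fraction \code{r}, single-colour seed arise at combined
#' frequency \code{(N_G + N_R)/N_T = (1 - (1-r)^2) / 2}, so
#' \code{cM = 100 (1 - sqrt(1 - 2 (N_G + N_R) / N_T))}.  The standard error
#' is propagated from the binomial variance of the single-colour proportion.
#'
#' @param counts A \code{\link{seed_counts}} object (or list/one-row data
#'   frame with fields \code{N_GR}, \code{N_G}, \code{N_R}, \code{N_N}).
#' @return A \code{"crossover_estimate"}.  Estimates above 50 cM trigger a
#'   warning (the single-interval model saturates); a negative radicand is a
#'   domain error.
#' @examples
#' seed_cm(seed_counts(N_GR = 660, N_G = 90, N_R = 90, N_N = 160))
#' @export
seed_cm <- function(counts) {
  if (!inherits(counts, "seed_counts"))
    counts <- seed_counts(counts$N_GR, counts$N_G, counts$N_R, counts$N_N)
  if (counts$N_T <= 0) stop("no seeds counted")
  p <- (counts$N_G + counts$N_R) / counts$N_T
  rad <- 1 - 2 * p
  if (rad < 0)
    stop(sprintf(
      "radicand negative: 2(N_G + N_R) = %d exceeds N_T = %d",
      as.integer(2 * (counts$N_G + counts$N_R)), as.integer(counts$N_T)))
  cM <- 100 * (1 - sqrt(rad))
  if (cM > 50)
    warning("seed cM estimate exceeds 50; single-interval model saturating")
  se <- if (rad > 0)
    100 / sqrt(rad) * sqrt(p * (1 - p) / counts$N_T) else Inf
  new_estimate(cM = cM, se = se, n = counts$N_T, method = "seed")
}

#' Genetic distance from tetrad counts (Perkins formula)
#'
#' \code{cM = 100 (T/2 + 3 NPD) / n} with \code{n = PD + NPD + T}; the
#' non-parental ditypes, which require a four-strand double crossover, are
#' weighted to recover the doubles missed by the tetratype count.  The
#' standard error follows from the multinomial delta method:
#' \code{se = (100 / sqrt(n)) sqrt(t(1-t)/4 + 9 d(1-d) - 3 t d)} with
#' \code{t = T/n}, \code{d = NPD/n}.
#'
#' @param counts A \code{\link{tetrad_counts}} object (or list/one-row data
#'   frame with fields \code{PD}, \code{NPD}, \code{T}).
#' @return A \code{"crossover_estimate"}.
#' @examples
#' tetrad_cm(tetrad_counts(PD = 3976, NPD = 3, T = 742))  # 8.05 +/- 0.29
#' @export
tetrad_cm <- function(counts) {
  if (!inherits(counts, "tetrad_counts"))
    counts <- tetrad_counts(counts$PD, counts$NPD, counts$T)
  n <- counts$PD + counts$NPD + counts$T
  if (n <= 0) stop("PD + NPD + T must be positive")
  t <- counts$T / n
  d <- counts$NPD / n
  new_estimate(cM = 100 * (counts$T / 2 + 3 * counts$NPD) / n,
               se = 100 / sqrt(n) *
                 sqrt(0.25 * t * (1 - t) + 9 * d * (1 - d) - 3 * t * d),
               n = n, method = "tetrad")
}

#' Genetic distances of both intervals from three-colour pollen counts
#'
#' For a B-Y-R reporter triple, interval b (B to Y) counts every class
#' discordant between B and Y as recombinant, and likewise interval c
#' (Y to R): \code{cM_b = 100 (N_-Y- + N_B-R + N_-YR + N_B--) / N_total},
#' \code{cM_c = 100 (N_-Y- + N_B-R + N_BY- + N_--R) / N_total}, each with a
#' binomial standard error.
#'
#' @param counts A \code{\link{threecolour_counts}} object.
#' @return List with elements \code{b} and \code{c}, each a
#'   \code{"crossover_estimate"}.
#' @export
threecolour_cms <- function(counts) {
  if (!inherits(counts, "threecolour_counts"))
    counts <- do.call(threecolour_counts, as.list(counts))
  v <- counts$counts; N <- counts$N_total
  if (N <= 0) stop("N_total must be positive")
  est <- function(num, tag) {
    p <- unname(num) / N
    new_estimate(cM = 100 * p, se = 100 * sqrt(p * (1 - p) / N), n = N,
                 method = tag)
  }
  list(b = est(v["-Y-"] + v["B-R"] + v["-YR"] + v["B--"], "pollen3_b"),
       c = est(v["-Y-"] + v["B-R"] + v["BY-"] + v["--R"], "pollen3_c"))
}

# internal: deepest valley between the two highest modes of log-intensities
valley_cut <- function(x) {
  d <- density(log1p(x))
  s <- diff(sign(diff(d$y)))
  peaks <- which(s == -2) + 1L
  pits <- which(s == 2) + 1L
  if (length(peaks) < 2)
    stop("intensity histogram is unimodal; supply explicit thresholds")
  top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
  between <- pits[pits > top2[1] & pits < top2[2]]
  if (!length(between))
    stop("no valley between intensity modes; supply explicit thresholds")
  expm1(d$x[between[which.min(d$y[between])]])
}

#' Classify seed objects into fluorescence categories
#'
#' Assigns each seed object to one of the four fluorescence categories by
#' comparing its red and green intensities to per-channel cuts.  In automatic
#' mode each cut is placed at the deepest valley of a kernel-smoothed
#' log-intensity histogram, mirroring the threshold placement used when
#' scoring seed images.
#'
#' @param objects Data frame with numeric columns \code{red} and
#'   \code{green} (arbitrary intensity units, >= 0), one row per seed.
#' @param thresholds \code{NULL} for automatic cuts, or a numeric vector
#'   \code{c(red_cut, green_cut)}; a seed is fluorescent in a channel when
#'   its intensity exceeds the cut.
#' @return A \code{\link{seed_counts}} object.
#' @export
classify_seed_objects <- function(objects, thresholds = NULL) {
  if (!all(c("red", "green") %in% names(objects)))
    stop("'objects' needs columns 'red' and 'green'")
  if (nrow(objects) < 1) stop("need at least one seed object")
  if (any(objects$red < 0) || any(objects$green < 0))
    stop("intensities must be >= 0")
  if (is.null(thresholds))
    thresholds <- c(valley_cut(objects$red), valley_cut(objects$green))
  r <- objects$red > thresholds[1]
  g <- objects$green > thresholds[2]
  seed_counts(N_GR = sum(g & r), N_G = sum(g & !r),
              N_R = sum(!g & r), N_N = sum(!g & !r))
}

#' Call the transgene linkage configuration from seed class counts
#'
#' Progeny heterozygous for both seed reporters can carry them in coupling
#' (cis: parental gametes \code{GR} and \code{++}) or in repulsion (trans:
#' parental gametes \code{G+} and \code{+R}); the fluorescent seed classes
#' representing parental and crossover genotypes are reversed between the two
#' configurations.  The call compares the multinomial log-likelihood of the
#' observed four-category counts under each model at a reference recombinant
#' fraction.
#'
#' @param counts A \code{\link{seed_counts}} object.
#' @param r_ref Reference recombinant fraction (default 0.15, typical of the
#'   scored intervals).
#' @param margin Minimum log-likelihood difference required for a call;
#'   below it the result is \code{"ambiguous"}.
#' @return \code{"cis"}, \code{"trans"} or \code{"ambiguous"}, with the
#'   log-likelihood difference (cis minus trans) in attribute \code{"llr"}.
#' @export
call_configuration <- function(counts, r_ref = 0.15, margin = 2) {
  if (!inherits(counts, "seed_counts"))
    counts <- seed_counts(counts$N_GR, counts$N_G, counts$N_R, counts$N_N)
  if (counts$N_T <= 0) stop("no seeds counted")
  probs <- function(r) {          # categories: both, G alone, R alone, none
    q <- (1 - r) / 2
    none <- q^2; single <- 0.25 - q^2
    c(1 - none - 2 * single, single, single, none)
  }
  obs <- c(counts$N_GR, counts$N_G, counts$N_R, counts$N_N)
  ll <- function(p) sum(obs * log(p))
  llr <- ll(probs(r_ref)) - ll(probs(1 - r_ref))   # trans swaps the roles
  call <- if (abs(llr) < margin) "ambiguous" else
    if (llr > 0) "cis" else "trans"
  structure(call, llr = llr)
}

#' Per-kilobase heterozygosity of a region
#'
#' Sum of SNP counts and indel lengths (bp) inside the region, divided by the
#' region length in kb.
#'
#' @param variants Data frame with columns \code{position} (bp),
#'   \code{type} (\code{"SNP"} or \code{"indel"}) and \code{length}
#'   (indel length in bp; ignored for SNPs).
#' @param region Numeric \code{c(start_bp, end_bp)}, inclusive.
#' @return Heterozygosity per kb.
#' @examples
#' v <- data.frame(position = c(100, 200, 5000), type = c("SNP", "indel", "SNP"),
#'                 length = c(NA, 10, NA))
#' interval_heterozygosity(v, c(1, 10000))
#' @export
interval_heterozygosity <- function(variants, region) {
  if (length(region) != 2 || region[2] < region[1])
    stop("'region' must be c(start, end) with start <= end")
  len_kb <- (region[2] - region[1] + 1) / 1000
  if (len_kb <= 0) stop("region length must be positive")
  if (nrow(variants) == 0) return(0)
  inside <- variants$position >= region[1] & variants$position <= region[2]
  v <- variants[inside, , drop = FALSE]
  (sum(v$type == "SNP") +
     sum(as.numeric(v$length[v$type == "indel"]), na.rm = TRUE)) / len_kb
}
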