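# Four-strand meiosis simulator with a gamma-renewal interference model.
#
# Crossovers (chiasmata) are placed on the genetic scale of a bivalent as a
# stationary gamma renewal process (shape nu) with mean inter-event distance
# 0.5 Morgan, optionally mixed with a Poisson "escape" component carrying a
# fraction of events free of interference.  Each crossover is assigned to one
# randomly chosen chromatid of each homolog (no chromatid interference) and
# exchanges the segments distal to its position.

#' Build a simulation model for one chromosome
#'
#' Defines the physical and genetic layout of a simulated chromosome together
#' with the crossover-interference parameters.  The genetic map is piecewise
#' linear in physical position; by default it is uniform with total length
#' \code{map_length_morgans}, and \code{region_modifiers} rescale the local
#' map density (cM per bp) multiplicatively within physical windows.
#'
#' @param chromosome_length_bp Physical chromosome length in bp (>= 2).
#' @param map_length_morgans Total genetic length in Morgans of the base
#'   (unmodified) map.  Ignored when \code{map_points} is supplied.
#' @param nu Interference shape parameter of the gamma renewal process
#'   (> 0).  \code{nu = 1} gives interference-free Poisson placement; larger
#'   values space crossovers more evenly.
#' @param escape_fraction Fraction of crossovers placed by an independent
#'   Poisson process irrespective of \code{nu} (two-pathway mixture), in
#'   \code{[0, 1]}.
#' @param region_modifiers Optional list of \code{c(start_bp, end_bp, factor)}
#'   triples (or a 3-column matrix); the local map density is multiplied by
#'   \code{factor} (>= 0) within each window.
#' @param map_points Optional data frame with columns \code{bp} and
#'   \code{morgan} giving a non-decreasing genetic map directly; overrides
#'   \code{map_length_morgans}.
#' @param rng_seed Optional integer seed used by default in the simulation
#'   functions, making runs reproducible bit-for-bit.
#'
#' @return An object of class \code{"sim_model"}.
#' @examples
#' mod <- sim_model(1e6, map_length_morgans = 0.1, nu = 1, rng_seed = 1)
#' bp_to_morgan(mod, c(1, 5e5, 1e6))
#' @export
sim_model <- function(chromosome_length_bp, map_length_morgans = NULL,
                      nu = 1, escape_fraction = 0, region_modifiers = NULL,
                      map_points = NULL, rng_seed = NULL) {
  L <- as.numeric(chromosome_length_bp)
  if (!is.finite(L) || L < 2)
    stop("'chromosome_length_bp' must be a finite length >= 2 bp")
  if (!is.finite(nu) || nu <= 0)
    stop("'nu' must be a positive number")
  if (!is.finite(escape_fraction) || escape_fraction < 0 || escape_fraction > 1)
    stop("'escape_fraction' must lie in [0, 1]")
  if (!is.null(rng_seed)) {
    rng_seed <- as.integer(rng_seed)
    if (is.na(rng_seed)) stop("'rng_seed' must be an integer")
  }

  if (is.null(map_points)) {
    if (is.null(map_length_morgans) || !is.finite(map_length_morgans) ||
        map_length_morgans < 0)
      stop("'map_length_morgans' must be a finite non-negative number")
    base <- data.frame(bp = c(0, L),
                       morgan = c(0, as.numeric(map_length_morgans)))
  } else {
    base <- data.frame(bp = as.numeric(map_points$bp),
                       morgan = as.numeric(map_points$morgan))
    if (any(!is.finite(base$bp)) || any(!is.finite(base$morgan)))
      stop("non-finite genetic map")
    if (is.unsorted(base$bp, strictly = TRUE))
      stop("'map_points$bp' must be strictly increasing")
    if (is.unsorted(base$morgan))
      stop("genetic map must be non-decreasing")
    if (base$bp[1] > 0) base <- rbind(data.frame(bp = 0, morgan = 0), base)
    if (base$bp[nrow(base)] < L)
      base <- rbind(base, data.frame(bp = L,
                                     morgan = base$morgan[nrow(base)]))
  }

  mods <- NULL
  if (!is.null(region_modifiers)) {
    if (is.list(region_modifiers) && !is.data.frame(region_modifiers))
      mods <- do.call(rbind, region_modifiers)
    else mods <- as.matrix(region_modifiers)
    if (ncol(mods) != 3)
      stop("'region_modifiers' must be (start, end, factor) triples")
    if (any(mods[, 3] < 0) || any(!is.finite(mods)))
      stop("region modifier factors must be finite and >= 0")
    if (any(mods[, 1] >= mods[, 2]))
      stop("region modifier start must be < end")
  }

  # split the map at region boundaries and rescale the per-segment density
  brk <- sort(unique(c(base$bp, pmin(pmax(c(mods[, 1], mods[, 2]), 0), L))))
  m0 <- approx(base$bp, base$morgan, xout = brk, rule = 2)$y
  rate <- diff(m0) / diff(brk)
  if (!is.null(mods)) {
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    for (i in seq_len(nrow(mods)))
      rate <- ifelse(mid > mods[i, 1] & mid < mods[i, 2],
                     rate * mods[i, 3], rate)
  }
  map <- data.frame(bp = brk, morgan = c(0, cumsum(rate * diff(brk))))

  structure(list(chromosome_length_bp = L, map = map, nu = nu,
                 escape_fraction = escape_fraction,
                 region_modifiers = mods, rng_seed = rng_seed),
            class = "sim_model")
}

#' @export
print.sim_model <- function(x, ...) {
  cat(sprintf(
    "sim_model: %.3g bp, %.4g Morgan, nu = %g, escape fraction = %g\n",
    x$chromosome_length_bp, total_morgan(x), x$nu, x$escape_fraction))
  invisible(x)
}

#' Total genetic length of a simulation model, in Morgans
#' @param model A \code{\link{sim_model}}.
#' @return Numeric scalar.
#' @export
total_morgan <- function(model) model$map$morgan[nrow(model$map)]

#' Convert physical to genetic position
#' @param model A \code{\link{sim_model}}.
#' @param bp Physical positions (bp, 1-based).
#' @return Genetic positions in Morgans.
#' @export
bp_to_morgan <- function(model, bp) {
  approx(model$map$bp, model$map$morgan, xout = bp, rule = 2)$y
}

#' Haldane mapping function and its inverse
#'
#' Under interference-free (Poisson) crossover placement a genetic distance of
#' \code{d} Morgans produces a recombinant-chromatid fraction
#' \code{r = (1 - exp(-2 d)) / 2}.  \code{haldane_r} applies the map;
#' \code{haldane_d} inverts it, which is convenient for choosing a simulator
#' map length that targets a given recombinant fraction.
#'
#' @param d Genetic distance in Morgans.
#' @param r Recombinant fraction in \code{[0, 0.5)}.
#' @return Numeric vector.
#' @export
haldane_r <- function(d) (1 - exp(-2 * d)) / 2

#' @rdname haldane_r
#' @export
haldane_d <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("'r' must lie in [0, 0.5)")
  -log(1 - 2 * r) / 2
}

#' Reporter transgene layout
#'
#' Describes the fluorescent transgene (T-DNA) markers of an FTL reporter
#' construct and the scoring modality.  The transgenic parental chromosome
#' (homolog 1 in the simulator) carries all markers in coupling.
#'
#' @param markers Data frame with columns \code{name}, \code{pos_bp}
#'   (1-based, strictly increasing) and \code{colour} (one of
#'   \code{"G","R","Y","B","C"}).
#' @param modality One of \code{"pollen2"}, \code{"pollen3"}, \code{"seed"},
#'   \code{"tetrad"}.  Two markers are required for \code{pollen2} and
#'   \code{seed}, three for \code{pollen3}; \code{tetrad} accepts two markers
#'   (one interval) or three (two adjacent intervals).
#' @return An object of class \code{"reporter_layout"}.
#' @examples
#' reporter_layout(data.frame(name = c("CFP", "YFP", "dsRed"),
#'                            pos_bp = c(498916, 3126994, 4319513),
#'                            colour = c("B", "Y", "R")), "pollen3")
#' @export
reporter_layout <- function(markers, modality = c("pollen2", "pollen3",
                                                  "seed", "tetrad")) {
  modality <- match.arg(modality)
  markers <- as.data.frame(markers)
  need <- c("name", "pos_bp", "colour")
  if (!all(need %in% names(markers)))
    stop("'markers' needs columns: ", paste(need, collapse = ", "))
  if (is.unsorted(markers$pos_bp, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  if (!all(markers$colour %in% c("G", "R", "Y", "B", "C")))
    stop("marker colours must be in {G, R, Y, B, C}")
  k <- nrow(markers)
  ok <- switch(modality, pollen2 = k == 2, seed = k == 2,
               pollen3 = k == 3, tetrad = k %in% c(2, 3))
  if (!ok) stop("modality '", modality, "' does not take ", k, " markers")
  structure(list(markers = markers, modality = modality),
            class = "reporter_layout")
}

# internal: run the gamma-renewal + escape placement for n meioses.
# Returns events sorted by (meiosis, pos); pos in Morgans over (0, M].
place_crossovers <- function(model, n) {
  M <- total_morgan(model)
  e <- model$escape_fraction
  mei <- integer(0); pos <- numeric(0)

  lam_i <- 2 * (1 - e)                   # chiasmata per Morgan, interfering
  if (M > 0 && lam_i > 0) {
    nu <- model$nu
    b <- nu * lam_i                      # gamma rate: mean spacing 1/lam_i
    B <- 10 / lam_i                      # burn-in to reach stationarity
    target <- B + M
    mu_k <- lam_i * target
    K <- ceiling(mu_k + 8 * sqrt(mu_k / min(nu, 1)) + 10)
    gaps <- matrix(rgamma(n * K, shape = nu, rate = b), n, K)
    for (j in 2:K) gaps[, j] <- gaps[, j] + gaps[, j - 1L]
    while (min(gaps[, ncol(gaps)]) < target) {   # rare tail extension
      add <- matrix(rgamma(n * 8, shape = nu, rate = b), n, 8)
      add[, 1] <- add[, 1] + gaps[, ncol(gaps)]
      for (j in 2:8) add[, j] <- add[, j] + add[, j - 1L]
      gaps <- cbind(gaps, add)
    }
    keep <- gaps > B & gaps <= target
    mei <- row(gaps)[keep]
    pos <- gaps[keep] - B
  }
  lam_e <- 2 * e                         # escape (Poisson) component
  if (M > 0 && lam_e > 0) {
    ke <- rpois(n, lam_e * M)
    mei <- c(mei, rep.int(seq_len(n), ke))
    pos <- c(pos, runif(sum(ke)) * M)
  }
  o <- order(mei, pos)
  nev <- length(o)
  data.frame(meiosis = mei[o], pos = pos[o],
             sa = sample(1:2, nev, replace = TRUE),
             sb = sample(3:4, nev, replace = TRUE))
}

#' Simulate meioses
#'
#' Draws crossover positions for \code{n} four-chromatid meioses from the
#' model's stationary gamma-renewal process (shape \code{nu}, mean
#' inter-chiasma distance 0.5 Morgan on the bivalent), mixed with a Poisson
#' escape component, and assigns each crossover to one random chromatid of
#' each homolog.
#'
#' @param model A \code{\link{sim_model}}.
#' @param n Number of meioses (>= 1).
#' @param seed Integer seed; defaults to the model's \code{rng_seed}.
#' @return An object of class \code{"ftl_meioses"}: a list with \code{events}
#'   (data frame of \code{meiosis}, \code{pos} in Morgans, \code{pos_bp},
#'   chromatid slots \code{sa} in \{1,2\} and \code{sb} in \{3,4\}),
#'   \code{n} and \code{model}.
#' @examples
#' mod <- sim_model(1e6, 0.05, rng_seed = 1)
#' sim <- simulate_meioses(mod, 100)
#' head(sim$events)
#' @export
simulate_meioses <- function(model, n, seed = model$rng_seed) {
  if (!inherits(model, "sim_model")) stop("'model' must be a sim_model")
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("'n' must be a positive count")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  ev <- place_crossovers(model, n)
  ev$pos_bp <- approx(model$map$morgan, model$map$bp, xout = ev$pos,
                      rule = 2, ties = "ordered")$y
  structure(list(events = ev, n = n, model = model), class = "ftl_meioses")
}

#' Chromatid origins at a genetic position
#'
#' Traces each of the four gamete molecules (identified by the original
#' chromatid carrying its centromere, at the left end) through the meiosis'
#' crossovers in position order: at every exchange involving the strand a
#' molecule is currently following, the molecule switches to the partner
#' strand.  Because each crossover involves the followed strand with
#' probability 1/2 under random pairing, this realises interference-free
#' thinning at the chromatid level (no chromatid interference).
#'
#' @param sim An \code{"ftl_meioses"} object.
#' @param at_morgan Genetic position (Morgans).
#' @return An \code{n x 4} logical matrix; \code{FALSE} = homolog 1 (the
#'   transgenic parent), \code{TRUE} = homolog 2.
#' @export
chromatid_origins <- function(sim, at_morgan) {
  ev <- sim$events[sim$events$pos < at_morgan, , drop = FALSE]
  cur <- matrix(rep(1:4, each = sim$n), sim$n, 4)   # strand being followed
  if (nrow(ev)) {
    rk <- stats::ave(ev$pos, ev$meiosis, FUN = seq_along)
    for (k in seq_len(max(rk))) {
      i <- which(rk == k)
      m <- ev$meiosis[i]; a <- ev$sa[i]; b <- ev$sb[i]
      for (j in 1:4) {
        idx <- cbind(m, j)
        cj <- cur[idx]
        isa <- cj == a; isb <- cj == b
        cj[isa] <- b[isa]; cj[isb] <- a[isb]
        cur[idx] <- cj
      }
    }
  }
  cur > 2L
}

# internal: origins at each marker of a layout -> list of n x 4 matrices
marker_origins <- function(sim, layout) {
  pos <- bp_to_morgan(sim$model, layout$markers$pos_bp)
  lapply(pos, function(p) chromatid_origins(sim, p))
}

# internal: tetrad PD/NPD/T classification from origins at two markers
classify_tetrads <- function(S1, S2) {
  nrec <- rowSums(S1 != S2)          # recombinant chromatids: 0, 2 or 4
  c(PD = sum(nrec == 0), NPD = sum(nrec == 4), T = sum(nrec == 2))
}

#' Simulate tetrad counts for one interval
#'
#' Runs \code{n} meioses and classifies each four-chromatid bundle into
#' parental ditype, non-parental ditype or tetratype by co-segregation of the
#' two markers.
#'
#' @param model A \code{\link{sim_model}}.
#' @param layout A two-marker \code{\link{reporter_layout}} with modality
#'   \code{"tetrad"}.
#' @param n Number of tetrads.
#' @param seed Integer seed; defaults to the model's \code{rng_seed}.
#' @return A \code{\link{tetrad_counts}} object with \code{PD + NPD + T = n}.
#' @examples
#' mod <- sim_model(1e6, 0.08, rng_seed = 1)
#' lay <- reporter_layout(data.frame(name = c("G", "R"),
#'                                   pos_bp = c(1, 1e6),
#'                                   colour = c("G", "R")), "tetrad")
#' simulate_tetrad_counts(mod, lay, 1000)
#' @export
simulate_tetrad_counts <- function(model, layout, n, seed = model$rng_seed) {
  if (layout$modality != "tetrad" || nrow(layout$markers) != 2)
    stop("'layout' must be a two-marker tetrad layout")
  sim <- simulate_meioses(model, n, seed = seed)
  S <- marker_origins(sim, layout)
  k <- classify_tetrads(S[[1]], S[[2]])
  tetrad_counts(k["PD"], k["NPD"], k["T"])
}

#' Simulate per-tetrad interval calls for two adjacent intervals
#'
#' For a three-marker tetrad layout, classifies every tetrad in both flanking
#' intervals, the input expected by
#' \code{\link{tetrad_adjacent_interference}}.
#'
#' @inheritParams simulate_tetrad_counts
#' @param layout A three-marker \code{\link{reporter_layout}} with modality
#'   \code{"tetrad"}.
#' @return Data frame with columns \code{tetrad_id}, \code{class_b},
#'   \code{class_c} (each \code{"PD"}, \code{"NPD"} or \code{"T"}).
#' @export
simulate_tetrad_calls <- function(model, layout, n, seed = model$rng_seed) {
  if (layout$modality != "tetrad" || nrow(layout$markers) != 3)
    stop("'layout' must be a three-marker tetrad layout")
  sim <- simulate_meioses(model, n, seed = seed)
  S <- marker_origins(sim, layout)
  cls <- function(Sa, Sb) {
    nrec <- rowSums(Sa != Sb)
    c("PD", "T", "NPD")[match(nrec, c(0, 2, 4))]
  }
  data.frame(tetrad_id = seq_len(n),
             class_b = cls(S[[1]], S[[2]]),
             class_c = cls(S[[2]], S[[3]]))
}

#' Simulate two-colour pollen class counts
#'
#' Samples one random chromatid per meiosis as a pollen gamete and scores the
#' presence of the green- and red-channel transgenes.  A fraction of extra
#' objects scored as red-alone can be added, emulating the excess of
#' red-alone events contributed by non-hydrated pollen in flow cytometry.
#'
#' @param model A \code{\link{sim_model}}.
#' @param layout A two-marker \code{\link{reporter_layout}} with modality
#'   \code{"pollen2"}; the first marker is read in the green channel, the
#'   second in the red channel.
#' @param n Number of gametes (one per meiosis).
#' @param artifact_fraction Expected number of artifactual red-alone objects
#'   as a fraction of \code{n}, in \code{[0, 1)}.
#' @param seed Integer seed; defaults to the model's \code{rng_seed}.
#' @return A \code{\link{pollen2_counts}} object; the four classes sum to the
#'   number of scored objects (\code{n} plus artifacts).
#' @export
simulate_pollen_two_colour <- function(model, layout, n,
                                       artifact_fraction = 0,
                                       seed = model$rng_seed) {
  if (layout$modality != "pollen2")
    stop("'layout' must have modality 'pollen2'")
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    stop("'artifact_fraction' must lie in [0, 1)")
  sim <- simulate_meioses(model, n, seed = seed)
  S <- marker_origins(sim, layout)
  ch <- sample(4L, n, replace = TRUE)
  idx <- cbind(seq_len(n), ch)
  g <- !S[[1]][idx]                       # carries green transgene
  r <- !S[[2]][idx]                       # carries red transgene
  n_art <- rbinom(1, n, artifact_fraction)
  pollen2_counts(R3 = sum(g & r), R5 = sum(g & !r),
                 red_alone = sum(!g & r) + n_art, none = sum(!g & !r))
}

#' Simulate three-colour pollen class counts
#'
#' Samples one random chromatid per meiosis and scores presence of the blue,
#' yellow and red transgenes, yielding the eight fluorescence classes of a
#' three-reporter interval pair.
#'
#' @param model A \code{\link{sim_model}}.
#' @param layout A three-marker \code{\link{reporter_layout}} with modality
#'   \code{"pollen3"}, markers ordered B, Y, R along the chromosome.
#' @param n Number of gametes.
#' @param seed Integer seed; defaults to the model's \code{rng_seed}.
#' @return A \code{\link{threecolour_counts}} object whose eight classes sum
#'   to \code{n}.
#' @export
simulate_pollen_three_colour <- function(model, layout, n,
                                         seed = model$rng_seed) {
  if (layout$modality != "pollen3")
    stop("'layout' must have modality 'pollen3'")
  sim <- simulate_meioses(model, n, seed = seed)
  S <- marker_origins(sim, layout)
  ch <- sample(4L, n, replace = TRUE)
  idx <- cbind(seq_len(n), ch)
  b <- !S[[1]][idx]; y <- !S[[2]][idx]; r <- !S[[3]][idx]
  code <- 4L * b + 2L * y + r            # 7 = BYR ... 0 = none
  k <- tabulate(code + 1L, nbins = 8L)
  threecolour_counts(BYR = k[8], `BY-` = k[7], `B-R` = k[6], `B--` = k[5],
                     `-YR` = k[4], `-Y-` = k[3], `--R` = k[2], `---` = k[1])
}

#' Simulate selfed-seed fluorescence class counts
#'
#' Models self-fertilization of a plant heterozygous for linked green and red
#' seed-expressed transgenes in coupling: gametes are parental
#' (\code{GR} or \code{++}, probability \code{(1-r)/2} each) or recombinant
#' (\code{G+} or \code{+R}, probability \code{r/2} each); a seed unites two
#' independent gametes and its fluorescence category follows from transgene
#' presence.  Optionally draws per-seed intensities by transgene copy number.
#'
#' @param r Recombinant gamete fraction in \code{[0, 1]}.
#' @param n Number of seeds.
#' @param intensity_params Optional list with elements \code{base}
#'   (autofluorescence level of a zero-copy seed), \code{fold} (intensity of
#'   a one-copy seed relative to background; two copies fluoresce twice as
#'   brightly, so the 1- and 2-copy groups overlap far more than either does
#'   with the background) and \code{sdlog} (lognormal scatter); when
#'   supplied, a per-seed object table of red/green intensities is returned
#'   as well.
#' @param seed Integer seed.
#' @return A list with \code{counts} (a \code{\link{seed_counts}} object) and
#'   \code{objects} (data frame of per-seed \code{red}, \code{green}
#'   intensities, or \code{NULL}).
#' @examples
#' simulate_selfed_seed(0.2, 1000, seed = 1)$counts
#' @export
simulate_selfed_seed <- function(r, n, intensity_params = NULL, seed = NULL) {
  if (!is.finite(r) || r < 0 || r > 1) stop("'r' must lie in [0, 1]")
  if (n < 1) stop("'n' must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  # gamete types: 1 = GR, 2 = ++, 3 = G+, 4 = +R
  pg <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  g1 <- sample(4L, n, replace = TRUE, prob = pg)
  g2 <- sample(4L, n, replace = TRUE, prob = pg)
  hasG <- function(g) g == 1L | g == 3L
  hasR <- function(g) g == 1L | g == 4L
  cg <- hasG(g1) + hasG(g2)              # green copy number 0..2
  cr <- hasR(g1) + hasR(g2)
  counts <- seed_counts(N_GR = sum(cg > 0 & cr > 0),
                        N_G  = sum(cg > 0 & cr == 0),
                        N_R  = sum(cg == 0 & cr > 0),
                        N_N  = sum(cg == 0 & cr == 0))
  objects <- NULL
  if (!is.null(intensity_params)) {
    ip <- intensity_params
    base <- if (is.null(ip$base)) 30 else ip$base
    fold <- if (is.null(ip$fold)) 8 else ip$fold
    sdlog <- if (is.null(ip$sdlog)) 0.25 else ip$sdlog
    level <- function(copies) log(base) + log(ifelse(copies == 0, 1,
                                                     fold * copies))
    objects <- data.frame(red = rlnorm(n, meanlog = level(cr), sdlog = sdlog),
                          green = rlnorm(n, meanlog = level(cg),
                                         sdlog = sdlog))
  }
  list(counts = counts, objects = objects)
}

#' Simulate an F2 reporter population with an optional cis effect
#'
#' Generates F2 individuals from selfing of an F1 that is heterozygous
#' genome-wide and carries the two linked seed reporters in coupling on one
#' chromosome.  Each individual is formed from two independently simulated
#' gametes; only individuals heterozygous for the intact reporter chromosome
#' over a non-transgenic chromosome are retained (the configuration scored in
#' practice).  Marker genotypes follow 1:2:1 expectations away from the
#' selected region.  Each retained individual's reporter-interval genetic
#' length is multiplied by \code{cis_effect(genotypes)} and its seed counts
#' are drawn at the resulting recombinant fraction.
#'
#' Markers on chromosomes other than the reporter chromosome are generated
#' from independent meioses with a uniform genetic map of
#' \code{background_cm_per_mb}.
#'
#' @param model A \code{\link{sim_model}} for the reporter chromosome.
#' @param layout A two-marker \code{"seed"} \code{\link{reporter_layout}}
#'   giving the reporter T-DNA positions on the reporter chromosome.
#' @param markers Data frame with columns \code{chrom} and \code{pos_bp};
#'   markers with \code{chrom == reporter_chrom} are linked to the reporter.
#' @param reporter_chrom Chromosome label of the reporter (default the first
#'   \code{markers$chrom} value).
#' @param cis_effect \code{NULL}, or a function taking one individual's named
#'   genotype vector (values \code{"HET"}, \code{"HOM_REF"},
#'   \code{"HOM_ALT"}) and returning a multiplicative factor for the reporter
#'   interval genetic length.
#' @param n_individuals Number of retained F2 individuals (>= 1).
#' @param seeds_per_individual Seeds scored per individual.
#' @param background_cm_per_mb Map density used for non-reporter chromosomes.
#' @param seed Integer seed; defaults to the model's \code{rng_seed}.
#' @return A list of class \code{"ftl_f2"} with \code{pheno} (data frame:
#'   \code{id}, seed class counts, \code{cM}) and \code{geno} (character
#'   matrix individuals x markers), plus \code{markers}.
#' @export
simulate_f2_population <- function(model, layout, markers,
                                   reporter_chrom = NULL, cis_effect = NULL,
                                   n_individuals, seeds_per_individual = 2000,
                                   background_cm_per_mb = 4,
                                   seed = model$rng_seed) {
  if (layout$modality != "seed")
    stop("'layout' must be a two-marker seed layout")
  markers <- as.data.frame(markers)
  if (nrow(markers) == 0) stop("empty marker list")
  if (!all(c("chrom", "pos_bp") %in% names(markers)))
    stop("'markers' needs columns 'chrom' and 'pos_bp'")
  if (length(n_individuals) != 1 || !is.finite(n_individuals) ||
      n_individuals < 1)
    stop("'n_individuals' must be a positive count")
  n_individuals <- as.integer(n_individuals)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reporter_chrom)) reporter_chrom <- markers$chrom[1]

  rep_pos <- bp_to_morgan(model, layout$markers$pos_bp)
  d_base <- diff(rep_pos)
  on_rep <- markers$chrom == reporter_chrom
  mk_rep_morgan <- bp_to_morgan(model, markers$pos_bp[on_rep])

  # draw gametes in batches until enough reporter-heterozygous individuals
  geno_rep <- NULL
  want <- n_individuals
  while (want > 0) {
    nb <- max(2L * (want + 10L), 50L)    # gamete pairs per batch
    sim1 <- simulate_meioses(model, nb, seed = NULL)
    sim2 <- simulate_meioses(model, nb, seed = NULL)
    pick <- function(sim, pos) {
      ch <- sample(4L, nb, replace = TRUE)
      vapply(pos, function(p)
        chromatid_origins(sim, p)[cbind(seq_len(nb), ch)], logical(nb))
    }
    qpos <- c(rep_pos, mk_rep_morgan)
    h1 <- pick(sim1, qpos); h2 <- pick(sim2, qpos)
    if (nb == 1) { h1 <- matrix(h1, 1); h2 <- matrix(h2, 1) }
    # retain RG/++: one gamete carries both reporters, the other neither
    keep <- (!h1[, 1] & !h1[, 2] & h2[, 1] & h2[, 2]) |
            (!h2[, 1] & !h2[, 2] & h1[, 1] & h1[, 2])
    keep <- which(keep)[seq_len(min(sum(keep), want))]
    if (length(keep)) {
      gm <- matrix("HET", length(keep), length(mk_rep_morgan))
      if (length(mk_rep_morgan)) {
        a <- h1[keep, -(1:2), drop = FALSE]
        b <- h2[keep, -(1:2), drop = FALSE]
        gm[!a & !b] <- "HOM_REF"
        gm[a & b] <- "HOM_ALT"
      }
      geno_rep <- rbind(geno_rep, gm)
      want <- want - length(keep)
    }
  }

  geno <- matrix(NA_character_, n_individuals, nrow(markers))
  colnames(geno) <- paste0(markers$chrom, "_",
                           format(markers$pos_bp, scientific = FALSE,
                                  trim = TRUE))
  if (any(on_rep)) geno[, on_rep] <- geno_rep

  for (chr in setdiff(unique(markers$chrom), reporter_chrom)) {
    j <- which(markers$chrom == chr)
    Lc <- max(markers$pos_bp[j]) * 1.05
    mc <- sim_model(Lc, map_length_morgans =
                      Lc / 1e6 * background_cm_per_mb / 100,
                    nu = model$nu, escape_fraction = model$escape_fraction)
    pos <- bp_to_morgan(mc, markers$pos_bp[j])
    for (side in 1:2) {
      simc <- simulate_meioses(mc, n_individuals, seed = NULL)
      ch <- sample(4L, n_individuals, replace = TRUE)
      hc <- vapply(pos, function(p)
        chromatid_origins(simc, p)[cbind(seq_len(n_individuals), ch)],
        logical(n_individuals))
      if (n_individuals == 1) hc <- matrix(hc, 1)
      if (side == 1) h1c <- hc else h2c <- hc
    }
    gm <- matrix("HET", n_individuals, length(j))
    gm[!h1c & !h2c] <- "HOM_REF"
    gm[h1c & h2c] <- "HOM_ALT"
    geno[, j] <- gm
  }

  pheno <- data.frame(id = sprintf("F2_%04d", seq_len(n_individuals)),
                      N_GR = NA_integer_, N_G = NA_integer_,
                      N_R = NA_integer_, N_N = NA_integer_,
                      cM = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n_individuals)) {
    f <- if (is.null(cis_effect)) 1 else cis_effect(geno[i, ])
    r_eff <- min(max(haldane_r(f * d_base), 0), 0.999)
    cc <- simulate_selfed_seed(r_eff, seeds_per_individual)$counts
    pheno[i, c("N_GR", "N_G", "N_R", "N_N")] <-
      c(cc$N_GR, cc$N_G, cc$N_R, cc$N_N)
    pheno$cM[i] <- seed_cm(cc)$cM
  }
  rownames(geno) <- pheno$id
  structure(list(pheno = pheno, geno = geno, markers = markers),
            class = "ftl_f2")
}
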