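# Tabular input/output: validated count tables per scoring modality,
# report writing with a run manifest, and access to the bundled example
# tables.

modality_schema <- list(
  pollen2 = c("R3", "R5", "red_alone", "none"),
  seed = c("N_GR", "N_G", "N_R", "N_N"),
  tetrad = c("PD", "NPD", "T"),
  pollen3 = c("N_BYR", "N_BY-", "N_B-R", "N_B--",
              "N_-YR", "N_-Y-", "N_--R", "N_---"))

#' Read and validate a count table
#'
#' Reads a tab-separated count table for one scoring modality, checking the
#' header against the modality's schema and every cell for a non-negative
#' integer.  Identifier columns (any columns before the count columns, e.g.
#' \code{id}, \code{interval}, \code{background}) are carried through.
#'
#' @param path Path to a TSV file with one row per biological replicate.
#' @param modality One of \code{"pollen2"}, \code{"seed"}, \code{"tetrad"},
#'   \code{"pollen3"}.
#' @return Validated data frame; the modality is recorded in attribute
#'   \code{"modality"}.
#' @export
read_count_table <- function(path, modality = names(modality_schema)) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  schema <- modality_schema[[modality]]
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop("missing column(s) for modality '", modality, "': ",
         paste(missing, collapse = ", "))
  for (cn in schema) {
    x <- df[[cn]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad))
      stop("column '", cn, "': invalid count at row ",
           paste(bad, collapse = ", "),
           " (counts must be non-negative integers)")
  }
  attr(df, "modality") <- modality
  df
}

#' Estimate genetic distance for every row of a count table
#'
#' Applies the modality's estimator to each replicate row of a validated
#' count table.
#'
#' @param df Data frame from \code{\link{read_count_table}} (or of the same
#'   shape).
#' @param modality Scoring modality; defaults to the table's
#'   \code{"modality"} attribute.
#' @return Data frame with columns \code{id}, \code{method}, \code{cM},
#'   \code{se}, \code{n} (two rows per replicate for \code{pollen3}, one
#'   otherwise).
#' @export
estimate_cm <- function(df, modality = attr(df, "modality")) {
  if (is.null(modality)) stop("specify 'modality'")
  ids <- if ("id" %in% names(df)) as.character(df$id)
         else as.character(seq_len(nrow(df)))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    ests <- switch(modality,
      pollen2 = list(pollen2_cm(pollen2_counts(r$R3, r$R5, r$red_alone,
                                               r$none))),
      seed = list(seed_cm(seed_counts(r$N_GR, r$N_G, r$N_R, r$N_N))),
      tetrad = list(tetrad_cm(tetrad_counts(r$PD, r$NPD, r$T))),
      pollen3 = unname(threecolour_cms(
        do.call(threecolour_counts,
                list(unlist(r[modality_schema$pollen3]))))))
    do.call(rbind, lapply(ests, function(e)
      data.frame(id = ids[i], method = e$method, cM = e$cM, se = e$se,
                 n = e$n, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: polynomial rolling hash of a deparsed object, for run manifests
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write an analysis report
#'
#' Writes results as TSV (stable column order; numeric columns at full
#' precision, with a display-rounded \code{cM_2dp} column added when a
#' \code{cM} column is present) or as JSON including a run manifest
#' (package version, seed, configuration and its hash).  Output is
#' byte-identical for identical input.
#'
#' @param results Data frame of results.
#' @param path Output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param seed Seed recorded in the JSON manifest.
#' @param config Arbitrary configuration recorded in the JSON manifest.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         seed = NULL, config = NULL) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if ("cM" %in% names(results)) results$cM_2dp <- round(results$cM, 2)
  if (format == "tsv") {
    con <- file(path, open = "wb")         # fixed EOL for byte-identity
    on.exit(close(con))
    write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
  } else {
    payload <- list(
      manifest = list(package = "ftlrec",
                      version = as.character(packageVersion("ftlrec")),
                      seed = seed, config = config,
                      config_hash = config_hash(config)),
      results = results)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Path to a bundled example table
#'
#' The package ships small plain-text example tables: tetrad class counts
#' and adjacent-crossover stratum estimates for eight FTL intervals scored in
#' Col/Col and Col/Ler backgrounds, hot/cold-quartile marker genotype counts
#' for three F2 reporter populations, and per-cross F1 genetic distances for
#' five intervals.
#'
#' @param file File name under \code{extdata}; with no argument, lists the
#'   available files.
#' @return Full path, or a vector of file names.
#' @examples
#' ftl_example()
#' read_count_table(ftl_example("tetrad_counts.tsv"), "tetrad")
#' @export
ftl_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "ftlrec")))
  p <- system.file("extdata", file, package = "ftlrec")
  if (p == "") stop("no such example file: ", file)
  p
}
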