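#' Column dialect of a vendor-style cluster CSV export
#'
#' HDX vendor exports (e.g. DynamX cluster files) differ in column naming
#' and exposure units; the dialect object maps the required logical fields
#' to actual column headers so files can be ingested without code changes.
#'
#' @param state,sequence,start,end,exposure,replicate,deuterium Column
#'   headers holding each field.
#' @param exposure_unit `"s"` or `"min"`; exposures are normalized to
#'   seconds on read.
#'
#' @return List of class `cluster_csv_dialect`.
#' @export
cluster_csv_dialect <- function(state = "State", sequence = "Sequence",
                                start = "Start", end = "End",
                                exposure = "Exposure", replicate = "Replicate",
                                deuterium = "Uptake",
                                exposure_unit = c("s", "min")) {
  exposure_unit <- match.arg(exposure_unit)
  structure(list(state = state, sequence = sequence, start = start,
                 end = end, exposure = exposure, replicate = replicate,
                 deuterium = deuterium, exposure_unit = exposure_unit),
            class = "cluster_csv_dialect")
}

#' Read a peptide-level uptake table from a cluster CSV file
#'
#' @param path CSV file path.
#' @param dialect A [cluster_csv_dialect()] describing the columns.
#'
#' @return Uptake table tibble (`state`, `peptide_id`, `sequence`, `start`,
#'   `end`, `time`, `replicate`, `deuterium`); exposure converted to
#'   seconds. Rows whose numeric fields fail to parse are skipped, with one
#'   message per skipped row naming its line number. `peptide_id` is
#'   assigned per distinct `(sequence, start, end)` in N- to C-order.
#' @export
read_uptake_csv <- function(path, dialect = cluster_csv_dialect()) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- unlist(dialect[c("state", "sequence", "start", "end", "exposure",
                           "replicate", "deuterium")])
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("cluster CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    state = raw[[dialect$state]],
    sequence = toupper(raw[[dialect$sequence]]),
    start = suppressWarnings(as.integer(raw[[dialect$start]])),
    end = suppressWarnings(as.integer(raw[[dialect$end]])),
    time = suppressWarnings(as.numeric(raw[[dialect$exposure]])),
    replicate = suppressWarnings(as.integer(raw[[dialect$replicate]])),
    deuterium = suppressWarnings(as.numeric(raw[[dialect$deuterium]]))
  )
  bad <- !stats::complete.cases(out)
  if (any(bad)) {
    for (ln in which(bad)) {
      message("skipping unparsable row at line ", ln + 1L, " of ",
              basename(path))
    }
    out <- out[!bad, ]
  }
  if (dialect$exposure_unit == "min") out$time <- out$time * 60
  peps <- dplyr::arrange(
    dplyr::distinct(out, .data$sequence, .data$start, .data$end),
    .data$start, .data$end)
  peps$peptide_id <- sprintf("p%03d", seq_len(nrow(peps)))
  out <- dplyr::left_join(out, peps, by = c("sequence", "start", "end"))
  dplyr::select(out, "state", "peptide_id", "sequence", "start", "end",
                "time", "replicate", "deuterium")
}

#' Write an uptake table as a cluster CSV file
#'
#' @param table Uptake table tibble.
#' @param path Output path.
#' @inheritParams read_uptake_csv
#' @return `path`, invisibly.
#' @export
write_uptake_csv <- function(table, path, dialect = cluster_csv_dialect()) {
  time <- if (dialect$exposure_unit == "min") table$time / 60 else table$time
  out <- stats::setNames(
    tibble::tibble(table$state, table$sequence, table$start, table$end,
                   time, table$replicate, table$deuterium),
    unlist(dialect[c("state", "sequence", "start", "end", "exposure",
                     "replicate", "deuterium")]))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a two-column NMR trace
#'
#' Plain-text traces: two whitespace-separated columns (ppm, intensity),
#' no header. On read the axis is sorted to descending ppm.
#'
#' @param path File path.
#' @return [read_nmr_trace()]: tibble with `ppm`, `intensity`.
#' @export
read_nmr_trace <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_table(path, col_names = c("ppm", "intensity"),
                           col_types = "dd", progress = FALSE)
  dplyr::arrange(raw, dplyr::desc(.data$ppm))
}

#' @rdname read_nmr_trace
#' @param trace Trace tibble (`ppm`, `intensity`).
#' @return [write_nmr_trace()]: `path`, invisibly.
#' @export
write_nmr_trace <- function(trace, path) {
  stopifnot(all(c("ppm", "intensity") %in% names(trace)))
  readr::write_delim(trace[c("ppm", "intensity")], path, delim = " ",
                     col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return Single amino-acid string.
#' @export
read_protein_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path, progress = FALSE)
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("not a FASTA file: ", path, call. = FALSE)
  from <- headers[1] + 1L
  to <- if (length(headers) > 1) headers[2] - 1L else length(lines)
  seqc <- toupper(gsub("\\s", "", paste(lines[from:to], collapse = "")))
  check_sequence(seqc)
  seqc
}

#' Write residue annotations as TSV
#'
#' @param annotations Tibble from [consolidate_residues()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_annotations <- function(annotations, path) {
  out <- tibble::tibble(
    residue = annotations$residue,
    category = as.character(annotations$category),
    peptides = vapply(annotations$supporting_peptides,
                      paste, character(1), collapse = ","))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized top-level keys: `thresholds` (`modest`, `major`), `domains`
#' (label: `[start, end]`), `nmr` (`centers`, `fwhm`), `times` (labeling
#' durations, s), `seed`. Missing keys fall back to package defaults; all
#' seeds must be explicit integers when given.
#'
#' @param path YAML file path.
#' @return List with elements `thresholds` ([hdx_thresholds()]), `domains`
#'   (tibble), `nmr` (list), `times` (numeric), `seed` (integer).
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  thr <- if (!is.null(cfg$thresholds)) {
    hdx_thresholds(modest = cfg$thresholds$modest, major = cfg$thresholds$major)
  } else hdx_thresholds()
  domains <- if (!is.null(cfg$domains)) {
    tibble::tibble(
      domain = names(cfg$domains),
      start = unname(vapply(cfg$domains, function(x) as.integer(x[[1]]),
                            integer(1))),
      end = unname(vapply(cfg$domains, function(x) as.integer(x[[2]]),
                          integer(1))))
  } else btk_domains()
  nmr <- list(centers = c(10.10, 9.90), fwhm = 0.03)
  if (!is.null(cfg$nmr)) {
    if (!is.null(cfg$nmr$centers)) nmr$centers <- as.numeric(cfg$nmr$centers)
    if (!is.null(cfg$nmr$fwhm)) nmr$fwhm <- as.numeric(cfg$nmr$fwhm)
  }
  times <- if (!is.null(cfg$times)) as.numeric(cfg$times)
           else c(10, 60, 600, 3600, 14400)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  list(thresholds = thr, domains = domains, nmr = nmr, times = times,
       seed = seed)
}
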