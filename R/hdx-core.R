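#' Relative deuterium level of a peptide
#'
#' The relative deuterium level is the labeled centroid mass minus the
#' undeuterated-control centroid mass. No back-exchange correction is
#' applied, so values are relative, not absolute, deuterium counts. Small
#' negative values (down to -0.5 Da) are retained as measurement noise with
#' a warning; values below -0.5 Da are flagged as suspect but still
#' returned.
#'
#' @param centroid_labeled Centroid mass of the deuterium-labeled peptide, Da.
#' @param centroid_undeuterated Centroid mass of the undeuterated control, Da.
#'
#' @return Deuterium level in Da (vectorized).
#' @export
#' @examples
#' relative_deuterium(1505.3, 1502.1)  # 3.2 Da
relative_deuterium <- function(centroid_labeled, centroid_undeuterated) {
  stopifnot(all(is.finite(centroid_labeled)),
            all(is.finite(centroid_undeuterated)))
  d <- centroid_labeled - centroid_undeuterated
  if (any(d < -0.5)) {
    warning(sum(d < -0.5), " record(s) below -0.5 Da flagged as suspect",
            call. = FALSE)
  } else if (any(d < 0)) {
    warning(sum(d < 0), " small negative deuterium value(s) retained",
            call. = FALSE)
  }
  d
}

#' Maximum exchangeable amides of a peptide
#'
#' Standard HDX-MS bookkeeping: the peptide's first two residues are
#' excluded (their amides back-exchange too fast to retain label) as are
#' prolines from position 3 on (no backbone amide NH), giving
#' `length - 2 - n_prolines(positions 3..end)`.
#'
#' @param sequence Peptide amino-acid string (vectorized).
#'
#' @return Integer count(s); 0 with a warning for peptides shorter than 3.
#' @export
#' @examples
#' max_exchangeable("ANSLYK")  # 4
#' max_exchangeable("ANPLPK")  # 2
max_exchangeable <- function(sequence) {
  out <- vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    n <- length(aa)
    if (n < 3L) return(0L)
    n - 2L - sum(aa[3:n] == "P")
  }, integer(1), USE.NAMES = FALSE)
  if (any(nchar(sequence) < 3L)) {
    warning("peptide(s) shorter than 3 residues have no exchangeable amides",
            call. = FALSE)
  }
  out
}

#' Aggregate replicate uptake measurements into an uptake curve
#'
#' @param table Uptake table (tibble with `state`, `peptide_id`, `time`,
#'   `replicate`, `deuterium`).
#' @param state State label to extract.
#' @param peptide_id Peptide identifier to extract.
#'
#' @return Tibble with columns `state`, `peptide_id`, `time`, `mean`, `sd`,
#'   `n`, ordered by ascending time; `sd` is 0 when `n = 1`.
#' @export
aggregate_replicates <- function(table, state, peptide_id) {
  rec <- dplyr::filter(table, .data$state == !!state,
                       .data$peptide_id == !!peptide_id)
  if (nrow(rec) == 0) {
    stop("no records for state '", state, "', peptide '", peptide_id, "'",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$state, .data$peptide_id, .data$time),
    mean = mean(.data$deuterium),
    sd = if (dplyr::n() > 1) stats::sd(.data$deuterium) else 0,
    n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$time)
}

#' Curate the peptide set coincident across all experimental states
#'
#' Difference maps require identical peptides measured in every state. A
#' peptide is coincident when the exact `(sequence, start, end)` triple is
#' present in every table with records at every time point shared across
#' all tables. Charge states are assumed merged upstream; peptide identity
#' is purely the sequence/coordinate triple.
#'
#' @param tables List of uptake tables (>= 2).
#'
#' @return Tibble of coincident peptides (`peptide_id`, `sequence`, `start`,
#'   `end`) ordered N- to C-terminal (by `start`, then `end`). Empty, with a
#'   warning, when the intersection is empty. `peptide_id` is taken from the
#'   first table.
#' @export
curate_coincident <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  shared_times <- Reduce(intersect, lapply(tables, function(t) unique(t$time)))
  keysets <- lapply(tables, function(t) {
    full <- dplyr::distinct(t, .data$sequence, .data$start, .data$end,
                            .data$time)
    # require presence at every time point shared across all tables
    have <- dplyr::summarise(
      dplyr::group_by(full, .data$sequence, .data$start, .data$end),
      all_times = all(shared_times %in% .data$time), .groups = "drop")
    have[have$all_times, c("sequence", "start", "end")]
  })
  common <- Reduce(function(a, b) dplyr::inner_join(
    a, b, by = c("sequence", "start", "end")), keysets)
  if (nrow(common) == 0) {
    warning("no peptides are coincident across all tables", call. = FALSE)
    return(tibble::tibble(peptide_id = character(0), sequence = character(0),
                          start = integer(0), end = integer(0)))
  }
  ids <- dplyr::distinct(tables[[1]], .data$peptide_id, .data$sequence,
                         .data$start, .data$end)
  out <- dplyr::inner_join(common, ids, by = c("sequence", "start", "end"))
  dplyr::arrange(
    dplyr::select(out, "peptide_id", "sequence", "start", "end"),
    .data$start, .data$end)
}
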