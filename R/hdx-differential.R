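#' Classification thresholds for deuterium differences
#'
#' Defaults follow the descriptive convention used for full-length BTK
#' difference maps: differences greater than 1.0 Da are *major*, differences
#' between 0.5 and 1.0 Da are *modest*, smaller differences are treated as
#' no change. Boundary convention: a difference exactly equal to either
#' threshold is classified *modest* ("between 0.5 Da and 1.0 Da" is read
#' inclusively; "greater than 1.0 Da" strictly).
#'
#' @param modest Lower bound of the modest band, Da (> 0).
#' @param major Lower (exclusive) bound of the major band, Da (> modest).
#'
#' @return List of class `hdx_thresholds`.
#' @export
hdx_thresholds <- function(modest = 0.5, major = 1.0) {
  stopifnot(modest > 0, major > modest)
  structure(list(modest = modest, major = major), class = "hdx_thresholds")
}

difference_categories <- c("major_decrease", "modest_decrease", "none",
                           "modest_increase", "major_increase")

#' Classify a deuterium difference
#'
#' Pure threshold step function: `|delta| > major` is major,
#' `modest <= |delta| <= major` is modest, `|delta| < modest` is none; the
#' sign selects increase (more deuterium in the state than the reference)
#' versus decrease (protection).
#'
#' @param delta Deuterium difference(s), Da (state minus reference).
#' @param thresholds An [hdx_thresholds()] object.
#'
#' @return Factor with levels `major_decrease`, `modest_decrease`, `none`,
#'   `modest_increase`, `major_increase`.
#' @export
#' @examples
#' classify_difference(c(0.7, -1.3, 0, 0.5, 1.0))
classify_difference <- function(delta, thresholds = hdx_thresholds()) {
  stopifnot(all(is.finite(delta)), inherits(thresholds, "hdx_thresholds"))
  a <- abs(delta)
  band <- dplyr::case_when(
    a > thresholds$major ~ "major",
    a >= thresholds$modest ~ "modest",
    TRUE ~ "none"
  )
  lab <- dplyr::case_when(
    band == "none" ~ "none",
    delta > 0 ~ paste0(band, "_increase"),
    TRUE ~ paste0(band, "_decrease")
  )
  factor(lab, levels = difference_categories)
}

#' Peptide-level deuterium difference map against a reference state
#'
#' For every curated peptide and every time point shared between the two
#' states, the replicate-mean relative deuterium level of the reference is
#' subtracted from that of the state (`delta = mean_state -
#' mean_reference`), and the difference is classified with the active
#' thresholds. Peptides missing a time point in either state are skipped
#' for that time with a message.
#'
#' @param table Uptake table containing both states.
#' @param state State label of interest (e.g. a drug-bound form).
#' @param reference Reference state label (e.g. apo).
#' @param peptides Curated peptide tibble (see [curate_coincident()]);
#'   defaults to all peptides present in both states at all shared times.
#' @param thresholds An [hdx_thresholds()] object.
#'
#' @return Tibble with columns `peptide_id`, `sequence`, `start`, `end`,
#'   `time`, `delta`, `category`, plus attributes `state` and `reference`.
#' @export
difference_map <- function(table, state, reference, peptides = NULL,
                           thresholds = hdx_thresholds()) {
  stopifnot(all(c(state, reference) %in% unique(table$state)))
  if (is.null(peptides)) {
    peptides <- curate_coincident(list(
      dplyr::filter(table, .data$state == !!state),
      dplyr::filter(table, .data$state == !!reference)
    ))
  }
  means <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(table, .data$state %in% c(!!state, !!reference),
                    .data$sequence %in% peptides$sequence),
      .data$state, .data$sequence, .data$start, .data$end, .data$time),
    mean_d = mean(.data$deuterium), .groups = "drop")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(means,
                  role = ifelse(.data$state == !!state, "state", "reference")),
    id_cols = c("sequence", "start", "end", "time"),
    names_from = "role", values_from = "mean_d")
  if (!"state" %in% names(wide)) wide$state <- NA_real_
  if (!"reference" %in% names(wide)) wide$reference <- NA_real_
  dropped <- sum(is.na(wide$state) | is.na(wide$reference))
  if (dropped > 0) {
    message(dropped, " peptide x time record(s) missing in one state; skipped")
    wide <- dplyr::filter(wide, !is.na(.data$state), !is.na(.data$reference))
  }
  out <- dplyr::inner_join(
    peptides, wide, by = c("sequence", "start", "end"))
  out <- dplyr::mutate(out, delta = .data$state - .data$reference,
                       category = classify_difference(.data$delta, thresholds))
  out <- dplyr::arrange(
    dplyr::select(out, "peptide_id", "sequence", "start", "end", "time",
                  "delta", "category"),
    .data$start, .data$end, .data$time)
  attr(out, "state") <- state
  attr(out, "reference") <- reference
  attr(out, "thresholds") <- thresholds
  out
}

#' Localize deuterium differences to residues via overlapping peptides
#'
#' Peptide-level differences cannot pinpoint residues, but overlapping
#' peptides narrow them down: each covered residue inherits the category of
#' the *shortest* peptide covering it (ties broken by larger maximum
#' `|delta|`, then by lower start). A peptide's category is taken at its
#' strongest-`|delta|` time point, i.e. the strongest change observed over
#' the time course. Residues covered by no peptide are absent from the
#' output. The localization is only as sharp as the peptide map: an
#' annotated region may exceed the true perturbed segment by up to the
#' length of its shortest covering peptides.
#'
#' @param diffs Difference map from [difference_map()].
#' @param map Optional peptide map restricting/defining coverage; defaults
#'   to the peptides present in `diffs`.
#' @param thresholds Thresholds used to re-derive the per-peptide category
#'   at the strongest time point.
#'
#' @return Tibble with columns `residue`, `category`, `peptide_id` (the
#'   deciding peptide) and `supporting_peptides` (list of all covering
#'   peptide ids).
#' @export
consolidate_residues <- function(diffs, map = NULL,
                                 thresholds = attr(diffs, "thresholds")) {
  if (is.null(thresholds)) thresholds <- hdx_thresholds()
  if (is.null(map)) {
    map <- dplyr::distinct(diffs, .data$peptide_id, .data$sequence,
                           .data$start, .data$end)
  }
  stopifnot(all(diffs$peptide_id %in% map$peptide_id))
  if (nrow(diffs) == 0) {
    return(tibble::tibble(
      residue = integer(0),
      category = factor(character(0), levels = difference_categories),
      peptide_id = character(0), supporting_peptides = list()))
  }
  # per-peptide strongest-|delta| time point (vectorized: order rows by
  # |delta| descending, keep the first row of each peptide)
  ord <- order(diffs$peptide_id, -abs(diffs$delta))
  pp <- diffs[ord, ]
  pp <- pp[!duplicated(pp$peptide_id), ]
  pp$length <- pp$end - pp$start + 1L
  pp$category <- classify_difference(pp$delta, thresholds)

  reps <- pp$length
  cover <- data.frame(
    residue = unlist(Map(seq.int, pp$start, pp$end)),
    peptide_id = rep(pp$peptide_id, reps),
    category = rep(as.character(pp$category), reps),
    length = rep(pp$length, reps),
    absdelta = rep(abs(pp$delta), reps),
    start = rep(pp$start, reps)
  )
  o <- order(cover$residue, cover$length, -cover$absdelta, cover$start)
  cover <- cover[o, ]
  deciding <- cover[!duplicated(cover$residue), ]
  support <- lapply(split(cover$peptide_id, cover$residue),
                    function(p) sort(unique(p)))
  tibble::tibble(
    residue = deciding$residue,
    category = factor(deciding$category, levels = difference_categories),
    peptide_id = deciding$peptide_id,
    supporting_peptides = unname(support[as.character(deciding$residue)])
  )
}

#' Named domain boundaries of full-length BTK
#'
#' Residue ranges for the regulatory and catalytic regions of the
#' 659-residue multidomain kinase, anchored on T316 (SH2), W395
#' (SH2-kinase linker) and the linker-kinase fragment starting at residue
#' 381. Boundaries are configuration, not measurement: replace them for
#' other constructs.
#'
#' @return Tibble with columns `domain`, `start`, `end`.
#' @export
btk_domains <- function() {
  tibble::tribble(
    ~domain,  ~start, ~end,
    "PHTH",      1L, 170L,
    "PRR",     171L, 214L,
    "SH3",     215L, 280L,
    "SH2",     281L, 380L,
    "linker",  381L, 396L,
    "kinase",  397L, 659L
  )
}

#' Summarize residue annotations per protein domain
#'
#' @param annotations Residue annotations from [consolidate_residues()].
#' @param domains Domain map tibble (`domain`, `start`, `end`), e.g.
#'   [btk_domains()]. Residues outside every domain are counted under
#'   `"unassigned"`.
#'
#' @return Tibble with one row per domain x category: columns `domain`,
#'   `category`, `n_residues`, `fraction` (of annotated residues in the
#'   domain). All domains and categories are present (zero-filled).
#' @export
domain_summary <- function(annotations, domains = btk_domains()) {
  stopifnot(all(c("domain", "start", "end") %in% names(domains)),
            !anyDuplicated(domains$domain))
  lab <- function(res) {
    hit <- domains$domain[res >= domains$start & res <= domains$end]
    if (length(hit) == 0) "unassigned" else hit[1]
  }
  levs <- c(domains$domain, "unassigned")
  if (nrow(annotations) == 0) {
    grid <- tidyr::expand_grid(domain = levs, category = difference_categories)
    return(dplyr::mutate(grid, n_residues = 0L, fraction = NA_real_))
  }
  ann <- dplyr::mutate(annotations,
                       domain = vapply(.data$residue, lab, character(1)))
  counts <- dplyr::count(ann, .data$domain, .data$category,
                         name = "n_residues")
  grid <- tidyr::expand_grid(domain = levs, category = difference_categories)
  out <- dplyr::left_join(grid, counts, by = c("domain", "category"))
  out$n_residues[is.na(out$n_residues)] <- 0L
  dplyr::mutate(
    dplyr::group_by(out, .data$domain),
    fraction = if (sum(.data$n_residues) > 0)
      .data$n_residues / sum(.data$n_residues) else NA_real_
  ) |> dplyr::ungroup()
}

#' Classify an inhibitor's conformational response type
#'
#' Active-site inhibitors fall into two categories: those that displace the
#' regulatory domains from the kinase (increased exchange in SH3/SH2/linker
#' on binding) and those whose effects stay local to the kinase domain. A
#' drug is `regulatory_displacing` when at least `min_residues` residues
#' across the regulatory domains carry any increase category;
#' `kinase_local` when the kinase domain shows changes but the regulatory
#' criterion fails; `no_effect` otherwise.
#'
#' @param summary Per-domain table from [domain_summary()].
#' @param regulatory_labels Domain labels making up the regulatory regions.
#' @param kinase_label Domain label of the kinase (catalytic) domain.
#' @param min_residues Minimum increase-annotated regulatory residues for
#'   the `regulatory_displacing` call.
#'
#' @return One of `"regulatory_displacing"`, `"kinase_local"`, `"no_effect"`.
#' @export
classify_inhibitor_response <- function(summary,
                                        regulatory_labels = c("SH3", "SH2",
                                                              "linker"),
                                        kinase_label = "kinase",
                                        min_residues = 5L) {
  known <- unique(summary$domain)
  bad <- setdiff(c(regulatory_labels, kinase_label), known)
  if (length(bad) > 0) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inc <- c("modest_increase", "major_increase")
  reg_up <- sum(summary$n_residues[summary$domain %in% regulatory_labels &
                                     summary$category %in% inc])
  kin_any <- sum(summary$n_residues[summary$domain == kinase_label &
                                      summary$category != "none"])
  if (reg_up >= min_residues) return("regulatory_displacing")
  if (kin_any > 0) return("kinase_local")
  "no_effect"
}
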