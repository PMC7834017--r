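#' Per-residue protection profile for one conformational state
#'
#' A protection profile stores, for every residue of the protein, the base-10
#' logarithm of its protection factor (PF): the fold-slowdown of amide
#' hydrogen exchange relative to the intrinsic (unstructured) rate. High
#' `log10_pf` means structured / hydrogen-bonded; 0 means fully exposed.
#' Prolines have no backbone amide NH and are marked non-exchanging
#' (`log10_pf = NA`).
#'
#' @param sequence Single amino-acid string (standard one-letter codes).
#' @param log10_pf Numeric vector, one value per residue, all `>= 0`.
#'   Values supplied at proline positions are replaced by `NA`.
#' @param state Label for the conformational state (e.g. `"closed"`).
#'
#' @return A tibble of class `protection_profile` with columns `residue`,
#'   `aa`, `log10_pf` and attribute `state`.
#' @export
#' @examples
#' protection_profile("ANSLYK", log10_pf = rep(3, 6), state = "closed")
protection_profile <- function(sequence, log10_pf, state = "state") {
  aa <- check_sequence(sequence)
  L <- length(aa)
  if (length(log10_pf) == 1L) log10_pf <- rep(log10_pf, L)
  stopifnot(length(log10_pf) == L)
  if (any(log10_pf < 0, na.rm = TRUE)) {
    stop("all log10 protection factors must be >= 0", call. = FALSE)
  }
  log10_pf[aa == "P"] <- NA_real_
  out <- tibble::tibble(residue = seq_len(L), aa = aa, log10_pf = log10_pf)
  class(out) <- c("protection_profile", class(out))
  attr(out, "state") <- state
  out
}

#' Mixture of conformational states
#'
#' Represents the solution-state conformational ensemble as a discrete
#' mixture of protection profiles with mixing fractions. The generative
#' uptake model is linear in the fractions, so a two-member ensemble with
#' fractions `(1 - f_open, f_open)` reproduces the population-weighted
#' exchange behaviour of a protein in two-state equilibrium.
#'
#' @param profiles List of [protection_profile()] objects sharing one length.
#' @param fractions Numeric mixing fractions, `>= 0`, summing to 1 (1e-9).
#'
#' @return An object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(profiles, fractions) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            length(profiles) == length(fractions))
  lens <- vapply(profiles, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all profiles must share the same protein length", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be >= 0 and sum to 1", call. = FALSE)
  }
  structure(list(profiles = profiles, fractions = as.numeric(fractions)),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  states <- vapply(x$profiles, function(p) attr(p, "state"), character(1))
  cat("<conformational_ensemble> ", nrow(x$profiles[[1]]), " residues\n", sep = "")
  for (i in seq_along(states)) {
    cat(sprintf("  %-12s fraction %.3f\n", states[i], x$fractions[i]))
  }
  invisible(x)
}

#' Exchange-labeling conditions for the uptake simulator
#'
#' @param times Labeling durations in seconds, strictly increasing.
#' @param k_int Intrinsic exchange rate(s), s^-1; scalar or one per residue.
#'   Default 1 s^-1 for every residue, keeping ground truth analytic.
#' @param back_exchange_fraction Fraction of label lost during workup,
#'   in `[0, 1)`; applied as a uniform multiplicative loss.
#' @param noise_sd Additive Gaussian noise on peptide deuterium, Da.
#' @param seed Integer seed controlling the noise draws.
#'
#' @return A list of class `exchange_conditions`.
#' @export
exchange_conditions <- function(times = c(10, 60, 600, 3600, 14400),
                                k_int = 1,
                                back_exchange_fraction = 0,
                                noise_sd = 0.05,
                                seed = 1L) {
  stopifnot(all(k_int > 0), all(diff(times) > 0), all(times >= 0),
            noise_sd >= 0,
            back_exchange_fraction >= 0, back_exchange_fraction < 1)
  structure(list(times = as.numeric(times), k_int = as.numeric(k_int),
                 back_exchange_fraction = back_exchange_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "exchange_conditions")
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad) > 0) {
    stop("sequence contains non-standard residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  aa
}

#' Generate an overlapping peptic-peptide map
#'
#' Emulates the peptide coverage produced by online pepsin digestion: a
#' tiling of peptides whose lengths vary around `mean_length` and whose
#' consecutive members overlap by at least `min_overlap` residues, so that
#' every residue is covered and overlapping peptides are available for
#' residue-level localization of exchange differences.
#'
#' @param sequence Protein amino-acid string.
#' @param mean_length Target mean peptide length (residues), `>= 4`.
#' @param min_overlap Minimum overlap between consecutive peptides
#'   (residues), `< mean_length`.
#' @param seed Integer seed; the map is deterministic for a fixed seed.
#'
#' @return A tibble with columns `peptide_id`, `sequence`, `start`, `end`
#'   and attribute `protein_length`.
#' @export
#' @examples
#' generate_peptide_map("MKVLNSAGQRTWEDFYHICP", mean_length = 8,
#'                      min_overlap = 3, seed = 1)
generate_peptide_map <- function(sequence, mean_length = 12, min_overlap = 3,
                                 seed = 1L) {
  aa <- check_sequence(sequence)
  L <- length(aa)
  stopifnot(L >= mean_length, mean_length >= 4, min_overlap < mean_length,
            min_overlap >= 1)
  withr::with_seed(as.integer(seed), {
    starts <- integer(0)
    ends <- integer(0)
    start <- 1L
    repeat {
      len <- round(rnorm(1, mean = mean_length, sd = mean_length / 6))
      len <- max(4L, min(as.integer(len), L - start + 1L))
      end <- start + len - 1L
      starts <- c(starts, start)
      ends <- c(ends, end)
      if (end >= L) break
      hi <- min(min_overlap + 2L, len - 1L)
      lo <- min(min_overlap, hi)
      overlap <- sample(lo:hi, 1L)
      start <- min(end - overlap + 1L, L - 3L)
    }
  })
  out <- tibble::tibble(
    peptide_id = sprintf("p%03d", seq_along(starts)),
    sequence = vapply(seq_along(starts),
                      function(i) paste(aa[starts[i]:ends[i]], collapse = ""),
                      character(1)),
    start = starts, end = ends
  )
  attr(out, "protein_length") <- L
  out
}

#' Build a two-state (closed/open) conformational ensemble
#'
#' Models regulatory-domain release as a loss of protection: the open state
#' is the closed profile with `log10_pf` reduced by `delta_log_pf` (floored
#' at 0) inside the supplied regions, mixed with the closed state at
#' fractions `(1 - f_open, f_open)`.
#'
#' @param closed_profile A [protection_profile()] for the compact
#'   (autoinhibited) state.
#' @param open_regions List of two-element `c(start, end)` residue ranges
#'   that lose protection in the open state.
#' @param delta_log_pf Positive drop in log10 protection factor.
#' @param f_open Open-state fraction in `[0, 1]`.
#'
#' @return A [conformational_ensemble()] with members closed then open.
#' @export
build_two_state_ensemble <- function(closed_profile, open_regions,
                                     delta_log_pf, f_open) {
  stopifnot(inherits(closed_profile, "protection_profile"),
            delta_log_pf > 0, f_open >= 0, f_open <= 1)
  L <- nrow(closed_profile)
  open <- closed_profile
  for (rg in open_regions) {
    stopifnot(length(rg) == 2L)
    if (rg[1] < 1 || rg[2] > L || rg[1] > rg[2]) {
      stop("open region [", rg[1], ", ", rg[2],
           "] falls outside the sequence (length ", L, ")", call. = FALSE)
    }
    idx <- rg[1]:rg[2]
    open$log10_pf[idx] <- pmax(open$log10_pf[idx] - delta_log_pf, 0)
  }
  attr(open, "state") <- paste0(attr(closed_profile, "state"), "_open")
  conformational_ensemble(list(closed_profile, open), c(1 - f_open, f_open))
}

# residue indices (within the protein) of a peptide's exchange-reporting
# amides: the first two positions and prolines from position 3 on are
# excluded (fast back-exchange convention)
exchangeable_indices <- function(sequence, start) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 3L) return(integer(0))
  pos <- 3:n
  pos <- pos[aa[pos] != "P"]
  start + pos - 1L
}

#' Simulate a peptide-level deuterium uptake table
#'
#' Generative model (Linderstrom-Lang, EX2 limit): per exchanging residue
#' `r` the deuterium fraction at labeling time `t` is the mixture
#' `d_r(t) = sum_s f_s * (1 - exp(-k_int_r * t / 10^log10_pf_{s,r}))`
#' over ensemble members `s`; the peptide-level deuterium is
#' `D(t) = (1 - back_exchange_fraction) * sum_{r in exchangeable} d_r(t)`
#' plus additive Gaussian noise per record. Exchangeable residues of a
#' peptide exclude its first two positions and any prolines beyond
#' position 2. Deuterium levels are relative (uncorrected centroid-style
#' values), matching vendor cluster exports.
#'
#' @param ensemble A [conformational_ensemble()].
#' @param map Peptide map from [generate_peptide_map()] (or any tibble with
#'   `peptide_id`, `sequence`, `start`, `end`).
#' @param cond An [exchange_conditions()] object.
#' @param state_label State name written to the `state` column.
#' @param replicates Number of labeling replicates per time point.
#'
#' @return Tibble with columns `state`, `peptide_id`, `sequence`, `start`,
#'   `end`, `time`, `replicate`, `deuterium` (one row per peptide x time x
#'   replicate).
#' @export
simulate_uptake_table <- function(ensemble, map, cond, state_label,
                                  replicates = 3L) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(cond, "exchange_conditions"), replicates >= 1L)
  L <- nrow(ensemble$profiles[[1]])
  if (max(map$end) > L) {
    stop("peptide map extends beyond the ensemble's protein length",
         call. = FALSE)
  }
  k_int <- cond$k_int
  if (length(k_int) == 1L) k_int <- rep(k_int, L)
  stopifnot(length(k_int) == L)
  times <- cond$times

  # residue x time deuterium fractions, mixture-weighted over states
  mix <- matrix(0, nrow = L, ncol = length(times))
  for (s in seq_along(ensemble$profiles)) {
    pf <- ensemble$profiles[[s]]$log10_pf
    rate <- ifelse(is.na(pf), 0, k_int / 10^pf)
    mix <- mix + ensemble$fractions[s] * (1 - exp(-outer(rate, times)))
  }
  mix[is.na(ensemble$profiles[[1]]$log10_pf), ] <- 0  # prolines

  idx <- purrr::map2(map$sequence, map$start, exchangeable_indices)
  d_pep <- t(vapply(idx, function(i) {
    if (length(i) == 0) rep(0, length(times))
    else colSums(mix[i, , drop = FALSE])
  }, numeric(length(times))))
  d_pep <- (1 - cond$back_exchange_fraction) * d_pep

  out <- tidyr::expand_grid(
    peptide_id = map$peptide_id,
    time = times,
    replicate = seq_len(replicates)
  )
  out$deuterium <- d_pep[cbind(match(out$peptide_id, map$peptide_id),
                               match(out$time, times))]
  if (cond$noise_sd > 0) {
    noise <- withr::with_seed(cond$seed,
                              rnorm(nrow(out), sd = cond$noise_sd))
    out$deuterium <- out$deuterium + noise
  }
  out <- dplyr::left_join(out,
                          map[, c("peptide_id", "sequence", "start", "end")],
                          by = "peptide_id")
  tibble::as_tibble(dplyr::select(
    dplyr::mutate(out, state = state_label),
    "state", "peptide_id", "sequence", "start", "end",
    "time", "replicate", "deuterium"
  ))
}

lorentzian <- function(x, center, fwhm) {
  1 / (1 + (2 * (x - center) / fwhm)^2)
}

#' Simulate a 1D NMR trace of the W395 indole region
#'
#' Two Lorentzian lines on a descending ppm axis: a downfield line for the
#' active (alphaC-in) conformation and an upfield line for the inactive
#' (alphaC-out) conformation, with integrated areas proportional to
#' `(1 - f_inactive, f_inactive)`. The default 0.2 ppm separation matches
#' the upfield shift of the W395 indole NH proton between the two states;
#' slow conformational exchange gives two resolved peaks whose integrals
#' report the populations.
#'
#' @param f_inactive Inactive-state (upfield) population in `[0, 1]`.
#' @param centers Two distinct ppm positions; the larger (downfield) one is
#'   the active-state line.
#' @param fwhm Full width at half maximum, ppm.
#' @param amplitude_scale Overall intensity scale (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   maximum noise-free intensity.
#' @param seed Integer seed for the noise.
#' @param n Number of points in the trace.
#'
#' @return Tibble with columns `ppm` (strictly decreasing) and `intensity`.
#'   Attribute `overlap_warning` is `TRUE` when the centers are separated by
#'   less than `fwhm / 10`.
#' @export
simulate_nmr_trace <- function(f_inactive, centers = c(10.10, 9.90),
                               fwhm = 0.03, amplitude_scale = 1,
                               noise_sd = 0.01, seed = 1L, n = 601L) {
  stopifnot(f_inactive >= 0, f_inactive <= 1, length(centers) == 2L,
            fwhm > 0, n >= 50L)
  if (centers[1] == centers[2]) stop("centers must be distinct", call. = FALSE)
  downfield <- max(centers)
  upfield <- min(centers)
  overlap <- (downfield - upfield) < fwhm / 10
  if (overlap) {
    warning("peak centers are separated by less than fwhm/10; ",
            "populations will be poorly determined", call. = FALSE)
  }
  ppm <- seq(downfield + 0.15, upfield - 0.15, length.out = n)
  clean <- amplitude_scale *
    ((1 - f_inactive) * lorentzian(ppm, downfield, fwhm) +
       f_inactive * lorentzian(ppm, upfield, fwhm))
  intensity <- clean
  if (noise_sd > 0) {
    intensity <- clean + withr::with_seed(
      as.integer(seed), rnorm(n, sd = noise_sd * max(clean)))
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  attr(out, "overlap_warning") <- overlap
  out
}

#' Simulate western-blot band intensities for an autophosphorylation assay
#'
#' pY551 band intensity is proportional to kinase activity times the amount
#' of protein loaded; the anti-His band reports loading alone. Noise is
#' multiplicative lognormal per band with coefficient of variation
#' `noise_cv` (unbiased: each band has expectation equal to its clean
#' value).
#'
#' @param samples Tibble with columns `label`, `activity_ratio` (relative
#'   kinase activity, > 0) and `loading` (relative protein amount, > 0).
#' @param noise_cv Coefficient of variation of the lognormal band noise.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `label`, `py551`, `his`.
#' @export
simulate_blot <- function(samples, noise_cv = 0, seed = 1L) {
  stopifnot(all(c("label", "activity_ratio", "loading") %in% names(samples)),
            all(samples$activity_ratio > 0), all(samples$loading > 0),
            noise_cv >= 0)
  py <- 100 * samples$activity_ratio * samples$loading
  his <- 100 * samples$loading
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- withr::with_seed(as.integer(seed), {
      exp(rnorm(2 * nrow(samples), mean = -sdlog^2 / 2, sd = sdlog))
    })
    py <- py * fac[seq_len(nrow(samples))]
    his <- his * fac[nrow(samples) + seq_len(nrow(samples))]
  }
  tibble::tibble(label = samples$label, py551 = py, his = his)
}

#' Simulate a covalent-inhibitor NMR titration series
#'
#' For an irreversible one-site binder the bound fraction at drug:protein
#' molar ratio `r` is `min(r, 1)`; drug-bound protein populates the
#' inactive (upfield) state, so
#' `f_inactive(r) = f0 + min(r, 1) * (1 - f0)`, where `f0` is the apo
#' inactive fraction.
#'
#' @param molar_ratios Drug:protein molar ratios, `>= 0`.
#' @param f0 Apo inactive-state fraction.
#' @param seed Integer seed; each trace gets an independent derived seed.
#' @inheritParams simulate_nmr_trace
#'
#' @return Tibble with columns `molar_ratio`, `f_inactive_true` and a
#'   list-column `trace` of NMR traces.
#' @export
simulate_titration_series <- function(molar_ratios, f0 = 0, seed = 1L,
                                      centers = c(10.10, 9.90), fwhm = 0.03,
                                      noise_sd = 0.01, n = 601L) {
  stopifnot(all(molar_ratios >= 0), f0 >= 0, f0 <= 1)
  f_true <- f0 + pmin(molar_ratios, 1) * (1 - f0)
  traces <- purrr::map2(f_true, seq_along(f_true), function(f, i) {
    simulate_nmr_trace(f, centers = centers, fwhm = fwhm,
                       noise_sd = noise_sd, seed = as.integer(seed) + 7L * i,
                       n = n)
  })
  tibble::tibble(molar_ratio = as.numeric(molar_ratios),
                 f_inactive_true = f_true, trace = traces)
}
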