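#' Synthetic full-length BTK-like sequence
#'
#' A deterministic 659-residue stand-in for full-length BTK used by the
#' packaged simulation scenarios. It is synthetic — residue identities are
#' drawn from typical globular-protein amino-acid frequencies with a fixed
#' internal seed — but the landmark residues of the real kinase are placed
#' at their canonical positions (T316 in the SH2 domain, W395 in the
#' SH2-kinase linker, C481 in the active site) and the proline-rich region
#' (residues 171-214) is enriched in proline. It is *not* the real BTK
#' sequence and must not be used for sequence-level biology.
#'
#' @return Single amino-acid string of length 659.
#' @export
synthetic_btk_sequence <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # rough globular-protein composition; proline kept moderate
  w <- c(A = 8, C = 1.5, D = 5.5, E = 6.5, F = 4, G = 7, H = 2.5, I = 5.5,
         K = 6, L = 9.5, M = 2.5, N = 4, P = 4.5, Q = 4, R = 5, S = 7,
         T = 5.5, V = 6.5, W = 1.5, Y = 3.5)
  seq_aa <- withr::with_seed(20290L, {
    s <- sample(aa, 659, replace = TRUE, prob = w[aa])
    prr <- 171:214
    make_p <- sample(prr, 14)
    s[make_p] <- "P"
    s
  })
  seq_aa[316] <- "T"
  seq_aa[395] <- "W"
  seq_aa[481] <- "C"
  paste(seq_aa, collapse = "")
}

# baseline closed-state profile shared by all packaged scenarios:
# log10 PFs drawn once (fixed internal seed) from U[2.5, 5.5] so that the
# default labeling times 10 s - 4 h probe the full uptake range
baseline_closed_profile <- function(sequence = synthetic_btk_sequence()) {
  L <- nchar(sequence)
  pf <- withr::with_seed(65901L, runif(L, 2.5, 5.5))
  protection_profile(sequence, pf, state = "closed")
}

# regulatory regions released in the open conformation (SH3 + SH2 + linker)
regulatory_open_regions <- function(domains = btk_domains()) {
  reg <- domains[domains$domain %in% c("SH3", "SH2", "linker"), ]
  purrr::map2(reg$start, reg$end, c)
}

# per-scenario generative parameters: open-state fraction and active-site
# protection footprint (positive delta = protection gained on drug binding)
drug_panel_params <- function() {
  tibble::tribble(
    ~state,            ~f_open, ~site_start, ~site_end, ~site_delta,
    "apo",                0.28,          NA,        NA,          NA,
    "ibrutinib_like",     0.60,        430L,      520L,         1.0,
    "dasatinib_like",     0.85,        430L,      470L,         0.8,
    "gdc_like",           0.28,        430L,      550L,         1.2,
    "cgi_like",           0.28,        430L,      550L,         1.2,
    "cc292_like",         0.28,        430L,      480L,         0.6
  )
}

apply_site_protection <- function(profile, start, end, delta) {
  idx <- start:end
  profile$log10_pf[idx] <- profile$log10_pf[idx] + delta
  profile
}

#' Simulate the six-state drug-panel HDX scenario
#'
#' Generates uptake tables for apo full-length kinase plus five drug-bound
#' forms sharing one peptide map, with the conformational structure the
#' differential analysis is designed to detect. The apo ensemble mixes a
#' compact autoinhibited state with an open state (regulatory SH3/SH2/
#' linker regions deprotected) at open fraction 0.28, matching the apo
#' active-state population seen by NMR. Drug binding adds active-site
#' protection in all five complexes; the two regulatory-displacing drugs
#' additionally raise the open fraction (`ibrutinib_like` 0.60,
#' `dasatinib_like` 0.85 — the latter also deprotects the kinase C-lobe,
#' emulating its activation-loop exposure), while `gdc_like`, `cgi_like`
#' and `cc292_like` leave the regulatory equilibrium at the apo value.
#'
#' @param seed Integer seed for the measurement noise.
#' @param noise_sd Additive Gaussian noise on peptide deuterium, Da.
#' @param replicates Replicates per peptide x time.
#' @param times Labeling times, s.
#'
#' @return One combined uptake table (tibble) with six `state` values; the
#'   peptide map is attached as attribute `peptide_map` and the generative
#'   parameters as attribute `params`.
#' @export
hdx_drug_panel <- function(seed = 1L, noise_sd = 0.05, replicates = 3L,
                           times = c(10, 60, 600, 3600, 14400)) {
  seqc <- synthetic_btk_sequence()
  closed <- baseline_closed_profile(seqc)
  map <- generate_peptide_map(seqc, mean_length = 12, min_overlap = 3,
                              seed = 659L)
  regions <- regulatory_open_regions()
  params <- drug_panel_params()
  tabs <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    prof <- closed
    if (!is.na(p$site_start)) {
      prof <- apply_site_protection(prof, p$site_start, p$site_end,
                                    p$site_delta)
    }
    if (p$state == "dasatinib_like") {
      prof$log10_pf[520:600] <- pmax(prof$log10_pf[520:600] - 0.8, 0)
    }
    ens <- build_two_state_ensemble(prof, regions, delta_log_pf = 1.2,
                                    f_open = p$f_open)
    cond <- exchange_conditions(times = times, noise_sd = noise_sd,
                                seed = as.integer(seed) + 101L * i)
    tabs[[i]] <- simulate_uptake_table(ens, map, cond, state_label = p$state,
                                       replicates = replicates)
  }
  out <- dplyr::bind_rows(tabs)
  attr(out, "peptide_map") <- map
  attr(out, "params") <- params
  out
}

#' Simulate the wild-type / T316A / C481S mutant HDX scenario
#'
#' The T316A resistance mutation destabilizes the autoinhibited
#' conformation: its open-state fraction is raised from the wild-type 0.28
#' to 0.40 (the populations seen by NMR for the two proteins), which at
#' the default conditions yields the characteristic small 0.5-1.0 Da
#' uptake increases across the regulatory SH3/SH2/linker regions. The
#' active-site C481S mutant exchanges identically to wild type and shares
#' its generative parameters (only the noise draw differs).
#'
#' @inheritParams hdx_drug_panel
#'
#' @return Combined uptake table with states `WT`, `T316A`, `C481S`;
#'   peptide map attached as attribute `peptide_map`.
#' @export
hdx_t316a_scenario <- function(seed = 1L, noise_sd = 0.05, replicates = 3L,
                               times = c(10, 60, 600, 3600, 14400)) {
  seqc <- synthetic_btk_sequence()
  closed <- baseline_closed_profile(seqc)
  map <- generate_peptide_map(seqc, mean_length = 12, min_overlap = 3,
                              seed = 659L)
  regions <- regulatory_open_regions()
  f_open <- c(WT = 0.28, T316A = 0.40, C481S = 0.28)
  tabs <- purrr::imap(f_open, function(f, st) {
    ens <- build_two_state_ensemble(closed, regions, delta_log_pf = 1.2,
                                    f_open = f)
    cond <- exchange_conditions(times = times, noise_sd = noise_sd,
                                seed = as.integer(seed) + 211L *
                                  match(st, names(f_open)))
    simulate_uptake_table(ens, map, cond, state_label = st,
                          replicates = replicates)
  })
  out <- dplyr::bind_rows(tabs)
  attr(out, "peptide_map") <- map
  out
}

#' Packaged W395 NMR trace fixtures
#'
#' Synthetic single-proton traces of the tryptophan indole region with the
#' populations measured for full-length wild-type kinase (72% inactive /
#' 28% active) and the T316A mutant (60% / 40%): two Lorentzians 0.2 ppm
#' apart (downfield = active), fwhm 0.03 ppm, 1% Gaussian noise.
#'
#' @param which `"wt_fl"` or `"t316a_fl"`.
#' @param seed Noise seed; defaults 7 (`wt_fl`) and 11 (`t316a_fl`).
#'
#' @return NMR trace tibble (`ppm`, `intensity`) with attribute
#'   `f_inactive_true`.
#' @export
nmr_state_fixture <- function(which = c("wt_fl", "t316a_fl"), seed = NULL) {
  which <- match.arg(which)
  f <- switch(which, wt_fl = 0.72, t316a_fl = 0.60)
  if (is.null(seed)) seed <- switch(which, wt_fl = 7L, t316a_fl = 11L)
  tr <- simulate_nmr_trace(f_inactive = f, centers = c(10.10, 9.90),
                           fwhm = 0.03, noise_sd = 0.01,
                           seed = as.integer(seed))
  attr(tr, "f_inactive_true") <- f
  tr
}
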