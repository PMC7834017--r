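# Independent brute-force oracles, written as plain loops so they share no
# code path with the vectorized implementations they check.

# per-residue Linderstrom-Lang uptake sum for one peptide at one time
oracle_peptide_uptake <- function(ensemble, pep_seq, pep_start, time,
                                  k_int, back_exchange = 0) {
  aa <- strsplit(pep_seq, "")[[1]]
  total <- 0
  for (pos in seq_along(aa)) {
    if (pos <= 2) next          # first two residues: fast back-exchange
    if (aa[pos] == "P") next    # no backbone amide
    res <- pep_start + pos - 1
    d <- 0
    for (s in seq_along(ensemble$profiles)) {
      pf <- ensemble$profiles[[s]]$log10_pf[res]
      if (is.na(pf)) next
      k <- if (length(k_int) == 1) k_int else k_int[res]
      d <- d + ensemble$fractions[s] * (1 - exp(-k * time / 10^pf))
    }
    total <- total + d
  }
  (1 - back_exchange) * total
}

# if-chain classification oracle for the threshold step function
oracle_classify <- function(delta, modest = 0.5, major = 1.0) {
  vapply(delta, function(d) {
    if (d > major) "major_increase"
    else if (d >= modest) "modest_increase"
    else if (d > -modest) "none"
    else if (d >= -major) "modest_decrease"
    else "major_decrease"
  }, character(1))
}

# random small simulation instance (protein <= 30 residues, 1-3 states)
random_instance <- function(seed) {
  withr::with_seed(seed, {
    L <- sample(8:30, 1)
    aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE)
    seqc <- paste(aa, collapse = "")
    n_states <- sample(1:3, 1)
    profs <- lapply(seq_len(n_states), function(i) {
      protection_profile(seqc, runif(L, 0, 5), state = paste0("s", i))
    })
    frac <- runif(n_states)
    frac <- frac / sum(frac)
    n_pep <- sample(2:5, 1)
    starts <- sort(sample(seq_len(L - 4), n_pep, replace = TRUE))
    ends <- pmin(starts + sample(3:8, n_pep, replace = TRUE), L)
    map <- tibble::tibble(
      peptide_id = sprintf("p%02d", seq_len(n_pep)),
      sequence = vapply(seq_len(n_pep), function(i)
        substr(seqc, starts[i], ends[i]), character(1)),
      start = as.integer(starts), end = as.integer(ends))
    times <- sort(sample(c(5, 30, 120, 600, 3600), sample(2:4, 1)))
    list(
      ensemble = conformational_ensemble(profs, frac),
      map = map,
      cond = exchange_conditions(times = times,
                                 k_int = runif(1, 0.2, 3),
                                 back_exchange_fraction = runif(1, 0, 0.3),
                                 noise_sd = 0, seed = seed)
    )
  })
}

# numeric trapezoid integration of a trace region (independent of the
# Lorentzian closed-form areas used by the fitter)
trapz_area <- function(ppm, intensity) {
  o <- order(ppm)
  x <- ppm[o]
  y <- intensity[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# residues of a peptide that both exchange and fall inside [lo, hi]
exchangeable_residues_in <- function(pep_seq, pep_start, lo, hi) {
  aa <- strsplit(pep_seq, "")[[1]]
  pos <- seq_along(aa)
  keep <- pos > 2 & aa != "P"
  res <- pep_start + pos - 1
  res[keep] >= lo & res[keep] <= hi
}
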