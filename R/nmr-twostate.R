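#' Fit two Lorentzian lines plus a flat baseline to a 1D NMR trace
#'
#' Quantification route for the W395 indole reporter: in the slow-exchange
#' limit the active (alphaC-in, downfield) and inactive (alphaC-out,
#' upfield) conformations give two resolved Lorentzian lines whose
#' integrated areas are proportional to the state populations. The model
#' `baseline + A1 L(c1, w1) + A2 L(c2, w2)` is fitted by Levenberg-Marquardt
#' least squares; absent `init_centers`, the two highest distinct local
#' maxima of the trace seed the centers.
#'
#' @param trace Tibble with columns `ppm`, `intensity` (>= 50 points; any
#'   axis direction is accepted and normalized to descending ppm).
#' @param init_centers Optional length-2 ppm vector of starting centers.
#' @param center_window Optional half-width (ppm) of a box constraint
#'   keeping each fitted center within `init_centers[i] +/- center_window`;
#'   used to anchor known line positions, e.g. across a titration series.
#'
#' @return Object of class `peak_fit`: a list with `peaks` (tibble of
#'   `peak` = downfield/upfield, `center`, `fwhm`, `amplitude`, `area`),
#'   `baseline`, `rss`, `converged`, `degenerate` and the input `trace`.
#'   The downfield peak is reported first. Peak area uses the Lorentzian
#'   closed form `pi * amplitude * fwhm / 2`.
#' @export
fit_two_peaks <- function(trace, init_centers = NULL,
                          center_window = NULL) {
  stopifnot(all(c("ppm", "intensity") %in% names(trace)),
            nrow(trace) >= 50L)
  trace <- dplyr::arrange(tibble::as_tibble(trace[c("ppm", "intensity")]),
                          dplyr::desc(.data$ppm))
  if (any(diff(trace$ppm) >= 0)) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  x <- trace$ppm
  y <- trace$intensity
  span <- diff(range(x))

  if (is.null(init_centers)) {
    init_centers <- find_peak_centers(x, y)
  }
  stopifnot(length(init_centers) == 2L)
  c0 <- sort(init_centers, decreasing = TRUE)
  w0 <- span / 20
  a0 <- vapply(c0, function(cc) max(y[abs(x - cc) <= span / 20]), numeric(1))
  w_min <- max(span / 1e4, 2 * stats::median(abs(diff(x))))
  c_lo <- rep(min(x), 2)
  c_hi <- rep(max(x), 2)
  if (!is.null(center_window)) {
    stopifnot(center_window > 0)
    c_lo <- c0 - center_window
    c_hi <- c0 + center_window
  }

  model <- function(p) {
    p[["b0"]] + p[["A1"]] / (1 + (2 * (x - p[["c1"]]) / p[["w1"]])^2) +
      p[["A2"]] / (1 + (2 * (x - p[["c2"]]) / p[["w2"]])^2)
  }
  fit <- minpack.lm::nls.lm(
    par = list(b0 = min(y), A1 = a0[1], A2 = a0[2],
               c1 = c0[1], c2 = c0[2], w1 = w0, w2 = w0),
    lower = c(b0 = -Inf, A1 = 0, A2 = 0,
              c1 = c_lo[1], c2 = c_lo[2], w1 = w_min, w2 = w_min),
    upper = c(b0 = Inf, A1 = Inf, A2 = Inf,
              c1 = c_hi[1], c2 = c_hi[2], w1 = span, w2 = span),
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  rss <- sum(fit$fvec^2)
  if (!fit$info %in% 1:4) {
    stop("two-peak fit did not converge (residual norm ",
         format(sqrt(rss), digits = 4), "): ", fit$message, call. = FALSE)
  }
  peaks <- tibble::tibble(
    center = c(p[["c1"]], p[["c2"]]),
    fwhm = c(p[["w1"]], p[["w2"]]),
    amplitude = c(p[["A1"]], p[["A2"]])
  )
  degenerate <- FALSE
  if (abs(diff(peaks$center)) < 0.5 * mean(peaks$fwhm)) {
    # centers collapsed onto one line: the trace holds a single detectable
    # peak, so refit one Lorentzian and report a zero-area phantom partner
    # on the far side of the window to keep the two-peak contract
    one <- minpack.lm::nls.lm(
      par = list(b0 = min(y), A = max(y) - min(y),
                 c = mean(peaks$center), w = mean(peaks$fwhm)),
      lower = c(-Inf, 0, min(x), w_min),
      upper = c(Inf, Inf, max(x), span),
      fn = function(q) y - (q[["b0"]] + q[["A"]] /
                              (1 + (2 * (x - q[["c"]]) / q[["w"]])^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    q <- one$par
    off <- max(2 * q[["w"]], span / 10)
    phantom_center <- if (q[["c"]] <= mean(range(x)))
      q[["c"]] + off else q[["c"]] - off
    peaks <- tibble::tibble(center = c(q[["c"]], phantom_center),
                            fwhm = c(q[["w"]], q[["w"]]),
                            amplitude = c(q[["A"]], 0))
    p <- c(b0 = q[["b0"]])
    rss <- sum(one$fvec^2)
    degenerate <- TRUE
  }
  peaks <- peaks[order(peaks$center, decreasing = TRUE), ]
  peaks$peak <- c("downfield", "upfield")
  peaks$area <- pi * peaks$amplitude * peaks$fwhm / 2
  peaks <- peaks[, c("peak", "center", "fwhm", "amplitude", "area")]

  degenerate <- degenerate ||
    min(peaks$amplitude) < 1e-3 * max(peaks$amplitude)
  if (degenerate) {
    warning("degenerate fit: one peak is vanishing or the centers collapsed",
            call. = FALSE)
  }
  structure(list(peaks = peaks, baseline = p[["b0"]], rss = rss,
                 converged = TRUE, degenerate = degenerate, trace = trace),
            class = "peak_fit")
}

# two highest distinct interior local maxima of the lightly smoothed trace
# (running mean suppresses noise spikes on peak shoulders); falls back to
# the global maximum plus an offset point when only one maximum exists
find_peak_centers <- function(x, y) {
  n <- length(y)
  k <- max(3L, 2L * (n %/% 200L) + 1L)
  y <- stats::filter(y, rep(1 / k, k), sides = 2)
  y[is.na(y)] <- min(y, na.rm = TRUE)
  i <- 2:(n - 1)
  is_max <- y[i] >= y[i - 1] & y[i] >= y[i + 1] &
    (y[i] > y[i - 1] | y[i] > y[i + 1])
  cand <- i[is_max]
  cand <- cand[order(y[cand], decreasing = TRUE)]
  sep <- diff(range(x)) / 10
  centers <- numeric(0)
  for (j in cand) {
    if (all(abs(x[j] - centers) > sep)) centers <- c(centers, x[j])
    if (length(centers) == 2L) break
  }
  if (length(centers) == 0L) {
    stop("trace contains no local maximum", call. = FALSE)
  }
  if (length(centers) == 1L) {
    centers <- c(centers, centers + diff(range(x)) / 10)
  }
  centers
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("<peak_fit> two-Lorentzian fit, baseline ",
      format(x$baseline, digits = 3), ", rss ",
      format(x$rss, digits = 4), "\n", sep = "")
  print(x$peaks)
  invisible(x)
}

#' @rdname fit_two_peaks
#' @param x A `peak_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.peak_fit <- function(x, ...) {
  x$peaks
}

#' @rdname fit_two_peaks
#' @exportS3Method generics::glance
glance.peak_fit <- function(x, ...) {
  tibble::tibble(baseline = x$baseline, rss = x$rss,
                 converged = x$converged, degenerate = x$degenerate,
                 n_points = nrow(x$trace))
}

#' Estimate conformational populations from a two-peak fit
#'
#' The upfield (alphaC-out) peak reports the inactive conformation and the
#' downfield (alphaC-in) peak the active conformation; populations are the
#' fitted peak areas normalized to their sum. Areas, not heights, are used
#' because heights misreport populations when the two linewidths differ.
#'
#' @param fit A `peak_fit` from [fit_two_peaks()].
#'
#' @return One-row tibble with columns `f_active`, `f_inactive` (summing
#'   to 1).
#' @export
estimate_populations <- function(fit) {
  stopifnot(inherits(fit, "peak_fit"))
  a_down <- fit$peaks$area[fit$peaks$peak == "downfield"]
  a_up <- fit$peaks$area[fit$peaks$peak == "upfield"]
  tot <- a_down + a_up
  if (!is.finite(tot) || tot <= 0) {
    stop("both peak areas are ~0; populations undefined", call. = FALSE)
  }
  tibble::tibble(f_active = a_down / tot, f_inactive = a_up / tot)
}

#' Bound fraction of an irreversible covalent inhibitor
#'
#' A covalent, single-site binder in excess-time conditions converts
#' protein stoichiometrically: the bound fraction at drug:protein molar
#' ratio `r` is `min(r, 1)`; at a 1:1 ratio the protein is fully converted.
#'
#' @param molar_ratio Drug:protein molar ratio(s), `>= 0`.
#'
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
stoichiometric_bound_fraction <- function(molar_ratio) {
  stopifnot(all(molar_ratio >= 0))
  pmin(molar_ratio, 1)
}

#' Analyze a covalent-inhibitor titration series
#'
#' Each trace is fitted with [fit_two_peaks()] and converted to populations
#' with [estimate_populations()]. For a covalent one-site binder that
#' drives the bound protein into the inactive conformation, `f_inactive`
#' should rise with the molar ratio and saturate at ratio 1
#' (stoichiometric conversion). Non-monotonicity beyond `tolerance` is
#' flagged, not fatal.
#'
#' @param series Tibble with columns `molar_ratio` and list-column `trace`
#'   (e.g. from [simulate_titration_series()]), or a list of
#'   `list(molar_ratio, trace)` pairs. At least 2 ratios including one
#'   `>= 1`.
#' @param tolerance Allowed non-monotone dip in `f_inactive` (absolute).
#'
#' @return Tibble with columns `molar_ratio`, `f_active`, `f_inactive` and
#'   attribute `monotone` (logical).
#' @export
analyze_titration <- function(series, tolerance = 0.03) {
  if (!is.data.frame(series)) {
    series <- tibble::tibble(
      molar_ratio = vapply(series, function(e) e$molar_ratio, numeric(1)),
      trace = lapply(series, function(e) e$trace))
  }
  stopifnot(all(c("molar_ratio", "trace") %in% names(series)),
            nrow(series) >= 2L)
  if (!any(series$molar_ratio >= 1)) {
    stop("titration series must include a molar ratio >= 1", call. = FALSE)
  }
  series <- dplyr::arrange(series, .data$molar_ratio)
  # pass 1: unconstrained fits to locate the two line positions across the
  # whole series (an endpoint trace may show only one of the two lines)
  fits1 <- purrr::map(series$trace,
                      function(tr) suppressWarnings(fit_two_peaks(tr)))
  sig <- dplyr::bind_rows(purrr::map(fits1, function(f) {
    f$peaks[f$peaks$area >= 0.05 * sum(f$peaks$area), ]
  }))
  down <- max(sig$center)
  up <- min(sig$center)
  if ((down - up) > mean(sig$fwhm)) {
    # pass 2: refit every trace with the consensus line positions anchored,
    # so a vanished line keeps its label at its known position
    pops <- purrr::map(series$trace, function(tr) {
      estimate_populations(suppressWarnings(
        fit_two_peaks(tr, init_centers = c(down, up),
                      center_window = (down - up) / 4)))
    })
  } else {
    pops <- purrr::map(fits1, estimate_populations)
  }
  out <- dplyr::bind_cols(series["molar_ratio"], dplyr::bind_rows(pops))
  monotone <- all(diff(out$f_inactive) >= -tolerance)
  if (!monotone) {
    warning("f_inactive is non-monotone in molar ratio beyond tolerance ",
            tolerance, call. = FALSE)
  }
  attr(out, "monotone") <- monotone
  out
}
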