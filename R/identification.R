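#' Construct a centroided mass spectrum
#'
#' A stick spectrum: unique m/z positions with nonnegative finite
#' intensities, at least one of them positive.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Numeric vector of intensities (>= 0), same length.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) stopf("mz and intensity lengths differ")
  if (length(mz) == 0) stopf("spectrum needs at least one peak")
  if (any(!is.finite(mz)) || any(mz <= 0)) stopf("m/z values must be finite and > 0")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("intensities must be finite and >= 0")
  if (anyDuplicated(mz)) stopf("duplicate m/z values within spectrum")
  if (all(intensity == 0)) stopf("spectrum has all-zero intensities")
  ord <- order(mz)
  structure(list(mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord])),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum: %d peaks, m/z %g-%g, base peak %g\n",
              length(x$mz), min(x$mz), max(x$mz), x$mz[which.max(x$intensity)]))
  invisible(x)
}

#' Construct a spectral library entry
#'
#' @param name Compound name.
#' @param spectrum A [mass_spectrum()].
#' @param reference_ri Reference retention index (> 0).
#' @return An object of class `spectral_library_entry`.
#' @export
spectral_library_entry <- function(name, spectrum, reference_ri) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (!is.finite(reference_ri) || reference_ri <= 0)
    stopf("reference_ri must be positive")
  structure(list(name = as.character(name), spectrum = spectrum,
                 reference_ri = as.numeric(reference_ri)),
            class = "spectral_library_entry")
}

#' Construct an n-alkane retention-time ladder
#'
#' @param carbons Integer carbon numbers, ascending, within 10..40.
#' @param retention_times Strictly increasing retention times (seconds).
#' @return An object of class `alkane_series`.
#' @export
alkane_series <- function(carbons, retention_times) {
  if (length(carbons) != length(retention_times)) stopf("length mismatch")
  if (length(carbons) < 2) stopf("ladder needs >= 2 alkanes")
  if (any(carbons < 10 | carbons > 40)) stopf("carbons must lie in 10..40")
  if (any(diff(carbons) <= 0)) stopf("carbons must be strictly increasing")
  if (any(diff(retention_times) <= 0))
    stopf("retention times must be strictly increasing")
  structure(list(carbons = as.integer(carbons),
                 retention_times = as.numeric(retention_times)),
            class = "alkane_series")
}

# Half-up rounding to an integer (round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Weighted dot-product spectral match value
#'
#' Similarity of two stick spectra on the 0-999 scale. Peaks are aligned on a
#' shared nominal-mass grid (m/z rounded to the nearest integer; a peak
#' missing from the other spectrum contributes zero there), each intensity is
#' weighted as `mz^mass_exponent * I^intensity_exponent` so that higher,
#' more compound-specific m/z peaks count more, and the squared cosine of the
#' two weighted vectors is scaled to 999 and rounded half-up. A spectrum
#' matched against itself scores exactly 999; spectra sharing no m/z score 0.
#' The score is symmetric and invariant to scaling either spectrum's
#' intensities by a positive constant.
#'
#' @param query,reference [mass_spectrum()] objects.
#' @param mass_exponent,intensity_exponent Weighting exponents; the defaults
#'   (3, 0.6) follow the common library-search convention.
#' @return Integer-valued score in [0, 999].
#' @export
match_value <- function(query, reference, mass_exponent = 3,
                        intensity_exponent = 0.6) {
  stopifnot(inherits(query, "mass_spectrum"), inherits(reference, "mass_spectrum"))
  weigh <- function(sp) {
    mz <- round_half_up(sp$mz)
    w <- mz^mass_exponent * sp$intensity^intensity_exponent
    tapply(w, mz, sum)
  }
  u <- weigh(query); q <- weigh(reference)
  grid <- union(names(u), names(q))
  uu <- ifelse(grid %in% names(u), u[grid], 0)
  qq <- ifelse(grid %in% names(q), q[grid], 0)
  num <- sum(uu * qq)^2
  den <- sum(uu^2) * sum(qq^2)
  if (den == 0) stopf("spectrum has zero weighted intensity")
  as.integer(round_half_up(999 * num / den))
}

#' Retention index by alkane interpolation
#'
#' Piecewise-linear (van den Dool/Kratz) index for an isothermal-rate
#' temperature program: between bracketing alkanes with carbon numbers c_n
#' and c_{n+1}, `RI = 100 c_n + 100 (c_{n+1} - c_n) (rt - t_n)/(t_{n+1} -
#' t_n)`. No extrapolation outside the ladder range.
#'
#' @param rt Retention time in seconds (vectorized).
#' @param ladder An [alkane_series()].
#' @return Retention index (C10 = 1000, ..., C40 = 4000).
#' @export
retention_index <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_series"))
  tt <- ladder$retention_times
  cc <- ladder$carbons
  if (any(rt < tt[1] | rt > tt[length(tt)]))
    stopf("retention time outside ladder range [%g, %g]", tt[1], tt[length(tt)])
  idx <- pmin(findInterval(rt, tt), length(tt) - 1L)
  100 * cc[idx] + 100 * (cc[idx + 1L] - cc[idx]) *
    (rt - tt[idx]) / (tt[idx + 1L] - tt[idx])
}

#' Identify a spectrum against a reference library
#'
#' Candidates are the library entries whose reference retention index lies
#' within `ri_window` of the query's; among them the highest match value
#' wins, with ties broken by smaller absolute retention-index deviation and
#' then lexicographic name. The winner is returned only if its match value
#' reaches `min_match`; otherwise (or with no candidates) `NULL`.
#'
#' @param query A [mass_spectrum()].
#' @param query_ri The query's retention index.
#' @param library List of [spectral_library_entry()] objects.
#' @param min_match Minimum acceptable match value (default 700).
#' @param ri_window Retention-index acceptance half-width (default 10).
#' @param ... Passed to [match_value()].
#' @return A list (`name`, `match_value`, `ri_deviation`, `accepted`) or
#'   `NULL` when nothing is acceptable.
#' @export
identify_spectrum <- function(query, query_ri, library, min_match = 700,
                              ri_window = 10, ...) {
  if (ri_window <= 0) stopf("ri_window must be positive")
  if (length(library) == 0) return(NULL)
  dev <- vapply(library, function(e) query_ri - e$reference_ri, numeric(1))
  cand <- which(abs(dev) <= ri_window)
  if (length(cand) == 0) return(NULL)
  mv <- vapply(library[cand], function(e) match_value(query, e$spectrum, ...),
               numeric(1))
  nm <- vapply(library[cand], function(e) e$name, character(1))
  ord <- order(-mv, abs(dev[cand]), nm)
  best <- ord[1]
  if (mv[best] < min_match) return(NULL)
  list(name = nm[best], match_value = mv[best], ri_deviation = dev[cand][best],
       accepted = TRUE)
}

#' Read and write MSP-style spectral libraries
#'
#' Minimal NAME/RI/Num Peaks block format: one block per compound, peaks as
#' "mz intensity" lines.
#'
#' @param path File path.
#' @return `read_msp()` returns a list of [spectral_library_entry()].
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  entries <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^NAME:", lines[i])) {
      name <- trimws(sub("^NAME:", "", lines[i]))
      ri <- as.numeric(trimws(sub("^RI:", "", lines[i + 1])))
      n <- as.integer(trimws(sub("^Num Peaks:", "", lines[i + 2])))
      peaks <- do.call(rbind, lapply(lines[i + 2 + seq_len(n)], function(l)
        as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
      entries[[length(entries) + 1L]] <- spectral_library_entry(
        name, mass_spectrum(peaks[, 1], peaks[, 2]), ri)
      i <- i + 3L + n
    } else i <- i + 1L
  }
  entries
}

#' @rdname read_msp
#' @param library List of [spectral_library_entry()] objects.
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in library) {
    writeLines(c(sprintf("NAME: %s", e$name),
                 sprintf("RI: %.6g", e$reference_ri),
                 sprintf("Num Peaks: %d", length(e$spectrum$mz)),
                 sprintf("%g %g", e$spectrum$mz, e$spectrum$intensity),
                 ""), con)
  }
  invisible(path)
}
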