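# Spectral irradiance objects, I/O, unit conversion, resampling and
# waveband photon integration.

# CODATA constants; hc*NA in J m mol^-1
.PLANCK <- 6.62607015e-34
.LIGHTSPEED <- 2.99792458e8
.AVOGADRO <- 6.02214076e23

#' Spectral irradiance object
#'
#' Container for a measured or simulated solar spectrum: a strictly
#' increasing wavelength grid (nm) with spectral photon irradiance
#' (µmol m⁻² s⁻¹ nm⁻¹) or spectral energy irradiance (W m⁻² nm⁻¹), plus
#' metadata identifying the stand, day of year (DOY), measurement position
#' (sunfleck, shade, leaf or open) and measurement point.
#'
#' Negative values (common instrument noise in the UV-B tail of calibrated
#' field spectra) are clipped to zero on construction; the number of
#' clipped samples is retained in the `clip_count` attribute.
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths
#'   in nm.
#' @param values numeric vector of spectral irradiance, same length as
#'   `wavelengths_nm`.
#' @param unit `"photon"` (µmol m⁻² s⁻¹ nm⁻¹) or `"energy"`
#'   (W m⁻² nm⁻¹); decides integration semantics downstream.
#' @param stand,doy,position,point,timestamp optional metadata. `position`
#'   must be one of `"sunfleck"`, `"shade"`, `"leaf"`, `"open"` when given.
#' @return an object of class `spectral_irradiance`.
#' @export
spectral_irradiance <- function(wavelengths_nm, values,
                                unit = c("photon", "energy"),
                                stand = NA_character_, doy = NA_integer_,
                                position = NA_character_,
                                point = NA_character_,
                                timestamp = NA_character_) {
  unit <- match.arg(unit)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least two samples")
  if (length(values) != length(wavelengths_nm))
    stop("wavelengths and values differ in length")
  if (anyNA(wavelengths_nm) || anyNA(values))
    stop("NA in spectrum")
  if (any(diff(wavelengths_nm) <= 0))
    stop("non-monotone grid: wavelengths must be strictly increasing")
  if (!is.na(position) &&
      !position %in% c("sunfleck", "shade", "leaf", "open"))
    stop("unknown position: ", position)
  clip <- sum(values < 0)
  values[values < 0] <- 0
  structure(
    list(wavelengths_nm = wavelengths_nm, values = values, unit = unit,
         meta = list(stand = stand, doy = as.integer(doy),
                     position = position, point = point,
                     timestamp = timestamp)),
    clip_count = clip,
    class = "spectral_irradiance")
}

#' @export
print.spectral_irradiance <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("<spectral_irradiance> %d samples, %.1f-%.1f nm, %s units\n",
              length(x$values), rng[1], rng[2], x$unit))
  m <- x$meta
  if (!is.na(m$stand) || !is.na(m$doy) || !is.na(m$position))
    cat(sprintf("  stand=%s doy=%s position=%s point=%s\n",
                m$stand, m$doy, m$position, m$point))
  invisible(x)
}

#' Read a spectrum from its CSV dialect
#'
#' The file format is plain CSV with leading `# key=value` comment lines
#' holding metadata (`stand`, `doy`, `position`, `point`, `unit`,
#' `timestamp`) followed by a `wavelength_nm,value` header and two numeric
#' columns, `.` decimal separator, UTF-8.
#'
#' @param path file path.
#' @param unit unit flag overriding (or supplying, if absent) the file's
#'   `unit` metadata line.
#' @return a [spectral_irradiance()] object; negatives clipped with the
#'   clip count in `attr(, "clip_count")`.
#' @export
read_spectrum <- function(path, unit = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in sub("^#\\s*", "", lines[is_meta])) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_meta]
  if (!length(body)) stop("no data rows in ", path)
  tab <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(tab)))
    stop("missing columns: expected wavelength_nm,value in ", path)
  u <- if (!is.null(unit)) unit else meta$unit
  if (is.null(u)) stop("unit not given and not in file metadata")
  spectral_irradiance(
    tab$wavelength_nm, tab$value, unit = u,
    stand = meta$stand %||% NA_character_,
    doy = as.integer(meta$doy %||% NA),
    position = meta$position %||% NA_character_,
    point = meta$point %||% NA_character_,
    timestamp = meta$timestamp %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum in the CSV dialect read by [read_spectrum()]
#'
#' @param spectrum a [spectral_irradiance()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectral_irradiance"))
  m <- spectrum$meta
  hdr <- c(
    sprintf("# unit=%s", spectrum$unit),
    if (!is.na(m$stand)) sprintf("# stand=%s", m$stand),
    if (!is.na(m$doy)) sprintf("# doy=%d", m$doy),
    if (!is.na(m$position)) sprintf("# position=%s", m$position),
    if (!is.na(m$point)) sprintf("# point=%s", m$point),
    if (!is.na(m$timestamp)) sprintf("# timestamp=%s", m$timestamp))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.10g,%.10g", spectrum$wavelengths_nm,
                     spectrum$values), con)
  invisible(path)
}

#' Convert spectral energy irradiance to photon irradiance
#'
#' Per wavelength, N(λ) = E(λ)·λ / (h·c·N_A) with λ in m, giving
#' mol m⁻² s⁻¹ nm⁻¹, scaled to µmol. Uses exact CODATA constants.
#'
#' @param spectrum a [spectral_irradiance()] with `unit == "energy"`.
#' @return the same spectrum in photon units.
#' @export
energy_to_photon <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectral_irradiance"))
  if (spectrum$unit != "energy")
    stop("spectrum is not in energy units")
  factor_umol <- (spectrum$wavelengths_nm * 1e-9) /
    (.PLANCK * .LIGHTSPEED * .AVOGADRO) * 1e6
  out <- spectrum
  out$values <- spectrum$values * factor_umol
  out$unit <- "photon"
  attr(out, "clip_count") <- attr(spectrum, "clip_count")
  out
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; no extrapolation outside the source coverage.
#'
#' @param spectrum a [spectral_irradiance()].
#' @param grid target wavelengths (nm), strictly increasing, within the
#'   source coverage.
#' @return the resampled spectrum.
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "spectral_irradiance"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid not strictly increasing")
  rng <- range(spectrum$wavelengths_nm)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop("target grid outside source coverage (no extrapolation)")
  out <- spectrum
  out$wavelengths_nm <- grid
  out$values <- stats::approx(spectrum$wavelengths_nm, spectrum$values,
                              xout = grid, method = "linear")$y
  attr(out, "clip_count") <- attr(spectrum, "clip_count")
  out
}

#' Wavebands
#'
#' A waveband is a half-open interval \[lower, upper) of wavelengths in nm.
#' The half-open closure means adjacent bands (UV-B and UV-A at 315 nm,
#' UV-A and PAR at 400 nm) partition the spectrum without double counting.
#'
#' @param name band label.
#' @param lower_nm,upper_nm band bounds in nm, `lower_nm < upper_nm`.
#' @return an object of class `waveband`.
#' @export
waveband <- function(name, lower_nm, upper_nm) {
  if (!(lower_nm < upper_nm)) stop("waveband needs lower < upper")
  structure(list(name = name, lower_nm = lower_nm, upper_nm = upper_nm),
            class = "waveband")
}

#' @describeIn waveband the canonical bands: UV-B \[280,315), UV-A
#'   \[315,400), PAR \[400,700), RED \[655,665), FAR_RED \[725,735).
#' @export
canonical_bands <- function() {
  list(UVB = waveband("UVB", 280, 315),
       UVA = waveband("UVA", 315, 400),
       PAR = waveband("PAR", 400, 700),
       RED = waveband("RED", 655, 665),
       FAR_RED = waveband("FAR_RED", 725, 735))
}

# Trapezoid integral of (x, y) over [lo, hi) with virtual samples linearly
# interpolated at the band edges, so adjacent bands tile exactly.
.trapz_band <- function(x, y, lo, hi) {
  if (lo < x[1] || hi > x[length(x)])
    stop(sprintf("insufficient coverage: band [%g,%g) vs grid [%g,%g]",
                 lo, hi, x[1], x[length(x)]))
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)])) / 2
}

#' Integrate photon irradiance over a waveband
#'
#' Trapezoidal integration of the spectrum over the half-open band, with
#' virtual samples interpolated exactly at the band edges so that adjacent
#' bands sum to the integral of their union.
#'
#' @param spectrum a [spectral_irradiance()] in photon units whose
#'   coverage contains the band.
#' @param band a [waveband()].
#' @return photon irradiance in µmol m⁻² s⁻¹.
#' @export
integrate_band <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "spectral_irradiance"),
            inherits(band, "waveband"))
  if (spectrum$unit != "photon")
    stop("integrate_band needs photon units; see energy_to_photon()")
  .trapz_band(spectrum$wavelengths_nm, spectrum$values,
              band$lower_nm, band$upper_nm)
}

#' Leaf-extract absorbance spectrum
#'
#' Absorbance (AU) of a methanolic leaf-disk extract versus wavelength,
#' with the dilution factor, extract volume and leaf fresh weight needed to
#' normalise band summaries. Raw absorbance above 2 AU is outside the
#' reliable photometric range and triggers a warning (samples should have
#' been diluted).
#'
#' @param wavelengths_nm strictly increasing wavelengths (nm).
#' @param absorbance absorbance values (AU), finite.
#' @param dilution dilution factor, >= 1.
#' @param volume_ml extract volume (ml).
#' @param fresh_weight_g leaf fresh weight (g), > 0 for normalisation.
#' @return an object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelengths_nm, absorbance, dilution = 1,
                                volume_ml = NA_real_,
                                fresh_weight_g = NA_real_) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  absorbance <- as.numeric(absorbance)
  if (any(diff(wavelengths_nm) <= 0)) stop("non-monotone grid")
  if (length(absorbance) != length(wavelengths_nm))
    stop("length mismatch")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  if (dilution < 1) stop("dilution factor must be >= 1")
  if (any(absorbance > 2))
    warning("absorbance > 2 AU before normalisation; sample should be diluted")
  structure(list(wavelengths_nm = wavelengths_nm, absorbance = absorbance,
                 dilution = dilution, volume_ml = volume_ml,
                 fresh_weight_g = fresh_weight_g),
            class = "absorbance_spectrum")
}

#' Band summaries of a leaf-extract absorbance spectrum
#'
#' The four quantities compared against the optical flavonol index:
#' absorbance at 375 nm, and mean absorbance over the UV-B, UV-A and whole
#' UV (280-400 nm) bands (band integral divided by band width). Normalised
#' versions are raw × dilution × volume / fresh weight, in AU·ml·g⁻¹.
#'
#' @param abs_spec an [absorbance_spectrum()] covering 280-400 nm.
#' @return a one-row data.frame with columns `A375`, `mean_UVB`,
#'   `mean_UVA`, `mean_UV` and (when volume and fresh weight are known)
#'   their `_norm` counterparts.
#' @export
extract_band_summary <- function(abs_spec) {
  stopifnot(inherits(abs_spec, "absorbance_spectrum"))
  x <- abs_spec$wavelengths_nm
  y <- abs_spec$absorbance
  if (x[1] > 280 || x[length(x)] < 400)
    stop("coverage must contain 280-400 nm")
  band_mean <- function(lo, hi) .trapz_band(x, y, lo, hi) / (hi - lo)
  out <- data.frame(
    A375 = stats::approx(x, y, xout = 375)$y,
    mean_UVB = band_mean(280, 315),
    mean_UVA = band_mean(315, 400),
    mean_UV = band_mean(280, 400))
  if (!is.na(abs_spec$volume_ml) && !is.na(abs_spec$fresh_weight_g)) {
    if (abs_spec$fresh_weight_g <= 0) stop("fresh weight must be > 0")
    k <- abs_spec$dilution * abs_spec$volume_ml / abs_spec$fresh_weight_g
    norm <- out * k
    names(norm) <- paste0(names(out), "_norm")
    out <- cbind(out, norm)
  }
  out
}
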