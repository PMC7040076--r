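# Biological spectral weighting functions (BSWFs), effective UV doses and
# the red:far-red photon ratio.
#
# All BSWFs are normalised to w = 1 at a reference wavelength (default
# 300 nm, the community convention) and are zero outside their domain.

#' Biological spectral weighting function
#'
#' A BSWF is a non-negative weight w(λ) expressing the biological
#' effectiveness of radiation at wavelength λ; the effective dose of a
#' spectrum E(λ) is the integral of w(λ)·E(λ). Closed-form and tabulated
#' (linearly interpolated) forms are supported; both are normalised so
#' that w(normalization_nm) = 1 exactly and are zero outside
#' `domain_nm`.
#'
#' @param name label, e.g. `"PG"`.
#' @param raw_fun vectorised function λ → raw (unnormalised) weight;
#'   exactly one of `raw_fun` / `nodes` must be given.
#' @param nodes two-column data.frame/matrix (`lambda_nm`, `weight`) of
#'   interpolation nodes, strictly increasing in wavelength, weights >= 0.
#' @param domain_nm numeric length-2, wavelength domain outside which the
#'   weight is zero.
#' @param normalization_nm normalization wavelength (default 300 nm).
#' @return an object of class `bswf`: calling `bswf_weight(b, lambda)`
#'   evaluates the normalised weight.
#' @export
bswf <- function(name, raw_fun = NULL, nodes = NULL,
                 domain_nm, normalization_nm = 300) {
  if (is.null(raw_fun) == is.null(nodes))
    stop("give exactly one of raw_fun or nodes")
  if (!is.null(nodes)) {
    nodes <- as.data.frame(nodes)
    names(nodes)[1:2] <- c("lambda_nm", "weight")
    if (any(diff(nodes$lambda_nm) <= 0))
      stop("nodes must be strictly increasing in wavelength")
    if (any(nodes$weight < 0)) stop("node weights must be >= 0")
    raw_fun <- local({
      nd <- nodes
      function(l) {
        out <- numeric(length(l))
        ok <- l >= nd$lambda_nm[1] & l <= nd$lambda_nm[nrow(nd)]
        if (any(ok))
          out[ok] <- stats::approx(nd$lambda_nm, nd$weight, xout = l[ok])$y
        out
      }
    })
  }
  anchor <- raw_fun(normalization_nm)
  if (!is.finite(anchor) || anchor <= 0)
    stop("raw weight at the normalization wavelength must be positive")
  structure(list(name = name, raw_fun = raw_fun, nodes = nodes,
                 domain_nm = as.numeric(domain_nm),
                 normalization_nm = normalization_nm, anchor = anchor),
            class = "bswf")
}

#' Evaluate a normalised BSWF weight
#'
#' @param b a [bswf()].
#' @param lambda_nm wavelengths (nm), vectorised.
#' @return normalised weights; exactly 0 outside the domain and exactly 1
#'   at the normalization wavelength.
#' @export
bswf_weight <- function(b, lambda_nm) {
  stopifnot(inherits(b, "bswf"))
  out <- numeric(length(lambda_nm))
  ok <- lambda_nm >= b$domain_nm[1] & lambda_nm <= b$domain_nm[2]
  if (any(ok)) out[ok] <- b$raw_fun(lambda_nm[ok]) / b$anchor
  out
}

#' @export
print.bswf <- function(x, ...) {
  cat(sprintf("<bswf> %s (%s), domain %g-%g nm, w(%g)=1\n", x$name,
              if (is.null(x$nodes)) "closed form" else
                sprintf("%d nodes", nrow(x$nodes)),
              x$domain_nm[1], x$domain_nm[2], x$normalization_nm))
  invisible(x)
}

# Plant-growth action spectrum, mathematical formulation (raw form,
# nonzero up to 390 nm):
#   exp{4.688272·exp[-exp(0.1703411·(λ-307.867)/1.15)]
#       + (390-λ)/121.7557 - 4.183832}
.pg_raw <- function(l) {
  out <- numeric(length(l))
  ok <- l <= 390
  out[ok] <- exp(4.688272 * exp(-exp(0.1703411 * (l[ok] - 307.867) / 1.15)) +
                   ((390 - l[ok]) / 121.7557 - 4.183832))
  out
}

# Generalised plant action spectrum, mathematical formulation GEN(G)
# (raw form, vanishes at and above 313.3 nm):
#   2.618·[1-(λ/313.3)²]·exp(-(λ-300)/31.08)
.gen_g_raw <- function(l) {
  out <- numeric(length(l))
  ok <- l < 313.3
  out[ok] <- 2.618 * (1 - (l[ok] / 313.3)^2) * exp(-(l[ok] - 300) / 31.08)
  out
}

#' Built-in weighting functions
#'
#' `bswf_pg()` is the plant-growth (PG) action spectrum in its closed
#' mathematical formulation, spanning the UV-B and UV-A regions up to
#' 390 nm. `bswf_gen_g()` is the mathematical formulation of the
#' generalised plant action spectrum GEN(G), nonzero only below 313.3 nm.
#' `bswf_flav()` is a weighting function for UV-driven flavonoid
#' accumulation built from the node table shipped with the package; the
#' shipped table is a synthetic stand-in with the qualitative shape of
#' published flavonoid-accumulation spectra (monotone decline from UV-B
#' into UV-A, zero by 400 nm), not a transcription of a published table.
#'
#' All are normalised to 1 at `normalization_nm`.
#'
#' @param normalization_nm normalization wavelength, default 300 nm.
#' @return a [bswf()].
#' @export
bswf_pg <- function(normalization_nm = 300) {
  bswf("PG", raw_fun = .pg_raw, domain_nm = c(250, 390),
       normalization_nm = normalization_nm)
}

#' @rdname bswf_pg
#' @export
bswf_gen_g <- function(normalization_nm = 300) {
  bswf("GEN_G", raw_fun = .gen_g_raw, domain_nm = c(250, 313.3),
       normalization_nm = normalization_nm)
}

#' @rdname bswf_pg
#' @param nodes_file path to a 2-column CSV (`lambda_nm,weight`);
#'   defaults to the synthetic table in the package's `extdata`.
#' @export
bswf_flav <- function(normalization_nm = 300, nodes_file = NULL) {
  if (is.null(nodes_file))
    nodes_file <- system.file("extdata", "bswf_flav_synthetic.csv",
                              package = "photodose", mustWork = TRUE)
  nodes <- utils::read.csv(nodes_file, comment.char = "#")
  bswf("FLAV", nodes = nodes,
       domain_nm = range(nodes$lambda_nm),
       normalization_nm = normalization_nm)
}

#' The default BSWF registry
#'
#' @return named list of the three built-in [bswf()] objects (PG, FLAV,
#'   GEN_G).
#' @export
bswf_registry <- function() {
  list(PG = bswf_pg(), FLAV = bswf_flav(), GEN_G = bswf_gen_g())
}

#' Biologically effective UV dose
#'
#' Trapezoidal integral of w(λ)·E(λ) over the intersection of the BSWF
#' domain and the spectrum coverage, with the weight evaluated on the
#' spectrum's own grid (measured values are never resampled). The result
#' is in weighted photon units, µmol m⁻² s⁻¹.
#'
#' @param spectrum a [spectral_irradiance()] in photon units.
#' @param b a [bswf()].
#' @return a one-row data.frame: `dose`, `bswf`, `normalization_nm` plus
#'   the spectrum metadata columns.
#' @export
effective_dose <- function(spectrum, b) {
  stopifnot(inherits(spectrum, "spectral_irradiance"), inherits(b, "bswf"))
  if (spectrum$unit != "photon")
    stop("effective_dose needs photon units; see energy_to_photon()")
  x <- spectrum$wavelengths_nm
  lo <- max(b$domain_nm[1], x[1])
  hi <- min(b$domain_nm[2], x[length(x)])
  dose <- 0
  if (lo < hi) {
    # the measured spectrum is piecewise linear on its grid; the weight
    # function is smooth but may have kinks (domain edges, table nodes),
    # so w is sampled on a 5x refined sub-grid with the domain edges
    # inserted as explicit nodes before the trapezoid pass
    inside <- x > lo & x < hi
    xs <- sort(unique(c(lo, hi, x[inside],
                        lo + (hi - lo) * seq(0, 1, length.out =
                                               5L * (sum(inside) + 1L)))))
    e <- stats::approx(x, spectrum$values, xout = xs)$y
    wy <- bswf_weight(b, xs) * e
    dose <- sum(diff(xs) * (wy[-1] + wy[-length(wy)])) / 2
  }
  m <- spectrum$meta
  data.frame(dose = dose, bswf = b$name,
             normalization_nm = b$normalization_nm,
             stand = m$stand, doy = m$doy, position = m$position,
             point = m$point, stringsAsFactors = FALSE)
}

#' Red : far-red photon ratio
#'
#' Photon integral over RED \[655,665) divided by the photon integral over
#' FAR_RED \[725,735), the standard 10-nm-band convention. Depressed under
#' leaf-filtered light because chlorophyll absorbs red but not far-red.
#'
#' @param spectrum a [spectral_irradiance()] in photon units covering
#'   655-735 nm.
#' @return dimensionless ratio.
#' @export
red_far_red_ratio <- function(spectrum) {
  b <- canonical_bands()
  red <- integrate_band(spectrum, b$RED)
  fr <- integrate_band(spectrum, b$FAR_RED)
  if (fr <= 0) stop("undefined R:FR: far-red integral is zero")
  red / fr
}

#' Tidy dose table for a set of spectra
#'
#' For each spectrum computes the waveband photon irradiances (PPFD,
#' UV-B, UV-A), the effective doses for every registered BSWF, and the
#' red:far-red ratio — the full quantity set used in the stand × DOY ×
#' position summaries and the irradiance-correlation analysis.
#'
#' @param spectra list of [spectral_irradiance()] objects (photon units).
#' @param registry named list of [bswf()]s, default [bswf_registry()].
#' @return a data.frame with one row per spectrum: stand, doy, position,
#'   point, PPFD, UVB, UVA, one column per BSWF, R_FR.
#' @export
dose_table <- function(spectra, registry = bswf_registry()) {
  bands <- canonical_bands()
  rows <- lapply(spectra, function(s) {
    m <- s$meta
    row <- data.frame(stand = m$stand, doy = m$doy, position = m$position,
                      point = m$point,
                      PPFD = integrate_band(s, bands$PAR),
                      UVB = integrate_band(s, bands$UVB),
                      UVA = integrate_band(s, bands$UVA),
                      stringsAsFactors = FALSE)
    for (nm in names(registry))
      row[[nm]] <- effective_dose(s, registry[[nm]])$dose
    row$R_FR <- red_far_red_ratio(s)
    row
  })
  do.call(rbind, rows)
}
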