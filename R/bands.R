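#' Define a vibrational band
#'
#' A band is a single Raman line described by its centre, half-width at
#' half-maximum, peak amplitude, line shape and a class-dependent
#' attenuation factor. `case_attenuation < 1` means the band is less
#' intense in case-class (diseased) spectra, emulating the loss of
#' collagen-associated signal seen in malignant biofluids.
#'
#' @param center Band centre, in wavenumbers (cm^-1).
#' @param width Half-width at half-maximum (cm^-1); must be positive.
#' @param amplitude Peak intensity in arbitrary units; non-negative.
#' @param shape `"lorentzian"` (default; Raman lines are near-Lorentzian)
#'   or `"gaussian"`.
#' @param case_attenuation Multiplicative factor in \[0, 1\] applied to
#'   `amplitude` for case-class spectra. 1 means the band does not
#'   discriminate.
#' @return A one-row data frame with class `band_spec` columns.
#' @export
band_spec <- function(center, width, amplitude, shape = c("lorentzian", "gaussian"),
                      case_attenuation = 1) {
  shape <- match.arg(shape)
  stopifnot(is.finite(center), width > 0, amplitude >= 0,
            case_attenuation >= 0, case_attenuation <= 1)
  data.frame(center = center, width = width, amplitude = amplitude,
             shape = shape, case_attenuation = case_attenuation,
             stringsAsFactors = FALSE)
}

#' Default band library for simulated biofluid spectra
#'
#' The library mirrors the biofingerprint of a protein-rich biofluid:
#' a dominant, class-neutral background of broad protein/lipid bands
#' (ring breathing, C-C/C-O stretching, Amide III, CH envelopes, the
#' Amide I envelope) carrying most of the Raman intensity, on top of
#' which four narrower collagen-associated bands — phenylalanine at
#' 1004 cm^-1, CH3CH2 wagging at 1334 cm^-1, CH2 deformation at
#' 1448 cm^-1 and Amide I at 1657 cm^-1 — are attenuated in the case
#' (diseased) class. The neutral 1342 cm^-1 (CH deformation) and
#' 1660 cm^-1 (protein Amide I) lines sit next to two of the
#' discriminant bands, as in real biofluid spectra.
#'
#' Disease-related intensity changes in biofluids are small
#' perturbations of a large shared spectral background; the
#' discriminant bands therefore carry only a modest share of the total
#' intensity, which keeps multiplicative corrections (EMSC, vector
#' normalisation) from converting planted band attenuation into
#' spurious apparent changes elsewhere (spectral closure). Amplitudes
#' and the default attenuation (0.85) are simulation choices — no
#' measured effect sizes exist — documented in the methods vignette
#' and swept in tests.
#'
#' @param attenuation Case attenuation applied to the four discriminant
#'   bands (default 0.85). Set to 1 for a null (exchangeable-classes)
#'   library.
#' @return A data frame of `band_spec` rows with a logical
#'   `discriminant` column.
#' @export
default_band_library <- function(attenuation = 0.85) {
  stopifnot(attenuation >= 0, attenuation <= 1)
  lib <- rbind(
    # discriminant collagen-associated bands (narrow, prominent)
    band_spec(1004, 4,  0.80, case_attenuation = attenuation), # phenylalanine
    band_spec(1334, 7,  0.80, case_attenuation = attenuation), # CH3CH2 wagging
    band_spec(1448, 8,  0.80, case_attenuation = attenuation), # CH2 deformation
    band_spec(1657, 9,  0.80, case_attenuation = attenuation), # Amide I
    # neutral neighbours of the discriminant bands
    band_spec(1342, 6,  0.35),   # CH deformation
    band_spec(1660, 9,  0.40),   # Amide I (proteins)
    # broad shared protein/lipid background (class neutral); carries
    # most of the total intensity, as in real protein-rich biofluids
    band_spec(760,  10, 0.90),   # tryptophan ring breathing
    band_spec(820,  12, 0.90),   # tyrosine doublet
    band_spec(880,  12, 1.00),   # tryptophan / C-C skeletal
    band_spec(940,  14, 1.10),   # C-C backbone
    band_spec(1030, 14, 0.90),   # phenylalanine C-H in-plane
    band_spec(1080, 18, 1.20),   # C-C / C-O stretching
    band_spec(1130, 14, 0.90),   # C-N stretching
    band_spec(1210, 16, 1.10),   # C-C6H5 stretching
    band_spec(1250, 18, 1.40),   # Amide III
    band_spec(1310, 16, 1.20),   # CH deformation envelope
    band_spec(1400, 16, 1.00),   # COO- symmetric stretch
    band_spec(1420, 14, 1.10),   # CH2/CH3 envelope
    band_spec(1550, 15, 0.90),   # tryptophan / amide II remnant
    band_spec(1585, 12, 0.70),   # phenylalanine ring
    band_spec(1620, 14, 0.90),   # tyrosine / tryptophan
    band_spec(1690, 16, 0.90),   # Amide I shoulder
    band_spec(1745, 12, 0.70)    # lipid C=O ester
  )
  lib$discriminant <- lib$case_attenuation < 1
  lib
}

# Evaluate the noiseless band-sum profile of one class on an axis.
# Closed form: sum over bands of amp * shape((nu - center)/width),
# lorentzian = 1/(1+u^2), gaussian = exp(-log(2) u^2) (u in HWHM units).
band_profile <- function(bands, axis, class = c("control", "case")) {
  class <- match.arg(as.character(class), c("control", "case"))
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    amp <- bands$amplitude[i]
    if (class == "case") amp <- amp * bands$case_attenuation[i]
    u <- (axis - bands$center[i]) / bands$width[i]
    y <- y + if (bands$shape[i] == "gaussian") amp * exp(-log(2) * u^2)
             else amp / (1 + u^2)
  }
  y
}
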