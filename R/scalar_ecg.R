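# Kors regression matrix for synthesizing the vectorcardiogram from the
# eight independent standard leads. Coefficients from Kors JA, van Herpen G,
# Sittig AC, van Bemmel JH, Eur Heart J 1990;11:1083-92 (Table; regression
# method). Rows X/Y/Z, columns in the order V1..V6, I, II. Version 1990-1.
KORS_MATRIX <- matrix(
  c(-0.13,  0.05, -0.01,  0.14,  0.06,  0.54,  0.38, -0.07,
     0.06, -0.02, -0.05,  0.06, -0.17,  0.13, -0.07,  0.93,
    -0.43, -0.06, -0.14, -0.20, -0.11,  0.31,  0.11, -0.23),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"),
                  c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")))

#' Reconstruct unipolar limb leads from the augmented leads
#'
#' The augmented (Goldberger) limb leads are scaled true unipolar limb
#' potentials referenced to the Wilson central terminal: each unipolar lead
#' equals 2/3 of its augmented counterpart (VR = 2/3 aVR, VL = 2/3 aVL,
#' VF = 2/3 aVF).
#'
#' @param avr,avl,avf simultaneous augmented-lead time series (microvolts),
#'   equal length.
#' @return list with elements `VR`, `VL`, `VF`.
#' @export
reconstruct_unipolar <- function(avr, avl, avf) {
  n <- length(avr)
  if (length(avl) != n || length(avf) != n)
    stop("augmented leads must have identical length")
  list(VR = (2 / 3) * avr, VL = (2 / 3) * avl, VF = (2 / 3) * avf)
}

#' Cross-lead RMS and SD scalar channels
#'
#' From nine simultaneous unipolar traces (the three reconstructed unipolar
#' limb leads and V1-V6), computes per time point the root mean square over
#' the nine leads and the standard deviation over the nine leads (divisor 9,
#' population form). These satisfy the identity `sd^2 + mean^2 = rms^2`
#' pointwise.
#'
#' @param nine_leads numeric matrix with 9 columns (samples x leads),
#'   microvolts.
#' @return list with numeric vectors `rms` and `sd` (microvolts).
#' @export
compute_rms_sd <- function(nine_leads) {
  nine_leads <- as.matrix(nine_leads)
  if (ncol(nine_leads) != 9L)
    stop(sprintf("expected 9 unipolar channels, got %d", ncol(nine_leads)))
  m <- rowMeans(nine_leads)
  msq <- rowMeans(nine_leads^2)
  rms <- sqrt(msq)
  sd <- sqrt(pmax(msq - m^2, 0))
  list(rms = rms, sd = sd)
}

#' Kors vectorcardiogram from the eight independent leads
#'
#' Applies the fixed Kors regression matrix to leads I, II and V1-V6 to
#' obtain the orthogonal X/Y/Z leads and the VCG magnitude
#' `sqrt(X^2 + Y^2 + Z^2)`.
#'
#' @param leads numeric matrix (samples x leads) with named columns including
#'   I, II, V1-V6, in microvolts.
#' @return list with vectors `X`, `Y`, `Z`, `mag`.
#' @export
kors_vcg <- function(leads) {
  leads <- as.matrix(leads)
  need <- colnames(KORS_MATRIX)
  have <- normalize_lead_names(colnames(leads))
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing lead(s) for VCG synthesis: ", paste(miss, collapse = ", "))
  colnames(leads) <- have
  xyz <- leads[, need, drop = FALSE] %*% t(KORS_MATRIX)
  list(X = xyz[, "X"], Y = xyz[, "Y"], Z = xyz[, "Z"],
       mag = sqrt(rowSums(xyz^2)))
}

# Derive missing limb leads from I and II (Einthoven/Goldberger relations).
# Returns the record with any of III, aVR, aVL, aVF filled in.
derive_limb_leads <- function(record) {
  nm <- colnames(record$samples)
  if (!all(c("I", "II") %in% nm))
    stop("leads I and II are required to derive the limb leads")
  I <- record$samples[, "I"]; II <- record$samples[, "II"]
  derived <- list(III = II - I,
                  aVR = -(I + II) / 2,
                  aVL = I - II / 2,
                  aVF = II - I / 2)
  for (lead in names(derived)) {
    if (!lead %in% nm)
      record$samples <- cbind(record$samples,
                              stats::setNames(data.frame(derived[[lead]]),
                                              lead))
  }
  record$samples <- as.matrix(record$samples)
  record
}

#' Append the three scalar channels to a conditioned record
#'
#' Builds the heart-axis-robust scalar channels and appends them under the
#' reserved names `RMS`, `SD` and `VCGMAG`:
#' \itemize{
#'   \item `RMS`, `SD`: cross-lead root mean square / standard deviation over
#'     the nine unipolar traces (2/3 aVR, 2/3 aVL, 2/3 aVF, V1-V6). Augmented
#'     leads are taken as recorded when present, derived from I and II
#'     otherwise.
#'   \item `VCGMAG`: magnitude of the Kors-synthesized vectorcardiogram.
#' }
#' The scalar channels are exempt from the 50 uV T-amplitude exclusion rule.
#'
#' @param record an [ecg_record] containing at least leads I, II and V1-V6.
#' @return the record with three additional channels.
#' @export
add_scalar_channels <- function(record) {
  record <- derive_limb_leads(record)
  nm <- colnames(record$samples)
  prec <- paste0("V", 1:6)
  if (!all(prec %in% nm))
    stop("precordial leads V1-V6 are required for the scalar channels")
  uni <- reconstruct_unipolar(record$samples[, "aVR"],
                              record$samples[, "aVL"],
                              record$samples[, "aVF"])
  nine <- cbind(VR = uni$VR, VL = uni$VL, VF = uni$VF,
                record$samples[, prec, drop = FALSE])
  rs <- compute_rms_sd(nine)
  vcg <- kors_vcg(record$samples[, c("I", "II", prec), drop = FALSE])
  record$samples <- cbind(record$samples,
                          RMS = rs$rms, SD = rs$sd, VCGMAG = vcg$mag)
  record
}
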