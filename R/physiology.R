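#' @include AllClasses.R
NULL

## Reference adult physiology at 70 kg: tissue volumes (L) and regional blood
## flows (L/h). Volumes follow standard reference-adult organ weights at unit
## density; flows are fractions of a 390 L/h (6.5 L/min) cardiac output.
## "rest_of_body" closes both the mass and the flow balance so that non-lung
## flows sum exactly to cardiac output and total volume stays within the
## anatomical range of a 70 kg adult. Blood volume 5.2 L, venous:arterial 3:1.
.REFERENCE_BW <- 70

.REFERENCE_PHYSIOLOGY <- data.frame(
  name = .TISSUES,
  volume = c(
    lung = 0.50, heart = 0.33, brain = 1.45, muscle = 26.00,
    adipose = 15.00, skin = 3.30, spleen = 0.15, pancreas = 0.10,
    liver = 1.80, stomach = 0.15, gut = 1.65, bone = 8.50,
    kidney = 0.31, rest_of_body = 3.00),
  blood_flow = c(
    lung = 390.00, heart = 15.60, brain = 46.80, muscle = 66.30,
    adipose = 19.50, skin = 19.50, spleen = 7.80, pancreas = 3.90,
    liver = 25.35, stomach = 3.90, gut = 54.60, bone = 16.38,
    kidney = 74.10, rest_of_body = 36.27),
  row.names = NULL, stringsAsFactors = FALSE)

.REFERENCE_VENOUS <- 3.9
.REFERENCE_ARTERIAL <- 1.3

#' Reference virtual subject
#'
#' Builds the virtual healthy adult the whole-body model is integrated over:
#' 14 perfusion-limited tissues plus venous and arterial blood. All volumes
#' and flows are scaled linearly to `bodyWeight` from a documented 70 kg
#' reference table (cardiac output 390 L/h, blood 5.2 L split venous:arterial
#' 3:1 at 70 kg). Lung blood flow equals cardiac output and the non-lung flows
#' sum to it exactly.
#'
#' Individual tissues can be overridden via `overrides`, either a named list
#' `list(tissue = list(volume_L =, flow_L_per_h =), ...)` (each sub-field
#' optional; `venous_volume_L`/`arterial_volume_L` accepted at the top level)
#' or the path of a YAML file with the same structure. After overrides the
#' lung flow is recomputed as the sum of the non-lung flows, so cardiac output
#' follows the overridden regional flows and the flow-balance invariant always
#' holds; all other invariants are validated on load.
#'
#' @param bodyWeight body weight in kg (> 0).
#' @param overrides optional named list or YAML file path of physiology
#'   overrides, applied after allometric scaling.
#' @return A [VirtualSubject-class] object.
#' @export
#' @examples
#' subj <- referenceSubject(70)
#' cardiacOutput(subj)
#' tissueTable(subj)
referenceSubject <- function(bodyWeight = 70, overrides = NULL) {
  if (!.is_scalar_num(bodyWeight) || bodyWeight <= 0)
    stop("bodyWeight must be a positive number (kg)")
  scale <- bodyWeight / .REFERENCE_BW
  tt <- .REFERENCE_PHYSIOLOGY
  tt$volume <- tt$volume * scale
  tt$blood_flow <- tt$blood_flow * scale
  ven <- .REFERENCE_VENOUS * scale
  art <- .REFERENCE_ARTERIAL * scale

  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L)
      overrides <- yaml::read_yaml(overrides)
    if (!is.list(overrides))
      stop("overrides must be a named list or the path of a YAML file")
    for (key in names(overrides)) {
      if (key == "venous_volume_L") { ven <- as.numeric(overrides[[key]]); next }
      if (key == "arterial_volume_L") { art <- as.numeric(overrides[[key]]); next }
      if (!key %in% .TISSUES)
        stop(sprintf("unknown tissue '%s' in physiology overrides (known: %s)",
                     key, paste(.TISSUES, collapse = ", ")))
      ov <- overrides[[key]]
      if (!is.null(ov$volume_L))
        tt$volume[tt$name == key] <- as.numeric(ov$volume_L)
      if (!is.null(ov$flow_L_per_h))
        tt$blood_flow[tt$name == key] <- as.numeric(ov$flow_L_per_h)
    }
    ## cardiac output tracks the (possibly overridden) regional flows
    tt$blood_flow[tt$name == "lung"] <-
      sum(tt$blood_flow[tt$name != "lung"])
  }

  new("VirtualSubject", bodyWeight = bodyWeight, tissues = tt,
      venousVolume = ven, arterialVolume = art)
}

#' Total volume of a virtual subject
#'
#' Sum of the 14 tissue volumes plus venous and arterial blood, in litres.
#'
#' @param subject a [VirtualSubject-class].
#' @return Total volume, L.
#' @export
totalVolume <- function(subject) {
  stopifnot(is(subject, "VirtualSubject"))
  sum(tissueTable(subject)$volume) + venousVolume(subject) +
    arterialVolume(subject)
}
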