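# Plate-assay arithmetic: LDH relative cell death, dual-luciferase ratio,
# and control-mean normalization (densitometry-style).

#' Relative cell death from an LDH release assay
#'
#' `death = Abs_supernatant / (Abs_supernatant + Abs_attached)`, in [0, 1].
#'
#' @param abs_sup,abs_att non-negative absorbance readings (vectorized).
#' @return fraction in [0, 1]; errors when a pair sums to zero (undefined).
#' @export
relative_cell_death <- function(abs_sup, abs_att) {
  if (any(abs_sup < 0) || any(abs_att < 0))
    stop("absorbances must be non-negative")
  tot <- abs_sup + abs_att
  if (any(tot == 0))
    stop("relative cell death undefined: total absorbance is zero")
  abs_sup / tot
}

#' Relative luciferase activity
#'
#' Firefly luminescence divided by the Renilla internal-control luminescence.
#'
#' @param firefly,renilla luminescence readings (vectorized); `renilla` must
#'   be strictly positive.
#' @return firefly / renilla ratio.
#' @export
relative_luciferase <- function(firefly, renilla) {
  if (any(renilla == 0))
    stop("relative luciferase undefined: Renilla luminescence is zero")
  firefly / renilla
}

#' Normalize values to the mean of control samples
#'
#' Divides every value by the arithmetic mean of the control values, so the
#' normalized controls average exactly 1 (band-intensity quantification
#' convention).
#'
#' @param values numeric vector of non-negative readings.
#' @param control_idx indices (or logical mask) of the control samples.
#' @return `values / mean(values[control_idx])`.
#' @export
normalize_to_control_mean <- function(values, control_idx) {
  ctrl <- values[control_idx]
  if (length(ctrl) < 1L) stop("need >= 1 control sample")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0")
  values / m
}

#' Apply an assay formula over a long plate table
#'
#' Consumes a plate table (`well`, `group`, `kind`, `value`; see
#' [simulate_assay_plate()]) and computes, per well, the LDH relative cell
#' death, the firefly/Renilla ratio, or control-mean-normalized band
#' intensities.
#'
#' @param plate data.frame with columns `well`, `group`, `kind`, `value`.
#' @param mode one of `"ldh"`, `"luciferase"`, `"densitometry"`.
#' @param control_group group label defining controls (densitometry mode).
#' @param blank optional background reading subtracted from every value
#'   before the formula (off by default).
#' @return data.frame with `well`, `group` and the computed statistic.
#' @export
quantify_plate <- function(plate, mode = c("ldh", "luciferase",
                                           "densitometry"),
                           control_group = "control", blank = 0) {
  mode <- match.arg(mode)
  stopifnot(all(c("well", "group", "kind", "value") %in% names(plate)))
  plate$value <- plate$value - blank
  pick <- function(kind) {
    sub <- plate[plate$kind == kind, ]
    stats::setNames(sub$value, sub$well)
  }
  if (mode == "ldh") {
    sup <- pick("absorbance_supernatant")
    att <- pick("absorbance_attached")
    wells <- intersect(names(sup), names(att))
    if (!length(wells)) stop("no paired supernatant/attached readings")
    out <- data.frame(well = wells,
                      relative_cell_death =
                        relative_cell_death(sup[wells], att[wells]),
                      stringsAsFactors = FALSE)
  } else if (mode == "luciferase") {
    ff <- pick("firefly")
    rn <- pick("renilla")
    wells <- intersect(names(ff), names(rn))
    if (!length(wells)) stop("no paired firefly/renilla readings")
    out <- data.frame(well = wells,
                      relative_luciferase =
                        relative_luciferase(ff[wells], rn[wells]),
                      stringsAsFactors = FALSE)
  } else {
    sub <- plate[plate$kind == "band_intensity", ]
    if (!nrow(sub)) stop("no band_intensity readings")
    out <- data.frame(well = sub$well,
                      relative_intensity = normalize_to_control_mean(
                        sub$value, sub$group == control_group),
                      stringsAsFactors = FALSE)
  }
  grp <- plate$group[match(out$well, plate$well)]
  out$group <- grp
  rownames(out) <- NULL
  out[, c("well", "group", setdiff(names(out), c("well", "group")))]
}
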