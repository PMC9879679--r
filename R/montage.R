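#' Canonical 32-channel montage order
#'
#' The fixed channel order used throughout the package: the 32 electrode
#' sites of the international 10-20 system (extended 10-10 names) in the
#' order recordings are stored, features are tabulated and models are
#' indexed.
#'
#' @return Character vector of 32 channel names.
#' @export
canonical_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

## unit vector on the scalp sphere from inclination (degrees from the
## vertex Cz) and azimuth (degrees from the nose direction +y, positive
## toward the right ear +x)
.sph_unit <- function(incl, az) {
  i <- incl * pi / 180
  a <- az * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

## spherical linear interpolation between two unit vectors
.slerp <- function(u, v, t) {
  d <- max(-1, min(1, sum(u * v)))
  ang <- acos(d)
  if (ang < 1e-12) return(u)
  w <- (sin((1 - t) * ang) * u + sin(t * ang) * v) / sin(ang)
  w / sqrt(sum(w^2))
}

## azimuthal-equidistant projection onto the unit head disc: radius is
## proportional to inclination, the 10-20 outer ring (72 deg) lands at 0.8
.project_ae <- function(u) {
  incl <- acos(max(-1, min(1, u[3])))
  az <- atan2(u[1], u[2])
  r <- incl / (pi / 2)
  c(x = r * sin(az), y = r * cos(az))
}

#' Standard 10-20 electrode positions on the unit head disc
#'
#' Constructs idealized 10-20 scalp positions: electrodes are placed on
#' great-circle arcs of a sphere exactly as the 10-20 placement scheme
#' prescribes (midline and central arcs in 18-degree steps, the outer ring
#' at 72 degrees inclination, intermediate sites midway along the
#' fronto/parieto-lateral arcs) and projected azimuthal-equidistantly onto
#' a disc of radius 1 with the nose at +y.  Right-hemisphere sites are
#' exact mirror images of their left homologs, Cz maps to the origin.
#'
#' @return Object of class `saetm_montage`: a named list with `positions`,
#'   a 32 x 2 matrix of (x, y) coordinates rownamed by channel.
#' @export
standard_montage <- function() {
  ## left-hemisphere and midline sites defined on arcs; right homologs by
  ## mirroring so left/right symmetry is exact
  unit <- list(
    Cz  = c(0, 0, 1),
    Fz  = .sph_unit(36, 0),
    Pz  = .sph_unit(36, 180),
    Oz  = .sph_unit(72, 180),
    Fp1 = .sph_unit(72, -18),
    F7  = .sph_unit(72, -54),
    T7  = .sph_unit(72, -90),
    P7  = .sph_unit(72, -126),
    O1  = .sph_unit(72, -162),
    C3  = .sph_unit(36, -90)
  )
  unit$F3  <- .slerp(unit$Fz, unit$F7, 0.5)
  unit$P3  <- .slerp(unit$Pz, unit$P7, 0.5)
  unit$AF3 <- .slerp(.sph_unit(54, 0), .sph_unit(72, -36), 0.5)
  unit$PO3 <- .slerp(.sph_unit(54, 180), .sph_unit(72, -144), 0.5)
  unit$FC1 <- .slerp(.sph_unit(18, 0), .sph_unit(72, -72), 0.25)
  unit$FC5 <- .slerp(.sph_unit(18, 0), .sph_unit(72, -72), 0.75)
  unit$CP1 <- .slerp(.sph_unit(18, 180), .sph_unit(72, -108), 0.25)
  unit$CP5 <- .slerp(.sph_unit(18, 180), .sph_unit(72, -108), 0.75)

  pos <- matrix(NA_real_, nrow = 32, ncol = 2,
                dimnames = list(canonical_channels(), c("x", "y")))
  for (ch in names(unit)) pos[ch, ] <- .project_ae(unit[[ch]])
  ## midline sites sit exactly on x = 0
  for (ch in c("Cz", "Fz", "Pz", "Oz")) pos[ch, "x"] <- 0
  mirror <- c(Fp2 = "Fp1", AF4 = "AF3", F4 = "F3", F8 = "F7",
              FC6 = "FC5", FC2 = "FC1", C4 = "C3", T8 = "T7",
              CP6 = "CP5", CP2 = "CP1", P4 = "P3", P8 = "P7",
              PO4 = "PO3", O2 = "O1")
  for (r in names(mirror)) {
    pos[r, ] <- c(-pos[mirror[[r]], "x"], pos[mirror[[r]], "y"])
  }
  structure(list(positions = pos), class = "saetm_montage")
}

#' @export
print.saetm_montage <- function(x, ...) {
  cat("10-20 montage,", nrow(x$positions), "electrodes on the unit head disc\n")
  invisible(x)
}

#' Mirror-pair table of the montage
#'
#' @return Data frame with columns `left` and `right` listing homologous
#'   electrode pairs.
#' @keywords internal
.mirror_pairs <- function() {
  data.frame(
    left  = c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
              "CP5", "CP1", "P3", "P7", "PO3", "O1"),
    right = c("Fp2", "AF4", "F4", "F8", "FC6", "FC2", "C4", "T8",
              "CP6", "CP2", "P4", "P8", "PO4", "O2"),
    stringsAsFactors = FALSE
  )
}
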