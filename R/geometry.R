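#' Idealized backbone geometry parameters
#'
#' The chain model fixes bond lengths and bond angles at canonical values so
#' that the only remaining degrees of freedom are the phi/psi backbone
#' dihedrals.  Defaults follow the CHARMM22 / Engh-Huber class of ideal
#' values for the four modeled backbone heavy atoms (N, CA, C, O); every
#' value can be overridden.
#'
#' @param b_n_ca  N-CA bond length (Angstrom).
#' @param b_ca_c  CA-C bond length (Angstrom).
#' @param b_c_n   C-N peptide bond length (Angstrom).
#' @param b_c_o   C=O bond length (Angstrom).
#' @param a_n_ca_c  N-CA-C bond angle (degrees).
#' @param a_ca_c_n  CA-C-N bond angle (degrees).
#' @param a_c_n_ca  C-N-CA bond angle (degrees).
#' @param a_ca_c_o  CA-C=O bond angle (degrees).
#' @param omega  Peptide-bond dihedral, fixed (degrees); trans = 180.
#' @return An object of class \code{geometry_params}.
#' @examples
#' geo <- geometry_params()
#' geo$b_n_ca
#' @export
geometry_params <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                            b_c_o = 1.231,
                            a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                            a_c_n_ca = 121.7, a_ca_c_o = 120.8,
                            omega = 180) {
  g <- list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n, b_c_o = b_c_o,
            a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n, a_c_n_ca = a_c_n_ca,
            a_ca_c_o = a_ca_c_o, omega = omega)
  lens <- unlist(g[1:4]); angs <- unlist(g[5:8])
  if (any(!is.finite(unlist(g)))) stop("geometry parameters must be finite")
  if (any(lens <= 0)) stop("bond lengths must be > 0")
  if (any(angs <= 0 | angs >= 180)) stop("bond angles must lie in (0, 180)")
  structure(g, class = "geometry_params")
}

#' Sentinel marking an undefined dihedral angle
#'
#' phi of the first residue and psi of the last residue of a linear chain are
#' undefined; they are stored as this sentinel and never used in kinematics.
#' @export
ANGLE_UNDEF <- 999.0

#' Construct a backbone conformation
#'
#' A conformation is a sequence plus per-residue (phi, psi) backbone
#' dihedrals in degrees.  Cartesian coordinates are derived on demand by
#' \code{\link{forward_kinematics}}.  Angles are taken in degrees on
#' [-180, 180); \code{phi[1]} and \code{psi[n]} must be the
#' \code{\link{ANGLE_UNDEF}} sentinel (they are forced to it).
#'
#' @param sequence Character vector of one-letter residue codes (or a single
#'   string), length n >= 1.
#' @param phi,psi Numeric vectors of length n, degrees.
#' @return An object of class \code{conformation} with fields
#'   \code{sequence}, \code{phi}, \code{psi}.
#' @export
conformation <- function(sequence, phi, psi) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  if (n < 1) stop("empty sequence")
  if (length(phi) != n || length(psi) != n)
    stop("phi and psi must each have one value per residue")
  phi[1] <- ANGLE_UNDEF
  psi[n] <- ANGLE_UNDEF
  def <- c(phi[-1], psi[-n])
  if (any(!is.finite(def))) stop("non-finite dihedral angle")
  phi[-1] <- wrap_angle(phi[-1])
  psi[-n] <- wrap_angle(psi[-n])
  structure(list(sequence = sequence, phi = phi, psi = psi),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("conformation:", length(x$sequence), "residues (",
      paste(x$sequence[seq_len(min(10, length(x$sequence)))], collapse = ""),
      if (length(x$sequence) > 10) "..." else "", ")\n")
  invisible(x)
}

n_residues <- function(conf) length(conf$sequence)

# wrap degrees into [-180, 180)
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y >= 180] <- -180  # guard against FP edge at exactly 360 %% 360
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Place atom D given positions A, B, C, the B-C-D bond angle (deg), the
# A-B-C-D dihedral (deg) and the C-D bond length.  Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Backbone coordinates from dihedral angles (forward kinematics)
#'
#' Builds cartesian coordinates for the 4 modeled backbone heavy atoms per
#' residue (N, CA, C, O) under the idealized-geometry assumption.  The anchor
#' convention is fixed so that identical angles give bitwise-identical
#' coordinates: N1 at the origin, CA1 on the +x axis, C1 in the xy-plane with
#' positive y.  The carbonyl O of residue i is placed anti to the next
#' residue's N (N-CA-C-O dihedral = psi_i + 180); for the last residue, where
#' psi is undefined, the N-CA-C-O dihedral is fixed at 180.
#'
#' @param conf A \code{\link{conformation}}.
#' @param geo A \code{\link{geometry_params}} object.
#' @return Numeric matrix (4n x 3), rows ordered N, CA, C, O per residue.
#' @export
forward_kinematics <- function(conf, geo = geometry_params()) {
  stopifnot(inherits(conf, "conformation"))
  n <- n_residues(conf)
  phi <- conf$phi; psi <- conf$psi
  def <- c(phi[-1], psi[-n])
  if (length(def) && any(!is.finite(def) | def == ANGLE_UNDEF))
    stop("undefined or non-finite dihedral angle in conformation")
  xyz <- matrix(NA_real_, nrow = 4 * n, ncol = 3)

  # anchor: N1 at origin, CA1 on +x, C1 in xy-plane (positive y)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(geo$b_n_ca, 0, 0)
  th <- deg2rad(geo$a_n_ca_c)
  xyz[3, ] <- xyz[2, ] + geo$b_ca_c * c(-cos(th), sin(th), 0)

  for (i in seq_len(n)) {
    r <- 4L * (i - 1L)
    Ni <- xyz[r + 1L, ]; CAi <- xyz[r + 2L, ]; Ci <- xyz[r + 3L, ]
    if (i < n) {
      # next N via psi_i about CA(i)-C(i)
      Nn <- place_atom(Ni, CAi, Ci, geo$b_c_n, geo$a_ca_c_n, psi[i])
      xyz[r + 5L, ] <- Nn
      # next CA via omega about C(i)-N(i+1)
      CAn <- place_atom(CAi, Ci, Nn, geo$b_n_ca, geo$a_c_n_ca, geo$omega)
      xyz[r + 6L, ] <- CAn
      # next C via phi_{i+1} about N(i+1)-CA(i+1)
      xyz[r + 7L, ] <- place_atom(Ci, Nn, CAn, geo$b_ca_c,
                                  geo$a_n_ca_c, phi[i + 1])
      # O(i) anti to N(i+1)
      xyz[r + 4L, ] <- place_atom(Ni, CAi, Ci, geo$b_c_o, geo$a_ca_c_o,
                                  wrap_angle(psi[i] + 180))
    } else {
      xyz[r + 4L, ] <- place_atom(Ni, CAi, Ci, geo$b_c_o, geo$a_ca_c_o, 180)
    }
  }
  xyz
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking from b to c, the angle is positive when
#' the far bond c-d is rotated clockwise from the near bond b-a.  Returned
#' in degrees on [-180, 180).
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2) / b2n
  wrap_angle(rad2deg(atan2(y, x)))
}

#' Measure phi/psi dihedrals from backbone coordinates
#'
#' Inverse of \code{\link{forward_kinematics}}.  Residues missing a backbone
#' atom needed for an angle get the \code{\link{ANGLE_UNDEF}} sentinel for
#' that angle rather than raising an error; \code{phi[1]} and \code{psi[n]}
#' are always the sentinel.
#'
#' @param xyz Numeric matrix (4n x 3), rows ordered N, CA, C, O per residue.
#'   Rows containing any NA are treated as missing atoms.
#' @return List with numeric vectors \code{phi} and \code{psi} (degrees).
#' @export
measure_dihedrals <- function(xyz) {
  if (!is.matrix(xyz) || ncol(xyz) != 3 || nrow(xyz) %% 4 != 0)
    stop("xyz must be a (4n x 3) coordinate matrix")
  n <- nrow(xyz) / 4
  if (n < 1) stop("at least one residue required")
  at <- function(atom, i) {
    v <- xyz[(i - 1) * 4 + match(atom, c("N", "CA", "C", "O")), ]
    if (any(!is.finite(v))) NULL else v
  }
  phi <- rep(ANGLE_UNDEF, n); psi <- rep(ANGLE_UNDEF, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      p <- list(at("C", i - 1), at("N", i), at("CA", i), at("C", i))
      if (!any(vapply(p, is.null, logical(1))))
        phi[i] <- torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    }
    if (i < n) {
      p <- list(at("N", i), at("CA", i), at("C", i), at("N", i + 1))
      if (!any(vapply(p, is.null, logical(1))))
        psi[i] <- torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    }
  }
  list(phi = phi, psi = psi)
}

#' Backbone coordinates of a conformation
#'
#' Convenience wrapper computing \code{\link{forward_kinematics}}.
#' @inheritParams forward_kinematics
#' @return 4n x 3 coordinate matrix.
#' @export
coords <- function(conf, geo = geometry_params()) forward_kinematics(conf, geo)
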