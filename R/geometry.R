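# Backbone geometry helpers: dihedrals, internal-coordinate atom placement
# (NeRF), idealized chain construction, rigid-body moves.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) v / vnorm(v)

#' Dihedral angle of four points
#'
#' Signed torsion angle in degrees, in (-180, 180], using the IUPAC sign
#' convention (clockwise positive when viewed from p2 toward p3).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (coordinates in Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place atom D given positions A, B, C and internal coordinates:
# bond |C-D|, angle B-C-D (deg), torsion A-B-C-D (deg).  Standard NeRF.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180   # sign fixed so dihedral_angle(a,b,c,d) == torsion
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

# Idealized backbone bond lengths (Angstrom) and angles (degrees).
BB_GEOM <- list(n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23,
                ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.9,
                ang_ca_c_o = 120.5)

#' Build an idealized peptide backbone from phi/psi dihedrals
#'
#' Constructs N, CA, C, O coordinates for `n` residues with standard bond
#' lengths and angles, trans peptide bonds (omega = 180 deg), and the given
#' backbone dihedrals. The carbonyl O is placed anti to the next residue's N.
#'
#' @param phi,psi numeric vectors of length `n` (degrees). `phi[1]` and
#'   `psi[n]` still orient terminal atoms and must be supplied.
#' @return numeric array `n x 4 x 3`; atom slices ordered N, CA, C, O.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(n >= 1, length(psi) == n)
  g <- BB_GEOM
  coords <- array(NA_real_, dim = c(n, 4, 3),
                  dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  # seed residue 1 in a canonical frame
  coords[1, "N", ] <- c(0, 0, 0)
  coords[1, "CA", ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  coords[1, "C", ] <- coords[1, "CA", ] +
    g$ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      prev <- i - 1
      coords[i, "N", ] <- place_atom(coords[prev, "N", ], coords[prev, "CA", ],
                                     coords[prev, "C", ],
                                     g$c_n, g$ang_ca_c_n, psi[prev])
      coords[i, "CA", ] <- place_atom(coords[prev, "CA", ], coords[prev, "C", ],
                                      coords[i, "N", ],
                                      g$n_ca, g$ang_c_n_ca, 180)
      coords[i, "C", ] <- place_atom(coords[prev, "C", ], coords[i, "N", ],
                                     coords[i, "CA", ],
                                     g$ca_c, g$ang_n_ca_c, phi[i])
    }
    # carbonyl O: torsion N-CA-C-O = psi - 180 (anti to the next N)
    coords[i, "O", ] <- place_atom(coords[i, "N", ], coords[i, "CA", ],
                                   coords[i, "C", ],
                                   g$c_o, g$ang_ca_c_o, psi[i] - 180)
  }
  coords
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_matrix <- function(axis, theta) {
  u <- unitv(axis)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Canonical phi/psi by 3-state secondary-structure type.
CANONICAL_DIHEDRALS <- list(
  H = c(phi = -60, psi = -45),
  E = c(phi = -120, psi = 130),
  L = c(phi = -80, psi = 150)   # extended, polyproline-like
)
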