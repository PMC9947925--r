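# Bounded perturbation of peptide backbones: all-glycine stripping and
# seeded rigid-body + noise moves with an exact RMSD target.

#' Perturbation settings
#'
#' @param max_rmsd upper bound on the backbone RMSD of the perturbed pose
#'   from the native one, in Angstrom (default 1.07).
#' @param seed integer RNG seed; every draw is reproducible given the seed.
#' @param mode perturbation mode; only `"rigid+noise"` is implemented.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(max_rmsd = 1.07, seed = 1L,
                              mode = "rigid+noise") {
  if (!is.numeric(max_rmsd) || max_rmsd <= 0)
    stop("max_rmsd must be > 0")
  mode <- match.arg(mode, "rigid+noise")
  structure(list(max_rmsd = max_rmsd, seed = as.integer(seed), mode = mode),
            class = "perturbation_spec")
}

#' Backbone RMSD between two peptide poses
#'
#' Coordinate root-mean-square deviation over the backbone atoms
#' (N, CA, C, O) without superposition: deviation is measured in the
#' binding-site frame, so rigid displacement of the whole peptide counts.
#'
#' @param a,b `residue_set`s with equal residue counts.
#' @return RMSD in Angstrom.
#' @export
compute_rmsd <- function(a, b) {
  if (length(a) != length(b))
    stop("residue counts differ: ", length(a), " vs ", length(b))
  xa <- rs_atoms(a)
  xb <- rs_atoms(b)
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Replace the peptide sequence by all-glycine
#'
#' Residue identities of the peptide become GLY; coordinates and the
#' binding site are untouched. Idempotent.
#'
#' @param cr a `complex_record`.
#' @return the record with peptide sequence `GGGGGG`.
#' @export
strip_to_glycine <- function(cr) {
  stopifnot(inherits(cr, "complex_record"))
  cr$peptide$aa <- rep("G", length(cr$peptide))
  cr
}

#' Perturb a peptide backbone within a bounded RMSD
#'
#' Applies a small random rigid-body move (rotation up to 10 degrees about
#' the peptide centroid, translation up to 1 Angstrom) plus per-atom
#' Gaussian noise, then scales the net displacement so the coordinate RMSD
#' from the native pose equals a target drawn uniformly in
#' `(0, max_rmsd]`. Coordinate RMSD is linear in the displacement, so the
#' scaling is exact. Draws that break consecutive CA-CA geometry
#' (outside 3.2-4.2 Angstrom) are redrawn. Deterministic given the seed.
#'
#' @param peptide a `residue_set` (typically 6 residues).
#' @param spec a [perturbation_spec()].
#' @return a perturbed copy of `peptide`.
#' @export
perturb_peptide <- function(peptide, spec = perturbation_spec()) {
  stopifnot(inherits(peptide, "residue_set"),
            inherits(spec, "perturbation_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  x0 <- rs_atoms(peptide)
  centroid <- colMeans(x0)
  for (attempt in 1:100) {
    target <- stats::runif(1, 0, spec$max_rmsd)
    axis <- stats::rnorm(3)
    theta <- stats::runif(1, 0, 10) * pi / 180
    rot <- rotation_matrix(axis, theta)
    shift <- stats::runif(3, -1, 1)
    shift <- shift / max(vnorm(shift), 1) * stats::runif(1, 0, 1)
    moved <- sweep(sweep(x0, 2, centroid) %*% t(rot), 2, centroid, "+")
    moved <- sweep(moved, 2, shift, "+")
    moved <- moved + matrix(stats::rnorm(length(moved), sd = 0.15),
                            nrow(moved), 3)
    disp <- moved - x0
    cur <- sqrt(mean(rowSums(disp^2)))
    if (cur < 1e-9) next
    xn <- x0 + disp * (target / cur)
    out <- peptide
    atoms <- c("N", "CA", "C", "O")
    for (k in 1:4)
      out$coords[, atoms[k], ] <-
        xn[seq(k, by = 4, length.out = length(peptide)), , drop = FALSE]
    ca <- out$coords[, "CA", , drop = FALSE]
    n <- length(peptide)
    if (n >= 2) {
      gaps <- sqrt(rowSums((out$coords[-1, "CA", , drop = FALSE] -
                              out$coords[-n, "CA", , drop = FALSE])^2))
      if (any(gaps <= 3.2 | gaps >= 4.2)) next
    }
    return(out)
  }
  stop("could not generate a geometry-preserving perturbation in 100 attempts")
}

# save/restore global RNG state so seeded helpers do not clobber callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
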