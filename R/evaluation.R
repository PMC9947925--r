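# Recovery-based evaluation statistics and the pluggable per-residue
# binding-energy interface with its deterministic surrogate.

#' Deterministic surrogate binding-energy model
#'
#' A pluggable stand-in for physics-based interface scoring (it is not a
#' Rosetta energy; units are labeled "surrogate REU"). The binding
#' pseudo-energy is minus a weighted interface contact count: for each
#' peptide residue, heavy-atom proxy positions (backbone N, CA, C, O plus
#' an idealized CB, CA for glycine) are counted against the site's proxy
#' atoms within a 5 Angstrom shell, smoothly down-weighted with distance,
#' and scaled by a hydrophobicity weight of the residue identity.
#' Per-residue contributions are additive:
#' \eqn{\Delta G_B = -\sum_i w(aa_i) c_i}.
#'
#' Alanine scanning under this model gives
#' \eqn{\Delta\Delta G_i = (w(aa_i) - w(A)) c_i} for non-alanine residues.
#'
#' @param shell contact shell radius in Angstrom (default 5).
#' @param scale multiplier applied to every contribution (default 1).
#' @return an object of class `energy_model`: a list with functions
#'   `binding_energy(cr)`, `per_residue(cr)` (vector of contributions such
#'   that `binding_energy = -sum(per_residue)`), and fields `name`, `units`.
#' @export
surrogate_energy <- function(shell = 5, scale = 1) {
  proxy_atoms <- function(rs) {
    rbind(rs_atoms(rs), rs_cb_proxy(rs))
  }
  contact_counts <- function(cr) {
    sa <- proxy_atoms(cr$site)
    n <- length(cr$peptide)
    counts <- numeric(n)
    for (i in seq_len(n)) {
      pa <- rbind(cr$peptide$coords[i, , ], rs_cb_proxy(rs_subset(cr$peptide, i)))
      d2 <- outer(rowSums(pa^2), rowSums(sa^2), "+") - 2 * pa %*% t(sa)
      d <- sqrt(pmax(d2, 0))
      w <- pmax(1 - d / shell, 0)   # linear taper to 0 at the shell edge
      counts[i] <- sum(w)
    }
    counts
  }
  per_residue <- function(cr) {
    stopifnot(inherits(cr, "complex_record"))
    scale * AA_WEIGHT[cr$peptide$aa] * contact_counts(cr)
  }
  structure(list(
    name = "surrogate", units = "surrogate REU",
    per_residue = per_residue,
    binding_energy = function(cr) -sum(per_residue(cr))
  ), class = "energy_model")
}

#' Energy model backed by an external per-residue table
#'
#' Wraps externally computed per-residue binding contributions (e.g. from a
#' physics-based alanine scan) in the same interface as
#' [surrogate_energy()].
#'
#' @param contributions numeric vector, one positive-is-favorable
#'   contribution per peptide residue.
#' @return an `energy_model`.
#' @export
table_energy <- function(contributions) {
  contributions <- as.numeric(contributions)
  structure(list(
    name = "external-table", units = "REU",
    per_residue = function(cr) {
      stopifnot(length(cr$peptide) == length(contributions))
      contributions
    },
    binding_energy = function(cr) -sum(contributions)
  ), class = "energy_model")
}

#' Alanine scan of the peptide under an energy model
#'
#' For each peptide residue, \eqn{\Delta\Delta G_i} is the loss of binding
#' energy upon mutation to alanine:
#' \eqn{\Delta\Delta G_i = \Delta G_B(i \to A) - \Delta G_B(\mathrm{native})}
#' (positive = the native residue contributes). Residues with
#' \eqn{\Delta\Delta G_i \ge 3} REU are labeled hot-spots.
#'
#' @param cr a `complex_record`.
#' @param em an `energy_model`.
#' @param threshold hot-spot threshold in REU (default 3; boundary
#'   inclusive).
#' @return list of per-residue labels: `index`, `ddG`, `is_hotspot`.
#' @export
alanine_scan <- function(cr, em = surrogate_energy(), threshold = HOTSPOT_DDG) {
  stopifnot(inherits(cr, "complex_record"), inherits(em, "energy_model"))
  base <- em$binding_energy(cr)
  n <- length(cr$peptide)
  lapply(seq_len(n), function(i) {
    mut <- cr
    mut$peptide$aa[i] <- "A"
    ddg <- em$binding_energy(mut) - base
    list(index = i, ddG = ddg, is_hotspot = ddg >= threshold)
  })
}

#' Hot-spot labels from an explicit ddG vector
#'
#' @param ddg numeric vector of per-residue \eqn{\Delta\Delta G_i} in REU.
#' @param threshold hot-spot threshold (default 3, inclusive).
#' @return list of labels as in [alanine_scan()].
#' @export
hotspot_labels <- function(ddg, threshold = HOTSPOT_DDG) {
  lapply(seq_along(ddg), function(i)
    list(index = i, ddG = ddg[i], is_hotspot = ddg[i] >= threshold))
}

#' Sequence recovery between native and designed sequences
#'
#' Fraction of positions where the designed residue is identical to the
#' native one (no similarity-matrix credit).
#'
#' @param native,designed equal-length amino-acid strings.
#' @return fraction in `[0, 1]`.
#' @export
sequence_recovery <- function(native, designed) {
  a <- strsplit(native, "")[[1]]
  b <- strsplit(designed, "")[[1]]
  if (length(a) != length(b))
    stop("sequence lengths differ: ", length(a), " vs ", length(b))
  mean(a == b)
}

#' Sequence recovery restricted to hot-spot positions
#'
#' @param native,designed equal-length amino-acid strings.
#' @param labels hot-spot labels from [alanine_scan()] or
#'   [hotspot_labels()] for the native complex.
#' @return fraction in `[0, 1]`, or `NA` when there are no hot-spots
#'   (undefined; never coerced to 0).
#' @export
hotspot_recovery <- function(native, designed, labels) {
  hot <- vapply(labels, `[[`, logical(1), "is_hotspot")
  if (!any(hot)) return(NA_real_)
  a <- strsplit(native, "")[[1]]
  b <- strsplit(designed, "")[[1]]
  if (length(a) != length(b)) stop("sequence lengths differ")
  mean((a == b)[hot])
}

#' Best-of-n recovery over a design set
#'
#' @param native amino-acid string.
#' @param designs character vector of designed sequences (or a
#'   `design_set`).
#' @return the maximum [sequence_recovery()] over the designs.
#' @export
best_of_n_recovery <- function(native, designs) {
  seqs <- design_sequences(designs)
  stopifnot(length(seqs) >= 1)
  max(vapply(seqs, function(s) sequence_recovery(native, s), numeric(1)))
}

design_sequences <- function(designs) {
  if (inherits(designs, "design_set"))
    vapply(designs$predictions, `[[`, character(1), "sequence")
  else as.character(designs)
}

#' Mean pairwise design diversity
#'
#' Mean Hamming distance (number of differing positions) over all unordered
#' pairs of designs.
#'
#' @param designs character vector of equal-length sequences (or a
#'   `design_set`).
#' @return mean differing positions (0 for identical designs).
#' @export
design_diversity <- function(designs) {
  seqs <- design_sequences(designs)
  n <- length(seqs)
  stopifnot(n >= 2)
  mat <- do.call(rbind, strsplit(seqs, ""))
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / (n * (n - 1) / 2)
}

#' Amino-acid composition of a set of sequences
#'
#' @param seqs character vector of amino-acid strings.
#' @return named numeric 20-vector of frequencies summing to 1.
#' @export
aa_distribution <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  letters_all <- unlist(strsplit(seqs, ""))
  counts <- table(factor(letters_all, levels = AA_VOCAB))
  stats::setNames(as.numeric(counts) / length(letters_all), AA_VOCAB)
}

#' Recovery report for one native/designed pair
#'
#' Bundles overall recovery, hot-spot recovery, per-position and
#' per-secondary-structure breakdowns.
#'
#' @param native,designed equal-length amino-acid strings.
#' @param labels optional hot-spot labels for the native complex.
#' @param ss optional secondary-structure string/vector for the peptide.
#' @param energy_model_name provenance tag naming the energy model that
#'   produced `labels`.
#' @return an object of class `recovery_report`.
#' @export
recovery_report <- function(native, designed, labels = NULL, ss = NULL,
                            energy_model_name = "none") {
  per_pos <- {
    a <- strsplit(native, "")[[1]]
    b <- strsplit(designed, "")[[1]]
    if (length(a) != length(b)) stop("sequence lengths differ")
    as.numeric(a == b)
  }
  r_all <- mean(per_pos)
  r_hot <- if (is.null(labels)) NA_real_ else
    hotspot_recovery(native, designed, labels)
  n_hot <- if (is.null(labels)) 0L else
    sum(vapply(labels, `[[`, logical(1), "is_hotspot"))
  per_ss <- c(H = NA_real_, E = NA_real_, L = NA_real_)
  if (!is.null(ss)) {
    sv <- if (length(ss) == 1) strsplit(ss, "")[[1]] else as.character(ss)
    for (k in names(per_ss))
      if (any(sv == k)) per_ss[k] <- mean(per_pos[sv == k])
  }
  structure(list(R_all = r_all, R_hotspot = r_hot, per_position = per_pos,
                 per_ss = per_ss, n_residues = length(per_pos),
                 n_hotspots = n_hot, energy_model = energy_model_name),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> R_all = %.3f (%d residues), R_hotspot = %s (%d hot-spots), energy model: %s\n",
              x$R_all, x$n_residues,
              if (is.na(x$R_hotspot)) "undefined" else sprintf("%.3f", x$R_hotspot),
              x$n_hotspots, x$energy_model))
  invisible(x)
}
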