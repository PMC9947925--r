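# Synthetic peptide-pocket complexes with controllable geometry and a
# planted geometry -> sequence mapping.  These are first-class generators
# used for end-to-end testing of extraction, featurization, training and
# evaluation; they make no attempt to mimic real PDB statistics.

#' Settings for the synthetic complex generator
#'
#' @param n_complexes number of complexes for dataset generation.
#' @param site_size integer range `c(min, max)` within `[24, 48]`, or a
#'   single integer for an exact size.
#' @param peptide_ss secondary-structure type of the peptide backbone:
#'   `"H"`, `"E"` or `"L"` (canonical dihedrals).
#' @param mapping planted mapping rule id; only `"nearest-bin"` exists.
#' @param noise Gaussian coordinate jitter (Angstrom, sd) added to all
#'   atoms; default 0.
#' @param seed integer RNG seed.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(n_complexes = 50L, site_size = c(24L, 48L),
                     peptide_ss = "H", mapping = "nearest-bin",
                     noise = 0, seed = 1L) {
  if (length(site_size) == 1) site_size <- rep(site_size, 2)
  stopifnot(site_size[1] >= 24, site_size[2] <= 48,
            site_size[1] <= site_size[2], n_complexes >= 1)
  peptide_ss <- match.arg(peptide_ss, c("H", "E", "L"))
  mapping <- match.arg(mapping, "nearest-bin")
  structure(list(n_complexes = as.integer(n_complexes),
                 site_size = as.integer(site_size),
                 peptide_ss = peptide_ss, mapping = mapping,
                 noise = noise, seed = as.integer(seed)),
            class = "toy_spec")
}

# single-residue backbone template centered at the origin
.residue_template <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      bb <- build_backbone(phi = -80, psi = 150)
      tmpl <<- sweep(bb[1, , ], 2, colMeans(bb[1, , ]))
    }
    tmpl
  }
})

#' Generate one synthetic peptide-pocket complex
#'
#' Builds an ideal-geometry 6-residue peptide backbone from canonical
#' dihedrals and poses a procedurally built pocket around it: site residues
#' are rigid single-residue backbone templates placed at 4-8 Angstrom from
#' peptide anchor atoms, facing the peptide from scattered directions.
#' The peptide's native sequence is the planted mapping applied to the
#' final geometry (see [planted_rule_read()]). Deterministic given
#' `spec$seed`.
#'
#' @param spec a [toy_spec()].
#' @return a `complex_record` satisfying all record invariants.
#' @export
generate_toy_complex <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  dih <- CANONICAL_DIHEDRALS[[spec$peptide_ss]]
  n <- PEPTIDE_LEN
  bb <- build_backbone(phi = rep(dih["phi"], n), psi = rep(dih["psi"], n))
  pep <- residue_set("P", seq_len(n), rep("G", n), bb,
                     ss = rep(spec$peptide_ss, n))
  n_site <- if (spec$site_size[1] == spec$site_size[2]) spec$site_size[1] else
    sample(spec$site_size[1]:spec$site_size[2], 1)
  tmpl <- .residue_template()
  anchors <- pep$coords[, "CA", ]
  axis_dir <- unitv(anchors[n, ] - anchors[1, ])
  co <- array(NA_real_, dim = c(n_site, 4, 3))
  for (j in seq_len(n_site)) {
    anchor <- anchors[((j - 1) %% n) + 1, ]
    # random direction not too parallel to the chain axis
    repeat {
      dir <- stats::rnorm(3)
      dir <- dir - sum(dir * axis_dir) * axis_dir * 0.7
      if (vnorm(dir) > 0.3) break
    }
    dir <- unitv(dir)
    center <- anchor + dir * stats::runif(1, 4, 8)
    rot <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    co[j, , ] <- sweep(tmpl %*% t(rot), 2, center, "+")
  }
  site <- residue_set("B", seq_len(n_site),
                      sample(AA_VOCAB, n_site, replace = TRUE), co,
                      ss = sample(SS_VOCAB, n_site, replace = TRUE,
                                  prob = c(0.4, 0.3, 0.3)))
  if (spec$noise > 0) {
    pep$coords <- pep$coords + stats::rnorm(length(pep$coords),
                                            sd = spec$noise)
    site$coords <- site$coords + stats::rnorm(length(site$coords),
                                              sd = spec$noise)
  }
  label <- sample(0:1, 1)
  cr <- complex_record(pep, site, label,
                       provenance = list(source_id = sprintf("toy%06d",
                                                             spec$seed),
                                         mapping = spec$mapping))
  cr$peptide$aa <- strsplit(planted_rule_read(cr), "")[[1]]
  cr
}

#' Read the planted target sequence off a complex's geometry
#'
#' The planted mapping (`"nearest-bin"`) is a deterministic function of
#' observable features: for peptide position i, let j be the site residue
#' whose backbone N atom is nearest to the peptide residue's N atom, `a`
#' the amino-acid code (1-20) of that site residue, and b = 0 if the N-N
#' distance is below 6 Angstrom, else 1. The target residue is
#' `AA_VOCAB[((a - 1 + 7 b) mod 20) + 1]`. This brute-force reader is the
#' ground truth the sequence-design model is expected to learn.
#'
#' @param cr a `complex_record`.
#' @return the 6-letter target sequence.
#' @export
planted_rule_read <- function(cr) {
  stopifnot(inherits(cr, "complex_record"))
  pn <- cr$peptide$coords[, "N", ]
  sn <- cr$site$coords[, "N", ]
  codes <- aa_encode(cr$site$aa)
  out <- character(PEPTIDE_LEN)
  for (i in seq_len(PEPTIDE_LEN)) {
    d <- sqrt(colSums((t(sn) - pn[i, ])^2))
    j <- which.min(d)
    b <- as.integer(d[j] >= 6)
    out[i] <- AA_VOCAB[((codes[j] - 1 + 7 * b) %% 20) + 1]
  }
  paste(out, collapse = "")
}

#' Generate a planted-mapping dataset
#'
#' A list of (complex, target) pairs in which every target sequence is the
#' planted rule applied to that complex's geometry: with zero noise the
#' mapping is exactly consistent (no label conflicts), and a non-learned
#' rule reader recovers 100% of the targets.
#'
#' @param spec a [toy_spec()].
#' @return list with `records` (list of `complex_record`) and `targets`
#'   (character vector of 6-letter sequences).
#' @export
planted_mapping_dataset <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  records <- vector("list", spec$n_complexes)
  targets <- character(spec$n_complexes)
  for (i in seq_len(spec$n_complexes)) {
    si <- spec
    si$seed <- spec$seed + i - 1L
    records[[i]] <- generate_toy_complex(si)
    targets[i] <- planted_rule_read(records[[i]])
  }
  list(records = records, targets = targets)
}

#' Assemble a toy complex into a 2-chain structure
#'
#' Packages a synthetic record as a `protein_structure` (peptide chain plus
#' pocket chain), e.g. for writing to PDB and re-extracting.
#'
#' @param cr a `complex_record`.
#' @return a `protein_structure`.
#' @export
toy_structure <- function(cr) {
  stopifnot(inherits(cr, "complex_record"))
  chains <- list()
  chains[[cr$site$chain_id[1]]] <- cr$site
  chains[[cr$peptide$chain_id[1]]] <- cr$peptide
  protein_structure(chains, source_id = cr$provenance$source_id %||% "toy")
}
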