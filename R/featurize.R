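# Featurization of a complex_record into the five fixed-shape model inputs:
#   input1  48 x 6 x 2  intermolecular N-N / O-O backbone distance maps
#   input2  48          binding-site amino-acid codes (0 = pad)
#   input3  48          binding-site secondary-structure codes (0 = pad)
#   input4  6 x 6 x 2   intramolecular peptide N-N / O-O distance maps
#   input5  1           homo(1)/hetero(0) oligomeric label
# Distances are raw Angstrom; rows beyond the true site size are zero.

SITE_CAPACITY <- 48L

pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Intermolecular site-peptide distance maps
#'
#' Channel 1 holds pairwise distances between site and peptide backbone N
#' atoms, channel 2 the O-O distances. Site rows follow chain order; rows
#' beyond the true site size are zero padding.
#'
#' @param cr a `complex_record`.
#' @param capacity number of site rows in the output (default 48).
#' @return numeric array `capacity x 6 x 2` (Angstrom).
#' @export
inter_distance_maps <- function(cr, capacity = SITE_CAPACITY) {
  stopifnot(inherits(cr, "complex_record"), capacity >= length(cr$site))
  out <- array(0, dim = c(capacity, PEPTIDE_LEN, 2))
  s <- length(cr$site)
  out[seq_len(s), , 1] <- pair_dist(cr$site$coords[, "N", , drop = TRUE],
                                    cr$peptide$coords[, "N", , drop = TRUE])
  out[seq_len(s), , 2] <- pair_dist(cr$site$coords[, "O", , drop = TRUE],
                                    cr$peptide$coords[, "O", , drop = TRUE])
  out
}

#' Intramolecular peptide distance maps
#'
#' Channel 1: peptide N-N distances; channel 2: O-O distances. Each channel
#' is symmetric with a zero diagonal.
#'
#' @param peptide a 6-residue `residue_set`.
#' @return numeric array `6 x 6 x 2` (Angstrom).
#' @export
intra_distance_maps <- function(peptide) {
  stopifnot(inherits(peptide, "residue_set"), length(peptide) == PEPTIDE_LEN)
  out <- array(0, dim = c(PEPTIDE_LEN, PEPTIDE_LEN, 2))
  n <- peptide$coords[, "N", , drop = TRUE]
  o <- peptide$coords[, "O", , drop = TRUE]
  out[, , 1] <- pair_dist(n, n)
  out[, , 2] <- pair_dist(o, o)
  diag(out[, , 1]) <- 0
  diag(out[, , 2]) <- 0
  out
}

#' Integer-encode the binding site sequence and secondary structure
#'
#' @param cr a `complex_record` whose site residues carry `aa` and `ss`.
#' @param capacity padded length (default 48).
#' @return list with `site_aa` and `site_ss`, length-`capacity` integer
#'   vectors (0 = pad; amino acids 1-20 alphabetical; H/E/L = 1/2/3).
#' @export
encode_site <- function(cr, capacity = SITE_CAPACITY) {
  stopifnot(inherits(cr, "complex_record"), capacity >= length(cr$site))
  s <- length(cr$site)
  if (anyNA(cr$site$ss))
    stop("site secondary structure unassigned; run assign_secondary_structure")
  aa <- integer(capacity)
  ss <- integer(capacity)
  aa[seq_len(s)] <- aa_encode(cr$site$aa)
  ss[seq_len(s)] <- ss_encode(cr$site$ss)
  list(site_aa = aa, site_ss = ss)
}

#' Featurize a complex into the five model inputs
#'
#' Deterministic composition of [inter_distance_maps()],
#' [encode_site()], [intra_distance_maps()] and the oligomeric label.
#' The geometry channels use backbone atoms only, so stripping the peptide
#' to glycine does not change them.
#'
#' @param cr a `complex_record`.
#' @param capacity padded site length (default 48).
#' @return an object of class `feature_tensors` with fields `inter_maps`,
#'   `site_aa`, `site_ss`, `intra_maps`, `oligo`, `site_size`.
#' @export
featurize_complex <- function(cr, capacity = SITE_CAPACITY) {
  enc <- encode_site(cr, capacity)
  structure(list(inter_maps = inter_distance_maps(cr, capacity),
                 site_aa = enc$site_aa, site_ss = enc$site_ss,
                 intra_maps = intra_distance_maps(cr$peptide),
                 oligo = as.numeric(cr$oligomeric_label),
                 site_size = length(cr$site)),
            class = "feature_tensors")
}

#' @export
print.feature_tensors <- function(x, ...) {
  cat(sprintf("<feature_tensors> inter %s, site %d/%d residues, oligo=%d\n",
              paste(dim(x$inter_maps), collapse = "x"), x$site_size,
              length(x$site_aa), x$oligo))
  invisible(x)
}

#' Save featurized complexes to a JSON tensor store
#'
#' One group per complex with datasets named `input1`..`input5` (the
#' intermolecular maps, site amino-acid codes, site secondary-structure
#' codes, intramolecular maps and oligomeric label), plus a TSV manifest
#' linking group names to provenance.
#'
#' @param fts list of `feature_tensors`.
#' @param path output `.json` path; the manifest is written next to it.
#' @param provenance optional character vector (one id per complex).
#' @return `path`, invisibly.
#' @export
save_feature_store <- function(fts, path, provenance = NULL) {
  groups <- lapply(seq_along(fts), function(i) {
    ft <- fts[[i]]
    list(input1 = ft$inter_maps, input2 = ft$site_aa, input3 = ft$site_ss,
         input4 = ft$intra_maps, input5 = ft$oligo,
         site_size = ft$site_size)
  })
  names(groups) <- sprintf("complex%05d", seq_along(fts))
  jsonlite::write_json(groups, path, digits = NA)
  manifest <- data.frame(group = names(groups),
                         provenance = provenance %||%
                           rep(NA_character_, length(fts)))
  utils::write.table(manifest, paste0(path, ".manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a JSON tensor store
#'
#' @param path path written by [save_feature_store()].
#' @return list of `feature_tensors`.
#' @export
load_feature_store <- function(path) {
  groups <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_arr <- function(x, default_dim) {
    if (is.null(dim(x))) array(as.numeric(x), dim = default_dim)
    else array(as.numeric(x), dim = dim(x))
  }
  lapply(groups, function(g) {
    structure(list(inter_maps = as_arr(g$input1,
                                       c(length(g$input2), PEPTIDE_LEN, 2)),
                   site_aa = as.integer(g$input2),
                   site_ss = as.integer(g$input3),
                   intra_maps = as_arr(g$input4,
                                       c(PEPTIDE_LEN, PEPTIDE_LEN, 2)),
                   oligo = as.numeric(g$input5),
                   site_size = as.integer(g$site_size)),
              class = "feature_tensors")
  })
}
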