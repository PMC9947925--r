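# A residue_set is the package's backbone container: a vectorized run of
# residues with chain id, author numbering, one-letter identity, optional
# 3-state secondary structure, and an n x 4 x 3 coordinate array (atom
# slices N, CA, C, O, Angstrom).  Chains, peptides and binding sites are
# all residue_sets.

#' Construct a residue set
#'
#' @param chain_id character vector (recycled) of chain identifiers.
#' @param res_seq integer vector of author residue numbers.
#' @param aa character vector of one-letter amino-acid codes (or `"X"`).
#' @param coords numeric array `n x 4 x 3`, atoms ordered N, CA, C, O.
#' @param ss optional character vector over `{"H","E","L"}` (or `NA`).
#' @return an object of class `residue_set`.
#' @export
residue_set <- function(chain_id, res_seq, aa, coords, ss = NULL) {
  n <- length(res_seq)
  chain_id <- rep_len(as.character(chain_id), n)
  if (is.null(ss)) ss <- rep(NA_character_, n)
  stopifnot(length(aa) == n, length(ss) == n,
            is.array(coords), length(dim(coords)) == 3,
            dim(coords)[1] == n, dim(coords)[2] == 4, dim(coords)[3] == 3)
  dimnames(coords) <- list(NULL, c("N", "CA", "C", "O"), NULL)
  structure(list(chain_id = chain_id, res_seq = as.integer(res_seq),
                 aa = as.character(aa), ss = as.character(ss),
                 coords = coords),
            class = "residue_set")
}

#' @export
length.residue_set <- function(x) length(x$res_seq)

#' Subset a residue set by residue index
#' @param rs a `residue_set`.
#' @param idx integer or logical index over residues.
#' @return a `residue_set` with the selected residues, in `idx` order.
#' @export
rs_subset <- function(rs, idx) {
  residue_set(rs$chain_id[idx], rs$res_seq[idx], rs$aa[idx],
              rs$coords[idx, , , drop = FALSE], rs$ss[idx])
}

#' Concatenate residue sets
#' @param ... `residue_set` objects.
#' @return one combined `residue_set` in argument order.
#' @export
rs_bind <- function(...) {
  parts <- list(...)
  co <- do.call(abind3, lapply(parts, function(p) p$coords))
  residue_set(unlist(lapply(parts, `[[`, "chain_id")),
              unlist(lapply(parts, `[[`, "res_seq")),
              unlist(lapply(parts, `[[`, "aa")),
              co,
              unlist(lapply(parts, `[[`, "ss")))
}

# bind n x 4 x 3 arrays along the first margin
abind3 <- function(...) {
  parts <- list(...)
  ns <- vapply(parts, function(p) dim(p)[1], integer(1))
  out <- array(NA_real_, dim = c(sum(ns), 4, 3))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    if (n > 0) out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}

#' Flatten a residue set's backbone atoms to an (4n) x 3 matrix
#' @param rs a `residue_set`.
#' @param atoms which atom names to include, in order.
#' @return numeric matrix with one row per atom, residues varying slowest.
#' @export
rs_atoms <- function(rs, atoms = c("N", "CA", "C", "O")) {
  n <- length(rs)
  out <- matrix(NA_real_, n * length(atoms), 3)
  for (k in seq_along(atoms)) {
    out[seq(k, by = length(atoms), length.out = n), ] <- rs$coords[, atoms[k], ]
  }
  out
}

#' Single-letter sequence of a residue set
#' @param rs a `residue_set`.
#' @return a character scalar.
#' @export
rs_sequence <- function(rs) paste(rs$aa, collapse = "")

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("<residue_set> %d residues, chain(s) %s: %s\n", length(x),
              paste(unique(x$chain_id), collapse = ","), rs_sequence(x)))
  invisible(x)
}

# Pseudo-CB position from backbone geometry (ideal tetrahedral branch);
# for glycine the CA itself is the side-chain proxy.
rs_cb_proxy <- function(rs) {
  n <- length(rs)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (rs$aa[i] == "G") {
      out[i, ] <- rs$coords[i, "CA", ]
    } else {
      out[i, ] <- place_atom(rs$coords[i, "N", ], rs$coords[i, "C", ],
                             rs$coords[i, "CA", ], 1.52, 110.6, -122.6)
    }
  }
  out
}
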