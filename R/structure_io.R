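# PDB structure input/output.  Parsing is delegated to bio3d; this layer
# enforces the package's backbone-completeness contract and produces the
# internal protein_structure container.

#' Construct a protein structure container
#' @param chains named list of `residue_set` objects (one per chain).
#' @param source_id provenance string (file stem or PDB code).
#' @return an object of class `protein_structure`.
#' @export
protein_structure <- function(chains, source_id = "unknown") {
  stopifnot(is.list(chains), length(chains) >= 1)
  structure(list(chains = chains, source_id = source_id),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d chain(s)\n", x$source_id,
              length(x$chains)))
  for (nm in names(x$chains))
    cat(sprintf("  chain %s: %d residues\n", nm, length(x$chains[[nm]])))
  invisible(x)
}

#' Read a multichain PDB file
#'
#' Parses ATOM records only. Waters, HETATM records and non-canonical
#' residues are excluded. A residue is retained only if all four backbone
#' atoms (N, CA, C, O) are present and CA-N / CA-C distances fall in
#' (0.5, 2.5) Angstrom; dropped residues are counted and reported via
#' `message()`. Alternate locations resolve to the highest occupancy
#' (ties: first listed); residue-number collisions keep the first
#' occurrence. Residues are ordered by author number within each chain.
#'
#' @param path path to a PDB-format text file.
#' @return a `protein_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("PDB parse error for '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(AA_ONE) &
             at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  dropped <- 0L
  chains <- list()
  if (nrow(at) > 0) {
    at$chain[is.na(at$chain)] <- " "
    # altloc: highest occupancy first, then file order, per residue-atom
    at$o[is.na(at$o)] <- 1
    at <- at[order(at$chain, at$resno, at$elety, -at$o,
                   seq_len(nrow(at))), , drop = FALSE]
    at <- at[!duplicated(at[, c("chain", "resno", "insert", "elety")]), ,
             drop = FALSE]
    # first-occurrence rule for insertion-code collisions on one resno
    at <- at[order(at$chain, at$resno, seq_len(nrow(at))), , drop = FALSE]
    key <- paste(at$chain, at$resno, at$elety)
    at <- at[!duplicated(key), , drop = FALSE]
    for (ch in unique(at$chain)) {
      sub <- at[at$chain == ch, , drop = FALSE]
      resnos <- unique(sub$resno)
      keep_aa <- character(0); keep_no <- integer(0)
      keep_xyz <- list()
      for (rn in resnos) {
        rsub <- sub[sub$resno == rn, , drop = FALSE]
        rows <- match(c("N", "CA", "C", "O"), rsub$elety)
        if (anyNA(rows)) { dropped <- dropped + 1L; next }
        xyz <- as.matrix(rsub[rows, c("x", "y", "z")])
        d_n <- vnorm(xyz[2, ] - xyz[1, ])
        d_c <- vnorm(xyz[2, ] - xyz[3, ])
        if (d_n <= 0.5 || d_n >= 2.5 || d_c <= 0.5 || d_c >= 2.5) {
          dropped <- dropped + 1L; next
        }
        keep_aa <- c(keep_aa, AA_ONE[[rsub$resid[1]]])
        keep_no <- c(keep_no, rn)
        keep_xyz[[length(keep_xyz) + 1L]] <- xyz
      }
      if (length(keep_no) == 0) next
      co <- array(NA_real_, dim = c(length(keep_no), 4, 3))
      for (i in seq_along(keep_xyz)) co[i, , ] <- keep_xyz[[i]]
      chains[[ch]] <- residue_set(ch, keep_no, keep_aa, co)
    }
  }
  if (length(chains) == 0)
    stop("no backbone-complete canonical residues in '", path, "'")
  if (dropped > 0)
    message(sprintf("read_pdb: dropped %d incomplete residue(s) from %s",
                    dropped, basename(path)))
  src <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  protein_structure(chains, source_id = src)
}

# phi/psi dihedrals for one chain; NA at termini where undefined.
chain_phi_psi <- function(rs) {
  n <- length(rs)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral_angle(rs$coords[i - 1, "C", ], rs$coords[i, "N", ],
                               rs$coords[i, "CA", ], rs$coords[i, "C", ])
    if (i < n)
      psi[i] <- dihedral_angle(rs$coords[i, "N", ], rs$coords[i, "CA", ],
                               rs$coords[i, "C", ], rs$coords[i + 1, "N", ])
  }
  list(phi = phi, psi = psi)
}

ss_from_phipsi <- function(phi, psi) {
  n <- length(phi)
  ss <- rep("L", n)
  for (i in seq_len(n)) {
    if (is.na(phi[i]) || is.na(psi[i])) next   # chain termini stay L
    if (phi[i] > -100 && phi[i] < -30 && psi[i] > -80 && psi[i] < -5) {
      ss[i] <- "H"
    } else if (phi[i] > -170 && phi[i] < -50 &&
               (psi[i] > 90 || psi[i] < -170)) {
      ss[i] <- "E"
    }
  }
  # smoothing: H/E runs shorter than 3 revert to loop
  r <- rle(ss)
  r$values[r$values %in% c("H", "E") & r$lengths < 3] <- "L"
  inverse.rle(r)
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' Labels every residue H (helix), E (strand) or L (loop) from its phi/psi
#' dihedrals: H for phi in (-100, -30) and psi in (-80, -5); E for phi in
#' (-170, -50) with psi in (90, 180) or (-180, -170); otherwise L. Runs of
#' H or E shorter than 3 are smoothed to L, and chain-terminal residues
#' (undefined phi or psi) are L. Purely a function of coordinates.
#'
#' @param s a `protein_structure`.
#' @return the same structure with the `ss` field filled on every chain.
#' @export
assign_secondary_structure <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  s$chains <- lapply(s$chains, function(rs) {
    pp <- chain_phi_psi(rs)
    rs$ss <- ss_from_phipsi(pp$phi, pp$psi)
    rs
  })
  s
}

#' Write a designed complex as a PDB file
#'
#' Emits backbone-only ATOM records for the peptide (with residue names
#' replaced by `seq`) followed by the binding-site residues with their
#' native identities. Round-trips through [read_pdb()].
#'
#' @param cr a `complex_record`.
#' @param seq designed peptide sequence; length must equal the peptide's.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_designed_pdb <- function(cr, seq, path) {
  stopifnot(inherits(cr, "complex_record"))
  aa <- strsplit(seq, "")[[1]]
  if (length(aa) != length(cr$peptide))
    stop(sprintf("designed sequence length %d != peptide length %d",
                 length(aa), length(cr$peptide)))
  aa_encode(aa)   # validates letters
  pep <- cr$peptide
  pep$aa <- aa
  all_rs <- rs_bind(pep, cr$site)
  n <- length(all_rs)
  xyz <- as.numeric(t(rs_atoms(all_rs)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", 4 * n),
                   resno = rep(all_rs$res_seq, each = 4),
                   resid = rep(AA_THREE[all_rs$aa], each = 4),
                   chain = rep(all_rs$chain_id, each = 4),
                   elety = rep(c("N", "CA", "C", "O"), n),
                   eleno = seq_len(4 * n))
  invisible(path)
}

#' Write designed sequences to FASTA
#'
#' One record per design; headers are `<source_id>_design<i>`.
#'
#' @param seqs character vector of designed sequences.
#' @param path output FASTA path.
#' @param source_id provenance string used in headers.
#' @return `path`, invisibly.
#' @export
write_designs_fasta <- function(seqs, path, source_id = "design") {
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- sprintf("%s_design%d", source_id, seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
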