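# Shared fixture builders.  Everything is generated in code; no binary
# fixtures.

# A residue_set with the given sequence on an idealized helix backbone.
helix_peptide <- function(seq = "GGGGGG", chain = "P", ss = "H") {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  dih <- pepdesign:::CANONICAL_DIHEDRALS[[ss]]
  residue_set(chain, seq_len(n), aa,
              build_backbone(rep(dih["phi"], n), rep(dih["psi"], n)),
              ss = rep(ss, n))
}

# A pocket record built directly from the toy generator.
toy_record <- function(seed = 1, site_size = c(24L, 48L), noise = 0) {
  generate_toy_complex(toy_spec(site_size = site_size, noise = noise,
                                seed = seed))
}

# Mock energy model with per-letter alanine-scan increments: mutating
# residue aa -> A changes the binding energy by exactly vals[aa]
# (vals["A"] is forced to 0), so alanine_scan() returns vals[aa_i] per
# position.  `offset` shifts the total binding energy.
mock_energy <- function(vals, offset = 5) {
  vals <- c(vals, A = 0)[!duplicated(c(names(vals), "A"))]
  vals["A"] <- 0
  structure(list(
    name = "mock", units = "surrogate REU",
    per_residue = function(cr) unname(vals[cr$peptide$aa]),
    binding_energy = function(cr)
      -(sum(vals[cr$peptide$aa], na.rm = TRUE) + offset)
  ), class = "energy_model")
}

# Tiny model configuration for fast training tests.
tiny_config <- function(seed = 1) {
  designer_config(conv_inter = rep(8L, 8), conv_intra = rep(8L, 4),
                  emb_aa = 8, emb_ss = 4, emb_dec = 8, d_model = 48,
                  enc_rnn = 16, dec_rnn = 32, att = 16, seed = seed)
}

# Random (non-physical) feature tensors for pure-contract tests.
random_tensors <- function(seed = 1, site_size = 30L, capacity = 48L) {
  withr::with_seed(seed, {
    inter <- array(0, dim = c(capacity, 6, 2))
    inter[seq_len(site_size), , ] <- runif(site_size * 12, 2, 15)
    intra <- array(0, dim = c(6, 6, 2))
    for (ch in 1:2) {
      m <- matrix(runif(36, 3, 12), 6, 6)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      intra[, , ch] <- m
    }
    structure(list(inter_maps = inter,
                   site_aa = c(sample(1:20, site_size, replace = TRUE),
                               rep(0L, capacity - site_size)),
                   site_ss = c(sample(1:3, site_size, replace = TRUE),
                               rep(0L, capacity - site_size)),
                   intra_maps = intra, oligo = sample(0:1, 1),
                   site_size = as.integer(site_size)),
              class = "feature_tensors")
  })
}

# Minimal PDB text for one residue's backbone; helper for read_pdb tests.
# Fixed-width columns per the PDB ATOM record layout (altLoc at col 17).
pdb_atom_line <- function(serial, elety, resid, chain, resno, xyz,
                          occ = 1, type = "ATOM", alt = " ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, elety, alt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0)
}

# Write a PDB file for a list of residue_sets (one per chain);
# optionally drop named atoms of specific residues.
write_test_pdb <- function(chains, path, drop = NULL) {
  lines <- character(0)
  serial <- 0L
  for (rs in chains) {
    for (i in seq_along(rs)) {
      for (at in c("N", "CA", "C", "O")) {
        if (!is.null(drop) &&
            any(drop$chain == rs$chain_id[i] & drop$resno == rs$res_seq[i] &
                  drop$atom == at)) next
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, at,
                                        pepdesign:::AA_THREE[rs$aa[i]],
                                        rs$chain_id[i], rs$res_seq[i],
                                        rs$coords[i, at, ]))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}
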