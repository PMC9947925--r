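# Extraction of 6-residue peptide fragments and their 24-48-residue binding
# sites from multichain structures, plus the dataset selection filters.

PEPTIDE_LEN <- 6L
SITE_MIN <- 24L
SITE_MAX <- 48L
CA_CA_BREAK <- 4.2        # Angstrom; larger consecutive CA-CA = chain break
DEFAULT_SITE_CUTOFF <- 10 # Angstrom; min backbone-atom distance to peptide
HOTSPOT_DDG <- 3          # REU; alanine-scanning hot-spot threshold

#' Construct and validate a peptide-site complex record
#'
#' A complex record pairs one contiguous 6-residue peptide fragment with the
#' 24-48-residue binding-site patch on the partner chain(s). Invariants
#' (peptide length and contiguity, site size band) are enforced here.
#'
#' @param peptide `residue_set` of exactly 6 contiguous residues (one chain).
#' @param site `residue_set` of 24-48 partner residues, in chain order.
#' @param oligomeric_label 0 (hetero) or 1 (homo).
#' @param provenance list with at least `source_id`; free-form otherwise.
#' @return an object of class `complex_record`.
#' @export
complex_record <- function(peptide, site, oligomeric_label = 0L,
                           provenance = list(source_id = "synthetic")) {
  stopifnot(inherits(peptide, "residue_set"), inherits(site, "residue_set"))
  if (length(peptide) != PEPTIDE_LEN)
    stop("peptide must have exactly ", PEPTIDE_LEN, " residues")
  if (length(unique(peptide$chain_id)) != 1)
    stop("peptide must come from a single chain")
  if (any(diff(peptide$res_seq) != 1L))
    stop("peptide residues must be consecutive in author numbering")
  ca <- peptide$coords[, "CA", ]
  gaps <- sqrt(rowSums((ca[-1, , drop = FALSE] -
                          ca[-nrow(ca), , drop = FALSE])^2))
  if (any(gaps >= CA_CA_BREAK))
    stop("peptide has a chain break (CA-CA >= ", CA_CA_BREAK, " A)")
  if (length(site) < SITE_MIN || length(site) > SITE_MAX)
    stop("site must have ", SITE_MIN, "-", SITE_MAX, " residues, got ",
         length(site))
  if (!is.numeric(oligomeric_label) || !oligomeric_label %in% c(0, 1))
    stop("oligomeric_label must be 0 or 1")
  structure(list(peptide = peptide, site = site,
                 oligomeric_label = as.integer(oligomeric_label),
                 provenance = provenance),
            class = "complex_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("<complex_record> %s: peptide %s (chain %s, start %d), site %d residues, %s-oligomeric\n",
              x$provenance$source_id %||% "?", rs_sequence(x$peptide),
              x$peptide$chain_id[1], x$peptide$res_seq[1], length(x$site),
              if (x$oligomeric_label == 1) "homo" else "hetero"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate contiguous 6-residue windows of a ligand chain
#'
#' Returns every length-6 window with consecutive author numbering and no
#' chain break (consecutive CA-CA < 4.2 Angstrom). Windows touching
#' non-canonical (`"X"`) residues are excluded.
#'
#' @param chain a `residue_set` (one chain, ordered).
#' @return list of 6-residue `residue_set` windows (possibly empty).
#' @export
enumerate_fragments <- function(chain) {
  n <- length(chain)
  if (n < PEPTIDE_LEN) return(list())
  ca <- chain$coords[, "CA", ]
  gap_ok <- c(sqrt(rowSums((ca[-1, , drop = FALSE] -
                              ca[-n, , drop = FALSE])^2)) < CA_CA_BREAK &
                diff(chain$res_seq) == 1L)
  canon <- chain$aa %in% AA_VOCAB
  out <- list()
  for (s in seq_len(n - PEPTIDE_LEN + 1L)) {
    idx <- s:(s + PEPTIDE_LEN - 1L)
    if (all(gap_ok[idx[-PEPTIDE_LEN]]) && all(canon[idx]))
      out[[length(out) + 1L]] <- rs_subset(chain, idx)
  }
  out
}

# minimum backbone-atom distance from each partner residue to any peptide
# backbone atom
min_backbone_dist <- function(peptide, partner_rs) {
  pa <- rs_atoms(peptide)          # 24 x 3
  n <- length(partner_rs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ra <- partner_rs$coords[i, , ]            # 4 x 3
    d2 <- outer(rowSums(ra^2), rowSums(pa^2), "+") - 2 * ra %*% t(pa)
    out[i] <- sqrt(max(min(d2), 0))
  }
  out
}

#' Select the binding-site patch for a peptide fragment
#'
#' Collects partner residues whose minimum backbone-atom distance to any
#' peptide backbone atom is at most `cutoff`, keeps the nearest 48 when
#' over-subscribed, and returns `NULL` when fewer than 24 qualify. Selected
#' residues are returned re-sorted to chain order (chain id, then residue
#' number).
#'
#' @param peptide 6-residue `residue_set`.
#' @param partner a `protein_structure` (the binder side); the peptide's own
#'   chain is excluded by chain id.
#' @param cutoff proximity cutoff in Angstrom (default 10).
#' @return a `residue_set` of 24-48 residues, or `NULL` if under-subscribed.
#' @export
select_binding_site <- function(peptide, partner,
                                cutoff = DEFAULT_SITE_CUTOFF) {
  stopifnot(inherits(partner, "protein_structure"))
  pool <- partner$chains[setdiff(names(partner$chains),
                                 peptide$chain_id[1])]
  if (length(pool) == 0) return(NULL)
  all_rs <- do.call(rs_bind, unname(pool))
  d <- min_backbone_dist(peptide, all_rs)
  within <- which(d <= cutoff)
  if (length(within) < SITE_MIN) return(NULL)
  if (length(within) > SITE_MAX)
    within <- within[order(d[within])][seq_len(SITE_MAX)]
  within <- within[order(all_rs$chain_id[within], all_rs$res_seq[within])]
  rs_subset(all_rs, within)
}

#' Label a complex homo- or hetero-oligomeric
#'
#' Compares the peptide chain's full parent sequence with the partner
#' chain's sequence by pairwise alignment; identity of at least
#' `threshold` over the shorter chain length labels the interface
#' homo-oligomeric (1), otherwise hetero-oligomeric (0).
#'
#' @param chain_a,chain_b one-letter sequences of the two interacting chains.
#' @param threshold identity fraction for the homo call (default 0.9).
#' @return integer 0 or 1.
#' @export
label_oligomeric <- function(chain_a, chain_b, threshold = 0.9) {
  if (identical(chain_a, chain_b)) return(1L)
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(chain_a),
                                      Biostrings::AAString(chain_b),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  ident <- Biostrings::nmatch(al) / min(nchar(chain_a), nchar(chain_b))
  as.integer(ident >= threshold)
}

#' Apply the dataset selection filters to a candidate complex
#'
#' A complex is accepted if (in order):
#' \enumerate{
#'   \item at least 2 peptide residues contribute binding energy
#'     increments \eqn{\Delta\Delta G_i > 0.5} REU (alanine scanning under
#'     the supplied energy model);
#'   \item at least 3 non-terminal peptide residues lie within 6 Angstrom of
#'     the site (closest side-chain heavy-atom distance; an idealized CB —
#'     CA for glycine — is the side-chain proxy on backbone-only input);
#'   \item the structure's resolution, when known, passes the per-class
#'     threshold (2.0 A homo, 2.5 A hetero, 3.5 A antibody complexes);
#'     skipped with a warning when no resolution metadata is available;
#'   \item the complex binding energy is negative;
#'   \item at least one non-polar residue is present among the peptide's
#'     hot-spot residues (\eqn{\Delta\Delta G_i \ge 3} REU).
#' }
#' The rejection reason names the first failed criterion.
#'
#' @param cr a `complex_record`.
#' @param em an energy model (see [surrogate_energy()]).
#' @param resolution optional resolution in Angstrom (`NA` = unknown).
#' @param is_antibody whether the complex is an antibody-antigen interface
#'   (affects the resolution threshold only).
#' @return list with `accept` (logical) and `reason` (string, `"ok"` when
#'   accepted).
#' @export
apply_selection_filters <- function(cr, em = surrogate_energy(),
                                    resolution = NA_real_,
                                    is_antibody = FALSE) {
  stopifnot(inherits(cr, "complex_record"))
  labs <- alanine_scan(cr, em)
  ddg <- vapply(labs, `[[`, numeric(1), "ddG")
  if (sum(ddg > 0.5) < 2)
    return(list(accept = FALSE,
                reason = "fewer than 2 residues with ddG > 0.5 REU"))
  cb_pep <- rs_cb_proxy(cr$peptide)
  cb_site <- rs_cb_proxy(cr$site)
  d2 <- outer(rowSums(cb_pep^2), rowSums(cb_site^2), "+") -
    2 * cb_pep %*% t(cb_site)
  near <- sqrt(pmax(apply(d2, 1, min), 0)) <= 6
  if (sum(near[2:(PEPTIDE_LEN - 1)]) < 3)
    return(list(accept = FALSE,
                reason = "fewer than 3 non-terminal residues within 6 A of site"))
  if (is.na(resolution)) {
    warning("no resolution metadata; resolution filter skipped",
            call. = FALSE)
  } else {
    thr <- if (is_antibody) 3.5 else if (cr$oligomeric_label == 1) 2.0 else 2.5
    if (resolution > thr)
      return(list(accept = FALSE,
                  reason = sprintf("resolution %.2f A exceeds %.1f A threshold",
                                   resolution, thr)))
  }
  if (em$binding_energy(cr) >= 0)
    return(list(accept = FALSE, reason = "non-negative binding energy"))
  # composition check: hot-spots (>= 3 REU); when the complex has no
  # hot-spot at that threshold, the > 0.5 REU binding contributors stand in
  hot <- vapply(labs, `[[`, logical(1), "is_hotspot")
  if (!any(hot)) hot <- ddg > 0.5
  if (!any(cr$peptide$aa[hot] %in% AA_NONPOLAR))
    return(list(accept = FALSE, reason = "no non-polar residue among hot-spots"))
  list(accept = TRUE, reason = "ok")
}

#' Extract accepted peptide-site complexes from a structure
#'
#' Runs fragment enumeration on the ligand chain, binding-site selection
#' against the remaining chains, oligomeric labeling, and the selection
#' filters; returns accepted records plus a manifest of all candidates.
#'
#' @param s a `protein_structure` (secondary structure is assigned if absent).
#' @param ligand_chain chain id of the ligand (peptide source) chain.
#' @param cutoff binding-site proximity cutoff in Angstrom.
#' @param em energy model used by the filters.
#' @param resolution optional resolution in Angstrom.
#' @return list with `records` (accepted `complex_record`s) and `manifest`
#'   (data.frame: provenance, site size, label, accept flag and reason).
#' @export
extract_complexes <- function(s, ligand_chain, cutoff = DEFAULT_SITE_CUTOFF,
                              em = surrogate_energy(),
                              resolution = NA_real_) {
  stopifnot(inherits(s, "protein_structure"))
  if (!ligand_chain %in% names(s$chains))
    stop("ligand chain '", ligand_chain, "' not in structure")
  if (all(is.na(s$chains[[1]]$ss))) s <- assign_secondary_structure(s)
  frags <- enumerate_fragments(s$chains[[ligand_chain]])
  records <- list()
  rows <- list()
  for (fr in frags) {
    site <- select_binding_site(fr, s, cutoff)
    start <- fr$res_seq[1]
    if (is.null(site)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = s$source_id, ligand_chain = ligand_chain,
        start = start, site_size = NA_integer_, label = NA_integer_,
        accept = FALSE, reason = "binding site under 24 residues")
      next
    }
    partner_seq <- rs_sequence(s$chains[[site$chain_id[1]]])
    lab <- label_oligomeric(rs_sequence(s$chains[[ligand_chain]]),
                            partner_seq)
    cr <- complex_record(fr, site, lab,
                         provenance = list(source_id = s$source_id,
                                           ligand_chain = ligand_chain,
                                           partner_chains = unique(site$chain_id),
                                           start = start))
    verdict <- apply_selection_filters(cr, em, resolution = resolution)
    rows[[length(rows) + 1L]] <- data.frame(
      source_id = s$source_id, ligand_chain = ligand_chain, start = start,
      site_size = length(site), label = lab, accept = verdict$accept,
      reason = verdict$reason)
    if (verdict$accept) records[[length(records) + 1L]] <- cr
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(0), ligand_chain = character(0),
               start = integer(0), site_size = integer(0),
               label = integer(0), accept = logical(0),
               reason = character(0))
  list(records = records, manifest = manifest)
}
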