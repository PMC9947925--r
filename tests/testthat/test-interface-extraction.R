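test_that("fragment enumeration slides over contiguous windows only", {
  ch <- helix_peptide("ACDEFGHK", chain = "L")
  expect_length(enumerate_fragments(ch), 3L)   # 8 - 6 + 1

  expect_length(enumerate_fragments(helix_peptide("ACDEF", chain = "L")),
                0L)

  # break between residues 4 and 5 of a 10-mer: only the 6-residue tail
  # hosts a window
  ch10 <- helix_peptide("ACDEFGHKLM", chain = "L")
  ch10$coords[5:10, , ] <- ch10$coords[5:10, , ] + 7
  frags <- enumerate_fragments(ch10)
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$res_seq, 5:10)

  # brute-force oracle: windows are exactly those with all CA-CA < 4.2
  # and consecutive numbering
  ca <- ch10$coords[, "CA", ]
  ok <- sapply(1:5, function(s) {
    idx <- s:(s + 5)
    all(sqrt(rowSums(diff(ca[idx, ])^2)) < 4.2)
  })
  expect_equal(length(frags), sum(ok))
})

test_that("windows overlapping non-canonical residues are excluded", {
  ch <- helix_peptide("ACDEFGHK", chain = "L")
  ch$aa[7] <- "X"
  frags <- enumerate_fragments(ch)
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$res_seq, 1:6)
})

test_that("binding-site selection keeps the nearest 48 and rejects under 24", {
  cr <- toy_record(seed = 5, site_size = 30L)
  parent <- toy_structure(cr)
  site <- select_binding_site(cr$peptide, parent, cutoff = 10)
  expect_equal(length(site), 30L)
  # chain-order invariant after selection
  expect_false(is.unsorted(site$res_seq))

  # no partner within cutoff -> NULL
  far <- parent
  far$chains$B$coords <- far$chains$B$coords + 500
  expect_null(select_binding_site(cr$peptide, far, cutoff = 10))

  # over-subscription truncates to the nearest 48: widen the cutoff so all
  # pocket residues qualify, then add a second shell
  cr2 <- toy_record(seed = 6, site_size = 48L)
  parent2 <- toy_structure(cr2)
  extra <- cr2$site
  extra$res_seq <- extra$res_seq + 100L
  extra$coords <- extra$coords + 6
  parent2$chains$B <- rs_bind(parent2$chains$B, extra)
  site2 <- select_binding_site(cr2$peptide, parent2, cutoff = 25)
  expect_equal(length(site2), 48L)
})

test_that("site selection matches an exhaustive distance scan and is monotone in cutoff", {
  cr <- toy_record(seed = 9, site_size = c(26L, 40L))
  parent <- toy_structure(cr)
  pep_atoms <- rs_atoms(cr$peptide)
  all_rs <- parent$chains$B
  brute <- vapply(seq_along(all_rs), function(i) {
    ra <- all_rs$coords[i, , ]
    min(sqrt(outer(rowSums(ra^2), rowSums(pep_atoms^2), "+") -
               2 * ra %*% t(pep_atoms)))
  }, numeric(1))
  for (cutoff in c(7, 9, 11)) {
    site <- select_binding_site(cr$peptide, parent, cutoff = cutoff)
    expected <- which(brute <= cutoff)
    if (length(expected) < 24) {
      expect_null(site)
    } else {
      expect_equal(sort(site$res_seq), sort(all_rs$res_seq[expected]))
    }
  }
  # monotonicity below the cap
  s1 <- select_binding_site(cr$peptide, parent, cutoff = 9)
  s2 <- select_binding_site(cr$peptide, parent, cutoff = 11)
  if (!is.null(s1) && !is.null(s2))
    expect_true(all(s1$res_seq %in% s2$res_seq))
})

test_that("oligomeric labeling uses sequence identity over the shorter chain", {
  expect_equal(label_oligomeric("ACDEFGHIKLMNPQRSTVWY",
                                "ACDEFGHIKLMNPQRSTVWY"), 1L)
  expect_equal(label_oligomeric("ACDEFGHIKLMNPQRSTVWY",
                                "WYWYWYWYWYWYWYWYWYWY"), 0L)
  # single point mutant of a 20-mer: 95% identity -> homo
  expect_equal(label_oligomeric("ACDEFGHIKLMNPQRSTVWY",
                                "ACDEFGHIKLMNPQRSTVWV"), 1L)
})

test_that("each selection filter triggers independently with its reason", {
  cr <- toy_record(seed = 11)
  cr$peptide$aa <- strsplit("LIVCMF", "")[[1]]

  accept_em <- mock_energy(c(L = 0.9, I = 0.8, V = 0.1, C = 0.1, M = 0.1,
                             F = 0.1))
  expect_warning(v <- apply_selection_filters(cr, accept_em),
                 "resolution")
  expect_true(v$accept)
  expect_equal(v$reason, "ok")

  # criterion 1: only one residue above 0.5 REU
  one_em <- mock_energy(c(L = 0.9, I = 0.2, V = 0.1, C = 0.1, M = 0.1,
                          F = 0.1))
  v1 <- suppressWarnings(apply_selection_filters(cr, one_em))
  expect_false(v1$accept)
  expect_match(v1$reason, "fewer than 2 residues")

  # criterion 2: pull the site away so no residue is within 6 A
  far <- cr
  far$site$coords <- far$site$coords + 40
  v2 <- suppressWarnings(apply_selection_filters(far, accept_em))
  expect_false(v2$accept)
  expect_match(v2$reason, "within 6 A")

  # resolution metadata filter
  v3 <- apply_selection_filters(cr, accept_em, resolution = 3.0)
  expect_false(v3$accept)
  expect_match(v3$reason, "resolution")
  v3b <- apply_selection_filters(cr, accept_em, resolution = 3.0,
                                 is_antibody = TRUE)
  expect_true(v3b$accept)

  # negative binding energy criterion
  pos_em <- mock_energy(c(L = 0.9, I = 0.8, V = 0.1, C = 0.1, M = 0.1,
                          F = 0.1), offset = -10)
  v4 <- suppressWarnings(apply_selection_filters(cr, pos_em))
  expect_false(v4$accept)
  expect_match(v4$reason, "non-negative binding energy")

  # non-polar hot-spot criterion: all strong contributors polar
  polar <- cr
  polar$peptide$aa <- strsplit("DENQKR", "")[[1]]
  polar_em <- mock_energy(c(D = 4, E = 3.5, N = 0.1, Q = 0.1, K = 0.1,
                            R = 0.1))
  v5 <- suppressWarnings(apply_selection_filters(polar, polar_em))
  expect_false(v5$accept)
  expect_match(v5$reason, "non-polar")
})

test_that("accepted records satisfy all complex invariants (property)", {
  for (seed in c(21, 22, 23, 24, 25)) {
    cr <- toy_record(seed = seed)
    expect_s3_class(cr, "complex_record")
    expect_length(cr$peptide, 6L)
    expect_equal(diff(cr$peptide$res_seq), rep(1L, 5))
    gaps <- sqrt(rowSums(diff(cr$peptide$coords[, "CA", ])^2))
    expect_true(all(gaps < 4.2))
    expect_true(length(cr$site) >= 24 && length(cr$site) <= 48)
    pep_atoms <- rs_atoms(cr$peptide)
    for (i in seq_along(cr$site)) {
      ra <- cr$site$coords[i, , ]
      d <- min(sqrt(outer(rowSums(ra^2), rowSums(pep_atoms^2), "+") -
                      2 * ra %*% t(pep_atoms)))
      expect_lt(d, 10)
    }
  }
})

test_that("extract_complexes produces a manifest over all windows", {
  cr <- toy_record(seed = 31, site_size = 36L)
  s <- toy_structure(cr)
  s <- assign_secondary_structure(s)
  res <- suppressWarnings(extract_complexes(s, ligand_chain = "P"))
  expect_equal(nrow(res$manifest), 1L)   # a 6-residue chain has one window
  expect_true(all(c("accept", "reason", "site_size") %in%
                    colnames(res$manifest)))
  expect_error(extract_complexes(s, "Z"), "not in structure")
})
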