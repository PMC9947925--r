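test_that("sequence recovery is the exact identity fraction", {
  expect_equal(sequence_recovery("ACDEFG", "ACDEFG"), 1)
  expect_equal(sequence_recovery("ACDEFG", "ACDYYY"), 0.5)
  expect_equal(sequence_recovery("ACDEFG", "VVVVVV"), 0)
  expect_error(sequence_recovery("ACDEFG", "ACDEF"), "differ")
})

test_that("alanine scanning labels hot-spots at the inclusive 3 REU boundary", {
  labs <- hotspot_labels(c(3.2, 4.1, 3.9, 4.4, 1.0, 0.2))
  expect_equal(sum(vapply(labs, `[[`, logical(1), "is_hotspot")), 4L)
  expect_false(hotspot_labels(2.99)[[1]]$is_hotspot)
  expect_true(hotspot_labels(3.00)[[1]]$is_hotspot)
  none <- hotspot_labels(rep(0, 6))
  expect_equal(sum(vapply(none, `[[`, logical(1), "is_hotspot")), 0L)
  expect_true(is.na(hotspot_recovery("ACDEFG", "ACDEFG", none)))
})

test_that("alanine scan under a model equals the mutant energy difference", {
  cr <- toy_record(seed = 91)
  cr$peptide$aa <- strsplit("LIVCMF", "")[[1]]
  em <- mock_energy(c(L = 2.5, I = 3.0, V = 0.5, C = 4.4, M = 0.1, F = 1.0))
  labs <- alanine_scan(cr, em)
  expect_equal(vapply(labs, `[[`, numeric(1), "ddG"),
               c(2.5, 3.0, 0.5, 4.4, 0.1, 1.0))
  expect_equal(vapply(labs, `[[`, logical(1), "is_hotspot"),
               c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("hot-spot recovery restricts to hot-spot positions", {
  labs <- hotspot_labels(c(0, 5, 0, 4, 0, 0))
  expect_equal(hotspot_recovery("ACDEFG", "ACDEFG", labs), 1)
  expect_equal(hotspot_recovery("ACDEFG", "ACYEFG", labs), 1)  # non-hot miss
  expect_equal(hotspot_recovery("ACDEFG", "AYDEFG", labs), 0.5)
  expect_equal(hotspot_recovery("ACDEFG", "AYDYFG", labs), 0)
})

test_that("best-of-n is the max over designs and dominates entry recovery", {
  native <- "ACDEFG"
  designs <- c("AYYYYY", "ACDYYY", "AYYYYY", "ACYYYY", "ACDYYY", "ACDEYY")
  recov <- vapply(designs, function(d) sequence_recovery(native, d),
                  numeric(1))
  expect_equal(best_of_n_recovery(native, designs), max(recov))
  expect_equal(best_of_n_recovery(native, rep("ACDEFG", 6)), 1)
  expect_gte(best_of_n_recovery(native, designs), recov[6])
})

test_that("diversity is the mean pairwise Hamming distance", {
  expect_equal(design_diversity(rep("AAAAAA", 6)), 0)
  # two groups of three differing at 2 positions: 9 cross pairs of 15
  designs <- c(rep("AAAAAA", 3), rep("AAAAWW", 3))
  expect_equal(design_diversity(designs), 2 * 9 / 15)
  # maximally distinct
  expect_equal(design_diversity(c("AAAAAA", "CCCCCC", "DDDDDD", "EEEEEE",
                                  "FFFFFF", "GGGGGG")), 6)
  # brute-force oracle on random design sets
  withr::with_seed(7, {
    for (rep_i in 1:5) {
      seqs <- vapply(1:6, function(i)
        paste(sample(pepdesign:::AA_VOCAB, 6, replace = TRUE),
              collapse = ""), character(1))
      brute <- mean(utils::combn(6, 2, function(p) {
        a <- strsplit(seqs[p[1]], "")[[1]]
        b <- strsplit(seqs[p[2]], "")[[1]]
        sum(a != b)
      }))
      expect_equal(design_diversity(seqs), brute)
    }
  })
})

test_that("amino-acid composition is a normalized 20-vector", {
  d <- aa_distribution("GGGGGG")
  expect_equal(unname(d["G"]), 1)
  expect_equal(sum(d), 1)
  d2 <- aa_distribution(c("AAAGGG", "GGGAAA"))
  expect_equal(unname(d2[c("A", "G")]), c(0.5, 0.5))
})

test_that("surrogate energy is additive, contact-driven and monotone", {
  cr <- toy_record(seed = 95)
  em <- surrogate_energy()
  # isolated peptide: no contacts
  far <- cr
  far$site$coords <- far$site$coords + 300
  expect_equal(em$binding_energy(far), 0)
  # additivity of per-residue contributions
  expect_equal(em$binding_energy(cr), -sum(em$per_residue(cr)))
  # adding one contacting residue strictly decreases the binding energy
  bigger <- cr
  extra <- rs_subset(cr$site, 1)
  extra$res_seq <- max(cr$site$res_seq) + 1L
  extra$coords <- cr$peptide$coords[3, , , drop = FALSE] + 2.5
  bigger$site <- rs_bind(cr$site, extra)
  expect_lt(em$binding_energy(bigger), em$binding_energy(cr))
  expect_true(em$binding_energy(cr) < 0)
})

test_that("recovery report ties the summaries to per-position matches", {
  labs <- hotspot_labels(c(5, 0, 0, 4, 0, 0))
  rep1 <- recovery_report("ACDEFG", "ACYEFG", labels = labs, ss = "HHHEEL",
                          energy_model_name = "mock")
  expect_equal(rep1$R_all, mean(rep1$per_position))
  expect_equal(rep1$R_all, 5 / 6)
  expect_equal(rep1$R_hotspot, 1)
  expect_equal(rep1$n_hotspots, 2L)
  expect_equal(unname(rep1$per_ss["H"]), 2 / 3)
  expect_equal(unname(rep1$per_ss["E"]), 1)
  expect_equal(unname(rep1$per_ss["L"]), 1)
  expect_equal(rep1$energy_model, "mock")
  # bounds property over random pairs
  withr::with_seed(11, {
    for (i in 1:10) {
      nat <- paste(sample(pepdesign:::AA_VOCAB, 6, TRUE), collapse = "")
      des <- paste(sample(pepdesign:::AA_VOCAB, 6, TRUE), collapse = "")
      r <- recovery_report(nat, des)
      expect_true(r$R_all >= 0 && r$R_all <= 1)
      expect_equal(r$R_all, mean(r$per_position))
    }
  })
})

test_that("best/mean/min ordering holds on any design set", {
  withr::with_seed(13, {
    for (i in 1:10) {
      nat <- paste(sample(pepdesign:::AA_VOCAB, 6, TRUE), collapse = "")
      designs <- vapply(1:6, function(j)
        paste(sample(pepdesign:::AA_VOCAB, 6, TRUE), collapse = ""),
        character(1))
      recov <- vapply(designs, function(d) sequence_recovery(nat, d),
                      numeric(1))
      expect_gte(best_of_n_recovery(nat, designs), mean(recov))
      expect_gte(mean(recov), min(recov))
    }
  })
})
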