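test_that("annotated-string parsing recovers residues, sites and offsets", {
  fr <- idp_fragments()
  expect_equal(sapply(fr, function(s) s$n_residues),
               c(Ash1 = 81L, CTD2p = 83L, ECadherin = 66L, p130Cas = 66L))
  expect_equal(sapply(fr, function(s) length(s$phospho_sites)),
               c(Ash1 = 10L, CTD2p = 10L, ECadherin = 8L, p130Cas = 6L))
  expect_equal(sapply(fr, function(s) s$offset),
               c(Ash1 = 420L, CTD2p = 1659L, ECadherin = 735L,
                 p130Cas = 631L))
  # all annotated sites sit on S/T/Y
  for (s in fr)
    expect_true(all(s$residues[s$phospho_sites] %in% c("S", "T", "Y")))

  plain <- parse_annotated_sequence("GGG")
  expect_equal(plain$n_residues, 3L)
  expect_length(plain$phospho_sites, 0L)
})

test_that("parser rejects malformed annotations", {
  expect_error(parse_annotated_sequence("GA_G"), "non-S/T/Y")
  expect_error(parse_annotated_sequence("_GG"), "no preceding")
  expect_error(parse_annotated_sequence("GXG"), "unknown residue")
  expect_error(parse_annotated_sequence("GSG", sites = 5L), "out of range")
  expect_error(parse_annotated_sequence("GSG", sites = 2L), NA)
})

test_that("FASTA + site-list input matches the annotated-string dialect", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", "MKKSAADESGKRH"), fa)
  sl <- tempfile()
  writeLines(c("4", "9"), sl)
  s <- read_annotated_fasta(fa, sl)
  ref <- toy_sequence()
  expect_equal(s$residues, ref$residues)
  expect_equal(s$phospho_sites, ref$phospho_sites)
})

test_that("net charges reproduce the printed values for all eight states", {
  fr <- idp_fragments()
  cm <- charge_model()  # D/E -1, K/R +1, phosphate -2, capped termini
  expected <- list(Ash1 = c(15, -5), CTD2p = c(0, -20),
                   ECadherin = c(-9, -25), p130Cas = c(-4, -16))
  for (nm in names(expected)) {
    s <- fr[[nm]]
    expect_equal(net_charge(assign_charges(s, cm, integer(0))),
                 expected[[nm]][1], info = nm)
    expect_equal(net_charge(assign_charges(s, cm)),
                 expected[[nm]][2], info = nm)
  }
})

test_that("charge accounting is additive in the phosphate charge", {
  fr <- idp_fragments()
  for (s in fr) {
    for (qp in c(-1, -2)) {
      cm <- charge_model(phosphate_charge = qp)
      nu <- net_charge(assign_charges(s, cm, integer(0)))
      nf <- net_charge(assign_charges(s, cm))
      expect_equal(nf, nu + qp * length(s$phospho_sites))
    }
  }
  # mono-protonated Ash1: +15 + 10 * (-1)
  ash <- fr$Ash1
  expect_equal(net_charge(assign_charges(ash, charge_model(-1))), 5)
})

test_that("phosphomimetic mode rewrites sites to Glu with charge -1", {
  ash <- idp_fragments()$Ash1
  cv <- assign_charges(ash, charge_model(phosphomimetic = TRUE))
  expect_equal(net_charge(cv), 15 - 10)
  expect_true(all(attr(cv, "residues")[ash$phospho_sites] == "E"))
  expect_true(all(unclass(cv)[ash$phospho_sites] == -1))
})

test_that("NCPR and charged fraction follow their definitions", {
  ten_pos <- structure(rep(1, 10), class = "charge_vector")
  expect_equal(ncpr(ten_pos), 1.0)
  expect_equal(charged_fraction(ten_pos), 1.0)

  fr <- idp_fragments()
  cm <- charge_model()
  expect_equal(ncpr(assign_charges(fr$Ash1, cm, integer(0))), 15 / 81)
  expect_equal(ncpr(assign_charges(fr$CTD2p, cm, integer(0))), 0)
  # CTD2' repeat region carries no D/E/K/R at all
  expect_equal(charged_fraction(assign_charges(fr$CTD2p, cm, integer(0))), 0)
  # Ash1 fully phosphorylated: 17 charged residues + 10 phosphosites
  expect_equal(charged_fraction(assign_charges(fr$Ash1, cm)), 27 / 81)
})

test_that("Coulomb descriptors match the closed forms and the brute force", {
  expect_equal(coulomb_descriptors(c(1, -1)),
               c(potential = -1.0, force = -1.0))
  expect_equal(coulomb_descriptors(c(1, 0, -1)),
               c(potential = -0.5, force = -0.25))
  set.seed(42)
  for (rep in 1:5) {
    q <- sample(c(-2, -1, 0, 0, 1), 20, replace = TRUE)
    expect_equal(coulomb_descriptors(q), brute_coulomb(q), tolerance = 1e-12)
  }
})

test_that("descriptors are invariant under sign flip and reversal", {
  set.seed(7)
  q <- sample(c(-2, -1, 0, 1), 30, replace = TRUE)
  expect_equal(coulomb_descriptors(q), coulomb_descriptors(-q))
  expect_equal(coulomb_descriptors(q), coulomb_descriptors(rev(q)))
  expect_equal(net_charge(rev(q)), net_charge(q))
  expect_equal(ncpr(rev(q)), ncpr(q))
  expect_equal(charged_fraction(rev(q)), charged_fraction(q))
})

test_that("descriptor tables cover the default states", {
  s <- idp_fragments()$ECadherin
  tab <- sequence_descriptors(s)
  expect_equal(tab$state, c("unphos", "partial", "full"))
  expect_equal(tab$net_charge, c(-9, -9 - 4, -25))
  expect_equal(tab$n_active_sites, c(0L, 2L, 8L))
})
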