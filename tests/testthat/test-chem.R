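test_that("peptide construction validates sequence, modifications and charge", {
  expect_error(peptide("GXK"), "X")
  expect_error(peptide("GAK", list(list(position = 5, name = "diGly"))),
               "outside")
  expect_error(peptide("GAK", charge = 0), "positive")
  p <- peptide("GAK", list(list(position = 3, name = "diGly")), charge = 2)
  expect_s3_class(p, "peptide")
  expect_equal(p$modifications[[1]]$delta_mass, 114.04293, tolerance = 1e-5)
})

test_that("elemental composition sums residues plus one water", {
  expect_equal(peptide_composition(peptide("G")),
               c(C = 2, H = 5, N = 1, O = 2, S = 0))
  expect_equal(peptide_composition(peptide("GG")),
               c(C = 4, H = 8, N = 2, O = 3, S = 0))
  # diGly remnant adds its registered formula
  comp <- peptide_composition(peptide("GAK", list(list(position = 3, name = "diGly"))))
  expect_equal(unname(comp - peptide_composition(peptide("GAK"))),
               c(4, 6, 2, 2, 0))
})

test_that("monoisotopic masses match independent hand summation", {
  expect_equal(monoisotopic_mass(peptide("G")), 75.03203, tolerance = 1e-5)
  expect_equal(monoisotopic_mass(peptide("LLSGVTIAQGGVLPNIQAVLLPKK")),
               hand_peptide_mass("LLSGVTIAQGGVLPNIQAVLLPKK"), tolerance = 1e-3)
  expect_equal(monoisotopic_mass(peptide("LLSGVTIAQGGVLPNIQAVLLPKK")),
               2428.478, tolerance = 1e-3)
  # additive in modifications; a +0 modification changes nothing
  p0 <- peptide("VTIAQGGVLPNIQAVLLPKK")
  pz <- peptide("VTIAQGGVLPNIQAVLLPKK",
                list(list(position = 1, name = "nothing", delta_mass = 0)))
  expect_identical(monoisotopic_mass(p0), monoisotopic_mass(pz))
  pg <- peptide("VTIAQGGVLPNIQAVLLPKK", list(list(position = 19, name = "diGly")))
  expect_equal(monoisotopic_mass(pg), 2172.29948, tolerance = 2e-4)
})

test_that("modification table reproduces the printed two-decimal shifts", {
  tab <- modification_table()
  shifts <- setNames(round(tab$delta_mass, 2), tab$name)
  expect_equal(shifts[["diGly"]], 114.04)
  expect_equal(shifts[["carbamidomethyl"]], 57.02)
  expect_equal(shifts[["oxidation"]], 15.99)
  expect_equal(tab$delta_mass[tab$name == "diGly"], 114.04293, tolerance = 1e-5)
})

test_that("precursor m/z reproduces the three printed PRM values", {
  mz <- function(seq, pos) {
    precursor_mz(peptide(seq, list(list(position = pos, name = "diGly"))), 3)
  }
  expect_equal(round(mz("LLSGVTIAQGGVLPNIQAVLLPKK", 23), 4), 848.5143)
  expect_equal(round(mz("VTIAQGGVLPNIQAVLLPKK", 19), 4), 725.1071)
  expect_equal(round(mz("LLGGVTIAQGGVLPNIQAVLLPKK", 23), 4), 838.5108)
})

test_that("precursor m/z is additive in modification mass", {
  base <- peptide("VTIAQGGVLPNIQAVLLPKK")
  for (z in 1:3) {
    delta <- 114.04293
    withmod <- peptide("VTIAQGGVLPNIQAVLLPKK",
                       list(list(position = 19, name = "x", delta_mass = delta)))
    expect_equal(precursor_mz(withmod, z) - precursor_mz(base, z), delta / z,
                 tolerance = 1e-9)
  }
  expect_error(precursor_mz(base), "charge")
})

test_that("fragment m/z: y1, diGly-containing y3, ladder conservation", {
  expect_equal(fragment_mz(peptide("AK"), "y", 1), 147.11280, tolerance = 1e-4)
  p <- peptide("LLSGVTIAQGGVLPNIQAVLLPKK", list(list(position = 23, name = "diGly")))
  expect_equal(fragment_mz(p, "y", 3), 486.30345, tolerance = 2e-5)
  # ladder conservation: y_{L-1} + b_1 = M + 2 protons (singly charged each)
  L <- length(p$residues)
  expect_equal(fragment_mz(p, "y", L - 1) + fragment_mz(p, "b", 1),
               monoisotopic_mass(p) + 2 * 1.007276, tolerance = 1e-9)
  expect_error(fragment_mz(p, "y", L), "ion length")
  expect_error(fragment_mz(p, "y", 0), "ion length")
})

test_that("y-ion ladder steps equal C-terminal residue masses", {
  p <- peptide("LLSGVTIAQGGVLPNIQAVLLPKK", list(list(position = 23, name = "diGly")))
  L <- length(p$residues)
  for (n in 2:(L - 1)) {
    step <- fragment_mz(p, "y", n) - fragment_mz(p, "y", n - 1)
    res <- p$residues[L - n + 1]
    expected <- HAND_RESIDUE_MASS[[res]] + if (L - n + 1 == 23) 114.04293 else 0
    expect_equal(step, expected, tolerance = 1e-4)
  }
})

test_that("tryptic digestion obeys KP suppression and missed-cleavage rules", {
  expect_equal(tryptic_digest("AKPR", 0)$sequence, "AKPR")
  d0 <- tryptic_digest("AKRG", 0)
  expect_equal(d0$sequence, c("AK", "R", "G"))
  expect_equal(d0$start, c(1L, 3L, 4L))
  expect_equal(d0$end, c(2L, 3L, 4L))
  d1 <- tryptic_digest("AKRG", 1)
  expect_setequal(d1$sequence, c("AK", "R", "G", "AKR", "RG"))
  expect_equal(tryptic_digest("", 0), tryptic_digest("X", 0)[0, ],
               ignore_attr = TRUE)
})

test_that("digestion properties: partition and missed-cleavage superset", {
  set.seed(7)
  for (rep in 1:5) {
    prot <- paste(sample(names(HAND_RESIDUE_MASS), 60, replace = TRUE),
                  collapse = "")
    d0 <- tryptic_digest(prot, 0)
    expect_identical(paste(d0$sequence, collapse = ""), prot)
    expect_true(all(d0$start == c(1L, head(d0$end, -1) + 1L)))
    d1 <- tryptic_digest(prot, 1)
    d2 <- tryptic_digest(prot, 2)
    key <- function(d) paste(d$start, d$end)
    expect_true(all(key(d0) %in% key(d1)))
    expect_true(all(key(d1) %in% key(d2)))
  }
})

test_that("FASTA round trip keeps first-token ids and sequences", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "MKAVLR", ">prot2", "GGSPK"), fa)
  seqs <- read_fasta(fa)
  expect_equal(seqs, c(prot1 = "MKAVLR", prot2 = "GGSPK"))
})
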