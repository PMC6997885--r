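comp_subtract_test <- function(a, b) {
  syms <- union(names(a), names(b))
  v <- setNames(integer(length(syms)), syms)
  v[names(a)] <- v[names(a)] + as.integer(a)
  v[names(b)] <- v[names(b)] - as.integer(b)
  v <- v[v != 0]
  v[order(names(v))]
}

test_that("elemental compositions of reference species match manual assembly", {
  expect_equal(format(species_composition("PC 34:1")), "C42H82NO8P")
  expect_equal(format(species_composition("PI 28:0")), "C37H71O13P")
  # LPC 16:0 and PC 16:0/16:0 differ by exactly one acyl-minus-water unit
  lpc <- species_composition("LPC 16:0")
  pc <- species_composition("PC 16:0/16:0")
  diff <- comp_subtract_test(pc, lpc)
  expect_equal(diff, c(C = 16L, H = 30L, O = 1L))
  # sum-level and sn-resolved compositions agree
  expect_equal(species_composition("PI 28:0"), species_composition("PI 18:0/10:0"))
})

test_that("monoisotopic masses agree with frozen values and brute-force oracle", {
  m <- monoisotopic_mass(elemental_composition(C = 42, H = 82, N = 1, O = 8, P = 1))
  expect_equal(m, 759.5778, tolerance = 1e-4 / 759)
  expect_equal(monoisotopic_mass(elemental_composition()), 0)
  # adding one carbon adds exactly 12
  c1 <- elemental_composition(C = 5, H = 10)
  c2 <- elemental_composition(C = 6, H = 10)
  expect_identical(monoisotopic_mass(c2) - monoisotopic_mass(c1), 12)
  expect_error(monoisotopic_mass(setNames(1L, "Xx")), "unknown element")
})

test_that("adduct m/z arithmetic is exact", {
  m <- 759.5778051
  expect_equal(adduct_mz(m, "[M+H]+") - adduct_mz(m, "[M-H]-"),
               2 * 1.007276, tolerance = 1e-6)
  expect_equal(adduct_mz(m, "[M+H]+"), 760.5851, tolerance = 1e-4)
  pi28 <- monoisotopic_mass(species_composition("PI 28:0"))
  expect_equal(adduct_mz(pi28, "[M-H]-"), 753.4559, tolerance = 2e-4)
  expect_error(adduct_mz(700, "[M+K]+"), "unsupported adduct")
})

test_that("species database enumerates the (class, C, DB) grid", {
  db <- build_species_database("PI", 26:36, 0:2)
  expect_equal(nrow(db), 33L)
  expect_false(anyDuplicated(db$label) > 0)
  expect_error(build_species_database(character(0), 26:36, 0:2), "no classes")
  one <- build_species_database("PC", 34, 1)
  expect_equal(one$label, "PC 34:1")
})

test_that("database masses match the brute-force oracle over random species", {
  set.seed(101)
  db <- build_species_database(lipid_classes()$class, 24:72, 0:4)
  idx <- sample(nrow(db), 500L)
  for (i in idx) {
    expect_lt(abs(db$neutral_mass[i] - oracle_formula_mass(db$formula[i])), 1e-4)
  }
})

test_that("species labels round-trip through parsing", {
  for (lab in c("PC 34:1", "PI 18:0/10:0", "Cer 44:0:3", "TG 48:1", "CL 68:2")) {
    p <- parse_species_label(lab)
    expect_identical(species_label(p$class, p$total_c, p$total_db, p$total_oh,
                                   p$chains), lab)
  }
})

test_that("peak matching respects the inclusive 3 ppm boundary", {
  db <- annotate_adducts(build_species_database("PI", 26:36, 0:2),
                         match_config(3, "negative"))
  theo <- db$mz[db$label == "PI 28:0"]
  expect_equal(theo, 753.4559, tolerance = 2e-4)
  hit <- match_peaks(data.frame(mz = 753.4570, intensity = 10), db,
                     match_config(3, "negative"))
  expect_equal(nrow(hit[hit$label == "PI 28:0", ]), 1L)
  expect_equal(hit$ppm_error[hit$label == "PI 28:0"],
               (753.4570 - theo) / theo * 1e6, tolerance = 1e-6)
  # exact hit at 0 ppm
  hit0 <- match_peaks(data.frame(mz = theo, intensity = 1), db,
                      match_config(3, "negative"))
  expect_true(any(hit0$label == "PI 28:0" & abs(hit0$ppm_error) < 1e-9))
  # 5.4 ppm away is rejected at 3 ppm tolerance
  far <- match_peaks(data.frame(mz = 753.46, intensity = 1), db,
                     match_config(3, "negative"))
  expect_false("PI 28:0" %in% far$label)
  # boundary: a peak shifted by exactly +3 ppm is accepted
  b <- match_peaks(data.frame(mz = theo * (1 + 3e-6), intensity = 1), db,
                   match_config(3, "negative"))
  expect_true("PI 28:0" %in% b$label)
  # empty inputs give empty output
  expect_equal(nrow(match_peaks(data.frame(mz = numeric(0), intensity = numeric(0)),
                                db, match_config())), 0L)
})

test_that("quantification follows the linear single-standard scheme", {
  asg <- data.frame(
    mz_obs = c(1, 2), intensity = c(2, 1), label = c("PI 34:1", "PI 36:2"),
    class = "PI", adduct = "[M-H]-", mz_theo = c(1, 2), ppm_error = 0,
    n_candidates = 1L, ambiguous = FALSE, stringsAsFactors = FALSE
  )
  std <- data.frame(class = "PI", spiked_pmol = 43, intensity = 1)
  q <- quantify_species(asg, std)
  expect_equal(sort(q$amount_pmol), c(43, 86))
  expect_equal(sum(q$mol_percent_polar), 100, tolerance = 1e-9)
  # intensity ratio 1 recovers the spike; single polar species is 100 mol%
  one <- quantify_species(asg[1, ], data.frame(class = "PI", spiked_pmol = 43,
                                               intensity = 2))
  expect_equal(one$amount_pmol, 43)
  expect_equal(one$mol_percent_polar, 100)
  # scaling one species' intensity by k scales its amount by k
  asg2 <- asg; asg2$intensity[1] <- asg$intensity[1] * 5
  q2 <- quantify_species(asg2, std)
  expect_equal(q2$amount_pmol[q2$label == "PI 34:1"],
               5 * q$amount_pmol[q$label == "PI 34:1"])
  # missing standard errors with the class name
  expect_error(quantify_species(asg, data.frame(class = "PC", spiked_pmol = 71,
                                                intensity = 1)),
               "PI")
  expect_error(quantify_species(asg, data.frame(class = "PI", spiked_pmol = 43,
                                                intensity = 0)),
               "zero intensity")
})

test_that("class profiles normalize over polar classes", {
  q <- data.frame(label = c("PC 34:1", "PI 34:1", "TG 48:1"),
                  class = c("PC", "PI", "TG"),
                  amount_pmol = c(10, 10, 100),
                  mol_percent_polar = c(50, 50, NA))
  p <- class_profiles(q)
  expect_equal(sort(p$class_profile$mol_percent), c(50, 50))
  expect_false("TG" %in% p$class_profile$class)
  expect_true(all(p$species_profile$within_class_percent >= 0 &
                    p$species_profile$within_class_percent <= 100))
  expect_error(class_profiles(transform(q, amount_pmol = 0)), "zero")
})

test_that("quantified mol% sums to 100 on generated lipidomes", {
  sim <- gen_lipidome(7, intensity_cv = 0.2, ppm_jitter = 0.5)
  res <- lipidome_pipeline(sim$peaks_pos, sim$peaks_neg, sim$standards)
  expect_equal(sum(res$quant$mol_percent_polar, na.rm = TRUE), 100,
               tolerance = 1e-9)
})
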