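test_that("diagnostic fragments obey mass conservation", {
  fr <- diagnostic_fragments("PI 18:0/10:0")
  prec <- fr$precursor_mz[1]
  # carboxylate anions: acid mass minus a proton
  acid18 <- 18 * 12 + 36 * 1.0078250319 + 2 * 15.9949146221
  acid10 <- 10 * 12 + 20 * 1.0078250319 + 2 * 15.9949146221
  expect_equal(fr$mz[fr$chain == "sn-1" & fr$fragment == "carboxylate"],
               acid18 - 1.00727646688, tolerance = 1e-6)
  expect_equal(fr$mz[fr$chain == "sn-2" & fr$fragment == "carboxylate"],
               acid10 - 1.00727646688, tolerance = 1e-6)
  # [M-H-RCOOH]- + RCOOH = [M-H]-
  expect_equal(fr$mz[fr$chain == "sn-1" & fr$fragment == "acid_loss"] + acid18,
               prec, tolerance = 1e-6)
  # ketene loss - acid loss = water mass
  water <- 2 * 1.0078250319 + 15.9949146221
  expect_equal(fr$mz[fr$fragment == "ketene_loss"] - fr$mz[fr$fragment == "acid_loss"],
               rep(water, 2), tolerance = 1e-9)
  expect_error(diagnostic_fragments("PI 28:0"), "resolve chains")
})

test_that("sn assignment applies the intensity rule with inclusive threshold", {
  ms2 <- gen_ms2("PI 18:0/10:0", sn2_factor = 8)
  a <- assign_sn_positions(ms2$spectrum, "PI 28:0")
  expect_equal(a$species, "PI 18:0/10:0")
  expect_equal(a$confidence, "assigned")
  expect_equal(a$sn2_over_sn1_ratio, 8, tolerance = 1e-9)
  # equal losses are ambiguous
  tie <- gen_ms2("PI 18:0/10:0", sn2_factor = 1)
  expect_equal(assign_sn_positions(tie$spectrum, "PI 28:0")$confidence, "ambiguous")
  # ratio exactly at min_ratio is assigned (inclusive boundary)
  edge <- gen_ms2("PI 18:0/10:0", sn2_factor = 7)
  expect_equal(assign_sn_positions(edge$spectrum, "PI 28:0", min_ratio = 7)$confidence,
               "assigned")
  # uninformative spectrum errors
  expect_error(assign_sn_positions(data.frame(mz = 100, intensity = 1), "PI 28:0"),
               "uninformative")
})

test_that("sn assignment is invariant to uniform intensity scaling", {
  ms2 <- gen_ms2("PC 16:0/10:0", sn2_factor = 9)
  a1 <- assign_sn_positions(ms2$spectrum, "PC 26:0")
  sc <- ms2$spectrum; sc$intensity <- sc$intensity * 10
  a2 <- assign_sn_positions(sc, "PC 26:0")
  expect_equal(a1$species, a2$species)
  expect_equal(a1$sn2_over_sn1_ratio, a2$sn2_over_sn1_ratio)
})

test_that("sn assignment accuracy is 100% noise-free and degrades gracefully", {
  species <- c("PI 18:0/10:0", "PI 16:0/10:0", "PC 16:0/18:1", "PE 18:0/10:0")
  acc <- function(noise_cv, seed0) {
    mean(vapply(seq_along(species), function(i) {
      sp <- species[i]
      p <- parse_species_label(sp)
      ms2 <- gen_ms2(sp, sn2_factor = 8, noise_cv = noise_cv, seed = seed0 + i)
      a <- assign_sn_positions(ms2$spectrum,
                               species_label(p$class, p$total_c, p$total_db))
      a$species == sp
    }, logical(1)))
  }
  expect_equal(acc(0, 1), 1)
  # heavy multiplicative noise cannot beat the noise-free limit
  set.seed(5)
  noisy <- mean(vapply(1:8, function(s) acc(1.5, 100 * s), numeric(1)))
  expect_lte(noisy, 1)
})

test_that("PLA2 digestion removes sn-2 chains and conserves composition", {
  tab <- data.frame(label = c("PI 18:0/10:0", "PC 16:0/16:0"),
                    amount = c(2, 1), stringsAsFactors = FALSE)
  dig <- pla2_digest(tab)
  expect_equal(dig$products$lyso_species[1], "LPI 18:0")
  expect_equal(dig$products$free_fa[1], "C10:0")
  bound <- dig$fa_profile[dig$fa_profile$pool == "lipid_bound", ]
  expect_false("C10:0" %in% bound$fa)       # C10:0 not recovered in lipids
  expect_true("C10:0" %in% dig$fa_profile$fa[dig$fa_profile$pool == "free_fa"])
  # symmetric species leave the bound profile composition unchanged
  expect_true("C16:0" %in% bound$fa)
  # mass conservation: parent = lyso + free acid - water, for every product
  water <- elemental_composition(H = 2, O = 1)
  for (i in seq_len(nrow(dig$products))) {
    parent <- species_composition(dig$products$parent[i])
    lyso <- species_composition(dig$products$lyso_species[i])
    fa <- sub("^C", "", dig$products$free_fa[i])
    cd <- as.integer(strsplit(fa, ":")[[1]])
    acid <- elemental_composition(C = cd[1], H = 2 * cd[1] - 2 * cd[2], O = 2)
    lhs <- monoisotopic_mass(parent) + monoisotopic_mass(water)
    rhs <- monoisotopic_mass(lyso) + monoisotopic_mass(acid)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  # lyso and sphingolipid inputs are skipped with a warning
  expect_warning(pla2_digest(data.frame(label = c("PI 18:0/10:0", "Cer 44:0:3"),
                                        amount = c(1, 1))), "skipped")
})

test_that("asymmetry metrics use the >= 6 carbon rule, symmetric in chain order", {
  a <- asymmetry_metrics("PI 18:0/10:0")
  expect_equal(a$chain_diff, 8)
  expect_true(a$is_asymmetrical)
  b <- asymmetry_metrics("PC 16:0/18:1")
  expect_equal(b$chain_diff, 2)
  expect_false(b$is_asymmetrical)
  c6 <- asymmetry_metrics("PI 16:0/10:0")
  expect_equal(c6$chain_diff, 6)
  expect_true(c6$is_asymmetrical)
  # order symmetry
  expect_equal(asymmetry_metrics("PI 10:0/18:0")$chain_diff, 8)
  # sum-level with assumed sn-2
  s <- asymmetry_metrics("PI 26:0", sn2_carbons = 10)
  expect_equal(s$chain_diff, 6)
  expect_error(asymmetry_metrics("PI 28:0"), "undeterminable")
})

test_that("acyl summaries compute weighted combined length and DB distribution", {
  q <- data.frame(label = c("PI 28:0", "PI 36:2"), class = "PI",
                  amount_pmol = c(1, 1), mol_percent_polar = c(50, 50))
  s <- acyl_summaries(q)
  expect_equal(s$mean_combined_length, 32)
  dbd <- attr(s, "db_distribution")
  expect_equal(dbd$fraction[dbd$total_db == 0], 0.5)
  expect_equal(dbd$fraction[dbd$total_db == 2], 0.5)
  one <- acyl_summaries(data.frame(label = "PI 28:0", class = "PI",
                                   amount_pmol = 3, mol_percent_polar = 100))
  expect_equal(one$mean_combined_length, 28)
})

test_that("planted asymmetric fraction is recovered through the MS2 route", {
  sim <- gen_lipidome(13)
  res <- lipidome_pipeline(sim$peaks_pos, sim$peaks_neg, sim$standards)
  quant <- res$quant
  # resolve PI species by simulated MS2 fragmentation and promote the labels
  pi_rows <- which(quant$class == "PI")
  for (i in pi_rows) {
    truth_lab <- sim$truth$label[sim$truth$label_sum == quant$label[i]][1]
    ms2 <- gen_ms2(truth_lab, sn2_factor = 8)
    asn <- assign_sn_positions(ms2$spectrum, quant$label[i])
    expect_equal(asn$confidence, "assigned")
    quant$label[i] <- asn$species
  }
  s <- acyl_summaries(quant)
  planted <- 0.90
  expect_equal(s$asym_fraction[s$class == "PI"], planted, tolerance = 1e-9)
})
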