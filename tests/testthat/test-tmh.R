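test_that("hydropathy predictor finds planted hydrophobic stretches", {
  # poly-L core flanked by poly-D: one segment inside the core
  seq1 <- paste0(strrep("D", 40), strrep("L", 30), strrep("D", 40))
  seg <- predict_tmh_hydropathy(seq1)
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$start, 41)
  expect_lte(seg$end, 70)
  expect_gte(seg$length, 12)
  # poly-D alone yields nothing
  expect_equal(nrow(predict_tmh_hydropathy(strrep("D", 80))), 0L)
  # planted 21-mer in hydrophilic background: one segment, length 21 +/- 9
  set.seed(21)
  bg <- function(n) paste(sample(c("D","E","K","R","N","Q","S","T"), n, TRUE),
                          collapse = "")
  core <- paste(sample(c("L","I","V","F"), 21, TRUE), collapse = "")
  seg2 <- predict_tmh_hydropathy(paste0(bg(50), core, bg(50)))
  expect_equal(nrow(seg2), 1L)
  expect_lte(abs(seg2$length - 21), 9)
  expect_error(predict_tmh_hydropathy("ACDEFGHIKLMNPQRSTVWYX"), "non-amino-acid")
})

test_that("median length filter applies the inclusive >= 50% discard rule", {
  expect_identical(tmh_filter_cutoff(23), 12L)
  segs <- data.frame(length = c(23, 23, 23, 11, 35))
  kept <- filter_by_median(segs)
  expect_equal(kept$length, c(23, 23, 23))
  expect_equal(attr(kept, "median_length"), 23)
  expect_equal(attr(kept, "cutoff"), 12L)
  # a segment of exactly the median is always kept
  expect_true(23 %in% filter_by_median(data.frame(length = c(23, 60)))$length)
  # idempotence at fixed cutoff: filtering the kept set changes nothing
  segs2 <- data.frame(length = c(20, 21, 22, 23, 24, 25, 26, 40, 9))
  k1 <- filter_by_median(segs2)
  k2 <- filter_by_median(k1)
  expect_equal(k2$length, k1$length)
})

test_that("single-span ortholog selection keys on the reference member", {
  groups <- data.frame(
    group_id = rep(c("G1", "G2", "G3"), each = 2),
    species = rep(c("pombe", "japonicus"), 3),
    protein_id = c("p1", "j1", "p2", "j2", "p3", "j3"),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(protein_id = c("p1", "p2", "p2", "j1", "j2", "j3"),
                    start = 1, end = 21, length = 21)
  # p3 lacks annotations entirely: skipped with a warning
  expect_warning(sel <- single_span_orthologs(groups, ann, "pombe"),
                 "without annotations")
  # p1 has 1 helix (kept), p2 has 2 (dropped), p3 has 0 (dropped)
  expect_equal(unique(sel$group_id), "G1")
  expect_equal(nrow(sel), 2L)
})

test_that("Wilcoxon comparison matches exact enumeration for small samples", {
  set.seed(8)
  for (rep in 1:25) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    # tie-free samples so the exact null applies
    pool <- sample(1000, m + n)
    a <- pool[seq_len(m)]; b <- pool[m + seq_len(n)]
    got <- length_comparison(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_wilcoxon_p(a, b), tolerance = 1e-12,
                 info = sprintf("m=%d n=%d", m, n))
  }
  # identical samples give p = 1
  expect_equal(length_comparison(c(20, 21, 22), c(20, 21, 22))$p_value, 1)
})

test_that("a planted median length shift is detected at cohort scale", {
  pr <- gen_ortholog_proteomes(31, n_groups = 200, single_span_fraction = 1)
  sp_map <- setNames(pr$groups$species, pr$groups$protein_id)
  ann <- predict_tmh_table(pr$sequences, sp_map)
  kept <- filter_by_median(ann)
  sel <- suppressWarnings(single_span_orthologs(pr$groups, kept, "pombe"))
  keep_prot <- function(sp) kept$length[kept$species == sp &
                                          kept$protein_id %in% sel$protein_id]
  cmp <- length_comparison(keep_prot("pombe"), keep_prot("japonicus"))
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$median_a, cmp$median_b)     # japonicus planted shorter
  # no shift between the two unshifted species
  cmp0 <- length_comparison(keep_prot("octosporus"), keep_prot("cryophilus"))
  expect_gt(cmp0$p_value, 0.001)
})

test_that("count differences locate planted helix dropout", {
  pr <- gen_ortholog_proteomes(17, n_groups = 150, single_span_fraction = 0,
                               dropout = c(japonicus = 0.2))
  # counts on the raw predictions: the background plants no spurious helices,
  # so differences reflect the planted dropout exactly
  ann <- predict_tmh_table(pr$sequences,
                           setNames(pr$groups$species, pr$groups$protein_id))
  d <- count_difference_distribution(pr$groups, ann, "pombe")
  dj <- d$diff[d$species == "japonicus"]
  expect_lt(abs(mean(dj == -1) - 0.2), 0.08)   # binomial sd ~ 0.033 at n = 150
  d0 <- d$diff[d$species == "octosporus"]
  expect_true(all(d0 == 0))
  # swapping reference negates the signs
  dj2 <- count_difference_distribution(pr$groups, ann, "japonicus")
  dp <- dj2$diff[dj2$species == "pombe"]
  expect_equal(sort(unique(dp)), sort(unique(-dj)))
})

test_that("residue class composition sums to one and recovers enrichment", {
  segs <- data.frame(protein_id = c("x", "y"), species = c("s1", "s1"),
                     start = 1, end = 4)
  seqs <- c(x = "AAAA", y = "AAFF")
  comp <- residue_class_composition(segs, seqs)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_equal(comp$fraction[comp$class == "small_nonpolar"], 0.75)
  expect_equal(comp$fraction[comp$class == "large_nonpolar"], 0.25)
  expect_error(residue_class_composition(segs, seqs,
                                         class_table = c(A = "small_nonpolar")),
               "absent from class table")
  # planted G/A/S enrichment in one species is recovered
  w_base <- c(L = 0.28, I = 0.2, V = 0.2, F = 0.12, A = 0.15, M = 0.05)
  w_gas <- c(w_base, G = 0.10, S = 0.06)   # extra small residues
  pr <- gen_ortholog_proteomes(9, n_groups = 120, single_span_fraction = 1,
                               per_species_tmh_weights = list(japonicus = w_gas))
  truth <- pr$truth_segments
  comp2 <- residue_class_composition(truth, pr$sequences)
  small <- function(sp) comp2$fraction[comp2$species == sp &
                                         comp2$class == "small_nonpolar"]
  expect_gt(small("japonicus"), small("pombe"))
})

test_that("composition fractions sum to one per species on synthetic cohorts", {
  pr <- gen_ortholog_proteomes(2, n_groups = 30)
  comp <- residue_class_composition(pr$truth_segments, pr$sequences)
  sums <- tapply(comp$fraction, comp$species, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
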