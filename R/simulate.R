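# Seeded synthetic-data generators.  Each generator emulates the statistical
# structure one pipeline stage assumes and returns its ground truth in
# machine-readable form alongside the data.

#' Default internal standard mix
#'
#' One spiked standard per lipid class, modelled on a deuterated/odd-chain
#' shotgun standard mix: d31-labelled 16:0/18:1 species for the diacyl GPL
#' classes, tetra-14:0 cardiolipin, di-22:1 DG, tri-22:1 TG and t18:0/16:0
#' ceramide.  m/z values are computed from the labelled compositions so
#' standards never collide with endogenous species.
#'
#' @param classes classes to include (default: all with a defined standard).
#' @return data frame: `class`, `label`, `spiked_pmol`, `neutral_mass`,
#'   `adduct`, `mz`, `polarity`.
#' @export
internal_standard_mix <- function(classes = NULL) {
  d31 <- function(class) {
    comp <- species_composition(sprintf("%s 34:1", class))
    comp <- comp_add(comp_subtract(comp, c(H = 31)), c(D = 31))
    list(label = sprintf("%s d31-16:0/18:1", class),
         mass = monoisotopic_mass(comp))
  }
  plain <- function(label) list(label = label,
                                mass = monoisotopic_mass(species_composition(label)))
  defs <- list(
    PC  = c(d31("PC"),  spiked = 71),
    PE  = c(d31("PE"),  spiked = 50),
    PI  = c(d31("PI"),  spiked = 43),
    PS  = c(d31("PS"),  spiked = 24),
    PA  = c(d31("PA"),  spiked = 5),
    PG  = c(d31("PG"),  spiked = 1),
    CL  = c(plain("CL 56:0"),   spiked = 1),
    Cer = c(plain("Cer 34:0:3"), spiked = 4),
    DG  = c(plain("DG 44:2"),   spiked = 7),
    TG  = c(plain("TG 66:3"),   spiked = 5)
  )
  cls <- if (is.null(classes)) names(defs) else intersect(names(defs), classes)
  if (length(cls) == 0L) stop("no standards defined for requested classes")
  rows <- .class_row(cls)
  out <- data.frame(
    class = cls,
    label = vapply(defs[cls], function(d) d$label, character(1)),
    spiked_pmol = vapply(defs[cls], function(d) d$spiked, numeric(1)),
    neutral_mass = vapply(defs[cls], function(d) d$mass, numeric(1)),
    adduct = rows$adduct,
    polarity = rows$polarity,
    stringsAsFactors = FALSE
  )
  out$mz <- adduct_mz(out$neutral_mass, out$adduct)
  rownames(out) <- NULL
  out
}

#' Default species palette of the synthetic lipidome
#'
#' A two-species-style membrane lipidome dominated by the four main GPL
#' classes, with a tunable asymmetric (C10:0 at sn-2) fraction per diacyl
#' class.  Class weights and the per-class split between asymmetric
#' (16:0/10:0, 18:0/10:0) and symmetric (34:x, 36:x) species are molar
#' fractions.
#'
#' @param asym_fraction named numeric vector: per-class molar fraction of
#'   asymmetric species (defaults mirror a short-chain-rich lipidome with
#'   PI = 0.9).
#' @param class_weights named numeric vector of class molar weights
#'   (normalized internally; DG/TG are storage lipids outside the polar
#'   denominator).
#' @return data frame: `label` (sn-resolved where applicable), `class`,
#'   `weight` (overall molar fraction), `asym`.
#' @export
lipidome_palette <- function(asym_fraction = c(PC = 0.55, PE = 0.45,
                                               PI = 0.90, PS = 0.35),
                             class_weights = c(PC = 0.36, PE = 0.22, PI = 0.25,
                                               PS = 0.08, PA = 0.02, PG = 0.01,
                                               CL = 0.01, Cer = 0.03,
                                               DG = 0.01, TG = 0.01)) {
  stopifnot(all(asym_fraction >= 0), all(asym_fraction <= 1),
            all(class_weights >= 0), sum(class_weights) > 0)
  class_weights <- class_weights / sum(class_weights)
  rows <- list()
  add <- function(label, class, w, asym) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, class = class, weight = w, asym = asym,
      stringsAsFactors = FALSE)
  }
  for (cl in intersect(c("PC", "PE", "PI", "PS"), names(class_weights))) {
    wcl <- class_weights[[cl]]
    if (wcl == 0) next
    fa <- if (cl %in% names(asym_fraction)) asym_fraction[[cl]] else 0
    sym2 <- if (cl == "PI") "18:0/18:1" else "18:1/18:1"
    add(sprintf("%s 16:0/10:0", cl), cl, wcl * fa * 0.4, TRUE)
    add(sprintf("%s 18:0/10:0", cl), cl, wcl * fa * 0.6, TRUE)
    add(sprintf("%s 16:0/18:1", cl), cl, wcl * (1 - fa) * 0.5, FALSE)
    add(sprintf("%s %s", cl, sym2), cl, wcl * (1 - fa) * 0.5, FALSE)
  }
  singles <- c(PA = "PA 34:1", PG = "PG 34:1", CL = "CL 68:2",
               Cer = "Cer 44:0:3", DG = "DG 34:1", TG = "TG 48:1")
  for (cl in intersect(names(singles), names(class_weights))) {
    if (class_weights[[cl]] > 0) add(singles[[cl]], cl, class_weights[[cl]], FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$weight > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic shotgun lipidome
#'
#' Places one peak per palette species at its theoretical adduct m/z with
#' multiplicative log-normal intensity noise and Gaussian ppm jitter, plus the
#' internal-standard peaks, split into positive- and negative-mode lists.
#' Ground truth (molar fractions, sn-resolution, asymmetry flags) is returned
#' alongside.
#'
#' @param seed integer RNG seed.
#' @param palette a [lipidome_palette()].
#' @param total_pmol total analyte amount in pmol (default 500).
#' @param intensity_cv multiplicative (log-normal) intensity noise, as a
#'   coefficient of variation (default 0: noiseless).
#' @param ppm_jitter standard deviation of Gaussian m/z jitter in ppm
#'   (default 0).
#' @param response counts per pmol converting amounts to intensities.
#' @return a list: `truth` (palette + `label_sum`, `amount_pmol`,
#'   `mol_percent_polar`), `peaks_pos`, `peaks_neg`, `standards` (the mix with
#'   an `intensity` column carrying its own noisy peak intensity).
#' @export
gen_lipidome <- function(seed, palette = lipidome_palette(), total_pmol = 500,
                         intensity_cv = 0, ppm_jitter = 0, response = 1000) {
  if (nrow(palette) == 0L) stop("empty species palette")
  set.seed(seed)
  truth <- palette
  truth$weight <- truth$weight / sum(truth$weight)
  parsed <- lapply(truth$label, parse_species_label)
  truth$label_sum <- vapply(parsed, function(p)
    species_label(p$class, p$total_c, p$total_db, p$total_oh), character(1))
  truth$amount_pmol <- truth$weight * total_pmol
  polar <- .class_row(truth$class)$polar
  truth$mol_percent_polar <- ifelse(
    polar, 100 * truth$amount_pmol / sum(truth$amount_pmol[polar]), NA_real_)
  rows <- .class_row(truth$class)
  mass <- vapply(parsed, function(p) monoisotopic_mass(species_composition(p)),
                 numeric(1))
  mz <- adduct_mz(mass, rows$adduct)
  lnsd <- if (intensity_cv > 0) sqrt(log(1 + intensity_cv^2)) else 0
  noise <- function(n) if (lnsd > 0) exp(stats::rnorm(n, -lnsd^2 / 2, lnsd)) else rep(1, n)
  intensity <- truth$amount_pmol * response * noise(nrow(truth))
  jit <- function(m) if (ppm_jitter > 0)
    m * (1 + stats::rnorm(length(m), 0, ppm_jitter * 1e-6)) else m
  std <- internal_standard_mix(unique(truth$class))
  std$intensity <- std$spiked_pmol * response * noise(nrow(std))
  std$mz_obs <- jit(std$mz)
  pk <- data.frame(mz = jit(mz), intensity = intensity,
                   polarity = rows$polarity, stringsAsFactors = FALSE)
  spk <- data.frame(mz = std$mz_obs, intensity = std$intensity,
                    polarity = std$polarity, stringsAsFactors = FALSE)
  all_pk <- rbind(pk, spk)
  list(
    truth = truth,
    peaks_pos = all_pk[all_pk$polarity == "positive", c("mz", "intensity")],
    peaks_neg = all_pk[all_pk$polarity == "negative", c("mz", "intensity")],
    standards = std
  )
}

#' Recover internal-standard peak intensities from measured peak lists
#'
#' Matches each standard's theoretical m/z in the peak list of its polarity at
#' the given ppm tolerance.  Runs in which a class standard is not recovered
#' fail quantification QC and raise an error.
#'
#' @param peaks_pos,peaks_neg peak lists (`mz`, `intensity`).
#' @param standards an [internal_standard_mix()] table.
#' @param tol_ppm matching tolerance (default 3).
#' @return `standards` with a (re)computed `intensity` column.
#' @export
recover_standard_intensities <- function(peaks_pos, peaks_neg, standards,
                                         tol_ppm = 3) {
  intensity <- numeric(nrow(standards))
  for (i in seq_len(nrow(standards))) {
    pk <- if (standards$polarity[i] == "positive") peaks_pos else peaks_neg
    ppm <- abs(pk$mz - standards$mz[i]) / standards$mz[i] * 1e6
    hit <- which(ppm <= tol_ppm)
    if (length(hit) == 0L) {
      stop("internal standard for class ", standards$class[i],
           " not recovered within ", tol_ppm, " ppm")
    }
    intensity[i] <- sum(pk$intensity[hit[which.min(ppm[hit])]])
  }
  standards$intensity <- intensity
  standards
}

#' Annotate and quantify a two-polarity peak-list pair end to end
#'
#' Convenience wrapper: builds (or takes) a species database, matches both
#' polarities, recovers the standard intensities and quantifies.
#'
#' @param peaks_pos,peaks_neg peak lists (`mz`, `intensity`).
#' @param standards an [internal_standard_mix()] table (theoretical m/z;
#'   intensities are recovered from the peak lists).
#' @param database species database (default: all classes, C 24-72, DB 0-4).
#' @param tol_ppm matching tolerance in ppm.
#' @return a list: `quant` ([quantify_species()] output), `assignments`,
#'   `profiles` ([class_profiles()]).
#' @export
lipidome_pipeline <- function(peaks_pos, peaks_neg, standards,
                              database = NULL, tol_ppm = 3) {
  if (is.null(database)) {
    database <- build_species_database(lipid_classes()$class, 24:72, 0:4)
  }
  asg <- rbind(
    match_peaks(peaks_pos, database, match_config(tol_ppm, "positive")),
    match_peaks(peaks_neg, database, match_config(tol_ppm, "negative"))
  )
  # spiked standards that coincide with database species must not be
  # quantified as endogenous analytes
  asg <- asg[!(asg$label %in% standards$label), , drop = FALSE]
  std <- recover_standard_intensities(peaks_pos, peaks_neg, standards, tol_ppm)
  quant <- quantify_species(asg, std)
  list(quant = quant, assignments = asg, profiles = class_profiles(quant))
}

#' Generate a synthetic MS2 spectrum of an sn-resolved species
#'
#' Carboxylate and neutral-loss fragments at exact m/z; the acid- and
#' ketene-loss intensities of the sn-2 chain are `sn2_factor` times those of
#' the sn-1 chain before noise.
#'
#' @param species sn-resolved species label.
#' @param sn2_factor sn-2 / sn-1 neutral-loss intensity factor (> 0).
#' @param noise_cv multiplicative log-normal intensity noise (default 0).
#' @param seed RNG seed (only used when `noise_cv > 0`).
#' @param base_intensity sn-1 loss intensity before noise.
#' @return a list: `spectrum` (`mz`, `intensity`), `precursor_mz`,
#'   `truth` (the planted sn-resolved label).
#' @export
gen_ms2 <- function(species, sn2_factor, noise_cv = 0, seed = 1,
                    base_intensity = 100) {
  stopifnot(sn2_factor > 0)
  frags <- diagnostic_fragments(species)
  base <- ifelse(frags$fragment == "carboxylate", 2 * base_intensity,
                 base_intensity)
  fac <- ifelse(frags$chain == "sn-2" &
                  frags$fragment %in% c("acid_loss", "ketene_loss"),
                sn2_factor, 1)
  intensity <- base * fac
  if (noise_cv > 0) {
    set.seed(seed)
    lnsd <- sqrt(log(1 + noise_cv^2))
    intensity <- intensity * exp(stats::rnorm(length(intensity), -lnsd^2 / 2, lnsd))
  }
  list(spectrum = data.frame(mz = frags$mz, intensity = intensity),
       precursor_mz = frags$precursor_mz[1L],
       truth = if (is.character(species)) species else species_label(
         species$class, chains = species$chains))
}

#' Generate thermally fluctuating quasi-spherical vesicle contours
#'
#' Per frame, independent complex Gaussian mode coefficients with the
#' Helfrich model variances (quasi-static approximation) build
#' `r(phi) = R (1 + sum_q Re(c_q e^{i q phi}))` on a uniform angular grid.
#'
#' @param seed RNG seed.
#' @param kappa bending rigidity in k_B T.
#' @param sigma_bar reduced tension.
#' @param radius mean radius in micrometres (default 15).
#' @param n_frames number of contours (default 4000).
#' @param n_points points per contour (default 512, >= 128).
#' @param q_max highest excited mode (default 40).
#' @param temperature kelvin (metadata).
#' @param pixel_noise Gaussian radial noise in micrometres (default 0).
#' @param l_max truncation of the Helfrich sum.
#' @return a [contour_series()] with attribute `truth` = list(kappa,
#'   sigma_bar, radius, mode_variance).
#' @export
gen_guv_contours <- function(seed, kappa, sigma_bar = 0, radius = 15,
                             n_frames = 4000L, n_points = 512L, q_max = 40L,
                             temperature = 298.15, pixel_noise = 0,
                             l_max = 100L) {
  stopifnot(kappa > 0, n_points >= 128L, q_max >= 2L)
  set.seed(seed)
  qs <- 2:q_max
  vq <- helfrich_variance(qs, kappa, sigma_bar, l_max)
  phi <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
  Cm <- cos(outer(qs, phi))          # n_q x n_points
  Sm <- sin(outer(qs, phi))
  A <- matrix(stats::rnorm(n_frames * length(qs), 0, rep(sqrt(vq), each = n_frames)),
              n_frames, length(qs))
  B <- matrix(stats::rnorm(n_frames * length(qs), 0, rep(sqrt(vq), each = n_frames)),
              n_frames, length(qs))
  U <- A %*% Cm + B %*% Sm           # n_frames x n_points
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    r <- radius * (1 + U[i, ])
    if (pixel_noise > 0) r <- r + stats::rnorm(n_points, 0, pixel_noise)
    frames[[i]] <- cbind(r * cos(phi), r * sin(phi))
  }
  out <- contour_series(frames, temperature = temperature)
  attr(out, "truth") <- list(kappa = kappa, sigma_bar = sigma_bar,
                             radius = radius,
                             mode_variance = data.frame(q = qs, variance = vq))
  out
}

#' Generate isotopologue vectors from a binomial labeling mixture
#'
#' A fraction of molecules is uniformly tracer-labeled (each skeleton carbon
#' 13C with probability `tracer_purity`); the rest carry only natural
#' abundance.  Derivatization carbons always draw from natural abundance.
#' Counts are multinomial at the given depth, truncated at shift M+n.
#'
#' @param seed RNG seed.
#' @param n_carbons skeleton carbons.
#' @param labeled_fraction fraction of the pool that is tracer-labeled.
#' @param tracer_purity per-carbon tracer enrichment (default 0.99).
#' @param depth total ion count sampled (default 1e5).
#' @param config an [isotope_config()].
#' @return a list: `measured` (counts M+0..M+n), `truth` = labeled_fraction,
#'   `expected` (noise-free shift distribution).
#' @export
gen_mids <- function(seed, n_carbons, labeled_fraction, tracer_purity = 0.99,
                     depth = 1e5, config = isotope_config()) {
  stopifnot(labeled_fraction >= 0, labeled_fraction <= 1)
  set.seed(seed)
  n <- as.integer(n_carbons)
  shifts <- 0:n
  conv_trunc <- function(p1, p2) {
    # convolution of two shift pmf vectors, truncated at n
    out <- numeric(n + 1L)
    for (i in seq_along(p1)) {
      js <- seq_along(p2) + i - 2L
      keep <- js <= n
      out[js[keep] + 1L] <- out[js[keep] + 1L] + p1[i] * p2[keep]
    }
    out
  }
  nat_deriv <- stats::dbinom(0:min(n, config$derivatization_carbons),
                             config$derivatization_carbons, config$p_natural)
  p_unlab <- conv_trunc(stats::dbinom(shifts, n, config$p_natural), nat_deriv)
  p_lab <- conv_trunc(stats::dbinom(shifts, n, tracer_purity), nat_deriv)
  p <- (1 - labeled_fraction) * p_unlab + labeled_fraction * p_lab
  measured <- as.numeric(stats::rmultinom(1L, size = depth, prob = p / sum(p)))
  list(measured = measured, truth = labeled_fraction, expected = p)
}

#' Generate synthetic ortholog proteomes with planted TMHs
#'
#' Four fission-yeast-style species; each ortholog group carries the same
#' number of planted hydrophobic helices in every species (subject to
#' per-species dropout), with species-specific helix length distributions.
#' Backgrounds are strictly hydrophilic so the sliding-window predictor finds
#' exactly the planted helices.
#'
#' @param seed RNG seed.
#' @param n_groups number of 1:1:1:1 ortholog groups (default 200).
#' @param species species ids (default the four fission yeasts; the first is
#'   the reference).
#' @param mean_length baseline mean planted helix length in residues
#'   (default 27).
#' @param length_shift named numeric vector of per-species additive shifts of
#'   the mean (default `c(japonicus = -4)`).
#' @param length_sd SD of planted lengths (default 3; lengths are rounded and
#'   clamped to >= 16).
#' @param single_span_fraction fraction of groups with exactly one helix;
#'   the rest have two (default 0.7).
#' @param dropout named numeric vector: per-species probability that a
#'   multi-helix member loses one helix (default none).
#' @param tmh_residue_weights named numeric vector of residue weights inside
#'   helices (default a hydrophobic palette); may be overridden per species
#'   via a named list `per_species_tmh_weights`.
#' @param per_species_tmh_weights optional named list (species -> weights).
#' @param flank_length hydrophilic flank/spacer length (default 60).
#' @return a list: `sequences` (named character vector, protein_id ->
#'   sequence), `groups` (group_id, species, protein_id), `truth_segments`
#'   (protein_id, species, start, end, length).
#' @export
gen_ortholog_proteomes <- function(seed, n_groups = 200L,
                                   species = c("pombe", "japonicus",
                                               "octosporus", "cryophilus"),
                                   mean_length = 27, length_shift = c(japonicus = -4),
                                   length_sd = 3, single_span_fraction = 0.7,
                                   dropout = NULL,
                                   tmh_residue_weights = c(L = 0.28, I = 0.2,
                                                           V = 0.2, F = 0.12,
                                                           A = 0.15, M = 0.05),
                                   per_species_tmh_weights = NULL,
                                   flank_length = 60L) {
  set.seed(seed)
  bg_res <- c(D = 0.12, E = 0.12, K = 0.12, R = 0.1, N = 0.1, Q = 0.1,
              S = 0.12, T = 0.1, G = 0.07, P = 0.05)
  seqs <- character(0)
  groups <- list(); truth <- list()
  n_helices <- ifelse(stats::runif(n_groups) < single_span_fraction, 1L, 2L)
  for (g in seq_len(n_groups)) {
    gid <- sprintf("OG%04d", g)
    for (sp in species) {
      pid <- sprintf("%s_%04d", sp, g)
      nh <- n_helices[g]
      if (!is.null(dropout) && sp %in% names(dropout) && nh > 1L &&
          stats::runif(1) < dropout[[sp]]) {
        nh <- nh - 1L
      }
      mu <- mean_length + if (sp %in% names(length_shift)) length_shift[[sp]] else 0
      w <- if (!is.null(per_species_tmh_weights) && sp %in% names(per_species_tmh_weights)) {
        per_species_tmh_weights[[sp]]
      } else tmh_residue_weights
      w <- w / sum(w)
      parts <- character(0); segs <- list(); pos <- 0L
      for (h in seq_len(nh)) {
        flank <- paste(sample(names(bg_res), flank_length, TRUE, bg_res), collapse = "")
        len <- max(16L, round(stats::rnorm(1, mu, length_sd)))
        helix <- paste(sample(names(w), len, TRUE, w), collapse = "")
        parts <- c(parts, flank, helix)
        segs[[h]] <- c(start = pos + flank_length + 1L,
                       end = pos + flank_length + len)
        pos <- pos + flank_length + len
      }
      parts <- c(parts, paste(sample(names(bg_res), flank_length, TRUE, bg_res),
                              collapse = ""))
      seqs[pid] <- paste(parts, collapse = "")
      groups[[length(groups) + 1L]] <- data.frame(
        group_id = gid, species = sp, protein_id = pid, stringsAsFactors = FALSE)
      if (length(segs)) {
        sd_ <- do.call(rbind, segs)
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = pid, species = sp, start = sd_[, "start"],
          end = sd_[, "end"], length = sd_[, "end"] - sd_[, "start"] + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(sequences = seqs,
       groups = do.call(rbind, groups),
       truth_segments = truth)
}

#' Write / read proteome FASTA
#'
#' @param sequences named character vector of protein sequences.
#' @param path file path.
#' @export
write_proteome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
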