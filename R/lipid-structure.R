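# sn-regiochemistry from MS/MS neutral losses, in-silico PLA2 digestion, and
# acyl asymmetry / chain summaries.

#' Diagnostic MS2 fragments of an sn-resolved glycerophospholipid
#'
#' For each acyl chain of a diacyl species three negative-mode diagnostic ions
#' are returned: the carboxylate anion RCOO-, the neutral acid loss
#' [M-H-RCOOH]- and the neutral ketene loss [M-H-R'CH=C=O]-.
#'
#' @param species an sn-resolved species label (e.g. `"PI 18:0/10:0"`) or
#'   parsed species list.
#' @param polarity only `"negative"` is supported (diagnostic losses are
#'   negative-mode ions).
#' @return data frame: `chain` (sn position), `carbons`, `double_bonds`,
#'   `fragment` (`carboxylate`, `acid_loss`, `ketene_loss`), `mz`.
#' @export
diagnostic_fragments <- function(species, polarity = "negative") {
  if (is.character(species)) species <- parse_species_label(species)
  if (is.null(species$chains) || length(species$chains) != 2L) {
    stop("resolve chains first: diagnostic fragments need an sn-resolved diacyl species")
  }
  if (polarity != "negative") stop("diagnostic neutral losses are negative-mode only")
  prec <- adduct_mz(monoisotopic_mass(species_composition(species)), "[M-H]-")
  water <- monoisotopic_mass(elemental_composition(H = 2, O = 1))
  rows <- lapply(seq_along(species$chains), function(i) {
    ch <- species$chains[[i]]
    acid <- monoisotopic_mass(elemental_composition(
      .acid_composition(ch[[1L]], ch[[2L]])))
    data.frame(
      chain = paste0("sn-", i),
      carbons = ch[[1L]], double_bonds = ch[[2L]],
      fragment = c("carboxylate", "acid_loss", "ketene_loss"),
      mz = c(acid - .PROTON_MASS, prec - acid, prec - (acid - water)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$precursor_mz <- prec
  rownames(out) <- NULL
  out
}

# enumerate (c1,d1)/(c2,d2) chain pairs consistent with a sum composition
.chain_decompositions <- function(total_c, total_db,
                                  chain_carbons = 8:26, chain_db = 0:3) {
  out <- list()
  for (c1 in chain_carbons) {
    c2 <- total_c - c1
    if (c2 < min(chain_carbons) || c2 > max(chain_carbons) || c2 < c1) next
    for (d1 in chain_db) {
      d2 <- total_db - d1
      if (d2 < 0 || d2 > max(chain_db)) next
      if (2 * d1 > c1 || 2 * d2 > c2) next
      out[[length(out) + 1L]] <- list(c(carbons = c1, double_bonds = d1),
                                      c(carbons = c2, double_bonds = d2))
    }
  }
  out
}

#' Assign sn-1/sn-2 positions from an MS2 spectrum
#'
#' Implements the intensity rule: neutral losses of the acid and the ketene
#' are more abundant from sn-2 than from sn-1.  For every chain decomposition
#' consistent with the candidate sum composition, the acid-loss and
#' ketene-loss fragment intensities are summed per chain; the decomposition
#' with the largest total matched intensity is taken, its higher-loss chain is
#' placed at sn-2, and the call is `assigned` when the sn-2/sn-1 intensity
#' ratio reaches `min_ratio` (inclusive), otherwise `ambiguous`.
#'
#' @param ms2 data frame of fragments with columns `mz`, `intensity`.
#' @param candidate sum-level species label (e.g. `"PI 28:0"`).
#' @param min_ratio minimum sn-2/sn-1 intensity ratio for a confident call
#'   (default 7, the empirical floor for diacyl glycerophospholipids).
#' @param tol_mz fragment matching tolerance in Da.
#' @param chain_carbons,chain_db candidate per-chain carbon and double-bond
#'   values used to enumerate decompositions.
#' @return a list of class `sn_assignment`: `species` (sn-resolved label,
#'   sn-1 first), `sn1`, `sn2`, `sn2_over_sn1_ratio`, `confidence`.
#' @export
assign_sn_positions <- function(ms2, candidate, min_ratio = 7,
                                tol_mz = 0.01,
                                chain_carbons = 8:26, chain_db = 0:3) {
  stopifnot(min_ratio >= 1, all(c("mz", "intensity") %in% names(ms2)))
  cand <- if (is.character(candidate)) parse_species_label(candidate) else candidate
  if (.is_sphingo(cand$class)) stop("sphingolipid fragmentation is not supported")
  decomps <- if (!is.null(cand$chains)) list(cand$chains) else
    .chain_decompositions(cand$total_c, cand$total_db, chain_carbons, chain_db)
  if (length(decomps) == 0L) stop("no chain decomposition consistent with ", cand$total_c,
                                  ":", cand$total_db)
  loss_intensity <- function(frags, who) {
    f <- frags[frags$chain == who & frags$fragment %in% c("acid_loss", "ketene_loss"), ]
    sum(vapply(f$mz, function(m) {
      hit <- abs(ms2$mz - m) <= tol_mz
      if (any(hit)) sum(ms2$intensity[hit]) else 0
    }, numeric(1)))
  }
  best <- NULL
  for (dec in decomps) {
    sp <- list(class = cand$class, level = "sn_resolved",
               total_c = cand$total_c, total_db = cand$total_db,
               total_oh = 0L, chains = dec)
    frags <- diagnostic_fragments(sp)
    i1 <- loss_intensity(frags, "sn-1")
    i2 <- loss_intensity(frags, "sn-2")
    tot <- i1 + i2
    if (is.null(best) || tot > best$tot) {
      best <- list(chains = dec, i1 = i1, i2 = i2, tot = tot)
    }
  }
  if (is.null(best) || best$tot <= 0) stop("uninformative spectrum: no diagnostic fragments matched")
  # the chain with the larger summed neutral-loss intensity sits at sn-2
  if (best$i2 >= best$i1) {
    sn1 <- best$chains[[1L]]; sn2 <- best$chains[[2L]]
    hi <- best$i2; lo <- best$i1
  } else {
    sn1 <- best$chains[[2L]]; sn2 <- best$chains[[1L]]
    hi <- best$i1; lo <- best$i2
  }
  ratio <- if (lo > 0) hi / lo else Inf
  # identical chains are trivially resolved
  symmetric <- sn1[["carbons"]] == sn2[["carbons"]] &&
    sn1[["double_bonds"]] == sn2[["double_bonds"]]
  confidence <- if (symmetric || ratio >= min_ratio) "assigned" else "ambiguous"
  structure(list(
    species = species_label(cand$class, chains = list(sn1, sn2)),
    sn1 = sn1, sn2 = sn2,
    sn2_over_sn1_ratio = ratio,
    confidence = confidence
  ), class = "sn_assignment")
}

#' @export
print.sn_assignment <- function(x, ...) {
  cat(sprintf("<sn assignment> %s  (sn-2/sn-1 ratio %.2f, %s)\n",
              x$species, x$sn2_over_sn1_ratio, x$confidence))
  invisible(x)
}

#' In-silico phospholipase A2 digestion
#'
#' PLA2 hydrolyses the sn-2 ester of diacyl glycerophospholipids, yielding the
#' sn-1 lyso-lipid and the free sn-2 fatty acid.  The recovered lipid-bound
#' fatty-acid profile after digestion therefore contains only sn-1 chains.
#'
#' @param species_table data frame with columns `label` (sn-resolved diacyl
#'   labels, sn-1 first) and `amount` (molar units).
#' @return a list: `products` (parent, lyso species, free fatty acid, amount),
#'   `fa_profile` (free vs lipid-bound fatty-acid molar profile by chain).
#' @export
pla2_digest <- function(species_table) {
  stopifnot(all(c("label", "amount") %in% names(species_table)))
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(species_table))) {
    sp <- parse_species_label(species_table$label[i])
    lyso <- .class_row(sp$class)$lyso_class
    if (is.null(sp$chains) || length(sp$chains) != 2L || is.na(lyso)) {
      skipped <- c(skipped, species_table$label[i]); next
    }
    sn1 <- sp$chains[[1L]]; sn2 <- sp$chains[[2L]]
    rows[[length(rows) + 1L]] <- data.frame(
      parent = species_table$label[i],
      lyso_species = species_label(lyso, chains = list(sn1)),
      free_fa = sprintf("C%d:%d", sn2[["carbons"]], sn2[["double_bonds"]]),
      sn1_fa = sprintf("C%d:%d", sn1[["carbons"]], sn1[["double_bonds"]]),
      amount = species_table$amount[i],
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning("skipped species without diacyl sn-resolution or lyso counterpart: ",
            paste(skipped, collapse = ", "))
  }
  if (length(rows) == 0L) stop("no digestible species in input")
  products <- do.call(rbind, rows)
  bound <- stats::aggregate(products$amount, by = list(fa = products$sn1_fa), FUN = sum)
  names(bound)[2L] <- "amount"
  bound$pool <- "lipid_bound"
  free <- stats::aggregate(products$amount, by = list(fa = products$free_fa), FUN = sum)
  names(free)[2L] <- "amount"
  free$pool <- "free_fa"
  list(products = products, fa_profile = rbind(bound, free))
}

#' Acyl chain-length asymmetry of a diacyl species
#'
#' @param species sn-resolved label or parsed list; alternatively a sum-level
#'   species with `sn2_carbons` supplied (e.g. the class-wide PLA2 result that
#'   C10:0 is exclusively esterified at sn-2).
#' @param sn2_carbons optional sn-2 chain length used to resolve a sum-level
#'   species.
#' @param threshold minimum |sn-1 - sn-2| carbon difference to call a species
#'   asymmetrical (default 6).
#' @return a list: `chain_diff` (carbons), `is_asymmetrical`.
#' @examples
#' asymmetry_metrics("PI 18:0/10:0")     # diff 8, asymmetrical
#' asymmetry_metrics("PC 16:0/18:1")     # diff 2, not
#' @export
asymmetry_metrics <- function(species, sn2_carbons = NULL, threshold = 6L) {
  if (is.character(species)) species <- parse_species_label(species)
  if (!is.null(species$chains) && length(species$chains) == 2L) {
    c1 <- species$chains[[1L]][["carbons"]]
    c2 <- species$chains[[2L]][["carbons"]]
  } else if (!is.null(sn2_carbons)) {
    c2 <- sn2_carbons
    c1 <- species$total_c - c2
    if (c1 < 2) stop("sn-2 chain length inconsistent with sum composition")
  } else {
    stop("chain lengths undeterminable: need an sn-resolved species or sn2_carbons")
  }
  diff <- abs(c1 - c2)
  list(chain_diff = diff, is_asymmetrical = diff >= threshold)
}

#' Per-class acyl summaries from a quantified lipidome
#'
#' For each polar class: mol%-weighted mean combined fatty-acid length,
#' distribution over double-bond counts, and (where sn-resolution or an
#' assumed sn-2 chain is available) the asymmetrical fraction.
#'
#' @param quant output of [quantify_species()], labels at sum or sn-resolved
#'   level.
#' @param assume_sn2_carbons optional named list mapping class code to an
#'   assumed sn-2 chain length for sum-level species flagged by
#'   `assume_for_labels` (e.g. `list(PI = 10)` after a PLA2 experiment).
#' @param assume_for_labels labels to which `assume_sn2_carbons` applies;
#'   default all sum-level species of the listed classes.
#' @param threshold asymmetry threshold in carbons (see [asymmetry_metrics()]).
#' @return data frame per class: `class`, `mean_combined_length`,
#'   `asym_fraction` (NA when no species could be resolved), plus an attribute
#'   `db_distribution` (long data frame class, total_db, fraction).
#' @export
acyl_summaries <- function(quant, assume_sn2_carbons = NULL,
                           assume_for_labels = NULL, threshold = 6L) {
  stopifnot(nrow(quant) > 0)
  info <- lapply(quant$label, parse_species_label)
  total_c <- vapply(info, `[[`, numeric(1), "total_c")
  total_db <- vapply(info, `[[`, numeric(1), "total_db")
  cls <- vapply(info, `[[`, character(1), "class")
  polar <- .class_row(cls)$polar
  w <- quant$amount_pmol
  asym <- vapply(seq_along(info), function(i) {
    sp <- info[[i]]
    if (!is.null(sp$chains) && length(sp$chains) == 2L) {
      return(asymmetry_metrics(sp, threshold = threshold)$is_asymmetrical)
    }
    a2 <- assume_sn2_carbons[[sp$class]]
    if (!is.null(a2) &&
        (is.null(assume_for_labels) || quant$label[i] %in% assume_for_labels) &&
        sp$total_c - a2 >= 2) {
      return(asymmetry_metrics(sp, sn2_carbons = a2, threshold = threshold)$is_asymmetrical)
    }
    NA
  }, logical(1))
  per_class <- lapply(split(seq_along(cls)[polar], cls[polar]), function(idx) {
    wi <- w[idx]
    if (sum(wi) == 0) return(NULL)
    known <- !is.na(asym[idx])
    data.frame(
      class = cls[idx][1L],
      mean_combined_length = sum(wi * total_c[idx]) / sum(wi),
      asym_fraction = if (any(known)) {
        sum(wi[known & asym[idx] %in% TRUE]) / sum(wi[known])
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_class[!vapply(per_class, is.null, logical(1))])
  rownames(out) <- NULL
  dbd <- do.call(rbind, lapply(split(seq_along(cls)[polar], cls[polar]), function(idx) {
    wi <- w[idx]
    agg <- stats::aggregate(wi, by = list(total_db = total_db[idx]), FUN = sum)
    data.frame(class = cls[idx][1L], total_db = agg$total_db,
               fraction = agg$x / sum(agg$x), stringsAsFactors = FALSE)
  }))
  rownames(dbd) <- NULL
  attr(out, "db_distribution") <- dbd
  out
}
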