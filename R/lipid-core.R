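# Lipid class chemistry table.
#
# `head_formula` is the complete head-group + backbone molecule with free
# hydroxyls at every acylation position (e.g. glycerophosphocholine for PC);
# a species composition is head + sum of fatty-acid compositions minus one
# water per ester bond.  Sphingolipids (Cer/IPC/MIPC) are handled by a closed
# formula over total carbons / double bonds / hydroxyls and are flagged here.
.LIPID_CLASSES <- data.frame(
  class      = c("PC", "PE", "PI", "PS", "PA", "PG", "CL",
                 "LPC", "LPE", "LPI", "LPS",
                 "DG", "TG", "EE",
                 "Cer", "IPC", "MIPC"),
  n_chains   = c(2L, 2L, 2L, 2L, 2L, 2L, 4L,
                 1L, 1L, 1L, 1L,
                 2L, 3L, 1L,
                 2L, 2L, 2L),
  category   = c(rep("GPL", 7L), rep("lysoGPL", 4L),
                 rep("neutral", 3L), rep("sphingolipid", 3L)),
  polar      = c(rep(TRUE, 11L), rep(FALSE, 3L), rep(TRUE, 3L)),
  polarity   = c("positive", "negative", "negative", "negative", "negative",
                 "negative", "negative",
                 "positive", "negative", "negative", "negative",
                 "positive", "positive", "positive",
                 "negative", "negative", "negative"),
  adduct     = c("[M+H]+", "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-",
                 "[M-H]-", "[M-H]-",
                 "[M+H]+", "[M-H]-", "[M-H]-", "[M-H]-",
                 "[M+NH4]+", "[M+NH4]+", "[M+NH4]+",
                 "[M-H]-", "[M-H]-", "[M-H]-"),
  lyso_class = c("LPC", "LPE", "LPI", "LPS", NA, NA, NA,
                 rep(NA, 10L)),
  stringsAsFactors = FALSE
)

.HEAD_FORMULAS <- list(
  PC  = c(C = 8, H = 20, N = 1, O = 6, P = 1),   # glycerophosphocholine
  PE  = c(C = 5, H = 14, N = 1, O = 6, P = 1),
  PI  = c(C = 9, H = 19, O = 11, P = 1),
  PS  = c(C = 6, H = 14, N = 1, O = 8, P = 1),
  PA  = c(C = 3, H = 9, O = 6, P = 1),
  PG  = c(C = 6, H = 15, O = 8, P = 1),
  CL  = c(C = 9, H = 18, O = 13, P = 2),          # bis(glycerophospho)glycerol
  LPC = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  LPE = c(C = 5, H = 14, N = 1, O = 6, P = 1),
  LPI = c(C = 9, H = 19, O = 11, P = 1),
  LPS = c(C = 6, H = 14, N = 1, O = 8, P = 1),
  DG  = c(C = 3, H = 8, O = 3),                   # glycerol
  TG  = c(C = 3, H = 8, O = 3),
  EE  = c(C = 28, H = 44, O = 1)                  # ergosterol
)

# sphingolipid head-group additions on top of the ceramide closed formula
.SPHINGO_ADDITIONS <- list(
  Cer  = c(),
  IPC  = c(C = 6, H = 11, O = 8, P = 1),          # inositol phosphate - H2O
  MIPC = c(C = 6, H = 11, O = 8, P = 1, C = 6, H = 10, O = 5)
)

.WATER <- c(H = 2, O = 1)

#' Lipid class table
#'
#' Supported lipid classes with chain counts, polar-lipid membership (used for
#' the mol%-of-polar-lipids denominator), and the default detection polarity
#' and adduct for each class.
#'
#' @return a data frame with one row per class.
#' @export
lipid_classes <- function() .LIPID_CLASSES

.class_row <- function(class) {
  i <- match(class, .LIPID_CLASSES$class)
  if (anyNA(i)) stop("unknown lipid class: ", paste(class[is.na(i)], collapse = ", "))
  .LIPID_CLASSES[i, , drop = FALSE]
}

.is_sphingo <- function(class) .class_row(class)$category == "sphingolipid"

# fatty-acid (free acid) composition for a chain of c carbons / d double bonds
.acid_composition <- function(carbons, double_bonds) {
  stopifnot(carbons >= 2, double_bonds >= 0, 2 * double_bonds <= carbons)
  c(C = carbons, H = 2 * carbons - 2 * double_bonds, O = 2)
}

#' Canonical species label
#'
#' Sum-level glycerolipids are written `CLASS C:D` (total carbons : total
#' double bonds); sn-resolved species `CLASS c1:d1/c2:d2` with sn-1 first;
#' sphingolipids `CLASS C:D:H` with the total hydroxyl count appended.
#'
#' @param class lipid class code.
#' @param total_c,total_db sum-level totals.
#' @param total_oh total hydroxyls (sphingolipids only).
#' @param chains optional list of per-chain `c(carbons, double_bonds)`
#'   vectors, sn-1 first; when given the label is sn-resolved.
#' @return character label.
#' @export
species_label <- function(class, total_c, total_db, total_oh = 0L, chains = NULL) {
  .class_row(class)
  if (!is.null(chains)) {
    paste0(class, " ", paste(vapply(chains, function(ch)
      sprintf("%d:%d", ch[[1L]], ch[[2L]]), character(1)), collapse = "/"))
  } else if (.is_sphingo(class)) {
    sprintf("%s %d:%d:%d", class, total_c, total_db, total_oh)
  } else {
    sprintf("%s %d:%d", class, total_c, total_db)
  }
}

#' Parse a canonical species label
#'
#' Inverse of [species_label()]; round-trips both sum-level and sn-resolved
#' labels.
#'
#' @param label character label such as `"PC 34:1"`, `"PI 18:0/10:0"` or
#'   `"Cer 34:0:3"`.
#' @return a list with `class`, `level`, `total_c`, `total_db`, `total_oh`
#'   and (for sn-resolved labels) `chains`.
#' @export
parse_species_label <- function(label) {
  stopifnot(length(label) == 1L, is.character(label))
  parts <- strsplit(trimws(label), " +")[[1L]]
  if (length(parts) != 2L) stop("malformed species label: ", label)
  class <- parts[1L]
  .class_row(class)
  body <- parts[2L]
  if (grepl("/", body, fixed = TRUE)) {
    chain_strs <- strsplit(body, "/", fixed = TRUE)[[1L]]
    chains <- lapply(chain_strs, function(s) {
      v <- as.integer(strsplit(s, ":", fixed = TRUE)[[1L]])
      if (length(v) != 2L || anyNA(v)) stop("malformed chain in label: ", label)
      c(carbons = v[1L], double_bonds = v[2L])
    })
    list(class = class, level = "sn_resolved",
         total_c = sum(vapply(chains, `[[`, integer(1), "carbons")),
         total_db = sum(vapply(chains, `[[`, integer(1), "double_bonds")),
         total_oh = 0L, chains = chains)
  } else {
    v <- as.integer(strsplit(body, ":", fixed = TRUE)[[1L]])
    if (anyNA(v) || !(length(v) %in% c(2L, 3L))) stop("malformed species label: ", label)
    list(class = class, level = "sum",
         total_c = v[1L], total_db = v[2L],
         total_oh = if (length(v) == 3L) v[3L] else 0L,
         chains = NULL)
  }
}

#' Elemental composition of a lipid species
#'
#' Assembles head group + backbone + acyl chains, removing one water per
#' ester bond.  Works from a canonical label or a parsed species list; the
#' result depends only on the sum composition.
#'
#' @param species a species label string or the result of
#'   [parse_species_label()].
#' @return an [elemental_composition()].
#' @examples
#' format(species_composition("PC 34:1"))   # "C42H82NO8P"
#' @export
species_composition <- function(species) {
  if (is.character(species)) species <- parse_species_label(species)
  class <- species$class
  row <- .class_row(class)
  if (.is_sphingo(class)) {
    # ceramide closed formula C_n H_{2n+1-2d} N O_{h+1}, then head additions
    n <- species$total_c; d <- species$total_db; h <- species$total_oh
    if (n < 2) stop("sphingolipid must have >= 2 carbons")
    core <- c(C = n, H = 2 * n + 1 - 2 * d, N = 1, O = h + 1)
    add <- .SPHINGO_ADDITIONS[[class]]
    return(if (length(add)) comp_add(elemental_composition(core), add)
           else elemental_composition(core))
  }
  head <- .HEAD_FORMULAS[[class]]
  if (is.null(head)) stop("no head-group formula for class ", class)
  n_chains <- row$n_chains
  if (!is.null(species$chains)) {
    if (length(species$chains) != n_chains) {
      stop(class, " requires ", n_chains, " chains, got ", length(species$chains))
    }
    acyl <- Reduce(comp_add, lapply(species$chains, function(ch)
      elemental_composition(.acid_composition(ch[[1L]], ch[[2L]]))))
  } else {
    # sum level: total acids C_C H_{2C-2D} O_{2n}
    C <- species$total_c; D <- species$total_db
    if (C < 2 * n_chains) stop("too few total carbons for ", n_chains, " chains")
    acyl <- elemental_composition(c(C = C, H = 2 * C - 2 * D, O = 2 * n_chains))
  }
  comp <- comp_add(elemental_composition(head), acyl)
  comp_subtract(comp, c(H = 2 * n_chains, O = n_chains))
}

#' Build an in-silico species database
#'
#' Enumerates one sum-level species per (class, total carbons, total double
#' bonds) combination over the given ranges, with neutral monoisotopic masses.
#'
#' @param classes character vector of lipid class codes.
#' @param carbon_range integer vector (range) of total acyl carbons.
#' @param db_range integer vector (range) of total double bonds.
#' @param hydroxyls total hydroxyl count applied to sphingolipid classes
#'   (default 3, a phytoceramide-type base with a non-hydroxylated amide FA).
#' @return a data frame: `label`, `class`, `total_c`, `total_db`, `total_oh`,
#'   `formula`, `neutral_mass`.
#' @examples
#' db <- build_species_database("PI", 26:36, 0:2)
#' nrow(db)  # 33
#' @export
build_species_database <- function(classes, carbon_range, db_range, hydroxyls = 3L) {
  if (length(classes) == 0L) stop("no classes")
  .class_row(classes)
  carbon_range <- sort(unique(as.integer(carbon_range)))
  db_range <- sort(unique(as.integer(db_range)))
  if (length(carbon_range) == 0L || length(db_range) == 0L) {
    stop("carbon_range and db_range must be non-empty")
  }
  grid <- expand.grid(class = classes, total_c = carbon_range,
                      total_db = db_range, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$total_oh <- ifelse(.is_sphingo(grid$class), as.integer(hydroxyls), 0L)
  sp <- lapply(seq_len(nrow(grid)), function(i) {
    s <- list(class = grid$class[i], level = "sum",
              total_c = grid$total_c[i], total_db = grid$total_db[i],
              total_oh = grid$total_oh[i], chains = NULL)
    comp <- species_composition(s)
    list(label = species_label(s$class, s$total_c, s$total_db, s$total_oh),
         formula = format(comp), neutral_mass = monoisotopic_mass(comp))
  })
  out <- data.frame(
    label = vapply(sp, `[[`, character(1), "label"),
    class = grid$class,
    total_c = grid$total_c,
    total_db = grid$total_db,
    total_oh = grid$total_oh,
    formula = vapply(sp, `[[`, character(1), "formula"),
    neutral_mass = vapply(sp, `[[`, numeric(1), "neutral_mass"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$label))
  rownames(out) <- NULL
  out
}

#' Peak-matching configuration
#'
#' @param tol_ppm mass tolerance in parts per million (inclusive boundary).
#' @param polarity `"positive"` or `"negative"`; only classes detected in this
#'   polarity are searched.
#' @param adducts optional named character vector overriding the per-class
#'   default adduct (names are class codes).
#' @return a list of class `match_config`.
#' @export
match_config <- function(tol_ppm = 3, polarity = c("negative", "positive"),
                         adducts = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(tol_ppm > 0)
  structure(list(tol_ppm = tol_ppm, polarity = polarity, adducts = adducts),
            class = "match_config")
}

#' Annotate a species database with adduct m/z for one polarity
#'
#' Keeps the classes detected in `config$polarity` and adds their adduct and
#' theoretical m/z columns.
#'
#' @param database output of [build_species_database()].
#' @param config a [match_config()].
#' @return the database subset with `adduct` and `mz` columns appended.
#' @export
annotate_adducts <- function(database, config = match_config()) {
  rows <- .class_row(database$class)
  keep <- rows$polarity == config$polarity
  db <- database[keep, , drop = FALSE]
  adduct <- rows$adduct[keep]
  if (!is.null(config$adducts)) {
    override <- config$adducts[db$class]
    adduct <- ifelse(is.na(override), adduct, override)
  }
  db$adduct <- adduct
  db$mz <- adduct_mz(db$neutral_mass, adduct)
  rownames(db) <- NULL
  db
}

#' Match observed peaks to a species database
#'
#' A peak is assigned to a species when `|mz_obs - mz_theo| / mz_theo * 1e6`
#' is at most `tol_ppm` (inclusive).  All candidates within tolerance are
#' reported; peaks with more than one candidate are flagged ambiguous.
#'
#' @param peaks data frame with columns `mz` and `intensity`.
#' @param database adduct-annotated database ([annotate_adducts()]), or a raw
#'   database (annotated on the fly with `config`).
#' @param config a [match_config()].
#' @return a data frame of assignments: `mz_obs`, `intensity`, `label`,
#'   `class`, `adduct`, `mz_theo`, `ppm_error`, `n_candidates`, `ambiguous`.
#' @export
match_peaks <- function(peaks, database, config = match_config()) {
  empty <- data.frame(mz_obs = numeric(0), intensity = numeric(0),
                      label = character(0), class = character(0),
                      adduct = character(0), mz_theo = numeric(0),
                      ppm_error = numeric(0), n_candidates = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  if (is.null(peaks) || nrow(peaks) == 0L || is.null(database) || nrow(database) == 0L) {
    return(empty)
  }
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    stop("peaks must have mz > 0 and intensity >= 0")
  }
  if (is.null(database$mz)) database <- annotate_adducts(database, config)
  if (nrow(database) == 0L) return(empty)
  ord <- order(database$mz)
  db <- database[ord, , drop = FALSE]
  tol <- config$tol_ppm * 1e-6
  res <- vector("list", nrow(peaks))
  lo_all <- findInterval(peaks$mz * (1 - tol) - 1e-9, db$mz) + 1L
  hi_all <- findInterval(peaks$mz * (1 + tol) + 1e-9, db$mz)
  for (i in seq_len(nrow(peaks))) {
    lo <- lo_all[i]; hi <- hi_all[i]
    if (hi < lo) next
    cand <- lo:hi
    ppm <- (peaks$mz[i] - db$mz[cand]) / db$mz[cand] * 1e6
    keep <- abs(ppm) <= config$tol_ppm + 1e-12
    if (!any(keep)) next
    cand <- cand[keep]; ppm <- ppm[keep]
    res[[i]] <- data.frame(
      mz_obs = peaks$mz[i], intensity = peaks$intensity[i],
      label = db$label[cand], class = db$class[cand],
      adduct = db$adduct[cand], mz_theo = db$mz[cand],
      ppm_error = ppm, n_candidates = length(cand),
      ambiguous = length(cand) > 1L, stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quantify matched species against class internal standards
#'
#' One spiked internal standard per lipid class; amounts follow the linear
#' single-point scheme `amount = intensity / intensity(standard) *
#' spiked_amount` (response factors assumed 1).  Intensity of ambiguous peaks
#' is split equally among their candidate species.  `mol_percent_polar` is
#' computed over glycerophospholipid + sphingolipid species only; neutral
#' storage lipids (DG, TG, EE) carry `NA`.
#'
#' @param assignments output of [match_peaks()] (possibly concatenated over
#'   polarities).
#' @param standards data frame with columns `class`, `spiked_pmol`,
#'   `intensity` (the standard's own matched peak intensity).
#' @return a data frame: `label`, `class`, `amount_pmol`, `mol_percent_polar`.
#' @export
quantify_species <- function(assignments, standards) {
  stopifnot(all(c("class", "spiked_pmol", "intensity") %in% names(standards)))
  if (nrow(assignments) == 0L) {
    return(data.frame(label = character(0), class = character(0),
                      amount_pmol = numeric(0), mol_percent_polar = numeric(0)))
  }
  need <- unique(assignments$class)
  for (cl in need) {
    hit <- standards$class == cl
    if (sum(hit) == 0L) stop("no internal standard for class ", cl)
    if (sum(hit) > 1L) stop("multiple internal standards for class ", cl)
    if (standards$intensity[hit] <= 0) {
      stop("internal standard for class ", cl, " has zero intensity")
    }
  }
  # equal split of ambiguous peak intensity among isobaric candidates
  eff_int <- assignments$intensity / assignments$n_candidates
  std_int <- standards$intensity[match(assignments$class, standards$class)]
  std_amt <- standards$spiked_pmol[match(assignments$class, standards$class)]
  amount <- eff_int / std_int * std_amt
  agg <- stats::aggregate(amount,
                          by = list(label = assignments$label,
                                    class = assignments$class), FUN = sum)
  names(agg)[3L] <- "amount_pmol"
  polar <- .class_row(agg$class)$polar
  total_polar <- sum(agg$amount_pmol[polar])
  agg$mol_percent_polar <- ifelse(polar, 100 * agg$amount_pmol / total_polar, NA_real_)
  agg <- agg[order(agg$class, agg$label), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Class-level and within-class composition profiles
#'
#' @param quant output of [quantify_species()].
#' @return a list with `class_profile` (class, mol_percent over polar classes)
#'   and `species_profile` (label, class, within-class mol%).
#' @export
class_profiles <- function(quant) {
  stopifnot(nrow(quant) > 0)
  if (all(quant$amount_pmol == 0)) stop("all species amounts are zero")
  polar <- quant[.class_row(quant$class)$polar, , drop = FALSE]
  cls <- stats::aggregate(polar$amount_pmol, by = list(class = polar$class), FUN = sum)
  names(cls)[2L] <- "amount_pmol"
  cls$mol_percent <- 100 * cls$amount_pmol / sum(cls$amount_pmol)
  within <- do.call(rbind, lapply(split(polar, polar$class), function(d) {
    d$within_class_percent <- 100 * d$amount_pmol / sum(d$amount_pmol)
    d[, c("label", "class", "within_class_percent")]
  }))
  rownames(within) <- NULL
  list(class_profile = cls[, c("class", "mol_percent")],
       species_profile = within)
}
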