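# Comparative transmembrane-helix (TMH) statistics across ortholog groups:
# a hydropathy stand-in predictor, median-based length quality filter,
# single-span ortholog selection, Wilcoxon rank-sum comparisons and residue
# class composition.

# Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Sliding-window hydropathy TMH prediction
#'
#' A simple deterministic stand-in for profile-HMM predictors, used to run the
#' comparative pipeline on synthetic proteomes: window-averaged Kyte-Doolittle
#' hydropathy is assigned to the window centre residue, runs of centres at or
#' above `threshold` (merged across gaps shorter than 3 residues) are reported
#' as helix segments.  External predictor output can be substituted through
#' the TMH annotation table interface instead.
#'
#' @param sequence amino-acid sequence (single string, 20-letter alphabet).
#' @param window sliding window length (odd; default 19).
#' @param threshold minimum window-mean hydropathy (default 1.6).
#' @return data frame with columns `start`, `end`, `length` (1-based
#'   inclusive residue coordinates); zero rows when no helix is found.
#' @export
predict_tmh_hydropathy <- function(sequence, window = 19L, threshold = 1.6) {
  stopifnot(length(sequence) == 1L, window %% 2L == 1L, window >= 3L)
  aa <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(aa), names(.KD_SCALE))
  if (length(bad)) stop("non-amino-acid characters in sequence: ",
                        paste(bad, collapse = ", "))
  n <- length(aa)
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  if (n < window) return(empty)
  s <- .KD_SCALE[aa]
  cs <- cumsum(c(0, s))
  win_mean <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  half <- (window - 1L) %/% 2L
  centre <- (1L + half):(n - half)       # centre residue of each window
  hot <- win_mean >= threshold
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- data.frame(start = centre[starts[r$values]], end = centre[ends[r$values]])
  # merge segments separated by fewer than 3 residues
  if (nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (i in 2L:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$start[i] - last$end < 3L + 1L) {
        keep[[length(keep)]]$end <- seg$end[i]
      } else {
        keep[[length(keep) + 1L]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }
  seg$length <- seg$end - seg$start + 1L
  rownames(seg) <- NULL
  seg
}

#' Predict TMHs for a set of proteins
#'
#' Runs [predict_tmh_hydropathy()] over a named set of sequences and stacks
#' the segments into an annotation table.
#'
#' @param sequences named character vector (protein_id -> sequence).
#' @param species optional named vector mapping protein_id to species id,
#'   copied into the output.
#' @inheritParams predict_tmh_hydropathy
#' @return data frame: `protein_id`, (`species`), `start`, `end`, `length`.
#' @export
predict_tmh_table <- function(sequences, species = NULL, window = 19L,
                              threshold = 1.6) {
  rows <- lapply(names(sequences), function(pid) {
    seg <- predict_tmh_hydropathy(sequences[[pid]], window, threshold)
    if (nrow(seg) == 0L) return(NULL)
    seg$protein_id <- pid
    seg
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[, c("protein_id", "start", "end", "length")]
  if (!is.null(species)) out$species <- unname(species[out$protein_id])
  rownames(out) <- NULL
  out
}

#' Median-based TMH length filter
#'
#' Computes the median helix length `m` over the whole segment set (pooled
#' across species) and discards segments whose length differs from `m` by at
#' least `ceiling(median_fraction * m)` (inclusive discard boundary; with the
#' canonical median of 23 aa and fraction 0.5 the cutoff is 12 aa).
#'
#' @param segments data frame with a `length` column (plus any id columns,
#'   preserved).
#' @param median_fraction fraction of the median defining the discard cutoff
#'   (default 0.5).
#' @return the kept subset, with attributes `median_length` and `cutoff`.
#' @export
filter_by_median <- function(segments, median_fraction = 0.5) {
  stopifnot(nrow(segments) >= 1L, median_fraction > 0, median_fraction < 1)
  m <- stats::median(segments$length)
  cutoff <- tmh_filter_cutoff(m, median_fraction)
  kept <- segments[abs(segments$length - m) < cutoff, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "median_length") <- m
  attr(kept, "cutoff") <- cutoff
  kept
}

#' Discard cutoff of the median length filter
#'
#' @param median_length median TMH length in residues.
#' @param median_fraction fraction of the median (default 0.5).
#' @return smallest integer at least `median_fraction * median_length`;
#'   segments deviating by at least this many residues are discarded.
#' @examples
#' tmh_filter_cutoff(23)  # 12
#' @export
tmh_filter_cutoff <- function(median_length, median_fraction = 0.5) {
  as.integer(ceiling(median_fraction * median_length))
}

#' Select ortholog groups whose reference member is single-span
#'
#' @param groups data frame with columns `group_id`, `species`, `protein_id`
#'   (one row per member; 1:1:1:1 groups).
#' @param annotations data frame of kept TMH segments with columns
#'   `protein_id`, `start`, `end`, `length`.
#' @param reference_species species id whose member must have exactly one
#'   kept helix.
#' @return the subset of `groups` (all members) for selected groups.
#' @export
single_span_orthologs <- function(groups, annotations, reference_species) {
  stopifnot(all(c("group_id", "species", "protein_id") %in% names(groups)))
  ref <- groups[groups$species == reference_species, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference species not present in groups")
  missing <- setdiff(groups$protein_id, unique(annotations$protein_id))
  counts <- table(annotations$protein_id)
  n_ref <- as.integer(counts[ref$protein_id])
  n_ref[is.na(n_ref)] <- 0L
  if (length(missing)) {
    # proteins absent from the annotation table are treated as zero-helix;
    # flag reference members we cannot score
    unscored <- intersect(missing, ref$protein_id)
    if (length(unscored)) {
      warning(length(unscored), " reference protein(s) without annotations treated as 0 helices")
    }
  }
  sel <- ref$group_id[n_ref == 1L]
  out <- groups[groups$group_id %in% sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum comparison of TMH lengths between two species
#'
#' Two-sided Wilcoxon rank-sum test on kept single-span helix lengths.  The
#' exact null distribution is used for combined sample sizes up to 25 when the
#' data are tie-free; otherwise the normal approximation with tie-corrected
#' variance (no continuity correction) is used.
#'
#' @param lengths_a,lengths_b numeric vectors of helix lengths.
#' @param exact_max combined sample size up to which the exact null is used
#'   (default 25).
#' @return a list: `statistic` (Mann-Whitney U of sample a), `p_value`,
#'   `method`, `median_a`, `median_b`.
#' @export
length_comparison <- function(lengths_a, lengths_b, exact_max = 25L) {
  if (length(lengths_a) < 2L || length(lengths_b) < 2L) {
    stop("need at least two observations per species")
  }
  ties <- anyDuplicated(c(lengths_a, lengths_b)) > 0L
  use_exact <- (length(lengths_a) + length(lengths_b)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    lengths_a, lengths_b, alternative = "two.sided",
    exact = use_exact, correct = FALSE
  ))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation (tie-corrected)",
       median_a = stats::median(lengths_a), median_b = stats::median(lengths_b))
}

#' Per-group TMH count differences relative to a reference species
#'
#' @param groups ortholog table (`group_id`, `species`, `protein_id`).
#' @param annotations kept TMH segments (`protein_id`, ...); counts are taken
#'   after filtering.
#' @param reference_species reference species id.
#' @return data frame: `group_id`, `species`, `count`, `ref_count`, `diff`
#'   (count minus reference count), for non-reference species.
#' @export
count_difference_distribution <- function(groups, annotations, reference_species) {
  counts <- table(annotations$protein_id)
  cnt <- function(p) {
    v <- as.integer(counts[p]); v[is.na(v)] <- 0L; v
  }
  ref <- groups[groups$species == reference_species, c("group_id", "protein_id")]
  if (nrow(ref) == 0L) stop("reference species not present in groups")
  ref$ref_count <- cnt(ref$protein_id)
  oth <- groups[groups$species != reference_species, , drop = FALSE]
  oth$count <- cnt(oth$protein_id)
  oth$ref_count <- ref$ref_count[match(oth$group_id, ref$group_id)]
  oth$diff <- oth$count - oth$ref_count
  out <- oth[, c("group_id", "species", "count", "ref_count", "diff")]
  rownames(out) <- NULL
  out
}

#' Default residue class table
#'
#' Maps every amino acid to one of four classes: small non-polar
#' (G, A, S, C, P), large non-polar (V, L, I, M, F, W, Y), polar (N, Q, T, H)
#' and charged (D, E, K, R).
#'
#' @return named character vector, residue -> class.
#' @export
residue_classes <- function() {
  c(G = "small_nonpolar", A = "small_nonpolar", S = "small_nonpolar",
    C = "small_nonpolar", P = "small_nonpolar",
    V = "large_nonpolar", L = "large_nonpolar", I = "large_nonpolar",
    M = "large_nonpolar", F = "large_nonpolar", W = "large_nonpolar",
    Y = "large_nonpolar",
    N = "polar", Q = "polar", T = "polar", H = "polar",
    D = "charged", E = "charged", K = "charged", R = "charged")
}

#' Residue-class composition of TMH segments
#'
#' @param segments data frame with `protein_id`, `start`, `end` and a
#'   `species` column.
#' @param sequences named character vector of protein sequences
#'   (`protein_id` -> sequence).
#' @param class_table named vector mapping each residue to a class
#'   (default [residue_classes()]).
#' @return data frame: `species`, `class`, `fraction`; fractions sum to 1 per
#'   species.
#' @export
residue_class_composition <- function(segments, sequences,
                                      class_table = residue_classes()) {
  stopifnot(all(c("protein_id", "start", "end", "species") %in% names(segments)))
  res_by_species <- list()
  for (i in seq_len(nrow(segments))) {
    seq <- sequences[[segments$protein_id[i]]]
    if (is.null(seq) || is.na(seq)) stop("missing sequence for ", segments$protein_id[i])
    aa <- strsplit(substr(seq, segments$start[i], segments$end[i]), "")[[1L]]
    sp <- segments$species[i]
    res_by_species[[sp]] <- c(res_by_species[[sp]], aa)
  }
  out <- do.call(rbind, lapply(names(res_by_species), function(sp) {
    aa <- res_by_species[[sp]]
    bad <- setdiff(unique(aa), names(class_table))
    if (length(bad)) stop("residues absent from class table: ",
                          paste(bad, collapse = ", "))
    cl <- factor(class_table[aa], levels = sort(unique(class_table)))
    tab <- table(cl) / length(aa)
    data.frame(species = sp, class = names(tab),
               fraction = as.numeric(tab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
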