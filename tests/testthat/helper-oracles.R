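# Independent oracles, coded separately from the package internals.

# --- brute-force monoisotopic mass from a molecular formula string ----------
# Own copy of the monoisotopic mass table (IUPAC), parsed and summed by
# repeated addition; deliberately naive.
ORACLE_MASSES <- list(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, Cl = 34.96885271,
  D = 2.0141017780, C13 = 13.0033548378
)

# Handles Hill-notation formulas over single-letter elements (C, H, N, O, P,
# S) plus Na/Cl/D, e.g. "C42H82NO8P".
oracle_formula_mass <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("(Na|Cl|[CHNOPSD])([0-9]*)", formula))[[1L]]
  stopifnot(sum(nchar(toks)) == nchar(formula))
  total <- 0
  for (tok in toks) {
    sym <- gsub("[0-9]", "", tok)
    cnt <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(ORACLE_MASSES)) stop("oracle: unknown element ", sym)
    for (k in seq_len(n)) total <- total + ORACLE_MASSES[[sym]]
  }
  total
}

# --- exact Wilcoxon rank-sum p-value by full enumeration --------------------
# Enumerates every assignment of the pooled observations to group A, computes
# the Mann-Whitney U for each, and returns the two-sided p-value as
# min(1, 2 * min(P(U <= u), P(U >= u))).
oracle_wilcoxon_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2L, function(i) sum(r[i]) - m * (m + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# --- tiny helpers -----------------------------------------------------------
circle_frame <- function(r = 10, n = 256, centre = c(0, 0)) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cbind(centre[1L] + r * cos(phi), centre[2L] + r * sin(phi))
}
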