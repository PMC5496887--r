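# Shared builders and independent oracles for the test suite. Everything
# is generated in code; no fixture files.

# A tiny hand-checkable proteome. K positions:
#   P1: 11 (center of the 21-mer), P2: 5 and 12, P3: none, P4: 1, 12, 22.
toy_proteome <- function() {
  c(P1 = "AAAAAAAAAAKAAAAAAAAAA",
    P2 = "CCCCKCCCCCCKCCCCCCCCCC",
    P3 = "DDDDDDDDDDDDDDDDDDDDD",
    P4 = "KAAAAAAAAAAKAAAAAAAAAK")
}

toy_sites <- function(protein_id, position) {
  data.frame(protein_id = protein_id, position = position,
             stringsAsFactors = FALSE)
}

# Random protein of given length with lysines forced at `k_at`.
random_protein <- function(len, k_at = integer(0), seed = 1) {
  withr::with_seed(seed, {
    s <- sample(aa_alphabet(), len, replace = TRUE)
    s[k_at] <- "K"
    paste0(s, collapse = "")
  })
}

# Exhaustive-enumeration hypergeometric oracle: the first K of N proteins
# carry the term; enumerate all C(N, n) draws and count tail events.
# Independent of stats::phyper by construction.
enum_hyper <- function(k, n, K, N) {
  if (n == 0) {
    overlaps <- 0L
  } else {
    draws <- utils::combn(N, n)
    overlaps <- apply(draws, 2, function(d) sum(d <= K))
  }
  c(p_over = mean(overlaps >= k), p_under = mean(overlaps <= k))
}

# Direct textbook formula for the Yates-corrected 2x2 chi-squared,
# independent of stats::chisq.test. Doubles throughout: the denominator
# product overflows 32-bit integers already at moderate counts.
yates_chi2_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  T <- a + b + c + d
  num <- abs(a * d - b * c) - T / 2
  if (num < 0) num <- 0
  stat <- T * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

# Direct-formula confusion-matrix oracle for Sn/Sp/MCC.
metrics_oracle <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  list(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fn * fp) / den)
}

# Scaled-down synthetic config for fast unit tests.
small_config <- function(seed = 1, ...) {
  synth_config(n_proteins = 120, protein_length = c(60, 120),
               n_substrate_proteins = 15, sites_per_substrate = c(1, 2),
               n_terms_per_source = 10, n_signal_terms = 4,
               seed = seed, ...)
}

# Small site_set directly from windows (bypasses a proteome).
windows_site_set <- function(windows, protein_id = NULL, label = "positive",
                             L = NULL) {
  L <- L %||% unique(nchar(windows))
  stopifnot(length(L) == 1)
  df <- data.frame(
    protein_id = protein_id %||% sprintf("W%03d", seq_along(windows)),
    position = rep((L + 1) %/% 2, length(windows)),
    window = windows, label = rep(label, length.out = length(windows)),
    stringsAsFactors = FALSE)
  deacpred:::new_site_set(df, L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
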