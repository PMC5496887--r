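# Internal helpers shared across modules.

#' The 20-letter amino-acid alphabet used for one-hot encoding
#'
#' Standard one-letter codes in alphabetical order
#' (A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y).
#' This order defines the layout of every 20-bit sequence block.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity / non-standard codes tolerated in sequences; they encode as
# all-zero blocks and are excluded from positional frequencies.
.ambiguity_codes <- c("X", "B", "Z", "U", "O", "J", "*")

# Deterministic child-seed derivation: a fixed affine rule modulo a large
# prime, so member/repeat seeds are reproducible across platforms. All
# arithmetic stays below 2^53, hence exact in doubles; the result is a
# positive integer below 2^31.
derive_seed <- function(master_seed, index) {
  m <- as.double(master_seed) %% 2147483647
  as.integer(((m * 48271 + as.double(index) * 10007) %% 2147483629) + 1)
}

# Round half away from zero (the convention behind printed percentages such
# as 30.80); base round() is half-to-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_percent <- function(x) sprintf("%.2f%%", round_half_up(x, 2))

# Light TSV wrappers so every table in the package goes through one door.
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
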