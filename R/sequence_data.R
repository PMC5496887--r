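# Proteome and site-window handling: reading FASTA proteomes, extracting
# lysine-centered windows, building the background site universe, filtering
# sequence redundancy and summarising positional residue frequencies.

#' Read a proteome from a FASTA file
#'
#' Reads a multi-record protein FASTA and returns a named character vector
#' of uppercase sequences. The record id is the description line up to the
#' first whitespace, following the usual Swiss-Prot/UniProt convention.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are accession ids.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate protein ids in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  as_proteome(seqs)
}

#' Coerce a named character vector to a validated proteome
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @return The validated vector (uppercased).
#' @export
as_proteome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("proteome sequences must be named by non-empty accession ids",
         call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) stop("duplicate protein ids", call. = FALSE)
  if (any(nchar(seqs) < 1)) stop("zero-length sequence in proteome", call. = FALSE)
  toupper(seqs)
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

new_site_set <- function(df, L) {
  rownames(df) <- NULL
  structure(df, L = as.integer(L), class = c("site_set", "data.frame"))
}

#' Window length of a site set
#' @param sites A `site_set`.
#' @return Integer window length L.
#' @export
site_length <- function(sites) attr(sites, "L", exact = TRUE)

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set: %d windows of length %d (%d proteins)\n",
              nrow(x), site_length(x), length(unique(x$protein_id))))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

.check_odd_L <- function(L) {
  if (length(L) != 1 || is.na(L) || L < 1 || L %% 2 == 0) {
    stop("window length L must be a positive odd integer, got ", L,
         call. = FALSE)
  }
  as.integer(L)
}

#' Extract lysine-centered peptide windows from a proteome
#'
#' For each (protein, position) site, takes the central lysine with
#' (L-1)/2 residues of flanking sequence on both sides. Sites whose full
#' window would run past either terminus are dropped (unless `pad_char` is
#' given) and counted in the `dropped` attribute of the result.
#'
#' @param proteome Named character vector of sequences (see [read_proteome]).
#' @param sites Data frame with columns `protein_id` and `position`
#'   (1-based index of the lysine). Duplicate rows are removed with a warning.
#' @param L Odd window length (the classical choice is 21: the modified
#'   lysine plus 10 residues on each side).
#' @param label Label to assign to extracted windows: `"positive"`,
#'   `"negative"` or `"unlabeled"`.
#' @param pad_char Optional single character used to pad windows that
#'   overhang a terminus instead of dropping them. Padded positions encode
#'   as all-zero blocks when `pad_char = "X"`.
#' @return A `site_set` data frame (`protein_id`, `position`, `window`,
#'   `label`) with attributes `L` and `dropped` (count of sites removed by
#'   the terminal rule).
#' @export
extract_windows <- function(proteome, sites, L = 21, label = "positive",
                            pad_char = NULL) {
  proteome <- as_proteome(proteome)
  L <- .check_odd_L(L)
  label <- match.arg(label, c("positive", "negative", "unlabeled"))
  stopifnot(is.data.frame(sites),
            all(c("protein_id", "position") %in% names(sites)))
  sites <- data.frame(protein_id = as.character(sites$protein_id),
                      position = as.integer(sites$position),
                      stringsAsFactors = FALSE)

  dup <- duplicated(sites[c("protein_id", "position")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (protein, position) row(s) removed",
            call. = FALSE)
    sites <- sites[!dup, , drop = FALSE]
  }

  unknown <- setdiff(sites$protein_id, names(proteome))
  if (length(unknown) > 0) {
    stop("site table refers to protein id(s) absent from the proteome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  seqs <- proteome[sites$protein_id]
  central <- substring(seqs, sites$position, sites$position)
  bad <- which(central != "K")
  if (length(bad) > 0) {
    stop("site residue is not lysine at: ",
         paste(sprintf("%s:%d (%s)", sites$protein_id[bad],
                       sites$position[bad], central[bad]),
               collapse = ", "), call. = FALSE)
  }

  flank <- (L - 1L) %/% 2L
  start <- sites$position - flank
  end <- sites$position + flank
  fits <- start >= 1L & end <= nchar(seqs)

  if (!is.null(pad_char)) {
    stopifnot(is.character(pad_char), nchar(pad_char) == 1)
    left_pad <- pmax(0L, 1L - start)
    right_pad <- pmax(0L, end - nchar(seqs))
    core <- substring(seqs, pmax(start, 1L), pmin(end, nchar(seqs)))
    windows <- paste0(strrep(pad_char, left_pad), core,
                      strrep(pad_char, right_pad))
    kept <- rep(TRUE, nrow(sites))
    dropped <- 0L
  } else {
    windows <- substring(seqs, start, end)
    kept <- fits
    dropped <- sum(!fits)
    if (dropped > 0) {
      message(dropped, " site(s) dropped: full ", L,
              "-mer window does not fit inside the protein")
    }
  }

  out <- data.frame(protein_id = sites$protein_id[kept],
                    position = sites$position[kept],
                    window = windows[kept],
                    label = rep(label, sum(kept)),
                    stringsAsFactors = FALSE)
  res <- new_site_set(out, L)
  attr(res, "dropped") <- dropped
  res
}

#' Enumerate all full-window lysine sites of a background proteome
#'
#' Builds the background site universe: every lysine of every protein not in
#' `excluded_proteins` whose full L-mer window fits inside the protein.
#' Windows are labeled `"unlabeled"` and returned in deterministic order
#' (protein id, then position), so negative sampling is reproducible.
#'
#' @param proteome Named character vector of sequences.
#' @param excluded_proteins Accessions to exclude (typically the known
#'   substrate proteins, so negatives never come from positive proteins).
#' @param L Odd window length.
#' @return A `site_set` of unlabeled background windows.
#' @export
build_background <- function(proteome, excluded_proteins = character(0),
                             L = 21) {
  proteome <- as_proteome(proteome)
  L <- .check_odd_L(L)
  flank <- (L - 1L) %/% 2L
  keep_ids <- sort(setdiff(names(proteome), excluded_proteins))

  recs <- lapply(keep_ids, function(id) {
    s <- proteome[[id]]
    pos <- gregexpr("K", s, fixed = TRUE)[[1]]
    pos <- pos[pos > 0]
    pos <- pos[pos - flank >= 1 & pos + flank <= nchar(s)]
    if (length(pos) == 0) return(NULL)
    data.frame(protein_id = id, position = as.integer(pos),
               window = substring(s, pos - flank, pos + flank),
               label = "unlabeled", stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) {
    stop("background is empty: no full-window lysine site outside the ",
         "excluded proteins; cannot sample negatives", call. = FALSE)
  }
  new_site_set(do.call(rbind, recs), L)
}

#' Remove redundant windows by ungapped sequence identity
#'
#' Greedy scan in input order: a window is kept iff its ungapped identity
#' fraction (matching aligned positions / L) with every previously kept
#' window is at or below `threshold`. With the default 0.70, of any pair
#' sharing more than 70% identity only the first survives.
#'
#' @param sites A `site_set` (all windows the same length).
#' @param threshold Maximum allowed pairwise identity fraction (default 0.70).
#' @return The filtered `site_set`.
#' @export
filter_redundancy <- function(sites, threshold = 0.70) {
  stopifnot(inherits(sites, "site_set"))
  n <- nrow(sites)
  if (n <= 1) return(sites)
  L <- site_length(sites)
  mat <- matrix(unlist(strsplit(sites$window, "")), nrow = n, byrow = TRUE)
  kept <- integer(0)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in kept) {
      if (sum(mat[i, ] == mat[j, ]) / L > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  new_site_set(as.data.frame(sites)[keep, , drop = FALSE], L)
}

#' Per-position amino-acid frequencies of a site set
#'
#' For each window position, the frequency of each of the 20 standard
#' residues among the windows, ignoring ambiguity codes (excluded from both
#' numerator and denominator at that position). The central column is all
#' lysine by construction. This is the matrix behind sequence-logo displays.
#'
#' @param sites A non-empty `site_set`.
#' @return A 20 x L numeric matrix; rows named by residue, columns by offset
#'   from the central lysine (-flank .. +flank).
#' @export
position_frequency <- function(sites) {
  stopifnot(inherits(sites, "site_set"))
  if (nrow(sites) == 0) stop("cannot compute frequencies of an empty site set",
                             call. = FALSE)
  L <- site_length(sites)
  flank <- (L - 1L) %/% 2L
  aa <- aa_alphabet()
  mat <- matrix(unlist(strsplit(sites$window, "")), ncol = L, byrow = TRUE)
  freq <- matrix(0, nrow = 20, ncol = L,
                 dimnames = list(aa, as.character(seq(-flank, flank))))
  for (p in seq_len(L)) {
    col <- mat[, p]
    col <- col[col %in% aa]
    if (length(col) > 0) {
      tab <- table(factor(col, levels = aa))
      freq[, p] <- as.numeric(tab) / length(col)
    }
  }
  freq
}

#' Read a site table (protein id + 1-based lysine position) from TSV
#'
#' @param path Headered TSV with columns `protein_id` and `position`.
#' @return Data frame with character `protein_id` and integer `position`.
#' @export
read_site_table <- function(path) {
  df <- read_tsv_strict(path, c("protein_id", "position"))
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos)) stop("non-integer position value in ", path, call. = FALSE)
  data.frame(protein_id = as.character(df$protein_id), position = pos,
             stringsAsFactors = FALSE)
}

#' Write a site set as TSV
#'
#' @param sites A `site_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_site_set <- function(sites, path) {
  write_tsv(as.data.frame(sites)[c("protein_id", "position", "window",
                                   "label")], path)
}

#' Read a site set written by [write_site_set]
#'
#' @param path TSV with columns `protein_id`, `position`, `window`, `label`.
#' @return A `site_set`.
#' @export
read_site_set <- function(path) {
  df <- read_tsv_strict(path, c("protein_id", "position", "window", "label"))
  if (nrow(df) == 0) stop("empty site set file: ", path, call. = FALSE)
  Ls <- unique(nchar(df$window))
  if (length(Ls) != 1) stop("windows of mixed length in ", path, call. = FALSE)
  df$position <- as.integer(df$position)
  new_site_set(df, Ls)
}
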