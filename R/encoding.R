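# Binary feature encoding: a lysine-centered window plus a feature space
# becomes a fixed-length 0/1 vector — position-major 20-bit one-hot blocks
# over the alphabet, then one presence bit per selected (source, term).

# Precompute, per selected feature, the set of proteins carrying it.
.carrier_sets <- function(space, annotations) {
  if (nrow(space$selected) == 0) return(list())
  stopifnot(inherits(annotations, "annotation_table"))
  key <- paste(annotations$source, annotations$term_id, sep = "\r")
  want <- paste(space$selected$source, space$selected$term, sep = "\r")
  idx <- split(annotations$protein_id, key)
  lapply(want, function(w) unique(idx[[w]] %||% character(0)))
}

#' Encode a set of site windows as a binary sample matrix
#'
#' Row order follows site order. The first `20*L` columns (when the space
#' includes sequence bits) are position-major one-hot blocks over
#' [aa_alphabet()]; ambiguity codes (X, B, Z, U, O) give an all-zero block.
#' The remaining columns are 1 iff the site's parent protein carries the
#' corresponding selected term. All sites of one protein therefore share
#' their functional bits — the reason evaluation must split at protein
#' level.
#'
#' @param sites A `site_set` with window length equal to `space$L`.
#' @param annotations An `annotation_table` covering all sources in the
#'   space (proteins absent from it get all-zero functional bits).
#' @param space A `feature_space`.
#' @param require_labels If TRUE (training use), any `unlabeled` site is an
#'   error; labels are mapped positive -> +1, negative -> -1.
#' @return List of class `sample_matrix`: `x` (numeric 0/1 matrix, one row
#'   per site), `y` (+1/-1 vector, NA for unlabeled when allowed),
#'   `feature_space`, and the `protein_id`/`position` row metadata.
#' @export
encode_set <- function(sites, annotations, space, require_labels = FALSE) {
  stopifnot(inherits(sites, "site_set"), inherits(space, "feature_space"))
  L <- space$L
  if (nrow(sites) > 0 && site_length(sites) != L) {
    stop("window length mismatch: sites have L=", site_length(sites),
         " but feature space expects L=", L, call. = FALSE)
  }
  if (require_labels && any(sites$label == "unlabeled")) {
    stop("training set contains unlabeled sites", call. = FALSE)
  }
  n <- nrow(sites)
  seq_dim <- if (space$include_seq) 20L * L else 0L
  x <- matrix(0, nrow = n, ncol = space$dimension)

  if (n > 0 && space$include_seq) {
    chars <- matrix(unlist(strsplit(sites$window, "")), nrow = n, byrow = TRUE)
    aaidx <- match(chars, aa_alphabet())  # NA for ambiguity codes
    pos <- matrix(rep(seq_len(L), each = n), nrow = n)
    ok <- !is.na(aaidx)
    x[cbind(row(chars)[ok], (pos[ok] - 1L) * 20L + aaidx[ok])] <- 1
  }
  if (n > 0 && nrow(space$selected) > 0) {
    carriers <- .carrier_sets(space, annotations)
    for (j in seq_along(carriers)) {
      x[sites$protein_id %in% carriers[[j]], seq_dim + j] <- 1
    }
  }
  y <- ifelse(sites$label == "positive", 1,
              ifelse(sites$label == "negative", -1, NA_real_))
  structure(list(x = x, y = y, feature_space = space,
                 protein_id = sites$protein_id, position = sites$position),
            class = "sample_matrix")
}

#' Encode a single site window
#'
#' Convenience wrapper around [encode_set] for one site.
#'
#' @param site A one-row `site_set` (or any `site_set`; the first row is
#'   used).
#' @param annotations An `annotation_table`.
#' @param space A `feature_space`.
#' @return Numeric 0/1 vector of length `space$dimension`.
#' @export
encode_window <- function(site, annotations, space) {
  stopifnot(inherits(site, "site_set"), nrow(site) >= 1)
  first <- new_site_set(as.data.frame(site)[1, , drop = FALSE],
                        site_length(site))
  encode_set(first, annotations, space)$x[1, ]
}

#' Dump an encoded matrix as a headered TSV (debugging aid)
#'
#' @param m A `sample_matrix` from [encode_set].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_matrix <- function(m, path) {
  stopifnot(inherits(m, "sample_matrix"))
  df <- data.frame(protein_id = m$protein_id, position = m$position,
                   stringsAsFactors = FALSE)
  bits <- as.data.frame(m$x)
  names(bits) <- paste0("b", seq_len(ncol(bits)))
  write_tsv(cbind(df, bits), path)
}
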