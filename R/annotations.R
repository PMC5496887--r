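# Functional annotations: loading per-source term tables (GO BP/CC/MF,
# protein domains, protein-protein interaction partners), hypergeometric
# over/under-representation testing against a background proteome, and
# selection of the terms that become binary classifier features.

.annotation_sources <- c("BP", "CC", "MF", "DOMAIN", "PPI")

#' Coerce a (protein, source, term) table to a validated annotation table
#'
#' The package represents all annotation sources in one long-format data
#' frame with columns `protein_id`, `source` and `term_id`; a source is one
#' of `BP`, `CC`, `MF` (Gene Ontology namespaces), `DOMAIN` (e.g. Pfam) or
#' `PPI` (interaction partners, where the term id is the partner accession).
#' Proteins may be absent entirely, meaning they carry no annotation.
#'
#' @param df Data frame with columns `protein_id`, `source`, `term_id`.
#' @return The validated, deduplicated table with class `annotation_table`.
#' @export
as_annotation_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("protein_id", "source", "term_id") %in% names(df)))
  df <- data.frame(protein_id = as.character(df$protein_id),
                   source = as.character(df$source),
                   term_id = as.character(df$term_id),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$source), .annotation_sources)
  if (length(bad) > 0) {
    stop("unknown annotation source(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.annotation_sources, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$term_id)) || any(!nzchar(df$protein_id))) {
    stop("empty protein or term id in annotation table", call. = FALSE)
  }
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Read an annotation TSV (`protein_id`, `source`, `term_id`)
#'
#' @param path Headered TSV path.
#' @return An `annotation_table`.
#' @export
read_annotations <- function(path) {
  as_annotation_table(read_tsv_strict(path, c("protein_id", "source",
                                              "term_id")))
}

#' Read a PPI links TSV (`protein_a`, `protein_b`, `score`)
#'
#' @param path Headered TSV path, STRING-style.
#' @return Data frame with character partners and numeric scores.
#' @export
read_ppi_links <- function(path) {
  df <- read_tsv_strict(path, c("protein_a", "protein_b", "score"))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | !nzchar(as.character(df$protein_a)) |
                 !nzchar(as.character(df$protein_b)))
  if (length(bad) > 0) {
    stop("malformed PPI link row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  data.frame(protein_a = as.character(df$protein_a),
             protein_b = as.character(df$protein_b),
             score = score, stringsAsFactors = FALSE)
}

#' Convert scored interaction links into PPI annotation terms
#'
#' Each link at or above `min_score` makes the two partners terms of each
#' other: protein A carries term "B" and vice versa. The default cutoff 400
#' is the conventional medium-confidence STRING combined score.
#'
#' @param links Data frame with `protein_a`, `protein_b`, `score`
#'   (see [read_ppi_links]).
#' @param min_score Minimum link score to keep (default 400).
#' @return An `annotation_table` with source `PPI`.
#' @export
ppi_to_annotation <- function(links, min_score = 400) {
  stopifnot(is.data.frame(links),
            all(c("protein_a", "protein_b", "score") %in% names(links)))
  if (!is.numeric(links$score)) stop("PPI scores must be numeric", call. = FALSE)
  keep <- links$score >= min_score
  a <- as.character(links$protein_a[keep])
  b <- as.character(links$protein_b[keep])
  df <- data.frame(protein_id = c(a, b),
                   source = rep("PPI", 2 * length(a)),
                   term_id = c(b, a), stringsAsFactors = FALSE)
  as_annotation_table(df)
}

#' Hypergeometric over- and under-representation tail probabilities
#'
#' For a background of N proteins of which K carry a term, and a draw of n
#' positives of which k carry it: `p_over = P(X >= k)` and
#' `p_under = P(X <= k)` with X ~ Hypergeometric(N, K, n). The two tails
#' share the point mass at k, so they always sum to at least 1.
#'
#' @param k Positives carrying the term.
#' @param n Number of positives.
#' @param K Background proteins carrying the term.
#' @param N Background size.
#' @return Named numeric vector `c(p_over =, p_under =)`.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N ||
      k > K || (n - k) > (N - K)) {
    stop("invalid hypergeometric counts: need 0 <= k <= min(n, K), ",
         "n <= N, K <= N, n - k <= N - K ",
         sprintf("(got k=%s, n=%s, K=%s, N=%s)", k, n, K, N), call. = FALSE)
  }
  c(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_under = stats::phyper(k, K, N - K, n))
}

#' Test every term of one annotation source for enrichment in the positives
#'
#' Counts, for each term annotated to any background protein of the given
#' source, how many positive and background proteins carry it, and computes
#' hypergeometric over/under-representation p-values. The reported direction
#' is the smaller tail; `p_raw = min(p_over, p_under)` and `p_corrected` is
#' Bonferroni within the source (`p_raw` times the number of terms tested,
#' capped at 1).
#'
#' @param positives Character vector of positive protein accessions
#'   (must be a subset of `background`).
#' @param background Character vector of background protein accessions (the
#'   proteome universe).
#' @param table An `annotation_table`; rows of other sources are ignored
#'   when `source` is given.
#' @param source Optional single source to test; defaults to the only
#'   source present in `table` (an error if the table mixes sources).
#' @return Data frame of class `enrichment_records` with columns `source`,
#'   `term`, `k`, `n`, `K`, `N`, `direction`, `p_raw`, `p_corrected`,
#'   ordered by term id.
#' @export
enrich_terms <- function(positives, background, table, source = NULL) {
  stopifnot(inherits(table, "annotation_table"))
  positives <- unique(as.character(positives))
  background <- unique(as.character(background))
  if (length(positives) == 0) stop("empty positive protein set", call. = FALSE)
  extra <- setdiff(positives, background)
  if (length(extra) > 0) {
    stop("positives not contained in background: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(source)) {
    source <- unique(table$source)
    if (length(source) != 1) {
      stop("table contains ", length(source),
           " sources; pass `source` explicitly", call. = FALSE)
    }
  }
  ann <- table[table$source == source & table$protein_id %in% background, ,
               drop = FALSE]
  n <- length(positives)
  N <- length(background)

  if (nrow(ann) == 0) {
    out <- data.frame(source = character(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), direction = character(0),
                      p_raw = numeric(0), p_corrected = numeric(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_records", "data.frame")))
  }

  terms <- sort(unique(ann$term_id))
  Kv <- as.integer(table(factor(ann$term_id, levels = terms)))
  in_pos <- ann$protein_id %in% positives
  kv <- as.integer(table(factor(ann$term_id[in_pos], levels = terms)))

  p_over <- stats::phyper(kv - 1, Kv, N - Kv, n, lower.tail = FALSE)
  p_under <- stats::phyper(kv, Kv, N - Kv, n)
  m <- length(terms)
  p_raw <- pmin(p_over, p_under)
  out <- data.frame(source = source, term = terms, k = kv, n = n, K = Kv,
                    N = N,
                    direction = ifelse(p_over <= p_under, "over", "under"),
                    p_raw = p_raw,
                    p_corrected = pmin(1, p_raw * m),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("enrichment_records", "data.frame"))
}

#' Select significant terms as classifier features
#'
#' Keeps records with Bonferroni-corrected p below `alpha`; if more than
#' `cap` survive, keeps the `cap` with smallest corrected p, breaking ties
#' by raw p and then term id. Returned in that sorted order, which becomes
#' part of the feature-vector layout.
#'
#' @param records An `enrichment_records` data frame (see [enrich_terms]).
#' @param alpha Significance threshold on `p_corrected` (default 1e-2).
#' @param cap Maximum number of terms kept per source (default 100).
#' @return The selected subset, sorted; possibly empty.
#' @export
select_features <- function(records, alpha = 1e-2, cap = 100) {
  stopifnot(is.data.frame(records))
  sel <- records[records$p_corrected < alpha, , drop = FALSE]
  ord <- order(sel$p_corrected, sel$p_raw, sel$term)
  sel <- sel[ord, , drop = FALSE]
  if (nrow(sel) > cap) sel <- sel[seq_len(cap), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Build the feature space for a set of annotation sources
#'
#' Runs [enrich_terms] and [select_features] per requested source (in the
#' canonical order BP, CC, MF, DOMAIN, PPI) and assembles the result into a
#' `feature_space`: the ordered list of selected (source, term) pairs that,
#' together with the window length L, fixes the binary vector layout
#' 20*L sequence bits followed by one presence bit per selected term.
#'
#' @param positives Positive protein accessions.
#' @param background Background protein accessions (universe).
#' @param annotations An `annotation_table` (all sources together).
#' @param sources Annotation sources to use; default all five.
#' @param L Window length the space is built for.
#' @param alpha,cap Passed to [select_features].
#' @param include_seq Whether the 20*L one-hot sequence block is part of
#'   the space (TRUE for all standard configurations).
#' @return A `feature_space` object with fields `L`, `include_seq`,
#'   `selected` (data frame `source`, `term`) and `dimension`.
#' @export
build_feature_space <- function(positives, background, annotations,
                                sources = .annotation_sources, L = 21,
                                alpha = 1e-2, cap = 100,
                                include_seq = TRUE) {
  L <- .check_odd_L(L)
  sources <- intersect(.annotation_sources, sources)
  parts <- lapply(sources, function(src) {
    rec <- enrich_terms(positives, background, annotations, source = src)
    sel <- select_features(rec, alpha = alpha, cap = cap)
    if (nrow(sel) == 0) return(NULL)
    data.frame(source = sel$source, term = sel$term, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  selected <- if (length(parts) > 0) do.call(rbind, parts) else
    data.frame(source = character(0), term = character(0),
               stringsAsFactors = FALSE)
  feature_space(L, selected, include_seq = include_seq)
}

#' Construct a feature space from an explicit term list
#'
#' @param L Odd window length.
#' @param selected Data frame with columns `source` and `term`; the row
#'   order is the feature-bit order and is preserved exactly.
#' @param include_seq Whether the sequence one-hot block is included.
#' @return A `feature_space`.
#' @export
feature_space <- function(L, selected = NULL, include_seq = TRUE) {
  L <- .check_odd_L(L)
  if (is.null(selected)) {
    selected <- data.frame(source = character(0), term = character(0),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "term") %in% names(selected)))
  selected <- data.frame(source = as.character(selected$source),
                         term = as.character(selected$term),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(selected)) {
    stop("duplicate (source, term) pair in feature space", call. = FALSE)
  }
  rownames(selected) <- NULL
  structure(list(L = L, include_seq = isTRUE(include_seq),
                 selected = selected,
                 dimension = (if (isTRUE(include_seq)) 20L * L else 0L) +
                   nrow(selected)),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("feature_space: L=%d, %s%d functional term(s), dimension %d\n",
              x$L, if (x$include_seq) sprintf("20*%d sequence bits + ", x$L)
              else "", nrow(x$selected), x$dimension))
  if (nrow(x$selected) > 0) {
    print(table(factor(x$selected$source, levels = .annotation_sources)))
  }
  invisible(x)
}

#' Serialize a feature space to versioned plain text
#'
#' One `source<TAB>term` line per selected feature after a small header;
#' reloading with [read_feature_space] is bit-exact.
#'
#' @param space A `feature_space`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_space <- function(space, path) {
  stopifnot(inherits(space, "feature_space"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#deacpred_feature_space\tv1",
               paste0("L\t", space$L),
               paste0("include_seq\t", space$include_seq),
               "source\tterm"), con)
  if (nrow(space$selected) > 0) {
    writeLines(paste(space$selected$source, space$selected$term, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a feature space written by [write_feature_space]
#'
#' @param path Path to the plain-text feature-space file.
#' @return A `feature_space`.
#' @export
read_feature_space <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4 || !startsWith(lines[1], "#deacpred_feature_space")) {
    stop("not a feature_space file: ", path, call. = FALSE)
  }
  L <- as.integer(sub("^L\t", "", lines[2]))
  include_seq <- as.logical(sub("^include_seq\t", "", lines[3]))
  body <- lines[-(1:4)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    selected <- data.frame(source = vapply(parts, `[`, character(1), 1L),
                           term = vapply(parts, `[`, character(1), 2L),
                           stringsAsFactors = FALSE)
  } else {
    selected <- NULL
  }
  feature_space(L, selected, include_seq = include_seq)
}
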