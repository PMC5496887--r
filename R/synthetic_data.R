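# Synthetic fixture generator. Emits exactly the inputs the pipeline
# consumes — a proteome, a positive-site table, annotation tables, PPI
# links — plus a truth table kept apart from everything training code
# reads. The planted structure mirrors what the method exploits in real
# data: substrate proteins preferentially share designated annotation
# terms and a hub interaction partner, while the peptide sequence around
# the lysine carries little or no signal.

#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate the scale of a hand-curated deacetylation substrate
#' study: ~50 substrate proteins with one to three sites each (~100
#' positive windows) inside a 600-protein proteome, five planted signal
#' terms carried by 90% of substrates versus 5% of other proteins, a PPI
#' hub wired to substrates at the same rates, and no planted sequence
#' motif — so discriminative power comes from the functional bits, as
#' observed for deacetylase substrates.
#'
#' @param n_proteins Proteome size.
#' @param protein_length Length range `c(min, max)` (or one number).
#' @param n_substrate_proteins Number of substrate (positive) proteins.
#' @param sites_per_substrate Range of planted sites per substrate.
#' @param n_terms_per_source Background terms per source (BP, CC, MF,
#'   DOMAIN).
#' @param n_signal_terms Planted signal terms, assigned round-robin to the
#'   four term sources.
#' @param p_signal_in_substrate Probability a substrate protein carries a
#'   signal term (and a hub link).
#' @param p_signal_in_background Same probability for non-substrates.
#'   Setting it equal to `p_signal_in_substrate` (with motif strength 0)
#'   yields a null fixture with no signal by construction.
#' @param p_background_term Carry probability of every non-signal term.
#' @param seq_motif_strength Probability in `[0, 1]` that each flanking
#'   motif residue is written into a positive window (0 = no sequence
#'   signal, the default).
#' @param ppi_mean_degree Mean degree of the random noise interaction
#'   graph.
#' @param min_flank Minimum distance of a planted site from either
#'   terminus (10 keeps every planted site extractable at L = 21).
#' @param seed Integer seed; fixtures are a pure function of the config.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 600,
                         protein_length = c(200, 400),
                         n_substrate_proteins = 50,
                         sites_per_substrate = c(1, 3),
                         n_terms_per_source = 40,
                         n_signal_terms = 5,
                         p_signal_in_substrate = 0.9,
                         p_signal_in_background = 0.05,
                         p_background_term = 0.05,
                         seq_motif_strength = 0,
                         ppi_mean_degree = 2,
                         min_flank = 10,
                         seed = 1) {
  if (length(protein_length) == 1) protein_length <- rep(protein_length, 2)
  if (length(sites_per_substrate) == 1) {
    sites_per_substrate <- rep(sites_per_substrate, 2)
  }
  cfg <- list(n_proteins = as.integer(n_proteins),
              protein_length = as.integer(protein_length),
              n_substrate_proteins = as.integer(n_substrate_proteins),
              sites_per_substrate = as.integer(sites_per_substrate),
              n_terms_per_source = as.integer(n_terms_per_source),
              n_signal_terms = as.integer(n_signal_terms),
              p_signal_in_substrate = p_signal_in_substrate,
              p_signal_in_background = p_signal_in_background,
              p_background_term = p_background_term,
              seq_motif_strength = seq_motif_strength,
              ppi_mean_degree = ppi_mean_degree,
              min_flank = as.integer(min_flank),
              seed = as.integer(seed))
  if (cfg$n_substrate_proteins > cfg$n_proteins) {
    stop("n_substrate_proteins exceeds n_proteins", call. = FALSE)
  }
  probs <- c(cfg$p_signal_in_substrate, cfg$p_signal_in_background,
             cfg$p_background_term, cfg$seq_motif_strength)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$protein_length[1] < 2 * cfg$min_flank + 1) {
    stop("proteins too short to host a full window: min length must be >= ",
         2 * cfg$min_flank + 1, call. = FALSE)
  }
  if (cfg$sites_per_substrate[2] >
      (cfg$protein_length[1] - 2 * cfg$min_flank)) {
    stop("sites_per_substrate infeasible for the shortest protein",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Null-signal variant of a synthetic configuration
#'
#' Sets the substrate signal-term (and hub-link) probability equal to the
#' background probability and removes any sequence motif, so labels are
#' independent of every feature the classifier can see.
#'
#' @param config A `synth_config`.
#' @return A `synth_config` with no planted signal.
#' @export
null_config <- function(config = synth_config()) {
  config$p_signal_in_substrate <- config$p_signal_in_background
  config$seq_motif_strength <- 0
  config
}

# Mild flanking preference used when a sequence motif is requested:
# offsets relative to the central K and the residue written there.
.motif_spec <- data.frame(offset = c(-2L, -1L, 1L, 2L),
                          residue = c("A", "K", "T", "E"),
                          stringsAsFactors = FALSE)

#' Generate a complete synthetic fixture
#'
#' Returns, as in-memory objects, every input the pipeline consumes:
#' `proteome` (named character vector), `positives` (site table),
#' `annotations` (`annotation_table` for BP/CC/MF/DOMAIN), `ppi` (links
#' table, convertible with [ppi_to_annotation]), `truth` (the planted
#' positive sites) and bookkeeping (`substrate_proteins`, `signal_terms`,
#' `hub`, the echoed `config`). Identical configs give identical fixtures.
#'
#' @param config A `synth_config`.
#' @return List of class `synth_fixture`.
#' @export
generate_fixture <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, .generate_fixture_impl(config))
}

.generate_fixture_impl <- function(cfg) {
  aa <- aa_alphabet()
  ids <- sprintf("SP%04d", seq_len(cfg$n_proteins))
  lens <- sample(cfg$protein_length[1]:cfg$protein_length[2],
                 cfg$n_proteins, replace = TRUE)
  chars <- lapply(lens, function(n) sample(aa, n, replace = TRUE))

  substrates <- sort(sample(ids, cfg$n_substrate_proteins))
  is_sub <- ids %in% substrates

  # Plant lysine sites away from the termini; overwrite the residue with K.
  pos_list <- vector("list", cfg$n_proteins)
  for (i in which(is_sub)) {
    ns <- sample(cfg$sites_per_substrate[1]:cfg$sites_per_substrate[2], 1)
    eligible <- (cfg$min_flank + 1):(lens[i] - cfg$min_flank)
    pos <- sort(sample(eligible, ns))
    chars[[i]][pos] <- "K"
    if (cfg$seq_motif_strength > 0) {
      for (p in pos) {
        for (r in seq_len(nrow(.motif_spec))) {
          tgt <- p + .motif_spec$offset[r]
          if (tgt >= 1 && tgt <= lens[i] && !(tgt %in% pos) &&
              stats::runif(1) < cfg$seq_motif_strength) {
            chars[[i]][tgt] <- .motif_spec$residue[r]
          }
        }
      }
    }
    pos_list[[i]] <- pos
  }
  proteome <- vapply(chars, paste0, character(1), collapse = "")
  names(proteome) <- ids

  positives <- do.call(rbind, lapply(which(is_sub), function(i) {
    data.frame(protein_id = ids[i], position = pos_list[[i]],
               stringsAsFactors = FALSE)
  }))
  rownames(positives) <- NULL

  # Annotation terms: four term-based sources; signal terms round-robin.
  term_sources <- c("BP", "CC", "MF", "DOMAIN")
  signal_terms <- if (cfg$n_signal_terms > 0) {
    src <- term_sources[((seq_len(cfg$n_signal_terms) - 1) %% 4) + 1]
    data.frame(source = src,
               term_id = sprintf("%s_SIG%02d", src,
                                 seq_len(cfg$n_signal_terms)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), term_id = character(0),
               stringsAsFactors = FALSE)
  }
  ann <- list()
  for (s in term_sources) {
    terms <- sprintf("%s_T%03d", s, seq_len(cfg$n_terms_per_source))
    for (tm in terms) {
      carry <- stats::runif(cfg$n_proteins) < cfg$p_background_term
      if (any(carry)) {
        ann[[length(ann) + 1]] <- data.frame(protein_id = ids[carry],
                                             source = s, term_id = tm,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  for (r in seq_len(nrow(signal_terms))) {
    p <- ifelse(is_sub, cfg$p_signal_in_substrate,
                cfg$p_signal_in_background)
    carry <- stats::runif(cfg$n_proteins) < p
    if (any(carry)) {
      ann[[length(ann) + 1]] <- data.frame(protein_id = ids[carry],
                                           source = signal_terms$source[r],
                                           term_id = signal_terms$term_id[r],
                                           stringsAsFactors = FALSE)
    }
  }
  annotations <- as_annotation_table(do.call(rbind, ann))

  # PPI: substrates attach to a designated non-substrate hub protein with
  # the signal probability (background proteins with the background
  # probability), on top of a sparse random noise graph.
  hub <- sample(setdiff(ids, substrates), 1)
  p_link <- ifelse(is_sub, cfg$p_signal_in_substrate,
                   cfg$p_signal_in_background)
  linked <- ids[stats::runif(cfg$n_proteins) < p_link & ids != hub]
  hub_links <- if (length(linked) > 0) {
    data.frame(protein_a = linked, protein_b = hub, score = 900,
               stringsAsFactors = FALSE)
  } else NULL
  n_noise <- round(cfg$n_proteins * cfg$ppi_mean_degree / 2)
  noise <- if (n_noise > 0) {
    a <- sample(ids, n_noise, replace = TRUE)
    b <- sample(ids, n_noise, replace = TRUE)
    keep <- a != b
    data.frame(protein_a = a[keep], protein_b = b[keep],
               score = round(stats::runif(sum(keep), 150, 999)),
               stringsAsFactors = FALSE)
  } else NULL
  ppi <- rbind(hub_links, noise)
  rownames(ppi) <- NULL

  structure(list(proteome = proteome, positives = positives,
                 annotations = annotations, ppi = ppi,
                 truth = positives,
                 substrate_proteins = substrates,
                 signal_terms = signal_terms, hub = hub,
                 config = cfg),
            class = "synth_fixture")
}

#' @export
print.synth_fixture <- function(x, ...) {
  cat(sprintf(paste0("synth_fixture: %d proteins (%d substrates, %d planted",
                     " sites), %d annotation rows, %d PPI links, hub %s\n"),
              length(x$proteome), length(x$substrate_proteins),
              nrow(x$positives), nrow(x$annotations), nrow(x$ppi), x$hub))
  invisible(x)
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Produces `proteome.fasta`, `positives.tsv`, `annotations.tsv`,
#' `ppi_links.tsv` and, under a separate `truth/` subdirectory that no
#' training code path reads, `truth.tsv`.
#'
#' @param fixture A `synth_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synth_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome(fixture$proteome, file.path(dir, "proteome.fasta"))
  write_tsv(fixture$positives, file.path(dir, "positives.tsv"))
  ann <- as.data.frame(fixture$annotations)
  write_tsv(ann, file.path(dir, "annotations.tsv"))
  write_tsv(fixture$ppi, file.path(dir, "ppi_links.tsv"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_tsv(fixture$truth, file.path(dir, "truth", "truth.tsv"))
  invisible(dir)
}

#' Assemble pipeline-ready objects from a fixture
#'
#' Convenience helper: extracts positive windows, builds the background
#' site set (excluding substrate proteins) and merges the term annotations
#' with the PPI-derived ones.
#'
#' @param fixture A `synth_fixture`.
#' @param L Window length (default 21).
#' @param min_score PPI score cutoff (default 400).
#' @param redundancy Identity threshold applied to the positive windows
#'   (default 0.70; `NULL` skips the filter).
#' @return List with `positives` and `background` site sets and the merged
#'   `annotations` table.
#' @export
fixture_inputs <- function(fixture, L = 21, min_score = 400,
                           redundancy = 0.70) {
  stopifnot(inherits(fixture, "synth_fixture"))
  pos <- extract_windows(fixture$proteome, fixture$positives, L = L,
                         label = "positive")
  if (!is.null(redundancy)) pos <- filter_redundancy(pos, redundancy)
  bg <- build_background(fixture$proteome,
                         excluded_proteins = unique(fixture$positives$protein_id),
                         L = L)
  ann <- as_annotation_table(rbind(
    as.data.frame(fixture$annotations),
    as.data.frame(ppi_to_annotation(fixture$ppi, min_score = min_score))))
  list(positives = pos, background = bg, annotations = ann)
}
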