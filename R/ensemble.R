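# Voting ensemble of RBF-kernel SVMs. Every member shares the positive set
# and the feature space; members differ only in their randomly resampled
# negative sets. A candidate's score is its count of positive votes, called
# a substrate when the count reaches the vote cutoff. Resampling negatives
# and voting makes proteome-scale predictions far more repeatable than any
# single model trained on one negative draw.

#' Draw a random non-redundant sample of background windows
#'
#' Visits the background sites in a seeded random order and accepts
#' greedily while pairwise ungapped identity with already-accepted windows
#' stays at or below the redundancy threshold — the same redundancy rule
#' applied to positives. Used for member negative sets and for building
#' random candidate site samples.
#'
#' @param background A `site_set` to sample from.
#' @param n Number of windows to draw (without replacement).
#' @param seed Integer seed.
#' @param redundancy Identity threshold (default 0.70); `NULL` or >= 1
#'   disables the filter.
#' @param label Label assigned to the drawn windows (default `negative`).
#' @return A `site_set` of n windows.
#' @export
draw_negatives <- function(background, n, seed, redundancy = 0.70,
                           label = "negative") {
  stopifnot(inherits(background, "site_set"))
  if (nrow(background) < n) {
    stop("background (", nrow(background),
         " sites) smaller than requested negative set (", n, ")",
         call. = FALSE)
  }
  L <- site_length(background)
  idx <- withr::with_seed(seed, sample.int(nrow(background)))
  if (is.null(redundancy) || redundancy >= 1) {
    take <- idx[seq_len(n)]
  } else {
    mat <- matrix(unlist(strsplit(background$window, "")),
                  nrow = nrow(background), byrow = TRUE)
    take <- integer(0)
    for (i in idx) {
      ok <- TRUE
      for (j in take) {
        if (sum(mat[i, ] == mat[j, ]) / L > redundancy) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        take <- c(take, i)
        if (length(take) == n) break
      }
    }
    if (length(take) < n) {
      stop("could not draw ", n, " non-redundant negatives from ",
           nrow(background), " background sites", call. = FALSE)
    }
  }
  out <- as.data.frame(background)[take, , drop = FALSE]
  out$label <- label
  new_site_set(out, L)
}

.fit_member <- function(x, y, cost, gamma) {
  if (length(unique(y)) < 2) {
    stop("degenerate single-class training set", call. = FALSE)
  }
  e1071::svm(x = x, y = factor(y, levels = c(-1, 1)),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

.member_votes <- function(members, x) {
  if (nrow(x) == 0) return(integer(0))
  votes <- integer(nrow(x))
  for (m in members) {
    votes <- votes + (as.character(stats::predict(m, x)) == "1")
  }
  votes
}

#' Train a voting ensemble of RBF-SVM classifiers
#'
#' Feature selection runs once on the full positive set (the final-model
#' regime; repeated evaluation with per-fold re-selection is the job of
#' [run_harness]). Each of the K members then draws its own negative set of
#' size equal to the positives from the background (without replacement,
#' redundancy-filtered) using a seed derived deterministically from
#' `seed`, and is fitted independently on the shared positives plus its
#' negatives.
#'
#' @param positives `site_set` of positive windows (label `positive`).
#' @param background `site_set` of background lysine windows from
#'   non-substrate proteins (see [build_background]).
#' @param annotations An `annotation_table`.
#' @param K Number of members (default 9).
#' @param cutoff Votes required for a positive call (default 5 of 9).
#' @param sources Annotation sources used as functional features.
#' @param alpha,cap Feature-selection threshold and per-source cap.
#' @param include_seq Include the one-hot sequence block (default TRUE).
#' @param seed Master seed; member seeds are derived from it by a fixed
#'   rule, so retraining with the same inputs reproduces the ensemble.
#' @param cost SVM soft-margin constant C (default 1).
#' @param gamma RBF kernel width; default `1 / dimension` of the feature
#'   vector.
#' @param redundancy Identity threshold for negative-set redundancy
#'   filtering (default 0.70; `NULL` disables).
#' @return A `voting_ensemble` object.
#' @export
train_ensemble <- function(positives, background, annotations, K = 9,
                           cutoff = 5, sources = .annotation_sources,
                           alpha = 1e-2, cap = 100, include_seq = TRUE,
                           seed = 1, cost = 1, gamma = NULL,
                           redundancy = 0.70) {
  stopifnot(inherits(positives, "site_set"), inherits(background, "site_set"))
  if (nrow(positives) == 0) stop("empty positive set", call. = FALSE)
  if (nrow(background) <= nrow(positives)) {
    stop("background must be larger than the positive set", call. = FALSE)
  }
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (cutoff < 1 || cutoff > K) {
    stop("cutoff must be in 1..K", call. = FALSE)
  }
  L <- site_length(positives)
  if (site_length(background) != L) {
    stop("positive and background window lengths differ", call. = FALSE)
  }

  universe <- unique(c(positives$protein_id, background$protein_id))
  space <- build_feature_space(unique(positives$protein_id), universe,
                               annotations, sources = sources, L = L,
                               alpha = alpha, cap = cap,
                               include_seq = include_seq)
  if (space$dimension == 0) {
    stop("feature space is empty: no sequence bits and no selected terms",
         call. = FALSE)
  }
  gamma <- gamma %||% (1 / space$dimension)

  pos_enc <- encode_set(positives, annotations, space)
  member_seeds <- vapply(seq_len(K), function(m) derive_seed(seed, m),
                         integer(1))
  members <- vector("list", K)
  negative_sets <- vector("list", K)
  for (m in seq_len(K)) {
    negs <- draw_negatives(background, nrow(positives), member_seeds[m],
                           redundancy = redundancy)
    neg_enc <- encode_set(negs, annotations, space)
    x <- rbind(pos_enc$x, neg_enc$x)
    y <- c(rep(1, nrow(positives)), rep(-1, nrow(negs)))
    members[[m]] <- .fit_member(x, y, cost = cost, gamma = gamma)
    negative_sets[[m]] <- paste(negs$protein_id, negs$position)
  }
  structure(list(members = members, K = as.integer(K),
                 cutoff = as.integer(cutoff), feature_space = space,
                 master_seed = as.integer(seed),
                 member_seeds = member_seeds,
                 negative_sets = negative_sets,
                 config = list(cost = cost, gamma = gamma, alpha = alpha,
                               cap = cap, sources = sources,
                               include_seq = include_seq,
                               redundancy = redundancy)),
            class = "voting_ensemble")
}

#' @export
print.voting_ensemble <- function(x, ...) {
  cat(sprintf(
    "voting_ensemble: %d RBF-SVM member(s), cutoff %d, L=%d, dimension %d\n",
    x$K, x$cutoff, x$feature_space$L, x$feature_space$dimension))
  invisible(x)
}

#' Predict sites with a voting ensemble
#'
#' Each member casts a vote; a site is called positive when its vote count
#' reaches the cutoff.
#'
#' @param ensemble A `voting_ensemble`.
#' @param sites `site_set` of candidate windows (same L as the ensemble).
#' @param annotations An `annotation_table`.
#' @param cutoff Override of the ensemble's vote cutoff; 0 calls everything.
#' @return Data frame `protein_id`, `position`, `window`, `votes`, `call`.
#' @export
vote_predict <- function(ensemble, sites, annotations,
                         cutoff = ensemble$cutoff) {
  stopifnot(inherits(ensemble, "voting_ensemble"), inherits(sites, "site_set"))
  if (nrow(sites) > 0 &&
      site_length(sites) != ensemble$feature_space$L) {
    stop("window length mismatch: sites have L=", site_length(sites),
         ", model expects L=", ensemble$feature_space$L, call. = FALSE)
  }
  enc <- encode_set(sites, annotations, ensemble$feature_space)
  votes <- .member_votes(ensemble$members, enc$x)
  data.frame(protein_id = sites$protein_id, position = sites$position,
             window = sites$window, votes = as.integer(votes),
             call = votes >= cutoff, stringsAsFactors = FALSE)
}

#' ROC points from sweeping the vote cutoff
#'
#' Computes (FPR, TPR) at every integer cutoff 0..K+1 on a labeled site
#' set. Cutoff 0 calls everything (1, 1); cutoff K+1 calls nothing (0, 0);
#' both rates are non-increasing in the cutoff because `votes >= c+1`
#' implies `votes >= c`.
#'
#' @param ensemble A `voting_ensemble`.
#' @param labeled_sites `site_set` containing both positive and negative
#'   labels.
#' @param annotations An `annotation_table`.
#' @return Data frame `cutoff`, `FPR`, `TPR` with K+2 rows.
#' @export
vote_roc <- function(ensemble, labeled_sites, annotations) {
  stopifnot(inherits(labeled_sites, "site_set"))
  lab <- labeled_sites$label
  if (!all(c("positive", "negative") %in% lab)) {
    stop("vote_roc needs both positive and negative labels", call. = FALSE)
  }
  pred <- vote_predict(ensemble, labeled_sites, annotations, cutoff = 0)
  cutoffs <- 0:(ensemble$K + 1L)
  tpr <- vapply(cutoffs, function(cc)
    mean(pred$votes[lab == "positive"] >= cc), numeric(1))
  fpr <- vapply(cutoffs, function(cc)
    mean(pred$votes[lab == "negative"] >= cc), numeric(1))
  data.frame(cutoff = cutoffs, FPR = fpr, TPR = tpr)
}

#' Overlap between two prediction runs on the same candidate sites
#'
#' Jaccard overlap, as a percentage, between the positively called
#' (protein, position) sets of two prediction runs over the same candidate
#' universe: `100 * |A intersect B| / |A union B|`, and 100 when both are
#' empty. This quantifies run-to-run repeatability under negative-set
#' resampling.
#'
#' @param predA,predB Prediction data frames from [vote_predict] covering
#'   identical site universes.
#' @return Percentage in `[0, 100]`.
#' @export
reproducibility_overlap <- function(predA, predB) {
  keyA <- paste(predA$protein_id, predA$position)
  keyB <- paste(predB$protein_id, predB$position)
  if (!setequal(keyA, keyB)) {
    stop("prediction runs cover different site universes", call. = FALSE)
  }
  posA <- keyA[predA$call]
  posB <- keyB[predB$call]
  u <- union(posA, posB)
  if (length(u) == 0) return(100)
  100 * length(intersect(posA, posB)) / length(u)
}

#' Save an ensemble as a model bundle directory
#'
#' Writes the feature space (versioned plain text), each member classifier,
#' and a JSON manifest (K, cutoff, seeds, configuration).
#'
#' @param ensemble A `voting_ensemble`.
#' @param dir Bundle directory (created if needed).
#' @return The directory, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "voting_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_space(ensemble$feature_space,
                      file.path(dir, "feature_space.tsv"))
  for (m in seq_len(ensemble$K)) {
    saveRDS(ensemble$members[[m]],
            file.path(dir, sprintf("member_%02d.rds", m)))
  }
  manifest <- list(format = "deacpred_model_bundle", version = 1L,
                   K = ensemble$K, cutoff = ensemble$cutoff,
                   master_seed = ensemble$master_seed,
                   member_seeds = ensemble$member_seeds,
                   negative_sets = ensemble$negative_sets,
                   config = ensemble$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model bundle written by [save_ensemble]
#'
#' @param dir Bundle directory.
#' @return A `voting_ensemble`.
#' @export
load_ensemble <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("not a model bundle: ", dir, call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(man$format, "deacpred_model_bundle")) {
    stop("unrecognized bundle format in ", mpath, call. = FALSE)
  }
  space <- read_feature_space(file.path(dir, "feature_space.tsv"))
  members <- lapply(seq_len(man$K), function(m)
    readRDS(file.path(dir, sprintf("member_%02d.rds", m))))
  negsets <- man$negative_sets
  if (is.data.frame(negsets)) negsets <- as.list(as.data.frame(t(negsets)))
  structure(list(members = members, K = as.integer(man$K),
                 cutoff = as.integer(man$cutoff), feature_space = space,
                 master_seed = as.integer(man$master_seed),
                 member_seeds = as.integer(man$member_seeds),
                 negative_sets = negsets,
                 config = man$config),
            class = "voting_ensemble")
}
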