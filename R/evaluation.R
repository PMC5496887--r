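# Evaluation: sensitivity / specificity / Matthews correlation coefficient,
# the repeated protein-level train/test harness, and the Yates-corrected
# chi-squared comparison of predicted-substrate proportions.

#' Sensitivity, specificity and Matthews correlation coefficient
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' When any margin of the confusion matrix is empty the MCC denominator is
#' zero and MCC is defined as 0; empty Sn or Sp margins are an error
#' because the ratio itself is undefined.
#'
#' @param TP,TN,FP,FN Non-negative confusion-matrix counts.
#' @return Named list with `Sn`, `Sp`, `MCC`.
#' @export
compute_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || anyNA(counts)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  if (TP + FN == 0) stop("Sn undefined: no positive examples (TP+FN = 0)",
                         call. = FALSE)
  if (TN + FP == 0) stop("Sp undefined: no negative examples (TN+FP = 0)",
                         call. = FALSE)
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  denom <- sqrt((TP + FN) * (TN + FP) * (TP + FP) * (TN + FN))
  list(Sn = TP / (TP + FN),
       Sp = TN / (TN + FP),
       MCC = if (denom == 0) 0 else (TP * TN - FN * FP) / denom)
}

#' Split a site set into train and test partitions at protein level
#'
#' Proteins (not sites) are shuffled with the seed and partitioned so that
#' every site of a protein lands in exactly one partition. Sites of one
#' protein share all functional-annotation bits, so a site-level split
#' would leak protein identity into the test fold and overestimate
#' performance.
#'
#' @param sites A `site_set` with at least two distinct proteins.
#' @param fraction Fraction of proteins assigned to training (default 4/5).
#'   The train count is `round(fraction * n_proteins)`, clamped so both
#'   partitions are non-empty; the remainder goes to test.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` site sets.
#' @export
protein_level_split <- function(sites, fraction = 0.8, seed = 1) {
  stopifnot(inherits(sites, "site_set"))
  proteins <- unique(sites$protein_id)
  if (length(proteins) < 2) {
    stop("protein-level split needs at least 2 distinct proteins",
         call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(proteins))
  n_train <- round(fraction * length(proteins))
  n_train <- min(max(n_train, 1L), length(proteins) - 1L)
  train_ids <- shuffled[seq_len(n_train)]
  L <- site_length(sites)
  df <- as.data.frame(sites)
  list(train = new_site_set(df[df$protein_id %in% train_ids, , drop = FALSE],
                            L),
       test = new_site_set(df[!df$protein_id %in% train_ids, , drop = FALSE],
                           L))
}

.bind_site_sets <- function(a, b) {
  new_site_set(rbind(as.data.frame(a), as.data.frame(b)), site_length(a))
}

#' Repeated leakage-safe evaluation of the classifier
#'
#' Per repeat: draw a fresh negative set (1:1 with the positives,
#' redundancy-filtered, from non-substrate background proteins), split the
#' positives and negatives 4/5 - 1/5 at protein level, re-select functional
#' features using only the training-fold positive proteins, encode, fit one
#' RBF-SVM, and score the held-out fold. Means and standard errors over the
#' repeats are reported, matching the usual repeated-subsampling protocol
#' for site predictors.
#'
#' Per-fold feature re-selection is what keeps the harness honest: selecting
#' terms on all positives lets annotation profiles of test proteins steer
#' the feature space, inflating apparent accuracy. `select_on = "all"`
#' exists only to demonstrate that inflation.
#'
#' @param positives `site_set` of positive windows.
#' @param background `site_set` of background windows (negative pool).
#' @param annotations An `annotation_table`.
#' @param feature_groups Subset of `c("seq", "BP", "CC", "MF", "DOMAIN",
#'   "PPI")`; must contain `seq` or at least one annotation source.
#' @param R Number of repeats (default 100).
#' @param fraction Training fraction for the protein-level split.
#' @param seed Master seed; each repeat derives its own seeds from it.
#' @param alpha,cap Feature-selection threshold and per-source cap.
#' @param cost,gamma SVM hyperparameters (gamma defaults to 1/dimension).
#' @param redundancy Negative-set redundancy threshold.
#' @param select_on `"train"` (leakage-safe, default) or `"all"`
#'   (deliberately leaky feature selection, for demonstration only).
#' @param max_retries Redraws allowed when a fold ends up single-class.
#' @return A `harness_result`: `repeats` (data frame of per-repeat Sn, Sp,
#'   MCC), `mean`, `se` (sd/sqrt(R); NA when R = 1) and the echoed config.
#' @export
run_harness <- function(positives, background, annotations,
                        feature_groups = c("seq", .annotation_sources),
                        R = 100, fraction = 0.8, seed = 1, alpha = 1e-2,
                        cap = 100, cost = 1, gamma = NULL,
                        redundancy = 0.70, select_on = c("train", "all"),
                        max_retries = 10) {
  stopifnot(inherits(positives, "site_set"), inherits(background, "site_set"))
  select_on <- match.arg(select_on)
  feature_groups <- unique(feature_groups)
  bad <- setdiff(feature_groups, c("seq", .annotation_sources))
  if (length(bad) > 0) {
    stop("unknown feature group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  include_seq <- "seq" %in% feature_groups
  sources <- intersect(.annotation_sources, feature_groups)
  if (!include_seq && length(sources) == 0) {
    stop("feature_groups must contain 'seq' or at least one annotation source",
         call. = FALSE)
  }
  L <- site_length(positives)
  if (site_length(background) != L) {
    stop("positive and background window lengths differ", call. = FALSE)
  }
  universe <- unique(c(positives$protein_id, background$protein_id))

  one_repeat <- function(r) {
    empty_space <- 0L
    for (attempt in seq_len(max_retries)) {
      rs <- derive_seed(derive_seed(seed, r), attempt)
      negs <- draw_negatives(background, nrow(positives),
                             derive_seed(rs, 1), redundancy = redundancy)
      pos_split <- protein_level_split(positives, fraction, derive_seed(rs, 2))
      neg_split <- protein_level_split(negs, fraction, derive_seed(rs, 3))
      train <- .bind_site_sets(pos_split$train, neg_split$train)
      test <- .bind_site_sets(pos_split$test, neg_split$test)
      if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
        next
      }
      sel_proteins <- if (select_on == "train") {
        unique(pos_split$train$protein_id)
      } else {
        unique(positives$protein_id)
      }
      space <- build_feature_space(sel_proteins, universe, annotations,
                                   sources = sources, L = L, alpha = alpha,
                                   cap = cap, include_seq = include_seq)
      if (space$dimension == 0) {  # nothing selected and no seq bits
        empty_space <- empty_space + 1L
        next
      }
      g <- gamma %||% (1 / space$dimension)
      tr <- encode_set(train, annotations, space, require_labels = TRUE)
      te <- encode_set(test, annotations, space, require_labels = TRUE)
      fit <- .fit_member(tr$x, tr$y, cost = cost, gamma = g)
      pred <- as.numeric(as.character(stats::predict(fit, te$x)))
      m <- compute_metrics(TP = sum(pred == 1 & te$y == 1),
                           TN = sum(pred == -1 & te$y == -1),
                           FP = sum(pred == 1 & te$y == -1),
                           FN = sum(pred == -1 & te$y == 1))
      return(c(Sn = m$Sn, Sp = m$Sp, MCC = m$MCC))
    }
    if (empty_space == max_retries) {
      stop("repeat ", r, ": feature selection returned no terms in any of ",
           max_retries, " attempts and no sequence bits were requested",
           call. = FALSE)
    }
    stop("repeat ", r, ": could not obtain two-class folds after ",
         max_retries, " redraws", call. = FALSE)
  }

  reps <- t(vapply(seq_len(R), one_repeat, numeric(3)))
  reps <- as.data.frame(reps)
  means <- vapply(reps, mean, numeric(1))
  ses <- if (R > 1) vapply(reps, stats::sd, numeric(1)) / sqrt(R) else
    c(Sn = NA_real_, Sp = NA_real_, MCC = NA_real_)
  structure(list(repeats = cbind(repeat_ = seq_len(R), reps),
                 mean = means, se = ses,
                 config = list(L = L, feature_groups = feature_groups,
                               R = R, fraction = fraction, seed = seed,
                               alpha = alpha, cap = cap, cost = cost,
                               gamma = gamma, redundancy = redundancy,
                               select_on = select_on)),
            class = "harness_result")
}

#' @export
print.harness_result <- function(x, ...) {
  cat(sprintf("harness_result: R=%d repeats, L=%d, features: %s\n",
              x$config$R, x$config$L,
              paste(x$config$feature_groups, collapse = "+")))
  for (m in c("Sn", "Sp", "MCC")) {
    cat(sprintf("  %-3s mean %.4f  se %s\n", m, x$mean[[m]],
                if (is.na(x$se[[m]])) "-" else sprintf("%.4f", x$se[[m]])))
  }
  invisible(x)
}

#' Write a harness result as TSV (one row per repeat plus a summary block)
#'
#' @param result A `harness_result`.
#' @param path Output path for the per-repeat table; a companion
#'   `<path>.summary.tsv` holds means, standard errors and the echoed
#'   configuration.
#' @return `path`, invisibly.
#' @export
write_harness_result <- function(result, path) {
  stopifnot(inherits(result, "harness_result"))
  write_tsv(result$repeats, path)
  cfg <- result$config
  summary_df <- data.frame(
    metric = c("Sn", "Sp", "MCC"),
    mean = as.numeric(result$mean[c("Sn", "Sp", "MCC")]),
    se = as.numeric(result$se[c("Sn", "Sp", "MCC")]),
    R = cfg$R, L = cfg$L,
    feature_groups = paste(cfg$feature_groups, collapse = "+"),
    seed = cfg$seed, stringsAsFactors = FALSE)
  write_tsv(summary_df, paste0(path, ".summary.tsv"))
  invisible(path)
}

#' Format a hit proportion as a percentage string
#'
#' `100 * hits / total`, rounded half away from zero to two decimals and
#' suffixed with `%` — the convention used in reported substrate
#' proportions (e.g. 5412/17572 prints as `"30.80%"`).
#'
#' @param hits,total Counts (vectorized).
#' @return Character vector like `"30.80%"`.
#' @export
format_proportion <- function(hits, total) {
  vapply(100 * hits / total, fmt_percent, character(1))
}

#' Yates-corrected chi-squared comparison of two hit proportions
#'
#' Tests whether hitsA/totalA differs from hitsB/totalB with Pearson's
#' chi-squared on the 2x2 table, with Yates' continuity correction, df = 1.
#'
#' @param hitsA,totalA Hits and total for set A.
#' @param hitsB,totalB Hits and total for set B.
#' @return List with `statistic` and `p_value`.
#' @export
proportion_enrichment_test <- function(hitsA, totalA, hitsB, totalB) {
  if (totalA <= 0 || totalB <= 0) stop("totals must be positive", call. = FALSE)
  if (hitsA < 0 || hitsB < 0 || hitsA > totalA || hitsB > totalB) {
    stop("hits must lie in [0, total]", call. = FALSE)
  }
  tab <- matrix(c(hitsA, totalA - hitsA, hitsB, totalB - hitsB),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is zero (e.g. no positive call ",
         "in either set)", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Predict two candidate site sets and compare their hit proportions
#'
#' Runs [vote_predict] on a candidate set and a comparison set (e.g. known
#' acetylation sites versus random lysine sites), reports per-set predicted
#' counts and percentages (half-up, two decimals), and the
#' [proportion_enrichment_test] between them. A materially higher
#' proportion among real acetylation sites than among random lysines is
#' the expected signature of a working substrate classifier.
#'
#' @param ensemble A `voting_ensemble`.
#' @param candidate_sites `site_set` A.
#' @param annotations An `annotation_table`.
#' @param comparison_sites `site_set` B.
#' @param cutoff Vote cutoff (defaults to the ensemble's).
#' @param set_names Length-2 labels for the two sets.
#' @return A `substrate_summary`: `table` (set, predicted, total, percent),
#'   `statistic`, `p_value` (NA with an explanatory `note` if the 2x2 test
#'   is degenerate), and the cutoff used.
#' @export
predict_and_summarize <- function(ensemble, candidate_sites, annotations,
                                  comparison_sites,
                                  cutoff = ensemble$cutoff,
                                  set_names = c("candidate", "comparison")) {
  predA <- vote_predict(ensemble, candidate_sites, annotations, cutoff)
  predB <- vote_predict(ensemble, comparison_sites, annotations, cutoff)
  nA <- nrow(predA); kA <- sum(predA$call)
  nB <- nrow(predB); kB <- sum(predB$call)
  tab <- data.frame(set = set_names,
                    predicted = c(kA, kB),
                    total = c(nA, nB),
                    percent = format_proportion(c(kA, kB), c(nA, nB)),
                    stringsAsFactors = FALSE)
  test <- tryCatch(proportion_enrichment_test(kA, nA, kB, nB),
                   error = function(e) e)
  if (inherits(test, "error")) {
    res <- list(table = tab, statistic = NA_real_, p_value = NA_real_,
                note = conditionMessage(test), cutoff = cutoff)
  } else {
    res <- list(table = tab, statistic = test$statistic,
                p_value = test$p_value, note = NULL, cutoff = cutoff)
  }
  structure(res, class = "substrate_summary")
}

#' @export
print.substrate_summary <- function(x, ...) {
  cat(sprintf("substrate_summary (vote cutoff %d)\n", x$cutoff))
  print.data.frame(x$table, row.names = FALSE)
  if (!is.null(x$note)) {
    cat("proportion test not available:", x$note, "\n")
  } else {
    cat(sprintf("chi-squared (Yates) = %.4g, p = %.4g\n",
                x$statistic, x$p_value))
  }
  invisible(x)
}

#' Write a substrate summary as TSV
#'
#' @param summary A `substrate_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substrate_summary <- function(summary, path) {
  stopifnot(inherits(summary, "substrate_summary"))
  df <- summary$table
  df$chi2 <- summary$statistic
  df$p_value <- summary$p_value
  write_tsv(df, path)
}
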