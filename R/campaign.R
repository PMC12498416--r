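#' Run an iterative active-learning screening campaign
#'
#' Seeds the tested set with an initial batch (a supplied "docking hits"
#' list or a uniform random draw), then iterates: train the two-stage
#' surrogate on all measurements so far, score the untested pool with the
#' upper-confidence-bound acquisition, select a batch, measure it with the
#' assay oracle, and record the per-iteration hit rates under the strict
#' screen thresholds (normalized half-time > 1.5 potent, > 2 highly
#' potent).
#'
#' @param library_df data.frame with columns `id` and `smiles` (e.g. from
#'   [gen_library()] or [read_library()]).
#' @param oracle Function (ids, smiles) -> measured normalized half-times;
#'   stands in for the aggregation assay.
#' @param n_iter Number of active-learning iterations (default 3).
#' @param batch_sizes Integer vector, molecules per iteration (recycled if
#'   length 1); default c(32, 45, 49).
#' @param beta Acquisition uncertainty weight (default 1).
#' @param rng_seed Seed controlling the initial draw and forest training.
#' @param init_batch Either ids for the initial tested set or an integer
#'   size for a random draw (default 105).
#' @param features Optional precomputed fingerprint matrix (rownames =
#'   ids) to avoid re-featurizing.
#' @param diversity_cutoff Batch diversity filter passed to
#'   [select_batch()] (default 1 = off).
#' @return A `campaign_state`: list with `library`, `tested` (data.frame
#'   id, smiles, measured_t12_norm, iteration_tested), `surrogate` (last
#'   model), `beta`, `history` (data.frame iteration, n_tested, n_potent,
#'   n_highly_potent, hit_rate), `rng_seed`.
#' @export
run_campaign <- function(library_df, oracle, n_iter = 3,
                         batch_sizes = c(32, 45, 49), beta = 1,
                         rng_seed = 1, init_batch = 105,
                         features = NULL, diversity_cutoff = 1) {
  stopifnot(all(c("id", "smiles") %in% names(library_df)))
  ids <- as.character(library_df$id)
  smiles <- as.character(library_df$smiles)
  names(smiles) <- ids
  if (length(batch_sizes) == 1) batch_sizes <- rep(batch_sizes, n_iter)
  stopifnot(length(batch_sizes) == n_iter)

  if (is.null(features)) {
    f <- featurize(smiles, ids)
    if (nrow(f$rejected)) {
      stop("library contains unparseable SMILES: ",
           paste(utils::head(f$rejected$id, 3), collapse = ", "))
    }
    features <- f$features
  }
  features <- features[ids, , drop = FALSE]

  # initial tested set
  if (length(init_batch) == 1 && is.numeric(init_batch)) {
    set.seed(rng_seed)
    init_ids <- sample(ids, init_batch)
  } else {
    init_ids <- as.character(init_batch)
    stopifnot(all(init_ids %in% ids))
  }
  tested <- data.frame(id = init_ids, smiles = unname(smiles[init_ids]),
                       measured_t12_norm = oracle(init_ids, smiles[init_ids]),
                       iteration_tested = 0L, stringsAsFactors = FALSE)

  hist_rows <- list(campaign_history_row(0L, tested))
  model <- NULL
  for (it in seq_len(n_iter)) {
    pool <- setdiff(ids, tested$id)
    if (length(pool) < batch_sizes[it]) stop("untested pool exhausted")
    model <- train_surrogate(features[tested$id, , drop = FALSE],
                             tested$measured_t12_norm,
                             seed = rng_seed + it)
    pr <- predict(model, features[pool, , drop = FALSE])
    sc <- stats::setNames(acquisition_score(pr$mean, pr$sd, beta), pool)
    batch <- select_batch(sc, batch_sizes[it],
                          fp = if (diversity_cutoff < 1) features else NULL,
                          diversity_cutoff = diversity_cutoff)
    meas <- oracle(batch, smiles[batch])
    tested <- rbind(tested,
                    data.frame(id = batch, smiles = unname(smiles[batch]),
                               measured_t12_norm = meas,
                               iteration_tested = it,
                               stringsAsFactors = FALSE))
    hist_rows <- c(hist_rows,
                   list(campaign_history_row(it,
                        tested[tested$iteration_tested == it, ])))
  }
  structure(list(library = library_df, tested = tested, surrogate = model,
                 beta = beta, history = do.call(rbind, hist_rows),
                 rng_seed = rng_seed),
            class = "campaign_state")
}

campaign_history_row <- function(iteration, tested_it) {
  cls <- classify_hit(tested_it$measured_t12_norm)
  n <- nrow(tested_it)
  data.frame(iteration = iteration, n_tested = n,
             n_potent = sum(cls == "potent"),
             n_highly_potent = sum(cls == "highly_potent"),
             hit_rate = sum(cls %in% c("potent", "highly_potent")) / n)
}

#' @export
print.campaign_state <- function(x, ...) {
  cat(sprintf("<campaign_state> %d molecules tested over %d iterations\n",
              nrow(x$tested), max(x$history$iteration)))
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Budget-matched random-selection baseline
#'
#' Replays a campaign schedule with uniformly random (surrogate-free)
#' selection, for enrichment comparisons.
#'
#' @inheritParams run_campaign
#' @return A `campaign_state` with random selections.
#' @export
random_campaign <- function(library_df, oracle, n_iter = 3,
                            batch_sizes = c(32, 45, 49), rng_seed = 1,
                            init_batch = 105) {
  ids <- as.character(library_df$id)
  smiles <- stats::setNames(as.character(library_df$smiles), ids)
  if (length(batch_sizes) == 1) batch_sizes <- rep(batch_sizes, n_iter)
  set.seed(rng_seed)
  if (length(init_batch) == 1 && is.numeric(init_batch)) {
    init_ids <- sample(ids, init_batch)
  } else init_ids <- as.character(init_batch)
  tested <- data.frame(id = init_ids, smiles = unname(smiles[init_ids]),
                       measured_t12_norm = oracle(init_ids, smiles[init_ids]),
                       iteration_tested = 0L, stringsAsFactors = FALSE)
  hist_rows <- list(campaign_history_row(0L, tested))
  for (it in seq_len(n_iter)) {
    pool <- setdiff(ids, tested$id)
    batch <- sample(pool, batch_sizes[it])
    tested <- rbind(tested,
                    data.frame(id = batch, smiles = unname(smiles[batch]),
                               measured_t12_norm = oracle(batch, smiles[batch]),
                               iteration_tested = it,
                               stringsAsFactors = FALSE))
    hist_rows <- c(hist_rows,
                   list(campaign_history_row(it,
                        tested[tested$iteration_tested == it, ])))
  }
  structure(list(library = library_df, tested = tested, surrogate = NULL,
                 beta = NA_real_, history = do.call(rbind, hist_rows),
                 rng_seed = rng_seed),
            class = "campaign_state")
}
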