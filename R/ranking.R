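#' Model-comparison indicators for one entity
#'
#' Five indicators per candidate model fitted to the same count table:
#' mean 95% credible-interval width for the \eqn{\lambda_i}, posterior
#' mean of \eqn{\sigma}, and the fit criteria WAIC1, WAIC2 and DIC.
#' Lower is better for every indicator.
#'
#' @param fits named list of `posterior_fit` objects (one per model, all
#'   fitted to the same [count_table()]).
#' @param level credible level for the width indicator.
#' @return Data frame with one row per model and columns `model`,
#'   `width`, `sigma`, `waic1`, `waic2`, `dic`.
#' @export
compute_indicators <- function(fits, level = 0.95) {
  stopifnot(length(fits) >= 1L)
  ref <- fits[[1L]]$data
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    if (!identical(f$data$observed, ref$observed) ||
        !identical(f$data$expected, ref$expected))
      stop("all fits must be on the same count table")
    iv <- lambda_intervals(f, level)
    crit <- model_criteria(f)
    data.frame(model = names(fits)[k] %||% paste0("model", k),
               width = mean(iv$upper - iv$lower),
               sigma = mean(f$sigma),
               waic1 = crit$waic1, waic2 = crit$waic2, dic = crit$dic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a

#' Difference-from-minimum matrix
#'
#' For each entity and indicator, subtracts the minimum over models, so
#' the best model scores 0 on that indicator and every column of
#' differences contains at least one zero per entity.
#'
#' @param indicators data frame with columns `entity`, `model` and one
#'   column per indicator (as stacked [compute_indicators()] results).
#' @param indicator_cols names of the indicator columns.
#' @return Same-shape data frame with indicator values replaced by
#'   differences from the per-entity minimum.
#' @export
diff_from_min <- function(indicators,
                          indicator_cols = c("width", "sigma", "waic1",
                                             "waic2", "dic")) {
  stopifnot(all(c("entity", "model") %in% names(indicators)),
            all(indicator_cols %in% names(indicators)))
  out <- indicators
  for (ent in unique(indicators$entity)) {
    idx <- which(indicators$entity == ent)
    for (col in indicator_cols) {
      v <- indicators[idx, col]
      if (anyNA(v)) stop("incomplete indicator grid for entity ", ent)
      out[idx, col] <- v - min(v)
    }
  }
  out
}

#' Rank models within each entity and average ranks across indicators
#'
#' For each entity, models are ranked within each selected indicator
#' (ascending, 1 = best, ties get the average rank) and the ranks are
#' averaged across the selected indicators with equal weight.  The
#' restricted subset `c("dic", "waic1", "waic2")` is the "overall"
#' goodness-of-fit indicator used to pick a working model.
#'
#' @param indicators stacked indicator data frame (`entity`, `model`,
#'   indicator columns).
#' @param indicator_cols non-empty subset of the indicator columns to
#'   rank on.
#' @return List with `per_entity` (data frame: `entity`, `model`, one
#'   rank column per indicator, `avg_rank`) and `by_model` (data frame:
#'   `model`, `mean_avg_rank` over entities, `n_entities`).
#' @export
rank_models <- function(indicators,
                        indicator_cols = c("width", "sigma", "waic1",
                                           "waic2", "dic")) {
  if (length(indicator_cols) == 0L)
    stop("need at least one indicator to rank on")
  stopifnot(all(indicator_cols %in% names(indicators)))
  per <- lapply(unique(indicators$entity), function(ent) {
    sub <- indicators[indicators$entity == ent, , drop = FALSE]
    ranks <- vapply(indicator_cols,
                    function(col) rank(sub[[col]], ties.method = "average"),
                    numeric(nrow(sub)))
    ranks <- matrix(ranks, nrow = nrow(sub),
                    dimnames = list(NULL, paste0("rank_", indicator_cols)))
    cbind(data.frame(entity = ent, model = sub$model,
                     stringsAsFactors = FALSE),
          as.data.frame(ranks),
          data.frame(avg_rank = rowMeans(ranks)))
  })
  per <- do.call(rbind, per)
  agg <- stats::aggregate(avg_rank ~ model, data = per, FUN = mean)
  names(agg)[2L] <- "mean_avg_rank"
  agg$n_entities <- as.vector(table(per$model)[agg$model])
  agg <- agg[order(agg$mean_avg_rank), ]
  rownames(agg) <- NULL
  list(per_entity = per, by_model = agg)
}

#' Incidence-rate scenario membership
#'
#' Entities are stratified by crude incidence rate (cases per 100,000
#' person-years) into four scenarios defined cumulatively from the IR
#' quartile cuts 0.03, 0.12 and 0.5: scenario A contains entities with
#' IR < 0.03; B those with IR < 0.12 (so it includes A's); C those with
#' IR < 0.5 (includes B's); D those with IR >= 0.5 only.
#'
#' @param ir non-negative crude incidence rate(s).
#' @return For a single IR, a character vector of scenario labels; for a
#'   vector, a list of such vectors.
#' @export
stratify_by_incidence <- function(ir) {
  if (any(ir < 0)) stop("incidence rates must be non-negative")
  one <- function(x) {
    if (x >= 0.5) return("D")
    c(if (x < 0.03) "A", if (x < 0.12) "B", "C")
  }
  if (length(ir) == 1L) one(ir) else lapply(ir, one)
}

#' Scenario-level percentile summaries of indicator differences
#'
#' For the entities belonging to one scenario, summarises each model's
#' difference-from-minimum per indicator by the median and the 2.5th and
#' 97.5th percentiles (type-7 quantiles).
#'
#' @param diffs difference matrix from [diff_from_min()], with an `ir`
#'   column (crude IR per entity) or a precomputed `scenario` list-column
#'   absent — membership is derived from `ir`.
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param indicator_cols indicator columns to summarise.
#' @return Data frame with `scenario`, `model`, `indicator`, `median`,
#'   `p2.5`, `p97.5`, `n_entities`.
#' @export
summarize_scenario <- function(diffs, scenario,
                               indicator_cols = c("width", "sigma", "waic1",
                                                  "waic2", "dic")) {
  stopifnot("ir" %in% names(diffs), scenario %in% c("A", "B", "C", "D"))
  member <- vapply(diffs$ir,
                   function(x) scenario %in% stratify_by_incidence(x), TRUE)
  sub <- diffs[member, , drop = FALSE]
  if (!nrow(sub)) stop("no entities fall in scenario ", scenario)
  rows <- list()
  for (m in unique(sub$model)) {
    msub <- sub[sub$model == m, , drop = FALSE]
    for (col in indicator_cols) {
      q <- stats::quantile(msub[[col]], c(0.5, 0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = scenario, model = m, indicator = col,
                   median = q[1L], p2.5 = q[2L], p97.5 = q[3L],
                   n_entities = length(unique(msub$entity)),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
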