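# Reporting: model-comparison tables, group aggregates, CV-inflation
# arithmetic and the published reference values used to validate them.

#' Published reference model performance
#'
#' Performance of the six predictive model types (adjusted R^2, training
#' RMSE and 10-fold cross-validated RMSE) as reported by the original
#' 93-male cohort analysis this package's methodology follows, for both
#' dependent variables: body-fat percentage (`fat_pct`, RMSE in
#' percentage points) and trunk:peripheral fat ratio (`tpfr`, RMSE as a
#' ratio). Shipped so that the report-level aggregate arithmetic can be
#' validated against its published group summaries.
#'
#' @return a data frame with columns `dependent`, `model`, `group`
#'   (`shape_only`, `size_only` or `size_and_shape`), `adj_r2`, `rmse`,
#'   `cv_rmse`.
#' @export
reference_model_performance <- function() {
  fat <- data.frame(
    dependent = "fat_pct",
    model = c("shape_only", "anthro_sa", "anthro_vol",
              "anthro_shape", "shape_sa", "shape_vol"),
    adj_r2 = c(0.8331, 0.7365, 0.7390, 0.8463, 0.8096, 0.8482),
    rmse = c(3.19, 4.01, 4.00, 2.93, 3.41, 3.05),
    cv_rmse = c(3.79, 4.35, 4.27, 3.11, 3.63, 3.35)
  )
  tpfr <- data.frame(
    dependent = "tpfr",
    model = fat$model,
    adj_r2 = c(0.4904, 0.5321, 0.5673, 0.7864, 0.6776, 0.6676),
    rmse = c(0.160, 0.153, 0.147, 0.103, 0.127, 0.129),
    cv_rmse = c(0.181, 0.167, 0.157, 0.122, 0.144, 0.142)
  )
  out <- rbind(fat, tpfr)
  out$group <- model_group(out$model)
  out[, c("dependent", "model", "group", "adj_r2", "rmse", "cv_rmse")]
}

#' Model group membership
#'
#' Shape-containing combined models are `anthro_shape`, `shape_sa` and
#' `shape_vol`; size-only models are `anthro_sa` and `anthro_vol`;
#' `shape_only` stands alone.
#'
#' @param model character vector of model-type labels.
#' @return character vector of group labels.
#' @export
model_group <- function(model) {
  ifelse(model == "shape_only", "shape_only",
         ifelse(model %in% c("anthro_sa", "anthro_vol"), "size_only",
                ifelse(model %in% c("anthro_shape", "shape_sa", "shape_vol"),
                       "size_and_shape", NA_character_)))
}

#' Mean adjusted R^2 of a model group
#'
#' Arithmetic mean of the adjusted R^2 values over the rows belonging to
#' the requested models.
#'
#' @param rows a data frame with columns `model` and `adj_r2`.
#' @param models character vector defining the group.
#' @return the group mean adjusted R^2.
#' @export
aggregate_group_r2 <- function(rows, models) {
  sub <- rows[rows$model %in% models, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty model group")
  mean(sub$adj_r2)
}

#' Cross-validation RMSE inflation
#'
#' Percentage increase of the cross-validated RMSE over the training
#' RMSE: 100 (cv/trained - 1).
#'
#' @param trained_rmse training RMSE (> 0).
#' @param cv_rmse cross-validated RMSE.
#' @return percent increase (vectorized).
#' @export
cv_inflation <- function(trained_rmse, cv_rmse) {
  if (any(trained_rmse <= 0)) stop("trained RMSE must be positive")
  100 * (cv_rmse / trained_rmse - 1)
}

#' Top significant terms by relative weight
#'
#' Filters a relative-weight table to significant terms (p < alpha),
#' sorts by descending weight and keeps the top k, as used in published
#' per-model contribution tables.
#'
#' @param weights a `relative_weights` data frame.
#' @param k number of terms to keep.
#' @param alpha significance threshold.
#' @return the filtered, sorted data frame (possibly empty).
#' @export
top_weights_table <- function(weights, k = 3L, alpha = 0.05) {
  sig <- weights[!is.na(weights$p_value) & weights$p_value < alpha, ,
                 drop = FALSE]
  sig <- sig[order(-sig$raw_weight), , drop = FALSE]
  head(sig, k)
}

#' Assemble a model-comparison report
#'
#' Collects per-model rows (model type, adjusted R^2, RMSE, CV RMSE,
#' chosen shape subset) and recomputes every aggregate from those rows at
#' render time: group mean adjusted R^2 and group mean CV inflation for
#' the shape-containing, size-only and shape-only groups, per dependent
#' variable.
#'
#' @param rows data frame with columns `dependent`, `model`, `adj_r2`,
#'   `rmse`, `cv_rmse` and optionally `shape_subset`.
#' @return an object of class `comparison_report`: list with `rows` and
#'   `aggregates` (data frame: dependent, group, n_models, mean_adj_r2,
#'   mean_cv_inflation_pct).
#' @export
comparison_report <- function(rows) {
  stopifnot(all(c("dependent", "model", "adj_r2", "rmse", "cv_rmse") %in%
                names(rows)))
  rows$group <- model_group(rows$model)
  aggs <- list()
  for (dep in unique(rows$dependent)) {
    for (grp in unique(rows$group)) {
      sub <- rows[rows$dependent == dep & rows$group == grp, , drop = FALSE]
      if (nrow(sub) == 0L) next
      aggs[[length(aggs) + 1L]] <- data.frame(
        dependent = dep, group = grp, n_models = nrow(sub),
        mean_adj_r2 = mean(sub$adj_r2),
        mean_cv_inflation_pct = mean(cv_inflation(sub$rmse, sub$cv_rmse))
      )
    }
  }
  rep <- list(rows = rows, aggregates = do.call(rbind, aggs))
  class(rep) <- "comparison_report"
  rep
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat("Model comparison\n================\n")
  rows <- x$rows
  rows$adj_r2 <- round(rows$adj_r2, 4)
  rows$rmse <- signif(rows$rmse, 3)
  rows$cv_rmse <- signif(rows$cv_rmse, 3)
  print(rows, row.names = FALSE)
  cat("\nGroup aggregates (recomputed from the rows above)\n")
  ag <- x$aggregates
  ag$mean_adj_r2 <- round(ag$mean_adj_r2, 4)
  ag$mean_cv_inflation_pct <- round(ag$mean_cv_inflation_pct, 1)
  print(ag, row.names = FALSE)
  invisible(x)
}
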