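#' Compute an all-pairs element similarity table for two models
#'
#' Orchestrates one of the three similarity measures between every same-type
#' element pair of two models:
#' \describe{
#'   \item{`direct`}{similarity of direct feature vectors (annotations only).}
#'   \item{`fp`}{feature propagation — propagate features in each model
#'     separately (each with its own `lambda = c/r`), then compare inferred
#'     vectors.}
#'   \item{`sp`}{similarity propagation — propagate the direct similarities on
#'     the cross-model pair graph.}
#' }
#' Similarities between elements of different types are fixed to 0 and
#' omitted from the table.
#'
#' @param model_m,model_n Two [network_model()] objects.
#' @param measure `"direct"`, `"fp"` or `"sp"`.
#' @param space Optional shared `semprop_space`; built from both models when
#'   `NULL`.
#' @param S Optional concept similarity matrix (default identity).
#' @param weights A [propagation_weights()] object.
#' @param lambda Override the scaling factor (default: chosen per matrix via
#'   [choose_lambda()] with `weights$lambda_fraction`).
#' @param max_steps `Inf` for the exact solves, or a finite truncation of the
#'   propagation series (e.g. `max_steps = 1`, `lambda = 1` gives the
#'   single-step reading of pair-graph propagation).
#' @return An object of class `semprop_simtable`: fields `model_m`, `model_n`
#'   (model ids), `measure`, and `pairs` (`data.frame` with columns `x`, `y`,
#'   `type`, `psi`).
#' @export
similarity_table <- function(model_m, model_n,
                             measure = c("direct", "fp", "sp"),
                             space = NULL, S = NULL,
                             weights = propagation_weights(),
                             lambda = NULL, max_steps = Inf) {
  measure <- match.arg(measure)
  if (is.null(space)) space <- build_concept_space(list(model_m, model_n))
  fm <- featurize(model_m, space)
  fn <- featurize(model_n, space)

  if (measure == "direct") {
    sig <- cross_similarity(fm, fn, S)
    return(simtable_from_matrix(model_m, model_n, fm, fn, sig, measure))
  }

  if (measure == "fp") {
    RM <- build_propagation_matrix(model_m, weights)
    RN <- build_propagation_matrix(model_n, weights)
    lm <- if (is.null(lambda)) choose_lambda(RM, weights$lambda_fraction) else lambda
    ln <- if (is.null(lambda)) choose_lambda(RN, weights$lambda_fraction) else lambda
    wm <- feature_propagate(fm, RM, lm, max_steps)
    wn <- feature_propagate(fn, RN, ln, max_steps)
    psi <- cross_similarity(wm, wn, S)
    return(simtable_from_matrix(model_m, model_n, fm, fn, psi, measure))
  }

  # sp
  RM <- build_propagation_matrix(model_m, weights)
  RN <- build_propagation_matrix(model_n, weights)
  Q <- build_pair_graph(RM, RN, fm$element_types, fn$element_types)
  sig <- cross_similarity(fm, fn, S)
  sigma <- sig[cbind(match(Q$pairs$x, fm$element_ids),
                     match(Q$pairs$y, fn$element_ids))]
  lq <- if (is.null(lambda)) choose_lambda(Q, weights$lambda_fraction) else lambda
  psi <- similarity_propagate(sigma, Q, lq, max_steps)
  pairs <- Q$pairs
  pairs$psi <- psi
  structure(
    list(model_m = model_m$model_id, model_n = model_n$model_id,
         measure = measure, pairs = pairs),
    class = "semprop_simtable"
  )
}

# internal: build a simtable from a dense |M| x |N| similarity matrix,
# keeping only same-type pairs (cross-type similarity is 0 by definition).
simtable_from_matrix <- function(model_m, model_n, fm, fn, psi_mat, measure) {
  same <- which(outer(fm$element_types, fn$element_types, "=="),
                arr.ind = TRUE)
  same <- same[order(same[, 1], same[, 2]), , drop = FALSE]
  pairs <- data.frame(
    x = fm$element_ids[same[, 1]], y = fn$element_ids[same[, 2]],
    type = fm$element_types[same[, 1]],
    psi = psi_mat[same], stringsAsFactors = FALSE)
  structure(
    list(model_m = model_m$model_id, model_n = model_n$model_id,
         measure = measure, pairs = pairs),
    class = "semprop_simtable"
  )
}

#' @export
print.semprop_simtable <- function(x, ...) {
  cat(sprintf("<semprop_simtable> %s ~ %s (%s): %d same-type pairs, %d positive\n",
              x$model_m, x$model_n, x$measure, nrow(x$pairs),
              sum(x$pairs$psi > 1e-12)))
  invisible(x)
}

#' Look up a similarity value in a table
#'
#' @param table A `semprop_simtable`.
#' @param x,y Element ids in the table's two models (in order).
#' @return The psi value, or 0 if the pair is absent (cross-type).
#' @export
similarity_of <- function(table, x, y) {
  hit <- table$pairs$psi[table$pairs$x == x & table$pairs$y == y]
  if (length(hit)) hit[[1]] else 0
}
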