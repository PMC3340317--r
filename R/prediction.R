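#' Propagation weights for annotation prediction
#'
#' Annotation prediction uses a deliberately restricted propagation: transfer
#' weight 1/2 between a reaction and its reactants/products in both
#' directions, all other edges 0, and a single propagation step (the series
#' is truncated after k = 1 with scaling factor 1). This keeps the number of
#' suggested annotations small while still letting elements inherit semantic
#' information from their direct neighbours.
#'
#' @param rho Reaction-reactant/product transfer weight (default 1/2).
#' @param cofactors Cofactor table, as in [propagation_weights()].
#' @return A `semprop_weights` object.
#' @export
prediction_weights <- function(rho = 0.5, cofactors = default_cofactors()) {
  propagation_weights(alpha = rho, beta = rho, modifier_weight = 0,
                      compartment_weight = 0, lambda_fraction = 0.5,
                      cofactors = cofactors)
}

# internal: one-step propagated feature matrix under prediction weights
prediction_features <- function(model, space, weights = prediction_weights()) {
  V <- featurize(model, space)
  R <- build_propagation_matrix(model, weights)
  feature_propagate(V, R, lambda = 1, max_steps = 1)
}

#' Build a leave-one-feature-out annotation collection
#'
#' For every element of every corpus model, its propagated feature vector is
#' computed under the prediction-mode propagation; then, for each annotation
#' concept `i` carried by the element, a copy of the vector with component `i`
#' zeroed is stored together with the concept and its provenance. Querying
#' the collection with a propagated vector retrieves the concepts whose
#' holders look most similar.
#'
#' @param corpus List of [network_model()] objects (the annotated corpus).
#' @param space A `semprop_space` covering the corpus (and the query models).
#' @param weights Prediction-mode weights; see [prediction_weights()].
#' @return An object of class `semprop_collection`: fields `space`,
#'   `concepts` (character), `vectors` (sparse entries-by-concepts matrix) and
#'   `provenance` (`data.frame` with `model_id`, `element_id`).
#' @export
build_collection <- function(corpus, space, weights = prediction_weights()) {
  if (inherits(corpus, "semprop_model")) corpus <- list(corpus)
  concepts <- character()
  vecs <- list()
  prov_model <- character(); prov_element <- character()
  for (m in corpus) {
    W <- prediction_features(m, space, weights)
    V <- featurize(m, space)$values
    Wm <- W$values
    for (k in seq_along(W$element_ids)) {
      direct_idx <- which(V[k, ] > 0)
      if (!length(direct_idx)) next
      wrow <- as.numeric(Wm[k, ])
      for (j in direct_idx) {
        v <- wrow
        v[j] <- 0
        concepts <- c(concepts, space$concepts[j])
        vecs[[length(vecs) + 1L]] <- v
        prov_model <- c(prov_model, m$model_id)
        prov_element <- c(prov_element, W$element_ids[k])
      }
    }
  }
  vectors <- if (length(vecs))
    Matrix::Matrix(do.call(rbind, vecs), sparse = TRUE)
  else Matrix::Matrix(0, nrow = 0, ncol = space$dimension, sparse = TRUE)
  structure(
    list(space = space, concepts = concepts, vectors = vectors,
         provenance = data.frame(model_id = prov_model,
                                 element_id = prov_element,
                                 stringsAsFactors = FALSE)),
    class = "semprop_collection"
  )
}

#' @export
print.semprop_collection <- function(x, ...) {
  cat(sprintf("<semprop_collection> %d entries over %d concepts from %d models\n",
              length(x$concepts), x$space$dimension,
              length(unique(x$provenance$model_id))))
  invisible(x)
}

#' Predict annotations for a model element
#'
#' Computes the element's prediction-mode propagated feature vector within its
#' model and compares it (cosine similarity on propagated vectors) against
#' every entry of the leave-one-feature-out collection. Entries are ranked by
#' similarity; concepts are de-duplicated keeping their best score and the top
#' `top_n` are returned. An element whose propagated vector is zero (no own
#' annotations and no annotated reactant/product neighbourhood) yields an
#' empty prediction with a notice.
#'
#' @param element_id Id of the query element.
#' @param model The [network_model()] containing it.
#' @param collection A `semprop_collection` from [build_collection()].
#' @param top_n Maximum number of suggested concepts (>= 1).
#' @param weights Prediction-mode weights; see [prediction_weights()].
#' @return `data.frame` with columns `concept`, `resource`, `identifier`,
#'   `score`, ranked best-first (ties broken by concept key).
#' @export
predict_annotations <- function(element_id, model, collection, top_n = 10,
                                weights = prediction_weights()) {
  stopifnot(top_n >= 1)
  if (!element_id %in% element_ids(model))
    stop("unknown element id: ", element_id)
  space <- collection$space
  W <- prediction_features(model, space, weights)
  q <- as.numeric(W$values[match(element_id, W$element_ids), ])
  empty <- data.frame(concept = character(), resource = character(),
                      identifier = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (sqrt(sum(q^2)) < 1e-15) {
    message("element '", element_id,
            "' has an empty propagated feature vector; no predictions")
    return(empty)
  }
  if (!length(collection$concepts)) return(empty)
  # cosine of q against every collection entry, vectorised
  num <- as.numeric(collection$vectors %*% q)
  norms <- sqrt(Matrix::rowSums(collection$vectors^2))
  qn <- sqrt(sum(q^2))
  sims <- ifelse(norms < 1e-15, 0, num / (norms * qn))
  df <- data.frame(concept = collection$concepts, score = sims,
                   stringsAsFactors = FALSE)
  df <- df[df$score > 1e-12, , drop = FALSE]  # dissimilar entries say nothing
  df <- df[order(-df$score, df$concept), , drop = FALSE]
  df <- df[!duplicated(df$concept), , drop = FALSE]
  df <- utils::head(df, top_n)
  ra <- lapply(df$concept, concept_to_annotation, space = space)
  df$resource <- vapply(ra, `[[`, character(1), "resource")
  df$identifier <- vapply(ra, `[[`, character(1), "identifier")
  rownames(df) <- NULL
  df[, c("concept", "resource", "identifier", "score")]
}

#' Predict annotations for all non-annotated elements of a model
#'
#' @param model A [network_model()].
#' @param collection A `semprop_collection`.
#' @param top_n Suggestions per element.
#' @param weights Prediction-mode weights.
#' @param element_types Restrict to these element types.
#' @return Named list (by element id) of prediction `data.frame`s, suitable
#'   for [write_annotation_suggestions()].
#' @export
predict_model_annotations <- function(model, collection, top_n = 10,
                                      weights = prediction_weights(),
                                      element_types = ELEMENT_TYPES) {
  out <- list()
  for (el in model$elements) {
    if (!el$element_type %in% element_types) next
    if (length(el$annotations)) next
    out[[el$element_id]] <-
      suppressMessages(predict_annotations(el$element_id, model, collection,
                                           top_n, weights))
  }
  out
}
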