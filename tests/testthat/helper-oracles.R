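# Independent oracles and small generators shared across the test files.

# Truncated Neumann series sum_{k=0..K} (lambda M)^k B, computed densely and
# step by step -- independent of the package's sparse linear solver.
series_oracle <- function(M, B, lambda, K = 100) {
  M <- as.matrix(M)
  B <- as.matrix(B)
  acc <- B
  term <- B
  for (k in seq_len(K)) {
    term <- lambda * (M %*% term)
    acc <- acc + term
  }
  acc
}

# Exhaustive optimal one-to-one matching score for a similarity matrix
# (rows = elements of one model, columns = the other; unmatched allowed).
brute_force_matching_score <- function(psi) {
  m <- nrow(psi); n <- ncol(psi)
  best <- 0
  recurse <- function(i, free_cols, acc) {
    if (i > m) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(i + 1, free_cols, acc)  # leave row i unmatched
    for (j in free_cols) {
      if (psi[i, j] > 0)
        recurse(i + 1, setdiff(free_cols, j), acc + psi[i, j])
    }
    invisible()
  }
  recurse(1, seq_len(n), 0)
  best
}

# Random sparse non-negative square matrix (a stand-in propagation matrix).
random_nonneg_sparse <- function(n, density = 0.15, seed = 1) {
  set.seed(seed)
  nnz <- max(1L, round(density * n * n))
  i <- sample.int(n, nnz, replace = TRUE)
  j <- sample.int(n, nnz, replace = TRUE)
  x <- stats::runif(nnz, 0.1, 1)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

# Random correlation-style PSD matrix with unit diagonal.
random_unit_psd <- function(d, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(d * d), d, d)
  stats::cov2cor(crossprod(A) + diag(d) * 1e-6)
}

# Two models in which two species carry identical annotations but different
# network contexts (phosphostate-style ambiguity). In the second model the
# lexicographically first cross pairing is the structurally wrong one.
make_ambiguous_pair <- function() {
  annA <- semprop::annotation("toydb", "KIN0001")
  annB <- semprop::annotation("toydb", "CTX0001")
  annC <- semprop::annotation("toydb", "CTX0002")
  build <- function(mid, amb1, amb2, ctx1_ann, ctx2_ann) {
    semprop::network_model(mid, list(
      semprop::model_element(amb1, "species", annotations = list(annA)),
      semprop::model_element(amb2, "species", annotations = list(annA)),
      semprop::model_element("w1", "species", annotations = list(ctx1_ann)),
      semprop::model_element("w2", "species", annotations = list(ctx2_ann)),
      semprop::model_element("r1", "reaction"),
      semprop::model_element("r2", "reaction")
    ), data.frame(
      source_id = c("r1", "r1", "r2", "r2"),
      target_id = c(amb1, "w1", amb2, "w2"),
      role = c("reactant", "product", "reactant", "product"),
      stringsAsFactors = FALSE))
  }
  # model M: u1 converts to B-context, u2 to C-context
  # model N: t1 converts to C-context, t2 to B-context  => correct matching
  # is (u1, t2), (u2, t1); the naive lexicographic pick would be (u1, t1).
  list(m = build("amb_m", "u1", "u2", annB, annC),
       n = build("amb_n", "t1", "t2", annC, annB))
}

# Corpus of random models with globally unique concepts, two annotations per
# element -- every element keeps semantic context when one annotation is held
# out, so leave-one-out retrieval can be checked exactly.
make_loo_corpus <- function(n_models = 10, n_species = 6, n_reactions = 4,
                            seed = 42) {
  lapply(seq_len(n_models), function(i)
    semprop::make_random_model(
      n_species, n_reactions, annotation_density = 1,
      annotations_per_element = 2, distinct_concepts = TRUE,
      model_id = sprintf("corpus%02d", i), seed = seed + i))
}

# Leave-one-out sweep: hide each single annotation of each corpus element,
# query the collection, record the rank of the hidden concept (NA if absent
# from the returned top_n).
loo_ranks <- function(corpus, top_n = 10) {
  space <- semprop::build_concept_space(corpus)
  coll <- semprop::build_collection(corpus, space)
  ranks <- integer()
  for (m in corpus) for (el in m$elements) {
    nk <- length(el$annotations)
    if (!nk) next
    for (k in seq_len(nk)) {
      hidden <- paste(el$annotations[[k]]$resource,
                      el$annotations[[k]]$identifier, sep = "|")
      q <- m
      q$elements[[el$element_id]]$annotations <-
        q$elements[[el$element_id]]$annotations[-k]
      pred <- suppressMessages(semprop::predict_annotations(
        el$element_id, q, coll, top_n = top_n))
      r <- match(hidden, pred$concept)
      ranks <- c(ranks, if (is.na(r)) NA_integer_ else r)
    }
  }
  ranks
}
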