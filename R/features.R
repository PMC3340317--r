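#' Build a biological concept space
#'
#' The concept space is the index set of feature-vector components: one
#' concept per distinct `(resource, identifier)` annotation pair, except that
#' pairs declared synonymous in the equivalence table collapse to a single
#' concept (entries from different resources can describe the same biological
#' concept, e.g. a ChEBI and a KEGG Compound entry for the same sugar).
#' Concept ordering is deterministic (sorted by key).
#'
#' @param models A [network_model()] or list of them.
#' @param equivalences Optional synonym table: `data.frame` with columns
#'   `resource`, `identifier`, `concept_key` (see [read_equivalence_table()]).
#' @return An object of class `semprop_space` with fields `concepts`
#'   (ordered keys), `equivalence_map` (named character, `"resource|identifier"`
#'   to concept key) and `dimension`.
#' @export
build_concept_space <- function(models, equivalences = NULL) {
  if (inherits(models, "semprop_model")) models <- list(models)
  eq_map <- character()
  if (!is.null(equivalences) && nrow(equivalences)) {
    keys <- paste(tolower(equivalences$resource), equivalences$identifier,
                  sep = "|")
    eq_map <- stats::setNames(as.character(equivalences$concept_key), keys)
  }
  concepts <- character()
  for (m in models) for (el in m$elements) {
    ks <- element_annotation_keys(el)
    if (!length(ks)) next
    mapped <- ifelse(ks %in% names(eq_map), unname(eq_map[ks]), ks)
    concepts <- c(concepts, mapped)
  }
  concepts <- sort(unique(c(concepts, unname(eq_map))))
  structure(
    list(concepts = concepts, equivalence_map = eq_map,
         dimension = length(concepts)),
    class = "semprop_space"
  )
}

#' @export
print.semprop_space <- function(x, ...) {
  cat(sprintf("<semprop_space> %d concepts, %d synonym mappings\n",
              x$dimension, length(x$equivalence_map)))
  invisible(x)
}

# internal: concept key for an annotation within a space
concept_of <- function(space, ann) {
  key <- annotation_key(ann)
  if (key %in% names(space$equivalence_map))
    unname(space$equivalence_map[[key]])
  else key
}

#' Map a concept key back to a (resource, identifier) pair
#'
#' The default concept keys are `"resource|identifier"`; keys introduced by an
#' equivalence table are resolved to their lexicographically first synonym.
#'
#' @param space A `semprop_space`.
#' @param key A concept key from `space$concepts`.
#' @return List with fields `resource` and `identifier`.
#' @export
concept_to_annotation <- function(space, key) {
  if (length(space$equivalence_map)) {
    syn <- sort(names(space$equivalence_map)[space$equivalence_map == key])
    if (length(syn)) key <- syn[[1]]
  }
  i <- regexpr("|", key, fixed = TRUE)
  if (i < 1) return(list(resource = key, identifier = key))
  list(resource = substr(key, 1L, i - 1L),
       identifier = substr(key, i + 1L, nchar(key)))
}

#' Read a concept equivalence (synonym) table
#'
#' Tab-separated with columns `resource`, `identifier`, `concept_key`.
#'
#' @param path File path.
#' @return A `data.frame` suitable for [build_concept_space()].
#' @export
read_equivalence_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("resource", "identifier", "concept_key")
  if (!all(need %in% names(df)))
    stop("equivalence table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Compute direct feature vectors for a model
#'
#' Builds the binary direct feature matrix V: entry `(x, i)` is 1 if element
#' `x` carries an annotation mapping to concept `i`, else 0. Non-annotated
#' elements get all-zero rows (their feature vectors are unknown and zero by
#' definition). Annotations whose concept is absent from the space are dropped
#' with a warning.
#'
#' @param model A [network_model()].
#' @param space A `semprop_space` from [build_concept_space()].
#' @return An object of class `semprop_features`: fields `space`,
#'   `element_ids`, `element_types` and `values` (a sparse
#'   elements-by-concepts [Matrix::Matrix()]).
#' @export
featurize <- function(model, space) {
  ids <- element_ids(model)
  n <- length(ids)
  d <- space$dimension
  ii <- integer(); jj <- integer()
  for (k in seq_len(n)) {
    el <- model$elements[[k]]
    if (!length(el$annotations)) next
    for (ann in el$annotations) {
      key <- concept_of(space, ann)
      j <- match(key, space$concepts)
      if (is.na(j)) {
        warning("annotation concept '", key, "' not in concept space; dropped",
                call. = FALSE)
        next
      }
      ii <- c(ii, k); jj <- c(jj, j)
    }
  }
  values <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, d),
                                 dimnames = list(ids, space$concepts))
  values@x[] <- pmin(values@x, 1)  # duplicate (resource,id) records count once
  structure(
    list(space = space, element_ids = ids,
         element_types = unname(element_types(model)), values = values),
    class = "semprop_features"
  )
}

#' @export
print.semprop_features <- function(x, ...) {
  cat(sprintf("<semprop_features> %d elements x %d concepts, %d non-zeros\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' Read a concept similarity matrix
#'
#' White-space separated square matrix with a header row of concept keys;
#' rows follow the header order.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames set to the concept keys.
#' @export
read_concept_similarity <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  S <- as.matrix(df)
  if (nrow(S) != ncol(S)) stop("concept similarity matrix must be square")
  rownames(S) <- colnames(S)
  if (max(abs(S - t(S))) > 1e-12) stop("concept similarity matrix must be symmetric")
  S
}

#' Direct semantic similarity between two feature vectors
#'
#' The normalised quadratic form
#' \deqn{\sigma_{xy} = \frac{v_x^T S v_y}{\sqrt{(v_x^T S v_x)(v_y^T S v_y)}},}
#' which reduces to the cosine of the angle between the vectors when `S` is
#' the identity (concepts logically independent). By definition the similarity
#' is 0 whenever either element is non-annotated (zero vector); denominators
#' below `1e-15` are treated as zero vectors.
#'
#' @param vx,vy Non-negative numeric feature vectors over the same concept
#'   space.
#' @param S Optional symmetric positive semidefinite concept similarity matrix
#'   with unit diagonal; `NULL` means identity.
#' @return Similarity in `[0, 1]` for non-negative inputs and the default `S`.
#' @export
direct_similarity <- function(vx, vy, S = NULL) {
  vx <- as.numeric(vx); vy <- as.numeric(vy)
  if (length(vx) != length(vy))
    stop("feature vectors have different dimensions: ",
         length(vx), " vs ", length(vy))
  if (!is.null(S)) {
    if (nrow(S) != length(vx) || ncol(S) != length(vx))
      stop("S dimensions do not match feature vectors")
    sx <- as.numeric(S %*% vx)
    num <- sum(sx * vy)
    dx <- sum(sx * vx)
    dy <- sum(as.numeric(S %*% vy) * vy)
  } else {
    num <- sum(vx * vy)
    dx <- sum(vx * vx)
    dy <- sum(vy * vy)
  }
  den <- sqrt(dx * dy)
  if (!is.finite(den) || den < 1e-15) return(0)
  num / den
}

# internal: all-pairs similarity between two feature matrices.
# Returns dense |M| x |N| matrix with cross-type entries set to 0.
cross_similarity <- function(fm_m, fm_n, S = NULL, zero_cross_type = TRUE) {
  Vm <- fm_m$values; Vn <- fm_n$values
  if (!identical(fm_m$space$concepts, fm_n$space$concepts))
    stop("feature matrices use different concept spaces")
  if (is.null(S)) {
    num <- as.matrix(Vm %*% Matrix::t(Vn))
    nm <- sqrt(Matrix::rowSums(Vm * Vm))
    nn <- sqrt(Matrix::rowSums(Vn * Vn))
  } else {
    SV <- Vm %*% S
    num <- as.matrix(SV %*% Matrix::t(Vn))
    nm <- sqrt(Matrix::rowSums(SV * Vm))
    nn <- sqrt(Matrix::rowSums((Vn %*% S) * Vn))
  }
  den <- outer(nm, nn)
  sig <- ifelse(den < 1e-15, 0, num / den)
  if (zero_cross_type)
    sig[outer(fm_m$element_types, fm_n$element_types, "!=")] <- 0
  dimnames(sig) <- list(fm_m$element_ids, fm_n$element_ids)
  sig
}
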