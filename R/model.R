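#' Create a MIRIAM-style annotation record
#'
#' An annotation cross-references a model element to an entry in a public
#' biological resource (for example a ChEBI compound or a UniProt protein),
#' together with the relation qualifier under which the reference was made.
#'
#' @param resource Name of the web resource (e.g. `"chebi"`). Stored
#'   lower-cased so that the two MIRIAM URI dialects compare equal.
#' @param identifier Entry identifier within the resource (e.g.
#'   `"CHEBI:17925"`).
#' @param qualifier Relation qualifier (e.g. `"is"`, `"isVersionOf"`). All
#'   identity-like qualifiers are treated identically during featurisation.
#' @return An object of class `semprop_annotation`.
#' @export
annotation <- function(resource, identifier, qualifier = "is") {
  if (!nzchar(resource)) stop("annotation resource must be non-empty")
  if (!nzchar(identifier)) stop("annotation identifier must be non-empty")
  structure(
    list(resource = tolower(resource), identifier = as.character(identifier),
         qualifier = as.character(qualifier)),
    class = "semprop_annotation"
  )
}

#' @export
format.semprop_annotation <- function(x, ...) {
  sprintf("%s|%s [%s]", x$resource, x$identifier, x$qualifier)
}

#' @export
print.semprop_annotation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

ELEMENT_TYPES <- c("species", "reaction", "compartment")
REFERENCE_ROLES <- c("reactant", "product", "modifier", "compartment-of")

#' Create a model element
#'
#' A model element is a species, reaction or compartment of a biochemical
#' network model, carrying a (possibly empty) set of annotations.
#'
#' @param element_id Unique identifier within its model.
#' @param element_type One of `"species"`, `"reaction"`, `"compartment"`.
#' @param annotations List of [annotation()] records.
#' @param display_name Optional human-readable label.
#' @return An object of class `semprop_element`.
#' @export
model_element <- function(element_id, element_type,
                          annotations = list(), display_name = NULL) {
  element_type <- match.arg(element_type, ELEMENT_TYPES)
  stopifnot(nzchar(element_id))
  if (!all(vapply(annotations, inherits, logical(1), "semprop_annotation")))
    stop("annotations must be a list of annotation() records")
  structure(
    list(element_id = as.character(element_id), element_type = element_type,
         annotations = unname(annotations), display_name = display_name),
    class = "semprop_element"
  )
}

#' Create a biochemical network model
#'
#' Holds typed elements plus the directed, role-labelled references among them
#' (the network structure). References follow the conventions: a reaction
#' points at its reactants, products and modifiers (roles `"reactant"`,
#' `"product"`, `"modifier"`, with the reaction as source), and each species
#' points at its compartment (role `"compartment-of"`).
#'
#' @param model_id Model identifier.
#' @param elements List of [model_element()] objects with unique ids.
#' @param references `data.frame` with columns `source_id`, `target_id`,
#'   `role`; both endpoints must name elements of this model.
#' @return An object of class `semprop_model`.
#' @export
network_model <- function(model_id, elements, references = NULL) {
  if (is.null(references))
    references <- data.frame(source_id = character(), target_id = character(),
                             role = character(), stringsAsFactors = FALSE)
  stopifnot(nzchar(model_id), length(elements) >= 1)
  if (!all(vapply(elements, inherits, logical(1), "semprop_element")))
    stop("elements must be model_element() objects")
  ids <- vapply(elements, function(e) e$element_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate element ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(elements) <- ids
  references <- as.data.frame(references, stringsAsFactors = FALSE)
  if (nrow(references)) {
    bad <- setdiff(c(references$source_id, references$target_id), ids)
    if (length(bad))
      stop("reference endpoints not in model: ", paste(bad, collapse = ", "))
    if (!all(references$role %in% REFERENCE_ROLES))
      stop("unknown reference role")
  }
  structure(
    list(model_id = as.character(model_id), elements = elements,
         references = references),
    class = "semprop_model"
  )
}

#' @export
print.semprop_model <- function(x, ...) {
  tt <- table(element_types(x))
  cat(sprintf("<semprop_model> '%s': %d elements (%s), %d references\n",
              x$model_id, length(x$elements),
              paste(sprintf("%s %s", tt, names(tt)), collapse = ", "),
              nrow(x$references)))
  invisible(x)
}

#' Element ids of a model
#' @param model A [network_model()].
#' @return Character vector of element ids, in model order.
#' @export
element_ids <- function(model) {
  vapply(model$elements, function(e) e$element_id, character(1),
         USE.NAMES = FALSE)
}

#' Element types of a model
#' @param model A [network_model()].
#' @return Character vector (named by element id) of element types.
#' @export
element_types <- function(model) {
  vapply(model$elements, function(e) e$element_type, character(1))
}

#' Number of annotated elements in a model
#' @param model A [network_model()].
#' @param element_types Restrict the count to these element types.
#' @return Integer count of elements with at least one annotation.
#' @export
n_annotated <- function(model, element_types = ELEMENT_TYPES) {
  sum(vapply(model$elements, function(e)
    e$element_type %in% element_types && length(e$annotations) > 0,
    logical(1)))
}

# internal: canonical "resource|identifier" key of an annotation
annotation_key <- function(ann) paste(ann$resource, ann$identifier, sep = "|")

# internal: all annotation keys of an element
element_annotation_keys <- function(element) {
  if (!length(element$annotations)) return(character())
  vapply(element$annotations, annotation_key, character(1))
}
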