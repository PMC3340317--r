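#' Read an SBML model
#'
#' Parses an SBML Level 2 or 3 file into a [network_model()]. One element is
#' created per species, reaction and compartment; rules, events and parameters
#' are ignored. For every reaction, references with roles `"reactant"`,
#' `"product"` and `"modifier"` point from the reaction to the listed species,
#' and every species gets a `"compartment-of"` reference to its compartment.
#' MIRIAM annotations are read from the RDF block in both URI dialects,
#' `urn:miriam:<resource>:<id>` and `http(s)://identifiers.org/<resource>/<id>`;
#' URIs in neither dialect are skipped with a warning.
#'
#' @param path Path to an SBML file.
#' @return A [network_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing"))
    stop("no <model> element in SBML file: ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id) || !nzchar(model_id))
    model_id <- tools::file_path_sans_ext(basename(path))

  elements <- list()
  refs <- list()

  read_one <- function(node, type) {
    id <- xml2::xml_attr(node, "id")
    anns <- parse_element_annotations(node, path)
    nm <- xml2::xml_attr(node, "name")
    model_element(id, type, annotations = anns,
                  display_name = if (is.na(nm)) NULL else nm)
  }

  for (node in xml2::xml_find_all(model_node, "./listOfCompartments/compartment"))
    elements[[length(elements) + 1L]] <- read_one(node, "compartment")

  for (node in xml2::xml_find_all(model_node, "./listOfSpecies/species")) {
    el <- read_one(node, "species")
    elements[[length(elements) + 1L]] <- el
    comp <- xml2::xml_attr(node, "compartment")
    if (!is.na(comp) && nzchar(comp))
      refs[[length(refs) + 1L]] <-
        c(source_id = el$element_id, target_id = comp, role = "compartment-of")
  }

  for (node in xml2::xml_find_all(model_node, "./listOfReactions/reaction")) {
    el <- read_one(node, "reaction")
    elements[[length(elements) + 1L]] <- el
    rid <- el$element_id
    for (spec in list(c("./listOfReactants/speciesReference", "reactant"),
                      c("./listOfProducts/speciesReference", "product"),
                      c("./listOfModifiers/modifierSpeciesReference", "modifier"))) {
      for (sr in xml2::xml_find_all(node, spec[[1]])) {
        sp <- xml2::xml_attr(sr, "species")
        refs[[length(refs) + 1L]] <-
          c(source_id = rid, target_id = sp, role = spec[[2]])
      }
    }
  }

  references <- if (length(refs))
    as.data.frame(do.call(rbind, refs), stringsAsFactors = FALSE)
  else NULL
  network_model(model_id, elements, references)
}

# internal: annotations of one SBML element node (namespace-stripped document)
parse_element_annotations <- function(node, path) {
  lis <- xml2::xml_find_all(node, "./annotation//*[local-name()='li']")
  anns <- list()
  for (li in lis) {
    uri <- xml2::xml_attr(li, "resource")
    if (is.na(uri)) next
    qualifier <- xml2::xml_name(xml2::xml_parent(xml2::xml_parent(li)))
    ann <- parse_miriam_uri(uri, qualifier)
    if (is.null(ann)) {
      warning("skipping annotation URI with unknown scheme in '",
              path, "': ", uri, call. = FALSE)
      next
    }
    anns[[length(anns) + 1L]] <- ann
  }
  anns
}

#' Parse a MIRIAM URI into an annotation
#'
#' Accepts `urn:miriam:<resource>:<id>` (percent-encoded ids are decoded) and
#' `http(s)://identifiers.org/<resource>/<id>`.
#'
#' @param uri Annotation URI string.
#' @param qualifier Relation qualifier to attach.
#' @return An [annotation()], or `NULL` if the URI follows neither dialect.
#' @export
parse_miriam_uri <- function(uri, qualifier = "is") {
  if (grepl("^urn:miriam:", uri)) {
    rest <- sub("^urn:miriam:", "", uri)
    i <- regexpr(":", rest, fixed = TRUE)
    if (i < 1) return(NULL)
    resource <- substr(rest, 1L, i - 1L)
    id <- utils::URLdecode(substr(rest, i + 1L, nchar(rest)))
    if (!nzchar(resource) || !nzchar(id)) return(NULL)
    return(annotation(resource, id, qualifier))
  }
  if (grepl("^https?://identifiers\\.org/", uri)) {
    rest <- sub("^https?://identifiers\\.org/", "", uri)
    i <- regexpr("/", rest, fixed = TRUE)
    if (i < 1) return(NULL)
    resource <- substr(rest, 1L, i - 1L)
    id <- utils::URLdecode(substr(rest, i + 1L, nchar(rest)))
    if (!nzchar(resource) || !nzchar(id)) return(NULL)
    return(annotation(resource, id, qualifier))
  }
  NULL
}

# internal: identifiers.org URI for an annotation
miriam_uri <- function(ann) {
  sprintf("http://identifiers.org/%s/%s", ann$resource, ann$identifier)
}

#' Write a network model as SBML
#'
#' Serialises a [network_model()] to SBML Level 3 Version 1 with MIRIAM
#' annotations in the identifiers.org dialect. Only structure and annotations
#' are written (no kinetics); species lacking a `compartment-of` reference are
#' placed into a default compartment.
#'
#' @param model A [network_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  ann_block <- function(el, indent) {
    if (!length(el$annotations)) return(character())
    quals <- vapply(el$annotations, function(a) a$qualifier, character(1))
    lines <- c(
      paste0(indent, "<annotation>"),
      paste0(indent, "  <rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">"),
      paste0(indent, "    <rdf:Description rdf:about=\"#meta_", esc(el$element_id), "\">"))
    for (q in unique(quals)) {
      lines <- c(lines,
                 paste0(indent, "      <bqbiol:", q, "><rdf:Bag>"))
      for (a in el$annotations[quals == q])
        lines <- c(lines, paste0(indent, "        <rdf:li rdf:resource=\"",
                                 esc(miriam_uri(a)), "\"/>"))
      lines <- c(lines, paste0(indent, "      </rdf:Bag></bqbiol:", q, ">"))
    }
    c(lines,
      paste0(indent, "    </rdf:Description>"),
      paste0(indent, "  </rdf:RDF>"),
      paste0(indent, "</annotation>"))
  }

  types <- element_types(model)
  refs <- model$references
  compartment_of <- function(sid) {
    if (nrow(refs)) {
      hit <- refs$target_id[refs$source_id == sid & refs$role == "compartment-of"]
      if (length(hit)) return(hit[[1]])
    }
    "default_compartment"
  }
  comp_ids <- names(types)[types == "compartment"]
  need_default <- any(types == "species") &&
    any(vapply(names(types)[types == "species"], function(s)
      compartment_of(s) == "default_compartment", logical(1))) &&
    !("default_compartment" %in% comp_ids)

  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">",
           sprintf("  <model id=\"%s\">", esc(model$model_id)))

  out <- c(out, "    <listOfCompartments>")
  for (cid in comp_ids) {
    el <- model$elements[[cid]]
    if (length(el$annotations)) {
      out <- c(out, sprintf("      <compartment id=\"%s\" metaid=\"meta_%s\" constant=\"true\">",
                            esc(cid), esc(cid)),
               ann_block(el, "        "),
               "      </compartment>")
    } else {
      out <- c(out, sprintf("      <compartment id=\"%s\" constant=\"true\"/>", esc(cid)))
    }
  }
  if (need_default)
    out <- c(out, "      <compartment id=\"default_compartment\" constant=\"true\"/>")
  out <- c(out, "    </listOfCompartments>")

  sp_ids <- names(types)[types == "species"]
  if (length(sp_ids)) {
    out <- c(out, "    <listOfSpecies>")
    for (sid in sp_ids) {
      el <- model$elements[[sid]]
      head <- sprintf("      <species id=\"%s\" metaid=\"meta_%s\" compartment=\"%s\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\"",
                      esc(sid), esc(sid), esc(compartment_of(sid)))
      if (!is.null(el$display_name))
        head <- paste0(head, sprintf(" name=\"%s\"", esc(el$display_name)))
      if (length(el$annotations)) {
        out <- c(out, paste0(head, ">"), ann_block(el, "        "),
                 "      </species>")
      } else out <- c(out, paste0(head, "/>"))
    }
    out <- c(out, "    </listOfSpecies>")
  }

  rx_ids <- names(types)[types == "reaction"]
  if (length(rx_ids)) {
    out <- c(out, "    <listOfReactions>")
    for (rid in rx_ids) {
      el <- model$elements[[rid]]
      out <- c(out, sprintf("      <reaction id=\"%s\" metaid=\"meta_%s\" reversible=\"false\" fast=\"false\">",
                            esc(rid), esc(rid)),
               ann_block(el, "        "))
      rr <- refs[refs$source_id == rid, , drop = FALSE]
      for (spec in list(c("reactant", "listOfReactants", "speciesReference"),
                        c("product", "listOfProducts", "speciesReference"),
                        c("modifier", "listOfModifiers", "modifierSpeciesReference"))) {
        tgt <- rr$target_id[rr$role == spec[[1]]]
        if (!length(tgt)) next
        out <- c(out, sprintf("        <%s>", spec[[2]]))
        extra <- if (spec[[1]] == "modifier") "" else " stoichiometry=\"1\" constant=\"true\""
        for (s in tgt)
          out <- c(out, sprintf("          <%s species=\"%s\"%s/>",
                                spec[[3]], esc(s), extra))
        out <- c(out, sprintf("        </%s>", spec[[2]]))
      }
      out <- c(out, "      </reaction>")
    }
    out <- c(out, "    </listOfReactions>")
  }

  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write ranked annotation suggestions
#'
#' Writes a tab-separated report with columns `element_id`, `rank`,
#' `resource`, `identifier`, `score`, ordered by element id then rank.
#'
#' @param model The [network_model()] the suggestions refer to.
#' @param suggestions Named list (by element id) of `data.frame`s with columns
#'   `resource`, `identifier`, `score`, ranked best-first, as returned by
#'   [predict_annotations()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotation_suggestions <- function(model, suggestions, path) {
  ids <- element_ids(model)
  bad <- setdiff(names(suggestions), ids)
  if (length(bad))
    stop("suggestions for unknown element id(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (eid in sort(names(suggestions))) {
    df <- suggestions[[eid]]
    if (is.null(df) || !nrow(df)) next
    if (is.unsorted(rev(df$score))) df <- df[order(-df$score), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = eid, rank = seq_len(nrow(df)),
      resource = df$resource, identifier = df$identifier,
      score = df$score, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(element_id = character(), rank = integer(),
                  resource = character(), identifier = character(),
                  score = numeric(), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
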