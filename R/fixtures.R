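# Generators for the toy networks and removal benchmarks used to evaluate
# semantic propagation. All randomness is drawn from an explicit seed via a
# local RNG scope, so fixtures are bit-for-bit reproducible.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Linear metabolic chain fixture
#'
#' Species `s1 ... sn` linked by reactions `r1 ... r(n-1)` (`s_i` reactant,
#' `s_{i+1}` product), each species in compartment `cell`. With
#' `annotate_endpoints_only = TRUE` only the first and the last species carry
#' a (distinct, single-concept) annotation — the setting in which direct
#' similarity can match just two elements while propagation recovers the
#' whole chain. Otherwise every species gets its own distinct concept;
#' reactions are never annotated by this generator.
#'
#' @param n_species Chain length (>= 2).
#' @param annotate_endpoints_only Logical; see above.
#' @param model_id Model id (also used to make a self-alignment partner with
#'   a different id).
#' @return A [network_model()].
#' @export
make_linear_chain <- function(n_species, annotate_endpoints_only = TRUE,
                              model_id = "chain") {
  stopifnot(n_species >= 2)
  sp_ids <- sprintf("s%d", seq_len(n_species))
  rx_ids <- sprintf("r%d", seq_len(n_species - 1))
  ann_for <- function(i) list(annotation("toydb", sprintf("MET%04d", i)))
  elements <- list(model_element("cell", "compartment"))
  for (i in seq_len(n_species)) {
    anns <- if (!annotate_endpoints_only || i == 1L || i == n_species)
      ann_for(i) else list()
    elements[[length(elements) + 1L]] <-
      model_element(sp_ids[i], "species", annotations = anns)
  }
  refs <- data.frame(source_id = sp_ids, target_id = "cell",
                     role = "compartment-of", stringsAsFactors = FALSE)
  for (i in seq_len(n_species - 1)) {
    elements[[length(elements) + 1L]] <- model_element(rx_ids[i], "reaction")
    refs <- rbind(refs,
                  data.frame(source_id = rx_ids[i], target_id = sp_ids[i],
                             role = "reactant", stringsAsFactors = FALSE),
                  data.frame(source_id = rx_ids[i], target_id = sp_ids[i + 1],
                             role = "product", stringsAsFactors = FALSE))
  }
  network_model(model_id, elements, refs)
}

#' Two one-reaction models of the same biochemical conversion
#'
#' Each model is a single reaction `a -> b` (resp. `p -> q`). The reactant
#' pair shares one of two concepts (`sigma_ap = 1/sqrt(2)`), the product pair
#' carries identical annotations (`sigma_bq = 1`), and the reactions are
#' unannotated — so their direct similarity is 0 and any similarity between
#' them must be inferred through propagation.
#'
#' @return List of two [network_model()] objects, `m1` and `m2`.
#' @export
make_reaction_pair <- function() {
  c1 <- annotation("toydb", "SUB0001")
  c2 <- annotation("toydb", "SUB0002")
  c3 <- annotation("toydb", "PRO0001")
  m1 <- network_model("pair_m1", list(
    model_element("c", "compartment"),
    model_element("a", "species", annotations = list(c1)),
    model_element("b", "species", annotations = list(c3)),
    model_element("x", "reaction")
  ), data.frame(
    source_id = c("a", "b", "x", "x"),
    target_id = c("c", "c", "a", "b"),
    role = c("compartment-of", "compartment-of", "reactant", "product"),
    stringsAsFactors = FALSE))
  m2 <- network_model("pair_m2", list(
    model_element("c", "compartment"),
    model_element("p", "species", annotations = list(c1, c2)),
    model_element("q", "species", annotations = list(c3)),
    model_element("y", "reaction")
  ), data.frame(
    source_id = c("p", "q", "y", "y"),
    target_id = c("c", "c", "p", "q"),
    role = c("compartment-of", "compartment-of", "reactant", "product"),
    stringsAsFactors = FALSE))
  list(m1 = m1, m2 = m2)
}

#' Random bipartite species-reaction model
#'
#' Erdős–Rényi-style generator: each reaction draws one or two reactants and
#' one or two products from the species pool (degree capped at 4 per species
#' to stay biologically plausible). A fraction `annotation_density` of
#' elements (species and reactions) is annotated with `annotations_per_element`
#' concepts drawn from a finite pool; with `distinct_concepts = TRUE` every
#' annotation gets a globally unique concept instead.
#'
#' @param n_species,n_reactions Network size.
#' @param annotation_density Fraction of elements annotated, in `[0, 1]`.
#' @param concept_pool_size Size of the concept vocabulary.
#' @param annotations_per_element Annotations per annotated element.
#' @param distinct_concepts If `TRUE`, concepts are unique per annotation
#'   (prefixed with the model id).
#' @param model_id Model id.
#' @param seed Integer seed; fixed seed implies identical output.
#' @return A [network_model()].
#' @export
make_random_model <- function(n_species, n_reactions,
                              annotation_density = 1,
                              concept_pool_size = 50,
                              annotations_per_element = 1,
                              distinct_concepts = FALSE,
                              model_id = "random", seed = 1) {
  stopifnot(n_species >= 2, n_reactions >= 1,
            annotation_density >= 0, annotation_density <= 1)
  with_seed(seed, {
    sp_ids <- sprintf("s%d", seq_len(n_species))
    rx_ids <- sprintf("r%d", seq_len(n_reactions))
    degree <- stats::setNames(integer(n_species), sp_ids)
    refs <- data.frame(source_id = sp_ids, target_id = "cell",
                       role = "compartment-of", stringsAsFactors = FALSE)
    for (r in rx_ids) {
      avail <- sp_ids[degree[sp_ids] < 4L]
      if (length(avail) < 2) avail <- sp_ids
      k_sub <- min(sample(1:2, 1), length(avail) - 1L)
      subs <- sample(avail, k_sub)
      rest <- setdiff(avail, subs)
      pros <- sample(rest, min(sample(1:2, 1), length(rest)))
      degree[c(subs, pros)] <- degree[c(subs, pros)] + 1L
      refs <- rbind(refs, data.frame(
        source_id = r, target_id = c(subs, pros),
        role = rep(c("reactant", "product"), c(length(subs), length(pros))),
        stringsAsFactors = FALSE))
    }
    all_ids <- c(sp_ids, rx_ids)
    n_ann <- round(annotation_density * length(all_ids))
    annotated <- sample(all_ids, n_ann)
    next_unique <- 0L
    make_anns <- function(eid) {
      if (!eid %in% annotated) return(list())
      lapply(seq_len(annotations_per_element), function(j) {
        if (distinct_concepts) {
          next_unique <<- next_unique + 1L
          annotation("toydb", sprintf("%s-U%05d", model_id, next_unique))
        } else {
          annotation("toydb", sprintf("C%04d",
                                      sample.int(concept_pool_size, 1)))
        }
      })
    }
    elements <- c(
      list(model_element("cell", "compartment")),
      lapply(sp_ids, function(s)
        model_element(s, "species", annotations = make_anns(s))),
      lapply(rx_ids, function(r)
        model_element(r, "reaction", annotations = make_anns(r)))
    )
    network_model(model_id, elements, refs)
  })
}

#' Randomly remove annotations from a model
#'
#' Strips all annotations from `floor(fraction * n)` uniformly chosen
#' annotated elements of the given types, where `n` is the number of
#' annotated elements of those types (removal is per element: an element
#' keeps all of its annotations or none). The input model is untouched.
#'
#' @param model A [network_model()].
#' @param fraction Fraction in `[0, 1]` of annotated elements to strip.
#' @param element_types Types eligible for removal.
#' @param seed Integer seed; the same seed gives the same removal.
#' @return A modified copy of `model`.
#' @export
remove_annotations <- function(model, fraction,
                               element_types = ELEMENT_TYPES, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  eligible <- names(Filter(function(e)
    e$element_type %in% element_types && length(e$annotations) > 0,
    model$elements))
  k <- floor(fraction * length(eligible))
  if (k == 0) return(model)
  strip <- with_seed(seed, sample(eligible, k))
  for (eid in strip) model$elements[[eid]]$annotations <- list()
  model
}

#' Identity reference alignment between two structurally equal models
#'
#' Pairs every element of `model_m` with the equally indexed element of
#' `model_n` (by position), the correct matching for copies of one network.
#'
#' @param model_m,model_n Two [network_model()] objects with equal layout.
#' @param element_types Restrict the reference to these element types
#'   (default: species and reactions, the elements the aligner is judged on).
#' @return A `semprop_alignment`.
#' @export
identity_alignment <- function(model_m, model_n,
                               element_types = c("species", "reaction")) {
  idm <- element_ids(model_m); idn <- element_ids(model_n)
  stopifnot(length(idm) == length(idn))
  tm <- unname(semprop::element_types(model_m))
  keep <- which(tm %in% element_types)
  tuples <- lapply(keep, function(i)
    data.frame(model_id = c(model_m$model_id, model_n$model_id),
               element_id = c(idm[i], idn[i]),
               type = tm[[i]], stringsAsFactors = FALSE))
  alignment_from_tuples(tuples)
}

#' Annotation-removal alignment benchmark
#'
#' Full factorial protocol: for each removal fraction and replicate,
#' annotations are randomly removed from `model_a`, similarities are computed
#' under each requested measure, the models are aligned greedily, and the
#' alignment is scored against the reference by precision and recall. The
#' whole table is reproducible for a fixed seed.
#'
#' @param model_a,model_b Models to align (removal is applied to `model_a`).
#' @param reference Gold-standard `semprop_alignment`.
#' @param fractions Removal fractions.
#' @param replicates Replicates per fraction.
#' @param measures Subset of `c("direct", "fp", "sp")`.
#' @param seed Base integer seed.
#' @param weights A [propagation_weights()] object.
#' @param element_types Element types whose annotations may be removed.
#' @return `data.frame` with columns `measure`, `fraction`, `replicate`,
#'   `precision`, `recall`.
#' @export
benchmark_alignment <- function(model_a, model_b, reference,
                                fractions = c(0, 0.2, 0.4, 0.6, 0.8),
                                replicates = 25,
                                measures = c("direct", "fp", "sp"),
                                seed = 1,
                                weights = propagation_weights(),
                                element_types = ELEMENT_TYPES) {
  measures <- match.arg(measures, c("direct", "fp", "sp"), several.ok = TRUE)
  rows <- list()
  for (fi in seq_along(fractions)) {
    for (rep in seq_len(replicates)) {
      sub_seed <- (seed + 7919L * fi + 104729L * rep) %% 2147483647L
      stripped <- remove_annotations(model_a, fractions[fi],
                                     element_types, seed = sub_seed)
      space <- build_concept_space(list(stripped, model_b))
      for (ms in measures) {
        tb <- similarity_table(stripped, model_b, measure = ms,
                               space = space, weights = weights)
        al <- greedy_align(tb, list(stripped, model_b))
        pr <- evaluate_alignment(al, reference)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = ms, fraction = fractions[fi], replicate = rep,
          precision = pr[["precision"]], recall = pr[["recall"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a fixture manifest
#'
#' Tab-separated companion to an SBML fixture: columns `element_id`, `type`,
#' `concepts` (comma-joined `resource|identifier` keys).
#'
#' @param model A [network_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(model, path) {
  df <- data.frame(
    element_id = element_ids(model),
    type = unname(element_types(model)),
    concepts = vapply(model$elements, function(e)
      paste(sort(element_annotation_keys(e)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
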