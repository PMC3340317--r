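#' Greedy model alignment
#'
#' Aligns two or more models by greedily matching element pairs in order of
#' decreasing similarity: the highest-psi pair is matched first, then the next
#' highest among the remaining pairs, until no positive psi values are left.
#' A candidate that conflicts with existing matches (it would place two
#' elements of the same model into one tuple) is discarded and the next best
#' pair considered. For three or more models, matching two elements also
#' merges all their previously determined matching partners, keeping the
#' alignment transitive by construction. The final score is the sum of psi
#' over all cross-model element pairs inside tuples.
#'
#' Ties in psi are broken lexicographically by `(model_id, element_id)` of
#' both pair members, making the alignment deterministic even when elements
#' carry identical annotations.
#'
#' @param tables A `semprop_simtable` or list of them, covering every
#'   unordered pair of the given models.
#' @param models List of two or more [network_model()] objects.
#' @param epsilon Scores at or below this floor are never matched (guards
#'   against matching on numerical dust).
#' @return An object of class `semprop_alignment`: fields `tuples` (list of
#'   `data.frame`s with columns `model_id`, `element_id`, `type`; singletons
#'   included) and `score`.
#' @export
greedy_align <- function(tables, models, epsilon = 1e-12) {
  if (inherits(tables, "semprop_simtable")) tables <- list(tables)
  if (inherits(models, "semprop_model")) models <- list(models)
  if (length(models) < 2) stop("alignment needs at least 2 models")
  mids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(mids)) stop("models must have distinct model_ids")

  covered <- vapply(tables, function(tb)
    paste(sort(c(tb$model_m, tb$model_n)), collapse = "\r"), character(1))
  wanted <- utils::combn(sort(mids), 2, paste, collapse = "\r")
  missing <- setdiff(wanted, covered)
  if (length(missing))
    stop("no similarity table for model pair(s): ",
         paste(gsub("\r", " ~ ", missing), collapse = ", "))

  # global candidate list across all model pairs
  cand <- do.call(rbind, lapply(tables, function(tb)
    data.frame(model_m = tb$model_m, x = tb$pairs$x,
               model_n = tb$model_n, y = tb$pairs$y,
               type = tb$pairs$type, psi = tb$pairs$psi,
               stringsAsFactors = FALSE)))
  cand <- cand[cand$psi > epsilon, , drop = FALSE]
  cand <- cand[order(-cand$psi, cand$model_m, cand$x, cand$model_n, cand$y), ,
               drop = FALSE]

  # union-find over "model\relement" keys, tracking member model ids
  key <- function(m, e) paste(m, e, sep = "\r")
  parent <- list()
  members <- list()  # root key -> data.frame(model_id, element_id, type)
  all_elements <- do.call(rbind, lapply(models, function(m)
    data.frame(model_id = m$model_id, element_id = element_ids(m),
               type = unname(element_types(m)), stringsAsFactors = FALSE)))
  for (i in seq_len(nrow(all_elements))) {
    k <- key(all_elements$model_id[i], all_elements$element_id[i])
    parent[[k]] <- k
    members[[k]] <- all_elements[i, , drop = FALSE]
  }
  find <- function(k) {
    while (parent[[k]] != k) k <- parent[[k]]
    k
  }

  for (i in seq_len(nrow(cand))) {
    ka <- key(cand$model_m[i], cand$x[i])
    kb <- key(cand$model_n[i], cand$y[i])
    ra <- find(ka); rb <- find(kb)
    if (ra == rb) next
    ma <- members[[ra]]; mb <- members[[rb]]
    if (length(intersect(ma$model_id, mb$model_id))) next  # conflict: discard
    if (ma$type[1] != mb$type[1]) next
    parent[[rb]] <- ra
    members[[ra]] <- rbind(ma, mb)
    members[[rb]] <- NULL
  }

  roots <- unique(vapply(names(parent), find, character(1)))
  tuples <- lapply(roots, function(r) {
    df <- members[[r]]
    df[order(df$model_id, df$element_id), , drop = FALSE]
  })
  # deterministic tuple order: by first member
  first <- vapply(tuples, function(df)
    paste(df$model_id[1], df$element_id[1], sep = "\r"), character(1))
  tuples <- tuples[order(first)]

  al <- structure(list(tuples = tuples, score = 0),
                  class = "semprop_alignment")
  al$score <- alignment_score(al, tables)
  al
}

# internal: Eq.-9-style score — sum of psi over all matched cross-model pairs
alignment_score <- function(alignment, tables) {
  lookup <- new.env(parent = emptyenv())
  for (tb in tables) {
    p <- tb$pairs
    for (i in seq_len(nrow(p))) {
      assign(paste(tb$model_m, p$x[i], tb$model_n, p$y[i], sep = "\r"),
             p$psi[i], envir = lookup)
    }
  }
  get_psi <- function(m1, e1, m2, e2) {
    k1 <- paste(m1, e1, m2, e2, sep = "\r")
    if (!is.null(v <- lookup[[k1]])) return(v)
    k2 <- paste(m2, e2, m1, e1, sep = "\r")
    if (!is.null(v <- lookup[[k2]])) return(v)
    0
  }
  total <- 0
  for (df in alignment$tuples) {
    n <- nrow(df)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
      total <- total + get_psi(df$model_id[i], df$element_id[i],
                               df$model_id[j], df$element_id[j])
  }
  total
}

#' @export
print.semprop_alignment <- function(x, ...) {
  sizes <- vapply(x$tuples, nrow, integer(1))
  cat(sprintf("<semprop_alignment> %d tuples (%d matched, %d singletons), score %.4f\n",
              length(x$tuples), sum(sizes > 1), sum(sizes == 1), x$score))
  invisible(x)
}

#' Matched element pairs of an alignment
#'
#' Expands every tuple into its unordered cross-model element pairs; the unit
#' in which precision and recall are counted.
#'
#' @param alignment A `semprop_alignment`.
#' @return Character vector of canonical pair keys
#'   (`"model:element||model:element"`, members sorted).
#' @export
alignment_pairs <- function(alignment) {
  out <- character()
  for (df in alignment$tuples) {
    n <- nrow(df)
    if (n < 2) next
    tags <- paste(df$model_id, df$element_id, sep = ":")
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      pr <- sort(c(tags[i], tags[j]))
      out <- c(out, paste(pr, collapse = "||"))
    }
  }
  out
}

#' Build an alignment object from explicit tuples
#'
#' Convenience constructor for reference (gold-standard) alignments.
#'
#' @param tuples List of `data.frame`s with columns `model_id`, `element_id`
#'   and optionally `type`.
#' @param score Optional total score (default `NA`).
#' @return A `semprop_alignment`.
#' @export
alignment_from_tuples <- function(tuples, score = NA_real_) {
  tuples <- lapply(tuples, function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (is.null(df$type)) df$type <- NA_character_
    df
  })
  structure(list(tuples = tuples, score = score),
            class = "semprop_alignment")
}

#' Precision and recall of a predicted alignment
#'
#' Counts matched element pairs within tuples. Precision is the fraction of
#' predicted pairs present in the reference (1 when nothing is predicted);
#' recall is the fraction of reference pairs recovered.
#'
#' @param predicted,reference `semprop_alignment` objects over the same
#'   models.
#' @return Named numeric vector with components `precision` and `recall`.
#' @export
evaluate_alignment <- function(predicted, reference) {
  pp <- alignment_pairs(predicted)
  rp <- alignment_pairs(reference)
  correct <- length(intersect(pp, rp))
  precision <- if (length(pp)) correct / length(pp) else 1
  recall <- if (length(rp)) correct / length(rp) else 1
  c(precision = precision, recall = recall)
}

#' Write an alignment table
#'
#' One tuple per line: `model_id:element_id` members joined by tabs, then the
#' tuple's pair-score sum; a trailing summary line carries the total score.
#'
#' @param alignment A `semprop_alignment`.
#' @param tables The similarity tables used to score (list of
#'   `semprop_simtable`), or `NULL` to omit per-tuple scores.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path, tables = NULL) {
  lines <- character()
  for (df in alignment$tuples) {
    tags <- paste(df$model_id, df$element_id, sep = ":")
    sc <- if (is.null(tables)) NA_real_
    else alignment_score(alignment_from_tuples(list(df)), tables)
    lines <- c(lines, paste(c(tags, formatC(sc, format = "g")),
                            collapse = "\t"))
  }
  lines <- c(lines, sprintf("# total_score\t%s",
                            formatC(alignment$score, format = "g")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
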