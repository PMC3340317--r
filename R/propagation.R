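#' Propagation weights
#'
#' Bundles the transfer weights used to build propagation matrices: `alpha`
#' for species-to-reaction transfer, `beta` for reaction-to-species transfer,
#' a weight for modifier (enzyme/regulator) edges, a weight for
#' compartment-species edges, the scaling-factor fraction `c` in
#' `lambda = c / r` (with `r` the spectral radius), and the cofactor list at
#' which propagation is blocked.
#'
#' Defaults: `alpha = beta = modifier_weight = 0.5`, `compartment_weight = 0`
#' (compartment edges exist in the structure but carry no weight unless
#' configured), `lambda_fraction = 0.5` (i.e. `lambda = 1/(2r)`), and the
#' shipped currency-metabolite cofactor list.
#'
#' @param alpha Weight species -> reaction (>= 0).
#' @param beta Weight reaction -> species (>= 0).
#' @param modifier_weight Weight on modifier edges, both directions (>= 0).
#' @param compartment_weight Weight on compartment edges, both directions
#'   (>= 0).
#' @param lambda_fraction Multiplier `c` in `lambda = c/r`, in (0, 1).
#' @param cofactors `data.frame` with columns `resource`, `identifier`
#'   naming cofactor species annotations, or `NULL` for none. Defaults to
#'   [default_cofactors()].
#' @return An object of class `semprop_weights`.
#' @export
propagation_weights <- function(alpha = 0.5, beta = 0.5,
                                modifier_weight = 0.5,
                                compartment_weight = 0,
                                lambda_fraction = 0.5,
                                cofactors = default_cofactors()) {
  stopifnot(alpha >= 0, beta >= 0, modifier_weight >= 0,
            compartment_weight >= 0,
            lambda_fraction > 0, lambda_fraction < 1 || lambda_fraction == 1)
  if (lambda_fraction >= 1 && lambda_fraction != 1)
    stop("lambda_fraction must lie in (0, 1)")
  cof_keys <- character()
  if (!is.null(cofactors) && nrow(cofactors))
    cof_keys <- paste(tolower(cofactors$resource), cofactors$identifier,
                      sep = "|")
  structure(
    list(alpha = alpha, beta = beta, modifier_weight = modifier_weight,
         compartment_weight = compartment_weight,
         lambda_fraction = lambda_fraction,
         cofactor_keys = unique(cof_keys)),
    class = "semprop_weights"
  )
}

#' Shipped default cofactor list
#'
#' Currency metabolites (ATP, ADP, AMP, NAD(+/H), NADP(+/H), water, proton,
#' inorganic phosphate, CO2, O2) as `(resource, identifier)` pairs; these are
#' highly connected hubs at which propagation is stopped so that unrelated
#' reactions do not acquire spurious similarity. Override with
#' [read_cofactor_table()] or `cofactors = NULL`.
#'
#' @return `data.frame` with columns `resource`, `identifier`, `name`.
#' @export
default_cofactors <- function() {
  path <- system.file("extdata", "cofactors.tsv", package = "semprop")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "cofactors.tsv")
  read_cofactor_table(path)
}

#' Read a cofactor table
#'
#' Tab-separated with columns `resource`, `identifier` (extra columns such as
#' `name` are kept but unused).
#'
#' @param path File path.
#' @return `data.frame` with at least columns `resource`, `identifier`.
#' @export
read_cofactor_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("resource", "identifier") %in% names(df)))
    stop("cofactor table must have columns resource, identifier")
  df
}

#' Read a propagation config file
#'
#' `key = value` lines for keys `alpha`, `beta`, `modifier_weight`,
#' `compartment_weight`, `lambda_fraction`, `cofactor_file`. Missing keys fall
#' back to the [propagation_weights()] defaults.
#'
#' @param path File path.
#' @return A `semprop_weights` object.
#' @export
read_propagation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  cof <- if (!is.null(kv[["cofactor_file"]]))
    read_cofactor_table(kv[["cofactor_file"]])
  else default_cofactors()
  propagation_weights(
    alpha = num("alpha", 0.5), beta = num("beta", 0.5),
    modifier_weight = num("modifier_weight", 0.5),
    compartment_weight = num("compartment_weight", 0),
    lambda_fraction = num("lambda_fraction", 0.5),
    cofactors = cof)
}

# internal: is this element a cofactor species under the given weights?
is_cofactor <- function(element, weights) {
  element$element_type == "species" &&
    any(element_annotation_keys(element) %in% weights$cofactor_keys)
}

#' Build the propagation matrix of a model
#'
#' Builds the sparse |M| x |M| matrix R of transfer weights: for every
#' reactant/product reference between reaction `x` and species `a`,
#' `R[x, a] = alpha` (the reaction receives from the species) and
#' `R[a, x] = beta`; modifier edges get `modifier_weight` in both directions,
#' compartment edges `compartment_weight` in both directions. All entries in
#' the row and column of a cofactor species are zero, stopping propagation at
#' these hubs.
#'
#' @param model A [network_model()].
#' @param weights A [propagation_weights()] object.
#' @return An object of class `semprop_propmat`: fields `element_ids` and
#'   `matrix` (sparse non-negative [Matrix::Matrix()]).
#' @export
build_propagation_matrix <- function(model, weights = propagation_weights()) {
  ids <- element_ids(model)
  n <- length(ids)
  refs <- model$references
  ii <- integer(); jj <- integer(); xx <- numeric()
  add <- function(i, j, w) {
    if (w > 0) {
      ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, w)
    }
  }
  if (nrow(refs)) {
    si <- match(refs$source_id, ids)
    ti <- match(refs$target_id, ids)
    for (k in seq_len(nrow(refs))) {
      role <- refs$role[k]
      if (role %in% c("reactant", "product")) {
        add(si[k], ti[k], weights$alpha)   # reaction <- species
        add(ti[k], si[k], weights$beta)    # species <- reaction
      } else if (role == "modifier") {
        add(si[k], ti[k], weights$modifier_weight)
        add(ti[k], si[k], weights$modifier_weight)
      } else if (role == "compartment-of") {
        add(si[k], ti[k], weights$compartment_weight)
        add(ti[k], si[k], weights$compartment_weight)
      }
    }
  }
  R <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ids, ids))
  cof <- which(vapply(model$elements, is_cofactor, logical(1),
                      weights = weights))
  if (length(cof)) {
    R[cof, ] <- 0
    R[, cof] <- 0
    R <- Matrix::drop0(R)
  }
  structure(list(element_ids = ids, matrix = R), class = "semprop_propmat")
}

#' Spectral radius of a sparse non-negative matrix
#'
#' Dense eigenvalue computation for small matrices; power iteration (valid
#' for the non-negative matrices produced here) for larger ones, with a dense
#' fallback if iteration stalls.
#'
#' @param M Square matrix (base or [Matrix::Matrix()]).
#' @param dense_limit Below this dimension a dense `eigen` call is used.
#' @return The largest absolute eigenvalue, a non-negative scalar.
#' @export
spectral_radius <- function(M, dense_limit = 200L) {
  n <- nrow(M)
  if (n == 0L) return(0)
  nz <- if (inherits(M, "sparseMatrix")) length(M@x) else sum(M != 0)
  if (nz == 0L) return(0)
  if (n < dense_limit)
    return(max(abs(eigen(as.matrix(M), only.values = TRUE)$values)))
  # power iteration on the non-negative matrix from a positive start vector
  v <- rep(1 / sqrt(n), n)
  r_old <- 0
  for (it in seq_len(1000L)) {
    w <- as.numeric(M %*% v)
    r <- sqrt(sum(w^2))
    if (r < 1e-300) return(0)
    v <- w / r
    if (abs(r - r_old) < 1e-10 * max(r, 1)) return(r)
    r_old <- r
  }
  message("power iteration did not converge; falling back to dense eigen")
  max(abs(eigen(as.matrix(M), only.values = TRUE)$values))
}

#' Choose the propagation scaling factor lambda
#'
#' Returns `lambda = lambda_fraction / r` with `r` the spectral radius of the
#' propagation (or pair) matrix, guaranteeing convergence of the propagation
#' series for `lambda_fraction < 1`. When `r = 0` (no propagation paths) the
#' series terminates at its first term and `lambda = 1` by convention.
#'
#' @param R A `semprop_propmat`, `semprop_pairgraph`, or square matrix.
#' @param lambda_fraction Multiplier `c` in `lambda = c/r`.
#' @return The scalar lambda.
#' @export
choose_lambda <- function(R, lambda_fraction = 0.5) {
  M <- propagation_matrix_of(R)
  r <- spectral_radius(M)
  if (r < 1e-12) return(1)
  lambda_fraction / r
}

# internal: accept semprop_propmat / semprop_pairgraph / plain matrix
propagation_matrix_of <- function(R) {
  if (inherits(R, "semprop_propmat") || inherits(R, "semprop_pairgraph"))
    R$matrix
  else R
}

#' Propagate feature vectors across a model (feature propagation)
#'
#' Computes the inferred feature matrix W solving the fixed-point equation
#' `W = V + lambda R W`, i.e. `W = (I - lambda R)^{-1} V`, by a sparse linear
#' solve (the dense inverse is never formed). Elements that receive no
#' information keep their direct vectors; inferred vectors are non-negative
#' whenever V and R are. With `max_steps = K` finite, the truncated series
#' `sum_{k=0..K} (lambda R)^k V` is returned instead, which reproduces the
#' step-by-step reading of the propagation process.
#'
#' @param V A `semprop_features` object (direct features).
#' @param R A `semprop_propmat` from [build_propagation_matrix()].
#' @param lambda Scaling factor; see [choose_lambda()]. Must satisfy
#'   `lambda * r < 1` for the full solve.
#' @param max_steps `Inf` for the exact solve, or a finite number of
#'   propagation steps.
#' @return A `semprop_features` object holding W.
#' @export
feature_propagate <- function(V, R, lambda, max_steps = Inf) {
  M <- propagation_matrix_of(R)
  if (!identical(V$element_ids, R$element_ids))
    stop("feature matrix and propagation matrix index different elements")
  W <- propagate_linear(M, V$values, lambda, max_steps)
  out <- V
  out$values <- W
  out
}

# internal: shared solver for FP and SP.
# Solves X = B + lambda M X (sparse solve), or truncates the Neumann series.
propagate_linear <- function(M, B, lambda, max_steps = Inf) {
  n <- nrow(M)
  if (n == 0L) return(B)
  if (is.finite(max_steps)) {
    X <- B
    term <- B
    for (k in seq_len(max_steps)) {
      term <- lambda * (M %*% term)
      X <- X + term
    }
    return(X)
  }
  r <- spectral_radius(M)
  if (lambda * r >= 1)
    stop(sprintf(
      "lambda * spectral_radius = %.6g >= 1: propagation series diverges",
      lambda * r))
  A <- Matrix::Diagonal(n) - lambda * M
  Matrix::solve(A, B)
}

#' Inferred element similarity from propagated features
#'
#' Applies the direct similarity measure to inferred (propagated) feature
#' vectors; contracts are identical to [direct_similarity()] with `w` in
#' place of `v`.
#'
#' @inheritParams direct_similarity
#' @param wx,wy Inferred feature vectors (rows of the W matrix).
#' @return Similarity value; 0 if either vector is zero.
#' @export
inferred_fp_similarity <- function(wx, wy, S = NULL) {
  direct_similarity(wx, wy, S)
}

#' Build the pair propagation graph of two models
#'
#' Nodes are same-type element pairs `(x in M, y in N)`; the edge weight from
#' pair `(a, p)` into pair `(x, y)` is `Q[(x,y),(a,p)] = RM[x,a] * RN[y,p]` —
#' information flows simultaneously in both models. Species-pair and
#' reaction-pair nodes live in separate strongly-typed subgraphs, so an
#' initial species matching can never create species-reaction similarity.
#'
#' @param RM,RN `semprop_propmat` objects for the two models.
#' @param types_m,types_n Character vectors of element types, parallel to the
#'   element ids of `RM` and `RN`.
#' @return An object of class `semprop_pairgraph`: fields `pairs`
#'   (`data.frame` with `x`, `y`, `type`) and `matrix` (sparse Q).
#' @export
build_pair_graph <- function(RM, RN, types_m, types_n) {
  idsM <- RM$element_ids; idsN <- RN$element_ids
  nM <- length(idsM); nN <- length(idsN)
  stopifnot(length(types_m) == nM, length(types_n) == nN)
  # kronecker index (x - 1) * nN + y  <->  pair (x, y)
  K <- Matrix::kronecker(RM$matrix, RN$matrix)
  same <- which(outer(types_m, types_n, "=="), arr.ind = TRUE)
  same <- same[order(same[, 1], same[, 2]), , drop = FALSE]
  sel <- (same[, 1] - 1L) * nN + same[, 2]
  Q <- K[sel, sel, drop = FALSE]
  pairs <- data.frame(x = idsM[same[, 1]], y = idsN[same[, 2]],
                      type = types_m[same[, 1]], stringsAsFactors = FALSE)
  dimnames(Q) <- list(paste(pairs$x, pairs$y, sep = "~"),
                      paste(pairs$x, pairs$y, sep = "~"))
  structure(list(pairs = pairs, matrix = Q), class = "semprop_pairgraph")
}

#' @export
print.semprop_pairgraph <- function(x, ...) {
  cat(sprintf("<semprop_pairgraph> %d element pairs, %d edges\n",
              nrow(x$pairs), length(x$matrix@x)))
  invisible(x)
}

#' Propagate similarities on the pair graph (similarity propagation)
#'
#' Computes inferred pairwise similarities solving
#' `psi = sigma + lambda Q psi`, i.e. `psi = (I - lambda Q)^{-1} sigma`, by a
#' sparse linear solve. The process is the stationary state of a diffusion on
#' the pair graph with production `sigma` and linear decay. With finite
#' `max_steps` the truncated series `sum_{k=0..K} (lambda Q)^k sigma` is
#' returned. Values are not clipped at 1; clipping is a display choice.
#'
#' @param sigma Non-negative vector of direct similarities, parallel to the
#'   pair set of `Q`.
#' @param Q A `semprop_pairgraph` from [build_pair_graph()].
#' @param lambda Scaling factor; `lambda * r < 1` required for the full solve.
#' @param max_steps `Inf` for the exact solve, or a finite step count.
#' @return Numeric vector of inferred similarities `psi^sp`.
#' @export
similarity_propagate <- function(sigma, Q, lambda, max_steps = Inf) {
  M <- propagation_matrix_of(Q)
  if (length(sigma) != nrow(M))
    stop("sigma length does not match the pair set")
  as.numeric(propagate_linear(M, matrix(sigma, ncol = 1), lambda, max_steps))
}
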