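one_reaction_model <- function() {
  network_model("mini", list(
    model_element("a", "species",
                  annotations = list(annotation("toydb", "A"))),
    model_element("b", "species",
                  annotations = list(annotation("toydb", "B"))),
    model_element("x", "reaction")
  ), data.frame(source_id = c("x", "x"), target_id = c("a", "b"),
                role = c("reactant", "product"), stringsAsFactors = FALSE))
}

test_that("propagation matrix mirrors the reference structure with alpha/beta weights", {
  m <- one_reaction_model()
  R <- build_propagation_matrix(m, propagation_weights(alpha = 0.5, beta = 0.5))
  M <- R$matrix
  expect_equal(length(M@x), 4)              # two edges, both directions
  expect_true(all(M@x == 0.5))
  expect_equal(M["x", "a"], 0.5)            # reaction <- reactant (alpha)
  expect_equal(M["a", "x"], 0.5)            # reactant <- reaction (beta)
  expect_equal(M["x", "b"], 0.5)
  expect_equal(M["b", "x"], 0.5)

  # asymmetric weights land on the right sides
  R2 <- build_propagation_matrix(m, propagation_weights(alpha = 0.3, beta = 0.7))
  expect_equal(R2$matrix["x", "a"], 0.3)
  expect_equal(R2$matrix["a", "x"], 0.7)

  # no references -> zero matrix
  lone <- network_model("lone", list(model_element("s1", "species")))
  expect_equal(length(build_propagation_matrix(lone)$matrix@x), 0)
})

test_that("propagation stops at cofactor species", {
  atp <- annotation("chebi", "CHEBI:15422")
  m <- network_model("cof", list(
    model_element("a", "species",
                  annotations = list(annotation("toydb", "A"))),
    model_element("atp", "species", annotations = list(atp)),
    model_element("x", "reaction")
  ), data.frame(source_id = c("x", "x"), target_id = c("a", "atp"),
                role = c("reactant", "product"), stringsAsFactors = FALSE))
  M <- build_propagation_matrix(m)$matrix
  expect_equal(sum(abs(M["atp", ])), 0)
  expect_equal(sum(abs(M[, "atp"])), 0)
  expect_equal(M["x", "a"], 0.5)  # non-cofactor edges untouched
})

test_that("modifier and compartment edges carry their configured weights", {
  m <- network_model("mod", list(
    model_element("c", "compartment"),
    model_element("s", "species"),
    model_element("e", "species"),
    model_element("x", "reaction")
  ), data.frame(source_id = c("x", "x", "s"), target_id = c("s", "e", "c"),
                role = c("reactant", "modifier", "compartment-of"),
                stringsAsFactors = FALSE))
  M0 <- build_propagation_matrix(m)$matrix  # defaults: modifier .5, compartment 0
  expect_equal(M0["x", "e"], 0.5)
  expect_equal(M0["e", "x"], 0.5)
  expect_equal(M0["s", "c"], 0)
  M1 <- build_propagation_matrix(
    m, propagation_weights(modifier_weight = 0, compartment_weight = 0.2))$matrix
  expect_equal(M1["x", "e"], 0)
  expect_equal(M1["s", "c"], 0.2)
  expect_equal(M1["c", "s"], 0.2)
})

test_that("lambda is the configured fraction of the inverse spectral radius", {
  # zero matrix: series terminates at k = 0, lambda = 1 by convention
  zero <- structure(list(element_ids = "s1",
                         matrix = Matrix::sparseMatrix(i = integer(),
                                                       j = integer(),
                                                       x = numeric(),
                                                       dims = c(1, 1))),
                    class = "semprop_propmat")
  expect_equal(choose_lambda(zero), 1)

  # known spectral radius 2
  M <- Matrix::Matrix(matrix(c(0, 2, 2, 0), 2, 2), sparse = TRUE)
  expect_equal(choose_lambda(M, 0.5), 0.25)

  # random sparse matrices against a dense eigenvalue oracle
  for (seed in 1:8) {
    n <- sample(5:40, 1)
    R <- random_nonneg_sparse(n, 0.2, seed = seed)
    r_oracle <- max(abs(eigen(as.matrix(R), only.values = TRUE)$values))
    lam <- choose_lambda(R, 0.5)
    expect_lt(abs(lam * r_oracle - 0.5), 1e-8)
  }

  # power-iteration path (above the dense threshold) agrees with dense eigen
  Rbig <- random_nonneg_sparse(250, 0.02, seed = 99)
  r_dense <- max(abs(eigen(as.matrix(Rbig), only.values = TRUE)$values))
  expect_equal(spectral_radius(Rbig), r_dense, tolerance = 1e-6)
})

test_that("feature propagation solves its fixed point and matches the series oracle", {
  m <- one_reaction_model()
  sp <- build_concept_space(m)
  V <- featurize(m, sp)
  R <- build_propagation_matrix(m)
  lam <- choose_lambda(R)
  W <- feature_propagate(V, R, lam)

  # fixed point W = V + lambda R W
  resid <- W$values - (V$values + lam * (R$matrix %*% W$values))
  expect_lt(max(abs(resid)), 1e-9)

  # truncated series oracle
  expect_lt(max(abs(as.matrix(W$values) -
                      series_oracle(R$matrix, V$values, lam, 100))), 1e-8)

  # R = 0 leaves features untouched
  lone <- network_model("lone", list(
    model_element("s1", "species",
                  annotations = list(annotation("toydb", "A")))))
  Vl <- featurize(lone, build_concept_space(lone))
  Rl <- build_propagation_matrix(lone)
  expect_equal(as.matrix(feature_propagate(Vl, Rl, 1)$values),
               as.matrix(Vl$values))

  # an element receiving no information keeps w_x = v_x: with beta = 0 the
  # species rows of R are empty, so species keep their direct vectors
  Rb0 <- build_propagation_matrix(m, propagation_weights(beta = 0))
  Wb0 <- feature_propagate(V, Rb0, choose_lambda(Rb0))
  expect_equal(as.numeric(Wb0$values["a", ]), as.numeric(V$values["a", ]))
  expect_equal(as.numeric(Wb0$values["b", ]), as.numeric(V$values["b", ]))
  expect_gt(sum(Wb0$values["x", ]), 0)  # the reaction still inherits

  # divergent scaling is refused
  expect_error(feature_propagate(V, R, 10), "diverges")
})

test_that("solve and truncated series agree on random sparse instances", {
  for (seed in 1:12) {
    n <- sample(10:50, 1)
    R <- random_nonneg_sparse(n, 0.1, seed = seed)
    lam <- choose_lambda(R, 0.5)
    B <- Matrix::Matrix(matrix(runif(n * 3) * (runif(n * 3) > 0.5), n, 3),
                        sparse = TRUE)
    X <- semprop:::propagate_linear(R, B, lam)
    expect_lt(max(abs(as.matrix(X) - series_oracle(R, B, lam, 100))), 1e-8)
    resid <- X - (B + lam * (R %*% X))
    expect_lt(max(abs(resid)), 1e-9)
    expect_gt(min(X), -1e-12)  # non-negativity under non-negative inputs
  }
})

test_that("one-directional propagation on an acyclic chain terminates exactly", {
  chain <- make_linear_chain(5)
  # beta = 0: information flows only species -> reaction along a DAG
  R <- build_propagation_matrix(chain, propagation_weights(beta = 0))$matrix
  V <- featurize(chain, build_concept_space(chain))$values
  term <- as.matrix(V)
  depth <- 1  # each reaction is one step from its reactants/products
  for (k in seq_len(depth)) term <- as.matrix(R %*% term)
  expect_gt(max(abs(term)), 0)
  expect_equal(max(abs(as.matrix(R %*% term))), 0)  # term depth+1 vanishes
  # spectral radius 0 => the full series equals the finite sum
  expect_equal(spectral_radius(R), 0)
})

test_that("chain self-similarity after propagation is exactly 1 on the diagonal", {
  chain <- make_linear_chain(5)
  sp <- build_concept_space(chain)
  V <- featurize(chain, sp)
  R <- build_propagation_matrix(chain)
  W <- feature_propagate(V, R, choose_lambda(R))
  for (i in seq_along(W$element_ids)) {
    w <- as.numeric(W$values[i, ])
    if (sum(w) > 0)
      expect_equal(inferred_fp_similarity(w, w), 1)
  }
  # every species and reaction of the chain obtains a nonzero inferred vector
  types <- W$element_types
  expect_true(all(Matrix::rowSums(W$values)[types != "compartment"] > 0))
})

test_that("pair graph holds same-type pairs with product edge weights", {
  # two bare one-reaction models (no compartments): 2x2 species pairs + 1
  # reaction pair = 5 nodes
  bare <- function(mid, s1, s2, rx) {
    network_model(mid, list(
      model_element(s1, "species",
                    annotations = list(annotation("toydb", paste0(s1, "c")))),
      model_element(s2, "species",
                    annotations = list(annotation("toydb", paste0(s2, "c")))),
      model_element(rx, "reaction")
    ), data.frame(source_id = c(rx, rx), target_id = c(s1, s2),
                  role = c("reactant", "product"), stringsAsFactors = FALSE))
  }
  m <- bare("m", "a", "b", "x")
  n <- bare("n", "p", "q", "y")
  alpha <- 0.5
  RM <- build_propagation_matrix(m, propagation_weights(alpha = alpha))
  RN <- build_propagation_matrix(n, propagation_weights(alpha = alpha))
  Q <- build_pair_graph(RM, RN, unname(element_types(m)),
                        unname(element_types(n)))
  expect_equal(nrow(Q$pairs), 5)
  expect_true(all(Q$pairs$type %in% c("species", "reaction")))

  # edges into (x, y) come from (a, p) and (b, q) with weight alpha^2
  xy <- which(Q$pairs$x == "x" & Q$pairs$y == "y")
  ap <- which(Q$pairs$x == "a" & Q$pairs$y == "p")
  bq <- which(Q$pairs$x == "b" & Q$pairs$y == "q")
  expect_equal(Q$matrix[xy, ap], alpha^2)
  expect_equal(Q$matrix[xy, bq], alpha^2)

  # Q entries are exactly the products of the factor entries
  for (i in seq_len(nrow(Q$pairs))) for (j in seq_len(nrow(Q$pairs))) {
    expect_equal(Q$matrix[i, j],
                 RM$matrix[Q$pairs$x[i], Q$pairs$x[j]] *
                   RN$matrix[Q$pairs$y[i], Q$pairs$y[j]])
  }

  # zero factor matrices give a zero pair matrix
  m0 <- network_model("m0", list(model_element("s", "species")))
  R0 <- build_propagation_matrix(m0)
  Q0 <- build_pair_graph(R0, R0, "species", "species")
  expect_equal(length(Q0$matrix@x), 0)
})

test_that("similarity propagation solves its fixed point and matches the series", {
  p <- make_reaction_pair()
  sp <- build_concept_space(p)
  fm <- featurize(p$m1, sp); fn <- featurize(p$m2, sp)
  RM <- build_propagation_matrix(p$m1)
  RN <- build_propagation_matrix(p$m2)
  Q <- build_pair_graph(RM, RN, fm$element_types, fn$element_types)
  sig <- semprop:::cross_similarity(fm, fn)
  sigma <- sig[cbind(match(Q$pairs$x, fm$element_ids),
                     match(Q$pairs$y, fn$element_ids))]
  lam <- choose_lambda(Q)
  psi <- similarity_propagate(sigma, Q, lam)

  resid <- sigma + lam * as.numeric(Q$matrix %*% psi) - psi
  expect_lt(max(abs(resid)), 1e-9)  # stationary state of the diffusion
  expect_lt(max(abs(psi - as.numeric(series_oracle(Q$matrix, matrix(sigma),
                                                   lam, 100)))), 1e-8)
  expect_gt(min(psi), -1e-12)

  # Q = 0 returns sigma unchanged
  m0 <- network_model("m0", list(
    model_element("s", "species",
                  annotations = list(annotation("toydb", "A")))))
  R0 <- build_propagation_matrix(m0)
  Q0 <- build_pair_graph(R0, R0, "species", "species")
  expect_equal(similarity_propagate(0.7, Q0, 1), 0.7)
})

test_that("pair-graph size scales as the pair count, not the element count", {
  m <- make_linear_chain(6, model_id = "m6")
  n <- make_linear_chain(4, model_id = "n4")
  RM <- build_propagation_matrix(m)
  RN <- build_propagation_matrix(n)
  Q <- build_pair_graph(RM, RN, unname(element_types(m)),
                        unname(element_types(n)))
  n_pairs <- 6 * 4 + 5 * 3 + 1  # species pairs + reaction pairs + compartment
  expect_equal(nrow(Q$pairs), n_pairs)
  expect_equal(dim(Q$matrix), c(n_pairs, n_pairs))
  expect_equal(length(RM$element_ids), 12)
  expect_equal(length(RN$element_ids), 8)
})

test_that("a shared cofactor hub does not couple unrelated reactions", {
  two_rx <- function(mid, with_cofactor) {
    els <- list(
      model_element("a", "species",
                    annotations = list(annotation("toydb", "A"))),
      model_element("b", "species",
                    annotations = list(annotation("toydb", "B"))),
      model_element("c2", "species",
                    annotations = list(annotation("toydb", "C"))),
      model_element("d", "species",
                    annotations = list(annotation("toydb", "D"))),
      model_element("r1", "reaction"),
      model_element("r2", "reaction"))
    refs <- data.frame(
      source_id = c("r1", "r1", "r2", "r2"),
      target_id = c("a", "b", "c2", "d"),
      role = c("reactant", "product", "reactant", "product"),
      stringsAsFactors = FALSE)
    if (with_cofactor) {
      els <- c(els, list(model_element(
        "atp", "species",
        annotations = list(annotation("chebi", "CHEBI:15422")))))
      refs <- rbind(refs, data.frame(
        source_id = c("r1", "r2"), target_id = "atp", role = "reactant",
        stringsAsFactors = FALSE))
    }
    network_model(mid, els, refs)
  }
  for (ms in c("fp", "sp")) {
    without <- similarity_table(two_rx("m", FALSE), two_rx("n", FALSE),
                                measure = ms)
    with_c <- similarity_table(two_rx("m", TRUE), two_rx("n", TRUE),
                               measure = ms)
    expect_identical(similarity_of(with_c, "r1", "r2") -
                       similarity_of(without, "r1", "r2"), 0)
    expect_identical(similarity_of(with_c, "r1", "r2"), 0)
  }
})
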