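make_panel <- function(W, year = 2011) {
  M <- (W > 0) + 0L
  storage.mode(M) <- "integer"
  if (is.null(rownames(W))) rownames(W) <- sprintf("c%02d", seq_len(nrow(W)))
  if (is.null(colnames(W))) colnames(W) <- sprintf("p%02d", seq_len(ncol(W)))
  dimnames(M) <- dimnames(W)
  foodfitness:::new_bipartite_panel(year, rownames(W), colnames(W), M, W)
}

test_that("project builds Gram matrices on both sides and sources", {
  panel <- make_panel(rbind(A = c(1, 1, 1, 0), B = c(1, 1, 0, 0)))
  Cb <- project(panel, "country", "binary")
  expect_equal(Cb["A", "B"], 2)
  expect_equal(diag(unclass(Cb)), c(A = 3, B = 2))

  # product side is the Gram matrix of t(M)
  Pb <- project(panel, "product", "binary")
  expect_equal(unname(unclass(Pb)), unname(crossprod(panel$M + 0)),
               ignore_attr = TRUE)

  # weighted source, diagonal Gram matrix for orthogonal rows
  panel2 <- make_panel(rbind(c(2, 0), c(0, 3)))
  Cw <- project(panel2, "country", "weighted")
  expect_equal(unname(unclass(Cw)), diag(c(4, 9)), ignore_attr = TRUE)

  # Gram matrices are PSD
  set.seed(3)
  W <- matrix(runif(30), 6, 5)
  ev <- eigen(unclass(project(make_panel(W), "country")), TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("similarity implements the Dice normalization", {
  C <- matrix(c(3, 2, 2, 2), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  S <- similarity(structure(C, class = "projection_matrix"))
  expect_equal(S["A", "B"], 0.8)
  expect_equal(diag(unclass(S)), c(A = 1, B = 1))

  # identical rows give similarity 1; disjoint rows 0
  p_same <- make_panel(rbind(c(1, 2), c(1, 2)))
  S2 <- similarity(project(p_same, "country"))
  expect_equal(unname(unclass(S2)), matrix(1, 2, 2), ignore_attr = TRUE)
  p_disj <- make_panel(rbind(c(1, 0), c(0, 1)))
  expect_equal(similarity(project(p_disj, "country"))[1, 2], 0)

  # entries stay in [0, 1] on random panels
  set.seed(8)
  S3 <- unclass(similarity(project(make_panel(matrix(runif(48), 8, 6)))))
  expect_true(all(S3 >= 0 & S3 <= 1 + 1e-12))

  # zero-diagonal nodes are dropped with a warning
  W <- rbind(c(1, 1), c(0, 0))
  C0 <- structure(tcrossprod(W), class = "projection_matrix")
  expect_warning(S4 <- similarity(C0), "zero")
  expect_equal(dim(unclass(S4)), c(1, 1))
  expect_warning(similarity(structure(matrix(0, 2, 2),
                                      class = "projection_matrix")), "zero")
})

test_that("msf reproduces the worked 4-node example", {
  S <- diag(4)
  rownames(S) <- colnames(S) <- paste0("n", 1:4)
  S["n1", "n2"] <- S["n2", "n1"] <- 0.9
  S["n3", "n4"] <- S["n4", "n3"] <- 0.8
  S["n2", "n3"] <- S["n3", "n2"] <- 0.7
  S["n1", "n3"] <- S["n3", "n1"] <- 0.6
  f <- msf(S)
  expect_equal(nrow(f$edges), 2)
  expect_setequal(paste(f$edges$from, f$edges$to),
                  c("n1 n2", "n3 n4"))
  expect_equal(length(unique(f$membership)), 2)
  expect_equal(as.integer(sort(table(f$membership))), c(2L, 2L))
  # the rejected edge (n2, n3) would have merged the two sub-trees;
  # plain Kruskal accepts it
  fk <- msf(S, rule = "kruskal")
  expect_equal(nrow(fk$edges), 3)
  expect_equal(length(unique(fk$membership)), 1)
})

test_that("msf trivial cases and tie-breaking are deterministic", {
  S2 <- matrix(c(1, .5, .5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f2 <- msf(S2)
  expect_equal(nrow(f2$edges), 1)
  expect_equal(length(unique(f2$membership)), 1)

  # all-zero off-diagonal: edgeless forest of singletons
  f0 <- msf(diag(3))
  expect_equal(nrow(f0$edges), 0)
  expect_equal(length(unique(f0$membership)), 3)

  # tie-break: equal weights resolved by lexicographic endpoint pair
  S4 <- diag(4)
  rownames(S4) <- colnames(S4) <- c("d", "c", "b", "a")
  S4[lower.tri(S4)] <- 0.5
  S4[upper.tri(S4)] <- t(S4)[upper.tri(S4)]
  f4 <- msf(S4)
  expect_equal(f4$edges$from[1], "a")
  expect_equal(f4$edges$to[1], "b")
  # relabeling nodes permutes but does not restructure the forest
  perm <- c(4, 3, 2, 1)
  f4b <- msf(S4[perm, perm])
  expect_equal(sort(paste(f4b$edges$from, f4b$edges$to)),
               sort(paste(f4$edges$from, f4$edges$to)))
})

test_that("forest invariants hold on random similarity matrices", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    W <- matrix(rexp(n * 6), n, 6) * rbinom(n * 6, 1, 0.7)
    keep <- rowSums(W) > 0
    W <- W[keep, , drop = FALSE]
    if (nrow(W) < 3) next
    rownames(W) <- sprintf("n%02d", seq_len(nrow(W)))
    S <- similarity(structure(tcrossprod(W), class = "projection_matrix"))
    f <- msf(S)
    n_nodes <- length(f$nodes)
    n_comp <- length(unique(f$membership))
    # edge/component identity <=> acyclicity for a forest
    expect_equal(nrow(f$edges), n_nodes - n_comp)
    # acceptance rule: replaying the edge list, one endpoint was always
    # isolated at acceptance time
    deg <- setNames(integer(n_nodes), f$nodes)
    for (e in seq_len(nrow(f$edges))) {
      expect_true(deg[f$edges$from[e]] == 0 || deg[f$edges$to[e]] == 0)
      deg[f$edges$from[e]] <- deg[f$edges$from[e]] + 1L
      deg[f$edges$to[e]] <- deg[f$edges$to[e]] + 1L
    }
    # every node with a positive candidate edge ends attached under the
    # isolated-endpoint rule only if its first scanned edge found an
    # isolated endpoint; at minimum, isolated nodes must have had no
    # positive similarity to anyone
    isolated <- names(deg)[deg == 0]
    for (nd in isolated) {
      expect_true(all(unclass(S)[nd, setdiff(f$nodes, nd)] == 0))
    }
  }
})

test_that("components filters sub-trees by size", {
  S <- diag(6)
  labs <- paste0("n", 1:6)
  dimnames(S) <- list(labs, labs)
  link <- function(i, j, w) S[i, j] <<- S[j, i] <<- w
  link(1, 2, .9); link(2, 3, .8); link(3, 4, .7)  # chain of 4 via n2? no:
  # isolated rule: (1,2) accepted, (2,3) accepted (3 isolated),
  # (3,4) accepted (4 isolated) -> one 4-node sub-tree
  link(5, 6, .6)
  f <- msf(S)
  expect_equal(length(components(f, min_size = 2)), 2)
  big <- components(f, min_size = 4)
  expect_equal(length(big), 1)
  expect_setequal(big[[1]]$members, paste0("n", 1:4))
  expect_equal(length(components(f, min_size = 5)), 0)
  # singletons never appear at min_size >= 2
  expect_false(any(vapply(components(f, 2),
                          function(x) length(x$members), 0L) < 2))
})

test_that("import_composition ranks normalized shares", {
  panel <- make_panel(rbind(X = c(60, 30, 10), Y = c(5, 0, 0)))
  colnames(panel$W) <- panel$products <- c("maize", "wheat", "rice")
  colnames(panel$M) <- c("maize", "wheat", "rice")
  top <- import_composition(panel, "X", top_k = 2)
  expect_equal(top$product, c("maize", "wheat"))
  expect_equal(top$share, c(0.6, 0.3))
  expect_lte(sum(top$share), 1)
  # single-product importer and top_k overflow
  expect_equal(import_composition(panel, "Y", top_k = 5)$share[1], 1)
  expect_error(import_composition(panel, "Z", 3), "unknown")
  zero <- make_panel(rbind(X = c(1, 1), Y = c(1, 0)))
  zero$W["Y", ] <- 0; zero$M["Y", ] <- 0L
  expect_error(import_composition(zero, "Y", 1), "zero imports")
})

test_that("forest writer emits a parseable edge list and DOT text", {
  S <- matrix(c(1, .4, .4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- msf(S)
  p <- tempfile()
  write_forest(f, p)
  tab <- read.delim(p)
  expect_equal(tab$from, "a")
  expect_equal(tab$weight, 0.4)
  dot <- readLines(paste0(p, ".dot"))
  expect_true(any(grepl("\"a\" -- \"b\"", dot)))
})
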