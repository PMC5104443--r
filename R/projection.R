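#' One-mode projection of a bipartite panel
#'
#' The country-side projection is the Gram matrix `C = X X^T` where `X`
#' is the weighted matrix `W` (default) or the binary matrix `M`; the
#' product side uses `X^T`. With a binary source the diagonal holds the
#' degrees (products per country / countries per product) and the
#' off-diagonal entries the overlap counts.
#'
#' @param panel A `bipartite_panel`.
#' @param side `"country"` or `"product"`.
#' @param source `"weighted"` (matrix `W`, default) or `"binary"`.
#' @return A `projection_matrix`: the symmetric positive-semidefinite
#'   Gram matrix with `side` and `source` attached as attributes.
#' @export
project <- function(panel, side = c("country", "product"),
                    source = c("weighted", "binary")) {
  side <- match.arg(side)
  source <- match.arg(source)
  X <- if (source == "weighted") panel$W else panel$M + 0
  C <- if (side == "country") tcrossprod(X) else crossprod(X)
  structure(C, side = side, source = source, class = "projection_matrix")
}

#' Dice-type similarity from a projection matrix
#'
#' `S_ij = 2 C_ij / (C_ii + C_jj)`, a symmetric matrix with entries in
#' `[0, 1]` and unit diagonal. Rows/columns with a zero diagonal (no
#' production at all) carry no information and are dropped with a
#' warning.
#'
#' @param C A `projection_matrix` (or any symmetric Gram matrix with
#'   dimnames).
#' @return A `similarity_matrix` over the retained labels.
#' @export
similarity <- function(C) {
  C <- unclass(C)
  d <- diag(C)
  if (any(d == 0)) {
    if (all(d == 0)) {
      warning("all diagonal entries are zero; empty similarity matrix")
      S <- matrix(numeric(0), 0, 0)
      return(structure(S, class = "similarity_matrix"))
    }
    warning("dropping ", sum(d == 0),
            " node(s) with zero self-projection")
    keep <- d > 0
    C <- C[keep, keep, drop = FALSE]
    d <- diag(C)
  }
  S <- 2 * C / outer(d, d, `+`)
  diag(S) <- 1
  structure(S, class = "similarity_matrix")
}

#' Maximum spanning forest of a similarity matrix
#'
#' Scans candidate edges (all unordered pairs with strictly positive
#' similarity) in decreasing weight; ties are broken by the
#' lexicographic order of the endpoint label pair, making the result
#' deterministic. Under the default `rule = "isolated"` an edge is
#' accepted only if at least one endpoint is still unattached (degree
#' zero), which splits the graph into disconnected sub-trees -- a
#' forest of tightly correlated communities. `rule = "kruskal"` instead
#' rejects only edges inside an existing component (plain maximum
#' spanning tree/forest, for comparison).
#'
#' @param S A `similarity_matrix` (any symmetric numeric matrix works;
#'   rows need labels, else `V1..Vn` are assigned).
#' @param rule Edge-acceptance rule, `"isolated"` or `"kruskal"`.
#' @return A `forest`: list with `nodes`, `edges` (data.frame
#'   `from, to, weight, component` in acceptance order), `membership`
#'   (named component id per node) and `rule`.
#' @export
msf <- function(S, rule = c("isolated", "kruskal")) {
  rule <- match.arg(rule)
  S <- unclass(S)
  n <- nrow(S)
  labs <- rownames(S)
  if (is.null(labs)) labs <- paste0("V", seq_len(n))
  cand <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  if (nrow(cand)) {
    w <- S[cand]
    a <- pmin(labs[cand[, 1]], labs[cand[, 2]])
    b <- pmax(labs[cand[, 1]], labs[cand[, 2]])
    ord <- order(-w, a, b)
    cand <- cand[ord, , drop = FALSE]
    w <- w[ord]
  } else {
    w <- numeric(0)
  }

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  deg <- integer(n)
  acc <- matrix(0L, 0, 2)
  accw <- numeric(0)
  for (e in seq_len(nrow(cand))) {
    i <- cand[e, 1]; j <- cand[e, 2]
    take <- if (rule == "isolated") {
      deg[i] == 0L || deg[j] == 0L
    } else {
      find(i) != find(j)
    }
    if (take) {
      parent[find(i)] <- find(j)
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
      acc <- rbind(acc, c(i, j))
      accw <- c(accw, w[e])
    }
  }
  comp_root <- vapply(seq_len(n), find, integer(1))
  membership <- stats::setNames(match(comp_root, unique(comp_root)), labs)
  ea <- labs[acc[, 1]]
  eb <- labs[acc[, 2]]
  edges <- data.frame(
    from = pmin(ea, eb),
    to = pmax(ea, eb),
    weight = accw,
    component = unname(membership[ea]),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = labs, edges = edges, membership = membership,
                 rule = rule), class = "forest")
}

#' @export
print.forest <- function(x, ...) {
  cat(sprintf("forest (%s rule): %d nodes, %d edges, %d components\n",
              x$rule, length(x$nodes), nrow(x$edges),
              length(unique(x$membership))))
  invisible(x)
}

#' Sub-trees of a forest above a minimum size
#'
#' @param forest A `forest` from [msf()].
#' @param min_size Smallest component reported (default 4, so
#'   singleton and pair sub-trees are hidden as in typical forest
#'   figures).
#' @return List of components, largest first; each has `members`
#'   (labels) and `edges` (the sub-tree's rows of the edge table).
#' @export
components <- function(forest, min_size = 4) {
  ids <- unique(forest$membership)
  out <- lapply(ids, function(id) {
    members <- sort(names(forest$membership)[forest$membership == id])
    list(members = members,
         edges = forest$edges[forest$edges$component == id, , drop = FALSE])
  })
  out <- out[vapply(out, function(x) length(x$members), 0L) >= min_size]
  out[order(-vapply(out, function(x) length(x$members), 0L))]
}

#' Top import shares of one country
#'
#' Normalises a country's row of an import panel's weighted matrix to
#' shares of its total per-capita import volume and returns the largest
#' `top_k` products.
#'
#' @param panel A `bipartite_panel` built from import records.
#' @param country Country label; must import something.
#' @param top_k Number of products to return (capped at the number of
#'   products).
#' @return data.frame with columns `product` and `share`, sorted by
#'   decreasing share.
#' @export
import_composition <- function(panel, country, top_k = 3) {
  if (!country %in% panel$countries) {
    stop("unknown country: ", country)
  }
  row <- panel$W[match(country, panel$countries), ]
  tot <- sum(row)
  if (tot <= 0) stop("country ", country, " has zero imports")
  share <- row / tot
  ord <- order(-share, panel$products)
  k <- min(top_k, length(ord))
  data.frame(product = panel$products[ord[seq_len(k)]],
             share = unname(share[ord[seq_len(k)]]),
             stringsAsFactors = FALSE)
}

#' Export a forest as an edge-list TSV and a DOT graph
#'
#' @param forest A `forest`.
#' @param path Path of the edge-list TSV (`node_i, node_j, weight,
#'   component_id`); the DOT text goes to `<path>.dot`.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path) {
  e <- forest$edges
  e$weight <- sprintf("%.17g", e$weight)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dot <- c("graph forest {",
           paste0("  \"", forest$nodes, "\";"),
           sprintf("  \"%s\" -- \"%s\" [weight=%s];",
                   forest$edges$from, forest$edges$to, e$weight),
           "}")
  writeLines(dot, paste0(path, ".dot"))
  invisible(path)
}
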