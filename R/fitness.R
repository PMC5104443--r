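#' One step of the coupled fitness-specialization map
#'
#' From the previous normalized state `(F, Q)` the intermediates are
#' \deqn{\tilde F_c = \sum_p W_{cp} Q_p, \qquad
#'       \tilde Q_p = 1 / \sum_c W_{cp} (1 / F_c),}
#' both computed from the previous state simultaneously, and each
#' vector is then divided by its arithmetic mean so that `mean(F) =
#' mean(Q) = 1` after every iteration. Country fitness thus aggregates
#' a country's basket weighted by product specialization, while a
#' product's specialization is suppressed by every low-fitness country
#' able to produce it.
#'
#' For the reciprocal in the `Q` update, fitness values are floored at
#' `1e-15` (components of this map are known to decay towards zero);
#' the reported `F` itself is never floored.
#'
#' @param W Non-negative weighted matrix with no all-zero row/column.
#' @param state List with numeric `F` (length `nrow(W)`) and `Q`
#'   (length `ncol(W)`); use `fitness_init(W)` for the all-ones start.
#' @return A state list with updated `F`, `Q`, the pre-normalization
#'   `F_raw`, `Q_raw`, and the incremented `iteration` counter.
#' @export
fitness_step <- function(W, state) {
  if (any(state$F == 0)) stop("zero fitness in previous state")
  F_raw <- as.vector(W %*% state$Q)
  Q_raw <- 1 / as.vector(crossprod(W, 1 / pmax(state$F, 1e-15)))
  list(F = F_raw / mean(F_raw),
       Q = Q_raw / mean(Q_raw),
       F_raw = F_raw, Q_raw = Q_raw,
       iteration = state$iteration + 1L)
}

fitness_init <- function(W, init = c("ones", "random")) {
  init <- match.arg(init)
  n <- nrow(W); m <- ncol(W)
  if (init == "ones") {
    F0 <- rep(1, n); Q0 <- rep(1, m)
  } else {
    F0 <- stats::rlnorm(n); Q0 <- stats::rlnorm(m)
    F0 <- F0 / mean(F0); Q0 <- Q0 / mean(Q0)
  }
  list(F = F0, Q = Q0, F_raw = F0, Q_raw = Q0, iteration = 0L)
}

#' Fixed point of the fitness-specialization map
#'
#' Iterates [fitness_step()] from the all-ones initial condition (or a
#' random positive one) until the sup-norm change of both normalized
#' vectors falls below `tolerance`, or `max_iter` is reached. The map
#' has a unique attractive fixed point for any positive initial
#' condition, so the starting point only affects the iteration count.
#'
#' All-zero rows (countries producing nothing) and columns (products
#' produced by no one) are removed before iterating -- an empty product
#' column would make the `Q` update divide by zero -- and reported in
#' the result.
#'
#' @param W Non-negative weighted matrix, typically `panel$W`; dimnames
#'   are carried through to the result.
#' @param tolerance Convergence threshold on
#'   `max(||dF||_inf, ||dQ||_inf)`; default `1e-10`.
#' @param max_iter Iteration cap, default 10000.
#' @param init `"ones"` (default) or `"random"`.
#' @param seed Seed used when `init = "random"`.
#' @return A `fitness_result`: list with named vectors `F`, `Q`,
#'   `converged`, `n_iterations`, `delta_final`, `dropped_countries`,
#'   `dropped_products` and the final `state`.
#' @export
fitness_fixed_point <- function(W, tolerance = 1e-10, max_iter = 10000,
                                init = c("ones", "random"), seed = 1) {
  init <- match.arg(init)
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be non-negative")
  if (is.null(rownames(W))) rownames(W) <- paste0("c", seq_len(nrow(W)))
  if (is.null(colnames(W))) colnames(W) <- paste0("p", seq_len(ncol(W)))
  keep_r <- rowSums(W) > 0
  keep_c <- colSums(W) > 0
  dropped_countries <- rownames(W)[!keep_r]
  dropped_products <- colnames(W)[!keep_c]
  W <- W[keep_r, keep_c, drop = FALSE]
  if (nrow(W) == 0 || ncol(W) == 0) stop("no non-zero rows/columns left")

  if (init == "random") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  state <- fitness_init(W, init)
  delta <- Inf
  converged <- FALSE
  log_delta <- numeric(0)
  for (it in seq_len(max_iter)) {
    nxt <- fitness_step(W, state)
    delta <- max(max(abs(nxt$F - state$F)), max(abs(nxt$Q - state$Q)))
    log_delta[it] <- delta
    state <- nxt
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    F = stats::setNames(state$F, rownames(W)),
    Q = stats::setNames(state$Q, colnames(W)),
    state = state,
    converged = converged,
    n_iterations = state$iteration,
    delta_final = delta,
    delta_trace = log_delta,
    dropped_countries = dropped_countries,
    dropped_products = dropped_products,
    tolerance = tolerance
  ), class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("fitness_result: %d countries, %d products; %s after %d iterations (delta %.3g)\n",
              length(x$F), length(x$Q),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$delta_final))
  if (length(x$dropped_countries) || length(x$dropped_products)) {
    cat(sprintf("  dropped all-zero: %d countries, %d products\n",
                length(x$dropped_countries), length(x$dropped_products)))
  }
  invisible(x)
}

#' Rank a named score vector
#'
#' Rank 1 is the largest value when `descending = TRUE`. Ties share the
#' minimum rank; the returned table lists tied labels in lexicographic
#' order.
#'
#' @param values Named finite numeric vector.
#' @param descending Rank largest first (default `TRUE`).
#' @return data.frame `label, value, rank` in display order.
#' @export
rank_scores <- function(values, descending = TRUE) {
  if (length(values) == 0) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  labs <- names(values)
  if (is.null(labs)) labs <- as.character(seq_along(values))
  key <- if (descending) -values else values
  r <- rank(key, ties.method = "min")
  ord <- order(r, labs)
  data.frame(label = labs[ord], value = unname(values[ord]),
             rank = unname(r[ord]), stringsAsFactors = FALSE)
}

#' Fitness fixed points across a panel series
#'
#' Runs [fitness_fixed_point()] independently for each year's panel and
#' aligns the results into long tables.
#'
#' @param panels List of `bipartite_panel` objects (one per year).
#' @param tolerance,max_iter Passed through.
#' @return A `fitness_trajectory`: list with `results` (per-year
#'   `fitness_result`, named by year), long data.frames `F_table`
#'   (`country, year, F`) and `Q_table` (`product, year, Q`).
#' @export
fitness_trajectory <- function(panels, tolerance = 1e-10,
                               max_iter = 10000) {
  stopifnot(length(panels) >= 1)
  years <- vapply(panels, function(p) p$year, integer(1))
  res <- lapply(panels, function(p) {
    fitness_fixed_point(p$W, tolerance = tolerance, max_iter = max_iter)
  })
  names(res) <- years
  bind <- function(field, key) {
    do.call(rbind, lapply(seq_along(res), function(i) {
      v <- res[[i]][[field]]
      df <- data.frame(names(v), years[i], unname(v),
                       stringsAsFactors = FALSE)
      names(df) <- c(key, "year", field)
      df
    }))
  }
  structure(list(results = res,
                 F_table = bind("F", "country"),
                 Q_table = bind("Q", "product")),
            class = "fitness_trajectory")
}

#' Percent change of a score between two years
#'
#' @param trajectory A `fitness_trajectory`.
#' @param label Country (side `"country"`) or product label.
#' @param from,to Years present in the trajectory.
#' @param side `"country"` (uses `F`) or `"product"` (uses `Q`).
#' @return Percent change, e.g. `-25` for a drop from 2.0 to 1.5.
#' @export
percent_change <- function(trajectory, label, from, to,
                           side = c("country", "product")) {
  side <- match.arg(side)
  tab <- if (side == "country") trajectory$F_table else trajectory$Q_table
  key <- names(tab)[1]
  val <- names(tab)[3]
  pick <- function(y) {
    v <- tab[tab[[key]] == label & tab$year == y, val]
    if (length(v) != 1) stop(label, " not present in year ", y)
    v
  }
  100 * (pick(to) - pick(from)) / pick(from)
}

#' Write ranked fitness tables
#'
#' Emits `<prefix>_countries.tsv` (`country, F, rank`),
#' `<prefix>_products.tsv` (`product, Q, rank`) and a convergence log
#' `<prefix>_convergence.tsv` (`iteration, delta`). Dropped all-zero
#' labels are appended with empty value and rank after all ranked rows.
#'
#' @param result A `fitness_result`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_fitness <- function(result, prefix) {
  paths <- paste0(prefix, c("_countries.tsv", "_products.tsv",
                            "_convergence.tsv"))
  emit <- function(values, dropped, key, val, path) {
    tab <- rank_scores(values)
    names(tab) <- c(key, val, "rank")
    tab[[val]] <- sprintf("%.17g", tab[[val]])
    if (length(dropped)) {
      tab <- rbind(tab, data.frame(stats::setNames(
        list(sort(dropped), "", ""), names(tab))))
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  emit(result$F, result$dropped_countries, "country", "F", paths[1])
  emit(result$Q, result$dropped_products, "product", "Q", paths[2])
  conv <- data.frame(iteration = seq_along(result$delta_trace),
                     delta = sprintf("%.6g", result$delta_trace))
  utils::write.table(conv, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
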