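#' Row and column degrees of a binary matrix
#'
#' `k_country[c]` is the number of products country `c` produces (row
#' sum); `k_product[p]` the number of countries producing product `p`
#' (column sum).
#'
#' @param M Binary matrix (0/1), typically `panel$M`.
#' @return List with integer vectors `k_country` and `k_product`.
#' @export
degrees <- function(M) {
  M <- check_binary(M)
  list(k_country = as.integer(rowSums(M)),
       k_product = as.integer(colSums(M)))
}

#' Overlap matrix of a binary bipartite matrix
#'
#' Counts of shared partners between pairs of rows (country side,
#' `o_ij = sum_p M_ip M_jp`) or pairs of columns (product side). The
#' diagonal holds the degrees.
#'
#' @param M Binary matrix.
#' @param side `"country"` (rows) or `"product"` (columns).
#' @return Symmetric integer matrix.
#' @export
overlap <- function(M, side = c("country", "product")) {
  side <- match.arg(side)
  M <- check_binary(M)
  o <- if (side == "country") tcrossprod(M) else crossprod(M)
  storage.mode(o) <- "integer"
  o
}

check_binary <- function(M) {
  M <- as.matrix(M)
  if (!all(M %in% c(0, 1))) stop("matrix is not binary")
  storage.mode(M) <- "double"
  M
}

#' NODF nestedness of a binary bipartite matrix
#'
#' Nestedness based on overlap and decreasing fill, on the 0-1 scale.
#' For every unordered pair `i < j` within one side, the pair
#' contributes `T_ij = o_ij / min(k_i, k_j)` unless the two degrees are
#' equal, in which case it contributes 0; the sum over both sides is
#' divided by `C(C-1)/2 + P(P-1)/2`. Zero-degree rows/columns are kept:
#' their pairs contribute 0 (equal-degree rule when both are zero,
#' zero overlap otherwise).
#'
#' The default `variant = "symmetric"` evaluates the formula exactly as
#' written, with unordered pairs and the min-degree denominator. The
#' `"classic"` variant instead walks the matrix in its given row/column
#' order and zeroes any pair whose fill does not strictly decrease
#' (`k_i <= k_j` for `i` before `j`): the original NODF definition,
#' useful for cross-checking against reference implementations on
#' degree-sorted matrices. The two variants coincide when rows and
#' columns are sorted by decreasing degree.
#'
#' @param M Binary matrix with at least 2 rows and 2 columns.
#' @param variant `"symmetric"` (as the defining formula prints) or
#'   `"classic"` (order-sensitive decreasing-fill rule).
#' @param percent Multiply by 100 for display on the conventional
#'   0-100 scale.
#' @return A single numeric value in `[0, 1]` (or `[0, 100]`).
#' @export
nodf <- function(M, variant = c("symmetric", "classic"), percent = FALSE) {
  variant <- match.arg(variant)
  M <- check_binary(M)
  if (nrow(M) < 2 || ncol(M) < 2) {
    stop("NODF needs at least 2 rows and 2 columns")
  }
  val <- (nodf_side(M, variant) + nodf_side(t(M), variant)) /
    (choose(nrow(M), 2) + choose(ncol(M), 2))
  if (percent) 100 * val else val
}

# Sum of T_ij over unordered row pairs of M.
nodf_side <- function(M, variant) {
  k <- rowSums(M)
  o <- tcrossprod(M)
  n <- nrow(M)
  iu <- which(upper.tri(o))
  ki <- k[row(o)[iu]]
  kj <- k[col(o)[iu]]
  tij <- numeric(length(iu))
  mn <- pmin(ki, kj)
  # mn == 0 forces o_ij == 0: the pair contributes 0, never 0/0
  ok <- (if (variant == "symmetric") ki != kj else ki > kj) & mn > 0
  tij[ok] <- o[iu][ok] / mn[ok]
  sum(tij)
}

#' Significance of observed nestedness against a random null ensemble
#'
#' Draws `n_null` random binary matrices with the same dimensions and
#' the same number of links as `M` ([simulate_random_panel()]),
#' computes their NODF, and reports the empirical upper-tail
#' probability with the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_null + 1)` together with the
#' z-score `(obs - mean_null) / sd_null`.
#'
#' @param M Binary matrix.
#' @param n_null Ensemble size (default 100).
#' @param seed RNG seed for the ensemble.
#' @param variant Passed to [nodf()].
#' @return A `nestedness_result`: list with `nodf_observed`,
#'   `nodf_null` (numeric vector), `p_empirical`, `z_score` (`NA` when
#'   the null ensemble is degenerate), `n_null`, `seed`.
#' @export
nodf_significance <- function(M, n_null = 100, seed = 1,
                              variant = "symmetric") {
  stopifnot(n_null >= 1)
  M <- check_binary(M)
  obs <- nodf(M, variant = variant)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    nodf(simulate_random_panel(nrow(M), ncol(M), sum(M))$M,
         variant = variant)
  }, numeric(1))
  sdn <- stats::sd(nulls)
  z <- if (n_null < 2 || sdn == 0) NA_real_ else (obs - mean(nulls)) / sdn
  structure(list(
    nodf_observed = obs,
    nodf_null = nulls,
    p_empirical = (1 + sum(nulls >= obs)) / (n_null + 1),
    z_score = z,
    n_null = n_null,
    seed = seed
  ), class = "nestedness_result")
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("NODF = %.4f vs %d-network null: mean %.4f, sd %.4f\n",
              x$nodf_observed, x$n_null, mean(x$nodf_null),
              stats::sd(x$nodf_null)))
  cat(sprintf("empirical p = %.4g, z = %s\n", x$p_empirical,
              ifelse(is.na(x$z_score), "undefined",
                     sprintf("%.2f", x$z_score))))
  invisible(x)
}

#' Write a nestedness result as a flat report plus null-ensemble TSV
#'
#' @param result A `nestedness_result`.
#' @param path Path of the key-value report; the null ensemble goes to
#'   `<path>.null.tsv` as one column.
#' @return `path`, invisibly.
#' @export
write_nestedness <- function(result, path) {
  kv <- c(nodf_observed = sprintf("%.17g", result$nodf_observed),
          null_mean = sprintf("%.17g", mean(result$nodf_null)),
          null_sd = sprintf("%.17g", stats::sd(result$nodf_null)),
          p_empirical = sprintf("%.17g", result$p_empirical),
          z_score = sprintf("%.17g", result$z_score),
          n_null = result$n_null,
          seed = result$seed)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  writeLines(c("nodf_null", sprintf("%.17g", result$nodf_null)),
             paste0(path, ".null.tsv"))
  invisible(path)
}
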