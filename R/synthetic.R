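#' Simulate a bipartite panel with planted nested structure
#'
#' Generates a country-product world with known ground truth. Each
#' country gets a latent capability `f*_c` and each product a latent
#' difficulty `q*_p`, both i.i.d. log-normal. A country produces a
#' product with probability `1 - noise` when its capability meets the
#' product's difficulty (`f*_c >= q*_p`) and with probability `noise`
#' otherwise; at `noise = 0` this hard-threshold rule yields a perfectly
#' nested binary matrix. Production volumes for realised links are
#' `persons * exp(Normal(0, volume_sigma^2))` tonnes, so the per-capita
#' weights are log-normal with log-scale `volume_sigma`. Populations are
#' drawn uniformly on `pop_range`, above the half-million inclusion
#' filter by default.
#'
#' @param n_countries,n_products Matrix dimensions (>= 2). Defaults
#'   177 x 157, the scale of a world production table.
#' @param noise Flip probability in `[0, 0.5]`; default 0.05.
#' @param volume_sigma Log-scale of per-capita volumes; default 1.
#' @param seed RNG seed; identical seeds give bit-identical worlds.
#' @param capability_sdlog Log-sd of the capability/difficulty draws
#'   (default 1).
#' @param pop_range Population range in persons, default
#'   `c(6e5, 1e8)`.
#' @param year Year label attached to the panel (default 2011).
#' @return A `planted_world`: list with `capabilities` (named, by
#'   country), `difficulties` (named, by product), `panel`
#'   (a [bipartite_panel][build_panel]), `population` (named persons
#'   vector), `seed` and `params`.
#' @export
simulate_panel <- function(n_countries = 177, n_products = 157,
                           noise = 0.05, volume_sigma = 1, seed = 1,
                           capability_sdlog = 1,
                           pop_range = c(6e5, 1e8), year = 2011) {
  stopifnot(n_countries >= 2, n_products >= 2)
  if (noise < 0 || noise > 0.5) stop("noise must lie in [0, 0.5]")
  stopifnot(volume_sigma > 0, length(pop_range) == 2, pop_range[1] > 0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  countries <- sprintf("C%03d", seq_len(n_countries))
  products <- sprintf("P%03d", seq_len(n_products))
  f_star <- stats::setNames(stats::rlnorm(n_countries, 0, capability_sdlog),
                            countries)
  q_star <- stats::setNames(stats::rlnorm(n_products, 0, capability_sdlog),
                            products)
  able <- outer(f_star, q_star, `>=`)
  p_link <- ifelse(able, 1 - noise, noise)
  M <- (matrix(stats::runif(n_countries * n_products),
               n_countries, n_products) < p_link) + 0L
  storage.mode(M) <- "integer"
  dimnames(M) <- list(countries, products)

  persons <- stats::setNames(
    stats::runif(n_countries, pop_range[1], pop_range[2]), countries)
  W <- matrix(0, n_countries, n_products,
              dimnames = list(countries, products))
  nlink <- sum(M)
  if (nlink) {
    W[M == 1L] <- exp(stats::rnorm(nlink, 0, volume_sigma))
  }

  panel <- new_bipartite_panel(year, countries, products, M, W)
  structure(list(
    capabilities = f_star,
    difficulties = q_star,
    panel = panel,
    population = persons,
    seed = seed,
    params = list(n_countries = n_countries, n_products = n_products,
                  noise = noise, volume_sigma = volume_sigma,
                  capability_sdlog = capability_sdlog,
                  pop_range = pop_range, year = year)
  ), class = "planted_world")
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("planted_world: seed %d, noise %.3f\n", x$seed,
              x$params$noise))
  print(x$panel)
  invisible(x)
}

#' Simulate a random bipartite panel with a fixed number of links
#'
#' Places exactly `n_links` ones uniformly at random (without
#' replacement) in an `n_countries x n_products` binary matrix: the
#' null model of "links placed at random" with the same size and
#' connectivity as an observed network.
#'
#' @param n_countries,n_products Matrix dimensions.
#' @param n_links Number of links, `0 <= n_links <= n_countries *
#'   n_products`.
#' @param seed Optional RNG seed; `NULL` uses the current RNG stream
#'   (so an ensemble can be drawn inside one seeded run).
#' @param year Year label attached to the panel (default 0).
#' @return A `bipartite_panel` whose `W` equals `M` (unit weights).
#' @export
simulate_random_panel <- function(n_countries, n_products, n_links,
                                  seed = NULL, year = 0) {
  n_cells <- n_countries * n_products
  if (n_links < 0 || n_links > n_cells) {
    stop("n_links must lie in [0, ", n_cells, "]")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  M <- integer(n_cells)
  M[sample.int(n_cells, n_links)] <- 1L
  M <- matrix(M, n_countries, n_products,
              dimnames = list(sprintf("C%03d", seq_len(n_countries)),
                              sprintf("P%03d", seq_len(n_products))))
  new_bipartite_panel(year, rownames(M), colnames(M), M, M + 0)
}

#' Write a planted world's ground truth to two-column TSVs
#'
#' Saves `<prefix>_capabilities.tsv` (country, f_star) and
#' `<prefix>_difficulties.tsv` (product, q_star) with full precision.
#'
#' @param world A `planted_world`.
#' @param prefix Path prefix for the two files.
#' @return The two paths, invisibly.
#' @export
write_ground_truth <- function(world, prefix) {
  paths <- paste0(prefix, c("_capabilities.tsv", "_difficulties.tsv"))
  side <- list(world$capabilities, world$difficulties)
  key <- c("country", "product")
  val <- c("f_star", "q_star")
  for (i in 1:2) {
    df <- data.frame(names(side[[i]]), sprintf("%.17g", side[[i]]))
    names(df) <- c(key[i], val[i])
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

# Save/restore the global RNG state so seeded generators do not
# perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
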