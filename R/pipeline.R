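#' Build a validated pipeline run configuration
#'
#' A flat configuration for [run_pipeline()]. Either point `production`
#' (and optionally `imports`) plus `population` at record files, or set
#' `simulate = TRUE` to analyse a synthetic planted world instead.
#'
#' @param production,imports,population Paths to record files
#'   ([read_records()] dialects); `imports` may be `NA`.
#' @param simulate Analyse a [simulate_panel()] world instead of files.
#' @param n_countries,n_products,noise,volume_sigma Generator settings
#'   used when `simulate = TRUE`.
#' @param years Integer vector of years to analyse (a simulated world
#'   has a single year, taken from the generator).
#' @param min_pop Population inclusion threshold, strict (default
#'   500000 persons).
#' @param n_null Null-ensemble size for nestedness (default 100).
#' @param tolerance,max_iter Fitness convergence settings.
#' @param msf_rule `"isolated"` or `"kruskal"` ([msf()]).
#' @param source Projection source, `"weighted"` or `"binary"`.
#' @param gof_boot Bootstrap replicates for distribution GOF inside the
#'   pipeline (default 0 = skip; fits themselves are always computed).
#' @param seed Master RNG seed recorded in the manifest.
#' @param out_dir Output directory (created if missing).
#' @param strict Treat fitness non-convergence as an error.
#' @return A `run_config` list.
#' @export
run_config <- function(production = NA, imports = NA, population = NA,
                       simulate = FALSE, n_countries = 20, n_products = 15,
                       noise = 0.05, volume_sigma = 1, years = NULL,
                       min_pop = 5e5, n_null = 100, tolerance = 1e-10,
                       max_iter = 10000, msf_rule = "isolated",
                       source = "weighted", gof_boot = 0, seed = 1,
                       out_dir = "ff_out", strict = FALSE) {
  cfg <- list(production = production, imports = imports,
              population = population, simulate = isTRUE(simulate) ||
                identical(simulate, "TRUE") || identical(simulate, "true"),
              n_countries = as.integer(n_countries),
              n_products = as.integer(n_products),
              noise = as.numeric(noise),
              volume_sigma = as.numeric(volume_sigma),
              years = if (is.null(years)) NULL else as.integer(years),
              min_pop = as.numeric(min_pop), n_null = as.integer(n_null),
              tolerance = as.numeric(tolerance),
              max_iter = as.integer(max_iter),
              msf_rule = match.arg(msf_rule, c("isolated", "kruskal")),
              source = match.arg(source, c("weighted", "binary")),
              gof_boot = as.integer(gof_boot), seed = as.integer(seed),
              out_dir = out_dir,
              strict = isTRUE(strict) || identical(strict, "TRUE") ||
                identical(strict, "true"))
  stopifnot(cfg$min_pop >= 0, cfg$n_null >= 1, cfg$tolerance > 0,
            cfg$max_iter >= 1, cfg$gof_boot >= 0)
  if (cfg$noise < 0 || cfg$noise > 0.5) stop("noise must lie in [0, 0.5]")
  if (!cfg$simulate && (is.na(cfg$production) || is.na(cfg$population))) {
    stop("need production and population paths unless simulate = TRUE")
  }
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment; `years` may be a comma-separated list. Unknown keys are an
#' error. Values given in `overrides` (e.g. parsed CLI flags) take
#' precedence over the file, which takes precedence over defaults.
#'
#' @param path Config file path, or `NA` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A `run_config`.
#' @export
read_config <- function(path = NA, overrides = list()) {
  vals <- list()
  if (!is.na(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) stop("cannot parse config line: ", ln)
      vals[[m[2]]] <- trimws(m[3])
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$years) && is.character(vals$years)) {
    vals$years <- as.integer(strsplit(vals$years, ",")[[1]])
  }
  do.call(run_config, vals)
}

config_hash <- function(cfg) {
  # out_dir is where the run lands, not what it computes
  cfg <- cfg[sort(setdiff(names(cfg), "out_dir"))]
  flat <- vapply(cfg, function(v) {
    paste(format(v, digits = 17), collapse = ",")
  }, character(1))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(flat), flat, sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_stage <- function(stage, year, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed for year ", year, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' For each year: builds (or simulates) the production panel, writes its
#' binary and weighted matrices, runs the NODF null-ensemble
#' significance test, extracts country and product spanning forests
#' (production, and imports when available), computes the fitness /
#' specialization fixed point with ranked output tables, and fits the
#' degree distributions (three-parameter Weibull) and the fitness and
#' specialization distributions (log-normal). A `MANIFEST.json` listing
#' every artifact with its MD5 checksum, the configuration, its hash
#' and the seed is written last; reruns with an identical configuration
#' are byte-identical.
#'
#' @param config A `run_config` from [run_config()] / [read_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)

  if (cfg$simulate) {
    world <- simulate_panel(cfg$n_countries, cfg$n_products,
                            noise = cfg$noise,
                            volume_sigma = cfg$volume_sigma,
                            seed = cfg$seed)
    panels <- list(world$panel)
    import_panels <- list(NULL)
    years <- world$panel$year
    write_ground_truth(world, file.path(cfg$out_dir, "ground_truth"))
  } else {
    prod <- read_records(cfg$production, "production")
    popl <- read_records(cfg$population, "population")
    impr <- if (!is.na(cfg$imports)) read_records(cfg$imports, "import")
    years <- if (is.null(cfg$years)) sort(unique(prod$year)) else cfg$years
    missing_years <- setdiff(years, unique(prod$year))
    if (length(missing_years)) {
      stop("year(s) not present in production data: ",
           paste(missing_years, collapse = ", "))
    }
    panels <- lapply(years, function(y) {
      rec <- filter_countries(prod, popl, cfg$min_pop, y)
      build_panel(rec, popl, y)
    })
    import_panels <- lapply(years, function(y) {
      if (is.null(impr)) return(NULL)
      rec <- filter_countries(impr, popl, cfg$min_pop, y)
      build_panel(rec, popl, y)
    })
  }

  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  for (i in seq_along(years)) {
    y <- years[i]
    panel <- panels[[i]]
    pre <- file.path(cfg$out_dir, sprintf("year%04d", y))

    pipeline_stage("panel", y, {
      write_matrix(panel, paste0(pre, "_M.tsv"), "binary")
      write_matrix(panel, paste0(pre, "_W.tsv"), "weighted")
      emit(paste0(pre, "_M.tsv")); emit(paste0(pre, "_W.tsv"))
    })

    pipeline_stage("nestedness", y, {
      nst <- nodf_significance(panel$M, n_null = cfg$n_null,
                               seed = cfg$seed + y)
      write_nestedness(nst, paste0(pre, "_nestedness.txt"))
      emit(paste0(pre, "_nestedness.txt"))
      emit(paste0(pre, "_nestedness.txt.null.tsv"))
    })

    pipeline_stage("msf", y, {
      for (side in c("country", "product")) {
        S <- similarity(project(panel, side, cfg$source))
        fo <- msf(S, rule = cfg$msf_rule)
        p <- paste0(pre, "_forest_", side, ".tsv")
        write_forest(fo, p)
        emit(p); emit(paste0(p, ".dot"))
      }
      if (!is.null(import_panels[[i]])) {
        S <- similarity(project(import_panels[[i]], "country", cfg$source))
        p <- paste0(pre, "_forest_import_country.tsv")
        write_forest(msf(S, rule = cfg$msf_rule), p)
        emit(p); emit(paste0(p, ".dot"))
      }
    })

    fit_res <- pipeline_stage("fitness", y, {
      fr <- fitness_fixed_point(panel$W, tolerance = cfg$tolerance,
                                max_iter = cfg$max_iter)
      if (!fr$converged && cfg$strict) {
        stop("fitness map did not converge in ", cfg$max_iter,
             " iterations")
      }
      write_fitness(fr, paste0(pre, "_fitness"))
      emit(paste0(pre, "_fitness_countries.tsv"))
      emit(paste0(pre, "_fitness_products.tsv"))
      emit(paste0(pre, "_fitness_convergence.tsv"))
      fr
    })

    pipeline_stage("fitdist", y, {
      deg <- degrees(panel$M)
      sets <- list(k_country = deg$k_country, k_product = deg$k_product,
                   fitness = unname(fit_res$F),
                   specialization = unname(fit_res$Q))
      fams <- c(k_country = "weibull3", k_product = "weibull3",
                fitness = "lognormal", specialization = "lognormal")
      for (nm in names(sets)) {
        smp <- sets[[nm]]
        if (fams[[nm]] == "lognormal") smp <- smp[smp > 0]
        ft <- tryCatch(
          fit_dist(smp, fams[[nm]], n_boot = cfg$gof_boot,
                   seed = cfg$seed + y),
          error = function(e) NULL)
        p <- paste0(pre, "_fit_", nm, ".txt")
        if (is.null(ft)) {
          writeLines(c("family\tunfit", paste0("reason\t",
                       "sample unsuitable for ", fams[[nm]], " fit")), p)
          emit(p)
        } else {
          write_fit(ft, smp, p)
          emit(p); emit(paste0(p, ".ccdf.tsv"))
        }
      }
    })
  }

  rel <- sub(paste0("^", cfg$out_dir, "/?"), "", artifacts)
  sums <- tools::md5sum(artifacts)
  manifest <- list(
    package = "foodfitness",
    config = cfg[sort(setdiff(names(cfg), "out_dir"))],
    config_hash = hash,
    seed = cfg$seed,
    years = years,
    artifacts = data.frame(path = rel, md5 = unname(sums))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
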