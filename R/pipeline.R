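# End-to-end orchestration: load -> project -> overlap -> rates -> density
# -> ensemble test -> summaries, with a reproducibility manifest.

#' Build and validate a pipeline run configuration
#'
#' A flat key/value configuration (supply a YAML file or a named list);
#' every default is pinned here and echoed into the run manifest so that
#' no analysis choice stays implicit.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated `run_config` list.  Keys: `trees`, `ranges` (paths),
#'   `out_dir`, `coords` ("lonlat" or "planar"), `filter` (list of
#'   [filter_spec()] arguments or NULL), `include_self`, `area_scale`,
#'   `n_sim`, `alpha`, `trait_transform`, `rate_transform`, `seed`,
#'   `max_trees`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(coords = "planar", filter = NULL, include_self = FALSE,
                   area_scale = 1, n_sim = 100, alpha = 0.05,
                   trait_transform = "log_shift", rate_transform = "log",
                   seed = 1L, max_trees = 100L)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("trees", "ranges", "out_dir")) {
    if (is.null(config[[k]])) stop("config is missing required key '", k, "'")
  }
  for (k in c("trees", "ranges")) {
    if (!file.exists(config[[k]])) stop("config path does not exist: ", config[[k]])
  }
  if (config$n_sim < 1) stop("n_sim must be >= 1")
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must be in (0, 1)")
  structure(config, class = "run_config")
}

# deterministic FNV-1a hash of the analysis-relevant config (the output
# location does not change what is computed) for a reproducible run id
config_run_id <- function(config) {
  keys <- unclass(config)
  keys$out_dir <- NULL
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(keys)),
                           collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low + bitwXor(as.integer(low), as.integer(b %% 256)))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("run-%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_tsv_stamped <- function(df, path, run_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# run_id: ", run_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the whole clade-density pipeline
#'
#' Executes load, projection (for geographic coordinates), overlap matrix,
#' full-tree lambda-DR, clade density with top-decile selection, and the
#' topology-ensemble ES-sim test; writes every stage output (TSV/GeoJSON,
#' stamped with a deterministic run id) plus `manifest.json` to the output
#' directory.  The manifest (config echo, input checksums, seeds, stage
#' record counts and wall-clock, versions) is written even when a stage
#' fails; downstream stages are then skipped.
#'
#' @param config a [run_config()] (or something accepted by it).
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (`ranges`, `overlap`, `rates`, `density`, `ensemble`).
#' @export
run_all <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_id <- config_run_id(config)
  manifest <- list(
    run_id = run_id,
    config = unclass(config),
    checksums = as.list(tools::md5sum(c(config$trees, config$ranges))),
    versions = list(r = R.version.string,
                    cladedensity = as.character(utils::packageVersion("cladedensity")),
                    ape = as.character(utils::packageVersion("ape"))),
    stages = list()
  )
  state <- list()
  failed <- FALSE
  finish <- function() {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(config$out_dir, "manifest.json"))
  }
  stage <- function(name, fun) {
    if (failed) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    rec <- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
      failed <<- TRUE
      warning("stage '", name, "' failed: ", rec$error,
              "; downstream stages skipped")
    }
    manifest$stages[[name]] <<- utils::modifyList(
      manifest$stages[[name]] %||% list(), rec)
    res
  }

  r <- stage("load", function() {
    rs <- load_ranges(config$ranges,
                      filters = if (is.null(config$filter)) filter_spec()
                                else do.call(filter_spec, config$filter),
                      projection = config$coords)
    if (rs$projection == "lonlat") rs <- project_equal_area(rs)
    manifest$stages$load$n_species <<- length(rs$species)
    manifest$stages$load$dropped_species <<- rs$report$dropped_species
    rs
  })
  if (!failed) state$ranges <- r

  O <- stage("overlap", function() {
    O <- compute_overlap_matrix(state$ranges)
    long <- data.frame(
      species_a = rownames(O)[row(O)[upper.tri(O)]],
      species_b = colnames(O)[col(O)[upper.tri(O)]],
      overlap = O[upper.tri(O)])
    write_tsv_stamped(long, file.path(config$out_dir, "overlap.tsv"), run_id)
    write_tsv_stamped(range_size_table(O),
                      file.path(config$out_dir, "range_sizes.tsv"), run_id)
    manifest$stages$overlap$n_pairs_positive <<- sum(long$overlap > 0)
    O
  })
  if (!failed) state$overlap <- O

  trees <- stage("trees", function() {
    tr <- read_newick(config$trees)
    if (inherits(tr, "phylo")) tr <- list(tr)
    if (length(tr) > config$max_trees) tr <- tr[seq_len(config$max_trees)]
    manifest$stages$trees$n_trees <<- length(tr)
    tr
  })
  if (!failed) state$trees <- trees

  rates <- stage("rates", function() {
    rates <- dr_statistic(state$trees[[1]])
    write_tsv_stamped(rates, file.path(config$out_dir, "rates.tsv"), run_id)
    rates
  })
  if (!failed) state$rates <- rates

  density <- stage("density", function() {
    tree <- state$trees[[1]]
    al <- align_species(state$overlap, phylo_vcv(tree))
    cd <- clade_density(al$overlap, al$vcv,
                        include_self = config$include_self,
                        area_scale = config$area_scale)
    sel <- suppressWarnings(top_decile(cd))
    cd$rank <- rank(-cd$clade_density, ties.method = "min")
    cd$top_decile <- cd$species %in% sel
    write_tsv_stamped(cd, file.path(config$out_dir, "density.tsv"), run_id)
    export_top_decile_geo(state$ranges, as.character(sel),
                          file.path(config$out_dir, "top_decile.geojson"),
                          table = cd)
    manifest$stages$density$n_species <<- nrow(cd)
    manifest$stages$density$dropped_geography <<- al$dropped_geography
    manifest$stages$density$dropped_tree <<- al$dropped_tree
    cd
  })
  if (!failed) state$density <- density

  ens <- stage("test", function() {
    ens <- run_ensemble(state$trees, state$overlap,
                        n_sim = config$n_sim, seed = config$seed,
                        alpha = config$alpha,
                        include_self = config$include_self,
                        area_scale = config$area_scale,
                        trait_transform = config$trait_transform,
                        rate_transform = config$rate_transform)
    write_tsv_stamped(ens$records,
                      file.path(config$out_dir, "ensemble.tsv"), run_id)
    manifest$stages$test$n_records <<- nrow(ens$records)
    manifest$stages$test$fraction_significant <<- ens$summary$fraction_significant
    ens
  })
  if (!failed) state$ensemble <- ens

  finish()
  invisible(list(manifest = manifest, config = config, state = state))
}

#' Human-readable summary of a pipeline run
#'
#' Prints (and saves as `report.txt`) the clade-density quantile table, the
#' ensemble slope distribution, the fraction of topologies significant at
#' alpha, and the species dropped at alignment.
#'
#' @param run the list returned by [run_all()].
#' @return the report lines, invisibly.
#' @export
report <- function(run) {
  st <- run$state
  lines <- c(sprintf("Clade-density pipeline report (%s)", run$manifest$run_id))
  if (is.null(st$density) || !nrow(st$density)) {
    lines <- c(lines, "No species with geography: clade density unavailable.")
  } else {
    s <- summarize_density(st$density)
    lines <- c(lines,
      sprintf("Species with clade density: %d", s$n),
      sprintf("Clade density quantiles: min %.4g | Q1 %.4g | median %.4g | Q3 %.4g | max %.4g",
              s$min, s$q25, s$median, s$q75, s$max),
      sprintf("Whiskers (Tukey): lower %.4g, upper %.4g", s$lower_whisker, s$upper_whisker),
      sprintf("Top-decile species: %d", sum(st$density$top_decile)))
    dg <- run$manifest$stages$density$dropped_geography
    if (length(dg)) {
      lines <- c(lines, sprintf("Dropped (no geography): %s", paste(dg, collapse = ", ")))
    }
  }
  if (!is.null(st$ensemble)) {
    sm <- st$ensemble$summary
    if (sm$n_trees > 1) {
      sq <- sm$slope_quantiles
      lines <- c(lines,
        sprintf("Ensemble: %d topologies (%d analysed)", sm$n_trees, sm$n_ok),
        sprintf("Slope distribution: min %.4g | median %.4g | max %.4g (%d positive, %d negative%s)",
                sq[[1]], sq[[3]], sq[[5]], sm$n_slope_positive, sm$n_slope_negative,
                if (sm$n_slope_positive > 0 && sm$n_slope_negative > 0)
                  "; spans zero" else ""),
        sprintf("Fraction of topologies significant at alpha = %.2f: %.3f",
                sm$alpha, sm$fraction_significant))
    } else {
      r1 <- st$ensemble$records[1, ]
      lines <- c(lines, sprintf(
        "Single topology: rho = %.4f, slope = %.4g, p = %.4f",
        r1$rho, r1$slope, r1$p))
    }
  }
  writeLines(lines, file.path(run$config$out_dir, "report.txt"))
  cat(lines, sep = "\n")
  invisible(lines)
}
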