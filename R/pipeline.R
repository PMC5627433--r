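#' Run the specificity pipeline end to end
#'
#' Chains the analysis stages in dependency order: `filter` (length +
#' greedy redundancy), `entropy`, `distance`, `prominent`, `summary`
#' (coverage and cross-protease proportions) and `pca`. Each stage writes a
#' plain-text table into `outdir`, and every run writes `manifest.json`
#' recording parameters, seed, input checksum and package version so the
#' outputs are reproducible: stage outputs are pure functions of (input,
#' parameters, seed).
#'
#' @param config A named list, or path to a YAML/JSON file holding one.
#'   Recognised fields: `input` (window TSV; required unless `simulate`
#'   runs first), `outdir` (required), `stages` (character vector, default
#'   all), `threshold` (greedy filter, default 0.875), `min_residues`
#'   (default 2), `reps` (default 1000), `alpha` (default 0.05), `seed`
#'   (default 1), `background` (`"per_position"`/`"pooled"`),
#'   `distance_format` (`"csv"`/`"phylip"`), and `simulate` (a
#'   [synthetic_spec()] argument list for the optional simulate stage).
#' @return Invisibly, a named character vector of output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(stages = c("filter", "entropy", "distance", "prominent",
                              "summary", "pca"),
                   threshold = 0.875, min_residues = 2L, reps = 1000L,
                   alpha = 0.05, seed = 1L, background = "per_position",
                   distance_format = "csv")
  cfg <- utils::modifyList(defaults, config)
  valid <- c("simulate", "filter", "entropy", "distance", "prominent",
             "summary", "pca")
  if (!all(cfg$stages %in% valid))
    stop(sprintf("unknown stage '%s'; valid stages: %s",
                 setdiff(cfg$stages, valid)[1], paste(valid, collapse = ", ")),
         call. = FALSE)
  if (is.null(cfg$outdir)) stop("config must name 'outdir'", call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  path <- function(f) file.path(cfg$outdir, f)

  if ("simulate" %in% cfg$stages) {
    if (is.null(cfg$simulate))
      stop("simulate stage requires a 'simulate' spec in the config",
           call. = FALSE)
    spec <- do.call(synthetic_spec, cfg$simulate)
    write_substrate_table(generate_substrate_set(spec), path("synthetic.tsv"))
    out["synthetic"] <- path("synthetic.tsv")
    if (is.null(cfg$input)) cfg$input <- path("synthetic.tsv")
  }
  if (is.null(cfg$input)) stop("config must name 'input'", call. = FALSE)
  if (!file.exists(cfg$input))
    stop(sprintf("input not found: %s", cfg$input), call. = FALSE)
  sets <- read_substrate_table(cfg$input)

  if ("filter" %in% cfg$stages) {
    sets <- lapply(sets, function(s)
      greedy_filter(min_length_filter(s, cfg$min_residues), cfg$threshold))
    write_substrate_table(sets, path("filtered.tsv"))
    out["filtered"] <- path("filtered.tsv")
  }
  profiles <- NULL
  if (any(c("entropy", "distance", "pca") %in% cfg$stages)) {
    profiles <- lapply(sets, entropy_profile)
    write_entropy_table(profiles, path("entropies.tsv"))
    out["entropies"] <- path("entropies.tsv")
  }
  if ("distance" %in% cfg$stages) {
    f <- if (cfg$distance_format == "phylip") "dist.phy" else "dist.csv"
    write_matrix(distance_matrix(profiles), path(f), cfg$distance_format)
    out["distance"] <- path(f)
  }
  records <- NULL
  if (any(c("prominent", "summary") %in% cfg$stages)) {
    records <- lapply(sets, find_prominent, reps = cfg$reps,
                      alpha = cfg$alpha, seed = cfg$seed,
                      background = cfg$background)
    utils::write.table(do.call(rbind, lapply(records, as.data.frame)),
                       path("prominent.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out["prominent"] <- path("prominent.tsv")
  }
  if ("summary" %in% cfg$stages) {
    cov <- do.call(rbind, lapply(names(sets), function(id)
      cbind(protease_id = id,
            substrate_coverage(sets[[id]], records[[id]]))))
    utils::write.table(cov, path("coverage.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out["coverage"] <- path("coverage.tsv")
    prop <- protease_block_proportions(records)
    utils::write.table(
      data.frame(block = names(prop), proportion_pct = sprintf("%.3f", prop)),
      path("proportions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    out["proportions"] <- path("proportions.tsv")
  }
  if ("pca" %in% cfg$stages) {
    if (length(profiles) < 2L)
      stop("pca stage needs at least two proteases", call. = FALSE)
    write_pca(pca_correlation(entropy_matrix(profiles)), path("pca.tsv"))
    out["pca"] <- path("pca.tsv")
  }

  manifest <- list(
    package = "blockspec",
    version = as.character(utils::packageVersion("blockspec")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input = cfg$input,
    input_md5 = unname(tools::md5sum(cfg$input)),
    parameters = cfg[c("stages", "threshold", "min_residues", "reps",
                       "alpha", "seed", "background", "distance_format")],
    outputs = as.list(out))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  out["manifest"] <- path("manifest.json")
  invisible(out)
}
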