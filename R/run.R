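# Subcommand dispatcher behind the command-line entry point: configuration
# handling, stage seeding, TSV artifacts and a machine-readable run manifest.

#' Default run configuration
#'
#' All defaults mirror the published analysis settings: 75 top-variance genes
#' per tissue, 15 gamma values on [1, 4], 200 partitions entering the
#' consensus, 100 localization randomizations, specialist threshold 0.5, eQTL
#' co-expression threshold 0.5, and generalist genes kept when present in at
#' least 3 tissues.
#'
#' @return named list of settings.
#' @export
default_config <- function() {
  list(
    expression = character(0),      # paths, one per layer
    format = "tsv",
    annotation = NULL,
    eqtl = NULL,
    k = 75,
    gamma_min = 1,
    gamma_max = 4,
    gamma_points = 15,
    n_consensus = 200,
    n_rand = 100,
    specialist_threshold = 0.5,
    eqtl_rho_threshold = 0.5,
    min_layers = 3,
    significance_divisor = "per_layer_samples",
    seed = 1,
    out_dir = "mlcoexp_out"
  )
}

load_config <- function(config) {
  base <- default_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_mlc("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_mlc("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop_mlc("reading JSON configs requires the jsonlite package")
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_mlc("config must be a list or a file path")
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0)
    stop_mlc("unknown config field(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

write_manifest <- function(cfg, outdir, stage) {
  man <- list(
    package = "mlcoexp",
    version = as.character(utils::packageVersion("mlcoexp")),
    stage = stage,
    seed = cfg$seed,
    config = cfg,
    config_hash = fnv1a(paste(names(cfg), vapply(cfg, function(v)
      paste(format(v), collapse = ","), character(1)), collapse = ";"))
  )
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(man, file = path)
  }
  invisible(path)
}

read_layers_from_config <- function(cfg) {
  if (length(cfg$expression) == 0)
    stop_mlc("config error: no expression files given")
  missing <- cfg$expression[!file.exists(cfg$expression)]
  if (length(missing) > 0)
    stop_mlc("config error: input file not found: %s", missing[1])
  lapply(cfg$expression, read_expression, format = cfg$format)
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (write a planted synthetic data set), `build`
#' (multilayer correlation object summary), `sweep` (CHAMP sweep table),
#' `detect` (build + sweep + consensus at the selected resolutions +
#' significance + specialist profiles), `significance` and `metrics` (only
#' those tables), `localize` (per-community chromosome localization), `eqtl`
#' (shared-eQTL pairs in the first layer). Each
#' subcommand writes TSV artifacts and a JSON run manifest into
#' `config$out_dir`.
#'
#' @param subcommand one of `simulate`, `build`, `sweep`, `detect`,
#'   `significance`, `metrics`, `localize`, `eqtl`.
#' @param config named list or path of a YAML/JSON file; unset fields take
#'   [default_config()] values.
#' @return (invisibly) the output directory.
#' @export
mlc_run <- function(subcommand = c("simulate", "build", "sweep", "detect",
                                   "significance", "metrics",
                                   "localize", "eqtl"),
                    config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- seq(cfg$gamma_min, cfg$gamma_max, length.out = cfg$gamma_points)

  if (subcommand == "simulate") {
    design <- planted_design(seed = cfg$seed)
    layers <- generate_expression(design)
    for (ly in layers)
      write_expression(ly, file.path(cfg$out_dir,
                                     paste0(ly$tissue_label, ".tsv")))
    ann <- generate_annotation(design)
    write_stats(as.data.frame(ann), file.path(cfg$out_dir, "annotation.tsv"))
    write_stats(generate_eqtl(design), file.path(cfg$out_dir, "eqtl.tsv"))
    truth <- supra_partition(planted_truth(design) + 1L, design$gene_ids,
                             design$layer_labels, renumber = FALSE)
    write_partition(truth, file.path(cfg$out_dir, "truth_partition.tsv"))
    write_manifest(cfg, cfg$out_dir, "simulate")
    return(invisible(cfg$out_dir))
  }

  layers <- read_layers_from_config(cfg)

  if (subcommand == "build") {
    mlc <- build_multilayer(layers, k = cfg$k)
    write_stats(data.frame(layer = mlc$layer_labels,
                           samples = mlc$sample_counts$per_layer),
                file.path(cfg$out_dir, "layers.tsv"))
    write_stats(data.frame(gene_id = mlc$gene_ids),
                file.path(cfg$out_dir, "selected_genes.tsv"))
    write_manifest(cfg, cfg$out_dir, "build")
    return(invisible(cfg$out_dir))
  }

  fit <- multilayer_communities(
    layers, k = cfg$k, gamma_grid = grid, n_consensus = cfg$n_consensus,
    seed = cfg$seed, specialist_threshold = cfg$specialist_threshold)

  if (subcommand == "sweep") {
    write_stats(fit$sweep$champ$domains,
                file.path(cfg$out_dir, "champ_domains.tsv"))
    write_manifest(cfg, cfg$out_dir, "sweep")
    return(invisible(cfg$out_dir))
  }

  if (subcommand %in% c("detect", "significance", "metrics")) {
    if (subcommand == "detect")
      write_stats(fit$sweep$champ$domains,
                  file.path(cfg$out_dir, "champ_domains.tsv"))
    for (res in fit$results) {
      tag <- sprintf("gamma%.3g", res$gamma)
      if (subcommand == "detect")
        write_partition(res$partition,
                        file.path(cfg$out_dir, paste0("partition_", tag,
                                                      ".tsv")))
      if (subcommand %in% c("detect", "significance"))
        write_stats(res$significance,
                    file.path(cfg$out_dir, paste0("significance_", tag,
                                                  ".tsv")))
      if (subcommand %in% c("detect", "metrics"))
        write_stats(res$profiles,
                    file.path(cfg$out_dir, paste0("profiles_", tag, ".tsv")))
    }
    write_manifest(cfg, cfg$out_dir, subcommand)
    return(invisible(cfg$out_dir))
  }

  if (subcommand == "localize") {
    if (is.null(cfg$annotation))
      stop_mlc("config error: 'annotation' is required for localize")
    ann <- read_annotation(cfg$annotation)
    res1 <- fit$results[[1]]
    p <- res1$partition
    universe <- fit$mlc$gene_ids
    rows <- lapply(sort(unique(p$labels)), function(cc) {
      prof <- specialist_profile(p, cc)
      cls <- classify_communities(list(prof), cfg$specialist_threshold)
      genes <- if (cls == "generalist")
        generalist_gene_filter(p, cc, cfg$min_layers)
      else unique(p$gene_ids[node_gene(p, community_nodes(p, cc))])
      if (length(genes) < 2) return(NULL)
      loc <- localization_test(genes, ann, universe, n_rand = cfg$n_rand,
                               seed = derive_seed(cfg$seed, "localize", cc))
      data.frame(community = cc, n_genes = length(genes), x_c = loc$x_c,
                 z_x = loc$z_x, d_c = loc$d_c, z_d = loc$z_d)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    write_stats(do.call(rbind, rows),
                file.path(cfg$out_dir, "localization.tsv"))
    write_manifest(cfg, cfg$out_dir, "localize")
    return(invisible(cfg$out_dir))
  }

  # eqtl
  if (is.null(cfg$eqtl)) stop_mlc("config error: 'eqtl' table is required")
  eq <- read_eqtl(cfg$eqtl)
  pairs <- shared_eqtl_pairs(fit$mlc$rho[[1]], eq,
                             threshold = cfg$eqtl_rho_threshold)
  write_stats(pairs, file.path(cfg$out_dir, "shared_eqtl_pairs.tsv"))
  write_manifest(cfg, cfg$out_dir, "eqtl")
  invisible(cfg$out_dir)
}
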