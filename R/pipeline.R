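#' Pipeline run configuration
#'
#' Collects paths, thresholds and seeds for the command-style entry points.
#' Threshold defaults are the study conventions: relative resolution >= 5,
#' absolute connectivity >= 50, significance level 0.05. Every command
#' writes the resolved configuration as JSON next to its outputs, and all
#' randomness flows from the seeds recorded here.
#'
#' @param out_dir output directory.
#' @param stacks data frame (or NULL) describing input stacks: columns
#'   `path`, optionally `voxel_size` (mm), `side`, `head_mask`,
#'   `cortex_mask`, `specimen`, `juvenile`.
#' @param tree_file Newick file for the analysis stage.
#' @param trait_file trait CSV for the analysis stage.
#' @param voxel_size default voxel size (mm) when a stack has no own value
#'   and no sidecar.
#' @param min_resolution,min_conn,alpha quality and significance thresholds.
#' @param n_directions MIL direction count.
#' @param bh_family `"per_trait"` or `"global"` correction family.
#' @param lambda `"REML"`, `"ML"` or fixed Pagel's lambda.
#' @param seed master seed.
#' @param sim_spec a [simulation_spec()] for `cmd_simulate`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = ".", stacks = NULL, tree_file = NULL,
                       trait_file = NULL, voxel_size = NULL,
                       min_resolution = 5, min_conn = 50, alpha = 0.05,
                       n_directions = 512L,
                       bh_family = c("per_trait", "global"),
                       lambda = "REML", seed = 1L, sim_spec = NULL) {
  bh_family <- match.arg(bh_family)
  structure(list(out_dir = out_dir, stacks = stacks, tree_file = tree_file,
                 trait_file = trait_file, voxel_size = voxel_size,
                 min_resolution = min_resolution, min_conn = min_conn,
                 alpha = alpha, n_directions = as.integer(n_directions),
                 bh_family = bh_family, lambda = lambda,
                 seed = as.integer(seed), sim_spec = sim_spec),
            class = "run_config")
}

write_resolved_config <- function(config, name) {
  cfg <- config
  cfg$stacks <- NULL
  cfg$sim_spec <- if (!is.null(config$sim_spec))
    lapply(unclass(config$sim_spec), function(v)
      if (is.matrix(v)) as.data.frame(v) else v)
  jsonlite::write_json(cfg, file.path(config$out_dir, name),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
}

run_log <- function(config) file.path(config$out_dir, "run.log")

log_line <- function(config, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  cat(msg, "\n", sep = "", file = run_log(config), append = TRUE)
  message(msg)
}

header_checksum <- function(path) {
  header <- readLines(path, n = 1L)
  tmp <- tempfile()
  writeLines(header, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Simulate a full synthetic study (tree, traits, optional phantoms)
#'
#' Writes `tree.nwk`, `traits.csv` and the resolved configuration to the
#' output directory; deterministic under the configured seed.
#'
#' @param config a [run_config()]; `config$sim_spec` defaults to
#'   `simulation_spec(seed = config$seed)`.
#' @param phantoms optional list of [phantom_spec()]s to render as TIFF
#'   stacks with JSON sidecars.
#' @return Invisibly, the `trab_simulation`.
#' @export
cmd_simulate <- function(config, phantoms = NULL) {
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE))
    stop("cannot create output directory ", config$out_dir)
  spec <- config$sim_spec
  if (is.null(spec)) spec <- simulation_spec(seed = config$seed)
  sim <- simulate_comparative_dataset(spec)
  ape::write.tree(sim$tree, file.path(config$out_dir, "tree.nwk"))
  traits_path <- file.path(config$out_dir, "traits.csv")
  write.csv(sim$traits, traits_path, row.names = FALSE)
  config$sim_spec <- spec
  write_resolved_config(config, "simulate_config.json")
  log_line(config, "simulate: ", nrow(sim$traits), " species; traits.csv ",
           "header md5 ", header_checksum(traits_path))
  for (ph in phantoms) {
    gen <- generate_phantom(ph)
    write_stack(gen$volume,
                file.path(config$out_dir, paste0("phantom_", ph$kind,
                                                 ".tif")),
                sidecar = list(spec = unclass(ph)[c("kind", "grid_shape",
                                                    "voxel_size", "seed")],
                               truth = gen$truth))
  }
  invisible(sim)
}

#' Measure per-specimen morphometry from image stacks
#'
#' For every stack: read, binarize if grayscale (skipped and logged for
#' binary input), purify, optionally select the cubic VOI from head and
#' cortex masks, compute the full morphometric summary and the quality
#' record. Failed-QC rows are retained with `qc_passed = FALSE`; exclusion
#' happens at the analysis stage.
#'
#' @param config a [run_config()] with a `stacks` table.
#' @return The per-specimen data frame (also written to
#'   `morphometry.csv`).
#' @export
cmd_measure <- function(config) {
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE))
    stop("cannot create output directory ", config$out_dir)
  st <- config$stacks
  if (is.null(st) || !nrow(st)) stop("config$stacks is empty")
  rows <- list()
  for (i in seq_len(nrow(st))) {
    path <- st$path[i]
    vs <- if (!is.null(st$voxel_size)) st$voxel_size[i] else NA_real_
    if (is.na(vs)) vs <- NULL  # fall back to sidecar
    vol <- tryCatch(read_stack(path, voxel_size = vs),
                    error = function(e) {
                      if (is.null(vs) && is.null(config$voxel_size))
                        stop("missing voxel size for ", path, call. = FALSE)
                      read_stack(path, voxel_size = config$voxel_size)
                    })
    side <- if (!is.null(st$side)) st$side[i] else "left"
    specimen <- if (!is.null(st$specimen)) st$specimen[i] else
      basename(path)
    if (inherits(vol, "gray_volume")) {
      vol <- binarize(vol)
      log_line(config, "measure ", specimen, ": binarized (",
               vol$provenance$threshold_method, " threshold ",
               vol$provenance$threshold, ")")
    } else {
      log_line(config, "measure ", specimen,
               ": binary input, binarize skipped")
    }
    vol <- purify(vol)
    if (!is.null(st$head_mask) && !is.na(st$head_mask[i])) {
      head <- read_stack(st$head_mask[i], voxel_size = vol$voxel_size)
      cortex <- if (!is.null(st$cortex_mask) && !is.na(st$cortex_mask[i]))
        read_stack(st$cortex_mask[i], voxel_size = vol$voxel_size) else NULL
      voi <- fit_max_cube(head, cortex)
      vol <- extract_voi(vol, voi)
      vl <- voi$vl
    } else {
      vl <- dim(vol$data)[1] * vol$voxel_size
    }
    sm <- summarize_morphometry(vol, side = side,
                                n_directions = config$n_directions,
                                mil_seed = config$seed)
    qc <- qc_filter(sm, config$min_resolution, config$min_conn)
    row <- as.data.frame(sm)
    row$specimen <- specimen
    row$vl <- vl
    row$juvenile <- if (!is.null(st$juvenile)) st$juvenile[i] else FALSE
    row$qc_passed <- qc$passed && !row$juvenile
    row$qc_reasons <- paste(c(qc$reasons,
                              if (row$juvenile) "juvenile specimen"),
                            collapse = "; ")
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out_path <- file.path(config$out_dir, "morphometry.csv")
  write.csv(out, out_path, row.names = FALSE)
  write_resolved_config(config, "measure_config.json")
  log_line(config, "measure: ", nrow(out), " specimens; morphometry.csv ",
           "header md5 ", header_checksum(out_path))
  out
}

#' Allometry and lifestyle analysis of a trait table
#'
#' Reads the trait CSV and Newick tree, keeps QC-passed rows (when a
#' `qc_passed` column is present), and writes the allometry table
#' (trait, a_iso, a_obs, p, classification) and the pairwise lifestyle
#' table (trait, pair, coefficient, raw and adjusted p). Fitted Pagel's
#' lambda values are recorded in the run log.
#'
#' @param config a [run_config()] with `trait_file` and `tree_file`.
#' @return A list with `allometry` and `pairwise` data frames.
#' @export
cmd_analyze <- function(config) {
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE))
    stop("cannot create output directory ", config$out_dir)
  if (is.null(config$trait_file) || is.null(config$tree_file))
    stop("trait_file and tree_file are required")
  traits <- read_trait_table(config$trait_file)
  tree <- ape::read.tree(config$tree_file)
  orphans <- setdiff(traits$species, tree$tip.label)
  if (length(orphans))
    stop("species absent from the tree: ", paste(orphans, collapse = ", "))
  if (!is.null(traits$qc_passed)) {
    n0 <- nrow(traits)
    traits <- traits[traits$qc_passed, , drop = FALSE]
    log_line(config, "analyze: ", n0 - nrow(traits),
             " specimens excluded by QC flags")
  }
  allo <- allometry_table(traits, tree, lambda = config$lambda,
                          alpha = config$alpha)
  pw <- lifestyle_analysis(traits, tree, family = config$bh_family,
                           alpha = config$alpha, lambda = config$lambda)
  allo_path <- file.path(config$out_dir, "allometry.csv")
  pw_path <- file.path(config$out_dir, "lifestyle_pairwise.csv")
  write.csv(allo, allo_path, row.names = FALSE)
  write.csv(pw, pw_path, row.names = FALSE)
  write_resolved_config(config, "analyze_config.json")
  for (i in seq_len(nrow(allo)))
    log_line(config, "analyze: ", allo$trait[i], " lambda_hat = ",
             signif(allo$lambda[i], 4))
  log_line(config, "analyze: allometry.csv header md5 ",
           header_checksum(allo_path))
  log_line(config, "analyze: lifestyle_pairwise.csv header md5 ",
           header_checksum(pw_path))
  list(allometry = allo, pairwise = pw)
}

#' Read a trait table CSV with optional column mapping
#'
#' Accepts the package's native schema (species, lifestyle, vl, DA, ConnD,
#' TbTh, TbSp, BVTV, BSBV) and renames any columns listed in `mapping`
#' (external name -> native name); the default mapping covers common
#' variants like `BV.TV` or `BS.BV`.
#'
#' @param path CSV path.
#' @param mapping named character vector, external -> native.
#' @return A data frame in the native schema.
#' @export
read_trait_table <- function(path,
                             mapping = c(BV.TV = "BVTV", BS.BV = "BSBV",
                                         `BV/TV` = "BVTV",
                                         `BS/BV` = "BSBV",
                                         Species = "species",
                                         Lifestyle = "lifestyle")) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hit <- names(df) %in% names(mapping)
  names(df)[hit] <- unname(mapping[names(df)[hit]])
  names(df) <- make.names(names(df))
  required <- c("species", "lifestyle", "vl")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("trait table lacks required columns: ",
         paste(miss, collapse = ", "))
  df
}
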