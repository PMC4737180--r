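.config_defaults <- list(
  track = NA_character_, events = NA_character_, fasta = NA_character_,
  motifs = NA_character_, out_dir = ".",
  flank_bp = 200, bin_size = 20, max_gap = 2, band_radius = 5,
  rows = NA, cols = NA, epochs = 30,
  alpha0 = 0.5, alphaT = 0.01, sigmaT = 0.5, theta = 1,
  K = 8, m = 50, M = 16, delta_min = 0.025,
  fdr_level = 0.05, min_edge = 0.05, n_groups = 4, min_members = 5,
  seed = 1)

#' Build a run configuration
#'
#' Flat key-value configuration shared by the pipeline stages. Unknown keys
#' are rejected. `rows`/`cols` may be left `NA`, in which case the typing
#' stage selects the cluster number with the light-weight consensus
#' procedure and uses its near-square grid.
#'
#' @param ... configuration values overriding the defaults (see
#'   `fsomtype:::.config_defaults` for the full key set: input paths,
#'   flank/bin geometry, DTW band, SOM grid and schedule, consensus
#'   parameters, FDR level, meta-grouping parameters, seed).
#' @return a `run_config` object (named list).
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown))
    stop(sprintf("run_config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.config_defaults, over)
  structure(cfg, class = "run_config")
}

#' Write / read a configuration as key=value text
#'
#' @param path config file.
#' @param config a `run_config`.
#' @export
write_config <- function(path, config) {
  keys <- names(.config_defaults)
  writeLines(sprintf("%s=%s", keys,
                     vapply(config[keys], function(v) as.character(v), character(1))),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  unknown <- setdiff(keys, names(.config_defaults))
  if (length(unknown))
    stop(sprintf("read_config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- .config_defaults
  for (i in seq_along(keys)) {
    proto <- .config_defaults[[keys[i]]]
    cfg[[keys[i]]] <- if (is.character(proto)) vals[i] else as.numeric(vals[i])
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

# config hash + seed stamp written next to every artifact set
write_run_info <- function(out_dir, config) {
  cfg_path <- file.path(out_dir, "config.txt")
  write_config(cfg_path, config)
  hash <- unname(tools::md5sum(cfg_path))
  df <- data.frame(key = c("config_hash", "seed"),
                   value = c(hash, as.character(config$seed)))
  write_report(file.path(out_dir, "run_info.tsv"), df)
}

#' Run the typing pipeline: profiles, cluster-number selection, FSOM
#'
#' Reads the methylation track and event table named in the config, builds
#' border profiles, selects the cluster number (unless `rows`/`cols` are
#' fixed), trains the flexible SOM and writes all artifacts to
#' `config$out_dir`: `profiles.tsv`, `dropped.tsv`, `selection.tsv` (when
#' run), `model.tsv`, `assignments.tsv`, `config.txt` and `run_info.tsv`
#' (config hash + seed).
#'
#' @param config a `run_config`.
#' @return invisibly, a list with `profiles`, `assignments`, `grid`, and
#'   `k_star` (NA when the grid was fixed).
#' @export
run_typing <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  track <- stage("read_track", {
    if (!file.exists(config$track)) stop(sprintf("input '%s' not found", config$track))
    read_track(config$track, config$bin_size)
  })
  events <- stage("read_events", {
    if (!file.exists(config$events)) stop(sprintf("input '%s' not found", config$events))
    read_events(config$events)
  })
  built <- stage("build_profiles",
                 build_profiles(track, events$events, config$flank_bp,
                                config$max_gap, config$bin_size))
  write_profiles(file.path(out, "profiles.tsv"), built$profiles)
  write_report(file.path(out, "dropped.tsv"), rbind(
    data.frame(event_id = events$rejected$event_id,
               reason = events$rejected$reason),
    built$dropped))

  k_star <- NA_integer_
  rows <- config$rows; cols <- config$cols
  if (is.na(rows) || is.na(cols)) {
    sel <- stage("select_k",
                 select_k_profiles(built$profiles, K = config$K, m = config$m,
                                   M = config$M, seed = config$seed,
                                   band_radius = config$band_radius,
                                   delta_min = config$delta_min))
    k_star <- sel$k_star
    write_report(file.path(out, "selection.tsv"), sel$table)
    dims <- near_square(k_star)
    rows <- dims[["rows"]]; cols <- dims[["cols"]]
  }
  fit <- stage("fsom",
               fsom(built$profiles, rows, cols, epochs = config$epochs,
                    seed = config$seed, alpha0 = config$alpha0,
                    alphaT = config$alphaT, sigmaT = config$sigmaT,
                    theta = config$theta, band_radius = config$band_radius))
  write_som_grid(file.path(out, "model.tsv"), fit$grid)
  write_assignments(file.path(out, "assignments.tsv"), fit$assignments)
  write_run_info(out, config)
  invisible(list(profiles = built$profiles, assignments = fit$assignments,
                 grid = fit$grid, k_star = k_star))
}

#' Run the association stage
#'
#' Tests per-cluster property associations (all numeric event columns)
#' and, when a FASTA of border sequences and a motif list are configured,
#' motif enrichment/depletion. Writes `property_report.tsv` and
#' `motif_report.tsv` into `config$out_dir`.
#'
#' @param config a `run_config`; `out_dir` must contain `assignments.tsv`
#'   from [run_typing()].
#' @return invisibly, list with `properties` and `motifs` (NULL when not
#'   run).
#' @export
run_association <- function(config) {
  out <- config$out_dir
  asg_path <- file.path(out, "assignments.tsv")
  if (!file.exists(asg_path))
    stop("stage 'association' failed: assignments.tsv not found; run run_typing first",
         call. = FALSE)
  assignments <- read_assignments(asg_path)
  events <- stage("read_events", read_events(config$events))$events
  prop <- stage("association_report",
                association_report(assignments, events,
                                   level = config$fdr_level))
  write_report(file.path(out, "property_report.tsv"), prop)
  mot <- NULL
  if (!is.na(config$fasta) && !is.na(config$motifs)) {
    mot <- stage("motif_report", {
      seqs <- Biostrings::readDNAStringSet(config$fasta)
      motifs <- read_motifs(config$motifs)
      motif_report(assignments, seqs, motifs, level = config$fdr_level)
    })
    write_report(file.path(out, "motif_report.tsv"), mot)
  }
  invisible(list(properties = prop, motifs = mot))
}

#' Run the cross-sample meta-grouping stage
#'
#' Pools per-sample cluster median profiles, meta-clusters them into
#' super-groups and writes `dendrogram.nwk`, `groups.tsv`, `edges.tsv` and
#' `ratios.tsv` into `out_dir`.
#'
#' @param samples named list (>= 2 samples) of lists with paths
#'   `assignments` and `profiles` (as written by [run_typing()]).
#' @param out_dir output directory.
#' @param n_groups number of super-groups (default 4).
#' @param min_members minimal cluster size for a median (default 5).
#' @param min_edge minimal reported sharing fraction (default 0.05).
#' @return invisibly, list with `grouping`, `sharing`.
#' @export
run_meta <- function(samples, out_dir, n_groups = 4L, min_members = 5L,
                     min_edge = 0.05) {
  if (length(samples) < 2L)
    stop("stage 'meta' failed: need >= 2 samples", call. = FALSE)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("stage 'meta' failed: samples must be named", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  medians <- list()
  asgs <- list()
  for (s in names(samples)) {
    asg <- read_assignments(samples[[s]]$assignments)
    prof <- read_profiles(samples[[s]]$profiles)
    med <- median_profiles(asg, prof, min_members, sample_id = s)
    medians <- c(medians, med$medians)
    asgs[[s]] <- asg
  }
  grouping <- stage("meta_cluster", meta_cluster(medians, n_groups))
  write_dendrogram(file.path(out_dir, "dendrogram.nwk"), grouping)
  write_report(file.path(out_dir, "groups.tsv"), grouping$groups)
  memberships <- lapply(names(samples), function(s)
    supergroup_membership(asgs[[s]], grouping, s))
  names(memberships) <- names(samples)
  sharing <- stage("membership_sharing",
                   membership_sharing(memberships, min_edge))
  write_report(file.path(out_dir, "edges.tsv"), sharing$edges)
  write_report(file.path(out_dir, "ratios.tsv"), sharing$ratios)
  invisible(list(grouping = grouping, sharing = sharing,
                 memberships = memberships))
}
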