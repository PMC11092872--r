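# Configuration, output files and the top-level run() dispatcher.
#
# Configs are flat YAML documents that round-trip losslessly through
# read_config()/write_config().  Every output file carries the seed and a
# config checksum in '#' comment headers, so a result can always be traced
# to the exact run that produced it.

#' Build a run configuration
#'
#' @param mode one of `"full"`, `"minimal"`, `"polymer"`, `"meanfield"`,
#'   `"analyze"`, `"enumerate"`.
#' @param dims lattice dimensions (simulation modes).
#' @param params list of [model_params()] arguments.
#' @param schedule list with `sweeps`, `equil`, `meas_every`.
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @param segments optional list `list(types =, counts =, delta =)`.
#' @param meanfield list of [mean_field_params()] arguments (meanfield
#'   mode).
#' @param scan list `list(axis =, from =, to =, step =)` (meanfield mode).
#' @param n_reservoir reservoir size (full mode).
#' @param enumerate list `list(start =, end =, n_max =)` (enumerate mode).
#' @param trajectory path of a trajectory to analyze (analyze mode).
#' @param collect_frames write trajectory frames (simulation modes).
#' @return a validated `run_config` list.
#' @export
run_config <- function(mode, dims = c(64L, 64L, 64L), params = list(),
                       schedule = list(sweeps = 1000L, equil = 0L,
                                       meas_every = 10L),
                       seed = 1L, out_dir = ".", segments = NULL,
                       meanfield = list(), scan = NULL, n_reservoir = 0L,
                       enumerate = NULL, trajectory = NULL,
                       collect_frames = FALSE) {
  cfg <- list(mode = mode, dims = as.integer(dims), params = params,
              schedule = schedule, seed = as.integer(seed), out_dir = out_dir,
              segments = segments, meanfield = meanfield, scan = scan,
              n_reservoir = as.integer(n_reservoir), enumerate = enumerate,
              trajectory = trajectory, collect_frames = collect_frames)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (!cfg$mode %in% c("full", "minimal", "polymer", "meanfield", "analyze",
                       "enumerate"))
    bad <- c(bad, "mode")
  sch <- cfg$schedule
  if (cfg$mode %in% c("full", "minimal", "polymer")) {
    if (is.null(sch$sweeps) || sch$sweeps < 1) bad <- c(bad, "schedule.sweeps")
    if (!is.null(sch$meas_every) && sch$meas_every < 1)
      bad <- c(bad, "schedule.meas_every")
    if (length(cfg$dims) != 3 || any(cfg$dims < 2)) bad <- c(bad, "dims")
  }
  if (cfg$mode == "meanfield" && !is.null(cfg$scan)) {
    if (!all(c("axis", "from", "to", "step") %in% names(cfg$scan)))
      bad <- c(bad, "scan")
  }
  if (cfg$mode == "analyze" && is.null(cfg$trajectory))
    bad <- c(bad, "trajectory")
  if (length(bad))
    stop("invalid configuration keys: ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

# order-independent checksum of the config document (FNV-style, 32 bit)
config_checksum <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  b <- utf8ToInt(s)
  h <- 2166136261
  for (k in seq_along(b)) h <- (h * 31 + b[k]) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

meta_header <- function(config, extra = character(0)) {
  c(sprintf("# seed: %d", config$seed),
    sprintf("# config: %s", config_checksum(config)),
    extra)
}

#' Write an observables table as CSV with a traceability header
#'
#' @param df data.frame of per-frame observables.
#' @param path output path.
#' @param config the [run_config()] that produced it.
#' @export
write_observables <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a dense matrix (contact map, free-energy surface) as plain text
#'
#' One `#` header line with the dimensions, then whitespace-separated rows.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param config a [run_config()] for the traceability header.
#' @export
write_matrix_txt <- function(m, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(meta_header(config), con)
  writeLines(sprintf("# matrix %d %d", nrow(m), ncol(m)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write trajectory frames in extended XYZ format
#'
#' Each frame is a standard XYZ block for the polymer (the element column
#' carries the segment-type label, coordinates are unwrapped lattice
#' integers) followed by sparse bulk records: a line `BULK<k> <n>` per
#' species and `n` lines of occupied wrapped sites.  Frames are
#' self-delimiting and re-read by [read_trajectory()].
#'
#' @param run a `prewet_run` with collected frames, or a list of frames.
#' @param path output path.
#' @param config optional [run_config()] for the traceability header.
#' @param type_labels labels per type id (taken from the run when omitted).
#' @export
write_trajectory <- function(run, path, config = NULL, type_labels = NULL) {
  frames <- if (inherits(run, "prewet_run")) run$frames else run
  if (is.null(type_labels) && inherits(run, "prewet_run"))
    type_labels <- run$final$chain$type_labels
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(meta_header(config), con)
  for (f in frames) {
    n <- nrow(f$chain)
    writeLines(as.character(n), con)
    writeLines(sprintf("sweep=%d", f$sweep), con)
    lab <- if (is.null(type_labels)) as.character(f$types)
           else type_labels[f$types]
    writeLines(sprintf("%s %d %d %d", lab, f$chain[, 1], f$chain[, 2],
                       f$chain[, 3]), con)
    for (k in 1:2) {
      b <- f[[paste0("bulk", k)]]
      nb <- if (is.null(b)) 0L else nrow(b)
      writeLines(sprintf("BULK%d %d", k, nb), con)
      if (nb > 0)
        writeLines(sprintf("%d %d %d", b[, 1], b[, 2], b[, 3]), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param type_map named integer vector mapping labels back to type ids;
#'   inferred from the file when omitted.
#' @export
read_trajectory <- function(path, type_map = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  frames <- list()
  i <- 1L
  labels_seen <- character(0)
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    sweep <- as.integer(sub("sweep=", "", lines[i + 1L]))
    atom <- strsplit(lines[(i + 2L):(i + 1L + n)], " ", fixed = TRUE)
    atom <- do.call(rbind, atom)
    lab <- atom[, 1]
    labels_seen <- union(labels_seen, unique(lab))
    chain <- matrix(as.integer(atom[, 2:4]), ncol = 3)
    i <- i + 2L + n
    bulk <- list()
    for (k in 1:2) {
      hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
      nb <- as.integer(hdr[2])
      if (nb > 0) {
        rows <- strsplit(lines[i + seq_len(nb)], " ", fixed = TRUE)
        bulk[[k]] <- matrix(as.integer(do.call(rbind, rows)), ncol = 3)
      } else {
        bulk[[k]] <- matrix(integer(0), ncol = 3)
      }
      i <- i + 1L + nb
    }
    tm <- if (is.null(type_map)) setNames(seq_along(labels_seen), labels_seen)
          else type_map
    frames[[length(frames) + 1L]] <-
      list(sweep = sweep, chain = chain, types = as.integer(tm[lab]),
           bulk1 = bulk[[1]], bulk2 = bulk[[2]])
  }
  frames
}

#' Execute a run configuration
#'
#' Dispatches on `config$mode`, runs the corresponding computation and
#' writes the output bundle into `config$out_dir`: a config echo
#' (`config.yaml`), a log with the seed and acceptance summary, per-frame
#' observables (`observables.csv`), optionally a trajectory
#' (`trajectory.xyz`), a mean-field scan table (`scan.csv`), or an
#' enumeration summary (`enumeration.csv`).  Identical seed and config give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the computed objects and output paths.
#' @export
run <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(config$out_dir, "config.yaml"))
  write_config(config, paths$config)
  out <- list(paths = paths)
  log_lines <- c(sprintf("prewetting run, mode=%s", config$mode),
                 sprintf("seed=%d config=%s", config$seed,
                         config_checksum(config)))

  if (config$mode %in% c("full", "minimal", "polymer")) {
    geometry <- lattice_geometry(config$dims)
    params <- do.call(model_params, config$params)
    chain <- straight_spanning_chain(geometry)
    if (!is.null(config$segments))
      chain <- assign_segments(chain, segment_spec(config$segments$types,
                                                   config$segments$counts,
                                                   config$segments$delta))
    sch <- config$schedule
    runner <- switch(config$mode, polymer = run_polymer,
                     minimal = run_minimal, full = run_full)
    extra <- if (config$mode == "full")
      list(n_reservoir = config$n_reservoir) else list()
    res <- do.call(runner, c(list(geometry, chain, params,
                                  sweeps = sch$sweeps,
                                  equil = if (is.null(sch$equil)) 0
                                          else sch$equil,
                                  meas_every = if (is.null(sch$meas_every)) 1
                                               else sch$meas_every,
                                  seed = config$seed,
                                  collect_frames = config$collect_frames),
                             extra))
    paths$observables <- file.path(config$out_dir, "observables.csv")
    write_observables(res$observables, paths$observables, config)
    if (config$collect_frames) {
      paths$trajectory <- file.path(config$out_dir, "trajectory.xyz")
      write_trajectory(res, paths$trajectory, config)
    }
    acc <- res$acceptance
    log_lines <- c(log_lines, sprintf("acceptance %s: %d/%d (%.3f)",
                                      acc$move, acc$accepted, acc$attempts,
                                      acc$rate))
    out$run <- res
  } else if (config$mode == "meanfield") {
    params <- do.call(mean_field_params, config$meanfield)
    if (!is.null(config$scan)) {
      sc <- config$scan
      values <- seq(sc$from, sc$to, by = sc$step)
      tr <- scan_transition(params, sc$axis, values)
      paths$scan <- file.path(config$out_dir, "scan.csv")
      write_observables(tr$table, paths$scan, config)
      log_lines <- c(log_lines,
                     if (tr$found)
                       sprintf("transition: %s at %s=%.6g", tr$order, sc$axis,
                               tr$location)
                     else "transition: none found in range")
      out$transition <- tr
    } else {
      out$minima <- minimize_fsys(params)
      paths$minima <- file.path(config$out_dir, "minima.csv")
      write_observables(out$minima, paths$minima, config)
    }
  } else if (config$mode == "enumerate") {
    geometry <- lattice_geometry(config$dims)
    params <- do.call(model_params, config$params)
    en <- config$enumerate
    res <- enumerate_pinned_walks(geometry, en$start, en$end, en$n_max,
                                  params)
    paths$enumeration <- file.path(config$out_dir, "enumeration.csv")
    write_observables(as.data.frame(unclass(res)), paths$enumeration, config)
    out$enumeration <- res
  } else if (config$mode == "analyze") {
    geometry <- lattice_geometry(config$dims)
    frames <- read_trajectory(config$trajectory)
    prof <- occupancy_profile(frames, geometry)
    cmap <- contact_map(frames, geometry)
    paths$profile <- file.path(config$out_dir, "occupancy_profile.csv")
    write_observables(prof, paths$profile, config)
    paths$contact_map <- file.path(config$out_dir, "contact_map.txt")
    write_matrix_txt(cmap, paths$contact_map, config)
    out$profile <- prof
    out$contact_map <- cmap
  }

  paths$log <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, paths$log)
  out$paths <- paths
  invisible(out)
}
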