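#' Run configuration for the build / run / analyze pipeline
#'
#' A single YAML file drives all stages.  Top-level keys:
#' \describe{
#'   \item{`params`}{all [ring_params()] fields.}
#'   \item{`schedule`}{list of phases (`phase`, `duration`, `stride`),
#'     see [run_protocol()].}
#'   \item{`analysis`}{`observables` (character vector), `t0`, `q`,
#'     `Delta`, `L_cutoff` (grid), `threading_stride` (frames).}
#'   \item{`seed`}{integer master seed; each stage derives its own.}
#'   \item{`out`}{output directory.}
#' }
#' The MD5 hash of the normalized configuration is embedded in every
#' output; stages refuse to mix files from different configurations.
#'
#' @param path YAML config file.
#' @return list of class `"run_config"` with a `hash` field.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params)) stop("config lacks a 'params' block")
  # YAML 1.1 reads a bare key `N` as boolean; restore the parameter name
  names(cfg$params)[names(cfg$params) == "FALSE"] <- "N"
  cfg$params <- do.call(ring_params, cfg$params)
  cfg$seed <- cfg$seed %||% 1
  cfg$out <- cfg$out %||% "."
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # identify the scientific configuration: output location is not part of it
  norm <- cfg[setdiff(names(cfg), c("hash", "out"))]
  norm$params <- unclass(norm$params)
  yaml::write_yaml(norm, tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(cfg, stage, ...) {
  message(sprintf("[%s] %s %s (config %s, seed %d)",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  paste0(..., collapse = " "), substr(cfg$hash, 1, 8),
                  cfg$seed))
}

write_meta <- function(cfg, path, stage, extra = list()) {
  meta <- c(list(stage = stage, config_hash = cfg$hash, seed = cfg$seed,
                 package = as.character(utils::packageVersion("ringmelt")),
                 created = format(Sys.time())), extra)
  yaml::write_yaml(meta, path)
}

check_meta <- function(cfg, path) {
  if (!file.exists(path)) stop("missing provenance file: ", path)
  meta <- yaml::read_yaml(path)
  if (!identical(meta$config_hash, cfg$hash))
    stop("refusing to mix outputs: file was produced under config hash ",
         meta$config_hash, ", current config is ", cfg$hash)
  meta
}

#' Pipeline stages: build, run, analyze
#'
#' `cmd_build()` constructs the initial melt (with activity labels),
#' writes it as a LAMMPS data file plus a tab-separated topology report.
#' `cmd_run()` executes the configured schedule and writes the trajectory
#' as LAMMPS dump text with a provenance sidecar.  `cmd_analyze()` reads
#' the trajectory back and emits the requested observable series as
#' tab-separated files plus a machine-readable JSON summary.  All stages
#' are deterministic given the config seed, and every output embeds the
#' config hash.
#'
#' @param cfg a [read_config()] object.
#' @return `cmd_build`: path of the data file; `cmd_run`: path of the dump
#'   file; `cmd_analyze`: path of the JSON summary (invisibly).
#' @export
cmd_build <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  stage_log(cfg, "build", sprintf("M=%d N=%d", cfg$params$M, cfg$params$N))
  st <- build_melt(cfg$params, seed = derive_seed(cfg$seed, 1),
                   pushoff_steps = cfg$pushoff_steps %||% 3000,
                   equil_steps = cfg$equil_steps %||% 5000)
  st <- assign_activity(st, seed = derive_seed(cfg$seed, 2))
  rep <- verify_topology(st, knot_screen = isTRUE(cfg$knot_screen))
  data_path <- file.path(cfg$out, "init.data")
  write_lammps_data(st, data_path)
  tr <- data.frame(pair_i = rep(seq_len(cfg$params$M), cfg$params$M),
                   pair_j = rep(seq_len(cfg$params$M),
                                each = cfg$params$M),
                   linking = as.vector(rep$linking))
  utils::write.table(tr[tr$pair_i < tr$pair_j, ],
                     file.path(cfg$out, "topology.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_meta(cfg, file.path(cfg$out, "init.meta.yaml"), "build",
             list(topology_pass = rep$pass))
  if (!rep$pass) stop("topology verification failed after build")
  stage_log(cfg, "build", "done; topology PASS")
  invisible(data_path)
}

#' @param state_path LAMMPS data file from [cmd_build()] (default
#'   `init.data` under the config output directory).
#' @rdname cmd_build
#' @export
cmd_run <- function(cfg, state_path = file.path(cfg$out, "init.data")) {
  check_meta(cfg, sub("\\.data$", ".meta.yaml", state_path))
  st <- read_lammps_data(state_path, cfg$params)
  stage_log(cfg, "run", sprintf("%d phases", length(cfg$schedule)))
  traj <- run_protocol(st, cfg$schedule, seed = derive_seed(cfg$seed, 3))
  dump_path <- file.path(cfg$out, "traj.dump")
  write_lammps_dump(traj, dump_path)
  write_meta(cfg, file.path(cfg$out, "traj.meta.yaml"), "run",
             list(n_frames = dim(traj$pos)[1],
                  kinetic_T = as.list(kinetic_temperatures(traj))))
  stage_log(cfg, "run", "done")
  invisible(dump_path)
}

#' @param traj_path LAMMPS dump file from [cmd_run()].
#' @param t0 measurement origin (tau); default first frame.
#' @rdname cmd_build
#' @export
cmd_analyze <- function(cfg, traj_path = file.path(cfg$out, "traj.dump"),
                        t0 = NULL) {
  check_meta(cfg, sub("\\.dump$", ".meta.yaml", traj_path))
  traj <- read_lammps_dump(traj_path, cfg$params)
  an <- cfg$analysis %||% list()
  obs <- an$observables %||% c("g3")
  t0 <- t0 %||% an$t0 %||% traj$times[1]
  summary <- list(config_hash = cfg$hash, t0 = t0)
  put <- function(df, name) {
    p <- file.path(cfg$out, paste0(name, ".tsv"))
    con <- file(p, "w")
    writeLines(sprintf("# observable: %s  t0: %g  config: %s",
                       name, t0, cfg$hash), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  for (o in obs) {
    res <- tryCatch(switch(o,
      g3 = {
        srs <- g3(traj, t0)
        fit <- fit_power_law(srs$t, srs$g3,
                             window = an$g3_fit_window %||% range(srs$t[-1]))
        summary$g3_exponent <- fit$exponent
        summary$g3_exponent_se <- fit$se
        put(srs, "g3")
      },
      isf = {
        srs <- self_isf(traj, an$q %||% 0.35, t0)
        summary$f_q <- srs$Fs[nrow(srs)]
        put(srs, "isf")
      },
      eb = {
        srs <- ergodicity_breaking(traj, an$Delta %||%
                                     diff(traj$times[1:2]), t0)
        put(srs, "eb")
      },
      internal_distances = {
        sts <- lapply(seq_len(dim(traj$pos)[1]), function(f)
          traj_frame_state(traj, f))
        srs <- internal_distances(sts, block = an$block %||% "all",
                                  fit_window = an$s_fit_window %||% c(10, 100))
        summary$nu <- attr(srs, "nu")
        summary$nu_se <- attr(srs, "nu_se")
        put(srs, "internal_distances")
      },
      threading = {
        stride <- an$threading_stride %||% 1
        fidx <- seq(1, dim(traj$pos)[1], by = stride)
        series <- list(); tables <- list()
        for (f in fidx) {
          tb <- analyze_threading(traj_frame_state(traj, f))
          tables[[length(tables) + 1]] <- tb
          series[[length(series) + 1]] <- pair_keys(tb)
        }
        all_tb <- do.call(rbind, lapply(tables, as.data.frame))
        put(all_tb, "threading")
        M <- max(traj$ring)
        summary$n_tn <- mean(vapply(series, length, numeric(1))) / M
        cuts <- an$L_cutoff %||% c(1, 5, 10)
        last <- tables[[length(tables)]]
        summary$biggest_cluster <- vapply(cuts, function(lc)
          threading_clusters(last, lc, M = M)$biggest, numeric(1))
        if (length(series) > 1) {
          phi <- threading_correlation(series, 1)
          if (!is.null(phi)) put(phi, "threading_phi")
          surv <- survival_distribution(series, 1)
          if (!is.null(surv)) put(surv, "threading_survival")
        }
      },
      stop("unknown observable: ", o)), error = function(e) {
        warning(sprintf("analysis '%s' failed: %s", o, conditionMessage(e)))
        summary$errors <<- c(summary$errors, stats::setNames(
          conditionMessage(e), o))
      })
  }
  sp <- file.path(cfg$out, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stage_log(cfg, "analyze", "done")
  invisible(sp)
}
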